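# Shared fixtures, memoized per test run so expensive featurization and
# generation happen once.

fixture <- local({
  cache <- new.env(parent = emptyenv())
  function(name, producer) {
    if (!exists(name, envir = cache)) assign(name, producer(), envir = cache)
    get(name, envir = cache)
  }
})

# small labeled library shared by several files
small_library <- function() fixture("small_library", function() {
  spec <- synthesis_spec(n_molecules = 60L, seed = 101L,
                         label_rule = "substructure_class")
  gen_labels(gen_molecules(spec), spec)
})

# the substructure-classification study set (held-out learning checks)
study_table <- function() fixture("study_table", function() {
  spec <- synthesis_spec(n_molecules = 2000L, seed = 7L,
                         label_rule = "substructure_class")
  gen_labels(gen_molecules(spec), spec)
})

study_features <- function() fixture("study_features", function() {
  view_features(study_table(), multiview_config())
})

study_scaffolds <- function() fixture("study_scaffolds", function() {
  scaffold_keys(study_table()$records$canonical_smiles)
})

# seeded Erdos-Renyi style random graph (igraph), possibly disconnected
random_graph <- function(seed, max_nodes = 20L) {
  set.seed(seed)
  n <- sample(2:max_nodes, 1L)
  m <- sample(0:min(2L * n, n * (n - 1L) / 2L), 1L)
  igraph::sample_gnm(n, m)
}

# independent cycle-rank oracle: edges left over after removing a spanning
# forest
cycle_rank_oracle <- function(g) {
  igraph::ecount(g) - igraph::ecount(igraph::mst(g))
}

# zero-eigenvalue multiplicity of the graph Laplacian
laplacian_zero_multiplicity <- function(g, tol = 1e-8) {
  n <- igraph::vcount(g)
  if (n == 0L) return(0L)
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  L <- diag(igraph::degree(g), n) - A
  sum(abs(eigen(L, symmetric = TRUE, only.values = TRUE)$values) < tol)
}

# synthetic graph_view wrapper around an igraph (dummy chemistry features)
make_graph_view <- function(g) {
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g)
  m <- nrow(el)
  structure(list(
    n_nodes = n, n_edges = m,
    edges = data.frame(from = el[, 1], to = el[, 2]),
    node_features = data.frame(
      atomic_number = rep(6, n), chirality = rep("none", n),
      degree = igraph::degree(g), formal_charge = rep(0L, n),
      hybridization = rep("sp3", n), stringsAsFactors = FALSE),
    edge_features = data.frame(
      bond_type = rep("single", m), bond_dir = rep("none", m),
      stereo = rep("none", m), conjugated = rep(FALSE, m),
      in_ring = rep(FALSE, m), stringsAsFactors = FALSE),
    token_kind = c(rep("node", n), rep("edge", m)),
    laplacian_eigenvalues = NULL, laplacian_eigenvectors = NULL,
    pe_k = NULL, smiles = NA_character_), class = "graph_view")
}

# apply a node permutation to a graph view (features, edges, eigenvectors)
permute_graph_view <- function(view, perm) {
  inv <- order(perm)
  out <- view
  out$node_features <- view$node_features[perm, , drop = FALSE]
  out$edges <- data.frame(from = inv[view$edges$from],
                          to = inv[view$edges$to])
  if (!is.null(view$laplacian_eigenvectors)) {
    out$laplacian_eigenvectors <-
      view$laplacian_eigenvectors[perm, , drop = FALSE]
  }
  out
}

# independent arithmetic evaluation of the batch gate (plain loops)
gate_oracle <- function(Z, q, W, b) {
  M <- length(Z)
  w <- numeric(M)
  for (m in seq_len(M)) {
    s <- 0
    for (i in seq_len(nrow(Z[[m]]))) {
      z <- Z[[m]][i, ]
      u <- tanh(W %*% (z / sqrt(sum(z^2))) + b)
      s <- s + sum(q * u)
    }
    w[m] <- s / nrow(Z[[m]])
  }
  e <- exp(w - max(w))
  list(w = w, alpha = e / sum(e))
}
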