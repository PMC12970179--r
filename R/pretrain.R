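# Self-supervised target generators: token masking, graph feature masking,
# edge corruption, and per-node Betti-number topology targets.

#' Masked-language-model masking plan for a token sequence
#'
#' Selects a uniformly random set of round(rate * n) maskable positions
#' (reserved special tokens are never masked), reproducible from the seed.
#' The count rounding is half-away-from-zero.
#'
#' @param view a \code{text_view}.
#' @param rate masking fraction in [0, 1] (default 0.15).
#' @param seed integer seed.
#' @return object of class \code{masking_plan}: \code{positions},
#'   \code{rate}, \code{seed}, \code{n_tokens}, \code{n_maskable}.
#' @export
mlm_mask <- function(view, rate = 0.15, seed = 1L) {
  stopifnot(inherits(view, "text_view"), rate >= 0, rate <= 1)
  maskable <- which(!(view$tokens %in% special_tokens))
  n_mask <- round_half_away(rate * length(maskable))
  positions <- if (n_mask > 0L) {
    sort(with_seed(seed, sample(maskable, n_mask)))
  } else integer(0)
  structure(list(positions = positions, rate = rate, seed = seed,
                 n_tokens = length(view$tokens),
                 n_maskable = length(maskable)),
            class = "masking_plan")
}

#' Graph feature-masking plan over node and edge tokens jointly
#'
#' Masks the features of round(rate * (|V| + |E|)) tokens drawn uniformly
#' over atoms and bonds together (default rate 0.85). Masked features are
#' replaced with a sentinel category downstream; the plan only records
#' positions.
#'
#' @param view a \code{graph_view}.
#' @param rate masking fraction (default 0.85).
#' @param seed integer seed.
#' @return a \code{masking_plan} over token positions 1..(|V|+|E|)
#'   (nodes first, then edges).
#' @export
mask_graph_features <- function(view, rate = 0.85, seed = 1L) {
  stopifnot(inherits(view, "graph_view"), rate >= 0, rate <= 1)
  n <- view$n_nodes + view$n_edges
  if (n == 0L) stop("token sequence is empty")
  n_mask <- round_half_away(rate * n)
  positions <- if (n_mask > 0L) sort(with_seed(seed, sample.int(n, n_mask)))
  else integer(0)
  structure(list(positions = positions, rate = rate, seed = seed,
                 n_tokens = n, n_maskable = n),
            class = "masking_plan")
}

#' Edge-corruption plan for a molecular graph
#'
#' Selects round(rate * |E|) edges (default rate 0.15) and rewires one
#' endpoint of each to a uniformly chosen different node, keeping the bond
#' feature vector unchanged. Emits a per-edge binary label (1 = corrupted).
#'
#' @param view a \code{graph_view}.
#' @param rate corruption fraction (default 0.15).
#' @param seed integer seed.
#' @return object of class \code{edge_corruption_plan}:
#'   \code{corrupted_edges}, \code{replacements} (edge, endpoint slot, new
#'   node), \code{labels}, \code{rate}, \code{seed}.
#' @export
corrupt_edges <- function(view, rate = 0.15, seed = 1L) {
  stopifnot(inherits(view, "graph_view"), rate >= 0, rate <= 1)
  m <- view$n_edges; n <- view$n_nodes
  labels <- integer(m)
  empty <- data.frame(edge = integer(0), endpoint = integer(0),
                      new_node = integer(0))
  if (n < 2L || m == 0L) {
    return(structure(list(corrupted_edges = integer(0), replacements = empty,
                          labels = labels, rate = rate, seed = seed),
                     class = "edge_corruption_plan"))
  }
  n_cor <- round_half_away(rate * m)
  plan <- with_seed(seed, {
    sel <- if (n_cor > 0L) sort(sample.int(m, n_cor)) else integer(0)
    reps <- empty
    for (e in sel) {
      u <- view$edges$from[e]; v <- view$edges$to[e]
      cand <- setdiff(seq_len(n), c(u, v))
      if (length(cand) == 0L) next       # 2-node graph: no valid rewiring
      slot <- sample(1:2, 1L)
      new_node <- cand[sample.int(length(cand), 1L)]
      reps <- rbind(reps, data.frame(edge = e, endpoint = slot,
                                     new_node = new_node))
    }
    list(sel = sel, reps = reps)
  })
  labels[plan$reps$edge] <- 1L
  structure(list(corrupted_edges = plan$reps$edge, replacements = plan$reps,
                 labels = labels, rate = rate, seed = seed),
            class = "edge_corruption_plan")
}

# graph_view -> igraph
graph_view_igraph <- function(view) {
  g <- igraph::make_empty_graph(n = view$n_nodes, directed = FALSE)
  if (view$n_edges > 0L) {
    g <- igraph::add_edges(g, rbind(view$edges$from, view$edges$to))
  }
  g
}

#' Betti numbers of a whole graph
#'
#' beta0 = number of connected components; beta1 = cycle rank
#' |E| - |V| + beta0.
#'
#' @param g an igraph object.
#' @return named numeric vector \code{c(b0, b1)}.
#' @export
graph_betti <- function(g) {
  b0 <- igraph::components(g)$no
  c(b0 = b0, b1 = igraph::ecount(g) - igraph::vcount(g) + b0)
}

#' Per-node Betti-number targets
#'
#' For every node v, extracts the induced subgraph on all nodes within
#' \code{radius} hops of v and records (beta0, beta1) of that subgraph:
#' beta0 counts connected components, beta1 = |E| - |V| + beta0 counts
#' independent cycles. These local topological invariants serve as
#' self-supervision targets.
#'
#' @param view a \code{graph_view} or an igraph object.
#' @param radius neighborhood radius in hops (default 2).
#' @param max_class optional cap applied by \code{\link{betti_class_labels}}.
#' @return object of class \code{betti_targets}: data.frame
#'   (\code{node}, \code{b0}, \code{b1}) plus \code{radius}.
#' @export
betti_targets <- function(view, radius = 2L, max_class = 8L) {
  stopifnot(radius >= 1L)
  g <- if (inherits(view, "graph_view")) graph_view_igraph(view) else view
  n <- igraph::vcount(g)
  hoods <- igraph::ego(g, order = radius, nodes = seq_len(n))
  b0 <- b1 <- integer(n)
  for (v in seq_len(n)) {
    sub <- igraph::induced_subgraph(g, hoods[[v]])
    bb <- graph_betti(sub)
    b0[v] <- bb[["b0"]]; b1[v] <- bb[["b1"]]
  }
  structure(list(targets = data.frame(node = seq_len(n), b0 = b0, b1 = b1),
                 radius = radius, max_class = max_class),
            class = "betti_targets")
}

#' Clip Betti targets into classification labels
#'
#' Raw values are retained in the target object; this accessor returns
#' labels clipped at \code{max_class} for use as class targets.
#'
#' @param targets a \code{betti_targets} object.
#' @return data.frame with clipped \code{b0}, \code{b1}.
#' @export
betti_class_labels <- function(targets) {
  mx <- targets$max_class
  data.frame(node = targets$targets$node,
             b0 = pmin(targets$targets$b0, mx),
             b1 = pmin(targets$targets$b1, mx))
}
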