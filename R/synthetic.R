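# Deterministic synthetic molecule libraries, labeled tasks, and protein
# embeddings: the no-download test surface for every other module.

#' Default scaffold templates
#'
#' Twelve ring-system templates with distinct Murcko frameworks; \code{{R}}
#' marks the substitution site. The special pool \code{"acyclic"} switches
#' the generator to chain molecules (empty scaffolds, one singleton cluster
#' per unique molecule).
#' @export
default_scaffolds <- function() c(
  benzene      = "c1ccc({R})cc1",
  pyridine     = "c1ccc({R})nc1",
  diazine      = "c1ncc({R})cn1",
  furan        = "c1cc({R})oc1",
  thiophene    = "c1cc({R})sc1",
  pyrrole      = "c1cc({R})[nH]c1",
  naphthalene  = "c1ccc2cc({R})ccc2c1",
  indole       = "c1ccc2[nH]c({R})cc2c1",
  cyclohexane  = "C1CCC({R})CC1",
  piperidine   = "C1CCC({R})NC1",
  biphenyl     = "c1ccc(-c2ccc({R})cc2)cc1",
  quinoline    = "c1ccc2nc({R})ccc2c1")

#' Default substituent fragments
#'
#' Common organic substituents, written attachment-atom-first. The nitro
#' fragment is excluded: it is introduced only by the label rule's
#' controlled positive-rate draw, so substructure classes stay clean.
#' @export
default_substituents <- function() c(
  "C", "CC", "CCC", "C(C)C", "CCCC", "O", "OC", "OCC", "N", "NC", "N(C)C",
  "F", "Cl", "Br", "C#N", "C(F)(F)F", "CO", "CCO", "C(=O)O", "C(=O)OC",
  "CC=C", "S", "SC", "CN", "CCN", "C(=O)N")

.linker_units <- c("C", "CC", "CCC", "CC(C)", "C(C)C", "CCCC")

#' Nitro group fragment used by the default substructure label rule
#' @export
nitro_fragment <- "[N+](=O)[O-]"

#' Specification for a synthetic molecule library
#'
#' @param n_molecules number of unique molecules to generate.
#' @param scaffold_pool named character vector of templates with an
#'   \code{{R}} site, or \code{"acyclic"} for chain molecules.
#' @param substituent_pool character vector of attachment-first fragments.
#' @param seed integer seed; the same spec always yields the same table.
#' @param label_rule \code{"substructure_class"},
#'   \code{"descriptor_regression"} or \code{"latent_affinity"}.
#' @param noise_sd Gaussian label noise (regression/affinity rules).
#' @param positive_rate fraction of molecules carrying the marker fragment
#'   under the substructure rule.
#' @param fragment marker fragment SMILES for the substructure rule.
#' @return object of class \code{synthesis_spec}.
#' @export
synthesis_spec <- function(n_molecules = 100L,
                           scaffold_pool = default_scaffolds(),
                           substituent_pool = default_substituents(),
                           seed = 1L,
                           label_rule = c("substructure_class",
                                          "descriptor_regression",
                                          "latent_affinity"),
                           noise_sd = 0.1,
                           positive_rate = 0.4,
                           fragment = nitro_fragment) {
  label_rule <- match.arg(label_rule)
  stopifnot(n_molecules >= 1L, length(scaffold_pool) >= 1L,
            length(substituent_pool) >= 1L)
  structure(list(n_molecules = as.integer(n_molecules),
                 scaffold_pool = scaffold_pool,
                 substituent_pool = substituent_pool,
                 seed = as.integer(seed), label_rule = label_rule,
                 noise_sd = noise_sd, positive_rate = positive_rate,
                 fragment = fragment),
            class = "synthesis_spec")
}

# one substituent string: 0-3 linker units then a terminal fragment; with
# probability `p_marker` the marker fragment is grafted as a branch on an
# extra carbon, so marker-bearing molecules span the full chain x terminal
# space and the positive rate stays controllable at large n
.draw_substituent <- function(pool, p_marker, fragment) {
  depth <- sample(0:3, 1L, prob = c(0.35, 0.3, 0.2, 0.15))
  chain <- if (depth > 0L)
    paste(sample(.linker_units, depth, replace = TRUE), collapse = "") else ""
  term <- pool[sample.int(length(pool), 1L)]
  if (stats::runif(1) < p_marker) {
    paste0(chain, "C(", fragment, ")", term)
  } else {
    paste0(chain, term)
  }
}

.draw_acyclic <- function() {
  k <- sample(3:12, 1L)
  units <- character(k)
  last_hetero <- TRUE                     # force a carbon start
  for (j in seq_len(k)) {
    u <- if (last_hetero) sample(c("C", "CC", "CCC"), 1L)
    else sample(c("C", "CC", "CCC", "O", "N"), 1L,
                prob = c(0.3, 0.2, 0.2, 0.15, 0.15))
    last_hetero <- u %in% c("O", "N")
    units[j] <- u
  }
  if (last_hetero) units <- c(units, "C")
  paste(units, collapse = "")
}

#' Generate a synthetic molecule library
#'
#' Enumerates scaffold x substituent combinations (round-robin over the
#' scaffold pool, so each template appears when n allows), canonicalizes,
#' and keeps the first \code{n_molecules} unique molecules. Every output
#' parses; with a pool of k templates and n >= k the table carries at least
#' k distinct Murcko scaffold keys.
#'
#' @param spec a \code{synthesis_spec}.
#' @return a \code{dataset_table} (no labels yet); the per-molecule marker
#'   indicator drawn during generation is kept as attribute
#'   \code{"marker_drawn"} for bookkeeping.
#' @export
gen_molecules <- function(spec) {
  stopifnot(inherits(spec, "synthesis_spec"))
  acyclic <- identical(unname(spec$scaffold_pool), "acyclic")
  n <- spec$n_molecules
  p_marker <- if (spec$label_rule == "substructure_class")
    spec$positive_rate else 0
  smis <- character(0)
  with_seed(spec$seed, {
    tries <- 0L
    while (length(smis) < n) {
      batch <- max(64L, ceiling((n - length(smis)) * 1.6))
      cand <- character(batch)
      for (b in seq_len(batch)) {
        if (acyclic) {
          cand[b] <- .draw_acyclic()
        } else {
          tpl_i <- (length(smis) + b - 1L) %% length(spec$scaffold_pool) + 1L
          sub <- .draw_substituent(spec$substituent_pool, p_marker,
                                   spec$fragment)
          cand[b] <- sub("{R}", sub, spec$scaffold_pool[[tpl_i]],
                         fixed = TRUE)
        }
      }
      can <- canonicalize_smiles(cand)
      can <- can[!is.na(can)]
      smis <- c(smis, setdiff(unique(can), smis))
      tries <- tries + 1L
      if (tries > 200L) {
        stop("combinatorial pool too small for ", n, " unique molecules")
      }
    }
  })
  smis <- smis[seq_len(n)]
  parsed <- parse_records(smis)
  if (parsed$n_dropped > 0L) {
    stop("generator produced unparseable SMILES; pool definitions invalid")
  }
  tab <- dataset_table(parsed$records,
                       task_kind = if (spec$label_rule ==
                                         "substructure_class")
                         "classification" else "regression",
                       name = if (acyclic) "synthetic_acyclic"
                       else "synthetic_library")
  tab
}

# atom-composition summary used by affinity labels
.composition <- function(smiles) {
  mols <- parse_mol_graph(smiles)
  t(vapply(mols, function(m) {
    el <- m$atoms$element
    n <- max(1L, length(el))
    c(frac_n = sum(el == "N") / n, frac_o = sum(el == "O") / n,
      frac_arom = sum(m$atoms$aromatic |
                        seq_along(el) %in%
                        c(m$bonds$from[m$bonds$type == "ar"],
                          m$bonds$to[m$bonds$type == "ar"])) / n)
  }, c(frac_n = 0, frac_o = 0, frac_arom = 0)))
}

#' Substructure test via colored subgraph matching
#'
#' Monomorphism search (igraph LAD with per-vertex domains) on the
#' heavy-atom graph; pattern and target atoms match when element and formal
#' charge agree. Bond orders are not compared.
#'
#' @param smiles character vector of target SMILES.
#' @param fragment pattern SMILES.
#' @return logical vector.
#' @export
has_substructure <- function(smiles, fragment = nitro_fragment) {
  pat <- parse_mol_graph(fragment)[[1L]]
  if (is.null(pat)) stop_invalid_molecule(fragment)
  pg <- mol_to_igraph(pat)
  pcol <- paste(pat$atoms$element, pat$atoms$charge)
  mols <- parse_mol_graph(smiles)
  vapply(mols, function(m) {
    if (is.null(m) || m$n_atoms < pat$n_atoms) return(FALSE)
    tcol <- paste(m$atoms$element, m$atoms$charge)
    domains <- lapply(pcol, function(cc) which(tcol == cc))
    if (any(lengths(domains) == 0L)) return(FALSE)
    tg <- mol_to_igraph(m)
    igraph::subgraph_isomorphic(pg, tg, method = "lad", induced = FALSE,
                                domains = domains)
  }, TRUE)
}

#' Attach synthetic labels to a molecule table
#'
#' \describe{
#'   \item{substructure_class}{binary: the molecule contains the marker
#'     fragment (computed structurally via \code{\link{has_substructure}}).}
#'   \item{descriptor_regression}{label = 0.02 * MW + 0.6 * logP +
#'     N(0, noise_sd); exact function of the descriptors when noise_sd = 0.}
#'   \item{latent_affinity}{pKI-like values in [4, 10] driven by marker
#'     presence, heteroatom fractions and aromaticity, plus noise.}
#' }
#'
#' @param table a \code{dataset_table} from \code{\link{gen_molecules}}.
#' @param spec the same \code{synthesis_spec}.
#' @return the table with labels (and \code{task_kind}) set; degenerate
#'   single-class substructure labels are flagged with a warning and
#'   attribute \code{"degenerate"}.
#' @export
gen_labels <- function(table, spec) {
  stopifnot(inherits(table, "dataset_table"), inherits(spec, "synthesis_spec"))
  rec <- table$records
  if (spec$label_rule == "substructure_class") {
    lab <- as.numeric(has_substructure(rec$canonical_smiles, spec$fragment))
    out <- dataset_table(rec, lab, "classification", table$name,
                         table$n_dropped)
    if (length(unique(lab)) < 2L) {
      warning("degenerate substructure labels: single class")
      attr(out, "degenerate") <- TRUE
    }
    return(out)
  }
  noise <- with_seed(spec$seed + 1L,
                     stats::rnorm(nrow(rec), sd = spec$noise_sd))
  if (spec$label_rule == "descriptor_regression") {
    lab <- 0.02 * rec$mol_weight + 0.6 * rec$logp + noise
    return(dataset_table(rec, lab, "regression", table$name, table$n_dropped))
  }
  comp <- .composition(rec$canonical_smiles)
  marker <- as.numeric(has_substructure(rec$canonical_smiles, spec$fragment))
  raw <- 4.5 + 2.5 * marker + 4 * comp[, "frac_n"] + 3 * comp[, "frac_o"] +
    1.2 * comp[, "frac_arom"] + noise
  lab <- pmin(pmax(raw, 4), 10)
  dataset_table(rec, lab, "regression", table$name, table$n_dropped)
}

#' Generate reproducible synthetic protein embeddings
#'
#' Gaussian embedding vectors, optionally with low-rank latent structure
#' (embeddings = U V with U of the requested rank) for affinity-recovery
#' experiments.
#'
#' @param n_proteins number of proteins.
#' @param dim embedding dimension.
#' @param seed integer seed.
#' @param rank optional latent rank.
#' @return matrix (n_proteins x dim) with rownames \code{prot_i}; the
#'   latent factors, when used, are kept in attribute \code{"latent"}.
#' @export
gen_protein_embeddings <- function(n_proteins, dim, seed = 1L, rank = NULL) {
  stopifnot(n_proteins >= 1L, dim >= 1L)
  with_seed(seed, {
    if (is.null(rank)) {
      m <- matrix(stats::rnorm(n_proteins * dim), n_proteins, dim)
    } else {
      U <- matrix(stats::rnorm(n_proteins * rank), n_proteins, rank)
      V <- matrix(stats::rnorm(rank * dim), rank, dim)
      m <- U %*% V
      attr(m, "latent") <- U
    }
    rownames(m) <- paste0("prot_", seq_len(n_proteins))
    m
  })
}
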