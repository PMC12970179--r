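# Open Babel backend: batch SMILES conversion and MOL2 graph extraction.
#
# Open Babel stops a multi-molecule conversion at the first unparseable
# entry, so every batch call runs under a resume-on-failure loop that maps
# each input row to its output (or NA) by a numeric title.

#' @importFrom ChemmineOB convertFormat
NULL

.ob_gen2d <- data.frame(names = "gen2D", args = "")
.ob_noopts <- data.frame(names = character(0), args = character(0))

# Convert a character vector of SMILES to `to` ("CAN" or "MOL2"), returning a
# list with $chunks (per-input output text or NA) split per molecule.
ob_convert_batch <- function(smiles, to = c("CAN", "MOL2"), gen2d = FALSE) {
  to <- match.arg(to)
  n <- length(smiles)
  out <- vector("list", n)
  todo <- which(!is.na(smiles) & nzchar(smiles))
  opts <- if (gen2d) .ob_gen2d else .ob_noopts
  while (length(todo) > 0L) {
    inp <- paste0(smiles[todo], " ", todo, collapse = "\n")
    txt <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", to, inp, options = opts)),
      error = function(e) ""
    )
    parsed <- if (to == "CAN") .split_can(txt) else .split_mol2(txt)
    done <- parsed$idx
    if (length(done) > 0L) out[done] <- parsed$chunks
    # outputs are a prefix of `todo`; the entry after the last success failed
    n_ok <- length(done)
    if (n_ok + 1L <= length(todo)) {
      todo <- todo[seq.int(n_ok + 2L, length.out = max(0L, length(todo) - n_ok - 1L))]
    } else {
      todo <- integer(0)
    }
  }
  out
}

.split_can <- function(txt) {
  if (!nzchar(txt)) return(list(idx = integer(0), chunks = list()))
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(list(idx = integer(0), chunks = list()))
  parts <- strsplit(lines, "[ \t]+")
  idx <- as.integer(vapply(parts, function(p) p[length(p)], ""))
  smi <- vapply(parts, `[[`, "", 1L)
  list(idx = idx, chunks = as.list(smi))
}

.split_mol2 <- function(txt) {
  if (!nzchar(txt)) return(list(idx = integer(0), chunks = list()))
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  starts <- which(lines == "@<TRIPOS>MOLECULE")
  if (length(starts) == 0L) return(list(idx = integer(0), chunks = list()))
  ends <- c(starts[-1] - 1L, length(lines))
  idx <- suppressWarnings(as.integer(trimws(lines[starts + 1L])))
  keep <- !is.na(idx)
  chunks <- Map(function(s, e) lines[s:e], starts[keep], ends[keep])
  list(idx = idx[keep], chunks = chunks)
}

#' Canonicalize SMILES strings
#'
#' Batch canonicalization through Open Babel. Unparseable entries yield
#' \code{NA}; multi-fragment inputs stay multi-fragment (dot-separated).
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, \code{NA} where parsing failed.
#' @export
canonicalize_smiles <- function(smiles) {
  res <- ob_convert_batch(as.character(smiles), "CAN")
  vapply(res, function(x) if (is.null(x)) NA_character_ else x, "")
}

# Parse MOL2 blocks (lists of lines) into mol_graph objects. Explicit
# hydrogens (rare in SMILES-sourced MOL2) are dropped; the graph is the
# heavy-atom skeleton. Returns NULL for NULL input chunks.
.parse_mol2_block <- function(block, smiles = NA_character_) {
  counts <- strsplit(trimws(block[3L]), "\\s+")[[1]]
  n_atoms <- as.integer(counts[1L])
  n_bonds <- as.integer(counts[2L])
  a0 <- which(block == "@<TRIPOS>ATOM")[1L]
  atom_lines <- if (n_atoms > 0L) block[(a0 + 1L):(a0 + n_atoms)] else character(0)
  ap <- strsplit(trimws(atom_lines), "\\s+")
  type <- vapply(ap, `[[`, "", 6L)
  element <- sub("\\..*$", "", type)
  suffix <- ifelse(grepl(".", type, fixed = TRUE), sub("^[^.]*\\.", "", type), "")
  x <- as.numeric(vapply(ap, `[[`, "", 3L))
  y <- as.numeric(vapply(ap, `[[`, "", 4L))
  charge <- integer(n_atoms)
  u0 <- which(block == "@<TRIPOS>UNITY_ATOM_ATTR")
  if (length(u0) == 1L) {
    b0 <- which(block == "@<TRIPOS>BOND")[1L]
    attr_lines <- block[(u0 + 1L):(b0 - 1L)]
    i <- 1L
    while (i <= length(attr_lines)) {
      hdr <- strsplit(trimws(attr_lines[i]), "\\s+")[[1]]
      aid <- as.integer(hdr[1L]); nat <- as.integer(hdr[2L])
      for (k in seq_len(nat)) {
        kv <- strsplit(trimws(attr_lines[i + k]), "\\s+")[[1]]
        if (kv[1L] == "charge") charge[aid] <- as.integer(kv[2L])
      }
      i <- i + 1L + nat
    }
  }
  b0 <- which(block == "@<TRIPOS>BOND")[1L]
  if (!is.na(b0) && n_bonds > 0L) {
    bond_lines <- block[(b0 + 1L):(b0 + n_bonds)]
    bp <- strsplit(trimws(bond_lines), "\\s+")
    from <- as.integer(vapply(bp, `[[`, "", 2L))
    to <- as.integer(vapply(bp, `[[`, "", 3L))
    btype <- vapply(bp, `[[`, "", 4L)
  } else {
    from <- to <- integer(0); btype <- character(0)
  }
  heavy <- element != "H"
  n_h <- integer(n_atoms)
  if (any(!heavy)) {
    h_ids <- which(!heavy)
    for (k in seq_along(from)) {
      if (from[k] %in% h_ids && !(to[k] %in% h_ids)) n_h[to[k]] <- n_h[to[k]] + 1L
      if (to[k] %in% h_ids && !(from[k] %in% h_ids)) n_h[from[k]] <- n_h[from[k]] + 1L
    }
    remap <- cumsum(heavy)
    keep_b <- heavy[from] & heavy[to]
    from <- remap[from[keep_b]]; to <- remap[to[keep_b]]; btype <- btype[keep_b]
    element <- element[heavy]; suffix <- suffix[heavy]
    x <- x[heavy]; y <- y[heavy]; charge <- charge[heavy]; n_h <- n_h[heavy]
  }
  hyb <- rep("other", length(element))
  hyb[suffix == "1"] <- "sp"
  hyb[suffix %in% c("2", "ar", "pl3", "am", "co2", "cat")] <- "sp2"
  hyb[suffix %in% c("3", "4", "t3h", "o", "o2", "")] <- ifelse(
    element[suffix %in% c("3", "4", "t3h", "o", "o2", "")] %in% c("F", "Cl", "Br", "I"),
    "other", "sp3")
  structure(list(
    n_atoms = length(element),
    atoms = data.frame(element = element, hyb = hyb, charge = charge,
                       aromatic = suffix == "ar", x = x, y = y,
                       stringsAsFactors = FALSE),
    bonds = data.frame(from = from, to = to, type = btype,
                       stringsAsFactors = FALSE),
    smiles = smiles
  ), class = "mol_graph")
}

#' Parse SMILES into heavy-atom molecular graphs
#'
#' Returns one \code{mol_graph} per input: atoms (element, hybridization,
#' formal charge, aromatic flag, 2D coordinates when \code{coords = TRUE})
#' and bonds (endpoint indices plus Open Babel bond type \code{"1"},
#' \code{"2"}, \code{"3"}, \code{"ar"} or \code{"am"}).
#'
#' @param smiles character vector of SMILES.
#' @param coords generate 2D depiction coordinates (slower; needed for
#'   image rendering only).
#' @return list of \code{mol_graph} objects, \code{NULL} where parsing failed.
#' @export
parse_mol_graph <- function(smiles, coords = FALSE) {
  chunks <- ob_convert_batch(as.character(smiles), "MOL2", gen2d = coords)
  out <- vector("list", length(smiles))
  for (i in seq_along(chunks)) {
    if (!is.null(chunks[[i]])) {
      out[[i]] <- .parse_mol2_block(chunks[[i]], smiles = smiles[i])
    }
  }
  out
}

# Numeric bond order (aromatic ~ 1.5, amide 1).
bond_order_numeric <- function(type) {
  ord <- suppressWarnings(as.numeric(type))
  ord[type == "ar"] <- 1.5
  ord[type == "am"] <- 1
  ord[is.na(ord)] <- 1
  ord
}

# mol_graph -> igraph (heavy-atom skeleton; vertices keep element labels)
mol_to_igraph <- function(mol) {
  g <- igraph::make_empty_graph(n = mol$n_atoms, directed = FALSE)
  if (nrow(mol$bonds) > 0L) {
    g <- igraph::add_edges(g, rbind(mol$bonds$from, mol$bonds$to))
  }
  igraph::set_vertex_attr(g, "element", value = mol$atoms$element)
}

#' Physicochemical descriptors for valid SMILES
#'
#' Open Babel descriptor block (molecular weight, H-bond donors/acceptors,
#' logP, TPSA) for SMILES that are already known to parse.
#'
#' @param smiles character vector of parseable SMILES.
#' @return data.frame with columns \code{mw}, \code{hbd}, \code{hba},
#'   \code{logp}, \code{tpsa}.
#' @export
ob_descriptors <- function(smiles) {
  if (length(smiles) == 0L) {
    return(data.frame(mw = numeric(0), hbd = numeric(0), hba = numeric(0),
                      logp = numeric(0), tpsa = numeric(0)))
  }
  sdf <- ChemmineR::smiles2sdf(stats::setNames(as.character(smiles),
                                               seq_along(smiles)))
  pr <- ChemmineR::propOB(sdf)
  data.frame(mw = pr$MW, hbd = pr$HBD, hba = pr$HBA1,
             logp = pr$logP, tpsa = pr$TPSA)
}
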