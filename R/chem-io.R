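# Molecule parsing, canonicalization, curation filters, Murcko scaffolds,
# and dataset table I/O.

#' Parse and canonicalize SMILES into molecule records
#'
#' Canonicalizes each input, keeps the largest fragment (by heavy-atom
#' count; ties broken by molecular weight, then lexicographically smallest
#' canonical SMILES), and populates the descriptor snapshot: molecular
#' weight, H-bond donors/acceptors, rotatable bonds, heavy atoms, logP,
#' TPSA. Descriptors are computed on the retained fragment only.
#'
#' @param smiles character vector of SMILES strings.
#' @return a \code{molecule_record} data.frame, one row per input.
#' @export
parse_and_canonicalize <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  if (any(!nzchar(smiles) | is.na(smiles))) {
    stop_invalid_molecule(smiles[!nzchar(smiles) | is.na(smiles)])
  }
  res <- parse_records(smiles)
  if (any(!res$valid)) stop_invalid_molecule(smiles[!res$valid])
  res$records
}

#' Parse SMILES, reporting failures instead of erroring
#'
#' Backend of \code{\link{parse_and_canonicalize}} used by dataset readers:
#' invalid rows are flagged, not fatal.
#'
#' @param smiles character vector.
#' @return list with \code{records} (valid rows only), \code{valid} logical
#'   mask over the input, \code{n_dropped}.
#' @export
parse_records <- function(smiles) {
  can <- canonicalize_smiles(smiles)
  valid <- !is.na(can) & nzchar(can)
  frag <- rep(NA_character_, length(smiles))
  idx <- which(valid)
  if (length(idx) > 0L) {
    frag[idx] <- vapply(can[idx], .largest_fragment, "", USE.NAMES = FALSE)
    # fragments of a canonical multi-fragment string may not be in canonical
    # form on their own; re-canonicalize the multi-fragment cases
    multi <- idx[grepl(".", can[idx], fixed = TRUE)]
    if (length(multi) > 0L) {
      re <- canonicalize_smiles(frag[multi])
      ok <- !is.na(re)
      frag[multi[ok]] <- re[ok]
      valid[multi[!ok]] <- FALSE
    }
  }
  idx <- which(valid)
  rec <- NULL
  if (length(idx) > 0L) {
    desc <- ob_descriptors(frag[idx])
    mols <- parse_mol_graph(frag[idx])
    bad <- vapply(mols, is.null, TRUE)
    if (any(bad)) { valid[idx[bad]] <- FALSE; idx <- idx[!bad]
                    desc <- desc[!bad, , drop = FALSE]; mols <- mols[!bad] }
    rec <- data.frame(
      raw_smiles = smiles[idx],
      canonical_smiles = frag[idx],
      mol_weight = desc$mw,
      h_donors = desc$hbd,
      h_acceptors = desc$hba,
      rotatable_bonds = vapply(mols, rotatable_bond_count, 0L),
      heavy_atom_count = vapply(mols, function(m) m$n_atoms, 0L),
      logp = desc$logp,
      tpsa = desc$tpsa,
      stringsAsFactors = FALSE
    )
    class(rec) <- c("molecule_record", "data.frame")
  }
  list(records = rec, valid = valid, n_dropped = sum(!valid))
}

# pick the largest fragment of a (canonical) SMILES
.largest_fragment <- function(can) {
  frags <- strsplit(can, ".", fixed = TRUE)[[1]]
  frags <- frags[nzchar(frags)]
  if (length(frags) == 1L) return(frags)
  counts <- vapply(frags, smiles_atom_count, 0L, USE.NAMES = FALSE)
  cand <- frags[counts == max(counts)]
  if (length(cand) > 1L) {
    mw <- ob_descriptors(cand)$mw
    cand <- cand[mw == max(mw)]
    cand <- sort(cand)[1L]
  }
  cand[1L]
}

#' Count rotatable bonds of a molecular graph
#'
#' Acyclic single (or amide-typed) bonds between two non-terminal heavy
#' atoms, excluding bonds with a triple-bonded endpoint — the standard
#' default rotatable-bond definition.
#'
#' @param mol a \code{mol_graph} from \code{\link{parse_mol_graph}}.
#' @return integer count.
#' @export
rotatable_bond_count <- function(mol) {
  b <- mol$bonds
  if (nrow(b) == 0L) return(0L)
  g <- mol_to_igraph(mol)
  deg <- igraph::degree(g)
  bridge <- rep(FALSE, nrow(b))
  bridge[igraph::bridges(g)] <- TRUE
  triple_atom <- unique(c(b$from[b$type == "3"], b$to[b$type == "3"]))
  ok <- b$type %in% c("1", "am") & bridge &
    deg[b$from] >= 2L & deg[b$to] >= 2L &
    !(b$from %in% triple_atom) & !(b$to %in% triple_atom)
  sum(ok)
}

#' Drug-likeness curation filter
#'
#' Keeps records with molecular weight <= 600 Da, <= 5 H-bond donors,
#' <= 10 H-bond acceptors and <= 10 rotatable bonds (all bounds inclusive);
#' input order is preserved.
#'
#' @param records a \code{molecule_record} data.frame.
#' @return the retained subset, same class.
#' @export
drug_likeness_filter <- function(records) {
  if (is.null(records) || nrow(records) == 0L) return(records)
  keep <- records$mol_weight <= 600 & records$h_donors <= 5 &
    records$h_acceptors <= 10 & records$rotatable_bonds <= 10
  records[keep, , drop = FALSE]
}

# ---- Murcko scaffolds -------------------------------------------------------

# minimal V2000 ctab reader for Open Babel SDF output (keeps M CHG lines,
# which the higher-level SDF containers drop)
.read_ctab <- function(lines) {
  counts <- lines[4L]
  na <- as.integer(substr(counts, 1, 3)); nb <- as.integer(substr(counts, 4, 6))
  al <- lines[4L + seq_len(na)]
  atoms <- data.frame(
    x = as.numeric(substr(al, 1, 10)), y = as.numeric(substr(al, 11, 20)),
    element = trimws(substr(al, 32, 34)), charge = 0L,
    stringsAsFactors = FALSE)
  bl <- if (nb > 0L) lines[4L + na + seq_len(nb)] else character(0)
  bonds <- data.frame(
    from = as.integer(substr(bl, 1, 3)), to = as.integer(substr(bl, 4, 6)),
    order = as.integer(substr(bl, 7, 9)))
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
    n <- f[1L]
    for (k in seq_len(n)) atoms$charge[f[2 * k]] <- f[2 * k + 1L]
  }
  list(atoms = atoms, bonds = bonds)
}

.write_ctab <- function(atoms, bonds, title = "") {
  hdr <- c(title, " molfuse", "")
  cnt <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                 nrow(atoms), nrow(bonds))
  al <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                atoms$x, atoms$y, 0, atoms$element)
  bl <- if (nrow(bonds) > 0L)
    sprintf("%3d%3d%3d  0  0  0  0", bonds$from, bonds$to, bonds$order)
  else character(0)
  chg <- which(atoms$charge != 0L)
  ml <- character(0)
  while (length(chg) > 0L) {
    take <- chg[seq_len(min(8L, length(chg)))]
    ml <- c(ml, paste0("M  CHG", sprintf("%3d", length(take)),
                       paste0(sprintf("%4d%4d", take, atoms$charge[take]),
                              collapse = "")))
    chg <- chg[-seq_len(min(8L, length(chg)))]
  }
  paste(c(hdr, cnt, al, bl, ml, "M  END", "$$$$"), collapse = "\n")
}

# Murcko framework atom set on a kekulized ctab: iteratively prune terminal
# atoms (ring systems + linkers survive), then restore atoms attached to the
# framework by a multiple-order bond (e.g. exocyclic carbonyl oxygens).
.scaffold_atom_set <- function(ctab) {
  n <- nrow(ctab$atoms)
  b <- ctab$bonds
  alive <- rep(TRUE, n)
  repeat {
    deg <- tabulate(c(b$from[alive[b$from] & alive[b$to]],
                      b$to[alive[b$from] & alive[b$to]]), nbins = n)
    drop <- alive & deg <= 1L
    if (!any(drop)) break
    alive[drop] <- FALSE
  }
  if (!any(alive)) return(integer(0))
  exo <- (alive[b$from] & !alive[b$to] & b$order >= 2L) |
         (alive[b$to] & !alive[b$from] & b$order >= 2L)
  keep <- alive
  keep[b$to[exo & alive[b$from]]] <- TRUE
  keep[b$from[exo & alive[b$to]]] <- TRUE
  which(keep)
}

#' Murcko scaffold keys for a set of molecules
#'
#' Bemis-Murcko framework (ring systems, linkers, and exocyclic
#' multiple-bonded attachments) as a canonical SMILES; acyclic molecules get
#' the empty key \code{""}. Identical molecules map to identical keys
#' regardless of input atom ordering.
#'
#' @param smiles character vector of parseable SMILES (canonical or not).
#' @return character vector of scaffold keys.
#' @export
scaffold_keys <- function(smiles) {
  n <- length(smiles)
  if (n == 0L) return(character(0))
  sdf_chunks <- ob_convert_sdf(smiles)
  keys <- rep(NA_character_, n)
  ctabs <- character(0); ctab_idx <- integer(0)
  for (i in seq_len(n)) {
    if (is.null(sdf_chunks[[i]])) next
    ct <- .read_ctab(sdf_chunks[[i]])
    keep <- .scaffold_atom_set(ct)
    if (length(keep) == 0L) { keys[i] <- ""; next }
    remap <- match(seq_len(nrow(ct$atoms)), keep)
    bsub <- ct$bonds[ct$bonds$from %in% keep & ct$bonds$to %in% keep, ,
                     drop = FALSE]
    bsub$from <- remap[bsub$from]; bsub$to <- remap[bsub$to]
    ctabs <- c(ctabs, .write_ctab(ct$atoms[keep, , drop = FALSE], bsub,
                                  title = as.character(i)))
    ctab_idx <- c(ctab_idx, i)
  }
  if (length(ctabs) > 0L) {
    out <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat(
        "SDF", "CAN", paste0(paste(ctabs, collapse = "\n"), "\n"),
        options = .ob_noopts)),
      error = function(e) "")
    parsed <- .split_can(out)
    keys[parsed$idx] <- unlist(parsed$chunks)
  }
  keys
}

# batch SMILES -> SDF chunks (list of ctab line vectors, NULL on failure)
ob_convert_sdf <- function(smiles) {
  n <- length(smiles)
  out <- vector("list", n)
  todo <- which(!is.na(smiles) & nzchar(smiles))
  while (length(todo) > 0L) {
    inp <- paste0(smiles[todo], " ", todo, collapse = "\n")
    txt <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "SDF", inp,
                                                 options = .ob_noopts)),
      error = function(e) "")
    done <- integer(0)
    if (nzchar(txt)) {
      lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
      ends <- which(lines == "$$$$")
      starts <- c(1L, ends[-length(ends)] + 1L)
      for (k in seq_along(ends)) {
        blk <- lines[starts[k]:ends[k]]
        id <- suppressWarnings(as.integer(trimws(blk[1L])))
        if (!is.na(id)) { out[[id]] <- blk; done <- c(done, id) }
      }
    }
    n_ok <- length(done)
    if (n_ok + 1L <= length(todo)) {
      todo <- todo[seq.int(n_ok + 2L, length.out = max(0L, length(todo) - n_ok - 1L))]
    } else todo <- integer(0)
  }
  out
}

#' Murcko scaffold of a single molecule record
#' @param record one-row \code{molecule_record} (or a SMILES string).
#' @return list of class \code{scaffold_key} with \code{scaffold_smiles}.
#' @export
murcko_scaffold <- function(record) {
  smi <- if (is.character(record)) record else record$canonical_smiles[1L]
  structure(list(scaffold_smiles = scaffold_keys(smi)), class = "scaffold_key")
}

# ---- Dataset tables ---------------------------------------------------------

#' Construct a dataset table
#'
#' The unit consumed by splitting, fine-tuning and screening: an ordered set
#' of molecule records with optional aligned labels.
#'
#' @param records \code{molecule_record} data.frame.
#' @param labels numeric vector aligned 1:1 with records, or NULL.
#' @param task_kind \code{"classification"} or \code{"regression"}.
#' @param name dataset name.
#' @param n_dropped rows dropped during parsing (bookkeeping).
#' @return object of class \code{dataset_table}.
#' @export
dataset_table <- function(records, labels = NULL,
                          task_kind = c("regression", "classification"),
                          name = "dataset", n_dropped = 0L) {
  task_kind <- match.arg(task_kind)
  if (!is.null(labels) && length(labels) != nrow(records)) {
    stop("labels must align 1:1 with records")
  }
  structure(list(records = records, labels = labels, task_kind = task_kind,
                 name = name, n_dropped = as.integer(n_dropped)),
            class = "dataset_table")
}

#' @export
print.dataset_table <- function(x, ...) {
  cat(sprintf("<dataset_table '%s'> %d molecules, task = %s, labels = %s",
              x$name, nrow(x$records), x$task_kind,
              if (is.null(x$labels)) "none" else "present"), "\n")
  if (x$n_dropped > 0L) cat("  rows dropped at parse time:", x$n_dropped, "\n")
  invisible(x)
}

#' Read a molecule dataset from delimited text
#'
#' CSV/TSV with a mandatory \code{smiles} column (case-insensitive) and an
#' optional \code{label} column; \code{.smi} files are read as one SMILES
#' per line. Rows whose SMILES fail to parse are dropped with a reported
#' count.
#'
#' @param path file path.
#' @param task_kind label interpretation; \code{NULL} infers classification
#'   for 0/1 labels.
#' @param name dataset name (default: file name).
#' @return a \code{dataset_table}.
#' @export
read_dataset <- function(path, task_kind = NULL, name = NULL) {
  stopifnot(file.exists(path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "smi") {
    df <- data.frame(smiles = readLines(path), stringsAsFactors = FALSE)
    df <- df[nzchar(trimws(df$smiles)), , drop = FALSE]
    df$smiles <- vapply(strsplit(trimws(df$smiles), "[ \t]+"), `[[`, "", 1L)
  } else {
    sep <- if (ext == "tsv") "\t" else ","
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, comment.char = "",
                            quote = "\"", check.names = FALSE)
    names(df) <- tolower(names(df))
    if (!"smiles" %in% names(df)) stop("no 'smiles' column in ", path)
  }
  parsed <- parse_records(df$smiles)
  labels <- NULL
  if ("label" %in% names(df)) {
    labels <- as.numeric(df$label)[parsed$valid]
    if (anyNA(labels)) stop("label/record mismatch: non-numeric labels")
  }
  if (parsed$n_dropped > 0L) {
    message(parsed$n_dropped, " row(s) failed to parse and were dropped")
  }
  if (is.null(task_kind)) {
    task_kind <- if (!is.null(labels) && all(labels %in% c(0, 1)))
      "classification" else "regression"
  }
  dataset_table(parsed$records, labels, task_kind,
                name = name %||% basename(path), n_dropped = parsed$n_dropped)
}

#' Write a dataset table to CSV
#' @param table a \code{dataset_table}.
#' @param path output path.
#' @export
write_dataset <- function(table, path) {
  df <- data.frame(smiles = table$records$canonical_smiles,
                   stringsAsFactors = FALSE)
  if (!is.null(table$labels)) df$label <- table$labels
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' GPCR-style dataset curation
#'
#' Applies the molecular-weight cutoff first (default 600 Da), then rejects
#' tables left with fewer than \code{min_rows} rows (default 50), returning
#' \code{NULL} with a warning in that case.
#'
#' @param table a \code{dataset_table}.
#' @param mw_max molecular-weight cutoff in daltons.
#' @param min_rows minimum post-filter dataset size.
#' @return the curated \code{dataset_table}, or \code{NULL} if rejected.
#' @export
curate_gpcr <- function(table, mw_max = 600, min_rows = 50L) {
  keep <- table$records$mol_weight <= mw_max
  rec <- table$records[keep, , drop = FALSE]
  lab <- if (is.null(table$labels)) NULL else table$labels[keep]
  if (nrow(rec) < min_rows) {
    warning(sprintf("dataset '%s' rejected: %d rows after MW filter (< %d)",
                    table$name, nrow(rec), min_rows))
    return(NULL)
  }
  dataset_table(rec, lab, table$task_kind, table$name, table$n_dropped)
}
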