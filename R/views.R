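# The three per-molecule views: graph tokens + spectral positional encoding,
# rendered 2D depiction, and the tokenized SMILES sequence (tokenizer in
# tokenize.R).

.element_z <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15,
                S = 16, Cl = 17, Se = 34, Br = 35, I = 53)

#' Featurize a molecule as a token-level graph
#'
#' Undirected heavy-atom graph with one token per atom and one per bond.
#' Atom features: atomic number, chirality, degree, formal charge,
#' hybridization. Bond features: bond type, bond direction, double-bond
#' stereo, conjugation flag, in-ring flag. Chirality and bond-direction
#' annotations are aligned from the SMILES token stream.
#'
#' @param x a SMILES string or one-row \code{molecule_record}.
#' @param mol optional pre-parsed \code{mol_graph} for \code{x}.
#' @return object of class \code{graph_view}.
#' @export
featurize_graph <- function(x, mol = NULL) {
  smi <- if (is.character(x)) x else x$canonical_smiles[1L]
  if (is.null(mol)) mol <- parse_mol_graph(smi)[[1L]]
  if (is.null(mol)) stop_invalid_molecule(smi)
  n <- mol$n_atoms
  if (n == 0L) stop("empty molecule cannot be featurized")
  top <- suppressWarnings(smiles_topology(tokenize_smiles(smi)$tokens))
  chir <- rep("none", n)
  if (top$n_atoms == n) {
    chir[top$chirality == "@"] <- "at"
    chir[top$chirality == "@@"] <- "at_at"
  }
  b <- mol$bonds
  m <- nrow(b)
  deg <- tabulate(c(b$from, b$to), nbins = n)
  node_features <- data.frame(
    atomic_number = unname(.element_z[mol$atoms$element]),
    chirality = chir,
    degree = deg,
    formal_charge = mol$atoms$charge,
    hybridization = mol$atoms$hyb,
    stringsAsFactors = FALSE)
  node_features$atomic_number[is.na(node_features$atomic_number)] <- 0
  bond_type <- c("1" = "single", "2" = "double", "3" = "triple",
                 "ar" = "aromatic", "am" = "single")[b$type]
  bond_type[is.na(bond_type)] <- "single"
  # direction symbols resolved from the SMILES token stream, matched by
  # unordered endpoint pair
  dir <- rep("none", m)
  if (m > 0L && nrow(top$bonds) > 0L && top$n_atoms == n) {
    key_m <- paste(pmin(b$from, b$to), pmax(b$from, b$to))
    key_t <- paste(pmin(top$bonds$from, top$bonds$to),
                   pmax(top$bonds$from, top$bonds$to))
    hit <- match(key_m, key_t)
    sym <- ifelse(is.na(hit), "", top$bonds$sym[hit])
    dir[sym == "/"] <- "up"
    dir[sym == "\\"] <- "down"
  }
  in_ring <- rep(FALSE, m)
  if (m > 0L) {
    g <- mol_to_igraph(mol)
    in_ring <- !(seq_len(m) %in% igraph::bridges(g))
  }
  multi <- bond_type %in% c("double", "triple", "aromatic") | b$type == "am"
  atom_multi <- rep(FALSE, n)
  atom_multi[c(b$from[multi], b$to[multi])] <- TRUE
  conjugated <- multi | (bond_type == "single" & atom_multi[b$from] &
                           atom_multi[b$to])
  # double-bond cis/trans: a double bond whose both endpoints carry a
  # direction-marked single bond
  dir_atom <- rep(FALSE, n)
  dir_atom[c(b$from[dir != "none"], b$to[dir != "none"])] <- TRUE
  stereo <- ifelse(bond_type == "double" & dir_atom[b$from] & dir_atom[b$to],
                   "cis_trans", "none")
  edge_features <- data.frame(
    bond_type = bond_type, bond_dir = dir, stereo = stereo,
    conjugated = conjugated, in_ring = in_ring, stringsAsFactors = FALSE)
  structure(list(
    n_nodes = n, n_edges = m,
    edges = data.frame(from = b$from, to = b$to),
    node_features = node_features, edge_features = edge_features,
    token_kind = c(rep("node", n), rep("edge", m)),
    laplacian_eigenvalues = NULL, laplacian_eigenvectors = NULL,
    pe_k = NULL, smiles = smi), class = "graph_view")
}

#' Attach Laplacian positional encoding to a graph view
#'
#' Computes the k smallest eigenpairs of the combinatorial Laplacian
#' L = D - A of the heavy-atom graph. Eigenvalues are ascending; each
#' eigenvector's sign is fixed by making its first nonzero component
#' positive. Graphs with fewer than k nodes are zero-padded.
#'
#' @param view a \code{graph_view}.
#' @param k number of eigenpairs to retain (default 8).
#' @return the view with \code{laplacian_eigenvalues} (length k) and
#'   \code{laplacian_eigenvectors} (n x k matrix) attached.
#' @export
laplacian_pe <- function(view, k = 8L) {
  stopifnot(inherits(view, "graph_view"), k >= 1L)
  n <- view$n_nodes
  A <- matrix(0, n, n)
  if (view$n_edges > 0L) {
    idx <- cbind(view$edges$from, view$edges$to)
    A[idx] <- 1; A[idx[, 2:1, drop = FALSE]] <- 1
  }
  L <- diag(rowSums(A), n) - A
  eig <- eigen(L, symmetric = TRUE)
  ord <- order(eig$values)            # ascending, stable for ties
  vals <- pmax(eig$values[ord], 0)
  vecs <- eig$vectors[, ord, drop = FALSE]
  for (j in seq_len(ncol(vecs))) {
    nz <- which(abs(vecs[, j]) > 1e-8)
    if (length(nz) > 0L && vecs[nz[1L], j] < 0) vecs[, j] <- -vecs[, j]
  }
  kk <- min(k, n)
  ev <- numeric(k); ev[seq_len(kk)] <- vals[seq_len(kk)]
  V <- matrix(0, n, k); V[, seq_len(kk)] <- vecs[, seq_len(kk), drop = FALSE]
  view$laplacian_eigenvalues <- ev
  view$laplacian_eigenvectors <- V
  view$pe_k <- k
  view
}

# ---- Image view -------------------------------------------------------------

.atom_palette <- list(
  N = c(0.10, 0.10, 0.90), O = c(0.90, 0.10, 0.10), S = c(0.80, 0.70, 0.05),
  P = c(0.95, 0.50, 0.05), F = c(0.10, 0.65, 0.10), Cl = c(0.10, 0.65, 0.10),
  Br = c(0.55, 0.25, 0.05), I = c(0.45, 0.10, 0.55), B = c(0.95, 0.60, 0.45))

#' Fixed per-channel normalization constants for rendered images
#' @export
image_norm_constants <- list(mean = c(0.9, 0.9, 0.9), sd = c(0.25, 0.25, 0.25))

# sample points along one sub-line of a bond; returns x/y pixel vectors
.segment_points <- function(x1, y1, x2, y2, dash = FALSE) {
  len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  ns <- max(2L, ceiling(len * 2))
  t <- seq(0, 1, length.out = ns)
  if (dash) t <- t[(seq_along(t) %% 4) < 2]
  list(x = round(x1 + t * (x2 - x1)), y = round(y1 + t * (y2 - y1)))
}

.rasterize_mol <- function(mol, size = 256L, margin = 20L) {
  img <- array(1, c(size, size, 3))
  x <- mol$atoms$x; y <- mol$atoms$y
  span <- max(diff(range(x)), diff(range(y)), 1e-6)
  scale <- (size - 2 * margin) / span
  px <- (x - mean(range(x))) * scale + size / 2
  py <- (mean(range(y)) - y) * scale + size / 2
  b <- mol$bonds
  segx <- segy <- vector("list", 0L)
  for (k in seq_len(nrow(b))) {
    i <- b$from[k]; j <- b$to[k]
    dx <- px[j] - px[i]; dy <- py[j] - py[i]
    nrm <- sqrt(dx^2 + dy^2) + 1e-9
    ox <- -dy / nrm; oy <- dx / nrm
    offsets <- switch(b$type[k], "2" = c(-1.6, 1.6), "3" = c(-2.4, 0, 2.4),
                      "ar" = c(0, 2.2), 0)
    for (si in seq_along(offsets)) {
      s <- offsets[si]
      pt <- .segment_points(px[i] + s * ox, py[i] + s * oy,
                            px[j] + s * ox, py[j] + s * oy,
                            dash = (b$type[k] == "ar" && si == 2L))
      segx[[length(segx) + 1L]] <- pt$x
      segy[[length(segy) + 1L]] <- pt$y
    }
  }
  if (length(segx) > 0L) {
    bx <- unlist(segx); by <- unlist(segy)
    bx <- c(bx, bx - 1L, bx, bx - 1L)       # 2x2 stroke thickness
    by <- c(by, by, by - 1L, by - 1L)
    ok <- bx >= 1 & bx <= size & by >= 1 & by <= size
    bx <- bx[ok]; by <- by[ok]
    for (ch in 1:3) img[cbind(by, bx, ch)] <- 0
  }
  rmax <- 7L
  dg <- expand.grid(dx = -rmax:rmax, dy = -rmax:rmax)
  d2 <- dg$dx^2 + dg$dy^2
  for (v in seq_len(mol$n_atoms)) {
    el <- mol$atoms$element[v]
    col <- .atom_palette[[el]]
    r <- if (is.null(col)) 2L else 5L
    if (mol$atoms$charge[v] != 0L) r <- r + 2L
    if (is.null(col)) col <- c(0, 0, 0)
    sel <- d2 <= r^2
    xs <- round(px[v]) + dg$dx[sel]; ys <- round(py[v]) + dg$dy[sel]
    ok <- xs >= 1 & xs <= size & ys >= 1 & ys <= size
    for (ch in 1:3) img[cbind(ys[ok], xs[ok], ch)] <- col[ch]
  }
  img
}

#' Render a molecule as a normalized pixel grid
#'
#' Rasterizes the 2D depiction (bond segments plus element-colored atom
#' disks on a white background) at 256 x 256, then crops to 224 x 224:
#' a deterministic central crop in eval mode, or a seeded random crop with
#' random horizontal flip in train mode. Pixels are normalized per channel
#' with the fixed constants in \code{\link{image_norm_constants}}.
#'
#' @param x SMILES string or one-row \code{molecule_record}.
#' @param mode \code{"eval"} or \code{"train"}.
#' @param seed integer controlling train-mode augmentation.
#' @param mol optional pre-parsed \code{mol_graph} with coordinates.
#' @param augment optional list(dx, dy, flip) overriding the seeded
#'   augmentation draw (testing hook).
#' @return object of class \code{image_view} with \code{pixels}
#'   (224 x 224 x 3), \code{mode} and \code{seed}.
#' @export
render_image <- function(x, mode = c("eval", "train"), seed = 1L, mol = NULL,
                         augment = NULL) {
  mode <- match.arg(mode)
  smi <- if (is.character(x)) x else x$canonical_smiles[1L]
  if (is.null(mol)) mol <- parse_mol_graph(smi, coords = TRUE)[[1L]]
  if (is.null(mol) || mol$n_atoms == 0L) {
    stop(structure(class = c("molfuse_render_error", "error", "condition"),
                   list(message = paste0("cannot render: ", smi),
                        call = sys.call(-1))))
  }
  raw <- 256L; out <- 224L
  img <- .rasterize_mol(mol, size = raw)
  pad <- raw - out
  if (mode == "eval") {
    dx <- dy <- pad %/% 2L; flip <- FALSE
  } else if (!is.null(augment)) {
    dx <- augment$dx; dy <- augment$dy; flip <- isTRUE(augment$flip)
  } else {
    draw <- with_seed(seed, list(dx = sample.int(pad + 1L, 1L) - 1L,
                                 dy = sample.int(pad + 1L, 1L) - 1L,
                                 flip = stats::runif(1) < 0.5))
    dx <- draw$dx; dy <- draw$dy; flip <- draw$flip
  }
  crop <- img[dy + seq_len(out), dx + seq_len(out), , drop = FALSE]
  if (flip) crop <- crop[, out:1, , drop = FALSE]
  for (ch in 1:3) {
    crop[, , ch] <- (crop[, , ch] - image_norm_constants$mean[ch]) /
      image_norm_constants$sd[ch]
  }
  structure(list(pixels = crop, mode = mode, seed = seed, smiles = smi),
            class = "image_view")
}

#' Export an image view (or raw render) to PNG
#' @param view an \code{image_view}.
#' @param path output file.
#' @export
write_image_png <- function(view, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required for PNG export")
  }
  px <- view$pixels
  for (ch in 1:3) {
    px[, , ch] <- px[, , ch] * image_norm_constants$sd[ch] +
      image_norm_constants$mean[ch]
  }
  px[px < 0] <- 0; px[px > 1] <- 1
  png::writePNG(px, path)
  invisible(path)
}
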