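# Drug-target interaction head: ligand embeddings (frozen multi-view
# backbone features) and externally supplied protein embeddings are each
# projected to 64 dimensions, concatenated to a 128-D pair embedding, and
# passed through a small prediction head. Protein embeddings are consumed
# as an input table; computing them is out of scope.

#' Read / write a protein embedding table
#'
#' Delimited text with an \code{id} column followed by numeric embedding
#' dimensions.
#'
#' @param mat matrix with protein ids as rownames.
#' @param path file path.
#' @export
write_protein_embeddings <- function(mat, path) {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_protein_embeddings
#' @export
read_protein_embeddings <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$id
  m
}

#' Construct a ligand-protein pair table
#'
#' @param ligand_smiles SMILES per pair.
#' @param protein_id protein identifier per pair.
#' @param affinity numeric binding affinity (pKd/pKI-like).
#' @return data.frame of class \code{dti_pairs}.
#' @export
dti_pairs <- function(ligand_smiles, protein_id, affinity) {
  stopifnot(length(ligand_smiles) == length(protein_id),
            length(protein_id) == length(affinity))
  structure(data.frame(ligand_smiles = ligand_smiles,
                       protein_id = protein_id,
                       affinity = as.numeric(affinity),
                       stringsAsFactors = FALSE),
            class = c("dti_pairs", "data.frame"))
}

#' DTI model configuration
#'
#' @param proj_dim per-side projection width (default 64, giving the 128-D
#'   concatenated pair embedding).
#' @param hidden prediction-head hidden width.
#' @param epochs,lr,unfreeze_at training schedule: the head trains alone
#'   until \code{unfreeze_at} (fraction of epochs), after which the two
#'   projections unfreeze (staged unfreezing).
#' @export
dti_config <- function(proj_dim = 64L, hidden = 64L, epochs = 300L,
                       lr = 5e-3, unfreeze_at = 0.2) {
  list(proj_dim = as.integer(proj_dim), hidden = as.integer(hidden),
       epochs = as.integer(epochs), lr = lr, unfreeze_at = unfreeze_at)
}

.init_dti_params <- function(p_lig, p_prot, cfg, seed) {
  with_seed(seed, list(
    Wl = .init_mat(cfg$proj_dim, p_lig), bl = numeric(cfg$proj_dim),
    Wp = .init_mat(cfg$proj_dim, p_prot), bp = numeric(cfg$proj_dim),
    A = .init_mat(cfg$hidden, 2L * cfg$proj_dim), a = numeric(cfg$hidden),
    C = .init_mat(1L, cfg$hidden), c0 = 0))
}

.dti_forward <- function(L, Pm, params) {
  zl <- sweep(L %*% t(params$Wl), 2, params$bl, "+")
  zp <- sweep(Pm %*% t(params$Wp), 2, params$bp, "+")
  cc <- cbind(zl, zp)
  H <- tanh(sweep(cc %*% t(params$A), 2, params$a, "+"))
  y <- drop(H %*% t(params$C)) + params$c0
  list(zl = zl, zp = zp, cc = cc, H = H, y = y)
}

.dti_backward <- function(fw, L, Pm, y_true, params) {
  B <- length(fw$y)
  dY <- matrix(2 * (fw$y - y_true) / B, ncol = 1L)
  gr <- list(C = t(dY) %*% fw$H, c0 = sum(dY))
  G_h <- (dY %*% params$C) * (1 - fw$H^2)
  gr$A <- t(G_h) %*% fw$cc; gr$a <- colSums(G_h)
  G_cc <- G_h %*% params$A
  d <- ncol(fw$zl)
  G_zl <- G_cc[, seq_len(d), drop = FALSE]
  G_zp <- G_cc[, d + seq_len(d), drop = FALSE]
  gr$Wl <- t(G_zl) %*% L; gr$bl <- colSums(G_zl)
  gr$Wp <- t(G_zp) %*% Pm; gr$bp <- colSums(G_zp)
  gr
}

.train_dti <- function(L, Pm, y, train_idx, val_idx, cfg, seed) {
  params <- .init_dti_params(ncol(L), ncol(Pm), cfg, seed)
  opt <- .adam_new()
  best <- list(loss = Inf, params = params)
  head_only <- c("A", "a", "C", "c0")
  n_stage1 <- max(1L, floor(cfg$epochs * cfg$unfreeze_at))
  for (ep in seq_len(cfg$epochs)) {
    fw <- .dti_forward(L[train_idx, , drop = FALSE],
                       Pm[train_idx, , drop = FALSE], params)
    if (!is.finite(mean(fw$y))) stop("DTI training diverged")
    gr <- .dti_backward(fw, L[train_idx, , drop = FALSE],
                        Pm[train_idx, , drop = FALSE], y[train_idx], params)
    if (ep <= n_stage1) gr <- gr[head_only]    # projections still frozen
    st <- .adam_step(opt, params, gr, lr_groups = c(cfg$lr, cfg$lr))
    params <- st$params; opt <- st$state
    va <- .dti_forward(L[val_idx, , drop = FALSE],
                       Pm[val_idx, , drop = FALSE], params)
    v_loss <- mean((va$y - y[val_idx])^2)
    if (v_loss < best$loss) best <- list(loss = v_loss, params = params)
  }
  best$params
}

#' Predict binding affinity for ligand-protein pairs
#'
#' @param model a trained \code{dti_model} (from \code{\link{crossval_dti}}
#'   or internal training).
#' @param pairs a \code{dti_pairs} table.
#' @param ligand_features per-unique-ligand feature matrix (rownames =
#'   canonical SMILES); computed from the model config when omitted.
#' @return numeric affinity predictions.
#' @export
predict_affinity <- function(model, pairs, ligand_features = NULL) {
  if (is.null(ligand_features)) ligand_features <- model$ligand_features
  prot <- model$protein_embeddings
  unknown <- setdiff(unique(pairs$protein_id), rownames(prot))
  if (length(unknown) > 0L) {
    stop("unknown protein id(s): ", paste(unknown, collapse = ", "))
  }
  can <- canonicalize_smiles(pairs$ligand_smiles)
  miss <- setdiff(unique(can), rownames(ligand_features))
  if (length(miss) > 0L) stop("ligand(s) without features: ",
                              paste(miss, collapse = ", "))
  L <- ligand_features[can, , drop = FALSE]
  Pm <- prot[pairs$protein_id, , drop = FALSE]
  .dti_forward(L, Pm, model$params)$y
}

#' Sixfold cross-validation for the DTI head
#'
#' Pairs are permuted by seed and divided into six blocks; fold f uses
#' block f for testing, the next block for validation, and the remaining
#' four for training, so every pair is tested exactly once. The ligand side
#' uses concatenated frozen multi-view backbone features; the head trains
#' staged (head first, projections unfrozen later).
#'
#' @param pairs a \code{dti_pairs} table.
#' @param protein_embeddings matrix with protein ids as rownames.
#' @param mv_config a \code{multiview_config} for ligand featurization.
#' @param dti_cfg a \code{\link{dti_config}}.
#' @param seed fold-assignment and initialization seed.
#' @return list of class \code{dti_cv}: \code{fold_metrics},
#'   \code{mean_metrics}, \code{fold_of_pair}, and the fold-6 model as
#'   \code{model}.
#' @export
crossval_dti <- function(pairs, protein_embeddings,
                         mv_config = multiview_config(),
                         dti_cfg = dti_config(), seed = 1L) {
  n <- nrow(pairs)
  if (n < 6L) stop("need at least 6 pairs for sixfold cross-validation")
  can <- canonicalize_smiles(pairs$ligand_smiles)
  uniq <- unique(can)
  tab <- dataset_table(data.frame(canonical_smiles = uniq,
                                  stringsAsFactors = FALSE))
  feats <- view_features(tab, mv_config)
  L_uniq <- do.call(cbind, feats)
  rownames(L_uniq) <- uniq
  L <- L_uniq[can, , drop = FALSE]
  Pm <- protein_embeddings[pairs$protein_id, , drop = FALSE]
  y <- pairs$affinity
  perm <- with_seed(seed, sample.int(n))
  fold_id <- integer(n)
  fold_id[perm] <- cut(seq_len(n), breaks = 6L, labels = FALSE)
  metrics <- vector("list", 6L)
  model <- NULL
  for (f in seq_len(6L)) {
    test_idx <- which(fold_id == f)
    val_idx <- which(fold_id == (f %% 6L) + 1L)
    train_idx <- setdiff(seq_len(n), c(test_idx, val_idx))
    params <- .train_dti(L, Pm, y, train_idx, val_idx, dti_cfg,
                         seed = seed + f)
    pred <- .dti_forward(L[test_idx, , drop = FALSE],
                         Pm[test_idx, , drop = FALSE], params)$y
    truth <- y[test_idx]
    metrics[[f]] <- c(pearson = stats::cor(pred, truth),
                      rmse = sqrt(mean((pred - truth)^2)))
    model <- list(params = params, ligand_features = L_uniq,
                  protein_embeddings = protein_embeddings,
                  mv_config = mv_config, dti_cfg = dti_cfg)
  }
  fm <- do.call(rbind, metrics)
  structure(list(fold_metrics = fm, mean_metrics = colMeans(fm),
                 fold_of_pair = fold_id, model = model),
            class = "dti_cv")
}
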