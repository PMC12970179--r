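# Gated late fusion: softmax gate weights alpha_m computed from a
# batch-averaged attention score per view,
#   w_m = (1/B) sum_i q' tanh(W z_im / ||z_im|| + b),   alpha = softmax(w),
# followed by an MLP on the alpha-weighted sum of view embeddings. Also the
# three alternative late-fusion schemes and aggregator reconstruction
# pre-training.

#' Gate weights recorded after large-scale aggregator pre-training
#'
#' Reference constants for the (image, graph, text) gate weights reported
#' after reconstruction pre-training at foundation scale. Stored for
#' comparison only; desk-scale pre-training does not reproduce them.
#' @export
alpha_pretrained_reference <- c(image = 0.6, graph = 0.3, text = 0.1)

#' Initialize gated-fusion parameters
#'
#' @param d embedding dimension shared by the views.
#' @param gate_dim dimension of the gate's tanh projection.
#' @param d_out fused-embedding dimension (MLP output).
#' @param hidden MLP hidden width (default = d).
#' @param n_views number of views.
#' @param seed initialization seed.
#' @return list of class \code{gating_params} with \code{q}, \code{W},
#'   \code{b} (gate) and the 2-layer MLP head.
#' @export
init_gating_params <- function(d, gate_dim = 16L, d_out = d, hidden = d,
                               n_views = 3L, seed = 1L) {
  with_seed(seed, structure(list(
    q = stats::rnorm(gate_dim, sd = sqrt(1 / gate_dim)),
    W = .init_mat(gate_dim, d),
    b = numeric(gate_dim),
    A = .init_mat(hidden, d), a = numeric(hidden),
    B = .init_mat(d_out, hidden), b2 = numeric(d_out)),
    class = "gating_params"))
}

# gate scores for one view's batch matrix Z (B x d)
.gate_scores <- function(Z, params) {
  r <- sqrt(rowSums(Z^2))
  if (any(r < 1e-12)) stop("zero-norm embedding: gate normalization undefined")
  N <- Z / r
  U <- tanh(sweep(N %*% t(params$W), 2, params$b, "+"))
  drop(U %*% params$q)
}

#' Fuse per-view embeddings with the gated aggregator
#'
#' Computes the per-view gate weights over the batch and the fused
#' embedding. With a single view the softmax degenerates to weight 1. For
#' frozen-gate inference, pass \code{frozen_w} (pre-softmax scores recorded
#' at training time) to decouple predictions from batch composition.
#'
#' @param embeddings named list, one B x d matrix per view (or
#'   \code{view_embedding} objects / plain vectors for B = 1).
#' @param params a \code{gating_params}.
#' @param frozen_w optional fixed pre-softmax scores (one per view).
#' @return object of class \code{fusion_output}: \code{z_mv} (B x d_out),
#'   \code{alpha}, \code{w}, \code{batch_size}.
#' @export
fuse_views <- function(embeddings, params, frozen_w = NULL) {
  Z <- lapply(embeddings, function(e) {
    if (inherits(e, "view_embedding")) e <- e$z
    if (is.null(dim(e))) e <- matrix(e, nrow = 1L)
    e
  })
  B <- nrow(Z[[1]])
  stopifnot(all(vapply(Z, nrow, 0L) == B))
  M <- length(Z)
  w <- if (!is.null(frozen_w)) {
    stopifnot(length(frozen_w) == M)
    as.numeric(frozen_w)
  } else {
    vapply(Z, function(z) mean(.gate_scores(z, params)), 0)
  }
  alpha <- drop(.softmax_rows(matrix(w, 1L)))
  zbar <- Reduce(`+`, Map(function(a, z) a * z, alpha, Z))
  H <- tanh(sweep(zbar %*% t(params$A), 2, params$a, "+"))
  z_mv <- sweep(H %*% t(params$B), 2, params$b2, "+")
  structure(list(z_mv = z_mv, alpha = stats::setNames(alpha, names(Z)),
                 w = stats::setNames(w, names(Z)), batch_size = B),
            class = "fusion_output")
}

# ---- Alternative late-fusion schemes ---------------------------------------

#' Configuration for the alternative late-fusion schemes
#'
#' Scheme \code{projected_gating}: per-view projections to min(d) feed a
#' gate over the 3*min(d) concatenation; output is the weighted
#' concatenation of the original embeddings. \code{unprojected_gating}:
#' gate input is the d1+d2+d3 concatenation; same weighted-concatenation
#' output. \code{projected_gating_feature_addition}: gate as in scheme 1,
#' output is the weighted sum of the projected embeddings, with
#' batch-averaged weights reported.
#'
#' @param scheme one of the three scheme names.
#' @param dims integer vector of per-view embedding dimensions.
#' @return list of class \code{alt_fusion_config} with the gate input
#'   dimension \code{D}.
#' @export
alt_fusion_config <- function(scheme = c("projected_gating",
                                         "unprojected_gating",
                                         "projected_gating_feature_addition"),
                              dims) {
  scheme <- match.arg(scheme)
  stopifnot(length(dims) >= 2L, all(dims >= 1L))
  D <- if (scheme == "unprojected_gating") sum(dims)
  else min(dims) * length(dims)
  structure(list(scheme = scheme, dims = as.integer(dims), D = as.integer(D),
                 d_proj = as.integer(min(dims))),
            class = "alt_fusion_config")
}

#' Initialize parameters for an alternative fusion scheme
#' @param config an \code{alt_fusion_config}.
#' @param seed initialization seed.
#' @export
init_alt_fusion_params <- function(config, seed = 1L) {
  with_seed(seed, {
    p <- list(gate_W = .init_mat(length(config$dims), config$D),
              gate_b = numeric(length(config$dims)))
    if (config$scheme != "unprojected_gating") {
      p$proj <- lapply(config$dims, function(d) .init_mat(config$d_proj, d))
    }
    p
  })
}

#' Apply an alternative late-fusion scheme
#'
#' @param embeddings named list of B x d_m matrices.
#' @param config an \code{alt_fusion_config}.
#' @param params from \code{\link{init_alt_fusion_params}}.
#' @return list of class \code{fusion_output} with \code{z_final},
#'   per-sample \code{weights} (B x M) and batch-averaged \code{w_bar}.
#' @export
alt_fuse <- function(embeddings, config, params) {
  Z <- lapply(embeddings, function(e) {
    if (is.null(dim(e))) matrix(e, nrow = 1L) else e
  })
  stopifnot(length(Z) == length(config$dims))
  for (m in seq_along(Z)) {
    if (ncol(Z[[m]]) != config$dims[m]) stop("embedding dim mismatch")
  }
  P <- if (config$scheme == "unprojected_gating") Z
  else Map(function(z, W) z %*% t(W), Z, params$proj)
  gate_in <- do.call(cbind, P)
  stopifnot(ncol(gate_in) == config$D)
  weights <- .softmax_rows(sweep(gate_in %*% t(params$gate_W), 2,
                                 params$gate_b, "+"))
  if (config$scheme == "projected_gating_feature_addition") {
    z_final <- Reduce(`+`, Map(function(m) weights[, m] * P[[m]],
                               seq_along(P)))
  } else {
    z_final <- do.call(cbind, Map(function(m) weights[, m] * Z[[m]],
                                  seq_along(Z)))
  }
  structure(list(z_final = z_final, weights = weights,
                 w_bar = colMeans(weights), scheme = config$scheme),
            class = "fusion_output")
}

# ---- Aggregator reconstruction pre-training --------------------------------

#' Pre-train the aggregator by embedding reconstruction
#'
#' Trains the gate and fusion MLP, together with one linear reconstruction
#' head per view mapping the fused embedding back to that view's input
#' embedding, under mean squared error. Returns the trained parameters, the
#' gate-weight history, and per-view reconstruction losses before and after
#' training.
#'
#' @param triples named list, one N x d matrix per view (aligned rows).
#' @param gate_dim,hidden gate / MLP widths.
#' @param epochs,lr full-batch Adam training schedule.
#' @param seed initialization seed.
#' @return list: \code{params}, \code{recon_heads}, \code{alpha},
#'   \code{w}, \code{alpha_history}, \code{losses} (per-view, before/after).
#' @export
pretrain_aggregator <- function(triples, gate_dim = 16L, hidden = NULL,
                                epochs = 200L, lr = 5e-3, seed = 1L) {
  stopifnot(length(triples) >= 1L)
  d <- ncol(triples[[1]])
  stopifnot(all(vapply(triples, ncol, 0L) == d))
  hidden <- hidden %||% d
  params <- init_gating_params(d, gate_dim, d_out = d, hidden = hidden,
                               n_views = length(triples), seed = seed)
  M <- length(triples)
  recon <- with_seed(seed + 1L, lapply(seq_len(M), function(m) {
    list(R = .init_mat(d, d), r = numeric(d))
  }))
  mv <- list(P = NULL, gate = params, head = NULL, recon = recon)
  per_view_loss <- function(mvp) {
    fw <- .mv_forward(triples, mvp, loss = "recon", targets = triples)
    fw$per_view_loss
  }
  loss_before <- per_view_loss(mv)
  opt <- .adam_new()
  alpha_hist <- matrix(NA_real_, epochs, M)
  fw <- NULL
  for (ep in seq_len(epochs)) {
    fw <- .mv_forward(triples, mv, loss = "recon", targets = triples)
    if (!is.finite(fw$loss)) {
      stop("aggregator pre-training diverged (non-finite loss)")
    }
    gr <- .mv_backward(fw, triples, mv, loss = "recon", targets = triples)
    upd <- .adam_step(opt, mv, gr, lr_groups = c(0, 0, 0, lr))
    mv <- upd$params; opt <- upd$state
    alpha_hist[ep, ] <- fw$alpha
  }
  fw <- .mv_forward(triples, mv, loss = "recon", targets = triples)
  list(params = mv$gate, recon_heads = mv$recon,
       alpha = stats::setNames(fw$alpha, names(triples)),
       w = stats::setNames(fw$w, names(triples)),
       alpha_history = alpha_hist,
       losses = list(before = loss_before, after = fw$per_view_loss))
}
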