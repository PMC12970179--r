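# Training core for the fused model: analytic forward/backward through the
# per-view output projections, the batch gate, the fusion MLP and the task
# or reconstruction heads, with per-parameter-group Adam updates (up to
# four learning rates: one per view encoder projection, one for the
# aggregator + head).

.sigmoid <- function(x) 1 / (1 + exp(-x))

# params: list(P = NULL | list(per view: list(W, b)),
#              gate = gating_params, head = list(C, c0) | NULL,
#              recon = list(per view: list(R, r)) | NULL)
.mv_forward <- function(F_list, params, loss, targets = NULL,
                        frozen_w = NULL) {
  M <- length(F_list)
  Z <- if (is.null(params$P)) F_list else {
    Map(function(F, p) sweep(F %*% t(p$W), 2, p$b, "+"), F_list, params$P)
  }
  B <- nrow(Z[[1]]); d <- ncol(Z[[1]])
  g <- params$gate
  r <- lapply(Z, function(z) sqrt(rowSums(z^2)))
  if (any(unlist(r) < 1e-12)) {
    stop("zero-norm embedding: gate normalization undefined")
  }
  N <- Map(`/`, Z, r)
  U <- lapply(N, function(n) tanh(sweep(n %*% t(g$W), 2, g$b, "+")))
  s <- lapply(U, function(u) drop(u %*% g$q))
  w <- if (is.null(frozen_w)) vapply(s, mean, 0) else as.numeric(frozen_w)
  alpha <- drop(.softmax_rows(matrix(w, 1L)))
  zbar <- Reduce(`+`, Map(`*`, as.list(alpha), Z))
  H <- tanh(sweep(zbar %*% t(g$A), 2, g$a, "+"))
  z_mv <- sweep(H %*% t(g$B), 2, g$b2, "+")
  out <- list(Z = Z, r = r, N = N, U = U, s = s, w = w, alpha = alpha,
              zbar = zbar, H = H, z_mv = z_mv, B = B, M = M, d = d)
  if (loss == "recon") {
    zhat <- Map(function(h) sweep(z_mv %*% t(h$R), 2, h$r, "+"), params$recon)
    pv <- vapply(seq_len(M),
                 function(m) mean((zhat[[m]] - Z[[m]])^2), 0)
    out$zhat <- zhat
    out$per_view_loss <- pv
    out$loss <- mean(pv)
  } else {
    y <- drop(sweep(z_mv %*% t(params$head$C), 2, params$head$c0, "+"))
    out$y <- y
    if (loss == "bce") {
      p <- pmin(pmax(.sigmoid(y), 1e-12), 1 - 1e-12)
      out$p <- p
      out$loss <- -mean(targets * log(p) + (1 - targets) * log(1 - p))
    } else {
      out$loss <- mean((y - targets)^2)
    }
  }
  out
}

.mv_backward <- function(fw, F_list, params, loss, targets) {
  g <- params$gate
  B <- fw$B; M <- fw$M; d <- fw$d
  gr <- list(gate = list(q = 0 * g$q, W = 0 * g$W, b = 0 * g$b,
                         A = 0 * g$A, a = 0 * g$a, B = 0 * g$B,
                         b2 = 0 * g$b2))
  G_zm_extra <- vector("list", M)
  if (loss == "recon") {
    G_mv <- matrix(0, B, nrow(g$B))
    gr$recon <- vector("list", M)
    for (m in seq_len(M)) {
      dz <- 2 * (fw$zhat[[m]] - fw$Z[[m]]) / (B * M * d)
      gr$recon[[m]] <- list(R = t(dz) %*% fw$z_mv, r = colSums(dz))
      G_mv <- G_mv + dz %*% params$recon[[m]]$R
      G_zm_extra[[m]] <- -dz            # z_m as reconstruction target
    }
  } else {
    dY <- if (loss == "bce") (fw$p - targets) / B
    else 2 * (fw$y - targets) / B
    dY <- matrix(dY, ncol = nrow(params$head$C))
    gr$head <- list(C = t(dY) %*% fw$z_mv, c0 = colSums(dY))
    G_mv <- dY %*% params$head$C
  }
  gr$gate$B <- t(G_mv) %*% fw$H
  gr$gate$b2 <- colSums(G_mv)
  G_h <- (G_mv %*% g$B) * (1 - fw$H^2)
  gr$gate$A <- t(G_h) %*% fw$zbar
  gr$gate$a <- colSums(G_h)
  G_zbar <- G_h %*% g$A
  dalpha <- vapply(seq_len(M), function(m) sum(G_zbar * fw$Z[[m]]), 0)
  dw <- fw$alpha * (dalpha - sum(fw$alpha * dalpha))
  G_Z <- vector("list", M)
  for (m in seq_len(M)) {
    G_U <- outer(rep(dw[m] / B, B), g$q)
    Gpre <- G_U * (1 - fw$U[[m]]^2)
    gr$gate$W <- gr$gate$W + t(Gpre) %*% fw$N[[m]]
    gr$gate$b <- gr$gate$b + colSums(Gpre)
    gr$gate$q <- gr$gate$q + colSums(fw$U[[m]]) * dw[m] / B
    G_n <- Gpre %*% g$W
    G_gate_z <- (G_n - fw$N[[m]] * rowSums(G_n * fw$N[[m]])) / fw$r[[m]]
    G_Z[[m]] <- fw$alpha[m] * G_zbar + G_gate_z
    if (!is.null(G_zm_extra[[m]])) G_Z[[m]] <- G_Z[[m]] + G_zm_extra[[m]]
  }
  if (!is.null(params$P)) {
    gr$P <- Map(function(Gz, F) list(W = t(Gz) %*% F, b = colSums(Gz)),
                G_Z, F_list)
  }
  gr
}

# ---- Adam over nested parameter lists --------------------------------------

.adam_new <- function() list(t = 0L, m = NULL, v = NULL)

.tree_zero <- function(a) if (is.list(a)) lapply(a, .tree_zero) else 0 * a

# lr_groups: c(view1, view2, view3, rest); P[[m]] uses group m, everything
# else the last entry
.adam_step <- function(state, params, grads, lr_groups,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (is.null(state$m)) {
    state$m <- .tree_zero(params); state$v <- .tree_zero(params)
  }
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, gset, mset, vset, lr) {
    if (is.list(p)) {
      out_p <- p; out_m <- mset; out_v <- vset
      for (nm in names(p) %||% seq_along(p)) {
        if (is.null(gset[[nm]])) next
        r <- upd(p[[nm]], gset[[nm]], mset[[nm]], vset[[nm]], lr)
        out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      m2 <- beta1 * mset + (1 - beta1) * gset
      v2 <- beta2 * vset + (1 - beta2) * gset^2
      mh <- m2 / (1 - beta1^t); vh <- v2 / (1 - beta2^t)
      list(p = p - lr * mh / (sqrt(vh) + eps), m = m2, v = v2)
    }
  }
  out <- params
  nm_all <- names(grads)
  for (nm in nm_all) {
    if (nm == "P") {
      for (m in seq_along(grads$P)) {
        lr <- lr_groups[min(m, length(lr_groups) - 1L)]
        r <- upd(params$P[[m]], grads$P[[m]], state$m$P[[m]],
                 state$v$P[[m]], lr)
        out$P[[m]] <- r$p; state$m$P[[m]] <- r$m; state$v$P[[m]] <- r$v
      }
    } else {
      lr <- lr_groups[length(lr_groups)]
      r <- upd(params[[nm]], grads[[nm]], state$m[[nm]], state$v[[nm]], lr)
      out[[nm]] <- r$p; state$m[[nm]] <- r$m; state$v[[nm]] <- r$v
    }
  }
  list(params = out, state = state)
}

# ---- Full-batch training with early stopping --------------------------------

.subset_F <- function(F_list, idx) lapply(F_list, function(F) F[idx, ,
                                                                drop = FALSE])

# Train projections + gate + head. Returns best-validation parameters, the
# frozen pre-softmax gate scores recorded on the training batch, and the
# loss history.
train_mv <- function(F_list, y, train_idx, val_idx, params, loss,
                     lr_groups, epochs = 100L, patience = 10L) {
  Ftr <- .subset_F(F_list, train_idx); ytr <- y[train_idx]
  Fva <- .subset_F(F_list, val_idx); yva <- y[val_idx]
  opt <- .adam_new()
  best <- list(loss = Inf, params = params, epoch = 0L)
  hist <- data.frame(epoch = integer(0), train = numeric(0),
                     val = numeric(0))
  wait <- 0L
  for (ep in seq_len(epochs)) {
    fw <- .mv_forward(Ftr, params, loss, ytr)
    if (!is.finite(fw$loss)) stop("training diverged (non-finite loss)")
    gr <- .mv_backward(fw, Ftr, params, loss, ytr)
    st <- .adam_step(opt, params, gr, lr_groups)
    params <- st$params; opt <- st$state
    va <- .mv_forward(Fva, params, loss, yva)
    hist <- rbind(hist, data.frame(epoch = ep, train = fw$loss,
                                   val = va$loss))
    if (va$loss < best$loss - 1e-9) {
      best <- list(loss = va$loss, params = params, epoch = ep)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  final <- .mv_forward(Ftr, best$params, loss, ytr)
  list(params = best$params,
       w_frozen = stats::setNames(final$w, names(F_list)),
       alpha = stats::setNames(final$alpha, names(F_list)),
       history = hist, best_epoch = best$epoch)
}

# frozen-gate prediction; returns scores (sigmoid-mapped for bce)
predict_mv <- function(F_list, params, w_frozen, loss) {
  fw <- .mv_forward(F_list, params, loss = "mse",
                    targets = numeric(nrow(F_list[[1]])),
                    frozen_w = w_frozen)
  if (loss == "bce") .sigmoid(fw$y) else fw$y
}
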