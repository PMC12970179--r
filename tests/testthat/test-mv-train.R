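# Training core: analytic gradients vs finite differences, learning-rate
# groups, early stopping determinism.

finite_diff <- function(F_list, params, loss, y, get, set, eps = 1e-6) {
  p2 <- set(params, get(params) + eps)
  p3 <- set(params, get(params) - eps)
  (molfuse:::.mv_forward(F_list, p2, loss, y)$loss -
     molfuse:::.mv_forward(F_list, p3, loss, y)$loss) / (2 * eps)
}

test_that("analytic gradients match finite differences for both losses", {
  set.seed(42)
  B <- 5L; p <- c(4L, 3L, 6L); d <- 3L
  F_list <- lapply(p, function(pp) matrix(rnorm(B * pp), B, pp))
  cfg <- structure(list(d = d, gate_dim = 2L, hidden = 4L),
                   class = "multiview_config")
  params <- molfuse:::.init_mv_params(cfg, p, seed = 7L)
  for (loss in c("bce", "mse")) {
    y <- if (loss == "bce") rbinom(B, 1, 0.5) else rnorm(B)
    fw <- molfuse:::.mv_forward(F_list, params, loss, y)
    gr <- molfuse:::.mv_backward(fw, F_list, params, loss, y)
    probes <- list(
      list(g = function(p) p$gate$q[1],
           s = function(p, v) { p$gate$q[1] <- v; p },
           a = gr$gate$q[1]),
      list(g = function(p) p$gate$W[1, 2],
           s = function(p, v) { p$gate$W[1, 2] <- v; p },
           a = gr$gate$W[1, 2]),
      list(g = function(p) p$gate$A[2, 3],
           s = function(p, v) { p$gate$A[2, 3] <- v; p },
           a = gr$gate$A[2, 3]),
      list(g = function(p) p$P[[2]]$W[2, 1],
           s = function(p, v) { p$P[[2]]$W[2, 1] <- v; p },
           a = gr$P[[2]]$W[2, 1]),
      list(g = function(p) p$head$C[1, 2],
           s = function(p, v) { p$head$C[1, 2] <- v; p },
           a = gr$head$C[1, 2]))
    for (pr in probes) {
      expect_equal(pr$a, finite_diff(F_list, params, loss, y, pr$g, pr$s),
                   tolerance = 1e-5)
    }
  }
})

test_that("reconstruction gradients are exact too", {
  set.seed(9)
  B <- 6L; d <- 4L
  Z <- lapply(1:3, function(m) matrix(rnorm(B * d), B, d))
  gate <- init_gating_params(d, gate_dim = 3L, d_out = d, hidden = d,
                             seed = 4L)
  recon <- lapply(1:3, function(m)
    list(R = matrix(rnorm(d * d, sd = 0.5), d, d), r = numeric(d)))
  params <- list(P = NULL, gate = gate, recon = recon)
  fw <- molfuse:::.mv_forward(Z, params, "recon", Z)
  gr <- molfuse:::.mv_backward(fw, Z, params, "recon", Z)
  fd <- finite_diff(Z, params, "recon", Z,
                    function(p) p$recon[[2]]$R[1, 2],
                    function(p, v) { p$recon[[2]]$R[1, 2] <- v; p })
  expect_equal(gr$recon[[2]]$R[1, 2], fd, tolerance = 1e-5)
  fd2 <- finite_diff(Z, params, "recon", Z,
                     function(p) p$gate$W[2, 1],
                     function(p, v) { p$gate$W[2, 1] <- v; p })
  expect_equal(gr$gate$W[2, 1], fd2, tolerance = 1e-5)
})

test_that("zero learning rates leave parameter groups untouched", {
  set.seed(10)
  B <- 20L; p <- c(4L, 5L); d <- 3L
  F_list <- lapply(p, function(pp) matrix(rnorm(B * pp), B, pp))
  y <- rnorm(B)
  cfg <- structure(list(d = d, gate_dim = 2L, hidden = 3L),
                   class = "multiview_config")
  params <- molfuse:::.init_mv_params(cfg, p, seed = 3L)
  tr <- molfuse:::train_mv(F_list, y, 1:15, 16:20, params, "mse",
                           lr_groups = c(0, 0, 0), epochs = 3L,
                           patience = 10L)
  expect_equal(tr$params, params, tolerance = 1e-14)
  # only the first view's projection frozen
  tr2 <- molfuse:::train_mv(F_list, y, 1:15, 16:20, params, "mse",
                            lr_groups = c(0, 1e-2, 1e-2), epochs = 3L,
                            patience = 10L)
  expect_equal(tr2$params$P[[1]], params$P[[1]], tolerance = 1e-14)
  expect_gt(max(abs(tr2$params$P[[2]]$W - params$P[[2]]$W)), 0)
})

test_that("training is deterministic and early stopping returns best epoch", {
  set.seed(11)
  B <- 40L; p <- c(4L, 5L); d <- 3L
  F_list <- lapply(p, function(pp) matrix(rnorm(B * pp), B, pp))
  y <- F_list[[1]][, 1] + 0.1 * rnorm(B)
  cfg <- structure(list(d = d, gate_dim = 2L, hidden = 3L),
                   class = "multiview_config")
  params <- molfuse:::.init_mv_params(cfg, p, seed = 3L)
  run <- function() molfuse:::train_mv(F_list, y, 1:30, 31:40, params,
                                       "mse", lr_groups = c(5e-3, 5e-3,
                                                            5e-3),
                                       epochs = 50L, patience = 5L)
  a <- run(); b <- run()
  expect_identical(a$params, b$params)
  expect_identical(a$w_frozen, b$w_frozen)
  expect_lte(a$best_epoch, nrow(a$history))
  expect_lt(a$history$train[nrow(a$history)], a$history$train[1])
})
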