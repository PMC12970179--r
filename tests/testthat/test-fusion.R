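# Gated late fusion: gate arithmetic against an independent oracle,
# softmax invariances, alternative schemes, aggregator pre-training.

test_that("gate weights match an independent arithmetic oracle", {
  params <- init_gating_params(d = 2L, gate_dim = 3L, d_out = 2L,
                               hidden = 2L, seed = 21L)
  set.seed(22)
  Z <- lapply(1:3, function(m) matrix(rnorm(4), 2L, 2L))   # batch 2, 2-D
  out <- fuse_views(Z, params)
  oracle <- gate_oracle(Z, params$q, params$W, params$b)
  expect_equal(unname(out$alpha), oracle$alpha, tolerance = 1e-10)
  expect_equal(unname(out$w), oracle$w, tolerance = 1e-10)
  expect_equal(sum(out$alpha), 1, tolerance = 1e-12)
  expect_equal(dim(out$z_mv), c(2L, 2L))
})

test_that("degenerate view sets give the symmetric gate weights", {
  params <- init_gating_params(d = 4L, seed = 2L)
  set.seed(3)
  Z1 <- matrix(rnorm(12), 3L, 4L)
  one <- fuse_views(list(only = Z1), params)
  expect_equal(unname(one$alpha), 1)
  two <- fuse_views(list(a = Z1, b = Z1), params)
  expect_equal(unname(two$alpha), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("gate is invariant to batch order, score shifts and view scale", {
  params <- init_gating_params(d = 5L, gate_dim = 4L, seed = 31L)
  for (case in 1:100) {
    set.seed(case)
    B <- sample(2:6, 1L)
    Z <- lapply(1:3, function(m) matrix(rnorm(B * 5), B, 5L))
    out <- fuse_views(Z, params)
    expect_equal(sum(out$alpha), 1, tolerance = 1e-12)
    expect_true(all(out$alpha > 0))
    # batch order: w is a mean over the batch
    perm <- sample(B)
    out_p <- fuse_views(lapply(Z, function(z) z[perm, , drop = FALSE]),
                        params)
    expect_equal(out_p$alpha, out$alpha, tolerance = 1e-12)
    # per-view positive rescaling: W z / ||z|| is scale-free
    cs <- runif(3, 0.1, 10)
    out_s <- fuse_views(Map(`*`, cs, Z), params)
    expect_equal(out_s$alpha, out$alpha, tolerance = 1e-10)
    # adding a constant to all scores leaves the softmax unchanged
    shifted <- fuse_views(Z, params, frozen_w = out$w + 3.7)
    expect_equal(shifted$alpha, out$alpha, tolerance = 1e-12)
  }
})

test_that("zero-norm embeddings are rejected explicitly", {
  params <- init_gating_params(d = 3L, seed = 1L)
  Z <- list(a = matrix(0, 2L, 3L), b = matrix(1, 2L, 3L),
            c = matrix(1, 2L, 3L))
  expect_error(fuse_views(Z, params), "zero-norm")
})

test_that("alternative schemes compute the stated gate input dimensions", {
  expect_equal(alt_fusion_config("unprojected_gating",
                                 c(256L, 256L, 256L))$D, 768L)
  expect_equal(alt_fusion_config("projected_gating",
                                 c(256L, 512L, 768L))$D, 768L)
  cfgs <- list(
    alt_fusion_config("projected_gating", c(8L, 12L, 6L)),
    alt_fusion_config("unprojected_gating", c(8L, 12L, 6L)),
    alt_fusion_config("projected_gating_feature_addition", c(8L, 12L, 6L)))
  set.seed(9)
  Z <- list(a = matrix(rnorm(40), 5L, 8L), b = matrix(rnorm(60), 5L, 12L),
            c = matrix(rnorm(30), 5L, 6L))
  for (cfg in cfgs) {
    p <- init_alt_fusion_params(cfg, seed = 10L)
    out <- alt_fuse(Z, cfg, p)
    expect_equal(rowSums(out$weights), rep(1, 5L), tolerance = 1e-12)
    expect_equal(out$w_bar, colMeans(out$weights))
    if (cfg$scheme == "projected_gating_feature_addition") {
      expect_equal(ncol(out$z_final), cfg$d_proj)
    } else {
      expect_equal(ncol(out$z_final), sum(cfg$dims))
    }
  }
  # convexity: equal weights and equal (projected) inputs reproduce the input
  cfg3 <- alt_fusion_config("projected_gating_feature_addition",
                            c(6L, 6L, 6L))
  p3 <- init_alt_fusion_params(cfg3, seed = 2L)
  p3$gate_W[] <- 0; p3$gate_b[] <- 0          # uniform weights
  for (m in 1:3) p3$proj[[m]] <- diag(6L)      # identity projections
  z <- matrix(rnorm(18), 3L, 6L)
  same <- alt_fuse(list(z, z, z), cfg3, p3)
  expect_equal(same$z_final, z, tolerance = 1e-12)
  expect_error(alt_fuse(list(z, z, z[, 1:3]), cfgs[[1]], p3), "mismatch")
})

test_that("aggregator reconstruction pre-training descends and ranks a
           pure-noise view lowest", {
  set.seed(1)
  N <- 120L; d <- 6L
  S <- matrix(rnorm(N * d), N, d)
  for (seed in 1:3) {
    set.seed(seed)
    triples <- list(a = S + 0.3 * matrix(rnorm(N * d), N, d),
                    b = S + 0.3 * matrix(rnorm(N * d), N, d),
                    noise = matrix(rnorm(N * d), N, d))
    pa <- pretrain_aggregator(triples, epochs = 250L, lr = 5e-3,
                              seed = seed)
    expect_lt(mean(pa$losses$after), mean(pa$losses$before))
    expect_equal(which.min(pa$alpha), 3L, ignore_attr = TRUE)
    expect_equal(sum(pa$alpha), 1, tolerance = 1e-12)
  }
  # identity-realizable optimum: all three views equal and noiseless
  same <- list(a = S[1:40, ], b = S[1:40, ], c = S[1:40, ])
  pa0 <- pretrain_aggregator(same, epochs = 400L, lr = 1e-2, seed = 5L)
  expect_lt(mean(pa0$losses$after), 0.1 * mean(pa0$losses$before))
})
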