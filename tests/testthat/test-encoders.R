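# Per-view encoders: shape/determinism contracts, pooling symmetry,
# attention extraction, one-step learning sanity.

small_graph_cfg <- function() encoder_config("graph", embed_dim = 32L,
                                             feature_embed_dim = 8L,
                                             output_dim = 16L, pe_k = 4L,
                                             seed = 3L)

test_that("default encoder widths match the published embedding sizes", {
  expect_equal(encoder_config("graph")$embed_dim, 512L)
  expect_equal(encoder_config("graph")$feature_embed_dim, 128L)
  expect_equal(encoder_config("text")$embed_dim, 768L)
})

test_that("graph encoder: shape, determinism, permutation symmetry", {
  cfg <- small_graph_cfg()
  p <- init_encoder_params(cfg)
  gv <- laplacian_pe(featurize_graph("CC(=O)Oc1ccccc1C(=O)O"), k = 4L)
  e1 <- encode_graph(gv, cfg, p)
  expect_length(e1$z, 16L)
  expect_true(all(is.finite(e1$z)))
  expect_identical(e1$z, encode_graph(gv, cfg, p)$z)
  expect_error(encode_graph(featurize_graph("CCO"), cfg, p), "Laplacian")
  # permuting node order (with consistently permuted PE) leaves the pooled
  # embedding unchanged up to numerics
  set.seed(8)
  perm <- sample(gv$n_nodes)
  e2 <- encode_graph(permute_graph_view(gv, perm), cfg, p)
  expect_lt(max(abs(e1$z - e2$z)), 1e-5)
  # feature masking changes the embedding (sentinel rows are distinct)
  e3 <- encode_graph(gv, cfg, p, masked_tokens = 1:5)
  expect_gt(max(abs(e1$z - e3$z)), 1e-8)
})

test_that("text encoder: id validation and pad invariance", {
  cfg <- encoder_config("text", embed_dim = 32L, output_dim = 16L, seed = 4L)
  p <- init_encoder_params(cfg)
  tv <- tokenize_smiles("CC(=O)Oc1ccccc1")
  e <- encode_text(tv, cfg, p)
  expect_length(e$z, 16L)
  padded <- tv
  pad_id <- match("<pad>", tv$vocab)
  padded$tokens <- c(tv$tokens, rep("<pad>", 7L))
  padded$token_ids <- c(tv$token_ids, rep(pad_id, 7L))
  expect_equal(encode_text(padded, cfg, p)$z, e$z, tolerance = 1e-12)
  bad <- tv; bad$token_ids[1] <- cfg$vocab_size + 10L
  expect_error(encode_text(bad, cfg, p), "vocabulary")
})

test_that("image encoder: spatial contract and numeric hygiene", {
  cfg <- encoder_config("image", channels = c(6L, 12L), output_dim = 16L,
                        seed = 5L)
  p <- init_encoder_params(cfg)
  iv <- render_image("Cc1ccc(O)cc1", mode = "eval")
  e <- encode_image(iv, cfg, p)
  expect_length(e$z, 16L)
  small <- iv; small$pixels <- iv$pixels[1:100, 1:100, , drop = FALSE]
  expect_error(encode_image(small, cfg, p), "224")
  zero <- iv; zero$pixels <- array(0, c(224, 224, 3))
  expect_true(all(is.finite(encode_image(zero, cfg, p)$z)))
})

test_that("attention weights are a distribution over tokens", {
  cfg <- small_graph_cfg()
  p <- init_encoder_params(cfg)
  gv <- laplacian_pe(featurize_graph("O=[N+]([O-])c1ccccc1"), k = 4L)
  e <- encode_graph(gv, cfg, p, record_attention = TRUE)
  w <- extract_attention(e)
  expect_length(w, gv$n_nodes + gv$n_edges)
  expect_true(all(w >= 0))
  expect_equal(sum(w), 1, tolerance = 1e-6)
  single <- laplacian_pe(featurize_graph("C"), k = 4L)
  ws <- extract_attention(encode_graph(single, cfg, p,
                                       record_attention = TRUE))
  expect_equal(ws, 1)
  e_off <- encode_graph(gv, cfg, p)
  expect_error(extract_attention(e_off), "recording")
})

test_that("one optimization step decreases the loss for every encoder", {
  tab <- small_library()
  sub <- dataset_table(tab$records[1:2, ], tab$labels[1:2],
                       "classification", "tiny")
  for (v in c("graph", "image", "text")) {
    cfg <- multiview_config(views = v)
    feats <- view_features(sub, cfg)
    params <- molfuse:::.init_mv_params(cfg, vapply(feats, ncol, 0L),
                                        seed = 1L)
    F1 <- lapply(feats, function(F) F[1, , drop = FALSE])
    y1 <- tab$labels[1]
    fw0 <- molfuse:::.mv_forward(F1, params, "bce", y1)
    gr <- molfuse:::.mv_backward(fw0, F1, params, "bce", y1)
    st <- molfuse:::.adam_step(molfuse:::.adam_new(), params, gr,
                               lr_groups = c(1e-2, 1e-2))
    fw1 <- molfuse:::.mv_forward(F1, st$params, "bce", y1)
    expect_lt(fw1$loss, fw0$loss)
  }
})

test_that("encoder checkpoints round-trip through the text format", {
  cfg <- small_graph_cfg()
  p <- init_encoder_params(cfg)
  path <- withr::local_tempfile(fileext = ".json")
  save_encoder(p, cfg, path)
  back <- load_encoder(path)
  expect_equal(back$config$embed_dim, cfg$embed_dim)
  gv <- laplacian_pe(featurize_graph("CCO"), k = 4L)
  expect_equal(encode_graph(gv, cfg, back$params)$z,
               encode_graph(gv, cfg, p)$z, tolerance = 1e-12)
})
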