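# Graph/image/text view construction.

test_that("SMILES tokenizer splits into chemical units and round-trips", {
  expect_identical(tokenize_smiles("C=O")$tokens, c("C", "=", "O"))
  benz <- tokenize_smiles("c1ccccc1")
  expect_length(benz$tokens, 8L)            # 6 aromatic atoms + 2 closures
  expect_identical(tokenize_smiles("[nH]")$tokens, "[nH]")
  expect_error(tokenize_smiles(""), "empty")
  smis <- small_library()$records$canonical_smiles
  for (s in smis[1:30]) {
    expect_identical(detokenize(tokenize_smiles(s)), s)
  }
  expect_warning(v <- tokenize_smiles("CC!O"), "unk")
  expect_true("<unk>" %in% v$tokens)
  expect_identical(detokenize(v), "CC!O")   # surface is preserved even so
})

test_that("graph featurization yields one token per atom and per bond", {
  benz <- featurize_graph("c1ccccc1")
  expect_equal(benz$n_nodes, 6L)
  expect_equal(benz$n_edges, 6L)
  expect_length(benz$token_kind, 12L)
  expect_named(benz$node_features,
               c("atomic_number", "chirality", "degree", "formal_charge",
                 "hybridization"))
  expect_named(benz$edge_features,
               c("bond_type", "bond_dir", "stereo", "conjugated", "in_ring"))
  methane <- featurize_graph("C")
  expect_equal(methane$n_nodes, 1L)
  expect_equal(methane$n_edges, 0L)
  ethane <- featurize_graph("CC")
  expect_false(ethane$edge_features$bond_type[1] ==
                 benz$edge_features$bond_type[1])
})

test_that("node feature multiset is invariant to SMILES atom ordering", {
  a <- featurize_graph("Cc1ccccc1")
  b <- featurize_graph("c1ccccc1C")
  srt <- function(df) df[do.call(order, df), , drop = FALSE]
  expect_equal(unname(as.matrix(srt(a$node_features))),
               unname(as.matrix(srt(b$node_features))))
  expect_equal(unname(as.matrix(srt(a$edge_features))),
               unname(as.matrix(srt(b$edge_features))))
})

test_that("Laplacian PE matches closed-form cycle spectrum and pads", {
  benz <- laplacian_pe(featurize_graph("c1ccccc1"), k = 8L)
  closed_form <- sort(2 - 2 * cos(2 * pi * (0:5) / 6))
  expect_equal(benz$laplacian_eigenvalues[1:6], closed_form,
               tolerance = 1e-10)
  expect_equal(benz$laplacian_eigenvalues[7:8], c(0, 0))   # zero padding
  expect_equal(dim(benz$laplacian_eigenvectors), c(6L, 8L))
  # sign convention: first nonzero component positive
  for (j in 1:6) {
    v <- benz$laplacian_eigenvectors[, j]
    nz <- which(abs(v) > 1e-8)
    expect_gt(v[nz[1]], 0)
  }
  # connected molecule: exactly one zero eigenvalue
  asp <- laplacian_pe(featurize_graph("CC(=O)Oc1ccccc1C(=O)O"), k = 8L)
  expect_equal(sum(abs(asp$laplacian_eigenvalues[1:8]) < 1e-8 &
                     seq_len(8) <= asp$n_nodes), 1L)
  # two disjoint triangles: two zero eigenvalues
  two <- laplacian_pe(featurize_graph("C1CC1.C1CC1"), k = 6L)
  expect_equal(sum(abs(two$laplacian_eigenvalues) < 1e-8), 2L)
})

test_that("zero-eigenvalue multiplicity equals the component count beta0", {
  for (seed in 1:25) {
    g <- random_graph(seed, max_nodes = 15L)
    gv <- laplacian_pe(make_graph_view(g), k = igraph::vcount(g))
    zeros <- sum(abs(gv$laplacian_eigenvalues) < 1e-8)
    expect_equal(zeros, unname(graph_betti(g)["b0"]))
  }
})

test_that("image rendering is 224x224, seeded, and flip is an involution", {
  iv <- render_image("Cc1ccc(O)cc1", mode = "eval")
  expect_equal(dim(iv$pixels), c(224L, 224L, 3L))
  lo <- (0 - image_norm_constants$mean[1]) / image_norm_constants$sd[1]
  hi <- (1 - image_norm_constants$mean[1]) / image_norm_constants$sd[1]
  expect_true(all(iv$pixels >= lo - 1e-12 & iv$pixels <= hi + 1e-12))
  t1 <- render_image("Cc1ccc(O)cc1", mode = "train", seed = 9L)
  t2 <- render_image("Cc1ccc(O)cc1", mode = "train", seed = 9L)
  expect_identical(t1$pixels, t2$pixels)
  base <- render_image("Cc1ccc(O)cc1", mode = "train",
                       augment = list(dx = 4L, dy = 4L, flip = FALSE))
  flip <- render_image("Cc1ccc(O)cc1", mode = "train",
                       augment = list(dx = 4L, dy = 4L, flip = TRUE))
  expect_identical(flip$pixels[, 224:1, ], base$pixels)
  err <- tryCatch(render_image("xy((z"), error = function(e) e)
  expect_true(inherits(err, "molfuse_render_error") ||
                inherits(err, "molfuse_invalid_molecule"))
})
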