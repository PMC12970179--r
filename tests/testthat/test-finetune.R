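# Splitting, metric scaling, fine-tuning orchestration, agreement, ranking.

test_that("splits are disjoint, exhaustive, and scaffold-leakage free", {
  tab <- small_library()
  keys <- scaffold_keys(tab$records$canonical_smiles)
  for (method in c("random", "size_ordered_scaffold", "balanced_scaffold")) {
    sp <- split_dataset(tab, method, seed = 17L, keys = keys)
    expect_false(anyNA(sp$partition))
    expect_setequal(unique(sp$partition),
                    intersect(c("train", "validation", "test"),
                              sp$partition))
    if (method != "random") {
      cl <- ifelse(keys == "", paste0("s", seq_along(keys)), keys)
      spans <- tapply(sp$partition, cl, function(p) length(unique(p)))
      expect_true(all(spans == 1L))
    }
  }
})

test_that("singleton scaffolds fill the 0.8/0.1/0.1 partitions exactly", {
  spec <- synthesis_spec(n_molecules = 100L, scaffold_pool = "acyclic",
                         seed = 23L)
  tab <- gen_molecules(spec)
  keys <- scaffold_keys(tab$records$canonical_smiles)
  expect_true(all(keys == ""))
  sp <- split_dataset(tab, "size_ordered_scaffold", c(0.8, 0.1, 0.1),
                      seed = 1L, keys = keys)
  expect_equal(unname(table(sp$partition)[c("train", "validation", "test")]),
               c(80L, 10L, 10L), ignore_attr = TRUE)
})

test_that("balanced split forces oversized clusters into train", {
  # all molecules share the benzene scaffold -> single cluster -> train
  smis <- paste0(c("C", "CC", "CCC", "CCCC", "O", "OC", "N", "CCO",
                   "CCCCC", "F"), "c1ccccc1")
  tab <- dataset_table(parse_and_canonicalize(smis))
  w <- capture_warnings(sp <- split_dataset(tab, "balanced_scaffold",
                                            seed = 2L))
  expect_true(any(grepl("single scaffold", w)))
  expect_true(any(grepl("empty test", w)))
  expect_true(all(sp$partition == "train"))
})

test_that("metric scaling reproduces the registry and inverts cleanly", {
  cases <- list(esol = 0.7, freesolv = 1.5, lipophilicity = 0.50,
                qm7 = 55.0, computational_adme = 0.30)
  for (nm in names(cases)) {
    p <- scaled_metric_params(nm)
    expect_equal(scale_metric(cases[[nm]], p), 1.0)      # m = m0 -> 1
    m <- cases[[nm]] + 0.37 * p$s
    expect_equal(unscale_metric(scale_metric(m, p), p), m,
                 tolerance = 1e-12)
    expect_lt(scale_metric(m + p$s, p), scale_metric(m, p)) # decreasing
  }
  expect_equal(scale_metric(75, scaled_metric_params("qm7")), 0.8)
})

test_that("model agreement statistics follow their closed forms", {
  expect_equal(model_agreement(c(1, 1, 0, 0), c(1, 1, 0, 0),
                               "classification")$f1, 1.0)
  a <- rep(1, 8); b <- c(rep(1, 4), rep(0, 4))
  suppressWarnings(ag <- model_agreement(a, b, "classification"))
  expect_equal(ag$precision, 1.0)
  expect_equal(ag$recall, 0.5)
  expect_equal(ag$f1, 2 / 3)
  x <- rnorm(30)
  reg <- model_agreement(x, x, "regression")
  expect_equal(reg$pearson, 1.0)
  expect_lt(reg$p_value, 1e-6)
  expect_error(model_agreement(1:3, 1:4, "classification"))
})

test_that("fine-tuning reports seed-averaged metrics deterministically", {
  tab <- study_table()
  sub <- dataset_table(tab$records[1:150, ], tab$labels[1:150],
                       "classification", "mini")
  cfg <- multiview_config(views = c("graph", "text"))
  feats <- view_features(sub, cfg)
  sp <- split_dataset(sub, "random", seed = 4L)
  mod <- finetune_task(sub, sp, cfg, optim_config(epochs = 40L),
                       seeds = 1:2, features = feats)
  expect_s3_class(mod$report, "metric_report")
  expect_equal(mod$report$n_seeds, 2L)
  expect_true(mod$report$mean["roc_auc"] >= 0 &&
                mod$report$mean["roc_auc"] <= 1)
  expect_length(mod$alpha, 2L)
  expect_equal(sum(mod$alpha), 1, tolerance = 1e-12)
  # bit-identical rerun with the same seeds
  mod2 <- finetune_task(sub, sp, cfg, optim_config(epochs = 40L),
                        seeds = 1:2, features = feats)
  expect_identical(mod$report$per_seed, mod2$report$per_seed)
  expect_identical(mod$w_frozen, mod2$w_frozen)
})

test_that("screen ranking is deterministic, tie-broken, and recovers the
           trained-on substructure", {
  tab <- study_table()
  sub <- dataset_table(tab$records[1:300, ], tab$labels[1:300],
                       "classification", "screen_train")
  cfg <- multiview_config(views = c("graph", "text"))
  feats <- view_features(sub, cfg)
  sp <- split_dataset(sub, "random", seed = 5L)
  mod <- finetune_task(sub, sp, cfg, optim_config(epochs = 60L),
                       seeds = 1L, features = feats)
  # library: mostly negatives plus one marker-bearing molecule
  neg <- which(sub$labels == 0)[1:49]
  pos <- which(sub$labels == 1)[1]
  lib_idx <- c(neg, pos)
  lib <- dataset_table(sub$records[lib_idx, ], task_kind = "classification")
  lib_feats <- lapply(feats, function(F) F[lib_idx, , drop = FALSE])
  out <- rank_screen(mod, lib, top_k = 100L, features = lib_feats)
  expect_equal(nrow(out$ranking), 50L)       # top_k capped at library size
  hot <- sub$records$canonical_smiles[pos]
  expect_lte(which(out$ranking$smiles == hot), 5L)  # top decile of 50
  out2 <- rank_screen(mod, lib, top_k = 100L, features = lib_feats)
  expect_identical(out$ranking, out2$ranking)
  expect_equal(sum(out$alpha), 1, tolerance = 1e-12)
})
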