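# Dataset splitting (random / size-ordered scaffold / balanced scaffold),
# metric scaling, fine-tuning with per-subnetwork learning rates,
# model-agreement analysis, and screen ranking.

#' Split a dataset into train/validation/test
#'
#' \describe{
#'   \item{random}{seeded permutation sliced to the target counts.}
#'   \item{size_ordered_scaffold}{molecules are clustered by Murcko
#'     scaffold (acyclic molecules form singleton clusters) and clusters
#'     are assigned in descending size order, filling train to capacity,
#'     then validation, then test.}
#'   \item{balanced_scaffold}{clusters larger than the test-partition
#'     target size are forced into train; the remaining clusters are
#'     shuffled by seed and fill test, then validation, then train.}
#' }
#' In both scaffold methods no scaffold key ever spans two partitions.
#'
#' @param table a \code{dataset_table}.
#' @param method split method.
#' @param ratios train/validation/test fractions summing to 1.
#' @param seed integer seed.
#' @param keys optional precomputed scaffold keys (skips recomputation).
#' @return object of class \code{split_assignment}: \code{partition}
#'   (character vector \code{"train"/"validation"/"test"} per record),
#'   \code{method}, \code{ratios}, \code{seed}, \code{scaffold_keys}.
#' @export
split_dataset <- function(table,
                          method = c("random", "size_ordered_scaffold",
                                     "balanced_scaffold"),
                          ratios = c(0.8, 0.1, 0.1), seed = 1L,
                          keys = NULL) {
  method <- match.arg(method)
  stopifnot(abs(sum(ratios) - 1) < 1e-8, length(ratios) == 3L)
  n <- nrow(table$records)
  stopifnot(n >= 3L)
  cap_train <- round(ratios[1] * n)
  cap_val <- round(ratios[2] * n)
  cap_test <- n - cap_train - cap_val
  part <- rep(NA_character_, n)
  if (method == "random") {
    perm <- with_seed(seed, sample.int(n))
    part[perm[seq_len(cap_train)]] <- "train"
    part[perm[cap_train + seq_len(cap_val)]] <- "validation"
    part[perm[cap_train + cap_val + seq_len(cap_test)]] <- "test"
    keys <- NULL
  } else {
    if (is.null(keys)) keys <- scaffold_keys(table$records$canonical_smiles)
    cluster_id <- ifelse(keys == "" | is.na(keys),
                         paste0("singleton_", seq_len(n)), keys)
    clusters <- split(seq_len(n), cluster_id)
    sizes <- lengths(clusters)
    if (length(clusters) == 1L) {
      warning("single scaffold cluster: everything assigned to train")
    }
    counts <- c(train = 0L, validation = 0L, test = 0L)
    assign_to <- function(ix, p) {
      part[ix] <<- p
      counts[p] <<- counts[p] + length(ix)
    }
    if (method == "size_ordered_scaffold") {
      ord <- order(-sizes)
      for (ci in ord) {
        ix <- clusters[[ci]]
        if (counts["train"] + length(ix) <= cap_train) assign_to(ix, "train")
        else if (counts["validation"] + length(ix) <= cap_val)
          assign_to(ix, "validation")
        else if (counts["test"] + length(ix) <= cap_test)
          assign_to(ix, "test")
        else assign_to(ix, "train")
      }
    } else {                                   # balanced_scaffold
      big <- sizes > cap_test
      for (ci in which(big)) assign_to(clusters[[ci]], "train")
      rest <- which(!big)
      rest <- with_seed(seed, rest[sample.int(length(rest))])
      for (ci in rest) {
        ix <- clusters[[ci]]
        if (counts["test"] + length(ix) <= cap_test) assign_to(ix, "test")
        else if (counts["validation"] + length(ix) <= cap_val)
          assign_to(ix, "validation")
        else assign_to(ix, "train")
      }
      if (counts["test"] == 0L) {
        warning("balanced scaffold split produced an empty test partition")
      }
    }
  }
  structure(list(partition = part, method = method, ratios = ratios,
                 seed = as.integer(seed), scaffold_keys = keys),
            class = "split_assignment")
}

#' Write a split assignment to CSV
#' @param split a \code{split_assignment}.
#' @param table the matching \code{dataset_table}.
#' @param path output path.
#' @export
write_split <- function(split, table, path) {
  utils::write.csv(data.frame(smiles = table$records$canonical_smiles,
                              partition = split$partition),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- Metric scaling ---------------------------------------------------------

.metric_registry <- list(
  esol = c(m0 = 0.7, s = 1.0),
  freesolv = c(m0 = 1.5, s = 5.0),
  lipophilicity = c(m0 = 0.50, s = 1.0),
  qm7 = c(m0 = 55.0, s = 100.0),
  computational_adme = c(m0 = 0.30, s = 1.0))

#' Scaled-metric parameters for the benchmark registry
#'
#' Offset/scale pairs (m0, s) used to place regression metrics from
#' different datasets on a common axis via m' = 1 - (m - m0)/s.
#'
#' @param dataset one of \code{"esol"}, \code{"freesolv"},
#'   \code{"lipophilicity"}, \code{"qm7"}, \code{"computational_adme"}.
#' @return list of class \code{scaled_metric_params} with \code{m0}, \code{s}.
#' @export
scaled_metric_params <- function(dataset = names(.metric_registry)) {
  dataset <- match.arg(dataset)
  p <- .metric_registry[[dataset]]
  structure(list(m0 = unname(p["m0"]), s = unname(p["s"]),
                 dataset = dataset), class = "scaled_metric_params")
}

#' Scale a regression metric
#'
#' m' = 1 - (m - m0)/s; affine and invertible
#' (\code{\link{unscale_metric}}), strictly decreasing in m, with
#' m = m0 mapping to 1.
#'
#' @param m unscaled metric value.
#' @param params a \code{scaled_metric_params} (or list with m0, s).
#' @return scaled value m'.
#' @export
scale_metric <- function(m, params) {
  stopifnot(params$s > 0)
  1 - (m - params$m0) / params$s
}

#' @rdname scale_metric
#' @param m_prime scaled metric value.
#' @export
unscale_metric <- function(m_prime, params) {
  stopifnot(params$s > 0)
  params$m0 + (1 - m_prime) * params$s
}

# ---- View featurization -----------------------------------------------------

#' Desk-scale model configuration for fine-tuning
#'
#' Small encoder widths keep the full pipeline tractable on one CPU while
#' preserving every architectural element (transformers over graph/text
#' tokens, residual CNN, gate, MLP head).
#'
#' @param views views to include.
#' @param d shared fused embedding dimension.
#' @param gate_dim,hidden gate / MLP widths.
#' @param graph_embed,text_embed,feature_embed,channels,pe_k encoder sizes.
#' @param backbone_seed seed for the frozen encoder backbones.
#' @return list of class \code{multiview_config}.
#' @export
multiview_config <- function(views = c("graph", "image", "text"),
                             d = 32L, gate_dim = 16L, hidden = 32L,
                             graph_embed = 48L, text_embed = 48L,
                             feature_embed = 16L, channels = c(12L, 24L),
                             pe_k = 8L, backbone_seed = 2024L) {
  views <- match.arg(views, several.ok = TRUE)
  cfgs <- list()
  if ("graph" %in% views) {
    cfgs$graph <- encoder_config("graph", embed_dim = graph_embed,
                                 feature_embed_dim = feature_embed,
                                 output_dim = d, pe_k = pe_k,
                                 seed = backbone_seed)
  }
  if ("image" %in% views) {
    cfgs$image <- encoder_config("image", channels = channels,
                                 output_dim = d, seed = backbone_seed + 1L)
  }
  if ("text" %in% views) {
    cfgs$text <- encoder_config("text", embed_dim = text_embed,
                                 output_dim = d, seed = backbone_seed + 2L)
  }
  structure(list(views = views, d = d, gate_dim = gate_dim, hidden = hidden,
                 encoder_configs = cfgs), class = "multiview_config")
}

#' Frozen-backbone feature matrices for a molecule table
#'
#' Runs each configured encoder over every molecule and returns the pooled
#' pre-projection backbone features (one N x p_m matrix per view). These
#' are the inputs whose trainable output projections fine-tuning updates.
#'
#' @param table a \code{dataset_table}.
#' @param config a \code{multiview_config}.
#' @param progress print a dot every 200 molecules.
#' @return named list of feature matrices with attribute \code{"params"}
#'   (the backbone parameter lists).
#' @export
view_features <- function(table, config, progress = FALSE) {
  smis <- table$records$canonical_smiles
  n <- length(smis)
  params <- lapply(config$encoder_configs, init_encoder_params)
  out <- list()
  if ("graph" %in% config$views) {
    cfg <- config$encoder_configs$graph
    mols <- parse_mol_graph(smis)
    F <- matrix(0, n, cfg$embed_dim)
    for (i in seq_len(n)) {
      gv <- laplacian_pe(featurize_graph(smis[i], mol = mols[[i]]),
                         k = cfg$pe_k)
      F[i, ] <- encode_graph(gv, cfg, params$graph)$pooled
      if (progress && i %% 200L == 0L) cat(".")
    }
    out$graph <- F
  }
  if ("image" %in% config$views) {
    cfg <- config$encoder_configs$image
    mols <- parse_mol_graph(smis, coords = TRUE)
    F <- matrix(0, n, cfg$channels[2])
    for (i in seq_len(n)) {
      iv <- render_image(smis[i], mode = "eval", mol = mols[[i]])
      F[i, ] <- encode_image(iv, cfg, params$image)$pooled
      if (progress && i %% 200L == 0L) cat(".")
    }
    out$image <- F
  }
  if ("text" %in% config$views) {
    cfg <- config$encoder_configs$text
    F <- matrix(0, n, cfg$embed_dim)
    vocab <- build_vocab()
    for (i in seq_len(n)) {
      tv <- suppressWarnings(tokenize_smiles(smis[i], vocab))
      F[i, ] <- encode_text(tv, cfg, params$text)$pooled
      if (progress && i %% 200L == 0L) cat(".")
    }
    out$text <- F
  }
  attr(out, "params") <- params
  out
}

# ---- Fine-tuning ------------------------------------------------------------

#' Optimizer configuration for fine-tuning
#'
#' Up to four learning-rate groups: one per view-encoder output projection
#' and one for the aggregator + head.
#'
#' @param lr_views learning rate(s) for the per-view projections (recycled).
#' @param lr_head learning rate for gate + MLP + task head.
#' @param epochs,patience early-stopping schedule.
#' @export
optim_config <- function(lr_views = 5e-3, lr_head = 5e-3, epochs = 100L,
                         patience = 10L) {
  list(lr_views = lr_views, lr_head = lr_head, epochs = as.integer(epochs),
       patience = as.integer(patience))
}

.init_mv_params <- function(config, p_dims, seed) {
  d <- config$d
  with_seed(seed, {
    P <- lapply(p_dims, function(p) list(W = .init_mat(d, p),
                                         b = numeric(d)))
    gate <- init_gating_params(d, config$gate_dim, d_out = d,
                               hidden = config$hidden,
                               n_views = length(p_dims),
                               seed = seed + 1L)
    head <- list(C = .init_mat(1L, d), c0 = 0)
    list(P = P, gate = gate, head = head)
  })
}

.eval_metrics <- function(pred, truth, task_kind) {
  if (task_kind == "classification") {
    auc <- as.numeric(pROC::auc(pROC::roc(truth, pred, quiet = TRUE,
                                          direction = "<", levels = c(0, 1))))
    c(roc_auc = auc)
  } else {
    r <- suppressWarnings(stats::cor(pred, truth))
    c(rmse = sqrt(mean((pred - truth)^2)),
      mae = mean(abs(pred - truth)),
      pearson = if (is.na(r)) 0 else r)
  }
}

#' Fine-tune the fused model on a labeled dataset
#'
#' Trains the per-view output projections, the batch gate and the MLP/task
#' head with per-subnetwork Adam learning rates and validation early
#' stopping, repeating over \code{seeds} and reporting held-out metrics as
#' mean with a 95% confidence interval. The returned model is the highest
#' average-validation performer, with its gate scores frozen for
#' deterministic inference.
#'
#' @param table a labeled \code{dataset_table}.
#' @param split a \code{split_assignment} for the table.
#' @param config a \code{multiview_config}.
#' @param optim an \code{\link{optim_config}}.
#' @param seeds integer vector of training seeds (default 5).
#' @param features optional precomputed \code{\link{view_features}}.
#' @return list of class \code{multiview_model}: trained \code{params},
#'   \code{w_frozen}, \code{alpha}, \code{config}, \code{task_kind}, and
#'   \code{report} (a \code{metric_report}).
#' @export
finetune_task <- function(table, split, config = multiview_config(),
                          optim = optim_config(), seeds = 1:5,
                          features = NULL) {
  stopifnot(!is.null(table$labels))
  if (is.null(features)) features <- view_features(table, config)
  part <- split$partition
  idx <- list(train = which(part == "train"),
              val = which(part == "validation"),
              test = which(part == "test"))
  if (any(lengths(idx) == 0L)) stop("empty partition in split")
  y <- table$labels
  loss <- if (table$task_kind == "classification") "bce" else "mse"
  p_dims <- vapply(features, ncol, 0L)
  lr_views <- rep_len(optim$lr_views, length(features))
  lr_groups <- c(lr_views, optim$lr_head)
  runs <- vector("list", length(seeds))
  for (k in seq_along(seeds)) {
    params0 <- .init_mv_params(config, p_dims, seed = seeds[k])
    tr <- train_mv(features, y, idx$train, idx$val, params0, loss,
                   lr_groups, epochs = optim$epochs,
                   patience = optim$patience)
    pred_val <- predict_mv(.subset_F(features, idx$val), tr$params,
                           tr$w_frozen, loss)
    pred_test <- predict_mv(.subset_F(features, idx$test), tr$params,
                            tr$w_frozen, loss)
    runs[[k]] <- list(seed = seeds[k], train = tr,
                      val_metrics = .eval_metrics(pred_val, y[idx$val],
                                                  table$task_kind),
                      test_metrics = .eval_metrics(pred_test, y[idx$test],
                                                   table$task_kind))
  }
  key <- if (table$task_kind == "classification") "roc_auc" else "pearson"
  val_perf <- vapply(runs, function(r) r$val_metrics[[key]], 0)
  best <- which.max(val_perf)
  test_mat <- do.call(rbind, lapply(runs, `[[`, "test_metrics"))
  report <- metric_report(test_mat, table$task_kind, seeds)
  structure(list(params = runs[[best]]$train$params,
                 w_frozen = runs[[best]]$train$w_frozen,
                 alpha = runs[[best]]$train$alpha,
                 config = config, task_kind = table$task_kind,
                 views = names(features), best_seed = seeds[best],
                 report = report, runs = runs),
            class = "multiview_model")
}

#' Seed-averaged metric report
#'
#' Mean and 95% confidence interval (t-quantile on the standard error of
#' the mean) of each held-out metric across seed runs.
#'
#' @param metric_mat matrix, one row per seed run.
#' @param task_kind task type.
#' @param seeds the seeds used.
#' @return list of class \code{metric_report}.
#' @export
metric_report <- function(metric_mat, task_kind, seeds) {
  n <- nrow(metric_mat)
  mean_v <- colMeans(metric_mat)
  ci <- if (n >= 2L) {
    se <- apply(metric_mat, 2, stats::sd) / sqrt(n)
    stats::qt(0.975, n - 1L) * se
  } else rep(NA_real_, ncol(metric_mat))
  structure(list(task_kind = task_kind, n_seeds = n, seeds = seeds,
                 per_seed = metric_mat, mean = mean_v,
                 ci95 = stats::setNames(ci, colnames(metric_mat))),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> %s over %d seeds\n", x$task_kind, x$n_seeds))
  for (nm in names(x$mean)) {
    cat(sprintf("  %-8s %.4f +/- %.4f\n", nm, x$mean[nm], x$ci95[nm]))
  }
  invisible(x)
}

#' Predict with a fine-tuned model (frozen gate)
#'
#' @param object a \code{multiview_model}.
#' @param table a \code{dataset_table} (or precomputed features via
#'   \code{features}).
#' @param features optional \code{\link{view_features}} output.
#' @param ... unused.
#' @return numeric predictions (sigmoid scores for classification).
#' @export
predict.multiview_model <- function(object, table, features = NULL, ...) {
  if (is.null(features)) features <- view_features(table, object$config)
  loss <- if (object$task_kind == "classification") "bce" else "mse"
  predict_mv(features, object$params, object$w_frozen, loss)
}

# ---- Model agreement --------------------------------------------------------

#' Agreement between two models' predictions
#'
#' Classification: both prediction vectors are binarized at 0.5 and the F1
#' score of \code{preds_b} against \code{preds_a} (a as reference) is
#' returned — an asymmetric measure of how well b's positives predict a's.
#' Regression: Pearson correlation with a chi-squared p-value
#' (n r^2 ~ chi^2_1 under the null).
#'
#' @param preds_a,preds_b equal-length prediction vectors.
#' @param task_kind task type.
#' @return list with \code{statistic} (f1 or pearson) and components.
#' @export
model_agreement <- function(preds_a, preds_b,
                            task_kind = c("classification", "regression")) {
  task_kind <- match.arg(task_kind)
  stopifnot(length(preds_a) == length(preds_b))
  if (task_kind == "classification") {
    a <- as.integer(preds_a >= 0.5); b <- as.integer(preds_b >= 0.5)
    if (length(unique(a)) < 2L) {
      warning("degenerate reference predictions: single class")
    }
    tp <- sum(a == 1L & b == 1L)
    prec <- if (sum(b) > 0L) tp / sum(b) else 0
    rec <- if (sum(a) > 0L) tp / sum(a) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    list(statistic = f1, f1 = f1, precision = prec, recall = rec)
  } else {
    r <- stats::cor(preds_a, preds_b)
    n <- length(preds_a)
    p <- stats::pchisq(n * r^2, df = 1L, lower.tail = FALSE)
    list(statistic = r, pearson = r, p_value = p)
  }
}

# ---- Screening --------------------------------------------------------------

#' Rank a screening library by predicted activity
#'
#' Predicts with the frozen-gate model, sorts descending (ties broken by
#' canonical SMILES), and reports the per-view gate weights alongside the
#' ranking for interpretability.
#'
#' @param model a \code{multiview_model}.
#' @param library_table a \code{dataset_table} of candidate molecules.
#' @param top_k rows to return (capped at the library size).
#' @param features optional precomputed features.
#' @return list: \code{ranking} (data.frame rank/smiles/score),
#'   \code{alpha}, \code{n_dropped}.
#' @export
rank_screen <- function(model, library_table, top_k = 50L, features = NULL) {
  scores <- predict(model, library_table, features = features)
  smis <- library_table$records$canonical_smiles
  ord <- order(-scores, smis)
  k <- min(top_k, length(ord))
  ranking <- data.frame(rank = seq_along(ord),
                        smiles = smis[ord],
                        score = scores[ord])[seq_len(k), ]
  alpha <- drop(.softmax_rows(matrix(model$w_frozen, 1L)))
  list(ranking = ranking,
       alpha = stats::setNames(alpha, model$views),
       n_dropped = library_table$n_dropped)
}
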