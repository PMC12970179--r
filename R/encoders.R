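# Desk-scale per-view encoders. Each maps a view to a fixed-dimension
# embedding through (i) a backbone whose parameters are drawn once from the
# config seed and (ii) an output projection. Forward passes are pure
# functions of (input, params); attention can be recorded for
# interpretability.

# categorical level tables for graph tokens; the final level of every
# feature is the mask sentinel used by feature-masking pre-training
.node_levels <- list(
  atomic_number = c(5, 6, 7, 8, 9, 14, 15, 16, 17, 34, 35, 53, 0),
  chirality = c("none", "at", "at_at"),
  degree = as.character(0:6),
  formal_charge = as.character(-2:2),
  hybridization = c("sp", "sp2", "sp3", "other"))
.edge_levels <- list(
  bond_type = c("single", "double", "triple", "aromatic"),
  bond_dir = c("none", "up", "down"),
  stereo = c("none", "cis_trans"),
  conjugated = c("FALSE", "TRUE"),
  in_ring = c("FALSE", "TRUE"))

#' Encoder configuration
#'
#' Defaults follow the published embedding widths — graph tokens embedded at
#' 512 (128 per categorical feature), text tokens at 768 — with desk-scale
#' depth 2, 4 heads and a 256-dimensional output. Tests and fine-tuning use
#' smaller widths via the arguments.
#'
#' @param view \code{"graph"}, \code{"image"} or \code{"text"}.
#' @param embed_dim token embedding width (graph default 512, text 768).
#' @param depth number of transformer layers / residual stages.
#' @param heads attention heads (must divide embed_dim).
#' @param output_dim embedding dimension produced by the encoder.
#' @param feature_embed_dim per-categorical-feature width (graph; default 128).
#' @param pe_k retained Laplacian eigenpairs (graph).
#' @param channels two-stage channel counts (image).
#' @param vocab_size text vocabulary size.
#' @param seed parameter-initialization seed.
#' @return object of class \code{encoder_config}.
#' @export
encoder_config <- function(view = c("graph", "image", "text"),
                           embed_dim = NULL, depth = 2L, heads = 4L,
                           output_dim = 256L, feature_embed_dim = NULL,
                           pe_k = 8L, channels = c(16L, 32L),
                           vocab_size = length(build_vocab()), seed = 1L) {
  view <- match.arg(view)
  if (is.null(embed_dim)) embed_dim <- switch(view, graph = 512L,
                                              text = 768L, image = NA_integer_)
  if (is.null(feature_embed_dim)) {
    feature_embed_dim <- if (view == "graph") 128L else 0L
  }
  if (view != "image") stopifnot(embed_dim %% heads == 0L)
  stopifnot(output_dim >= 1L, depth >= 1L)
  structure(list(view = view, embed_dim = embed_dim, depth = depth,
                 heads = heads, output_dim = output_dim,
                 feature_embed_dim = feature_embed_dim, pe_k = pe_k,
                 channels = channels, vocab_size = vocab_size,
                 seed = as.integer(seed)),
            class = "encoder_config")
}

#' Initialize encoder parameters from a config
#' @param config an \code{encoder_config}.
#' @return parameter list; deterministic in \code{config$seed}.
#' @export
init_encoder_params <- function(config) {
  with_seed(config$seed, switch(config$view,
    graph = .init_graph_params(config),
    text = .init_text_params(config),
    image = .init_image_params(config)))
}

.init_graph_params <- function(cfg) {
  fe <- cfg$feature_embed_dim
  emb <- function(levels) .init_mat(length(levels) + 1L, fe)  # +1 = sentinel
  list(
    node_emb = lapply(.node_levels, emb),
    edge_emb = lapply(.edge_levels, emb),
    type_emb = .init_mat(2L, cfg$embed_dim),        # node vs edge token
    Win = .init_mat(cfg$embed_dim, 5L * fe),
    Wpe = .init_mat(cfg$embed_dim, 2L * cfg$pe_k),
    layers = replicate(cfg$depth, .init_transformer_layer(cfg$embed_dim),
                       simplify = FALSE),
    Wout = .init_mat(cfg$output_dim, cfg$embed_dim),
    bout = numeric(cfg$output_dim))
}

.init_text_params <- function(cfg) {
  list(
    tok_emb = .init_mat(cfg$vocab_size, cfg$embed_dim),
    layers = replicate(cfg$depth, .init_transformer_layer(cfg$embed_dim),
                       simplify = FALSE),
    Wout = .init_mat(cfg$output_dim, cfg$embed_dim),
    bout = numeric(cfg$output_dim))
}

.init_image_params <- function(cfg) {
  c1 <- cfg$channels[1]; c2 <- cfg$channels[2]
  list(
    stem_W = array(stats::rnorm(7 * 7 * 3 * c1, sd = sqrt(1 / (49 * 3))),
                   c(7, 7, 3, c1)),
    stem_b = numeric(c1),
    b1a_W = array(stats::rnorm(9 * c1 * c1, sd = sqrt(1 / (9 * c1))),
                  c(3, 3, c1, c1)),
    b1a_b = numeric(c1),
    b1b_W = array(stats::rnorm(9 * c1 * c1, sd = sqrt(1 / (9 * c1))),
                  c(3, 3, c1, c1)),
    b1b_b = numeric(c1),
    b2a_W = array(stats::rnorm(9 * c1 * c2, sd = sqrt(1 / (9 * c1))),
                  c(3, 3, c1, c2)),
    b2a_b = numeric(c2),
    b2b_W = array(stats::rnorm(9 * c2 * c2, sd = sqrt(1 / (9 * c2))),
                  c(3, 3, c2, c2)),
    b2b_b = numeric(c2),
    skip_W = array(stats::rnorm(c1 * c2, sd = sqrt(1 / c1)),
                   c(1, 1, c1, c2)),
    skip_b = numeric(c2),
    Wout = .init_mat(cfg$output_dim, c2),
    bout = numeric(cfg$output_dim))
}

.lookup <- function(tab, levels, values, masked) {
  idx <- match(as.character(values), levels)
  idx[is.na(idx)] <- length(levels)          # unknown -> last regular level
  idx[masked] <- length(levels) + 1L         # sentinel row
  tab[idx, , drop = FALSE]
}

#' Encode a graph view
#'
#' Transformer over node + edge tokens. Each token is the projection of its
#' five concatenated categorical feature embeddings, plus a node/edge type
#' embedding and a projection of the Laplacian positional encoding (node
#' tokens use their own eigenvector row twice; edge tokens the rows of
#' their two endpoints). Mean-pooled, then projected to the output
#' dimension.
#'
#' @param view a \code{graph_view} with Laplacian PE attached.
#' @param config a graph \code{encoder_config} (same \code{pe_k}).
#' @param params from \code{\link{init_encoder_params}}.
#' @param masked_tokens optional token positions whose features are replaced
#'   by the mask sentinel (feature-masking pre-training).
#' @param record_attention record head-averaged last-layer attention.
#' @return object of class \code{view_embedding}: \code{z}, \code{pooled}
#'   (pre-projection backbone feature), \code{view}, optional
#'   \code{attention}.
#' @export
encode_graph <- function(view, config, params, masked_tokens = integer(0),
                         record_attention = FALSE) {
  stopifnot(inherits(view, "graph_view"))
  if (is.null(view$laplacian_eigenvectors)) {
    stop("attach Laplacian positional encoding first (laplacian_pe)")
  }
  if (ncol(view$laplacian_eigenvectors) != config$pe_k) {
    stop("pe_k mismatch between view and config")
  }
  n <- view$n_nodes; m <- view$n_edges
  nf <- view$node_features; ef <- view$edge_features
  nm <- intersect(masked_tokens, seq_len(n))
  em <- intersect(masked_tokens, n + seq_len(m)) - n
  nX <- do.call(cbind, lapply(names(.node_levels), function(f) {
    .lookup(params$node_emb[[f]], .node_levels[[f]], nf[[f]],
            seq_len(n) %in% nm)
  }))
  X <- nX
  if (m > 0L) {
    eX <- do.call(cbind, lapply(names(.edge_levels), function(f) {
      .lookup(params$edge_emb[[f]], .edge_levels[[f]], ef[[f]],
              seq_len(m) %in% em)
    }))
    X <- rbind(nX, eX)
  }
  X <- X %*% t(params$Win)
  V <- view$laplacian_eigenvectors
  pe <- rbind(cbind(V, V),
              if (m > 0L) cbind(V[view$edges$from, , drop = FALSE],
                                V[view$edges$to, , drop = FALSE]))
  X <- X + pe %*% t(params$Wpe)
  X <- X + params$type_emb[c(rep(1L, n), rep(2L, m)), , drop = FALSE]
  attn <- NULL
  for (l in params$layers) {
    step <- .transformer_layer(X, l, config$heads)
    X <- step$out
    attn <- step$attn
  }
  pooled <- colMeans(X)
  z <- drop(params$Wout %*% pooled) + params$bout
  weights <- NULL
  if (record_attention) {
    w <- colMeans(attn)          # attention received per token
    weights <- w / sum(w)
  }
  structure(list(z = z, pooled = pooled, view = "graph",
                 attention = weights), class = "view_embedding")
}

#' Encode a text view
#'
#' Transformer with sinusoidal positional encoding over the token-id
#' sequence. Padding tokens are excluded from attention keys and from the
#' mean pooling, so the embedding is invariant to trailing padding.
#'
#' @param view a \code{text_view} (optionally padded with \code{"<pad>"}).
#' @param config a text \code{encoder_config}.
#' @param params from \code{\link{init_encoder_params}}.
#' @param record_attention record head-averaged last-layer attention.
#' @return a \code{view_embedding}.
#' @export
encode_text <- function(view, config, params, record_attention = FALSE) {
  stopifnot(inherits(view, "text_view"))
  ids <- view$token_ids
  if (any(ids < 1L | ids > config$vocab_size)) {
    stop("token id out of vocabulary range")
  }
  pad_id <- match("<pad>", view$vocab)
  is_pad <- ids == pad_id
  X <- params$tok_emb[ids, , drop = FALSE] +
    .sinusoid_pe(length(ids), config$embed_dim)
  attn <- NULL
  for (l in params$layers) {
    step <- .transformer_layer(X, l, config$heads, key_mask = is_pad)
    X <- step$out
    attn <- step$attn
  }
  pooled <- colMeans(X[!is_pad, , drop = FALSE])
  z <- drop(params$Wout %*% pooled) + params$bout
  weights <- NULL
  if (record_attention) {
    w <- colMeans(attn[!is_pad, !is_pad, drop = FALSE])
    weights <- w / sum(w)
  }
  structure(list(z = z, pooled = pooled, view = "text",
                 attention = weights), class = "view_embedding")
}

#' Encode an image view
#'
#' Small residual convolutional network: 7x7 stride-4 stem, an identity
#' residual block, a strided residual block with projection skip, global
#' average pooling, output projection. Requires the 224 x 224 eval-sized
#' grid.
#'
#' @param view an \code{image_view}.
#' @param config an image \code{encoder_config}.
#' @param params from \code{\link{init_encoder_params}}.
#' @param record_attention record normalized spatial activation weights.
#' @return a \code{view_embedding}.
#' @export
encode_image <- function(view, config, params, record_attention = FALSE) {
  stopifnot(inherits(view, "image_view"))
  px <- view$pixels
  if (!all(dim(px)[1:2] == c(224L, 224L))) {
    stop("image encoder requires a 224 x 224 grid")
  }
  x <- .relu(.conv2d(px, params$stem_W, params$stem_b, stride = 4L, pad = 3L))
  x <- .avg_pool2(x)                                   # 28 x 28 x c1
  h <- .relu(.conv2d(x, params$b1a_W, params$b1a_b, stride = 1L, pad = 1L))
  h <- .conv2d(h, params$b1b_W, params$b1b_b, stride = 1L, pad = 1L)
  x <- .relu(x + h)
  hs <- .relu(.conv2d(x, params$b2a_W, params$b2a_b, stride = 2L, pad = 1L))
  hs <- .conv2d(hs, params$b2b_W, params$b2b_b, stride = 1L, pad = 1L)
  sk <- .conv2d(x, params$skip_W, params$skip_b, stride = 2L, pad = 0L)
  x <- .relu(sk + hs)                                  # 14 x 14 x c2
  pooled <- apply(x, 3, mean)
  z <- drop(params$Wout %*% pooled) + params$bout
  weights <- NULL
  if (record_attention) {
    w <- sqrt(apply(x^2, c(1, 2), mean))
    w <- as.vector(w); weights <- w / sum(w)
  }
  structure(list(z = z, pooled = pooled, view = "image",
                 attention = weights), class = "view_embedding")
}

#' Per-token attention weights of an encoded view
#'
#' Nonnegative weights over input tokens (graph/text) or spatial cells
#' (image), summing to one; available when the encoder ran with
#' \code{record_attention = TRUE}.
#'
#' @param embedding a \code{view_embedding}.
#' @return numeric weight vector.
#' @export
extract_attention <- function(embedding) {
  stopifnot(inherits(embedding, "view_embedding"))
  if (is.null(embedding$attention)) {
    stop("attention recording was not enabled for this embedding")
  }
  embedding$attention
}

#' Save / load encoder parameters with embedded config
#'
#' Single-file plain-text checkpoint (JSON) holding the config and all
#' parameter tensors.
#'
#' @param params parameter list.
#' @param config the matching \code{encoder_config}.
#' @param path file path.
#' @export
save_encoder <- function(params, config, path) {
  ser <- function(x) {
    if (is.array(x) || is.matrix(x)) list(dim = dim(x), data = as.vector(x))
    else if (is.list(x)) lapply(x, ser)
    else x
  }
  jsonlite::write_json(list(config = unclass(config), params = ser(params)),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_encoder
#' @export
load_encoder <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  de <- function(x) {
    if (is.list(x) && !is.null(x$dim) && !is.null(x$data)) {
      array(x$data, dim = x$dim)
    } else if (is.list(x)) lapply(x, de)
    else x
  }
  cfg <- raw$config
  class(cfg) <- "encoder_config"
  list(config = cfg, params = de(raw$params))
}
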