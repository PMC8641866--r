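# The reverse fusion attention residual network (RFARN).
#
# Topology: a side-input image pyramid feeds four residual encoder stages
# (3x3 conv -> BN -> ReLU -> dilated 3x3 conv -> BN -> ReLU, plus a shortcut,
# then 2x2 max pooling between stages). Reverse channel attention modules
# (RCAM) replace the plain skip tensors: the deeper stage's 1-channel
# prediction is upsampled, complemented (1 - sigmoid) and used to re-weight
# the shallower features towards edges and faint vessels before a learned
# channel-affinity mixing. Three decoder stages (2x2 stride-2 deconvolution,
# skip concatenation, two 3x3 convs with ReLU) restore resolution, each
# followed by a reverse spatial attention module (RSAM) that gates the
# decoder features with a pixel mask derived from the coarser encoder output.
# A 1x1 convolution with sigmoid produces the per-pixel vessel probability.

#' Network configuration
#'
#' @param patch_size Input patch side in pixels; must be divisible by
#'   `2^(depth - 1)`.
#' @param depth Number of encoder stages.
#' @param base_channels Channel width of the first stage; doubled per stage.
#' @param dilation Dilation (atrous) rate of the second encoder convolution.
#' @return An object of class `network_config` with derived fields
#'   `pyramid_sizes` (side-input sizes, halving per stage) and `widths`
#'   (channels per stage).
#' @export
network_config <- function(patch_size = 48, depth = 4, base_channels = 32,
                           dilation = 2) {
  if (!is_count(patch_size) || !is_count(depth) || !is_count(base_channels) ||
      !is_count(dilation)) {
    abort_param("patch_size, depth, base_channels and dilation must be positive integers")
  }
  if (patch_size %% 2^(depth - 1) != 0) {
    abort_param("patch_size must be divisible by 2^(depth - 1)")
  }
  structure(list(
    patch_size = as.integer(patch_size),
    depth = as.integer(depth),
    base_channels = as.integer(base_channels),
    dilation = as.integer(dilation),
    pyramid_sizes = as.integer(patch_size / 2^(0:(depth - 1))),
    widths = as.integer(base_channels * 2^(0:(depth - 1)))
  ), class = "network_config")
}

pn <- function(...) paste(c(...), collapse = ".")

kaiming_uniform <- function(d) {
  fan_in <- prod(d[-length(d)])
  lim <- sqrt(6 / fan_in)
  array(runif(prod(d), -lim, lim), d)
}

#' Initialise an RFARN model
#'
#' Creates all convolution, attention and normalisation parameters
#' (Kaiming-uniform weights, zero biases, unit batch-norm scale) under a
#' fixed seed.
#'
#' @param config A [network_config()].
#' @param seed Integer seed controlling the initialisation.
#' @return An environment of class `rfarn_model` with fields `config`,
#'   `params` (flat named list of arrays) and `bn` (running statistics).
#' @export
rfarn_init <- function(config = network_config(), seed = 1) {
  if (!inherits(config, "network_config")) abort_param("config must be a network_config")
  D <- config$depth
  w <- config$widths
  params <- list()
  bn <- list()
  conv <- function(name, d) params[[name]] <<- kaiming_uniform(d)
  bias <- function(name, n) params[[name]] <<- numeric(n)
  with_seed(seed, {
    for (i in seq_len(D)) {
      cin <- if (i == 1) w[1] else w[i - 1]
      conv(pn("enc", i, "side_w"), c(3, 3, 1, cin)); bias(pn("enc", i, "side_b"), cin)
      conv(pn("enc", i, "w1"), c(3, 3, cin, w[i])); bias(pn("enc", i, "b1"), w[i])
      params[[pn("enc", i, "g1")]] <- rep(1, w[i]); bias(pn("enc", i, "be1"), w[i])
      conv(pn("enc", i, "w2"), c(3, 3, w[i], w[i])); bias(pn("enc", i, "b2"), w[i])
      params[[pn("enc", i, "g2")]] <- rep(1, w[i]); bias(pn("enc", i, "be2"), w[i])
      if (cin != w[i]) {
        conv(pn("enc", i, "ws"), c(1, 1, cin, w[i])); bias(pn("enc", i, "bs"), w[i])
      }
      bn[[pn("enc", i, "bn1")]] <- list(mean = numeric(w[i]), var = rep(1, w[i]))
      bn[[pn("enc", i, "bn2")]] <- list(mean = numeric(w[i]), var = rep(1, w[i]))
    }
    for (l in seq_len(D - 1)) {
      conv(pn("rcam", l, "wc"), c(1, 1, w[l + 1], 1)); bias(pn("rcam", l, "bc"), 1)
      conv(pn("rcam", l, "wu"), c(2, 2, 1, 1)); bias(pn("rcam", l, "bu"), 1)
      params[[pn("rcam", l, "rho")]] <- rep(1, w[l])
      cin <- if (l == D - 1) w[D] else w[l + 1]
      conv(pn("dec", l, "wd"), c(2, 2, cin, w[l])); bias(pn("dec", l, "bd"), w[l])
      conv(pn("dec", l, "w1"), c(3, 3, 2 * w[l], w[l])); bias(pn("dec", l, "b1"), w[l])
      conv(pn("dec", l, "w2"), c(3, 3, w[l], w[l])); bias(pn("dec", l, "b2"), w[l])
      conv(pn("rsam", l, "w1"), c(1, 1, w[l + 1], 1)); bias(pn("rsam", l, "b1"), 1)
      conv(pn("rsam", l, "wu"), c(2, 2, 1, 1)); bias(pn("rsam", l, "bu"), 1)
      conv(pn("rsam", l, "wm"), c(1, 1, w[l], 1)); bias(pn("rsam", l, "bm"), 1)
      conv(pn("rsam", l, "wd"), c(1, 1, w[l], w[l])); bias(pn("rsam", l, "bd"), w[l])
    }
    conv("head.w", c(1, 1, w[1], 1)); bias("head.b", 1)
  })
  m <- new.env(parent = emptyenv())
  m$config <- config
  m$params <- params
  m$bn <- bn
  m$seed <- as.integer(seed)
  class(m) <- "rfarn_model"
  m
}

#' Save / load a model checkpoint
#'
#' The checkpoint is an RDS container holding the parameters, batch-norm
#' running statistics and seed, written next to a JSON sidecar
#' (`<path>.json`) describing the network configuration, so a checkpoint is
#' self-describing.
#'
#' @param model An `rfarn_model`.
#' @param path Checkpoint file path.
#' @return `path` (for `rfarn_save`); the restored model (for `rfarn_load`).
#' @export
rfarn_save <- function(model, path) {
  saveRDS(list(params = model$params, bn = model$bn, seed = model$seed,
               config = unclass(model$config)), path)
  jsonlite::write_json(unclass(model$config), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname rfarn_save
#' @export
rfarn_load <- function(path) {
  ck <- readRDS(path)
  cfg <- network_config(ck$config$patch_size, ck$config$depth,
                        ck$config$base_channels, ck$config$dilation)
  m <- rfarn_init(cfg, seed = ck$seed)
  m$params <- ck$params
  m$bn <- ck$bn
  m
}

#' Number of trainable parameters
#' @param model An `rfarn_model`.
#' @return Integer parameter count.
#' @export
rfarn_num_params <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

#' @export
print.rfarn_model <- function(x, ...) {
  cfg <- x$config
  cat("<rfarn_model>\n")
  cat("  patch size:", cfg$patch_size, " depth:", cfg$depth, "\n")
  cat("  stage widths:", paste(cfg$widths, collapse = "/"), "\n")
  cat("  pyramid sizes:", paste(cfg$pyramid_sizes, collapse = "/"), "\n")
  cat("  parameters:", format(rfarn_num_params(x), big.mark = ","), "\n")
  invisible(x)
}

# ---- plain-array helpers (exported primitives) ----

#' Reverse attention weight
#'
#' `1 - sigmoid(logits)`: the complement of the sigmoid prediction, strictly
#' in (0, 1). Regions the network already predicts confidently are
#' suppressed, steering attention towards edges and faint vessels.
#'
#' @param logits Numeric array of prediction logits.
#' @return Array of the same shape with values strictly in (0, 1).
#' @export
reverse_weight <- function(logits) {
  if (!all(is.finite(logits))) abort_input("logits must be finite")
  1 - 1 / (1 + exp(-logits))
}

#' Channel affinity matrix
#'
#' For pooled feature vectors `avg` and `max` of length C, computes
#' `A[i, j] = exp(avg[i] * max[j]) / sum_i exp(avg[i] * max[j])` - a softmax
#' over the first index, so every column sums to 1.
#'
#' @param avg,max Numeric vectors of equal length (global average- and
#'   max-pooled channel descriptors).
#' @return C x C column-stochastic matrix.
#' @export
channel_affinity <- function(avg, max) {
  if (length(avg) != length(max)) abort_input("avg and max must have equal length")
  z <- outer(avg, max)
  e <- exp(sweep(z, 2, apply(z, 2, base::max)))
  sweep(e, 2, colSums(e), "/")
}

avg_pool2 <- function(m) {
  h <- nrow(m) %/% 2
  w <- ncol(m) %/% 2
  (m[2 * seq_len(h) - 1, 2 * seq_len(w) - 1, drop = FALSE] +
     m[2 * seq_len(h), 2 * seq_len(w) - 1, drop = FALSE] +
     m[2 * seq_len(h) - 1, 2 * seq_len(w), drop = FALSE] +
     m[2 * seq_len(h), 2 * seq_len(w), drop = FALSE]) / 4
}

#' Side-input image pyramid
#'
#' Successively average-pools a patch by factor 2, producing the downsampled
#' copies injected at each encoder stage (48, 24, 12, 6 for the default
#' configuration).
#'
#' @param patch Grayscale matrix of side `config$patch_size`.
#' @param config A [network_config()].
#' @return List of `config$depth` matrices, halving in size.
#' @export
build_side_pyramid <- function(patch, config = network_config()) {
  validate_gray(patch)
  if (nrow(patch) != config$patch_size || ncol(patch) != config$patch_size) {
    abort_input(paste0("patch must be ", config$patch_size, "x", config$patch_size))
  }
  out <- vector("list", config$depth)
  out[[1]] <- patch
  for (i in seq_len(config$depth - 1)) out[[i + 1]] <- avg_pool2(out[[i]])
  out
}

# batch version: x (H, W, 1, N) -> list of (h, w, 1, N)
side_pyramid_batch <- function(x, depth) {
  out <- vector("list", depth)
  out[[1]] <- x
  for (i in seq_len(depth - 1)) {
    prev <- out[[i]]
    d <- dim(prev)
    nxt <- array(0, c(d[1] / 2, d[2] / 2, 1, d[4]))
    for (n in seq_len(d[4])) nxt[, , 1, n] <- avg_pool2(prev[, , 1, n])
    out[[i + 1]] <- nxt
  }
  out
}

# ---- graph builders (operate on tape nodes) ----

graph_encoder <- function(P, model, i, xin_node, side_node, training) {
  cfg <- model$config
  s <- ad_conv(side_node, P[[pn("enc", i, "side_w")]], P[[pn("enc", i, "side_b")]])
  xin <- if (is.null(xin_node)) s else ad_add(xin_node, s)
  t1 <- ad_relu(ad_bn(ad_conv(xin, P[[pn("enc", i, "w1")]], P[[pn("enc", i, "b1")]]),
                      P[[pn("enc", i, "g1")]], P[[pn("enc", i, "be1")]],
                      model, pn("enc", i, "bn1"), training))
  t2 <- ad_relu(ad_bn(ad_conv(t1, P[[pn("enc", i, "w2")]], P[[pn("enc", i, "b2")]],
                              dilation = cfg$dilation),
                      P[[pn("enc", i, "g2")]], P[[pn("enc", i, "be2")]],
                      model, pn("enc", i, "bn2"), training))
  sc <- if (!is.null(P[[pn("enc", i, "ws")]])) {
    ad_conv(xin, P[[pn("enc", i, "ws")]], P[[pn("enc", i, "bs")]])
  } else {
    xin
  }
  ad_add(t2, sc)
}

graph_rcam <- function(P, l, deep, shallow) {
  logits <- ad_convt2(ad_conv(deep, P[[pn("rcam", l, "wc")]], P[[pn("rcam", l, "bc")]]),
                      P[[pn("rcam", l, "wu")]], P[[pn("rcam", l, "bu")]])
  rw <- ad_affine(ad_sigmoid(logits), scale = -1, shift = 1)  # 1 - sigmoid
  bh <- ad_mul_c1(shallow, rw)                                # edge features
  CB <- ad_chan_affinity(ad_gap(bh), ad_gmp(bh))
  A <- ad_rowscale(ad_sigmoid(CB), P[[pn("rcam", l, "rho")]])
  ad_add(ad_chanmix(A, bh), shallow)
}

graph_decoder <- function(P, l, x, skip) {
  u <- ad_convt2(x, P[[pn("dec", l, "wd")]], P[[pn("dec", l, "bd")]])
  t <- ad_relu(ad_conv(ad_concat(u, skip), P[[pn("dec", l, "w1")]], P[[pn("dec", l, "b1")]]))
  ad_relu(ad_conv(t, P[[pn("dec", l, "w2")]], P[[pn("dec", l, "b2")]]))
}

graph_rsam <- function(P, l, enc, dec) {
  r <- ad_convt2(ad_conv(enc, P[[pn("rsam", l, "w1")]], P[[pn("rsam", l, "b1")]]),
                 P[[pn("rsam", l, "wu")]], P[[pn("rsam", l, "bu")]])
  s <- ad_add_c1(dec, r)
  mask <- ad_sigmoid(ad_conv(s, P[[pn("rsam", l, "wm")]], P[[pn("rsam", l, "bm")]]))
  d <- ad_conv(dec, P[[pn("rsam", l, "wd")]], P[[pn("rsam", l, "bd")]])
  SB <- ad_spatial_softmax(ad_mul_c1(d, mask))
  ad_add(SB, dec)
}

# Full network graph. x: (H, W, 1, N) array. Returns list(out = sigmoid
# probability node, P = leaf nodes by name).
rfarn_graph <- function(model, x, training = FALSE) {
  cfg <- model$config
  D <- cfg$depth
  P <- lapply(model$params, ad_leaf)
  pyr <- side_pyramid_batch(x, D)
  feats <- vector("list", D)
  pooled <- NULL
  for (i in seq_len(D)) {
    feats[[i]] <- graph_encoder(P, model, i, pooled, ad_leaf(pyr[[i]]), training)
    if (i < D) pooled <- ad_maxpool2(feats[[i]])
  }
  skips <- vector("list", D - 1)
  for (l in seq_len(D - 1)) skips[[l]] <- graph_rcam(P, l, feats[[l + 1]], feats[[l]])
  cur <- feats[[D]]
  for (l in rev(seq_len(D - 1))) {
    cur <- graph_decoder(P, l, cur, skips[[l]])
    cur <- graph_rsam(P, l, feats[[l + 1]], cur)
  }
  out <- ad_sigmoid(ad_conv(cur, P[["head.w"]], P[["head.b"]]))
  list(out = out, P = P)
}

patches_to_array <- function(patches, size) {
  if (is.matrix(patches)) patches <- list(patches)
  if (is.list(patches)) {
    x <- array(0, c(size, size, 1, length(patches)))
    for (n in seq_along(patches)) {
      p <- patches[[n]]
      if (!is.matrix(p) || nrow(p) != size || ncol(p) != size) {
        abort_input(paste0("patches must be ", size, "x", size))
      }
      x[, , 1, n] <- p
    }
    return(x)
  }
  d <- dim(patches)
  if (length(d) == 3) {
    if (d[1] != size || d[2] != size) abort_input(paste0("patches must be ", size, "x", size))
    return(array(patches, c(size, size, 1, d[3])))
  }
  if (length(d) == 4) {
    if (d[1] != size || d[2] != size) abort_input(paste0("patches must be ", size, "x", size))
    return(patches)
  }
  abort_input("patches must be a matrix, list of matrices, or 3-D/4-D array")
}

#' Forward pass of the network
#'
#' Runs a batch of grayscale patches through the network in inference mode
#' (batch-norm running statistics; deterministic given fixed weights).
#' Patches are expected on the [0, 1] scale.
#'
#' @param model An [rfarn_init()] model.
#' @param patches A `patch_size` x `patch_size` matrix, list of such
#'   matrices, or an (H, W, N) / (H, W, 1, N) array.
#' @param chunk Maximum number of patches evaluated per tape (memory bound).
#' @return An (H, W, N) array of vessel probabilities, strictly in (0, 1).
#' @export
rfarn_forward <- function(model, patches, chunk = 64L) {
  size <- model$config$patch_size
  x <- patches_to_array(patches, size)
  N <- dim(x)[4]
  out <- array(0, c(size, size, N))
  for (start in seq(1, N, by = chunk)) {
    idx <- start:min(start + chunk - 1, N)
    tape_begin(grad = FALSE)
    g <- rfarn_graph(model, x[, , , idx, drop = FALSE], training = FALSE)
    out[, , idx] <- g$out$value[, , 1, ]
    tape_end()
  }
  out
}

# ---- standalone block wrappers (inference mode, plain arrays in/out) ----

as_feature4 <- function(x) {
  d <- dim(x)
  if (length(d) == 2) array(x, c(d, 1, 1)) else if (length(d) == 3) array(x, c(d, 1)) else x
}

#' Run one residual encoder block
#'
#' @param model An `rfarn_model`.
#' @param stage Encoder stage index.
#' @param x Incoming pooled features (H, W, C, N array), or `NULL` for the
#'   first stage.
#' @param side Side-input pyramid level matching `x`'s spatial size
#'   ((H, W, 1, N) array or matrix).
#' @return List with `features` (same spatial size) and `pooled` (halved).
#' @export
encoder_block <- function(model, stage, x, side) {
  if (!is_count(stage) || stage > model$config$depth) abort_param("stage out of range")
  side <- as_feature4(side)
  if (!is.null(x)) {
    x <- as_feature4(x)
    if (!all(dim(x)[1:2] == dim(side)[1:2])) abort_input("side size must match x")
  }
  tape_begin(grad = FALSE)
  on.exit(tape_end())
  P <- lapply(model$params, ad_leaf)
  f <- graph_encoder(P, model, stage, if (is.null(x)) NULL else ad_leaf(x),
                     ad_leaf(side), training = FALSE)
  list(features = f$value, pooled = cpp_maxpool2_fwd(f$value)$out)
}

#' Fuse deep and shallow features with reverse channel attention
#'
#' @param model An `rfarn_model`.
#' @param link RCAM link index (1 fuses stages 2 and 1, etc.).
#' @param deep Deeper feature block (C x H x W as (H, W, C, N) array).
#' @param shallow Shallower feature block at twice the spatial size.
#' @return Array shaped like `shallow`.
#' @export
rcam_fuse <- function(model, link, deep, shallow) {
  deep <- as_feature4(deep)
  shallow <- as_feature4(shallow)
  if (!all(dim(shallow)[1:2] == 2 * dim(deep)[1:2])) {
    abort_input("shallow must be exactly twice the spatial size of deep")
  }
  tape_begin(grad = FALSE)
  on.exit(tape_end())
  P <- lapply(model$params, ad_leaf)
  graph_rcam(P, link, ad_leaf(deep), ad_leaf(shallow))$value
}

#' Run one decoder block
#'
#' @param model An `rfarn_model`.
#' @param stage Decoder stage index.
#' @param x Incoming features.
#' @param skip Skip features at twice `x`'s spatial size.
#' @return Array shaped like `skip` (spatial), with the stage's channels.
#' @export
decoder_block <- function(model, stage, x, skip) {
  x <- as_feature4(x)
  skip <- as_feature4(skip)
  if (!all(dim(skip)[1:2] == 2 * dim(x)[1:2])) {
    abort_input("skip must be exactly twice the spatial size of x")
  }
  tape_begin(grad = FALSE)
  on.exit(tape_end())
  P <- lapply(model$params, ad_leaf)
  graph_decoder(P, stage, ad_leaf(x), ad_leaf(skip))$value
}

#' Fuse encoder and decoder features with reverse spatial attention
#'
#' @param model An `rfarn_model`.
#' @param link RSAM link index.
#' @param enc Encoder feature block.
#' @param dec Decoder feature block at twice the spatial size.
#' @return Array shaped like `dec`.
#' @export
rsam_fuse <- function(model, link, enc, dec) {
  enc <- as_feature4(enc)
  dec <- as_feature4(dec)
  if (!all(dim(dec)[1:2] == 2 * dim(enc)[1:2])) {
    abort_input("dec must be exactly twice the spatial size of enc")
  }
  tape_begin(grad = FALSE)
  on.exit(tape_end())
  P <- lapply(model$params, ad_leaf)
  graph_rsam(P, link, ad_leaf(enc), ad_leaf(dec))$value
}
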