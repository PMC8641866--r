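# Architecture contracts: pyramid, encoder, attention modules, decoder,
# full forward pass and gradient flow.

test_that("the side pyramid halves sizes and averages cells", {
  cfg <- network_config()
  pyr <- build_side_pyramid(matrix(7.5, 48, 48), cfg)
  expect_equal(vapply(pyr, nrow, integer(1)), c(48L, 24L, 12L, 6L))
  for (lv in pyr) expect_true(all(lv == 7.5))

  # checkerboard whose 2x2 pooling cells each hold two 0s and two 1s:
  # one pooling step averages every cell to exactly 0.5
  cb <- outer(0:47, 0:47, function(i, j) (i + j) %% 2)
  pyr2 <- build_side_pyramid(cb, cfg)
  expect_true(all(pyr2[[2]] == 0.5))

  expect_error(build_side_pyramid(matrix(0, 24, 24), cfg),
               class = "rfarn_invalid_input")
})

avg_pool2_fixture <- function(m) rfarn:::avg_pool2(m)

test_that("encoder blocks preserve spatial size, pool by two, and keep a residual path", {
  model <- fixture_model()
  x <- with_seed(5, matrix(runif(48 * 48), 48, 48))
  eb <- encoder_block(model, 1, NULL, x)
  w1 <- model$config$widths[1]
  expect_equal(dim(eb$features), c(48, 48, w1, 1))
  expect_equal(dim(eb$pooled), c(24, 24, w1, 1))

  # stage 2 consumes pooled features plus its side input
  eb2 <- encoder_block(model, 2, eb$pooled, avg_pool2_fixture(x))
  expect_equal(dim(eb2$features), c(24, 24, model$config$widths[2], 1))

  # zeroing the residual-branch convolutions leaves only the shortcut:
  # stage 1 has matching channels, so features equal the fused input
  mz <- zero_params(model, "^enc\\.1\\.(w1|b1|w2|b2)$")
  ebz <- encoder_block(mz, 1, NULL, x)
  side4 <- array(x, c(48, 48, 1, 1))
  xin <- rfarn:::cpp_conv2d_fwd(side4, mz$params[["enc.1.side_w"]],
                                mz$params[["enc.1.side_b"]], 1L)
  expect_equal(ebz$features, xin, tolerance = 1e-12)

  expect_error(encoder_block(model, 99, NULL, x), class = "rfarn_invalid_parameter")
})

test_that("reverse weights complement the sigmoid exactly", {
  expect_equal(reverse_weight(0), 0.5)
  expect_lt(reverse_weight(20), 1e-8)
  phi <- with_seed(6, array(rnorm(100, 0, 4), c(10, 10)))
  expect_equal(reverse_weight(phi) + 1 / (1 + exp(-phi)),
               array(1, c(10, 10)))
  expect_true(all(reverse_weight(phi) > 0 & reverse_weight(phi) < 1))
})

test_that("channel affinity is a column softmax of the pooled outer product", {
  u <- channel_affinity(rep(0, 5), rep(0, 5))
  expect_equal(u, matrix(1 / 5, 5, 5))
  a <- with_seed(7, rnorm(6)); m <- with_seed(8, rnorm(6))
  A <- channel_affinity(a, m)
  expect_equal(colSums(A), rep(1, 6), tolerance = 1e-6)
  # C = 2 scalar softmax oracle
  A2 <- channel_affinity(c(1, 0), c(1, 0))
  expect_equal(A2[, 1], c(exp(1), 1) / (exp(1) + 1))
  expect_equal(A2[1, 1], 0.73106, tolerance = 1e-4)
  expect_equal(A2[2, 1], 0.26894, tolerance = 1e-4)
})

test_that("rcam output matches an independent step-by-step trace", {
  model <- fixture_model()
  w <- model$config$widths
  deep <- with_seed(9, array(rnorm(6 * 6 * w[4]), c(6, 6, w[4], 1)))
  shallow <- with_seed(10, array(rnorm(12 * 12 * w[3]), c(12, 12, w[3], 1)))
  out <- rcam_fuse(model, 3, deep, shallow)
  expect_equal(dim(out), dim(shallow))
  expect_true(all(is.finite(out)))

  # manual trace of the module semantics, written with scalar loops
  p <- model$params
  logits <- rfarn:::cpp_convt2_fwd(
    rfarn:::cpp_conv2d_fwd(deep, p[["rcam.3.wc"]], p[["rcam.3.bc"]], 1L),
    p[["rcam.3.wu"]], p[["rcam.3.bu"]])
  rw <- 1 - 1 / (1 + exp(-logits[, , 1, 1]))
  C <- w[3]
  bh <- array(0, c(12, 12, C))
  for (c in seq_len(C)) bh[, , c] <- shallow[, , c, 1] * rw
  avg <- apply(bh, 3, mean)
  mx <- apply(bh, 3, max)
  CB <- channel_affinity(avg, mx)
  A <- (1 / (1 + exp(-CB))) * p[["rcam.3.rho"]]
  manual <- array(0, c(12, 12, C))
  for (ci in seq_len(C)) {
    acc <- matrix(0, 12, 12)
    for (k in seq_len(C)) acc <- acc + A[ci, k] * bh[, , k]
    manual[, , ci] <- acc + shallow[, , ci, 1]
  }
  expect_equal(out[, , , 1], manual, tolerance = 1e-10)

  # zeroed projection weights give logits 0, reverse weight exactly 0.5
  mz <- zero_params(model, "^rcam\\.3\\.(wc|bc|wu|bu)$")
  lz <- rfarn:::cpp_convt2_fwd(
    rfarn:::cpp_conv2d_fwd(deep, mz$params[["rcam.3.wc"]], mz$params[["rcam.3.bc"]], 1L),
    mz$params[["rcam.3.wu"]], mz$params[["rcam.3.bu"]])
  expect_true(all(1 - 1 / (1 + exp(-lz)) == 0.5))

  expect_error(rcam_fuse(model, 3, deep, deep), class = "rfarn_invalid_input")
})

test_that("decoder blocks double resolution and stay non-negative", {
  model <- fixture_model()
  w <- model$config$widths
  x <- with_seed(11, array(rnorm(6 * 6 * w[4]), c(6, 6, w[4], 1)))
  skip <- with_seed(12, array(rnorm(12 * 12 * w[3]), c(12, 12, w[3], 1)))
  out <- decoder_block(model, 3, x, skip)
  expect_equal(dim(out), c(12, 12, w[3], 1))
  expect_true(all(out >= 0))
  expect_error(decoder_block(model, 3, x, x), class = "rfarn_invalid_input")
})

test_that("rsam gates the decoder features and reduces to a 0.5 mask at zero weights", {
  model <- fixture_model()
  w <- model$config$widths
  enc <- with_seed(13, array(rnorm(6 * 6 * w[4]), c(6, 6, w[4], 1)))
  dec <- with_seed(14, array(rnorm(12 * 12 * w[3]), c(12, 12, w[3], 1)))
  out <- rsam_fuse(model, 3, enc, dec)
  expect_equal(dim(out), dim(dec))
  expect_true(all(is.finite(out)))

  # with every rsam convolution zeroed: mask = sigmoid(0) = 0.5 everywhere,
  # the gated map is all-zero, its spatial softmax is uniform 1/(H'W'),
  # and the output is dec + 1/(H'W')
  mz <- zero_params(model, "^rsam\\.3\\.")
  outz <- rsam_fuse(mz, 3, enc, dec)
  expect_equal(outz, dec + 1 / (12 * 12), tolerance = 1e-12)

  expect_error(rsam_fuse(model, 3, enc, enc), class = "rfarn_invalid_input")
})

test_that("softmax normalisation slices sum to one in both attention modules", {
  rfarn:::tape_begin()
  x <- rfarn:::ad_leaf(with_seed(15, array(rnorm(8 * 8 * 3 * 2), c(8, 8, 3, 2))))
  s <- rfarn:::ad_spatial_softmax(x)$value
  for (c in 1:3) for (n in 1:2) {
    expect_equal(sum(s[, , c, n]), 1, tolerance = 1e-6)
  }
  avg <- rfarn:::ad_leaf(matrix(rnorm(8), 4, 2))
  mx <- rfarn:::ad_leaf(matrix(rnorm(8), 4, 2))
  A <- rfarn:::ad_chan_affinity(avg, mx)$value
  for (j in 1:4) for (n in 1:2) {
    expect_equal(sum(A[, j, n]), 1, tolerance = 1e-6)
  }
  rfarn:::tape_end()
})

test_that("the forward pass maps 48x48 patches to probabilities in (0,1)", {
  model <- fixture_model()
  x <- with_seed(16, matrix(runif(48 * 48), 48, 48))
  p <- rfarn_forward(model, x)
  expect_equal(dim(p), c(48, 48, 1))
  expect_true(all(p > 0 & p < 1))
  # deterministic inference
  expect_identical(p, rfarn_forward(model, x))
  expect_error(rfarn_forward(model, matrix(0, 32, 32)), class = "rfarn_invalid_input")
})

test_that("every parameter receives gradient in one optimisation step", {
  model <- fixture_model()
  x <- with_seed(17, array(runif(48 * 48), c(48, 48, 1, 1)))
  y <- with_seed(18, array(rbinom(48 * 48, 1, 0.15), c(48, 48, 1, 1)))
  rfarn:::tape_begin()
  g <- rfarn:::rfarn_graph(model, x, training = TRUE)
  loss <- rfarn:::ad_bce(g$out, y)
  rfarn:::ad_backward(loss)
  norms <- vapply(g$P, function(n) {
    if (is.null(n$grad)) 0 else sqrt(sum(n$grad^2))
  }, numeric(1))
  rfarn:::tape_end()
  expect_true(all(norms > 0), info = paste("zero-gradient params:",
              paste(names(norms)[norms == 0], collapse = ", ")))
})

test_that("network gradients agree with finite differences", {
  cfg <- network_config(patch_size = 8, depth = 2, base_channels = 2)
  model <- rfarn_init(cfg, seed = 3)
  x <- with_seed(19, array(runif(8 * 8 * 2), c(8, 8, 1, 2)))
  y <- with_seed(20, array(rbinom(8 * 8 * 2, 1, 0.3), c(8, 8, 1, 2)))
  bn0 <- model$bn
  loss_at <- function(params) {
    m2 <- rfarn_init(cfg, seed = 3)
    m2$params <- params
    m2$bn <- bn0
    rfarn:::tape_begin()
    g <- rfarn:::rfarn_graph(m2, x, training = TRUE)
    l <- rfarn:::ad_bce(g$out, y)$value
    rfarn:::tape_end()
    l
  }
  mg <- rfarn_init(cfg, seed = 3)
  rfarn:::tape_begin()
  g <- rfarn:::rfarn_graph(mg, x, training = TRUE)
  ln <- rfarn:::ad_bce(g$out, y)
  rfarn:::ad_backward(ln)
  grads <- lapply(g$P, function(n) n$grad)
  rfarn:::tape_end()
  eps <- 1e-6
  check <- c("enc.1.w1", "enc.2.w2", "enc.2.g1", "rcam.1.rho", "rcam.1.wc",
             "dec.1.w1", "rsam.1.wm", "head.w", "head.b")
  for (nm in check) {
    i <- with_seed(nchar(nm), sample(length(model$params[[nm]]), 1))
    pp <- model$params; pp[[nm]][i] <- pp[[nm]][i] + eps
    pm <- model$params; pm[[nm]][i] <- pm[[nm]][i] - eps
    fd <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
    expect_equal(grads[[nm]][i], fd, tolerance = 1e-4,
                 info = paste("gradient of", nm))
  }
})

test_that("checkpoints round-trip weights, statistics and configuration", {
  model <- fixture_model()
  path <- withr::local_tempfile(fileext = ".rds")
  rfarn_save(model, path)
  expect_true(file.exists(paste0(path, ".json")))
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$base_channels, model$config$base_channels)
  back <- rfarn_load(path)
  expect_equal(back$params, model$params)
  expect_equal(back$config, model$config)
  x <- with_seed(22, matrix(runif(48 * 48), 48, 48))
  expect_identical(rfarn_forward(back, x), rfarn_forward(model, x))
})

test_that("encoder/decoder shape algebra follows the 48-24-12-6 ladder", {
  model <- fixture_model()
  x <- with_seed(21, array(runif(48 * 48 * 2), c(48, 48, 1, 2)))
  rfarn:::tape_begin(grad = FALSE)
  P <- lapply(model$params, rfarn:::ad_leaf)
  pyr <- rfarn:::side_pyramid_batch(x, 4)
  sizes <- integer(4)
  pooled <- NULL
  for (i in 1:4) {
    f <- rfarn:::graph_encoder(P, model, i, pooled, rfarn:::ad_leaf(pyr[[i]]), FALSE)
    sizes[i] <- dim(f$value)[1]
    if (i < 4) pooled <- rfarn:::ad_maxpool2(f)
  }
  rfarn:::tape_end()
  expect_equal(sizes, c(48L, 24L, 12L, 6L))
})
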