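# MSRCR enhancement, grayscale conversion and normalisation.

test_that("single-scale retinex is zero on uniform input and matches a dense oracle", {
  # uniform image: log P - log(F * P) = 0 because the surround is unit-sum
  uni <- matrix(100, 16, 16)
  for (sigma in c(1, 5, 40)) {
    expect_equal(single_scale_retinex(uni, sigma), matrix(0, 16, 16))
  }

  # dense brute-force 2-D convolution oracle with the same truncated kernel
  # and reflect-101 borders, evaluated with explicit loops
  ramp <- matrix(rep(0:7, each = 8), 8, 8, byrow = TRUE)
  sigma <- 2; epsv <- 1
  k1 <- exp(-(-6:6)^2 / (2 * sigma^2)); k1 <- k1 / sum(k1)
  k2 <- outer(k1, k1)
  refl <- function(i, n) {
    while (i < 1 || i > n) { if (i < 1) i <- 2 - i; if (i > n) i <- 2 * n - i }
    i
  }
  surround <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8) {
    acc <- 0
    for (a in -6:6) for (b in -6:6) {
      acc <- acc + k2[a + 7, b + 7] * ramp[refl(i + a, 8), refl(j + b, 8)]
    }
    surround[i, j] <- acc
  }
  oracle <- log(ramp + epsv) - log(surround + epsv)
  expect_equal(single_scale_retinex(ramp, sigma, epsv), oracle, tolerance = 1e-6)

  # a bright pixel exceeds its local surround; its neighbourhood is depressed
  spot <- matrix(1, 9, 9); spot[5, 5] <- 255
  r <- single_scale_retinex(spot, 2)
  expect_gt(r[5, 5], 0)
  expect_lt(min(r), 0)
})

test_that("single-scale retinex validates its inputs", {
  m <- matrix(1, 4, 4)
  expect_error(single_scale_retinex(m, -1), class = "rfarn_invalid_parameter")
  expect_error(single_scale_retinex(m, 0), class = "rfarn_invalid_parameter")
  expect_error(single_scale_retinex(matrix(-1, 4, 4), 2), class = "rfarn_invalid_input")
})

test_that("multiscale retinex is the weighted sum of its scales", {
  img <- fixture_rgb(12, 12)[, , 2]
  cfg3 <- msrcr_config(sigmas = c(2, 5, 9))
  # degenerate weighting picks out one scale
  cfg1 <- msrcr_config(sigmas = c(2, 5, 9), weights = c(1, 0, 0))
  expect_equal(multi_scale_retinex(img, cfg1), single_scale_retinex(img, 2))
  # equal weights = arithmetic mean; linearity in the weights
  ssr <- lapply(c(2, 5, 9), function(s) single_scale_retinex(img, s))
  expect_equal(multi_scale_retinex(img, cfg3),
               (ssr[[1]] + ssr[[2]] + ssr[[3]]) / 3, tolerance = 1e-6)
  w <- c(0.5, 0.3, 0.2)
  cfgw <- msrcr_config(sigmas = c(2, 5, 9), weights = w)
  expect_equal(multi_scale_retinex(img, cfgw),
               w[1] * ssr[[1]] + w[2] * ssr[[2]] + w[3] * ssr[[3]],
               tolerance = 1e-6)
  # uniform input stays zero for any config
  expect_equal(multi_scale_retinex(matrix(42, 10, 10), cfg3), matrix(0, 10, 10))
  expect_error(msrcr_config(sigmas = c(2, 5), weights = c(1, 1, 1)),
               class = "rfarn_invalid_parameter")
})

test_that("colour restoration matches the closed-form gain", {
  px <- array(c(80, 80, 80), c(1, 1, 3))
  g <- color_restoration(px)
  expect_equal(g[1, 1, 1], g[1, 1, 2])
  expect_equal(g[1, 1, 2], g[1, 1, 3])

  px2 <- array(c(50, 100, 150), c(1, 1, 3))
  g2 <- color_restoration(px2, cr_alpha = 125, cr_beta = 46, epsilon = 1)
  # hand evaluation of beta * (log(alpha P_i + eps) - log(sum P_j + eps))
  expect_equal(g2[1, 1, 1], 46 * (log(125 * 50 + 1) - log(301)))
  expect_equal(g2[1, 1, 2], 46 * (log(125 * 100 + 1) - log(301)))
  expect_equal(g2[1, 1, 3], 46 * (log(125 * 150 + 1) - log(301)))

  g0 <- color_restoration(array(0, c(2, 2, 3)))
  expect_true(all(is.finite(g0)))
})

test_that("msrcr enhancement is deterministic and composes its stages", {
  cfg <- msrcr_config(sigmas = c(2, 4), weights = c(0.5, 0.5))
  img <- fixture_rgb(8, 8, seed = 3)
  out1 <- msrcr_enhance(img, cfg)
  out2 <- msrcr_enhance(img, cfg)
  expect_identical(out1, out2)
  expect_true(all(out1 >= 0 & out1 <= 255))

  # uniform image in, uniform image out (translation invariance per stage)
  uni <- array(120, c(10, 10, 3))
  outu <- msrcr_enhance(uni, cfg)
  for (c in 1:3) expect_equal(stats::sd(as.vector(outu[, , c])), 0)

  # explicit step-by-step composition oracle
  cr <- color_restoration(img, cfg$cr_alpha, cfg$cr_beta, cfg$epsilon)
  manual <- array(0, dim(img))
  for (c in 1:3) {
    prod <- cr[, , c] * multi_scale_retinex(img[, , c], cfg)
    mu <- mean(prod); sdv <- stats::sd(as.vector(prod))
    lo <- mu - 2 * sdv; hi <- mu + 2 * sdv
    manual[, , c] <- pmin(pmax((prod - lo) / (hi - lo) * 255, 0), 255)
  }
  expect_equal(out1, manual, tolerance = 1e-12)
})

test_that("grayscale conversion uses the 29.9/58.7/11.4 weighting", {
  px <- function(r, g, b) array(c(r, g, b), c(1, 1, 3))
  expect_equal(rgb_to_gray(px(255, 0, 0))[1, 1], 76.245)
  expect_equal(rgb_to_gray(px(0, 255, 0))[1, 1], 149.685)
  expect_equal(rgb_to_gray(px(0, 0, 255))[1, 1], 29.07)
  for (v in c(0, 17.5, 128, 255)) {
    expect_equal(rgb_to_gray(px(v, v, v))[1, 1], v)
  }
})

test_that("z-score normalisation standardises pooled pixels", {
  z <- zscore_normalize(matrix(c(1, 2, 3), 1, 3))
  expect_equal(as.vector(z$images), c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-6)

  imgs <- list(matrix(rnorm(40, 5, 3), 5, 8), matrix(rnorm(30, 7, 2), 5, 6))
  z2 <- zscore_normalize(imgs)
  px <- unlist(lapply(z2$images, as.vector))
  expect_lt(abs(mean(px)), 1e-6)
  expect_lt(abs(sqrt(mean((px - mean(px))^2)) - 1), 1e-6)

  # idempotence: re-standardising standardised data changes nothing
  z3 <- zscore_normalize(z2$images)
  expect_equal(z3$images[[1]], z2$images[[1]], tolerance = 1e-6)

  expect_error(zscore_normalize(matrix(5, 4, 4)), class = "rfarn_degenerate_input")
})

test_that("min-max rescaling hits its endpoints and preserves order", {
  x <- matrix(0:10, 1, 11)
  expect_equal(as.vector(minmax_rescale(x)), seq(0, 255, by = 25.5))
  y <- matrix(c(-2, 0, 2), 1, 3)
  expect_equal(as.vector(minmax_rescale(y)), c(0, 127.5, 255))
  r <- with_seed(4, matrix(rnorm(64), 8, 8))
  rs <- minmax_rescale(r)
  expect_equal(which.min(rs), which.min(r))
  expect_equal(which.max(rs), which.max(r))
  expect_equal(order(as.vector(rs)), order(as.vector(r)))
  expect_error(minmax_rescale(matrix(1, 3, 3)), class = "rfarn_degenerate_input")
})

test_that("the full preprocessing pipeline preserves shape and gains contrast", {
  cfg_lo <- synth_config(vessel_contrast = 20, illumination_gradient = 1.15,
                         noise_sigma = 3, seed = 11)
  smp <- render_fundus(generate_vessel_mask(cfg_lo), cfg_lo)
  out <- preprocess_image(smp$image)
  expect_equal(dim(out), dim(smp$image)[1:2])
  expect_gte(min(out), 0)
  expect_lte(max(out), 255)
  expect_identical(out, preprocess_image(smp$image))
  # enhancement stretches the low-contrast fixture
  expect_gt(stats::sd(as.vector(out)), stats::sd(as.vector(rgb_to_gray(smp$image))))
})

test_that("frozen training statistics are reapplied to held-out samples", {
  cfg <- synth_config(size = c(64, 64), seed = 21)
  samples <- make_synth_dataset(3, cfg)
  pp <- preprocess_samples(samples[1:2])
  held <- preprocess_samples(samples[3], stats = pp$stats)
  expect_equal(held$stats, pp$stats)
  expect_false(is.null(held$samples[[1]]$proc))
  # per-image stats differ from the frozen ones, so the images must too
  own <- preprocess_samples(samples[3])
  expect_false(isTRUE(all.equal(own$stats, pp$stats)))
})
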