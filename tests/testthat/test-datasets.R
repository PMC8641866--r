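# Loading, patch sampling, sliding windows, stitching and splits.

test_that("synthetic DRIVE-style layouts round-trip through the loader", {
  dir <- withr::local_tempdir()
  written <- make_synth_dataset(3, synth_config(size = c(64, 64), seed = 31), dir = dir)
  expect_length(list.files(file.path(dir, "images")), 3)
  expect_length(list.files(file.path(dir, "1st_manual")), 3)
  expect_length(list.files(file.path(dir, "mask")), 3)
  loaded <- load_dataset(dir, "synth")
  expect_length(loaded, 3)
  for (k in 1:3) {
    expect_true(all(loaded[[k]]$truth %in% c(0, 1)))
    expect_equal(loaded[[k]]$truth, written[[k]]$truth)
    expect_equal(loaded[[k]]$fov, written[[k]]$fov)
    expect_equal(loaded[[k]]$image, written[[k]]$image, tolerance = 0.51)
  }
  expect_error(load_dataset(file.path(dir, "nope"), "synth"), class = "rfarn_io_error")
})

test_that("STARE-style PPM layouts load with an all-ones FOV fallback", {
  dir <- withr::local_tempdir()
  dir.create(file.path(dir, "stare-images"))
  dir.create(file.path(dir, "labels-ah"))
  smp <- fixture_sample()
  write_image(smp$image, file.path(dir, "stare-images", "im0001.ppm"))
  write_image(smp$truth * 255, file.path(dir, "labels-ah", "im0001.ah.ppm"))
  loaded <- load_dataset(dir, "stare")
  expect_length(loaded, 1)
  expect_equal(loaded[[1]]$truth, smp$truth)
  expect_true(all(loaded[[1]]$fov == 1))
  expect_equal(loaded[[1]]$image, smp$image, tolerance = 0.51)
})

test_that("missing companion files produce a descriptive load error", {
  dir <- withr::local_tempdir()
  make_synth_dataset(2, synth_config(size = c(64, 64), seed = 32), dir = dir)
  file.remove(list.files(file.path(dir, "1st_manual"), full.names = TRUE)[1])
  err <- tryCatch(load_dataset(dir, "synth"), error = function(e) e)
  expect_s3_class(err, "rfarn_io_error")
  expect_match(conditionMessage(err), "01")
})

test_that("patch sampling is reproducible, sized and FOV-constrained", {
  smp <- fixture_sample()
  spec <- patch_spec(48, 5)
  a <- sample_patches(smp, 20, spec, seed = 42)
  b <- sample_patches(smp, 20, spec, seed = 42)
  expect_identical(a$corners, b$corners)
  expect_false(identical(a$corners, sample_patches(smp, 20, spec, seed = 43)$corners))
  for (p in a$patches) expect_equal(dim(p), c(48, 48))
  # every accepted patch has at least half its pixels inside the FOV
  for (k in seq_len(20)) {
    r <- a$corners[k, 1]; c <- a$corners[k, 2]
    expect_gte(mean(smp$fov[r + 1:48, c + 1:48]), 0.5)
  }
  expect_error(sample_patches(smp, 1, patch_spec(256, 5)), class = "rfarn_invalid_input")
})

test_that("corner sampling covers the valid grid like a uniform draw", {
  smp <- fixture_sample()
  ps <- sample_patches(smp, 1000, patch_spec(48, 5), seed = 7)
  H <- nrow(smp$fov); W <- ncol(smp$fov)
  # rows/cols achievable under the >= 50% FOV constraint, by enumeration
  sat_ok <- function(r, c) mean(smp$fov[r + 1:48, c + 1:48]) >= 0.5
  valid_r <- c(); valid_c <- c()
  for (r in 0:(H - 48)) for (c in 0:(W - 48)) {
    if (sat_ok(r, c)) { valid_r <- c(valid_r, r); valid_c <- c(valid_c, c) }
  }
  expect_gte(length(unique(ps$corners[, 1])) / length(unique(valid_r)), 0.9)
  expect_gte(length(unique(ps$corners[, 2])) / length(unique(valid_c)), 0.9)
})

test_that("sliding windows tile completely with a flush final corner", {
  # closed-form count on the DRIVE width: ceil((565 - 48) / 5) + 1 = 105
  img <- matrix(0, 48, 565)
  sw <- sliding_windows(img, patch_spec(48, 5))
  expect_equal(length(unique(sw$coords[, 2])), 105)
  expect_equal(length(unique(sw$coords[, 1])), 1)
  # exhaustive enumeration oracle for several widths
  for (w in c(48, 50, 565, 103)) {
    cs <- rfarn:::axis_corners(w, 48, 5)
    oracle <- sort(unique(c(seq(0, w - 48, by = 5), w - 48)))
    expect_equal(sort(cs), oracle)
  }
  # degenerate tiling: image equals the window
  sw1 <- sliding_windows(matrix(1, 48, 48), patch_spec(48, 5))
  expect_equal(sw1$coords, cbind(0L, 0L))
  # coverage: every pixel is inside at least one window
  img2 <- matrix(0, 97, 111)
  sw2 <- sliding_windows(img2, patch_spec(48, 7))
  cov <- matrix(0, 97, 111)
  for (k in seq_len(nrow(sw2$coords))) {
    r <- sw2$coords[k, 1]; c <- sw2$coords[k, 2]
    cov[r + 1:48, c + 1:48] <- cov[r + 1:48, c + 1:48] + 1
  }
  expect_true(all(cov >= 1))
})

test_that("stitching averages overlaps and inverts extraction", {
  # constant patches stitch to the constant
  coords <- rbind(c(0L, 0L), c(0L, 24L), c(24L, 0L), c(24L, 24L))
  patches <- array(0.7, c(48, 48, 4))
  st <- stitch_predictions(patches, coords, c(72, 72))
  expect_true(all(abs(st - 0.7) < 1e-12))

  # two half-overlapping patches: the overlap is the exact mean
  co2 <- rbind(c(0L, 0L), c(0L, 24L))
  p2 <- array(0, c(48, 48, 2)); p2[, , 1] <- 0.2; p2[, , 2] <- 0.8
  st2 <- stitch_predictions(p2, co2, c(48, 72))
  expect_true(all(st2[, 25:48] == 0.5))
  expect_true(all(st2[, 1:24] == 0.2))
  expect_true(all(st2[, 49:72] == 0.8))

  # extract-then-stitch reproduces an arbitrary map
  map <- with_seed(33, matrix(runif(90 * 130), 90, 130))
  sw <- sliding_windows(map, patch_spec(48, 11))
  back <- stitch_predictions(sw$patches, sw$coords, dim(map))
  expect_equal(back, map, tolerance = 1e-6)

  expect_error(stitch_predictions(list(), coords, c(48, 48)),
               class = "rfarn_invalid_input")
})

test_that("split plans partition the ids", {
  ids <- sprintf("%02d", 1:20)
  loo <- make_splits(ids, "leave_one_out")
  expect_length(loo, 20)
  for (f in loo) {
    expect_length(f$train_ids, 19)
    expect_length(intersect(f$train_ids, f$test_ids), 0)
  }
  expect_setequal(unlist(lapply(loo, `[[`, "test_ids")), ids)

  fixed <- make_splits(sprintf("%02d", 1:40), "fixed",
                       train_ids = sprintf("%02d", 1:20))
  expect_length(fixed[[1]]$train_ids, 20)
  expect_length(fixed[[1]]$test_ids, 20)
  expect_error(make_splits(ids, "fixed", train_ids = ids, test_ids = ids),
               class = "rfarn_invalid_parameter")
  expect_error(make_splits("a", "leave_one_out"), class = "rfarn_invalid_parameter")
})
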