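# Dataset handling: on-disk layouts for the public fundus collections (and
# the synthetic mirror of the DRIVE layout), random patch sampling for
# training, sliding-window enumeration and prediction stitching for
# inference, and train/test split plans including leave-one-out.

#' Construct a fundus sample
#'
#' One fundus photograph together with its binary vessel ground truth and
#' binary field-of-view (FOV) mask.
#'
#' @param image H x W x 3 RGB array (0-255).
#' @param truth Binary H x W vessel mask.
#' @param fov Binary H x W field-of-view mask.
#' @param id Sample identifier.
#' @param dataset One of `"DRIVE"`, `"STARE"`, `"CHASE"`, `"SYNTH"`.
#' @return An object of class `fundus_sample`.
#' @export
fundus_sample <- function(image, truth, fov, id, dataset = "SYNTH") {
  validate_rgb(image)
  d <- dim(image)[1:2]
  if (!is.matrix(truth) || !all(dim(truth) == d)) abort_input("truth must match image size")
  if (!is.matrix(fov) || !all(dim(fov) == d)) abort_input("fov must match image size")
  if (!all(truth %in% c(0, 1))) abort_input("truth must be binary")
  if (!all(fov %in% c(0, 1))) abort_input("fov must be binary")
  dataset <- match.arg(dataset, c("DRIVE", "STARE", "CHASE", "SYNTH"))
  structure(list(image = image, truth = truth, fov = fov,
                 id = as.character(id), dataset = dataset, proc = NULL),
            class = "fundus_sample")
}

#' @export
print.fundus_sample <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<fundus_sample %s [%s] %dx%d, vessel fraction %.3f%s>\n",
              x$id, x$dataset, d[1], d[2],
              sum(x$truth) / sum(x$fov),
              if (is.null(x$proc)) "" else ", preprocessed"))
  invisible(x)
}

img_exts <- c("png", "tif", "tiff", "ppm", "pgm")

find_role_file <- function(dir, pattern, id) {
  if (!dir.exists(dir)) return(NA_character_)
  files <- list.files(dir, full.names = TRUE)
  files <- files[tolower(tools::file_ext(files)) %in% img_exts]
  hit <- files[grepl(pattern, basename(files), fixed = TRUE)]
  if (length(hit) == 0) NA_character_ else hit[[1]]
}

to_rgb <- function(img) {
  if (is.matrix(img)) {
    a <- array(0, c(dim(img), 3))
    for (c in 1:3) a[, , c] <- img
    a
  } else {
    img
  }
}

binarize_mask <- function(img) {
  if (!is.matrix(img)) img <- rgb_to_gray(img)
  (img > 127) + 0
}

#' Load a fundus dataset from disk
#'
#' Reads one of the supported directory layouts and returns a list of
#' [fundus_sample()] objects. Truth and FOV rasters are binarised at
#' intensity 127. The STARE layout synthesises an all-ones FOV when no mask
#' directory is present.
#'
#' Layouts (files may use any supported raster format - png, tif/tiff,
#' ppm/pgm):
#' * `drive` / `synth`: `images/`, `1st_manual/`, `mask/`; ids are the
#'   leading `_`-separated token of each image file name.
#' * `stare`: `stare-images/`, `labels-ah/`, optional `masks/`.
#' * `chase`: `Image_*` files beside `*_1stHO` label files.
#'
#' @param root Dataset root directory.
#' @param layout One of `"drive"`, `"stare"`, `"chase"`, `"synth"`.
#' @return List of `fundus_sample` objects, ordered by id.
#' @export
load_dataset <- function(root, layout = c("synth", "drive", "stare", "chase")) {
  layout <- match.arg(layout)
  if (!dir.exists(root)) abort_io(paste0("dataset root does not exist: ", root))
  ds_name <- c(drive = "DRIVE", stare = "STARE", chase = "CHASE", synth = "SYNTH")[layout]
  if (layout %in% c("drive", "synth")) {
    img_dir <- file.path(root, "images")
    lab_dir <- file.path(root, "1st_manual")
    fov_dir <- file.path(root, "mask")
    imgs <- list.files(img_dir)
    imgs <- sort(imgs[tolower(tools::file_ext(imgs)) %in% img_exts])
    if (length(imgs) == 0) abort_io(paste0("no images found under ", img_dir))
    ids <- vapply(strsplit(imgs, "_"), `[[`, character(1), 1)
    samples <- lapply(seq_along(imgs), function(k) {
      id <- ids[[k]]
      lab <- find_role_file(lab_dir, paste0(id, "_"), id)
      fov <- find_role_file(fov_dir, paste0(id, "_"), id)
      if (is.na(lab)) abort_io(paste0("missing ground-truth file for id ", id))
      if (is.na(fov)) abort_io(paste0("missing FOV mask file for id ", id))
      fundus_sample(to_rgb(read_image(file.path(img_dir, imgs[[k]]))),
                    binarize_mask(read_image(lab)),
                    binarize_mask(read_image(fov)), id, ds_name)
    })
  } else if (layout == "stare") {
    img_dir <- file.path(root, "stare-images")
    lab_dir <- file.path(root, "labels-ah")
    fov_dir <- file.path(root, "masks")
    imgs <- list.files(img_dir)
    imgs <- sort(imgs[tolower(tools::file_ext(imgs)) %in% img_exts])
    if (length(imgs) == 0) abort_io(paste0("no images found under ", img_dir))
    ids <- tools::file_path_sans_ext(imgs)
    samples <- lapply(seq_along(imgs), function(k) {
      id <- ids[[k]]
      lab <- find_role_file(lab_dir, id, id)
      if (is.na(lab)) abort_io(paste0("missing label file for id ", id))
      img <- to_rgb(read_image(file.path(img_dir, imgs[[k]])))
      fov_file <- find_role_file(fov_dir, id, id)
      fov <- if (is.na(fov_file)) {
        matrix(1, dim(img)[1], dim(img)[2])
      } else {
        binarize_mask(read_image(fov_file))
      }
      fundus_sample(img, binarize_mask(read_image(lab)), fov, id, ds_name)
    })
  } else {  # chase
    files <- list.files(root)
    files <- files[tolower(tools::file_ext(files)) %in% img_exts]
    imgs <- sort(files[grepl("^Image_", files) & !grepl("1stHO|2ndHO", files)])
    if (length(imgs) == 0) abort_io(paste0("no Image_* files found under ", root))
    ids <- tools::file_path_sans_ext(imgs)
    samples <- lapply(seq_along(imgs), function(k) {
      id <- ids[[k]]
      lab <- find_role_file(root, paste0(id, "_1stHO"), id)
      if (is.na(lab)) abort_io(paste0("missing 1stHO label for id ", id))
      img <- to_rgb(read_image(file.path(root, imgs[[k]])))
      fundus_sample(img, binarize_mask(read_image(lab)),
                    matrix(1, dim(img)[1], dim(img)[2]), id, ds_name)
    })
  }
  samples
}

#' Patch extraction geometry
#'
#' @param size Patch side in pixels (48 for training and inference).
#' @param stride Sliding-window step at test time (5 pixels).
#' @return An object of class `patch_spec`. Coordinates are 0-based
#'   `(row, col)` top-left corners with half-open extents.
#' @export
patch_spec <- function(size = 48, stride = 5) {
  if (!is_count(size) || !is_count(stride)) abort_param("size and stride must be positive integers")
  structure(list(size = as.integer(size), stride = as.integer(stride)),
            class = "patch_spec")
}

sample_source_image <- function(sample) {
  if (!is.null(sample$proc)) sample$proc else rgb_to_gray(sample$image)
}

#' Randomly sample training patches from one fundus sample
#'
#' Draws `n` patch corners uniformly over all valid positions, rejecting
#' corners whose patch covers less than half field-of-view pixels (avoids
#' training dominated by the black camera border). Fully reproducible given
#' the seed. Patches are taken from the preprocessed image when present
#' (`sample$proc`), otherwise from the grayscale of the raw image.
#'
#' @param sample A [fundus_sample()].
#' @param n Number of patches.
#' @param spec A [patch_spec()].
#' @param seed Integer seed.
#' @param min_fov Minimum fraction of the patch inside the FOV.
#' @return List with `patches` (list of size x size matrices), `truths`
#'   (aligned binary matrices) and `corners` (n x 2, 0-based row/col).
#' @export
sample_patches <- function(sample, n, spec = patch_spec(), seed = 1,
                           min_fov = 0.5) {
  img <- sample_source_image(sample)
  s <- spec$size
  H <- nrow(img)
  W <- ncol(img)
  if (H < s || W < s) abort_input("image smaller than the patch size")
  # summed-area table of the fov for O(1) coverage queries
  sat <- apply(apply(sample$fov, 2, cumsum), 1, cumsum)  # W x H (transposed)
  frac_in_fov <- function(r, c) {
    # patch rows r+1..r+s, cols c+1..c+s (1-based)
    r2 <- r + s; c2 <- c + s
    tot <- sat[c2, r2] -
      (if (c > 0) sat[c, r2] else 0) -
      (if (r > 0) sat[c2, r] else 0) +
      (if (r > 0 && c > 0) sat[c, r] else 0)
    tot / s^2
  }
  corners <- matrix(0L, n, 2)
  with_seed(seed, {
    k <- 0
    guard <- 0
    while (k < n) {
      guard <- guard + 1
      if (guard > 1000 * n) abort_input("could not find patches meeting the FOV constraint")
      r <- sample.int(H - s + 1, 1) - 1L
      c <- sample.int(W - s + 1, 1) - 1L
      if (frac_in_fov(r, c) >= min_fov) {
        k <- k + 1
        corners[k, ] <- c(r, c)
      }
    }
  })
  patches <- vector("list", n)
  truths <- vector("list", n)
  for (k in seq_len(n)) {
    r <- corners[k, 1]; c <- corners[k, 2]
    patches[[k]] <- img[r + seq_len(s), c + seq_len(s)]
    truths[[k]] <- sample$truth[r + seq_len(s), c + seq_len(s)]
  }
  list(patches = patches, truths = truths, corners = corners)
}

axis_corners <- function(extent, size, stride) {
  if (extent <= size) return(0L)
  last <- extent - size
  cs <- seq.int(0L, last, by = stride)
  if (cs[length(cs)] != last) cs <- c(cs, last)
  cs
}

#' Enumerate sliding-window patches over an image
#'
#' Corners are placed every `stride` pixels along each axis, plus a final
#' corner flush with the far edge so every pixel is covered. If the image is
#' smaller than the patch along an axis, the patch is zero-filled beyond the
#' image.
#'
#' @param image Grayscale matrix.
#' @param spec A [patch_spec()].
#' @return List with `coords` (n x 2, 0-based row/col) and `patches`
#'   (size x size x n array).
#' @export
sliding_windows <- function(image, spec = patch_spec()) {
  validate_gray(image)
  s <- spec$size
  rows <- axis_corners(nrow(image), s, spec$stride)
  cols <- axis_corners(ncol(image), s, spec$stride)
  coords <- cbind(rep(rows, times = length(cols)),
                  rep(cols, each = length(rows)))
  patches <- array(0, c(s, s, nrow(coords)))
  H <- nrow(image); W <- ncol(image)
  for (k in seq_len(nrow(coords))) {
    r <- coords[k, 1]; c <- coords[k, 2]
    ri <- seq_len(min(s, H - r)); ci <- seq_len(min(s, W - c))
    patches[ri, ci, k] <- image[r + ri, c + ci]
  }
  list(coords = coords, patches = patches)
}

#' Stitch per-patch predictions into a full probability map
#'
#' Overlapping predictions are averaged pixel-wise (sum divided by coverage);
#' contributions falling outside the target shape are discarded.
#'
#' @param patches size x size x n array (or list) of probability patches.
#' @param coords n x 2 matrix of 0-based top-left corners.
#' @param shape Target `(H, W)`.
#' @return H x W probability map.
#' @export
stitch_predictions <- function(patches, coords, shape) {
  if (is.list(patches)) {
    if (length(patches) == 0) abort_input("empty patch list")
    patches <- array(unlist(patches), c(dim(patches[[1]]), length(patches)))
  }
  if (length(dim(patches)) != 3 || dim(patches)[3] == 0) abort_input("empty patch list")
  s <- dim(patches)[1]
  H <- shape[1]; W <- shape[2]
  acc <- matrix(0, H, W)
  cov <- matrix(0, H, W)
  for (k in seq_len(dim(patches)[3])) {
    r <- coords[k, 1]; c <- coords[k, 2]
    ri <- seq_len(min(s, H - r)); ci <- seq_len(min(s, W - c))
    acc[r + ri, c + ci] <- acc[r + ri, c + ci] + patches[ri, ci, k]
    cov[r + ri, c + ci] <- cov[r + ri, c + ci] + 1
  }
  out <- acc
  nz <- cov > 0
  out[nz] <- acc[nz] / cov[nz]
  out
}

#' Build train/test split plans
#'
#' @param ids Character vector of sample ids (or a list of samples, from
#'   which ids are taken).
#' @param scheme `"fixed"` (one plan) or `"leave_one_out"` (one plan per
#'   sample, each id tested exactly once).
#' @param train_ids,test_ids For the fixed scheme: explicit id partition.
#'   When omitted, the first half of `ids` trains and the rest tests.
#' @return List of plans, each `list(train_ids, test_ids, scheme)`.
#' @export
make_splits <- function(ids, scheme = c("fixed", "leave_one_out"),
                        train_ids = NULL, test_ids = NULL) {
  scheme <- match.arg(scheme)
  if (is.list(ids)) ids <- vapply(ids, function(s) s$id, character(1))
  ids <- as.character(ids)
  if (scheme == "leave_one_out") {
    if (length(ids) < 2) abort_param("leave-one-out needs at least 2 samples")
    return(lapply(seq_along(ids), function(k) {
      list(train_ids = ids[-k], test_ids = ids[k], scheme = scheme)
    }))
  }
  if (is.null(train_ids)) {
    half <- floor(length(ids) / 2)
    train_ids <- ids[seq_len(half)]
    test_ids <- ids[-seq_len(half)]
  } else if (is.null(test_ids)) {
    test_ids <- setdiff(ids, train_ids)
  }
  if (length(intersect(train_ids, test_ids)) > 0) {
    abort_param("train and test ids overlap")
  }
  list(list(train_ids = as.character(train_ids),
            test_ids = as.character(test_ids), scheme = scheme))
}
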