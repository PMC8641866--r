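# Synthetic fundus generator: seed-reproducible branching vessel trees
# rendered into low-contrast, unevenly illuminated, noisy RGB images with a
# circular field of view. Every sample is a pure function of (config, index),
# so all other modules are testable without downloading clinical data.

#' Synthetic fundus configuration
#'
#' Defaults emulate the properties the enhancement stage targets - vessels
#' darkest in the green channel, a radial illumination fall-off and additive
#' sensor noise - at a 128 x 128 size that keeps full-pipeline runs
#' desk-scale. Clinical-resolution generation is available by raising `size`.
#'
#' @param size `(H, W)` in pixels (at least 64 x 64).
#' @param n_trees Number of vessel trees grown from the optic-disc region.
#' @param branch_prob Probability per step of spawning a child branch.
#' @param max_depth Maximum branching level.
#' @param width_root Stamp width of a root branch, pixels.
#' @param width_decay Width multiplier per branching level, in (0, 1).
#' @param vessel_contrast Intensity drop of vessels in the green channel.
#' @param illumination_gradient Centre-to-edge brightness ratio (> 1 darkens
#'   the periphery).
#' @param noise_sigma Additive Gaussian noise standard deviation.
#' @param fov_radius_frac FOV radius as a fraction of `min(H, W) / 2`.
#' @param seed Integer seed; every sample is reproducible from it.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(size = c(128, 128), n_trees = 5, branch_prob = 0.04,
                         max_depth = 4, width_root = 2.6, width_decay = 0.75,
                         vessel_contrast = 55, illumination_gradient = 1.6,
                         noise_sigma = 8, fov_radius_frac = 0.95, seed = 1) {
  if (length(size) != 2 || any(size < 64)) abort_param("size must be at least 64 x 64")
  if (branch_prob < 0 || branch_prob > 1) abort_param("branch_prob must be in [0, 1]")
  if (width_decay <= 0 || width_decay >= 1) abort_param("width_decay must be in (0, 1)")
  if (noise_sigma < 0) abort_param("noise_sigma must be >= 0")
  structure(list(size = as.integer(size), n_trees = as.integer(n_trees),
                 branch_prob = branch_prob, max_depth = as.integer(max_depth),
                 width_root = width_root, width_decay = width_decay,
                 vessel_contrast = vessel_contrast,
                 illumination_gradient = illumination_gradient,
                 noise_sigma = noise_sigma, fov_radius_frac = fov_radius_frac,
                 seed = as.integer(seed)),
            class = "synth_config")
}

stamp_disc <- function(mask, r, c, radius) {
  H <- nrow(mask); W <- ncol(mask)
  ir <- max(1, floor(r - radius)):min(H, ceiling(r + radius))
  ic <- max(1, floor(c - radius)):min(W, ceiling(c + radius))
  for (i in ir) for (j in ic) {
    if ((i - r)^2 + (j - c)^2 <= radius^2) mask[i, j] <- 1
  }
  mask
}

#' Generate a binary vessel-tree mask
#'
#' Grows `n_trees` recursive branching random walks from seed points near an
#' optic-disc location: each step advances with angular jitter and stamps a
#' disc of the branch's current width; child branches spawn with
#' `branch_prob` and their width decays by `width_decay` per level. The walk
#' stops at the field-of-view boundary.
#'
#' @param cfg A [synth_config()].
#' @return Binary H x W matrix; identical for identical configs.
#' @export
generate_vessel_mask <- function(cfg = synth_config()) {
  H <- cfg$size[1]; W <- cfg$size[2]
  mask <- matrix(0, H, W)
  if (cfg$n_trees == 0) {
    warning("zero vessel trees requested; returning an empty mask")
    return(mask)
  }
  ctr <- c(H, W) / 2
  fov_r <- cfg$fov_radius_frac * min(H, W) / 2
  disc <- ctr + c(0, -0.55 * fov_r)  # optic disc left of centre
  with_seed(cfg$seed, {
    # stack of branches: position, angle, width, depth
    for (t in seq_len(cfg$n_trees)) {
      ang0 <- runif(1, -pi / 2.2, pi / 2.2)  # fan out towards image centre
      stack <- list(list(pos = disc + rnorm(2, 0, 1.5), ang = ang0,
                         width = cfg$width_root, depth = 1))
      while (length(stack) > 0) {
        br <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        pos <- br$pos; ang <- br$ang
        # deeper branches are shorter, as in real vascular trees
        n_steps <- round(110 * 0.65^(br$depth - 1))
        for (step in seq_len(n_steps)) {
          pos <- pos + 1.8 * c(sin(ang), cos(ang))
          if (sum((pos - ctr)^2) > (1.02 * fov_r)^2) break
          if (pos[1] < 1 || pos[1] > H || pos[2] < 1 || pos[2] > W) break
          ang <- ang + rnorm(1, 0, 0.16)
          mask <- stamp_disc(mask, pos[1], pos[2], br$width / 2)
          if (br$depth < cfg$max_depth && runif(1) < cfg$branch_prob) {
            side <- sample(c(-1, 1), 1)
            stack[[length(stack) + 1]] <-
              list(pos = pos, ang = ang + side * runif(1, 0.5, 1.0),
                   width = br$width * cfg$width_decay, depth = br$depth + 1)
          }
        }
      }
    }
  })
  mask
}

#' Render a vessel mask into a fundus-like RGB sample
#'
#' Builds a reddish background (R > G > B) modulated by a radial illumination
#' gradient, darkens the green channel (and, more weakly, red) along the
#' vessels, adds Gaussian noise, and cuts a circular field of view. The truth
#' mask is the input mask restricted to the FOV.
#'
#' @param mask Binary vessel mask matching `cfg$size`.
#' @param cfg A [synth_config()].
#' @param id Sample identifier.
#' @return A [fundus_sample()].
#' @export
render_fundus <- function(mask, cfg = synth_config(), id = "synth") {
  H <- cfg$size[1]; W <- cfg$size[2]
  if (!all(dim(mask) == c(H, W))) abort_input("mask size must match cfg$size")
  ctr <- c(H, W) / 2
  fov_r <- cfg$fov_radius_frac * min(H, W) / 2
  rr <- outer(seq_len(H) - ctr[1], rep(1, W))
  cc <- outer(rep(1, H), seq_len(W) - ctr[2])
  dist2 <- rr^2 + cc^2
  fov <- (dist2 <= fov_r^2) + 0
  # radial illumination: 1 at the centre, 1/gradient at the FOV edge
  g <- cfg$illumination_gradient
  illum <- 1 - (1 - 1 / g) * pmin(dist2 / fov_r^2, 1)
  base <- c(r = 185, g = 125, b = 70)
  drop <- c(r = 0.45, g = 1, b = 0.15) * cfg$vessel_contrast
  img <- array(0, c(H, W, 3))
  with_seed(child_seed(cfg$seed, 104729L), {
    for (ch in 1:3) {
      plane <- (base[ch] - drop[ch] * mask) * illum
      if (cfg$noise_sigma > 0) plane <- plane + rnorm(H * W, 0, cfg$noise_sigma)
      plane[fov == 0] <- 8
      img[, , ch] <- pmin(pmax(plane, 0), 255)
    }
  })
  fundus_sample(img, mask * fov, fov, id, "SYNTH")
}

#' Generate a synthetic dataset
#'
#' Produces `n` samples with per-sample derived seeds (`cfg$seed + i`), and
#' optionally writes them to disk in the DRIVE-style layout (`images/`,
#' `1st_manual/`, `mask/`, PNG files) read back by
#' `load_dataset(dir, "synth")`.
#'
#' @param n Number of samples.
#' @param cfg A [synth_config()]; its seed is the master seed.
#' @param dir Optional output directory.
#' @return List of [fundus_sample()] objects (invisibly when written).
#' @export
make_synth_dataset <- function(n, cfg = synth_config(), dir = NULL) {
  if (!is_count(n)) abort_param("n must be a positive integer")
  samples <- lapply(seq_len(n), function(i) {
    ci <- cfg
    ci$seed <- cfg$seed + i
    id <- sprintf("%02d", i)
    render_fundus(generate_vessel_mask(ci), ci, id = id)
  })
  if (!is.null(dir)) {
    for (sub in c("images", "1st_manual", "mask")) {
      ok <- dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)
      if (!dir.exists(file.path(dir, sub))) abort_io(paste0("cannot create ", file.path(dir, sub)))
    }
    for (s in samples) {
      write_image(s$image, file.path(dir, "images", paste0(s$id, "_synth.png")))
      write_image(s$truth * 255, file.path(dir, "1st_manual", paste0(s$id, "_manual1.png")))
      write_image(s$fov * 255, file.path(dir, "mask", paste0(s$id, "_mask.png")))
    }
    yaml::write_yaml(unclass(cfg), file.path(dir, "synth_config.yaml"))
    return(invisible(samples))
  }
  samples
}
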