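# Training: pixel-wise binary cross-entropy, Adam with decoupled-from-nothing
# classic L2 weight decay, and plateau learning-rate decay driven by a
# held-out validation loss.

#' Training configuration
#'
#' Defaults follow the published recipe: Adam (beta1 0.9, beta2 0.999,
#' eps 1e-8), learning rate 0.001, weight decay 0.0005, batch size 32,
#' 200 epochs, 48 x 48 patches, plateau learning-rate decay.
#'
#' @param lr Initial learning rate.
#' @param beta1,beta2,adam_eps Adam moment coefficients and stabiliser.
#' @param weight_decay L2 coefficient added to the gradient.
#' @param batch_size Patches per optimisation step.
#' @param epochs Training epochs.
#' @param patches_per_epoch Freshly sampled patches per epoch.
#' @param plateau_patience Epochs without validation improvement before the
#'   learning rate is multiplied by `plateau_factor`.
#' @param plateau_factor Multiplicative decay in (0, 1).
#' @param min_lr Learning-rate floor.
#' @param val_fraction Fraction of each epoch's patches held out for the
#'   plateau criterion.
#' @param seed Root seed for patch sampling and shuffling.
#' @return An object of class `train_config`.
#' @export
train_config <- function(lr = 0.001, beta1 = 0.9, beta2 = 0.999,
                         adam_eps = 1e-8, weight_decay = 5e-4,
                         batch_size = 32, epochs = 200,
                         patches_per_epoch = 4096, plateau_patience = 10,
                         plateau_factor = 0.5, min_lr = 1e-6,
                         val_fraction = 0.1, seed = 1) {
  vals <- c(lr = lr, beta1 = beta1, beta2 = beta2, adam_eps = adam_eps,
            batch_size = batch_size, epochs = epochs,
            patches_per_epoch = patches_per_epoch,
            plateau_patience = plateau_patience,
            plateau_factor = plateau_factor, min_lr = min_lr)
  bad <- names(vals)[!is.finite(vals) | vals <= 0]
  if (weight_decay < 0) bad <- c(bad, "weight_decay")
  if (plateau_factor >= 1) bad <- c(bad, "plateau_factor")
  if (length(bad)) abort_param(paste0("invalid training parameters: ",
                                      paste(unique(bad), collapse = ", ")))
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2, adam_eps = adam_eps,
                 weight_decay = weight_decay, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 patches_per_epoch = as.integer(patches_per_epoch),
                 plateau_patience = as.integer(plateau_patience),
                 plateau_factor = plateau_factor, min_lr = min_lr,
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "train_config")
}

#' Mean binary cross-entropy
#'
#' `-(1/n) sum(p log q + (1 - p) log(1 - q))` over all pixels, with
#' predictions clamped to `[eps, 1 - eps]`.
#'
#' @param pred Predicted probabilities (any shape).
#' @param truth Binary labels of the same shape.
#' @param eps Clamping floor.
#' @return Non-negative scalar loss.
#' @export
bce_loss <- function(pred, truth, eps = 1e-7) {
  if (length(pred) != length(truth)) abort_input("pred and truth shapes differ")
  q <- pmin(pmax(pred, eps), 1 - eps)
  -mean(truth * log(q) + (1 - truth) * log(1 - q))
}

#' Plateau learning-rate scheduler
#'
#' `plateau_init()` creates the scheduler state; `plateau_step()` consumes
#' one validation loss. After `patience` consecutive epochs without
#' improvement the learning rate is multiplied by `factor` (never below
#' `min_lr`).
#'
#' @param lr Initial learning rate.
#' @param patience Epochs without improvement tolerated.
#' @param factor Multiplicative decay in (0, 1).
#' @param min_lr Floor.
#' @return Scheduler state list with element `lr`.
#' @export
plateau_init <- function(lr, patience = 10, factor = 0.5, min_lr = 1e-6) {
  list(lr = lr, best = Inf, bad = 0L, patience = as.integer(patience),
       factor = factor, min_lr = min_lr)
}

#' @rdname plateau_init
#' @param state Scheduler state.
#' @param val_loss Finite validation loss for the epoch.
#' @export
plateau_step <- function(state, val_loss) {
  if (!is.finite(val_loss)) abort_input("val_loss must be finite")
  if (val_loss < state$best) {
    state$best <- val_loss
    state$bad <- 0L
  } else {
    state$bad <- state$bad + 1L
    if (state$bad >= state$patience) {
      state$lr <- max(state$lr * state$factor, state$min_lr)
      state$bad <- 0L
    }
  }
  state
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(opt, params, grads, lr, cfg) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - cfg$beta1^opt$t
  bc2 <- 1 - cfg$beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    g <- g + cfg$weight_decay * params[[nm]]
    opt$m[[nm]] <- cfg$beta1 * opt$m[[nm]] + (1 - cfg$beta1) * g
    opt$v[[nm]] <- cfg$beta2 * opt$v[[nm]] + (1 - cfg$beta2) * g^2
    step <- (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + cfg$adam_eps)
    params[[nm]] <- params[[nm]] - lr * step
  }
  list(opt = opt, params = params)
}

# one optimisation step on a batch; returns the loss and updates model/opt
train_step <- function(model, opt, xb, yb, lr, cfg) {
  tape_begin()
  g <- rfarn_graph(model, xb, training = TRUE)
  loss_node <- ad_bce(g$out, yb)
  loss <- loss_node$value
  if (!is.finite(loss)) {
    tape_end()
    rf_abort(sprintf("non-finite training loss at Adam step %d", opt$t + 1L),
             "rfarn_nan_loss")
  }
  ad_backward(loss_node)
  grads <- lapply(g$P, function(n) n$grad)
  tape_end()
  upd <- adam_step(opt, model$params, grads, lr, cfg)
  model$params <- upd$params
  list(opt = upd$opt, loss = loss)
}

batch_from <- function(patches, truths, idx, size) {
  xb <- array(0, c(size, size, 1, length(idx)))
  yb <- array(0, c(size, size, 1, length(idx)))
  for (j in seq_along(idx)) {
    xb[, , 1, j] <- patches[[idx[j]]] / 255
    yb[, , 1, j] <- truths[[idx[j]]]
  }
  list(x = xb, y = yb)
}

#' Train a network on fundus samples
#'
#' Each epoch freshly samples `patches_per_epoch` random patches across the
#' training samples, holds out `val_fraction` of them for the plateau
#' criterion, and performs Adam steps on shuffled mini-batches. Fully
#' reproducible given `cfg$seed`. Samples are preprocessed first (shared
#' Z-score statistics across the training set) unless they already carry a
#' `proc` image.
#'
#' @param model An [rfarn_init()] model (updated in place and returned).
#' @param samples List of [fundus_sample()] objects.
#' @param cfg A [train_config()].
#' @param msrcr An [msrcr_config()] used if samples still need preprocessing.
#' @param spec A [patch_spec()]; only `size` is used during training.
#' @param verbose Print one line per epoch.
#' @return List with `model`, `history` (tibble: epoch, loss, val_loss, lr)
#'   and `stats` (frozen normalisation statistics, or NULL).
#' @export
train_model <- function(model, samples, cfg = train_config(),
                        msrcr = msrcr_config(), spec = patch_spec(),
                        verbose = FALSE) {
  if (length(samples) < 1) abort_input("need at least one training sample")
  stats <- NULL
  if (any(vapply(samples, function(s) is.null(s$proc), logical(1)))) {
    pp <- preprocess_samples(samples, msrcr)
    samples <- pp$samples
    stats <- pp$stats
  }
  size <- model$config$patch_size
  sched <- plateau_init(cfg$lr, cfg$plateau_patience, cfg$plateau_factor, cfg$min_lr)
  opt <- adam_init(model$params)
  hist <- list()
  per_sample <- ceiling(cfg$patches_per_epoch / length(samples))
  for (epoch in seq_len(cfg$epochs)) {
    eseed <- child_seed(cfg$seed, epoch)
    pool_p <- list()
    pool_t <- list()
    for (si in seq_along(samples)) {
      ps <- sample_patches(samples[[si]], per_sample, patch_spec(size, 1),
                           seed = child_seed(eseed, si))
      pool_p <- c(pool_p, ps$patches)
      pool_t <- c(pool_t, ps$truths)
    }
    n <- length(pool_p)
    ord <- with_seed(child_seed(eseed, 0L), sample.int(n))
    n_val <- max(1L, floor(cfg$val_fraction * n))
    val_idx <- ord[seq_len(n_val)]
    tr_idx <- ord[-seq_len(n_val)]
    losses <- c()
    for (start in seq(1, length(tr_idx), by = cfg$batch_size)) {
      take <- tr_idx[start:min(start + cfg$batch_size - 1, length(tr_idx))]
      b <- batch_from(pool_p, pool_t, take, size)
      st <- train_step(model, opt, b$x, b$y, sched$lr, cfg)
      opt <- st$opt
      losses <- c(losses, st$loss)
    }
    vb <- batch_from(pool_p, pool_t, val_idx, size)
    val_pred <- rfarn_forward(model, vb$x)
    val_loss <- bce_loss(val_pred, vb$y[, , 1, ])
    lr_now <- sched$lr
    sched <- plateau_step(sched, val_loss)
    hist[[epoch]] <- c(epoch = epoch, loss = mean(losses),
                       val_loss = val_loss, lr = lr_now)
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  val %.4f  lr %.2g",
                      epoch, mean(losses), val_loss, lr_now))
    }
  }
  history <- tibble::as_tibble(do.call(rbind, hist))
  list(model = model, history = history, stats = stats)
}

#' Predict a vessel probability map for one image
#'
#' Slides `spec`-sized windows over the (preprocessed) image, runs the
#' network on every patch and stitches the per-patch probabilities back with
#' overlap averaging.
#'
#' @param model Trained `rfarn_model`.
#' @param image Preprocessed grayscale matrix on the 0-255 scale.
#' @param spec A [patch_spec()] (stride 5 reproduces the published
#'   inference protocol).
#' @return H x W probability map in [0, 1].
#' @export
predict_image <- function(model, image, spec = patch_spec()) {
  sw <- sliding_windows(image, spec)
  probs <- rfarn_forward(model, sw$patches / 255)
  stitch_predictions(probs, sw$coords, dim(image))
}

#' Predict probability maps for a list of samples
#'
#' @param model Trained `rfarn_model`.
#' @param samples List of [fundus_sample()] with `proc` images (run
#'   [preprocess_samples()] with the training statistics first).
#' @param spec A [patch_spec()].
#' @return Named list of probability maps.
#' @export
predict_samples <- function(model, samples, spec = patch_spec()) {
  out <- lapply(samples, function(s) predict_image(model, sample_source_image(s), spec))
  names(out) <- vapply(samples, function(s) s$id, character(1))
  out
}
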