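# Shared fixtures. Everything is generated in code; heavier objects are
# cached for the session so several test files can reuse them.

.fix <- new.env()

with_seed <- rfarn:::with_seed

# small deterministic RGB test image
fixture_rgb <- function(h = 16, w = 16, seed = 1) {
  with_seed(seed, array(runif(h * w * 3, 0, 255), c(h, w, 3)))
}

# one rendered synthetic sample (cached)
fixture_sample <- function(seed = 7) {
  key <- paste0("sample", seed)
  if (is.null(.fix[[key]])) {
    cfg <- synth_config(seed = seed)
    .fix[[key]] <- render_fundus(generate_vessel_mask(cfg), cfg, id = "fx")
  }
  .fix[[key]]
}

# a reduced model for architecture tests (cached)
fixture_model <- function(base = 4, seed = 2) {
  key <- paste0("model", base, "_", seed)
  if (is.null(.fix[[key]])) {
    .fix[[key]] <- rfarn_init(network_config(base_channels = base), seed = seed)
  }
  .fix[[key]]
}

# set every parameter whose name matches `pattern` to zero, returning a copy
zero_params <- function(model, pattern) {
  m2 <- rfarn_init(model$config, seed = model$seed)
  for (nm in names(m2$params)) {
    if (grepl(pattern, nm)) m2$params[[nm]][] <- 0
  }
  m2
}
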