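# Reverse-mode automatic differentiation on dense arrays.
#
# The network is small and static, so a simple eager tape suffices: every
# operation computes its value immediately and records a closure that maps the
# output gradient to gradients for its parents. `ad_backward()` walks the tape
# in reverse creation order. Tensors are (H, W, C, N) arrays; heavy kernels
# (convolutions, pooling) live in src/ops.cpp.

.ad <- new.env(parent = emptyenv())
.ad$tape <- NULL
.ad$grad_on <- TRUE

# grad = FALSE builds a value-only tape (no backward closures are recorded),
# which makes pure inference cheaper in time and memory.
tape_begin <- function(grad = TRUE) {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$k <- 0L
  .ad$tape <- t
  .ad$grad_on <- grad
  invisible(t)
}

tape_end <- function() {
  .ad$tape <- NULL
  .ad$grad_on <- TRUE
  invisible(NULL)
}

ad_node <- function(value, parents = list(), backfn = NULL) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  if (.ad$grad_on) {
    n$parents <- parents
    n$backfn <- backfn
  } else {
    n$parents <- list()
    n$backfn <- NULL
  }
  t <- .ad$tape
  t$k <- t$k + 1L
  if (t$k > length(t$nodes)) t$nodes <- c(t$nodes, vector("list", length(t$nodes)))
  t$nodes[[t$k]] <- n
  n
}

ad_leaf <- function(value) ad_node(value)

ad_value <- function(n) n$value

# Accumulate gradients from a scalar root back to every leaf on the tape.
ad_backward <- function(root) {
  t <- .ad$tape
  root$grad <- 1
  for (i in rev(seq_len(t$k))) {
    n <- t$nodes[[i]]
    if (is.null(n$grad) || is.null(n$backfn)) next
    gs <- n$backfn(n$grad)
    ps <- n$parents
    for (j in seq_along(ps)) {
      gj <- gs[[j]]
      if (is.null(gj)) next
      p <- ps[[j]]
      p$grad <- if (is.null(p$grad)) gj else p$grad + gj
    }
  }
  invisible(NULL)
}

# ---- elementwise ----

ad_relu <- function(x) {
  v <- x$value
  mask <- v > 0
  ad_node(v * mask, list(x), function(g) list(g * mask))
}

ad_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$value))
  ad_node(s, list(x), function(g) list(g * s * (1 - s)))
}

# out = shift + scale * x (constants)
ad_affine <- function(x, scale = 1, shift = 0) {
  ad_node(shift + scale * x$value, list(x), function(g) list(scale * g))
}

ad_add <- function(a, b) {
  ad_node(a$value + b$value, list(a, b), function(g) list(g, g))
}

# replicate a single-channel (H, W, 1, N) array across C channels
rep_c1 <- function(m, C) {
  d <- dim(m)
  npix <- d[1] * d[2]
  N <- d[4]
  idx <- rep.int(seq_len(npix), C * N) +
    rep((seq_len(N) - 1L) * npix, each = npix * C)
  array(m[idx], c(d[1], d[2], C, N))
}

sum_to_c1 <- function(g) {
  d <- dim(g)
  out <- array(0, c(d[1], d[2], 1L, d[4]))
  for (n in seq_len(d[4])) {
    out[, , 1L, n] <- rowSums(array(g[, , , n], d[1:3]), dims = 2L)
  }
  out
}

# a + b where b has one channel, broadcast across a's channels
ad_add_c1 <- function(a, b) {
  C <- dim(a$value)[3]
  ad_node(a$value + rep_c1(b$value, C), list(a, b),
          function(g) list(g, sum_to_c1(g)))
}

# a * m where m has one channel, broadcast across a's channels
ad_mul_c1 <- function(a, m) {
  C <- dim(a$value)[3]
  mv <- rep_c1(m$value, C)
  av <- a$value
  ad_node(av * mv, list(a, m),
          function(g) list(g * mv, sum_to_c1(g * av)))
}

# ---- convolution / pooling (C++ kernels) ----

ad_conv <- function(x, w, b, dilation = 1L) {
  xv <- x$value
  wv <- w$value
  out <- cpp_conv2d_fwd(xv, wv, b$value, as.integer(dilation))
  ad_node(out, list(x, w, b), function(g) {
    r <- cpp_conv2d_bwd(xv, wv, g, as.integer(dilation))
    list(r$gx, r$gw, r$gb)
  })
}

ad_convt2 <- function(x, w, b) {
  xv <- x$value
  wv <- w$value
  out <- cpp_convt2_fwd(xv, wv, b$value)
  ad_node(out, list(x, w, b), function(g) {
    r <- cpp_convt2_bwd(xv, wv, g)
    list(r$gx, r$gw, r$gb)
  })
}

ad_maxpool2 <- function(x) {
  r <- cpp_maxpool2_fwd(x$value)
  xd <- dim(x$value)
  ad_node(r$out, list(x), function(g) list(cpp_maxpool2_bwd(g, r$idx, xd)))
}

# ---- batch normalisation ----

# Per-channel batch normalisation over (H, W, N). In training mode batch
# statistics (population variance) are used and running statistics on `model`
# are updated in place; in inference mode the stored running statistics are
# used, which makes inference deterministic.
ad_bn <- function(x, gamma, beta, model, name, training, momentum = 0.1,
                  eps = 1e-5) {
  v <- x$value
  d <- dim(v)
  C <- d[3]
  npix <- d[1] * d[2]
  m <- npix * d[4]
  # per-channel sum without transposition: columns of (npix, C*N) group as
  # (channel, sample), so fold the sample axis with rowSums
  per_chan <- function(a) {
    .rowSums(.colSums(a, npix, C * d[4]), C, d[4])
  }
  if (training) {
    mu <- per_chan(v) / m
    ctr <- v - arr_chan(mu, d)
    var <- per_chan(ctr^2) / m
    st <- model$bn[[name]]
    model$bn[[name]] <- list(mean = (1 - momentum) * st$mean + momentum * mu,
                             var = (1 - momentum) * st$var + momentum * var)
  } else {
    st <- model$bn[[name]]
    mu <- st$mean
    var <- st$var
    ctr <- NULL
  }
  s <- sqrt(var + eps)
  g <- gamma$value
  # y = scale * x + shift with per-channel constants
  scale <- g / s
  shift <- beta$value - mu * scale
  out <- v * arr_chan(scale, d) + arr_chan(shift, d)
  ad_node(out, list(x, gamma, beta), function(gy) {
    xhat <- if (training) ctr / arr_chan(s, d) else (v - arr_chan(mu, d)) / arr_chan(s, d)
    dgamma <- per_chan(gy * xhat)
    dbeta <- per_chan(gy)
    if (training) {
      mg <- per_chan(gy) / m
      mgx <- dgamma / m
      dx <- arr_chan(scale, d) * (gy - arr_chan(mg, d) - xhat * arr_chan(mgx, d))
    } else {
      dx <- gy * arr_chan(scale, d)
    }
    list(dx, dgamma, dbeta)
  })
}

# expand a per-channel vector to a full (H, W, C, N) array
arr_chan <- function(vec, d) {
  array(rep(rep(vec, each = d[1] * d[2]), times = d[4]), d)
}

# ---- concatenation ----

ad_concat <- function(a, b) {
  da <- dim(a$value)
  db <- dim(b$value)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a$value
  out[, , da[3] + seq_len(db[3]), ] <- b$value
  ad_node(out, list(a, b), function(g) {
    list(g[, , seq_len(da[3]), , drop = FALSE],
         g[, , da[3] + seq_len(db[3]), , drop = FALSE])
  })
}

# ---- global pooling to (C, N) matrices ----

ad_gap <- function(x) {
  d <- dim(x$value)
  npix <- d[1] * d[2]
  out <- matrix(0, d[3], d[4])
  for (n in seq_len(d[4])) {
    out[, n] <- colSums(matrix(x$value[, , , n], npix, d[3])) / npix
  }
  ad_node(out, list(x), function(g) {
    list(array(rep(as.vector(g) / npix, each = npix), d))
  })
}

ad_gmp <- function(x) {
  d <- dim(x$value)
  npix <- d[1] * d[2]
  out <- matrix(0, d[3], d[4])
  idx <- matrix(0L, d[3], d[4])
  for (n in seq_len(d[4])) {
    m <- matrix(x$value[, , , n], npix, d[3])
    w <- apply(m, 2, which.max)
    idx[, n] <- w
    out[, n] <- m[cbind(w, seq_len(d[3]))]
  }
  ad_node(out, list(x), function(g) {
    gx <- array(0, d)
    for (n in seq_len(d[4])) {
      m <- matrix(0, npix, d[3])
      m[cbind(idx[, n], seq_len(d[3]))] <- g[, n]
      gx[, , , n] <- m
    }
    list(gx)
  })
}

# ---- attention-specific ops ----

# Channel affinity: for each sample n, z[i, j] = avg[i] * max[j] and the
# affinity is softmax over i (columns sum to 1). avg, mx: (C, N) nodes.
ad_chan_affinity <- function(avg, mx) {
  av <- avg$value
  mv <- mx$value
  C <- nrow(av)
  N <- ncol(av)
  s <- array(0, c(C, C, N))
  for (n in seq_len(N)) {
    z <- outer(av[, n], mv[, n])
    e <- exp(sweep(z, 2, apply(z, 2, max)))
    s[, , n] <- sweep(e, 2, colSums(e), "/")
  }
  ad_node(s, list(avg, mx), function(g) {
    ga <- matrix(0, C, N)
    gm <- matrix(0, C, N)
    for (n in seq_len(N)) {
      sn <- s[, , n]
      gn <- g[, , n]
      tj <- colSums(gn * sn)
      gz <- sn * sweep(gn, 2, tj)  # d L / d z
      ga[, n] <- gz %*% mv[, n]
      gm[, n] <- t(gz) %*% av[, n]
    }
    list(ga, gm)
  })
}

# Scale the rows of a (C, C, N) matrix stack by a learnable per-channel vector.
ad_rowscale <- function(S, rho) {
  sv <- S$value
  rv <- rho$value
  d <- dim(sv)
  out <- sv * array(rv, d)  # rho recycles down rows (column-major)
  ad_node(out, list(S, rho), function(g) {
    grho <- rowSums(g * sv, dims = 1L)
    list(g * array(rv, d), grho)
  })
}

# Channel mixing: out[, , c, n] = sum_k A[c, k, n] * X[, , k, n].
ad_chanmix <- function(A, X) {
  av <- A$value
  xv <- X$value
  d <- dim(xv)
  npix <- d[1] * d[2]
  C <- d[3]
  out <- array(0, d)
  for (n in seq_len(d[4])) {
    out[, , , n] <- matrix(xv[, , , n], npix, C) %*% t(av[, , n])
  }
  ad_node(out, list(A, X), function(g) {
    gA <- array(0, dim(av))
    gX <- array(0, d)
    for (n in seq_len(d[4])) {
      gm <- matrix(g[, , , n], npix, C)
      xm <- matrix(xv[, , , n], npix, C)
      gA[, , n] <- t(gm) %*% xm
      gX[, , , n] <- gm %*% av[, , n]
    }
    list(gA, gX)
  })
}

# Softmax over all spatial positions, independently per channel and sample.
ad_spatial_softmax <- function(x) {
  v <- x$value
  d <- dim(v)
  npix <- d[1] * d[2]
  K <- d[3] * d[4]
  m <- matrix(v, npix, K)
  e <- exp(m - rep(apply(m, 2, max), each = npix))
  s <- e / rep(.colSums(e, npix, K), each = npix)
  out <- array(s, d)
  ad_node(out, list(x), function(g) {
    gm <- matrix(g, npix, K)
    tj <- .colSums(gm * s, npix, K)
    gz <- s * (gm - rep(tj, each = npix))
    list(array(gz, d))
  })
}

# ---- loss ----

# Mean binary cross-entropy with predictions clamped to [eps, 1 - eps].
ad_bce <- function(pred, target, eps = 1e-7) {
  q0 <- pred$value
  q <- pmin(pmax(q0, eps), 1 - eps)
  p <- target
  n <- length(q)
  L <- -sum(p * log(q) + (1 - p) * log(1 - q)) / n
  ad_node(L, list(pred), function(g) {
    dq <- -(p / q - (1 - p) / (1 - q)) / n
    dq[q0 < eps | q0 > 1 - eps] <- 0
    list(g * dq)
  })
}
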