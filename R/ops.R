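# Differentiable tensor operations.
#
# All feature maps are dense arrays of dim (H, W, C, N): rows, columns,
# channels, batch. Channel descriptors are (C, N) matrices. Convolution
# weights are (k, k, C_in, C_out) arrays; transposed-convolution weights
# are (k, k, C_out, C_in). Every op returns an ag_node whose backward
# closure produces exact gradients for its parents.

conv_out_len <- function(n, k, stride, pad, dil = 1L) {
  (n + 2L * pad - (dil * (k - 1L) + 1L)) %/% stride + 1L
}

fm_dims <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) != 4L)
    stop("feature maps must be 4-axis arrays (H, W, C, N)")
  d
}

slab <- function(x, n, d) array(x[, , , n, drop = FALSE], d[1:3])

#' @noRd
ag_conv2d <- function(x, w, b = NULL, stride = 1L, pad = 0L, dil = 1L) {
  xv <- x$value; wv <- w$value
  d <- fm_dims(xv)
  H <- d[1]; W <- d[2]; Cin <- d[3]; N <- d[4]
  k <- dim(wv)[1]; Cout <- dim(wv)[4]
  if (dim(wv)[3] != Cin)
    stop(sprintf("conv weights expect %d input channels, got %d", dim(wv)[3], Cin))
  Hout <- conv_out_len(H, k, stride, pad, dil)
  Wout <- conv_out_len(W, k, stride, pad, dil)
  if (Hout < 1L || Wout < 1L)
    stop("convolution output would be empty; input too small for kernel")
  Wmat <- matrix(wv, nrow = k * k * Cin)
  bv <- if (!is.null(b)) b$value else NULL
  out <- array(0, c(Hout, Wout, Cout, N))
  cols_list <- vector("list", N)
  for (n in seq_len(N)) {
    cols <- cpp_im2col(as.double(slab(xv, n, d)), H, W, Cin, k, stride, pad, dil)
    if (grad_enabled()) cols_list[[n]] <- cols
    om <- crossprod(cols, Wmat)
    if (!is.null(bv)) om <- om + rep(bv, each = Hout * Wout)
    out[, , , n] <- om
  }
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  new_node(out, parents, backward = function(g) {
    dW <- array(0, dim(wv))
    db <- if (!is.null(bv)) numeric(Cout) else NULL
    dx <- array(0, d)
    for (n in seq_len(N)) {
      dm <- matrix(g[, , , n], nrow = Hout * Wout, ncol = Cout)
      dW <- dW + array(cols_list[[n]] %*% dm, dim(wv))
      if (!is.null(bv)) db <- db + colSums(dm)
      dcols <- Wmat %*% t(dm)
      dx[, , , n] <- cpp_col2im(dcols, H, W, Cin, k, stride, pad, dil)
    }
    if (is.null(bv)) list(dx, dW) else list(dx, dW, db)
  })
}

# 2x stride-2 transposed convolution ("deconvolution"); exactly doubles H, W
#' @noRd
ag_conv_transpose2 <- function(x, w, b = NULL) {
  xv <- x$value; wv <- w$value
  d <- fm_dims(xv)
  H <- d[1]; W <- d[2]; Cin <- d[4 - 1]; N <- d[4]
  k <- dim(wv)[1]
  Cout <- dim(wv)[3]
  if (dim(wv)[4] != Cin)
    stop(sprintf("deconv weights expect %d input channels, got %d", dim(wv)[4], Cin))
  Ho <- 2L * H; Wo <- 2L * W
  Wmat <- matrix(wv, nrow = k * k * Cout)
  bv <- if (!is.null(b)) b$value else NULL
  out <- array(0, c(Ho, Wo, Cout, N))
  xm_list <- vector("list", N)
  for (n in seq_len(N)) {
    xm <- matrix(slab(xv, n, d), nrow = H * W, ncol = Cin)
    if (grad_enabled()) xm_list[[n]] <- xm
    cols <- Wmat %*% t(xm)
    os <- cpp_col2im(cols, Ho, Wo, Cout, k, 2L, 0L, 1L)
    if (!is.null(bv)) os <- os + rep(bv, each = Ho * Wo)
    out[, , , n] <- os
  }
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  new_node(out, parents, backward = function(g) {
    dW <- array(0, dim(wv))
    db <- if (!is.null(bv)) numeric(Cout) else NULL
    dx <- array(0, d)
    for (n in seq_len(N)) {
      gs <- as.double(g[, , , n])
      dcols <- cpp_im2col(gs, Ho, Wo, Cout, k, 2L, 0L, 1L)
      dx[, , , n] <- t(t(Wmat) %*% dcols)
      dW <- dW + array(dcols %*% xm_list[[n]], dim(wv))
      if (!is.null(bv))
        db <- db + colSums(matrix(gs, nrow = Ho * Wo, ncol = Cout))
    }
    if (is.null(bv)) list(dx, dW) else list(dx, dW, db)
  })
}

#' @noRd
ag_maxpool <- function(x, k, stride = k, pad = 0L) {
  xv <- x$value
  d <- fm_dims(xv)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  if (k > H + 2L * pad || k > W + 2L * pad)
    stop(sprintf("pool size %d exceeds spatial extent %dx%d", k, H, W))
  Hout <- conv_out_len(H, k, stride, pad)
  Wout <- conv_out_len(W, k, stride, pad)
  out <- array(0, c(Hout, Wout, C, N))
  args <- vector("list", N)
  for (n in seq_len(N)) {
    r <- cpp_maxpool(as.double(slab(xv, n, d)), H, W, C, k, stride, pad)
    out[, , , n] <- r$value
    if (grad_enabled()) args[[n]] <- r$argmax
  }
  new_node(out, list(x), backward = function(g) {
    dx <- array(0, d)
    for (n in seq_len(N)) {
      dx[, , , n] <- cpp_maxpool_backward(as.double(g[, , , n]), args[[n]], H, W, C)
    }
    list(dx)
  })
}

# 2x2 stride-2 average pooling (transition layers); requires even H, W
#' @noRd
ag_avgpool2 <- function(x) {
  xv <- x$value
  d <- fm_dims(xv)
  H <- d[1]; W <- d[2]
  if (H %% 2L != 0L || W %% 2L != 0L)
    stop("average pooling requires even spatial dimensions")
  io <- seq(1L, H, 2L); ie <- io + 1L
  jo <- seq(1L, W, 2L); je <- jo + 1L
  out <- (xv[io, jo, , , drop = FALSE] + xv[ie, jo, , , drop = FALSE] +
          xv[io, je, , , drop = FALSE] + xv[ie, je, , , drop = FALSE]) / 4
  new_node(out, list(x), backward = function(g) {
    dx <- array(0, d)
    q <- g / 4
    dx[io, jo, , ] <- q
    dx[ie, jo, , ] <- q
    dx[io, je, , ] <- q
    dx[ie, je, , ] <- q
    list(dx)
  })
}

# spatial squeeze: global average pool to a (C, N) descriptor
#' @noRd
ag_global_avgpool <- function(x) {
  xv <- x$value
  d <- fm_dims(xv)
  HW <- d[1] * d[2]
  v <- matrix(colMeans(matrix(xv, nrow = HW)), nrow = d[3], ncol = d[4])
  new_node(v, list(x), backward = function(g) {
    list(array(rep(as.vector(g) / HW, each = HW), d))
  })
}

# generalized-mean pooling to a (C, N) descriptor; x must be non-negative
#' @noRd
ag_gem_pool <- function(x, pk) {
  xv <- x$value
  d <- fm_dims(xv)
  if (pk < 1) stop("GeM exponent pk must be >= 1")
  if (any(xv < 0))
    stop("GeM pooling requires non-negative inputs (apply a rectifier first)")
  HW <- d[1] * d[2]
  xm <- matrix(xv, nrow = HW)
  if (pk == 1) {                      # exactly average pooling
    v <- matrix(colMeans(xm), nrow = d[3], ncol = d[4])
    return(new_node(v, list(x), backward = function(g) {
      list(array(rep(as.vector(g) / HW, each = HW), d))
    }))
  }
  # factor out the per-channel maximum so x^pk cannot overflow at large pk
  M <- apply(xm, 2, max)
  Ms <- ifelse(M > 0, M, 1)
  scaled <- sweep(xm, 2, Ms, "/")
  m <- colMeans(scaled^pk)
  v <- matrix(M * m^(1 / pk), nrow = d[3], ncol = d[4])
  new_node(v, list(x), backward = function(g) {
    coef <- as.vector(g) * ifelse(M > 0, m^(1 / pk - 1), 0) / HW
    list(array(scaled^(pk - 1) * rep(coef, each = HW), d))
  })
}

# fully connected layer on (C, N) descriptors
#' @noRd
ag_linear <- function(v, w, b = NULL) {
  vv <- v$value; wv <- w$value
  if (ncol(wv) != nrow(vv))
    stop(sprintf("linear weights expect %d inputs, got %d", ncol(wv), nrow(vv)))
  out <- wv %*% vv
  bv <- if (!is.null(b)) b$value else NULL
  if (!is.null(bv)) out <- out + bv
  parents <- if (is.null(b)) list(v, w) else list(v, w, b)
  new_node(out, parents, backward = function(g) {
    g <- matrix(g, nrow = nrow(wv))
    dv <- t(wv) %*% g
    dW <- g %*% t(vv)
    if (is.null(bv)) list(dv, dW) else list(dv, dW, rowSums(g))
  })
}

#' @noRd
ag_relu <- function(x) {
  xv <- x$value
  out <- pmax(xv, 0)
  if (!is.null(dim(xv))) dim(out) <- dim(xv)
  new_node(out, list(x), backward = function(g) list(g * (xv > 0)))
}

#' @noRd
ag_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$value))
  new_node(s, list(x), backward = function(g) list(g * s * (1 - s)))
}

# channel re-weighting: multiply map x by per-channel gate gch of dim (C, N)
#' @noRd
ag_mul_channel <- function(x, gch) {
  xv <- x$value; gv <- gch$value
  d <- fm_dims(xv)
  HW <- d[1] * d[2]
  if (nrow(gv) != d[3] || ncol(gv) != d[4])
    stop("channel gate length must equal the map's channel count")
  big <- array(rep(as.vector(gv), each = HW), d)
  new_node(xv * big, list(x, gch), backward = function(g) {
    dg <- matrix(colSums(matrix(g * xv, nrow = HW)), nrow = d[3], ncol = d[4])
    list(g * big, dg)
  })
}

#' @noRd
ag_add <- function(x, y) {
  if (!identical(dim(x$value), dim(y$value)))
    stop("residual addition requires identical shapes")
  new_node(x$value + y$value, list(x, y), backward = function(g) list(g, g))
}

# channel-axis concatenation of feature maps
#' @noRd
ag_concat_ch <- function(nodes) {
  ds <- lapply(nodes, function(n) fm_dims(n$value))
  Cs <- vapply(ds, function(d) d[3], numeric(1))
  d0 <- ds[[1]]
  out <- array(0, c(d0[1], d0[2], sum(Cs), d0[4]))
  at <- 0L
  for (i in seq_along(nodes)) {
    out[, , at + seq_len(Cs[i]), ] <- nodes[[i]]$value
    at <- at + Cs[i]
  }
  new_node(out, nodes, backward = function(g) {
    gs <- vector("list", length(nodes))
    at <- 0L
    for (i in seq_along(nodes)) {
      gs[[i]] <- array(g[, , at + seq_len(Cs[i]), , drop = FALSE], ds[[i]])
      at <- at + Cs[i]
    }
    gs
  })
}

# interpolation matrix for 1-d linear resampling (half-pixel centres)
bilin_mat <- function(n_in, n_out) {
  A <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) * n_in / n_out - 0.5
    src <- min(max(src, 0), n_in - 1)
    i0 <- floor(src)
    w1 <- src - i0
    i1 <- min(i0 + 1, n_in - 1)
    A[i, i0 + 1] <- A[i, i0 + 1] + (1 - w1)
    A[i, i1 + 1] <- A[i, i1 + 1] + w1
  }
  A
}

#' @noRd
ag_bilinear_resize <- function(x, h_out, w_out) {
  xv <- x$value
  d <- fm_dims(xv)
  A <- bilin_mat(d[1], h_out)
  B <- bilin_mat(d[2], w_out)
  out <- array(0, c(h_out, w_out, d[3], d[4]))
  for (n in seq_len(d[4])) {
    for (c in seq_len(d[3])) {
      out[, , c, n] <- A %*% xv[, , c, n] %*% t(B)
    }
  }
  new_node(out, list(x), backward = function(g) {
    dx <- array(0, d)
    for (n in seq_len(d[4])) {
      for (c in seq_len(d[3])) {
        dx[, , c, n] <- t(A) %*% g[, , c, n] %*% B
      }
    }
    list(dx)
  })
}

# instance normalisation: each channel of each sample is standardised over
# its spatial extent, then rescaled by learnable gain/offset. With batch
# size 1 this coincides with batch normalisation's training behaviour and
# needs no running statistics at inference.
#' @noRd
ag_instance_norm <- function(x, gamma, beta, eps = 1e-5) {
  xv <- x$value
  d <- fm_dims(xv)
  HW <- d[1] * d[2]
  gv <- gamma$value; bv <- beta$value
  xm <- matrix(xv, nrow = HW)
  mu <- colMeans(xm)
  va <- colMeans(xm^2) - mu^2
  istd <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, istd, "*")
  grep_ <- rep(gv, times = d[4])
  out <- sweep(xhat, 2, grep_, "*") + rep(rep(bv, times = d[4]), each = HW)
  new_node(array(out, d), list(x, gamma, beta), backward = function(g) {
    gm <- matrix(g, nrow = HW)
    dgamma_cn <- colSums(gm * xhat)
    dbeta_cn <- colSums(gm)
    dgamma <- rowSums(matrix(dgamma_cn, nrow = d[3]))
    dbeta <- rowSums(matrix(dbeta_cn, nrow = d[3]))
    dxhat <- sweep(gm, 2, grep_, "*")
    # standard normalisation backward, per (channel, sample) column
    dx <- sweep(dxhat - rep(colMeans(dxhat), each = HW) -
                  xhat * rep(colMeans(dxhat * xhat), each = HW),
                2, istd, "*")
    list(array(dx, d), dgamma, dbeta)
  })
}

# alpha-blended dice + cross-entropy loss, averaged over batch images;
# dice is computed per image with additive smoothing S, cross-entropy on
# probabilities clipped to [clip_eps, 1 - clip_eps]
#' @noRd
ag_combined_loss <- function(p, truth, alpha = 0.5, S = 1, clip_eps = 1e-7) {
  pv <- p$value
  d <- fm_dims(pv)
  if (!identical(dim(truth), d))
    stop("prediction and ground truth must share one grid")
  if (!all(truth %in% c(0, 1))) stop("ground-truth mask must be binary")
  Np <- d[1] * d[2] * d[3]
  N <- d[4]
  pc <- pmin(pmax(pv, clip_eps), 1 - clip_eps)
  total <- 0
  dL <- array(0, d)
  for (n in seq_len(N)) {
    pi_ <- array(pv[, , , n], d[1:3])
    pci <- array(pc[, , , n], d[1:3])
    ti <- array(truth[, , , n], d[1:3])
    ce <- -mean(ti * log(pci) + (1 - ti) * log(1 - pci))
    num <- 2 * sum(pi_ * ti) + S
    den <- sum(pi_) + sum(ti) + S
    dc <- num / den
    total <- total + alpha * ce + (1 - alpha) * (1 - dc)
    inner <- array(pi_ > clip_eps & pi_ < 1 - clip_eps, d[1:3])
    dce <- (-(ti / pci) + (1 - ti) / (1 - pci)) / Np * inner
    ddc <- (2 * ti * den - num) / den^2
    dL[, , , n] <- (alpha * dce - (1 - alpha) * ddc) / N
  }
  new_node(total / N, list(p), backward = function(g) list(as.numeric(g) * dL))
}
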