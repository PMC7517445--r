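# Independent reference implementations used as oracles. Deliberately
# written as plain nested loops / direct formula transcriptions, sharing no
# code with the package's vectorised + compiled implementations.

# direct 2-d convolution; x (H, W, Cin), w (k, k, Cin, Cout), b length Cout
ref_conv2d <- function(x, w, b = NULL, stride = 1, pad = 0, dil = 1) {
  H <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]
  k <- dim(w)[1]; Cout <- dim(w)[4]
  eff <- dil * (k - 1) + 1
  Ho <- (H + 2 * pad - eff) %/% stride + 1
  Wo <- (W + 2 * pad - eff) %/% stride + 1
  out <- array(0, c(Ho, Wo, Cout))
  for (co in 1:Cout) {
    for (ho in 1:Ho) for (wo in 1:Wo) {
      acc <- if (is.null(b)) 0 else b[co]
      for (ci in 1:Cin) for (kh in 1:k) for (kw in 1:k) {
        hi <- (ho - 1) * stride - pad + (kh - 1) * dil + 1
        wi <- (wo - 1) * stride - pad + (kw - 1) * dil + 1
        if (hi >= 1 && hi <= H && wi >= 1 && wi <= W)
          acc <- acc + x[hi, wi, ci] * w[kh, kw, ci, co]
      }
      out[ho, wo, co] <- acc
    }
  }
  out
}

# direct 2x2 stride-2 transposed convolution; w (2, 2, Cout, Cin)
ref_deconv2 <- function(x, w, b = NULL) {
  H <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]
  Cout <- dim(w)[3]
  out <- array(0, c(2 * H, 2 * W, Cout))
  for (co in 1:Cout) {
    if (!is.null(b)) out[, , co] <- b[co]
    for (hi in 1:H) for (wi in 1:W) for (ci in 1:Cin) {
      for (kh in 1:2) for (kw in 1:2) {
        out[2 * (hi - 1) + kh, 2 * (wi - 1) + kw, co] <-
          out[2 * (hi - 1) + kh, 2 * (wi - 1) + kw, co] +
          x[hi, wi, ci] * w[kh, kw, co, ci]
      }
    }
  }
  out
}

# per-channel instance normalisation on an (H, W, C) array
ref_inorm <- function(x, gamma, beta, eps = 1e-5) {
  out <- x
  for (c in seq_len(dim(x)[3])) {
    v <- x[, , c]
    mu <- mean(v)
    va <- mean((v - mu)^2)
    out[, , c] <- gamma[c] * (v - mu) / sqrt(va + eps) + beta[c]
  }
  out
}

# direct generalized-mean pooling on an (H, W, C) array
ref_gem <- function(x, pk) {
  vapply(seq_len(dim(x)[3]),
         function(c) mean(x[, , c]^pk)^(1 / pk), numeric(1))
}

ref_sigmoid <- function(x) 1 / (1 + exp(-x))

# centroid (row, col) of a binary mask
mask_centroid <- function(m) {
  idx <- which(m == 1, arr.ind = TRUE)
  colMeans(idx)
}

# central finite-difference gradient of scalar f at selected flat indices
fd_grad <- function(f, x, idx, eps = 1e-6) {
  vapply(idx, function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}

# small deterministic image/mask fixture set
desk_dataset <- function(n = 8, size = 64, seed = 7) {
  generate_dataset(synthetic_spec(size = size, seed = seed), n)
}

param_values <- function(wts) lapply(acaunet:::layer_params(wts),
                                     function(p) p$value)
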