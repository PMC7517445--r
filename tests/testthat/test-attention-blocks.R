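# the architecture's building blocks against direct-formula oracles

test_that("squeeze_gap averages each channel over its spatial extent", {
  expect_equal(squeeze_gap(array(3, c(4, 5, 2, 1))), matrix(3, 2, 1))
  ch <- array(c(1, 2, 3, 4), c(2, 2, 1, 1))
  expect_equal(squeeze_gap(ch)[1, 1], 2.5)
  # equals GeM with pk = 1 on non-negative input
  set.seed(21)
  x <- array(runif(6 * 6 * 3 * 2), c(6, 6, 3, 2))
  expect_identical(squeeze_gap(x), gem_pool(x, 1))
})

test_that("excitation gate is sigmoid(W2 relu(W1 v)) with outputs in (0,1)", {
  v <- c(0.3, -1, 2)
  z <- matrix(0, 3, 3)
  expect_equal(excitation_gate(v, z, z), matrix(0.5, 3, 1))
  set.seed(22)
  W1 <- matrix(rnorm(9), 3, 3); W2 <- matrix(rnorm(9), 3, 3)
  got <- excitation_gate(v, W1, W2)
  expect_true(all(got > 0 & got < 1))
  # brute-force two-layer evaluation
  expect_equal(as.numeric(got),
               ref_sigmoid(as.numeric(W2 %*% pmax(W1 %*% v, 0))),
               tolerance = 1e-12)
  expect_error(excitation_gate(v, matrix(0, 2, 2), z), "conform")
})

test_that("squeeze-excitation shrinks magnitudes without changing signs", {
  set.seed(23)
  x <- array(rnorm(5 * 5 * 4 * 2), c(5, 5, 4, 2))
  W1 <- matrix(rnorm(8), 2, 4); W2 <- matrix(rnorm(8), 4, 2)
  y <- squeeze_excite(x, W1, W2)
  expect_true(all(abs(y) <= abs(x)))
  expect_true(all(sign(y) == sign(x) | y == 0))
  # loop oracle for the channel-wise product
  gate <- excitation_gate(squeeze_gap(x), W1, W2)
  for (n in 1:2) for (c in 1:4)
    expect_equal(y[, , c, n], x[, , c, n] * gate[c, n], tolerance = 1e-12)
  # gate forced to 1: infinitely positive pre-activation is approximated
  # by huge weights; use the identity route instead
  big <- squeeze_excite(abs(x) + 1, matrix(50, 1, 4), matrix(50, 4, 1))
  expect_equal(big, abs(x) + 1, tolerance = 1e-9)
})

test_that("GeM pooling interpolates between average and max pooling", {
  ch <- array(c(1, 2, 3, 4), c(2, 2, 1, 1))
  expect_identical(gem_pool(ch, 1)[1, 1], 2.5)
  expect_equal(gem_pool(ch, 2)[1, 1], sqrt(30 / 4), tolerance = 1e-12)
  expect_equal(gem_pool(ch, 100)[1, 1], 4, tolerance = 1e-1)
  # exact convergence bound: max * (1/HW)^(1/pk) <= gem <= max
  expect_lte(abs(gem_pool(ch, 1000)[1, 1] - 4) / 4, log(4) / 1000 + 1e-12)
  two <- array(c(2, 5), c(1, 2, 1, 1))
  expect_equal(gem_pool(two, 1000)[1, 1], 5, tolerance = 1e-3)
  # monotone non-decreasing in pk on any fixed non-negative map
  set.seed(24)
  x <- array(runif(8 * 8), c(8, 8, 1, 1))
  vals <- vapply(c(1, 2, 3, 5, 10, 50), function(p) gem_pool(x, p)[1, 1],
                 numeric(1))
  expect_true(all(diff(vals) >= -1e-12))
  expect_error(gem_pool(array(-1, c(2, 2, 1, 1)), 2.5), "non-negative")
  expect_error(gem_pool(x, 0.5), ">= 1")
})

test_that("dense block concatenation wiring and channel arithmetic are exact", {
  set.seed(25)
  for (cfg in list(c(8, 3, 4), c(4, 1, 2), c(6, 2, 8))) {
    w <- dense_block_weights(cfg[1], cfg[2], cfg[3], seed = 1)
    x <- array(rnorm(6 * 6 * cfg[1]), c(6, 6, cfg[1], 1))
    out <- dense_block_forward(x, w)
    expect_equal(dim(out), c(6, 6, cfg[1] + cfg[2] * cfg[3], 1))
  }
  # one layer: output must be concat(input, H1(input)); removing the
  # concatenation (i.e. H1 alone) differs from the block output
  w <- dense_block_weights(2, 1, 3, seed = 2)
  x <- array(rnorm(4 * 4 * 2), c(4, 4, 2, 1))
  out <- dense_block_forward(x, w)
  expect_equal(out[, , 1:2, 1], x[, , , 1])
  pv <- param_values(w)
  h1 <- pmax(ref_inorm(ref_conv2d(x[, , , 1], pv[[1]], pv[[2]], pad = 1),
                       pv[[3]], pv[[4]]), 0)
  expect_equal(out[, , 3:5, 1], h1, tolerance = 1e-10)
  expect_false(isTRUE(all.equal(dim(out)[3], dim(h1)[3])))
  expect_error(dense_block_forward(array(0, c(4, 4, 5, 1)), w), "channels")
})

test_that("gradient flows to the dense-block input through both the direct path and H1", {
  # smallest spatial map on which the per-channel normalisation inside H1
  # is non-degenerate (a single pixel has zero variance)
  ag <- asNamespace("acaunet")
  w <- dense_block_weights(1, 1, 1, seed = 3)
  set.seed(35)
  x <- array(rnorm(4), c(2, 2, 1, 1))
  cw <- c(1, 2)                         # weighs both output channels
  f <- function(xv) {
    out <- dense_block_forward(array(xv, c(2, 2, 1, 1)), w)
    sum(out[, , 1, 1]) + 2 * sum(out[, , 2, 1])
  }
  xn <- ag$ag_input(x)
  out <- ag$dense_block_node(xn, w)
  seedg <- array(rep(cw, each = 4), dim(out$value))
  loss <- ag$new_node(f(x), list(out),
                      backward = function(g) list(seedg * as.numeric(g)))
  ag$backward_ag(loss)
  num <- fd_grad(f, x, 1:4)
  expect_equal(as.numeric(xn$grad), num, tolerance = 1e-5)
  # the direct path alone would contribute exactly 1 per pixel; the H1
  # path must shift at least one of the gradients away from that
  expect_gt(max(abs(as.numeric(xn$grad) - 1)), 1e-6)
})

test_that("residual block satisfies out = H(x) + x", {
  set.seed(26)
  x <- array(rnorm(5 * 5 * 3), c(5, 5, 3, 1))
  wz <- residual_block_weights(3, zero = TRUE)
  expect_equal(residual_block_forward(x, wz), as_feature_map(x))
  w <- residual_block_weights(3, seed = 4)
  out <- residual_block_forward(x, w)
  body <- residual_block_forward(x, w, body_only = TRUE)
  expect_equal(out - body, as_feature_map(x), tolerance = 1e-6)
  z <- array(0, c(5, 5, 3, 1))
  expect_equal(residual_block_forward(z, w),
               residual_block_forward(z, w, body_only = TRUE))
})

test_that("ACAU stage matches a step-by-step scripted composition", {
  set.seed(27)
  c_low <- 4; c_high <- 3; c_out <- 4
  w <- acau_weights(c_low, c_high, c_out, se_reduction = 2, pk = 5, seed = 5)
  x_low <- array(abs(rnorm(4 * 4 * c_low)), c(4, 4, c_low, 1))
  x_high <- array(rnorm(2 * 2 * c_high), c(2, 2, c_high, 1))
  got <- acau_forward(x_low, x_high, w)
  expect_identical(dim(got), c(4L, 4L, as.integer(c_out), 1L))

  # scripted oracle: squeeze, excite, re-weight; 1x1-match + rectify, GeM,
  # sigmoid, multiply; deconv the high path; concatenate; fuse
  se1 <- w$se$w1$value; se2 <- w$se$w2$value
  vl <- vapply(1:c_low, function(c) mean(x_low[, , c, 1]), numeric(1))
  gate <- ref_sigmoid(as.numeric(se2 %*% pmax(se1 %*% vl, 0)))
  yl <- x_low[, , , 1]
  for (c in 1:c_low) yl[, , c] <- yl[, , c] * gate[c]
  xh <- pmax(ref_conv2d(x_high[, , , 1], w$match1x1$w$value, w$match1x1$b$value), 0)
  vh <- ref_gem(xh, 5)
  att <- yl
  for (c in 1:c_low) att[, , c] <- att[, , c] * ref_sigmoid(vh[c])
  up <- ref_deconv2(x_high[, , , 1], w$up$w$value, w$up$b$value)
  cat_ <- array(0, c(4, 4, c_low + c_out))
  cat_[, , 1:c_low] <- att
  cat_[, , c_low + 1:c_out] <- up
  fused <- ref_conv2d(cat_, w$fuse$w$value, w$fuse$b$value, pad = 1)
  want <- pmax(ref_inorm(fused, w$fuse$gamma$value, w$fuse$beta$value), 0)
  expect_equal(got[, , , 1], want, tolerance = 1e-5)

  # annihilation: zero skip features kill the attention product
  got0 <- acau_forward(array(0, dim(x_low)), x_high, w)
  up_only <- ref_conv2d(
    array(c(array(0, c(4, 4, c_low)), up), c(4, 4, c_low + c_out)),
    w$fuse$w$value, w$fuse$b$value, pad = 1)
  expect_equal(got0[, , , 1],
               pmax(ref_inorm(up_only, w$fuse$gamma$value, w$fuse$beta$value), 0),
               tolerance = 1e-5)
  expect_error(acau_forward(x_low, array(0, c(3, 3, c_high, 1)), w), "twice")
})

test_that("DAC preserves shape and reduces to identity at zero weights", {
  set.seed(28)
  w <- dac_weights(3, c(1, 3, 5), seed = 6)
  x <- array(rnorm(11 * 11 * 3), c(11, 11, 3, 1))
  out <- dac_forward(x, w)
  expect_identical(dim(out), dim(as_feature_map(x)))
  wz <- dac_weights(3, c(1, 3, 5), seed = 6)
  for (p in acaunet:::layer_params(wz$branches)) p$value[] <- 0
  expect_equal(dac_forward(x, wz), as_feature_map(x))
})

test_that("RMP adds one channel per pool size and rejects oversized pools", {
  set.seed(29)
  w <- rmp_weights(3, c(2, 3, 5, 6), seed = 7)
  x <- array(rnorm(12 * 12 * 3), c(12, 12, 3, 1))
  out <- rmp_forward(x, w)
  expect_identical(dim(out), c(12L, 12L, 7L, 1L))
  expect_equal(out[, , 1:3, ], as_feature_map(x)[, , 1:3, ])
  small <- array(rnorm(4 * 4 * 3), c(4, 4, 3, 1))
  expect_error(rmp_forward(small, w), "exceeds spatial extent")
})

test_that("every block maps finite inputs to finite outputs across seeds", {
  for (s in 1:20) {
    set.seed(s)
    x <- array(rnorm(8 * 8 * 4, sd = 3), c(8, 8, 4, 1))
    expect_true(all(is.finite(dense_block_forward(
      x, dense_block_weights(4, 2, 2, seed = s)))))
    expect_true(all(is.finite(dac_forward(x, dac_weights(4, seed = s)))))
    expect_true(all(is.finite(rmp_forward(
      x, rmp_weights(4, c(2, 3), seed = s)))))
    xh <- array(rnorm(4 * 4 * 2), c(4, 4, 2, 1))
    expect_true(all(is.finite(acau_forward(
      x, xh, acau_weights(4, 2, 4, se_reduction = 2, seed = s)))))
  }
})
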