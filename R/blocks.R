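#' Block configuration
#'
#' Collects the hyper-parameters shared by the architecture's building
#' blocks: the dense-encoder geometry, the squeeze-and-excitation reduction
#' ratio, the GeM pooling exponent and the bottleneck branch settings.
#'
#' @param growth_rate channels added by each dense-block layer.
#' @param layers_per_block integer vector of length 4; layers in each of the
#'   four encoder dense blocks (DenseNet-121 geometry by default).
#' @param se_reduction reduction ratio `r` of the excitation gate; must
#'   divide every gated channel count.
#' @param pk GeM pooling exponent, `>= 1`. `pk = 1` is average pooling and
#'   large `pk` approaches max pooling; 5 is the tuned default.
#' @param dac_dilations dilation factors of the parallel atrous branches in
#'   the bottleneck.
#' @param rmp_pool_sizes window sizes of the residual multi-kernel pooling
#'   branches; each adds one channel to the bottleneck output.
#' @return a list of class `block_config`.
#' @export
block_config <- function(growth_rate = 32L,
                         layers_per_block = c(6L, 12L, 24L, 16L),
                         se_reduction = 16L,
                         pk = 5,
                         dac_dilations = c(1L, 3L, 5L),
                         rmp_pool_sizes = c(2L, 3L, 5L, 6L)) {
  stopifnot(growth_rate >= 1, length(layers_per_block) == 4L,
            all(layers_per_block >= 1), se_reduction >= 1,
            all(dac_dilations >= 1), all(rmp_pool_sizes >= 1))
  if (pk < 1) stop("pk must be >= 1")
  structure(list(growth_rate = as.integer(growth_rate),
                 layers_per_block = as.integer(layers_per_block),
                 se_reduction = as.integer(se_reduction),
                 pk = pk,
                 dac_dilations = as.integer(dac_dilations),
                 rmp_pool_sizes = as.integer(rmp_pool_sizes)),
            class = "block_config")
}

## ---- squeeze-and-excitation ------------------------------------------------

#' Spatial squeeze by global average pooling
#'
#' Shrinks each channel of a feature map over its spatial extent, producing
#' one descriptor value per channel per batch element.
#'
#' @param x feature map, coercible by [as_feature_map()].
#' @return a (channels x batch) matrix.
#' @export
squeeze_gap <- function(x) {
  ag_global_avgpool(ag_input(as_feature_map(x)))$value
}

#' Excitation gate
#'
#' The two-layer bottleneck gate of a squeeze-and-excitation block:
#' `sigmoid(W2 %*% relu(W1 %*% v))`. Every output lies strictly in (0, 1).
#'
#' @param v channel descriptor: numeric vector or (channels x batch) matrix.
#' @param W1 weight matrix mapping C to C/r.
#' @param W2 weight matrix mapping C/r back to C.
#' @return gated descriptor with the shape of `v` (as a matrix).
#' @export
excitation_gate <- function(v, W1, W2) {
  v <- as_descriptor(v)
  if (ncol(W1) != nrow(v) || nrow(W2) != nrow(v) || ncol(W2) != nrow(W1))
    stop("gate weights do not conform: need W1 (C/r x C) and W2 (C x C/r)")
  excitation_node(ag_input(v), list(w1 = ag_input(W1), w2 = ag_input(W2)))$value
}

excitation_node <- function(v, wts) {
  w1 <- if (is_node(wts$w1)) wts$w1 else ag_use_param(wts$w1)
  w2 <- if (is_node(wts$w2)) wts$w2 else ag_use_param(wts$w2)
  ag_sigmoid(ag_linear(ag_relu(ag_linear(v, w1)), w2))
}

#' Squeeze-and-excitation weights
#' @param channels gated channel count.
#' @param reduction reduction ratio r; must divide `channels`.
#' @param seed optional RNG seed for reproducible initialisation.
#' @return weight list for [squeeze_excite()].
#' @export
se_weights <- function(channels, reduction, seed = NULL) {
  if (channels %% reduction != 0)
    stop(sprintf("se_reduction %d does not divide channel count %d",
                 reduction, channels))
  with_rng_seed(seed, {
    list(w1 = new_param(kaiming_linear(channels, channels %/% reduction)),
         w2 = new_param(kaiming_linear(channels %/% reduction, channels)))
  })
}

se_node <- function(x, wts) {
  gate <- excitation_node(ag_global_avgpool(x), wts)
  ag_mul_channel(x, gate)
}

#' Squeeze-and-excitation channel re-weighting
#'
#' Squeezes `x` to a channel descriptor, passes it through the excitation
#' gate, and rescales every channel by the resulting (0, 1) weight. Never
#' changes a value's sign nor increases its magnitude.
#'
#' @inheritParams squeeze_gap
#' @param W1,W2 gate weights as in [excitation_gate()].
#' @return feature map with the same shape as `x`.
#' @export
squeeze_excite <- function(x, W1, W2) {
  x <- as_feature_map(x)
  se_node(ag_input(x), list(w1 = ag_input(W1), w2 = ag_input(W2)))$value
}

## ---- GeM pooling -----------------------------------------------------------

#' Generalized-mean (GeM) spatial pooling
#'
#' Pools each channel to `(mean(x^pk))^(1/pk)`. `pk = 1` reproduces average
#' pooling exactly; as `pk` grows the result approaches the channel maximum.
#' Inputs must be non-negative (rectify first).
#'
#' @inheritParams squeeze_gap
#' @param pk pooling exponent, `>= 1`.
#' @return a (channels x batch) matrix.
#' @export
gem_pool <- function(x, pk) {
  ag_gem_pool(ag_input(as_feature_map(x)), pk)$value
}

## ---- dense and residual blocks --------------------------------------------

#' Dense-block weights
#'
#' Builds the convolution weights of a dense block in which layer `l`
#' receives the channel-concatenation of the input and all previous layer
#' outputs, and contributes `growth` new channels (3x3 convolution,
#' instance normalisation, ReLU).
#'
#' @param in_channels channels of the block input.
#' @param n_layers number of layers.
#' @param growth channels added per layer.
#' @param seed optional RNG seed.
#' @return weight list; block output has `in_channels + n_layers * growth`
#'   channels.
#' @export
dense_block_weights <- function(in_channels, n_layers, growth, seed = NULL) {
  with_rng_seed(seed, {
    layers <- vector("list", n_layers)
    cin <- in_channels
    for (l in seq_len(n_layers)) {
      layers[[l]] <- c(conv_layer(3L, cin, growth), norm_layer(growth))
      cin <- cin + growth
    }
    list(layers = layers, in_channels = as.integer(in_channels),
         growth = as.integer(growth))
  })
}

dense_block_node <- function(x, wts) {
  if (dim(x$value)[3] != wts$in_channels)
    stop(sprintf("dense block was built for %d input channels, got %d",
                 wts$in_channels, dim(x$value)[3]))
  cat <- x
  for (ly in wts$layers) {
    h <- ag_conv2d(cat, ag_use_param(ly$w), ag_use_param(ly$b),
                   stride = 1L, pad = 1L)
    h <- ag_instance_norm(h, ag_use_param(ly$gamma), ag_use_param(ly$beta))
    cat <- ag_concat_ch(list(cat, ag_relu(h)))
  }
  cat
}

#' Dense block forward pass
#'
#' @inheritParams squeeze_gap
#' @param weights from [dense_block_weights()].
#' @return feature map with `in_channels + n_layers * growth` channels and
#'   unchanged spatial size.
#' @export
dense_block_forward <- function(x, weights) {
  dense_block_node(ag_input(as_feature_map(x)), weights)$value
}

#' Residual-block weights (two 3x3 convolutions with an identity skip)
#' @param channels channel count, preserved by the block.
#' @param seed optional RNG seed.
#' @param zero if `TRUE`, initialise the body to zero so the block is the
#'   identity map.
#' @return weight list for [residual_block_forward()].
#' @export
residual_block_weights <- function(channels, seed = NULL, zero = FALSE) {
  with_rng_seed(seed, {
    list(conv1 = conv_layer(3L, channels, channels, zero = zero),
         conv2 = conv_layer(3L, channels, channels, zero = zero),
         channels = as.integer(channels))
  })
}

residual_body_node <- function(x, wts) {
  h <- ag_relu(ag_conv2d(x, ag_use_param(wts$conv1$w), ag_use_param(wts$conv1$b),
                         stride = 1L, pad = 1L))
  ag_conv2d(h, ag_use_param(wts$conv2$w), ag_use_param(wts$conv2$b),
            stride = 1L, pad = 1L)
}

residual_block_node <- function(x, wts) {
  h <- residual_body_node(x, wts)
  if (!identical(dim(h$value), dim(x$value)))
    stop("residual body changed the feature-map shape; skip addition impossible")
  ag_add(h, x)
}

#' Residual block forward pass: `H(x) + x`
#' @inheritParams dense_block_forward
#' @param weights from [residual_block_weights()].
#' @param body_only if `TRUE`, return `H(x)` without the skip addition.
#' @export
residual_block_forward <- function(x, weights, body_only = FALSE) {
  xn <- ag_input(as_feature_map(x))
  if (body_only) residual_body_node(xn, weights)$value
  else residual_block_node(xn, weights)$value
}

## ---- ACAU decoder unit -----------------------------------------------------

#' ACAU (aggregation channel-attention upsampling) weights
#'
#' One decoder stage: low-level skip features are re-weighted by a
#' squeeze-and-excitation gate, the high-level map is compressed to the
#' low-level channel count by a rectified 1x1 convolution and GeM-pooled to
#' a per-channel guidance vector, whose sigmoid multiplies the gated
#' low-level features; the product is concatenated with the 2x-upsampled
#' high-level path and fused by a 3x3 convolution.
#'
#' @param c_low channels of the skip (low-level) map.
#' @param c_high channels of the coarser (high-level) map.
#' @param c_out output width of the stage.
#' @param se_reduction reduction ratio of the SE gate on the skip map.
#' @param pk GeM exponent.
#' @param upsample `"deconv"` (2x2 stride-2 transposed convolution) or
#'   `"bilinear"` (bilinear resize followed by a 1x1 convolution).
#' @param seed optional RNG seed.
#' @return weight list for [acau_forward()].
#' @export
acau_weights <- function(c_low, c_high, c_out, se_reduction = 16L, pk = 5,
                         upsample = c("deconv", "bilinear"), seed = NULL) {
  upsample <- match.arg(upsample)
  with_rng_seed(seed, {
    list(se = se_weights(c_low, se_reduction),
         match1x1 = conv_layer(1L, c_high, c_low),
         up = if (upsample == "deconv") deconv_layer(2L, c_high, c_out)
              else conv_layer(1L, c_high, c_out),
         fuse = c(conv_layer(3L, c_low + c_out, c_out), norm_layer(c_out)),
         pk = pk, upsample = upsample,
         c_low = as.integer(c_low), c_high = as.integer(c_high),
         c_out = as.integer(c_out))
  })
}

acau_node <- function(x_low, x_high, wts) {
  dl <- dim(x_low$value); dh <- dim(x_high$value)
  if (dl[1] != 2L * dh[1] || dl[2] != 2L * dh[2])
    stop(sprintf(
      "skip map %dx%d is not twice the high-level map %dx%d; stages misaligned",
      dl[1], dl[2], dh[1], dh[2]))
  yl <- se_node(x_low, wts$se)
  xh <- ag_relu(ag_conv2d(x_high, ag_use_param(wts$match1x1$w),
                          ag_use_param(wts$match1x1$b)))
  vh <- ag_gem_pool(xh, wts$pk)
  att <- ag_mul_channel(yl, ag_sigmoid(vh))
  up <- if (wts$upsample == "deconv") {
    ag_conv_transpose2(x_high, ag_use_param(wts$up$w), ag_use_param(wts$up$b))
  } else {
    ag_conv2d(ag_bilinear_resize(x_high, dl[1], dl[2]),
              ag_use_param(wts$up$w), ag_use_param(wts$up$b))
  }
  fused <- ag_conv2d(ag_concat_ch(list(att, up)),
                     ag_use_param(wts$fuse$w), ag_use_param(wts$fuse$b),
                     stride = 1L, pad = 1L)
  fused <- ag_instance_norm(fused, ag_use_param(wts$fuse$gamma),
                            ag_use_param(wts$fuse$beta))
  ag_relu(fused)
}

#' ACAU decoder stage forward pass
#'
#' @param x_low skip-connection map at the stage's output resolution.
#' @param x_high coarser map from the previous decoder stage or bottleneck;
#'   spatial size must be exactly half of `x_low`.
#' @param weights from [acau_weights()].
#' @return feature map at `x_low` resolution with `c_out` channels.
#' @export
acau_forward <- function(x_low, x_high, weights) {
  acau_node(ag_input(as_feature_map(x_low)),
            ag_input(as_feature_map(x_high)), weights)$value
}

## ---- bottleneck: DAC and RMP ----------------------------------------------

#' Dense atrous convolution (DAC) weights
#'
#' Parallel 3x3 convolution branches at increasing dilation, each rectified,
#' summed onto a residual copy of the input. Spatial size and channel count
#' are preserved.
#'
#' @param channels channel count.
#' @param dilations dilation factor per branch.
#' @param seed optional RNG seed.
#' @export
dac_weights <- function(channels, dilations = c(1L, 3L, 5L), seed = NULL) {
  with_rng_seed(seed, {
    list(branches = lapply(dilations, function(d)
           c(conv_layer(3L, channels, channels), norm_layer(channels))),
         dilations = as.integer(dilations), channels = as.integer(channels))
  })
}

dac_node <- function(x, wts) {
  out <- x
  for (i in seq_along(wts$dilations)) {
    d <- wts$dilations[i]
    br <- ag_conv2d(x, ag_use_param(wts$branches[[i]]$w),
                    ag_use_param(wts$branches[[i]]$b),
                    stride = 1L, pad = d, dil = d)
    br <- ag_instance_norm(br, ag_use_param(wts$branches[[i]]$gamma),
                           ag_use_param(wts$branches[[i]]$beta))
    out <- ag_add(out, ag_relu(br))
  }
  out
}

#' @rdname dac_weights
#' @inheritParams dense_block_forward
#' @param weights from [dac_weights()].
#' @export
dac_forward <- function(x, weights) {
  dac_node(ag_input(as_feature_map(x)), weights)$value
}

#' Residual multi-kernel pooling (RMP) weights
#'
#' Max-pools the input at several window sizes, compresses each pooled map
#' to a single channel with a 1x1 convolution, bilinearly upsamples it back
#' to the input size, and concatenates all branches to the input: output
#' channels = input channels + one per pool size.
#'
#' @param channels input channel count.
#' @param pool_sizes pooling window sizes (stride equals the window).
#' @param seed optional RNG seed.
#' @export
rmp_weights <- function(channels, pool_sizes = c(2L, 3L, 5L, 6L), seed = NULL) {
  with_rng_seed(seed, {
    list(reduce = lapply(pool_sizes, function(s) conv_layer(1L, channels, 1L)),
         pool_sizes = as.integer(pool_sizes), channels = as.integer(channels))
  })
}

rmp_node <- function(x, wts) {
  d <- dim(x$value)
  parts <- list(x)
  for (i in seq_along(wts$pool_sizes)) {
    s <- wts$pool_sizes[i]
    if (s > d[1] || s > d[2])
      stop(sprintf("pool size %d exceeds spatial extent %dx%d", s, d[1], d[2]))
    p <- ag_maxpool(x, k = s, stride = s)
    r <- ag_conv2d(p, ag_use_param(wts$reduce[[i]]$w),
                   ag_use_param(wts$reduce[[i]]$b))
    parts[[length(parts) + 1L]] <- ag_bilinear_resize(r, d[1], d[2])
  }
  ag_concat_ch(parts)
}

#' @rdname rmp_weights
#' @inheritParams dense_block_forward
#' @param weights from [rmp_weights()].
#' @export
rmp_forward <- function(x, weights) {
  rmp_node(ag_input(as_feature_map(x)), weights)$value
}
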