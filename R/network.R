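#' Network configuration
#'
#' Full assembly of the segmentation network: a 7x7 stride-2 stem
#' convolution followed by a 3x3 stride-2 max-pool, four dense encoder
#' stages separated by 1x1-convolution + 2x2-average-pool transitions, a
#' DAC + RMP bottleneck, four ACAU decoder stages, and a prediction head
#' (2x deconvolution, ReLU, 3x3 convolution, sigmoid). Total downsampling
#' before the head is 32, so the input size must be divisible by 32.
#'
#' @param in_channels image channels (3 for RGB fundus photographs).
#' @param input_size spatial size of (square) inputs; 448 at full scale.
#' @param blocks a [block_config()].
#' @param init_features channels produced by the stem; defaults to twice
#'   the growth rate (DenseNet convention).
#' @param decoder_widths output channels of the four decoder stages, coarse
#'   to fine.
#' @param upsample decoder upsampling mode, `"deconv"` or `"bilinear"`.
#' @return a list of class `network_config`.
#' @export
network_config <- function(in_channels = 3L,
                           input_size = 448L,
                           blocks = block_config(),
                           init_features = 2L * blocks$growth_rate,
                           decoder_widths = c(512L, 256L, 128L, 64L),
                           upsample = c("deconv", "bilinear")) {
  upsample <- match.arg(upsample)
  stopifnot(in_channels >= 1, length(decoder_widths) == 4L,
            all(decoder_widths >= 1))
  if (length(input_size) == 1L) input_size <- c(input_size, input_size)
  for (ax in c(1L, 2L)) {
    if (input_size[ax] %% 32L != 0L)
      stop(sprintf("input %s %d is not divisible by the downsampling factor 32",
                   c("height", "width")[ax], input_size[ax]))
  }
  structure(list(in_channels = as.integer(in_channels),
                 input_size = as.integer(input_size),
                 blocks = blocks,
                 init_features = as.integer(init_features),
                 decoder_widths = as.integer(decoder_widths),
                 upsample = upsample),
            class = "network_config")
}

#' Reduced test-scale configuration
#'
#' A small profile (growth 8, blocks 2-2-2-2, 64x64 inputs) whose forward
#' and backward passes run in well under a second on one CPU; used for unit
#' tests and desk-scale training studies.
#'
#' @param input_size spatial input size, divisible by 32.
#' @param pk GeM exponent of the decoder stages.
#' @return a `network_config`.
#' @export
network_config_test <- function(input_size = 64L, pk = 5) {
  # bottleneck extent is input_size / 32; pool windows must fit inside it
  pools <- unique(pmin(c(1L, 2L), max(min(input_size) %/% 32L, 1L)))
  network_config(
    input_size = input_size,
    blocks = block_config(growth_rate = 8L, layers_per_block = c(2L, 2L, 2L, 2L),
                          se_reduction = 2L, pk = pk,
                          rmp_pool_sizes = pools),
    decoder_widths = c(32L, 16L, 8L, 8L))
}

# channel bookkeeping shared by build and summary
plan_channels <- function(config) {
  b <- config$blocks
  ch <- config$init_features
  enc <- integer(4)   # dense-block output channels (skip taps)
  trans <- integer(3) # transition output channels
  for (i in 1:4) {
    ch <- ch + b$layers_per_block[i] * b$growth_rate
    enc[i] <- ch
    if (i < 4L) {
      ch <- ch %/% 2L
      trans[i] <- ch
    }
  }
  list(stem = config$init_features, enc = enc, trans = trans,
       bottleneck = enc[4] + length(b$rmp_pool_sizes),
       skips = c(enc[3], enc[2], enc[1], config$init_features))
}

#' Build the segmentation network
#'
#' Instantiates all trainable parameters (Kaiming fan-in initialisation
#' under the given seed) and returns a network object holding the weights,
#' the configuration and a flat parameter registry for the optimiser.
#' Externally supplied weights can be loaded afterwards with
#' [set_network_weights()].
#'
#' @param config a [network_config()].
#' @param seed RNG seed for weight initialisation.
#' @return an object of class `acau_net`.
#' @export
build_network <- function(config, seed = 1L) {
  b <- config$blocks
  plan <- plan_channels(config)
  # every gated channel count must be divisible by the SE reduction ratio
  for (cl in plan$skips) {
    if (cl %% b$se_reduction != 0L)
      stop(sprintf("se_reduction %d does not divide skip channel count %d",
                   b$se_reduction, cl))
  }
  with_rng_seed(seed, {
    stem <- c(conv_layer(7L, config$in_channels, config$init_features),
              norm_layer(config$init_features))
    encoder <- vector("list", 4)
    transitions <- vector("list", 3)
    cin <- config$init_features
    for (i in 1:4) {
      encoder[[i]] <- dense_block_weights(cin, b$layers_per_block[i], b$growth_rate)
      cin <- plan$enc[i]
      if (i < 4L) {
        transitions[[i]] <- c(conv_layer(1L, cin, plan$trans[i]),
                              norm_layer(plan$trans[i]))
        cin <- plan$trans[i]
      }
    }
    dac <- dac_weights(plan$enc[4], b$dac_dilations)
    rmp <- rmp_weights(plan$enc[4], b$rmp_pool_sizes)
    c_high <- plan$bottleneck
    decoder <- vector("list", 4)
    for (i in 1:4) {
      decoder[[i]] <- acau_weights(plan$skips[i], c_high, config$decoder_widths[i],
                                   se_reduction = b$se_reduction, pk = b$pk,
                                   upsample = config$upsample)
      c_high <- config$decoder_widths[i]
    }
    head <- list(deconv = deconv_layer(2L, config$decoder_widths[4],
                                       config$decoder_widths[4]),
                 conv = conv_layer(3L, config$decoder_widths[4], 1L))
    wts <- list(stem = stem, encoder = encoder, transitions = transitions,
                dac = dac, rmp = rmp, decoder = decoder, head = head)
    net <- list(config = config, weights = wts, plan = plan,
                params = layer_params(wts), seed = as.integer(seed))
    class(net) <- "acau_net"
    net
  })
}

# graph-building forward pass; x is an ag_node
forward_node <- function(net, x) {
  cfg <- net$config
  w <- net$weights
  stem <- ag_conv2d(x, ag_use_param(w$stem$w), ag_use_param(w$stem$b),
                    stride = 2L, pad = 3L)
  stem <- ag_relu(ag_instance_norm(stem, ag_use_param(w$stem$gamma),
                                   ag_use_param(w$stem$beta)))
  h <- ag_maxpool(stem, k = 3L, stride = 2L, pad = 1L)
  skips <- vector("list", 4)
  for (i in 1:4) {
    h <- dense_block_node(h, w$encoder[[i]])
    skips[[i]] <- h
    if (i < 4L) {
      h <- ag_conv2d(h, ag_use_param(w$transitions[[i]]$w),
                     ag_use_param(w$transitions[[i]]$b))
      h <- ag_instance_norm(h, ag_use_param(w$transitions[[i]]$gamma),
                            ag_use_param(w$transitions[[i]]$beta))
      h <- ag_avgpool2(h)
    }
  }
  h <- dac_node(h, w$dac)
  h <- rmp_node(h, w$rmp)
  lows <- list(skips[[3]], skips[[2]], skips[[1]], stem)
  for (i in 1:4) {
    h <- acau_node(lows[[i]], h, w$decoder[[i]])
  }
  h <- ag_relu(ag_conv_transpose2(h, ag_use_param(w$head$deconv$w),
                                  ag_use_param(w$head$deconv$b)))
  h <- ag_conv2d(h, ag_use_param(w$head$conv$w), ag_use_param(w$head$conv$b),
                 stride = 1L, pad = 1L)
  ag_sigmoid(h)
}

#' Forward pass: image to prediction map
#'
#' @param net an `acau_net` from [build_network()].
#' @param image array coercible by [as_feature_map()]; spatial size must
#'   match the configuration and channel count must equal `in_channels`.
#' @return probability map of dim (H, W, 1, N), values in `[0, 1]`.
#' @export
net_forward <- function(net, image) {
  x <- as_feature_map(image)
  d <- dim(x)
  cfg <- net$config
  if (d[3] != cfg$in_channels)
    stop(sprintf("network expects %d-channel images, got %d", cfg$in_channels, d[3]))
  if (d[1] != cfg$input_size[1] || d[2] != cfg$input_size[2])
    stop(sprintf("network was configured for %dx%d inputs, got %dx%d",
                 cfg$input_size[1], cfg$input_size[2], d[1], d[2]))
  with_no_grad(forward_node(net, ag_input(x))$value)
}

#' Threshold a prediction map into a hard binary mask
#'
#' Ties (`p == threshold`) go to the foreground.
#'
#' @param p probability map.
#' @param threshold decision threshold in (0, 1).
#' @return binary array shaped like `p`.
#' @export
predict_mask <- function(p, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  m <- (p >= threshold) * 1
  if (!is.null(dim(p))) dim(m) <- dim(p)
  m
}

#' @export
print.acau_net <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' @export
format.acau_net <- function(x, ...) {
  cfg <- x$config
  p <- x$plan
  npar <- n_parameters(x$weights)
  c(sprintf("Aggregation channel-attention segmentation network"),
    sprintf("  input: %dx%d, %d channel(s); downsampling factor 32 (stem 2 x pool 2 x 3 transitions)",
            cfg$input_size[1], cfg$input_size[2], cfg$in_channels),
    sprintf("  stem: 7x7/2 conv -> %d ch, 3x3/2 max-pool", cfg$init_features),
    sprintf("  encoder: 4 dense stages (growth %d, layers %s) -> channels %s",
            cfg$blocks$growth_rate,
            paste(cfg$blocks$layers_per_block, collapse = "-"),
            paste(p$enc, collapse = ", ")),
    sprintf("  bottleneck: DAC (dilations %s) + RMP (pools %s) -> %d ch",
            paste(cfg$blocks$dac_dilations, collapse = ","),
            paste(cfg$blocks$rmp_pool_sizes, collapse = ","), p$bottleneck),
    sprintf("  decoder: 4 ACAU stages (r=%d, pk=%g, %s) -> widths %s",
            cfg$blocks$se_reduction, cfg$blocks$pk, cfg$upsample,
            paste(cfg$decoder_widths, collapse = ", ")),
    sprintf("  head: 2x deconv + ReLU + 3x3 conv + sigmoid -> 1 ch"),
    sprintf("  parameters: %d", npar))
}

#' Extract / restore network weights
#'
#' `get_network_weights()` returns a flat list of numeric arrays;
#' `set_network_weights()` writes such a list back (shapes must match).
#' Serialize the list with `saveRDS()`/`readRDS()` for checkpointing, or
#' supply externally trained encoder weights.
#'
#' @param net an `acau_net`.
#' @return for `get_network_weights`, a list of arrays.
#' @export
get_network_weights <- function(net) {
  lapply(net$params, function(p) p$value)
}

#' @rdname get_network_weights
#' @param values list of arrays as returned by `get_network_weights()`.
#' @export
set_network_weights <- function(net, values) {
  if (length(values) != length(net$params))
    stop(sprintf("expected %d weight arrays, got %d",
                 length(net$params), length(values)))
  for (i in seq_along(values)) {
    p <- net$params[[i]]
    if (length(p$value) != length(values[[i]]))
      stop(sprintf("weight array %d has %d values, expected %d",
                   i, length(values[[i]]), length(p$value)))
    dm <- dim(p$value)
    p$value <- if (is.null(dm)) as.numeric(values[[i]]) else array(values[[i]], dm)
  }
  invisible(net)
}
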