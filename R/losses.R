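#' Loss configuration
#'
#' @param alpha blend weight in `[0, 1]`: `alpha = 1` is pure cross-entropy,
#'   `alpha = 0` is pure (one minus smoothed) dice. 0.5 is the tuned default.
#' @param S additive ("add-one") smoothing constant of the dice term,
#'   protecting against 0/0 on empty masks. Unity by default.
#' @param clip_eps probabilities are clipped to `[clip_eps, 1 - clip_eps]`
#'   before logarithms; the cross-entropy is unbounded at 0 and 1.
#' @return a list of class `loss_config`.
#' @export
loss_config <- function(alpha = 0.5, S = 1, clip_eps = 1e-7) {
  stopifnot(alpha >= 0, alpha <= 1, S > 0, clip_eps > 0, clip_eps < 0.5)
  structure(list(alpha = alpha, S = S, clip_eps = clip_eps),
            class = "loss_config")
}

check_pair <- function(prediction, truth) {
  prediction <- as.array(prediction)
  truth <- as.array(truth)
  if (!identical(dim(prediction), dim(truth)) &&
      length(prediction) != length(truth))
    stop("prediction and ground truth must share one grid")
  if (!all(truth %in% c(0, 1)))
    stop("ground-truth mask must be strictly binary")
  if (any(prediction < 0 | prediction > 1))
    stop("predicted probabilities must lie in [0, 1]")
  list(p = as.numeric(prediction), t = as.numeric(truth))
}

#' Binary cross-entropy
#'
#' Mean over pixels of `-(t*log(p) + (1-t)*log(1-p))`, with `p` clipped to
#' `[clip_eps, 1 - clip_eps]`.
#'
#' @param prediction probabilities in `[0, 1]`.
#' @param truth binary mask on the same grid.
#' @param clip_eps clipping bound for the logarithms.
#' @return non-negative scalar.
#' @export
cross_entropy <- function(prediction, truth, clip_eps = 1e-7) {
  z <- check_pair(prediction, truth)
  p <- pmin(pmax(z$p, clip_eps), 1 - clip_eps)
  -mean(z$t * log(p) + (1 - z$t) * log(1 - p))
}

#' Dice coefficient with additive smoothing
#'
#' `(2 * sum(p*t) + S) / (sum(p) + sum(t) + S)`. With `S = 0` this is the
#' plain dice overlap; a positive `S` rescues the empty-vs-empty case.
#'
#' @inheritParams cross_entropy
#' @param S smoothing constant (`>= 0` here; the loss uses `S > 0`).
#' @return scalar in (0, 1] (in [0, 1] when `S = 0`).
#' @export
dice_coefficient <- function(prediction, truth, S = 1) {
  z <- check_pair(prediction, truth)
  num <- 2 * sum(z$p * z$t) + S
  den <- sum(z$p) + sum(z$t) + S
  if (den == 0) return(1)        # S = 0 and both masks empty
  num / den
}

#' Combined dice + cross-entropy segmentation loss
#'
#' `L = alpha * CE + (1 - alpha) * (1 - dice_S)`: the convex blend of the
#' pixel-wise cross-entropy and the complement of the smoothed dice
#' coefficient, balancing per-pixel classification against small-region
#' overlap.
#'
#' @inheritParams cross_entropy
#' @param config a [loss_config()].
#' @return scalar loss.
#' @export
combined_loss <- function(prediction, truth, config = loss_config()) {
  config$alpha * cross_entropy(prediction, truth, config$clip_eps) +
    (1 - config$alpha) *
      (1 - dice_coefficient(prediction, truth, config$S))
}

#' Gradient of the combined loss with respect to the prediction
#'
#' Exact analytic gradient, matching [combined_loss()] (pixels at the clip
#' boundary get zero cross-entropy gradient).
#'
#' @inheritParams combined_loss
#' @return numeric array shaped like `prediction`.
#' @export
combined_loss_grad <- function(prediction, truth, config = loss_config()) {
  shp <- dim(prediction)
  z <- check_pair(prediction, truth)
  eps <- config$clip_eps
  p <- pmin(pmax(z$p, eps), 1 - eps)
  inner <- z$p > eps & z$p < 1 - eps
  n <- length(p)
  dce <- (-(z$t / p) + (1 - z$t) / (1 - p)) / n * inner
  num <- 2 * sum(z$p * z$t) + config$S
  den <- sum(z$p) + sum(z$t) + config$S
  ddc <- (2 * z$t * den - num) / den^2
  g <- config$alpha * dce - (1 - config$alpha) * ddc
  if (!is.null(shp)) dim(g) <- shp
  g
}

#' Overlapping error (one minus intersection-over-union)
#'
#' `E = 1 - |X ∩ Y| / |X ∪ Y| = (FP + FN) / (TP + FP + FN)` for binary
#' masks X (prediction) and Y (truth). Zero iff the masks agree on their
#' union; two empty masks score 0 by convention. Lower is better.
#'
#' @param pred_mask,truth_mask binary masks on one grid.
#' @return scalar in `[0, 1]`.
#' @export
overlapping_error <- function(pred_mask, truth_mask) {
  x <- as.numeric(pred_mask)
  y <- as.numeric(truth_mask)
  if (length(x) != length(y))
    stop("masks must share one grid")
  if (!all(x %in% c(0, 1)) || !all(y %in% c(0, 1)))
    stop("overlapping error is defined on binary masks")
  inter <- sum(x * y)
  uni <- sum(pmax(x, y))
  if (uni == 0) return(0)
  1 - inter / uni
}
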