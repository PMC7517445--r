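#' Training configuration
#'
#' @param base_lr base learning rate of the polynomial decay schedule.
#' @param epochs number of passes over the training set.
#' @param batch_size images per optimiser step.
#' @param poly_power exponent of the polynomial decay.
#' @param alpha loss blend weight (see [loss_config()]).
#' @param S dice smoothing constant.
#' @param clip_eps cross-entropy clipping bound.
#' @param seed RNG seed governing shuffling (and any photometric jitter).
#' @param max_iter total optimiser steps of the schedule; defaults to
#'   `epochs * steps_per_epoch` and also caps the run when reached early.
#' @param val_fraction fraction of samples held out (seeded shuffle) for
#'   the per-epoch validation overlapping error in the history; 0 disables.
#' @param beta1,beta2,adam_eps Adam moment decay rates and stabiliser.
#' @param eval_every record validation error every this many epochs.
#' @return a list of class `train_config`.
#' @export
train_config <- function(base_lr = 2e-4, epochs = 200L, batch_size = 1L,
                         poly_power = 0.9, alpha = 0.5, S = 1,
                         clip_eps = 1e-7, seed = 42L, max_iter = NULL,
                         val_fraction = 0.2, beta1 = 0.9, beta2 = 0.999,
                         adam_eps = 1e-8, eval_every = 1L) {
  stopifnot(base_lr > 0, epochs >= 1, batch_size >= 1, poly_power > 0,
            alpha >= 0, alpha <= 1, S > 0, val_fraction >= 0, val_fraction < 1)
  structure(list(base_lr = base_lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), poly_power = poly_power,
                 alpha = alpha, S = S, clip_eps = clip_eps,
                 seed = as.integer(seed),
                 max_iter = if (is.null(max_iter)) NULL else as.integer(max_iter),
                 val_fraction = val_fraction, beta1 = beta1, beta2 = beta2,
                 adam_eps = adam_eps, eval_every = as.integer(eval_every)),
            class = "train_config")
}

#' Desk-scale training configuration
#'
#' The configuration used for the package's small-scale training studies:
#' full-batch Adam (all samples per step, so one iteration is one optimiser
#' step on the exact loss), base learning rate 0.01, 200 steps of
#' polynomial decay, no validation split. Paired with
#' [network_config_test()] and a handful of 64x64 synthetic pairs it
#' overfits to near-zero overlapping error within the 200 steps.
#'
#' @param alpha loss blend weight.
#' @param iterations optimiser steps (= epochs at full batch).
#' @param n_samples training-set size (sets the batch).
#' @return a `train_config`.
#' @export
train_config_desk <- function(alpha = 0.5, iterations = 200L, n_samples = 8L) {
  train_config(base_lr = 1e-2, epochs = as.integer(iterations),
               batch_size = as.integer(n_samples), alpha = alpha,
               val_fraction = 0, seed = 42L)
}

#' Polynomial learning-rate decay
#'
#' `lr = base_lr * (1 - iter / max_iter)^power`: equal to `base_lr` at
#' iteration 0 and 0 at `max_iter`, non-increasing in between. Iterations
#' beyond `max_iter` are clamped to 0 with a warning.
#'
#' @param iter 0-based optimiser step.
#' @param config a [train_config()] with `max_iter` set (or a list with
#'   `base_lr`, `max_iter`, `poly_power`).
#' @return scalar learning rate.
#' @export
poly_lr <- function(iter, config) {
  if (is.null(config$max_iter))
    stop("poly_lr needs max_iter in the configuration")
  if (iter < 0) stop("iter must be >= 0")
  if (iter > config$max_iter) {
    warning(sprintf("iter %d beyond max_iter %d; learning rate clamped to 0",
                    iter, config$max_iter))
    return(0)
  }
  config$base_lr * (1 - iter / config$max_iter)^config$poly_power
}

stack_batch <- function(pairs) {
  d <- dim(pairs[[1]]$image)
  n <- length(pairs)
  x <- array(0, c(d[1], d[2], d[3], n))
  t <- array(0, c(d[1], d[2], 1L, n))
  for (i in seq_len(n)) {
    x[, , , i] <- pairs[[i]]$image
    t[, , 1L, i] <- pairs[[i]]$mask
  }
  list(x = x, t = t)
}

adam_state <- function(params) {
  # p$value * 0 clones the exact shape (vectors stay dimensionless)
  lapply(params, function(p) list(m = p$value * 0, v = p$value * 0))
}

adam_step <- function(params, state, lr, t, cfg) {
  b1 <- cfg$beta1; b2 <- cfg$beta2; eps <- cfg$adam_eps
  for (i in seq_along(params)) {
    p <- params[[i]]
    g <- p$grad
    st <- state[[i]]
    st$m <- b1 * st$m + (1 - b1) * g
    st$v <- b2 * st$v + (1 - b2) * g^2
    state[[i]] <- st
    mh <- st$m / (1 - b1^t)
    vh <- st$v / (1 - b2^t)
    p$value <- p$value - lr * mh / (sqrt(vh) + eps)
  }
  state
}

#' Train the network
#'
#' Per optimiser step: forward pass, combined dice + cross-entropy loss,
#' backpropagation, Adam update at the polynomially decayed learning rate.
#' Fully reproducible given the seeds (weights from [build_network()],
#' shuffling from `config$seed`). Aborts if the loss becomes non-finite.
#'
#' @param net an `acau_net`; updated in place (parameters are mutable) and
#'   also returned.
#' @param dataset non-empty list of `sample_pair`s at the network's
#'   configured input size.
#' @param config a [train_config()].
#' @param verbose print a line per epoch.
#' @return an `acau_fit`: list with `net`, `history` (one row per step:
#'   iter, epoch, lr, loss) and `val_history` (epoch, mean overlapping
#'   error on the held-out split, if any).
#' @export
train <- function(net, dataset, config = train_config(), verbose = FALSE) {
  if (length(dataset) == 0) stop("training dataset is empty")
  n <- length(dataset)
  with_rng_seed(config$seed, {
    idx <- sample.int(n)
    n_val <- floor(config$val_fraction * n)
    val_idx <- if (n_val > 0) idx[seq_len(n_val)] else integer(0)
    tr_idx <- setdiff(idx, val_idx)
    if (length(tr_idx) == 0) stop("validation split left no training samples")
    steps_per_epoch <- ceiling(length(tr_idx) / config$batch_size)
    max_iter <- config$max_iter %||% (config$epochs * steps_per_epoch)
    sched <- list(base_lr = config$base_lr, max_iter = max_iter,
                  poly_power = config$poly_power)
    state <- adam_state(net$params)
    hist <- vector("list", config$epochs * steps_per_epoch)
    val_hist <- list()
    step <- 0L
    done <- FALSE
    for (epoch in seq_len(config$epochs)) {
      order_ep <- sample(tr_idx)
      for (bi in seq_len(steps_per_epoch)) {
        lo <- (bi - 1L) * config$batch_size + 1L
        hi <- min(bi * config$batch_size, length(order_ep))
        batch <- stack_batch(dataset[order_ep[lo:hi]])
        lr <- poly_lr(step, sched)
        zero_grads(net$params)
        pred <- forward_node(net, ag_input(batch$x))
        loss <- ag_combined_loss(pred, batch$t, alpha = config$alpha,
                                 S = config$S, clip_eps = config$clip_eps)
        lv <- as.numeric(loss$value)
        if (!is.finite(lv))
          stop(sprintf("non-finite loss at iteration %d; aborting", step))
        backward_ag(loss)
        step <- step + 1L
        state <- adam_step(net$params, state, lr, step, config)
        hist[[step]] <- c(iter = step - 1L, epoch = epoch, lr = lr, loss = lv)
        if (step >= max_iter) { done <- TRUE; break }
      }
      if (length(val_idx) > 0 && (epoch %% config$eval_every == 0L || done)) {
        ev <- evaluate(net, dataset[val_idx])
        val_hist[[length(val_hist) + 1L]] <-
          c(epoch = epoch, mean_E = ev$summary$mean_E)
      }
      if (verbose) {
        ep_rows <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
        ep_loss <- mean(ep_rows[ep_rows[, "epoch"] == epoch, "loss"])
        message(sprintf("epoch %d/%d  loss %.4f  lr %.2e",
                        epoch, config$epochs, ep_loss, poly_lr(min(step, max_iter), sched)))
      }
      if (done) break
    }
    hist <- hist[!vapply(hist, is.null, logical(1))]
    structure(list(net = net,
                   history = as.data.frame(do.call(rbind, hist)),
                   val_history = if (length(val_hist))
                     as.data.frame(do.call(rbind, val_hist)) else NULL,
                   config = config),
              class = "acau_fit")
  })
}

#' Evaluate segmentations by overlapping error
#'
#' Runs the network (or any predictor function mapping a `sample_pair` to
#' a probability map) on every sample, thresholds the prediction, and
#' scores it against the ground truth: overlapping error E, dice
#' coefficient (unsmoothed) and cross-entropy per image.
#'
#' @param net an `acau_net`, or a `function(pair)` returning a probability
#'   map.
#' @param dataset non-empty list of `sample_pair`s.
#' @param threshold mask decision threshold.
#' @param csv optional path; per-image metrics are written as CSV.
#' @return list with `metrics` (data.frame: image_id, E, DC, CE) and
#'   `summary` (mean_E, median_E, mean_DC).
#' @export
evaluate <- function(net, dataset, threshold = 0.5, csv = NULL) {
  if (length(dataset) == 0) stop("evaluation dataset is empty")
  predictor <- if (is.function(net)) net else function(pair) net_forward(net, pair$image)
  rows <- lapply(dataset, function(pair) {
    p <- predictor(pair)
    p <- array(p, dim(as_feature_map(p))[1:2])
    m <- predict_mask(p, threshold)
    data.frame(image_id = pair$id,
               E = overlapping_error(m, pair$mask),
               DC = dice_coefficient(m, pair$mask, S = 0),
               CE = cross_entropy(p, pair$mask),
               stringsAsFactors = FALSE)
  })
  metrics <- do.call(rbind, rows)
  if (!is.null(csv)) write.csv(metrics, csv, row.names = FALSE)
  list(metrics = metrics,
       summary = list(mean_E = mean(metrics$E),
                      median_E = median(metrics$E),
                      mean_DC = mean(metrics$DC)))
}

#' Grid sweep over the GeM exponent and the loss blend weight
#'
#' Re-trains a fresh network for every (pk, alpha) combination at the given
#' configuration and reports the resulting mean overlapping error on the
#' evaluation set; the desk-scale analogue of a hyper-parameter sweep.
#'
#' @param dataset training pairs.
#' @param pks,alphas grids to sweep.
#' @param make_config `function(pk)` returning the `network_config` to use.
#' @param train_cfg base [train_config()]; `alpha` is overridden per run.
#' @param eval_dataset pairs to score (defaults to `dataset`).
#' @param net_seed weight-initialisation seed shared by all runs.
#' @return data.frame with columns pk, alpha, mean_E, final_loss.
#' @export
sweep_hyper <- function(dataset, pks, alphas,
                        make_config = function(pk) network_config_test(pk = pk),
                        train_cfg = train_config(), eval_dataset = dataset,
                        net_seed = 1L) {
  grid <- expand.grid(pk = pks, alpha = alphas)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- train_cfg
    cfg$alpha <- grid$alpha[i]
    net <- build_network(make_config(grid$pk[i]), seed = net_seed)
    fit <- train(net, dataset, cfg)
    ev <- evaluate(net, eval_dataset)
    data.frame(pk = grid$pk[i], alpha = grid$alpha[i],
               mean_E = ev$summary$mean_E,
               final_loss = fit$history$loss[nrow(fit$history)])
  })
  do.call(rbind, res)
}
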