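# Evaluate expr under a temporary RNG seed, restoring the caller's RNG state.
with_rng_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Coerce an image or map to the internal (H, W, C, N) layout
#'
#' Accepts a matrix (H x W), a 3-axis array (H, W, C) or a 4-axis array and
#' returns a 4-axis array, adding singleton channel/batch axes as needed.
#'
#' @param x numeric matrix or array.
#' @return a 4-axis numeric array of dim (H, W, C, N).
#' @export
as_feature_map <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("feature maps need at least two axes")
  if (length(d) == 2L) d <- c(d, 1L, 1L)
  if (length(d) == 3L) d <- c(d, 1L)
  if (length(d) != 4L) stop("feature maps have at most four axes (H, W, C, N)")
  if (any(d < 1L)) stop("all feature-map axis lengths must be >= 1")
  array(x, d)
}

as_descriptor <- function(v) {
  if (is.matrix(v)) v else matrix(v, ncol = 1L)
}

# Kaiming (He) fan-in initialisation for ReLU networks
kaiming_conv <- function(k, cin, cout) {
  array(rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))), c(k, k, cin, cout))
}

kaiming_linear <- function(cin, cout) {
  matrix(rnorm(cin * cout, 0, sqrt(2 / cin)), nrow = cout, ncol = cin)
}

conv_layer <- function(k, cin, cout, zero = FALSE) {
  w <- if (zero) array(0, c(k, k, cin, cout)) else kaiming_conv(k, cin, cout)
  list(w = new_param(w), b = new_param(numeric(cout)))
}

deconv_layer <- function(k, cin, cout, zero = FALSE) {
  w <- if (zero) array(0, c(k, k, cout, cin)) else
    array(rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))), c(k, k, cout, cin))
  list(w = new_param(w), b = new_param(numeric(cout)))
}

norm_layer <- function(cout) {
  list(gamma = new_param(rep(1, cout)), beta = new_param(rep(0, cout)))
}

layer_params <- function(wts) {
  out <- list()
  walk <- function(x) {
    if (inherits(x, "ag_param")) out[[length(out) + 1L]] <<- x
    else if (is.list(x)) for (el in x) walk(el)
  }
  walk(wts)
  out
}

n_parameters <- function(wts) {
  sum(vapply(layer_params(wts), function(p) length(p$value), numeric(1)))
}
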