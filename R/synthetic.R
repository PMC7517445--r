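#' Synthetic fundus-image specification
#'
#' Parameters of the synthetic generator, which renders a bright, roughly
#' circular optic-disc region on a darker, textured reddish background with
#' optional dark vessel curves, together with the exact binary disc mask.
#' The disc is an ellipse with mild random eccentricity and rotation whose
#' expected area equals that of a circle with the drawn radius.
#'
#' @param size square image size in pixels (448 at full scale, 64 in tests).
#' @param disc_radius_range radius as a fraction of `size`; drawn uniformly.
#' @param disc_center_jitter maximal center offset from the image center,
#'   as a fraction of `size`.
#' @param disc_brightness peak disc intensity in `[0, 1]`.
#' @param background_texture_scale amplitude of the low-frequency
#'   background texture.
#' @param vessel_count number of dark vessel curves crossing the frame.
#' @param noise_sd standard deviation of additive Gaussian pixel noise.
#' @param seed base RNG seed; together with the sample index it makes every
#'   sample fully deterministic.
#' @return a list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(size = 448L,
                           disc_radius_range = c(0.12, 0.18),
                           disc_center_jitter = 0.06,
                           disc_brightness = 0.95,
                           background_texture_scale = 0.05,
                           vessel_count = 3L,
                           noise_sd = 0.02,
                           seed = 1L) {
  stopifnot(size >= 16, length(disc_radius_range) == 2L,
            disc_radius_range[1] <= disc_radius_range[2],
            disc_radius_range[1] > 0, disc_center_jitter >= 0,
            vessel_count >= 0, noise_sd >= 0)
  # worst case: largest radius, maximal eccentricity stretch, maximal jitter
  if (disc_radius_range[2] * 1.15 + disc_center_jitter > 0.5)
    stop("disc radius plus center jitter would not fit inside the image")
  structure(list(size = as.integer(size),
                 disc_radius_range = disc_radius_range,
                 disc_center_jitter = disc_center_jitter,
                 disc_brightness = disc_brightness,
                 background_texture_scale = background_texture_scale,
                 vessel_count = as.integer(vessel_count),
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

sample_seed <- function(spec, index) {
  as.integer((as.numeric(spec$seed) * 7919 + as.numeric(index)) %%
               .Machine$integer.max)
}

#' Generate one synthetic image/mask pair
#'
#' Deterministic given `(spec$seed, index)`. The mask is the exact pixel
#' support of the rendered elliptical disc; the image blends the bright
#' disc into the textured background with a narrow smooth boundary, then
#' overlays vessels and noise (mask unaffected by either).
#'
#' @param spec a [synthetic_spec()].
#' @param index sample index (1-based).
#' @return a `sample_pair`: list with `image` (H x W x 3 array in `[0,1]`),
#'   `mask` (H x W binary matrix) and `id`.
#' @export
generate_sample <- function(spec, index = 1L) {
  s <- spec$size
  with_rng_seed(sample_seed(spec, index), {
    r_frac <- runif(1, spec$disc_radius_range[1], spec$disc_radius_range[2])
    radius <- r_frac * s
    jit <- spec$disc_center_jitter * s
    cx <- s / 2 + runif(1, -jit, jit)
    cy <- s / 2 + runif(1, -jit, jit)
    ecc <- runif(1, 0, 0.15)
    theta <- runif(1, 0, pi)
    a <- radius * (1 + ecc)
    b <- radius / (1 + ecc)

    row <- matrix(seq_len(s), s, s)          # y coordinate
    col <- matrix(seq_len(s), s, s, byrow = TRUE)
    dx <- col - cx
    dy <- row - cy
    u <- (dx * cos(theta) + dy * sin(theta)) / a
    v <- (-dx * sin(theta) + dy * cos(theta)) / b
    q <- u^2 + v^2
    mask <- (q <= 1) * 1

    # smooth radial blend for the image only; the mask stays exact
    w <- 1 / (1 + exp((sqrt(q) - 1) / 0.03))
    tex <- matrix(0, s, s)
    for (k in 1:3) {
      f <- runif(2, 1, 4)
      ph <- runif(1, 0, 2 * pi)
      tex <- tex + sin(2 * pi * (f[1] * row + f[2] * col) / s + ph)
    }
    tex <- tex / 3 * spec$background_texture_scale

    bg <- c(0.55, 0.26, 0.16)                 # reddish fundus background
    disc <- c(1.0, 0.9, 0.6) * spec$disc_brightness
    img <- array(0, c(s, s, 3))
    for (ch in 1:3) {
      img[, , ch] <- bg[ch] * (1 + tex) * (1 - w) + disc[ch] * w
    }

    if (spec$vessel_count > 0) {
      shade <- c(0.45, 0.30, 0.30)            # dark red vessel tint
      for (vn in seq_len(spec$vessel_count)) {
        ang <- runif(1, 0, pi)
        amp <- runif(1, 0.02, 0.08) * s
        freq <- runif(1, 1, 2.5)
        off <- runif(1, -0.3, 0.3) * s
        width <- runif(1, 0.006, 0.015) * s + 0.6
        # signed distance of each pixel to a sinusoidally perturbed line
        # through the disc center at angle ang
        t_par <- dx * cos(ang) + dy * sin(ang)
        d_perp <- -dx * sin(ang) + dy * cos(ang) - off -
          amp * sin(2 * pi * freq * t_par / s)
        hit <- abs(d_perp) <= width
        for (ch in 1:3) {
          plane <- img[, , ch]
          plane[hit] <- plane[hit] * shade[ch]
          img[, , ch] <- plane
        }
      }
    }

    if (spec$noise_sd > 0) {
      img <- img + array(rnorm(length(img), 0, spec$noise_sd), dim(img))
    }
    img <- pmin(pmax(img, 0), 1)
    dim(img) <- c(s, s, 3)
    structure(list(image = img, mask = mask,
                   id = sprintf("synth_%05d", as.integer(index))),
              class = "sample_pair")
  })
}

#' Generate a list of synthetic pairs
#' @inheritParams generate_sample
#' @param n number of samples.
#' @param start_index index of the first sample.
#' @return list of `sample_pair`s.
#' @export
generate_dataset <- function(spec, n, start_index = 1L) {
  lapply(seq_len(n) + start_index - 1L, function(i) generate_sample(spec, i))
}

flip_plane <- function(m, op) {
  switch(op,
         id = m,
         h = m[, rev(seq_len(ncol(m))), drop = FALSE],
         v = m[rev(seq_len(nrow(m))), , drop = FALSE],
         hv = m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m))), drop = FALSE],
         t = t(m),
         th = t(m)[, rev(seq_len(nrow(m))), drop = FALSE],
         tv = t(m)[rev(seq_len(ncol(m))), , drop = FALSE],
         thv = t(m)[rev(seq_len(ncol(m))), rev(seq_len(nrow(m))), drop = FALSE])
}

apply_flip <- function(pair, op) {
  img <- pair$image
  out <- array(0, dim(img)[c(1, 2, 3)])
  for (ch in seq_len(dim(img)[3])) out[, , ch] <- flip_plane(img[, , ch], op)
  structure(list(image = out, mask = flip_plane(pair$mask, op),
                 id = paste0(pair$id, "_", op)),
            class = "sample_pair")
}

#' Eightfold orientation augmentation
#'
#' Returns the full dihedral-group orbit of a square sample: identity,
#' horizontal flip, vertical flip, both, transposition and its three flips
#' — the eight orientation variants generated by composing horizontal,
#' vertical and diagonal flips. Image and mask are transformed identically,
#' so mask area is invariant.
#'
#' @param pair a `sample_pair` with a square image.
#' @return list of exactly 8 `sample_pair`s (the first is the original).
#' @export
augment_eightfold <- function(pair) {
  d <- dim(pair$image)
  if (d[1] != d[2])
    stop("diagonal flips require square images")
  lapply(c("id", "h", "v", "hv", "t", "th", "tv", "thv"),
         function(op) apply_flip(pair, op))
}

shift_plane <- function(m, dx, dy) {
  out <- matrix(0, nrow(m), ncol(m))
  src_r <- seq_len(nrow(m)) - dy
  src_c <- seq_len(ncol(m)) - dx
  ok_r <- src_r >= 1 & src_r <= nrow(m)
  ok_c <- src_c >= 1 & src_c <= ncol(m)
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c], drop = FALSE]
  out
}

#' Photometric and translation jitter
#'
#' Multiplies the image by a brightness factor (mask untouched) and shifts
#' image and mask together by an integer offset with zero padding. Draws
#' are uniform over the given ranges unless exact values are supplied.
#'
#' @param pair a `sample_pair`.
#' @param brightness_range multiplicative factor range.
#' @param shift_range integer pixel-offset range, applied to both axes.
#' @param seed optional RNG seed for the draws.
#' @param brightness,shift exact overrides: a scalar factor and/or an
#'   integer vector `c(dx, dy)` (columns right, rows down).
#' @return a jittered `sample_pair`, or `NULL` (with a warning) if the
#'   shift pushes the whole disc out of frame.
#' @export
jitter_photometric <- function(pair, brightness_range = c(0.8, 1.2),
                               shift_range = c(-10L, 10L), seed = NULL,
                               brightness = NULL, shift = NULL) {
  with_rng_seed(seed, {
    if (is.null(brightness))
      brightness <- runif(1, brightness_range[1], brightness_range[2])
    if (is.null(shift))
      shift <- sample(seq(shift_range[1], shift_range[2]), 2L, replace = TRUE)
  })
  img <- pmin(pmax(pair$image * brightness, 0), 1)
  dx <- as.integer(shift[1]); dy <- as.integer(shift[2])
  if (dx != 0L || dy != 0L) {
    out <- array(0, dim(img))
    for (ch in seq_len(dim(img)[3])) out[, , ch] <- shift_plane(img[, , ch], dx, dy)
    img <- out
    mask <- shift_plane(pair$mask, dx, dy)
  } else {
    mask <- pair$mask
  }
  if (sum(mask) == 0 && sum(pair$mask) > 0) {
    warning(sprintf("shift (%d, %d) ejected the disc from sample %s; dropped",
                    dx, dy, pair$id))
    return(NULL)
  }
  structure(list(image = img, mask = mask, id = paste0(pair$id, "_j")),
            class = "sample_pair")
}

resize_image <- function(img, size) {
  d <- dim(img)
  A <- bilin_mat(d[1], size)
  B <- bilin_mat(d[2], size)
  out <- array(0, c(size, size, d[3]))
  for (ch in seq_len(d[3])) out[, , ch] <- A %*% img[, , ch] %*% t(B)
  out
}

resize_mask_nn <- function(mask, size) {
  d <- dim(mask)
  ri <- pmin(pmax(round((seq_len(size) - 0.5) * d[1] / size + 0.5), 1), d[1])
  ci <- pmin(pmax(round((seq_len(size) - 0.5) * d[2] / size + 0.5), 1), d[2])
  mask[ri, ci, drop = FALSE]
}

read_image_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF images requires the 'tiff' package")
    img <- tiff::readTIFF(path)
  } else {
    img <- png::readPNG(path)
  }
  if (length(dim(img)) == 2L) dim(img) <- c(dim(img), 1L)
  img[, , seq_len(min(3L, dim(img)[3])), drop = FALSE]
}

#' Read an images/masks dataset from disk
#'
#' Expects `root/images/<id>.png` (or `.tif`) paired with
#' `root/masks/<id>.png`. Images are decoded to `[0, 1]`; masks are
#' binarized at 0.5. Images without a matching mask are skipped with a
#' message reporting the count. If `size` is given, images are bilinearly
#' resized and masks resampled nearest-neighbour (preserving binarity).
#'
#' @param root dataset root directory.
#' @param size optional square output size.
#' @param layout names of the image and mask subdirectories.
#' @return list of `sample_pair`s.
#' @export
read_dataset <- function(root, size = NULL,
                         layout = list(images = "images", masks = "masks")) {
  img_dir <- file.path(root, layout$images)
  msk_dir <- file.path(root, layout$masks)
  files <- list.files(img_dir, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE)
  ids <- tools::file_path_sans_ext(files)
  pairs <- list()
  skipped <- 0L
  for (i in seq_along(files)) {
    mask_path <- file.path(msk_dir, paste0(ids[i], ".png"))
    if (!file.exists(mask_path)) {
      skipped <- skipped + 1L
      next
    }
    img <- read_image_file(file.path(img_dir, files[i]))
    if (dim(img)[3] == 1L) img <- array(rep(img, 3L), c(dim(img)[1:2], 3L))
    msk <- png::readPNG(mask_path)
    if (length(dim(msk)) == 3L) msk <- msk[, , 1]
    msk <- (msk >= 0.5) * 1
    if (!is.null(size)) {
      img <- resize_image(img, size)
      msk <- resize_mask_nn(msk, size)
    }
    img <- pmin(pmax(img, 0), 1)
    pairs[[length(pairs) + 1L]] <-
      structure(list(image = img, mask = msk, id = ids[i]), class = "sample_pair")
  }
  if (skipped > 0L)
    message(sprintf("read_dataset: skipped %d image(s) without a matching mask",
                    skipped))
  pairs
}

#' Write a dataset as 8-bit PNG files
#'
#' Writes `root/images/<id>.png` (RGB) and `root/masks/<id>.png`
#' (single-channel, 0/255).
#'
#' @param pairs list of `sample_pair`s.
#' @param root output directory (created if missing).
#' @return invisibly, the vector of ids written.
#' @export
write_dataset <- function(pairs, root) {
  dir.create(file.path(root, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(root, "masks"), recursive = TRUE, showWarnings = FALSE)
  for (p in pairs) {
    png::writePNG(p$image, file.path(root, "images", paste0(p$id, ".png")))
    png::writePNG(p$mask, file.path(root, "masks", paste0(p$id, ".png")))
  }
  invisible(vapply(pairs, function(p) p$id, character(1)))
}
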