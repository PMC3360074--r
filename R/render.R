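#' Gabor rendering parameters
#'
#' @param envelope_sigma Gaussian envelope standard deviation, DVA.
#' @param wavelength Carrier wavelength, DVA.
#' @param contrast Michelson contrast of a single patch, in `(0, 1]`.
#' @param mean_luminance Background grey level in `[0, 1]`.
#' @param pixels_per_dva Raster scale.
#' @return An object of class `gabor_render_params`.
#' @export
gabor_render_params <- function(envelope_sigma = 0.115, wavelength = 0.46,
                                contrast = 0.9, mean_luminance = 0.5,
                                pixels_per_dva = 34.6) {
  for (nm in c("envelope_sigma", "wavelength", "contrast", "pixels_per_dva")) {
    check_positive_scalar(get(nm), nm)
  }
  structure(list(envelope_sigma = envelope_sigma, wavelength = wavelength,
                 contrast = contrast, mean_luminance = mean_luminance,
                 pixels_per_dva = pixels_per_dva),
            class = "gabor_render_params")
}

#' Render a stimulus as a grey-level Gabor image
#'
#' Places one Gabor patch per edge: a cosine grating along the edge's
#' direction under a circular Gaussian envelope, with an independent uniform
#' random phase per patch, added onto the mean luminance. Values are clipped
#' to `[0, 1]`; clipping from overlapping envelopes raises a warning, not an
#' error. With `phase = 0` the deviation from mean luminance at a patch
#' centre equals the contrast.
#'
#' @param stimulus A stimulus tibble (one stimulus; rows are edges). An empty
#'   tibble yields a uniform image at `mean_luminance`.
#' @param params A [gabor_render_params()].
#' @param field_width,field_height Image extent in DVA.
#' @param seed Optional seed (for the random phases).
#' @param phases Optional numeric vector of phases (radians), one per edge,
#'   overriding the random draw.
#' @return A numeric matrix in `[0, 1]` with attribute `pixels_per_dva`; rows
#'   run top to bottom.
#' @export
render_gabor_image <- function(stimulus, params = gabor_render_params(),
                               field_width = 26.6, field_height = 20,
                               seed = NULL, phases = NULL) {
  stopifnot(inherits(params, "gabor_render_params"))
  if (!is.null(seed)) withr::local_seed(seed)
  ppd <- params$pixels_per_dva
  nx <- max(1L, round(field_width * ppd))
  ny <- max(1L, round(field_height * ppd))
  img <- matrix(params$mean_luminance, ny, nx)
  n_edges <- nrow(stimulus)
  if (n_edges == 0L) {
    attr(img, "pixels_per_dva") <- ppd
    return(img)
  }
  if (is.null(phases)) phases <- runif(n_edges, 0, 2 * pi)
  # pixel-centre coordinates in DVA (y decreasing down the rows)
  px <- (seq_len(nx) - 0.5) / ppd - field_width / 2
  py <- field_height / 2 - (seq_len(ny) - 0.5) / ppd
  half <- 3 * params$envelope_sigma
  for (i in seq_len(n_edges)) {
    x0 <- stimulus$x[i]; y0 <- stimulus$y[i]; th <- stimulus$theta[i]
    ix <- which(px >= x0 - half & px <= x0 + half)
    iy <- which(py >= y0 - half & py <= y0 + half)
    if (!length(ix) || !length(iy)) next
    gx <- matrix(px[ix] - x0, length(iy), length(ix), byrow = TRUE)
    gy <- matrix(py[iy] - y0, length(iy), length(ix))
    # carrier varies perpendicular to the edge direction
    perp <- -gx * sin(th) + gy * cos(th)
    patch <- params$contrast *
      exp(-(gx^2 + gy^2) / (2 * params$envelope_sigma^2)) *
      cos(2 * pi * perp / params$wavelength + phases[i])
    img[iy, ix] <- img[iy, ix] + patch
  }
  n_clip <- sum(img < 0 | img > 1)
  if (n_clip > 0L) {
    warn(sprintf("%d pixel(s) clipped to the valid luminance range.", n_clip))
    img[img < 0] <- 0
    img[img > 1] <- 1
  }
  attr(img, "pixels_per_dva") <- ppd
  img
}
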