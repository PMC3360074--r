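#' Association-field parameters
#'
#' The association field (AF) is the conditional link density between two
#' oriented edge elements. Its shape is controlled by three scales:
#'
#' * `sigma_align` (radians): how quickly link probability decays with the
#'   deviation of the second edge's direction from the perfect co-circular
#'   continuation (direction change `2 * phi` at viewing angle `phi`).
#' * `sigma_curv` (radians): how quickly link probability decays with the
#'   direction difference `dtheta` between the two edges; at fixed pair
#'   distance, `dtheta` is proportional to the curvature of the connecting
#'   circular arc.
#' * `lambda_radial` (degrees of visual angle): spatial constant of the
#'   exponentially decaying radial part.
#'
#' @param sigma_align Angular scale for co-circularity deviation, radians > 0.
#' @param sigma_curv Angular scale for direction difference, radians > 0.
#' @param lambda_radial Radial decay constant, DVA > 0. Default 10 DVA.
#' @return An object of class `af_params`.
#' @examples
#' af_params(0.2, 0.4)
#' @export
af_params <- function(sigma_align, sigma_curv, lambda_radial = 10) {
  check_positive_scalar(sigma_align, "sigma_align")
  check_positive_scalar(sigma_curv, "sigma_curv")
  check_positive_scalar(lambda_radial, "lambda_radial")
  structure(
    list(sigma_align = sigma_align, sigma_curv = sigma_curv,
         lambda_radial = lambda_radial),
    class = "af_params"
  )
}

#' @export
print.af_params <- function(x, ...) {
  cat(sprintf(
    "<af_params> sigma_align = %.4g rad, sigma_curv = %.4g rad, lambda_radial = %.4g DVA\n",
    x$sigma_align, x$sigma_curv, x$lambda_radial))
  invisible(x)
}

#' @export
format.af_params <- function(x, ...) {
  sprintf("s1=%.3g,s2=%.3g,lam=%.3g", x$sigma_align, x$sigma_curv, x$lambda_radial)
}

#' Eccentricity-dependent edge salience parameters
#'
#' Edge salience `w` scales the evidence an edge contributes to contour
#' inference and falls off with eccentricity `eps` (distance from fixation)
#' as `w(eps) = 1 - amplitude * (eps / eps_max)^exponent`. `amplitude = 0`
#' gives constant salience and reduces the weighted observer to the unweighted
#' one; `exponent` controls the concavity of the fall-off.
#'
#' @param amplitude Salience loss at maximum eccentricity, in `[0, 1)`.
#' @param exponent Concavity exponent, > 0.
#' @param eps_max Maximum eccentricity of the display, DVA. Default 16.66.
#' @return An object of class `ecc_params`.
#' @examples
#' ecc_params(0.5, 2)
#' @export
ecc_params <- function(amplitude = 0, exponent = 1, eps_max = 16.66) {
  if (!is.numeric(amplitude) || length(amplitude) != 1L ||
      amplitude < 0 || amplitude >= 1) {
    abort("`amplitude` must be a single value in [0, 1).",
          class = "afield_parameter_error")
  }
  check_positive_scalar(exponent, "exponent")
  check_positive_scalar(eps_max, "eps_max")
  structure(
    list(amplitude = amplitude, exponent = exponent, eps_max = eps_max),
    class = "ecc_params"
  )
}

#' @export
print.ecc_params <- function(x, ...) {
  cat(sprintf("<ecc_params> amplitude = %.4g, exponent = %.4g, eps_max = %.4g DVA\n",
              x$amplitude, x$exponent, x$eps_max))
  invisible(x)
}

#' Serialize / deserialize association-field parameters
#'
#' `af_to_list()` and `af_from_list()` convert between `af_params` and the
#' plain list stored under the `"af"` key of JSON configuration files
#' (`{"sigma_align": rad, "sigma_curv": rad, "lambda_radial": dva}`).
#'
#' @param params An `af_params` object.
#' @param x A named list with entries `sigma_align`, `sigma_curv`,
#'   `lambda_radial`.
#' @return A plain named list, or an `af_params` object.
#' @export
af_to_list <- function(params) {
  stopifnot(inherits(params, "af_params"))
  unclass(params)
}

#' @rdname af_to_list
#' @export
af_from_list <- function(x) {
  af_params(x$sigma_align, x$sigma_curv,
            if (is.null(x$lambda_radial)) 10 else x$lambda_radial)
}
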