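# Pair geometry and the association-field density.
#
# An edge is a row (x, y, theta): position in degrees of visual angle
# (screen-centred, +x rightward, +y upward) and a full-circle direction in
# [0, 2*pi). A pair of edges reduces, by translation and rotation symmetry,
# to three relative coordinates:
#   d      Euclidean distance,
#   phi    viewing angle: the angle under which an observer sitting on the
#          source edge and looking along its direction sees the target,
#   dtheta direction difference theta_target - theta_source.
# Both angles are wrapped to (-pi, pi].

#' Construct an edge table
#'
#' Convenience constructor for tables of oriented edge elements. Directions
#' are wrapped to `[0, 2*pi)`.
#'
#' @param x,y Positions in degrees of visual angle (DVA), screen-centred.
#' @param theta Directions in radians.
#' @return A tibble with columns `x`, `y`, `theta`.
#' @examples
#' edge_tbl(c(0, 2), c(0, 0), c(0, pi / 4))
#' @export
edge_tbl <- function(x, y, theta) {
  tibble(x = as.numeric(x), y = as.numeric(y), theta = wrap_2pi(as.numeric(theta)))
}

#' Relative coordinates of an edge pair
#'
#' Reduces ordered edge pairs to the three pair coordinates `(d, phi, dtheta)`
#' that the association field depends on. Rows of `source` and `target` are
#' matched (and recycled if one has a single row).
#'
#' @param source,target Data frames with columns `x`, `y`, `theta` (see
#'   [edge_tbl()]).
#' @return A tibble with columns `d` (DVA), `phi` and `dtheta` (radians in
#'   `(-pi, pi]`).
#' @examples
#' relative_coordinates(edge_tbl(0, 0, 0), edge_tbl(2, 0, 0))
#' @export
relative_coordinates <- function(source, target) {
  n <- max(nrow(source), nrow(target))
  rec <- function(v) if (length(v) == 1L) rep(v, n) else v
  xs <- rec(source$x); ys <- rec(source$y); ts <- rec(source$theta)
  xt <- rec(target$x); yt <- rec(target$y); tt <- rec(target$theta)
  dx <- xt - xs
  dy <- yt - ys
  d <- sqrt(dx^2 + dy^2)
  if (any(d < 1e-12)) {
    abort("Coincident edge positions: the viewing angle is undefined at d = 0.",
          class = "afield_degenerate_geometry")
  }
  beta <- atan2(dy, dx)
  tibble(d = d, phi = wrap_pi(beta - ts), dtheta = wrap_pi(tt - ts))
}

#' Angular part of the association field
#'
#' Joint density over `(phi, dtheta)` of the next edge's viewing angle and
#' direction difference, as a product of two von Mises factors:
#' one concentrating the placement around the co-circular configuration
#' `dtheta = 2 * phi` (deviation measured at direction scale `sigma_align`,
#' i.e. angular scale `sigma_align / 2` in `phi`), and one concentrating the
#' direction difference `dtheta` around zero at scale `sigma_curv`. The
#' density is single-moded and forward: placing the next element *behind* the
#' current one (`phi` near `pi`) is strongly suppressed, which keeps the
#' creation process from turning around by 180 degrees. It integrates to 1
#' over `(phi, dtheta) in (-pi, pi]^2`.
#'
#' @param phi Viewing angles, radians.
#' @param dtheta Direction differences, radians.
#' @param params An [af_params()] object.
#' @return Density values over `(phi, dtheta)`.
#' @export
af_angular_density <- function(phi, dtheta, params) {
  stopifnot(inherits(params, "af_params"))
  von_mises_density(wrap_pi(phi - dtheta / 2), 0, params$sigma_align / 2) *
    von_mises_density(dtheta, 0, params$sigma_curv)
}

#' Radial part of the association field
#'
#' Exponentially decaying density in pair distance, truncated to
#' `[0, d_max]`: `R(d) = exp(-d / lambda) / Z_R` with
#' `Z_R = lambda * (1 - exp(-d_max / lambda))`. With the default
#' `d_max = Inf`, `Z_R = lambda`.
#'
#' @param d Pair distances, DVA.
#' @param params An [af_params()] object.
#' @param d_max Truncation distance (e.g. the field diagonal); `Inf` for the
#'   untruncated density.
#' @return Density values in `d`.
#' @export
af_radial_density <- function(d, params, d_max = Inf) {
  stopifnot(inherits(params, "af_params"))
  lam <- params$lambda_radial
  z <- lam * (1 - exp(-d_max / lam))
  out <- exp(-d / lam) / z
  out[d < 0 | d > d_max] <- 0
  out
}

#' Association-field density of ordered edge pairs
#'
#' The full link density `R(d) * A(phi, dtheta)`: the probability density that
#' a contour passing through the source edge continues through the target
#' edge. It is invariant under joint translation and rotation of the pair and
#' under reversal (flipping both directions by `pi` and swapping the roles of
#' source and target).
#'
#' @inheritParams relative_coordinates
#' @inheritParams af_radial_density
#' @return A numeric vector of density values, one per pair.
#' @examples
#' p <- af_params(0.2, 0.4, lambda_radial = 2)
#' af_density(edge_tbl(0, 0, 0), edge_tbl(1.5, 0, 0), p)
#' @export
af_density <- function(source, target, params, d_max = Inf) {
  rc <- relative_coordinates(source, target)
  af_radial_density(rc$d, params, d_max) *
    af_angular_density(rc$phi, rc$dtheta, params)
}

#' Reverse edges
#'
#' Flips edge directions by `pi` (traversing the same elements the other way).
#'
#' @param edges A data frame with columns `x`, `y`, `theta`.
#' @return The edges with reversed directions.
#' @export
reverse_edges <- function(edges) {
  mutate(edges, theta = wrap_2pi(.data$theta + pi))
}

# Sample (d, phi, dtheta) transitions exactly from the AF density:
# d by inverse-CDF of the truncated exponential, dtheta from its von Mises
# factor, and phi = dtheta/2 + deviation with the deviation von Mises at
# scale sigma_align / 2.
sample_af_transition <- function(n, params, d_max = Inf) {
  lam <- params$lambda_radial
  u <- runif(n)
  cap <- 1 - exp(-d_max / lam)
  d <- -lam * log(1 - u * cap)
  dtheta <- rvon_mises(n, 0, params$sigma_curv)
  dev <- rvon_mises(n, 0, params$sigma_align / 2)
  tibble(d = d, phi = wrap_pi(dtheta / 2 + dev), dtheta = dtheta)
}
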