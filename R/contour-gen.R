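# Markov contour generation. A contour of length L is a directed sequence of
# edges: the first edge is placed uniformly in the region with a uniform
# direction, and each subsequent edge is drawn from the association field
# conditioned on its predecessor.

#' Sample a contour from the association-field Markov process
#'
#' @param L Number of edges, >= 2.
#' @param params An [af_params()] object: the generating association field.
#' @param region Numeric vector `c(xmin, xmax, ymin, ymax)` in DVA; every edge
#'   of the contour must fall inside it. Steps leaving the region are
#'   resampled (not reflected) so the angular statistics of accepted steps are
#'   unbiased.
#' @param seed Optional integer seed for reproducibility; `NULL` uses the
#'   current RNG state.
#' @param max_tries Resampling budget per edge before a sampling-failure error
#'   is raised.
#' @return A tibble of `L` edges with columns `x`, `y`, `theta`, in contour
#'   order.
#' @examples
#' sample_contour(5, af_params(0.2, 0.3, 2), c(-8, 8, -8, 8), seed = 1)
#' @export
sample_contour <- function(L, params, region, seed = NULL, max_tries = 1e5) {
  stopifnot(inherits(params, "af_params"))
  if (!is.numeric(L) || length(L) != 1L || L < 2) {
    abort("`L` must be a single integer >= 2.", class = "afield_parameter_error")
  }
  check_region(region)
  if (!is.null(seed)) withr::local_seed(seed)
  d_max <- region_diagonal(region)
  batch <- 32L
  # A contour that wanders into a corner facing outward can make any further
  # step nearly impossible; rather than forcing degenerate tiny steps, the
  # whole contour is restarted when one edge's proposal budget runs out.
  per_edge_budget <- max(batch, min(max_tries, 2048L))
  total <- 0L
  repeat {
    x <- numeric(L); y <- numeric(L); th <- numeric(L)
    x[1] <- runif(1, region[1], region[2])
    y[1] <- runif(1, region[3], region[4])
    th[1] <- runif(1, 0, 2 * pi)
    stuck <- FALSE
    for (i in 2:L) {
      tries <- 0L
      repeat {
        tr <- sample_af_transition(batch, params, d_max)
        nx <- x[i - 1] + tr$d * cos(th[i - 1] + tr$phi)
        ny <- y[i - 1] + tr$d * sin(th[i - 1] + tr$phi)
        ok <- which(nx >= region[1] & nx <= region[2] &
                      ny >= region[3] & ny <= region[4])
        if (length(ok) > 0L) {
          j <- ok[1]
          x[i] <- nx[j]; y[i] <- ny[j]
          th[i] <- wrap_2pi(th[i - 1] + tr$dtheta[j])
          break
        }
        tries <- tries + batch
        total <- total + batch
        if (total >= max_tries) {
          abort(sprintf("Contour sampling failed: %d proposals rejected.", total),
                class = "afield_sampling_failure")
        }
        if (tries >= per_edge_budget) {
          stuck <- TRUE
          break
        }
      }
      if (stuck) break
    }
    if (!stuck) return(edge_tbl(x, y, th))
  }
}

# Relative steps of a contour: one (d, phi, dtheta) triple per transition.
contour_steps <- function(contour) {
  n <- nrow(contour)
  relative_coordinates(contour[-n, , drop = FALSE], contour[-1, , drop = FALSE])
}

# Rebuild contour coordinates from a starting edge and relative steps;
# plain-vector core so permutation searches stay cheap.
rebuild_xyt <- function(x0, y0, th0, d, phi, dtheta) {
  L <- length(d) + 1L
  x <- numeric(L); y <- numeric(L); th <- numeric(L)
  x[1] <- x0; y[1] <- y0; th[1] <- th0
  for (i in seq_along(d)) {
    x[i + 1] <- x[i] + d[i] * cos(th[i] + phi[i])
    y[i + 1] <- y[i] + d[i] * sin(th[i] + phi[i])
    th[i + 1] <- th[i] + dtheta[i]
  }
  list(x = x, y = y, theta = wrap_2pi(th))
}

rebuild_contour <- function(start, steps) {
  p <- rebuild_xyt(start$x[1], start$y[1], start$theta[1],
                   steps$d, steps$phi, steps$dtheta)
  edge_tbl(p$x, p$y, p$theta)
}

# Overlap test on plain coordinates: TRUE if any non-consecutive pair is
# closer than min_sep.
xy_overlap <- function(x, y, min_sep) {
  n <- length(x)
  if (n < 3L) return(FALSE)
  dm <- outer(x, x, "-")^2 + outer(y, y, "-")^2
  dm[abs(row(dm) - col(dm)) <= 1] <- Inf
  any(dm < min_sep^2)
}

# TRUE if some non-consecutive pair of contour edges is closer than min_sep.
has_overlap <- function(contour, min_separation) {
  xy_overlap(contour$x, contour$y, min_separation)
}

#' Repair rendering overlaps by permuting relative steps
#'
#' Strongly curved contours can fold back so that two non-consecutive edges
#' would overlap when rendered as finite-width Gabor patches. Rather than
#' rejecting such contours (which would bias the ensemble statistics), the
#' sequence of relative steps `(d, phi, dtheta)` is randomly permuted and the
#' contour rebuilt from the same starting edge until no non-consecutive pair
#' is closer than `min_separation`. The multiset of consecutive-pair
#' configurations -- and hence the pairwise edge statistics of the ensemble --
#' is preserved exactly.
#'
#' @param contour A contour tibble (ordered edges `x`, `y`, `theta`).
#' @param min_separation Minimum allowed distance between non-consecutive
#'   edges, DVA (typically the rendered Gabor envelope diameter).
#' @param seed Optional integer seed.
#' @param region Optional `c(xmin, xmax, ymin, ymax)`; when given, repaired
#'   contours must also stay inside it.
#' @param max_permutations Budget before a repair-failure error is raised.
#' @return A contour tibble with all non-consecutive pairwise distances
#'   `>= min_separation`; the input is returned unchanged when it already
#'   satisfies the constraint.
#' @export
repair_overlaps <- function(contour, min_separation, seed = NULL, region = NULL,
                            max_permutations = 2000L) {
  in_region <- function(ct) {
    is.null(region) ||
      all(ct$x >= region[1] & ct$x <= region[2] &
            ct$y >= region[3] & ct$y <= region[4])
  }
  if (!has_overlap(contour, min_separation) && in_region(contour)) return(contour)
  if (!is.null(seed)) withr::local_seed(seed)
  steps <- contour_steps(contour)
  x0 <- contour$x[1]; y0 <- contour$y[1]; th0 <- contour$theta[1]
  for (k in seq_len(max_permutations)) {
    o <- sample.int(nrow(steps))
    p <- rebuild_xyt(x0, y0, th0, steps$d[o], steps$phi[o], steps$dtheta[o])
    ok_region <- is.null(region) ||
      (min(p$x) >= region[1] && max(p$x) <= region[2] &&
         min(p$y) >= region[3] && max(p$y) <= region[4])
    if (ok_region && !xy_overlap(p$x, p$y, min_separation)) {
      return(edge_tbl(p$x, p$y, p$theta))
    }
  }
  abort(sprintf("Overlap repair failed after %d permutations.", max_permutations),
        class = "afield_repair_failure")
}

check_region <- function(region) {
  if (!is.numeric(region) || length(region) != 4L ||
      region[2] <= region[1] || region[4] <= region[3]) {
    abort("`region` must be c(xmin, xmax, ymin, ymax) with positive extent.",
          class = "afield_parameter_error")
  }
  invisible(region)
}

region_diagonal <- function(region) {
  sqrt((region[2] - region[1])^2 + (region[4] - region[3])^2)
}
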