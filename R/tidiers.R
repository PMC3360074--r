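# broom-style tidiers for the package's result objects.

#' Tidy a grid-search result
#'
#' @param x An `af_grid_search` object.
#' @param ... Unused.
#' @return The candidate map: one row per parameter combination with
#'   `phi_mh`, `p_perf`, `admissible`.
#' @export
tidy.af_grid_search <- function(x, ...) {
  x$map
}

#' @rdname tidy.af_grid_search
#' @export
glance.af_grid_search <- function(x, ...) {
  b <- x$best
  tibble(
    sigma_align = b$sigma_align, sigma_curv = b$sigma_curv,
    amplitude = b$amplitude, gamma = b$gamma,
    phi_mh = b$phi_mh, p_perf = b$p_perf,
    n_candidates = nrow(x$map),
    n_admissible = sum(x$map$admissible),
    inadmissible_best = x$inadmissible_best
  )
}

#' Tidy an excess-correlation result
#'
#' @param x An `af_phi` object.
#' @param ... Unused.
#' @return The per-pair table (`observer_a`, `observer_b`, `phi`).
#' @export
tidy.af_phi <- function(x, ...) {
  x$pairs
}

#' @rdname tidy.af_phi
#' @export
glance.af_phi <- function(x, ...) {
  tibble(phi = x$phi, n_pairs = nrow(x$pairs),
         n_conditions = n_distinct(
           x$conditions %>% select(-dplyr::any_of(c("observer_a", "observer_b",
                                                    "S", "k", "n_a", "n_b",
                                                    "phi")))),
         kind = x$kind)
}

#' Pair matrix of excess correlations
#'
#' Arranges the per-pair `Phi` values of an `af_phi` object as a symmetric
#' observer-by-observer matrix (diagonal `NA`).
#'
#' @param x An `af_phi` object.
#' @return A symmetric numeric matrix.
#' @export
phi_pair_matrix <- function(x) {
  stopifnot(inherits(x, "af_phi"))
  ids <- sort(unique(c(x$pairs$observer_a, x$pairs$observer_b)))
  m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  for (r in seq_len(nrow(x$pairs))) {
    a <- x$pairs$observer_a[r]; b <- x$pairs$observer_b[r]
    m[a, b] <- m[b, a] <- x$pairs$phi[r]
  }
  m
}

#' Tidy a null pmf
#'
#' @param x An `af_null_pmf` object.
#' @param ... Unused.
#' @return A tibble with columns `k` and `prob`.
#' @export
tidy.af_null_pmf <- function(x, ...) {
  tibble(k = x$k, prob = x$prob)
}
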