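# Four-parameter model search. Candidate observers vary the two angular
# scales of the association field and the two eccentricity-scaling parameters
# (amplitude, exponent). Every candidate is run over the same stimuli, and
# both criteria -- the performance score against the reference observers and
# the model-human excess correlation -- are computed from the same decision
# pass. Candidates whose performance falls short of the reference are
# excluded; among the admissible ones the candidate with the largest excess
# correlation wins.

#' Candidate grid for the model search
#'
#' @param sigma_align,sigma_curv Candidate angular scales, radians.
#' @param amplitude,gamma Candidate eccentricity-scaling parameters.
#' @param lambda_radial Radial scale shared by all candidates, DVA, or
#'   `NULL` to use each ensemble's spacing (the generating radial scale).
#' @param eps_max Maximum eccentricity for the salience weights, DVA.
#' @return A list of class `af_search_grid`; the candidate table has one row
#'   per parameter combination.
#' @export
search_grid <- function(sigma_align, sigma_curv, amplitude = 0, gamma = 1,
                        lambda_radial = NULL, eps_max = 16.66) {
  candidates <- tidyr::expand_grid(
    sigma_align = sigma_align, sigma_curv = sigma_curv,
    amplitude = amplitude, gamma = gamma
  ) %>%
    mutate(candidate = row_number())
  structure(list(candidates = candidates, lambda_radial = lambda_radial,
                 eps_max = eps_max),
            class = "af_search_grid")
}

#' Grid search for the observer model that best explains reference decisions
#'
#' For every candidate parameter combination, simulates the (noise-free)
#' observer over all stimuli at full iteration depth, then scores it against
#' the reference decisions on both criteria: the performance score `P`
#' (fraction of conditions where the model reaches mean reference
#' performance) and the excess correlation `Phi_MH`. Candidates with
#' `P < perf_cutoff` are inadmissible (the reference out-detects them too
#' often); among admissible candidates the one maximizing `Phi_MH` is
#' returned. Both maps come from a single decision pass per candidate.
#'
#' @param grid An [search_grid()].
#' @param stimuli Stimulus tibble covering the reference decisions.
#' @param reference Decision table of the reference observers.
#' @param specs Ensemble specification tibble (`ensemble_id`, `L`, `spacing`);
#'   defaults to the `"ensemble_spec"` attributes when `stimuli` came from a
#'   single ensemble.
#' @param perf_cutoff Admissibility threshold on the performance score.
#' @param seed Optional seed (tie-breaking only).
#' @return An object of class `af_grid_search` with elements `map` (candidate
#'   tibble with `phi_mh`, `p_perf`, `admissible`), `best` (one-row tibble),
#'   and `inadmissible_best` (flag: `TRUE` when no candidate was admissible
#'   and the best is reported regardless).
#' @export
grid_search <- function(grid, stimuli, reference, specs = NULL,
                        perf_cutoff = 0.5, seed = NULL) {
  stopifnot(inherits(grid, "af_search_grid"))
  check_decision_table(reference, "`reference`")
  if (!is.null(seed)) withr::local_seed(seed)
  if (is.null(specs)) {
    sp <- attr(stimuli, "ensemble_spec")
    specs <- tibble(ensemble_id = sp$ensemble_id, L = sp$L, spacing = sp$spacing)
  }
  Lmap <- stats::setNames(as.integer(specs$L), specs$ensemble_id)
  lam_map <- if (is.null(grid$lambda_radial)) {
    stats::setNames(specs$spacing, specs$ensemble_id)
  } else {
    stats::setNames(rep(grid$lambda_radial, nrow(specs)), specs$ensemble_id)
  }
  geos <- stimulus_geometries(stimuli)
  cand <- grid$candidates
  res <- purrr::pmap(cand, function(sigma_align, sigma_curv, amplitude, gamma,
                                    candidate) {
    ecc <- ecc_params(amplitude, gamma, eps_max = grid$eps_max)
    rows <- purrr::map(geos, function(g) {
      L <- Lmap[[g$ensemble_id]]
      af <- af_params(sigma_align, sigma_curv, lam_map[[g$ensemble_id]])
      bl <- hemifield_likelihood(NULL, af, ecc, L, L - 1L, geo = g$left)
      br <- hemifield_likelihood(NULL, af, ecc, L, L - 1L, geo = g$right)
      resp <- if (bl > br) "left" else if (br > bl) "right"
      else sample(c("left", "right"), 1L)
      tibble(observer_id = sprintf("cand%03d", candidate),
             ensemble_id = g$ensemble_id, stimulus_id = g$stimulus_id,
             soa = NA_real_, response = resp,
             correct = as.integer(resp == g$target_side))
    }) %>% bind_rows()
    tibble(candidate = candidate,
           phi_mh = phi_model_human(rows, reference)$phi,
           p_perf = performance_score(rows, reference))
  }) %>% bind_rows()
  map <- left_join(cand, res, by = "candidate") %>%
    mutate(admissible = .data$p_perf >= perf_cutoff)
  adm <- map %>% filter(.data$admissible)
  inadmissible_best <- nrow(adm) == 0L
  pool <- if (inadmissible_best) map else adm
  best <- pool %>% arrange(dplyr::desc(.data$phi_mh)) %>% head(1L)
  structure(list(map = map, best = best,
                 inadmissible_best = inadmissible_best,
                 perf_cutoff = perf_cutoff, grid = grid),
            class = "af_grid_search")
}

#' @export
print.af_grid_search <- function(x, ...) {
  b <- x$best
  cat(sprintf(
    "<af_grid_search> %d candidates; best%s: sigma_align = %.3g, sigma_curv = %.3g, a = %.3g, gamma = %.3g (Phi_MH = %.4f, P = %.3f)\n",
    nrow(x$map), if (x$inadmissible_best) " (inadmissible!)" else "",
    b$sigma_align, b$sigma_curv, b$amplitude, b$gamma, b$phi_mh, b$p_perf))
  invisible(x)
}
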