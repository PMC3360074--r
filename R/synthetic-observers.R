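# Synthetic 2-AFC observers. They stand in for a panel of human subjects:
# every observer shares the stimulus-dependent difficulty structure of a
# common base model (which stimuli are hard is a property of the stimulus),
# while decision noise is independent across observers. That combination is
# exactly what produces excess correlations above the independence null.

#' Synthetic observer panel specification
#'
#' @param af Base model association field ([af_params()]).
#' @param ecc Base model eccentricity scaling ([ecc_params()]).
#' @param eta Lapse rate(s) in `[0, 0.5]`: each observer's base-model response
#'   is flipped independently with probability `eta`. A scalar is recycled;
#'   `eta = 0.5` yields pure noise.
#' @param n_observers Number of observers.
#' @param shared_difficulty If `TRUE` (default) all observers share the base
#'   model's per-stimulus decisions; if `FALSE`, each observer's responses
#'   are drawn independently with the same marginal accuracy, which removes
#'   all stimulus-locked correlation.
#' @param mode `"flip"` for symmetric lapse noise; `"softmax"` for graded
#'   difficulty sensitivity, where the response is drawn with probability
#'   `plogis(beta * log(B_left / B_right))` of "left".
#' @param beta Inverse temperature of the softmax mode.
#' @return An object of class `synthetic_observer_spec`.
#' @export
synthetic_observer_spec <- function(af, ecc = ecc_params(0, 1), eta = 0.15,
                                    n_observers = 5L, shared_difficulty = TRUE,
                                    mode = c("flip", "softmax"), beta = 1) {
  stopifnot(inherits(af, "af_params"), inherits(ecc, "ecc_params"))
  mode <- match.arg(mode)
  if (any(eta < 0 | eta > 0.5)) {
    abort("`eta` must lie in [0, 0.5].", class = "afield_parameter_error")
  }
  eta <- rep_len(eta, n_observers)
  structure(list(af = af, ecc = ecc, eta = eta,
                 n_observers = as.integer(n_observers),
                 shared_difficulty = shared_difficulty,
                 mode = mode, beta = beta),
            class = "synthetic_observer_spec")
}

#' Simulate a panel of noisy observers
#'
#' Runs the base model once over the stimuli and derives each observer's
#' responses from it: with `mode = "flip"`, the base response is inverted
#' independently with the observer's lapse rate; with `mode = "softmax"`,
#' responses are drawn from a logistic function of the log likelihood ratio.
#'
#' @param stimuli A stimulus tibble.
#' @param spec A [synthetic_observer_spec()].
#' @param specs Optional ensemble specification tibble (`ensemble_id`, `L`).
#' @param soa Value recorded in the `soa` column.
#' @param seed Optional seed.
#' @return A decision table with observers `obs01`, `obs02`, ...
#' @export
simulate_observers <- function(stimuli, spec, specs = NULL, soa = NA_real_,
                               seed = NULL) {
  stopifnot(inherits(spec, "synthetic_observer_spec"))
  if (!is.null(seed)) withr::local_seed(seed)
  Lmap <- ensemble_L_map(stimuli, specs)
  geos <- stimulus_geometries(stimuli)
  base <- purrr::map(geos, function(g) {
    L <- Lmap[[g$ensemble_id]]
    bl <- hemifield_likelihood(NULL, spec$af, spec$ecc, L, L - 1L, geo = g$left)
    br <- hemifield_likelihood(NULL, spec$af, spec$ecc, L, L - 1L, geo = g$right)
    tibble(ensemble_id = g$ensemble_id, stimulus_id = g$stimulus_id,
           target_side = g$target_side, lik_left = bl, lik_right = br)
  }) %>% bind_rows()
  base <- base %>%
    mutate(base_response = ifelse(.data$lik_left > .data$lik_right, "left",
                                  ifelse(.data$lik_right > .data$lik_left,
                                         "right",
                                         sample(c("left", "right"), dplyr::n(),
                                                replace = TRUE))))
  flip <- function(r) ifelse(r == "left", "right", "left")
  out <- purrr::map(seq_len(spec$n_observers), function(m) {
    n <- nrow(base)
    if (spec$mode == "softmax") {
      p_left <- stats::plogis(spec$beta * log(base$lik_left / base$lik_right))
      resp <- ifelse(runif(n) < p_left, "left", "right")
      # lapse still applies on top of the graded draw
      do_flip <- runif(n) < spec$eta[m]
      resp[do_flip] <- flip(resp[do_flip])
    } else if (spec$shared_difficulty) {
      do_flip <- runif(n) < spec$eta[m]
      resp <- ifelse(do_flip, flip(base$base_response), base$base_response)
    } else {
      # independent observers with the same marginal accuracy
      acc <- mean(base$base_response == base$target_side) * (1 - 2 * spec$eta[m]) +
        spec$eta[m]
      hit <- runif(n) < acc
      resp <- ifelse(hit, base$target_side, flip(base$target_side))
    }
    tibble(observer_id = sprintf("obs%02d", m),
           ensemble_id = base$ensemble_id,
           stimulus_id = base$stimulus_id,
           soa = soa, response = resp,
           correct = as.integer(resp == base$target_side))
  })
  bind_rows(out)
}

#' Read and write decision tables
#'
#' Round-trips the CSV schema `observer_id, ensemble_id, stimulus_id, soa,
#' response, correct`. Reading validates the schema and the invariant that
#' every observer saw the same stimulus set within each condition, and that
#' `correct` is consistent across observers given the responses.
#'
#' @param tbl A decision table.
#' @param path File path.
#' @return `read_decision_table()` returns the validated tibble;
#'   `write_decision_table()` returns `path` invisibly.
#' @export
write_decision_table <- function(tbl, path) {
  check_decision_table(tbl)
  readr::write_csv(tbl, path)
  invisible(path)
}

#' @rdname write_decision_table
#' @export
read_decision_table <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("observer_id", "ensemble_id", "stimulus_id", "response", "correct")
  miss <- setdiff(need, names(tbl))
  if (length(miss)) {
    abort(sprintf("Decision table at '%s' is missing column(s): %s.",
                  path, paste(miss, collapse = ", ")),
          class = "afield_schema_error")
  }
  bad <- which(!tbl$response %in% c("left", "right"))
  if (length(bad)) {
    abort(sprintf("Invalid `response` at row %d of '%s' (must be left/right).",
                  bad[1], path),
          class = "afield_schema_error")
  }
  if (!all(tbl$correct %in% c(0L, 1L))) {
    abort(sprintf("`correct` must be 0/1 in '%s'.", path),
          class = "afield_schema_error")
  }
  tbl$correct <- as.integer(tbl$correct)
  if ("soa" %in% names(tbl)) tbl$soa <- as.numeric(tbl$soa)
  cv <- condition_vars(tbl)
  sets <- tbl %>%
    group_by(dplyr::across(dplyr::all_of(c(cv, "observer_id")))) %>%
    summarise(set = paste(sort(.data$stimulus_id), collapse = "|"),
              .groups = "drop") %>%
    group_by(dplyr::across(dplyr::all_of(cv))) %>%
    summarise(n_sets = n_distinct(.data$set), .groups = "drop")
  if (any(sets$n_sets > 1L)) {
    abort(sprintf("Observers saw different stimulus sets within a condition in '%s'.",
                  path),
          class = "afield_invariant_error")
  }
  # implied target side must agree across observers for each stimulus
  tg <- tbl %>%
    mutate(target = ifelse(.data$correct == 1L, .data$response,
                           ifelse(.data$response == "left", "right", "left"))) %>%
    group_by(dplyr::across(dplyr::all_of(c(cv, "stimulus_id")))) %>%
    summarise(n_targets = n_distinct(.data$target), .groups = "drop")
  if (any(tg$n_targets > 1L)) {
    abort(sprintf("`correct` is inconsistent with a unique target side in '%s'.",
                  path),
          class = "afield_invariant_error")
  }
  tbl
}
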