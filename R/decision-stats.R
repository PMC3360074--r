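# Decision statistics. A decision table has one row per (observer, stimulus)
# with columns observer_id, ensemble_id, stimulus_id, soa, response
# ("left"/"right"), correct (0/1). A "condition" is an (ensemble_id, soa)
# block; all observers must share the same stimulus set within a condition.
#
# The excess-correlation statistic Phi asks whether two observers give the
# same response on the same stimuli more often than expected if each made
# errors independently of the particular stimulus. Under that independence
# null, the number m of stimuli both answer correctly is hypergeometric (n_b
# correct stimuli drawn uniformly among S, overlapping the n_a of the other
# observer), and because a 2-AFC response is identical exactly when both are
# correct or both are wrong, the identical-response count is
# k = S - n_a - n_b + 2 m. Phi is the mid-p probability that a draw from this
# null is below the observed k; its null expectation is exactly 1/2.

condition_vars <- function(tbl) {
  v <- c("ensemble_id")
  if ("soa" %in% names(tbl) && any(!is.na(tbl$soa))) v <- c(v, "soa")
  v
}

check_decision_table <- function(tbl, what = "decision table") {
  need <- c("observer_id", "ensemble_id", "stimulus_id", "response", "correct")
  miss <- setdiff(need, names(tbl))
  if (length(miss)) {
    abort(sprintf("%s is missing column(s): %s.", what,
                  paste(miss, collapse = ", ")),
          class = "afield_schema_error")
  }
  if (!all(tbl$response %in% c("left", "right"))) {
    abort(sprintf("%s: `response` must be 'left' or 'right'.", what),
          class = "afield_schema_error")
  }
  invisible(tbl)
}

align_pair <- function(a, b) {
  cv <- intersect(condition_vars(a), condition_vars(b))
  key <- c(cv, "stimulus_id")
  ja <- a %>% select(dplyr::all_of(c(key, "response", "correct")))
  jb <- b %>% select(dplyr::all_of(c(key, "response", "correct")))
  j <- inner_join(ja, jb, by = key, suffix = c("_a", "_b"))
  if (nrow(j) != nrow(ja) || nrow(j) != nrow(jb)) {
    abort("Observers do not share the same stimulus set within conditions.",
          class = "afield_alignment_error")
  }
  list(joined = j, condition_vars = cv)
}

#' Performance score of a model against human observers
#'
#' The fraction of stimulus conditions in which the model detects at least as
#' many contours as the human observers do on average (ties count as
#' reaching: the Heaviside step is 1 at 0).
#'
#' @param model Decision table of a single model observer.
#' @param humans Decision table of one or more reference observers.
#' @return A fraction in `[0, 1]`.
#' @export
performance_score <- function(model, humans) {
  check_decision_table(model, "`model`")
  check_decision_table(humans, "`humans`")
  cv <- condition_vars(humans)
  hm <- humans %>%
    group_by(dplyr::across(dplyr::all_of(c(cv, "observer_id")))) %>%
    summarise(n_correct = sum(.data$correct), .groups = "drop") %>%
    group_by(dplyr::across(dplyr::all_of(cv))) %>%
    summarise(human_mean = mean(.data$n_correct), .groups = "drop")
  mm <- model %>%
    group_by(dplyr::across(dplyr::all_of(cv))) %>%
    summarise(model_n = sum(.data$correct), .groups = "drop")
  j <- inner_join(mm, hm, by = cv)
  if (nrow(j) != nrow(hm) || nrow(j) != nrow(mm)) {
    abort("Model and human tables do not cover the same conditions.",
          class = "afield_alignment_error")
  }
  mean(j$model_n >= j$human_mean)
}

#' Identical responses of two observers
#'
#' Counts, per condition, the stimuli on which two observers gave the same
#' response.
#'
#' @param a,b Decision tables of single observers over the same stimuli.
#' @return A tibble with the condition columns plus `S` (stimuli per
#'   condition), `k` (identical responses), `n_a`, `n_b` (correct counts).
#' @export
identical_responses <- function(a, b) {
  al <- align_pair(a, b)
  al$joined %>%
    group_by(dplyr::across(dplyr::all_of(al$condition_vars))) %>%
    summarise(S = dplyr::n(),
              k = sum(.data$response_a == .data$response_b),
              n_a = sum(.data$correct_a),
              n_b = sum(.data$correct_b),
              .groups = "drop")
}

#' Null distribution of the identical-response count
#'
#' Exact pmf of the number `k` of identical 2-AFC responses of two observers
#' with fixed correct counts `n_a` and `n_b` over `S` shared stimuli, under
#' the assumption that errors fall on stimuli uniformly at random. The
#' both-correct overlap `m` is hypergeometric and `k = S - n_a - n_b + 2 m`,
#' so the support satisfies `k = S - n_a - n_b (mod 2)`.
#'
#' @param S Number of stimuli in the condition.
#' @param n_a,n_b Correct counts of the two observers, each in `[0, S]`.
#' @return A tibble of class `af_null_pmf` with columns `k`, `prob`.
#' @examples
#' null_pmf(4, 3, 2)
#' @export
null_pmf <- function(S, n_a, n_b) {
  if (n_a < 0 || n_a > S || n_b < 0 || n_b > S) {
    abort("Need 0 <= n_a, n_b <= S.", class = "afield_parameter_error")
  }
  m <- max(0L, n_a + n_b - S):min(n_a, n_b)
  out <- tibble(k = S - n_a - n_b + 2L * m,
                prob = dhyper(m, n_a, S - n_a, n_b))
  attr(out, "S") <- S
  attr(out, "n_a") <- n_a
  attr(out, "n_b") <- n_b
  class(out) <- c("af_null_pmf", class(out))
  out
}

#' Mid-p excess-correlation statistic for one observer pair
#'
#' `Phi = P(k' < k_obs) + 0.5 * P(k' = k_obs)` under the identical-response
#' null. The continuity (mid-p) correction makes the null expectation of
#' `Phi` exactly 0.5 for any `(S, n_a, n_b)`; values above 0.5 indicate more
#' identical responses than independent stimulus-blind errors can produce.
#'
#' @param k_observed Observed identical-response count.
#' @param null An `af_null_pmf` from [null_pmf()].
#' @return `Phi` in `[0, 1]`.
#' @examples
#' phi_pair(3, null_pmf(4, 3, 2))
#' @export
phi_pair <- function(k_observed, null) {
  stopifnot(inherits(null, "af_null_pmf"))
  kr <- range(null$k)
  if (k_observed < kr[1] || k_observed > kr[2]) {
    warn(sprintf("k_observed = %d outside null support [%d, %d]; clamped.",
                 k_observed, kr[1], kr[2]))
    k_observed <- min(max(k_observed, kr[1]), kr[2])
  }
  sum(null$prob[null$k < k_observed]) +
    0.5 * sum(null$prob[null$k == k_observed])
}

# Phi per condition for an aligned observer pair.
phi_conditions <- function(a, b) {
  identical_responses(a, b) %>%
    mutate(phi = purrr::pmap_dbl(
      list(.data$S, .data$n_a, .data$n_b, .data$k),
      function(S, na, nb, k) phi_pair(k, null_pmf(S, na, nb))
    ))
}

#' Excess correlations among a set of observers
#'
#' Mean mid-p excess correlation over all unordered observer pairs and all
#' conditions, with the per-pair means reported as a (symmetric) pair table.
#'
#' @param humans Decision table with at least two observers.
#' @return An object of class `af_phi` with elements `phi` (overall mean),
#'   `pairs` (tibble `observer_a`, `observer_b`, `phi`), and `conditions`
#'   (per-pair, per-condition values).
#' @export
phi_human_human <- function(humans) {
  check_decision_table(humans)
  ids <- sort(unique(humans$observer_id))
  if (length(ids) < 2L) {
    abort("Need at least 2 observers.", class = "afield_parameter_error")
  }
  pr <- utils::combn(ids, 2L, simplify = FALSE)
  cond <- purrr::map(pr, function(p) {
    phi_conditions(humans %>% filter(.data$observer_id == p[1]),
                   humans %>% filter(.data$observer_id == p[2])) %>%
      mutate(observer_a = p[1], observer_b = p[2])
  }) %>% bind_rows()
  pairs <- cond %>%
    group_by(.data$observer_a, .data$observer_b) %>%
    summarise(phi = mean(.data$phi), .groups = "drop")
  structure(list(phi = mean(cond$phi), pairs = pairs, conditions = cond,
                 kind = "human-human"),
            class = "af_phi")
}

#' Excess correlation of a model with human observers
#'
#' Mean mid-p excess correlation of one model observer against every human
#' observer, over all conditions.
#'
#' @param model Decision table of a single model observer.
#' @param humans Decision table of the reference observers.
#' @return An object of class `af_phi`.
#' @export
phi_model_human <- function(model, humans) {
  check_decision_table(model, "`model`")
  check_decision_table(humans, "`humans`")
  ids <- sort(unique(humans$observer_id))
  cond <- purrr::map(ids, function(h) {
    phi_conditions(model, humans %>% filter(.data$observer_id == h)) %>%
      mutate(observer_a = model$observer_id[1], observer_b = h)
  }) %>% bind_rows()
  pairs <- cond %>%
    group_by(.data$observer_a, .data$observer_b) %>%
    summarise(phi = mean(.data$phi), .groups = "drop")
  structure(list(phi = mean(cond$phi), pairs = pairs, conditions = cond,
                 kind = "model-human"),
            class = "af_phi")
}

#' @export
print.af_phi <- function(x, ...) {
  cat(sprintf("<af_phi> %s excess correlation: Phi = %.4f over %d pair(s), %d condition value(s)\n",
              x$kind, x$phi, nrow(x$pairs), nrow(x$conditions)))
  invisible(x)
}

#' Leave-one-out prototype observers
#'
#' For each observer, builds a noise-reduced "prototype": the stimulus-wise
#' majority vote of the remaining observers (ties broken by a seeded coin
#' flip). The mean excess correlation between each prototype and its held-out
#' observer is the benchmark a noise-free model must reach to explain the
#' observers as well as the observers explain each other.
#'
#' @param humans Decision table with at least three observers.
#' @param seed Optional seed for tie-breaking.
#' @return A list of class `af_prototypes`: `prototypes` (decision table with
#'   observer ids `"proto_<id>"`), `phi` (benchmark mean), `pairs`
#'   (per-observer values), `tie_rate` (fraction of majority votes decided by
#'   coin flip).
#' @export
prototype_observers <- function(humans, seed = NULL) {
  check_decision_table(humans)
  if (!is.null(seed)) withr::local_seed(seed)
  ids <- sort(unique(humans$observer_id))
  if (length(ids) < 3L) {
    abort("Need at least 3 observers for leave-one-out prototypes.",
          class = "afield_parameter_error")
  }
  cv <- condition_vars(humans)
  key <- c(cv, "stimulus_id")
  # target side recovered from response + correctness
  base <- humans %>%
    mutate(target = ifelse(.data$correct == 1L, .data$response,
                           ifelse(.data$response == "left", "right", "left")))
  n_ties <- 0L
  n_votes <- 0L
  protos <- purrr::map(ids, function(m) {
    rest <- base %>% filter(.data$observer_id != m)
    votes <- rest %>%
      group_by(dplyr::across(dplyr::all_of(key))) %>%
      summarise(n_left = sum(.data$response == "left"),
                n_right = sum(.data$response == "right"),
                target = .data$target[1], .groups = "drop")
    tie <- votes$n_left == votes$n_right
    n_ties <<- n_ties + sum(tie)
    n_votes <<- n_votes + nrow(votes)
    resp <- ifelse(votes$n_left > votes$n_right, "left",
                   ifelse(votes$n_right > votes$n_left, "right", NA))
    if (any(tie)) {
      resp[tie] <- sample(c("left", "right"), sum(tie), replace = TRUE)
    }
    votes %>%
      mutate(observer_id = paste0("proto_", m),
             response = resp,
             correct = as.integer(resp == .data$target)) %>%
      select(dplyr::all_of(c("observer_id", key, "response", "correct")))
  })
  names(protos) <- ids
  cond <- purrr::map(ids, function(m) {
    phi_conditions(protos[[m]], humans %>% filter(.data$observer_id == m)) %>%
      mutate(observer_a = paste0("proto_", m), observer_b = m)
  }) %>% bind_rows()
  pairs <- cond %>%
    group_by(.data$observer_a, .data$observer_b) %>%
    summarise(phi = mean(.data$phi), .groups = "drop")
  structure(list(prototypes = bind_rows(protos), phi = mean(cond$phi),
                 pairs = pairs, conditions = cond,
                 tie_rate = n_ties / n_votes),
            class = "af_prototypes")
}

#' @export
print.af_prototypes <- function(x, ...) {
  cat(sprintf("<af_prototypes> benchmark Phi = %.4f (%d prototypes, tie rate %.3f)\n",
              x$phi, nrow(x$pairs), x$tie_rate))
  invisible(x)
}

# One surrogate: permute each observer's correctness pattern across the
# stimuli of every condition, keeping per-condition correct counts exact, and
# rebuild the responses from the (stimulus-specific) target sides.
shuffle_decisions <- function(humans) {
  cv <- condition_vars(humans)
  humans %>%
    mutate(target = ifelse(.data$correct == 1L, .data$response,
                           ifelse(.data$response == "left", "right", "left"))) %>%
    group_by(dplyr::across(dplyr::all_of(c(cv, "observer_id")))) %>%
    mutate(correct = .data$correct[sample.int(dplyr::n())]) %>%
    ungroup() %>%
    mutate(response = ifelse(.data$correct == 1L, .data$target,
                             ifelse(.data$target == "left", "right", "left"))) %>%
    select(-"target")
}

#' Permutation significance threshold for excess correlations
#'
#' Shuffles each observer's correctness pattern across the stimuli within
#' every condition -- preserving each observer's per-condition correct count
#' exactly -- and recomputes the excess correlation for each surrogate. The
#' `(1 - alpha)` quantile of the surrogate distribution is the threshold an
#' observed `Phi` must exceed to be called significant.
#'
#' @param humans Decision table of the reference observers.
#' @param model Optional decision table of a model observer; when supplied the
#'   surrogate statistic is the model-human `Phi` (model fixed, humans
#'   shuffled), otherwise the human-human `Phi`.
#' @param n_surrogates Number of shuffles (a warning is issued below 100).
#' @param alpha Significance level.
#' @param seed Optional seed.
#' @return A list of class `af_phi_sig`: `threshold`, `alpha`, `surrogates`
#'   (the surrogate `Phi` values).
#' @export
shuffle_significance <- function(humans, model = NULL, n_surrogates = 200L,
                                 alpha = 0.01, seed = NULL) {
  check_decision_table(humans)
  if (!is.null(seed)) withr::local_seed(seed)
  if (n_surrogates < 100L) {
    warn("Fewer than 100 surrogates gives a coarse significance threshold.")
  }
  surr <- purrr::map_dbl(seq_len(n_surrogates), function(i) {
    sh <- shuffle_decisions(humans)
    if (is.null(model)) phi_human_human(sh)$phi
    else phi_model_human(model, sh)$phi
  })
  structure(list(threshold = unname(quantile(surr, 1 - alpha)),
                 alpha = alpha, surrogates = surr),
            class = "af_phi_sig")
}

#' @export
print.af_phi_sig <- function(x, ...) {
  cat(sprintf("<af_phi_sig> Phi_sig = %.4f at alpha = %.3g (%d surrogates, mean %.4f)\n",
              x$threshold, x$alpha, length(x$surrogates), mean(x$surrogates)))
  invisible(x)
}
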