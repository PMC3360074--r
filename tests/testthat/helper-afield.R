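# Shared helpers and lazily-built stimulus pools. Expensive ensembles are
# built once per test run and reused across test files.

.afield_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (!exists(key, envir = .afield_cache)) {
    assign(key, fn(), envir = .afield_cache)
  }
  get(key, envir = .afield_cache)
}

ks_stat <- function(a, b) {
  unname(suppressWarnings(stats::ks.test(a, b)$statistic))
}

# Rayleigh test p-value for circular uniformity.
rayleigh_p <- function(theta) {
  n <- length(theta)
  r <- sqrt(mean(cos(theta))^2 + mean(sin(theta))^2)
  z <- n * r^2
  exp(-z) * (1 + (2 * z - z^2) / (4 * n))
}

# A small, quickly-built matched ensemble reused by several files.
small_pool <- function() {
  cached("small_pool", function() {
    spec <- ensemble_spec(af_params(0.28, 0.56, 2.4), L = 5, n_stimuli = 12,
                          field_width = 20, field_height = 16, spacing = 2.4,
                          ensemble_id = "sp1")
    st <- build_ensemble(spec, seed = 421)
    list(stimuli = st, spec = spec,
         specs = tibble::tibble(ensemble_id = "sp1", L = 5, spacing = 2.4))
  })
}

# Two-ensemble pool for search / decision-table tests.
search_pool <- function() {
  cached("search_pool", function() {
    mk <- function(sa, sc, id, seed) {
      build_ensemble(
        ensemble_spec(af_params(sa, sc, 2.4), L = 5, n_stimuli = 12,
                      field_width = 20, field_height = 16, spacing = 2.4,
                      ensemble_id = id),
        seed = seed)
    }
    st <- dplyr::bind_rows(mk(0.14, 0.28, "q1", 881), mk(0.42, 0.84, "q2", 882))
    list(stimuli = st,
         specs = tibble::tibble(ensemble_id = c("q1", "q2"), L = 5, spacing = 2.4))
  })
}

# Directly constructed (not embedded) stimulus: a perfectly colinear chain in
# one hemifield, uniform random edges elsewhere. Fast, for observer tests.
chain_stimulus <- function(L = 5, n_bg = 25, target_side = "left",
                           spacing = 2, jitter = 0) {
  x0 <- if (target_side == "left") -1 - spacing * (L - 1) else 1
  chain <- tibble::tibble(
    hemifield = target_side, role = "contour", contour_order = 1:L,
    x = x0 + spacing * (0:(L - 1)),   # rightward chain, theta = 0 everywhere
    y = stats::rnorm(L, 0, jitter),
    theta = 0
  )
  bg <- function(side) {
    s <- if (side == "left") -1 else 1
    tibble::tibble(
      hemifield = side, role = "background", contour_order = NA_integer_,
      x = s * stats::runif(n_bg, 0.5, 10), y = stats::runif(n_bg, -8, 8),
      theta = stats::runif(n_bg, 0, 2 * pi)
    )
  }
  out <- dplyr::bind_rows(chain, bg("left"), bg("right"))
  out$target_side <- target_side
  out$stimulus_id <- "chain"
  out$ensemble_id <- "chain"
  out
}

# Directly constructed decision tables (no stimuli needed): `n_cond`
# conditions of `S` stimuli; observers share a per-stimulus difficulty when
# `shared` is TRUE, otherwise answer independently with accuracy `acc`.
fake_decisions <- function(n_obs, n_cond, S, acc = 0.75, shared = FALSE,
                           noise = 0.1) {
  rows <- list()
  for (cc in seq_len(n_cond)) {
    target <- sample(c("left", "right"), S, replace = TRUE)
    p_stim <- if (shared) stats::rbeta(S, 2 * acc / (1 - acc), 2) else rep(acc, S)
    for (m in seq_len(n_obs)) {
      p <- if (shared) (1 - noise) * p_stim + noise * 0.5 else p_stim
      hit <- stats::runif(S) < p
      resp <- ifelse(hit, target, ifelse(target == "left", "right", "left"))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        observer_id = sprintf("o%02d", m),
        ensemble_id = sprintf("c%03d", cc),
        stimulus_id = sprintf("c%03d_s%02d", cc, seq_len(S)),
        soa = NA_real_, response = resp, correct = as.integer(hit)
      )
    }
  }
  dplyr::bind_rows(rows)
}

# Exhaustive oracle for the identical-response null: enumerate all placements
# of the two correct sets over S stimuli and tabulate identical responses.
# Sets are represented as indicator columns; pairwise overlaps come from one
# crossproduct.
enumerate_null <- function(S, n_a, n_b) {
  indicators <- function(n) {
    if (n == 0L) return(matrix(0L, S, 1L))
    sets <- utils::combn(S, n)
    out <- matrix(0L, S, ncol(sets))
    out[cbind(as.vector(sets), rep(seq_len(ncol(sets)), each = n))] <- 1L
    out
  }
  A <- indicators(n_a)
  B <- indicators(n_b)
  m <- as.vector(crossprod(A, B))
  k <- S - n_a - n_b + 2L * m
  tab <- table(k) / length(k)
  tibble::tibble(k = as.integer(names(tab)), prob = as.numeric(tab))
}

# Chi-squared goodness-of-fit of sampled AF transitions against the angular
# density, in the decoupled coordinates U = phi - dtheta/2 ~ VM(0, s1/2) and
# V = dtheta ~ VM(0, s2), using equal-probability quantile bins (n_bins^2
# cells, each with expected probability 1/n_bins^2).
angular_gof_p <- function(params, n = 10000L, n_bins = 6L) {
  tr <- afield:::sample_af_transition(n, params)
  u <- afield:::wrap_pi(tr$phi - tr$dtheta / 2)
  v <- tr$dtheta
  qu <- afield:::qvon_mises(seq(0, 1, length.out = n_bins + 1L),
                            sigma = params$sigma_align / 2)
  qv <- afield:::qvon_mises(seq(0, 1, length.out = n_bins + 1L),
                            sigma = params$sigma_curv)
  qu[1] <- -pi; qu[n_bins + 1L] <- pi
  qv[1] <- -pi; qv[n_bins + 1L] <- pi
  cu <- cut(u, qu, include.lowest = TRUE)
  cv <- cut(v, qv, include.lowest = TRUE)
  counts <- as.numeric(table(cu, cv))
  suppressWarnings(stats::chisq.test(counts, p = rep(1 / length(counts),
                                                     length(counts)))$p.value)
}
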