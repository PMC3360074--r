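# The contour observer. Given the edges of one hemifield, a link matrix Q of
# pairwise association-field densities is built; per-edge starting-edge
# likelihoods are accumulated by the weighted matrix iteration
#   b(0) = w,   b(n) = W Q b(n-1)   (W = diag of the salience weights w),
# where b(n)_i sums, over all n-step paths beginning at edge i (consecutive
# edges distinct), the product of link densities and salience weights.
# Finding a contour of L edges takes L - 1 iterations. With w == 1 the
# weighted iteration reduces exactly to the unweighted one.

#' Eccentricity-dependent salience weights
#'
#' `w_i = 1 - amplitude * (eps_i / eps_max)^exponent`, where `eps_i` is the
#' edge's eccentricity (distance from fixation). Weights lie in `(0, 1]`;
#' `amplitude = 0` gives `w == 1` for any exponent. Eccentricities beyond
#' `eps_max` are clamped with a warning.
#'
#' @param edges Data frame with columns `x`, `y` (DVA).
#' @param ecc An [ecc_params()] object.
#' @return Numeric vector of weights, one per edge.
#' @examples
#' salience_weights(edge_tbl(c(0, 10), c(0, 0), c(0, 0)), ecc_params(0.5, 2))
#' @export
salience_weights <- function(edges, ecc) {
  stopifnot(inherits(ecc, "ecc_params"))
  eps <- sqrt(edges$x^2 + edges$y^2)
  if (any(eps > ecc$eps_max)) {
    warn(sprintf("%d edge(s) beyond eps_max = %.3g DVA; eccentricity clamped.",
                 sum(eps > ecc$eps_max), ecc$eps_max))
    eps <- pmin(eps, ecc$eps_max)
  }
  1 - ecc$amplitude * (eps / ecc$eps_max)^ecc$exponent
}

# Pairwise geometry of an edge set, cached so that link matrices for many
# candidate association fields can be evaluated from the same arrays:
# D distance, C1 = cos(phi - dtheta/2), C2 = cos(dtheta).
link_geometry <- function(edges) {
  n <- nrow(edges)
  x <- edges$x; y <- edges$y; th <- edges$theta
  dx <- matrix(x, n, n, byrow = TRUE) - x
  dy <- matrix(y, n, n, byrow = TRUE) - y
  D <- sqrt(dx^2 + dy^2)
  bad <- which(D < 1e-12 & row(D) != col(D), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    abort(sprintf("Coincident edges %d and %d: link density undefined.",
                  bad[1, 1], bad[1, 2]),
          class = "afield_degenerate_geometry")
  }
  beta <- atan2(dy, dx)
  thi <- matrix(th, n, n)                 # source direction, by row
  dth <- wrap_pi(matrix(th, n, n, byrow = TRUE) - thi)
  phi <- wrap_pi(beta - thi)
  list(D = D, C1 = cos(wrap_pi(phi - dth / 2)), C2 = cos(dth),
       eps = sqrt(x^2 + y^2), n = n)
}

# Link matrix from cached geometry; one exp() per entry.
q_from_geometry <- function(geo, af, d_max = Inf) {
  k1 <- 4 / af$sigma_align^2
  k2 <- 1 / af$sigma_curv^2
  lam <- af$lambda_radial
  zr <- lam * (1 - exp(-d_max / lam))
  za <- 4 * pi^2 * besselI(k1, 0, expon.scaled = TRUE) *
    besselI(k2, 0, expon.scaled = TRUE)
  Q <- exp(k1 * (geo$C1 - 1) + k2 * (geo$C2 - 1) - geo$D / lam) / (za * zr)
  diag(Q) <- 0
  Q
}

#' Link matrix of pairwise association probabilities
#'
#' `Q[i, j] = af_density(edge_i -> edge_j)` for all ordered pairs, with a zero
#' diagonal.
#'
#' @param edges Data frame of edges (`x`, `y`, `theta`).
#' @param af An [af_params()] object.
#' @param d_max Truncation distance for the radial normalization.
#' @return An `n x n` matrix of non-negative link densities.
#' @export
link_matrix <- function(edges, af, d_max = Inf) {
  stopifnot(inherits(af, "af_params"))
  if (nrow(edges) < 2L) {
    abort("Need at least 2 edges.", class = "afield_parameter_error")
  }
  q_from_geometry(link_geometry(edges), af, d_max)
}

#' Starting-edge likelihoods by matrix iteration
#'
#' Iterates `b(0) = w`, `b(n) = W Q b(n-1)` for `n = 1 .. L-1` and returns all
#' iterates. `b(n)_i` accumulates the likelihood that edge `i` is the starting
#' edge of a contour of `n + 1` elements.
#'
#' @param Q Link matrix from [link_matrix()].
#' @param w Salience weight vector (use `rep(1, n)` for the unweighted ideal
#'   observer).
#' @param L Contour length; `L - 1` iterations are performed.
#' @return A matrix of class `af_likelihood` with `L` rows (iterations
#'   `0 .. L-1`) and one column per edge.
#' @export
starting_likelihoods <- function(Q, w, L) {
  n <- length(w)
  if (!is.matrix(Q) || nrow(Q) != n || ncol(Q) != n) {
    abort("`Q` must be a square matrix matching length(w).",
          class = "afield_parameter_error")
  }
  if (L < 2) abort("`L` must be >= 2.", class = "afield_parameter_error")
  B <- matrix(NA_real_, L, n)
  b <- w
  B[1, ] <- b
  for (it in seq_len(L - 1L)) {
    b <- w * as.numeric(Q %*% b)
    B[it + 1L, ] <- b
  }
  rownames(B) <- paste0("iter", 0:(L - 1L))
  class(B) <- c("af_likelihood", class(B))
  B
}

#' @export
tidy.af_likelihood <- function(x, ...) {
  m <- unclass(x)
  tibble(
    iteration = rep(0:(nrow(m) - 1L), times = ncol(m)),
    edge = rep(seq_len(ncol(m)), each = nrow(m)),
    likelihood = as.numeric(m)
  )
}

#' Brute-force starting-edge likelihoods
#'
#' Independent oracle for [starting_likelihoods()]: explicitly enumerates
#' every edge sequence of length `L` with distinct consecutive elements and
#' sums the products of salience weights and link densities, aggregated by
#' starting edge. Guarded to small instances (`n <= 12`, `L <= 5`).
#'
#' @param edges Data frame of edges.
#' @param af An [af_params()] object.
#' @param ecc An [ecc_params()] object.
#' @param L Contour length.
#' @param d_max Radial truncation distance.
#' @return Numeric vector: per-edge likelihood of being the starting edge,
#'   after `L - 1` transitions.
#' @export
brute_force_likelihood <- function(edges, af, ecc, L, d_max = Inf) {
  n <- nrow(edges)
  if (n > 12L || L > 5L) {
    abort("Brute force guarded to n <= 12 and L <= 5.",
          class = "afield_size_error")
  }
  w <- salience_weights(edges, ecc)
  # per-pair densities computed through the public af_density path
  src <- edges[rep(seq_len(n), each = n), c("x", "y", "theta")]
  tgt <- edges[rep(seq_len(n), times = n), c("x", "y", "theta")]
  same <- rep(seq_len(n), each = n) == rep(seq_len(n), times = n)
  q <- numeric(n * n)
  q[!same] <- af_density(src[!same, ], tgt[!same, ], af, d_max)
  qm <- matrix(q, n, n, byrow = TRUE)   # qm[i, j] = density(edge_i -> edge_j)
  total <- numeric(n)
  walk <- function(cur, depth, value) {
    if (depth == L) return(value)
    acc <- 0
    for (nxt in seq_len(n)) {
      if (nxt == cur) next
      acc <- acc + walk(nxt, depth + 1L, value * qm[cur, nxt] * w[nxt])
    }
    acc
  }
  for (i in seq_len(n)) total[i] <- walk(i, 1L, w[i])
  total
}

#' Two-alternative forced-choice decision
#'
#' Per hemifield, the summed starting-edge likelihood after `n_iter`
#' iterations is normalized by the number of ordered edge configurations
#' `M_X = N (N-1) ... (N - n_iter)` and the observer responds with the
#' hemifield of larger normalized likelihood; exact ties are broken by a
#' seeded coin flip.
#'
#' @param stimulus A stimulus tibble (a single stimulus).
#' @param af An [af_params()] object: the observer's association field.
#' @param ecc An [ecc_params()] object: the observer's salience scaling.
#' @param L Contour length assumed by the observer.
#' @param n_iter Number of iterations, or `"full"` for `L - 1`.
#' @param seed Optional seed (used only for tie-breaking).
#' @param d_max Radial truncation distance.
#' @return A one-row tibble: `response`, `lik_left`, `lik_right`, `n_iter`.
#' @export
decide_2afc <- function(stimulus, af, ecc, L, n_iter = "full", seed = NULL,
                        d_max = Inf) {
  if (!is.null(seed)) withr::local_seed(seed)
  n_it <- if (identical(n_iter, "full")) L - 1L else as.integer(n_iter)
  lik <- purrr::map_dbl(c("left", "right"), function(side) {
    e <- stimulus %>%
      filter(.data$hemifield == side, .data$role != "mask")
    hemifield_likelihood(e, af, ecc, L, n_it, d_max)
  })
  resp <- if (lik[1] > lik[2]) "left" else if (lik[2] > lik[1]) "right"
  else sample(c("left", "right"), 1L)
  tibble(response = resp, lik_left = lik[1], lik_right = lik[2], n_iter = n_it)
}

hemifield_likelihood <- function(edges, af, ecc, L, n_it, d_max = Inf,
                                 geo = NULL) {
  n <- if (is.null(geo)) nrow(edges) else geo$n
  if (n < L) {
    abort(sprintf("Hemifield has %d edges; need at least L = %d.", n, L),
          class = "afield_parameter_error")
  }
  if (is.null(geo)) geo <- link_geometry(edges)
  Q <- q_from_geometry(geo, af, d_max)
  w <- weights_from_eps(geo$eps, ecc)
  b <- w
  for (it in seq_len(n_it)) b <- w * as.numeric(Q %*% b)
  m_x <- prod(n - 0:n_it)
  sum(b) / m_x
}

weights_from_eps <- function(eps, ecc) {
  1 - ecc$amplitude * (pmin(eps, ecc$eps_max) / ecc$eps_max)^ecc$exponent
}

#' Observer model
#'
#' Bundles an association field and an eccentricity scaling into one observer
#' (the four-parameter model class searched by [grid_search()]).
#'
#' @param af An [af_params()] object.
#' @param ecc An [ecc_params()] object.
#' @param id Observer identifier used in decision tables.
#' @return An object of class `af_observer`.
#' @export
observer_model <- function(af, ecc = ecc_params(0, 1), id = "model") {
  stopifnot(inherits(af, "af_params"), inherits(ecc, "ecc_params"))
  structure(list(af = af, ecc = ecc, id = id), class = "af_observer")
}

#' @export
print.af_observer <- function(x, ...) {
  cat(sprintf("<af_observer> %s: AF(%s), ecc(a = %.3g, gamma = %.3g)\n",
              x$id, format(x$af), x$ecc$amplitude, x$ecc$exponent))
  invisible(x)
}

# Cache per-hemifield link geometries for a set of stimuli, so many observer
# models can be evaluated in a single pass over the stimuli.
stimulus_geometries <- function(stimuli) {
  stimuli %>%
    filter(.data$role != "mask") %>%
    group_by(.data$ensemble_id, .data$stimulus_id) %>%
    group_split() %>%
    purrr::map(function(st) {
      list(
        ensemble_id = st$ensemble_id[1],
        stimulus_id = st$stimulus_id[1],
        target_side = st$target_side[1],
        left = link_geometry(st %>% filter(.data$hemifield == "left")),
        right = link_geometry(st %>% filter(.data$hemifield == "right"))
      )
    })
}

# Decisions of one or more observer models over cached geometries.
# n_iter_by_ensemble: named integer vector (ensemble_id -> iterations) or NULL
# for full depth given L_by_ensemble.
decide_from_geometries <- function(geos, observers, L_by_ensemble,
                                   n_iter_by_ensemble = NULL, soa = NA_real_,
                                   d_max = Inf) {
  if (inherits(observers, "af_observer")) observers <- list(observers)
  rows <- vector("list", length(geos) * length(observers))
  k <- 0L
  for (g in geos) {
    L <- L_by_ensemble[[g$ensemble_id]]
    n_it <- if (is.null(n_iter_by_ensemble)) L - 1L
    else n_iter_by_ensemble[[g$ensemble_id]]
    for (ob in observers) {
      bl <- hemifield_likelihood(NULL, ob$af, ob$ecc, L, n_it, d_max,
                                 geo = g$left)
      br <- hemifield_likelihood(NULL, ob$af, ob$ecc, L, n_it, d_max,
                                 geo = g$right)
      resp <- if (bl > br) "left" else if (br > bl) "right"
      else sample(c("left", "right"), 1L)
      k <- k + 1L
      rows[[k]] <- tibble(
        observer_id = ob$id, ensemble_id = g$ensemble_id,
        stimulus_id = g$stimulus_id, soa = soa, response = resp,
        correct = as.integer(resp == g$target_side)
      )
    }
  }
  bind_rows(rows)
}

#' Run an observer model over a set of stimuli
#'
#' Applies [decide_2afc()] to every stimulus at full iteration depth and
#' returns a decision table.
#'
#' @param stimuli A stimulus tibble (one or more stimuli).
#' @param model An [observer_model()].
#' @param specs Ensemble specification table (tibble with `ensemble_id`, `L`)
#'   or `NULL` to use the `"ensemble_spec"` attribute of `stimuli`.
#' @param soa Value recorded in the `soa` column of the output.
#' @param seed Optional seed (tie-breaking only).
#' @return A decision table: `observer_id`, `ensemble_id`, `stimulus_id`,
#'   `soa`, `response`, `correct`.
#' @export
run_observer <- function(stimuli, model, specs = NULL, soa = NA_real_,
                         seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  Lmap <- ensemble_L_map(stimuli, specs)
  geos <- stimulus_geometries(stimuli)
  decide_from_geometries(geos, model, Lmap, soa = soa)
}

ensemble_L_map <- function(stimuli, specs = NULL) {
  if (is.null(specs)) {
    sp <- attr(stimuli, "ensemble_spec")
    if (!is.null(sp)) {
      specs <- tibble(ensemble_id = sp$ensemble_id, L = sp$L)
    } else {
      # fall back to counting labelled contour edges
      specs <- stimuli %>%
        filter(.data$role == "contour") %>%
        count(.data$ensemble_id, .data$stimulus_id) %>%
        group_by(.data$ensemble_id) %>%
        summarise(L = max(.data$n), .groups = "drop")
    }
  }
  stats::setNames(as.integer(specs$L), specs$ensemble_id)
}

#' Map stimulus-onset asynchrony to iteration depth
#'
#' Assumes association-field interactions propagate at a constant speed `v`,
#' so one matrix iteration bridges the mean element distance `d_bar` in time
#' `dt = d_bar / v`. An SOA of `t` ms then corresponds to
#' `round(t / dt)` iterations, clamped to `[1, L - 1]`. The default speed,
#' 13.9 DVA per 200 ms (the average contour length in the default design),
#' makes the largest SOA correspond to the full `L - 1` iterations.
#'
#' @param v Propagation speed, DVA per ms.
#' @param d_bar Mean element distance, DVA.
#' @return An object of class `soa_map`.
#' @export
soa_map <- function(v = 13.9 / 200, d_bar = 2.4) {
  check_positive_scalar(v, "v")
  check_positive_scalar(d_bar, "d_bar")
  structure(list(v = v, d_bar = d_bar), class = "soa_map")
}

#' @rdname soa_map
#' @param soa SOA values in ms.
#' @param map An `soa_map` object.
#' @param L Contour length.
#' @export
soa_iterations <- function(soa, map, L) {
  dt <- map$d_bar / map$v
  pmin(pmax(round(soa / dt), 1L), L - 1L)
}

#' Detection performance as a function of SOA
#'
#' Simulates the 2-AFC observer at the iteration depth implied by each SOA
#' and reports the fraction of correct responses per ensemble and SOA.
#'
#' @param stimuli A stimulus tibble.
#' @param model An [observer_model()].
#' @param soas SOA values in ms.
#' @param specs Tibble with `ensemble_id`, `L`, `spacing` (or `NULL` to use
#'   the ensemble attribute).
#' @param v Propagation speed, DVA per ms.
#' @param seed Optional seed.
#' @return A tibble: `ensemble_id`, `soa`, `n_iter`, `fraction_correct`, `n`.
#' @export
soa_performance_curve <- function(stimuli, model,
                                  soas = c(20, 30, 60, 100, 200),
                                  specs = NULL, v = 13.9 / 200, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  if (is.null(specs)) {
    sp <- attr(stimuli, "ensemble_spec")
    specs <- tibble(ensemble_id = sp$ensemble_id, L = sp$L, spacing = sp$spacing)
  }
  Lmap <- stats::setNames(as.integer(specs$L), specs$ensemble_id)
  geos <- stimulus_geometries(stimuli)
  out <- purrr::map(soas, function(s) {
    nmap <- stats::setNames(
      purrr::map2_int(specs$spacing, specs$L,
                      ~ as.integer(soa_iterations(s, soa_map(v = v, d_bar = .x), .y))),
      specs$ensemble_id)
    dec <- decide_from_geometries(geos, model, Lmap, n_iter_by_ensemble = nmap,
                                  soa = s)
    dec %>%
      group_by(.data$ensemble_id) %>%
      summarise(fraction_correct = mean(.data$correct),
                n = dplyr::n(), .groups = "drop") %>%
      mutate(soa = s, n_iter = as.integer(nmap[.data$ensemble_id])) %>%
      select("ensemble_id", "soa", "n_iter", "fraction_correct", "n")
  })
  bind_rows(out)
}

#' Per-edge likelihood dynamics for uni- and bidirectional association fields
#'
#' Tracks the starting-edge likelihood of every contour element (by its
#' position 1..L along the contour) and of the background edges across
#' iterations. In `"unidirectional"` mode the observer's own directed link
#' matrix is used; contour creation is directed, so likelihood accumulates
#' toward an end element. In `"bidirectional"` mode the link matrix is
#' symmetrized (averaged over flipping either edge's direction by `pi`) so
#' that it is invariant to the directions of arbitrary edge pairs; likelihood
#' then accumulates from both sides and peaks at interior elements.
#'
#' @param stimuli A stimulus tibble with labelled contours.
#' @param model An [observer_model()].
#' @param mode `"unidirectional"` or `"bidirectional"`.
#' @param specs Optional ensemble specification tibble (`ensemble_id`, `L`).
#' @return A tibble of class `af_dynamics`: `ensemble_id`, `iteration`,
#'   `position` (`"1" .. "L"` or `"background"`), `likelihood` (per-iteration
#'   likelihoods normalized within stimulus before averaging).
#' @export
symmetrize_af_dynamics <- function(stimuli, model,
                                   mode = c("unidirectional", "bidirectional"),
                                   specs = NULL) {
  mode <- match.arg(mode)
  Lmap <- ensemble_L_map(stimuli, specs)
  rows <- stimuli %>%
    filter(.data$role != "mask") %>%
    group_by(.data$ensemble_id, .data$stimulus_id) %>%
    group_split() %>%
    purrr::map(function(st) {
      side <- st$target_side[1]
      e <- st %>% filter(.data$hemifield == side)
      L <- Lmap[[st$ensemble_id[1]]]
      Q <- if (mode == "unidirectional") {
        link_matrix(e, model$af)
      } else {
        symmetrized_link_matrix(e, model$af)
      }
      w <- salience_weights(e, model$ecc)
      B <- unclass(starting_likelihoods(Q, w, L))
      B <- B / rowSums(B)   # normalize each iteration within the stimulus
      pos <- ifelse(is.na(e$contour_order), "background",
                    as.character(e$contour_order))
      tibble(
        ensemble_id = st$ensemble_id[1],
        iteration = rep(0:(L - 1L), times = ncol(B)),
        position = rep(pos, each = L),
        likelihood = as.numeric(B)
      )
    }) %>%
    bind_rows() %>%
    group_by(.data$ensemble_id, .data$iteration, .data$position) %>%
    summarise(likelihood = mean(.data$likelihood), .groups = "drop")
  class(rows) <- c("af_dynamics", class(rows))
  attr(rows, "mode") <- mode
  rows
}

# Average the link density over flips of either edge's direction by pi,
# making it invariant to the (arbitrary) direction labels of the pair.
symmetrized_link_matrix <- function(edges, af, d_max = Inf) {
  flips <- list(c(0, 0), c(pi, 0), c(0, pi), c(pi, pi))
  qs <- purrr::map(flips, function(f) {
    # flip applies to source direction (rows) and target direction (cols)
    n <- nrow(edges)
    th_src <- wrap_2pi(edges$theta + f[1])
    th_tgt <- wrap_2pi(edges$theta + f[2])
    dx <- matrix(edges$x, n, n, byrow = TRUE) - edges$x
    dy <- matrix(edges$y, n, n, byrow = TRUE) - edges$y
    D <- sqrt(dx^2 + dy^2)
    beta <- atan2(dy, dx)
    thi <- matrix(th_src, n, n)
    dth <- wrap_pi(matrix(th_tgt, n, n, byrow = TRUE) - thi)
    phi <- wrap_pi(beta - thi)
    geo <- list(D = D, C1 = cos(wrap_pi(phi - dth / 2)), C2 = cos(dth))
    q_from_geometry(geo, af, d_max)
  })
  (qs[[1]] + qs[[2]] + qs[[3]] + qs[[4]]) / 4
}

#' Which contour position holds the likelihood maximum?
#'
#' Summarises [symmetrize_af_dynamics()] output: for each ensemble, the
#' contour position (1..L) with the largest mean likelihood at the final
#' iteration, and whether it is an end element (position 1 or L).
#'
#' @param dynamics An `af_dynamics` tibble.
#' @return A tibble: `ensemble_id`, `argmax_position`, `L`, `at_end`.
#' @export
dynamics_peak_position <- function(dynamics) {
  dynamics %>%
    filter(.data$position != "background") %>%
    group_by(.data$ensemble_id) %>%
    filter(.data$iteration == max(.data$iteration)) %>%
    summarise(
      argmax_position = as.integer(.data$position[which.max(.data$likelihood)]),
      L = max(as.integer(.data$position)),
      .groups = "drop"
    ) %>%
    mutate(at_end = .data$argmax_position %in% c(1L, .data$L))
}
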