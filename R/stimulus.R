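# Stimulus construction: hide a contour in one hemifield among distractors
# whose nearest-neighbour distance statistics match the contour's, add a
# decoy path with random directions on the opposite hemifield, and build
# balanced ensembles.
#
# A stimulus is a long tibble, one row per edge, with columns
#   stimulus_id, ensemble_id, target_side, hemifield, role, contour_order,
#   x, y, theta, theta_mask
# role is one of "contour", "decoy", "background"; contour_order numbers the
# contour edges 1..L (the decoy reuses the ordering of its template);
# theta_mask holds the random directions of the corresponding mask display,
# which by construction shares every edge position with the stimulus.

#' Ensemble specification
#'
#' Bundles everything needed to generate one contour ensemble: the generating
#' association field, contour length, trial count, field geometry and the
#' target spacing of the distractor field.
#'
#' @param af An [af_params()] object used to generate the contours.
#' @param L Contour length (number of edges), >= 2.
#' @param n_stimuli Number of stimuli in the ensemble; must be even so that
#'   targets can be balanced across hemifields.
#' @param field_width,field_height Stimulus field extent in DVA; the field is
#'   centred on fixation and split into hemifields at `x = 0`.
#' @param spacing Target mean inter-edge distance in DVA (also the pitch of
#'   the initial background grid).
#' @param min_separation Minimum distance between any two rendered elements,
#'   DVA (the Gabor envelope diameter by default).
#' @param ensemble_id Identifier carried by every stimulus of the ensemble.
#' @return An object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(af, L, n_stimuli = 48L,
                          field_width = 26.6, field_height = 20,
                          spacing = 2.4, min_separation = 0.46,
                          ensemble_id = "e01") {
  stopifnot(inherits(af, "af_params"))
  if (n_stimuli %% 2L != 0L) {
    abort("`n_stimuli` must be even (targets are balanced left/right).",
          class = "afield_parameter_error")
  }
  if (L < 2) abort("`L` must be >= 2.", class = "afield_parameter_error")
  check_positive_scalar(spacing, "spacing")
  structure(
    list(af = af, L = as.integer(L), n_stimuli = as.integer(n_stimuli),
         field_width = field_width, field_height = field_height,
         spacing = spacing, min_separation = min_separation,
         ensemble_id = ensemble_id),
    class = "ensemble_spec"
  )
}

#' @export
print.ensemble_spec <- function(x, ...) {
  cat(sprintf(
    "<ensemble_spec> %s: L = %d, n = %d, field %.3g x %.3g DVA, spacing %.3g DVA, AF %s\n",
    x$ensemble_id, x$L, x$n_stimuli, x$field_width, x$field_height, x$spacing,
    format(x$af)))
  invisible(x)
}

hemifield_region <- function(spec, side, inset = 0) {
  w <- spec$field_width / 2
  h <- spec$field_height / 2
  if (side == "left") {
    c(-w + inset, -inset, -h + inset, h - inset)
  } else {
    c(inset, w - inset, -h + inset, h - inset)
  }
}

opposite_side <- function(side) ifelse(side == "left", "right", "left")

# min distance from each row of `a` to rows of `b`; `self = TRUE` when a and b
# are the same set (the zero self-distance is excluded).
min_dist_to <- function(a, b, self = FALSE) {
  if (nrow(b) == 0L || (self && nrow(b) < 2L)) return(rep(Inf, nrow(a)))
  dx <- outer(a$x, b$x, "-")
  dy <- outer(a$y, b$y, "-")
  dm <- sqrt(dx^2 + dy^2)
  if (self) diag(dm) <- Inf
  apply(dm, 1L, min)
}

# Re-insert n background edges at random admissible positions.
replenish_background <- function(bg, obstacles, spec, side, n_new,
                                 max_tries = 400L) {
  if (n_new <= 0L) return(bg)
  reg <- hemifield_region(spec, side)
  added <- 0L
  for (k in seq_len(max_tries)) {
    if (added >= n_new) break
    p <- tibble(x = runif(1, reg[1], reg[2]), y = runif(1, reg[3], reg[4]))
    d_bg <- min_dist_to(p, bg)
    d_ob <- min_dist_to(p, obstacles)
    if (min(d_bg, d_ob) >= spec$min_separation) {
      bg <- bind_rows(bg, mutate(p, theta = runif(1, 0, 2 * pi)))
      added <- added + 1L
    }
  }
  bg
}

# Jittered-grid initialization of one hemifield's background, excluding
# positions too close to fixed obstacle edges.
init_background <- function(spec, side, obstacles) {
  reg <- hemifield_region(spec, side)
  p <- spec$spacing
  xc <- seq(reg[1] + p / 2, reg[2] - p / 2, by = p)
  yc <- seq(reg[3] + p / 2, reg[4] - p / 2, by = p)
  g <- tidyr::expand_grid(x = xc, y = yc)
  g$x <- g$x + runif(nrow(g), -p / 4, p / 4)
  g$y <- g$y + runif(nrow(g), -p / 4, p / 4)
  if (nrow(obstacles) > 0L) {
    keep <- min_dist_to(g, obstacles) >= spec$min_separation
    g <- g[keep, , drop = FALSE]
  }
  g$theta <- runif(nrow(g), 0, 2 * pi)
  as_tibble(g)
}

# One Brownian sweep over a hemifield's background edges: all edges propose a
# Gaussian step in parallel; moves that leave the hemifield or violate the
# minimum separation against the current positions of the other edges (or the
# fixed obstacle edges) are rejected, and among the surviving moves, pairs
# that would collide with each other revert the higher-indexed member.
brownian_sweep <- function(bg, obstacles, spec, side) {
  reg <- hemifield_region(spec, side)
  sdstep <- 0.1 * spec$spacing
  n <- nrow(bg)
  if (n == 0L) return(bg)
  px <- bg$x + rnorm(n, 0, sdstep)
  py <- bg$y + rnorm(n, 0, sdstep)
  ok <- px >= reg[1] & px <= reg[2] & py >= reg[3] & py <= reg[4]
  ms2 <- spec$min_separation^2
  d2 <- outer(px, bg$x, "-")^2 + outer(py, bg$y, "-")^2
  diag(d2) <- Inf
  ok <- ok & (apply(d2, 1L, min) >= ms2)
  if (nrow(obstacles) > 0L) {
    d2o <- outer(px, obstacles$x, "-")^2 + outer(py, obstacles$y, "-")^2
    ok <- ok & (apply(d2o, 1L, min) >= ms2)
  }
  idx <- which(ok)
  if (length(idx) > 1L) {
    d2a <- outer(px[idx], px[idx], "-")^2 + outer(py[idx], py[idx], "-")^2
    d2a[!upper.tri(d2a)] <- Inf
    clash <- which(d2a < ms2, arr.ind = TRUE)
    if (nrow(clash) > 0L) ok[idx[unique(clash[, 2L])]] <- FALSE
  }
  bg$x[ok] <- px[ok]
  bg$y[ok] <- py[ok]
  bg
}

# Run Brownian motion to a dynamical steady state. The steady-state test
# compares the background-background nearest-neighbour distribution between
# successive epochs (KS statistic < epoch_tol for `consecutive` epochs);
# max_epochs bounds the run.
settle_background <- function(bg, obstacles, spec, side,
                              max_epochs = 25L, min_epochs = 10L,
                              epoch_tol = 0.02, consecutive = 5L) {
  prev_nn <- NULL
  streak <- 0L
  for (e in seq_len(max_epochs)) {
    bg <- brownian_sweep(bg, obstacles, spec, side)
    nn <- min_dist_to(bg, bg, self = TRUE)
    if (!is.null(prev_nn)) {
      ks <- suppressWarnings(ks.test(nn, prev_nn)$statistic)
      streak <- if (ks < epoch_tol) streak + 1L else 0L
      if (e >= min_epochs && streak >= consecutive) break
    }
    prev_nn <- nn
  }
  bg
}

# Nearest-neighbour distance samples of one embedded stimulus's target side:
# background-background (bb), background-contour (bc: each contour edge to its
# nearest background edge), contour-contour (cc). The bb sample uses a
# minus-sampling border correction: edges within half a grid spacing of the
# hemifield boundary keep serving as neighbours but do not contribute their
# own (boundary-inflated) NN distance, mirroring the interior placement of
# the contour.
target_nn_sets <- function(contour, bg, spec = NULL, side = NULL) {
  bb <- min_dist_to(bg, bg, self = TRUE)
  if (!is.null(spec) && !is.null(side) && nrow(bg) > 0L) {
    reg <- hemifield_region(spec, side)
    m <- spec$spacing / 2
    interior <- bg$x >= reg[1] + m & bg$x <= reg[2] - m &
      bg$y >= reg[3] + m & bg$y <= reg[4] - m
    if (sum(interior) >= 10L) bb <- bb[interior]
  }
  list(
    bb = bb,
    bc = min_dist_to(contour, bg),
    cc = min_dist_to(contour, contour, self = TRUE)
  )
}

# Resample contour step lengths from the measured background NN distribution.
# An interior contour edge's NN distance is the minimum of its two flanking
# steps, so interior steps are drawn at the max-of-two-uniforms quantile of
# F_bb (u -> 1 - (1-u)^2), which makes min(step_i, step_{i+1}) marginally
# distributed as F_bb; the two end steps, which serve as the end edges' NN
# distances directly, are drawn from F_bb itself.
match_contour_steps <- function(contour, bb, spec, side, attempts = 8L) {
  steps <- contour_steps(contour)
  reg <- hemifield_region(spec, side)
  for (a in seq_len(attempts)) {
    u <- runif(nrow(steps))
    q <- 1 - (1 - u)^2
    ends <- unique(c(1L, nrow(steps)))
    q[ends] <- u[ends]
    steps$d <- as.numeric(quantile(bb, q, type = 8, names = FALSE))
    cand <- rebuild_contour(contour[1, , drop = FALSE], steps)
    # translate to fit the hemifield (relative statistics are unaffected)
    shift_x <- max(0, reg[1] - min(cand$x)) - max(0, max(cand$x) - reg[2])
    shift_y <- max(0, reg[3] - min(cand$y)) - max(0, max(cand$y) - reg[4])
    cand$x <- cand$x + shift_x
    cand$y <- cand$y + shift_y
    if (min(cand$x) < reg[1] || max(cand$x) > reg[2] ||
        min(cand$y) < reg[3] || max(cand$y) > reg[4]) {
      next
    }
    if (has_overlap(cand, spec$min_separation)) {
      cand <- tryCatch(
        repair_overlaps(cand, spec$min_separation, region = reg,
                        max_permutations = 500L),
        afield_repair_failure = function(e) NULL
      )
    }
    if (!is.null(cand)) return(cand)
  }
  NULL
}

embed_core <- function(contour, spec, target_side, decoy = NULL,
                       max_outer = 6L, settle_epochs = 25L, ks_alpha = 0.1,
                       verbose = FALSE) {
  other <- opposite_side(target_side)
  bg_t <- init_background(spec, target_side, contour)
  obs_o <- if (is.null(decoy)) contour[0, ] else decoy
  bg_o <- init_background(spec, other, obs_o)
  bg_t <- settle_background(bg_t, contour, spec, target_side,
                            max_epochs = settle_epochs)
  bg_o <- settle_background(bg_o, obs_o, spec, other,
                            max_epochs = settle_epochs)
  ks_stats <- c(cc = NA_real_, bc = NA_real_)
  converged <- max_outer == 0L
  for (it in seq_len(max_outer)) {
    nn <- target_nn_sets(contour, bg_t, spec, target_side)
    t_cc <- suppressWarnings(ks.test(nn$cc, nn$bb))
    t_bc <- suppressWarnings(ks.test(nn$bc, nn$bb))
    ks_stats <- c(cc = unname(t_cc$statistic), bc = unname(t_bc$statistic))
    if (verbose) {
      message(sprintf(
        "outer %d: cc {%s} bb_q {%s} bc {%s} | KS cc %.2f (p %.3f) bc %.2f (p %.3f)",
        it, paste(round(sort(nn$cc), 2), collapse = ","),
        paste(round(quantile(nn$bb, c(.1, .5, .9)), 2), collapse = ","),
        paste(round(sort(nn$bc), 2), collapse = ","),
        t_cc$statistic, t_cc$p.value, t_bc$statistic, t_bc$p.value))
    }
    if (t_cc$p.value > ks_alpha && t_bc$p.value > ks_alpha) {
      converged <- TRUE
      break
    }
    cand <- match_contour_steps(contour, nn$bb, spec, target_side)
    if (!is.null(cand)) {
      contour <- cand
      keep <- min_dist_to(bg_t, contour) >= spec$min_separation
      n_removed <- sum(!keep)
      bg_t <- bg_t[keep, , drop = FALSE]
      # replace displaced edges so hemifield density carries no cue
      bg_t <- replenish_background(bg_t, contour, spec, target_side, n_removed)
    }
    bg_t <- settle_background(bg_t, contour, spec, target_side,
                              max_epochs = 15L, min_epochs = 8L)
  }
  if (!converged) {
    abort(sprintf(
      "Distance matching did not converge: KS(cc,bb) = %.3f, KS(bc,bb) = %.3f after %d iterations.",
      ks_stats[["cc"]], ks_stats[["bc"]], max_outer),
      class = "afield_embedding_failure")
  }
  assemble <- function(edges, side, role, order = NA_integer_) {
    if (nrow(edges) == 0L) return(NULL)
    tibble(hemifield = side, role = role,
           contour_order = if (length(order) == 1L && is.na(order)) {
             rep(NA_integer_, nrow(edges))
           } else order,
           x = edges$x, y = edges$y, theta = edges$theta)
  }
  out <- bind_rows(
    assemble(contour, target_side, "contour", seq_len(nrow(contour))),
    if (!is.null(decoy)) assemble(decoy, other, "decoy", seq_len(nrow(decoy))),
    assemble(bg_t, target_side, "background"),
    assemble(bg_o, other, "background")
  )
  out$target_side <- target_side
  out
}

#' Embed a contour among distance-matched distractors
#'
#' Fills both hemifields with randomly oriented background edges (jittered
#' grid at the spacing of the ensemble), relaxes them by Brownian motion under
#' a minimum-separation constraint until the background nearest-neighbour
#' (NN) distance distribution is stationary, and then iteratively replaces the
#' contour's step lengths with draws matched to the measured background NN
#' distribution until the three NN distance distributions
#' (background-background, background-contour, contour-contour) are
#' statistically indistinguishable. After embedding, local element density
#' carries no information about the contour's location: only the relative
#' alignment of the edges does.
#'
#' @param contour A contour tibble lying entirely in one hemifield.
#' @param spec An [ensemble_spec()].
#' @param seed Optional integer seed.
#' @param max_outer Maximum distance-matching iterations before an
#'   embedding-failure error (which reports the final KS statistics).
#' @return A stimulus tibble (one row per edge) with columns `hemifield`,
#'   `role`, `contour_order`, `x`, `y`, `theta`, `target_side`.
#' @export
embed_contour <- function(contour, spec, seed = NULL, max_outer = 6L) {
  stopifnot(inherits(spec, "ensemble_spec"))
  if (!is.null(seed)) withr::local_seed(seed)
  side <- if (mean(contour$x) < 0) "left" else "right"
  if (!(all(contour$x <= 0) || all(contour$x >= 0))) {
    abort("The contour must lie entirely in one hemifield.",
          class = "afield_parameter_error")
  }
  embed_core(contour, spec, side, max_outer = max_outer)
}

#' Add a decoy path on the non-target hemifield
#'
#' Suppresses residual higher-order positional cues by placing a second path
#' with the positional statistics of a contour -- the template's step lengths
#' are copied exactly -- but uniformly random edge directions on the hemifield
#' opposite the target. Background edges colliding with the decoy are removed
#' and the hemifield is re-settled by Brownian motion.
#'
#' @param stimulus A stimulus tibble from [embed_contour()].
#' @param spec The [ensemble_spec()] used to build the stimulus.
#' @param contour_template Optional contour whose positional steps the decoy
#'   copies; defaults to the stimulus's own contour.
#' @param seed Optional integer seed.
#' @param max_tries Placement attempts before an error.
#' @return The stimulus with `role = "decoy"` rows added on the non-target
#'   side.
#' @export
add_decoy_path <- function(stimulus, spec, contour_template = NULL, seed = NULL,
                           max_tries = 200L) {
  if (!is.null(seed)) withr::local_seed(seed)
  target_side <- stimulus$target_side[1]
  other <- opposite_side(target_side)
  if (is.null(contour_template)) {
    contour_template <- stimulus %>%
      filter(.data$role == "contour") %>%
      arrange(.data$contour_order) %>%
      select("x", "y", "theta")
  }
  decoy <- make_decoy(contour_template, spec, other, max_tries)
  bg <- stimulus %>% filter(.data$role == "background", .data$hemifield == other)
  keep <- min_dist_to(bg, decoy) >= spec$min_separation
  bg <- bg[keep, , drop = FALSE]
  bg_settled <- settle_background(bg[, c("x", "y", "theta")],
                                  decoy, spec, other,
                                  max_epochs = 15L, min_epochs = 5L)
  bg[, c("x", "y", "theta")] <- bg_settled
  decoy_rows <- tibble(
    hemifield = other, role = "decoy",
    contour_order = seq_len(nrow(decoy)),
    x = decoy$x, y = decoy$y, theta = decoy$theta,
    target_side = target_side
  )
  extra <- setdiff(names(stimulus), names(decoy_rows))
  for (col in extra) decoy_rows[[col]] <- stimulus[[col]][1]
  bind_rows(
    stimulus %>% filter(!(.data$role == "background" & .data$hemifield == other)),
    bg,
    decoy_rows[names(stimulus)]
  )
}

# Mirror the template into the opposite hemifield with a random in-field
# translation; mirroring preserves all step lengths exactly.
make_decoy <- function(template, spec, side, max_tries = 200L) {
  reg <- hemifield_region(spec, side)
  mx <- -template$x
  my <- template$y
  wx <- range(mx); wy <- range(my)
  for (k in seq_len(max_tries)) {
    ox <- runif(1, reg[1] - wx[1], reg[2] - wx[2])
    oy <- runif(1, reg[3] - wy[1], reg[4] - wy[2])
    if (ox + wx[1] >= reg[1] && ox + wx[2] <= reg[2] &&
        oy + wy[1] >= reg[3] && oy + wy[2] <= reg[4]) {
      return(edge_tbl(mx + ox, my + oy, runif(length(mx), 0, 2 * pi)))
    }
  }
  abort("Decoy placement failed: template does not fit the hemifield.",
        class = "afield_placement_failure")
}

#' Mask of a stimulus
#'
#' The mask shares every edge position with the stimulus but has all
#' directions redrawn uniformly at random; contour membership is erased.
#'
#' @param stimulus A stimulus tibble.
#' @param seed Optional integer seed.
#' @return A tibble with the same rows and positions, `role = "mask"`,
#'   `contour_order = NA`, and fresh uniform directions.
#' @export
make_mask <- function(stimulus, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  mutate(stimulus,
         theta = runif(dplyr::n(), 0, 2 * pi),
         role = "mask",
         contour_order = NA_integer_)
}

#' Build a contour ensemble
#'
#' Generates `n_stimuli` stimuli for one ensemble: contours sampled from the
#' generating association field (overlaps repaired), embedded among
#' distance-matched distractors, with a decoy path on the opposite hemifield
#' and mask directions attached (`theta_mask`). Exactly half the targets lie
#' in each hemifield.
#'
#' @param spec An [ensemble_spec()].
#' @param seed Integer master seed; the same seed reproduces the ensemble
#'   exactly.
#' @param match_distances If `TRUE` (default), run the iterative
#'   distance-matching loop so that local density carries no cue to the
#'   contour's location. With `FALSE` the contour keeps the raw step
#'   statistics of the generating Markov process (the setting under which
#'   the matched-parameter observer is exactly ideal).
#' @return A long tibble of edges for all stimuli, with attribute
#'   `"ensemble_spec"`.
#' @export
build_ensemble <- function(spec, seed = NULL, match_distances = TRUE) {
  stopifnot(inherits(spec, "ensemble_spec"))
  if (!is.null(seed)) withr::local_seed(seed)
  sides <- rep(c("left", "right"), spec$n_stimuli / 2L)
  inset <- spec$spacing / 2
  stims <- vector("list", spec$n_stimuli)
  for (i in seq_len(spec$n_stimuli)) {
    side <- sides[i]
    reg <- hemifield_region(spec, side, inset = inset)
    st <- NULL
    for (attempt in 1:6) {
      contour <- NULL
      for (k in 1:50) {
        cand <- sample_contour(spec$L, spec$af, reg)
        cand <- tryCatch(
          repair_overlaps(cand, spec$min_separation, region = reg),
          afield_repair_failure = function(e) NULL
        )
        if (!is.null(cand)) { contour <- cand; break }
      }
      if (is.null(contour)) {
        abort("Could not draw an overlap-free contour for this ensemble.",
              class = "afield_sampling_failure")
      }
      st <- tryCatch(embed_core(contour, spec, side,
                                max_outer = if (match_distances) 6L else 0L),
                     afield_embedding_failure = function(e) NULL)
      if (!is.null(st)) break
    }
    if (is.null(st)) {
      abort("Distance matching failed repeatedly for this ensemble.",
            class = "afield_embedding_failure")
    }
    # the decoy copies the *matched* contour's positional steps, so that
    # neither hemifield carries a density or path-statistics cue
    st <- add_decoy_path(st, spec)
    st$stimulus_id <- sprintf("%s_%03d", spec$ensemble_id, i)
    st$ensemble_id <- spec$ensemble_id
    st$theta_mask <- runif(nrow(st), 0, 2 * pi)
    stims[[i]] <- st
  }
  out <- bind_rows(stims) %>%
    select("stimulus_id", "ensemble_id", "target_side", "hemifield", "role",
           "contour_order", "x", "y", "theta", "theta_mask")
  attr(out, "ensemble_spec") <- spec
  out
}

#' Nearest-neighbour distance statistics of embedded stimuli
#'
#' Pools, per stimulus, the three nearest-neighbour distance samples of the
#' target hemifield: background-background (`bb`), background-contour (`bc`),
#' and contour-contour (`cc`). Matching of these three distributions is what
#' removes first-order density cues to the contour's location.
#'
#' @param stimuli A stimulus tibble (one or many stimuli).
#' @param spec The generating [ensemble_spec()] (defaults to the
#'   `"ensemble_spec"` attribute of `stimuli`); used for the border
#'   correction of the `bb` sample. With `NULL` no correction is applied.
#' @return A tibble with columns `ensemble_id`, `stimulus_id`, `kind`
#'   (`"bb"`, `"bc"`, `"cc"`) and `d` (DVA).
#' @export
distance_statistics <- function(stimuli, spec = NULL) {
  if (is.null(spec)) spec <- attr(stimuli, "ensemble_spec")
  stimuli %>%
    group_by(.data$ensemble_id, .data$stimulus_id) %>%
    group_split() %>%
    purrr::map(function(st) {
      side <- st$target_side[1]
      ct <- st %>% filter(.data$role == "contour")
      bg <- st %>% filter(.data$role == "background", .data$hemifield == side)
      nn <- target_nn_sets(ct, bg, spec, side)
      tibble(ensemble_id = st$ensemble_id[1], stimulus_id = st$stimulus_id[1],
             kind = rep(c("bb", "bc", "cc"),
                        times = c(length(nn$bb), length(nn$bc), length(nn$cc))),
             d = c(nn$bb, nn$bc, nn$cc))
    }) %>%
    bind_rows()
}

#' Locate the contour from local density alone
#'
#' A control classifier that ignores edge alignment entirely: for each
#' stimulus it guesses the hemifield whose edges are more crowded (smaller
#' mean nearest-neighbour distance). On properly distance-matched stimuli it
#' performs at chance, confirming that first-order positional cues have been
#' removed.
#'
#' @param stimuli A stimulus tibble.
#' @return A tibble with one row per stimulus: `stimulus_id`, `guess`,
#'   `target_side`, `correct`.
#' @export
classify_by_density <- function(stimuli) {
  stimuli %>%
    filter(.data$role != "mask") %>%
    group_by(.data$stimulus_id) %>%
    group_split() %>%
    purrr::map(function(st) {
      mean_nn <- function(side) {
        e <- st %>% filter(.data$hemifield == side)
        mean(min_dist_to(e, e, self = TRUE))
      }
      guess <- if (mean_nn("left") < mean_nn("right")) "left" else "right"
      tibble(stimulus_id = st$stimulus_id[1], guess = guess,
             target_side = st$target_side[1],
             correct = as.integer(guess == st$target_side[1]))
    }) %>%
    bind_rows()
}
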