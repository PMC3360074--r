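test_that("ensembles are balanced, labelled and reproducible", {
  spec <- ensemble_spec(af_params(0.2, 0.4, 2.6), L = 4, n_stimuli = 8,
                        field_width = 18, field_height = 14, spacing = 2.6,
                        ensemble_id = "bal")
  st1 <- build_ensemble(spec, seed = 91)
  st2 <- build_ensemble(spec, seed = 91)
  expect_identical(st1, st2)
  expect_equal(dplyr::n_distinct(st1$stimulus_id), 8)
  sides <- st1 |> dplyr::distinct(stimulus_id, target_side)
  expect_equal(sum(sides$target_side == "left"), 4)
  expect_equal(sum(sides$target_side == "right"), 4)
  expect_true(all(st1$ensemble_id == "bal"))
  # exactly one ordered contour per stimulus, on the target side
  ct <- st1 |> dplyr::filter(role == "contour")
  per <- ct |> dplyr::count(stimulus_id)
  expect_true(all(per$n == 4))
  expect_true(all(ct$hemifield == ct$target_side))
  orders <- ct |> dplyr::group_by(stimulus_id) |>
    dplyr::summarise(ok = all(sort(contour_order) == 1:4))
  expect_true(all(orders$ok))
  expect_error(ensemble_spec(af_params(0.2, 0.4), L = 4, n_stimuli = 7),
               class = "afield_parameter_error")
})

test_that("embedding matches nearest-neighbour distance distributions", {
  pool <- small_pool()
  ds <- distance_statistics(pool$stimuli, spec = pool$spec)
  bb <- ds$d[ds$kind == "bb"]
  cc <- ds$d[ds$kind == "cc"]
  bc <- ds$d[ds$kind == "bc"]
  # pooled over 12 stimuli; small-sample noise allows a looser bound than the
  # ensemble-scale check
  expect_lt(ks_stat(cc, bb), 0.2)
  expect_lt(ks_stat(bc, bb), 0.2)
  # no element pair violates the rendering separation
  one <- pool$stimuli |> dplyr::filter(stimulus_id == "sp1_001",
                                        hemifield == target_side)
  dm <- as.matrix(stats::dist(one[, c("x", "y")]))
  diag(dm) <- Inf
  ok_pairs <- dm >= pool$spec$min_separation
  # consecutive contour edges may be closer; all other pairs must separate
  idx <- which(one$role == "contour")
  for (i in seq_along(idx)[-1]) ok_pairs[idx[i - 1], idx[i]] <- ok_pairs[idx[i], idx[i - 1]] <- TRUE
  expect_true(all(ok_pairs))
})

test_that("decoys sit opposite the target with copied steps and random directions", {
  pool <- small_pool()
  st <- pool$stimuli
  dec <- st |> dplyr::filter(role == "decoy")
  expect_true(all(dec$hemifield != dec$target_side))
  # positional step lengths match the contour's exactly (mirrored copy)
  for (sid in unique(st$stimulus_id)[1:4]) {
    one <- st |> dplyr::filter(stimulus_id == sid)
    step_len <- function(e) {
      e <- e |> dplyr::arrange(contour_order)
      sqrt(diff(e$x)^2 + diff(e$y)^2)
    }
    expect_equal(step_len(one |> dplyr::filter(role == "decoy")),
                 step_len(one |> dplyr::filter(role == "contour")),
                 tolerance = 1e-10)
  }
  # pooled decoy directions are circularly uniform
  expect_gt(rayleigh_p(dec$theta), 0.01)
})

test_that("masks share positions, erase roles, and decorrelate directions", {
  pool <- small_pool()
  one <- pool$stimuli |> dplyr::filter(stimulus_id == "sp1_002")
  m <- make_mask(one, seed = 5)
  expect_equal(m$x, one$x)
  expect_equal(m$y, one$y)
  expect_true(all(m$role == "mask"))
  expect_true(all(is.na(m$contour_order)))
  m2 <- make_mask(m, seed = 6)
  expect_equal(m2$x, one$x)
  # circular correlation between stimulus and mask directions is near zero
  allm <- make_mask(pool$stimuli, seed = 7)
  circ_cor <- function(a, b) {
    num <- sum(sin(a - mean(a)) * sin(b - mean(b)))
    den <- sqrt(sum(sin(a - mean(a))^2) * sum(sin(b - mean(b))^2))
    num / den
  }
  expect_lt(abs(circ_cor(pool$stimuli$theta, allm$theta)), 0.05)
})

test_that("stimulus tables round-trip through CSV with their sidecar", {
  pool <- small_pool()
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_stimuli(pool$stimuli, tmp, seed = 421)
  back <- read_stimuli(tmp)
  expect_equal(as.data.frame(back), as.data.frame(pool$stimuli),
               tolerance = 1e-12)
  sp <- attr(back, "ensemble_spec")
  expect_equal(sp$L, pool$spec$L)
  expect_equal(sp$af, pool$spec$af)
})

test_that("Gabor rendering behaves at its analytic anchors", {
  # empty stimulus: uniform field at mean luminance
  img <- render_gabor_image(tibble::tibble(x = numeric(0), y = numeric(0),
                                           theta = numeric(0)),
                            field_width = 2, field_height = 2)
  expect_true(all(img == 0.5))
  # an edge on an exact pixel centre at phase 0: the deviation from mean
  # luminance at that pixel equals the contrast
  pars <- gabor_render_params(contrast = 0.4, pixels_per_dva = 40)
  one <- tibble::tibble(x = 0.0125, y = 0.0125, theta = 0)
  img1 <- render_gabor_image(one, pars, field_width = 4, field_height = 4,
                             phases = 0)
  expect_equal(max(abs(img1 - 0.5)), 0.4, tolerance = 1e-10)
  # zero-mean carrier: image mean stays at mean luminance over random phases
  set.seed(17)
  st <- tibble::tibble(x = runif(30, -4, 4), y = runif(30, -4, 4),
                       theta = runif(30, 0, 2 * pi))
  means <- replicate(15, mean(suppressWarnings(
    render_gabor_image(st, pars, 10, 10))))
  expect_equal(mean(means), 0.5, tolerance = 0.005)
})
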