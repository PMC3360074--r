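test_that("performance score counts conditions with ties as reached", {
  mk <- function(id, correct_by_cond) {
    dplyr::bind_rows(lapply(seq_along(correct_by_cond), function(cc) {
      S <- 4
      corr <- c(rep(1L, correct_by_cond[cc]), rep(0L, S - correct_by_cond[cc]))
      tibble::tibble(observer_id = id, ensemble_id = sprintf("c%d", cc),
                     stimulus_id = sprintf("c%d_s%d", cc, 1:S), soa = NA_real_,
                     response = ifelse(corr == 1L, "left", "right"),
                     correct = corr)
    }))
  }
  humans <- dplyr::bind_rows(mk("h1", c(2, 3, 4)), mk("h2", c(2, 1, 4)))
  # human means: 2, 2, 4; model better in two conditions, worse in one
  expect_equal(performance_score(mk("m", c(3, 1, 4)), humans), 2 / 3)
  # identical to the mean everywhere: ties count, score 1
  expect_equal(performance_score(mk("m", c(2, 2, 4)), humans), 1)
  # at chance against above-chance humans: 0
  expect_equal(performance_score(mk("m", c(0, 0, 1)), humans), 0)
  expect_error(performance_score(mk("m", c(1, 1)), humans),
               class = "afield_alignment_error")
})

test_that("identical-response counts match direct enumeration", {
  a <- tibble::tibble(observer_id = "a", ensemble_id = "c1",
                      stimulus_id = paste0("s", 1:4), soa = NA_real_,
                      response = c("left", "left", "right", "right"),
                      correct = c(1L, 1L, 1L, 0L))
  b <- dplyr::mutate(a, observer_id = "b",
                     response = c("left", "left", "right", "left"),
                     correct = c(1L, 1L, 1L, 1L))
  expect_equal(identical_responses(a, b)$k, 3)
  expect_equal(identical_responses(a, a)$k, 4)
  compl <- dplyr::mutate(a, response = ifelse(response == "left", "right", "left"),
                         correct = 1L - correct)
  expect_equal(identical_responses(a, compl)$k, 0)
  bad <- dplyr::mutate(b, stimulus_id = paste0("z", 1:4))
  expect_error(identical_responses(a, bad), class = "afield_alignment_error")
})

test_that("the identical-response null matches exhaustive enumeration", {
  n4 <- null_pmf(4, 3, 2)
  expect_equal(n4$k, c(1, 3))
  expect_equal(n4$prob, c(0.5, 0.5))
  # degenerate: one observer all correct
  nd <- null_pmf(5, 5, 3)
  expect_equal(nd$k[nd$prob > 0], 3)
  expect_equal(sum(nd$prob), 1)
  # exact equality with brute-force placement enumeration, all S <= 6
  for (S in 2:6) for (na in 0:S) for (nb in 0:S) {
    got <- null_pmf(S, na, nb)
    want <- enumerate_null(S, na, nb)
    got <- got[got$prob > 1e-15, ]
    expect_equal(got$k, want$k, info = sprintf("S=%d na=%d nb=%d", S, na, nb))
    expect_equal(got$prob, want$prob, tolerance = 1e-12)
    # parity: k = S - na - nb (mod 2) on the whole support
    expect_true(all((got$k - (S - na - nb)) %% 2 == 0))
  }
  # normalization for larger random triples
  set.seed(141)
  for (i in 1:100) {
    S <- sample(2:50, 1); na <- sample(0:S, 1); nb <- sample(0:S, 1)
    expect_equal(sum(null_pmf(S, na, nb)$prob), 1, tolerance = 1e-12)
  }
  expect_error(null_pmf(4, 5, 1), class = "afield_parameter_error")
})

test_that("mid-p excess correlation is exactly calibrated", {
  n4 <- null_pmf(4, 3, 2)
  expect_equal(phi_pair(3, n4), 0.75)
  expect_equal(phi_pair(min(n4$k), n4), 0.5 * n4$prob[1])
  expect_warning(phi_pair(0, n4), "outside")
  # E[Phi] under the null is exactly 0.5, any (S, n_a, n_b)
  set.seed(151)
  for (i in 1:20) {
    S <- sample(2:40, 1); na <- sample(0:S, 1); nb <- sample(0:S, 1)
    null <- null_pmf(S, na, nb)
    ephi <- sum(null$prob * vapply(null$k, phi_pair, numeric(1), null = null))
    expect_equal(ephi, 0.5, tolerance = 1e-12)
  }
})

test_that("excess correlations separate shared difficulty from independence", {
  set.seed(161)
  # independent observers: Phi near 0.5 and the pair matrix is symmetric
  ind <- fake_decisions(4, 60, 24, acc = 0.75, shared = FALSE)
  ph_ind <- phi_human_human(ind)
  expect_equal(ph_ind$phi, 0.5, tolerance = 0.02)
  m <- phi_pair_matrix(ph_ind)
  expect_equal(m, t(m))
  # shared stimulus difficulty: Phi well above 0.5 and above the shuffle bar
  sh <- fake_decisions(4, 40, 24, acc = 0.75, shared = TRUE)
  ph_sh <- phi_human_human(sh)
  expect_gt(ph_sh$phi, 0.55)
  sig <- shuffle_significance(sh, n_surrogates = 100, alpha = 0.01, seed = 5)
  expect_gt(ph_sh$phi, sig$threshold)
  expect_equal(mean(sig$surrogates), 0.5, tolerance = 0.02)
})

test_that("shuffling preserves per-observer per-condition correct counts", {
  set.seed(171)
  sh <- fake_decisions(3, 10, 16, acc = 0.7, shared = TRUE)
  counts <- function(tbl) {
    dplyr::summarise(dplyr::group_by(tbl, observer_id, ensemble_id),
                     n = sum(correct), .groups = "drop")
  }
  for (i in 1:5) {
    surr <- afield:::shuffle_decisions(sh)
    expect_equal(counts(surr), counts(sh))
    # responses remain consistent with a unique target side per stimulus
    tg <- surr |>
      dplyr::mutate(target = ifelse(correct == 1L, response,
                                    ifelse(response == "left", "right", "left"))) |>
      dplyr::group_by(ensemble_id, stimulus_id) |>
      dplyr::summarise(nt = dplyr::n_distinct(target), .groups = "drop")
    expect_true(all(tg$nt == 1))
  }
})

test_that("model-human excess correlation behaves at its anchors", {
  set.seed(181)
  humans <- fake_decisions(3, 40, 24, acc = 0.75, shared = TRUE)
  # the model that copies one human correlates far above chance
  copycat <- humans |> dplyr::filter(observer_id == "o01") |>
    dplyr::mutate(observer_id = "model")
  expect_gt(phi_model_human(copycat, humans)$phi, 0.7)
  # a stimulus-scrambled model (same accuracy, no stimulus lock) is at chance
  rand <- afield:::shuffle_decisions(copycat)
  expect_equal(phi_model_human(rand, humans)$phi, 0.5, tolerance = 0.05)
})

test_that("prototype observers form a noise-reduced benchmark", {
  set.seed(191)
  humans <- fake_decisions(5, 30, 24, acc = 0.75, shared = TRUE)
  pr <- prototype_observers(humans, seed = 7)
  expect_equal(sort(unique(pr$prototypes$observer_id)),
               sort(paste0("proto_", unique(humans$observer_id))))
  expect_gte(pr$tie_rate, 0)   # 4 voters: ties possible, logged
  # identical observers: prototypes reproduce them, benchmark near its maximum
  one <- humans |> dplyr::filter(observer_id == "o01")
  clones <- dplyr::bind_rows(lapply(1:3, function(m) {
    dplyr::mutate(one, observer_id = sprintf("o%02d", m))
  }))
  prc <- prototype_observers(clones, seed = 8)
  j <- dplyr::inner_join(
    prc$prototypes |> dplyr::filter(observer_id == "proto_o01"),
    one, by = c("ensemble_id", "stimulus_id"))
  expect_true(all(j$response.x == j$response.y))
  expect_gt(prc$phi, 0.9)
  # the prototype of the real panel out-correlates a left-out human's twin
  expect_gt(pr$phi, 0.5)
  # independent observers: benchmark collapses to chance
  ind <- fake_decisions(5, 30, 24, acc = 0.75, shared = FALSE)
  pri <- prototype_observers(ind, seed = 9)
  expect_equal(pri$phi, 0.5, tolerance = 0.05)
  expect_error(prototype_observers(one), class = "afield_parameter_error")
})
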