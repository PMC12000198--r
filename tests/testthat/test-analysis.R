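# hand-built trial tables targeting single pipeline stages

make_rating_rows <- function(participant, old_ratings, new_ratings) {
  tibble::tibble(
    participant = participant, phase = "rating",
    item_a = sprintf("%s_i%03d", participant,
                     seq_along(c(old_ratings, new_ratings))),
    item_b = NA_character_,
    status = rep(c("old", "new"), c(length(old_ratings), length(new_ratings))),
    rating_a = as.integer(c(old_ratings, new_ratings)),
    rating_b = NA_integer_, pair_type = NA_character_,
    response = NA_character_, correct = NA_integer_, living_rating = NA_real_
  )
}

make_afc_rows <- function(participant, correct, pair_type = "equal",
                          rating = 1L) {
  n <- length(correct)
  tibble::tibble(
    participant = participant, phase = "afc",
    item_a = sprintf("%s_a%03d", participant, seq_len(n)),
    item_b = sprintf("%s_b%03d", participant, seq_len(n)),
    status = ifelse(pair_type == "truly_new", "truly_new", "new"),
    rating_a = as.integer(rating),
    rating_b = ifelse(pair_type == "equal", as.integer(rating), NA_integer_),
    pair_type = pair_type,
    response = "left", correct = as.integer(correct), living_rating = NA_real_
  )
}

make_study_rows <- function(participant, correct, living_rating = 650) {
  n <- length(correct)
  tibble::tibble(
    participant = participant, phase = "study",
    item_a = sprintf("%s_s%03d", participant, seq_len(n)),
    item_b = NA_character_, status = "old",
    rating_a = NA_integer_, rating_b = NA_integer_, pair_type = NA_character_,
    response = "living", correct = as.integer(correct),
    living_rating = living_rating
  )
}

# a participant with controllable filter statistics
make_participant <- function(id, study_correct = rep(1, 50),
                             tn_correct = rep(1, 20),
                             n_rating1 = 5L, rating1_correct = NULL) {
  rating1_correct <- rating1_correct %||% rep(1L, n_rating1)
  dplyr::bind_rows(
    make_study_rows(id, study_correct),
    make_rating_rows(id, rep(c(1, 4), c(10, 20)), rep(c(1, 4), c(20, 10))),
    if (n_rating1 > 0) make_afc_rows(id, rating1_correct, "equal", 1L),
    make_afc_rows(id, rep(1L, 10), "equal", 4L),
    make_afc_rows(id, tn_correct, "truly_new", 4L)
  )
}
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("exclusion filters use strict thresholds and the clear-word subset", {
  trials <- dplyr::bind_rows(
    make_participant("ok"),
    # 84% on clear words (21/25), perfect on ambiguous ones: excluded
    dplyr::bind_rows(
      make_study_rows("low_study", c(rep(1, 21), rep(0, 4)), 650),
      make_study_rows("low_study", rep(1, 25), 400)
    ) |> dplyr::bind_rows(
      make_rating_rows("low_study", rep(4, 30), rep(1, 30)),
      make_afc_rows("low_study", rep(1L, 5), "equal", 1L),
      make_afc_rows("low_study", rep(1L, 20), "truly_new", 4L)
    ),
    # exactly 60% truly-new accuracy (12/20): retained
    make_participant("tn_60", tn_correct = rep(c(1, 0), c(12, 8))),
    # 55% truly-new accuracy: excluded
    make_participant("tn_55", tn_correct = rep(c(1, 0), c(11, 9))),
    # only 2 rating-1 equal pairs: retained but not critically eligible
    make_participant("few_crit", n_rating1 = 2L)
  )
  res <- apply_exclusions(trials)
  rep <- res$report
  expect_identical(rep$excluded[rep$participant == "low_study"], TRUE)
  expect_identical(rep$reason[rep$participant == "low_study"], "study")
  expect_identical(rep$excluded[rep$participant == "tn_60"], FALSE)
  expect_identical(rep$excluded[rep$participant == "tn_55"], TRUE)
  expect_identical(rep$critical_eligible[rep$participant == "few_crit"], FALSE)
  expect_identical(rep$excluded[rep$participant == "few_crit"], FALSE)
  expect_setequal(unique(res$kept$participant), c("ok", "tn_60", "few_crit"))
  # idempotent: filtering the kept table changes nothing
  res2 <- apply_exclusions(res$kept)
  expect_identical(res2$kept, res$kept)
})

test_that("rating distribution gives per-status percentages summing to 100", {
  trials <- make_rating_rows("p1", c(rep(4, 7), 3, 2, 1), rep(1, 10))
  rd <- rating_distribution(trials)
  old <- rd[rd$status == "old", ]
  expect_equal(old$percent[match(1:4, old$rating)], c(10, 10, 10, 70))
  sums <- tapply(rd$percent, rd$status, sum)
  expect_true(all(abs(sums - 100) < 0.01))
})

test_that("binary d-prime matches the z-transform and handles degenerate rates", {
  # H = 0.84 (42/50), FA = 0.16 (8/50): d' = 1.989
  trials <- make_rating_rows("p1", rep(c(4, 1), c(42, 8)), rep(c(4, 1), c(8, 42)))
  dp <- dprime_binary(trials)
  expect_equal(dp$mean_d_prime, 1.989, tolerance = 1e-3)
  # H = FA gives 0
  sym <- make_rating_rows("p2", rep(c(4, 1), c(20, 20)), rep(c(4, 1), c(20, 20)))
  expect_equal(dprime_binary(sym)$mean_d_prime, 0)
  # perfect participant: log-linear correction keeps d' finite
  perf <- make_rating_rows("p3", rep(4, 30), rep(1, 30))
  dpp <- dprime_binary(perf)
  expect_true(is.finite(dpp$mean_d_prime))
  expect_true(dpp$by_participant$corrected)
})

test_that("mean d-prime recovers the generating separation", {
  s_obs <- sqrt(1 + 0.8^2)
  cfg <- experiment_config(n_participants = 30, sd_mu_participant = 0,
                           sdt = sdt_params(mu_old = 2.03 * s_obs, sd_old = 1,
                                            sd_error = 0.8),
                           criteria = c(0.03, 0.75, 1.20) * s_obs)
  dps <- sapply(1:6, function(s) {
    tr <- simulate_experiment(cfg, seed = 500 + s)
    dprime_binary(tr)$mean_d_prime
  })
  expect_lt(abs(mean(dps) - 2.03), 0.1)
})

test_that("ML fit recovers d' and criteria from exact expected counts", {
  d <- 2; cr <- c(0.03, 0.75, 1.20); n <- 1e5
  cuts <- c(-Inf, cr, Inf)
  counts <- list(old = round(diff(pnorm(cuts, mean = d)) * n),
                 new = round(diff(pnorm(cuts)) * n))
  fit <- fit_criteria_mle(counts)
  expect_equal(fit$d_prime, d, tolerance = 0.02)
  expect_equal(fit$criteria, cr, tolerance = 0.02)
  # invariance to doubling all counts
  fit2 <- fit_criteria_mle(list(old = 2 * counts$old, new = 2 * counts$new))
  expect_equal(fit2$d_prime, fit$d_prime, tolerance = 1e-4)
  expect_equal(fit2$criteria, fit$criteria, tolerance = 1e-4)
  # symmetric counts: no separation
  sym <- fit_criteria_mle(list(old = counts$new, new = counts$new))
  expect_lt(abs(sym$d_prime), 1e-3)
  # tidy/glance accessors
  expect_identical(tidy(fit)$term, c("d_prime", "c1", "c2", "c3"))
  expect_identical(nrow(glance(fit)), 1L)
})

test_that("ML fit reports empty categories instead of hiding them", {
  fit <- fit_criteria_mle(list(old = c(0, 10, 20, 70), new = c(0, 60, 30, 10)))
  expect_identical(fit$collapsed_categories, 1L)
})

test_that("2AFC t-tests reproduce the hand-computed record", {
  trials <- dplyr::bind_rows(
    make_afc_rows("a", rep(c(1, 0), c(6, 4))),   # 0.6
    make_afc_rows("b", rep(c(1, 0), c(7, 3))),   # 0.7
    make_afc_rows("c", rep(c(1, 0), c(8, 2)))    # 0.8
  )
  rec <- afc_tests(trials)
  overall <- rec[rec$test == "overall", ]
  expect_equal(overall$t, 3.464, tolerance = 1e-3)
  expect_equal(overall$df, 2)
  expect_equal(overall$d_z, 2.0, tolerance = 1e-6)
  crit <- rec[rec$test == "rating1_equal", ]
  expect_equal(crit$t, overall$t)  # same data feed both subsets here
  # all-chance accuracies give t = 0
  null_tr <- dplyr::bind_rows(
    make_afc_rows("a", rep(c(1, 0), 5)),
    make_afc_rows("b", rep(c(1, 0), 5)),
    make_afc_rows("c", rep(c(1, 0), 5))
  )
  expect_equal(afc_tests(null_tr)$t[1], 0)
})

test_that("split-half reliability hits both limiting cases", {
  # ratings fixed within participant: halves identical, coefficient 1
  trials <- dplyr::bind_rows(purrr::map_dfr(1:8, function(i) {
    make_rating_rows(paste0("p", i), rep(min(i, 4), 20), rep(1, 20))
  }))
  sh <- split_half_reliability(trials, n_splits = 20, seed = 1)
  expect_equal(sh$reliability, 1)
  # ratings independent of status and participant: coefficient ~ 0 on
  # average (each dataset's split-mean keeps sampling noise of order
  # 1/sqrt(participants), so average over datasets)
  set.seed(2)
  rels <- sapply(1:3, function(k) {
    null_tr <- purrr::map_dfr(1:60, function(i) {
      make_rating_rows(paste0("p", i), sample(1:4, 30, TRUE), sample(1:4, 30, TRUE))
    })
    split_half_reliability(null_tr, n_splits = 150, seed = k)$reliability
  })
  expect_lt(abs(mean(rels)), 0.25)
})

test_that("reliability falls as rating noise grows", {
  rels <- sapply(c(0.4, 0.8, 1.6), function(se) {
    cfg <- experiment_config(n_participants = 40,
                             sdt = sdt_params(mu_old = 2.6, sd_error = se))
    tr <- simulate_experiment(cfg, seed = 71)
    split_half_reliability(apply_exclusions(tr)$kept,
                           n_splits = 150, seed = 8)$reliability
  })
  expect_true(all(diff(rels) < 0))
})

test_that("random-intercept logistic model collapses to plain logistic", {
  # zero between-participant variance, rating-1 accuracy 0.65 exactly
  trials <- purrr::map_dfr(1:50, function(i) {
    dplyr::bind_rows(
      make_afc_rows(paste0("p", i), rep(c(1, 0), c(13, 7)), "equal", 1L),
      make_afc_rows(paste0("p", i), rep(c(1, 0), c(18, 2)), "equal", 4L),
      make_afc_rows(paste0("p", i), rep(c(1, 0), c(4, 1)), "truly_new", 4L),
      make_afc_rows(paste0("p", i), rep(1L, 3), "unequal", 2L)
    )
  })
  rec <- fit_random_intercept_logistic(trials)
  expect_equal(rec$b, qlogis(0.65), tolerance = 0.02)
  expect_equal(rec$accuracy, 0.65, tolerance = 0.005)
  expect_identical(rec$n_trials, 50L * 40L)  # unequal + truly-new dropped
  expect_lt(rec$p, 0.001)
  td <- tidy(rec)
  expect_identical(td$term, "(Intercept)")
  # back-transform agrees with raw pooled accuracy when RE variance is small
  expect_lt(abs(rec$accuracy - 0.65), 0.05)
})

test_that("GLMM recovers a known intercept with participant heterogeneity", {
  set.seed(9)
  b0 <- 0.6; sd_u <- 0.5
  trials <- purrr::map_dfr(1:200, function(i) {
    u <- rnorm(1, 0, sd_u)
    make_afc_rows(paste0("p", i),
                  rbinom(8, 1, plogis(b0 + u)), "equal", 1L)
  })
  rec <- fit_random_intercept_logistic(trials)
  expect_lt(abs(rec$b - b0), 2 * rec$se)
})

test_that("accuracy/trial-count correlation matches hand computations", {
  trials <- dplyr::bind_rows(
    make_afc_rows("a", rep(c(1, 0), c(3, 0))),           # n=3, acc 1.0
    make_afc_rows("b", rep(c(1, 0), c(3, 2))),           # n=5, acc 0.6
    make_afc_rows("c", rep(c(1, 0), c(2, 5))),           # n=7, acc ~0.286
    make_afc_rows("d", rep(c(1, 0), c(2, 2)))            # n=4, acc 0.5
  )
  out <- accuracy_trialcount_correlation(trials)
  acc <- c(1, 0.6, 2 / 7, 0.5); n <- c(3, 5, 7, 4)
  expect_equal(out$r, cor(acc, n), tolerance = 1e-10)
  expect_equal(out$df, 2)
  # perfectly linear in trial count: accuracies 1, 0.75, 0.5 at n = 2, 4, 6
  lin <- dplyr::bind_rows(
    make_afc_rows("a", rep(1L, 2)),
    make_afc_rows("b", rep(c(1, 0), c(3, 1))),
    make_afc_rows("c", rep(c(1, 0), c(3, 3)))
  )
  lout <- accuracy_trialcount_correlation(lin, min_critical_trials = 2L)
  expect_equal(lout$r, -1, tolerance = 1e-10)
  expect_error(accuracy_trialcount_correlation(make_afc_rows("a", rep(1, 5))),
               "Too few")
})

test_that("noncentral-t sample sizes match the power targets", {
  expect_identical(power_n_one_sample_t(0.3, 0.80, 0.05, "one"), 71L)
  expect_identical(power_n_one_sample_t(0.5, 0.80, 0.05, "one"), 27L)
  # power is nondecreasing in n at fixed effect size
  pw <- sapply(c(20, 40, 80), function(n) {
    crit <- qt(0.95, n - 1)
    pt(crit, n - 1, ncp = 0.3 * sqrt(n), lower.tail = FALSE)
  })
  expect_true(all(diff(pw) > 0))
  # two-tailed needs more participants than one-tailed
  expect_gt(power_n_one_sample_t(0.3, 0.80, 0.05, "two"),
            power_n_one_sample_t(0.3, 0.80, 0.05, "one"))
})

test_that("the full pipeline wrapper returns a coherent report", {
  cfg <- experiment_config(n_participants = 15)
  tr <- simulate_experiment(cfg, seed = 81)
  rep <- analyze_experiment(tr, n_splits = 60, seed = 4)
  expect_s3_class(rep, "analysis_report")
  expect_lte(rep$n_kept, rep$n_total)
  expect_true(all(c("overall") %in% rep$afc_tests$test))
  g <- glance(rep)
  expect_identical(nrow(g), 1L)
  td <- tidy(rep)
  expect_true(all(c("d_prime_binary", "split_half_reliability") %in% td$statistic))
  sums <- tapply(rep$rating_distribution$percent,
                 rep$rating_distribution$status, sum)
  expect_true(all(abs(sums - 100) < 0.01))
})
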