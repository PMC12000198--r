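#' Apply participant-level exclusion filters
#'
#' Two exclusion rules plus one analysis flag: (a) exclude participants with
#' study-phase accuracy strictly below `study_threshold`, computed only on
#' clearly living (`living_rating > 600`) or clearly nonliving (`< 200`)
#' words; (b) exclude participants with accuracy strictly below
#' `truly_new_threshold` on the truly-new 2AFC pairs (exactly the threshold
#' passes); and participants with fewer than `min_critical_trials`
#' equal-rating pairs rated 1 are retained overall but flagged ineligible
#' for the critical rating-1 test. The filters are idempotent and
#' order-independent.
#'
#' @param trials A trial table from [simulate_experiment()] or
#'   [read_trials()].
#' @param study_threshold,truly_new_threshold,min_critical_trials The
#'   filter constants.
#' @return A list with `kept` (the filtered trial table) and `report` (a
#'   per-participant tibble with the filter statistics, `excluded`,
#'   `reason` and `critical_eligible`).
#' @export
apply_exclusions <- function(trials, study_threshold = 0.85,
                             truly_new_threshold = 0.60,
                             min_critical_trials = 3L) {
  for (ph in c("study", "rating", "afc")) {
    if (!any(trials$phase == ph)) {
      stop("Trial table is missing phase '", ph, "'.", call. = FALSE)
    }
  }
  has_norms <- "living_rating" %in% names(trials) &&
    any(!is.na(trials$living_rating[trials$phase == "study"]))
  study <- dplyr::filter(trials, .data$phase == "study")
  if (has_norms) {
    study <- dplyr::filter(study, .data$living_rating > 600 | .data$living_rating < 200)
  }
  study_acc <- study |>
    dplyr::summarise(study_acc_clear = mean(.data$correct),
                     .by = "participant")
  tn_acc <- trials |>
    dplyr::filter(.data$phase == "afc", .data$pair_type == "truly_new") |>
    dplyr::summarise(truly_new_acc = mean(.data$correct), .by = "participant")
  crit_n <- trials |>
    dplyr::filter(.data$phase == "afc", .data$pair_type == "equal",
                  .data$rating_a == 1L) |>
    dplyr::count(.data$participant, name = "n_rating1_equal")
  report <- study_acc |>
    dplyr::left_join(tn_acc, by = "participant") |>
    dplyr::left_join(crit_n, by = "participant") |>
    dplyr::mutate(
      n_rating1_equal = dplyr::coalesce(.data$n_rating1_equal, 0L),
      fail_study = .data$study_acc_clear < study_threshold,
      fail_truly_new = .data$truly_new_acc < truly_new_threshold,
      excluded = .data$fail_study | .data$fail_truly_new,
      reason = dplyr::case_when(
        fail_study & fail_truly_new ~ "study+truly_new",
        fail_study ~ "study",
        fail_truly_new ~ "truly_new",
        .default = NA_character_
      ),
      critical_eligible = !.data$excluded &
        .data$n_rating1_equal >= min_critical_trials
    ) |>
    dplyr::select(-"fail_study", -"fail_truly_new")
  kept_ids <- report$participant[!report$excluded]
  list(
    kept = dplyr::filter(trials, .data$participant %in% kept_ids),
    report = report
  )
}

#' Rating percentage distribution by item status
#'
#' Percentages of old and of new items receiving each confidence rating,
#' pooled over participants; each status row sums to 100.
#'
#' @param kept A (filtered) trial table.
#' @return A tibble with columns `status`, `rating`, `n`, `percent`.
#' @export
rating_distribution <- function(kept) {
  kept |>
    dplyr::filter(.data$phase == "rating") |>
    dplyr::count(.data$status, rating = .data$rating_a) |>
    tidyr::complete(.data$status, rating = 1:4, fill = list(n = 0L)) |>
    dplyr::mutate(percent = 100 * .data$n / sum(.data$n), .by = "status")
}

# hit/false-alarm rates with a log-linear correction (add 0.5 to the cell,
# 1 to the denominator) applied only to participants with a 0 or 1 rate.
rate_corrected <- function(k, n) {
  p <- k / n
  degenerate <- p == 0 | p == 1
  p[degenerate] <- (k[degenerate] + 0.5) / (n[degenerate] + 1)
  p
}

#' Binary d-prime from confidence ratings
#'
#' Collapses ratings 3-4 to "old" responses: hits are old items rated >= 3,
#' false alarms new items rated >= 3. Per participant
#' `d' = z(H) - z(FA)`; degenerate rates (0 or 1) get a log-linear
#' correction (add 0.5 to the cell and 1 to the denominator) before the
#' z-transform.
#'
#' @param kept A (filtered) trial table.
#' @return A list with `by_participant` (tibble: `participant`, `hit_rate`,
#'   `fa_rate`, `d_prime`, `n_corrected` flag) and `mean_d_prime`.
#' @export
dprime_binary <- function(kept) {
  by_p <- kept |>
    dplyr::filter(.data$phase == "rating") |>
    dplyr::summarise(
      hits = sum(.data$status == "old" & .data$rating_a >= 3L),
      n_old = sum(.data$status == "old"),
      fas = sum(.data$status == "new" & .data$rating_a >= 3L),
      n_new = sum(.data$status == "new"),
      .by = "participant"
    ) |>
    dplyr::mutate(
      corrected = .data$hits %in% c(0L, .data$n_old) |
        .data$fas %in% c(0L, .data$n_new),
      hit_rate = rate_corrected(.data$hits, .data$n_old),
      fa_rate = rate_corrected(.data$fas, .data$n_new),
      d_prime = stats::qnorm(.data$hit_rate) - stats::qnorm(.data$fa_rate)
    ) |>
    dplyr::select("participant", "hit_rate", "fa_rate", "d_prime", "corrected")
  list(by_participant = by_p, mean_d_prime = mean(by_p$d_prime))
}

# negative multinomial log-likelihood of pooled rating counts under the
# equal-variance Gaussian rating model; theta = (d', c1, log dc2, log dc3).
rating_negll <- function(theta, counts_old, counts_new) {
  d <- theta[1L]
  cr <- cumsum(c(theta[2L], exp(theta[3L]), exp(theta[4L])))
  cuts_new <- c(-Inf, cr, Inf)
  p_new <- diff(stats::pnorm(cuts_new))
  p_old <- diff(stats::pnorm(cuts_new, mean = d))
  eps <- 1e-12
  -sum(counts_new * log(pmax(p_new, eps))) -
    sum(counts_old * log(pmax(p_old, eps)))
}

#' Maximum-likelihood d-prime and criteria from rating counts
#'
#' Fits the equal-variance Gaussian confidence-rating model to the pooled
#' 4-category rating counts of old and new items by maximising the
#' multinomial likelihood. Criteria are reported relative to the new-item
#' mean (0) in new-item SD units. Optimised by BFGS on an unconstrained
#' parameterisation (criterion increments on the log scale), with a
#' method-of-moments start from the cumulative-proportion z-values plus
#' jittered multistarts; relative tolerance 1e-8.
#'
#' Empty rating categories make adjacent cutpoints unidentifiable; the fit
#' reports them via `collapsed_categories` rather than silently fixing them.
#'
#' @param kept A (filtered) trial table, or a named list with numeric
#'   vectors `old` and `new` of 4 rating counts each.
#' @param n_starts Number of jittered multistarts beyond the
#'   method-of-moments start.
#' @return An object of class `sdt_mle`: `d_prime`, `criteria` (length 3),
#'   `logLik`, `counts`, `convergence`, `collapsed_categories`.
#' @export
fit_criteria_mle <- function(kept, n_starts = 4L) {
  if (is.data.frame(kept)) {
    rt <- dplyr::filter(kept, .data$phase == "rating")
    counts_old <- tabulate(rt$rating_a[rt$status == "old"], nbins = 4L)
    counts_new <- tabulate(rt$rating_a[rt$status == "new"], nbins = 4L)
  } else {
    counts_old <- kept$old
    counts_new <- kept$new
  }
  stopifnot(length(counts_old) == 4L, length(counts_new) == 4L)
  pooled <- counts_old + counts_new
  collapsed <- which(pooled == 0)

  # method-of-moments start: z of cumulative new-item proportions
  n_new <- sum(counts_new)
  n_old <- sum(counts_old)
  cum_new <- pmin(pmax(cumsum(counts_new)[1:3] / n_new, 0.02), 0.98)
  cum_old <- pmin(pmax(cumsum(counts_old)[1:3] / n_old, 0.02), 0.98)
  c0 <- stats::qnorm(cum_new)
  c0 <- cummax(c0 + seq(0, 0.02, length.out = 3))  # enforce increasing
  d0 <- mean(c0 - stats::qnorm(cum_old))
  start <- c(d0, c0[1L], log(max(diff(c0)[1L], 0.05)), log(max(diff(c0)[2L], 0.05)))

  starts <- c(list(start), purrr::map(seq_len(n_starts), function(i) {
    start + c(0.3, 0.3, 0.4, 0.4) * stats::qnorm((i %% 7 + 1) / 8) * i %% 3
  }))
  fits <- purrr::map(starts, function(s) {
    stats::optim(s, rating_negll, counts_old = counts_old, counts_new = counts_new,
                 method = "BFGS", control = list(reltol = 1e-8, maxit = 500))
  })
  best <- fits[[which.min(purrr::map_dbl(fits, "value"))]]
  cr <- cumsum(c(best$par[2L], exp(best$par[3L]), exp(best$par[4L])))
  structure(
    list(d_prime = best$par[1L], criteria = cr, logLik = -best$value,
         counts = list(old = counts_old, new = counts_new),
         convergence = best$convergence,
         collapsed_categories = collapsed),
    class = "sdt_mle"
  )
}

#' @export
print.sdt_mle <- function(x, ...) {
  cat(sprintf("<sdt_mle: d' = %.3f, criteria = (%.3f, %.3f, %.3f), logLik = %.1f>\n",
              x$d_prime, x$criteria[1], x$criteria[2], x$criteria[3], x$logLik))
  if (length(x$collapsed_categories)) {
    cat("  note: empty rating categories ", toString(x$collapsed_categories),
        " leave adjacent criteria unidentified\n", sep = "")
  }
  invisible(x)
}

# one-sample t-test record against mu0 with d_z effect size; written out
# explicitly so a zero-variance sample at mu0 yields t = 0 rather than an
# error (a possible corner for all-chance accuracy vectors)
t_record <- function(x, mu0 = 0.5, label = "test") {
  n <- length(x)
  if (n < 2L) stop("Need at least two participants for a t-test.", call. = FALSE)
  m <- mean(x)
  s <- stats::sd(x)
  t_stat <- if (s == 0) {
    if (m == mu0) 0 else sign(m - mu0) * Inf
  } else {
    (m - mu0) / (s / sqrt(n))
  }
  tibble::tibble(
    test = label, n = n, mean = m, sd = s,
    t = t_stat, df = n - 1,
    p_two_sided = 2 * stats::pt(-abs(t_stat), df = n - 1),
    p_one_sided = stats::pt(t_stat, df = n - 1, lower.tail = FALSE),
    d_z = if (s == 0) t_stat / sqrt(n) else (m - mu0) / s
  )
}

#' Per-participant 2AFC accuracies
#'
#' Accuracy (proportion of pairs where the old word was chosen) per
#' participant, on three subsets: all 60 pairs, the truly-new pairs, and
#' the critical equal-rating pairs rated 1.
#'
#' @param kept A (filtered) trial table.
#' @return A tibble: `participant`, `overall_acc`, `truly_new_acc`,
#'   `rating1_acc`, `n_rating1` (rating-1 equal-pair trial count; accuracy
#'   is `NA` when the count is 0).
#' @export
afc_accuracy <- function(kept) {
  afc <- dplyr::filter(kept, .data$phase == "afc")
  afc |>
    dplyr::summarise(
      overall_acc = mean(.data$correct),
      truly_new_acc = mean(.data$correct[.data$pair_type == "truly_new"]),
      rating1_acc = mean(.data$correct[.data$pair_type == "equal" &
                                         .data$rating_a == 1L]),
      n_rating1 = sum(.data$pair_type == "equal" & .data$rating_a == 1L),
      .by = "participant"
    )
}

#' One-sample t-tests of 2AFC accuracy against chance
#'
#' Tests mean accuracy against 0.5 for (i) all pairs and (ii) the critical
#' equal-rating pairs rated 1, the latter restricted to participants with
#' at least `min_critical_trials` such pairs. Reports t, df, two- and
#' one-sided p, and `d_z` (mean difference / SD of differences).
#'
#' @param kept A (filtered) trial table.
#' @param min_critical_trials Minimum rating-1 equal-pair count for the
#'   critical test.
#' @return A tibble of test records, one row per test.
#' @export
afc_tests <- function(kept, min_critical_trials = 3L) {
  acc <- afc_accuracy(kept)
  crit <- dplyr::filter(acc, .data$n_rating1 >= min_critical_trials)
  recs <- list(t_record(acc$overall_acc, 0.5, "overall"))
  if (nrow(crit) >= 2L) {
    recs <- c(recs, list(t_record(crit$rating1_acc, 0.5, "rating1_equal")))
  }
  dplyr::bind_rows(recs)
}

#' Spearman-Brown split-half reliability of the recognition task
#'
#' For each of `n_splits` random splits of the 120 rating trials into
#' halves (stratified 30/30 within old and new items, split by trial serial
#' position so the same split applies to every participant), computes each
#' participant's half-score — mean rating of old minus mean rating of new
#' items — in both halves, correlates the half-scores across participants,
#' applies the Spearman-Brown step-up `2r / (1 + r)`, and averages over
#' splits. Splits where either half has zero between-participant variance
#' are skipped and counted.
#'
#' @param kept A (filtered) trial table with at least 2 participants.
#' @param n_splits Number of random splits.
#' @param seed Optional integer seed.
#' @return A list: `reliability` (mean corrected coefficient), `n_splits`,
#'   `n_degenerate`, `split_sd` (SD of the coefficient over splits).
#' @export
split_half_reliability <- function(kept, n_splits = 5000, seed = NULL) {
  rt <- kept |>
    dplyr::filter(.data$phase == "rating") |>
    dplyr::arrange(.data$participant) |>
    dplyr::mutate(pos = dplyr::row_number(), .by = c("participant", "status"))
  ids <- unique(rt$participant)
  if (length(ids) < 2L) stop("Need at least two participants.", call. = FALSE)
  mat <- function(st) {
    m <- rt |>
      dplyr::filter(.data$status == st) |>
      tidyr::pivot_wider(id_cols = "participant", names_from = "pos",
                         values_from = "rating_a") |>
      dplyr::arrange(.data$participant)
    as.matrix(m[, -1L, drop = FALSE])
  }
  m_old <- mat("old")
  m_new <- mat("new")
  n_old <- ncol(m_old)
  n_new <- ncol(m_new)
  with_seed_if(seed, {
    vals <- purrr::map_dbl(seq_len(n_splits), function(i) {
      h_old <- sample.int(n_old, n_old %/% 2L)
      h_new <- sample.int(n_new, n_new %/% 2L)
      s1 <- rowMeans(m_old[, h_old, drop = FALSE]) -
        rowMeans(m_new[, h_new, drop = FALSE])
      s2 <- rowMeans(m_old[, -h_old, drop = FALSE]) -
        rowMeans(m_new[, -h_new, drop = FALSE])
      if (stats::sd(s1) == 0 || stats::sd(s2) == 0) return(NA_real_)
      r <- stats::cor(s1, s2)
      2 * r / (1 + r)
    })
    list(reliability = mean(vals, na.rm = TRUE),
         n_splits = n_splits,
         n_degenerate = sum(is.na(vals)),
         split_sd = stats::sd(vals, na.rm = TRUE))
  })
}

#' Random-intercept logistic model of 2AFC accuracy by rating
#'
#' Restricted to equal-rating pairs (different-rating and truly-new pairs
#' are dropped), fits `correct ~ factor(rating) + (1 | participant)` with a
#' binomial link by maximum likelihood with the Laplace approximation
#' (via [lme4::glmer()]). Rating 1 is the baseline, so the intercept is
#' the logit accuracy for pairs both rated "sure new"; it is returned with
#' its Wald SE, z, p and the back-transformed accuracy with a 95% CI.
#'
#' @param kept A (filtered) trial table.
#' @return An object of class `glmm_record`: `b`, `se`, `z`, `p`,
#'   `accuracy`, `ci` (length 2), `n_trials`, `n_participants`,
#'   `converged`, `messages`, and the fitted `model`.
#' @export
fit_random_intercept_logistic <- function(kept) {
  dat <- kept |>
    dplyr::filter(.data$phase == "afc", .data$pair_type == "equal") |>
    dplyr::mutate(rating = factor(.data$rating_a))
  form <- if (nlevels(dat$rating) > 1L) {
    correct ~ rating + (1 | participant)
  } else {
    correct ~ (1 | participant)  # single rating level present
  }
  fit <- lme4::glmer(form, data = dat, family = stats::binomial(), nAGQ = 1L)
  msgs <- unlist(fit@optinfo$conv$lme4$messages) %||% character()
  co <- summary(fit)$coefficients
  b <- co["(Intercept)", "Estimate"]
  se <- co["(Intercept)", "Std. Error"]
  structure(
    list(b = b, se = se, z = b / se,
         p = 2 * stats::pnorm(-abs(b / se)),
         accuracy = stats::plogis(b),
         ci = stats::plogis(b + c(-1, 1) * stats::qnorm(0.975) * se),
         n_trials = nrow(dat),
         n_participants = dplyr::n_distinct(dat$participant),
         converged = length(msgs) == 0L,
         messages = msgs,
         model = fit),
    class = "glmm_record"
  )
}

#' @export
print.glmm_record <- function(x, ...) {
  cat(sprintf(
    "<glmm_record: intercept b = %.3f (SE %.3f), z = %.2f, p = %.2g;\n  rating-1 accuracy %.3f, 95%% CI [%.3f, %.3f]; %d trials, %d participants>\n",
    x$b, x$se, x$z, x$p, x$accuracy, x$ci[1], x$ci[2],
    x$n_trials, x$n_participants))
  invisible(x)
}

#' Correlation between critical-pair accuracy and trial count
#'
#' Pearson correlation, across critically eligible participants, between
#' rating-1 equal-pair accuracy and the number of such pairs encountered,
#' with df = n - 2, a two-sided p and the Fisher-z 95% CI.
#'
#' @param kept A (filtered) trial table.
#' @param min_critical_trials Eligibility threshold on the rating-1 count.
#' @return A one-row tibble: `r`, `df`, `p`, `ci_lower`, `ci_upper`, `n`.
#' @export
accuracy_trialcount_correlation <- function(kept, min_critical_trials = 3L) {
  acc <- afc_accuracy(kept) |>
    dplyr::filter(.data$n_rating1 >= min_critical_trials)
  if (nrow(acc) < 3L) stop("Too few eligible participants to correlate.", call. = FALSE)
  ct <- stats::cor.test(acc$rating1_acc, acc$n_rating1)
  ci <- if (is.null(ct$conf.int)) c(NA_real_, NA_real_) else ct$conf.int
  tibble::tibble(
    r = unname(ct$estimate), df = unname(ct$parameter), p = ct$p.value,
    ci_lower = ci[1], ci_upper = ci[2], n = nrow(acc)
  )
}

#' Sample size for a one-sample t-test from the noncentral t
#'
#' Smallest `n` whose power reaches the target: power is
#' `P(T' > t_crit(n - 1))` for noncentral t with noncentrality
#' `d_z * sqrt(n)` (both tails summed in the two-tailed case).
#'
#' @param d_z Standardized effect size.
#' @param power Target power.
#' @param alpha Significance level.
#' @param tails `"one"` or `"two"`.
#' @param n_max Search cap.
#' @return The sample size, an integer.
#' @examples
#' power_n_one_sample_t(0.3, 0.80, 0.05, "one")  # 71
#' @export
power_n_one_sample_t <- function(d_z, power = 0.80, alpha = 0.05,
                                 tails = c("one", "two"), n_max = 1e6) {
  tails <- match.arg(tails)
  assert_number(d_z, "d_z")
  if (d_z <= 0) stop("`d_z` must be positive.", call. = FALSE)
  a <- if (tails == "one") alpha else alpha / 2
  for (n in 2:n_max) {
    ncp <- d_z * sqrt(n)
    crit <- stats::qt(1 - a, df = n - 1)
    pw <- stats::pt(crit, df = n - 1, ncp = ncp, lower.tail = FALSE)
    if (tails == "two") pw <- pw + stats::pt(-crit, df = n - 1, ncp = ncp)
    if (pw >= power) return(n)
  }
  stop("No sample size up to `n_max` reaches the target power.", call. = FALSE)
}

#' Run the full analysis pipeline on a trial table
#'
#' Applies the exclusion filters and computes every downstream statistic:
#' rating distributions, binary d-prime, maximum-likelihood d-prime and
#' criteria, 2AFC accuracy tests, split-half reliability, the
#' random-intercept logistic model, and the accuracy-by-trial-count
#' correlation.
#'
#' @param trials A trial table.
#' @param n_splits Random splits for the reliability estimate.
#' @param seed Optional integer seed (used only by the split-half
#'   resampling).
#' @param glmm Set `FALSE` to skip the mixed model (e.g. in large
#'   replication loops).
#' @return An object of class `analysis_report`; see [tidy()] and
#'   [glance()] methods for tabular access.
#' @examples
#' trials <- simulate_experiment(experiment_config(n_participants = 12), seed = 7)
#' rep <- analyze_experiment(trials, n_splits = 50, seed = 1, glmm = FALSE)
#' glance(rep)
#' @export
analyze_experiment <- function(trials, n_splits = 5000, seed = NULL,
                               glmm = TRUE) {
  excl <- apply_exclusions(trials)
  kept <- excl$kept
  dp <- dprime_binary(kept)
  out <- list(
    exclusions = excl$report,
    n_total = dplyr::n_distinct(trials$participant),
    n_kept = dplyr::n_distinct(kept$participant),
    n_critical = sum(excl$report$critical_eligible),
    rating_distribution = rating_distribution(kept),
    d_prime_by_participant = dp$by_participant,
    d_prime = dp$mean_d_prime,
    mle = fit_criteria_mle(kept),
    afc_accuracy = afc_accuracy(kept),
    afc_tests = afc_tests(kept),
    split_half = split_half_reliability(kept, n_splits = n_splits, seed = seed),
    correlation = tryCatch(accuracy_trialcount_correlation(kept),
                           error = function(e) NULL),
    glmm = if (glmm) fit_random_intercept_logistic(kept) else NULL
  )
  structure(out, class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report: %d/%d participants kept, %d critically eligible>\n",
              x$n_kept, x$n_total, x$n_critical))
  cat(sprintf("  mean binary d' = %.2f; ML d' = %.2f, criteria (%.2f, %.2f, %.2f)\n",
              x$d_prime, x$mle$d_prime, x$mle$criteria[1], x$mle$criteria[2],
              x$mle$criteria[3]))
  print(x$afc_tests)
  cat(sprintf("  split-half reliability (Spearman-Brown, %d splits): %.3f\n",
              x$split_half$n_splits, x$split_half$reliability))
  if (!is.null(x$glmm)) print(x$glmm)
  invisible(x)
}
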