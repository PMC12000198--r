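#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the maximum-likelihood rating-model fit
#'
#' @param x An `sdt_mle` object from [fit_criteria_mle()].
#' @param ... Unused.
#' @return A tibble with one row per parameter (`d_prime`, `c1`-`c3`).
#' @method tidy sdt_mle
#' @export
tidy.sdt_mle <- function(x, ...) {
  tibble::tibble(
    term = c("d_prime", "c1", "c2", "c3"),
    estimate = c(x$d_prime, x$criteria)
  )
}

#' @rdname tidy.sdt_mle
#' @return `glance()` returns a one-row tibble with `d_prime`, `logLik`,
#'   `convergence` and `n_collapsed`.
#' @method glance sdt_mle
#' @export
glance.sdt_mle <- function(x, ...) {
  tibble::tibble(
    d_prime = x$d_prime, logLik = x$logLik,
    convergence = x$convergence,
    n_collapsed = length(x$collapsed_categories)
  )
}

#' Tidy the random-intercept logistic record
#'
#' @param x A `glmm_record` from [fit_random_intercept_logistic()].
#' @param ... Unused.
#' @return A one-row tibble with the intercept estimate, SE, z, p and the
#'   back-transformed accuracy with its CI.
#' @method tidy glmm_record
#' @export
tidy.glmm_record <- function(x, ...) {
  tibble::tibble(
    term = "(Intercept)", estimate = x$b, std.error = x$se,
    statistic = x$z, p.value = x$p,
    accuracy = x$accuracy, ci_lower = x$ci[1], ci_upper = x$ci[2]
  )
}

#' Tidy and summarise an analysis report
#'
#' `tidy()` stacks every scalar statistic of the pipeline into a long
#' `statistic`/`value` tibble; `glance()` returns the headline one-row
#' summary.
#'
#' @param x An `analysis_report` from [analyze_experiment()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy analysis_report
#' @export
tidy.analysis_report <- function(x, ...) {
  rows <- list(
    tibble::tibble(statistic = c("n_total", "n_kept", "n_critical"),
                   value = c(x$n_total, x$n_kept, x$n_critical)),
    tibble::tibble(statistic = c("d_prime_binary", "d_prime_ml",
                                 "c1", "c2", "c3"),
                   value = c(x$d_prime, x$mle$d_prime, x$mle$criteria)),
    x$afc_tests |>
      dplyr::transmute(statistic = paste0("afc_", .data$test, "_mean"),
                       value = .data$mean),
    x$afc_tests |>
      dplyr::transmute(statistic = paste0("afc_", .data$test, "_t"),
                       value = .data$t),
    tibble::tibble(statistic = "split_half_reliability",
                   value = x$split_half$reliability)
  )
  if (!is.null(x$correlation)) {
    rows <- c(rows, list(tibble::tibble(
      statistic = c("acc_trialcount_r", "acc_trialcount_p"),
      value = c(x$correlation$r, x$correlation$p))))
  }
  if (!is.null(x$glmm)) {
    rows <- c(rows, list(tibble::tibble(
      statistic = c("glmm_intercept", "glmm_p", "glmm_accuracy"),
      value = c(x$glmm$b, x$glmm$p, x$glmm$accuracy))))
  }
  dplyr::bind_rows(rows)
}

#' @rdname tidy.analysis_report
#' @method glance analysis_report
#' @export
glance.analysis_report <- function(x, ...) {
  crit <- dplyr::filter(x$afc_tests, .data$test == "rating1_equal")
  overall <- dplyr::filter(x$afc_tests, .data$test == "overall")
  tibble::tibble(
    n_kept = x$n_kept,
    d_prime = x$d_prime,
    overall_accuracy = overall$mean,
    rating1_accuracy = if (nrow(crit)) crit$mean else NA_real_,
    rating1_p = if (nrow(crit)) crit$p_two_sided else NA_real_,
    split_half_reliability = x$split_half$reliability
  )
}
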