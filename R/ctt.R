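#' Classical-test-theory population
#'
#' A group whose members have true scores `T ~ Normal(mu_g, sigma_t^2)` and
#' measurement errors `E ~ Normal(0, sigma_e^2)`, observed as `X = T + E`.
#'
#' @param mu_g Group true-score mean (arbitrary score units).
#' @param sigma_t True-score standard deviation, `> 0`.
#' @param sigma_e Measurement-error standard deviation, `>= 0`.
#' @param label Group label carried into simulated score tables.
#' @return A `ctt_population` object.
#' @examples
#' ctt_population(60, 10, 10, label = "advantaged")
#' @export
ctt_population <- function(mu_g, sigma_t, sigma_e, label = "group") {
  assert_number(mu_g, "mu_g")
  assert_number(sigma_t, "sigma_t")
  assert_number(sigma_e, "sigma_e")
  if (sigma_t <= 0) stop("`sigma_t` must be positive.", call. = FALSE)
  if (sigma_e < 0) stop("`sigma_e` must be nonnegative.", call. = FALSE)
  structure(
    list(label = as.character(label), mu_g = mu_g,
         sigma_t = sigma_t, sigma_e = sigma_e),
    class = "ctt_population"
  )
}

#' @export
print.ctt_population <- function(x, ...) {
  cat(sprintf("<ctt_population '%s': T ~ N(%g, %g^2), E ~ N(0, %g^2), reliability %.3f>\n",
              x$label, x$mu_g, x$sigma_t, x$sigma_e,
              reliability(x$sigma_t, x$sigma_e)))
  invisible(x)
}

#' Reliability of an observed-score measure
#'
#' Classical-test-theory reliability: the share of observed-score variance
#' carried by true scores, `sigma_t^2 / (sigma_t^2 + sigma_e^2)`.
#'
#' @param sigma_t True-score SD, `> 0`.
#' @param sigma_e Error SD, `>= 0`.
#' @return A number in (0, 1].
#' @examples
#' reliability(10, 10)  # 0.5
#' reliability(10, 15)  # 0.3077
#' @export
reliability <- function(sigma_t, sigma_e) {
  assert_number(sigma_t, "sigma_t")
  assert_number(sigma_e, "sigma_e")
  if (sigma_t <= 0) stop("`sigma_t` must be positive.", call. = FALSE)
  if (sigma_e < 0) stop("`sigma_e` must be nonnegative.", call. = FALSE)
  sigma_t^2 / (sigma_t^2 + sigma_e^2)
}

#' Simulate a score table from a population
#'
#' Draws `n` individuals: `true ~ N(mu_g, sigma_t^2)`,
#' `error ~ N(0, sigma_e^2)`, `observed = true + error` row by row.
#'
#' @param pop A [ctt_population()].
#' @param n Number of individuals, `>= 1`.
#' @param seed Optional integer seed; the draw is deterministic given it and
#'   the global RNG state is left untouched.
#' @return A tibble with columns `id`, `group`, `true`, `error`, `observed`.
#' @examples
#' sample_scores(ctt_population(40, 10, 10), n = 5, seed = 1)
#' @export
sample_scores <- function(pop, n, seed = NULL) {
  stopifnot(inherits(pop, "ctt_population"))
  n <- assert_count(n, "n")
  with_seed_if(seed, {
    true <- stats::rnorm(n, pop$mu_g, pop$sigma_t)
    error <- if (pop$sigma_e > 0) stats::rnorm(n, 0, pop$sigma_e) else rep(0, n)
    tibble::tibble(
      id = seq_len(n),
      group = pop$label,
      true = true,
      error = error,
      observed = true + error
    )
  })
}

#' Select individuals by observed score
#'
#' Keeps rows whose `observed` score lies in the window (closed on finite
#' ends). This is the post hoc selection step that triggers Kelley's
#' Paradox: conditioning on the observed score induces a correlation with
#' the error term.
#'
#' @param scores A score table from [sample_scores()] (any data frame with
#'   an `observed` column).
#' @param window A [strength_window()] or length-2 numeric `c(lower, upper)`.
#' @return The subset tibble (possibly empty).
#' @export
select_by_observed <- function(scores, window) {
  w <- as_window(window)
  stopifnot("observed" %in% names(scores))
  dplyr::filter(tibble::as_tibble(scores),
                .data$observed >= w$lower, .data$observed <= w$upper)
}

#' Mean true score of a selected subset
#'
#' @param scores A nonempty score table (needs a `true` column).
#' @return The arithmetic mean of `true`.
#' @export
mean_true_of_selected <- function(scores) {
  stopifnot("true" %in% names(scores))
  if (nrow(scores) == 0L) {
    stop("Cannot take the mean true score of an empty selection.", call. = FALSE)
  }
  mean(scores$true)
}

#' Analytic conditional true-score mean in an observed-score window
#'
#' Closed-form counterpart of select-then-average: for `X = T + E` the pair
#' `(T, X)` is bivariate normal with correlation-squared equal to the
#' reliability `rho`, so
#' `E[T | X in window] = mu_g + rho * (E[X | X in window] - mu_g)` with the
#' truncated-normal mean of `X ~ N(mu_g, sigma_t^2 + sigma_e^2)` supplying
#' the inner expectation. Serves as the exact oracle for the Monte-Carlo
#' simulation.
#'
#' @param pop A [ctt_population()].
#' @param window Observed-score window with positive probability mass.
#' @return The conditional mean of the true score, a single number.
#' @examples
#' conditional_true_mean(ctt_population(40, 10, 10), c(48, 52))  # ~44.97
#' @export
conditional_true_mean <- function(pop, window) {
  stopifnot(inherits(pop, "ctt_population"))
  w <- as_window(window)
  rho <- reliability(pop$sigma_t, pop$sigma_e)
  sd_x <- sqrt(pop$sigma_t^2 + pop$sigma_e^2)
  m_x <- truncated_normal_mean(pop$mu_g, sd_x, w)
  pop$mu_g + rho * (m_x - pop$mu_g)
}

#' Expected true score at an exact observed score
#'
#' The bivariate-normal regression of true on observed score:
#' `mu_g + rho * (x - mu_g)` with `rho` the reliability. With low
#' reliability, members of groups with different means but the same
#' observed score have sharply different expected true scores.
#'
#' @param pop A [ctt_population()].
#' @param x Observed score.
#' @return The regression value, a single number.
#' @examples
#' expected_true_given_observed(ctt_population(60, 10, 20), 50)  # 58
#' @export
expected_true_given_observed <- function(pop, x) {
  stopifnot(inherits(pop, "ctt_population"))
  assert_number(x, "x")
  pop$mu_g + reliability(pop$sigma_t, pop$sigma_e) * (x - pop$mu_g)
}

#' Estimate the expected true score at an observed score from simulated data
#'
#' Two sample estimators of `E[T | X = x]`, matching how one would read the
#' quantity off a finite simulated dataset: `"local"` averages `true` over
#' rows with `observed` within `bandwidth` of `x`; `"regression"` fits the
#' within-group least-squares line of `true` on `observed` and evaluates it
#' at `x`.
#'
#' @param scores A score table.
#' @param x Observed score at which to estimate.
#' @param method `"local"` (default) or `"regression"`.
#' @param bandwidth Half-width of the local window (score units).
#' @return The estimate, a single number.
#' @export
estimate_true_at_observed <- function(scores, x, method = c("local", "regression"),
                                      bandwidth = 0.5) {
  method <- match.arg(method)
  assert_number(x, "x")
  if (method == "local") {
    sel <- dplyr::filter(scores, abs(.data$observed - x) <= bandwidth)
    if (nrow(sel) == 0L) stop("No observations within the local bandwidth.", call. = FALSE)
    mean(sel$true)
  } else {
    fit <- stats::lm(true ~ observed, data = scores)
    unname(stats::predict(fit, newdata = data.frame(observed = x)))
  }
}

#' Joint density of true and observed scores
#'
#' Density of the bivariate normal `(T, X)` with means `(mu_g, mu_g)`,
#' variances `(sigma_t^2, sigma_t^2 + sigma_e^2)` and covariance
#' `sigma_t^2` — the surface whose iso-probability contours tighten around
#' the diagonal as reliability rises. Vectorized over `t` and `x`.
#'
#' @param pop A [ctt_population()] with `sigma_e > 0` (at `sigma_e = 0` the
#'   joint law is singular, concentrated on the diagonal `t = x`, and no
#'   density exists).
#' @param t,x True- and observed-score coordinates.
#' @return Nonnegative density values.
#' @export
iso_density <- function(pop, t, x) {
  stopifnot(inherits(pop, "ctt_population"))
  if (pop$sigma_e <= 0) {
    stop("Joint density is degenerate at sigma_e = 0: all mass lies on t = x.",
         call. = FALSE)
  }
  # factorize f(t, x) = f(t) f(x | t): X | T = t ~ N(t, sigma_e^2)
  stats::dnorm(t, pop$mu_g, pop$sigma_t) * stats::dnorm(x, t, pop$sigma_e)
}

#' Two-group Kelley's Paradox simulation
#'
#' Samples two populations, selects both by a common observed-score window,
#' and contrasts the selected subgroups' true-score means against the
#' analytic conditional means. With nonzero error the matched-observed
#' subgroups diverge toward their own group means (regression to the mean).
#'
#' @param pop_a,pop_b Two [ctt_population()] objects (conventionally the
#'   disadvantaged and advantaged groups).
#' @param n Individuals per group.
#' @param window Observed-score selection window.
#' @param seed Optional integer seed.
#' @return A tibble with one row per group: `group`, `n_selected`,
#'   `mean_true_selected`, `mean_observed_selected`, `conditional_true_mean`
#'   (analytic), `reliability`.
#' @examples
#' kelley_simulation(ctt_population(40, 10, 10, "disadvantaged"),
#'                   ctt_population(60, 10, 10, "advantaged"),
#'                   n = 10000, window = c(48, 52), seed = 1)
#' @export
kelley_simulation <- function(pop_a, pop_b, n = 50000, window = c(48, 52),
                              seed = NULL) {
  w <- as_window(window)
  seeds <- split_seed(seed %||% sample.int(.Machine$integer.max - 1L, 1L), 2L)
  pops <- list(pop_a, pop_b)
  purrr::map2_dfr(pops, seeds, function(pop, s) {
    tab <- sample_scores(pop, n, seed = s)
    sel <- select_by_observed(tab, w)
    tibble::tibble(
      group = pop$label,
      n_selected = nrow(sel),
      mean_true_selected = mean_true_of_selected(sel),
      mean_observed_selected = mean(sel$observed),
      conditional_true_mean = conditional_true_mean(pop, w),
      reliability = reliability(pop$sigma_t, pop$sigma_e)
    )
  })
}
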