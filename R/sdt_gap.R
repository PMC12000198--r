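#' Signal-detection parameters for old and new item strengths
#'
#' Equal- or unequal-variance Gaussian strength model. New items are fixed
#' by convention at mean 0 and SD 1, so `mu_old` equals d' under equal
#' variance. `sd_error` is the SD of additive, zero-mean Gaussian
#' measurement noise on the strength axis (independent of true strength).
#'
#' @param mu_old True mean strength of old items.
#' @param sd_old True strength SD of old items, `> 0` (about 1.3 in typical
#'   ROC fits of recognition data; 1 under equal variance).
#' @param sd_error Measurement-error SD, `>= 0`.
#' @param mu_new,sd_new New-item mean and SD; override only for
#'   non-standard axes.
#' @return An `sdt_params` object.
#' @examples
#' sdt_params(mu_old = 1.5, sd_old = 1.3, sd_error = 0.5)
#' @export
sdt_params <- function(mu_old, sd_old = 1, sd_error = 0, mu_new = 0, sd_new = 1) {
  assert_number(mu_old, "mu_old")
  assert_number(sd_old, "sd_old")
  assert_number(sd_error, "sd_error")
  assert_number(mu_new, "mu_new")
  assert_number(sd_new, "sd_new")
  if (sd_old <= 0 || sd_new <= 0) stop("Strength SDs must be positive.", call. = FALSE)
  if (sd_error < 0) stop("`sd_error` must be nonnegative.", call. = FALSE)
  structure(
    list(mu_old = mu_old, sd_old = sd_old, sd_error = sd_error,
         mu_new = mu_new, sd_new = sd_new),
    class = "sdt_params"
  )
}

#' @export
print.sdt_params <- function(x, ...) {
  cat(sprintf("<sdt_params: old ~ N(%g, %g^2), new ~ N(%g, %g^2), error SD %g>\n",
              x$mu_old, x$sd_old, x$mu_new, x$sd_new, x$sd_error))
  invisible(x)
}

#' Expected true strength of items observed inside a window
#'
#' True strength is `T ~ Normal(mu, sigma_true^2)`; the observed strength is
#' `X = T + E` with `E ~ Normal(0, sigma_error^2)` independent of `T`.
#' Conditioning on `X` falling in `window`,
#' \deqn{E[T \mid X \in W] = \mu + \frac{\sigma_T^2}{\sigma_T^2+\sigma_E^2}
#'   \left( m_X(W) - \mu \right)}
#' where `m_X(W)` is the truncated mean of
#' `Normal(mu, sigma_true^2 + sigma_error^2)` on the window. The shrinkage
#' factor is the reliability of the strength observation; with zero error the
#' expression reduces to the plain truncated-normal mean.
#'
#' @param mu True mean strength.
#' @param sigma_true True strength SD, `> 0`.
#' @param sigma_error Measurement-error SD, `>= 0`.
#' @param window A [strength_window()] with positive mass under the
#'   observed-strength distribution.
#' @return Expected true strength, a single number.
#' @examples
#' expected_true_strength(0, 1, 1, strength_window(-Inf, 0))  # -0.5642
#' @export
expected_true_strength <- function(mu, sigma_true, sigma_error, window) {
  assert_number(mu, "mu")
  assert_number(sigma_true, "sigma_true")
  assert_number(sigma_error, "sigma_error")
  if (sigma_true <= 0) stop("`sigma_true` must be positive.", call. = FALSE)
  if (sigma_error < 0) stop("`sigma_error` must be nonnegative.", call. = FALSE)
  w <- as_window(window)
  sd_obs <- sqrt(sigma_true^2 + sigma_error^2)
  shrink <- sigma_true^2 / (sigma_true^2 + sigma_error^2)
  mu + shrink * (truncated_normal_mean(mu, sd_obs, w) - mu)
}

#' Monte-Carlo oracle for [expected_true_strength()]
#'
#' Draws true strengths, adds noise, conditions on the observed window, and
#' averages the retained true strengths. Used as the independent simulation
#' cross-check of the closed form.
#'
#' @inheritParams expected_true_strength
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @return A list with `estimate`, `se` (Monte-Carlo standard error) and
#'   `n_kept`.
#' @export
expected_true_strength_mc <- function(mu, sigma_true, sigma_error, window,
                                      n = 1e6, seed = NULL) {
  w <- as_window(window)
  with_seed_if(seed, {
    t_true <- stats::rnorm(n, mu, sigma_true)
    x_obs <- if (sigma_error > 0) t_true + stats::rnorm(n, 0, sigma_error) else t_true
    keep <- x_obs >= w$lower & x_obs <= w$upper
    kept <- t_true[keep]
    if (length(kept) < 2L) stop("Too few draws fell inside the window.", call. = FALSE)
    list(estimate = mean(kept),
         se = stats::sd(kept) / sqrt(length(kept)),
         n_kept = length(kept))
  })
}

#' True-strength gap between misses and correct rejections
#'
#' Misses are old items and correct rejections new items whose observed
#' strength falls below the decision criterion (window `(-Inf, criterion)`;
#' the criterion is on the observed-strength axis, measured from the
#' new-item mean). Returns both conditional true means and their difference
#' `gap = T_M - T_CR`. A positive gap means the "matched" item classes are
#' not matched in true strength.
#'
#' @param params An [sdt_params()] object.
#' @param criterion Finite decision criterion.
#' @return A one-row tibble: `criterion`, `sd_error`, `t_miss`, `t_cr`,
#'   `gap`.
#' @examples
#' miss_cr_gap(sdt_params(mu_old = 1), criterion = 0)  # gap 0.2728
#' @export
miss_cr_gap <- function(params, criterion) {
  stopifnot(inherits(params, "sdt_params"))
  assert_number(criterion, "criterion")
  w <- strength_window(-Inf, criterion)
  t_miss <- expected_true_strength(params$mu_old, params$sd_old, params$sd_error, w)
  t_cr <- expected_true_strength(params$mu_new, params$sd_new, params$sd_error, w)
  tibble::tibble(
    criterion = criterion, sd_error = params$sd_error,
    t_miss = t_miss, t_cr = t_cr, gap = t_miss - t_cr
  )
}

#' Miss-CR gap as a function of measurement-error SD
#'
#' Evaluates [miss_cr_gap()] over a grid of error SDs at fixed strength
#' parameters and criterion. Under equal variance the gap is positive
#' everywhere and grows with error (regression to the mean amplifies it);
#' under unequal variance with a low old-item mean the zero-error gap can
#' be negative or zero.
#'
#' @param params An [sdt_params()]; its `sd_error` is ignored in favour of
#'   the grid.
#' @param criterion Decision criterion.
#' @param error_grid Nonnegative error SDs.
#' @return A tibble with one row per grid point, columns as in
#'   [miss_cr_gap()] plus `mu_old` and `sd_old`.
#' @export
gap_curve <- function(params, criterion, error_grid = seq(0, 2, by = 0.1)) {
  stopifnot(inherits(params, "sdt_params"))
  if (length(error_grid) == 0L || any(error_grid < 0)) {
    stop("`error_grid` must be a nonempty vector of nonnegative SDs.", call. = FALSE)
  }
  purrr::map_dfr(error_grid, function(se) {
    p <- sdt_params(params$mu_old, params$sd_old, se, params$mu_new, params$sd_new)
    miss_cr_gap(p, criterion)
  }) |>
    dplyr::mutate(mu_old = params$mu_old, sd_old = params$sd_old, .before = 1L)
}

#' Zero-error miss-CR gap as a function of the decision criterion
#'
#' The equal-variance, zero-measurement-error special case: the gap that
#' remains is driven purely by differential truncation skewness of the old
#' and new strength distributions, is positive for every d' > 0 and every
#' finite criterion, and grows with d'.
#'
#' @param d_prime_list d' values (old-item means under equal variance).
#' @param criterion_grid Finite criteria.
#' @return A tibble with columns `d_prime`, `criterion`, `t_miss`, `t_cr`,
#'   `gap`.
#' @examples
#' skewness_gap_curve(1, 0)$gap  # 0.2728
#' @export
skewness_gap_curve <- function(d_prime_list = seq(0.1, 2.8, by = 0.3),
                               criterion_grid = seq(-2, 2, by = 0.1)) {
  tidyr::expand_grid(d_prime = d_prime_list, criterion = criterion_grid) |>
    dplyr::mutate(purrr::map2_dfr(
      .data$d_prime, .data$criterion,
      function(d, c) miss_cr_gap(sdt_params(mu_old = d), c)[c("t_miss", "t_cr", "gap")]
    ))
}
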