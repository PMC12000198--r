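#' Reproduce the package's full demonstration bundle
#'
#' One reproducible pass over every component: the two-group Kelley
#' simulation (50,000 per group, windows [48, 52] and (-inf, 30]), the
#' reliability grid (error SDs 5/10/15/20 at true-score SD 10) with its
#' iso-probability surfaces, the miss-CR gap curves over error SDs and over
#' criteria, and a synthetic recognition + 2AFC experiment run through the
#' complete analysis pipeline. Every figure's numbers are also written as
#' CSV, and a single JSON summary collects the headline statistics. Two
#' runs with the same seed produce identical CSV/JSON output.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Master integer seed.
#' @param n_per_group Individuals per group in the score simulation.
#' @param config Experiment configuration for the synthetic experiment.
#' @param n_splits Split-half resampling count for the reliability estimate.
#' @param figures Write PNG figures (set `FALSE` for headless speed).
#' @return Invisibly, the summary list written to `summary.json`.
#' @export
reproduce_paper <- function(outdir, seed = 1L, n_per_group = 50000,
                            config = experiment_config(), n_splits = 5000,
                            figures = TRUE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("Cannot create output directory.", call. = FALSE)
  seeds <- split_seed(seed, 5L)
  path <- function(f) file.path(outdir, f)
  save_fig <- function(p, name) {
    if (figures) {
      suppressMessages(ggplot2::ggsave(path(name), p, width = 7, height = 5,
                                       dpi = 150))
    }
  }

  # --- Kelley two-group simulation
  dis <- ctt_population(40, 10, 10, "disadvantaged")
  adv <- ctt_population(60, 10, 10, "advantaged")
  scores <- dplyr::bind_rows(
    sample_scores(dis, n_per_group, seed = seeds[1L]),
    sample_scores(adv, n_per_group, seed = seeds[2L])
  )
  kelley <- purrr::map_dfr(
    list(strength_window(48, 52), strength_window(-Inf, 30)),
    function(w) {
      purrr::map_dfr(list(dis, adv), function(pop) {
        sel <- select_by_observed(
          dplyr::filter(scores, .data$group == pop$label), w)
        tibble::tibble(
          group = pop$label, lower = w$lower, upper = w$upper,
          n_selected = nrow(sel),
          mean_true_selected = mean_true_of_selected(sel),
          conditional_true_mean = conditional_true_mean(pop, w)
        )
      })
    })
  readr::write_csv(kelley, path("kelley_selected_true_means.csv"))
  readr::write_csv(scores, path("kelley_scores.csv"))
  save_fig(plot_score_densities(scores, strength_window(48, 52)),
           "kelley_densities.png")

  # --- reliability grid + iso-probability surfaces
  rel_grid <- tibble::tibble(sigma_e = c(5, 10, 15, 20)) |>
    dplyr::mutate(sigma_t = 10,
                  reliability = purrr::map_dbl(.data$sigma_e,
                                               ~ reliability(10, .x)))
  readr::write_csv(rel_grid, path("reliability_grid.csv"))
  iso_pops <- purrr::map(c(5, 10, 15, 20), function(se) {
    list(ctt_population(40, 10, se, "disadvantaged"),
         ctt_population(60, 10, se, "advantaged"))
  })
  save_fig(plot_iso_probability(iso_pops[[4L]]), "iso_probability_sd20.png")

  # regression of true on observed at x = 50, error SD 20
  x50 <- purrr::map_dfr(
    list(ctt_population(40, 10, 20, "disadvantaged"),
         ctt_population(60, 10, 20, "advantaged")),
    function(pop) {
      tab <- sample_scores(pop, n_per_group, seed = seeds[3L] + (pop$mu_g > 50))
      tibble::tibble(
        group = pop$label,
        analytic = expected_true_given_observed(pop, 50),
        local_mean = estimate_true_at_observed(tab, 50, "local"),
        regression = estimate_true_at_observed(tab, 50, "regression")
      )
    })
  readr::write_csv(x50, path("expected_true_at_50.csv"))

  # --- miss-CR gap curves
  gap <- tidyr::expand_grid(mu_old = c(0.5, 1.0, 1.5), sd_old = c(1, 1.3),
                            criterion = c(-1, 0)) |>
    purrr::pmap_dfr(function(mu_old, sd_old, criterion) {
      gap_curve(sdt_params(mu_old = mu_old, sd_old = sd_old),
                criterion = criterion,
                error_grid = seq(0, 2, by = 0.1))
    })
  readr::write_csv(gap, path("gap_curves.csv"))
  save_fig(plot_gap_curves(gap), "gap_curves.png")
  skew <- skewness_gap_curve(seq(0.1, 2.8, by = 0.3), seq(-2, 2, by = 0.1))
  readr::write_csv(skew, path("skewness_gap_curves.csv"))
  save_fig(plot_skewness_gap_curves(skew), "skewness_gap_curves.png")

  # --- synthetic experiment + analysis
  trials <- simulate_experiment(config, seed = seeds[4L])
  write_trials(trials, path("trials.csv"))
  report <- analyze_experiment(trials, n_splits = n_splits, seed = seeds[5L])
  readr::write_csv(tidy(report), path("analysis_report.csv"))
  readr::write_csv(report$rating_distribution, path("rating_distribution.csv"))
  readr::write_csv(report$afc_tests, path("afc_tests.csv"))
  save_fig(plot_afc_accuracy(report$afc_accuracy), "afc_accuracy.png")

  crit <- dplyr::filter(report$afc_tests, .data$test == "rating1_equal")
  summary <- list(
    seed = seed,
    kelley_selected_true_means = kelley,
    reliabilities = rel_grid$reliability,
    expected_true_at_50 = x50,
    power_n = power_n_one_sample_t(0.3, 0.80, 0.05, "one"),
    experiment = list(
      n_kept = report$n_kept,
      n_critical = report$n_critical,
      d_prime = report$d_prime,
      d_prime_ml = report$mle$d_prime,
      criteria_ml = report$mle$criteria,
      overall = as.list(dplyr::filter(report$afc_tests,
                                      .data$test == "overall")),
      critical = as.list(crit),
      split_half_reliability = report$split_half$reliability,
      glmm = if (!is.null(report$glmm)) {
        report$glmm[c("b", "se", "z", "p", "accuracy", "ci")]
      }
    )
  )
  jsonlite::write_json(summary, path("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(summary)
}
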