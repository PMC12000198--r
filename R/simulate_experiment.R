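#' Synthetic word pool with living/nonliving norms
#'
#' Stands in for a normative word pool: each word carries a living/nonliving
#' rating on a 100-700 scale. Ratings are drawn from a three-part mixture
#' placing about 77% of mass outside (200, 600), so that a 180-word pool
#' contains roughly 138 clearly living (> 600) or clearly nonliving (< 200)
#' words; the remainder are ambiguous. Purely synthetic: ratings are not
#' tied to any real lexical norms.
#'
#' @param n Pool size, at least 140 (60 old + 60 new + 20 truly new).
#' @param seed Optional integer seed.
#' @param p_clear Probability a word is clearly classifiable (split evenly
#'   between clearly living and clearly nonliving).
#' @return A tibble with columns `word` (id, `w001`, ...) and
#'   `living_rating`.
#' @examples
#' generate_word_pool(180, seed = 1)
#' @export
generate_word_pool <- function(n = 180, seed = NULL, p_clear = 0.77) {
  n <- assert_count(n, "n")
  if (n < 140) stop("Pool must contain at least 140 words to fill the item sets.",
                    call. = FALSE)
  with_seed_if(seed, {
    kind <- sample(c("nonliving", "ambiguous", "living"), n, replace = TRUE,
                   prob = c(p_clear / 2, 1 - p_clear, p_clear / 2))
    rating <- numeric(n)
    rating[kind == "nonliving"] <- stats::runif(sum(kind == "nonliving"), 100, 200)
    rating[kind == "ambiguous"] <- stats::runif(sum(kind == "ambiguous"), 200, 600)
    rating[kind == "living"] <- stats::runif(sum(kind == "living"), 600, 700)
    tibble::tibble(
      word = sprintf("w%03d", seq_len(n)),
      living_rating = rating
    )
  })
}

#' Configuration of the synthetic recognition + 2AFC experiment
#'
#' Bundles the design constants (item-set sizes), the latent strength model
#' and the response model. Defaults emulate the kind of recognition
#' experiment the analysis pipeline targets: 75 participants, 60 studied +
#' 60 new + 20 truly new words per participant, a 4-point confidence scale
#' with ordered criteria, and a 2AFC stage judged from a fresh noisy
#' observation of the same true strengths.
#'
#' The confidence criteria are cutpoints on the *observed* strength axis
#' (true + rating-stage noise). The defaults place them so that, after
#' normalising by the observed-strength SD `sqrt(1 + sd_error^2)`, they sit
#' at 0.03, 0.75 and 1.20 new-item SDs — typical of a high-d' verbal
#' recognition task. `sd_mu_participant` adds a participant-level shift to
#' the old-item mean (individual differences in memory), without which
#' between-participant reliability of the recognition measure would be zero.
#'
#' @param n_participants Number of participants.
#' @param sdt An [sdt_params()] object for the latent strengths; `sd_error`
#'   is the rating-stage measurement noise.
#' @param criteria Three increasing rating cutpoints `C1 < C2 < C3` on the
#'   observed-strength axis; ratings are `1 + #\{C_k <= X\}`.
#' @param study_accuracy Probability of a correct living/nonliving response
#'   in the study phase.
#' @param retest_error_sd SD of the fresh measurement noise at the 2AFC
#'   stage.
#' @param sd_mu_participant SD of the participant-level shift of `mu_old`.
#' @param n_old,n_new,n_truly_new Item-set sizes.
#' @param pool_size Size of the word pool to draw item sets from.
#' @return An `experiment_config` object.
#' @export
experiment_config <- function(n_participants = 75,
                              sdt = sdt_params(mu_old = 2.6, sd_old = 1, sd_error = 0.8),
                              criteria = c(0.03, 0.75, 1.20) * sqrt(1 + 0.8^2),
                              study_accuracy = 0.95,
                              retest_error_sd = 1.4,
                              sd_mu_participant = 0.75,
                              n_old = 60, n_new = 60, n_truly_new = 20,
                              pool_size = 180) {
  stopifnot(inherits(sdt, "sdt_params"))
  n_participants <- assert_count(n_participants, "n_participants")
  if (length(criteria) != 3L || any(diff(criteria) <= 0)) {
    stop("`criteria` must be three strictly increasing cutpoints.", call. = FALSE)
  }
  if (study_accuracy < 0 || study_accuracy > 1) {
    stop("`study_accuracy` must be a probability.", call. = FALSE)
  }
  if (retest_error_sd < 0 || sd_mu_participant < 0) {
    stop("SD parameters must be nonnegative.", call. = FALSE)
  }
  if (pool_size < n_old + n_new + n_truly_new) {
    stop("`pool_size` too small for the item sets.", call. = FALSE)
  }
  structure(
    list(n_participants = n_participants, sdt = sdt, criteria = criteria,
         study_accuracy = study_accuracy, retest_error_sd = retest_error_sd,
         sd_mu_participant = sd_mu_participant,
         n_old = as.integer(n_old), n_new = as.integer(n_new),
         n_truly_new = as.integer(n_truly_new),
         pool_size = as.integer(pool_size)),
    class = "experiment_config"
  )
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf(
    paste0("<experiment_config: %d participants, %d old / %d new / %d truly new,\n",
           " strengths old ~ N(%g + participant shift (SD %g), %g^2), rating noise SD %g,\n",
           " criteria (%.3f, %.3f, %.3f), study accuracy %g, retest noise SD %g>\n"),
    x$n_participants, x$n_old, x$n_new, x$n_truly_new,
    x$sdt$mu_old, x$sd_mu_participant, x$sdt$sd_old, x$sdt$sd_error,
    x$criteria[1], x$criteria[2], x$criteria[3],
    x$study_accuracy, x$retest_error_sd))
  invisible(x)
}

# Ordered rating from observed strength: r = 1 + #{C_k <= x}.
rating_from_strength <- function(x, criteria) {
  1L + findInterval(x, criteria)
}

#' Build the 2AFC pair list for one participant
#'
#' Pairing algorithm: within each rating category, as many old-new pairs as
#' possible are matched at equal ratings (random matching within category);
#' the leftover old and new words are paired at random as "unequal" pairs.
#' Then 20 pairs have their new member replaced by a truly-new word, in this
#' order: unequal pairs first, then equal pairs rated 4, then rated 3, and
#' so on, choosing at random (seeded) within each tier. Every old word is
#' used exactly once, giving `n_old` pairs of which `length(truly_new)` are
#' truly-new pairs.
#'
#' @param ratings A data frame with one row per rated word: columns `word`,
#'   `status` (`"old"`/`"new"`) and `rating` (1-4).
#' @param truly_new Character vector of truly-new word ids.
#' @param seed Optional integer seed.
#' @return A tibble with columns `item_a` (the old word), `item_b`,
#'   `rating_a`, `rating_b` (`NA` for truly-new members) and `pair_type`
#'   (`"equal"`, `"unequal"`, `"truly_new"`).
#' @export
build_afc_pairs <- function(ratings, truly_new, seed = NULL) {
  old <- ratings[ratings$status == "old", , drop = FALSE]
  new <- ratings[ratings$status == "new", , drop = FALSE]
  if (nrow(old) != nrow(new)) {
    stop("Need equally many rated old and new words.", call. = FALSE)
  }
  with_seed_if(seed, {
    old_id <- old$word; old_r <- old$rating
    new_id <- new$word; new_r <- new$rating
    pa <- pb <- ra <- rb <- ptype <- list()
    used_old <- used_new <- logical(length(old_id))
    for (r in sort(unique(c(old_r, new_r)))) {
      io <- which(old_r == r & !used_old)
      ino <- which(new_r == r & !used_new)
      m <- min(length(io), length(ino))
      if (m == 0L) next
      io <- if (length(io) > 1L) sample(io, m) else io[seq_len(m)]
      ino <- if (length(ino) > 1L) sample(ino, m) else ino[seq_len(m)]
      pa <- c(pa, list(old_id[io])); pb <- c(pb, list(new_id[ino]))
      ra <- c(ra, list(old_r[io])); rb <- c(rb, list(new_r[ino]))
      ptype <- c(ptype, list(rep("equal", m)))
      used_old[io] <- TRUE; used_new[ino] <- TRUE
    }
    io <- which(!used_old); ino <- which(!used_new)
    if (length(io) != length(ino)) stop("Pairing bookkeeping failed.", call. = FALSE)
    if (length(io) > 0L) {
      io <- if (length(io) > 1L) sample(io) else io
      ino <- if (length(ino) > 1L) sample(ino) else ino
      pa <- c(pa, list(old_id[io])); pb <- c(pb, list(new_id[ino]))
      ra <- c(ra, list(old_r[io])); rb <- c(rb, list(new_r[ino]))
      ptype <- c(ptype, list(rep("unequal", length(io))))
    }
    pairs <- tibble::tibble(
      item_a = unlist(pa), item_b = unlist(pb),
      rating_a = unlist(ra), rating_b = unlist(rb),
      pair_type = unlist(ptype)
    )
    # replacement order: unequal, then equal rated 4, 3, 2, 1
    tier <- ifelse(pairs$pair_type == "unequal", 5L, pairs$rating_a)
    ord <- order(-tier, stats::runif(nrow(pairs)))  # random within tier
    n_tn <- length(truly_new)
    if (n_tn > nrow(pairs)) stop("More truly-new words than pairs.", call. = FALSE)
    repl <- ord[seq_len(n_tn)]
    pairs$item_b[repl] <- truly_new
    pairs$rating_b[repl] <- NA_integer_
    pairs$pair_type[repl] <- "truly_new"
    pairs[sample.int(nrow(pairs)), , drop = FALSE]  # shuffle trial order
  })
}

#' Simulate one participant's trials
#'
#' Generative model: item sets of sizes 60/60/20 are drawn without
#' replacement from the pool; study responses are correct independently
#' with probability `study_accuracy`; each rated item has latent true
#' strength `T ~ N(mu_old + delta_p, sd_old^2)` if old and `N(0, 1)` if new,
#' where `delta_p` is the participant's memory shift; the rating-stage
#' observation is `X1 = T + e1` with `e1 ~ N(0, sd_error^2)`, cut into a
#' 1-4 rating by the criteria; the 2AFC stage re-observes each pair member
#' as `X2 = T + e2` with fresh `e2 ~ N(0, retest_error_sd^2)` (truly-new
#' words get a fresh `T ~ N(0,1)`) and picks the larger `X2`, breaking exact
#' ties by a fair coin. Misses and correct rejections are never referenced:
#' any above-chance accuracy on rating-1 pairs is an emergent consequence of
#' truncation plus regression to the mean.
#'
#' @param config An [experiment_config()].
#' @param participant Participant id (integer or string).
#' @param seed Optional integer seed.
#' @param pool Optional word pool from [generate_word_pool()]; generated
#'   from `seed` if missing.
#' @param keep_latent Attach the latent true strengths (`strength_a`,
#'   `strength_b`) to rating and 2AFC rows, for model checking; analysis
#'   code never reads them.
#' @return A tibble of trial rows (`phase` = `"study"`, `"rating"`,
#'   `"afc"`) with the trial-table schema of [simulate_experiment()].
#' @export
simulate_participant <- function(config, participant, seed = NULL, pool = NULL,
                                 keep_latent = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  if (is.null(pool)) pool <- generate_word_pool(config$pool_size, seed = seed)
  n_items <- config$n_old + config$n_new + config$n_truly_new
  with_seed_if(seed, {
    picks <- pool[sample.int(nrow(pool), n_items), , drop = FALSE]
    status <- rep(c("old", "new", "truly_new"),
                  c(config$n_old, config$n_new, config$n_truly_new))
    words <- picks$word
    lrate <- picks$living_rating

    # --- study phase (old words only)
    i_old <- which(status == "old")
    is_living <- lrate[i_old] > 400
    correct_study <- stats::rbinom(config$n_old, 1L, config$study_accuracy)
    truth <- ifelse(is_living, "living", "nonliving")
    flip <- ifelse(is_living, "nonliving", "living")
    study <- tibble::tibble(
      participant = as.character(participant), phase = "study",
      item_a = words[i_old], item_b = NA_character_, status = "old",
      rating_a = NA_integer_, rating_b = NA_integer_, pair_type = NA_character_,
      response = ifelse(correct_study == 1L, truth, flip),
      correct = as.integer(correct_study),
      living_rating = lrate[i_old]
    )[sample.int(config$n_old), ]

    # --- latent strengths for rated items
    delta_p <- stats::rnorm(1L, 0, config$sd_mu_participant)
    i_rated <- which(status != "truly_new")
    n_rated <- length(i_rated)
    t_true <- ifelse(
      status[i_rated] == "old",
      stats::rnorm(n_rated, config$sdt$mu_old + delta_p, config$sdt$sd_old),
      stats::rnorm(n_rated, config$sdt$mu_new, config$sdt$sd_new)
    )
    x1 <- t_true + if (config$sdt$sd_error > 0) {
      stats::rnorm(n_rated, 0, config$sdt$sd_error)
    } else 0
    rating <- rating_from_strength(x1, config$criteria)
    rating_tbl <- tibble::tibble(
      participant = as.character(participant), phase = "rating",
      item_a = words[i_rated], item_b = NA_character_,
      status = status[i_rated],
      rating_a = rating, rating_b = NA_integer_, pair_type = NA_character_,
      response = as.character(rating), correct = NA_integer_,
      living_rating = NA_real_
    )
    if (keep_latent) {
      rating_tbl$strength_a <- t_true
      rating_tbl$strength_b <- NA_real_
    }
    rating_tbl <- rating_tbl[sample.int(n_rated), ]

    # --- 2AFC phase
    pairs <- build_afc_pairs(
      data.frame(word = words[i_rated], status = status[i_rated], rating = rating),
      truly_new = words[status == "truly_new"]
    )
    strength <- stats::setNames(t_true, words[i_rated])
    t_a <- unname(strength[pairs$item_a])
    t_b <- unname(strength[pairs$item_b])
    tn <- is.na(t_b)  # truly-new members: fresh true strength
    t_b[tn] <- stats::rnorm(sum(tn), config$sdt$mu_new, config$sdt$sd_new)
    n_pairs <- nrow(pairs)
    noise <- function() if (config$retest_error_sd > 0) {
      stats::rnorm(n_pairs, 0, config$retest_error_sd)
    } else 0
    x2_a <- t_a + noise()
    x2_b <- t_b + noise()
    chose_a <- ifelse(x2_a == x2_b,
                      stats::rbinom(n_pairs, 1L, 0.5) == 1L,
                      x2_a > x2_b)
    a_left <- stats::rbinom(n_pairs, 1L, 0.5) == 1L
    afc <- tibble::tibble(
      participant = as.character(participant), phase = "afc",
      item_a = pairs$item_a, item_b = pairs$item_b,
      status = ifelse(pairs$pair_type == "truly_new", "truly_new", "new"),
      rating_a = as.integer(pairs$rating_a),
      rating_b = as.integer(pairs$rating_b),
      pair_type = pairs$pair_type,
      response = ifelse(chose_a == a_left, "left", "right"),
      correct = as.integer(chose_a),
      living_rating = NA_real_
    )
    if (keep_latent) {
      afc$strength_a <- t_a
      afc$strength_b <- t_b
      study$strength_a <- NA_real_
      study$strength_b <- NA_real_
    }
    dplyr::bind_rows(study, rating_tbl, afc)
  })
}

#' Simulate the full experiment
#'
#' Draws a word pool, then simulates every participant independently with
#' sub-seeds split deterministically from the master seed (see the seed
#' rule in the package vignette). The result is a tidy trial table: per
#' participant, 60 study rows, 120 rating rows and 60 2AFC rows of which
#' exactly 20 are truly-new pairs.
#'
#' @param config An [experiment_config()].
#' @param seed Master integer seed; the full table is reproducible given it.
#' @param keep_latent Attach latent strengths; see [simulate_participant()].
#' @return A tibble with columns `participant`, `phase`, `item_a`, `item_b`,
#'   `status`, `rating_a`, `rating_b`, `pair_type`, `response`, `correct`,
#'   `living_rating`.
#' @examples
#' trials <- simulate_experiment(experiment_config(n_participants = 3), seed = 1)
#' dplyr::count(trials, phase)
#' @export
simulate_experiment <- function(config = experiment_config(), seed = NULL,
                                keep_latent = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  seeds <- split_seed(seed %||% sample.int(.Machine$integer.max - 1L, 1L),
                      config$n_participants + 1L)
  pool <- generate_word_pool(config$pool_size, seed = seeds[1L])
  purrr::map_dfr(seq_len(config$n_participants), function(p) {
    simulate_participant(config, participant = sprintf("p%03d", p),
                         seed = seeds[p + 1L], pool = pool,
                         keep_latent = keep_latent)
  })
}

#' Read or write a trial table as CSV
#'
#' Plain-CSV serialization of the trial-table schema, so the pipeline runs
#' identically on synthetic tables and on externally collected data mapped
#' to the same columns.
#'
#' @param trials A trial table tibble.
#' @param path File path.
#' @return `write_trials()` returns `trials` invisibly; `read_trials()`
#'   returns the tibble.
#' @export
write_trials <- function(trials, path) {
  readr::write_csv(trials, path)
  invisible(trials)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    participant = readr::col_character(),
    phase = readr::col_character(),
    item_a = readr::col_character(),
    item_b = readr::col_character(),
    status = readr::col_character(),
    rating_a = readr::col_integer(),
    rating_b = readr::col_integer(),
    pair_type = readr::col_character(),
    response = readr::col_character(),
    correct = readr::col_integer(),
    living_rating = readr::col_double()
  ))
}
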