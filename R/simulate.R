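#' Simulate a cohort of respondents with controllable skill
#'
#' Generates synthetic respondents whose response behaviour follows a
#' single-parameter latent-skill model: within each exchange the
#' probability of selecting an option is proportional to
#' `exp(beta * mc_points)`. `beta = 0` gives uniform choice (probability
#' 0.2 per option); large `beta` concentrates choice on the most
#' MC-consistent (rank-1, +2 points) option. Utilities use the option's
#' MC-consistency points, not its display slot, so the simulator is
#' unaffected by option-order randomization.
#'
#' Each respondent receives a freshly assembled randomized form per
#' occasion (seeded from the cohort's RNG stream), making the cohort fully
#' reproducible from `(bank, n, beta, occasions, seed)`.
#'
#' @param bank an `mccat_bank`.
#' @param n number of respondents (>= 1).
#' @param beta the skill parameter: a nonnegative scalar (common skill), a
#'   numeric vector of length `n` (per-respondent skills), or a function
#'   `function(n)` drawing `n` skills (e.g. a two-point or uniform mixture
#'   emulating pre/post-training heterogeneity).
#' @param occasions number of assessment occasions per respondent (1 or 2).
#' @param seed integer seed for the cohort RNG stream.
#' @return An object of class `mccat_cohort`: a list with `logs` (one
#'   response-log tibble covering the whole cohort), `forms` (named list of
#'   `mccat_form`, keyed `<respondent>.<occasion>`), `respondents` (tibble
#'   `respondent_id`, `beta`), and `seed`.
#' @examples
#' bank <- generate_fixture_bank(seed = 1)
#' cohort <- simulate_cohort(bank, n = 4, beta = 1, seed = 42)
#' score_cohort(cohort$logs, bank)$overall
#' @export
simulate_cohort <- function(bank, n, beta = 1, occasions = 1L, seed = 1L) {
  stopifnot(inherits(bank, "mccat_bank"), n >= 1,
            occasions %in% c(1L, 2L))
  withr::with_seed(as.integer(seed), {
    betas <- if (is.function(beta)) {
      beta(n)
    } else if (length(beta) == 1) {
      rep(as.numeric(beta), n)
    } else if (length(beta) == n) {
      as.numeric(beta)
    } else {
      stop("`beta` must be a scalar, a length-n vector, or a function",
           call. = FALSE)
    }
    if (any(is.na(betas)) || any(betas < 0)) {
      stop("skill parameter `beta` must be nonnegative", call. = FALSE)
    }
    respondent_ids <- sprintf("r%03d", seq_len(n))

    # choice probabilities over ranks 1..5 depend only on beta
    pts <- points_for_rank(1:5)
    rank_probs <- function(b) {
      w <- exp(b * pts)
      w / sum(w)
    }

    forms <- list()
    log_parts <- list()
    for (occ in seq_len(occasions)) {
      for (i in seq_len(n)) {
        form_seed <- sample.int(.Machine$integer.max - 1L, 1)
        form <- assemble_form(
          bank, seed = form_seed,
          form_id = paste0("sim-", respondent_ids[i], "-o", occ))
        forms[[paste0(respondent_ids[i], ".", occ)]] <- form
        k <- nrow(form$permutations)
        p <- rank_probs(betas[i])
        ranks <- sample.int(5, k, replace = TRUE, prob = p)
        log_parts[[length(log_parts) + 1]] <- tibble::new_tibble(list(
          respondent_id = rep(respondent_ids[i], k),
          form_id = rep(form$form_id, k),
          case_id = form$permutations$case_id,
          exchange_index = form$permutations$exchange_index,
          rank = ranks,
          occasion = rep(as.integer(occ), k)
        ), nrow = k)
      }
    }
    logs <- dplyr::bind_rows(log_parts)
    logs <- dplyr::left_join(
      logs,
      dplyr::select(bank$options, "case_id", "exchange_index", "rank",
                    "option_id"),
      by = c("case_id", "exchange_index", "rank"))
    logs <- dplyr::select(logs, "respondent_id", "form_id", "case_id",
                          "exchange_index", "option_id", "occasion")
    structure(
      list(
        logs = logs,
        forms = forms,
        respondents = tibble::tibble(respondent_id = respondent_ids,
                                     beta = betas),
        seed = as.integer(seed)
      ),
      class = "mccat_cohort")
  })
}

#' @export
print.mccat_cohort <- function(x, ...) {
  cat("<mccat_cohort> ", nrow(x$respondents), " respondents, ",
      length(unique(x$logs$occasion)), " occasion(s), seed ", x$seed,
      "\n", sep = "")
  cat("  beta: ", paste(format(range(x$respondents$beta)), collapse = " to "),
      "\n", sep = "")
  invisible(x)
}

#' Check that scores recover the simulated skill ordering
#'
#' Sanity check for the end-to-end pipeline: mean global competency and
#' ranking scores should increase strictly with the simulated skill level
#' `beta`. Requires at least 3 distinct levels to call the ordering
#' meaningful.
#'
#' @param cohort an `mccat_cohort`.
#' @param bank the `mccat_bank` it was simulated from.
#' @return A list with `by_level` (tibble: beta, n, mean_ranking,
#'   mean_global), `monotone_ranking`, `monotone_global` (logical), and
#'   `sufficient_levels` (logical; `FALSE` flags fewer than 3 distinct
#'   levels, in which case the monotonicity flags are `NA`).
#' @export
skill_recovery_check <- function(cohort, bank) {
  stopifnot(inherits(cohort, "mccat_cohort"))
  scores <- score_cohort(cohort$logs, bank, by_family = FALSE)$overall
  scored <- dplyr::left_join(scores, cohort$respondents,
                             by = "respondent_id")
  by_level <- scored |>
    dplyr::group_by(beta = .data$beta) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_ranking = mean(.data$ranking),
                     mean_global = mean(.data$global_competency),
                     .groups = "drop") |>
    dplyr::arrange(.data$beta)
  sufficient <- nrow(by_level) >= 3
  list(
    by_level = by_level,
    monotone_ranking = if (sufficient) !is.unsorted(by_level$mean_ranking,
                                                    strictly = TRUE) else NA,
    monotone_global = if (sufficient) !is.unsorted(by_level$mean_global,
                                                   strictly = TRUE) else NA,
    sufficient_levels = sufficient
  )
}
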