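#' Read / write respondent response logs
#'
#' A response log records one respondent's selections on an assembled form:
#' one row per exchange, columns `respondent_id`, `form_id`, `case_id`,
#' `exchange_index`, `option_id` and `occasion` (assessment occasion, 1 or
#' 2).
#'
#' @param path CSV path.
#' @param log a response-log tibble.
#' @return A tibble (`read_response_log`); `path` invisibly
#'   (`write_response_log`).
#' @export
read_response_log <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      respondent_id = readr::col_character(),
      form_id = readr::col_character(),
      case_id = readr::col_character(),
      exchange_index = readr::col_integer(),
      option_id = readr::col_character(),
      occasion = readr::col_integer()
    ))
}

#' @rdname read_response_log
#' @export
write_response_log <- function(log, path) {
  readr::write_csv(log, path)
  invisible(path)
}

# ---- internal helpers -----------------------------------------------------

# resolve the case set a log is scored against, and check completeness:
# exactly one selection per exchange, each option belonging to its exchange
resolve_selections <- function(log, bank, form = NULL) {
  log <- tibble::as_tibble(log)
  required <- c("case_id", "exchange_index", "option_id")
  miss <- setdiff(required, names(log))
  if (length(miss)) {
    stop("log is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  case_ids <- if (is.null(form)) unique(log$case_id) else form$cases$case_id
  unknown <- setdiff(case_ids, bank$cases$case_id)
  if (length(unknown)) {
    stop("log references case(s) not in bank: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  expected <- bank$exchanges[bank$exchanges$case_id %in% case_ids,
                             c("case_id", "exchange_index")]
  key_exp <- paste(expected$case_id, expected$exchange_index)
  key_log <- paste(log$case_id, log$exchange_index)
  if (anyDuplicated(key_log)) {
    stop("log contains more than one selection for exchange(s): ",
         paste(unique(key_log[duplicated(key_log)]), collapse = "; "),
         call. = FALSE)
  }
  missing_ex <- setdiff(key_exp, key_log)
  if (length(missing_ex)) {
    stop("log is incomplete; no selection for exchange(s): ",
         paste(missing_ex, collapse = "; "), call. = FALSE)
  }
  extra <- setdiff(key_log, key_exp)
  if (length(extra)) {
    stop("log contains selection(s) outside the scored cases: ",
         paste(extra, collapse = "; "), call. = FALSE)
  }
  sel <- dplyr::inner_join(
    log,
    dplyr::select(bank$options, "case_id", "exchange_index", "option_id",
                  "rank", "mc_points", "tags"),
    by = c("case_id", "exchange_index", "option_id"))
  if (nrow(sel) != nrow(log)) {
    key_sel <- paste(sel$case_id, sel$exchange_index)
    bad <- setdiff(key_log, key_sel)
    stop("selected option does not belong to its exchange for: ",
         paste(bad, collapse = "; "), call. = FALSE)
  }
  sel
}

# exchange-level opportunity counts per competency over a set of cases
opportunity_counts <- function(bank, case_ids) {
  tag_rows <- bank$options[bank$options$case_id %in% case_ids, ]
  tag_rows <- tidyr::unnest(
    dplyr::select(tag_rows, "case_id", "exchange_index", "tags"), "tags")
  tag_rows <- dplyr::distinct(tag_rows, .data$case_id,
                              .data$exchange_index, .data$tags)
  counts <- dplyr::count(tag_rows, competency = .data$tags, name = "O")
  dplyr::left_join(mc_competencies(), counts, by = "competency") |>
    dplyr::mutate(O = as.integer(dplyr::coalesce(.data$O, 0L)))
}

# the weighting convention, isolated in one place: positive competencies are
# weighted by their share of positive opportunities (renormalized over the
# competencies actually assessed, i.e. O > 0, so a perfect respondent scores
# exactly 100); the pooled negative block is weighted by the negative share
# of all opportunities
competency_weights <- function(counts) {
  pos <- counts$polarity == "positive"
  assessed <- counts$O > 0
  pos_total <- sum(counts$O[pos & assessed])
  neg_total <- sum(counts$O[!pos])
  counts$assessed <- assessed
  counts$weight <- NA_real_
  if (pos_total > 0) {
    counts$weight[pos & assessed] <-
      100 * counts$O[pos & assessed] / pos_total
  }
  counts$weight[pos & !assessed] <- 0
  attr(counts, "neg_weight") <-
    if (neg_total > 0) 100 * neg_total / (pos_total + neg_total) else 0
  attr(counts, "neg_total") <- neg_total
  counts
}

# full per-competency table + global score from a selections table
competency_table <- function(sel, bank, case_ids) {
  counts <- competency_weights(opportunity_counts(bank, case_ids))
  chosen <- tidyr::unnest(dplyr::select(sel, "case_id", "tags"), "tags")
  s_counts <- dplyr::count(chosen, competency = .data$tags, name = "S")
  tab <- dplyr::left_join(counts, s_counts, by = "competency") |>
    dplyr::mutate(S = as.integer(dplyr::coalesce(.data$S, 0L)))
  stopifnot(all(tab$S <= tab$O))
  pos <- tab$polarity == "positive"
  tab$contribution <- NA_real_
  tab$contribution[pos] <- ifelse(
    tab$assessed[pos],
    (tab$S[pos] / pmax(tab$O[pos], 1L)) * tab$weight[pos],
    0)
  neg_total <- attr(counts, "neg_total")
  neg_weight <- attr(counts, "neg_weight")
  neg_block <- if (neg_total > 0) {
    sum(tab$S[!pos]) / neg_total * neg_weight
  } else {
    0
  }
  list(
    table = dplyr::select(tab, "competency", "label", "polarity",
                          "S", "O", "assessed", "weight", "contribution"),
    neg_block = neg_block,
    neg_weight = neg_weight,
    global = sum(tab$contribution[pos]) - neg_block
  )
}

# ---- user-facing scoring --------------------------------------------------

#' Ranking score of a response log
#'
#' The ranking score rewards choosing MC-consistent replies: each selection
#' earns the points of its rank (+2, +1, 0, -1, -2 for ranks 1..5); the sum
#' is divided by twice the number of exchanges and expressed as a percent,
#' so the score lies in \[-100, 100\] and a respondent always selecting the
#' most MC-consistent option scores 100.
#'
#' @param log a response log (see [read_response_log()]) covering every
#'   exchange of the scored cases exactly once.
#' @param bank the `mccat_bank`.
#' @param form optional `mccat_form`; if supplied, the log must cover
#'   exactly that form's cases. Without it, the cases present in the log are
#'   scored.
#' @return A single numeric percent in \[-100, 100\].
#' @examples
#' bank <- generate_fixture_bank(seed = 1)
#' form <- assemble_form(bank, seed = 7)
#' # a respondent always picking the rank-1 option:
#' log <- perfect_log(bank, form)
#' score_ranking(log, bank, form) # 100
#' @export
score_ranking <- function(log, bank, form = NULL) {
  sel <- resolve_selections(log, bank, form)
  sum(sel$mc_points) / (2 * nrow(sel)) * 100
}

#' Global competency score and per-competency subscales
#'
#' Per-competency scores consider how often the respondent chose a reply
#' demonstrating the competency (S) out of the occasions on which it was
#' available (O, counted at exchange level over the scored cases). Each
#' positive competency contributes its selection ratio S/O times a weight
#' proportional to its share of positive opportunities; the three negative
#' competencies are pooled into one block — the pooled selection ratio times
#' the negative share of all opportunities — which is subtracted. The
#' resulting global score has a ceiling of exactly 100 (all positive ratios
#' 1, no negative selections). Competencies never offered by the scored
#' cases (O = 0) contribute 0, are flagged `assessed = FALSE`, and the
#' positive weights renormalize over the assessed competencies.
#'
#' @inheritParams score_ranking
#' @return An object of class `mccat_scores`; use [tidy()][tidy.mccat_scores]
#'   for the per-competency table and [glance()][glance.mccat_scores] for the
#'   one-row summary. Fields: `per_competency` (tibble with S, O, weight,
#'   contribution, assessed), `global_competency`, `ranking`,
#'   `negative_block`, `rank_histogram` (counts of chosen ranks 1..5),
#'   `case_ids`.
#' @examples
#' bank <- generate_fixture_bank(seed = 1)
#' form <- assemble_form(bank, seed = 7)
#' scores <- score_competencies(perfect_log(bank, form), bank, form)
#' scores$global_competency # 100
#' @export
score_competencies <- function(log, bank, form = NULL) {
  sel <- resolve_selections(log, bank, form)
  case_ids <- if (is.null(form)) unique(sel$case_id) else form$cases$case_id
  ct <- competency_table(sel, bank, case_ids)
  hist <- tabulate(sel$rank, nbins = 5)
  structure(
    list(
      per_competency = ct$table,
      global_competency = ct$global,
      ranking = sum(sel$mc_points) / (2 * nrow(sel)) * 100,
      negative_block = ct$neg_block,
      negative_weight = ct$neg_weight,
      rank_histogram = stats::setNames(hist, paste0("rank", 1:5)),
      case_ids = case_ids,
      respondent_id = if ("respondent_id" %in% names(sel))
        unique(sel$respondent_id)[1] else NA_character_
    ),
    class = "mccat_scores"
  )
}

#' @export
print.mccat_scores <- function(x, ...) {
  cat("<mccat_scores>",
      if (!is.na(x$respondent_id)) paste0(" respondent ", x$respondent_id),
      "\n", sep = "")
  cat("  cases: ", paste(x$case_ids, collapse = ", "), "\n", sep = "")
  cat(sprintf("  global competency score: %.1f\n", x$global_competency))
  cat(sprintf("  ranking score:           %.1f\n", x$ranking))
  cat("  chosen ranks 1..5: ",
      paste(x$rank_histogram, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Per-competency subscale table
#'
#' Convenience wrapper returning the machine-readable subscale table of a
#' scored log: selected count S, occasion count O, weight, contribution,
#' and the not-assessed flag, per competency.
#'
#' @param scores an `mccat_scores` object, or a response log (in which case
#'   `bank`/`form` are forwarded to [score_competencies()]).
#' @param bank,form see [score_competencies()].
#' @return A tibble with one row per competency.
#' @export
subscale_report <- function(scores, bank = NULL, form = NULL) {
  if (!inherits(scores, "mccat_scores")) {
    scores <- score_competencies(scores, bank, form)
  }
  scores$per_competency
}

#' Score every respondent and occasion of a cohort of logs
#'
#' Batch scoring: computes, per respondent and occasion, the overall global
#' competency and ranking scores and (optionally) the same scores restricted
#' to each case family — the unit used by the case-variant consistency
#' analysis.
#'
#' @param logs a response-log tibble covering several respondents/occasions
#'   (columns as in [read_response_log()]).
#' @param bank the `mccat_bank`.
#' @param by_family also return per-family scores.
#' @return A list of tibbles: `overall` (respondent_id, occasion, form_id,
#'   global_competency, ranking) and, if requested, `by_family`
#'   (respondent_id, occasion, family, case_id, variant, global_competency,
#'   ranking).
#' @export
score_cohort <- function(logs, bank, by_family = TRUE) {
  logs <- tibble::as_tibble(logs)
  if (!"occasion" %in% names(logs)) logs$occasion <- 1L
  sel <- dplyr::inner_join(
    logs,
    dplyr::select(bank$options, "case_id", "exchange_index", "option_id",
                  "rank", "mc_points", "tags"),
    by = c("case_id", "exchange_index", "option_id"))
  if (nrow(sel) != nrow(logs)) {
    stop("some selections do not match an option in the bank", call. = FALSE)
  }

  # per-case opportunity totals by polarity (exchange level); because the
  # positive weights are proportional to opportunity shares, the global
  # score reduces exactly to
  #   100 * S_pos / O_pos - 100 * S_neg / (O_pos + O_neg)
  pos <- positive_competencies()
  tag_rows <- tidyr::unnest(
    dplyr::select(bank$options, "case_id", "exchange_index", "tags"),
    "tags") |>
    dplyr::distinct(.data$case_id, .data$exchange_index, .data$tags)
  case_opp <- tag_rows |>
    dplyr::group_by(.data$case_id) |>
    dplyr::summarise(
      O_pos = sum(.data$tags %in% pos),
      O_neg = sum(!.data$tags %in% pos),
      .groups = "drop")

  n_pos_tags <- vapply(sel$tags, function(tg) sum(tg %in% pos), numeric(1))
  n_neg_tags <- lengths(sel$tags) - n_pos_tags
  sel$S_pos <- n_pos_tags
  sel$S_neg <- n_neg_tags

  score_groups <- function(grouped) {
    opp <- grouped |>
      dplyr::distinct(.data$case_id) |>
      dplyr::left_join(case_opp, by = "case_id") |>
      dplyr::summarise(O_pos = sum(.data$O_pos), O_neg = sum(.data$O_neg),
                       .groups = "drop")
    sums <- grouped |>
      dplyr::summarise(
        S_pos = sum(.data$S_pos), S_neg = sum(.data$S_neg),
        points = sum(.data$mc_points), k = dplyr::n(), .groups = "drop")
    keys <- setdiff(names(sums), c("S_pos", "S_neg", "points", "k"))
    dplyr::left_join(sums, opp, by = keys) |>
      dplyr::mutate(
        global_competency =
          ifelse(.data$O_pos > 0, 100 * .data$S_pos / .data$O_pos, 0) -
          ifelse(.data$O_pos + .data$O_neg > 0,
                 100 * .data$S_neg / (.data$O_pos + .data$O_neg), 0),
        ranking = .data$points / (2 * .data$k) * 100) |>
      dplyr::select(-"S_pos", -"S_neg", -"points", -"k",
                    -"O_pos", -"O_neg")
  }

  overall <- score_groups(dplyr::group_by(
    sel, .data$respondent_id, .data$occasion, .data$form_id))
  out <- list(overall = overall)
  if (by_family) {
    fam_map <- dplyr::select(bank$cases, "case_id", "family", "variant")
    out$by_family <- sel |>
      dplyr::left_join(fam_map, by = "case_id") |>
      dplyr::group_by(.data$respondent_id, .data$occasion, .data$family,
                      .data$case_id, .data$variant) |>
      score_groups()
  }
  out
}

#' Theoretical range of the global competency score
#'
#' The global competency score is additive over selections, so the exact
#' minimum and maximum achievable scores are found by optimizing each
#' exchange independently: each option's marginal contribution is the sum of
#' the per-opportunity weights of its positive tags minus the per-occasion
#' negative weight for each negative tag.
#'
#' @param bank an `mccat_bank`.
#' @param case_ids the cases making up the scored assessment. Defaults to
#'   the cases of `form` if given, else the lowest-numbered variant of each
#'   family present in the bank (for the canonical bank all variant choices
#'   give the same range, by structural equivalence).
#' @param form optional `mccat_form`.
#' @return A one-row tibble with columns `min` and `max` (percent).
#' @export
theoretical_range <- function(bank, case_ids = NULL, form = NULL) {
  stopifnot(inherits(bank, "mccat_bank"))
  if (is.null(case_ids)) {
    case_ids <- if (!is.null(form)) {
      form$cases$case_id
    } else {
      bank$cases |>
        dplyr::group_by(.data$family) |>
        dplyr::slice_min(.data$variant, n = 1, with_ties = FALSE) |>
        dplyr::pull(.data$case_id)
    }
  }
  counts <- competency_weights(opportunity_counts(bank, case_ids))
  per_opp <- stats::setNames(
    ifelse(counts$polarity == "positive",
           ifelse(counts$assessed, counts$weight / pmax(counts$O, 1L), 0),
           -(if (attr(counts, "neg_total") > 0)
               attr(counts, "neg_weight") / attr(counts, "neg_total")
             else 0)),
    counts$competency)

  opts <- bank$options[bank$options$case_id %in% case_ids, ]
  contrib <- vapply(opts$tags, function(tg) sum(per_opp[tg]), numeric(1))
  key <- paste(opts$case_id, opts$exchange_index)
  mins <- tapply(contrib, key, min)
  maxs <- tapply(contrib, key, max)
  tibble::tibble(min = sum(mins), max = sum(maxs))
}

#' A log in which every selection is the rank-1 option
#'
#' Utility used in examples and tests: the response log of an ideal
#' respondent who always picks the most MC-consistent reply of the form.
#'
#' @param bank an `mccat_bank`.
#' @param form an `mccat_form`.
#' @param respondent_id,occasion identifiers recorded on the log.
#' @return A response-log tibble.
#' @export
perfect_log <- function(bank, form, respondent_id = "ideal", occasion = 1L) {
  opts <- bank$options[bank$options$case_id %in% form$cases$case_id &
                         bank$options$rank == 1L, ]
  tibble::tibble(
    respondent_id = respondent_id,
    form_id = form$form_id,
    case_id = opts$case_id,
    exchange_index = opts$exchange_index,
    option_id = opts$option_id,
    occasion = as.integer(occasion)
  )
}
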