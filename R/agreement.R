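#' Classify an expert's rank against the reference rank
#'
#' Content validation asks a panel of behaviour-change experts to re-rank
#' each exchange's five response options. An expert judgment is *good* when
#' it matches the reference rank exactly, *acceptable* at a one-point
#' deviation in either direction, and *poor* at a deviation of two or more
#' points (deviations beyond two are a fortiori poor).
#'
#' @param expert_rank,reference_rank integer vectors of ranks in 1..5
#'   (recycled against each other).
#' @return A character vector in `c("good", "acceptable", "poor")`.
#' @examples
#' classify_rank_agreement(5, 4) # acceptable
#' classify_rank_agreement(1, 3) # poor
#' @export
classify_rank_agreement <- function(expert_rank, reference_rank) {
  for (x in list(expert_rank, reference_rank)) {
    if (!is.numeric(x) || anyNA(x) || any(x < 1 | x > 5 | x != as.integer(x))) {
      stop("ranks must be integers in 1..5", call. = FALSE)
    }
  }
  dev <- abs(as.integer(expert_rank) - as.integer(reference_rank))
  dplyr::case_when(
    dev == 0 ~ "good",
    dev == 1 ~ "acceptable",
    .default = "poor"
  )
}

#' Read / write expert rating files
#'
#' One row per expert judgment: `expert_id`, `case_id`, `exchange_index`,
#' `option_id`, `assigned_rank` and `identified_tags` (semicolon-separated
#' competency identifiers, possibly empty).
#'
#' @param path CSV path.
#' @param ratings a ratings tibble (with `identified_tags` as either a
#'   list-column or a semicolon string).
#' @return A tibble with `identified_tags` as a list-column
#'   (`read_expert_ratings`); `path` invisibly (`write_expert_ratings`).
#' @export
read_expert_ratings <- function(path) {
  out <- readr::read_csv(
    path,
    col_types = readr::cols(
      expert_id = readr::col_character(),
      case_id = readr::col_character(),
      exchange_index = readr::col_integer(),
      option_id = readr::col_character(),
      assigned_rank = readr::col_integer(),
      identified_tags = readr::col_character()
    ))
  out$identified_tags <- strsplit(
    dplyr::coalesce(out$identified_tags, ""), ";", fixed = TRUE)
  out$identified_tags <- lapply(out$identified_tags,
                                function(x) x[nzchar(x)])
  out
}

#' @rdname read_expert_ratings
#' @export
write_expert_ratings <- function(ratings, path) {
  ratings <- tibble::as_tibble(ratings)
  if (is.list(ratings$identified_tags)) {
    ratings$identified_tags <- vapply(
      ratings$identified_tags, paste, character(1), collapse = ";")
  }
  readr::write_csv(ratings, path)
  invisible(path)
}

#' Aggregate an expert panel's rank judgments into an agreement report
#'
#' Every rating is classified against the bank's reference rank with
#' [classify_rank_agreement()]. Percentages of good / acceptable / poor
#' judgments are computed per option, then pooled per exchange (all five
#' options of the exchange, over all experts) — one row per "choice of
#' response" slot, the unit at which consensus tables are reported — and
#' summarized per case and overall with [summarize_agreement_table()].
#'
#' @param ratings an expert-ratings tibble (see [read_expert_ratings()]).
#' @param bank the `mccat_bank` holding the reference ranks.
#' @return An object of class `mccat_agreement`: a list with `per_option`
#'   (option-level percentages), `per_exchange` (exchange-level rows:
#'   `case_id`, `exchange_index`, `good`, `acceptable`, `poor`,
#'   `n_judgments`), and `summary` (per-case and overall means/SDs from
#'   [summarize_agreement_table()]).
#' @export
aggregate_agreement <- function(ratings, bank) {
  ratings <- tibble::as_tibble(ratings)
  if (nrow(ratings) == 0) stop("no ratings supplied", call. = FALSE)
  ref <- dplyr::select(bank$options, "case_id", "exchange_index",
                       "option_id", reference_rank = "rank")
  joined <- dplyr::inner_join(
    ratings, ref, by = c("case_id", "exchange_index", "option_id"))
  if (nrow(joined) != nrow(ratings)) {
    stop("rating(s) reference option(s) not present in the bank",
         call. = FALSE)
  }
  joined$class <- classify_rank_agreement(joined$assigned_rank,
                                          joined$reference_rank)
  pct <- function(cls, n) 100 * sum(cls == n) / length(cls)
  per_option <- joined |>
    dplyr::group_by(.data$case_id, .data$exchange_index, .data$option_id) |>
    dplyr::summarise(
      good = pct(.data$class, "good"),
      acceptable = pct(.data$class, "acceptable"),
      poor = pct(.data$class, "poor"),
      n_judgments = dplyr::n(),
      .groups = "drop")
  per_exchange <- joined |>
    dplyr::group_by(.data$case_id, .data$exchange_index) |>
    dplyr::summarise(
      good = pct(.data$class, "good"),
      acceptable = pct(.data$class, "acceptable"),
      poor = pct(.data$class, "poor"),
      n_judgments = dplyr::n(),
      .groups = "drop")
  rows <- dplyr::mutate(per_exchange,
                        case = substr(.data$case_id, 1, 1))
  structure(
    list(
      per_option = per_option,
      per_exchange = per_exchange,
      summary = summarize_agreement_table(
        dplyr::select(rows, "case", "good", "acceptable", "poor"))
    ),
    class = "mccat_agreement"
  )
}

#' @export
print.mccat_agreement <- function(x, ...) {
  cat("<mccat_agreement> ", nrow(x$per_exchange), " exchange rows, ",
      nrow(x$per_option), " option rows\n", sep = "")
  ov <- x$summary[x$summary$case == "Overall", ]
  cat(sprintf("  overall good %.1f (SD %.1f), acceptable %.1f, poor %.1f\n",
              ov$good_mean, ov$good_sd, ov$acceptable_mean, ov$poor_mean))
  invisible(x)
}

#' Summarize per-exchange agreement rows into case and overall means
#'
#' Takes the per-row good / acceptable / poor percentages (one row per
#' choice-of-response slot, grouped by case) and returns unweighted
#' per-case means and sample SDs plus the unweighted overall mean and SD
#' over all rows — the arithmetic used in published consensus tables.
#'
#' @param rows a tibble with columns `case` (grouping label) and `good`,
#'   `acceptable`, `poor` (percentages per row).
#' @return A tibble with one row per case plus an `"Overall"` row; columns
#'   `case`, `n_rows`, and `<class>_mean` / `<class>_sd` for each of the
#'   three classes.
#' @examples
#' rows <- expert_agreement_rows()
#' summarize_agreement_table(
#'   dplyr::transmute(rows, case, good = good_initial,
#'                    acceptable = acceptable_initial, poor = poor_initial))
#' @export
summarize_agreement_table <- function(rows) {
  rows <- tibble::as_tibble(rows)
  miss <- setdiff(c("case", "good", "acceptable", "poor"), names(rows))
  if (length(miss)) {
    stop("rows missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  per_case <- rows |>
    dplyr::group_by(.data$case) |>
    dplyr::summarise(
      n_rows = dplyr::n(),
      good_mean = mean(.data$good), good_sd = stats::sd(.data$good),
      acceptable_mean = mean(.data$acceptable),
      acceptable_sd = stats::sd(.data$acceptable),
      poor_mean = mean(.data$poor), poor_sd = stats::sd(.data$poor),
      .groups = "drop")
  overall <- tibble::tibble(
    case = "Overall",
    n_rows = nrow(rows),
    good_mean = mean(rows$good), good_sd = stats::sd(rows$good),
    acceptable_mean = mean(rows$acceptable),
    acceptable_sd = stats::sd(rows$acceptable),
    poor_mean = mean(rows$poor), poor_sd = stats::sd(rows$poor))
  dplyr::bind_rows(per_case, overall)
}

#' Competency-identification agreement of an expert panel
#'
#' For each expert and option, agreement is the recall of the reference
#' tag-set: the proportion of the option's reference competencies the
#' expert listed. Options whose reference tag-set is empty are excluded
#' (recall is undefined there). Tags the expert listed that are not in the
#' reference set are counted separately as `false_positives` and are not
#' penalized; this definition is isolated here so an alternative (e.g.
#' Jaccard) can be substituted.
#'
#' @inheritParams aggregate_agreement
#' @return A list of tibbles: `per_option` (case_id, exchange_index,
#'   option_id, agreement %, mean false positives), `per_case`, and
#'   `overall` (one row).
#' @export
competency_identification_agreement <- function(ratings, bank) {
  ratings <- tibble::as_tibble(ratings)
  ref <- dplyr::select(bank$options, "case_id", "exchange_index",
                       "option_id", ref_tags = "tags")
  joined <- dplyr::inner_join(
    ratings, ref, by = c("case_id", "exchange_index", "option_id"))
  if (nrow(joined) != nrow(ratings)) {
    stop("rating(s) reference option(s) not present in the bank",
         call. = FALSE)
  }
  joined <- joined[lengths(joined$ref_tags) > 0, ]
  if (nrow(joined) == 0) {
    stop("no rated option has a nonempty reference tag-set", call. = FALSE)
  }
  joined$recall <- purrr::map2_dbl(
    joined$identified_tags, joined$ref_tags,
    function(id, ref) 100 * length(intersect(id, ref)) / length(ref))
  joined$false_positives <- purrr::map2_int(
    joined$identified_tags, joined$ref_tags,
    function(id, ref) length(setdiff(id, ref)))
  per_option <- joined |>
    dplyr::group_by(.data$case_id, .data$exchange_index, .data$option_id) |>
    dplyr::summarise(agreement = mean(.data$recall),
                     false_positives = mean(.data$false_positives),
                     n_experts = dplyr::n(), .groups = "drop")
  per_case <- per_option |>
    dplyr::mutate(case = substr(.data$case_id, 1, 1)) |>
    dplyr::group_by(.data$case) |>
    dplyr::summarise(agreement = mean(.data$agreement),
                     sd = stats::sd(.data$agreement), n_options = dplyr::n(),
                     .groups = "drop")
  overall <- tibble::tibble(
    agreement = mean(per_option$agreement),
    sd = stats::sd(per_option$agreement),
    n_options = nrow(per_option))
  list(per_option = per_option, per_case = per_case, overall = overall)
}

#' Modification decision for a rated item
#'
#' Applies the content-validation decision rules to a row's agreement
#' percentages. Rank side: no modification is needed when good agreement is
#' at least 70% with at most 10% poor, or when good plus acceptable reaches
#' 90% with at most 10% poor; otherwise the item must be modified and then
#' re-reach one of those thresholds with under 10% complete disagreement.
#' Competency side: the tagged competencies are kept (or missing ones
#' added) at 70%+ identification agreement, left to the development team's
#' discretion at 40–69%, and deleted at 30% or below. Agreement strictly
#' between 30 and 40 falls in a gap the published criteria do not address;
#' it is treated as DELETE and flagged `gap_region`.
#'
#' @param good,acceptable,poor rank-agreement percentages (vectors).
#' @param competency_agreement competency-identification percentages.
#' @return A tibble with columns `rank_decision`
#'   (`"NO_MODIFICATION"`/`"MODIFY"`), `competency_decision`
#'   (`"KEEP_OR_ADD"`/`"TEAM_DISCRETION"`/`"DELETE"`), `gap_region`
#'   (logical), and `post_modification_requirement` (the re-validation
#'   threshold recorded for items flagged MODIFY, `NA` otherwise).
#' @examples
#' modification_decision(72, 20, 8, 80)
#' modification_decision(50, 41, 9, 55)
#' @export
modification_decision <- function(good, acceptable, poor,
                                  competency_agreement) {
  n <- max(lengths(list(good, acceptable, poor, competency_agreement)))
  good <- rep_len(good, n); acceptable <- rep_len(acceptable, n)
  poor <- rep_len(poor, n)
  competency_agreement <- rep_len(competency_agreement, n)
  for (x in list(good, acceptable, poor, competency_agreement)) {
    if (any(x < 0 | x > 100)) {
      stop("percentages must lie in [0, 100]", call. = FALSE)
    }
  }
  rank_ok <- (good >= 70 & poor <= 10) |
    (good + acceptable >= 90 & poor <= 10)
  comp_decision <- dplyr::case_when(
    competency_agreement >= 70 ~ "KEEP_OR_ADD",
    competency_agreement >= 40 ~ "TEAM_DISCRETION",
    .default = "DELETE"
  )
  tibble::tibble(
    rank_decision = ifelse(rank_ok, "NO_MODIFICATION", "MODIFY"),
    competency_decision = comp_decision,
    gap_region = competency_agreement > 30 & competency_agreement < 40,
    post_modification_requirement = ifelse(
      rank_ok, NA_character_,
      paste("minimum of 70% perfect agreement or 90% perfect and partial",
            "agreement and <10% of complete disagreement"))
  )
}

#' Bundled reference expert-panel agreement rows
#'
#' The 25 per-exchange good / acceptable / poor agreement percentages from
#' the tool's development-round expert validation (initial round and after
#' item modification), bundled as reference data for demonstrating and
#' checking the consensus-summary arithmetic.
#'
#' @return A tibble with columns `case` (A–D), `item` (choice-of-response
#'   slot within the case), `good_initial`, `acceptable_initial`,
#'   `poor_initial`, `good_post`, `acceptable_post`, `poor_post`.
#' @export
expert_agreement_rows <- function() {
  path <- system.file("extdata", "expert_rank_agreement.csv",
                      package = "mccat", mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(
    case = readr::col_character(),
    item = readr::col_integer(),
    .default = readr::col_double()))
}
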