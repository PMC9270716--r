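#' Tidy a score report
#'
#' @param x an `mccat_scores` object.
#' @param ... unused.
#' @return The per-competency tibble: competency, label, polarity, S
#'   (selected count), O (occasion count), assessed, weight, contribution.
#' @export
tidy.mccat_scores <- function(x, ...) {
  x$per_competency
}

#' One-row summary of a score report
#'
#' @param x an `mccat_scores` object.
#' @param ... unused.
#' @return A one-row tibble: global_competency, ranking, negative_block,
#'   n_exchanges, and the chosen-rank histogram as rank1..rank5 columns.
#' @export
glance.mccat_scores <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(
      global_competency = x$global_competency,
      ranking = x$ranking,
      negative_block = x$negative_block,
      n_exchanges = sum(x$rank_histogram)),
    tibble::as_tibble(as.list(x$rank_histogram)))
}

#' Tidy an agreement report
#'
#' @param x an `mccat_agreement` object.
#' @param ... unused.
#' @return The per-exchange agreement rows (case_id, exchange_index, good,
#'   acceptable, poor, n_judgments).
#' @export
tidy.mccat_agreement <- function(x, ...) {
  x$per_exchange
}

#' One-row summary of an agreement report
#'
#' @param x an `mccat_agreement` object.
#' @param ... unused.
#' @return The overall row of the consensus summary as a one-row tibble.
#' @export
glance.mccat_agreement <- function(x, ...) {
  x$summary[x$summary$case == "Overall", ]
}

#' Tidy a reliability report
#'
#' @param x an `mccat_reliability` object.
#' @param ... unused.
#' @return The variant-ANOVA table (one row per occasion x family x score).
#' @export
tidy.mccat_reliability <- function(x, ...) {
  x$anova
}

#' One-row-per-occasion summary of a reliability report
#'
#' @param x an `mccat_reliability` object.
#' @param ... unused.
#' @return The overall-alpha rows (scope `"all"`) of the alpha table.
#' @export
glance.mccat_reliability <- function(x, ...) {
  x$alpha[x$alpha$scope == "all", ]
}
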