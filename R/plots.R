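#' Plot an opportunity census as a competency-by-case tile map
#'
#' @param object an `mccat_census` from [opportunity_census()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.mccat_census <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$competency <- factor(d$competency,
                         levels = rev(mc_competencies()$competency))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$case_id, y = .data$competency,
                                  fill = .data$n)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "grey95", high = "steelblue") +
    ggplot2::labs(x = "Case", y = NULL, fill = "Opportunities",
                  title = "Competency opportunities per case") +
    ggplot2::theme_minimal()
}

#' Plot a score report's per-competency contributions
#'
#' Positive competencies are shown as their weighted contributions (summing
#' to the positive part of the global score); the pooled negative block is
#' shown as one negative bar.
#'
#' @param object an `mccat_scores` object.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.mccat_scores <- function(object, ...) {
  pc <- object$per_competency
  pos <- pc[pc$polarity == "positive", c("label", "contribution")]
  d <- dplyr::bind_rows(
    pos,
    tibble::tibble(label = "Negative competencies (pooled)",
                   contribution = -object$negative_block))
  d$direction <- ifelse(d$contribution >= 0, "positive", "negative")
  d$label <- factor(d$label, levels = rev(d$label))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$contribution, y = .data$label,
                                  fill = .data$direction)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(
      values = c(positive = "steelblue", negative = "firebrick")) +
    ggplot2::labs(
      x = "Contribution to global score (percentage points)", y = NULL,
      title = sprintf("Global competency score: %.1f",
                      object$global_competency)) +
    ggplot2::theme_minimal()
}

#' Plot an agreement report as stacked consensus bars
#'
#' @param object an `mccat_agreement` object.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.mccat_agreement <- function(object, ...) {
  d <- tidyr::pivot_longer(
    object$per_exchange, c("good", "acceptable", "poor"),
    names_to = "class", values_to = "pct")
  d$class <- factor(d$class, levels = c("poor", "acceptable", "good"))
  d$item <- paste0(d$case_id, "-", d$exchange_index)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pct, y = .data$item,
                                  fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(
      values = c(good = "steelblue", acceptable = "goldenrod",
                 poor = "firebrick")) +
    ggplot2::labs(x = "% of expert judgments", y = NULL, fill = NULL,
                  title = "Rank-order agreement by exchange") +
    ggplot2::theme_minimal()
}

#' Plot a reliability report
#'
#' Alpha coefficients per scope with the acceptance band, and variant-ANOVA
#' p-values per family and score type.
#'
#' @param object an `mccat_reliability` object.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.mccat_reliability <- function(object, ...) {
  a <- object$alpha
  a$occasion <- factor(a$occasion)
  ggplot2::ggplot(a, ggplot2::aes(x = .data$scope, y = .data$alpha,
                                  color = .data$occasion)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = object$band[1], ymax = object$band[2],
                      alpha = 0.15, fill = "steelblue") +
    ggplot2::geom_point(size = 3,
                        position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::labs(x = "Item scope", y = "Cronbach's alpha",
                  color = "Occasion",
                  title = "Internal consistency by item scope") +
    ggplot2::theme_minimal()
}
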