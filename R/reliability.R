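#' Item-rank matrix of a cohort of response logs
#'
#' Reshapes response logs into the respondents-by-items matrix used for
#' internal-consistency analysis: one row per respondent and occasion, one
#' column per item slot, entries being the rank (1–5) of the selected
#' option. Item identity across respondents is the slot
#' `(family, exchange_index)` — well-defined because every variant of a
#' family is structurally equivalent, so respondents who saw different
#' variants still answered the same 25 slots.
#'
#' @param logs a response-log tibble (several respondents/occasions).
#' @param bank the `mccat_bank`.
#' @return A tibble with columns `respondent_id`, `occasion`, then one
#'   integer column per slot named `<family><exchange_index>` (e.g. `A1`,
#'   ..., `C7`), families in order A–D. Incomplete respondents (missing any
#'   slot) are dropped with a warning (listwise completeness).
#' @export
item_rank_matrix <- function(logs, bank) {
  logs <- tibble::as_tibble(logs)
  if (!"occasion" %in% names(logs)) logs$occasion <- 1L
  sel <- dplyr::inner_join(
    logs,
    dplyr::select(bank$options, "case_id", "exchange_index", "option_id",
                  "rank"),
    by = c("case_id", "exchange_index", "option_id"))
  if (nrow(sel) != nrow(logs)) {
    stop("some selections do not match an option in the bank", call. = FALSE)
  }
  sel <- dplyr::left_join(
    sel, dplyr::select(bank$cases, "case_id", "family"), by = "case_id")
  sel$slot <- paste0(sel$family, sel$exchange_index)

  slot_levels <- bank$exchanges |>
    dplyr::left_join(dplyr::select(bank$cases, "case_id", "family"),
                     by = "case_id") |>
    dplyr::distinct(.data$family, .data$exchange_index) |>
    dplyr::arrange(.data$family, .data$exchange_index)
  slot_levels <- paste0(slot_levels$family, slot_levels$exchange_index)

  wide <- sel |>
    dplyr::select("respondent_id", "occasion", "slot", "rank") |>
    tidyr::pivot_wider(names_from = "slot", values_from = "rank")
  present <- intersect(slot_levels, names(wide))
  wide <- wide[, c("respondent_id", "occasion", present)]
  complete <- stats::complete.cases(wide[present])
  if (!all(complete)) {
    warning(sum(!complete), " incomplete respondent row(s) dropped",
            call. = FALSE)
    wide <- wide[complete, ]
  }
  wide
}

#' Cronbach's alpha over item columns
#'
#' Internal-consistency coefficient
#' \eqn{\alpha = k/(k-1)\,(1 - \sum_i s_i^2 / s_T^2)}, with \eqn{k} items,
#' \eqn{s_i^2} the sample variance of item \eqn{i} and \eqn{s_T^2} the
#' sample variance of the row totals. The conventional acceptance band for
#' an assessment of this kind is .70–.95.
#'
#' @param x an item matrix: a numeric matrix, a numeric data frame, or a
#'   tibble from [item_rank_matrix()] (its `respondent_id`/`occasion`
#'   columns are ignored).
#' @param items optional character vector naming the item columns to use
#'   (e.g. one family's slots); default: all numeric item columns.
#' @return The alpha coefficient (scalar), `NA` with attribute
#'   `reason = "degenerate"` if the total-score variance is zero.
#' @examples
#' m <- cbind(a = c(1, 3, 5), b = c(1, 3, 5))
#' cronbach_alpha(m) # 1: perfectly parallel items
#' @export
cronbach_alpha <- function(x, items = NULL) {
  if (is.data.frame(x)) {
    x <- x[, setdiff(names(x), c("respondent_id", "occasion")), drop = FALSE]
    x <- as.matrix(x)
  }
  if (!is.null(items)) x <- x[, items, drop = FALSE]
  storage.mode(x) <- "double"
  k <- ncol(x)
  if (k < 2 || nrow(x) < 2) {
    stop("alpha needs at least 2 items and 2 respondents", call. = FALSE)
  }
  item_var <- apply(x, 2, stats::var)
  total_var <- stats::var(rowSums(x))
  if (total_var <= .Machine$double.eps) {
    out <- NA_real_
    attr(out, "reason") <- "degenerate"
    return(out)
  }
  k / (k - 1) * (1 - sum(item_var) / total_var)
}

#' One-way ANOVA of scores across case variants
#'
#' Tests whether a family's variants produce different scores: a one-way
#' fixed-effects ANOVA of `score` on `variant`. Structurally equivalent
#' variants should show no effect; this is the parallel-form consistency
#' check. Degenerate inputs are resolved by convention: when the
#' between-group sum of squares is (numerically) zero the test is reported
#' as F = 0, p = 1; when groups differ but all within-group variance is
#' zero, F = Inf, p = 0.
#'
#' @param data a data frame of per-respondent scores.
#' @param score column holding the score (tidy-eval).
#' @param variant column holding the group label (tidy-eval).
#' @return A one-row tibble: `statistic` (F), `p.value`, `df_between`,
#'   `df_within`, `n`, and `groups`, a list-column holding the per-group
#'   `n`/`mean`/`sd` table.
#' @examples
#' d <- data.frame(v = rep(1:3, each = 4), y = rnorm(12))
#' variant_anova(d, y, v)
#' @export
variant_anova <- function(data, score, variant) {
  data <- tibble::as_tibble(data)
  y <- dplyr::pull(data, {{ score }})
  g <- factor(dplyr::pull(data, {{ variant }}))
  keep <- !is.na(y) & !is.na(g)
  y <- y[keep]; g <- droplevels(g[keep])
  sizes <- table(g)
  if (length(sizes) < 2 || sum(sizes >= 2) < 2) {
    stop("ANOVA needs at least 2 groups with at least 2 observations",
         call. = FALSE)
  }
  groups <- tibble::tibble(
    variant = names(sizes),
    n = as.integer(sizes),
    mean = as.numeric(tapply(y, g, mean)),
    sd = as.numeric(tapply(y, g, stats::sd))
  )
  grand <- mean(y)
  ssb <- sum(sizes * (groups$mean - grand)^2)
  ssw <- sum((y - groups$mean[as.integer(g)])^2)
  df1 <- length(sizes) - 1L
  df2 <- length(y) - length(sizes)
  sst <- ssb + ssw
  if (sst <= .Machine$double.eps || ssb <= 1e-12 * max(sst, 1)) {
    f <- 0; p <- 1
  } else if (ssw <= 1e-12 * sst) {
    f <- Inf; p <- 0
  } else {
    f <- (ssb / df1) / (ssw / df2)
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  tibble::tibble(
    statistic = f, p.value = p,
    df_between = df1, df_within = df2, n = length(y),
    groups = list(groups)
  )
}

#' Reliability report for a simulated or observed cohort
#'
#' Assembles the internal-consistency and parallel-form analytics for a
#' cohort of scored response logs: Cronbach's alpha over all item slots and
#' per family, and a one-way ANOVA across case variants for each family and
#' score type (global competency and ranking), per assessment occasion.
#'
#' @param logs a response-log tibble with variant attribution implicit in
#'   `case_id` (a [simulate_cohort()] cohort's `$logs` works directly).
#' @param bank the `mccat_bank`.
#' @param band the alpha acceptance band, default `c(0.70, 0.95)`.
#' @return An object of class `mccat_reliability`: a list with `alpha`
#'   (tibble: occasion, scope, n_items, n_respondents, alpha, degenerate,
#'   acceptable), `anova` (tibble: occasion, family, score, statistic,
#'   p.value, dfs, groups list-column), and `band`.
#' @export
consistency_report <- function(logs, bank, band = c(0.70, 0.95)) {
  logs <- tibble::as_tibble(logs)
  if (!"occasion" %in% names(logs)) logs$occasion <- 1L
  scores <- score_cohort(logs, bank, by_family = TRUE)

  alpha_rows <- list()
  for (occ in sort(unique(logs$occasion))) {
    irm <- item_rank_matrix(logs[logs$occasion == occ, ], bank)
    item_cols <- setdiff(names(irm), c("respondent_id", "occasion"))
    scopes <- c(list(all = item_cols),
                split(item_cols, substr(item_cols, 1, 1)))
    for (nm in names(scopes)) {
      a <- tryCatch(cronbach_alpha(irm, items = scopes[[nm]]),
                    error = function(e) NA_real_)
      alpha_rows[[length(alpha_rows) + 1]] <- tibble::tibble(
        occasion = occ, scope = nm,
        n_items = length(scopes[[nm]]), n_respondents = nrow(irm),
        alpha = as.numeric(a),
        degenerate = identical(attr(a, "reason"), "degenerate"),
        acceptable = !is.na(a) && a >= band[1] && a <= band[2])
    }
  }

  fam_scores <- tidyr::pivot_longer(
    scores$by_family, c("global_competency", "ranking"),
    names_to = "score", values_to = "value")
  anova_rows <- fam_scores |>
    dplyr::group_by(.data$occasion, .data$family, .data$score) |>
    dplyr::group_modify(function(d, key) {
      tryCatch(
        variant_anova(d, value, variant),
        error = function(e) tibble::tibble(
          statistic = NA_real_, p.value = NA_real_,
          df_between = NA_integer_, df_within = NA_integer_,
          n = nrow(d), groups = list(NULL))
      )
    }) |>
    dplyr::ungroup()

  structure(
    list(alpha = dplyr::bind_rows(alpha_rows), anova = anova_rows,
         band = band),
    class = "mccat_reliability")
}

#' @export
print.mccat_reliability <- function(x, ...) {
  cat("<mccat_reliability>\n")
  ov <- x$alpha[x$alpha$scope == "all", ]
  for (i in seq_len(nrow(ov))) {
    cat(sprintf(
      "  occasion %d: alpha = %s over %d items (%d respondents)%s\n",
      ov$occasion[i],
      ifelse(is.na(ov$alpha[i]), "undefined", sprintf("%.2f", ov$alpha[i])),
      ov$n_items[i], ov$n_respondents[i],
      ifelse(isTRUE(ov$acceptable[i]),
             sprintf(" [within %.2f-%.2f]", x$band[1], x$band[2]), "")))
  }
  sig <- sum(x$anova$p.value < 0.05, na.rm = TRUE)
  cat("  variant ANOVAs: ", nrow(x$anova), " cells, ",
      sig, " with p < .05\n", sep = "")
  invisible(x)
}
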