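#' Construct a case bank from its component tables
#'
#' A case bank holds competency-tagged virtual-patient cases. Each case
#' belongs to a family (`A`–`D`, one behavioural target each) and is one of
#' up to four structurally equivalent variants; each case is a sequence of
#' 6–7 conversational exchanges, and each exchange offers exactly 5 response
#' options ranked 1 (most MC-consistent, +2 points) to 5 (least consistent,
#' -2 points). Options carry tags naming the competencies they demonstrate.
#'
#' The bank is represented relationally as three tibbles (cases, exchanges,
#' options) plus metadata, so the usual dplyr verbs apply directly to its
#' components.
#'
#' @param cases tibble with columns `case_id`, `family`, `variant`,
#'   `behavior_target`, `language`, and `chart` (a list-column of named
#'   lists with `age`, `sex`, `condition`, `behavior_status`, `medications`,
#'   and optional `picture_ref`).
#' @param exchanges tibble with columns `case_id`, `exchange_index`,
#'   `patient_statement`.
#' @param options tibble with columns `case_id`, `exchange_index`,
#'   `option_id`, `text`, `rank`, `mc_points`, and `tags` (list-column of
#'   character vectors; possibly empty).
#' @param name,version bank metadata.
#' @param languages character vector of language tags present in the bank.
#' @param check validation level: `"strict"` additionally requires all four
#'   families to be present (the canonical-bank completeness invariant);
#'   `"structural"` checks only the per-case/per-exchange invariants and is
#'   intended for small experimental banks; `"none"` skips validation.
#' @return An object of class `mccat_bank`.
#' @seealso [validate_bank()], [load_bank()], [generate_fixture_bank()]
#' @export
mccat_bank <- function(cases, exchanges, options,
                       name = "unnamed bank", version = "1",
                       languages = unique(cases$language),
                       check = c("strict", "structural", "none")) {
  check <- match.arg(check)
  bank <- structure(
    list(
      metadata = list(name = name, version = version, languages = languages),
      cases = tibble::as_tibble(cases),
      exchanges = tibble::as_tibble(exchanges),
      options = tibble::as_tibble(options)
    ),
    class = "mccat_bank"
  )
  if (check != "none") {
    assert_valid_bank(bank, complete = check == "strict")
  }
  bank
}

#' @export
print.mccat_bank <- function(x, ...) {
  cat("<mccat_bank> ", x$metadata$name,
      " (version ", x$metadata$version, ")\n", sep = "")
  cat("  cases:     ", nrow(x$cases), " (",
      paste0(sort(unique(x$cases$family)), collapse = ", "), ")\n", sep = "")
  cat("  exchanges: ", nrow(x$exchanges), "\n", sep = "")
  cat("  options:   ", nrow(x$options), "\n", sep = "")
  invisible(x)
}

violation_row <- function(scope, case_id, exchange_index, message) {
  tibble::tibble(
    scope = scope,
    case_id = case_id %||% NA_character_,
    exchange_index = exchange_index %||% NA_integer_,
    message = message
  )
}

#' Validate a case bank against its structural invariants
#'
#' Checks, with case/exchange coordinates attached to every violation:
#' unique case ids; families in A–D and variants in 1–4; 6–7 exchanges per
#' case; exactly 5 options per exchange carrying ranks 1–5 once each;
#' `mc_points` equal to [points_for_rank()] of the rank; tags drawn from the
#' 11 known competencies; positive tags only on ranks 1–3 and negative tags
#' only on ranks 3–5; no competency tagging more than one option within an
#' exchange; structural equivalence of variants within a family (same
#' exchange count and identical rank-to-tag-set structure per exchange
#' slot); and, at the `complete` level, presence of all four families.
#'
#' @param bank an `mccat_bank`.
#' @param complete also require all four families (canonical completeness).
#' @return A tibble of violations (zero rows if the bank is valid) with
#'   columns `scope`, `case_id`, `exchange_index`, `message`.
#' @export
validate_bank <- function(bank, complete = TRUE) {
  stopifnot(inherits(bank, "mccat_bank"))
  v <- list()
  cases <- bank$cases
  exchanges <- bank$exchanges
  options <- bank$options

  if (anyDuplicated(cases$case_id)) {
    dup <- unique(cases$case_id[duplicated(cases$case_id)])
    v[[length(v) + 1]] <- violation_row(
      "bank", paste(dup, collapse = ","), NA_integer_, "duplicated case_id")
  }
  bad_fam <- cases$case_id[!cases$family %in% c("A", "B", "C", "D")]
  for (id in bad_fam) {
    v[[length(v) + 1]] <- violation_row(
      "case", id, NA_integer_, "family must be one of A, B, C, D")
  }
  bad_var <- cases$case_id[!cases$variant %in% 1:4]
  for (id in bad_var) {
    v[[length(v) + 1]] <- violation_row(
      "case", id, NA_integer_, "variant must be in 1..4")
  }
  if (complete) {
    missing_fam <- setdiff(c("A", "B", "C", "D"), cases$family)
    if (length(missing_fam)) {
      v[[length(v) + 1]] <- violation_row(
        "bank", NA_character_, NA_integer_,
        paste0("missing families: ", paste(missing_fam, collapse = ", ")))
    }
  }

  n_ex <- dplyr::count(exchanges, .data$case_id)
  for (i in seq_len(nrow(n_ex))) {
    if (n_ex$n[i] < 6 || n_ex$n[i] > 7) {
      v[[length(v) + 1]] <- violation_row(
        "case", n_ex$case_id[i], NA_integer_,
        paste0("case has ", n_ex$n[i], " exchanges; must have 6 or 7"))
    }
  }
  orphan <- setdiff(cases$case_id, exchanges$case_id)
  for (id in orphan) {
    v[[length(v) + 1]] <- violation_row(
      "case", id, NA_integer_, "case has no exchanges")
  }

  comp <- mc_competencies()
  pos <- comp$competency[comp$polarity == "positive"]
  neg <- comp$competency[comp$polarity == "negative"]

  opt_groups <- split(
    options,
    paste(options$case_id, options$exchange_index, sep = "\r"))
  for (g in opt_groups) {
    cid <- g$case_id[1]
    ex <- g$exchange_index[1]
    if (nrow(g) != 5 || !setequal(g$rank, 1:5) || anyDuplicated(g$rank)) {
      v[[length(v) + 1]] <- violation_row(
        "exchange", cid, ex,
        "exchange must have exactly 5 options with ranks 1..5 once each")
      next
    }
    if (!all(g$mc_points == points_for_rank(g$rank))) {
      v[[length(v) + 1]] <- violation_row(
        "exchange", cid, ex,
        "mc_points must map ranks 1..5 to 2,1,0,-1,-2")
    }
    tags <- unlist(g$tags)
    unknown <- setdiff(tags, comp$competency)
    if (length(unknown)) {
      v[[length(v) + 1]] <- violation_row(
        "exchange", cid, ex,
        paste0("unknown competency tag(s): ", paste(unknown, collapse = ", ")))
    }
    if (anyDuplicated(tags)) {
      dup <- unique(tags[duplicated(tags)])
      v[[length(v) + 1]] <- violation_row(
        "exchange", cid, ex,
        paste0("competency tags more than one option: ",
               paste(dup, collapse = ", ")))
    }
    for (j in seq_len(nrow(g))) {
      tg <- g$tags[[j]]
      if (g$rank[j] > 3 && any(tg %in% pos)) {
        v[[length(v) + 1]] <- violation_row(
          "option", cid, ex,
          paste0("positive tag on rank-", g$rank[j], " option ",
                 g$option_id[j], " (positive tags allowed on ranks 1-3)"))
      }
      if (g$rank[j] < 3 && any(tg %in% neg)) {
        v[[length(v) + 1]] <- violation_row(
          "option", cid, ex,
          paste0("negative tag on rank-", g$rank[j], " option ",
                 g$option_id[j], " (negative tags allowed on ranks 3-5)"))
      }
    }
  }

  # variant structural equivalence within each family
  sig <- structure_signatures(bank)
  for (fam in unique(cases$family)) {
    ids <- cases$case_id[cases$family == fam]
    if (length(ids) < 2) next
    ref <- sig[[ids[1]]]
    for (id in ids[-1]) {
      if (!identical(sig[[id]], ref)) {
        v[[length(v) + 1]] <- violation_row(
          "family", id, NA_integer_,
          paste0("variant structure differs from ", ids[1],
                 " within family ", fam))
      }
    }
  }

  if (length(v)) {
    dplyr::bind_rows(v)
  } else {
    tibble::tibble(
      scope = character(), case_id = character(),
      exchange_index = integer(), message = character())
  }
}

# canonical description of a case's (exchange, rank) -> tag-set structure,
# used to compare variants within a family
structure_signatures <- function(bank) {
  opts <- dplyr::arrange(bank$options, .data$case_id,
                         .data$exchange_index, .data$rank)
  split(
    lapply(opts$tags, function(t) sort(unlist(t))),
    opts$case_id
  ) |>
    lapply(unname)
}

assert_valid_bank <- function(bank, complete = TRUE) {
  v <- validate_bank(bank, complete = complete)
  if (nrow(v) > 0) {
    msgs <- paste0(
      "- [", v$scope,
      ifelse(is.na(v$case_id), "", paste0(" ", v$case_id)),
      ifelse(is.na(v$exchange_index),
             "", paste0(" exchange ", v$exchange_index)),
      "] ", v$message)
    stop("invalid case bank:\n", paste(msgs, collapse = "\n"), call. = FALSE)
  }
  invisible(bank)
}

#' Read a case bank from its JSON file
#'
#' The on-disk format is a single JSON document:
#' `{name, version, languages, cases: [{case_id, family, variant,
#' behavior_target, language, chart: {...}, exchanges: [{exchange_index,
#' patient_statement, options: [{option_id, text, rank, mc_points,
#' tags: [...]}]}]}]}`. The bank is validated on load; violations abort with
#' the offending case/exchange named.
#'
#' @param path path to a bank JSON file.
#' @param check validation level, as in [mccat_bank()].
#' @return An `mccat_bank`.
#' @seealso [write_bank()]
#' @export
load_bank <- function(path, check = "strict") {
  if (!file.exists(path)) {
    stop("bank file does not exist: ", path, call. = FALSE)
  }
  doc <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) {
      stop("could not parse bank JSON '", path, "': ",
           conditionMessage(e), call. = FALSE)
    })
  required <- c("name", "version", "cases")
  miss <- setdiff(required, names(doc))
  if (length(miss)) {
    stop("bank JSON is missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }

  cases <- purrr::map(doc$cases, function(cs) {
    for (f in c("case_id", "family", "variant", "exchanges")) {
      if (is.null(cs[[f]])) {
        stop("case entry missing field '", f, "'", call. = FALSE)
      }
    }
    tibble::tibble(
      case_id = as.character(cs$case_id),
      family = as.character(cs$family),
      variant = as.integer(cs$variant),
      behavior_target = as.character(cs$behavior_target %||% NA_character_),
      language = as.character(cs$language %||% "en"),
      chart = list(cs$chart %||% list())
    )
  }) |> dplyr::bind_rows()

  exchanges <- purrr::map(doc$cases, function(cs) {
    purrr::map(cs$exchanges, function(ex) {
      if (is.null(ex$exchange_index)) {
        stop("exchange in case ", cs$case_id,
             " missing 'exchange_index'", call. = FALSE)
      }
      tibble::tibble(
        case_id = as.character(cs$case_id),
        exchange_index = as.integer(ex$exchange_index),
        patient_statement = as.character(ex$patient_statement %||% "")
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  options <- purrr::map(doc$cases, function(cs) {
    purrr::map(cs$exchanges, function(ex) {
      purrr::map(ex$options, function(op) {
        for (f in c("option_id", "rank", "mc_points")) {
          if (is.null(op[[f]])) {
            stop("option in case ", cs$case_id, " exchange ",
                 ex$exchange_index, " missing '", f, "'", call. = FALSE)
          }
        }
        tibble::tibble(
          case_id = as.character(cs$case_id),
          exchange_index = as.integer(ex$exchange_index),
          option_id = as.character(op$option_id),
          text = as.character(op$text %||% ""),
          rank = as.integer(op$rank),
          mc_points = as.integer(op$mc_points),
          tags = list(as.character(unlist(op$tags)))
        )
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  mccat_bank(
    cases, exchanges, options,
    name = doc$name,
    version = as.character(doc$version),
    languages = as.character(unlist(doc$languages %||% unique(cases$language))),
    check = check
  )
}

#' Write a case bank to JSON
#'
#' Serialization is deterministic (stable key order, no timestamps), so a
#' bank written twice produces byte-identical files and
#' `load_bank(write_bank(bank))` round-trips field-by-field.
#'
#' @param bank an `mccat_bank`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bank <- function(bank, path) {
  stopifnot(inherits(bank, "mccat_bank"))
  doc <- list(
    name = bank$metadata$name,
    version = bank$metadata$version,
    languages = as.list(bank$metadata$languages),
    cases = purrr::map(seq_len(nrow(bank$cases)), function(i) {
      cs <- bank$cases[i, ]
      ex_rows <- bank$exchanges[bank$exchanges$case_id == cs$case_id, ]
      ex_rows <- ex_rows[order(ex_rows$exchange_index), ]
      list(
        case_id = cs$case_id,
        family = cs$family,
        variant = cs$variant,
        behavior_target = cs$behavior_target,
        language = cs$language,
        chart = cs$chart[[1]],
        exchanges = purrr::map(seq_len(nrow(ex_rows)), function(j) {
          ex <- ex_rows[j, ]
          op_rows <- bank$options[
            bank$options$case_id == cs$case_id &
              bank$options$exchange_index == ex$exchange_index, ]
          op_rows <- op_rows[order(op_rows$rank), ]
          list(
            exchange_index = ex$exchange_index,
            patient_statement = ex$patient_statement,
            options = purrr::map(seq_len(nrow(op_rows)), function(k) {
              op <- op_rows[k, ]
              list(
                option_id = op$option_id,
                text = op$text,
                rank = op$rank,
                mc_points = op$mc_points,
                tags = as.list(op$tags[[1]])
              )
            })
          )
        })
      )
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' Census of competency opportunities in a bank
#'
#' An opportunity is an occasion on which a competency could be demonstrated
#' by selecting a tagged response option. `option_level` counts tagged
#' options; `exchange_level` counts exchanges offering the competency on at
#' least one option. Because a valid bank never lets one competency tag two
#' options of the same exchange, the two modes coincide on valid banks.
#'
#' @param bank an `mccat_bank`.
#' @param mode `"option_level"` or `"exchange_level"`.
#' @return A tibble of class `mccat_census` with one row per
#'   (competency, case) pair: columns `competency`, `case_id`, `family`,
#'   `variant`, `n`. All 11 competencies appear for every case (zero counts
#'   included). Use [census_totals()] for marginal totals.
#' @examples
#' bank <- generate_fixture_bank(seed = 1)
#' census <- opportunity_census(bank)
#' census_totals(census)$grand # 126 for one variant set... over 16 cases
#' @export
opportunity_census <- function(bank,
                               mode = c("option_level", "exchange_level")) {
  mode <- match.arg(mode)
  stopifnot(inherits(bank, "mccat_bank"))
  tag_rows <- tidyr::unnest(
    dplyr::select(bank$options, "case_id", "exchange_index", "tags"),
    "tags")
  if (mode == "exchange_level") {
    tag_rows <- dplyr::distinct(
      tag_rows, .data$case_id, .data$exchange_index, .data$tags)
  }
  counts <- dplyr::count(tag_rows, .data$case_id, competency = .data$tags)
  grid <- tidyr::expand_grid(
    competency = mc_competencies()$competency,
    case_id = bank$cases$case_id
  )
  out <- dplyr::left_join(grid, counts,
                          by = c("competency", "case_id")) |>
    dplyr::mutate(n = as.integer(dplyr::coalesce(.data$n, 0L))) |>
    dplyr::left_join(
      dplyr::select(bank$cases, "case_id", "family", "variant"),
      by = "case_id") |>
    dplyr::select("competency", "case_id", "family", "variant", "n")
  class(out) <- c("mccat_census", class(out))
  attr(out, "mode") <- mode
  out
}

#' Marginal totals of an opportunity census
#'
#' @param census a census from [opportunity_census()].
#' @return A list with `per_competency` (tibble competency, n),
#'   `per_case` (tibble case_id, n) and `grand` (integer).
#' @export
census_totals <- function(census) {
  list(
    per_competency = dplyr::count(
      tibble::as_tibble(census), .data$competency, wt = .data$n, name = "n"),
    per_case = dplyr::count(
      tibble::as_tibble(census), .data$case_id, wt = .data$n, name = "n"),
    grand = sum(census$n)
  )
}

#' Export a census in the wide, publication-style layout
#'
#' Rows are competencies, columns are cases, plus a `Total` column; a final
#' `Total` row holds per-case totals.
#'
#' @param census a census from [opportunity_census()].
#' @param path optional path; if given the table is written as CSV.
#' @return The wide tibble (invisibly if `path` is given).
#' @export
census_wide <- function(census, path = NULL) {
  wide <- tidyr::pivot_wider(
    dplyr::select(tibble::as_tibble(census), "competency", "case_id", "n"),
    names_from = "case_id", values_from = "n")
  wide$Total <- rowSums(wide[-1])
  total_row <- wide[1, ]
  total_row$competency <- "Total"
  total_row[-1] <- as.list(colSums(wide[-1]))
  wide <- dplyr::bind_rows(wide, total_row)
  if (!is.null(path)) {
    readr::write_csv(wide, path)
    return(invisible(wide))
  }
  wide
}
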