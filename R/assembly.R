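#' Assemble a randomized four-case assessment form
#'
#' An administered assessment presents one randomly chosen variant from each
#' of the four case families, in randomized order, with each exchange's five
#' response options presented in randomized order. Assembly is fully
#' reproducible: one RNG stream is seeded from `seed` and sub-draws happen in
#' a fixed documented order (variant choice for families A through D, then
#' case presentation order, then one option permutation per exchange in
#' presentation order), so identical `(bank, seed)` always yields an
#' identical form. Variant selection is uniform within each family.
#'
#' The option permutation is display-only: scoring depends on the option
#' actually selected, never on the slot it was shown in.
#'
#' @param bank an `mccat_bank` containing at least one variant per family.
#' @param seed integer seed for the form's RNG stream.
#' @param form_id identifier for the form; defaults to `"form-<seed>"`.
#' @return An object of class `mccat_form`: a list with `form_id`, `seed`,
#'   `cases` (tibble `position`, `family`, `case_id`) and `permutations`
#'   (tibble `case_id`, `exchange_index`, `display_order`, a list-column of
#'   length-5 integer vectors; element s is the rank of the option shown in
#'   display slot s).
#' @export
assemble_form <- function(bank, seed, form_id = NULL) {
  stopifnot(inherits(bank, "mccat_bank"), is.numeric(seed), length(seed) == 1)
  fams <- c("A", "B", "C", "D")
  missing_fam <- setdiff(fams, bank$cases$family)
  if (length(missing_fam)) {
    stop("bank is missing family/ies: ",
         paste(missing_fam, collapse = ", "), call. = FALSE)
  }
  form_id <- form_id %||% paste0("form-", format(seed, scientific = FALSE))

  withr::with_seed(as.integer(seed), {
    selected <- vapply(fams, function(fam) {
      ids <- sort(bank$cases$case_id[bank$cases$family == fam])
      ids[sample.int(length(ids), 1)]
    }, character(1))
    order_idx <- sample.int(4)
    case_ids <- unname(selected[order_idx])
    families <- unname(fams[order_idx])

    ex_idx <- lapply(case_ids, function(id) {
      sort(bank$exchanges$exchange_index[bank$exchanges$case_id == id])
    })
    perm_case <- rep(case_ids, lengths(ex_idx))
    perm_ex <- unlist(ex_idx)
    display <- lapply(seq_along(perm_ex), function(i) sample.int(5))

    structure(
      list(
        form_id = form_id,
        seed = as.integer(seed),
        cases = tibble::new_tibble(list(
          position = seq_along(case_ids),
          family = families,
          case_id = case_ids
        ), nrow = length(case_ids)),
        permutations = tibble::new_tibble(list(
          case_id = perm_case,
          exchange_index = as.integer(perm_ex),
          display_order = display
        ), nrow = length(perm_ex))
      ),
      class = "mccat_form"
    )
  })
}

#' @export
print.mccat_form <- function(x, ...) {
  cat("<mccat_form> ", x$form_id, " (seed ", x$seed, ")\n", sep = "")
  cat("  cases (in order): ",
      paste(x$cases$case_id, collapse = ", "), "\n", sep = "")
  cat("  exchanges: ", nrow(x$permutations), "\n", sep = "")
  invisible(x)
}

#' Check a form against its bank
#'
#' @param form an `mccat_form`.
#' @param bank the `mccat_bank` it was assembled from.
#' @return A tibble of violations (zero rows if the form is valid) with
#'   columns `scope` and `message`.
#' @export
validate_form <- function(form, bank) {
  stopifnot(inherits(form, "mccat_form"), inherits(bank, "mccat_bank"))
  v <- list()
  add <- function(scope, message) {
    v[[length(v) + 1]] <<- tibble::tibble(scope = scope, message = message)
  }
  dangling <- setdiff(form$cases$case_id, bank$cases$case_id)
  for (id in dangling) add("case", paste0("case_id not in bank: ", id))

  known <- form$cases$case_id[form$cases$case_id %in% bank$cases$case_id]
  fam <- bank$cases$family[match(known, bank$cases$case_id)]
  if (anyDuplicated(fam)) {
    add("form", paste0("more than one case from family ",
                       paste(unique(fam[duplicated(fam)]), collapse = ", ")))
  }
  if (!setequal(fam, c("A", "B", "C", "D")) || length(known) != 4) {
    add("form", "form must contain exactly one case per family A-D")
  }
  bad_perm <- !vapply(form$permutations$display_order,
                      function(p) length(p) == 5 && setequal(p, 1:5),
                      logical(1))
  if (any(bad_perm)) {
    add("permutation", paste0(
      "display_order is not a permutation of 1..5 for ",
      sum(bad_perm), " exchange(s)"))
  }
  for (id in known) {
    in_bank <- sort(bank$exchanges$exchange_index[bank$exchanges$case_id == id])
    in_form <- sort(form$permutations$exchange_index[
      form$permutations$case_id == id])
    if (!identical(as.integer(in_bank), as.integer(in_form))) {
      add("case", paste0("exchanges of case ", id,
                         " not covered exactly once by permutations"))
    }
  }
  if (length(v)) dplyr::bind_rows(v) else
    tibble::tibble(scope = character(), message = character())
}

#' Write / read an assessment form as JSON
#'
#' @param form an `mccat_form`.
#' @param path file path.
#' @return `path` invisibly (`write_form`); an `mccat_form` (`read_form`).
#' @export
write_form <- function(form, path) {
  stopifnot(inherits(form, "mccat_form"))
  doc <- list(
    form_id = form$form_id,
    seed = form$seed,
    cases = purrr::pmap(form$cases, function(position, family, case_id) {
      list(position = position, family = family, case_id = case_id)
    }),
    permutations = purrr::pmap(
      form$permutations,
      function(case_id, exchange_index, display_order) {
        list(case_id = case_id, exchange_index = exchange_index,
             display_order = as.list(display_order))
      })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_form
#' @export
read_form <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  structure(
    list(
      form_id = as.character(doc$form_id),
      seed = as.integer(doc$seed),
      cases = dplyr::bind_rows(purrr::map(doc$cases, function(cs) {
        tibble::tibble(position = as.integer(cs$position),
                       family = as.character(cs$family),
                       case_id = as.character(cs$case_id))
      })),
      permutations = dplyr::bind_rows(purrr::map(doc$permutations, function(p) {
        tibble::tibble(case_id = as.character(p$case_id),
                       exchange_index = as.integer(p$exchange_index),
                       display_order = list(as.integer(unlist(p$display_order))))
      }))
    ),
    class = "mccat_form"
  )
}
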