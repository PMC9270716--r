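test_that("bank JSON round-trips field-by-field and byte-identically", {
  bank <- fixture_bank_cached()
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_bank(bank, f1)
  bank2 <- load_bank(f1)
  expect_identical(dplyr::select(bank$cases, -chart),
                   dplyr::select(bank2$cases, -chart))
  expect_equal(bank$cases$chart, bank2$cases$chart)
  expect_identical(bank$exchanges, bank2$exchanges)
  expect_equal(bank$options, bank2$options)
  expect_identical(bank$metadata, bank2$metadata)
  write_bank(bank2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("structural violations are reported with coordinates", {
  bank <- fixture_bank_cached()
  # duplicate rank 3 in one exchange
  broken <- bank
  idx <- which(broken$options$case_id == "A1" &
                 broken$options$exchange_index == 2)
  broken$options$rank[idx[broken$options$rank[idx] == 4]] <- 3L
  v <- validate_bank(broken)
  expect_true(any(grepl("ranks 1..5", v$message, fixed = TRUE) &
                    v$case_id == "A1" & v$exchange_index == 2))

  # positive tag on a rank-5 option
  broken <- bank
  i5 <- which(broken$options$case_id == "B1" &
                broken$options$exchange_index == 1 &
                broken$options$rank == 5)
  broken$options$tags[[i5]] <- c("expressing_empathy")
  v <- validate_bank(broken)
  expect_true(any(grepl("positive tag on rank-5", v$message) &
                    v$case_id == "B1"))

  # negative tag on a rank-1 option
  broken <- bank
  i1 <- which(broken$options$case_id == "B1" &
                broken$options$exchange_index == 1 &
                broken$options$rank == 2)
  broken$options$tags[[i1]] <- c("negatively_judging")
  v <- validate_bank(broken)
  expect_true(any(grepl("negative tag on rank-2", v$message)))

  # unknown competency and a competency tagging two options of one exchange
  broken <- bank
  i2 <- which(broken$options$case_id == "C1" &
                broken$options$exchange_index == 3 &
                broken$options$rank == 2)
  broken$options$tags[[i2]] <- c("made_up_competency")
  v <- validate_bank(broken)
  expect_true(any(grepl("unknown competency", v$message)))

  broken <- bank
  ex1 <- which(broken$options$case_id == "D1" &
                 broken$options$exchange_index == 1)
  tagged <- ex1[lengths(broken$options$tags[ex1]) > 0][1]
  other <- ex1[broken$options$rank[ex1] == 3]
  tg <- broken$options$tags[[tagged]][1]
  # copy one tag onto the rank-3 option (polarity-safe for either polarity)
  broken$options$tags[[other]] <- c(broken$options$tags[[other]], tg)
  v <- validate_bank(broken)
  expect_true(any(grepl("more than one option", v$message)))
})

test_that("variant structural divergence within a family is flagged", {
  bank <- fixture_bank_cached()
  broken <- bank
  i <- which(broken$options$case_id == "A2" &
               broken$options$exchange_index == 1 &
               broken$options$rank == 1)
  # providing_information_neutrally is never offered by family A, so adding
  # it changes A2's structure without violating any per-exchange rule
  broken$options$tags[[i]] <-
    c(broken$options$tags[[i]], "providing_information_neutrally")
  v <- validate_bank(broken)
  expect_true(any(v$scope == "family" & v$case_id == "A2"))
})

test_that("loading a tampered bank file names the offending element", {
  bank <- fixture_bank_cached()
  f <- withr::local_tempfile(fileext = ".json")
  write_bank(bank, f)
  doc <- jsonlite::read_json(f, simplifyVector = FALSE)
  # give case A1 exchange 1 two rank-3 options
  doc$cases[[1]]$exchanges[[1]]$options[[4]]$rank <- 3
  jsonlite::write_json(doc, f, auto_unbox = TRUE, null = "null")
  expect_error(load_bank(f), "exchange 1")
  expect_error(load_bank("/nonexistent/bank.json"), "does not exist")
  writeLines("{not json", f)
  expect_error(load_bank(f), "parse")
})

test_that("option-level and exchange-level censuses coincide on valid banks", {
  bank <- fixture_bank_cached()
  c_opt <- opportunity_census(bank, mode = "option_level")
  c_ex <- opportunity_census(bank, mode = "exchange_level")
  expect_equal(tibble::as_tibble(c_opt), tibble::as_tibble(c_ex),
               ignore_attr = TRUE)
})

test_that("census conservation: grand total equals both marginal sums", {
  bank <- fixture_bank_cached()
  tot <- census_totals(opportunity_census(bank))
  expect_identical(sum(tot$per_competency$n), tot$grand)
  expect_identical(sum(tot$per_case$n), tot$grand)
})

test_that("a single tagged option yields a count of one and zero elsewhere", {
  bank <- toy_bank(list(list("1" = "expressing_empathy"),
                        list(), list(), list(), list(), list()))
  tot <- census_totals(opportunity_census(bank))$per_competency
  expect_identical(tot$n[tot$competency == "expressing_empathy"], 1L)
  expect_identical(sum(tot$n), 1L)
})

test_that("census_wide adds consistent marginal totals", {
  bank <- fixture_bank_cached()
  wide <- census_wide(opportunity_census(bank))
  expect_identical(nrow(wide), 12L) # 11 competencies + total row
  body <- wide[wide$competency != "Total", ]
  expect_equal(body$Total, rowSums(body[, bank$cases$case_id]))
  expect_equal(wide$Total[wide$competency == "Total"], sum(body$Total))
})
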