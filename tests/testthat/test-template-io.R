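# Template reading, validation and stratification.

test_that("a template CSV round-trips through read_indicator_table", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_indicator_data(base_raw(), path)
  raw <- read_indicator_table(path)
  expect_equal(nrow(raw), 4)
  expect_true(all(healthineq:::TEMPLATE_COLUMNS %in% names(raw)))
  expect_identical(raw$estimate, c("40", "60", "50", "65"))
  expect_length(attr(raw, "unknown_columns"), 0)
})

test_that("the same content read from .xlsx equals the CSV read", {
  csv <- withr::local_tempfile(fileext = ".csv")
  xlsx <- withr::local_tempfile(fileext = ".xlsx")
  rows <- dplyr::bind_rows(base_raw(), ordered_raw())
  write_indicator_data(rows, csv)
  write_indicator_xlsx(rows, xlsx)
  strip <- function(x) {
    attr(x, "source_path") <- NULL
    x
  }
  from_csv <- strip(read_indicator_table(csv))
  from_xlsx <- strip(read_indicator_table(xlsx))
  expect_identical(as.data.frame(from_xlsx), as.data.frame(from_csv))
})

test_that("header-only files read as empty and are rejected as empty datasets", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste(healthineq:::TEMPLATE_HEADERS, collapse = ","), path)
  raw <- read_indicator_table(path)
  expect_equal(nrow(raw), 0)
  rep <- validate_indicator_data(raw)
  expect_false(rep$accepted)
  expect_true("empty_dataset" %in% rep$errors$code)
})

test_that("header matching is case-insensitive, trimmed, and alias-aware", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    " Setting ,YEAR,source,Indicator_abbr,indicator_name,dimension,subgroup,Estimate,favourable_indicator,indicator_scale,ordered_dimension,subgroup_order,reference_subgroup,95CI_LB,95ci_ub",
    "A,2015,DHS,anc,Antenatal care,Residence,Rural,40,1,100,0,0,0,38,42",
    "A,2015,DHS,anc,Antenatal care,Residence,Urban,60,1,100,0,0,0,58,62"
  ), path)
  raw <- read_indicator_table(path)
  expect_true(all(c("setting", "year", "ci_lb", "ci_ub") %in% names(raw)))
  expect_true(validate_indicator_data(raw)$accepted)
})

test_that("unreadable, unsupported and duplicate-header inputs are errors", {
  expect_error(read_indicator_table("no/such/file.csv"), "not found")
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines("a,b", path)
  expect_error(read_indicator_table(path), "unsupported format")
  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("setting,Setting,year", "A,B,2000"), dup)
  expect_error(read_indicator_table(dup), "duplicated header")
})

test_that("seeded template violations are caught with the right codes", {
  flip <- function(raw, i, col, value) {
    raw[[col]][i] <- as.character(value)
    raw
  }
  cases <- list(
    list(raw = flip(base_raw(), 1, "favourable_indicator", 2),
         code = "bad_favourable_flag"),
    list(raw = flip(ordered_raw(), 1, "subgroup_order", 2),  # orders 2,1,2
         code = "bad_subgroup_order"),
    list(raw = flip(base_raw(), 1, "reference_subgroup", 1),
         code = "multiple_reference_subgroups"),
    list(raw = flip(base_raw(), 2, "estimate", NA),
         code = "missing_mandatory"),
    list(raw = flip(flip(base_raw(), 1, "ordered_dimension", 1),
                    2, "ordered_dimension", 1) |>
           (\(r) {r$subgroup_order[1:2] <- c("1", "2"); r})(),
         code = "ordered_binary")
  )
  for (case in cases) {
    rep <- validate_indicator_data(case$raw)
    expect_false(rep$accepted)
    expect_true(case$code %in% rep$errors$code,
                info = paste("expected code", case$code, "got",
                             paste(rep$errors$code, collapse = ",")))
  }
})

test_that("bad data values never throw, only accumulate errors", {
  raw <- base_raw()
  raw$estimate[1] <- "forty"
  raw$year[2] <- NA
  raw$indicator_scale[3] <- "-5"
  rep <- NULL
  expect_no_error(rep <- validate_indicator_data(raw))
  expect_false(rep$accepted)
  expect_setequal(
    intersect(c("unparseable_number", "missing_mandatory",
                "bad_indicator_scale"), rep$errors$code),
    c("unparseable_number", "missing_mandatory", "bad_indicator_scale"))
})

test_that("missing recommended variables warn but never block acceptance", {
  raw <- base_raw()
  raw$population <- NA_character_
  rep <- validate_indicator_data(raw)
  expect_true(rep$accepted)
  expect_true("no_population" %in% rep$warnings$code)
  # downstream only the unweighted measures remain
  res <- compute_stratum(stratify(rep$dataset)[[1]])
  expect_setequal(res$measure, c("D", "R"))

  raw2 <- base_raw()
  raw2$se[1] <- NA_character_
  rep2 <- validate_indicator_data(raw2)
  expect_true(rep2$accepted)
  expect_true("partial_se" %in% rep2$warnings$code)
})

test_that("subgroup_order gaps are accepted with a warning", {
  raw <- ordered_raw()
  raw$subgroup_order <- c("5", "1", "3")
  rep <- validate_indicator_data(raw)
  expect_true(rep$accepted)
  expect_true("subgroup_order_gaps" %in% rep$warnings$code)
})

test_that("re-validating an accepted dataset is idempotent", {
  rep <- validate_indicator_data(base_raw(), name = "orig")
  expect_true(rep$accepted)
  rep2 <- validate_indicator_data(dataset_rows(rep$dataset), name = "again")
  expect_true(rep2$accepted)
  expect_equal(nrow(rep2$errors), 0)
  expect_identical(dataset_rows(rep2$dataset), dataset_rows(rep$dataset))
})

test_that("writing an accepted dataset and re-reading is bit-identical", {
  spec <- scenario_spec(n_settings = 2, seed = 11)
  rep <- validate_indicator_data(generate_dataset(spec))
  path <- withr::local_tempfile(fileext = ".csv")
  write_indicator_data(rep$dataset, path)
  rep2 <- validate_indicator_data(read_indicator_table(path))
  expect_true(rep2$accepted)
  expect_identical(dataset_rows(rep2$dataset), dataset_rows(rep$dataset))
})

test_that("stratify counts, orders and types strata correctly", {
  rep <- validate_indicator_data(base_raw())
  strata <- stratify(rep$dataset)
  expect_length(strata, 2)  # 1 setting x 2 years x 1 indicator x 1 dimension
  expect_true(all(vapply(strata, `[[`, character(1), "dimension_type") ==
                    "binary"))

  # ordered stratum listed out of order comes back most disadvantaged first
  strata2 <- stratify(validate_indicator_data(ordered_raw())$dataset)
  expect_equal(strata2[[1]]$dimension_type, "ordered")
  expect_equal(strata2[[1]]$subgroups$subgroup,
               c("No education", "Primary", "Secondary +"))
})

test_that("row order never affects strata or subgroup order", {
  rows <- dplyr::bind_rows(base_raw(), ordered_raw())
  shuffled <- rows[c(5, 2, 7, 1, 4, 6, 3), ]
  s1 <- stratify(validate_indicator_data(rows)$dataset)
  s2 <- stratify(validate_indicator_data(shuffled)$dataset)
  expect_equal(length(s1), length(s2))
  for (i in seq_along(s1)) {
    expect_identical(s1[[i]]$subgroups, s2[[i]]$subgroups)
  }
})

test_that("year can repeat across sources: source is part of the stratum key", {
  raw <- base_raw()[1:2, ]
  other <- base_raw()[1:2, ]
  other$source <- "MICS"
  rep <- validate_indicator_data(dplyr::bind_rows(raw, other))
  expect_true(rep$accepted)
  expect_length(stratify(rep$dataset), 2)
})

test_that("validation reports serialise to JSON lines and text", {
  raw <- base_raw()
  raw$favourable_indicator[1] <- "2"
  rep <- validate_indicator_data(raw)
  jl <- withr::local_tempfile(fileext = ".jsonl")
  tx <- withr::local_tempfile(fileext = ".txt")
  write_validation_report(rep, json_path = jl, text_path = tx)
  recs <- lapply(readLines(jl), jsonlite::fromJSON)
  expect_equal(recs[[1]]$type, "summary")
  expect_false(recs[[1]]$accepted)
  expect_true(any(vapply(recs, function(r)
    identical(r$type, "error") && identical(r$code, "bad_favourable_flag"),
    logical(1))))
  expect_match(readLines(tx)[1], "rejected")
})
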