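make_ris <- function(entries) {
  path <- withr::local_tempfile(fileext = ".ris",
                                .local_envir = parent.frame())
  writeLines(unlist(entries), path)
  path
}

entry <- function(id, title, year, abstract = "Some abstract.",
                  kw = "keyword") {
  c("TY  - JOUR", paste0("AN  - ", id), paste0("TI  - ", title),
    paste0("AB  - ", abstract), paste0("KW  - ", kw),
    if (!is.null(year)) paste0("PY  - ", year), "ER  - ", "")
}

test_that("well-formed tagged entries are read; malformed ones skipped", {
  path <- make_ris(list(entry("A1", "First title", 1990),
                        entry("A2", "Second title", 2005)))
  recs <- read_ris(path)
  expect_equal(nrow(recs), 2)
  expect_equal(recs$record_id, c("A1", "A2"))
  expect_equal(recs$year, c(1990L, 2005L))

  path2 <- make_ris(list(entry("B1", "Has year", 1990),
                         entry("B2", "No year", NULL)))
  expect_warning(recs2 <- read_ris(path2), "skipped 1")
  expect_equal(recs2$record_id, "B1")
})

test_that("the committed 10-entry demo corpus yields 9 records", {
  expect_warning(recs <- read_ris(fixture_path("corpus_demo.ris")),
                 "skipped 1")
  expect_equal(nrow(recs), 9)
  expect_false("DEMO-07" %in% recs$record_id)
  # repeated KW tags accumulate as author keywords
  expect_equal(recs$keywords[[which(recs$record_id == "DEMO-01")]],
               c("herbivory", "coral reefs"))
})

test_that("phrase filtering is exact, case-insensitive and multi-field", {
  recs <- bib_records(
    list(record_id = "R1", abstract = "Fish density in coral reefs of Palau."),
    list(record_id = "R2", title = "Coral recruitment",
         abstract = "Larvae of corals settle on reef substrate."),
    list(record_id = "R3", keywords = c("ecology", "Kelp Forests")),
    list(record_id = "R4", title = "Change in coral-reef fish"),
    list(record_id = "R5", title = "Seagrass bed mapping",
         abstract = "Also discusses mangrove forests."))
  out <- filter_corpus(recs)
  expect_equal(out$coral_reef, c("R1", "R4")) # R2: no whole phrase anywhere
  expect_equal(out$kelp_forest, "R3")
  expect_equal(out$seagrass_bed, "R5")
  expect_equal(out$mangrove_forest, "R5") # one record, two ecosystems
})

test_that("phrases ignored in database-generated keyword fields", {
  expect_warning(recs <- read_ris(fixture_path("corpus_demo.ris")))
  out <- filter_corpus(recs)
  expect_false("DEMO-09" %in% unlist(out["mangrove_forest"]))
  expect_true("DEMO-09" %in% out$coral_reef) # via hyphenated title only
  expect_false("DEMO-10" %in% unlist(out)) # no phrase at all -> dropped
})

test_that("single-word query phrases are rejected", {
  recs <- bib_records(list(record_id = "R1", title = "t"))
  expect_error(filter_corpus(recs, list(coral_reef = c("coral reef",
                                                       "coral"))),
               "2 words")
})

test_that("assignments are stable under addition of unrelated records", {
  base <- bib_records(
    list(record_id = "R1", abstract = "Surveys of coral reefs."))
  more <- rbind(base, bib_records(
    list(record_id = "R9", abstract = "Unrelated soil chemistry.")))
  expect_equal(filter_corpus(base)$coral_reef,
               filter_corpus(more)$coral_reef)
  expect_true(all(unlist(filter_corpus(more)) %in% more$record_id))
})

test_that("period binning partitions records at the study boundaries", {
  recs <- bib_records(
    list(record_id = "R1", title = "a", year = 1990L),
    list(record_id = "R2", title = "b", year = 2000L),
    list(record_id = "R3", title = "c", year = 2006L),
    list(record_id = "R4", title = "d", year = 2007L))
  bins <- split_periods(recs)
  expect_equal(names(bins), c("pre-2000", "2000-2006", "2007-2009"))
  expect_equal(vapply(bins, nrow, 1L), c(`pre-2000` = 1L,
                                         `2000-2006` = 2L,
                                         `2007-2009` = 1L))

  one <- bib_records(list(record_id = "R1", title = "a", year = 1980L))
  expect_equal(vapply(split_periods(one), nrow, 1L)[["pre-2000"]], 1L)

  late <- bib_records(list(record_id = "R9", title = "z", year = 2012L))
  expect_error(split_periods(late), "R9")
  expect_error(split_periods(recs, boundaries = c(2006, 1999)),
               "strictly increasing")
})

test_that("binning is a partition for random year vectors", {
  set.seed(42)
  recs <- bib_records(list(record_id = "X", title = "t"))
  recs <- recs[rep(1, 500), ]
  recs$record_id <- paste0("X", seq_len(500))
  recs$year <- sample(1957:2009, 500, replace = TRUE)
  bins <- split_periods(recs)
  ids <- unlist(lapply(bins, `[[`, "record_id"))
  expect_equal(sum(vapply(bins, nrow, 1L)), 500L)
  expect_false(anyDuplicated(ids) > 0)
  expect_setequal(ids, recs$record_id)
})
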