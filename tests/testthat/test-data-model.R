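test_that("read_visitation parses well-formed files and flags bad rows", {
  df <- make_records(c("A", "A", "B"), c("P", "Q", "P"),
                     c("2020-07-01", "2020-07-01", "2020-07-08"),
                     count = c(2L, 1L, 3L))
  path <- write_visit_csv(df)
  out <- read_visitation(path)
  expect_equal(nrow(out), 3)
  expect_s3_class(out$date, "Date")
  expect_equal(sum(out$count), 6)

  # zero-count row dropped with a warning naming the line
  df0 <- df
  df0$count[2] <- 0L
  p0 <- write_visit_csv(df0)
  expect_warning(out0 <- read_visitation(p0), "line\\(s\\) 3")
  expect_equal(nrow(out0), 2)

  # invalid date is a hard error naming the row
  dfb <- df
  dfb$date <- as.character(dfb$date)
  dfb$date[1] <- "2020-13-01"
  pb <- write_visit_csv(dfb)
  expect_error(read_visitation(pb), "2020-13-01.*row 2")

  # date outside its stated year
  dfy <- df
  dfy$year[3] <- 2019L
  py <- write_visit_csv(dfy)
  expect_error(read_visitation(py), "does not fall in year")

  expect_error(read_visitation(tempfile()), "not found")
  dfm <- df[, setdiff(names(df), "bee_species")]
  expect_error(read_visitation(write_visit_csv(dfm)), "bee_species")
})

test_that("missing count column defaults to one individual per row", {
  df <- make_records(c("A", "B"), c("P", "P"), "2020-07-01")
  df$count <- NULL
  out <- read_visitation(write_visit_csv(df))
  expect_equal(out$count, c(1L, 1L))
})

test_that("core-season filter keeps only July and August", {
  df <- make_records("A", "P", c("2020-06-28", "2020-07-01", "2020-09-02"))
  out <- restrict_to_core_season(df)
  expect_equal(out$date, as.Date("2020-07-01"))

  all_july <- make_records("A", "P", c("2020-07-03", "2020-07-10"))
  expect_identical(restrict_to_core_season(all_july), all_july)
  expect_equal(nrow(restrict_to_core_season(df[0, ])), 0)
})

test_that("rare-species filter removes species below the total-count threshold", {
  df <- make_records(c("A", "A", "B"), c("P", "Q", "P"),
                     "2020-07-01", count = c(5000L, 48L, 13L))
  out <- filter_rare_species(df, min_total = 20)
  expect_setequal(unique(out$bee_species), "A")
  expect_identical(filter_rare_species(df, min_total = 1), df)
  expect_equal(nrow(filter_rare_species(
    make_records("A", "P", "2020-07-01", count = 19L), 20)), 0)
})

test_that("rare-species filter is idempotent and monotone in the threshold", {
  set.seed(101)
  for (rep in 1:20) {
    df <- make_records(
      bee = sample(LETTERS[1:6], 30, replace = TRUE),
      plant = sample(letters[1:4], 30, replace = TRUE),
      date = "2021-07-05",
      count = sample(1:10, 30, replace = TRUE)
    )
    for (thr in c(2, 10, 25)) {
      once <- filter_rare_species(df, thr)
      expect_identical(filter_rare_species(once, thr), once)
    }
    sp_low <- unique(filter_rare_species(df, 5)$bee_species)
    sp_high <- unique(filter_rare_species(df, 15)$bee_species)
    expect_true(all(sp_high %in% sp_low))
  }
})

test_that("flowering-period stages partition the season at the documented boundaries", {
  expect_equal(as.character(classify_flowering_period(as.Date("2020-07-10"))), "early")
  expect_equal(as.character(classify_flowering_period(as.Date("2020-07-20"))), "early")
  expect_equal(as.character(classify_flowering_period(as.Date("2021-07-21"))), "middle")
  expect_equal(as.character(classify_flowering_period(as.Date("2021-08-20"))), "middle")
  expect_equal(as.character(classify_flowering_period(as.Date("2019-08-21"))), "late")

  # every date of a full calendar year maps to exactly one stage
  days <- seq(as.Date("2020-01-01"), as.Date("2020-12-31"), by = "day")
  cls <- classify_flowering_period(days)
  expect_false(anyNA(cls))
  expect_equal(length(cls), length(days))
  jul_aug <- days[format(days, "%m") %in% c("07", "08")]
  expect_setequal(as.character(unique(classify_flowering_period(jul_aug))),
                  c("early", "middle", "late"))
})

test_that("visitation summary computes shares and link persistence", {
  # single species, one link seen in two years
  df <- make_records(c("A", "A"), c("P", "P"), c("2020-07-01", "2021-07-01"))
  s <- summarize_visitation(df)
  expect_equal(s$species_shares$share_pct, 100)
  expect_equal(s$link_persistence$n_years, 2)
  expect_equal(s$link_persistence$n_links, 1)
  expect_equal(s$total_links, 1)

  expect_error(summarize_visitation(df[0, ]), "empty")
})

test_that("summary shares sum to 100 and persistence buckets partition the links", {
  set.seed(7)
  for (rep in 1:10) {
    df <- make_records(
      bee = sample(paste0("bee", 1:8), 200, replace = TRUE),
      plant = sample(paste0("plant", 1:12), 200, replace = TRUE),
      date = sample(seq(as.Date("2018-07-01"), as.Date("2022-08-30"), by = "day"),
                    200, replace = TRUE),
      count = sample(1:50, 200, replace = TRUE)
    )
    s <- summarize_visitation(df)
    expect_lt(abs(sum(s$species_shares$share_pct) - 100), 0.05)
    expect_equal(sum(s$link_persistence$n_links), s$total_links)
    expect_equal(s$total_links,
                 nrow(dplyr::distinct(df, bee_species, plant_species)))
  }
})
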