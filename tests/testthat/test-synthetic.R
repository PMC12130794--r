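small_config <- function(seed, ...) {
  synthetic_config(years = 2020:2021, days_per_year = c(4, 4),
                   n_bees = 6, n_plants = 12, transects_per_day = 8,
                   visits_per_transect = 12, seed = seed, ...)
}

test_that("the generator is deterministic in its seed", {
  a <- generate_community(small_config(seed = 9))
  b <- generate_community(small_config(seed = 9))
  expect_identical(a$visits, b$visits)
  expect_identical(a$plots, b$plots)
  expect_identical(a$truth$x_bee, b$truth$x_bee)
  c <- generate_community(small_config(seed = 10))
  expect_false(identical(a$visits, c$visits))
})

test_that("every configured census day appears and records pass validation", {
  sim <- generate_community(small_config(seed = 12))
  expect_equal(length(unique(sim$visits$date)), 8)
  expect_true(all(format(sim$visits$date, "%m") %in% c("07", "08")))
  expect_no_warning(pacnet:::validate_visitation(sim$visits))
  expect_true(all(sim$visits$count >= 1))
  expect_true(all(sim$plots$floral_units >= 0))
  expect_equal(nrow(sim$traits), 6)
  expect_error(synthetic_config(n_bees = 0, seed = 1), "species")
  expect_error(synthetic_config(years = 2020), "seed")
})

test_that("realized visit shares converge to the latent bee abundances", {
  # uniform preferences (huge kernel width flattens trait matching) and ~1e5
  # expected visits: law of large numbers pins per-bee shares to x_bee
  cfg <- synthetic_config(years = 2020, days_per_year = 5, n_bees = 6,
                          n_plants = 10, transects_per_day = 40,
                          visits_per_transect = 500,
                          kernel_sd_mm = 1e9, seed = 77)
  sim <- generate_community(cfg)
  expect_gt(sum(sim$visits$count), 5e4)
  shares <- tapply(sim$visits$count, sim$visits$bee_species, sum)
  shares <- shares / sum(shares)
  truth <- sim$truth$x_bee[names(shares)]
  expect_lt(max(abs(shares - truth)), 0.02)
})

test_that("skewed abundance configurations give a dominant top species", {
  tops <- vapply(1:8, function(s) {
    sim <- generate_community(small_config(seed = 100 + s))
    max(tapply(sim$visits$count, sim$visits$bee_species, sum)) /
      sum(sim$visits$count)
  }, numeric(1))
  expect_gt(mean(tops), 0.4)
})

test_that("a long-proboscis specialist shows elevated intraspecific pressure", {
  # one deep-tongued bee among short-tongued generalists monopolizes the
  # deep flowers it visits, raising its diagonal PAC value
  hits <- 0
  for (s in 1:10) {
    cfg <- synthetic_config(
      years = 2020, days_per_year = 6, n_bees = 6, n_plants = 15,
      proboscis_mm = c(rep(7, 5), 14.5),
      corolla_mm = seq(2, 16, length.out = 15),
      kernel_floor = 0.05, kernel_sd_mm = 2,
      transects_per_day = 10, visits_per_transect = 30, seed = 300 + s)
    sim <- generate_community(cfg)
    idx <- competition_indices(build_daily_networks(sim$visits))
    per_sp <- tapply(idx$intra, idx$species, mean)
    if (!"bee_06" %in% names(per_sp)) next
    if (per_sp[["bee_06"]] > stats::median(per_sp)) hits <- hits + 1
  }
  expect_gte(hits, 7)
})

test_that("planted-effect scenarios are reproducible and bounded", {
  cfg <- scenario_config(seed = 21)
  a <- generate_competition_scenario(cfg)
  b <- generate_competition_scenario(cfg)
  expect_identical(a$table, b$table)
  expect_equal(nrow(a$table), sum(c(5, 9, 9, 8, 7)) * 7)
  # transformed columns are standardized over the table
  expect_equal(mean(a$table$abundance_lz), 0, tolerance = 1e-9)
  expect_equal(stats::sd(a$table$floral_density_lz), 1, tolerance = 1e-9)

  wild <- scenario_config(
    coef_inter = c(intercept = 0.1, abundance = 0.4, density = 0,
                   proboscis = 0, interaction = -0.3,
                   period_middle = 0, period_late = 0),
    seed = 22)
  expect_error(generate_competition_scenario(wild), "outside \\[0, 1\\]")
})

test_that("zero planted effects yield null estimates", {
  nullcf <- c(intercept = 0.4, abundance = 0, density = 0, proboscis = 0,
              interaction = 0, period_middle = 0, period_late = 0)
  terms <- c("abundance_lz", "floral_density_lz", "proboscis_z",
             "abundance_lz:floral_density_lz")
  ok <- total <- 0
  for (s in 1:10) {
    g <- generate_competition_scenario(scenario_config(
      coef_inter = nullcf, coef_intra = nullcf, seed = 400 + s))
    m <- fit_interspecific_model(g$table)
    slopes <- m$coefficients[m$coefficients$term %in% terms, ]
    ok <- ok + sum(abs(slopes$estimate) < 2 * slopes$std_error)
    total <- total + nrow(slopes)
  }
  # each term covers zero at the ~95% Wald level
  expect_gte(ok / total, 0.85)
})
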