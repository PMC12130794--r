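test_that("log_z standardizes the log scale to mean 0 and unit sd", {
  out <- log_z(c(exp(1), exp(2), exp(3)))
  expect_equal(out, c(-1, 0, 1))  # z of (1,2,3) with sample sd 1
  set.seed(51)
  x <- stats::rlnorm(40)
  z <- log_z(x)
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(stats::sd(z), 1, tolerance = 1e-9)
  expect_error(log_z(c(1, 0, 2)), "positive")
  expect_error(log_z(c(5, 5, 5)), "constant")
})

test_that("model table assembly joins by day and species and flags missing traits", {
  idx <- tibble::tibble(
    date = as.Date(c(rep("2020-07-01", 3), rep("2020-07-08", 2))),
    species = c("A", "B", "C", "A", "B"),
    inter_acting = seq(0.1, 0.5, by = 0.1),
    intra = seq(0.5, 0.9, by = 0.1)
  )
  ab <- idx[, c("date", "species")]
  ab$abundance_est <- c(0.5, 0.3, 0.2, 0.6, 0.4)
  dens <- tibble::tibble(date = as.Date(c("2020-07-01", "2020-07-08")),
                         floral_density = c(120, 80))
  traits <- tibble::tibble(bee_species = c("A", "B", "C"),
                           proboscis_mm = c(7, 9, 13))
  tab <- assemble_model_table(idx, ab, dens, traits)
  expect_equal(nrow(tab), 5)
  expect_equal(tab$inter_acting, idx$inter_acting)
  expect_equal(tab$abundance_est, ab$abundance_est)
  expect_equal(tab$floral_density, dens$floral_density[match(tab$date, dens$date)])
  expect_equal(tab$proboscis_mm, traits$proboscis_mm[match(tab$species, traits$bee_species)])
  expect_equal(as.character(unique(tab$flowering_period)), "early")
  expect_equal(mean(tab$abundance_lz), 0, tolerance = 1e-6)
  expect_equal(stats::sd(tab$floral_density_lz), 1, tolerance = 1e-6)

  expect_error(assemble_model_table(idx, ab, dens, traits[1:2, ]),
               "species: C")
})

test_that("VIF matches the auxiliary-regression oracle on correlated designs", {
  set.seed(52)
  n <- 120
  x1 <- stats::rnorm(n)
  x2 <- 0.7 * x1 + stats::rnorm(n, 0, 0.5)
  x3 <- stats::rnorm(n)
  tab <- tibble::tibble(
    intra = stats::rnorm(n),
    abundance_lz = x1, floral_density_lz = x2, proboscis_z = x3,
    year = 2020, year_f = factor(2020),
    flowering_period = factor("early")
  )
  v <- collinearity_vif(tab)
  for (nm in c("abundance_lz", "floral_density_lz", "proboscis_z")) {
    others <- setdiff(c("abundance_lz", "floral_density_lz", "proboscis_z"), nm)
    r2 <- summary(stats::lm(stats::reformulate(others, nm), data = tab))$r.squared
    expect_equal(unname(v[nm]), 1 / (1 - r2), tolerance = 1e-8)
  }
  # near-orthogonal predictors sit near 1
  expect_lt(v[["proboscis_z"]], 1.1)
  # duplicated predictor makes the design singular
  tab2 <- tab
  tab2$floral_density_lz <- tab2$abundance_lz
  expect_error(collinearity_vif(tab2), "singular")
})

test_that("mixed models recover structure and their Wald table is coherent", {
  tab <- tiny_competition_table(seed = 3)
  m <- fit_interspecific_model(tab)
  expect_s3_class(m, "competition_model")
  expect_true(m$converged)
  expect_equal(nrow(m$data), nrow(tab))
  # reference levels: first year and early period absorbed in the intercept
  expect_false(any(grepl("2018|early", m$coefficients$term)))
  # single-df Wald chi-square equals the squared coefficient z value for
  # terms not marginal to the interaction (type II adjusts main effects for
  # terms that do not contain them)
  w <- m$wald
  expect_false("(Intercept)" %in% w$term)
  for (trm in c("proboscis_z", "abundance_lz:floral_density_lz")) {
    z <- m$coefficients$z_value[m$coefficients$term == trm]
    expect_equal(w$chisq[w$term == trm], z^2, tolerance = 1e-6)
  }
  # VIFs of the screened main effects are >= 1
  expect_true(all(m$vif >= 1))
})

test_that("model estimates are invariant to row order and species relabeling", {
  tab <- tiny_competition_table(seed = 4)
  m0 <- fit_intraspecific_model(tab)
  m1 <- fit_intraspecific_model(tab[sample(nrow(tab)), ])
  expect_equal(m1$coefficients$estimate, m0$coefficients$estimate,
               tolerance = 1e-6)
  relab <- tab
  relab$species <- paste0("zz_", relab$species)
  m2 <- fit_intraspecific_model(relab)
  expect_equal(m2$coefficients$estimate, m0$coefficients$estimate,
               tolerance = 1e-6)
})

test_that("adding a fixed effect never worsens the ML deviance", {
  tab <- tiny_competition_table(seed = 5)
  df <- as.data.frame(tab)
  df$year_f <- factor(df$year)
  base <- glmmTMB::glmmTMB(intra ~ abundance_lz + (1 | species),
                           data = df, REML = FALSE)
  fuller <- glmmTMB::glmmTMB(intra ~ abundance_lz + proboscis_z + (1 | species),
                             data = df, REML = FALSE)
  expect_gte(as.numeric(stats::logLik(fuller)),
             as.numeric(stats::logLik(base)) - 1e-6)
})

test_that("year-subset refits run and return the same structure", {
  tab <- tiny_competition_table(seed = 6)
  m <- fit_interspecific_model(tab, years = 2019:2020)
  expect_setequal(unique(m$data$year), 2019:2020)
  expect_equal(names(m$coefficients),
               c("term", "estimate", "std_error", "z_value", "p_value"))
})

test_that("partial residuals isolate a term's contribution", {
  tab <- tiny_competition_table(seed = 7)
  m <- fit_interspecific_model(tab)
  pr <- partial_residuals(m, "proboscis_z")
  b <- m$coefficients$estimate[m$coefficients$term == "proboscis_z"]
  resid <- stats::residuals(m$fit)
  expect_equal(pr$points$partial_residual, b * m$data$proboscis_z + resid,
               tolerance = 1e-9)
  # regressing the partial residual on the predictor returns the coefficient
  slope <- stats::coef(stats::lm(pr$points$partial_residual ~ m$data$proboscis_z))[2]
  expect_lt(abs(unname(slope) - b), 0.05)

  pri <- partial_residuals(m, "abundance_lz:floral_density_lz")
  expect_equal(length(unique(pri$lines$density_level)), 3)
  expect_equal(length(unique(pri$lines$floral_density_lz)), 3)
  expect_error(partial_residuals(m, "no_such_term"), "not in model")
})
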