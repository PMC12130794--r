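#' Configuration for the synthetic visitation generator
#'
#' Defaults emulate a five-year weekly survey of an alpine meadow bumblebee
#' community: 38 census days over 2018-2022, 14 bee species with strongly
#' skewed log-normal abundances, 60 bee-visited plant species with individual
#' flowering phenologies and a community floral curve peaking mid-July and
#' declining late in the season, visitation generated under mass action with a
#' Gaussian proboscis-corolla trait-matching preference (with a floor, so
#' short-tongued generalists still visit open flowers broadly).
#'
#' @param years Survey years.
#' @param days_per_year Weekly census days per year (recycled); weekly dates
#'   start July 1.
#' @param n_bees,n_plants Species pool sizes.
#' @param bee_abund_meanlog,bee_abund_sdlog Log-normal parameters of the
#'   latent bee relative abundances (sdlog >= 1 gives the strongly skewed
#'   community structure typical of these assemblages).
#' @param plant_abund_sdlog Log-normal sd of latent plant base abundances.
#' @param proboscis_mm Optional vector of proboscis lengths (mm); default
#'   drawn uniformly on 6.5-14.5 mm.
#' @param corolla_mm Optional vector of plant corolla depths (mm); default
#'   uniform on 2-16 mm.
#' @param kernel_sd_mm Gaussian trait-matching kernel width (mm).
#' @param kernel_floor Preference floor so no link has zero prior weight.
#' @param season_peak_doy,season_width Mean and sd (days) of plant flowering
#'   peak days (day-of-year; 196 = mid-July).
#' @param late_decline_rate Extra per-day exponential decline of floral
#'   availability after day-of-year 222 (~Aug 10).
#' @param peak_units Expected total open floral units per 4 m² plot at peak.
#' @param transects_per_day,plots_per_transect Survey effort per census day.
#' @param visits_per_transect Expected bee captures per transect walk.
#' @param seed Mandatory RNG seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(years = 2018:2022,
                             days_per_year = c(5, 9, 9, 8, 7),
                             n_bees = 14, n_plants = 60,
                             bee_abund_meanlog = 0, bee_abund_sdlog = 1.5,
                             plant_abund_sdlog = 1,
                             proboscis_mm = NULL, corolla_mm = NULL,
                             kernel_sd_mm = 3, kernel_floor = 0.2,
                             season_peak_doy = 196, season_width = 18,
                             late_decline_rate = 0.03,
                             peak_units = 150,
                             transects_per_day = 37, plots_per_transect = 5,
                             visits_per_transect = 7.5,
                             seed) {
  if (missing(seed) || !is.finite(seed)) stop("a seed is mandatory", call. = FALSE)
  days_per_year <- rep_len(days_per_year, length(years))
  cfg <- list(
    years = as.integer(years), days_per_year = as.integer(days_per_year),
    n_bees = as.integer(n_bees), n_plants = as.integer(n_plants),
    bee_abund_meanlog = bee_abund_meanlog, bee_abund_sdlog = bee_abund_sdlog,
    plant_abund_sdlog = plant_abund_sdlog,
    proboscis_mm = proboscis_mm, corolla_mm = corolla_mm,
    kernel_sd_mm = kernel_sd_mm, kernel_floor = kernel_floor,
    season_peak_doy = season_peak_doy, season_width = season_width,
    late_decline_rate = late_decline_rate, peak_units = peak_units,
    transects_per_day = as.integer(transects_per_day),
    plots_per_transect = as.integer(plots_per_transect),
    visits_per_transect = visits_per_transect,
    seed = as.integer(seed)
  )
  if (cfg$n_bees < 1 || cfg$n_plants < 1) stop("need >= 1 species per side", call. = FALSE)
  if (any(cfg$days_per_year < 1) || cfg$transects_per_day < 1) {
    stop("counts must be positive", call. = FALSE)
  }
  structure(cfg, class = "synthetic_config")
}

census_dates <- function(years, days_per_year) {
  purrr::map2(years, days_per_year, function(y, k)
    as.Date(paste0(y, "-07-01")) + 7 * (seq_len(k) - 1))
}

#' Generate a synthetic multi-year visitation dataset
#'
#' Per census day, each plant's open floral units follow its individual
#' Gaussian phenology scaled by the community curve; expected visits per
#' (bee, plant, transect) are proportional to
#' `x_bee * availability_plant(day) * c(proboscis, corolla)` (mass action with
#' trait-matching preference), normalized so a transect walk yields
#' `visits_per_transect` expected captures; realized counts are Poisson.
#'
#' @param config A [synthetic_config()].
#' @return List: `visits` (visitation record tibble), `plots` (floral plot
#'   tibble), `traits` (bee trait tibble), and `truth` — the latent
#'   parameters: bee/plant abundances, preference matrix, phenology table,
#'   per-day expected plant availability, and the config.
#' @export
generate_community <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  bees <- sprintf("bee_%02d", seq_len(config$n_bees))
  plants <- sprintf("plant_%02d", seq_len(config$n_plants))

  x_bee <- stats::rlnorm(config$n_bees, config$bee_abund_meanlog,
                         config$bee_abund_sdlog)
  x_bee <- stats::setNames(x_bee / sum(x_bee), bees)
  base_plant <- stats::rlnorm(config$n_plants, 0, config$plant_abund_sdlog)
  base_plant <- stats::setNames(base_plant / sum(base_plant), plants)

  proboscis <- config$proboscis_mm %||% stats::runif(config$n_bees, 6.5, 14.5)
  corolla <- config$corolla_mm %||% stats::runif(config$n_plants, 2, 16)
  proboscis <- stats::setNames(rep_len(proboscis, config$n_bees), bees)
  corolla <- stats::setNames(rep_len(corolla, config$n_plants), plants)

  pref <- config$kernel_floor +
    exp(-outer(proboscis, corolla, "-")^2 / (2 * config$kernel_sd_mm^2))
  dimnames(pref) <- list(bees, plants)

  phen <- tibble::tibble(
    plant_species = plants,
    peak_doy = pmin(pmax(stats::rnorm(config$n_plants, config$season_peak_doy,
                                      config$season_width), 175), 245),
    width = stats::runif(config$n_plants, 10, 25)
  )

  dates <- census_dates(config$years, config$days_per_year)
  all_dates <- as.Date(unlist(dates), origin = "1970-01-01")
  doy <- as.integer(format(all_dates, "%j"))

  # expected floral units per plot: plant x day
  avail <- vapply(seq_along(all_dates), function(d) {
    a <- base_plant * exp(-(doy[d] - phen$peak_doy)^2 / (2 * phen$width^2)) *
      exp(-config$late_decline_rate * pmax(0, doy[d] - 222))
    a
  }, numeric(config$n_plants))
  dimnames(avail) <- list(plants, format(all_dates))
  units_per_plot <- avail / max(colSums(avail)) * config$peak_units

  visits_list <- vector("list", length(all_dates))
  plots_list <- vector("list", length(all_dates))
  for (d in seq_along(all_dates)) {
    lam_link <- outer(x_bee, units_per_plot[, d]) * pref
    lam_link <- lam_link / sum(lam_link) * config$visits_per_transect
    nt <- config$transects_per_day
    counts <- stats::rpois(nt * length(lam_link), rep(as.numeric(lam_link), nt))
    counts <- array(counts, dim = c(config$n_bees, config$n_plants, nt))
    nz <- which(counts > 0, arr.ind = TRUE)
    if (nrow(nz) > 0) {
      visits_list[[d]] <- tibble::tibble(
        year = as.integer(format(all_dates[d], "%Y")),
        date = all_dates[d],
        transect_id = sprintf("T%02d", nz[, 3]),
        bee_species = bees[nz[, 1]],
        plant_species = plants[nz[, 2]],
        count = counts[nz]
      )
    }
    np <- nt * config$plots_per_transect
    u <- stats::rpois(np * config$n_plants, rep(units_per_plot[, d], np))
    u <- matrix(u, nrow = config$n_plants)
    pnz <- which(u > 0, arr.ind = TRUE)
    if (nrow(pnz) > 0) {
      plot_of <- pnz[, 2]
      plots_list[[d]] <- tibble::tibble(
        date = all_dates[d],
        transect_id = sprintf("T%02d", (plot_of - 1L) %/% config$plots_per_transect + 1L),
        plot_id = sprintf("P%d", (plot_of - 1L) %% config$plots_per_transect + 1L),
        plant_species = plants[pnz[, 1]],
        floral_units = u[pnz]
      )
    }
  }

  visits <- dplyr::bind_rows(visits_list)
  validate_visitation(visits)
  list(
    visits = visits,
    plots = dplyr::bind_rows(plots_list),
    traits = tibble::tibble(bee_species = bees,
                            proboscis_mm = unname(proboscis)),
    truth = list(x_bee = x_bee, x_plant_base = base_plant,
                 proboscis_mm = proboscis, corolla_mm = corolla,
                 preferences = pref, phenology = phen,
                 units_per_plot = units_per_plot, config = config)
  )
}

#' Configuration for a planted-effect competition scenario
#'
#' Generates a model-ready competition table whose responses follow the
#' mixed-model structure with known coefficients on the transformed
#' (log-z / z) covariate scale, so parameter recovery by the model fitters can
#' be tested directly.
#'
#' @param years,days_per_year As in [synthetic_config()].
#' @param n_species Bee species pool (all present every day).
#' @param coef_inter,coef_intra Named coefficient vectors with elements
#'   `intercept`, `abundance`, `density`, `proboscis`, `interaction`,
#'   `period_middle`, `period_late` on the transformed scale.
#' @param sd_species,sd_resid Species random-intercept and residual SDs
#'   (shared by both responses). `sd_species` defaults to 0: the planted
#'   proboscis effect is a between-species contrast, identified from only a
#'   handful of species, and any unexplained species-level noise degrades the
#'   nominal coverage of its Wald interval in a way no estimator can repair;
#'   with the default, the planted fixed effects are the complete
#'   species-level structure. Set it above 0 to stress the fitter instead.
#' @param density_noise_sd Log-scale day-to-day noise on floral density.
#' @param abundance_noise_sd Log-scale day-to-day noise on species abundance.
#' @param seed Mandatory RNG seed.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(years = 2018:2022,
                            days_per_year = c(5, 9, 9, 8, 7),
                            n_species = 7,
                            coef_inter = c(intercept = 0.35, abundance = 0.07,
                                           density = 0, proboscis = 0,
                                           interaction = -0.02,
                                           period_middle = 0, period_late = 0.05),
                            coef_intra = c(intercept = 0.50, abundance = 0.10,
                                           density = 0, proboscis = 0.08,
                                           interaction = -0.02,
                                           period_middle = 0, period_late = 0),
                            sd_species = 0, sd_resid = 0.1,
                            density_noise_sd = 0.25,
                            abundance_noise_sd = 0.5,
                            seed) {
  if (missing(seed) || !is.finite(seed)) stop("a seed is mandatory", call. = FALSE)
  needed <- c("intercept", "abundance", "density", "proboscis", "interaction",
              "period_middle", "period_late")
  for (cf in list(coef_inter, coef_intra)) {
    if (!all(needed %in% names(cf))) {
      stop("coefficient vector must name: ", paste(needed, collapse = ", "),
           call. = FALSE)
    }
  }
  structure(
    list(years = as.integer(years),
         days_per_year = rep_len(as.integer(days_per_year), length(years)),
         n_species = as.integer(n_species),
         coef_inter = coef_inter, coef_intra = coef_intra,
         sd_species = sd_species, sd_resid = sd_resid,
         density_noise_sd = density_noise_sd,
         abundance_noise_sd = abundance_noise_sd,
         seed = as.integer(seed)),
    class = "scenario_config"
  )
}

#' Generate a competition table with planted model coefficients
#'
#' Covariates (seasonally declining floral density, log-normal within-day
#' relative abundances, fixed proboscis lengths) are drawn first; responses
#' are then built from the linear predictor with the configured coefficients
#' on the log-z / z transformed covariates, species random intercepts, and
#' Gaussian noise. Errors if any expected response falls outside the `[0, 1]`
#' range of the competition index.
#'
#' @param config A [scenario_config()].
#' @return List: `table` (competition table, one row per day x species) and
#'   `truth` (the coefficient vectors and variance components).
#' @export
generate_competition_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  species <- sprintf("bee_%02d", seq_len(config$n_species))
  proboscis <- stats::setNames(stats::runif(config$n_species, 6.5, 14.5), species)
  sp_mean <- stats::setNames(stats::rlnorm(config$n_species, 0, 1), species)

  dates <- census_dates(config$years, config$days_per_year)
  all_dates <- as.Date(unlist(dates), origin = "1970-01-01")
  doy <- as.integer(format(all_dates, "%j"))
  dens <- 150 * exp(-(doy - 196)^2 / (2 * 22^2)) *
    exp(stats::rnorm(length(doy), 0, config$density_noise_sd))

  tab <- tidyr::expand_grid(
    date = all_dates,
    species = species
  )
  tab$year <- as.integer(format(tab$date, "%Y"))
  tab$flowering_period <- classify_flowering_period(tab$date)
  tab$floral_density <- dens[match(tab$date, all_dates)]
  raw_ab <- sp_mean[tab$species] *
    exp(stats::rnorm(nrow(tab), 0, config$abundance_noise_sd))
  tab$abundance_est <- as.numeric(raw_ab)
  tab <- tab |>
    dplyr::group_by(.data$date) |>
    dplyr::mutate(abundance_est = .data$abundance_est / sum(.data$abundance_est)) |>
    dplyr::ungroup()
  tab$proboscis_mm <- unname(proboscis[tab$species])

  tab$abundance_lz <- log_z(tab$abundance_est)
  tab$floral_density_lz <- log_z(tab$floral_density)
  tab$proboscis_z <- z_score(tab$proboscis_mm)

  u <- stats::setNames(stats::rnorm(config$n_species, 0, config$sd_species), species)
  linpred <- function(cf) {
    cf[["intercept"]] +
      cf[["abundance"]] * tab$abundance_lz +
      cf[["density"]] * tab$floral_density_lz +
      cf[["proboscis"]] * tab$proboscis_z +
      cf[["interaction"]] * tab$abundance_lz * tab$floral_density_lz +
      cf[["period_middle"]] * (tab$flowering_period == "middle") +
      cf[["period_late"]] * (tab$flowering_period == "late") +
      u[tab$species]
  }
  # requested effects must keep the expected index inside [0, 1] over the
  # typical (+/- 2 sd) covariate range; far-tail rows are tolerated, as the
  # Gaussian model itself is an approximation at the index boundaries
  check_bounds <- function(cf) {
    half <- 2 * (abs(cf[["abundance"]]) + abs(cf[["density"]]) +
                   abs(cf[["proboscis"]])) + 4 * abs(cf[["interaction"]])
    per <- c(0, cf[["period_middle"]], cf[["period_late"]])
    lo <- cf[["intercept"]] + min(per) - half
    hi <- cf[["intercept"]] + max(per) + half
    if (lo < 0 || hi > 1) {
      stop("planted effects push expected index outside [0, 1]; ",
           "reduce coefficient magnitudes", call. = FALSE)
    }
  }
  check_bounds(config$coef_inter)
  check_bounds(config$coef_intra)
  mu_inter <- linpred(config$coef_inter)
  mu_intra <- linpred(config$coef_intra)
  tab$inter_acting <- mu_inter + stats::rnorm(nrow(tab), 0, config$sd_resid)
  tab$intra <- mu_intra + stats::rnorm(nrow(tab), 0, config$sd_resid)

  tab <- dplyr::select(tab, "year", "date", "flowering_period", "species",
                       "inter_acting", "intra", "abundance_est",
                       "floral_density", "proboscis_mm",
                       "abundance_lz", "floral_density_lz", "proboscis_z")
  list(table = tab,
       truth = list(coef_inter = config$coef_inter,
                    coef_intra = config$coef_intra,
                    sd_species = config$sd_species,
                    sd_resid = config$sd_resid,
                    random_intercepts = u,
                    proboscis_mm = proboscis))
}

#' Write synthetic inputs in the standard CSV schemas
#'
#' @param sim Output of [generate_community()].
#' @param dir Output directory.
#' @return Invisibly, the written paths (visits, plots, traits CSVs and a
#'   truth-bundle JSON).
#' @export
write_synthetic_inputs <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(visits = file.path(dir, "visits.csv"),
             plots = file.path(dir, "floral_plots.csv"),
             traits = file.path(dir, "traits.csv"),
             truth = file.path(dir, "truth.json"))
  readr::write_csv(sim$visits, paths[["visits"]])
  readr::write_csv(sim$plots, paths[["plots"]])
  readr::write_csv(sim$traits, paths[["traits"]])
  truth <- sim$truth
  truth$preferences <- NULL
  truth$units_per_plot <- NULL
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
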