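#' Configuration for the end-to-end analysis pipeline
#'
#' Either point `visits`/`plots`/`traits` at CSV inputs or supply a
#' [synthetic_config()] as `synthetic`; exactly one source is required.
#'
#' @param visits,plots,traits Paths to input CSVs (see [read_visitation()],
#'   [read_floral_plots()], [read_traits()]).
#' @param synthetic Optional [synthetic_config()] used instead of file inputs.
#' @param outdir Output directory for all result files.
#' @param min_total Rare-species threshold (see [filter_rare_species()]).
#' @param season_months Months retained (see [restrict_to_core_season()]).
#' @param early_end,middle_end Flowering-period boundaries (month-day).
#' @param chao2_variant `"bias_corrected"` or `"classic"`.
#' @param ml Fit models by ML (default) or REML.
#' @param model_years Optional year subset for a sensitivity refit of both
#'   models (reported alongside the full-data fits).
#' @param seed Seed recorded in the manifest (mandatory when `synthetic` is
#'   used; overrides the synthetic config's own seed).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(visits = NULL, plots = NULL, traits = NULL,
                            synthetic = NULL, outdir,
                            min_total = 20L, season_months = c(7L, 8L),
                            early_end = "07-20", middle_end = "08-20",
                            chao2_variant = "bias_corrected",
                            ml = TRUE, model_years = NULL, seed = NULL) {
  has_files <- !is.null(visits) && !is.null(plots) && !is.null(traits)
  if (is.null(synthetic) == !has_files) {
    stop("supply either all three input paths or a synthetic config",
         call. = FALSE)
  }
  if (!is.null(synthetic)) {
    stopifnot(inherits(synthetic, "synthetic_config"))
    if (!is.null(seed)) synthetic$seed <- as.integer(seed)
    seed <- synthetic$seed
  }
  structure(
    list(visits = visits, plots = plots, traits = traits,
         synthetic = synthetic, outdir = outdir,
         min_total = as.integer(min_total),
         season_months = as.integer(season_months),
         early_end = early_end, middle_end = middle_end,
         chao2_variant = chao2_variant, ml = ml,
         model_years = model_years, seed = seed),
    class = "pipeline_config"
  )
}

#' Run the full competition analysis pipeline
#'
#' Stages: load (or simulate) inputs → core-season and rare-species filters →
#' daily networks → PAC competition indices → mass-action abundances → floral
#' densities → per-year Chao2 completeness (+ effort correlation) → model
#' table → interspecific and intraspecific mixed models. Every stage writes
#' its table under `outdir`, and a run manifest records the config, seed and
#' input hashes so any output can be regenerated from the manifest alone.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a `pipeline_result` list with all intermediate objects
#'   (`records`, `networks`, `indices`, `abundances`, `densities`,
#'   `completeness`, `table`, `model_inter`, `model_intra`, `summary`,
#'   `files`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message("[pacnet] ", ...)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(config$outdir, name)
    readr::write_csv(df, path)
    files[[name]] <<- path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # -- inputs
  if (!is.null(config$synthetic)) {
    say("simulating synthetic community (seed ", config$seed, ")")
    sim <- stage("simulate", generate_community(config$synthetic))
    input_dir <- file.path(config$outdir, "inputs")
    paths <- write_synthetic_inputs(sim, input_dir)
    visits <- sim$visits; plots <- sim$plots; traits <- sim$traits
    input_paths <- as.list(paths)
  } else {
    say("reading inputs")
    visits <- stage("read", read_visitation(config$visits))
    plots <- stage("read", read_floral_plots(config$plots))
    traits <- stage("read", read_traits(config$traits))
    input_paths <- list(visits = config$visits, plots = config$plots,
                        traits = config$traits)
  }
  say(nrow(visits), " visitation rows, ", nrow(plots), " floral plot rows")

  # -- filters
  records <- stage("filter", {
    r <- restrict_to_core_season(visits, config$season_months)
    filter_rare_species(r, config$min_total)
  })
  say(nrow(records), " rows after season + rare-species filters (",
      length(unique(records$bee_species)), " bee species)")
  if (nrow(records) == 0) stop("pipeline stage 'filter' left no records", call. = FALSE)

  summary <- summarize_visitation(records)
  write_visitation_summary(summary, config$outdir)

  # -- networks and indices
  networks <- stage("networks", build_daily_networks(records))
  say(length(networks), " daily networks")
  emit(networks_to_edgelist(networks), "networks_edgelist.csv")

  indices <- stage("pac", competition_indices(networks))
  emit(indices, "competition_indices.csv")

  abundances <- stage("abundance", abundance_table(networks))
  emit(abundances, "abundance_estimates.csv")

  vp <- visited_plant_species(records)
  densities <- stage("floral_density", floral_density_series(
    plots, dates = as.Date(names(networks)), visited_plants = vp))
  emit(densities, "floral_density.csv")

  # -- completeness
  completeness <- stage("completeness",
                        completeness_by_year(networks, config$chao2_variant))
  efforts <- records |>
    dplyr::group_by(year = .data$year) |>
    dplyr::summarise(transects = dplyr::n_distinct(.data$date, .data$transect_id),
                     .groups = "drop")
  effort_cor <- if (nrow(completeness) >= 3) {
    tryCatch(effort_completeness_correlation(completeness, efforts),
             error = function(e) NULL)
  } else NULL
  emit(completeness, "completeness.csv")

  # -- models
  table <- stage("model_table", assemble_model_table(
    indices, abundances, densities, traits))
  emit(table, "competition_table.csv")
  say(nrow(table), " model-table rows")

  model_inter <- stage("model_inter", fit_interspecific_model(
    table, ml = config$ml, years = config$model_years))
  model_intra <- stage("model_intra", fit_intraspecific_model(
    table, ml = config$ml, years = config$model_years))
  emit(model_inter$coefficients, "model_interspecific_coefficients.csv")
  emit(model_inter$wald, "model_interspecific_wald.csv")
  emit(model_intra$coefficients, "model_intraspecific_coefficients.csv")
  emit(model_intra$wald, "model_intraspecific_wald.csv")
  for (m in list(model_inter, model_intra)) {
    say("model (", m$response, "): ", nrow(m$data), " rows, converged: ",
        m$converged)
  }

  # -- manifest
  manifest <- list(
    package = "pacnet",
    package_version = as.character(utils::packageVersion("pacnet")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    config = serialize_config(config),
    input_md5 = as.list(tools::md5sum(unlist(input_paths[
      vapply(input_paths, function(p) is.character(p) && file.exists(p),
             logical(1))]))),
    outputs = as.list(unlist(files)),
    effort_correlation = effort_cor
  )
  manifest_path <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")

  invisible(structure(
    list(records = records, networks = networks, indices = indices,
         abundances = abundances, densities = densities,
         completeness = completeness, effort_correlation = effort_cor,
         table = table, model_inter = model_inter, model_intra = model_intra,
         summary = summary, files = files, manifest = manifest),
    class = "pipeline_result"
  ))
}

serialize_config <- function(config) {
  cfg <- unclass(config)
  if (!is.null(cfg$synthetic)) cfg$synthetic <- unclass(cfg$synthetic)
  cfg
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pacnet pipeline result:", length(x$networks), "daily networks,",
      nrow(x$table), "model rows\n")
  cat("Outputs in:", dirname(x$files[[1]]), "\n")
  invisible(x)
}
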