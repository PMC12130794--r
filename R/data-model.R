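#' Read a visitation record file
#'
#' Reads a CSV/TSV of flower-visitation records, one row per observed bee (or
#' per bee-plant count) on one transect on one date. Expected columns:
#' `year`, `date`, `transect_id`, `bee_species`, `plant_species` and an
#' optional `count` (defaults to 1 individual per row when absent or missing).
#' Dates must be ISO-8601 (`YYYY-MM-DD`).
#'
#' Rows with `count == 0` carry no observed interaction and are dropped with a
#' warning naming their line numbers; an unparseable date or a date outside its
#' stated year is a hard error naming the offending row.
#'
#' @param path Path to a `.csv` or `.tsv`/`.txt` file with a header row.
#' @return A tibble of visitation records with columns
#'   `year`, `date` (Date), `transect_id`, `bee_species`, `plant_species`,
#'   `count` (positive integer).
#' @export
read_visitation <- function(path) {
  df <- read_delim_auto(path)
  required <- c("year", "date", "transect_id", "bee_species", "plant_species")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("visitation file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"count" %in% names(df)) df$count <- 1L
  df$count <- as.integer(df$count)
  df$count[is.na(df$count)] <- 1L

  date_parsed <- as.Date(as.character(df$date), format = "%Y-%m-%d")
  bad <- which(is.na(date_parsed))
  if (length(bad) > 0) {
    stop("unparseable date '", df$date[bad[1]], "' in row ", bad[1] + 1L,
         " of ", path, call. = FALSE)
  }
  df$date <- date_parsed
  df$year <- as.integer(df$year)
  mismatch <- which(as.integer(format(df$date, "%Y")) != df$year)
  if (length(mismatch) > 0) {
    stop("date ", df$date[mismatch[1]], " does not fall in year ",
         df$year[mismatch[1]], " (row ", mismatch[1] + 1L, " of ", path, ")",
         call. = FALSE)
  }

  zero <- which(df$count == 0)
  if (length(zero) > 0) {
    warning("dropping ", length(zero), " zero-count row(s) at line(s) ",
            paste(zero + 1L, collapse = ", "), call. = FALSE)
    df <- df[-zero, , drop = FALSE]
  }
  df$count <- as.integer(df$count)
  validate_visitation(df)
  tibble::as_tibble(df[c(required, "count")])
}

#' Read floral plot counts
#'
#' Reads per-plot counts of open floral units: columns `date`, `transect_id`,
#' `plot_id`, `plant_species`, `floral_units` — one row per species per
#' 2 x 2 m plot per survey date.
#'
#' @param path Path to a CSV/TSV file.
#' @return A tibble with a parsed `date` column and non-negative
#'   `floral_units`.
#' @export
read_floral_plots <- function(path) {
  df <- read_delim_auto(path)
  required <- c("date", "transect_id", "plot_id", "plant_species", "floral_units")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("floral plot file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  date_parsed <- as.Date(as.character(df$date), format = "%Y-%m-%d")
  bad <- which(is.na(date_parsed))
  if (length(bad) > 0) {
    stop("unparseable date '", df$date[bad[1]], "' in row ", bad[1] + 1L,
         " of ", path, call. = FALSE)
  }
  df$date <- date_parsed
  df$floral_units <- as.numeric(df$floral_units)
  if (anyNA(df$floral_units) || any(df$floral_units < 0)) {
    stop("floral_units must be non-negative numbers", call. = FALSE)
  }
  tibble::as_tibble(df[required])
}

#' Read a bee trait table
#'
#' @param path CSV/TSV with columns `bee_species`, `proboscis_mm`
#'   (prementum + glossa length, millimetres; one row per species).
#' @return A tibble with positive `proboscis_mm` per species.
#' @export
read_traits <- function(path) {
  df <- read_delim_auto(path)
  required <- c("bee_species", "proboscis_mm")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("trait file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$proboscis_mm <- as.numeric(df$proboscis_mm)
  if (any(!is.finite(df$proboscis_mm)) || any(df$proboscis_mm <= 0)) {
    stop("proboscis_mm must be positive and finite", call. = FALSE)
  }
  if (anyDuplicated(df$bee_species)) {
    stop("duplicated bee_species in trait table", call. = FALSE)
  }
  tibble::as_tibble(df[required])
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  delim <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  # read everything as character: dates and counts are validated explicitly,
  # with errors that name the offending row
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE, trim_ws = TRUE,
                    col_types = readr::cols(.default = readr::col_character()))
}

validate_visitation <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) return(invisible(records))
  if (any(records$count < 1)) stop("stored records must have count >= 1", call. = FALSE)
  if (any(!nzchar(records$bee_species)) || any(!nzchar(records$plant_species))) {
    stop("species names must be non-empty", call. = FALSE)
  }
  invisible(records)
}

#' Restrict records to the core flowering season
#'
#' Interaction sampling at the fringes of the flowering season is too sparse
#' to support daily networks, so the analysis is restricted to July and August
#' by default.
#'
#' @param records Visitation record tibble.
#' @param months Integer months to retain (default `c(7, 8)`).
#' @return The records whose date falls in `months`.
#' @export
restrict_to_core_season <- function(records, months = c(7L, 8L)) {
  if (nrow(records) == 0) return(records)
  keep <- as.integer(format(records$date, "%m")) %in% months
  records[keep, , drop = FALSE]
}

#' Drop rarely recorded bee species
#'
#' Species whose total individual count across the whole record set falls
#' below `min_total` are removed entirely: a handful of records cannot support
#' competition indices or abundance estimates.
#'
#' @param records Visitation record tibble.
#' @param min_total Minimum total individuals for a species to be retained
#'   (default 20, between the most abundant excluded and least abundant
#'   retained species of a typical alpine bumblebee survey).
#' @return Records for retained species only.
#' @export
filter_rare_species <- function(records, min_total = 20L) {
  stopifnot(min_total >= 1)
  if (nrow(records) == 0) return(records)
  totals <- tapply(records$count, records$bee_species, sum)
  keep_sp <- names(totals)[totals >= min_total]
  records[records$bee_species %in% keep_sp, , drop = FALSE]
}

#' Classify a date into a flowering-period stage
#'
#' The flowering season is split into early / middle / late stages at fixed
#' month-day boundaries. `early_end` belongs to the early stage and
#' `middle_end` to the middle stage, so every date maps to exactly one stage.
#'
#' @param date A `Date` vector.
#' @param early_end Last month-day of the early stage (default `"07-20"`).
#' @param middle_end Last month-day of the middle stage (default `"08-20"`).
#' @return A factor with levels `early`, `middle`, `late`.
#' @export
classify_flowering_period <- function(date, early_end = "07-20",
                                      middle_end = "08-20") {
  md <- format(as.Date(date), "%m-%d")
  out <- ifelse(md <= early_end, "early",
                ifelse(md <= middle_end, "middle", "late"))
  factor(out, levels = c("early", "middle", "late"))
}

#' Descriptive summary of a visitation record set
#'
#' Computes per-species totals with percentage shares of all recorded
#' individuals, and the link-persistence distribution: how many distinct
#' bee-plant pairs (links) were observed in exactly 1, 2, ... of the surveyed
#' years.
#'
#' @param records Visitation record tibble.
#' @return An object of class `visitation_summary`: a list with
#'   `species_shares` (tibble: `bee_species`, `total`, `share_pct`, shares
#'   rounded to 2 decimals, descending), `link_persistence` (tibble:
#'   `n_years`, `n_links`, `share_pct`), `total_links`, `grand_total`.
#' @export
summarize_visitation <- function(records) {
  if (nrow(records) == 0) stop("cannot summarize an empty record set", call. = FALSE)
  shares <- records |>
    dplyr::group_by(.data$bee_species) |>
    dplyr::summarise(total = sum(.data$count), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$total))
  grand <- sum(shares$total)
  shares$share_pct <- round(100 * shares$total / grand, 2)

  links <- records |>
    dplyr::distinct(.data$bee_species, .data$plant_species, .data$year) |>
    dplyr::count(.data$bee_species, .data$plant_species, name = "n_years")
  persistence <- links |>
    dplyr::count(.data$n_years, name = "n_links") |>
    dplyr::arrange(.data$n_years)
  persistence$share_pct <- round(100 * persistence$n_links / nrow(links), 2)

  structure(
    list(species_shares = shares,
         link_persistence = persistence,
         total_links = nrow(links),
         grand_total = grand),
    class = "visitation_summary"
  )
}

#' @export
print.visitation_summary <- function(x, ...) {
  cat("Visitation summary:", x$grand_total, "individuals,",
      nrow(x$species_shares), "bee species,", x$total_links,
      "distinct bee-plant links\n")
  cat("Top species:\n")
  print(utils::head(x$species_shares, 5))
  cat("Link persistence (distinct years observed):\n")
  print(x$link_persistence)
  invisible(x)
}

#' Write a visitation summary to disk
#'
#' @param summary A `visitation_summary`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (species shares CSV, link persistence
#'   CSV, and a JSON with the totals).
#' @export
write_visitation_summary <- function(summary, dir) {
  stopifnot(inherits(summary, "visitation_summary"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    shares = file.path(dir, "species_shares.csv"),
    persistence = file.path(dir, "link_persistence.csv"),
    totals = file.path(dir, "summary.json")
  )
  readr::write_csv(summary$species_shares, paths[["shares"]])
  readr::write_csv(summary$link_persistence, paths[["persistence"]])
  jsonlite::write_json(
    list(grand_total = summary$grand_total, total_links = summary$total_links),
    paths[["totals"]], auto_unbox = TRUE)
  invisible(paths)
}
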