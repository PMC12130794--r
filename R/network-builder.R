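#' Pool visitation records into daily quantitative networks
#'
#' Builds one quantitative bipartite visitation matrix per distinct sampling
#' date, summing counts over transects. Rows are bee species, columns plant
#' species; a species with no interaction on a day simply has no row (or
#' column) in that day's network — no zero-filled species are retained.
#'
#' @param records Visitation record tibble (see [read_visitation()]).
#' @return A named list (names = ISO dates) of `daily_network` objects, each a
#'   list with `date`, `year`, and `counts` — an integer matrix with bee
#'   species as dimnames rows and plant species as columns.
#' @export
build_daily_networks <- function(records) {
  if (nrow(records) == 0) stop("no records to build networks from", call. = FALSE)
  split_by_date <- split(records, records$date)
  nets <- lapply(split_by_date, function(day) {
    agg <- day |>
      dplyr::group_by(.data$bee_species, .data$plant_species) |>
      dplyr::summarise(count = sum(.data$count), .groups = "drop")
    bees <- sort(unique(agg$bee_species))
    plants <- sort(unique(agg$plant_species))
    m <- matrix(0L, length(bees), length(plants),
                dimnames = list(bees, plants))
    m[cbind(agg$bee_species, agg$plant_species)] <- as.integer(agg$count)
    structure(
      list(date = day$date[1], year = as.integer(format(day$date[1], "%Y")),
           counts = m),
      class = "daily_network"
    )
  })
  nets[order(as.Date(names(nets)))]
}

#' @export
print.daily_network <- function(x, ...) {
  cat("Daily visitation network", format(x$date), "-", nrow(x$counts),
      "bee species x", ncol(x$counts), "plant species,",
      sum(x$counts), "visits\n")
  invisible(x)
}

#' Plant species visited at least once
#'
#' @param records Visitation record tibble (typically the full multi-year set).
#' @return Character vector of plant species with at least one recorded visit.
#' @export
visited_plant_species <- function(records) {
  sort(unique(records$plant_species))
}

#' Floral density on one sampling date
#'
#' Mean number of open floral units per 2 x 2 m plot on `date`, restricted to
#' plant species actually used by the bees (`visited_plants`): each surveyed
#' plot contributes the sum of its units over those species (0 if it holds
#' none of them), and the mean is taken across all plots surveyed that date.
#'
#' @param plots Floral plot tibble (see [read_floral_plots()]).
#' @param date The sampling date.
#' @param visited_plants Character vector of bee-visited plant species.
#' @return A single non-negative number (floral units per 4 m² plot).
#' @export
floral_density <- function(plots, date, visited_plants) {
  day <- plots[plots$date == as.Date(date), , drop = FALSE]
  if (nrow(day) == 0) stop("no floral plots surveyed on ", date, call. = FALSE)
  roster <- dplyr::distinct(day, .data$transect_id, .data$plot_id)
  sums <- day |>
    dplyr::filter(.data$plant_species %in% visited_plants) |>
    dplyr::group_by(.data$transect_id, .data$plot_id) |>
    dplyr::summarise(units = sum(.data$floral_units), .groups = "drop")
  roster <- dplyr::left_join(roster, sums, by = c("transect_id", "plot_id"))
  roster$units[is.na(roster$units)] <- 0
  mean(roster$units)
}

#' Per-date floral density series
#'
#' @param plots Floral plot tibble.
#' @param dates Dates to evaluate (default: all survey dates in `plots`).
#' @param visited_plants Bee-visited plant species (see
#'   [visited_plant_species()]).
#' @return Tibble `date`, `floral_density`.
#' @export
floral_density_series <- function(plots, dates = NULL, visited_plants) {
  if (is.null(dates)) dates <- sort(unique(plots$date))
  tibble::tibble(
    date = as.Date(dates),
    floral_density = vapply(dates, function(d)
      floral_density(plots, d, visited_plants), numeric(1))
  )
}

#' Export daily networks as a long edge list
#'
#' @param networks List of `daily_network` objects.
#' @return Tibble `date`, `bee_species`, `plant_species`, `count` with one row
#'   per observed link.
#' @export
networks_to_edgelist <- function(networks) {
  purrr::map_dfr(networks, function(net) {
    idx <- which(net$counts > 0, arr.ind = TRUE)
    tibble::tibble(
      date = net$date,
      bee_species = rownames(net$counts)[idx[, 1]],
      plant_species = colnames(net$counts)[idx[, 2]],
      count = net$counts[idx]
    )
  })
}
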