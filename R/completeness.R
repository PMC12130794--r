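#' Chao2 interaction sampling completeness for one year
#'
#' Treats each sampling day as an incidence unit and each distinct bee-plant
#' link as a "species" for the incidence-based Chao2 richness estimator. With
#' `S_obs` observed links, `Q1` links seen on exactly one day, `Q2` on exactly
#' two, and `m` sampling days, the bias-corrected estimator is
#'
#' \deqn{\hat S = S_{obs} + \frac{m-1}{m}\,\frac{Q_1 (Q_1 - 1)}{2 (Q_2 + 1)}}
#'
#' which stays defined when `Q2 = 0`. The classic form
#' `S_obs + Q1^2 / (2 Q2)` is available when `Q2 > 0`. Completeness is
#' `S_obs / S_est`.
#'
#' @param networks List of `daily_network` objects from one year (>= 2 days).
#' @param variant `"bias_corrected"` (default) or `"classic"`.
#' @return A one-row tibble: `year`, `S_obs`, `Q1`, `Q2`, `m`, `S_est`,
#'   `completeness`.
#' @export
chao2_completeness <- function(networks, variant = c("bias_corrected", "classic")) {
  variant <- match.arg(variant)
  m <- length(networks)
  if (m < 2) stop("Chao2 needs >= 2 sampling days", call. = FALSE)
  edges <- networks_to_edgelist(networks)
  inc <- edges |>
    dplyr::distinct(.data$date, .data$bee_species, .data$plant_species) |>
    dplyr::count(.data$bee_species, .data$plant_species, name = "n_days")
  s_obs <- nrow(inc)
  q1 <- sum(inc$n_days == 1)
  q2 <- sum(inc$n_days == 2)
  s_est <- chao2_estimate(s_obs, q1, q2, m, variant)
  tibble::tibble(
    year = as.integer(format(networks[[1]]$date, "%Y")),
    S_obs = s_obs, Q1 = q1, Q2 = q2, m = m,
    S_est = s_est, completeness = s_obs / s_est
  )
}

#' Chao2 estimate from incidence counts
#'
#' @param s_obs Observed richness (here: distinct links).
#' @param q1,q2 Singleton and doubleton incidence counts.
#' @param m Number of incidence units (sampling days).
#' @param variant `"bias_corrected"` or `"classic"`.
#' @return The estimated richness `S_est >= s_obs`.
#' @export
chao2_estimate <- function(s_obs, q1, q2, m,
                           variant = c("bias_corrected", "classic")) {
  variant <- match.arg(variant)
  if (variant == "classic") {
    if (q2 == 0) stop("classic Chao2 undefined when Q2 = 0", call. = FALSE)
    s_obs + q1^2 / (2 * q2)
  } else {
    s_obs + ((m - 1) / m) * q1 * (q1 - 1) / (2 * (q2 + 1))
  }
}

#' Per-year completeness table
#'
#' @param networks List of `daily_network` objects across all years.
#' @param variant Passed to [chao2_completeness()].
#' @return Tibble with one row per year.
#' @export
completeness_by_year <- function(networks, variant = "bias_corrected") {
  years <- vapply(networks, function(n) n$year, integer(1))
  purrr::map_dfr(sort(unique(years)), function(y)
    chao2_completeness(networks[years == y], variant = variant))
}

#' Does sampling effort drive completeness?
#'
#' Spearman rank correlation (two-sided) between per-year sampling effort
#' (number of transects walked) and Chao2 completeness. A strong positive
#' correlation would indicate completeness is an artifact of effort.
#'
#' @param completeness Tibble from [completeness_by_year()].
#' @param efforts Tibble `year`, `transects`.
#' @return List with `rho` and `p_value`.
#' @export
effort_completeness_correlation <- function(completeness, efforts) {
  df <- dplyr::inner_join(completeness, efforts, by = "year")
  if (nrow(df) < 3) stop("need >= 3 years for a rank correlation", call. = FALSE)
  if (length(unique(df$transects)) == 1 || length(unique(df$completeness)) == 1) {
    stop("rank correlation undefined for a constant vector", call. = FALSE)
  }
  ct <- suppressWarnings(
    stats::cor.test(df$transects, df$completeness, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}
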