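# in-code fixtures shared across test files

make_records <- function(bee, plant, date, count = 1L,
                         transect = "T1") {
  date <- as.Date(date)
  tibble::tibble(
    year = as.integer(format(date, "%Y")),
    date = date,
    transect_id = transect,
    bee_species = bee,
    plant_species = plant,
    count = as.integer(count)
  )
}

write_visit_csv <- function(df, path = tempfile(fileext = ".csv")) {
  readr::write_csv(df, path)
  path
}

# random count matrix with no all-zero row or column
random_network <- function(n_bees, n_plants, max_count = 20) {
  repeat {
    a <- matrix(sample(0:max_count, n_bees * n_plants, replace = TRUE),
                n_bees, n_plants,
                dimnames = list(paste0("b", seq_len(n_bees)),
                                paste0("p", seq_len(n_plants))))
    if (all(rowSums(a) > 0) && all(colSums(a) > 0)) return(a)
  }
}

# naive triple-loop evaluation of the PAC double sum
pac_oracle <- function(a) {
  n <- nrow(a)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      acc <- 0
      for (k in seq_len(ncol(a))) {
        acc <- acc + (a[i, k] / sum(a[i, ])) * (a[j, k] / sum(a[, k]))
      }
      d[i, j] <- acc
    }
  }
  d
}

# Spearman rho from first principles (average ranks)
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# tiny model-ready competition table with both responses
tiny_competition_table <- function(seed = 1) {
  g <- generate_competition_scenario(scenario_config(
    years = 2018:2020, days_per_year = c(4, 4, 4), n_species = 5, seed = seed))
  g$table
}
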