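#' Estimate effective relative abundances under the mass-action principle
#'
#' Raw capture counts are circular with the visitation frequencies that define
#' the networks, so abundance is instead inferred from the interaction matrix
#' itself. Under mass action the frequency of an observed link is
#' `F_ij = x_i * x_j * c_ij` — the product of the two partners' relative
#' abundances and an interaction preference. Taking logs over the observed
#' (nonzero) links gives an additive decomposition
#' `log F_ij = mu + r_i + s_j + e_ij`, fitted by least squares with
#' sum-to-zero constraints on the bee effects `r` and plant effects `s`;
#' zeros are treated as unobserved links, not as `log(0)`. Then
#' `x_i ∝ exp(r_i)` and `x_j ∝ exp(s_j)`, each side normalized to sum 1, and
#' the preference `c_ij = F_ij / (x_i * x_j)` absorbs the free scale.
#'
#' If the bipartite graph of observed links is disconnected the relative scale
#' between components is not identified; effects are estimated within each
#' connected component, components are weighted by their share of total
#' visits, and a warning is emitted.
#'
#' @param network A `daily_network` or non-negative count matrix (bees x
#'   plants, no all-zero rows/columns).
#' @return An `abundance_estimate`: list with `date`, `bee_abundances` and
#'   `plant_abundances` (named, each summing to 1), and `preferences` (matrix
#'   of `c_ij` on observed links, `NA` elsewhere).
#' @export
estimate_abundances <- function(network) {
  a <- if (inherits(network, "daily_network")) network$counts else as.matrix(network)
  if (any(a < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(rowSums(a) == 0) || any(colSums(a) == 0)) {
    stop("all retained species must have >= 1 interaction", call. = FALSE)
  }
  bees <- rownames(a)
  plants <- colnames(a)
  if (is.null(bees)) bees <- paste0("bee", seq_len(nrow(a)))
  if (is.null(plants)) plants <- paste0("plant", seq_len(ncol(a)))
  dimnames(a) <- list(bees, plants)

  idx <- which(a > 0, arr.ind = TRUE)
  links <- data.frame(
    bee = bees[idx[, 1]], plant = plants[idx[, 2]],
    y = log(a[idx]), w = a[idx], stringsAsFactors = FALSE
  )

  # connected components of the bipartite link graph
  g <- igraph::graph_from_data_frame(
    data.frame(from = paste0("B:", links$bee), to = paste0("P:", links$plant)),
    directed = FALSE)
  comp <- igraph::components(g)$membership
  links$component <- comp[paste0("B:", links$bee)]
  n_comp <- length(unique(links$component))
  if (n_comp > 1) {
    warning("bipartite graph has ", n_comp, " connected components; ",
            "cross-component abundance scaling is arbitrary", call. = FALSE)
  }

  x_bee <- stats::setNames(numeric(length(bees)), bees)
  x_plant <- stats::setNames(numeric(length(plants)), plants)
  for (cc in unique(links$component)) {
    sub <- links[links$component == cc, , drop = FALSE]
    eff <- twoway_log_effects(sub)
    xb <- exp(eff$r); xb <- xb / sum(xb)
    xp <- exp(eff$s); xp <- xp / sum(xp)
    w <- sum(sub$w) / sum(links$w)   # component share of total visits
    x_bee[names(xb)] <- w * xb
    x_plant[names(xp)] <- w * xp
  }
  x_bee <- x_bee / sum(x_bee)
  x_plant <- x_plant / sum(x_plant)

  pref <- matrix(NA_real_, length(bees), length(plants),
                 dimnames = list(bees, plants))
  pref[idx] <- a[idx] / (x_bee[idx[, 1]] * x_plant[idx[, 2]])

  structure(
    list(date = if (inherits(network, "daily_network")) network$date else NULL,
         bee_abundances = x_bee,
         plant_abundances = x_plant,
         preferences = pref),
    class = "abundance_estimate"
  )
}

# least-squares fit of y ~ mu + r[bee] + s[plant] with sum-to-zero effects
twoway_log_effects <- function(links) {
  bees <- sort(unique(links$bee))
  plants <- sort(unique(links$plant))
  r <- stats::setNames(numeric(length(bees)), bees)
  s <- stats::setNames(numeric(length(plants)), plants)
  df <- data.frame(
    y = links$y,
    bee = factor(links$bee, levels = bees),
    plant = factor(links$plant, levels = plants)
  )
  terms <- c(if (length(bees) > 1) "bee", if (length(plants) > 1) "plant")
  if (length(terms) == 0) {
    return(list(mu = mean(df$y), r = r, s = s))
  }
  fml <- stats::reformulate(terms, response = "y")
  contr <- lapply(stats::setNames(terms, terms), function(.) "contr.sum")
  fit <- stats::lm(fml, data = df, contrasts = contr)
  cf <- stats::coef(fit)
  cf[is.na(cf)] <- 0   # aliased effects (sparse designs) pinned to 0
  if (length(bees) > 1) {
    rb <- cf[grep("^bee", names(cf))]
    r[] <- c(rb, -sum(rb))
  }
  if (length(plants) > 1) {
    sp <- cf[grep("^plant", names(cf))]
    s[] <- c(sp, -sum(sp))
  }
  list(mu = unname(cf[["(Intercept)"]]), r = r, s = s)
}

#' @export
print.abundance_estimate <- function(x, ...) {
  cat("Mass-action abundance estimate",
      if (!is.null(x$date)) paste0("(", format(x$date), ")"), "\n")
  cat("Bees:\n"); print(round(sort(x$bee_abundances, decreasing = TRUE), 4))
  invisible(x)
}

#' Per-day bee abundance covariate table
#'
#' Joins daily abundance estimates into the long covariate table used by the
#' competition models. A species absent from a day's network has no row for
#' that date (absence, not zero abundance).
#'
#' @param networks List of `daily_network` objects.
#' @param estimates List of `abundance_estimate` objects, parallel to
#'   `networks` (default: computed from `networks`).
#' @return Tibble `date`, `species`, `abundance_est`.
#' @export
abundance_table <- function(networks, estimates = NULL) {
  if (is.null(estimates)) estimates <- lapply(networks, estimate_abundances)
  dates <- vapply(networks, function(n) format(n$date), character(1))
  est_dates <- vapply(estimates, function(e) {
    if (is.null(e$date)) NA_character_ else format(e$date)
  }, character(1))
  if (anyNA(est_dates) || !setequal(dates, est_dates)) {
    stop("abundance estimate missing for some network date", call. = FALSE)
  }
  purrr::map_dfr(estimates, function(e) {
    tibble::tibble(date = e$date,
                   species = names(e$bee_abundances),
                   abundance_est = unname(e$bee_abundances))
  })
}
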