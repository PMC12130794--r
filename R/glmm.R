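#' Log then z-transform a positive covariate
#'
#' Natural log followed by centering and scaling to unit sample standard
#' deviation, the transform applied to floral density and abundance before
#' model fitting.
#'
#' @param values Positive numeric vector with at least two distinct values.
#' @return Numeric vector with mean 0 and sample sd 1.
#' @export
log_z <- function(values) {
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("log_z requires strictly positive finite values", call. = FALSE)
  }
  z_score(log(values))
}

#' Center and scale to unit sd
#'
#' @param values Numeric vector with at least two distinct values.
#' @return Numeric vector with mean 0 and sample sd 1.
#' @export
z_score <- function(values) {
  if (length(unique(values)) < 2) {
    stop("cannot z-scale a constant vector", call. = FALSE)
  }
  as.numeric(scale(values))
}

#' Assemble the model-ready competition table
#'
#' Inner-joins the per-(date, species) competition indices with the estimated
#' abundances, the per-date floral densities and the per-species proboscis
#' lengths, and derives year and flowering period from the date. One row per
#' species present in each daily network. Transformed covariate columns
#' (`abundance_lz`, `floral_density_lz`, `proboscis_z`) are computed over the
#' assembled rows; the model fitters recompute them over the rows actually
#' entering each model.
#'
#' @param indices Tibble from [competition_indices()].
#' @param abundances Tibble from [abundance_table()].
#' @param densities Tibble `date`, `floral_density`.
#' @param traits Tibble `bee_species`, `proboscis_mm`.
#' @param transform Add transformed columns (default `TRUE`).
#' @return A `competition table` tibble: `year`, `date`, `flowering_period`,
#'   `species`, `inter_acting`, `intra`, `abundance_est`, `floral_density`,
#'   `proboscis_mm` (+ transformed columns).
#' @export
assemble_model_table <- function(indices, abundances, densities, traits,
                                 transform = TRUE) {
  missing_traits <- setdiff(unique(indices$species), traits$bee_species)
  if (length(missing_traits) > 0) {
    stop("no proboscis length for species: ",
         paste(missing_traits, collapse = ", "), call. = FALSE)
  }
  tab <- indices |>
    dplyr::inner_join(abundances, by = c("date", "species")) |>
    dplyr::inner_join(densities, by = "date") |>
    dplyr::inner_join(
      dplyr::rename(traits, species = "bee_species"), by = "species") |>
    dplyr::mutate(
      year = as.integer(format(.data$date, "%Y")),
      flowering_period = classify_flowering_period(.data$date)
    ) |>
    dplyr::select("year", "date", "flowering_period", "species",
                  "inter_acting", "intra", "abundance_est", "floral_density",
                  "proboscis_mm")
  if (transform && nrow(tab) >= 2) {
    tab$abundance_lz <- log_z(tab$abundance_est)
    tab$floral_density_lz <- log_z(tab$floral_density)
    tab$proboscis_z <- z_score(tab$proboscis_mm)
  }
  tab
}

#' Fit a Gaussian mixed model of potential competition
#'
#' Response is either the mean interspecific index of each acting species per
#' network day (`response = "inter"`) or the intraspecific (diagonal) index
#' (`response = "intra"`). Fixed effects: log-z abundance, log-z floral
#' density, their interaction, z proboscis length, year (categorical, first
#' year as reference) and flowering period (early as reference). Random
#' intercept for species identity. Fitted by maximum likelihood
#' (`REML = FALSE`) by default so Wald tests across fixed-effect structures
#' are coherent.
#'
#' @param table Competition table from [assemble_model_table()] (raw covariate
#'   columns suffice; transforms are recomputed over the model rows).
#' @param response `"inter"` or `"intra"`.
#' @param years Optional integer vector restricting the fit to a subset of
#'   years (e.g. the high-effort years).
#' @param ml Fit by ML (default `TRUE`); `FALSE` for REML.
#' @return A `competition_model`: list with the `glmmTMB` `fit`, `response`,
#'   `data` (model rows), `coefficients` (tibble: term, estimate, std_error,
#'   z_value, p_value), `random` (species intercept variance and sd),
#'   `wald` (type-II chi-square table), `vif` (main-effects collinearity),
#'   and `converged` flag.
#' @export
fit_competition_model <- function(table, response = c("inter", "intra"),
                                  years = NULL, ml = TRUE) {
  response <- match.arg(response)
  resp_col <- if (response == "inter") "inter_acting" else "intra"
  df <- as.data.frame(table)
  if (!is.null(years)) df <- df[df$year %in% years, , drop = FALSE]
  df <- df[is.finite(df[[resp_col]]), , drop = FALSE]
  if (length(unique(df$species)) < 2) stop("need >= 2 species", call. = FALSE)
  if (length(unique(df$year)) < 2) stop("need >= 2 years", call. = FALSE)

  df$resp <- df[[resp_col]]
  df$abundance_lz <- log_z(df$abundance_est)
  df$floral_density_lz <- log_z(df$floral_density)
  df$proboscis_z <- z_score(df$proboscis_mm)
  df$year_f <- factor(df$year)
  df$flowering_period <- factor(df$flowering_period,
                                levels = c("early", "middle", "late"))
  df$flowering_period <- droplevels(df$flowering_period)
  df$species <- factor(df$species)

  fit <- glmmTMB::glmmTMB(
    resp ~ abundance_lz * floral_density_lz + proboscis_z + year_f +
      flowering_period + (1 | species),
    data = df, family = stats::gaussian(), REML = !ml)

  sm <- summary(fit)$coefficients$cond
  coefs <- tibble::tibble(
    term = rownames(sm),
    estimate = unname(sm[, "Estimate"]),
    std_error = unname(sm[, "Std. Error"]),
    z_value = unname(sm[, "z value"]),
    p_value = unname(sm[, "Pr(>|z|)"])
  )
  vc <- glmmTMB::VarCorr(fit)$cond$species
  random <- tibble::tibble(
    group = "species", term = "(Intercept)",
    variance = as.numeric(vc), sd = sqrt(as.numeric(vc))
  )
  converged <- isTRUE(fit$sdr$pdHess) && fit$fit$convergence == 0
  if (!converged) warning("model did not converge cleanly", call. = FALSE)

  res <- structure(
    list(fit = fit, response = response, data = df,
         coefficients = coefs, random = random,
         converged = converged),
    class = "competition_model"
  )
  res$wald <- wald_tests(res)
  res$vif <- collinearity_vif(df, resp_col = "resp")
  res
}

#' @rdname fit_competition_model
#' @param ... Passed to [fit_competition_model()].
#' @export
fit_interspecific_model <- function(table, ...) {
  fit_competition_model(table, response = "inter", ...)
}

#' @rdname fit_competition_model
#' @export
fit_intraspecific_model <- function(table, ...) {
  fit_competition_model(table, response = "intra", ...)
}

#' @export
print.competition_model <- function(x, ...) {
  cat("Gaussian mixed model of potential",
      if (x$response == "inter") "interspecific" else "intraspecific",
      "competition\n")
  cat(nrow(x$data), "rows,", nlevels(x$data$species), "species; converged:",
      x$converged, "\n\nFixed effects:\n")
  print(as.data.frame(x$coefficients), digits = 3)
  cat("\nRandom intercept (species): variance",
      signif(x$random$variance, 3), "sd", signif(x$random$sd, 3), "\n")
  invisible(x)
}

#' Type-II Wald chi-square tests per fixed-effect term
#'
#' @param model A `competition_model` (or a `glmmTMB` fit).
#' @return Tibble `term`, `chisq`, `df`, `p_value` (intercept excluded).
#' @export
wald_tests <- function(model) {
  fit <- if (inherits(model, "competition_model")) model$fit else model
  an <- car::Anova(fit, type = "II")
  tibble::tibble(
    term = rownames(an),
    chisq = an[["Chisq"]],
    df = an[["Df"]],
    p_value = an[["Pr(>Chisq)"]]
  )
}

#' Variance inflation factors for the main-effects design
#'
#' Collinearity screen computed on the fixed main effects only — the
#' abundance x density interaction is excluded, since an interaction is
#' collinear with its components by construction. Factors are summarized by
#' the generalized VIF. Values are reported, not enforced; < 3 is the usual
#' comfort zone.
#'
#' @param table Competition table (rows entering the model) with transformed
#'   columns, or the `data` slot of a fitted model.
#' @param resp_col Response column name (default `"intra"`).
#' @return Named numeric vector of (G)VIFs per predictor.
#' @export
collinearity_vif <- function(table, resp_col = "intra") {
  df <- as.data.frame(table)
  if (!"abundance_lz" %in% names(df)) {
    df$abundance_lz <- log_z(df$abundance_est)
    df$floral_density_lz <- log_z(df$floral_density)
    df$proboscis_z <- z_score(df$proboscis_mm)
  }
  if (!"year_f" %in% names(df)) df$year_f <- factor(df$year)
  df$resp <- df[[resp_col]]
  terms <- c("abundance_lz", "floral_density_lz", "proboscis_z")
  if (nlevels(droplevels(factor(df$year_f))) > 1) terms <- c(terms, "year_f")
  if (nlevels(droplevels(factor(df$flowering_period))) > 1) {
    terms <- c(terms, "flowering_period")
  }
  fml <- stats::reformulate(terms, response = "resp")
  lmfit <- stats::lm(fml, data = df)
  if (any(is.na(stats::coef(lmfit)))) {
    stop("singular main-effects design; VIF undefined", call. = FALSE)
  }
  v <- car::vif(lmfit)
  if (is.matrix(v)) stats::setNames(v[, "GVIF"], rownames(v)) else v
}

#' Partial residuals for one model term
#'
#' Component-plus-residual values isolating a term's relationship in the
#' fitted model: the term's fixed-effect contribution plus the conditional
#' residual, against the term's covariate values. For the abundance x density
#' interaction, predicted lines of the fixed-effect response over the
#' abundance range are also returned at low / medium / high floral density
#' (10th, 50th, 90th quantiles by default), holding other covariates at their
#' reference or zero (centered) values.
#'
#' @param model A `competition_model`.
#' @param term A fixed-effect term label, e.g. `"abundance_lz"`,
#'   `"proboscis_z"`, `"flowering_period"` or
#'   `"abundance_lz:floral_density_lz"`.
#' @param density_quantiles Floral-density quantiles for the interaction
#'   display (default `c(0.1, 0.5, 0.9)`).
#' @param n_grid Points per predicted line (default 50).
#' @return List with `points` (tibble `term_value`, `partial_residual`) and,
#'   for the interaction term, `lines` (tibble `abundance_lz`,
#'   `floral_density_lz`, `density_level`, `predicted`).
#' @export
partial_residuals <- function(model, term,
                              density_quantiles = c(0.1, 0.5, 0.9),
                              n_grid = 50) {
  stopifnot(inherits(model, "competition_model"))
  fit <- model$fit
  fixed <- lme4::nobars(stats::formula(fit))
  tt <- stats::delete.response(stats::terms(fixed))
  labels <- attr(tt, "term.labels")
  if (!term %in% labels) {
    stop("term '", term, "' not in model; available: ",
         paste(labels, collapse = ", "), call. = FALSE)
  }
  X <- stats::model.matrix(tt, model$data)
  beta <- glmmTMB::fixef(fit)$cond
  assign <- attr(X, "assign")
  cols <- which(assign == match(term, labels))
  contrib <- as.numeric(X[, cols, drop = FALSE] %*% beta[cols])
  resid <- stats::residuals(fit)

  term_value <- if (term %in% names(model$data)) {
    model$data[[term]]
  } else if (term == "abundance_lz:floral_density_lz") {
    model$data$abundance_lz
  } else {
    contrib
  }
  out <- list(points = tibble::tibble(term_value = term_value,
                                      partial_residual = contrib + resid))

  if (term == "abundance_lz:floral_density_lz") {
    qs <- stats::quantile(model$data$floral_density_lz, density_quantiles)
    grid <- expand.grid(
      abundance_lz = seq(min(model$data$abundance_lz),
                         max(model$data$abundance_lz), length.out = n_grid),
      floral_density_lz = unname(qs)
    )
    grid$density_level <- rep(names(qs), each = n_grid)
    newdata <- grid
    newdata$proboscis_z <- 0
    newdata$year_f <- factor(levels(model$data$year_f)[1],
                             levels = levels(model$data$year_f))
    newdata$flowering_period <- factor(
      levels(model$data$flowering_period)[1],
      levels = levels(model$data$flowering_period))
    Xg <- stats::model.matrix(tt, newdata)
    grid$predicted <- as.numeric(Xg %*% beta)
    out$lines <- tibble::as_tibble(grid)
  }
  out
}
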