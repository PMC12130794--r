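#' Mueller's potential apparent competition (PAC) matrix
#'
#' For a quantitative bee x plant visitation matrix `a` the index is
#'
#' \deqn{d_{ij} = \sum_k \frac{a_{ik}}{\sum_l a_{il}} \times
#'               \frac{a_{jk}}{\sum_m a_{mk}}}
#'
#' where `i` is the target bee species, `j` the acting species, and `k` runs
#' over plant species. The first factor is the share of target `i`'s visits
#' going to plant `k`; the second is acting `j`'s share of all bee visits
#' received by plant `k`. `d_ij` therefore measures how much of `i`'s resource
#' use falls on plants dominated by `j`: 0 when the pair shares no plants, 1
#' when `j` monopolizes every plant `i` uses. Rows (targets) sum to 1. The
#' diagonal `d_ii` is the species' own contribution to the visitation of its
#' plants — the potential intraspecific competition.
#'
#' @param network A `daily_network` or a non-negative count matrix (bees in
#'   rows, plants in columns) with no all-zero row or column.
#' @return A `pac_matrix`: square numeric matrix, acting species in columns,
#'   target species in rows, with a `date` attribute when available.
#' @export
pac_matrix <- function(network) {
  a <- if (inherits(network, "daily_network")) network$counts else as.matrix(network)
  if (nrow(a) < 1 || ncol(a) < 1) stop("network needs >= 1 bee and >= 1 plant", call. = FALSE)
  if (any(a < 0)) stop("counts must be non-negative", call. = FALSE)
  rs <- rowSums(a)
  cs <- colSums(a)
  if (any(rs == 0)) stop("all-zero bee row in network", call. = FALSE)
  if (any(cs == 0)) stop("all-zero plant column in network", call. = FALSE)
  p <- a / rs                      # target's use shares over plants
  q <- sweep(a, 2, cs, "/")        # acting species' share of each plant's visits
  d <- p %*% t(q)
  dimnames(d) <- list(target = rownames(a), acting = rownames(a))
  structure(d, class = c("pac_matrix", "matrix"),
            date = if (inherits(network, "daily_network")) network$date else NULL)
}

#' Potential interspecific competition per acting species
#'
#' Column means of the PAC matrix excluding the diagonal: the mean effect the
#' acting species exerts on every other species in the network.
#'
#' @param pac A `pac_matrix`.
#' @return Named numeric vector (one value per acting species); empty for a
#'   single-species network, where interspecific influence is undefined.
#' @export
interspecific_index <- function(pac) {
  n <- nrow(pac)
  if (n < 2) return(stats::setNames(numeric(0), character(0)))
  stats::setNames((colSums(pac) - diag(pac)) / (n - 1), colnames(pac))
}

#' Potential intraspecific competition per species
#'
#' The diagonal of the PAC matrix: the focal species' own contribution to the
#' total visitation of the plants it uses.
#'
#' @param pac A `pac_matrix`.
#' @return Named numeric vector of diagonal values in `[0, 1]`.
#' @export
intraspecific_index <- function(pac) {
  stats::setNames(diag(pac), colnames(pac))
}

#' Competition indices for a set of daily networks
#'
#' @param networks List of `daily_network` objects.
#' @return Tibble `date`, `species`, `inter_acting`, `intra`. `inter_acting`
#'   is `NA` on single-species days.
#' @export
competition_indices <- function(networks) {
  purrr::map_dfr(networks, function(net) {
    d <- pac_matrix(net)
    intra <- intraspecific_index(d)
    inter <- interspecific_index(d)
    tibble::tibble(
      date = net$date,
      species = names(intra),
      inter_acting = if (length(inter)) unname(inter[names(intra)]) else NA_real_,
      intra = unname(intra)
    )
  })
}
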