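#' Configuration of the dendritic-truncation Monte-Carlo
#'
#' The SPN dendritic field is modeled as a sphere centered on the soma.
#' A fraction `frac_dendritic` of S1 synapses (default 80%) is distributed
#' radially along dendrites according to `radial_density` with isotropic
#' directions; the remainder is somatic and can never be lost. Slicing
#' removes a spherical cap: a dendritic synapse is lost iff its coordinate
#' toward the cut surface exceeds `soma_depth_um` (default 80 um, the
#' shallowest recording depth - a conservative, worst-case plane). The
#' second slice face (350 um thickness) is far enough to be ignored.
#'
#' The default radial density is an anatomy-inspired triangular profile
#' rising from 0 to a peak at 80 um and vanishing at the 200 um dendritic
#' radius: proximal synapse density grows with the expanding dendritic tree
#' and distal synapses are proportionally rare. It is an explicit assumption
#' of the model and fully user-overridable.
#'
#' @param dendritic_radius_um Radius of the spherical dendritic field.
#' @param frac_dendritic Fraction of synapses on dendrites (the rest is
#'   somatic).
#' @param radial_density Data.frame with columns `r_lo_um`, `r_hi_um`,
#'   `weight` (non-negative, not all zero; bins within
#'   `[0, dendritic_radius_um]`). Radii are drawn by bin weight, uniformly
#'   within a bin.
#' @param soma_depth_um Depth of the cut plane below the soma.
#' @param n_synapses Monte-Carlo sample size.
#' @return An object of class `truncation_config`.
#' @export
truncation_config <- function(dendritic_radius_um = 200, frac_dendritic = 0.8,
                              radial_density = NULL, soma_depth_um = 80,
                              n_synapses = 1e5) {
  if (is.null(radial_density))
    radial_density <- triangular_radial_density(dendritic_radius_um)
  stopifnot(dendritic_radius_um > 0,
            frac_dendritic >= 0, frac_dendritic <= 1,
            soma_depth_um >= 0, n_synapses >= 1)
  rd <- as.data.frame(radial_density)
  if (!all(c("r_lo_um", "r_hi_um", "weight") %in% names(rd)) || nrow(rd) == 0L)
    stop("radial_density must be a non-empty table with r_lo_um, r_hi_um, weight")
  if (any(rd$weight < 0) || sum(rd$weight) <= 0)
    stop("radial_density weights must be >= 0 and not all zero")
  if (any(rd$r_lo_um < 0) || any(rd$r_hi_um > dendritic_radius_um) ||
      any(rd$r_hi_um < rd$r_lo_um))
    stop("radial_density bins must lie within [0, dendritic_radius_um]")
  structure(list(dendritic_radius_um = dendritic_radius_um,
                 frac_dendritic = frac_dendritic, radial_density = rd,
                 soma_depth_um = soma_depth_um,
                 n_synapses = as.integer(n_synapses)),
            class = "truncation_config")
}

#' Triangular radial synapse density
#'
#' Piecewise-linear density rising from 0 at the soma to a peak (default
#' 80 um) and falling to 0 at the dendritic radius, discretized into 5 um
#' bins.
#'
#' @param radius_um Dendritic-field radius.
#' @param peak_um Radius of maximal synapse density.
#' @param bin_um Bin width of the table.
#' @return Data.frame with r_lo_um, r_hi_um, weight.
#' @export
triangular_radial_density <- function(radius_um = 200, peak_um = 80,
                                      bin_um = 5) {
  stopifnot(radius_um > 0, peak_um > 0, peak_um < radius_um)
  lo <- seq(0, radius_um - bin_um, by = bin_um)
  hi <- lo + bin_um
  mid <- (lo + hi) / 2
  w <- ifelse(mid <= peak_um, mid / peak_um,
              (radius_um - mid) / (radius_um - peak_um))
  data.frame(r_lo_um = lo, r_hi_um = hi, weight = w)
}

#' Monte-Carlo estimate of synapse loss from slice truncation
#'
#' Samples `n_synapses` synapses: somatic with probability
#' `1 - frac_dendritic` (never lost), otherwise at a radius drawn from the
#' radial density with an isotropic direction (the coordinate toward the cut
#' surface is `r * u`, `u ~ Uniform(-1, 1)`). A dendritic synapse is lost
#' iff `r * u > soma_depth_um`. For all mass at a single radius `r > d` the
#' closed form is `frac_dendritic * (r - d) / (2 r)` (see
#' [truncation_loss_closed_form()]), which the estimator matches within
#' Monte-Carlo error.
#'
#' @param config A [truncation_config()].
#' @param seed Integer seed.
#' @return A list: loss_fraction, se (binomial standard error
#'   `sqrt(p(1-p)/n)`), n_synapses, n_lost.
#' @export
estimate_truncation_loss <- function(config = truncation_config(), seed = 1L) {
  stopifnot(inherits(config, "truncation_config"))
  n <- config$n_synapses
  rd <- config$radial_density
  with_seed(derive_seed(seed, "truncation"), {
    dendritic <- stats::runif(n) < config$frac_dendritic
    nd <- sum(dendritic)
    lost <- 0L
    if (nd > 0L) {
      bin <- sample.int(nrow(rd), nd, replace = TRUE, prob = rd$weight)
      r <- stats::runif(nd, rd$r_lo_um[bin], rd$r_hi_um[bin])
      u <- stats::runif(nd, -1, 1)
      lost <- sum(r * u > config$soma_depth_um)
    }
    p <- lost / n
    list(loss_fraction = p, se = sqrt(p * (1 - p) / n),
         n_synapses = n, n_lost = as.integer(lost))
  })
}

#' Closed-form truncation loss for a single-radius density
#'
#' With all dendritic synapses at radius `r` and isotropic directions, the
#' fraction beyond a cut plane at depth `d` is the spherical-cap fraction
#' `(r - d) / (2 r)` for `r > d`, else 0; multiplied by the dendritic
#' fraction.
#'
#' @param r_um Synapse radius.
#' @param depth_um Cut-plane depth below the soma.
#' @param frac_dendritic Dendritic synapse fraction.
#' @return Expected loss fraction.
#' @export
truncation_loss_closed_form <- function(r_um, depth_um, frac_dendritic = 0.8) {
  stopifnot(r_um > 0, depth_um >= 0)
  frac_dendritic * pmax(0, r_um - depth_um) / (2 * r_um)
}
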