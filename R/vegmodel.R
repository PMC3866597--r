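# Simplified bioclimatic vegetation forward model.
#
# This is deliberately NOT a full dynamic vegetation model: the inversion
# machinery only needs a continuous, ecologically monotone map from the 36
# monthly climate variables to relative abundances of 13 plant functional
# groups. Each group's affinity is a trapezoidal climate envelope over
# (coldest-month temperature, growing degree-days) times a piecewise-linear
# moisture ramp times a logarithmic CO2 scalar; all constants live in the
# versioned parameter table shipped with the package (see [pft_params()]).

#' Construct a monthly climate vector
#'
#' @param temp 12 monthly mean temperatures, deg C (Jan..Dec).
#' @param precip 12 monthly precipitation totals, mm; must be non-negative.
#' @param cloud 12 monthly cloud covers, percent in [0, 100].
#' @return Named numeric vector of length 36 (`tmp1..12`, `pre1..12`,
#'   `cld1..12`).
#' @export
monthly_climate <- function(temp, precip, cloud) {
  stopifnot(length(temp) == 12, length(precip) == 12, length(cloud) == 12)
  if (any(precip < 0)) stop("precipitation must be non-negative")
  if (any(cloud < 0 | cloud > 100)) stop("cloud cover must lie in [0, 100]")
  x <- c(temp, precip, cloud)
  names(x) <- climate_var_names()
  x
}

#' Names of the 36 monthly climate variables
#' @return Character vector `tmp1..tmp12, pre1..pre12, cld1..cld12`.
#' @export
climate_var_names <- function() {
  c(paste0("tmp", 1:12), paste0("pre", 1:12), paste0("cld", 1:12))
}

climate_parts <- function(climate) {
  stopifnot(length(climate) == 36)
  list(temp = climate[1:12], precip = climate[13:24], cloud = climate[25:36])
}

# Thornthwaite-style potential evapotranspiration, mm/month: a temperature
# term scaled by (1 - cloud/200) so all three variable blocks enter the
# moisture index. 5 mm per deg C per 30-day month above 0 deg C.
PET_MM_PER_DEGC_MONTH <- 5

#' Bioclimatic indices from monthly climate
#'
#' Computes the summary indices the forward model and the reconstructions
#' are expressed in: mean annual temperature (MAT), mean temperature of the
#' coldest and warmest months (MTCO, MTWA), annual precipitation (PANN),
#' growing degree-days above 5 deg C (GDD5, using standard Gregorian month
#' lengths), and a moisture index alpha = PANN / (PANN + PET) in [0, 1].
#'
#' @param climate Numeric vector of length 36 as from [monthly_climate()].
#' @return Named list with `mat`, `mtco`, `mtwa`, `pann`, `gdd5`, `alpha`.
#' @export
bioclim <- function(climate) {
  p <- climate_parts(climate)
  pann <- sum(p$precip)
  pet <- sum(PET_MM_PER_DEGC_MONTH * pmax(p$temp, 0) * (MONTH_DAYS / 30) *
               (1 - p$cloud / 200))
  list(mat  = mean(p$temp),
       mtco = min(p$temp),
       mtwa = max(p$temp),
       pann = pann,
       gdd5 = sum(pmax(0, p$temp - 5) * MONTH_DAYS),
       alpha = if (pann + pet <= 0) 0 else pann / (pann + pet))
}

# trapezoid membership, vectorized over parameter rows for a scalar x
trapezoid <- function(x, a, b, c, d) {
  up   <- ifelse(b > a, (x - a) / (b - a), as.numeric(x >= a))
  down <- ifelse(d > c, (d - x) / (d - c), as.numeric(x <= c))
  clamp(pmin(up, down, 1), 0, 1)
}

ramp <- function(x, x0, v0, x1, v1) {
  f <- clamp((x - x0) / (x1 - x0), 0, 1)
  v0 + f * (v1 - v0)
}

#' Plant-functional-group affinity profile
#'
#' Maps bioclimatic indices (and CO2) to a normalized 13-group affinity
#' profile: per group, raw score = envelope(mtco) * envelope(gdd5) *
#' moisture ramp(alpha) * (1 + beta * ln(co2/280)), then normalized to sum 1.
#' If every raw score is zero (climate outside all envelopes) a uniform
#' profile is returned with a warning.
#'
#' @param indices Output of [bioclim()].
#' @param co2 Atmospheric CO2, ppm.
#' @return Named numeric vector of 13 non-negative scores summing to 1.
#' @export
pft_scores <- function(indices, co2 = 280) {
  pp <- pft_params()
  raw <- trapezoid(indices$mtco, pp$mtco_a, pp$mtco_b, pp$mtco_c, pp$mtco_d) *
    trapezoid(indices$gdd5, pp$gdd_a, pp$gdd_b, pp$gdd_c, pp$gdd_d) *
    ramp(indices$alpha, pp$alpha_lo, pp$v_lo, pp$alpha_hi, pp$v_hi) *
    pmax(1 + pp$beta * log(co2 / 280), 0)
  names(raw) <- pp$group
  s <- sum(raw)
  if (s <= 0) {
    warning("climate outside all group envelopes; returning uniform profile")
    return(stats::setNames(rep(1 / nrow(pp), nrow(pp)), pp$group))
  }
  raw / s
}

#' Forward model: monthly climate to group profile
#'
#' Convenience composition `pft_scores(bioclim(climate), co2)`.
#'
#' @inheritParams bioclim
#' @inheritParams pft_scores
#' @return Normalized 13-group profile.
#' @export
forward_model <- function(climate, co2 = 280) {
  pft_scores(bioclim(climate), co2 = co2)
}
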