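# Radiocarbon calibration against an IntCal-format curve.
#
# The calibrated-age density on a uniform calendar grid is
#   pdf(t) proportional to Normal(c14_age; mu(t), sqrt(err^2 + curve_err(t)^2))
# with mu and curve_err linearly interpolated between curve knots (the
# convention of the classic calibration programs). Point estimates follow the
# legacy intercept method (calendar age where the curve crosses the measured
# 14C age), alongside the posterior median and probability-weighted mean.

#' Read a calibration curve file
#'
#' Accepts IntCal-style text: comment lines starting with `#`, then at least
#' three columns (cal BP, 14C age BP, curve error), comma- or
#' whitespace-separated, in either cal-BP order. Extra columns are ignored.
#'
#' @param path File path.
#' @return A `calcurve`: data frame with `cal_bp`, `c14_bp`, `error`,
#'   sorted by increasing cal BP.
#' @export
read_calcurve <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  # tolerate a column-header line (as written by write_calcurve)
  first <- strsplit(trimws(lines[1]), "[,\\s]+")[[1]]
  if (anyNA(suppressWarnings(as.numeric(first)))) lines <- lines[-1]
  sep <- if (any(grepl(",", lines[1]))) "," else ""
  df <- utils::read.table(text = lines, sep = sep, header = FALSE,
                          strip.white = TRUE)
  as_calcurve(df[[1]], df[[2]], df[[3]])
}

#' Construct a calibration-curve object
#'
#' @param cal_bp Calendar ages, cal yr BP.
#' @param c14_bp 14C ages at those calendar ages, 14C yr BP.
#' @param error 1-sigma curve error, 14C yr; non-negative.
#' @return A `calcurve` data frame sorted by increasing `cal_bp`.
#' @export
as_calcurve <- function(cal_bp, c14_bp, error) {
  o <- order(cal_bp)
  cc <- data.frame(cal_bp = cal_bp[o], c14_bp = c14_bp[o], error = error[o])
  if (any(duplicated(cc$cal_bp))) stop("duplicate cal BP knots in curve")
  if (any(cc$error < 0)) stop("curve error must be non-negative")
  if (nrow(cc) < 2) stop("calibration curve needs at least two knots")
  class(cc) <- c("calcurve", "data.frame")
  cc
}

#' Write a calibration curve as IntCal-style text
#' @param curve A `calcurve`.
#' @param path Output path.
#' @param meta Optional named vector of `# key: value` header lines.
#' @return `path`, invisibly.
#' @export
write_calcurve <- function(curve, path, meta = NULL) {
  write_tsv_meta(as.data.frame(unclass(curve)), path, meta)
}

curve_at <- function(curve, cal_bp) {
  list(mu = stats::approx(curve$cal_bp, curve$c14_bp, xout = cal_bp)$y,
       err = stats::approx(curve$cal_bp, curve$error, xout = cal_bp)$y)
}

# highest-posterior-density interval set on a discrete grid
hpd_intervals <- function(grid, mass, level) {
  o <- order(mass, decreasing = TRUE)
  keep <- o[cumsum(mass[o]) <= level]
  # include the cell that crosses the level so coverage >= level - one cell
  if (length(keep) < length(o)) keep <- c(keep, o[length(keep) + 1L])
  inside <- sort(keep)
  breaks <- which(diff(inside) > 1L)
  starts <- inside[c(1L, breaks + 1L)]
  ends <- inside[c(breaks, length(inside))]
  cbind(lo = grid[starts], hi = grid[ends])
}

#' Calibrate a radiocarbon date
#'
#' Computes the calibrated-age probability density of a 14C determination on
#' a uniform calendar grid, its 68.3% and 95.4% highest-posterior-density
#' interval sets, and three point estimates: the legacy intercept (calendar
#' age where the curve crosses the measured 14C age; with multiple crossings,
#' the one inside the highest-probability 95.4% interval with the largest
#' posterior density), the posterior median, and the probability-weighted
#' mean.
#'
#' @param c14_age Conventional 14C age, 14C yr BP.
#' @param c14_error 1-sigma lab error, 14C yr; positive.
#' @param curve A `calcurve` (see [read_calcurve()], [as_calcurve()]).
#' @param grid_step Calendar grid step in years (default 1).
#' @param lab_code Optional identifier carried into the result.
#' @return A `cal14_age` object: `grid`, `pdf` (sums to 1), `hpd68`, `hpd95`
#'   (matrices of `lo`/`hi` cal BP), `intercept`, `median`, `wmean`.
#' @export
calibrate_c14 <- function(c14_age, c14_error, curve, grid_step = 1,
                          lab_code = NA_character_) {
  stopifnot(inherits(curve, "calcurve"))
  if (c14_error <= 0) stop("c14_error must be positive")
  rng <- range(curve$c14_bp)
  if (c14_age < rng[1] - 3 * c14_error || c14_age > rng[2] + 3 * c14_error) {
    stop(sprintf("14C age %s BP outside curve range [%s, %s]",
                 c14_age, rng[1], rng[2]))
  }
  grid <- seq(min(curve$cal_bp), max(curve$cal_bp), by = grid_step)
  ca <- curve_at(curve, grid)
  sd_tot <- sqrt(c14_error^2 + ca$err^2)
  dens <- stats::dnorm(c14_age, mean = ca$mu, sd = sd_tot)
  if (sum(dens) <= 0) stop("zero calibrated density: date incompatible with curve")
  mass <- dens / sum(dens)

  hpd68 <- hpd_intervals(grid, mass, 0.683)
  hpd95 <- hpd_intervals(grid, mass, 0.954)

  cdf <- cumsum(mass)
  med <- grid[which(cdf >= 0.5)[1]]
  wmean <- sum(grid * mass)

  # intercept: sign changes of mu(t) - c14_age along the grid
  f <- ca$mu - c14_age
  idx <- which(f[-length(f)] * f[-1] < 0)
  cross <- grid[idx] + grid_step * f[idx] / (f[idx] - f[idx + 1L])
  cross <- c(cross, grid[f == 0])
  if (length(cross) == 0L) {
    intercept <- grid[which.max(mass)]
  } else if (length(cross) == 1L) {
    intercept <- cross
  } else {
    best <- hpd95[which.max(apply(hpd95, 1, function(iv) {
      sum(mass[grid >= iv[1] & grid <= iv[2]])
    })), , drop = TRUE]
    inside <- cross[cross >= best[1] & cross <= best[2]]
    cand <- if (length(inside)) inside else cross
    dens_at <- stats::approx(grid, mass, xout = cand)$y
    intercept <- cand[which.max(dens_at)]
  }

  structure(list(lab_code = lab_code, c14_age = c14_age,
                 c14_error = c14_error, grid = grid, pdf = mass,
                 hpd68 = hpd68, hpd95 = hpd95,
                 intercept = intercept, median = med, wmean = wmean),
            class = "cal14_age")
}

#' @export
print.cal14_age <- function(x, ...) {
  cat(sprintf("Calibrated 14C date%s: %d +/- %d 14C BP\n",
              if (is.na(x$lab_code)) "" else paste0(" ", x$lab_code),
              round(x$c14_age), round(x$c14_error)))
  cat(sprintf("  intercept %.0f cal BP | median %.0f | weighted mean %.1f\n",
              x$intercept, x$median, x$wmean))
  fmt <- function(iv) paste(sprintf("%.0f-%.0f", iv[, "hi"], iv[, "lo"]),
                            collapse = ", ")
  cat("  68.3% HPD:", fmt(x$hpd68), "\n")
  cat("  95.4% HPD:", fmt(x$hpd95), "\n")
  invisible(x)
}

#' @export
plot.cal14_age <- function(x, ...) {
  keep <- x$pdf > max(x$pdf) * 1e-4
  plot(x$grid[keep], x$pdf[keep], type = "l", xlab = "cal yr BP",
       ylab = "probability mass", ...)
  graphics::abline(v = x$intercept, lty = 2)
  invisible(x)
}
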