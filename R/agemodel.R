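# Piecewise-linear age-depth model through calibrated intercepts, with
# per-segment deposition rates (optionally compaction-corrected).

#' Build an age-depth model
#'
#' Constructs the piecewise-linear depth-to-calendar-age map through dated
#' horizons and computes per-segment deposition rates,
#' rate = (delta depth / delta age) * compaction_factor, in cm/kyr. Ages must
#' increase strictly with depth; any reversal is an error naming the
#' offending pair (no automatic outlier rejection).
#'
#' @param depth Depths of dated horizons, cm below core top, strictly
#'   increasing.
#' @param age Calibrated point ages at those depths, cal yr BP.
#' @param compaction Per-segment compaction factor(s), recycled; default 1
#'   (no correction).
#' @return An `age_model`: knot table, per-segment `rate_cm_kyr`.
#' @export
build_age_model <- function(depth, age, compaction = 1) {
  stopifnot(length(depth) == length(age), length(depth) >= 2)
  o <- order(depth)
  depth <- depth[o]; age <- age[o]
  if (any(diff(depth) <= 0)) stop("depths must be strictly increasing")
  rev_i <- which(diff(age) <= 0)
  if (length(rev_i)) {
    stop(sprintf("age reversal between depths %g cm (%g cal BP) and %g cm (%g cal BP)",
                 depth[rev_i[1]], age[rev_i[1]],
                 depth[rev_i[1] + 1], age[rev_i[1] + 1]))
  }
  nseg <- length(depth) - 1L
  compaction <- rep_len(compaction, nseg)
  rate <- diff(depth) / (diff(age) / 1000) * compaction
  structure(list(knots = data.frame(depth = depth, age = age),
                 rate_cm_kyr = rate, compaction = compaction),
            class = "age_model")
}

#' Age at depth from an age-depth model
#'
#' Linear interpolation within the containing segment; depths outside the
#' dated interval are an error unless `extrapolate = TRUE`, in which case the
#' terminal segment's slope is extended.
#'
#' @param object An `age_model`.
#' @param depth Depth(s), cm.
#' @param extrapolate Allow extrapolation beyond the dated knots.
#' @param ... Ignored.
#' @return Calendar age(s), cal yr BP.
#' @export
predict.age_model <- function(object, depth, extrapolate = FALSE, ...) {
  k <- object$knots
  if (!extrapolate && (any(depth < min(k$depth)) || any(depth > max(k$depth)))) {
    stop(sprintf("depth outside dated interval [%g, %g] cm (set extrapolate = TRUE to extend)",
                 min(k$depth), max(k$depth)))
  }
  stats::approx(k$depth, k$age, xout = depth, rule = 2)$y +
    if (extrapolate) {
      lo <- depth < min(k$depth); hi <- depth > max(k$depth)
      out <- numeric(length(depth))
      s1 <- (k$age[2] - k$age[1]) / (k$depth[2] - k$depth[1])
      n <- nrow(k)
      sn <- (k$age[n] - k$age[n - 1]) / (k$depth[n] - k$depth[n - 1])
      out[lo] <- (depth[lo] - min(k$depth)) * s1
      out[hi] <- (depth[hi] - max(k$depth)) * sn
      out
    } else 0
}

#' @export
print.age_model <- function(x, ...) {
  k <- x$knots
  cat(sprintf("Age-depth model: %d knots, %g-%g cm, %g-%g cal BP\n",
              nrow(k), min(k$depth), max(k$depth), min(k$age), max(k$age)))
  seg <- data.frame(from_cm = k$depth[-nrow(k)], to_cm = k$depth[-1],
                    rate_cm_kyr = round(x$rate_cm_kyr, 2),
                    compaction = x$compaction)
  print(seg, row.names = FALSE)
  invisible(x)
}
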