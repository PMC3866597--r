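# Synthetic-data generators.
#
# Every input the pipeline consumes can be generated here with known ground
# truth: an IntCal-style calibration curve, a dated sediment core with
# multinomial pollen counts driven by a known climate trajectory through the
# vegetation forward model, and a gridded modern monthly climate table with
# seasonal and spatial structure. All generators are pure functions of
# (parameters, seed).

#' Make a synthetic calibration curve
#'
#' Builds a strictly monotone calendar-age to 14C-age map over
#' [0, `cal_max`] cal BP at `step`-year knots. `"identity"` gives
#' 14C(t) = t; `"linear"` gives 14C(t) = intercept + slope * t;
#' `"piecewise"` draws per-segment slopes uniformly in `slope_range`
#' (seeded), giving a gently wiggly but monotone curve.
#'
#' @param kind Curve family.
#' @param slope,intercept Linear parameters (kind = "linear").
#' @param n_segments Number of slope segments (kind = "piecewise").
#' @param slope_range Range of piecewise segment slopes; must be positive.
#' @param error Constant 1-sigma curve error, 14C yr.
#' @param seed Integer seed (piecewise only).
#' @param cal_max Upper calendar limit, cal BP.
#' @param step Knot spacing, yr.
#' @return A `calcurve`.
#' @export
make_calibration_curve <- function(kind = c("identity", "linear", "piecewise"),
                                   slope = 1, intercept = 0, n_segments = 6,
                                   slope_range = c(0.75, 1.35), error = 0,
                                   seed = 1, cal_max = 7000, step = 5) {
  kind <- match.arg(kind)
  if (error < 0) stop("curve error must be non-negative")
  cal <- seq(0, cal_max, by = step)
  c14 <- switch(kind,
    identity = cal,
    linear = {
      if (slope <= 0) stop("non-monotone curve: slope must be positive")
      intercept + slope * cal
    },
    piecewise = {
      if (any(slope_range <= 0)) stop("non-monotone curve: slopes must be positive")
      with_seed(seed, {
        sl <- stats::runif(n_segments, slope_range[1], slope_range[2])
        seg <- pmin(floor(cal / (cal_max / n_segments)) + 1L, n_segments)
        intercept + cumsum(c(0, sl[seg[-1]] * diff(cal)))
      })
    })
  as_calcurve(cal, c14, rep(error, length(cal)))
}

#' Make a synthetic modern climate grid
#'
#' Generates `n_cells` grid cells of monthly climate: temperatures follow a
#' sinusoidal seasonal cycle (peak in July) around a cell mean that varies
#' along a cross-cell gradient; precipitation is winter-weighted with a
#' cell-varying annual total (clamped non-negative); cloud cover tracks the
#' precipitation seasonality (clamped to [0, 100]). With all gradients and
#' noise at zero, every cell is identical.
#'
#' @param n_cells Number of grid cells (>= 8).
#' @param seed Integer seed.
#' @param t_gradient Cross-cell range of mean temperature, deg C.
#' @param p_gradient Cross-cell range of annual precipitation, mm.
#' @param amp_gradient Cross-cell range of seasonal temperature amplitude.
#' @param cloud_gradient Cross-cell range of cloud offset, percent.
#' @param noise_sd Per-cell-month Gaussian noise sd (deg C for temperature;
#'   scaled for precipitation and cloud).
#' @return Matrix `n_cells` x 36 (columns [climate_var_names()]), with
#'   attributes `site` (index of the cell nearest the gradient centre) and
#'   `coords`.
#' @export
make_modern_climate_grid <- function(n_cells, seed = 1, t_gradient = 4,
                                     p_gradient = 250, amp_gradient = 1.5,
                                     cloud_gradient = 8, noise_sd = 0.4) {
  if (n_cells < 8) stop("need at least 8 grid cells")
  w <- c(0.18, 0.15, 0.11, 0.07, 0.03, 0.01, 0, 0, 0.02, 0.08, 0.15, 0.20)
  m <- 1:12
  season <- cos(2 * pi * (m - 7) / 12)
  with_seed(seed, {
    x <- seq(-1, 1, length.out = n_cells)
    y <- stats::runif(n_cells, -1, 1)
    grid <- matrix(NA_real_, n_cells, 36,
                   dimnames = list(paste0("cell", seq_len(n_cells)),
                                   climate_var_names()))
    for (i in seq_len(n_cells)) {
      tmean <- 19 - t_gradient * x[i]
      amp <- 7 + amp_gradient * y[i]
      pann <- 600 + p_gradient * x[i] + 0.3 * p_gradient * y[i]
      temp <- tmean + amp * season + stats::rnorm(12, 0, noise_sd)
      pre <- pmax(0, pann * w + stats::rnorm(12, 0, 6 * noise_sd))
      cld <- clamp(25 + 200 * w + cloud_gradient * y[i] +
                     stats::rnorm(12, 0, 4 * noise_sd), 0, 100)
      grid[i, ] <- c(temp, pre, cld)
    }
    attr(grid, "coords") <- cbind(x = x, y = y)
    attr(grid, "site") <- which.min(abs(x))
    grid
  })
}

# split plant-functional-group mass onto taxa using flora weights
group_mass_to_taxa <- function(pft_mass) {
  fl <- synthetic_flora()
  terr <- fl[fl$ecological_class == "terrestrial", ]
  p <- numeric(nrow(terr))
  for (g in unique(terr$pft_group)) {
    sel <- terr$pft_group == g
    if (g %in% names(pft_mass)) {
      p[sel] <- pft_mass[[g]] * terr$weight[sel] / sum(terr$weight[sel])
    }
  }
  stats::setNames(p / sum(p), terr$taxon)
}

smooth_series <- function(n, half_window = 4) {
  z <- stats::rnorm(n + 2 * half_window)
  s <- stats::filter(z, rep(1, 2 * half_window + 1) / (2 * half_window + 1))
  s <- as.numeric(s)[(half_window + 1):(half_window + n)]
  (s - mean(s)) / stats::sd(s)
}

#' Generate the ground-truth record for a synthetic core
#'
#' Builds everything a synthetic core needs with known truth: a monotone
#' calendar age sequence and depths, a smooth climate trajectory expressed
#' as four principal-component scores of a synthetic modern climate grid, the
#' implied plant-functional-group profiles (through the forward model), the
#' per-taxon sampling probabilities and the 9-ecosystem mixture per sample.
#' With `mixture_mode = "free"` the 9 ecosystem mixtures are instead nine
#' independent smooth trajectories (softmax-combined), which makes the
#' clustering stage's generating partition sharply identifiable.
#'
#' @param n_samples Number of core samples (>= 2).
#' @param seed Master seed; sub-generators use [derive_seed()] offsets.
#' @param mixture_mode `"climate"` (default) or `"free"`.
#' @param grid_cells Cells in the synthetic modern climate grid.
#' @param age_max Basal age, cal yr BP.
#' @param depth_max Basal depth, cm.
#' @param theta_sd Marginal scale of the true PC-score trajectories.
#' @return A `truth_record` list: `ages`, `depths`, `theta`, `climate`,
#'   `pft`, `taxon_prob`, `mixture`, `basis`, `curve`, `co2`, `seeds`.
#' @export
make_truth <- function(n_samples = 70, seed = 1,
                       mixture_mode = c("climate", "free"),
                       grid_cells = 48, age_max = 6000, depth_max = 215,
                       theta_sd = 0.9) {
  mixture_mode <- match.arg(mixture_mode)
  stopifnot(n_samples >= 2)
  seeds <- c(curve = derive_seed(seed, 1), grid = derive_seed(seed, 2),
             traj = derive_seed(seed, 3), counts = derive_seed(seed, 4),
             dates = derive_seed(seed, 5))
  curve <- make_calibration_curve("piecewise", seed = seeds[["curve"]],
                                  error = 8)
  grid <- make_modern_climate_grid(grid_cells, seed = seeds[["grid"]])
  basis <- build_climate_pc_basis(grid)
  ages <- seq(0, age_max, length.out = n_samples)
  depths <- depth_max * (ages / age_max)^0.95
  co2 <- co2_at_age(ages)

  fl <- synthetic_flora()
  terr <- fl[fl$ecological_class == "terrestrial", ]
  eco <- unique(terr$ecosystem)

  with_seed(seeds[["traj"]], {
    if (mixture_mode == "climate") {
      theta <- sapply(1:4, function(k) theta_sd * smooth_series(n_samples))
      climate <- theta_to_climate(theta, basis)
      pft <- t(sapply(seq_len(n_samples), function(i) {
        forward_model(climate[i, ], co2 = co2[i])
      }))
      taxon_prob <- t(apply(pft, 1, group_mass_to_taxa))
    } else {
      theta <- NULL; climate <- NULL; pft <- NULL
      raw <- sapply(eco, function(e) exp(1.6 * smooth_series(n_samples)))
      mix <- sweep(raw, 1, rowSums(raw), "/")
      taxon_prob <- matrix(0, n_samples, nrow(terr),
                           dimnames = list(NULL, terr$taxon))
      for (j in seq_len(nrow(terr))) {
        taxon_prob[, j] <- mix[, terr$ecosystem[j]] * terr$weight[j]
      }
    }
    mixture <- sapply(eco, function(e) {
      rowSums(taxon_prob[, terr$taxon[terr$ecosystem == e], drop = FALSE])
    })
    structure(list(n = n_samples, ages = ages, depths = depths,
                   theta = theta, climate = climate, pft = pft,
                   taxon_prob = taxon_prob, mixture = mixture,
                   basis = basis, curve = curve, co2 = co2,
                   seed = seed, seeds = seeds),
              class = "truth_record")
  })
}

#' Simulate a dated pollen core from a truth record
#'
#' Draws per-sample multinomial pollen counts from the taxon probabilities
#' implied by the true ecosystem mixtures (optionally diluted by a fixed
#' fraction of non-terrestrial palynomorphs), and produces dated horizons by
#' pushing true ages through the synthetic calibration curve and adding
#' Gaussian lab error.
#'
#' @param truth A `truth_record` from [make_truth()].
#' @param counts_per_sample Pollen count total per sample (>= 100).
#' @param seed Integer seed.
#' @param n_dates Number of dated horizons.
#' @param lab_error 1-sigma lab error on synthetic 14C ages, 14C yr.
#' @param nonterrestrial_fraction Fraction of each count allotted to
#'   hygrophyte/cryptogam/micro-charcoal/dinocyst classes (0 for a purely
#'   terrestrial core).
#' @return List with `counts` (samples x taxa integer matrix), `depths`,
#'   `dated_horizons` (lab_code, depth_cm, c14_age, c14_error), `meta`
#'   (taxon metadata), class `synthetic_core`.
#' @export
simulate_core <- function(truth, counts_per_sample = 500, seed = 1,
                          n_dates = 5, lab_error = 30,
                          nonterrestrial_fraction = 0.15) {
  stopifnot(inherits(truth, "truth_record"), counts_per_sample >= 100,
            truth$n >= 2)
  if (any(truth$mixture < 0) ||
      any(abs(rowSums(truth$mixture) - 1) > 1e-8)) {
    stop("ecosystem mixtures must be non-negative and sum to 1 per sample")
  }
  fl <- synthetic_flora()
  f <- nonterrestrial_fraction
  stopifnot(f >= 0, f < 1)
  # fixed split of the non-terrestrial fraction over classes
  class_share <- c(hygro_hydrophyte = 0.75, cryptogam_spore = 0.20,
                   microcharcoal = 0.04, dinocyst = 0.01)
  nonterr <- fl[fl$ecological_class != "terrestrial", ]
  p_non <- f * class_share[nonterr$ecological_class] * nonterr$weight /
    stats::ave(nonterr$weight, nonterr$ecological_class, FUN = sum)
  taxa <- c(colnames(truth$taxon_prob), nonterr$taxon)
  with_seed(seed, {
    counts <- t(sapply(seq_len(truth$n), function(i) {
      p <- c((1 - f) * truth$taxon_prob[i, ], p_non)
      stats::rmultinom(1, counts_per_sample, p)[, 1]
    }))
    dimnames(counts) <- list(sprintf("S%03d", seq_len(truth$n)), taxa)
    di <- unique(round(seq(2, truth$n, length.out = n_dates)))
    mu <- stats::approx(truth$curve$cal_bp, truth$curve$c14_bp,
                        xout = truth$ages[di])$y
    horizons <- data.frame(
      lab_code = sprintf("SYN-%03d", seq_along(di)),
      depth_cm = truth$depths[di],
      c14_age = round(mu + stats::rnorm(length(di), 0, lab_error)),
      c14_error = lab_error)
    structure(list(counts = counts, depths = truth$depths,
                   dated_horizons = horizons,
                   meta = fl[match(taxa, fl$taxon), ], seed = seed),
              class = "synthetic_core")
  })
}

#' Write all synthetic pipeline inputs to a directory
#'
#' Emits the five input files downstream stages read: pollen counts TSV
#' (depth column + taxa), taxon metadata TSV, dated horizons TSV,
#' IntCal-style calibration curve, and the modern climate grid TSV.
#'
#' @param core A `synthetic_core`.
#' @param truth The `truth_record` it came from.
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_synth_inputs <- function(core, truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta_hdr <- c(seed = truth$seed, generator = "pollenclim-synth")
  paths <- c(
    counts = file.path(dir, "pollen_counts.tsv"),
    taxa = file.path(dir, "taxon_meta.tsv"),
    dates = file.path(dir, "dated_horizons.tsv"),
    curve = file.path(dir, "calibration_curve.txt"),
    grid = file.path(dir, "climate_grid.tsv"))
  write_tsv_meta(data.frame(sample = rownames(core$counts),
                            depth_cm = core$depths, core$counts,
                            check.names = FALSE),
                 paths["counts"], meta_hdr)
  write_tsv_meta(core$meta, paths["taxa"], meta_hdr)
  write_tsv_meta(core$dated_horizons, paths["dates"], meta_hdr)
  write_calcurve(truth$curve, paths["curve"], meta_hdr)
  grid <- truth$basis$grid
  write_tsv_meta(data.frame(cell = rownames(grid), grid, check.names = FALSE),
                 paths["grid"], c(meta_hdr, site = truth$basis$site))
  invisible(paths)
}
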