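# Bayesian climate reconstruction by inversion of the vegetation forward
# model. The 36 monthly climate variables are parameterized by the scores of
# the first four principal components of a modern climate grid; a
# random-walk Metropolis sampler explores the posterior of those four scores
# given an observed 13-group pollen spectrum, with a standard Gaussian prior
# on the (modern-variability-scaled) scores and an isotropic Gaussian
# observation model on group proportions.

#' Principal-component basis of a modern climate grid
#'
#' PCA (mean-centred; optionally per-block standardized so degrees Celsius,
#' millimetres and percent are put on comparable footing) of the
#' cells x 36 modern climate matrix; the first `n_pc` components are kept.
#' The prior scale of each retained component is the standard deviation of
#' its modern scores, so a unit prior score spans modern spatial
#' variability.
#'
#' @param grid Matrix cells x 36 (see [make_modern_climate_grid()]).
#' @param site Row index of the target site cell; defaults to the grid's
#'   `site` attribute or 1.
#' @param n_pc Number of components retained (default 4).
#' @param block_scale Standardize each 12-column block by its pooled sd
#'   before the PCA (default FALSE: covariance on raw units).
#' @return A `climate_basis`: `baseline` (site climate), `rotation`
#'   (36 x n_pc, orthonormal columns), `scales` (modern score sds),
#'   `block_sc`, `center`, `site`, `grid`.
#' @export
build_climate_pc_basis <- function(grid, site = NULL, n_pc = 4,
                                   block_scale = FALSE) {
  stopifnot(is.matrix(grid), ncol(grid) == 36, nrow(grid) >= 8)
  if (is.null(site)) site <- attr(grid, "site") %||% 1L
  block_sc <- rep(1, 36)
  if (block_scale) {
    for (b in 0:2) {
      cols <- b * 12 + 1:12
      block_sc[cols] <- stats::sd(as.vector(grid[, cols]))
    }
  }
  g <- sweep(grid, 2, block_sc, "/")
  pc <- stats::prcomp(g, center = TRUE, scale. = FALSE)
  if (sum(pc$sdev > 1e-9 * pc$sdev[1]) < n_pc) {
    stop(sprintf("climate grid has rank < %d", n_pc))
  }
  structure(list(baseline = grid[site, ], rotation = pc$rotation[, 1:n_pc],
                 scales = pc$sdev[1:n_pc], block_sc = block_sc,
                 center = pc$center, site = site, grid = grid),
            class = "climate_basis")
}

#' Map principal-component scores to monthly climate
#'
#' climate = baseline + sum_k theta_k * scale_k * pc_vector_k (undoing any
#' per-block standardization), then monthly precipitation is clamped at 0
#' and cloud cover to [0, 100].
#'
#' @param theta Numeric vector of length `n_pc`, or a draws x n_pc matrix.
#' @param basis A `climate_basis`.
#' @return A 36-vector (or draws x 36 matrix) of monthly climate.
#' @export
theta_to_climate <- function(theta, basis) {
  A <- sweep(basis$rotation, 2, basis$scales, "*") * basis$block_sc
  one <- is.null(dim(theta))
  th <- if (one) matrix(theta, 1) else as.matrix(theta)
  cl <- sweep(th %*% t(A), 2, basis$baseline, "+")
  cl[, 13:24][cl[, 13:24] < 0] <- 0
  cl[, 25:36] <- clamp(cl[, 25:36], 0, 100)
  colnames(cl) <- climate_var_names()
  if (one) cl[1, ] else cl
}

#' Log-posterior of PC scores given an observed group spectrum
#'
#' Standard Gaussian prior on the scores plus an isotropic Gaussian
#' likelihood on the 13 group proportions:
#' log N(theta; 0, I) + sum_g log N(obs_g - pred_g; 0, sigma_obs^2), with
#' pred = forward_model(theta_to_climate(theta)). Non-finite forward output
#' yields -Inf (a rejected state).
#'
#' @param theta PC-score vector.
#' @param observed Observed 13-group proportion vector.
#' @param basis A `climate_basis`.
#' @param sigma_obs Observation sd on proportions (> 0).
#' @param co2 CO2, ppm.
#' @param distort Optional function climate -> climate applied before the
#'   forward model (used to study model distortions; default identity).
#' @return Log posterior density (unnormalized).
#' @export
pollen_log_posterior <- function(theta, observed, basis, sigma_obs,
                                 co2 = 280, distort = NULL) {
  stopifnot(sigma_obs > 0)
  cl <- theta_to_climate(theta, basis)
  if (!is.null(distort)) cl <- distort(cl)
  pred <- forward_model(cl, co2 = co2)
  if (any(!is.finite(pred))) return(-Inf)
  sum(stats::dnorm(theta, log = TRUE)) +
    sum(stats::dnorm(observed - pred, 0, sigma_obs, log = TRUE))
}

#' Random-walk Metropolis sampler
#'
#' Gaussian-proposal Metropolis targeting an arbitrary log density. During
#' burn-in the (per-dimension) proposal scale is optionally adapted every 50
#' iterations toward an acceptance rate of ~0.3 and then frozen, preserving
#' detailed balance for the retained draws. Fully reproducible from `seed`.
#'
#' @param log_post Function(theta) -> log density.
#' @param init Initial state.
#' @param n_iter Total iterations.
#' @param burn_in Iterations discarded (default 20% of `n_iter`).
#' @param proposal_scale Initial proposal sd (scalar or per-dimension).
#' @param seed Integer seed.
#' @param adapt Adapt the proposal scale during burn-in.
#' @return An `mcmc_chain`: `draws` (post-burn-in matrix), `log_post`,
#'   `acceptance_rate` (post-burn-in), `proposal_scale` (final), `seed`.
#' @export
run_mcmc <- function(log_post, init, n_iter = 12500,
                     burn_in = floor(0.2 * n_iter), proposal_scale = 0.5,
                     seed = 1, adapt = TRUE) {
  stopifnot(n_iter > burn_in, burn_in >= 0)
  d <- length(init)
  scale <- rep_len(proposal_scale, d)
  with_seed(seed, {
    eps <- matrix(stats::rnorm(n_iter * d), n_iter, d)
    lu <- log(stats::runif(n_iter))
    cur <- init
    lp <- log_post(cur)
    if (!is.finite(lp)) stop("log_post not finite at init")
    draws <- matrix(NA_real_, n_iter, d)
    lps <- numeric(n_iter)
    acc <- logical(n_iter)
    win_acc <- 0L
    for (t in seq_len(n_iter)) {
      prop <- cur + eps[t, ] * scale
      lpp <- log_post(prop)
      if (is.finite(lpp) && lu[t] < lpp - lp) {
        cur <- prop; lp <- lpp; acc[t] <- TRUE; win_acc <- win_acc + 1L
      }
      draws[t, ] <- cur
      lps[t] <- lp
      if (adapt && t <= burn_in && t %% 50 == 0) {
        rate <- win_acc / 50
        scale <- scale * exp(clamp(rate - 0.3, -0.3, 0.3))
        win_acc <- 0L
      }
    }
    keep <- (burn_in + 1L):n_iter
    rate <- mean(acc[keep])
    if (rate < 0.02 || rate > 0.9) {
      warning(sprintf("post-burn-in acceptance rate %.3f outside (0.02, 0.9)",
                      rate))
    }
    structure(list(draws = draws[keep, , drop = FALSE], log_post = lps[keep],
                   acceptance_rate = rate, proposal_scale = scale,
                   n_iter = n_iter, burn_in = burn_in, seed = seed),
              class = "mcmc_chain")
  })
}

#' Posterior summary of derived climate variables
#'
#' Maps each retained draw to monthly climate, then to MAT, MTCO, MTWA and
#' PANN, and summarizes each with the posterior median and the equal-tailed
#' credible interval at level `ci` (default 90%).
#'
#' @param draws Post-burn-in score draws (matrix n x n_pc) or an
#'   `mcmc_chain`.
#' @param basis A `climate_basis`.
#' @param co2 CO2, ppm.
#' @param ci Credible level (default 0.90).
#' @return Data frame `variable`, `median`, `ci_lo`, `ci_hi`.
#' @export
summarize_posterior <- function(draws, basis, co2 = 280, ci = 0.90) {
  if (inherits(draws, "mcmc_chain")) draws <- draws$draws
  if (is.null(dim(draws)) || nrow(draws) == 0) stop("empty chain")
  cl <- theta_to_climate(draws, basis)
  v <- cbind(MAT = rowMeans(cl[, 1:12, drop = FALSE]),
             MTCO = apply(cl[, 1:12, drop = FALSE], 1, min),
             MTWA = apply(cl[, 1:12, drop = FALSE], 1, max),
             PANN = rowSums(cl[, 13:24, drop = FALSE]))
  a <- (1 - ci) / 2
  q <- apply(v, 2, stats::quantile, probs = c(a, 0.5, 1 - a), names = FALSE)
  data.frame(variable = colnames(v), median = q[2, ],
             ci_lo = q[1, ], ci_hi = q[3, ], row.names = NULL)
}

#' Reconstruct climate from one pollen group spectrum
#'
#' The package's central fitting function: runs the Metropolis sampler on
#' [pollen_log_posterior()] for one observed 13-group spectrum and returns a
#' fitted `climate_inversion` object with posterior summaries of MAT, MTCO,
#' MTWA and PANN.
#'
#' @param observed Observed 13-group proportion vector (e.g. a row of
#'   [group_spectra()]).
#' @param basis A `climate_basis`.
#' @param sigma_obs Observation sd on group proportions.
#' @param co2 CO2, ppm, for this sample's epoch (see [co2_at_age()]).
#' @param n_iter,burn_in,proposal_scale,seed,adapt Passed to [run_mcmc()].
#' @param ci Credible level for summaries.
#' @param distort Optional climate distortion (see
#'   [pollen_log_posterior()]).
#' @return A `climate_inversion` with components `chain`, `summary`,
#'   `observed`, `acceptance_rate`; methods: `print`, `summary`, `coef`,
#'   `predict`, `residuals`, `plot`.
#' @export
invert_climate <- function(observed, basis, sigma_obs = 0.05, co2 = 280,
                           n_iter = 12500, burn_in = floor(0.2 * n_iter),
                           proposal_scale = 0.5, seed = 1, adapt = TRUE,
                           ci = 0.90, distort = NULL) {
  stopifnot(inherits(basis, "climate_basis"),
            length(observed) == nrow(pft_params()))
  lp <- function(theta) {
    pollen_log_posterior(theta, observed, basis, sigma_obs, co2, distort)
  }
  chain <- run_mcmc(lp, init = rep(0, ncol(basis$rotation)), n_iter = n_iter,
                    burn_in = burn_in, proposal_scale = proposal_scale,
                    seed = seed, adapt = adapt)
  structure(list(chain = chain,
                 summary = summarize_posterior(chain, basis, co2, ci),
                 observed = observed, basis = basis, sigma_obs = sigma_obs,
                 co2 = co2, ci = ci, distort = distort,
                 acceptance_rate = chain$acceptance_rate,
                 call = match.call()),
            class = "climate_inversion")
}

#' @export
print.climate_inversion <- function(x, ...) {
  cat(sprintf("Climate inversion: %d retained draws, acceptance %.2f\n",
              nrow(x$chain$draws), x$acceptance_rate))
  s <- x$summary
  cat(sprintf("%d%% credible intervals:\n", round(x$ci * 100)))
  print(transform(s, median = round(median, 1), ci_lo = round(ci_lo, 1),
                  ci_hi = round(ci_hi, 1)), row.names = FALSE)
  invisible(x)
}

#' @export
summary.climate_inversion <- function(object, ...) object$summary

#' @export
coef.climate_inversion <- function(object, ...) {
  apply(object$chain$draws, 2, stats::median)
}

#' Forward prediction at the posterior median scores
#' @param object A `climate_inversion`.
#' @param ... Ignored.
#' @return Predicted 13-group profile.
#' @export
predict.climate_inversion <- function(object, ...) {
  cl <- theta_to_climate(coef(object), object$basis)
  if (!is.null(object$distort)) cl <- object$distort(cl)
  forward_model(cl, co2 = object$co2)
}

#' @export
residuals.climate_inversion <- function(object, ...) {
  object$observed - predict(object)
}

#' @export
plot.climate_inversion <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (k in seq_len(ncol(x$chain$draws))) {
    plot(x$chain$draws[, k], type = "l", xlab = "iteration",
         ylab = sprintf("PC%d score", k), ...)
  }
  invisible(x)
}

#' Verify against modern spectra and estimate bias corrections
#'
#' Runs the inversion for each modern surface spectrum with co-located
#' observed climate, computes per-variable bias
#' (mean reconstructed - observed) and RMSE, and returns bias-corrected
#' reconstructions (reconstruction minus bias).
#'
#' @param modern_spectra Matrix n x 13 of modern group proportions (n >= 2).
#' @param observed_climate Data frame/matrix n x 4 with columns MAT, MTCO,
#'   MTWA, PANN of observed modern climate at the spectra's sites.
#' @param basis A `climate_basis`.
#' @param ... Passed to [invert_climate()] (sigma_obs, n_iter, seed, ...).
#' @return A `bias_table`: `table` (variable, rmse, bias),
#'   `reconstructed`, `corrected`, `residuals` (all n x 4).
#' @export
verify_and_bias_correct <- function(modern_spectra, observed_climate, basis,
                                    ...) {
  modern_spectra <- as.matrix(modern_spectra)
  if (nrow(modern_spectra) < 2) stop("need at least 2 modern spectra")
  obs <- as.matrix(as.data.frame(observed_climate)[, c("MAT", "MTCO",
                                                       "MTWA", "PANN")])
  stopifnot(nrow(obs) == nrow(modern_spectra))
  dots <- list(...)
  seed0 <- dots$seed %||% 1
  dots$seed <- NULL
  rec <- t(vapply(seq_len(nrow(modern_spectra)), function(i) {
    fit <- do.call(invert_climate,
                   c(list(observed = modern_spectra[i, ], basis = basis,
                          seed = derive_seed(seed0, 100 + i)), dots))
    stats::setNames(fit$summary$median, fit$summary$variable)
  }, numeric(4)))
  res <- rec - obs
  bias <- colMeans(res)
  rmse <- sqrt(colMeans(res^2))
  corrected <- sweep(rec, 2, bias, "-")
  structure(list(table = data.frame(variable = colnames(obs), rmse = rmse,
                                    bias = bias, row.names = NULL),
                 reconstructed = rec, corrected = corrected,
                 residuals = res),
            class = "bias_table")
}

#' @export
print.bias_table <- function(x, ...) {
  cat(sprintf("Modern-spectra verification (n = %d):\n", nrow(x$reconstructed)))
  print(transform(x$table, rmse = signif(rmse, 3), bias = signif(bias, 3)),
        row.names = FALSE)
  invisible(x)
}

#' Anchor down-core reconstructions to observed modern climate
#'
#' Expresses each down-core posterior summary as an anomaly from the
#' top-core (modern) reconstruction and adds the observed modern climate:
#' adjusted_v(t) = downcore_v(t) - topcore_median_v + modern_obs_v, applied
#' to the median and both credible bounds.
#'
#' @param downcore Long data frame of down-core summaries: columns `sample`,
#'   `variable`, `median`, `ci_lo`, `ci_hi` (stack of
#'   [summarize_posterior()] outputs).
#' @param topcore A single posterior summary (data frame `variable`,
#'   `median`, ...) for the top-core sample from the same configuration.
#' @param modern_obs Named vector of observed modern climate (MAT, MTCO,
#'   MTWA, PANN).
#' @return `downcore` with adjusted `median`, `ci_lo`, `ci_hi`.
#' @export
anomaly_adjust <- function(downcore, topcore, modern_obs) {
  vars <- unique(downcore$variable)
  if (!setequal(vars, topcore$variable) || !all(vars %in% names(modern_obs))) {
    stop("variable mismatch between down-core, top-core and modern climate")
  }
  off <- stats::setNames(modern_obs[topcore$variable] - topcore$median,
                         topcore$variable)
  for (col in c("median", "ci_lo", "ci_hi")) {
    downcore[[col]] <- downcore[[col]] + off[downcore$variable]
  }
  downcore
}
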