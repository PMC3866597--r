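basis_fixture <- function(seed = 3, cells = 48) {
  build_climate_pc_basis(make_modern_climate_grid(cells, seed = seed))
}

test_that("the climate PC basis is orthonormal and rank-checked", {
  b <- basis_fixture()
  expect_equal(crossprod(b$rotation), diag(4), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(all(b$scales > 0))

  # gradient-only grid: the leading component carries almost all variance
  g1 <- make_modern_climate_grid(16, seed = 2, amp_gradient = 0,
                                 cloud_gradient = 0, noise_sd = 0.01)
  pc <- stats::prcomp(g1)
  expect_gt(pc$sdev[1]^2 / sum(pc$sdev^2), 0.99)

  flat <- make_modern_climate_grid(10, seed = 1, t_gradient = 0,
                                   p_gradient = 0, amp_gradient = 0,
                                   cloud_gradient = 0, noise_sd = 0)
  expect_error(build_climate_pc_basis(flat), "rank")
})

test_that("the leading principal subspace beats random 4-dim bases", {
  b <- basis_fixture()
  g <- b$grid
  centered <- scale(g, center = TRUE, scale = FALSE)
  proj_resid <- function(V) {
    P <- V %*% solve(crossprod(V), t(V))
    sum((centered - centered %*% P)^2)
  }
  pc_resid <- proj_resid(b$rotation)
  with_seed(17, {
    for (trial in 1:100) {
      V <- qr.Q(qr(matrix(stats::rnorm(36 * 4), 36, 4)))
      expect_lte(pc_resid, proj_resid(V) + 1e-8)
    }
  })
})

test_that("theta maps to climate linearly with physical clamps", {
  b <- basis_fixture()
  expect_equal(theta_to_climate(rep(0, 4), b), b$baseline)

  th <- c(1, 0, 0, 0)
  manual <- b$baseline + b$scales[1] * b$rotation[, 1]
  manual[13:24] <- pmax(manual[13:24], 0)
  manual[25:36] <- pmin(pmax(manual[25:36], 0), 100)
  expect_equal(theta_to_climate(th, b), manual, tolerance = 1e-12)

  # drive one month's precipitation negative by solving the linear map
  m <- which.max(abs(b$rotation[13:24, 1])) + 12
  t_need <- -(b$baseline[m] / (b$scales[1] * b$rotation[m, 1])) * 1.5
  cl <- theta_to_climate(c(t_need, 0, 0, 0), b)
  expect_equal(unname(cl[m]), 0)
  expect_true(all(cl[13:24] >= 0))
})

test_that("log posterior has the exact Gaussian structure", {
  b <- basis_fixture()
  th <- c(0.3, -0.2, 0.1, 0)
  obs <- forward_model(theta_to_climate(th, b), co2 = 280)
  s <- 0.04
  lp <- pollen_log_posterior(th, obs, b, sigma_obs = s, co2 = 280)
  prior <- sum(stats::dnorm(th, log = TRUE))
  expect_equal(lp - prior, 13 * log(1 / (sqrt(2 * pi) * s)),
               tolerance = 1e-9)

  # doubling sigma at fixed residuals follows the closed-form rescaling
  obs2 <- obs + 0.02
  l1 <- pollen_log_posterior(th, obs2, b, sigma_obs = s)
  l2 <- pollen_log_posterior(th, obs2, b, sigma_obs = 2 * s)
  resid_ss <- sum((obs2 - obs)^2)
  expect_equal(l2 - l1,
               -13 * log(2) + resid_ss / 2 * (1 / s^2 - 1 / (2 * s)^2),
               tolerance = 1e-9)
})

test_that("the sampler reproduces a standard Gaussian target", {
  ch <- run_mcmc(function(x) stats::dnorm(x, log = TRUE), init = 0,
                 n_iter = 62500, burn_in = 12500, seed = 19)
  x <- as.vector(ch$draws)
  expect_lt(abs(mean(x)), 0.05)
  expect_lt(abs(stats::var(x) - 1), 0.1)
  expect_true(ch$acceptance_rate > 0.02 && ch$acceptance_rate < 0.9)
})

test_that("the sampler matches the conjugate Gaussian posterior", {
  # identity forward model, prior N(0,1), observation y = 2, sigma = 1:
  # the posterior is N(1, 1/2) by conjugate algebra
  lp <- function(th) {
    stats::dnorm(th, log = TRUE) + stats::dnorm(2 - th, 0, 1, log = TRUE)
  }
  ch <- run_mcmc(lp, init = 0, n_iter = 62500, burn_in = 12500, seed = 11)
  x <- as.vector(ch$draws)
  expect_true(mean(x) > 0.95 && mean(x) < 1.05)
  expect_true(stats::var(x) > 0.45 && stats::var(x) < 0.55)

  ch2 <- run_mcmc(lp, init = 0, n_iter = 62500, burn_in = 12500, seed = 11)
  expect_identical(ch$draws, ch2$draws)
})

test_that("posterior summaries use equal-tailed intervals around the median", {
  b <- basis_fixture()
  const <- matrix(rep(c(0.4, -0.1, 0, 0.2), each = 50), 50, 4)
  s <- summarize_posterior(const, b)
  expect_equal(s$ci_lo, s$median)
  expect_equal(s$ci_hi, s$median)

  with_seed(23, draws <- matrix(stats::rnorm(4000), 1000, 4))
  s2 <- summarize_posterior(draws, b)
  expect_true(all(s2$ci_lo <= s2$median & s2$median <= s2$ci_hi))

  # 1-D harness: interval ends bracketed by adjacent order statistics
  cl <- theta_to_climate(draws, b)
  pann <- rowSums(cl[, 13:24])
  srt <- sort(pann)
  lo_bracket <- srt[c(floor(0.05 * 999) + 1, ceiling(0.05 * 999) + 1)]
  hi_bracket <- srt[c(floor(0.95 * 999) + 1, ceiling(0.95 * 999) + 1)]
  p <- s2[s2$variable == "PANN", ]
  expect_gte(p$ci_lo, lo_bracket[1] - 1e-9)
  expect_lte(p$ci_lo, lo_bracket[2] + 1e-9)
  expect_gte(p$ci_hi, hi_bracket[1] - 1e-9)
  expect_lte(p$ci_hi, hi_bracket[2] + 1e-9)

  expect_error(summarize_posterior(matrix(0, 0, 4), b), "empty")
})

test_that("a full inversion recovers known climates", {
  b <- basis_fixture()
  with_seed(41, ths <- matrix(stats::rnorm(12, sd = 0.8), 3, 4))
  for (i in 1:3) {
    clim <- theta_to_climate(ths[i, ], b)
    y <- forward_model(clim, co2 = 280)
    fit <- invert_climate(y, b, sigma_obs = 0.04, n_iter = 4000,
                          seed = 50 + i, ci = 0.99)
    truth <- bioclim(clim)
    s <- fit$summary
    for (v in c("MAT", "PANN")) {
      tv <- if (v == "MAT") truth$mat else truth$pann
      row <- s[s$variable == v, ]
      expect_true(row$ci_lo <= tv && tv <= row$ci_hi)
    }
    expect_equal(length(predict(fit)), 13)
    expect_equal(residuals(fit), y - predict(fit))
  }
})

test_that("posterior width shrinks as observation noise decreases", {
  b <- basis_fixture()
  y <- forward_model(theta_to_climate(c(0.5, -0.4, 0.2, 0), b), co2 = 280)
  width <- function(sig) {
    s <- invert_climate(y, b, sigma_obs = sig, n_iter = 4000,
                        seed = 77)$summary
    mean(s$ci_hi - s$ci_lo)
  }
  expect_lt(width(0.02), width(0.08))
})

test_that("bias estimation and correction follow their definitions", {
  b <- basis_fixture(seed = 8, cells = 16)
  g <- b$grid
  idx <- 1:4
  spectra <- t(sapply(idx, function(i) forward_model(g[i, ], co2 = 280)))
  obs <- t(sapply(idx, function(i) {
    bb <- bioclim(g[i, ])
    c(MAT = bb$mat, MTCO = bb$mtco, MTWA = bb$mtwa, PANN = bb$pann)
  }))
  bt <- verify_and_bias_correct(spectra, obs, b, sigma_obs = 0.05,
                                n_iter = 1500, seed = 5)
  expect_equal(unname(colMeans(bt$corrected - obs)), rep(0, 4),
               tolerance = 1e-9)
  expect_true(all(bt$table$rmse >= 0))
  expect_equal(bt$table$bias, unname(colMeans(bt$residuals)))
  expect_error(verify_and_bias_correct(spectra[1, , drop = FALSE],
                                       obs[1, , drop = FALSE], b),
               "at least 2")
})

test_that("anomaly adjustment anchors series to modern climate", {
  top <- data.frame(variable = c("MAT", "MTCO", "MTWA", "PANN"),
                    median = c(18, 11, 26, 620),
                    ci_lo = c(17, 10, 25, 580), ci_hi = c(19, 12, 27, 660))
  down <- do.call(rbind, lapply(1:3, function(i) {
    transform(top, sample = paste0("S", i))
  }))
  modern <- c(MAT = 19.5, MTCO = 12.5, MTWA = 27, PANN = 600)
  adj <- anomaly_adjust(down, top, modern)
  expect_equal(adj$median, rep(unname(modern), 3))

  adj2 <- anomaly_adjust(down, top, modern + 5)
  expect_equal(adj2$median, adj$median + 5)
  expect_equal(adj2$ci_lo - adj$ci_lo, rep(5, 12))

  expect_error(anomaly_adjust(down, top[1:3, ], modern), "mismatch")
})
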