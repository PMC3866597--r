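test_that("Spearman similarity handles monotone, antitone and tied series", {
  a <- c(1, 3, 7, 20, 21)
  x <- cbind(A = a, B = 2 * a, C = rev(a))
  s <- spearman_similarity(x)
  expect_equal(s["A", "B"], 1)
  expect_equal(s["A", "C"], -1)
  expect_true(isSymmetric(s))
  expect_equal(diag(s), c(A = 1, B = 1, C = 1))

  # midrank oracle: rank with ties.method = "average", then Pearson by hand
  u <- c(1, 2, 2, 4); v <- c(3, 1, 1, 2)
  ru <- c(1, 2.5, 2.5, 4); rv <- c(4, 1.5, 1.5, 3)
  oracle <- sum((ru - mean(ru)) * (rv - mean(rv))) /
    sqrt(sum((ru - mean(ru))^2) * sum((rv - mean(rv))^2))
  s2 <- spearman_similarity(cbind(U = u, V = v))
  expect_equal(s2["U", "V"], oracle, tolerance = 1e-12)

  expect_warning(s3 <- spearman_similarity(cbind(A = a, K = rep(2, 5))),
                 "constant")
  expect_equal(s3["A", "K"], 0)
  expect_equal(s3["K", "K"], 1)
})

test_that("UPGMA merges forced cases correctly", {
  d <- matrix(c(0, 0.1, 0.8,
                0.1, 0, 0.8,
                0.8, 0.8, 0), 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  tr <- upgma(d, is_distance = TRUE)
  expect_equal(tr$height, c(0.1, 0.8))
  expect_equal(merge_leaf_sets(tr), list(c(1, 2), c(1, 2, 3)))

  dup <- matrix(c(0, 0, 0.5, 0, 0, 0.5, 0.5, 0.5, 0), 3,
                dimnames = list(letters[1:3], letters[1:3]))
  tr2 <- upgma(dup, is_distance = TRUE)
  expect_equal(tr2$height[1], 0)

  expect_error(upgma(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("UPGMA equals the naive oracle and hclust on random instances", {
  with_seed(71, {
    for (rep in 1:40) {
      n <- sample(5:10, 1)
      d <- random_distance_matrix(n)
      tr <- upgma(d, is_distance = TRUE)
      or <- naive_upgma(d)
      expect_equal(tr$height, or$heights, tolerance = 1e-12)
      expect_equal(merge_leaf_sets(tr), or$merges)
      # independent reference implementation
      hc <- stats::hclust(stats::as.dist(d), method = "average")
      expect_equal(tr$height, hc$height, tolerance = 1e-12)
      expect_equal(as.vector(stats::cophenetic(tr)),
                   as.vector(stats::cophenetic(hc)), tolerance = 1e-12)
    }
  })
})

test_that("UPGMA merge heights are non-decreasing and ties break by label", {
  with_seed(5, {
    for (rep in 1:20) {
      d <- random_distance_matrix(7)
      expect_true(all(diff(upgma(d, is_distance = TRUE)$height) >= -1e-12))
    }
  })
  # three equidistant leaves: the (1,2) pair must merge first
  eq <- matrix(0.4, 3, 3); diag(eq) <- 0
  dimnames(eq) <- list(c("t1", "t2", "t3"), c("t1", "t2", "t3"))
  tr <- upgma(eq, is_distance = TRUE)
  expect_equal(merge_leaf_sets(tr)[[1]], c(1, 2))
})

test_that("cutting the tree yields the requested number of ecosystems", {
  with_seed(9, d <- random_distance_matrix(8))
  dimnames(d) <- list(paste0("tx", 1:8), paste0("tx", 1:8))
  tr <- upgma(d, is_distance = TRUE)
  expect_equal(nrow(unique(cut_to_ecosystems(tr, 8)["cluster"])), 8)
  expect_equal(unique(cut_to_ecosystems(tr, 1)$cluster), 1)
  expect_error(cut_to_ecosystems(tr, 9), "cannot cut")
})

test_that("clustering recovers the generating 9-ecosystem partition", {
  truth <- make_truth(60, seed = 9, mixture_mode = "free")
  core <- simulate_core(truth, 2000, seed = 2, nonterrestrial_fraction = 0)
  pct <- pollen_percentages(core$counts, core$meta, "terrestrial")
  terr <- core$meta$taxon[core$meta$ecological_class == "terrestrial"]
  emap <- cut_to_ecosystems(upgma(spearman_similarity(pct[, terr])), k = 9)
  true_eco <- core$meta$ecosystem[match(emap$taxon, core$meta$taxon)]
  tab <- table(emap$cluster, true_eco)
  expect_true(all(rowSums(tab > 0) == 1))
  expect_true(all(colSums(tab > 0) == 1))
})

test_that("ecosystem series are additive and conserve percentages", {
  pct <- matrix(c(10, 5, 20, 30, 2, 8), 2,
                dimnames = list(NULL, c("A", "B", "C")))
  map <- data.frame(taxon = c("A", "B", "C"),
                    ecosystem = c("e1", "e1", "e2"))
  es <- ecosystem_series(pct, map)
  expect_equal(unname(es[, "e1"]), c(10 + 20, 5 + 30))
  expect_equal(unname(rowSums(es)), unname(rowSums(pct)))

  all_one <- data.frame(taxon = c("A", "B", "C"), ecosystem = "all")
  expect_equal(unname(ecosystem_series(pct, all_one)[, 1]),
               unname(rowSums(pct)))

  meta <- data.frame(taxon = c("A", "B", "C"),
                     ecological_class = "terrestrial")
  expect_warning(ecosystem_series(pct, map[1:2, ], meta = meta), "C")
})

test_that("kernel density surface integrates to the point count", {
  one <- kernel_density_2d(matrix(c(2, -1), 1), radius = 3)
  peak <- which(one$z == max(one$z), arr.ind = TRUE)
  expect_lt(abs(one$x[peak[1]] - 2), diff(one$x[1:2]))
  expect_lt(abs(one$y[peak[2]] + 1), diff(one$y[1:2]))

  with_seed(4, pts <- matrix(stats::rnorm(40, sd = 4), 20, 2))
  surf <- kernel_density_2d(pts, radius = 3)
  integral <- sum(surf$z) * diff(surf$x[1:2]) * diff(surf$y[1:2])
  expect_equal(integral, 20, tolerance = 1e-3)

  two <- kernel_density_2d(rbind(c(0, 0), c(30, 0)), radius = 1, grid_n = 256)
  mid <- two$z[findInterval(15, two$x), findInterval(0, two$y)]
  expect_lt(mid, max(two$z) / 10)  # distinct modes separated by a trough

  expect_error(kernel_density_2d(pts, radius = 0), "positive")
})

test_that("ecosystem PCA has exact spectral-decomposition structure", {
  with_seed(22, x <- matrix(stats::runif(180, 0, 30), 20, 9))
  colnames(x) <- ecosystem_names()
  ord <- pca_axis(x)
  L <- ord$loadings
  expect_equal(crossprod(L), diag(9), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(sum(ord$inertia_fraction), 1, tolerance = 1e-12)
  centered <- scale(x, center = TRUE, scale = FALSE)
  expect_equal(max(abs(ord$scores %*% t(L) - centered)), 0, tolerance = 1e-9)
  expect_gte(L["medit_open_forest", 1], 0)

  # rank-1 data: one axis carries all inertia
  g <- seq(0, 1, length.out = 12)
  r1 <- outer(g, c(3, -2, 1, 0, 0, 0, 0, 0, 1)) +
    matrix(5, 12, 9)
  colnames(r1) <- ecosystem_names()
  expect_equal(pca_axis(r1)$inertia_fraction[1], 1, tolerance = 1e-12)

  dup <- rbind(x, x[3, , drop = FALSE])
  sd2 <- pca_axis(dup)$scores
  expect_equal(unname(sd2[3, ]), unname(sd2[21, ]), tolerance = 1e-9)

  expect_error(pca_axis(matrix(1, 5, 9)), "constant")
})

test_that("PCA scores are invariant under sample reordering", {
  with_seed(14, x <- matrix(stats::runif(90, 0, 50), 10, 9))
  colnames(x) <- ecosystem_names()
  perm <- with_seed(15, sample(10))
  a <- pca_axis(x)$scores
  b <- pca_axis(x[perm, ])$scores
  expect_equal(unname(b), unname(a[perm, ]), tolerance = 1e-9)
})

test_that("axis 1 tracks a natural-versus-urban mixture gradient", {
  n <- 50
  g <- sin(seq(0, 3 * pi, length.out = n))          # the generating gradient
  nat <- c("medit_open_forest", "wet_meadow_steppe",
           "quercus_ithaburensis_forest", "fen_trees")
  urb <- c("phrygana_batha", "dry_steppe", "quercus_calliprinos_woodland",
           "shrub_steppe", "cultivated_urban")
  x <- matrix(0, n, 9, dimnames = list(NULL, c(nat, urb)))
  with_seed(33, {
    for (e in nat) x[, e] <- 12 + 9 * g + stats::rnorm(n, 0, 0.8)
    for (e in urb) x[, e] <- 12 - 9 * g + stats::rnorm(n, 0, 0.8)
  })
  ord <- pca_axis(x)
  expect_gt(abs(stats::cor(ord$scores[, 1], g)), 0.95)
  # sign convention: the natural forest pole is positive
  expect_gt(stats::cor(ord$scores[, 1], g), 0)
  expect_gt(ord$loadings["medit_open_forest", 1], 0)
})
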