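# From taxa to pollen-derived ecosystems and sample ordination:
# Spearman similarity between taxon time series, UPGMA (paired-group,
# average-linkage) clustering on d = 1 - rho, a cut into k ecosystems,
# summed ecosystem percentage series, 2-D Gaussian kernel density in the
# ordination plane, and covariance-mode PCA of the ecosystem series.

#' Spearman similarity matrix between taxon time series
#'
#' Midrank (average-rank) Spearman correlation between the columns of a
#' samples x taxa table; `mode = "presence"` first reduces the table to
#' presence/absence. Constant series have undefined rank correlation and are
#' assigned similarity 0 (uninformative) with a warning.
#'
#' @param x Numeric matrix, samples x taxa (counts or percentages).
#' @param mode `"abundance"` (default) or `"presence"`.
#' @return A symmetric taxa x taxa matrix with unit diagonal, entries in
#'   [-1, 1].
#' @export
spearman_similarity <- function(x, mode = c("abundance", "presence")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(x), nrow(x) >= 3)
  if (mode == "presence") x <- (x > 0) * 1
  rho <- suppressWarnings(stats::cor(x, method = "spearman"))
  if (anyNA(rho)) {
    warning("constant taxon series: similarity set to 0")
    rho[is.na(rho)] <- 0
  }
  diag(rho) <- 1
  rho
}

#' UPGMA (paired-group) clustering on a similarity matrix
#'
#' Agglomerative average-linkage clustering on the distance d = 1 - rho.
#' Equal-distance merges are broken deterministically by the
#' lexicographically smallest pair of original leaf indices. The result is
#' `hclust`-compatible, so [stats::cutree()], [stats::cophenetic()] and
#' `plot()` all work.
#'
#' @param sim Symmetric similarity matrix (e.g. [spearman_similarity()]),
#'   or a distance matrix if `is_distance = TRUE`.
#' @param is_distance Interpret `sim` directly as distances.
#' @return Object of class `c("upgma", "hclust")`.
#' @export
upgma <- function(sim, is_distance = FALSE) {
  stopifnot(is.matrix(sim), nrow(sim) == ncol(sim))
  if (max(abs(sim - t(sim))) > 1e-8) stop("similarity matrix must be symmetric")
  d <- if (is_distance) sim else 1 - sim
  n <- nrow(d)
  if (n < 2) stop("need at least two leaves")
  labels <- colnames(d) %||% as.character(seq_len(n))
  diag(d) <- Inf

  size <- rep(1L, n)
  code <- -seq_len(n)          # hclust coding: negative leaf, positive merge
  minleaf <- seq_len(n)        # for deterministic tie-breaking
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    idx <- which(active)
    dm <- d[idx, idx, drop = FALSE]
    hmin <- min(dm)
    # candidate pairs at the minimum; pick lexicographically smallest by
    # (smallest original leaf of first cluster, then of second)
    cand <- which(dm == hmin, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    a <- idx[cand[, 1]]; b <- idx[cand[, 2]]
    key1 <- pmin(minleaf[a], minleaf[b]); key2 <- pmax(minleaf[a], minleaf[b])
    pick <- order(key1, key2)[1]
    i <- a[pick]; j <- b[pick]

    m <- sort(c(code[i], code[j]))
    merge[step, ] <- m
    height[step] <- hmin
    # UPGMA update: size-weighted average distance to the new cluster
    others <- setdiff(idx, c(i, j))
    if (length(others)) {
      newd <- (size[i] * d[i, others] + size[j] * d[j, others]) /
        (size[i] + size[j])
      d[i, others] <- newd
      d[others, i] <- newd
    }
    size[i] <- size[i] + size[j]
    minleaf[i] <- min(minleaf[i], minleaf[j])
    code[i] <- step
    active[j] <- FALSE
  }

  leaf_order <- function(row) {
    unlist(lapply(merge[row, ], function(m) {
      if (m < 0) -m else leaf_order(m)
    }))
  }
  structure(list(merge = merge, height = height,
                 order = leaf_order(n - 1L), labels = labels,
                 method = "average",
                 dist.method = if (is_distance) "distance" else "1 - rho",
                 call = match.call()),
            class = c("upgma", "hclust"))
}

#' Cut a dendrogram into k pollen-derived ecosystems
#'
#' Cuts the tree at the lowest height yielding exactly `k` groups and
#' attaches ecosystem labels (cluster ids are ordered by first appearance
#' along the leaf sequence).
#'
#' @param tree An `upgma`/`hclust` tree over taxa.
#' @param k Number of ecosystems (default 9).
#' @param labels Optional character vector of `k` ecosystem names.
#' @return Data frame `taxon`, `cluster`, `ecosystem`.
#' @export
cut_to_ecosystems <- function(tree, k = 9, labels = NULL) {
  n <- length(tree$labels)
  if (k > n) stop(sprintf("cannot cut %d leaves into %d groups", n, k))
  cl <- stats::cutree(tree, k = k)
  first <- order(vapply(seq_len(k), function(g) which(cl == g)[1], numeric(1)))
  remap <- match(seq_len(k), first)
  cl <- remap[cl]
  if (is.null(labels)) labels <- paste0("ecosystem_", seq_len(k))
  stopifnot(length(labels) == k)
  data.frame(taxon = tree$labels, cluster = cl, ecosystem = labels[cl],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Sum taxon percentages into ecosystem series
#'
#' @param pct Percentage matrix, samples x taxa.
#' @param map Data frame `taxon`, `ecosystem` (e.g. [cut_to_ecosystems()]
#'   or the flora table).
#' @param ages Optional per-sample ages carried as an attribute.
#' @param meta Optional taxon metadata; if given, terrestrial taxa present in
#'   `pct` but missing from `map` trigger a warning listing them.
#' @return Matrix samples x ecosystems of summed percentages, attribute
#'   `ages`.
#' @export
ecosystem_series <- function(pct, map, ages = NULL, meta = NULL) {
  if (!is.null(meta)) {
    terr <- meta$taxon[meta$ecological_class == "terrestrial"]
    un <- setdiff(intersect(colnames(pct), terr), map$taxon)
    if (length(un)) {
      warning("terrestrial taxa not mapped to any ecosystem: ",
              paste(un, collapse = ", "))
    }
  }
  eco <- unique(map$ecosystem)
  out <- matrix(0, nrow(pct), length(eco),
                dimnames = list(rownames(pct), eco))
  common <- intersect(map$taxon, colnames(pct))
  for (tx in common) {
    e <- map$ecosystem[map$taxon == tx][1]
    out[, e] <- out[, e] + pct[, tx]
  }
  attr(out, "ages") <- ages
  out
}

#' Two-dimensional Gaussian kernel density surface
#'
#' Sum of isotropic Gaussian kernels of standard deviation `radius` centred
#' on the sample points in an ordination plane, evaluated on a regular grid
#' extending `pad` radii beyond the data range. The surface integrates to
#' the number of points.
#'
#' @param points Numeric matrix n x 2.
#' @param radius Gaussian sigma in plane units (default 3).
#' @param grid_n Grid resolution per axis.
#' @param pad Margin, in multiples of `radius`.
#' @return List `x`, `y`, `z` (length-`grid_n` axes and `grid_n` x `grid_n`
#'   density matrix), class `kde2d_surface`.
#' @export
kernel_density_2d <- function(points, radius = 3, grid_n = 128, pad = 5) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2, nrow(points) >= 1)
  if (radius <= 0) stop("radius must be positive")
  gx <- seq(min(points[, 1]) - pad * radius, max(points[, 1]) + pad * radius,
            length.out = grid_n)
  gy <- seq(min(points[, 2]) - pad * radius, max(points[, 2]) + pad * radius,
            length.out = grid_n)
  z <- matrix(0, grid_n, grid_n)
  for (i in seq_len(nrow(points))) {
    z <- z + outer(stats::dnorm(gx, points[i, 1], radius),
                   stats::dnorm(gy, points[i, 2], radius))
  }
  structure(list(x = gx, y = gy, z = z, radius = radius, n = nrow(points)),
            class = "kde2d_surface")
}

#' Principal-component ordination of an ecosystem series
#'
#' PCA of the samples x ecosystems percentage matrix. Default is
#' covariance-mode (centred, unscaled); `mode = "correlation"` standardizes
#' each ecosystem. Because a principal axis is defined only up to sign, the
#' first axis is oriented so the reference ecosystem (by default the
#' Mediterranean open forest, i.e. the natural end of the gradient) loads
#' positively; remaining axes get their largest-magnitude loading positive.
#'
#' @param series Matrix samples x ecosystems (see [ecosystem_series()]).
#' @param ages Optional sample ages (taken from `attr(series, "ages")` if
#'   absent).
#' @param mode `"covariance"` or `"correlation"`.
#' @param sign_ref Ecosystem whose axis-1 loading is forced non-negative.
#' @return An `eco_pca`: `scores` (samples x axes), `loadings`
#'   (ecosystems x axes, each column unit norm), `inertia_fraction`, `ages`.
#' @export
pca_axis <- function(series, ages = NULL, mode = c("covariance", "correlation"),
                     sign_ref = "medit_open_forest") {
  mode <- match.arg(mode)
  stopifnot(nrow(series) >= 2, ncol(series) >= 2)
  if (all(apply(series, 2, stats::sd) == 0)) stop("constant data matrix")
  if (is.null(ages)) ages <- attr(series, "ages")
  if (mode == "correlation" && any(apply(series, 2, stats::sd) == 0)) {
    stop("correlation mode undefined with constant ecosystem columns")
  }
  pc <- stats::prcomp(series, center = TRUE, scale. = mode == "correlation")
  inertia <- pc$sdev^2 / sum(pc$sdev^2)
  ref <- if (sign_ref %in% colnames(series)) sign_ref else colnames(series)[1]
  for (a in seq_len(ncol(pc$rotation))) {
    flip <- if (a == 1) pc$rotation[ref, 1] < 0 else {
      pc$rotation[which.max(abs(pc$rotation[, a])), a] < 0
    }
    if (flip) {
      pc$rotation[, a] <- -pc$rotation[, a]
      pc$x[, a] <- -pc$x[, a]
    }
  }
  structure(list(scores = pc$x, loadings = pc$rotation,
                 inertia_fraction = inertia, ages = ages, mode = mode),
            class = "eco_pca")
}

#' @export
print.eco_pca <- function(x, ...) {
  cat(sprintf("Ecosystem PCA (%s mode): %d samples, %d ecosystems\n",
              x$mode, nrow(x$scores), nrow(x$loadings)))
  cat(sprintf("Axis 1 inertia fraction: %.3f\n", x$inertia_fraction[1]))
  cat("Axis 1 loadings:\n")
  l1 <- sort(x$loadings[, 1], decreasing = TRUE)
  print(round(l1, 2))
  invisible(x)
}

#' @export
plot.eco_pca <- function(x, axis = 1, ...) {
  if (is.null(x$ages)) {
    plot(x$scores[, 1], x$scores[, 2], xlab = "Axis 1", ylab = "Axis 2", ...)
  } else {
    plot(x$ages, x$scores[, axis], type = "l", xlim = rev(range(x$ages)),
         xlab = "cal yr BP", ylab = sprintf("Axis %d score", axis), ...)
    graphics::abline(h = 0, lty = 3)
  }
  invisible(x)
}
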