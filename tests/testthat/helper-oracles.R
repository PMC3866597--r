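# Independent oracles and small fixture builders used across tests.

# Naive average-linkage (UPGMA) oracle: at every step the distance between
# two clusters is recomputed as the arithmetic mean of ALL original
# leaf-pair distances (no Lance-Williams update), so it shares no code path
# with the implementation.
naive_upgma <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(n - 1)
  merges <- vector("list", n - 1)
  for (step in seq_len(n - 1)) {
    m <- length(clusters)
    best <- Inf; bi <- bj <- NA
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      dd <- mean(d[clusters[[i]], clusters[[j]]])
      if (dd < best - 1e-15) { best <- dd; bi <- i; bj <- j }
    }
    heights[step] <- best
    merges[[step]] <- sort(c(clusters[[bi]], clusters[[bj]]))
    clusters[[bi]] <- merges[[step]]
    clusters[[bj]] <- NULL
  }
  list(heights = heights, merges = merges)
}

# leaf sets merged at each step of an hclust-style tree
merge_leaf_sets <- function(tree) {
  sets <- vector("list", nrow(tree$merge))
  expand <- function(m) if (m < 0) -m else sets[[m]]
  for (s in seq_len(nrow(tree$merge))) {
    sets[[s]] <- sort(c(expand(tree$merge[s, 1]), expand(tree$merge[s, 2])))
  }
  sets
}

random_distance_matrix <- function(n) {
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- stats::runif(n * (n - 1) / 2, 0.05, 2)
  d + t(d)
}

# truth record with all mixture mass on one ecosystem (degenerate core)
degenerate_truth <- function(ecosystem, n = 5) {
  fl <- synthetic_flora()
  terr <- fl[fl$ecological_class == "terrestrial", ]
  tp <- matrix(0, n, nrow(terr), dimnames = list(NULL, terr$taxon))
  sel <- terr$ecosystem == ecosystem
  tp[, sel] <- rep(terr$weight[sel], each = n)
  mix <- sapply(unique(terr$ecosystem), function(e) {
    rowSums(tp[, terr$taxon[terr$ecosystem == e], drop = FALSE])
  })
  structure(list(n = n, ages = seq(0, 4000, length.out = n),
                 depths = seq(10, 200, length.out = n),
                 theta = NULL, climate = NULL, pft = NULL,
                 taxon_prob = tp, mixture = mix,
                 basis = NULL,
                 curve = make_calibration_curve("identity"),
                 co2 = rep(280, n), seed = 1,
                 seeds = c(counts = 1)),
            class = "truth_record")
}

table1_dates <- function() {
  read_tsv_meta(system.file("extdata", "akko_c14_dates.tsv",
                            package = "pollenclim"))
}
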