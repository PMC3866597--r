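# Pollen percentages and diversity.
#
# Percentages follow the two standard pollen-sum conventions: the
# terrestrial sum (excluding local hygrophytes-hydrophytes and cryptogam
# spores) and the terrestrial-plus-aquatic sum (hygrophytes-hydrophytes
# added to the denominator, the convention for quoting aquatic taxa).
# Micro-charcoal and dinocysts are bookkept but never enter any sum.

check_counts <- function(counts, meta) {
  stopifnot(is.matrix(counts))
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  miss <- setdiff(colnames(counts), meta$taxon)
  if (length(miss)) stop("taxa missing from metadata: ", paste(miss, collapse = ", "))
  cls <- meta$ecological_class[match(colnames(counts), meta$taxon)]
  ok <- c("terrestrial", "hygro_hydrophyte", "cryptogam_spore",
          "microcharcoal", "dinocyst")
  if (any(!cls %in% ok)) stop("unknown ecological class")
  cls
}

#' Pollen percentages under a stated pollen-sum convention
#'
#' @param counts Integer matrix, samples x taxa (column names are taxa).
#' @param meta Taxon metadata with columns `taxon`, `ecological_class`.
#' @param convention `"terrestrial"` (denominator = terrestrial counts) or
#'   `"terrestrial_aquatic"` (hygrophytes-hydrophytes added to the
#'   denominator). Micro-charcoal and dinocyst columns are returned as `NA`:
#'   they are counted but have no percentage under either convention.
#' @return Matrix of percentages, same shape as `counts`, with attribute
#'   `sum_convention`. Under the terrestrial convention, terrestrial columns
#'   sum to 100 per sample.
#' @export
pollen_percentages <- function(counts, meta,
                               convention = c("terrestrial",
                                              "terrestrial_aquatic")) {
  convention <- match.arg(convention)
  cls <- check_counts(counts, meta)
  in_denom <- cls == "terrestrial"
  if (convention == "terrestrial_aquatic") {
    in_denom <- in_denom | cls == "hygro_hydrophyte"
  }
  denom <- rowSums(counts[, in_denom, drop = FALSE])
  bad <- which(denom == 0)
  if (length(bad)) {
    stop("zero pollen sum in sample(s): ",
         paste(rownames(counts)[bad] %||% bad, collapse = ", "))
  }
  pct <- sweep(counts, 1, denom, "/") * 100
  pct[, cls %in% c("microcharcoal", "dinocyst")] <- NA_real_
  attr(pct, "sum_convention") <- convention
  pct
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-sample palynological diversity
#'
#' Richness S (terrestrial taxa with count > 0), total terrestrial count N,
#' Margalef index (S - 1)/ln N and Shannon index -sum p_i ln p_i, computed
#' on terrestrial counts with natural logarithms. Hygrophytes, cryptogam
#' spores, micro-charcoal and dinocysts are excluded.
#'
#' @inheritParams pollen_percentages
#' @return Data frame with columns `sample`, `S`, `N`, `margalef`, `shannon`.
#' @export
pollen_diversity <- function(counts, meta) {
  cls <- check_counts(counts, meta)
  terr <- counts[, cls == "terrestrial", drop = FALSE]
  N <- rowSums(terr)
  if (any(N < 2)) {
    stop("Margalef index undefined for terrestrial count N < 2 in sample(s): ",
         paste(rownames(counts)[N < 2] %||% which(N < 2), collapse = ", "))
  }
  S <- rowSums(terr > 0)
  shannon <- vapply(seq_len(nrow(terr)), function(i) {
    p <- terr[i, terr[i, ] > 0] / N[i]
    -sum(p * log(p))
  }, numeric(1))
  data.frame(sample = rownames(counts) %||% seq_len(nrow(counts)),
             S = S, N = N,
             margalef = (S - 1) / log(N),
             shannon = shannon,
             row.names = NULL)
}

#' Aggregate terrestrial percentages into plant functional groups
#'
#' Sums terrestrial taxon percentages by the taxa's plant-functional-group
#' labels onto the canonical 13-group vector (absent groups get 0) and
#' normalizes to sum 1 — the observation vector the climate inversion fits.
#'
#' @param pct Percentage matrix from [pollen_percentages()].
#' @param meta Taxon metadata with `taxon`, `ecological_class`, `pft_group`.
#' @return Matrix samples x 13, rows summing to 1.
#' @export
group_spectra <- function(pct, meta) {
  groups <- pft_group_names()
  g <- meta$pft_group[match(colnames(pct), meta$taxon)]
  keep <- !is.na(g) &
    meta$ecological_class[match(colnames(pct), meta$taxon)] == "terrestrial"
  out <- matrix(0, nrow(pct), length(groups),
                dimnames = list(rownames(pct), groups))
  for (j in which(keep)) out[, g[j]] <- out[, g[j]] + pct[, j]
  sweep(out, 1, rowSums(out), "/")
}
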