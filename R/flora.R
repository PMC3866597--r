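# Built-in synthetic flora: a 30-taxon terrestrial pollen flora partitioned
# over 9 pollen-derived ecosystems and 13 plant functional groups, plus
# hygrophyte, cryptogam-spore, micro-charcoal and dinocyst palynomorphs.
# Real-data users supply their own taxon metadata in the same layout.

.pkg_cache <- new.env(parent = emptyenv())

#' Synthetic taxon metadata table
#'
#' Returns the package's built-in synthetic flora: taxon name, ecological
#' class (`terrestrial`, `hygro_hydrophyte`, `cryptogam_spore`,
#' `microcharcoal`, `dinocyst`), ecosystem membership (9 ecosystems,
#' terrestrial taxa only), plant-functional-group membership (13 groups) and
#' the within-ecosystem weight used to split ecosystem abundance over member
#' taxa.
#'
#' @return Data frame with columns `taxon`, `ecological_class`, `ecosystem`,
#'   `pft_group`, `weight`.
#' @export
synthetic_flora <- function() {
  if (is.null(.pkg_cache$flora)) {
    path <- system.file("extdata", "synthetic_flora.tsv", package = "pollenclim")
    fl <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                            stringsAsFactors = FALSE, na.strings = "NA")
    .pkg_cache$flora <- fl
  }
  .pkg_cache$flora
}

#' Names of the 9 pollen-derived ecosystems
#' @return Character vector, length 9.
#' @export
ecosystem_names <- function() {
  fl <- synthetic_flora()
  unique(fl$ecosystem[fl$ecological_class == "terrestrial"])
}

#' Names of the 13 plant functional groups
#'
#' Order matches the forward-model parameter table.
#' @return Character vector, length 13.
#' @export
pft_group_names <- function() pft_params()$group

#' Forward-model parameter table
#'
#' The versioned envelope/ramp parameter set of the simplified vegetation
#' model: per group, a trapezoidal membership over mean temperature of the
#' coldest month (`mtco_*`, deg C), a trapezoid over growing degree-days
#' above 5 deg C (`gdd_*`), a piecewise-linear moisture ramp over the
#' moisture index alpha, and a CO2 sensitivity `beta`.
#'
#' @return Data frame with one row per plant functional group.
#' @export
pft_params <- function() {
  if (is.null(.pkg_cache$pft)) {
    path <- system.file("extdata", "pft_params_v1.tsv", package = "pollenclim")
    .pkg_cache$pft <- utils::read.table(path, header = TRUE, sep = "\t",
                                        comment.char = "#",
                                        stringsAsFactors = FALSE)
  }
  .pkg_cache$pft
}
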