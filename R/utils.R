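#' @keywords internal
"_PACKAGE"

# Month lengths: standard Gregorian, no leap years.
MONTH_DAYS <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global random-number state set from `seed`, then
#' restores the previous state, so generators are pure functions of their
#' seed and never perturb the caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a sub-seed from a master seed
#'
#' Deterministic integer mixing so each pipeline stage gets its own
#' reproducible stream from one configuration value. Result is always a
#' positive integer below 2^31.
#'
#' @param master Master integer seed.
#' @param offset Integer offset identifying the sub-generator.
#' @return Integer seed.
#' @export
derive_seed <- function(master, offset) {
  m <- as.double(master) %% 1000003
  as.integer((m * 2099 + as.double(offset) * 7919 + 12345) %% 2147483629) + 1L
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Write a table as TSV with commented metadata header
#'
#' All pipeline stage outputs are plain TSV with `#`-prefixed metadata lines
#' (seed, package version, stage name) so runs are inspectable and diffable.
#'
#' @param x Data frame to write.
#' @param path Output path.
#' @param meta Named character/numeric vector written as `# key: value` lines.
#' @return `path`, invisibly.
#' @export
write_tsv_meta <- function(x, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta)) {
    writeLines(sprintf("# %s: %s", names(meta), as.character(meta)), con)
  }
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_meta()]
#'
#' @param path File path; lines starting `#` are skipped.
#' @return Data frame.
#' @export
read_tsv_meta <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE)
}

#' Atmospheric CO2 concentration at a calendar age
#'
#' Small built-in ice-core-style lookup giving late-Holocene CO2 by linear
#' interpolation between epoch anchors; override per analysis via config.
#'
#' @param age_bp Calendar age(s), cal yr BP.
#' @return CO2 in ppm.
#' @export
co2_at_age <- function(age_bp) {
  anchors_age <- c(0, 100, 250, 1000, 3000, 7000)
  anchors_ppm <- c(370, 330, 285, 280, 275, 262)
  stats::approx(anchors_age, anchors_ppm, xout = clamp(age_bp, 0, 7000),
                rule = 2)$y
}
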