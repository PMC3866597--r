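# End-to-end orchestration: synth -> chronology -> pollen -> ecosystems ->
# inversion -> summary. Every stage communicates through plain TSV files
# with '#'-prefixed metadata headers; rerunning with the same configuration
# reproduces byte-identical numeric outputs, recorded in a checksum manifest.

#' Build a pipeline configuration
#'
#' @param outdir Output directory.
#' @param seed Master seed; each stage derives its own sub-seed.
#' @param n_samples Core samples to simulate.
#' @param counts_per_sample Pollen count total per sample.
#' @param grid_cells Modern climate grid cells.
#' @param k Number of pollen-derived ecosystems to cut.
#' @param n_iter MCMC iterations per inverted sample.
#' @param sigma_obs Observation sd on group proportions.
#' @param invert_every Invert every `invert_every`-th core sample (the
#'   top-core sample is always included).
#' @param n_modern Modern spectra used for verification/bias estimation.
#' @param inputs Optional named list of existing input file paths
#'   (`counts`, `taxa`, `dates`, `curve`, `grid`); when NULL the synth stage
#'   generates them.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(outdir, seed = 1, n_samples = 40,
                            counts_per_sample = 500, grid_cells = 48,
                            k = 9, n_iter = 2000, sigma_obs = 0.05,
                            invert_every = 4, n_modern = 11,
                            inputs = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full reconstruction pipeline
#'
#' Executes all stages on synthetic (or supplied) inputs and writes: the
#' calibrated dates and age-depth model, percentage and diversity series,
#' ecosystem map/series and PCA axis-1 scores, reconstructed climate series
#' with credible intervals anchored to modern climate, the modern-spectra
#' bias table, and a manifest with per-file checksums. Any stage failure
#' halts with the stage name.
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, a list with the manifest data frame and in-memory
#'   stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  hdr <- c(seed = config$seed,
           package = paste0("pollenclim ",
                            as.character(utils::packageVersion("pollenclim"))))
  out <- list()
  files <- character()
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # -- stage 1: synth ------------------------------------------------------
  truth <- NULL
  inputs <- config$inputs
  stage("synth", {
    if (is.null(inputs)) {
      truth <- make_truth(config$n_samples, seed = config$seed,
                          grid_cells = config$grid_cells)
      core <- simulate_core(truth, config$counts_per_sample,
                            seed = derive_seed(config$seed, 10))
      inputs <- write_synth_inputs(core, truth,
                                   file.path(config$outdir, "inputs"))
      out$truth <- truth
    }
    files[names(inputs)] <- inputs
  })

  # -- stage 2: chronology -------------------------------------------------
  stage("chronology", {
    horizons <- read_tsv_meta(inputs[["dates"]])
    curve <- read_calcurve(inputs[["curve"]])
    cals <- lapply(seq_len(nrow(horizons)), function(i) {
      calibrate_c14(horizons$c14_age[i], horizons$c14_error[i], curve,
                    lab_code = horizons$lab_code[i])
    })
    cal_df <- data.frame(
      lab_code = horizons$lab_code, depth_cm = horizons$depth_cm,
      c14_age = horizons$c14_age, c14_error = horizons$c14_error,
      intercept_cal_bp = vapply(cals, `[[`, 0, "intercept"),
      median_cal_bp = vapply(cals, `[[`, 0, "median"),
      wmean_cal_bp = vapply(cals, `[[`, 0, "wmean"))
    am <- build_age_model(cal_df$depth_cm, cal_df$intercept_cal_bp)
    counts_df <- read_tsv_meta(inputs[["counts"]])
    ages <- predict(am, clamp(counts_df$depth_cm, min(am$knots$depth),
                              max(am$knots$depth)))
    files["calibrated"] <- write_tsv_meta(cal_df,
      file.path(config$outdir, "calibrated_dates.tsv"), hdr)
    files["agemodel"] <- write_tsv_meta(
      data.frame(am$knots,
                 rate_cm_kyr = c(am$rate_cm_kyr, NA)),
      file.path(config$outdir, "age_model.tsv"), hdr)
    out$age_model <- am
    out$sample_ages <- ages
  })

  # -- stage 3: pollen -----------------------------------------------------
  stage("pollen", {
    counts_df <- read_tsv_meta(inputs[["counts"]])
    meta <- read_tsv_meta(inputs[["taxa"]])
    counts <- as.matrix(counts_df[, !(names(counts_df) %in%
                                        c("sample", "depth_cm"))])
    rownames(counts) <- counts_df$sample
    pct <- pollen_percentages(counts, meta, "terrestrial")
    div <- pollen_diversity(counts, meta)
    div$depth_cm <- counts_df$depth_cm
    div$age_cal_bp <- out$sample_ages
    files["percent"] <- write_tsv_meta(
      data.frame(sample = rownames(pct), pct, check.names = FALSE),
      file.path(config$outdir, "percent_terrestrial.tsv"), hdr)
    files["diversity"] <- write_tsv_meta(div,
      file.path(config$outdir, "diversity.tsv"), hdr)
    out$pct <- pct
    out$meta <- meta
  })

  # -- stage 4: ecosystems -------------------------------------------------
  stage("ecosystems", {
    terr <- out$meta$taxon[out$meta$ecological_class == "terrestrial"]
    pterr <- out$pct[, intersect(colnames(out$pct), terr)]
    sim <- spearman_similarity(pterr)
    tree <- upgma(sim)
    emap <- cut_to_ecosystems(tree, k = config$k)
    series <- ecosystem_series(pterr, emap, ages = out$sample_ages)
    ord <- pca_axis(series, sign_ref = colnames(series)[1])
    files["ecomap"] <- write_tsv_meta(emap,
      file.path(config$outdir, "ecosystem_map.tsv"), hdr)
    files["ecoseries"] <- write_tsv_meta(
      data.frame(sample = rownames(series), age_cal_bp = out$sample_ages,
                 series, check.names = FALSE),
      file.path(config$outdir, "ecosystem_series.tsv"), hdr)
    files["scores"] <- write_tsv_meta(
      data.frame(sample = rownames(series), age_cal_bp = out$sample_ages,
                 axis1_score = ord$scores[, 1]),
      file.path(config$outdir, "pca_axis1.tsv"),
      c(hdr, axis1_inertia = sprintf("%.6f", ord$inertia_fraction[1])))
    files["loadings"] <- write_tsv_meta(
      data.frame(ecosystem = rownames(ord$loadings),
                 round(ord$loadings, 6), check.names = FALSE),
      file.path(config$outdir, "pca_loadings.tsv"), hdr)
    out$ordination <- ord
  })

  # -- stage 5: inversion --------------------------------------------------
  stage("inversion", {
    grid_df <- read_tsv_meta(inputs[["grid"]])
    grid <- as.matrix(grid_df[, climate_var_names()])
    rownames(grid) <- grid_df$cell
    basis <- build_climate_pc_basis(grid)
    spectra <- group_spectra(out$pct, out$meta)
    idx <- sort(unique(c(1L, seq(1L, nrow(spectra),
                                 by = config$invert_every))))
    summaries <- lapply(idx, function(i) {
      fit <- invert_climate(spectra[i, ], basis,
                            sigma_obs = config$sigma_obs,
                            co2 = co2_at_age(out$sample_ages[i]),
                            n_iter = config$n_iter,
                            seed = derive_seed(config$seed, 200 + i))
      cbind(sample = rownames(spectra)[i],
            age_cal_bp = out$sample_ages[i], fit$summary)
    })
    down <- do.call(rbind, summaries)
    modern_obs_l <- bioclim(basis$baseline)
    modern_obs <- c(MAT = modern_obs_l$mat, MTCO = modern_obs_l$mtco,
                    MTWA = modern_obs_l$mtwa, PANN = modern_obs_l$pann)
    top <- summaries[[1]][, c("variable", "median", "ci_lo", "ci_hi")]
    adj <- anomaly_adjust(down, top, modern_obs)
    # modern-spectra verification: forward profiles at grid cells + noise
    mi <- seq_len(min(config$n_modern, nrow(grid)))
    mspec <- t(sapply(mi, function(i) forward_model(grid[i, ], co2 = 370)))
    mobs <- t(sapply(mi, function(i) {
      b <- bioclim(grid[i, ])
      c(MAT = b$mat, MTCO = b$mtco, MTWA = b$mtwa, PANN = b$pann)
    }))
    bt <- verify_and_bias_correct(mspec, mobs, basis,
                                  sigma_obs = config$sigma_obs, co2 = 370,
                                  n_iter = config$n_iter,
                                  seed = derive_seed(config$seed, 300))
    files["reconstruction"] <- write_tsv_meta(adj,
      file.path(config$outdir, "climate_reconstruction.tsv"), hdr)
    files["bias"] <- write_tsv_meta(bt$table,
      file.path(config$outdir, "bias_table.tsv"), hdr)
    out$reconstruction <- adj
    out$reconstruction_raw <- down
    out$inverted_samples <- idx
    out$bias <- bt
  })

  # -- stage 6: summary / manifest ----------------------------------------
  stage("summary", {
    stage_of <- c(counts = "synth", taxa = "synth", dates = "synth",
                  curve = "synth", grid = "synth",
                  calibrated = "chronology", agemodel = "chronology",
                  percent = "pollen", diversity = "pollen",
                  ecomap = "ecosystems", ecoseries = "ecosystems",
                  scores = "ecosystems", loadings = "ecosystems",
                  reconstruction = "inversion", bias = "inversion")
    manifest <- data.frame(
      stage = c(unname(stage_of[names(files)]), "summary"),
      output = c(names(files), "manifest"),
      file = c(basename(unlist(files)), "manifest.tsv"),
      md5 = c(unname(tools::md5sum(unlist(files))), NA))
    files["manifest"] <- write_tsv_meta(manifest,
      file.path(config$outdir, "manifest.tsv"), hdr)
    out$manifest <- manifest
  })
  out$files <- files
  invisible(out)
}
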