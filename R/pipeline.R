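#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. Unknown
#' keys are rejected before any computation. The `cohort` entry takes
#' [cohort_config()] overrides for the simulated study; processing keys
#' mirror the stage parameters.
#'
#' @param config Named list (e.g. parsed from YAML) of overrides.
#' @return A validated configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  defaults <- list(
    cohort = list(),
    level = "spectra",
    qc_cv_threshold = 0.5,
    snr_min = 3,
    bin_tol = 0.3,
    min_halfwidth = 0.25,
    max_shift = 0.5,
    align = TRUE,
    contrast = "HD",
    alpha = 0.05,
    average_runs = TRUE,
    region = "SN_lateral",
    make_images = TRUE
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L) {
    stop("invalid config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, config)
  unknown_cohort <- setdiff(names(cfg$cohort),
                            names(formals(cohort_config)))
  if (length(unknown_cohort) > 0L) {
    stop("invalid cohort config keys: ",
         paste(unknown_cohort, collapse = ", "), call. = FALSE)
  }
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file path.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  pipeline_config(yaml::read_yaml(path))
}

pipeline_log <- function(quiet, stage, fmt, ...) {
  if (!quiet) {
    message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the full chain in fixed order: simulate -> QC -> preprocess ->
#' ROI summarization -> per-bin statistics -> behavior correlation ->
#' report. QC-failing sections are excluded and logged; a failing stage
#' stops the run with the stage named. All outputs (CSV tables, optional
#' PNG composite, JSON manifest with checksums) are written under
#' `out_dir`.
#'
#' @param config A `pipeline_config` (or list of overrides).
#' @param out_dir Output directory.
#' @param seed Master seed for the simulated study.
#' @param quiet Suppress per-stage log lines?
#' @return Invisibly, a list with `results` (per-bin statistics),
#'   `roi_summary`, `correlations`, `excluded` and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile(),
                         seed = 1L, quiet = FALSE) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  cohort_cfg <- do.call(cohort_config, c(config$cohort, list(seed = seed)))
  catalog <- default_catalog()

  pipeline_log(quiet, "simulate", "level=%s seed=%d", config$level, seed)
  bundle <- generate_cohort(cohort_cfg, seed = seed, level = config$level)
  animals <- bundle$animals
  excluded <- character(0)

  if (config$level == "spectra") {
    pipeline_log(quiet, "qc", "checking %d sections",
                 length(bundle$sections))
    keep <- list()
    for (sid in names(bundle$sections)) {
      verdict <- qc_section(bundle$sections[[sid]]$section,
                            config$qc_cv_threshold)
      if (verdict$pass) keep[[sid]] <- bundle$sections[[sid]]
      else {
        excluded <- c(excluded, sid)
        pipeline_log(quiet, "qc", "excluded %s (%s)", sid, verdict$reason)
      }
    }
    if (length(keep) == 0L) {
      stop("pipeline stage qc: all sections excluded", call. = FALSE)
    }
    panel_mz <- catalog$mz_mh[match(cohort_cfg$panel$name, catalog$name)]
    refs <- panel_mz[cohort_cfg$panel$base >= 50 &
                       panel_mz > cohort_cfg$mz_range[1L] &
                       panel_mz < cohort_cfg$mz_range[2L]]
    roi_rows <- list()
    for (sid in names(keep)) {
      res <- keep[[sid]]
      proc <- tryCatch(
        process_section(res$section,
                        reference_mz = if (config$align) refs else NULL,
                        snr_min = config$snr_min,
                        bin_tol = config$bin_tol,
                        min_halfwidth = config$min_halfwidth,
                        max_shift = config$max_shift),
        error = function(e) stop("pipeline stage preprocess: ",
                                 conditionMessage(e), call. = FALSE))
      pipeline_log(quiet, "preprocess", "%s: %d bins", sid,
                   nrow(proc$bins))
      roi_rows[[sid]] <- summarize_roi(proc$table, res$mask)
    }
    roi_summary <- do.call(rbind, roi_rows)
    rownames(roi_summary) <- NULL

    # match section bins to panel species by mass (0.3 Da) and build the
    # per-run log2 lesioned/intact design on the requested region
    ann <- annotate_peaks(unique(roi_summary$mz), catalog, tolerance = 0.3)
    ann <- ann[!duplicated(ann$observed_mz), ]
    roi_summary$peptide <- ann$peptide_name[
      match(roi_summary$mz, ann$observed_mz)]
    roi_summary$theoretical_mz <- ann$theoretical_mz[
      match(roi_summary$mz, ann$observed_mz)]
    sec_meta <- do.call(rbind, lapply(keep, function(res) {
      data.frame(section_id = res$section$section_id,
                 animal = res$section$animal_id,
                 run = res$section$run_id, stringsAsFactors = FALSE)
    }))
    dat <- merge(roi_summary[!is.na(roi_summary$peptide), ], sec_meta,
                 by = "section_id")
    dat <- dat[dat$region == config$region, ]
    design_rows <- list()
    for (key in unique(paste(dat$section_id, dat$peptide))) {
      sub <- dat[paste(dat$section_id, dat$peptide) == key, ]
      les <- sub$mean_area[sub$hemisphere == "lesioned"]
      int <- sub$mean_area[sub$hemisphere == "intact"]
      if (length(les) != 1L || length(int) != 1L || int <= 0 || les <= 0) next
      design_rows[[key]] <- data.frame(
        animal = sub$animal[1L], run = sub$run[1L],
        group = animals$group[match(sub$animal[1L], animals$animal_id)],
        bin = sub$theoretical_mz[1L], peptide = sub$peptide[1L],
        value = log2(les / int), stringsAsFactors = FALSE)
    }
    design <- do.call(rbind, design_rows)
  } else {
    roi_summary <- NULL
    design <- bundle$design[bundle$design$region == config$region, ]
  }

  pipeline_log(quiet, "stats", "%d observations, %d bins", nrow(design),
               length(unique(design$bin)))
  results <- fit_all_bins(design, contrast = config$contrast,
                          catalog = catalog)
  results$significant <- results$p_adj < config$alpha

  # behavior correlation: per-animal region value (runs averaged) vs
  # cumulative dyskinesia score, treated animals only
  treated <- animals$animal_id[animals$group %in% c("LD", "HD")]
  correlations <- do.call(rbind, lapply(unique(design$bin), function(b) {
    sub <- design[design$bin == b & design$animal %in% treated, ]
    per_animal <- if (config$average_runs) {
      tapply(sub$value, sub$animal, mean)
    } else {
      stats::setNames(sub$value, sub$animal)
    }
    scores <- animals$cumulative[match(names(per_animal),
                                       animals$animal_id)]
    ct <- tryCatch(correlate_with_behavior(as.numeric(per_animal), scores),
                   error = function(e) NULL)
    if (is.null(ct)) return(NULL)
    data.frame(mz = b, peptide = sub$peptide[1L], r = ct$r, p = ct$p,
               slope = ct$slope, intercept = ct$intercept, n = ct$n)
  }))
  pipeline_log(quiet, "behavior", "%d bins correlated",
               if (is.null(correlations)) 0L else nrow(correlations))

  # report
  utils::write.csv(results, file.path(out_dir, "results.csv"),
                   row.names = FALSE)
  utils::write.csv(animals, file.path(out_dir, "animals.csv"),
                   row.names = FALSE)
  if (!is.null(roi_summary)) {
    utils::write.csv(roi_summary, file.path(out_dir, "roi_summary.csv"),
                     row.names = FALSE)
  }
  if (!is.null(correlations)) {
    utils::write.csv(correlations,
                     file.path(out_dir, "behavior_correlation.csv"),
                     row.names = FALSE)
  }
  if (config$make_images && config$level == "spectra") {
    first_hd <- animals$animal_id[animals$group == "HD"][1L]
    sid <- sprintf("%s_run1", first_hd)
    if (sid %in% names(bundle$sections) && !(sid %in% excluded)) {
      res <- bundle$sections[[sid]]
      proc <- process_section(res$section, reference_mz = NULL)
      dynb <- catalog$mz_mh[catalog$name == "Dyn B"]
      ler <- catalog$mz_mh[catalog$name == "Leu-Enk-Arg"]
      near <- function(target) {
        proc$table$centers[which.min(abs(proc$table$centers - target))]
      }
      imgs <- list(
        red = make_ion_image(proc$table, near(ler), res$section),
        green = make_ion_image(proc$table, near(dynb), res$section))
      save_composite_png(composite_rgb(imgs),
                         file.path(out_dir, "composite_dynb_ler.png"))
    }
  }

  files <- list.files(out_dir, full.names = TRUE)
  manifest <- list(
    seed = seed,
    config = unclass(config),
    n_animals = nrow(animals),
    n_sections = if (config$level == "spectra")
      length(bundle$sections) else NA,
    excluded_sections = excluded,
    n_bins = length(unique(design$bin)),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    checksums = as.list(tools::md5sum(files))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pipeline_log(quiet, "report", "wrote %d files to %s", length(files) + 1L,
               out_dir)
  invisible(list(results = results, roi_summary = roi_summary,
                 correlations = correlations, design = design,
                 excluded = excluded, manifest = manifest))
}
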