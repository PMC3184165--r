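#' Configuration of a synthetic imaging-dyskinesia study
#'
#' Defines the study conditions emulated by the generator: 14 animals
#' (4 lesion-only controls, 5 low-dyskinetic, 5 high-dyskinetic), duplicate
#' sections per animal, a 250-um spot grid over the substantia nigra, ~30%
#' coefficient of variation on per-spot peak areas, group-dependent
#' lesion-side fold changes (Dyn B whole-SN 1.44 / lateral 1.75; aNeo 1.26 /
#' 1.54, high-dyskinetic group only), linear dyskinesia trajectories
#' (slope 0.68, offset 0.41 low-dyskinetic; 0.81 / 29.94 high-dyskinetic)
#' and a latent-severity coupling producing a configurable correlation
#' (default 0.8) between planted peptide elevation and planted dyskinesia
#' severity.
#'
#' @param n_lc,n_ld,n_hd Group sizes.
#' @param runs Duplicate sections (runs) per animal.
#' @param grid_ncol,grid_nrow,spacing_um Section grid geometry; the left
#'   half of the columns is the intact hemisphere, the right half the
#'   lesioned one, and each hemisphere splits into a medial (inner columns)
#'   and lateral (outer columns) region.
#' @param mz_range,mz_step m/z axis of synthetic spectra (Da).
#' @param peak_sd Gaussian peak standard deviation (Da).
#' @param panel Peptide panel data frame (`name`, `base`, `pattern`,
#'   `fold_whole`, `fold_lateral`, `patch`); defaults to [default_panel()].
#' @param background_n,background_base Number and height of inert background
#'   species; they carry the bulk of the TIC so normalization does not
#'   distort planted folds.
#' @param noise_cv Lognormal CV of per-spot peak amplitudes.
#' @param baseline_amp,white_noise_sd,tic_sd,jitter_max Spectrum nuisance
#'   parameters: exponential chemical-baseline height, additive white noise
#'   sd, lognormal sd of the per-spectrum TIC scale factor, and the maximum
#'   rigid m/z jitter (uniform, Da).
#' @param conversion_patch Plant the dorsolateral conversion patch (locally
#'   high Leu-Enk-Arg where Dyn B is locally low)?
#' @param tau_log2 Log2-scale sd of the per-animal severity modulation of
#'   planted folds.
#' @param rho Target correlation between the severity latent and the
#'   fold-modulation latent.
#' @param m_ld,b_ld,m_hd,b_hd Trajectory slope/offset per group (score/day,
#'   score).
#' @param score_sd Session-score noise sd; `severity_gain` converts the
#'   severity latent into score units.
#' @param severity_gain See `score_sd`.
#' @param slope_sd Between-animal sd of the trajectory slope (score/day);
#'   the group slopes are means over animals with individual spread.
#' @param n_timepoints Rating timepoints per session (1-min observation
#'   every 20 min).
#' @param days Treatment days on which sessions are rated.
#' @param knockout Prodynorphin-knockout scenario: all dynorphin-family base
#'   intensities set to zero (substance P and background unchanged).
#' @param isotopes Also plant the first two isotope peaks (off by default).
#' @param seed Master seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_lc = 4, n_ld = 5, n_hd = 5, runs = 2,
                          grid_ncol = 8, grid_nrow = 6, spacing_um = 250,
                          mz_range = c(500, 2200), mz_step = 0.05,
                          peak_sd = 0.06,
                          panel = default_panel(),
                          background_n = 40, background_base = 1000,
                          noise_cv = 0.30,
                          baseline_amp = 200, white_noise_sd = 2,
                          tic_sd = 0.2, jitter_max = 0.1,
                          conversion_patch = TRUE,
                          tau_log2 = 0.1, rho = 0.8,
                          m_ld = 0.68, b_ld = 0.41,
                          m_hd = 0.81, b_hd = 29.94,
                          score_sd = 1.5, severity_gain = 2, slope_sd = 0.3,
                          n_timepoints = 9, days = seq(1, 15, by = 2),
                          knockout = FALSE, isotopes = FALSE, seed = 1L) {
  stopifnot(grid_ncol %% 4 == 0, noise_cv >= 0, runs >= 1,
            all(panel$base >= 0), rho >= -1, rho <= 1)
  if (isTRUE(knockout)) {
    panel$base[panel$name != "Substance P"] <- 0
  }
  cfg <- list(
    n_lc = n_lc, n_ld = n_ld, n_hd = n_hd, runs = runs,
    grid_ncol = grid_ncol, grid_nrow = grid_nrow, spacing_um = spacing_um,
    mz_range = mz_range, mz_step = mz_step, peak_sd = peak_sd,
    panel = panel, background_n = background_n,
    background_base = background_base,
    noise_cv = noise_cv, baseline_amp = baseline_amp,
    white_noise_sd = white_noise_sd, tic_sd = tic_sd,
    jitter_max = jitter_max, conversion_patch = conversion_patch,
    tau_log2 = tau_log2, rho = rho,
    m_ld = m_ld, b_ld = b_ld, m_hd = m_hd, b_hd = b_hd,
    score_sd = score_sd, severity_gain = severity_gain,
    slope_sd = slope_sd,
    n_timepoints = n_timepoints, days = days,
    knockout = isTRUE(knockout), isotopes = isTRUE(isotopes),
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  cfg
}

#' Default synthetic peptide panel
#'
#' ~14 catalog species with base peak heights, spatial patterns and planted
#' lesion-side fold changes (high-dyskinetic group only; all folds are 1 in
#' the lesion-control and low-dyskinetic groups). `fold_whole` and
#' `fold_lateral` are the planted whole-SN and lateral-SN lesioned/intact
#' ratios; the medial fold follows from the two by weighted-mean algebra.
#' The Leu-Enk-Arg lateral fold (1.5) is a package default, not a
#' literature-derived value. `patch` marks participation in the
#' dorsolateral conversion patch.
#'
#' @return The panel data frame.
#' @export
default_panel <- function() {
  data.frame(
    name = c("Dyn B", "aNeo", "Leu-Enk-Arg",
             "aNeo(1-7)", "Dyn A(1-8)", "Dyn A(1-17)", "Dyn A(10-17)",
             "Leu-Enk-Arg-Arg", "bNeo", "Substance P",
             "Dyn B(2-13)", "aNeo(2-10)", "Dyn A(1-8)(2-8)", "Leu-Enk"),
    base = c(120, 80, 60, 40, 50, 30, 25, 30, 30, 70, 20, 20, 20, 35),
    pattern = c("medial", "medial", "uniform",
                "uniform", "uniform", "uniform", "uniform",
                "uniform", "uniform", "uniform",
                "uniform", "uniform", "uniform", "uniform"),
    fold_whole = c(1.44, 1.26, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA,
                   NA),
    fold_lateral = c(1.75, 1.54, 1.5, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1),
    patch = c("low", "", "high", "", "", "", "", "", "", "", "", "", "",
              ""),
    stringsAsFactors = FALSE
  )
}

# spot layout shared by both generator levels
cohort_spot_layout <- function(config) {
  g <- expand.grid(col = seq_len(config$grid_ncol) - 1L,
                   row = seq_len(config$grid_nrow) - 1L)
  half <- config$grid_ncol / 2
  quarter <- config$grid_ncol / 4
  g$hemisphere <- ifelse(g$col < half, "intact", "lesioned")
  dist_mid <- ifelse(g$col < half, half - 1L - g$col, g$col - half)
  g$region <- ifelse(dist_mid < quarter, "SN_medial", "SN_lateral")
  g$spot_id <- sprintf("x%02dy%02d", g$col, g$row)
  # dorsolateral 2x2 conversion patch on the lesioned side (top outer corner)
  g$patch <- g$hemisphere == "lesioned" &
    g$col >= config$grid_ncol - 2L & g$row <= 1L
  g
}

# pattern multiplier per spot
pattern_mult <- function(pattern, region) {
  switch(pattern,
         medial = ifelse(region == "SN_medial", 1.3, 0.7),
         lateral = ifelse(region == "SN_medial", 0.7, 1.3),
         uniform = rep(1, length(region)),
         stop("unknown spatial pattern: ", pattern, call. = FALSE))
}

# medial fold implied by whole-SN and lateral targets given the intact
# spatial pattern (equal region spot counts)
medial_fold <- function(fold_whole, fold_lateral, pattern) {
  if (is.na(fold_whole)) return(1)
  w_med <- if (pattern == "medial") 1.3 else if (pattern == "lateral") 0.7 else 1
  w_lat <- if (pattern == "medial") 0.7 else if (pattern == "lateral") 1.3 else 1
  (fold_whole * (w_med + w_lat) - fold_lateral * w_lat) / w_med
}

# planted per-region log2 folds for one animal (severity latent w)
animal_folds <- function(config, group, w) {
  panel <- config$panel
  folds <- data.frame(name = panel$name,
                      f_medial = 1, f_lateral = 1,
                      stringsAsFactors = FALSE)
  if (group != "HD") return(folds)
  for (i in seq_len(nrow(panel))) {
    f_lat <- panel$fold_lateral[i]
    if (is.na(f_lat) || f_lat == 1) next
    f_med <- medial_fold(panel$fold_whole[i], f_lat, panel$pattern[i])
    mod <- config$tau_log2 * w
    folds$f_lateral[i] <- 2^(log2(f_lat) + mod)
    folds$f_medial[i] <- if (f_med == 1) 1 else 2^(log2(f_med) + mod)
  }
  folds
}

#' Generate behavioral data for one synthetic animal
#'
#' Session scores follow the group's linear trajectory
#' `round(max(0, m * day + b + gain * z + noise))`, distributed over rating
#' timepoints and the four AIM categories; lesion-control animals score zero
#' throughout. The pre-treatment cylinder test always satisfies the
#' inclusion rule (percent left use < 30); the post test reflects the
#' group-typical change (low-dyskinetic animals improve, high-dyskinetic
#' stay, controls worsen).
#'
#' @param config A [cohort_config].
#' @param group `"LC"`, `"LD"` or `"HD"`.
#' @param seed Integer seed for this animal.
#' @param z Severity latent (standard-normal scale; 0 for the group-typical
#'   animal).
#' @param animal_id Identifier for the generated records.
#' @return A list with `sessions` (list of [aim_session]), `cylinder`
#'   (`pre`/`post` [cylinder_test]), and `cumulative` (integer).
#' @export
generate_behavior <- function(config, group, seed = config$seed, z = 0,
                              animal_id = "A") {
  if (!group %in% c("LC", "LD", "HD")) {
    stop("group must be LC, LD or HD", call. = FALSE)
  }
  set.seed(seed)
  days <- config$days
  n_tp <- config$n_timepoints
  # each animal follows its own line: group-mean slope plus individual spread
  m_animal <- if (group == "LC") 0 else {
    m <- if (group == "LD") config$m_ld else config$m_hd
    if (config$slope_sd > 0) m + stats::rnorm(1, 0, config$slope_sd) else m
  }
  sessions <- vector("list", length(days))
  for (si in seq_along(days)) {
    target <- if (group == "LC") 0 else {
      b <- if (group == "LD") config$b_ld else config$b_hd
      eps <- if (config$score_sd > 0) stats::rnorm(1, 0, config$score_sd) else 0
      round(max(0, m_animal * days[si] + b + config$severity_gain * z + eps))
    }
    target <- min(target, n_tp * 16L)
    m <- matrix(0L, nrow = n_tp, ncol = 4L)
    if (target > 0) {
      q <- target %/% (n_tp * 4L)
      r <- target %% (n_tp * 4L)
      m[] <- q
      if (r > 0) m[seq_len(r)] <- m[seq_len(r)] + 1L
    }
    sessions[[si]] <- aim_session(animal_id, si, m)
  }
  pre_pct <- stats::runif(1, 5, 27)
  pre_left <- round(pre_pct / 100 * 20)
  change <- switch(group, LD = 10, HD = 0, LC = -5) + stats::rnorm(1, 0, 3)
  post_left <- min(20L, max(0L, round((pre_pct + change) / 100 * 20)))
  list(
    sessions = sessions,
    cylinder = list(
      pre = cylinder_test(animal_id, "pre", pre_left, 20L - pre_left),
      post = cylinder_test(animal_id, "post", post_left, 20L - post_left)
    ),
    cumulative = cumulative_score(sessions)
  )
}

# per-spot planted amplitudes for every panel species of one section.
# Lesioned-region means are renormalized to hit the planted folds exactly,
# so the conversion-patch texture never biases the region-level targets.
planted_amplitudes <- function(config, layout, folds) {
  panel <- config$panel
  amps <- matrix(0, nrow = nrow(layout), ncol = nrow(panel),
                 dimnames = list(layout$spot_id, panel$name))
  for (i in seq_len(nrow(panel))) {
    if (panel$base[i] <= 0) next
    raw <- panel$base[i] * pattern_mult(panel$pattern[i], layout$region)
    if (config$conversion_patch && nzchar(panel$patch[i])) {
      pm <- if (panel$patch[i] == "low") 0.5 else 2.5
      raw[layout$patch] <- raw[layout$patch] * pm
    }
    amp <- raw
    for (region in c("SN_medial", "SN_lateral")) {
      les <- layout$hemisphere == "lesioned" & layout$region == region
      int <- layout$hemisphere == "intact" & layout$region == region
      f <- if (region == "SN_medial") folds$f_medial[i] else folds$f_lateral[i]
      target_mean <- f * mean(raw[int])
      amp[les] <- raw[les] * (target_mean / mean(raw[les]))
    }
    amps[, i] <- amp
  }
  amps
}

#' Generate one synthetic imaging-MS section
#'
#' Builds a spectrum for each grid spot as a sum of Gaussian peaks at the
#' catalog \[M+H\]+ m/z values of the panel species, with amplitude = base
#' intensity x spatial pattern x group/hemisphere fold x lognormal noise
#' (configured CV), plus inert background species, a convex exponential
#' chemical baseline, additive white noise, a per-spectrum TIC scale factor
#' and a rigid per-spectrum m/z jitter. Returns the section, its ROI mask
#' and the ground truth (planted amplitudes and areas per spot and species).
#'
#' @param config A [cohort_config].
#' @param animal A list with `id`, `group` and severity latent `w` (use
#'   `w = 0` for a group-typical animal).
#' @param run Run index (1 or 2).
#' @param seed Integer seed.
#' @return A list with `section` ([ims_section]), `mask` ([roi_mask]) and
#'   `truth` (data frame: `spot_id`, `peptide`, `mz`, `amplitude`,
#'   `area_noiseless`, `area` with per-spot noise applied).
#' @export
generate_section <- function(config, animal, run, seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  if (!all(config$panel$name %in% default_catalog()$name)) {
    bad <- setdiff(config$panel$name, default_catalog()$name)
    stop("panel species absent from catalog: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  set.seed(seed)
  layout <- cohort_spot_layout(config)
  folds <- animal_folds(config, animal$group, animal$w)
  amps <- planted_amplitudes(config, layout, folds)

  cat_df <- default_catalog()
  panel_mz <- cat_df$mz_mh[match(config$panel$name, cat_df$name)]
  in_range <- panel_mz >= config$mz_range[1L] + 1 &
    panel_mz <= config$mz_range[2L] - 1

  # inert background species spread over the axis, dodging panel masses
  bg_mz <- seq(config$mz_range[1L] + 5, config$mz_range[2L] - 5,
               length.out = config$background_n)
  for (k in seq_along(bg_mz)) {
    while (any(abs(bg_mz[k] - panel_mz) < 2)) bg_mz[k] <- bg_mz[k] + 2.5
  }

  mz <- seq(config$mz_range[1L], config$mz_range[2L], by = config$mz_step)
  sdp <- config$peak_sd
  area_factor <- sdp * sqrt(2 * pi)

  add_peak <- function(y, center, height) {
    if (height <= 0) return(y)
    lo <- findInterval(center - 6 * sdp, mz) + 1L
    hi <- findInterval(center + 6 * sdp, mz)
    if (hi < lo) return(y)
    idx <- lo:hi
    y[idx] <- y[idx] + height * exp(-(mz[idx] - center)^2 / (2 * sdp^2))
    y
  }

  sdlog <- sqrt(log(1 + config$noise_cv^2))
  spectra <- vector("list", nrow(layout))
  truth <- vector("list", nrow(layout))
  for (s in seq_len(nrow(layout))) {
    jit <- if (config$jitter_max > 0) {
      stats::runif(1, -config$jitter_max, config$jitter_max)
    } else 0
    noise_mult <- if (config$noise_cv > 0) {
      stats::rlnorm(nrow(config$panel), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else rep(1, nrow(config$panel))
    realized <- amps[s, ] * noise_mult
    y <- numeric(length(mz))
    for (i in seq_len(nrow(config$panel))) {
      if (!in_range[i]) next
      y <- add_peak(y, panel_mz[i] + jit, realized[i])
      if (config$isotopes) {
        y <- add_peak(y, panel_mz[i] + jit + 1.00336, realized[i] * 0.5)
        y <- add_peak(y, panel_mz[i] + jit + 2.00671, realized[i] * 0.15)
      }
    }
    bg_mult <- if (config$noise_cv > 0) {
      stats::rlnorm(length(bg_mz), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else rep(1, length(bg_mz))
    for (k in seq_along(bg_mz)) {
      y <- add_peak(y, bg_mz[k] + jit, config$background_base * bg_mult[k])
    }
    if (config$baseline_amp > 0) {
      # exponential chemical background plus a small constant detector
      # offset; both are convex, so hull correction removes them, and the
      # offset keeps the additive noise clear of the non-negativity clamp
      y <- y + config$baseline_amp *
        exp(-(mz - config$mz_range[1L]) / 300) + 0.05 * config$baseline_amp
    }
    if (config$white_noise_sd > 0) {
      y <- y + stats::rnorm(length(mz), 0, config$white_noise_sd)
    }
    scale <- if (config$tic_sd > 0) stats::rlnorm(1, 0, config$tic_sd) else 1
    spectra[[s]] <- mass_spectrum(mz, pmax(y * scale, 0))
    truth[[s]] <- data.frame(
      spot_id = layout$spot_id[s],
      peptide = config$panel$name,
      mz = panel_mz,
      amplitude = realized,
      area_noiseless = amps[s, ] * area_factor,
      area = realized * area_factor,
      in_range = in_range,
      stringsAsFactors = FALSE
    )
  }
  names(spectra) <- layout$spot_id

  section_id <- sprintf("%s_run%d", animal$id, run)
  spots <- layout[, c("spot_id", "col", "row", "hemisphere")]
  section <- ims_section(section_id, animal$id, run, spots, spectra,
                         config$spacing_um)
  mask <- roi_mask(section_id,
                   layout[, c("spot_id", "hemisphere", "region")])
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(section = section, mask = mask, truth = truth)
}

#' Generate a complete synthetic study
#'
#' Draws the animal roster (default 4 lesion controls, 5 low-, 5
#' high-dyskinetic), the per-animal severity latents that couple behavioral
#' severity to peptide elevation at the configured correlation, the
#' behavioral records, and the imaging data — either full spectra
#' (`level = "spectra"`, via [generate_section()]) or the per-spot peak-area
#' tier directly (`level = "areas"`, fast path for statistical simulation).
#' Everything is deterministic given the master seed; per-animal seeds are
#' derived from it and recorded.
#'
#' @param config A [cohort_config].
#' @param seed Master seed (defaults to `config$seed`).
#' @param level `"areas"` or `"spectra"`.
#' @return A list bundle: `config`, `animals` (roster with latents, planted
#'   folds, cumulative scores and seeds), `behavior` (per animal),
#'   `design` (areas level: long data frame of per-run log2 lesioned/intact
#'   region ratios per bin), `truth_bins` (per-bin true lateral log2 fold
#'   and null/alternative label), and `sections` (spectra level).
#' @export
generate_cohort <- function(config = cohort_config(), seed = config$seed,
                            level = c("areas", "spectra")) {
  level <- match.arg(level)
  set.seed(seed)
  groups <- rep(c("LC", "LD", "HD"), c(config$n_lc, config$n_ld, config$n_hd))
  n <- length(groups)
  ids <- sprintf("A%02d", seq_len(n))
  z <- stats::rnorm(n)
  e <- stats::rnorm(n)
  w <- config$rho * z + sqrt(1 - config$rho^2) * e
  seeds <- sample.int(.Machine$integer.max - 1L, n * (config$runs + 1L))
  beh_seeds <- seeds[seq_len(n)]
  sec_seeds <- matrix(seeds[-seq_len(n)], nrow = n)

  behavior <- vector("list", n)
  for (i in seq_len(n)) {
    behavior[[i]] <- generate_behavior(config, groups[i], beh_seeds[i],
                                       z = z[i], animal_id = ids[i])
  }
  names(behavior) <- ids

  animals <- data.frame(
    animal_id = ids, group = groups,
    severity_latent = z, fold_latent = w,
    cumulative = vapply(behavior, `[[`, numeric(1), "cumulative"),
    behavior_seed = beh_seeds,
    stringsAsFactors = FALSE
  )
  # planted lateral log2 fold per animal for the panel's effect species
  eff <- config$panel[!is.na(config$panel$fold_lateral) &
                        config$panel$fold_lateral != 1, ]
  for (pn in eff$name) {
    animals[[paste0("log2fold_lat_", pn)]] <- vapply(seq_len(n), function(i) {
      fl <- animal_folds(config, groups[i], w[i])
      log2(fl$f_lateral[fl$name == pn])
    }, numeric(1))
  }

  cat_df <- default_catalog()
  panel_mz <- cat_df$mz_mh[match(config$panel$name, cat_df$name)]
  truth_bins <- data.frame(
    peptide = config$panel$name, mz = panel_mz,
    true_log2fold_lateral = ifelse(
      is.na(config$panel$fold_lateral), 0, log2(config$panel$fold_lateral)),
    is_null = is.na(config$panel$fold_lateral) |
      config$panel$fold_lateral == 1,
    stringsAsFactors = FALSE
  )

  bundle <- list(config = config, animals = animals, behavior = behavior,
                 truth_bins = truth_bins, level = level)

  if (level == "areas") {
    layout <- cohort_spot_layout(config)
    n_reg <- sum(layout$hemisphere == "intact" &
                   layout$region == "SN_medial")
    sdlog <- sqrt(log(1 + config$noise_cv^2))
    keep <- which(config$panel$base > 0)
    grid <- expand.grid(region = c("SN_medial", "SN_lateral"),
                        j = keep, run = seq_len(config$runs),
                        i = seq_len(n), stringsAsFactors = FALSE)
    # planted fold per (animal, peptide, region)
    fold_tab <- vapply(seq_len(n), function(i) {
      fl <- animal_folds(config, groups[i], w[i])
      c(fl$f_medial, fl$f_lateral)
    }, numeric(2L * nrow(config$panel)))   # (peptide x region) x animal
    np <- nrow(config$panel)
    fold_row <- ifelse(grid$region == "SN_medial", grid$j, grid$j + np)
    f <- fold_tab[cbind(fold_row, grid$i)]
    m <- nrow(grid)
    noise_mean <- function() {
      if (config$noise_cv > 0) {
        rowMeans(matrix(stats::rlnorm(m * n_reg, meanlog = -sdlog^2 / 2,
                                      sdlog = sdlog), nrow = m))
      } else rep(1, m)
    }
    # ROI means: per-spot amplitudes share the region's base level, so the
    # ratio of means reduces to f times the ratio of two lognormal means
    bundle$design <- data.frame(
      animal = ids[grid$i], group = groups[grid$i], run = grid$run,
      region = grid$region, bin = panel_mz[grid$j],
      peptide = config$panel$name[grid$j],
      value = log2(f * noise_mean() / noise_mean()),
      stringsAsFactors = FALSE
    )
  } else {
    sections <- list()
    for (i in seq_len(n)) {
      for (run in seq_len(config$runs)) {
        res <- generate_section(
          config, list(id = ids[i], group = groups[i], w = w[i]),
          run, seed = sec_seeds[i, run])
        sections[[res$section$section_id]] <- res
      }
    }
    bundle$sections <- sections
  }
  bundle
}

#' Write a synthetic study bundle to disk
#'
#' Sections in the csvjson dialect, masks and behavior tables as CSV, and
#' the roster/ground truth as CSV, under one directory.
#'
#' @param bundle A [generate_cohort()] result (spectra level).
#' @param dir Output directory (created if needed).
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bundle$animals, file.path(dir, "animals.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$truth_bins, file.path(dir, "truth_bins.csv"),
                   row.names = FALSE)
  write_aim_csv(lapply(bundle$behavior, `[[`, "sessions"),
                file.path(dir, "aim_scores.csv"))
  cyl <- do.call(rbind, lapply(names(bundle$behavior), function(an) {
    b <- bundle$behavior[[an]]
    data.frame(animal = an,
               occasion = c("pre", "post"),
               left = c(b$cylinder$pre$left, b$cylinder$post$left),
               right = c(b$cylinder$pre$right, b$cylinder$post$right))
  }))
  utils::write.csv(cyl, file.path(dir, "cylinder.csv"), row.names = FALSE)
  if (!is.null(bundle$sections)) {
    for (sid in names(bundle$sections)) {
      res <- bundle$sections[[sid]]
      write_section(res$section, file.path(dir, sid), dialect = "csvjson")
      write_roi_mask(res$mask, file.path(dir, paste0(sid, "_mask.csv")))
      utils::write.csv(res$truth, file.path(dir, paste0(sid, "_truth.csv")),
                       row.names = FALSE)
    }
  }
  if (!is.null(bundle$design)) {
    utils::write.csv(bundle$design, file.path(dir, "design.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}
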