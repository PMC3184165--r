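# small study configuration for spectrum-level tests
tiny_config <- function(...) {
  panel <- default_panel()
  panel <- panel[panel$name %in%
                   c("Leu-Enk-Arg", "aNeo(1-7)", "Leu-Enk-Arg-Arg"), ]
  args <- utils::modifyList(list(
    grid_ncol = 4, grid_nrow = 2, mz_range = c(500, 900), mz_step = 0.05,
    panel = panel, background_n = 8, conversion_patch = FALSE), list(...))
  do.call(cohort_config, args)
}

test_that("noiseless behavior trajectories match the group formulas", {
  cfg <- cohort_config(score_sd = 0, slope_sd = 0)
  ld <- generate_behavior(cfg, "LD", seed = 1)
  # day 15 is the 8th session: round(0.68 * 15 + 0.41) = 11
  expect_equal(session_score(ld$sessions[[8]]), 11L)
  hd <- generate_behavior(cfg, "HD", seed = 1)
  # day 1: round(0.81 + 29.94) = 31
  expect_equal(session_score(hd$sessions[[1]]), 31L)
  lc <- generate_behavior(cfg, "LC", seed = 1)
  expect_true(all(vapply(lc$sessions, session_score, integer(1)) == 0L))
  expect_error(generate_behavior(cfg, "XX"), "group")
})

test_that("generated animals always satisfy the cylinder inclusion rule", {
  cfg <- cohort_config()
  for (seed in 1:20) {
    beh <- generate_behavior(cfg, sample(c("LC", "LD", "HD"), 1), seed)
    expect_true(percent_left_use(beh$cylinder$pre)$include)
  }
})

test_that("section generation is bit-deterministic under a fixed seed", {
  cfg <- tiny_config()
  a <- generate_section(cfg, list(id = "A01", group = "HD", w = 0.3), 1, 99)
  b <- generate_section(cfg, list(id = "A01", group = "HD", w = 0.3), 1, 99)
  expect_identical(a$section$spectra, b$section$spectra)
  expect_identical(a$truth, b$truth)
  c_ <- generate_section(cfg, list(id = "A01", group = "HD", w = 0.3), 1, 100)
  expect_false(identical(a$section$spectra, c_$section$spectra))
})

test_that("noiseless sections integrate back to the planted areas", {
  cfg <- tiny_config(noise_cv = 0, baseline_amp = 0, white_noise_sd = 0,
                     tic_sd = 0, jitter_max = 0)
  res <- generate_section(cfg, list(id = "A01", group = "HD", w = 0), 1, 7)
  truth <- res$truth[res$truth$in_range, ]
  bins <- data.frame(center = sort(unique(truth$mz)), halfwidth = 0.25,
                     count = 1L)
  tab <- integrate_areas(res$section, bins)
  for (k in seq_len(nrow(truth))) {
    j <- which(abs(bins$center - truth$mz[k]) < 1e-9)
    got <- tab$areas[truth$spot_id[k], j]
    expect_equal(unname(got), truth$area[k], tolerance = 0.01)
  }
})

test_that("planted region folds are realized exactly in the noiseless limit", {
  cfg <- tiny_config(noise_cv = 0, baseline_amp = 0, white_noise_sd = 0,
                     tic_sd = 0, jitter_max = 0, conversion_patch = TRUE)
  res <- generate_section(cfg, list(id = "A01", group = "HD", w = 0), 1, 7)
  truth <- res$truth
  lab <- res$mask$labels
  ler <- truth[truth$peptide == "Leu-Enk-Arg", ]
  for (region in c("SN_medial", "SN_lateral")) {
    ids_les <- lab$spot_id[lab$region == region & lab$hemisphere == "lesioned"]
    ids_int <- lab$spot_id[lab$region == region & lab$hemisphere == "intact"]
    fold <- mean(ler$area_noiseless[ler$spot_id %in% ids_les]) /
      mean(ler$area_noiseless[ler$spot_id %in% ids_int])
    expect_equal(fold, if (region == "SN_lateral") 1.5 else 1,
                 tolerance = 1e-9)
  }
})

test_that("unknown panel species are rejected", {
  cfg <- tiny_config()
  cfg$panel$name[1] <- "Mystery Peptide"
  expect_error(generate_section(cfg, list(id = "A", group = "LC", w = 0), 1, 1),
               "absent from catalog")
})

test_that("the knockout scenario removes dynorphin bins but not substance P", {
  panel <- default_panel()
  panel <- panel[panel$name %in%
                   c("Leu-Enk-Arg", "Dyn A(1-8)", "Substance P"), ]
  cfg <- cohort_config(grid_ncol = 4, grid_nrow = 2,
                       mz_range = c(500, 1400), mz_step = 0.05,
                       panel = panel, background_n = 8,
                       conversion_patch = FALSE, knockout = TRUE)
  res <- generate_section(cfg, list(id = "A01", group = "HD", w = 0), 1, 3)
  proc <- process_section(res$section, reference_mz = NULL)
  has_bin <- function(target) any(abs(proc$bins$center - target) < 0.3)
  expect_false(has_bin(712.3777))   # Leu-Enk-Arg gone
  expect_false(has_bin(981.5628))   # Dyn A(1-8) gone
  expect_true(has_bin(1347.7354))   # substance P unchanged
})

test_that("the default cohort has the study's group structure", {
  b <- generate_cohort(cohort_config(), seed = 5, level = "areas")
  expect_equal(nrow(b$animals), 14L)
  expect_equal(as.integer(table(b$animals$group)[c("LC", "LD", "HD")]),
               c(4L, 5L, 5L))
  expect_equal(length(b$behavior), 14L)
  # every panel bin has a ground-truth twin
  expect_setequal(unique(b$design$peptide), b$truth_bins$peptide)
  expect_true(all(c("severity_latent", "fold_latent") %in%
                    names(b$animals)))

  b2 <- generate_cohort(cohort_config(), seed = 5, level = "areas")
  expect_identical(b$design$value, b2$design$value)
  expect_identical(b$animals, b2$animals)
})

test_that("spectra-level cohorts carry sections, masks and ground truth", {
  cfg <- tiny_config(n_lc = 1, n_ld = 1, n_hd = 1, runs = 2)
  b <- generate_cohort(cfg, seed = 2, level = "spectra")
  expect_equal(length(b$sections), 6L)
  for (res in b$sections) {
    expect_s3_class(res$section, "ims_section")
    expect_setequal(res$mask$labels$spot_id, res$section$spots$spot_id)
    expect_equal(nrow(res$truth),
                 nrow(res$section$spots) * nrow(cfg$panel))
  }
})

test_that("severity coupling is off when rho is zero", {
  cors <- vapply(1:50, function(s) {
    b <- generate_cohort(cohort_config(rho = 0), seed = s, level = "areas")
    tr <- b$animals$group != "LC"
    cor(b$animals$severity_latent[tr], b$animals$fold_latent[tr])
  }, numeric(1))
  expect_lt(abs(mean(cors)), 0.1)
})

test_that("a cohort bundle can be written to disk as plain text", {
  cfg <- tiny_config(n_lc = 1, n_ld = 1, n_hd = 1, runs = 1)
  b <- generate_cohort(cfg, seed = 4, level = "spectra")
  dir <- tempfile()
  write_cohort(b, dir)
  expect_true(file.exists(file.path(dir, "animals.csv")))
  expect_true(file.exists(file.path(dir, "aim_scores.csv")))
  expect_true(file.exists(file.path(dir, "cylinder.csv")))
  sid <- names(b$sections)[1]
  back <- read_section(file.path(dir, sid), "csvjson")
  expect_identical(back$spectra[[1]]$intensity,
                   b$sections[[sid]]$section$spectra[[1]]$intensity)
})
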