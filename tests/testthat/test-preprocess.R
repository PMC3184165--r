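test_that("convex-hull baseline removes constant and linear backgrounds exactly", {
  mz <- seq(500, 600, by = 0.5)
  const <- mass_spectrum(mz, rep(7.5, length(mz)))
  expect_equal(baseline_convex_hull(const)$intensity, rep(0, length(mz)))

  ramp <- mass_spectrum(mz, 0.3 * mz + 10)
  expect_equal(baseline_convex_hull(ramp)$intensity, rep(0, length(mz)),
               tolerance = 1e-9)

  expect_error(baseline_convex_hull(mass_spectrum(c(1, 2), c(1, 1))),
               "3 points")
})

test_that("baseline correction preserves a Gaussian riding on a ramp", {
  A <- 50
  s <- gaussian_spectrum(center = 700, amplitude = A, sd = 0.2,
                         from = 690, to = 710, step = 0.01,
                         baseline = function(mz) 2 * (mz - 690) + 5)
  out <- baseline_convex_hull(s)
  expect_equal(max(out$intensity), A, tolerance = 0.01)
  expect_equal(out$intensity[1], 0)
  expect_equal(out$intensity[length(out$intensity)], 0)
})

test_that("baseline correction is idempotent", {
  set.seed(21)
  for (k in 1:5) {
    mz <- seq(500, 520, by = 0.1)
    s <- mass_spectrum(mz, runif(length(mz), 0, 100))
    b1 <- baseline_convex_hull(s)
    b2 <- baseline_convex_hull(b1)
    expect_equal(b2$intensity, b1$intensity, tolerance = 1e-10)
  }
})

test_that("TIC normalization rescales to the target and is idempotent", {
  s <- mass_spectrum(c(500, 501, 502, 503), c(1, 2, 3, 4))
  out <- tic_normalize(s, 1)
  expect_equal(tic(out), 1, tolerance = 1e-9)
  expect_equal(out$intensity, c(1, 2, 3, 4) / 10)

  # proportional spectra normalize to identical outputs
  s2 <- mass_spectrum(s$mz, s$intensity * 13)
  expect_equal(tic_normalize(s2, 1)$intensity, out$intensity,
               tolerance = 1e-12)

  expect_equal(tic_normalize(out, 1)$intensity, out$intensity,
               tolerance = 1e-12)

  zero <- mass_spectrum(c(500, 501), c(0, 0))
  expect_error(tic_normalize(zero, 1), "zero TIC")
})

test_that("alignment recovers planted rigid shifts", {
  refs <- c(700, 705, 712)
  make_shifted <- function(shift) {
    mz <- seq(695, 717, by = 0.01)
    y <- rowSums(sapply(refs, function(r) {
      80 * exp(-(mz - r - shift)^2 / (2 * 0.1^2))
    }))
    mass_spectrum(mz, y)
  }
  res <- align_spectra(list(make_shifted(0.40), make_shifted(0)),
                       reference_mz = refs, max_shift = 1.0)
  expect_equal(res$shifts[1], 0.40, tolerance = 0.05)
  expect_equal(res$shifts[2], 0, tolerance = 0.05)
  expect_equal(res$flags, c("", ""))
  # corrected spectrum has its apex back at the reference
  apex_mz <- res$spectra[[1]]$mz[which.max(res$spectra[[1]]$intensity)]
  expect_equal(min(abs(apex_mz - refs)), 0, tolerance = 0.05)
})

test_that("alignment clamps out-of-range shifts and flags missing references", {
  mz <- seq(695, 717, by = 0.01)
  y <- 80 * exp(-(mz - 702)^2 / (2 * 0.1^2))
  displaced <- mass_spectrum(mz, y)  # true peak at 700 shifted by +2.0
  res <- align_spectra(list(displaced), reference_mz = 700, max_shift = 1.0)
  expect_equal(res$flags[1], "clamped")
  expect_lte(abs(res$shifts[1]), 1.0)

  out_of_range <- align_spectra(list(displaced), reference_mz = 2000,
                                max_shift = 1.0)
  expect_equal(out_of_range$flags[1], "no_reference")
  expect_equal(out_of_range$shifts[1], 0)
  expect_equal(out_of_range$spectra[[1]]$intensity, displaced$intensity)
})

test_that("TIC normalization commutes with alignment", {
  mz <- seq(695, 717, by = 0.01)
  y <- 80 * exp(-(mz - 705.3)^2 / (2 * 0.1^2)) +
    40 * exp(-(mz - 710.3)^2 / (2 * 0.1^2))
  s <- mass_spectrum(mz, y)
  refs <- c(705, 710)
  a_then_n <- tic_normalize(
    align_spectra(list(s), refs, max_shift = 1)$spectra[[1]], 1)
  n_then_a <- align_spectra(list(tic_normalize(s, 1)), refs,
                            max_shift = 1)$spectra[[1]]
  expect_equal(a_then_n$intensity, n_then_a$intensity, tolerance = 1e-6)
})

test_that("peak detection finds nothing in flat spectra", {
  flat <- mass_spectrum(seq(500, 510, by = 0.01), rep(0, 1001))
  expect_equal(nrow(detect_peaks(flat)), 0L)
})

test_that("a single strong Gaussian is detected exactly once at its apex", {
  set.seed(5)
  # TOF-like sampling (~1 sample per peak sd); noise rides on a positive
  # pedestal, as after baseline correction
  mz <- seq(500, 520, by = 0.05)
  noise_sd <- 1
  y <- pmax(10 * noise_sd * exp(-(mz - 510)^2 / (2 * 0.06^2)) +
              rnorm(length(mz), 5, noise_sd), 0)
  s <- mass_spectrum(mz, y)
  pk <- detect_peaks(s, snr_min = 3)
  strong <- pk[pk$snr > 5, ]
  expect_equal(nrow(strong), 1L)
  expect_equal(strong$mz, 510, tolerance = 0.051)
  expect_true(all(pk$left_mz < pk$mz & pk$mz < pk$right_mz))
})

test_that("peak detection equals the exhaustive S/N oracle on noisy spectra", {
  for (seed in c(1, 2, 3)) {
    set.seed(seed)
    n <- sample(800:2000, 1)
    mz <- 500 + seq_len(n) * 0.01
    y <- pmax(rnorm(n, 5, 1), 0)
    # sprinkle a few genuine peaks
    for (c0 in sample(mz[50:(n - 50)], 4)) {
      y <- y + runif(1, 8, 30) * exp(-(mz - c0)^2 / (2 * 0.03^2))
    }
    s <- mass_spectrum(mz, y)
    got <- detect_peaks(s, snr_min = 3, noise_halfwindow = 50L)
    expect_equal(got$mz, oracle_detect(s, 3, 50L))
  }
})

test_that("binning groups jittered apexes and separates distinct populations", {
  # identical apexes across spectra: one bin per distinct apex
  pl <- replicate(5, data.frame(mz = c(700.0, 712.38)), simplify = FALSE)
  bins <- bin_peaks(pl, tol = 0.3)
  expect_equal(bins$center, c(700.0, 712.38))
  expect_equal(bins$count, c(5L, 5L))

  set.seed(9)
  jit <- lapply(1:50, function(i) data.frame(mz = 712.38 + runif(1, -0.05, 0.05)))
  bins <- bin_peaks(jit, tol = 0.15)
  expect_equal(nrow(bins), 1L)
  expect_equal(bins$center, 712.38, tolerance = 0.02)

  two <- lapply(1:20, function(i) data.frame(mz = c(712.38, 712.80)))
  expect_equal(nrow(bin_peaks(two, tol = 0.15)), 2L)

  expect_equal(nrow(bin_peaks(list(data.frame(mz = numeric(0))), 0.3)), 0L)
})

test_that("binning partitions every apex and bins never overlap", {
  set.seed(31)
  for (k in 1:5) {
    centers <- sort(runif(6, 500, 600))
    apexes <- unlist(lapply(centers, function(c0) c0 + rnorm(20, 0, 0.02)))
    pl <- list(data.frame(mz = apexes))
    bins <- bin_peaks(pl, tol = 0.15)
    expect_equal(sum(bins$count), length(apexes))
    if (nrow(bins) > 1L) {
      upper <- bins$center + bins$halfwidth
      lower <- bins$center - bins$halfwidth
      expect_true(all(upper[-nrow(bins)] < lower[-1L]))
    }
  }
})

test_that("area integration matches closed forms", {
  # unit triangle: base 1 Da, height 1 -> area 0.5
  mz <- seq(699, 701, by = 0.005)
  tri <- pmax(1 - abs(mz - 700) / 0.5, 0)
  sec <- toy_section(1, spectrum_fun = function(i) mass_spectrum(mz, tri))
  bins <- data.frame(center = 700, halfwidth = 0.6, count = 1L)
  tab <- integrate_areas(sec, bins)
  expect_equal(unname(tab$areas[1, 1]), 0.5, tolerance = 1e-6)

  # Gaussian amplitude A, sd sigma: area A * sigma * sqrt(2 pi)
  A <- 40; sigma <- 0.08
  g <- A * exp(-(mz - 700)^2 / (2 * sigma^2))
  sec <- toy_section(1, spectrum_fun = function(i) mass_spectrum(mz, g))
  tab <- integrate_areas(sec, bins)
  expect_equal(unname(tab$areas[1, 1]), A * sigma * sqrt(2 * pi),
               tolerance = 0.01)

  # empty window -> 0; bin outside the mass range -> NA
  zero <- toy_section(1, spectrum_fun = function(i) {
    mass_spectrum(mz, rep(0, length(mz)))
  })
  bins2 <- data.frame(center = c(700, 900), halfwidth = c(0.6, 0.6),
                      count = c(1L, 1L))
  tab <- integrate_areas(zero, bins2)
  expect_equal(unname(tab$areas[1, 1]), 0)
  expect_true(is.na(tab$areas[1, 2]))
})

test_that("the processing chain produces a provenance-flagged table", {
  mz <- seq(690, 720, by = 0.01)
  sec <- toy_section(4, spectrum_fun = function(i) {
    set.seed(i)
    y <- pmax(100 * exp(-(mz - 700)^2 / (2 * 0.05^2)) +
                60 * exp(-(mz - 712.4)^2 / (2 * 0.05^2)) +
                rnorm(length(mz), 5, 1), 0)
    mass_spectrum(mz, y)
  })
  # require peaks in every spectrum so sporadic noise maxima drop out
  proc <- process_section(sec, reference_mz = c(700, 712.4),
                          min_bin_frac = 1)
  expect_true(proc$table$normalized)
  expect_true(proc$table$aligned)
  expect_equal(nrow(proc$bins), 2L)
  expect_equal(proc$bins$center, c(700, 712.4), tolerance = 0.02)
})
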