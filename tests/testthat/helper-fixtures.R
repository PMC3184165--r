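# Fixtures and independent oracles shared across test files.

# Gaussian peak on a regular m/z axis
gaussian_spectrum <- function(center = 700, amplitude = 100, sd = 0.1,
                              from = 690, to = 710, step = 0.01,
                              baseline = function(mz) 0) {
  mz <- seq(from, to, by = step)
  mass_spectrum(mz, pmax(amplitude * exp(-(mz - center)^2 / (2 * sd^2)) +
                           baseline(mz), 0))
}

# tiny section: n spots on a 2-column grid sharing one spectrum builder
toy_section <- function(n = 4, spectrum_fun = function(i) {
  mass_spectrum(seq(500, 510, by = 0.5), rep(i, 21))
}, run_id = 1) {
  cols <- (seq_len(n) - 1L) %% 2L
  rows <- (seq_len(n) - 1L) %/% 2L
  ids <- sprintf("s%02d", seq_len(n))
  spots <- data.frame(spot_id = ids, col = cols, row = rows,
                      hemisphere = rep(c("intact", "lesioned"), length.out = n),
                      stringsAsFactors = FALSE)
  spectra <- lapply(seq_len(n), spectrum_fun)
  names(spectra) <- ids
  ims_section("sec1", "A01", run_id, spots, spectra)
}

# random valid section for round-trip properties
random_section <- function(seed, n_spots = 5, n_points = 40) {
  set.seed(seed)
  ids <- sprintf("s%02d", seq_len(n_spots))
  spots <- data.frame(
    spot_id = ids,
    col = (seq_len(n_spots) - 1L) %% 3L,
    row = (seq_len(n_spots) - 1L) %/% 3L,
    hemisphere = sample(c("intact", "lesioned"), n_spots, replace = TRUE),
    stringsAsFactors = FALSE)
  spectra <- lapply(seq_len(n_spots), function(i) {
    mz <- 500 + cumsum(runif(n_points, 0.01, 2))
    mass_spectrum(mz, runif(n_points, 0, 1000))
  })
  names(spectra) <- ids
  ims_section(sprintf("sec%d", seed), "A01", 1L, spots, spectra)
}

# exhaustive reference implementation of the S/N peak detector:
# scan every interior point, test strict local maximum, estimate the local
# baseline (window median) and noise (window MAD x 1.4826), keep
# (apex - baseline)/noise > snr_min
oracle_detect <- function(s, snr_min = 3, noise_halfwindow = 100L) {
  y <- s$intensity
  n <- length(y)
  hits <- integer(0)
  for (i in 2:(n - 1L)) {
    if (!(y[i] > y[i - 1L] && y[i] > y[i + 1L])) next
    w <- y[max(1L, i - noise_halfwindow):min(n, i + noise_halfwindow)]
    med <- stats::median(w)
    noise <- 1.4826 * stats::median(abs(w - med))
    signal <- y[i] - med
    snr <- if (noise > 0) signal / noise else if (signal > 0) Inf else 0
    if (snr > snr_min) hits <- c(hits, i)
  }
  s$mz[hits]
}

# single-linkage clustering oracle for peak binning
oracle_single_linkage_bins <- function(apexes, tol) {
  apexes <- sort(apexes)
  if (length(apexes) == 1L) return(data.frame(center = apexes, count = 1L))
  cl <- stats::cutree(stats::hclust(stats::dist(apexes), method = "single"),
                      h = tol)
  centers <- tapply(apexes, cl, mean)
  data.frame(center = sort(as.numeric(centers)),
             count = as.integer(table(cl)[order(centers)]))
}

# hand step-up BH oracle
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}
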