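#' Convex-hull baseline correction
#'
#' Subtracts the lower convex hull (greatest convex minorant) of the
#' (m/z, intensity) point set from the spectrum, the classical baseline model
#' for MALDI-TOF spectra whose chemical background decays smoothly and
#' convexly with m/z. The corrected intensities are non-negative and both
#' endpoints map to zero; applying the correction twice is a no-op.
#'
#' @param s A [mass_spectrum] with at least 3 points.
#' @return The baseline-corrected [mass_spectrum].
#' @export
baseline_convex_hull <- function(s) {
  stopifnot(inherits(s, "mass_spectrum"))
  n <- length(s$mz)
  if (n < 3L) stop("spectrum must have at least 3 points", call. = FALSE)
  idx <- lower_hull_indices(s$mz, s$intensity)
  baseline <- stats::approx(s$mz[idx], s$intensity[idx], xout = s$mz,
                            method = "linear", rule = 2)$y
  corrected <- pmax(s$intensity - baseline, 0)
  mass_spectrum(s$mz, corrected)
}

# Andrew's monotone-chain lower hull on points already sorted by x.
lower_hull_indices <- function(x, y) {
  n <- length(x)
  hull <- integer(n)
  k <- 0L
  for (i in seq_len(n)) {
    while (k >= 2L) {
      a <- hull[k - 1L]; b <- hull[k]
      # drop b if it lies on or above segment a->i (non-left turn)
      cross <- (x[b] - x[a]) * (y[i] - y[a]) - (y[b] - y[a]) * (x[i] - x[a])
      if (cross <= 0) k <- k - 1L else break
    }
    k <- k + 1L
    hull[k] <- i
  }
  hull[seq_len(k)]
}

#' Total-ion-current normalization
#'
#' Rescales one spectrum so that its TIC equals `target_tic`, removing
#' per-spot variation in matrix deposition and ionization efficiency.
#' Applied to each spectrum individually.
#'
#' @param s A [mass_spectrum] with positive TIC.
#' @param target_tic Positive target TIC; typically the dataset mean raw TIC
#'   so normalized intensities stay on a familiar scale.
#' @return The normalized [mass_spectrum].
#' @export
tic_normalize <- function(s, target_tic) {
  stopifnot(inherits(s, "mass_spectrum"), target_tic > 0)
  total <- tic(s)
  if (total <= 0) {
    stop("zero TIC: spot should have been removed by QC", call. = FALSE)
  }
  mass_spectrum(s$mz, s$intensity * (target_tic / total))
}

#' Rigid m/z alignment of spectra to reference peaks
#'
#' Estimates one rigid m/z shift per spectrum by maximizing the
#' cross-correlation of the spectrum's intensity with Gaussian templates
#' centred on the reference m/z values, then applies the shift by linear
#' interpolation back onto the original m/z axis. TOF drift at this mass
#' range is locally rigid, so a single shift parameter per spectrum is used
#' (no stretch).
#'
#' @param spectra List of [mass_spectrum].
#' @param reference_mz Non-empty numeric vector of reference peak m/z.
#' @param max_shift Maximum |shift| searched (Da).
#' @param shift_step Search grid resolution (Da, default 0.01).
#' @param window Half-width of the correlation window around each reference
#'   peak (Da).
#' @param template_sd Gaussian template standard deviation (Da).
#' @return A list with `spectra` (aligned), `shifts` (Da, one per spectrum)
#'   and `flags` (character: `""`, `"clamped"` when the estimate hit the
#'   search boundary, `"no_reference"` when no reference peak lies in the
#'   spectrum's range, in which case it is returned unshifted).
#' @export
align_spectra <- function(spectra, reference_mz, max_shift = 1.0,
                          shift_step = 0.01, window = 0.5,
                          template_sd = 0.1) {
  stopifnot(length(reference_mz) > 0L, max_shift > 0)
  shifts_grid <- seq(-max_shift, max_shift, by = shift_step)
  w <- seq(-window, window, by = shift_step)
  gw <- stats::dnorm(w, sd = template_sd)

  out_spectra <- vector("list", length(spectra))
  shifts <- numeric(length(spectra))
  flags <- character(length(spectra))
  for (k in seq_along(spectra)) {
    s <- spectra[[k]]
    refs <- reference_mz[reference_mz >= min(s$mz) & reference_mz <= max(s$mz)]
    if (length(refs) == 0L) {
      out_spectra[[k]] <- s
      shifts[k] <- 0
      flags[k] <- "no_reference"
      next
    }
    # query all (ref + shift + w) positions in one interpolation call
    grid <- outer(w, shifts_grid, `+`)            # n_w x n_shift
    q <- as.vector(outer(as.vector(grid), refs, `+`))
    iq <- stats::approx(s$mz, s$intensity, xout = q, method = "linear",
                        rule = 1)$y
    iq[is.na(iq)] <- 0
    arr <- array(iq, dim = c(length(w), length(shifts_grid), length(refs)))
    score <- apply(arr, 2, function(m) sum(m * gw))
    best <- shifts_grid[which.max(score)]
    flag <- ""
    if (abs(best) >= max_shift - shift_step / 2) flag <- "clamped"
    shifted <- stats::approx(s$mz, s$intensity, xout = s$mz + best,
                             method = "linear", rule = 1)$y
    shifted[is.na(shifted)] <- 0
    out_spectra[[k]] <- mass_spectrum(s$mz, pmax(shifted, 0))
    shifts[k] <- best
    flags[k] <- flag
  }
  names(out_spectra) <- names(spectra)
  list(spectra = out_spectra, shifts = shifts, flags = flags)
}

#' Peak detection by local maxima above a robust noise floor
#'
#' Detects peaks in a baseline-corrected spectrum as strict local maxima
#' whose signal-to-noise ratio exceeds `snr_min` (default 3). Both the local
#' baseline level and the noise are estimated robustly over a sliding window
#' of `2 * noise_halfwindow + 1` samples centred on each candidate apex: the
#' baseline as the window median, the noise as the median absolute deviation
#' times 1.4826. S/N is the apex height above the window median divided by
#' the noise, which reduces to apex/noise for a zero-centred residual and
#' stays calibrated when the baseline correction leaves a small positive
#' offset. Integration bounds are placed at the nearest local minima
#' flanking each apex.
#'
#' @param s A baseline-corrected [mass_spectrum].
#' @param snr_min Minimum signal-to-noise ratio (default 3).
#' @param noise_halfwindow Half-window for the noise estimate, in samples.
#' @return A data frame (class `peak_list`) with columns `mz`, `intensity`,
#'   `left_mz`, `right_mz`, `snr`; zero rows when no peak qualifies.
#' @export
detect_peaks <- function(s, snr_min = 3, noise_halfwindow = 100L) {
  stopifnot(inherits(s, "mass_spectrum"))
  y <- s$intensity
  n <- length(y)
  empty <- data.frame(mz = numeric(0), intensity = numeric(0),
                      left_mz = numeric(0), right_mz = numeric(0),
                      snr = numeric(0))
  class(empty) <- c("peak_list", "data.frame")
  if (n < 3L) return(empty)
  interior <- 2:(n - 1L)
  is_max <- y[interior] > y[interior - 1L] & y[interior] > y[interior + 1L]
  apexes <- interior[is_max]
  if (length(apexes) == 0L) return(empty)

  mm <- window_med_mad(y, apexes, as.integer(noise_halfwindow))
  signal <- y[apexes] - mm[, 1L]
  noise <- mm[, 2L]
  snr <- ifelse(noise > 0, signal / noise,
                ifelse(signal > 0, Inf, 0))
  keep <- snr > snr_min
  apexes <- apexes[keep]
  snr <- snr[keep]
  if (length(apexes) == 0L) return(empty)

  # local minima (non-strict, catches flat zero stretches) plus both ends
  minima <- c(1L,
              interior[y[interior] <= y[interior - 1L] &
                       y[interior] <= y[interior + 1L]],
              n)
  left <- vapply(apexes, function(i) max(minima[minima < i]), integer(1))
  right <- vapply(apexes, function(i) min(minima[minima > i]), integer(1))

  out <- data.frame(mz = s$mz[apexes], intensity = y[apexes],
                    left_mz = s$mz[left], right_mz = s$mz[right], snr = snr)
  class(out) <- c("peak_list", "data.frame")
  out
}

#' Greedy m/z binning of peaks across spectra
#'
#' Pools all apex m/z values from a set of peak lists, sorts them ascending,
#' and opens a new bin whenever the next apex is more than `tol` away from
#' the current bin's running mean. Bin centers are the means of member
#' apexes. The pass is single and strictly by ascending m/z with no re-merge,
#' so the result is deterministic for fixed input. Half-widths cover the
#' member spread (with a floor of `tol / 2`), capped so adjacent bin
#' intervals never overlap.
#'
#' @param peaklists List of peak lists (data frames with an `mz` column).
#' @param tol Positive binning tolerance (Da, default 0.3 for unit-resolution
#'   TOF data).
#' @return A data frame with columns `center`, `halfwidth`, `count`; zero
#'   rows when all peak lists are empty.
#' @export
bin_peaks <- function(peaklists, tol = 0.3) {
  stopifnot(tol > 0)
  apexes <- sort(unlist(lapply(peaklists, function(p) p$mz),
                        use.names = FALSE))
  if (length(apexes) == 0L) {
    return(data.frame(center = numeric(0), halfwidth = numeric(0),
                      count = integer(0)))
  }
  centers <- numeric(0); counts <- integer(0); spreads <- numeric(0)
  cur_sum <- apexes[1L]; cur_n <- 1L; cur_members_start <- 1L
  flush <- function(center, members) {
    centers <<- c(centers, center)
    counts <<- c(counts, length(members))
    spreads <<- c(spreads, max(abs(members - center)))
  }
  for (i in seq_along(apexes)[-1L]) {
    mean_cur <- cur_sum / cur_n
    if (apexes[i] - mean_cur > tol) {
      flush(mean_cur, apexes[cur_members_start:(i - 1L)])
      cur_sum <- apexes[i]; cur_n <- 1L; cur_members_start <- i
    } else {
      cur_sum <- cur_sum + apexes[i]; cur_n <- cur_n + 1L
    }
  }
  flush(cur_sum / cur_n, apexes[cur_members_start:length(apexes)])

  hw <- pmax(spreads, tol / 2)
  if (length(centers) > 1L) {
    gaps <- diff(centers)
    cap <- pmin(c(Inf, gaps), c(gaps, Inf)) * 0.4999
    hw <- pmin(hw, cap)
  }
  data.frame(center = centers, halfwidth = hw, count = counts)
}

#' Integrate peak areas per spot and bin
#'
#' For every spot spectrum and every bin, computes the trapezoidal area under
#' the intensity curve over the window `center +/- halfwidth` (half-width
#' floored at `min_halfwidth`, default 0.25 Da, reflecting unit-resolution
#' TOF peak widths). Window endpoints are linearly interpolated. Bins lying
#' entirely outside a spectrum's m/z range are recorded as `NA` (missing, not
#' zero); windows containing no signal integrate to 0.
#'
#' @param section An [ims_section] whose spectra are baseline-corrected and
#'   normalized.
#' @param bins Bin definitions from [bin_peaks()].
#' @param min_halfwidth Integration half-width floor (Da).
#' @param normalized,aligned Provenance flags recorded in the output.
#' @return A [peak_bin_table].
#' @export
integrate_areas <- function(section, bins, min_halfwidth = 0.25,
                            normalized = FALSE, aligned = FALSE) {
  stopifnot(inherits(section, "ims_section"), nrow(bins) > 0L)
  ids <- section$spots$spot_id
  hw <- pmax(bins$halfwidth, min_halfwidth)
  areas <- matrix(NA_real_, nrow = length(ids), ncol = nrow(bins),
                  dimnames = list(ids, NULL))
  interp_at <- function(mz, int, x) {
    i <- findInterval(x, mz, all.inside = TRUE)
    int[i] + (int[i + 1L] - int[i]) * (x - mz[i]) / (mz[i + 1L] - mz[i])
  }
  for (k in seq_along(ids)) {
    s <- section$spectra[[ids[k]]]
    rng <- range(s$mz)
    for (j in seq_len(nrow(bins))) {
      lo <- bins$center[j] - hw[j]
      hi <- bins$center[j] + hw[j]
      if (hi < rng[1L] || lo > rng[2L]) next  # stays NA: out of range
      lo_c <- max(lo, rng[1L]); hi_c <- min(hi, rng[2L])
      i0 <- findInterval(lo_c, s$mz) + 1L   # first sample strictly inside
      i1 <- findInterval(hi_c, s$mz)        # last sample at or below hi_c
      if (i1 >= i0 && s$mz[i1] == hi_c) i1 <- i1 - 1L
      inside <- if (i1 >= i0) i0:i1 else integer(0)
      xs <- c(lo_c, s$mz[inside], hi_c)
      ys <- c(interp_at(s$mz, s$intensity, lo_c),
              s$intensity[inside],
              interp_at(s$mz, s$intensity, hi_c))
      areas[k, j] <- max(pracma::trapz(xs, ys), 0)
    }
  }
  peak_bin_table(section$section_id, bins$center, areas,
                 normalized = normalized, aligned = aligned)
}

#' Run the full spectral processing chain on one section
#'
#' Applies the canonical stage order — baseline correction, TIC
#' normalization, alignment (when reference peaks are supplied), peak
#' detection, cross-spectrum binning and area integration — and returns the
#' section's peak-area table together with stage diagnostics.
#'
#' @param section A raw [ims_section].
#' @param reference_mz Optional reference peak m/z for alignment; `NULL`
#'   skips the alignment stage.
#' @param target_tic Target TIC; default is the section's mean raw TIC.
#' @param snr_min,bin_tol,min_halfwidth,max_shift Stage parameters, see the
#'   individual stage functions.
#' @param min_bin_frac Keep only bins whose member-peak count reaches this
#'   fraction of the section's spot count (default 0.5), discarding sporadic
#'   noise peaks that are not reproduced across spectra.
#' @return A list with `table` (a [peak_bin_table]), `bins`, `shifts`,
#'   `n_peaks` (per spot) and `target_tic`.
#' @export
process_section <- function(section, reference_mz = NULL, target_tic = NULL,
                            snr_min = 3, bin_tol = 0.3, min_halfwidth = 0.25,
                            max_shift = 0.5, min_bin_frac = 0.5) {
  stopifnot(inherits(section, "ims_section"))
  spectra <- section$spectra
  spectra <- lapply(spectra, baseline_convex_hull)
  if (is.null(target_tic)) {
    target_tic <- mean(vapply(section$spectra, tic, numeric(1)))
  }
  spectra <- lapply(spectra, tic_normalize, target_tic = target_tic)
  shifts <- rep(0, length(spectra))
  aligned <- FALSE
  if (!is.null(reference_mz)) {
    al <- align_spectra(spectra, reference_mz, max_shift = max_shift)
    spectra <- al$spectra
    shifts <- al$shifts
    aligned <- TRUE
  }
  peaklists <- lapply(spectra, detect_peaks, snr_min = snr_min)
  bins <- bin_peaks(peaklists, tol = bin_tol)
  bins <- bins[bins$count >= min_bin_frac * length(spectra), , drop = FALSE]
  if (nrow(bins) == 0L) {
    stop("no peaks detected in section ", section$section_id, call. = FALSE)
  }
  proc <- section
  proc$spectra <- spectra
  table <- integrate_areas(proc, bins, min_halfwidth = min_halfwidth,
                           normalized = TRUE, aligned = aligned)
  list(table = table, bins = bins, shifts = shifts,
       n_peaks = vapply(peaklists, nrow, integer(1)),
       target_tic = target_tic)
}
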