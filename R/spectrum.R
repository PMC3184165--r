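#' Construct a mass spectrum
#'
#' A single MALDI-TOF spectrum for one matrix spot: paired m/z and intensity
#' arrays. m/z must be strictly increasing and intensities non-negative.
#'
#' @param mz Numeric vector of m/z values (Da), strictly increasing, length
#'   >= 2.
#' @param intensity Numeric vector of intensities, same length, all >= 0.
#' @return An object of class `mass_spectrum`.
#' @export
mass_spectrum <- function(mz, intensity) {
  if (!is.numeric(mz) || !is.numeric(intensity)) {
    stop("mz and intensity must be numeric", call. = FALSE)
  }
  if (length(mz) != length(intensity) || length(mz) < 2L) {
    stop("mz and intensity must have equal length >= 2", call. = FALSE)
  }
  if (anyNA(mz) || anyNA(intensity)) stop("NA in spectrum", call. = FALSE)
  if (any(diff(mz) <= 0)) {
    stop("mz must be strictly increasing", call. = FALSE)
  }
  if (any(intensity < 0)) stop("negative intensity", call. = FALSE)
  structure(list(mz = as.numeric(mz), intensity = as.numeric(intensity)),
            class = "mass_spectrum")
}

#' @export
print.mass_spectrum <- function(x, ...) {
  cat(sprintf("<mass_spectrum> %d points, m/z %.2f-%.2f, TIC %.4g\n",
              length(x$mz), min(x$mz), max(x$mz), tic(x)))
  invisible(x)
}

#' Total ion current of a spectrum
#'
#' @param s A [mass_spectrum].
#' @return Sum of all intensities.
#' @export
tic <- function(s) {
  stopifnot(inherits(s, "mass_spectrum"))
  sum(s$intensity)
}

#' Construct an imaging-MS section
#'
#' One tissue section acquired in one analysis run: a 2-D grid of matrix
#' spots (default spacing 250 um) with one spectrum and one hemisphere label
#' per spot. Experiments are acquired in duplicate runs on consecutive
#' sections, so `run_id` is 1 or 2.
#'
#' @param section_id,animal_id Identifiers.
#' @param run_id Integer, 1 or 2 (duplicate experiment index).
#' @param spots Data frame with columns `spot_id` (unique character), `col`,
#'   `row` (0-based integer grid coordinates, unique pairs) and `hemisphere`
#'   (`"intact"` or `"lesioned"`).
#' @param spectra Named list of [mass_spectrum], names matching `spot_id`.
#' @param spacing_um Grid spacing in micrometres (default 250).
#' @return An object of class `ims_section`.
#' @export
ims_section <- function(section_id, animal_id, run_id, spots, spectra,
                        spacing_um = 250) {
  stopifnot(is.data.frame(spots))
  need <- c("spot_id", "col", "row", "hemisphere")
  if (!all(need %in% names(spots))) {
    stop("spots must have columns spot_id, col, row, hemisphere",
         call. = FALSE)
  }
  if (!run_id %in% c(1L, 2L)) stop("run_id must be 1 or 2", call. = FALSE)
  if (anyDuplicated(spots$spot_id)) {
    stop("duplicate spot_id", call. = FALSE)
  }
  if (anyDuplicated(spots[, c("col", "row")])) {
    stop("duplicate grid coordinates", call. = FALSE)
  }
  if (!all(spots$hemisphere %in% c("intact", "lesioned"))) {
    stop("hemisphere must be 'intact' or 'lesioned'", call. = FALSE)
  }
  missing <- setdiff(spots$spot_id, names(spectra))
  if (length(missing) > 0L) {
    stop(sprintf("missing spectrum for spot '%s'", missing[1L]),
         call. = FALSE)
  }
  for (id in spots$spot_id) {
    if (!inherits(spectra[[id]], "mass_spectrum")) {
      stop(sprintf("spectra[['%s']] is not a mass_spectrum", id),
           call. = FALSE)
    }
  }
  structure(
    list(section_id = section_id, animal_id = animal_id,
         run_id = as.integer(run_id), spacing_um = spacing_um,
         spots = spots[, need], spectra = spectra[spots$spot_id]),
    class = "ims_section"
  )
}

#' @export
print.ims_section <- function(x, ...) {
  cat(sprintf("<ims_section> %s (animal %s, run %d): %d spots, %g um spacing\n",
              x$section_id, x$animal_id, x$run_id, nrow(x$spots),
              x$spacing_um))
  invisible(x)
}

#' Construct a region-of-interest mask
#'
#' Maps spots of a section to anatomical regions. Regions follow the
#' substantia-nigra medial/lateral split (`"SN_medial"`, `"SN_lateral"`) with
#' `"other"` for spots outside the SN.
#'
#' @param section_id Section identifier the mask belongs to.
#' @param labels Data frame with columns `spot_id`, `hemisphere`, `region`.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(section_id, labels) {
  stopifnot(is.data.frame(labels))
  need <- c("spot_id", "region")
  if (!all(need %in% names(labels))) {
    stop("labels must have columns spot_id, region", call. = FALSE)
  }
  if (!all(labels$region %in% c("SN_medial", "SN_lateral", "other"))) {
    stop("region must be SN_medial, SN_lateral or other", call. = FALSE)
  }
  if (is.null(labels$hemisphere)) labels$hemisphere <- NA_character_
  structure(list(section_id = section_id,
                 labels = labels[, c("spot_id", "hemisphere", "region")]),
            class = "roi_mask")
}

#' Construct a peak-area table
#'
#' Per-section matrix of integrated peak areas: rows are spots, columns are
#' m/z bins. Carries provenance flags recording whether the source spectra
#' were TIC-normalized and aligned.
#'
#' @param section_id Section identifier.
#' @param centers Strictly increasing numeric vector of bin-center m/z.
#' @param areas Numeric matrix (spots x bins), non-negative; `NA` marks bins
#'   outside a spectrum's mass range. Row names are spot ids.
#' @param normalized,aligned Logical provenance flags.
#' @return An object of class `peak_bin_table`.
#' @export
peak_bin_table <- function(section_id, centers, areas,
                           normalized = FALSE, aligned = FALSE) {
  stopifnot(is.numeric(centers), is.matrix(areas))
  if (any(diff(centers) <= 0)) {
    stop("bin centers must be strictly increasing", call. = FALSE)
  }
  if (ncol(areas) != length(centers)) {
    stop("area matrix columns must match bin count", call. = FALSE)
  }
  if (any(areas < 0, na.rm = TRUE)) stop("negative peak area", call. = FALSE)
  colnames(areas) <- sprintf("%.4f", centers)
  structure(
    list(section_id = section_id, centers = as.numeric(centers),
         areas = areas, normalized = isTRUE(normalized),
         aligned = isTRUE(aligned)),
    class = "peak_bin_table"
  )
}

#' @export
print.peak_bin_table <- function(x, ...) {
  cat(sprintf(
    "<peak_bin_table> %s: %d spots x %d bins (normalized=%s, aligned=%s)\n",
    x$section_id, nrow(x$areas), length(x$centers), x$normalized, x$aligned))
  invisible(x)
}

#' Section quality control on raw total ion current
#'
#' Sections with freeze damage or an uneven TIC before normalization are
#' excluded from analysis. The check computes each spot's raw TIC and fails
#' the section when the coefficient of variation of TIC across spots exceeds
#' the threshold, or when any spot is empty.
#'
#' @param section An [ims_section] (raw, not yet normalized).
#' @param cv_threshold Maximum tolerated CV of per-spot TIC (default 0.5).
#' @return A list with elements `pass` (logical), `cv` and `reason`.
#' @export
qc_section <- function(section, cv_threshold = 0.5) {
  stopifnot(inherits(section, "ims_section"))
  tics <- vapply(section$spectra, tic, numeric(1))
  if (any(tics <= 0)) {
    return(list(pass = FALSE, cv = NA_real_, reason = "empty spectrum"))
  }
  cv <- stats::sd(tics) / mean(tics)
  if (cv > cv_threshold) {
    list(pass = FALSE, cv = cv,
         reason = sprintf("uneven TIC (CV %.3f > %.3f)", cv, cv_threshold))
  } else {
    list(pass = TRUE, cv = cv, reason = "")
  }
}
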