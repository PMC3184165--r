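#' Build an ion image for one m/z bin
#'
#' Places each spot's integrated peak area onto the section's bounding grid.
#' Grid cells without a spot are masked (`NA`), never imputed, and no
#' smoothing is applied: the image is the data.
#'
#' @param table A [peak_bin_table].
#' @param bin Bin-center m/z to render (must match a table column within
#'   1e-6).
#' @param section The [ims_section] providing the grid geometry.
#' @return An object of class `ion_image`: list with `mz`, `grid` (matrix,
#'   rows = grid rows, columns = grid columns) and `section_id`.
#' @export
make_ion_image <- function(table, bin, section) {
  stopifnot(inherits(table, "peak_bin_table"), inherits(section, "ims_section"))
  j <- which(abs(table$centers - bin) < 1e-6)
  if (length(j) != 1L) {
    nearest <- table$centers[order(abs(table$centers - bin))]
    stop(sprintf("bin %.4f not in table; nearest available centers: %s",
                 bin, paste(sprintf("%.4f", utils::head(nearest, 3L)),
                            collapse = ", ")), call. = FALSE)
  }
  ncol_g <- max(section$spots$col) + 1L
  nrow_g <- max(section$spots$row) + 1L
  grid <- matrix(NA_real_, nrow = nrow_g, ncol = ncol_g)
  ids <- section$spots$spot_id
  areas <- table$areas[match(ids, rownames(table$areas)), j]
  grid[cbind(section$spots$row + 1L, section$spots$col + 1L)] <- areas
  structure(list(mz = table$centers[j], grid = grid,
                 section_id = section$section_id),
            class = "ion_image")
}

#' @export
print.ion_image <- function(x, ...) {
  cat(sprintf("<ion_image> m/z %.4f, %d x %d grid (%d masked cells)\n",
              x$mz, nrow(x$grid), ncol(x$grid), sum(is.na(x$grid))))
  invisible(x)
}

#' Multi-channel composite of ion images
#'
#' Merges up to three ion images into an RGB composite, the standard
#' rendering for visualizing complementary peptide distributions (e.g. a
#' locally low species in green against a locally high one in red). Each
#' channel is min-max scaled to \[0, 1\] per image before merging; a constant
#' image renders at mid-intensity 0.5 (degenerate-range guard). The scaling
#' used is recorded in the result's `scaling` attribute.
#'
#' @param images Named list of up to 3 [make_ion_image()] results; names are
#'   channels among `"red"`, `"green"`, `"blue"`.
#' @return An array `nrow x ncol x 3` of values in \[0, 1\] (masked cells 0),
#'   class `ims_composite`, with attribute `scaling` (per-channel min/max).
#' @export
composite_rgb <- function(images) {
  stopifnot(is.list(images), length(images) >= 1L, length(images) <= 3L)
  chans <- names(images)
  if (is.null(chans) || !all(chans %in% c("red", "green", "blue"))) {
    stop("images must be named with channels red/green/blue", call. = FALSE)
  }
  dims <- lapply(images, function(im) dim(im$grid))
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L) {
    stop("ion images do not share geometry", call. = FALSE)
  }
  d <- dims[[1L]]
  out <- array(0, dim = c(d[1L], d[2L], 3L))
  scaling <- list()
  chan_index <- c(red = 1L, green = 2L, blue = 3L)
  for (ch in chans) {
    g <- images[[ch]]$grid
    rng <- range(g, na.rm = TRUE)
    if (diff(rng) == 0) {
      scaled <- ifelse(is.na(g), 0, 0.5)
    } else {
      scaled <- (g - rng[1L]) / diff(rng)
      scaled[is.na(scaled)] <- 0
    }
    out[, , chan_index[[ch]]] <- scaled
    scaling[[ch]] <- list(min = rng[1L], max = rng[2L])
  }
  structure(out, scaling = scaling, class = "ims_composite")
}

#' Save a composite image as PNG with a JSON legend
#'
#' @param comp An `ims_composite` from [composite_rgb()].
#' @param path PNG file path; the channel-scaling legend is written next to
#'   it as `<path>.json`.
#' @export
save_composite_png <- function(comp, path) {
  stopifnot(inherits(comp, "ims_composite"))
  arr <- unclass(comp)
  attr(arr, "scaling") <- NULL
  png::writePNG(arr, target = path)
  jsonlite::write_json(attr(comp, "scaling"), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Split a substantia-nigra ROI into medial and lateral halves
#'
#' The SN is divided into two regions of interest by the perpendicular
#' bisector of the segment joining its ventromedial and dorsolateral
#' corners: spots on the ventromedial side of the bisector are labeled
#' `SN_medial`, the rest `SN_lateral`. Spots falling exactly on the boundary
#' go medial (fixed tie rule).
#'
#' @param spots Data frame with columns `spot_id`, `col`, `row` (the SN ROI
#'   spot set) and optionally `hemisphere`.
#' @param vm_spot,dl_spot Spot ids of the ventromedial and dorsolateral
#'   corners; both must belong to `spots` and must not coincide.
#' @param section_id Identifier attached to the returned mask.
#' @return An [roi_mask] labeling every input spot.
#' @export
split_sn_medial_lateral <- function(spots, vm_spot, dl_spot,
                                    section_id = NA_character_) {
  stopifnot(is.data.frame(spots))
  iv <- match(vm_spot, spots$spot_id)
  id <- match(dl_spot, spots$spot_id)
  if (is.na(iv) || is.na(id)) {
    stop("corner spots must belong to the ROI spot set", call. = FALSE)
  }
  vm <- c(spots$col[iv], spots$row[iv])
  dl <- c(spots$col[id], spots$row[id])
  if (all(vm == dl)) stop("corner spots coincide", call. = FALSE)
  mid <- (vm + dl) / 2
  d <- dl - vm
  proj <- (spots$col - mid[1L]) * d[1L] + (spots$row - mid[2L]) * d[2L]
  region <- ifelse(proj <= 0, "SN_medial", "SN_lateral")
  hemi <- if ("hemisphere" %in% names(spots)) spots$hemisphere else NA
  roi_mask(section_id,
           data.frame(spot_id = spots$spot_id, hemisphere = hemi,
                      region = region, stringsAsFactors = FALSE))
}

#' Summarize peak areas per ROI region and hemisphere
#'
#' Computes the arithmetic mean peak area over the spots of each
#' (region, hemisphere) cell for every m/z bin, always reporting the spot
#' count so region-size imbalance stays visible. Regions with no spots are
#' omitted with a warning. `"other"` spots are excluded.
#'
#' @param table A [peak_bin_table].
#' @param mask An [roi_mask] whose labels carry `hemisphere`.
#' @return A data frame with columns `section_id`, `region`, `hemisphere`,
#'   `mz`, `mean_area`, `n_spots`.
#' @export
summarize_roi <- function(table, mask) {
  stopifnot(inherits(table, "peak_bin_table"), inherits(mask, "roi_mask"))
  lab <- mask$labels[mask$labels$region != "other", , drop = FALSE]
  if (nrow(lab) == 0L) stop("mask covers no SN spots", call. = FALSE)
  out <- list()
  for (region in unique(lab$region)) {
    for (hemi in unique(lab$hemisphere)) {
      ids <- lab$spot_id[lab$region == region & lab$hemisphere == hemi]
      ids <- intersect(ids, rownames(table$areas))
      if (length(ids) == 0L) {
        warning(sprintf("region %s/%s has no spots; omitted", region, hemi),
                call. = FALSE)
        next
      }
      sub <- table$areas[ids, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        section_id = table$section_id, region = region, hemisphere = hemi,
        mz = table$centers,
        mean_area = colMeans(sub, na.rm = TRUE),
        n_spots = length(ids),
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Lesioned side as percent of the intact side
#'
#' The paper-convention effect scale: mean peak area on the lesioned
#' hemisphere expressed as a percentage of the intact hemisphere, so 144
#' means "44% higher" and 175 a 1.75-fold increase.
#'
#' @param lesioned_mean,intact_mean Mean peak areas; `intact_mean` must be
#'   positive.
#' @return `100 * lesioned_mean / intact_mean` (vectorized).
#' @export
percent_of_intact <- function(lesioned_mean, intact_mean) {
  if (any(intact_mean <= 0)) {
    stop("intact mean must be positive", call. = FALSE)
  }
  100 * lesioned_mean / intact_mean
}
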