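#' Read and write imaging-MS sections
#'
#' Two on-disk dialects are supported. The `csvjson` dialect is a
#' human-readable pair `<path>.json` (section metadata and spot table) plus
#' `<path>.csv` (long table of `spot_id,mz,intensity` triples, full double
#' precision) that round-trips bit-consistently. The `imzml` dialect is a
#' minimal continuous-mode imzML file `<path>.imzML` with its external binary
#' `<path>.ibd` (one shared m/z axis, one intensity array per spot,
#' little-endian 64-bit floats), for interoperability with imaging-MS tools.
#'
#' @param section An [ims_section].
#' @param path Base path without extension; the dialect-specific extensions
#'   are appended.
#' @param dialect `"csvjson"` or `"imzml"`.
#' @return `write_section()` returns `path` invisibly; `read_section()`
#'   returns an [ims_section].
#' @export
write_section <- function(section, path, dialect = c("csvjson", "imzml")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(section, "ims_section"))
  switch(dialect,
         csvjson = write_section_csvjson(section, path),
         imzml = write_section_imzml(section, path))
  invisible(path)
}

#' @rdname write_section
#' @export
read_section <- function(path, dialect = c("csvjson", "imzml")) {
  dialect <- match.arg(dialect)
  switch(dialect,
         csvjson = read_section_csvjson(path),
         imzml = read_section_imzml(path))
}

write_section_csvjson <- function(section, path) {
  meta <- list(
    section_id = section$section_id,
    animal_id = section$animal_id,
    run_id = section$run_id,
    spacing_um = section$spacing_um,
    spots = section$spots
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  ids <- section$spots$spot_id
  n_per <- vapply(section$spectra[ids], function(s) length(s$mz), integer(1))
  lines <- sprintf(
    "%s,%.17g,%.17g",
    rep(ids, n_per),
    unlist(lapply(section$spectra[ids], `[[`, "mz"), use.names = FALSE),
    unlist(lapply(section$spectra[ids], `[[`, "intensity"), use.names = FALSE)
  )
  con <- file(paste0(path, ".csv"), "w")
  on.exit(close(con))
  writeLines(c("spot_id,mz,intensity", lines), con)
}

read_section_csvjson <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  spots <- as.data.frame(meta$spots, stringsAsFactors = FALSE)
  spots$col <- as.integer(spots$col)
  spots$row <- as.integer(spots$row)
  dat <- data.table::fread(paste0(path, ".csv"),
                           colClasses = list(character = "spot_id",
                                             numeric = c("mz", "intensity")),
                           showProgress = FALSE, data.table = TRUE)
  declared <- spots$spot_id
  missing <- setdiff(declared, unique(dat$spot_id))
  if (length(missing) > 0L) {
    stop(sprintf("missing spectrum for spot '%s'", missing[1L]),
         call. = FALSE)
  }
  spectra <- lapply(declared, function(id) {
    sub <- dat[dat$spot_id == id, ]
    if (any(diff(sub$mz) <= 0)) {
      stop(sprintf("non-monotone m/z in spot '%s'", id), call. = FALSE)
    }
    mass_spectrum(sub$mz, sub$intensity)
  })
  names(spectra) <- declared
  ims_section(meta$section_id, meta$animal_id, meta$run_id,
              spots, spectra, meta$spacing_um)
}

# ---- minimal continuous-mode imzML ----------------------------------------

imzml_cv <- function(accession, name, value = NULL) {
  if (is.null(value)) {
    sprintf('<cvParam cvRef="IMS" accession="%s" name="%s"/>', accession, name)
  } else {
    sprintf('<cvParam cvRef="IMS" accession="%s" name="%s" value="%s"/>',
            accession, name, value)
  }
}

write_section_imzml <- function(section, path) {
  ids <- section$spots$spot_id
  mz0 <- section$spectra[[ids[1L]]]$mz
  for (id in ids) {
    if (!identical(section$spectra[[id]]$mz, mz0)) {
      stop("continuous-mode imzML requires a shared m/z axis across spots",
           call. = FALSE)
    }
  }
  ibd_path <- paste0(path, ".ibd")
  con <- file(ibd_path, "wb")
  uuid <- as.raw(rep(0L, 16L))
  writeBin(uuid, con)
  mz_offset <- 16L
  writeBin(mz0, con, size = 8L, endian = "little")
  n <- length(mz0)
  int_offsets <- mz_offset + 8L * n + 8L * n * (seq_along(ids) - 1L)
  for (id in ids) {
    writeBin(section$spectra[[id]]$intensity, con, size = 8L,
             endian = "little")
  }
  close(con)

  spec_xml <- vapply(seq_along(ids), function(i) {
    sp <- section$spots[i, ]
    paste0(
      sprintf('<spectrum index="%d" id="spot=%s">', i - 1L, sp$spot_id),
      '<scanList count="1"><scan>',
      imzml_cv("IMS:1000050", "position x", sp$col + 1L),
      imzml_cv("IMS:1000051", "position y", sp$row + 1L),
      sprintf('<userParam name="spot_id" value="%s"/>', sp$spot_id),
      sprintf('<userParam name="hemisphere" value="%s"/>', sp$hemisphere),
      '</scan></scanList>',
      '<binaryDataArrayList count="2">',
      '<binaryDataArray encodedLength="0"><referenceableParamGroupRef ref="mzArray"/>',
      imzml_cv("IMS:1000102", "external offset", mz_offset),
      imzml_cv("IMS:1000103", "external array length", n),
      imzml_cv("IMS:1000104", "external encoded length", 8L * n),
      '<binary/></binaryDataArray>',
      '<binaryDataArray encodedLength="0"><referenceableParamGroupRef ref="intensityArray"/>',
      imzml_cv("IMS:1000102", "external offset", int_offsets[i]),
      imzml_cv("IMS:1000103", "external array length", n),
      imzml_cv("IMS:1000104", "external encoded length", 8L * n),
      '<binary/></binaryDataArray>',
      '</binaryDataArrayList></spectrum>'
    )
  }, character(1))

  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    '<fileDescription><fileContent>',
    imzml_cv("IMS:1000030", "continuous"),
    sprintf('<userParam name="section_id" value="%s"/>', section$section_id),
    sprintf('<userParam name="animal_id" value="%s"/>', section$animal_id),
    sprintf('<userParam name="run_id" value="%d"/>', section$run_id),
    sprintf('<userParam name="spacing_um" value="%.17g"/>',
            section$spacing_um),
    '</fileContent></fileDescription>',
    '<referenceableParamGroupList count="2">',
    '<referenceableParamGroup id="mzArray"/>',
    '<referenceableParamGroup id="intensityArray"/>',
    '</referenceableParamGroupList>',
    sprintf('<run id="%s"><spectrumList count="%d">', section$section_id,
            length(ids)),
    paste0(spec_xml, collapse = ""),
    '</spectrumList></run></mzML>'
  )
  writeLines(xml, paste0(path, ".imzML"))
}

read_section_imzml <- function(path) {
  doc <- xml2::read_xml(paste0(path, ".imzML"))
  xml2::xml_ns_strip(doc)
  fc <- xml2::xml_find_first(doc, ".//fileContent")
  get_user <- function(node, name) {
    xml2::xml_attr(
      xml2::xml_find_first(node, sprintf(".//userParam[@name='%s']", name)),
      "value")
  }
  mode_node <- xml2::xml_find_first(fc, ".//cvParam[@accession='IMS:1000030']")
  if (is.na(xml2::xml_name(mode_node))) {
    stop("not a continuous-mode imzML file", call. = FALSE)
  }
  section_id <- get_user(fc, "section_id")
  animal_id <- get_user(fc, "animal_id")
  run_id <- as.integer(get_user(fc, "run_id"))
  spacing <- as.numeric(get_user(fc, "spacing_um"))

  spec_nodes <- xml2::xml_find_all(doc, ".//spectrum")
  ibd <- file(paste0(path, ".ibd"), "rb")
  on.exit(close(ibd))

  read_array <- function(offset, len) {
    seek(ibd, where = offset, origin = "start")
    readBin(ibd, "double", n = len, size = 8L, endian = "little")
  }
  spots <- list(); spectra <- list(); mz_shared <- NULL
  for (i in seq_along(spec_nodes)) {
    node <- spec_nodes[[i]]
    cvv <- function(scope, acc) {
      as.numeric(xml2::xml_attr(
        xml2::xml_find_first(scope, sprintf(".//cvParam[@accession='%s']", acc)),
        "value"))
    }
    col <- cvv(node, "IMS:1000050") - 1L
    row <- cvv(node, "IMS:1000051") - 1L
    spot_id <- get_user(node, "spot_id")
    hemi <- get_user(node, "hemisphere")
    arrays <- xml2::xml_find_all(node, ".//binaryDataArray")
    refs <- vapply(arrays, function(a) {
      xml2::xml_attr(xml2::xml_find_first(a, ".//referenceableParamGroupRef"),
                     "ref")
    }, character(1))
    mz_node <- arrays[[which(refs == "mzArray")]]
    int_node <- arrays[[which(refs == "intensityArray")]]
    if (is.null(mz_shared)) {
      mz_shared <- read_array(cvv(mz_node, "IMS:1000102"),
                              cvv(mz_node, "IMS:1000103"))
    }
    inten <- read_array(cvv(int_node, "IMS:1000102"),
                        cvv(int_node, "IMS:1000103"))
    if (any(diff(mz_shared) <= 0)) {
      stop(sprintf("non-monotone m/z in spot '%s'", spot_id), call. = FALSE)
    }
    spots[[i]] <- data.frame(spot_id = spot_id, col = as.integer(col),
                             row = as.integer(row), hemisphere = hemi,
                             stringsAsFactors = FALSE)
    spectra[[spot_id]] <- mass_spectrum(mz_shared, inten)
  }
  ims_section(section_id, animal_id, run_id, do.call(rbind, spots),
              spectra, spacing)
}

#' Read / write an ROI mask CSV
#'
#' Plain CSV with columns `spot_id`, `hemisphere`, `region`.
#'
#' @param mask An [roi_mask].
#' @param path CSV file path.
#' @param section_id Section id to attach on read.
#' @export
write_roi_mask <- function(mask, path) {
  stopifnot(inherits(mask, "roi_mask"))
  utils::write.csv(mask$labels, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_roi_mask
#' @export
read_roi_mask <- function(path, section_id = NA_character_) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(spot_id = "character"))
  roi_mask(section_id, df)
}

#' Export a peak-area table as CSV
#'
#' Rows are spots, columns are bin centers (formatted to 4 decimals);
#' the first column is `spot_id`.
#'
#' @param table A [peak_bin_table].
#' @param path CSV file path.
#' @export
write_peak_table <- function(table, path) {
  stopifnot(inherits(table, "peak_bin_table"))
  df <- data.frame(spot_id = rownames(table$areas), table$areas,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
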