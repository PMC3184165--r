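#' Monoisotopic mass constants
#'
#' Standard monoisotopic residue masses for the 20 proteinogenic amino acids,
#' together with the mass of water, the proton mass used for \[M+H\]+
#' protonation, and the mass change of C-terminal amidation (OH replaced by
#' NH2).
#'
#' @return A list with elements `residues` (named numeric vector, Da),
#'   `water`, `proton` and `amide_delta` (Da).
#' @export
#' @examples
#' mass_constants()$residues[["G"]]
mass_constants <- function() {
  list(
    residues = c(
      G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
      V = 99.068414, T = 101.047678, C = 103.009185, L = 113.084064,
      I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
      K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
      F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
    ),
    water = 18.010565,
    proton = 1.007276,
    amide_delta = -0.984016
  )
}

#' Monoisotopic [M+H]+ m/z of a peptide
#'
#' Computes the singly protonated monoisotopic mass of a peptide from its
#' one-letter sequence: the sum of residue masses plus water plus one proton,
#' with the amidation mass change applied when the C-terminus is an amide.
#' MALDI-TOF neuropeptide peaks are dominated by the \[M+H\]+ ion, so this is
#' the theoretical m/z used for annotation throughout the package.
#'
#' @param sequence One-letter amino-acid string (standard 20-letter alphabet).
#' @param c_term_amide Logical; `TRUE` for a C-terminally amidated peptide
#'   (e.g. substance P).
#' @return The monoisotopic \[M+H\]+ m/z in Da.
#' @export
#' @examples
#' monoisotopic_mh("YGGFLR")            # Leu-Enk-Arg, 712.3777
#' monoisotopic_mh("RPKPQQFFGLM", TRUE) # substance P, 1347.7354
monoisotopic_mh <- function(sequence, c_term_amide = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (is.na(sequence) || !nzchar(sequence)) {
    stop("empty peptide sequence", call. = FALSE)
  }
  const <- mass_constants()
  aa <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- setdiff(aa, names(const$residues))
  if (length(bad) > 0L) {
    stop(sprintf("unknown amino-acid letter '%s' in sequence '%s'",
                 bad[1L], sequence), call. = FALSE)
  }
  m <- sum(const$residues[aa]) + const$water + const$proton
  if (isTRUE(c_term_amide)) m <- m + const$amide_delta
  unname(m)
}

#' Construct a peptide record
#'
#' @param name Peptide name (e.g. `"Dyn B"`).
#' @param sequence One-letter amino-acid sequence.
#' @param c_term_amide Logical; C-terminal amidation flag.
#' @param precursor Optional name of the parent peptide.
#' @param range_start,range_end Optional 1-based inclusive residue positions
#'   within the precursor; the range length must equal the sequence length.
#' @return An object of class `peptide`.
#' @export
peptide <- function(name, sequence, c_term_amide = FALSE,
                    precursor = NA_character_,
                    range_start = NA_integer_, range_end = NA_integer_) {
  if (!nzchar(sequence)) stop("empty peptide sequence", call. = FALSE)
  const <- mass_constants()
  aa <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- setdiff(aa, names(const$residues))
  if (length(bad) > 0L) {
    stop(sprintf("unknown amino-acid letter '%s' in sequence '%s'",
                 bad[1L], sequence), call. = FALSE)
  }
  if (!is.na(range_start) && !is.na(range_end)) {
    if (range_end - range_start + 1L != nchar(sequence)) {
      stop("residue_range length does not equal sequence length", call. = FALSE)
    }
  }
  structure(
    list(name = name, sequence = sequence,
         c_term_amide = isTRUE(c_term_amide),
         precursor = precursor,
         range_start = as.integer(range_start),
         range_end = as.integer(range_end)),
    class = "peptide"
  )
}

#' @export
print.peptide <- function(x, ...) {
  cat(sprintf("<peptide> %s  %s%s  [M+H]+ %.4f\n", x$name, x$sequence,
              if (x$c_term_amide) "-NH2" else "",
              monoisotopic_mh(x$sequence, x$c_term_amide)))
  invisible(x)
}

#' Remove the N-terminal tyrosine of an opioid peptide
#'
#' Generates the des-tyrosine metabolite of a dynorphin-family peptide.
#' Removal of the N-terminal tyrosine abolishes opioid-receptor activation and
#' is a major inactivating bioconversion route; the product is exactly one
#' tyrosine residue mass (163.0633 Da) lighter.
#'
#' @param p A [peptide] whose sequence starts with `Y` and has length >= 2.
#' @return A new [peptide] with the first residue removed and the name
#'   suffixed `(2-N)` where `N` is the original length.
#' @export
#' @examples
#' des_tyr(peptide("aNeo", "YGGFLRKYPK"))   # aNeo(2-10)
des_tyr <- function(p) {
  stopifnot(inherits(p, "peptide"))
  if (substr(p$sequence, 1L, 1L) != "Y" || nchar(p$sequence) < 2L) {
    stop("des-Tyr undefined: sequence does not start with an N-terminal Y ",
         "followed by at least one residue", call. = FALSE)
  }
  n <- nchar(p$sequence)
  peptide(
    name = sprintf("%s(2-%d)", p$name, n),
    sequence = substr(p$sequence, 2L, n),
    c_term_amide = p$c_term_amide,
    precursor = p$name,
    range_start = 2L, range_end = n
  )
}

#' Default prodynorphin peptide catalog
#'
#' The catalog of prodynorphin-derived peptides and reference species used
#' throughout the package: the classical dynorphins (Dyn A 1-17, Dyn A 1-8,
#' Dyn A 10-17, Dyn B), the neoendorphins (alpha/beta), the enkephalin-family
#' bioconversion products (Leu-Enk, Leu-Enk-Arg, Leu-Enk-Arg-Arg, aNeo 1-7),
#' the des-tyrosine metabolites of Dyn A(1-8), aNeo and Dyn B, and substance P
#' (C-terminally amidated) as a non-dynorphin reference. Shipped as a
#' plain-text CSV under `inst/extdata/`; theoretical masses are always
#' recomputed from the sequences at load time.
#'
#' Entries whose commonly printed integer m/z disagrees with the computed
#' monoisotopic \[M+H\]+ carry an explanatory `note`.
#'
#' @return A data frame with columns `name`, `sequence`, `c_term_amide`,
#'   `precursor`, `range_start`, `range_end`, `mz_mh` (computed monoisotopic
#'   \[M+H\]+) and `note`.
#' @export
default_catalog <- function() {
  path <- system.file("extdata", "pdyn_catalog.csv", package = "pdynims",
                      mustWork = TRUE)
  read_catalog(path)
}

#' Read / write a peptide catalog CSV
#'
#' The catalog interchange format has columns
#' `name,sequence,c_term_amide,precursor,range_start,range_end,note`.
#' `read_catalog()` validates sequences and recomputes `mz_mh`.
#'
#' @param path CSV file path.
#' @return `read_catalog()` returns the catalog data frame.
#' @export
read_catalog <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(name = "character",
                                       sequence = "character"))
  need <- c("name", "sequence", "c_term_amide")
  if (!all(need %in% names(df))) {
    stop("catalog CSV must have columns name, sequence, c_term_amide",
         call. = FALSE)
  }
  if (is.null(df$precursor)) df$precursor <- NA_character_
  if (is.null(df$range_start)) df$range_start <- NA_integer_
  if (is.null(df$range_end)) df$range_end <- NA_integer_
  if (is.null(df$note)) df$note <- ""
  df$c_term_amide <- as.logical(df$c_term_amide)
  # constructor validates each entry
  for (i in seq_len(nrow(df))) {
    peptide(df$name[i], df$sequence[i], df$c_term_amide[i],
            df$precursor[i], df$range_start[i], df$range_end[i])
  }
  df$mz_mh <- vapply(seq_len(nrow(df)), function(i) {
    monoisotopic_mh(df$sequence[i], df$c_term_amide[i])
  }, numeric(1))
  df
}

#' @rdname read_catalog
#' @param catalog A catalog data frame.
#' @export
write_catalog <- function(catalog, path) {
  cols <- c("name", "sequence", "c_term_amide", "precursor",
            "range_start", "range_end", "note")
  cols <- intersect(cols, names(catalog))
  utils::write.csv(catalog[, cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Annotate observed m/z values against a peptide catalog
#'
#' For each observed m/z, finds all catalog peptides whose theoretical
#' monoisotopic \[M+H\]+ lies within the tolerance, sorted by absolute mass
#' error (ppm) with alphabetical tie-break. The default 0.3 Da tolerance
#' reflects linear-TOF-scale matching at unit m/z resolution.
#'
#' @param mz_list Numeric vector of observed m/z values (Da).
#' @param catalog Catalog data frame as from [default_catalog()].
#' @param tolerance Positive match tolerance.
#' @param unit `"Da"` (default) or `"ppm"`.
#' @return A data frame with columns `observed_mz`, `peptide_name`,
#'   `theoretical_mz`, `delta_ppm` (signed, observed relative to theoretical).
#'   Zero rows when nothing matches.
#' @export
annotate_peaks <- function(mz_list, catalog = default_catalog(),
                           tolerance = 0.3, unit = c("Da", "ppm")) {
  unit <- match.arg(unit)
  if (is.null(catalog) || nrow(catalog) == 0L) {
    stop("empty peptide catalog", call. = FALSE)
  }
  stopifnot(is.numeric(tolerance), tolerance > 0)
  out <- lapply(mz_list, function(obs) {
    delta <- obs - catalog$mz_mh
    ppm <- delta / catalog$mz_mh * 1e6
    hit <- if (unit == "Da") abs(delta) <= tolerance else abs(ppm) <= tolerance
    if (!any(hit)) return(NULL)
    res <- data.frame(
      observed_mz = obs,
      peptide_name = catalog$name[hit],
      theoretical_mz = catalog$mz_mh[hit],
      delta_ppm = ppm[hit],
      stringsAsFactors = FALSE
    )
    res[order(abs(res$delta_ppm), res$peptide_name), , drop = FALSE]
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(observed_mz = numeric(0), peptide_name = character(0),
                      theoretical_mz = numeric(0), delta_ppm = numeric(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
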