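# Containers and file I/O for mass spectra, UV spectra and dilution series.

#' Mass spectrum container
#'
#' Ordered (m/z, intensity) pairs with a charge assumption and free-form
#' acquisition metadata. Points are sorted by m/z; intensities at duplicate
#' m/z values are summed.
#'
#' @param mz_Da Numeric vector of m/z values, Da (charge 1 by default).
#' @param intensity Numeric vector of intensities, same length.
#' @param charge Integer charge assumption (default 1; linear-mode MALDI of
#'   intact proteins is dominated by the singly-protonated species).
#' @param metadata Free-form list of acquisition metadata.
#' @return A `mass_spectrum` object with fields `mz`, `intensity`, `charge`,
#'   `metadata`.
#' @export
mass_spectrum <- function(mz_Da, intensity, charge = 1L, metadata = list()) {
  if (length(mz_Da) != length(intensity))
    stop_arg("mz and intensity lengths differ (%d vs %d)",
             length(mz_Da), length(intensity))
  if (!all(is.finite(mz_Da)) || !all(is.finite(intensity)))
    stop_arg("mass spectrum contains non-finite values")
  if (length(charge) != 1L || charge < 1) stop_arg("charge must be >= 1")
  o <- order(mz_Da)
  mz <- mz_Da[o]; it <- intensity[o]
  if (anyDuplicated(mz)) {
    it <- as.numeric(tapply(it, factor(mz, levels = unique(mz)), sum))
    mz <- unique(mz)
  }
  structure(list(mz = mz, intensity = it, charge = as.integer(charge),
                 metadata = metadata),
            class = "mass_spectrum")
}

#' @export
print.mass_spectrum <- function(x, ...) {
  cat(sprintf("<mass_spectrum> %d points, m/z %.1f-%.1f, charge %d\n",
              length(x$mz), min(x$mz), max(x$mz), x$charge))
  invisible(x)
}

#' UV absorbance spectrum container
#'
#' @param wavelength_nm Strictly increasing wavelengths, nm.
#' @param absorbance_AU Absorbances, AU.
#' @param sample_id Sample label.
#' @param path_cm Optical path length, cm (0.56 for the half-area UV
#'   microplate geometry used throughout).
#' @return A `uv_spectrum` object.
#' @export
uv_spectrum <- function(wavelength_nm, absorbance_AU, sample_id = "sample",
                        path_cm = 0.56) {
  if (length(wavelength_nm) != length(absorbance_AU))
    stop_arg("wavelength and absorbance lengths differ")
  o <- order(wavelength_nm)
  wl <- wavelength_nm[o]; ab <- absorbance_AU[o]
  if (any(diff(wl) <= 0)) stop_arg("wavelengths must be strictly increasing")
  check_number(path_cm, "path_cm", positive = TRUE)
  structure(list(wavelength_nm = wl, absorbance_AU = ab,
                 sample_id = sample_id, path_cm = path_cm),
            class = "uv_spectrum")
}

#' @export
print.uv_spectrum <- function(x, ...) {
  cat(sprintf("<uv_spectrum> \"%s\": %d points, %g-%g nm, path %.2f cm\n",
              x$sample_id, length(x$wavelength_nm), min(x$wavelength_nm),
              max(x$wavelength_nm), x$path_cm))
  invisible(x)
}

#' Dilution series container
#'
#' Replicate (concentration, absorbance) measurements at one wavelength, the
#' input to Beer-Lambert standard-curve fitting. Concentrations are either
#' mass-per-volume (mg/mL, typical for the antibody) or millimolar (typical
#' for the small-molecule drug); the unit decides how a fitted slope is
#' converted to a molar extinction coefficient.
#'
#' @param conc Concentrations (mg/mL or mM per `conc_unit`).
#' @param absorbance Absorbances, AU. Small negative values (to -0.05) are
#'   tolerated as blanked noise.
#' @param replicate Replicate identifiers (default all 1).
#' @param wavelength_nm Measurement wavelength, nm.
#' @param conc_unit `"mass_per_volume"` or `"millimolar"`.
#' @return A `dilution_series` data frame with columns `conc`, `replicate`,
#'   `absorbance` and attributes `wavelength_nm`, `conc_unit`.
#' @export
dilution_series <- function(conc, absorbance, replicate = 1L,
                            wavelength_nm,
                            conc_unit = c("mass_per_volume", "millimolar")) {
  conc_unit <- match.arg(conc_unit)
  check_number(wavelength_nm, "wavelength_nm", positive = TRUE)
  if (length(conc) != length(absorbance))
    stop_arg("conc and absorbance lengths differ")
  if (length(unique(conc)) < 3L)
    stop_arg("dilution series needs >= 3 distinct concentrations")
  if (any(absorbance < -0.05))
    stop_arg("absorbance below -0.05 AU: check blanking")
  df <- data.frame(conc = conc,
                   replicate = rep_len(replicate, length(conc)),
                   absorbance = absorbance)
  structure(df, wavelength_nm = wavelength_nm, conc_unit = conc_unit,
            class = c("dilution_series", "data.frame"))
}

# ---- file I/O -------------------------------------------------------------

#' Read a mass spectrum from TSV or mzML
#'
#' TSV input is two columns (m/z TAB intensity) without a header. The mzML
#' reader covers the uncompressed 64-bit profile-spectrum subset written by
#' [write_spectrum_mzml()] (a single spectrum; no vendor compression).
#'
#' @param path Input file.
#' @param format `"tsv"`, `"mzml"`, or `"auto"` (by file extension).
#' @param charge Charge assumption attached to the spectrum.
#' @return A [mass_spectrum()].
#' @export
load_spectrum <- function(path, format = c("auto", "tsv", "mzml"),
                          charge = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_arg("file not found: %s", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mzml = "mzml", tsv = "tsv", txt = "tsv",
                     stop_arg("unsupported spectrum format \".%s\"", ext))
  }
  if (format == "tsv") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(vapply(parts, length, 0L) != 2L)
    if (length(bad))
      stop_arg("parse error in %s at line %d: expected 2 tab-separated fields",
               path, bad[1L])
    mz <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
    it <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
    bad <- which(is.na(mz) | is.na(it))
    if (length(bad))
      stop_arg("parse error in %s at line %d: non-numeric field",
               path, bad[1L])
  } else {
    xy <- read_mzml_arrays(path)
    mz <- xy$mz; it <- xy$intensity
  }
  if (length(mz) < 10L)
    stop_arg("spectrum in %s has %d points; at least 10 required",
             path, length(mz))
  mass_spectrum(mz, it, charge = charge, metadata = list(source = path))
}

#' Write a mass spectrum as two-column TSV
#'
#' @param spectrum A [mass_spectrum()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_spectrum_tsv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "mass_spectrum"))
  writeLines(sprintf("%.6f\t%.8g", spectrum$mz, spectrum$intensity), path)
  invisible(path)
}

#' Write a mass spectrum as minimal mzML
#'
#' Emits a single profile spectrum with uncompressed little-endian 64-bit
#' m/z and intensity arrays -- the subset [load_spectrum()] reads back.
#'
#' @param spectrum A [mass_spectrum()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_spectrum_mzml <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "mass_spectrum"))
  enc <- function(x) jsonlite::base64_enc(writeBin(as.numeric(x), raw(),
                                                   size = 8L,
                                                   endian = "little"))
  n <- length(spectrum$mz)
  arr <- function(x, acc, nm) paste0(
    '      <binaryDataArray encodedLength="', nchar(enc(x)), '">\n',
    '        <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>\n',
    '        <cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>\n',
    '        <cvParam cvRef="MS" accession="', acc, '" name="', nm, '"/>\n',
    '        <binary>', enc(x), '</binary>\n',
    '      </binaryDataArray>\n')
  xml <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">\n',
    '<run id="run1" defaultInstrumentConfigurationRef="IC1">\n',
    '<spectrumList count="1">\n',
    '  <spectrum index="0" id="scan=1" defaultArrayLength="', n, '">\n',
    '    <cvParam cvRef="MS" accession="MS:1000128" name="profile spectrum"/>\n',
    '    <binaryDataArrayList count="2">\n',
    arr(spectrum$mz, "MS:1000514", "m/z array"),
    arr(spectrum$intensity, "MS:1000515", "intensity array"),
    '    </binaryDataArrayList>\n',
    '  </spectrum>\n',
    '</spectrumList>\n</run>\n</mzML>\n')
  writeLines(xml, path, sep = "")
  invisible(path)
}

read_mzml_arrays <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  arrays <- xml2::xml_find_all(doc, ".//binaryDataArray")
  if (length(arrays) < 2L)
    stop_arg("mzML file %s: expected two binaryDataArray elements", path)
  out <- list()
  for (a in arrays) {
    accs <- xml2::xml_attr(xml2::xml_find_all(a, "./cvParam"), "accession")
    bin <- xml2::xml_text(xml2::xml_find_first(a, "./binary"))
    vals <- readBin(jsonlite::base64_dec(bin), "double",
                    n = length(jsonlite::base64_dec(bin)) %/% 8L,
                    size = 8L, endian = "little")
    if ("MS:1000514" %in% accs) out$mz <- vals
    if ("MS:1000515" %in% accs) out$intensity <- vals
  }
  if (is.null(out$mz) || is.null(out$intensity))
    stop_arg("mzML file %s: missing m/z or intensity array", path)
  out
}

#' Read a UV spectrum CSV (columns `wavelength_nm`, `absorbance`)
#' @param path Input CSV.
#' @param sample_id Sample label (defaults to file name).
#' @param path_cm Optical path length, cm.
#' @return A [uv_spectrum()].
#' @export
read_uv_csv <- function(path, sample_id = NULL, path_cm = 0.56) {
  df <- read.csv(path)
  need <- c("wavelength_nm", "absorbance")
  if (!all(need %in% names(df)))
    stop_arg("%s must have columns %s", path, paste(need, collapse = ", "))
  uv_spectrum(df$wavelength_nm, df$absorbance,
              sample_id = sample_id %||% basename(path), path_cm = path_cm)
}

#' Write a UV spectrum CSV
#' @param spectrum A [uv_spectrum()].
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_uv_csv <- function(spectrum, path) {
  write.csv(data.frame(wavelength_nm = spectrum$wavelength_nm,
                       absorbance = spectrum$absorbance),
            path, row.names = FALSE)
  invisible(path)
}

#' Read a dilution-series CSV
#'
#' Expects columns `replicate`, `absorbance`, and one of `conc_mg_ml` or
#' `conc_mM` (deciding the concentration unit).
#'
#' @param path Input CSV.
#' @param wavelength_nm Measurement wavelength, nm.
#' @return A [dilution_series()].
#' @export
read_dilution_csv <- function(path, wavelength_nm) {
  df <- read.csv(path)
  if ("conc_mg_ml" %in% names(df)) {
    conc <- df$conc_mg_ml; unit <- "mass_per_volume"
  } else if ("conc_mM" %in% names(df)) {
    conc <- df$conc_mM; unit <- "millimolar"
  } else stop_arg("%s needs a conc_mg_ml or conc_mM column", path)
  dilution_series(conc, df$absorbance, df$replicate %||% 1L,
                  wavelength_nm = wavelength_nm, conc_unit = unit)
}

#' Write a dilution-series CSV
#' @param series A [dilution_series()].
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_dilution_csv <- function(series, path) {
  col <- if (attr(series, "conc_unit") == "millimolar") "conc_mM"
         else "conc_mg_ml"
  df <- data.frame(series$conc, series$replicate, series$absorbance)
  names(df) <- c(col, "replicate", "absorbance")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
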