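# Tandem-spectrum container and MGF / mzML input-output.
#
# MGF is read and written natively (compact key-value format; fragmentation
# mode is carried in a FRAGMENTATION= line and mirrored into the TITLE).
# mzML is written as uncompressed 64-bit-float PSI mzML and read back with
# the Bioconductor mzR parser.

#' Construct a tandem spectrum
#'
#' @param scan_id scan identifier (character or integer).
#' @param precursor_mz precursor m/z (> 0).
#' @param charge precursor charge state, 1-8, or `NA` for unknown.
#' @param frag_type `"HCD"` or `"CID"`.
#' @param mz,intensity centroided peak arrays; stored sorted by m/z.
#' @param rt retention time in seconds (default `NA`).
#' @return object of class `ms_spectrum`.
#' @export
ms_spectrum <- function(scan_id, precursor_mz, charge, frag_type,
                        mz, intensity, rt = NA_real_) {
  stopifnot(length(mz) == length(intensity), precursor_mz > 0,
            frag_type %in% c("HCD", "CID"),
            is.na(charge) || (charge >= 1 && charge <= 8))
  o <- order(mz)
  structure(list(scan_id = as.character(scan_id),
                 precursor_mz = as.numeric(precursor_mz),
                 charge = if (is.na(charge)) NA_integer_ else as.integer(charge),
                 frag_type = frag_type,
                 mz = as.numeric(mz[o]),
                 intensity = as.numeric(intensity[o]),
                 rt = as.numeric(rt)),
            class = "ms_spectrum")
}

#' @export
print.ms_spectrum <- function(x, ...) {
  cat("<spectrum ", x$scan_id, "> ", x$frag_type, ", precursor ",
      sprintf("%.4f", x$precursor_mz), " (z=",
      if (is.na(x$charge)) "?" else x$charge, "), ",
      length(x$mz), " peaks\n", sep = "")
  invisible(x)
}

#' Write spectra to MGF
#'
#' @param spectra list of `ms_spectrum`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines(c(
      "BEGIN IONS",
      paste0("TITLE=", s$scan_id, " frag=", s$frag_type),
      paste0("FRAGMENTATION=", s$frag_type),
      paste0("PEPMASS=", format(s$precursor_mz, digits = 15)),
      if (!is.na(s$charge)) paste0("CHARGE=", s$charge, "+"),
      if (!is.na(s$rt)) paste0("RTINSECONDS=", format(s$rt, digits = 15)),
      if (length(s$mz)) paste(format(s$mz, digits = 15, trim = TRUE),
                              format(s$intensity, digits = 15, trim = TRUE)),
      "END IONS", ""
    ), con)
  }
  invisible(path)
}

#' Read spectra from MGF
#'
#' Lossless for files written by [write_mgf()]; tolerant of generic MGF
#' (fragmentation defaults to HCD when unannotated, charge to unknown).
#'
#' @param path MGF file.
#' @return list of `ms_spectrum`.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends) || any(ends < starts)) {
    stop("malformed MGF (unbalanced BEGIN/END IONS): ", path)
  }
  lapply(seq_along(starts), function(i) {
    block <- lines[(starts[i] + 1L):(ends[i] - 1L)]
    is_kv <- grepl("^[A-Z]+=", block)
    kv <- block[is_kv]
    keys <- sub("=.*$", "", kv)
    vals <- sub("^[A-Z]+=", "", kv)
    get <- function(k) if (k %in% keys) vals[match(k, keys)] else NA_character_
    title <- get("TITLE")
    scan_id <- if (is.na(title)) paste0("scan_", i) else
      strsplit(title, " ", fixed = TRUE)[[1]][1]
    frag <- get("FRAGMENTATION")
    if (is.na(frag) && !is.na(title) && grepl("frag=", title)) {
      frag <- sub("^.*frag=", "", title)
    }
    if (is.na(frag) || !frag %in% c("HCD", "CID")) frag <- "HCD"
    pep <- get("PEPMASS")
    if (is.na(pep)) stop("MGF scan ", scan_id, " lacks PEPMASS (", path, ")")
    pmz <- as.numeric(strsplit(trimws(pep), "[ \t]+")[[1]][1])
    ch <- get("CHARGE")
    charge <- if (is.na(ch)) NA_integer_ else as.integer(sub("[+-]$", "", ch))
    rt <- as.numeric(get("RTINSECONDS"))
    pk <- block[!is_kv & nzchar(trimws(block))]
    if (length(pk)) {
      mat <- do.call(rbind, lapply(strsplit(trimws(pk), "[ \t]+"), function(tk) {
        v <- suppressWarnings(as.numeric(tk[1:2]))
        if (anyNA(v)) stop("malformed peak line in scan ", scan_id, ": ",
                           paste(tk, collapse = " "))
        v
      }))
    } else {
      mat <- matrix(numeric(0), ncol = 2)
    }
    ms_spectrum(scan_id, pmz, charge, frag, mat[, 1], mat[, 2], rt = rt)
  })
}

# base64 of a numeric vector as little-endian 64-bit floats
encode_b64_doubles <- function(x) {
  # base64_enc wraps long output; mzML binary must be a single run
  gsub("[\r\n ]", "",
       jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8L,
                                     endian = "little")))
}

#' Write spectra to mzML
#'
#' Emits PSI mzML 1.1.0 with uncompressed 64-bit float arrays; the
#' dissociation method is recorded as an activation cvParam (HCD/CID).
#'
#' @param spectra list of `ms_spectrum`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mzml <- function(spectra, path) {
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  spec_xml <- vapply(seq_along(spectra), function(i) {
    s <- spectra[[i]]
    act <- if (s$frag_type == "HCD") {
      '<cvParam cvRef="MS" accession="MS:1000422" name="beam-type collision-induced dissociation" value=""/>'
    } else {
      '<cvParam cvRef="MS" accession="MS:1000133" name="collision-induced dissociation" value=""/>'
    }
    charge_xml <- if (!is.na(s$charge)) {
      sprintf('<cvParam cvRef="MS" accession="MS:1000041" name="charge state" value="%d"/>', s$charge)
    } else ""
    rt <- if (is.na(s$rt)) 0 else s$rt
    paste0(
      # proteowizard-style nativeID requires a numeric scan number; a
      # non-numeric scan_id maps to the 1-based stream index
      sprintf('<spectrum index="%d" id="scan=%s" defaultArrayLength="%d">',
              i - 1L,
              if (grepl("^[0-9]+$", s$scan_id)) s$scan_id else as.character(i),
              length(s$mz)),
      '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="2"/>',
      '<cvParam cvRef="MS" accession="MS:1000580" name="MSn spectrum" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>',
      '<scanList count="1"><cvParam cvRef="MS" accession="MS:1000795" name="no combination" value=""/><scan>',
      sprintf('<cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="%.6f" unitCvRef="UO" unitAccession="UO:0000010" unitName="second"/>', rt),
      # dissociation mode also mirrored into the filter string, the field
      # mzR exposes (Thermo-style "hcd"/"cid" tokens)
      sprintf('<cvParam cvRef="MS" accession="MS:1000512" name="filter string" value="ITMS + c NSI d Full ms2 %.4f@%s35.00"/>',
              s$precursor_mz, tolower(s$frag_type)),
      '</scan></scanList>',
      '<precursorList count="1"><precursor><selectedIonList count="1"><selectedIon>',
      sprintf('<cvParam cvRef="MS" accession="MS:1000744" name="selected ion m/z" value="%.10f" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>', s$precursor_mz),
      charge_xml,
      '</selectedIon></selectedIonList><activation>', act, '</activation></precursor></precursorList>',
      '<binaryDataArrayList count="2">',
      binary_array_xml(s$mz, "MS:1000514", "m/z array"),
      binary_array_xml(s$intensity, "MS:1000515", "intensity array"),
      '</binaryDataArrayList></spectrum>')
  }, character(1))
  xml <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">\n',
    '<cvList count="2">',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '<cv id="UO" fullName="Unit Ontology" URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/>',
    '</cvList>\n',
    '<fileDescription><fileContent>',
    '<cvParam cvRef="MS" accession="MS:1000580" name="MSn spectrum" value=""/>',
    '</fileContent></fileDescription>\n',
    '<softwareList count="1"><software id="glycosplice" version="0.1.0"/></softwareList>\n',
    '<instrumentConfigurationList count="1"><instrumentConfiguration id="IC1"/></instrumentConfigurationList>\n',
    '<dataProcessingList count="1"><dataProcessing id="dp1"><processingMethod order="1" softwareRef="glycosplice">',
    '<cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/>',
    '</processingMethod></dataProcessing></dataProcessingList>\n',
    '<run id="run1" defaultInstrumentConfigurationRef="IC1">\n',
    sprintf('<spectrumList count="%d" defaultDataProcessingRef="dp1">\n', length(spectra)),
    paste(spec_xml, collapse = "\n"),
    '\n</spectrumList></run></mzML>\n')
  writeLines(xml, path, sep = "")
  invisible(path)
}

binary_array_xml <- function(x, accession, name) {
  b64 <- encode_b64_doubles(x)
  paste0(sprintf('<binaryDataArray encodedLength="%d">', nchar(b64)),
         '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
         '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
         sprintf('<cvParam cvRef="MS" accession="%s" name="%s" value=""/>', accession, name),
         '<binary>', b64, '</binary></binaryDataArray>')
}

#' Read spectra from mzML (via mzR)
#'
#' MS2 scans are mapped losslessly onto `ms_spectrum` objects; unknown
#' precursor charges are preserved as unknown. The dissociation method is
#' taken from the mzR activation field when available, else defaults to
#' HCD.
#'
#' @param path mzML file.
#' @return list of `ms_spectrum`.
#' @export
read_mzml <- function(path) {
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh))
  hd <- mzR::header(fh)
  pk <- mzR::peaks(fh)
  if (is.matrix(pk)) pk <- list(pk)
  idx <- which(hd$msLevel == 2L)
  lapply(idx, function(i) {
    charge <- hd$precursorCharge[i]
    if (!is.na(charge) && charge == 0L) charge <- NA_integer_
    frag <- "HCD"
    fs <- if ("filterString" %in% names(hd)) hd$filterString[i] else NA
    if (!is.na(fs) && grepl("@cid", fs, ignore.case = TRUE)) frag <- "CID"
    scan_id <- sub("^.*scan=", "", hd$spectrumId[i])
    rt <- hd$retentionTime[i]
    ms_spectrum(scan_id, hd$precursorMZ[i], charge, frag,
                pk[[i]][, 1], pk[[i]][, 2], rt = rt)
  })
}

#' Read spectra from MGF or mzML
#'
#' @param path input file; format chosen by extension unless `format` is
#'   given.
#' @param format `"MGF"` or `"mzML"`.
#' @return list of `ms_spectrum`.
#' @export
read_spectra <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzML" else "MGF"
  }
  switch(format, MGF = read_mgf(path), mzML = read_mzml(path),
         stop("unsupported spectrum format: ", format))
}
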