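# HexNAc oxonium diagnostics in HCD scans and CID inclusion-list
# construction (the HCD-triggered-CID acquisition logic, run offline).

#' Detect HexNAc oxonium diagnostic peaks in an HCD spectrum
#'
#' Matches the spectrum against the [oxonium_series()] within a Dalton
#' window. The trigger decision for CID scheduling uses the parent HexNAc
#' oxonium ion (m/z 204.087) within +/- 0.01 Da.
#'
#' @param s an `ms_spectrum` (HCD).
#' @param window half-width of the matching window in Da (default 0.01).
#' @param min_intensity relative-intensity floor for evidence, as a
#'   fraction of the base peak (default 0: any peak counts).
#' @return data.frame of matched diagnostics (`label`, `mz_theoretical`,
#'   `mz_observed`, `intensity`), with attribute `trigger` (logical: parent
#'   oxonium present).
#' @export
detect_oxonium <- function(s, window = 0.01, min_intensity = 0) {
  stopifnot(inherits(s, "ms_spectrum"))
  if (s$frag_type != "HCD") {
    stop("oxonium triggering is defined on HCD spectra (got ", s$frag_type, ")")
  }
  series <- oxonium_series("HexNAc")
  floor_abs <- if (length(s$intensity)) min_intensity * max(s$intensity) else 0
  rows <- lapply(seq_len(nrow(series)), function(i) {
    hit <- which(abs(s$mz - series$mz[i]) <= window &
                   s$intensity >= floor_abs)
    if (!length(hit)) return(NULL)
    data.frame(label = series$label[i], mz_theoretical = series$mz[i],
               mz_observed = s$mz[hit], intensity = s$intensity[hit],
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(label = character(0), mz_theoretical = numeric(0),
               mz_observed = numeric(0), intensity = numeric(0))
  }
  attr(out, "trigger") <- "HexNAc-oxonium" %in% out$label
  out
}

#' GalNAc/GlcNAc diagnostic intensity ratio I(144.066)/I(138.055)
#'
#' Ratio of summed intensities within the matching window around the
#' 144.066 and 138.055 HexNAc fragment ions. A high ratio is
#' characteristic of GalNAc (mucin-type O-glycosylation) rather than
#' GlcNAc. When the 138.055 denominator is absent the ratio is undefined
#' and `NA` is returned with attribute `defined = FALSE`.
#'
#' @param s an `ms_spectrum` (HCD).
#' @param window matching half-width in Da (default 0.01).
#' @return numeric ratio (or `NA`), with attribute `defined`.
#' @export
diagnostic_ratio <- function(s, window = 0.01) {
  stopifnot(inherits(s, "ms_spectrum"))
  if (s$frag_type != "HCD") stop("diagnostic ratio is defined on HCD spectra")
  series <- oxonium_series("HexNAc")
  mz144 <- series$mz[series$label == "HexNAc-C2H6O3"]
  mz138 <- series$mz[series$label == "HexNAc-CH4O2-CH2O"]
  num <- sum(s$intensity[abs(s$mz - mz144) <= window])
  den <- sum(s$intensity[abs(s$mz - mz138) <= window])
  if (den <= 0) {
    return(structure(NA_real_, defined = FALSE))
  }
  structure(num / den, defined = TRUE)
}

#' Build a CID inclusion list from triggered HCD spectra
#'
#' One entry per distinct triggered precursor: precursors within
#' `merge_ppm` of each other at the same charge state are merged
#' (intensity-weighted mean m/z, pooled retention-time range). Entries are
#' sorted by descending best oxonium-evidence intensity. Deterministic in
#' the spectrum stream.
#'
#' @param spectra list of `ms_spectrum`; non-HCD scans are ignored.
#' @param window oxonium matching half-width in Da (default 0.01).
#' @param merge_ppm precursor merging tolerance (default 5 ppm, the search
#'   precursor tolerance).
#' @param min_intensity relative oxonium intensity floor (default 0).
#' @return data.frame with `mz`, `z`, `rt_start`, `rt_end`,
#'   `evidence_intensity`, `n_scans`, `scan_ids`.
#' @export
build_inclusion_list <- function(spectra, window = 0.01, merge_ppm = 5,
                                 min_intensity = 0) {
  trig <- list()
  for (s in spectra) {
    if (s$frag_type != "HCD") next
    ev <- detect_oxonium(s, window = window, min_intensity = min_intensity)
    if (!isTRUE(attr(ev, "trigger"))) next
    parent <- ev[ev$label == "HexNAc-oxonium", , drop = FALSE]
    trig[[length(trig) + 1L]] <- data.frame(
      mz = s$precursor_mz,
      z = if (is.na(s$charge)) NA_integer_ else s$charge,
      rt = s$rt, evidence = max(parent$intensity),
      scan_id = s$scan_id, stringsAsFactors = FALSE)
  }
  if (!length(trig)) {
    return(data.frame(mz = numeric(0), z = integer(0), rt_start = numeric(0),
                      rt_end = numeric(0), evidence_intensity = numeric(0),
                      n_scans = integer(0), scan_ids = character(0)))
  }
  df <- do.call(rbind, trig)
  df <- df[order(df$z, df$mz), , drop = FALSE]
  group <- integer(nrow(df))
  gid <- 0L
  for (i in seq_len(nrow(df))) {
    if (i == 1L || !identical(df$z[i], df$z[i - 1L]) ||
        abs(ppm_error(df$mz[i], df$mz[i - 1L])) > merge_ppm) {
      gid <- gid + 1L
    }
    group[i] <- gid
  }
  merged <- do.call(rbind, lapply(split(df, group), function(g) {
    data.frame(
      mz = sum(g$mz * g$evidence) / sum(g$evidence),
      z = g$z[1],
      rt_start = if (all(is.na(g$rt))) NA_real_ else min(g$rt, na.rm = TRUE),
      rt_end = if (all(is.na(g$rt))) NA_real_ else max(g$rt, na.rm = TRUE),
      evidence_intensity = max(g$evidence),
      n_scans = nrow(g),
      scan_ids = collapse_tags(g$scan_id),
      stringsAsFactors = FALSE)
  }))
  merged <- merged[order(-merged$evidence_intensity, merged$mz), , drop = FALSE]
  rownames(merged) <- NULL
  merged
}

#' Write an inclusion list to CSV
#' @param inclusion data.frame from [build_inclusion_list()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_inclusion_csv <- function(inclusion, path) {
  utils::write.csv(inclusion, path, row.names = FALSE)
  invisible(path)
}
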