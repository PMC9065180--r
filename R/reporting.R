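# Aggregation of accepted GPSMs into junction evidence, isoform
# assignment per band, protein coverage and glycosite summaries.

#' Assign isoforms and compute coverage for a band of spectra
#'
#' GPSMs passing the q-value threshold are aggregated per exon-exon
#' junction. An isoform is assigned when at least `min_gpsm` accepted
#' GPSMs support a junction diagnostic of it (a junction unique to that
#' isoform within the database); peptides from shared constitutive regions
#' contribute to the coverage of every compatible isoform but never to
#' assignment. Coverage is the fraction of distinct isoform residues
#' covered by accepted peptides mapped to the complete variant.
#'
#' @param gpsms GPSM data.frame with `q_value` (see [target_decoy_fdr()]);
#'   target GPSMs only are used.
#' @param isoforms list of `protein_isoform` (the searched database).
#' @param band free-text band label (e.g. a molecular-weight window).
#' @param q_threshold acceptance threshold (default 0.01).
#' @param min_gpsm accepted junction GPSMs required to list a junction
#'   (default 1).
#' @return object of class `band_report`: list with `band`, `status`
#'   (`"ID"` or `"No ID"`), `junctions` (data.frame `tag`, `n_gpsm`),
#'   `assignments` (data.frame `isoform_id`, `diagnostic_junctions`,
#'   `coverage`), `n_accepted`.
#' @export
assign_isoforms <- function(gpsms, isoforms, band = "band", q_threshold = 0.01,
                            min_gpsm = 1L) {
  iso_ids <- vapply(isoforms, `[[`, character(1), "isoform_id")
  names(isoforms) <- iso_ids
  acc <- gpsms[!gpsms$is_decoy & !is.na(gpsms$q_value) &
                 gpsms$q_value <= q_threshold, , drop = FALSE]
  if (!nrow(acc)) {
    return(structure(list(band = band, status = "No ID",
                          junctions = data.frame(tag = character(0),
                                                 n_gpsm = integer(0)),
                          assignments = data.frame(isoform_id = character(0),
                                                   diagnostic_junctions = character(0),
                                                   coverage = numeric(0)),
                          n_accepted = 0L),
                     class = "band_report"))
  }
  # junction evidence
  tag_lists <- strsplit(acc$junction_tags, ",", fixed = TRUE)
  all_tags <- unlist(lapply(tag_lists, function(x) x[nzchar(x)]))
  jn <- if (length(all_tags)) {
    tb <- table(all_tags)
    data.frame(tag = names(tb), n_gpsm = as.integer(tb),
               stringsAsFactors = FALSE)
  } else {
    data.frame(tag = character(0), n_gpsm = integer(0))
  }
  jn <- jn[jn$n_gpsm >= min_gpsm, , drop = FALSE]
  jn <- jn[order(-jn$n_gpsm, jn$tag), , drop = FALSE]
  # junction -> isoforms carrying it; diagnostic = unique to one isoform
  jmap <- lapply(isoforms, function(iso) iso$junctions$tag)
  diagnostic_of <- function(tag) {
    carriers <- iso_ids[vapply(jmap, function(tt) tag %in% tt, logical(1))]
    if (length(carriers) == 1L) carriers else character(0)
  }
  assigned <- list()
  for (tag in jn$tag) {
    for (iso_id in diagnostic_of(tag)) {
      assigned[[iso_id]] <- c(assigned[[iso_id]], tag)
    }
  }
  assignments <- if (length(assigned)) {
    data.frame(isoform_id = names(assigned),
               diagnostic_junctions = vapply(assigned, collapse_tags,
                                             character(1)),
               coverage = vapply(names(assigned), function(iso_id) {
                 isoform_coverage(acc, isoforms[[iso_id]])
               }, numeric(1)),
               stringsAsFactors = FALSE)
  } else {
    data.frame(isoform_id = character(0), diagnostic_junctions = character(0),
               coverage = numeric(0))
  }
  rownames(assignments) <- NULL
  structure(list(band = band,
                 status = if (nrow(assignments)) "ID" else "No ID",
                 junctions = jn, assignments = assignments,
                 n_accepted = nrow(acc)),
            class = "band_report")
}

#' Coverage of an isoform by accepted GPSM peptides
#'
#' Fraction of distinct residues covered by accepted peptides mapped to
#' the isoform, either by recorded provenance (`isoform_id`, `start0`,
#' `end0`) or, for peptides identified on other database entries, by exact
#' substring match of the peptide in the isoform sequence. Never decreases
#' as GPSMs are added.
#'
#' @param gpsms accepted GPSM rows.
#' @param iso a `protein_isoform`.
#' @return coverage fraction in [0, 1].
#' @export
isoform_coverage <- function(gpsms, iso) {
  len <- nchar(iso$aa_sequence)
  covered <- logical(len)
  for (i in seq_len(nrow(gpsms))) {
    row <- gpsms[i, ]
    if (!is.null(row$isoform_id) && !is.na(row$isoform_id) &&
        identical(row$isoform_id, iso$isoform_id) &&
        !is.null(row$start0) && !is.na(row$start0 %||% NA)) {
      covered[(row$start0 + 1L):row$end0] <- TRUE
    } else {
      hit <- gregexpr(row$peptide, iso$aa_sequence, fixed = TRUE)[[1]]
      if (hit[1] > 0L) {
        for (h in hit) covered[h:(h + nchar(row$peptide) - 1L)] <- TRUE
      }
    }
  }
  mean(covered)
}

#' @export
print.band_report <- function(x, ...) {
  cat("<band report '", x$band, "'> ", x$status, "; ", x$n_accepted,
      " accepted GPSMs\n", sep = "")
  if (nrow(x$assignments)) {
    for (i in seq_len(nrow(x$assignments))) {
      cat("  ", x$assignments$isoform_id[i], " via ",
          x$assignments$diagnostic_junctions[i], ", coverage ",
          sprintf("%.2f", x$assignments$coverage[i]), "\n", sep = "")
    }
  }
  invisible(x)
}

#' Summarize glycosites across accepted GPSMs
#'
#' Counts GPSMs per (peptide-context site, composition); localized and
#' ambiguous site assignments are tallied in separate strata.
#'
#' @param gpsms GPSM data.frame; if a `localized` logical column is absent
#'   every glycosylated GPSM counts as ambiguous.
#' @return data.frame with `junction_tags`, `peptide`, `site`,
#'   `composition`, `stratum`, `n_gpsm`.
#' @export
summarize_glycosites <- function(gpsms) {
  rows <- list()
  for (i in seq_len(nrow(gpsms))) {
    g <- gpsms[i, ]
    gl <- candidate_glyco(g)
    if (!length(gl$sites)) next
    stratum <- if (!is.null(g$localized) && isTRUE(g$localized)) {
      "localized"
    } else "ambiguous"
    for (j in seq_along(gl$sites)) {
      rows[[length(rows) + 1L]] <- data.frame(
        junction_tags = g$junction_tags %||% "", peptide = g$peptide,
        site = gl$sites[j], composition = gl$compositions[j],
        stratum = stratum, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(junction_tags = character(0), peptide = character(0),
                      site = integer(0), composition = character(0),
                      stratum = character(0), n_gpsm = integer(0)))
  }
  df <- do.call(rbind, rows)
  agg <- stats::aggregate(list(n_gpsm = rep(1L, nrow(df))),
                          by = df[, c("junction_tags", "peptide", "site",
                                      "composition", "stratum")],
                          FUN = sum)
  agg <- agg[order(agg$peptide, agg$site, agg$composition, agg$stratum), ,
             drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Write band reports and glycosite summaries to disk
#'
#' Emits `band_reports.tsv`, `glycosites.tsv` and `reports.json` with a
#' deterministic column order: byte-identical output for identical inputs.
#'
#' @param reports list of `band_report`.
#' @param dir output directory (created if needed).
#' @param glycosites optional data.frame from [summarize_glycosites()].
#' @return named character vector of the files written, invisibly.
#' @export
write_reports <- function(reports, dir, glycosites = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  band_rows <- do.call(rbind, lapply(reports, function(r) {
    if (nrow(r$assignments)) {
      data.frame(band = r$band, status = r$status,
                 isoform_id = r$assignments$isoform_id,
                 diagnostic_junctions = r$assignments$diagnostic_junctions,
                 coverage = round(r$assignments$coverage, 4),
                 junctions = collapse_tags(r$junctions$tag),
                 n_accepted = r$n_accepted, stringsAsFactors = FALSE)
    } else {
      data.frame(band = r$band, status = r$status, isoform_id = NA_character_,
                 diagnostic_junctions = "", coverage = NA_real_,
                 junctions = collapse_tags(r$junctions$tag),
                 n_accepted = r$n_accepted, stringsAsFactors = FALSE)
    }
  }))
  files <- c(bands = file.path(dir, "band_reports.tsv"),
             json = file.path(dir, "reports.json"))
  utils::write.table(band_rows, files[["bands"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(glycosites)) {
    files["glycosites"] <- file.path(dir, "glycosites.tsv")
    utils::write.table(glycosites, files[["glycosites"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  payload <- lapply(reports, function(r) {
    list(band = r$band, status = r$status,
         junctions = r$junctions, assignments = r$assignments,
         n_accepted = r$n_accepted)
  })
  jsonlite::write_json(payload, files[["json"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "rows")
  invisible(files)
}
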