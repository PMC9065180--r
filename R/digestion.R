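# In-silico chymotryptic digestion and combinatorial glycoform expansion.

#' In-silico chymotryptic digest
#'
#' Cleaves C-terminal to F/Y/W/L except when the next residue is proline,
#' returning all products with up to `max_missed` internal cleavage sites.
#' For a `protein_isoform`, peptides spanning an exon-exon junction carry
#' the junction tags (a peptide spans a junction iff it has at least one
#' residue on each side of the boundary).
#'
#' @param iso a `protein_isoform` or a plain amino-acid string.
#' @param max_missed maximum missed cleavages (default 2).
#' @param min_length,max_length peptide length bounds applied to the
#'   products (defaults 1 and `Inf`: the raw digest; search-space
#'   construction narrows to 5-45).
#' @param specificity residues cleaved after (default chymotryptic FYWL).
#' @param no_cut_before residues blocking cleavage when following the site
#'   (default P).
#' @return data.frame with `peptide`, `start0`, `end0` (0-based half-open
#'   on the isoform), `missed_cleavages`, `junction_tags` (comma string).
#' @export
digest <- function(iso, max_missed = 2L, min_length = 1L, max_length = Inf,
                   specificity = c("F", "Y", "W", "L"),
                   no_cut_before = "P") {
  if (inherits(iso, "protein_isoform")) {
    seq <- iso$aa_sequence
    isoform_id <- iso$isoform_id
    junctions <- iso$junctions
  } else {
    stopifnot(is.character(iso), length(iso) == 1L)
    seq <- iso
    isoform_id <- NA_character_
    junctions <- data.frame(tag = character(0), aa_boundary = integer(0))
  }
  if (!nzchar(seq)) stop("cannot digest an empty sequence")
  stopifnot(max_missed >= 0L)
  aa <- strsplit(seq, "")[[1]]
  n <- length(aa)
  is_site <- aa %in% specificity &
    c(!(aa[-1] %in% no_cut_before), FALSE)  # position n is the terminus
  bounds <- c(0L, which(is_site[-n]), n)    # 0-based cut points
  bounds <- unique(bounds)
  out <- list()
  nb <- length(bounds)
  for (j in seq_len(nb - 1L)) {
    for (k in (j + 1L):min(nb, j + 1L + max_missed)) {
      s0 <- bounds[j]; e0 <- bounds[k]
      len <- e0 - s0
      if (len < min_length || len > max_length) next
      tags <- junctions$tag[junctions$aa_boundary > s0 &
                              junctions$aa_boundary < e0]
      out[[length(out) + 1L]] <- data.frame(
        peptide = substr(seq, s0 + 1L, e0),
        start0 = s0, end0 = e0,
        missed_cleavages = k - j - 1L,
        junction_tags = collapse_tags(tags),
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else {
    data.frame(peptide = character(0), start0 = integer(0), end0 = integer(0),
               missed_cleavages = integer(0), junction_tags = character(0))
  }
  res$isoform_id <- isoform_id
  res[, c("isoform_id", "peptide", "start0", "end0", "missed_cleavages",
          "junction_tags")]
}

#' Expand a peptide into glycopeptide candidates
#'
#' Enumerates all assignments of 0 to `max_occupied_sites` distinct Ser/Thr
#' sites to glycan compositions from the search space (compositions may
#' repeat across sites), in a deterministic lexicographic order, capped at
#' `max_candidates`. Fixed modifications (carbamidomethyl-C by default) are
#' always applied. The theoretical neutral mass is the peptide backbone
#' plus all modification deltas.
#'
#' @param peptide one row of a [digest()] result, or an amino-acid string.
#' @param space list of `glycan_composition` (or composition strings); every
#'   member must have `HexNAc >= 1` (O-GalNAc core).
#' @param max_occupied_sites maximum glycosylated sites per peptide
#'   (default 3).
#' @param max_candidates enumeration cap; exceeding it truncates the list
#'   and sets the `truncated` attribute (default 1e4).
#' @param fixed_mods named numeric vector of per-residue fixed deltas
#'   (default carbamidomethyl on C).
#' @return data.frame of candidates: `peptide`, `sites` (comma-separated
#'   1-based positions within the peptide), `compositions`
#'   (semicolon-separated, parallel to `sites`), `glyco_delta`,
#'   `neutral_mass`, `n_glyco_sites`, plus provenance columns when a digest
#'   row was supplied. Attribute `truncated` reports cap hits.
#' @export
expand_glycoforms <- function(peptide, space, max_occupied_sites = 3L,
                              max_candidates = 1e4L,
                              fixed_mods = default_fixed_mods()) {
  if (is.data.frame(peptide)) {
    stopifnot(nrow(peptide) == 1L)
    seq <- peptide$peptide
    prov <- peptide[, intersect(c("isoform_id", "start0", "end0",
                                  "missed_cleavages", "junction_tags"),
                                names(peptide)), drop = FALSE]
  } else {
    seq <- peptide
    prov <- NULL
  }
  stopifnot(length(space) >= 1L)
  space <- lapply(space, as_composition)
  if (any(vapply(space, function(cc) cc[["HexNAc"]] < 1L, logical(1)))) {
    stop("every search-space composition must have HexNAc >= 1")
  }
  comp_str <- vapply(space, composition_string, character(1))
  deltas <- vapply(space, modification_delta, numeric(1))
  aa <- strsplit(seq, "")[[1]]
  st <- which(aa %in% c("S", "T"))
  base_mass <- peptide_mass(seq) +
    sum(fixed_mods[aa[aa %in% names(fixed_mods)]])
  m <- length(space)
  rows <- list(list(sites = integer(0), comps = integer(0)))
  truncated <- FALSE
  kmax <- min(max_occupied_sites, length(st))
  for (k in seq_len(kmax)) {
    if (truncated) break
    # combn over indices: combn(x, k) with scalar x would enumerate 1:x
    site_sets <- lapply(utils::combn(seq_along(st), k, simplify = FALSE),
                        function(ix) st[ix])
    for (ss in site_sets) {
      grid <- do.call(expand.grid,
                      c(rev(replicate(k, seq_len(m), simplify = FALSE)),
                        KEEP.OUT.ATTRS = FALSE))
      grid <- grid[, rev(seq_len(k)), drop = FALSE]  # first site varies slowest
      for (g in seq_len(nrow(grid))) {
        if (length(rows) >= max_candidates) { truncated <- TRUE; break }
        rows[[length(rows) + 1L]] <- list(sites = ss,
                                          comps = as.integer(grid[g, ]))
      }
      if (truncated) break
    }
  }
  res <- data.frame(
    peptide = seq,
    sites = vapply(rows, function(r) collapse_tags(r$sites), character(1)),
    compositions = vapply(rows, function(r) {
      if (!length(r$comps)) "" else paste(comp_str[r$comps], collapse = ";")
    }, character(1)),
    glyco_delta = vapply(rows, function(r) sum(deltas[r$comps]), numeric(1)),
    n_glyco_sites = vapply(rows, function(r) length(r$sites), integer(1)),
    stringsAsFactors = FALSE)
  res$neutral_mass <- base_mass + res$glyco_delta
  if (!is.null(prov)) res <- cbind(prov, res, row.names = NULL)
  attr(res, "truncated") <- truncated
  res
}

#' Default fixed modifications (carbamidomethyl cysteine)
#' @return named numeric vector of residue deltas in Da.
#' @export
default_fixed_mods <- function() {
  c(C = formula_mass("C2H3NO"))
}

#' Precursor m/z of a glycopeptide candidate
#'
#' @param candidate a candidate data.frame row (needs `neutral_mass`) or a
#'   neutral mass.
#' @param z charge state, >= 1.
#' @return (neutral mass + z * proton) / z.
#' @export
precursor_mz <- function(candidate, z) {
  m <- if (is.data.frame(candidate)) candidate$neutral_mass else candidate
  mass_to_mz(m, z)
}

#' Build a target-decoy glycopeptide candidate database
#'
#' Digests each isoform (length bounds 5-45 by default), expands glycoforms
#' against the search space, and appends reversed-sequence decoys
#' (C-terminal residue preserved) expanded identically so that decoys match
#' targets in peptide mass distribution and glyco-site counts.
#'
#' @param isoforms list of `protein_isoform`.
#' @param space glycan search space (list of compositions).
#' @param max_missed,min_length,max_length digestion parameters.
#' @param max_occupied_sites,max_candidates expansion parameters.
#' @param decoys add reversed decoys (default TRUE).
#' @return data.frame of candidates with an `is_decoy` column, sorted by
#'   `neutral_mass`.
#' @export
build_candidate_db <- function(isoforms, space, max_missed = 2L,
                               min_length = 5L, max_length = 45L,
                               max_occupied_sites = 3L, max_candidates = 1e4L,
                               decoys = TRUE) {
  all_rows <- list()
  for (iso in isoforms) {
    pep <- digest(iso, max_missed = max_missed, min_length = min_length,
                  max_length = max_length)
    pep <- pep[!duplicated(pep[, c("peptide", "start0", "end0")]), , drop = FALSE]
    for (i in seq_len(nrow(pep))) {
      tgt <- expand_glycoforms(pep[i, ], space,
                               max_occupied_sites = max_occupied_sites,
                               max_candidates = max_candidates)
      tgt$is_decoy <- FALSE
      all_rows[[length(all_rows) + 1L]] <- tgt
      if (decoys) {
        dec_seq <- reverse_decoy(pep$peptide[i])
        if (!identical(dec_seq, pep$peptide[i])) {
          dec <- expand_glycoforms(dec_seq, space,
                                   max_occupied_sites = max_occupied_sites,
                                   max_candidates = max_candidates)
          dec$isoform_id <- paste0("decoy_", pep$isoform_id[i])
          dec$start0 <- pep$start0[i]; dec$end0 <- pep$end0[i]
          dec$missed_cleavages <- pep$missed_cleavages[i]
          dec$junction_tags <- ""
          dec$is_decoy <- TRUE
          all_rows[[length(all_rows) + 1L]] <-
            dec[, names(all_rows[[1L]]), drop = FALSE]
        }
      }
    }
  }
  db <- do.call(rbind, all_rows)
  db <- db[!(db$is_decoy &
               db$peptide %in% db$peptide[!db$is_decoy]), , drop = FALSE]
  db <- db[order(db$neutral_mass, db$peptide, db$sites), , drop = FALSE]
  rownames(db) <- NULL
  db
}

#' Reversed-sequence decoy peptide (C-terminal residue preserved)
#'
#' @param seq amino-acid string.
#' @return decoy sequence.
#' @export
reverse_decoy <- function(seq) {
  aa <- strsplit(seq, "")[[1]]
  n <- length(aa)
  if (n <= 2L) return(seq)
  paste(c(rev(aa[seq_len(n - 1L)]), aa[n]), collapse = "")
}

#' Write a candidate database to TSV
#' @param db candidate data.frame from [build_candidate_db()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_candidate_tsv <- function(db, path) {
  utils::write.table(db, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
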