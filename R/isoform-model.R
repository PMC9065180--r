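# Exon grammar, transcript models, translation to protein isoforms and
# exon-exon junction bookkeeping.
#
# An exon model is the splice grammar of a gene: constitutive and variable
# exons with nucleotide (or directly amino-acid) sequences. Transcripts are
# ordered lists of (possibly partial) exon usages; translating a transcript
# yields a protein isoform annotated with the exon-exon junction positions
# that make splice events diagnosable at the peptide level.

#' Construct an exon model
#'
#' @param exons data.frame with columns `exon_id` (unique), `category`
#'   (`"constitutive"` or `"variable"`), `sequence` (non-empty; A/C/G/T in
#'   nucleotide mode, amino acids in aa mode) and optionally
#'   `partial_allowed` (logical, default `TRUE`).
#' @param mode `"nt"` for nucleotide exons (translated at transcript
#'   level) or `"aa"` for amino-acid exons (isoforms spliced directly).
#' @return an object of class `exon_model`.
#' @export
exon_model <- function(exons, mode = c("nt", "aa")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(exons),
            all(c("exon_id", "category", "sequence") %in% names(exons)))
  if (!"partial_allowed" %in% names(exons)) exons$partial_allowed <- TRUE
  exons$exon_id <- as.character(exons$exon_id)
  exons$sequence <- toupper(as.character(exons$sequence))
  if (anyDuplicated(exons$exon_id)) stop("exon_id values must be unique")
  if (any(!nzchar(exons$sequence))) stop("exon sequences must be non-empty")
  if (!all(exons$category %in% c("constitutive", "variable"))) {
    stop("exon category must be 'constitutive' or 'variable'")
  }
  alphabet <- if (mode == "nt") "^[ACGT]+$" else "^[ACDEFGHIKLMNPQRSTVWY]+$"
  if (any(!grepl(alphabet, exons$sequence))) {
    stop("exon sequence contains characters outside the ", mode, " alphabet")
  }
  structure(list(exons = exons[, c("exon_id", "category", "sequence",
                                   "partial_allowed")],
                 mode = mode),
            class = "exon_model")
}

#' @export
print.exon_model <- function(x, ...) {
  cat("<exon model> ", nrow(x$exons), " exons (",
      sum(x$exons$category == "variable"), " variable), mode=", x$mode,
      "\n", sep = "")
  invisible(x)
}

#' Construct a transcript model
#'
#' @param transcript_id character scalar.
#' @param exon_refs either a character vector of exon ids (full exons) or a
#'   data.frame with columns `exon_id`, `start`, `end` giving 0-based
#'   half-open offsets on exon-local coordinates (`NA` start/end = full
#'   exon). Order is preserved in all derived products.
#' @param declared_coding logical annotation carried through reports.
#' @return an object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, exon_refs, declared_coding = TRUE) {
  if (is.character(exon_refs)) {
    exon_refs <- data.frame(exon_id = exon_refs, start = NA_integer_,
                            end = NA_integer_, stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(exon_refs),
            all(c("exon_id", "start", "end") %in% names(exon_refs)),
            nrow(exon_refs) >= 1L)
  structure(list(transcript_id = as.character(transcript_id),
                 exon_refs = exon_refs,
                 declared_coding = isTRUE(declared_coding)),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat("<transcript> ", x$transcript_id, ": ",
      paste(x$exon_refs$exon_id, collapse = " - "), "\n", sep = "")
  invisible(x)
}

# Resolve a transcript against a model: returns the spliced sequence, the
# per-usage slices, and junction tags with cumulative boundary positions
# (in spliced-sequence letters: nt in nt mode, aa in aa mode).
splice_transcript <- function(model, transcript) {
  stopifnot(inherits(model, "exon_model"), inherits(transcript, "transcript_model"))
  refs <- transcript$exon_refs
  idx <- match(refs$exon_id, model$exons$exon_id)
  if (anyNA(idx)) {
    stop("transcript ", transcript$transcript_id, " references unknown exon(s): ",
         paste(refs$exon_id[is.na(idx)], collapse = ", "))
  }
  pieces <- character(nrow(refs))
  partial <- logical(nrow(refs))
  for (i in seq_len(nrow(refs))) {
    full <- model$exons$sequence[idx[i]]
    s <- refs$start[i]; e <- refs$end[i]
    if (is.na(s)) s <- 0L
    if (is.na(e)) e <- nchar(full)
    if (s < 0L || e > nchar(full) || s >= e) {
      stop("offsets [", s, ",", e, ") out of bounds for exon ",
           refs$exon_id[i], " (length ", nchar(full), ")")
    }
    partial[i] <- (s > 0L) || (e < nchar(full))
    if (partial[i] && !model$exons$partial_allowed[idx[i]]) {
      stop("partial usage not allowed for exon ", refs$exon_id[i])
    }
    pieces[i] <- substr(full, s + 1L, e)
  }
  lens <- nchar(pieces)
  tag_part <- ifelse(partial, paste0(refs$exon_id, "(partial)"), refs$exon_id)
  n <- nrow(refs)
  junctions <- if (n > 1L) {
    data.frame(tag = paste0(tag_part[-n], "-", tag_part[-1L]),
               boundary = cumsum(lens)[-n],
               stringsAsFactors = FALSE)
  } else {
    data.frame(tag = character(0), boundary = integer(0))
  }
  list(sequence = paste(pieces, collapse = ""), junctions = junctions)
}

#' Screen a transcript for protein-coding plausibility
#'
#' Classifies a nucleotide-mode transcript by scanning the spliced sequence
#' from its first AUG: `no_orf` when no start codon exists, `premature_stop`
#' when a stop codon truncates the open reading frame below `min_orf_aa`
#' residues, `fragment_noncoding` when the sequence runs out below
#' `min_orf_aa` without a stop, else `coding`. Deterministic given the model
#' and the rules.
#'
#' @param model an `exon_model` in nucleotide mode.
#' @param transcript a `transcript_model`.
#' @param min_orf_aa minimum ORF length in residues (default 30, excluding
#'   the stop codon) below which a transcript is considered non-coding.
#' @return an object of class `transcript_verdict`: list with
#'   `transcript_id`, `status`, `reason`.
#' @export
screen_transcript <- function(model, transcript, min_orf_aa = 30L) {
  if (model$mode != "nt") {
    stop("ORF screening applies to nucleotide-mode models only")
  }
  sp <- splice_transcript(model, transcript)
  orf <- find_first_orf(sp$sequence)
  verdict <- function(status, reason) {
    structure(list(transcript_id = transcript$transcript_id,
                   status = status, reason = reason),
              class = "transcript_verdict")
  }
  if (is.null(orf)) {
    return(verdict("no_orf", "no AUG start codon in the spliced sequence"))
  }
  if (orf$n_aa < min_orf_aa) {
    if (orf$stopped) {
      return(verdict("premature_stop",
                     sprintf("ORF of %d aa terminated by an in-frame stop (< %d aa)",
                             orf$n_aa, min_orf_aa)))
    }
    return(verdict("fragment_noncoding",
                   sprintf("ORF of %d aa runs off the transcript end (< %d aa)",
                           orf$n_aa, min_orf_aa)))
  }
  verdict("coding", sprintf("ORF of %d aa from the first AUG", orf$n_aa))
}

#' @export
print.transcript_verdict <- function(x, ...) {
  cat("<verdict> ", x$transcript_id, ": ", x$status, " (", x$reason, ")\n",
      sep = "")
  invisible(x)
}

# First-AUG ORF: start offset (0-based nt), residues translated (excluding
# stop), whether a stop codon was reached, and the protein sequence.
find_first_orf <- function(nt, genetic_code = Biostrings::GENETIC_CODE) {
  start0 <- regexpr("ATG", nt, fixed = TRUE)[1]
  if (start0 < 0L) return(NULL)
  start0 <- start0 - 1L
  coding <- substr(nt, start0 + 1L, nchar(nt))
  n_codon <- nchar(coding) %/% 3L
  if (n_codon == 0L) return(list(start0 = start0, n_aa = 0L, stopped = FALSE,
                                 protein = ""))
  coding <- substr(coding, 1L, n_codon * 3L)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(coding),
                                           genetic.code = genetic_code,
                                           if.fuzzy.codon = "error"))
  stop_at <- regexpr("*", aa, fixed = TRUE)[1]
  if (stop_at > 0L) {
    list(start0 = start0, n_aa = stop_at - 1L, stopped = TRUE,
         protein = substr(aa, 1L, stop_at - 1L))
  } else {
    list(start0 = start0, n_aa = nchar(aa), stopped = FALSE, protein = aa)
  }
}

#' Translate a transcript into a protein isoform
#'
#' In nucleotide mode the spliced transcript is translated from its first
#' AUG until the first stop codon; exon-exon junction positions are carried
#' into amino-acid coordinates. In amino-acid mode the exon sequences are
#' concatenated directly. Junctions falling outside the translated region
#' are dropped (they leave no peptide-level trace).
#'
#' When the transcript fails ORF screening a `transcript_verdict` is
#' returned instead of an isoform; check the class of the result.
#'
#' @param model an `exon_model`.
#' @param transcript a `transcript_model`.
#' @param min_orf_aa see [screen_transcript()].
#' @param isoform_id identifier for the product (default the transcript id).
#' @param genetic_code a Biostrings-style genetic code table.
#' @return a `protein_isoform` (list with `isoform_id`, `aa_sequence`,
#'   `junctions` data.frame of `tag`, `aa_boundary` — the number of residues
#'   fully encoded upstream, so the junction lies between residues
#'   `aa_boundary` and `aa_boundary + 1` — and `downstream_start0`, the
#'   0-based index of the first residue containing downstream-exon
#'   nucleotides — and `source_transcript`), or a `transcript_verdict` for
#'   non-coding transcripts.
#' @export
translate_transcript <- function(model, transcript, min_orf_aa = 30L,
                                 isoform_id = transcript$transcript_id,
                                 genetic_code = Biostrings::GENETIC_CODE) {
  sp <- splice_transcript(model, transcript)
  if (model$mode == "aa") {
    jn <- sp$junctions
    len <- nchar(sp$sequence)
    keep <- jn$boundary >= 1L & jn$boundary <= len - 1L
    return(new_protein_isoform(
      isoform_id, sp$sequence,
      data.frame(tag = jn$tag[keep], aa_boundary = jn$boundary[keep],
                 downstream_start0 = jn$boundary[keep], stringsAsFactors = FALSE),
      transcript$transcript_id))
  }
  v <- screen_transcript(model, transcript, min_orf_aa = min_orf_aa)
  if (v$status != "coding") return(v)
  orf <- find_first_orf(sp$sequence, genetic_code = genetic_code)
  n_aa <- orf$n_aa
  jn <- sp$junctions
  r <- jn$boundary - orf$start0
  aa_boundary <- r %/% 3L
  keep <- r > 0L & r < 3L * n_aa & aa_boundary >= 1L & aa_boundary <= n_aa - 1L
  new_protein_isoform(
    isoform_id, orf$protein,
    data.frame(tag = jn$tag[keep], aa_boundary = aa_boundary[keep],
               downstream_start0 = aa_boundary[keep], stringsAsFactors = FALSE),
    transcript$transcript_id)
}

new_protein_isoform <- function(isoform_id, aa_sequence, junctions,
                                source_transcript) {
  stopifnot(nzchar(aa_sequence))
  if (nrow(junctions)) {
    stopifnot(all(junctions$aa_boundary >= 1L),
              all(junctions$aa_boundary <= nchar(aa_sequence) - 1L),
              !is.unsorted(junctions$aa_boundary))
  }
  structure(list(isoform_id = as.character(isoform_id),
                 aa_sequence = aa_sequence,
                 junctions = junctions,
                 source_transcript = as.character(source_transcript)),
            class = "protein_isoform")
}

#' @export
print.protein_isoform <- function(x, ...) {
  cat("<isoform> ", x$isoform_id, ": ", nchar(x$aa_sequence), " aa, junctions: ",
      if (nrow(x$junctions)) collapse_tags(x$junctions$tag) else "none",
      "\n", sep = "")
  invisible(x)
}

#' Enumerate junction-flanking sequence windows
#'
#' For each exon-exon junction of an isoform, extract the window of `flank`
#' residues on each side of the boundary (clipped at the sequence ends). A
#' peptide is junction-diagnostic iff it spans the boundary with at least
#' one residue on each side.
#'
#' @param iso a `protein_isoform`.
#' @param flank residues per side, >= 1.
#' @return data.frame with `junction_tag`, `window`, `start`, `end`
#'   (1-based inclusive positions of the window on the isoform).
#' @export
enumerate_junction_windows <- function(iso, flank) {
  stopifnot(inherits(iso, "protein_isoform"), flank >= 1L)
  jn <- iso$junctions
  len <- nchar(iso$aa_sequence)
  start <- pmax(1L, jn$aa_boundary - as.integer(flank) + 1L)
  end <- pmin(len, jn$aa_boundary + as.integer(flank))
  data.frame(junction_tag = jn$tag,
             window = substring(iso$aa_sequence, start, end),
             start = start, end = end, stringsAsFactors = FALSE)
}

#' Write protein isoforms to FASTA
#'
#' Headers follow `<isoform_id> transcript=<id> junctions=<tag,tag,...>`
#' with 60-column sequence wrapping. Junction boundary positions are
#' appended as `@<aa_boundary>` to each tag so that [read_isoform_fasta()]
#' recovers the full junction table.
#'
#' @param isoforms a list of `protein_isoform` objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_isoform_fasta <- function(isoforms, path) {
  stopifnot(length(isoforms) >= 1L)
  ids <- vapply(isoforms, `[[`, character(1), "isoform_id")
  if (anyDuplicated(ids)) stop("duplicate isoform_id in FASTA export")
  headers <- vapply(isoforms, function(iso) {
    jn <- iso$junctions
    jtag <- if (nrow(jn)) {
      paste0(jn$tag, "@", jn$aa_boundary, collapse = ",")
    } else "none"
    paste0(iso$isoform_id, " transcript=", iso$source_transcript,
           " junctions=", jtag)
  }, character(1))
  seqs <- Biostrings::AAStringSet(vapply(isoforms, `[[`, character(1),
                                         "aa_sequence"))
  names(seqs) <- headers
  Biostrings::writeXStringSet(seqs, filepath = path, width = 60L)
  invisible(path)
}

#' Read protein isoforms from FASTA written by [write_isoform_fasta()]
#'
#' @param path FASTA file path.
#' @return list of `protein_isoform` objects.
#' @export
read_isoform_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  lapply(seq_along(seqs), function(i) {
    header <- names(seqs)[i]
    parts <- strsplit(header, " ", fixed = TRUE)[[1]]
    iso_id <- parts[1]
    kv <- parts[grepl("=", parts, fixed = TRUE)]
    vals <- stats::setNames(sub("^[^=]+=", "", kv), sub("=.*$", "", kv))
    jn <- if (identical(unname(vals["junctions"]), "none")) {
      data.frame(tag = character(0), aa_boundary = integer(0),
                 downstream_start0 = integer(0))
    } else {
      toks <- strsplit(vals[["junctions"]], ",", fixed = TRUE)[[1]]
      tag <- sub("@[0-9]+$", "", toks)
      b <- as.integer(sub("^.*@", "", toks))
      data.frame(tag = tag, aa_boundary = b, downstream_start0 = b,
                 stringsAsFactors = FALSE)
    }
    new_protein_isoform(iso_id, as.character(seqs[[i]]), jn,
                        unname(vals["transcript"]))
  })
}

#' Read an exon model from TSV
#'
#' Expected columns: `exon_id`, `category`, `mode` (constant per file,
#' `"nt"` or `"aa"`), `sequence`, optional `partial_allowed`.
#'
#' @param path TSV file path.
#' @return an `exon_model`.
#' @export
read_exon_model_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot("mode" %in% names(df), length(unique(df$mode)) == 1L)
  exon_model(df[, setdiff(names(df), "mode")], mode = unique(df$mode))
}

#' Read transcript definitions from JSON
#'
#' The JSON is a list of objects with `transcript_id` and `exon_refs`,
#' where each exon ref is either an exon id string or an object with
#' `exon_id`, `start`, `end` (0-based half-open exon-local offsets).
#'
#' @param path JSON file path.
#' @return list of `transcript_model` objects.
#' @export
read_transcripts_json <- function(path) {
  defs <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(defs, function(d) {
    refs <- do.call(rbind, lapply(d$exon_refs, function(r) {
      if (is.character(r)) {
        data.frame(exon_id = r, start = NA_integer_, end = NA_integer_,
                   stringsAsFactors = FALSE)
      } else {
        off <- function(x) {
          if (is.null(x) || !length(x)) NA_integer_ else as.integer(x)
        }
        data.frame(exon_id = r$exon_id, start = off(r$start),
                   end = off(r$end), stringsAsFactors = FALSE)
      }
    }))
    transcript_model(d$transcript_id, refs,
                     declared_coding = isTRUE(d$declared_coding %||% TRUE))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
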