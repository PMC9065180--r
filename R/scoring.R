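# Glycopeptide-spectrum matching: binomial-tail scoring, target-decoy
# q-values, and glycosite localization.
#
# The scorer is an open, documented surrogate for proprietary search-engine
# internals: each candidate is scored by the upper tail probability of
# matching as many theoretical ions by chance as were observed, with the
# per-ion chance-match probability estimated from the spectrum's peak
# density. Presence/absence only: the score is invariant to peak order and
# intensity scaling. A GPSM is reported only when it reaches a minimum
# number of matched ions: one or two matched peaks are no evidence for a
# glycopeptide, and the sparse decoy tail cannot calibrate them.

# number of theoretical ions with at least one observed peak within +/- tol
count_matches <- function(theo_mz, obs_mz, tol) {
  if (!length(obs_mz) || !length(theo_mz)) return(0L)
  idx <- findInterval(theo_mz, obs_mz)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(obs_mz))
  d <- pmin(abs(theo_mz - obs_mz[lo]), abs(obs_mz[hi] - theo_mz))
  sum(d <= tol)
}

matched_flags <- function(theo_mz, obs_mz, tol) {
  if (!length(obs_mz)) return(rep(FALSE, length(theo_mz)))
  idx <- findInterval(theo_mz, obs_mz)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(obs_mz))
  pmin(abs(theo_mz - obs_mz[lo]), abs(obs_mz[hi] - theo_mz)) <= tol
}

default_fragment_tol <- function(frag_type) {
  switch(frag_type, HCD = 0.02, CID = 0.6,
         stop("unknown fragmentation type: ", frag_type))
}

binomial_score <- function(k, n, p) {
  if (k <= 0L || n <= 0L) return(0)
  logp <- stats::pbinom(k - 1L, n, p, lower.tail = FALSE, log.p = TRUE)
  max(0, -logp / log(10))
}

#' Score a spectrum against glycopeptide candidates
#'
#' Candidates whose precursor m/z (at the spectrum's charge) lies within
#' `precursor_tol_ppm` of the observed precursor are scored by
#' `-log10 P[Binomial(n, p) >= k]`, where `n` is the number of theoretical
#' ions, `k` the number matched within the fragment tolerance, and
#' `p = 2 * tol * n_peaks / span` the chance-match probability for the
#' spectrum's peak density. Ties are broken by fewer glyco sites, then by
#' peptide and site annotation lexicographically.
#'
#' @param s an `ms_spectrum`.
#' @param candidates candidate data.frame ([build_candidate_db()]).
#' @param tol fragment tolerance in Da (default 0.02 for HCD, 0.6 for
#'   CID).
#' @param precursor_tol_ppm precursor window (default 5 ppm).
#' @param assume_charge charge used when the spectrum's is unknown
#'   (default 2).
#' @param max_charge highest fragment charge generated.
#' @param min_matched minimum matched ions for a GPSM to be reported
#'   (default 4, the usual search-engine floor); candidates below it are
#'   dropped, not ranked.
#' @param fragment_cache optional environment memoizing theoretical
#'   fragments across spectra (used by [search_spectra()]).
#' @return data.frame of ranked GPSMs (may be empty): `scan_id`, `rank`,
#'   `peptide`, `isoform_id`, `junction_tags`, `sites`, `compositions`,
#'   `n_glyco_sites`, `neutral_mass`, `precursor_ppm`, `n_theoretical`,
#'   `n_matched`, `score`, `is_decoy`.
#' @export
score_spectrum <- function(s, candidates, tol = NULL, precursor_tol_ppm = 5,
                           assume_charge = 2L, max_charge = 2L,
                           min_matched = 4L, fragment_cache = NULL) {
  stopifnot(inherits(s, "ms_spectrum"))
  if (is.null(tol)) tol <- default_fragment_tol(s$frag_type)
  empty <- data.frame(scan_id = character(0), rank = integer(0),
                      peptide = character(0), isoform_id = character(0),
                      junction_tags = character(0), sites = character(0),
                      compositions = character(0), n_glyco_sites = integer(0),
                      neutral_mass = numeric(0), precursor_ppm = numeric(0),
                      n_theoretical = integer(0), n_matched = integer(0),
                      score = numeric(0), is_decoy = logical(0))
  if (!nrow(candidates)) return(empty)
  z <- if (is.na(s$charge)) as.integer(assume_charge) else s$charge
  obs_neutral <- z * (s$precursor_mz - .PROTON_MASS)
  dppm <- ppm_error(obs_neutral, candidates$neutral_mass)
  hits <- which(abs(dppm) <= precursor_tol_ppm)
  if (!length(hits)) return(empty)
  span <- if (length(s$mz) > 1L) diff(range(s$mz)) else 0
  p_rand <- if (span > 0) min(0.5, 2 * tol * length(s$mz) / span) else 0.5
  rows <- lapply(hits, function(i) {
    cand <- candidates[i, , drop = FALSE]
    fr <- if (!is.null(fragment_cache)) {
      key <- paste(cand$peptide, cand$sites, cand$compositions, s$frag_type,
                   max_charge, sep = "|")
      if (!exists(key, envir = fragment_cache, inherits = FALSE)) {
        assign(key, theoretical_fragments(cand, mode = s$frag_type,
                                          max_charge = max_charge),
               envir = fragment_cache)
      }
      get(key, envir = fragment_cache, inherits = FALSE)
    } else {
      theoretical_fragments(cand, mode = s$frag_type, max_charge = max_charge)
    }
    k <- count_matches(sort(fr$mz), s$mz, tol)
    if (k < min_matched) return(NULL)
    data.frame(scan_id = s$scan_id, rank = NA_integer_,
               peptide = cand$peptide,
               isoform_id = cand$isoform_id %||% NA_character_,
               junction_tags = cand$junction_tags %||% "",
               sites = cand$sites, compositions = cand$compositions,
               n_glyco_sites = cand$n_glyco_sites,
               neutral_mass = cand$neutral_mass,
               precursor_ppm = dppm[i],
               n_theoretical = nrow(fr), n_matched = k,
               score = binomial_score(k, nrow(fr), p_rand),
               is_decoy = isTRUE(cand$is_decoy),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  o <- order(-out$score, out$n_glyco_sites, out$peptide, out$sites)
  out <- out[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Search a spectrum stream, keeping the top match per spectrum
#'
#' @param spectra list of `ms_spectrum`.
#' @param candidates candidate database.
#' @param ... passed to [score_spectrum()].
#' @param report_ratio also record the 144.066/138.055 diagnostic ratio of
#'   each HCD spectrum (default TRUE).
#' @return data.frame of top-ranked GPSMs, one row per spectrum with any
#'   candidate in the precursor window.
#' @export
search_spectra <- function(spectra, candidates, ..., report_ratio = TRUE) {
  cache <- new.env(parent = emptyenv())
  rows <- lapply(spectra, function(s) {
    g <- score_spectrum(s, candidates, ..., fragment_cache = cache)
    if (!nrow(g)) return(NULL)
    top <- g[1L, , drop = FALSE]
    if (report_ratio && s$frag_type == "HCD") {
      top$oxonium_ratio <- as.numeric(diagnostic_ratio(s))
    } else {
      top$oxonium_ratio <- NA_real_
    }
    top
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    out <- score_spectrum(ms_spectrum("void", 1, 1, "HCD", numeric(0),
                                      numeric(0)),
                          candidates[0, , drop = FALSE])
    out$oxonium_ratio <- numeric(0)
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Target-decoy q-values for a GPSM table
#'
#' Sorting GPSMs by decreasing score, the FDR at a score threshold is
#' estimated as (number of decoys) / (number of targets) at or above the
#' threshold; the q-value is the minimum estimated FDR over all thresholds
#' at or below the GPSM's score, so q-values are monotone non-decreasing in
#' decreasing score.
#'
#' @param gpsms GPSM data.frame with `score` and `is_decoy`.
#' @return the table with a `q_value` column, sorted by decreasing score.
#' @export
target_decoy_fdr <- function(gpsms) {
  if (!nrow(gpsms)) {
    gpsms$q_value <- numeric(0)
    return(gpsms)
  }
  o <- order(-gpsms$score, gpsms$is_decoy)
  g <- gpsms[o, , drop = FALSE]
  n_decoy <- cumsum(g$is_decoy)
  n_target <- cumsum(!g$is_decoy)
  fdr <- n_decoy / pmax(n_target, 1L)
  g$q_value <- rev(cummin(rev(pmin(fdr, 1))))
  rownames(g) <- NULL
  g
}

#' Glycosite localization by site-determining ions
#'
#' For the top candidate of a spectrum, every alternative placement of the
#' same glycan multiset on the peptide's Ser/Thr sites is enumerated. Ions
#' whose m/z depends on the placement (glycan-retained b/y ions in HCD)
#' are site-determining; the assignment is `localized` iff its matched
#' site-determining ion count strictly exceeds every alternative's.
#' Candidates with a single possible placement are localized trivially;
#' spectra with no discriminating ions matched are `ambiguous`.
#'
#' @param gpsm one GPSM row.
#' @param s the matched `ms_spectrum`.
#' @param tol fragment tolerance in Da (defaults per fragmentation type).
#' @return list with `localized` (logical), `status` (`"localized"` or
#'   `"ambiguous"`), `margin` (matched site-determining ions beyond the
#'   best alternative), `n_alternatives`.
#' @export
localize_sites <- function(gpsm, s, tol = NULL) {
  stopifnot(nrow(gpsm) == 1L)
  if (is.null(tol)) tol <- default_fragment_tol(s$frag_type)
  gl <- candidate_glyco(gpsm)
  k <- length(gl$sites)
  aa <- strsplit(gpsm$peptide, "")[[1]]
  st <- which(aa %in% c("S", "T"))
  if (k == 0L) {
    return(list(localized = TRUE, status = "localized", margin = Inf,
                n_alternatives = 0L))
  }
  # all placements of the composition multiset on the S/T sites
  placements <- placement_set(st, gl$compositions)
  own_key <- placement_key(gl$sites, gl$compositions)
  keys <- vapply(placements, function(p) placement_key(p$sites, p$comps),
                 character(1))
  alt <- placements[keys != own_key]
  if (!length(alt)) {
    return(list(localized = TRUE, status = "localized", margin = Inf,
                n_alternatives = 0L))
  }
  score_placement <- function(sites, comps) {
    cand <- data.frame(peptide = gpsm$peptide,
                       sites = collapse_tags(sites),
                       compositions = paste(comps, collapse = ";"),
                       stringsAsFactors = FALSE)
    fr <- theoretical_fragments(cand, mode = s$frag_type)
    fr <- fr[fr$site_dependent, , drop = FALSE]
    if (!nrow(fr)) return(0L)
    count_matches(sort(fr$mz), s$mz, tol)
  }
  own <- score_placement(gl$sites, gl$compositions)
  alt_scores <- vapply(alt, function(p) score_placement(p$sites, p$comps),
                       integer(1))
  margin <- own - max(alt_scores)
  list(localized = margin > 0L,
       status = if (margin > 0L) "localized" else "ambiguous",
       margin = margin, n_alternatives = length(alt))
}

placement_key <- function(sites, comps) {
  o <- order(sites)
  paste(sites[o], comps[o], sep = ":", collapse = ",")
}

# distinct assignments of a composition multiset to site subsets
placement_set <- function(st_sites, comps) {
  k <- length(comps)
  if (k > length(st_sites)) stop("more glycans than available S/T sites")
  site_sets <- lapply(utils::combn(seq_along(st_sites), k, simplify = FALSE),
                      function(ix) st_sites[ix])
  perms <- unique_permutations(comps)
  out <- list()
  for (ss in site_sets) {
    for (pp in perms) {
      out[[length(out) + 1L]] <- list(sites = ss, comps = pp)
    }
  }
  out
}

unique_permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (v in unique(x)) {
    rest <- x[-match(v, x)]
    for (p in unique_permutations(rest)) {
      out[[length(out) + 1L]] <- c(v, p)
    }
  }
  out
}

#' Write a GPSM table to TSV
#' @param gpsms GPSM data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gpsm_tsv <- function(gpsms, path) {
  utils::write.table(gpsms, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
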