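# Ground-truthed synthetic fixtures: a CD44-like toy exon grammar,
# glycome peak lists, and HCD/CID spectra for known glycopeptides with a
# configurable noise model. Everything is deterministic under a fixed
# seed; the caller's RNG state is never disturbed.

# Codon per amino acid (stop-free by construction); a fixed choice keeps
# the grammar deterministic and codon-aligned exons keep reading frames
# transparent across variable-exon skipping.
.CODON_OF <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
               Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
               L = "CTG", K = "AAA", M = "ATG", F = "TTT", P = "CCT",
               S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")

sample_exon_nt <- function(n_aa, st_weight) {
  aa_pool <- names(.CODON_OF)
  w <- rep(1, length(aa_pool))
  names(w) <- aa_pool
  w[c("S", "T")] <- st_weight
  w[c("L", "F", "Y")] <- 2.2          # chymotryptic sites keep peptides short
  w["W"] <- 0.5
  w["M"] <- 0.3
  w["P"] <- 0.6
  aa <- sample(aa_pool, n_aa, replace = TRUE, prob = w / sum(w))
  paste(.CODON_OF[aa], collapse = "")
}

#' Generate the CD44-like toy exon grammar
#'
#' A 19-exon synthetic nucleotide grammar shaped like the CD44 locus: five
#' constitutive N-terminal exons (e1-e5, e1 opening with ATG), nine
#' variable exons (v2-v10, Ser/Thr-rich to stress glycoform
#' combinatorics), and five constitutive C-terminal exons (e15-e19, e19
#' closing with a stop codon). All exons are codon-aligned and stop-free,
#' so every exon combination translates cleanly and junction positions
#' follow cumulative exon lengths. Sequences are synthetic; only the
#' grammar shape mirrors CD44. Transcripts emulate CD44s
#' (all-variable-skipped, diagnostic junction e5-e15), v2-10, v3-10 and
#' v8-10 structures, plus a short soluble-like form using partial exons
#' (junction e2(partial)-e3(partial)).
#'
#' @param seed integer fixing the grammar (default 44).
#' @return list with `model` (an `exon_model`), `transcripts` (named list
#'   of `transcript_model`).
#' @export
generate_toy_cd44_grammar <- function(seed = 44L) {
  with_seed(seed, {
    const_n <- paste0("e", 1:5)
    var_ids <- paste0("v", 2:10)
    const_c <- paste0("e", 15:19)
    exons <- list()
    for (id in const_n) {
      n_aa <- sample(20:28, 1)
      seq <- sample_exon_nt(n_aa, st_weight = 1.2)
      if (id == "e1") seq <- paste0("ATG", substr(seq, 4, nchar(seq)))
      exons[[id]] <- data.frame(exon_id = id, category = "constitutive",
                                sequence = seq, stringsAsFactors = FALSE)
    }
    for (id in var_ids) {
      n_aa <- sample(14:20, 1)
      exons[[id]] <- data.frame(exon_id = id, category = "variable",
                                sequence = sample_exon_nt(n_aa, st_weight = 4),
                                stringsAsFactors = FALSE)
    }
    for (id in const_c) {
      n_aa <- sample(16:24, 1)
      seq <- sample_exon_nt(n_aa, st_weight = 1.2)
      if (id == "e19") seq <- paste0(seq, "TAA")
      exons[[id]] <- data.frame(exon_id = id, category = "constitutive",
                                sequence = seq, stringsAsFactors = FALSE)
    }
    model <- exon_model(do.call(rbind, exons), mode = "nt")
    e2_len <- nchar(model$exons$sequence[model$exons$exon_id == "e2"])
    e3_len <- nchar(model$exons$sequence[model$exons$exon_id == "e3"])
    half3 <- function(len) (len %/% 6L) * 3L  # codon-aligned midpoint
    transcripts <- list(
      CD44s_like = transcript_model("CD44s_like", c(const_n, const_c)),
      CD44v2_10_like = transcript_model("CD44v2_10_like",
                                        c(const_n, var_ids, const_c)),
      CD44v3_10_like = transcript_model("CD44v3_10_like",
                                        c(const_n, paste0("v", 3:10), const_c)),
      CD44v8_10_like = transcript_model("CD44v8_10_like",
                                        c(const_n, paste0("v", 8:10), const_c)),
      CD44sol_like = transcript_model(
        "CD44sol_like",
        data.frame(exon_id = c("e1", "e2", "e3", "e19"),
                   start = c(NA, 0L, half3(e3_len), NA),
                   end = c(NA, half3(e2_len), NA, NA),
                   stringsAsFactors = FALSE))
    )
    list(model = model, transcripts = transcripts)
  })
}

#' Generator configuration for synthetic spectra
#'
#' @param seed RNG seed; fixes all generated output bit-for-bit.
#' @param efficiency fragment-sampling efficiency in (0, 1]: probability
#'   that a theoretical backbone/Y fragment appears in the spectrum.
#'   Oxonium ions of glycosylated precursors are always emitted (they are
#'   the high-abundance ions the acquisition triggers on).
#' @param lambda_noise expected number of noise peaks per spectrum
#'   (Poisson), uniform in m/z over `mz_range`, log-normal intensities.
#' @param jitter_ppm mass jitter (uniform, bounded) applied to fragment
#'   and precursor m/z, in ppm.
#' @param mz_range scan m/z range for noise peaks.
#' @param intensity_meanlog,intensity_sdlog log-normal intensity model for
#'   signal peaks; noise uses `noise_meanlog` with the same sdlog.
#' @param oxonium_ratio generated I(144.066)/I(138.055) intensity ratio
#'   (GalNAc-like default 2.5).
#' @param charges candidate precursor charge states sampled uniformly.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, efficiency = 0.7, lambda_noise = 20,
                             jitter_ppm = 5, mz_range = c(100, 2000),
                             intensity_meanlog = log(1e5),
                             intensity_sdlog = 0.6,
                             noise_meanlog = log(2e4),
                             oxonium_ratio = 2.5,
                             charges = 2:3) {
  stopifnot(efficiency > 0, efficiency <= 1, lambda_noise >= 0,
            jitter_ppm >= 0)
  structure(list(seed = as.integer(seed), efficiency = efficiency,
                 lambda_noise = lambda_noise, jitter_ppm = jitter_ppm,
                 mz_range = mz_range, intensity_meanlog = intensity_meanlog,
                 intensity_sdlog = intensity_sdlog,
                 noise_meanlog = noise_meanlog,
                 oxonium_ratio = oxonium_ratio, charges = charges),
            class = "generator_config")
}

jitter_mz <- function(mz, jitter_ppm) {
  if (jitter_ppm <= 0) return(mz)
  mz * (1 + stats::runif(length(mz), -jitter_ppm, jitter_ppm) * 1e-6)
}

# one synthetic spectrum for a candidate row; called inside with_seed
synth_one_spectrum <- function(cand, scan_id, frag_type, z, cfg) {
  fr <- theoretical_fragments(cand, mode = frag_type, max_charge = min(2L, z))
  is_ox <- fr$series == "oxonium"
  keep <- is_ox | stats::runif(nrow(fr)) <= cfg$efficiency
  fr <- fr[keep, , drop = FALSE]
  mz <- jitter_mz(fr$mz, cfg$jitter_ppm)
  int <- stats::rlnorm(nrow(fr), cfg$intensity_meanlog, cfg$intensity_sdlog)
  # impose the configured GalNAc-like oxonium intensity ratio
  i144 <- which(fr$label == "HexNAc-C2H6O3")
  i138 <- which(fr$label == "HexNAc-CH4O2-CH2O")
  if (length(i144) && length(i138)) {
    int[i144] <- int[i138] * cfg$oxonium_ratio
  }
  n_noise <- stats::rpois(1, cfg$lambda_noise)
  if (n_noise > 0) {
    mz <- c(mz, stats::runif(n_noise, cfg$mz_range[1], cfg$mz_range[2]))
    int <- c(int, stats::rlnorm(n_noise, cfg$noise_meanlog, cfg$intensity_sdlog))
  }
  pmz <- jitter_mz(precursor_mz(cand$neutral_mass, z), cfg$jitter_ppm)
  ms_spectrum(scan_id, pmz, z, frag_type, mz, int,
              rt = 60 * as.numeric(sub("^[a-zA-Z_]*", "", scan_id) %||% 0))
}

#' Generate ground-truthed tandem spectra for known glycopeptides
#'
#' For each truth candidate an HCD spectrum (and optionally a CID
#' spectrum) is generated: theoretical fragments sampled at the configured
#' efficiency (oxonium ions always present for glycosylated candidates,
#' never for unglycosylated ones), log-normal intensities, Poisson noise
#' peaks uniform in m/z, and bounded uniform m/z jitter on fragments and
#' precursor.
#'
#' @param candidates data.frame of truth candidates
#'   ([expand_glycoforms()] rows).
#' @param cfg a [generator_config()].
#' @param make_cid also emit a CID spectrum per candidate (default FALSE).
#' @return list with `spectra` (list of `ms_spectrum`) and `truth`
#'   (data.frame: `scan_id`, `peptide`, `sites`, `compositions`, `charge`,
#'   `glycosylated`, `neutral_mass`).
#' @export
generate_spectra <- function(candidates, cfg = generator_config(),
                             make_cid = FALSE) {
  with_seed(cfg$seed, {
    spectra <- list()
    truth <- list()
    for (i in seq_len(nrow(candidates))) {
      cand <- candidates[i, , drop = FALSE]
      z <- if (length(cfg$charges) == 1L) cfg$charges else
        sample(cfg$charges, 1)
      sid <- sprintf("hcd_%04d", i)
      spectra[[sid]] <- synth_one_spectrum(cand, sid, "HCD", z, cfg)
      truth[[sid]] <- data.frame(scan_id = sid, peptide = cand$peptide,
                                 sites = cand$sites,
                                 compositions = cand$compositions,
                                 charge = z,
                                 glycosylated = cand$n_glyco_sites > 0L,
                                 neutral_mass = cand$neutral_mass,
                                 frag_type = "HCD", stringsAsFactors = FALSE)
      if (make_cid) {
        sidc <- sprintf("cid_%04d", i)
        spectra[[sidc]] <- synth_one_spectrum(cand, sidc, "CID", z, cfg)
        truth[[sidc]] <- within(truth[[sid]], {
          scan_id <- sidc; frag_type <- "CID"
        })
      }
    }
    list(spectra = unname(spectra), truth = do.call(rbind, c(truth, list(
      make.row.names = FALSE))))
  })
}

#' Generate null (noise-only) spectra
#'
#' Pure-noise HCD spectra whose precursors sit inside the search windows
#' of randomly chosen database candidates, so that they are scored against
#' real candidates and exercise the false-match behavior of the scorer and
#' the target-decoy FDR.
#'
#' @param n number of spectra.
#' @param candidates candidate database supplying precursor masses.
#' @param cfg a [generator_config()]; `lambda_noise` gives the expected
#'   peak count.
#' @param scan_prefix id prefix (default "null_").
#' @return list of `ms_spectrum`.
#' @export
generate_null_spectra <- function(n, candidates, cfg = generator_config(),
                                  scan_prefix = "null_") {
  with_seed(cfg$seed + 1L, {
    lapply(seq_len(n), function(i) {
      cand <- candidates[sample(nrow(candidates), 1), , drop = FALSE]
      z <- if (length(cfg$charges) == 1L) cfg$charges else
        sample(cfg$charges, 1)
      n_noise <- max(1L, stats::rpois(1, cfg$lambda_noise))
      mz <- stats::runif(n_noise, cfg$mz_range[1], cfg$mz_range[2])
      int <- stats::rlnorm(n_noise, cfg$noise_meanlog, cfg$intensity_sdlog)
      pmz <- jitter_mz(precursor_mz(cand$neutral_mass, z),
                       cfg$jitter_ppm * 0.8)
      ms_spectrum(sprintf("%s%04d", scan_prefix, i), pmz, z, "HCD", mz, int)
    })
  })
}

#' Generate a synthetic MALDI glycome peak list
#'
#' Theoretical permethylated benzyl [M+Na]+ m/z values for the given
#' compositions, with bounded uniform ppm jitter and configurable
#' intensity ranks (to emulate, e.g., disialyl-T dominating a T24-like
#' glycome).
#'
#' @param compositions list of `glycan_composition` or composition
#'   strings.
#' @param jitter_ppm bounded uniform m/z jitter (default 0).
#' @param seed RNG seed.
#' @param intensities optional numeric vector (recycled); default
#'   descending ranks.
#' @return a `peak_list`.
#' @export
generate_glycome_peaks <- function(compositions, jitter_ppm = 0, seed = 1L,
                                   intensities = NULL) {
  if (!length(compositions)) {
    return(peak_list(numeric(0), numeric(0)))
  }
  with_seed(seed, {
    mz <- vapply(lapply(compositions, as_composition), permethylated_bn_mz,
                 numeric(1))
    if (is.null(intensities)) {
      intensities <- rev(seq_along(mz)) * 1000
    }
    peak_list(jitter_mz(mz, jitter_ppm),
              rep_len(intensities, length(mz)))
  })
}
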