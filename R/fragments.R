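# Theoretical fragment ions for glycopeptide candidates.

# Parse the candidate's site/composition annotation into parallel vectors.
candidate_glyco <- function(candidate) {
  sites <- if (nzchar(candidate$sites)) {
    as.integer(strsplit(candidate$sites, ",", fixed = TRUE)[[1]])
  } else integer(0)
  comps <- if (nzchar(candidate$compositions)) {
    strsplit(candidate$compositions, ";", fixed = TRUE)[[1]]
  } else character(0)
  stopifnot(length(sites) == length(comps))
  list(sites = sites, compositions = comps)
}

# per-residue masses including fixed modifications
residue_masses_fixed <- function(seq, fixed_mods = default_fixed_mods()) {
  aa <- strsplit(seq, "")[[1]]
  m <- aa_residue_masses()[aa]
  fix <- fixed_mods[aa]
  fix[is.na(fix)] <- 0
  unname(m + fix)
}

#' Theoretical fragment ions of a glycopeptide candidate
#'
#' HCD treats O-glycans as labile: both glycan-stripped (naked backbone)
#' and glycan-retained b/y ions are generated, plus the HexNAc oxonium
#' series when the candidate is glycosylated. CID generates the Y series -
#' the intact peptide retaining every sub-composition of the total glycan,
#' from Y0 (naked peptide) up to the full precursor - plus the oxonium
#' series. Singly and doubly charged fragments are emitted (charge 2 only
#' for fragments above m/z 200 at charge 1... pragmatically, all).
#'
#' @param candidate one row of a candidate data.frame
#'   ([expand_glycoforms()] / [build_candidate_db()]).
#' @param mode `"HCD"` or `"CID"`.
#' @param max_charge highest fragment charge generated (default 2).
#' @param fixed_mods named fixed-modification deltas (default
#'   carbamidomethyl-C, matching candidate expansion).
#' @return data.frame with `label`, `series` (`b`, `y`, `b_glyco`,
#'   `y_glyco`, `Y`, `oxonium`), `index`, `charge`, `mz`,
#'   `site_dependent` (logical: m/z depends on which sites carry the
#'   glycans).
#' @export
theoretical_fragments <- function(candidate, mode = c("HCD", "CID"),
                                  max_charge = 2L,
                                  fixed_mods = default_fixed_mods()) {
  mode <- match.arg(mode)
  if (is.data.frame(candidate)) stopifnot(nrow(candidate) == 1L)
  seq <- candidate$peptide
  gl <- candidate_glyco(candidate)
  res <- residue_masses_fixed(seq, fixed_mods)
  n <- length(res)
  glyco_res <- numeric(n)
  if (length(gl$sites)) {
    glyco_res[gl$sites] <- vapply(gl$compositions, function(cs) {
      modification_delta(parse_composition(cs))
    }, numeric(1))
  }
  water <- formula_mass("H2O")
  lab <- ser <- character(0)
  idx <- integer(0)
  neu <- numeric(0)
  dep <- logical(0)
  add <- function(label, series, index, neutral, site_dependent) {
    lab <<- c(lab, label); ser <<- c(ser, series); idx <<- c(idx, index)
    neu <<- c(neu, neutral); dep <<- c(dep, site_dependent)
  }
  if (mode == "HCD") {
    pre_naked <- cumsum(res)
    suf_naked <- rev(cumsum(rev(res)))
    pre_glyco <- cumsum(res + glyco_res)
    suf_glyco <- rev(cumsum(rev(res + glyco_res)))
    # b ion neutral = prefix residues (acylium); y ion neutral = suffix
    # residues + H2O
    for (i in seq_len(n - 1L)) {
      add(paste0("b", i), "b", i, pre_naked[i], FALSE)
      add(paste0("y", i), "y", i, suf_naked[n - i + 1L] + water, FALSE)
      if (any(glyco_res > 0)) {
        if (pre_glyco[i] > pre_naked[i]) {
          add(paste0("b", i, "+glyco"), "b_glyco", i, pre_glyco[i], TRUE)
        }
        if (suf_glyco[n - i + 1L] > suf_naked[n - i + 1L]) {
          add(paste0("y", i, "+glyco"), "y_glyco", i,
              suf_glyco[n - i + 1L] + water, TRUE)
        }
      }
    }
  } else {
    backbone <- sum(res) + water
    total <- Reduce(`+`, lapply(gl$compositions, function(cs) {
      unclass(parse_composition(cs))
    }), accumulate = FALSE) %||% unclass(glycan_composition())
    subs <- expand.grid(Hex = 0:total[["Hex"]], HexNAc = 0:total[["HexNAc"]],
                        dHex = 0:total[["dHex"]], NeuAc = 0:total[["NeuAc"]],
                        KEEP.OUT.ATTRS = FALSE)
    for (i in seq_len(nrow(subs))) {
      cc <- do.call(glycan_composition, as.list(subs[i, ]))
      delta <- if (sum(cc) == 0L) 0 else modification_delta(cc)
      lbl <- if (sum(cc) == 0L) "Y0" else paste0("Y[", composition_string(cc), "]")
      add(lbl, "Y", sum(cc), backbone + delta, FALSE)
    }
  }
  zz <- rep(seq_len(max_charge), each = length(lab))
  out <- data.frame(
    label = paste0(rep(lab, max_charge),
                   ifelse(zz == 1L, "", paste0("^", zz))),
    series = rep(ser, max_charge), index = rep(idx, max_charge),
    charge = zz, mz = mass_to_mz(rep(neu, max_charge), zz),
    site_dependent = rep(dep, max_charge), stringsAsFactors = FALSE)
  if (any(glyco_res > 0)) {
    ox <- oxonium_series("HexNAc")
    out <- rbind(out, data.frame(label = ox$label, series = "oxonium",
                                 index = NA_integer_, charge = 1L,
                                 mz = ox$mz, site_dependent = FALSE,
                                 stringsAsFactors = FALSE))
  }
  out <- out[!duplicated(out[, c("series", "label")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}
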