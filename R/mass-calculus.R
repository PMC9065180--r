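# Monoisotopic mass calculus for glycan compositions, peptides and
# sequence modifications. All masses are derived at load time from atomic
# monoisotopic masses (CODATA/IUPAC) via elemental formulas, never typed in
# as pre-rounded decimals.

# Atomic monoisotopic masses, Da. Electron mass is carried separately so
# that cation m/z values (oxonium, [M+Na]+) can be corrected for the
# missing electron.
.ATOMIC_MASS <- c(
  C  = 12.0,
  H  = 1.00782503207,
  N  = 14.0030740048,
  O  = 15.9949146196,
  S  = 31.97207100,
  Na = 22.9897692809,
  P  = 30.97376163
)
.ELECTRON_MASS <- 0.000548579909
.PROTON_MASS <- .ATOMIC_MASS[["H"]] - .ELECTRON_MASS

#' Monoisotopic mass of an elemental formula
#'
#' Parses a Hill-style formula such as `"C8H13NO5"` and sums atomic
#' monoisotopic masses. Negative counts are not representable in a formula
#' string; use [formula_delta()] for elemental differences.
#'
#' @param formula character scalar, e.g. `"C8H13NO5"`.
#' @return monoisotopic mass in Da.
#' @examples
#' formula_mass("H2O")
#' @export
formula_mass <- function(formula) {
  counts <- parse_formula(formula)
  sum(counts * .ATOMIC_MASS[names(counts)])
}

# derived mass tables are computed once per session from the formulas
.mass_cache <- new.env(parent = emptyenv())
cached_table <- function(key, compute) {
  if (!exists(key, envir = .mass_cache, inherits = FALSE)) {
    assign(key, compute(), envir = .mass_cache)
  }
  get(key, envir = .mass_cache, inherits = FALSE)
}

# named integer vector of element counts
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  if (sum(nchar(toks)) != nchar(formula)) {
    stop("cannot parse elemental formula: ", formula)
  }
  el <- sub("[0-9]*$", "", toks)
  n <- as.integer(ifelse(grepl("[0-9]$", toks), sub("^[A-Za-z]+", "", toks), "1"))
  bad <- setdiff(el, names(.ATOMIC_MASS))
  if (length(bad)) stop("unknown element(s): ", paste(bad, collapse = ", "))
  counts <- tapply(n, factor(el, levels = names(.ATOMIC_MASS)), sum)
  counts[is.na(counts)] <- 0L
  counts <- as.integer(counts)
  names(counts) <- names(.ATOMIC_MASS)
  counts
}

#' Mass of an elemental difference
#'
#' Monoisotopic mass of `gain` minus mass of `loss`; either may be `NULL`.
#' Used to derive modification deltas such as deamidation (`+O -HN`).
#'
#' @param gain,loss formula strings or `NULL`.
#' @return mass difference in Da.
#' @export
formula_delta <- function(gain = NULL, loss = NULL) {
  v <- 0
  if (!is.null(gain)) v <- v + formula_mass(gain)
  if (!is.null(loss)) v <- v - formula_mass(loss)
  v
}

# --- glycan compositions ----------------------------------------------------

.GLYCAN_RESIDUE_FORMULA <- c(
  Hex    = "C6H10O5",
  HexNAc = "C8H13NO5",
  dHex   = "C6H10O4",
  NeuAc  = "C11H17NO8"
)

.MONOSACCH <- names(.GLYCAN_RESIDUE_FORMULA)

glycan_residue_masses <- function() {
  cached_table("glycan_residues", function() {
    vapply(.GLYCAN_RESIDUE_FORMULA, formula_mass, numeric(1))
  })
}

#' Construct a glycan composition
#'
#' A composition is a count vector over the mucin-type monosaccharide
#' classes Hex, HexNAc, dHex (fucose) and NeuAc (sialic acid). Linkage and
#' branching are not represented: composition masses are
#' linkage-independent.
#'
#' @param Hex,HexNAc,dHex,NeuAc non-negative integer counts.
#' @return an object of class `glycan_composition` (named integer vector).
#' @examples
#' glycan_composition(HexNAc = 1, Hex = 1)  # T antigen
#' @export
glycan_composition <- function(Hex = 0L, HexNAc = 0L, dHex = 0L, NeuAc = 0L) {
  counts <- c(Hex = Hex, HexNAc = HexNAc, dHex = dHex, NeuAc = NeuAc)
  counts <- vapply(counts, function(x) {
    stopifnot(length(x) == 1L, !is.na(x), x >= 0, x == round(x))
    as.integer(x)
  }, integer(1))
  structure(counts[.MONOSACCH], class = "glycan_composition")
}

#' @export
print.glycan_composition <- function(x, ...) {
  cat("<glycan composition> ", composition_string(x), "\n", sep = "")
  invisible(x)
}

#' Canonical composition string, e.g. "HexNAc1Hex1NeuAc2"
#'
#' HexNAc is printed first (the O-GalNAc core), then Hex, dHex, NeuAc;
#' zero counts are omitted.
#'
#' @param comp a `glycan_composition`.
#' @return character scalar; `"none"` for the all-zero composition.
#' @export
composition_string <- function(comp) {
  ord <- c("HexNAc", "Hex", "dHex", "NeuAc")
  nz <- ord[comp[ord] > 0]
  if (!length(nz)) return("none")
  paste0(nz, comp[nz], collapse = "")
}

#' Parse a composition string such as "HexNAc1Hex1NeuAc2"
#'
#' @param x character scalar (`"none"` maps to the all-zero composition).
#' @return a `glycan_composition`.
#' @export
parse_composition <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (x %in% c("", "none")) return(glycan_composition())
  m <- gregexpr("(HexNAc|Hex|dHex|NeuAc)([0-9]+)", x)[[1]]
  toks <- regmatches(x, list(m))[[1]]
  if (sum(nchar(toks)) != nchar(x)) stop("cannot parse glycan composition: ", x)
  cls <- sub("[0-9]+$", "", toks)
  n <- as.integer(sub("^[A-Za-z]+", "", toks))
  args <- stats::setNames(as.list(rep(0L, 4L)), .MONOSACCH)
  for (i in seq_along(cls)) args[[cls[i]]] <- args[[cls[i]]] + n[i]
  do.call(glycan_composition, args)
}

#' Ser/Thr glyco-modification mass delta of a composition
#'
#' The mass added to a peptide when the composition is attached to a
#' hydroxyl: the sum of glycosyl residue masses (each residue contributes
#' its dehydrated mass). Additive and linear in the counts.
#'
#' @param comp a `glycan_composition` with at least one nonzero count.
#' @return delta in Da (e.g. 203.0794 for a single HexNAc).
#' @export
modification_delta <- function(comp) {
  comp <- as_composition(comp)
  if (sum(comp) == 0L) stop("modification_delta() of an empty composition")
  sum(comp * glycan_residue_masses()[names(comp)])
}

as_composition <- function(x) {
  if (inherits(x, "glycan_composition")) return(x)
  if (is.character(x)) return(parse_composition(x))
  if (is.numeric(x) && !is.null(names(x))) {
    return(do.call(glycan_composition, as.list(x[.MONOSACCH])))
  }
  stop("cannot interpret as glycan composition")
}

# --- permethylated benzyl glycosides ---------------------------------------

# Permethylation replaces every free hydroxyl hydrogen by methyl and
# methylates the acetamido nitrogen; the NeuAc carboxyl is methyl-esterified.
# Per-residue increments are composition-only quantities: each glycosidic
# bond consumes exactly one methylation site, independent of topology, so
# residue increments (residue mass + k * CH2) plus a constant end correction
# give the exact molecular mass.
#   Hex    +3 CH2, HexNAc +3 CH2, dHex +2 CH2, NeuAc +5 CH2
# End correction for a benzyl glycoside: the anomeric position carries
# O-benzyl and the non-reducing termini carry the methyls already counted,
# leaving a net C8H10O (= H2O + 2 CH2 with one methyl exchanged for benzyl).
.PERMETHYL_CH2 <- c(Hex = 3L, HexNAc = 3L, dHex = 2L, NeuAc = 5L)
.BENZYL_END_FORMULA <- "C8H10O"

permethyl_increments <- function() {
  cached_table("permethyl_increments", function() {
    glycan_residue_masses() + .PERMETHYL_CH2[.MONOSACCH] * formula_mass("CH2")
  })
}

#' [M+Na]+ m/z of a permethylated benzyl glycoside
#'
#' Theoretical monoisotopic m/z of the sodiated, fully permethylated benzyl
#' O-glycoside of a composition, the species observed in MALDI-MS of
#' benzyl-GalNAc-reporter O-glycomes. Requires HexNAc >= 1 (the reducing-end
#' GalNAc bearing the benzyl aglycone). Includes the electron-mass
#' correction for the cation.
#'
#' @param comp a `glycan_composition` (or string) with `HexNAc >= 1`.
#' @return m/z of the singly charged [M+Na]+ ion.
#' @examples
#' permethylated_bn_mz(glycan_composition(Hex = 1, HexNAc = 1))  # T antigen
#' @export
permethylated_bn_mz <- function(comp) {
  comp <- as_composition(comp)
  if (comp[["HexNAc"]] < 1L) {
    stop("permethylated benzyl glycosides require HexNAc >= 1 (reducing-end GalNAc)")
  }
  m <- sum(comp * permethyl_increments()[names(comp)]) +
    formula_mass(.BENZYL_END_FORMULA)
  m + .ATOMIC_MASS[["Na"]] - .ELECTRON_MASS
}

# --- oxonium / diagnostic ions ---------------------------------------------

# HexNAc oxonium cation and its water-loss / cross-ring fragment set.
# Formulas are for the cation; m/z subtracts one electron mass.
.HEXNAC_OXONIUM_FORMULAS <- c(
  "HexNAc-oxonium"        = "C8H14NO5",   # 204.087
  "HexNAc-H2O"            = "C8H12NO4",   # 186.076
  "HexNAc-2H2O"           = "C8H10NO3",   # 168.066
  "HexNAc-CH6O3"          = "C6H8NO2",    # 126.055
  "HexNAc-C2H6O3"         = "C6H10NO3",   # 144.066, prominent for GalNAc
  "HexNAc-CH4O2-CH2O"     = "C7H8NO2"     # 138.055
)

#' Diagnostic oxonium ion series
#'
#' The HexNAc oxonium cation (m/z 204.087) and its neutral-loss/cross-ring
#' fragments (186.076, 168.066, 144.066, 138.055, 126.055), computed from
#' cation elemental formulas. The 144.066/138.055 pair discriminates GalNAc
#' from GlcNAc in HCD spectra.
#'
#' @param kind currently only `"HexNAc"`.
#' @return data.frame with columns `label`, `formula`, `mz`, `charge`.
#' @export
oxonium_series <- function(kind = "HexNAc") {
  if (!identical(kind, "HexNAc")) stop("unknown oxonium series kind: ", kind)
  cached_table("hexnac_oxonium", function() {
    mz <- vapply(.HEXNAC_OXONIUM_FORMULAS, formula_mass, numeric(1)) -
      .ELECTRON_MASS
    out <- data.frame(
      label = names(.HEXNAC_OXONIUM_FORMULAS),
      formula = unname(.HEXNAC_OXONIUM_FORMULAS),
      mz = unname(mz),
      charge = 1L,
      stringsAsFactors = FALSE
    )
    out <- out[order(out$mz), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

# --- amino acids and peptides ----------------------------------------------

.AA_RESIDUE_FORMULA <- c(
  G = "C2H3NO",  A = "C3H5NO",   S = "C3H5NO2",  P = "C5H7NO",
  V = "C5H9NO",  T = "C4H7NO2",  C = "C3H5NOS",  L = "C6H11NO",
  I = "C6H11NO", N = "C4H6N2O2", D = "C4H5NO3",  Q = "C5H8N2O2",
  K = "C6H12N2O", E = "C5H7NO3", M = "C5H9NOS",  H = "C6H7N3O",
  F = "C9H9NO",  R = "C6H12N4O", Y = "C9H9NO2",  W = "C11H10N2O"
)

aa_residue_masses <- function() {
  cached_table("aa_residues", function() {
    vapply(.AA_RESIDUE_FORMULA, formula_mass, numeric(1))
  })
}

#' Neutral monoisotopic mass of an unmodified peptide
#'
#' @param seq amino-acid string (standard 20 one-letter codes).
#' @return neutral mass in Da (residues + H2O).
#' @export
peptide_mass <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  aa <- strsplit(seq, "")[[1]]
  bad <- setdiff(aa, names(.AA_RESIDUE_FORMULA))
  if (length(bad)) stop("unknown residue(s): ", paste(unique(bad), collapse = ""))
  sum(aa_residue_masses()[aa]) + formula_mass("H2O")
}

#' m/z of a neutral mass at a given positive charge
#'
#' @param neutral_mass neutral monoisotopic mass, Da.
#' @param z charge state, >= 1.
#' @return (M + z * proton) / z.
#' @export
mass_to_mz <- function(neutral_mass, z) {
  stopifnot(all(z >= 1))
  (neutral_mass + z * .PROTON_MASS) / z
}

# --- sequence-modification catalogue ---------------------------------------

#' Load the sequence-modification catalogue
#'
#' Reads the packaged TSV of fixed/variable peptide modifications
#' (carbamidomethyl, oxidation, deamidation, N-terminal formylation and
#' acetylation, pyro-Glu, and the FFPE oxidative set: semialdehydes,
#' kynurenines, methylation, carbonylation). Every delta is recomputed at
#' load time from the catalogued elemental gain/loss formulas; the stored
#' `delta_da` column (which tolerates comma decimal separators) is
#' cross-checked against the elemental value and exists only for human
#' inspection.
#'
#' @param path optional path to an alternative catalogue TSV.
#' @return data.frame with columns `name`, `targets`, `gain`, `loss`,
#'   `delta_da` (elemental, authoritative).
#' @export
modification_catalogue <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "modifications.tsv", package = "glycosplice",
                        mustWork = TRUE)
  }
  cat_df <- utils::read.delim(path, stringsAsFactors = FALSE,
                              colClasses = "character")
  stopifnot(all(c("name", "targets", "gain", "loss", "delta_da") %in% names(cat_df)))
  elemental <- mapply(function(g, l) {
    formula_delta(if (nzchar(g)) g else NULL, if (nzchar(l)) l else NULL)
  }, cat_df$gain, cat_df$loss)
  stored <- as.numeric(sub(",", ".", cat_df$delta_da, fixed = TRUE))
  if (any(abs(stored - elemental) > 5e-4)) {
    bad <- cat_df$name[abs(stored - elemental) > 5e-4]
    stop("catalogue delta_da disagrees with elemental formula for: ",
         paste(bad, collapse = ", "))
  }
  cat_df$delta_da <- unname(elemental)
  cat_df
}

#' Monoisotopic delta of a named sequence modification
#'
#' @param name modification name as listed in [modification_catalogue()].
#' @param catalogue optionally a preloaded catalogue data.frame.
#' @return monoisotopic delta in Da, computed from elemental composition.
#' @examples
#' sequence_modification_delta("oxidation")
#' @export
sequence_modification_delta <- function(name, catalogue = modification_catalogue()) {
  i <- match(name, catalogue$name)
  if (is.na(i)) {
    stop("unknown modification '", name, "'; catalogue lists: ",
         paste(catalogue$name, collapse = ", "))
  }
  catalogue$delta_da[i]
}
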