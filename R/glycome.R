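# MALDI O-glycome annotation: composition library enumeration, peak
# assignment, and conversion of an annotated glycome into the Ser/Thr
# glycopeptide modification search space.

# Fixed composition -> trivial-name map for mono-structure compositions.
# Ambiguous compositions keep their composition-string labels.
.GLYCAN_NAME_MAP <- c(
  "HexNAc1"             = "Tn",
  "HexNAc1NeuAc1"       = "STn",
  "HexNAc1Hex1"         = "T",
  "HexNAc2"             = "core 3",
  "HexNAc1Hex1dHex1"    = "fucosyl-T",
  "HexNAc1Hex1NeuAc1"   = "sialyl-T",
  "HexNAc1Hex1NeuAc2"   = "disialyl-T"
)

glycan_label <- function(comp_str) {
  lbl <- .GLYCAN_NAME_MAP[comp_str]
  ifelse(is.na(lbl), comp_str, lbl)
}

#' Construct a MALDI peak list
#'
#' @param mz,intensity numeric vectors (m/z > 0, intensity >= 0); stored
#'   sorted by ascending m/z.
#' @param adduct metadata string (default `"[M+Na]+"`).
#' @return object of class `peak_list`.
#' @export
peak_list <- function(mz, intensity, adduct = "[M+Na]+") {
  stopifnot(length(mz) == length(intensity), all(mz > 0), all(intensity >= 0))
  o <- order(mz)
  structure(list(mz = as.numeric(mz[o]), intensity = as.numeric(intensity[o]),
                 adduct = adduct),
            class = "peak_list")
}

#' Read a 2-column CSV/TSV peak list
#' @param path file with columns m/z and intensity (header optional).
#' @param sep field separator; guessed from the extension by default.
#' @return a `peak_list`.
#' @export
read_peak_list <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  first <- readLines(path, n = 1L)
  has_header <- !grepl("^[0-9]", trimws(first))
  df <- utils::read.table(path, sep = sep, header = has_header)
  peak_list(df[[1]], df[[2]])
}

#' Enumerate a permethylated benzyl-glycoside composition library
#'
#' All compositions with `HexNAc >= 1` up to the per-monosaccharide maxima
#' whose permethylated benzyl [M+Na]+ m/z falls in `mz_range`,
#' deduplicated and sorted by m/z.
#'
#' @param max_counts named vector of maxima for Hex, HexNAc, dHex, NeuAc.
#' @param mz_range numeric length-2 (default the 540-2000 MALDI reflector
#'   acquisition window).
#' @return data.frame with `composition` (string), `label`, `mz`.
#' @export
enumerate_composition_library <- function(max_counts = c(Hex = 3, HexNAc = 3,
                                                         dHex = 2, NeuAc = 2),
                                          mz_range = c(540, 2000)) {
  stopifnot(all(max_counts >= 0), length(mz_range) == 2L,
            mz_range[1] < mz_range[2])
  mx <- function(k) if (k %in% names(max_counts)) max_counts[[k]] else 0
  grid <- expand.grid(Hex = 0:mx("Hex"), HexNAc = 1:max(1, mx("HexNAc")),
                      dHex = 0:mx("dHex"), NeuAc = 0:mx("NeuAc"),
                      KEEP.OUT.ATTRS = FALSE)
  if (mx("HexNAc") < 1) grid <- grid[0, , drop = FALSE]
  comps <- lapply(seq_len(nrow(grid)), function(i) {
    do.call(glycan_composition, as.list(grid[i, ]))
  })
  mz <- vapply(comps, permethylated_bn_mz, numeric(1))
  keep <- mz >= mz_range[1] & mz <= mz_range[2]
  cs <- vapply(comps[keep], composition_string, character(1))
  lib <- data.frame(composition = cs, label = unname(glycan_label(cs)),
                    mz = mz[keep], stringsAsFactors = FALSE)
  lib <- lib[!duplicated(lib$composition), , drop = FALSE]
  lib <- lib[order(lib$mz), , drop = FALSE]
  rownames(lib) <- NULL
  lib
}

#' Annotate a MALDI peak list against a composition library
#'
#' Nearest-mass assignment within `tol_ppm`; ties broken by smaller
#' absolute ppm error, then by fewer total monosaccharides. At most one
#' composition per peak. Annotation is independent of peak order and
#' intensity scale.
#'
#' @param peaks a `peak_list`.
#' @param library data.frame from [enumerate_composition_library()].
#' @param tol_ppm matching tolerance (default 10 ppm, MALDI-reflector
#'   scale).
#' @return object of class `glycome_annotation`: list with `assignments`
#'   (data.frame `mz_observed`, `intensity`, `composition`, `label`,
#'   `mz_theoretical`, `ppm_error`) and `unassigned` (data.frame
#'   `mz_observed`, `intensity`).
#' @export
annotate_peaks <- function(peaks, library, tol_ppm = 10) {
  stopifnot(inherits(peaks, "peak_list"), nrow(library) >= 1L)
  n_res <- vapply(library$composition,
                  function(s) sum(as_composition(s)), numeric(1))
  rows <- lapply(seq_along(peaks$mz), function(i) {
    mzo <- peaks$mz[i]
    err <- ppm_error(mzo, library$mz)
    ok <- which(abs(err) <= tol_ppm)
    if (!length(ok)) return(NULL)
    ok <- ok[order(abs(err[ok]), n_res[ok], library$composition[ok])]
    j <- ok[1]
    data.frame(mz_observed = mzo, intensity = peaks$intensity[i],
               composition = library$composition[j], label = library$label[j],
               mz_theoretical = library$mz[j], ppm_error = err[j],
               stringsAsFactors = FALSE)
  })
  hit <- !vapply(rows, is.null, logical(1))
  assignments <- if (any(hit)) do.call(rbind, rows[hit]) else {
    data.frame(mz_observed = numeric(0), intensity = numeric(0),
               composition = character(0), label = character(0),
               mz_theoretical = numeric(0), ppm_error = numeric(0))
  }
  structure(list(assignments = assignments,
                 unassigned = data.frame(mz_observed = peaks$mz[!hit],
                                         intensity = peaks$intensity[!hit]),
                 tol_ppm = tol_ppm),
            class = "glycome_annotation")
}

#' @export
print.glycome_annotation <- function(x, ...) {
  cat("<glycome annotation> ", nrow(x$assignments), " assigned, ",
      nrow(x$unassigned), " unassigned (tol ", x$tol_ppm, " ppm)\n", sep = "")
  invisible(x)
}

#' Convert an annotated glycome into the Ser/Thr modification search space
#'
#' Returns the glycan compositions to consider as variable Ser/Thr
#' modifications during glycopeptide search: the observed compositions,
#' optionally augmented with their progressively desialylated forms (to
#' admit incomplete de-sialylation of the sample), always including the Tn
#' core (`HexNAc1`); deduplicated. Every member has `HexNAc >= 1`.
#'
#' @param annotation a `glycome_annotation` (or character vector of
#'   composition strings).
#' @param include_desialylated_partials when `TRUE` (default), each
#'   observed composition also contributes all NeuAc-stripped forms.
#' @return list of `glycan_composition`, sorted by modification delta.
#' @export
glycome_to_search_space <- function(annotation,
                                    include_desialylated_partials = TRUE) {
  observed <- if (inherits(annotation, "glycome_annotation")) {
    unique(annotation$assignments$composition)
  } else {
    unique(as.character(annotation))
  }
  comps <- lapply(observed, parse_composition)
  if (include_desialylated_partials) {
    stripped <- list()
    for (cc in comps) {
      while (cc[["NeuAc"]] > 0L) {
        cc <- glycan_composition(Hex = cc[["Hex"]], HexNAc = cc[["HexNAc"]],
                                 dHex = cc[["dHex"]], NeuAc = cc[["NeuAc"]] - 1L)
        stripped[[length(stripped) + 1L]] <- cc
      }
    }
    comps <- c(comps, stripped)
  }
  comps <- c(comps, list(glycan_composition(HexNAc = 1L)))
  keys <- vapply(comps, composition_string, character(1))
  comps <- comps[!duplicated(keys)]
  comps <- comps[vapply(comps, function(cc) cc[["HexNAc"]] >= 1L, logical(1))]
  comps[order(vapply(comps, modification_delta, numeric(1)))]
}

#' Write a glycome annotation to TSV
#' @param annotation a `glycome_annotation`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation_tsv <- function(annotation, path) {
  utils::write.table(annotation$assignments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
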