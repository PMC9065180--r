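# Fragment generation, binomial-tail scoring, target-decoy FDR, site
# localization.

test_that("b1/y1 of an unmodified dipeptide match the elemental oracle", {
  cand <- data.frame(peptide = "GA", sites = "", compositions = "",
                     n_glyco_sites = 0L, stringsAsFactors = FALSE)
  fr <- theoretical_fragments(cand, "HCD", max_charge = 1,
                              fixed_mods = c(X = 0))
  # frozen: b1(G) = C2H3NO + proton; y1(A) = C3H5NO + H2O + proton
  expect_equal(fr$mz[fr$label == "b1"], 58.028740, tolerance = 1e-5)
  expect_equal(fr$mz[fr$label == "y1"], 90.054955, tolerance = 1e-5)
})

test_that("CID Y-series steps by one glycan residue: Y1 - Y0 = HexNAc", {
  cand <- data.frame(peptide = "ASTK", sites = "2", compositions = "HexNAc1",
                     n_glyco_sites = 1L, stringsAsFactors = FALSE)
  fr <- theoretical_fragments(cand, "CID", max_charge = 1)
  y <- fr[fr$series == "Y", ]
  expect_equal(y$mz[y$label == "Y[HexNAc1]"] - y$mz[y$label == "Y0"],
               203.079373, tolerance = 1e-5)
})

test_that("fragment counts for a 6-mer with one glycan match the closed form", {
  # HCD: (n-1) b + (n-1) y naked, (n-1) site-bearing glyco variants total,
  # each at 2 charges, plus 6 oxonium ions
  for (site in c(1L, 3L, 6L)) {
    cand <- data.frame(peptide = "SAKTGS", sites = as.character(site),
                       compositions = "HexNAc1", n_glyco_sites = 1L,
                       stringsAsFactors = FALSE)
    fr <- theoretical_fragments(cand, "HCD", max_charge = 2)
    n <- 6L
    n_b_glyco <- length(seq_len(n - 1L)[seq_len(n - 1L) >= site])
    n_y_glyco <- length(seq_len(n - 1L)[(n - seq_len(n - 1L) + 1L) <= site])
    expected <- 2L * (2L * (n - 1L) + n_b_glyco + n_y_glyco) + 6L
    expect_identical(nrow(fr), expected)
  }
  # CID: sub-compositions of the glycan (2 here) at 2 charges + 6 oxonium
  cand <- data.frame(peptide = "SAKTGS", sites = "1", compositions = "HexNAc1",
                     n_glyco_sites = 1L, stringsAsFactors = FALSE)
  frc <- theoretical_fragments(cand, "CID", max_charge = 2)
  expect_identical(nrow(frc), 2L * 2L + 6L)
})

test_that("a spectrum that is exactly a candidate's fragment set ranks that candidate first", {
  space <- list(glycan_composition(HexNAc = 1),
                glycan_composition(HexNAc = 1, Hex = 1))
  cands <- expand_glycoforms("SAYTGKF", space, max_occupied_sites = 2)
  cands$isoform_id <- "iso"
  cands$junction_tags <- ""
  cands$is_decoy <- FALSE
  target <- cands[cands$sites == "1,4", ][2, ]
  fr <- theoretical_fragments(target, "HCD")
  s <- ms_spectrum("s", precursor_mz(target, 2), 2, "HCD", fr$mz,
                   rep(1, nrow(fr)))
  # widen the precursor window so isobaric site-isomers compete
  g <- score_spectrum(s, cands, precursor_tol_ppm = 50)
  expect_identical(g$sites[1], target$sites)
  expect_identical(g$compositions[1], target$compositions)
  # score invariant to intensity scaling and peak order
  s2 <- ms_spectrum("s", precursor_mz(target, 2), 2, "HCD", rev(fr$mz),
                    rep(1000, nrow(fr)))
  g2 <- score_spectrum(s2, cands, precursor_tol_ppm = 50)
  expect_equal(g$score, g2$score)
})

test_that("pure-noise spectra score far below well-matched candidates", {
  space <- list(glycan_composition(HexNAc = 1))
  cands <- expand_glycoforms("SATLKWGY", space)
  cands$isoform_id <- "iso"; cands$junction_tags <- ""; cands$is_decoy <- FALSE
  target <- cands[cands$n_glyco_sites == 1, ][1, ]
  fr <- theoretical_fragments(target, "HCD")
  set.seed(77)
  half <- sample(nrow(fr), ceiling(nrow(fr) / 2))
  s_half <- ms_spectrum("h", precursor_mz(target, 2), 2, "HCD",
                        fr$mz[half], rep(1, length(half)))
  half_score <- score_spectrum(s_half, cands)$score[1]
  noise_scores <- vapply(1:40, function(i) {
    s <- ms_spectrum("n", precursor_mz(target, 2), 2, "HCD",
                     runif(30, 100, 1800), rep(1, 30))
    g <- score_spectrum(s, cands)
    if (nrow(g)) g$score[1] else 0
  }, numeric(1))
  expect_lt(stats::median(noise_scores), half_score)
})

test_that("adding an unmatched noise peak never increases the matched count", {
  cand <- data.frame(peptide = "SAKTGSF", sites = "1", compositions = "HexNAc1",
                     n_glyco_sites = 1L, neutral_mass = NA, stringsAsFactors = FALSE)
  cand$neutral_mass <- peptide_mass("SAKTGSF") + 203.079373
  fr <- theoretical_fragments(cand, "HCD")
  s0 <- ms_spectrum("a", precursor_mz(cand, 2), 2, "HCD", fr$mz[1:10],
                    rep(1, 10))
  s1 <- ms_spectrum("a", precursor_mz(cand, 2), 2, "HCD",
                    c(fr$mz[1:10], 1234.5678), rep(1, 11))
  cand$is_decoy <- FALSE
  k0 <- score_spectrum(s0, cand)$n_matched
  k1 <- score_spectrum(s1, cand)$n_matched
  expect_identical(k0, k1)
})

test_that("target-decoy q-values are monotone and handle degenerate tables", {
  all_t <- data.frame(score = c(9, 5, 2), is_decoy = FALSE)
  q <- target_decoy_fdr(all_t)$q_value
  expect_identical(q, c(0, 0, 0))
  inter <- data.frame(score = rep(c(5, 5), 5),
                      is_decoy = rep(c(FALSE, TRUE), 5))
  qi <- target_decoy_fdr(inter)$q_value
  expect_true(all(diff(qi) >= 0))
  expect_equal(max(qi), 1)
  set.seed(13)
  rnd <- data.frame(score = rnorm(200), is_decoy = rep(c(TRUE, FALSE), 100))
  qr <- target_decoy_fdr(rnd)
  expect_true(all(diff(qr$q_value) >= 0))
  expect_false(is.unsorted(-qr$score))
})

test_that("a simulated null accepts almost nothing at q <= 0.01", {
  accepted <- 0L
  total <- 0L
  for (seed in 1:10) {
    set.seed(seed)
    n <- 300L
    null_gpsms <- data.frame(score = rnorm(2 * n),
                             is_decoy = rep(c(FALSE, TRUE), n))
    q <- target_decoy_fdr(null_gpsms)
    accepted <- accepted + sum(!q$is_decoy & q$q_value <= 0.01)
    total <- total + n
  }
  # Wilson 95% upper bound of the acceptance rate stays in the low percents
  phat <- accepted / total
  wilson_hi <- (phat + 1.96^2 / (2 * total) +
                  1.96 * sqrt(phat * (1 - phat) / total +
                                1.96^2 / (4 * total^2))) /
    (1 + 1.96^2 / total)
  expect_lt(wilson_hi, 0.03)
})

test_that("site localization distinguishes resolvable from ambiguous assignments", {
  # single S/T: trivially localized
  g1 <- data.frame(peptide = "SAKGF", sites = "1", compositions = "HexNAc1",
                   stringsAsFactors = FALSE)
  s_any <- ms_spectrum("s", 500, 2, "HCD", c(300, 400), c(1, 1))
  loc1 <- localize_sites(g1, s_any)
  expect_true(loc1$localized)
  # two sites, no site-determining ions in the spectrum: ambiguous
  g2 <- data.frame(peptide = "SATKF", sites = "1", compositions = "HexNAc1",
                   stringsAsFactors = FALSE)
  loc2 <- localize_sites(g2, s_any)
  expect_identical(loc2$status, "ambiguous")
})

test_that("localization recovers the generated site in nearly all informative spectra", {
  set.seed(55)
  space <- list(glycan_composition(HexNAc = 1))
  n_ok <- 0L
  n_tot <- 0L
  cfg <- generator_config(seed = 99, efficiency = 1.0, lambda_noise = 0,
                          jitter_ppm = 0, charges = 2L)
  plain <- function(n) paste(sample(strsplit("ACDEGHIKMNQRVW", "")[[1]], n,
                                    replace = TRUE), collapse = "")
  for (i in 1:40) {
    # exactly two S/T sites, separated by backbone residues
    pep <- paste0(plain(3), "S", plain(3), "T", plain(2), "K")
    cands <- expand_glycoforms(pep, space, max_occupied_sites = 1)
    cands <- cands[cands$n_glyco_sites == 1, ]
    truth <- cands[sample(nrow(cands), 1), ]
    gen <- generate_spectra(truth, cfg)
    loc <- localize_sites(truth, gen$spectra[[1]])
    n_tot <- n_tot + 1L
    if (loc$localized) n_ok <- n_ok + 1L
  }
  expect_gte(n_ok / n_tot, 0.95)
})
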