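# Mass calculus: glycan deltas, permethylated benzyl glycosides, oxonium
# ions, sequence-modification catalogue. Frozen expected values were
# computed independently from atomic monoisotopic masses (cross-checked
# against pyteomics' elemental calculator).

test_that("glycan residue deltas match independently computed elemental masses", {
  expect_equal(modification_delta(glycan_composition(HexNAc = 1)),
               203.079373, tolerance = 1e-6)
  expect_equal(modification_delta(glycan_composition(Hex = 1)),
               162.052823, tolerance = 1e-6)
  expect_equal(modification_delta(glycan_composition(dHex = 1)),
               146.057909, tolerance = 1e-6)
  expect_equal(modification_delta(glycan_composition(NeuAc = 1)),
               291.095417, tolerance = 1e-6)
  # composite cross-check: HexNAc1Hex1dHex1 = HexNAcHex + dHex
  expect_equal(modification_delta(parse_composition("HexNAc1Hex1dHex1")),
               511.190105, tolerance = 1e-5)
  expect_error(modification_delta(glycan_composition()), "empty")
})

test_that("modification_delta is additive and linear in the counts", {
  set.seed(71)
  for (i in 1:25) {
    c1 <- glycan_composition(Hex = sample(0:2, 1), HexNAc = sample(0:2, 1),
                             dHex = sample(0:2, 1), NeuAc = sample(0:2, 1))
    c2 <- glycan_composition(Hex = sample(0:2, 1), HexNAc = sample(0:2, 1),
                             dHex = sample(0:2, 1), NeuAc = sample(0:2, 1))
    if (sum(c1) == 0 || sum(c2) == 0) next
    csum <- do.call(glycan_composition, as.list(unclass(c1) + unclass(c2)))
    expect_equal(modification_delta(csum),
                 modification_delta(c1) + modification_delta(c2),
                 tolerance = 1e-6)
  }
})

test_that("permethylated benzyl [M+Na]+ values reproduce the annotated glycome series", {
  # frozen full-precision values from an independent elemental build of the
  # permethylated benzyl glycosides
  expect_equal(permethylated_bn_mz("HexNAc1Hex1"), 594.288482, tolerance = 1e-5)
  expect_equal(permethylated_bn_mz("HexNAc2"), 635.315031, tolerance = 1e-5)
  expect_equal(permethylated_bn_mz("HexNAc1NeuAc1"), 751.362375, tolerance = 1e-5)
  expect_equal(permethylated_bn_mz("HexNAc1Hex1dHex1"), 768.377691, tolerance = 1e-5)
  expect_equal(permethylated_bn_mz("HexNAc1Hex1NeuAc1"), 955.462149, tolerance = 1e-5)
  expect_equal(permethylated_bn_mz("HexNAc1Hex1NeuAc2"), 1316.635816, tolerance = 1e-5)
  expect_error(permethylated_bn_mz("Hex2"), "HexNAc")
})

test_that("permethylated series forms constant-increment ladders per monosaccharide", {
  base <- glycan_composition(HexNAc = 1, Hex = 1)
  for (sugar in c("Hex", "HexNAc", "dHex", "NeuAc")) {
    args <- as.list(unclass(base))
    args[[sugar]] <- args[[sugar]] + 1L
    plus1 <- do.call(glycan_composition, args)
    args[[sugar]] <- args[[sugar]] + 1L
    plus2 <- do.call(glycan_composition, args)
    inc1 <- permethylated_bn_mz(plus1) - permethylated_bn_mz(base)
    inc2 <- permethylated_bn_mz(plus2) - permethylated_bn_mz(plus1)
    expect_equal(inc1, inc2, tolerance = 1e-9)
  }
})

test_that("oxonium series matches cation formula masses and water-loss arithmetic", {
  ox <- oxonium_series("HexNAc")
  mz <- function(lbl) ox$mz[ox$label == lbl]
  # each ion equals its cation formula mass minus one electron
  for (i in seq_len(nrow(ox))) {
    expect_equal(ox$mz[i], formula_mass(ox$formula[i]) - 0.000548579909,
                 tolerance = 1e-9)
  }
  expect_equal(mz("HexNAc-H2O"), mz("HexNAc-oxonium") - formula_mass("H2O"),
               tolerance = 1e-9)
  expect_equal(mz("HexNAc-2H2O"), mz("HexNAc-oxonium") - 2 * formula_mass("H2O"),
               tolerance = 1e-9)
  expect_equal(round(sort(ox$mz), 3),
               c(126.055, 138.055, 144.066, 168.066, 186.076, 204.087))
  expect_error(oxonium_series("Hex"), "unknown")
})

test_that("sequence-modification catalogue agrees with elemental-difference oracle", {
  cat_df <- modification_catalogue()
  # independent elemental differences, frozen from atomic masses
  oracle <- c(
    carbamidomethyl = 57.021464, oxidation = 15.994915,
    deamidation = 0.984016, Nterm_formylation = 27.994915,
    Nterm_acetylation = 42.010565, Gln_to_pyroGlu = -17.026549,
    Lys_to_aminoadipic_semialdehyde = -1.031634,
    Arg_to_glutamic_semialdehyde = -43.053433,
    Pro_to_pyroglutamic_acid = 13.979265,
    Trp_to_hydroxykynurenine = 19.989829, Trp_to_kynurenine = 3.994915,
    Trp_to_N_formylkynurenine = 31.989829,
    Thr_to_2_amino_3_ketobutyric_acid = -2.015650,
    Lys_methylation = 14.015650, hydroxylation = 15.994915,
    carbonylation = 13.979265)
  for (nm in names(oracle)) {
    expect_equal(sequence_modification_delta(nm, cat_df), oracle[[nm]],
                 tolerance = 1e-5, label = nm)
  }
  expect_error(sequence_modification_delta("no_such_mod", cat_df),
               "catalogue lists")
})

test_that("composition strings round-trip and peptide masses match elemental sums", {
  for (s in c("HexNAc1", "HexNAc2Hex2NeuAc1", "HexNAc1Hex1dHex1NeuAc2")) {
    expect_identical(composition_string(parse_composition(s)), s)
  }
  # glycine-glycine frozen from an independent elemental build
  expect_equal(peptide_mass("GG"), 132.053492, tolerance = 1e-5)
  # m/z charge identity: m1 = 2*m2 - proton
  m <- peptide_mass("SAMPLER")
  expect_equal(mass_to_mz(m, 1), 2 * mass_to_mz(m, 2) - 1.007276466,
               tolerance = 1e-6)
  expect_error(peptide_mass("SAMPLEZ"), "unknown residue")
})
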