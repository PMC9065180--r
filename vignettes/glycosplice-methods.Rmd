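---
title: "Methods: splice-isoform glycoproteogenomics with glycosplice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: splice-isoform glycoproteogenomics with glycosplice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycosplice)
```

# The problem

Alternative splicing of a mucin-type glycoprotein such as CD44 produces
isoforms that differ only in which variable exons are retained. At the
peptide level the discriminating evidence is a proteolytic peptide that
spans an exon–exon junction: `e5-e15` exists only in the short isoform
that skips all variable exons, `e5-v3` only in isoforms retaining v3, and
so on. These junction regions are dense in Ser/Thr and carry O-GalNAc
glycans, so conventional searches that ignore glycosylation fail to match
the very spectra that decide the isoform question. `glycosplice`
implements the full desk-side chain: isoform database construction from
transcript models, a glycan search space taken from the measured
O-glycome, oxonium-based spectral filtering, glycopeptide–spectrum
matching with decoy-based error control, and junction-level reporting.

# Isoform model

An exon grammar holds exon sequences (nucleotide or amino-acid mode) with
a constitutive/variable category; transcripts are ordered lists of exon
usages with optional 0-based half-open exon-local offsets for partial
exons (rendered as `e2(partial)` in junction tags). Offsets on exon-local
coordinates were chosen over genomic coordinates because the partial
notation of junction nomenclature carries no genomic anchor, and toy
grammars should not have to invent one.

Translation uses a first-AUG rule: the spliced transcript is scanned for
its first ATG and translated on the forward strand until the first stop
codon. Transcripts are already stranded mRNA models, so no reverse-strand
or internal-AUG search is attempted; where a real annotation pipeline
would use Kozak context, the first-AUG longest-ORF rule is the simplest
deterministic surrogate. Screening classifies transcripts as `no_orf`
(no AUG), `premature_stop` (in-frame stop before `min_orf_aa` residues),
`fragment_noncoding` (runs off the end short of `min_orf_aa`), or
`coding`. The default `min_orf_aa = 30` is intended to exclude the class
of short computational transcripts unlikely to be translated while
remaining far below any real isoform length; it is a parameter, not a
biological claim.

Junction positions are carried as the number of residues fully encoded
upstream of the boundary (`aa_boundary`), so a junction lies between
residues `aa_boundary` and `aa_boundary + 1`, and a codon split across
the boundary belongs to the downstream-containing residue. A peptide is
junction-diagnostic iff it has at least one residue on each side.

# Mass calculus

All masses derive at run time from atomic monoisotopic masses
(CODATA/IUPAC, ≥5 decimals) through elemental formulas — no pre-rounded
literals enter the computation. Glycan compositions are count vectors
over Hex, HexNAc, dHex, NeuAc; their Ser/Thr modification delta is the
sum of dehydrated residue masses (HexNAc 203.0794, Hex 162.0528, dHex
146.0579, NeuAc 291.0954 Da), additive and linkage-independent.

For the MALDI O-glycome, the package computes [M+Na]⁺ m/z of
permethylated benzyl glycosides. Permethylation adds one methyl per free
hydroxyl and one on the acetamido nitrogen, and methyl-esterifies the
NeuAc carboxyl; because each glycosidic bond consumes exactly one
methylation site regardless of topology, per-residue increments (Hex/
HexNAc +3 CH₂, dHex +2 CH₂, NeuAc +5 CH₂ over the dehydrated residue)
plus a constant benzyl-end correction (C₈H₁₀O) give the exact molecular
mass for any composition. The sodium adduct subtracts one electron mass
(0.00055 Da — below the 2-decimal precision of MALDI annotation either
way, but kept for correctness).

The sequence-modification catalogue (carbamidomethyl, oxidation,
deamidation, N-terminal formylation/acetylation, pyro-Glu, and the FFPE
oxidative set: lysine→aminoadipic semialdehyde, arginine→glutamic
semialdehyde, kynurenines, methylation, hydroxylation, carbonylation) is
shipped as a TSV of elemental gain/loss formulas. The loader recomputes
every delta from the formulas and cross-checks the stored decimal column,
which tolerates comma decimal separators. Where published decimal values
disagree with their own elemental chemistry in the fourth decimal (the
proline→pyroglutamic-acid/carbonylation delta is −H₂+O = +13.9793, and
tryptophan→kynurenine is −C+O = +3.9949), the catalogue stores the
elemental value: the formula, not the printed rounding, is authoritative.

# Glycome annotation and the search space

The composition library enumerates all compositions with HexNAc ≥ 1 (the
reducing-end GalNAc of the benzyl reporter) up to per-monosaccharide
maxima, default 3/3/2/2 within the 540–2000 m/z reflector window. Peaks
are assigned to the nearest library mass within a tolerance of 10 ppm by
default; the instrument section reports internal calibration but no
matching tolerance, and 10 ppm is a routine choice for reflector-mode
MALDI-TOF. Ties break by smaller |ppm| and then fewer residues, so
simpler compositions win exact ties. Inputs are assumed to be calibrated
centroids; baseline correction and centroiding are upstream concerns.

The search space is the annotated glycome plus, by default, all
progressively desialylated forms of each observed composition — samples
are commonly desialylated before digestion and the stripped forms admit
incomplete desialylation — and always includes the Tn core (HexNAc₁).
Composition labels use a fixed map for mono-structure compositions (Tn,
STn, T, core 3, fucosyl-T, sialyl-T, disialyl-T); compositions with
several plausible structures keep their composition strings, since
composition mass cannot distinguish them.

# Digestion and candidate expansion

Chymotryptic specificity is FYWL with no cleavage before proline, the
dominant convention when only the enzyme name is given, and is
configurable. Up to two missed cleavages are allowed by default. The raw
`digest()` applies no length bounds; search-space construction
(`build_candidate_db`) bounds peptides to 5–45 residues as a search
practicality.

Glycoform expansion assigns 0..`max_occupied_sites` distinct S/T sites
compositions from the search space, with repetition across sites, in
deterministic lexicographic order, capped at `max_candidates` = 10⁴ per
peptide with an explicit truncation flag. The defaults
(`max_occupied_sites = 3`) bound the combinatorics on S/T-dense
variable-exon peptides, whose glycosite density is precisely what makes
them hard to observe. Carbamidomethyl-C is applied as a fixed
modification throughout.

Decoys are reversed peptides with the C-terminal residue preserved
(retaining the enzymatic C-terminus), expanded over the same search
space, so decoys match targets in mass distribution and glyco-site
counts. Decoys whose sequence collides with a target peptide are dropped.

# Spectra, trigger logic and scoring

MGF is read and written natively; mzML is written as uncompressed 64-bit
PSI mzML and read through `mzR`. The dissociation mode travels in a
Thermo-style filter string, the field `mzR` exposes.

The CID trigger follows the acquisition rule: an HCD scan schedules its
precursor iff a peak lies within ±0.01 Da of the HexNAc oxonium at m/z
204.087. All other fragment matching uses Dalton tolerances of 0.02 (HCD)
and 0.6 (CID, ion-trap readout) by default. The trigger demands presence
only — the instrument's absolute intensity threshold is hardware-specific
— with an optional relative-intensity floor. Duplicate precursors merge
at 5 ppm, the search precursor tolerance. The I(144.066)/I(138.055)
cross-ring ratio is reported per spectrum as GalNAc evidence but never
thresholded: no numeric cutoff is established for it, so it stays
descriptive.

Scoring replaces proprietary search-engine internals with an open
surrogate. Theoretical ions are: in HCD, b/y series both glycan-stripped
and glycan-retained (O-glycans are labile, yet glycan-retained backbone
ions do occur) plus the oxonium series; in CID, the Y series — the intact
peptide with every sub-composition of its total glycan, down to Y0 — plus
oxonium ions; singly and doubly charged. A candidate's score is
−log₁₀ P[Binomial(n, p) ≥ k] with n theoretical ions, k matched within
tolerance, and p = 2·tol·n_peaks/span the per-ion chance-match
probability of the spectrum's peak density (capped at 0.5). The matcher
is presence/absence, so scores are invariant to intensity scaling and
peak order; an unmatched noise peak can only raise p slightly, never k.
Ties break by fewer glyco sites (parsimony), then lexicographically.
A GPSM is only reported when at least `min_matched` ions (default 4)
are matched: one or two matched peaks — typically a noise peak landing
on an oxonium m/z — are no evidence for a glycopeptide, and with
realistically sized runs the decoy tail is too sparse to calibrate such
matches; a minimum matched-fragment floor is standard search-engine
practice. q-values are the standard target–decoy minimum of
#decoys/#targets over score thresholds, monotone by construction. The default acceptance
threshold for downstream reporting and for a second-pass
"high-confidence" database is q ≤ 0.01; the threshold is exposed because
the upstream criterion it mimics is not quantified anywhere
authoritative.

Site localization enumerates every alternative placement of the matched
glycan multiset on the peptide's S/T sites and counts matched
site-determining ions (glycan-retained b/y, whose m/z depends on the
placement). An assignment is localized iff it strictly beats every
alternative; otherwise it is reported ambiguous, mirroring the honest
ambiguity of HCD-only data. Recovery of the spiked site on informative
spectra is itself a tested property.

# Synthetic data: what it emulates and what it does not

The generator produces the toy CD44-like grammar (19 codon-aligned,
stop-free exons: 5 constitutive N-terminal, 9 Ser/Thr-rich variable, 5
constitutive C-terminal; transcripts shaped like CD44s, v2-10, v3-10,
v8-10 and a partial-exon soluble form), glycome peak lists, and HCD/CID
spectra for known candidates. Spectra take Bernoulli-sampled theoretical
fragments at a configurable efficiency (default 0.7), log-normal
intensities, Poisson noise peaks (default λ = 20) uniform in m/z, and
bounded-uniform mass jitter (default 5 ppm) on fragments and precursors.
Oxonium ions of glycosylated precursors are always emitted — they are
the high-abundance ions acquisition triggers on — and never for
unglycosylated ones, which makes trigger ground truth exact. A
configurable I(144)/I(138) ratio (default 2.5) emulates GalNAc-like
cross-ring intensities. Null spectra are pure noise placed inside the
precursor windows of real candidates so that they exercise false-match
behavior.

The noise model is deliberately minimal: it exercises the binomial
score's false-match arithmetic but does not emulate isotope envelopes,
co-isolation chimeras, peak-shape effects, retention-time structure, or
intensity correlation between fragments. Passing recovery tests on this
generator therefore demonstrates the correctness of the matching and
error-control machinery, not instrument-level performance on real data.
Determinism is bit-for-bit under a fixed seed: all generation runs under
a seed-scoped RNG that restores the caller's stream (single-threaded
base-R RNG; no platform-dependent float ordering is involved).

Problem sizes used by the test suite were chosen to keep a laptop-scale
run comfortable: 100 random 200-residue sequences for the digestion
oracle, 1000 spectra for trigger-logic equivalence, and five seeds of 50
spike-ins among 500 nulls for recovery/FDR measurement.

# Reporting

Accepted GPSMs (targets at q ≤ threshold) aggregate into per-band
reports. A junction is listed when supported by at least one accepted
junction-spanning GPSM (configurable). An isoform is assigned only from
junctions diagnostic of it — unique to that isoform within the searched
database; shared constitutive-region peptides count toward coverage of
every compatible isoform but never toward assignment. Coverage is the
fraction of distinct residues of the complete variant covered by
accepted peptides. Bands are free-text labels on spectra groups; gel
electrophoresis itself is not modelled. Report writers emit
deterministic, byte-stable TSV/JSON.

# Known limitations

- Composition-level glycan identification only: no linkage or structure
  elucidation, no isotope-pattern modelling beyond monoisotopic peaks.
- Fully specific digestion only; no semi-tryptic/non-specific search.
- The binomial score ignores intensities and fragment correlations;
  it is a transparent surrogate, not a tuned rescorer.
- HCD-only localization is frequently ambiguous by design; CID
  Y-series evidence constrains compositions, not sites.
- Exon sequences are user-supplied; the package fetches nothing.
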