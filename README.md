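# glycosplice

Splice-isoform glycoproteogenomics in R: identify which splice isoforms of
a heavily O-glycosylated protein (the motivating case is CD44 in bladder
cancer) are present in a sample, from tandem mass spectrometry of
glycopeptides, when the discriminating peptides span exon–exon junctions
and cannot be identified without modelling their O-glycans.

The package is aimed at proteomics bioinformaticians who have (i) a set of
candidate transcripts (e.g. from RNA-seq) over a known exon structure,
(ii) a MALDI-MS profile of the cellular O-glycome as permethylated benzyl
glycosides, and (iii) HCD (and optionally CID) tandem spectra of
protease-digested glycoprotein isolates.

## What it does

1. **Isoform database construction** (`exon_model`, `transcript_model`,
   `translate_transcript`, `write_isoform_fasta`): an exon grammar
   (constitutive + variable exons) plus ordered, possibly partial, exon
   lists are spliced and translated (first-AUG ORF, configurable minimum
   length); each protein isoform carries its exon–exon junction positions
   in amino-acid coordinates, so junction-spanning peptides are diagnostic
   of splice events (e.g. `e5-e15` ⇒ CD44s). Implausible transcripts are
   screened out (`screen_transcript`: `no_orf`, `premature_stop`,
   `fragment_noncoding`).
2. **Glycan search space** (`enumerate_composition_library`,
   `annotate_peaks`, `glycome_to_search_space`): MALDI peak lists of
   permethylated benzyl glycosides are annotated with glycan compositions
   by exact [M+Na]⁺ mass (e.g. T at m/z 594.29, STn at 751.36, disialyl-T
   at 1316.64), and the observed glycome — optionally augmented with
   desialylated partials — becomes the variable Ser/Thr modification list.
3. **Oxonium-triggered CID** (`detect_oxonium`, `diagnostic_ratio`,
   `build_inclusion_list`): HCD scans are screened for the HexNAc oxonium
   ion (m/z 204.087 ± 0.01) and its cross-ring fragments (126.055,
   138.055, 144.066, 168.066, 186.076); triggered precursors are merged
   (5 ppm) into a CID inclusion list. The I(144.066)/I(138.055) ratio is
   reported as GalNAc-vs-GlcNAc evidence.
4. **Glycopeptide–spectrum matching** (`digest`, `expand_glycoforms`,
   `build_candidate_db`, `search_spectra`, `target_decoy_fdr`,
   `localize_sites`): chymotryptic peptides (FYWL, no cleavage before P,
   ≤2 missed cleavages) are expanded into glycoforms over the search
   space; spectra are scored with a binomial-tail score
   `-log10 P[Binom(n, p) ≥ k]` (n theoretical ions, k matched, p the
   chance-match probability from peak density); reversed-peptide decoys
   give q-values; glycosites are localized by site-determining ions.
5. **Reporting** (`assign_isoforms`, `summarize_glycosites`,
   `write_reports`): accepted GPSMs aggregate into junction evidence,
   isoform assignment per gel band (junction-diagnostic evidence only),
   protein coverage and glycosite summaries.
6. **Synthetic data** (`generate_toy_cd44_grammar`, `generate_spectra`,
   `generate_null_spectra`, `generate_glycome_peaks`): ground-truthed
   fixtures for every stage, fully deterministic under a seed.

## Worked example

```r
library(glycosplice)

# toy CD44-like grammar: 19 exons, 9 variable; CD44s skips all of them
g <- generate_toy_cd44_grammar()
isoforms <- lapply(g$transcripts[c("CD44s_like", "CD44v2_10_like")],
                   function(t) translate_transcript(g$model, t))
isoforms$CD44s_like
#> <isoform> CD44s_like: 221 aa, junctions: e1-e2,e2-e3,e3-e4,e4-e5,e5-e15,
#>   e15-e16,e16-e17,e17-e18,e18-e19

# O-glycome -> Ser/Thr search space
space <- glycome_to_search_space("HexNAc1Hex1NeuAc1")
sapply(space, composition_string)
#> [1] "HexNAc1"  "HexNAc1Hex1"  "HexNAc1Hex1NeuAc1"

# candidate database with reversed decoys, then search synthetic spectra
db <- build_candidate_db(isoforms, space)
set.seed(7)
pool <- db[!db$is_decoy, ]
truth <- rbind(pool[grepl("e5-e15", pool$junction_tags), ][1, ],
               pool[sample(which(pool$n_glyco_sites == 1), 9), ])
gen <- generate_spectra(truth, generator_config(seed = 7))
gpsms <- target_decoy_fdr(search_spectra(gen$spectra, db))
head(gpsms[, c("peptide", "junction_tags", "compositions", "score", "q_value")], 3)
#>             peptide junction_tags      compositions    score q_value
#>  SSSHCIHLRVSSMNYSVL         v4-v5           HexNAc1 190.5642       0
#>   QLSSSHCIHLRVSSMNY         v4-v5           HexNAc1 182.8625       0
#>     QNTDQFTSTHSLKCY       e16-e17 HexNAc1Hex1NeuAc1 164.2551       0

# band-level report: junction evidence and isoform assignment
report <- assign_isoforms(gpsms, isoforms, band = "75-50")
report
#> <band report '75-50'> ID; 10 accepted GPSMs
#>   CD44v2_10_like via v4-v5, coverage 0.22
#>   CD44s_like via e5-e15, coverage 0.26
```

A score of ~190 means the match would arise by chance with probability
10⁻¹⁹⁰; `q_value = 0` means no decoy outscored it. The band report lists
the exon–exon junctions observed and assigns each isoform only from
junctions diagnostic of it within the searched database — here `v4-v5`
(variable-exon retention) and `e5-e15` (all-variable skipping) — with
the fraction of each isoform's sequence covered by accepted peptides.

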