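Package: glycosplice
Title: Glycoproteogenomics of Splice-Isoform Glycopeptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for identifying splice-isoform glycoproteoforms from
    tandem mass spectrometry. Builds protein isoform search databases from
    exon grammars and transcript models, derives the glycan search space
    from an annotated MALDI O-glycome of permethylated benzyl glycosides,
    filters HCD spectra by HexNAc oxonium diagnostics to schedule CID
    acquisition, scores glycopeptide-spectrum matches with a binomial-tail
    score under target-decoy false discovery rate control, localizes
    glycosites by site-determining ions, and reports exon-exon junction
    evidence, isoform assignments and protein coverage. Ships a
    ground-truthed synthetic-data generator (toy CD44-like exon grammar,
    glycome peak lists, HCD/CID spectra) so the full workflow is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    mzR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
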