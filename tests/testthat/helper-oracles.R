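# Independent brute-force oracles used across the suite. These deliberately
# re-derive results by the most direct route (string concatenation, codon
# loops, all-substring filters, linear scans) and share no code paths with
# the package internals they check.

# codon-loop translation of a concatenated nucleotide string from its
# first ATG, stopping at the first stop codon
oracle_translate <- function(nt) {
  code <- Biostrings::GENETIC_CODE
  start <- regexpr("ATG", nt, fixed = TRUE)[1]
  if (start < 0) return(NULL)
  aa <- character(0)
  i <- start
  stopped <- FALSE
  while (i + 2 <= nchar(nt)) {
    cod <- substr(nt, i, i + 2)
    res <- code[[cod]]
    if (res == "*") { stopped <- TRUE; break }
    aa <- c(aa, res)
    i <- i + 3
  }
  list(protein = paste(aa, collapse = ""), start0 = start - 1L,
       stopped = stopped)
}

# brute-force coding verdict matching the screening rules
oracle_verdict <- function(nt, min_orf_aa) {
  tr <- oracle_translate(nt)
  if (is.null(tr)) return("no_orf")
  if (nchar(tr$protein) >= min_orf_aa) return("coding")
  if (tr$stopped) "premature_stop" else "fragment_noncoding"
}

# all-substring chymotryptic filter: keep substrings whose boundaries are
# valid cleavage points with at most max_missed internal sites
oracle_digest <- function(seq, max_missed) {
  aa <- strsplit(seq, "")[[1]]
  n <- length(aa)
  cut_after <- aa %in% c("F", "Y", "W", "L") &
    c(aa[-1] != "P", FALSE)
  cut_after[n] <- FALSE
  C <- c(0L, cumsum(cut_after))          # C[i+1] = number of cut sites <= i
  ok_start <- c(TRUE, cut_after)         # position s0 (0-based) valid start
  res <- character(0)
  for (s0 in 0:(n - 1)) {
    if (!ok_start[s0 + 1]) next
    for (e0 in (s0 + 1):n) {
      if (!(e0 == n || cut_after[e0])) next
      internal <- C[e0] - C[s0 + 1]      # cut sites i with s0 < i < e0
      if (internal <= max_missed) {
        res <- c(res, substr(seq, s0 + 1, e0))
      }
    }
  }
  sort(res)
}

# linear scan for any peak within +/- window of a reference m/z
oracle_trigger <- function(s, ref_mz, window) {
  any(vapply(s$mz, function(p) abs(p - ref_mz) <= window, logical(1)))
}

# random protein sequence over the 20 standard residues
random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# shared toy grammar fixture (built once per test run)
toy_grammar <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_toy_cd44_grammar()
    cache
  }
})
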