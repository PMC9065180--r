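# Exon grammar, transcript translation, ORF screening, junction windows,
# FASTA round trip.

tiny_model <- function() {
  exon_model(data.frame(
    exon_id = c("e1", "e2"), category = "constitutive",
    sequence = c("ATGGCT", "GGTTAA"), stringsAsFactors = FALSE), mode = "nt")
}

test_that("hand-translatable transcripts produce the expected isoforms and junctions", {
  m <- tiny_model()
  iso <- translate_transcript(m, transcript_model("t1", c("e1", "e2")),
                              min_orf_aa = 1)
  expect_s3_class(iso, "protein_isoform")
  expect_identical(iso$aa_sequence, "MAG")
  expect_identical(iso$junctions$tag, "e1-e2")
  expect_identical(iso$junctions$aa_boundary, 2L)

  m1 <- exon_model(data.frame(exon_id = "e1", category = "constitutive",
                              sequence = "ATGTAA"), mode = "nt")
  iso1 <- translate_transcript(m1, transcript_model("t", "e1"), min_orf_aa = 1)
  expect_identical(iso1$aa_sequence, "M")   # stop consumed, not emitted
  expect_identical(nrow(iso1$junctions), 0L)
})

test_that("splice-then-translate equals concatenate-then-translate on all 2^3 variable-exon combinations", {
  # 9-exon toy grammar, 3 variable exons; junction tags and proteins are
  # compared against direct string concatenation + codon-loop translation
  set.seed(12)
  seqs <- c(paste0("ATG", paste(sample(c("GCT", "TCT", "TTT", "GGT"), 7,
                                       TRUE), collapse = "")),
            vapply(1:8, function(i) {
              paste(sample(c("GCT", "ACT", "CTG", "TAT", "GGT", "CAT"),
                           6, TRUE), collapse = "")
            }, character(1)))
  ids <- c("c1", "c2", "c3", "va", "vb", "vc", "c4", "c5", "c6")
  cat_v <- ifelse(ids %in% c("va", "vb", "vc"), "variable", "constitutive")
  m <- exon_model(data.frame(exon_id = ids, category = cat_v,
                             sequence = seqs, stringsAsFactors = FALSE),
                  mode = "nt")
  for (mask in 0:7) {
    vs <- c("va", "vb", "vc")[as.logical(bitwAnd(mask, c(1L, 2L, 4L)))]
    order_ids <- c("c1", "c2", "c3", vs, "c4", "c5", "c6")
    t <- transcript_model(paste0("t", mask), order_ids)
    iso <- translate_transcript(m, t, min_orf_aa = 1)
    concat <- paste(seqs[match(order_ids, ids)], collapse = "")
    tr <- oracle_translate(concat)
    expect_identical(iso$aa_sequence, tr$protein)
    # oracle junction tags: adjacency scan with cumulative lengths
    lens <- nchar(seqs[match(order_ids, ids)])
    b <- cumsum(lens)[-length(lens)]
    r <- b - tr$start0
    keep <- r > 0 & r < 3 * nchar(tr$protein) & r %/% 3 >= 1 &
      r %/% 3 <= nchar(tr$protein) - 1
    expect_identical(iso$junctions$tag,
                     paste0(order_ids[-length(order_ids)], "-",
                            order_ids[-1])[keep])
    expect_identical(iso$junctions$aa_boundary, as.integer((r %/% 3)[keep]))
  }
})

test_that("transcript screening reproduces a brute-force ORF scanner on random transcripts", {
  expect_identical(
    screen_transcript(exon_model(data.frame(exon_id = "x",
                                            category = "constitutive",
                                            sequence = "CCCCCC"),
                                 mode = "nt"),
                      transcript_model("t", "x"))$status, "no_orf")
  long_tail <- paste(rep("GGG", 20), collapse = "")
  expect_identical(
    screen_transcript(exon_model(data.frame(exon_id = "x",
                                            category = "constitutive",
                                            sequence = paste0("ATGTAA", long_tail)),
                                 mode = "nt"),
                      transcript_model("t", "x"), min_orf_aa = 10)$status,
    "premature_stop")

  set.seed(31)
  statuses <- character(0)
  oracle_statuses <- character(0)
  for (i in 1:100) {
    nt <- paste(sample(c("A", "C", "G", "T"), sample(30:150, 1), TRUE),
                collapse = "")
    m <- exon_model(data.frame(exon_id = "x", category = "constitutive",
                               sequence = nt), mode = "nt")
    t <- transcript_model("t", "x")
    statuses <- c(statuses, screen_transcript(m, t, min_orf_aa = 15)$status)
    oracle_statuses <- c(oracle_statuses, oracle_verdict(nt, 15))
  }
  expect_identical(statuses, oracle_statuses)
  expect_identical(as.vector(table(statuses)), as.vector(table(oracle_statuses)))
})

test_that("screening is idempotent and order-independent across a transcript set", {
  g <- toy_grammar()
  v1 <- vapply(g$transcripts, function(t) screen_transcript(g$model, t)$status,
               character(1))
  v2 <- vapply(rev(g$transcripts),
               function(t) screen_transcript(g$model, t)$status, character(1))
  expect_identical(v1, rev(v2))
  expect_identical(v1, vapply(g$transcripts,
                              function(t) screen_transcript(g$model, t)$status,
                              character(1)))
})

test_that("junction windows are clipped substrings at the recorded offsets", {
  m <- tiny_model()
  iso <- translate_transcript(m, transcript_model("t1", c("e1", "e2")),
                              min_orf_aa = 1)
  w <- enumerate_junction_windows(iso, flank = 2)
  expect_identical(w$window, "MAG")  # clipped at both ends

  g <- toy_grammar()
  isoS <- translate_transcript(g$model, g$transcripts$CD44s_like)
  wS <- enumerate_junction_windows(isoS, flank = 6)
  expect_true("e5-e15" %in% wS$junction_tag)
  expect_false(any(grepl("^v|[-]v", wS$junction_tag)))
  for (i in seq_len(nrow(wS))) {
    expect_identical(substr(isoS$aa_sequence, wS$start[i], wS$end[i]),
                     wS$window[i])
  }
  # junction positions strictly increasing and within bounds
  expect_true(all(diff(isoS$junctions$aa_boundary) > 0))
  expect_true(all(isoS$junctions$aa_boundary >= 1 &
                    isoS$junctions$aa_boundary <= nchar(isoS$aa_sequence) - 1))
})

test_that("isoform FASTA round-trips sequences, transcripts and junction tables", {
  g <- toy_grammar()
  isoforms <- lapply(g$transcripts[1:4], function(t)
    translate_transcript(g$model, t))
  path <- tempfile(fileext = ".fasta")
  write_isoform_fasta(isoforms, path)
  lines <- readLines(path)
  expect_identical(sum(grepl("^>", lines)), length(isoforms))
  expect_true(all(nchar(lines[!grepl("^>", lines)]) <= 60))
  back <- read_isoform_fasta(path)
  for (i in seq_along(isoforms)) {
    expect_identical(back[[i]]$isoform_id, isoforms[[i]]$isoform_id)
    expect_identical(back[[i]]$aa_sequence, isoforms[[i]]$aa_sequence)
    expect_identical(back[[i]]$junctions$tag, isoforms[[i]]$junctions$tag)
    expect_identical(back[[i]]$junctions$aa_boundary,
                     isoforms[[i]]$junctions$aa_boundary)
    expect_identical(back[[i]]$source_transcript,
                     isoforms[[i]]$source_transcript)
  }
  dup <- isoforms[c(1, 1)]
  expect_error(write_isoform_fasta(dup, tempfile()), "duplicate")
})

test_that("amino-acid-mode models splice isoforms directly and refuse ORF screening", {
  m <- exon_model(data.frame(exon_id = c("a", "b"), category = "constitutive",
                             sequence = c("MKT", "SSAR")), mode = "aa")
  t <- transcript_model("t", c("a", "b"))
  iso <- translate_transcript(m, t)
  expect_identical(iso$aa_sequence, "MKTSSAR")
  expect_identical(iso$junctions$aa_boundary, 3L)
  expect_error(screen_transcript(m, t), "nucleotide")
})

test_that("exon model and transcript TSV/JSON readers reconstruct the models", {
  g <- toy_grammar()
  tsv <- tempfile(fileext = ".tsv")
  df <- g$model$exons
  df$mode <- "nt"
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  m2 <- read_exon_model_tsv(tsv)
  expect_identical(m2$exons$sequence, g$model$exons$sequence)

  js <- tempfile(fileext = ".json")
  jsonlite::write_json(list(
    list(transcript_id = "tx", exon_refs = list("e1", "e2",
      list(exon_id = "e3", start = 0, end = 6)))), js, auto_unbox = TRUE)
  ts <- read_transcripts_json(js)
  expect_identical(ts[[1]]$transcript_id, "tx")
  expect_identical(ts[[1]]$exon_refs$end, c(NA_integer_, NA_integer_, 6L))
  sp <- splice_result <- translate_transcript(g$model, ts[[1]], min_orf_aa = 5)
  expect_true(grepl("e3\\(partial\\)", utils::tail(sp$junctions$tag, 1)))
})
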