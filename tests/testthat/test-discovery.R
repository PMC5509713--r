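## a tiny hand-built world exercising every cascade predicate
tiny_world <- function() {
  set.seed(17)
  lnc <- random_noncoding_tiny(350)
  tr <- Biostrings::DNAStringSet(c(
    good = lnc,
    symb = random_dna(400),
    prot = random_dna(400),
    shorty = random_dna(150),
    longorf = paste0("TAA", paste(rep("GCA", 100), collapse = ""), "TAA"),
    hk = random_noncoding_tiny(400),
    lowex = random_noncoding_tiny(320)))
  counts <- matrix(c(6L, 5L,   20L, 20L, 20L, 20L, 30L, 0L, 15L, 20L,
                     9L, 2L,   4L, 5L),
                   ncol = 2, byrow = TRUE,
                   dimnames = list(names(tr), c("s1", "s2")))
  ev <- build_evidence_bundle(
    names(tr), symbiont_ids = "symb",
    protein_hits = data.frame(qseqid = "prot", sseqid = "P1", pident = 99,
                              length = 100L, mismatch = 0L, gapopen = 0L,
                              qstart = 1L, qend = 100L, sstart = 1L,
                              send = 100L, evalue = 1e-9, bitscore = 200,
                              stringsAsFactors = FALSE),
    housekeeping_hits = data.frame(qseqid = "hk", sseqid = "RF1",
                                   pident = 99, length = 100L,
                                   mismatch = 0L, gapopen = 0L,
                                   qstart = 1L, qend = 100L, sstart = 1L,
                                   send = 100L, evalue = 1e-12,
                                   bitscore = 200,
                                   stringsAsFactors = FALSE))
  model <- train_kmer_model(c(c1 = random_dna(300, c(A = .15, C = .35,
                                                     G = .35, T = .15))),
                            c(n1 = lnc))
  list(tr = tr, counts = counts, ev = ev, model = model)
}

## AT-rich noncoding sequence without package-internal helpers
random_noncoding_tiny <- function(len) {
  repeat {
    s <- random_dna(len, c(A = .3, C = .2, G = .2, T = .3))
    if (unname(longest_orf_aa(setNames(s, "x"))) <= 75) return(s)
  }
}

test_that("classify_transcripts applies every predicate and names classes", {
  w <- tiny_world()
  res <- classify_transcripts(w$tr, w$ev, w$counts, filter_config(),
                              kmer_model = w$model)
  tclass <- setNames(res$trace$final_class, res$trace$transcript_id)
  expect_equal(unname(tclass["good"]), "lncRNA")
  expect_equal(unname(tclass["symb"]), "contaminant")
  expect_equal(unname(tclass["prot"]), "mRNA-like")
  expect_equal(unname(tclass["shorty"]), "short")
  expect_equal(unname(tclass["longorf"]), "coding-ORF")
  expect_equal(unname(tclass["hk"]), "housekeeping")
  expect_equal(unname(tclass["lowex"]), "low-expression")
  expect_equal(res$lncrna_ids, "good")
  ## counts (6, 5) pass the >= 10 total rule; (4, 5) would not
  expect_equal(res$trace$total_counts[res$trace$transcript_id == "good"],
               11)
})

test_that("dropping counts below the threshold excludes as low-expression", {
  w <- tiny_world()
  w$counts["good", ] <- c(4L, 5L)
  res <- classify_transcripts(w$tr, w$ev, w$counts, filter_config(),
                              kmer_model = w$model)
  expect_false("good" %in% res$lncrna_ids)
  expect_equal(res$trace$final_class[res$trace$transcript_id == "good"],
               "low-expression")
})

test_that("cascade thresholds are monotone", {
  w <- tiny_world()
  base <- classify_transcripts(w$tr, w$ev, w$counts, filter_config(),
                               kmer_model = w$model)$lncrna_ids
  stricter_len <- classify_transcripts(
    w$tr, w$ev, w$counts, filter_config(min_length_nt = 360L),
    kmer_model = w$model)$lncrna_ids
  expect_true(all(stricter_len %in% base))
  stricter_orf <- classify_transcripts(
    w$tr, w$ev, w$counts, filter_config(max_orf_aa = 10L),
    kmer_model = w$model)$lncrna_ids
  expect_true(all(stricter_orf %in% base))
})

test_that("summarize_filters conserves the transcript count", {
  w <- tiny_world()
  res <- classify_transcripts(w$tr, w$ev, w$counts, filter_config(),
                              kmer_model = w$model)
  s <- summarize_filters(res$trace)
  expect_equal(sum(s$n), length(w$tr))
  one <- summarize_filters(data.frame(final_class = rep("lncRNA", 3)))
  expect_equal(nrow(one), 1L)
  expect_equal(one$n, 3L)
})

test_that("empty inputs and invalid configs error", {
  w <- tiny_world()
  expect_error(classify_transcripts(Biostrings::DNAStringSet(), w$ev,
                                    w$counts, filter_config()),
               "empty")
  expect_error(filter_config(min_length_nt = 0), "positive")
  expect_error(filter_config(contaminant_rule = "xor"))
})

test_that("evidence bundle must cover every transcript", {
  w <- tiny_world()
  ev2 <- w$ev[w$ev$transcript_id != "good", ]
  expect_error(classify_transcripts(w$tr, ev2, w$counts, filter_config(),
                                    kmer_model = w$model),
               "does not cover.*good")
})

test_that("external labels replace the kmer model when supplied", {
  w <- tiny_world()
  plek <- setNames(rep(FALSE, length(w$tr)), names(w$tr))
  ev <- build_evidence_bundle(names(w$tr), symbiont_ids = "symb",
                              plek_labels = plek)
  res <- classify_transcripts(w$tr, ev, w$counts, filter_config())
  expect_false(any(res$trace$kmer_coding))
  plek["good"] <- TRUE
  ev2 <- build_evidence_bundle(names(w$tr), symbiont_ids = "symb",
                               plek_labels = plek)
  res2 <- classify_transcripts(w$tr, ev2, w$counts, filter_config())
  expect_equal(res2$trace$final_class[res2$trace$transcript_id == "good"],
               "coding-by-kmer")
})

test_that("trace writers emit readable TSV", {
  w <- tiny_world()
  res <- classify_transcripts(w$tr, w$ev, w$counts, filter_config(),
                              kmer_model = w$model)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_trace(res$trace, f)
  back <- read.table(f, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
  expect_equal(back$transcript_id, res$trace$transcript_id)
  expect_equal(back$final_class, res$trace$final_class)
})
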