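test_that("sim_config validates its inputs", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(de_fold = 1), "de_fold")
  expect_error(sim_config(segment_length = 5), "segment_length")
  expect_error(sim_config(lncrna_length = c(200L, 400L)), "infeasible|300")
})

test_that("simulate_transcriptome: class sizes, invariants, determinism", {
  cfg <- sim_config(seed = 7L, n_mrna = 8L, n_lncrna = 10L,
                    n_symbiont = 4L, n_housekeeping = 3L, n_short = 5L,
                    n_small_orf = 4L, n_low_expression = 2L,
                    n_true_edges = 0L, n_decoy_outside = 0L,
                    n_decoy_half = 0L)
  sim <- simulate_transcriptome(cfg)
  expect_equal(table(sim$manifest$sim_class)[["lncrna"]], 10L)
  expect_equal(nrow(sim$manifest), 36L)
  expect_equal(sim$manifest$transcript_id, names(sim$transcripts))

  ## lncRNA-class invariants hold by construction
  lnc <- sim$transcripts[sim$manifest$sim_class %in%
                           c("lncrna", "low_expression")]
  expect_true(all(Biostrings::width(lnc) >= 300))
  expect_true(all(longest_orf_aa(lnc) <= 75))
  ## mRNAs carry a long ORF
  mr <- sim$transcripts[sim$manifest$sim_class == "mrna"]
  expect_true(all(longest_orf_aa(mr) >= 100))
  ## short class is below the cascade minimum
  expect_true(all(sim$manifest$length[sim$manifest$sim_class == "short"] <
                    300))

  sim2 <- simulate_transcriptome(cfg)
  expect_identical(as.character(sim$transcripts),
                   as.character(sim2$transcripts))
})

test_that("emit_evidence_tables: noiseless evidence follows the plant", {
  fx <- get_fixture42()
  ev <- fx$evidence_tables
  man <- fx$manifest
  lnc_ids <- man$transcript_id[man$sim_class %in%
                                 c("lncrna", "low_expression")]
  ## zero evidence rows mention any true lncRNA
  expect_length(intersect(ev$symbiont_hits$qseqid, lnc_ids), 0L)
  expect_length(intersect(ev$protein_hits$qseqid, lnc_ids), 0L)
  expect_length(intersect(ev$domain_hits$qseqid, lnc_ids), 0L)
  expect_length(intersect(ev$housekeeping_hits$qseqid, lnc_ids), 0L)
  expect_false(any(ev$signal_calls[lnc_ids]))
  ## every contaminant satisfies the AND rule as emitted
  widths <- setNames(Biostrings::width(fx$transcripts),
                     names(fx$transcripts))
  got <- symbiont_contaminants(ev$symbiont_hits, widths,
                               ev$subject_lengths)
  expect_setequal(got, man$transcript_id[man$sim_class == "symbiont"])
})

test_that("noise flips are deterministic under seed and recorded", {
  cfg <- sim_config(seed = 11L, n_mrna = 15L, n_lncrna = 15L,
                    n_symbiont = 2L, n_housekeeping = 2L, n_short = 2L,
                    n_small_orf = 2L, n_low_expression = 2L,
                    n_true_edges = 0L, n_decoy_outside = 0L,
                    n_decoy_half = 0L)
  f1 <- simulate_fixture(cfg, noise_rate = 0.3)
  f2 <- simulate_fixture(cfg, noise_rate = 0.3)
  expect_identical(f1$noise_flipped, f2$noise_flipped)
  expect_gt(length(f1$noise_flipped), 0L)
  ## flipped lncRNAs now carry protein evidence and expected mRNA-like
  flnc <- intersect(f1$noise_flipped,
                    f1$manifest$transcript_id[f1$manifest$sim_class ==
                                                "lncrna"])
  if (length(flnc) > 0L) {
    expect_true(all(flnc %in% f1$evidence_tables$protein_hits$qseqid))
    expect_true(all(f1$manifest$expected_class[
      f1$manifest$transcript_id %in% flnc] == "mRNA-like"))
  }
})

test_that("simulate_counts: planted DE structure and Poisson limit", {
  fx <- get_fixture42()
  man <- fx$manifest
  expect_equal(colnames(fx$counts$counts), c("healthy", "bleaching"))
  up <- man[man$de_truth == "up", ]
  expect_true(all(up$mu_bleaching / up$mu_healthy == 4))
  dn <- man[man$de_truth == "down", ]
  expect_true(all(dn$mu_healthy / dn$mu_bleaching == 4))
  ns <- man[man$de_truth == "ns", ]
  expect_true(all(ns$mu_healthy == ns$mu_bleaching))

  ## dispersion -> 0 limit behaves like Poisson (variance ~ mean)
  cfg0 <- sim_config(seed = 5L, n_mrna = 0L, n_lncrna = 0L,
                     n_symbiont = 0L, n_housekeeping = 0L, n_short = 0L,
                     n_small_orf = 0L, n_low_expression = 0L,
                     nb_dispersion = 0)
  set.seed(5)
  draws <- rpois(10000, 100)
  expect_lt(abs(var(draws) / mean(draws) - 1), 0.05)
  ## and the NB path is genuinely overdispersed
  set.seed(5)
  nb <- rnbinom(10000, mu = 100, size = 1 / 0.1)
  expect_gt(var(nb) / mean(nb), 5)
})

test_that("plant_interactions: complements present, decoys out of region", {
  fx <- get_fixture42()
  ed <- fx$truth_edges
  seqs <- as.character(fx$transcripts)
  for (k in seq_len(nrow(ed))) {
    e <- ed[k, ]
    seg <- substr(seqs[[e$lncrna_id]], e$lnc_seg_start + 1L, e$lnc_seg_end)
    ins <- if (e$edge_type == "decoy_half") {
      substr(seg, 1L, nchar(seg) %/% 2L)
    } else seg
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(ins)))
    expect_true(grepl(rc, seqs[[e$mrna_id]], fixed = TRUE),
                info = paste(e$edge_type, e$lncrna_id))
  }
  ## outside decoys: planted segment does not intersect any emitted region
  regions <- conserved_regions_from_hits(
    fx$lncref_hits,
    setNames(Biostrings::width(fx$transcripts), names(fx$transcripts)),
    e_cutoff = 1e-3)
  out <- ed[ed$edge_type == "decoy_outside", ]
  for (k in seq_len(nrow(out))) {
    e <- out[k, ]
    reg <- regions[regions$lncrna_id == e$lncrna_id, ]
    expect_true(all(reg$end <= e$lnc_seg_start |
                      reg$start >= e$lnc_seg_end))
  }
})

test_that("fixture writes round-trip losslessly", {
  fx <- get_fixture42()
  dir <- withr::local_tempdir()
  write_fixture(fx, dir)
  tr <- read_fasta(file.path(dir, "transcripts.fasta"))
  expect_identical(as.character(tr), as.character(fx$transcripts))
  ct <- read_counts_table(file.path(dir, "counts.tsv"))
  expect_equal(ct$counts, fx$counts$counts)
  man <- read_manifest(file.path(dir, "manifest.tsv"))
  expect_equal(man$transcript_id, fx$manifest$transcript_id)
  expect_equal(man$expected_class, fx$manifest$expected_class)
  hits <- parse_hit_table(file.path(dir, "lncref_hits.tsv"))
  expect_equal(hits$qseqid, fx$lncref_hits$qseqid)
  expect_equal(hits$qstart, fx$lncref_hits$qstart)
  km <- read_kmer_model(file.path(dir, "kmer_model.tsv"))
  expect_equal(km$log_odds, fx$kmer_model$log_odds)
})
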