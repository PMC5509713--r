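region_hit <- function(q, qs, qe, ev = 1e-8, s = "NONC000001") {
  data.frame(qseqid = q, sseqid = s, pident = 95, length = qe - qs + 1L,
             mismatch = 0L, gapopen = 0L, qstart = qs, qend = qe,
             sstart = 1L, send = qe - qs + 1L, evalue = ev, bitscore = 80,
             stringsAsFactors = FALSE)
}

test_that("energy model files parse; toy model is temperature-invariant", {
  toy <- toy_model()
  expect_equal(toy$stack["GC", "CG"], -2)
  expect_equal(toy$stack["GU", "AU"], -1)
  expect_equal(toy$max_span, 0L)
  expect_equal(toy$init, 0)
  toy37 <- read_energy_model(energy_model_path("toy"), temperature = 37)
  expect_equal(toy37$stack, toy$stack)

  def <- default_model()
  ## rescaling toward 25C from 37C stabilizes stacks (dH < dG37 < 0)
  def37 <- read_energy_model(energy_model_path("default"), temperature = 37)
  expect_equal(def37$stack["GC", "GC"], -3.26, tolerance = 1e-9)
  expect_true(all(def$stack < def37$stack))
  expect_equal(def$init, 4.1)      # dh == dg -> invariant
  expect_equal(def$max_span, 4L)
})

test_that("duplex_fold: no complementarity, forced toy case, N unpairable", {
  toy <- toy_model()
  expect_null(duplex_fold("AAAA", "AAAA", toy))
  d <- duplex_fold("GGGG", "CCCC", toy)
  expect_equal(d$energy, -6)
  expect_equal(nrow(d$pairs), 4L)
  expect_equal(d$lncrna_interval, c(0L, 4L))
  expect_equal(d$paired_fraction, 1)
  ## antiparallel: ascending on lncRNA, descending on mRNA
  expect_true(all(diff(d$pairs$lncrna_pos) > 0))
  expect_true(all(diff(d$pairs$mrna_pos) < 0))
  expect_null(duplex_fold("GNGN", "CNCN", toy))
  expect_error(duplex_fold("", "CCCC", toy), "non-empty")
})

test_that("toy-model DP equals exhaustive enumeration (contiguous runs)", {
  toy <- toy_model()
  set.seed(61)
  for (i in 1:80) {
    x <- random_dna(sample(3:12, 1))
    y <- random_dna(sample(3:12, 1))
    d <- duplex_fold(x, y, toy)
    o <- oracle_duplex_energy(x, y, toy)
    if (is.null(o) || o >= 0) {
      expect_null(d, info = paste(x, y))
    } else {
      expect_equal(d$energy, o, info = paste(x, y))
    }
  }
})

test_that("loop-enabled DP equals exhaustive enumeration on tiny inputs", {
  model <- default_model()
  model$max_span <- 3L   # keep the oracle's recursion tractable
  set.seed(67)
  for (i in 1:25) {
    x <- random_dna(sample(4:8, 1))
    y <- random_dna(sample(4:8, 1))
    d <- duplex_fold(x, y, model)
    o <- oracle_duplex_energy(x, y, model)
    if (is.null(o) || o >= 0) {
      expect_null(d, info = paste(x, y))
    } else {
      expect_equal(d$energy, o, tolerance = 1e-9, info = paste(x, y))
    }
  }
})

test_that("duplex energy is swap-symmetric under the symmetric toy table", {
  toy <- toy_model()
  set.seed(71)
  for (i in 1:25) {
    x <- random_dna(10); y <- random_dna(10)
    dx <- duplex_fold(x, y, toy)
    dy <- duplex_fold(y, x, toy)
    if (is.null(dx)) expect_null(dy) else expect_equal(dx$energy, dy$energy)
  }
})

test_that("windowed scan finds the same plant as the full fold", {
  model <- default_model()
  set.seed(73)
  seg <- random_dna(30, c(A = .5, C = 0, G = 0, T = .5))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seg)))
  lnc <- paste0(random_dna(60), seg, random_dna(60))
  mr <- paste0(random_dna(400), rc, random_dna(100))
  full <- duplex_fold(lnc, mr, model)
  win <- duplex_fold(lnc, mr, model, window = 200L, stride = 100L)
  expect_false(is.null(full))
  expect_false(is.null(win))
  expect_equal(win$energy, full$energy, tolerance = 1e-6)
  expect_equal(win$mrna_interval, full$mrna_interval)
})

test_that("conserved_regions_from_hits merges and applies the cutoff", {
  lens <- c(l1 = 200)
  hits <- rbind(region_hit("l1", 1L, 30L), region_hit("l1", 20L, 50L))
  r <- conserved_regions_from_hits(hits, lens, 1e-3)
  expect_equal(nrow(r), 1L)
  expect_equal(r$start, 0L)
  expect_equal(r$end, 50L)

  ## adjacent intervals merge too
  hits2 <- rbind(region_hit("l1", 1L, 30L), region_hit("l1", 31L, 60L))
  r2 <- conserved_regions_from_hits(hits2, lens, 1e-3)
  expect_equal(nrow(r2), 1L)

  ## strict vs loose threshold (the DEL mode)
  h5 <- region_hit("l1", 10L, 40L, ev = 5)
  expect_equal(nrow(conserved_regions_from_hits(h5, lens, 1e-3)), 0L)
  expect_equal(nrow(conserved_regions_from_hits(h5, lens, 10)), 1L)

  expect_equal(nrow(conserved_regions_from_hits(empty_hit_table(),
                                                lens, 1e-3)), 0L)
  expect_error(conserved_regions_from_hits(region_hit("l1", 190L, 210L),
                                           lens, 1), "exceeds")
})

test_that("gate_interactions applies the three gates conjunctively", {
  mkdup <- function(energy, pf, s, e, id = "l1") {
    structure(list(lncrna_id = id, mrna_id = "m1",
                   lncrna_interval = c(s, e), mrna_interval = c(0L, e - s),
                   energy = energy, pairs = NULL, paired_fraction = pf),
              class = "duplex_result")
  }
  regions <- data.frame(lncrna_id = "l1", start = 100L, end = 140L,
                        stringsAsFactors = FALSE)
  ed <- gate_interactions(list(
    mkdup(-25, 1.0, 105L, 135L),   # all pass
    mkdup(-15, 1.0, 105L, 135L),   # energy fails
    mkdup(-25, 0.7, 105L, 135L),   # pairing fails
    mkdup(-25, 1.0, 300L, 330L)),  # outside every region
    regions)
  expect_equal(ed$accepted, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(ed$passes_energy, c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(ed$passes_pairing, c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(ed$in_conserved_region, c(TRUE, TRUE, TRUE, FALSE))

  ## coverage rule boundary: half-in interval passes at >= 50%
  half <- mkdup(-25, 1.0, 120L, 160L)  # 20 of 40 nt covered
  expect_true(gate_interactions(list(half), regions)$accepted)
  expect_false(gate_interactions(list(half), regions,
                                 overlap_rule = "containment")$accepted)
  expect_true(gate_interactions(list(mkdup(-25, 1, 138L, 178L)), regions,
                                overlap_rule = "any")$accepted)
  expect_error(gate_interactions(list(half), regions,
                                 overlap_rule = "sometimes"))
})

test_that("gate monotonicity: stricter energy cutoff never adds edges", {
  set.seed(79)
  model <- toy_model()
  regions <- data.frame(lncrna_id = "l1", start = 0L, end = 40L,
                        stringsAsFactors = FALSE)
  dups <- list()
  for (i in 1:12) {
    d <- duplex_fold(random_dna(40), random_dna(40), model,
                     lncrna_id = "l1", mrna_id = sprintf("m%d", i))
    if (!is.null(d)) dups[[length(dups) + 1L]] <- d
  }
  prev <- NULL
  for (cut in c(-4, -8, -12, -16)) {
    acc <- with(gate_interactions(dups, regions, energy_cutoff = cut,
                                  min_paired_fraction = 0),
                paste(lncrna_id, mrna_id)[accepted])
    if (!is.null(prev)) expect_true(all(acc %in% prev))
    prev <- acc
  }
})

test_that("build_network counts nodes and edges deterministically", {
  ed <- data.frame(
    lncrna_id = rep(c("l1", "l2"), each = 3),
    mrna_id = paste0("m", c(1, 2, 3, 4, 5, 6)),
    accepted = TRUE, stringsAsFactors = FALSE)
  net <- build_network(ed)
  expect_equal(net$summary$n_lncrna, 2L)
  expect_equal(net$summary$n_mrna, 6L)
  expect_equal(net$summary$n_edges, 6L)
  expect_equal(igraph::vcount(net$graph), 8L)
  expect_true(igraph::is_bipartite(net$graph))
  expect_equal(net$degree$degree[net$degree$id == "l1"], 3L)

  empty <- build_network(ed[0, ])
  expect_equal(empty$summary$n_edges, 0L)
  expect_equal(igraph::vcount(empty$graph), 0L)
})

test_that("read_rnaplex parses native output lines", {
  f <- withr::local_tempfile(fileext = ".out")
  writeLines(c(">mrna_0001", ">lnc_0002",
               "((((((&)))))) 140,145 : 3,8 (-8.50)"), f)
  dl <- read_rnaplex(f)
  expect_length(dl, 1L)
  d <- dl[[1L]]
  expect_equal(d$lncrna_id, "lnc_0002")
  expect_equal(d$mrna_id, "mrna_0001")
  expect_equal(d$energy, -8.5)
  expect_equal(d$lncrna_interval, c(2L, 8L))
  expect_equal(d$mrna_interval, c(139L, 145L))
  expect_equal(d$paired_fraction, 1)
})
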