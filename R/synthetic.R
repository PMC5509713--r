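#' Configuration of the synthetic transcriptome generator
#'
#' The generator emulates the structure of a de novo assembled coral
#' transcriptome as the discovery cascade sees it: host mRNAs (GC-shifted
#' codon composition, a long ORF flanked by UTRs), lncRNAs (AT-shifted,
#' no ORF above the cascade limit), endosymbiont contaminant copies,
#' housekeeping-RNA copies, spurious short contigs, and small-ORF coding
#' transcripts, plus two-condition negative-binomial counts
#' (healthy/bleaching) and planted lncRNA-mRNA interactions.
#'
#' @param seed Integer master seed; every stage derives its own stream.
#' @param n_mrna,n_lncrna,n_symbiont,n_housekeeping,n_short,n_small_orf,n_low_expression
#'   Class sizes (defaults total 500, the standard fixture).
#' @param lncrna_length,mrna_utr5,mrna_orf_aa,mrna_utr3,short_length,small_orf_aa
#'   Length ranges (`c(min, max)`), in nt except the `_aa` ones.
#' @param nb_mean_range Baseline negative-binomial mean range per library
#'   (log-uniform draw).
#' @param nb_dispersion NB dispersion (variance = mu + dispersion * mu^2);
#'   0 degenerates to Poisson.
#' @param de_fraction Fraction of mRNAs and lncRNAs planted as
#'   differentially expressed.
#' @param de_fold Planted fold change (> 1; default 4).
#' @param low_expression_mean Per-library NB mean of the planted
#'   low-expression lncRNA-like transcripts.
#' @param n_true_edges,n_decoy_outside,n_decoy_half Interaction plants:
#'   true in-region complements, decoys with the complement outside the
#'   conserved region, and decoys with only a half-length complement.
#' @param segment_length Planted complement length (>= 10 nt, default 30).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 42L, n_mrna = 120L, n_lncrna = 150L,
                       n_symbiont = 60L, n_housekeeping = 40L,
                       n_short = 60L, n_small_orf = 40L,
                       n_low_expression = 30L,
                       lncrna_length = c(300L, 800L),
                       mrna_utr5 = c(50L, 200L),
                       mrna_orf_aa = c(100L, 350L),
                       mrna_utr3 = c(100L, 400L),
                       short_length = c(80L, 299L),
                       small_orf_aa = c(90L, 150L),
                       nb_mean_range = c(20, 500),
                       nb_dispersion = 0.1,
                       de_fraction = 0.1, de_fold = 4,
                       low_expression_mean = 0.5,
                       n_true_edges = 6L, n_decoy_outside = 3L,
                       n_decoy_half = 3L, segment_length = 30L) {
  cfg <- list(seed = as.integer(seed), n_mrna = n_mrna,
              n_lncrna = n_lncrna, n_symbiont = n_symbiont,
              n_housekeeping = n_housekeeping, n_short = n_short,
              n_small_orf = n_small_orf,
              n_low_expression = n_low_expression,
              lncrna_length = lncrna_length, mrna_utr5 = mrna_utr5,
              mrna_orf_aa = mrna_orf_aa, mrna_utr3 = mrna_utr3,
              short_length = short_length, small_orf_aa = small_orf_aa,
              nb_mean_range = nb_mean_range,
              nb_dispersion = nb_dispersion, de_fraction = de_fraction,
              de_fold = de_fold, low_expression_mean = low_expression_mean,
              n_true_edges = n_true_edges,
              n_decoy_outside = n_decoy_outside,
              n_decoy_half = n_decoy_half,
              segment_length = as.integer(segment_length))
  counts <- unlist(cfg[grep("^n_", names(cfg))])
  if (any(counts < 0)) stop("class counts must be >= 0")
  if (de_fold <= 1) stop("de_fold must be > 1")
  if (cfg$segment_length < 10L) stop("segment_length must be >= 10")
  if (lncrna_length[1L] < 300L) {
    stop("lncRNA length below the 300-nt cascade minimum is infeasible")
  }
  structure(cfg, class = "sim_config")
}

## Composition presets. lncRNAs run AT-rich relative to coding sequence,
## which is what lets a k-mer log-odds screen separate the classes.
COMP_LNC <- c(A = 0.30, C = 0.20, G = 0.20, T = 0.30)
COMP_MRNA <- c(A = 0.20, C = 0.30, G = 0.30, T = 0.20)
COMP_FLAT <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)

random_seq <- function(n, probs = COMP_FLAT) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs),
        collapse = "")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

## n random sense codons (no stops), base composition `probs`
random_codons <- function(n, probs = COMP_MRNA) {
  out <- character(n)
  need <- seq_len(n)
  while (length(need) > 0L) {
    cand <- vapply(need, function(i) random_seq(3L, probs), "")
    ok <- !(cand %in% STOP_CODONS)
    out[need[ok]] <- cand[ok]
    need <- need[!ok]
  }
  paste(out, collapse = "")
}

mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  x <- strsplit(seq, "")[[1L]]
  hit <- which(runif(length(x)) < rate)
  for (i in hit) {
    x[i] <- sample(setdiff(c("A", "C", "G", "T"), x[i]), 1L)
  }
  paste(x, collapse = "")
}

## A random AT-shifted sequence rejected until its longest stop-to-stop
## ORF (both strands) is at or below max_aa.
random_noncoding_seq <- function(len, max_aa = 75L, probs = COMP_LNC,
                                 max_tries = 400L) {
  for (i in seq_len(max_tries)) {
    s <- random_seq(len, probs)
    if (unname(longest_orf_aa(setNames(s, "x"))) <= max_aa) return(s)
  }
  stop("could not sample a noncoding sequence of length ", len,
       " within ", max_tries, " tries")
}

shipped_reference <- function(which = c("symbiont", "rrna")) {
  which <- match.arg(which)
  f <- system.file("extdata", sprintf("%s_ref_synthetic.fasta", which),
                   package = "lncoral")
  if (f == "") stop("shipped reference not found: ", which)
  read_fasta(f)
}

#' Simulate a synthetic transcriptome with a ground-truth manifest
#'
#' Generates every transcript class of [sim_config()]. mRNA-like
#' transcripts carry a random-codon ORF of at least 100 aa flanked by
#' UTRs; lncRNA-like transcripts (including the planted low-expression
#' ones) are >= 300 nt and rejection-sampled until the longest
#' stop-to-stop ORF on both strands is <= 75 aa; housekeeping transcripts
#' are copies of a shipped (synthetic) rRNA-like reference with <= 2%
#' point mutations; contaminants are near-identical copies of a shipped
#' (synthetic) symbiont-like reference. Deterministic under the config
#' seed.
#'
#' @param config A [sim_config()].
#' @return List with `transcripts` (named [Biostrings::DNAStringSet]) and
#'   `manifest` (data.frame: `transcript_id`, `sim_class`, `length`).
#' @export
simulate_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  seqs <- character(0)
  cls <- character(0)
  add <- function(id, s, klass) {
    seqs[[id]] <<- s
    cls[[id]] <<- klass
  }
  rint <- function(rng) if (rng[1L] >= rng[2L]) rng[1L] else
    sample(rng[1L]:rng[2L], 1L)

  for (i in seq_len(config$n_mrna)) {
    s <- paste0(random_seq(rint(config$mrna_utr5), COMP_MRNA),
                "ATG", random_codons(rint(config$mrna_orf_aa) - 1L),
                sample(STOP_CODONS, 1L),
                random_seq(rint(config$mrna_utr3), COMP_MRNA))
    add(sprintf("mrna_%04d", i), s, "mrna")
  }
  for (i in seq_len(config$n_lncrna)) {
    add(sprintf("lnc_%04d", i),
        random_noncoding_seq(rint(config$lncrna_length)), "lncrna")
  }
  for (i in seq_len(config$n_low_expression)) {
    add(sprintf("lowexp_%04d", i),
        random_noncoding_seq(rint(config$lncrna_length)), "low_expression")
  }
  symb <- shipped_reference("symbiont")
  for (i in seq_len(config$n_symbiont)) {
    ref <- sample(length(symb), 1L)
    add(sprintf("symb_%04d", i),
        mutate_seq(as.character(symb[[ref]]), 0.005), "symbiont")
  }
  rrna <- shipped_reference("rrna")
  for (i in seq_len(config$n_housekeeping)) {
    ref <- sample(length(rrna), 1L)
    add(sprintf("hk_%04d", i),
        mutate_seq(as.character(rrna[[ref]]), runif(1L, 0, 0.02)),
        "housekeeping")
  }
  for (i in seq_len(config$n_short)) {
    add(sprintf("short_%04d", i),
        random_seq(rint(config$short_length)), "short")
  }
  for (i in seq_len(config$n_small_orf)) {
    n_aa <- rint(config$small_orf_aa)
    core <- paste0("TAA", random_codons(n_aa), "TAA")
    flank <- max(0L, rint(config$lncrna_length) - nchar(core))
    left <- flank %/% 2L
    s <- paste0(random_seq(left, COMP_LNC), core,
                random_seq(flank - left, COMP_LNC))
    add(sprintf("sorf_%04d", i), s, "small_orf")
  }

  transcripts <- Biostrings::DNAStringSet(unlist(seqs))
  manifest <- data.frame(transcript_id = names(transcripts),
                         sim_class = unname(unlist(cls)),
                         length = Biostrings::width(transcripts),
                         stringsAsFactors = FALSE)
  list(transcripts = transcripts, manifest = manifest)
}

#' Plant conserved-region-gated lncRNA-mRNA interactions
#'
#' For each planted triple, a random A/U-only segment (default 30 nt) is
#' spliced into a lncRNA, a reference-database hit covering it is emitted
#' (so the segment becomes a conserved region), and the exact reverse
#' complement is spliced into the 3' portion of a target mRNA. A/U-only
#' segments are used because their stack energetics put the full-length
#' duplex far below the -20 kcal/mol gate while a half-length duplex
#' stays well above it. Decoys either move the emitted conserved region
#' elsewhere on the lncRNA (complement outside the region) or truncate
#' the complement to half length. The lncRNA is re-checked (and the plant
#' re-drawn) so splicing never pushes its longest ORF over the cascade
#' limit.
#'
#' @param sim Output of [simulate_transcriptome()].
#' @param config The [sim_config()].
#' @return `sim`, augmented with modified `transcripts`,
#'   `lncref_hits` (reference-lncRNA hit table), `regions_truth`
#'   (planted conserved regions), and `truth_edges` (data.frame:
#'   `lncrna_id`, `mrna_id`, `edge_type` in
#'   `planted`/`decoy_outside`/`decoy_half`, plant coordinates).
#' @export
plant_interactions <- function(sim, config) {
  set.seed(config$seed + 1L)
  n_plant <- config$n_true_edges + config$n_decoy_outside +
    config$n_decoy_half
  if (n_plant == 0L) {
    sim$lncref_hits <- empty_hit_table()
    sim$regions_truth <- data.frame()
    sim$truth_edges <- data.frame()
    return(sim)
  }
  lnc_ids <- sim$manifest$transcript_id[sim$manifest$sim_class == "lncrna"]
  mrna_ids <- sim$manifest$transcript_id[sim$manifest$sim_class == "mrna"]
  if (length(lnc_ids) < n_plant || length(mrna_ids) < n_plant) {
    stop("not enough lncRNAs or mRNAs for the requested plants")
  }
  pick_lnc <- sample(lnc_ids, n_plant)
  pick_mrna <- sample(mrna_ids, n_plant)
  types <- c(rep("planted", config$n_true_edges),
             rep("decoy_outside", config$n_decoy_outside),
             rep("decoy_half", config$n_decoy_half))
  seqs <- as.character(sim$transcripts)
  seg_len <- config$segment_length
  hits <- list(); regions <- list(); edges <- list()
  for (k in seq_len(n_plant)) {
    lid <- pick_lnc[k]; mid <- pick_mrna[k]
    L <- nchar(seqs[[lid]])
    if (L < seg_len + 120L) stop("lncRNA too short to host a plant: ", lid)
    placed <- FALSE
    for (try in 1:100) {
      segment <- random_seq(seg_len, c(A = 0.5, C = 0, G = 0, T = 0.5))
      p <- sample(seq(10L, L - seg_len - 10L), 1L)
      cand <- paste0(substr(seqs[[lid]], 1L, p),
                     segment,
                     substr(seqs[[lid]], p + seg_len + 1L, L))
      if (unname(longest_orf_aa(setNames(cand, "x"))) > 75L) next
      if (types[k] == "decoy_outside") {
        ## emitted region must stay >= 60 nt clear of the planted segment
        left_ok <- p >= 100L
        right_ok <- (L - (p + seg_len)) >= 100L
        if (!left_ok && !right_ok) next
        if (left_ok) { rs <- 0L; re <- min(40L, p - 60L) }
        else { rs <- p + seg_len + 60L; re <- min(L, rs + 40L) }
        if (re - rs < 20L) next
      } else {
        rs <- p; re <- p + seg_len
      }
      seqs[[lid]] <- cand
      placed <- TRUE
      break
    }
    if (!placed) stop("could not place interaction plant on ", lid)
    ## reference-database hit covering [rs, re) (1-based inclusive in hits)
    hits[[k]] <- data.frame(
      qseqid = lid, sseqid = sprintf("NONC%06d", k),
      pident = 95, length = re - rs, mismatch = 1L, gapopen = 0L,
      qstart = rs + 1L, qend = re, sstart = 1L, send = re - rs,
      evalue = 1e-8, bitscore = 80, stringsAsFactors = FALSE)
    regions[[k]] <- data.frame(lncrna_id = lid, start = rs, end = re,
                               stringsAsFactors = FALSE)
    ## splice the (possibly truncated) reverse complement into the mRNA
    insert <- if (types[k] == "decoy_half") {
      substr(segment, 1L, seg_len %/% 2L)
    } else segment
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(insert)))
    M <- nchar(seqs[[mid]])
    mp <- sample(seq(max(2L, floor(0.7 * M)),
                     M - nchar(rc) - 1L), 1L)
    seqs[[mid]] <- paste0(substr(seqs[[mid]], 1L, mp), rc,
                          substr(seqs[[mid]], mp + nchar(rc) + 1L, M))
    edges[[k]] <- data.frame(
      lncrna_id = lid, mrna_id = mid, edge_type = types[k],
      lnc_seg_start = p, lnc_seg_end = p + seg_len,
      mrna_seg_start = mp, mrna_seg_end = mp + nchar(rc),
      stringsAsFactors = FALSE)
  }
  sim$transcripts <- Biostrings::DNAStringSet(seqs)
  sim$manifest$length <- Biostrings::width(sim$transcripts)[
    match(sim$manifest$transcript_id, names(sim$transcripts))]
  sim$lncref_hits <- do.call(rbind, hits)
  sim$regions_truth <- do.call(rbind, regions)
  sim$truth_edges <- do.call(rbind, edges)
  sim
}

#' Emit synthetic evidence tables for a simulated transcriptome
#'
#' Noiseless mode (`noise_rate = 0`): contaminant copies receive symbiont
#' hits satisfying the 50%/50% coverage + e-value rule, mRNA-like
#' transcripts receive protein hits at e <= 1e-6 (a subset also domain
#' hits and signal-peptide calls), housekeeping copies receive
#' housekeeping-database hits, and true lncRNAs receive nothing. With
#' `noise_rate > 0` a seeded fraction of labels is flipped (lncRNAs gain
#' a spurious protein hit; mRNAs lose their evidence) and recorded.
#'
#' @param sim Output of [simulate_transcriptome()] (after optional
#'   [plant_interactions()]).
#' @param config The [sim_config()].
#' @param noise_rate Label-flip probability (default 0).
#' @return `sim` augmented with `evidence_tables` (list: `symbiont_hits`,
#'   `protein_hits`, `domain_hits`, `signal_calls`, `housekeeping_hits`,
#'   `subject_lengths`) and `noise_flipped` (character vector).
#' @export
emit_evidence_tables <- function(sim, config, noise_rate = 0) {
  set.seed(config$seed + 2L)
  man <- sim$manifest
  widths <- setNames(Biostrings::width(sim$transcripts),
                     names(sim$transcripts))
  symb_ref <- shipped_reference("symbiont")
  symb_len <- setNames(Biostrings::width(symb_ref), names(symb_ref))

  flips <- character(0)
  if (noise_rate > 0) {
    flippable <- man$transcript_id[man$sim_class %in% c("lncrna", "mrna")]
    flips <- flippable[runif(length(flippable)) < noise_rate]
  }

  hit_row <- function(q, s, alen, ev) {
    data.frame(qseqid = q, sseqid = s, pident = 98, length = alen,
               mismatch = 1L, gapopen = 0L, qstart = 1L, qend = alen,
               sstart = 1L, send = alen, evalue = ev, bitscore = 200,
               stringsAsFactors = FALSE)
  }

  symb_ids <- man$transcript_id[man$sim_class == "symbiont"]
  symbiont_hits <- do.call(rbind, c(list(empty_hit_table()),
    lapply(symb_ids, function(id) {
      ref <- names(symb_len)[which.min(abs(symb_len - widths[[id]]))]
      alen <- ceiling(0.9 * min(widths[[id]], symb_len[[ref]]))
      hit_row(id, ref, alen, 1e-30)
    })))

  mrna_ids <- setdiff(man$transcript_id[man$sim_class == "mrna"], flips)
  lnc_flips <- intersect(flips,
                         man$transcript_id[man$sim_class == "lncrna"])
  protein_targets <- c(mrna_ids, lnc_flips)
  protein_hits <- do.call(rbind, c(list(empty_hit_table()),
    lapply(protein_targets, function(id) {
      hit_row(id, sprintf("SP|%s", toupper(substr(id, 1L, 8L))),
              max(30L, floor(widths[[id]] / 4)),
              10^(-runif(1L, 6, 30)))
    })))

  with_domain <- mrna_ids[runif(length(mrna_ids)) < 0.5]
  domain_hits <- do.call(rbind, c(list(empty_hit_table()),
    lapply(with_domain, function(id) {
      hit_row(id, sprintf("PF%05d", sample(20000L, 1L)), 60L,
              10^(-runif(1L, 4, 20)))
    })))

  with_signal <- mrna_ids[runif(length(mrna_ids)) < 0.2]
  signal_calls <- setNames(man$transcript_id %in% with_signal,
                           man$transcript_id)

  hk_ids <- man$transcript_id[man$sim_class == "housekeeping"]
  housekeeping_hits <- do.call(rbind, c(list(empty_hit_table()),
    lapply(hk_ids, function(id) {
      hit_row(id, sprintf("RF%05d", sample(3000L, 1L)),
              max(50L, floor(widths[[id]] * 0.8)), 1e-12)
    })))

  sim$evidence_tables <- list(symbiont_hits = symbiont_hits,
                              protein_hits = protein_hits,
                              domain_hits = domain_hits,
                              signal_calls = signal_calls,
                              housekeeping_hits = housekeeping_hits,
                              subject_lengths = symb_len)
  sim$noise_flipped <- sort(flips)
  sim
}

#' Simulate two-condition counts for a simulated transcriptome
#'
#' Negative-binomial counts for a `healthy` and a `bleaching` library.
#' A seeded fraction of mRNAs and lncRNAs is planted as differentially
#' expressed at the configured fold (half up in bleaching, half down);
#' planted low-expression transcripts get a tiny mean in both conditions;
#' everything else is null (equal means). Dispersion 0 degenerates to
#' Poisson.
#'
#' @param sim Simulation state.
#' @param config The [sim_config()].
#' @return `sim` augmented with `counts` (a [counts_table()]) and
#'   manifest columns `mu_healthy`, `mu_bleaching`, `de_truth`
#'   (`up`/`down`/`ns`, direction = bleaching vs healthy).
#' @export
simulate_counts <- function(sim, config) {
  set.seed(config$seed + 3L)
  man <- sim$manifest
  n <- nrow(man)
  mu <- 10^runif(n, log10(config$nb_mean_range[1L]),
                 log10(config$nb_mean_range[2L]))
  low <- man$sim_class == "low_expression"
  mu[low] <- config$low_expression_mean
  de_eligible <- which(man$sim_class %in% c("mrna", "lncrna"))
  n_de <- round(config$de_fraction * length(de_eligible))
  de_idx <- sample(de_eligible, n_de)
  up_idx <- de_idx[seq_len(n_de %/% 2L)]
  dn_idx <- setdiff(de_idx, up_idx)
  mu1 <- mu; mu2 <- mu
  mu2[up_idx] <- mu[up_idx] * config$de_fold
  mu2[dn_idx] <- mu[dn_idx] / config$de_fold
  draw <- function(m) {
    if (config$nb_dispersion <= 0) rpois_int(m) else
      rnbinom(length(m), mu = m, size = 1 / config$nb_dispersion)
  }
  cm <- cbind(healthy = draw(mu1), bleaching = draw(mu2))
  rownames(cm) <- man$transcript_id
  sim$counts <- counts_table(cm, totals = colSums(cm))
  man$mu_healthy <- mu1
  man$mu_bleaching <- mu2
  man$de_truth <- "ns"
  man$de_truth[up_idx] <- "up"
  man$de_truth[dn_idx] <- "down"
  sim$manifest <- man
  sim
}

rpois_int <- function(mu) stats::rpois(length(mu), mu)

## First failing cascade predicate -> expected final class, computed from
## generator-side knowledge (evidence is read off the planted labels, the
## ORF/kmer predicates from the sequence primitives).
finalize_truth <- function(sim, config) {
  man <- sim$manifest
  ids <- man$transcript_id
  flips <- sim$noise_flipped
  widths <- setNames(Biostrings::width(sim$transcripts),
                     names(sim$transcripts))[ids]
  orf <- longest_orf_aa(sim$transcripts)[ids]
  score <- kmer_coding_score(sim$transcripts, sim$kmer_model)[ids]
  totals <- rowSums(sim$counts$counts)[ids]
  flip_lnc <- man$sim_class == "lncrna" & ids %in% flips
  flip_mrna <- man$sim_class == "mrna" & ids %in% flips
  pred <- cbind(
    is_symbiont = man$sim_class == "symbiont",
    has_coding_evidence = (man$sim_class == "mrna" & !flip_mrna) | flip_lnc,
    too_short = widths < 300L,
    orf_too_long = orf > 75L,
    is_housekeeping = man$sim_class == "housekeeping",
    low_expression = totals < 10,
    kmer_coding = score > 0)
  first <- apply(pred, 1L, function(x) {
    w <- which(x)
    if (length(w) == 0L) 0L else w[1L]
  })
  man$kmer_score <- unname(score)
  man$total_counts <- unname(totals)
  man$expected_class <- ifelse(first == 0L, "lncRNA",
                               CASCADE$class[pmax(first, 1L)])
  sim$manifest <- man
  sim
}

## A small pathway annotation over the mRNA ids, with the first pathway
## deliberately enriched in DE-planted mRNAs.
make_pathway_annotation <- function(sim, config) {
  set.seed(config$seed + 4L)
  man <- sim$manifest
  mrna <- man$transcript_id[man$sim_class == "mrna"]
  de_mrna <- man$transcript_id[man$sim_class == "mrna" &
                                 man$de_truth != "ns"]
  n_path <- 10L
  genes <- vector("list", n_path)
  n_enr <- min(length(de_mrna), 8L)
  genes[[1L]] <- unique(c(sample(de_mrna, n_enr),
                          sample(mrna, min(4L, length(mrna)))))
  for (i in 2:n_path) {
    sz <- sample(seq(min(8L, length(mrna)), min(25L, length(mrna))), 1L)
    genes[[i]] <- sample(mrna, sz)
  }
  data.frame(pathway_id = sprintf("map%05d", seq_len(n_path) * 10L),
             name = c("Planted enriched pathway",
                      sprintf("Background pathway %d", 2:n_path)),
             genes = I(genes), stringsAsFactors = FALSE)
}

#' Build the complete seeded fixture
#'
#' Runs every generator stage in order: transcriptome, interaction
#' plants, k-mer model training (mRNA vs lncRNA classes), evidence
#' tables, counts, pathway annotation, and ground-truth finalization.
#' The manifest's `expected_class` gives, per transcript, the cascade
#' class it must receive; in the noiseless fixture the `expected_class ==
#' "lncRNA"` set is exactly the set [classify_transcripts()] must return.
#'
#' @param config A [sim_config()].
#' @param noise_rate Evidence label-flip rate (default 0).
#' @return List of class `lnc_fixture` with `config`, `transcripts`,
#'   `manifest`, `kmer_model`, `evidence_tables`, `counts`,
#'   `lncref_hits`, `regions_truth`, `truth_edges`, `pathways`,
#'   `noise_flipped`.
#' @export
simulate_fixture <- function(config = sim_config(), noise_rate = 0) {
  sim <- simulate_transcriptome(config)
  sim <- plant_interactions(sim, config)
  man <- sim$manifest
  coding_ids <- man$transcript_id[man$sim_class == "mrna"]
  nonc_ids <- man$transcript_id[man$sim_class %in%
                                  c("lncrna", "low_expression")]
  sim$kmer_model <- train_kmer_model(sim$transcripts[coding_ids],
                                     sim$transcripts[nonc_ids])
  sim <- emit_evidence_tables(sim, config, noise_rate)
  sim <- simulate_counts(sim, config)
  sim$pathways <- make_pathway_annotation(sim, config)
  sim <- finalize_truth(sim, config)
  sim$config <- config
  class(sim) <- "lnc_fixture"
  sim
}

#' Write a fixture to a directory of plain-text files
#'
#' Emits every artifact the pipeline stages consume: combined FASTA,
#' candidate-mRNA FASTA, the five evidence tables, counts TSV, k-mer
#' model, reference-lncRNA hit table, pathway annotation, truth manifest
#' (TSV + JSON), truth edges, and planted-region BED.
#'
#' @param fixture From [simulate_fixture()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_fasta(fixture$transcripts, p("transcripts.fasta"))
  man <- fixture$manifest
  ## candidate mRNAs for the interaction stage: the planted targets when
  ## plants exist (fixture-scale search set), otherwise every mRNA
  mrna_ids <- if (NROW(fixture$truth_edges) > 0L) {
    sort(unique(fixture$truth_edges$mrna_id))
  } else {
    man$transcript_id[man$sim_class == "mrna"]
  }
  write_fasta(fixture$transcripts[mrna_ids], p("candidate_mrnas.fasta"))
  ev <- fixture$evidence_tables
  write_hit_table(ev$symbiont_hits, p("symbiont_hits.tsv"))
  write_hit_table(ev$protein_hits, p("protein_hits.tsv"))
  write_hit_table(ev$domain_hits, p("domain_hits.tsv"))
  write_hit_table(ev$housekeeping_hits, p("housekeeping_hits.tsv"))
  write.table(data.frame(names(ev$signal_calls),
                         ifelse(ev$signal_calls, "Y", "N")),
              p("signalp.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(data.frame(id = names(ev$subject_lengths),
                         length = ev$subject_lengths),
              p("symbiont_subject_lengths.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_counts_table(fixture$counts, p("counts.tsv"))
  write_kmer_model(fixture$kmer_model, p("kmer_model.tsv"))
  write_hit_table(fixture$lncref_hits, p("lncref_hits.tsv"))
  write_pathway_annotation(fixture$pathways, p("pathways.tsv"))
  write.table(fixture$manifest, p("manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(fixture$manifest, p("manifest.json"),
                       dataframe = "rows", digits = NA)
  write.table(fixture$truth_edges, p("truth_edges.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (nrow(fixture$regions_truth) > 0L) {
    bed <- data.frame(fixture$regions_truth$lncrna_id,
                      fixture$regions_truth$start,
                      fixture$regions_truth$end)
    write.table(bed, p("planted_regions.bed"), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' Read a fixture manifest back
#'
#' @param path `manifest.tsv` as written by [write_fixture()].
#' @return data.frame.
#' @export
read_manifest <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
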