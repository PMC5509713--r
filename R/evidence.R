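## Column names of the 12-column BLAST tabular layout ("outfmt 6").
HIT_COLUMNS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")

empty_hit_table <- function() {
  data.frame(qseqid = character(), sseqid = character(),
             pident = numeric(), length = integer(), mismatch = integer(),
             gapopen = integer(), qstart = integer(), qend = integer(),
             sstart = integer(), send = integer(), evalue = numeric(),
             bitscore = numeric(), stringsAsFactors = FALSE)
}

#' Parse a 12-column BLAST tabular hit file
#'
#' Reads the classical tab-separated, header-less "outfmt 6" layout:
#' query id, subject id, percent identity, alignment length, mismatches,
#' gap opens, query start/end (1-based inclusive), subject start/end
#' (start > end flags a minus-strand subject), e-value, bit score.
#'
#' @param path Path to the hit table.
#' @return A data.frame with columns [HIT_COLUMNS], one row per line, in
#'   file order; an empty file yields a 0-row table.
#' @details A line with a column count other than 12, or an unparseable
#'   numeric field, raises an error naming the line number. Basic record
#'   invariants (`qstart <= qend`, `length >= 1`, `evalue >= 0`) are also
#'   checked.
#' @export
parse_hit_table <- function(path) {
  if (!file.exists(path)) stop("hit table not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_hit_table())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 12L)) {
    i <- which(nf != 12L)[1L]
    stop(sprintf("line %d has %d columns (12 expected)", i, nf[i]))
  }
  m <- matrix(unlist(parts), ncol = 12L, byrow = TRUE)
  num <- function(col, as_int = FALSE) {
    v <- suppressWarnings(as.numeric(m[, col]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1L]
      stop(sprintf("line %d: cannot parse '%s' in column %d (%s)",
                   i, m[i, col], col, HIT_COLUMNS[col]))
    }
    if (as_int) as.integer(v) else v
  }
  hits <- data.frame(
    qseqid = m[, 1L], sseqid = m[, 2L],
    pident = num(3L), length = num(4L, TRUE), mismatch = num(5L, TRUE),
    gapopen = num(6L, TRUE), qstart = num(7L, TRUE), qend = num(8L, TRUE),
    sstart = num(9L, TRUE), send = num(10L, TRUE),
    evalue = num(11L), bitscore = num(12L), stringsAsFactors = FALSE)
  bad <- which(hits$qstart > hits$qend | hits$length < 1L | hits$evalue < 0)
  if (length(bad) > 0L) {
    stop(sprintf("line %d violates hit-record invariants", bad[1L]))
  }
  hits
}

#' Write hits in 12-column BLAST tabular layout
#'
#' @param hits A hit data.frame as returned by [parse_hit_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_hit_table <- function(hits, path) {
  stopifnot(all(HIT_COLUMNS %in% names(hits)))
  h <- hits[, HIT_COLUMNS]
  h$evalue <- formatC(h$evalue, format = "g", digits = 6)
  write.table(h, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Flag transcripts as endosymbiont contaminants
#'
#' A transcript counts as a symbiont contaminant when some hit against the
#' symbiont reference covers more than 50% of the query length and more
#' than 50% of the subject length (conjunctive by default; see `rule`)
#' with e-value below `e_cutoff`.
#'
#' @param hits Hit table (queries are transcripts, subjects symbiont
#'   reference sequences).
#' @param query_lengths,subject_lengths Named numeric vectors of sequence
#'   lengths covering every id appearing in `hits`.
#' @param e_cutoff E-value upper bound, exclusive (default `1e-3`).
#' @param rule `"and"` (default: both coverage conditions must hold) or
#'   `"or"` -- the underlying sentence is ambiguous, so both readings are
#'   supported.
#' @return Character vector of contaminant transcript ids (unique, sorted).
#' @export
symbiont_contaminants <- function(hits, query_lengths, subject_lengths,
                                  e_cutoff = 1e-3,
                                  rule = c("and", "or")) {
  rule <- match.arg(rule)
  if (nrow(hits) == 0L) return(character())
  mq <- setdiff(unique(hits$qseqid), names(query_lengths))
  if (length(mq) > 0L) stop("missing query length for id: ", mq[1L])
  ms <- setdiff(unique(hits$sseqid), names(subject_lengths))
  if (length(ms) > 0L) stop("missing subject length for id: ", ms[1L])
  covq <- hits$length > 0.5 * query_lengths[hits$qseqid]
  covs <- hits$length > 0.5 * subject_lengths[hits$sseqid]
  cov <- if (rule == "and") covq & covs else covq | covs
  sort(unique(hits$qseqid[cov & hits$evalue < e_cutoff]))
}

#' Read a signal-peptide call table
#'
#' @param path Two-column TSV (`transcript_id`, `Y`/`N`), no header.
#' @return Named logical vector (`TRUE` = signal peptide predicted).
#' @export
read_signalp_calls <- function(path) {
  if (!file.exists(path)) stop("signal-peptide table not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(setNames(logical(), character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    stop("signal-peptide table must have exactly 2 columns")
  }
  ids <- vapply(parts, `[`, "", 1L)
  call <- toupper(vapply(parts, `[`, "", 2L))
  if (!all(call %in% c("Y", "N"))) {
    stop("signal-peptide calls must be Y or N")
  }
  setNames(call == "Y", ids)
}

#' Per-transcript protein-coding evidence flags
#'
#' Combines the three protein-level evidence tracks of the discovery
#' cascade: similarity to known proteins (BLASTx-style, thresholded at
#' `e_protein`), protein-domain hits (any hit counts by default), and
#' signal-peptide calls.
#'
#' @param transcript_ids Character vector: the transcript universe.
#' @param protein_hits,domain_hits Hit tables (possibly 0-row).
#' @param signal_calls Named logical vector from [read_signalp_calls()]
#'   (ids absent from it are taken as negative).
#' @param e_protein Inclusive e-value cutoff for the protein track
#'   (default `1e-4`).
#' @param e_domain Inclusive e-value cutoff for the domain track (default
#'   `Inf`: any reported hit counts).
#' @return data.frame with columns `transcript_id`, `protein_hit`,
#'   `protein_best_e`, `domain_hit`, `domain_best_e`, `signal_peptide`.
#' @export
coding_evidence_flags <- function(transcript_ids, protein_hits = NULL,
                                  domain_hits = NULL, signal_calls = NULL,
                                  e_protein = 1e-4, e_domain = Inf) {
  best_e <- function(hits, cutoff) {
    out <- setNames(rep(NA_real_, length(transcript_ids)), transcript_ids)
    if (!is.null(hits) && nrow(hits) > 0L) {
      keep <- hits$evalue <= cutoff & hits$qseqid %in% transcript_ids
      if (any(keep)) {
        be <- tapply(hits$evalue[keep], hits$qseqid[keep], min)
        out[names(be)] <- as.numeric(be)
      }
    }
    out
  }
  pe <- best_e(protein_hits, e_protein)
  de <- best_e(domain_hits, e_domain)
  sig <- setNames(rep(FALSE, length(transcript_ids)), transcript_ids)
  if (!is.null(signal_calls)) {
    hit <- intersect(names(signal_calls)[signal_calls], transcript_ids)
    sig[hit] <- TRUE
  }
  data.frame(transcript_id = transcript_ids,
             protein_hit = !is.na(pe), protein_best_e = unname(pe),
             domain_hit = !is.na(de), domain_best_e = unname(de),
             signal_peptide = unname(sig), stringsAsFactors = FALSE)
}

#' Assemble the per-transcript evidence bundle
#'
#' Aggregates all evidence tracks of the discovery cascade into one table:
#' symbiont contamination, protein/domain/signal coding evidence,
#' housekeeping-RNA hits, and (optionally) an external coding/noncoding
#' label table.
#'
#' @param transcript_ids Transcript universe.
#' @param symbiont_ids Ids flagged by [symbiont_contaminants()].
#' @param protein_hits,domain_hits,housekeeping_hits Hit tables (`NULL` for
#'   none).
#' @param signal_calls Named logical vector, or `NULL`.
#' @param plek_labels Optional named logical vector from
#'   [read_plek_labels()] (`TRUE` = called coding).
#' @param e_protein,e_domain,e_housekeeping Track e-value cutoffs
#'   (inclusive); housekeeping and domain default to accepting any hit.
#' @return data.frame of class `evidence_bundle`, one row per transcript.
#'   Evidence naming ids outside the universe is dropped with a warning.
#' @export
build_evidence_bundle <- function(transcript_ids, symbiont_ids = character(),
                                  protein_hits = NULL, domain_hits = NULL,
                                  signal_calls = NULL,
                                  housekeeping_hits = NULL,
                                  plek_labels = NULL,
                                  e_protein = 1e-4, e_domain = Inf,
                                  e_housekeeping = Inf) {
  unknown <- setdiff(symbiont_ids, transcript_ids)
  if (length(unknown) > 0L) {
    warning("dropping evidence for unknown transcript id(s): ",
            paste(head(unknown, 3L), collapse = ", "))
    symbiont_ids <- intersect(symbiont_ids, transcript_ids)
  }
  flags <- coding_evidence_flags(transcript_ids, protein_hits, domain_hits,
                                 signal_calls, e_protein, e_domain)
  hk <- setNames(rep(NA_real_, length(transcript_ids)), transcript_ids)
  if (!is.null(housekeeping_hits) && nrow(housekeeping_hits) > 0L) {
    keep <- housekeeping_hits$evalue <= e_housekeeping
    kh <- housekeeping_hits[keep, ]
    unknown <- setdiff(unique(kh$qseqid), transcript_ids)
    if (length(unknown) > 0L) {
      warning("dropping housekeeping evidence for unknown id(s): ",
              paste(head(unknown, 3L), collapse = ", "))
      kh <- kh[kh$qseqid %in% transcript_ids, ]
    }
    if (nrow(kh) > 0L) {
      be <- tapply(kh$evalue, kh$qseqid, min)
      hk[names(be)] <- as.numeric(be)
    }
  }
  plek <- setNames(rep(NA, length(transcript_ids)), transcript_ids)
  if (!is.null(plek_labels)) {
    common <- intersect(names(plek_labels), transcript_ids)
    plek[common] <- plek_labels[common]
  }
  out <- data.frame(
    transcript_id = transcript_ids,
    symbiont_hit = transcript_ids %in% symbiont_ids,
    protein_hit = flags$protein_hit,
    protein_best_e = flags$protein_best_e,
    domain_hit = flags$domain_hit,
    domain_best_e = flags$domain_best_e,
    signal_peptide = flags$signal_peptide,
    housekeeping_hit = !is.na(hk),
    housekeeping_best_e = unname(hk),
    plek_coding = unname(plek),
    stringsAsFactors = FALSE)
  class(out) <- c("evidence_bundle", "data.frame")
  out
}

#' Fixture-grade local alignment
#'
#' A plain affine-gap Smith-Waterman aligner used to build test fixtures
#' without an external search tool. The e-value is a documented heuristic
#' (`e = m * n * 2^-bit`, `bit = score / 2`) -- adequate for thresholding
#' toy fixtures, not a substitute for real search statistics.
#'
#' @param query,subject Sequences (single named or unnamed strings, or
#'   length-1 `DNAStringSet`s).
#' @param match,mismatch,gap_open,gap_extend Scoring parameters; a gap of
#'   length L costs `gap_open + L * gap_extend`.
#' @return A hit table with 0 rows (best score <= 0) or 1 row (the best
#'   local alignment, in [HIT_COLUMNS] layout).
#' @export
builtin_local_align <- function(query, subject, match = 2, mismatch = -3,
                                gap_open = -5, gap_extend = -2) {
  ids <- c(query = "query", subject = "subject")
  if (!is.null(names(query))) ids["query"] <- names(query)[1L]
  if (!is.null(names(subject))) ids["subject"] <- names(subject)[1L]
  q <- strsplit(toupper(as.character(query)[1L]), "")[[1L]]
  s <- strsplit(toupper(as.character(subject)[1L]), "")[[1L]]
  n <- length(q); m <- length(s)
  if (n == 0L || m == 0L) stop("sequences must be non-empty")
  NEG <- -1e9
  M <- matrix(NEG, n + 1L, m + 1L)   # best ending in a match/mismatch
  Ix <- matrix(NEG, n + 1L, m + 1L)  # gap in subject (consumes query)
  Iy <- matrix(NEG, n + 1L, m + 1L)  # gap in query (consumes subject)
  ## backpointers: 0 = local restart, 1 = from M, 2 = from Ix, 3 = from Iy
  bM <- matrix(0L, n + 1L, m + 1L)
  bX <- matrix(0L, n + 1L, m + 1L)
  bY <- matrix(0L, n + 1L, m + 1L)
  bestscore <- 0; besti <- 0L; bestj <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sub <- if (q[i] == s[j]) match else mismatch
      cand <- c(0, M[i, j], Ix[i, j], Iy[i, j])
      w <- which.max(cand)
      M[i + 1L, j + 1L] <- cand[w] + sub
      bM[i + 1L, j + 1L] <- w - 1L
      co <- M[i, j + 1L] + gap_open + gap_extend
      ce <- Ix[i, j + 1L] + gap_extend
      if (co >= ce) { Ix[i + 1L, j + 1L] <- co; bX[i + 1L, j + 1L] <- 1L }
      else          { Ix[i + 1L, j + 1L] <- ce; bX[i + 1L, j + 1L] <- 2L }
      co <- M[i + 1L, j] + gap_open + gap_extend
      ce <- Iy[i + 1L, j] + gap_extend
      if (co >= ce) { Iy[i + 1L, j + 1L] <- co; bY[i + 1L, j + 1L] <- 1L }
      else          { Iy[i + 1L, j + 1L] <- ce; bY[i + 1L, j + 1L] <- 3L }
      if (M[i + 1L, j + 1L] > bestscore) {
        bestscore <- M[i + 1L, j + 1L]; besti <- i; bestj <- j
      }
    }
  }
  if (bestscore <= 0) return(empty_hit_table())
  ## traceback from (besti, bestj), state M
  i <- besti; j <- bestj; state <- 1L
  nid <- 0L; alen <- 0L; mism <- 0L; gap_opens <- 0L
  qe <- besti; se <- bestj
  repeat {
    if (state == 1L) {
      alen <- alen + 1L
      if (q[i] == s[j]) nid <- nid + 1L else mism <- mism + 1L
      nxt <- bM[i + 1L, j + 1L]
      i <- i - 1L; j <- j - 1L
      if (nxt == 0L) break
      state <- nxt
    } else if (state == 2L) {
      alen <- alen + 1L
      nxt <- bX[i + 1L, j + 1L]
      if (nxt == 1L) gap_opens <- gap_opens + 1L
      i <- i - 1L
      state <- nxt
    } else {
      alen <- alen + 1L
      nxt <- bY[i + 1L, j + 1L]
      if (nxt == 1L) gap_opens <- gap_opens + 1L
      j <- j - 1L
      state <- nxt
    }
  }
  qs <- i + 1L; ss <- j + 1L
  bit <- bestscore / 2
  ev <- n * m * 2^(-bit)
  data.frame(qseqid = ids[["query"]], sseqid = ids[["subject"]],
             pident = 100 * nid / alen, length = alen, mismatch = mism,
             gapopen = gap_opens, qstart = qs, qend = qe,
             sstart = ss, send = se, evalue = ev, bitscore = bit,
             stringsAsFactors = FALSE)
}
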