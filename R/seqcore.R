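#' Read transcripts from a FASTA file
#'
#' Reads a (possibly multi-record) FASTA file into a
#' [Biostrings::DNAStringSet]. Sequences are uppercased and `U` is mapped to
#' `T`, so RNA and DNA FASTA are both accepted. Record ids are the first
#' whitespace-delimited token of each header line.
#'
#' @param path Path to a FASTA text file.
#' @return A [Biostrings::DNAStringSet] named by transcript id, in file
#'   order. An empty file yields an empty set.
#' @details Errors are raised for duplicate ids (naming the id), for empty
#'   sequence records, and for characters outside `ACGTN` after
#'   normalization (reporting the record and position of the first
#'   offender).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) return(Biostrings::DNAStringSet())
  ids <- sub("\\s.*$", "", names(raw))
  if (any(ids == "")) stop("FASTA record with empty id")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate transcript id in FASTA: ", dup[1L])
  }
  seqs <- toupper(as.character(raw))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  empty <- which(nchar(seqs) == 0L)
  if (length(empty) > 0L) {
    stop("empty sequence for record: ", ids[empty[1L]])
  }
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("non-IUPAC character '%s' in record %s at position %d",
                 substr(seqs[i], bad[i], bad[i]), ids[i], bad[i]))
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write transcripts to a FASTA file
#'
#' @param transcripts A named [Biostrings::DNAStringSet] or named character
#'   vector of sequences.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(transcripts, path) {
  transcripts <- as_transcripts(transcripts)
  Biostrings::writeXStringSet(transcripts, path, width = 70L)
  invisible(path)
}

## Coerce user input (named character vector or DNAStringSet) to a
## validated DNAStringSet over ACGTN with unique non-empty ids.
as_transcripts <- function(x) {
  if (is.character(x)) {
    if (is.null(names(x)) || any(names(x) == "")) {
      stop("transcripts given as a character vector must be uniquely named")
    }
    x <- Biostrings::DNAStringSet(gsub("U", "T", toupper(x), fixed = TRUE))
  }
  if (!methods::is(x, "DNAStringSet")) {
    stop("transcripts must be a DNAStringSet or a named character vector")
  }
  if (length(x) > 0L && (is.null(names(x)) || anyDuplicated(names(x)))) {
    stop("transcript ids must be present and unique")
  }
  x
}

## Translate a vector of codon strings with the standard code; codons
## containing N become "X" (never a stop).
translate_codons <- function(codons) {
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  unname(aa)
}

#' Find stop-to-stop open reading frames
#'
#' Enumerates, for each requested strand and each frame offset 0..2, the
#' maximal runs of codons uninterrupted by a stop codon -- including the
#' runs bounded by the sequence ends. No start codon is required (the
#' stop-to-stop definition used for coding-potential screening of lncRNA
#' candidates). Trailing partial codons are ignored and coordinates are
#' always reported on the forward strand as 0-based half-open intervals.
#'
#' @param transcripts A named [Biostrings::DNAStringSet] or named character
#'   vector (a single unnamed string is also accepted and given id `"t1"`).
#' @param strands Character subset of `c("+", "-")`.
#' @return A data.frame with columns `transcript_id`, `strand`, `frame`,
#'   `start`, `end`, `aa_length`, `peptide`. Sequences shorter than 3 nt
#'   contribute no rows.
#' @details Codons containing `N` translate to `X` and never count as stop
#'   codons. Zero-length runs (two adjacent stops) are not reported.
#' @export
find_orfs <- function(transcripts, strands = c("+", "-")) {
  if (is.character(transcripts) && length(transcripts) == 1L &&
      is.null(names(transcripts))) {
    names(transcripts) <- "t1"
  }
  transcripts <- as_transcripts(transcripts)
  if (length(strands) == 0L || !all(strands %in% c("+", "-"))) {
    stop("strands must be a non-empty subset of c('+', '-')")
  }
  strands <- unique(strands)
  rows <- vector("list", length(transcripts))
  for (t in seq_along(transcripts)) {
    id <- names(transcripts)[t]
    fwd <- as.character(transcripts[[t]])
    L <- nchar(fwd)
    acc <- list()
    for (st in strands) {
      s <- if (st == "+") fwd else
        as.character(Biostrings::reverseComplement(transcripts[[t]]))
      for (f in 0:2) {
        n_codon <- (L - f) %/% 3L
        if (n_codon < 1L) next
        starts <- f + 3L * (seq_len(n_codon) - 1L) + 1L
        codons <- substring(s, starts, starts + 2L)
        aa <- translate_codons(codons)
        is_stop <- aa == "*"
        ## run starts/ends over non-stop codons
        r <- rle(is_stop)
        ends_c <- cumsum(r$lengths)
        starts_c <- ends_c - r$lengths + 1L
        keep <- which(!r$values)
        for (k in keep) {
          c1 <- starts_c[k]; c2 <- ends_c[k]
          s0 <- f + 3L * (c1 - 1L)        # on-strand 0-based start
          e0 <- f + 3L * c2               # on-strand 0-based end
          if (st == "+") { a <- s0; b <- e0 } else { a <- L - e0; b <- L - s0 }
          acc[[length(acc) + 1L]] <- list(
            transcript_id = id, strand = st, frame = f,
            start = a, end = b, aa_length = c2 - c1 + 1L,
            peptide = paste(aa[c1:c2], collapse = ""))
        }
      }
    }
    rows[[t]] <- acc
  }
  acc <- unlist(rows, recursive = FALSE)
  if (length(acc) == 0L) {
    return(data.frame(transcript_id = character(), strand = character(),
                      frame = integer(), start = integer(), end = integer(),
                      aa_length = integer(), peptide = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    transcript_id = vapply(acc, `[[`, "", "transcript_id"),
    strand = vapply(acc, `[[`, "", "strand"),
    frame = vapply(acc, `[[`, 0L, "frame"),
    start = vapply(acc, `[[`, 0L, "start"),
    end = vapply(acc, `[[`, 0L, "end"),
    aa_length = vapply(acc, `[[`, 0L, "aa_length"),
    peptide = vapply(acc, `[[`, "", "peptide"),
    stringsAsFactors = FALSE)
}

#' Length of the longest stop-to-stop ORF, in amino acids
#'
#' @inheritParams find_orfs
#' @return Named integer vector (one entry per transcript): the maximum
#'   `aa_length` over [find_orfs()] output, or 0 when no codon fits.
#' @export
longest_orf_aa <- function(transcripts, strands = c("+", "-")) {
  if (is.character(transcripts) && length(transcripts) == 1L &&
      is.null(names(transcripts))) {
    names(transcripts) <- "t1"
  }
  transcripts <- as_transcripts(transcripts)
  orfs <- find_orfs(transcripts, strands)
  out <- setNames(integer(length(transcripts)), names(transcripts))
  if (nrow(orfs) > 0L) {
    mx <- tapply(orfs$aa_length, orfs$transcript_id, max)
    out[names(mx)] <- as.integer(mx)
  }
  out
}

all_kmers <- function(k_max) {
  unlist(lapply(seq_len(k_max), function(k) {
    mkAllStrings <- Biostrings::mkAllStrings
    mkAllStrings(c("A", "C", "G", "T"), k)
  }))
}

## Occurrence counts of every ACGT k-mer (k = 1..k_max) in a set;
## k-mers containing N are never counted.
kmer_counts <- function(transcripts, k_max) {
  transcripts <- as_transcripts(transcripts)
  unlist(lapply(seq_len(k_max), function(k) {
    m <- Biostrings::oligonucleotideFrequency(transcripts, width = k)
    if (is.null(dim(m))) m else colSums(m)
  }))
}

#' Train a k-mer log-odds coding-potential model
#'
#' A transparent stand-in for SVM-based lncRNA classifiers (PLEK-style):
#' for every k-mer w of size 1..`k_max`, the model stores the log-odds of w
#' under the coding versus the noncoding training set, with additive
#' smoothing.
#'
#' @param coding,noncoding Non-empty transcript sets (named
#'   [Biostrings::DNAStringSet] or named character vectors).
#' @param k_max Largest k-mer size (default 5, the classical PLEK range).
#' @param pseudocount Positive additive smoothing constant.
#' @return An object of class `kmer_model`: a list with `k_max`,
#'   `pseudocount`, and `log_odds` (named numeric over all k-mers).
#' @export
train_kmer_model <- function(coding, noncoding, k_max = 5L, pseudocount = 1) {
  if (k_max < 1L) stop("k_max must be >= 1")
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  coding <- as_transcripts(coding)
  noncoding <- as_transcripts(noncoding)
  if (length(coding) == 0L || length(noncoding) == 0L) {
    stop("both training sets must be non-empty")
  }
  cc <- kmer_counts(coding, k_max)
  nc <- kmer_counts(noncoding, k_max)
  kk <- nchar(names(cc))
  tot_c <- vapply(seq_len(k_max), function(k) sum(cc[kk == k]), 0)
  tot_n <- vapply(seq_len(k_max), function(k) sum(nc[kk == k]), 0)
  lo <- log((cc + pseudocount) / (tot_c[kk] + pseudocount * 4^kk)) -
        log((nc + pseudocount) / (tot_n[kk] + pseudocount * 4^kk))
  structure(list(k_max = as.integer(k_max), pseudocount = pseudocount,
                 log_odds = lo), class = "kmer_model")
}

#' Score transcripts with a k-mer coding-potential model
#'
#' The score is the occurrence-weighted mean of the model's log-odds over
#' every k-mer token (k = 1..`k_max`) present in the sequence; k-mers
#' containing `N` are skipped. Downstream, a transcript is treated as
#' noncoding when its score is at or below the configured threshold
#' (default 0).
#'
#' @param transcripts Transcript set (see [as_transcripts()]-compatible
#'   input of [find_orfs()]).
#' @param model A `kmer_model` from [train_kmer_model()].
#' @return Named numeric vector of scores. A sequence with no scorable
#'   k-mer (all `N`) scores 0.
#' @export
kmer_coding_score <- function(transcripts, model) {
  if (is.character(transcripts) && length(transcripts) == 1L &&
      is.null(names(transcripts))) {
    names(transcripts) <- "t1"
  }
  transcripts <- as_transcripts(transcripts)
  if (!inherits(model, "kmer_model")) stop("model must be a kmer_model")
  if (any(Biostrings::width(transcripts) < 1L)) {
    stop("transcripts must have length >= 1")
  }
  lo <- model$log_odds
  scores <- numeric(length(transcripts))
  ntok <- numeric(length(transcripts))
  for (k in seq_len(model$k_max)) {
    m <- Biostrings::oligonucleotideFrequency(transcripts, width = k)
    scores <- scores + as.numeric(m %*% lo[colnames(m)])
    ntok <- ntok + rowSums(m)
  }
  setNames(ifelse(ntok > 0, scores / ntok, 0), names(transcripts))
}

#' Write / read a k-mer model as TSV
#'
#' Two columns (`kmer`, `log_odds`) preceded by a header comment line
#' recording `k_max` and `pseudocount`.
#'
#' @param model A `kmer_model`.
#' @param path File path.
#' @return `write_kmer_model` returns `path` invisibly; `read_kmer_model`
#'   returns a `kmer_model`.
#' @export
write_kmer_model <- function(model, path) {
  stopifnot(inherits(model, "kmer_model"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#k_max=%d\tpseudocount=%.17g",
                     model$k_max, model$pseudocount), con)
  writeLines(sprintf("%s\t%.17g", names(model$log_odds), model$log_odds), con)
  invisible(path)
}

#' @rdname write_kmer_model
#' @export
read_kmer_model <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L || !startsWith(lines[1L], "#")) {
    stop("k-mer model file must start with a '#k_max=...' header line")
  }
  hdr <- sub("^#", "", lines[1L])
  kv <- strsplit(strsplit(hdr, "\t")[[1L]], "=")
  vals <- setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  lo <- setNames(as.numeric(vapply(body, `[`, "", 2L)),
                 vapply(body, `[`, "", 1L))
  structure(list(k_max = as.integer(vals[["k_max"]]),
                 pseudocount = as.numeric(vals[["pseudocount"]]),
                 log_odds = lo), class = "kmer_model")
}

#' Read a precomputed coding/noncoding label table (PLEK-style adapter)
#'
#' @param path Two-column TSV (`transcript_id`, label); labels `coding`/
#'   `noncoding` (or `C`/`N`, case-insensitive) are accepted.
#' @return Named logical vector: `TRUE` where the tool called the
#'   transcript coding.
#' @export
read_plek_labels <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("transcript_id", "label"),
                    colClasses = "character")
  lab <- tolower(tab$label)
  ok <- lab %in% c("coding", "noncoding", "c", "n")
  if (!all(ok)) stop("unrecognized PLEK label: ", tab$label[!ok][1L])
  setNames(lab %in% c("coding", "c"), tab$transcript_id)
}
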