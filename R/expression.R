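#' Fragments per kilobase of transcript per million mapped fragments
#'
#' `FPKM = count * 1e9 / (transcript_length_nt * total_mapped)`.
#'
#' @param count Raw fragment count(s), >= 0.
#' @param transcript_length_nt Transcript length(s) in nt, >= 1.
#' @param total_mapped Total mapped fragments in the library, >= 1.
#' @return Numeric FPKM value(s); linear in `count`, inversely
#'   proportional to length and library size.
#' @export
compute_fpkm <- function(count, transcript_length_nt, total_mapped) {
  if (any(transcript_length_nt < 1)) stop("transcript length must be >= 1")
  if (any(total_mapped < 1)) stop("total mapped fragments must be >= 1")
  if (any(count < 0)) stop("counts must be >= 0")
  count * 1e9 / (transcript_length_nt * total_mapped)
}

## log P(Y = k | x) for k = 0..kmax under the two-library Poisson
## (Audic-Claverie) model with library-size ratio r = total2/total1:
##   p(k|x) = r^k (x+k)! / (x! k! (1+r)^(x+k+1))
ac_log_pmf <- function(kmax, x, r) {
  k <- 0:kmax
  k * log(r) + lgamma(x + k + 1) - lgamma(x + 1) - lgamma(k + 1) -
    (x + k + 1) * log1p(r)
}

log_sum_exp <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}

#' Two-library count-significance test (Audic-Claverie)
#'
#' For a transcript observed `x` times in library 1 and `y` times in
#' library 2 (library sizes `total1`, `total2`), computes the two-sided
#' p-value `min(1, 2 * min(P(Y <= y | x), P(Y >= y | x)))` under the
#' conditional Poisson model with `r = total2 / total1`:
#' `p(k | x) = r^k (x+k)! / (x! k! (1+r)^(x+k+1))`.
#' This is the classical replicate-free test for comparing one count
#' between two sequencing libraries. Both tails are accumulated directly
#' in log space (the upper tail is truncated once the remaining mass is
#' negligible), so small p-values keep full relative precision.
#'
#' @param x,y Non-negative integer counts (vectorized, recycled).
#' @param total1,total2 Library sizes (total mapped fragments), >= 1.
#' @return p-value(s) in `[0, 1]`. Symmetric:
#'   `audic_claverie_p(x, y, t1, t2) == audic_claverie_p(y, x, t2, t1)`.
#' @export
audic_claverie_p <- function(x, y, total1, total2) {
  if (any(x < 0) || any(y < 0)) stop("counts must be >= 0")
  if (any(x != floor(x)) || any(y != floor(y))) stop("counts must be integers")
  if (any(total1 < 1) || any(total2 < 1)) stop("library totals must be >= 1")
  n <- max(length(x), length(y), length(total1), length(total2))
  x <- rep_len(x, n); y <- rep_len(y, n)
  total1 <- rep_len(total1, n); total2 <- rep_len(total2, n)
  vapply(seq_len(n), function(i) {
    r <- total2[i] / total1[i]
    xi <- x[i]; yi <- y[i]
    lower_lp <- ac_log_pmf(yi, xi, r)
    p_lower <- exp(log_sum_exp(lower_lp))
    ## upper tail summed outward from yi until terms are negligible
    ratio_limit <- r / (1 + r)
    lp <- lower_lp[yi + 1L]
    terms <- lp
    k <- yi
    repeat {
      k <- k + 1L
      lp <- lp + log(r) + log(xi + k) - log(k) - log1p(r)
      terms <- c(terms, lp)
      if (lp < max(terms) - 40 &&
          (xi + k + 1) / k * ratio_limit < 0.999) break
      if (k > yi + xi + 2000L + 50L * ceiling(sqrt(xi + yi + 1))) break
    }
    p_upper <- exp(log_sum_exp(terms))
    min(1, 2 * min(p_lower, p_upper))
  }, 0)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH adjusted p-values (monotone-enforced, input order
#' preserved). A thin validating wrapper over [stats::p.adjust()].
#'
#' @param p_values Numeric vector in `[0, 1]`.
#' @return Adjusted values in `[0, 1]`, same order as input.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric())
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Call differential expression between two libraries
#'
#' Computes FPKM for the two samples, a fold change
#' `log2fc = log2((fpkm2 + fc_pseudo) / (fpkm1 + fc_pseudo))`, the
#' Audic-Claverie two-library p-value on the raw counts, BH-adjusted q
#' over all tested transcripts, and a status call.
#'
#' Direction convention: `status == "up"` means higher expression in the
#' SECOND sample of `sample_pair` (e.g., up-regulated in bleaching when
#' the pair is `c(healthy, bleaching)`); `log2fc` is positive for "up".
#'
#' @param counts A `counts_table` (see [counts_table()]) or matrix with
#'   columns named by sample.
#' @param lengths Named numeric vector of transcript lengths (nt) covering
#'   all tested transcripts.
#' @param sample_pair Character length 2: (sample1, sample2).
#' @param fc_pseudo Pseudo-FPKM added to both terms of the ratio (default
#'   0.01) so zero-expression transcripts give finite fold changes.
#' @param fc_min Minimum `|log2fc|` for significance (default 1).
#' @param alpha FDR level (default 0.05).
#' @param use_q If `FALSE`, gate significance on the raw p-value instead
#'   of the BH-adjusted one.
#' @return data.frame of class `de_result` with columns `transcript_id`,
#'   `count1`, `count2`, `fpkm1`, `fpkm2`, `log2fc`, `p_raw`, `q_bh`,
#'   `status` (`up`/`down`/`ns`).
#' @export
call_differential <- function(counts, lengths, sample_pair,
                              fc_pseudo = 0.01, fc_min = 1, alpha = 0.05,
                              use_q = TRUE) {
  ct <- as_counts_table(counts)
  if (length(sample_pair) != 2L || !all(sample_pair %in% colnames(ct$counts))) {
    stop("sample_pair must name two samples present in the counts")
  }
  ids <- rownames(ct$counts)
  if (length(ids) == 0L) stop("empty transcript list")
  miss <- setdiff(ids, names(lengths))
  if (length(miss) > 0L) stop("missing transcript length for: ", miss[1L])
  x <- ct$counts[, sample_pair[1L]]
  y <- ct$counts[, sample_pair[2L]]
  t1 <- ct$totals[[sample_pair[1L]]]
  t2 <- ct$totals[[sample_pair[2L]]]
  len <- lengths[ids]
  fpkm1 <- compute_fpkm(x, len, t1)
  fpkm2 <- compute_fpkm(y, len, t2)
  log2fc <- log2((fpkm2 + fc_pseudo) / (fpkm1 + fc_pseudo))
  p <- audic_claverie_p(x, y, t1, t2)
  q <- bh_adjust(p)
  sig <- (if (use_q) q else p) < alpha & abs(log2fc) >= fc_min
  status <- ifelse(!sig, "ns", ifelse(log2fc > 0, "up", "down"))
  out <- data.frame(transcript_id = ids, count1 = unname(x),
                    count2 = unname(y), fpkm1 = unname(fpkm1),
                    fpkm2 = unname(fpkm2), log2fc = unname(log2fc),
                    p_raw = unname(p), q_bh = unname(q), status = status,
                    stringsAsFactors = FALSE)
  class(out) <- c("de_result", "data.frame")
  out
}

#' Construct a two-or-more-sample counts table
#'
#' @param counts Integer matrix, transcripts in rows (rownames = ids),
#'   samples in columns (colnames = sample ids).
#' @param totals Named numeric vector of per-sample total mapped
#'   fragments; defaults to the column sums (with a message), since the
#'   true mapping totals are ordinarily supplied by the mapper.
#' @return List of class `counts_table` with elements `counts`, `totals`.
#' @export
counts_table <- function(counts, totals = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts matrix must have transcript rownames and sample colnames")
  }
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers")
  }
  if (is.null(totals)) {
    message("counts_table: totals not supplied; using column sums")
    totals <- colSums(counts)
  }
  if (!all(colnames(counts) %in% names(totals))) {
    stop("totals must cover every sample column")
  }
  structure(list(counts = counts, totals = as.list(totals[colnames(counts)])),
            class = "counts_table")
}

as_counts_table <- function(x) {
  if (inherits(x, "counts_table")) return(x)
  counts_table(x)
}

#' Read / write a counts table TSV
#'
#' Layout: a comment line `#totals: <sample>=<total> ...`, then a header
#' (`transcript_id` plus sample columns) and one row per transcript.
#'
#' @param ct A `counts_table`.
#' @param path File path.
#' @return `write_counts_table` returns `path` invisibly;
#'   `read_counts_table` a `counts_table`.
#' @export
write_counts_table <- function(ct, path) {
  stopifnot(inherits(ct, "counts_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#totals: ",
                    paste(sprintf("%s=%.17g", names(ct$totals),
                                  unlist(ct$totals)), collapse = " ")), con)
  df <- data.frame(transcript_id = rownames(ct$counts), ct$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_table
#' @export
read_counts_table <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L || !startsWith(lines[1L], "#totals:")) {
    stop("counts table must start with a '#totals:' comment line")
  }
  kv <- strsplit(strsplit(sub("^#totals:\\s*", "", lines[1L]), " ")[[1L]], "=")
  totals <- setNames(as.numeric(vapply(kv, `[`, "", 2L)),
                     vapply(kv, `[`, "", 1L))
  tab <- read.table(text = lines[-1L], sep = "\t", header = TRUE,
                    check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab[[1L]]
  counts_table(m, totals)
}

#' Write differential-expression results as TSV
#'
#' The header comment records the direction convention.
#'
#' @param de A `de_result` from [call_differential()].
#' @param path Output path.
#' @param sample_pair Optional character(2) recorded in the header.
#' @return Invisibly, `path`.
#' @export
write_de_results <- function(de, path, sample_pair = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  note <- if (is.null(sample_pair)) {
    "#log2fc = log2(fpkm2/fpkm1 with pseudo); status 'up' = higher in sample2"
  } else {
    sprintf("#log2fc = log2(%s/%s with pseudo); status 'up' = higher in %s",
            sample_pair[2L], sample_pair[1L], sample_pair[2L])
  }
  writeLines(note, con)
  write.table(de, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
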