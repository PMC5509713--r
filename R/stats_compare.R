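#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |ECDF_a - ECDF_b|` with the asymptotic p-value from the
#' Kolmogorov distribution evaluated at `sqrt(ne) * D`, where
#' `ne = n1 * n2 / (n1 + n2)` is the effective sample size. Used to
#' compare transcript-length and expression distributions between mRNA
#' and lncRNA repertoires (which number in the thousands, where the
#' asymptotic p is accurate); an exact permutation option is provided for
#' small samples.
#'
#' @param a,b Non-empty numeric samples.
#' @param exact If `TRUE`, the p-value is instead estimated by `n_perm`
#'   seeded permutations of the pooled sample.
#' @param n_perm,perm_seed Permutation count and seed for `exact = TRUE`.
#' @return List of class `ks_outcome`: `d_statistic`, `p_value`, `n1`,
#'   `n2`. Symmetric in `a` and `b`; `D` is invariant under any strictly
#'   increasing transform applied to both samples.
#' @export
ks_two_sample <- function(a, b, exact = FALSE, n_perm = 2000L,
                          perm_seed = 1L) {
  if (length(a) == 0L || length(b) == 0L) stop("samples must be non-empty")
  if (anyNA(a) || anyNA(b)) stop("samples must not contain NA")
  d <- ks_d_statistic(a, b)
  n1 <- length(a); n2 <- length(b)
  ne <- n1 * n2 / (n1 + n2)
  if (exact) {
    pool <- c(a, b)
    set.seed(perm_seed)
    ge <- 0L
    for (i in seq_len(n_perm)) {
      idx <- sample.int(n1 + n2, n1)
      if (ks_d_statistic(pool[idx], pool[-idx]) >= d - 1e-12) ge <- ge + 1L
    }
    p <- (ge + 1L) / (n_perm + 1L)
  } else {
    p <- 1 - kolmogorov_cdf(sqrt(ne) * d)
  }
  structure(list(d_statistic = d, p_value = min(1, max(0, p)),
                 n1 = n1, n2 = n2), class = "ks_outcome")
}

## sup-norm distance between the two empirical CDFs, evaluated over the
## pooled jump points
ks_d_statistic <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  fa <- vapply(pts, function(t) mean(a <= t), 0)
  fb <- vapply(pts, function(t) mean(b <= t), 0)
  max(abs(fa - fb))
}

## Kolmogorov distribution CDF K(x) = 1 - 2 sum_{k>=1} (-1)^(k-1) e^{-2k^2x^2}
kolmogorov_cdf <- function(x) {
  if (x <= 0) return(0)
  k <- 1:100
  terms <- (-1)^(k - 1) * exp(-2 * k^2 * x^2)
  max(0, min(1, 1 - 2 * sum(terms)))
}

#' Shared lncRNAs between two species
#'
#' The strict cross-species similarity rule: a pair of lncRNAs (one per
#' species) is "shared" when some hit's aligned region is longer than half
#' the length of BOTH compared lncRNAs.
#'
#' @param hits_between_species Hit table with species-A lncRNAs as queries
#'   and species-B lncRNAs as subjects.
#' @param lengths_a,lengths_b Named numeric length vectors for the two
#'   species.
#' @return data.frame with columns `id_a`, `id_b` (unique pairs, sorted).
#' @export
shared_lncrnas <- function(hits_between_species, lengths_a, lengths_b) {
  h <- hits_between_species
  if (nrow(h) == 0L) {
    return(data.frame(id_a = character(), id_b = character(),
                      stringsAsFactors = FALSE))
  }
  ma <- setdiff(unique(h$qseqid), names(lengths_a))
  if (length(ma) > 0L) stop("missing length for id: ", ma[1L])
  mb <- setdiff(unique(h$sseqid), names(lengths_b))
  if (length(mb) > 0L) stop("missing length for id: ", mb[1L])
  keep <- h$length > 0.5 * lengths_a[h$qseqid] &
          h$length > 0.5 * lengths_b[h$sseqid]
  pairs <- unique(data.frame(id_a = h$qseqid[keep], id_b = h$sseqid[keep],
                             stringsAsFactors = FALSE))
  pairs <- pairs[order(pairs$id_a, pairs$id_b), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' mRNA-vs-lncRNA repertoire comparison report
#'
#' The standard companion analysis to lncRNA discovery: compares the
#' transcript-length and expression distributions of the mRNA and lncRNA
#' repertoires with two-sample KS tests (lengths on log10, expression on
#' log10(FPKM + 1), mirroring the usual presentation).
#'
#' @param mrna_lengths,lncrna_lengths Numeric length vectors (nt).
#' @param mrna_fpkm,lncrna_fpkm Optional FPKM vectors; the expression row
#'   is omitted when either is `NULL`.
#' @param label Free-text label for the species / repertoire pair.
#' @return data.frame with one row per compared metric: `label`,
#'   `metric`, `d_statistic`, `p_value`, `n_mrna`, `n_lncrna`.
#' @export
compare_repertoires <- function(mrna_lengths, lncrna_lengths,
                                mrna_fpkm = NULL, lncrna_fpkm = NULL,
                                label = "mRNA_vs_lncRNA") {
  row_of <- function(metric, a, b) {
    k <- ks_two_sample(a, b)
    data.frame(label = label, metric = metric,
               d_statistic = k$d_statistic, p_value = k$p_value,
               n_mrna = k$n1, n_lncrna = k$n2, stringsAsFactors = FALSE)
  }
  out <- row_of("log10_length", log10(mrna_lengths),
                log10(lncrna_lengths))
  if (!is.null(mrna_fpkm) && !is.null(lncrna_fpkm)) {
    out <- rbind(out, row_of("log10_fpkm_plus_1", log10(mrna_fpkm + 1),
                             log10(lncrna_fpkm + 1)))
  }
  out
}

#' @rdname compare_repertoires
#' @param report Output of [compare_repertoires()].
#' @param path Output TSV path.
#' @export
write_ks_report <- function(report, path) {
  write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
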