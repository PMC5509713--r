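#' Hypergeometric pathway-enrichment p-value
#'
#' Evaluates the enrichment statistic
#' \deqn{P = 1 - \sum_{i=0}^{m-1} \frac{\binom{M}{i}\binom{N-M}{n-i}}
#'   {\binom{N}{n}}}
#' where `N` is the number of genes in the annotated universe, `n` the
#' number of differentially expressed genes (DEGs) within it, `M` the
#' genes annotated to the pathway, and `m` the DEGs in the pathway. The
#' value equals the upper-tail hypergeometric probability `P(X >= m)` and
#' is computed as the upper-tail sum in log space, so tiny p-values retain
#' full relative precision (a literal `1 - sum` would lose it to
#' cancellation).
#'
#' @param N,n,M,m Integers with `0 <= m <= min(n, M)`, `n <= N`, `M <= N`.
#' @return The p-value in `[0, 1]`; `m = 0` gives exactly 1.
#' @export
enrichment_p <- function(N, n, M, m) {
  if (length(N) != 1L || length(n) != 1L || length(M) != 1L ||
      length(m) != 1L) stop("arguments must be scalars")
  if (m < 0 || n > N || M > N || m > min(n, M)) {
    stop("need 0 <= m <= min(n, M) <= N")
  }
  if (m == 0L) return(1)
  i <- m:min(n, M)
  lt <- lchoose(M, i) + lchoose(N - M, n - i) - lchoose(N, n)
  min(1, exp(log_sum_exp(lt)))
}

#' Bonferroni correction
#'
#' @param p_values Numeric vector in `[0, 1]`.
#' @return `min(1, p * k)` with `k = length(p_values)`.
#' @export
bonferroni_adjust <- function(p_values) {
  if (any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  pmin(1, p_values * length(p_values))
}

#' Read a pathway annotation map
#'
#' @param path TSV with three columns and no header: pathway id, pathway
#'   name, comma-separated member gene ids.
#' @return data.frame with columns `pathway_id`, `name`, and list-column
#'   `genes`.
#' @export
read_pathway_annotation <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE, quote = "",
                    col.names = c("pathway_id", "name", "genes"),
                    colClasses = "character")
  tab$genes <- I(lapply(strsplit(tab$genes, ","), unique))
  if (any(lengths(tab$genes) == 0L)) stop("pathway with empty member set")
  tab
}

#' Write a pathway annotation map
#'
#' @param annotation data.frame as from [read_pathway_annotation()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pathway_annotation <- function(annotation, path) {
  df <- data.frame(annotation$pathway_id, annotation$name,
                   vapply(annotation$genes, paste, "", collapse = ","))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Pathway enrichment of a differentially expressed gene set
#'
#' The universe `N` is the set of genes carrying any pathway annotation
#' (the formula's own convention), not the full transcriptome. One result
#' is produced per pathway containing at least one DEG; the Bonferroni
#' factor is the number of pathways tested that way.
#'
#' @param de_gene_ids Character vector of DEG ids (may be empty). Ids
#'   absent from the annotated universe are dropped with a warning.
#' @param annotation data.frame from [read_pathway_annotation()] (or of
#'   the same shape).
#' @param alpha Significance level on the corrected p-value.
#' @return data.frame of class `enrichment_result`, sorted by raw p-value
#'   (ties broken by pathway id), with columns `pathway_id`, `name`, `N`,
#'   `n`, `M`, `m`, `p_raw`, `p_corrected`, `significant`.
#' @export
enrich <- function(de_gene_ids, annotation, alpha = 0.05) {
  universe <- unique(unlist(annotation$genes))
  if (length(universe) == 0L) stop("annotation universe is empty")
  de_gene_ids <- unique(de_gene_ids)
  outside <- setdiff(de_gene_ids, universe)
  if (length(outside) > 0L) {
    warning(length(outside), " DE gene(s) without pathway annotation dropped")
  }
  degs <- intersect(de_gene_ids, universe)
  N <- length(universe); n <- length(degs)
  res <- data.frame(pathway_id = character(), name = character(),
                    N = integer(), n = integer(), M = integer(),
                    m = integer(), p_raw = numeric(),
                    p_corrected = numeric(), significant = logical(),
                    stringsAsFactors = FALSE)
  if (n == 0L) { class(res) <- c("enrichment_result", "data.frame"); return(res) }
  Ms <- lengths(lapply(annotation$genes, unique))
  ms <- vapply(annotation$genes, function(g) length(intersect(g, degs)), 0L)
  keep <- which(ms >= 1L)
  if (length(keep) == 0L) {
    class(res) <- c("enrichment_result", "data.frame"); return(res)
  }
  p <- vapply(keep, function(i) enrichment_p(N, n, Ms[i], ms[i]), 0)
  res <- data.frame(pathway_id = annotation$pathway_id[keep],
                    name = annotation$name[keep],
                    N = N, n = n, M = as.integer(Ms[keep]),
                    m = as.integer(ms[keep]), p_raw = p,
                    stringsAsFactors = FALSE)
  res$p_corrected <- bonferroni_adjust(res$p_raw)
  res$significant <- res$p_corrected <= alpha
  res <- res[order(res$p_raw, res$pathway_id), ]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Write enrichment results as TSV
#'
#' Mirrors the usual pathway-table layout (pathway, id, m/M, p, corrected
#' p); optional up/down DEG counts per pathway when a `de_result` is
#' supplied.
#'
#' @param res An `enrichment_result`.
#' @param path Output path.
#' @param de Optional `de_result` used to split each pathway's DEGs into
#'   up/down counts.
#' @param annotation Required when `de` is given: the annotation map used.
#' @return Invisibly, `path`.
#' @export
write_enrichment <- function(res, path, de = NULL, annotation = NULL) {
  out <- data.frame(pathway = res$name, pathway_id = res$pathway_id,
                    deg_ratio = sprintf("%d/%d", res$m, res$M),
                    stringsAsFactors = FALSE)
  if (!is.null(de)) {
    if (is.null(annotation)) stop("annotation required when de is supplied")
    up <- de$transcript_id[de$status == "up"]
    dn <- de$transcript_id[de$status == "down"]
    idx <- match(res$pathway_id, annotation$pathway_id)
    out$up <- vapply(annotation$genes[idx],
                     function(g) length(intersect(g, up)), 0L)
    out$down <- vapply(annotation$genes[idx],
                       function(g) length(intersect(g, dn)), 0L)
  }
  out$p <- res$p_raw
  out$p_corrected <- res$p_corrected
  out$significant <- res$significant
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
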