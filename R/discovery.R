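#' Configuration for the lncRNA discovery cascade
#'
#' Bundles every threshold of the stepwise filtering pipeline. Defaults are
#' the pipeline's published operating point: minimum transcript length
#' 300 nt, maximum ORF 75 aa, at least 10 raw read counts summed over all
#' libraries, protein-track e-value 1e-4, symbiont-track e-value 1e-3, and
#' a k-mer coding-score threshold of 0.
#'
#' @param min_length_nt Minimum transcript length in nucleotides.
#' @param max_orf_aa Maximum allowed longest stop-to-stop ORF, in amino
#'   acids.
#' @param min_total_counts Minimum raw read counts. By default the sum over
#'   all libraries must reach this value; set `per_library = TRUE` to
#'   require it in every library instead.
#' @param e_protein,e_symbiont E-value thresholds of the protein and
#'   symbiont tracks.
#' @param plek_threshold Transcripts with k-mer coding score above this are
#'   classified coding.
#' @param contaminant_rule `"and"` or `"or"` (see
#'   [symbiont_contaminants()]).
#' @param strands Strands scanned for ORFs.
#' @param per_library Logical; see `min_total_counts`.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_length_nt = 300L, max_orf_aa = 75L,
                          min_total_counts = 10L, e_protein = 1e-4,
                          e_symbiont = 1e-3, plek_threshold = 0,
                          contaminant_rule = c("and", "or"),
                          strands = c("+", "-"), per_library = FALSE) {
  contaminant_rule <- match.arg(contaminant_rule)
  if (min_length_nt <= 0 || max_orf_aa <= 0 || min_total_counts <= 0 ||
      e_protein <= 0 || e_symbiont <= 0) {
    stop("filter_config thresholds must be positive")
  }
  if (!all(strands %in% c("+", "-")) || length(strands) == 0L) {
    stop("strands must be a non-empty subset of c('+', '-')")
  }
  structure(list(min_length_nt = as.integer(min_length_nt),
                 max_orf_aa = as.integer(max_orf_aa),
                 min_total_counts = as.integer(min_total_counts),
                 e_protein = e_protein, e_symbiont = e_symbiont,
                 plek_threshold = plek_threshold,
                 contaminant_rule = contaminant_rule,
                 strands = strands, per_library = per_library),
            class = "filter_config")
}

## Cascade order: first failing predicate names the exclusion class.
CASCADE <- data.frame(
  predicate = c("is_symbiont", "has_coding_evidence", "too_short",
                "orf_too_long", "is_housekeeping", "low_expression",
                "kmer_coding"),
  class = c("contaminant", "mRNA-like", "short", "coding-ORF",
            "housekeeping", "low-expression", "coding-by-kmer"),
  stringsAsFactors = FALSE)

#' Classify transcripts through the lncRNA discovery cascade
#'
#' Applies the full filtering pipeline: transcripts with no symbiont hit,
#' no protein/domain/signal-peptide evidence, length at or above the
#' minimum, longest stop-to-stop ORF at or below the maximum, no
#' housekeeping-RNA hit, sufficient raw counts, and a noncoding k-mer
#' score are returned as high-confidence lncRNAs. All predicates are
#' evaluated for every transcript, so the trace is complete and the final
#' set does not depend on evaluation order; the reported `final_class` is
#' the first failing predicate in cascade order, for explainability.
#'
#' @param transcripts Named [Biostrings::DNAStringSet] (or named character
#'   vector); must be non-empty.
#' @param evidence An `evidence_bundle` from [build_evidence_bundle()].
#' @param counts A counts matrix (transcripts x samples), a named vector of
#'   totals per transcript, or a `counts_table`; transcripts missing from
#'   it count 0.
#' @param config A [filter_config()].
#' @param kmer_model Optional `kmer_model`; when `NULL`, the
#'   `plek_coding` column of the evidence bundle is used (external
#'   classifier adapter). Transcripts with neither are treated as
#'   noncoding with a warning.
#' @return List with `lncrna_ids` (character, in input order) and `trace`
#'   (data.frame, one row per transcript: every predicate plus
#'   `final_class`).
#' @export
classify_transcripts <- function(transcripts, evidence, counts, config,
                                 kmer_model = NULL) {
  transcripts <- as_transcripts(transcripts)
  if (length(transcripts) == 0L) stop("empty transcript set")
  if (!inherits(config, "filter_config")) stop("config must be a filter_config")
  ids <- names(transcripts)
  ev <- evidence[match(ids, evidence$transcript_id), ]
  if (anyNA(ev$transcript_id)) {
    stop("evidence bundle does not cover transcript: ",
         ids[which(is.na(ev$transcript_id))[1L]])
  }

  total_counts <- count_totals(counts, ids, config$per_library)

  kmer_score <- rep(NA_real_, length(ids))
  if (!is.null(kmer_model)) {
    kmer_score <- unname(kmer_coding_score(transcripts, kmer_model))
    kmer_coding <- kmer_score > config$plek_threshold
  } else if (!all(is.na(ev$plek_coding))) {
    kmer_coding <- ev$plek_coding
    if (anyNA(kmer_coding)) {
      warning("transcripts without external coding label treated as noncoding")
      kmer_coding[is.na(kmer_coding)] <- FALSE
    }
  } else {
    warning("no kmer model and no external labels; ",
            "coding-by-kmer predicate disabled")
    kmer_coding <- rep(FALSE, length(ids))
  }

  trace <- data.frame(
    transcript_id = ids,
    is_symbiont = ev$symbiont_hit,
    has_coding_evidence = ev$protein_hit | ev$domain_hit | ev$signal_peptide,
    too_short = Biostrings::width(transcripts) < config$min_length_nt,
    orf_too_long = unname(longest_orf_aa(transcripts, config$strands)) >
      config$max_orf_aa,
    is_housekeeping = ev$housekeeping_hit,
    low_expression = total_counts < config$min_total_counts,
    kmer_coding = kmer_coding,
    kmer_score = kmer_score,
    total_counts = total_counts,
    stringsAsFactors = FALSE)

  pred <- as.matrix(trace[, CASCADE$predicate])
  first_fail <- apply(pred, 1L, function(x) {
    w <- which(x)
    if (length(w) == 0L) 0L else w[1L]
  })
  trace$final_class <- ifelse(first_fail == 0L, "lncRNA",
                              CASCADE$class[pmax(first_fail, 1L)])
  list(lncrna_ids = ids[first_fail == 0L], trace = trace)
}

## Total (or minimum per-library) raw counts per transcript id.
count_totals <- function(counts, ids, per_library = FALSE) {
  if (inherits(counts, "counts_table")) counts <- counts$counts
  if (is.matrix(counts) || is.data.frame(counts)) {
    counts <- as.matrix(counts)
    agg <- if (per_library) apply(counts, 1L, min) else rowSums(counts)
  } else if (is.numeric(counts)) {
    agg <- counts
  } else {
    stop("counts must be a matrix, counts_table, or named numeric vector")
  }
  out <- setNames(rep(0, length(ids)), ids)
  common <- intersect(ids, names(agg))
  out[common] <- agg[common]
  unname(out)
}

#' Summarize a filter trace by exclusion class
#'
#' @param trace The `trace` data.frame from [classify_transcripts()].
#' @return data.frame with `final_class` and `n`; counts sum to the number
#'   of transcripts. Classes are listed in cascade order, lncRNA last, and
#'   empty classes are omitted.
#' @export
summarize_filters <- function(trace) {
  if (nrow(trace) == 0L) stop("trace must be non-empty")
  lev <- c(CASCADE$class, "lncRNA")
  tab <- table(factor(trace$final_class, levels = lev))
  out <- data.frame(final_class = names(tab), n = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[out$n > 0L, , drop = FALSE]
}

#' Write the per-transcript filter trace / class summary as TSV
#'
#' @param trace,summary Outputs of [classify_transcripts()] and
#'   [summarize_filters()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_trace <- function(trace, path) {
  write.table(trace, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
write_filter_summary <- function(summary, path) {
  write.table(summary, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
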