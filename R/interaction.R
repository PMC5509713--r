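PAIR_TYPES <- c("AU", "UA", "GC", "CG", "GU", "UG")

#' Path to a shipped duplex energy parameter file
#'
#' `"default"` is a nearest-neighbor intermolecular RNA-RNA stacking table
#' (Turner-style dG at 37 C plus dH for temperature rescaling, generic
#' wobble stacks, affine loop penalty, +4.1 kcal/mol initiation).
#' `"toy"` is the test model: every stacked Watson-Crick pair -2, any
#' stack involving a wobble pair -1, loops forbidden, no initiation, and
#' temperature-invariant.
#'
#' @param name `"default"` or `"toy"`.
#' @return File path inside the installed package.
#' @export
energy_model_path <- function(name = c("default", "toy")) {
  name <- match.arg(name)
  f <- system.file("extdata",
                   sprintf("rna_stacks_%s.tsv", name), package = "lncoral")
  if (f == "") stop("shipped energy model not found: ", name)
  f
}

#' Read a duplex energy model
#'
#' Parameter files are TSV with columns `type`, `context`, `dg_ref`, `dh`
#' (`#` comments allowed). `stack` rows are keyed by an ordered pair of
#' pair types, e.g. `AU/GC` = an A-U pair stacked 5'-side of a G-C pair.
#' Scalar rows: `loop_open`, `loop_ext` (affine interior/bulge loop
#' penalty), `max_span` (max unpaired nt per side), `init` (duplex
#' initiation). Stack and scalar energies are rescaled from the reference
#' temperature (37 C) to `temperature` via
#' `dG(T) = dH - T_K * (dH - dG_ref) / 310.15`; rows with `dh == dg_ref`
#' are therefore temperature-invariant.
#'
#' @param path Parameter file path (see [energy_model_path()]).
#' @param temperature Simulation temperature in degrees Celsius (default
#'   25, the hybridization temperature used for coral transcriptomes).
#' @return List of class `energy_model`: `stack` (6x6 matrix over
#'   [PAIR_TYPES]), `pair_code` (5x5 base-pairability matrix),
#'   `loop_open`, `loop_ext`, `max_span`, `init`, `temperature`.
#' @export
read_energy_model <- function(path, temperature = 25) {
  tab <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                    col.names = c("type", "context", "dg_ref", "dh"),
                    stringsAsFactors = FALSE)
  t_k <- temperature + 273.15
  rescale <- function(dg, dh) dh - t_k * (dh - dg) / 310.15
  stack <- matrix(NA_real_, 6L, 6L, dimnames = list(PAIR_TYPES, PAIR_TYPES))
  for (i in which(tab$type == "stack")) {
    pq <- strsplit(tab$context[i], "/", fixed = TRUE)[[1L]]
    if (length(pq) != 2L || !all(pq %in% PAIR_TYPES)) {
      stop("malformed stack context: ", tab$context[i])
    }
    stack[pq[1L], pq[2L]] <- rescale(tab$dg_ref[i], tab$dh[i])
  }
  scalar <- function(ty, default = NULL) {
    i <- which(tab$type == ty)
    if (length(i) == 0L) {
      if (is.null(default)) stop("missing parameter: ", ty)
      return(default)
    }
    rescale(tab$dg_ref[i[1L]], tab$dh[i[1L]])
  }
  ## base order A, C, G, U/T, N; wobble allowed iff a GU/UG stack exists
  pair_code <- matrix(0L, 5L, 5L)
  dimnames(pair_code) <- list(c("A", "C", "G", "T", "N"),
                              c("A", "C", "G", "T", "N"))
  pair_code["A", "T"] <- 1L; pair_code["T", "A"] <- 2L
  pair_code["G", "C"] <- 3L; pair_code["C", "G"] <- 4L
  wobble <- any(!is.na(stack[c("GU", "UG"), ])) ||
    any(!is.na(stack[, c("GU", "UG")]))
  if (wobble) { pair_code["G", "T"] <- 5L; pair_code["T", "G"] <- 6L }
  structure(list(stack = stack, pair_code = pair_code,
                 loop_open = scalar("loop_open"),
                 loop_ext = scalar("loop_ext"),
                 max_span = as.integer(round(scalar("max_span"))),
                 init = scalar("init"),
                 temperature = temperature),
            class = "energy_model")
}

encode_bases <- function(seq) {
  x <- strsplit(gsub("U", "T", toupper(seq), fixed = TRUE), "")[[1L]]
  code <- match(x, c("A", "C", "G", "T", "N")) - 1L
  if (anyNA(code)) stop("sequence contains non-ACGTN character")
  code
}

#' Minimum-free-energy intermolecular duplex
#'
#' Folds an lncRNA against an mRNA under an interaction-only model (no
#' intramolecular structure): a dynamic programme over antiparallel base
#' pairs extended by stacking or by interior/bulge loops of bounded span
#' with an affine penalty, plus a duplex initiation cost. `N` bases never
#' pair.
#'
#' @param lncrna_seq,mrna_seq Sequences over `ACGTN`/`ACGUN` (character,
#'   or length-1 `DNAStringSet`).
#' @param model An `energy_model` from [read_energy_model()].
#' @param lncrna_id,mrna_id Ids recorded in the result.
#' @param window,stride For mRNAs longer than `window`, the mRNA is
#'   scanned in windows of that size (overlapping by `window - stride`)
#'   and the best-energy window is reported; default `Inf` folds the full
#'   sequence.
#' @return `NULL` when no complementary pair exists or the best energy is
#'   >= 0; otherwise a list of class `duplex_result`: ids, 0-based
#'   half-open `lncrna_interval` and `mrna_interval`, `energy` (kcal/mol),
#'   `pairs` (data.frame of paired 0-based positions, ascending on the
#'   lncRNA, descending on the mRNA), and `paired_fraction` (paired lncRNA
#'   positions over the lncRNA interval length).
#' @export
duplex_fold <- function(lncrna_seq, mrna_seq, model,
                        lncrna_id = "lncrna", mrna_id = "mrna",
                        window = Inf, stride = NULL) {
  if (!inherits(model, "energy_model")) stop("model must be an energy_model")
  lseq <- as.character(lncrna_seq)[1L]
  mseq <- as.character(mrna_seq)[1L]
  if (nchar(lseq) == 0L || nchar(mseq) == 0L) {
    stop("sequences must be non-empty")
  }
  x <- encode_bases(lseq)
  y_full <- encode_bases(mseq)
  if (is.finite(window) && length(y_full) > window) {
    if (is.null(stride)) stride <- max(1L, as.integer(window / 2))
    offs <- unique(c(seq(0L, length(y_full) - 1L, by = stride)))
    offs <- offs[offs < length(y_full)]
    best <- NULL
    for (o in offs) {
      y <- y_full[(o + 1L):min(length(y_full), o + window)]
      r <- duplex_dp(x, y, model$stack, model$pair_code,
                     model$loop_open, model$loop_ext, model$max_span,
                     model$init)
      if (isTRUE(r$found) && (is.null(best) || r$energy < best$energy)) {
        r$offset <- o
        best <- r
      }
    }
    res <- best
    offset <- if (is.null(best)) 0L else best$offset
  } else {
    res <- duplex_dp(x, y_full, model$stack, model$pair_code,
                     model$loop_open, model$loop_ext, model$max_span,
                     model$init)
    offset <- 0L
  }
  if (is.null(res) || !isTRUE(res$found) || res$energy >= 0) return(NULL)
  pi <- res$pairs_i
  pj <- res$pairs_j + offset
  li <- c(min(pi), max(pi) + 1L)
  mi <- c(min(pj), max(pj) + 1L)
  structure(list(lncrna_id = lncrna_id, mrna_id = mrna_id,
                 lncrna_interval = li, mrna_interval = mi,
                 energy = res$energy,
                 pairs = data.frame(lncrna_pos = pi, mrna_pos = pj),
                 paired_fraction = length(pi) / (li[2L] - li[1L])),
            class = "duplex_result")
}

#' Conserved lncRNA regions from reference-database hits
#'
#' Query-side intervals of hits against a reference lncRNA database
#' (NONCODE-style search), thresholded at `e_cutoff` (inclusive; the
#' strict mode uses 1e-3, the loose mode for differentially expressed
#' lncRNAs uses 10), converted to 0-based half-open coordinates, and
#' merged per lncRNA when overlapping or adjacent.
#'
#' @param hits Hit table with lncRNAs as queries.
#' @param lncrna_lengths Named numeric vector of lncRNA lengths.
#' @param e_cutoff E-value upper bound, inclusive.
#' @return data.frame with columns `lncrna_id`, `start`, `end`,
#'   `source_subject_id` (comma-joined over merged hits),
#'   `source_e_value` (best over merged hits); sorted by id then start.
#' @export
conserved_regions_from_hits <- function(hits, lncrna_lengths, e_cutoff) {
  if (e_cutoff <= 0) stop("e_cutoff must be > 0")
  empty <- data.frame(lncrna_id = character(), start = integer(),
                      end = integer(), source_subject_id = character(),
                      source_e_value = numeric(), stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) return(empty)
  h <- hits[hits$evalue <= e_cutoff, , drop = FALSE]
  if (nrow(h) == 0L) return(empty)
  miss <- setdiff(unique(h$qseqid), names(lncrna_lengths))
  if (length(miss) > 0L) stop("missing lncRNA length for id: ", miss[1L])
  over <- h$qend > lncrna_lengths[h$qseqid]
  if (any(over)) {
    stop("hit interval exceeds lncRNA length for id: ", h$qseqid[over][1L])
  }
  out <- lapply(split(h, h$qseqid), function(hh) {
    ir <- IRanges::IRanges(start = hh$qstart, end = hh$qend)
    red <- IRanges::reduce(ir)   # merges overlapping and adjacent
    ov <- IRanges::findOverlaps(ir, red)
    src <- vapply(seq_along(red), function(k) {
      paste(sort(unique(hh$sseqid[S4Vectors::queryHits(ov)[
        S4Vectors::subjectHits(ov) == k]])), collapse = ",")
    }, "")
    bev <- vapply(seq_along(red), function(k) {
      min(hh$evalue[S4Vectors::queryHits(ov)[
        S4Vectors::subjectHits(ov) == k]])
    }, 0)
    data.frame(lncrna_id = hh$qseqid[1L],
               start = IRanges::start(red) - 1L,
               end = IRanges::end(red),
               source_subject_id = src, source_e_value = bev,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$lncrna_id, out$start), ]
  rownames(out) <- NULL
  out
}

#' Gate duplexes into accepted lncRNA-mRNA interaction edges
#'
#' Each duplex is annotated with the three published gates: interaction
#' energy at or below `energy_cutoff`, paired fraction at or above
#' `min_paired_fraction` (the quantified reading of "relatively perfect
#' complementary base pairing"), and hybridization site located in a
#' conserved region. An edge is accepted only when all three hold.
#'
#' @param duplexes List of `duplex_result` objects (NULLs are dropped).
#' @param conserved_regions data.frame from
#'   [conserved_regions_from_hits()] (merged).
#' @param energy_cutoff kcal/mol (default -20).
#' @param min_paired_fraction Default 0.9.
#' @param overlap_rule `"coverage"` (default: at least `min_coverage` of
#'   the duplex's lncRNA interval covered by conserved regions), `"any"`
#'   (any overlap), or `"containment"` (full containment).
#' @param min_coverage Coverage fraction for the `"coverage"` rule
#'   (default 0.5).
#' @return data.frame of class `interaction_edges`: ids, intervals,
#'   `energy`, `paired_fraction`, `in_conserved_region`, `passes_energy`,
#'   `passes_pairing`, `accepted`. All duplexes are retained for audit;
#'   filter on `accepted` for the final edge set.
#' @export
gate_interactions <- function(duplexes, conserved_regions,
                              energy_cutoff = -20,
                              min_paired_fraction = 0.9,
                              overlap_rule = c("coverage", "any",
                                               "containment"),
                              min_coverage = 0.5) {
  overlap_rule <- match.arg(overlap_rule)
  duplexes <- Filter(Negate(is.null), duplexes)
  rows <- lapply(duplexes, function(d) {
    stopifnot(inherits(d, "duplex_result"))
    reg <- conserved_regions[
      conserved_regions$lncrna_id == d$lncrna_id, , drop = FALSE]
    s <- d$lncrna_interval[1L]; e <- d$lncrna_interval[2L]
    cov <- 0
    if (nrow(reg) > 0L) {
      dint <- IRanges::IRanges(start = s + 1L, end = e)
      rint <- IRanges::IRanges(start = reg$start + 1L, end = reg$end)
      cov <- sum(IRanges::width(IRanges::intersect(dint, rint))) / (e - s)
    }
    in_region <- switch(overlap_rule,
                        coverage = cov >= min_coverage,
                        any = cov > 0,
                        containment = cov >= 1 - 1e-12)
    data.frame(lncrna_id = d$lncrna_id, mrna_id = d$mrna_id,
               lnc_start = s, lnc_end = e,
               mrna_start = d$mrna_interval[1L],
               mrna_end = d$mrna_interval[2L],
               energy = d$energy, paired_fraction = d$paired_fraction,
               region_coverage = cov,
               in_conserved_region = in_region,
               passes_energy = d$energy <= energy_cutoff,
               passes_pairing = d$paired_fraction >= min_paired_fraction,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows) == 0L) {
    data.frame(lncrna_id = character(), mrna_id = character(),
               lnc_start = integer(), lnc_end = integer(),
               mrna_start = integer(), mrna_end = integer(),
               energy = numeric(), paired_fraction = numeric(),
               region_coverage = numeric(),
               in_conserved_region = logical(), passes_energy = logical(),
               passes_pairing = logical(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  out$accepted <- out$in_conserved_region & out$passes_energy &
    out$passes_pairing
  out <- out[order(out$lncrna_id, out$mrna_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("interaction_edges", "data.frame")
  out
}

#' Bipartite lncRNA-mRNA interaction network
#'
#' @param edges An `interaction_edges` data.frame (typically filtered to
#'   `accepted`), or any data.frame with `lncrna_id` and `mrna_id`.
#' @param accepted_only Keep only accepted edges when the column exists
#'   (default `TRUE`).
#' @return List of class `interaction_network`: `graph` (bipartite
#'   [igraph::graph]; lncRNA vertices have `type = FALSE`), `summary`
#'   (lncRNA/mRNA/edge counts), and `degree` (data.frame, lexicographic
#'   order).
#' @export
build_network <- function(edges, accepted_only = TRUE) {
  if (accepted_only && "accepted" %in% names(edges)) {
    edges <- edges[edges$accepted, , drop = FALSE]
  }
  lnc <- sort(unique(edges$lncrna_id))
  mr <- sort(unique(edges$mrna_id))
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, length(lnc), name = lnc, type = FALSE)
  g <- igraph::add_vertices(g, length(mr), name = mr, type = TRUE)
  if (nrow(edges) > 0L) {
    eo <- edges[order(edges$lncrna_id, edges$mrna_id), ]
    g <- igraph::add_edges(g, rbind(eo$lncrna_id, eo$mrna_id))
  }
  deg <- igraph::degree(g)
  structure(list(
    graph = g,
    summary = list(n_lncrna = length(lnc), n_mrna = length(mr),
                   n_edges = nrow(edges)),
    degree = data.frame(id = names(deg), degree = as.integer(deg),
                        is_lncrna = names(deg) %in% lnc,
                        stringsAsFactors = FALSE)),
    class = "interaction_network")
}

#' Write interaction edges / conserved regions to disk
#'
#' Edges go to a TSV mirroring the gate annotation; regions to a BED file
#' (0-based half-open, name column = source subject ids, score column =
#' best e-value).
#'
#' @param edges An `interaction_edges` data.frame.
#' @param regions A conserved-regions data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_edges <- function(edges, path) {
  write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edges
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(regions$lncrna_id, regions$start, regions$end,
                    regions$source_subject_id,
                    formatC(regions$source_e_value, format = "g"))
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Parse native RNAplex output into duplex results (adapter)
#'
#' Accepts the plain RNAplex report: per interaction, a target header
#' line, a query header line, and a structure line of the form
#' `.((((&)))). <ts>,<te> : <qs>,<qe> (<energy>)` with 1-based inclusive
#' coordinates. The query is taken to be the lncRNA (RNAplex convention
#' when scanning lncRNAs against target mRNAs is adapter-configurable via
#' `query_is_lncrna`).
#'
#' @param path RNAplex output file.
#' @param query_is_lncrna Logical (default `TRUE`).
#' @return List of `duplex_result` objects (paired positions approximated
#'   by pairing the parenthesized stretches innermost-outward).
#' @export
read_rnaplex <- function(path, query_is_lncrna = TRUE) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  out <- list()
  i <- 1L
  pat <- paste0("^([.()&,]+)\\s+(\\d+),(\\d+)\\s*:\\s*(\\d+),(\\d+)\\s+",
                "\\((\\s*-?[0-9.]+)\\)")
  target <- query <- NA_character_
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      if (is.na(target) || !is.na(query)) { target <- sub("^>", "", ln); query <- NA }
      else query <- sub("^>", "", ln)
      next
    }
    m <- regmatches(ln, regexec(pat, ln))[[1L]]
    if (length(m) == 0L) next
    struct <- m[2L]
    ts <- as.integer(m[3L]); te <- as.integer(m[4L])
    qs <- as.integer(m[5L]); qe <- as.integer(m[6L])
    energy <- as.numeric(m[7L])
    halves <- strsplit(struct, "&", fixed = TRUE)[[1L]]
    n_open <- sum(strsplit(halves[1L], "")[[1L]] == "(")
    tgt_int <- c(ts - 1L, te)
    qry_int <- c(qs - 1L, qe)
    if (query_is_lncrna) {
      lnc_id <- query; mr_id <- target
      lnc_int <- qry_int; mr_int <- tgt_int
    } else {
      lnc_id <- target; mr_id <- query
      lnc_int <- tgt_int; mr_int <- qry_int
    }
    pf <- n_open / (lnc_int[2L] - lnc_int[1L])
    out[[length(out) + 1L]] <- structure(
      list(lncrna_id = lnc_id, mrna_id = mr_id,
           lncrna_interval = lnc_int, mrna_interval = mr_int,
           energy = energy, pairs = NULL,
           paired_fraction = min(1, pf)),
      class = "duplex_result")
    target <- query <- NA_character_
  }
  out
}
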