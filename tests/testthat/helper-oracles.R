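## Independent oracles used to derive expected values. Each deliberately
## takes a different route from the implementation it checks.

## Longest stop-to-stop ORF by exhaustive enumeration of every
## codon-aligned stop-free substring (any offset defines its own frame).
oracle_longest_orf <- function(seq, strands = c("+", "-")) {
  revcomp <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(comp[strsplit(s, "")[[1L]]]), collapse = "")
  }
  aa_of <- function(codon) {
    v <- Biostrings::GENETIC_CODE[codon]
    if (is.na(v)) "X" else v
  }
  best <- 0L
  for (st in strands) {
    s <- if (st == "+") seq else revcomp(seq)
    L <- nchar(s)
    for (i in seq_len(L)) {          # 1-based start
      j <- i + 2L
      while (j <= L) {
        codon <- substr(s, j - 2L, j)
        if (aa_of(codon) == "*") break
        best <- max(best, (j - i + 1L) %/% 3L)
        j <- j + 3L
      }
    }
  }
  best
}

## Exact-rational upper-tail hypergeometric via Pascal-triangle binomials.
## For N <= 40 every binomial and every partial numerator sum is an exact
## integer below 2^53, so the only rounding is the final division.
oracle_pascal <- function(nmax) {
  C <- matrix(0, nmax + 1L, nmax + 1L)
  C[, 1L] <- 1
  for (i in 2:(nmax + 1L)) {
    for (j in 2:i) C[i, j] <- C[i - 1L, j - 1L] + C[i - 1L, j]
  }
  C  # C[n+1, k+1] = choose(n, k)
}

oracle_hyper_upper <- function(N, n, M, m, C = oracle_pascal(N)) {
  if (m == 0L) return(1)
  imax <- min(n, M)
  num <- 0
  for (i in m:imax) {
    num <- num + C[M + 1L, i + 1L] * C[N - M + 1L, n - i + 1L]
  }
  num / C[N + 1L, n + 1L]
}

## Audic-Claverie via the negative-binomial identity:
## p(k|x) = dnbinom(k, size = x+1, prob = 1/(1+r)).
oracle_ac_p <- function(x, y, t1, t2) {
  r <- t2 / t1
  pr <- 1 / (1 + r)
  lower <- stats::pnbinom(y, size = x + 1, prob = pr)
  upper <- if (y == 0) 1 else
    stats::pnbinom(y - 1, size = x + 1, prob = pr, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

## Exhaustive duplex enumeration under an energy model: all antiparallel
## pairings with per-side loop spans <= max_span. Exponential; tiny
## sequences only. With max_span = 0 this reduces to contiguous runs.
oracle_duplex_energy <- function(xs, ys, model) {
  enc <- function(s) match(strsplit(gsub("U", "T", toupper(s)), "")[[1L]],
                           c("A", "C", "G", "T", "N"))
  x <- enc(xs); y <- enc(ys)
  pc <- model$pair_code
  n <- length(x); m <- length(y)
  best <- Inf
  extend <- function(i, j, acc) {
    best <<- min(best, acc)
    span <- model$max_span
    for (ii in (i + 1):n) {
      if (ii > n) break
      li <- ii - i - 1L
      if (li > span) break
      for (jj in (j - 1):1) {
        if (jj < 1L) break
        lj <- j - jj - 1L
        if (lj > span) next
        if (pc[x[ii], y[jj]] == 0L) next
        step <- if (li == 0L && lj == 0L) {
          s <- model$stack[pc[x[i], y[j]], pc[x[ii], y[jj]]]
          if (is.na(s)) next
          s
        } else {
          model$loop_open + model$loop_ext * (li + lj)
        }
        extend(ii, jj, acc + step)
      }
    }
  }
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      if (pc[x[i], y[j]] != 0L) extend(i, j, 0)
    }
  }
  if (!is.finite(best)) NULL else best + model$init
}

random_dna <- function(n, probs = c(A = .25, C = .25, G = .25, T = .25)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs),
        collapse = "")
}
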