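---
title: "lncoral: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lncoral: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What the package computes

`lncoral` re-implements, as a tested and reusable pipeline, the standard
computational strategy for cataloguing long non-coding RNAs (lncRNAs) in
a de novo assembled transcriptome of a non-model organism — the
motivating system is reef anthozoans (zoanthids) whose tissues also
contain large amounts of RNA from their photosynthetic endosymbionts —
and for proposing mRNA targets of those lncRNAs through
conserved-region-gated RNA–RNA hybridization. Five analysis layers are
covered:

1. a **discovery cascade** that strips a transcript set down to
   high-confidence lncRNAs,
2. **two-library differential expression** (healthy vs bleaching
   colonies) without replicates,
3. **hypergeometric pathway enrichment** with Bonferroni correction,
4. **lncRNA–mRNA interaction prediction** by intermolecular duplex
   energy minimization gated on conserved lncRNA regions, and
5. a **synthetic-transcriptome generator** with a ground-truth manifest
   that makes all of the above verifiable at desk scale.

## The discovery cascade

A transcript is retained as a high-confidence lncRNA only if **all** of
the following hold (each predicate is recorded per transcript in an
audit trace; the reported exclusion class is the first failing predicate
in cascade order, but all predicates are always evaluated, so the final
set is independent of ordering):

| step | predicate | default |
|------|-----------|---------|
| 1 | no symbiont-reference hit covering > 50% of query **and** subject at e < 1e-3 | `e_symbiont = 1e-3`, `contaminant_rule = "and"` |
| 2 | no protein hit (e <= 1e-4), no domain hit, no signal peptide | `e_protein = 1e-4` |
| 3 | length >= 300 nt | `min_length_nt = 300` |
| 4 | longest stop-to-stop ORF <= 75 aa | `max_orf_aa = 75` |
| 5 | no housekeeping-RNA (rRNA/tRNA-style) hit | any hit counts |
| 6 | >= 10 raw read counts summed over libraries | `min_total_counts = 10` |
| 7 | k-mer coding score <= 0 | `plek_threshold = 0` |

Notes on interpretation choices:

* **Stop-to-stop ORFs.** ORFs are maximal stop-free codon runs in all
  six (configurable to three) frames, including the runs bounded by the
  sequence ends; no ATG is required. Codons containing `N` translate to
  `X` and never count as stops.
* **Contamination coverage rule.** The 50%-coverage contamination rule
  is read conjunctively (both query and subject must be more than half
  covered); a `contaminant_rule = "or"` switch exists because the
  underlying phrasing admits both readings.
* **Expression floor.** "At least 10 raw counts" is the sum over all
  libraries by default (`per_library = TRUE` switches to a per-library
  minimum).
* **Coding-potential screen.** SVM-based classifiers (PLEK-style) are
  external tools; the built-in stand-in is a transparent k-mer
  (k = 1..5) log-odds model trained on a coding and a noncoding
  sequence set, scoring each transcript by the occurrence-weighted mean
  log-odds of its k-mers (noncoding iff score <= 0). An adapter
  (`read_plek_labels()`) ingests a precomputed external label table
  instead when one is available.

## Differential expression between two libraries

Expression is normalized as FPKM
(`count * 1e9 / (length_nt * total_mapped)`). With one library per
condition there are no replicates, so significance comes from the
classical Audic–Claverie conditional-Poisson test: given count `x` in
library 1 and library-size ratio `r = total2/total1`, the second count
follows `p(y|x) = r^y (x+y)! / (x! y! (1+r)^(x+y+1))`, and the reported
p-value is `min(1, 2*min(P(Y<=y), P(Y>=y)))`, computed tail-wise in log
space so small values keep relative precision. Benjamini–Hochberg
adjustment is applied across all tested transcripts, and a transcript is
called differential only when `|log2fc| >= 1` **and** `q < 0.05` (the
FDR phrasing wins over a raw-p reading; `use_q = FALSE` restores the
latter). The fold change is
`log2((fpkm2 + 0.01) / (fpkm1 + 0.01))`; the pseudo-FPKM of 0.01 keeps
zero-expression transcripts finite and is configurable. **Direction
convention:** "up" means higher in the *second* sample of the pair
(bleaching, when the pair is healthy/bleaching); the output header
records this.

One caution documented deliberately: the two-sided min-tail construction
is *not* exactly symmetric under swapping the libraries (the two
directions condition on different margins; only the point probability is
symmetric at `r = 1`). Swapping flips every `log2fc` sign exactly, and
p-values agree on the log scale to within a small factor; the tests
assert precisely that, rather than a symmetry the formula does not have.

## Pathway enrichment

For a pathway with `M` annotated genes, `m` of them differentially
expressed, in a universe of `N` annotated genes containing `n` DEGs, the
enrichment p-value is the upper-tail hypergeometric probability

$$P = 1 - \sum_{i=0}^{m-1}
  \frac{\binom{M}{i}\binom{N-M}{n-i}}{\binom{N}{n}}
  \;=\; P(X \ge m).$$

The implementation evaluates the *upper-tail* sum in log space. The
literal `1 - sum` form is mathematically identical but numerically
destroys all relative precision when `P` is tiny, which would defeat the
package's own oracle test (agreement with exact rational arithmetic to
rel. err. < 1e-12 over the whole `N <= 40` grid). The universe `N` is
the set of genes with *any* pathway annotation — the formula's own
convention — not the full transcriptome; Bonferroni multiplies by the
number of pathways actually tested (those containing at least one DEG).
Significance means corrected p <= 0.05. (The source material prints the
threshold with the inequality reversed, an apparent typo: its own result
tables list only small corrected p-values.)

## Interaction prediction

### Conserved regions

Hit intervals of lncRNAs against a reference lncRNA database, at
e <= 1e-3 (strict mode) or e <= 10 (the loose mode used for
differentially expressed lncRNAs), become candidate functional regions;
overlapping or abutting intervals are merged per lncRNA.

### Duplex folding

`duplex_fold()` minimizes the free energy of an *intermolecular-only*
duplex (no intramolecular structure, no pseudoknots): a dynamic
programme over antiparallel base pairs where `H(i,j)` — the best energy
of a duplex whose rightmost pair is `(i,j)` — is extended either by a
nearest-neighbor stack or across an interior/bulge loop of bounded span
with an affine penalty, plus a one-off duplex initiation cost.
Watson–Crick stack free energies are the standard nearest-neighbor
dG(37 °C)/dH set; wobble (G·U) stacks use a single generic value and are
flagged approximate in the parameter file. All terms are rescaled to the
simulation temperature via `dG(T) = dH − T_K (dH − dG37)/310.15`; the
default 25 °C matches the hybridization temperature used for coral
transcriptome screening. Loop and initiation terms carry `dH = dG`, i.e.
they are temperature-invariant by construction.

**Parameter choice that was genuinely open.** With an affine loop
penalty and no per-nucleotide duplex-length normalization (which
tool-grade interaction scanners apply), generous loop spans let the
recursion chain incidental 5–7-pair helices across hundreds of
nucleotides into physically meaningless −100 kcal/mol "duplexes". The
shipped default therefore uses a deliberately tight loop regime —
`loop_open = 5.0`, `loop_ext = 1.5` kcal/mol per unpaired nt,
`max_span = 4` per side, initiation +4.1 — under which a planted
30-nt perfect complement folds as one contiguous helix while incidental
chaining is unprofitable. A second shipped file (`toy`) — every WC stack
−2, wobble-containing stack −1, loops forbidden, no initiation — is the
reference model for exhaustive-enumeration tests. A `read_rnaplex()`
adapter ingests native RNAplex output for production use.

### Gates

An edge is accepted only when all three published gates hold:
energy <= −20 (read as kcal/mol; the source omits units), paired
fraction >= 0.9 on the lncRNA-side interval (the quantified reading of
"relatively perfect complementary pairing" — no number is stated in the
source), and hybridization site *located in* a conserved region. The
default site rule is >= 50% coverage of the duplex's lncRNA interval by
conserved regions: "located in" suggests more than incidental overlap,
while full containment would be brittle at region edges. All three
policies (`coverage`, `any`, `containment`) are selectable, and every
candidate duplex is retained in the output with its gate annotation for
audit.

## The synthetic world

The generator emulates what the analysis *assumes* about real data, not
the data themselves:

* **mRNA-like** transcripts: a random-codon ORF of 100–350 aa flanked by
  UTRs, GC-shifted composition (A/T 0.20, C/G 0.30 each).
* **lncRNA-like** transcripts (and the planted low-expression ones):
  300–800 nt, AT-shifted (A/T 0.30, C/G 0.20), rejection-sampled until
  the longest stop-to-stop ORF on both strands is <= 75 aa. The
  composition contrast is the real, documented AT-richness of lncRNAs
  relative to coding sequence, and it is what gives the k-mer screen its
  separation; it is chosen once, not tuned against any test.
* **Contaminants / housekeeping RNAs**: near-identical copies (0.5% and
  up-to-2% point mutations) of two shipped *synthetic* reference
  sequences each (`*_ref_synthetic.fasta` — stand-ins for symbiont and
  rRNA references that cannot be shipped).
* **Counts**: negative-binomial (dispersion 0.1, mean 20–500
  log-uniform) for a healthy and a bleaching library; 10% of
  mRNAs+lncRNAs planted as 4-fold differential (half up, half down).
  The NB/Poisson mismatch with the Audic–Claverie test is deliberate and
  documented so calibration robustness can be probed; the calibration
  acceptance check itself uses a Poisson null, matching the test's
  assumption.
* **Interaction plants**: 30-nt A/U-only segments spliced into lncRNAs,
  their exact reverse complements into target mRNAs' 3' regions, with a
  reference-database hit emitted over the segment. A/U-only composition
  is a physics choice, not a tuning knob: under the shipped stack table
  a full-length A/U duplex sits far below the −20 gate (≈ −35) while a
  half-length decoy sits far above it (≈ −15), giving the
  planted-vs-decoy contrast a margin on both sides. Decoys either move
  the emitted region elsewhere on the lncRNA or truncate the complement
  to half length.
* **Ground truth** is finalized *by construction*: the manifest's
  `expected_class` is the first failing cascade predicate computed from
  generator-side knowledge (planted evidence labels, realized counts,
  sequence primitives). A green planted-truth test therefore establishes
  that the cascade's evidence wiring, thresholds and trace logic are
  correct — the sequence-level primitives (ORF finder, k-mer scorer,
  duplex DP, enrichment statistic) are validated separately against
  independent brute-force oracles, not by the fixture.

What the generator does **not** emulate: read-level error profiles,
assembly artifacts and chimeras, positional coverage bias, homology
structure inside a class, or genuine secondary-structure constraints.
A green fixture test is evidence about the pipeline's logic, not about
biological discovery power.

## Numerical and degenerate-input policy

* Thresholds follow the published operating point exactly; boundary
  semantics: contaminant e-value strictly `<` 1e-3 (quoted "less
  than"), protein track `<=` 1e-4 and conserved-region `<=` cutoff
  (quoted "set to"), length `>= 300`, ORF `<= 75`, counts `>= 10`.
* Enrichment and Audic–Claverie tails are accumulated in log space with
  `logsumexp`; the AC upper tail is truncated only when the remaining
  geometric mass is below 1e-17 of the running sum.
* Sequences shorter than 3 nt yield no ORFs (not an error); empty
  FASTA files yield empty sets; an all-`N` transcript has k-mer score 0.
* Transcripts missing from the counts table count 0; evidence naming
  unknown transcript ids is dropped with a warning.
* KS p-values are asymptotic (series truncated at 100 terms, well below
  1e-12 truncation error for any statistic the tests exercise); an
  exact permutation option exists for small samples.

## Known limitations

* The duplex model ignores target-site accessibility, intramolecular
  structure and suboptimal ensembles; its energies are comparable
  *within* a run, not calibrated against experiment.
* The k-mer screen is a linear log-odds model, weaker than a trained
  SVM; with the external-label adapter the real tool can be used.
* The built-in local aligner is fixture-grade (quadratic DP, heuristic
  e-value `m·n·2^(−score/2)`); production evidence should come from real
  search tools in 12-column tabular form.
* Without replicates, differential-expression p-values inherit all the
  caveats of the Audic–Claverie model: overdispersion inflates the
  nominal type-I error, which is why the generator exposes a dispersion
  knob.
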