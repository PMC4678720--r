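---
title: "Predicting cellular IRES elements in fungal 5'-UTRs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting cellular IRES elements in fungal 5'-UTRs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Cellular internal ribosome entry sites (IRESs) recruit ribosomes to an
mRNA independently of the 5'-m7G cap. Under stress, when cap-dependent
initiation is suppressed, IRES-bearing transcripts stay translated —
which is why stress-response genes are over-represented among known
cellular IRESs. Fungal cellular IRESs are short, A-rich and weakly
structured: there is no conserved motif or fold to scan for, which
defeats alignment- and structure-based detectors. What remains is a
statistical signature, and the extreme scarcity of verified examples
(on the order of ten usable training positives against a candidate pool
of ~10^5 upstream windows) makes this a textbook rare-class learning
problem.

`iresfinder` addresses it with a fixed-window design: for every
protein-coding gene, the 60 nucleotides immediately upstream of the
translation initiation codon (the *60-nt UTR window*) are scored by a
polynomial-kernel support vector machine over 29 sequence, folding and
comparative-genomic features, the minority class being inflated by SMOTE
before training. Predictions are then filtered for evolutionary signal
(ortholog-group enrichment) and characterized on a protein-protein
interaction (PPI) network.

## Window extraction

Coordinates are 1-based and inclusive throughout (the GFF convention);
the single site where coordinates meet string indexing is `substr()`,
which uses the same convention, so there is no conversion arithmetic
anywhere. For a plus-strand gene the upstream window is
`chromosome[cds_start - 60, cds_start - 1]`; minus-strand genes take the
reverse complement of the mirrored interval, so every emitted window is
the sense (mRNA-equivalent) strand. Genes with less than 60 nt of
contig flank are skipped and logged rather than padded — padded windows
would have no meaningful folding energy. Windows overlapping an
upstream gene's CDS are taken verbatim (the window is fixed by design),
windows containing `N` are retained (every feature handles ambiguity
explicitly), and all-`N` windows are skipped. Multi-exon genes are
treated as single CDS spans (`min(start)..max(end)`): fungal genes are
intron-poor, and the upstream window of the span start is the
biologically relevant one. Contigs are treated as linear.

The negative-control window is the 60 *coding* nucleotides immediately
5' of the stop codon (`chromosome[cds_end - 62, cds_end - 3]` on the
plus strand, strand-mirrored otherwise). Since internal coding sequence
is not expected to harbor IRESs, positive calls there estimate the
pipeline's empirical false discovery rate; CDSs shorter than 63 nt are
skipped.

## The 29 features

| block | features | count |
|---|---|---|
| folding energy | `mfe` | 1 |
| relative GC | `relGCintergenic`, `relGCchr` | 2 |
| position | `relPosChr` | 1 |
| composition | `dinuc_AA` … `dinuc_TT` | 16 |
| ortholog-group dispersion | mean/mode/sd/skewness of `relGCintergenic` and of `mfe` | 8 |
| context | `intergenic_length` | 1 |

**Folding energy.** The default backend is a Nussinov-style dynamic
program (compiled, `src/fold.cpp`) that maximizes total base-pair weight
(GC = 3, AU = 2, GU wobble = 1) with a minimum hairpin loop of 3
unpaired nucleotides, returning the negated optimum in arbitrary units;
`N` pairs with nothing. This captures what the classifier needs —
pairing *potential*, which separates unstructured A-rich windows from
structured ones — while remaining fully self-contained and exactly
testable: the test suite checks it against exhaustive enumeration of
all admissible structures for sequences up to length 12. An `external`
backend delegates to a thermodynamic nearest-neighbor engine (`RNAfold`)
behind the same contract and returns kcal/mol. Because features are
standardized per organism downstream, the two backends' unit systems
are interchangeable for classification.

**Relative GC.** GC fractions carry a +1/+2 pseudocount
(`(G + C + 1) / (unambiguous + 2)`), which keeps the ratios finite for
GC-free windows and empty references. `relGCintergenic` divides the
window's GC by that of the gene's upstream intergenic region (the span
from the translation start to the nearest annotated CDS boundary on
either strand, or the contig edge); when that region is empty — abutting
or overlapping annotations — the chromosome GC is used as the reference
and the fallback is logged. `relGCchr` divides by the chromosome GC.

**Relative position.** Subtelomeric regions are enriched for
stress-responsive genes, so proximity to a chromosome end is
informative symmetrically for both arms. With gene midpoint *m* on a
chromosome of length *L*, `relPosChr = min(m - 1, L - m) / L`, in
[0, 0.5]: near 0 at either telomere, 0.5 at the center.

**Dinucleotide frequencies.** Overlapping counts of the 16 unambiguous
dinucleotides divided by the number of unambiguous overlapping
positions; any position touching an `N` leaves both numerator and
denominator. A fully ambiguous window scores 0 everywhere.

**Ortholog-group dispersion.** If IRES-dependent translation is
conserved within an orthologous group, the group's distribution of
window properties shifts as a whole. For each group, pooled across all
organisms over the members with an extractable window, the package
computes mean, mode, standard deviation (n−1 denominator; 0 for
singletons) and moment skewness (`m3 / m2^1.5`; 0 for n < 3 or zero
variance) of `relGCintergenic` and of `mfe`, and attaches the group's
values to each member. Ungrouped genes form singleton groups. The
*mode* of a continuous sample is not canonically defined; here it is
the midpoint of the most populated bin of a 10-bin histogram spanning
[min, max], with the lowest bin winning ties — a deterministic,
easily-audited choice isolated in one function (`group_statistics()`)
so an alternative (e.g. a kernel-density argmax) can be swapped in
without touching anything else.

## Preprocessing

Features are standardized to mean 0, variance 1 *within each organism*
(`standardize_features()`), which makes inter-species attributes
comparable; organism-level constant features map to 0 with a warning,
and an organism contributing a single gene is an error because its
variance is undefined. The fitted means and standard deviations are
part of the model and are re-applied verbatim to any prediction-time
data, including the negative-control windows.

Redundant features are then pruned at |Pearson r| > 0.55 on the pooled
standardized matrix with one deterministic greedy pass in canonical
column order: for each ordered pair (i < j) above the threshold, the
later feature is dropped if both are still retained. Pooling (rather
than per-organism correlation) yields a single global retained set;
keeping the earlier feature makes the pass deterministic and auditable,
and the audit log records every (dropped, kept, r) triple. Pruning an
already-pruned matrix is a no-op, which the tests assert.

## Balancing: SMOTE plus undersampling

With ~9 usable positives against ~10^5 candidates, the classifier would
otherwise learn to say "negative". `build_training_set()` produces
exactly `n_pos_out` positives (originals plus SMOTE interpolants) and
`n_neg_out` uniformly undersampled negatives; the reference
configuration is 5,000 : 12,500 (a 2.5:1 negative:positive ratio,
17,500 rows). Each synthetic row is `x_i + u (x_nn - x_i)` with
`u ~ U(0, 1)`, `x_i` cycling through the minority rows and `x_nn` drawn
uniformly from the `k_eff` nearest minority neighbors (Euclidean, on
the standardized pruned space — standardization makes this metric
scale-free). The conventional neighbor parameter k = 300 exceeds what
9 originals can offer, so the implementation is parameterized by target
output counts and clamps k to `n_minority - 1`, recording both the
requested and the effective value in the manifest. All randomness
derives from one seed.

## Classifier

A soft-margin SVM with the degree-2 polynomial kernel
`(gamma <x, x'> + coef0)^2` (e1071/libsvm), with per-class
misclassification costs 2 (positive) : 1 (negative) to favor
sensitivity on the rare class. Tuning, when requested, is a repeated
stratified 10-fold cross-validated grid search over 32 combinations
(8 kernel scales `gamma = 2^-7 … 2^0` × 4 costs `0.25, 1, 4, 16`),
selecting by mean accuracy with mean Cohen's kappa and then grid order
as tie-breaks.

Cross-validation folds are drawn on the *balanced* (post-SMOTE) set.
This matches the reference protocol but lets synthetic points derived
from a test-fold original leak into training folds, so fold metrics are
optimistic for truly unseen genes; the orthogonal negative-control FDR
estimate exists precisely to provide an honest error rate, and
re-balancing within folds can be had by calling `build_training_set()`
inside a custom fold loop.

Posterior probabilities use Platt scaling:
`P(IRES | f) = 1 / (1 + exp(A f + B))` fitted on the training decision
values by penalized maximum likelihood with smoothed targets
`(N+ + 1)/(N+ + 2)` and `1/(N- + 2)`, Newton iterations with
backtracking to gradient norm < 1e-8 (a stalled line search on a flat,
noise-like surface is treated as convergence, as in the reference
implementations). For a correctly oriented classifier the fitted slope
A is negative. The decision threshold is posterior ≥ 0.5; because the
Platt fit re-absorbs the class priors, this is deliberately *not* the
same boundary as the cost-weighted SVM sign — the class weights buy
sensitivity at the margin-fitting stage, the posterior reports
calibrated confidence.

The empirical FDR is
`100 × (positive calls on negative-control windows) / (positive calls
on upstream windows)`, valid because both sets contain one window per
analyzable gene.

## Enrichment and ranking

Over-representation of predictions in an ortholog group is the
one-sided Fisher exact (hypergeometric upper-tail) probability
`P(X ≥ k)` for `k` predicted members among `n` group members, `K` total
predictions, `N` universe genes — computed by the stable log-space
upper tail, and verified in the tests against exhaustive
binomial-coefficient sums for every table with N ≤ 25. The universe is
every gene with an analyzable upstream window. Benjamini-Hochberg
correction uses, by default, the groups actually tested (those with at
least one prediction) as the family; the full group catalog can be used
instead (`family = "all"`), which is the more conservative reading when
group counts are quoted against a database-wide family.

The ranking score of an SVM-positive gene is
`(1 - posterior) × group_p`, ascending, with top predictions at
score ≤ 0.05. The complement form makes "lower is better" coherent:
a strong posterior (→ 1) and a strongly enriched group (p → 0) both
drive the score toward 0. The group p is the BH-adjusted value by
default (raw available); genes in unenriched or absent groups use
p = 1, and SVM-negative genes are excluded outright rather than
allowed to sneak in through a tiny group p. A literal
`posterior × group_p` variant is exposed as a configuration switch for
comparison.

Generic term enrichment (`term_enrichment()`) applies the same Fisher +
BH machinery to any flat gene → term map; ontology-graph propagation is
intentionally out of scope.

## Network characterization

Interactions load from a STRING-style TSV (`node1`, `node2`,
`combined_score` 0–1000): self-loops dropped, duplicate edges merged
keeping the maximum score, and a minimum-score threshold of 400
("medium confidence") applied by default — the threshold, and whether
Louvain uses edge weights, are both configurable because published
practice varies; defaults are unweighted with score used only for
thresholding.

Cohesion is measured by density `2E / (n(n-1))`. Its null distribution
comes from simulation: sample m genes uniformly from the *entire*
protein-coding universe (genes absent from the interaction data enter
as isolated nodes and dilute density — omitting them would bias the
null upward), record the induced-subgraph density, repeat (default
10,000 replicates; a flag raises this to 100,000 when publication-grade
tail accuracy is worth the runtime — the inference contract is
identical). The replicates are Box-Cox transformed (shift 0 for
positive samples, otherwise −min plus half the smallest positive value,
or 10^-6 if all are zero — zeros are certain in sparse nulls; lambda by
profile maximum likelihood on a 0.01 grid over [−2, 2]) and the
p-value is the upper-tail normal probability of the transformed
observation under the transformed null's mean and standard deviation.
The tests verify this calibration directly: under the null the
p-values are uniform (Kolmogorov–Smirnov) for subgraphs of m = 80 on a
300-node background. For small subgraphs (m ≲ 40 on sparse networks)
the density support is too discrete for any continuous approximation
and the p-values develop visible steps — module reports on very small
modules should be read accordingly, and single-protein modules are
excluded from density statistics altogether since their density is
undefined.

Modules come from Louvain multi-level modularity optimization
(igraph, resolution 1, unweighted by default) with the sweep order
seeded for reproducibility. The per-module report gives size, density,
a density p-value against a size-matched null, and node degrees in the
full analyzed network.

## The synthetic-data generator

`generate_genomes()` emulates the statistical structure the method
assumes, not fungal biology: random-composition chromosomes
(A = T = 0.30, G = C = 0.20) with genes laid at 120–400 nt spacings on
random strands, ortholog groups spanning organisms, and a small set of
*planted* groups whose members (80% of them) carry upstream windows
drawn A-rich and GC-depleted (A = 0.45, T = 0.25, G = C = 0.15). The
GC depletion simultaneously suppresses pairing potential, so the
folding-energy feature separates the classes the way unstructured
A-rich IRESs do. The default configuration is 3 organisms × 2
chromosomes × 5,000 genes = 30,000 genes, ~3,000 ortholog groups, 8
planted groups — roughly 50–60 true positives, an order-10^-3 class
prevalence. What it does *not* emulate: codon structure, introns,
repeat content, GC isochores, phylogenetic correlation between
organisms, or any relationship between the interaction network and the
genomes. Passing the end-to-end tests therefore demonstrates that the
machinery recovers a planted compositional signal at realistic
imbalance — not that real fungal IRESs are detectable at any particular
accuracy.

`generate_labeled_features()` (two spherical Gaussians separated along
a random direction) supports classifier unit tests where the decision
geometry must be known exactly, and `generate_planted_partition()`
(stochastic block model) benchmarks module recovery.

## Problem sizes and numerical choices in the shipped tests

The end-to-end benchmark runs the full pipeline on the default 30,000
gene fixture with 9 training positives, a 600 : 1,500 balanced set
(the reference 2.5:1 ratio at benchmark scale) and 10-fold × 3
cross-validation — sizes chosen so the whole suite completes in a few
minutes on one CPU while every stage still operates in its intended
regime. The desk-scale checks exercise the reference configuration
itself (17,500-row balanced set; published contingency tables for the
enrichment and overlap statistics). Null-density simulations use
5,000–10,000 replicates; the folding and Fisher oracles are exhaustive
(length ≤ 12 sequences, N ≤ 25 tables). Determinism is asserted
bitwise: identical configuration and seed reproduce identical FASTA,
TSV and prediction artifacts.

## Known limitations

* The 60-nt window is fixed by design; IRESs further upstream, or
  elements whose activity depends on longer-range structure, are out of
  reach.
* The internal folding backend ranks pairing potential; its arbitrary
  units are fine for classification but are not free energies. Use the
  external backend when kcal/mol matter.
* CV metrics on the post-SMOTE set overstate generalization (see
  above); the negative-control FDR is the honest error estimate.
* Platt posteriors are fitted on training decision values; with very
  few true positives the calibration inherits their noise.
* The density null assumes exchangeable gene sampling; degree-biased
  gene sets (e.g. well-studied proteins) violate it and will look
  denser than random for reasons unrelated to the prediction set.
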