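---
title: "Divisive clustering of peak sequences: model and methods"
author: "divMotif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Divisive clustering of peak sequences: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divMotif)
```

## The problem

ChIP-seq experiments produce thousands of bound regions per factor, and the
bound sequence is rarely explained by a single crisp motif: co-factor
motifs, motif variants, dimers with variable spacing, and extended flanking
preferences all mix in one dataset.  Rather than fitting a fixed number of
short motif models, `divMotif` *clusters* the sequences: each input
sequence contributes one fixed-width window (width `W`, deliberately much
longer than a typical 7--15 bp binding site), whose placement and
orientation are free, and clusters are groups of windows that look like
draws from one position weight matrix (PWM).  Motifs then emerge as the
informative columns of each cluster's alignment, without the number or
length of motifs being specified in advance.

## The scoring model

A cluster `C` of `M` aligned windows is summarized by per-column nucleotide
counts `n_ia` (column `i`, base `a`).  Its score is the marginal likelihood
of the windows under one unknown PWM with a symmetric Dirichlet prior of
pseudocount `c` (default 0.5), computed column-wise in log space:

    log P(C) = sum_i [ sum_a lgamma(n_ia + c) + lgamma(4c)
                       - lgamma(N_i + 4c) - 4 lgamma(c) ]

with `N_i = sum_a n_ia`.  A single-window cluster reduces to `(1/4)^W`.
The predictive likelihood that a window `S` belongs to `C` is

    log P(S | C) = sum_i log( (n_i,S_i + c) / (N_i + 4c) )

and the two are linked exactly: `log P(C + S) - log P(C) = log P(S | C)`.

**Missing data.**  Windows may overhang their sequence by up to half their
width; overhanging positions are read as `N`.  An `N` contributes a flat
factor `1/4` to the predictive likelihood, adds nothing to `n_ia`, and is
excluded from `N_i`.  So that the additivity identity above holds *exactly*
also for windows containing `N`s, `log P(C)` carries a `log(1/4)` term per
`N` in the cluster (tracked in a fifth count row).  For N-free windows this
is the plain Dirichlet-multinomial expression.  `N`s inside genuine
sequence (masked bases) are treated identically to padding -- both are
uninformative missing data.

**Window search.**  For a sequence of length `L`, admissible 0-based window
starts are `-floor(W/2) .. L - ceiling(W/2) - 1` (at least half the window
overlaps the sequence), each on both strands: about `2L` configurations.
The reverse-strand window at offset `o` is the reverse complement of the
forward extraction at the mirrored offset `L - W - o`.  Ties in the search
are broken toward the smallest offset, forward before reverse, so runs are
deterministic given a seed.

## Splitting a cluster

A split proceeds in replicates.  The first replicate seeds the two-way
partition by ranking members by their leave-one-out predictive likelihood
and moving the best 25% to a new cluster; subsequent replicates move a
random 25% instead, giving genuinely independent initializations.  Each
replicate is then refined: members are visited in fresh random order,
removed from their cluster, re-scored with the full window search against
both clusters, and inserted into the more likely one, until a full sweep
changes nothing (sweep cap 200; fixed points typically arrive in well under
50 sweeps).

Two criteria guard acceptance:

1. **Reproducibility.**  Up to four replicate splits are compared by the
   adjusted Rand index (ARI) of their two-way labelings.  If the first
   three agree pairwise (all three ARIs `> r`, default `r = 0.2`) the
   fourth is skipped; otherwise at least three of the six pairwise ARIs
   must exceed `r`.  A replicate that empties a child fails all its
   comparisons.  Replicate labels are then matched by majority membership,
   and members not placed identically across the three consensus
   replicates are routed to a pooled "inconsistent" cluster.

2. **Significance.**  The log-likelihood ratio of the split --
   `log P(C1) + log P(C2) - log P(C1 u C2)`, evaluated on the consensus
   children -- must reach `L1 + T (L2 - L1)` (default `T = 0.4`).  `L1`
   and `L2` anchor the scale: they are the LLRs of idealized splits of
   `M` random sequences that separate cleanly ("one child only A or C,
   the other only G or T") on one and two columns respectively, with all
   other columns evenly distributed.  One clean column is always
   achievable by chance and is *not* significant; two clean columns are.

**Balanced idealization.**  The idealized `L1`/`L2` matrices use child
sizes `M/2` each, because a clean base-identity split of random sequences
is balanced by construction.  Evaluating the idealization at the observed
(possibly very unbalanced) child sizes was tried during development and is
defective: for accepted children like 580/20 the resulting threshold is
*negative*, so any reproducible noise split would be accepted.  With the
balanced form, splits of clusters drawn from a single PWM are reliably
rejected while genuine motif mixtures pass with large margins.

## The top-level loop

Starting from one cluster holding every sequence (centred forward
windows), every pass attempts to split every current cluster (clusters
smaller than `minSplitSize = 8` are never attempted).  Inconsistent
sequences from all of a pass's splits are concatenated into one pool
cluster, which gets an immediate split attempt in the pass that creates it
(mixed pools usually dissolve into their motif groups right away) and
remains an ordinary split candidate afterwards; it may also receive or
lose members during reassignment.  After every two
passes, when more than two clusters exist, the poorest-scoring 20% of all
sequences (leave-one-out predictive likelihood, total per window -- widths
are equal so totals are comparable) are re-examined one at a time: the
sequence is removed, its best window is scored against every cluster, and
it joins the argmax (staying put on ties).  After the splits of each pass, the split criterion is also applied in
reverse as a standing invariant: any two clusters whose division does not
reach the significance threshold are joined again.  This dissolves
duplicate clusters — when the pool re-splits into a motif that already has
a cluster, the duplicate cannot be distinguished from the original by the
method's own criterion and is merged into it.  Reassignment then relocates
individual stragglers (junk or weak-motif sequences misplaced by earlier
two-way cuts of multi-motif mixtures); the per-step fraction moved is
small once the state is clean, but can spike when an unsplittable mixed
pool is being drained.

The run terminates when a full even/odd pass cycle makes no splits *and*
no reassignments -- checking a single pass is not enough, because
reassignment only runs on alternate passes and may still be draining
clusters.  A pass budget of 50 bounds the loop; the budget has never been
reached on the benchmark datasets.  If more clusters remain than
`maxClusters` (default 15), pairs are merged by least likelihood loss
(`log P(Ci u Cj) - log P(Ci) - log P(Cj)` maximal) until the cap is met,
and the join order is recorded as a Newick dendrogram.

Per-split replicate randomness, sweep orders, and all generator draws flow
from one seed set at the start of `runClustering()`, so runs are exactly
reproducible.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `W` | `floor(median(L)/3)` bp | window width; wide on purpose, so flanking structure is captured |
| `pseudocount` | 0.5 | Dirichlet prior weight per base per column |
| `splitT` | 0.4 | position of the acceptance threshold between the `L1` and `L2` anchors |
| `ariThreshold` | 0.2 | pairwise replicate-ARI that counts as agreement |
| `reassignFraction` | 0.20 | poorest fraction re-examined per reassignment step |
| `initMoveFraction` | 0.25 | fraction moved by the initial seeding of a split |
| `minSplitSize` | 8 | below this, the Dirichlet-multinomial split statistics are degenerate |
| `maxClusters` | 15 | reporting cap, enforced by dendrogram merging |

## The synthetic benchmark generator

`generateDataset()` emulates the benchmark design the method is evaluated
on: 100-bp sequences with i.i.d. uniform background (each base 0.25), one
motif instance per sequence (a zero-or-one-occurrence design with
occurrence probability one), placed uniformly at random wholly inside the
central 40 bp, on a uniformly random strand.  Motif PWMs have a core of
5--10 columns drawn from a symmetric Dirichlet with hyperparameter
`dirichletC` (0.1 = sharp, 0.5 = weak) and flanks tapering to a
hyperparameter of 20 (essentially background).  The taper is geometric --
column `j` of `f` flank columns uses `dirichletC * (20/dirichletC)^(j/f)`
-- which is smooth, rapid, and hits both endpoints; the shape beyond those
properties is a free choice.  Planted strands are randomized so the
reverse-complement search is genuinely exercised.  `generateRuntimeSet()`
produces the timing variant: 1000-bp sequences, two 10-bp
core-only motifs (Dirichlet 0.2) in 60:40 proportion; placement stays in
the central 40 bp so the window search cost, not the placement zone,
dominates.

What the generator does *not* emulate: real peak-length distributions, GC
bias, repeats, multiple motif occurrences, or positional bias of binding
sites within peaks.  Passing the synthetic recovery tests therefore shows
the clustering machinery works under the model's own assumptions, not that
every real dataset will resolve as cleanly.

## Numerical and procedural choices

* All likelihoods stay in log space (nats); products over `W >= 33`
  columns underflow otherwise.
* Idealized threshold matrices use fractional counts (`M/4`, `M/8`)
  directly in the log-gamma functions, which are defined on positive
  reals.
* The consensus split handed back on acceptance is the first replicate of
  the consensus triple, filtered for inconsistency; when the fourth
  replicate was needed, the triple with the highest summed pairwise ARI is
  used (deterministic tie-break by replicate index).
* The degenerate ARI case (correction denominator zero, e.g. both
  partitions a single cluster) returns 1 for identical partitions and 0
  otherwise.
* Label matching across replicates or against truth is greedy
  maximum-overlap with deterministic tie-breaks; on small label sets it
  coincides with the exhaustive-search optimum in all tested cases.
* Benchmark problem sizes used in the tests and the acceptance script --
  up to 2000 sequences of 100 bp with three planted motifs, and 20
  replicate noise sets of 500 sequences for the spurious-split control --
  were chosen as the smallest sizes at which the acceptance behavior of
  the split criteria is clearly expressed.

## Known limitations

* One window per sequence: at most one motif occurrence per sequence is
  modeled (co-occurring motifs are captured only when their spacing fits
  inside one window).
* Columns are independent in the model; internal dependencies show up
  only through the clustering, not inside a cluster's PWM.
* The pool cluster can transiently duplicate an existing motif cluster;
  reassignment dissolves these, but runs stopped early (small
  `maxPasses`) may retain them.
* Very unbalanced true mixtures (a motif in a few percent of sequences)
  need enough absolute members (`minSplitSize`, and enough signal to clear
  the `L1`/`L2` threshold) to separate.
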