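---
title: "Benchmarking TFBS predictors with ChIP-seq peaks and sequence conservation"
author: "tfbsbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking TFBS predictors with ChIP-seq peaks and sequence conservation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfbsbench)
```

## The problem

Transcription factor binding sites (TFBS) are short (5-20 bp) DNA
segments bound by sequence-specific regulatory proteins. Scanning a
genome with a known binding motif produces vastly more candidate sites
than a factor actually binds, so the practical questions are (i) how
well different motif-scoring methods rank true sites above background,
and (ii) when cross-species sequence conservation ("phylogenetic
footprinting") helps. This package builds benchmark datasets for these
questions from ChIP-seq peak calls -- peaks are the positives, the
peak-free surroundings supply negatives -- and evaluates five scoring
methods on them: two that see only one genome (log-odds PWM scanning
and MotifScan k-mer nearest-neighbour scoring) and three that use a
multiple alignment (a weighted sum over aligned species windows, and
the Bayesian branch length score driven by either PWM or MotifScan leaf
scores).

Because the real inputs (genome-wide peak sets, 28-way alignments,
licensed motif libraries) are far beyond desk scale, the package also
contains a first-class simulator that evolves sequences along a
phylogeny with planted motif instances under purifying selection, so
the entire pipeline is testable end to end from nothing but a seed.

## Scoring methods

All methods emit one score per genomic position per strand; the score
at position $i$ refers to a motif whose 5' end starts at $i$ on that
strand, and minus-strand scores are reported at the forward coordinate
of the window start, so region maxima can be taken in one coordinate
system.

**PWM.** From a motif count matrix $n_{b,j}$ and background base
frequencies $p_b$ (obtained by counting bases in the reference
sequence), the log-odds matrix is
$$W_{b,j} = \log_2 \frac{(n_{b,j} + \alpha p_b) / (N_j + \alpha)}{p_b},$$
with pseudocount $\alpha = 1$ distributed across bases in proportion to
the background (the pseudocount keeps log-odds finite; a standard unit pseudocount is the conventional choice). A window
scores $\sum_j W_{s_{i+j-1},j}$. An ambiguous base contributes its
column's background expectation $\sum_b p_b W_{b,j}$ -- deterministic
and conservative. Motif information content is reported in the classic
uniform-background form $IC_j = 2 + \sum_b q_{b,j}\log_2 q_{b,j}$ bits
(so certainty gives 2 bits, a uniform column 0); a genome-background
relative-entropy variant is available behind a flag. The genome
background affects only the log-odds scores.

**MotifScan.** Instead of collapsing the motif's known binding k-mers
into one distribution, each window $x$ is compared with each motif
k-mer $m$ explicitly: the contribution is
$\prod_{j : m_j \ne x_j} s(m_j, x_j)$ when the Hamming distance is at
most $d_{\max}$, else 0; contributions are multiplicity-weighted,
summed over k-mers, and $\log_2(1+\cdot)$-transformed. The 4x4
substitution matrix $s$ is estimated from the column-wise base
co-occurrences in all available motif k-mer stacks, Laplace-smoothed,
symmetrised, normalised by its maximum, with the diagonal forced to 1.
(The original method's estimator is not public in detail; the above is
fixed as the reference behaviour and every piece -- $d_{\max} = 3$, sum aggregation, log
transform -- is configurable. Row-wise max normalisation would break
the symmetry the matrix is required to have, hence the global-maximum
normalisation.) The reverse strand scores the reverse-complemented
window against the same k-mers, because $s$ is not
complement-symmetric.

**Weighted sum (WS).** The baseline conservation method:
$$WS(i) = S_{\mathrm{ref}}(i) + \sum_s w_s \max_{j \in \mathrm{window}_s(i)} S_s(j),$$
where the species window is anchored by alignment columns (so indels
shift it correctly), reaches $h = 15$ bp beyond the motif footprint on
each side, its gap-free sequence is rescanned in the aligned species,
and the maximum is over window positions and both strands. Weights
default to $w_s = 0.25$ per aligned species (for two species the added
term is half the mean of the species maxima, keeping the reference
score dominant); the multiplier is fixed as the reference behaviour
and configurable. Species without alignment contribute 0, so unaligned
positions fall back to the reference score.

**BBLS.** The branch length score of a set of motif-bearing species is
the total branch length of the phylogenetic subtree spanning them. The
Bayesian form replaces the hard indicator with per-leaf presence
probabilities $p_i$: treating the tree as unrooted, each branch $b$
splits the leaves into sides $A(b)$ and $B(b)$ and
$$BBLS = \sum_b l(b)\Bigl(1 - \prod_{i \in A(b)}(1-p_i)\Bigr)\Bigl(1 - \prod_{i \in B(b)}(1-p_i)\Bigr),$$
which is exactly the expectation of the plain branch length score under
independent leaf presence (verified in the tests against exhaustive
$2^n$ enumeration). The reference leaf is always present
($p_{\mathrm{ref}} = 1$) because scoring is anchored at a concrete
reference position. Leaf probabilities come from each species' best
score over the aligned motif footprint, thresholded at a motif-specific
cutoff: the $q$-th percentile (default $q = 95$, linear interpolation)
of the reference genome's own per-position score distribution.
`calibrate_cutoff()` reproduces the calibration procedure: it evaluates
a percentile grid on calibration datasets and keeps the percentile with
the best mean ROC, ties broken toward higher ROC-50 and then the higher
percentile.

### Two BBLS design choices worth spelling out

*Window width.* Each species is scored over the aligned motif footprint
only ($h = 0$ by default, configurable in `bbls_config()`). A wide
window (say $h = 15$, i.e. 31 candidate starts) combined with a 95th
percentile per-position cutoff makes the per-species exceedance
probability in background sequence roughly $1 - 0.95^{31} \approx 0.8$,
which saturates the score at the full tree length across most of the
genome and -- under the conservative tie policy below -- collapses the
method's ranking power entirely. The original branch-length methods
score the aligned motif instance, which is what the footprint window
does.

*Leaf probability model.* Three models are implemented
(`leaf_probabilities()`): `binary` (above-cutoff leaves count as
certainly present), `soft` (every leaf gets its percentile rank in the
reference distribution), and the default `gated`: leaves above the
cutoff enter the calculation, weighted by their percentile rank rather
than rounded to 1. The gated model reflects the method's two stated
ingredients -- a cutoff deciding which leaves are used, and a
probability weighting each branch -- and keeps the score fine-grained.
Binary presence ties large numbers of regions at the exact total tree
length (species are correlated through shared ancestry, so joint
exceedances are common), and under negatives-first tie counting those
ties are charged entirely against the method; the fine-grained gated
score avoids this artefact and is the reason BBLS retains non-zero
early-retrieval (ROC-50) performance.

## Benchmark construction

**Site benchmark.** Every peak receives a test region of exactly
$L_T$ bp (default 20000; scaled-down fixtures use 2000) placed
uniformly at random around it, clipped inward at chromosome edges with
its length preserved. Overlapping regions are merged into a region
starting at the leftmost start with length equal to the *sum* of the
merged lengths -- this conserves the global ratio of peak to non-peak
sequence, and the merge repeats until no overlaps remain. The peak-free
remainder of each region, minus an exclusion mask (peak calls that did
not survive the stricter meta peak-calling, i.e. likely weak binding),
is cut into $c$-bp chunks (default 200) from each gap's left edge; a
terminal remainder of at least $c/2$ stands alone, shorter remainders
merge into the previous chunk, and gaps shorter than $c$ form a single
chunk. The remainder rule is the package's own reading of
"approximately equal length".

**Promoter benchmark.** Per gene, a promoter region (2000 bp upstream
to 200 bp downstream of the TSS, strand-aware) and a first-intron
region capped at 3000 bp downstream of the intron start. Among genes
with overlapping regions only the first in (chrom, start) order is kept
(either choice is defensible; this one is deterministic); peaks partially overlapping a region
extend it to contain them; negatives are the undivided peak-free
flanks.

## Evaluation

Each peak contributes one positive label (the maximum score over all
positions and strands inside the peak) and each negative sub-region one
negative label. The ROC is computed by sorting labels by descending
score **counting negatives before positives at tied scores**: the AUC
equals the fraction of (positive, negative) pairs where the positive is
strictly higher. This is deliberately conservative -- a method that hits
its score ceiling on many regions (as short PWMs do) cannot collect
credit from ties. If all scores are equal the AUC is 0. ROC-50
truncates the curve after the 50 highest-scoring negatives and
normalises the truncated area by $50 \times P$, so 1 means every
positive outranked the 50 best negatives and the value coincides with
the AUC whenever there are at most 50 negatives. (ROC-50 has no single agreed scale in the literature; this
normalisation makes values comparable across datasets and is the
package's documented convention.)

Method comparison across datasets uses the median and the plain median
absolute deviation (no consistency constant) of per-dataset AUCs, plus
one-sided Wilcoxon signed-rank tests on the paired AUCs: zeros dropped,
average ranks, and an exact tie-aware null distribution (computed by
convolution over signed ranks) for $n \le 25$, normal approximation
with tie correction above. Spearman correlations use average ranks;
their two-sided p-value is an exact full-permutation enumeration for
$n \le 9$ and the t-approximation above that ($10!$ permutations buy
nothing at the study's $n = 9$ and cost disproportionate memory).
Stratified evaluation keeps peaks strictly below the 10th / strictly
above the 90th height percentile (linear interpolation) with all
negatives retained. `positional_profile()` tallies, in a 500 bp window
centered on each peak midpoint, where the score maximum falls (ties to
the leftmost) and the per-offset mean of a per-base conservation track.

## The simulator

`simulate_bundle()` emulates the statistical structure the benchmark
assumes; its defaults are the package's fixed study conditions:

| parameter | default | rationale |
|---|---|---|
| tree | 5 mammal-like species, total branch length 1.57 subs/site | human/rodent/carnivore/marsupial-like depths |
| background | A,T 0.30; C,G 0.20 | mammalian AT-richness |
| reference length | 150 kb; 60 planted sites | one site per 2.5 kb, fits the 2 kb fixture regions |
| substitution model | Jukes-Cantor, rate 1 per unit branch length | no claim beyond single-parameter drift |
| site_conservation | 0.9 per branch | strong but imperfect purifying selection |
| peak height | 30 + 4 x (site log-odds) + N(0, 10), truncated at 0 | taller peaks mark stronger sites |
| peak length | uniform 100-400 bp | the trimmed ChIP-seq peak range |
| decoys | 25 background intervals | exercise the exclusion mask |

Sites are sampled from the motif's column distributions, planted
without overlap on a jittered grid, and evolved outward from the
reference leaf (Jukes-Cantor is reversible, so rooting at the reference
is exact); each planted site is frozen on a branch with its
conservation probability, otherwise it drifts at the background rate.
`conservation_range = c(lo, hi)` instead maps each site's conservation
from its peak-height rank, coupling conservation to binding strength.
Optional deletions (off by default) never hit planted sites, keeping
the ground truth exact. The conservation track stand-in is the
per-column identity fraction across species rescaled to $[-1, 1]$ --
sufficient to exercise profile and averaging code, not a real
evolutionary rate test. `sim_motif(width, dominance)` provides motifs
of controlled information content (dominance 0.7: ~0.64 bits/column;
0.95: ~1.63 bits/column).

What the simulator does *not* emulate: alignment errors and missing
species, context-dependent or lineage-specific substitution, indirect
(cofactor-mediated) binding, and read-level ChIP-seq noise. Passing
tests therefore show the machinery is correct and that the expected
qualitative behaviour emerges under idealised evolution -- not that the
methods would attain the same numbers on real data.

### The two headline experiments

The acceptance suite reruns, at fixed seeds, the two qualitative
findings the benchmark was built to expose:

1. *Conservation helps most on information-poor motifs.* An 8 bp,
   0.64 bits/column motif and a 12 bp, 1.63 bits/column motif are each
   planted under the default conditions; the (WS or BBLS) minus PWM AUC
   gap must be larger for the weak motif, and non-negative there. With
   the strong motif PWM is already near-perfect, so conservation has
   nothing to add.
2. *Conservation helps most on strong (tall) peaks.* Here conservation
   is coupled to height. This experiment uses 150 sites in 375 kb (so
   the >90th / <10th percentile strata hold ~15 peaks each rather than
   6 -- stratum AUCs on 6 positives are too noisy to compare) and a
   deliberately weak height-score link (50 + 1.5 x score + N(0, 15)):
   with the default strong link, peak height is nearly a proxy for PWM
   score, the PWM gains as much from high peaks as BBLS does, and the
   contrast is confounded. With height carrying mainly the conservation
   signal, the BBLS-PWM gap on the high stratum exceeds the gap on the
   low stratum, which is the finding under test.

## Numerical conventions and degenerate inputs

* Coordinates are 0-based half-open throughout; fixedStep wiggle starts
  and TRANSFAC position rows are converted at the parsing boundary.
* Percentiles (cutoffs, stratification) use linear interpolation
  (quantile type 7).
* Background frequencies floor unobserved bases at $10^{-4}$ before
  renormalising; an all-ambiguous sequence falls back to uniform with a
  warning.
* A sequence shorter than the motif yields an empty track with a
  warning; a zero-sum count-matrix column, inverted BED intervals,
  unbalanced newick parentheses, and single-class ROC inputs are
  errors.
* Negative sub-regions flush against a chromosome's scorable tail (too
  short to host any motif start) are dropped from labeling with a
  warning; peaks in that position are an error.
* Motif k-mers with ambiguity codes are rejected outright, keeping
  k-mer set semantics exact.
* All simulations in the tests and the acceptance script run at the
  problem sizes stated above (30-375 kb, 6-150 sites), chosen so the
  full suite completes in about a minute while keeping the stochastic
  assertions stable across seeds.

## Limitations

The MotifScan scoring formula and parameter settings, the WS weight,
and the exact ROC-50 normalisation are reference interpretations of
methods whose precise published values are not fully specified; all
are parameterised and documented above. The BBLS here is the expectation-of-BLS reading with gated
rank-based leaf probabilities -- a reconstruction, not the original
authors' code. Benchmarks built from real peak data inherit every bias
of peak calling and of cell-context-specific binding; the conservative
tie policy deliberately penalises coarse-grained scorers, which should
be kept in mind when comparing methods whose score resolution differs.
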