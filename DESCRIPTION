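Package: tfbsbench
Title: Benchmarking Transcription Factor Binding Site Predictors with
    ChIP-Seq Peaks and Sequence Conservation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to build ChIP-seq based benchmarks for transcription
    factor binding site (TFBS) prediction and to evaluate motif-scoring
    methods on them. Implements two single-genome scoring methods
    (log-odds position weight matrix scanning and MotifScan-style k-mer
    nearest-neighbour scoring) and three conservation-based methods (a
    weighted sum over aligned species windows and the Bayesian branch
    length score with either PWM or MotifScan leaf scores), together
    with site and promoter benchmark construction from peak calls,
    max-score ROC and ROC-50 evaluation with a conservative
    negatives-first tie policy, peak-height stratification, Wilcoxon and
    Spearman method comparisons, and a phylogeny-aware sequence
    simulator that plants motif instances under purifying selection so
    the full pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
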