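# Max-score labeling, ROC/ROC-50 against pair-counting oracles, the tie
# policy, stratification, and the comparison statistics.

make_labels <- function(pos, neg) {
  data.frame(score = c(pos, neg),
             label = rep(c("positive", "negative"), c(length(pos), length(neg))),
             region_id = "r", height = NA_real_, stringsAsFactors = FALSE)
}

test_that("label_scores takes interval maxima per peak and negative", {
  trk <- score_track("r", "pwm", 3, fwd = c(1, 5, 2, 0, 7, 1, 1, 1),
                     rev = c(0, 0, 9, 0, 0, 0, 2, 0), offset = 100)
  ds <- benchmark_dataset(
    "t",
    regions = data.frame(region_id = "r", chrom = "c", start = 100,
                         end = 110, kind = "site"),
    peaks = data.frame(region_id = "r", chrom = "c", start = 101, end = 104,
                       height = 3),
    negatives = data.frame(region_id = "r", chrom = "c",
                           start = c(104, 106), end = c(106, 110)))
  lab <- label_scores(ds, list(r = trk))
  expect_equal(nrow(lab), 3)
  expect_equal(lab$score[lab$label == "positive"], 9)  # max over strands
  expect_equal(sort(lab$score[lab$label == "negative"]), c(2, 7))
  expect_error(label_scores(ds, list()), "no score track")
})

test_that("roc_auc matches strict-pair counting with negatives-first ties", {
  set.seed(55)
  for (rep in 1:60) {
    P <- sample(2:15, 1); N <- sample(2:30, 1)
    # integer grid forces plenty of ties
    sc <- sample(1:6, P + N, replace = TRUE) + 0
    is_pos <- rep(c(TRUE, FALSE), c(P, N))
    r <- roc_auc(sc, is_pos)
    expect_identical(r$auc, oracle_auc(sc, is_pos))
    expect_identical(r$roc50, oracle_roc50(sc, is_pos))
    expect_identical(roc50(sc, is_pos), oracle_roc50(sc, is_pos))
  }
})

test_that("degenerate ROC cases follow the conservative policy", {
  expect_equal(roc_auc(c(3, 2, 1), c(TRUE, FALSE, FALSE))$auc, 1)
  expect_equal(roc_auc(rep(1, 5), c(TRUE, TRUE, FALSE, FALSE, FALSE))$auc, 0)
  expect_equal(roc50(c(3, 2, 1), c(TRUE, FALSE, FALSE)), 1)
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "at least one")
})

test_that("negatives-first AUC is bounded by mid-rank AUC, equal iff no
           cross-class ties", {
  set.seed(77)
  for (rep in 1:40) {
    P <- sample(2:10, 1); N <- sample(2:20, 1)
    sc <- sample(1:5, P + N, replace = TRUE) + 0
    is_pos <- rep(c(TRUE, FALSE), c(P, N))
    strict <- roc_auc(sc, is_pos, ties = "negatives_first")$auc
    mid <- roc_auc(sc, is_pos, ties = "midrank")$auc
    expect_lte(strict, mid + 1e-12)
    has_tie <- any(outer(sc[is_pos], sc[!is_pos], "=="))
    if (has_tie) expect_lt(strict, mid) else expect_equal(strict, mid)
  }
})

test_that("roc50 equals auc when there are at most 50 negatives", {
  set.seed(88)
  sc <- rnorm(40)
  is_pos <- sample(c(TRUE, FALSE), 40, replace = TRUE, prob = c(.3, .7))
  r <- roc_auc(sc, is_pos)
  expect_equal(r$roc50, r$auc, tolerance = 1e-12)
})

test_that("stratification keeps strict percentile membership", {
  set.seed(3)
  peaks <- data.frame(region_id = sprintf("r%02d", 1:50), chrom = "c",
                      start = 1:50 * 100, end = 1:50 * 100 + 50,
                      height = sample(1:1000, 50))
  ds <- benchmark_dataset("t",
                          regions = data.frame(region_id = peaks$region_id,
                                               chrom = "c",
                                               start = peaks$start - 10,
                                               end = peaks$end + 10,
                                               kind = "site"),
                          peaks = peaks,
                          negatives = peaks[0, c("region_id", "chrom",
                                                 "start", "end")])
  st <- stratify_by_height(ds)
  qs <- stats::quantile(peaks$height, c(.1, .9), type = 7, names = FALSE)
  expect_true(all(st$low$peaks$height < qs[1]))
  expect_true(all(st$high$peaks$height > qs[2]))
  expect_true(max(st$low$peaks$height) <= min(st$high$peaks$height))
  expect_identical(st$low$negatives, ds$negatives)
  flat <- ds; flat$peaks$height <- 7
  expect_error(stratify_by_height(flat), "empty stratum")
})

test_that("signed-rank test is exact, drops zeros, matches enumeration", {
  # n = 9, all differences positive: p = 1 / 2^9
  w <- wilcoxon_signed_rank(2:10, 1:9)
  expect_equal(w$p_value, 1 / 512, tolerance = 1e-12)
  # identical vectors: p = 1 by convention
  expect_equal(wilcoxon_signed_rank(1:5, 1:5)$p_value, 1)
  set.seed(101)
  for (rep in 1:15) {
    n <- sample(4:10, 1)
    x <- round(rnorm(n), 1)
    y <- round(rnorm(n), 1)  # rounding induces ties and zeros
    expect_equal(wilcoxon_signed_rank(x, y)$p_value,
                 oracle_wilcoxon_enum(x, y), tolerance = 1e-12)
  }
  # tie-free case agrees with stats::wilcox.test's exact distribution
  set.seed(102)
  x <- rnorm(12); y <- rnorm(12)
  ref <- stats::wilcox.test(x, y, paired = TRUE, alternative = "greater",
                            exact = TRUE)$p.value
  expect_equal(wilcoxon_signed_rank(x, y)$p_value, ref, tolerance = 1e-12)
})

test_that("compare_methods reports medians, plain MAD and pairwise p", {
  set.seed(5)
  auc <- rbind(a = runif(9, .6, .8), b = runif(9, .5, .7))
  res <- compare_methods(auc)
  expect_equal(res$summary$median, unname(apply(auc, 1, median)))
  expect_equal(res$summary$mad[1],
               median(abs(auc[1, ] - median(auc[1, ]))))
  expect_equal(res$p_values["a", "a"], 1)  # self-comparison: all zeros
  expect_equal(res$p_values["a", "b"],
               wilcoxon_signed_rank(auc["a", ], auc["b", ])$p_value)
  expect_equal(compare_methods(rbind(a = c(1, 1, 1), b = c(0, 0, 0)))$summary$mad,
               c(0, 0))
  bad <- auc; bad[1, 1] <- NA
  expect_error(compare_methods(bad), "missing")
})

test_that("spearman_cor matches full permutation enumeration at n = 9", {
  expect_equal(spearman_cor(1:6, c(2, 4, 6, 8, 10, 12))$rho, 1)
  expect_equal(spearman_cor(1:6, 6:1)$rho, -1)
  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
  set.seed(7)
  x <- rnorm(9); y <- rnorm(9)
  res <- spearman_cor(x, y)
  expect_true(res$exact)
  expect_equal(res$rho, cor(x, y, method = "spearman"))
  # reference: cor.test's exact Spearman p (no ties at n = 9)
  ref <- stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value
  expect_equal(res$p_value, ref, tolerance = 1e-9)
  # t-approximation path for larger n
  x2 <- rnorm(20); y2 <- x2 + rnorm(20)
  res2 <- spearman_cor(x2, y2)
  expect_false(res2$exact)
  expect_lt(res2$p_value, 0.05)
})

test_that("positional profiles locate planted maxima and average tracks", {
  score <- rep(0, 2000)
  cons <- rep(0.5, 2000)
  peaks <- data.frame(chrom = "c", start = c(900, 1400), end = c(1100, 1600),
                      height = c(10, 20))
  score[1001] <- 5  # 0-based position 1000 = midpoint of peak 1
  prof <- positional_profile(peaks, score, cons, flank = 250)
  expect_equal(sum(prof$argmax_counts), 2)
  expect_equal(prof$argmax_counts[251], 1)  # center offset for peak 1
  expect_equal(unique(prof$conservation_profile), 0.5)
  expect_equal(prof$peak_conservation$mean_conservation, c(0.5, 0.5))
  # out-of-bounds window is skipped with a warning
  edge <- data.frame(chrom = "c", start = 0, end = 100, height = 1)
  expect_warning(p2 <- positional_profile(edge, score, cons), "skipped")
  expect_equal(sum(p2$argmax_counts), 0)
})
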