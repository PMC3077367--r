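# Max-score region labeling, ROC and ROC-50 with the conservative
# negatives-first tie policy, peak-height stratification, and the summary
# statistics used to compare methods across datasets.

#' Label benchmark regions with their maximum scores
#'
#' One positive score per peak and one negative score per negative
#' sub-region: the maximum, over both strands, of all motif-start
#' positions inside the interval. A motif start belongs to an interval
#' when it lies in [start, end).
#'
#' @param dataset a [benchmark_dataset()].
#' @param tracks named list of [score_track()], one per region id, each
#'   covering its region (track offset = region start).
#' @return data.frame of class \code{labeled_scores}: \code{score},
#'   \code{label} ("positive"/"negative"), \code{region_id},
#'   \code{height} (peak height, NA for negatives).
#' @export
label_scores <- function(dataset, tracks) {
  interval_max <- function(track, start, end) {
    i0 <- max(start - track$offset + 1, 1)
    i1 <- min(end - track$offset, length(track$fwd))
    if (i1 < i0) return(NA_real_)
    max(track$fwd[i0:i1], track$rev[i0:i1])
  }
  get_track <- function(rid) {
    tr <- tracks[[rid]]
    if (is.null(tr)) stop(sprintf("no score track for region '%s'", rid))
    tr
  }
  pos <- lapply(seq_len(nrow(dataset$peaks)), function(i) {
    p <- dataset$peaks[i, ]
    s <- interval_max(get_track(p$region_id), p$start, p$end)
    if (is.na(s)) stop(sprintf("peak in region '%s' not covered by its track",
                               p$region_id))
    data.frame(score = s, label = "positive", region_id = p$region_id,
               height = p$height, stringsAsFactors = FALSE)
  })
  neg <- lapply(seq_len(nrow(dataset$negatives)), function(i) {
    n <- dataset$negatives[i, ]
    tr <- get_track(n$region_id)
    s <- interval_max(tr, n$start, n$end)
    if (is.na(s)) {
      # a sub-region flush against the track's tail can be too short to
      # host a motif start; anything else is a caller error
      if (n$start - tr$offset + 1 > length(tr$fwd)) return(NULL)
      stop(sprintf("negative interval in region '%s' not covered by its track",
                   n$region_id))
    }
    data.frame(score = s, label = "negative", region_id = n$region_id,
               height = NA_real_, stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(neg, is.null, TRUE))
  if (dropped > 0) {
    warning(sprintf(
      "%d negative sub-region(s) beyond the scorable track tail dropped",
      dropped))
  }
  out <- do.call(rbind, c(pos, neg))
  class(out) <- c("labeled_scores", class(out))
  out
}

#' ROC area under the curve with negatives-first tie handling
#'
#' Labels are sorted by descending score; within a tied score all
#' negatives are counted before all positives (the conservative policy: a
#' method that cannot rank a positive above a tied negative gets no credit
#' for it). The AUC then equals the fraction of (positive, negative) pairs
#' in which the positive scores strictly higher. \code{ties = "midrank"}
#' gives the usual convention where cross-class ties contribute half a
#' pair.
#'
#' @param scores numeric vector, or a \code{labeled_scores} data.frame (in
#'   which case \code{labels} is taken from it).
#' @param labels character/logical vector: "positive"/"negative" or
#'   TRUE/FALSE.
#' @param ties \code{"negatives_first"} (default) or \code{"midrank"}.
#' @return object of class \code{roc_result}: \code{auc}, \code{roc50},
#'   \code{curve} (data.frame of fp/tp counts), \code{n_pos}, \code{n_neg}.
#' @export
roc_auc <- function(scores, labels = NULL,
                    ties = c("negatives_first", "midrank")) {
  ties <- match.arg(ties)
  parsed <- parse_labels(scores, labels)
  pos <- parsed$pos; neg <- parsed$neg
  P <- length(pos); N <- length(neg)
  if (P == 0 || N == 0) stop("ROC needs at least one positive and one negative")
  ns <- sort(neg)
  n_less <- findInterval(pos, ns, left.open = TRUE)   # negatives < each pos
  n_leq <- findInterval(pos, ns)                      # negatives <= each pos
  strict_pairs <- sum(n_less)
  tie_pairs <- sum(n_leq - n_less)
  auc <- if (ties == "negatives_first") {
    strict_pairs / (P * N)
  } else {
    (strict_pairs + 0.5 * tie_pairs) / (P * N)
  }
  # stepwise curve under negatives-first ordering
  all_scores <- c(pos, neg)
  is_pos <- rep(c(TRUE, FALSE), c(P, N))
  ord <- order(-all_scores, is_pos)   # ties: negatives (FALSE) first
  tp <- cumsum(is_pos[ord]); fp <- cumsum(!is_pos[ord])
  curve <- data.frame(fp = c(0, fp), tp = c(0, tp))
  structure(list(auc = auc, roc50 = roc50_pairs(pos, ns, P, N),
                 curve = curve, n_pos = P, n_neg = N),
            class = "roc_result")
}

parse_labels <- function(scores, labels) {
  if (is.data.frame(scores)) {
    labels <- scores$label
    scores <- scores$score
  }
  if (is.character(labels)) labels <- labels == "positive"
  stopifnot(length(scores) == length(labels))
  list(pos = scores[labels], neg = scores[!labels])
}

roc50_pairs <- function(pos, ns, P, N, n_stop = 50L) {
  m <- min(n_stop, N)
  top_neg <- ns[seq(N, N - m + 1L)]   # m highest-scoring negatives, desc
  # positives strictly above each of the first m negatives
  pos_sorted <- sort(pos)
  above <- P - findInterval(top_neg, pos_sorted)
  sum(above) / (m * P)
}

#' ROC-50 score
#'
#' The ROC curve is truncated after the 50th negative (negatives counted
#' before tied positives) and the truncated area is normalised by 50 x P,
#' so a method that ranks every positive above the 50 best-scoring
#' negatives scores 1 and a method with no positive above them scores 0.
#' With fewer than 50 negatives the truncation point is all of them and
#' the normalisation matches, making ROC-50 equal to the full AUC.
#'
#' @inheritParams roc_auc
#' @param n_stop number of negatives at which to stop (default 50).
#' @return scalar in [0, 1].
#' @export
roc50 <- function(scores, labels = NULL, n_stop = 50L) {
  parsed <- parse_labels(scores, labels)
  pos <- parsed$pos; neg <- parsed$neg
  P <- length(pos); N <- length(neg)
  if (P == 0 || N == 0) stop("ROC needs at least one positive and one negative")
  roc50_pairs(pos, sort(neg), P, N, n_stop)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC %.4f, ROC-50 %.4f (%d positives, %d negatives)\n",
              x$auc, x$roc50, x$n_pos, x$n_neg))
  invisible(x)
}

#' Stratification thresholds configuration
#' @param low,high peak-height percentiles bounding the strata (defaults
#'   10 and 90).
#' @export
stratify_config <- function(low = 10, high = 90) {
  stopifnot(low > 0, low < high, high < 100)
  structure(list(low = low, high = high), class = "stratify_config")
}

#' Split a benchmark by peak height
#'
#' Returns two sub-datasets: one whose positives are the peaks with height
#' strictly below the low percentile, one with height strictly above the
#' high percentile (linear-interpolation percentiles). Negatives are
#' retained unchanged in both, so ROC can be recomputed per stratum.
#'
#' @param dataset a [benchmark_dataset()] whose peaks carry heights.
#' @param cfg a [stratify_config()].
#' @return list with elements \code{low} and \code{high}
#'   ([benchmark_dataset()]s) and the numeric \code{thresholds}.
#' @export
stratify_by_height <- function(dataset, cfg = stratify_config()) {
  h <- dataset$peaks$height
  if (length(h) == 0) stop("dataset has no peaks")
  qs <- stats::quantile(h, c(cfg$low, cfg$high) / 100, type = 7,
                        names = FALSE)
  low_idx <- which(h < qs[1]); high_idx <- which(h > qs[2])
  if (length(low_idx) == 0 || length(high_idx) == 0) {
    stop("empty stratum: peak heights do not spread across the percentiles")
  }
  subset_ds <- function(idx, tag) {
    benchmark_dataset(paste0(dataset$dataset_id, "_", tag),
                      dataset$regions, dataset$peaks[idx, , drop = FALSE],
                      dataset$negatives, dataset$config)
  }
  list(low = subset_ds(low_idx, "low"), high = subset_ds(high_idx, "high"),
       thresholds = qs)
}

#' One-sided Wilcoxon signed-rank test (exact, tie-aware)
#'
#' Paired test of whether \code{x} tends to exceed \code{y}. Zero
#' differences are dropped (Wilcoxon's convention); absolute differences
#' are ranked with average ranks. For n <= \code{exact_limit} the p-value
#' is exact, computed by convolving the signed-rank generating function
#' (valid under ties); above it a normal approximation with tie correction
#' and continuity correction is used. All differences zero gives p = 1 by
#' convention.
#'
#' @param x,y paired numeric vectors.
#' @param exact_limit largest n for the exact distribution (default 25).
#' @return list with \code{statistic} (W+), \code{n} (non-zero pairs),
#'   \code{p_value}, \code{exact}.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_limit = 25L) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(statistic = 0, n = 0L, p_value = 1, exact = TRUE))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_limit) {
    # distribution of W+ over all 2^n sign assignments, on a half-rank grid
    r2 <- round(2 * r)
    total <- sum(r2)
    f <- c(1, rep(0, total))   # f[s + 1] = #assignments with 2*W+ = s
    for (ri in r2) {
      g <- f
      g[(ri + 1):(total + 1)] <- g[(ri + 1):(total + 1)] + f[1:(total + 1 - ri)]
      f <- g
    }
    p <- sum(f[(round(2 * W) + 1):(total + 1)]) / 2^n
    list(statistic = W, n = n, p_value = p, exact = TRUE)
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (W - mu - 0.5) / sqrt(sigma2)
    list(statistic = W, n = n, p_value = stats::pnorm(z, lower.tail = FALSE),
         exact = FALSE)
  }
}

#' Compare methods across benchmark datasets
#'
#' Given a matrix of per-dataset ROC AUCs (rows = methods, columns =
#' datasets), reports per-method median and median absolute deviation
#' (plain MAD, no consistency constant) and, for every ordered method
#' pair, the one-sided exact Wilcoxon signed-rank p-value that the row
#' method outperforms the column method on the paired per-dataset AUCs.
#'
#' @param auc_matrix numeric matrix, methods x datasets, no missing cells.
#' @return list with \code{summary} (data.frame: method, median, mad) and
#'   \code{p_values} (square matrix; entry [i, j] tests method i > method
#'   j).
#' @export
compare_methods <- function(auc_matrix) {
  stopifnot(is.matrix(auc_matrix), nrow(auc_matrix) >= 2L,
            ncol(auc_matrix) >= 2L)
  if (anyNA(auc_matrix)) stop("missing cells in the AUC table")
  methods <- rownames(auc_matrix)
  if (is.null(methods)) methods <- paste0("method", seq_len(nrow(auc_matrix)))
  summary <- data.frame(
    method = methods,
    median = apply(auc_matrix, 1, stats::median),
    mad = apply(auc_matrix, 1, function(x) stats::mad(x, constant = 1)),
    stringsAsFactors = FALSE)
  k <- nrow(auc_matrix)
  p <- matrix(NA_real_, k, k, dimnames = list(methods, methods))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      p[i, j] <- wilcoxon_signed_rank(auc_matrix[i, ],
                                      auc_matrix[j, ])$p_value
    }
  }
  list(summary = summary, p_values = p)
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Rank correlation with average ranks for ties. The two-sided p-value is
#' exact (full permutation enumeration) for n <= 9 and uses the
#' t-approximation above that.
#'
#' @param x,y numeric vectors of equal length >= 3; constant vectors are
#'   an error (the correlation is undefined).
#' @return list with \code{rho}, \code{p_value}, \code{exact}.
#' @export
spearman_cor <- function(x, y) {
  n <- length(x)
  stopifnot(n == length(y), n >= 3)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop("Spearman correlation undefined for a constant vector")
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 9) {
    perms <- all_permutations(n)
    # rho is linear in sum(rx * ry[perm]); enumerate that sum
    S_obs <- sum(rx * ry)
    S_perm <- as.vector(perms_apply_sum(perms, rx, ry))
    mu <- n * mean(rx) * mean(ry)
    p <- mean(abs(S_perm - mu) >= abs(S_obs - mu) - 1e-9)
    list(rho = rho, p_value = p, exact = TRUE)
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    list(rho = rho, p_value = 2 * stats::pt(-abs(tstat), df = n - 2),
         exact = FALSE)
  }
}

# All permutations of 1..n as an n! x n integer matrix (n <= 9).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n)
  for (pos in seq_len(n)) {
    block <- matrix(0L, nrow(sub), n)
    block[, pos] <- n
    block[, -pos] <- sub
    out[[pos]] <- block
  }
  do.call(rbind, out)
}

perms_apply_sum <- function(perms, rx, ry) {
  # sum_i rx[i] * ry[perm[i]] for every permutation (rows)
  matrix(ry[perms], nrow = nrow(perms)) %*% rx
}

#' Positional score / conservation profile around peak centers
#'
#' For a window of 2 x \code{flank} bp centered on each peak midpoint,
#' tallies the offset of the maximum-scoring position (ties go to the
#' leftmost) and averages the per-base conservation values per offset.
#' Also returns the mean conservation over each full peak region, for
#' low/high peak comparisons. Peaks whose window exceeds the available
#' positions are skipped with a warning.
#'
#' @param peaks peak data.frame (chrom/start/end/height).
#' @param score numeric vector of per-position scores for the peaks'
#'   chromosome (index i = 0-based position i - 1), e.g. a
#'   \code{track_best} vector.
#' @param conservation numeric vector of per-base conservation values
#'   (e.g. a phyloP track), same indexing.
#' @param flank half-window in bp (default 250 for a 500 bp window).
#' @return list with \code{argmax_counts} (integer vector over offsets
#'   0..2*flank-1), \code{conservation_profile} (mean per offset),
#'   \code{peak_conservation} (data.frame with per-peak mean and height).
#' @export
positional_profile <- function(peaks, score, conservation, flank = 250L) {
  w <- 2L * flank
  counts <- integer(w)
  cons_sum <- numeric(w); cons_n <- integer(w)
  per_peak <- list()
  skipped <- 0L
  for (i in seq_len(nrow(peaks))) {
    center <- floor((peaks$start[i] + peaks$end[i]) / 2)
    a <- center - flank            # 0-based window start
    if (a < 0 || a + w > length(score) || a + w > length(conservation)) {
      skipped <- skipped + 1L
      next
    }
    win <- score[(a + 1):(a + w)]
    counts[which.max(win)] <- counts[which.max(win)] + 1L
    cwin <- conservation[(a + 1):(a + w)]
    cons_sum <- cons_sum + cwin; cons_n <- cons_n + 1L
    p0 <- max(peaks$start[i], 0) + 1
    p1 <- min(peaks$end[i], length(conservation))
    per_peak[[length(per_peak) + 1L]] <- data.frame(
      peak = i, height = peaks$height[i],
      mean_conservation = mean(conservation[p0:p1]))
  }
  if (skipped > 0) {
    warning(sprintf("%d peak(s) skipped: window exceeds sequence bounds",
                    skipped))
  }
  list(argmax_counts = counts,
       conservation_profile = ifelse(cons_n > 0, cons_sum / cons_n, NA_real_),
       peak_conservation = if (length(per_peak)) do.call(rbind, per_peak)
       else data.frame(peak = integer(0), height = numeric(0),
                       mean_conservation = numeric(0)))
}
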