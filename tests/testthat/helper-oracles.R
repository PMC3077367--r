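# Independent brute-force oracles used across the test files. These stay
# deliberately naive (nested loops, exhaustive enumeration) so they share
# no code path with the implementation they check.

# Naive PWM scan: per-position, per-strand lookup loop.
oracle_scan_pwm <- function(seq, pwm) {
  bases <- strsplit(toupper(seq), "")[[1]]
  L <- pwm$length
  n <- length(bases) - L + 1
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  col_score <- function(b, j, W, bg) {
    if (b %in% names(bg)) W[b, j] else sum(bg * W[, j])
  }
  # an unknown plus-strand base X ~ bg appears as comp(X) in the reverse
  # window, so ambiguous bases there are weighted by the complement bg
  bg_rc <- stats::setNames(pwm$bg[comp[names(pwm$bg)]], names(pwm$bg))
  fwd <- rev <- numeric(n)
  for (i in seq_len(n)) {
    win <- bases[i:(i + L - 1)]
    fwd[i] <- sum(vapply(seq_len(L), function(j)
      col_score(win[j], j, pwm$W, pwm$bg), 0))
    # reverse strand: motif on the minus strand, 5' end at the window end
    rcwin <- rev(unname(ifelse(win %in% names(comp), comp[win], "N")))
    rev[i] <- sum(vapply(seq_len(L), function(j)
      col_score(rcwin[j], j, pwm$W, bg_rc), 0))
  }
  list(fwd = fwd, rev = rev)
}

# Naive MotifScan: explicit loop over windows and k-mers.
oracle_scan_motifscan <- function(seq, kmers, submat, cfg) {
  bases <- strsplit(toupper(seq), "")[[1]]
  k <- kmers$k
  n <- length(bases) - k + 1
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  s <- submat$s
  one_window <- function(win) {
    agg <- 0
    for (m in seq_along(kmers$kmers)) {
      mk <- strsplit(kmers$kmers[m], "")[[1]]
      w <- 1; ham <- 0
      for (j in seq_len(k)) {
        b <- win[j]
        if (!b %in% names(comp)) {  # ambiguous base: always a mismatch
          ham <- ham + 1
          w <- w * min(s[mk[j], ])
        } else if (b != mk[j]) {
          ham <- ham + 1
          w <- w * s[mk[j], b]
        }
      }
      contrib <- if (ham <= cfg$d_max) w else 0
      agg <- if (cfg$aggregation == "sum") agg + kmers$mult[m] * contrib
             else max(agg, contrib)
    }
    if (cfg$log2_transform) log2(1 + agg) else agg
  }
  fwd <- rev <- numeric(n)
  for (i in seq_len(n)) {
    win <- bases[i:(i + k - 1)]
    fwd[i] <- one_window(win)
    rcwin <- rev(unname(ifelse(win %in% names(comp), comp[win], "N")))
    rev[i] <- one_window(rcwin)
  }
  list(fwd = fwd, rev = rev)
}

# Strict-pair-count ROC AUC with negatives-first ties (double loop).
oracle_auc <- function(scores, is_pos) {
  pos <- scores[is_pos]; neg <- scores[!is_pos]
  wins <- 0
  for (p in pos) for (q in neg) if (p > q) wins <- wins + 1
  wins / (length(pos) * length(neg))
}

# Truncated ROC-50 by explicit negatives-first walk down the ranking.
oracle_roc50 <- function(scores, is_pos, n_stop = 50) {
  ord <- order(-scores, is_pos)  # ties: negatives first
  P <- sum(is_pos)
  m <- min(n_stop, sum(!is_pos))
  area <- 0; tp <- 0; fp <- 0
  for (i in ord) {
    if (is_pos[i]) {
      tp <- tp + 1
    } else {
      fp <- fp + 1
      area <- area + tp
      if (fp == m) break
    }
  }
  area / (m * P)
}

# Expected branch length score by exhaustive enumeration over all 2^n
# leaf presence configurations.
oracle_bbls_enum <- function(tree, p) {
  n <- length(tree$tip.label)
  p <- p[tree$tip.label]
  ets <- tfbsbench:::edge_tip_sets(tree)
  tr <- ets$tree
  bls_of_set <- function(present) {
    total <- 0
    for (e in seq_len(nrow(tr$edge))) {
      A <- ets$below[[e]]
      B <- setdiff(seq_len(n), A)
      if (any(present[A]) && any(present[B])) {
        total <- total + tr$edge.length[e]
      }
    }
    total
  }
  out <- 0
  for (mask in 0:(2^n - 1)) {
    present <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
    prob <- prod(ifelse(present, p, 1 - p))
    if (prob > 0) out <- out + prob * bls_of_set(present)
  }
  out
}

# One-sided signed-rank p-value by enumerating all 2^n sign assignments.
oracle_wilcoxon_enum <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  count <- 0
  for (mask in 0:(2^n - 1)) {
    signs <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
    if (sum(r[signs]) >= W - 1e-12) count <- count + 1
  }
  count / 2^n
}

# Random peak set on one chromosome for benchmark-builder property tests.
random_peaks <- function(n, chrom_len, min_len = 100, max_len = 400) {
  len <- sample(min_len:max_len, n, replace = TRUE)
  start <- vapply(len, function(l) sample.int(chrom_len - l, 1), 0L)
  data.frame(chrom = "chrT", start = start, end = start + len,
             name = sprintf("p%d", seq_len(n)),
             height = stats::rexp(n, 1 / 50), stringsAsFactors = FALSE)
}

write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
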