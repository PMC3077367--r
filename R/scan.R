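# Single-genome scanners: PWM scanning and MotifScan k-mer
# nearest-neighbour scoring. Both produce one score per position per
# strand; the score at position i refers to a motif whose 5' end starts at
# i on the given strand, and reverse-strand scores are reported at the
# forward coordinate of the window start, so region maxima can be taken in
# one coordinate system.

#' Per-position, per-strand score track
#'
#' @param seq_id sequence identifier.
#' @param method scoring method label.
#' @param motif_length motif width L in bp.
#' @param fwd,rev numeric score vectors of length \code{n - L + 1} (window
#'   start positions on the forward coordinate).
#' @param offset genomic coordinate (0-based) of the first window start;
#'   track index i corresponds to genomic position \code{offset + i - 1}.
#' @return object of class \code{score_track}.
#' @export
score_track <- function(seq_id, method, motif_length, fwd, rev,
                        offset = 0) {
  stopifnot(length(fwd) == length(rev))
  if (any(!is.finite(fwd)) || any(!is.finite(rev))) {
    stop("score track contains non-finite values")
  }
  structure(list(seq_id = seq_id, method = method,
                 motif_length = motif_length,
                 fwd = as.numeric(fwd), rev = as.numeric(rev),
                 offset = offset),
            class = "score_track")
}

#' @export
print.score_track <- function(x, ...) {
  cat(sprintf("score_track '%s' (%s): %d positions, L=%d, offset=%d\n",
              x$seq_id, x$method, length(x$fwd), x$motif_length,
              as.integer(x$offset)))
  invisible(x)
}

#' Per-position best-of-both-strands scores of a track
#' @param track a [score_track()].
#' @return numeric vector, \code{pmax(fwd, rev)}.
#' @export
track_best <- function(track) pmax(track$fwd, track$rev)

empty_track <- function(seq_id, method, L, offset = 0) {
  score_track(seq_id, method, L, numeric(0), numeric(0), offset)
}

# Lookup table for PWM scanning: rows A,C,G,T plus a 5th "ambiguous" row
# holding the background-expected column contribution.
pwm_lookup <- function(W, bg) {
  rbind(W, colSums(bg * W))
}

# Reverse-complemented PWM: W_rc[b, j] = W[comp(b), L + 1 - j]
revcomp_pwm <- function(W) {
  W[4:1, ncol(W):1, drop = FALSE]
}

scan_pwm_one <- function(idx, lookup) {
  L <- ncol(lookup)
  np <- length(idx) - L + 1L
  S <- numeric(np)
  for (j in seq_len(L)) {
    S <- S + lookup[cbind(idx[j:(j + np - 1L)], j)]
  }
  S
}

#' Scan a sequence with a log-odds PWM
#'
#' Scores every window start on both strands. The forward score at i is
#' \eqn{\sum_j W[s_{i+j-1}, j]}; the reverse score at i is the score of the
#' reverse-complemented matrix over the same window (equivalently, of the
#' reverse strand's motif whose 5' end aligns to the window). Ambiguous
#' bases (N etc.) contribute the background expectation
#' \eqn{\sum_b p_b W[b, j]} for their column.
#'
#' @param seq DNA string.
#' @param pwm a [build_pwm()] result.
#' @param seq_id identifier stored in the track.
#' @param offset genomic coordinate of the first sequence base.
#' @return a [score_track()]; empty (with a warning) if the sequence is
#'   shorter than the motif.
#' @export
scan_pwm <- function(seq, pwm, seq_id = "seq", offset = 0) {
  stopifnot(inherits(pwm, "log_odds_matrix"))
  code <- seq_to_code(seq)
  L <- pwm$length
  if (length(code) < L) {
    warning("sequence shorter than motif; returning empty track")
    return(empty_track(seq_id, "pwm", L, offset))
  }
  idx <- ifelse(is.na(code), 5L, code)
  fwd <- scan_pwm_one(idx, pwm_lookup(pwm$W, pwm$bg))
  rev <- scan_pwm_one(idx, pwm_lookup(revcomp_pwm(pwm$W), pwm$bg))
  score_track(seq_id, "pwm", L, fwd, rev, offset)
}

#' MotifScan configuration
#'
#' Reference parameter settings for the k-mer nearest-neighbour scorer:
#' windows farther than \code{d_max} mismatches from every motif k-mer
#' score 0; contributions are summed (or maximised) over k-mers; the
#' aggregate is log2(1 + x) transformed.
#'
#' @param d_max maximum mismatches counted (default 3).
#' @param aggregation \code{"sum"} (default) or \code{"max"} over k-mers.
#' @param log2_transform apply log2(1 + x) to the aggregate (default TRUE).
#' @return object of class \code{motifscan_config}.
#' @export
motifscan_config <- function(d_max = 3L, aggregation = c("sum", "max"),
                             log2_transform = TRUE) {
  aggregation <- match.arg(aggregation)
  stopifnot(d_max >= 0L)
  structure(list(d_max = as.integer(d_max), aggregation = aggregation,
                 log2_transform = isTRUE(log2_transform)),
            class = "motifscan_config")
}

# One strand of MotifScan scoring over encoded windows.
motifscan_strand <- function(idx, kmer_codes, mult, sx, cfg) {
  k <- ncol(kmer_codes)
  np <- length(idx) - k + 1L
  agg <- numeric(np)
  for (m in seq_len(nrow(kmer_codes))) {
    w <- rep(1, np)
    ham <- integer(np)
    for (j in seq_len(k)) {
      b <- idx[j:(j + np - 1L)]
      mj <- kmer_codes[m, j]
      mismatch <- b != mj          # N (code 5) never matches
      ham <- ham + mismatch
      w[mismatch] <- w[mismatch] * sx[mj, b[mismatch]]
    }
    contrib <- ifelse(ham <= cfg$d_max, w, 0)
    if (cfg$aggregation == "sum") {
      agg <- agg + mult[m] * contrib
    } else {
      agg <- pmax(agg, contrib)
    }
  }
  if (cfg$log2_transform) log2(1 + agg) else agg
}

#' Scan a sequence with MotifScan k-mer nearest-neighbour scoring
#'
#' The contribution of motif k-mer m to window x is the product over
#' mismatch positions j of the substitution weight s(m_j, x_j), provided
#' Hamming(m, x) <= d_max, and 0 otherwise. Contributions are weighted by
#' k-mer multiplicity and summed (default) over the motif's k-mers, then
#' log2(1 + x) transformed. Both strands are scored; the reverse strand
#' scores the reverse-complemented window at the same forward coordinate.
#' An ambiguous base mismatches every k-mer base with weight equal to the
#' row minimum of s.
#'
#' @param seq DNA string.
#' @param kmers a [kmer_set()].
#' @param submat a [build_substitution_matrix()] result.
#' @param cfg a [motifscan_config()].
#' @param seq_id,offset as in [scan_pwm()].
#' @return a [score_track()].
#' @export
scan_motifscan <- function(seq, kmers, submat, cfg = motifscan_config(),
                           seq_id = "seq", offset = 0) {
  stopifnot(inherits(kmers, "kmer_set"),
            inherits(submat, "substitution_matrix"),
            inherits(cfg, "motifscan_config"))
  k <- kmers$k
  if (cfg$d_max > k) stop("d_max exceeds k-mer length")
  code <- seq_to_code(seq)
  if (length(code) < k) {
    warning("sequence shorter than k; returning empty track")
    return(empty_track(seq_id, "motifscan", k, offset))
  }
  idx <- ifelse(is.na(code), 5L, code)
  # extended substitution lookup: column 5 is the ambiguous-base weight
  sx <- cbind(submat$s, apply(submat$s, 1, min))
  kc <- matrix(unlist(lapply(kmers$kmers, seq_to_code)), ncol = k, byrow = TRUE)
  fwd <- motifscan_strand(idx, kc, kmers$mult, sx, cfg)
  # reverse strand: score the reverse-complemented windows against the
  # same k-mers (s is not complement-symmetric, so the k-mers themselves
  # are not reverse-complemented)
  idx_rc <- rev(ifelse(idx == 5L, 5L, 5L - idx))
  rev_scores <- rev(motifscan_strand(idx_rc, kc, kmers$mult, sx, cfg))
  score_track(seq_id, "motifscan", k, fwd, rev_scores, offset)
}
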