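# Motif models: count matrices, background base frequencies, log-odds PWMs,
# information content, k-mer statistics, and the MotifScan substitution
# matrix.

#' Motif count matrix
#'
#' A 4 x L matrix of (possibly fractional) non-negative base counts, rows
#' A, C, G, T, columns motif positions 1..L.
#'
#' @param counts 4 x L numeric matrix; rows may be named A/C/G/T (reordered
#'   if so) or unnamed (assumed in A, C, G, T order).
#' @param motif_id label for the motif.
#' @return object of class \code{count_matrix} with elements \code{counts},
#'   \code{length}, \code{motif_id}.
#' @export
count_matrix <- function(counts, motif_id = "motif") {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == 4L, ncol(counts) >= 1L, is.numeric(counts))
  if (!is.null(rownames(counts))) {
    stopifnot(setequal(rownames(counts), DNA_BASES))
    counts <- counts[DNA_BASES, , drop = FALSE]
  } else {
    rownames(counts) <- DNA_BASES
  }
  if (any(counts < 0)) stop("negative counts in count matrix")
  if (any(colSums(counts) <= 0)) stop("count matrix has a zero-sum column")
  structure(list(counts = counts, length = ncol(counts), motif_id = motif_id),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix '%s' (%d positions)\n", x$motif_id, x$length))
  print(x$counts)
  invisible(x)
}

#' Set of motif k-mers with multiplicities
#'
#' @param kmers character vector of equal-length DNA strings over A/C/G/T.
#'   Ambiguity codes are rejected.
#' @param mult integer multiplicities (recycled).
#' @param motif_id label.
#' @return object of class \code{kmer_set} with elements \code{kmers},
#'   \code{mult}, \code{k}, \code{motif_id}.
#' @export
kmer_set <- function(kmers, mult = 1L, motif_id = "motif") {
  kmers <- toupper(kmers)
  stopifnot(length(kmers) >= 1L)
  k <- unique(nchar(kmers))
  if (length(k) != 1L) stop("k-mers must all have the same length")
  if (any(grepl(sprintf("[^%s]", paste(DNA_BASES, collapse = "")), kmers))) {
    stop("k-mers must use only A/C/G/T (ambiguity codes are rejected)")
  }
  mult <- rep_len(as.integer(mult), length(kmers))
  stopifnot(all(mult >= 1L))
  structure(list(kmers = kmers, mult = mult, k = k, motif_id = motif_id),
            class = "kmer_set")
}

#' @export
print.kmer_set <- function(x, ...) {
  cat(sprintf("kmer_set '%s': %d distinct %d-mers (total multiplicity %d)\n",
              x$motif_id, length(x$kmers), x$k, sum(x$mult)))
  invisible(x)
}

#' Background base frequencies from a sequence
#'
#' Counts A/C/G/T in the sequence, skipping N and other ambiguity codes.
#' Bases never observed get a floor frequency of 1e-4 before
#' renormalisation, so downstream log-odds stay finite. A sequence with no
#' unambiguous bases falls back to the uniform distribution with a warning.
#'
#' @param seq DNA string (or character vector of strings, pooled).
#' @return named numeric vector p(A), p(C), p(G), p(T) summing to 1.
#' @examples
#' background_from_sequence("ACGT")   # uniform
#' @export
background_from_sequence <- function(seq) {
  stopifnot(is.character(seq), length(seq) >= 1L)
  code <- unlist(lapply(seq, seq_to_code), use.names = FALSE)
  code <- code[!is.na(code)]
  if (length(code) == 0L) {
    warning("no unambiguous bases; using uniform background")
    return(stats::setNames(rep(0.25, 4), DNA_BASES))
  }
  counts <- tabulate(code, nbins = 4L)
  p <- counts / sum(counts)
  p[p == 0] <- 1e-4
  p <- p / sum(p)
  stats::setNames(p, DNA_BASES)
}

#' Build a log-odds position weight matrix
#'
#' \deqn{W_{b,j} = \log_2\frac{(n_{b,j} + \alpha p_b)/(N_j + \alpha)}{p_b}}
#' where \eqn{n_{b,j}} are the motif counts, \eqn{N_j} the column sum,
#' \eqn{p_b} the background frequency and \eqn{\alpha} a pseudocount
#' distributed across bases in proportion to the background. Scores are in
#' bits; the consensus sequence attains the matrix maximum.
#'
#' @param counts a [count_matrix()].
#' @param bg background frequencies (named as A/C/G/T); defaults to uniform.
#' @param alpha pseudocount, must be > 0.
#' @return object of class \code{log_odds_matrix} with elements \code{W}
#'   (4 x L, bits), \code{length}, \code{motif_id}, \code{bg}, \code{alpha}.
#' @examples
#' cm <- count_matrix(matrix(c(10, 0, 0, 0), nrow = 4))
#' build_pwm(cm)$W["A", 1]  # ~1.898 bits
#' @export
build_pwm <- function(counts, bg = NULL, alpha = 1) {
  stopifnot(inherits(counts, "count_matrix"), alpha > 0)
  if (is.null(bg)) bg <- stats::setNames(rep(0.25, 4), DNA_BASES)
  bg <- bg[DNA_BASES]
  stopifnot(all(bg > 0), abs(sum(bg) - 1) < 1e-9)
  cm <- counts$counts
  csum <- colSums(cm)
  if (any(csum <= 0)) stop("zero-sum column in count matrix")
  prob <- sweep(cm + alpha * bg, 2, csum + alpha, "/")
  W <- log2(prob / bg)
  structure(list(W = W, length = ncol(W), motif_id = counts$motif_id,
                 bg = bg, alpha = alpha),
            class = "log_odds_matrix")
}

#' @export
print.log_odds_matrix <- function(x, ...) {
  cat(sprintf("log_odds_matrix '%s' (%d positions, bits; alpha=%g)\n",
              x$motif_id, x$length, x$alpha))
  print(round(x$W, 3))
  invisible(x)
}

#' Consensus k-mer of a PWM (column-wise argmax; ties take the first base
#' in A,C,G,T order)
#' @param pwm a [build_pwm()] result.
#' @return character string of length L.
#' @export
consensus_kmer <- function(pwm) {
  paste(DNA_BASES[apply(pwm$W, 2, which.max)], collapse = "")
}

#' Score a single k-mer against a PWM (forward orientation)
#' @param pwm a [build_pwm()] result.
#' @param kmer DNA string of the motif's length.
#' @return log-odds score in bits.
#' @export
pwm_score_kmer <- function(pwm, kmer) {
  code <- seq_to_code(kmer)
  stopifnot(length(code) == pwm$length, !anyNA(code))
  sum(pwm$W[cbind(code, seq_len(pwm$length))])
}

#' Motif information content
#'
#' Per-position information content of the (pseudocount-smoothed) column
#' probabilities. With the default uniform background this is the classic
#' \eqn{IC_j = 2 + \sum_b q_{b,j} \log_2 q_{b,j}} in bits per position
#' (0 for a uniform column, 2 for a certain one); with
#' \code{background = "genome"} it is the relative entropy against
#' \code{bg}.
#'
#' @param counts a [count_matrix()].
#' @param alpha pseudocount (>= 0, default 0: raw column frequencies).
#' @param background \code{"uniform"} (default) or \code{"genome"}.
#' @param bg genome background frequencies, used when
#'   \code{background = "genome"}.
#' @return list with \code{total} (bits), \code{per_position} (bits),
#'   \code{average} (= total / motif length).
#' @export
information_content <- function(counts, alpha = 0,
                                background = c("uniform", "genome"),
                                bg = NULL) {
  stopifnot(inherits(counts, "count_matrix"), alpha >= 0)
  background <- match.arg(background)
  cm <- counts$counts
  q <- sweep(cm + alpha / 4, 2, colSums(cm) + alpha, "/")
  plogp <- function(x) ifelse(x > 0, x * log2(x), 0)
  if (background == "uniform") {
    per <- 2 + colSums(plogp(q))
  } else {
    if (is.null(bg)) stop("genome background requested but bg not given")
    bg <- bg[DNA_BASES]
    per <- colSums(ifelse(q > 0, q * log2(q / bg), 0))
  }
  list(total = sum(per), per_position = unname(per),
       average = sum(per) / counts$length)
}

#' Mean pairwise Hamming distance of a k-mer set
#'
#' Mean over all unordered pairs of the multiplicity-expanded k-mer stack
#' (pairs of identical copies contribute distance 0).
#'
#' @param kmers a [kmer_set()] with total multiplicity >= 2.
#' @return mean Hamming distance in mismatches.
#' @examples
#' mean_pairwise_hamming(kmer_set(c("AAA", "AAT", "ATT")))  # 4/3
#' @export
mean_pairwise_hamming <- function(kmers) {
  stopifnot(inherits(kmers, "kmer_set"))
  M <- sum(kmers$mult)
  if (M < 2L) stop("need at least 2 k-mers (counting multiplicity)")
  k <- kmers$k
  total <- 0
  for (j in seq_len(k)) {
    bases <- substr(kmers$kmers, j, j)
    n_b <- tapply(kmers$mult, factor(bases, levels = DNA_BASES), sum,
                  default = 0L)
    # mismatching unordered pairs in this column
    total <- total + (M^2 - sum(n_b^2)) / 2
  }
  total / (M * (M - 1) / 2)
}

#' Build the MotifScan substitution matrix from motif k-mer sets
#'
#' Counts, for every motif and every motif column, the unordered base
#' co-occurrences across the multiplicity-expanded k-mer stack, pools the
#' counts over all motifs, Laplace-smooths (+1) so every entry is positive,
#' symmetrises, and normalises by the matrix maximum. The diagonal is then
#' forced to exactly 1, so a matching base always outweighs any
#' substitution.
#'
#' @param motifs list of [kmer_set()] objects (k may differ across motifs).
#' @return object of class \code{substitution_matrix}: a 4 x 4 matrix
#'   \code{s} with \code{0 < s(a,b) <= 1}, \code{s(a,a) = 1},
#'   \code{s(a,b) = s(b,a)}.
#' @export
build_substitution_matrix <- function(motifs) {
  if (inherits(motifs, "kmer_set")) motifs <- list(motifs)
  stopifnot(length(motifs) >= 1L,
            all(vapply(motifs, inherits, TRUE, "kmer_set")))
  if (!any(vapply(motifs, function(m) sum(m$mult) >= 2L, TRUE))) {
    stop("no co-occurrence data: every motif has fewer than 2 k-mers")
  }
  C <- matrix(0, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  for (m in motifs) {
    for (j in seq_len(m$k)) {
      bases <- substr(m$kmers, j, j)
      n_b <- tapply(m$mult, factor(bases, levels = DNA_BASES), sum,
                    default = 0L)
      pair <- outer(n_b, n_b)        # ordered pairs
      diag(pair) <- n_b * (n_b - 1)  # ordered same-base pairs, no self-pair
      C <- C + pair / 2              # unordered
    }
  }
  C <- C + 1                 # Laplace smoothing: all entries > 0
  C <- (C + t(C)) / 2        # symmetrise
  s <- C / max(C)
  diag(s) <- 1
  structure(list(s = s), class = "substitution_matrix")
}

#' @export
print.substitution_matrix <- function(x, ...) {
  cat("substitution_matrix:\n")
  print(round(x$s, 3))
  invisible(x)
}

#' Summarise motifs as an id/length/IC/Hamming table
#'
#' One row per motif: id, length, total and average information content and
#' (when a matching k-mer set is supplied) the mean pairwise Hamming
#' distance of its k-mers.
#'
#' @param matrices list of [count_matrix()].
#' @param kmer_sets optional list of [kmer_set()] parallel to
#'   \code{matrices}.
#' @param alpha pseudocount passed to [information_content()].
#' @return data.frame with columns \code{motif_id}, \code{length},
#'   \code{total_ic}, \code{avg_ic}, \code{mean_hamming}.
#' @export
motif_summary <- function(matrices, kmer_sets = NULL, alpha = 0) {
  stopifnot(length(matrices) >= 1L)
  rows <- lapply(seq_along(matrices), function(i) {
    cm <- matrices[[i]]
    ic <- information_content(cm, alpha = alpha)
    mh <- NA_real_
    if (!is.null(kmer_sets) && length(kmer_sets) >= i &&
        !is.null(kmer_sets[[i]]) && sum(kmer_sets[[i]]$mult) >= 2L) {
      mh <- mean_pairwise_hamming(kmer_sets[[i]])
    }
    data.frame(motif_id = cm$motif_id, length = cm$length,
               total_ic = ic$total, avg_ic = ic$average, mean_hamming = mh,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
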