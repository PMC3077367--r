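# Conservation-based scoring: projection of reference windows onto aligned
# species, the weighted-sum (WS) method, and the Bayesian branch length
# score (BBLS) with either PWM or MotifScan leaf scores.
#
# Windows are anchored by alignment columns, never by independent
# coordinate arithmetic, so indels shift species windows correctly. A
# window with half-width h around reference motif-start position i covers
# the alignment columns of reference positions [i - h, i + h + L - 1]
# (h bases of flank on each side of the motif footprint); the species'
# candidate motif starts are all positions of its gap-free window
# sequence.

# Per-block index: reference genomic position of each column, and for each
# species the cumulative count of non-gap characters up to each column.
block_index <- function(block, ref_species = NULL) {
  r <- block$records
  if (is.null(ref_species)) ref_species <- r$species[1]
  ri <- match(ref_species, r$species)
  if (is.na(ri)) stop(sprintf("reference species '%s' not in block", ref_species))
  if (r$strand[ri] != "+") {
    stop("reference record must be on the + strand")
  }
  chars <- strsplit(r$text, "", fixed = TRUE)
  nongap <- lapply(chars, function(x) x != "-")
  cum <- lapply(nongap, cumsum)
  ref_pos <- ifelse(nongap[[ri]], r$start[ri] + cum[[ri]] - 1, NA_real_)
  col_of_pos <- which(nongap[[ri]])          # column of k-th reference base
  list(ref_species = ref_species, ref_idx = ri,
       ref_start = r$start[ri], ref_len = r$size[ri],
       ref_pos = ref_pos, col_of_pos = col_of_pos,
       cum = cum, chars = chars)
}

#' Project a reference window onto every aligned species
#'
#' Extracts, for each species in the block, the gap-free sequence of the
#' alignment columns spanning reference positions
#' \code{ref_pos - h .. ref_pos + h} (clipped to the block). A species row
#' that is entirely gaps in the window yields an empty string.
#'
#' @param block an [alignment_block()].
#' @param ref_pos 0-based reference genomic position; must be covered by
#'   the block's reference record.
#' @param h window half-width in reference bp.
#' @param ref_species reference species id; defaults to the block's first
#'   record.
#' @return named character vector of per-species window sequences.
#' @export
project_species_window <- function(block, ref_pos, h, ref_species = NULL) {
  bi <- block_index(block, ref_species)
  first <- bi$ref_start
  last <- bi$ref_start + bi$ref_len - 1
  if (ref_pos < first || ref_pos > last) {
    stop(sprintf("ref_pos %d outside block [%d, %d]", as.integer(ref_pos),
                 as.integer(first), as.integer(last)))
  }
  lo <- max(ref_pos - h, first)
  hi <- min(ref_pos + h, last)
  ca <- bi$col_of_pos[lo - first + 1]
  cb <- bi$col_of_pos[hi - first + 1]
  r <- block$records
  out <- vapply(seq_len(nrow(r)), function(i) {
    piece <- bi$chars[[i]][ca:cb]
    paste(piece[piece != "-"], collapse = "")
  }, "")
  stats::setNames(out, r$species)
}

#' Weighted-sum configuration
#'
#' @param weights named numeric vector of per-species weights for the
#'   non-reference species (default 0.25 each for two species, so the added
#'   conservation term is half the mean of the two species maxima).
#' @param h window half-width in bp (default 15: the species window reaches
#'   15 bp upstream and 15 bp downstream of the motif footprint).
#' @return object of class \code{ws_config}.
#' @export
ws_config <- function(weights = NULL, h = 15L) {
  stopifnot(h >= 0)
  if (!is.null(weights)) {
    stopifnot(is.numeric(weights), all(weights >= 0),
              !is.null(names(weights)))
  }
  structure(list(weights = weights, h = as.integer(h)), class = "ws_config")
}

# Shift a vector by d, padding with -Inf.
shift_pad <- function(x, d) {
  n <- length(x)
  if (d == 0 || n == 0) return(x)
  if (abs(d) >= n) return(rep(-Inf, n))
  if (d > 0) c(rep(-Inf, d), x[seq_len(n - d)]) else
    c(x[(1 - d):n], rep(-Inf, -d))
}

# Centered rolling max with half-width h (edge-clipped).
rolling_max <- function(x, h) {
  if (h == 0 || length(x) == 0) return(x)
  out <- x
  for (d in seq_len(h)) {
    out <- pmax(out, shift_pad(x, d), shift_pad(x, -d))
  }
  out
}

#' Per-position window maxima of a scorer in aligned species
#'
#' For every reference motif-start position and every requested species,
#' computes the maximum (over window positions and both strands) of the
#' scoring function applied to the species' gap-free window sequence.
#' Positions not covered by any alignment block, or where the species
#' window is too short for the motif, are \code{-Inf} (no score).
#'
#' @param blocks list of [alignment_block()].
#' @param ref_species reference species id.
#' @param species character vector of species to score.
#' @param scorer function(seq) returning a [score_track()].
#' @param h window half-width in reference bp.
#' @param motif_length motif width L.
#' @param n_pos number of reference motif-start positions (genome length
#'   minus L + 1).
#' @param ref_offset genomic position of reference coordinate 0.
#' @return numeric matrix \code{n_pos x length(species)} with species as
#'   column names.
#' @export
species_window_max <- function(blocks, ref_species, species, scorer, h,
                               motif_length, n_pos, ref_offset = 0) {
  L <- motif_length
  M <- matrix(-Inf, nrow = n_pos, ncol = length(species),
              dimnames = list(NULL, species))
  for (block in blocks) {
    bi <- block_index(block, ref_species)
    r <- block$records
    gapless <- all(vapply(bi$cum, function(cc) {
      length(cc) == 0 || cc[length(cc)] == length(cc)
    }, TRUE)) && nrow(r) == length(bi$cum)
    # reference motif-start positions covered by this block (track coords)
    blk_first <- bi$ref_start
    blk_len <- bi$ref_len
    for (s in intersect(species, r$species)) {
      si <- match(s, r$species)
      sp_seq <- paste(bi$chars[[si]][bi$chars[[si]] != "-"], collapse = "")
      if (nchar(sp_seq) < L) next
      t_s <- track_best(scorer(sp_seq))
      if (gapless) {
        # species positions coincide with block offsets
        wmax <- rolling_max(t_s, h)
        # block offset o (0-based) hosts ref motif start blk_first + o
        valid <- seq_len(min(length(wmax), blk_len - L + 1))
        tgt <- blk_first + valid - 1 - ref_offset + 1
        keep <- tgt >= 1 & tgt <= n_pos
        M[tgt[keep], s] <- pmax(M[tgt[keep], s], wmax[valid][keep])
      } else {
        cum_s <- bi$cum[[si]]
        n_col <- length(cum_s)
        for (o in seq_len(blk_len - L + 1)) {
          i <- blk_first + o - 1          # genomic motif start
          lo_pos <- max(i - h, blk_first)
          hi_pos <- min(i + h + L - 1, blk_first + blk_len - 1)
          ca <- bi$col_of_pos[lo_pos - blk_first + 1]
          cb <- bi$col_of_pos[hi_pos - blk_first + 1]
          lo_s <- if (ca > 1) cum_s[ca - 1] + 1 else 1
          hi_s <- cum_s[cb]
          if (hi_s - lo_s + 1 < L) next
          rng <- lo_s:(hi_s - L + 1)
          tgt <- i - ref_offset + 1
          if (tgt >= 1 && tgt <= n_pos) {
            M[tgt, s] <- max(M[tgt, s], max(t_s[rng]))
          }
        }
      }
    }
  }
  M
}

#' Weighted-sum conservation score
#'
#' Adds to the reference score, per position and strand, the weighted
#' species-window maxima: \deqn{WS(i) = S_{ref}(i) + \sum_s w_s \max_{j \in
#' window(i)} S_s(j).} Species with no aligned window at a position
#' contribute 0, so positions without alignment fall back to the reference
#' score.
#'
#' @param ref_track reference-species [score_track()].
#' @param species_max matrix from [species_window_max()] (rows aligned with
#'   the track positions).
#' @param cfg a [ws_config()]; weights default to 0.25 for every column of
#'   \code{species_max}.
#' @return a [score_track()] with method \code{"ws"}.
#' @export
ws_score <- function(ref_track, species_max, cfg = ws_config()) {
  stopifnot(inherits(ref_track, "score_track"), is.matrix(species_max))
  if (nrow(species_max) != length(ref_track$fwd)) {
    stop("species_max rows must match the reference track length")
  }
  weights <- cfg$weights
  if (is.null(weights)) {
    weights <- stats::setNames(rep(0.25, ncol(species_max)),
                               colnames(species_max))
  }
  term <- rep(0, nrow(species_max))
  for (s in names(weights)) {
    if (!s %in% colnames(species_max)) next
    col <- species_max[, s]
    term <- term + ifelse(is.finite(col), weights[[s]] * col, 0)
  }
  score_track(ref_track$seq_id, "ws", ref_track$motif_length,
              ref_track$fwd + term, ref_track$rev + term, ref_track$offset)
}

#' Percentile cutoff of a score distribution
#'
#' The q-th percentile (linear interpolation, quantile type 7) of the
#' reference-species genome-wide per-position score distribution for a
#' motif.
#'
#' @param scores numeric vector.
#' @param q percentile in (0, 100).
#' @return scalar threshold.
#' @examples
#' percentile_cutoff(1:100, 95)  # 95.05
#' @export
percentile_cutoff <- function(scores, q) {
  stopifnot(length(scores) > 0, q > 0, q < 100)
  stats::quantile(scores, q / 100, type = 7, names = FALSE)
}

#' Leaf motif-presence probabilities
#'
#' Converts per-leaf best window scores into presence probabilities.
#' \code{binary} sets p = 1 when the score reaches the threshold (ties
#' count as present) and 0 otherwise. \code{soft} uses the empirical
#' percentile rank of the score within the reference score distribution,
#' clipped to [0, 1]. \code{gated} (the BBLS default) combines the two as
#' the method prescribes: only leaves whose score reaches the cutoff enter
#' the calculation, and those that do are weighted by their percentile
#' rank rather than counted as certainly present -- this keeps the score
#' fine-grained, so region maxima are rarely tied. Unaligned leaves (NA or
#' -Inf scores) get p = 0; the reference leaf is always forced to p = 1
#' because scoring is anchored at a concrete reference position.
#'
#' @param species_best named numeric vector of per-leaf max window scores.
#' @param threshold cutoff from [percentile_cutoff()].
#' @param model \code{"binary"}, \code{"soft"} or \code{"gated"}.
#' @param ref_species reference leaf id (must be present in the result).
#' @param ref_scores reference score distribution, required for the
#'   \code{soft} and \code{gated} models.
#' @return named numeric vector of probabilities in [0, 1].
#' @export
leaf_probabilities <- function(species_best, threshold,
                               model = c("gated", "binary", "soft"),
                               ref_species, ref_scores = NULL) {
  model <- match.arg(model)
  p <- species_best
  absent <- is.na(p) | !is.finite(p)
  if (model == "binary") {
    p <- ifelse(p >= threshold, 1, 0)
  } else {
    if (is.null(ref_scores)) stop(sprintf("%s model needs ref_scores", model))
    rk <- pmin(pmax(stats::ecdf(ref_scores)(p), 0), 1)
    rk <- stats::setNames(rk, names(p))
    p <- if (model == "soft") rk else ifelse(p >= threshold, rk, 0)
  }
  p[absent] <- 0
  if (!ref_species %in% names(species_best)) {
    p <- c(p, stats::setNames(1, ref_species))
  } else {
    p[ref_species] <- 1
  }
  p
}

# Tip sets below every edge of a phylo tree; returns a list parallel to
# the rows of tree$edge, each element the tip indices on the child side.
edge_tip_sets <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tree$tip.label)
  sets <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) sets[[i]] <- i
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1]
    child <- tree$edge[e, 2]
    sets[[parent]] <- c(sets[[parent]], sets[[child]])
  }
  list(tree = tree,
       below = lapply(seq_len(nrow(tree$edge)),
                      function(e) sets[[tree$edge[e, 2]]]))
}

#' Bayesian branch length score of one position
#'
#' Treating the tree as unrooted, every branch b partitions the leaves
#' into sides A(b) and B(b). With independent per-leaf presence
#' probabilities p, the expected branch length of the spanning subtree of
#' the present leaves is \deqn{BBLS = \sum_b l(b)\,\bigl(1 - \prod_{i \in
#' A(b)} (1 - p_i)\bigr)\bigl(1 - \prod_{i \in B(b)} (1 - p_i)\bigr),}
#' i.e. each branch contributes when both of its sides contain at least
#' one motif-bearing leaf. With all p in {0, 1} this is the plain branch
#' length score of the present set; with the reference leaf fixed at p = 1
#' it reduces to summing over the far-side products.
#'
#' @param tree \code{ape::phylo} with branch lengths.
#' @param p named numeric vector of per-leaf presence probabilities
#'   covering every tip of the tree.
#' @return scalar BBLS (same units as the branch lengths).
#' @examples
#' tree <- read_newick("(a:0.1,b:0.2);")
#' bbls(tree, c(a = 1, b = 1))    # 0.3
#' bbls(tree, c(a = 1, b = 0.5))  # 0.15
#' @export
bbls <- function(tree, p) {
  missing <- setdiff(tree$tip.label, names(p))
  if (length(missing) > 0) {
    stop(sprintf("leaf probabilities missing for: %s",
                 paste(missing, collapse = ", ")))
  }
  P <- matrix(p[tree$tip.label], nrow = 1)
  colnames(P) <- tree$tip.label
  unname(bbls_many(tree, P)[1])
}

#' Vectorised BBLS over many positions
#'
#' @param tree \code{ape::phylo} with branch lengths.
#' @param P numeric matrix, one row per position, one column per tree leaf
#'   (column names must cover the tip labels).
#' @return numeric vector of BBLS values, one per row of \code{P}.
#' @export
bbls_many <- function(tree, P) {
  stopifnot(is.matrix(P))
  missing <- setdiff(tree$tip.label, colnames(P))
  if (length(missing) > 0) {
    stop(sprintf("leaf probabilities missing for: %s",
                 paste(missing, collapse = ", ")))
  }
  P <- P[, tree$tip.label, drop = FALSE]
  if (any(P < 0 | P > 1)) stop("leaf probabilities must be in [0, 1]")
  ets <- edge_tip_sets(tree)
  tr <- ets$tree
  n_tip <- length(tr$tip.label)
  out <- rep(0, nrow(P))
  for (e in seq_len(nrow(tr$edge))) {
    A <- ets$below[[e]]
    B <- setdiff(seq_len(n_tip), A)
    out <- out + tr$edge.length[e] *
      (1 - complement_product(P, A)) * (1 - complement_product(P, B))
  }
  out
}

#' BBLS configuration
#'
#' @param q cutoff percentile in (0, 100); the calibrated default is 95.
#' @param model leaf probability model: \code{"gated"} (default; leaves
#'   above the cutoff enter with their percentile-rank probability),
#'   \code{"binary"} or \code{"soft"} (see [leaf_probabilities()]).
#' @param h window half-width in bp around the motif footprint when scoring
#'   each species (default 0: score exactly the aligned motif instance).
#' @return object of class \code{bbls_config}.
#' @export
bbls_config <- function(q = 95, model = c("gated", "binary", "soft"), h = 0L) {
  model <- match.arg(model)
  stopifnot(q > 0, q < 100, h >= 0)
  structure(list(q = q, model = model, h = as.integer(h)),
            class = "bbls_config")
}

#' Per-position BBLS track
#'
#' For every reference motif-start position: project the species windows,
#' score each species with the supplied scorer, form leaf presence
#' probabilities against the precomputed threshold, and return the BBLS.
#' Positions with no alignment coverage score 0 (never NaN), so region
#' maxima stay well-defined. The track is strand-symmetric (the BBLS of a
#' position does not depend on the strand; species maxima already cover
#' both strands).
#'
#' @param ref_track reference-species [score_track()] (supplies positions,
#'   offset and motif length).
#' @param blocks list of [alignment_block()]; their species must jointly
#'   cover all tree leaves.
#' @param tree \code{ape::phylo} whose tip labels are species ids,
#'   including the reference.
#' @param scorer function(seq) returning a [score_track()] (PWM or
#'   MotifScan leaf scorer).
#' @param threshold leaf-score cutoff from [percentile_cutoff()].
#' @param ref_species reference species id.
#' @param cfg a [bbls_config()].
#' @param ref_scores reference score distribution (needed for the soft
#'   model).
#' @param species_max optional precomputed [species_window_max()] matrix
#'   for the non-reference leaves (skips the projection step).
#' @return a [score_track()] with method \code{"bbls"}.
#' @export
bbls_track <- function(ref_track, blocks, tree, scorer, threshold,
                       ref_species, cfg = bbls_config(), ref_scores = NULL,
                       species_max = NULL) {
  stopifnot(inherits(ref_track, "score_track"), inherits(cfg, "bbls_config"))
  others <- setdiff(tree$tip.label, ref_species)
  if (length(others) > 0 && is.null(species_max)) {
    aligned <- unique(unlist(lapply(blocks, function(b) b$records$species)))
    missing <- setdiff(others, aligned)
    if (length(missing) > 0) {
      stop(sprintf("tree leaves absent from alignment: %s",
                   paste(missing, collapse = ", ")))
    }
    species_max <- species_window_max(
      blocks, ref_species, others, scorer, cfg$h,
      ref_track$motif_length, length(ref_track$fwd), ref_track$offset)
  }
  n_pos <- length(ref_track$fwd)
  P <- matrix(1, nrow = n_pos, ncol = 1,
              dimnames = list(NULL, ref_species))
  if (length(others) > 0) {
    Po <- matrix(0, nrow = n_pos, ncol = length(others),
                 dimnames = list(NULL, others))
    for (s in others) {
      col <- species_max[, s]
      absent <- !is.finite(col)
      if (cfg$model == "binary") {
        pr <- ifelse(col >= threshold, 1, 0)
      } else {
        if (is.null(ref_scores)) {
          stop(sprintf("%s model needs ref_scores", cfg$model))
        }
        pr <- pmin(pmax(stats::ecdf(ref_scores)(col), 0), 1)
        if (cfg$model == "gated") pr <- ifelse(col >= threshold, pr, 0)
      }
      pr[absent] <- 0
      Po[, s] <- pr
    }
    P <- cbind(P, Po)
  }
  vals <- bbls_many(tree, P)
  score_track(ref_track$seq_id, "bbls", ref_track$motif_length,
              vals, vals, ref_track$offset)
}

#' Calibrate the BBLS cutoff percentile on benchmark datasets
#'
#' Evaluates a grid of percentiles on one or more calibration benchmarks
#' and returns the percentile with the highest mean ROC AUC; ties are
#' broken toward higher mean ROC-50 and then toward the higher percentile.
#'
#' @param benchmarks list of calibration benchmarks (passed through to
#'   \code{evaluator}).
#' @param evaluator function(benchmark, percentile) returning a
#'   [roc_result()] (or any list with \code{auc} and \code{roc50}).
#' @param grid percentile grid (default \code{c(50, 75, 90, 95, 99)}).
#' @return list with \code{best} (the selected percentile) and
#'   \code{table} (data.frame of percentile, mean_roc, mean_roc50).
#' @export
calibrate_cutoff <- function(benchmarks, evaluator,
                             grid = c(50, 75, 90, 95, 99)) {
  stopifnot(length(grid) >= 1L, length(benchmarks) >= 1L)
  rows <- lapply(grid, function(q) {
    rr <- lapply(benchmarks, evaluator, percentile = q)
    data.frame(percentile = q,
               mean_roc = mean(vapply(rr, function(x) x$auc, 0)),
               mean_roc50 = mean(vapply(rr, function(x) x$roc50, 0)))
  })
  tab <- do.call(rbind, rows)
  ord <- order(-tab$mean_roc, -tab$mean_roc50, -tab$percentile)
  list(best = tab$percentile[ord[1]], table = tab)
}
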