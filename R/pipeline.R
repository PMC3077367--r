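# High-level pipeline: genome-wide score tracks per method, slicing per
# benchmark region, and AUC tables across methods.

#' Slice a genomic score track to a sub-interval
#'
#' Keeps motif-start positions in [start, end - L] so every retained
#' window lies inside the interval.
#'
#' @param track a [score_track()].
#' @param start,end 0-based half-open genomic interval.
#' @return a [score_track()] with offset \code{start}.
#' @export
slice_track <- function(track, start, end) {
  L <- track$motif_length
  i0 <- max(start - track$offset + 1, 1)
  i1 <- min(end - L - track$offset + 1, length(track$fwd))
  if (i1 < i0) {
    return(empty_track(track$seq_id, track$method, L, start))
  }
  score_track(track$seq_id, track$method, L, track$fwd[i0:i1],
              track$rev[i0:i1], track$offset + i0 - 1)
}

#' Genome-wide score track for one method
#'
#' Dispatches to the five scoring methods. Conservation methods need the
#' alignment blocks and (for BBLS) the tree; thresholds for BBLS are
#' computed from the reference genome's own per-position score
#' distribution at the configured percentile.
#'
#' @param method one of \code{"pwm"}, \code{"motifscan"}, \code{"ws"},
#'   \code{"bbls_pwm"}, \code{"bbls_ms"}.
#' @param genome reference genome as a single DNA string (one chromosome).
#' @param pwm a [build_pwm()] result (pwm/ws/bbls_pwm).
#' @param kmers,submat [kmer_set()] and [build_substitution_matrix()]
#'   (motifscan/bbls_ms).
#' @param blocks list of [alignment_block()] (conservation methods).
#' @param tree \code{ape::phylo} (BBLS).
#' @param ref_species reference species id (conservation methods).
#' @param ws_cfg a [ws_config()]; default weights 0.25 per non-reference
#'   species found in the blocks.
#' @param bbls_cfg a [bbls_config()].
#' @param ms_cfg a [motifscan_config()].
#' @param seq_id stored sequence id.
#' @return a [score_track()].
#' @export
score_genome <- function(method, genome, pwm = NULL, kmers = NULL,
                         submat = NULL, blocks = NULL, tree = NULL,
                         ref_species = NULL, ws_cfg = ws_config(),
                         bbls_cfg = bbls_config(),
                         ms_cfg = motifscan_config(), seq_id = "genome") {
  method <- match.arg(method,
                      c("pwm", "motifscan", "ws", "bbls_pwm", "bbls_ms"))
  base_scorer <- switch(
    method,
    pwm = , ws = , bbls_pwm = {
      stopifnot(!is.null(pwm))
      function(s) scan_pwm(s, pwm)
    },
    motifscan = , bbls_ms = {
      stopifnot(!is.null(kmers), !is.null(submat))
      function(s) scan_motifscan(s, kmers, submat, ms_cfg)
    })
  ref_track <- base_scorer(genome)
  ref_track$seq_id <- seq_id
  if (method %in% c("pwm", "motifscan")) return(ref_track)
  stopifnot(!is.null(blocks), !is.null(ref_species))
  if (method == "ws") {
    species <- setdiff(unique(unlist(lapply(blocks,
                                            function(b) b$records$species))),
                       ref_species)
    if (!is.null(ws_cfg$weights)) species <- names(ws_cfg$weights)
    sm <- species_window_max(blocks, ref_species, species, base_scorer,
                             ws_cfg$h, ref_track$motif_length,
                             length(ref_track$fwd), ref_track$offset)
    return(ws_score(ref_track, sm, ws_cfg))
  }
  stopifnot(!is.null(tree))
  ref_scores <- track_best(ref_track)
  threshold <- percentile_cutoff(ref_scores, bbls_cfg$q)
  out <- bbls_track(ref_track, blocks, tree, base_scorer, threshold,
                    ref_species, bbls_cfg, ref_scores = ref_scores)
  out$method <- method
  out
}

#' Evaluate scoring methods on a benchmark dataset
#'
#' Computes a genome-wide track per method, slices it to each test
#' region, labels peak/negative maxima and reports ROC AUC and ROC-50
#' under the negatives-first tie policy.
#'
#' @param dataset a [benchmark_dataset()] on a single chromosome.
#' @param genome the reference chromosome sequence (DNA string).
#' @param methods character vector of method names (see
#'   [score_genome()]).
#' @param ... passed to [score_genome()] (pwm, kmers, blocks, tree, ...).
#' @return list with \code{results} (data.frame: method, auc, roc50,
#'   n_pos, n_neg) and \code{labels} (named list of labeled-score
#'   data.frames per method).
#' @export
evaluate_methods <- function(dataset, genome, methods = "pwm", ...) {
  labels <- list()
  rows <- list()
  for (m in methods) {
    gt <- score_genome(m, genome, ...)
    # every region reads from the genome-wide track, as in a genome-wide
    # scan; motif windows may extend past a region boundary
    tracks <- rep(list(gt), nrow(dataset$regions))
    names(tracks) <- dataset$regions$region_id
    lab <- label_scores(dataset, tracks)
    rr <- roc_auc(lab)
    labels[[m]] <- lab
    rows[[m]] <- data.frame(method = m, auc = rr$auc, roc50 = rr$roc50,
                            n_pos = rr$n_pos, n_neg = rr$n_neg,
                            stringsAsFactors = FALSE)
  }
  list(results = do.call(rbind, rows), labels = labels)
}

#' ROC within a peak-height stratum of labeled scores
#'
#' Restricts the positives of a labeled-score table to those with height
#' strictly below/above the configured percentiles (computed over all
#' positive heights) while keeping every negative, and recomputes the
#' ROC. Convenience equivalent of [stratify_by_height()] +
#' [label_scores()] when the labels are already in hand.
#'
#' @param labels a labeled-score data.frame from [label_scores()].
#' @param stratum \code{"low"} or \code{"high"}.
#' @param cfg a [stratify_config()].
#' @return a [roc_auc()] result.
#' @export
roc_by_stratum <- function(labels, stratum = c("low", "high"),
                           cfg = stratify_config()) {
  stratum <- match.arg(stratum)
  h <- labels$height[labels$label == "positive"]
  qs <- stats::quantile(h, c(cfg$low, cfg$high) / 100, type = 7,
                        names = FALSE)
  keep <- labels$label == "negative" |
    (if (stratum == "low") labels$height < qs[1] else labels$height > qs[2])
  roc_auc(labels[keep, , drop = FALSE])
}
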