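# Construction of the site and promoter benchmark datasets from peak
# calls, gene annotations, chromosome sizes and an exclusion mask.

#' Site benchmark configuration
#'
#' @param region_length test-region length L_T in bp (default 20000: a
#'   randomly placed region surrounding each peak, roughly 100x the
#'   average peak).
#' @param chunk_length negative sub-region length c in bp (default 200, so
#'   positives and negatives are of approximately equal length).
#' @param seed integer seed for the random placement (NULL: use the
#'   current RNG state).
#' @return object of class \code{site_benchmark_config}.
#' @export
site_benchmark_config <- function(region_length = 20000L,
                                  chunk_length = 200L, seed = NULL) {
  stopifnot(region_length > chunk_length, chunk_length > 0)
  structure(list(region_length = as.integer(region_length),
                 chunk_length = as.integer(chunk_length), seed = seed),
            class = "site_benchmark_config")
}

#' Promoter benchmark configuration
#'
#' @param upstream bp upstream of the TSS in the promoter region (2000).
#' @param downstream bp downstream of the TSS (200).
#' @param intron_cap maximum first-intron region length (3000), measured
#'   downstream from the start of the first intron.
#' @return object of class \code{promoter_benchmark_config}.
#' @export
promoter_benchmark_config <- function(upstream = 2000L, downstream = 200L,
                                      intron_cap = 3000L) {
  stopifnot(upstream > 0, downstream > 0, intron_cap > 0)
  structure(list(upstream = as.integer(upstream),
                 downstream = as.integer(downstream),
                 intron_cap = as.integer(intron_cap)),
            class = "promoter_benchmark_config")
}

#' Benchmark dataset container
#'
#' @param dataset_id TF / cell-line label.
#' @param regions data.frame of test regions: \code{region_id},
#'   \code{chrom}, \code{start}, \code{end}, \code{kind} (site, promoter
#'   or intron).
#' @param peaks data.frame of positive peak regions with \code{region_id},
#'   \code{chrom}, \code{start}, \code{end}, \code{height}.
#' @param negatives data.frame of negative sub-regions with
#'   \code{region_id}, \code{chrom}, \code{start}, \code{end}.
#' @param config provenance configuration object.
#' @return object of class \code{benchmark_dataset}.
#' @export
benchmark_dataset <- function(dataset_id, regions, peaks, negatives,
                              config = NULL) {
  stopifnot(is.data.frame(regions), is.data.frame(peaks),
            is.data.frame(negatives))
  structure(list(dataset_id = dataset_id, regions = regions, peaks = peaks,
                 negatives = negatives, config = config),
            class = "benchmark_dataset")
}

#' @export
print.benchmark_dataset <- function(x, ...) {
  cat(sprintf("benchmark_dataset '%s': %d regions, %d peaks, %d negatives\n",
              x$dataset_id, nrow(x$regions), nrow(x$peaks),
              nrow(x$negatives)))
  invisible(x)
}

#' Randomly place a test region around each peak
#'
#' Each peak gets a region of exactly \code{region_length} bp whose start
#' is the peak start minus U, with U uniform on \code{0 .. L_T - peak
#' length} from the seeded generator. Regions falling off a chromosome
#' edge are shifted inward, preserving their length and the containment of
#' their peak.
#'
#' @param peaks peak data.frame (chrom/start/end/height).
#' @param chrom_sizes named vector of chromosome lengths.
#' @param cfg a [site_benchmark_config()].
#' @return data.frame of regions with one peak index each
#'   (\code{region_id}, \code{chrom}, \code{start}, \code{end},
#'   \code{peak_idx}).
#' @export
place_site_regions <- function(peaks, chrom_sizes, cfg = site_benchmark_config()) {
  L_T <- cfg$region_length
  lens <- peaks$end - peaks$start
  too_long <- which(lens > L_T)
  if (length(too_long) > 0) {
    stop(sprintf("peak(s) longer than the %d bp test region: %s", L_T,
                 paste(sprintf("%s:%d-%d", peaks$chrom[too_long],
                               as.integer(peaks$start[too_long]),
                               as.integer(peaks$end[too_long])),
                       collapse = ", ")))
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  span <- L_T - lens
  U <- vapply(span, function(s) sample.int(s + 1L, 1L) - 1L, 0L)
  start <- peaks$start - U
  size <- chrom_sizes[peaks$chrom]
  if (anyNA(size)) stop("peak chromosome missing from chrom_sizes")
  if (any(size < L_T)) stop("chromosome shorter than the test region length")
  start <- pmax(start, 0)
  start <- pmin(start, size - L_T)
  data.frame(region_id = sprintf("region%04d", seq_len(nrow(peaks))),
             chrom = peaks$chrom, start = start, end = start + L_T,
             peak_idx = seq_len(nrow(peaks)), stringsAsFactors = FALSE)
}

#' Iteratively merge overlapping test regions, conserving total length
#'
#' Two overlapping regions are replaced by one region that starts at the
#' leftmost merged start and whose length equals the sum of the two
#' lengths, so the ratio of peak to non-peak sequence is conserved. The
#' merge repeats until no overlaps remain; merging is deterministic (no
#' RNG). If a merged region would run past its chromosome end it is
#' shifted left, preserving length and peak containment.
#'
#' @param regions data.frame from [place_site_regions()].
#' @param chrom_sizes named vector of chromosome lengths (optional; used
#'   only for the edge shift).
#' @return data.frame of merged regions; the \code{peak_idx} column
#'   becomes a list column of the contained peak indices.
#' @export
merge_overlapping <- function(regions, chrom_sizes = NULL) {
  out <- list()
  for (chrom in unique(regions$chrom)) {
    sub <- regions[regions$chrom == chrom, , drop = FALSE]
    items <- lapply(seq_len(nrow(sub)), function(i) {
      list(start = sub$start[i], end = sub$end[i],
           peaks = if (is.list(sub$peak_idx)) sub$peak_idx[[i]] else sub$peak_idx[i])
    })
    repeat {
      items <- items[order(vapply(items, `[[`, 0, "start"))]
      merged_any <- FALSE
      i <- 1L
      res <- list()
      while (i <= length(items)) {
        cur <- items[[i]]
        j <- i + 1L
        while (j <= length(items) && items[[j]]$start < cur$end) {
          nxt <- items[[j]]
          len <- (cur$end - cur$start) + (nxt$end - nxt$start)
          cur <- list(start = min(cur$start, nxt$start),
                      end = min(cur$start, nxt$start) + len,
                      peaks = c(cur$peaks, nxt$peaks))
          if (!is.null(chrom_sizes) && !is.na(chrom_sizes[chrom]) &&
              cur$end > chrom_sizes[chrom]) {
            shift <- cur$end - chrom_sizes[chrom]
            cur$start <- cur$start - shift
            cur$end <- cur$end - shift
          }
          merged_any <- TRUE
          j <- j + 1L
        }
        res[[length(res) + 1L]] <- cur
        i <- j
      }
      items <- res
      if (!merged_any) break
    }
    for (it in items) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = it$start, end = it$end,
        stringsAsFactors = FALSE)
      out[[length(out)]]$peak_idx <- I(list(it$peaks))
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  res$region_id <- sprintf("region%04d", seq_len(nrow(res)))
  rownames(res) <- NULL
  res[, c("region_id", "chrom", "start", "end", "peak_idx")]
}

#' Cut the peak-free remainder of a region into negative chunks
#'
#' Non-peak, non-masked gaps are cut into consecutive \code{c}-bp chunks
#' from each gap's left edge. A terminal remainder of at least c/2 stands
#' as its own chunk; a shorter remainder merges into the previous chunk. A
#' gap shorter than c forms a single chunk of its own length.
#'
#' @param region one-row data.frame (or list) with \code{chrom},
#'   \code{start}, \code{end}.
#' @param peaks data.frame of peak intervals inside the region.
#' @param mask data.frame of masked intervals (excluded peak calls); may
#'   be NULL.
#' @param chunk_length chunk size c (default 200).
#' @return data.frame of negative intervals (\code{chrom}, \code{start},
#'   \code{end}).
#' @export
chunk_negatives <- function(region, peaks, mask = NULL, chunk_length = 200L) {
  c_len <- as.integer(chunk_length)
  blocked <- peaks[, c("start", "end"), drop = FALSE]
  if (!is.null(mask) && nrow(mask) > 0) {
    m <- mask[mask$chrom == region$chrom &
                mask$end > region$start & mask$start < region$end,
              c("start", "end"), drop = FALSE]
    blocked <- rbind(blocked, m)
  }
  gaps <- subtract_intervals(region$start, region$end, blocked)
  out_s <- numeric(0); out_e <- numeric(0)
  for (g in seq_len(nrow(gaps))) {
    gs <- gaps$start[g]; ge <- gaps$end[g]
    len <- ge - gs
    if (len <= 0) next
    n_full <- len %/% c_len
    rem <- len - n_full * c_len
    if (n_full == 0L) {
      out_s <- c(out_s, gs); out_e <- c(out_e, ge)
    } else {
      starts <- gs + c_len * (seq_len(n_full) - 1L)
      ends <- starts + c_len
      if (rem == 0) {
        # exact division
      } else if (rem >= c_len / 2) {
        starts <- c(starts, gs + c_len * n_full)
        ends <- c(ends, ge)
      } else {
        ends[n_full] <- ge  # short remainder merges into the last chunk
      }
      out_s <- c(out_s, starts); out_e <- c(out_e, ends)
    }
  }
  data.frame(chrom = rep(region$chrom, length(out_s)), start = out_s,
             end = out_e, stringsAsFactors = FALSE)
}

#' Build a site benchmark from peak calls
#'
#' Places a test region of \code{cfg$region_length} bp randomly around
#' each peak, merges overlapping regions conserving total length, and cuts
#' the peak-free remainder of each region (minus the exclusion mask) into
#' \code{cfg$chunk_length}-bp negative chunks.
#'
#' @param peaks peak data.frame (chrom/start/end/height), e.g. from
#'   [read_bed()].
#' @param chrom_sizes named vector of chromosome lengths.
#' @param mask optional data.frame of intervals excluded from the
#'   negatives (peaks called by any single peak caller).
#' @param cfg a [site_benchmark_config()].
#' @param dataset_id label for the dataset.
#' @return a [benchmark_dataset()].
#' @export
build_site_benchmark <- function(peaks, chrom_sizes, mask = NULL,
                                 cfg = site_benchmark_config(),
                                 dataset_id = "dataset") {
  placed <- place_site_regions(peaks, chrom_sizes, cfg)
  merged <- merge_overlapping(placed, chrom_sizes)
  peak_rows <- list(); neg_rows <- list()
  for (i in seq_len(nrow(merged))) {
    idx <- merged$peak_idx[[i]]
    pk <- peaks[idx, , drop = FALSE]
    pk$region_id <- merged$region_id[i]
    peak_rows[[i]] <- pk[, c("region_id", "chrom", "start", "end", "height")]
    neg <- chunk_negatives(merged[i, ], pk, mask, cfg$chunk_length)
    if (nrow(neg) > 0) neg$region_id <- merged$region_id[i]
    neg_rows[[i]] <- neg
  }
  regions <- merged[, c("region_id", "chrom", "start", "end")]
  regions$kind <- "site"
  negatives <- do.call(rbind, neg_rows[vapply(neg_rows, nrow, 0L) > 0])
  benchmark_dataset(dataset_id, regions, do.call(rbind, peak_rows),
                    negatives[, c("region_id", "chrom", "start", "end")],
                    config = cfg)
}

#' Build a promoter benchmark from gene annotations and peaks
#'
#' Two test regions per gene: the promoter (upstream/downstream of the
#' TSS, strand-aware) and the first intron capped at
#' \code{cfg$intron_cap} bp downstream from the intron start. Among genes
#' with overlapping promoter or intron regions only the first region in
#' (chrom, start) order is kept. Peaks are mapped into the regions; a
#' peak partially overlapping a region extends the region to fully
#' contain it. Negatives are the peak-free flanks of each region (minus
#' the mask) and are not subdivided.
#'
#' @param genes data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{strand} (+/-), \code{tss} (0-based position of the transcription
#'   start), and optionally \code{intron_start}, \code{intron_end} (NA for
#'   genes without an intron).
#' @param peaks peak data.frame (chrom/start/end/height).
#' @param chrom_sizes named vector of chromosome lengths.
#' @param mask optional excluded intervals.
#' @param cfg a [promoter_benchmark_config()].
#' @param dataset_id label.
#' @return a [benchmark_dataset()] with region kinds \code{promoter} and
#'   \code{intron}.
#' @export
build_promoter_benchmark <- function(genes, peaks, chrom_sizes, mask = NULL,
                                     cfg = promoter_benchmark_config(),
                                     dataset_id = "dataset") {
  regs <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (g$strand == "+") {
      ps <- g$tss - cfg$upstream; pe <- g$tss + cfg$downstream
    } else {
      ps <- g$tss - cfg$downstream; pe <- g$tss + cfg$upstream
    }
    regs[[length(regs) + 1L]] <- data.frame(
      gene_id = g$gene_id, chrom = g$chrom, start = ps, end = pe,
      kind = "promoter", stringsAsFactors = FALSE)
    has_intron <- !is.null(g$intron_start) && !is.na(g$intron_start) &&
      !is.na(g$intron_end)
    if (has_intron) {
      if (g$strand == "+") {
        is_ <- g$intron_start
        ie <- min(g$intron_end, g$intron_start + cfg$intron_cap)
      } else {
        ie <- g$intron_end
        is_ <- max(g$intron_start, g$intron_end - cfg$intron_cap)
      }
      regs[[length(regs) + 1L]] <- data.frame(
        gene_id = g$gene_id, chrom = g$chrom, start = is_, end = ie,
        kind = "intron", stringsAsFactors = FALSE)
    }
  }
  regs <- do.call(rbind, regs)
  size <- chrom_sizes[regs$chrom]
  regs$start <- pmax(regs$start, 0)
  regs$end <- pmin(regs$end, ifelse(is.na(size), Inf, size))
  regs <- regs[regs$start < regs$end, , drop = FALSE]
  regs <- regs[order(regs$chrom, regs$start, regs$end), , drop = FALSE]
  # keep the first of any overlapping regions
  keep <- logical(nrow(regs))
  last_end <- -Inf; last_chrom <- ""
  for (i in seq_len(nrow(regs))) {
    if (regs$chrom[i] != last_chrom || regs$start[i] >= last_end) {
      keep[i] <- TRUE
      last_chrom <- regs$chrom[i]; last_end <- regs$end[i]
    }
  }
  regs <- regs[keep, , drop = FALSE]
  regs$region_id <- sprintf("region%04d", seq_len(nrow(regs)))
  peak_rows <- list(); neg_rows <- list()
  for (i in seq_len(nrow(regs))) {
    r <- regs[i, ]
    hit <- which(peaks$chrom == r$chrom & peaks$end > r$start &
                   peaks$start < r$end)
    pk <- peaks[hit, , drop = FALSE]
    if (nrow(pk) > 0) {
      # extend the region to fully encompass partially overlapping peaks
      regs$start[i] <- min(r$start, min(pk$start))
      regs$end[i] <- max(r$end, max(pk$end))
      r <- regs[i, ]
      pk$region_id <- r$region_id
      peak_rows[[length(peak_rows) + 1L]] <-
        pk[, c("region_id", "chrom", "start", "end", "height")]
    }
    blocked <- pk[, c("start", "end"), drop = FALSE]
    if (!is.null(mask) && nrow(mask) > 0) {
      m <- mask[mask$chrom == r$chrom & mask$end > r$start &
                  mask$start < r$end, c("start", "end"), drop = FALSE]
      blocked <- rbind(blocked, m)
    }
    neg <- subtract_intervals(r$start, r$end, blocked)
    if (nrow(neg) > 0) {
      neg$chrom <- r$chrom
      neg$region_id <- r$region_id
      neg_rows[[length(neg_rows) + 1L]] <-
        neg[, c("region_id", "chrom", "start", "end")]
    }
  }
  benchmark_dataset(
    dataset_id,
    regs[, c("region_id", "chrom", "start", "end", "kind")],
    if (length(peak_rows)) do.call(rbind, peak_rows) else
      data.frame(region_id = character(0), chrom = character(0),
                 start = numeric(0), end = numeric(0), height = numeric(0)),
    if (length(neg_rows)) do.call(rbind, neg_rows) else
      data.frame(region_id = character(0), chrom = character(0),
                 start = numeric(0), end = numeric(0)),
    config = cfg)
}

#' Write / read a benchmark dataset as text
#'
#' \code{write_benchmark} emits two files: \code{<prefix>_regions.txt} in
#' the semicolon dialect (one line per test region: "chrom start stop
#' label" then any contained peak regions "chrom start stop height"
#' separated by semicolons) and \code{<prefix>_negatives.bed}.
#' \code{read_benchmark} reconstructs the dataset from them.
#'
#' @param dataset a [benchmark_dataset()].
#' @param prefix output path prefix.
#' @return \code{write_benchmark}: the prefix, invisibly;
#'   \code{read_benchmark}: a [benchmark_dataset()].
#' @export
write_benchmark <- function(dataset, prefix) {
  lines <- vapply(seq_len(nrow(dataset$regions)), function(i) {
    r <- dataset$regions[i, ]
    pk <- dataset$peaks[dataset$peaks$region_id == r$region_id, , drop = FALSE]
    head <- sprintf("%s %d %d %s", r$chrom, as.integer(r$start),
                    as.integer(r$end), dataset$dataset_id)
    if (nrow(pk) == 0) return(head)
    paste(c(head, sprintf("%s %d %d %s", pk$chrom, as.integer(pk$start),
                          as.integer(pk$end),
                          format(pk$height, trim = TRUE, scientific = FALSE))),
          collapse = ";")
  }, "")
  writeLines(lines, paste0(prefix, "_regions.txt"))
  neg <- dataset$negatives
  writeLines(sprintf("%s\t%d\t%d\t%s", neg$chrom, as.integer(neg$start),
                     as.integer(neg$end), neg$region_id),
             paste0(prefix, "_negatives.bed"))
  invisible(prefix)
}

#' @rdname write_benchmark
#' @export
read_benchmark <- function(prefix) {
  lines <- readLines(paste0(prefix, "_regions.txt"))
  regions <- list(); peaks <- list()
  dataset_id <- "dataset"
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], ";", fixed = TRUE)[[1]]
    head <- strsplit(trimws(fields[1]), "\\s+")[[1]]
    if (length(head) < 4L) {
      stop(sprintf("benchmark line %d: expected 'chrom start stop label'", i))
    }
    rid <- sprintf("region%04d", i)
    dataset_id <- head[4]
    regions[[i]] <- data.frame(region_id = rid, chrom = head[1],
                               start = as.numeric(head[2]),
                               end = as.numeric(head[3]), kind = "site",
                               stringsAsFactors = FALSE)
    if (length(fields) > 1L) {
      for (f in fields[-1]) {
        p <- strsplit(trimws(f), "\\s+")[[1]]
        peaks[[length(peaks) + 1L]] <- data.frame(
          region_id = rid, chrom = p[1], start = as.numeric(p[2]),
          end = as.numeric(p[3]),
          height = if (length(p) >= 4L) as.numeric(p[4]) else 0,
          stringsAsFactors = FALSE)
      }
    }
  }
  neg_path <- paste0(prefix, "_negatives.bed")
  neg_raw <- utils::read.table(neg_path, header = FALSE, sep = "\t",
                               stringsAsFactors = FALSE)
  negatives <- data.frame(region_id = neg_raw[[4]], chrom = neg_raw[[1]],
                          start = as.numeric(neg_raw[[2]]),
                          end = as.numeric(neg_raw[[3]]),
                          stringsAsFactors = FALSE)
  benchmark_dataset(dataset_id, do.call(rbind, regions),
                    if (length(peaks)) do.call(rbind, peaks) else
                      data.frame(region_id = character(0), chrom = character(0),
                                 start = numeric(0), end = numeric(0),
                                 height = numeric(0)),
                    negatives)
}
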