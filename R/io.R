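# Readers and writers for the standard text formats the toolkit touches:
# BED peaks, FASTA, MAF alignment blocks, JASPAR/TRANSFAC count matrices,
# k-mer lists, newick trees, fixedStep wiggle tracks, and the benchmark
# region dialect. All coordinates are 0-based half-open internally.

#' Read peak regions from a BED-like file
#'
#' Expects at least three tab- (or whitespace-) separated columns
#' chrom/start/end. Column 4, when present, is kept as the region name and
#' column 5 is parsed as the peak height (ChIP-seq tag count); missing
#' heights default to 0. Extra columns are ignored. Input order is
#' preserved.
#'
#' @param path path to a BED file.
#' @return a data.frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{name}, \code{height}. Coordinates are 0-based half-open as in BED.
#' @examples
#' tf <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t300\tp1\t57", tf)
#' read_bed(tf)
#' @export
read_bed <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  rows <- lapply(idx, function(i) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) < 3L) stop_bad_line(path, i, "fewer than 3 columns")
    start <- suppressWarnings(as.numeric(f[2]))
    end <- suppressWarnings(as.numeric(f[3]))
    if (is.na(start) || is.na(end)) {
      stop_bad_line(path, i, "non-numeric start/end")
    }
    if (start >= end) stop_bad_line(path, i, sprintf(
      "start (%s) must be < end (%s)", f[2], f[3]))
    height <- 0
    if (length(f) >= 5L) {
      height <- suppressWarnings(as.numeric(f[5]))
      if (is.na(height)) stop_bad_line(path, i, "non-numeric height column")
    }
    list(chrom = f[1], start = start, end = end,
         name = if (length(f) >= 4L) f[4] else NA_character_,
         height = height)
  })
  out <- data.frame(
    chrom = vapply(rows, `[[`, "", "chrom"),
    start = vapply(rows, `[[`, 0, "start"),
    end = vapply(rows, `[[`, 0, "end"),
    name = vapply(rows, `[[`, "", "name"),
    height = vapply(rows, `[[`, 0, "height"),
    stringsAsFactors = FALSE
  )
  long <- out$end - out$start
  if (any(out$height > 0 & (long < 100 | long > 400))) {
    warning("some peaks fall outside the typical 100-400 bp trimmed length")
  }
  out
}

#' Write peak regions to BED (name in column 4, height in column 5)
#' @param peaks data.frame as returned by [read_bed()].
#' @param path output path.
#' @export
write_bed <- function(peaks, path) {
  nm <- peaks$name
  if (is.null(nm)) nm <- rep(NA_character_, nrow(peaks))
  nm[is.na(nm)] <- "."
  h <- peaks$height
  if (is.null(h)) h <- rep(0, nrow(peaks))
  writeLines(sprintf("%s\t%d\t%d\t%s\t%s", peaks$chrom,
                     as.integer(peaks$start), as.integer(peaks$end), nm,
                     format(h, trim = TRUE, scientific = FALSE)), path)
  invisible(path)
}

#' Read a two-column chromosome sizes file
#' @param path TSV with chromosome name and length in bp.
#' @return named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df[[2]]), df[[1]])
}

#' Read/write FASTA sequences
#'
#' Thin wrappers over Biostrings returning plain named character vectors,
#' which is how sequences travel inside this package.
#' @param path FASTA file.
#' @return named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# MAF multiple alignment blocks

#' Construct an alignment block
#'
#' One paragraph of a MAF file: per-species records of source interval and
#' aligned text (with "-" gaps). The first record is conventionally the
#' reference species. Species ids are the part of the MAF source name before
#' the first dot (assembly names such as hg18), the remainder is the
#' chromosome.
#'
#' @param records data.frame with columns \code{species}, \code{chrom},
#'   \code{start} (0-based), \code{size} (ungapped length), \code{strand},
#'   \code{src_size}, \code{text} (aligned sequence with gaps).
#' @return object of class \code{alignment_block}.
#' @export
alignment_block <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  widths <- nchar(records$text)
  if (length(unique(widths)) != 1L) {
    stop("aligned texts within a block must have equal length")
  }
  ungapped <- nchar(gsub("-", "", records$text, fixed = TRUE))
  if (any(ungapped != records$size)) {
    stop("record size does not match its ungapped text length")
  }
  if (anyDuplicated(records$species)) {
    stop("duplicate species in alignment block")
  }
  structure(list(records = records, width = widths[1]),
            class = "alignment_block")
}

#' @export
print.alignment_block <- function(x, ...) {
  cat(sprintf("alignment_block: %d species, %d columns\n",
              nrow(x$records), x$width))
  invisible(x)
}

#' Read a MAF multiple alignment file
#'
#' Parses "a"-line paragraphs with "s"-lines into [alignment_block()]
#' objects. Reverse-strand records keep their aligned text exactly as
#' written, with the strand recorded, so the block's columns always line up.
#'
#' @param path MAF file.
#' @return list of \code{alignment_block}.
#' @export
read_maf <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  blocks <- list()
  cur <- NULL
  flush <- function(cur) {
    if (is.null(cur) || length(cur) == 0L) return(NULL)
    recs <- do.call(rbind, cur)
    alignment_block(recs)
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^a(\\s|$)", ln)) {
      b <- flush(cur)
      if (!is.null(b)) blocks[[length(blocks) + 1L]] <- b
      cur <- list()
    } else if (grepl("^s\\s", ln)) {
      if (is.null(cur)) stop_bad_line(path, i, "s-line before any a-line")
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(f) < 7L) stop_bad_line(path, i, "s-line with fewer than 7 fields")
      src <- f[2]
      dot <- regexpr(".", src, fixed = TRUE)
      species <- if (dot > 0) substr(src, 1, dot - 1) else src
      chrom <- if (dot > 0) substr(src, dot + 1, nchar(src)) else src
      cur[[length(cur) + 1L]] <- data.frame(
        species = species, chrom = chrom,
        start = as.numeric(f[3]), size = as.numeric(f[4]),
        strand = f[5], src_size = as.numeric(f[6]),
        text = toupper(f[7]), stringsAsFactors = FALSE)
    }
  }
  b <- flush(cur)
  if (!is.null(b)) blocks[[length(blocks) + 1L]] <- b
  blocks
}

#' Write alignment blocks to MAF
#' @param blocks list of [alignment_block()].
#' @param path output path.
#' @export
write_maf <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  for (b in blocks) {
    writeLines("", con)
    writeLines("a score=0", con)
    r <- b$records
    writeLines(sprintf("s %s.%s %d %d %s %d %s", r$species, r$chrom,
                       as.integer(r$start), as.integer(r$size), r$strand,
                       as.integer(r$src_size), r$text), con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Motif matrices and k-mer lists

#' Read a motif count matrix (JASPAR or TRANSFAC dialect)
#'
#' JASPAR: an optional \code{>id name} header followed by four rows labeled
#' A/C/G/T, with counts optionally wrapped in square brackets. TRANSFAC: a
#' paragraph whose column header line starts with \code{P0} (or \code{PO})
#' listing A C G T, followed by one numbered row per motif position,
#' terminated by \code{XX}.
#'
#' @param path motif file.
#' @param dialect \code{"jaspar"} or \code{"transfac"}.
#' @return a [count_matrix()].
#' @export
read_motif_matrix <- function(path, dialect = c("jaspar", "transfac")) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  lines <- readLines(path)
  if (dialect == "jaspar") {
    id <- NA_character_
    hdr <- grep("^>", lines)
    if (length(hdr) > 0) {
      id <- strsplit(sub("^>", "", lines[hdr[1]]), "\\s+")[[1]][1]
    }
    rows <- list()
    for (i in seq_along(lines)) {
      m <- regmatches(lines[i], regexec("^[ \t]*([ACGT])[ \t|\\[]+(.*)$", lines[i]))[[1]]
      if (length(m) == 3L) {
        body <- trimws(gsub("[][|]", " ", m[3]))
        if (!nzchar(body)) next
        vals <- suppressWarnings(as.numeric(strsplit(body, "\\s+")[[1]]))
        if (anyNA(vals)) stop_bad_line(path, i, "non-numeric count")
        rows[[m[2]]] <- vals
      }
    }
    missing <- setdiff(DNA_BASES, names(rows))
    if (length(missing) > 0) {
      stop(sprintf("%s: missing base row(s): %s", path,
                   paste(missing, collapse = ", ")))
    }
    lens <- lengths(rows[DNA_BASES])
    if (length(unique(lens)) != 1L) stop("base rows have unequal lengths")
    counts <- do.call(rbind, rows[DNA_BASES])
    if (is.na(id)) id <- sub("\\.[^.]*$", "", basename(path))
    return(count_matrix(counts, motif_id = id))
  }
  # TRANSFAC
  id <- NA_character_
  for (tag in c("^ID\\s+", "^AC\\s+", "^NA\\s+")) {
    hit <- grep(tag, lines, value = TRUE)
    if (length(hit) > 0) { id <- sub(tag, "", hit[1]); break }
  }
  p0 <- grep("^P[0O]\\b", lines)
  if (length(p0) == 0L) stop(sprintf("%s: no P0 header line", path))
  hdr <- strsplit(trimws(lines[p0[1]]), "\\s+")[[1]][-1]
  base_order <- toupper(hdr[seq_len(min(4, length(hdr)))])
  if (!setequal(base_order, DNA_BASES)) {
    stop(sprintf("%s: P0 header must list A C G T", path))
  }
  mat <- list()
  for (i in seq(p0[1] + 1L, length(lines))) {
    ln <- trimws(lines[i])
    if (grepl("^XX", ln) || !nzchar(ln)) break
    f <- strsplit(ln, "\\s+")[[1]]
    if (!grepl("^[0-9]+$", f[1])) break
    if (length(f) < 5L) stop_bad_line(path, i, "position row with fewer than 4 counts")
    vals <- suppressWarnings(as.numeric(f[2:5]))
    if (anyNA(vals)) stop_bad_line(path, i, "non-numeric count")
    mat[[length(mat) + 1L]] <- vals
  }
  if (length(mat) == 0L) stop(sprintf("%s: no position rows", path))
  counts <- t(do.call(rbind, mat))
  rownames(counts) <- base_order
  counts <- counts[DNA_BASES, , drop = FALSE]
  if (is.na(id)) id <- sub("\\.[^.]*$", "", basename(path))
  count_matrix(counts, motif_id = trimws(id))
}

#' Read a plain-text k-mer list (one k-mer per line)
#'
#' Repeated lines accumulate multiplicity.
#' @param path text file.
#' @return a [kmer_set()].
#' @export
read_kmers <- function(path) {
  stopifnot(file.exists(path))
  km <- toupper(trimws(readLines(path)))
  km <- km[nzchar(km) & !grepl("^#", km)]
  if (length(km) == 0L) stop(sprintf("%s: no k-mers", path))
  tab <- table(km)
  kmer_set(names(tab), mult = as.integer(tab))
}

#' @rdname read_kmers
#' @param kmers a [kmer_set()].
#' @export
write_kmers <- function(kmers, path) {
  writeLines(rep(kmers$kmers, kmers$mult), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Trees

#' Read a newick tree with branch lengths
#'
#' Wraps \code{ape::read.tree} with stricter validation: unbalanced
#' parentheses are an error and missing branch lengths are set to 0 with a
#' warning. Leaf labels must be unique.
#'
#' @param path file containing a single newick string (a literal newick
#'   string is also accepted).
#' @return an \code{ape::phylo} tree.
#' @export
read_newick <- function(path) {
  txt <- if (file.exists(path)) paste(readLines(path), collapse = "") else path
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  n_open <- sum(chars == "(")
  n_close <- sum(chars == ")")
  if (n_open != n_close) stop("unbalanced parentheses in newick string")
  tree <- ape::read.tree(text = txt)
  if (is.null(tree)) stop("could not parse newick string")
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf labels in tree")
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; setting all to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  } else if (anyNA(tree$edge.length)) {
    warning("missing branch lengths set to 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  tree
}

#' Write a tree to a newick file
#' @param tree \code{ape::phylo}.
#' @param path output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# fixedStep wiggle

#' Read a fixedStep wiggle track
#'
#' The 1-based \code{start} of each declaration is converted to 0-based
#' positions; \code{step} is honored. A value line before any declaration is
#' an error.
#'
#' @param path fixedStep WIG file.
#' @return data.frame with columns \code{chrom}, \code{pos} (0-based),
#'   \code{value}.
#' @export
read_fixedstep_wig <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  chrom <- NULL; nxt <- NA_real_; step <- 1
  out_chrom <- character(0); out_pos <- numeric(0); out_val <- numeric(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || grepl("^(track|#)", ln)) next
    if (grepl("^fixedStep\\b", ln)) {
      get <- function(key, default = NA) {
        m <- regmatches(ln, regexec(paste0(key, "=(\\S+)"), ln))[[1]]
        if (length(m) == 2L) m[2] else default
      }
      chrom <- get("chrom")
      if (is.na(chrom)) stop_bad_line(path, i, "fixedStep without chrom=")
      start1 <- as.numeric(get("start"))
      if (is.na(start1)) stop_bad_line(path, i, "fixedStep without start=")
      step <- as.numeric(get("step", "1"))
      nxt <- start1 - 1  # 1-based wiggle start -> 0-based
    } else {
      if (is.null(chrom)) stop_bad_line(path, i, "value line before fixedStep declaration")
      v <- suppressWarnings(as.numeric(ln))
      if (is.na(v)) stop_bad_line(path, i, "non-numeric value")
      out_chrom <- c(out_chrom, chrom)
      out_pos <- c(out_pos, nxt)
      out_val <- c(out_val, v)
      nxt <- nxt + step
    }
  }
  data.frame(chrom = out_chrom, pos = out_pos, value = out_val,
             stringsAsFactors = FALSE)
}

#' Write a per-position score map as fixedStep wiggle (step 1)
#' @param scores data.frame as returned by [read_fixedstep_wig()].
#' @param path output path.
#' @export
write_fixedstep_wig <- function(scores, path) {
  con <- file(path, "w")
  on.exit(close(con))
  ord <- order(scores$chrom, scores$pos)
  scores <- scores[ord, , drop = FALSE]
  run_start <- c(TRUE, diff(scores$pos) != 1 |
                   scores$chrom[-1] != scores$chrom[-nrow(scores)])
  grp <- cumsum(run_start)
  for (g in unique(grp)) {
    sub <- scores[grp == g, , drop = FALSE]
    writeLines(sprintf("fixedStep chrom=%s start=%d step=1",
                       sub$chrom[1], as.integer(sub$pos[1]) + 1L), con)
    writeLines(format(sub$value, trim = TRUE, scientific = FALSE), con)
  }
  invisible(path)
}
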