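# Shared low-level helpers: DNA encoding, interval arithmetic, checks.

DNA_BASES <- c("A", "C", "G", "T")

#' Encode a DNA string as integer codes
#'
#' A, C, G, T map to 1..4; any other character (N and all other ambiguity
#' codes, in any case) maps to NA.
#'
#' @param seq single character string.
#' @return integer vector, one element per base.
#' @keywords internal
#' @noRd
seq_to_code <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  match(strsplit(toupper(seq), "", fixed = TRUE)[[1]], DNA_BASES)
}

code_to_seq <- function(code) {
  out <- DNA_BASES[code]
  out[is.na(out)] <- "N"
  paste(out, collapse = "")
}

#' Reverse complement of a DNA string (ambiguity codes become N, except N
#' which stays N).
#' @keywords internal
#' @noRd
revcomp <- function(seq) {
  chars <- rev(strsplit(chartr("ACGTacgt", "TGCAtgca", seq), "", fixed = TRUE)[[1]])
  chars[!chars %in% c(DNA_BASES, tolower(DNA_BASES))] <- "N"
  paste(toupper(chars), collapse = "")
}

# Merge overlapping-or-touching intervals given as a data.frame with
# columns start/end (0-based half-open). Returns sorted disjoint intervals.
merge_intervals <- function(df) {
  if (nrow(df) == 0L) return(df[, c("start", "end"), drop = FALSE])
  df <- df[order(df$start, df$end), , drop = FALSE]
  starts <- df$start
  ends <- df$end
  keep_start <- starts[1]
  out_s <- numeric(0)
  out_e <- numeric(0)
  cur_e <- ends[1]
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= cur_e) {
      cur_e <- max(cur_e, ends[i])
    } else {
      out_s <- c(out_s, keep_start)
      out_e <- c(out_e, cur_e)
      keep_start <- starts[i]
      cur_e <- ends[i]
    }
  }
  data.frame(start = c(out_s, keep_start), end = c(out_e, cur_e))
}

# Subtract merged intervals `sub` from a single interval [start, end);
# returns data.frame of the remaining gaps, left to right.
subtract_intervals <- function(start, end, sub) {
  if (nrow(sub) == 0L) return(data.frame(start = start, end = end))
  sub <- merge_intervals(sub)
  sub$start <- pmax(sub$start, start)
  sub$end <- pmin(sub$end, end)
  sub <- sub[sub$start < sub$end, , drop = FALSE]
  if (nrow(sub) == 0L) return(data.frame(start = start, end = end))
  gaps_s <- c(start, sub$end)
  gaps_e <- c(sub$start, end)
  keep <- gaps_s < gaps_e
  data.frame(start = gaps_s[keep], end = gaps_e[keep])
}

# Row-wise product of (1 - P) over a column subset; empty subset gives 1.
complement_product <- function(P, cols) {
  if (length(cols) == 0L) return(rep(1, nrow(P)))
  out <- rep(1, nrow(P))
  for (j in cols) out <- out * (1 - P[, j])
  out
}

stop_bad_line <- function(path, i, msg) {
  stop(sprintf("%s: line %d: %s", path, i, msg), call. = FALSE)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
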