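# Window projection, weighted-sum scoring, percentile cutoffs, leaf
# probabilities, BBLS against the exhaustive-enumeration oracle, and
# cutoff calibration.

block_from_texts <- function(texts, start = 0) {
  alignment_block(data.frame(
    species = names(texts), chrom = "chr1", start = start,
    size = nchar(gsub("-", "", texts, fixed = TRUE)), strand = "+",
    src_size = 10000, text = texts, stringsAsFactors = FALSE))
}

test_that("project_species_window extracts gap-free column windows", {
  b <- block_from_texts(c(hs = "ACGTA", mm = "ACGTA", rn = "AC-TA"))
  w0 <- project_species_window(b, 2, 0)
  expect_equal(unname(w0), c("G", "G", ""))
  # all-gap species row yields an empty string
  b2 <- block_from_texts(c(hs = "ACGT", mm = "----"))
  expect_equal(project_species_window(b2, 1, 1)[["mm"]], "")
  # indel shifts the window by columns, not coordinates
  b3 <- block_from_texts(c(hs = "AC-GT", mm = "ACTGT"))
  w <- project_species_window(b3, 2, 1)  # around the G, one base flank
  expect_equal(w[["hs"]], "CGT")
  expect_equal(w[["mm"]], "CTGT")
  expect_error(project_species_window(b3, 99, 1), "outside block")
})

test_that("ws_score adds weighted species maxima and honors gaps", {
  pwm <- build_pwm(count_matrix(matrix(c(9, 1, 1, 1, 1, 9, 1, 1), nrow = 4)))
  seq <- "TTACGTAC"
  ref <- scan_pwm(seq, pwm)
  # zero weights: WS is bitwise the reference track
  sm <- matrix(5, nrow = length(ref$fwd), ncol = 2,
               dimnames = list(NULL, c("mm", "rn")))
  ws0 <- ws_score(ref, sm, ws_config(weights = c(mm = 0, rn = 0)))
  expect_identical(ws0$fwd, ref$fwd)
  expect_identical(ws0$rev, ref$rev)
  # unaligned species (-Inf) contribute nothing
  sm_gap <- sm; sm_gap[, "rn"] <- -Inf
  ws1 <- ws_score(ref, sm_gap, ws_config(weights = c(mm = 0.25, rn = 0.25)))
  expect_equal(ws1$fwd, ref$fwd + 0.25 * 5)
  # identical aligned species at full weight add their own window max
  b <- block_from_texts(c(hs = seq, mm = seq, rn = seq))
  smx <- species_window_max(list(b), "hs", c("mm", "rn"),
                            function(s) scan_pwm(s, pwm), h = 15,
                            motif_length = 2, n_pos = length(ref$fwd))
  best <- max(track_best(ref))
  expect_equal(unname(smx[1, ]), rep(best, 2))
  ws2 <- ws_score(ref, smx, ws_config(weights = c(mm = 0.25, rn = 0.25)))
  i <- which.max(track_best(ref))
  expect_gte(max(ws2$fwd[i], ws2$rev[i]),
             max(ref$fwd[i], ref$rev[i]) + 0.5 * best - 1e-12)
})

test_that("species_window_max matches hand projection on gapped blocks", {
  pwm <- build_pwm(count_matrix(matrix(c(8, 1, 2, 1, 1, 7, 1, 1), nrow = 4)))
  hs_text <- "ACGT--ACGTAC"
  mm_text <- "AC-TGGAC--AC"
  b <- block_from_texts(c(hs = hs_text, mm = mm_text), start = 5)
  L <- 2L; h <- 2L
  smx <- species_window_max(list(b), "hs", "mm",
                            function(s) scan_pwm(s, pwm), h = h,
                            motif_length = L, n_pos = 30, ref_offset = 0)
  # independent column bookkeeping from the raw texts
  hs_ch <- strsplit(hs_text, "")[[1]]
  mm_ch <- strsplit(mm_text, "")[[1]]
  col_of_pos <- which(hs_ch != "-")          # column of ref base k
  ref_first <- 5L
  ref_last <- ref_first + length(col_of_pos) - 1L
  for (pos in ref_first:(ref_last - L + 1L)) {
    lo <- max(pos - h, ref_first)
    hi <- min(pos + h + L - 1L, ref_last)
    ca <- col_of_pos[lo - ref_first + 1L]
    cb <- col_of_pos[hi - ref_first + 1L]
    piece <- mm_ch[ca:cb]
    sp <- paste(piece[piece != "-"], collapse = "")
    expected <- if (nchar(sp) >= L) {
      max(track_best(scan_pwm(sp, pwm)))
    } else -Inf
    expect_equal(unname(smx[pos + 1L, "mm"]), expected, tolerance = 1e-9)
  }
  # uncovered positions stay -Inf
  expect_true(all(!is.finite(smx[1:4, ])))
  expect_true(all(!is.finite(smx[16:30, ])))
})

test_that("percentile cutoffs interpolate linearly", {
  expect_equal(percentile_cutoff(1:100, 95), 95.05)
  expect_equal(percentile_cutoff(rep(3.5, 10), 80), 3.5)
  expect_equal(percentile_cutoff(c(1, 2, 3), 50), 2)
  expect_error(percentile_cutoff(numeric(0), 95), "length")
})

test_that("leaf probabilities follow the tie and absence conventions", {
  sb <- c(hs = 10, mm = 7, rn = 5, cf = NA)
  p <- leaf_probabilities(sb, threshold = 5, model = "binary",
                          ref_species = "hs")
  expect_equal(unname(p), c(1, 1, 1, 0))  # score == threshold counts
  p2 <- leaf_probabilities(c(hs = 1, mm = -Inf), threshold = 5,
                           model = "binary", ref_species = "hs")
  expect_equal(unname(p2), c(1, 0))  # reference forced present
  ref_scores <- 1:100
  p3 <- leaf_probabilities(c(hs = 2, mm = 90, rn = 10), threshold = 50,
                           model = "gated", ref_species = "hs",
                           ref_scores = ref_scores)
  expect_equal(unname(p3["mm"]), 0.9)
  expect_equal(unname(p3["rn"]), 0)    # below the gate
  expect_equal(unname(p3["hs"]), 1)
  p4 <- leaf_probabilities(c(hs = 2, mm = 90, rn = 10), threshold = 50,
                           model = "soft", ref_species = "hs",
                           ref_scores = ref_scores)
  expect_equal(unname(p4["rn"]), 0.1)  # soft model is ungated
})

test_that("bbls reproduces closed-form two-leaf cases", {
  tr <- read_newick("(a:0.1,b:0.2);")
  expect_equal(bbls(tr, c(a = 1, b = 1)), 0.3)
  expect_equal(bbls(tr, c(a = 1, b = 0.5)), 0.15)
  expect_equal(bbls(tr, c(a = 1, b = 0)), 0)
  tr3 <- read_newick("((h:0.1,m:0.2):0.05,r:0.3);")
  expect_equal(bbls(tr3, c(h = 1, m = 0, r = 0)), 0)  # no spanning subtree
  expect_equal(bbls(tr3, c(h = 1, m = 1, r = 1)), 0.65)
  expect_error(bbls(tr3, c(h = 1, m = 1)), "missing")
})

test_that("bbls equals exhaustive expected-BLS enumeration on random trees", {
  set.seed(123)
  for (rep in 1:25) {
    n <- sample(3:9, 1)
    tree <- ape::rtree(n, br = function(k) stats::runif(k, 0, 1))
    p <- stats::setNames(stats::runif(n), tree$tip.label)
    expect_equal(bbls(tree, p), oracle_bbls_enum(tree, p),
                 tolerance = 1e-9)
  }
})

test_that("bbls is monotone in leaf probabilities and branch lengths", {
  set.seed(31)
  tree <- ape::rtree(6, br = function(k) stats::runif(k, 0, 1))
  p <- stats::setNames(stats::runif(6), tree$tip.label)
  base <- bbls(tree, p)
  for (tip in tree$tip.label) {
    p2 <- p; p2[tip] <- min(1, p2[tip] + 0.2)
    expect_gte(bbls(tree, p2), base - 1e-12)
  }
  tree2 <- tree; tree2$edge.length <- tree$edge.length * 2
  expect_gte(bbls(tree2, p), base - 1e-12)
  # all p in {0,1}: plain BLS of the present set
  pb <- stats::setNames(c(1, 1, 0, 0, 1, 0), tree$tip.label)
  expect_equal(bbls(tree, pb), oracle_bbls_enum(tree, pb), tolerance = 1e-12)
})

test_that("bbls_track is zero without other species and structure-only", {
  pwm <- build_pwm(count_matrix(matrix(c(9, 1, 1, 1, 1, 9, 1, 1), nrow = 4)))
  seq <- "ACACACAC"
  ref <- scan_pwm(seq, pwm)
  tr1 <- read_newick("(hs:1);")
  out <- bbls_track(ref, list(), tr1, function(s) scan_pwm(s, pwm),
                    threshold = 0, ref_species = "hs",
                    cfg = bbls_config(model = "binary"))
  expect_equal(out$fwd, rep(0, length(ref$fwd)))
  # missing species in the alignment is an error naming them
  tr2 <- read_newick("((hs:1,mm:1):1,zz:2);")
  b <- block_from_texts(c(hs = seq, mm = seq))
  expect_error(
    bbls_track(ref, list(b), tr2, function(s) scan_pwm(s, pwm),
               threshold = 0, ref_species = "hs",
               cfg = bbls_config(model = "binary")),
    "zz")
})

test_that("calibrate_cutoff maximises mean ROC with documented ties", {
  fake <- list(
    "50" = list(auc = 0.6, roc50 = 0.1), "75" = list(auc = 0.8, roc50 = 0.1),
    "90" = list(auc = 0.8, roc50 = 0.3), "95" = list(auc = 0.8, roc50 = 0.3),
    "99" = list(auc = 0.7, roc50 = 0.9))
  evaluator <- function(bench, percentile) fake[[as.character(percentile)]]
  res <- calibrate_cutoff(list("b1"), evaluator)
  # 75/90/95 tie on ROC; 90/95 tie on ROC-50; higher percentile wins
  expect_equal(res$best, 95)
  expect_equal(nrow(res$table), 5)
  res1 <- calibrate_cutoff(list("b1"), evaluator, grid = 75)
  expect_equal(res1$best, 75)
})
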