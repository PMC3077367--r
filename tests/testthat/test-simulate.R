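# The phylogeny-aware simulator: determinism, ground truth, purifying
# selection, height model, and fixture round-trips.

small_cfg <- function(seed = 1L, ...) {
  defaults <- list(ref_length = 30000L, n_sites = 10L, n_decoys = 5L,
                   seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

test_that("the same seed yields a byte-identical bundle", {
  b1 <- simulate_bundle(small_cfg(4L))
  b2 <- simulate_bundle(small_cfg(4L))
  expect_identical(b1$seqs, b2$seqs)
  expect_identical(b1$truth, b2$truth)
  expect_identical(b1$peaks, b2$peaks)
  b3 <- simulate_bundle(small_cfg(5L))
  expect_false(identical(b1$seqs, b3$seqs))
})

test_that("planted k-mers sit at their recorded positions and strands", {
  b <- simulate_bundle(small_cfg(7L))
  ref <- b$seqs[[b$ref_species]]
  for (i in seq_len(nrow(b$truth))) {
    t <- b$truth[i, ]
    found <- substr(ref, t$start + 1, t$end)
    expected <- if (t$strand == "+") t$kmer else tfbsbench:::revcomp(t$kmer)
    expect_equal(found, expected)
  }
  # every peak contains its site
  expect_true(all(b$peaks$start <= b$truth$start &
                    b$peaks$end >= b$truth$end))
})

test_that("zero substitution rate copies the reference to every leaf", {
  b <- simulate_bundle(small_cfg(2L, subst_rate = 0))
  for (s in names(b$seqs)) expect_identical(b$seqs[[s]], b$seqs[[b$ref_species]])
  # and the conservation stand-in is maximal everywhere
  expect_true(all(b$phylop == 1))
})

test_that("full conservation freezes planted sites across all species", {
  b <- simulate_bundle(small_cfg(3L, site_conservation = 1))
  for (i in seq_len(nrow(b$truth))) {
    t <- b$truth[i, ]
    planted <- substr(b$seqs[[b$ref_species]], t$start + 1, t$end)
    for (s in names(b$seqs)) {
      expect_identical(substr(b$seqs[[s]], t$start + 1, t$end), planted)
    }
  }
})

test_that("background divergence grows with branch length", {
  cfg <- small_cfg(11L)
  b <- simulate_bundle(cfg)
  ref <- strsplit(b$seqs[[b$ref_species]], "")[[1]]
  dist_to_ref <- vapply(setdiff(names(b$seqs), b$ref_species), function(s) {
    mean(strsplit(b$seqs[[s]], "")[[1]] != ref)
  }, 0)
  # md (0.55 + 0.10 + 0.07 + 0.12 from hs) is the farthest leaf
  expect_equal(names(which.max(dist_to_ref)), "md")
  expect_true(all(dist_to_ref > 0.05 & dist_to_ref < 0.75))
})

test_that("peak heights regress on site scores with the configured slope", {
  cfg <- sim_config(seed = 21L)  # full default size for a stable fit
  b <- simulate_bundle(cfg)
  fit <- summary(stats::lm(height ~ score, data = b$truth))$coefficients
  slope <- fit["score", 1]; se <- fit["score", 2]
  expect_lt(abs(slope - cfg$peak_height$slope), 2 * se)
})

test_that("conservation_range couples per-site conservation to height", {
  b <- simulate_bundle(small_cfg(13L, conservation_range = c(0.2, 0.95)))
  expect_equal(cor(rank(b$truth$height), rank(b$truth$conservation)), 1)
  expect_equal(min(b$truth$conservation), 0.2)
  expect_equal(max(b$truth$conservation), 0.95)
})

test_that("decoy mask intervals avoid all peaks", {
  b <- simulate_bundle(small_cfg(17L))
  expect_equal(nrow(b$mask), 5)
  for (i in seq_len(nrow(b$mask))) {
    expect_false(any(b$mask$start[i] < b$peaks$end &
                       b$mask$end[i] > b$peaks$start))
  }
})

test_that("deletion indels never hit planted sites and stay consistent", {
  b <- simulate_bundle(small_cfg(19L, indel_rate = 2e-4))
  rec <- b$blocks[[1]]$records
  expect_true(any(grepl("-", rec$text, fixed = TRUE)))
  # gap-free text matches the emitted sequences
  for (i in seq_len(nrow(rec))) {
    expect_identical(gsub("-", "", rec$text[i], fixed = TRUE),
                     unname(b$seqs[rec$species[i]]))
  }
  # site columns have no gaps in any species
  for (i in seq_len(nrow(b$truth))) {
    cols <- (b$truth$start[i] + 1):b$truth$end[i]
    for (j in seq_len(nrow(rec))) {
      expect_false(any(strsplit(rec$text[j], "")[[1]][cols] == "-"))
    }
  }
})

test_that("bundles round-trip through the format writers", {
  b <- simulate_bundle(small_cfg(23L))
  dir <- file.path(tempdir(), "simfix")
  write_sim_bundle(b, dir)
  expect_identical(read_fasta(file.path(dir, "genome.fa")), b$seqs)
  blocks <- read_maf(file.path(dir, "alignment.maf"))
  expect_equal(blocks[[1]]$records$text, b$blocks[[1]]$records$text)
  peaks <- read_bed(file.path(dir, "peaks.bed"))
  expect_equal(peaks$start, b$peaks$start)
  expect_equal(peaks$height, b$peaks$height)
  tree <- read_newick(file.path(dir, "tree.nwk"))
  expect_setequal(tree$tip.label, b$tree$tip.label)
  wig <- read_fixedstep_wig(file.path(dir, "phylop.wig"))
  expect_equal(wig$value, b$phylop, tolerance = 1e-6)
})

test_that("make_benchmark_fixture ties truth to regions", {
  fx <- make_benchmark_fixture(small_cfg(29L), region_length = 2000)
  ds <- fx$dataset
  expect_s3_class(ds, "benchmark_dataset")
  expect_equal(nrow(ds$peaks), 10)
  expect_lte(nrow(ds$regions), 10)
  # zero decoys: benchmark never sees a mask
  fx0 <- make_benchmark_fixture(small_cfg(29L, n_decoys = 0L))
  expect_null(fx0$bundle$mask)
  # promoter flavour produces promoter/intron regions
  fxp <- make_benchmark_fixture(small_cfg(31L), type = "promoter")
  expect_true(all(fxp$dataset$regions$kind %in% c("promoter", "intron")))
  expect_gt(nrow(fxp$dataset$peaks), 0)
})
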