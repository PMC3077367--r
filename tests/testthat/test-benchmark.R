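# Benchmark construction: region placement, sum-length merging, negative
# chunking, promoter/intron regions, and the dataset-level conservation
# laws.

test_that("site regions are 20 kb by default, contain their peak, and are
           deterministic under a seed", {
  peaks <- data.frame(chrom = "chrT", start = 50000, end = 50200,
                      name = "p1", height = 10, stringsAsFactors = FALSE)
  sizes <- c(chrT = 2e6)
  r1 <- place_site_regions(peaks, sizes, site_benchmark_config(seed = 42))
  expect_equal(r1$end - r1$start, 20000)
  expect_lte(r1$start, 50000)
  expect_gte(r1$end, 50200)
  r2 <- place_site_regions(peaks, sizes, site_benchmark_config(seed = 42))
  expect_equal(r1, r2)
  r3 <- place_site_regions(peaks, sizes, site_benchmark_config(seed = 43))
  # different seed moves the window (with overwhelming probability)
  expect_false(isTRUE(all.equal(r1$start, r3$start)))
})

test_that("regions at chromosome edges shift inward, length preserved", {
  peaks <- data.frame(chrom = "chrT", start = c(10, 99800),
                      end = c(200, 99990), name = c("p1", "p2"),
                      height = c(1, 1), stringsAsFactors = FALSE)
  r <- place_site_regions(peaks, c(chrT = 1e5),
                          site_benchmark_config(seed = 1))
  expect_equal(r$end - r$start, c(20000, 20000))
  expect_gte(min(r$start), 0)
  expect_lte(max(r$end), 1e5)
  expect_true(all(r$start <= peaks$start & r$end >= peaks$end))
})

test_that("peaks longer than the region length are rejected by name", {
  peaks <- data.frame(chrom = "chrT", start = 0, end = 30000, name = "big",
                      height = 1, stringsAsFactors = FALSE)
  expect_error(place_site_regions(peaks, c(chrT = 1e6)), "chrT:0-30000")
})

test_that("merging conserves total length and collects peaks", {
  regions <- data.frame(
    region_id = c("a", "b", "c"), chrom = "chrT",
    start = c(100, 1500, 10000), end = c(2100, 3500, 12000),
    peak_idx = c(1L, 2L, 3L), stringsAsFactors = FALSE)
  merged <- merge_overlapping(regions)
  expect_equal(nrow(merged), 2)
  expect_equal(sum(merged$end - merged$start),
               sum(regions$end - regions$start))
  expect_setequal(merged$peak_idx[[1]], c(1L, 2L))
  # disjoint input is untouched
  expect_equal(merged$end[2] - merged$start[2], 2000)
  # two overlapping 20 kb regions give one 40 kb region
  r2 <- data.frame(region_id = c("a", "b"), chrom = "chrT",
                   start = c(0, 10000), end = c(20000, 30000),
                   peak_idx = c(1L, 2L), stringsAsFactors = FALSE)
  m2 <- merge_overlapping(r2)
  expect_equal(m2$end - m2$start, 40000)
})

test_that("chunking follows the 200 bp rule with documented remainders", {
  region <- data.frame(chrom = "chrT", start = 0, end = 1000)
  no_peaks <- data.frame(start = numeric(0), end = numeric(0))
  ch <- chunk_negatives(region, no_peaks, chunk_length = 200)
  expect_equal(nrow(ch), 5)
  expect_true(all(ch$end - ch$start == 200))
  # 450 bp gap: 200 + 250 (50 bp remainder merges into the last chunk)
  r450 <- data.frame(chrom = "chrT", start = 0, end = 450)
  ch450 <- chunk_negatives(r450, no_peaks, chunk_length = 200)
  expect_equal(ch450$end - ch450$start, c(200, 250))
  # 500 bp gap: 200 + 200 + 100 (remainder >= c/2 stands alone)
  ch500 <- chunk_negatives(data.frame(chrom = "chrT", start = 0, end = 500),
                           no_peaks, chunk_length = 200)
  expect_equal(ch500$end - ch500$start, c(200, 200, 100))
  # fully masked gap: no chunks
  mask <- data.frame(chrom = "chrT", start = 0, end = 1000)
  expect_equal(nrow(chunk_negatives(region, no_peaks, mask, 200)), 0)
  # gap shorter than c stands alone
  tiny <- chunk_negatives(data.frame(chrom = "chrT", start = 0, end = 70),
                          no_peaks, chunk_length = 200)
  expect_equal(tiny$end - tiny$start, 70)
})

test_that("benchmark conservation laws hold on random peak sets", {
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(5:25, 1)
    chrom_len <- 300000
    peaks <- random_peaks(n, chrom_len)
    mask <- random_peaks(5, chrom_len)
    cfg <- site_benchmark_config(2000, 200, seed = rep)
    placed <- place_site_regions(peaks, c(chrT = chrom_len), cfg)
    merged <- merge_overlapping(placed, c(chrT = chrom_len))
    # total length conserved by merging
    expect_equal(sum(merged$end - merged$start),
                 sum(placed$end - placed$start))
    ds <- build_site_benchmark(peaks, c(chrT = chrom_len), mask, cfg)
    # every peak lands in a region that contains it
    expect_equal(nrow(ds$peaks), n)
    for (i in seq_len(nrow(ds$peaks))) {
      r <- ds$regions[ds$regions$region_id == ds$peaks$region_id[i], ]
      expect_lte(r$start, ds$peaks$start[i])
      expect_gte(r$end, ds$peaks$end[i])
    }
    # no negative overlaps any peak or mask interval
    blocked <- rbind(peaks[, c("start", "end")], mask[, c("start", "end")])
    for (j in seq_len(nrow(ds$negatives))) {
      expect_false(any(ds$negatives$start[j] < blocked$end &
                         ds$negatives$end[j] > blocked$start))
    }
    # chunks are 200 bp except documented remainders (100..299)
    lens <- ds$negatives$end - ds$negatives$start
    expect_true(all(lens == 200 | (lens > 0 & lens < 300)))
    # positive/total bp ratio invariant under merging = over whole dataset
    expect_equal(sum(ds$regions$end - ds$regions$start),
                 nrow(peaks) * 2000)
  }
})

test_that("promoter regions follow strand and the intron cap", {
  genes <- data.frame(
    gene_id = c("g1", "g2", "g3"), chrom = "chrT",
    strand = c("+", "-", "+"), tss = c(10000, 50000, 90000),
    intron_start = c(12000, NA, 91000),
    intron_end = c(17000, NA, 91800), stringsAsFactors = FALSE)
  peaks <- data.frame(chrom = "chrT", start = 8100, end = 8400,
                      name = "p1", height = 20, stringsAsFactors = FALSE)
  ds <- build_promoter_benchmark(genes, peaks, c(chrT = 2e5))
  prom <- ds$regions[ds$regions$kind == "promoter", ]
  expect_equal(prom$start[prom$region_id == ds$regions$region_id[1]], 8000)
  expect_equal(prom$end[1] - prom$start[1], 2200)
  # minus strand mirrors the window
  g2 <- ds$regions[ds$regions$start == 49800, ]
  expect_equal(g2$end, 52000)
  # 5000 bp intron capped at 3000; 800 bp intron kept whole
  introns <- ds$regions[ds$regions$kind == "intron", ]
  expect_setequal(introns$end - introns$start, c(3000, 800))
  # the peak is fully inside g1's promoter and labels it positive
  expect_equal(nrow(ds$peaks), 1)
  # negatives are undivided flanks, not 200 bp chunks
  g1neg <- ds$negatives[ds$negatives$region_id == ds$peaks$region_id[1], ]
  expect_equal(nrow(g1neg), 2)
  expect_equal(sort(g1neg$end - g1neg$start), sort(c(8100 - 8000,
                                                     10200 - 8400)))
})

test_that("overlapping promoter/intron regions keep only the first", {
  genes <- data.frame(
    gene_id = c("g1", "g2"), chrom = "chrT", strand = "+",
    tss = c(10000, 10500), intron_start = NA, intron_end = NA,
    stringsAsFactors = FALSE)
  no_peaks <- data.frame(chrom = character(0), start = numeric(0),
                         end = numeric(0), name = character(0),
                         height = numeric(0), stringsAsFactors = FALSE)
  ds <- build_promoter_benchmark(genes, no_peaks, c(chrT = 1e5))
  expect_equal(nrow(ds$regions), 1)
  expect_equal(ds$regions$start, 8000)
})

test_that("a partially overlapping peak extends its test region", {
  genes <- data.frame(gene_id = "g1", chrom = "chrT", strand = "+",
                      tss = 10000, intron_start = NA, intron_end = NA,
                      stringsAsFactors = FALSE)
  peaks <- data.frame(chrom = "chrT", start = 10100, end = 10500,
                      name = "p1", height = 5, stringsAsFactors = FALSE)
  ds <- build_promoter_benchmark(genes, peaks, c(chrT = 1e5))
  expect_equal(ds$regions$end, 10500)  # extended beyond tss + 200
})
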