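# Phylogeny-aware synthetic data: a background reference sequence with
# planted motif instances, evolved to the leaves of a tree under
# Jukes-Cantor substitution with per-site purifying selection, plus peaks
# with strength-linked heights, decoy peaks, and a conservation track.
# The bundle round-trips through the package's own BED/MAF/FASTA/newick/
# WIG writers, so every other module can be exercised end to end.

#' Simulation configuration
#'
#' The generator emulates the statistical structure the benchmark assumes:
#' real motif instances sit in ChIP-seq peaks, stronger instances give
#' taller peaks, and functional instances are held fixed across species by
#' purifying selection while the background drifts.
#'
#' @param tree newick string or \code{ape::phylo}; default a five-species
#'   mammal-like tree (total branch length 1.57 substitutions/site).
#' @param ref_species reference leaf id (default \code{"hs"}).
#' @param ref_length reference sequence length in bp (default 150000).
#' @param background named base frequencies (default A/T 0.30, C/G 0.20).
#' @param motif a [count_matrix()] (sites are sampled per column from its
#'   distribution) or a [kmer_set()] (sites sampled uniformly from it).
#' @param n_sites number of planted sites (default 60).
#' @param site_conservation probability, per branch, that a planted site is
#'   held fixed (default 0.9). 1 freezes sites completely, 0 lets them
#'   drift like background.
#' @param conservation_range optional c(lo, hi): per-site conservation is
#'   instead mapped from the site's peak-height rank, coupling conservation
#'   to binding strength (taller peaks more conserved).
#' @param subst_rate background substitutions per site per unit branch
#'   length (default 1).
#' @param indel_rate expected deletions per bp per non-reference species
#'   (default 0 = gapless alignments); deletions never hit planted sites,
#'   so the ground truth stays exact.
#' @param peak_height list(base, slope, sd): height = base + slope x (site
#'   log-odds score) + Gaussian noise, truncated at 0 (default 30, 4, 10).
#' @param peak_length c(min, max) peak lengths in bp (default 100-400,
#'   the trimmed ChIP-seq peak range).
#' @param n_decoys number of decoy "lesser peak" mask intervals placed on
#'   background positions (default 25).
#' @param seed integer RNG seed.
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(tree = NULL, ref_species = "hs",
                       ref_length = 150000L,
                       background = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
                       motif = NULL, n_sites = 60L,
                       site_conservation = 0.9, conservation_range = NULL,
                       subst_rate = 1, indel_rate = 0,
                       peak_height = list(base = 30, slope = 4, sd = 10),
                       peak_length = c(100L, 400L), n_decoys = 25L,
                       seed = 1L) {
  if (is.null(tree)) {
    tree <- "(((hs:0.12,(mm:0.09,rn:0.10):0.24):0.07,cf:0.30):0.10,md:0.55);"
  }
  if (is.character(tree)) tree <- read_newick(tree)
  stopifnot(ref_species %in% tree$tip.label)
  if (is.null(motif)) motif <- sim_motif(10L, 0.9, seed = 7L)
  stopifnot(inherits(motif, "count_matrix") || inherits(motif, "kmer_set"))
  stopifnot(n_sites >= 1L, site_conservation >= 0, site_conservation <= 1,
            subst_rate >= 0, indel_rate >= 0)
  background <- background[DNA_BASES]
  stopifnot(all(background > 0), abs(sum(background) - 1) < 1e-9)
  if (!is.null(conservation_range)) {
    stopifnot(length(conservation_range) == 2L,
              all(conservation_range >= 0), all(conservation_range <= 1),
              conservation_range[1] <= conservation_range[2])
  }
  structure(list(tree = tree, ref_species = ref_species,
                 ref_length = as.integer(ref_length),
                 background = background, motif = motif,
                 n_sites = as.integer(n_sites),
                 site_conservation = site_conservation,
                 conservation_range = conservation_range,
                 subst_rate = subst_rate, indel_rate = indel_rate,
                 peak_height = peak_height,
                 peak_length = as.integer(peak_length),
                 n_decoys = as.integer(n_decoys), seed = seed),
            class = "sim_config")
}

#' Make a simple synthetic count matrix of given width and dominance
#'
#' Each column puts probability \code{dominance} on one randomly chosen
#' consensus base and spreads the rest uniformly; counts are scaled to
#' 100 observations. Useful for generating motifs of controlled
#' information content (dominance 0.7 gives ~0.64 bits/column, 0.95 gives
#' ~1.63 bits/column).
#'
#' @param width motif width in bp.
#' @param dominance consensus base probability per column, in (0.25, 1].
#' @param seed RNG seed for the consensus choice.
#' @return a [count_matrix()].
#' @export
sim_motif <- function(width, dominance, seed = 1L) {
  stopifnot(width >= 1, dominance > 0.25, dominance <= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  consensus <- sample.int(4L, width, replace = TRUE)
  counts <- matrix(100 * (1 - dominance) / 3, nrow = 4, ncol = width,
                   dimnames = list(DNA_BASES, NULL))
  counts[cbind(consensus, seq_len(width))] <- 100 * dominance
  count_matrix(counts, motif_id = sprintf("sim_w%d_d%02d", width,
                                          round(100 * dominance)))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# Sample one site k-mer from the motif model; returns list(kmer, code).
sample_site_kmer <- function(motif) {
  if (inherits(motif, "count_matrix")) {
    prob <- sweep(motif$counts, 2, colSums(motif$counts), "/")
    code <- vapply(seq_len(motif$length),
                   function(j) sample.int(4L, 1L, prob = prob[, j]), 0L)
  } else {
    km <- sample(rep(motif$kmers, motif$mult), 1L)
    code <- seq_to_code(km)
  }
  list(kmer = code_to_seq(code), code = code)
}

motif_width <- function(motif) {
  if (inherits(motif, "count_matrix")) motif$length else motif$k
}

#' Simulate a complete synthetic fixture bundle
#'
#' Samples a background reference sequence, plants non-overlapping motif
#' instances, evolves the sequence outward from the reference leaf along
#' the (unrooted) tree under Jukes-Cantor substitution -- planted-site
#' columns are frozen on a branch with the site's conservation
#' probability -- and emits the per-species sequences, a MAF alignment,
#' peaks with strength-linked heights, decoy mask intervals, a
#' phyloP-like per-column identity track (rescaled to [-1, 1]) and the
#' ground-truth site table.
#'
#' @param cfg a [sim_config()].
#' @return object of class \code{sim_bundle}: \code{config}, \code{tree},
#'   \code{ref_species}, \code{chrom}, \code{seqs} (named per-species
#'   gap-free sequences), \code{blocks} (list of [alignment_block()]),
#'   \code{peaks}, \code{mask}, \code{truth} (data.frames),
#'   \code{phylop} (numeric per-base vector).
#' @export
simulate_bundle <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  tree <- cfg$tree
  L <- motif_width(cfg$motif)
  N <- cfg$ref_length
  ref <- sample.int(4L, N, replace = TRUE, prob = cfg$background)

  # --- plant sites on a jittered grid so they never overlap -------------
  margin <- 600L
  usable <- N - 2L * margin
  slot <- usable / cfg$n_sites
  if (slot < max(cfg$peak_length) + L + 10) {
    stop("sites do not fit without overlap; increase ref_length or reduce n_sites")
  }
  site_start <- integer(cfg$n_sites)
  site_strand <- character(cfg$n_sites)
  site_kmer <- character(cfg$n_sites)
  pwm <- if (inherits(cfg$motif, "count_matrix")) {
    build_pwm(cfg$motif, bg = cfg$background, alpha = 1)
  } else NULL
  site_score <- numeric(cfg$n_sites)
  for (i in seq_len(cfg$n_sites)) {
    lo <- margin + floor((i - 1) * slot)
    jitter <- sample.int(max(floor(slot) - L - max(cfg$peak_length), 1L), 1L)
    site_start[i] <- lo + jitter
    sk <- sample_site_kmer(cfg$motif)
    site_kmer[i] <- sk$kmer
    site_strand[i] <- sample(c("+", "-"), 1L)
    planted <- if (site_strand[i] == "+") sk$code else
      rev(5L - sk$code)  # reverse complement in code space (A<->T, C<->G)
    ref[(site_start[i] + 1):(site_start[i] + L)] <- planted
    site_score[i] <- if (!is.null(pwm)) {
      sum(pwm$W[cbind(sk$code, seq_len(L))])
    } else L - mean_hamming_to_set(sk$kmer, cfg$motif)
  }

  # --- peaks around sites, heights linked to site strength --------------
  plen <- sample(seq(cfg$peak_length[1], cfg$peak_length[2]),
                 cfg$n_sites, replace = TRUE)
  peak_start <- pmax(site_start - vapply(plen, function(p)
    sample.int(p - L + 1L, 1L) - 1L, 0L), 0L)
  peak_end <- pmin(peak_start + plen, N)
  ph <- cfg$peak_height
  height <- pmax(ph$base + ph$slope * site_score +
                   stats::rnorm(cfg$n_sites, 0, ph$sd), 0)
  peaks <- data.frame(chrom = "sim1", start = peak_start, end = peak_end,
                      name = sprintf("peak%03d", seq_len(cfg$n_sites)),
                      height = round(height, 2), stringsAsFactors = FALSE)

  # --- per-site conservation, optionally coupled to peak height ---------
  if (!is.null(cfg$conservation_range)) {
    rk <- rank(peaks$height, ties.method = "first")
    cons <- cfg$conservation_range[1] +
      (cfg$conservation_range[2] - cfg$conservation_range[1]) *
      (rk - 1) / max(cfg$n_sites - 1, 1)
  } else {
    cons <- rep(cfg$site_conservation, cfg$n_sites)
  }

  # --- evolve outward from the reference leaf ---------------------------
  site_cols <- lapply(site_start, function(s) (s + 1):(s + L))
  seqs_code <- evolve_from_reference(tree, cfg$ref_species, ref,
                                     cfg$subst_rate, site_cols, cons)
  seqs <- vapply(seqs_code, code_to_seq, "")

  # --- alignment block (deletions only, never in planted sites) ---------
  texts <- seqs
  if (cfg$indel_rate > 0) {
    protected <- unlist(site_cols)
    for (s in setdiff(names(texts), cfg$ref_species)) {
      n_del <- stats::rpois(1, cfg$indel_rate * N)
      if (n_del == 0) next
      del_cols <- integer(0)
      for (d in seq_len(n_del)) {
        len <- sample.int(5L, 1L)
        at <- sample.int(N - len, 1L)
        cols <- at:(at + len - 1L)
        if (any(cols %in% protected)) next
        del_cols <- union(del_cols, cols)
      }
      ch <- strsplit(texts[[s]], "", fixed = TRUE)[[1]]
      ch[del_cols] <- "-"
      texts[[s]] <- paste(ch, collapse = "")
      seqs[[s]] <- gsub("-", "", texts[[s]], fixed = TRUE)
    }
  }
  species_order <- c(cfg$ref_species,
                     setdiff(tree$tip.label, cfg$ref_species))
  records <- data.frame(
    species = species_order, chrom = "sim1", start = 0,
    size = nchar(seqs[species_order]), strand = "+",
    src_size = nchar(seqs[species_order]), text = texts[species_order],
    stringsAsFactors = FALSE)
  block <- alignment_block(records)

  # --- decoy mask intervals on background positions ---------------------
  mask <- NULL
  if (cfg$n_decoys > 0) {
    rows <- list()
    tries <- 0L
    while (length(rows) < cfg$n_decoys && tries < 50L * cfg$n_decoys) {
      tries <- tries + 1L
      dl <- sample(seq(cfg$peak_length[1], cfg$peak_length[2]), 1L)
      ds <- sample.int(N - dl, 1L)
      if (any(ds < peaks$end & ds + dl > peaks$start)) next
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = "sim1", start = ds, end = ds + dl,
        name = sprintf("decoy%03d", length(rows) + 1L), height = 0,
        stringsAsFactors = FALSE)
    }
    mask <- do.call(rbind, rows)
  }

  # --- phyloP stand-in: per-column identity fraction, rescaled ----------
  others <- setdiff(species_order, cfg$ref_species)
  ident <- rep(0, N)
  for (s in others) {
    ident <- ident + (seqs_code[[s]] == seqs_code[[cfg$ref_species]])
  }
  phylop <- 2 * ident / length(others) - 1

  truth <- data.frame(
    site_id = sprintf("site%03d", seq_len(cfg$n_sites)), chrom = "sim1",
    start = site_start, end = site_start + L, strand = site_strand,
    kmer = site_kmer, score = site_score, conservation = cons,
    peak = peaks$name, height = peaks$height, stringsAsFactors = FALSE)

  structure(list(config = cfg, tree = tree, ref_species = cfg$ref_species,
                 chrom = "sim1", seqs = seqs, blocks = list(block),
                 peaks = peaks, mask = mask, truth = truth,
                 phylop = phylop),
            class = "sim_bundle")
}

# Hamming fallback score for kmer_set motifs: mean distance to the set.
mean_hamming_to_set <- function(kmer, kset) {
  a <- strsplit(kmer, "", fixed = TRUE)[[1]]
  d <- vapply(kset$kmers, function(m) {
    sum(a != strsplit(m, "", fixed = TRUE)[[1]])
  }, 0)
  stats::weighted.mean(d, kset$mult)
}

# Evolve integer-coded sequences outward from the reference leaf over the
# unrooted tree; Jukes-Cantor substitution, sites frozen per branch with
# their conservation probability.
evolve_from_reference <- function(tree, ref_species, ref_code, rate,
                                  site_cols, cons) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  adj <- vector("list", n_node)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
    l <- tree$edge.length[e]
    adj[[a]] <- c(adj[[a]], list(list(to = b, len = l)))
    adj[[b]] <- c(adj[[b]], list(list(to = a, len = l)))
  }
  start <- match(ref_species, tree$tip.label)
  seqs <- vector("list", n_node)
  seqs[[start]] <- ref_code
  visited <- logical(n_node)
  visited[start] <- TRUE
  queue <- list(start)
  while (length(queue) > 0) {
    u <- queue[[1]]; queue <- queue[-1]
    for (nb in adj[[u]]) {
      v <- nb$to
      if (visited[v]) next
      visited[v] <- TRUE
      seqs[[v]] <- mutate_branch(seqs[[u]], rate, nb$len, site_cols, cons)
      queue <- c(queue, list(v))
    }
  }
  out <- seqs[seq_len(n_tip)]
  names(out) <- tree$tip.label
  out
}

mutate_branch <- function(code, rate, len, site_cols, cons) {
  n <- length(code)
  p_sub <- 0.75 * (1 - exp(-4 / 3 * rate * len))
  hit <- stats::runif(n) < p_sub
  # purifying selection: freeze each site on this branch with prob cons[i]
  for (i in seq_along(site_cols)) {
    if (stats::runif(1) < cons[i]) hit[site_cols[[i]]] <- FALSE
  }
  idx <- which(hit)
  if (length(idx) > 0) {
    shift <- sample.int(3L, length(idx), replace = TRUE)
    code[idx] <- ((code[idx] - 1L + shift) %% 4L) + 1L
  }
  code
}

#' Write a simulation bundle to a fixture directory
#'
#' Emits genome.fa (all species), reference.fa (the reference sequence
#' under its chromosome name, ready for `scan`), alignment.maf, tree.nwk,
#' peaks.bed, mask.bed, truth.tsv and phylop.wig using the package's own
#' writers.
#'
#' @param bundle a [simulate_bundle()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_sim_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(bundle$seqs, file.path(dir, "genome.fa"))
  ref <- stats::setNames(bundle$seqs[bundle$ref_species], bundle$chrom)
  write_fasta(ref, file.path(dir, "reference.fa"))
  write_maf(bundle$blocks, file.path(dir, "alignment.maf"))
  write_newick(bundle$tree, file.path(dir, "tree.nwk"))
  write_bed(bundle$peaks, file.path(dir, "peaks.bed"))
  if (!is.null(bundle$mask)) write_bed(bundle$mask, file.path(dir, "mask.bed"))
  utils::write.table(bundle$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_fixedstep_wig(
    data.frame(chrom = bundle$chrom,
               pos = seq_along(bundle$phylop) - 1, value = bundle$phylop),
    file.path(dir, "phylop.wig"))
  invisible(dir)
}

#' Simulate and build a benchmark in one step
#'
#' Runs [simulate_bundle()] and then the benchmark builder on the emitted
#' peaks, with a scaled-down region length so the full pipeline runs in
#' seconds.
#'
#' @param cfg a [sim_config()].
#' @param type \code{"site"} (default) or \code{"promoter"}.
#' @param region_length site test-region length (default 2000).
#' @param chunk_length negative chunk length (default 200).
#' @return list with \code{bundle} (the [simulate_bundle()] output) and
#'   \code{dataset} (a [benchmark_dataset()]).
#' @export
make_benchmark_fixture <- function(cfg, type = c("site", "promoter"),
                                   region_length = 2000L,
                                   chunk_length = 200L) {
  type <- match.arg(type)
  bundle <- simulate_bundle(cfg)
  sizes <- stats::setNames(cfg$ref_length, bundle$chrom)
  if (type == "site") {
    dataset <- build_site_benchmark(
      bundle$peaks, sizes, bundle$mask,
      site_benchmark_config(region_length, chunk_length, seed = NULL),
      dataset_id = "sim_site")
  } else {
    genes <- synth_genes_for_peaks(bundle$peaks, cfg$ref_length)
    dataset <- build_promoter_benchmark(
      genes, bundle$peaks, sizes, bundle$mask,
      dataset_id = "sim_promoter")
  }
  list(bundle = bundle, dataset = dataset)
}

# Synthetic gene models whose promoters cover the given peaks.
synth_genes_for_peaks <- function(peaks, chrom_len) {
  n <- nrow(peaks)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  tss <- integer(n)
  for (i in seq_len(n)) {
    if (strand[i] == "+") {
      tss[i] <- min(peaks$end[i] + sample.int(1200L, 1L), chrom_len - 1L)
    } else {
      tss[i] <- max(peaks$start[i] - sample.int(1200L, 1L), 0L)
    }
  }
  intron_off <- sample(300:800, n, replace = TRUE)
  intron_len <- sample(1000:5000, n, replace = TRUE)
  is_ <- ifelse(strand == "+", tss + intron_off,
                pmax(tss - intron_off - intron_len, 0))
  ie <- ifelse(strand == "+", pmin(tss + intron_off + intron_len, chrom_len),
               pmax(tss - intron_off, 0))
  data.frame(gene_id = sprintf("gene%03d", seq_len(n)),
             chrom = peaks$chrom, strand = strand, tss = tss,
             intron_start = is_, intron_end = ie, stringsAsFactors = FALSE)
}
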