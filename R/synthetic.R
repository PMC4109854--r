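#' Configuration for the synthetic regulatory dataset generator
#'
#' Defines a simulated study: a gene universe on one chromosome, one
#' upstream regulatory region per gene, orthologous sequences in
#' `n_species` species derived by per-base substitution, one planted
#' ("true") motif whose homotypic site clusters are inserted into the
#' regions of the target genes, decoy motifs, a ChIP-like peak track
#' over the planted regions, and input gene sets at graded noise
#' levels.
#'
#' Defaults emulate a planted-signal recovery study: 1000 genes, 3
#' species, 20 target genes with on average 3 sites each
#' (Poisson(2)+1), a 12-position motif of 1.3 bits per column, 49
#' decoys, 30% per-base background divergence vs 5% within planted
#' sites, 500 bp regions at GC 0.5.
#'
#' @param seed master seed; the dataset is fully deterministic given it.
#' @param G universe size.
#' @param n_species number of species (first species is the base).
#' @param n_decoy_pwms number of decoy motifs (half column-shuffled
#'   copies of the true motif, half Dirichlet-random).
#' @param true_pwm_length motif length in bp.
#' @param true_pwm_ic target information content per column (bits).
#' @param n_target_genes number of genes receiving planted clusters.
#' @param sites_per_region_lambda Poisson mean; each target region gets
#'   Poisson(lambda) + 1 sites.
#' @param conservation_background per-base substitution rate for
#'   non-site sequence in non-base species.
#' @param conservation_site per-base substitution rate within planted
#'   sites (must not exceed the background rate).
#' @param gc_content background GC fraction.
#' @param region_length length of each gene's regulatory region (bp).
#' @param peak_noise expected background peaks per gene (Poisson).
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1, G = 1000, n_species = 3,
                              n_decoy_pwms = 49, true_pwm_length = 12,
                              true_pwm_ic = 1.3, n_target_genes = 20,
                              sites_per_region_lambda = 2,
                              conservation_background = 0.3,
                              conservation_site = 0.05,
                              gc_content = 0.5, region_length = 500,
                              peak_noise = 0.05) {
  stopifnot(G >= 10, n_species >= 1, n_decoy_pwms >= 0,
            true_pwm_length >= 4, n_target_genes >= 1,
            n_target_genes <= G, sites_per_region_lambda >= 0,
            gc_content > 0, gc_content < 1, region_length >= 50,
            peak_noise >= 0)
  if (conservation_site > conservation_background)
    stop("site substitution rate must not exceed the background rate")
  if (any(c(conservation_background, conservation_site) < 0) ||
      any(c(conservation_background, conservation_site) > 1))
    stop("substitution rates must lie in [0, 1]")
  structure(as.list(environment()), class = "simulation_config")
}

# Dominant-base probability achieving a per-column information content
# (column shape p, q, q, q with q = (1-p)/3, uniform background).
dominance_for_ic <- function(ic) {
  stopifnot(ic > 0, ic < 2)
  f <- function(p) {
    q <- (1 - p) / 3
    2 + p * log2(p) + 3 * q * log2(q) - ic
  }
  stats::uniroot(f, c(0.2500001, 0.9999999))$root
}

draw_background <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

mutate_bases <- function(chars, rate) {
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    alt <- setdiff(c("A", "C", "G", "T"), chars[i])
    chars[i] <- alt[sample.int(3L, 1L)]
  }
  chars
}

revcomp_chr <- function(x) chartr("ACGT", "TGCA",
                                  paste(rev(strsplit(x, "")[[1]]),
                                        collapse = ""))

#' Simulate a complete synthetic dataset
#'
#' See [simulation_config()] for the model. Byte-identical output for
#' identical configurations (including the seed).
#'
#' @param config a [simulation_config].
#' @return list of class `synthetic_dataset` with elements
#'   `annotation` (gene annotation table; regions correspond to mode
#'   "up500" when `region_length` is 500), `regions` (search-space
#'   table), `sequences` (per species, a named character vector keyed
#'   `gene|region|species`), `pwms` (true motif first, then decoys),
#'   `true_motif_id`, `truth` (planted-site table with region-relative
#'   and genomic coordinates), `peaks` (BED-like peak table with
#'   signalValue), `target_genes`, `gene_sets` (noise fractions 0,
#'   0.25, 0.5, 0.75, 1), and the `config`.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  cf <- config
  local_seed(cf$seed, {
    universe <- sprintf("g%04d", seq_len(cf$G))
    L <- cf$region_length
    w <- cf$true_pwm_length
    spacing <- L + 1000L
    tss <- seq_len(cf$G) * spacing
    annotation <- gene_annotation(
      gene_id = universe, chrom = "chr1", strand = "+",
      tx_start = tss, tx_end = tss + 200L, tss = as.character(tss),
      cds_exons = sprintf("%d-%d", tss + 50L, tss + 150L))
    regions <- data.frame(gene_id = universe, chrom = "chr1",
                          start = tss - L, end = tss, region = 1L,
                          stringsAsFactors = FALSE)

    # true motif: one dominant base per position at the IC-matched
    # probability, scaled to counts of 100
    pdom <- dominance_for_ic(cf$true_pwm_ic)
    dom <- sample.int(4L, w, replace = TRUE)
    counts <- matrix((1 - pdom) / 3 * 100, w, 4)
    counts[cbind(seq_len(w), dom)] <- pdom * 100
    true_pwm <- pwm("planted_motif", counts, "synthetic")
    site_prob <- pwm_prob(true_pwm)

    n_shuf <- floor(cf$n_decoy_pwms / 2)
    decoys <- list()
    if (n_shuf > 0) for (i in seq_len(n_shuf)) {
      decoys[[sprintf("decoy_shuffle_%02d", i)]] <-
        pwm(sprintf("decoy_shuffle_%02d", i),
            counts[sample.int(w), , drop = FALSE], "synthetic")
    }
    if (cf$n_decoy_pwms - n_shuf > 0)
      for (i in seq_len(cf$n_decoy_pwms - n_shuf)) {
        cm <- matrix(stats::rgamma(4 * w, shape = 1), w, 4)
        cm <- cm / rowSums(cm) * 100
        decoys[[sprintf("decoy_random_%02d", i)]] <-
          pwm(sprintf("decoy_random_%02d", i), cm, "synthetic")
      }
    pwms <- c(stats::setNames(list(true_pwm), true_pwm$motif_id), decoys)

    target_genes <- sort(sample(universe, cf$n_target_genes))
    base_seqs <- vapply(universe, function(g) draw_background(L, cf$gc_content),
                        character(1))

    truth_rows <- list()
    for (g in target_genes) {
      n_sites <- stats::rpois(1L, cf$sites_per_region_lambda) + 1L
      block <- floor(L / n_sites)
      if (block < w)
        stop("region_length too short for ", n_sites, " planted sites")
      starts <- (seq_len(n_sites) - 1L) * block +
        vapply(seq_len(n_sites),
               function(i) sample.int(block - w + 1L, 1L) - 1L, integer(1))
      chars <- strsplit(base_seqs[[g]], "")[[1]]
      for (st in starts) {
        site <- paste(vapply(seq_len(w), function(j)
          c("A", "C", "G", "T")[sample.int(4L, 1L, prob = site_prob[j, ])],
          character(1)), collapse = "")
        strand <- sample(c("+", "-"), 1L)
        planted <- if (strand == "-") revcomp_chr(site) else site
        chars[(st + 1):(st + w)] <- strsplit(planted, "")[[1]]
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          gene_id = g, region = 1L, start = st,
          genomic_start = regions$start[match(g, universe)] + st,
          strand = strand, site_seq = planted, stringsAsFactors = FALSE)
      }
      base_seqs[[g]] <- paste(chars, collapse = "")
    }
    truth <- do.call(rbind, truth_rows)

    species <- sprintf("sp%d", seq_len(cf$n_species))
    site_mask <- lapply(universe, function(g) {
      m <- rep(FALSE, L)
      tr <- truth[truth$gene_id == g, , drop = FALSE]
      for (i in seq_len(nrow(tr)))
        m[(tr$start[i] + 1):(tr$start[i] + w)] <- TRUE
      m
    })
    names(site_mask) <- universe
    sequences <- list()
    sequences[[species[1]]] <- stats::setNames(
      base_seqs, sprintf("%s|1|%s", universe, species[1]))
    for (k in seq_len(cf$n_species)[-1]) {
      sp <- species[k]
      mut <- vapply(universe, function(g) {
        chars <- strsplit(base_seqs[[g]], "")[[1]]
        m <- site_mask[[g]]
        chars[m] <- mutate_bases(chars[m], cf$conservation_site)
        chars[!m] <- mutate_bases(chars[!m], cf$conservation_background)
        paste(chars, collapse = "")
      }, character(1))
      sequences[[sp]] <- stats::setNames(
        mut, sprintf("%s|1|%s", universe, sp))
    }

    peak_rows <- list()
    for (g in target_genes) {
      rs <- regions$start[match(g, universe)]
      peak_rows[[length(peak_rows) + 1L]] <- data.frame(
        chrom = "chr1", start = rs + floor(L / 4), end = rs + floor(3 * L / 4),
        name = paste0("peak_", g), score = 0L, strand = ".",
        signalValue = stats::runif(1, 50, 100), stringsAsFactors = FALSE)
    }
    n_bg <- stats::rpois(1L, cf$G * cf$peak_noise)
    if (n_bg > 0) for (i in seq_len(n_bg)) {
      g <- sample(universe, 1L)
      rs <- regions$start[match(g, universe)]
      st <- rs + sample.int(L - 50L, 1L) - 1L
      peak_rows[[length(peak_rows) + 1L]] <- data.frame(
        chrom = "chr1", start = st, end = st + 50L,
        name = sprintf("bgpeak_%03d", i), score = 0L, strand = ".",
        signalValue = stats::runif(1, 1, 30), stringsAsFactors = FALSE)
    }
    peaks <- do.call(rbind, peak_rows)

    noise_levels <- c(0, 0.25, 0.5, 0.75, 1)
    gene_sets <- stats::setNames(lapply(noise_levels, function(nf)
      mix_noise(target_genes, universe, nf, cf$n_target_genes,
                derive_seed(cf$seed, round(100 * nf) + 7L))),
      sprintf("noise_%03d", round(100 * noise_levels)))

    structure(list(annotation = annotation, regions = regions,
                   sequences = sequences, pwms = pwms,
                   true_motif_id = true_pwm$motif_id, truth = truth,
                   peaks = peaks, target_genes = target_genes,
                   gene_sets = gene_sets, config = cf),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(paste0("synthetic_dataset: %d genes, %d species, %d PWMs ",
                     "(1 planted), %d target gene(s), %d planted site(s)\n"),
              x$config$G, x$config$n_species, length(x$pwms),
              length(x$target_genes), nrow(x$truth)))
  invisible(x)
}

#' Mix true targets with noise genes into an input set
#'
#' Returns exactly `set_size` genes: `round(noise_fraction * set_size)`
#' non-targets drawn without replacement from the universe minus the
#' targets, the remainder drawn from the true targets (noise replaces
#' positives, keeping the set size fixed).
#'
#' @param true_targets character vector of positive gene ids.
#' @param universe character vector of all gene ids.
#' @param noise_fraction fraction of the set replaced by noise, in
#'   `[0, 1]`.
#' @param set_size number of genes to return.
#' @param seed integer seed.
#' @return character vector of `set_size` gene ids.
#' @export
mix_noise <- function(true_targets, universe, noise_fraction, set_size,
                      seed = 1) {
  if (noise_fraction < 0 || noise_fraction > 1)
    stop("noise_fraction must lie in [0, 1]")
  n_noise <- round(noise_fraction * set_size)
  n_true <- set_size - n_noise
  negatives <- setdiff(universe, true_targets)
  if (n_true > length(true_targets))
    stop("not enough true targets for set_size at this noise fraction")
  if (n_noise > length(negatives))
    stop("not enough negative genes for set_size at this noise fraction")
  local_seed(seed, {
    c(sample(true_targets, n_true), sample(negatives, n_noise))
  })
}

#' Write a synthetic dataset as a fixture directory
#'
#' Writes annotation.tsv, regions.bed, one FASTA per species
#' (`regions_<species>.fa`), pwms.cb, peaks.bed, truth.tsv,
#' gene_sets.gmt and config.json under `dir`.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(dir, ...)
  write_gene_annotation(dataset$annotation, fp("annotation.tsv"))
  write_regions_bed(dataset$regions, fp("regions.bed"))
  for (sp in names(dataset$sequences)) {
    ss <- Biostrings::DNAStringSet(dataset$sequences[[sp]])
    Biostrings::writeXStringSet(ss, fp(sprintf("regions_%s.fa", sp)))
  }
  write_pwms(dataset$pwms, fp("pwms.cb"))
  utils::write.table(dataset$peaks, fp("peaks.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(dataset$truth, fp("truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gmt(dataset$gene_sets, fp("gene_sets.gmt"))
  jsonlite::write_json(unclass(dataset$config), fp("config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
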