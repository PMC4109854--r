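#' Build a run manifest
#'
#' A manifest records everything needed to re-run a stage
#' bit-identically: package version, subcommand, parameters, md5 hashes
#' of the input files and the seed. Wall-clock timestamps are excluded
#' by default so that identical runs produce byte-identical manifests;
#' set `timestamp = TRUE` to include one.
#'
#' @param subcommand stage name.
#' @param parameters named list of parameters.
#' @param inputs character vector of input file paths (hashed).
#' @param seed integer seed used by the stage (or NULL).
#' @param timestamp include the current time (breaks byte-level
#'   reproducibility of the manifest itself).
#' @return named list (the manifest).
#' @export
run_manifest <- function(subcommand, parameters = list(),
                         inputs = character(), seed = NULL,
                         timestamp = FALSE) {
  ex <- file.exists(inputs)
  hashes <- rep(NA_character_, length(inputs))
  hashes[ex] <- unname(tools::md5sum(inputs[ex]))
  hashes <- as.list(stats::setNames(hashes, basename(inputs)))
  m <- list(tool = "rankrecover",
            version = as.character(utils::packageVersion("rankrecover")),
            subcommand = subcommand,
            parameters = parameters,
            input_hashes = hashes,
            seed = seed)
  if (timestamp) m$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  m
}

#' Write a manifest next to a stage's outputs
#' @param manifest list from [run_manifest()].
#' @param dir output directory.
#' @return the manifest path, invisibly.
#' @export
write_run_manifest <- function(manifest, dir) {
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Run the full ranking-and-recovery pipeline
#'
#' Chains search-space delineation, CRM scanning, ranking-database
#' construction (motifs, and tracks when peaks are given), recovery
#' enrichment, motif-to-TF mapping and regulon assembly. Stages can be
#' skipped by supplying their artifact (`scores` skips scanning;
#' `motif_db` skips both scanning and ranking). Outputs (TSVs, ranking
#' databases, manifest) are written under `out_dir`.
#'
#' @param annotation annotation table (data.frame or TSV path).
#' @param fasta named character vector of per-species region FASTA
#'   paths (sequence keys `gene_id|region|species`), or a list of named
#'   sequence vectors. Ignored when `scores` or `motif_db` is given.
#' @param pwms list of [pwm] objects or a Cluster-Buster file path.
#' @param gene_set character vector of input genes, or a file path.
#' @param out_dir output directory.
#' @param peaks optional track collection: a peak data.frame, a BED
#'   path, or a named list of either (one entry per ChIP track). NES
#'   normalization needs at least 3 tracks in the collection.
#' @param graph optional [motif2tf_graph] for TF mapping.
#' @param mode search-space mode (used when regions must be computed
#'   for track scoring).
#' @param seed master seed (sub-seeded per ranking column).
#' @param scores optional precomputed score table (data.frame or TSV).
#' @param motif_db,track_db optional prebuilt [ranking_db] objects or
#'   `.rankdb` paths.
#' @param crm a [crm_params]; `recovery` a [recovery_params]; `m2tf` a
#'   [motif2tf_params].
#' @param recovery,m2tf see above.
#' @param query_species species of acceptable candidate TFs.
#' @return list with elements `enrichment`, `regulons`, `tf_candidates`,
#'   `motif_db`, `track_db`, `manifest` (also written to disk).
#' @export
run_pipeline <- function(annotation = NULL, fasta = NULL, pwms = NULL,
                         gene_set, out_dir, peaks = NULL, graph = NULL,
                         mode = "tss20kb", seed = 1, scores = NULL,
                         motif_db = NULL, track_db = NULL,
                         crm = crm_params(),
                         recovery = recovery_params(),
                         m2tf = motif2tf_params(),
                         query_species = "human") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  input_files <- character()
  if (is.character(annotation)) {
    input_files <- c(input_files, annotation)
    annotation <- read_gene_annotation(annotation)
  }
  if (is.character(pwms) && length(pwms) == 1L && file.exists(pwms)) {
    input_files <- c(input_files, pwms)
    pwms <- read_pwms_clusterbuster(pwms)
  }
  if (is.character(gene_set) && length(gene_set) == 1L &&
      file.exists(gene_set)) {
    input_files <- c(input_files, gene_set)
    gene_set <- read_gene_set(gene_set)
  }
  if (!is.null(peaks)) {
    if (is.data.frame(peaks)) peaks <- list(track = peaks)
    if (is.character(peaks))
      peaks <- stats::setNames(as.list(peaks),
                               names(peaks) %||%
                                 tools::file_path_sans_ext(basename(peaks)))
    peaks <- lapply(peaks, function(p) {
      if (is.character(p)) {
        input_files <<- c(input_files, p)
        read_bed_peaks(p)
      } else p
    })
    if (is.null(names(peaks)))
      names(peaks) <- sprintf("track_%02d", seq_along(peaks))
  }
  if (is.character(scores)) {
    input_files <- c(input_files, scores)
    scores <- read_scores_tsv(scores)
  }
  if (is.character(motif_db)) {
    input_files <- c(input_files, motif_db)
    motif_db <- read_ranking_db(motif_db)
  }
  if (is.character(track_db)) {
    input_files <- c(input_files, track_db)
    track_db <- read_ranking_db(track_db)
  }

  universe <- if (!is.null(annotation)) annotation$gene_id
              else if (!is.null(motif_db)) motif_db$universe
              else stop("need an annotation table or a prebuilt database")

  if (is.null(motif_db)) {
    if (is.null(scores)) {
      if (is.null(fasta) || is.null(pwms))
        stop("scanning needs per-species FASTA input and PWMs")
      if (is.character(fasta)) {
        input_files <- c(input_files, fasta)
        seqs <- lapply(fasta, Biostrings::readDNAStringSet)
      } else seqs <- fasta
      scores <- do.call(rbind, lapply(seqs, scan_regions, pwms = pwms,
                                      params = crm))
      write_scores_tsv(scores, file.path(out_dir, "scores.tsv"))
      message("scan: ", length(unique(scores$motif_id)), " motifs x ",
              length(unique(scores$gene_id)), " genes x ",
              length(unique(scores$species)), " species")
    }
    cols <- lapply(seq_along(unique(scores$motif_id)), function(i) {
      mid <- unique(scores$motif_id)[i]
      build_motif_ranking(scores[scores$motif_id == mid, , drop = FALSE],
                          universe, derive_seed(seed, i))
    })
    names(cols) <- unique(scores$motif_id)
    motif_db <- ranking_db_from_columns(cols, "motifs",
                                        list(seed = seed, mode = mode))
    write_ranking_db(motif_db, file.path(out_dir, "motifs.rankdb"))
    message("build-db: motif ranking database with ",
            length(motif_db$features), " features")
  }

  if (is.null(track_db) && !is.null(peaks)) {
    regions <- delineate_search_space(annotation, mode)
    cols <- lapply(seq_along(peaks), function(i)
      build_track_ranking(peaks[[i]], regions, universe,
                          derive_seed(seed, 10000L + i)))
    names(cols) <- names(peaks)
    track_db <- ranking_db_from_columns(cols, "tracks",
                                        list(seed = seed, mode = mode))
    write_ranking_db(track_db, file.path(out_dir, "tracks.rankdb"))
    message("build-db: track ranking database with ",
            length(track_db$features), " features")
  }

  dbs <- Filter(Negate(is.null), list(motif_db, track_db))
  enrichment <- run_enrichment(dbs, gene_set, recovery)
  write_enrichment_tsv(enrichment, file.path(out_dir, "enrichment.tsv"))
  message("enrich: ", nrow(enrichment), " feature(s) at NES >= ",
          recovery$nes_threshold)

  tf_candidates <- list()
  if (!is.null(graph)) {
    motif_feats <- enrichment$feature_id[enrichment$collection == "motifs"]
    tf_candidates <- stats::setNames(
      lapply(motif_feats, map_motif_to_tfs, graph = graph,
             input_genes = gene_set, params = m2tf,
             query_species = query_species),
      motif_feats)
  }
  regulons <- assemble_regulons(enrichment, tf_candidates)
  write_regulons(regulons, file.path(out_dir, "regulons.tsv"),
                 file.path(out_dir, "regulons.sif"))

  manifest <- run_manifest(
    "pipeline",
    parameters = list(mode = mode,
                      top_fraction = recovery$top_fraction,
                      nes_threshold = recovery$nes_threshold,
                      rank_threshold = recovery$rank_threshold,
                      gap_expectation = crm$gap_expectation,
                      pseudocount = crm$pseudocount,
                      min_identity_pct = m2tf$min_identity_pct,
                      max_similarity_p = m2tf$max_similarity_p,
                      universe_hash = motif_db$metadata$universe_hash),
    inputs = input_files, seed = seed)
  write_run_manifest(manifest, out_dir)

  list(enrichment = enrichment, regulons = regulons,
       tf_candidates = tf_candidates, motif_db = motif_db,
       track_db = track_db, manifest = manifest)
}
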