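#' Rank order-statistic q-value for a configuration of rank ratios
#'
#' Given per-species rank ratios r = rank/universe size in (0, 1] for
#' one gene, returns the probability Q of observing a rank configuration
#' at least this good if all K ratios were independent uniforms. With
#' the ratios sorted ascending as r_(1) <= ... <= r_(K),
#' Q = K! * V_K where V_0 = 1 and
#' V_k = sum_{i=1..k} (-1)^(i-1) * V_{k-i} * r_(K-k+1)^i / i!.
#' Small Q means the gene ranks consistently high across species.
#'
#' @param ratios numeric vector of rank ratios in (0, 1]; sorted
#'   internally if needed.
#' @return Q, clamped to (0, 1].
#' @examples
#' orderstat_q(0.25)            # 0.25
#' orderstat_q(c(0.1, 0.5))     # 2*0.1*0.5 - 0.1^2 = 0.09
#' @export
orderstat_q <- function(ratios) {
  if (!length(ratios)) stop("need at least one rank ratio")
  if (any(!is.finite(ratios)) || any(ratios <= 0) || any(ratios > 1))
    stop("rank ratios must lie in (0, 1]")
  r <- sort(ratios)
  K <- length(r)
  V <- numeric(K + 1)
  V[1] <- 1
  for (k in seq_len(K)) {
    i <- seq_len(k)
    terms <- (-1)^(i - 1) * V[k - i + 1] * r[K - k + 1]^i / factorial(i)
    V[k + 1] <- sum(terms)
  }
  q <- factorial(K) * V[K + 1]
  min(max(q, .Machine$double.xmin), 1)
}

# Vectorised over rows of a ratio matrix (NA = species without data).
orderstat_q_rows <- function(ratio_matrix) {
  apply(ratio_matrix, 1L, function(r) orderstat_q(r[!is.na(r)]))
}

#' Ranking database of whole-universe gene rankings
#'
#' Container for one total ordering of the gene universe per feature
#' (motif or track). Each column of `ranks` is a permutation of
#' 1..G (rank 1 = most likely target).
#'
#' @param ranks integer matrix, genes x features; rownames are gene ids,
#'   colnames feature ids.
#' @param collection label of the feature collection (e.g. "motifs",
#'   "tracks"); AUC normalization never crosses collections.
#' @param metadata list of build parameters (seed, mode, species, ...).
#' @return object of class `ranking_db`.
#' @export
ranking_db <- function(ranks, collection = "motifs", metadata = list()) {
  ranks <- as.matrix(ranks)
  storage.mode(ranks) <- "integer"
  if (is.null(rownames(ranks)) || is.null(colnames(ranks)))
    stop("ranks must carry gene ids (rownames) and feature ids (colnames)")
  G <- nrow(ranks)
  ok <- apply(ranks, 2L, function(col)
    identical(sort(unname(col)), seq_len(G)))
  if (!all(ok))
    stop("every ranking column must be a permutation of 1..G; offending: ",
         paste(colnames(ranks)[!ok], collapse = ", "))
  metadata$universe_hash <- hash_strings(rownames(ranks))
  structure(list(universe = rownames(ranks), features = colnames(ranks),
                 collection = collection, ranks = ranks,
                 metadata = metadata),
            class = "ranking_db")
}

#' @export
print.ranking_db <- function(x, ...) {
  cat(sprintf("ranking_db: %d genes x %d features (collection '%s')\n",
              length(x$universe), length(x$features), x$collection))
  invisible(x)
}

# Descending-score gene ranks for one species; ties get average ranks,
# giving each tied gene the same rank ratio.
species_rank_ratio <- function(scores) {
  r <- rank(-scores, ties.method = "average", na.last = "keep")
  r / sum(!is.na(scores))
}

#' Build one motif ranking column from cross-species region scores
#'
#' Per species, each gene's best region score is rank-transformed into a
#' rank ratio; ratios are aggregated across species with
#' [orderstat_q()] (species without data for a gene simply reduce K);
#' genes are ordered by ascending q-value. Genes scoring zero in every
#' available species are appended in seeded-random order, and ties in
#' q-value are broken by a seeded shuffle of the tied block.
#'
#' @param scores data.frame with columns gene_id, species, score
#'   (region-level tables with a `region` column are aggregated by max).
#' @param universe character vector of all gene ids.
#' @param seed integer seed for random queueing and tie-breaks.
#' @return named integer vector of ranks (1..G) over `universe`.
#' @export
build_motif_ranking <- function(scores, universe, seed = 1) {
  if (!all(c("gene_id", "species", "score") %in% names(scores)))
    stop("scores needs columns gene_id, species, score")
  unknown <- setdiff(unique(scores$gene_id), universe)
  if (length(unknown))
    stop("gene(s) in scores but not in universe: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  G <- length(universe)
  species <- sort(unique(scores$species))
  best <- matrix(NA_real_, G, length(species),
                 dimnames = list(universe, species))
  agg <- stats::aggregate(score ~ gene_id + species, scores, max)
  best[cbind(match(agg$gene_id, universe), match(agg$species, species))] <-
    agg$score

  ratios <- apply(best, 2L, species_rank_ratio)
  if (is.null(dim(ratios))) ratios <- matrix(ratios, nrow = G)
  all_zero <- apply(best, 1L, function(x) all(is.na(x) | x == 0))
  q <- rep(NA_real_, G)
  q[!all_zero] <- orderstat_q_rows(ratios[!all_zero, , drop = FALSE])

  order_with_random_tail(q, universe, seed)
}

# Rank genes by ascending key; NA keys go last in seeded-random order;
# tied key blocks are shuffled with the same seed.
order_with_random_tail <- function(key, universe, seed) {
  G <- length(universe)
  local_seed(seed, {
    scored <- which(!is.na(key))
    tail_g <- which(is.na(key))
    ord <- scored[order(key[scored], sample.int(length(scored)))]
    ord <- c(ord, tail_g[sample.int(length(tail_g))])
    stats::setNames(order(ord), universe)[universe]
  })
}

#' Build one track ranking column from ChIP peaks
#'
#' Each gene is scored by the maximum peak `signalValue` over all peaks
#' overlapping (>= 1 bp) any of its search-space regions; genes are
#' ranked by descending score. Genes whose regions overlap no peak are
#' appended in seeded-random order; score ties are broken by a seeded
#' shuffle.
#'
#' @param peaks data.frame with columns chrom, start, end, signalValue
#'   (0-based half-open), e.g. from [read_bed_peaks()].
#' @param regions search-space region table from
#'   [delineate_search_space()].
#' @param universe character vector of all gene ids.
#' @param seed integer seed.
#' @return named integer vector of ranks (1..G) over `universe`.
#' @export
build_track_ranking <- function(peaks, regions, universe, seed = 1) {
  stopifnot(all(c("chrom", "start", "end", "signalValue") %in% names(peaks)))
  chroms <- unique(c(regions$chrom, peaks$chrom))
  rgr <- GenomicRanges::GRanges(
    factor(regions$chrom, levels = chroms),
    IRanges::IRanges(start = regions$start + 1L, end = regions$end))
  pgr <- GenomicRanges::GRanges(
    factor(peaks$chrom, levels = chroms),
    IRanges::IRanges(start = peaks$start + 1L, end = peaks$end))
  hits <- GenomicRanges::findOverlaps(rgr, pgr)
  score <- rep(NA_real_, length(universe))
  names(score) <- universe
  if (length(hits)) {
    gene_hit <- regions$gene_id[S4Vectors::queryHits(hits)]
    sv <- peaks$signalValue[S4Vectors::subjectHits(hits)]
    mx <- tapply(sv, gene_hit, max)
    score[names(mx)] <- mx
  }
  key <- -score  # descending signal; NA = no overlap -> random tail
  order_with_random_tail(key, universe, seed)
}

#' Assemble ranking columns into a database
#'
#' @param columns named list of rank vectors (as returned by
#'   [build_motif_ranking()] / [build_track_ranking()]), all over the
#'   same universe.
#' @inheritParams ranking_db
#' @return a [ranking_db] object.
#' @export
ranking_db_from_columns <- function(columns, collection = "motifs",
                                    metadata = list()) {
  universe <- names(columns[[1]])
  m <- vapply(columns, function(col) col[universe], integer(length(universe)))
  rownames(m) <- universe
  ranking_db(m, collection, metadata)
}

#' Write / read a ranking database
#'
#' The on-disk artifact is a pair of files: `<path>` holds the
#' tab-separated rank matrix (gene_id + one column per feature) and
#' `<path>.meta.json` the metadata sidecar (collection, universe hash,
#' build parameters), which is required for reading back.
#'
#' @param db a [ranking_db].
#' @param path output path (conventionally `*.rankdb`).
#' @return `path` invisibly (writer); a [ranking_db] (reader).
#' @export
write_ranking_db <- function(db, path) {
  stopifnot(inherits(db, "ranking_db"))
  tab <- data.frame(gene_id = db$universe, db$ranks, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- c(list(collection = db$collection), db$metadata)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_ranking_db
#' @export
read_ranking_db <- function(path) {
  meta_path <- paste0(path, ".meta.json")
  if (!file.exists(meta_path))
    stop("metadata sidecar not found: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$gene_id
  collection <- meta$collection %||% "motifs"
  meta$collection <- NULL
  db <- ranking_db(m, collection, meta)
  stopifnot(identical(db$metadata$universe_hash, meta$universe_hash))
  db
}

#' Export a ranking database as plain TSV
#' @param db a [ranking_db].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
export_ranking_tsv <- function(db, path) {
  tab <- data.frame(gene_id = db$universe, db$ranks, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
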