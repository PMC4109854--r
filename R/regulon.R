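#' Assemble per-TF regulons from enrichment results
#'
#' Each reported feature (motif or track) is associated with a TF via
#' its motif2TF candidates; per TF, the target sets of all its features
#' are merged, annotating every target with the number of supporting
#' features. Features mapping to no TF are retained as orphan regulons
#' (tf_id `NA`): an unannotated motif can still be enriched. Regulons
#' are sorted by their best (maximum) NES.
#'
#' @param results an `enrichment_result` from [run_enrichment()] (its
#'   `targets_list` attribute supplies the per-feature targets).
#' @param tf_candidates named list: for each feature_id, a candidate
#'   data.frame from [map_motif_to_tfs()] (zero rows or missing entry =
#'   orphan). Tracks can be mapped by naming the ChIP'ped TF directly.
#' @param top_tf_only if TRUE (default) a feature contributes only to
#'   its rank-1 candidate TF; otherwise to all its candidate TFs.
#' @return list of class `regulon_set`; each element has tf_id,
#'   targets (named integer vector of supporting-feature counts),
#'   features (data.frame feature_id, collection, NES) and best_NES.
#' @export
assemble_regulons <- function(results, tf_candidates = list(),
                              top_tf_only = TRUE) {
  targets_list <- attr(results, "targets_list") %||% list()
  df <- as.data.frame(results)
  if (!nrow(df)) return(structure(list(), class = "regulon_set"))

  feat_tfs <- lapply(seq_len(nrow(df)), function(i) {
    cand <- tf_candidates[[df$feature_id[i]]]
    if (is.null(cand) || !nrow(cand)) return(NA_character_)
    if (top_tf_only) cand$tf_id[1] else unique(cand$tf_id)
  })

  groups <- list()
  for (i in seq_len(nrow(df))) {
    tg <- targets_list[[paste(df$collection[i], df$feature_id[i],
                              sep = ":")]]
    for (tf in feat_tfs[[i]]) {
      gkey <- if (is.na(tf)) paste0(".orphan:", df$feature_id[i]) else tf
      groups[[gkey]] <- c(groups[[gkey]], list(list(row = df[i, ],
                                                    targets = tg)))
    }
  }

  regs <- lapply(names(groups), function(gkey) {
    entries <- groups[[gkey]]
    feats <- do.call(rbind, lapply(entries, function(e)
      e$row[, c("feature_id", "collection", "NES")]))
    rownames(feats) <- NULL
    tgt_genes <- unlist(lapply(entries, function(e) e$targets$gene_id))
    counts <- if (length(tgt_genes)) table(tgt_genes) else table(character())
    counts <- stats::setNames(as.integer(counts), names(counts))
    list(tf_id = if (startsWith(gkey, ".orphan:")) NA_character_ else gkey,
         targets = counts,
         features = feats,
         best_NES = max(feats$NES))
  })
  regs <- regs[order(vapply(regs, `[[`, numeric(1), "best_NES"),
                     decreasing = TRUE)]
  structure(regs, class = "regulon_set")
}

#' @export
print.regulon_set <- function(x, ...) {
  cat(sprintf("regulon_set with %d regulon(s)\n", length(x)))
  for (r in x)
    cat(sprintf("  %s: %d target(s), %d feature(s), best NES %.2f\n",
                if (is.na(r$tf_id)) "(orphan)" else r$tf_id,
                length(r$targets), nrow(r$features), r$best_NES))
  invisible(x)
}

#' Write a regulon set as TSV and/or SIF edge list
#'
#' @param regulons a `regulon_set`.
#' @param path output TSV path (tf_id, target, n_features, best_NES).
#' @param sif_path optional SIF path (`tf regulates target`) for
#'   network tools; orphan regulons are skipped there.
#' @return `path`, invisibly.
#' @export
write_regulons <- function(regulons, path, sif_path = NULL) {
  rows <- lapply(regulons, function(r) {
    if (!length(r$targets)) return(NULL)
    data.frame(tf_id = ifelse(is.na(r$tf_id), "", r$tf_id),
               target = names(r$targets),
               n_features = unname(r$targets),
               best_NES = r$best_NES, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- data.frame(tf_id = character(), target = character(),
                      n_features = integer(), best_NES = numeric())
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(sif_path)) {
    sif <- tab[nzchar(tab$tf_id), c("tf_id", "target")]
    writeLines(sprintf("%s\tregulates\t%s", sif$tf_id, sif$target),
               sif_path)
  }
  invisible(path)
}

#' Aggregate a TF's regulons over many gene sets into a meta-regulon
#'
#' Applied to the per-gene-set outputs of a batch analysis: every
#' target gene is annotated with the number of gene sets in which the
#' TF was enriched and the gene was in the optimal target subset.
#' Targets recurring fewer than `min_count` times are dropped.
#'
#' @param batch list of `regulon_set` objects, one per analysed gene
#'   set.
#' @param tf_id the TF to aggregate.
#' @param min_count minimum recurrence to keep a target (default 1).
#' @return list of class `meta_regulon`: tf_id, n_gene_sets (sets where
#'   the TF was enriched), recurrence (named integer vector).
#' @export
aggregate_meta_regulon <- function(batch, tf_id, min_count = 1) {
  per_set <- lapply(batch, function(regset) {
    mine <- Filter(function(r) identical(r$tf_id, tf_id), regset)
    if (!length(mine)) return(NULL)
    # once per gene set, however many features/regulons support it
    unique(unlist(lapply(mine, function(r) names(r$targets))))
  })
  per_set <- Filter(Negate(is.null), per_set)
  rec <- table(unlist(per_set))
  rec <- stats::setNames(as.integer(rec), names(rec))
  rec <- rec[rec >= min_count]
  if (length(rec)) rec <- rec[order(-rec, names(rec))]
  structure(list(tf_id = tf_id, n_gene_sets = length(per_set),
                 recurrence = rec),
            class = "meta_regulon")
}

#' @export
print.meta_regulon <- function(x, ...) {
  cat(sprintf("meta_regulon %s: %d target(s) over %d gene set(s)\n",
              x$tf_id, length(x$recurrence), x$n_gene_sets))
  invisible(x)
}

#' Leading-edge overlap test of a gene set against an external ranking
#'
#' The unweighted running enrichment d(k) = c(k)/s - k/G (recovery of
#' the set minus the uniform expectation) is maximized over k; at the
#' maximizing rank k* with x = c(k*) set members recovered, the
#' upper-tail hypergeometric probability of drawing at least x set
#' members in k* draws from a universe of G genes containing s set
#' members is reported.
#'
#' @param ranking named integer vector: a permutation of 1..G over the
#'   universe (gene -> rank).
#' @param gene_set character vector of set members (must intersect the
#'   universe).
#' @return list with leading_edge_rank (k*), overlap (x) and p_value.
#' @export
rank_set_enrichment_test <- function(ranking, gene_set) {
  G <- length(ranking)
  if (!identical(sort(as.integer(ranking)), seq_len(G)))
    stop("ranking must be a permutation of 1..G")
  r <- set_ranks(ranking, gene_set)
  s <- length(r)
  ck <- cumsum(tabulate(r, nbins = G))
  d <- ck / s - seq_len(G) / G
  k_star <- which.max(d)
  x <- ck[k_star]
  p <- stats::phyper(x - 1, s, G - s, k_star, lower.tail = FALSE)
  list(leading_edge_rank = as.integer(k_star), overlap = as.integer(x),
       p_value = p)
}
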