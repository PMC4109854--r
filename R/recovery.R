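#' Parameters for recovery-based enrichment
#'
#' @param top_fraction fraction of the ranking over which the AUC is
#'   computed (default 0.03, i.e. the top 3%).
#' @param nes_threshold minimum normalized enrichment score for a
#'   feature to be reported (default 3.0).
#' @param rank_threshold maximum rank considered when searching for the
#'   leading edge (default 5000, capped at the universe size).
#' @return list of class `recovery_params`.
#' @export
recovery_params <- function(top_fraction = 0.03, nes_threshold = 3.0,
                            rank_threshold = 5000) {
  if (top_fraction <= 0 || top_fraction > 1)
    stop("top_fraction must be in (0, 1]")
  if (rank_threshold < 1) stop("rank_threshold must be >= 1")
  structure(list(top_fraction = top_fraction,
                 nes_threshold = nes_threshold,
                 rank_threshold = rank_threshold),
            class = "recovery_params")
}

# Ranks of the usable gene-set members in one ranking column.
set_ranks <- function(ranking, gene_set, warn = TRUE) {
  gene_set <- unique(gene_set)
  known <- gene_set[gene_set %in% names(ranking)]
  dropped <- length(gene_set) - length(known)
  if (dropped && warn)
    warning(dropped, " gene(s) not in the ranking universe were dropped")
  if (!length(known)) stop("no usable genes in the input set")
  unname(ranking[known])
}

#' Area under the cumulative recovery curve, in the top of a ranking
#'
#' With c(k) the number of input genes at rank <= k, s the effective set
#' size and T = ceiling(top_fraction * G),
#' AUC = sum_{k=1..T} c(k) / (T * s). Genes absent from the universe
#' are dropped with a warning.
#'
#' @param ranking named integer vector of ranks over the universe (one
#'   ranking-database column).
#' @param gene_set character vector of input gene ids.
#' @param params a [recovery_params] object.
#' @return AUC in `[0, 1)`.
#' @export
compute_recovery_auc <- function(ranking, gene_set,
                                 params = recovery_params()) {
  r <- set_ranks(ranking, gene_set)
  G <- length(ranking)
  T_ <- max(1L, as.integer(ceiling(params$top_fraction * G)))
  sum(pmax(0L, T_ - r[r <= T_] + 1L)) / (T_ * length(r))
}

# AUCs for every feature of a ranking_db (vectorised over columns).
recovery_auc_all <- function(db, gene_set, params = recovery_params()) {
  idx <- which(db$universe %in% gene_set)
  dropped <- length(unique(gene_set)) - length(idx)
  if (dropped)
    warning(dropped, " gene(s) not in the ranking universe were dropped")
  if (!length(idx)) stop("no usable genes in the input set")
  G <- length(db$universe)
  T_ <- max(1L, as.integer(ceiling(params$top_fraction * G)))
  r <- db$ranks[idx, , drop = FALSE]
  contrib <- T_ - r + 1L
  contrib[contrib < 0L] <- 0L
  colSums(contrib) / (T_ * length(idx))
}

#' Normalize AUCs of one feature collection to enrichment scores
#'
#' NES_f = (AUC_f - mean(AUC)) / sd(AUC), using the sample (n-1)
#' standard deviation over all features of the collection. A degenerate
#' collection (sd = 0) yields all-zero NES with a warning. Motif and
#' track collections must be normalized separately.
#'
#' @param aucs named numeric vector of AUCs (>= 3 features).
#' @return named numeric vector of NES values.
#' @export
normalize_nes <- function(aucs) {
  if (length(aucs) < 3L)
    stop("NES normalization needs at least 3 features in the collection")
  s <- stats::sd(aucs)
  if (s == 0) {
    warning("degenerate collection: all AUCs equal; NES set to 0")
    return(stats::setNames(rep(0, length(aucs)), names(aucs)))
  }
  (aucs - mean(aucs)) / s
}

# Cumulative recovery counts c_f(k), k = 1..R, for every feature:
# features x R matrix.
recovery_count_matrix <- function(db, gene_set, R) {
  idx <- which(db$universe %in% gene_set)
  r <- db$ranks[idx, , drop = FALSE]
  t(apply(r, 2L, function(col) cumsum(tabulate(col[col <= R], nbins = R))))
}

#' Select candidate targets at the leading edge of a recovery curve
#'
#' The candidate feature's recovery fraction c(k)/s is compared with a
#' collection background b(k) = mean over all features of c_f(k)/s plus
#' twice the across-feature (population) standard deviation, for
#' k = 1..rank_threshold. The leading edge k* is the smallest rank
#' maximizing c(k)/s - b(k); the predicted targets are the input genes
#' ranked at or above k*. If the signal never exceeds the background,
#' k* = 0 and no targets are returned.
#'
#' @param feature_id the candidate feature (a column of `db`).
#' @param db a [ranking_db]; all of its features define the background.
#' @param gene_set character vector of input gene ids.
#' @param params a [recovery_params] object.
#' @return list with `leading_edge_rank` and `targets` (data.frame
#'   gene_id, rank, ordered by rank).
#' @export
select_targets_leading_edge <- function(feature_id, db, gene_set,
                                        params = recovery_params()) {
  if (length(db$features) < 3L)
    stop("leading-edge background needs >= 3 features in the collection")
  if (!feature_id %in% db$features) stop("unknown feature: ", feature_id)
  idx <- which(db$universe %in% gene_set)
  if (!length(idx)) stop("no usable genes in the input set")
  s <- length(idx)
  R <- min(as.integer(params$rank_threshold), length(db$universe))
  cm <- recovery_count_matrix(db, gene_set, R) / s
  mu <- colMeans(cm)
  sd_pop <- sqrt(colMeans(cm^2) - mu^2)
  b <- mu + 2 * sd_pop
  d <- cm[feature_id, ] - b
  if (max(d) <= 0)
    return(list(leading_edge_rank = 0L,
                targets = data.frame(gene_id = character(),
                                     rank = integer())))
  k_star <- which.max(d)  # smallest argmax
  r <- db$ranks[idx, feature_id]
  keep <- r <= k_star
  ord <- order(r[keep])
  list(leading_edge_rank = as.integer(k_star),
       targets = data.frame(gene_id = db$universe[idx][keep][ord],
                            rank = as.integer(r[keep][ord])))
}

#' Run ranking-and-recovery enrichment of a gene set
#'
#' For each ranking database (feature collection): computes the AUC of
#' every feature, normalizes to NES within the collection, reports the
#' features reaching the NES threshold (sorted by NES, descending) and
#' selects each reported feature's leading-edge targets. Collections
#' are kept separate for normalization and concatenated in the result.
#'
#' @param dbs a [ranking_db] or list of them (e.g. motifs and tracks).
#' @param gene_set character vector of input gene ids.
#' @param params a [recovery_params] object.
#' @return data.frame of class `enrichment_result` with columns
#'   collection, feature_id, AUC, NES, leading_edge_rank, n_targets,
#'   targets (comma-separated); the per-feature target data.frames are
#'   attached as the `targets_list` attribute. All AUC/NES values for
#'   every feature (reported or not) are attached as the `scores`
#'   attribute.
#' @export
run_enrichment <- function(dbs, gene_set, params = recovery_params()) {
  if (inherits(dbs, "ranking_db")) dbs <- list(dbs)
  hashes <- vapply(dbs, function(d) d$metadata$universe_hash, character(1))
  if (length(unique(hashes)) > 1L)
    stop("ranking databases span different universes (hashes: ",
         paste(unique(hashes), collapse = " vs "), ")")
  all_rows <- list(); all_targets <- list(); all_scores <- list()
  for (db in dbs) {
    aucs <- recovery_auc_all(db, gene_set, params)
    nes <- normalize_nes(aucs)
    all_scores[[db$collection]] <-
      data.frame(collection = db$collection, feature_id = names(aucs),
                 AUC = unname(aucs), NES = unname(nes),
                 stringsAsFactors = FALSE)
    hits <- names(sort(nes[nes >= params$nes_threshold], decreasing = TRUE))
    for (f in hits) {
      le <- select_targets_leading_edge(f, db, gene_set, params)
      all_targets[[paste(db$collection, f, sep = ":")]] <- le$targets
      all_rows[[paste(db$collection, f, sep = ":")]] <- data.frame(
        collection = db$collection, feature_id = f,
        AUC = unname(aucs[f]), NES = unname(nes[f]),
        leading_edge_rank = le$leading_edge_rank,
        n_targets = nrow(le$targets),
        targets = paste(le$targets$gene_id, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(all_rows)) do.call(rbind, all_rows) else
    data.frame(collection = character(), feature_id = character(),
               AUC = numeric(), NES = numeric(),
               leading_edge_rank = integer(), n_targets = integer(),
               targets = character(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "targets_list") <- all_targets
  attr(res, "scores") <- do.call(rbind, c(all_scores, make.row.names = FALSE))
  class(res) <- c("enrichment_result", class(res))
  res
}

#' Tidy recovery curves for plotting
#'
#' Returns the cumulative recovery fraction c(k)/s of selected features
#' over k = 1..rank_threshold, together with the collection background
#' envelope (mean + 2 population SD over all features), in long format.
#'
#' @param db a [ranking_db].
#' @param gene_set character vector of input gene ids.
#' @param features feature ids to extract (default: all).
#' @param params a [recovery_params] object.
#' @return data.frame with columns feature_id, rank, recovery,
#'   background.
#' @export
recovery_curve_table <- function(db, gene_set, features = db$features,
                                 params = recovery_params()) {
  idx <- which(db$universe %in% gene_set)
  if (!length(idx)) stop("no usable genes in the input set")
  R <- min(as.integer(params$rank_threshold), length(db$universe))
  cm <- recovery_count_matrix(db, gene_set, R) / length(idx)
  mu <- colMeans(cm)
  b <- mu + 2 * sqrt(colMeans(cm^2) - mu^2)
  do.call(rbind, lapply(features, function(f)
    data.frame(feature_id = f, rank = seq_len(R),
               recovery = cm[f, ], background = b,
               stringsAsFactors = FALSE)))
}

#' Write enrichment results as TSV
#' @param results an `enrichment_result` from [run_enrichment()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_tsv <- function(results, path) {
  utils::write.table(as.data.frame(results), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
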