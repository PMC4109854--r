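#' Motif-TF association graph
#'
#' A heterogeneous, undirected graph with motif and TF nodes and three
#' edge types: direct motif-TF annotations (with the species of the
#' annotated TF), TF-TF homology edges (percent identity) and
#' motif-motif similarity edges (p-value). Candidate TFs for an
#' enriched motif are found by path search with
#' [map_motif_to_tfs()].
#'
#' @param annotations data.frame: motif_id, tf_id, species.
#' @param homology data.frame: tf_a, tf_b, identity_pct (in `[0, 100]`);
#'   treated as symmetric. Optional.
#' @param similarity data.frame: motif_a, motif_b, p_value (in (0, 1]);
#'   treated as symmetric. Optional.
#' @param tf_species optional data.frame (tf_id, species) declaring the
#'   species of TFs that never appear in `annotations`; TFs without any
#'   species information are assumed to belong to the query species.
#' @return object of class `motif2tf_graph`.
#' @export
motif2tf_graph <- function(annotations,
                           homology = NULL,
                           similarity = NULL,
                           tf_species = NULL) {
  stopifnot(all(c("motif_id", "tf_id", "species") %in% names(annotations)))
  empty_h <- data.frame(tf_a = character(), tf_b = character(),
                        identity_pct = numeric(), stringsAsFactors = FALSE)
  empty_s <- data.frame(motif_a = character(), motif_b = character(),
                        p_value = numeric(), stringsAsFactors = FALSE)
  homology <- homology %||% empty_h
  similarity <- similarity %||% empty_s
  stopifnot(all(c("tf_a", "tf_b", "identity_pct") %in% names(homology)),
            all(c("motif_a", "motif_b", "p_value") %in% names(similarity)))
  if (nrow(homology) &&
      (any(homology$identity_pct < 0) || any(homology$identity_pct > 100)))
    stop("identity_pct must lie in [0, 100]")
  if (nrow(similarity) &&
      (any(similarity$p_value <= 0) || any(similarity$p_value > 1)))
    stop("similarity p_value must lie in (0, 1]")

  sp <- stats::setNames(as.character(annotations$species),
                        annotations$tf_id)
  if (!is.null(tf_species))
    sp <- c(sp, stats::setNames(as.character(tf_species$species),
                                tf_species$tf_id))
  sp <- sp[!duplicated(names(sp))]

  structure(list(
    annotations = annotations[, c("motif_id", "tf_id", "species")],
    homology = symmetrize(homology, "tf_a", "tf_b"),
    similarity = symmetrize(similarity, "motif_a", "motif_b"),
    tf_species = sp), class = "motif2tf_graph")
}

# Duplicate each undirected edge in both directions, dropping loops.
symmetrize <- function(df, a, b) {
  rev <- df
  rev[[a]] <- df[[b]]; rev[[b]] <- df[[a]]
  out <- unique(rbind(df, rev))
  out[out[[a]] != out[[b]], , drop = FALSE]
}

#' @export
print.motif2tf_graph <- function(x, ...) {
  cat(sprintf(paste0("motif2tf_graph: %d annotation, %d homology, ",
                     "%d similarity edge(s)\n"),
              nrow(x$annotations), nrow(x$homology) / 2,
              nrow(x$similarity) / 2))
  invisible(x)
}

#' Read the three motif2TF edge tables from TSV files
#'
#' @param annotations_path TSV with columns motif_id, tf_id, species.
#' @param homology_path optional TSV with tf_a, tf_b, identity_pct.
#' @param similarity_path optional TSV with motif_a, motif_b, p_value
#'   (e.g. an imported motif-comparison table).
#' @param tf_species_path optional TSV with tf_id, species.
#' @return a [motif2tf_graph].
#' @export
read_motif2tf_graph <- function(annotations_path, homology_path = NULL,
                                similarity_path = NULL,
                                tf_species_path = NULL) {
  rd <- function(p) if (is.null(p)) NULL else
    utils::read.delim(p, stringsAsFactors = FALSE)
  motif2tf_graph(rd(annotations_path), rd(homology_path),
                 rd(similarity_path), rd(tf_species_path))
}

#' Parameters for motif-to-TF mapping
#'
#' @param min_identity_pct minimum percent identity for a homology edge
#'   to be traversed (default 0, i.e. keep all).
#' @param max_similarity_p maximum p-value for a motif-motif similarity
#'   edge to be traversed (default 0.001).
#' @return list of class `motif2tf_params`.
#' @export
motif2tf_params <- function(min_identity_pct = 0, max_similarity_p = 0.001) {
  structure(list(min_identity_pct = min_identity_pct,
                 max_similarity_p = max_similarity_p),
            class = "motif2tf_params")
}

#' Map an enriched motif to candidate TFs
#'
#' Searches the motif2TF graph for paths from `motif_id` to TFs of the
#' query species, allowing at most one similarity edge and at most one
#' homology edge per path (the four admissible path shapes are
#' annotation; annotation + homology; similarity + annotation;
#' similarity + annotation + homology). Edges failing the parameter
#' thresholds are removed before traversal. Candidates are then ranked
#' by tier -- directly annotated TFs first, then TFs encoded by a gene
#' of the input set, then TFs reached through homology, then TFs
#' reached through motif similarity -- and within a tier by shortest
#' path, higher percent identity, lower similarity p-value and finally
#' lexicographic TF id. Each TF is reported once, with its best path.
#'
#' @param motif_id query motif; if absent from the graph an empty
#'   result is returned.
#' @param graph a [motif2tf_graph].
#' @param input_genes gene ids of the analysed set; a candidate TF
#'   whose gene is in this set is promoted (tier `in_input_set`).
#' @param params a [motif2tf_params] object.
#' @param query_species species whose TFs are acceptable candidates
#'   (default "human").
#' @return data.frame with columns tf_id, tier, path, path_length,
#'   identity_pct, similarity_p, rank; zero rows if nothing is found.
#' @export
map_motif_to_tfs <- function(motif_id, graph,
                             input_genes = character(),
                             params = motif2tf_params(),
                             query_species = "human") {
  stopifnot(inherits(graph, "motif2tf_graph"))
  ann <- graph$annotations
  hom <- graph$homology
  hom <- hom[hom$identity_pct >= params$min_identity_pct, , drop = FALSE]
  sim <- graph$similarity
  sim <- sim[sim$p_value <= params$max_similarity_p, , drop = FALSE]
  tf_sp <- function(tf) {
    s <- graph$tf_species[tf]
    ifelse(is.na(s), query_species, s)
  }

  cand <- list()
  add <- function(tf, kind, path, identity, simp) {
    cand[[length(cand) + 1L]] <<- data.frame(
      tf_id = tf, kind = kind, path = path,
      path_length = lengths(regmatches(path, gregexpr("->", path))),
      identity_pct = identity, similarity_p = simp,
      stringsAsFactors = FALSE)
  }

  # motifs one similarity hop away (plus the query itself at p = NA)
  sim_from <- sim[sim$motif_a == motif_id, , drop = FALSE]
  starts <- data.frame(motif = c(motif_id, sim_from$motif_b),
                       simp = c(NA_real_, sim_from$p_value),
                       stringsAsFactors = FALSE)

  for (i in seq_len(nrow(starts))) {
    m <- starts$motif[i]; sp_ <- starts$simp[i]
    via_sim <- !is.na(sp_)
    prefix <- if (via_sim)
      sprintf("%s -sim-> %s", motif_id, m) else motif_id
    a <- ann[ann$motif_id == m, , drop = FALSE]
    for (j in seq_len(nrow(a))) {
      tf1 <- a$tf_id[j]
      if (identical(unname(tf_sp(tf1)), query_species))
        add(tf1, if (via_sim) "similarity" else "direct",
            sprintf("%s -ann-> %s", prefix, tf1), NA_real_, sp_)
      h <- hom[hom$tf_a == tf1, , drop = FALSE]
      for (k in seq_len(nrow(h))) {
        tf2 <- h$tf_b[k]
        if (!identical(unname(tf_sp(tf2)), query_species)) next
        add(tf2, if (via_sim) "similarity" else "homology",
            sprintf("%s -ann-> %s -hom-> %s", prefix, tf1, tf2),
            h$identity_pct[k], sp_)
      }
    }
  }

  empty <- data.frame(tf_id = character(), tier = character(),
                      path = character(), path_length = integer(),
                      identity_pct = numeric(), similarity_p = numeric(),
                      rank = integer(), stringsAsFactors = FALSE)
  if (!length(cand)) return(empty)
  cc <- do.call(rbind, cand)

  tier_rank <- c(direct = 1L, in_input_set = 2L, homology = 3L,
                 similarity = 4L)
  cc$tier <- ifelse(cc$kind == "direct", "direct",
                    ifelse(cc$tf_id %in% input_genes, "in_input_set",
                           cc$kind))
  cc$tier_num <- tier_rank[cc$tier]
  ord <- order(cc$tier_num, cc$path_length, -ifelse(is.na(cc$identity_pct),
                                                    -Inf, cc$identity_pct),
               ifelse(is.na(cc$similarity_p), Inf, cc$similarity_p),
               cc$tf_id)
  cc <- cc[ord, , drop = FALSE]
  cc <- cc[!duplicated(cc$tf_id), , drop = FALSE]  # best path per TF
  cc$rank <- seq_len(nrow(cc))
  rownames(cc) <- NULL
  cc[, c("tf_id", "tier", "path", "path_length", "identity_pct",
         "similarity_p", "rank")]
}
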