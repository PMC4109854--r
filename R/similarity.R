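#' Ungapped similarity between two PWMs
#'
#' Aligns the two matrices at every ungapped offset, in both the given
#' and the reverse-complement orientation of `pwm_b`, requiring at least
#' `min_overlap` overlapping columns. The alignment score is the mean
#' per-column Pearson correlation of the pseudocounted probability
#' columns; the reported score is the maximum over all alignments. An
#' empirical p-value is obtained by re-scoring against `n_shuffles`
#' column-order-shuffled copies of `pwm_b`:
#' p = (1 + #\{shuffled >= observed\}) / (1 + n_shuffles).
#'
#' This is a deliberately simple native metric for building motif-motif
#' similarity edges; precomputed similarity tables from a dedicated motif
#' comparison tool can be supplied to [motif2tf_graph()] instead.
#'
#' @param pwm_a,pwm_b [pwm] objects, each with at least 4 positions.
#' @param n_shuffles number of column-shuffled null copies.
#' @param seed integer seed for the shuffles.
#' @param min_overlap minimum number of overlapping columns per alignment.
#' @param pseudocount additive count per cell for probability columns.
#' @return list with `score` (max mean column correlation, or `NA` when no
#'   alignment satisfies the overlap constraint), `p_value`, `motif_a`,
#'   `motif_b`.
#' @examples
#' p <- pwm("m", matrix(rep(c(80, 5, 10, 5), 6), ncol = 4, byrow = TRUE))
#' motif_similarity(p, p, n_shuffles = 50, seed = 1)$score
#' @export
motif_similarity <- function(pwm_a, pwm_b, n_shuffles = 1000, seed = 1,
                             min_overlap = 5, pseudocount = 0.375) {
  stopifnot(inherits(pwm_a, "pwm"), inherits(pwm_b, "pwm"))
  if (length(pwm_a) < 4L || length(pwm_b) < 4L)
    stop("both PWMs must have at least 4 positions")
  pa <- pwm_prob(pwm_a, pseudocount)
  pb <- pwm_prob(pwm_b, pseudocount)
  obs <- best_alignment_score(pa, pb, min_overlap)
  if (is.na(obs))
    return(list(score = NA_real_, p_value = NA_real_,
                motif_a = pwm_a$motif_id, motif_b = pwm_b$motif_id))
  null <- local_seed(seed, {
    vapply(seq_len(n_shuffles), function(i) {
      shuf <- pb[sample.int(nrow(pb)), , drop = FALSE]
      best_alignment_score(pa, shuf, min_overlap)
    }, numeric(1))
  })
  p <- (1 + sum(null >= obs, na.rm = TRUE)) / (1 + n_shuffles)
  list(score = obs, p_value = p,
       motif_a = pwm_a$motif_id, motif_b = pwm_b$motif_id)
}

# Max over both orientations and all offsets of the mean per-column
# Pearson correlation; columns with zero variance contribute 0.
best_alignment_score <- function(pa, pb, min_overlap) {
  pb_rc <- pb[rev(seq_len(nrow(pb))), c(4L, 3L, 2L, 1L), drop = FALSE]
  best <- NA_real_
  for (mb in list(pb, pb_rc)) {
    na <- nrow(pa); nb <- nrow(mb)
    for (off in seq(-(nb - min_overlap), na - min_overlap)) {
      ia <- max(1L, 1L + off):min(na, nb + off)
      if (length(ia) < min_overlap) next
      ib <- ia - off
      cc <- vapply(seq_along(ia), function(k) {
        x <- pa[ia[k], ]; y <- mb[ib[k], ]
        if (stats::sd(x) == 0 || stats::sd(y) == 0) 0 else stats::cor(x, y)
      }, numeric(1))
      sc <- mean(cc)
      if (is.na(best) || sc > best) best <- sc
    }
  }
  best
}

#' All-pairs PWM similarity table
#'
#' Convenience wrapper computing [motif_similarity()] for every unordered
#' pair of motifs in a collection, in the three-column edge-table layout
#' consumed by [motif2tf_graph()].
#'
#' @param pwms named list of [pwm] objects.
#' @inheritParams motif_similarity
#' @return data.frame with columns motif_a, motif_b, score, p_value.
#' @export
motif_similarity_table <- function(pwms, n_shuffles = 1000, seed = 1,
                                   min_overlap = 5, pseudocount = 0.375) {
  ids <- vapply(pwms, function(p) p$motif_id, character(1))
  pairs <- utils::combn(seq_along(pwms), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    r <- motif_similarity(pwms[[i1]], pwms[[i2]], n_shuffles,
                          derive_seed(seed, j), min_overlap, pseudocount)
    data.frame(motif_a = ids[i1], motif_b = ids[i2],
               score = r$score, p_value = r$p_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
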