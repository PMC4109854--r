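#' Position weight matrix (PWM) objects
#'
#' A PWM is stored as a positions x 4 matrix of non-negative nucleotide
#' counts in A,C,G,T column order, together with a motif identifier and a
#' free-form source tag. Count matrices from frequency sources are
#' conventionally scaled to 100 per column by the readers.
#'
#' @param motif_id single string naming the motif.
#' @param counts numeric matrix, one row per motif position, four columns
#'   (A, C, G, T). Values must be non-negative and no row may be all zero.
#' @param source_tag free-form provenance label.
#' @return An object of class `pwm`.
#' @examples
#' p <- pwm("toy", matrix(c(10, 0, 0, 0,
#'                          0, 10, 0, 0,
#'                          0, 0, 10, 0,
#'                          0, 0, 0, 10), 4, 4, byrow = TRUE))
#' pwm_consensus(p)
#' @export
pwm <- function(motif_id, counts, source_tag = "unknown") {
  counts <- as.matrix(counts)
  if (ncol(counts) != 4L)
    stop("PWM counts must have 4 columns (A,C,G,T)")
  if (nrow(counts) < 1L)
    stop("PWM must have at least one position")
  storage.mode(counts) <- "double"
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("PWM counts must be finite and non-negative")
  if (any(rowSums(counts) == 0))
    stop("PWM has a position with all-zero counts")
  colnames(counts) <- c("A", "C", "G", "T")
  rownames(counts) <- NULL
  structure(list(motif_id = as.character(motif_id), counts = counts,
                 source_tag = as.character(source_tag)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM '%s' (%d positions, source: %s)\n  consensus: %s\n",
              x$motif_id, nrow(x$counts), x$source_tag, pwm_consensus(x)))
  invisible(x)
}

#' @export
length.pwm <- function(x) nrow(x$counts)

#' Pseudocounted probability matrix of a PWM
#'
#' @param x a [pwm] object.
#' @param pseudocount additive count per matrix cell (default 0.375).
#' @return positions x 4 matrix of probabilities (rows sum to 1).
#' @export
pwm_prob <- function(x, pseudocount = 0.375) {
  m <- x$counts + pseudocount
  m / rowSums(m)
}

#' Log2 odds matrix of a PWM against a background model
#'
#' @param x a [pwm] object.
#' @param background length-4 nucleotide frequency vector (A,C,G,T),
#'   summing to 1.
#' @param pseudocount additive count per cell.
#' @return positions x 4 matrix of log2(p_motif / p_background).
#' @export
pwm_log_odds <- function(x, background = rep(0.25, 4), pseudocount = 0.375) {
  background <- check_background(background)
  log2(sweep(pwm_prob(x, pseudocount), 2, background, "/"))
}

#' Reverse complement of a PWM
#'
#' @param x a [pwm] object.
#' @return a [pwm] with positions reversed and A/T, C/G columns swapped.
#' @export
pwm_revcomp <- function(x) {
  m <- x$counts[rev(seq_len(nrow(x$counts))), c(4L, 3L, 2L, 1L), drop = FALSE]
  pwm(x$motif_id, m, x$source_tag)
}

#' Consensus string of a PWM
#' @param x a [pwm] object.
#' @return character string of per-position majority bases.
#' @export
pwm_consensus <- function(x) {
  paste(c("A", "C", "G", "T")[max.col(x$counts, ties.method = "first")],
        collapse = "")
}

#' Information content of a PWM
#'
#' Per-column information content in bits relative to a uniform
#' background, using pseudocounted probabilities.
#'
#' @param x a [pwm] object.
#' @param pseudocount additive count per cell.
#' @return numeric vector, one value per motif position.
#' @export
pwm_information <- function(x, pseudocount = 0.375) {
  p <- pwm_prob(x, pseudocount)
  2 + rowSums(p * log2(p))
}

check_background <- function(background) {
  if (length(background) != 4L || any(!is.finite(background)) ||
      any(background <= 0))
    stop("background must be 4 positive frequencies (A,C,G,T)")
  if (abs(sum(background) - 1) > 1e-6)
    stop("background frequencies must sum to 1")
  background / sum(background)
}
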