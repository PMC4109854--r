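#' Parameters for homotypic CRM scoring
#'
#' The cluster model scores a region as the best-scoring homotypic
#' cluster of motif sites it contains: the sum of per-site log2-odds
#' (pseudocounted motif probabilities over a 0-order background) plus,
#' for every within-cluster gap of g bp, `log2(p) + g*log2(1-p)` with
#' `p = 1/(1 + gap_expectation)` (geometric gap lengths), plus a
#' cluster-opening cost of `-log2(p)`. The region score is the maximum
#' over all clusters, floored at 0, so every region scores (no minimum
#' cluster-score threshold).
#'
#' @param gap_expectation expected bp between neighbouring sites of a
#'   cluster (default 35).
#' @param pseudocount additive count per PWM cell (default 0.375).
#' @param background length-4 A,C,G,T frequency vector, or `NULL`
#'   (default) to estimate the background from each scanned sequence.
#' @return list of class `crm_params`.
#' @export
crm_params <- function(gap_expectation = 35, pseudocount = 0.375,
                       background = NULL) {
  if (!is.numeric(gap_expectation) || gap_expectation <= 0)
    stop("gap_expectation must be > 0")
  if (!is.null(background)) background <- check_background(background)
  structure(list(gap_expectation = gap_expectation,
                 pseudocount = pseudocount,
                 background = background),
            class = "crm_params")
}

# Encode A,C,G,T,N -> 0..4; anything else is an error.
encode_sequence <- function(x) {
  lut <- rep(NA_integer_, 256)
  lut[utf8ToInt("A")] <- 0L; lut[utf8ToInt("a")] <- 0L
  lut[utf8ToInt("C")] <- 1L; lut[utf8ToInt("c")] <- 1L
  lut[utf8ToInt("G")] <- 2L; lut[utf8ToInt("g")] <- 2L
  lut[utf8ToInt("T")] <- 3L; lut[utf8ToInt("t")] <- 3L
  lut[utf8ToInt("N")] <- 4L; lut[utf8ToInt("n")] <- 4L
  enc <- lut[utf8ToInt(x)]
  if (anyNA(enc))
    stop("invalid alphabet: sequence contains characters outside A,C,G,T,N")
  enc
}

local_background <- function(enc) {
  cnt <- tabulate(enc[enc < 4L] + 1L, nbins = 4L) + 1  # add-one smoothing
  cnt / sum(cnt)
}

#' Score a sequence for a homotypic cluster of one motif
#'
#' Finds the maximum-scoring cluster of non-overlapping sites of `pwm`
#' (both strands) in `sequence` under the model described in
#' [crm_params()], by dynamic programming. `N` bases contribute
#' background probability (zero log-odds).
#'
#' @param sequence a single nucleotide string over A,C,G,T,N.
#' @param pwm a [pwm] object with at least 4 positions.
#' @param params a [crm_params] object.
#' @return list of class `crm_score`: `score` (log2 likelihood ratio,
#'   >= 0), `sites` (data.frame start/strand/log_odds, 0-based starts;
#'   zero rows when no positive-scoring cluster exists) and `cluster`
#'   (0-based half-open interval of the best cluster, or NULL).
#' @examples
#' p <- pwm("m", matrix(rep(c(97, 1, 1, 1), 8), ncol = 4, byrow = TRUE))
#' s <- paste(rep("ACGT", 20), collapse = "")
#' score_homotypic_crm(s, p, crm_params())$score
#' @export
score_homotypic_crm <- function(sequence, pwm, params = crm_params()) {
  stopifnot(inherits(pwm, "pwm"), inherits(params, "crm_params"))
  if (length(pwm) < 4L)
    stop("PWM too short for CRM scoring (need >= 4 positions)")
  if (!is.character(sequence) || length(sequence) != 1L)
    stop("'sequence' must be a single string")
  enc <- encode_sequence(sequence)
  w <- length(pwm)
  empty <- structure(list(score = 0,
                          sites = data.frame(start = integer(),
                                             strand = character(),
                                             log_odds = numeric()),
                          cluster = NULL),
                     class = "crm_score")
  if (length(enc) < w) return(empty)
  bg <- params$background %||% local_background(enc)
  res <- cpp_crm_score_detail(enc, pwm_prob(pwm, params$pseudocount),
                              bg, params$gap_expectation)
  if (res$score <= 0) return(empty)
  sites <- data.frame(start = res$site_start,
                      strand = ifelse(res$site_strand > 0, "+", "-"),
                      log_odds = res$site_log_odds)
  structure(list(score = res$score, sites = sites,
                 cluster = c(min(sites$start), max(sites$start) + w)),
            class = "crm_score")
}

#' @export
print.crm_score <- function(x, ...) {
  cat(sprintf("CRM score %.3f bits, %d site(s)\n", x$score, nrow(x$sites)))
  invisible(x)
}

#' Score many sequences against many PWMs
#'
#' @param sequences named character vector or `Biostrings::DNAStringSet`.
#' @param pwms list of [pwm] objects.
#' @param params a [crm_params] object.
#' @return numeric matrix, sequences x motifs, of cluster scores.
#' @export
scan_sequences <- function(sequences, pwms, params = crm_params()) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  if (methods::is(sequences, "DNAStringSet"))
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  short <- vapply(pwms, length, integer(1)) < 4L
  if (any(short)) stop("PWM(s) with fewer than 4 positions cannot be scored")
  enc <- lapply(sequences, encode_sequence)
  probs <- lapply(pwms, pwm_prob, pseudocount = params$pseudocount)
  bg <- params$background %||% numeric(0)
  m <- cpp_crm_scan(enc, probs, bg, params$gap_expectation)
  dimnames(m) <- list(names(sequences),
                      vapply(pwms, function(p) p$motif_id, character(1)))
  m
}

#' Scan a region FASTA and return a tidy score table
#'
#' Sequence names must follow the `gene_id|region|species` key
#' convention used by the synthetic generator and the region writers.
#'
#' @param fasta path to a FASTA of region sequences, or a named
#'   character vector / DNAStringSet with such keys.
#' @param pwms list of [pwm] objects.
#' @param params a [crm_params] object.
#' @return data.frame with columns motif_id, gene_id, region, species,
#'   score (one row per sequence x motif).
#' @export
scan_regions <- function(fasta, pwms, params = crm_params()) {
  seqs <- if (is.character(fasta) && length(fasta) == 1L &&
              file.exists(fasta)) {
    Biostrings::readDNAStringSet(fasta)
  } else fasta
  m <- scan_sequences(seqs, pwms, params)
  keys <- strsplit(rownames(m), "|", fixed = TRUE)
  if (any(lengths(keys) != 3L))
    stop("sequence names must be 'gene_id|region|species'")
  data.frame(
    motif_id = rep(colnames(m), each = nrow(m)),
    gene_id = rep(vapply(keys, `[`, "", 1), ncol(m)),
    region = rep(as.integer(vapply(keys, `[`, "", 2)), ncol(m)),
    species = rep(vapply(keys, `[`, "", 3), ncol(m)),
    score = as.vector(m),
    stringsAsFactors = FALSE)
}
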