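#' Read a plain gene list
#'
#' One gene id per line; blank lines and `#` comments ignored.
#'
#' @param path file path.
#' @return character vector of gene ids.
#' @export
read_gene_set <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x) & !startsWith(x, "#")])
}

#' Read / write gene sets in GMT format
#'
#' GMT: one set per line, tab-separated `name`, `description`, then the
#' member gene ids.
#'
#' @param path file path.
#' @return named list of character vectors (reader); `path` invisibly
#'   (writer).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  f <- strsplit(lines, "\t")
  if (any(lengths(f) < 3L)) stop("malformed GMT line (need >= 3 fields)")
  stats::setNames(lapply(f, function(v) unique(v[-(1:2)])),
                  vapply(f, `[`, "", 1))
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param descriptions optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read ChIP peaks from a BED or narrowPeak file
#'
#' Reads at least chrom/start/end; `signalValue` is taken from column 7
#' (narrowPeak and the BED6+signal layout used here) when present,
#' otherwise from the score column 5, otherwise set to 1. Malformed
#' lines (fewer than 3 fields or non-numeric coordinates) are skipped
#' with a warning reporting their count.
#'
#' @param path file path.
#' @return data.frame with columns chrom, start, end, signalValue
#'   (0-based half-open coordinates).
#' @export
read_bed_peaks <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#") &
                   !startsWith(lines, "track") &
                   !startsWith(lines, "browser")]
  f <- strsplit(lines, "\t")
  ok <- lengths(f) >= 3L
  if (any(ok)) {
    st <- suppressWarnings(as.numeric(vapply(f[ok], `[`, "", 2)))
    en <- suppressWarnings(as.numeric(vapply(f[ok], `[`, "", 3)))
    ok[ok] <- !is.na(st) & !is.na(en) & st < en
  }
  n_bad <- sum(!ok)
  if (n_bad) warning("skipped ", n_bad, " malformed BED line(s)")
  f <- f[ok]
  if (!length(f))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), signalValue = numeric()))
  sv <- vapply(f, function(v) {
    raw <- if (length(v) >= 7L) v[7] else if (length(v) >= 5L) v[5] else "1"
    val <- suppressWarnings(as.numeric(raw))
    if (is.na(val)) 1 else val
  }, numeric(1))
  data.frame(chrom = vapply(f, `[`, "", 1),
             start = as.integer(as.numeric(vapply(f, `[`, "", 2))),
             end = as.integer(as.numeric(vapply(f, `[`, "", 3))),
             signalValue = sv, stringsAsFactors = FALSE)
}

#' Write a score table (motif_id, gene_id, region, species, score)
#' @param scores data.frame from [scan_regions()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_scores_tsv <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_scores_tsv
#' @export
read_scores_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
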