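#' Read PWMs in Cluster-Buster count-matrix format
#'
#' The format is a series of records, each a `>motif_id` header followed
#' by one line per motif position holding four whitespace-separated
#' counts in A,C,G,T order.
#'
#' @param path file path.
#' @param source_tag provenance label stored on each PWM.
#' @return named list of [pwm] objects.
#' @export
read_pwms_clusterbuster <- function(path, source_tag = "clusterbuster") {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines) || !startsWith(lines[1], ">"))
    stop("not a Cluster-Buster PWM file: ", path)
  idx <- cumsum(startsWith(lines, ">"))
  recs <- split(lines, idx)
  out <- lapply(recs, function(rec) {
    id <- sub("^>\\s*", "", rec[1])
    id <- strsplit(id, "\\s+")[[1]][1]
    if (length(rec) < 2L) stop("PWM '", id, "' has no count rows")
    rows <- lapply(rec[-1], function(l) as.numeric(strsplit(l, "\\s+")[[1]]))
    if (any(lengths(rows) != 4L))
      stop("PWM '", id, "': every row needs exactly 4 counts")
    pwm(id, do.call(rbind, rows), source_tag)
  })
  names(out) <- vapply(out, function(p) p$motif_id, character(1))
  out
}

#' Read PWMs in JASPAR format
#'
#' Accepts the bracketed JASPAR layout (`>id name` then four rows like
#' `A [ 1 2 3 ]`) and the plain 4-row variant without base labels. Rows
#' are A, C, G, T; the matrix is transposed to positions x 4.
#'
#' @inheritParams read_pwms_clusterbuster
#' @return named list of [pwm] objects.
#' @export
read_pwms_jaspar <- function(path, source_tag = "jaspar") {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (!length(lines) || !startsWith(lines[1], ">"))
    stop("not a JASPAR PWM file: ", path)
  idx <- cumsum(startsWith(lines, ">"))
  recs <- split(lines, idx)
  out <- lapply(recs, function(rec) {
    id <- strsplit(sub("^>\\s*", "", rec[1]), "\\s+")[[1]][1]
    body <- rec[-1]
    if (length(body) != 4L)
      stop("JASPAR PWM '", id, "' must have 4 base rows")
    rows <- lapply(body, function(l) {
      l <- sub("^[ACGTacgt]\\s*", "", l)
      l <- gsub("\\[|\\]", " ", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    if (length(unique(lengths(rows))) != 1L)
      stop("JASPAR PWM '", id, "': ragged rows")
    pwm(id, t(do.call(rbind, rows)), source_tag)
  })
  names(out) <- vapply(out, function(p) p$motif_id, character(1))
  out
}

#' Read PWMs in TRANSFAC-like format
#'
#' Parses blocks delimited by `//`, taking the identifier from the `ID`
#' (or `AC`) line and count rows from numbered lines (`01 5 0 3 2 R`),
#' with counts in A,C,G,T order followed by an optional consensus letter.
#'
#' @inheritParams read_pwms_clusterbuster
#' @return named list of [pwm] objects.
#' @export
read_pwms_transfac <- function(path, source_tag = "transfac") {
  lines <- trimws(readLines(path, warn = FALSE))
  blocks <- split(lines, cumsum(lines == "//"))
  out <- list()
  for (blk in blocks) {
    blk <- blk[nzchar(blk) & blk != "//"]
    if (!length(blk)) next
    idl <- grep("^(ID|AC)\\s+", blk, value = TRUE)
    if (!length(idl)) next
    id <- strsplit(idl[1], "\\s+")[[1]][2]
    rowl <- grep("^[0-9]+\\s+", blk, value = TRUE)
    if (!length(rowl)) next
    rows <- lapply(rowl, function(l) {
      f <- strsplit(l, "\\s+")[[1]]
      as.numeric(f[2:5])
    })
    out[[id]] <- pwm(id, do.call(rbind, rows), source_tag)
  }
  if (!length(out)) stop("no TRANSFAC matrices found in ", path)
  out
}

#' Write PWMs in Cluster-Buster format
#'
#' @param pwms list of [pwm] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pwms <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", p$motif_id), con)
    utils::write.table(format(p$counts, trim = TRUE), con,
                       quote = FALSE, sep = "\t",
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
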