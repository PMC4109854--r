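#' Regulatory search-space modes
#'
#' Three predefined windows around each transcription start site (TSS):
#' `up500` is the 500 bp immediately upstream of the TSS, `tss10kb` is
#' 10 kb centred on the TSS (TSS +/- 5 kb) and `tss20kb` is 20 kb centred
#' on the TSS (TSS +/- 10 kb). All coordinates in this package are
#' 0-based half-open (BED convention); each window has exactly the
#' stated length.
#'
#' @return character vector of the mode names.
#' @export
search_space_modes <- function() c("up500", "tss10kb", "tss20kb")

# Window for one TSS (0-based half-open). Only up500 is strand-dependent.
tss_window <- function(tss, strand, mode) {
  switch(mode,
    up500   = if (strand == "-") c(tss + 1, tss + 501) else c(tss - 500, tss),
    tss10kb = c(tss - 5000, tss + 5000),
    tss20kb = c(tss - 10000, tss + 10000),
    stop("unknown search-space mode: ", mode))
}

#' Build a gene annotation table
#'
#' Constructs the annotation data.frame used throughout the package. One
#' row per gene; `tss` may list several transcription start sites
#' (comma-separated) and `cds_exons` lists coding exon intervals as
#' comma-separated `start-end` pairs, all 0-based half-open.
#'
#' @param gene_id,chrom,strand,tx_start,tx_end vectors, one entry per gene.
#' @param tss character vector of comma-separated TSS positions.
#' @param cds_exons character vector of comma-separated `start-end`
#'   intervals ("" for none).
#' @return data.frame with the seven annotation columns.
#' @export
gene_annotation <- function(gene_id, chrom, strand, tx_start, tx_end,
                            tss, cds_exons = "") {
  df <- data.frame(gene_id = as.character(gene_id),
                   chrom = as.character(chrom),
                   strand = as.character(strand),
                   tx_start = as.integer(tx_start),
                   tx_end = as.integer(tx_end),
                   tss = as.character(tss),
                   cds_exons = as.character(cds_exons),
                   stringsAsFactors = FALSE)
  validate_annotation(df)
}

validate_annotation <- function(df) {
  need <- c("gene_id", "chrom", "strand", "tx_start", "tx_end", "tss",
            "cds_exons")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("annotation table is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id in annotation table")
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (any(df$tx_start >= df$tx_end))
    stop("tx_start must be < tx_end (0-based half-open)")
  tss <- parse_int_list(df$tss)
  if (any(lengths(tss) == 0))
    stop("every gene needs at least one TSS")
  df
}

parse_int_list <- function(x) {
  lapply(strsplit(as.character(x), ","), function(v) {
    v <- trimws(v[nzchar(trimws(v))])
    as.integer(v)
  })
}

parse_exon_list <- function(x) {
  lapply(strsplit(as.character(x), ","), function(v) {
    v <- trimws(v[nzchar(trimws(v))])
    if (!length(v)) return(matrix(integer(), 0, 2))
    parts <- strsplit(v, "-")
    if (any(lengths(parts) != 2))
      stop("malformed cds_exons entry; expected start-end pairs")
    m <- matrix(as.integer(unlist(parts)), ncol = 2, byrow = TRUE)
    if (any(m[, 1] >= m[, 2])) stop("exon with start >= end")
    m
  })
}

#' Read a gene annotation table from TSV
#'
#' @param path tab-separated file with header columns gene_id, chrom,
#'   strand, tx_start, tx_end, tss, cds_exons.
#' @return validated annotation data.frame.
#' @export
read_gene_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  df$tx_start <- as.integer(df$tx_start)
  df$tx_end <- as.integer(df$tx_end)
  if (!"cds_exons" %in% names(df)) df$cds_exons <- ""
  df$cds_exons[is.na(df$cds_exons)] <- ""
  validate_annotation(df)
}

#' Write a gene annotation table to TSV
#' @param annotation annotation data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read gene models from a minimal GFF3 file
#'
#' Supports `gene` features (ID attribute), `mRNA`/`transcript` children
#' (Parent attribute; their strand-aware 5' ends become TSSs) and `CDS`
#' children (coding exons, attached to the gene through their transcript
#' Parent). Genes without transcript children get a single TSS at their
#' own 5' end. GFF3 1-based closed coordinates are converted to 0-based
#' half-open. A CDS or transcript on a different chromosome than its
#' gene is rejected.
#'
#' @param path GFF3 file path.
#' @return annotation data.frame as from [gene_annotation()].
#' @export
read_gff3_genes <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  f <- strsplit(lines, "\t")
  if (any(lengths(f) < 9)) stop("malformed GFF3 line(s)")
  gff <- data.frame(chrom = vapply(f, `[`, "", 1),
                    type = vapply(f, `[`, "", 3),
                    start = as.integer(vapply(f, `[`, "", 4)),
                    end = as.integer(vapply(f, `[`, "", 5)),
                    strand = vapply(f, `[`, "", 7),
                    attrs = vapply(f, `[`, "", 9),
                    stringsAsFactors = FALSE)
  attr_val <- function(attrs, key) {
    ifelse(grepl(paste0("(^|;)", key, "="), attrs),
           sub(paste0(".*(^|;)", key, "=([^;]+).*"), "\\2", attrs),
           NA_character_)
  }
  gff$id <- attr_val(gff$attrs, "ID")
  gff$parent <- attr_val(gff$attrs, "Parent")

  genes <- gff[gff$type == "gene", ]
  if (!nrow(genes)) stop("no gene features in GFF3")
  tx <- gff[gff$type %in% c("mRNA", "transcript"), ]
  cds <- gff[gff$type == "CDS", ]
  tx2gene <- stats::setNames(tx$parent, tx$id)

  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    gtx <- tx[!is.na(tx$parent) & tx$parent == g$id, ]
    if (nrow(gtx) && any(gtx$chrom != g$chrom))
      stop("transcript of gene ", g$id, " on a different chromosome")
    tss <- if (nrow(gtx)) {
      ifelse(gtx$strand == "-", gtx$end - 1L, gtx$start - 1L)
    } else {
      if (g$strand == "-") g$end - 1L else g$start - 1L
    }
    gcds <- cds[!is.na(cds$parent) &
                  (cds$parent == g$id | tx2gene[cds$parent] %in% g$id), ]
    if (nrow(gcds) && any(gcds$chrom != g$chrom))
      stop("CDS of gene ", g$id, " on a different chromosome")
    ex <- if (nrow(gcds))
      paste(sprintf("%d-%d", gcds$start - 1L, gcds$end), collapse = ",")
    else ""
    data.frame(gene_id = g$id, chrom = g$chrom, strand = g$strand,
               tx_start = g$start - 1L, tx_end = g$end,
               tss = paste(sort(unique(tss)), collapse = ","),
               cds_exons = ex, stringsAsFactors = FALSE)
  })
  validate_annotation(do.call(rbind, rows))
}

#' Delineate the regulatory search space of every gene
#'
#' For each gene, a candidate window is laid around every TSS according
#' to `mode`; overlapping windows of alternative TSSs are merged; the
#' merged windows are truncated wherever another gene's span
#' (tx_start..tx_end) intrudes; and the coding exons of all genes are
#' subtracted, which may split a window into several regions. Fragments
#' shorter than `min_region_length` are dropped, so a gene may end up
#' with no region at all. Windows reaching below coordinate 0 are
#' clipped with a warning.
#'
#' @param annotation annotation data.frame (see [gene_annotation()]).
#' @param mode one of [search_space_modes()].
#' @param min_region_length drop regions shorter than this many bp.
#' @return data.frame with columns gene_id, chrom, start, end, region
#'   (1-based index within gene); 0-based half-open coordinates.
#' @export
delineate_search_space <- function(annotation, mode = "tss20kb",
                                   min_region_length = 10) {
  mode <- match.arg(mode, search_space_modes())
  annotation <- validate_annotation(annotation)
  tss_list <- parse_int_list(annotation$tss)
  exon_list <- parse_exon_list(annotation$cds_exons)
  chroms <- unique(annotation$chrom)

  # Per-chromosome obstacle ranges: gene spans and all coding exons.
  spans <- GenomicRanges::GRanges(
    factor(annotation$chrom, levels = chroms),
    IRanges::IRanges(start = annotation$tx_start + 1L,
                     end = annotation$tx_end))
  names(spans) <- annotation$gene_id
  nex <- vapply(exon_list, nrow, integer(1))
  exons <- if (sum(nex)) {
    em <- do.call(rbind, exon_list)
    GenomicRanges::GRanges(
      factor(rep(annotation$chrom, nex), levels = chroms),
      IRanges::IRanges(start = em[, 1] + 1L, end = em[, 2]))
  } else GenomicRanges::GRanges(factor(character(), levels = chroms),
                                IRanges::IRanges())

  clipped <- FALSE
  out <- vector("list", nrow(annotation))
  for (i in seq_len(nrow(annotation))) {
    win <- vapply(tss_list[[i]],
                  function(t) tss_window(t, annotation$strand[i], mode),
                  numeric(2))
    s0 <- win[1, ]; e0 <- win[2, ]
    if (any(s0 < 0)) { clipped <- TRUE; s0 <- pmax(s0, 0) }
    keep <- e0 > s0
    if (!any(keep)) { out[[i]] <- NULL; next }
    wgr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      factor(rep(annotation$chrom[i], sum(keep)), levels = chroms),
      IRanges::IRanges(start = s0[keep] + 1L, end = e0[keep])))
    obstacles <- c(spans[-i], exons)
    regions <- GenomicRanges::setdiff(wgr, obstacles)
    regions <- regions[IRanges::width(regions) >= min_region_length]
    if (!length(regions)) { out[[i]] <- NULL; next }
    out[[i]] <- data.frame(
      gene_id = annotation$gene_id[i],
      chrom = annotation$chrom[i],
      start = GenomicRanges::start(regions) - 1L,
      end = GenomicRanges::end(regions),
      region = seq_along(regions),
      stringsAsFactors = FALSE)
  }
  if (clipped)
    warning("windows extending below coordinate 0 were clipped")
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      region = integer(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Write search-space regions as 6-column BED
#'
#' The name column is `gene_id|region`; score 0, strand ".".
#'
#' @param regions region data.frame from [delineate_search_space()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(regions$chrom, regions$start, regions$end,
                    paste0(regions$gene_id, "|", regions$region),
                    0L, ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
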