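test_that("isolated gene in up500 mode gets the plain upstream window", {
  ann <- gene_annotation("g1", "chr1", "+", 10000, 12000, "10000")
  reg <- delineate_search_space(ann, "up500")
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$start, 9500)
  expect_equal(reg$end, 10000)
})

test_that("upstream window is cut where a neighboring gene lies", {
  ann <- gene_annotation(c("g1", "g2"), "chr1", c("+", "+"),
                         c(10000, 9000), c(12000, 9800),
                         c("10000", "9000"))
  reg <- delineate_search_space(ann, "up500")
  r1 <- reg[reg$gene_id == "g1", ]
  expect_equal(r1$start, 9800)  # neighbor span [9000,9800) truncates
  expect_equal(r1$end, 10000)
})

test_that("windows of nearby alternative TSSs merge into one region", {
  ann <- gene_annotation("g1", "chr1", "+", 50000, 60000, "50000,52000")
  reg <- delineate_search_space(ann, "tss10kb")
  expect_equal(nrow(reg), 1L)        # overlapping windows merged
  expect_equal(reg$start, 45000)
  expect_equal(reg$end, 57000)       # 52000 + 5000
})

test_that("coding exons are excluded and can split a window", {
  ann <- gene_annotation(c("g1", "g2"), "chr1", c("+", "+"),
                         c(10000, 100000), c(12000, 101000),
                         c("10000", "100500"),
                         cds_exons = c("9600-9700", ""))  # exon inside g1's
  reg <- delineate_search_space(ann, "up500")
  r1 <- reg[reg$gene_id == "g1", ]
  expect_equal(nrow(r1), 2L)
  expect_equal(r1$start, c(9500, 9700))
  expect_equal(r1$end, c(9600, 10000))
})

test_that("minus-strand up500 windows lie downstream in coordinates", {
  ann <- gene_annotation("g1", "chr1", "-", 8000, 10000, "9999")
  reg <- delineate_search_space(ann, "up500")
  expect_equal(reg$end - reg$start, 500)
  expect_true(reg$start >= 9999)
})

test_that("regions are disjoint, exon-free and bounded (property)", {
  set.seed(21)
  for (rep in 1:5) {
    n <- 12
    starts <- sort(sample.int(3e5, n))
    ann <- gene_annotation(
      gene_id = sprintf("g%02d", 1:n), chrom = "chr1",
      strand = sample(c("+", "-"), n, replace = TRUE),
      tx_start = starts, tx_end = starts + sample(500:5000, n),
      tss = as.character(starts),
      cds_exons = sprintf("%d-%d", starts + 10, starts + 200))
    for (mode in search_space_modes()) {
      reg <- suppressWarnings(delineate_search_space(ann, mode))
      wlen <- c(up500 = 500, tss10kb = 10000, tss20kb = 20000)[[mode]]
      for (g in unique(reg$gene_id)) {
        rg <- reg[reg$gene_id == g, ]
        # pairwise disjoint per gene
        if (nrow(rg) > 1) {
          o <- order(rg$start)
          expect_true(all(rg$start[o][-1] >= rg$end[o][-nrow(rg)]))
        }
        # total length bounded by window length x number of TSSs
        expect_lte(sum(rg$end - rg$start), wlen)
      }
      # no region intersects any coding exon or another gene's span
      if (nrow(reg)) {
        ex <- do.call(rbind, Map(function(e, id) cbind(e, id),
                                 rankrecover:::parse_exon_list(ann$cds_exons),
                                 seq_len(n)))
        for (i in seq_len(nrow(reg))) {
          expect_false(any(reg$start[i] < ex[, 2] & reg$end[i] > ex[, 1]))
          other <- ann$gene_id != reg$gene_id[i]
          expect_false(any(reg$start[i] < ann$tx_end[other] &
                             reg$end[i] > ann$tx_start[other]))
        }
      }
    }
  }
})

test_that("delineation is idempotent on its own output", {
  # isolated genes whose windows survive untruncated: treating each
  # resulting region as a gene and delineating again reproduces it
  ann <- gene_annotation(c("gA", "gC"), "chr1", c("+", "-"),
                         c(10000, 40000), c(12000, 42000),
                         c("10000", "41999"))
  reg1 <- delineate_search_space(ann, "up500")
  ann2 <- gene_annotation(
    gene_id = paste0(reg1$gene_id, "_", reg1$region),
    chrom = reg1$chrom, strand = "+",
    tx_start = reg1$start, tx_end = reg1$end,
    tss = as.character(reg1$end))
  reg2 <- delineate_search_space(ann2, "up500")
  reg2 <- reg2[order(reg2$start), ]
  reg1 <- reg1[order(reg1$start), ]
  expect_equal(reg2$start, reg1$start)
  expect_equal(reg2$end, reg1$end)
})

test_that("windows below zero are clipped with a warning", {
  ann <- gene_annotation("g1", "chr1", "+", 100, 900, "100")
  expect_warning(reg <- delineate_search_space(ann, "up500"), "clipped")
  expect_equal(reg$start, 0)
  expect_equal(reg$end, 100)
  ann2 <- gene_annotation("g2", "chr1", "+", 3, 900, "3")
  expect_warning(reg2 <- delineate_search_space(ann2, "up500"), "clipped")
  expect_equal(nrow(reg2), 0L)  # 3 bp fragment dropped (< 10 bp minimum)
})

test_that("GFF3 reader builds gene models with TSSs and coding exons", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1001\t3000\t.\t+\t.\tID=geneX",
    "chr1\tsrc\tmRNA\t1001\t3000\t.\t+\t.\tID=txX1;Parent=geneX",
    "chr1\tsrc\tmRNA\t1501\t3000\t.\t+\t.\tID=txX2;Parent=geneX",
    "chr1\tsrc\tCDS\t1801\t2100\t.\t+\t0\tID=cdsX;Parent=txX1",
    "chr2\tsrc\tgene\t501\t900\t.\t-\t.\tID=geneY"), gff)
  ann <- read_gff3_genes(gff)
  gx <- ann[ann$gene_id == "geneX", ]
  expect_equal(gx$tss, "1000,1500")        # 0-based
  expect_equal(gx$cds_exons, "1800-2100")
  gy <- ann[ann$gene_id == "geneY", ]
  expect_equal(gy$tss, "899")              # minus strand: 5' end = end
  # chromosome mismatch between CDS and gene is rejected
  writeLines(c(
    "chr1\tsrc\tgene\t1001\t3000\t.\t+\t.\tID=geneZ",
    "chr1\tsrc\tmRNA\t1001\t3000\t.\t+\t.\tID=txZ;Parent=geneZ",
    "chr2\tsrc\tCDS\t1801\t2100\t.\t+\t0\tID=cdsZ;Parent=txZ"), gff)
  expect_error(read_gff3_genes(gff), "different chromosome")
})

test_that("annotation TSV round-trips", {
  ann <- toy_annotation()
  tmp <- tempfile(fileext = ".tsv")
  write_gene_annotation(ann, tmp)
  expect_equal(read_gene_annotation(tmp), ann)
})
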