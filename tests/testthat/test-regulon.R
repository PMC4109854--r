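fake_enrichment <- function(features, collections, nes, targets_list) {
  df <- data.frame(collection = collections, feature_id = features,
                   AUC = nes / 10, NES = nes,
                   leading_edge_rank = 10L,
                   n_targets = vapply(targets_list, nrow, integer(1)),
                   targets = vapply(targets_list, function(t)
                     paste(t$gene_id, collapse = ","), character(1)),
                   stringsAsFactors = FALSE)
  attr(df, "targets_list") <-
    stats::setNames(targets_list, paste(collections, features, sep = ":"))
  class(df) <- c("enrichment_result", class(df))
  df
}

tgt <- function(...) {
  g <- c(...)
  data.frame(gene_id = g, rank = seq_along(g), stringsAsFactors = FALSE)
}

cand <- function(tf) data.frame(tf_id = tf, tier = "direct", path = "p",
                                path_length = 1L, identity_pct = NA_real_,
                                similarity_p = NA_real_,
                                rank = seq_along(tf),
                                stringsAsFactors = FALSE)

test_that("two motifs of one TF merge with per-target support counts", {
  enr <- fake_enrichment(c("m1", "m2"), c("motifs", "motifs"), c(5, 4),
                         list(tgt("a", "b"), tgt("b", "c")))
  regs <- assemble_regulons(enr, list(m1 = cand("TFX"), m2 = cand("TFX")))
  expect_length(regs, 1L)
  r <- regs[[1]]
  expect_equal(r$tf_id, "TFX")
  expect_equal(r$targets[c("a", "b", "c")], c(a = 1L, b = 2L, c = 1L))
  expect_equal(r$best_NES, 5)
  expect_equal(nrow(r$features), 2L)
  # evidence conservation: total counts == total target-list lengths
  expect_equal(sum(r$targets), 2L + 2L)
})

test_that("single motif, single TF gives unit counts; orphans are kept", {
  enr <- fake_enrichment(c("m1", "m_orphan"), c("motifs", "motifs"),
                         c(6, 3.5), list(tgt("a", "b", "c"), tgt("d")))
  regs <- assemble_regulons(enr, list(m1 = cand("TFY")))
  expect_length(regs, 2L)
  expect_equal(regs[[1]]$tf_id, "TFY")
  expect_equal(unname(regs[[1]]$targets), c(1L, 1L, 1L))
  orphan <- regs[[2]]
  expect_true(is.na(orphan$tf_id))        # enriched but unidentified TF
  expect_equal(names(orphan$targets), "d")
  empty_enr <- fake_enrichment("m1", "motifs", 1, list(tgt("a")))[0, ]
  expect_length(assemble_regulons(empty_enr, list()), 0L)
})

test_that("meta-regulon counts recurrence across gene sets", {
  mk_regset <- function(tf, genes) {
    structure(list(list(tf_id = tf,
                        targets = stats::setNames(rep(1L, length(genes)),
                                                  genes),
                        features = data.frame(feature_id = "m",
                                              collection = "motifs",
                                              NES = 4),
                        best_NES = 4)), class = "regulon_set")
  }
  batch <- list(mk_regset("TFZ", c("g1", "g2")),
                mk_regset("TFZ", c("g2", "g3")),
                mk_regset("TFZ", c("g2")),
                mk_regset("other", c("g1")),
                structure(list(), class = "regulon_set"))
  meta <- aggregate_meta_regulon(batch, "TFZ")
  expect_equal(meta$n_gene_sets, 3L)
  expect_equal(meta$recurrence[["g2"]], 3L)
  expect_equal(meta$recurrence[["g1"]], 1L)
  filtered <- aggregate_meta_regulon(batch, "TFZ", min_count = 3)
  expect_equal(names(filtered$recurrence), "g2")
  # order of the batch does not matter
  meta_rev <- aggregate_meta_regulon(rev(batch), "TFZ")
  expect_equal(meta_rev$recurrence[names(meta$recurrence)],
               meta$recurrence)
  empty <- aggregate_meta_regulon(batch, "TF_absent")
  expect_length(empty$recurrence, 0L)
})

test_that("recurrence equals a naive recount over stored target lists", {
  set.seed(66)
  genes <- sprintf("g%02d", 1:30)
  batch <- lapply(1:8, function(i) {
    tgts <- sample(genes, sample(3:10, 1))
    structure(list(list(tf_id = "TF1",
                        targets = stats::setNames(rep(1L, length(tgts)),
                                                  tgts),
                        features = data.frame(feature_id = "m",
                                              collection = "motifs",
                                              NES = 3.5),
                        best_NES = 3.5)), class = "regulon_set")
  })
  meta <- aggregate_meta_regulon(batch, "TF1")
  naive <- table(unlist(lapply(batch, function(rs) names(rs[[1]]$targets))))
  for (g in names(meta$recurrence))
    expect_equal(meta$recurrence[[g]], unname(naive[g])[[1]])
})

test_that("hypergeometric leading-edge test matches exact tail sums", {
  universe <- sprintf("g%03d", 1:100)
  # set = the top s genes: maximal enrichment
  rk <- stats::setNames(1:100, universe)
  res <- rank_set_enrichment_test(rk, universe[1:10])
  expect_equal(res$leading_edge_rank, 10L)
  expect_equal(res$overlap, 10L)
  expect_equal(res$p_value, 1 / choose(100, 10), tolerance = 1e-9)
  # members at ranks 1-5 and 51-55
  gs <- universe[c(1:5, 51:55)]
  res2 <- rank_set_enrichment_test(rk, gs)
  expect_equal(res2$leading_edge_rank, 5L)
  expect_equal(res2$overlap, 5L)
  expect_equal(res2$p_value, oracle_hyper_tail(5, 10, 100, 5),
               tolerance = 1e-12)
  expect_error(rank_set_enrichment_test(rk, character(0)), "no usable")
  expect_error(rank_set_enrichment_test(c(a = 1, b = 3), "a"),
               "permutation")
})

test_that("hypergeometric tail equals combinatorial summation (random)", {
  set.seed(12)
  universe <- sprintf("g%03d", 1:150)
  for (i in 1:25) {
    rk <- stats::setNames(sample.int(150), universe)
    gs <- sample(universe, sample(5:20, 1))
    res <- rank_set_enrichment_test(rk, gs)
    expect_equal(res$p_value,
                 oracle_hyper_tail(res$overlap, length(gs), 150,
                                   res$leading_edge_rank),
                 tolerance = 1e-12)
  }
})

test_that("regulon TSV and SIF writers emit the merged targets", {
  enr <- fake_enrichment("m1", "motifs", 4, list(tgt("a", "b")))
  regs <- assemble_regulons(enr, list(m1 = cand("TFW")))
  tsv <- tempfile(); sif <- tempfile()
  write_regulons(regs, tsv, sif)
  tab <- utils::read.delim(tsv)
  expect_equal(tab$target, c("a", "b"))
  expect_equal(readLines(sif),
               c("TFW\tregulates\ta", "TFW\tregulates\tb"))
})
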