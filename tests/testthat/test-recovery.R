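ranking_from_order <- function(ids_in_rank_order) {
  stats::setNames(seq_along(ids_in_rank_order), ids_in_rank_order)
}

test_that("recovery AUC matches hand-computed cases", {
  universe <- sprintf("g%03d", 1:100)
  rk <- ranking_from_order(universe)
  pars <- recovery_params(top_fraction = 0.10)  # T = 10
  # set entirely outside the top
  expect_equal(compute_recovery_auc(rk, c("g050", "g099"), pars), 0)
  # two genes at ranks 1 and 2: sum c(k) = 1 + 2*9 = 19; 19 / (10*2)
  expect_equal(compute_recovery_auc(rk, c("g001", "g002"), pars), 0.95)
  expect_error(compute_recovery_auc(rk, character(0)), "no usable")
  expect_warning(compute_recovery_auc(rk, c("g001", "nope"), pars),
                 "dropped")
})

test_that("AUC equals the naive cumulative-curve oracle (random cases)", {
  set.seed(14)
  universe <- sprintf("g%04d", 1:1000)
  for (i in 1:30) {
    rk <- ranking_from_order(sample(universe))
    gs <- sample(universe, 20)
    expect_equal(compute_recovery_auc(rk, gs),
                 oracle_recovery_auc(rk, gs), tolerance = 1e-12)
  }
})

test_that("promoting a member to a better rank never lowers the AUC", {
  set.seed(26)
  universe <- sprintf("g%04d", 1:500)
  rk <- ranking_from_order(sample(universe))
  gs <- sample(universe, 15)
  base <- compute_recovery_auc(rk, gs)
  g <- gs[which.max(rk[gs])]
  # swap the worst-ranked member up to rank 1
  top_gene <- names(rk)[rk == 1]
  rk2 <- rk
  rk2[top_gene] <- rk[g]
  rk2[g] <- 1L
  expect_gte(compute_recovery_auc(rk2, gs), base)
})

test_that("NES is an exact z-score within a collection", {
  expect_equal(unname(normalize_nes(c(a = 0.1, b = 0.2, c = 0.3))),
               c(-1, 0, 1))
  expect_warning(z <- normalize_nes(c(a = 0.2, b = 0.2, c = 0.2)),
                 "degenerate")
  expect_equal(unname(z), c(0, 0, 0))
  expect_error(normalize_nes(c(a = 1, b = 2)), "at least 3")
  set.seed(8)
  x <- stats::setNames(runif(50), paste0("f", 1:50))
  z <- normalize_nes(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(stats::sd(z), 1, tolerance = 1e-12)
})

test_that("leading edge lands where signal beats the collection envelope", {
  universe <- sprintf("g%03d", 1:600)
  set.seed(33)
  gs <- c("s1", "s2", "s3", "s4")
  universe <- c(gs, universe)
  # candidate feature: members at ranks 1,2,3 and 500
  order1 <- c("s1", "s2", "s3",
              setdiff(universe, gs)[1:496], "s4",
              setdiff(universe, gs)[-(1:496)])
  # background features: members scattered deep (flat background); a
  # sizeable collection keeps the candidate from inflating the envelope
  mk_flat <- function(seed) {
    set.seed(seed)
    c(sample(setdiff(universe, gs)), sample(gs))
  }
  flats <- lapply(101:112, function(s) ranking_from_order(mk_flat(s)))
  names(flats) <- paste0("b", 1:12)
  cols <- c(list(candidate = ranking_from_order(order1)), flats)
  db <- ranking_db_from_columns(cols, "motifs")
  le <- select_targets_leading_edge("candidate", db, gs,
                                    recovery_params(rank_threshold = 400))
  expect_equal(le$leading_edge_rank, 3L)
  expect_equal(le$targets$gene_id, c("s1", "s2", "s3"))
  expect_equal(le$targets$rank, 1:3)

  # a feature with members at the very bottom yields no targets
  worst <- ranking_from_order(c(setdiff(universe, gs), gs))
  db2 <- ranking_db_from_columns(c(cols[2:4], list(worst = worst)), "motifs")
  le2 <- select_targets_leading_edge("worst", db2, gs)
  expect_equal(le2$leading_edge_rank, 0L)
  expect_equal(nrow(le2$targets), 0L)
  expect_error(select_targets_leading_edge(
    "candidate", ranking_db_from_columns(cols[1:2], "motifs"), gs),
    ">= 3 features")
})

test_that("collections are normalized separately but share AUC math", {
  set.seed(44)
  universe <- sprintf("g%03d", 1:200)
  cols <- lapply(1:5, function(i) ranking_from_order(sample(universe)))
  names(cols) <- paste0("f", 1:5)
  mdb <- ranking_db_from_columns(cols, "motifs")
  tdb <- ranking_db_from_columns(cols, "tracks")
  gs <- sample(universe, 10)
  res <- run_enrichment(list(mdb, tdb), gs,
                        recovery_params(nes_threshold = -Inf))
  sco <- attr(res, "scores")
  m <- sco[sco$collection == "motifs", ]
  t_ <- sco[sco$collection == "tracks", ]
  expect_equal(m$AUC, t_$AUC)   # identical rank columns -> identical AUCs
  expect_equal(m$NES, t_$NES)   # ... normalized within each collection
  expect_equal(sum(m$NES), 0, tolerance = 1e-9)
  expect_equal(stats::sd(m$NES), 1, tolerance = 1e-9)
})

test_that("recovery-curve export is consistent with the AUC machinery", {
  set.seed(91)
  universe <- sprintf("g%03d", 1:100)
  cols <- lapply(1:4, function(i) ranking_from_order(sample(universe)))
  names(cols) <- paste0("f", 1:4)
  db <- ranking_db_from_columns(cols, "motifs")
  gs <- sample(universe, 8)
  tab <- recovery_curve_table(db, gs, "f1",
                              recovery_params(rank_threshold = 50))
  expect_equal(nrow(tab), 50L)
  expect_true(all(diff(tab$recovery) >= 0))   # cumulative
  expect_equal(tab$recovery[50], sum(cols$f1[gs] <= 50) / 8)
  # a duplicated input id must not double-count
  expect_equal(compute_recovery_auc(cols$f1, c(gs, gs[1])),
               compute_recovery_auc(cols$f1, gs))
})

test_that("enrichment on mismatched universes is refused", {
  set.seed(3)
  u1 <- sprintf("a%02d", 1:50)
  u2 <- sprintf("b%02d", 1:50)
  mk <- function(u) ranking_db_from_columns(
    stats::setNames(lapply(1:3, function(i)
      stats::setNames(sample.int(50), u)), paste0("f", 1:3)), "motifs")
  expect_error(run_enrichment(list(mk(u1), mk(u2)), u1[1:5]),
               "different universes")
})
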