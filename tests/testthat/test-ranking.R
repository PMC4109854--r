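test_that("order-statistic q-value matches closed forms", {
  expect_equal(orderstat_q(0.25), 0.25)
  expect_equal(orderstat_q(c(1, 1, 1)), 1)
  expect_equal(orderstat_q(c(0.1, 0.5)), 2 * 0.1 * 0.5 - 0.1^2)
  expect_equal(orderstat_q(c(0.5, 0.1)), orderstat_q(c(0.1, 0.5)))  # sorts
  set.seed(3)
  for (i in 1:20) {                      # K = 2 closed form, random ratios
    r <- sort(runif(2))
    expect_equal(orderstat_q(r), 2 * r[1] * r[2] - r[1]^2,
                 tolerance = 1e-12)
  }
  expect_error(orderstat_q(numeric(0)), "at least one")
  expect_error(orderstat_q(c(0.5, 1.2)), "in \\(0, 1\\]")
})

test_that("q-value is monotone in every ratio (property)", {
  set.seed(19)
  for (i in 1:50) {
    K <- sample(1:5, 1)
    r <- runif(K)
    q0 <- orderstat_q(r)
    j <- sample(K, 1)
    r2 <- r
    r2[j] <- min(1, r[j] + runif(1, 0, 1 - r[j]))
    expect_gte(orderstat_q(r2), q0 - 1e-12)
  }
})

test_that("recursion agrees with Monte-Carlo order statistics (K <= 5)", {
  set.seed(101)
  for (K in 1:5) {
    r <- sort(runif(K))
    mc <- oracle_orderstat_mc(r, n = 2e5)
    expect_lt(abs(orderstat_q(r) - mc$estimate), 3 * mc$se + 1e-9)
  }
})

test_that("single-species ranking orders by score with random zero tail", {
  sc <- data.frame(gene_id = c("a", "b", "c"), species = "sp1",
                   score = c(5, 2, 0))
  r <- build_motif_ranking(sc, c("a", "b", "c"), seed = 1)
  expect_equal(r[["a"]], 1L)
  expect_equal(r[["b"]], 2L)
  expect_equal(r[["c"]], 3L)  # zero-score gene queued last
})

test_that("consistently top gene beats a top/bottom gene across species", {
  sc <- data.frame(
    gene_id = rep(c("a", "b", "c", "d"), 2),
    species = rep(c("sp1", "sp2"), each = 4),
    score = c(10, 9, 5, 1,   10, 1, 5, 9))  # a: 1st/1st, b: 2nd/4th
  r <- build_motif_ranking(sc, c("a", "b", "c", "d"), seed = 1)
  expect_lt(r[["a"]], r[["b"]])
  # direct q comparison backs the ordering
  q_a <- orderstat_q(c(1 / 4, 1 / 4))
  q_b <- orderstat_q(c(2 / 4, 4 / 4))
  expect_lt(q_a, q_b)
})

test_that("ranking columns are permutations and seed-reproducible", {
  set.seed(77)
  universe <- sprintf("g%03d", 1:200)
  sc <- expand.grid(gene_id = universe, species = c("sp1", "sp2"),
                    stringsAsFactors = FALSE)
  sc$score <- ifelse(runif(nrow(sc)) < 0.7, 0, rexp(nrow(sc)))
  r1 <- build_motif_ranking(sc, universe, seed = 9)
  r2 <- build_motif_ranking(sc, universe, seed = 9)
  r3 <- build_motif_ranking(sc, universe, seed = 10)
  expect_identical(r1, r2)
  expect_false(identical(r1, r3))  # zero tail reshuffled
  expect_setequal(r1, seq_along(universe))
  expect_error(build_motif_ranking(
    data.frame(gene_id = "zz", species = "sp1", score = 1), universe),
    "not in universe")
})

test_that("track ranking uses max overlapping signalValue", {
  regions <- data.frame(gene_id = c("x", "y", "z", "w", "v"),
                        chrom = "chr1",
                        start = c(0, 1000, 2000, 3000, 4000),
                        end = c(500, 1500, 2500, 3500, 4500),
                        region = 1L)
  peaks <- data.frame(chrom = "chr1",
                      start = c(100, 1100, 450),
                      end = c(200, 1200, 1100),
                      signalValue = c(80, 20, 50))
  universe <- c("x", "y", "z", "w", "v")
  r <- build_track_ranking(peaks, regions, universe, seed = 4)
  expect_equal(r[["x"]], 1L)   # max(80, 50)
  expect_equal(r[["y"]], 2L)   # max(20, 50)
  expect_true(all(r[c("z", "w", "v")] %in% 3:5))
  # brute-force interval check: peak 3 overlaps both x and y
  expect_true(450 < 500 && 1100 > 1000)

  # no overlaps at all: seeded random permutation, reproducible
  far <- data.frame(chrom = "chr9", start = 1, end = 2, signalValue = 5)
  rr1 <- build_track_ranking(far, regions, universe, seed = 6)
  rr2 <- build_track_ranking(far, regions, universe, seed = 6)
  expect_identical(rr1, rr2)
  expect_setequal(rr1, 1:5)
})

test_that("ranking database round-trips through disk with metadata", {
  set.seed(55)
  universe <- sprintf("g%02d", 1:40)
  cols <- lapply(1:3, function(i)
    stats::setNames(sample.int(40), universe))
  names(cols) <- c("f1", "f2", "f3")
  db <- ranking_db_from_columns(cols, "motifs", list(seed = 55))
  tmp <- tempfile(fileext = ".rankdb")
  write_ranking_db(db, tmp)
  back <- read_ranking_db(tmp)
  expect_equal(back$ranks, db$ranks)
  expect_equal(back$collection, "motifs")
  expect_equal(back$metadata$universe_hash, db$metadata$universe_hash)
  # non-permutation column is rejected
  bad <- db$ranks; bad[1, 1] <- bad[2, 1]
  expect_error(ranking_db(bad, "motifs"), "permutation")
})
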