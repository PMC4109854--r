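# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive (enumeration / closed forms / brute-force sums) and
# share no code with the package internals they check.

# Random PWM with a given width: Dirichlet-ish columns scaled to 100.
random_pwm <- function(id, width, concentration = 0.5) {
  m <- matrix(stats::rgamma(width * 4, shape = concentration), width, 4)
  m <- m / rowSums(m) * 100
  pwm(id, m)
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

revcomp_str <- function(x)
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))

# Per-position site log2-odds on both strands, computed independently of
# the C++ code (plain R).
oracle_site_log_odds <- function(seq, p, background, pseudocount = 0.375) {
  enc <- match(strsplit(toupper(seq), "")[[1]], c("A", "C", "G", "T", "N"))
  prob <- (p$counts + pseudocount) / rowSums(p$counts + pseudocount)
  lo <- log2(sweep(prob, 2, background, "/"))
  w <- nrow(prob)
  L <- length(enc)
  n <- L - w + 1
  if (n <= 0) return(NULL)
  fwd <- rev <- numeric(n)
  lo_rc <- lo[w:1, 4:1, drop = FALSE]
  for (i in seq_len(n)) {
    b <- enc[i:(i + w - 1)]
    ok <- b < 5
    fwd[i] <- sum(lo[cbind(which(ok), b[ok])])
    rev[i] <- sum(lo_rc[cbind(which(ok), b[ok])])
  }
  list(fwd = fwd, rev = rev, w = w)
}

# Brute-force CRM score: enumerate every placement of 1..3 non-overlapping
# sites (both strands) and apply the cluster score formula directly.
# Valid only when no more than 3 sites can fit (floor(L/w) <= 3).
oracle_crm_score <- function(seq, p, gap_expectation = 35,
                             background = NULL, pseudocount = 0.375) {
  if (is.null(background)) {
    enc <- match(strsplit(toupper(seq), "")[[1]], c("A", "C", "G", "T", "N"))
    cnt <- tabulate(enc[enc < 5], nbins = 4) + 1
    background <- cnt / sum(cnt)
  }
  sl <- oracle_site_log_odds(seq, p, background, pseudocount)
  if (is.null(sl)) return(0)
  w <- sl$w
  stopifnot(floor(nchar(seq) / w) <= 3)
  gp <- 1 / (1 + gap_expectation)
  lp <- log2(gp); lg <- log2(1 - gp)
  starts <- seq_along(sl$fwd) - 1L        # 0-based
  lo <- c(sl$fwd, sl$rev)
  st <- c(starts, starts)
  best <- max(0, max(lo + lp))                     # singletons
  gap1 <- outer(st + w, st, function(e, s2) s2 - e) # gap i -> j
  valid <- gap1 >= 0
  if (any(valid)) {
    pair_sc <- outer(lo, lo, "+") + 2 * lp + lg * gap1
    best <- max(best, max(pair_sc[valid]))
    pr <- which(valid, arr.ind = TRUE)             # all ordered pairs
    for (row in seq_len(nrow(pr))) {               # extend with a third site
      j <- pr[row, 2]
      g2 <- st - (st[j] + w)
      ok <- g2 >= 0
      if (any(ok))
        best <- max(best, pair_sc[pr[row, 1], j] + lp +
                      max(lo[ok] + lg * g2[ok]))
    }
  }
  best
}

# Naive O(G * s) recovery AUC: build the full cumulative recovery curve
# and sum it over the top T ranks.
oracle_recovery_auc <- function(ranking, gene_set, top_fraction = 0.03) {
  G <- length(ranking)
  T_ <- max(1L, as.integer(ceiling(top_fraction * G)))
  r <- unname(ranking[gene_set[gene_set %in% names(ranking)]])
  s <- length(r)
  ck <- vapply(seq_len(T_), function(k) sum(r <= k), numeric(1))
  sum(ck) / (T_ * s)
}

# Monte-Carlo estimate of the order-statistic probability
# P(U_(i) <= r_(i) for all i), with a pmin/pmax sorting network so that
# 10^6 draws stay vectorized.
oracle_orderstat_mc <- function(ratios, n = 1e6) {
  K <- length(ratios)
  r <- sort(ratios)
  u <- matrix(stats::runif(n * K), n, K)
  for (pass in seq_len(K)) for (j in seq_len(K - 1)) {
    lo <- pmin(u[, j], u[, j + 1]); hi <- pmax(u[, j], u[, j + 1])
    u[, j] <- lo; u[, j + 1] <- hi
  }
  hit <- rep(TRUE, n)
  for (j in seq_len(K)) hit <- hit & (u[, j] <= r[j])
  est <- mean(hit)
  list(estimate = est, se = sqrt(est * (1 - est) / n))
}

# Exact hypergeometric upper tail by direct combinatorial summation.
oracle_hyper_tail <- function(x, s, G, k) {
  xs <- x:min(s, k)
  sum(choose(s, xs) * choose(G - s, k - xs)) / choose(G, k)
}

# Tiny deterministic annotation fixture: three genes on one chromosome.
toy_annotation <- function() {
  gene_annotation(
    gene_id = c("gA", "gB", "gC"),
    chrom = "chr1",
    strand = c("+", "+", "-"),
    tx_start = c(10000, 9000, 40000),
    tx_end = c(12000, 9800, 42000),
    tss = c("10000", "9000", "41999"),
    cds_exons = c("10100-10400", "9100-9300", "40100-40500"))
}
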