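# Independent oracles used to cross-check the package implementations.
# Each deliberately takes a different computational route from the code
# under test.

# Exhaustive integer-ratio fit via a grid enumeration (expand.grid), with
# the same decision rule as fit_integer_ratio: among coprime positive
# vectors with sum <= max_copies, the smallest-sum vector with max
# relative deviation <= eps (ties by deviation); else the global
# minimum-deviation vector, flagged.
oracle_fit_ratio <- function(shares, max_copies = 15L, eps = 0.10) {
  k <- length(shares)
  grid <- as.matrix(do.call(expand.grid, rep(list(seq_len(max_copies)), k)))
  grid <- grid[rowSums(grid) <= max_copies, , drop = FALSE]
  gcd1 <- apply(grid, 1L, function(r) Reduce(function(a, b) {
    while (b != 0) { t <- b; b <- a %% b; a <- t }; a
  }, r) == 1L)
  grid <- grid[gcd1, , drop = FALSE]
  dev <- apply(grid, 1L, function(r) max(abs(r / sum(r) - shares) / shares))
  tot <- rowSums(grid)
  ok <- dev <= eps
  lex <- as.data.frame(grid)
  pick <- if (any(ok)) {
    cand <- which(ok)
    cand[do.call(order, c(list(tot[cand], dev[cand]),
                          lex[cand, , drop = FALSE]))][1L]
  } else {
    do.call(order, c(list(dev, tot), lex))[1L]
  }
  list(ratio = as.integer(grid[pick, ]), deviation = dev[pick],
       rejected = !any(ok))
}

# Spearman rho by explicit midrank transform followed by Pearson.
oracle_spearman <- function(x, y) {
  stats::cor(rank(x, ties.method = "average"),
             rank(y, ties.method = "average"), method = "pearson")
}

# Exact one-factor PERMANOVA p for small n: enumerate every assignment of
# the observed label multiset to the samples.
oracle_permanova_exact <- function(D, groups) {
  D <- as.matrix(D)
  d2 <- D^2
  f_stat <- function(g) {
    n <- nrow(d2); a <- length(unique(g))
    ss_t <- sum(d2) / (2 * n)
    ss_w <- sum(vapply(unique(g), function(gv) {
      i <- which(g == gv); sum(d2[i, i]) / (2 * length(i))
    }, 0))
    ((ss_t - ss_w) / (a - 1)) / (ss_w / (n - a))
  }
  lv <- unique(groups)
  stopifnot(length(lv) == 2L)
  n1 <- sum(groups == lv[1L])
  f_obs <- f_stat(groups)
  idx_sets <- utils::combn(length(groups), n1, simplify = FALSE)
  f_all <- vapply(idx_sets, function(ix) {
    g <- rep(lv[2L], length(groups)); g[ix] <- lv[1L]; f_stat(g)
  }, 0)
  mean(f_all >= f_obs - 1e-12)
}

# Naive Ward.D2 agglomerative clustering via the Lance-Williams update,
# tracking merge heights; returns them sorted (for height comparison).
oracle_ward_heights <- function(m) {
  d <- as.matrix(stats::dist(m))
  n <- nrow(d)
  active <- seq_len(n)
  size <- rep(1L, n)
  heights <- numeric(0)
  while (length(active) > 1L) {
    best <- c(NA, NA); bd <- Inf
    for (ii in seq_along(active)) for (jj in seq_along(active)) {
      if (jj <= ii) next
      i <- active[ii]; j <- active[jj]
      if (d[i, j] < bd) { bd <- d[i, j]; best <- c(i, j) }
    }
    i <- best[1L]; j <- best[2L]
    heights <- c(heights, bd)
    for (k in setdiff(active, c(i, j))) {
      ni <- size[i]; nj <- size[j]; nk <- size[k]
      d[i, k] <- d[k, i] <- sqrt(((ni + nk) * d[i, k]^2 +
                                  (nj + nk) * d[j, k]^2 -
                                  nk * d[i, j]^2) / (ni + nj + nk))
    }
    size[i] <- size[i] + size[j]
    active <- setdiff(active, j)
  }
  sort(heights)
}

# Small random ASV table fixture (no cluster structure) for io/pipeline tests.
random_asv_table <- function(n_samples = 6L, n_asvs = 4L, seed = 42L) {
  set.seed(seed)
  counts <- matrix(rpois(n_samples * n_asvs, 50) + 1L, n_samples, n_asvs,
                   dimnames = list(sprintf("S%02d", seq_len(n_samples)),
                                   sprintf("ASV_%03d", seq_len(n_asvs))))
  seqs <- vapply(seq_len(n_asvs), function(i)
    paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = ""), "")
  names(seqs) <- colnames(counts)
  asv_table(counts,
            asv_species = setNames(rep("Testspecies", n_asvs), colnames(counts)),
            asv_seqs = seqs,
            sample_meta = data.frame(sample_id = rownames(counts),
                                     starter = rep(c("A", "B"), length.out = n_samples)))
}
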