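test_that("relative abundances normalise rows and flag empty samples", {
  m <- matrix(c(30L, 10L, 5L, 0L), 2L, 2L, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("a", "b")))
  ra <- relative_abundances(m)
  expect_equal(unname(ra["s1", ]), c(0.75, 0.25))
  expect_equal(unname(ra["s2", ]), c(1, 0))
  expect_equal(unname(rowSums(ra)), c(1, 1))
  m["s2", ] <- 0L
  expect_error(relative_abundances(m), "s2")
})

test_that("pair ratio statistics detect exact proportionality", {
  xj <- c(10L, 20L, 40L, 15L, 25L, 30L, 50L, 12L, 18L, 22L)
  m <- cbind(a = 3L * xj, b = xj)
  rownames(m) <- sprintf("s%02d", 1:10)
  st <- pair_ratio_stats(m, "a", "b")
  expect_equal(st$n_copresent, 10L)
  expect_equal(st$mean_logratio, log(3))
  expect_equal(st$sd_logratio, 0)
  expect_equal(st$spearman_rho, 1)
  expect_true(st$pass)
})

test_that("too few co-present samples fails the pair test with a flag", {
  m <- cbind(a = c(30L, 60L, 90L, 0L, 0L, 0L, 0L),
             b = c(10L, 20L, 30L, 5L, 8L, 2L, 4L))
  rownames(m) <- sprintf("s%02d", 1:7)
  st <- pair_ratio_stats(m, "a", "b", inference_params(m = 6L))
  expect_false(st$pass)
  expect_false(st$defined)
  expect_equal(st$n_copresent, 3L)
  expect_true(is.na(st$sd_logratio))
})

test_that("integer ratio fitting reproduces the canonical copy ratios", {
  cases <- list(
    list(s = c(0.75, 0.25), want = c(3L, 1L), dev = 0),
    list(s = c(0.60, 0.20, 0.20), want = c(3L, 1L, 1L), dev = 0),
    list(s = rep(0.2, 5L), want = rep(1L, 5L), dev = 0),
    list(s = c(0.74, 0.26), want = c(3L, 1L), dev = NA)
  )
  for (cs in cases) {
    fit <- fit_integer_ratio(cs$s)
    expect_equal(fit$ratio, cs$want)
    if (!is.na(cs$dev)) expect_equal(fit$deviation, cs$dev)
    expect_false(fit$rejected)
  }
  expect_error(fit_integer_ratio(c(0.9, 0.1, 0)), "positive")
  expect_error(fit_integer_ratio(1), "at least 2")
})

test_that("integer ratio fitting agrees with the exhaustive grid oracle", {
  set.seed(501)
  for (i in 1:200) {
    k <- sample(2:4, 1L)
    s <- runif(k, 0.05, 1)
    s <- s / sum(s)
    fit <- fit_integer_ratio(s)
    orc <- oracle_fit_ratio(s)
    expect_identical(fit$ratio, orc$ratio)
    expect_equal(fit$deviation, orc$deviation, tolerance = 1e-12)
    expect_identical(fit$rejected, orc$rejected)
  }
})

test_that("copy-number lower bound is the ratio total", {
  pr <- preset("leuconostoc", seed = 2)
  tab <- simulate_counts(pr$strains, pr$design)
  cl <- build_strain_clusters(tab)
  multi <- Filter(function(x) length(x$member_asvs) > 1L, cl)
  expect_length(multi, 1L)
  expect_equal(as.integer(infer_copy_number(multi[[1L]])), 4L)
  expect_false(attr(infer_copy_number(multi[[1L]]), "ambiguous"))
  single <- Filter(function(x) length(x$member_asvs) == 1L, cl)[[1L]]
  expect_equal(as.integer(infer_copy_number(single)), 1L)
  expect_true(attr(infer_copy_number(single), "ambiguous"))
})

test_that("cluster building recovers the preset strain structures", {
  pr <- preset("rennini", seed = 4)
  cl <- build_strain_clusters(simulate_counts(pr$strains, pr$design))
  cs <- clusters_summary(cl)
  ren <- cs[cs$species == "Loigolactobacillus rennini", ]
  expect_equal(nrow(ren), 1L)
  expect_equal(ren$n_asvs, 3L)
  expect_equal(ren$ratio, "3:1:1")
  expect_equal(ren$copy_number_lower_bound, 5L)

  pr2 <- preset("tetragenococcus", seed = 4)
  cl2 <- build_strain_clusters(simulate_counts(pr2$strains, pr2$design))
  cs2 <- clusters_summary(cl2)
  expect_equal(nrow(cs2), 2L)
  expect_equal(cs2$n_asvs, c(5L, 5L))
  expect_setequal(cs2$ratio, "1:1:1:1:1")

  pr3 <- preset("null_community", seed = 4)
  cl3 <- build_strain_clusters(simulate_counts(pr3$strains, pr3$design))
  expect_true(all(clusters_summary(cl3)$n_asvs == 1L))
})

test_that("clustering output is invariant to sample and ASV relabelling", {
  pr <- preset("tetragenococcus", seed = 6)
  tab <- simulate_counts(pr$strains, pr$design)
  cl <- build_strain_clusters(tab)
  part <- lapply(cl, function(x) sort(x$member_asvs))

  set.seed(61)
  sp <- sample(nrow(tab$counts))
  ap <- sample(ncol(tab$counts))
  tab2 <- asv_table(tab$counts[sp, ap],
                    asv_species = tab$asv_species[colnames(tab$counts)[ap]])
  cl2 <- build_strain_clusters(tab2)
  part2 <- lapply(cl2, function(x) sort(x$member_asvs))
  expect_setequal(vapply(part, paste, "", collapse = ","),
                  vapply(part2, paste, "", collapse = ","))
  expect_setequal(vapply(cl, function(x) paste(x$ratio, collapse = ":"), ""),
                  vapply(cl2, function(x) paste(x$ratio, collapse = ":"), ""))
})

test_that("shared-ASV decomposition solves the mixture exactly", {
  cl <- list(list(cluster_id = "c1", member_asvs = "A", ratio = 1L),
             list(cluster_id = "c2", member_asvs = c("A", "B"),
                  ratio = c(3L, 1L)))
  m <- matrix(c(80L, 10L, 80L, 0L), 2L, 2L, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("A", "B")))
  dec <- decompose_clusters(m, cl)
  expect_equal(unname(dec$abundance["s1", ]), c(50, 40))
  expect_equal(unname(dec$residual[["s1"]]), 0)
  # B absent: everything goes to the single-ASV cluster
  expect_equal(unname(dec$abundance["s2", ]), c(80, 0))
  # read conservation for exactly decomposable samples
  expect_equal(rowSums(dec$abundance), rowSums(m), ignore_attr = TRUE)
})

test_that("decomposition recovers a noise-free simulated mixture", {
  cl <- list(list(cluster_id = "c1", member_asvs = c("A", "B"),
                  ratio = c(3L, 1L)),
             list(cluster_id = "c2", member_asvs = c("C", "D", "E"),
                  ratio = c(3L, 1L, 1L)))
  truth <- matrix(c(400, 1000, 2000, 0, 800, 1200), 3L, 2L,
                  dimnames = list(c("s1", "s2", "s3"), c("c1", "c2")))
  S <- matrix(0, 5L, 2L, dimnames = list(LETTERS[1:5], c("c1", "c2")))
  S[c("A", "B"), "c1"] <- c(3, 1) / 4
  S[c("C", "D", "E"), "c2"] <- c(3, 1, 1) / 5
  counts <- truth %*% t(S)
  dec <- decompose_clusters(counts, cl)
  expect_equal(dec$abundance, truth)
  expect_true(all(dec$residual < 1e-9))
})

test_that("rank-deficient signatures are rejected with the confounded ids", {
  cl <- list(list(cluster_id = "c1", member_asvs = c("A", "B"),
                  ratio = c(1L, 1L)),
             list(cluster_id = "c2", member_asvs = c("A", "B"),
                  ratio = c(1L, 1L)))
  m <- matrix(c(10L, 10L), 1L, 2L, dimnames = list("s1", c("A", "B")))
  expect_error(decompose_clusters(m, cl), "confounded.*c1.*c2")
})
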