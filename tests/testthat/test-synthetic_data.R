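hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

test_that("make_strain produces the requested copy structure", {
  cases <- list(
    list(n = 4L, vm = 1L, mm = 1L, want = c(3L, 1L)),
    list(n = 5L, vm = c(1L, 1L), mm = 2L, want = c(3L, 1L, 1L)),
    list(n = 1L, vm = integer(), mm = 1L, want = 1L)
  )
  for (cs in cases) {
    st <- make_strain("Sp", cs$n, cs$vm, cs$mm, seed = 7)
    expect_equal(st$copies$multiplicity, cs$want)
    expect_true(all(nchar(st$copies$sequence) == 1492L))
    # dominant copy holds the maximal multiplicity
    expect_equal(max(st$copies$multiplicity), st$copies$multiplicity[1L])
    for (i in seq_along(cs$vm)) {
      expect_equal(hamming(st$copies$sequence[1L], st$copies$sequence[i + 1L]),
                   rep_len(cs$mm, length(cs$vm))[i])
    }
    # all copies pairwise distinct
    expect_equal(anyDuplicated(st$copies$sequence), 0L)
  }
})

test_that("make_strain rejects impossible copy configurations", {
  expect_error(make_strain("Sp", 4L, c(2L, 2L), 1L), "less than n_copies")
  expect_error(make_strain("Sp", 4L, 1L, 0L), "zero substitutions|>= 1")
  expect_error(make_strain("Sp", 4L, 1L, 1L, length = 50L), ">= 100")
})

test_that("make_strain is reproducible for a fixed seed", {
  a <- make_strain("Sp", 4L, 1L, 2L, seed = 11)
  b <- make_strain("Sp", 4L, 1L, 2L, seed = 11)
  c <- make_strain("Sp", 4L, 1L, 2L, seed = 12)
  expect_identical(a, b)
  expect_false(identical(a$copies$sequence, c$copies$sequence))
})

test_that("presets encode the observed strain configurations", {
  pr <- preset("leuconostoc", seed = 3)
  focal <- pr$strains[[1L]]
  expect_equal(focal$copies$multiplicity, c(3L, 1L))
  tab <- simulate_counts(pr$strains, pr$design)
  focal_asvs <- tab$truth[[focal$strain_id]]$asvs
  expect_length(focal_asvs, 2L)
  # within-species read share 0.75 / 0.25
  sh <- colSums(tab$counts[, focal_asvs])
  expect_equal(unname(sh[1L] / sum(sh)), 0.75, tolerance = 0.02)

  pr2 <- preset("tetragenococcus", seed = 3)
  tab2 <- simulate_counts(pr2$strains, pr2$design)
  expect_equal(ncol(tab2$counts), 10L)
  expect_equal(anyDuplicated(tab2$asv_seqs), 0L)
  expect_setequal(
    vapply(pr2$strains, function(s) nrow(s$copies), 0L), 5L)

  expect_error(preset("gorgonzola"), "unknown preset")
})

test_that("copy weighting matches the closed form and conserves mass", {
  # one 4-copy (3,1) strain alone: ASV fractions forced to (0.75, 0.25)
  st <- make_strain("Sp", 4L, 1L, 1L, seed = 5)
  des <- community_design(list(st), n_samples = 2L, depth = 200000L, seed = 5)
  tab <- simulate_counts(list(st), des)
  frac <- tab$counts / rowSums(tab$counts)
  expect_equal(unname(frac[1L, ]), c(0.75, 0.25), tolerance = 0.01)

  # two single-copy strains at equal cell abundance: fractions (0.5, 0.5)
  s1 <- make_strain("SpA", 1L, seed = 6, strain_id = "a")
  s2 <- make_strain("SpB", 1L, seed = 7, strain_id = "b")
  des2 <- community_design(list(s1, s2), n_samples = 2L, depth = 200000L,
                           abundance = matrix(0.5, 2L, 2L), seed = 6)
  tab2 <- simulate_counts(list(s1, s2), des2)
  frac2 <- tab2$counts / rowSums(tab2$counts)
  expect_equal(unname(frac2[1L, ]), c(0.5, 0.5), tolerance = 0.01)

  # copy weighting: a 2-copy strain gets twice the reads of a 1-copy
  # strain at equal cell abundance
  s3 <- make_strain("SpC", 2L, seed = 8, strain_id = "c")
  des3 <- community_design(list(s1, s3), n_samples = 2L, depth = 300000L,
                           abundance = matrix(0.5, 2L, 2L), seed = 8)
  tab3 <- simulate_counts(list(s1, s3), des3)
  frac3 <- tab3$counts / rowSums(tab3$counts)
  expect_equal(unname(frac3[1L, ]), c(1 / 3, 2 / 3), tolerance = 0.01)
})

test_that("strains sharing a copy sequence collapse into one ASV", {
  s1 <- make_strain("SpA", 1L, seed = 21, strain_id = "a")
  s2 <- make_strain("SpB", 2L, 1L, 1L, seed = 22, strain_id = "b")
  s2$copies$sequence[1L] <- s1$copies$sequence[1L]  # shared dominant copy
  des <- community_design(list(s1, s2), n_samples = 2L, depth = 400000L,
                          abundance = matrix(0.5, 2L, 2L), seed = 23)
  tab <- simulate_counts(list(s1, s2), des)
  expect_equal(ncol(tab$counts), 2L)       # 3 copies, 2 unique sequences
  shared <- intersect(tab$truth[["a"]]$asvs, tab$truth[["b"]]$asvs)
  expect_length(shared, 1L)
  expect_equal(tab$asv_species[[shared]], "SpA/SpB")
  # expectation: shared ASV carries 0.5*1 + 0.5*1 of 1.5 copy-units
  frac <- tab$counts[1L, ] / sum(tab$counts[1L, ])
  expect_equal(unname(frac[shared]), 2 / 3, tolerance = 0.01)
})

test_that("simulate_counts is seed-deterministic and validates input", {
  pr <- preset("rennini", seed = 9)
  t1 <- simulate_counts(pr$strains, pr$design)
  t2 <- simulate_counts(pr$strains, pr$design)
  expect_identical(t1$counts, t2$counts)
  expect_error(simulate_counts(list(), pr$design), "empty strain list")
})

test_that("per-sample dominant:variant count ratio stays near 3 at depth 20,000", {
  # binomial sampling makes the per-sample ratio concentrate around 3
  pr <- preset("leuconostoc", n_samples = 24L, depth = 20000L, seed = 1)
  tab <- simulate_counts(pr$strains, pr$design)
  asvs <- tab$truth[["Leuc_pseudo_A"]]$asvs
  ratio <- tab$counts[, asvs[1L]] / tab$counts[, asvs[2L]]
  expect_gte(sum(abs(ratio - 3) <= 0.15), 23L)
})

test_that("metabolite simulation follows the linear link model", {
  ab <- matrix(seq(0.1, 1, length.out = 10L), ncol = 1L,
               dimnames = list(sprintf("S%02d", 1:10), "strain1"))
  model0 <- list(effects = matrix(0, 1L, 1L, dimnames = list("met1", NULL)),
                 baseline = 12, noise_sd = 0)
  conc0 <- simulate_metabolites(ab, model0, seed = 1)
  expect_true(all(conc0 == 12))

  model1 <- list(effects = matrix(100, 1L, 1L, dimnames = list("met1", NULL)),
                 baseline = 0, noise_sd = 0)
  conc1 <- simulate_metabolites(ab, model1, seed = 1)
  expect_equal(suppressWarnings(
    cor(ab[, 1L], conc1[, 1L], method = "spearman")), 1)

  expect_error(
    simulate_metabolites(ab, list(effects = model1$effects, baseline = 0,
                                  noise_sd = -1), seed = 1),
    "noise_sd")
})

test_that("a noisy metabolite link is recovered by Spearman correlation", {
  # median over seeds of rho between strain abundance and its metabolite
  ab <- matrix(seq(0.01, 0.5, length.out = 46L), ncol = 1L,
               dimnames = list(sprintf("S%02d", 1:46), "strain1"))
  model <- list(effects = matrix(100, 1L, 1L, dimnames = list("met1", NULL)),
                baseline = 10, noise_sd = 5)
  rhos <- vapply(1:50, function(s) {
    conc <- simulate_metabolites(ab, model, seed = s)
    ct <- suppressWarnings(cor.test(ab[, 1L], conc[, 1L],
                                    method = "spearman", exact = FALSE))
    ifelse(ct$p.value < 0.05, unname(ct$estimate), 0)
  }, 0)
  expect_gt(stats::median(rhos), 0.6)
})

test_that("sensory simulation respects the panel model", {
  panel <- list(assessors = data.frame(bias = c(0, 0), scale = c(1, 1)),
                true_quality = c(c1 = 8, c2 = 12, c3 = 16), noise_sd = 0)
  sc <- simulate_sensory(panel, seed = 1)
  expect_equal(sc$score, rep(c(8, 12, 16), each = 2L))

  # assessor-specific bias vanishes after Z-normalisation
  panel2 <- list(assessors = data.frame(bias = c(0, 3), scale = c(1, 1)),
                 true_quality = c(c1 = 8, c2 = 12, c3 = 16), noise_sd = 0)
  z <- assessor_zscores(simulate_sensory(panel2, seed = 1))
  z1 <- z$z[z$assessor == "assessor_01"][order(z$cheese[z$assessor == "assessor_01"])]
  z2 <- z$z[z$assessor == "assessor_02"][order(z$cheese[z$assessor == "assessor_02"])]
  expect_equal(z1, z2)

  expect_error(simulate_sensory(list(
    assessors = data.frame(bias = 0, scale = -1),
    true_quality = 1:3, noise_sd = 0), seed = 1), "scale")
})

test_that("mean Z-score ranks cheeses by latent quality under panel noise", {
  set.seed(99)
  quality <- rnorm(23L, 10, 2)
  names(quality) <- sprintf("cheese_%02d", 1:23)
  panel <- list(
    assessors = data.frame(bias = runif(10L, -2, 2),
                           scale = runif(10L, 0.7, 1.3)),
    true_quality = quality, noise_sd = 1)
  rhos <- vapply(1:25, function(s) {
    z <- cheese_zscore(assessor_zscores(simulate_sensory(panel, seed = s)))
    cor(z$mean_z[match(names(quality), z$cheese)], quality,
        method = "spearman")
  }, 0)
  expect_gt(stats::median(rhos), 0.8)
})
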