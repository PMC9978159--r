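#' Construct a simulated strain with intragenomic 16S copy variants
#'
#' A strain carries `n_copies` copies of the 16S rRNA gene. Some copies are
#' single-nucleotide variants of the dominant copy; within a community they
#' surface as distinct ASVs whose read counts sit in a constant integer
#' ratio given by the copy multiplicities (e.g. a 4-copy strain with one
#' variant copy yields two ASVs in a 3:1 ratio).
#'
#' @param species Species label attached to every ASV of this strain.
#' @param n_copies Total 16S gene copies in the genome (>= 1).
#' @param variant_multiplicities Integer vector; multiplicity of each variant
#'   copy. The dominant copy keeps `n_copies - sum(variant_multiplicities)`
#'   copies, which must stay positive and is expected to be the maximum.
#' @param mismatches_per_variant Substitutions separating each variant from
#'   the dominant copy (scalar, recycled, or one value per variant; >= 1).
#'   Variant positions are disjoint across variants, so all copy sequences
#'   are pairwise distinct.
#' @param length Sequence length in nt (>= 100; full-length 16S ~ 1492).
#' @param seed Integer seed; fixed seed gives a bit-identical strain.
#' @param strain_id Identifier; defaults to the species label.
#'
#' @return A `strain_spec`: list with `strain_id`, `species`, and `copies`
#'   (data.frame of `sequence`, `multiplicity`, dominant copy first).
#' @export
make_strain <- function(species, n_copies, variant_multiplicities = integer(),
                        mismatches_per_variant = 1L, length = 1492L,
                        seed = 1L, strain_id = species) {
  stopifnot(is.character(species), length(species) == 1L)
  n_copies <- as.integer(n_copies)
  vm <- as.integer(variant_multiplicities)
  if (n_copies < 1L) stop("n_copies must be >= 1")
  if (any(vm < 1L)) stop("variant multiplicities must be positive")
  if (sum(vm) >= n_copies)
    stop("variant multiplicities (", sum(vm),
         ") must total less than n_copies (", n_copies, ")")
  if (length < 100L) stop("sequence length must be >= 100")
  mm <- rep_len(as.integer(mismatches_per_variant), length(vm))
  if (length(vm) > 0L && any(mm < 1L))
    stop("mismatches_per_variant must be >= 1 (a variant with zero ",
         "substitutions would collide with the dominant copy)")
  if (sum(mm) > length)
    stop("total substitutions exceed sequence length")

  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  dominant <- sample(bases, length, replace = TRUE)
  # disjoint substitution positions across variants -> pairwise distinct copies
  pos_pool <- if (length(vm) > 0L) sample.int(length, sum(mm)) else integer()
  offset <- 0L
  copies <- list(list(sequence = paste(dominant, collapse = ""),
                      multiplicity = n_copies - sum(vm)))
  for (k in seq_along(vm)) {
    v <- dominant
    for (p in pos_pool[offset + seq_len(mm[k])]) {
      v[p] <- sample(setdiff(bases, v[p]), 1L)
    }
    offset <- offset + mm[k]
    copies[[k + 1L]] <- list(sequence = paste(v, collapse = ""),
                             multiplicity = vm[k])
  }
  structure(list(
    strain_id = strain_id,
    species = species,
    copies = data.frame(
      sequence = vapply(copies, `[[`, "", "sequence"),
      multiplicity = vapply(copies, function(x) as.integer(x$multiplicity), 0L)
    )
  ), class = "strain_spec")
}

#' @export
print.strain_spec <- function(x, ...) {
  cat("<strain_spec>", x$strain_id, "(", x$species, ")\n")
  cat("  copies:", nrow(x$copies), "variant sequences, multiplicities",
      paste(x$copies$multiplicity, collapse = ":"), "\n")
  invisible(x)
}

#' Build a community design (samples, metadata, strain abundances)
#'
#' Cell-level strain abundances are drawn per sample from independent
#' log-normal variates and row-normalised, emulating strain loads that vary
#' over orders of magnitude across cheese batches and ripening times.
#'
#' @param strains List of `strain_spec` objects.
#' @param n_samples Number of samples (metadata cycles starter A/B/C and
#'   ripening weeks 36/45/75/100; all samples are cores).
#' @param depth Sequencing reads per sample (>= 1).
#' @param seed Integer seed for the abundance draw and downstream sampling.
#' @param sdlog Log-normal sd of the raw strain loads.
#' @param weights Optional per-strain relative mean loads (multiply the
#'   log-normal draws before row normalisation); default all equal.
#' @param abundance Optional explicit samples x strains abundance matrix
#'   (rows must sum to 1); overrides the log-normal draw.
#' @return A `community_design`: list with `samples` (data.frame),
#'   `abundance`, `depth`, `seed`.
#' @export
community_design <- function(strains, n_samples = 24L, depth = 20000L,
                             seed = 1L, sdlog = 1, weights = NULL,
                             abundance = NULL) {
  n_samples <- as.integer(n_samples)
  depth <- as.integer(depth)
  if (depth < 1L) stop("depth must be >= 1")
  if (n_samples < 1L) stop("need at least one sample")
  ids <- vapply(strains, `[[`, "", "strain_id")
  samples <- data.frame(
    sample_id = sprintf("S%02d", seq_len(n_samples)),
    starter = rep_len(c("A", "B", "C"), n_samples),
    ripening_week = rep_len(rep(c(36L, 45L, 75L, 100L), each = 3L), n_samples),
    fraction = "core"
  )
  if (is.null(abundance)) {
    set.seed(seed)
    raw <- matrix(stats::rlnorm(n_samples * length(ids), 0, sdlog),
                  nrow = n_samples, ncol = length(ids))
    if (!is.null(weights)) {
      if (length(weights) != length(ids) || any(weights <= 0))
        stop("weights must be positive, one per strain")
      raw <- sweep(raw, 2L, weights, `*`)
    }
    abundance <- raw / rowSums(raw)
  } else {
    abundance <- as.matrix(abundance)
    if (any(abs(rowSums(abundance) - 1) > 1e-9))
      stop("abundance rows must sum to 1")
  }
  dimnames(abundance) <- list(samples$sample_id, ids)
  structure(list(samples = samples, abundance = abundance,
                 depth = depth, seed = as.integer(seed)),
            class = "community_design")
}

#' Named community presets mirroring observed strain configurations
#'
#' * `leuconostoc`: one *Leuconostoc pseudomesenteroides*-like strain with
#'   four 16S copies split 3 + 1 over two variants (two ASVs, 3:1 ratio),
#'   embedded in a background of three unrelated single-copy species so
#'   that the focal strain's absolute abundance varies across samples (in
#'   a one-strain community the two ASV counts would be multinomially
#'   anti-correlated and no co-occurrence signal could exist).
#' * `rennini`: one *Loigolactobacillus rennini*-like strain with five
#'   copies split 3 + 1 + 1 (three ASVs, 3:1:1 ratio), same background.
#' * `tetragenococcus`: two *Tetragenococcus halophilus*-like strains, each
#'   with five distinct single-copy variants (two independent 5-ASV groups
#'   in equal ratios).
#' * `lactococcus_pair`: two single-copy *Lactococcus* strains placed at a
#'   configurable Hamming distance from two synthetic type-strain
#'   references (returned in `$references`) for threshold-rule tests.
#' * `null_community`: twelve unrelated single-copy strains sharing one
#'   species label (so every pair is eligible for within-species
#'   clustering) with independent abundances; contains no true ASV
#'   cluster.
#'
#' @param name Preset name.
#' @param n_samples,depth,seed Passed to [community_design()].
#' @param mismatches_to_ref For `lactococcus_pair`: substitutions between
#'   each strain's sequence and its own type-strain reference (the two
#'   references differ at ~0.6% of sites, as the two species' 16S do).
#' @return List with `strains`, `design`, and (for `lactococcus_pair`)
#'   `references` (named character vector of reference sequences).
#' @export
preset <- function(name, n_samples = 24L, depth = 20000L, seed = 1L,
                   mismatches_to_ref = 1L) {
  known <- c("leuconostoc", "rennini", "tetragenococcus",
             "lactococcus_pair", "null_community")
  if (!name %in% known)
    stop("unknown preset '", name, "'; expected one of: ",
         paste(known, collapse = ", "))
  refs <- NULL
  weights <- NULL
  sdlog <- 1
  background <- function(seed0) lapply(1:3, function(i)
    make_strain(sprintf("Background_sp_%02d", i), 1L, seed = seed0 + i,
                strain_id = sprintf("background_%02d", i)))
  strains <- switch(
    name,
    leuconostoc = {
      weights <- c(8, 1, 1, 1); sdlog <- 0.8
      c(list(make_strain("Leuconostoc pseudomesenteroides", n_copies = 4L,
                         variant_multiplicities = 1L,
                         mismatches_per_variant = 1L,
                         seed = seed + 101L, strain_id = "Leuc_pseudo_A")),
        background(seed + 300L))
    },
    rennini = {
      weights <- c(8, 1, 1, 1); sdlog <- 0.8
      c(list(make_strain("Loigolactobacillus rennini", n_copies = 5L,
                         variant_multiplicities = c(1L, 1L),
                         mismatches_per_variant = 1L,
                         seed = seed + 103L, strain_id = "Loil_rennini_A")),
        background(seed + 310L))
    },
    tetragenococcus = list(
      make_strain("Tetragenococcus halophilus", n_copies = 5L,
                  variant_multiplicities = rep(1L, 4L),
                  mismatches_per_variant = 1L,
                  seed = seed + 105L, strain_id = "T_halophilus_1"),
      make_strain("Tetragenococcus halophilus", n_copies = 5L,
                  variant_multiplicities = rep(1L, 4L),
                  mismatches_per_variant = 2L,
                  seed = seed + 106L, strain_id = "T_halophilus_2")),
    lactococcus_pair = {
      set.seed(seed + 107L)
      len <- 1492L
      bases <- c("A", "C", "G", "T")
      ref_lactis <- sample(bases, len, replace = TRUE)
      ref_cremoris <- ref_lactis
      div_pos <- sample.int(len, 9L)     # ~0.6% divergence between species
      for (p in div_pos)
        ref_cremoris[p] <- sample(setdiff(bases, ref_cremoris[p]), 1L)
      mutate <- function(ref, k, avoid) {
        s <- ref
        for (p in sample(setdiff(seq_len(len), avoid), k))
          s[p] <- sample(setdiff(bases, s[p]), 1L)
        paste(s, collapse = "")
      }
      seq1 <- mutate(ref_lactis, mismatches_to_ref, div_pos)
      seq2 <- mutate(ref_cremoris, mismatches_to_ref, div_pos)
      refs <- c(lactis = paste(ref_lactis, collapse = ""),
                cremoris = paste(ref_cremoris, collapse = ""))
      s1 <- make_strain("Lactococcus lactis", 1L, seed = seed + 108L,
                        strain_id = "Lc_lactis_A")
      s2 <- make_strain("Lactococcus cremoris", 1L, seed = seed + 109L,
                        strain_id = "Lc_cremoris_A")
      s1$copies$sequence <- seq1
      s2$copies$sequence <- seq2
      list(s1, s2)
    },
    # twelve unrelated single-copy strains of one species: within-species
    # clustering sees all 66 pairs, none a true cluster
    null_community = lapply(seq_len(12L), function(i)
      make_strain("Nullspecies", 1L, seed = seed + 200L + i,
                  strain_id = sprintf("null_strain_%02d", i)))
  )
  design <- community_design(strains, n_samples = n_samples, depth = depth,
                             seed = seed, sdlog = sdlog, weights = weights)
  out <- list(strains = strains, design = design)
  if (!is.null(refs)) out$references <- refs
  out
}

#' Simulate an ASV count table from strains and a community design
#'
#' Read shares are copy-weighted: the expected fraction of ASV v is
#' sum_s a_s * m_sv / sum_s a_s * C_s, with a_s the cell-level strain
#' abundance, m_sv the multiplicity of v's sequence in strain s and C_s the
#' strain's total copy number. Counts are then multinomial at the design
#' depth. Identical sequences from different strains collapse into one ASV.
#'
#' @param strains List of `strain_spec`.
#' @param design A `community_design` whose abundance columns match the
#'   strains (by `strain_id`).
#' @return An `asv_table`: list with `counts` (samples x ASVs integer
#'   matrix), `asv_seqs`, `asv_species` (named character vectors),
#'   `sample_meta` (data.frame) and `truth` (per-strain ASV multiplicities).
#' @export
simulate_counts <- function(strains, design) {
  if (length(strains) == 0L) stop("empty strain list")
  stopifnot(inherits(design, "community_design"))
  A <- design$abundance
  ids <- vapply(strains, `[[`, "", "strain_id")
  if (!identical(colnames(A), ids))
    stop("design abundance columns do not match the strain list")
  if (any(abs(rowSums(A) - 1) > 1e-9))
    stop("abundance rows must sum to 1")

  # ASV registry: unique sequences in order of first appearance
  seqs <- character(); species <- list()
  M <- matrix(0, nrow = length(strains), ncol = 0)
  for (si in seq_along(strains)) {
    st <- strains[[si]]
    for (ci in seq_len(nrow(st$copies))) {
      s <- st$copies$sequence[ci]
      j <- match(s, seqs)
      if (is.na(j)) {
        seqs <- c(seqs, s)
        M <- cbind(M, 0)
        j <- length(seqs)
        species[[j]] <- character()
      }
      M[si, j] <- M[si, j] + st$copies$multiplicity[ci]
      species[[j]] <- union(species[[j]], st$species)
    }
  }
  asv_ids <- sprintf("ASV_%03d", seq_along(seqs))
  asv_species <- vapply(species, function(x) paste(sort(x), collapse = "/"), "")
  names(asv_species) <- asv_ids
  names(seqs) <- asv_ids

  E <- A %*% M                      # samples x ASVs expected read mass
  P <- E / rowSums(E)
  set.seed(design$seed)
  counts <- t(apply(P, 1L, function(p) stats::rmultinom(1L, design$depth, p)))
  dimnames(counts) <- list(rownames(A), asv_ids)
  storage.mode(counts) <- "integer"

  truth <- lapply(seq_along(strains), function(si) {
    j <- which(M[si, ] > 0)
    list(strain_id = ids[si], species = strains[[si]]$species,
         asvs = asv_ids[j], multiplicities = as.integer(M[si, j]))
  })
  names(truth) <- ids
  asv_table(counts, asv_species = asv_species, asv_seqs = seqs,
            sample_meta = design$samples, truth = truth)
}

#' Assemble an ASV table object
#'
#' @param counts Samples x ASVs non-negative integer matrix with dimnames.
#' @param asv_species Named character vector (ASV -> species label); ASVs
#'   without a label are set to "unassigned".
#' @param asv_seqs Optional named character vector of ASV sequences.
#' @param sample_meta Optional data.frame of per-sample metadata.
#' @param truth Optional ground-truth strain map (simulation only).
#' @return An `asv_table` object.
#' @export
asv_table <- function(counts, asv_species = NULL, asv_seqs = NULL,
                      sample_meta = NULL, truth = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative read counts")
  if (is.null(colnames(counts))) stop("counts must have ASV column names")
  if (is.null(rownames(counts))) stop("counts must have sample row names")
  sp <- stats::setNames(rep("unassigned", ncol(counts)), colnames(counts))
  if (!is.null(asv_species)) sp[names(asv_species)] <- asv_species
  structure(list(counts = counts, asv_species = sp, asv_seqs = asv_seqs,
                 sample_meta = sample_meta, truth = truth),
            class = "asv_table")
}

#' @export
print.asv_table <- function(x, ...) {
  cat("<asv_table>", nrow(x$counts), "samples x", ncol(x$counts), "ASVs;",
      length(unique(x$asv_species)), "species labels\n")
  invisible(x)
}

#' Simulate metabolite concentrations linearly linked to taxon abundances
#'
#' concentration = baseline + effects %*% abundance + Gaussian noise,
#' truncated at zero (concentrations in mg/kg dry mass cannot be negative).
#'
#' @param abundances Samples x taxa (strains or clusters) abundance matrix.
#' @param model List with `effects` (metabolites x taxa signed slopes,
#'   mg/kg per unit relative abundance), `baseline` (per-metabolite, >= 0)
#'   and `noise_sd` (per-metabolite, >= 0).
#' @param seed Integer seed.
#' @return Samples x metabolites concentration matrix (mg/kg dry mass).
#' @export
simulate_metabolites <- function(abundances, model, seed = 1L) {
  ab <- as.matrix(abundances)
  eff <- as.matrix(model$effects)
  nm <- nrow(eff)
  baseline <- rep_len(model$baseline, nm)
  noise_sd <- rep_len(model$noise_sd, nm)
  if (any(noise_sd < 0)) stop("noise_sd must be >= 0")
  if (any(baseline < 0)) stop("baseline must be >= 0")
  if (ncol(eff) != ncol(ab))
    stop("effects columns must match abundance columns")
  mu <- sweep(ab %*% t(eff), 2L, baseline, `+`)
  set.seed(seed)
  noise <- matrix(stats::rnorm(length(mu), 0,
                               rep(noise_sd, each = nrow(ab))),
                  nrow = nrow(ab))
  conc <- pmax(mu + noise, 0)
  dimnames(conc) <- list(rownames(ab), rownames(eff))
  conc
}

#' Simulate raw sensory panel scores
#'
#' Each assessor scores each cheese on a 0-20 scale as
#' clamp(bias + scale * true_quality + noise, 0, 20): assessors share a
#' latent per-cheese quality but apply their own location and scale, which
#' the per-assessor Z-transformation is designed to remove.
#'
#' @param panel List with `assessors` (data.frame of `bias`, `scale` > 0),
#'   `true_quality` (per-cheese latent quality) and `noise_sd` (>= 0).
#' @param seed Integer seed.
#' @return Long data.frame: `assessor`, `cheese`, `score`.
#' @export
simulate_sensory <- function(panel, seed = 1L) {
  a <- panel$assessors
  if (any(a$scale <= 0)) stop("assessor scales must be > 0")
  if (panel$noise_sd < 0) stop("noise_sd must be >= 0")
  q <- panel$true_quality
  cheeses <- if (is.null(names(q))) sprintf("cheese_%02d", seq_along(q)) else names(q)
  assessors <- if (is.null(rownames(a))) sprintf("assessor_%02d", seq_len(nrow(a))) else rownames(a)
  set.seed(seed)
  out <- expand.grid(assessor = assessors, cheese = cheeses,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  i <- match(out$assessor, assessors)
  j <- match(out$cheese, cheeses)
  raw <- a$bias[i] + a$scale[i] * q[j] + stats::rnorm(nrow(out), 0, panel$noise_sd)
  out$score <- pmin(pmax(raw, 0), 20)
  out
}
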