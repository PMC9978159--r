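#' Inverse Simpson alpha diversity
#'
#' 1 / sum(p_i^2): the effective number of equally abundant taxa. Bounded
#' above by the number of non-zero taxa, with equality at uniformity.
#'
#' @param p Proportion vector (entries >= 0, summing to 1), or a samples x
#'   taxa proportion matrix (one index per row).
#' @return Numeric value(s) >= 1.
#' @export
inverse_simpson <- function(p) {
  if (is.matrix(p)) return(apply(p, 1L, inverse_simpson))
  if (all(p == 0)) stop("all-zero abundance vector")
  if (any(p < 0)) stop("negative proportions")
  if (abs(sum(p) - 1) > 1e-8) stop("proportions must sum to 1")
  1 / sum(p^2)
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' sum(|x - y|) / sum(x + y), in [0, 1]; 0 for identical profiles, 1 for
#' disjoint supports; invariant to a common positive rescaling of both
#' vectors.
#'
#' @param x,y Non-negative abundance vectors of equal length.
#' @return Dissimilarity in [0, 1].
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (any(x < 0) || any(y < 0)) stop("abundances must be non-negative")
  if (sum(x) + sum(y) == 0) stop("both vectors are all-zero")
  sum(abs(x - y)) / sum(x + y)
}

#' Bray-Curtis dissimilarity matrix for a samples x taxa table
#'
#' @param x Samples x taxa non-negative matrix.
#' @return A symmetric samples x samples matrix with zero diagonal.
#' @export
bray_curtis_matrix <- function(x) {
  as.matrix(vegan::vegdist(as.matrix(x), method = "bray"))
}

# Anderson's distance-based pseudo-F for one factor
.permanova_F <- function(d2, groups) {
  n <- nrow(d2)
  a <- length(unique(groups))
  ss_t <- sum(d2) / (2 * n)
  ss_w <- 0
  for (g in unique(groups)) {
    i <- which(groups == g)
    ss_w <- ss_w + sum(d2[i, i]) / (2 * length(i))
  }
  ((ss_t - ss_w) / (a - 1)) / (ss_w / (n - a))
}

#' One-factor PERMANOVA on a dissimilarity matrix
#'
#' Distance-based pseudo-F (total minus within-group sums of squared
#' dissimilarities), with a permutation p-value from shuffling group
#' labels: p = (1 + #\{permuted F >= observed F\}) / (1 + n_perm).
#'
#' @param D Square symmetric dissimilarity matrix (or `dist`).
#' @param groups Group labels, one per sample (>= 2 groups, each of
#'   size >= 2).
#' @param n_perm Number of random label permutations.
#' @param seed Integer seed for the permutations.
#' @return A `permanova_result`: `pseudo_F`, `p_value`, `n_permutations`,
#'   `seed`, `df` (between, within).
#' @export
permanova <- function(D, groups, n_perm = 999L, seed = 1L) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D) || any(abs(D - t(D)) > 1e-12))
    stop("D must be a square symmetric dissimilarity matrix")
  groups <- as.character(groups)
  if (length(groups) != nrow(D)) stop("one group label per sample required")
  tab <- table(groups)
  if (length(tab) < 2L) stop("need at least 2 groups")
  if (any(tab < 2L)) stop("every group needs at least 2 members")
  d2 <- D^2
  f_obs <- .permanova_F(d2, groups)
  set.seed(seed)
  f_perm <- vapply(seq_len(n_perm), function(b)
    .permanova_F(d2, sample(groups)), 0)
  p <- (1 + sum(f_perm >= f_obs)) / (1 + n_perm)
  structure(list(pseudo_F = f_obs, p_value = p,
                 n_permutations = as.integer(n_perm), seed = as.integer(seed),
                 df = c(between = length(tab) - 1L,
                        within = nrow(D) - length(tab))),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat("PERMANOVA: pseudo-F =", signif(x$pseudo_F, 5),
      " p =", signif(x$p_value, 4),
      sprintf(" (%d permutations, df %d/%d)\n", x$n_permutations,
              x$df[1], x$df[2]))
  invisible(x)
}

#' Scaled principal component analysis
#'
#' Columns are centred and scaled to unit variance (Z-score transformation)
#' before singular value decomposition, so explained variances equal the
#' eigenvalues of the correlation matrix. Constant columns are dropped with
#' a warning. Component signs are fixed by making each loading vector's
#' largest-magnitude entry positive, for reproducible orientation.
#'
#' @param X Samples x variables numeric matrix (>= 2 samples).
#' @return List with `scores`, `loadings`, `explained_variance`
#'   (non-increasing eigenvalues) and `proportion`.
#' @export
pca_scaled <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 samples")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant column(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  if (ncol(X) == 0L) stop("no non-constant variables left")
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  ev <- pc$sdev^2
  list(scores = pc$x, loadings = pc$rotation,
       explained_variance = ev, proportion = ev / sum(ev))
}
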