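#' Filter taxa by average relative abundance
#'
#' Keeps taxa whose mean relative abundance over a designated sample set is
#' at or above the threshold (inclusive), matching the convention of
#' considering only species with an average relative abundance of at least
#' 0.2% across the late-ripening cheese cores.
#'
#' @param tab Samples x taxa proportion matrix or data.frame.
#' @param threshold Mean relative abundance cutoff (default 0.002).
#' @param samples Optional sample ids (or logical/integer index) selecting
#'   the rows over which the mean is taken; defaults to all.
#' @return The table restricted to retained taxa (all samples kept).
#' @export
prevalence_filter <- function(tab, threshold = 0.002, samples = NULL) {
  tab <- as.matrix(tab)
  sub <- if (is.null(samples)) tab else tab[samples, , drop = FALSE]
  if (nrow(sub) == 0L) stop("empty sample set for the abundance filter")
  keep <- colMeans(sub) >= threshold
  tab[, keep, drop = FALSE]
}

#' Pairwise taxa-metabolite correlation matrix
#'
#' Spearman (rank-based, midrank ties, p from the t-approximation) or
#' Pearson correlations between every column of `X` and every column of
#' `Y`, with pairwise deletion of missing values. Spearman is the choice
#' when data from different ripening times are pooled; Pearson when
#' correlating with a score at one ripening time. Cells with fewer than 4
#' complete pairs or a constant column are undefined (NA) and flagged. Raw
#' p-values are compared against `alpha`; an optional Benjamini-Hochberg
#' adjustment is available but off by default.
#'
#' @param X Samples x taxa matrix.
#' @param Y Samples x metabolites matrix (defaults to `X`).
#' @param method "spearman" or "pearson".
#' @param alpha Significance level for the flag matrix.
#' @param p_adjust NULL (raw p, the default) or a method for
#'   [stats::p.adjust()] such as "BH".
#' @return An `association_result`: `r` (taxa x metabolites), `p`,
#'   `significant`, `undefined`, `method`, and Ward leaf orders
#'   `row_order` / `col_order` computed on the coefficient matrix.
#' @export
correlation_matrix <- function(X, Y = NULL, method = c("spearman", "pearson"),
                               alpha = 0.05, p_adjust = NULL) {
  method <- match.arg(method)
  X <- as.matrix(X)
  Y <- if (is.null(Y)) X else as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have matched samples")
  nt <- ncol(X); nm <- ncol(Y)
  r <- p <- matrix(NA_real_, nt, nm,
                   dimnames = list(colnames(X), colnames(Y)))
  undefined <- matrix(FALSE, nt, nm, dimnames = dimnames(r))
  for (i in seq_len(nt)) {
    for (j in seq_len(nm)) {
      ok <- stats::complete.cases(X[, i], Y[, j])
      x <- X[ok, i]; y <- Y[ok, j]
      if (sum(ok) < 4L || stats::sd(x) == 0 || stats::sd(y) == 0) {
        undefined[i, j] <- TRUE
        next
      }
      ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                             exact = FALSE))
      r[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
    }
  }
  if (!is.null(p_adjust))
    p[] <- stats::p.adjust(p, method = p_adjust)
  lf <- ward_order(ifelse(is.na(r), 0, r))
  structure(list(r = r, p = p, significant = !is.na(p) & p < alpha,
                 undefined = undefined, method = method,
                 row_order = lf$rows, col_order = lf$cols),
            class = "association_result")
}

#' Ward.D2 dendrogram leaf orders for heatmap display
#'
#' Agglomerative clustering of rows and of columns on Euclidean distances
#' with the Ward.D2 update (duplicated rows merge first, at height 0); ties
#' resolve deterministically by lowest index.
#'
#' @param m Numeric matrix.
#' @return List with `rows` and `cols` leaf-order permutations.
#' @export
ward_order <- function(m) {
  m <- as.matrix(m)
  one <- function(mm) {
    if (nrow(mm) < 2L) return(seq_len(nrow(mm)))
    stats::hclust(stats::dist(mm), method = "ward.D2")$order
  }
  list(rows = one(m), cols = one(t(m)))
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' @param values Numeric response vector.
#' @param groups Group labels (>= 2 groups, each with >= 2 observations).
#' @param alpha Significance level for the pairwise flags.
#' @return List with `F`, `p`, `df`, `tukey` (data.frame: comparison,
#'   diff, lwr, upr, p_adj, significant) and `alpha`.
#' @export
group_compare <- function(values, groups, alpha = 0.05) {
  g <- factor(groups)
  tab <- table(g)
  if (length(tab) < 2L) stop("need at least 2 groups")
  if (any(tab < 2L))
    stop("group(s) with fewer than 2 observations: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  fit <- stats::aov(values ~ g)
  s <- summary(fit)[[1L]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"],
                      significant = tk[, "p adj"] < alpha,
                      row.names = NULL)
  list(F = s[1L, "F value"], p = s[1L, "Pr(>F)"],
       df = c(between = s[1L, "Df"], within = s[2L, "Df"]),
       tukey = tukey, alpha = alpha)
}
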