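# Normalization, dispersion estimation and NB Wald testing for two-group
# count comparisons, plus correlation-based sample clustering. This is the
# differential-analysis stage of the pipeline, written out explicitly:
# median-of-ratios normalization, method-of-moments dispersion (no
# empirical-Bayes shrinkage toward a trend), and a delta-method Wald test
# on fold-changes of normalized group means.

counts_to_matrix <- function(counts, id_col = NULL) {
  if (!is.data.frame(counts)) cre_abort("`counts` must be a data frame.")
  id_col <- id_col %||% names(counts)[1]
  mat <- as.matrix(counts[, setdiff(names(counts), id_col), drop = FALSE])
  rownames(mat) <- counts[[id_col]]
  if (any(mat < 0) || any(mat != floor(mat))) {
    cre_abort("Counts must be nonnegative integers.")
  }
  storage.mode(mat) <- "double"
  mat
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over features (nonzero in
#' every sample) of that sample's count divided by the feature's geometric
#' mean across samples.
#'
#' @param counts Count tibble: feature-id column first, one column per
#'   sample.
#' @return Tibble `sample`, `size_factor`.
#' @export
size_factors <- function(counts) {
  mat <- counts_to_matrix(counts)
  keep <- rowSums(mat > 0) == ncol(mat)
  if (!any(keep)) {
    cre_abort("No feature is nonzero in all samples; size factors are undefined.")
  }
  loggeo <- rowMeans(log(mat[keep, , drop = FALSE]))
  sf <- apply(log(mat[keep, , drop = FALSE]) - loggeo, 2,
              function(x) exp(median(x)))
  tibble(sample = colnames(mat), size_factor = unname(sf))
}

normalized_counts <- function(mat, sf) {
  sweep(mat, 2, sf[colnames(mat)], `/`)
}

#' Method-of-moments dispersion estimates
#'
#' Per-feature NB dispersion alpha in the parameterization
#' variance = mu + alpha * mu^2, estimated on normalized counts as
#' `max((s2 - mu) / mu^2, floor)` with `s2` the within-group pooled sample
#' variance and `mu` the grand mean. The floor (1e-8) keeps downstream
#' standard errors finite for constant features.
#'
#' @param counts Count tibble.
#' @param samples Sample sheet tibble: `sample`, `group`.
#' @param factors Optional size-factor tibble from [size_factors()];
#'   computed if missing.
#' @param floor_value Lower bound for the estimate.
#' @return Tibble `feature_id`, `base_mean`, `dispersion`.
#' @export
estimate_dispersion <- function(counts, samples, factors = NULL,
                                floor_value = 1e-8) {
  check_columns(samples, c("sample", "group"), "samples")
  mat <- counts_to_matrix(counts)
  factors <- factors %||% size_factors(counts)
  sf <- setNames(factors$size_factor, factors$sample)
  norm <- normalized_counts(mat, sf)
  groups <- setNames(samples$group, samples$sample)[colnames(norm)]
  if (max(table(groups)) < 2) {
    cre_abort("At least one group needs 2 or more replicates.")
  }
  mu <- rowMeans(norm)
  ss <- 0
  df <- 0
  for (g in unique(groups)) {
    sub <- norm[, groups == g, drop = FALSE]
    if (ncol(sub) >= 2) {
      ss <- ss + rowSums((sub - rowMeans(sub))^2)
      df <- df + ncol(sub) - 1
    }
  }
  s2 <- ss / df
  alpha <- ifelse(mu > 0, (s2 - mu) / mu^2, 0)
  tibble(
    feature_id = rownames(mat),
    base_mean = unname(mu),
    dispersion = unname(pmax(alpha, floor_value))
  )
}

#' Negative-binomial Wald test between two groups
#'
#' Computes per-feature log2 fold-changes of normalized group means
#' (moderated by a +0.5 pseudocount) and a Wald test with a delta-method
#' standard error under the NB variance function
#' var = mu + alpha * mu^2, referred to a t distribution with the residual
#' degrees of freedom (samples in the contrast minus two) to account for
#' the sampling noise of the plug-in dispersion at small replicate
#' numbers. P-values are two-sided and BH-adjusted; a
#' feature is called differential when |log2FC| >= `lfc_threshold` and
#' FDR < `alpha_fdr` (post-hoc filter). Setting `shifted_null = TRUE`
#' instead tests the composite null |log2FC| <= `lfc_threshold` inside the
#' Wald statistic.
#'
#' @param counts Count tibble (feature-id column first).
#' @param samples Sample sheet tibble `sample`, `group`.
#' @param contrast Two group names `c(numerator, denominator)`: positive
#'   log2FC means higher in the numerator group.
#' @param factors,dispersions Optional precomputed [size_factors()] /
#'   [estimate_dispersion()] outputs.
#' @param lfc_threshold Absolute log2 fold-change required to call a
#'   feature (default 1).
#' @param alpha_fdr FDR cutoff for calling (default 0.05).
#' @param shifted_null Use the shifted-null Wald statistic instead of the
#'   post-hoc fold filter.
#' @return An object of class `cre_nb_fit`; use [tidy()] for the
#'   per-feature table (`feature_id`, `base_mean`, `log2fc`, `se`,
#'   `statistic`, `p_value`, `fdr`, `called`) and [glance()] for a one-row
#'   summary.
#' @export
nb_wald_test <- function(counts, samples, contrast,
                         factors = NULL, dispersions = NULL,
                         lfc_threshold = 1, alpha_fdr = 0.05,
                         shifted_null = FALSE) {
  check_columns(samples, c("sample", "group"), "samples")
  if (length(contrast) != 2) {
    cre_abort("`contrast` must name two groups.")
  }
  missing <- setdiff(contrast, samples$group)
  if (length(missing) > 0) {
    cre_abort(sprintf("Group(s) not present in the sample sheet: %s.",
                      paste(missing, collapse = ", ")))
  }
  mat <- counts_to_matrix(counts)
  factors <- factors %||% size_factors(counts)
  dispersions <- dispersions %||% estimate_dispersion(counts, samples, factors)
  sf <- setNames(factors$size_factor, factors$sample)
  norm <- normalized_counts(mat, sf)
  groups <- setNames(samples$group, samples$sample)[colnames(norm)]
  alpha <- setNames(dispersions$dispersion, dispersions$feature_id)[rownames(mat)]

  group_stats <- function(g) {
    idx <- which(groups == g)
    sub <- norm[, idx, drop = FALSE]
    mu <- rowMeans(sub)
    # delta-method variance of the mean of normalized NB counts:
    # Var(c_ij / s_j) = mu / s_j + alpha * mu^2
    v <- rowSums(outer(pmax(mu, 1e-8), 1 / sf[colnames(sub)]) +
                   alpha * pmax(mu, 1e-8)^2) / ncol(sub)^2
    list(mu = mu, var = v)
  }
  a <- group_stats(contrast[1])
  b <- group_stats(contrast[2])
  df <- sum(groups %in% contrast) - 2
  log2fc <- log2((a$mu + 0.5) / (b$mu + 0.5))
  se <- sqrt(a$var / (a$mu + 0.5)^2 + b$var / (b$mu + 0.5)^2) / log(2)
  if (shifted_null) {
    stat <- pmax(abs(log2fc) - lfc_threshold, 0) / se
    p <- pmin(2 * stats::pt(-stat, df = df), 1)
  } else {
    stat <- log2fc / se
    p <- 2 * stats::pt(-abs(stat), df = df)
  }
  res <- tibble(
    feature_id = rownames(mat),
    base_mean = rowMeans(norm),
    log2fc = log2fc,
    se = se,
    statistic = stat,
    p_value = p,
    fdr = p.adjust(p, method = "BH")
  )
  res$called <- if (shifted_null) {
    res$fdr < alpha_fdr
  } else {
    abs(res$log2fc) >= lfc_threshold & res$fdr < alpha_fdr
  }
  structure(
    list(
      results = res, contrast = contrast, size_factors = factors,
      dispersions = dispersions, lfc_threshold = lfc_threshold,
      alpha_fdr = alpha_fdr, shifted_null = shifted_null
    ),
    class = "cre_nb_fit"
  )
}

#' @export
print.cre_nb_fit <- function(x, ...) {
  cat(sprintf(
    "NB Wald test: %s vs %s; %d features, %d called (|log2FC| >= %g, FDR < %g)\n",
    x$contrast[1], x$contrast[2], nrow(x$results), sum(x$results$called),
    x$lfc_threshold, x$alpha_fdr
  ))
  print(x$results, ...)
  invisible(x)
}

#' @describeIn nb_wald_test Per-feature results table.
#' @param x A `cre_nb_fit` object.
#' @param ... Unused.
#' @export
tidy.cre_nb_fit <- function(x, ...) {
  x$results
}

#' @describeIn nb_wald_test One-row model summary.
#' @export
glance.cre_nb_fit <- function(x, ...) {
  tibble(
    n_features = nrow(x$results),
    n_called = sum(x$results$called),
    n_up = sum(x$results$called & x$results$log2fc > 0),
    n_down = sum(x$results$called & x$results$log2fc < 0),
    median_dispersion = median(x$dispersions$dispersion),
    lfc_threshold = x$lfc_threshold,
    alpha_fdr = x$alpha_fdr
  )
}

#' Correlation-based sample clustering
#'
#' Pearson correlation of log2(normalized count + 1) profiles between all
#' sample pairs, followed by average-linkage hierarchical clustering on the
#' 1 - r distance.
#'
#' @param counts Count tibble (e.g. counts at union peaks).
#' @param factors Optional [size_factors()] output.
#' @return An object of class `cre_sample_clust` with elements
#'   `correlation` (matrix), `hclust`, and `order` (leaf order); use
#'   [tidy()] for the pairwise-correlation table.
#' @export
cluster_samples <- function(counts, factors = NULL) {
  mat <- counts_to_matrix(counts)
  if (ncol(mat) < 2) cre_abort("At least two samples are required.")
  factors <- factors %||% size_factors(counts)
  sf <- setNames(factors$size_factor, factors$sample)
  lognorm <- log2(normalized_counts(mat, sf) + 1)
  sds <- apply(lognorm, 2, sd)
  if (any(sds == 0)) {
    cre_abort(sprintf(
      "Correlation undefined for constant sample(s): %s.",
      paste(colnames(mat)[sds == 0], collapse = ", ")
    ))
  }
  r <- cor(lognorm)
  hc <- hclust(stats::as.dist(1 - r), method = "average")
  structure(
    list(correlation = r, hclust = hc, order = hc$labels[hc$order]),
    class = "cre_sample_clust"
  )
}

#' @export
print.cre_sample_clust <- function(x, ...) {
  cat(sprintf("Sample clustering of %d samples (average linkage on 1 - Pearson r)\n",
              ncol(x$correlation)))
  cat("Leaf order:", paste(x$order, collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn cluster_samples Long pairwise-correlation table.
#' @param x A `cre_sample_clust` object.
#' @param ... Unused.
#' @export
tidy.cre_sample_clust <- function(x, ...) {
  r <- x$correlation
  as_tibble(as.data.frame.table(r, responseName = "correlation")) |>
    rename(sample1 = "Var1", sample2 = "Var2") |>
    mutate(sample1 = as.character(.data$sample1),
           sample2 = as.character(.data$sample2))
}

#' @describeIn cluster_samples One-row summary of the correlation range.
#' @export
glance.cre_sample_clust <- function(x, ...) {
  off <- x$correlation[lower.tri(x$correlation)]
  tibble(
    n_samples = ncol(x$correlation),
    min_correlation = min(off),
    max_correlation = max(off)
  )
}
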