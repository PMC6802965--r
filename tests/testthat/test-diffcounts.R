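test_that("size factors implement median-of-ratios exactly", {
  d <- two_group_counts(n_features = 50, seed = 2)
  same <- d$counts
  sf1 <- size_factors(same)
  # identical columns -> all factors equal (to 1 by the geometric reference)
  ident <- dplyr::bind_cols(
    tibble::tibble(feature_id = same$feature_id),
    tibble::as_tibble(matrix(rep(same[[2]], 4), ncol = 4,
                             dimnames = list(NULL, paste0("s", 1:4))))
  )
  expect_equal(size_factors(ident)$size_factor, rep(1, 4))
  # second sample = 2x first -> factors (1/sqrt(2), sqrt(2))
  twocol <- tibble::tibble(feature_id = same$feature_id,
                           s1 = same[[2]] + 1L, s2 = 2L * (same[[2]] + 1L))
  expect_equal(size_factors(twocol)$size_factor, c(1 / sqrt(2), sqrt(2)))
  # random matrix: factors equal the direct formula
  mat <- as.matrix(d$counts[, -1])
  keep <- rowSums(mat > 0) == ncol(mat)
  loggeo <- rowMeans(log(mat[keep, ]))
  direct <- apply(mat[keep, ], 2, function(col) exp(median(log(col) - loggeo)))
  expect_equal(sf1$size_factor, unname(direct))
  # all-zero-containing features only -> error
  allz <- tibble::tibble(feature_id = c("x", "y"), s1 = c(0L, 5L),
                         s2 = c(3L, 0L))
  expect_error(size_factors(allz), "nonzero")
})

test_that("size factors agree with the DESeq2 reference on a small matrix", {
  skip_if_not_installed("DESeq2")
  d <- two_group_counts(n_features = 100, seed = 3)
  mat <- as.matrix(d$counts[, -1])
  storage.mode(mat) <- "integer"
  ref <- DESeq2::estimateSizeFactorsForMatrix(mat)
  expect_equal(size_factors(d$counts)$size_factor, unname(ref),
               tolerance = 1e-8)
})

test_that("dispersion estimation floors constants and recovers the truth", {
  const <- tibble::tibble(feature_id = "c", s1 = 5L, s2 = 5L, s3 = 5L,
                          s4 = 5L)
  samples <- tibble::tibble(sample = paste0("s", 1:4),
                            group = c("a", "a", "b", "b"))
  disp <- estimate_dispersion(const, samples)
  expect_equal(disp$dispersion, 1e-8)
  # Poisson-simulated features: estimate ~ 0
  withr::with_seed(4, {
    pois <- dplyr::bind_cols(
      tibble::tibble(feature_id = sprintf("f%03d", 1:500)),
      tibble::as_tibble(matrix(stats::rpois(500 * 20, 200), 500, 20,
                               dimnames = list(NULL, paste0("s", 1:20))))
    )
  })
  samples20 <- tibble::tibble(sample = paste0("s", 1:20),
                              group = rep(c("a", "b"), each = 10))
  disp_p <- estimate_dispersion(pois, samples20)
  expect_lt(abs(mean(disp_p$dispersion)), 0.005)
  # NB at alpha = 0.1 with 50 replicates/group: mean estimate within 20%
  d <- two_group_counts(n_features = 500, nrep = 50, dispersion = 0.1,
                        seed = 5)
  disp_nb <- estimate_dispersion(d$counts, d$samples)
  expect_lt(abs(mean(disp_nb$dispersion) - 0.1), 0.02)
  expect_error(
    estimate_dispersion(const, tibble::tibble(sample = paste0("s", 1:4),
                                              group = letters[1:4])),
    "replicates"
  )
})

test_that("NB Wald test calls planted effects and respects thresholds", {
  d <- two_group_counts(n_features = 300, mu = 500, lfc = 3,
                        dispersion = 0.05, seed = 6)
  fit <- nb_wald_test(d$counts, d$samples, contrast = c("a", "b"))
  res <- tidy(fit)
  planted <- res$feature_id %in% d$planted
  expect_gt(mean(res$called[planted]), 0.95)
  expect_lt(mean(res$called[!planted]), 0.02)
  expect_gt(median(abs(res$log2fc[planted])), 2.5)
  # contrast orientation: swapping groups negates the fold-change
  fit_sw <- nb_wald_test(d$counts, d$samples, contrast = c("b", "a"))
  expect_equal(tidy(fit_sw)$log2fc, -res$log2fc)
  # threshold monotonicity: raising the fold threshold never adds calls
  fit_hi <- nb_wald_test(d$counts, d$samples, contrast = c("a", "b"),
                         lfc_threshold = 2)
  expect_true(all(tidy(fit_hi)$called <= res$called))
  # glance summarises the fit
  g <- glance(fit)
  expect_equal(g$n_features, 300)
  expect_equal(g$n_called, sum(res$called))
  expect_error(
    nb_wald_test(d$counts, d$samples, contrast = c("a", "zzz")),
    "zzz"
  )
})

test_that("null p-values are approximately uniform and calls near zero", {
  d <- two_group_counts(n_features = 2000, mu = 400, lfc = 0,
                        dispersion = 0.05, seed = 7)
  fit <- nb_wald_test(d$counts, d$samples, contrast = c("a", "b"))
  res <- tidy(fit)
  # permuted-label null: essentially nothing passes the 2-fold filter
  expect_lt(mean(res$called), 0.005)
  ks <- stats::ks.test(res$p_value, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("normalization is scale-invariant per sample", {
  d <- two_group_counts(n_features = 300, seed = 8)
  scaled <- d$counts
  scaled[[2]] <- scaled[[2]] * 3L
  sf0 <- size_factors(d$counts)$size_factor
  sf1 <- size_factors(scaled)$size_factor
  mat0 <- sweep(as.matrix(d$counts[, -1]), 2, sf0, "/")
  mat1 <- sweep(as.matrix(scaled[, -1]), 2, sf1, "/")
  # the geometric-mean reference shifts by 3^(1/n); relative profiles are
  # unchanged
  expect_equal(mat1, mat0 * 3^(1 / 8), tolerance = 1e-8)
  expect_equal(mat1 / rowMeans(mat1), mat0 / rowMeans(mat0),
               tolerance = 1e-8)
})

test_that("sample clustering separates planted classes deterministically", {
  cfg <- small_config(seed = 41, planted_lfc = 3, da_fraction = 0.3)
  peaks <- tibble::tibble(peak_id = sprintf("pk%04d", 1:500))
  sim <- simulate_atac_counts(peaks, cfg,
                              groups = c("photoreceptor", "bipolar"))
  cl <- cluster_samples(sim$counts)
  expect_s3_class(cl, "cre_sample_clust")
  # correlation matrix symmetric with unit diagonal
  expect_equal(cl$correlation, t(cl$correlation))
  expect_equal(unname(diag(cl$correlation)), rep(1, 8))
  # two planted classes -> perfect two-cluster split
  groups <- setNames(sim$samples$group, sim$samples$sample)
  split2 <- stats::cutree(cl$hclust, k = 2)
  expect_equal(length(unique(tapply(split2, groups[names(split2)], unique))), 2)
  # duplicated sample: r = 1 and merged first
  dup <- dplyr::mutate(sim$counts, dup_sample = sim$counts[[2]])
  cl_dup <- cluster_samples(dup)
  nm <- colnames(sim$counts)[2]
  expect_equal(cl_dup$correlation[nm, "dup_sample"], 1)
  first_merge <- cl_dup$hclust$labels[-cl_dup$hclust$merge[1, ]]
  expect_setequal(first_merge, c(nm, "dup_sample"))
  # constant sample errors with its name
  bad <- sim$counts
  bad[[3]] <- 7L
  expect_error(cluster_samples(bad), colnames(sim$counts)[3])
})
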