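test_that("genome generation is deterministic and honors composition", {
  cfg <- sim_config(genome_length = 1e5, n_chromosomes = 1,
                    background_composition = c(A = 0.25, C = 0.25,
                                               G = 0.25, T = 0.25),
                    seed = 1)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1, g2)
  expect_true(all(strsplit(g1$sequence, "")[[1]] %in% c("A", "C", "G", "T")))
  # each base frequency within 3 binomial SDs of 0.25
  freqs <- table(strsplit(g1$sequence, "")[[1]]) / 1e5
  tol <- 3 * sqrt(0.25 * 0.75 / 1e5)
  expect_true(all(abs(freqs - 0.25) < tol))
  expect_error(sim_config(genome_length = 0), "positive")
})

test_that("peak sets plant the configured grammar and record exact truth", {
  cfg <- small_config(seed = 3)
  ps <- simulate_peak_sets(cfg, simulate_genome(cfg))
  peaks <- ps$peaks
  # non-overlapping peaks, summit at midpoint
  by_chrom <- split(peaks, peaks$chrom)
  for (p in by_chrom) {
    p <- dplyr::arrange(p, start)
    expect_true(all(diff(p$start) >= (p$end - p$start)[-nrow(p)]))
  }
  expect_equal(peaks$summit,
               cregrammar:::midpoint_summit(peaks$start, peaks$end))
  # Q50 density is 0 in bipolar: truth holds no bipolar Q50 planting
  expect_equal(
    nrow(dplyr::filter(ps$truth, class == "bipolar", motif == "Q50_HD")), 0
  )
  # every planting lies within its peak
  tr <- dplyr::left_join(ps$truth, peaks, by = c("peak_id", "class"))
  pos <- tr$offset + tr$summit
  expect_true(all(pos >= 0 & pos < tr$end - tr$start))
  # K50 planted at density 2/peak across 4 classes differs per class;
  # check total against a Poisson bound for the configured densities
  dens <- default_motif_densities()
  expected_k50 <- sum(vapply(dens, `[[`, numeric(1), "K50_HD")) *
    cfg$n_peaks_per_class
  n_k50 <- nrow(dplyr::filter(ps$truth, motif == "K50_HD"))
  expect_lt(abs(n_k50 - expected_k50), 3 * sqrt(expected_k50))
  # re-scan: every planted occurrence recovered by the scanner
  occ <- scan_motifs(peak_sequences(peaks, ps$genome))
  key <- function(d) paste(d$peak_id, d$motif, d$offset, d$strand)
  expect_true(all(key(ps$truth) %in% key(occ)))
})

test_that("peak demand beyond genome capacity errors", {
  cfg <- sim_config(genome_length = 2e4, n_peaks_per_class = 500, seed = 1)
  expect_error(simulate_peak_sets(cfg, simulate_genome(cfg)), "capacity")
})

test_that("ATAC counts carry planted fold-changes and NB moments", {
  cfg <- sim_config(genome_length = 1e5, n_peaks_per_class = 10,
                    n_genes = 10, seed = 5, da_fraction = 0,
                    nb_dispersion = 1e-13, nb_mean_range = c(500, 500),
                    n_replicates = 40)
  peaks <- tibble::tibble(peak_id = sprintf("pk%03d", 1:400))
  sim <- simulate_atac_counts(peaks, cfg)
  expect_identical(sim$counts,
                   simulate_atac_counts(peaks, cfg)$counts)
  # lfc = 0 everywhere: group means equal in expectation
  expect_equal(nrow(sim$truth), 0)
  expect_equal(sim$means$photoreceptor, sim$means$bipolar)
  # dispersion -> 0 limit: variance ~ mean (Poisson) on normalized counts
  mat <- as.matrix(sim$counts[, -1])
  sf <- size_factors(sim$counts)
  norm <- sweep(mat, 2, sf$size_factor, "/")
  ratio <- apply(norm, 1, var) / rowMeans(norm)
  expect_lt(abs(mean(ratio) - 1), 0.05)
  # moment-estimated dispersion on null features ~ configured dispersion
  cfg2 <- sim_config(seed = 6, da_fraction = 0, nb_dispersion = 0.1,
                     nb_mean_range = c(200, 2000), n_replicates = 50,
                     n_genes = 10)
  sim2 <- simulate_atac_counts(tibble::tibble(
    peak_id = sprintf("pk%04d", 1:2000)
  ), cfg2)
  disp <- estimate_dispersion(sim2$counts, sim2$samples)
  expect_lt(abs(mean(disp$dispersion) - 0.1), 0.02)
  expect_error(
    simulate_atac_counts(peaks, sim_config(n_replicates = 1)),
    "replicates"
  )
})

test_that("RNA counts plant contamination as configured", {
  cfg0 <- small_config(seed = 9, contamination_fraction = 0)
  sim0 <- simulate_rna_counts(cfg0)
  con <- sim0$truth$contaminant_genes
  m0 <- sim0$means[match(con, sim0$means$gene_id), ]
  expect_true(all(m0$pan_bc == 0))
  cfg <- small_config(seed = 9, contamination_fraction = 0.05)
  sim <- simulate_rna_counts(cfg)
  m <- sim$means[match(sim$truth$contaminant_genes, sim$means$gene_id), ]
  expect_equal(m$pan_bc, 0.05 * m$rod)
  # planted sets disjoint
  expect_length(
    intersect(sim$truth$planted_de$gene_id, sim$truth$contaminant_genes), 0
  )
})

test_that("single-cell matrix is clustered, deterministic, bulk-consistent", {
  cfg <- small_config(seed = 13, n_genes = 200, n_cells_per_cluster = 50,
                      sc_cluster_jitter_sd = 0)
  sc <- simulate_single_cell(cfg)
  expect_identical(sc$counts, simulate_single_cell(cfg)$counts)
  expect_equal(nrow(sc$cell_clusters), 6 * 50)
  # all clusters share one mean vector -> pseudo-bulk matches it closely
  cfg_flat <- small_config(seed = 13, n_genes = 200, de_fraction = 0,
                           n_cells_per_cluster = 100,
                           sc_cluster_jitter_sd = 0)
  scf <- simulate_single_cell(cfg_flat)
  pb <- pseudobulk_counts(scf$counts, scf$cell_clusters, scf$populations)
  mu <- scf$cluster_means[[2]]  # identical across clusters here
  expect_gt(cor(pb$pan, mu), 0.99)
  # pseudo-bulk of planted clusters vs planted bulk means: Pearson > 0.95
  pb2 <- pseudobulk_counts(sc$counts, sc$cell_clusters, sc$populations)
  r <- compare_bulk_pseudobulk(sc$population_means, pb2)
  self <- dplyr::filter(r, bulk_population == pseudo_population)
  expect_true(all(self$pearson > 0.95))
  expect_error(simulate_single_cell(cfg, clusters = c(one = "ON")),
               "two clusters")
  expect_error(
    simulate_single_cell(small_config(n_cells_per_cluster = 0)),
    "at least one cell"
  )
})
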