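presence_fixture <- function(n, probs, seed = 1) {
  withr::with_seed(seed, {
    out <- tibble::tibble(peak_id = sprintf("p%04d", seq_len(n)))
    for (m in names(probs)) {
      out[[m]] <- stats::runif(n) < probs[[m]]
    }
    out
  })
}

test_that("dinucleotide shuffle preserves composition and dinucleotides", {
  set.seed(31)
  s <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE), collapse = "")
  sh <- shuffle_dinucleotides(s)
  expect_equal(nchar(sh), nchar(s))
  dinucs <- function(x) {
    ch <- strsplit(x, "")[[1]]
    sort(paste0(ch[-length(ch)], ch[-1]))
  }
  expect_equal(dinucs(sh), dinucs(s))
  expect_false(sh == s)  # astronomically unlikely to be unchanged
})

test_that("enrichment against background behaves at the boundaries", {
  pres <- presence_fixture(200, c(M1 = 0, M2 = 0.5, M3 = 0.5), seed = 2)
  bg <- presence_fixture(200, c(M1 = 0, M2 = 0.5, M3 = 0.1), seed = 3)
  res <- motif_enrichment(pres, bg)
  # absent from peaks and background -> p = 1
  expect_equal(res$p_value[res$motif == "M1"], 1)
  # proportion equal to background -> non-significant
  expect_gt(res$p_value[res$motif == "M2"], 0.05)
  # genuinely enriched motif ranks first
  expect_equal(res$motif[1], "M3")
  expect_lt(res$fdr[1], 0.05)
  expect_error(motif_enrichment(pres[0, ], bg), "Empty")
})

test_that("planted K50-rich peaks rank K50 first against shuffled background", {
  cfg <- small_config(seed = 33)
  ps <- simulate_peak_sets(cfg, simulate_genome(cfg))
  pr <- dplyr::filter(ps$peaks, class == "photoreceptor")
  seqs <- peak_sequences(pr, ps$genome)
  bg_seqs <- seqs |>
    dplyr::mutate(sequence = shuffle_dinucleotides(sequence))
  motifs <- cre_motifs()
  pres <- motif_presence(scan_motifs(seqs, motifs), seqs$peak_id,
                         motifs$motif)
  bg <- motif_presence(scan_motifs(bg_seqs, motifs), seqs$peak_id,
                       motifs$motif)
  res <- motif_enrichment(pres, bg)
  expect_equal(res$motif[1], "K50_HD")
  expect_lt(res$fdr[res$motif == "K50_HD"], 0.01)
})

test_that("differential enrichment equals the pooled-proportion formula", {
  mk <- function(x, n) {
    tibble::tibble(peak_id = sprintf("q%04d", seq_len(n)),
                   M = seq_len(n) <= x)
  }
  # equal proportions: z = 0, p = 1
  res0 <- diff_motif_enrichment(mk(50, 100), mk(50, 100))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  # 60/100 vs 40/100 against the hand formula
  res <- diff_motif_enrichment(mk(60, 100), mk(40, 100))
  oracle <- prop_z_oracle(60, 100, 40, 100)
  expect_equal(res$statistic, oracle$z)
  expect_equal(res$p_value, oracle$p)
  expect_error(diff_motif_enrichment(mk(5, 10)[0, ], mk(5, 10)), "nonempty")
})

test_that("two-proportion test type-I error is near nominal", {
  set.seed(35)
  n_sim <- 2000
  alpha <- 0.05
  rejections <- vapply(seq_len(n_sim), function(i) {
    xa <- stats::rbinom(1, 150, 0.4)
    xb <- stats::rbinom(1, 150, 0.4)
    pooled <- (xa + xb) / 300
    if (pooled <= 0 || pooled >= 1) return(FALSE)
    z <- (xa / 150 - xb / 150) /
      sqrt(pooled * (1 - pooled) * (2 / 150))
    2 * stats::pnorm(-abs(z)) < alpha
  }, logical(1))
  se <- sqrt(alpha * (1 - alpha) / n_sim)
  expect_lt(abs(mean(rejections) - alpha), 3 * se)
})

test_that("density profile obeys its defining formula and conserves counts", {
  # every one of 1000 peaks has one occurrence at offset 0, 1 bp bins
  occ <- tibble::tibble(motif = "M", peak_id = sprintf("p%04d", 1:1000),
                        offset = 0L, strand = "+")
  prof <- motif_density_profile(occ, n_peaks = 1000, window = 10, bin = 1)
  # 1000 motifs in a 1 bp bin over 1000 peaks = 1000 motifs/bp/1000 peaks
  expect_equal(prof$density[prof$bin_start == 0],
               1000 / (1 * 1000 / 1000))
  expect_equal(sum(prof$density * 1 * 1000 / 1000), 1000)
  # conservation: sum(density * bin * n_peaks / 1000) = in-window total
  set.seed(36)
  occ2 <- tibble::tibble(
    motif = "M", peak_id = sample(sprintf("p%03d", 1:500), 3000, TRUE),
    offset = sample(-600:600, 3000, TRUE), strand = "+"
  )
  prof2 <- motif_density_profile(occ2, n_peaks = 500, window = 1000, bin = 25)
  expect_equal(sum(prof2$density) * 25 * 500 / 1000,
               sum(occ2$offset >= -500 & occ2$offset < 500))
  # uniform planting -> approximately flat profile
  expect_lt(sd(prof2$density) / mean(prof2$density), 0.25)
  expect_error(motif_density_profile(occ, n_peaks = 0), "positive")
  expect_error(motif_density_profile(occ, n_peaks = 10, window = 11), "even")
})

test_that("co-occurrence enrichment follows the log2((obs+1)/(exp+1)) formula", {
  # N=100, n1=50, n2=40, obs=20: expected = 20, enrichment 0
  pres <- tibble::tibble(
    peak_id = sprintf("p%03d", 1:100),
    A = c(rep(TRUE, 50), rep(FALSE, 50)),
    B = c(rep(TRUE, 20), rep(FALSE, 30), rep(TRUE, 20), rep(FALSE, 30))
  )
  res <- cooccurrence_enrichment(pres)
  expect_equal(res$expected, 20)
  expect_equal(res$observed, 20)
  expect_equal(res$log2_enrichment, 0)
  # obs=39, exp=19 -> log2(40/20) = 1
  pres2 <- tibble::tibble(
    peak_id = sprintf("p%03d", 1:100),
    A = rep(c(TRUE, FALSE), c(95, 5)),
    B = c(rep(TRUE, 39), FALSE, rep(c(TRUE, FALSE), c(0, 60)))
  )
  n1 <- sum(pres2$A); n2 <- sum(pres2$B)
  obs <- sum(pres2$A & pres2$B)
  res2 <- cooccurrence_enrichment(pres2)
  expect_equal(res2$observed, obs)
  expect_equal(res2$log2_enrichment,
               log2((obs + 1) / (n1 * n2 / 100 + 1)))
})

test_that("differential co-occurrence matches a hypergeometric oracle", {
  mk <- function(n_both, n) {
    tibble::tibble(peak_id = sprintf("p%03d", seq_len(n)),
                   A = c(rep(TRUE, n_both), rep(FALSE, n - n_both)),
                   B = c(rep(TRUE, n_both), rep(FALSE, n - n_both)))
  }
  # identical proportions -> p = 1
  res0 <- diff_cooccurrence(mk(5, 10), mk(5, 10))
  expect_equal(res0$p_value, 1)
  # table (8,2; 2,8) against the exhaustive hypergeometric tail sum
  res <- diff_cooccurrence(mk(8, 10), mk(2, 10))
  expect_equal(res$p_value, fisher_oracle(8, 2, 2, 8))
  # symmetry under swapping the sets
  res_sw <- diff_cooccurrence(mk(2, 10), mk(8, 10))
  expect_equal(res_sw$p_value, res$p_value)
})

test_that("BH adjustment is monotone in the raw p-values", {
  pres_a <- presence_fixture(150, c(M1 = 0.6, M2 = 0.4, M3 = 0.5, M4 = 0.3),
                             seed = 4)
  pres_b <- presence_fixture(150, c(M1 = 0.3, M2 = 0.45, M3 = 0.5, M4 = 0.6),
                             seed = 5)
  res <- diff_motif_enrichment(pres_a, pres_b) |> dplyr::arrange(p_value)
  expect_true(all(diff(res$fdr) >= -1e-12))
  expect_equal(res$fdr, p.adjust(res$p_value, method = "BH"))
})

test_that("spacing profile localizes pairs and mirrors under reflection", {
  anchors <- tibble::tibble(peak_id = "p1", motif = "A", offset = 0L,
                            strand = "+")
  second <- tibble::tibble(peak_id = "p1", motif = "B", offset = 10L,
                           strand = "+")
  prof <- spacing_profile(anchors, second, window = 100, bin = 5)
  spike <- dplyr::filter(prof, count > 0)
  expect_equal(nrow(spike), 1)
  expect_equal(spike$orientation, "same")
  expect_equal(spike$bin_start, 10)
  # anchor on the minus strand: orientation-normalized offset negates
  anchors_m <- dplyr::mutate(anchors, strand = "-")
  prof_m <- spacing_profile(anchors_m, second, window = 100, bin = 5)
  spike_m <- dplyr::filter(prof_m, count > 0)
  expect_equal(spike_m$bin_start, -10)
  expect_equal(spike_m$orientation, "opposite")
  # self-pairs at offset 0 excluded
  prof_self <- spacing_profile(anchors, anchors, window = 100, bin = 5)
  expect_equal(sum(prof_self$count), 0)
  # uniform secondaries -> flat on both strands (chi-square GOF sanity)
  set.seed(37)
  anch <- tibble::tibble(peak_id = sprintf("p%03d", 1:200), motif = "A",
                         offset = 0L, strand = "+")
  sec <- tibble::tibble(
    peak_id = rep(anch$peak_id, each = 10), motif = "B",
    offset = sample(-100:99, 2000, TRUE),
    strand = sample(c("+", "-"), 2000, TRUE)
  )
  prof_u <- spacing_profile(anch, sec, window = 200, bin = 20)
  counts <- prof_u$count
  chisq <- sum((counts - mean(counts))^2 / mean(counts))
  expect_lt(chisq, qchisq(0.999, length(counts) - 1))
})
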