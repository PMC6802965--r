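# Shared fixtures and independent oracles, all built in code.

# Small simulation config used across tests (fast but non-trivial).
small_config <- function(seed = 11, n_genes = 400, ...) {
  sim_config(
    genome_length = 3e5, n_peaks_per_class = 50, n_genes = n_genes,
    seed = seed, ...
  )
}

random_peaks <- function(n, chroms = c("chrA", "chrB"), max_pos = 5000,
                         max_width = 120) {
  start <- sample.int(max_pos, n, replace = TRUE)
  width <- sample.int(max_width, n, replace = TRUE)
  tibble::tibble(
    peak_id = sprintf("p%03d", seq_len(n)),
    chrom = sample(chroms, n, replace = TRUE),
    start = start, end = start + width
  ) |>
    dplyr::mutate(summit = cregrammar:::midpoint_summit(start, end)) |>
    dplyr::distinct(chrom, start, end, .keep_all = TRUE)
}

# Base-wise oracle: number of covered bases per chromosome.
coverage_oracle <- function(peaks) {
  sum(vapply(split(peaks, peaks$chrom), function(p) {
    covered <- logical(max(p$end))
    for (i in seq_len(nrow(p))) {
      covered[(p$start[i] + 1):p$end[i]] <- TRUE
    }
    sum(covered)
  }, numeric(1)))
}

# Base-wise oracle for >= 1 bp interval overlap.
overlaps_any_oracle <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    hit <- b$chrom == a$chrom[i] & b$start < a$end[i] & b$end > a$start[i]
    any(hit)
  }, logical(1))
}

# Exhaustive nearest-TSS search (summit-anchored, lexicographic ties).
nearest_tss_oracle <- function(peaks, tss) {
  vapply(seq_len(nrow(peaks)), function(i) {
    cand <- tss[tss$chrom == peaks$chrom[i], ]
    if (nrow(cand) == 0) return(NA_character_)
    pos <- peaks$start[i] + peaks$summit[i]
    d <- abs(cand$tss - pos)
    best <- cand[d == min(d), ]
    sort(best$gene_id)[1]
  }, character(1))
}

# Regex-style two-strand motif enumeration oracle (left-anchored offsets,
# palindromes collapsed to "+").
iupac_regex <- function(consensus) {
  codes <- list(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
                S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]", B = "[CGT]",
                D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  paste(vapply(strsplit(consensus, "")[[1]], function(ch) codes[[ch]],
               character(1)), collapse = "")
}

scan_oracle <- function(sequence, consensus, summit) {
  hits_at <- function(pattern) {
    re <- paste0("(?=", iupac_regex(pattern), ")")
    m <- gregexpr(re, sequence, perl = TRUE)[[1]]
    if (m[1] == -1) integer(0) else as.integer(m) - 1L
  }
  fwd <- tibble::tibble(offset = hits_at(consensus) - summit, strand = "+")
  rc <- cregrammar::revcomp_iupac(consensus)
  if (identical(rc, consensus)) {
    return(fwd)
  }
  rev <- tibble::tibble(offset = hits_at(rc) - summit, strand = "-")
  dplyr::bind_rows(fwd, rev)
}

# Exhaustive hypergeometric two-sided Fisher p for a 2x2 table
# (a, b; c, d) with rows = sets, cols = pair present / absent.
fisher_oracle <- function(a, b, c, d) {
  m <- a + c      # total "present"
  n <- b + d      # total "absent"
  k <- a + b      # size of set one
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Two-group NB count fixture; a fraction of features carries a planted
# fold-change (random sign), the rest are null.
two_group_counts <- function(n_features = 200, nrep = 4, mu = 500,
                             dispersion = 0.05, lfc = 0, frac = 0.3,
                             seed = 1, groups = c("a", "b")) {
  withr::with_seed(seed, {
    ids <- sprintf("f%04d", seq_len(n_features))
    planted <- if (lfc != 0) sort(sample.int(n_features, round(frac * n_features))) else integer(0)
    sign <- sample(c(-1, 1), length(planted), replace = TRUE)
    lfc_vec <- rep(0, n_features)
    lfc_vec[planted] <- sign * lfc
    mu_a <- mu * 2^(lfc_vec / 2)
    mu_b <- mu * 2^(-lfc_vec / 2)
    mk <- function(m, nrep) {
      matrix(stats::rnbinom(n_features * nrep, mu = m, size = 1 / dispersion),
             n_features, nrep)
    }
    mat <- cbind(mk(mu_a, nrep), mk(mu_b, nrep))
    rownames(mat) <- ids
    colnames(mat) <- c(sprintf("%s_r%d", groups[1], 1:nrep),
                       sprintf("%s_r%d", groups[2], 1:nrep))
    list(
      counts = dplyr::bind_cols(tibble::tibble(feature_id = ids),
                                tibble::as_tibble(mat)),
      samples = tibble::tibble(sample = colnames(mat),
                               group = rep(groups, each = nrep)),
      planted = ids[planted],
      planted_sign = sign
    )
  })
}

# Hand pooled-proportion z-test oracle.
prop_z_oracle <- function(xa, na, xb, nb) {
  p <- (xa + xb) / (na + nb)
  z <- (xa / na - xb / nb) / sqrt(p * (1 - p) * (1 / na + 1 / nb))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}
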