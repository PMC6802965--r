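# Synthetic-data generators. Every generator is a pure function of
# (config, seed): stage-specific sub-seeds are derived deterministically
# from config$seed, so identical configs give bit-identical outputs and
# stages stay decoupled.

#' Simulation configuration
#'
#' Assembles and validates the configuration shared by all synthetic-data
#' generators. Defaults describe a desk-scale version of a two-cell-class
#' open-chromatin study: a random dinucleotide-free genome, four peak
#' classes (photoreceptor, bipolar, shared, and a brain control) carrying a
#' class-specific motif grammar, negative-binomial count matrices with
#' planted differential features, photoreceptor contamination spiked into
#' bipolar RNA samples, and a clustered single-cell matrix.
#'
#' @param genome_length Total genome length in bp.
#' @param n_chromosomes Number of chromosomes the genome is split into.
#' @param n_peaks_per_class Peaks per peak class.
#' @param peak_width Peak width in bp.
#' @param motif_densities Named list: class -> named numeric vector of
#'   expected motif occurrences per peak, keyed by motif name from
#'   [cre_motifs()]. The default grammar plants K50 sites in both cell
#'   classes, Q50 sites only in photoreceptor peaks, E-boxes preferentially
#'   in bipolar peaks, and CTCF sites in shared/ubiquitous peaks.
#' @param background_composition Named nucleotide frequencies (A, C, G, T),
#'   summing to 1.
#' @param nb_mean_range Range of baseline feature means (counts); drawn
#'   log-uniformly.
#' @param nb_dispersion NB dispersion alpha in the parameterization
#'   variance = mu + alpha * mu^2.
#' @param planted_lfc Absolute log2 fold-change planted into differential
#'   features.
#' @param da_fraction,de_fraction Fraction of features planted as
#'   differentially accessible / expressed.
#' @param contamination_fraction Proportion of the photoreceptor mean
#'   spiked into bipolar samples for contaminant genes.
#' @param contaminant_gene_fraction Fraction of genes that are
#'   photoreceptor-specific contaminants.
#' @param n_genes Number of genes for expression matrices.
#' @param n_replicates Replicates per group in bulk count matrices.
#' @param n_cells_per_cluster Cells per single-cell cluster.
#' @param sc_depth_factor Scale from bulk means to per-cell means.
#' @param sc_cluster_jitter_sd Lognormal sd of per-cluster deviation from
#'   its population's mean profile (0 = clusters share the population
#'   mean).
#' @param seed Integer seed; the single source of randomness.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 2e6,
                       n_chromosomes = 2,
                       n_peaks_per_class = 300,
                       peak_width = 500,
                       motif_densities = default_motif_densities(),
                       background_composition = c(A = 0.29, C = 0.21,
                                                  G = 0.21, T = 0.29),
                       nb_mean_range = c(50, 2000),
                       nb_dispersion = 0.05,
                       planted_lfc = 2,
                       da_fraction = 0.1,
                       de_fraction = 0.1,
                       contamination_fraction = 0.05,
                       contaminant_gene_fraction = 0.05,
                       n_genes = 2000,
                       n_replicates = 4,
                       n_cells_per_cluster = 200,
                       sc_depth_factor = 0.02,
                       sc_cluster_jitter_sd = 0.1,
                       seed = 1L) {
  config <- list(
    genome_length = genome_length, n_chromosomes = n_chromosomes,
    n_peaks_per_class = n_peaks_per_class, peak_width = peak_width,
    motif_densities = motif_densities,
    background_composition = background_composition,
    nb_mean_range = nb_mean_range, nb_dispersion = nb_dispersion,
    planted_lfc = planted_lfc, da_fraction = da_fraction,
    de_fraction = de_fraction,
    contamination_fraction = contamination_fraction,
    contaminant_gene_fraction = contaminant_gene_fraction,
    n_genes = n_genes, n_replicates = n_replicates,
    n_cells_per_cluster = n_cells_per_cluster,
    sc_depth_factor = sc_depth_factor,
    sc_cluster_jitter_sd = sc_cluster_jitter_sd,
    seed = as.integer(seed)
  )
  if (genome_length <= 0) cre_abort("`genome_length` must be positive.")
  if (n_peaks_per_class < 0 || n_genes < 0 || n_cells_per_cluster < 0 ||
      n_replicates < 0) {
    cre_abort("Counts in the configuration must be nonnegative.")
  }
  if (nb_dispersion <= 0) cre_abort("`nb_dispersion` must be positive.")
  if (any(unlist(motif_densities) < 0)) {
    cre_abort("Motif densities must be nonnegative.")
  }
  comp <- background_composition
  if (!setequal(names(comp), c("A", "C", "G", "T")) ||
      abs(sum(comp) - 1) > 1e-6 || any(comp < 0)) {
    cre_abort("`background_composition` must be named A/C/G/T frequencies summing to 1.")
  }
  if (contamination_fraction < 0 || contamination_fraction > 1) {
    cre_abort("`contamination_fraction` must lie in [0, 1].")
  }
  structure(config, class = "sim_config")
}

#' Default class-specific motif planting densities
#'
#' Expected occurrences per peak of each built-in motif in each peak class.
#' K50 homeodomain sites are planted in both cell classes, Q50 sites only
#' in photoreceptor peaks, E-boxes preferentially in bipolar peaks, and
#' CTCF sites mainly in shared and control (ubiquitously open) peaks.
#'
#' @return Named list of named numeric vectors.
#' @export
default_motif_densities <- function() {
  list(
    photoreceptor = c(K50_HD = 2, Q50_HD = 1.5, Ebox = 0.3, CTCF = 0.05,
                      NR_halfsite = 0.3, MADS = 0.1),
    bipolar = c(K50_HD = 2, Q50_HD = 0, Ebox = 1.5, CTCF = 0.05,
                NR_halfsite = 0.3, MADS = 0.1),
    shared = c(K50_HD = 1.5, Q50_HD = 0.5, Ebox = 0.8, CTCF = 1,
               NR_halfsite = 0.2, MADS = 0.1),
    brain = c(K50_HD = 0.1, Q50_HD = 0.1, Ebox = 0.5, CTCF = 1,
              NR_halfsite = 0.2, MADS = 0.3)
  )
}

#' Generate a random genome
#'
#' Draws i.i.d. nucleotides at the configured background composition,
#' split evenly across chromosomes.
#'
#' @param config A [sim_config()].
#' @return Tibble with columns `chrom`, `length`, `sequence`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$genome_length <= 0) cre_abort("`genome_length` must be positive.")
  withr::with_seed(stage_seed(config$seed, "genome"), {
    lens <- rep(config$genome_length %/% config$n_chromosomes,
                config$n_chromosomes)
    lens[1] <- lens[1] + config$genome_length %% config$n_chromosomes
    comp <- config$background_composition[c("A", "C", "G", "T")]
    tibble(
      chrom = sprintf("chr%d", seq_along(lens)),
      length = as.integer(lens),
      sequence = vapply(lens, function(L) {
        paste(sample(names(comp), L, replace = TRUE, prob = comp),
              collapse = "")
      }, character(1))
    )
  })
}

#' Generate per-class peak sets with a planted motif grammar
#'
#' Places non-overlapping fixed-width peaks for each class of the
#' configured grammar, plants motif instances (Poisson counts at the
#' class-specific density, uniform positions within the central 80% of the
#' peak, random strand) into the genome sequence, and records every
#' planting in a ground-truth table. Summits are interval midpoints.
#'
#' @param config A [sim_config()].
#' @param genome Genome tibble from [simulate_genome()].
#' @param motifs Motif tibble (`motif`, `consensus`) the density names
#'   refer to; defaults to the built-in set.
#' @return A list: `peaks` (tibble `peak_id`, `class`, `chrom`, `start`,
#'   `end`, `summit`), `genome` (sequences with motifs written in), and
#'   `truth` (tibble `peak_id`, `class`, `motif`, `offset` from summit,
#'   `strand`, `instance`).
#' @export
simulate_peak_sets <- function(config, genome, motifs = cre_motifs()) {
  stopifnot(inherits(config, "sim_config"))
  check_columns(genome, c("chrom", "sequence"), "genome")
  check_columns(motifs, c("motif", "consensus"), "motifs")
  classes <- names(config$motif_densities)
  if (length(classes) < 2) {
    cre_abort("The grammar must define at least two peak classes.")
  }
  w <- config$peak_width
  gap <- 50L
  slot_w <- w + gap
  n_total <- length(classes) * config$n_peaks_per_class
  lens <- nchar(genome$sequence)
  slots_per_chrom <- lens %/% slot_w
  if (sum(slots_per_chrom) < n_total) {
    cre_abort(sprintf(
      "Requested %d peaks of width %d exceed genome capacity (%d slots).",
      n_total, w, sum(slots_per_chrom)
    ))
  }
  withr::with_seed(stage_seed(config$seed, "peaks"), {
    slot_tbl <- purrr::map_dfr(seq_len(nrow(genome)), function(i) {
      tibble(chrom = genome$chrom[i], slot = seq_len(slots_per_chrom[i]))
    })
    chosen <- slot_tbl[sort(sample.int(nrow(slot_tbl), n_total)), ]
    chosen$class <- sample(rep(classes, config$n_peaks_per_class))
    peaks <- chosen |>
      group_by(.data$class) |>
      mutate(peak_id = sprintf("%s_%04d", .data$class, dplyr::row_number())) |>
      ungroup() |>
      mutate(
        start = (.data$slot - 1L) * slot_w + gap %/% 2L,
        end = .data$start + w,
        summit = midpoint_summit(.data$start, .data$end)
      ) |>
      select("peak_id", "class", "chrom", "start", "end", "summit") |>
      arrange(.data$chrom, .data$start)

    chars <- lapply(genome$sequence, function(s) strsplit(s, "")[[1]])
    names(chars) <- genome$chrom
    lo <- ceiling(0.1 * w)
    truth <- vector("list", nrow(peaks))
    for (i in seq_len(nrow(peaks))) {
      pk <- peaks[i, ]
      dens <- config$motif_densities[[pk$class]]
      occupied <- integer(0)
      rows <- list()
      for (m in names(dens)) {
        if (dens[[m]] <= 0) next
        info <- motifs[motifs$motif == m, ]
        if (nrow(info) == 0) {
          cre_abort(sprintf("Density refers to unknown motif '%s'.", m))
        }
        len <- nchar(info$consensus)
        hi <- floor(0.9 * w) - len
        k <- rpois(1, dens[[m]])
        if (k == 0 || hi < lo) next
        for (j in seq_len(k)) {
          pos <- NA_integer_
          for (try in 1:100) {
            cand <- sample(lo:hi, 1)
            if (!any((cand:(cand + len - 1)) %in% occupied)) {
              pos <- cand
              break
            }
          }
          if (is.na(pos)) next  # peak too crowded; skip this planting
          occupied <- c(occupied, pos:(pos + len - 1))
          pal <- is_palindromic(info$consensus)
          strand <- if (pal) "+" else sample(c("+", "-"), 1)
          inst <- realize_iupac(info$consensus)
          written <- if (strand == "-") revcomp_iupac(inst) else inst
          g0 <- pk$start + pos  # 0-based genomic start of the instance
          chars[[pk$chrom]][(g0 + 1):(g0 + len)] <- strsplit(written, "")[[1]]
          rows[[length(rows) + 1]] <- tibble(
            peak_id = pk$peak_id, class = pk$class, motif = m,
            offset = as.integer(pos - pk$summit), strand = strand,
            instance = written
          )
        }
      }
      truth[[i]] <- bind_rows(rows)
    }
    genome$sequence <- vapply(genome$chrom, function(ch) {
      paste(chars[[ch]], collapse = "")
    }, character(1), USE.NAMES = FALSE)
    list(peaks = peaks, genome = genome, truth = bind_rows(truth))
  })
}

#' Extract peak sequences from a genome
#'
#' @param peaks Peak tibble (`peak_id`, `chrom`, `start`, `end`, `summit`).
#' @param genome Genome tibble (`chrom`, `sequence`).
#' @return Tibble `peak_id`, `sequence`, `summit` suitable for
#'   [scan_motifs()].
#' @export
peak_sequences <- function(peaks, genome) {
  check_peaks(peaks)
  check_columns(peaks, c("peak_id", "summit"))
  check_columns(genome, c("chrom", "sequence"), "genome")
  seqs <- setNames(genome$sequence, genome$chrom)
  tibble(
    peak_id = peaks$peak_id,
    sequence = substr(seqs[peaks$chrom], peaks$start + 1, peaks$end),
    summit = peaks$summit
  )
}

# Draw an NB (or Poisson in the zero-dispersion limit) count matrix around
# a features x samples mean matrix.
draw_counts <- function(mu, dispersion) {
  n <- length(mu)
  counts <- if (dispersion < 1e-12) {
    rpois(n, lambda = mu)
  } else {
    rnbinom(n, mu = mu, size = 1 / dispersion)
  }
  matrix(counts, nrow = nrow(mu), dimnames = dimnames(mu))
}

base_means <- function(n, range) {
  exp(runif(n, log(range[1]), log(range[2])))
}

counts_tibble <- function(mat, id_col = "feature_id") {
  out <- as_tibble(mat)
  out <- bind_cols(tibble(!!id_col := rownames(mat)), out)
  out
}

#' Generate an ATAC-seq-like count matrix with planted differential peaks
#'
#' Draws negative-binomial counts for each peak across replicated groups.
#' A random `da_fraction` of peaks is planted as differentially accessible
#' with expected |log2 fold-change| equal to `planted_lfc` (split
#' symmetrically around the baseline mean); all other peaks share a common
#' mean across groups. Per-sample library-size factors are drawn uniformly
#' in [0.7, 1.4].
#'
#' @param peaks Peak tibble (or any tibble with a `peak_id` column).
#' @param config A [sim_config()].
#' @param groups Two group labels.
#' @return List: `counts` (tibble `feature_id` + one column per sample),
#'   `samples` (tibble `sample`, `group`), `truth` (tibble `feature_id`,
#'   `sign`, `lfc` for planted peaks), `means` (true group means).
#' @export
simulate_atac_counts <- function(peaks, config,
                                 groups = c("photoreceptor", "bipolar")) {
  stopifnot(inherits(config, "sim_config"))
  check_columns(peaks, "peak_id")
  if (length(groups) != 2) cre_abort("`groups` must name two groups.")
  if (config$n_replicates < 2) {
    cre_abort("At least 2 replicates per group are required (dispersion is unidentifiable from one).")
  }
  withr::with_seed(stage_seed(config$seed, "atac_counts"), {
    simulate_two_group_counts(peaks$peak_id, config, groups)
  })
}

simulate_two_group_counts <- function(feature_ids, config, groups) {
  n <- length(feature_ids)
  nrep <- config$n_replicates
  base <- base_means(n, config$nb_mean_range)
  n_da <- round(config$da_fraction * n)
  da_idx <- sample.int(n, n_da)
  sign <- sample(c(-1, 1), n_da, replace = TRUE)
  lfc <- rep(0, n)
  lfc[da_idx] <- sign * config$planted_lfc
  mu_a <- base * 2^(lfc / 2)
  mu_b <- base * 2^(-lfc / 2)
  samples <- tibble(
    sample = c(sprintf("%s_rep%d", groups[1], seq_len(nrep)),
               sprintf("%s_rep%d", groups[2], seq_len(nrep))),
    group = rep(groups, each = nrep)
  )
  sf <- runif(nrow(samples), 0.7, 1.4)
  mu <- cbind(
    matrix(mu_a, n, nrep), matrix(mu_b, n, nrep)
  )
  mu <- sweep(mu, 2, sf, `*`)
  dimnames(mu) <- list(feature_ids, samples$sample)
  counts <- draw_counts(mu, config$nb_dispersion)
  means <- tibble(feature_id = feature_ids)
  means[[groups[1]]] <- mu_a
  means[[groups[2]]] <- mu_b
  list(
    counts = counts_tibble(counts),
    samples = samples,
    truth = tibble(feature_id = feature_ids[da_idx], sign = sign,
                   lfc = sign * config$planted_lfc),
    means = means
  )
}

#' Generate an RNA-seq-like count matrix with planted DE and contamination
#'
#' Simulates bulk expression for a rod, blue-cone and pan-bipolar design.
#' A `de_fraction` of genes is split between bipolar-enriched and
#' photoreceptor-enriched (both photoreceptor groups) at `planted_lfc`.
#' A further `contaminant_gene_fraction` of genes is rod-specific (very
#' high rod mean, background-level blue-cone expression, true bipolar
#' expression zero); bipolar
#' samples receive an additive mean of `contamination_fraction` times the
#' rod mean for these genes, emulating low-level photoreceptor
#' contamination of sorted bipolar populations.
#'
#' @param config A [sim_config()].
#' @param groups Group labels: rod-like, blue-cone-like, bipolar-like (in
#'   that order).
#' @return List: `counts`, `samples`, `truth` (with `planted_de`,
#'   `contaminant_genes`), and `means` (true per-group means).
#' @export
simulate_rna_counts <- function(config,
                                groups = c("rod", "blue_cone", "pan_bc")) {
  stopifnot(inherits(config, "sim_config"))
  if (length(groups) != 3) {
    cre_abort("`groups` must name three groups (rod-like, cone-like, bipolar-like).")
  }
  if (config$n_replicates < 2) {
    cre_abort("At least 2 replicates per group are required (dispersion is unidentifiable from one).")
  }
  withr::with_seed(stage_seed(config$seed, "rna_counts"), {
    n <- config$n_genes
    gene_ids <- sprintf("gene_%05d", seq_len(n))
    nrep <- config$n_replicates
    n_con <- round(config$contaminant_gene_fraction * n)
    n_de <- round(config$de_fraction * n)
    n_bp <- n_de %/% 2
    n_pr <- n_de - n_bp
    idx <- sample.int(n, n_con + n_de)
    con_idx <- idx[seq_len(n_con)]
    bp_idx <- idx[n_con + seq_len(n_bp)]
    pr_idx <- idx[n_con + n_bp + seq_len(n_pr)]

    base <- base_means(n, config$nb_mean_range)
    fc <- 2^config$planted_lfc
    rod <- base
    cone <- base
    bipolar <- base
    bipolar[bp_idx] <- base[bp_idx] * fc
    rod[pr_idx] <- base[pr_idx] * fc
    cone[pr_idx] <- base[pr_idx] * fc
    # rod-specific contaminants: very highly expressed in rod, near-absent
    # in blue cone (background leakage only), absent from the true bipolar
    # transcriptome
    rod[con_idx] <- runif(n_con, 1600, 6400)
    cone[con_idx] <- runif(n_con, 5, 25)
    bipolar[con_idx] <- 0
    bipolar_obs <- bipolar
    bipolar_obs[con_idx] <- config$contamination_fraction * rod[con_idx]

    samples <- tibble(
      sample = unlist(lapply(groups, function(g) {
        sprintf("%s_rep%d", g, seq_len(nrep))
      })),
      group = rep(groups, each = nrep)
    )
    sf <- runif(nrow(samples), 0.7, 1.4)
    mu <- cbind(
      matrix(rod, n, nrep), matrix(cone, n, nrep), matrix(bipolar_obs, n, nrep)
    )
    mu <- sweep(mu, 2, sf, `*`)
    dimnames(mu) <- list(gene_ids, samples$sample)
    counts <- draw_counts(mu, config$nb_dispersion)
    means <- tibble(gene_id = gene_ids)
    means[[groups[1]]] <- rod
    means[[groups[2]]] <- cone
    means[[groups[3]]] <- bipolar_obs
    list(
      counts = counts_tibble(counts, "gene_id"),
      samples = samples,
      truth = list(
        planted_de = bind_rows(
          tibble(gene_id = gene_ids[bp_idx], sign = 1),
          tibble(gene_id = gene_ids[pr_idx], sign = -1)
        ),
        contaminant_genes = gene_ids[con_idx]
      ),
      means = means
    )
  })
}

#' Generate a clustered single-cell count matrix
#'
#' Simulates Poisson counts per cell around cluster mean profiles. ON and
#' OFF bipolar populations each own half of the clusters; a fraction of
#' genes is enriched in one population at `planted_lfc`, and each cluster
#' deviates from its population profile by a lognormal jitter
#' (`sc_cluster_jitter_sd`). Per-cell means are the cluster means scaled by
#' `sc_depth_factor`.
#'
#' @param config A [sim_config()].
#' @param clusters Named character vector mapping cluster label ->
#'   population.
#' @return List: `counts` (tibble `gene_id` + one column per cell),
#'   `cell_clusters` (tibble `cell`, `cluster`), `populations` (list
#'   population -> cluster labels), `cluster_means` (tibble `gene_id` + one
#'   column per cluster, on the per-cell scale), and `population_means`
#'   (tibble `gene_id` + one column per population, bulk scale).
#' @export
simulate_single_cell <- function(config,
                                 clusters = c(BC5A = "ON", BC6 = "ON", BC7 = "ON",
                                              BC1A = "OFF", BC2 = "OFF", BC3A = "OFF")) {
  stopifnot(inherits(config, "sim_config"))
  if (length(unique(names(clusters))) < 2) {
    cre_abort("At least two clusters are required.")
  }
  if (config$n_cells_per_cluster < 1) {
    cre_abort("Each cluster must contain at least one cell.")
  }
  withr::with_seed(stage_seed(config$seed, "single_cell"), {
    n <- config$n_genes
    gene_ids <- sprintf("gene_%05d", seq_len(n))
    pops <- unique(unname(clusters))
    base <- base_means(n, config$nb_mean_range)
    fc <- 2^config$planted_lfc
    n_de <- round(config$de_fraction * n)
    idx <- sample.int(n, 2 * n_de)
    pop_means <- sapply(pops, function(p) base)
    rownames(pop_means) <- gene_ids
    if (length(pops) >= 2 && n_de > 0) {
      pop_means[idx[seq_len(n_de)], pops[1]] <-
        base[idx[seq_len(n_de)]] * fc
      pop_means[idx[n_de + seq_len(n_de)], pops[2]] <-
        base[idx[n_de + seq_len(n_de)]] * fc
    }
    cl_means <- sapply(names(clusters), function(cl) {
      jitter <- if (config$sc_cluster_jitter_sd > 0) {
        exp(stats::rnorm(n, 0, config$sc_cluster_jitter_sd))
      } else {
        rep(1, n)
      }
      pop_means[, clusters[[cl]]] * jitter * config$sc_depth_factor
    })
    rownames(cl_means) <- gene_ids
    cells <- tibble(
      cell = sprintf("%s_cell%03d",
                     rep(names(clusters), each = config$n_cells_per_cluster),
                     rep(seq_len(config$n_cells_per_cluster),
                         length(clusters))),
      cluster = rep(names(clusters), each = config$n_cells_per_cluster)
    )
    mu <- cl_means[, cells$cluster, drop = FALSE]
    colnames(mu) <- cells$cell
    counts <- matrix(rpois(length(mu), lambda = mu), nrow = n,
                     dimnames = dimnames(mu))
    populations <- split(names(clusters), unname(clusters))
    populations$pan <- names(clusters)
    pm <- as_tibble(pop_means)
    pm$pan <- rowMeans(pop_means[, pops, drop = FALSE])
    list(
      counts = counts_tibble(counts, "gene_id"),
      cell_clusters = cells,
      populations = populations,
      cluster_means = counts_tibble(cl_means, "gene_id"),
      population_means = bind_cols(tibble(gene_id = gene_ids), pm)
    )
  })
}
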