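# Motif grammar statistics: enrichment against a shuffled background,
# differential enrichment between peak sets, positional density profiles,
# co-occurrence and spacing, all computed on presence/absence tables.

#' Dinucleotide-preserving sequence shuffle
#'
#' Shuffles each sequence while preserving its exact dinucleotide counts
#' (random Eulerian path on the dinucleotide transition multigraph, drawn
#' by rejection). Shuffled copies of the peak sequences themselves serve as
#' the background model for single-set motif enrichment: composition is
#' preserved, planted grammar is destroyed.
#'
#' @param sequences Character vector of DNA sequences.
#' @return Character vector of shuffled sequences, same lengths.
#' @export
shuffle_dinucleotides <- function(sequences) {
  vapply(sequences, function(s) {
    chars <- strsplit(toupper(s), "")[[1]]
    L <- length(chars)
    if (L <= 2) {
      return(s)
    }
    targets <- split(chars[-1], chars[-L])     # out-edges per vertex
    repeat {
      shuffled <- lapply(targets, sample)
      ptr <- lapply(shuffled, function(x) 0L)
      out <- character(L)
      out[1] <- chars[1]
      cur <- chars[1]
      ok <- TRUE
      for (i in 2:L) {
        k <- ptr[[cur]] + 1L
        if (k > length(shuffled[[cur]])) {
          ok <- FALSE
          break
        }
        ptr[[cur]] <- k
        nxt <- shuffled[[cur]][k]
        out[i] <- nxt
        cur <- nxt
      }
      if (ok) {
        return(paste(out, collapse = ""))
      }
    }
  }, character(1), USE.NAMES = FALSE)
}

motif_cols <- function(presence) {
  setdiff(names(presence), "peak_id")
}

check_presence <- function(presence, what = "presence") {
  check_columns(presence, "peak_id", what)
  if (length(motif_cols(presence)) == 0) {
    cre_abort(sprintf("`%s` has no motif columns.", what))
  }
  invisible(presence)
}

#' Motif enrichment in peaks versus a background
#'
#' One-sided binomial test of the proportion of peaks containing each motif
#' against the proportion observed in background sequences (typically
#' dinucleotide-shuffled copies of the peaks; see
#' [shuffle_dinucleotides()]). P-values are BH-adjusted across motifs.
#'
#' @param presence Peak-by-motif presence table from [motif_presence()].
#' @param background Presence table for the background sequences, same
#'   motif columns.
#' @return A tibble per motif: counts and proportions in peaks and
#'   background, `p_value`, `fdr`, sorted by `p_value`.
#' @export
motif_enrichment <- function(presence, background) {
  check_presence(presence)
  check_presence(background, "background")
  if (nrow(presence) == 0) {
    cre_abort("Empty peak set: cannot test motif enrichment.")
  }
  motifs <- motif_cols(presence)
  res <- purrr::map_dfr(motifs, function(m) {
    xa <- sum(presence[[m]])
    na <- nrow(presence)
    xb <- sum(background[[m]])
    nb <- nrow(background)
    pb <- xb / nb
    # smoothed null proportion keeps the test defined when a motif is
    # absent from the finite background sample
    pb_test <- min((xb + 0.5) / (nb + 1), 1 - 1e-12)
    p <- if (xa == 0) {
      1
    } else {
      stats::binom.test(xa, na, p = pb_test, alternative = "greater")$p.value
    }
    tibble(
      motif = m, count_peaks = xa, total_peaks = na,
      count_background = xb, total_background = nb,
      proportion_peaks = xa / na, proportion_background = pb,
      p_value = p
    )
  })
  res$fdr <- p.adjust(res$p_value, method = "BH")
  arrange(res, .data$p_value)
}

#' Differential motif enrichment between two peak sets
#'
#' Two-sample test of equal proportions (z-test on the pooled proportion,
#' no continuity correction) comparing, for every motif, the proportion of
#' peaks containing it in set a versus set b. The z statistic is signed:
#' positive means more prevalent in set a. Two-sided p-values, BH-adjusted
#' across motifs. Set `correct = TRUE` for the continuity-corrected
#' variant.
#'
#' @param presence_a,presence_b Presence tables for the two peak sets.
#' @param correct Apply Yates continuity correction (default FALSE).
#' @return A tibble per motif: counts, proportions, `statistic` (signed z),
#'   `p_value`, `fdr`.
#' @export
diff_motif_enrichment <- function(presence_a, presence_b, correct = FALSE) {
  check_presence(presence_a, "presence_a")
  check_presence(presence_b, "presence_b")
  if (nrow(presence_a) == 0 || nrow(presence_b) == 0) {
    cre_abort("Both peak sets must be nonempty.")
  }
  motifs <- intersect(motif_cols(presence_a), motif_cols(presence_b))
  res <- purrr::map_dfr(motifs, function(m) {
    xa <- sum(presence_a[[m]]); na <- nrow(presence_a)
    xb <- sum(presence_b[[m]]); nb <- nrow(presence_b)
    pooled <- (xa + xb) / (na + nb)
    if (pooled <= 0 || pooled >= 1) {
      z <- 0
      p <- 1
    } else {
      z <- (xa / na - xb / nb) /
        sqrt(pooled * (1 - pooled) * (1 / na + 1 / nb))
      p <- suppressWarnings(
        stats::prop.test(c(xa, xb), c(na, nb), correct = correct)$p.value
      )
    }
    tibble(
      motif = m, count_a = xa, total_a = na, count_b = xb, total_b = nb,
      proportion_a = xa / na, proportion_b = xb / nb,
      statistic = z, p_value = p
    )
  })
  res$fdr <- p.adjust(res$p_value, method = "BH")
  arrange(res, .data$p_value)
}

#' Summit-anchored motif density profile
#'
#' Bins motif occurrences by signed offset from the peak summit and reports
#' density in motifs per base pair per 1000 peaks, the conventional unit
#' for aggregate footprint plots.
#'
#' @param occurrences Occurrence tibble from [scan_motifs()].
#' @param n_peaks Number of peaks the occurrences were scanned from.
#' @param window Total window width in bp centered on the summit (even).
#' @param bin Bin width in bp.
#' @return A tibble: `motif`, `bin_start` (offset of bin left edge),
#'   `bin_mid`, `count`, `density`.
#' @export
motif_density_profile <- function(occurrences, n_peaks, window = 1000, bin = 10) {
  check_columns(occurrences, c("motif", "offset"), "occurrences")
  if (n_peaks <= 0) {
    cre_abort("`n_peaks` must be positive.")
  }
  if (window %% 2 != 0) {
    cre_abort("`window` must be even.")
  }
  edges <- seq(-window / 2, window / 2, by = bin)
  occurrences |>
    filter(.data$offset >= -window / 2, .data$offset < window / 2) |>
    mutate(bin_start = edges[findInterval(.data$offset, edges)]) |>
    count(.data$motif, .data$bin_start, name = "count") |>
    tidyr::complete(
      motif = unique(occurrences$motif),
      bin_start = edges[-length(edges)],
      fill = list(count = 0L)
    ) |>
    mutate(
      bin_mid = .data$bin_start + bin / 2,
      density = .data$count / (bin * n_peaks / 1000)
    ) |>
    select("motif", "bin_start", "bin_mid", "count", "density") |>
    arrange(.data$motif, .data$bin_start)
}

#' Motif pair co-occurrence enrichment
#'
#' For every unordered motif pair, compares the observed number of peaks
#' containing both motifs to the number expected under independence
#' (n1 x n2 / N) via `log2((observed + 1) / (expected + 1))`. Values near 0
#' indicate pair frequencies consistent with motifs distributed
#' independently across peaks.
#'
#' @param presence Peak-by-motif presence table.
#' @return A tibble per pair: `motif1`, `motif2`, `n1`, `n2`, `observed`,
#'   `expected`, `log2_enrichment`.
#' @export
cooccurrence_enrichment <- function(presence) {
  check_presence(presence)
  motifs <- motif_cols(presence)
  N <- nrow(presence)
  if (N < 1) {
    cre_abort("Presence table must contain at least one peak.")
  }
  pairs <- utils::combn(motifs, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    n1 <- sum(presence[[pr[1]]])
    n2 <- sum(presence[[pr[2]]])
    obs <- sum(presence[[pr[1]]] & presence[[pr[2]]])
    expd <- n1 * n2 / N
    tibble(
      motif1 = pr[1], motif2 = pr[2], n1 = n1, n2 = n2,
      observed = obs, expected = expd,
      log2_enrichment = log2((obs + 1) / (expd + 1))
    )
  })
}

#' Differential motif pair co-occurrence between two peak sets
#'
#' For each motif pair, tests whether the proportion of peaks containing
#' both motifs differs between the two sets with a two-sided Fisher exact
#' test on the 2x2 table (pair present / absent by set), BH-adjusted across
#' pairs. Per-set co-occurrence enrichments are reported alongside.
#'
#' @param presence_a,presence_b Presence tables for the two peak sets.
#' @return A tibble per pair with per-set observed counts and enrichments,
#'   `p_value` and `fdr`.
#' @export
diff_cooccurrence <- function(presence_a, presence_b) {
  check_presence(presence_a, "presence_a")
  check_presence(presence_b, "presence_b")
  if (nrow(presence_a) == 0 || nrow(presence_b) == 0) {
    cre_abort("Both peak sets must be nonempty.")
  }
  ca <- cooccurrence_enrichment(presence_a)
  cb <- cooccurrence_enrichment(presence_b)
  res <- inner_join(ca, cb, by = c("motif1", "motif2"),
                    suffix = c("_a", "_b")) |>
    mutate(
      total_a = nrow(presence_a),
      total_b = nrow(presence_b),
      p_value = purrr::map2_dbl(
        .data$observed_a, .data$observed_b,
        function(oa, ob) {
          tab <- matrix(c(oa, nrow(presence_a) - oa,
                          ob, nrow(presence_b) - ob), nrow = 2)
          stats::fisher.test(tab)$p.value
        }
      )
    )
  res$fdr <- p.adjust(res$p_value, method = "BH")
  res |>
    select("motif1", "motif2", "observed_a", "expected_a",
           "log2_enrichment_a", "observed_b", "expected_b",
           "log2_enrichment_b", "total_a", "total_b", "p_value", "fdr") |>
    arrange(.data$p_value)
}

#' Spacing profile of a secondary motif around an anchor motif
#'
#' Histograms the positions of secondary-motif occurrences relative to each
#' anchor occurrence in the same peak, with offsets and strand orientation
#' normalized to the anchor's strand (positive = downstream of the anchor;
#' "same" = secondary on the anchor's strand). When anchor and secondary
#' are the same motif, each occurrence paired with itself is excluded.
#'
#' @param anchors Occurrence tibble for the anchor motif.
#' @param secondaries Occurrence tibble for the secondary motif.
#' @param window Total window width (bp) around the anchor.
#' @param bin Bin width (bp).
#' @return A tibble: `orientation` ("same"/"opposite"), `bin_start`,
#'   `bin_mid`, `count`, `density` (pairs per bp per 1000 anchors).
#' @export
spacing_profile <- function(anchors, secondaries, window = 200, bin = 5) {
  check_columns(anchors, c("peak_id", "offset", "strand"), "anchors")
  check_columns(secondaries, c("peak_id", "offset", "strand"), "secondaries")
  if (nrow(anchors) == 0) {
    cre_abort("Anchor occurrence list is empty.")
  }
  a <- anchors |>
    mutate(a_motif = if ("motif" %in% names(anchors)) .data$motif else NA) |>
    select(peak_id = "peak_id", a_off = "offset", a_strand = "strand", "a_motif")
  s <- secondaries |>
    mutate(s_motif = if ("motif" %in% names(secondaries)) .data$motif else NA) |>
    select(peak_id = "peak_id", s_off = "offset", s_strand = "strand", "s_motif")
  self_pair <- function(d) {
    d$a_off == d$s_off & d$a_strand == d$s_strand &
      (is.na(d$a_motif) | is.na(d$s_motif) | d$a_motif == d$s_motif)
  }
  pairs <- inner_join(a, s, by = "peak_id", relationship = "many-to-many") |>
    mutate(
      rel = ifelse(.data$a_strand == "-",
                   .data$a_off - .data$s_off,
                   .data$s_off - .data$a_off),
      orientation = ifelse(.data$s_strand == .data$a_strand, "same", "opposite")
    )
  pairs <- pairs[!self_pair(pairs), ]
  edges <- seq(-window / 2, window / 2, by = bin)
  pairs |>
    filter(.data$rel >= -window / 2, .data$rel < window / 2) |>
    mutate(bin_start = edges[findInterval(.data$rel, edges)]) |>
    count(.data$orientation, .data$bin_start, name = "count") |>
    tidyr::complete(
      orientation = c("same", "opposite"),
      bin_start = edges[-length(edges)],
      fill = list(count = 0L)
    ) |>
    mutate(
      bin_mid = .data$bin_start + bin / 2,
      density = .data$count / (bin * nrow(anchors) / 1000)
    ) |>
    arrange(.data$orientation, .data$bin_start)
}
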