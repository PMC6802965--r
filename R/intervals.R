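# Interval algebra on peak tibbles. Coordinates follow the BED convention:
# 0-based, half-open [start, end); `summit` is an offset from `start`.
# Chromosome names are compared as raw strings; distinct chromosomes never
# overlap.

peaks_to_granges <- function(peaks) {
  GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end)
  )
}

#' Merge peak sets into a disjoint union
#'
#' Combines peak sets (e.g. per-sample or per-class calls) into the minimal
#' set of disjoint intervals covering every input base. Each merged
#' interval's summit is its midpoint and its `sources` field records which
#' input sets contributed to it.
#'
#' @param sets A named list of peak tibbles (`chrom`, `start`, `end`), or a
#'   single tibble with a `label` column distinguishing the sets.
#' @return A peak tibble: `peak_id`, `chrom`, `start`, `end`, `summit`,
#'   `sources` (comma-separated contributing set labels).
#' @examples
#' merge_peak_union(list(
#'   a = tibble::tibble(chrom = "chr1", start = 0, end = 100),
#'   b = tibble::tibble(chrom = "chr1", start = 50, end = 150)
#' ))
#' @export
merge_peak_union <- function(sets) {
  if (is.data.frame(sets)) {
    check_columns(sets, "label", "sets")
    sets <- split(sets, sets$label)
  }
  if (length(sets) == 0 || sum(vapply(sets, nrow, integer(1))) == 0) {
    cre_abort("`sets` must contain at least one interval.")
  }
  labels <- names(sets) %||% as.character(seq_along(sets))
  all <- purrr::imap_dfr(sets, function(p, lab) {
    check_peaks(p, paste0("sets[['", lab, "']]"))
    tibble(chrom = p$chrom, start = as.integer(p$start),
           end = as.integer(p$end), label = lab)
  })
  gr <- peaks_to_granges(all)
  merged <- GenomicRanges::reduce(gr)
  hits <- GenomicRanges::findOverlaps(merged, gr)
  src <- tapply(
    all$label[S4Vectors::subjectHits(hits)],
    S4Vectors::queryHits(hits),
    function(x) paste(sort(unique(x)), collapse = ",")
  )
  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged) - 1L,
    end = GenomicRanges::end(merged)
  ) |>
    arrange(.data$chrom, .data$start) |>
    mutate(
      summit = midpoint_summit(.data$start, .data$end),
      sources = as.character(src[as.character(seq_len(dplyr::n()))]),
      peak_id = sprintf("union_%05d", seq_len(dplyr::n()))
    ) |>
    select("peak_id", "chrom", "start", "end", "summit", "sources")
  out
}

#' Classify peaks as promoter or enhancer
#'
#' A peak is a promoter when its summit lies between 1000 bp upstream and
#' 100 bp downstream of some transcription start site (strand-aware, window
#' bounds inclusive); all other peaks are enhancers (TSS-distal). With no
#' TSS annotation every peak is an enhancer.
#'
#' @param peaks Peak tibble with `chrom`, `start`, `end`, `summit`.
#' @param tss TSS tibble: `gene_id`, `chrom`, `tss` (bp), `strand`
#'   ("+"/"-").
#' @param upstream,downstream Window bounds in bp (defaults 1000 and 100).
#' @return `peaks` with an added `peak_type` column ("promoter" or
#'   "enhancer").
#' @export
classify_promoter_enhancer <- function(peaks, tss,
                                       upstream = 1000, downstream = 100) {
  check_peaks(peaks)
  check_columns(peaks, "summit")
  if (nrow(tss) > 0) {
    check_columns(tss, c("gene_id", "chrom", "tss", "strand"), "tss")
    if (any(!tss$strand %in% c("+", "-"))) {
      cre_abort("TSS strands must all be '+' or '-'.")
    }
  }
  if (nrow(peaks) == 0) {
    return(mutate(peaks, peak_type = character(0)))
  }
  if (nrow(tss) == 0) {
    return(mutate(peaks, peak_type = "enhancer"))
  }
  win_start <- ifelse(tss$strand == "+", tss$tss - upstream, tss$tss - downstream)
  win_end <- ifelse(tss$strand == "+", tss$tss + downstream, tss$tss + upstream)
  windows <- GenomicRanges::GRanges(
    seqnames = tss$chrom,
    ranges = IRanges::IRanges(start = win_start + 1L, end = win_end + 1L)
  )
  summits <- GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + peaks$summit + 1L, width = 1L)
  )
  hit <- GenomicRanges::countOverlaps(summits, windows) > 0
  mutate(peaks, peak_type = ifelse(hit, "promoter", "enhancer"))
}

#' Assign each peak to its nearest TSS
#'
#' Distance is measured from the peak summit to the TSS position; the
#' minimal absolute distance wins, with equidistant ties broken by the
#' lexicographically smaller gene id. Peaks on chromosomes without any TSS
#' are flagged unassigned (NA gene), never dropped.
#'
#' @param peaks Peak tibble with `chrom`, `start`, `end`, `summit` and
#'   (optionally) `peak_id`.
#' @param tss TSS tibble: `gene_id`, `chrom`, `tss`, `strand`.
#' @return `peaks` with added `gene_id` and `distance` (signed,
#'   TSS position minus summit position) columns.
#' @export
assign_nearest_tss <- function(peaks, tss) {
  check_peaks(peaks)
  check_columns(peaks, "summit")
  check_columns(tss, c("gene_id", "chrom", "tss"), "tss")
  summit_pos <- peaks$start + peaks$summit
  gene <- rep(NA_character_, nrow(peaks))
  dist <- rep(NA_integer_, nrow(peaks))
  for (chr in unique(peaks$chrom)) {
    p_idx <- which(peaks$chrom == chr)
    t_sub <- tss |>
      filter(.data$chrom == chr) |>
      arrange(.data$tss, .data$gene_id)
    if (nrow(t_sub) == 0) next
    pos <- summit_pos[p_idx]
    # candidate TSS on either side of each summit via a sorted search
    right <- findInterval(pos, t_sub$tss) + 1L
    left <- right - 1L
    for (k in seq_along(p_idx)) {
      cand <- c(left[k], right[k])
      # widen to capture runs of equal tss positions around the boundary
      cand <- unique(pmin(pmax(c(cand - 1L, cand, cand + 1L), 1L), nrow(t_sub)))
      d <- t_sub$tss[cand] - pos[k]
      best <- cand[abs(d) == min(abs(d))]
      best <- best[order(t_sub$gene_id[best])][1]
      gene[p_idx[k]] <- t_sub$gene_id[best]
      dist[p_idx[k]] <- as.integer(t_sub$tss[best] - pos[k])
    }
  }
  mutate(peaks, gene_id = gene, distance = dist)
}

#' Fraction of peaks overlapping another peak set
#'
#' The proportion of intervals in `a` that overlap at least one base of any
#' interval in `b`.
#'
#' @param a,b Peak tibbles (`chrom`, `start`, `end`).
#' @return A single proportion in \[0, 1\].
#' @export
overlap_fraction <- function(a, b) {
  check_peaks(a, "a")
  check_peaks(b, "b")
  if (nrow(a) == 0) {
    cre_abort("Overlap fraction is undefined for an empty query set.")
  }
  if (nrow(b) == 0) {
    return(0)
  }
  hits <- GenomicRanges::countOverlaps(peaks_to_granges(a), peaks_to_granges(b))
  mean(hits > 0)
}

#' Retain peaks accessible only in the target set
#'
#' Tissue-specificity filter: keeps exactly those target peaks that overlap
#' no interval (by even a single base) in any control set, mirroring the
#' exclusion of regions accessible in non-retinal control tissues.
#'
#' @param target Peak tibble.
#' @param controls List of control peak tibbles (possibly empty).
#' @return The retained subset of `target`, with an attribute
#'   `n_removed` giving the number filtered out.
#' @export
filter_tissue_specific <- function(target, controls = list()) {
  check_peaks(target, "target")
  if (is.data.frame(controls)) {
    controls <- list(controls)
  }
  controls <- purrr::keep(controls, function(x) nrow(x) > 0)
  if (length(controls) == 0 || nrow(target) == 0) {
    out <- target
    attr(out, "n_removed") <- 0L
    return(out)
  }
  ctrl <- bind_rows(lapply(controls, function(x) {
    check_peaks(x, "controls")
    select(x, "chrom", "start", "end")
  }))
  hits <- GenomicRanges::countOverlaps(
    peaks_to_granges(target), peaks_to_granges(ctrl)
  )
  out <- target[hits == 0, , drop = FALSE]
  attr(out, "n_removed") <- sum(hits > 0)
  out
}
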