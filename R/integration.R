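# Accessibility-expression integration: quadrant classification of
# peak/gene pairs and expression summaries per peak class.

#' Classify peaks by joint accessibility/expression quadrants
#'
#' Each peak carries a differential-accessibility (DA) record and the
#' differential-expression (DE) record of its assigned gene; both are log2
#' fold-changes oriented the same way (positive = class a). A peak is:
#'
#' * `concordant_class_a` when DA and DE both reach `fold`-fold toward
#'   class a (log2FC >= log2(fold), inclusive) with both FDRs below `fdr`;
#' * `concordant_class_b` symmetrically toward class b;
#' * `discordant` when both dimensions pass fold and FDR but in opposite
#'   directions;
#' * `shared_or_modest` otherwise.
#'
#' Peaks whose assigned gene lacks a DE record are flagged
#' (`missing_expression`) and excluded from label counts rather than
#' imputed.
#'
#' @param pairs Tibble: `peak_id`, `gene_id`, `da_log2fc`, `da_fdr`,
#'   `de_log2fc`, `de_fdr`.
#' @param fold Fold-change requirement applied to both dimensions
#'   (default 4).
#' @param fdr FDR cutoff applied to both dimensions (default 0.05).
#' @return The input with an added `label` column, classed
#'   `cre_quadrants`; excluded peaks carry label `missing_expression`.
#' @export
classify_quadrants <- function(pairs, fold = 4, fdr = 0.05) {
  check_columns(pairs, c("peak_id", "gene_id", "da_log2fc", "da_fdr",
                         "de_log2fc", "de_fdr"), "pairs")
  thr <- log2(fold)
  missing <- is.na(pairs$de_log2fc) | is.na(pairs$de_fdr)
  da_up <- pairs$da_log2fc >= thr & pairs$da_fdr < fdr
  da_dn <- pairs$da_log2fc <= -thr & pairs$da_fdr < fdr
  de_up <- pairs$de_log2fc >= thr & pairs$de_fdr < fdr
  de_dn <- pairs$de_log2fc <= -thr & pairs$de_fdr < fdr
  label <- dplyr::case_when(
    missing ~ "missing_expression",
    da_up & de_up ~ "concordant_class_a",
    da_dn & de_dn ~ "concordant_class_b",
    (da_up & de_dn) | (da_dn & de_up) ~ "discordant",
    TRUE ~ "shared_or_modest"
  )
  out <- mutate(pairs, label = label)
  class(out) <- c("cre_quadrants", class(out))
  attr(out, "fold") <- fold
  attr(out, "fdr") <- fdr
  out
}

#' Summarize assigned-gene expression by peak class
#'
#' For each peak label and each cell-class expression column, reports the
#' number of peaks and the median and quartiles of the assigned genes'
#' normalized expression, supporting comparisons of expression across
#' accessibility classes.
#'
#' @param classes Classification tibble from [classify_quadrants()] (or
#'   any tibble with `gene_id` and `label`).
#' @param expression Tibble `gene_id` plus one normalized-expression column
#'   per cell class.
#' @return Tibble: `label`, `cell_class`, `n`, `q1`, `median`, `q3`.
#' @export
expression_by_peak_class <- function(classes, expression) {
  check_columns(classes, c("gene_id", "label"), "classes")
  check_columns(expression, "gene_id", "expression")
  if (nrow(classes) == 0) {
    cre_abort("`classes` must be nonempty.")
  }
  cell_classes <- setdiff(names(expression), "gene_id")
  classes |>
    inner_join(expression, by = "gene_id") |>
    select("label", all_of(cell_classes)) |>
    tidyr::pivot_longer(all_of(cell_classes), names_to = "cell_class",
                        values_to = "expr") |>
    group_by(.data$label, .data$cell_class) |>
    summarise(
      n = dplyr::n(),
      q1 = unname(quantile(.data$expr, 0.25)),
      median = median(.data$expr),
      q3 = unname(quantile(.data$expr, 0.75)),
      .groups = "drop"
    )
}
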