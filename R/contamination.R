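# Rule-based removal of photoreceptor-contamination genes from bipolar
# differential-expression lists. Sorted bipolar populations carry traces of
# rod/cone material, so genes that are overwhelmingly photoreceptor-
# specific can masquerade as bipolar-enriched.

#' Contamination filter thresholds
#'
#' @param specificity_fold Fold-ratio above which a gene counts as specific
#'   to one photoreceptor versus the other (strict `>`, default 16).
#' @param enrichment_fold Fold-ratio above which a gene counts as higher in
#'   the photoreceptor than in the bipolar population (inclusive `>=`,
#'   default 4).
#' @return A list of class `filter_rule`.
#' @export
filter_rule <- function(specificity_fold = 16, enrichment_fold = 4) {
  if (specificity_fold <= 1 || enrichment_fold <= 1) {
    cre_abort("Both filter thresholds must exceed 1.")
  }
  structure(
    list(specificity_fold = specificity_fold,
         enrichment_fold = enrichment_fold),
    class = "filter_rule"
  )
}

ratio_of_means <- function(means, num, den, pseudocount = 0.5) {
  (means[[num]] + pseudocount) / (means[[den]] + pseudocount)
}

check_mean_columns <- function(means, cols) {
  missing <- setdiff(cols, names(means))
  if (length(missing) > 0) {
    cre_abort(sprintf(
      "Required population mean column(s) missing from `means`: %s.",
      paste(missing, collapse = ", ")
    ))
  }
}

#' Filter photoreceptor-contamination genes from a bipolar DE list
#'
#' Two variants of the rule-based filter:
#'
#' * `mode = "pan_vs_photoreceptor"`: for a bipolar-versus-photoreceptor
#'   comparison (e.g. pan-bipolar vs blue cone), genes enriched on the
#'   bipolar side are removed when they are specific to the *alternate*
#'   photoreceptor (ratio over the tested photoreceptor strictly above
#'   `specificity_fold`) and at least `enrichment_fold` higher in that
#'   alternate photoreceptor than in the bipolar population.
#' * `mode = "on_off"`: for an ON-versus-OFF bipolar comparison, genes
#'   enriched in either bipolar population are removed when *both*
#'   photoreceptor populations exceed `specificity_fold` over the bipolar
#'   population in which the gene appeared enriched.
#'
#' Fold ratios are computed on normalized means with a +0.5 pseudocount.
#' Removed genes are reported with their triggering ratios, never silently
#' dropped.
#'
#' @param de Differential-expression tibble with `gene_id` and `log2fc`
#'   (positive = enriched in the first population of `comparison`).
#'   Typically the called genes from [nb_wald_test()].
#' @param means Tibble of normalized per-population mean expression:
#'   `gene_id` plus one column per population.
#' @param comparison The two populations the DE table compares, in
#'   (first = bipolar side for `pan_vs_photoreceptor`) order.
#' @param mode Which variant of the rule to apply.
#' @param alternate For `pan_vs_photoreceptor`: the alternate
#'   photoreceptor population whose contamination is being flagged.
#' @param photoreceptors For `on_off`: the two photoreceptor populations.
#' @param rule A [filter_rule()].
#' @param pseudocount Added to means before forming ratios.
#' @return A list with `kept` (subset of `de`) and `removed` (subset with
#'   the triggering ratio columns).
#' @export
filter_contaminants <- function(de, means,
                                comparison,
                                mode = c("pan_vs_photoreceptor", "on_off"),
                                alternate = NULL,
                                photoreceptors = c("rod", "blue_cone"),
                                rule = filter_rule(),
                                pseudocount = 0.5) {
  mode <- match.arg(mode)
  check_columns(de, c("gene_id", "log2fc"), "de")
  check_columns(means, "gene_id", "means")
  if (length(comparison) != 2) {
    cre_abort("`comparison` must name the two compared populations.")
  }
  m <- means[match(de$gene_id, means$gene_id), ]
  if (anyNA(m$gene_id)) {
    cre_abort("Every gene in `de` needs a row in `means`.")
  }
  if (mode == "pan_vs_photoreceptor") {
    if (is.null(alternate)) {
      cre_abort("`alternate` photoreceptor population must be named for this mode.")
    }
    check_mean_columns(m, c(comparison, alternate))
    bipolar <- comparison[1]
    tested_pr <- comparison[2]
    specificity <- ratio_of_means(m, alternate, tested_pr, pseudocount)
    enrichment <- ratio_of_means(m, alternate, bipolar, pseudocount)
    flag <- de$log2fc > 0 &
      specificity > rule$specificity_fold &
      enrichment >= rule$enrichment_fold
    report <- de |>
      mutate(
        alternate_vs_tested = specificity,
        alternate_vs_bipolar = enrichment
      )
  } else {
    check_mean_columns(m, c(comparison, photoreceptors))
    enriched_in <- ifelse(de$log2fc > 0, comparison[1], comparison[2])
    r1 <- ifelse(de$log2fc > 0,
                 ratio_of_means(m, photoreceptors[1], comparison[1], pseudocount),
                 ratio_of_means(m, photoreceptors[1], comparison[2], pseudocount))
    r2 <- ifelse(de$log2fc > 0,
                 ratio_of_means(m, photoreceptors[2], comparison[1], pseudocount),
                 ratio_of_means(m, photoreceptors[2], comparison[2], pseudocount))
    flag <- r1 > rule$specificity_fold & r2 > rule$specificity_fold
    report <- de |>
      mutate(
        enriched_in = enriched_in,
        !!paste0(photoreceptors[1], "_vs_bipolar") := r1,
        !!paste0(photoreceptors[2], "_vs_bipolar") := r2
      )
  }
  list(
    kept = de[!flag, , drop = FALSE],
    removed = report[flag, , drop = FALSE]
  )
}
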