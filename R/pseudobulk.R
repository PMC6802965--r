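# Pseudo-bulk aggregation of clustered single-cell counts and comparison
# against bulk expression profiles.

#' Pseudo-bulk expression per population
#'
#' Averages single-cell counts over all cells belonging to the clusters
#' that constitute each population. The weighted average over clusters uses
#' cluster cell counts as weights, which is exactly the plain mean over all
#' member cells.
#'
#' @param sc Single-cell count tibble: `gene_id` plus one column per cell.
#' @param cell_clusters Tibble `cell`, `cluster`.
#' @param populations Named list: population -> character vector of cluster
#'   labels.
#' @return Tibble `gene_id` plus one pseudo-bulk column per population.
#' @export
pseudobulk_counts <- function(sc, cell_clusters, populations) {
  check_columns(sc, "gene_id", "sc")
  check_columns(cell_clusters, c("cell", "cluster"), "cell_clusters")
  if (length(populations) == 0) {
    cre_abort("`populations` must name at least one population.")
  }
  unknown <- setdiff(unique(unlist(populations)), cell_clusters$cluster)
  if (length(unknown) > 0) {
    cre_abort(sprintf("Cluster(s) not present in the matrix: %s.",
                      paste(unknown, collapse = ", ")))
  }
  out <- tibble(gene_id = sc$gene_id)
  for (pop in names(populations)) {
    cells <- cell_clusters$cell[cell_clusters$cluster %in% populations[[pop]]]
    cells <- intersect(cells, names(sc))
    if (length(cells) == 0) {
      cre_abort(sprintf("Population '%s' contains no cells.", pop))
    }
    out[[pop]] <- rowMeans(as.matrix(sc[, cells, drop = FALSE]))
  }
  out
}

#' Rescale a pseudo-bulk profile to match a bulk profile
#'
#' Applies one global multiplicative factor so that the rescaled
#' pseudo-bulk total over the shared gene universe equals the bulk total;
#' relative proportions (and hence correlations) are preserved.
#'
#' @param pseudo Tibble `gene_id`, `expr`.
#' @param bulk Tibble `gene_id`, `expr`.
#' @return `pseudo` with `expr` rescaled; the factor is attached as
#'   attribute `scale_factor`.
#' @export
rescale_to_bulk <- function(pseudo, bulk) {
  check_columns(pseudo, c("gene_id", "expr"), "pseudo")
  check_columns(bulk, c("gene_id", "expr"), "bulk")
  shared <- intersect(pseudo$gene_id, bulk$gene_id)
  if (length(shared) == 0) {
    cre_abort("The shared gene universe is empty.")
  }
  tot_p <- sum(pseudo$expr[pseudo$gene_id %in% shared])
  tot_b <- sum(bulk$expr[bulk$gene_id %in% shared])
  if (tot_p == 0) {
    cre_abort("Pseudo-bulk profile is all zero over the shared genes.")
  }
  fac <- tot_b / tot_p
  out <- mutate(pseudo, expr = .data$expr * fac)
  attr(out, "scale_factor") <- fac
  out
}

#' Correlate bulk and pseudo-bulk expression profiles
#'
#' Pearson correlations of log2(x + 1)-transformed expression over the
#' shared gene universe, for every bulk-population x pseudo-bulk-population
#' pair.
#'
#' @param bulk Tibble `gene_id` plus one column per bulk population.
#' @param pseudo Tibble `gene_id` plus one column per pseudo-bulk
#'   population (e.g. from [pseudobulk_counts()]).
#' @return Tibble `bulk_population`, `pseudo_population`, `pearson`.
#' @export
compare_bulk_pseudobulk <- function(bulk, pseudo) {
  check_columns(bulk, "gene_id", "bulk")
  check_columns(pseudo, "gene_id", "pseudo")
  shared <- intersect(bulk$gene_id, pseudo$gene_id)
  if (length(shared) < 2) {
    cre_abort("At least two shared genes are required.")
  }
  b <- bulk[match(shared, bulk$gene_id), setdiff(names(bulk), "gene_id"),
            drop = FALSE]
  p <- pseudo[match(shared, pseudo$gene_id),
              setdiff(names(pseudo), "gene_id"), drop = FALSE]
  lb <- log2(as.matrix(b) + 1)
  lp <- log2(as.matrix(p) + 1)
  const <- c(colnames(lb)[apply(lb, 2, sd) == 0],
             colnames(lp)[apply(lp, 2, sd) == 0])
  if (length(const) > 0) {
    cre_abort(sprintf("Constant expression vector(s): %s.",
                      paste(unique(const), collapse = ", ")))
  }
  r <- cor(lb, lp)
  as_tibble(as.data.frame.table(r, responseName = "pearson")) |>
    rename(bulk_population = "Var1", pseudo_population = "Var2") |>
    mutate(bulk_population = as.character(.data$bulk_population),
           pseudo_population = as.character(.data$pseudo_population))
}
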