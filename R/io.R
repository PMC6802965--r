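# Plain-text readers/writers for the formats the pipeline exchanges:
# BED intervals (0-based half-open, optional summit column), TSS tables,
# count matrices, motif sets, FASTA genomes, and the key = value
# simulation-config file.

#' Write peaks as BED
#'
#' Columns: chrom, start, end, name, score, strand, plus a 7th `summit`
#' column (offset from start) when present. Coordinates are BED-style
#' 0-based half-open.
#'
#' @param peaks Peak tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  check_peaks(peaks)
  out <- tibble(
    chrom = peaks$chrom,
    start = as.integer(peaks$start),
    end = as.integer(peaks$end),
    name = if ("peak_id" %in% names(peaks)) peaks$peak_id else
      sprintf("peak_%05d", seq_len(nrow(peaks))),
    score = 0L,
    strand = if ("strand" %in% names(peaks)) peaks$strand else "."
  )
  if ("summit" %in% names(peaks)) {
    out$summit <- as.integer(peaks$summit)
  }
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read a BED file of peaks
#'
#' Accepts 3-6 columns plus an optional 7th summit column. Missing summits
#' default to the interval midpoint.
#'
#' @param path BED file path.
#' @return Peak tibble: `peak_id`, `chrom`, `start`, `end`, `summit`
#'   (and `strand` when present).
#' @export
read_bed <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         progress = FALSE)
  if (ncol(raw) < 3) cre_abort("A BED file needs at least 3 columns.")
  names(raw)[1:3] <- c("chrom", "start", "end")
  out <- tibble(
    peak_id = if (ncol(raw) >= 4) as.character(raw[[4]]) else
      sprintf("peak_%05d", seq_len(nrow(raw))),
    chrom = as.character(raw$chrom),
    start = as.integer(raw$start),
    end = as.integer(raw$end)
  )
  if (ncol(raw) >= 6) out$strand <- as.character(raw[[6]])
  out$summit <- if (ncol(raw) >= 7) {
    as.integer(raw[[7]])
  } else {
    midpoint_summit(out$start, out$end)
  }
  check_peaks(out, path)
  out
}

#' Read a TSS annotation table
#'
#' Four tab-separated columns: gene id, chromosome, position (bp), strand.
#'
#' @param path File path.
#' @return Tibble `gene_id`, `chrom`, `tss`, `strand`.
#' @export
read_tss_tsv <- function(path) {
  raw <- readr::read_tsv(path, col_names = c("gene_id", "chrom", "tss", "strand"),
                         show_col_types = FALSE, progress = FALSE)
  if (anyDuplicated(raw$gene_id)) {
    cre_abort("Duplicate gene ids in the TSS table.")
  }
  if (any(raw$tss < 0)) cre_abort("TSS positions must be nonnegative.")
  raw
}

#' Write / read a count matrix as TSV
#'
#' Features in rows, samples in columns, with a header row of sample ids
#' and the feature id in the first column.
#'
#' @param counts Count tibble (feature-id column first).
#' @param path File path.
#' @return `path` invisibly / the count tibble.
#' @export
write_counts_tsv <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read a motif set from TSV
#'
#' Three columns: motif name, IUPAC consensus, family.
#'
#' @param path File path.
#' @return Motif tibble compatible with [scan_motifs()].
#' @export
read_motifs_tsv <- function(path) {
  raw <- readr::read_tsv(path, col_names = c("motif", "consensus", "family"),
                         show_col_types = FALSE, progress = FALSE)
  purrr::walk(raw$consensus, check_iupac)
  raw
}

#' Write a genome as FASTA
#'
#' @param genome Genome tibble (`chrom`, `sequence`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  check_columns(genome, c("chrom", "sequence"), "genome")
  seqs <- Biostrings::DNAStringSet(genome$sequence)
  names(seqs) <- genome$chrom
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a simulation config from a key = value file
#'
#' Plain-text schema: one `key = value` pair per line, `#` comments
#' allowed. Scalar keys match [sim_config()] argument names; vector values
#' are comma-separated (named elements as `name:value`, e.g.
#' `background_composition = A:0.3,C:0.2,G:0.2,T:0.3`). Motif densities use
#' keys of the form `density.<class> = motif:value,...`.
#'
#' @param path File path.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- stringr::str_trim(lines)
  lines <- lines[lines != "" & !stringr::str_starts(lines, "#")]
  kv <- stringr::str_split_fixed(lines, "=", 2)
  keys <- stringr::str_trim(kv[, 1])
  vals <- stringr::str_trim(kv[, 2])
  parse_val <- function(v) {
    parts <- stringr::str_trim(strsplit(v, ",")[[1]])
    if (all(stringr::str_detect(parts, ":"))) {
      pieces <- stringr::str_split_fixed(parts, ":", 2)
      setNames(as.numeric(pieces[, 2]), stringr::str_trim(pieces[, 1]))
    } else if (suppressWarnings(!anyNA(as.numeric(parts)))) {
      as.numeric(parts)
    } else {
      parts
    }
  }
  args <- list()
  densities <- list()
  for (i in seq_along(keys)) {
    if (stringr::str_starts(keys[i], "density.")) {
      cls <- sub("^density\\.", "", keys[i])
      densities[[cls]] <- parse_val(vals[i])
    } else {
      args[[keys[i]]] <- parse_val(vals[i])
    }
  }
  if (length(densities) > 0) {
    args$motif_densities <- densities
  }
  unknown <- setdiff(names(args), names(formals(sim_config)))
  if (length(unknown) > 0) {
    cre_abort(sprintf("Unknown config key(s): %s.",
                      paste(unknown, collapse = ", ")))
  }
  do.call(sim_config, args)
}
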