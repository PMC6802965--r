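IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Built-in transcription factor motif set
#'
#' A small curated set of consensus motifs covering the families that
#' dominate photoreceptor and bipolar-cell open chromatin: K50 and Q50
#' paired-type homeodomain sites, the bHLH E-box, CTCF, a nuclear-receptor
#' half site and a MADS box. The two Q50 variants (TAATTA/TAATTG) are
#' represented by the single degenerate consensus TAATTR. The E-box family
#' (CANNTG) is represented by the high-information palindromic instance
#' CAGCTG: the degenerate family consensus matches random sequence every
#' ~128 bp and would saturate peak-level presence calls.
#'
#' @return A tibble with columns `motif` (identifier), `consensus`
#'   (IUPAC string) and `family`.
#' @examples
#' cre_motifs()
#' @export
cre_motifs <- function() {
  tibble(
    motif = c("K50_HD", "Q50_HD", "Ebox", "CTCF", "NR_halfsite", "MADS"),
    consensus = c("TAATCC", "TAATTR", "CAGCTG", "CCACNAGGTGGCAG", "AGGTCA",
                  "CTAWWWWTAG"),
    family = c("K50", "Q50", "Ebox", "CTCF", "NR", "MADS")
  )
}

check_iupac <- function(consensus) {
  if (!is.character(consensus) || length(consensus) != 1 || nchar(consensus) == 0) {
    cre_abort("Motif consensus must be a single nonempty string.")
  }
  chars <- strsplit(consensus, "")[[1]]
  bad <- setdiff(unique(chars), names(IUPAC_CODES))
  if (length(bad) > 0) {
    cre_abort(sprintf(
      "Non-IUPAC character(s) in motif consensus '%s': %s.",
      consensus, paste(bad, collapse = ", ")
    ))
  }
  invisible(consensus)
}

#' Reverse-complement an IUPAC consensus
#'
#' @param consensus IUPAC string.
#' @return The reverse complement, with degenerate codes complemented
#'   (e.g. R to Y).
#' @examples
#' revcomp_iupac("TAATCC")
#' @export
revcomp_iupac <- function(consensus) {
  check_iupac(consensus)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(consensus)))
}

# A motif is palindromic when it equals its own IUPAC reverse complement;
# such motifs match both strands at the same positions and are collapsed
# to a single "+" occurrence to avoid double counting.
is_palindromic <- function(consensus) {
  identical(toupper(consensus), revcomp_iupac(consensus))
}

# Draw one concrete realization of an IUPAC consensus (used when planting
# motifs into synthetic sequence).
realize_iupac <- function(consensus) {
  chars <- strsplit(toupper(consensus), "")[[1]]
  paste(vapply(chars, function(ch) {
    opts <- IUPAC_CODES[[ch]]
    if (length(opts) == 1) opts else sample(opts, 1)
  }, character(1)), collapse = "")
}

#' Scan peak sequences for motif occurrences
#'
#' Matches each IUPAC consensus exactly on both strands of every peak
#' sequence. Occurrences are anchored at the leftmost (genomic) base of the
#' match and reported as a signed offset from the peak summit. For
#' palindromic consensi the forward and reverse hits coincide and are
#' collapsed to a single occurrence on the "+" strand.
#'
#' @param peak_seqs Tibble with columns `peak_id`, `sequence`, and `summit`
#'   (0-based offset of the summit within the sequence).
#' @param motifs Tibble with columns `motif` and `consensus` (see
#'   [cre_motifs()]), or a single consensus string.
#' @return A tibble of occurrences: `peak_id`, `motif`, `offset` (match
#'   start minus summit, in bp), `strand` ("+" or "-") and `score`
#'   (1 for an exact consensus match).
#' @examples
#' scan_motifs(
#'   tibble::tibble(peak_id = "p1", sequence = "GGTAATCCGG", summit = 5L),
#'   tibble::tibble(motif = "K50_HD", consensus = "TAATCC")
#' )
#' @export
scan_motifs <- function(peak_seqs, motifs = cre_motifs()) {
  check_columns(peak_seqs, c("peak_id", "sequence", "summit"), "peak_seqs")
  if (is.character(motifs)) {
    motifs <- tibble(motif = motifs, consensus = motifs)
  }
  check_columns(motifs, c("motif", "consensus"), "motifs")
  purrr::walk(motifs$consensus, check_iupac)

  subject <- Biostrings::DNAStringSet(peak_seqs$sequence)
  names(subject) <- peak_seqs$peak_id
  summit <- setNames(peak_seqs$summit, peak_seqs$peak_id)

  one_strand <- function(consensus, strand_label) {
    hits <- Biostrings::vmatchPattern(consensus, subject, fixed = FALSE)
    n_hit <- S4Vectors::elementNROWS(hits)
    if (sum(n_hit) == 0) {
      return(tibble(peak_id = character(), offset = integer(),
                    strand = character()))
    }
    starts <- unlist(IRanges::start(hits), use.names = FALSE)
    ids <- rep(peak_seqs$peak_id, n_hit)
    tibble(
      peak_id = ids,
      offset = as.integer(starts - 1L - summit[ids]),
      strand = strand_label
    )
  }

  res <- purrr::pmap(motifs[, c("motif", "consensus")], function(motif, consensus) {
    consensus <- toupper(consensus)
    fwd <- one_strand(consensus, "+")
    if (is_palindromic(consensus)) {
      hits <- fwd
    } else {
      rev <- one_strand(revcomp_iupac(consensus), "-")
      hits <- bind_rows(fwd, rev)
    }
    hits$motif <- motif
    hits
  })
  bind_rows(res) |>
    mutate(score = 1) |>
    select("peak_id", "motif", "offset", "strand", "score") |>
    arrange(.data$motif, .data$peak_id, .data$offset, .data$strand)
}

#' Peak-by-motif presence table
#'
#' Collapses an occurrence list to presence/absence: a peak "contains" a
#' motif when it has at least one occurrence, regardless of multiplicity.
#' All proportion-based enrichment statistics in the package operate on
#' this table.
#'
#' @param occurrences Occurrence tibble from [scan_motifs()].
#' @param peak_ids Character vector of all peak identifiers (so peaks with
#'   zero hits appear as absences).
#' @param motifs Optional character vector of motif names to include;
#'   defaults to those present in `occurrences`.
#' @return A tibble with `peak_id` and one logical column per motif.
#' @export
motif_presence <- function(occurrences, peak_ids, motifs = NULL) {
  check_columns(occurrences, c("peak_id", "motif"), "occurrences")
  motifs <- motifs %||% sort(unique(occurrences$motif))
  out <- tibble(peak_id = as.character(peak_ids))
  hits <- distinct(occurrences, .data$peak_id, .data$motif)
  for (m in motifs) {
    out[[m]] <- out$peak_id %in% hits$peak_id[hits$motif == m]
  }
  out
}

#' Mutate homeodomain core sites in a sequence
#'
#' In-silico reporter mutagenesis of TAAT-core homeodomain sites: the
#' inactivating edit rewrites the TAAT core to TGGT; the Q50-conversion
#' edit rewrites the 6-mer starting at the site to TAATTA. Sequence length
#' is always preserved.
#'
#' @param sequence A single DNA string.
#' @param sites Tibble with columns `offset` (0-based position of the TAAT
#'   core) and `mode` ("null" for TAAT->TGGT, "q50" for 6-mer -> TAATTA).
#' @return The edited sequence.
#' @examples
#' mutate_motif_sites("TAATCC", tibble::tibble(offset = 0, mode = "null"))
#' mutate_motif_sites("TAATCC", tibble::tibble(offset = 0, mode = "q50"))
#' @export
mutate_motif_sites <- function(sequence, sites) {
  if (!is.character(sequence) || length(sequence) != 1) {
    cre_abort("`sequence` must be a single string.")
  }
  if (nrow(sites) == 0) {
    return(sequence)
  }
  check_columns(sites, c("offset", "mode"), "sites")
  chars <- strsplit(toupper(sequence), "")[[1]]
  for (i in seq_len(nrow(sites))) {
    off <- sites$offset[i]
    mode <- sites$mode[i]
    core <- paste(chars[(off + 1):(off + 4)], collapse = "")
    if (is.na(off) || off < 0 || off + 4 > length(chars) || core != "TAAT") {
      cre_abort(sprintf(
        "Site at offset %s does not start with a TAAT core (found '%s').",
        off, core
      ))
    }
    if (mode == "null") {
      chars[(off + 1):(off + 4)] <- c("T", "G", "G", "T")
    } else if (mode == "q50") {
      if (off + 6 > length(chars)) {
        cre_abort(sprintf("Q50 replacement at offset %s runs past the sequence end.", off))
      }
      chars[(off + 1):(off + 6)] <- c("T", "A", "A", "T", "T", "A")
    } else {
      cre_abort(sprintf("Unknown mutation mode '%s' (use 'null' or 'q50').", mode))
    }
  }
  paste(chars, collapse = "")
}
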