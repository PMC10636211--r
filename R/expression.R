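# Transcript abundance (FPKM), small-RNA size profiling with
# piRNA-signature calling, the virus-discovery contig triage filter, and a
# generic differential-expression table filter.

#' FPKM quantification
#'
#' `fpkm = fragments / ((target_length_nt / 1000) * (library_fragments /
#' 1e6))`; zero fragments give 0. Jointly scaling fragment counts and
#' library size leaves FPKM unchanged.
#'
#' @param counts Tibble with `target_id`, `fragments`, `target_length_nt`.
#' @param library_size Total mapped fragments in the library; defaults to
#'   `sum(counts$fragments)`.
#' @return `counts` with `library_fragments` and `fpkm` columns.
#' @export
fpkm_quantify <- function(counts, library_size = NULL) {
  library_size <- library_size %||% sum(counts$fragments)
  stopifnot(library_size > 0, all(counts$target_length_nt > 0),
            all(counts$fragments >= 0))
  counts |>
    dplyr::mutate(
      library_fragments = library_size,
      fpkm = .data$fragments /
        ((.data$target_length_nt / 1000) * (library_size / 1e6))
    )
}

#' Small-RNA size profile of a transcript with piRNA-signature call
#'
#' A read maps iff it is an exact substring of the transcript or its
#' reverse complement (perfect-match rule; one mismatch is unmapped); a
#' read mapping at several positions still counts once. Only read lengths
#' in `[min_len, max_len]` are considered. The piRNA flag is raised when
#' at least `min_reads` reads map and at least `min_fraction` of them fall
#' in the piRNA band (24-29 nt by default, the signature length range).
#'
#' @param reads Tibble with a `seq` column (e.g. from
#'   [simulate_srna_reads()]) or a character vector of read sequences.
#' @param transcript Transcript sequence (single string).
#' @param min_len,max_len Considered read-length window (nt).
#' @param pirna_band Length-2 vector, the piRNA length band (inclusive).
#' @param min_reads Minimum mapped reads for a piRNA call.
#' @param min_fraction Minimum fraction of mapped reads inside the band.
#' @param target_id Label for the profiled transcript.
#' @return A one-row tibble: `target_id`, `total_mapped`,
#'   `pirna_fraction`, `pirna_flag`, `counts` (list column tibble
#'   `length`, `count` over the full considered window).
#' @export
srna_size_profile <- function(reads, transcript, min_len = 18, max_len = 30,
                              pirna_band = c(24, 29), min_reads = 50,
                              min_fraction = 0.5, target_id = "transcript") {
  stopifnot(nchar(transcript) > 0)
  seqs <- if (is.data.frame(reads)) reads$seq else reads
  seqs <- toupper(seqs)
  len <- nchar(seqs)
  seqs <- seqs[len >= min_len & len <= max_len]
  tx <- toupper(transcript)
  both <- c(tx, revcomp(tx))
  mapped <- vapply(seqs, function(s) {
    any(stringr::str_detect(both, stringr::fixed(s)))
  }, logical(1), USE.NAMES = FALSE)
  mlen <- nchar(seqs[mapped])
  counts <- tibble(length = seq(min_len, max_len)) |>
    dplyr::mutate(count = vapply(.data$length, function(l) sum(mlen == l),
                                 integer(1)))
  total <- length(mlen)
  frac <- if (total > 0) {
    sum(mlen >= pirna_band[1] & mlen <= pirna_band[2]) / total
  } else 0
  tibble(
    target_id = target_id, total_mapped = total, pirna_fraction = frac,
    pirna_flag = total >= min_reads & frac >= min_fraction,
    counts = list(counts)
  )
}

#' Triage assembled contigs for candidate viral genomes
#'
#' A contig is kept only when all three criteria pass strictly: coverage
#' above 20x, length above 2000 bp, and best homology E-value below 1e-20.
#' The filter is monotone: improving any one criterion never discards a
#' kept contig.
#'
#' @param contigs Tibble with `contig_id`, `coverage_x`, `length_nt`,
#'   `best_evalue`.
#' @param min_coverage,min_length_nt,max_evalue Strict thresholds.
#' @return `contigs` with a logical `kept` column.
#' @export
triage_virus_contigs <- function(contigs, min_coverage = 20,
                                 min_length_nt = 2000, max_evalue = 1e-20) {
  contigs |>
    dplyr::mutate(kept = .data$coverage_x > min_coverage &
                    .data$length_nt > min_length_nt &
                    .data$best_evalue < max_evalue)
}

#' Generic differential-expression table filter
#'
#' Plain threshold operation over an externally fitted DE table: keep rows
#' with |log2 ratio| above `log2fc_min` and adjusted p below `padj_max`.
#' The differential model itself is out of scope here.
#'
#' @param table Tibble with `log2_ratio` and `padj` columns.
#' @param log2fc_min Minimum absolute log2 ratio (strict).
#' @param padj_max Maximum adjusted p (strict).
#' @return The rows passing both filters.
#' @export
filter_deg <- function(table, log2fc_min = 1, padj_max = 0.05) {
  dplyr::filter(table, abs(.data$log2_ratio) > log2fc_min,
                .data$padj < padj_max)
}
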