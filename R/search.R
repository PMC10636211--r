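# In-repo replacement for a translated (tBLASTn-style) homology search:
# six-frame translation, seeded protein-space local alignment, and
# Karlin-Altschul E-values.

#' Scoring scheme for protein-space local alignment
#'
#' Bundles the substitution matrix, affine gap penalties and the
#' Karlin-Altschul constants used to convert raw scores to E-values.
#' Defaults are the conventional translated-search settings: BLOSUM62 with
#' gap open 11 / extend 1 and the published gapped constants
#' lambda = 0.267, K = 0.041 for that matrix. The stop character `*`
#' scores -4 against every residue, so alignments may cross stop codons
#' (decayed elements routinely contain them).
#'
#' @param matrix Substitution matrix name (only `"BLOSUM62"` ships) or an
#'   integer matrix with single-letter dimnames.
#' @param gap_open,gap_extend Affine gap penalties; a gap of length g costs
#'   `gap_open + g * gap_extend`.
#' @param lambda,K Karlin-Altschul parameters (nats per score unit;
#'   dimensionless search-space constant).
#' @return An object of class `eve_scoring`.
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                           lambda = 0.267, K = 0.041) {
  if (is.character(matrix)) {
    stopifnot(matrix == "BLOSUM62")
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62
  } else {
    m <- matrix
  }
  storage.mode(m) <- "integer"
  stopifnot(isTRUE(all.equal(m, t(m))), lambda > 0, K > 0,
            gap_open >= 0, gap_extend > 0)
  structure(
    list(matrix = m, gap_open = as.integer(gap_open),
         gap_extend = as.integer(gap_extend), lambda = lambda, K = K),
    class = "eve_scoring"
  )
}

#' Six-frame translation with coordinate metadata
#'
#' Translates a nucleotide sequence in all six reading frames under the
#' standard genetic code. Codons containing `N` translate to `X`; stop
#' codons are emitted as `*` and retained. Frames -1..-3 translate the
#' reverse complement. The returned offsets let any amino-acid interval be
#' mapped back to forward-strand nucleotide coordinates with
#' [frame_to_genome()].
#'
#' @param seq A nucleotide string over `ACGTN`.
#' @return A tibble with columns `frame` (+1..+3, -1..-3), `aa`
#'   (translation), `n_codons`, `offset` (0-based offset of codon 1 on the
#'   translated strand).
#' @export
six_frame_translate <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1)
  seq <- normalize_nuc(seq)
  rc <- revcomp(seq)
  len <- nchar(seq)
  one <- function(s, off) {
    ncod <- (nchar(s) - off) %/% 3
    if (ncod <= 0) return("")
    sub <- substr(s, off + 1, off + 3 * ncod)
    as.character(Biostrings::translate(
      Biostrings::DNAString(sub), if.fuzzy.codon = "X"
    ))
  }
  frames <- c(1L, 2L, 3L, -1L, -2L, -3L)
  aa <- vapply(frames, function(f) {
    one(if (f > 0) seq else rc, abs(f) - 1L)
  }, character(1))
  tibble(frame = frames, aa = aa, n_codons = nchar(aa),
         offset = abs(frames) - 1L, contig_length = len)
}

#' Map amino-acid coordinates in a frame back to the forward strand
#'
#' @param frame Frame in +1..+3, -1..-3.
#' @param aa_start,aa_end 1-based inclusive amino-acid positions within the
#'   frame translation.
#' @param contig_length Contig length in nucleotides.
#' @return A list with `start`, `end` (0-based half-open, forward strand)
#'   and `strand` (`"+"`/`"-"`).
#' @export
frame_to_genome <- function(frame, aa_start, aa_end, contig_length) {
  off <- abs(frame) - 1L
  s_local <- off + 3L * (aa_start - 1L)        # 0-based on translated strand
  e_local <- off + 3L * aa_end                 # half-open
  if (frame > 0) {
    list(start = s_local, end = e_local, strand = "+")
  } else {
    list(start = contig_length - e_local, end = contig_length - s_local,
         strand = "-")
  }
}

#' Optimal protein local alignment (Smith-Waterman, affine gaps)
#'
#' Exhaustive dynamic-programming local alignment; the oracle against which
#' the seeded search engine is benchmarked. Tie-breaks are deterministic:
#' diagonal > up > left in the traceback, and among equal-score optima the
#' one with the smallest subject coordinates.
#'
#' @param query,subject Amino-acid strings.
#' @param scheme A [scoring_scheme()].
#' @return A one-row tibble with `score`, `query_start`, `query_end`,
#'   `subject_start`, `subject_end` (1-based inclusive amino-acid
#'   coordinates), `q_aln`, `s_aln`, `n_ident`, `align_length`,
#'   `pident`. Empty inputs or all-negative scores give score 0 and an
#'   empty alignment.
#' @export
smith_waterman_protein <- function(query, subject, scheme = scoring_scheme()) {
  stopifnot(is.character(query), is.character(subject))
  r <- sw_protein_cpp(normalize_aa_keep_stop(query),
                      normalize_aa_keep_stop(subject),
                      scheme$matrix, scheme$gap_open, scheme$gap_extend)
  tibble(
    score = r$score, query_start = r$qstart, query_end = r$qend,
    subject_start = r$sstart, subject_end = r$send,
    q_aln = r$q_aln, s_aln = r$s_aln, n_ident = r$nident,
    align_length = r$length,
    pident = ifelse(r$length > 0, 100 * r$nident / r$length, NA_real_)
  )
}

# translations contain '*'; keep it for scoring, map other junk to X
normalize_aa_keep_stop <- function(x) {
  x <- toupper(x)
  stringr::str_replace_all(x, paste0("[^", paste(AA20, collapse = ""), "X*]"), "X")
}

#' Karlin-Altschul E-value and bit score from a raw score
#'
#' `E = K * m * n * exp(-lambda * S)` with `m` the query length in residues
#' and `n` the total translated subject residues searched (all six frames);
#' `bit = (lambda * S - ln K) / ln 2`. E is strictly decreasing in S and
#' exactly linear in `n`.
#'
#' @param raw_score Raw alignment score(s).
#' @param query_aa_len Query length (residues).
#' @param searched_aa_len Total translated residues searched.
#' @param scheme A [scoring_scheme()].
#' @return A tibble with columns `evalue` and `bit_score`.
#' @export
evalue_from_score <- function(raw_score, query_aa_len, searched_aa_len,
                              scheme = scoring_scheme()) {
  if (any(query_aa_len <= 0) || any(searched_aa_len <= 0)) {
    stop("sequence lengths must be positive")
  }
  tibble(
    evalue = scheme$K * query_aa_len * searched_aa_len *
      exp(-scheme$lambda * raw_score),
    bit_score = (scheme$lambda * raw_score - log(scheme$K)) / log(2)
  )
}

#' Seeded six-frame translated search of protein queries against a genome
#'
#' The engine behind EVE discovery: each contig is translated in six
#' frames; exact protein k-mer seeds shared with the query trigger an
#' ungapped X-drop extension, and extensions passing the trigger score are
#' realigned by banded affine-gap local DP around the seed diagonal.
#' Surviving alignments are deduplicated by containment, mapped to
#' forward-strand nucleotide coordinates and filtered by E-value. Hits in
#' different frames are reported separately; frameshift-decayed elements
#' are stitched downstream by [merge_hits()].
#'
#' @param queries Protein tibble (`id`, `seq`), e.g. from
#'   [read_fasta()] with `type = "protein"`.
#' @param genome Genome tibble (`id`, `seq`).
#' @param scheme A [scoring_scheme()].
#' @param seed_k Exact k-mer seed length (>= 3).
#' @param x_drop X-drop threshold (score units) for ungapped extension.
#' @param band Half-width of the gapped DP band around the seed diagonal.
#' @param trigger Minimum ungapped extension score to attempt gapped DP.
#' @param evalue_max Report hits with `evalue <= evalue_max`.
#' @return A tibble of hits: `query_id`, `contig_id`, `frame`, `strand`,
#'   `subject_start`/`subject_end` (0-based half-open nucleotides, forward
#'   strand), `query_start`/`query_end` (1-based inclusive residues),
#'   `raw_score`, `bit_score`, `evalue`, `pident`, `n_ident`,
#'   `align_length`, `q_aln`, `s_aln`.
#' @export
seeded_translated_search <- function(queries, genome,
                                     scheme = scoring_scheme(),
                                     seed_k = 4, x_drop = 20, band = 32,
                                     trigger = 30, evalue_max = 1e-10) {
  stopifnot(is.data.frame(queries), is.data.frame(genome), seed_k >= 3)
  empty <- tibble(
    query_id = character(), contig_id = character(), frame = integer(),
    strand = character(), subject_start = integer(), subject_end = integer(),
    query_start = integer(), query_end = integer(), raw_score = integer(),
    bit_score = numeric(), evalue = numeric(), pident = numeric(),
    n_ident = integer(), align_length = integer(), q_aln = character(),
    s_aln = character()
  )
  if (nrow(queries) == 0 || nrow(genome) == 0) return(empty)
  trans <- genome |>
    dplyr::rowwise() |>
    dplyr::reframe(contig_id = .data$id, six_frame_translate(.data$seq))
  searched_aa <- sum(trans$n_codons)
  if (searched_aa == 0) return(empty)

  hits <- purrr::pmap_dfr(
    tidyr::expand_grid(qi = seq_len(nrow(queries)), ti = seq_len(nrow(trans))),
    function(qi, ti) {
      fr <- trans[ti, ]
      if (fr$n_codons < seed_k) return(NULL)
      raw <- seeded_frame_search_cpp(
        queries$seq[qi], fr$aa, scheme$matrix, scheme$gap_open,
        scheme$gap_extend, as.integer(seed_k), as.integer(x_drop),
        as.integer(band), as.integer(trigger)
      )
      if (nrow(raw) == 0) return(NULL)
      raw <- as_tibble(raw)
      coords <- purrr::map2(raw$subject_aa_start, raw$subject_aa_end,
                            function(a, b) frame_to_genome(fr$frame, a, b,
                                                           fr$contig_length))
      raw |>
        dplyr::mutate(
          query_id = queries$id[qi],
          contig_id = fr$contig_id,
          frame = fr$frame,
          strand = purrr::map_chr(coords, "strand"),
          subject_start = purrr::map_int(coords, ~ as.integer(.x$start)),
          subject_end = purrr::map_int(coords, ~ as.integer(.x$end))
        )
    }
  )
  if (is.null(hits) || nrow(hits) == 0) return(empty)
  qlen <- setNames(nchar(queries$seq), queries$id)
  ka <- evalue_from_score(hits$raw_score, qlen[hits$query_id], searched_aa,
                          scheme)
  hits |>
    dplyr::mutate(
      evalue = ka$evalue, bit_score = ka$bit_score,
      pident = 100 * .data$n_ident / .data$align_length
    ) |>
    dplyr::filter(.data$evalue <= evalue_max) |>
    dplyr::select(dplyr::all_of(names(empty))) |>
    dplyr::arrange(.data$contig_id, .data$subject_start, .data$query_id)
}

#' Export hits in a BLAST tabular (outfmt-6 style) layout
#'
#' Coordinates in the export are 1-based inclusive, with subject start >
#' subject end on the minus strand, mirroring BLAST conventions; internal
#' tibbles stay 0-based half-open.
#'
#' @param hits Hit tibble from [seeded_translated_search()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  out <- hits |>
    dplyr::mutate(
      mismatches = .data$align_length - .data$n_ident -
        stringr::str_count(.data$q_aln, "-") -
        stringr::str_count(.data$s_aln, "-"),
      gaps = stringr::str_count(.data$q_aln, "-") +
        stringr::str_count(.data$s_aln, "-"),
      sstart = dplyr::if_else(.data$strand == "+",
                              .data$subject_start + 1L, .data$subject_end),
      send = dplyr::if_else(.data$strand == "+",
                            .data$subject_end, .data$subject_start + 1L)
    ) |>
    dplyr::transmute(
      qseqid = .data$query_id, sseqid = .data$contig_id,
      pident = round(.data$pident, 3), length = .data$align_length,
      mismatch = .data$mismatches, gapopen = .data$gaps,
      qstart = .data$query_start, qend = .data$query_end,
      sstart = .data$sstart, send = .data$send,
      evalue = .data$evalue, bitscore = round(.data$bit_score, 1),
      frame = .data$frame
    )
  readr::write_tsv(out, path)
  invisible(path)
}
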