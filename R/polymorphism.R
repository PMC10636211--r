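# Per-locus polymorphism levels from variant calls, and the fast-/slow-
# evolving gene (FEG/SEG) baseline built from ortholog p-distances.

#' Polymorphism level per individual per target
#'
#' Counts distinct non-reference variant positions inside each target
#' interval for each individual and scales to variants per kb. SNPs and
#' indels each count one position; duplicate records at the same position
#' count once.
#'
#' @param variants Variant tibble from [read_variants()] or
#'   [simulate_variants()].
#' @param targets Target tibble (`target_id` or `locus_id`, `contig_id`,
#'   `start`, `end`), 0-based half-open.
#' @param individuals Individuals to report; defaults to those present in
#'   `variants`. Individuals without variants in a target get level 0.
#' @return A tibble: `individual_id`, `target_id`, `variant_sites`,
#'   `target_length_nt`, `level` (variants per kb).
#' @export
polymorphism_level <- function(variants, targets, individuals = NULL) {
  if (!"target_id" %in% names(targets) && "locus_id" %in% names(targets)) {
    targets <- dplyr::rename(targets, target_id = "locus_id")
  }
  stopifnot(all(targets$end > targets$start))
  individuals <- individuals %||% sort(unique(variants$individual_id))
  v <- variants |>
    dplyr::filter(.data$genotype_is_nonref) |>
    dplyr::distinct(.data$individual_id, .data$contig_id, .data$position)
  grid <- tidyr::expand_grid(individual_id = individuals,
                             ti = seq_len(nrow(targets)))
  purrr::pmap_dfr(grid, function(individual_id, ti) {
    tg <- targets[ti, ]
    n <- sum(v$individual_id == individual_id &
               v$contig_id == tg$contig_id &
               v$position >= tg$start & v$position < tg$end)
    tibble(
      individual_id = individual_id, target_id = tg$target_id,
      variant_sites = as.integer(n),
      target_length_nt = as.integer(tg$end - tg$start),
      level = 1000 * n / (tg$end - tg$start)
    )
  })
}

#' p-distance of an alignment
#'
#' For each pair of rows, the fraction of differing sites over columns
#' with no gap in either row of the pair; for more than two rows the
#' alignment's value is the mean over all pairs. Errors if a pair has no
#' comparable (ungapped) columns.
#'
#' @param seqs Character vector of aligned sequences (equal length,
#'   `-` for gaps), length >= 2.
#' @return A single numeric value in [0, 1].
#' @export
p_distance <- function(seqs) {
  stopifnot(length(seqs) >= 2, length(unique(nchar(seqs))) == 1)
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  pairs <- utils::combn(nrow(m), 2)
  d <- apply(pairs, 2, function(pr) {
    a <- m[pr[1], ]; b <- m[pr[2], ]
    ok <- a != "-" & b != "-"
    if (!any(ok)) stop("no ungapped columns shared by a sequence pair")
    mean(a[ok] != b[ok])
  })
  mean(d)
}

#' Per-ortholog alignment statistics
#'
#' @param alignments Tibble (`ortholog_id`, `taxon`, `seq`) of aligned
#'   sequences.
#' @return A tibble: `ortholog_id`, `n_taxa`, `length`, `gap_fraction`
#'   (fraction of columns containing a gap in any row), `p_distance`.
#' @export
ortholog_stats <- function(alignments) {
  alignments |>
    dplyr::group_by(.data$ortholog_id) |>
    dplyr::summarise(
      n_taxa = dplyr::n(),
      length = nchar(.data$seq[1]),
      gap_fraction = {
        m <- do.call(rbind, strsplit(.data$seq, ""))
        mean(apply(m == "-", 2, any))
      },
      p_distance = p_distance(.data$seq),
      .groups = "drop"
    )
}

#' Drop poorly aligned orthologs
#'
#' An alignment is removed when strictly more than `max_gap_fraction` of
#' its columns are gapped.
#'
#' @param stats Tibble from [ortholog_stats()] (needs `gap_fraction`).
#' @param max_gap_fraction Gap-fraction ceiling (default 10%).
#' @return The retained rows.
#' @export
filter_poorly_aligned <- function(stats, max_gap_fraction = 0.10) {
  dplyr::filter(stats, .data$gap_fraction <= max_gap_fraction)
}

#' Classify fast- and slow-evolving genes from p-distances
#'
#' Orthologs are ranked by p-distance (descending); the first
#' `floor(top_fraction * n)` are fast-evolving genes (FEG) and the last as
#' many are slow-evolving genes (SEG). Ties are broken by ortholog id so
#' the classification is deterministic. At n = 1462 and the default 5%
#' fraction this yields 73 genes in each class.
#'
#' @param stats Gap-filtered tibble from [ortholog_stats()].
#' @param top_fraction Fraction taken at each extreme.
#' @return `stats` with a `class` column (`"FEG"`, `"SEG"`, `"neither"`),
#'   ordered by descending p-distance.
#' @export
classify_feg_seg <- function(stats, top_fraction = 0.05) {
  n <- nrow(stats)
  if (n < 20) {
    warning("fewer than 20 orthologs: FEG/SEG classes left empty")
    return(dplyr::mutate(stats, class = "neither"))
  }
  k <- floor(top_fraction * n)
  stats |>
    dplyr::arrange(dplyr::desc(.data$p_distance), .data$ortholog_id) |>
    dplyr::mutate(class = dplyr::case_when(
      dplyr::row_number() <= k ~ "FEG",
      dplyr::row_number() > n - k ~ "SEG",
      TRUE ~ "neither"
    ))
}

#' Compare polymorphism-level distributions between groups
#'
#' Distribution summaries (n, median, quartiles) per group, the numbers a
#' violin plot of EVE vs FEG vs SEG levels is drawn from. Empty groups are
#' reported with NA summaries.
#'
#' @param eve_records,feg_records,seg_records Tibbles from
#'   [polymorphism_level()] (any may be empty).
#' @return A tibble: `group`, `n`, `median`, `q25`, `q75`.
#' @export
compare_levels <- function(eve_records, feg_records, seg_records) {
  groups <- list(EVE = eve_records, FEG = feg_records, SEG = seg_records)
  purrr::imap_dfr(groups, function(rec, nm) {
    if (is.null(rec) || nrow(rec) == 0) {
      return(tibble(group = nm, n = 0L, median = NA_real_,
                    q25 = NA_real_, q75 = NA_real_))
    }
    tibble(group = nm, n = nrow(rec),
           median = median(rec$level),
           q25 = unname(quantile(rec$level, 0.25)),
           q75 = unname(quantile(rec$level, 0.75)))
  })
}
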