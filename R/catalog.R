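# Turn raw translated hits into a vetted EVE locus catalogue: merge,
# stringency-flag, reciprocal-filter, assign the cognate virus, and predict
# flank-extended ORFs.

#' Merge consecutive translated hits into candidate loci
#'
#' Hits with `evalue < evalue_merge` on the same contig and strand whose
#' intervals are separated by at most `max_gap_nt` are merged into one
#' locus spanning `min(start)..max(end)`. Frames may differ within a locus
#' — decayed elements are routinely disrupted by frameshifts, so stitching
#' across frames happens here rather than in the aligner. Merging is
#' independent of input order and idempotent. Hits on opposite strands are
#' never merged.
#'
#' @param hits Hit tibble from [seeded_translated_search()], or a locus
#'   tibble from a previous merge (idempotence).
#' @param max_gap_nt Maximum nucleotide gap between merged intervals.
#' @param evalue_merge Only hits below this E-value participate.
#' @return A locus tibble: `locus_id`, `contig_id`, `start`, `end`,
#'   `strand`, `length_nt`, `n_hits`, `best_evalue`, `best_raw_score`,
#'   `best_query_id`, `member_hits` (list column of member hit rows).
#' @export
merge_hits <- function(hits, max_gap_nt = 1000, evalue_merge = 1e-5) {
  stopifnot(is.data.frame(hits))
  if ("best_evalue" %in% names(hits) && !"evalue" %in% names(hits)) {
    # locus tibble fed back in: each locus is one interval carrying the
    # weight of its member hits (keeps merging idempotent)
    hits <- hits |>
      dplyr::mutate(evalue = .data$best_evalue,
                    raw_score = .data$best_raw_score,
                    query_id = .data$best_query_id,
                    subject_start = .data$start, subject_end = .data$end,
                    weight = .data$n_hits)
  }
  if (!"weight" %in% names(hits)) hits$weight <- 1L
  h <- hits |>
    dplyr::filter(.data$evalue < evalue_merge) |>
    dplyr::arrange(.data$contig_id, .data$strand, .data$subject_start)
  if (nrow(h) == 0) {
    return(tibble(locus_id = character(), contig_id = character(),
                  start = integer(), end = integer(), strand = character(),
                  length_nt = integer(), n_hits = integer(),
                  best_evalue = numeric(), best_raw_score = numeric(),
                  best_query_id = character(), member_hits = list()))
  }
  merged <- h |>
    dplyr::group_by(.data$contig_id, .data$strand) |>
    dplyr::group_modify(function(g, key) {
      ir <- IRanges::IRanges(start = g$subject_start + 1L, end = g$subject_end)
      red <- IRanges::reduce(ir, min.gapwidth = max_gap_nt + 1L,
                             with.revmap = TRUE)
      revmap <- S4Vectors::mcols(red)$revmap
      purrr::map_dfr(seq_along(red), function(i) {
        members <- g[revmap[[i]], , drop = FALSE]
        best <- members[order(members$evalue, -members$raw_score,
                              members$query_id)[1], ]
        tibble(
          start = as.integer(IRanges::start(red)[i] - 1L),
          end = as.integer(IRanges::end(red)[i]),
          n_hits = sum(members$weight),
          best_evalue = best$evalue,
          best_raw_score = as.numeric(best$raw_score),
          best_query_id = best$query_id,
          member_hits = list(members)
        )
      })
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$contig_id, .data$start, .data$strand)
  merged |>
    dplyr::mutate(
      locus_id = sprintf("eve%03d", dplyr::row_number()),
      length_nt = .data$end - .data$start
    ) |>
    dplyr::select("locus_id", "contig_id", "start", "end", "strand",
                  "length_nt", "n_hits", "best_evalue", "best_raw_score",
                  "best_query_id", "member_hits")
}

#' Flag loci passing stringent catalogue criteria
#'
#' `passes_stringent` is true when the best member hit's E-value is below
#' `evalue_max` and the locus spans at least `min_len_nt` nucleotides. No
#' locus is removed, only flagged.
#'
#' @param loci Locus tibble from [merge_hits()].
#' @param evalue_max Stringent E-value ceiling.
#' @param min_len_nt Minimum locus length (nt).
#' @return `loci` with a logical `passes_stringent` column.
#' @export
apply_stringency <- function(loci, evalue_max = 1e-10, min_len_nt = 350) {
  loci |>
    dplyr::mutate(passes_stringent = .data$best_evalue < evalue_max &
                    .data$length_nt >= min_len_nt)
}

#' Extract locus nucleotide sequences from the assembly
#'
#' @param loci Locus tibble.
#' @param genome Genome tibble (`id`, `seq`).
#' @return A tibble (`id` = locus id, `seq`, `length`) with forward-strand
#'   sequences.
#' @export
locus_sequences <- function(loci, genome) {
  seqs <- setNames(genome$seq, genome$id)
  missing <- setdiff(loci$contig_id, names(seqs))
  if (length(missing)) stop("contig(s) not in assembly: ",
                            paste(missing, collapse = ", "))
  tibble(
    id = loci$locus_id,
    seq = substr(seqs[loci$contig_id], loci$start + 1L, loci$end),
    length = loci$end - loci$start
  )
}

#' Reciprocal filter against a decoy proteome
#'
#' Each locus sequence is re-searched (same translated engine) against the
#' union of the viral query set and a background/decoy proteome; the locus
#' is kept only when its top bit-score hit is viral. An exact bit-score tie
#' keeps the locus but flags it. An empty decoy set keeps everything, with
#' a warning, since nothing can contradict the viral assignment.
#'
#' @param loci Locus tibble.
#' @param genome Genome tibble the loci live on.
#' @param decoy_proteins Background protein tibble (`id`, `seq`).
#' @param viral_proteins Viral protein tibble (`id`, `seq`).
#' @param scheme A [scoring_scheme()].
#' @param evalue_max Hit ceiling for the reciprocal search (loose by
#'   design; the comparison is on bit scores).
#' @return `loci` with columns `reciprocal_keep`, `reciprocal_tie`,
#'   `reciprocal_best_source` (`"viral"`, `"decoy"` or `"none"`).
#' @export
reciprocal_filter <- function(loci, genome, decoy_proteins, viral_proteins,
                              scheme = scoring_scheme(), evalue_max = 1e-3) {
  if (nrow(loci) == 0) {
    return(dplyr::mutate(loci, reciprocal_keep = logical(),
                         reciprocal_tie = logical(),
                         reciprocal_best_source = character()))
  }
  if (is.null(decoy_proteins) || nrow(decoy_proteins) == 0) {
    warning("empty decoy proteome: reciprocal filter keeps all loci")
    return(dplyr::mutate(loci, reciprocal_keep = TRUE,
                         reciprocal_tie = FALSE,
                         reciprocal_best_source = "viral"))
  }
  lseqs <- locus_sequences(loci, genome)
  db <- dplyr::bind_rows(
    dplyr::mutate(viral_proteins[c("id", "seq")], source = "viral"),
    dplyr::mutate(decoy_proteins[c("id", "seq")], source = "decoy")
  )
  res <- purrr::map_dfr(seq_len(nrow(loci)), function(i) {
    hits <- seeded_translated_search(db[c("id", "seq")], lseqs[i, c("id", "seq")],
                                     scheme = scheme, evalue_max = evalue_max)
    if (nrow(hits) == 0) {
      return(tibble(reciprocal_keep = FALSE, reciprocal_tie = FALSE,
                    reciprocal_best_source = "none"))
    }
    hits <- dplyr::left_join(hits, db[c("id", "source")],
                             by = c(query_id = "id"))
    top <- max(hits$bit_score)
    srcs <- unique(hits$source[hits$bit_score == top])
    tie <- length(srcs) > 1
    tibble(
      reciprocal_keep = "viral" %in% srcs,
      reciprocal_tie = tie,
      reciprocal_best_source = if (tie) "viral" else srcs[1]
    )
  })
  dplyr::bind_cols(loci, res)
}

#' Assign each locus its best-matching viral protein
#'
#' The locus sequence is searched (translated) against the viral protein
#' panel; the maximum bit-score alignment supplies the cognate virus, gene
#' label and percent identity reported in the catalogue.
#'
#' @param loci Locus tibble.
#' @param genome Genome tibble.
#' @param viral_proteins Protein tibble (`id`, `seq`, optionally
#'   `virus_id`, `gene_label`).
#' @param scheme A [scoring_scheme()].
#' @param evalue_max Ceiling for assignment hits; loci with nothing below
#'   it are flagged unassigned.
#' @return `loci` with `best_protein_id`, `best_virus_id`,
#'   `best_gene_label`, `best_pident`, `best_hit_evalue`, `assigned`.
#' @export
assign_best_hit <- function(loci, genome, viral_proteins,
                            scheme = scoring_scheme(), evalue_max = 1e-3) {
  if (nrow(loci) == 0) {
    return(dplyr::mutate(loci, best_protein_id = character(),
                         best_virus_id = character(),
                         best_gene_label = character(),
                         best_pident = numeric(),
                         best_hit_evalue = numeric(), assigned = logical()))
  }
  lseqs <- locus_sequences(loci, genome)
  res <- purrr::map_dfr(seq_len(nrow(loci)), function(i) {
    hits <- seeded_translated_search(viral_proteins[c("id", "seq")],
                                     lseqs[i, c("id", "seq")],
                                     scheme = scheme, evalue_max = evalue_max)
    if (nrow(hits) == 0) {
      return(tibble(best_protein_id = NA_character_,
                    best_virus_id = NA_character_,
                    best_gene_label = NA_character_,
                    best_pident = NA_real_, best_hit_evalue = NA_real_,
                    assigned = FALSE))
    }
    best <- hits[order(-hits$bit_score, hits$evalue, hits$query_id)[1], ]
    meta <- viral_proteins[match(best$query_id, viral_proteins$id), ]
    tibble(
      best_protein_id = best$query_id,
      best_virus_id = if ("virus_id" %in% names(meta))
        meta$virus_id else NA_character_,
      best_gene_label = if ("gene_label" %in% names(meta))
        meta$gene_label else NA_character_,
      best_pident = best$pident,
      best_hit_evalue = best$evalue,
      assigned = TRUE
    )
  })
  dplyr::bind_cols(loci, res)
}

#' Predict ORFs in a flank-extended window around each locus
#'
#' Each locus is extended by `flank_nt` bases on both sides (clipped at
#' contig bounds) and scanned on both strands for complete ORFs
#' (ATG ... stop, in frame) of at least `min_orf_nt` nucleotides
#' (stop codon included). Within each stop-to-stop segment the ORF starts
#' at the first ATG, i.e. the longest ORF per segment is reported. The
#' longest ORF overlapping the locus is flagged primary.
#'
#' @param loci Locus tibble.
#' @param genome Genome tibble.
#' @param flank_nt Flank size (nt) on each side.
#' @param min_orf_nt Minimum ORF length in nucleotides, stop included.
#' @return A tibble of ORF calls: `locus_id`, `orf_start`, `orf_end`
#'   (0-based half-open genome coordinates), `strand`, `length_nt`,
#'   `protein`, `overlaps_locus`, `primary`.
#' @export
predict_orf_with_flanks <- function(loci, genome, flank_nt = 2000,
                                    min_orf_nt = 300) {
  seqs <- setNames(genome$seq, genome$id)
  purrr::map_dfr(seq_len(nrow(loci)), function(i) {
    lc <- loci[i, ]
    clen <- nchar(seqs[[lc$contig_id]])
    wstart <- max(0L, lc$start - as.integer(flank_nt))
    wend <- min(clen, lc$end + as.integer(flank_nt))
    window <- substr(seqs[[lc$contig_id]], wstart + 1L, wend)
    orfs <- find_orfs(window, min_orf_nt = min_orf_nt)
    if (nrow(orfs) == 0) return(NULL)
    orfs |>
      dplyr::mutate(
        locus_id = lc$locus_id,
        orf_start = .data$start + wstart,
        orf_end = .data$end + wstart,
        overlaps_locus = .data$orf_start < lc$end & lc$start < .data$orf_end
      ) |>
      dplyr::mutate(
        primary = .data$overlaps_locus &
          .data$length_nt == max(.data$length_nt[.data$overlaps_locus],
                                 -Inf)
      ) |>
      dplyr::select("locus_id", "orf_start", "orf_end", "strand",
                    "length_nt", "protein", "overlaps_locus", "primary")
  })
}

# complete ORFs (ATG..stop) on both strands of a window; coordinates
# 0-based half-open relative to the window's forward strand
find_orfs <- function(window, min_orf_nt = 300) {
  len <- nchar(window)
  frames <- six_frame_translate(window)
  out <- purrr::pmap_dfr(frames, function(frame, aa, n_codons, offset,
                                          contig_length) {
    if (n_codons == 0) return(NULL)
    # stop-to-stop segments; ORF = first M .. following stop (inclusive)
    stops <- c(0L, stringr::str_locate_all(aa, "\\*")[[1]][, 1])
    purrr::map_dfr(seq_len(length(stops) - 1), function(k) {
      seg_start <- stops[k] + 1L      # first aa position after previous stop
      seg_stop <- stops[k + 1]        # position of the stop codon
      seg <- substr(aa, seg_start, seg_stop - 1L)
      m <- unname(stringr::str_locate(seg, "M")[1, 1])
      if (is.na(m)) return(NULL)
      aa_start <- seg_start + m - 1L  # position of the initiator M
      orf_nt <- 3L * (seg_stop - aa_start + 1L)  # incl. stop codon
      if (orf_nt < min_orf_nt) return(NULL)
      g <- frame_to_genome(frame, aa_start, seg_stop, contig_length)
      tibble(start = g$start, end = g$end, strand = g$strand,
             length_nt = orf_nt,
             protein = substr(aa, aa_start, seg_stop - 1L))
    })
  })
  if (is.null(out) || nrow(out) == 0) {
    return(tibble(start = integer(), end = integer(), strand = character(),
                  length_nt = integer(), protein = character()))
  }
  dplyr::arrange(out, .data$start, .data$strand)
}

#' Write the locus catalogue as a BED-like TSV
#'
#' @param loci Locus tibble (after [assign_best_hit()] if available).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalog_tsv <- function(loci, path) {
  out <- loci |> dplyr::select(-dplyr::any_of("member_hits"))
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write ORF calls as GFF3
#'
#' @param orfs ORF tibble from [predict_orf_with_flanks()].
#' @param loci Locus tibble (supplies the contig for each locus).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_orfs_gff3 <- function(orfs, loci, path) {
  contig <- setNames(loci$contig_id, loci$locus_id)
  lines <- c("##gff-version 3")
  if (nrow(orfs) > 0) {
    lines <- c(lines, sprintf(
      "%s\tevescan\tORF\t%d\t%d\t.\t%s\t0\tID=%s_orf%d;locus=%s;primary=%s",
      contig[orfs$locus_id], orfs$orf_start + 1L, orfs$orf_end,
      orfs$strand, orfs$locus_id, seq_len(nrow(orfs)), orfs$locus_id,
      tolower(orfs$primary)
    ))
  }
  readr::write_lines(lines, path)
  invisible(path)
}
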