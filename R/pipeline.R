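# Configuration and end-to-end orchestration: simulate -> discover ->
# population chains, with a run manifest for reproducibility.

#' Pipeline configuration
#'
#' All thresholds of the workflow in one validated list, with the
#' published screening values as defaults. Unknown keys are rejected.
#'
#' @param ... Overrides of the defaults shown in the usage.
#' @return A named list of class `eve_config`.
#' @export
eve_config <- function(...) {
  defaults <- list(
    seed = 1L,
    # translated search
    evalue_search = 1e-10, seed_k = 4L, x_drop = 20L, band = 32L,
    trigger = 30L, gap_open = 11L, gap_extend = 1L,
    lambda = 0.267, K = 0.041,
    # catalogue
    evalue_merge = 1e-5, max_gap_nt = 1000L, evalue_stringent = 1e-10,
    min_len_nt = 350L, flank_nt = 2000L, min_orf_nt = 300L,
    # presence
    presence_profile = "strict", window_nt = 100L,
    # polymorphism / rate classes
    max_gap_fraction = 0.10, top_fraction = 0.05,
    # sRNA
    pirna_min_reads = 50L, pirna_min_fraction = 0.5,
    # simulation shape
    n_loci = 20L, contig_length = 1000000L, identity_range = c(0.6, 1),
    frameshift_prob = 0.3, strand_mix = 0.5,
    depth_present = 30, depth_absent = 0, read_length = 100L,
    n_individuals = 10L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, over)
  stopifnot(cfg$evalue_search > 0, cfg$evalue_merge > 0,
            cfg$min_len_nt >= 1, cfg$max_gap_nt >= 0,
            cfg$max_gap_fraction >= 0, cfg$max_gap_fraction <= 1,
            cfg$top_fraction > 0, cfg$top_fraction <= 0.5,
            cfg$presence_profile %in% c("strict", "relaxed"))
  structure(cfg, class = "eve_config")
}

config_scheme <- function(config) {
  scoring_scheme(gap_open = config$gap_open, gap_extend = config$gap_extend,
                 lambda = config$lambda, K = config$K)
}

#' Generate the full synthetic input bundle with ground truth
#'
#' One call produces a totivirus-like query set, a host assembly with
#' implanted decayed loci, an implant-free control assembly, per-individual
#' read placements, variant sites, ortholog alignments and small-RNA
#' reads, all deterministic in the config seed. When `dir` is given, the
#' bundle is also written to disk (FASTA/TSV).
#'
#' @param config An [eve_config()].
#' @param dir Optional output directory.
#' @return A named list: `virus`, `genome`, `control_genome`, `truth`,
#'   `placements`, `presence`, `variants`, `orthologs`, `srna_reads`,
#'   `manifest`.
#' @export
run_simulate <- function(config = eve_config(), dir = NULL) {
  seed <- config$seed
  virus <- simulate_totivirus(seed)
  host <- simulate_host_genome(seed, n_contigs = 1,
                               contig_length = config$contig_length)
  control <- simulate_host_genome(seed + 1, n_contigs = 1,
                                  contig_length = config$contig_length)
  imp <- if (config$n_loci > 0) {
    implant_eves(seed, host, virus$proteins, n_loci = config$n_loci,
                 identity_range = config$identity_range,
                 frameshift_prob = config$frameshift_prob,
                 strand_mix = config$strand_mix)
  } else {
    list(genome = host, truth = tibble(
      locus_id = character(), contig_id = character(), start = integer(),
      end = integer(), strand = character(), protein_id = character(),
      gene_label = character(), fragment_aa_start = integer(),
      fragment_aa_len = integer(), target_identity = numeric(),
      realized_identity = numeric(), n_frameshift = integer()))
  }
  inds <- sprintf("ind%02d", seq_len(config$n_individuals))
  contig_lengths <- setNames(imp$genome$length, imp$genome$id)
  reads <- simulate_read_alignments(
    seed, imp$truth, inds, depth_present = config$depth_present,
    depth_absent = config$depth_absent, read_length = config$read_length,
    contig_lengths = contig_lengths
  )
  variants <- simulate_variants(seed, imp$truth, sites_per_kb = 6,
                                individuals = inds)
  orth <- simulate_ortholog_alignments(
    seed, n_orthologs = 200, taxa = 3,
    rate_classes = data.frame(rate = c(0.4, 0.2, 0.05),
                              fraction = c(0.05, 0.90, 0.05)),
    length_nt = 2000
  )
  srna <- simulate_srna_reads(seed, virus$genome$seq, n_reads = 500)
  out <- list(virus = virus, genome = imp$genome, control_genome = control,
              truth = imp$truth, placements = reads$placements,
              presence = reads$presence, variants = variants,
              orthologs = orth, srna_reads = srna,
              manifest = run_manifest(config, "simulate"))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(imp$genome, file.path(dir, "host_genome.fasta"))
    write_fasta(control, file.path(dir, "control_genome.fasta"))
    write_fasta(virus$proteins, file.path(dir, "viral_proteins.fasta"))
    readr::write_tsv(imp$truth, file.path(dir, "truth.tsv"))
    readr::write_tsv(
      dplyr::rename(reads$placements, individual = "individual_id",
                    contig = "contig_id"),
      file.path(dir, "placements.tsv"))
    readr::write_tsv(
      dplyr::transmute(variants, individual = .data$individual_id,
                       contig = .data$contig_id, position = .data$position,
                       ref = .data$ref_allele, alt = .data$alt_allele),
      file.path(dir, "variants.tsv"))
    write_fasta(dplyr::transmute(srna, id = .data$read_id, seq = .data$seq),
                file.path(dir, "srna_reads.fasta"))
    readr::write_tsv(tibble(key = names(out$manifest),
                            value = vapply(out$manifest, paste, character(1),
                                           collapse = ",")),
                     file.path(dir, "manifest.tsv"))
  }
  out
}

#' Run the discovery chain: search, merge, stringency, reciprocal, assign
#'
#' The full locus-catalogue workflow over one assembly: seeded translated
#' search at the search cutoff, merging of consecutive hits, stringency
#' flagging (E-value and minimum length), optional reciprocal filtering
#' against a decoy proteome, best-hit virus assignment, and flank-extended
#' ORF prediction.
#'
#' @param genome Genome tibble (`id`, `seq`).
#' @param proteins Viral protein tibble.
#' @param config An [eve_config()].
#' @param decoy_proteins Optional decoy proteome for the reciprocal filter
#'   (skipped when `NULL`).
#' @return A list: `hits`, `catalog` (stringent, reciprocally kept,
#'   assigned loci), `all_loci` (pre-filter), `orfs`, `manifest`.
#' @export
run_discover <- function(genome, proteins, config = eve_config(),
                         decoy_proteins = NULL) {
  scheme <- config_scheme(config)
  hits <- seeded_translated_search(
    proteins, genome, scheme = scheme, seed_k = config$seed_k,
    x_drop = config$x_drop, band = config$band, trigger = config$trigger,
    evalue_max = config$evalue_search
  )
  loci <- merge_hits(hits, max_gap_nt = config$max_gap_nt,
                     evalue_merge = config$evalue_merge) |>
    apply_stringency(evalue_max = config$evalue_stringent,
                     min_len_nt = config$min_len_nt)
  kept <- dplyr::filter(loci, .data$passes_stringent)
  if (!is.null(decoy_proteins) && nrow(kept) > 0) {
    kept <- reciprocal_filter(kept, genome, decoy_proteins, proteins,
                              scheme = scheme) |>
      dplyr::filter(.data$reciprocal_keep)
  }
  catalog <- assign_best_hit(kept, genome, proteins, scheme = scheme)
  orfs <- if (nrow(catalog) > 0) {
    predict_orf_with_flanks(catalog, genome, flank_nt = config$flank_nt,
                            min_orf_nt = config$min_orf_nt)
  } else {
    tibble(locus_id = character(), orf_start = integer(),
           orf_end = integer(), strand = character(), length_nt = integer(),
           protein = character(), overlaps_locus = logical(),
           primary = logical())
  }
  list(hits = hits, catalog = catalog, all_loci = loci, orfs = orfs,
       manifest = run_manifest(config, "discover"))
}

#' Run the population chain: QC, depth, presence, PCA, polymorphism
#'
#' @param placements Placement tibble.
#' @param loci Locus (or truth) tibble with `locus_id`, `contig_id`,
#'   `start`, `end`.
#' @param genome Genome tibble (for individual-level QC).
#' @param variants Optional variant tibble for polymorphism levels.
#' @param config An [eve_config()].
#' @return A list: `qc`, `profiles`, `calls`, `matrix`, `pca` (NULL when
#'   fewer than 3 individuals pass QC), `polymorphism` (NULL without
#'   variants), `manifest`.
#' @export
run_population <- function(placements, loci, genome, variants = NULL,
                           config = eve_config()) {
  qc <- qc_individual(placements, genome, profile = config$presence_profile)
  keep_ind <- qc$individual_id[qc$included]
  if (length(keep_ind) == 0) {
    warning("all individuals fail depth QC: empty presence matrix")
    empty <- matrix(numeric(0), nrow = 0, ncol = nrow(loci),
                    dimnames = list(NULL, loci$locus_id))
    return(list(qc = qc, profiles = NULL, calls = NULL, matrix = empty,
                pca = NULL, polymorphism = NULL,
                manifest = run_manifest(config, "population")))
  }
  profiles <- depth_profile(
    placements[placements$individual_id %in% keep_ind, ], loci,
    individuals = keep_ind, window_nt = config$window_nt
  )
  calls <- call_presence(profiles, profile = config$presence_profile)
  mat <- presence_matrix(calls)
  pca <- if (nrow(mat) >= 3 && ncol(mat) >= 2) {
    presence_matrix_pca(mat)
  } else NULL
  poly <- if (!is.null(variants)) {
    polymorphism_level(variants, loci, individuals = keep_ind)
  } else NULL
  list(qc = qc, profiles = profiles, calls = calls, matrix = mat, pca = pca,
       polymorphism = poly, manifest = run_manifest(config, "population"))
}

run_manifest <- function(config, stage) {
  list(
    stage = stage,
    package_version = as.character(utils::packageVersion("evescan")),
    seed = config$seed,
    thresholds = paste(
      sprintf("%s=%s",
              c("evalue_search", "evalue_merge", "evalue_stringent",
                "min_len_nt", "max_gap_nt", "presence_profile",
                "max_gap_fraction", "top_fraction"),
              vapply(config[c("evalue_search", "evalue_merge",
                              "evalue_stringent", "min_len_nt", "max_gap_nt",
                              "presence_profile", "max_gap_fraction",
                              "top_fraction")], format, character(1))),
      collapse = ";")
  )
}

#' Overlap-based recovery of truth loci by a catalogue
#'
#' A truth locus counts as recovered when some catalogued locus has
#' reciprocal overlap of at least `min_overlap` with it (intersection over
#' each interval's length, both ways).
#'
#' @param catalog Locus tibble.
#' @param truth Truth tibble from [implant_eves()].
#' @param min_overlap Reciprocal-overlap floor.
#' @return A tibble: `locus_id` (truth), `recovered`, `best_overlap`,
#'   `matched_locus`.
#' @export
recovery_vs_truth <- function(catalog, truth, min_overlap = 0.8) {
  purrr::map_dfr(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    cand <- catalog[catalog$contig_id == tr$contig_id, ]
    if (nrow(cand) == 0) {
      return(tibble(locus_id = tr$locus_id, recovered = FALSE,
                    best_overlap = 0, matched_locus = NA_character_))
    }
    inter <- pmax(0, pmin(cand$end, tr$end) - pmax(cand$start, tr$start))
    rec_ov <- pmin(inter / (tr$end - tr$start),
                   inter / (cand$end - cand$start))
    j <- which.max(rec_ov)
    tibble(locus_id = tr$locus_id,
           recovered = rec_ov[j] >= min_overlap,
           best_overlap = rec_ov[j],
           matched_locus = cand$locus_id[j])
  })
}
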