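# Synthetic-data generators: every pipeline input with known ground truth.
# Each simulator draws from its own named RNG stream derived from one
# integer seed, so adding one simulator never shifts another's stream.

SIM_SEED_OFFSETS <- c(
  host = 211L, totivirus = 101L, implant = 307L, reads = 401L,
  variants = 503L, orthologs = 601L, srna = 701L
)

sim_seed <- function(seed, stream) {
  (as.integer(seed) + SIM_SEED_OFFSETS[[stream]]) %% 2147483647L
}

CODON_TABLE <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
})

random_codons <- function(aas) {
  vapply(strsplit(aas, "")[[1]],
         function(a) sample(CODON_TABLE[[a]], 1), character(1),
         USE.NAMES = FALSE)
}

random_protein <- function(n, start_with_m = TRUE) {
  body <- paste(sample(AA20, n - start_with_m, replace = TRUE), collapse = "")
  if (start_with_m) paste0("M", body) else body
}

random_nuc <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a random host genome assembly
#'
#' Uniform-random ACGT contigs; the viral-free background into which
#' [implant_eves()] places decayed fragments, and the negative control for
#' the discovery chain.
#'
#' @param seed Integer seed.
#' @param n_contigs,contig_length Assembly shape.
#' @return A genome tibble (`id`, `seq`, `length`).
#' @export
simulate_host_genome <- function(seed, n_contigs = 1, contig_length = 1e6) {
  withr::with_seed(sim_seed(seed, "host"), {
    tibble(
      id = sprintf("contig%02d", seq_len(n_contigs)),
      seq = vapply(seq_len(n_contigs), function(i) random_nuc(contig_length),
                   character(1)),
      length = as.integer(contig_length)
    )
  })
}

#' Simulate a totivirus-like genome with CP and RdRp ORFs
#'
#' Emulates the canonical Totiviridae organization: one genome segment with
#' two non-overlapping intact ORFs (ATG ... stop) encoding a capsid protein
#' (CP) and an RNA-dependent RNA polymerase (RdRp). Coding regions use
#' uniform-random synonymous codons; untranslated regions are random
#' nucleotides. Byte-identical per seed.
#'
#' @param seed Integer seed.
#' @param genome_length Total genome length (nt).
#' @param cp_length_aa,rdrp_length_aa Protein lengths (residues, including
#'   the initiator M).
#' @param virus_id Identifier used for the genome and protein records.
#' @return A list with `genome` (tibble `id`, `seq`, `length`), `proteins`
#'   (tibble `id`, `seq`, `length`, `virus_id`, `gene_label`) and `orfs`
#'   (tibble with 0-based half-open genome coordinates per ORF).
#' @export
simulate_totivirus <- function(seed, genome_length = 7000, cp_length_aa = 700,
                               rdrp_length_aa = 900, virus_id = "simtoti1") {
  stopifnot(cp_length_aa > 1, rdrp_length_aa > 1)
  orf_nt <- 3 * (c(cp_length_aa, rdrp_length_aa) + 1)  # incl. stop codon
  spare <- genome_length - sum(orf_nt)
  if (spare < 30) {
    stop("genome_length too short for the requested ORFs (need >= ",
         sum(orf_nt) + 30, " nt)")
  }
  withr::with_seed(sim_seed(seed, "totivirus"), {
    utr <- c(0L, 0L, 0L)
    utr[1] <- sample(5:(spare - 20), 1)
    utr[2] <- sample(5:(spare - utr[1] - 10), 1)
    utr[3] <- spare - utr[1] - utr[2]
    prots <- c(CP = random_protein(cp_length_aa),
               RdRp = random_protein(rdrp_length_aa))
    cds <- vapply(prots, function(p) {
      paste0(paste(random_codons(p), collapse = ""),
             sample(c("TAA", "TAG", "TGA"), 1))
    }, character(1))
    genome_seq <- paste0(random_nuc(utr[1]), cds[["CP"]], random_nuc(utr[2]),
                         cds[["RdRp"]], random_nuc(utr[3]))
    orfs <- tibble(
      gene_label = c("CP", "RdRp"),
      start = c(utr[1], utr[1] + nchar(cds[["CP"]]) + utr[2]),
      end = c(utr[1] + nchar(cds[["CP"]]),
              utr[1] + nchar(cds[["CP"]]) + utr[2] + nchar(cds[["RdRp"]])),
      strand = "+"
    )
    list(
      genome = tibble(id = virus_id, seq = genome_seq,
                      length = nchar(genome_seq)),
      proteins = tibble(
        id = paste0(virus_id, "_", c("CP", "RdRp")),
        seq = unname(prots), length = nchar(unname(prots)),
        virus_id = virus_id, gene_label = c("CP", "RdRp")
      ),
      orfs = orfs
    )
  })
}

# substitute n_sub residues of a protein fragment at distinct positions,
# each with a uniformly drawn different residue
mutate_protein <- function(frag, n_sub) {
  chars <- strsplit(frag, "")[[1]]
  if (n_sub > 0) {
    pos <- sample(length(chars), n_sub)
    for (p in pos) {
      chars[p] <- sample(setdiff(AA20, chars[p]), 1)
    }
  }
  paste(chars, collapse = "")
}

#' Implant mutationally decayed viral protein fragments into a host genome
#'
#' Each locus is a back-translated fragment of a source viral protein,
#' mutated in protein space to a sampled target amino-acid identity,
#' optionally disrupted by one or two single-base indels (frameshifts), and
#' written onto the + or - strand of a host contig. Implants overwrite the
#' host sequence in place, so contig lengths are unchanged. The returned
#' truth table records final coordinates and realized identity per locus.
#'
#' @param seed Integer seed.
#' @param host_genome Genome tibble (`id`, `seq`).
#' @param proteins Protein tibble (`id`, `seq`, and optionally `virus_id`,
#'   `gene_label`).
#' @param n_loci Number of loci to implant.
#' @param identity_range Target amino-acid identity range, within (0, 1].
#' @param frameshift_prob Probability that a locus receives 1-2 single-base
#'   indels.
#' @param strand_mix Probability of the minus strand.
#' @param frag_aa_range Fragment length range in residues (120 residues
#'   corresponds to 360 nt, comfortably above the 350-nt stringency floor).
#' @param min_separation_nt Minimum distance between implanted loci, kept
#'   above typical hit-merging distances so neighbouring loci stay
#'   distinct.
#' @return A list with `genome` (host assembly carrying the implants) and
#'   `truth` (tibble: `locus_id`, `contig_id`, `start`, `end`, `strand`,
#'   `protein_id`, `gene_label`, `target_identity`, `realized_identity`,
#'   `n_frameshift`).
#' @export
implant_eves <- function(seed, host_genome, proteins, n_loci = 20,
                         identity_range = c(0.6, 1), frameshift_prob = 0.3,
                         strand_mix = 0.5, frag_aa_range = c(120, 400),
                         min_separation_nt = 5000) {
  stopifnot(identity_range[1] > 0, identity_range[2] <= 1,
            frag_aa_range[1] >= 2)
  withr::with_seed(sim_seed(seed, "implant"), {
    seqs <- setNames(host_genome$seq, host_genome$id)
    occupied <- setNames(vector("list", length(seqs)), names(seqs))
    truth <- vector("list", n_loci)
    for (k in seq_len(n_loci)) {
      pi <- sample(nrow(proteins), 1)
      prot <- proteins$seq[pi]
      flen <- sample(seq(frag_aa_range[1],
                         min(frag_aa_range[2], nchar(prot))), 1)
      fstart <- sample(nchar(prot) - flen + 1, 1)
      frag <- substr(prot, fstart, fstart + flen - 1)
      target <- runif(1, identity_range[1], identity_range[2])
      n_sub <- round((1 - target) * flen)
      mut <- mutate_protein(frag, n_sub)
      nt <- paste(random_codons(mut), collapse = "")
      n_fs <- 0L
      if (runif(1) < frameshift_prob) {
        n_fs <- sample(1:2, 1)
        for (f in seq_len(n_fs)) {
          p <- sample(nchar(nt) - 2, 1) + 1
          if (runif(1) < 0.5) {
            nt <- paste0(substr(nt, 1, p - 1), substr(nt, p + 1, nchar(nt)))
          } else {
            nt <- paste0(substr(nt, 1, p),
                         sample(c("A", "C", "G", "T"), 1),
                         substr(nt, p + 1, nchar(nt)))
          }
        }
      }
      strand <- if (runif(1) < strand_mix) "-" else "+"
      insert <- if (strand == "-") revcomp(nt) else nt
      ilen <- nchar(insert)
      placed <- FALSE
      for (try in 1:1000) {
        ci <- sample(length(seqs), 1)
        clen <- nchar(seqs[[ci]])
        if (clen < ilen + 2 * min_separation_nt) next
        pos <- sample(clen - ilen - min_separation_nt, 1) +
          min_separation_nt %/% 2
        clash <- any(vapply(occupied[[ci]], function(iv) {
          pos < iv[2] + min_separation_nt && iv[1] - min_separation_nt < pos + ilen
        }, logical(1)))
        if (clash) next
        substr(seqs[[ci]], pos + 1, pos + ilen) <- insert
        occupied[[ci]] <- c(occupied[[ci]], list(c(pos, pos + ilen)))
        truth[[k]] <- tibble(
          locus_id = sprintf("truth%02d", k),
          contig_id = names(seqs)[ci],
          start = as.integer(pos), end = as.integer(pos + ilen),
          strand = strand,
          protein_id = proteins$id[pi],
          gene_label = if ("gene_label" %in% names(proteins))
            proteins$gene_label[pi] else "other",
          fragment_aa_start = as.integer(fstart),
          fragment_aa_len = as.integer(flen),
          target_identity = target,
          realized_identity = 1 - n_sub / flen,
          n_frameshift = n_fs
        )
        placed <- TRUE
        break
      }
      if (!placed) stop("could not place ", n_loci,
                        " non-overlapping loci; host genome too small")
    }
    genome <- tibble(id = names(seqs), seq = unname(unlist(seqs)),
                     length = nchar(unname(unlist(seqs))))
    list(genome = genome, truth = dplyr::bind_rows(truth))
  })
}

#' Simulate per-individual read placements over implanted loci
#'
#' For each individual, reads tile each locus (and its flanks) with
#' Poisson-distributed counts and uniform start positions, so the expected
#' per-base depth inside the locus equals `depth_present` where the
#' presence map says present and `depth_absent` otherwise.
#'
#' @param seed Integer seed.
#' @param truth Truth tibble from [implant_eves()].
#' @param individuals Character vector of individual ids.
#' @param depth_present,depth_absent Expected per-base depths.
#' @param read_length Read length (nt).
#' @param contig_lengths Named integer vector of contig lengths (reads are
#'   clipped at contig bounds).
#' @param presence Optional presence map (tibble `individual_id`,
#'   `locus_id`, `present`); when `NULL` each individual carries each locus
#'   with probability `present_prob`.
#' @param present_prob Per-pair presence probability for the generated map.
#' @return A list with `placements` (tibble `individual_id`, `contig_id`,
#'   `start`, `length`, `multimap_count`) and `presence` (the map used).
#' @export
simulate_read_alignments <- function(seed, truth, individuals,
                                     depth_present = 30, depth_absent = 0,
                                     read_length = 100, contig_lengths = NULL,
                                     presence = NULL, present_prob = 0.5) {
  stopifnot(depth_present >= 0, depth_absent >= 0, read_length > 0)
  withr::with_seed(sim_seed(seed, "reads"), {
    if (is.null(presence)) {
      presence <- tidyr::expand_grid(individual_id = individuals,
                                     locus_id = truth$locus_id) |>
        dplyr::mutate(present = runif(dplyr::n()) < present_prob)
    }
    grid <- presence |>
      dplyr::left_join(truth, by = "locus_id")
    placements <- purrr::pmap_dfr(
      grid[c("individual_id", "locus_id", "present", "contig_id",
             "start", "end")],
      function(individual_id, locus_id, present, contig_id, start, end) {
        d <- if (present) depth_present else depth_absent
        if (d <= 0) return(NULL)
        L <- end - start
        n <- rpois(1, d * (L + read_length - 1) / read_length)
        if (n == 0) return(NULL)
        s <- sample(seq(start - read_length + 1, end - 1), n, replace = TRUE)
        s <- pmax(s, 0L)
        len <- rep(read_length, n)
        if (!is.null(contig_lengths) && contig_id %in% names(contig_lengths)) {
          len <- pmin(len, contig_lengths[[contig_id]] - s)
        }
        tibble(individual_id = individual_id, contig_id = contig_id,
               start = as.integer(s), length = as.integer(len),
               multimap_count = 1L)
      }
    )
    if (is.null(placements) || nrow(placements) == 0) {
      placements <- tibble(individual_id = character(),
                           contig_id = character(), start = integer(),
                           length = integer(), multimap_count = integer())
    }
    list(placements = dplyr::arrange(placements, .data$individual_id,
                                     .data$contig_id, .data$start),
         presence = presence)
  })
}

#' Simulate per-individual variant sites over loci
#'
#' Variant positions are drawn per individual uniformly within each locus
#' at the stated expected density (each position is a variant site with
#' probability `density / 1000`).
#'
#' @param seed Integer seed.
#' @param truth Truth tibble from [implant_eves()] (or any tibble with
#'   `locus_id`, `contig_id`, `start`, `end`).
#' @param sites_per_kb Expected variant sites per kb: a scalar, or a vector
#'   named by `locus_id`.
#' @param individuals Character vector of individual ids.
#' @return A tibble of variant sites (`individual_id`, `contig_id`,
#'   `position`, `ref_allele`, `alt_allele`, `genotype_is_nonref`,
#'   `locus_id`).
#' @export
simulate_variants <- function(seed, truth, sites_per_kb, individuals) {
  stopifnot(all(sites_per_kb >= 0))
  withr::with_seed(sim_seed(seed, "variants"), {
    dens <- if (length(sites_per_kb) == 1) {
      setNames(rep(sites_per_kb, nrow(truth)), truth$locus_id)
    } else sites_per_kb
    grid <- tidyr::expand_grid(individual_id = individuals,
                               idx = seq_len(nrow(truth)))
    out <- purrr::pmap_dfr(grid, function(individual_id, idx) {
      row <- truth[idx, ]
      L <- row$end - row$start
      p <- min(1, dens[[row$locus_id]] / 1000)
      n <- rbinom(1, L, p)
      if (n == 0) return(NULL)
      pos <- row$start + sample(L, n) - 1L
      ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
      alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                    character(1), USE.NAMES = FALSE)
      tibble(individual_id = individual_id, contig_id = row$contig_id,
             position = as.integer(sort(pos)), ref_allele = ref,
             alt_allele = alt, genotype_is_nonref = TRUE,
             locus_id = row$locus_id)
    })
    if (is.null(out) || nrow(out) == 0) {
      out <- tibble(individual_id = character(), contig_id = character(),
                    position = integer(), ref_allele = character(),
                    alt_allele = character(), genotype_is_nonref = logical(),
                    locus_id = character())
    }
    out
  })
}

# Per-branch substitution probability giving expected pairwise difference r
# under a star tree with uniform substitution to the three other bases:
# p_pair = 2a - (4/3)a^2  =>  a = (3/4) (1 - sqrt(1 - (4/3) r)), r <= 0.75.
branch_rate_for_pairwise <- function(r) {
  stopifnot(all(r >= 0), all(r <= 0.75))
  0.75 * (1 - sqrt(1 - (4 / 3) * r))
}

#' Simulate gap-free multi-taxon ortholog alignments with known rates
#'
#' Each ortholog gets a random ancestral sequence; every taxon then mutates
#' each column independently with a per-branch probability calibrated so
#' the expected pairwise difference fraction equals the assigned rate
#' class. Truth labels are retained for benchmarking the fast-/slow-gene
#' classifier.
#'
#' @param seed Integer seed.
#' @param n_orthologs Number of orthologs.
#' @param taxa Number of taxa (rows per alignment).
#' @param rate_classes Data frame with columns `rate` and `fraction`
#'   (fractions sum to 1), or a numeric vector of per-ortholog rates.
#' @param length_nt Alignment length.
#' @return A list with `alignments` (tibble `ortholog_id`, `taxon`, `seq`)
#'   and `truth` (tibble `ortholog_id`, `rate`).
#' @export
simulate_ortholog_alignments <- function(seed, n_orthologs, taxa = 3,
                                         rate_classes, length_nt = 10000) {
  withr::with_seed(sim_seed(seed, "orthologs"), {
    rates <- if (is.data.frame(rate_classes)) {
      counts <- floor(rate_classes$fraction * n_orthologs)
      counts[which.max(counts)] <- counts[which.max(counts)] +
        (n_orthologs - sum(counts))
      sample(rep(rate_classes$rate, counts))
    } else {
      stopifnot(length(rate_classes) == n_orthologs)
      rate_classes
    }
    a <- branch_rate_for_pairwise(rates)
    bases <- c("A", "C", "G", "T")
    # alt[b, k]: the k-th of the three bases differing from base b
    alt <- t(vapply(bases, function(b) setdiff(bases, b), character(3)))
    rows <- purrr::map_dfr(seq_len(n_orthologs), function(i) {
      anc <- sample.int(4, length_nt, replace = TRUE)
      seqs <- vapply(seq_len(taxa), function(t) {
        mut <- which(runif(length_nt) < a[i])
        derived <- bases[anc]
        if (length(mut)) {
          derived[mut] <- alt[cbind(anc[mut],
                                    sample.int(3, length(mut),
                                               replace = TRUE))]
        }
        paste(derived, collapse = "")
      }, character(1))
      tibble(ortholog_id = sprintf("og%05d", i),
             taxon = sprintf("taxon%d", seq_len(taxa)), seq = seqs)
    })
    list(alignments = rows,
         truth = tibble(ortholog_id = sprintf("og%05d", seq_len(n_orthologs)),
                        rate = rates))
  })
}

#' Simulate small-RNA reads from a transcript
#'
#' Reads are exact substrings of the transcript or its reverse complement,
#' with lengths drawn from a normal distribution rounded and clipped to
#' [18, 30] nt — the extraction window used for small-RNA libraries.
#'
#' @param seed Integer seed.
#' @param transcript Transcript sequence (single string).
#' @param n_reads Number of reads.
#' @param length_mean,length_sd Parameters of the read-length distribution;
#'   a mean near 26 emulates a piRNA-dominated library, near 21 an
#'   siRNA-dominated one.
#' @return A tibble (`read_id`, `seq`, `length`, `strand_of_origin`).
#' @export
simulate_srna_reads <- function(seed, transcript, n_reads = 1000,
                                length_mean = 26, length_sd = 1) {
  stopifnot(nchar(transcript) >= 30)
  withr::with_seed(sim_seed(seed, "srna"), {
    len <- pmin(30L, pmax(18L, as.integer(round(rnorm(n_reads, length_mean,
                                                      length_sd)))))
    start <- vapply(len, function(l) sample(nchar(transcript) - l + 1, 1),
                    integer(1))
    fwd <- runif(n_reads) < 0.5
    seqs <- substr(rep(transcript, n_reads), start, start + len - 1)
    seqs[!fwd] <- revcomp(seqs[!fwd])
    tibble(read_id = sprintf("sr%06d", seq_len(n_reads)), seq = seqs,
           length = len, strand_of_origin = ifelse(fwd, "+", "-"))
  })
}

#' Write placements as a minimal SAM file
#'
#' One mapped record per placement, with the individual id in the RG tag
#' and the multimap count in NH. Used for round-trip exercises of
#' [read_alignments()].
#'
#' @param placements Placement tibble.
#' @param contig_lengths Named vector of contig lengths (for the header).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_placements_sam <- function(placements, contig_lengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                   as.integer(contig_lengths)),
           sprintf("@RG\tID:%s", unique(placements$individual_id)))
  body <- sprintf(
    "r%06d\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*\tNH:i:%d\tRG:Z:%s",
    seq_len(nrow(placements)), placements$contig_id, placements$start + 1L,
    placements$length,
    strrep("A", placements$length),
    placements$multimap_count, placements$individual_id
  )
  readr::write_lines(c(hdr, body), path)
  invisible(path)
}

#' Write variant sites as a minimal multi-sample VCF
#'
#' Rows are unique (contig, position, ref, alt) records; each sample's GT
#' is 0/1 where that individual carries the variant and 0/0 otherwise.
#'
#' @param variants Variant tibble from [simulate_variants()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, path) {
  inds <- sort(unique(variants$individual_id))
  sites <- variants |>
    dplyr::distinct(.data$contig_id, .data$position, .data$ref_allele,
                    .data$alt_allele) |>
    dplyr::arrange(.data$contig_id, .data$position)
  carrier <- variants |>
    dplyr::mutate(key = paste(.data$contig_id, .data$position,
                              .data$ref_allele, .data$alt_allele))
  gt <- vapply(inds, function(ind) {
    have <- carrier$key[carrier$individual_id == ind]
    key <- paste(sites$contig_id, sites$position, sites$ref_allele,
                 sites$alt_allele)
    ifelse(key %in% have, "0/1", "0/0")
  }, character(nrow(sites)))
  gt <- matrix(gt, nrow = nrow(sites))
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", inds), collapse = "\t"))
  body <- vapply(seq_len(nrow(sites)), function(i) {
    paste(c(sites$contig_id[i], sites$position[i] + 1L, ".",
            sites$ref_allele[i], sites$alt_allele[i], ".", "PASS", ".",
            "GT", gt[i, ]), collapse = "\t")
  }, character(1))
  readr::write_lines(c(hdr, body), path)
  invisible(path)
}
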