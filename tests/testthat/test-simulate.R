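test_that("totivirus genomes carry exactly the two annotated ORFs", {
  v <- simulate_totivirus(1, genome_length = 7000, cp_length_aa = 700,
                          rdrp_length_aa = 900)
  expect_equal(nrow(v$orfs), 2)
  expect_equal(v$genome$length, 7000L)
  expect_equal(v$proteins$gene_label, c("CP", "RdRp"))
  expect_equal(nchar(v$proteins$seq), c(700L, 900L))
  # the ORF regions translate exactly to the returned proteins (plus stop)
  for (i in 1:2) {
    cds <- substr(v$genome$seq, v$orfs$start[i] + 1, v$orfs$end[i])
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
    expect_equal(sub("\\*$", "", aa), v$proteins$seq[i])
    expect_match(aa, "\\*$")
    expect_match(v$proteins$seq[i], "^M")
  }
  expect_false(v$orfs$end[1] > v$orfs$start[2])  # non-overlapping
})

test_that("simulators are byte-identical per seed and differ across seeds", {
  expect_identical(simulate_totivirus(7), simulate_totivirus(7))
  expect_false(identical(simulate_totivirus(7)$genome$seq,
                         simulate_totivirus(8)$genome$seq))
  host <- simulate_host_genome(2, 1, 40000)
  v <- simulate_totivirus(2, 4000, 300, 400)
  a <- implant_eves(3, host, v$proteins, n_loci = 3,
                    min_separation_nt = 2000)
  b <- implant_eves(3, host, v$proteins, n_loci = 3,
                    min_separation_nt = 2000)
  expect_identical(a, b)
  tr <- a$truth
  r1 <- simulate_read_alignments(4, tr, c("i1", "i2"))
  r2 <- simulate_read_alignments(4, tr, c("i1", "i2"))
  expect_identical(r1, r2)
  expect_identical(simulate_variants(4, tr, 6, "i1"),
                   simulate_variants(4, tr, 6, "i1"))
  expect_identical(simulate_srna_reads(4, v$genome$seq, 50),
                   simulate_srna_reads(4, v$genome$seq, 50))
})

test_that("infeasible totivirus lengths error", {
  expect_error(simulate_totivirus(1, genome_length = 5000,
                                  cp_length_aa = 3000, rdrp_length_aa = 400),
               "too short")
})

test_that("implanted loci are non-overlapping and truth-consistent", {
  host <- simulate_host_genome(5, 1, 300000)
  v <- simulate_totivirus(5, 4000, 300, 400)
  imp <- implant_eves(5, host, v$proteins, n_loci = 8,
                      identity_range = c(1, 1), frameshift_prob = 0,
                      min_separation_nt = 2000)
  tr <- dplyr::arrange(imp$truth, start)
  expect_equal(nrow(tr), 8)
  expect_true(all(tr$start[-1] >= tr$end[-nrow(tr)]))
  expect_true(all(tr$realized_identity == 1))
  # at identity 1 and no frameshift the implant translates back to the
  # source protein fragment in one frame
  prot <- setNames(v$proteins$seq, v$proteins$id)
  for (i in seq_len(nrow(tr))) {
    nt <- substr(imp$genome$seq[imp$genome$id == tr$contig_id[i]],
                 tr$start[i] + 1, tr$end[i])
    if (tr$strand[i] == "-") {
      nt <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(nt)))
    }
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(nt)))
    frag <- unname(substr(prot[tr$protein_id[i]], tr$fragment_aa_start[i],
                          tr$fragment_aa_start[i] + tr$fragment_aa_len[i] - 1))
    expect_equal(aa, frag)
  }
})

test_that("realized implant identity tracks the requested range", {
  host <- simulate_host_genome(6, 1, 400000)
  v <- simulate_totivirus(6, 4000, 300, 400)
  imp <- implant_eves(6, host, v$proteins, n_loci = 10,
                      identity_range = c(0.6, 0.8), frameshift_prob = 0.5,
                      min_separation_nt = 2000)
  expect_true(all(imp$truth$realized_identity >= 0.55))
  expect_true(all(imp$truth$realized_identity <= 0.85))
  expect_true(all(imp$truth$n_frameshift %in% 0:2))
  # strand mix draws both strands over 10 loci at p = 0.5 (seed-fixed)
  expect_true(length(unique(imp$truth$strand)) >= 1)
})

test_that("read counts follow the Poisson tiling expectation", {
  truth <- locus_tbl("L1", start = 5000, end = 6000)
  pres <- tibble::tibble(individual_id = "i1", locus_id = "L1",
                         present = TRUE)
  r <- simulate_read_alignments(9, truth, "i1", depth_present = 30,
                                depth_absent = 0, read_length = 100,
                                presence = pres)
  lambda <- 30 * (1000 + 100 - 1) / 100   # expected read count
  expect_lt(abs(nrow(r$placements) - lambda), 4 * sqrt(lambda))
  # absent loci at depth 0 get no reads at all
  pres$present <- FALSE
  r0 <- simulate_read_alignments(9, truth, "i1", depth_present = 30,
                                 depth_absent = 0, presence = pres)
  expect_equal(nrow(r0$placements), 0)
})

test_that("variant density matches the binomial expectation", {
  truth <- locus_tbl("L1", start = 0, end = 10000)
  inds <- sprintf("i%d", 1:20)
  v <- simulate_variants(11, truth, sites_per_kb = 6, individuals = inds)
  per_ind <- table(factor(v$individual_id, levels = inds))
  lambda <- 6 * 10          # 6 per kb over 10 kb
  expect_lt(abs(mean(per_ind) - lambda), 4 * sqrt(lambda / 20))
  expect_true(all(v$position >= 0 & v$position < 10000))
  expect_true(all(v$ref_allele != v$alt_allele))
  expect_equal(nrow(simulate_variants(11, truth, 0, inds)), 0)
})

test_that("ortholog alignments realize their assigned pairwise rates", {
  o0 <- simulate_ortholog_alignments(2, 3, taxa = 3, rate_classes = rep(0, 3),
                                     length_nt = 500)
  stats0 <- ortholog_stats(o0$alignments)
  expect_equal(stats0$p_distance, rep(0, 3))

  o <- simulate_ortholog_alignments(2, 5, taxa = 3,
                                    rate_classes = rep(0.3, 5),
                                    length_nt = 10000)
  stats <- ortholog_stats(o$alignments)
  expect_true(all(abs(stats$p_distance - 0.3) < 0.02))

  oc <- simulate_ortholog_alignments(
    2, 37, taxa = 3, length_nt = 100,
    rate_classes = data.frame(rate = c(0.4, 0.2, 0.05),
                              fraction = c(0.05, 0.90, 0.05)))
  expect_equal(nrow(oc$truth), 37)
  expect_equal(length(unique(oc$alignments$ortholog_id)), 37)
})

test_that("small-RNA reads are perfect substrings with clipped lengths", {
  tx <- rand_dna(500, seed = 1)
  r <- simulate_srna_reads(3, tx, n_reads = 300, length_mean = 26,
                           length_sd = 1)
  expect_true(all(r$length >= 18 & r$length <= 30))
  expect_gte(mean(r$length >= 24 & r$length <= 29), 0.9)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(tx)))
  ok <- vapply(r$seq, function(s) grepl(s, tx, fixed = TRUE) ||
                 grepl(s, rc, fixed = TRUE), logical(1))
  expect_true(all(ok))

  r21 <- simulate_srna_reads(3, tx, n_reads = 300, length_mean = 21,
                             length_sd = 1)
  expect_lt(mean(r21$length >= 24 & r21$length <= 29), 0.1)
})
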