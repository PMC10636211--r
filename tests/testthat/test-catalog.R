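test_that("hit merging follows the gap rule and never crosses strands", {
  h <- dplyr::bind_rows(
    hit_row(start = 100, end = 400),
    hit_row(start = 600, end = 900)
  )
  one <- merge_hits(h, max_gap_nt = 1000)
  expect_equal(nrow(one), 1)
  expect_equal(one$start, 100L)
  expect_equal(one$end, 900L)
  expect_equal(one$n_hits, 2L)
  expect_equal(one$length_nt, 800L)

  two <- merge_hits(h, max_gap_nt = 100)   # gap 200 > 100
  expect_equal(nrow(two), 2)

  single <- merge_hits(hit_row(start = 5, end = 50), max_gap_nt = 1000)
  expect_equal(single$start, 5L)
  expect_equal(single$end, 50L)

  opp <- dplyr::bind_rows(
    hit_row(start = 100, end = 400, strand = "+"),
    hit_row(start = 450, end = 900, strand = "-")
  )
  expect_equal(nrow(merge_hits(opp, max_gap_nt = 1000)), 2)
})

test_that("merging is idempotent and order-invariant", {
  set.seed(41)
  h <- purrr::map_dfr(1:12, function(i) {
    s <- sample(0:20000, 1)
    hit_row(start = s, end = s + sample(100:500, 1),
            strand = sample(c("+", "-"), 1),
            evalue = 10^-sample(6:30, 1))
  })
  m1 <- merge_hits(h, max_gap_nt = 300)
  m2 <- merge_hits(h[sample(nrow(h)), ], max_gap_nt = 300)
  cols <- c("contig_id", "start", "end", "strand", "n_hits", "best_evalue")
  expect_equal(m1[cols], m2[cols])
  m3 <- merge_hits(m1, max_gap_nt = 300)
  expect_equal(m3[cols], m1[cols])
  # every locus interval contains every member hit interval
  for (i in seq_len(nrow(m1))) {
    mem <- m1$member_hits[[i]]
    expect_true(all(mem$subject_start >= m1$start[i]))
    expect_true(all(mem$subject_end <= m1$end[i]))
  }
})

test_that("hits above the merge E-value ceiling are excluded", {
  h <- dplyr::bind_rows(
    hit_row(start = 0, end = 300, evalue = 1e-20),
    hit_row(start = 400, end = 700, evalue = 1e-4)  # above 1e-5 cutoff
  )
  m <- merge_hits(h, max_gap_nt = 1000, evalue_merge = 1e-5)
  expect_equal(nrow(m), 1)
  expect_equal(m$end, 300L)
})

test_that("stringency flags use the e-value and length boundaries", {
  loci <- tibble::tibble(
    locus_id = c("a", "b", "c"), contig_id = "c1",
    start = 0L, end = c(349L, 350L, 5000L), strand = "+",
    length_nt = c(349L, 350L, 5000L), n_hits = 1L,
    best_evalue = c(1e-20, 1e-11, 1e-9),
    best_raw_score = 100, best_query_id = "q1", member_hits = list(NULL)
  )
  out <- apply_stringency(loci)
  expect_equal(out$passes_stringent, c(FALSE, TRUE, FALSE))
})

test_that("reciprocal filter keeps viral loci and drops decoy look-alikes", {
  set.seed(43)
  viral <- tibble::tibble(id = "vp1", seq = rand_protein(300))
  decoy <- tibble::tibble(id = paste0("d", 1:3),
                          seq = vapply(1:3, function(i) rand_protein(300),
                                       character(1)))
  # locus built from the viral protein
  frag_v <- substr(viral$seq, 50, 200)
  # locus built from a decoy protein fragment
  frag_d <- substr(decoy$seq[2], 50, 200)
  genome <- tibble::tibble(
    id = "c1",
    seq = paste0(rand_dna(500), backtranslate(frag_v), rand_dna(500),
                 backtranslate(frag_d), rand_dna(500)))
  genome$length <- nchar(genome$seq)
  loci <- tibble::tibble(
    locus_id = c("lv", "ld"), contig_id = "c1",
    start = c(500L, 500L + 3L * 151L + 500L),
    end = c(500L + 3L * 151L, 500L + 3L * 151L + 500L + 3L * 151L),
    strand = "+")
  out <- reciprocal_filter(loci, genome, decoy, viral)
  expect_true(out$reciprocal_keep[out$locus_id == "lv"])
  expect_false(out$reciprocal_keep[out$locus_id == "ld"])
  expect_equal(out$reciprocal_best_source,
               c("viral", "decoy")[match(out$locus_id, c("lv", "ld"))])

  expect_warning(out2 <- reciprocal_filter(loci, genome,
                                           decoy[0, ], viral),
                 "empty decoy")
  expect_true(all(out2$reciprocal_keep))
})

test_that("best-hit assignment picks the higher-identity virus", {
  set.seed(47)
  protA <- rand_protein(250)
  protB <- mutate_aa(protA, 100)             # 60% identical to A
  implant <- mutate_aa(protA, 50)            # 80% identical to A
  genome <- tibble::tibble(
    id = "c1", seq = paste0(rand_dna(400), backtranslate(implant),
                            rand_dna(400)))
  loci <- tibble::tibble(locus_id = "L1", contig_id = "c1", start = 400L,
                         end = 400L + 3L * 250L, strand = "+")
  panel <- tibble::tibble(id = c("pA", "pB"), seq = c(protA, protB),
                          virus_id = c("virusA", "virusB"),
                          gene_label = c("CP", "CP"))
  out <- assign_best_hit(loci, genome, panel)
  expect_true(out$assigned)
  expect_equal(out$best_virus_id, "virusA")
  expect_equal(out$best_gene_label, "CP")
  expect_gt(out$best_pident, 70)

  # a locus with no viral resemblance stays unassigned
  junk <- tibble::tibble(locus_id = "L2", contig_id = "c2", start = 0L,
                         end = 600L, strand = "+")
  g2 <- tibble::tibble(id = "c2", seq = rand_dna(600))
  out2 <- assign_best_hit(junk, g2, panel, evalue_max = 1e-6)
  expect_false(out2$assigned)
})

test_that("flank-extended ORF prediction finds a boundary-spanning ORF", {
  set.seed(53)
  # 600-nt complete ORF: ATG + 198 non-stop codons + TAA
  prot <- paste0("M", rand_protein(198))
  orf_nt <- paste0(backtranslate(prot), "TAA")
  expect_equal(nchar(orf_nt), 600)
  # place the ORF so it starts 300 nt before the locus; an in-frame stop
  # just upstream guarantees the reported ORF begins at this ATG
  left <- paste0(rand_dna(997), "TAA")
  genome <- tibble::tibble(id = "c1",
                           seq = paste0(left, orf_nt, rand_dna(1000)))
  loci <- tibble::tibble(locus_id = "L1", contig_id = "c1", start = 1300L,
                         end = 1500L, strand = "+")
  orfs <- predict_orf_with_flanks(loci, genome, flank_nt = 2000,
                                  min_orf_nt = 590)
  hit <- orfs[orfs$orf_start == 1000 & orfs$strand == "+", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$length_nt, 600L)
  expect_equal(hit$orf_end, 1600L)
  expect_true(hit$overlaps_locus)
  expect_equal(hit$protein, prot)
  expect_false(grepl("\\*", hit$protein))
})

test_that("ORF windows clip at contig bounds and empty windows return none", {
  genome <- tibble::tibble(id = "c1", seq = paste0(
    backtranslate(paste0("M", rand_protein(120))), "TAA", rand_dna(200)))
  loci <- tibble::tibble(locus_id = "L1", contig_id = "c1", start = 0L,
                         end = 100L, strand = "+")
  orfs <- predict_orf_with_flanks(loci, genome, flank_nt = 2000,
                                  min_orf_nt = 300)
  expect_true(all(orfs$orf_start >= 0))
  expect_true(all(orfs$orf_end <= nchar(genome$seq)))
  expect_true(all(orfs$length_nt %% 3 == 0))

  # no ATG anywhere: no ORFs
  g2 <- tibble::tibble(id = "c2", seq = strrep("GC", 500))
  l2 <- tibble::tibble(locus_id = "L2", contig_id = "c2", start = 100L,
                       end = 200L, strand = "+")
  expect_equal(nrow(predict_orf_with_flanks(l2, g2, min_orf_nt = 30)), 0)
})

test_that("end-to-end discovery recovers implants and rejects the control", {
  cfg <- eve_config(seed = 61, n_loci = 6, contig_length = 200000L)
  v <- simulate_totivirus(61)
  host <- simulate_host_genome(61, 1, 200000)
  imp <- implant_eves(61, host, v$proteins, n_loci = 6)
  decoy <- tibble::tibble(
    id = paste0("decoy", 1:4),
    seq = vapply(1:4, function(i) rand_protein(400), character(1)))
  res <- run_discover(imp$genome, v$proteins, cfg, decoy_proteins = decoy)
  rec <- recovery_vs_truth(res$catalog, imp$truth, min_overlap = 0.8)
  expect_gte(sum(rec$recovered), 5)
  ctrl <- simulate_host_genome(62, 1, 200000)
  res0 <- run_discover(ctrl, v$proteins, cfg)
  expect_equal(nrow(res0$catalog), 0)
})
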