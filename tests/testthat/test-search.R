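test_that("six-frame translation follows the standard code with N -> X", {
  tr <- six_frame_translate("ATGAAA")
  expect_equal(tr$aa[tr$frame == 1], "MK")
  tr2 <- six_frame_translate("TTTCAT")
  expect_equal(tr2$aa[tr2$frame == -1], "MK")
  tr3 <- six_frame_translate("ATGNAA")
  expect_equal(tr3$aa[tr3$frame == 1], "MX")
  # stops are retained as '*'
  tr4 <- six_frame_translate("ATGTAAAAA")
  expect_equal(tr4$aa[tr4$frame == 1], "M*K")
})

test_that("frame coordinates map back to forward-strand nucleotides", {
  seq <- rand_dna(60, seed = 2)
  tr <- six_frame_translate(seq)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  for (i in seq_len(nrow(tr))) {
    f <- tr$frame[i]
    nc <- tr$n_codons[i]
    if (nc < 2) next
    g <- frame_to_genome(f, 1, nc, 60)
    expect_gte(g$start, 0)
    expect_lte(g$end, 60)
    sub <- substr(seq, g$start + 1, g$end)
    if (f < 0) sub <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(sub)))
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                             if.fuzzy.codon = "X"))
    expect_equal(aa, tr$aa[i])
  }
})

test_that("Smith-Waterman scores match hand-computed BLOSUM62 cases", {
  sw <- smith_waterman_protein("MKV", "MKV")
  expect_equal(sw$score, 14)   # 5 + 5 + 4 on the BLOSUM62 diagonal
  expect_equal(sw$pident, 100)
  expect_equal(sw$align_length, 3)
  # all pairwise scores negative: empty local alignment
  neg <- smith_waterman_protein("AAAA", "WWWW")
  expect_equal(neg$score, 0)
  expect_equal(neg$align_length, 0)
  # empty input
  expect_equal(smith_waterman_protein("", "MKV")$score, 0)
})

test_that("Smith-Waterman agrees with an independent aligner", {
  skip_if_not_installed("Biostrings")
  data(BLOSUM62, package = "Biostrings", envir = environment())
  set.seed(31)
  for (i in 1:20) {
    q <- rand_protein(sample(20:60, 1))
    s <- rand_protein(sample(40:120, 1))
    mine <- smith_waterman_protein(q, s)
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(q), Biostrings::AAString(s),
      type = "local", substitutionMatrix = BLOSUM62,
      gapOpening = 11, gapExtension = 1)
    expect_equal(mine$score, Biostrings::score(ref))
  }
})

test_that("stored alignments reproduce score and identity exactly", {
  scheme <- scoring_scheme()
  set.seed(17)
  for (i in 1:10) {
    prot <- rand_protein(80)
    mut <- mutate_aa(prot, 20)
    sw <- smith_waterman_protein(prot, mut, scheme)
    qa <- strsplit(sw$q_aln, "")[[1]]
    sa <- strsplit(sw$s_aln, "")[[1]]
    # rescore the aligned strings under the scheme
    sc <- 0; in_gap <- FALSE
    for (k in seq_along(qa)) {
      if (qa[k] == "-" || sa[k] == "-") {
        sc <- sc - scheme$gap_extend - if (in_gap) 0 else scheme$gap_open
        in_gap <- TRUE
      } else {
        sc <- sc + scheme$matrix[qa[k], sa[k]]
        in_gap <- FALSE
      }
    }
    expect_equal(sc, sw$score)
    expect_equal(sum(qa != "-" & qa == sa), sw$n_ident)
  }
})

test_that("E-values follow the Karlin-Altschul form", {
  scheme <- scoring_scheme()   # lambda 0.267, K 0.041
  ev <- evalue_from_score(50, 1000, 1000, scheme)
  expect_equal(ev$evalue, 0.041 * 1e6 * exp(-0.267 * 50))
  expect_equal(ev$evalue, 0.0653, tolerance = 1e-3)
  # strictly decreasing in S
  e2 <- evalue_from_score(51, 1000, 1000, scheme)
  expect_lt(e2$evalue, ev$evalue)
  # exactly linear in n
  e3 <- evalue_from_score(50, 1000, 2000, scheme)
  expect_equal(e3$evalue, 2 * ev$evalue)
  expect_error(evalue_from_score(50, 0, 1000, scheme), "positive")
})

test_that("planted loci are recovered at their exact coordinates", {
  host <- simulate_host_genome(21, 1, 60000)
  v <- simulate_totivirus(21, 4000, 300, 400)
  imp <- implant_eves(21, host, v$proteins, n_loci = 3,
                      identity_range = c(1, 1), frameshift_prob = 0,
                      min_separation_nt = 3000)
  hits <- seeded_translated_search(v$proteins, imp$genome,
                                   evalue_max = 1e-10)
  expect_gte(nrow(hits), 3)
  for (i in seq_len(nrow(imp$truth))) {
    tr <- imp$truth[i, ]
    match <- hits[hits$strand == tr$strand &
                    hits$subject_start <= tr$start + 30 &
                    hits$subject_end >= tr$end - 30, ]
    expect_gte(nrow(match), 1)
  }
  # every hit passes the coordinate invariant
  clen <- setNames(imp$genome$length, imp$genome$id)
  expect_true(all(hits$subject_start >= 0))
  expect_true(all(hits$subject_end <= clen[hits$contig_id]))
  expect_true(all(hits$subject_start < hits$subject_end))
  # subject span is 3 nt per aligned subject residue
  sres <- nchar(gsub("-", "", hits$s_aln))
  expect_equal(hits$subject_end - hits$subject_start, 3L * sres)
})

test_that("search is strand-symmetric under genome reverse complement", {
  host <- simulate_host_genome(23, 1, 30000)
  v <- simulate_totivirus(23, 3000, 200, 300)
  imp <- implant_eves(23, host, v$proteins, n_loci = 2,
                      identity_range = c(0.8, 1), min_separation_nt = 3000)
  genome <- imp$genome
  flipped <- dplyr::mutate(
    genome, seq = as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seq))))
  h1 <- seeded_translated_search(v$proteins, genome, evalue_max = 1e-5)
  h2 <- seeded_translated_search(v$proteins, flipped, evalue_max = 1e-5)
  key <- function(h) {
    dplyr::arrange(
      tibble::tibble(score = h$raw_score, len = h$align_length),
      score, len)
  }
  expect_equal(key(h2), key(h1))
  # coordinates mirror: start' = L - end
  L <- genome$length[1]
  m1 <- dplyr::arrange(h1, raw_score, query_id)
  m2 <- dplyr::arrange(h2, raw_score, query_id)
  expect_equal(m2$subject_start, L - m1$subject_end)
  expect_equal(m2$subject_end, L - m1$subject_start)
  expect_true(all(m2$strand != m1$strand))
})

test_that("hit scores never exceed the Smith-Waterman oracle per frame", {
  set.seed(29)
  scheme <- scoring_scheme()
  for (rep in 1:5) {
    prot <- rand_protein(120)
    mut <- mutate_aa(prot, 36)            # 70% identity
    subject <- paste0(rand_dna(600), backtranslate(mut), rand_dna(600))
    hits <- seeded_translated_search(
      tibble::tibble(id = "q", seq = prot),
      tibble::tibble(id = "s", seq = subject), evalue_max = 10)
    frames <- six_frame_translate(subject)
    best_frame_equal <- FALSE
    for (f in seq_len(nrow(frames))) {
      sw <- smith_waterman_protein(prot, frames$aa[f], scheme)$score
      hmax <- max(c(0, hits$raw_score[hits$frame == frames$frame[f]]))
      expect_lte(hmax, sw)
      if (sw > 100 && hmax == sw) best_frame_equal <- TRUE
    }
    expect_true(best_frame_equal)
  }
})

test_that("evalue_max = 0 yields an empty hit set", {
  v <- simulate_totivirus(25, 3000, 200, 300)
  host <- simulate_host_genome(25, 1, 20000)
  imp <- implant_eves(25, host, v$proteins, n_loci = 1,
                      identity_range = c(1, 1), min_separation_nt = 2000)
  h <- seeded_translated_search(v$proteins, imp$genome, evalue_max = 0)
  expect_equal(nrow(h), 0)
})
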