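# Shared fixture builders: everything generated in code at test time.

AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

rand_protein <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(AA_LETTERS, n, replace = TRUE), collapse = "")
}

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute exactly n_sub positions with a different residue
mutate_aa <- function(prot, n_sub) {
  chars <- strsplit(prot, "")[[1]]
  pos <- sample(length(chars), n_sub)
  for (p in pos) chars[p] <- sample(setdiff(AA_LETTERS, chars[p]), 1)
  paste(chars, collapse = "")
}

# uniform-random synonymous back-translation
backtranslate <- function(prot) {
  gc <- Biostrings::GENETIC_CODE
  codons <- vapply(strsplit(prot, "")[[1]],
                   function(a) sample(names(gc)[gc == a], 1), character(1))
  paste(codons, collapse = "")
}

# a hit-tibble row with the columns merge_hits() needs
hit_row <- function(contig = "c1", strand = "+", start = 0, end = 100,
                    evalue = 1e-20, raw_score = 100, query_id = "q1",
                    frame = 1L) {
  tibble::tibble(query_id = query_id, contig_id = contig, frame = frame,
                 strand = strand, subject_start = as.integer(start),
                 subject_end = as.integer(end), query_start = 1L,
                 query_end = 10L, raw_score = raw_score,
                 bit_score = raw_score / 2, evalue = evalue, pident = 100,
                 n_ident = 10L, align_length = 10L, q_aln = "MMMMMMMMMM",
                 s_aln = "MMMMMMMMMM")
}

# placement tibble from explicit intervals
placements_tbl <- function(starts, lengths, individual = "ind1",
                           contig = "c1") {
  tibble::tibble(individual_id = individual, contig_id = contig,
                 start = as.integer(starts), length = as.integer(lengths),
                 multimap_count = 1L)
}

locus_tbl <- function(id = "L1", contig = "c1", start = 0, end = 200) {
  tibble::tibble(locus_id = id, contig_id = contig,
                 start = as.integer(start), end = as.integer(end))
}

# exhaustive-enumeration oracle for the hypergeometric upper tail:
# fraction of n-subsets of 1..N whose overlap with 1..M is >= m
enum_hyper_upper <- function(N, n, M, m) {
  if (m == 0) return(1)
  subsets <- utils::combn(N, n)
  mean(apply(subsets, 2, function(s) sum(s <= M) >= m))
}
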