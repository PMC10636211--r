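# Readers/writers for the standard formats the pipeline touches, plus the
# shared coordinate conventions (0-based half-open, forward strand).

NUC_KEEP <- c("A", "C", "G", "T", "N")
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

normalize_nuc <- function(x) {
  x <- toupper(x)
  stringr::str_replace_all(x, "[^ACGTN]", "N")
}

normalize_aa <- function(x) {
  x <- toupper(x)
  stringr::str_replace_all(x, paste0("[^", paste(AA20, collapse = ""), "X]"), "X")
}

#' Read a FASTA file into a tibble
#'
#' Sequences are case-normalized on read. For nucleotide input every
#' character outside `ACGTN` (ambiguity codes, gaps, `U`) collapses to `N`;
#' for protein input every character outside the 20 standard amino acids
#' plus `X` (including stop `*`) collapses to `X`. Protein headers may carry
#' `virus=<id>` and `gene=<CP|RdRp|other>` tokens in the description, which
#' are parsed into columns.
#'
#' @param path Path to a FASTA file.
#' @param type `"dna"` for genome assemblies/transcripts, `"protein"` for
#'   protein sets.
#' @return A tibble with columns `id`, `seq`, `length`, and for proteins
#'   additionally `virus_id` and `gene_label`.
#' @export
read_fasta <- function(path, type = c("dna", "protein")) {
  type <- match.arg(type)
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  ids_full <- names(set)
  ids <- stringr::str_extract(ids_full, "^\\S+")
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(is.na(ids)) || any(ids == "")) stop("empty FASTA record id")
  seqs <- as.character(set)
  if (any(nchar(seqs) == 0)) stop("empty FASTA record (zero-length sequence)")
  seqs <- if (type == "dna") normalize_nuc(seqs) else normalize_aa(seqs)
  out <- tibble(id = ids, seq = unname(seqs), length = nchar(seqs))
  if (type == "protein") {
    out$virus_id <- stringr::str_match(ids_full, "virus=(\\S+)")[, 2]
    gene <- stringr::str_match(ids_full, "gene=(\\S+)")[, 2]
    out$gene_label <- dplyr::if_else(
      is.na(gene), "other",
      dplyr::if_else(gene %in% c("CP", "RdRp"), gene, "other")
    )
  }
  out
}

#' Write a sequence tibble to FASTA
#'
#' The inverse of [read_fasta()]: `virus_id`/`gene_label` columns, when
#' present, are serialized back into the description so a read/write cycle
#' round-trips ids and sequences exactly.
#'
#' @param seqs Tibble with columns `id` and `seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.data.frame(seqs), all(c("id", "seq") %in% names(seqs)))
  hdr <- seqs$id
  if ("virus_id" %in% names(seqs)) {
    extra <- paste0(
      ifelse(is.na(seqs$virus_id), "", paste0(" virus=", seqs$virus_id)),
      if ("gene_label" %in% names(seqs)) paste0(" gene=", seqs$gene_label) else ""
    )
    hdr <- paste0(hdr, extra)
  }
  set <- Biostrings::BStringSet(setNames(seqs$seq, hdr))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read mapped-read placements from SAM or TSV
#'
#' Returns one row per mapped alignment record with 0-based half-open
#' forward-strand coordinates. Unmapped SAM records are skipped; secondary
#' alignments are retained by default because multi-mapped reads carry the
#' depth evidence for repeated loci (set `drop_secondary = TRUE` to drop
#' them). The reference span of a SAM record is computed from its CIGAR.
#' The TSV dialect has columns `individual`, `contig`, `start` (0-based),
#' `length`, `multimap_count`.
#'
#' @param path Path to a SAM (`.sam`) or TSV file.
#' @param dialect `"auto"` (by extension), `"sam"` or `"tsv"`.
#' @param individual Individual id to assign to SAM records lacking an RG
#'   tag; defaults to the file name without extension.
#' @param drop_secondary Drop secondary/supplementary alignments.
#' @return A tibble with columns `individual_id`, `contig_id`, `start`,
#'   `length`, `multimap_count`.
#' @export
read_alignments <- function(path, dialect = c("auto", "sam", "tsv"),
                            individual = NULL, drop_secondary = FALSE) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  if (dialect == "auto") {
    dialect <- if (grepl("\\.sam$", path, ignore.case = TRUE)) "sam" else "tsv"
  }
  if (dialect == "tsv") {
    tbl <- readr::read_tsv(path, show_col_types = FALSE)
    need <- c("individual", "contig", "start", "length", "multimap_count")
    if (!all(need %in% names(tbl))) {
      stop("placement TSV must have columns: ", paste(need, collapse = ", "))
    }
    bad <- which(!stats::complete.cases(tbl[need]) |
                   tbl$start < 0 | tbl$length <= 0 | tbl$multimap_count < 1)
    if (length(bad)) stop("malformed placement TSV at data line ", bad[1])
    return(tibble(
      individual_id = as.character(tbl$individual),
      contig_id = as.character(tbl$contig),
      start = as.integer(tbl$start),
      length = as.integer(tbl$length),
      multimap_count = as.integer(tbl$multimap_count)
    ))
  }
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flags, tag = c("NH", "RG"),
    what = c("rname", "pos", "cigar", "flag")
  )
  rec <- Rsamtools::scanBam(bam, param = param)[[1]]
  keep <- !is.na(rec$pos)
  if (drop_secondary) keep <- keep & bitwAnd(rec$flag, 2048L + 256L) == 0L
  if (!any(keep)) {
    return(tibble(individual_id = character(), contig_id = character(),
                  start = integer(), length = integer(),
                  multimap_count = integer()))
  }
  width <- GenomicAlignments::cigarWidthAlongReferenceSpace(rec$cigar[keep])
  nh <- rec$tag$NH
  rg <- rec$tag$RG
  default_ind <- individual %||% sub("\\.[^.]*$", "", basename(path))
  tibble(
    individual_id = if (is.null(rg)) default_ind else
      dplyr::coalesce(as.character(rg[keep]), default_ind),
    contig_id = as.character(rec$rname[keep]),
    start = as.integer(rec$pos[keep] - 1L),
    length = as.integer(width),
    multimap_count = if (is.null(nh)) 1L else
      as.integer(dplyr::coalesce(nh[keep], 1L))
  )
}

#' Read non-reference variant sites from VCF or TSV
#'
#' Emits one row per sample per record whose genotype carries at least one
#' non-reference allele. VCF `POS` is converted to 0-based. Records with a
#' missing genotype are skipped with a warning. The TSV dialect has columns
#' `individual`, `contig`, `position` (0-based), `ref`, `alt`.
#'
#' @param path Path to a VCF (`.vcf`) or TSV file.
#' @param dialect `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @return A tibble with columns `individual_id`, `contig_id`, `position`,
#'   `ref_allele`, `alt_allele`, `genotype_is_nonref`.
#' @export
read_variants <- function(path, dialect = c("auto", "vcf", "tsv")) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  if (dialect == "auto") {
    dialect <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (dialect == "tsv") {
    tbl <- readr::read_tsv(path, show_col_types = FALSE)
    need <- c("individual", "contig", "position", "ref", "alt")
    if (!all(need %in% names(tbl))) {
      stop("variant TSV must have columns: ", paste(need, collapse = ", "))
    }
    return(tibble(
      individual_id = as.character(tbl$individual),
      contig_id = as.character(tbl$contig),
      position = as.integer(tbl$position),
      ref_allele = as.character(tbl$ref),
      alt_allele = as.character(tbl$alt),
      genotype_is_nonref = TRUE
    ))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt) || ncol(gt) == 0) stop("VCF has no sample genotypes")
  n_missing <- sum(is.na(gt))
  if (n_missing > 0) {
    warning(n_missing, " genotype call(s) missing; records skipped")
  }
  nonref <- !is.na(gt) & grepl("[1-9]", gt)
  idx <- which(nonref, arr.ind = TRUE)
  tibble(
    individual_id = colnames(gt)[idx[, 2]],
    contig_id = fix$CHROM[idx[, 1]],
    position = as.integer(fix$POS[idx[, 1]]) - 1L,
    ref_allele = fix$REF[idx[, 1]],
    alt_allele = fix$ALT[idx[, 1]],
    genotype_is_nonref = TRUE
  ) |>
    dplyr::arrange(.data$individual_id, .data$contig_id, .data$position)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# reverse complement for plain character vectors
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
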