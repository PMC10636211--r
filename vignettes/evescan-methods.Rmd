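---
title: "evescan: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{evescan: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evescan)
```

This vignette is the package's own account of the science it implements:
the models behind each stage, the tunable parameters with their defaults
and rationale, what the synthetic-data generator does and does not
emulate, and the numerical choices that make outputs deterministic.

## 1. Translated homology search

Endogenous viral elements (EVEs) decay after integration, so they are
found by comparing viral **proteins** against the six reading frames of
the host assembly. The engine works per (query, frame) pair:

1. exact protein k-mers (default `seed_k = 4`) shared between query and
   frame translation seed the search (one-hit trigger, no two-hit
   heuristic — simpler and easier to audit);
2. seeds are extended without gaps under an X-drop rule
   (`x_drop = 20` score units); extensions scoring at least
   `trigger = 30` proceed;
3. a banded affine-gap Smith–Waterman (half-width `band = 32` around the
   seed diagonal) produces the reported local alignment;
4. alignments are deduplicated by containment and mapped back to
   forward-strand, 0-based half-open nucleotide coordinates.

Scoring is BLOSUM62 with gap open 11 / extend 1 — the conventional
translated-search defaults; the published gapped Karlin–Altschul constants
for that scheme, λ = 0.267 and K = 0.041, convert raw scores to
`E = K·m·n·e^(−λS)` with `n` the total translated residues over all six
frames. The constants live in `scoring_scheme()` and are overridable; no
per-search empirical calibration is attempted, which keeps desk-scale runs
deterministic. The stop character `*` scores −4 against every residue, so
alignments may cross in-frame stops — decayed elements routinely contain
them. Frameshifted elements appear as separate hits in different frames
and are stitched downstream by `merge_hits()`, not inside the aligner.

Two deterministic tie-breaks fix the output: the dynamic-programming
traceback prefers diagonal over up over left, and among equal-score optima
the smallest subject coordinate wins.

`smith_waterman_protein()` is the exhaustive counterpart used as an
oracle: heuristic hit scores can never exceed it, and on planted
homologies of ≥ 60% amino-acid identity the two agree in well over 95% of
cases (the acceptance suite measures this on 200 random cases). The
heuristic can miss an optimum when the true alignment drifts more than
`band` diagonals from every seed, or when two homologous copies share one
diagonal — both rare at these settings and documented limitations.

## 2. Locus catalogue

* `merge_hits()` joins hits with E < 1e−5 on the same contig **and
  strand** whose intervals are ≤ `max_gap_nt = 1000` apart. The merge
  distance is not dictated by the screening procedure this reproduces, so
  it is a config knob; 1 kb comfortably spans frameshift breakpoints while
  keeping independently implanted loci (≥ 5 kb apart in the simulator)
  separate. Merging is idempotent and order-invariant; opposite strands
  never merge because sense and antisense insertions are distinct events.
* `apply_stringency()` flags (never removes) loci with best E < 1e−10 and
  length ≥ 350 bp — the stringent screening criteria.
* `reciprocal_filter()` re-searches each locus against the union of the
  viral panel and a user-supplied decoy (background) proteome. The
  decision rule is explicit since "eliminate false positives" needs one:
  the locus is kept iff its top bit-score hit is viral; exact ties keep
  the locus but flag it; an empty decoy keeps everything with a warning.
  A supplied decoy proteome replaces any dependence on a remote protein
  database.
* `assign_best_hit()` reports the maximum-bit-score viral protein, its
  gene label (CP/RdRp) and the alignment's percent identity.
* `predict_orf_with_flanks()` extends each locus by `flank_nt = 2000`
  (clipped at contig bounds) and reports complete ATG→stop ORFs of
  ≥ `min_orf_nt = 300` nt on both strands. Within one stop-to-stop
  segment the first ATG is used, i.e. the longest ORF per segment;
  nested sub-ORFs are not enumerated. 300 nt is permissive relative to
  the 528–4737 nt ORFs observed in real EVE transcripts.

## 3. Presence/absence genotyping

`depth_profile()` counts placements per base; multi-mapped placements
count once per placement, because reference assemblies can contain
multiple identical EVE copies and dropping multi-mappers would blind the
caller to all of them (a `drop_secondary` flag exists in the reader).
Windows are non-overlapping 100-bp tiles (trailing tile at actual width);
the window means, weighted by width, conserve the per-base total exactly.

`qc_individual()` excludes individuals below 15.0× genome-wide mean depth
(strict) or 5.0× (relaxed, for shallowly sequenced cohorts); boundary
values are included, reading "less than 15.0× excluded" literally.

`call_presence()` declares a locus present when mean depth is **strictly**
greater than 5 (strict profile) or 1 (relaxed) and **strictly** more than
50% of positions are covered at depth ≥ 1. "Coverage" at locus level is
interpreted as breadth at depth ≥ 1 rather than breadth at the profile's
depth threshold — the more common convention and the one that makes the
two profile thresholds act purely on depth. Boundary cases (mean depth
exactly 5.0) are therefore absent-side deterministic. Adding reads can
only raise both statistics, so calls are monotone in evidence.

`presence_matrix_pca()` runs a column-centred, unscaled PCA
(`stats::prcomp`) of the individuals × loci matrix; `tidy()`, `glance()`
and `autoplot()` methods expose scores, variance fractions and the usual
PC1/PC2 view. Population-structure interpretation is left to the user.

## 4. Polymorphism and rate baselines

The polymorphism level of a target interval in one individual is the
number of **distinct** non-reference variant positions inside it, scaled
to variants per kb. The upstream variant-calling script this stands in
for is not published as a formula, so the definition is stated here as
the module's own: SNPs and indels each count one position; duplicate
records at one position count once. Counts are additive over interval
splits.

`p_distance()` is the proportion of differing sites over columns with no
gap in either row of the pair, averaged over all row pairs (for
three-taxon alignments there are three pairs; the aggregation rule is the
mean since only "pairwise p-distance of each alignment" is specified).
`filter_poorly_aligned()` removes alignments with strictly more than 10%
gapped columns. `classify_feg_seg()` ranks by p-distance and takes
`floor(0.05 · n)` at each extreme — floor rounding reproduces the
published 73-of-1,462 count exactly — with ties broken by ortholog id for
determinism; fewer than 20 alignments yield empty classes with a warning.

## 5. Expression, small RNAs, triage

FPKM is `fragments / ((length/1000) · (library/10^6))`; it is invariant
under joint scaling of counts and library size. sRNA reads map to a
transcript iff they are exact substrings of it or its reverse complement
(perfect-match rule; the strand of origin of an sRNA read is unknown, so
both strands are searched; a read mapping several positions counts once).
Only 18–30 nt reads are considered — the extraction window of sRNA
libraries. The piRNA signature is abundance in the 24–29 nt band; since
"abundant" needs numbers, the flag defaults to ≥ 50 mapped reads with
≥ 50% of them in the band, both config-exposed
(`pirna_min_reads`, `pirna_min_fraction`).

`triage_virus_contigs()` keeps assembled contigs with coverage > 20×,
length > 2000 bp and best E-value < 1e−20, all strict; the filter is
monotone in each criterion. `filter_deg()` is a plain threshold utility
(|log2 ratio| > 1, adjusted p < 0.05) over an externally fitted
differential-expression table; the model itself is out of scope.

## 6. Enrichment

`hypergeometric_p()` evaluates the inclusive upper tail
`Pr(X ≥ m) = 1 − Σ_{i=0}^{m−1} C(M,i)·C(N−M,n−i)/C(N,n)` directly as the
upper sum with log-gamma binomial coefficients and a log-sum-exp
reduction, so `m = 0` returns exactly 1 and large (N, n, M) never
overflow. It agrees with exhaustive subset enumeration for every valid
query up to N = 12 (the acceptance suite checks all 3,179 of them) and
with `stats::phyper` elsewhere. Raw probabilities are reported by default
— whether the original GO tooling adjusted for multiple testing is not
stated, so adjustment is opt-in (`bh_adjust()`, Benjamini–Hochberg via
`stats::p.adjust`).

## 7. The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
with one integer seed driving a named RNG stream per simulator (adding a
simulator never shifts another's stream; identical seeds give
byte-identical outputs):

* **Virus**: one genome segment with two non-overlapping intact ORFs
  (CP 700 aa, RdRp 900 aa, 7 kb genome by default — canonical totivirus
  proportions). Coding sequence uses uniform-random synonymous codons:
  codon usage is irrelevant to protein-space detection.
* **Implants**: protein fragments of 120–400 aa (≥ 360 nt, above the
  350-nt stringency floor) mutated in protein space to a target identity
  drawn from 0.6–1.0 — substitutions uniform over non-identical residues,
  a deliberately simple decay model sufficient for detector
  benchmarking — back-translated, optionally frameshifted by 1–2
  single-base indels (probability 0.3), placed on either strand
  (probability 0.5) at ≥ 5 kb separation in a 1-Mb uniform-random host
  contig.
* **Reads**: Poisson read counts with uniform starts tile each locus so
  expected interior depth equals 30× where the presence map says present
  and 0× otherwise.
* **Variants**: per-position Bernoulli at 6 sites/kb per individual.
* **Orthologs**: gap-free three-taxon alignments under a star tree; the
  per-branch substitution probability `a` solves
  `p_pair = 2a − (4/3)a²` so the expected pairwise difference equals the
  assigned rate (5% at 0.4, 90% at 0.2, 5% at 0.05).
* **sRNA**: exact substrings of either strand with lengths from a
  rounded normal clipped to [18, 30]; mean 26 emulates a piRNA-dominated
  ovary library, mean 21 an siRNA-dominated one.

What it does **not** emulate — and hence what passing tests do not show
about real data: sequencing error and mapping ambiguity, transposon-rich
repeat context around insertions, codon-usage and GC structure,
demography/selection in the cohort, and empirically calibrated E-value
statistics for short or biased sequences. Recovery rates on this
generator are an upper bound on real-data performance.

## 8. Problem sizes and orchestration

The shipped test and acceptance runs use a 1-Mb host contig with 20
implants for discovery, a 10 × 10 cohort at 30×/0× for presence calling,
1,000–1,462 orthologs for the rate classifier (10-kb alignments where the
±0.02 sampling noise of a 0.05/0.2/0.4 contrast must be resolved, 120-nt
ones where only ranking and rounding are at stake), 200 planted
homologies for the search-vs-oracle comparison, and 20 seeds per sRNA
regime — sizes chosen so each property is measured with comfortable
statistical margin on a single CPU.

`run_simulate()`, `run_discover()` and `run_population()` chain the
modules; `eve_config()` holds every threshold (rejecting unknown keys)
and each run returns a manifest of seed, version and thresholds. The
package's functions are the primary interface; a thin command-line
wrapper (`inst/scripts/evescan-cli.R`) exposes simulate/discover/
population/all for shell use. The separate `express`/`srna`/`enrich`
steps are single function calls and are not wrapped further.

## Known limitations

* The seeded search reports one alignment per (band, region); a second
  homologous copy on the same diagonal within the band of a stronger one
  is absorbed by containment deduplication.
* No low-complexity masking or composition-based statistic corrections;
  on real genomes these would reduce spurious seeds.
* The reciprocal filter is only as good as the supplied decoy proteome.
* ORF prediction reports the longest ORF per stop segment; alternative
  downstream starts are not enumerated.
* Karlin–Altschul constants are fixed, not estimated per search; E-values
  for very short queries are approximate.
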