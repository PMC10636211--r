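# Per-individual presence/absence calling of catalogued loci from read
# placements: depth profiles, individual-level QC, windowed depth, and a
# presence-matrix PCA.

#' Per-base depth profiles of loci per individual
#'
#' depth[i] is the number of placements covering position i; multi-mapped
#' placements each count once per placement, which is what keeps repeated
#' loci visible. Non-overlapping 100-bp windows summarise the profile; the
#' trailing partial window is reported at its actual width.
#'
#' @param placements Placement tibble (`individual_id`, `contig_id`,
#'   `start`, `length`).
#' @param loci Locus tibble (`locus_id`, `contig_id`, `start`, `end`).
#' @param individuals Individuals to profile; defaults to those in
#'   `placements`. Individuals with no placements get all-zero profiles.
#' @param window_nt Window width for the summarised profile.
#' @return A tibble with one row per individual x locus: `individual_id`,
#'   `locus_id`, `mean_depth`, `covered_fraction`, `depth` (list column,
#'   per-base integer vector), `windows` (list column tibble
#'   `window_start`, `width`, `mean_depth`).
#' @export
depth_profile <- function(placements, loci, individuals = NULL,
                          window_nt = 100) {
  stopifnot(all(loci$end > loci$start))
  individuals <- individuals %||% sort(unique(placements$individual_id))
  grid <- tidyr::expand_grid(individual_id = individuals,
                             li = seq_len(nrow(loci)))
  purrr::pmap_dfr(grid, function(individual_id, li) {
    lc <- loci[li, ]
    p <- placements[placements$individual_id == individual_id &
                      placements$contig_id == lc$contig_id, ]
    L <- lc$end - lc$start
    if (nrow(p) == 0) {
      depth <- integer(L)
    } else {
      cov <- IRanges::coverage(
        IRanges::IRanges(start = p$start + 1L, width = p$length),
        width = max(lc$end, max(p$start + p$length))
      )
      depth <- as.integer(cov[(lc$start + 1L):lc$end])
    }
    wstarts <- seq(0L, L - 1L, by = window_nt)
    widths <- pmin(window_nt, L - wstarts)
    wmeans <- vapply(seq_along(wstarts), function(w) {
      mean(depth[(wstarts[w] + 1L):(wstarts[w] + widths[w])])
    }, numeric(1))
    tibble(
      individual_id = individual_id, locus_id = lc$locus_id,
      mean_depth = mean(depth),
      covered_fraction = mean(depth >= 1),
      depth = list(depth),
      windows = list(tibble(window_start = wstarts + lc$start,
                            width = widths, mean_depth = wmeans))
    )
  })
}

#' Individual-level sequencing-depth QC
#'
#' Genome-wide mean depth is total aligned bases over total assembly
#' length. The strict profile admits individuals at >= 15.0x (those below
#' are excluded); the relaxed profile admits >= 5.0x, the floor used for
#' cohorts sequenced more shallowly.
#'
#' @param placements Placement tibble.
#' @param genome Genome tibble (`id`, `seq` or `length`).
#' @param profile `"strict"` (15x floor) or `"relaxed"` (5x floor).
#' @return A tibble: `individual_id`, `genome_wide_mean_depth`,
#'   `min_depth_required`, `included`.
#' @export
qc_individual <- function(placements, genome, profile = c("strict", "relaxed")) {
  profile <- match.arg(profile)
  floor_x <- if (profile == "strict") 15.0 else 5.0
  total <- if ("length" %in% names(genome)) sum(genome$length)
           else sum(nchar(genome$seq))
  placements |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::summarise(genome_wide_mean_depth = sum(.data$length) / total,
                     .groups = "drop") |>
    dplyr::mutate(min_depth_required = floor_x,
                  included = .data$genome_wide_mean_depth >= floor_x)
}

#' Call locus presence per individual from depth profiles
#'
#' A locus is present in an individual when its mean depth is strictly
#' greater than the profile's depth threshold (5 strict, 1 relaxed) and
#' strictly more than 50% of its positions are covered at depth >= 1.
#' Boundary values (e.g. mean depth exactly 5.0 under strict) are called
#' absent, matching the strict inequalities of the criteria.
#'
#' @param profiles Tibble from [depth_profile()].
#' @param profile `"strict"` (depth > 5) or `"relaxed"` (depth > 1).
#' @return A tibble: `individual_id`, `locus_id`, `present`,
#'   `profile_used`, `mean_depth`, `covered_fraction`.
#' @export
call_presence <- function(profiles, profile = c("strict", "relaxed")) {
  profile <- match.arg(profile)
  thr <- if (profile == "strict") 5 else 1
  profiles |>
    dplyr::transmute(
      .data$individual_id, .data$locus_id,
      present = .data$mean_depth > thr & .data$covered_fraction > 0.5,
      profile_used = profile,
      .data$mean_depth, .data$covered_fraction
    )
}

#' Presence calls as an individuals-by-loci matrix
#'
#' @param calls Tibble from [call_presence()].
#' @param value `"present"` for a 0/1 matrix or `"covered_fraction"` for
#'   the companion continuous matrix.
#' @return A numeric matrix, rows = individuals, columns = loci.
#' @export
presence_matrix <- function(calls, value = c("present", "covered_fraction")) {
  value <- match.arg(value)
  wide <- calls |>
    dplyr::select("individual_id", "locus_id", dplyr::all_of(value)) |>
    tidyr::pivot_wider(names_from = "locus_id",
                       values_from = dplyr::all_of(value), values_fill = 0)
  m <- as.matrix(wide[-1]) * 1.0
  rownames(m) <- wide$individual_id
  m
}

#' PCA of the presence (or covered-fraction) matrix
#'
#' Column-centered singular value decomposition of the individuals-by-loci
#' matrix, the standard view of population structure in locus carriage.
#'
#' @param mat Matrix from [presence_matrix()] (individuals x loci; absent
#'   individuals should already be imputed as 0).
#' @param n_components Number of components to retain.
#' @return An object of class `eve_pca` with `scores` (tibble), `loadings`,
#'   `explained_variance` (fractions), and the fitted `prcomp` object.
#'   Methods: [tidy()], [glance()], [autoplot()].
#' @export
presence_matrix_pca <- function(mat, n_components = 2) {
  stopifnot(is.matrix(mat), !anyNA(mat))
  n_components <- min(n_components, nrow(mat) - 1, ncol(mat))
  fit <- prcomp(mat, center = TRUE, scale. = FALSE)
  ev <- fit$sdev^2
  evf <- if (sum(ev) > 0) ev / sum(ev) else ev
  keep <- seq_len(max(n_components, 1))
  scores <- as_tibble(fit$x[, keep, drop = FALSE]) |>
    dplyr::mutate(individual_id = rownames(mat), .before = 1)
  structure(
    list(scores = scores,
         loadings = fit$rotation[, keep, drop = FALSE],
         explained_variance = evf[keep],
         n_components = length(keep),
         prcomp = fit),
    class = "eve_pca"
  )
}

#' @export
print.eve_pca <- function(x, ...) {
  cat("Presence-matrix PCA:", nrow(x$scores), "individuals,",
      x$n_components, "components\n")
  cat("explained variance:",
      paste0(sprintf("%.1f%%", 100 * x$explained_variance), collapse = ", "),
      "\n")
  invisible(x)
}

#' @rdname presence_matrix_pca
#' @param x An `eve_pca` object.
#' @param ... Unused.
#' @export
tidy.eve_pca <- function(x, ...) {
  x$scores |>
    tidyr::pivot_longer(dplyr::starts_with("PC"), names_to = "component",
                        values_to = "score")
}

#' @rdname presence_matrix_pca
#' @export
glance.eve_pca <- function(x, ...) {
  tibble(n_individuals = nrow(x$scores), n_components = x$n_components,
         pc1_var = x$explained_variance[1],
         pc2_var = if (x$n_components >= 2) x$explained_variance[2] else NA_real_)
}
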