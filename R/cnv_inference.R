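#' Infer relative copy-number profiles against a reference population
#'
#' Smoothed relative-expression profile per cell, inferCNV-style, with an
#' internal reference population (e.g. T cells). Steps, in order: (1) drop
#' genes whose mean raw count among reference cells is below `min_ref_mean`;
#' (2) log-normalize all cells ([lognormalize()] semantics); (3) subtract
#' the reference-cell mean per gene; (4) per chromosome, centered moving
#' average over `window` genes ordered by genomic start (truncated at
#' chromosome ends, one window per gene); (5) subtract each cell's median
#' across all windows; (6) clamp to `+/-clamp`.
#'
#' @param counts genes x cells raw counts (sparse allowed).
#' @param positions data.frame `gene`, `chrom`, `start` (1-based).
#' @param reference_cells cell ids of the reference population.
#' @param window moving-average width in genes (default 101).
#' @param min_ref_mean reference-mean expression cutoff (default 0.1).
#' @param clamp profile clamp (default 1.0).
#' @return object of class `cnv_profile`: `values` (cells x windows),
#'   `window_map` (window, chrom, gene, start, span_first, span_last),
#'   `reference_cells`, `params`.
#' @export
infer_cnv_profile <- function(counts, positions, reference_cells,
                              window = 101L, min_ref_mean = 0.1, clamp = 1.0) {
  reference_cells <- intersect(reference_cells, colnames(counts))
  if (!length(reference_cells)) .fail("infer_cnv_profile: empty reference")
  ref_mean <- .rowmeans(counts[, reference_cells, drop = FALSE])
  keep <- rownames(counts)[ref_mean >= min_ref_mean]
  keep <- intersect(keep, positions$gene)
  pos <- positions[match(keep, positions$gene), ]
  n_per_chrom <- table(pos$chrom)
  if (!any(n_per_chrom >= window))
    .fail("infer_cnv_profile: no chromosome carries >= ", window,
          " genes after filtering")

  norm <- .dense(lognormalize(counts[keep, , drop = FALSE]))
  norm <- norm - rowMeans(norm[, reference_cells, drop = FALSE])

  ord <- order(pos$chrom, pos$start)
  pos <- pos[ord, ]
  norm <- norm[ord, , drop = FALSE]

  half <- (window - 1L) %/% 2L
  smoothed <- matrix(NA_real_, nrow(norm), ncol(norm), dimnames = dimnames(norm))
  span <- matrix(NA_integer_, nrow(norm), 2)
  offset <- 0L
  for (ch in unique(pos$chrom)) {
    rows <- which(pos$chrom == ch)
    nch <- length(rows)
    cs <- rbind(0, apply(norm[rows, , drop = FALSE], 2, cumsum))
    lo <- pmax(seq_len(nch) - half, 1L)
    hi <- pmin(seq_len(nch) + half, nch)
    smoothed[rows, ] <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) /
      (hi - lo + 1L)
    span[rows, ] <- cbind(rows[lo], rows[hi])
    offset <- offset + nch
  }
  med <- apply(smoothed, 2, stats::median)
  values <- t(pmin(pmax(sweep(smoothed, 2, med), -clamp), clamp))
  window_map <- data.frame(window = seq_len(nrow(pos)), chrom = pos$chrom,
                           gene = pos$gene, start = pos$start,
                           span_first = pos$gene[span[, 1]],
                           span_last = pos$gene[span[, 2]],
                           stringsAsFactors = FALSE)
  structure(list(values = values, window_map = window_map,
                 reference_cells = reference_cells,
                 params = list(window = window, min_ref_mean = min_ref_mean,
                               clamp = clamp)),
            class = "cnv_profile")
}

#' @export
print.cnv_profile <- function(x, ...) {
  cat("cnv_profile:", nrow(x$values), "cells x", ncol(x$values), "windows (",
      length(unique(x$window_map$chrom)), "chromosomes ), window",
      x$params$window, "\n")
  invisible(x)
}

#' Mask expression changes shared across all samples
#'
#' Changes present with the same sign in the epithelial cells of every
#' sample plausibly reflect lineage-dependent transcription rather than
#' genomic structural change. A window is masked when the mean profile of
#' epithelial cells exceeds `+shared_threshold` in all samples or falls
#' below `-shared_threshold` in all samples.
#'
#' @param profiles_by_sample named list of [infer_cnv_profile()] results
#'   with identical window maps (>= 2 samples).
#' @param epithelial_cells_by_sample named list of epithelial cell ids per
#'   sample.
#' @param shared_threshold exceedance threshold (default 0.15).
#' @return logical per window, `TRUE` = masked (excluded from burden and
#'   segment calls).
#' @export
exclude_shared_changes <- function(profiles_by_sample,
                                   epithelial_cells_by_sample,
                                   shared_threshold = 0.15) {
  if (length(profiles_by_sample) < 2)
    .fail("exclude_shared_changes: needs >= 2 samples")
  ref_map <- profiles_by_sample[[1]]$window_map
  for (p in profiles_by_sample[-1]) {
    if (!identical(p$window_map$gene, ref_map$gene) ||
        !identical(p$window_map$chrom, ref_map$chrom))
      .fail("exclude_shared_changes: window maps differ between samples")
  }
  means <- sapply(names(profiles_by_sample), function(s) {
    cells <- intersect(epithelial_cells_by_sample[[s]],
                       rownames(profiles_by_sample[[s]]$values))
    if (!length(cells)) .fail("exclude_shared_changes: sample ", s,
                              " has no epithelial cells in its profile")
    colMeans(profiles_by_sample[[s]]$values[cells, , drop = FALSE])
  })
  means <- matrix(means, nrow = nrow(ref_map))
  up <- rowSums(means > shared_threshold) == ncol(means)
  down <- rowSums(means < -shared_threshold) == ncol(means)
  stats::setNames(up | down, ref_map$gene)
}

#' Per-cell copy-number aberration burden
#'
#' Mean squared profile value over unmasked windows: a scalar summary of how
#' far a cell's smoothed expression deviates from the reference baseline,
#' used to compare aberration rates between cell populations (e.g. tumor
#' cells versus fibroblasts, via a rank-sum test).
#'
#' @param profile a [infer_cnv_profile()] result.
#' @param mask optional logical per window (`TRUE` = excluded), from
#'   [exclude_shared_changes()].
#' @return named numeric per cell, >= 0.
#' @export
cnv_burden <- function(profile, mask = NULL) {
  stopifnot(inherits(profile, "cnv_profile"))
  v <- profile$values
  if (!is.null(mask)) {
    if (length(mask) != ncol(v))
      .fail("cnv_burden: mask length does not match windows")
    if (all(mask)) .fail("cnv_burden: all windows masked")
    v <- v[, !mask, drop = FALSE]
  }
  rowMeans(v^2)
}

#' Call aberrant windows from mean group profiles
#'
#' Convenience caller used in recovery diagnostics: windows whose mean
#' profile over the given cells exceeds `threshold` in absolute value.
#'
#' @param profile a `cnv_profile`.
#' @param cells cell ids to average over.
#' @param threshold absolute mean-profile threshold (default 0.15).
#' @param mask optional shared-change mask (`TRUE` = excluded).
#' @return character vector of window gene ids called aberrant.
#' @export
call_aberrant_windows <- function(profile, cells, threshold = 0.15,
                                  mask = NULL) {
  stopifnot(inherits(profile, "cnv_profile"))
  mu <- colMeans(profile$values[intersect(cells, rownames(profile$values)),
                                , drop = FALSE])
  called <- abs(mu) > threshold
  if (!is.null(mask)) called <- called & !mask
  profile$window_map$gene[called]
}
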