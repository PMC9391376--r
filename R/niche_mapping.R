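#' Per-cell INF minus NOD enrichment difference
#'
#' The infiltrative-profile coordinate of each cell: the difference between
#' the spatial INF and NOD signature module scores.
#'
#' @param score_inf,score_nod [module_score()] results over the same cells.
#' @return named numeric per cell.
#' @export
score_difference <- function(score_inf, score_nod) {
  stopifnot(inherits(score_inf, "module_score"),
            inherits(score_nod, "module_score"))
  if (!identical(names(score_inf$scores), names(score_nod$scores)))
    .fail("score_difference: score vectors cover different cells")
  score_inf$scores - score_nod$scores
}

#' Rank clusters along the infiltrative gradient and group them
#'
#' Clusters are ordered by ascending mean score difference (ties broken by
#' original cluster id) and relabeled `<prefix>1..<prefix>k`. Groups are
#' assigned by `group_spec`: either explicit per-group counts (named, in
#' order), or the default rule — quartile singletons
#' Low/MedLow/MedHigh/High when k = 4, else cuts at the 25% and 75% cluster
#' quantiles into Low/Med/High (k = 15 gives 4/7/4).
#'
#' @param diff per-cell score difference ([score_difference()]).
#' @param clusters named cluster labels covering the same cells.
#' @param group_spec optional named integer vector of group sizes summing
#'   to the number of clusters.
#' @param prefix rank label prefix (default `"TC"`).
#' @return data.frame of class `cluster_ranking`: `cluster`, `mean_diff`,
#'   `rank`, `label`, `group`, plus attribute `cell_rank_labels` (named
#'   per-cell relabeling).
#' @export
rank_clusters <- function(diff, clusters, group_spec = NULL, prefix = "TC") {
  if (!all(names(clusters) %in% names(diff)))
    .fail("rank_clusters: every clustered cell needs a score difference")
  sizes <- table(clusters)
  if (any(sizes == 0)) .fail("rank_clusters: empty cluster")
  mean_diff <- tapply(diff[names(clusters)], clusters, mean)
  cl <- names(mean_diff)
  ord <- order(mean_diff, cl)
  k <- length(cl)
  if (is.null(group_spec)) {
    if (k == 4) {
      group_spec <- c(Low = 1L, MedLow = 1L, MedHigh = 1L, High = 1L)
    } else {
      n_low <- round(0.25 * k)
      n_high <- k - round(0.75 * k)
      group_spec <- c(Low = n_low, Med = k - n_low - n_high, High = n_high)
    }
  }
  if (sum(group_spec) != k)
    .fail("rank_clusters: group sizes must sum to the number of clusters")
  group <- rep(names(group_spec), group_spec)
  out <- data.frame(cluster = cl[ord],
                    mean_diff = as.numeric(mean_diff[ord]),
                    rank = seq_len(k),
                    label = paste0(prefix, seq_len(k)),
                    group = group, row.names = NULL, stringsAsFactors = FALSE)
  relabel <- stats::setNames(out$label, out$cluster)
  attr(out, "cell_rank_labels") <-
    stats::setNames(relabel[as.character(clusters)], names(clusters))
  class(out) <- c("cluster_ranking", "data.frame")
  out
}

#' NOD/INF signature anticorrelation
#'
#' Pearson correlation with a two-sided p-value between the NOD and INF
#' module scores over cells (the expected negative association along the
#' nodular-to-infiltrative continuum); Spearman is reported alongside.
#'
#' @param score_nod,score_inf [module_score()] results (or named numeric
#'   vectors) over the same cells.
#' @return list with `rho`, `p`, `spearman_rho`, `spearman_p`, `n`.
#' @export
signature_anticorrelation <- function(score_nod, score_inf) {
  x <- if (inherits(score_nod, "module_score")) score_nod$scores else score_nod
  y <- if (inherits(score_inf, "module_score")) score_inf$scores else score_inf
  if (length(x) != length(y) || length(x) < 3)
    .fail("signature_anticorrelation: need >= 3 paired cells")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    .fail("signature_anticorrelation: zero variance in a score")
  ct <- stats::cor.test(x, y, method = "pearson")
  cs <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value,
       spearman_rho = unname(cs$estimate), spearman_p = cs$p.value,
       n = length(x))
}
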