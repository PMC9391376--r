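#' Quality-control parameters for single cells
#'
#' Bounds on detected genes per cell and on the read fractions mapped to
#' mitochondrial and dissociation-stress genes. Detected-gene bounds are
#' inclusive; the fraction cuts are strict upper bounds.
#'
#' @param min_genes,max_genes inclusive detected-gene bounds (defaults 500
#'   and 6000).
#' @param max_mito_frac,max_dissoc_frac strict upper bounds on the read
#'   fractions (defaults 0.20).
#' @param mito_genes,dissoc_genes gene id lists defining the two classes.
#' @return object of class `qc_params`.
#' @export
qc_params <- function(min_genes = 500L, max_genes = 6000L,
                      max_mito_frac = 0.20, max_dissoc_frac = 0.20,
                      mito_genes = character(), dissoc_genes = character()) {
  if (!(min_genes > 0 && min_genes < max_genes))
    .fail("qc_params: need 0 < min_genes < max_genes")
  if (max_mito_frac <= 0 || max_mito_frac > 1 ||
      max_dissoc_frac <= 0 || max_dissoc_frac > 1)
    .fail("qc_params: fractions must lie in (0, 1]")
  structure(list(min_genes = min_genes, max_genes = max_genes,
                 max_mito_frac = max_mito_frac,
                 max_dissoc_frac = max_dissoc_frac,
                 mito_genes = mito_genes, dissoc_genes = dissoc_genes),
            class = "qc_params")
}

#' Filter cells on detected genes and mito/dissociation read fractions
#'
#' Retains exactly the cells with a detected-gene count inside
#' `[min_genes, max_genes]` (inclusive), mitochondrial read fraction below
#' `max_mito_frac`, and dissociation-gene read fraction below
#' `max_dissoc_frac`. Cell order is preserved.
#'
#' @param counts genes x cells raw count matrix (sparse allowed).
#' @param qc a [qc_params()]. Gene-list entries absent from the matrix are
#'   warned about and ignored.
#' @return logical vector named by cell, `TRUE` for retained cells. Subset
#'   the matrix and metadata with it.
#' @export
filter_cells <- function(counts, qc) {
  stopifnot(inherits(qc, "qc_params"))
  miss <- setdiff(c(qc$mito_genes, qc$dissoc_genes), rownames(counts))
  if (length(miss))
    warning("filter_cells: QC genes absent from matrix: ",
            paste(miss, collapse = ", "))
  mito <- intersect(qc$mito_genes, rownames(counts))
  diss <- intersect(qc$dissoc_genes, rownames(counts))
  detected <- .colsums(counts > 0)
  total <- .colsums(counts)
  frac <- function(gset) {
    if (!length(gset)) return(rep(0, ncol(counts)))
    .colsums(counts[gset, , drop = FALSE]) / pmax(total, 1)
  }
  keep <- detected >= qc$min_genes & detected <= qc$max_genes &
    frac(mito) < qc$max_mito_frac & frac(diss) < qc$max_dissoc_frac
  if (!any(keep)) .fail("filter_cells: no cell passes QC")
  stats::setNames(keep, colnames(counts))
}

#' Log-normalize counts to ln(1 + CP10K)
#'
#' `value = ln(1 + count * scale_factor / cell_total)`: zeros map to zero and
#' the transform is monotone within each cell.
#'
#' @param counts genes x cells raw counts (sparse allowed).
#' @param scale_factor library-size target (default 10,000).
#' @return normalized matrix of the same class and dimnames.
#' @export
lognormalize <- function(counts, scale_factor = 1e4) {
  total <- .colsums(counts)
  if (any(total == 0))
    .fail("lognormalize: zero-total cell(s): ",
          paste(colnames(counts)[total == 0], collapse = ", "))
  if (inherits(counts, "sparseMatrix")) {
    x <- methods::as(counts, "CsparseMatrix")
    percol <- rep.int(total, diff(x@p))
    x@x <- log1p(x@x * scale_factor / percol)
    x
  } else {
    log1p(sweep(as.matrix(counts), 2, total, `/`) * scale_factor)
  }
}

#' Select highly variable genes against a mean-variance trend
#'
#' Per-gene means and variances of the normalized matrix are computed, a
#' degree-2 polynomial of log variance on log mean is fit over genes with
#' nonzero variance, and genes are ranked by their residual (variance
#' standardized against the trend). The top `n` genes are returned; ties are
#' broken by gene id lexicographic order, so selection is deterministic.
#'
#' @param norm normalized genes x cells matrix.
#' @param n number of genes to select (default 2000).
#' @return character vector of gene ids, highest residual first.
#' @export
select_hvgs <- function(norm, n = 2000L) {
  m <- .rowmeans(norm)
  v <- .rowvars(norm)
  eligible <- which(v > 0 & m > 0)
  if (length(eligible) < n) {
    warning("select_hvgs: only ", length(eligible),
            " genes with nonzero variance; returning all")
    n <- length(eligible)
  }
  lm_fit <- stats::lm(lv ~ stats::poly(lmn, 2),
                      data = data.frame(lv = log(v[eligible]),
                                        lmn = log(m[eligible])))
  resid <- log(v[eligible]) - stats::fitted(lm_fit)
  ids <- rownames(norm)[eligible]
  ord <- order(-resid, ids)
  ids[ord][seq_len(n)]
}

#' Embed cells and cluster on a shared-nearest-neighbor graph
#'
#' The standard graph-clustering pipeline: scale and center the selected
#' genes (standardized values clipped at +/-10), PCA to `n_pcs` components,
#' k-nearest-neighbor graph (k = 20, Euclidean in PC space), shared
#' nearest-neighbor reweighting by the Jaccard index of neighbor sets
#' (weights below `prune` set to zero), then modularity community detection
#' (Leiden) at the given resolution under a fixed seed. Cluster labels are
#' contiguous integers ordered by decreasing cluster size.
#'
#' @param norm normalized genes x cells matrix.
#' @param hvgs genes to use (from [select_hvgs()]).
#' @param n_pcs number of principal components (default 25).
#' @param resolution modularity resolution parameter.
#' @param k neighbors for the kNN graph (default 20).
#' @param prune SNN weight pruning threshold (default 1/15).
#' @param seed seed for the community detection.
#' @return list of class `cluster_result`: `clusters` (named integer),
#'   `pcs` (cells x n_pcs), `snn` (sparse adjacency).
#' @export
embed_and_cluster <- function(norm, hvgs, n_pcs = 25L, resolution = 0.8,
                              k = 20L, prune = 1 / 15, seed = 0L) {
  hvgs <- intersect(hvgs, rownames(norm))
  x <- .dense(norm[hvgs, , drop = FALSE])
  n_cells <- ncol(x)
  if (n_pcs >= min(n_cells, length(hvgs)))
    .fail("embed_and_cluster: n_pcs must be < min(n cells, n genes)")
  mu <- rowMeans(x)
  sdv <- sqrt(.rowvars(x))
  sdv[sdv == 0] <- 1
  x <- pmin(pmax((x - mu) / sdv, -10), 10)
  pcs <- stats::prcomp(t(x), center = FALSE, scale. = FALSE,
                       rank. = n_pcs)$x[, seq_len(n_pcs), drop = FALSE]
  rownames(pcs) <- colnames(norm)

  nb <- .knn_indices(pcs, k)
  snn <- .snn_graph(nb, n_cells, prune)
  g <- igraph::graph_from_adjacency_matrix(snn, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  set.seed(seed)
  comm <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution, n_iterations = 10)
  raw <- igraph::membership(comm)
  sizes <- sort(table(raw), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  clusters <- stats::setNames(as.integer(relabel[as.character(raw)]),
                              colnames(norm))
  structure(list(clusters = clusters, pcs = pcs, snn = snn),
            class = "cluster_result")
}

# internal: k nearest neighbor indices (self excluded), brute-force Euclidean
.knn_indices <- function(emb, k) {
  n <- nrow(emb)
  if (k >= n) .fail("k must be < number of cells")
  d2 <- as.matrix(stats::dist(emb))^2
  diag(d2) <- Inf
  t(apply(d2, 1, function(r) order(r)[seq_len(k)]))
}

# internal: SNN adjacency with Jaccard weights over (self + kNN) sets
.snn_graph <- function(nb, n, prune) {
  k <- ncol(nb)
  i <- rep(seq_len(n), each = k + 1L)
  j <- as.integer(t(cbind(seq_len(n), nb)))
  m <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(m)
  # |A union B| = 2(k+1) - |A intersect B|
  snn <- shared
  snn@x <- snn@x / (2 * (k + 1L) - snn@x)
  snn@x[snn@x < prune] <- 0
  Matrix::drop0(snn)
}

#' Flag clusters co-expressing incompatible markers (putative doublets)
#'
#' A cluster is flagged when, for any marker pair, both genes are detected
#' (value > 0) in more than half of the cluster's cells — the signature of a
#' mixed-lineage (doublet) cluster, e.g. KRT14 with CD3E.
#'
#' @param norm normalized (or raw) genes x cells matrix; only the zero
#'   pattern is used.
#' @param clusters named cluster labels per cell.
#' @param incompatible_pairs list of length-2 gene id vectors.
#' @return named logical per cluster.
#' @export
flag_doublet_clusters <- function(norm, clusters, incompatible_pairs) {
  cl <- sort(unique(clusters))
  flags <- stats::setNames(rep(FALSE, length(cl)), cl)
  for (pair in incompatible_pairs) {
    if (!all(pair %in% rownames(norm))) next
    both <- (norm[pair[1], ] > 0) & (norm[pair[2], ] > 0)
    frac <- tapply(both[names(clusters)], clusters, mean)
    flags[names(frac)] <- flags[names(frac)] | (frac > 0.5)
  }
  flags
}

#' Annotate clusters by canonical marker expression
#'
#' Each cluster is assigned the cell type whose marker set has the highest
#' mean expression over the cluster's cells; exact ties go to the
#' alphabetically first type with a warning.
#'
#' @param norm normalized genes x cells matrix.
#' @param clusters named cluster labels per cell.
#' @param marker_map named list: cell type -> marker gene ids.
#' @return named character, cluster -> cell type.
#' @export
annotate_clusters <- function(norm, clusters, marker_map) {
  marker_map <- lapply(marker_map, intersect, y = rownames(norm))
  if (any(lengths(marker_map) == 0))
    .fail("annotate_clusters: cell type(s) without any marker in the matrix: ",
          paste(names(marker_map)[lengths(marker_map) == 0], collapse = ", "))
  cl <- sort(unique(clusters))
  types <- sort(names(marker_map))
  score <- sapply(types, function(tp) {
    ms <- .colmeans(norm[marker_map[[tp]], names(clusters), drop = FALSE])
    tapply(ms, clusters, mean)
  })
  score <- matrix(score, nrow = length(cl), dimnames = list(cl, types))
  ties <- FALSE
  out <- apply(score, 1, function(r) {
    best <- which(r == max(r))
    if (length(best) > 1) ties <<- TRUE
    types[best[1]]
  })
  if (ties) warning("annotate_clusters: tie(s) broken alphabetically")
  stats::setNames(out, cl)
}

#' Wilcoxon rank-sum differential expression between two cell groups
#'
#' Per gene, the two-sided rank-sum p-value from the normal approximation
#' with tie correction (no continuity correction), and a fold-change
#' estimate `log2((mean expm1 A + 1e-9) / (mean expm1 B + 1e-9))` computed
#' on back-transformed normalized values. P-values are BH-adjusted.
#'
#' @param norm normalized genes x cells matrix.
#' @param cells_a,cells_b disjoint, nonempty cell id vectors.
#' @param pseudocount fold-change pseudocount (default 1e-9).
#' @param adjust multiple-testing method for [stats::p.adjust()] (default
#'   `"BH"`).
#' @return data.frame with `gene`, `log2fc`, `p_value`, `p_adjusted`,
#'   `mean_a`, `mean_b`.
#' @export
rank_sum_deg <- function(norm, cells_a, cells_b, pseudocount = 1e-9,
                         adjust = "BH") {
  if (!length(cells_a) || !length(cells_b))
    .fail("rank_sum_deg: both groups must be nonempty")
  if (length(intersect(cells_a, cells_b)))
    .fail("rank_sum_deg: groups overlap")
  x <- .dense(norm[, c(cells_a, cells_b), drop = FALSE])
  na <- length(cells_a); nb <- length(cells_b); n <- na + nb
  stat <- apply(x, 1, function(v) {
    r <- rank(v)
    ties <- table(r)
    w <- sum(r[seq_len(na)]) - na * (na + 1) / 2
    sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    c(w = w, sigma2 = sigma2)
  })
  w <- stat["w", ]; sigma2 <- stat["sigma2", ]
  z <- (w - na * nb / 2) / sqrt(sigma2)
  p <- ifelse(sigma2 == 0, 1, 2 * stats::pnorm(-abs(z)))
  ma <- .rowmeans(expm1(norm[, cells_a, drop = FALSE]))
  mb <- .rowmeans(expm1(norm[, cells_b, drop = FALSE]))
  lfc <- log2((ma + pseudocount) / (mb + pseudocount))
  lfc[ma == 0 & mb == 0] <- 0
  data.frame(gene = rownames(norm), log2fc = lfc, p_value = p,
             p_adjusted = pmax(stats::p.adjust(p, adjust), p),
             mean_a = ma, mean_b = mb,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Signature module score with bin-matched control genes
#'
#' The per-cell enrichment of a gene signature: all genes are placed into
#' `n_bins` equal-frequency bins by their mean expression across cells; for
#' each signature gene, `n_ctrl` control genes are sampled with replacement
#' from its bin under the given seed; the score of a cell is the mean
#' expression of the signature genes minus the mean expression over all
#' sampled control genes. Deterministic given the seed.
#'
#' @param norm normalized genes x cells matrix.
#' @param signature gene id list; ids missing from the matrix are dropped
#'   with a warning.
#' @param signature_name label stored in the result.
#' @param n_bins expression bins (default 24).
#' @param n_ctrl control genes per signature gene (default 100).
#' @param seed sampling seed.
#' @return list of class `module_score`: `scores` (named per-cell),
#'   `signature_name`, `n_bins`, `n_ctrl`, `seed`, `used_genes`.
#' @export
module_score <- function(norm, signature, signature_name = "signature",
                         n_bins = 24L, n_ctrl = 100L, seed = 1L) {
  present <- intersect(signature, rownames(norm))
  if (!length(present)) .fail("module_score: no signature gene in the matrix")
  if (length(present) < length(signature))
    warning("module_score: dropping ", length(signature) - length(present),
            " signature gene(s) absent from the matrix")
  m <- .rowmeans(norm)
  ord <- order(m, rownames(norm))
  bin <- integer(length(m))
  bin[ord] <- ceiling(seq_along(m) / (length(m) / n_bins))
  names(bin) <- rownames(norm)
  by_bin <- split(rownames(norm), bin)

  set.seed(seed)
  ctrl <- unlist(lapply(present, function(g) {
    pool <- by_bin[[as.character(bin[g])]]
    pool[sample.int(length(pool), n_ctrl, replace = TRUE)]
  }), use.names = FALSE)
  sig_mean <- .colmeans(norm[present, , drop = FALSE])
  ctrl_mean <- .colmeans(norm[ctrl, , drop = FALSE])
  structure(list(scores = stats::setNames(as.numeric(sig_mean - ctrl_mean),
                                          colnames(norm)),
                 signature_name = signature_name, n_bins = n_bins,
                 n_ctrl = n_ctrl, seed = seed, used_genes = present),
            class = "module_score")
}

#' @export
print.module_score <- function(x, ...) {
  cat("module_score '", x$signature_name, "': ", length(x$scores),
      " cells, ", length(x$used_genes), " genes\n", sep = "")
  invisible(x)
}

#' Local inverse Simpson's index of sample mixing
#'
#' For each cell, the label proportions `p_s` among its `k` nearest
#' neighbors (Euclidean in the embedding) give `LISI = 1 / sum(p_s^2)`:
#' the effective number of samples in the neighborhood, between 1 and the
#' number of labels.
#'
#' @param embedding cells x dims matrix.
#' @param sample_labels per-cell labels (same order as rows).
#' @param k neighborhood size (default 30), must be < number of cells.
#' @return named numeric per cell, >= 1.
#' @export
lisi_score <- function(embedding, sample_labels, k = 30L) {
  n <- nrow(embedding)
  if (k >= n) .fail("lisi_score: k must be < number of cells")
  nb <- .knn_indices(embedding, k)
  out <- apply(nb, 1, function(idx) {
    p <- table(sample_labels[idx]) / k
    1 / sum(p^2)
  })
  stats::setNames(out, rownames(embedding))
}
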