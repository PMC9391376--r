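#' Pseudotime along a minimum spanning tree of cluster centroids
#'
#' A deterministic trajectory: the minimum spanning tree over cluster
#' centroids in PC space (Euclidean) is the backbone; each cell is projected
#' onto its nearest tree edge, and its pseudotime is the geodesic distance
#' along the tree from the root centroid to the projection point. With a
#' single cluster the trajectory degenerates to distance from the centroid
#' (with a warning).
#'
#' @param pcs cells x dims embedding (e.g. from [embed_and_cluster()]).
#' @param clusters named cluster labels covering the rows of `pcs`.
#' @param root_cluster label of the root cluster.
#' @return list of class `trajectory_result`: `pseudotime` (named, >= 0),
#'   `tree` (edge data.frame `from`, `to`, `length`), `root_cluster`.
#' @export
compute_pseudotime <- function(pcs, clusters, root_cluster) {
  clusters <- clusters[rownames(pcs)]
  cl <- sort(unique(as.character(clusters)))
  if (!(as.character(root_cluster) %in% cl))
    .fail("compute_pseudotime: root cluster not present")
  centroids <- t(sapply(cl, function(cc)
    colMeans(pcs[clusters == cc, , drop = FALSE])))
  if (length(cl) == 1) {
    warning("compute_pseudotime: single cluster; pseudotime = distance to centroid")
    pt <- sqrt(rowSums(sweep(pcs, 2, centroids[1, ])^2))
    return(structure(list(pseudotime = stats::setNames(pt, rownames(pcs)),
                          tree = data.frame(from = character(), to = character(),
                                            length = numeric()),
                          root_cluster = root_cluster),
                     class = "trajectory_result"))
  }
  d <- as.matrix(stats::dist(centroids))
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE)
  mst <- igraph::mst(g)
  edges <- igraph::as_data_frame(mst, what = "edges")
  root_dist <- igraph::distances(mst, v = as.character(root_cluster))[1, ]

  best_pt <- rep(Inf, nrow(pcs))
  best_d2 <- rep(Inf, nrow(pcs))
  for (e in seq_len(nrow(edges))) {
    u <- edges$from[e]; v <- edges$to[e]
    a <- centroids[u, ]; b <- centroids[v, ]
    ab <- b - a
    len2 <- sum(ab^2)
    tpar <- pmin(pmax(as.vector(sweep(pcs, 2, a) %*% ab) / len2, 0), 1)
    proj_d2 <- rowSums((sweep(pcs, 2, a) - outer(tpar, ab))^2)
    L <- sqrt(len2)
    pt <- pmin(root_dist[u] + tpar * L, root_dist[v] + (1 - tpar) * L)
    upd <- proj_d2 < best_d2
    best_d2[upd] <- proj_d2[upd]
    best_pt[upd] <- pt[upd]
  }
  structure(list(pseudotime = stats::setNames(best_pt, rownames(pcs)),
                 tree = data.frame(from = edges$from, to = edges$to,
                                   length = edges$weight,
                                   stringsAsFactors = FALSE),
                 root_cluster = root_cluster),
            class = "trajectory_result")
}

#' @export
print.trajectory_result <- function(x, ...) {
  cat("trajectory_result:", length(x$pseudotime), "cells, root",
      x$root_cluster, ",", nrow(x$tree), "tree edges\n")
  invisible(x)
}

#' Symmetrized binary k-nearest-neighbor graph
#'
#' Cell neighborhood graph in embedding space used for the Moran's I
#' autocorrelation screen: binary weights, symmetrized by union.
#'
#' @param emb cells x dims matrix.
#' @param k neighbors (default 20).
#' @return sparse symmetric adjacency with zero diagonal.
#' @export
knn_graph <- function(emb, k = 20L) {
  n <- nrow(emb)
  nb <- .knn_indices(emb, k)
  m <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k),
                            j = as.integer(t(nb)), x = 1, dims = c(n, n),
                            dimnames = list(rownames(emb), rownames(emb)))
  m <- (m + Matrix::t(m))
  m@x[] <- 1
  m
}

#' Moran's I graph autocorrelation
#'
#' `I = (n / W) * sum_ij w_ij z_i z_j / sum_i z_i^2` with `z = x - mean(x)`
#' and `W` the total off-diagonal weight. The p-value uses the normal
#' approximation under the randomization assumption (two-sided).
#'
#' @param x per-cell values (constant input is an error).
#' @param graph symmetric nonnegative weight matrix (diagonal ignored).
#' @return list with `I`, `expected`, `sd`, `p`.
#' @export
morans_i <- function(x, graph) {
  res <- morans_i_table(matrix(x, nrow = 1,
                               dimnames = list("x", names(x))), graph)
  list(I = res$morans_i, expected = attr(res, "expected"),
       sd = res$sd, p = res$p_value)
}

#' Moran's I for many genes on one graph
#'
#' Vectorized Moran's I over the rows of a genes x cells matrix, with
#' randomization-assumption normal p-values and BH q-values. Constant rows
#' are returned with `NA` statistics (a single constant input to
#' [morans_i()] is an error).
#'
#' @param mat genes x cells matrix.
#' @param graph symmetric nonnegative weight matrix over the cells.
#' @return data.frame (class `autocorrelation_table`): `gene`, `morans_i`,
#'   `sd`, `p_value`, `q_value`.
#' @export
morans_i_table <- function(mat, graph) {
  w <- Matrix::Matrix(graph, sparse = TRUE)
  w <- methods::as(methods::as(w, "generalMatrix"), "CsparseMatrix")
  Matrix::diag(w) <- 0
  w <- Matrix::drop0(w)
  n <- ncol(mat)
  if (n < 3) .fail("morans_i: need >= 3 cells")
  if (nrow(w) != n) .fail("morans_i: graph does not match the cells")
  w0 <- sum(w)
  if (w0 <= 0) .fail("morans_i: zero total weight")

  z <- .dense(mat) - rowMeans(mat)
  m2 <- rowSums(z^2)
  if (any(m2 == 0) && nrow(mat) == 1)
    .fail("morans_i: constant input, autocorrelation undefined")
  num <- rowSums(as.matrix(z %*% w) * z)
  iobs <- (n / w0) * num / m2

  s1 <- sum((w + Matrix::t(w))^2) / 2
  rsum <- Matrix::rowSums(w); csum <- Matrix::colSums(w)
  s2 <- sum((rsum + csum)^2)
  ei <- -1 / (n - 1)
  b2 <- n * rowSums(z^4) / m2^2
  var_i <- (n * ((n^2 - 3 * n + 3) * s1 - n * s2 + 3 * w0^2) -
              b2 * ((n^2 - n) * s1 - 2 * n * s2 + 6 * w0^2)) /
    ((n - 1) * (n - 2) * (n - 3) * w0^2) - ei^2
  sdv <- sqrt(pmax(var_i, 0))
  p <- 2 * stats::pnorm(-abs(iobs - ei) / sdv)
  bad <- m2 == 0
  iobs[bad] <- NA; sdv[bad] <- NA; p[bad] <- NA
  out <- data.frame(gene = rownames(mat), morans_i = iobs, sd = sdv,
                    p_value = p,
                    q_value = stats::p.adjust(p, "BH"),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "expected") <- ei
  class(out) <- c("autocorrelation_table", "data.frame")
  out
}

#' Select trajectory-variable genes
#'
#' Genes whose Moran's I strictly exceeds the cutoff (default 0.1), ordered
#' by decreasing autocorrelation.
#'
#' @param tbl an `autocorrelation_table`.
#' @param cutoff strict lower bound on Moran's I (default 0.1).
#' @return character vector of gene ids.
#' @export
select_trajectory_genes <- function(tbl, cutoff = 0.1) {
  keep <- !is.na(tbl$morans_i) & tbl$morans_i > cutoff
  tbl$gene[keep][order(-tbl$morans_i[keep])]
}

#' Overlap trajectory genes with known CAF activators
#'
#' Intersection of the (autocorrelation-ordered) trajectory gene list with a
#' list of secreted cancer-associated-fibroblast activators, preserving the
#' trajectory ordering. A default activator list covering the TGF-beta
#' superfamily, PDGFs, EGF family, FGFs and hedgehog ligands ships with the
#' package ([default_caf_activators()]).
#'
#' @param traj_genes ordered gene list from [select_trajectory_genes()].
#' @param activators activator gene list.
#' @return character vector, activators in trajectory order.
#' @export
overlap_with_activators <- function(traj_genes, activators) {
  traj_genes[traj_genes %in% activators]
}

#' Default secreted CAF-activator gene list
#'
#' @return character vector of gene symbols read from the shipped list.
#' @export
default_caf_activators <- function() {
  read_gene_list(system.file("extdata", "caf_activators.txt",
                             package = "spatialniche"))
}
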