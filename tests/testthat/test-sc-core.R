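test_that("cell QC applies the detected-gene window and fraction cuts", {
  ng <- 2000L
  counts <- Matrix::Matrix(0, ng, 5, sparse = TRUE,
                           dimnames = list(sprintf("g%04d", 1:ng),
                                           paste0("c", 1:5)))
  counts[1:400, 1] <- 1          # 400 detected -> removed
  counts[1:500, 2] <- 1          # 500 detected, 0% mito -> retained (boundary)
  counts[1:800, 3] <- 1          # healthy
  counts[1:800, 4] <- 1          # will get 25% mito reads -> removed
  counts["g0001", 4] <- 267      # 267/(267+799) ~ 25%
  counts[, 5] <- 1               # all 2000 genes detected, inside the window
  qc <- qc_params(mito_genes = "g0001", dissoc_genes = "g0002")
  keep <- filter_cells(counts, qc)
  expect_false(keep[["c1"]])
  expect_true(keep[["c2"]])
  expect_true(keep[["c3"]])
  expect_false(keep[["c4"]])
  # a cell over the max_genes bound is removed
  big <- Matrix::Matrix(1, 7000, 2, sparse = TRUE,
                        dimnames = list(sprintf("h%04d", 1:7000), c("a", "b")))
  big[5001:7000, 2] <- 0
  keep2 <- filter_cells(big, qc_params())
  expect_false(keep2[["a"]])   # 7000 detected > 6000
  expect_true(keep2[["b"]])    # 5000 detected
  expect_error(filter_cells(big[, 1, drop = FALSE], qc_params()),
               "no cell passes")
  expect_warning(filter_cells(counts, qc_params(mito_genes = "absent")),
                 "absent")
})

test_that("lognormalize matches ln(1 + count * sf / total) and preserves structure", {
  m <- matrix(c(10, 9990, 0, 5), 2, 2,
              dimnames = list(c("g1", "g2"), c("c1", "c2")))
  n <- lognormalize(m)
  expect_equal(n["g1", "c1"], log(11))          # total 10000, count 10
  expect_equal(n["g1", "c2"], 0)                # zero maps to zero
  n2 <- lognormalize(m, scale_factor = 2e4)
  expect_true(all(n2[m > 0] > n[m > 0]))        # monotone in scale factor
  # sparse path agrees with dense path
  sp <- lognormalize(Matrix::Matrix(m, sparse = TRUE))
  expect_equal(as.matrix(sp), n)
  # zero pattern and within-cell rank order preserved
  set.seed(1)
  r <- matrix(rpois(600, 2), 30, 20,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("c%02d", 1:20)))
  r[1, ] <- pmax(r[1, ], 1)
  nr <- lognormalize(r)
  expect_identical(nr == 0, r == 0)
  for (j in 1:20) expect_equal(order(nr[, j]), order(r[, j]))
  r0 <- r; r0[, 3] <- 0
  expect_error(lognormalize(r0), "c03")
})

test_that("variable-gene selection ranks excess variance above the trend", {
  set.seed(8)
  ng <- 300; nc <- 200
  m <- matrix(rnorm(ng * nc, mean = 5, sd = 1), ng, nc,
              dimnames = list(sprintf("g%03d", 1:ng), sprintf("c%03d", 1:nc)))
  m["g150", ] <- rnorm(nc, mean = 5, sd = sqrt(10))   # inflated variance
  hv <- select_hvgs(m, 10)
  expect_equal(hv[1], "g150")
  expect_setequal(select_hvgs(m, ng), rownames(m))    # n = all genes
  # deterministic under identical input
  expect_identical(select_hvgs(m, 50), select_hvgs(m, 50))
})

test_that("clustering recovers two well-separated blobs exactly", {
  set.seed(5)
  ng <- 60; nc <- 120
  truth <- rep(c(1, 2), each = nc / 2)
  m <- matrix(rnorm(ng * nc, 3, 0.2), ng, nc,
              dimnames = list(sprintf("g%02d", 1:ng), sprintf("c%03d", 1:nc)))
  m[1:30, truth == 2] <- m[1:30, truth == 2] + 5
  cl <- embed_and_cluster(m, rownames(m), n_pcs = 10, resolution = 0.8,
                          seed = 1)
  expect_equal(length(unique(cl$clusters)), 2L)
  expect_equal(adjusted_rand(cl$clusters, truth), 1)
  if (requireNamespace("mclust", quietly = TRUE))
    expect_equal(mclust::adjustedRandIndex(cl$clusters, truth), 1)
  # resolution -> 0 collapses a connected graph to one community (the two
  # blobs above are so separated that their SNN graph is disconnected)
  set.seed(6)
  cloud <- matrix(rnorm(40 * 100, 3, 1), 40, 100,
                  dimnames = list(sprintf("f%02d", 1:40), sprintf("d%03d", 1:100)))
  cl0 <- embed_and_cluster(cloud, rownames(cloud), n_pcs = 10,
                           resolution = 1e-4, seed = 1)
  expect_equal(length(unique(cl0$clusters)), 1L)
  expect_error(embed_and_cluster(m, rownames(m), n_pcs = 100, resolution = 1),
               "n_pcs")
})

test_that("doublet clusters are flagged on marker co-detection", {
  ng <- 10; nc <- 60
  m <- matrix(0, ng, nc, dimnames = list(c("KRT14", "CD3E", sprintf("g%d", 1:8)),
                                         sprintf("c%02d", 1:nc)))
  clusters <- stats::setNames(rep(1:3, each = 20), colnames(m))
  m["KRT14", clusters == 1] <- 5                  # epithelial only
  m["CD3E", clusters == 2] <- 5                   # T only
  m["KRT14", clusters == 3] <- 5                  # doublet-like
  m["CD3E", which(clusters == 3)[1:18]] <- 5      # 90% co-detection
  fl <- flag_doublet_clusters(m, clusters, list(c("KRT14", "CD3E")))
  expect_equal(unname(fl), c(FALSE, FALSE, TRUE))
  expect_false(any(flag_doublet_clusters(m, clusters, list())))
})

test_that("cluster annotation picks the top marker set and warns on ties", {
  ng <- 6; nc <- 40
  m <- matrix(0, ng, nc,
              dimnames = list(c("a1", "a2", "b1", "b2", "x1", "x2"),
                              sprintf("c%02d", 1:nc)))
  clusters <- stats::setNames(rep(1:2, each = 20), colnames(m))
  m[c("a1", "a2"), clusters == 1] <- 4
  m[c("b1", "b2"), clusters == 2] <- 4
  map <- list(typeA = c("a1", "a2"), typeB = c("b1", "b2"))
  expect_equal(annotate_clusters(m, clusters, map),
               c(`1` = "typeA", `2` = "typeB"))
  zero <- m * 0
  expect_warning(ann0 <- annotate_clusters(zero, clusters, map), "tie")
  expect_equal(unname(ann0), c("typeA", "typeA"))
  expect_equal(annotate_clusters(m[, 1:20], clusters[1:20],
                                 list(typeA = c("a1", "a2"))),
               c(`1` = "typeA"))
})

test_that("rank-sum DEG matches wilcox.test and behaves at the null", {
  norm <- random_norm(50, 60, seed = 2)
  a <- colnames(norm)[1:30]; b <- colnames(norm)[31:60]
  deg <- rank_sum_deg(norm, a, b)
  for (g in rownames(norm)[c(1, 17, 42)]) {
    ref <- stats::wilcox.test(as.numeric(norm[g, a]), as.numeric(norm[g, b]),
                              exact = FALSE, correct = FALSE)
    expect_equal(deg$p_value[deg$gene == g], ref$p.value, tolerance = 1e-12)
  }
  # all-zero gene
  nz <- as.matrix(norm); nz[1, ] <- 0
  deg0 <- rank_sum_deg(nz, a, b)
  expect_equal(deg0$log2fc[1], 0)
  expect_equal(deg0$p_value[1], 1)
  # antisymmetry
  rev <- rank_sum_deg(norm, b, a)
  expect_equal(rev$log2fc, -deg$log2fc, tolerance = 1e-9)
  expect_equal(rev$p_value, deg$p_value, tolerance = 1e-12)
  expect_true(all(deg$p_adjusted >= deg$p_value - 1e-15))
  expect_error(rank_sum_deg(norm, a, c(b, a[1])), "overlap")
  expect_error(rank_sum_deg(norm, character(), b), "nonempty")
})

test_that("rank-sum DEG null calibration and power are nominal", {
  set.seed(77)
  ng <- 2000; na <- 100; nb <- 100
  m <- matrix(rpois(ng * (na + nb), 4), ng, na + nb,
              dimnames = list(sprintf("g%04d", 1:ng),
                              sprintf("c%03d", 1:(na + nb))))
  norm <- lognormalize(m)
  cells <- colnames(norm)
  deg <- rank_sum_deg(norm, cells[1:na], cells[na + 1:nb])
  frac <- mean(deg$p_value < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
  # planted 4x shift in 50 genes, 200 cells per group
  set.seed(78)
  m2 <- matrix(rpois(1000 * 400, 3), 1000, 400,
               dimnames = list(sprintf("g%04d", 1:1000),
                               sprintf("c%03d", 1:400)))
  m2[1:50, 1:200] <- rpois(50 * 200, 12)
  norm2 <- lognormalize(m2)
  deg2 <- rank_sum_deg(norm2, colnames(m2)[1:200], colnames(m2)[201:400])
  expect_gte(mean(deg2$p_adjusted[1:50] < 0.01), 0.95)
})

test_that("module score matches a brute-force oracle and self-subtracts", {
  norm <- as.matrix(random_norm(40, 12, seed = 6))
  sig <- c("g005", "g011", "g030")
  res <- module_score(norm, sig, n_bins = 4, n_ctrl = 7, seed = 42)
  # independent recomputation of the same formula
  m <- rowMeans(norm)
  ord <- order(m, rownames(norm))
  bin <- integer(length(m)); bin[ord] <- ceiling(seq_along(m) / (length(m) / 4))
  names(bin) <- rownames(norm)
  set.seed(42)
  ctrl <- character()
  for (g in sig) {
    pool <- rownames(norm)[bin == bin[g]]
    ctrl <- c(ctrl, pool[sample.int(length(pool), 7, replace = TRUE)])
  }
  brute <- colMeans(norm[sig, ]) - colMeans(norm[ctrl, ])
  expect_equal(res$scores, brute, tolerance = 1e-12)
  # one gene per bin: control = the gene itself, score exactly zero
  res1 <- module_score(norm, "g005", n_bins = 40, n_ctrl = 5, seed = 1)
  expect_true(all(res1$scores == 0))
  # signature = whole universe: controls drawn from the same bins, score ~ 0
  resU <- module_score(norm, rownames(norm), n_bins = 4, n_ctrl = 200, seed = 2)
  expect_lt(max(abs(resU$scores)), 0.15)
  expect_warning(module_score(norm, c(sig, "missing")), "absent")
  expect_error(module_score(norm, "missing"), "no signature gene")
})

test_that("LISI equals the inverse Simpson index of neighbor labels", {
  set.seed(4)
  emb <- matrix(rnorm(200), 100, 2,
                dimnames = list(sprintf("c%03d", 1:100), NULL))
  # one isolated same-label island far away
  emb[1:10, ] <- emb[1:10, ] + 100
  labels <- c(rep("s1", 10), rep(c("s1", "s2", "s3"), 30))
  li <- lisi_score(emb, labels, k = 9)
  expect_equal(unname(li[1:10]), rep(1, 10))      # pure neighborhood
  expect_true(all(li >= 1 & li <= 3 + 1e-9))
  # brute-force check on one cell
  d <- as.matrix(dist(emb)); diag(d) <- Inf
  nb <- order(d[50, ])[1:9]
  p <- table(labels[nb]) / 9
  expect_equal(unname(li[50]), unname(1 / sum(p^2)), tolerance = 1e-12)
  # two perfectly interleaved samples on a line, k even
  line <- matrix(seq_len(40), ncol = 1,
                 dimnames = list(sprintf("c%02d", 1:40), NULL))
  li2 <- lisi_score(line, rep(c("a", "b"), 20), k = 4)
  expect_equal(unname(li2[20]), 2)   # neighbors 18,19,21,22: two of each label
  expect_error(lisi_score(line, rep("a", 40), k = 40), "k must be")
})
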