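test_that("AOI depth QC drops below 10,000 reads, boundary inclusive", {
  cnt <- matrix(5, 3, 4)
  tab <- toy_probe_table(cnt, targets = rep(c("gA", "gB"), each = 2),
                         total_reads = c(9999, 10000, 20000))
  expect_message(kept <- aoi_qc(tab), "A01")
  expect_equal(rownames(kept$counts), c("A02", "A03"))
  expect_error(aoi_qc(tab, min_reads = 1e6), "all AOIs below")
})

test_that("Grubbs flagging matches the closed-form critical value", {
  # probes with log2 values (3,3,3,10): counts 2^v - 1
  cnt <- matrix(rep(2^c(3, 3, 3, 10) - 1, each = 2), 2, 4, byrow = FALSE)
  tab <- toy_probe_table(cnt, targets = rep("gA", 4))
  fl <- flag_outlier_probes(tab, alpha = 0.01)
  # independent computation of G and the critical value from t quantiles
  x <- c(3, 3, 3, 10)
  g_stat <- max(abs(x - mean(x))) / sd(x)
  n <- 4
  tq <- qt(0.01 / (2 * n), n - 2, lower.tail = FALSE)
  crit <- (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2))
  expect_equal(grubbs_critical(4, 0.01), crit, tolerance = 1e-12)
  expect_identical(unname(fl$local[1, 4]), g_stat > crit)
  # zero-variance probe sets are never flagged
  flat <- toy_probe_table(matrix(8, 2, 4), targets = rep("gA", 4))
  expect_false(any(flag_outlier_probes(flat)$local))
  # 1-2 probe targets pass untested
  two <- toy_probe_table(matrix(c(1, 1000, 1, 1000), 2, 2),
                         targets = rep("gA", 2))
  expect_false(any(flag_outlier_probes(two)$local))
})

test_that("a persistent aberrant probe is globally excluded", {
  set.seed(31)
  n_aoi <- 50
  cnt <- matrix(rpois(n_aoi * 5, 100), n_aoi, 5)
  cnt[, 5] <- rpois(n_aoi, 800)   # planted 8x probe
  tab <- toy_probe_table(cnt, targets = rep("gA", 5))
  fl <- flag_outlier_probes(tab, alpha = 0.01, global_fraction = 0.20)
  expect_identical(fl$global, "p5")
  expect_gte(mean(fl$local[, "p5"]), 0.95)
})

test_that("probe collapse is an exact geometric mean with flag exclusion", {
  cnt <- matrix(c(4, 9, 1000), 1, 3)
  tab <- toy_probe_table(cnt, targets = rep("gA", 3))
  # no flags: geomean(4, 9, 1000)
  expect_equal(unname(collapse_probes(tab)[1, 1]), (4 * 9 * 1000)^(1 / 3),
               tolerance = 1e-9)
  # with p3 excluded: exactly 6
  fl <- list(global = "p3")
  expect_equal(unname(collapse_probes(tab, fl)[1, 1]), 6, tolerance = 1e-9)
  tab8 <- toy_probe_table(matrix(c(8, 8, 8), 1, 3), targets = rep("gA", 3))
  expect_equal(unname(collapse_probes(tab8)[1, 1]), 8, tolerance = 1e-9)
  # permutation invariance and scale equivariance
  set.seed(2)
  v <- rpois(6, 20) + 1
  t1 <- toy_probe_table(matrix(v, 1), targets = rep("gA", 6))
  t2 <- toy_probe_table(matrix(rev(v), 1), targets = rep("gA", 6))
  expect_equal(collapse_probes(t1)[1, 1], collapse_probes(t2)[1, 1])
  t3 <- toy_probe_table(matrix(3 * v, 1), targets = rep("gA", 6))
  expect_equal(unname(collapse_probes(t3)[1, 1]),
               3 * unname(collapse_probes(t1)[1, 1]), tolerance = 1e-9)
  # a gene with every probe excluded is dropped with a warning
  expect_warning(out <- collapse_probes(t1, list(global = paste0("p", 1:6))),
                 "no unflagged probe")
  expect_equal(nrow(out), 0)
})

test_that("negative-probe factors are per-pool geometric means", {
  cnt <- matrix(100, 2, 2)
  tab <- toy_probe_table(cnt, targets = rep("gA", 2), n_neg = 2, neg_value = 0)
  tab$counts[, c("n1", "n2")] <- matrix(rep(c(10, 40), each = 2), 2)
  expect_equal(unname(negative_probe_factors(tab)[, "P1"]), c(20, 20))
  tab1 <- toy_probe_table(cnt, targets = rep("gA", 2), n_neg = 1, neg_value = 7)
  expect_equal(unname(negative_probe_factors(tab1)[1, "P1"]), 7)
  tab0 <- toy_probe_table(cnt, targets = rep("gA", 2), n_neg = 2, neg_value = 0)
  expect_message(f0 <- negative_probe_factors(tab0), "floored")
  expect_equal(unname(f0[1, "P1"]), 0.5)
})

test_that("Q3 normalization equalizes the 75th percentile exactly", {
  set.seed(13)
  g <- matrix(rpois(200 * 6, 50) + 1, 200, 6,
              dimnames = list(sprintf("g%03d", 1:200), sprintf("A%02d", 1:6)))
  nrm <- q3_normalize(g)
  q_after <- apply(nrm$values, 2, quantile, probs = 0.75, names = FALSE)
  expect_lt(diff(range(q_after)), 1e-9)
  q_before <- apply(g, 2, quantile, probs = 0.75, names = FALSE)
  expect_equal(unname(q_after[1]), exp(mean(log(q_before))), tolerance = 1e-9)
  # identical AOIs: unit factors, identity transform
  same <- g[, c(1, 1, 1)]
  colnames(same) <- paste0("B", 1:3)
  nrm_same <- q3_normalize(same)
  expect_equal(unname(nrm_same$q3_factors), rep(1, 3))
  expect_equal(nrm_same$values, same)
  # the {100, 400} worked example
  two <- rbind(a = c(100, 400), b = c(100, 400), c = c(100, 400),
               d = c(100, 400))
  colnames(two) <- c("A1", "A2")
  n2 <- q3_normalize(two)
  expect_equal(unname(n2$q3_factors), c(0.5, 2.0))
  expect_equal(unname(apply(n2$values, 2, quantile, 0.75)), c(200, 200))
  bad <- cbind(g[, 1], 0)
  colnames(bad) <- c("ok", "zeroq")
  expect_error(q3_normalize(bad), "zeroq")
})

test_that("morphology DEG applies strict thresholds and is antisymmetric", {
  set.seed(41)
  ng <- 400
  vals <- matrix(rpois(ng * 12, 60), ng, 12,
                 dimnames = list(sprintf("g%03d", 1:ng), sprintf("A%02d", 1:12)))
  vals[1:10, 1:6] <- rpois(60, 240)      # planted up in infiltrative
  meta <- data.frame(aoi_id = colnames(vals), sample = "S",
                     compartment = "tumor",
                     morphology = rep(c("infiltrative", "nodular"), each = 6),
                     total_reads = colSums(vals))
  nrm <- structure(list(values = vals, q3_factors = rep(1, 12),
                        qc_flags = rep(FALSE, 12)), class = "normalized_aoi")
  deg <- dsp_deg(nrm, meta, "tumor")
  expect_true(all(deg$significant[1:10]))
  # strictness: a gene exactly at the fold-change cut is not significant
  fake <- deg
  expect_false(any(deg$significant[abs(deg$log2fc) <= 0.4]))
  # antisymmetry under morphology swap
  meta2 <- meta
  meta2$morphology <- rev(meta$morphology)
  deg2 <- dsp_deg(nrm, meta2, "tumor")
  expect_equal(deg2$log2fc, -deg$log2fc, tolerance = 1e-12)
  expect_equal(deg2$p_value, deg$p_value, tolerance = 1e-12)
  # group-size guard
  meta3 <- meta[c(1, 7:12), ]
  expect_error(dsp_deg(structure(list(values = vals[, meta3$aoi_id],
                                      q3_factors = rep(1, 7),
                                      qc_flags = rep(FALSE, 7)),
                                 class = "normalized_aoi"),
                       meta3, "tumor"), ">= 2 AOIs")
})

test_that("null morphology DEG keeps the significant fraction below alpha", {
  set.seed(43)
  ng <- 1800
  vals <- matrix(rpois(ng * 48, 80), ng, 48,
                 dimnames = list(sprintf("g%04d", 1:ng), sprintf("A%02d", 1:48)))
  meta <- data.frame(aoi_id = colnames(vals), sample = "S",
                     compartment = "tumor",
                     morphology = rep(c("infiltrative", "nodular"), each = 24),
                     total_reads = colSums(vals))
  nrm <- structure(list(values = vals, q3_factors = rep(1, 48),
                        qc_flags = rep(FALSE, 48)), class = "normalized_aoi")
  deg <- dsp_deg(nrm, meta, "tumor")
  # joint condition |lfc| > 0.4 AND p < 0.05 is rarer than alpha alone
  expect_lte(mean(deg$significant), 0.05)
  frac_p <- mean(deg$p_value < 0.05)
  expect_gt(frac_p, 0.03); expect_lt(frac_p, 0.07)
})

test_that("raw signatures partition significant genes by sign and report overlap", {
  mk <- function(genes, lfc, p) {
    data.frame(gene = genes, log2fc = lfc, p_value = p, p_adjusted = p,
               significant = abs(lfc) > 0.4 & p < 0.05)
  }
  deg_t <- mk(c("a", "b", "c", "d"), c(1, -1, 0.2, 0.8), c(0.01, 0.01, 0.01, 0.01))
  deg_s <- mk(c("a", "e", "f"), c(0.9, -0.7, 0.6), c(0.01, 0.01, 0.2))
  sig <- build_raw_signatures(deg_t, deg_s)
  expect_setequal(sig$t_inf, c("a", "d"))
  expect_equal(sig$t_nod, "b")
  expect_equal(sig$s_inf, "a")
  expect_equal(sig$s_nod, "e")
  expect_equal(sig$overlap$inf_shared, "a")
  expect_equal(length(sig$overlap$nod_shared), 0L)
  empty <- build_raw_signatures(mk(character(), numeric(), numeric()),
                                mk(character(), numeric(), numeric()))
  expect_equal(lengths(empty[c("t_nod", "t_inf", "s_nod", "s_inf")]),
               c(t_nod = 0L, t_inf = 0L, s_nod = 0L, s_inf = 0L))
})

test_that("planted DSP morphology DEGs are recovered with high sensitivity", {
  sim <- default_sim()
  cfg <- sim$truth$config
  dsp <- simulate_dsp_probes(cfg, sim)
  tab <- aoi_qc(dsp)
  fl <- flag_outlier_probes(tab)
  nrm <- q3_normalize(collapse_probes(tab, fl))
  deg_t <- dsp_deg(nrm, tab$aoi_meta, "tumor")
  sets <- sim$truth$program_gene_sets
  # sensitivity on the tumor compartment's own planted programs
  planted <- c(sets$inf, sets$nod)
  sens <- mean(deg_t$significant[deg_t$gene %in% planted])
  expect_gte(sens, 0.9)
  # false calls among genes with no planted AOI-level signal
  with_signal <- c(sets$inf, sets$nod, sets$ecm, sets$quiescent)
  null_genes <- setdiff(deg_t$gene, with_signal)
  called_null <- sum(deg_t$significant & deg_t$gene %in% null_genes)
  called_all <- sum(deg_t$significant)
  expect_lte(called_null / max(called_all, 1), 0.1)
})
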