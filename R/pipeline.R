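#' Pipeline configuration
#'
#' Assembles every stage parameter of the end-to-end analysis with the
#' package defaults. With `simulate = TRUE` the inputs are produced by the
#' synthetic generator under `sim`; otherwise `paths` must point to a
#' 10x-style scRNA directory, a DSP probe-table directory and a gene
#' position TSV, and `marker_map`, `qc_genes` must be supplied.
#'
#' @param outdir output directory.
#' @param seed master seed; per-stage seeds are derived as
#'   `seed + 1000 * stage_index`.
#' @param simulate generate inputs with [simulate_sc_counts()] /
#'   [simulate_dsp_probes()].
#' @param sim a [sim_config()] (its own seed is overridden by `seed`).
#' @param paths list `sc_dir`, `dsp_dir`, `positions` when
#'   `simulate = FALSE`.
#' @param qc_genes list with `mito` and `dissoc` gene lists (defaults to the
#'   simulation truth when simulating).
#' @param marker_map cell-type marker map for [annotate_clusters()]
#'   (defaults to the planted markers when simulating).
#' @param hvg_n,n_pcs,resolution,tumor_resolution clustering parameters.
#' @param cnv list: `window`, `min_ref_mean`, `clamp`, `shared_threshold`,
#'   `call_threshold`.
#' @param dsp list: `min_reads`, `alpha`, `global_fraction`, `log2fc_cut`,
#'   `p_cut`.
#' @param filter list: `f_on`, `r_max`, `u_min`.
#' @param score list: `n_bins`, `n_ctrl`.
#' @param traj list: `k` (Moran graph neighbors), `cutoff` (autocorrelation
#'   threshold), `n_dims` (leading PCs defining the trajectory manifold),
#'   `activators` (NULL = shipped list).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, seed = 1L, simulate = TRUE,
                            sim = sim_config(),
                            paths = list(), qc_genes = NULL,
                            marker_map = NULL,
                            hvg_n = 500L, n_pcs = 25L, resolution = 0.8,
                            tumor_resolution = 1.0,
                            cnv = list(), dsp = list(), filter = list(),
                            score = list(), traj = list()) {
  merge_defaults <- function(user, defaults) utils::modifyList(defaults, user)
  cfg <- list(
    outdir = outdir, seed = as.integer(seed), simulate = simulate, sim = sim,
    paths = paths, qc_genes = qc_genes, marker_map = marker_map,
    hvg_n = hvg_n, n_pcs = n_pcs, resolution = resolution,
    tumor_resolution = tumor_resolution,
    cnv = merge_defaults(cnv, list(window = 51L, min_ref_mean = 0.1,
                                   clamp = 1.0, shared_threshold = 0.15,
                                   call_threshold = 0.15)),
    dsp = merge_defaults(dsp, list(min_reads = 10000, alpha = 0.01,
                                   global_fraction = 0.20,
                                   log2fc_cut = 0.4, p_cut = 0.05)),
    filter = merge_defaults(filter, list(f_on = 0.10, r_max = 3.0,
                                         u_min = 0.25)),
    score = merge_defaults(score, list(n_bins = 24L, n_ctrl = 100L)),
    traj = merge_defaults(traj, list(k = 20L, cutoff = 0.1, n_dims = 5L,
                                     activators = NULL))
  )
  if (!simulate) {
    need <- c("sc_dir", "dsp_dir", "positions")
    miss <- setdiff(need, names(cfg$paths))
    if (length(miss))
      .fail("pipeline_config: simulate = FALSE requires paths: ",
            paste(miss, collapse = ", "))
    for (p in cfg$paths[need])
      if (!file.exists(p)) .fail("pipeline_config: input path missing: ", p)
    if (is.null(marker_map) || is.null(qc_genes))
      .fail("pipeline_config: marker_map and qc_genes required for user data")
  }
  class(cfg) <- "pipeline_config"
  cfg
}

# internal: seed for stage i under the documented derivation scheme
.stage_seed <- function(cfg, i) cfg$seed + 1000L * i

#' Run the full invasive-niche analysis
#'
#' Executes the stages in order: input generation or loading; single-cell
#' QC, normalization, clustering, doublet flagging and annotation; per-sample
#' copy-number inference with cross-sample shared-change exclusion and
#' burden comparison; DSP probe QC, collapse, normalization and morphology
#' differential expression; raw signature assembly and contamination
#' filtering; tumor subcluster scoring and infiltrative ranking; and the
#' pseudotime/autocorrelation screen for CAF-activator drivers. All
#' artifacts are written under `cfg$outdir` and listed in `manifest.json`;
#' the run is a pure function of the configuration and seed.
#'
#' @param cfg a [pipeline_config()].
#' @return list of class `niche_run` with every intermediate result and the
#'   manifest, invisibly also written to disk.
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  out <- cfg$outdir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character()
  emit <- function(obj, rel, writer) {
    path <- file.path(out, rel)
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    writer(obj, path)
    artifacts <<- c(artifacts, rel)
  }
  tsv <- function(d, path) utils::write.table(d, path, sep = "\t",
                                              quote = FALSE, row.names = FALSE)
  stage <- function(name, expr) {
    message("[", name, "] ...")
    tryCatch(expr, error = function(e)
      .fail("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  }

  # ---- stage 1: inputs -------------------------------------------------
  data <- stage("data", {
    if (cfg$simulate) {
      scfg <- cfg$sim
      scfg$seed <- .stage_seed(cfg, 1L)
      sc_sim <- simulate_sc_counts(scfg)
      dsp_tab <- simulate_dsp_probes(scfg, sc_sim)
      write_sc_mtx(sc_sim, file.path(out, "inputs/sc"))
      write_dsp_tables(dsp_tab, file.path(out, "inputs/dsp"))
      emit(sc_sim$truth$gene_positions, "inputs/gene_positions.tsv", tsv)
      list(counts = sc_sim$counts, cell_meta = sc_sim$cell_meta,
           dsp = dsp_tab, positions = sc_sim$truth$gene_positions,
           sim = sc_sim)
    } else {
      sc <- read_sc_mtx(cfg$paths$sc_dir)
      list(counts = sc$counts, cell_meta = sc$cell_meta,
           dsp = read_dsp_tables(cfg$paths$dsp_dir),
           positions = read_gene_positions(cfg$paths$positions), sim = NULL)
    }
  })
  sim <- data$sim

  # ---- stage 2: single-cell core --------------------------------------
  sc <- stage("sc_core", {
    qc_genes <- cfg$qc_genes
    if (is.null(qc_genes) && cfg$simulate)
      qc_genes <- list(mito = sim$truth$program_gene_sets$mito,
                       dissoc = sim$truth$program_gene_sets$dissoc)
    qc <- qc_params(mito_genes = qc_genes$mito, dissoc_genes = qc_genes$dissoc)
    keep <- filter_cells(data$counts, qc)
    counts <- data$counts[, keep, drop = FALSE]
    meta <- data$cell_meta[match(colnames(counts), data$cell_meta$cell_id), ]
    norm <- lognormalize(counts)
    hvgs <- select_hvgs(norm, cfg$hvg_n)
    clu <- embed_and_cluster(norm, hvgs, cfg$n_pcs, cfg$resolution,
                             seed = .stage_seed(cfg, 2L))
    marker_map <- cfg$marker_map
    if (is.null(marker_map) && cfg$simulate)
      marker_map <- sim$truth$program_gene_sets$markers
    pairs <- list(c("KRT14", "CD3E"), c("KRT14", "COL1A1"))
    doublet <- flag_doublet_clusters(counts, clu$clusters, pairs)
    annot <- annotate_clusters(norm, clu$clusters, marker_map)
    cell_types <- stats::setNames(annot[as.character(clu$clusters)],
                                  names(clu$clusters))
    lisi <- lisi_score(clu$pcs, meta$sample,
                       k = min(30L, nrow(clu$pcs) - 1L))
    emit(data.frame(cell_id = names(keep), retained = keep),
         "sc/cell_qc.tsv", tsv)
    emit(data.frame(cell_id = names(clu$clusters), cluster = clu$clusters,
                    cell_type = cell_types, sample = meta$sample,
                    lisi = lisi),
         "sc/clusters.tsv", tsv)
    emit(data.frame(cluster = names(annot), cell_type = annot,
                    doublet_flag = doublet[names(annot)]),
         "sc/annotation.tsv", tsv)
    list(counts = counts, meta = meta, norm = norm, hvgs = hvgs,
         clusters = clu$clusters, pcs = clu$pcs, annotation = annot,
         cell_types = cell_types, doublet = doublet, lisi = lisi)
  })
  epithelial_types <- c("tumor", "basal_keratinocyte", "diff_keratinocyte")

  # ---- stage 3: copy-number inference ---------------------------------
  cnv <- stage("cnv_inference", {
    ref_cells <- names(sc$cell_types)[sc$cell_types == "t_cell"]
    # gene filter on the pooled reference so per-sample window maps agree
    ref_mean <- .rowmeans(sc$counts[, ref_cells, drop = FALSE])
    genes <- rownames(sc$counts)[ref_mean >= cfg$cnv$min_ref_mean]
    samples <- sort(unique(sc$meta$sample))
    profiles <- lapply(samples, function(s) {
      cells <- sc$meta$cell_id[sc$meta$sample == s]
      infer_cnv_profile(sc$counts[genes, cells, drop = FALSE],
                        data$positions,
                        intersect(ref_cells, cells),
                        window = cfg$cnv$window, min_ref_mean = 0,
                        clamp = cfg$cnv$clamp)
    })
    names(profiles) <- samples
    epi_by_sample <- lapply(samples, function(s)
      intersect(sc$meta$cell_id[sc$meta$sample == s],
                names(sc$cell_types)[sc$cell_types %in% epithelial_types]))
    names(epi_by_sample) <- samples
    mask <- exclude_shared_changes(profiles, epi_by_sample,
                                   cfg$cnv$shared_threshold)
    burden <- unlist(lapply(profiles, cnv_burden, mask = mask))
    names(burden) <- unlist(lapply(profiles, function(p) rownames(p$values)))
    tum <- burden[names(burden) %in% names(sc$cell_types)[sc$cell_types == "tumor"]]
    fib <- burden[names(burden) %in% names(sc$cell_types)[sc$cell_types == "fibroblast"]]
    burden_p <- if (length(tum) && length(fib))
      stats::wilcox.test(tum, fib)$p.value else NA_real_
    emit(data.frame(cell_id = names(burden), burden = burden),
         "cnv/burden.tsv", tsv)
    emit(cbind(profiles[[1]]$window_map, masked = mask),
         "cnv/shared_mask.tsv", tsv)
    list(profiles = profiles, mask = mask, burden = burden,
         burden_tumor_vs_fibroblast_p = burden_p)
  })

  # ---- stage 4: DSP core ----------------------------------------------
  dsp <- stage("dsp_core", {
    tab <- aoi_qc(data$dsp, cfg$dsp$min_reads)
    flags <- flag_outlier_probes(tab, cfg$dsp$alpha, cfg$dsp$global_fraction)
    gene_counts <- collapse_probes(tab, flags)
    neg <- negative_probe_factors(tab)
    nrm <- q3_normalize(gene_counts)
    deg_t <- dsp_deg(nrm, tab$aoi_meta, "tumor",
                     cfg$dsp$log2fc_cut, cfg$dsp$p_cut)
    deg_s <- dsp_deg(nrm, tab$aoi_meta, "stroma",
                     cfg$dsp$log2fc_cut, cfg$dsp$p_cut)
    raw_sig <- build_raw_signatures(deg_t, deg_s)
    emit(data.frame(gene = rownames(nrm$values), nrm$values,
                    check.names = FALSE), "dsp/normalized.tsv", tsv)
    emit(as.data.frame(deg_t), "dsp/deg_tumor.tsv", tsv)
    emit(as.data.frame(deg_s), "dsp/deg_stroma.tsv", tsv)
    for (s in c("t_nod", "t_inf", "s_nod", "s_inf"))
      emit(raw_sig[[s]], paste0("signatures/raw_", s, ".txt"),
           function(g, p) writeLines(g, p))
    list(table = tab, flags = flags, gene_counts = gene_counts,
         neg_factors = neg, normalized = nrm, deg_tumor = deg_t,
         deg_stroma = deg_s, raw_signatures = raw_sig)
  })

  # ---- stage 5: signature contamination filter ------------------------
  sigs <- stage("signature_filter", {
    prof <- compartment_expression_profile(sc$counts, sc$norm, sc$cell_types,
                                           epithelial_types)
    filt <- filter_signature(dsp$raw_signatures, prof, cfg$filter$f_on,
                             cfg$filter$r_max, cfg$filter$u_min)
    for (s in c("t_nod", "t_inf", "s_nod", "s_inf"))
      emit(filt[[s]], paste0("signatures/filtered_", s, ".txt"),
           function(g, p) writeLines(g, p))
    emit(attr(filt, "decision_log"), "signatures/decision_log.tsv", tsv)
    list(profile = prof, filtered = filt)
  })

  # ---- stage 6: niche mapping -----------------------------------------
  niche <- stage("niche_mapping", {
    tumor_cells <- names(sc$cell_types)[sc$cell_types == "tumor"]
    tnorm <- sc$norm[, tumor_cells, drop = FALSE]
    thvg <- select_hvgs(tnorm, min(cfg$hvg_n, nrow(tnorm)))
    tclu <- embed_and_cluster(tnorm, thvg, min(cfg$n_pcs, length(tumor_cells) - 1L),
                              cfg$tumor_resolution,
                              seed = .stage_seed(cfg, 6L))
    s_inf <- module_score(tnorm, sigs$filtered$t_inf, "spatial_T_INF",
                          cfg$score$n_bins, cfg$score$n_ctrl,
                          seed = .stage_seed(cfg, 6L))
    s_nod <- module_score(tnorm, sigs$filtered$t_nod, "spatial_T_NOD",
                          cfg$score$n_bins, cfg$score$n_ctrl,
                          seed = .stage_seed(cfg, 6L) + 1L)
    diff <- score_difference(s_inf, s_nod)
    ranking <- rank_clusters(diff, tclu$clusters, prefix = "TC")
    anticorr <- signature_anticorrelation(s_nod, s_inf)
    emit(data.frame(cell_id = names(diff), score_inf = s_inf$scores,
                    score_nod = s_nod$scores, diff = diff,
                    cluster = attr(ranking, "cell_rank_labels")[names(diff)]),
         "niche/score_diff.tsv", tsv)
    emit(as.data.frame(ranking), "niche/ranking.tsv", tsv)
    list(tumor_cells = tumor_cells, clusters = tclu$clusters,
         pcs = tclu$pcs, score_inf = s_inf, score_nod = s_nod,
         diff = diff, ranking = ranking, anticorrelation = anticorr)
  })

  # ---- stage 7: trajectory --------------------------------------------
  traj <- stage("trajectory", {
    root <- niche$ranking$cluster[1]
    nd <- min(cfg$traj$n_dims, ncol(niche$pcs))
    pt <- compute_pseudotime(niche$pcs[, seq_len(nd), drop = FALSE],
                             niche$clusters, root)
    graph <- knn_graph(niche$pcs, cfg$traj$k)
    tnorm <- .dense(sc$norm[, niche$tumor_cells, drop = FALSE])
    tnorm <- tnorm[.rowvars(tnorm) > 0, , drop = FALSE]
    tbl <- morans_i_table(tnorm, graph)
    genes <- select_trajectory_genes(tbl, cfg$traj$cutoff)
    activators <- cfg$traj$activators
    if (is.null(activators)) activators <- default_caf_activators()
    overlap <- overlap_with_activators(genes, activators)
    emit(data.frame(cell_id = names(pt$pseudotime),
                    pseudotime = pt$pseudotime), "trajectory/pseudotime.tsv",
         tsv)
    emit(as.data.frame(tbl), "trajectory/autocorrelation.tsv", tsv)
    emit(overlap, "trajectory/activator_overlap.txt",
         function(g, p) writeLines(g, p))
    list(trajectory = pt, autocorrelation = tbl, trajectory_genes = genes,
         activator_overlap = overlap)
  })

  # ---- manifest --------------------------------------------------------
  manifest <- list(
    package = "spatialniche",
    seed = cfg$seed,
    simulate = cfg$simulate,
    parameters = cfg[c("hvg_n", "n_pcs", "resolution", "tumor_resolution",
                       "cnv", "dsp", "filter", "score")],
    artifacts = sort(unique(c(artifacts,
                              file.path("inputs/sc",
                                        c("matrix.mtx", "genes.tsv",
                                          "barcodes.tsv", "cells.tsv")),
                              file.path("inputs/dsp",
                                        c("probe_counts.tsv", "probe_map.tsv",
                                          "aoi_metadata.tsv")))))
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  res <- list(config = cfg, sim = sim, sc = sc, cnv = cnv, dsp = dsp,
              signatures = sigs, niche = niche, trajectory = traj,
              manifest = manifest, outdir = out)
  class(res) <- "niche_run"
  invisible(res)
}

#' @export
print.niche_run <- function(x, ...) {
  cat("niche_run (seed ", x$config$seed, "):\n",
      "  cells retained: ", ncol(x$sc$counts), "\n",
      "  tumor subclusters: ", nrow(x$niche$ranking), "\n",
      "  signatures (filtered): T^NOD ", length(x$signatures$filtered$t_nod),
      ", T^INF ", length(x$signatures$filtered$t_inf),
      ", S^NOD ", length(x$signatures$filtered$s_nod),
      ", S^INF ", length(x$signatures$filtered$s_inf), "\n",
      "  NOD/INF anticorrelation rho: ",
      round(x$niche$anticorrelation$rho, 3), "\n",
      "  top activator overlap: ",
      paste(utils::head(x$trajectory$activator_overlap, 3), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
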