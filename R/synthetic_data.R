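#' Simulation configuration for the invasive-niche study design
#'
#' Builds the configuration object consumed by [simulate_sc_counts()] and
#' [simulate_dsp_probes()]. Defaults encode the study conditions the package
#' is tested under: five cell types sampled from several patients, a latent
#' nodular-to-infiltrative coordinate `g` in tumor cells controlling two
#' antagonistic transcriptional programs, fibroblast activation controlling
#' an ECM program, planted copy-number segments in tumor cells, and DSP
#' pseudo-bulk areas of interest (AOIs) built as contamination mixtures of
#' the two compartment profiles with planted morphology fold-changes.
#'
#' @param n_cells_per_type named integer vector, cells per type. Must contain
#'   at least `tumor`, `basal_keratinocyte`, `diff_keratinocyte`,
#'   `fibroblast`, `t_cell`.
#' @param n_genes size of the gene universe.
#' @param n_chromosomes synthetic chromosomes; genes are laid out round-robin
#'   over chromosomes in gene-index order.
#' @param n_samples number of patient labels assigned to cells.
#' @param baseline_mean scale of baseline per-gene negative-binomial means.
#' @param nb_dispersion NB dispersion phi (variance = mu + phi * mu^2).
#' @param n_program_genes genes in each planted program (NOD, INF, ECM,
#'   quiescent).
#' @param n_marker_genes type-specific marker genes per cell type.
#' @param program_log2fc log2 fold-change slope of the gradient programs.
#' @param gradient_shape1,gradient_shape2 Beta parameters of the latent
#'   infiltrative coordinate `g` over tumor cells (and of fibroblast
#'   activation `a`).
#' @param cnv_segments list of segments `list(chrom, start, length,
#'   multiplier, sample)`: `start` and `length` index genes along the
#'   chromosome. Copy-number changes are patient-specific, so each segment
#'   applies to the tumor cells of one sample only; when `sample` is
#'   omitted, segments are assigned round-robin over samples.
#' @param lineage_segments like `cnv_segments` but applied to all epithelial
#'   cells of every sample (lineage-dependent transcription, the confounder
#'   that shared-change exclusion must mask).
#' @param n_lowq_cells planted low-library cells (fail the detected-gene QC).
#' @param n_himito_cells planted high-mitochondrial cells (fail the mito QC).
#' @param n_aoi_per_group DSP AOIs per (compartment x morphology) group.
#' @param contamination_beta length-2 Beta parameters of the per-AOI
#'   cross-compartment mixing fraction `c`.
#' @param dsp_log2fc magnitude of planted DSP morphology log2 fold-changes.
#' @param probes_per_gene probes representing each panel gene.
#' @param n_negative_probes no-target background probes per pool.
#' @param probe_cv coefficient of variation of probe efficiencies.
#' @param outlier_probe_rate fraction of probes planted as aberrant.
#' @param outlier_multiplier efficiency multiplier of aberrant probes (>= 8).
#' @param aoi_mean_reads expected sequencing depth per AOI.
#' @param seed integer seed; identical config + seed is bit-reproducible.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_cells_per_type = c(tumor = 800L, basal_keratinocyte = 200L,
                                            diff_keratinocyte = 200L,
                                            fibroblast = 250L, t_cell = 250L),
                       n_genes = 2000L,
                       n_chromosomes = 22L,
                       n_samples = 3L,
                       baseline_mean = 1.0,
                       nb_dispersion = 0.5,
                       n_program_genes = 60L,
                       n_marker_genes = 8L,
                       program_log2fc = 2.5,
                       gradient_shape1 = 2, gradient_shape2 = 2,
                       cnv_segments = list(
                         list(chrom = 1L, start = 11L, length = 60L, multiplier = 2.0),
                         list(chrom = 3L, start = 6L, length = 50L, multiplier = 0.5),
                         list(chrom = 5L, start = 11L, length = 50L, multiplier = 1.8)
                       ),
                       lineage_segments = list(
                         list(chrom = 2L, start = 10L, length = 60L, multiplier = 1.7)
                       ),
                       n_lowq_cells = 30L,
                       n_himito_cells = 20L,
                       n_aoi_per_group = 12L,
                       contamination_beta = c(2, 18),
                       dsp_log2fc = 1.0,
                       probes_per_gene = 5L,
                       n_negative_probes = 20L,
                       probe_cv = 0.15,
                       outlier_probe_rate = 0.005,
                       outlier_multiplier = 10,
                       aoi_mean_reads = 2e5,
                       seed = 1L) {
  required <- c("tumor", "basal_keratinocyte", "diff_keratinocyte",
                "fibroblast", "t_cell")
  if (!all(required %in% names(n_cells_per_type)))
    .fail("sim_config: n_cells_per_type must name types: ",
          paste(required, collapse = ", "))
  if (any(n_cells_per_type <= 0) || n_genes <= 0 || n_program_genes <= 0 ||
      n_marker_genes <= 0 || probes_per_gene <= 0 || n_negative_probes <= 0)
    .fail("sim_config: counts must be positive")
  if (length(contamination_beta) != 2 || any(contamination_beta <= 0))
    .fail("sim_config: contamination_beta must be two positive shapes")
  for (seg in c(cnv_segments, lineage_segments)) {
    if (seg$multiplier <= 0) .fail("sim_config: segment multipliers must be > 0")
  }
  if (outlier_multiplier < 8)
    .fail("sim_config: outlier_multiplier must be >= 8")
  cfg <- list(n_cells_per_type = n_cells_per_type, n_genes = as.integer(n_genes),
              n_chromosomes = as.integer(n_chromosomes),
              n_samples = as.integer(n_samples),
              baseline_mean = baseline_mean, nb_dispersion = nb_dispersion,
              n_program_genes = as.integer(n_program_genes),
              n_marker_genes = as.integer(n_marker_genes),
              program_log2fc = program_log2fc,
              gradient_shape1 = gradient_shape1, gradient_shape2 = gradient_shape2,
              cnv_segments = cnv_segments, lineage_segments = lineage_segments,
              n_lowq_cells = as.integer(n_lowq_cells),
              n_himito_cells = as.integer(n_himito_cells),
              n_aoi_per_group = as.integer(n_aoi_per_group),
              contamination_beta = contamination_beta,
              dsp_log2fc = dsp_log2fc,
              probes_per_gene = as.integer(probes_per_gene),
              n_negative_probes = as.integer(n_negative_probes),
              probe_cv = probe_cv, outlier_probe_rate = outlier_probe_rate,
              outlier_multiplier = outlier_multiplier,
              aoi_mean_reads = aoi_mean_reads, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Synthetic gene genomic positions
#'
#' Genes are assigned round-robin over chromosomes in gene-index order, so
#' every chromosome carries an interleaved, evenly sized gene complement and
#' copy-number windows are well defined without a real annotation. Positions
#' along a chromosome are 1-based and spaced 10 kb apart.
#'
#' @param gene_ids character vector of gene identifiers.
#' @param n_chromosomes number of synthetic chromosomes.
#' @return data.frame with columns `gene`, `chrom`, `start`.
#' @export
synthetic_gene_positions <- function(gene_ids, n_chromosomes = 22L) {
  n <- length(gene_ids)
  chrom <- ((seq_len(n) - 1L) %% n_chromosomes) + 1L
  idx_on_chrom <- ((seq_len(n) - 1L) %/% n_chromosomes) + 1L
  data.frame(gene = gene_ids, chrom = paste0("chr", chrom),
             start = idx_on_chrom * 10000L, stringsAsFactors = FALSE)
}

# internal: build the named gene universe and the planted role sets
.build_gene_universe <- function(cfg) {
  npg <- cfg$n_program_genes
  nmk <- cfg$n_marker_genes
  pad <- function(base, prefix, n) {
    if (length(base) >= n) return(base[seq_len(n)])
    c(base, sprintf("%s%02d", prefix, seq_len(n - length(base))))
  }
  markers <- list(
    tumor = pad(c("PTCH1", "GLI1", "GLI2", "HHIP", "MYCN"), "TUM", nmk),
    basal_keratinocyte = pad(c("KRT5", "TP63", "ITGA6", "COL17A1", "DST"), "BAS", nmk),
    diff_keratinocyte = pad(c("KRT1", "KRT10", "CALML5", "IVL", "LOR"), "DIF", nmk),
    fibroblast = pad(c("COL1A1", "PDGFRA", "LUM", "DCN", "PDGFRB"), "FIB", nmk),
    t_cell = pad(c("CD3E", "CD3D", "CD2", "IL7R", "CD7"), "TCL", nmk)
  )
  sets <- list(
    epithelial_markers = c("KRT14", "KRT17"),
    markers = markers,
    drivers = c("INHBA", "TGFB1"),
    nod = pad(c("MPPED1"), "NOD", npg),
    inf = pad(c("KRT6A", "SFN"), "INF", npg),
    ecm = pad(c("FN1", "COL1A2", "COL3A1", "POSTN"), "ECM", npg),
    quiescent = pad(character(), "QUI", npg),
    housekeeping = sprintf("HK%02d", 1:10),
    mito = sprintf("MT-G%02d", 1:10),
    dissoc = pad(c("FOS", "JUN", "JUNB", "EGR1", "HSPA1A", "HSPA1B"), "DIS", 10L)
  )
  named <- c(sets$epithelial_markers, unlist(sets$markers, use.names = FALSE),
             sets$drivers, sets$nod, sets$inf, sets$ecm, sets$quiescent,
             sets$housekeeping, sets$mito, sets$dissoc)
  if (anyDuplicated(named))
    .fail("internal: duplicated planted gene names")
  if (length(named) > cfg$n_genes)
    .fail("sim_config: gene universe (", cfg$n_genes,
          ") smaller than the planted program sets (", length(named), ")")
  filler <- sprintf("G%04d", seq_len(cfg$n_genes - length(named)))
  sets$gene_ids <- c(named, filler)
  sets
}

# internal: resolve a segment spec to gene ids on its chromosome
.segment_genes <- function(seg, positions) {
  chrom_genes <- positions$gene[positions$chrom == paste0("chr", seg$chrom)]
  if (length(chrom_genes) < seg$start + seg$length - 1L)
    .fail("sim_config: segment (chrom ", seg$chrom, ", start ", seg$start,
          ", length ", seg$length, ") exceeds the ", length(chrom_genes),
          " genes on that chromosome")
  chrom_genes[seq(seg$start, length.out = seg$length)]
}

#' Simulate single-cell RNA-seq counts with planted structure
#'
#' Draws negative-binomial counts (variance `mu + phi mu^2`) with log-normal
#' per-cell library-size factors (sdlog 0.3). Tumor cells carry a latent
#' infiltrative coordinate `g ~ Beta(shape1, shape2)`: the INF program is
#' amplified by `2^(log2fc * g)` and the NOD program by `2^(log2fc * (1-g))`,
#' so the two programs are antagonistic along the continuum. Fibroblasts
#' carry an analogous activation coordinate driving the ECM program against a
#' quiescent program. Copy-number segments multiply the means of their genes
#' in tumor cells only; lineage segments multiply them in all epithelial
#' cells (the shared-change confounder). Type markers, a shared epithelial
#' marker (KRT14-like), a planted monotone paracrine driver (INHBA-like), and
#' housekeeping/mitochondrial/dissociation genes are included, plus planted
#' low-quality cells for QC exercising.
#'
#' @param config a [sim_config()].
#' @return list of class `sc_sim` with elements `counts` (sparse genes x
#'   cells), `cell_meta` (cell_id, sample, cell_type, planted_lowq), and
#'   `truth` (gene sets, tumor gradient, fibroblast activation, segment gene
#'   ids, gene positions, expected compartment profiles).
#' @export
simulate_sc_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sets <- .build_gene_universe(config)
  genes <- sets$gene_ids
  ng <- length(genes)
  positions <- synthetic_gene_positions(genes, config$n_chromosomes)

  types <- rep(names(config$n_cells_per_type), config$n_cells_per_type)
  nc <- length(types)
  cell_ids <- sprintf("C%05d", seq_len(nc))
  samples <- paste0("S", (sample.int(config$n_samples, nc, replace = TRUE)))

  # baseline gene means, overridden for planted roles
  base <- stats::rlnorm(ng, meanlog = log(config$baseline_mean) - 0.5, sdlog = 1)
  names(base) <- genes
  off <- 0.02
  mu <- matrix(rep(base, nc), nrow = ng, ncol = nc,
               dimnames = list(genes, cell_ids))
  epithelial <- types %in% c("tumor", "basal_keratinocyte", "diff_keratinocyte")
  is_type <- function(t) types == t

  # markers: high in own type, near-absent elsewhere
  for (tp in names(sets$markers)) {
    mk <- sets$markers[[tp]]
    mu[mk, ] <- off
    mu[mk, is_type(tp)] <- 2.0
  }
  mu[sets$epithelial_markers, ] <- off
  mu[sets$epithelial_markers, epithelial] <- 2.0

  # gradient programs in tumor cells
  g <- stats::rbeta(sum(is_type("tumor")), config$gradient_shape1,
                    config$gradient_shape2)
  lfc <- config$program_log2fc
  mu[sets$nod, ] <- off
  mu[sets$inf, ] <- off
  mu[sets$nod, epithelial] <- 0.2
  mu[sets$inf, epithelial] <- 0.2
  mu[sets$nod, is_type("tumor")] <- 0.5 * rep(2^(lfc * (1 - g)), each = length(sets$nod))
  mu[sets$inf, is_type("tumor")] <- 0.5 * rep(2^(lfc * g), each = length(sets$inf))

  # fibroblast activation: ECM vs quiescent programs
  a <- stats::rbeta(sum(is_type("fibroblast")), config$gradient_shape1,
                    config$gradient_shape2)
  mu[sets$ecm, ] <- off
  mu[sets$quiescent, ] <- off
  mu[sets$ecm, is_type("fibroblast")] <- 1.0 * rep(2^(lfc * a), each = length(sets$ecm))
  mu[sets$quiescent, is_type("fibroblast")] <-
    1.0 * rep(2^(lfc * (1 - a)), each = length(sets$quiescent))

  # paracrine drivers: INHBA-like monotone in g, TGFB1-like flat
  mu["INHBA", ] <- off
  mu["INHBA", is_type("tumor")] <- 0.5 * 2^(4 * g)
  mu["TGFB1", ] <- 0.05
  mu["TGFB1", is_type("tumor")] <- 1.0

  # ubiquitous and QC gene classes
  mu[sets$housekeeping, ] <- 5.0
  mu[sets$mito, ] <- 3.0
  mu[sets$dissoc, ] <- 1.0

  # copy-number segments: patient-specific, applied to one sample's tumor cells
  cnv_genes <- lapply(config$cnv_segments, .segment_genes, positions = positions)
  cnv_samples <- vapply(seq_along(config$cnv_segments), function(i) {
    s <- config$cnv_segments[[i]]$sample
    if (is.null(s)) ((i - 1L) %% config$n_samples) + 1L else as.integer(s)
  }, integer(1))
  for (i in seq_along(config$cnv_segments)) {
    hit <- is_type("tumor") & samples == paste0("S", cnv_samples[i])
    mu[cnv_genes[[i]], hit] <- mu[cnv_genes[[i]], hit] *
      config$cnv_segments[[i]]$multiplier
  }
  lineage_genes <- lapply(config$lineage_segments, .segment_genes,
                          positions = positions)
  for (i in seq_along(config$lineage_segments)) {
    mu[lineage_genes[[i]], epithelial] <-
      mu[lineage_genes[[i]], epithelial] * config$lineage_segments[[i]]$multiplier
  }

  # expected pure compartment profiles (before library-size factors),
  # used by the DSP simulator as ground truth mixtures
  stroma <- is_type("fibroblast") | is_type("t_cell")
  profiles <- cbind(tumor = rowMeans(mu[, is_type("tumor"), drop = FALSE]),
                    stroma = rowMeans(mu[, stroma, drop = FALSE]))

  # library-size factors and planted low-quality cells
  sf <- stats::rlnorm(nc, meanlog = 0, sdlog = 0.3)
  n_lowq <- min(config$n_lowq_cells, nc)
  n_himito <- min(config$n_himito_cells, nc - n_lowq)
  lowq_idx <- if (n_lowq > 0) sample.int(nc, n_lowq) else integer()
  sf[lowq_idx] <- sf[lowq_idx] * 0.05
  himito_idx <- if (n_himito > 0) sample(setdiff(seq_len(nc), lowq_idx), n_himito)
                else integer()
  mu[sets$mito, himito_idx] <- mu[sets$mito, himito_idx] * 25

  mu_eff <- sweep(mu, 2, sf, `*`)
  counts <- matrix(stats::rnbinom(length(mu_eff), size = 1 / config$nb_dispersion,
                                  mu = mu_eff),
                   nrow = ng, dimnames = dimnames(mu_eff))
  counts <- Matrix::Matrix(counts, sparse = TRUE)

  planted_lowq <- rep("none", nc)
  planted_lowq[lowq_idx] <- "low_library"
  planted_lowq[himito_idx] <- "high_mito"
  cell_meta <- data.frame(cell_id = cell_ids, sample = samples,
                          cell_type = types, planted_lowq = planted_lowq,
                          stringsAsFactors = FALSE)

  truth <- list(
    cell_type_labels = stats::setNames(types, cell_ids),
    tumor_gradient = stats::setNames(g, cell_ids[is_type("tumor")]),
    fibro_activation = stats::setNames(a, cell_ids[is_type("fibroblast")]),
    program_gene_sets = list(nod = sets$nod, inf = sets$inf, ecm = sets$ecm,
                             quiescent = sets$quiescent,
                             markers = sets$markers,
                             epithelial_markers = sets$epithelial_markers,
                             drivers = sets$drivers,
                             housekeeping = sets$housekeeping,
                             mito = sets$mito, dissoc = sets$dissoc),
    cnv_segments = Map(function(seg, gg, ss)
                         c(seg[setdiff(names(seg), "sample")],
                           list(genes = gg, sample = paste0("S", ss))),
                       config$cnv_segments, cnv_genes, cnv_samples),
    lineage_segments = Map(function(seg, gg) c(seg, list(genes = gg)),
                           config$lineage_segments, lineage_genes),
    gene_positions = positions,
    expected_profiles = profiles,
    config = config
  )
  structure(list(counts = counts, cell_meta = cell_meta, truth = truth),
            class = "sc_sim")
}

#' @export
print.sc_sim <- function(x, ...) {
  cat("sc_sim:", nrow(x$counts), "genes x", ncol(x$counts), "cells;",
      length(unique(x$cell_meta$cell_type)), "cell types,",
      length(unique(x$cell_meta$sample)), "samples\n")
  invisible(x)
}

#' Simulate DSP probe-level counts as contaminated compartment mixtures
#'
#' Each AOI belongs to a (compartment, morphology) group. Its gene-level
#' expectation is `(1-c) * own-compartment profile + c * adjacent-compartment
#' profile`, where `c ~ Beta(a, b)` is the AOI's cross-contamination
#' fraction and both profiles carry the morphology fold-changes planted on
#' the compartment DEG programs (tumor: INF up / NOD down in infiltrative;
#' stroma: ECM up / quiescent down). Every gene is represented by
#' `probes_per_gene` probes whose efficiencies scatter log-normally with the
#' configured CV; a small fraction of probes is planted aberrant with
#' efficiency multiplied by `outlier_multiplier`. Negative (no-target) probes
#' are drawn around a low per-pool background. Counts are Poisson around the
#' probe expectations and per-AOI totals are recorded.
#'
#' @param config a [sim_config()].
#' @param sc_sim result of [simulate_sc_counts()] under the same config,
#'   providing the pure compartment profiles.
#' @return object of class `probe_count_table` (see [probe_count_table()])
#'   with a `truth` element (per-AOI contamination, planted morphology DEGs,
#'   planted outlier probes).
#' @export
simulate_dsp_probes <- function(config, sc_sim) {
  stopifnot(inherits(config, "sim_config"), inherits(sc_sim, "sc_sim"))
  set.seed(config$seed + 104729L) # distinct stream from the sc stage
  profiles <- sc_sim$truth$expected_profiles
  genes <- rownames(profiles)
  ng <- length(genes)
  sets <- sc_sim$truth$program_gene_sets

  lfc <- config$dsp_log2fc
  planted <- rbind(
    data.frame(gene = sets$inf, compartment = "tumor", log2fc = lfc),
    data.frame(gene = sets$nod, compartment = "tumor", log2fc = -lfc),
    data.frame(gene = sets$ecm, compartment = "stroma", log2fc = lfc),
    data.frame(gene = sets$quiescent, compartment = "stroma", log2fc = -lfc)
  )
  # morphology-adjusted profile: infiltrative gets 2^(+lfc/2), nodular 2^(-lfc/2)
  morph_profile <- function(compartment, morphology) {
    p <- profiles[, compartment]
    degs <- planted[planted$compartment == compartment, ]
    shift <- if (morphology == "infiltrative") degs$log2fc / 2 else -degs$log2fc / 2
    p[degs$gene] <- p[degs$gene] * 2^shift
    p
  }

  groups <- expand.grid(compartment = c("tumor", "stroma"),
                        morphology = c("nodular", "infiltrative"),
                        rep = seq_len(config$n_aoi_per_group),
                        stringsAsFactors = FALSE)
  n_aoi <- nrow(groups)
  aoi_ids <- sprintf("AOI%03d", seq_len(n_aoi))
  cvals <- stats::rbeta(n_aoi, config$contamination_beta[1],
                        config$contamination_beta[2])

  # probe layout: probes_per_gene per gene plus negatives, one pool
  ppg <- config$probes_per_gene
  probe_ids <- paste0(rep(genes, each = ppg), "_P", rep(seq_len(ppg), ng))
  neg_ids <- sprintf("NEG%03d", seq_len(config$n_negative_probes))
  probe_map <- data.frame(
    probe_id = c(probe_ids, neg_ids),
    target = c(rep(genes, each = ppg), rep("NEGATIVE", config$n_negative_probes)),
    pool = "P1", stringsAsFactors = FALSE)

  sdlog <- sqrt(log(1 + config$probe_cv^2))
  eff <- stats::rlnorm(length(probe_ids), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  n_out <- round(config$outlier_probe_rate * length(probe_ids))
  outlier_idx <- if (n_out > 0) sample.int(length(probe_ids), n_out) else integer()
  eff[outlier_idx] <- eff[outlier_idx] * config$outlier_multiplier

  aoi_sf <- stats::rlnorm(n_aoi, meanlog = 0, sdlog = 0.2)
  counts <- matrix(0L, nrow = n_aoi, ncol = nrow(probe_map),
                   dimnames = list(aoi_ids, probe_map$probe_id))
  neg_mean <- 1.0
  for (i in seq_len(n_aoi)) {
    own <- morph_profile(groups$compartment[i], groups$morphology[i])
    other_comp <- if (groups$compartment[i] == "tumor") "stroma" else "tumor"
    other <- morph_profile(other_comp, groups$morphology[i])
    mix <- (1 - cvals[i]) * own + cvals[i] * other
    gene_share <- mix / sum(mix)
    probe_mu <- rep(gene_share, each = ppg) / ppg * config$aoi_mean_reads *
      aoi_sf[i] * eff
    counts[i, seq_along(probe_ids)] <- stats::rpois(length(probe_mu), probe_mu)
    counts[i, neg_ids] <- stats::rpois(length(neg_ids), neg_mean * aoi_sf[i])
  }

  aoi_meta <- data.frame(aoi_id = aoi_ids,
                         sample = paste0("DSP_", substr(groups$morphology, 1, 3),
                                         "_", ((groups$rep - 1L) %% 6L) + 1L),
                         compartment = groups$compartment,
                         morphology = groups$morphology,
                         total_reads = rowSums(counts),
                         stringsAsFactors = FALSE)

  truth <- list(aoi_contamination = stats::setNames(cvals, aoi_ids),
                planted_morphology_degs = planted,
                outlier_probes = probe_ids[outlier_idx])
  out <- probe_count_table(counts, probe_map, aoi_meta)
  out$truth <- truth
  out
}

#' Least-squares mixing-fraction estimate
#'
#' Closed-form projection of an AOI profile onto the segment between two pure
#' compartment profiles: the argmin over `c` in \[0,1\] of
#' `||y - ((1-c) A + c B)||^2`, clipped to the unit interval. Used as the
#' independent oracle for contamination recovery.
#'
#' @param aoi_profile gene-level expression vector `y`.
#' @param pure_a,pure_b pure compartment profiles on the same gene universe.
#' @return scalar mixing fraction in \[0, 1\].
#' @export
estimate_mixing_fraction <- function(aoi_profile, pure_a, pure_b) {
  if (length(aoi_profile) != length(pure_a) || length(pure_a) != length(pure_b))
    .fail("estimate_mixing_fraction: profiles must share the gene universe")
  if (any(aoi_profile < 0) || any(pure_a < 0) || any(pure_b < 0))
    .fail("estimate_mixing_fraction: profiles must be nonnegative")
  d <- pure_b - pure_a
  denom <- sum(d^2)
  if (denom < 1e-12 * max(1, sum(pure_a^2)))
    .fail("estimate_mixing_fraction: pure profiles are identical (degenerate)")
  min(1, max(0, sum((aoi_profile - pure_a) * d) / denom))
}
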