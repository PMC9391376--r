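#' Probe-level DSP count table
#'
#' Container for digital spatial profiling data at probe resolution: an
#' AOI x probe count matrix, the probe-to-target map with pool labels
#' (negative probes carry target `"NEGATIVE"`), and per-AOI metadata.
#'
#' @param counts AOI x probe matrix of nonnegative integer counts with
#'   dimnames.
#' @param probe_map data.frame with columns `probe_id`, `target`, `pool`.
#' @param aoi_meta data.frame with columns `aoi_id`, `sample`, `compartment`
#'   (`tumor`/`stroma`), `morphology` (`nodular`/`infiltrative`),
#'   `total_reads`.
#' @return object of class `probe_count_table`.
#' @export
probe_count_table <- function(counts, probe_map, aoi_meta) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) .fail("probe_count_table: negative counts")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    .fail("probe_count_table: counts needs AOI rownames and probe colnames")
  if (!all(colnames(counts) %in% probe_map$probe_id))
    .fail("probe_count_table: every probe must be mapped")
  probe_map <- probe_map[match(colnames(counts), probe_map$probe_id), ]
  for (pool in unique(probe_map$pool)) {
    if (!any(probe_map$target[probe_map$pool == pool] == "NEGATIVE"))
      .fail("probe_count_table: pool ", pool, " has no negative probe")
  }
  if (!all(rownames(counts) %in% aoi_meta$aoi_id))
    .fail("probe_count_table: aoi_meta must cover every AOI")
  aoi_meta <- aoi_meta[match(rownames(counts), aoi_meta$aoi_id), ]
  structure(list(counts = counts, probe_map = probe_map, aoi_meta = aoi_meta),
            class = "probe_count_table")
}

#' @export
print.probe_count_table <- function(x, ...) {
  cat("probe_count_table:", nrow(x$counts), "AOIs x", ncol(x$counts),
      "probes (", sum(x$probe_map$target != "NEGATIVE"), "targeting,",
      sum(x$probe_map$target == "NEGATIVE"), "negative )\n")
  invisible(x)
}

#' AOI sequencing-depth QC
#'
#' Drops AOIs whose recorded total reads fall below the minimum depth
#' (default 10,000 reads, boundary inclusive).
#'
#' @param t a [probe_count_table()].
#' @param min_reads minimum total reads required per AOI.
#' @return filtered `probe_count_table`; dropped AOI ids are messaged.
#' @export
aoi_qc <- function(t, min_reads = 10000) {
  stopifnot(inherits(t, "probe_count_table"))
  if (nrow(t$counts) == 0) .fail("aoi_qc: empty probe table")
  keep <- t$aoi_meta$total_reads >= min_reads
  if (!any(keep)) .fail("aoi_qc: all AOIs below ", min_reads, " reads")
  if (any(!keep))
    message("aoi_qc: dropping ", sum(!keep), " AOI(s): ",
            paste(t$aoi_meta$aoi_id[!keep], collapse = ", "))
  probe_count_table(t$counts[keep, , drop = FALSE], t$probe_map,
                    t$aoi_meta[keep, , drop = FALSE])
}

#' Grubbs critical value
#'
#' Two-sided critical value for the Grubbs single-outlier statistic at level
#' `alpha` for `n` observations:
#' `((n-1)/sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))` with
#' `t = qt(alpha/(2n), n-2)` (upper tail).
#'
#' @param n number of observations (>= 3).
#' @param alpha significance level.
#' @return scalar critical value.
#' @export
grubbs_critical <- function(n, alpha = 0.01) {
  if (n < 3) .fail("grubbs_critical: needs n >= 3")
  t2 <- stats::qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)^2
  (n - 1) / sqrt(n) * sqrt(t2 / (n - 2 + t2))
}

#' Flag aberrant probes with a global Grubbs outlier test
#'
#' Within each (target, AOI), the Grubbs statistic
#' `G = max|x - mean(x)| / sd(x)` is computed on `log2(count + 1)` of the
#' target's probes; the most deviant probe is flagged when `G` exceeds the
#' critical value at `alpha`. Targets with fewer than three probes pass
#' untested, and zero-variance probe sets are skipped (G undefined). A probe
#' is globally excluded when flagged in at least `global_fraction` of AOIs.
#'
#' @param t a [probe_count_table()].
#' @param alpha Grubbs test level (default 0.01).
#' @param global_fraction AOI fraction at which a probe is globally excluded.
#' @return list with `local` (logical AOI x probe flag matrix), `global`
#'   (probe ids excluded globally) and `flag_fraction` per probe.
#' @export
flag_outlier_probes <- function(t, alpha = 0.01, global_fraction = 0.20) {
  stopifnot(inherits(t, "probe_count_table"))
  x <- log2(t$counts + 1)
  n_aoi <- nrow(x)
  local <- matrix(FALSE, n_aoi, ncol(x), dimnames = dimnames(x))
  targets <- split(seq_len(ncol(x)), t$probe_map$target)
  targets <- targets[names(targets) != "NEGATIVE"]
  for (cols in targets) {
    n <- length(cols)
    if (n < 3) next
    crit <- grubbs_critical(n, alpha)
    xm <- x[, cols, drop = FALSE]
    mu <- rowMeans(xm)
    s <- sqrt(rowSums((xm - mu)^2) / (n - 1))
    dev <- abs(xm - mu)
    gmax <- apply(dev, 1, max)
    hit <- s > 0 & gmax / ifelse(s > 0, s, 1) > crit
    if (any(hit)) {
      which_probe <- cols[apply(dev[hit, , drop = FALSE], 1, which.max)]
      local[cbind(which(hit), which_probe)] <- TRUE
    }
  }
  frac <- colMeans(local)
  list(local = local,
       global = colnames(x)[frac >= global_fraction],
       flag_fraction = frac)
}

#' Collapse probes to gene-level counts by geometric mean
#'
#' For each targeting gene, the unflagged probes of each AOI are collapsed to
#' their geometric mean. Zero counts are lifted to 0.5 before the log (see
#' [geo_mean()]); zero-free probe sets collapse to the exact geometric mean.
#' Genes whose probes are all globally excluded are dropped with a warning;
#' negative probes never enter the gene table.
#'
#' @param t a [probe_count_table()].
#' @param flags result of [flag_outlier_probes()], or `NULL` for no
#'   exclusions.
#' @return gene x AOI numeric matrix.
#' @export
collapse_probes <- function(t, flags = NULL) {
  stopifnot(inherits(t, "probe_count_table"))
  excluded <- if (is.null(flags)) character() else flags$global
  keep <- t$probe_map$target != "NEGATIVE" & !(t$probe_map$probe_id %in% excluded)
  dropped <- setdiff(unique(t$probe_map$target[t$probe_map$target != "NEGATIVE"]),
                     unique(t$probe_map$target[keep]))
  if (length(dropped))
    warning("collapse_probes: dropping gene(s) with no unflagged probe: ",
            paste(dropped, collapse = ", "))
  map <- t$probe_map[keep, ]
  cnt <- t$counts[, map$probe_id, drop = FALSE]
  genes <- unique(map$target)
  out <- matrix(NA_real_, length(genes), nrow(cnt),
                dimnames = list(genes, rownames(cnt)))
  idx <- split(seq_len(nrow(map)), map$target)
  for (g in genes) {
    xg <- cnt[, idx[[g]], drop = FALSE]
    out[g, ] <- exp(rowMeans(log(pmax(xg, 0.5))))
  }
  out
}

#' Pool-specific negative-probe background factors
#'
#' For each AOI and probe pool, the geometric mean of that pool's negative
#' probe counts (zeros lifted to 0.5). Used as a background QC metric: a gene
#' can be flagged below-background in an AOI when its collapsed count falls
#' under the factor of its pool.
#'
#' @param t a [probe_count_table()].
#' @return AOI x pool numeric matrix of factors.
#' @export
negative_probe_factors <- function(t) {
  stopifnot(inherits(t, "probe_count_table"))
  pools <- unique(t$probe_map$pool)
  out <- matrix(NA_real_, nrow(t$counts), length(pools),
                dimnames = list(rownames(t$counts), pools))
  for (p in pools) {
    neg <- t$probe_map$probe_id[t$probe_map$pool == p &
                                  t$probe_map$target == "NEGATIVE"]
    if (!length(neg)) .fail("negative_probe_factors: pool ", p, " has no negatives")
    xg <- t$counts[, neg, drop = FALSE]
    if (any(xg == 0))
      message("negative_probe_factors: zero negative counts floored at 0.5")
    out[, p] <- exp(rowMeans(log(pmax(xg, 0.5))))
  }
  out
}

#' Upper-quartile (Q3) normalization across AOIs
#'
#' Computes the 75th percentile (linear interpolation, type 7) of the
#' collapsed gene counts of each AOI, scales each AOI by
#' `q_i / geomean(q)`, and QC-flags AOIs whose log2 factor deviates from the
#' median by more than 3 MAD. After normalization every AOI's 75th
#' percentile equals the geometric mean of the original percentiles exactly.
#'
#' @param g gene x AOI matrix of collapsed counts.
#' @return list of class `normalized_aoi` with `values` (gene x AOI),
#'   `q3_factors` and `qc_flags`.
#' @export
q3_normalize <- function(g) {
  g <- as.matrix(g)
  q <- apply(g, 2, stats::quantile, probs = 0.75, names = FALSE, type = 7)
  if (any(q <= 0))
    .fail("q3_normalize: nonpositive 75th percentile in AOI(s): ",
          paste(colnames(g)[q <= 0], collapse = ", "))
  f <- q / exp(mean(log(q)))
  values <- sweep(g, 2, f, `/`)
  lf <- log2(f)
  dev <- abs(lf - stats::median(lf))
  madv <- stats::mad(lf)
  flags <- if (madv > 0) dev > 3 * madv else rep(FALSE, length(lf))
  structure(list(values = values, q3_factors = stats::setNames(f, colnames(g)),
                 qc_flags = stats::setNames(flags, colnames(g))),
            class = "normalized_aoi")
}

#' @export
print.normalized_aoi <- function(x, ...) {
  cat("normalized_aoi:", nrow(x$values), "genes x", ncol(x$values), "AOIs;",
      sum(x$qc_flags), "factor outlier flag(s)\n")
  invisible(x)
}

#' Morphology differential expression within a compartment
#'
#' Welch two-sided t-test per gene on `log2(normalized + 1)`, infiltrative
#' versus nodular AOIs of the given compartment. The log2 fold-change is the
#' difference of group means on the log2 scale. A gene is called significant
#' when `|log2fc| > log2fc_cut` and `p < p_cut`, both strict; BH-adjusted
#' p-values are reported alongside.
#'
#' @param n a `normalized_aoi` from [q3_normalize()].
#' @param aoi_meta AOI metadata with `aoi_id`, `compartment`, `morphology`.
#' @param compartment `"tumor"` or `"stroma"`.
#' @param log2fc_cut,p_cut significance thresholds (defaults 0.4 and 0.05).
#' @return data.frame (class `dsp_deg`) with columns `gene`, `log2fc`,
#'   `p_value`, `p_adjusted`, `mean_inf`, `mean_nod`, `significant`.
#' @export
dsp_deg <- function(n, aoi_meta, compartment, log2fc_cut = 0.4, p_cut = 0.05) {
  stopifnot(inherits(n, "normalized_aoi"))
  meta <- aoi_meta[match(colnames(n$values), aoi_meta$aoi_id), ]
  sel <- meta$compartment == compartment
  x <- log2(n$values[, sel, drop = FALSE] + 1)
  morph <- meta$morphology[sel]
  a <- x[, morph == "infiltrative", drop = FALSE]
  b <- x[, morph == "nodular", drop = FALSE]
  if (ncol(a) < 2 || ncol(b) < 2)
    .fail("dsp_deg: need >= 2 AOIs per morphology in compartment ", compartment)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- .rowvars(a); vb <- .rowvars(b)
  na <- ncol(a); nb <- ncol(b)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  p[se2 == 0] <- ifelse(ma[se2 == 0] == mb[se2 == 0], 1, 0)
  lfc <- ma - mb
  out <- data.frame(gene = rownames(x), log2fc = lfc, p_value = p,
                    p_adjusted = stats::p.adjust(p, "BH"),
                    mean_inf = ma, mean_nod = mb,
                    significant = abs(lfc) > log2fc_cut & p < p_cut,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "thresholds") <- c(log2fc_cut = log2fc_cut, p_cut = p_cut)
  class(out) <- c("dsp_deg", "data.frame")
  out
}

#' Spatial signature container
#'
#' The four compartment x morphology gene lists (tumor/stroma x
#' nodular/infiltrative), raw or contamination-filtered. Within a
#' compartment, the NOD and INF lists are disjoint by construction.
#'
#' @param t_nod,t_inf,s_nod,s_inf character gene lists.
#' @param stage `"raw"` or `"filtered"`.
#' @param overlap optional cross-compartment overlap report.
#' @return object of class `spatial_signatures`.
#' @export
spatial_signatures <- function(t_nod, t_inf, s_nod, s_inf,
                               stage = c("raw", "filtered"), overlap = NULL) {
  stage <- match.arg(stage)
  if (length(intersect(t_nod, t_inf)) || length(intersect(s_nod, s_inf)))
    .fail("spatial_signatures: NOD and INF lists must be disjoint per compartment")
  structure(list(t_nod = t_nod, t_inf = t_inf, s_nod = s_nod, s_inf = s_inf,
                 stage = stage, overlap = overlap),
            class = "spatial_signatures")
}

#' @export
print.spatial_signatures <- function(x, ...) {
  cat(sprintf("spatial_signatures (%s): T^NOD %d, T^INF %d, S^NOD %d, S^INF %d genes\n",
              x$stage, length(x$t_nod), length(x$t_inf), length(x$s_nod),
              length(x$s_inf)))
  if (!is.null(x$overlap))
    cat(sprintf("  cross-compartment overlap: %d nodular, %d infiltrative shared\n",
                length(x$overlap$nod_shared), length(x$overlap$inf_shared)))
  invisible(x)
}

#' Assemble raw spatial signatures from compartment DEG tables
#'
#' Splits the significant genes of the tumor and stroma morphology DEG
#' tables by fold-change sign into the four raw signatures, and reports the
#' per-direction cross-compartment overlaps (shared genes are a
#' cross-contamination diagnostic; they stay in both lists at this stage).
#'
#' @param deg_tumor,deg_stroma [dsp_deg()] tables.
#' @return [spatial_signatures()] with `stage = "raw"`.
#' @export
build_raw_signatures <- function(deg_tumor, deg_stroma) {
  pick <- function(d, dir) d$gene[d$significant & sign(d$log2fc) == dir]
  t_inf <- pick(deg_tumor, 1);  t_nod <- pick(deg_tumor, -1)
  s_inf <- pick(deg_stroma, 1); s_nod <- pick(deg_stroma, -1)
  spatial_signatures(t_nod, t_inf, s_nod, s_inf, stage = "raw",
                     overlap = list(nod_shared = intersect(t_nod, s_nod),
                                    inf_shared = intersect(t_inf, s_inf)))
}
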