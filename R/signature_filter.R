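#' Per-gene compartment expression profile from scRNA-seq
#'
#' For each gene: the fraction of epithelial (KRT14-positive analog) cells
#' detecting it, the fraction of stromal (all other) cells detecting it,
#' mean normalized expression in each compartment, and the detection
#' fraction per annotated cell type. This is the evidence base for the
#' cross-contamination filter.
#'
#' @param counts genes x cells raw counts (detection = count > 0).
#' @param norm matching normalized matrix.
#' @param cell_types named cell-type label per cell.
#' @param epithelial_types cell types forming the epithelial compartment.
#' @return data.frame of class `compartment_profile` with columns `gene`,
#'   `frac_pos_epithelial`, `frac_pos_stromal`, `mean_norm_epithelial`,
#'   `mean_norm_stromal`, plus attribute `frac_pos_by_type` (gene x type).
#' @export
compartment_expression_profile <- function(counts, norm, cell_types,
                                           epithelial_types) {
  cells <- intersect(colnames(counts), names(cell_types))
  types <- cell_types[cells]
  epi <- cells[types %in% epithelial_types]
  str <- cells[!(types %in% epithelial_types)]
  if (!length(epi) || !length(str))
    .fail("compartment_expression_profile: a compartment is empty")
  det <- function(cc) .rowmeans(counts[, cc, drop = FALSE] > 0)
  by_type <- sapply(sort(unique(types)),
                    function(tp) det(cells[types == tp]))
  out <- data.frame(gene = rownames(counts),
                    frac_pos_epithelial = det(epi),
                    frac_pos_stromal = det(str),
                    mean_norm_epithelial = .rowmeans(norm[, epi, drop = FALSE]),
                    mean_norm_stromal = .rowmeans(norm[, str, drop = FALSE]),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "frac_pos_by_type") <- by_type
  class(out) <- c("compartment_profile", "data.frame")
  out
}

#' Contamination-filter raw spatial signatures against scRNA-seq evidence
#'
#' Each raw signature gene is kept only if the single-cell data support
#' genuine expression by its own compartment. A tumor-signature gene is
#' retained iff (i) it is detected in at least `f_on` of epithelial cells
#' ("expressed in own compartment"); (ii) its mean normalized stromal
#' expression does not exceed `r_max` times its epithelial expression ("not
#' dominated by the adjacent compartment", the FN1/COL1A1 situation); and
#' (iii) it is not ubiquitous, i.e. not detected in at least `u_min` of the
#' cells of every annotated type. Stroma-signature genes use the mirrored
#' criteria. NOD/INF membership is preserved and every decision is logged.
#'
#' @param sig raw [spatial_signatures()].
#' @param prof a [compartment_expression_profile()].
#' @param f_on own-compartment detection floor (default 0.10).
#' @param r_max cross/own mean-expression ratio ceiling (default 3.0).
#' @param u_min per-type detection fraction defining ubiquity (default
#'   0.25).
#' @param eps ratio pseudo-denominator (default 1e-9).
#' @return filtered `spatial_signatures` with attribute `decision_log`
#'   (data.frame: gene, signature, decision, rule, statistics).
#' @export
filter_signature <- function(sig, prof, f_on = 0.10, r_max = 3.0,
                             u_min = 0.25, eps = 1e-9) {
  stopifnot(inherits(sig, "spatial_signatures"),
            inherits(prof, "compartment_profile"))
  if (sig$stage != "raw")
    warning("filter_signature: input signatures are not stage 'raw'")
  by_type <- attr(prof, "frac_pos_by_type")
  idx <- stats::setNames(seq_len(nrow(prof)), prof$gene)

  judge <- function(genes, signature_name, own_is_epithelial) {
    log_rows <- list()
    kept <- character()
    for (g in genes) {
      if (is.na(idx[g])) {
        warning("filter_signature: gene ", g, " missing from profile; dropped")
        log_rows[[g]] <- data.frame(gene = g, signature = signature_name,
                                    decision = "removed", rule = "missing",
                                    frac_pos_own = NA, ratio = NA,
                                    min_type_frac = NA)
        next
      }
      r <- prof[idx[g], ]
      own_frac <- if (own_is_epithelial) r$frac_pos_epithelial else r$frac_pos_stromal
      own_mean <- if (own_is_epithelial) r$mean_norm_epithelial else r$mean_norm_stromal
      other_mean <- if (own_is_epithelial) r$mean_norm_stromal else r$mean_norm_epithelial
      ratio <- other_mean / (own_mean + eps)
      min_type <- min(by_type[idx[g], ])
      rule <- if (own_frac < f_on) "not_expressed_in_own_compartment"
      else if (ratio > r_max) "dominated_by_other_compartment"
      else if (min_type >= u_min) "ubiquitous"
      else NA_character_
      decision <- if (is.na(rule)) "retained" else "removed"
      if (decision == "retained") kept <- c(kept, g)
      log_rows[[g]] <- data.frame(gene = g, signature = signature_name,
                                  decision = decision,
                                  rule = ifelse(is.na(rule), "", rule),
                                  frac_pos_own = own_frac, ratio = ratio,
                                  min_type_frac = min_type)
    }
    log_df <- if (length(log_rows))
      do.call(rbind, c(log_rows, list(make.row.names = FALSE)))
    else NULL
    list(kept = kept, log = log_df)
  }

  jt_nod <- judge(sig$t_nod, "t_nod", TRUE)
  jt_inf <- judge(sig$t_inf, "t_inf", TRUE)
  js_nod <- judge(sig$s_nod, "s_nod", FALSE)
  js_inf <- judge(sig$s_inf, "s_inf", FALSE)
  out <- spatial_signatures(jt_nod$kept, jt_inf$kept, js_nod$kept,
                            js_inf$kept, stage = "filtered")
  attr(out, "decision_log") <- rbind(jt_nod$log, jt_inf$log, js_nod$log,
                                     js_inf$log)
  attr(out, "params") <- c(f_on = f_on, r_max = r_max, u_min = u_min)
  out
}
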