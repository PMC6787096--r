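## Interaction-scoring chain -------------------------------------------------
##
## background correction on non-targeting control pairs -> CPM abundance
## filter -> TMM normalization -> negative-binomial differential abundance
## (T14 vs T0) -> gene-level arm aggregation -> anchor single-effect
## adjustment -> ratio-threshold synergy calls.

#' Background-correct a count matrix on control-control pairs
#'
#' For each sample, the median count of the CTRL_CTRL constructs (both
#' guides non-targeting) is subtracted from every construct, results are
#' floored at 0, and the CTRL_CTRL rows are removed.
#'
#' @param counts integer matrix (constructs x samples).
#' @param categories construct categories aligned with `rownames(counts)`
#'   (or a library data frame with `construct_id` and `category`).
#' @return corrected count matrix without CTRL_CTRL rows.
#' @export
background_correct <- function(counts, categories) {
  if (is.data.frame(categories)) {
    categories <- categories$category[match(rownames(counts),
                                            categories$construct_id)]
  }
  if (length(categories) != nrow(counts)) {
    stop("categories must align with count rows", call. = FALSE)
  }
  is_ctrl <- categories == "CTRL_CTRL"
  if (!any(is_ctrl)) stop("no CTRL_CTRL rows present", call. = FALSE)
  med <- apply(counts[is_ctrl, , drop = FALSE], 2L, stats::median)
  out <- sweep(counts, 2L, med, "-")
  out[out < 0] <- 0
  out[!is_ctrl, , drop = FALSE]
}

#' Abundance filter on counts per million
#'
#' Keeps a construct iff its CPM is at least `min_cpm` in at least
#' `min_samples` samples (CPM computed on the matrix as given, i.e. after
#' background correction).
#'
#' @param counts count matrix.
#' @param min_cpm CPM threshold (default 5).
#' @param min_samples required number of samples at or above it (default 2).
#' @return filtered matrix; attribute `n_removed` reports dropped rows.
#' @export
cpm_filter <- function(counts, min_cpm = 5, min_samples = 2L) {
  if (min_samples > ncol(counts)) {
    stop("min_samples exceeds the number of samples", call. = FALSE)
  }
  tot <- colSums(counts)
  if (any(tot <= 0)) stop("sample with zero total count", call. = FALSE)
  cpm <- sweep(counts, 2L, tot, "/") * 1e6
  keep <- rowSums(cpm >= min_cpm) >= min_samples
  out <- counts[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Trimmed-mean-of-M-values normalization factors
#'
#' Between-sample scaling factors by the published TMM estimator (double
#' trimming of M- and A-values, precision-weighted mean of the M-values,
#' factors rescaled to geometric mean 1), computed via edgeR.
#'
#' @param counts count matrix (non-negative).
#' @param reference_column index of the reference sample; `NULL` selects it
#'   by the 75th-percentile rule.
#' @param logratio_trim two-sided trim fraction on M-values (default 0.30).
#' @param sum_trim two-sided trim fraction on A-values (default 0.05).
#' @param A_cutoff lower bound on A-values entering the trimmed mean.
#' @return numeric vector of per-sample factors (geometric mean 1).
#' @export
tmm_factors <- function(counts, reference_column = NULL,
                        logratio_trim = 0.30, sum_trim = 0.05,
                        A_cutoff = -1e10) {
  if (any(colSums(counts) <= 0)) {
    stop("sample with zero total count", call. = FALSE)
  }
  f <- edgeR::calcNormFactors(as.matrix(counts), method = "TMM",
                              refColumn = reference_column,
                              logratioTrim = logratio_trim,
                              sumTrim = sum_trim, doWeighting = TRUE,
                              Acutoff = A_cutoff)
  stats::setNames(as.numeric(f), colnames(counts))
}

#' Negative-binomial differential abundance, T14 vs T0
#'
#' Fits the classic edgeR two-group model on the filtered counts with
#' TMM-scaled effective library sizes: common dispersion with optional
#' tagwise empirical-Bayes shrinkage, exact negative-binomial test, and
#' Benjamini-Hochberg FDR. Depletion at T14 gives negative logFC.
#'
#' @param counts filtered count matrix whose columns include the T0/T14
#'   samples.
#' @param sample_info data frame with `sample` and `timepoint` (`"T0"` /
#'   `"T14"`; other timepoints are ignored).
#' @param norm_factors optional TMM factors for the used columns (recycled
#'   from [tmm_factors()] on the same matrix when `NULL`).
#' @param dispersion `"tagwise"` (default) or `"common"`.
#' @param fdr_flag constructs with FDR below this are flagged `significant`
#'   (default 0.1).
#' @return data frame: `construct_id`, `logFC`, `logCPM`, `pvalue`, `fdr`,
#'   `significant`.
#' @export
differential_abundance <- function(counts, sample_info, norm_factors = NULL,
                                   dispersion = c("tagwise", "common"),
                                   fdr_flag = 0.1) {
  dispersion <- match.arg(dispersion)
  use <- sample_info$timepoint %in% c("T0", "T14")
  if (!any(sample_info$timepoint == "T0") ||
      !any(sample_info$timepoint == "T14")) {
    stop("need at least one T0 and one T14 sample", call. = FALSE)
  }
  si <- sample_info[use, ]
  m <- counts[, si$sample, drop = FALSE]
  if (any(colSums(m) <= 0)) {
    stop("sample with zero total count", call. = FALSE)
  }
  if (is.null(norm_factors)) norm_factors <- tmm_factors(m)
  grp <- factor(si$timepoint, levels = c("T0", "T14"))
  y <- edgeR::DGEList(counts = m, group = grp,
                      norm.factors = as.numeric(norm_factors))
  y <- edgeR::estimateDisp(y, robust = TRUE)
  disp <- if (dispersion == "common") y$common.dispersion else NULL
  et <- if (is.null(disp)) {
    edgeR::exactTest(y, pair = c("T0", "T14"))
  } else {
    edgeR::exactTest(y, pair = c("T0", "T14"), dispersion = disp)
  }
  tab <- et$table
  fdr <- stats::p.adjust(tab$PValue, method = "BH")
  data.frame(construct_id = rownames(tab), logFC = tab$logFC,
             logCPM = tab$logCPM, pvalue = tab$PValue, fdr = fdr,
             significant = fdr < fdr_flag,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Call genes synergistic with the anchor
#'
#' Aggregates construct-level logFC into three arms per gene -- single
#' knockout (`gCtrl-gTarget`), raw double knockout (`gAnchor-gTarget`) and
#' anchor alone (`gAnchor-gCtrl`) -- subtracts the anchor-alone phenotype
#' from the raw double phenotype (additive adjustment in log space), and
#' calls a gene when the ratio `P_single / P_double_adj` falls below
#' `ratio_threshold`.
#'
#' Under the default construct-level FDR gate, only constructs with
#' `fdr < fdr_threshold` contribute to an arm mean; an arm with no
#' significant construct is assigned phenotype 0 ("no detectable effect").
#' Ratios are only defined when the adjusted double phenotype shows real
#' depletion (`P_double_adj < -floor`) and the single phenotype does not
#' show enrichment (`P_single <= 0`); other genes are reported `UNDEFINED`
#' and never called.
#'
#' @param diff differential result from [differential_abundance()].
#' @param library construct library data frame (targets + categories).
#' @param anchor anchor gene symbol (e.g. `"TAZ"`).
#' @param ratio_threshold call threshold on the ratio (default 0.5).
#' @param fdr_threshold construct-level FDR gate (default 0.1).
#' @param floor smallest adjusted double depletion treated as a real
#'   phenotype (default 0.5 log2, i.e. ~1.4-fold depletion beyond the
#'   anchor's own effect); arm means below it are noise-scale and give
#'   meaningless ratios.
#' @param gate `"construct"` (default) applies the FDR gate before
#'   aggregation; `"none"` averages all constructs.
#' @param gate_anchor apply the FDR gate to the anchor-alone arm as well
#'   (default FALSE: that arm estimates a nuisance offset centred near 0,
#'   and averaging only its significant constructs would keep nothing but
#'   selection-biased extremes).
#' @param adjust `"subtract"` (default, additive in log space) or
#'   `"divide"` (ratio of fold changes: adjusted double logFC =
#'   `P_double_raw - P_anchor` vs `log2(2^raw / 2^anchor)` are identical, so
#'   `"divide"` instead divides the raw phenotype by the anchor phenotype in
#'   logFC units -- kept only to expose the alternative reading).
#' @return data frame with one row per gene: arm phenotypes, supporting
#'   construct counts, `ratio`, `status` (`CALLED`/`NOT_CALLED`/`UNDEFINED`)
#'   and `called`; the anchor-alone phenotype is attached as attribute
#'   `p_anchor`.
#' @export
call_interactions <- function(diff, library, anchor, ratio_threshold = 0.5,
                              fdr_threshold = 0.1, floor = 0.5,
                              gate = c("construct", "none"),
                              gate_anchor = FALSE,
                              adjust = c("subtract", "divide")) {
  gate <- match.arg(gate)
  adjust <- match.arg(adjust)
  lib <- library[match(diff$construct_id, library$construct_id), ]
  if (anyNA(lib$construct_id)) {
    stop("differential result contains constructs absent from the library",
         call. = FALSE)
  }
  all_targets <- setdiff(unique(c(library$target1, library$target2)),
                         CONTROL_TOKEN)
  if (!anchor %in% all_targets) {
    stop(sprintf("unknown anchor gene '%s'", anchor), call. = FALSE)
  }
  if (!any(library$target1 == anchor & library$target2 == CONTROL_TOKEN)) {
    stop("no anchor-control constructs in the library", call. = FALSE)
  }
  surviving <- if (gate == "construct") diff$fdr < fdr_threshold else
    rep(TRUE, nrow(diff))

  arm_single <- lib$target1 == CONTROL_TOKEN & lib$target2 != CONTROL_TOKEN
  arm_double <- lib$target1 == anchor & lib$target2 != CONTROL_TOKEN
  arm_anchor <- lib$target1 == anchor & lib$target2 == CONTROL_TOKEN

  arm_mean <- function(sel, by = NULL, gated = TRUE) {
    if (gated) sel <- sel & surviving
    if (is.null(by)) {
      if (!any(sel)) return(c(mean = 0, n = 0))
      c(mean = mean(diff$logFC[sel]), n = sum(sel))
    } else {
      mn <- tapply(diff$logFC[sel], by[sel], mean)
      nn <- tapply(diff$logFC[sel], by[sel], length)
      list(mean = mn, n = nn)
    }
  }
  p_anchor <- arm_mean(arm_anchor, gated = gate_anchor)

  genes <- sort(setdiff(unique(library$target2), CONTROL_TOKEN))
  single <- arm_mean(arm_single, lib$target2)
  dbl <- arm_mean(arm_double, lib$target2)
  p_single <- ifelse(genes %in% names(single$mean),
                     single$mean[genes], 0)
  n_single <- ifelse(genes %in% names(single$n),
                     single$n[genes], 0L)
  p_double_raw <- ifelse(genes %in% names(dbl$mean), dbl$mean[genes], NA_real_)
  n_double <- ifelse(genes %in% names(dbl$n), dbl$n[genes], 0L)

  p_double_adj <- if (adjust == "subtract") {
    p_double_raw - p_anchor[["mean"]]
  } else {
    if (abs(p_anchor[["mean"]]) < floor) p_double_raw else
      p_double_raw / abs(p_anchor[["mean"]])
  }

  ratio <- rep(NA_real_, length(genes))
  status <- rep("UNDEFINED", length(genes))
  defined <- n_double > 0L & !is.na(p_double_adj) &
    p_double_adj < -floor & p_single <= 0
  ratio[defined] <- p_single[defined] / p_double_adj[defined]
  status[defined] <- ifelse(ratio[defined] < ratio_threshold,
                            "CALLED", "NOT_CALLED")
  out <- data.frame(gene = genes, p_single = p_single,
                    p_double_raw = p_double_raw, p_double_adj = p_double_adj,
                    ratio = ratio, status = status,
                    called = status == "CALLED",
                    n_single = as.integer(n_single),
                    n_double = as.integer(n_double),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "p_anchor") <- unname(p_anchor[["mean"]])
  attr(out, "n_anchor") <- as.integer(p_anchor[["n"]])
  out
}

#' Run the full scoring chain on a raw count matrix
#'
#' Convenience wrapper: background correction, CPM filter, TMM, differential
#' abundance (T0/T14 columns) and interaction calls.
#'
#' @param counts raw count matrix (constructs x samples, incl. CTRL_CTRL
#'   rows).
#' @param library construct library data frame.
#' @param sample_info data frame with `sample` and `timepoint`.
#' @param anchor anchor gene symbol.
#' @param min_cpm,min_samples CPM filter parameters.
#' @param ... passed to [call_interactions()].
#' @return list with `corrected`, `filtered`, `norm_factors`, `diff`,
#'   `calls`.
#' @export
score_screen <- function(counts, library, sample_info, anchor,
                         min_cpm = 5, min_samples = 2L, ...) {
  corrected <- background_correct(counts, library)
  use <- sample_info$sample[sample_info$timepoint %in% c("T0", "T14")]
  filtered <- cpm_filter(corrected[, use, drop = FALSE],
                         min_cpm = min_cpm, min_samples = min_samples)
  nf <- tmm_factors(filtered)
  diff <- differential_abundance(filtered, sample_info, norm_factors = nf)
  calls <- call_interactions(diff, library, anchor, ...)
  list(corrected = corrected, filtered = filtered, norm_factors = nf,
       diff = diff, calls = calls)
}
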