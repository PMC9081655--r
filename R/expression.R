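#' Log2-transform a TPM matrix
#'
#' Cell-wise `log2(TPM + pseudocount)`; shape and labels preserved. This is
#' the transform applied to TPM tables before heatmap rendering.
#'
#' @param m A tibble whose first column is the gene id and remaining
#'   columns are numeric TPM values (as from [read_table()]).
#' @param pseudocount Added before taking logs (default 1, so TPM 0 maps
#'   to 0).
#' @return A tibble of the same shape with transformed values.
#' @export
log2_matrix <- function(m, pseudocount = 1) {
  stopifnot(is.data.frame(m), ncol(m) >= 2L)
  vals <- as.matrix(m[, -1L, drop = FALSE])
  if (any(vals < 0)) {
    abort("negative TPM value in expression matrix",
          class = "cwmyb_input_error")
  }
  out <- m
  out[, -1L] <- as.data.frame(log2(vals + pseudocount))
  out
}

# Welch t-test p-value that tolerates degenerate (constant) replicates:
# equal constant groups compare as p = 1, unequal constant groups as NA
welch_p <- function(x, y) {
  out <- tryCatch(stats::t.test(x, y)$p.value, error = function(e) NULL)
  if (!is.null(out) && is.finite(out)) return(out)
  if (isTRUE(all.equal(mean(x), mean(y)))) 1 else NA_real_
}

#' Differential-expression screen on a TPM matrix
#'
#' For each gene: `log2fc = log2((meanA + c) / (meanB + c))` with pseudo
#' count `c = 0.01` on the group mean TPM, and a two-sided Welch t-test on
#' `log2(TPM + 1)` replicate values. A gene passes the screen when it is
#' expressed (mean TPM > 0 in at least one group, or in all samples with
#' `expressed_rule = "all_samples"`), `|log2fc| > lfc_cutoff` and
#' `p < p_cutoff`.
#'
#' @param m TPM tibble (first column gene id).
#' @param group_a,group_b Character vectors of sample (column) labels for
#'   the two compared groups; each needs at least 2 replicates for the
#'   t-test.
#' @param lfc_cutoff Absolute log2 fold-change cutoff (default 1).
#' @param p_cutoff P-value cutoff (default 0.05).
#' @param pseudocount_fc Pseudocount on group-mean TPM for the fold change
#'   (default 0.01, keeping on/off genes finite).
#' @param expressed_rule `"any_group"` (default) or `"all_samples"`.
#' @param pvalues Optional named vector of precomputed p-values (by gene
#'   id) used instead of the Welch test, so externally deposited DE results
#'   can be screened verbatim.
#' @param fdr If `TRUE`, adds a Benjamini–Hochberg adjusted column `padj`
#'   and uses it for the pass flag instead of the raw p-value.
#' @return A tibble of class `myb_deg`, sorted by gene id: `gene`,
#'   `mean_a`, `mean_b`, `log2fc`, `pvalue` (and `padj` with `fdr`),
#'   `expressed`, `passes`.
#' @export
deg_screen <- function(m, group_a, group_b, lfc_cutoff = 1,
                       p_cutoff = 0.05, pseudocount_fc = 0.01,
                       expressed_rule = c("any_group", "all_samples"),
                       pvalues = NULL, fdr = FALSE) {
  expressed_rule <- match.arg(expressed_rule)
  stopifnot(is.data.frame(m), ncol(m) >= 2L)
  cols <- names(m)[-1L]
  missing_cols <- setdiff(c(group_a, group_b), cols)
  if (length(missing_cols) > 0L) {
    abort(paste0("unknown sample label(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "cwmyb_input_error")
  }
  if (length(intersect(group_a, group_b)) > 0L) {
    abort("groups must not share samples", class = "cwmyb_input_error")
  }
  if (is.null(pvalues) && (length(group_a) < 2L || length(group_b) < 2L)) {
    abort("each group needs >= 2 replicates for the Welch t-test",
          class = "cwmyb_input_error")
  }
  genes <- m[[1L]]
  va <- as.matrix(m[, group_a, drop = FALSE])
  vb <- as.matrix(m[, group_b, drop = FALSE])
  if (any(va < 0) || any(vb < 0)) {
    abort("negative TPM value", class = "cwmyb_input_error")
  }
  mean_a <- rowMeans(va)
  mean_b <- rowMeans(vb)
  log2fc <- log2((mean_a + pseudocount_fc) / (mean_b + pseudocount_fc))
  if (is.null(pvalues)) {
    pvalue <- vapply(seq_along(genes), function(i) {
      welch_p(log2(va[i, ] + 1), log2(vb[i, ] + 1))
    }, numeric(1))
  } else {
    pvalue <- unname(pvalues[genes])
  }
  expressed <- switch(expressed_rule,
                      any_group = mean_a > 0 | mean_b > 0,
                      all_samples = rowSums(cbind(va, vb) <= 0) == 0L)
  out <- tibble(gene = genes, mean_a = mean_a, mean_b = mean_b,
                log2fc = log2fc, pvalue = pvalue, expressed = expressed)
  p_used <- out$pvalue
  if (fdr) {
    out$padj <- stats::p.adjust(out$pvalue, method = "BH")
    p_used <- out$padj
  }
  out$passes <- out$expressed & abs(out$log2fc) > lfc_cutoff &
    !is.na(p_used) & p_used < p_cutoff
  out <- dplyr::arrange(out, .data$gene)
  class(out) <- c("myb_deg", class(out))
  out
}

#' Relative quantification by the comparative 2^-ddCt method
#'
#' For one gene and one treated/control pair of measurements:
#' `dCt = mean(Ct_target) - mean(Ct_reference)` per condition,
#' `ddCt = dCt_treated - dCt_control`, fold change `2^(-ddCt)`. Significance
#' is a two-sided t-test on the per-replicate `Ct_target - Ct_reference`
#' values of the two conditions; `signif` is `"**"` at p < 0.01, `"*"` at
#' p < 0.05, `""` otherwise.
#'
#' @param treated,control Tibbles (or lists) with numeric vectors
#'   `ct_target` and `ct_reference`, one value per replicate (replicates
#'   paired within a condition). All Ct values must be positive.
#' @return A one-row tibble: `dct_treated`, `dct_control`, `ddct`, `fold`,
#'   `pvalue`, `signif`.
#' @examples
#' trt <- list(ct_target = c(22, 22, 22), ct_reference = c(15, 15, 15))
#' ctl <- list(ct_target = c(25, 25, 25), ct_reference = c(15, 15, 15))
#' ddct(trt, ctl)  # fold 8
#' @export
ddct <- function(treated, control) {
  check_ct <- function(q, lab) {
    if (is.null(q$ct_target) || is.null(q$ct_reference) ||
        length(q$ct_target) == 0L || length(q$ct_reference) == 0L) {
      abort(paste0("missing target or reference Ct replicates in ", lab),
            class = "cwmyb_input_error")
    }
    if (any(q$ct_target <= 0) || any(q$ct_reference <= 0)) {
      abort(paste0("non-positive Ct value in ", lab),
            class = "cwmyb_input_error")
    }
    if (length(q$ct_target) != length(q$ct_reference)) {
      abort(paste0("unequal numbers of target and reference replicates in ",
                   lab), class = "cwmyb_input_error")
    }
  }
  check_ct(treated, "treated")
  check_ct(control, "control")
  d_trt <- treated$ct_target - treated$ct_reference
  d_ctl <- control$ct_target - control$ct_reference
  dct_t <- mean(d_trt)
  dct_c <- mean(d_ctl)
  dd <- dct_t - dct_c
  p <- if (length(d_trt) >= 2L && length(d_ctl) >= 2L) {
    welch_p(d_trt, d_ctl)
  } else {
    NA_real_
  }
  stars <- if (is.na(p)) "" else if (p < 0.01) "**" else
    if (p < 0.05) "*" else ""
  tibble(dct_treated = dct_t, dct_control = dct_c, ddct = dd,
         fold = 2^(-dd), pvalue = p, signif = stars)
}

#' qPCR screen over a long-format Ct table
#'
#' Applies [ddct()] per gene, condition and timepoint against the control
#' condition rows of the same gene (matched by timepoint when the control
#' has that timepoint, otherwise pooled).
#'
#' @param ct_long Tibble with columns `gene`, `condition`, `timepoint`,
#'   `replicate`, `ct_target`, `ct_reference`.
#' @param control_condition Label of the control/calibrator condition
#'   (default `"control"`).
#' @return A tibble of class `myb_ddct`: one row per gene x condition x
#'   timepoint with the [ddct()] columns.
#' @export
qpcr_screen <- function(ct_long, control_condition = "control") {
  need <- c("gene", "condition", "timepoint", "replicate",
            "ct_target", "ct_reference")
  missing_cols <- setdiff(need, names(ct_long))
  if (length(missing_cols) > 0L) {
    abort(paste0("Ct table missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "cwmyb_input_error")
  }
  ctl_all <- ct_long[ct_long$condition == control_condition, , drop = FALSE]
  if (nrow(ctl_all) == 0L) {
    abort(paste0("no rows for control condition '", control_condition, "'"),
          class = "cwmyb_input_error")
  }
  trt <- ct_long[ct_long$condition != control_condition, , drop = FALSE]
  groups <- unique(trt[, c("gene", "condition", "timepoint")])
  out <- purrr::pmap_dfr(groups, function(gene, condition, timepoint) {
    t_rows <- trt[trt$gene == gene & trt$condition == condition &
                    trt$timepoint == timepoint, ]
    c_rows <- ctl_all[ctl_all$gene == gene &
                        ctl_all$timepoint == timepoint, ]
    if (nrow(c_rows) == 0L) c_rows <- ctl_all[ctl_all$gene == gene, ]
    if (nrow(c_rows) == 0L) {
      abort(paste0("no control rows for gene '", gene, "'"),
            class = "cwmyb_input_error")
    }
    dplyr::bind_cols(tibble(gene = gene, condition = condition,
                            timepoint = timepoint),
                     ddct(t_rows, c_rows))
  })
  class(out) <- c("myb_ddct", class(out))
  out
}
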