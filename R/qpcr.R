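## Relative gene expression from qPCR Ct tables by the delta-delta-Ct
## (Livak) method with an internal reference gene.

#' Delta-delta-Ct for one quadruple of Ct values
#'
#' ddCt = (Ct_target,test - Ct_ref,test) - (Ct_target,ctrl - Ct_ref,ctrl);
#' fold change = efficiency^(-ddCt) with the classic amplification
#' efficiency of 2.
#'
#' @param ct_target_test,ct_ref_test,ct_target_ctrl,ct_ref_ctrl finite Ct
#'   values (cycles).
#' @param efficiency amplification efficiency (default 2, classic Livak).
#' @return list with `ddct` and `fold_change`.
#' @export
delta_delta_ct <- function(ct_target_test, ct_ref_test, ct_target_ctrl,
                           ct_ref_ctrl, efficiency = 2) {
  vals <- c(ct_target_test = ct_target_test, ct_ref_test = ct_ref_test,
            ct_target_ctrl = ct_target_ctrl, ct_ref_ctrl = ct_ref_ctrl)
  if (any(!is.finite(vals)))
    stop("missing Ct value(s): ",
         paste(names(vals)[!is.finite(vals)], collapse = ", "))
  ddct <- (ct_target_test - ct_ref_test) - (ct_target_ctrl - ct_ref_ctrl)
  list(ddct = ddct, fold_change = efficiency^(-ddct))
}

#' Relative expression report from a Ct table
#'
#' Computes per-replicate dCt (target minus reference gene within each
#' sample, replicates paired by index), then ddCt of each test sample
#' against the MEAN control-sample dCt, and reports fold changes
#' `efficiency^(-ddCt)` with standard errors propagated on the log2 scale.
#' Each gene/sample is tested against the control-sample dCt replicates
#' with a Welch t-test. The control sample is reported as exactly 1. The
#' reference gene is a required explicit parameter.
#'
#' @param ct data.frame (sample, gene, replicate, ct).
#' @param reference_gene internal-control gene, measured in every sample.
#' @param control_sample name of the control condition.
#' @param efficiency amplification efficiency (default 2).
#' @return data.frame (gene, sample, control_sample, n, ddct, fold_change,
#'   se_log2, t_stat, p_value, stars). Genes whose reference is missing in
#'   a sample are skipped and listed in attribute `"skipped"`. Ct values
#'   outside the typical 10-40 range are logged via warning, not rejected.
#' @export
expression_report <- function(ct, reference_gene, control_sample,
                              efficiency = 2) {
  stopifnot(is.data.frame(ct),
            all(c("sample", "gene", "replicate", "ct") %in% names(ct)))
  if (missing(reference_gene) || missing(control_sample))
    stop("reference_gene and control_sample must be given explicitly")
  if (!reference_gene %in% ct$gene)
    stop("reference gene '", reference_gene, "' absent from the Ct table")
  if (!control_sample %in% ct$sample)
    stop("control sample '", control_sample, "' absent from the Ct table")
  odd <- is.finite(ct$ct) & (ct$ct < 10 | ct$ct > 40)
  if (any(odd))
    warning(sum(odd), " Ct value(s) outside the typical 10-40 range")

  # replicate-wise dCt per (sample, gene)
  dct <- function(sample, gene) {
    tg <- ct[ct$sample == sample & ct$gene == gene, ]
    rf <- ct[ct$sample == sample & ct$gene == reference_gene, ]
    i <- match(tg$replicate, rf$replicate)
    if (anyNA(i)) return(NULL)  # reference missing for some replicate
    tg$ct - rf$ct[i]
  }

  genes <- setdiff(unique(ct$gene), reference_gene)
  samples <- unique(ct$sample)
  skipped <- character()
  rows <- list()
  for (g in genes) {
    dct_ctrl <- dct(control_sample, g)
    if (is.null(dct_ctrl) || length(dct_ctrl) < 2) {
      skipped <- c(skipped, paste0(g, "@", control_sample))
      next
    }
    for (s in samples) {
      dct_s <- dct(s, g)
      if (is.null(dct_s) || length(dct_s) < 2) {
        if (s != control_sample) skipped <- c(skipped, paste0(g, "@", s))
        next
      }
      if (s == control_sample) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, sample = s, control_sample = control_sample,
          n = length(dct_s), ddct = 0, fold_change = 1,
          se_log2 = stats::sd(dct_s) / sqrt(length(dct_s)),
          t_stat = 0, p_value = 1, stringsAsFactors = FALSE)
        next
      }
      ddct_rep <- dct_s - mean(dct_ctrl)
      se <- sqrt(stats::var(dct_s) / length(dct_s) +
                   stats::var(dct_ctrl) / length(dct_ctrl))
      ht <- welch_t_test(dct_s, dct_ctrl)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, sample = s, control_sample = control_sample,
        n = length(dct_s), ddct = mean(ddct_rep),
        fold_change = efficiency^(-mean(ddct_rep)), se_log2 = se,
        t_stat = ht$t, p_value = ht$p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no gene/sample pair had usable replicates")
  out$stars <- stars_from_p(out$p_value)
  rownames(out) <- NULL
  structure(out, skipped = skipped)
}
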