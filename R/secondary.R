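## Secondary-screen validation: per-gene significance testing of relative
## reporter activity against the negative control.

#' Welch two-sample t-test
#'
#' Unequal-variance (Welch) t statistic with Welch-Satterthwaite degrees of
#' freedom and a two-sided p-value. The degenerate case where both samples
#' have zero variance is handled explicitly: equal means report t = 0,
#' p = 1; unequal means report an infinite statistic with p = 0.
#'
#' @param a,b numeric samples with at least 2 finite values each.
#' @param pooled if `TRUE`, use the pooled-variance Student test instead.
#' @return list with components `t`, `df`, `p`.
#' @export
welch_t_test <- function(a, b, pooled = FALSE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("each sample needs at least 2 finite values")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = NA_real_, p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = NA_real_, p = 0))
  }
  ht <- stats::t.test(a, b, var.equal = pooled)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Validate candidate genes against the negative control
#'
#' For each candidate, tests its per-well relative reporter activities
#' against the negative-control wells (Welch t-test by default). A gene is
#' validated when the test is significant at `alpha` AND its mean activity
#' is below the control mean (direction gate: validation requires
#' reduction). Raw p-values are starred; no multiple-testing correction is
#' applied unless `adjust = "BH"`.
#'
#' @param activity numeric vector of per-well relative activities.
#' @param gene parallel character vector of gene labels (the control's wells
#'   carry the control label).
#' @param control label of the negative-control gene (e.g. `"neg_lacz"`).
#' @param alpha significance level for validation.
#' @param pooled use the pooled-variance Student test instead of Welch.
#' @param adjust `"none"` (default, mirrors raw-star reporting) or `"BH"`.
#' @return data.frame (gene, n, mean_rel_activity, control_mean, t_stat,
#'   df, p_value, stars, validated), sorted by p ascending; skipped genes
#'   (fewer than 2 usable wells) are reported in attribute `"skipped"`.
#' @export
validate_candidates <- function(activity, gene, control, alpha = 0.05,
                                pooled = FALSE,
                                adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(length(activity) == length(gene))
  ctrl <- activity[gene == control & is.finite(activity)]
  if (length(ctrl) < 2)
    stop("control '", control, "' has fewer than 2 usable wells")
  cand <- setdiff(unique(gene), control)
  skipped <- character()
  rows <- lapply(cand, function(g) {
    x <- activity[gene == g & is.finite(activity)]
    if (length(x) < 2) {
      skipped <<- c(skipped, g)
      return(NULL)
    }
    ht <- welch_t_test(x, ctrl, pooled = pooled)
    data.frame(gene = g, n = length(x), mean_rel_activity = mean(x),
               control_mean = mean(ctrl), t_stat = ht$t, df = ht$df,
               p_value = ht$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    stop("no candidate has enough usable wells")
  if (adjust == "BH") out$p_value <- stats::p.adjust(out$p_value, "BH")
  out$stars <- stars_from_p(out$p_value)
  out$validated <- out$p_value <= alpha &
    out$mean_rel_activity < out$control_mean
  out <- out[order(out$p_value, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, skipped = skipped)
}

#' Run the secondary validation screen from raw plates
#'
#' Applies the same plate-median correction and F/R ratio computation as
#' the primary screen to a (typically 96-well) validation plate set, then
#' tests every mapped gene against the negative-control wells via
#' [validate_candidates()].
#'
#' @inheritParams screen_zscore
#' @param control_role map role of the negative control (default
#'   `"neg_lacz"`).
#' @param alpha significance level.
#' @param pooled,adjust see [validate_candidates()].
#' @return see [validate_candidates()].
#' @export
secondary_screen <- function(measurements, map, control_role = "neg_lacz",
                             alpha = 0.05, pooled = FALSE,
                             adjust = c("none", "BH")) {
  stopifnot(all(c("experiment", "plate", "well", "channel", "intensity")
                %in% names(measurements)),
            all(c("plate", "well", "gene", "role") %in% names(map)))
  key <- function(p, w) paste(p, w, sep = ":")
  map$key <- key(map$plate, map$well)
  measurements$key <- key(measurements$plate, measurements$well)
  m <- merge(measurements, map[, c("key", "gene", "role")], by = "key")
  grp <- interaction(m$experiment, m$plate, m$channel, drop = TRUE)
  m$corrected <- NA_real_
  for (g in levels(grp)) {
    idx <- which(grp == g)
    m$corrected[idx] <- plate_median_correct(m$intensity[idx], m$role[idx])
  }
  wk <- paste(m$experiment, m$key, sep = "@")
  fi <- m$channel == "F"; ri <- m$channel == "R"
  wkey <- unique(wk)
  f <- m$corrected[fi][match(wkey, wk[fi])]
  r <- m$corrected[ri][match(wkey, wk[ri])]
  gene <- m$gene[match(wkey, wk)]
  ratio <- as.numeric(relative_activity(f, r))
  ctrl_gene <- unique(m$gene[m$role == control_role])
  if (length(ctrl_gene) != 1)
    stop("expected exactly one control gene with role '", control_role, "'")
  validate_candidates(ratio, gene, control = ctrl_gene, alpha = alpha,
                      pooled = pooled, adjust = adjust)
}
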