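## Primary screen analysis: plate-median correction, relative reporter
## activity, dual-effect masking, replicate averaging, robust Z-scores,
## control-derived cut-off and candidate calling.

#' Plate-median correction
#'
#' Divides every well's intensity on one plate/channel by the median
#' intensity of the plate's TEST wells (control wells are excluded from the
#' median but are corrected with it). After correction the median of the
#' test wells is exactly 1, which removes multiplicative plate effects.
#'
#' @param intensity numeric vector of raw intensities for one plate and one
#'   channel.
#' @param role character vector (same length): `"test"` marks library wells;
#'   any other value marks a control well.
#' @param min_test minimum number of positive test wells required.
#' @return numeric vector of corrected values, with the median used stored
#'   in attribute `"plate_median"`.
#' @export
plate_median_correct <- function(intensity, role, min_test = 4L) {
  stopifnot(length(intensity) == length(role))
  ok <- role == "test" & is.finite(intensity) & intensity > 0
  if (sum(ok) < min_test)
    stop("degenerate plate: only ", sum(ok),
         " positive test wells (need >= ", min_test, ")")
  med <- stats::median(intensity[ok])
  if (!is.finite(med) || med <= 0)
    stop("degenerate plate: nonpositive test-well median")
  structure(intensity / med, plate_median = med)
}

#' Per-well relative reporter activity
#'
#' Ratio of the corrected experimental reporter (F.Luc) to the corrected
#' invariant co-reporter (R.Luc). Wells whose Renilla reading is zero,
#' negative or missing are excluded (NA) rather than producing silent NaN;
#' the exclusion mask is returned as attribute `"excluded"`.
#'
#' @param f,r numeric vectors of plate-corrected F and R values per well.
#' @return numeric vector of ratios, NA where excluded.
#' @export
relative_activity <- function(f, r) {
  stopifnot(length(f) == length(r))
  bad <- !is.finite(r) | r <= 0 | !is.finite(f)
  out <- rep(NA_real_, length(f))
  out[!bad] <- f[!bad] / r[!bad]
  structure(out, excluded = bad)
}

#' Average replicate wells into per-gene values
#'
#' Means within each experiment over a gene's replicate wells, then the mean
#' of the experiment means. Genes observed in a single experiment keep that
#' experiment's mean and are flagged; genes with no usable wells are dropped
#' (reported via attribute `"dropped"`).
#'
#' @param gene,experiment,value parallel vectors of per-well observations;
#'   NA values are unusable wells.
#' @return data.frame (gene, value, n_experiments, single_experiment).
#' @export
aggregate_replicates <- function(gene, experiment, value) {
  stopifnot(length(gene) == length(experiment),
            length(gene) == length(value))
  keep <- is.finite(value)
  dropped <- setdiff(unique(gene), unique(gene[keep]))
  gene <- gene[keep]; experiment <- experiment[keep]; value <- value[keep]
  if (length(value) == 0) {
    return(structure(data.frame(gene = character(), value = numeric(),
                                n_experiments = integer(),
                                single_experiment = logical(),
                                stringsAsFactors = FALSE),
                     dropped = dropped))
  }
  per_exp <- stats::aggregate(value,
                              list(gene = gene, experiment = experiment),
                              mean)
  res <- stats::aggregate(per_exp$x, list(gene = per_exp$gene),
                          function(v) c(mean(v), length(v)))
  out <- data.frame(gene = res$gene, value = res$x[, 1],
                    n_experiments = as.integer(res$x[, 2]),
                    stringsAsFactors = FALSE)
  out$single_experiment <- out$n_experiments == 1L
  structure(out[order(out$gene), , drop = FALSE], dropped = dropped)
}

#' Robust reduction Z-score
#'
#' Z = (median(reference) - value) / (1.4826 * MAD(reference)). The sign
#' convention measures REDUCTION: genes whose knockdown lowers reporter
#' activity score positive, matching positive scores for trx/ash1 positive
#' controls. If the MAD is zero the scale falls back to the sample SD with a
#' warning; if that is also zero the reference is degenerate.
#'
#' @param values numeric vector to score.
#' @param reference numeric vector defining the empirical null (location and
#'   scale). Fewer than 8 usable values triggers a warning.
#' @return numeric vector of Z-scores.
#' @export
robust_z <- function(values, reference) {
  reference <- reference[is.finite(reference)]
  if (length(reference) < 2)
    stop("degenerate reference: need at least 2 finite values")
  if (length(reference) < 8)
    warning("robust_z reference has fewer than 8 values; ",
            "scale estimate will be unstable")
  loc <- stats::median(reference)
  sc <- stats::mad(reference)  # 1.4826 * median absolute deviation
  if (sc == 0) {
    warning("reference MAD is zero; falling back to sample SD")
    sc <- stats::sd(reference)
  }
  if (!is.finite(sc) || sc == 0)
    stop("degenerate reference: zero spread")
  (loc - values) / sc
}

#' Derive the hit-calling cut-off from positive-control Z-scores
#'
#' The screen's cut-off is the floor of the smallest positive-control
#' Z-score: trxG-member knockdowns scoring 6.13 and 6.15 yield a cut-off of
#' 6. Conservative by construction and overridable by explicit
#' configuration.
#'
#' @param control_z numeric vector of positive-control Z-scores.
#' @return integer cut-off.
#' @export
derive_cutoff <- function(control_z) {
  control_z <- control_z[is.finite(control_z)]
  if (length(control_z) == 0)
    stop("no positive-control Z-scores available to derive a cut-off")
  floor(min(control_z))
}

#' Call screen hits
#'
#' Hits are unmasked genes whose reduction Z-score meets the cut-off, sorted
#' by Z descending with ties broken by gene id ascending.
#'
#' @param scores data.frame with columns `gene`, `z` and optionally
#'   `masked` (missing column means nothing is masked).
#' @param cutoff numeric Z threshold.
#' @return the hit rows of `scores`, ranked.
#' @export
call_hits <- function(scores, cutoff) {
  stopifnot(is.data.frame(scores), all(c("gene", "z") %in% names(scores)),
            is.numeric(cutoff), length(cutoff) == 1)
  masked <- if ("masked" %in% names(scores)) scores$masked else
    rep(FALSE, nrow(scores))
  sel <- !masked & is.finite(scores$z) & scores$z >= cutoff
  out <- scores[sel, , drop = FALSE]
  out <- out[order(-out$z, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit the primary-screen hit-calling model
#'
#' Runs the complete primary analysis of a dual-reporter RNAi screen:
#' per-plate median correction of both channels, per-well F/R relative
#' activity, replicate averaging within then across experiments, masking of
#' genes that also depress the Renilla channel (general transcription /
#' viability artifacts), robust Z-scoring of the relative activity against
#' an empirical null, cut-off derivation from the trxG positive controls,
#' and candidate calling.
#'
#' @param measurements data.frame (experiment, plate, well, channel,
#'   intensity) of raw plate-reader values; channel is `"F"` or `"R"`.
#' @param map data.frame (plate, well, gene, role); role is `"test"` or one
#'   of the control roles (`pos_trx`, `pos_ash1`, `pos_fluc`, `neg_lacz`,
#'   `neg_gfp`).
#' @param mask_cutoff Renilla-channel reduction Z at or above which a gene
#'   is masked (default 3).
#' @param cutoff explicit hit-calling Z cut-off; if `NULL` (default) it is
#'   derived from the `pos_trx` / `pos_ash1` control Z-scores via
#'   [derive_cutoff()].
#' @param reference population supplying the empirical null for Z-scoring:
#'   `"test_genes"` (all unmasked library genes, the default) or
#'   `"neg_controls"` (per-well ratios of the negative-control wells).
#' @return an object of class `screen_zscore`; see [hits()],
#'   [summary.screen_zscore()], [plot.screen_zscore()].
#' @export
screen_zscore <- function(measurements, map, mask_cutoff = 3, cutoff = NULL,
                          reference = c("test_genes", "neg_controls")) {
  reference <- match.arg(reference)
  stopifnot(is.data.frame(measurements), is.data.frame(map),
            all(c("experiment", "plate", "well", "channel", "intensity")
                %in% names(measurements)),
            all(c("plate", "well", "gene", "role") %in% names(map)),
            mask_cutoff > 0)
  excl <- empty_exclusions()

  key <- function(p, w) paste(p, w, sep = ":")
  map$key <- key(map$plate, map$well)
  if (anyDuplicated(map$key))
    stop("library map assigns two roles to the same well")
  measurements$key <- key(measurements$plate, measurements$well)
  unmapped <- !(measurements$key %in% map$key)
  if (any(unmapped)) {
    excl <- rbind(excl, exclusion_record(
      "plate_correction", unique(measurements$key[unmapped]),
      "well_not_in_library_map"))
    measurements <- measurements[!unmapped, , drop = FALSE]
  }
  missing_wells <- setdiff(map$key, measurements$key)
  if (length(missing_wells) > 0)
    warning(length(missing_wells), " mapped wells have no measurement")

  m <- merge(measurements, map[, c("key", "gene", "role")], by = "key")

  # 1. plate-median correction per (experiment, plate, channel)
  grp <- interaction(m$experiment, m$plate, m$channel, drop = TRUE)
  m$corrected <- NA_real_
  for (g in levels(grp)) {
    idx <- which(grp == g)
    m$corrected[idx] <- plate_median_correct(m$intensity[idx], m$role[idx])
  }

  # 2. per-well F/R relative activity
  wk <- paste(m$experiment, m$key, sep = "@")
  fi <- m$channel == "F"; ri <- m$channel == "R"
  wells <- unique(data.frame(wkey = wk, experiment = m$experiment,
                             key = m$key, stringsAsFactors = FALSE))
  wells$f <- m$corrected[fi][match(wells$wkey, wk[fi])]
  wells$r <- m$corrected[ri][match(wells$wkey, wk[ri])]
  wells$gene <- map$gene[match(wells$key, map$key)]
  wells$role <- map$role[match(wells$key, map$key)]
  ratio <- relative_activity(wells$f, wells$r)
  if (any(attr(ratio, "excluded")))
    excl <- rbind(excl, exclusion_record(
      "relative_activity", wells$wkey[attr(ratio, "excluded")],
      "renilla_nonpositive_or_missing"))
  wells$ratio <- as.numeric(ratio)

  # 3. replicate averaging (per gene: within experiment, then across)
  agg_ratio <- aggregate_replicates(wells$gene, wells$experiment,
                                    wells$ratio)
  agg_r <- aggregate_replicates(wells$gene, wells$experiment, wells$r)
  agg_f <- aggregate_replicates(wells$gene, wells$experiment, wells$f)
  if (length(attr(agg_ratio, "dropped")) > 0)
    excl <- rbind(excl, exclusion_record(
      "aggregate_replicates", attr(agg_ratio, "dropped"),
      "no_usable_wells"))

  scores <- agg_ratio
  names(scores)[names(scores) == "value"] <- "rel_activity"
  scores$role <- map$role[match(scores$gene, map$gene)]
  scores$r_activity <- agg_r$value[match(scores$gene, agg_r$gene)]
  scores$f_activity <- agg_f$value[match(scores$gene, agg_f$gene)]

  is_test <- scores$role == "test"

  # 4. Renilla-channel Z and dual-effect masking (test genes only)
  scores$r_channel_z <- robust_z(scores$r_activity,
                                 scores$r_activity[is_test])
  scores$masked <- is_test & scores$r_channel_z >= mask_cutoff

  # 5. reduction Z of relative activity; masked genes are excluded from the
  #    reference population (second pass)
  ref_values <- switch(reference,
    test_genes = scores$rel_activity[is_test & !scores$masked],
    neg_controls = wells$ratio[wells$role %in% c("neg_lacz", "neg_gfp") &
                                 is.finite(wells$ratio)])
  scores$z <- robust_z(scores$rel_activity, ref_values)

  # 6. cut-off from trxG positive controls unless given explicitly
  derived <- is.null(cutoff)
  if (derived) {
    pos_z <- scores$z[scores$role %in% c("pos_trx", "pos_ash1")]
    cutoff <- derive_cutoff(pos_z)
  }

  # 7. candidate calling among unmasked test genes
  test_scores <- scores[is_test, , drop = FALSE]
  hit_tab <- call_hits(test_scores[, c("gene", "rel_activity", "z",
                                       "r_channel_z", "masked")], cutoff)
  scores$hit <- is_test & scores$gene %in% hit_tab$gene

  structure(list(
    scores = scores[order(scores$role != "test", -scores$z), , drop = FALSE],
    hits = hit_tab, cutoff = cutoff, derived_cutoff = derived,
    mask_cutoff = mask_cutoff, reference = reference,
    exclusions = excl, n_wells = nrow(wells),
    call = match.call()), class = "screen_zscore")
}

#' Extract called candidates
#'
#' @param object a fitted object.
#' @param ... passed to methods.
#' @return ranked candidate table.
#' @export
hits <- function(object, ...) UseMethod("hits")

#' @rdname hits
#' @export
hits.screen_zscore <- function(object, ...) object$hits

#' @export
print.screen_zscore <- function(x, ...) {
  st <- x$scores[x$scores$role == "test", ]
  cat("Dual-reporter RNAi screen Z-score fit\n")
  cat(sprintf("  %d test genes over %d wells; cut-off Z >= %g (%s)\n",
              nrow(st), x$n_wells, x$cutoff,
              if (x$derived_cutoff) "derived from positive controls"
              else "user supplied"))
  cat(sprintf("  %d masked (dual-channel, R Z >= %g), %d candidates\n",
              sum(st$masked), x$mask_cutoff, nrow(x$hits)))
  invisible(x)
}

#' Summary of a screen fit
#'
#' @param object a `screen_zscore` fit.
#' @param n number of top candidates to display.
#' @param ... unused.
#' @export
summary.screen_zscore <- function(object, n = 10, ...) {
  print(object)
  ctrl <- object$scores[object$scores$role != "test",
                        c("gene", "rel_activity", "z")]
  cat("\nControl scores:\n")
  print(ctrl, row.names = FALSE, digits = 3)
  cat("\nTop candidates:\n")
  print(utils::head(object$hits, n), row.names = FALSE, digits = 3)
  if (nrow(object$exclusions) > 0) {
    cat("\nExclusions:\n")
    tab <- table(object$exclusions$stage, object$exclusions$reason)
    print(tab)
  }
  invisible(object)
}

#' Coefficients (per-gene Z-scores) of a screen fit
#'
#' @param object a `screen_zscore` fit.
#' @param ... unused.
#' @return named numeric vector of test-gene reduction Z-scores.
#' @export
coef.screen_zscore <- function(object, ...) {
  st <- object$scores[object$scores$role == "test", ]
  stats::setNames(st$z, st$gene)
}

#' Scatter plot of per-gene corrected channel activities
#'
#' Plots mean plate-corrected Firefly against Renilla activity per gene,
#' marking masked genes, candidates and control roles — the classic
#' dual-reporter screen scatter.
#'
#' @param x a `screen_zscore` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.screen_zscore <- function(x, ...) {
  s <- x$scores
  col <- ifelse(s$role != "test", "red3",
                ifelse(s$masked, "grey60",
                       ifelse(s$hit, "magenta3", "grey20")))
  pch <- ifelse(s$role != "test", 17, 16)
  graphics::plot(s$r_activity, s$f_activity, col = col, pch = pch,
                 xlab = "corrected R.Luc activity",
                 ylab = "corrected F.Luc activity", ...)
  graphics::legend("topleft", bty = "n", pch = c(16, 16, 16, 17),
                   col = c("grey20", "magenta3", "grey60", "red3"),
                   legend = c("test", "candidate", "masked", "control"))
  invisible(x)
}
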