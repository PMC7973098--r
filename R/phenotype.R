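## Ordinal phenotype scoring for genetic-interaction crosses: extra-sex-comb
## severity distributions and A5-to-A4 transformation penetrance.

#' Standard ordinal severity categories
#'
#' Extra-sex-comb severity (`-` none, `+` 1-2 hairs on the 2nd leg, `++`
#' more than three hairs on the 2nd leg, `+++` additionally 1-2 hairs on
#' the 3rd leg, `++++` strong combs on both 2nd and 3rd leg pairs) and the
#' two-category A5-to-A4 transformation penetrance table.
#'
#' @name phenotype_categories
#' @export
SEVERITY_CATEGORIES <- c("-", "+", "++", "+++", "++++")

#' @rdname phenotype_categories
#' @export
PENETRANCE_CATEGORIES <- c("not_transformed", "transformed")

#' Per-cross category proportions
#'
#' Converts phenotype counts into per-replicate proportions (summing to 1
#' per replicate) and reports the replicate mean and standard error per
#' (cross, category).
#'
#' @param counts data.frame (cross, replicate, category, count).
#' @param categories fixed ordered category set; defaults to the categories
#'   present, in first-appearance order.
#' @return list with `proportions` (cross, replicate, category, proportion,
#'   total) and `summary` (cross, category, mean, se, n_replicates).
#' @export
category_proportions <- function(counts, categories = NULL) {
  stopifnot(is.data.frame(counts),
            all(c("cross", "replicate", "category", "count")
                %in% names(counts)),
            all(counts$count >= 0))
  if (is.null(categories)) categories <- unique(counts$category)
  stopifnot(all(counts$category %in% categories))
  rep_key <- interaction(counts$cross, counts$replicate, drop = TRUE)
  totals <- tapply(counts$count, rep_key, sum)
  if (any(totals == 0)) stop("empty replicate: no flies scored")
  prop <- counts
  prop$total <- as.integer(totals[as.character(rep_key)])
  prop$proportion <- prop$count / prop$total
  prop$category <- factor(prop$category, levels = categories)

  agg <- stats::aggregate(
    proportion ~ cross + category, data = prop,
    FUN = function(v) c(mean = mean(v),
                        se = stats::sd(v) / sqrt(length(v)),
                        n = length(v)))
  summ <- data.frame(cross = agg$cross, category = agg$category,
                     mean = agg$proportion[, "mean"],
                     se = agg$proportion[, "se"],
                     n_replicates = as.integer(agg$proportion[, "n"]),
                     stringsAsFactors = FALSE)
  summ <- summ[order(summ$cross, summ$category), ]
  rownames(summ) <- NULL
  list(proportions = prop[, c("cross", "replicate", "category", "count",
                              "total", "proportion")],
       summary = summ)
}

#' Compare two crosses category by category
#'
#' Welch t-tests on replicate-level proportions for every category, with
#' star annotations. A *suppression* call is made when the severe
#' categories (`+++`, `++++`) are significantly lower in cross A than in
#' cross B; an *enhancement* call when the penetrance category
#' (`transformed`) is significantly higher in A. Categories with zero
#' variance in both crosses and equal means report t = 0, p = 1. A pooled
#' chi-square test on the summed counts is reported alongside.
#'
#' @param counts data.frame (cross, replicate, category, count).
#' @param cross_a,cross_b cross ids to compare (A vs B).
#' @param categories fixed ordered category set.
#' @param alpha significance level for the calls.
#' @return list with `tests` (category, mean_a, mean_b, t_stat, p_value,
#'   stars), `suppression`, `enhancement` (logicals), and `chisq_p` from
#'   the pooled chi-square.
#' @export
compare_crosses <- function(counts, cross_a, cross_b, categories = NULL,
                            alpha = 0.05) {
  stopifnot(all(c(cross_a, cross_b) %in% counts$cross))
  cp <- category_proportions(counts[counts$cross %in% c(cross_a, cross_b), ],
                             categories)
  prop <- cp$proportions
  categories <- levels(prop$category)
  rows <- lapply(categories, function(cat) {
    pa <- prop$proportion[prop$cross == cross_a & prop$category == cat]
    pb <- prop$proportion[prop$cross == cross_b & prop$category == cat]
    if (length(pa) < 2 || length(pb) < 2)
      stop("need >= 2 replicates per cross (category ", cat, ")")
    ht <- welch_t_test(pa, pb)
    data.frame(category = cat, mean_a = mean(pa), mean_b = mean(pb),
               t_stat = ht$t, p_value = ht$p, stringsAsFactors = FALSE)
  })
  tests <- do.call(rbind, rows)
  tests$stars <- stars_from_p(tests$p_value)

  sig_lower <- tests$p_value <= alpha & tests$mean_a < tests$mean_b
  sig_higher <- tests$p_value <= alpha & tests$mean_a > tests$mean_b
  severe <- tests$category %in% c("+++", "++++")
  penet <- tests$category == "transformed"
  suppression <- any(sig_lower[severe])
  enhancement <- any(sig_higher[penet])

  pooled <- tapply(counts$count[counts$cross %in% c(cross_a, cross_b)],
                   list(counts$cross[counts$cross %in% c(cross_a, cross_b)],
                        factor(counts$category[counts$cross %in%
                                                 c(cross_a, cross_b)],
                               levels = categories)), sum)
  chisq_p <- tryCatch(
    suppressWarnings(stats::chisq.test(pooled[, colSums(pooled) > 0,
                                              drop = FALSE])$p.value),
    error = function(e) NA_real_)

  list(tests = tests, suppression = suppression, enhancement = enhancement,
       chisq_p = chisq_p)
}
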