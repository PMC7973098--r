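# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (and, where easy, base R shortcuts): medians by sorting,
# Welch statistics from first principles, annotation by exhaustive search.

oracle_median <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
}

oracle_robust_z <- function(values, reference) {
  m <- oracle_median(reference)
  raw_mad <- oracle_median(abs(reference - m))
  (m - values) / (1.4826 * raw_mad)
}

oracle_welch <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

oracle_ddct <- function(ct_tt, ct_rt, ct_tc, ct_rc) {
  d_test <- ct_tt - ct_rt
  d_ctrl <- ct_tc - ct_rc
  dd <- d_test - d_ctrl
  list(ddct = dd, fold = 2^(-dd))
}

# Exhaustive nearest-TSS annotation, one peak at a time.
oracle_annotate_one <- function(chrom, start, end, genes) {
  mid <- floor((start + end) / 2)
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  g <- g[order(g$gene_id), , drop = FALSE]
  best <- NULL; best_d <- Inf
  for (i in seq_len(nrow(g))) {
    d <- if (g$strand[i] == "+") mid - g$tss[i] else g$tss[i] - mid
    if (abs(d) < best_d) {  # strict: earlier gene_id wins ties
      best_d <- abs(d); best <- list(gene = g$gene_id[i], d = d)
    }
  }
  genic <- FALSE
  for (i in seq_len(nrow(g)))
    if (g$start[i] <= mid && mid < g$end[i]) genic <- TRUE
  cat_ <- if (abs(best$d) <= 1000) "Promoter (<=1kb)"
  else if (abs(best$d) <= 2000) "Promoter (1-2kb)"
  else if (abs(best$d) <= 3000) "Promoter (2-3kb)"
  else if (genic) "Genic" else "Distal Intergenic"
  list(gene = best$gene, distance = best$d, category = cat_)
}

# Nested-loop set overlap counts.
oracle_overlap <- function(a, b) {
  a <- unique(a); b <- unique(b)
  both <- 0L; only_a <- 0L
  for (x in a) {
    found <- FALSE
    for (y in b) if (identical(x, y)) found <- TRUE
    if (found) both <- both + 1L else only_a <- only_a + 1L
  }
  only_b <- 0L
  for (y in b) {
    found <- FALSE
    for (x in a) if (identical(x, y)) found <- TRUE
    if (!found) only_b <- only_b + 1L
  }
  c(both = both, only_a = only_a, only_b = only_b)
}

# A small random gene universe for annotation property tests: irregularly
# spaced genes on short chromosomes.
random_gene_table <- function(n_genes, chrom_sizes) {
  chrom <- sample(names(chrom_sizes), n_genes, replace = TRUE)
  start <- vapply(chrom, function(ch)
    sample.int(chrom_sizes[[ch]] - 6000L, 1), integer(1))
  len <- sample(1000:5000, n_genes, replace = TRUE)
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  data.frame(gene_id = sprintf("rg%03d", seq_len(n_genes)), chrom = chrom,
             strand = strand,
             tss = ifelse(strand == "+", start, start + len - 1L),
             start = start, end = start + len, stringsAsFactors = FALSE)
}
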