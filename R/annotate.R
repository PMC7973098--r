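## Peak annotation relative to transcription start sites: promoter distance
## bins, genic, distal intergenic; peak-to-gene assignment; TSS-centered
## signal matrices; gene-set overlap counts; ChIP-qPCR enrichment ratios.

#' Read a BED file of peak intervals
#'
#' Expects BED6 (chrom, start, end, name, score, strand) in 0-based
#' half-open coordinates; three-column BED is accepted with generated names
#' and zero scores. Malformed lines raise errors naming the line; intervals
#' with start >= end and duplicate peak names are rejected.
#'
#' @param path file path.
#' @return data.frame (chrom, start, end, name, score, strand).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  idx <- which(keep)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  n <- lengths(parts)
  if (any(n < 3))
    stop("BED parse error at line ", idx[which(n < 3)[1]],
         ": fewer than 3 fields")
  get <- function(k, default) vapply(parts, function(p)
    if (length(p) >= k) p[k] else default, character(1))
  start <- suppressWarnings(as.integer(get(2, NA)))
  end <- suppressWarnings(as.integer(get(3, NA)))
  bad <- is.na(start) | is.na(end)
  if (any(bad))
    stop("BED parse error at line ", idx[which(bad)[1]],
         ": non-integer coordinates")
  if (any(start < 0))
    stop("BED coordinate error at line ", idx[which(start < 0)[1]],
         ": negative start")
  if (any(start >= end))
    stop("BED coordinate-order error at line ", idx[which(start >= end)[1]],
         ": start >= end (0-based half-open expected)")
  name <- get(4, NA_character_)
  name[is.na(name)] <- sprintf("peak%05d", which(is.na(name)))
  if (anyDuplicated(name))
    stop("duplicate peak name '", name[anyDuplicated(name)], "' at line ",
         idx[anyDuplicated(name)])
  score <- suppressWarnings(as.numeric(get(5, "0")))
  score[is.na(score)] <- 0
  strand <- get(6, ".")
  data.frame(chrom = get(1, NA_character_), start = start, end = end,
             name = name, score = score, strand = strand,
             stringsAsFactors = FALSE)
}

#' Write peaks as BED6
#'
#' @param peaks data.frame as returned by [read_bed()].
#' @param path output path.
#' @export
write_bed <- function(peaks, path) {
  stopifnot(all(c("chrom", "start", "end", "name") %in% names(peaks)))
  score <- if ("score" %in% names(peaks)) peaks$score else 0
  strand <- if ("strand" %in% names(peaks)) peaks$strand else "."
  utils::write.table(
    data.frame(peaks$chrom, peaks$start, peaks$end, peaks$name, score,
               strand),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene/TSS table
#'
#' Tab-separated with header columns gene_id, chrom, strand, tss, start,
#' end (0-based half-open bodies). The TSS anchor must be consistent with
#' the strand: `tss == start` on `+`, `tss == end - 1` on `-`.
#'
#' @param path file path.
#' @return data.frame of gene models.
#' @export
read_gene_table <- function(path) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "strand", "tss", "start", "end")
  if (!all(need %in% names(g)))
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(g$gene_id))
    stop("duplicate gene_id in gene table")
  if (any(g$start >= g$end)) stop("gene with start >= end")
  if (!all(g$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  bad <- ifelse(g$strand == "+", g$tss != g$start, g$tss != g$end - 1)
  if (any(bad))
    stop("TSS inconsistent with strand for gene ", g$gene_id[which(bad)[1]])
  g[, need]
}

#' Write a gene/TSS table
#' @param genes gene-model data.frame.
#' @param path output path.
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

peak_midpoint <- function(start, end) (start + end) %/% 2L

#' Signed TSS distance of a peak
#'
#' Distance from the peak midpoint (floor of (start+end)/2) to a gene's
#' TSS, signed in gene orientation: negative values are upstream of the
#' TSS, positive downstream; the sign flips on minus-strand genes.
#'
#' @param peak one-row data.frame (chrom, start, end) or a list with those
#'   fields.
#' @param gene one-row data.frame (chrom, strand, tss).
#' @return signed base distance.
#' @export
tss_distance <- function(peak, gene) {
  if (any(peak$chrom != gene$chrom))
    stop("cross-chromosome comparison: peak on ", peak$chrom[1],
         ", gene on ", gene$chrom[1])
  mid <- peak_midpoint(peak$start, peak$end)
  ifelse(gene$strand == "+", mid - gene$tss, gene$tss - mid)
}

#' Annotate peaks relative to TSSs
#'
#' Each peak is assigned its nearest gene by absolute signed TSS distance
#' (ties broken by gene_id ascending) and exactly one category:
#' `Promoter (<=1kb)` for |d| <= 1000, `Promoter (1-2kb)` for
#' 1000 < |d| <= 2000, `Promoter (2-3kb)` for 2000 < |d| <= 3000; beyond
#' 3 kb, `Genic` when the peak midpoint falls inside any gene body, else
#' `Distal Intergenic`. Categories partition the peaks.
#'
#' @param peaks data.frame (chrom, start, end, name, ...).
#' @param genes data.frame of gene models (gene_id, chrom, strand, tss,
#'   start, end).
#' @return data.frame (name, chrom, midpoint, gene, distance, category).
#' @export
annotate_peaks <- function(peaks, genes) {
  stopifnot(nrow(genes) >= 1)
  out <- vector("list", length(unique(peaks$chrom)))
  i <- 0L
  for (ch in unique(peaks$chrom)) {
    p <- peaks[peaks$chrom == ch, , drop = FALSE]
    if (nrow(p) == 0) next
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (nrow(g) == 0)
      stop("no genes on chromosome ", ch, " to annotate against")
    g <- g[order(g$gene_id), , drop = FALSE]
    mid <- peak_midpoint(p$start, p$end)
    d <- outer(mid, g$tss, "-")
    flip <- g$strand == "-"
    d[, flip] <- -d[, flip, drop = FALSE]
    nearest <- apply(abs(d), 1, which.min)  # first min = gene_id tie-break
    dist <- d[cbind(seq_len(nrow(p)), nearest)]
    genic <- vapply(mid, function(m)
      any(g$start <= m & m < g$end), logical(1))
    ad <- abs(dist)
    category <- ifelse(ad <= 1000, "Promoter (<=1kb)",
                ifelse(ad <= 2000, "Promoter (1-2kb)",
                ifelse(ad <= 3000, "Promoter (2-3kb)",
                ifelse(genic, "Genic", "Distal Intergenic"))))
    i <- i + 1L
    out[[i]] <- data.frame(name = p$name, chrom = ch, midpoint = mid,
                           gene = g$gene_id[nearest], distance = dist,
                           category = category, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[match(peaks$name, res$name), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Gene set of annotated peaks
#'
#' @param annotation output of [annotate_peaks()].
#' @param categories restrict to these categories (default: all).
#' @return sorted character vector of unique gene ids.
#' @export
peak_gene_sets <- function(annotation, categories = NULL) {
  a <- annotation
  if (!is.null(categories)) a <- a[a$category %in% categories, ]
  sort(unique(a$gene))
}

#' Overlap counts of two gene sets
#'
#' Exact set algebra for Venn rendering.
#'
#' @param a,b character vectors (treated as sets).
#' @return named integer vector: `both`, `only_a`, `only_b`.
#' @export
overlap_counts <- function(a, b) {
  a <- unique(a); b <- unique(b)
  c(both = length(intersect(a, b)),
    only_a = length(setdiff(a, b)),
    only_b = length(setdiff(b, a)))
}

#' TSS-centered binned signal matrix
#'
#' Per-gene signal profile around the TSS: rows are genes (strand-oriented,
#' so upstream is always left), columns are bins across
#' \[-flank, +flank\); values are the mean per-base signal in each bin,
#' where the signal at a base is the sum of scores of peaks covering it.
#' Genes whose window runs off a chromosome end are zero-padded and flagged
#' in attribute `"edge_genes"`. Rows are ordered by descending row sum.
#'
#' @param peaks peak data.frame (chrom, start, end, score).
#' @param genes gene-model data.frame.
#' @param chrom_sizes named vector of chromosome lengths.
#' @param flank half-window in bases (must be a multiple of `bin`).
#' @param bin bin width in bases.
#' @return numeric matrix, rownames gene ids, colnames bin start offsets.
#' @export
tss_matrix <- function(peaks, genes, chrom_sizes, flank = 1000L,
                       bin = 50L) {
  stopifnot(flank %% bin == 0, flank > 0, bin > 0)
  nb <- 2L * (flank %/% bin)
  mat <- matrix(0, nrow = nrow(genes), ncol = nb,
                dimnames = list(genes$gene_id,
                                seq(-flank, flank - bin, by = bin)))
  edge <- character()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    w0 <- g$tss - flank
    cov <- numeric(2L * flank)  # window coverage, 0-padded at edges
    p <- peaks[peaks$chrom == g$chrom & peaks$end > w0 &
                 peaks$start < w0 + 2L * flank, , drop = FALSE]
    if (w0 < 0 || w0 + 2L * flank > chrom_sizes[[g$chrom]])
      edge <- c(edge, g$gene_id)
    if (nrow(p) > 0) {
      for (j in seq_len(nrow(p))) {
        lo <- max(p$start[j], w0, 0) - w0
        hi <- min(p$end[j], w0 + 2L * flank, chrom_sizes[[g$chrom]]) - w0
        if (hi > lo) cov[(lo + 1):hi] <- cov[(lo + 1):hi] + p$score[j]
      }
    }
    if (g$strand == "-") cov <- rev(cov)
    mat[i, ] <- colMeans(matrix(cov, nrow = bin))
  }
  mat <- mat[order(-rowSums(mat)), , drop = FALSE]
  structure(mat, edge_genes = edge)
}

#' ChIP-qPCR enrichment ratios
#'
#' Per-region ratio of immunoprecipitated (IP) signal over the control
#' signal (both on an already-normalized scale such as percent input).
#' Regions with zero control signal are excluded with a logged reason.
#'
#' @param region character vector of region ids.
#' @param ip,control numeric nonnegative signals, parallel to `region`.
#' @param threshold call a region enriched when ratio > threshold
#'   (default 2).
#' @return data.frame (region, ip, control, ratio, enriched); excluded
#'   regions in attribute `"excluded"`.
#' @export
chip_qpcr_enrichment <- function(region, ip, control, threshold = 2) {
  stopifnot(length(region) == length(ip), length(ip) == length(control))
  if (any(ip < 0, na.rm = TRUE) || any(control < 0, na.rm = TRUE))
    stop("validation error: negative signal input")
  bad <- !is.finite(control) | control == 0 | !is.finite(ip)
  out <- data.frame(region = region[!bad], ip = ip[!bad],
                    control = control[!bad],
                    ratio = ip[!bad] / control[!bad],
                    stringsAsFactors = FALSE)
  out$enriched <- out$ratio > threshold
  structure(out, excluded = region[bad])
}
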