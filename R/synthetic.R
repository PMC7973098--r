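## Synthetic-data generators: plates, Ct tables, genome fixtures, phenotype
## counts. Each generator plants a known ground truth so every downstream
## stage can be tested for exact parameter recovery.

CONTROL_ROLES <- c("pos_trx", "pos_ash1", "pos_fluc", "neg_lacz", "neg_gfp")

#' Screen design
#'
#' Describes the geometry of a dual-reporter RNAi screen: how many genes, how
#' many replicate wells per gene, how many independent experiments, the plate
#' format and the per-plate control wells. Defaults mirror a kinome-scale
#' screen: 400 genes in triplicate on six 384-well (16 x 24) plates per
#' experiment, the whole experiment performed twice, with positive controls
#' (trx, ash1 and reporter dsRNA) and negative controls (LacZ, GFP) on every
#' plate.
#'
#' @param n_genes number of test genes.
#' @param wells_per_gene replicate wells per gene within one experiment.
#' @param n_experiments independent repetitions of the whole screen.
#' @param plate_rows,plate_cols plate format (16 x 24 = 384-well).
#' @param n_plates plates per experiment.
#' @param controls_per_plate named integer vector: wells per control role per
#'   plate. Roles are `pos_trx`, `pos_ash1`, `pos_fluc`, `neg_lacz`,
#'   `neg_gfp`; every plate carries at least one well of each role.
#' @param seed integer master seed for the generator.
#' @return an object of class `screen_design`.
#' @export
screen_design <- function(n_genes = 400L, wells_per_gene = 3L,
                          n_experiments = 2L, plate_rows = 16L,
                          plate_cols = 24L, n_plates = 6L,
                          controls_per_plate = c(pos_trx = 3L, pos_ash1 = 3L,
                                                 pos_fluc = 3L, neg_lacz = 3L,
                                                 neg_gfp = 3L),
                          seed = 42L) {
  stopifnot(n_genes >= 1, wells_per_gene >= 1, n_experiments >= 1,
            plate_rows >= 1, plate_cols >= 1, n_plates >= 1)
  if (!setequal(names(controls_per_plate), CONTROL_ROLES))
    stop("controls_per_plate must name exactly the roles: ",
         paste(CONTROL_ROLES, collapse = ", "))
  if (any(controls_per_plate < 1))
    stop("every plate must carry at least one well of each control role")
  d <- list(n_genes = as.integer(n_genes),
            wells_per_gene = as.integer(wells_per_gene),
            n_experiments = as.integer(n_experiments),
            plate_rows = as.integer(plate_rows),
            plate_cols = as.integer(plate_cols),
            n_plates = as.integer(n_plates),
            controls_per_plate = controls_per_plate[CONTROL_ROLES],
            seed = as.integer(seed))
  capacity <- d$n_plates * (d$plate_rows * d$plate_cols -
                              sum(d$controls_per_plate))
  if (d$n_genes * d$wells_per_gene > capacity)
    stop("capacity error: ", d$n_genes * d$wells_per_gene,
         " test wells requested but only ", capacity, " available")
  structure(d, class = "screen_design")
}

#' Effect model for the synthetic screen
#'
#' Statistical structure of the planted effects. Hits reduce only the Firefly
#' (F) channel, emulating loss of activation-dependent reporter expression;
#' "general" genes reduce both channels, emulating an impact on general
#' transcription, translation or cell survival (these are the genes the
#' analysis must mask). Intensities carry a multiplicative log-normal plate
#' factor and multiplicative log-normal per-well noise.
#'
#' @param hit_fraction fraction of genes planted as trxG-like hits.
#' @param hit_f_reduction fractional F-channel reduction for hits (0.7 means
#'   F drops to 30 percent of baseline).
#' @param general_fraction fraction of genes reducing both channels.
#' @param general_reduction fractional reduction of both channels for them.
#' @param plate_effect_sd SD of the log-scale multiplicative plate factor.
#' @param well_cv per-well multiplicative noise, as a coefficient of
#'   variation.
#' @param baseline_f,baseline_r baseline intensities (arbitrary luminescence
#'   units) of the two channels.
#' @return an object of class `effect_model`.
#' @export
effect_model <- function(hit_fraction = 0.05, hit_f_reduction = 0.7,
                         general_fraction = 0.02, general_reduction = 0.5,
                         plate_effect_sd = 0.2, well_cv = 0.15,
                         baseline_f = 10000, baseline_r = 5000) {
  stopifnot(hit_fraction >= 0, hit_fraction <= 1,
            hit_f_reduction > 0, hit_f_reduction <= 1,
            general_fraction >= 0, general_reduction >= 0,
            general_reduction < 1,
            plate_effect_sd >= 0, well_cv >= 0,
            baseline_f > 0, baseline_r > 0)
  if (hit_fraction + general_fraction > 1)
    stop("hit_fraction + general_fraction must be <= 1")
  structure(list(hit_fraction = hit_fraction,
                 hit_f_reduction = hit_f_reduction,
                 general_fraction = general_fraction,
                 general_reduction = general_reduction,
                 plate_effect_sd = plate_effect_sd, well_cv = well_cv,
                 baseline_f = baseline_f, baseline_r = baseline_r),
            class = "effect_model")
}

# log-normal sigma giving a multiplicative coefficient of variation cv
lnorm_sigma <- function(cv) sqrt(log(1 + cv^2))

# Plate layout shared by all experiments: control wells first (fixed role
# order, column-major from A1), then consecutive triplicate blocks of genes.
screen_layout <- function(design) {
  wells <- well_names(design$plate_rows, design$plate_cols)
  per_plate_ctrl <- rep(names(design$controls_per_plate),
                        design$controls_per_plate)
  gene_ids <- sprintf("g%03d", seq_len(design$n_genes))
  # genes are split into near-equal consecutive blocks, one block per plate,
  # so every plate carries test wells alongside its controls
  breaks <- floor(seq(0, design$n_genes, length.out = design$n_plates + 1))
  map <- vector("list", design$n_plates)
  for (p in seq_len(design$n_plates)) {
    n_ctrl <- length(per_plate_ctrl)
    n_free <- length(wells) - n_ctrl
    block <- gene_ids[seq_len(breaks[p + 1] - breaks[p]) + breaks[p]]
    genes_here <- rep(block, each = design$wells_per_gene)
    take <- length(genes_here)
    if (take > n_free)
      stop("capacity error: plate ", p, " needs ", take,
           " test wells but has ", n_free)
    map[[p]] <- data.frame(
      plate = p,
      well = wells[seq_len(n_ctrl + take)],
      gene = c(per_plate_ctrl, genes_here),
      role = c(per_plate_ctrl, rep("test", take)),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, map)
}

#' Simulate a dual-reporter RNAi screen
#'
#' Generates raw plate-reader measurements (one Firefly and one Renilla
#' reading per occupied well per experiment), the library map, and the
#' planted ground truth. Control wells behave as planted effects: `pos_fluc`
#' ablates the F channel (95 percent reduction), `pos_trx` / `pos_ash1`
#' reduce F by `hit_f_reduction`, negative controls are neutral. Output is
#' deterministic for a fixed design seed.
#'
#' @param design a [screen_design()].
#' @param effects an [effect_model()].
#' @return a list with components `measurements` (data.frame: experiment,
#'   plate, well, channel, intensity), `map` (plate, well, gene, role) and
#'   `truth` (gene, label) where label is one of `hit`, `general`, `neutral`
#'   or `control:<role>`.
#' @export
simulate_screen <- function(design = screen_design(),
                            effects = effect_model()) {
  stopifnot(inherits(design, "screen_design"),
            inherits(effects, "effect_model"))
  map <- screen_layout(design)
  gene_ids <- sprintf("g%03d", seq_len(design$n_genes))

  with_seed(sub_seed(design$seed, "screen"), {
    n_hit <- round(effects$hit_fraction * design$n_genes)
    n_gen <- round(effects$general_fraction * design$n_genes)
    shuffled <- sample(gene_ids)
    label <- stats::setNames(rep("neutral", design$n_genes), gene_ids)
    if (n_hit > 0) label[shuffled[seq_len(n_hit)]] <- "hit"
    if (n_gen > 0) label[shuffled[n_hit + seq_len(n_gen)]] <- "general"

    # F-channel and R-channel effect multipliers per map row
    eff_f <- rep(1, nrow(map)); eff_r <- rep(1, nrow(map))
    gl <- label[map$gene]
    eff_f[!is.na(gl) & gl == "hit"] <- 1 - effects$hit_f_reduction
    eff_f[!is.na(gl) & gl == "general"] <- 1 - effects$general_reduction
    eff_r[!is.na(gl) & gl == "general"] <- 1 - effects$general_reduction
    eff_f[map$role %in% c("pos_trx", "pos_ash1")] <- 1 - effects$hit_f_reduction
    eff_f[map$role == "pos_fluc"] <- 0.05

    sig <- lnorm_sigma(effects$well_cv)
    out <- vector("list", design$n_experiments * 2L)
    i <- 0L
    for (e in seq_len(design$n_experiments)) {
      for (ch in c("F", "R")) {
        pf <- exp(stats::rnorm(design$n_plates, 0, effects$plate_effect_sd))
        base <- if (ch == "F") effects$baseline_f else effects$baseline_r
        eff <- if (ch == "F") eff_f else eff_r
        noise <- exp(stats::rnorm(nrow(map), 0, sig))
        i <- i + 1L
        out[[i]] <- data.frame(
          experiment = e, plate = map$plate, well = map$well, channel = ch,
          intensity = base * eff * pf[map$plate] * noise,
          stringsAsFactors = FALSE)
      }
    }
    meas <- do.call(rbind, out)
    rownames(meas) <- NULL
    stopifnot(all(is.finite(meas$intensity)), all(meas$intensity > 0))

    ctrl <- unique(map$role[map$role != "test"])
    truth <- data.frame(
      gene = c(gene_ids, ctrl),
      label = c(unname(label), paste0("control:", ctrl)),
      stringsAsFactors = FALSE)
    list(measurements = meas, map = map, truth = truth)
  })
}

#' Simulate a qPCR Ct table
#'
#' Generates cycle-threshold values such that, at zero noise, the fold change
#' of each gene in each condition recovered by the delta-delta-Ct method
#' equals the planted effect exactly. The reference gene amplifies at a fixed
#' Ct in every sample; target genes shift by -log2(fold) relative to the
#' control condition. Noise is additive Gaussian on the Ct scale.
#'
#' @param conditions character vector of sample names; the first is the
#'   control condition unless `control` says otherwise.
#' @param genes character vector of target gene names (reference excluded).
#' @param reference_gene internal-control gene (e.g. `"Actin"`).
#' @param effects data.frame (sample, gene, fold) of planted fold changes
#'   relative to the control condition; omitted pairs default to fold 1.
#' @param noise_sd additive Gaussian noise SD in cycles.
#' @param n_replicates replicates per (sample, gene).
#' @param control control condition name.
#' @param baseline_ct,reference_ct control-condition Ct of targets and the
#'   reference gene.
#' @param seed integer seed.
#' @return data.frame (sample, gene, replicate, ct).
#' @export
simulate_ct <- function(conditions, genes, reference_gene = "Actin",
                        effects = NULL, noise_sd = 0, n_replicates = 3L,
                        control = conditions[1], baseline_ct = 25,
                        reference_ct = 20, seed = 1L) {
  stopifnot(length(conditions) >= 1, length(genes) >= 1, noise_sd >= 0)
  if (reference_gene %in% genes)
    stop("reference_gene must not appear among the target genes")
  fold <- matrix(1, nrow = length(genes), ncol = length(conditions),
                 dimnames = list(genes, conditions))
  if (!is.null(effects)) {
    stopifnot(all(c("sample", "gene", "fold") %in% names(effects)))
    if (any(effects$fold <= 0))
      stop("parameter error: planted fold changes must be positive")
    for (i in seq_len(nrow(effects)))
      fold[effects$gene[i], effects$sample[i]] <- effects$fold[i]
  }
  fold[, control] <- 1

  grid <- expand.grid(replicate = seq_len(n_replicates),
                      gene = c(reference_gene, genes), sample = conditions,
                      stringsAsFactors = FALSE)[, c("sample", "gene",
                                                    "replicate")]
  is_ref <- grid$gene == reference_gene
  true_ct <- ifelse(is_ref, reference_ct,
                    baseline_ct - log2(fold[cbind(
                      ifelse(is_ref, genes[1], grid$gene), grid$sample)]))
  with_seed(sub_seed(seed, "ct"), {
    grid$ct <- true_ct + stats::rnorm(nrow(grid), 0, noise_sd)
    stopifnot(all(is.finite(grid$ct)))
    grid
  })
}

#' Simulate a secondary (validation) screen plate
#'
#' Generates a single-plate dual-reporter validation experiment in the same
#' measurement dialect as [simulate_screen()]: selected candidate genes in
#' replicate wells plus negative-control (LacZ-type) wells, each gene with a
#' planted F-channel reduction.
#'
#' @param genes character vector of candidate gene ids.
#' @param f_reduction named numeric vector of planted fractional F-channel
#'   reductions per gene (0 = no effect); genes absent from the vector get 0.
#' @param wells_per_gene replicate wells per gene.
#' @param control_wells number of negative-control wells.
#' @param well_cv per-well multiplicative noise CV.
#' @param baseline_f,baseline_r baseline channel intensities.
#' @param plate_rows,plate_cols plate format (8 x 12 = 96-well).
#' @param seed integer seed.
#' @return list with `measurements` and `map` in the screen dialect.
#' @export
simulate_validation <- function(genes, f_reduction = NULL,
                                wells_per_gene = 3L, control_wells = 6L,
                                well_cv = 0.1, baseline_f = 10000,
                                baseline_r = 5000, plate_rows = 8L,
                                plate_cols = 12L, seed = 1L) {
  stopifnot(length(genes) >= 1, wells_per_gene >= 2, control_wells >= 2)
  red <- stats::setNames(rep(0, length(genes)), genes)
  if (!is.null(f_reduction)) {
    stopifnot(!is.null(names(f_reduction)),
              all(f_reduction >= 0), all(f_reduction < 1))
    red[intersect(names(f_reduction), genes)] <-
      f_reduction[intersect(names(f_reduction), genes)]
  }
  wells <- well_names(plate_rows, plate_cols)
  gene_col <- c(rep("neg_lacz", control_wells),
                rep(genes, each = wells_per_gene))
  if (length(gene_col) > length(wells))
    stop("capacity error: ", length(gene_col), " wells requested on a ",
         length(wells), "-well plate")
  map <- data.frame(plate = 1L, well = wells[seq_along(gene_col)],
                    gene = gene_col,
                    role = ifelse(gene_col == "neg_lacz", "neg_lacz",
                                  "test"),
                    stringsAsFactors = FALSE)
  eff <- ifelse(map$role == "test", 1 - red[map$gene], 1)
  sig <- lnorm_sigma(well_cv)
  with_seed(sub_seed(seed, "screen"), {
    f <- baseline_f * eff * exp(stats::rnorm(nrow(map), 0, sig))
    r <- baseline_r * exp(stats::rnorm(nrow(map), 0, sig))
    meas <- rbind(
      data.frame(experiment = 1L, plate = 1L, well = map$well,
                 channel = "F", intensity = f, stringsAsFactors = FALSE),
      data.frame(experiment = 1L, plate = 1L, well = map$well,
                 channel = "R", intensity = r, stringsAsFactors = FALSE))
    list(measurements = meas, map = map)
  })
}

ANNOTATION_CATEGORIES <- c("Promoter (<=1kb)", "Promoter (1-2kb)",
                           "Promoter (2-3kb)", "Genic", "Distal Intergenic")

# Exact largest-remainder apportionment of n into fractions p
apportion <- function(n, p) {
  q <- n * p / sum(p)
  k <- floor(q)
  extra <- order(q - k, decreasing = TRUE)[seq_len(n - sum(k))]
  k[extra] <- k[extra] + 1
  as.integer(k)
}

#' Simulate a genome fixture with planted peak categories
#'
#' Lays genes out on a regular grid (20 kb spacing, 5 kb bodies, alternating
#' strands) and places ChIP peaks at controlled positions relative to a host
#' TSS so that the true annotation category of every peak is known: promoter
#' bins at |d| <= 1, 1-2 and 2-3 kb, genic (midpoint inside the body beyond
#' 3 kb of any TSS), and distal intergenic (outside all bodies, > 3 kb from
#' all TSSs).
#'
#' @param n_genes number of genes on the grid.
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param n_peaks number of peaks.
#' @param mix numeric vector of 5 placement fractions over the categories
#'   `Promoter (<=1kb)`, `Promoter (1-2kb)`, `Promoter (2-3kb)`, `Genic`,
#'   `Distal Intergenic`; must sum to 1. Counts are apportioned exactly.
#' @param peak_width width of each peak in bases.
#' @param seed integer seed.
#' @return list with `genes` (gene_id, chrom, strand, tss, start, end),
#'   `peaks` (chrom, start, end, name, score, strand) in 0-based half-open
#'   coordinates, and `truth` (name, category, gene, distance).
#' @export
simulate_genome <- function(n_genes = 50L,
                            chrom_sizes = c(chr2L = 1e6, chr2R = 1e6),
                            n_peaks = 1000L,
                            mix = c(0.5, 0.15, 0.1, 0.1, 0.15),
                            peak_width = 200L, seed = 1L) {
  stopifnot(length(mix) == 5, all(mix >= 0), abs(sum(mix) - 1) < 1e-8,
            peak_width >= 2, n_peaks >= 0, n_genes >= 1)
  spacing <- 20000L; body <- 5000L; first <- 10000L
  slots_per_chrom <- pmax(0L, (as.integer(chrom_sizes) - first - 15000L -
                                 as.integer(peak_width)) %/% spacing + 1L)
  if (sum(slots_per_chrom) < n_genes)
    stop("parameter error: chromosomes too small for ", n_genes,
         " gene slots (capacity ", sum(slots_per_chrom), ")")
  chrom <- rep(names(chrom_sizes), slots_per_chrom)[seq_len(n_genes)]
  slot <- unlist(lapply(slots_per_chrom, seq_len),
                 use.names = FALSE)[seq_len(n_genes)] - 1L
  anchor <- first + slot * spacing
  strand <- rep(c("+", "-"), length.out = n_genes)
  genes <- data.frame(
    gene_id = sprintf("gene%04d", seq_len(n_genes)),
    chrom = chrom, strand = strand,
    tss = ifelse(strand == "+", anchor, anchor + body - 1L),
    start = anchor, end = anchor + body, stringsAsFactors = FALSE)

  if (n_peaks == 0) {
    peaks <- data.frame(chrom = character(), start = integer(),
                        end = integer(), name = character(),
                        score = numeric(), strand = character(),
                        stringsAsFactors = FALSE)
    truth <- data.frame(name = character(), category = character(),
                        gene = character(), distance = integer(),
                        stringsAsFactors = FALSE)
    return(list(genes = genes, peaks = peaks, truth = truth))
  }

  counts <- apportion(n_peaks, mix)
  with_seed(sub_seed(seed, "genome"), {
    category <- rep(ANNOTATION_CATEGORIES, counts)
    host <- sample(seq_len(n_genes), n_peaks, replace = TRUE)
    sign <- sample(c(-1L, 1L), n_peaks, replace = TRUE)
    d <- integer(n_peaks)
    for (i in seq_len(n_peaks)) {
      d[i] <- switch(category[i],
        "Promoter (<=1kb)" = sign[i] * sample.int(1000L, 1),
        "Promoter (1-2kb)" = sign[i] * (1000L + sample.int(1000L, 1)),
        "Promoter (2-3kb)" = sign[i] * (2000L + sample.int(1000L, 1)),
        "Genic"            = 3100L + sample.int(1700L, 1),
        "Distal Intergenic" = NA_integer_)
    }
    g <- genes[host, ]
    mid <- ifelse(g$strand == "+", g$tss + d, g$tss - d)
    distal <- category == "Distal Intergenic"
    if (any(distal)) {
      # between-slot gap, > 3 kb from every TSS and outside all bodies;
      # the recorded truth is the genuinely nearest gene, which for a gap
      # position may be the neighbouring slot rather than the host
      jit <- sample(-2000:2000, sum(distal), replace = TRUE)
      mid[distal] <- anchor[host[distal]] + 12000L + jit
      for (k in which(distal)) {
        gc <- genes[genes$chrom == g$chrom[k], , drop = FALSE]
        dk <- ifelse(gc$strand == "+", mid[k] - gc$tss, gc$tss - mid[k])
        nearest <- which.min(abs(dk))  # gene ids ascend with row order
        host[k] <- match(gc$gene_id[nearest], genes$gene_id)
        d[k] <- dk[nearest]
      }
      g <- genes[host, ]
    }
    start <- as.integer(mid) - peak_width %/% 2L
    peaks <- data.frame(
      chrom = g$chrom, start = start, end = start + as.integer(peak_width),
      name = sprintf("peak%05d", seq_len(n_peaks)),
      score = round(stats::runif(n_peaks, 1, 100), 2), strand = ".",
      stringsAsFactors = FALSE)
    stopifnot(all(peaks$start >= 0),
              all(peaks$end <= chrom_sizes[peaks$chrom]))
    truth <- data.frame(name = peaks$name, category = category,
                        gene = g$gene_id, distance = as.integer(d),
                        stringsAsFactors = FALSE)
    list(genes = genes, peaks = peaks, truth = truth)
  })
}

#' Simulate ordinal phenotype counts
#'
#' Multinomial draws over ordinal phenotype categories (e.g. extra-sex-comb
#' severity `-`, `+`, `++`, `+++`, `++++`, or the two-category A5-to-A4
#' transformation table), one draw per replicate per cross.
#'
#' @param probs matrix of per-cross category probabilities (rows = crosses,
#'   columns = categories; rows must sum to 1) with dimnames set.
#' @param n_flies flies scored per replicate.
#' @param n_replicates replicates per cross.
#' @param seed integer seed.
#' @return data.frame (cross, replicate, category, count); per (cross,
#'   replicate) the counts sum to `n_flies`.
#' @export
simulate_phenotypes <- function(probs, n_flies = 200L, n_replicates = 3L,
                                seed = 1L) {
  stopifnot(is.matrix(probs), !is.null(rownames(probs)),
            !is.null(colnames(probs)), n_flies >= 1, n_replicates >= 1)
  if (any(probs < 0) || any(abs(rowSums(probs) - 1) > 1e-8))
    stop("parameter error: each cross's probabilities must be nonnegative ",
         "and sum to 1")
  with_seed(sub_seed(seed, "phenotype"), {
    out <- vector("list", nrow(probs) * n_replicates)
    i <- 0L
    for (cr in rownames(probs)) {
      draws <- stats::rmultinom(n_replicates, n_flies, probs[cr, ])
      for (r in seq_len(n_replicates)) {
        i <- i + 1L
        out[[i]] <- data.frame(cross = cr, replicate = r,
                               category = colnames(probs),
                               count = draws[, r], stringsAsFactors = FALSE)
      }
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}
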