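## End-to-end orchestration: synthesize inputs, run every analysis stage in
## dependency order, and record a machine-readable run manifest.

#' Transcribed candidate table from the published primary screen
#'
#' The 27 shortlisted candidates of the kinome-wide screen with their
#' reduction Z-scores, annotation symbols and secondary-screen outcome
#' (`Yes` validated, `No` not validated, `Not checked` not retested).
#'
#' @return data.frame (gene, z_score, annotation_symbol,
#'   secondary_outcome).
#' @export
table1_candidates <- function() {
  path <- system.file("extdata", "table1_candidates.tsv",
                      package = "trxscreen", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Default demo configuration
#'
#' A complete pipeline configuration exercising every stage on synthetic
#' data at the screen's native scale (400 genes, triplicate wells, six
#' 384-well plates, two experiments).
#'
#' @param outdir output directory for stage artifacts.
#' @param seed master seed; every stage's randomness derives from it.
#' @return nested configuration list accepted by [run_pipeline()].
#' @export
demo_config <- function(outdir = tempfile("trxscreen_run_"), seed = 42L) {
  list(
    seed = as.integer(seed),
    outdir = outdir,
    stages = c("synth", "primary", "secondary", "qpcr", "annotate",
               "phenotype"),
    screen = list(n_genes = 400L, wells_per_gene = 3L, n_experiments = 2L,
                  n_plates = 6L,
                  hit_fraction = 0.05, hit_f_reduction = 0.7,
                  general_fraction = 0.02, general_reduction = 0.5,
                  plate_effect_sd = 0.2, well_cv = 0.15),
    primary = list(mask_cutoff = 3, cutoff = NULL,
                   reference = "test_genes"),
    secondary = list(n_candidates = 13L, alpha = 0.05, well_cv = 0.1),
    qpcr = list(reference_gene = "Actin", control_sample = "w1118",
                genes = c("abd-A", "Abd-B", "pnt"),
                folds = c(0.4, 0.3, 0.5), noise_sd = 0.15,
                n_replicates = 3L),
    annotate = list(n_genes = 50L, n_peaks = 1000L,
                    mix = c(0.5, 0.15, 0.1, 0.1, 0.15),
                    flank = 1000L, bin = 50L),
    phenotype = list(n_flies = 200L, n_replicates = 3L,
                     control_probs = c(0.05, 0.1, 0.2, 0.3, 0.35),
                     mutant_probs = c(0.55, 0.2, 0.15, 0.06, 0.04))
  )
}

read_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("config error: file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config error: config must be a list or path")
  config
}

#' Write a configuration to YAML
#'
#' Configurations round-trip losslessly through their file form.
#'
#' @param config configuration list.
#' @param path output path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

require_field <- function(config, stage, field) {
  v <- config[[stage]][[field]]
  if (is.null(v))
    stop("config error in stage '", stage, "': missing field '", field, "'")
  v
}

#' Run the full analysis pipeline
#'
#' Executes the selected stages in dependency order (synth, primary,
#' secondary, qpcr, annotate, phenotype), writing each stage's artifacts
#' under `config$outdir` and returning a manifest that records the seed,
#' package and R versions, input/output file digests and headline numbers.
#' Identical configurations produce identical output digests.
#'
#' @param config configuration list (see [demo_config()]) or a path to a
#'   YAML file of the same structure.
#' @return the run manifest (also written to `manifest.json` in the output
#'   directory), invisibly.
#' @export
run_pipeline <- function(config = demo_config()) {
  config <- read_config(config)
  for (f in c("seed", "outdir", "stages"))
    if (is.null(config[[f]])) stop("config error: missing field '", f, "'")
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  manifest <- list(package = "trxscreen",
                   version = as.character(utils::packageVersion("trxscreen")),
                   r_version = as.character(getRversion()),
                   seed = seed, stages = list(), outputs = list(),
                   headline = list())
  paths <- list()
  out_file <- function(name) file.path(outdir, name)
  record <- function(name) {
    manifest$outputs[[name]] <<- unname(tools::md5sum(out_file(name)))
    paths[[name]] <<- out_file(name)
  }

  if ("synth" %in% config$stages) {
    sc <- config$screen
    design <- screen_design(n_genes = sc$n_genes,
                            wells_per_gene = sc$wells_per_gene,
                            n_experiments = sc$n_experiments,
                            n_plates = sc$n_plates, seed = seed)
    effects <- effect_model(hit_fraction = sc$hit_fraction,
                            hit_f_reduction = sc$hit_f_reduction,
                            general_fraction = sc$general_fraction,
                            general_reduction = sc$general_reduction,
                            plate_effect_sd = sc$plate_effect_sd,
                            well_cv = sc$well_cv)
    synth <- simulate_screen(design, effects)
    utils::write.csv(synth$measurements, out_file("plates.csv"),
                     row.names = FALSE)
    utils::write.csv(synth$map, out_file("map.csv"), row.names = FALSE)
    jsonlite::write_json(
      stats::setNames(as.list(synth$truth$label), synth$truth$gene),
      out_file("truth.json"), auto_unbox = TRUE)
    record("plates.csv"); record("map.csv"); record("truth.json")
    manifest$stages$synth <- list(n_genes = design$n_genes,
                                  n_wells = nrow(synth$map))
  }

  truth <- NULL
  if (file.exists(out_file("truth.json")))
    truth <- unlist(jsonlite::read_json(out_file("truth.json")))

  fit <- NULL
  if ("primary" %in% config$stages) {
    for (f in c("plates.csv", "map.csv"))
      if (!file.exists(out_file(f)))
        stop("data error in stage 'primary': missing input ", f)
    plates <- utils::read.csv(out_file("plates.csv"),
                              stringsAsFactors = FALSE)
    map <- utils::read.csv(out_file("map.csv"), stringsAsFactors = FALSE)
    pc <- config$primary
    fit <- screen_zscore(plates, map, mask_cutoff = pc$mask_cutoff,
                         cutoff = pc$cutoff, reference = pc$reference)
    utils::write.table(fit$scores, out_file("gene_scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(hits(fit), out_file("hits.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    record("gene_scores.tsv"); record("hits.tsv")
    manifest$stages$primary <- list(
      cutoff = fit$cutoff, derived = fit$derived_cutoff,
      n_masked = sum(fit$scores$masked), n_hits = nrow(hits(fit)))
    manifest$headline$cutoff <- fit$cutoff
    manifest$headline$hit_count <- nrow(hits(fit))
  }

  if ("secondary" %in% config$stages) {
    if (is.null(fit))
      stop("data error in stage 'secondary': primary stage must run first")
    sec <- config$secondary
    cand <- utils::head(hits(fit)$gene, require_field(config, "secondary",
                                                      "n_candidates"))
    # true effect of each candidate carried over from the planted truth
    red <- stats::setNames(
      ifelse(!is.null(truth) & truth[cand] == "hit",
             config$screen$hit_f_reduction, 0), cand)
    val_in <- simulate_validation(cand, f_reduction = red,
                                  well_cv = sec$well_cv, seed = seed + 10L)
    val <- secondary_screen(val_in$measurements, val_in$map,
                            alpha = sec$alpha)
    utils::write.table(val, out_file("validation.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    record("validation.tsv")
    manifest$stages$secondary <- list(n_tested = nrow(val),
                                      n_validated = sum(val$validated))
    manifest$headline$validated_count <- sum(val$validated)
  }

  if ("qpcr" %in% config$stages) {
    qc <- config$qpcr
    eff <- data.frame(sample = "mutant", gene = qc$genes, fold = qc$folds,
                      stringsAsFactors = FALSE)
    ctab <- simulate_ct(conditions = c(qc$control_sample, "mutant"),
                        genes = qc$genes,
                        reference_gene = qc$reference_gene, effects = eff,
                        noise_sd = qc$noise_sd,
                        n_replicates = qc$n_replicates, seed = seed + 20L)
    utils::write.csv(ctab, out_file("ct.csv"), row.names = FALSE)
    expr <- expression_report(utils::read.csv(out_file("ct.csv"),
                                              stringsAsFactors = FALSE),
                              reference_gene = qc$reference_gene,
                              control_sample = qc$control_sample)
    utils::write.table(expr, out_file("expression.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    record("ct.csv"); record("expression.tsv")
    mut <- expr[expr$sample == "mutant", ]
    manifest$stages$qpcr <- list(
      folds = stats::setNames(as.list(round(mut$fold_change, 4)), mut$gene))
  }

  if ("annotate" %in% config$stages) {
    an <- config$annotate
    fx <- simulate_genome(n_genes = an$n_genes, n_peaks = an$n_peaks,
                          mix = an$mix, seed = seed + 30L)
    write_bed(fx$peaks, out_file("peaks.bed"))
    write_gene_table(fx$genes, out_file("genes.tsv"))
    ann <- annotate_peaks(read_bed(out_file("peaks.bed")),
                          read_gene_table(out_file("genes.tsv")))
    utils::write.table(ann, out_file("annotation.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    frac <- as.list(table(factor(ann$category,
                                 levels = ANNOTATION_CATEGORIES)) /
                      max(1L, nrow(ann)))
    promoter_set <- peak_gene_sets(ann, grep("Promoter",
                                             ANNOTATION_CATEGORIES,
                                             value = TRUE))
    all_set <- peak_gene_sets(ann)
    ov <- overlap_counts(promoter_set, all_set)
    mat <- tss_matrix(fx$peaks, fx$genes,
                      chrom_sizes = c(chr2L = 1e6, chr2R = 1e6),
                      flank = an$flank, bin = an$bin)
    utils::write.table(round(mat, 4), out_file("tss_matrix.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    record("peaks.bed"); record("genes.tsv"); record("annotation.tsv")
    record("tss_matrix.tsv")
    manifest$stages$annotate <- list(category_fractions = frac,
                                     promoter_overlap = as.list(ov))
    manifest$headline$category_fractions <- frac
  }

  if ("phenotype" %in% config$stages) {
    ph <- config$phenotype
    probs <- rbind(control = ph$control_probs, mutant = ph$mutant_probs)
    colnames(probs) <- SEVERITY_CATEGORIES
    pcounts <- simulate_phenotypes(probs, n_flies = ph$n_flies,
                                   n_replicates = ph$n_replicates,
                                   seed = seed + 40L)
    utils::write.csv(pcounts, out_file("phenotype.csv"), row.names = FALSE)
    cmp <- compare_crosses(utils::read.csv(out_file("phenotype.csv"),
                                           stringsAsFactors = FALSE),
                           "mutant", "control",
                           categories = SEVERITY_CATEGORIES)
    utils::write.table(cmp$tests, out_file("phenotype_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    record("phenotype.csv"); record("phenotype_tests.tsv")
    manifest$stages$phenotype <- list(suppression = cmp$suppression,
                                      chisq_p = cmp$chisq_p)
    manifest$headline$suppression <- cmp$suppression
  }

  jsonlite::write_json(manifest, out_file("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
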