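test_that("plate-median correction divides by the test-well median", {
  # hand case: test medians over {2,4,6,8} -> median 5
  intensity <- c(2, 4, 6, 8, 10)
  role <- c("test", "test", "test", "test", "pos_trx")
  corr <- plate_median_correct(intensity, role)
  expect_equal(as.numeric(corr), c(0.4, 0.8, 1.2, 1.6, 2.0))
  expect_equal(attr(corr, "plate_median"), 5)
  # identity: all equal -> all 1
  expect_equal(as.numeric(plate_median_correct(rep(7, 6), rep("test", 6))),
               rep(1, 6))
  # scale invariance
  k <- 13.7
  expect_equal(as.numeric(plate_median_correct(k * intensity, role)),
               as.numeric(plate_median_correct(intensity, role)))
  # median of corrected test wells is exactly 1
  set.seed(1)
  x <- rlnorm(100, 8, 1)
  r <- c(rep("test", 90), rep("neg_lacz", 10))
  expect_equal(median(plate_median_correct(x, r)[r == "test"]), 1)
  expect_error(plate_median_correct(c(1, 2, 3), rep("test", 3)),
               "degenerate plate")
})

test_that("relative activity is F/R with explicit exclusion of bad wells", {
  r <- relative_activity(c(0.8, 1.2, 0.5, 0.7), c(1.0, 0.8, 0, NA))
  expect_equal(as.numeric(r), c(0.8, 1.5, NA, NA))
  expect_equal(attr(r, "excluded"), c(FALSE, FALSE, TRUE, TRUE))
})

test_that("replicate aggregation averages within then across experiments", {
  g <- rep("a", 6); e <- rep(1:2, each = 3)
  v <- c(0.9, 1.0, 1.1, 0.8, 1.0, 1.2)
  out <- aggregate_replicates(g, e, v)
  expect_equal(out$value, 1.0)
  expect_false(out$single_experiment)
  # single usable well in one experiment: flagged
  out1 <- aggregate_replicates("b", 1, 0.7)
  expect_equal(out1$value, 0.7)
  expect_true(out1$single_experiment)
  # idempotence on constant data
  out2 <- aggregate_replicates(rep("c", 4), c(1, 1, 2, 2), rep(0.42, 4))
  expect_equal(out2$value, 0.42)
  # unbalanced designs weight experiments, not wells
  out3 <- aggregate_replicates(rep("d", 3), c(1, 1, 2), c(1, 3, 10))
  expect_equal(out3$value, (2 + 10) / 2)
  # genes with no usable wells are dropped with a record
  out4 <- aggregate_replicates(c("e", "f"), c(1, 1), c(NA, 1))
  expect_equal(attr(out4, "dropped"), "e")
})

test_that("robust_z matches the published formula and sign convention", {
  ref8 <- c(0.8, 0.9, 1.0, 1.1, 1.2, 0.95, 1.05, 1.0)
  expect_equal(robust_z(1.0, ref8), 0)
  ref5 <- c(0.8, 0.9, 1.0, 1.1, 1.2)
  z <- suppressWarnings(robust_z(0.4, ref5))
  expect_equal(z, (1.0 - 0.4) / (1.4826 * 0.1))
  expect_equal(round(z, 3), 4.047)
  # reduced activity scores positive, increased negative
  expect_gt(suppressWarnings(robust_z(0.5, ref5)), 0)
  expect_lt(suppressWarnings(robust_z(1.5, ref5)), 0)
  expect_error(robust_z(1, c(1)), "degenerate")
  expect_error(suppressWarnings(robust_z(1, rep(2, 9))), "zero spread")
})

test_that("robust_z agrees with a direct-formula oracle", {
  set.seed(101)
  for (i in 1:100) {
    ref <- rnorm(sample(9:60, 1), mean = runif(1, -5, 5),
                 sd = runif(1, 0.1, 3))
    v <- rnorm(5)
    expect_equal(robust_z(v, ref), oracle_robust_z(v, ref),
                 tolerance = 1e-12)
  }
})

test_that("derive_cutoff floors the smallest positive-control Z", {
  expect_equal(derive_cutoff(c(6.13, 6.15)), 6)
  expect_equal(derive_cutoff(7.0), 7)
  expect_equal(derive_cutoff(c(3.2, 9.9)), 3)
  expect_error(derive_cutoff(numeric(0)), "no positive-control")
})

test_that("call_hits ranks by Z with gene-id tie-break and is monotone", {
  sc <- data.frame(gene = c("b", "a", "c", "d"),
                   z = c(7, 7, 9, 2),
                   masked = c(FALSE, FALSE, FALSE, FALSE))
  h <- call_hits(sc, 6)
  expect_equal(h$gene, c("c", "a", "b"))
  expect_equal(nrow(call_hits(sc[0, ], 6)), 0)
  # masked genes are never hits
  sc$masked[3] <- TRUE
  expect_false("c" %in% call_hits(sc, 6)$gene)
  # monotonicity over random tables
  set.seed(33)
  for (i in 1:20) {
    tab <- data.frame(gene = sprintf("g%02d", 1:50), z = rnorm(50, 0, 4),
                      masked = runif(50) < 0.1)
    cuts <- sort(runif(2, -2, 8))
    h1 <- call_hits(tab, cuts[1])$gene
    h2 <- call_hits(tab, cuts[2])$gene
    expect_true(all(h2 %in% h1))
  }
})

test_that("zero-noise screen analysis recovers the planted truth exactly", {
  d <- screen_design(n_genes = 60, wells_per_gene = 3, n_experiments = 2,
                     plate_rows = 16, plate_cols = 24, n_plates = 1,
                     seed = 8)
  e <- effect_model(hit_fraction = 0.1, hit_f_reduction = 0.7,
                    general_fraction = 0.05, general_reduction = 0.5,
                    plate_effect_sd = 0, well_cv = 0)
  s <- simulate_screen(d, e)
  fit <- suppressWarnings(screen_zscore(s$measurements, s$map))
  truth <- setNames(s$truth$label, s$truth$gene)
  called <- hits(fit)$gene
  expect_setequal(called, names(truth)[truth == "hit"])
  masked <- fit$scores$gene[fit$scores$masked]
  expect_setequal(masked, names(truth)[truth == "general"])
})

test_that("hit set is invariant under per-plate channel rescaling", {
  d <- screen_design(n_genes = 40, n_plates = 2, plate_rows = 8,
                     plate_cols = 24, n_experiments = 2, seed = 12)
  e <- effect_model(well_cv = 0.1, plate_effect_sd = 0)
  s <- simulate_screen(d, e)
  fit1 <- screen_zscore(s$measurements, s$map)
  m2 <- s$measurements
  # arbitrary positive factor per (experiment, plate, channel)
  f <- interaction(m2$experiment, m2$plate, m2$channel)
  scale <- setNames(runif(nlevels(f), 0.2, 5), levels(f))
  m2$intensity <- m2$intensity * scale[as.character(f)]
  fit2 <- screen_zscore(m2, s$map)
  expect_equal(hits(fit2)$gene, hits(fit1)$gene)
  expect_equal(fit2$scores$z, fit1$scores$z)
})

test_that("screen fit reports wells excluded for nonpositive Renilla", {
  d <- screen_design(n_genes = 20, n_plates = 1, plate_rows = 8,
                     plate_cols = 12, n_experiments = 1,
                     controls_per_plate = c(pos_trx = 2, pos_ash1 = 2,
                                            pos_fluc = 2, neg_lacz = 2,
                                            neg_gfp = 2), seed = 5)
  s <- simulate_screen(d, effect_model(well_cv = 0.05,
                                       plate_effect_sd = 0))
  bad_well <- s$map$well[s$map$role == "test"][1]
  s$measurements$intensity[s$measurements$well == bad_well &
                             s$measurements$channel == "R"] <- 0
  fit <- suppressWarnings(screen_zscore(s$measurements, s$map))
  expect_true(any(fit$exclusions$reason == "renilla_nonpositive_or_missing"))
})

test_that("screen_zscore S3 surface behaves like a model fit", {
  s <- simulate_screen(screen_design(n_genes = 40, n_plates = 1,
                                     plate_rows = 8, plate_cols = 24,
                                     n_experiments = 2, seed = 2),
                       effect_model())
  fit <- screen_zscore(s$measurements, s$map)
  expect_s3_class(fit, "screen_zscore")
  expect_output(print(fit), "cut-off")
  expect_output(summary(fit), "Top candidates")
  z <- coef(fit)
  expect_length(z, 40)
  expect_named(z)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
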