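test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(n_ref = 1), "n_ref")
  expect_error(sim_config(snps_per_gene = 0), "snps_per_gene")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(he2 = 1), "he2")
  expect_error(sim_config(pi_causal = 0), "pi_causal")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
})

test_that("same seed and config give bit-identical panels, expression and phenotypes", {
  cfg <- sim_config(n_genes = 3, seed = 11)
  a <- simulate_panel(cfg)
  b <- simulate_panel(cfg)
  expect_identical(a$ref$dosage, b$ref$dosage)
  expect_identical(a$test$dosage, b$test$dosage)
  ea <- simulate_expression(a, cfg)
  eb <- simulate_expression(b, cfg)
  expect_identical(ea$expression, eb$expression)
  expect_identical(simulate_phenotypes(ea$truth, a$test, cfg),
                   simulate_phenotypes(eb$truth, b$test, cfg))
})

test_that("missing_rate = 0 yields complete dosage matrices", {
  cfg <- sim_config(n_genes = 2, missing_rate = 0, seed = 3)
  sim <- simulate_panel(cfg)
  expect_false(anyNA(sim$ref$dosage))
  expect_false(anyNA(sim$test$dosage))
})

test_that("empirical MAF matches the sampling frequency at large n", {
  cfg <- sim_config(n_ref = 10000, n_test = 2, n_genes = 1,
                    snps_per_gene = 10, maf_range = c(0.5, 0.5),
                    missing_rate = 0, seed = 5)
  sim <- simulate_panel(cfg)
  maf <- allele_stats(sim$ref)$maf
  expect_true(all(abs(maf - 0.5) < 0.02))
})

test_that("simulated genotype counts are consistent with HWE", {
  cfg <- sim_config(n_ref = 2000, n_test = 2, n_genes = 5,
                    snps_per_gene = 20, missing_rate = 0, seed = 17)
  sim <- simulate_panel(cfg)
  st <- allele_stats(sim$ref)
  p <- vapply(seq_len(nrow(st)), function(i) {
    hwe_exact_test(st$n_hom_major[i], st$n_het[i], st$n_hom_minor[i])
  }, numeric(1))
  expect_gte(mean(p >= 1e-4), 0.99)
})

test_that("he2 = 0 gives a pure-noise architecture", {
  cfg <- sim_config(n_genes = 2, he2 = 0, batch_effect_sd = 0, seed = 19)
  sim <- simulate_panel(cfg)
  se <- simulate_expression(sim, cfg)
  for (t in se$truth) {
    expect_true(all(t$true_weights == 0))
    expect_true(all(t$true_grex_ref == 0))
  }
})

test_that("causal-SNP count follows round(pi_causal * snps_per_gene)", {
  cfg <- sim_config(n_genes = 4, snps_per_gene = 17, pi_causal = 0.3,
                    seed = 23)
  se <- simulate_expression(simulate_panel(cfg), cfg)
  for (t in se$truth) {
    expect_identical(sum(t$causal_flag), as.integer(round(0.3 * 17)))
    expect_identical(sum(t$true_weights != 0), sum(t$causal_flag))
  }
})

test_that("genetic variance fraction recovers he2 on a large panel", {
  cfg <- sim_config(n_ref = 2000, n_test = 2, n_genes = 1,
                    snps_per_gene = 20, pi_causal = 1, he2 = 0.5,
                    batch_effect_sd = 0, missing_rate = 0, seed = 29)
  sim <- simulate_panel(cfg)
  se <- simulate_expression(sim, cfg)
  ratio <- var(se$truth[[1]]$true_grex_ref) / var(se$expression[1, ])
  expect_lt(abs(ratio - 0.5), 0.05)
})

test_that("batch shifts are per-batch constants on the expression", {
  base <- list(n_ref = 40, n_test = 2, n_genes = 1, snps_per_gene = 5,
               missing_rate = 0, seed = 31)
  cfg0 <- do.call(sim_config, c(base, batch_effect_sd = 0))
  cfg1 <- do.call(sim_config, c(base, batch_effect_sd = 2))
  sim <- simulate_panel(cfg0)
  e0 <- simulate_expression(sim, cfg0)
  e1 <- simulate_expression(sim, cfg1)
  delta <- e1$expression[1, ] - e0$expression[1, ]
  shifts <- tapply(delta, e0$factors$batch, function(x) diff(range(x)))
  expect_true(all(shifts < 1e-12))
  expect_gt(diff(range(delta)), 0)  # nonzero shift actually applied
})

test_that("a gene with zero cis-SNPs raises an error naming it", {
  cfg <- sim_config(n_genes = 1, seed = 37)
  sim <- simulate_panel(cfg)
  sim$annotation <- rbind(sim$annotation,
                          gene_annotation("orphan", "9", 100L, 200L))
  expect_error(simulate_expression(sim, cfg), "orphan")
})

test_that("degenerate phenotype settings behave as the generative model implies", {
  cfg <- sim_config(n_genes = 1, n_test = 30, beta_trait = 0, noise_sd = 0,
                    covariate_effects = c(AFC = 0, bwt = 0), seed = 41)
  sim <- simulate_panel(cfg)
  se <- simulate_expression(sim, cfg)
  ph <- simulate_phenotypes(se$truth, sim$test, cfg)
  expect_true(all(ph$trait == 0))

  cfg2 <- sim_config(n_genes = 1, n_test = 30, beta_trait = 1, noise_sd = 0,
                     covariate_effects = c(AFC = 0, bwt = 0), seed = 41)
  se2 <- simulate_expression(sim, cfg2)
  ph2 <- simulate_phenotypes(se2$truth, sim$test, cfg2)
  expect_equal(ph2$trait, unname(true_grex(se2$truth, sim$test)[1, ]))
})

test_that("regression on true GReX recovers the trait effect", {
  cfg <- sim_config(n_ref = 100, n_test = 2000, n_genes = 1,
                    snps_per_gene = 10, pi_causal = 1, he2 = 0.3,
                    beta_trait = 0.5, covariate_effects = c(AFC = 0, bwt = 0),
                    missing_rate = 0, seed = 43)
  sim <- simulate_panel(cfg)
  se <- simulate_expression(sim, cfg)
  ph <- simulate_phenotypes(se$truth, sim$test, cfg)
  g <- true_grex(se$truth, sim$test)[1, ]
  fit <- summary(lm(ph$trait ~ g))
  expect_lt(abs(fit$coefficients["g", "Estimate"] - 0.5),
            3 * fit$coefficients["g", "Std. Error"])
})

test_that("fixtures round-trip through the readers and are byte-stable", {
  cfg <- sim_config(n_genes = 2, seed = 47)
  sim <- simulate_panel(cfg)
  se <- simulate_expression(sim, cfg)
  ph <- simulate_phenotypes(se$truth, sim$test, cfg)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_fixtures(sim, sim$annotation, se$expression, ph, d1)
  p2 <- write_fixtures(sim, sim$annotation, se$expression, ph, d2)
  for (nm in names(p1)) {
    expect_identical(unname(tools::md5sum(p1[[nm]])),
                     unname(tools::md5sum(p2[[nm]])), info = nm)
  }
  ref_rt <- read_genotypes(p1[["ref_vcf"]])
  expect_identical(ref_rt$dosage, sim$ref$dosage)
  test_rt <- match_minor_coding(
    read_genotypes(p1[["test_vcf"]], recode_minor = FALSE), ref_rt)
  expect_identical(test_rt$dosage, sim$test$dosage)
  expect_equal(read_expression_matrix(p1[["expression"]]), se$expression,
               ignore_attr = TRUE)
  ann <- read_gene_annotation(p1[["annotation"]])
  expect_identical(ann, sim$annotation)
})

test_that("zero genes produce a valid empty annotation fixture", {
  cfg <- sim_config(n_genes = 0, seed = 53)
  sim <- simulate_panel(cfg)
  se <- list(expression = matrix(numeric(0), 0, cfg$n_ref,
                                 dimnames = list(NULL, sim$ref$samples)))
  ph <- data.frame(sample_id = sim$test$samples, trait = 0,
                   AFC = 0, bwt = 0)
  d <- withr::local_tempdir()
  paths <- write_fixtures(sim, sim$annotation, se$expression, ph, d)
  ann <- read_gene_annotation(paths[["annotation"]])
  expect_identical(nrow(ann), 0L)
})
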