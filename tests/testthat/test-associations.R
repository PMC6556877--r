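test_that("planted phenotype coupling is recovered in a single cohort draw", {
  panel <- small_panel()
  co <- generate_cohort(panel, n = 766,
                        phenotype_couplings = list(
                          android_gynoid_ratio = list(
                            cell_type = "macrophage", r = 0.36)),
                        seed = 21, make_expression = FALSE)
  rec <- cell_phenotype_association(co$true_proportions, co$phenotypes,
                                    "android_gynoid_ratio", "macrophage")
  expect_lt(abs(rec$r - 0.36), 0.07)
  expect_lt(rec$p, 1e-10)
  expect_equal(rec$n, 766)
})

test_that("couplings mediated entirely by BMI vanish under BMI adjustment", {
  panel <- small_panel()
  co <- generate_cohort(panel, n = 1000, seed = 22,
                        make_expression = FALSE)
  # chain: proportion -> BMI -> trait; conditional on BMI the trait
  # carries no proportion signal
  z <- inverse_rank_normalize(co$true_proportions[, "macrophage"])
  withr::with_seed(23, {
    co$phenotypes$BMI <- 26 + 5 * (0.7 * z + sqrt(1 - 0.49) * rnorm(1000))
    bmi_std <- scale(co$phenotypes$BMI)[, 1]
    co$phenotypes$visceral_fat <-
      500 + 200 * (0.6 * bmi_std + 0.8 * rnorm(1000))
  })
  raw <- cell_phenotype_association(co$true_proportions, co$phenotypes,
                                    "visceral_fat", "macrophage")
  adj <- cell_phenotype_association(co$true_proportions, co$phenotypes,
                                    "visceral_fat", "macrophage",
                                    covariates = "BMI")
  expect_gt(raw$r, 0.25)
  expect_lt(abs(adj$r), 0.1)
  # an uncorrelated covariate barely moves the estimate
  withr::with_seed(24, co$phenotypes$age <- rnorm(1000, 60, 10))
  with_age <- cell_phenotype_association(co$true_proportions,
                                         co$phenotypes, "visceral_fat",
                                         "macrophage",
                                         covariates = "age")
  expect_lt(abs(with_age$r - raw$r), 0.02)
  expect_error(cell_phenotype_association(
    cbind(co$true_proportions[, 1:3],
          CD4T = rep(0.1, 1000)),
    co$phenotypes, "BMI", "CD4T"), "constant")
})

test_that("dual-model scan separates macrophage-mediated from direct BMI genes", {
  withr::with_seed(25, {
    n <- 400
    mac <- rbeta(n, 2, 20)
    z <- scale(mac)[, 1]
    bmi <- 26 + 5 * (0.6 * z + 0.8 * rnorm(n))
    bmi_std <- scale(bmi)[, 1]
    samples <- sprintf("S%03d", 1:n)
    # 5 genes driven by macrophage proportion only, 5 directly by
    # BMI, 10 null
    expr <- matrix(rnorm(20 * n), 20, n,
                   dimnames = list(sprintf("gene%02d", 1:20), samples))
    for (i in 1:5) expr[i, ] <- 1.2 * z + 0.6 * rnorm(n)
    for (i in 6:10) expr[i, ] <- 1.2 * bmi_std + 0.6 * rnorm(n)
    pheno <- data.frame(sample = samples, BMI = bmi)
  })
  scan <- dual_model_expression_scan(expr, pheno, adjust_cell = mac)
  rec <- scan$records
  expect_true(all(rec$sig_model1[1:10]))
  expect_true(all(rec$lost[1:5]))        # mediated genes lost
  expect_true(all(!rec$lost[6:10]))      # direct genes retained
  expect_lte(scan$summary$n_lost, scan$summary$n_significant_model1)
  expect_equal(scan$summary$threshold, 0.05 / 20)
  # no adjustment twice gives identical records
  s1 <- dual_model_expression_scan(expr, pheno)
  expect_identical(s1$records$p_model1, s1$records$p_model2)
})

test_that("ACE maximum likelihood hits the closed-form limits", {
  perfect <- generate_twin_pairs(100, 100, 1, 0, 0, seed = 26)
  # DZ correlation 0.5, MZ correlation 1 -> pure additive
  fit <- fit_ace(perfect)
  expect_gt(fit$a2, 0.9)
  # equal twin correlations -> no additive component
  same <- generate_twin_pairs(300, 300, 0, 0.4, 0.6, seed = 27)
  fit2 <- fit_ace(same)
  expect_lt(fit2$a2, 0.08)
  expect_equal(fit2$a2 + fit2$c2 + fit2$e2, 1, tolerance = 1e-6)
  expect_error(fit_ace(generate_twin_pairs(10, 10, 0.3, 0.1, 0.6)),
               "at least 20")
})

test_that("ACE recovery is unbiased across the heritability grid", {
  for (a2 in c(0, 0.30, 0.60)) {
    est <- vapply(1:10, function(i)
      fit_ace(generate_twin_pairs(200, 200, a2, 0.10, 0.90 - a2,
                                  seed = 28 + 100 * a2 + i))$a2,
      numeric(1))
    expect_lt(abs(mean(est) - a2), 0.08)
  }
})

test_that("covariate scan recovers a covariate aligned with composition PCs", {
  panel <- small_panel()
  co <- generate_cohort(panel, n = 326, seed = 29,
                        make_expression = FALSE)
  pcs <- props_pca(co$true_proportions)
  co$phenotypes$ischemic_time <- pcs[, 1]
  scan <- covariate_scan(co$true_proportions, co$phenotypes,
                         "ischemic_time")
  expect_equal(abs(scan$pcs$r[1]), 1, tolerance = 1e-10)
  # planted overall-heterogeneity loading r = 0.15 recovered
  withr::with_seed(30, {
    pc1 <- scale(pcs[, 1])[, 1]
    co$phenotypes$ischemic_time <- 0.15 * pc1 + sqrt(1 - 0.15^2) * rnorm(326)
  })
  scan2 <- covariate_scan(co$true_proportions, co$phenotypes,
                          "ischemic_time")
  expect_lt(abs(abs(scan2$pcs$r[1]) - 0.15), 0.11)
  # an independent covariate shows no strong PC correlation
  withr::with_seed(31, co$phenotypes$ischemic_time <- rnorm(326))
  scan3 <- covariate_scan(co$true_proportions, co$phenotypes,
                          "ischemic_time")
  expect_true(all(abs(scan3$pcs$r) < 0.2))
})

test_that("weighted GRS matches dosages and effect-allele orientation", {
  g <- generate_genotypes(200, 4, maf = 0.3, seed = 32)
  w0 <- data.frame(snp = g$info$snp, effect_allele = "G",
                   beta = 0)
  expect_true(all(compute_grs(g, w0)$grs == 0))
  w1 <- data.frame(snp = "rs000001", effect_allele = "G", beta = 1)
  expect_equal(compute_grs(g, w1)$grs, unname(g$dosages[1, ]))
  # effect allele on the REF strand counts the complement dosage
  w2 <- data.frame(snp = "rs000001", effect_allele = "A", beta = 1)
  expect_equal(compute_grs(g, w2)$grs, unname(2 - g$dosages[1, ]))
  w3 <- data.frame(snp = "rs000001", effect_allele = "T", beta = 1)
  expect_warning(out <- compute_grs(g, w3), "neither")
  expect_equal(attr(out, "n_matched"), 0)
})

test_that("a GRS driving BMI does not associate with cell proportions", {
  panel <- small_panel()
  co <- generate_cohort(panel, n = 500, seed = 33,
                        make_expression = FALSE)
  g <- generate_genotypes(500, 20, maf = c(0.1, 0.5), seed = 33)
  wts <- data.frame(snp = g$info$snp, effect_allele = "G",
                    beta = withr::with_seed(34, runif(20, 0.1, 0.5)))
  grs <- compute_grs(g, wts)
  grs$sample <- co$phenotypes$sample
  withr::with_seed(35, {
    co$phenotypes$BMI <- 26 + 2 * scale(grs$grs)[, 1] + 4 * rnorm(500)
  })
  bmi <- stats::setNames(co$phenotypes$BMI, co$phenotypes$sample)
  rec_bmi <- grs_association(grs, bmi, outcome_name = "BMI")
  expect_lt(rec_bmi$p, 1e-10)
  for (ct in panel$cell_types) {
    prop <- stats::setNames(co$true_proportions[, ct],
                            rownames(co$true_proportions))
    rec <- grs_association(grs, prop, outcome_name = ct)
    expect_gt(rec$p, 0.001)
  }
})
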