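test_that("reference panel plants disjoint markers with the requested fold", {
  panel <- small_panel()
  mk <- panel$marker_map
  expect_length(unlist(mk), 4 * 30)
  expect_false(anyDuplicated(unlist(mk)) > 0)
  # marker fold over other types >= 8x on the noiseless means
  for (ct in panel$cell_types) {
    m <- panel$means[mk[[ct]], , drop = FALSE]
    other <- apply(m[, setdiff(colnames(m), ct), drop = FALSE], 1, max)
    expect_true(all(m[, ct] / other >= 8 - 1e-9))
  }
})

test_that("replicate_cv = 0 gives identical replicates; generation is seed-reproducible", {
  p0 <- generate_reference_panel(n_genes = 100, markers_per_type = 10,
                                 replicates = 3, replicate_cv = 0, seed = 3)
  expect_equal(p0$profiles[, 1], p0$profiles[, 2],
               ignore_attr = TRUE)
  p1 <- generate_reference_panel(n_genes = 100, markers_per_type = 10,
                                 replicates = 3, replicate_cv = 0.2, seed = 4)
  p2 <- generate_reference_panel(n_genes = 100, markers_per_type = 10,
                                 replicates = 3, replicate_cv = 0.2, seed = 4)
  expect_identical(p1, p2)
  expect_error(generate_reference_panel(n_genes = 40, markers_per_type = 10,
                                        replicates = 2),
               "exceed")
})

test_that("hierarchical clustering of replicate profiles groups them by cell type", {
  panel <- small_panel()
  d <- dist(t(log2(panel$profiles + 1)))
  cl <- cutree(hclust(d, method = "average"), k = 4)
  # within each cut cluster all members come from one cell type
  purity <- tapply(panel$replicate_of, cl,
                   function(x) max(table(x)) / length(x))
  expect_true(all(purity == 1))
})

test_that("cohort proportions are exact simplex points matching the Dirichlet ranges", {
  panel <- small_panel()
  co <- generate_cohort(panel, n = 300, seed = 5, make_expression = FALSE)
  expect_equal(rowSums(co$true_proportions), rep(1, 300),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_true(all(co$true_proportions >= 0))
  # adipocyte-dominated mixtures
  expect_gt(median(co$true_proportions[, "adipocyte"]), 0.6)
})

test_that("noiseless uncoupled cohorts are exact mixtures of the panel means", {
  panel <- small_panel()
  co <- generate_cohort(panel, n = 20, noise_scale = 0, seed = 6)
  expect_equal(unname(co$expression),
               unname(panel$means %*% t(co$true_proportions)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("phenotype couplings hit the requested correlation and r = 0 stays null", {
  panel <- small_panel()
  co <- generate_cohort(panel, n = 5000,
                        phenotype_couplings = list(
                          android_gynoid_ratio = list(
                            cell_type = "macrophage", r = 0.36)),
                        seed = 7, make_expression = FALSE)
  z <- inverse_rank_normalize(co$true_proportions[, "macrophage"])
  expect_lt(abs(cor(co$phenotypes$android_gynoid_ratio, z) - 0.36), 0.05)
  # uncoupled trait: |r| below the null sampling bound 3/sqrt(n)
  expect_lt(abs(cor(co$phenotypes$BMI, z)), 3 / sqrt(5000))
  expect_error(generate_cohort(panel, n = 20,
                               phenotype_couplings = list(
                                 BMI = list(cell_type = "macrophage",
                                            r = 1.2))),
               "< 1")
})

test_that("twin pairs reproduce the expected MZ/DZ correlations", {
  t1 <- generate_twin_pairs(50, 50, 1, 0, 0, seed = 8)
  mz <- t1[t1$zygosity == "MZ", ]
  expect_equal(mz$twin1, mz$twin2, tolerance = 1e-12)

  t2 <- generate_twin_pairs(2000, 2000, 0, 0, 1, seed = 9)
  expect_lt(abs(cor(t2$twin1[t2$zygosity == "MZ"],
                    t2$twin2[t2$zygosity == "MZ"])), 0.06)

  t3 <- generate_twin_pairs(5000, 5000, 0.30, 0.10, 0.60, seed = 10)
  r_mz <- cor(t3$twin1[t3$zygosity == "MZ"], t3$twin2[t3$zygosity == "MZ"])
  r_dz <- cor(t3$twin1[t3$zygosity == "DZ"], t3$twin2[t3$zygosity == "DZ"])
  expect_lt(abs(r_mz - 0.40), 0.04)
  expect_lt(abs(r_dz - 0.25), 0.04)
  expect_error(generate_twin_pairs(10, 10, 0.5, 0.2, 0.2), "equal 1")
  expect_error(generate_twin_pairs(10, 10, -0.1, 0.5, 0.6), ">= 0")
})

test_that("genotypes follow the requested allele frequency and LD structure", {
  g <- generate_genotypes(10000, 5, maf = 0.5, seed = 11)
  expect_true(all(g$dosages %in% 0:2))
  expect_equal(mean(g$dosages), 1, tolerance = 0.03)

  g2 <- generate_genotypes(10000, 8, maf = 0.05, seed = 12)
  expect_true(all(abs(rowMeans(g2$dosages) / 2 - 0.05) < 0.01))

  g3 <- generate_genotypes(500, 4, maf = 0.3, seed = 13,
                           block_size = 2, flip_prob = 0)
  expect_equal(abs(cor(g3$dosages[1, ], g3$dosages[2, ])), 1)
  expect_error(generate_genotypes(10, 2, maf = 0.7), "maf")
})

test_that("plant_eqtl validates inputs and leaves zero-effect cohorts untouched", {
  panel <- small_panel()
  co <- generate_cohort(panel, n = 50, seed = 14)
  g <- generate_genotypes(50, 2, maf = 0.3, seed = 14)
  co <- attach_genotypes(co, g)
  same <- plant_eqtl(co, rownames(co$expression)[1], "rs000001",
                     beta_main = 0, beta_interaction = 0)
  expect_identical(same$expression, co$expression)
  expect_error(plant_eqtl(co, "nope", "rs000001", 1), "unknown gene")
  expect_error(plant_eqtl(co, rownames(co$expression)[1], "nope", 1),
               "unknown snp")
  planted <- plant_eqtl(co, rownames(co$expression)[1], "rs000001",
                        beta_main = 0.5)
  expect_length(planted$generation_config$planted, 1)
})
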