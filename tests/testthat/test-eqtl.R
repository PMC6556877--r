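test_that("cis windows are inclusive, chromosome-aware, and match brute force", {
  g <- generate_genotypes(20, 50, maf = 0.3, seed = 41)
  g$info$chrom[26:50] <- "2"
  annot <- data.frame(gene = "geneA", chrom = "1",
                      tss = g$info$pos[10], stringsAsFactors = FALSE)
  w <- cis_windows(annot, g, window = 5000)
  # 5 kb spacing: exactly tss +/- 5000 inclusive, same chromosome
  expect_setequal(w$geneA, g$info$snp[9:11])
  # same coordinate, other chromosome: excluded
  annot2 <- data.frame(gene = "geneB", chrom = "2", tss = g$info$pos[10])
  expect_false(g$info$snp[10] %in% cis_windows(annot2, g, 5000)$geneB)
  # random annotation set vs brute-force distance scan
  annot3 <- data.frame(gene = paste0("g", 1:5), chrom = "1",
                       tss = withr::with_seed(42,
                         sample(10000:150000, 5)))
  w3 <- cis_windows(annot3, g, window = 20000)
  for (i in 1:5) {
    brute <- g$info$snp[g$info$chrom == "1" &
                          abs(g$info$pos - annot3$tss[i]) <= 20000]
    expect_setequal(w3[[annot3$gene[i]]], brute)
  }
})

test_that("MAF filtering folds frequencies and keeps the boundary", {
  g <- generate_genotypes(200, 10, maf = c(0.05, 0.5), seed = 43)
  g$dosages[1, ] <- 0L                       # monomorphic
  g$dosages[2, ] <- c(rep(1L, 20), rep(0L, 180))  # freq 0.05 exactly
  out <- maf_filter(g, 0.05)
  expect_false("rs000001" %in% out$info$snp)
  expect_true("rs000002" %in% out$info$snp)
  freq <- rowMeans(g$dosages) / 2
  expect_setequal(out$info$snp,
                  g$info$snp[pmin(freq, 1 - freq) >= 0.05])
})

test_that("latent factors are orthonormal and capture planted batch structure", {
  expr <- withr::with_seed(44, {
    e <- matrix(2^rnorm(100 * 40, 5, 1), 100, 40,
                dimnames = list(paste0("g", 1:100), paste0("s", 1:40)))
    e[, 21:40] <- e[, 21:40] * 3   # batch shift
    e
  })
  lf <- latent_factors(expr, k = 3)
  expect_equal(dim(lf), c(40, 3))
  expect_equal(crossprod(lf), diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)
  batch <- rep(c(0, 1), each = 20)
  expect_gt(abs(cor(lf[, 1], batch)), 0.9)
  expect_equal(ncol(latent_factors(expr, k = 0)), 0)
  expect_error(latent_factors(expr, k = 40), "smaller")
})

test_that("cis-scan betas and p values equal the textbook OLS solution", {
  withr::with_seed(45, {
    n <- 10
    g <- generate_genotypes(n, 2, maf = 0.4, seed = 45)
    expr <- matrix(rnorm(n), 1, n,
                   dimnames = list("geneA", colnames(g$dosages)))
    covs <- matrix(rnorm(n * 2), n, 2)
  })
  win <- list(geneA = g$info$snp)
  scan <- cis_scan(expr, g, win, covariates = covs)
  e_int <- inverse_rank_normalize(expr[1, ])
  for (i in 1:2) {
    fit <- summary(lm(e_int ~ g$dosages[i, ] + covs))
    row <- scan$pairs[scan$pairs$snp == g$info$snp[i], ]
    expect_equal(row$beta, unname(coef(fit)[2, 1]), tolerance = 1e-8)
    expect_equal(row$p_nominal, unname(coef(fit)[2, 4]), tolerance = 1e-8)
  }
})

test_that("cis-scan detects a planted main-effect eQTL and stays null when permuted", {
  panel <- small_panel()
  co <- generate_cohort(panel, n = 300, seed = 46)
  g <- generate_genotypes(300, 10, maf = 0.3, seed = 46)
  co <- attach_genotypes(co, g)
  genes <- rownames(co$expression)[1:5]
  co <- plant_eqtl(co, genes[1], "rs000003", beta_main = 0.8)
  annot <- data.frame(gene = genes, chrom = "1",
                      tss = seq(10000L, by = 10000L, length.out = 5))
  win <- cis_windows(annot, co$genotypes, window = 50000)
  scan <- cis_scan(co$expression[genes, ], co$genotypes, win)
  hit <- scan$genes[scan$genes$gene == genes[1], ]
  expect_true(hit$significant)
  expect_identical(hit$snp, "rs000003")

  # permuting sample labels of the genotypes kills the signal
  gp <- co$genotypes
  perm <- withr::with_seed(47, sample(ncol(gp$dosages)))
  gp$dosages <- gp$dosages[, perm]
  colnames(gp$dosages) <- colnames(co$genotypes$dosages)
  scan0 <- cis_scan(co$expression[genes, ], gp, win)
  expect_equal(sum(scan0$genes$significant), 0)
})

test_that("eigenMT effective tests match hand eigenvalue computations", {
  g <- generate_genotypes(400, 6, maf = 0.3, seed = 48)
  # all rows identical: one effective test
  same <- matrix(rep(g$dosages[1, ], 4), 4, byrow = TRUE)
  expect_equal(eigenmt_effective_tests(same), 1L)
  # independent SNPs: close to the SNP count
  expect_gte(eigenmt_effective_tests(g$dosages), 5)
  # 2-SNP window with correlation 0.6: eigenvalues 1.6, 0.4; the top
  # one explains 80% < 99%, so both tests are effective
  expect_identical(
    which(cumsum(c(1.6, 0.4)) / 2 >= 0.99)[1], 2L)
  two <- withr::with_seed(49, {
    a <- rnorm(2000); b <- 0.6 * a + sqrt(1 - 0.36) * rnorm(2000)
    rbind(s1 = a, s2 = b)
  })
  expect_equal(eigenmt_effective_tests(two), 2L)
  # adjusted p is capped at 1 and never exceeds full Bonferroni
  expect_equal(eigenmt_adjust(0.5, 4), 1)
  k <- eigenmt_effective_tests(g$dosages)
  expect_lte(k, nrow(g$dosages))
  expect_lte(eigenmt_adjust(1e-4, k), 1e-4 * nrow(g$dosages))
  flat <- g$dosages; flat[1, ] <- 1L
  expect_warning(eigenmt_effective_tests(flat), "zero-variance")
})

test_that("interaction scan recovers the planted coefficient and flips sign with the proportion", {
  panel <- small_panel()
  co <- generate_cohort(panel, n = 720, seed = 50)
  g <- generate_genotypes(720, 2, maf = 0.3, seed = 50)
  co <- attach_genotypes(co, g)
  gene <- rownames(co$expression)[10]
  co <- plant_eqtl(co, gene, "rs000001", beta_main = 0.2,
                   beta_interaction = 0.37, cell_type = "macrophage")
  win <- stats::setNames(list("rs000001"), gene)
  mac <- co$true_proportions[, "macrophage"]
  scan <- interaction_scan(co$expression[gene, , drop = FALSE],
                           co$genotypes, mac, win)
  expect_lt(abs(scan$beta_interaction[1] - 0.37), 0.15)
  expect_lt(scan$p[1], 1e-6)
  flipped <- interaction_scan(co$expression[gene, , drop = FALSE],
                              co$genotypes, -mac, win)
  expect_equal(flipped$beta_interaction[1], -scan$beta_interaction[1],
               tolerance = 1e-8)
  expect_equal(attr(scan, "n_tests"), 1L)
})

test_that("interaction p values are uniform under a pure main effect", {
  withr::with_seed(51, {
    n <- 300
    g <- generate_genotypes(n, 1, maf = 0.3, seed = 51)
    mac <- rbeta(n, 2, 20)
    ps <- vapply(1:200, function(i) {
      e <- matrix(0.8 * g$dosages[1, ] + rnorm(n), 1, n,
                  dimnames = list("geneA", colnames(g$dosages)))
      interaction_scan(e, g, mac, list(geneA = "rs000001"))$p[1]
    }, numeric(1))
  })
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.04)
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("Bonferroni thresholds reproduce the genome-wide arithmetic", {
  expect_equal(signif(bonferroni_threshold(49219795), 3), 1.01e-9)
  expect_equal(bonferroni_threshold(1), 0.05)
  expect_equal(bonferroni_threshold(20), 0.0025)
  expect_error(bonferroni_threshold(0))
})
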