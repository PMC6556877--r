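# Phenotype - cell-proportion associations, the dual-model
# BMI-expression scan, ACE twin heritability, covariate checks, and
# genetic-risk-score association. Family structure is handled by
# generalized least squares with an exchangeable within-family
# correlation (a moment estimate of the intraclass correlation from
# OLS residuals, then closed-form whitening of each family block).

# GLS with exchangeable within-family correlation. X must include an
# intercept column. Returns coefficient table rows (est, se, t, p).
.family_gls <- function(y, X, family = NULL) {
  n <- length(y)
  if (is.null(family) || all(is.na(family)) ||
      !anyDuplicated(family[!is.na(family)])) {
    fit <- stats::lm.fit(X, y)
    rho <- 0
  } else {
    fit0 <- stats::lm.fit(X, y)
    r <- fit0$residuals
    s2 <- sum(r^2) / fit0$df.residual
    fam <- ifelse(is.na(family), paste0(".solo", seq_len(n)), family)
    cp <- 0; npair <- 0
    for (f in split(seq_len(n), fam)) {
      if (length(f) < 2) next
      for (a in seq_along(f)[-length(f)])
        for (b in (a + 1):length(f)) {
          cp <- cp + r[f[a]] * r[f[b]]; npair <- npair + 1
        }
    }
    rho <- if (npair == 0) 0 else max(0, min(0.98, cp / npair / s2))
    # whiten: within-family means shrunk by 1/sqrt(1 - rho + m*rho),
    # deviations by 1/sqrt(1 - rho)
    for (f in split(seq_len(n), fam)) {
      m <- length(f)
      if (m == 1) next
      wm <- 1 / sqrt(1 - rho + m * rho); wd <- 1 / sqrt(1 - rho)
      ybar <- mean(y[f]); Xbar <- colMeans(X[f, , drop = FALSE])
      y[f] <- wd * (y[f] - ybar) + wm * ybar
      X[f, ] <- wd * sweep(X[f, , drop = FALSE], 2, Xbar) +
        rep(wm, m) %o% Xbar
    }
    fit <- stats::lm.fit(X, y)
  }
  est <- fit$coefficients
  rss <- sum(fit$residuals^2)
  df <- n - fit$rank
  XtXinv <- solve(crossprod(X))
  se <- sqrt(diag(XtXinv) * rss / df)
  names(se) <- names(est)
  tt <- est / se
  list(est = est, se = se, t = tt, p = 2 * pt(-abs(tt), df), df = df,
       rho = rho)
}

#' Association between a cell-type proportion and a phenotype
#'
#' Ordinary least squares of the trait on the proportion plus
#' covariates; reports the partial Pearson correlation (from the
#' proportion's t statistic) and the slope p value. Passing
#' `covariates = "BMI"` reproduces a BMI-adjusted design.
#'
#' @param props samples x cell-types proportion matrix (rownames =
#'   sample ids).
#' @param pheno phenotype data.frame with a `sample` column.
#' @param trait phenotype column tested.
#' @param cell_type proportion column tested.
#' @param covariates character vector of phenotype columns adjusted
#'   for (may be empty).
#' @param family optional family-id vector/column name for
#'   exchangeable-correlation GLS.
#' @param transform transform applied to the proportion before the
#'   fit. Proportions are bounded and strongly skewed, so the default
#'   inverse-normal transform keeps the linear-model errors well
#'   behaved (the same normalization the interaction eQTL models
#'   apply to macrophage proportion); `"none"` uses the raw
#'   proportion.
#' @return data.frame row: trait, cell_type, r (partial correlation),
#'   beta, p, n, covariates.
#' @export
cell_phenotype_association <- function(props, pheno, trait, cell_type,
                                       covariates = character(0),
                                       family = NULL,
                                       transform = c("inverse-normal",
                                                     "none")) {
  transform <- match.arg(transform)
  stopifnot(cell_type %in% colnames(props), trait %in% names(pheno))
  idx <- match(pheno$sample, rownames(props))
  if (anyNA(idx)) stop("phenotype samples missing from proportions", call. = FALSE)
  x <- props[idx, cell_type]
  if (var(x, na.rm = TRUE) == 0)
    stop("proportion of ", cell_type, " is constant", call. = FALSE)
  if (transform == "inverse-normal") x <- inverse_rank_normalize(x)
  y <- pheno[[trait]]
  Z <- if (length(covariates)) as.matrix(pheno[covariates]) else NULL
  fam <- if (is.character(family) && length(family) == 1)
    pheno[[family]] else family

  keep <- complete.cases(cbind(y, x, Z))
  y <- y[keep]; x <- x[keep]
  X <- cbind(`(Intercept)` = 1, prop = x,
             if (!is.null(Z)) Z[keep, , drop = FALSE])
  fit <- .family_gls(y, X, if (!is.null(fam)) fam[keep])
  tt <- fit$t[["prop"]]
  r <- sign(tt) * sqrt(tt^2 / (tt^2 + fit$df))
  data.frame(trait = trait, cell_type = cell_type, r = r,
             beta = fit$est[["prop"]], p = fit$p[["prop"]],
             n = length(y),
             covariates = paste(covariates, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Dual-model BMI-expression scan
#'
#' Per gene, fits model 1 (`expression ~ BMI + covariates`) and model
#' 2 (model 1 plus a cell-type proportion). A gene is called
#' significant under each model when its BMI p value passes Bonferroni
#' 0.05 / n_genes; the summary counts how many model-1 significant
#' genes lose significance once cell composition is adjusted for.
#'
#' @param expr expression matrix (genes x samples), already filtered.
#' @param pheno phenotype data.frame with `sample` and `BMI` columns.
#' @param adjust_cell named/unnamed numeric vector of cell proportions
#'   in sample order, or `NULL` for no adjustment (model 2 then equals
#'   model 1).
#' @param covariates optional numeric matrix of technical covariates
#'   (samples x covariates).
#' @param family optional family ids for exchangeable GLS.
#' @param alpha family-wise error rate for the Bonferroni threshold.
#' @return list with `records` (per-gene p values and significance
#'   under both models) and `summary` (n_genes, threshold,
#'   n_significant_model1, n_lost, fraction_lost).
#' @export
dual_model_expression_scan <- function(expr, pheno, adjust_cell = NULL,
                                       covariates = NULL, family = NULL,
                                       alpha = 0.05) {
  .assert_matrix(expr, "expr")
  stopifnot("BMI" %in% names(pheno))
  samples <- colnames(expr)
  idx <- match(samples, pheno$sample)
  if (anyNA(idx)) stop("expression samples missing from phenotypes", call. = FALSE)
  bmi <- pheno$BMI[idx]
  fam <- if (!is.null(family)) family[idx]
  X1 <- cbind(`(Intercept)` = 1, BMI = bmi,
              if (!is.null(covariates)) covariates)
  X2 <- if (is.null(adjust_cell)) X1 else cbind(X1, cell = adjust_cell)
  thr <- bonferroni_threshold(nrow(expr), alpha)

  p1 <- p2 <- numeric(nrow(expr))
  for (i in seq_len(nrow(expr))) {
    y <- expr[i, ]
    p1[i] <- .family_gls(y, X1, fam)$p[["BMI"]]
    p2[i] <- if (is.null(adjust_cell)) p1[i]
             else .family_gls(y, X2, fam)$p[["BMI"]]
  }
  records <- data.frame(gene = rownames(expr), p_model1 = p1,
                        p_model2 = p2,
                        sig_model1 = p1 <= thr, sig_model2 = p2 <= thr,
                        stringsAsFactors = FALSE)
  records$lost <- records$sig_model1 & !records$sig_model2
  n_sig <- sum(records$sig_model1)
  list(records = records,
       summary = list(n_genes = nrow(expr), threshold = thr,
                      n_significant_model1 = n_sig,
                      n_lost = sum(records$lost),
                      fraction_lost = if (n_sig > 0)
                        sum(records$lost) / n_sig else NA_real_))
}

#' Maximum-likelihood ACE twin model
#'
#' Fits the classical twin variance decomposition by maximising the
#' bivariate-normal likelihood of standardized trait pairs with
#' expected correlation `a2 + c2` for MZ pairs and `a2/2 + c2` for DZ
#' pairs. Components are constrained non-negative and sum to 1; the
#' narrow-sense heritability is the additive fraction `a2`. Boundary
#' solutions (e.g. a2 = 0) are reported as is.
#'
#' @param pairs a `twin_pairs` data.frame (columns `zygosity`,
#'   `twin1`, `twin2`), at least 20 pairs of each zygosity.
#' @return an `ace_estimate` list: `a2`, `c2`, `e2`, `loglik`,
#'   `n_mz`, `n_dz`.
#' @export
fit_ace <- function(pairs) {
  stopifnot(all(c("zygosity", "twin1", "twin2") %in% names(pairs)))
  mz <- pairs$zygosity == "MZ"; dz <- pairs$zygosity == "DZ"
  if (sum(mz) < 20 || sum(dz) < 20)
    stop("need at least 20 MZ and 20 DZ pairs", call. = FALSE)
  vals <- c(pairs$twin1, pairs$twin2)
  z <- (cbind(pairs$twin1, pairs$twin2) - mean(vals)) / sd(vals)
  z_mz <- z[mz, , drop = FALSE]; z_dz <- z[dz, , drop = FALSE]

  pair_ll <- function(zz, rho) {
    rho <- max(min(rho, 0.9999), -0.9999)
    q <- (zz[, 1]^2 - 2 * rho * zz[, 1] * zz[, 2] + zz[, 2]^2) /
      (1 - rho^2)
    sum(-log(2 * pi) - 0.5 * log(1 - rho^2) - q / 2)
  }
  # smooth box parameterization: s = a2 + c2 (the MZ correlation),
  # t = a2 / (a2 + c2); keeps the optimizer away from constraint kinks
  negll <- function(par) {
    s <- par[1]; t <- par[2]
    -(pair_ll(z_mz, s) + pair_ll(z_dz, s * (1 - t / 2)))
  }
  opt <- optim(c(0.5, 0.6), negll, method = "L-BFGS-B",
               lower = c(0, 0), upper = c(0.9999, 1))
  if (opt$convergence != 0)
    stop("ACE fit did not converge: ", opt$message, call. = FALSE)
  a2 <- opt$par[1] * opt$par[2]; c2 <- opt$par[1] * (1 - opt$par[2])
  structure(list(a2 = a2, c2 = c2, e2 = 1 - a2 - c2,
                 loglik = -opt$value, n_mz = sum(mz), n_dz = sum(dz)),
            class = "ace_estimate")
}

#' @export
print.ace_estimate <- function(x, ...) {
  cat(sprintf("ACE estimate (%d MZ, %d DZ pairs):\n", x$n_mz, x$n_dz))
  cat(sprintf("  a2 (h2) = %.3f  c2 = %.3f  e2 = %.3f  logLik = %.2f\n",
              x$a2, x$c2, x$e2, x$loglik))
  invisible(x)
}

#' PCA of a cell-proportion matrix
#'
#' @param props samples x cell-types proportion matrix.
#' @return prcomp scores (samples x PCs) of the centered matrix.
#' @export
props_pca <- function(props) {
  prcomp(props, center = TRUE, scale. = FALSE)$x
}

#' Covariate scan against cell proportions and their PCs
#'
#' Fits, per cell type, a linear model of the proportion on a
#' covariate plus adjusters, and additionally correlates the
#' covariate with the first three principal components of the
#' proportion matrix (capturing overall compositional
#' heterogeneity).
#'
#' @param props samples x cell-types proportion matrix.
#' @param pheno phenotype data.frame with `sample` column.
#' @param covariate phenotype column scanned (e.g. ischemic time).
#' @param adjusters phenotype columns adjusted for.
#' @return list with `per_cell` (cell type, beta, p) and `pcs` (pc,
#'   r, p for PC1-PC3).
#' @export
covariate_scan <- function(props, pheno, covariate,
                           adjusters = character(0)) {
  stopifnot(covariate %in% names(pheno))
  idx <- match(pheno$sample, rownames(props))
  if (anyNA(idx)) stop("phenotype samples missing from proportions", call. = FALSE)
  P <- props[idx, , drop = FALSE]
  v <- pheno[[covariate]]
  Z <- if (length(adjusters)) as.matrix(pheno[adjusters]) else NULL

  per_cell <- do.call(rbind, lapply(colnames(P), function(ct) {
    X <- cbind(`(Intercept)` = 1, cov = v, Z)
    keep <- complete.cases(cbind(P[, ct], X))
    fit <- .family_gls(P[keep, ct], X[keep, , drop = FALSE])
    data.frame(cell_type = ct, beta = fit$est[["cov"]],
               p = fit$p[["cov"]], stringsAsFactors = FALSE)
  }))

  scores <- props_pca(P)
  n_pc <- min(3, ncol(scores))
  pcs <- do.call(rbind, lapply(seq_len(n_pc), function(i) {
    ct <- cor.test(v, scores[, i])
    data.frame(pc = paste0("PC", i), r = unname(ct$estimate),
               p = ct$p.value, stringsAsFactors = FALSE)
  }))
  list(per_cell = per_cell, pcs = pcs)
}

#' Weighted genetic risk score
#'
#' GRS per sample = sum of beta * dosage of the effect allele. Weights
#' whose effect allele matches neither REF nor ALT are skipped with a
#' warning; the matched count is attached.
#'
#' @param genotypes a `genotype_matrix`.
#' @param weights data.frame with columns `snp`, `effect_allele`,
#'   `beta`.
#' @return data.frame (`sample`, `grs`) with attribute `n_matched`.
#' @export
compute_grs <- function(genotypes, weights) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            all(c("snp", "effect_allele", "beta") %in% names(weights)))
  grs <- rep(0, ncol(genotypes$dosages))
  matched <- 0
  for (i in seq_len(nrow(weights))) {
    j <- match(weights$snp[i], genotypes$info$snp)
    if (is.na(j)) next
    ea <- weights$effect_allele[i]
    d <- genotypes$dosages[j, ]
    if (ea == genotypes$info$alt[j]) {
      grs <- grs + weights$beta[i] * d
    } else if (ea == genotypes$info$ref[j]) {
      grs <- grs + weights$beta[i] * (2 - d)
    } else {
      warning("effect allele of ", weights$snp[i],
              " matches neither REF nor ALT; skipped")
      next
    }
    matched <- matched + 1
  }
  out <- data.frame(sample = colnames(genotypes$dosages), grs = grs,
                    stringsAsFactors = FALSE)
  attr(out, "n_matched") <- matched
  out
}

#' Associate a genetic risk score with an outcome
#'
#' Linear association of an outcome (trait or cell proportion) with
#' the GRS, adjusting for covariates, with exchangeable within-family
#' GLS when family ids are supplied.
#'
#' @param grs data.frame from [compute_grs()].
#' @param outcome named numeric vector (names = sample ids).
#' @param covariates optional data.frame/matrix of covariates in GRS
#'   sample order.
#' @param family optional family ids in GRS sample order.
#' @param outcome_name label for the output row.
#' @return data.frame row: outcome, beta, se, p, n.
#' @export
grs_association <- function(grs, outcome, covariates = NULL,
                            family = NULL, outcome_name = "outcome") {
  y <- outcome[grs$sample]
  X <- cbind(`(Intercept)` = 1, grs = grs$grs,
             if (!is.null(covariates)) as.matrix(covariates))
  keep <- complete.cases(cbind(y, X))
  fit <- .family_gls(y[keep], X[keep, , drop = FALSE],
                     if (!is.null(family)) family[keep])
  data.frame(outcome = outcome_name, beta = fit$est[["grs"]],
             se = fit$se[["grs"]], p = fit$p[["grs"]], n = sum(keep),
             stringsAsFactors = FALSE)
}
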