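# cis-eQTL scanning with eigenMT effective-test correction, latent
# expression factors, and genotype-by-cell-proportion interaction
# modeling with Bonferroni control over the tests actually run.

#' Map genes to cis-window SNPs
#'
#' A SNP is cis to a gene when it lies on the same chromosome within
#' `window` bp of the transcription start site (inclusive on both
#' sides, i.e. TSS +/- window).
#'
#' @param annot data.frame with columns `gene`, `chrom`, `tss`.
#' @param genotypes a `genotype_matrix`.
#' @param window half-width in bp (default 1e6: a TSS-centered
#'   2 Mb scan region).
#' @return named list gene -> character vector of SNP ids (possibly
#'   empty).
#' @export
cis_windows <- function(annot, genotypes, window = 1e6) {
  stopifnot(all(c("gene", "chrom", "tss") %in% names(annot)),
            inherits(genotypes, "genotype_matrix"))
  info <- genotypes$info
  out <- lapply(seq_len(nrow(annot)), function(i) {
    hit <- info$chrom == annot$chrom[i] &
      abs(info$pos - annot$tss[i]) <= window
    info$snp[hit]
  })
  names(out) <- annot$gene
  out
}

#' Filter SNPs by minor allele frequency
#'
#' @param genotypes a `genotype_matrix`.
#' @param threshold minimum MAF (default 0.05); the frequency is
#'   computed from the dosage mean and folded to the minor allele.
#' @return the filtered `genotype_matrix`.
#' @export
maf_filter <- function(genotypes, threshold = 0.05) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  freq <- rowMeans(genotypes$dosages) / 2
  keep <- pmin(freq, 1 - freq) >= threshold
  genotypes$dosages <- genotypes$dosages[keep, , drop = FALSE]
  genotypes$info <- genotypes$info[keep, , drop = FALSE]
  genotypes$maf <- genotypes$maf[keep]
  genotypes
}

#' Latent expression factors (top principal components)
#'
#' Latent confounder adjustment via the top-k principal components of
#' the inverse-normal-transformed, centered expression matrix. PCs
#' and probabilistic factor models (PEER and kin) capture near
#' identical composition and batch structure in population expression
#' data, and PCs are deterministic.
#'
#' @param expr expression matrix (genes x samples).
#' @param k number of factors (0 <= k < n_samples).
#' @return samples x k matrix of orthonormal factor scores.
#' @export
latent_factors <- function(expr, k = 30) {
  .assert_matrix(expr, "expr")
  n <- ncol(expr)
  if (k >= n) stop("k must be smaller than the number of samples", call. = FALSE)
  if (k == 0)
    return(matrix(0, n, 0, dimnames = list(colnames(expr), NULL)))
  normed <- t(apply(expr, 1, inverse_rank_normalize))
  pc <- prcomp(t(normed), center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  scores <- sweep(scores, 2, sqrt(colSums(scores^2)), "/")
  rownames(scores) <- colnames(expr)
  scores
}

# Residualize the rows of a matrix (variables x samples) on covariate
# columns (samples x q), including an intercept.
.residualize_rows <- function(m, covariates) {
  X <- cbind(1, covariates)
  qx <- qr(X)
  t(qr.resid(qx, t(m)))
}

#' cis-eQTL scan
#'
#' Per gene-SNP pair, an OLS slope t-test of inverse-normal-transformed
#' expression on ALT-allele dosage, after residualizing both on the
#' covariates. Gene-level significance uses eigenMT: the minimum
#' nominal p per gene is multiplied by the effective number of tests
#' in its cis-window, then Benjamini-Hochberg FDR is applied across
#' genes.
#'
#' @param expr expression matrix (genes x samples); values are
#'   inverse-normal-transformed internally per gene.
#' @param genotypes a `genotype_matrix` (MAF-filtered).
#' @param windows gene -> SNP-id list from [cis_windows()].
#' @param covariates optional samples x q covariate matrix (e.g.
#'   [latent_factors()] output, phenotypes).
#' @param fdr across-gene FDR level for the significance call.
#' @param variance_explained eigenMT variance fraction (default 0.99).
#' @return list with `pairs` (gene, snp, beta, se, p_nominal) and
#'   `genes` (gene, best snp, p_min, k_eff, p_adjusted, fdr,
#'   significant).
#' @export
cis_scan <- function(expr, genotypes, windows, covariates = NULL,
                     fdr = 0.05, variance_explained = 0.99) {
  .assert_matrix(expr, "expr")
  stopifnot(inherits(genotypes, "genotype_matrix"))
  samples <- colnames(expr)
  if (!identical(samples, colnames(genotypes$dosages)))
    stop("expression and genotype samples differ or are reordered",
         call. = FALSE)
  n <- length(samples)
  q <- if (is.null(covariates)) 0 else ncol(covariates)
  df <- n - 2 - q

  E <- t(apply(expr, 1, inverse_rank_normalize))
  colnames(E) <- samples
  G <- genotypes$dosages
  if (!is.null(covariates)) {
    E <- .residualize_rows(E, covariates)
    G <- .residualize_rows(G, covariates)
  }
  E <- E - rowMeans(E)
  G <- G - rowMeans(G)

  pair_rows <- list()
  gene_rows <- list()
  for (gene in names(windows)) {
    snps <- intersect(windows[[gene]], rownames(G))
    if (length(snps) == 0 || !gene %in% rownames(E)) next
    e <- E[gene, ]
    gs <- G[snps, , drop = FALSE]
    sxx <- rowSums(gs^2)
    ok <- sxx > 0
    if (!any(ok)) next
    gs <- gs[ok, , drop = FALSE]; snps <- snps[ok]; sxx <- sxx[ok]
    beta <- drop(gs %*% e) / sxx
    syy <- sum(e^2)
    rss <- syy - beta^2 * sxx
    se <- sqrt(pmax(rss, 0) / df / sxx)
    tt <- beta / se
    p <- 2 * pt(-abs(tt), df)
    pair_rows[[gene]] <- data.frame(gene = gene, snp = snps,
                                    beta = beta, se = se, p_nominal = p,
                                    stringsAsFactors = FALSE,
                                    row.names = NULL)
    k_eff <- eigenmt_effective_tests(genotypes$dosages[snps, , drop = FALSE],
                                     variance_explained)
    i_min <- which.min(p)
    gene_rows[[gene]] <- data.frame(gene = gene, snp = snps[i_min],
                                    p_min = p[i_min], k_eff = k_eff,
                                    p_adjusted = eigenmt_adjust(p[i_min], k_eff),
                                    stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, pair_rows)
  genes <- do.call(rbind, gene_rows)
  rownames(pairs) <- rownames(genes) <- NULL
  if (!is.null(genes)) {
    genes$fdr <- p.adjust(genes$p_adjusted, method = "BH")
    genes$significant <- genes$fdr <= fdr
  }
  list(pairs = pairs, genes = genes)
}

#' Effective number of tests in a cis-window (eigenMT)
#'
#' The smallest number of leading eigenvalues of the SNP correlation
#' matrix whose sum reaches `variance_explained` of the trace.
#'
#' @param genotype_window dosage matrix, SNPs x samples.
#' @param variance_explained fraction of variance (default 0.99).
#' @return integer k_eff in \[1, n_snps\].
#' @export
eigenmt_effective_tests <- function(genotype_window,
                                    variance_explained = 0.99) {
  if (nrow(genotype_window) == 0) stop("empty cis-window", call. = FALSE)
  v <- .row_vars(genotype_window)
  if (any(v == 0)) {
    warning("dropping ", sum(v == 0), " zero-variance SNP(s)")
    genotype_window <- genotype_window[v > 0, , drop = FALSE]
    if (nrow(genotype_window) == 0) return(1L)
  }
  if (nrow(genotype_window) == 1) return(1L)
  cc <- cor(t(genotype_window))
  ev <- eigen(cc, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  which(cumsum(ev) / sum(ev) >= variance_explained)[1]
}

#' eigenMT-adjusted p value
#'
#' @param p_min minimum nominal p in the window.
#' @param k_eff effective number of tests.
#' @return `min(1, p_min * k_eff)`.
#' @export
eigenmt_adjust <- function(p_min, k_eff) pmin(1, p_min * k_eff)

#' Genotype-by-cell-proportion interaction scan
#'
#' Per gene-SNP pair, fits
#' `expression ~ genotype + cell + genotype:cell + covariates` on
#' inverse-normal-transformed expression and reports the Wald t test
#' of the interaction term. The cell proportion is inverse-normal
#' transformed (the transform is idempotent, so pre-transformed input
#' is safe). Significance is Bonferroni over the number of tests
#' actually executed.
#'
#' @param expr expression matrix (genes x samples).
#' @param genotypes a `genotype_matrix`.
#' @param cell_prop numeric vector of cell-type proportions in sample
#'   order.
#' @param windows gene -> SNP-id list from [cis_windows()].
#' @param covariates optional samples x q covariate matrix.
#' @param cell_type label recorded in the output.
#' @param alpha family-wise rate for the Bonferroni call.
#' @return data.frame (gene, snp, cell_type, beta_interaction, se, p,
#'   significant) with attributes `n_tests` and `threshold`.
#' @export
interaction_scan <- function(expr, genotypes, cell_prop, windows,
                             covariates = NULL,
                             cell_type = "macrophage", alpha = 0.05) {
  .assert_matrix(expr, "expr")
  stopifnot(inherits(genotypes, "genotype_matrix"))
  samples <- colnames(expr)
  if (!identical(samples, colnames(genotypes$dosages)))
    stop("expression and genotype samples differ or are reordered",
         call. = FALSE)
  z <- inverse_rank_normalize(cell_prop)

  rows <- list()
  for (gene in names(windows)) {
    snps <- intersect(windows[[gene]], rownames(genotypes$dosages))
    if (length(snps) == 0 || !gene %in% rownames(expr)) next
    e <- inverse_rank_normalize(expr[gene, ])
    for (snp in snps) {
      g <- genotypes$dosages[snp, ]
      X <- cbind(`(Intercept)` = 1, g = g, cell = z, gxc = g * z,
                 covariates)
      fit <- .family_gls(e, X, NULL)
      rows[[length(rows) + 1]] <-
        data.frame(gene = gene, snp = snp, cell_type = cell_type,
                   beta_interaction = fit$est[["gxc"]],
                   se = fit$se[["gxc"]], p = fit$p[["gxc"]],
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  n_tests <- if (is.null(out)) 0L else nrow(out)
  thr <- if (n_tests > 0) bonferroni_threshold(n_tests, alpha) else NA_real_
  if (!is.null(out)) out$significant <- out$p <= thr
  attr(out, "n_tests") <- n_tests
  attr(out, "threshold") <- thr
  out
}

#' Bonferroni p-value threshold
#'
#' @param n_tests number of tests (>= 1).
#' @param alpha family-wise error rate (default 0.05).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  stopifnot(n_tests >= 1)
  alpha / n_tests
}
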