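#' TMM scaling factors for a count matrix
#'
#' Computes trimmed-mean-of-M-values (TMM) normalization factors
#' (Robinson & Oshlack) for each sample of a gene-by-sample count
#' matrix. M-values (log fold changes against a reference sample) are
#' trimmed symmetrically by `trim_m`, A-values (average log abundance)
#' by `trim_a`, and the factor is the precision-weighted mean of the
#' surviving M-values. The reference sample is the one whose
#' library-size-scaled upper quartile is closest to the mean upper
#' quartile. Factors are rescaled so their geometric mean is exactly 1.
#'
#' @param counts numeric matrix of non-negative counts, genes in rows,
#'   samples in columns, both dimensions named.
#' @param trim_m fraction of M-values trimmed from each tail (default
#'   0.30).
#' @param trim_a fraction of A-values trimmed from each tail (default
#'   0.05).
#' @return named numeric vector of scaling factors, one per sample,
#'   with geometric mean 1.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  .assert_matrix(counts, "counts")
  if (ncol(counts) < 2) stop("need at least 2 samples", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  lib <- colSums(counts)
  if (any(lib == 0))
    stop("sample(s) with zero total counts: ",
         paste(colnames(counts)[lib == 0], collapse = ", "), call. = FALSE)

  # reference: upper quartile of counts/libsize closest to the mean
  uq <- apply(sweep(counts, 2, lib, "/"), 2, quantile, probs = 0.75)
  ref_i <- which.min(abs(uq - mean(uq)))
  ref <- counts[, ref_i]
  n_ref <- lib[ref_i]

  f <- vapply(seq_len(ncol(counts)), function(j) {
    .tmm_pair_factor(counts[, j], ref, lib[j], n_ref, trim_m, trim_a)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

# Weighted trimmed mean of M-values for one sample against the
# reference; weights are delta-method precisions of the M-values.
.tmm_pair_factor <- function(obs, ref, n_obs, n_ref, trim_m, trim_a) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  if (length(obs) == 0) return(1)
  log_r <- log2((obs / n_obs) / (ref / n_ref))
  abs_e <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  if (max(abs(log_r)) < 1e-6) return(1)
  n <- length(log_r)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  rk_m <- rank(log_r); rk_a <- rank(abs_e)
  keep2 <- rk_m >= lo_m & rk_m <= hi_m & rk_a >= lo_a & rk_a <= hi_a
  if (!any(keep2)) return(1)
  f <- sum(log_r[keep2] / v[keep2]) / sum(1 / v[keep2])
  2^f
}

#' TMM-normalize a count matrix
#'
#' Applies [tmm_factors()] and returns expression on the TMM scale:
#' counts divided by the effective library size (library size times
#' scaling factor), per million.
#'
#' @inheritParams tmm_factors
#' @return numeric matrix of TMM-normalized expression with
#'   `unit_label` attribute `"TMM"`, and the factors in attribute
#'   `"tmm_factors"`.
#' @export
tmm_normalize <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  f <- tmm_factors(counts, trim_m, trim_a)
  eff <- colSums(counts) * f
  out <- sweep(counts, 2, eff, "/") * 1e6
  attr(out, "tmm_factors") <- f
  .set_unit(out, "TMM")
}

#' Filter lowly expressed genes
#'
#' Retains genes expressed at `>= min_tmm` in at least `min_fraction`
#' of samples (both bounds inclusive). The defaults reproduce the
#' "at least 0.5 TMM in 90% of samples" rule used for association and
#' eQTL analysis; cell-type estimation itself is run unfiltered so
#' that abundance filtering cannot bias proportions toward the
#' dominant cell type.
#'
#' @param expr TMM expression matrix (genes x samples).
#' @param min_tmm minimum expression level, TMM units.
#' @param min_fraction minimum fraction of samples at or above
#'   `min_tmm`.
#' @return the filtered expression matrix; warns if no gene survives.
#' @export
filter_expressed <- function(expr, min_tmm = 0.5, min_fraction = 0.90) {
  .assert_matrix(expr, "expr")
  u <- .get_unit(expr)
  if (!is.na(u) && u != "TMM")
    stop("filter_expressed expects TMM-scale expression, got ", u, call. = FALSE)
  keep <- rowMeans(expr >= min_tmm) >= min_fraction
  if (!any(keep)) warning("no genes pass the expression filter")
  out <- expr[keep, , drop = FALSE]
  attr(out, "tmm_factors") <- attr(expr, "tmm_factors")
  .set_unit(out, "TMM")
}

#' Inverse-rank normal transform
#'
#' Maps values to normal quantiles of their Blom-offset ranks,
#' \eqn{\Phi^{-1}((r - 3/8)/(n + 1/4))}, with ties given average
#' ranks. Missing values are preserved in place; ranks are computed
#' over the non-missing values only.
#'
#' @param x numeric vector with at least 3 non-missing values.
#' @return numeric vector of the same length, approximately standard
#'   normal.
#' @export
inverse_rank_normalize <- function(x) {
  ok <- !is.na(x)
  v <- x[ok]
  if (length(v) < 3) stop("need at least 3 non-missing values", call. = FALSE)
  if (diff(range(v)) == 0)
    stop("all values identical; rank transform undefined", call. = FALSE)
  n <- length(v)
  out <- x
  out[ok] <- qnorm((rank(v, ties.method = "average") - 3 / 8) / (n + 1 / 4))
  out
}

#' Expression-PCA outlier detection by k-means
#'
#' Projects samples onto the first two expression principal components
#' and fits k-means (default k = 2, 10 restarts, fixed seed). Members
#' of the strictly smallest cluster are reported as outliers; if the
#' smallest cluster size is tied, no sample is called an outlier and a
#' warning is emitted.
#'
#' @param expr expression matrix (genes x samples).
#' @param k_clusters number of k-means clusters (default 2).
#' @param seed RNG seed for the k-means restarts.
#' @return character vector of outlier sample ids (possibly empty).
#' @export
pca_sample_outliers <- function(expr, k_clusters = 2, seed = 1) {
  .assert_matrix(expr, "expr")
  if (ncol(expr) < 2 * k_clusters)
    stop("need at least ", 2 * k_clusters, " samples", call. = FALSE)
  x <- t(expr)
  x <- x[, .row_vars(expr) > 0, drop = FALSE]
  if (ncol(x) == 0 || nrow(unique(x)) < k_clusters) {
    warning("samples are not separable into ", k_clusters,
            " distinct clusters; no outliers called")
    return(character(0))
  }
  pcs <- prcomp(x, center = TRUE, scale. = FALSE)$x
  scores <- pcs[, seq_len(min(2, ncol(pcs))), drop = FALSE]
  km <- withr::with_seed(seed, kmeans(scores, centers = k_clusters, nstart = 10))
  sizes <- tabulate(km$cluster, nbins = k_clusters)
  smallest <- which(sizes == min(sizes))
  if (length(smallest) > 1) {
    warning("smallest clusters tied in size; no outliers called")
    return(character(0))
  }
  colnames(expr)[km$cluster == smallest]
}
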