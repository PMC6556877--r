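# nu-SVR deconvolution of bulk mixtures against a signature matrix.
# Both the mixture and the signature columns are z-scored over their
# shared genes, a linear-kernel nu-SVR is fitted for each nu in a
# small grid, and the nu whose reconstruction has the lowest RMSE is
# kept. Negative coefficients are truncated at zero and the rest
# renormalized to the simplex, giving relative (not absolute)
# proportions.

#' Deconvolve a single bulk sample
#'
#' @param mixture named numeric vector of bulk expression (gene ids as
#'   names, linear TMM-like scale).
#' @param sig a `signature_matrix`.
#' @param nu_grid candidate nu values (default 0.25, 0.50, 0.75).
#' @param cost SVR regularization constant (default 1).
#' @return list with `proportions` (named, on the simplex, or NA if
#'   all coefficients were non-positive), `pearson_r` (correlation of
#'   reconstruction with the mixture), `rmse`, `nu`, `all_zero` flag.
#' @export
deconvolve_sample <- function(mixture, sig, nu_grid = c(0.25, 0.50, 0.75),
                              cost = 1) {
  stopifnot(inherits(sig, "signature_matrix"))
  shared <- intersect(names(mixture), rownames(sig$values))
  if (length(shared) < 0.5 * nrow(sig$values)) {
    missing <- setdiff(rownames(sig$values), names(mixture))
    stop("mixture covers < 50% of signature genes; missing: ",
         paste(utils::head(missing, 10), collapse = ", "),
         if (length(missing) > 10) ", ...", call. = FALSE)
  }
  if (sd(mixture[shared]) == 0)
    stop("mixture is constant over the signature genes", call. = FALSE)
  X <- .standardize_sig(sig$values[shared, , drop = FALSE])
  y <- as.numeric(scale(mixture[shared]))
  fit <- .nusvr_fit(X, y, nu_grid, cost)

  w <- fit$w
  all_zero <- all(w <= 0)
  if (all_zero) {
    warning("all nu-SVR coefficients non-positive; proportions undefined")
    props <- rep(NA_real_, ncol(X))
  } else {
    w[w < 0] <- 0
    props <- w / sum(w)
  }
  names(props) <- sig$cell_types
  list(proportions = props, pearson_r = fit$r, rmse = fit$rmse,
       nu = fit$nu, all_zero = all_zero)
}

# The signature is standardized globally (one mean and sd over the
# whole shared-gene submatrix) rather than per column: the relative
# magnitudes of the cell-type columns carry the information that maps
# SVR coefficients to proportions, and per-column scaling would
# discard it. The mixture is z-scored per sample, which also makes
# the estimates invariant to positive rescaling of the input.
.standardize_sig <- function(X) {
  (X - mean(X)) / sd(as.vector(X))
}

# Fit the nu grid and keep the minimum-RMSE solution. X and y are
# already standardized; w is the linear weight vector over cell
# types. The kernel matrix Q = X X^T depends only on the signature,
# so callers that deconvolve many mixtures (or permutations) against
# one signature precompute it once.
.nusvr_fit <- function(X, y, nu_grid, cost, Q = NULL) {
  if (is.null(Q)) Q <- tcrossprod(X)
  best <- NULL
  for (nu in nu_grid) {
    beta <- .nusvr_smo(Q, y, nu, cost)
    w <- drop(crossprod(X, beta))
    recon <- drop(X %*% w)
    rmse <- sqrt(mean((recon - y)^2))
    if (is.null(best) || rmse < best$rmse) {
      r <- suppressWarnings(cor(recon, y))
      if (is.na(r)) r <- 0
      best <- list(w = w, rmse = rmse, r = r, nu = nu)
    }
  }
  best
}

#' Permutation deconvolution p value for one sample
#'
#' The null distribution is the fit correlation of deconvolutions of
#' gene-permuted versions of the mixture; p = (1 + #(null >= observed))
#' / (1 + n_perm). The whole mixture vector is permuted — each null
#' draw assigns a random subset of all the sample's expression values
#' to the signature genes — not just the values already on signature
#' genes; shuffling within the signature subset understates the null
#' variance and inflates the tail.
#'
#' @inheritParams deconvolve_sample
#' @param n_perm number of permutations (>= 100; default 1000).
#' @param seed RNG seed.
#' @return p value in (0, 1].
#' @export
permutation_p <- function(mixture, sig, n_perm = 1000, seed = 1,
                          nu_grid = c(0.25, 0.50, 0.75), cost = 1) {
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  obs <- deconvolve_sample(mixture, sig, nu_grid, cost)$pearson_r
  shared <- intersect(names(mixture), rownames(sig$values))
  X <- .standardize_sig(sig$values[shared, , drop = FALSE])
  Q <- tcrossprod(X)
  pool <- as.numeric(mixture)
  n_sh <- length(shared)
  null_r <- withr::with_seed(seed, vapply(seq_len(n_perm), function(i) {
    yp <- as.numeric(scale(sample(pool, n_sh)))
    .nusvr_fit(X, yp, nu_grid, cost, Q = Q)$r
  }, numeric(1)))
  (1 + sum(null_r >= obs)) / (1 + n_perm)
}

#' Deconvolve a cohort of bulk samples
#'
#' Runs [deconvolve_sample()] on every column of an expression matrix
#' and assigns per-sample permutation p values (each sample gets its
#' own gene-permutation null; null distributions differ substantially
#' between samples, so sharing one null across samples miscalibrates
#' the tail).
#'
#' With `early_stop = TRUE` (default) permutations for a sample halt
#' as soon as enough null exceedances have accumulated to prove
#' `p >= p_threshold` at the full `n_perm` — the pass/fail call is
#' then exactly the one the complete run would make, while clearly
#' failing samples cost a fraction of the permutations. The reported
#' `p_value` uses the permutations actually run
#' (`(1 + exceedances) / (1 + n_perm_used)`); samples that pass always
#' complete all `n_perm` permutations, so their p values are the full
#' permutation p.
#'
#' @param expr expression matrix (genes x samples).
#' @param sig a `signature_matrix`.
#' @param nu_grid,cost see [deconvolve_sample()].
#' @param n_perm permutations per sample; 0 skips p values.
#' @param seed RNG seed.
#' @param early_stop halt a sample's permutations once failure at
#'   `p_threshold` is certain (decision unchanged; see above).
#' @param drop_failed if `TRUE`, rows failing p < `p_threshold` are
#'   removed from the returned table (they are flagged, not removed,
#'   by default).
#' @param p_threshold pass/fail threshold (default 0.01, i.e. 1% FDR).
#' @return data.frame with one row per sample: proportions (one column
#'   per cell type), `pearson_r`, `rmse`, `p_value`, `n_perm_used`,
#'   `nu`, `pass`; attribute `failed_fraction`.
#' @export
deconvolve_cohort <- function(expr, sig, nu_grid = c(0.25, 0.50, 0.75),
                              cost = 1, n_perm = 1000, seed = 1,
                              early_stop = TRUE, drop_failed = FALSE,
                              p_threshold = 0.01) {
  .assert_matrix(expr, "expr")
  samples <- colnames(expr)
  res <- lapply(samples, function(s) {
    tryCatch(deconvolve_sample(expr[, s], sig, nu_grid, cost),
             error = function(e) list(proportions = rep(NA_real_,
                                        length(sig$cell_types)),
                                      pearson_r = NA_real_, rmse = NA_real_,
                                      nu = NA_real_, all_zero = NA,
                                      error = conditionMessage(e)))
  })
  props <- do.call(rbind, lapply(res, function(x) x$proportions))
  colnames(props) <- sig$cell_types
  out <- data.frame(sample = samples, props,
                    pearson_r = vapply(res, function(x) x$pearson_r, 1),
                    rmse = vapply(res, function(x) x$rmse, 1),
                    p_value = NA_real_, n_perm_used = NA_integer_,
                    nu = vapply(res, function(x) x$nu, 1),
                    stringsAsFactors = FALSE, row.names = NULL)

  if (n_perm > 0) {
    shared <- intersect(rownames(expr), rownames(sig$values))
    X <- .standardize_sig(sig$values[shared, , drop = FALSE])
    Q <- tcrossprod(X)
    # failure at the threshold is certain once (1 + k) / (1 + n_perm)
    # >= p_threshold
    k_fail <- ceiling(p_threshold * (1 + n_perm)) - 1
    chunk <- 25L
    n_sh <- length(shared)
    for (j in seq_along(samples)) {
      if (is.na(out$pearson_r[j])) next
      obs <- out$pearson_r[j]
      pool <- as.numeric(expr[, samples[j]])
      withr::with_seed(.substream_seed(seed, j), {
        k <- 0L; done <- 0L
        while (done < n_perm) {
          m <- min(chunk, n_perm - done)
          nr <- vapply(seq_len(m), function(i) {
            yp <- as.numeric(scale(sample(pool, n_sh)))
            .nusvr_fit(X, yp, nu_grid, cost, Q = Q)$r
          }, numeric(1))
          k <- k + sum(nr >= obs)
          done <- done + m
          if (early_stop && k >= k_fail) break
        }
      })
      out$p_value[j] <- (1 + k) / (1 + done)
      out$n_perm_used[j] <- done
    }
    out$pass <- !is.na(out$p_value) & out$p_value < p_threshold
  } else {
    out$pass <- NA
  }

  attr(out, "failed_fraction") <-
    if (n_perm > 0) mean(!out$pass) else NA_real_
  if (drop_failed && n_perm > 0) out <- out[out$pass, , drop = FALSE]
  out
}
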