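# In silico mixture benchmarking: known mixing proportions, noise
# injection, contaminant spiking, and the mean-absolute-deviation
# accuracy metric.

#' Sample a random mixture design
#'
#' Each row is k iid Uniform(0,1) draws normalized to sum to 1 (the
#' construction used for the ground-truth mixtures).
#'
#' @param n_mixtures number of mixtures (default 1000).
#' @param k number of cell types.
#' @param seed RNG seed.
#' @param cell_types optional column labels.
#' @return n_mixtures x k matrix `M` with rows on the simplex.
#' @export
sample_mixture_matrix <- function(n_mixtures = 1000, k = 4, seed = 1,
                                  cell_types = NULL) {
  stopifnot(n_mixtures >= 1, k >= 1)
  M <- withr::with_seed(seed, matrix(runif(n_mixtures * k), n_mixtures, k))
  M <- M / rowSums(M)
  rownames(M) <- sprintf("mix%04d", seq_len(n_mixtures))
  colnames(M) <- if (!is.null(cell_types)) cell_types
                 else paste0("cell", seq_len(k))
  M
}

#' Synthesize ground-truth mixtures, S = C M^T
#'
#' @param C genes x cell-types matrix of reference profiles (a plain
#'   matrix, or a `reference_panel` whose type means are used).
#' @param design mixtures x cell-types proportion matrix `M`; column
#'   order must match `C`.
#' @return genes x mixtures expression matrix (no noise).
#' @export
synthesize <- function(C, design) {
  if (inherits(C, "reference_panel")) C <- C$means
  if (ncol(C) != ncol(design))
    stop("C and design disagree on the number of cell types", call. = FALSE)
  if (!is.null(colnames(C)) && !is.null(colnames(design)) &&
      !identical(colnames(C), colnames(design)))
    stop("C and design cell-type columns differ or are reordered", call. = FALSE)
  S <- C %*% t(design)
  S
}

#' Add scaled Gaussian noise to a mixture
#'
#' Default (`formula = "multiplicative"`): per gene,
#' `y1 = y0 * (1 + noise_scale * x)` with `x ~ N(0,1)` iid — each
#' expression value is distorted by zero-mean Gaussian noise whose SD
#' is `noise_scale` times the value ("10% noise" = noise_scale 0.1).
#' The literal additive form `y1 = y0 + x + y0 * noise_scale` is
#' available as `formula = "additive"` for comparison; it adds a unit
#' normal in expression units plus a deterministic scaling, and is
#' dimensionally odd, which is why the multiplicative reading is the
#' default. Negative values are clipped at 0 in both cases.
#'
#' @param y0 numeric vector or matrix of noiseless expression.
#' @param noise_scale scale factor in [0, 1].
#' @param seed RNG seed.
#' @param formula `"multiplicative"` (default) or `"additive"`.
#' @return noisy expression, same shape as `y0`.
#' @export
add_noise <- function(y0, noise_scale, seed = 1,
                      formula = c("multiplicative", "additive")) {
  stopifnot(noise_scale >= 0, noise_scale <= 1)
  formula <- match.arg(formula)
  if (noise_scale == 0 && formula == "multiplicative") return(y0)
  x <- withr::with_seed(seed, {
    v <- rnorm(length(y0))
    if (is.matrix(y0)) matrix(v, nrow(y0), ncol(y0)) else v
  })
  y1 <- if (formula == "multiplicative") y0 * (1 + noise_scale * x)
        else y0 + x + y0 * noise_scale
  y1[y1 < 0] <- 0
  if (is.matrix(y0)) dimnames(y1) <- dimnames(y0) else names(y1) <- names(y0)
  y1
}

#' Spike a contaminant profile into a mixture
#'
#' Returns `(1 - fraction) * mixture + fraction * contaminant`.
#'
#' @param mixture,contaminant_profile numeric vectors on the same gene
#'   index.
#' @param fraction contaminant fraction in [0, 1).
#' @return the contaminated mixture vector.
#' @export
spike_contaminant <- function(mixture, contaminant_profile, fraction) {
  stopifnot(fraction >= 0, fraction < 1)
  if (length(mixture) != length(contaminant_profile))
    stop("mixture and contaminant must share the gene index", call. = FALSE)
  (1 - fraction) * mixture + fraction * contaminant_profile
}

#' Mean absolute deviation of estimated versus true proportions
#'
#' @param truth mixtures x cell-types matrix of true proportions.
#' @param estimates matching matrix (or data.frame) of estimates; rows
#'   and columns are matched by name when named.
#' @return list with `per_type` (named mAD per cell type) and
#'   `overall` (mean across types).
#' @export
evaluate_mad <- function(truth, estimates) {
  estimates <- as.matrix(estimates)
  if (!is.null(rownames(truth)) && !is.null(rownames(estimates))) {
    if (!setequal(rownames(truth), rownames(estimates)))
      stop("truth and estimates sample ids differ", call. = FALSE)
    estimates <- estimates[rownames(truth), , drop = FALSE]
  }
  if (!is.null(colnames(truth)) && !is.null(colnames(estimates))) {
    if (!setequal(colnames(truth), colnames(estimates)))
      stop("truth and estimates cell types differ", call. = FALSE)
    estimates <- estimates[, colnames(truth), drop = FALSE]
  }
  if (!all(dim(truth) == dim(estimates)))
    stop("truth and estimates dimensions differ", call. = FALSE)
  per_type <- colMeans(abs(estimates - truth))
  list(per_type = per_type, overall = mean(per_type))
}

#' Run the full mixture benchmark
#'
#' Simulates `n_mixtures` known mixtures from held-out replicate
#' profiles of a reference panel (so the mixtures carry independent
#' replicate-level noise relative to the signature), optionally adds
#' scaled Gaussian noise and a contaminant, deconvolves every mixture,
#' and reports per-cell-type mAD.
#'
#' @param panel a `reference_panel`.
#' @param sig a `signature_matrix` built from the panel's stored
#'   replicates.
#' @param n_mixtures number of simulated mixtures.
#' @param noise_scale scaled Gaussian noise level (see [add_noise()]).
#' @param contaminant_fraction fraction of an out-of-signature
#'   contaminant profile spiked into every mixture (0 = none).
#' @param seed RNG seed.
#' @param nu_grid,cost see [deconvolve_sample()].
#' @return list with `mad` (from [evaluate_mad()]), `truth`,
#'   `estimates`, `noise_scale`, `contaminant_fraction`.
#' @export
run_mixture_benchmark <- function(panel, sig, n_mixtures = 1000,
                                  noise_scale = 0,
                                  contaminant_fraction = 0, seed = 1,
                                  nu_grid = c(0.25, 0.50, 0.75),
                                  cost = 1) {
  stopifnot(inherits(panel, "reference_panel"),
            inherits(sig, "signature_matrix"))
  C <- fresh_replicates(panel, n_rep = 1, seed = .substream_seed(seed, 1))
  colnames(C) <- panel$cell_types
  M <- sample_mixture_matrix(n_mixtures, ncol(C),
                             seed = .substream_seed(seed, 2),
                             cell_types = panel$cell_types)
  S <- synthesize(C, M)
  if (noise_scale > 0)
    S <- add_noise(S, noise_scale, seed = .substream_seed(seed, 3))
  if (contaminant_fraction > 0) {
    contam <- .contaminant_profile(panel, seed = .substream_seed(seed, 4))
    S <- apply(S, 2, spike_contaminant,
               contaminant_profile = contam,
               fraction = contaminant_fraction)
    rownames(S) <- rownames(panel$means)
  }
  res <- deconvolve_cohort(S, sig, nu_grid = nu_grid, cost = cost,
                           n_perm = 0)
  est <- as.matrix(res[, panel$cell_types])
  rownames(est) <- res$sample
  list(mad = evaluate_mad(M, est), truth = M, estimates = est,
       noise_scale = noise_scale,
       contaminant_fraction = contaminant_fraction)
}

# An out-of-signature cell type: background abundances with its own
# random marker set, disjoint from the panel's markers.
.contaminant_profile <- function(panel, n_markers = 50, seed = 1) {
  genes <- rownames(panel$means)
  taken <- unlist(panel$marker_map)
  withr::with_seed(seed, {
    base <- 2^rnorm(length(genes), mean = 5, sd = 2)
    mk <- sample(setdiff(genes, taken), n_markers)
    base[match(mk, genes)] <- base[match(mk, genes)] * 8
  })
  names(base) <- genes
  base
}
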