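# Signature-matrix construction: pairwise differential expression at
# a permissive FDR followed by fold-change-ranked marker selection
# with condition-number (kappa) minimisation over the per-type gene
# count. A deliberately lenient q (0.30 by default) keeps the false
# negative rate low; the downstream nu-SVR step selects the maximally
# separating genes per sample anyway.

#' Pairwise differentially expressed genes between cell types
#'
#' For every unordered pair of cell types, performs per-gene two-sided
#' Welch t-tests on log2(x + 1) replicate expression and applies
#' Benjamini-Hochberg correction within the pair. Genes with q-value
#' <= `q` are returned per pair.
#'
#' @param panel a `reference_panel` with >= 2 replicates per type.
#' @param q FDR threshold (default 0.30).
#' @return named list, one element per pair (`"typeA|typeB"`), each a
#'   character vector of significant gene ids.
#' @export
pairwise_differential_genes <- function(panel, q = 0.30) {
  stopifnot(inherits(panel, "reference_panel"))
  types <- panel$cell_types
  reps <- lapply(types, function(ct)
    log2(panel$profiles[, panel$replicate_of == ct, drop = FALSE] + 1))
  names(reps) <- types
  n_rep <- vapply(reps, ncol, integer(1))
  if (any(n_rep < 2))
    stop("cell type(s) with < 2 replicates: ",
         paste(types[n_rep < 2], collapse = ", "), call. = FALSE)

  out <- list()
  for (i in seq_along(types)[-length(types)]) {
    for (j in (i + 1):length(types)) {
      p <- .welch_rows(reps[[i]], reps[[j]])
      qv <- p.adjust(p, method = "BH")
      out[[paste(types[i], types[j], sep = "|")]] <-
        rownames(panel$profiles)[!is.na(qv) & qv <= q]
    }
  }
  out
}

# Vectorized per-row Welch t-test p-values between two replicate
# matrices (same rows).
.welch_rows <- function(x, y) {
  nx <- ncol(x); ny <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- .row_vars(x); vy <- .row_vars(y)
  se2 <- vx / nx + vy / ny
  tt <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * pt(-abs(tt), df)
  # identical rows give 0/0; no evidence of difference
  p[!is.finite(tt)] <- 1
  p
}

#' Condition number of a signature candidate
#'
#' The 2-norm condition number: the ratio of the largest to the
#' smallest singular value. Rank-deficient matrices return `Inf`.
#'
#' @param values numeric matrix (genes x cell types), at least as many
#'   rows as columns.
#' @return kappa (>= 1), or `Inf` if rank-deficient.
#' @export
condition_number <- function(values) {
  if (nrow(values) < ncol(values))
    stop("need at least as many genes as cell types", call. = FALSE)
  d <- svd(values, nu = 0, nv = 0)$d
  if (min(d) <= max(d) * 1e-12) return(Inf)
  max(d) / min(d)
}

#' Build a cell-type signature matrix
#'
#' From the pairwise-significant genes, ranks candidates for each cell
#' type by fold change (log2 of the type's mean + 1 versus the maximum
#' of the other type means + 1; ties broken by gene id). For each
#' per-type count G in `g_min:g_max` the union of top-G genes forms a
#' candidate matrix of per-type replicate means; the G minimising the
#' condition number kappa wins (ties: smaller G).
#'
#' @param panel a `reference_panel`.
#' @param q pairwise-DE FDR threshold (default 0.30).
#' @param g_min,g_max range of per-type marker counts searched
#'   (defaults 50, 150).
#' @return an object of class `signature_matrix`: list with `values`
#'   (genes x cell types, mean replicate expression), `cell_types`,
#'   `kappa`, `q_threshold`, `markers_per_type` (the selected G),
#'   `genes`.
#' @export
build_signature <- function(panel, q = 0.30, g_min = 50, g_max = 150) {
  stopifnot(inherits(panel, "reference_panel"), g_min <= g_max)
  de <- pairwise_differential_genes(panel, q)
  sig_genes <- sort(unique(unlist(de)))
  if (length(sig_genes) == 0)
    stop("no genes significant at q = ", q, call. = FALSE)

  types <- panel$cell_types
  means <- vapply(types, function(ct)
    rowMeans(panel$profiles[, panel$replicate_of == ct, drop = FALSE]),
    numeric(nrow(panel$profiles)))
  rownames(means) <- rownames(panel$profiles)

  # per-type candidates: significant genes upregulated in that type,
  # ranked by log2 fold change over the best other type
  ranked <- lapply(seq_along(types), function(j) {
    m <- means[sig_genes, , drop = FALSE]
    other_max <- apply(m[, -j, drop = FALSE], 1, max)
    fc <- log2(m[, j] + 1) - log2(other_max + 1)
    up <- fc > 0
    g <- sig_genes[up]
    g[order(-fc[up], g)]
  })

  best <- NULL
  for (G in g_min:g_max) {
    genes <- sort(unique(unlist(lapply(ranked, utils::head, n = G))))
    if (length(genes) < length(types)) next
    kappa <- condition_number(means[genes, , drop = FALSE])
    if (is.null(best) || kappa < best$kappa)
      best <- list(G = G, kappa = kappa, genes = genes)
  }
  if (is.null(best))
    stop("no candidate signature had enough genes", call. = FALSE)

  structure(list(values = means[best$genes, , drop = FALSE],
                 cell_types = types, kappa = best$kappa,
                 q_threshold = q, markers_per_type = best$G,
                 genes = best$genes),
            class = "signature_matrix")
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat("signature_matrix:", length(x$genes), "genes x",
      length(x$cell_types), "cell types\n")
  cat("  kappa =", format(x$kappa, digits = 4),
      "| q =", x$q_threshold,
      "| top-G per type =", x$markers_per_type, "\n")
  invisible(x)
}
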