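# Internal helpers shared across modules.

#' @importFrom stats rnorm runif rbinom rgamma qnorm pnorm pt cor sd var
#'   prcomp kmeans p.adjust lm coef anova optim quantile complete.cases
#'   cor.test na.omit
#' @importFrom utils read.delim write.table packageVersion
NULL

# Row means/vars without matrixStats; x is a numeric matrix.
.row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2) return(rep(NA_real_, nrow(x)))
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1)
}

.assert_matrix <- function(x, what = "matrix") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(what, " must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop(what, " must have row and column names", call. = FALSE)
  if (anyDuplicated(rownames(x)) || anyDuplicated(colnames(x)))
    stop(what, " has duplicated row or column names", call. = FALSE)
  invisible(x)
}

# Expression matrices carry their unit as an attribute so downstream
# stages can refuse input on the wrong scale.
.set_unit <- function(x, unit) {
  attr(x, "unit_label") <- unit
  x
}

.get_unit <- function(x) {
  u <- attr(x, "unit_label")
  if (is.null(u)) NA_character_ else u
}

# Derive a per-purpose stream seed from a master seed, staying within
# 32-bit integer range.
.substream_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + offset) %% 2147483629)
}
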