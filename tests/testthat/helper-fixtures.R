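# Shared fixtures, built once per test run. The small panel keeps the
# planted-marker structure of the full study conditions at a size
# that keeps unit tests fast; acceptance tests build the full-size
# conditions themselves.

.fixtures <- new.env(parent = emptyenv())

small_panel <- function() {
  if (is.null(.fixtures$panel))
    .fixtures$panel <- generate_reference_panel(
      n_genes = 600, k = 4, markers_per_type = 30, replicates = 3,
      replicate_cv = 0.1, seed = 1)
  .fixtures$panel
}

small_signature <- function() {
  if (is.null(.fixtures$sig))
    .fixtures$sig <- build_signature(small_panel(), g_min = 20,
                                     g_max = 40)
  .fixtures$sig
}

# Non-negative least squares oracle (pracma's Lawson-Hanson),
# normalized to the simplex; used to cross-check the nu-SVR route.
nnls_proportions <- function(y, X) {
  w <- pracma::lsqnonneg(X, y)$x
  w / sum(w)
}

# A tiny manually built reference panel (no generator involved) for
# edge-case tests.
manual_panel <- function(profiles, cell_types, replicate_of) {
  structure(list(means = NULL, profiles = profiles,
                 cell_types = cell_types, replicate_of = replicate_of,
                 marker_map = list(), replicate_cv = 0, seed = NA),
            class = "reference_panel")
}
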