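#' Run the full synthetic-to-results pipeline
#'
#' Executes the stages in order — simulate reference panel and cohort,
#' build the signature matrix, deconvolve the cohort, run the mixture
#' benchmark, fit phenotype associations and twin heritability, and
#' (optionally) a small interaction-eQTL scan — writing every artifact
#' as plain text into `out_dir` together with a JSON manifest of
#' parameters, seeds, package version and output checksums. A rerun
#' with the same config is bit-identical.
#'
#' Stage seeds are derived deterministically from the master seed, so
#' no stage's randomness depends on whether another stage ran.
#'
#' @param out_dir output directory (created if needed).
#' @param seed master seed.
#' @param params optional named list overriding stage parameters:
#'   `n_genes`, `markers_per_type`, `replicates`, `replicate_cv`,
#'   `n_samples`, `proportion_alpha`, `noise_scale`, `couplings`,
#'   `n_mixtures`, `n_perm`, `n_mz`, `n_dz`, `a2`, `c2`, `n_snps`,
#'   `run_eqtl`.
#' @return (invisibly) the manifest list.
#' @export
run_pipeline <- function(out_dir, seed = 1, params = list()) {
  defaults <- list(
    n_genes = 1000, markers_per_type = 50, replicates = 3,
    replicate_cv = 0.1, n_samples = 100,
    proportion_alpha = c(30, 2, 5, 0.5), noise_scale = 0.1,
    couplings = list(android_gynoid_ratio =
                       list(cell_type = "macrophage", r = 0.36)),
    n_mixtures = 100, n_perm = 200, n_mz = 100, n_dz = 100,
    a2 = 0.30, c2 = 0.10, n_snps = 20, run_eqtl = TRUE)
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  p <- utils::modifyList(defaults, params)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  panel <- generate_reference_panel(
    n_genes = p$n_genes, markers_per_type = p$markers_per_type,
    replicates = p$replicates, replicate_cv = p$replicate_cv,
    seed = .substream_seed(seed, 1))
  write_expression_tsv(panel$profiles,
                       file.path(out_dir, "reference_profiles.tsv"))

  sig <- build_signature(panel)
  write_signature(sig, file.path(out_dir, "signature.tsv"))

  cohort <- generate_cohort(panel, n = p$n_samples,
                            proportion_alpha = p$proportion_alpha,
                            noise_scale = p$noise_scale,
                            phenotype_couplings = p$couplings,
                            seed = .substream_seed(seed, 2))
  write_expression_tsv(cohort$expression,
                       file.path(out_dir, "bulk_expression.tsv"))
  write_phenotypes_tsv(cohort$phenotypes,
                       file.path(out_dir, "phenotypes.tsv"))
  write_expression_tsv(t(cohort$true_proportions),
                       file.path(out_dir, "true_proportions.tsv"),
                       id_column = "cell_type")

  dec <- deconvolve_cohort(cohort$expression, sig, n_perm = p$n_perm,
                           seed = .substream_seed(seed, 3))
  write.table(dec, file.path(out_dir, "deconvolution.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  bench <- run_mixture_benchmark(panel, sig, n_mixtures = p$n_mixtures,
                                 seed = .substream_seed(seed, 4))
  jsonlite::write_json(
    list(mad_per_type = as.list(bench$mad$per_type),
         mad_overall = bench$mad$overall,
         noise_scale = bench$noise_scale),
    file.path(out_dir, "benchmark.json"), auto_unbox = TRUE, digits = NA)

  props <- as.matrix(dec[, panel$cell_types])
  rownames(props) <- dec$sample
  assoc <- do.call(rbind, lapply(panel$cell_types, function(ct)
    cell_phenotype_association(props, cohort$phenotypes,
                               "android_gynoid_ratio", ct)))
  write.table(assoc, file.path(out_dir, "associations.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  twins <- generate_twin_pairs(p$n_mz, p$n_dz, p$a2, p$c2,
                               1 - p$a2 - p$c2,
                               seed = .substream_seed(seed, 5))
  ace <- fit_ace(twins)
  jsonlite::write_json(list(a2 = ace$a2, c2 = ace$c2, e2 = ace$e2),
                       file.path(out_dir, "heritability.json"),
                       auto_unbox = TRUE, digits = NA)

  if (isTRUE(p$run_eqtl)) {
    geno <- generate_genotypes(p$n_samples, p$n_snps, maf = c(0.05, 0.5),
                               seed = .substream_seed(seed, 6))
    cohort <- attach_genotypes(cohort, geno)
    write_vcf(cohort$genotypes, file.path(out_dir, "genotypes.vcf"))
    annot <- data.frame(gene = rownames(cohort$expression)[1:10],
                        chrom = "1",
                        tss = seq(10000L, by = 10000L, length.out = 10),
                        strand = "+", stringsAsFactors = FALSE)
    win <- cis_windows(annot, cohort$genotypes)
    scan <- cis_scan(cohort$expression[annot$gene, ], cohort$genotypes,
                     win)
    write.table(scan$genes, file.path(out_dir, "eqtl_genes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  files <- list.files(out_dir, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    package = "adipodecon",
    version = as.character(packageVersion("adipodecon")),
    seed = seed, params = p,
    outputs = as.list(stats::setNames(unname(tools::md5sum(files)),
                                      basename(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
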