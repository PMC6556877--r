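# Readers and writers for the pipeline's plain-text interchange
# formats: tab-separated expression/phenotype/annotation tables, the
# signature matrix with its JSON sidecar, and minimal biallelic VCF.

#' Read a gene-by-sample expression (or count) table
#'
#' Tab-separated, first column gene id, header row of sample ids;
#' `"."` or empty cells are missing.
#'
#' @param path file path.
#' @return numeric matrix, genes x samples.
#' @export
read_expression_tsv <- function(path) {
  d <- read.delim(path, check.names = FALSE, na.strings = c(".", ""))
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "double"
  .assert_matrix(m, "expression table")
}

#' Write a gene-by-sample expression table
#'
#' @param m numeric matrix, genes x samples.
#' @param path file path.
#' @param id_column name of the first (gene id) column.
#' @export
write_expression_tsv <- function(m, path, id_column = "gene") {
  d <- data.frame(rownames(m), m, check.names = FALSE,
                  stringsAsFactors = FALSE)
  names(d)[1] <- id_column
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' Tab-separated with a `sample` column.
#' @param path file path.
#' @return data.frame.
#' @export
read_phenotypes_tsv <- function(path) {
  d <- read.delim(path, check.names = FALSE, na.strings = c(".", ""),
                  stringsAsFactors = FALSE)
  if (!"sample" %in% names(d)) stop("phenotype table needs a 'sample' column",
                                    call. = FALSE)
  d
}

#' Write a phenotype table
#' @param pheno data.frame with a `sample` column.
#' @param path file path.
#' @export
write_phenotypes_tsv <- function(pheno, path) {
  write.table(pheno, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene annotation table (gene, chrom, tss, strand)
#' @param path file path.
#' @return data.frame.
#' @export
read_annotation_tsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "chrom", "tss")
  if (!all(need %in% names(d)))
    stop("annotation needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  d$chrom <- as.character(d$chrom)
  d
}

#' Write a signature matrix with a JSON sidecar
#'
#' The TSV holds gene id plus one column per cell type; the sidecar
#' (`<path>.json`) records kappa, the DE q threshold and the selected
#' per-type gene count.
#'
#' @param sig a `signature_matrix`.
#' @param path TSV path.
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "signature_matrix"))
  write_expression_tsv(sig$values, path)
  meta <- list(kappa = sig$kappa, q_threshold = sig$q_threshold,
               markers_per_type = sig$markers_per_type,
               n_genes = length(sig$genes), cell_types = sig$cell_types)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a signature matrix written by [write_signature()]
#' @param path TSV path (the sidecar is read from `<path>.json`).
#' @return a `signature_matrix`.
#' @export
read_signature <- function(path) {
  values <- read_expression_tsv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(values = values, cell_types = colnames(values),
                 kappa = meta$kappa, q_threshold = meta$q_threshold,
                 markers_per_type = meta$markers_per_type,
                 genes = rownames(values)),
            class = "signature_matrix")
}

#' Write genotypes as a minimal biallelic VCF
#'
#' VCFv4.2 with GT fields reconstructed from dosages (0 -> 0/0,
#' 1 -> 0/1, 2 -> 1/1).
#'
#' @param genotypes a `genotype_matrix`.
#' @param path file path (uncompressed).
#' @export
write_vcf <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  info <- genotypes$info
  gt <- c("0/0", "0/1", "1/1")[genotypes$dosages + 1L]
  gt <- matrix(gt, nrow(genotypes$dosages))
  body <- data.frame(CHROM = info$chrom, POS = info$pos, ID = info$snp,
                     REF = info$ref, ALT = info$alt, QUAL = ".",
                     FILTER = "PASS", INFO = ".", FORMAT = "GT", gt,
                     stringsAsFactors = FALSE, check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT",
                       colnames(genotypes$dosages)), collapse = "\t")),
             con)
  write.table(body, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read biallelic genotypes from a VCF
#'
#' Parses GT fields into ALT-allele dosages; multiallelic rows are
#' dropped with a warning. Uses vcfR when available, otherwise a
#' plain-text parser (the format written by [write_vcf()]).
#'
#' @param path VCF path.
#' @return a `genotype_matrix`.
#' @export
read_vcf <- function(path) {
  if (requireNamespace("vcfR", quietly = TRUE)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    samples <- colnames(gt)
  } else {
    lines <- readLines(path)
    hdr <- lines[startsWith(lines, "#CHROM")]
    cols <- strsplit(hdr, "\t")[[1]]
    samples <- cols[-(1:9)]
    body <- read.delim(text = lines[!startsWith(lines, "#")],
                       header = FALSE, stringsAsFactors = FALSE)
    names(body) <- cols
    fix <- body[, c("#CHROM", "POS", "ID", "REF", "ALT")]
    names(fix) <- c("CHROM", "POS", "ID", "REF", "ALT")
    gt <- as.matrix(body[, samples, drop = FALSE])
    rownames(gt) <- fix$ID
  }
  biallelic <- !grepl(",", fix$ALT)
  if (!all(biallelic)) {
    warning("dropping ", sum(!biallelic), " multiallelic site(s)")
    fix <- fix[biallelic, , drop = FALSE]
    gt <- gt[biallelic, , drop = FALSE]
  }
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt),
                dimnames = list(fix$ID, samples))
  alleles <- gsub("[^01]", "", gsub("\\|", "/", gt))
  dos[] <- vapply(strsplit(alleles, ""), function(a)
    sum(as.integer(a)), integer(1))
  info <- data.frame(snp = fix$ID, chrom = as.character(fix$CHROM),
                     pos = as.integer(fix$POS), ref = fix$REF,
                     alt = fix$ALT, stringsAsFactors = FALSE)
  freq <- rowMeans(dos) / 2
  structure(list(dosages = dos, info = info,
                 maf = pmin(freq, 1 - freq)),
            class = "genotype_matrix")
}
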