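#' Read a VCF file into a genotype panel
#'
#' Parses a VCF 4.x file with GT fields into a dosage matrix. Only
#' biallelic records are kept (multi-allelic records are skipped with a
#' warning). Minor allele frequencies are computed from the loaded samples,
#' not from INFO fields, and variants below `maf_min` are excluded. When
#' every genotype in the file is phased (`|` separator), the phased
#' haplotypes are retained on the panel.
#'
#' @param path path to a VCF file.
#' @param maf_min minimum in-sample minor allele frequency to retain a
#'   variant (default 0.01; set 0 to keep everything polymorphic or not).
#' @return A [genotype_panel()].
#' @export
read_vcf <- function(path, maf_min = 0.01) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop("VCF contains no variant records: ", path)
  multi <- grepl(",", fix$ALT %||% "")
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s) skipped")
  }
  keep <- !multi
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  if (nrow(fix) == 0L) stop("no biallelic records left in ", path)

  phased <- all(grepl("|", gt, fixed = TRUE))
  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  if (any(is.na(gt)) || any(!(a1 %in% c("0", "1")) | !(a2 %in% c("0", "1")))) {
    stop("malformed or missing GT field in ", path,
         " (only 0/1 biallelic calls are supported)")
  }
  h1 <- matrix(as.integer(a1), nrow = nrow(gt))
  h2 <- matrix(as.integer(a2), nrow = nrow(gt))
  dos <- t(h1 + h2)  # samples x variants

  variants <- data.frame(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    id = fix$ID,
    ref = fix$REF,
    alt = fix$ALT,
    maf = dosage_maf(dos),
    stringsAsFactors = FALSE
  )
  haplotypes <- NULL
  if (phased) {
    n <- ncol(gt)
    haplotypes <- matrix(0L, nrow = 2L * n, ncol = nrow(gt))
    haplotypes[seq(1, 2L * n, by = 2L), ] <- t(h1)
    haplotypes[seq(2, 2L * n, by = 2L), ] <- t(h2)
  }
  panel <- genotype_panel(dos, variants, haplotypes = haplotypes,
                          sample_ids = colnames(gt))
  keep_maf <- panel$variants$maf >= maf_min & panel$variants$maf > 0
  if (maf_min <= 0) keep_maf <- rep(TRUE, ncol(panel$dosages))
  subset_variants(panel, keep_maf)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a genotype panel as a plain-text VCF
#'
#' Emits a minimal valid VCF 4.2 with GT fields. Phased haplotypes are
#' written as `a|b` when present, otherwise unphased dosage-consistent
#' genotypes (`0/0`, `0/1`, `1/1`). `read_vcf()` recovers the panel
#' exactly.
#'
#' @param panel a [genotype_panel()] (or knockoff panel rounded to
#'   dosages).
#' @param path output file path.
#' @param id_suffix optional suffix appended to every variant id (used to
#'   distinguish knockoff panels, e.g. `".ko"`).
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(panel, path, id_suffix = "") {
  if (ncol(panel$dosages) == 0L) stop("cannot write a panel with no variants")
  v <- panel$variants
  n <- nrow(panel$dosages)
  if (!is.null(panel$haplotypes)) {
    h1 <- panel$haplotypes[seq(1, 2L * n, by = 2L), , drop = FALSE]
    h2 <- panel$haplotypes[seq(2, 2L * n, by = 2L), , drop = FALSE]
    gt <- matrix(paste0(h1, "|", h2), nrow = n)
  } else {
    codes <- c("0/0", "0/1", "1/1")
    gt <- matrix(codes[panel$dosages + 1L], nrow = n)
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=kfcombo",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$sample_ids), collapse = "\t")
  )
  body <- paste(
    v$chrom, v$pos, paste0(v$id, id_suffix), v$ref, v$alt, ".", "PASS", ".",
    "GT", apply(gt, 2L, paste, collapse = "\t"),
    sep = "\t"
  )
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Read a typed TSV table with schema validation
#'
#' Generic header-ed TSV reader used for expression matrices, covariates,
#' priors and gene annotation. Required columns and their types are given
#' by `schema`; missing required columns raise an error naming the column,
#' and row order is preserved.
#'
#' @param path TSV file with a header line.
#' @param schema named character vector mapping required column names to
#'   types (`"character"`, `"numeric"`, `"integer"`).
#' @return data.frame with the schema columns coerced to their types.
#' @export
read_table_schema <- function(path, schema) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(names(schema), names(df))
  if (length(miss) > 0L) {
    stop("table ", path, " is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  for (col in names(schema)) {
    df[[col]] <- switch(
      schema[[col]],
      character = as.character(df[[col]]),
      numeric = as.numeric(df[[col]]),
      integer = as.integer(df[[col]]),
      stop("unknown schema type: ", schema[[col]])
    )
  }
  df
}

#' Read a genes x samples expression TSV
#'
#' @param path TSV whose first column is `gene_id`, remaining columns one
#'   per sample.
#' @return Numeric matrix with genes as rows (rownames = gene ids).
#' @export
read_expression <- function(path) {
  df <- read_table_schema(path, c(gene_id = "character"))
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in expression table")
  m <- as.matrix(df[, setdiff(names(df), "gene_id"), drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df$gene_id
  m
}

#' Write a genes x samples expression matrix as TSV
#' @param expr numeric matrix, rownames = gene ids.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene annotation (gene_id, chrom, tss)
#'
#' @param path TSV with columns `gene_id`, `chrom`, `tss`.
#' @return data.frame; duplicated gene ids are an error.
#' @export
read_gene_annotation <- function(path) {
  df <- read_table_schema(path, c(gene_id = "character", chrom = "character",
                                  tss = "integer"))
  if (anyDuplicated(df$gene_id)) {
    stop("duplicate gene_id in gene annotation: ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  }
  if (any(df$tss < 1)) stop("tss must be >= 1")
  df
}

#' Read an external per-variant prior table
#'
#' Missing prior values (`NA`) are kept and flagged, not dropped: mean
#' imputation is the fine-mapper's job, see [build_external_prior()].
#'
#' @param path TSV with columns `gene_id`, `variant_id`, `prior`.
#' @return data.frame with a logical `missing` column.
#' @export
read_priors <- function(path) {
  df <- read_table_schema(path, c(gene_id = "character",
                                  variant_id = "character",
                                  prior = "numeric"))
  df$missing <- is.na(df$prior)
  df
}

#' Default run configuration
#'
#' Collects every tunable used across the pipeline with its default.
#' Values round-trip unchanged through [save_config()] / [load_config()].
#'
#' @param ... named overrides of the defaults.
#' @return A named list of class `kfc_config`.
#' @export
kfc_config <- function(...) {
  cfg <- list(
    # genotype simulator
    n_samples = 465L, n_chrom = 1L, n_variants = 400L, span_bp = 3e6,
    n_states = 12L, maf_min = 0.01, hmm_stay_min = 0.9, hmm_stay_max = 0.995,
    emit_min = 0.05, emit_max = 0.5,
    # expression simulator
    n_genes = 2000L, p_null = 0.381, h2_decay = 0.12,
    dtss_slope = -1, dtss_intercept = 2, k_causal_max = 5L,
    orthogonalize_noise = FALSE,
    # knockoffs
    engine = "gaussian", ko_ridge = 1e-4, group_bp = 1e6,
    hmm_fit_states = 20L, hmm_fit_iter = 20L,
    # association scan
    p_floor = 1e-300, emt_variance_explained = 0.99,
    n_perm = 100L, qvalue_lambda = 0.5,
    # fine-mapping
    prior_sd = 0.05, k_max = 5L, candidate_cap = 20L, candidate_p = 1e-4,
    # evaluation
    pip_grid_step = 0.01,
    calibration_edges = c(0, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1)
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  class(cfg) <- "kfc_config"
  cfg
}

#' @rdname kfc_config
#' @param cfg a `kfc_config`.
#' @param path YAML file path.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname kfc_config
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(kfc_config, raw)
}
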