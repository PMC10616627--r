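#' Genotype panel container
#'
#' A `genotype_panel` bundles a dosage matrix (samples x variants, entries
#' 0/1/2) with per-variant metadata and, optionally, the phased binary
#' haplotypes the dosages were formed from. It is the object knockoffs are
#' built from and association scans run over.
#'
#' @param dosages numeric matrix, samples x variants, entries in \{0, 1, 2\}.
#' @param variants data.frame with columns `chrom`, `pos`, `id`, `ref`,
#'   `alt`, `maf` (one row per dosage column).
#' @param haplotypes optional binary matrix with `2 * nrow(dosages)` rows;
#'   rows `2i - 1` and `2i` are the two haplotypes of sample `i` and must
#'   sum to the dosage row.
#' @param sample_ids optional character vector of sample labels.
#'
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(dosages, variants, haplotypes = NULL,
                           sample_ids = NULL) {
  dosages <- as.matrix(dosages)
  stopifnot(is.data.frame(variants))
  req <- c("chrom", "pos", "id", "ref", "alt", "maf")
  miss <- setdiff(req, names(variants))
  if (length(miss) > 0L) {
    stop("variant table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(variants) != ncol(dosages)) {
    stop("variant table has ", nrow(variants), " rows but dosage matrix has ",
         ncol(dosages), " columns")
  }
  if (anyDuplicated(variants$id)) {
    stop("variant ids must be unique within a panel")
  }
  if (any(variants$pos < 1)) stop("variant positions must be >= 1")
  if (any(variants$maf < 0 | variants$maf > 0.5)) {
    stop("maf must lie in [0, 0.5]")
  }
  bad <- !(dosages %in% c(0, 1, 2))
  if (any(bad)) stop("dosages outside {0, 1, 2} are not allowed")
  if (!is.null(haplotypes)) {
    haplotypes <- as.matrix(haplotypes)
    if (nrow(haplotypes) != 2L * nrow(dosages) ||
        ncol(haplotypes) != ncol(dosages)) {
      stop("haplotype matrix must be 2*samples x variants")
    }
    if (!all(haplotypes %in% c(0, 1))) stop("haplotypes must be binary")
    hsum <- haplotypes[seq(1, nrow(haplotypes), by = 2L), , drop = FALSE] +
      haplotypes[seq(2, nrow(haplotypes), by = 2L), , drop = FALSE]
    if (!isTRUE(all.equal(unname(hsum), unname(dosages), tolerance = 0))) {
      stop("dosages must equal the sum of each sample's two haplotypes")
    }
  }
  if (is.null(sample_ids)) {
    sample_ids <- sprintf("S%04d", seq_len(nrow(dosages)))
  }
  rownames(dosages) <- sample_ids
  colnames(dosages) <- variants$id
  structure(
    list(dosages = dosages, variants = variants, haplotypes = haplotypes,
         sample_ids = sample_ids),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", nrow(x$dosages), "samples x",
      ncol(x$dosages), "variants\n")
  cat("  chromosomes:", paste(unique(x$variants$chrom), collapse = ", "), "\n")
  cat("  haplotypes:", if (is.null(x$haplotypes)) "absent" else "present", "\n")
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$dosages)

#' Subset a panel to a set of variant columns
#'
#' @param panel a `genotype_panel`.
#' @param idx integer or logical index over variant columns.
#' @return A `genotype_panel` restricted to the selected variants.
#' @export
subset_variants <- function(panel, idx) {
  genotype_panel(
    dosages = panel$dosages[, idx, drop = FALSE],
    variants = panel$variants[idx, , drop = FALSE],
    haplotypes = if (is.null(panel$haplotypes)) NULL else
      panel$haplotypes[, idx, drop = FALSE],
    sample_ids = panel$sample_ids
  )
}

#' In-sample minor allele frequencies of a dosage matrix
#'
#' @param dosages samples x variants dosage matrix.
#' @return Numeric vector of per-column MAFs (folded to [0, 0.5]).
#' @export
dosage_maf <- function(dosages) {
  af <- colMeans(dosages) / 2
  pmin(af, 1 - af)
}

#' Standardize a dosage (or knockoff) matrix column-wise
#'
#' Centers each column and scales by the population (1/n) standard
#' deviation, the convention under which the simulated per-gene genetic
#' variance equals the target heritability exactly in-sample.
#'
#' @param x numeric matrix.
#' @return Matrix of the same shape; constant columns are returned as
#'   all-zero with attribute `constant_cols` marking them.
#' @export
standardize_columns <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu, "-")
  sd_pop <- sqrt(colSums(xc^2) / n)
  const <- sd_pop <= 0
  sd_pop[const] <- 1
  out <- sweep(xc, 2L, sd_pop, "/")
  attr(out, "constant_cols") <- which(const)
  out
}

#' 1 Mb group index of genomic positions
#'
#' Groups are fixed non-overlapping 1 Mb windows anchored at position 0 of
#' each chromosome; a position `p` (1-based) belongs to group
#' `floor((p - 1) / size)`.
#'
#' @param pos integer vector of 1-based positions.
#' @param size group width in bp (default 1 Mb).
#' @return Integer vector of 0-based group indices.
#' @export
position_group <- function(pos, size = 1e6) {
  as.integer(floor((pos - 1) / size))
}
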