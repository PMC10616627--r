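#' Bonferroni-thresholded PIPs
#'
#' Zeroes every PIP of a gene whose minimum cis p-value exceeds 5e-8
#' (strict inequality: a gene at exactly 5e-8 keeps its PIPs).
#'
#' @param raw_pips data.frame with columns `gene_id`, `variant_id`,
#'   `pip`.
#' @param min_p named numeric vector of per-gene minimum p-values.
#' @param threshold genome-wide significance cut-off (default 5e-8).
#' @return The input data.frame with an `adjusted_pip` column and
#'   `method = "bonferroni"`.
#' @export
adjust_bonferroni <- function(raw_pips, min_p, threshold = 5e-8) {
  mp <- lookup_gene_values(raw_pips$gene_id, min_p, "min_p")
  out <- raw_pips
  out$adjusted_pip <- ifelse(mp > threshold, 0, raw_pips$pip)
  out$method <- "bonferroni"
  out
}

#' Effective-test (EMT) thresholded PIPs
#'
#' Zeroes every PIP of a gene whose minimum p-value exceeds its per-gene
#' EMT threshold `0.05 / M_eff` (see [emt_effective_tests()]).
#'
#' @param raw_pips data.frame with `gene_id`, `variant_id`, `pip`.
#' @param min_p named per-gene minimum p-values.
#' @param emt_threshold named per-gene thresholds.
#' @return data.frame with `adjusted_pip` and `method = "emt"`.
#' @export
adjust_emt <- function(raw_pips, min_p, emt_threshold) {
  mp <- lookup_gene_values(raw_pips$gene_id, min_p, "min_p")
  th <- lookup_gene_values(raw_pips$gene_id, emt_threshold, "emt_threshold")
  out <- raw_pips
  out$adjusted_pip <- ifelse(mp > th, 0, raw_pips$pip)
  out$method <- "emt"
  out
}

#' Storey q-values with a fixed lambda
#'
#' `pi0_hat = min(1, #{p > lambda} / (m (1 - lambda)))`, then the
#' monotone step-up `q_i = pi0_hat * min_{j : p_j >= p_i} (m p_j /
#' rank_j)`. Forcing `pi0 = 1` reproduces Benjamini-Hochberg adjusted
#' p-values exactly.
#'
#' @param gene_pvalues numeric vector of p-values in [0, 1].
#' @param lambda_ tuning constant in [0, 1) for the pi0 estimate
#'   (default 0.5).
#' @param pi0 optional override of the pi0 estimate (e.g. 1 to recover
#'   BH).
#' @return Numeric q-values aligned with the input, with attribute
#'   `pi0`.
#' @export
storey_qvalues <- function(gene_pvalues, lambda_ = 0.5, pi0 = NULL) {
  p <- gene_pvalues
  if (length(p) == 0L) stop("empty p-value vector")
  if (any(p < 0 | p > 1, na.rm = TRUE) || anyNA(p)) {
    stop("p-values must lie in [0, 1] with no NA")
  }
  if (lambda_ < 0 || lambda_ >= 1) stop("lambda_ must lie in [0, 1)")
  m <- length(p)
  if (is.null(pi0)) {
    pi0 <- min(1, sum(p > lambda_) / (m * (1 - lambda_)))
    if (pi0 <= 0) pi0 <- 1 / m  # degenerate: every p below lambda
  }
  ord <- order(p, decreasing = TRUE)
  qs <- numeric(m)
  qs[ord] <- cummin(pi0 * m * p[ord] / (m:1))
  qs <- pmin(qs, 1)
  attr(qs, "pi0") <- pi0
  qs
}

#' q-value-thresholded PIPs
#'
#' Zeroes every PIP of a gene whose Storey q-value exceeds `fdr`.
#'
#' @param raw_pips data.frame with `gene_id`, `variant_id`, `pip`.
#' @param qvalues named per-gene q-values.
#' @param fdr gene-level FDR cut-off (default 0.05).
#' @return data.frame with `adjusted_pip` and `method = "qvalue"`.
#' @export
adjust_qvalue <- function(raw_pips, qvalues, fdr = 0.05) {
  q <- lookup_gene_values(raw_pips$gene_id, qvalues, "qvalue")
  out <- raw_pips
  out$adjusted_pip <- ifelse(q > fdr, 0, raw_pips$pip)
  out$method <- "qvalue"
  out
}

#' Knockoff (KFc) adjusted PIPs
#'
#' The core multiplication: `adjusted = raw * (1 - lFDP)` per gene,
#' turning a PIP conditional on the gene being an eGene into an
#' unconditional one. Never increases a PIP; equals the identity exactly
#' when lFDP = 0 and zeroes the gene when lFDP = 1.
#'
#' @param raw_pips data.frame with `gene_id`, `variant_id`, `pip`, or a
#'   bare numeric vector when `lfdp` is a same-length vector (scalar
#'   convenience form).
#' @param lfdp named per-gene lFDP values in [0, 1], or a numeric vector
#'   aligned with a numeric `raw_pips`.
#' @return Same shape as the input: data.frame with `adjusted_pip` and
#'   `method = "kfc"`, or a numeric vector.
#' @export
adjust_kfc <- function(raw_pips, lfdp) {
  if (is.numeric(raw_pips) && is.null(dim(raw_pips))) {
    if (any(lfdp < 0 | lfdp > 1)) stop("lfdp must lie in [0, 1]")
    return(raw_pips * (1 - lfdp))
  }
  lf <- lookup_gene_values(raw_pips$gene_id, lfdp, "lfdp")
  if (any(lf < 0 | lf > 1)) stop("lfdp must lie in [0, 1]")
  out <- raw_pips
  out$adjusted_pip <- raw_pips$pip * (1 - lf)
  out$method <- "kfc"
  out
}

#' Knockoff + Bonferroni adjusted PIPs
#'
#' Genes with minimum p below 5e-8 keep their raw PIPs (genome-wide
#' significant eGenes bypass the lFDP multiplication); all other genes
#' get `raw * (1 - lFDP)`. A gene at exactly the threshold is treated as
#' significant (keeps raw) -- the boundary falls in neither printed
#' branch of the rule and is logged.
#'
#' @param raw_pips data.frame with `gene_id`, `variant_id`, `pip`.
#' @param lfdp named per-gene lFDP values.
#' @param min_p named per-gene minimum p-values.
#' @param threshold genome-wide cut-off (default 5e-8).
#' @return data.frame with `adjusted_pip` and `method =
#'   "kfc_bonferroni"`.
#' @export
adjust_kfc_bonferroni <- function(raw_pips, lfdp, min_p, threshold = 5e-8) {
  lf <- lookup_gene_values(raw_pips$gene_id, lfdp, "lfdp")
  mp <- lookup_gene_values(raw_pips$gene_id, min_p, "min_p")
  if (any(mp == threshold)) {
    message("gene(s) with min_p exactly at the threshold kept raw PIPs")
  }
  out <- raw_pips
  out$adjusted_pip <- ifelse(mp <= threshold, raw_pips$pip,
                             raw_pips$pip * (1 - lf))
  out$method <- "kfc_bonferroni"
  out
}

#' Apply all PIP adjustment methods at once
#'
#' @param raw_pips data.frame with `gene_id`, `variant_id`, `pip`.
#' @param min_p,emt_threshold,qvalues,lfdp named per-gene vectors.
#' @param methods subset of `c("raw", "bonferroni", "emt", "qvalue",
#'   "kfc", "kfc_bonferroni")`.
#' @return Long-format data.frame (one block per method).
#' @export
adjust_all <- function(raw_pips, min_p, emt_threshold, qvalues, lfdp,
                       methods = c("raw", "bonferroni", "emt", "qvalue",
                                   "kfc", "kfc_bonferroni")) {
  blocks <- lapply(methods, function(mth) {
    switch(mth,
      raw = { out <- raw_pips; out$adjusted_pip <- raw_pips$pip
              out$method <- "raw"; out },
      bonferroni = adjust_bonferroni(raw_pips, min_p),
      emt = adjust_emt(raw_pips, min_p, emt_threshold),
      qvalue = adjust_qvalue(raw_pips, qvalues),
      kfc = adjust_kfc(raw_pips, lfdp),
      kfc_bonferroni = adjust_kfc_bonferroni(raw_pips, lfdp, min_p),
      stop("unknown method: ", mth))
  })
  do.call(rbind, blocks)
}

# Align a named per-gene vector with a gene_id column; any gene without
# a value is an error naming the gene.
lookup_gene_values <- function(gene_ids, values, what) {
  if (is.null(names(values))) stop(what, " must be a named per-gene vector")
  v <- values[gene_ids]
  if (anyNA(v)) {
    stop("missing ", what, " for gene(s): ",
         paste(unique(gene_ids[is.na(v)]), collapse = ", "))
  }
  as.numeric(v)
}
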