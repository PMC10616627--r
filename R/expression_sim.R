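#' Assign cis heritability to genes on the 0.01 grid
#'
#' Heritability is drawn per gene from a mixture of a point mass at 0
#' (null genes) and a weight function over the positive grid
#' 0.01, 0.02, ..., 0.99. The default positive weights decay
#' exponentially (`exp(-h2 / h2_decay)`), reflecting the empirical
#' observation that most genes have low cis heritability.
#'
#' @param gene_ids character vector of gene ids.
#' @param dist_spec list with `p_null` (mass at h2 = 0) and either
#'   `weights` (length-99 non-negative vector over the positive grid) or
#'   `h2_decay` (exponential decay scale for the default weights).
#' @param seed integer RNG seed.
#' @return Named numeric vector, gene id -> h2 on the 0.01 grid.
#' @export
assign_heritability <- function(gene_ids,
                                dist_spec = list(p_null = 0.381,
                                                 h2_decay = 0.12),
                                seed = 1L) {
  grid <- seq(0.01, 0.99, by = 0.01)
  p_null <- dist_spec$p_null
  if (is.null(p_null) || p_null < 0 || p_null > 1) {
    stop("dist_spec$p_null must lie in [0, 1]")
  }
  w <- dist_spec$weights
  if (is.null(w)) {
    decay <- dist_spec$h2_decay %||% 0.12
    w <- exp(-grid / decay)
  }
  if (length(w) != length(grid) || any(w < 0)) {
    stop("positive-grid weights must be 99 non-negative values")
  }
  tot <- sum(w)
  if (tot <= 0 && p_null < 1) stop("weights must not all be zero")
  probs <- c(p_null, (1 - p_null) * w / max(tot, .Machine$double.xmin))
  set.seed(as.integer(seed))
  h2 <- sample(c(0, grid), length(gene_ids), replace = TRUE, prob = probs)
  names(h2) <- gene_ids
  h2
}

#' Power-law causal probability as a function of dTSS
#'
#' The probability that a variant at distance `dtss_bp` from the TSS is
#' causal follows a line in log10-probability vs log10-dTSS space:
#' `10^(intercept + slope * log10(max(dtss_bp, 1)))`, clipped to (0, 1].
#' Defaults (`slope = -1`, `intercept = 2`) put probability 0.01 at 10 kb.
#'
#' @param dtss_bp non-negative distance(s) to the TSS in bp.
#' @param curve list with `slope` and `intercept` (log10 space).
#' @return Probabilities in (0, 1].
#' @export
causal_probability <- function(dtss_bp, curve = dtss_curve()) {
  if (any(dtss_bp < 0)) stop("dTSS must be non-negative")
  p <- 10^(curve$intercept + curve$slope * log10(pmax(dtss_bp, 1)))
  pmin(p, 1)
}

#' @rdname causal_probability
#' @param slope,intercept line coefficients in log-log space.
#' @param bin_bp,n_bins bookkeeping of the dTSS binning the curve form
#'   corresponds to (10 kb windows, 200 bins); not used numerically.
#' @export
dtss_curve <- function(slope = -1, intercept = 2, bin_bp = 1e4,
                       n_bins = 200L) {
  list(slope = slope, intercept = intercept, bin_bp = bin_bp, n_bins = n_bins)
}

#' Draw causal variants for one gene, dTSS-weighted, without replacement
#'
#' @param gene one-row data.frame (or list) with `gene_id`, `chrom`, `tss`.
#' @param panel a [genotype_panel()].
#' @param curve a [dtss_curve()].
#' @param k number of causal variants (1..5).
#' @param seed integer RNG seed.
#' @param region_idx optional integer index of cis variants in the panel;
#'   defaults to the 3-group cis region around the TSS.
#' @return Character vector of `k` variant ids.
#' @export
assign_causals <- function(gene, panel, curve = dtss_curve(), k = 1L,
                           seed = 1L, region_idx = NULL) {
  if (k < 1L || k > 5L) stop("k must be between 1 and 5")
  if (is.null(region_idx)) {
    region_idx <- cis_region_index(gene, panel)
  }
  if (length(region_idx) < k) {
    stop("gene ", gene$gene_id, " has ", length(region_idx),
         " cis variants, fewer than k = ", k)
  }
  v <- panel$variants[region_idx, , drop = FALSE]
  w <- causal_probability(abs(v$pos - gene$tss), curve)
  set.seed(as.integer(seed))
  if (length(region_idx) == k) return(v$id)
  v$id[sample.int(length(region_idx), k, replace = FALSE, prob = w)]
}

#' Exact-moment Gaussian noise vector
#'
#' Draws i.i.d. normal noise and rescales it so the sample mean is exactly
#' 0 and the population (1/n) variance exactly `1 - h2`. With `h2 = 1`
#' the vector is identically zero.
#'
#' @param n sample size (>= 2 unless `h2 = 1`).
#' @param h2 heritability in [0, 1].
#' @param seed integer RNG seed.
#' @return Numeric vector of length `n`.
#' @export
draw_noise <- function(n, h2, seed = 1L) {
  if (h2 < 0 || h2 > 1) stop("h2 must be in [0, 1]")
  if (h2 == 1) return(numeric(n))
  if (n < 2L) stop("n must be >= 2 when h2 < 1 (std of the draw undefined)")
  set.seed(as.integer(seed))
  e_hat <- stats::rnorm(n, mean = 0, sd = sqrt(1 - h2))
  e_c <- e_hat - mean(e_hat)
  sd_pop <- sqrt(sum(e_c^2) / n)
  e_c * sqrt(1 - h2) / sd_pop
}

#' Shared standardized effect size from heritability and causal LD
#'
#' All causal variants of a gene share one standardized effect
#' `beta = sqrt(h2 / sum(R))` where `R` is the in-sample correlation
#' matrix of the standardized causal genotypes, so that
#' `beta^2 * sum(R) = h2` exactly.
#'
#' @param h2 heritability.
#' @param R_causal correlation matrix of the causal genotypes (k x k).
#' @return Positive scalar beta.
#' @export
effect_size <- function(h2, R_causal) {
  s <- sum(R_causal)
  if (!is.finite(s) || s <= 0) {
    stop("sum of the causal LD matrix must be positive")
  }
  sqrt(h2 / s)
}

#' Simulation ground truth for one gene
#'
#' @param gene_id gene identifier.
#' @param h2 heritability on the 0.01 grid.
#' @param causal_ids character vector of causal variant ids (empty iff
#'   `h2 = 0`).
#' @param beta shared standardized effect.
#' @return A list of class `sim_truth`.
#' @export
sim_truth <- function(gene_id, h2, causal_ids, beta) {
  if ((h2 == 0) != (length(causal_ids) == 0L)) {
    stop("causal_ids must be empty exactly when h2 = 0")
  }
  if (h2 > 0 && (length(causal_ids) < 1L || length(causal_ids) > 5L)) {
    stop("eGenes carry between 1 and 5 causal variants")
  }
  structure(list(gene_id = gene_id, h2 = h2, causal_ids = causal_ids,
                 beta = beta),
            class = "sim_truth")
}

#' Simulate one gene's expression vector
#'
#' `y = X_causal %*% beta + eps` with in-sample standardized causal
#' genotypes and exact-moment noise from [draw_noise()]. The genetic
#' component's population variance equals `h2` exactly because `beta` is
#' computed from the in-sample LD. Optionally the noise is orthogonalized
#' against the causal genotype span so the total variance is exactly 1
#' (default off: the plain construction controls only the noise moments,
#' leaving a small genetic-noise covariance term).
#'
#' @param panel a [genotype_panel()].
#' @param truth a [sim_truth()].
#' @param seed integer RNG seed.
#' @param orthogonalize_noise logical; project the noise off the causal
#'   genotype span (and re-scale) before adding.
#' @return Numeric expression vector, one entry per sample.
#' @export
simulate_expression <- function(panel, truth, seed = 1L,
                                orthogonalize_noise = FALSE) {
  n <- nrow(panel$dosages)
  eps <- draw_noise(n, truth$h2, seed = seed)
  if (truth$h2 == 0) return(eps)
  idx <- match(truth$causal_ids, panel$variants$id)
  if (anyNA(idx)) {
    stop("causal id(s) missing from panel: ",
         paste(truth$causal_ids[is.na(idx)], collapse = ", "))
  }
  X <- standardize_columns(panel$dosages[, idx, drop = FALSE])
  g <- as.numeric(X %*% rep(truth$beta, length(idx)))
  if (orthogonalize_noise && truth$h2 < 1) {
    fit <- stats::lm.fit(cbind(1, X), eps)
    r <- fit$residuals
    sd_pop <- sqrt(sum((r - mean(r))^2) / n)
    eps <- if (sd_pop > 0) (r - mean(r)) * sqrt(1 - truth$h2) / sd_pop else r
  }
  g + eps
}

#' Simulate the whole study: heritabilities, causals, effects, expression
#'
#' Applies the five simulation steps to every gene: (1) grid heritability,
#' (2) dTSS-weighted causal draw for eGenes (k uniform on 1..k_max),
#' (3) exact-moment noise, (4) shared effect size from the in-sample
#' causal LD, (5) totals `y = X beta + eps`.
#'
#' @param panel a [genotype_panel()].
#' @param genes data.frame with `gene_id`, `chrom`, `tss`.
#' @param config a [kfc_config()].
#' @param seed integer RNG seed.
#' @return List with `expression` (genes x samples matrix) and `truths`
#'   (list of [sim_truth()] keyed by gene id).
#' @export
simulate_study_expression <- function(panel, genes, config = kfc_config(),
                                      seed = 1L) {
  seed <- as.integer(seed)
  h2 <- assign_heritability(
    genes$gene_id,
    dist_spec = list(p_null = config$p_null, h2_decay = config$h2_decay),
    seed = seed
  )
  curve <- dtss_curve(config$dtss_slope, config$dtss_intercept)
  set.seed(seed + 1L)
  k_draw <- sample.int(config$k_causal_max, nrow(genes), replace = TRUE)
  expr <- matrix(0, nrow = nrow(genes), ncol = nrow(panel$dosages),
                 dimnames = list(genes$gene_id, panel$sample_ids))
  truths <- vector("list", nrow(genes))
  names(truths) <- genes$gene_id
  for (i in seq_len(nrow(genes))) {
    gid <- genes$gene_id[i]
    seed_i <- seed + 13L * i
    if (h2[[gid]] == 0) {
      tr <- sim_truth(gid, 0, character(0), 0)
    } else {
      region_idx <- cis_region_index(genes[i, ], panel)
      k <- min(k_draw[i], length(region_idx))
      ids <- assign_causals(genes[i, ], panel, curve, k = k, seed = seed_i,
                            region_idx = region_idx)
      X <- standardize_columns(
        panel$dosages[, match(ids, panel$variants$id), drop = FALSE])
      R <- crossprod(X) / nrow(X)
      tr <- sim_truth(gid, h2[[gid]], ids, effect_size(h2[[gid]], R))
    }
    truths[[gid]] <- tr
    expr[i, ] <- simulate_expression(
      panel, tr, seed = seed_i + 1L,
      orthogonalize_noise = config$orthogonalize_noise)
  }
  list(expression = expr, truths = truths, h2 = h2)
}

#' Write / read a simulation truth table (TSV)
#'
#' Columns: gene_id, h2, causal_ids (comma-separated), beta.
#' @param truths list of [sim_truth()].
#' @param path TSV path.
#' @return `write_truths` returns `path`; `read_truths` the list.
#' @export
write_truths <- function(truths, path) {
  df <- data.frame(
    gene_id = vapply(truths, `[[`, character(1), "gene_id"),
    h2 = vapply(truths, `[[`, numeric(1), "h2"),
    causal_ids = vapply(truths, function(t)
      paste(t$causal_ids, collapse = ","), character(1)),
    beta = vapply(truths, `[[`, numeric(1), "beta"),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truths
#' @export
read_truths <- function(path) {
  df <- read_table_schema(path, c(gene_id = "character", h2 = "numeric",
                                  causal_ids = "character", beta = "numeric"))
  out <- lapply(seq_len(nrow(df)), function(i) {
    ids <- if (nzchar(df$causal_ids[i])) {
      strsplit(df$causal_ids[i], ",", fixed = TRUE)[[1L]]
    } else character(0)
    sim_truth(df$gene_id[i], df$h2[i], ids, df$beta[i])
  })
  names(out) <- df$gene_id
  out
}

#' Build non-uniform prior scenarios
#'
#' Three cases mirroring an external-prior (cross-population) setting:
#' `matched_eGene` puts the maximum prior on the true causal variant of a
#' single-causal eGene (h2 > 0.05), `mismatched_eGene` on a random
#' non-causal variant of such an eGene, and `null_gene` on a random
#' variant of a null gene. All remaining variants receive priors sampled
#' from `pip_pool` truncated below 0.01, so exactly one variant per gene
#' carries a prior >= 0.01.
#'
#' @param truths list of [sim_truth()].
#' @param panel a [genotype_panel()].
#' @param genes gene annotation data.frame.
#' @param pip_pool numeric pool of simulated PIP values to sample
#'   background priors from (values >= 0.01 are discarded).
#' @param counts named integer vector `c(matched, mismatched, null)`.
#' @param max_prior the maximum prior magnitude (0.01, 0.1 or 0.9).
#' @param seed integer RNG seed.
#' @param h2_min minimum heritability for an eligible eGene.
#' @return List of scenarios; each has `gene_id`, `case`, `max_prior`,
#'   `prior` (named numeric over the gene's cis variants) and `top_id`.
#' @export
make_prior_scenarios <- function(truths, panel, genes, pip_pool,
                                 counts = c(matched = 513L, mismatched = 512L,
                                            null = 512L),
                                 max_prior = 0.9, seed = 1L, h2_min = 0.05) {
  pool <- pip_pool[pip_pool < 0.01 & pip_pool > 0]
  if (length(pool) == 0L) {
    stop("pip_pool has no positive values below 0.01")
  }
  h2s <- vapply(truths, `[[`, numeric(1), "h2")
  nk <- vapply(truths, function(t) length(t$causal_ids), integer(1))
  eligible <- names(truths)[h2s > h2_min & nk == 1L]
  nulls <- names(truths)[h2s == 0]
  need_e <- counts[["matched"]] + counts[["mismatched"]]
  if (length(eligible) < need_e) {
    stop("need ", need_e, " single-causal eGenes with h2 > ", h2_min,
         " but only ", length(eligible), " are eligible")
  }
  if (length(nulls) < counts[["null"]]) {
    stop("need ", counts[["null"]], " null genes but only ", length(nulls),
         " are available")
  }
  set.seed(as.integer(seed))
  egenes <- sample(eligible, need_e)
  matched <- egenes[seq_len(counts[["matched"]])]
  mismatched <- setdiff(egenes, matched)
  null_sel <- sample(nulls, counts[["null"]])
  gene_row <- function(gid) genes[genes$gene_id == gid, , drop = FALSE]

  build <- function(gid, case) {
    region_idx <- cis_region_index(gene_row(gid), panel)
    ids <- panel$variants$id[region_idx]
    prior <- sample(pool, length(ids), replace = TRUE)
    names(prior) <- ids
    top_id <- switch(
      case,
      matched_eGene = truths[[gid]]$causal_ids[1L],
      mismatched_eGene = sample(setdiff(ids, truths[[gid]]$causal_ids), 1L),
      null_gene = sample(ids, 1L)
    )
    prior[top_id] <- max_prior
    list(gene_id = gid, case = case, max_prior = max_prior, prior = prior,
         top_id = top_id)
  }
  c(lapply(matched, build, case = "matched_eGene"),
    lapply(mismatched, build, case = "mismatched_eGene"),
    lapply(null_sel, build, case = "null_gene"))
}
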