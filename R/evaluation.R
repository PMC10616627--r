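#' PIP calibration bins
#'
#' For each bin `[lo, hi)` (last bin closed at 1), the fraction of
#' variant-gene pairs in the bin whose variant is truly causal, with the
#' pair count and the binomial standard error. A bin is calibrated when
#' its causal fraction lies within `[lo, hi]` up to 3 SE. Empty bins are
#' reported as `NA`, not zero.
#'
#' @param adjusted data.frame with `gene_id`, `variant_id`,
#'   `adjusted_pip`.
#' @param truths list of [sim_truth()] keyed by gene id.
#' @param bin_edges increasing vector of bin edges in [0, 1].
#' @return data.frame: lo, hi, n, n_causal, fraction, se, calibrated.
#' @export
calibration_bins <- function(adjusted, truths,
                             bin_edges = seq(0, 1, by = 0.1)) {
  lab <- causal_labels(adjusted, truths)
  k <- length(bin_edges) - 1L
  out <- data.frame(lo = bin_edges[-length(bin_edges)], hi = bin_edges[-1L],
                    n = 0L, n_causal = 0L, fraction = NA_real_,
                    se = NA_real_, calibrated = NA)
  idx <- findInterval(adjusted$adjusted_pip, bin_edges,
                      rightmost.closed = TRUE, all.inside = FALSE)
  idx[idx < 1L | idx > k] <- NA
  for (b in seq_len(k)) {
    sel <- which(idx == b)
    out$n[b] <- length(sel)
    if (length(sel) == 0L) next
    out$n_causal[b] <- sum(lab[sel])
    f <- out$n_causal[b] / out$n[b]
    se <- sqrt(f * (1 - f) / out$n[b])
    out$fraction[b] <- f
    out$se[b] <- se
    out$calibrated[b] <- (f >= out$lo[b] - 3 * se) &
      (f <= out$hi[b] + 3 * se)
  }
  out
}

# TRUE/FALSE per row of a long PIP table: is (variant, gene) a simulated
# causal pair? Vectorized via a causal-pair key set.
causal_labels <- function(df, truths) {
  if (!all(unique(df$gene_id) %in% names(truths))) {
    miss <- setdiff(unique(df$gene_id), names(truths))
    stop("no truth record for gene(s): ", paste(miss, collapse = ", "))
  }
  keys <- unlist(lapply(truths, function(tr) {
    if (length(tr$causal_ids) == 0L) return(character(0))
    paste(tr$gene_id, tr$causal_ids)
  }), use.names = FALSE)
  paste(df$gene_id, df$variant_id) %in% keys
}

#' Precision/recall of causal variant-gene prioritization vs PIP
#'
#' At each threshold `t` in the grid, precision is `TP / (TP + FP)` and
#' recall `TP / P` among variant-gene pairs with `adjusted_pip >= t`;
#' pairs with an adjusted PIP of exactly zero are never counted as
#' positives (an adjustment that zeroes a gene has withdrawn its pairs),
#' while causal pairs at zero still count against recall. Precision at
#' thresholds with zero positives is carried forward from the last
#' defined value. Areas (AUPPC for precision, AURC for recall) are
#' trapezoids over the grid.
#'
#' @param adjusted data.frame with `gene_id`, `variant_id`,
#'   `adjusted_pip`.
#' @param truths list of [sim_truth()].
#' @param grid sorted threshold grid in [0, 1].
#' @return List: `curve` (data.frame threshold, precision, recall,
#'   n_positive), `auppc`, `aurc`.
#' @export
precision_recall <- function(adjusted, truths, grid = seq(0, 1, by = 0.01)) {
  lab <- causal_labels(adjusted, truths)
  P <- sum(lab)
  if (P == 0L) stop("no causal variant-gene pairs in truth: recall undefined")
  pip <- adjusted$adjusted_pip
  scored <- pip > 0
  ord <- which(scored)[order(pip[scored], decreasing = TRUE)]
  pip_s <- pip[ord]
  tp_cum <- cumsum(lab[ord])
  n_pos <- findInterval(-grid, -pip_s)      # #{pip >= t, pip > 0} per t
  tp <- ifelse(n_pos > 0, tp_cum[pmax(n_pos, 1L)], 0L)
  precision <- ifelse(n_pos > 0, tp / n_pos, NA_real_)
  # carry the last defined precision forward into empty-threshold tails
  for (i in seq_along(precision)) {
    if (is.na(precision[i]) && i > 1L) precision[i] <- precision[i - 1L]
  }
  recall <- tp / P
  curve <- data.frame(threshold = grid, precision = precision,
                      recall = recall, n_positive = n_pos)
  list(curve = curve,
       auppc = trapezoid(grid, precision),
       aurc = trapezoid(grid, recall))
}

trapezoid <- function(x, y) {
  keep <- !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2L) return(NA_real_)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Simulate one complete study and run the KFc pipeline
#'
#' End-to-end orchestration with a single seed: genotype panel, gene
#' annotation, expression simulation, knockoff panel, real and knockoff
#' scans, W and lFDP, uniform-prior fine-mapping, and every PIP
#' adjustment method. All stages are deterministic given `seed`.
#'
#' @param config a [kfc_config()].
#' @param seed integer seed driving every stage.
#' @param methods adjustment methods to compute (see [adjust_all()]).
#' @param compute_gene_p logical; run the permutation/Beta gene-level p
#'   machinery (needed for the q-value method).
#' @return List of class `kfc_run`: `panel`, `knockoff`, `genes`,
#'   `truths`, `expression`, `scan` (per-gene table), `lfdp_table`,
#'   `raw_pips` (long), `adjusted` (long, all methods), `config`.
#' @export
run_kfc_pipeline <- function(config = kfc_config(), seed = 1L,
                             methods = c("raw", "bonferroni", "emt",
                                         "qvalue", "kfc", "kfc_bonferroni"),
                             compute_gene_p = "qvalue" %in% methods) {
  seed <- as.integer(seed)
  panel <- simulate_genotypes(
    n_samples = config$n_samples, n_variants = config$n_variants,
    n_chrom = config$n_chrom, span_bp = config$span_bp,
    n_states = config$n_states, maf_min = config$maf_min, seed = seed)
  genes <- make_gene_annotation(config, seed + 1L)
  sim <- simulate_study_expression(panel, genes, config, seed = seed + 2L)
  ko <- make_knockoffs(panel, engine = config$engine, seed = seed + 3L,
                       ridge = config$ko_ridge, config = config)
  scan <- scan_genes(panel, ko, sim$expression, genes, config = config,
                     seed = seed + 4L, compute_gene_p = compute_gene_p)
  lf <- estimate_lfdp(stats::setNames(
    compute_w(scan$min_p_real, scan$min_p_ko), scan$gene_id))
  raw <- finemap_all(panel, sim$expression, genes, config)
  qv <- if (compute_gene_p) {
    stats::setNames(storey_qvalues(scan$gene_p, config$qvalue_lambda),
                    scan$gene_id)
  } else NULL
  adjusted <- adjust_all(
    raw,
    min_p = stats::setNames(scan$min_p_real, scan$gene_id),
    emt_threshold = stats::setNames(scan$emt_threshold, scan$gene_id),
    qvalues = qv,
    lfdp = stats::setNames(lf$lfdp, lf$gene_id),
    methods = methods)
  structure(list(panel = panel, knockoff = ko, genes = genes,
                 truths = sim$truths, expression = sim$expression,
                 scan = scan, lfdp_table = lf, raw_pips = raw,
                 adjusted = adjusted, config = config, seed = seed),
            class = "kfc_run")
}

# Genes placed uniformly along each simulated chromosome.
make_gene_annotation <- function(config, seed) {
  set.seed(as.integer(seed))
  chrom <- rep_len(as.character(seq_len(config$n_chrom)), config$n_genes)
  data.frame(
    gene_id = sprintf("G%05d", seq_len(config$n_genes)),
    chrom = chrom,
    tss = sample.int(config$span_bp, config$n_genes, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

#' Per-gene scan summaries over real and knockoff panels
#'
#' Minimum cis p-values on the real and knockoff genotypes (identical
#' code path for both), the EMT effective-test threshold, and optionally
#' the permutation/Beta gene-level p-value. Vectorized across genes via
#' one correlation matrix per panel.
#'
#' @param panel real [genotype_panel()].
#' @param ko [knockoff_panel()].
#' @param expression genes x samples matrix.
#' @param genes gene annotation data.frame.
#' @param config a [kfc_config()].
#' @param covariates optional covariate matrix.
#' @param seed seed for the permutation machinery.
#' @param compute_gene_p logical.
#' @return data.frame: gene_id, min_p_real, min_p_ko, lead_variant,
#'   n_variants, m_eff, emt_threshold, gene_p (NA when skipped).
#' @export
scan_genes <- function(panel, ko, expression, genes, config = kfc_config(),
                       covariates = NULL, seed = 1L,
                       compute_gene_p = TRUE) {
  n <- nrow(panel$dosages)
  q <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  df <- n - q - 2L
  Y <- t(expression[genes$gene_id, , drop = FALSE])   # samples x genes
  if (!is.null(covariates)) {
    Y <- apply(Y, 2L, residualize, covariates)
    Xr <- apply(panel$dosages, 2L, residualize, covariates)
    Xk <- apply(ko$values, 2L, residualize, covariates)
  } else {
    Xr <- panel$dosages
    Xk <- ko$values
  }
  regions <- lapply(seq_len(nrow(genes)), function(i)
    cis_region_index(genes[i, ], panel, config$group_bp))
  n_var <- lengths(regions)
  if (any(n_var == 0L)) {
    stop("gene(s) with empty cis-region: ",
         paste(genes$gene_id[n_var == 0L], collapse = ", "))
  }
  abs_r_real <- abs_cor_matrix(Xr, Y)   # variants x genes
  abs_r_ko <- abs_cor_matrix(Xk, Y)
  r2p <- function(r) {
    tt <- r * sqrt(df / pmax(1 - r^2, .Machine$double.xmin))
    pmax(2 * stats::pt(-tt, df = df), config$p_floor)
  }
  min_p_real <- numeric(nrow(genes))
  min_p_ko <- numeric(nrow(genes))
  lead <- character(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    idx <- regions[[i]]
    rr <- abs_r_real[idx, i]
    best <- which.max(rr)
    min_p_real[i] <- r2p(rr[best])
    lead[i] <- panel$variants$id[idx[best]]
    min_p_ko[i] <- r2p(max(abs_r_ko[idx, i]))
  }
  # EMT thresholds: one eigen decomposition per distinct region
  reg_key <- vapply(regions, function(ix)
    paste(range(ix), collapse = "-"), character(1))
  emt <- numeric(nrow(genes))
  meff <- integer(nrow(genes))
  for (kk in unique(reg_key)) {
    sel <- which(reg_key == kk)
    idx <- regions[[sel[1L]]]
    R <- suppressWarnings(stats::cor(Xr[, idx, drop = FALSE]))
    R[is.na(R)] <- 0; diag(R) <- 1
    e <- emt_effective_tests(R, config$emt_variance_explained)
    meff[sel] <- e$m_eff
    emt[sel] <- e$threshold
  }
  gene_p <- rep(NA_real_, nrow(genes))
  if (compute_gene_p) {
    set.seed(as.integer(seed))
    perm_idx <- replicate(config$n_perm, sample.int(n))
    for (i in seq_len(nrow(genes))) {
      gp <- gene_level_p_permutation(panel, Y[, i], regions[[i]],
                                     covariates = NULL,
                                     perm_idx = perm_idx)
      gene_p[i] <- gp$p_beta
    }
  }
  data.frame(gene_id = genes$gene_id, min_p_real = min_p_real,
             min_p_ko = min_p_ko, lead_variant = lead, n_variants = n_var,
             m_eff = meff, emt_threshold = emt, gene_p = gene_p,
             stringsAsFactors = FALSE)
}

# |cor| between every column of X and every column of Y (constant X
# columns give 0).
abs_cor_matrix <- function(X, Y) {
  n <- nrow(X)
  Xc <- sweep(X, 2L, colMeans(X), "-")
  sx <- sqrt(colSums(Xc^2)); sx[sx <= 0] <- Inf
  Xs <- sweep(Xc, 2L, sx, "/")
  Yc <- sweep(Y, 2L, colMeans(Y), "-")
  sy <- sqrt(colSums(Yc^2)); sy[sy <= 0] <- Inf
  Ys <- sweep(Yc, 2L, sy, "/")
  R <- abs(crossprod(Xs, Ys))
  pmin(R, 1)
}

# Uniform-prior fine-mapping of every gene; long data.frame of raw PIPs.
finemap_all <- function(panel, expression, genes, config,
                        priors = NULL, covariates = NULL) {
  blocks <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    idx <- cis_region_index(genes[i, ], panel, config$group_bp)
    fm <- finemap_gene(expression[genes$gene_id[i], ], panel, idx,
                       prior = priors[[genes$gene_id[i]]],
                       k_max = config$k_max,
                       candidate_cap = config$candidate_cap,
                       candidate_p = config$candidate_p,
                       prior_sd = config$prior_sd,
                       covariates = covariates)
    blocks[[i]] <- data.frame(gene_id = genes$gene_id[i],
                              variant_id = names(fm$pip),
                              pip = as.numeric(fm$pip),
                              stringsAsFactors = FALSE)
  }
  do.call(rbind, blocks)
}

#' Method comparison on one simulated study
#'
#' Runs [run_kfc_pipeline()] and scores every adjustment method with
#' [calibration_bins()] and [precision_recall()]; the comparison table
#' is sorted by AUPPC.
#'
#' @param config a [kfc_config()].
#' @param seed integer seed.
#' @param methods adjustment methods to score.
#' @return List of class `kfc_eval`: `run`, `reports` (per method:
#'   calibration + curves + areas), `comparison` (data.frame sorted by
#'   AUPPC).
#' @export
run_method_comparison <- function(config = kfc_config(), seed = 1L,
                                  methods = c("raw", "bonferroni", "emt",
                                              "qvalue", "kfc",
                                              "kfc_bonferroni")) {
  run <- run_kfc_pipeline(config, seed, methods = methods)
  grid <- seq(0, 1, by = config$pip_grid_step)
  reports <- lapply(methods, function(mth) {
    adj <- run$adjusted[run$adjusted$method == mth, ]
    pr <- precision_recall(adj, run$truths, grid)
    list(method = mth,
         calibration = calibration_bins(adj, run$truths,
                                        config$calibration_edges),
         curve = pr$curve, auppc = pr$auppc, aurc = pr$aurc)
  })
  names(reports) <- methods
  comparison <- data.frame(
    method = methods,
    auppc = vapply(reports, `[[`, numeric(1), "auppc"),
    aurc = vapply(reports, `[[`, numeric(1), "aurc"),
    stringsAsFactors = FALSE
  )
  comparison <- comparison[order(-comparison$auppc), ]
  structure(list(run = run, reports = reports, comparison = comparison),
            class = "kfc_eval")
}

#' @export
print.kfc_eval <- function(x, ...) {
  cat("KFc method comparison (", nrow(x$run$genes), " genes)\n", sep = "")
  print(x$comparison, row.names = FALSE)
  invisible(x)
}

#' Non-uniform prior scenario experiment
#'
#' Fine-maps each scenario gene with its scenario prior (used as-is,
#' unnormalized) and scores the result with and without the KFc
#' adjustment: precision/recall curves for the two eGene cases and the
#' count of variant-gene pairs above each PIP threshold for the
#' null-gene case.
#'
#' @param scenarios list from [make_prior_scenarios()].
#' @param run a `kfc_run` (provides panel, expression, truths, lFDP).
#' @param grid threshold grid.
#' @return List per case: for eGene cases `with_kfc` / `without_kfc`
#'   precision-recall objects; for `null_gene` a data.frame of counts
#'   above threshold with and without KFc.
#' @export
run_prior_scenarios <- function(scenarios, run,
                                grid = seq(0, 1, by = 0.01)) {
  config <- run$config
  lfdp <- stats::setNames(run$lfdp_table$lfdp, run$lfdp_table$gene_id)
  blocks <- vector("list", length(scenarios))
  for (i in seq_along(scenarios)) {
    sc <- scenarios[[i]]
    g <- run$genes[run$genes$gene_id == sc$gene_id, , drop = FALSE]
    idx <- cis_region_index(g, run$panel, config$group_bp)
    fm <- finemap_gene(run$expression[sc$gene_id, ], run$panel, idx,
                       prior = sc$prior, k_max = config$k_max,
                       candidate_cap = config$candidate_cap,
                       candidate_p = config$candidate_p,
                       prior_sd = config$prior_sd)
    blocks[[i]] <- data.frame(gene_id = sc$gene_id, case = sc$case,
                              variant_id = names(fm$pip),
                              pip = as.numeric(fm$pip),
                              stringsAsFactors = FALSE)
  }
  long <- do.call(rbind, blocks)
  long$adjusted_pip <- long$pip
  kfc <- adjust_kfc(long[, c("gene_id", "variant_id", "pip")], lfdp)
  out <- list()
  for (case in unique(long$case)) {
    sel <- long$case == case
    plain <- long[sel, ]
    adj <- kfc[sel, ]
    if (case == "null_gene") {
      out[[case]] <- data.frame(
        threshold = grid,
        n_without_kfc = vapply(grid, function(t)
          sum(plain$adjusted_pip > t), numeric(1)),
        n_with_kfc = vapply(grid, function(t)
          sum(adj$adjusted_pip > t), numeric(1))
      )
    } else {
      out[[case]] <- list(
        without_kfc = precision_recall(plain, run$truths, grid),
        with_kfc = precision_recall(adj, run$truths, grid)
      )
    }
  }
  out
}
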