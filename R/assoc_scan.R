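#' Index of a gene's cis-region variants within a panel
#'
#' The cis-region is the 1 Mb group containing the gene's TSS plus the
#' immediately upstream and downstream groups (3 Mb total; fewer groups at
#' chromosome ends), restricted to the gene's chromosome.
#'
#' @param gene one-row data.frame (or list) with `chrom` and `tss`.
#' @param panel a [genotype_panel()].
#' @param group_bp group width in bp (default 1 Mb).
#' @return Integer vector of variant column indices (possibly empty).
#' @export
cis_region_index <- function(gene, panel, group_bp = 1e6) {
  g <- position_group(gene$tss, group_bp)
  vg <- position_group(panel$variants$pos, group_bp)
  which(panel$variants$chrom == as.character(gene$chrom) &
          vg >= g - 1L & vg <= g + 1L)
}

#' Residualize a vector against covariates
#'
#' Projects `y` onto the orthogonal complement of the span of
#' `cbind(1, covariates)`. Applying the projection twice is idempotent.
#'
#' @param y numeric vector.
#' @param covariates numeric matrix (rows = samples) or NULL for
#'   intercept-only (mean removal).
#' @return Residual vector.
#' @export
residualize <- function(y, covariates = NULL) {
  C <- cbind(intercept = rep(1, length(y)), covariates)
  qrC <- qr(C)
  if (qrC$rank < ncol(C)) {
    nm <- colnames(C) %||% paste0("V", seq_len(ncol(C)))
    bad <- nm[qrC$pivot[(qrC$rank + 1L):ncol(C)]]
    stop("covariate matrix is rank deficient (collinear column(s): ",
         paste(bad, collapse = ", "), ")")
  }
  as.numeric(qr.resid(qrC, y))
}

#' Per-variant marginal association scan in a cis-region
#'
#' Simple linear regression of (residualized) expression on each
#' (residualized) cis variant, Frisch-Waugh style: both phenotype and
#' genotype are projected off the covariates and the t statistic uses
#' `n - n_covariates - 2` degrees of freedom. p-values are two-sided and
#' floored at `p_floor` so `-log10(p)` stays finite.
#'
#' @param panel a [genotype_panel()] or a knockoff panel.
#' @param y expression vector.
#' @param region_idx integer index of the cis variants to test.
#' @param covariates optional covariate matrix.
#' @param p_floor lower bound applied to p-values (default 1e-300).
#' @return data.frame: variant_id, slope, se, t, p, constant (flag).
#' @export
marginal_scan <- function(panel, y, region_idx, covariates = NULL,
                          p_floor = 1e-300) {
  if (length(region_idx) == 0L) stop("empty cis-region")
  X <- geno_matrix(panel)[, region_idx, drop = FALSE]
  n <- length(y)
  q <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  df <- n - q - 2L
  if (df < 1L) stop("not enough samples for the residual degrees of freedom")
  yr <- residualize(y, covariates)
  Xr <- if (is.null(covariates)) X else apply(X, 2L, residualize, covariates)
  # correlation-based t statistics on the residualized data
  yc <- yr - mean(yr)
  Xc <- sweep(Xr, 2L, colMeans(Xr), "-")
  sx <- sqrt(colSums(Xc^2))
  sy <- sqrt(sum(yc^2))
  const <- sx <= .Machine$double.eps * sqrt(n)
  sx_safe <- ifelse(const, 1, sx)
  r <- as.numeric(crossprod(Xc, yc)) / (sx_safe * sy)
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt(df / pmax(1 - r^2, .Machine$double.xmin))
  p <- 2 * stats::pt(-abs(tstat), df = df)
  p <- pmax(p, p_floor)
  slope <- r * sy / sx_safe
  se <- ifelse(abs(tstat) > 0, slope / tstat, sy / (sx_safe * sqrt(df)))
  p[const] <- 1
  tstat[const] <- 0
  slope[const] <- 0
  data.frame(
    variant_id = geno_ids(panel)[region_idx],
    slope = slope, se = se, t = tstat, p = p, constant = const,
    stringsAsFactors = FALSE
  )
}

# Dosage-like matrix and ids from either a genotype_panel or a
# knockoff_panel.
geno_matrix <- function(panel) {
  if (inherits(panel, "genotype_panel")) return(panel$dosages)
  if (inherits(panel, "knockoff_panel")) return(panel$values)
  as.matrix(panel)
}

geno_ids <- function(panel) {
  if (inherits(panel, "genotype_panel")) return(panel$variants$id)
  if (inherits(panel, "knockoff_panel")) return(panel$variants$id)
  colnames(as.matrix(panel))
}

#' Gene-level minimum p-value and lead variant
#'
#' Ties are broken by smaller |dTSS|, then lexicographic variant id.
#'
#' @param records data.frame from [marginal_scan()].
#' @param tss optional TSS position for the dTSS tie-break.
#' @param pos optional vector of variant positions aligned with `records`.
#' @return List with `min_p` and `lead`.
#' @export
gene_min_p <- function(records, tss = NULL, pos = NULL) {
  if (nrow(records) == 0L) stop("no association records")
  p <- records$p
  best <- which(p == min(p))
  if (length(best) > 1L && !is.null(tss) && !is.null(pos)) {
    d <- abs(pos[best] - tss)
    best <- best[d == min(d)]
  }
  if (length(best) > 1L) {
    best <- best[order(records$variant_id[best])][1L]
  } else {
    best <- best[1L]
  }
  list(min_p = p[best], lead = records$variant_id[best])
}

#' Effective number of independent tests (eigenvalue rule)
#'
#' `M_eff` is the smallest number of leading eigenvalues of the cis LD
#' matrix whose sum reaches `variance_explained` of the trace; the
#' per-gene significance threshold is `0.05 / M_eff`.
#'
#' @param R_cis symmetric correlation matrix of the cis variants.
#' @param variance_explained fraction of the trace to cover (default
#'   0.99).
#' @return List with `m_eff` and `threshold`.
#' @export
emt_effective_tests <- function(R_cis, variance_explained = 0.99) {
  R_cis <- as.matrix(R_cis)
  if (!isSymmetric(R_cis, tol = 1e-8)) stop("R_cis must be symmetric")
  ev <- eigen(R_cis, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  target <- variance_explained * sum(ev)
  m_eff <- which(cumsum(ev) >= target - 1e-12)[1L]
  list(m_eff = m_eff, threshold = 0.05 / m_eff)
}

#' Permutation-based gene-level p-value with a Beta tail approximation
#'
#' Permutes the (residualized) phenotype `n_perm` times, records each
#' permutation's minimum cis p-value, fits a Beta(a, b) to the permuted
#' minima by maximum likelihood and evaluates the observed minimum under
#' its CDF. The plain empirical permutation p-value
#' `(1 + #{min_p_perm <= min_p_obs}) / (n_perm + 1)` is reported
#' alongside.
#'
#' @param panel a [genotype_panel()].
#' @param y expression vector.
#' @param region_idx cis variant index.
#' @param covariates optional covariates.
#' @param n_perm number of permutations (>= 50; the Beta fit is unstable
#'   below that).
#' @param seed integer RNG seed.
#' @param perm_idx optional precomputed n x n_perm matrix of permutation
#'   indices (shared permutations speed up genome-wide runs).
#' @return List: `p_beta`, `p_empirical`, `beta_shape`, `min_p_obs`.
#' @export
gene_level_p_permutation <- function(panel, y, region_idx, covariates = NULL,
                                     n_perm = 100L, seed = 1L,
                                     perm_idx = NULL) {
  if (is.null(perm_idx)) {
    if (n_perm < 50L) stop("n_perm must be >= 50 for a stable Beta fit")
    set.seed(as.integer(seed))
    perm_idx <- replicate(n_perm, sample.int(length(y)))
  }
  n_perm <- ncol(perm_idx)
  X <- geno_matrix(panel)[, region_idx, drop = FALSE]
  yr <- residualize(y, covariates)
  Xr <- if (is.null(covariates)) X else apply(X, 2L, residualize, covariates)
  q <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  obs <- min_p_cor(Xr, matrix(yr, ncol = 1L), df = length(y) - q - 2L)
  perm_min <- min_p_cor(Xr, matrix(yr[perm_idx], ncol = n_perm),
                        df = length(y) - q - 2L)
  fit <- fit_beta_ml(perm_min)
  list(
    p_beta = stats::pbeta(obs, fit[1L], fit[2L]),
    p_empirical = (1 + sum(perm_min <= obs)) / (n_perm + 1),
    beta_shape = fit,
    min_p_obs = obs
  )
}

# Column-wise minimum two-sided p over the correlation of each column of
# Y with every column of X (both will be centered internally).
min_p_cor <- function(X, Y, df, p_floor = 1e-300) {
  n <- nrow(X)
  Xc <- sweep(X, 2L, colMeans(X), "-")
  sx <- sqrt(colSums(Xc^2))
  keep <- sx > 0
  if (!any(keep)) return(rep(1, ncol(Y)))
  Xs <- sweep(Xc[, keep, drop = FALSE], 2L, sx[keep], "/")
  Yc <- sweep(Y, 2L, colMeans(Y), "-")
  sy <- sqrt(colSums(Yc^2))
  sy[sy <= 0] <- 1
  Ys <- sweep(Yc, 2L, sy, "/")
  R <- crossprod(Xs, Ys)                     # variants x phenotypes
  R <- pmin(pmax(R, -1), 1)
  rmax <- apply(abs(R), 2L, max)
  tmax <- rmax * sqrt(df / pmax(1 - rmax^2, .Machine$double.xmin))
  pmax(2 * stats::pt(-tmax, df = df), p_floor)
}

# Maximum-likelihood Beta(a, b) fit, moment-matched start, values clamped
# into the open unit interval for a finite log-likelihood.
fit_beta_ml <- function(x, eps = 1e-12) {
  x <- pmin(pmax(x, eps), 1 - eps)
  m <- mean(x); v <- stats::var(x)
  v <- max(v, 1e-12)
  common <- max(m * (1 - m) / v - 1, 0.1)
  start <- log(c(max(m * common, 1e-3), max((1 - m) * common, 1e-3)))
  nll <- function(lp) {
    a <- exp(lp[1L]); b <- exp(lp[2L])
    -sum(stats::dbeta(x, a, b, log = TRUE))
  }
  opt <- stats::optim(start, nll, method = "Nelder-Mead")
  exp(opt$par)
}
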