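#' Knockoff panel container
#'
#' Holds one knockoff column per original variant, aligned by index, plus
#' the engine tag and the 1 Mb group boundaries the construction used.
#' Gaussian knockoffs are continuous, HMM knockoffs integer dosages; both
#' run through the identical scan code path as the real panel.
#'
#' @param values numeric matrix samples x variants.
#' @param variants the source panel's variant table.
#' @param engine `"hmm"` or `"gaussian"`.
#' @param groups integer vector of 0-based group indices per variant.
#' @return Object of class `knockoff_panel`.
#' @export
knockoff_panel <- function(values, variants, engine, groups) {
  values <- as.matrix(values)
  if (ncol(values) != nrow(variants)) {
    stop("knockoff matrix and variant table are misaligned")
  }
  if (!engine %in% c("hmm", "gaussian")) stop("unknown engine: ", engine)
  colnames(values) <- variants$id
  structure(list(values = values, variants = variants, engine = engine,
                 groups = groups),
            class = "knockoff_panel")
}

#' @export
print.knockoff_panel <- function(x, ...) {
  cat("knockoff_panel (", x$engine, "): ", nrow(x$values), " samples x ",
      ncol(x$values), " variants\n", sep = "")
  invisible(x)
}

#' Fit a haplotype HMM by Baum-Welch
#'
#' Runs exactly `n_iter` EM iterations from a seeded random
#' initialization on phased binary haplotypes, with per-locus transition
#' and emission parameters. A small pseudocount keeps probabilities off
#' the boundary. The log-likelihood trace is attached as attribute
#' `loglik` and is non-decreasing up to numerical tolerance.
#'
#' @param haplotypes binary matrix, haplotypes x loci.
#' @param n_states number of states K (default 20).
#' @param n_iter number of EM iterations (default 20; 0 returns the
#'   initialization unchanged).
#' @param seed integer RNG seed for the initialization.
#' @param pseudocount Dirichlet-style smoothing added to every expected
#'   count; keeps probabilities off the exact boundary without visibly
#'   biasing the M-step (default 1e-8).
#' @return A [haplotype_hmm()] with attribute `loglik`.
#' @export
fit_hmm_em <- function(haplotypes, n_states = 20L, n_iter = 20L, seed = 1L,
                       pseudocount = 1e-8) {
  H <- as.matrix(haplotypes)
  if (!all(H %in% c(0, 1))) stop("haplotypes must be binary")
  n <- nrow(H); m <- ncol(H); K <- as.integer(n_states)
  if (K < 1L) stop("n_states must be >= 1")
  set.seed(as.integer(seed))
  init <- stats::runif(K, 0.5, 1.5); init <- init / sum(init)
  trans <- lapply(seq_len(m - 1L), function(j) {
    Q <- matrix(stats::runif(K * K, 0.5, 1.5), K, K)
    diag(Q) <- diag(Q) + 5 * K   # start near a sticky chain
    Q / rowSums(Q)
  })
  emit <- matrix(stats::runif(m * K, 0.1, 0.9), m, K)
  hmm <- haplotype_hmm(init, trans, emit)
  loglik <- numeric(0)
  if (n_iter > 0L) {
    for (it in seq_len(n_iter)) {
      es <- hmm_estep(hmm, H)
      loglik <- c(loglik, es$loglik)
      # M-step with pseudocounts
      init <- es$gamma1 + pseudocount
      init <- init / sum(init)
      trans <- lapply(es$xi, function(x) {
        x <- x + pseudocount
        x / rowSums(x)
      })
      ones <- es$gamma_alt + pseudocount
      tot <- es$gamma_tot + 2 * pseudocount
      emit <- ones / tot
      hmm <- haplotype_hmm(init, trans, emit)
    }
  }
  attr(hmm, "loglik") <- loglik
  hmm
}

# Forward-backward over all haplotypes at once (scaled). Returns the
# summed sufficient statistics and the total log-likelihood of the data
# under the *current* parameters.
hmm_estep <- function(hmm, H) {
  n <- nrow(H); m <- ncol(H); K <- hmm$n_states
  emis <- function(j) {
    e <- hmm$emit[j, ]
    outer(H[, j], e, function(x, p) ifelse(x == 1, p, 1 - p))
  }
  alpha <- vector("list", m)
  scale <- matrix(0, n, m)
  a <- sweep(emis(1L), 2L, hmm$init, "*")
  s <- rowSums(a); s[s <= 0] <- .Machine$double.xmin
  alpha[[1L]] <- a / s
  scale[, 1L] <- s
  for (j in seq_len(m - 1L)) {
    a <- (alpha[[j]] %*% hmm$trans[[j]]) * emis(j + 1L)
    s <- rowSums(a); s[s <= 0] <- .Machine$double.xmin
    alpha[[j + 1L]] <- a / s
    scale[, j + 1L] <- s
  }
  loglik <- sum(log(scale))
  beta <- matrix(1, n, K)
  gamma_alt <- matrix(0, m, K)   # expected count of allele-1 per state
  gamma_tot <- matrix(0, m, K)
  xi <- vector("list", m - 1L)
  g <- alpha[[m]] * beta
  g <- g / rowSums(g)
  gamma_tot[m, ] <- colSums(g)
  gamma_alt[m, ] <- colSums(g * (H[, m] == 1))
  for (j in rev(seq_len(m - 1L))) {
    eb <- emis(j + 1L) * beta               # n x K
    xi[[j]] <- hmm$trans[[j]] * (t(alpha[[j]]) %*% (eb / scale[, j + 1L]))
    beta <- (eb %*% t(hmm$trans[[j]])) / scale[, j + 1L]
    g <- alpha[[j]] * beta
    g <- g / rowSums(g)
    gamma_tot[j, ] <- colSums(g)
    gamma_alt[j, ] <- colSums(g * (H[, j] == 1))
  }
  g1 <- alpha[[1L]] * beta
  g1 <- g1 / rowSums(g1)
  list(loglik = loglik, gamma1 = colSums(g1), xi = xi,
       gamma_alt = gamma_alt, gamma_tot = gamma_tot)
}

#' Total log-likelihood of haplotypes under an HMM
#' @param hmm a [haplotype_hmm()].
#' @param H binary haplotype matrix.
#' @return Scalar log-likelihood (forward algorithm, scaled).
#' @export
hmm_loglik <- function(hmm, H) {
  hmm_forward(hmm, as.matrix(H))$loglik
}

# Scaled forward pass only.
hmm_forward <- function(hmm, H) {
  n <- nrow(H); m <- ncol(H); K <- hmm$n_states
  alpha <- vector("list", m)
  ll <- numeric(n)
  e <- hmm$emit[1L, ]
  a <- sweep(outer(H[, 1L], e, function(x, p) ifelse(x == 1, p, 1 - p)),
             2L, hmm$init, "*")
  s <- rowSums(a); s[s <= 0] <- .Machine$double.xmin
  alpha[[1L]] <- a / s
  ll <- log(s)
  for (j in seq_len(m - 1L)) {
    e <- hmm$emit[j + 1L, ]
    a <- (alpha[[j]] %*% hmm$trans[[j]]) *
      outer(H[, j + 1L], e, function(x, p) ifelse(x == 1, p, 1 - p))
    s <- rowSums(a); s[s <= 0] <- .Machine$double.xmin
    alpha[[j + 1L]] <- a / s
    ll <- ll + log(s)
  }
  list(alpha = alpha, loglik = sum(ll), loglik_per_seq = ll)
}

#' Sample HMM knockoff haplotypes
#'
#' Three stages per haplotype, all vectorized across haplotypes:
#' (1) forward-filter backward-sample the latent state path from its
#' posterior given the observed alleles; (2) build a knockoff state path
#' by the sequential conditional independent pairs (SCIP) recursion for
#' Markov chains -- at locus j the knockoff state is drawn with weights
#' `Q_j(z[j-1], k) * Q_j(z~[j-1], k) * Q_{j+1}(k, z[j+1]) / N_{j-1}(k)`,
#' where the normalizing function satisfies
#' `N_j(k') = sum_k Q_j(z[j-1], k) Q_j(z~[j-1], k) Q_{j+1}(k, k') / N_{j-1}(k)`
#' with `N_0 = 1`, the first-locus "transition" is the initial
#' distribution, and the factor beyond the last locus is 1; (3) emit
#' knockoff alleles from the per-state emissions. The construction makes
#' (Z, Z~) pairwise exchangeable, hence (X, X~) exchangeable when the
#' model is the true generator; the exchangeability test suite, not the
#' formula, is the operational contract.
#'
#' @param hmm a [haplotype_hmm()] (true or EM-fitted).
#' @param haplotypes binary matrix, haplotypes x loci.
#' @param seed integer RNG seed.
#' @return Binary knockoff haplotype matrix of the same shape.
#' @export
sample_hmm_knockoffs <- function(hmm, haplotypes, seed = 1L) {
  H <- as.matrix(haplotypes)
  if (ncol(H) != hmm$n_loci) stop("haplotype/HMM dimension mismatch")
  n <- nrow(H); m <- ncol(H); K <- hmm$n_states
  set.seed(as.integer(seed))

  # (1) posterior state path by forward filtering / backward sampling
  fw <- hmm_forward(hmm, H)
  Z <- matrix(0L, n, m)
  Z[, m] <- sample_categorical_rows(fw$alpha[[m]])
  for (j in rev(seq_len(m - 1L))) {
    w <- fw$alpha[[j]] * t(hmm$trans[[j]])[Z[, j + 1L], , drop = FALSE]
    Z[, j] <- sample_categorical_rows(w)
  }

  # (2) SCIP knockoff copy of the latent Markov chain
  Zt <- matrix(0L, n, m)
  Nprev <- matrix(1, n, K)
  for (j in seq_len(m)) {
    q_real <- if (j == 1L) matrix(hmm$init, n, K, byrow = TRUE) else
      hmm$trans[[j - 1L]][Z[, j - 1L], , drop = FALSE]
    q_ko <- if (j == 1L) matrix(1, n, K) else
      hmm$trans[[j - 1L]][Zt[, j - 1L], , drop = FALSE]
    num <- q_real * q_ko
    A <- num / Nprev
    A[num == 0] <- 0   # unreachable states: 0/0 counts as 0 mass
    if (j < m) {
      fwd <- t(hmm$trans[[j]])[Z[, j + 1L], , drop = FALSE]
      w <- A * fwd
      Zt[, j] <- sample_categorical_rows(w)
      Nprev <- A %*% hmm$trans[[j]]
    } else {
      Zt[, j] <- sample_categorical_rows(A)
    }
  }

  # (3) emit knockoff alleles
  Ht <- matrix(0L, n, m)
  for (j in seq_len(m)) {
    Ht[, j] <- stats::rbinom(n, 1L, hmm$emit[j, Zt[, j]])
  }
  Ht
}

#' HMM-engine knockoff panel
#'
#' Builds knockoff haplotypes with [sample_hmm_knockoffs()] (per
#' chromosome when the panel carries per-chromosome generating models),
#' sums them into knockoff dosages and aligns columns with the panel.
#'
#' @param panel a [genotype_panel()] with haplotypes.
#' @param hmm a [haplotype_hmm()] fit on (or generating) the panel's
#'   haplotypes, matching the panel's retained columns; or a list of
#'   models, one per chromosome.
#' @param seed integer RNG seed.
#' @param group_bp group width for bookkeeping.
#' @return A [knockoff_panel()] with engine `"hmm"`.
#' @export
make_hmm_knockoffs <- function(panel, hmm, seed = 1L, group_bp = 1e6) {
  if (is.null(panel$haplotypes)) {
    stop("the HMM engine requires phased haplotypes on the panel")
  }
  chroms <- unique(panel$variants$chrom)
  hmms <- if (inherits(hmm, "haplotype_hmm")) list(hmm) else hmm
  if (length(hmms) != length(chroms)) {
    stop("need one HMM per chromosome (", length(chroms), " chromosome(s), ",
         length(hmms), " model(s))")
  }
  n <- nrow(panel$dosages)
  values <- matrix(0, n, ncol(panel$dosages))
  for (ci in seq_along(chroms)) {
    idx <- which(panel$variants$chrom == chroms[ci])
    Ht <- sample_hmm_knockoffs(hmms[[ci]],
                               panel$haplotypes[, idx, drop = FALSE],
                               seed = as.integer(seed) + ci)
    values[, idx] <- Ht[seq(1, 2L * n, by = 2L), , drop = FALSE] +
      Ht[seq(2, 2L * n, by = 2L), , drop = FALSE]
  }
  knockoff_panel(values, panel$variants, "hmm",
                 position_group(panel$variants$pos, group_bp))
}

#' Second-order Gaussian knockoffs (equicorrelated construction)
#'
#' Within each 1 Mb group the standardized dosages are treated as
#' Gaussian with correlation `Sigma` (ridge-regularized); the
#' equicorrelated construction sets `s = min(1, 2 lambda_min(Sigma))` and
#' samples knockoffs from the conditional Gaussian with mean
#' `X (I - Sigma^{-1} diag(s))` and covariance
#' `2 diag(s) - diag(s) Sigma^{-1} diag(s)`. Columns are re-standardized
#' afterwards.
#'
#' @param panel a [genotype_panel()].
#' @param seed integer RNG seed.
#' @param ridge diagonal regularization added to the correlation matrix
#'   before inversion (default 1e-4).
#' @param group_bp group width in bp.
#' @return A [knockoff_panel()] with engine `"gaussian"`.
#' @export
sample_gaussian_knockoffs <- function(panel, seed = 1L, ridge = 1e-4,
                                      group_bp = 1e6) {
  set.seed(as.integer(seed))
  v <- panel$variants
  groups <- position_group(v$pos, group_bp)
  key <- paste(v$chrom, groups)
  n <- nrow(panel$dosages)
  values <- matrix(0, n, ncol(panel$dosages))
  for (g in unique(key)) {
    idx <- which(key == g)
    X <- scale(panel$dosages[, idx, drop = FALSE])  # unit sample variance
    Sigma <- stats::cor(panel$dosages[, idx, drop = FALSE])
    Sigma <- Sigma + diag(ridge, nrow(Sigma))
    Sigma <- Sigma / (1 + ridge)      # keep unit diagonal after the ridge
    eg <- eigen(Sigma, symmetric = TRUE)
    if (min(eg$values) <= 1e-10) {
      stop("cis LD matrix is numerically singular even after the ridge; ",
           "increase `ridge`")
    }
    s <- min(1, 2 * min(eg$values)) * 0.999   # stay inside the PSD cone
    Sinv <- eg$vectors %*% (t(eg$vectors) / eg$values)
    D <- diag(s, length(idx))
    mu <- X - X %*% (Sinv * s)                # X (I - Sigma^{-1} D)
    C <- 2 * D - s^2 * Sinv
    ec <- eigen((C + t(C)) / 2, symmetric = TRUE)
    sq <- ec$vectors %*% (t(ec$vectors) * sqrt(pmax(ec$values, 0)))
    Zn <- matrix(stats::rnorm(n * length(idx)), n, length(idx))
    values[, idx] <- standardize_columns(mu + Zn %*% sq)
  }
  knockoff_panel(values, v, "gaussian", groups)
}

#' Build a knockoff panel with the configured engine
#'
#' @param panel a [genotype_panel()].
#' @param engine `"gaussian"` (closed-form default) or `"hmm"` (the
#'   haplotype-model construction; needs `hmm`).
#' @param hmm HMM(s) for the hmm engine; when omitted, the generating
#'   models attached by [simulate_genotypes()] are used if present, else
#'   one model per chromosome is fit with [fit_hmm_em()].
#' @param seed integer RNG seed.
#' @param ridge ridge for the Gaussian engine.
#' @param config optional [kfc_config()] supplying EM fitting parameters.
#' @return A [knockoff_panel()].
#' @export
make_knockoffs <- function(panel, engine = c("gaussian", "hmm"), hmm = NULL,
                           seed = 1L, ridge = 1e-4, config = kfc_config()) {
  engine <- match.arg(engine)
  if (engine == "gaussian") {
    return(sample_gaussian_knockoffs(panel, seed = seed, ridge = ridge,
                                     group_bp = config$group_bp))
  }
  if (is.null(hmm)) hmm <- attr(panel, "hmms")
  if (is.null(hmm)) {
    chroms <- unique(panel$variants$chrom)
    hmm <- lapply(seq_along(chroms), function(ci) {
      idx <- which(panel$variants$chrom == chroms[ci])
      fit_hmm_em(panel$haplotypes[, idx, drop = FALSE],
                 n_states = config$hmm_fit_states,
                 n_iter = config$hmm_fit_iter,
                 seed = as.integer(seed) + 101L * ci)
    })
  }
  make_hmm_knockoffs(panel, hmm, seed = seed, group_bp = config$group_bp)
}

#' Knockoff quality diagnostics
#'
#' Reports, per 1 Mb group, the Frobenius distance between the real-real
#' and knockoff-knockoff correlation matrices, the distribution of the
#' per-variant correlation between a variant and its own knockoff, and
#' MAF-stratified medians (knockoff fidelity is typically worse at low
#' MAF). Degenerate knockoffs (exact copies, r = 1 everywhere) and LD
#' destruction (permutation-like knockoffs) raise flags.
#'
#' @param panel the real [genotype_panel()].
#' @param knockoff the [knockoff_panel()].
#' @param ld_tol flag when the median per-group Frobenius distance,
#'   scaled by the matrix size, exceeds this (default 0.1).
#' @param copy_tol flag when the median own-knockoff correlation exceeds
#'   this (default 0.95): the knockoff is (close to) a copy.
#' @param maf_breaks breaks for MAF stratification.
#' @return List of class `knockoff_diagnostics`.
#' @export
knockoff_diagnostics <- function(panel, knockoff, ld_tol = 0.1,
                                 copy_tol = 0.95,
                                 maf_breaks = c(0, 0.05, 0.1, 0.25, 0.5)) {
  if (!identical(panel$variants$id, knockoff$variants$id)) {
    stop("panel and knockoff variant tables are misaligned")
  }
  v <- panel$variants
  key <- paste(v$chrom, position_group(v$pos))
  per_group <- lapply(unique(key), function(g) {
    idx <- which(key == g)
    if (length(idx) < 2L) return(NULL)
    Rr <- stats::cor(panel$dosages[, idx, drop = FALSE])
    Rk <- suppressWarnings(stats::cor(knockoff$values[, idx, drop = FALSE]))
    Rk[is.na(Rk)] <- 0
    data.frame(group = g, n_variants = length(idx),
               frobenius = norm(Rr - Rk, type = "F") / length(idx),
               mean_offdiag_real = mean(abs(Rr[upper.tri(Rr)])),
               mean_offdiag_ko = mean(abs(Rk[upper.tri(Rk)])),
               stringsAsFactors = FALSE)
  })
  per_group <- do.call(rbind, per_group)
  Xs <- standardize_columns(panel$dosages)
  Ks <- standardize_columns(knockoff$values)
  r_self <- colSums(Xs * Ks) / nrow(Xs)
  maf_bin <- cut(v$maf, maf_breaks, include.lowest = TRUE)
  by_maf <- stats::aggregate(
    list(median_frobenius_proxy = abs(r_self)),
    by = list(maf_bin = maf_bin), FUN = stats::median)
  flags <- character(0)
  if (stats::median(r_self) >= copy_tol) {
    flags <- c(flags, "knockoff is (near-)identical to the original panel")
  }
  if (!is.null(per_group) &&
      stats::median(per_group$frobenius) > ld_tol) {
    flags <- c(flags, "knockoff LD structure deviates from the original")
  }
  structure(list(per_group = per_group, r_self = r_self, by_maf = by_maf,
                 flags = flags),
            class = "knockoff_diagnostics")
}

#' @export
print.knockoff_diagnostics <- function(x, ...) {
  cat("knockoff diagnostics over", length(x$r_self), "variants\n")
  cat("  median r(X, X~):", signif(stats::median(x$r_self), 3), "\n")
  if (!is.null(x$per_group)) {
    cat("  median scaled Frobenius LD distance:",
        signif(stats::median(x$per_group$frobenius), 3), "\n")
  }
  if (length(x$flags) == 0L) cat("  no flags\n")
  else for (f in x$flags) cat("  FLAG:", f, "\n")
  invisible(x)
}
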