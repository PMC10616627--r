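test_that("cis-region covers the TSS group plus flanking groups", {
  v <- data.frame(chrom = "1",
                  pos = c(1L, 5e5, 15e5, 25e5, 35e5, 45e5),
                  id = paste0("v", 1:6), ref = "A", alt = "G", maf = 0.2,
                  stringsAsFactors = FALSE)
  p <- genotype_panel(matrix(rbinom(12, 2, 0.4), 2, 6), v)
  g_mid <- list(gene_id = "g", chrom = "1", tss = 15e5)   # group 1
  expect_equal(cis_region_index(g_mid, p), 1:4)           # groups 0..2
  g_start <- list(gene_id = "g", chrom = "1", tss = 2L)   # group 0
  expect_equal(cis_region_index(g_start, p), 1:3)         # truncated left
  g_other <- list(gene_id = "g", chrom = "2", tss = 15e5)
  expect_length(cis_region_index(g_other, p), 0L)
})

test_that("residualization projects exactly and idempotently", {
  set.seed(1)
  y <- rnorm(100)
  C <- matrix(rnorm(500), 100, 5)
  r <- residualize(y, C)
  expect_true(all(abs(crossprod(cbind(1, C), r)) < 1e-10))
  expect_equal(residualize(r, C), r, tolerance = 1e-12)
  # intercept-only = mean removal
  expect_equal(residualize(y), y - mean(y))
  # y inside the covariate span -> zero
  expect_equal(residualize(C %*% rep(1, 5), C), rep(0, 100),
               tolerance = 1e-10)
  expect_error(residualize(y, cbind(C, C[, 1])), "rank deficient")
})

test_that("marginal scan matches the closed-form simple regression", {
  x <- c(0, 1, 2, 0, 1, 2)
  y <- c(0.1, 0.2, 0.3, 0.0, 0.1, 0.4)
  v <- data.frame(chrom = "1", pos = 10L, id = "v1", ref = "A", alt = "G",
                  maf = 0.5, stringsAsFactors = FALSE)
  p <- genotype_panel(matrix(x, ncol = 1), v)
  rec <- marginal_scan(p, y, 1L)
  # independent oracle: t = r * sqrt((n-2) / (1 - r^2))
  r <- stats::cor(x, y)
  t_ref <- r * sqrt(4 / (1 - r^2))
  p_ref <- 2 * stats::pt(-abs(t_ref), df = 4)
  expect_equal(rec$t, t_ref, tolerance = 1e-12)
  expect_equal(rec$p, p_ref, tolerance = 1e-12)
  # cross-check against lm()
  fit <- summary(stats::lm(y ~ x))$coefficients
  expect_equal(rec$slope, fit["x", "Estimate"], tolerance = 1e-10)
  expect_equal(rec$p, fit["x", "Pr(>|t|)"], tolerance = 1e-10)
})

test_that("marginal scan handles perfect fits and orthogonal phenotypes", {
  p <- small_panel()
  x <- standardize_columns(p$dosages)[, 1]
  rec_perfect <- marginal_scan(p, 3 * p$dosages[, 1] - 1, 1L)
  expect_equal(rec_perfect$p, 1e-300)   # p-value floored, not zero
  # orthogonal phenotype: t = 0, p = 1 (build y orthogonal to x)
  y <- rnorm(length(x))
  y <- residualize(y, cbind(x))
  rec0 <- marginal_scan(p, y, 1L)
  expect_lt(abs(rec0$t), 1e-8)
  expect_gt(rec0$p, 1 - 1e-6)
  # constant genotype column flagged with p = 1
  v <- p$variants[1:2, ]; v$id <- c("c1", "c2")
  pc <- genotype_panel(cbind(rep(1, 120), p$dosages[, 2]), v)
  recc <- marginal_scan(pc, y, 1:2)
  expect_true(recc$constant[1])
  expect_equal(recc$p[1], 1)
})

test_that("covariate-adjusted scan equals explicit two-stage regression", {
  set.seed(2)
  p <- small_panel()
  C <- matrix(rnorm(120 * 3), 120, 3)
  y <- rnorm(120) + C %*% c(1, -1, 0.5) + 0.5 * p$dosages[, 5]
  rec <- marginal_scan(p, y, 5L, covariates = C)
  fit <- summary(stats::lm(y ~ p$dosages[, 5] + C))$coefficients
  # Frisch-Waugh: same t and p as the full multiple regression
  expect_equal(rec$t, fit[2, "t value"], tolerance = 1e-8)
  expect_equal(rec$p, fit[2, "Pr(>|t|)"], tolerance = 1e-8)
})

test_that("gene-level minimum p breaks ties toward the TSS then by id", {
  rec <- data.frame(variant_id = c("b", "a", "c"), p = c(0.5, 0.01, 0.9))
  expect_equal(gene_min_p(rec)$min_p, 0.01)
  expect_equal(gene_min_p(rec)$lead, "a")
  ties <- data.frame(variant_id = c("v1", "v2", "v3"), p = c(1, 1, 1))
  out <- gene_min_p(ties, tss = 100L, pos = c(500L, 120L, 900L))
  expect_equal(out$lead, "v2")   # nearest TSS
  out2 <- gene_min_p(ties)
  expect_equal(out2$lead, "v1")  # lexicographic fallback
  expect_error(gene_min_p(rec[0, ]), "no association")
})

test_that("effective test counts follow the eigenvalue rule", {
  expect_equal(emt_effective_tests(diag(10))$m_eff, 10L)
  e1 <- emt_effective_tests(matrix(1, 5, 5))
  expect_equal(e1$m_eff, 1L)
  expect_equal(e1$threshold, 0.05)
  R <- matrix(c(1, 0.6, 0.6, 1), 2)   # eigenvalues 1.6 and 0.4
  e2 <- emt_effective_tests(R)
  expect_equal(e2$m_eff, 2L)          # 1.6 < 0.99 * 2
  expect_equal(e2$threshold, 0.025)
  expect_error(emt_effective_tests(matrix(c(1, 0.5, 0.1, 1), 2)),
               "symmetric")
})

test_that("permutation gene-level p behaves at its extremes", {
  p <- small_panel()
  idx <- seq_len(20L)
  x <- standardize_columns(p$dosages)[, 3]
  y <- x + rnorm(120, sd = 0.05)   # overwhelming signal
  gp <- gene_level_p_permutation(p, y, idx, n_perm = 60L, seed = 5)
  expect_equal(gp$p_empirical, 1 / 61)
  expect_lt(gp$p_beta, 0.01)
  expect_error(gene_level_p_permutation(p, y, idx, n_perm = 10L), "50")
})

test_that("permutation p-values are uniform under the null", {
  panel <- simulate_genotypes(n_samples = 80L, n_variants = 40L,
                              n_chrom = 1L, span_bp = 3e6, n_states = 5L,
                              seed = 500L)
  idx <- seq_len(ncol(panel$dosages))
  set.seed(501)
  perm_idx <- replicate(60, sample.int(80))
  pvals <- vapply(1:200, function(i) {
    y <- draw_noise(80L, 0, seed = 600 + i)
    gene_level_p_permutation(panel, y, idx, perm_idx = perm_idx)$p_empirical
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("single-variant regions need no minimum-p correction", {
  p <- small_panel()
  set.seed(7)
  y <- rnorm(120)
  gp <- gene_level_p_permutation(p, y, 4L, n_perm = 300L, seed = 8)
  obs <- marginal_scan(p, y, 4L)$p
  expect_lt(abs(gp$p_beta - obs), 0.15)
  expect_true(all(abs(gp$beta_shape - 1) < 0.5))  # near Beta(1, 1)
})

test_that("per-variant p-values are uniform under h2 = 0", {
  panel <- simulate_genotypes(n_samples = 100L, n_variants = 30L,
                              n_chrom = 1L, span_bp = 3e6, n_states = 5L,
                              seed = 700L)
  ps <- unlist(lapply(1:60, function(i) {
    y <- draw_noise(100L, 0, seed = 800 + i)
    marginal_scan(panel, y, seq_len(5))$p
  }))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("stronger heritability gives smaller minimum p", {
  p <- small_panel()
  ids <- p$variants$id
  wins <- vapply(1:40, function(i) {
    t_hi <- sim_truth("g", 0.9, ids[7], effect_size(0.9, matrix(1, 1, 1)))
    t_lo <- sim_truth("g", 0.05, ids[7], effect_size(0.05, matrix(1, 1, 1)))
    y_hi <- simulate_expression(p, t_hi, seed = 900 + i)
    y_lo <- simulate_expression(p, t_lo, seed = 900 + i)
    idx <- seq_len(ncol(p$dosages))
    min(marginal_scan(p, y_hi, idx)$p) < min(marginal_scan(p, y_lo, idx)$p)
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("the scan code path is identical for real and knockoff input", {
  p <- small_panel()
  set.seed(9)
  y <- rnorm(120)
  ko <- knockoff_panel(p$dosages, p$variants, "gaussian",
                       position_group(p$variants$pos))
  expect_equal(marginal_scan(ko, y, 1:10), marginal_scan(p, y, 1:10))
})
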