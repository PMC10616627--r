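test_that("Baum-Welch recovers closed-form answers in degenerate settings", {
  set.seed(1)
  H <- matrix(rbinom(500 * 6, 1, rep(c(0.2, 0.7, 0.4, 0.1, 0.55, 0.35),
                                     each = 500)), 500, 6)
  fit1 <- fit_hmm_em(H, n_states = 1L, n_iter = 5L, seed = 2)
  expect_equal(as.numeric(fit1$emit), colMeans(H), tolerance = 1e-6)

  init0 <- fit_hmm_em(H, n_states = 3L, n_iter = 0L, seed = 3)
  init0b <- fit_hmm_em(H, n_states = 3L, n_iter = 0L, seed = 3)
  expect_equal(init0$emit, init0b$emit)   # n_iter = 0 returns the init
  expect_length(attr(init0, "loglik"), 0L)
  expect_error(fit_hmm_em(matrix(c(0, 2), 2, 1), n_states = 1L),
               "binary")
})

test_that("EM log-likelihood is non-decreasing and fits a known model", {
  gen <- make_default_hmm(30, n_states = 3L, seed = 10)
  H <- sample_haplotypes(gen, 2000L, seed = 11)
  H_test <- sample_haplotypes(gen, 500L, seed = 12)
  fit <- fit_hmm_em(H, n_states = 3L, n_iter = 40L, seed = 13)
  ll <- attr(fit, "loglik")
  expect_true(all(diff(ll) >= -1e-8))
  ll_fit <- hmm_loglik(fit, H_test)
  ll_gen <- hmm_loglik(gen, H_test)
  expect_lt(abs(ll_fit - ll_gen) / abs(ll_gen), 0.02)
})

test_that("HMM knockoffs are fresh draws under a memoryless model", {
  hmm1 <- make_default_hmm(10, n_states = 1L, seed = 20)
  H <- sample_haplotypes(hmm1, 10000L, seed = 21)
  Ht <- sample_hmm_knockoffs(hmm1, H, seed = 22)
  for (j in 1:10) {
    if (stats::sd(H[, j]) == 0 || stats::sd(Ht[, j]) == 0) next
    r <- stats::cor(H[, j], Ht[, j])
    expect_lt(abs(r), 4 / sqrt(10000))
  }
})

test_that("deterministic chain and emissions reproduce the original exactly", {
  K <- 2L; m <- 8L
  trans <- replicate(m - 1, diag(K), simplify = FALSE)
  emit <- matrix(rep(c(1, 0), each = m), m, K)   # state1 -> all ones
  hmm <- haplotype_hmm(c(0.5, 0.5), trans, emit)
  H <- sample_haplotypes(hmm, 200L, seed = 30)
  Ht <- sample_hmm_knockoffs(hmm, H, seed = 31)
  expect_identical(unname(Ht), unname(H))
})

test_that("HMM knockoffs reproduce adjacent-pair LD moments", {
  gen <- make_default_hmm(30, n_states = 5L, seed = 40)
  H <- sample_haplotypes(gen, 4000L, seed = 41)
  Ht <- sample_hmm_knockoffs(gen, H, seed = 42)
  n <- nrow(H)
  for (j in 1:29) {
    if (min(stats::sd(H[, j]), stats::sd(H[, j + 1]),
            stats::sd(Ht[, j]), stats::sd(Ht[, j + 1])) == 0) next
    r_real <- stats::cor(H[, j], H[, j + 1])
    r_ko <- stats::cor(Ht[, j], Ht[, j + 1])
    mc_sd <- sqrt((1 - r_real^2)^2 / n + (1 - r_ko^2)^2 / n)
    expect_lt(abs(r_ko - r_real), 4 * pmax(mc_sd, 1 / sqrt(n)))
  }
  expect_error(sample_hmm_knockoffs(gen, H[, 1:10]), "mismatch")
})

test_that("swapping originals with true-model knockoffs preserves LD", {
  panel <- small_panel()
  hmms <- attr(panel, "hmms")
  ko <- make_hmm_knockoffs(panel, hmms, seed = 50)
  n <- nrow(panel$dosages)
  m <- ncol(panel$dosages)
  set.seed(51)
  swap <- sample(c(TRUE, FALSE), m, replace = TRUE)
  swapped <- panel$dosages
  swapped[, swap] <- ko$values[, swap]
  Xs <- standardize_columns(panel$dosages)
  Ss <- standardize_columns(swapped)
  r_orig <- crossprod(Xs)[upper.tri(diag(m))] / n
  r_swap <- crossprod(Ss)[upper.tri(diag(m))] / n
  # entrywise within 4 rough MC SDs, and no systematic shift
  expect_true(mean(abs(r_swap - r_orig) <= 8 / sqrt(n)) > 0.99)
  expect_lt(abs(mean(r_swap - r_orig)), 4 / sqrt(n * m))
})

test_that("gaussian knockoffs decorrelate singles and preserve pair LD", {
  set.seed(60)
  n <- 10000L
  # single variant: knockoff independent of the original
  v1 <- data.frame(chrom = "1", pos = 5L, id = "v1", ref = "A", alt = "G",
                   maf = 0.3, stringsAsFactors = FALSE)
  p1 <- genotype_panel(matrix(rbinom(n, 2, 0.3), ncol = 1), v1)
  k1 <- sample_gaussian_knockoffs(p1, seed = 61)
  expect_lt(abs(stats::cor(p1$dosages[, 1], k1$values[, 1])), 4 / sqrt(n))

  # correlated pair: knockoff-knockoff correlation matches the original
  z <- rbinom(n, 2, 0.4)
  flip <- rbinom(n, 1, 0.1) * sample(c(-1, 1), n, replace = TRUE)
  x2 <- pmin(pmax(z + flip, 0), 2)
  v2 <- data.frame(chrom = "1", pos = c(5L, 6L), id = c("a", "b"),
                   ref = "A", alt = "G", maf = 0.4,
                   stringsAsFactors = FALSE)
  p2 <- genotype_panel(cbind(z, x2), v2)
  r_real <- stats::cor(z, x2)
  k2 <- sample_gaussian_knockoffs(p2, seed = 62)
  r_ko <- stats::cor(k2$values[, 1], k2$values[, 2])
  expect_lt(abs(r_ko - r_real), 4 * sqrt(2) * (1 - r_real^2) / sqrt(n))
  # independent pair stays independent
  y <- rbinom(n, 2, 0.25)
  p3 <- genotype_panel(cbind(z, y), v2)
  k3 <- sample_gaussian_knockoffs(p3, seed = 63)
  expect_lt(abs(stats::cor(k3$values[, 1], k3$values[, 2])), 4 / sqrt(n))
})

test_that("knockoff diagnostics flag copies and destroyed LD", {
  p <- small_panel()
  copy <- knockoff_panel(p$dosages, p$variants, "gaussian",
                         position_group(p$variants$pos))
  d_copy <- knockoff_diagnostics(p, copy)
  expect_true(any(grepl("identical", d_copy$flags)))

  set.seed(70)
  perm <- apply(p$dosages, 2L, sample)
  d_perm <- knockoff_diagnostics(
    p, knockoff_panel(perm, p$variants, "gaussian",
                      position_group(p$variants$pos)))
  expect_true(any(grepl("LD", d_perm$flags)))
  # permuted knockoffs carry only sampling-noise LD, far below the real LD
  expect_lt(mean(d_perm$per_group$mean_offdiag_ko),
            mean(d_perm$per_group$mean_offdiag_real) / 2)

  ko <- sample_gaussian_knockoffs(p, seed = 71)
  d_ok <- knockoff_diagnostics(p, ko)
  expect_length(d_ok$flags, 0L)
  expect_error(knockoff_diagnostics(p, subset_variants(p, 1:3)),
               "misaligned")
})

test_that("knockoffs are reproducible by seed", {
  p <- small_panel()
  k1 <- sample_gaussian_knockoffs(p, seed = 80)
  k2 <- sample_gaussian_knockoffs(p, seed = 80)
  k3 <- sample_gaussian_knockoffs(p, seed = 81)
  expect_identical(k1$values, k2$values)
  expect_false(identical(k1$values, k3$values))
  h1 <- make_hmm_knockoffs(p, attr(p, "hmms"), seed = 82)
  h2 <- make_hmm_knockoffs(p, attr(p, "hmms"), seed = 82)
  expect_identical(h1$values, h2$values)
})
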