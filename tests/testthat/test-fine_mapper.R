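# Independent brute-force oracle: enumerate every configuration with
# direct multivariate-normal densities (no shared code with the package
# internals beyond base R).
oracle_pips <- function(z, R, n, prior, k_max, prior_sd = 0.05,
                        size_prior = function(k) 1 / k_max) {
  m <- length(z)
  a <- n * prior_sd^2
  logdens <- function(zz, S) {
    -0.5 * (length(zz) * log(2 * pi) + determinant(S)$modulus +
              sum(zz * solve(S, zz)))
  }
  pip <- numeric(m)
  logw <- c(); members <- list()
  for (k in seq_len(k_max)) {
    for (j in seq_len(ncol(utils::combn(m, k)))) {
      ix <- utils::combn(m, k)[, j]
      S0 <- R[ix, ix, drop = FALSE]
      S1 <- S0 + a * S0 %*% S0
        lw <- logdens(z[ix], S1) - logdens(z[ix], S0) +
        sum(log(prior[ix] / (1 - prior[ix]))) + log(size_prior(k))
      logw <- c(logw, lw)
      members <- c(members, list(ix))
    }
  }
  w <- exp(logw - max(logw)); w <- w / sum(w)
  for (j in seq_along(members)) pip[members[[j]]] <- pip[members[[j]]] + w[j]
  pip
}

test_that("configuration BF reduces to the Wakefield ABF for one variant", {
  n <- 465
  # z = 0: log BF = 0.5 * log(1 - r) < 0
  r <- 0.05^2 / (0.05^2 + 1 / n)
  expect_equal(config_log_bf(0, diag(1), 1L, n), 0.5 * log(1 - r))
  expect_lt(config_log_bf(0, diag(1), 1L, n), 0)
  # vanishing prior: BF -> 0 (null model recovered)
  expect_lt(abs(config_log_bf(5, diag(1), 1L, n, prior_sd = 1e-8)), 1e-10)
  # hand-computed Wakefield value
  z <- 5; se <- 1 / sqrt(n); s <- 0.05
  rr <- s^2 / (s^2 + se^2)
  by_hand <- log(sqrt(1 - rr) * exp(z^2 * rr / 2))
  expect_equal(config_log_bf(z, diag(1), 1L, n, prior_sd = s), by_hand,
               tolerance = 1e-10)
  expect_equal(wakefield_log_abf(z, se, s), by_hand, tolerance = 1e-12)
  expect_error(config_log_bf(c(1, 2), diag(2), c(1, 1), n), "distinct")
})

test_that("pruned enumeration equals the exhaustive oracle on small regions", {
  panel <- simulate_genotypes(n_samples = 150L, n_variants = 12L,
                              n_chrom = 1L, span_bp = 3e6, n_states = 4L,
                              seed = 1000L, maf_min = 0.05)
  m <- ncol(panel$dosages)
  g <- list(gene_id = "G", chrom = "1", tss = 1500000L)
  idx <- cis_region_index(g, panel)
  set.seed(1001)
  y <- rnorm(150) + 0.6 * standardize_columns(panel$dosages)[, 2]
  for (k_max in c(1L, 2L, 3L)) {
    fm <- finemap_gene(y, panel, idx, k_max = k_max, candidate_cap = m)
    z <- unname(fm$z)
    Xs <- standardize_columns(panel$dosages)
    R <- crossprod(sweep(Xs, 2, sqrt(colSums(Xs^2)), "/"))
    ref <- oracle_pips(z, R, 150, rep(1 / m, m), k_max)
    expect_lt(max(abs(unname(fm$pip) - ref)), 1e-10)
    # audit (pure R) path agrees with the compiled path
    fa <- finemap_gene(y, panel, idx, k_max = k_max, candidate_cap = m,
                       audit = TRUE)
    expect_lt(max(abs(fa$pip - fm$pip)), 1e-12)
    expect_equal(sum(fa$config_table$posterior), 1, tolerance = 1e-12)
  }
  # k_max = 1: PIPs sum to one
  fm1 <- finemap_gene(y, panel, idx, k_max = 1L, candidate_cap = m)
  expect_equal(sum(fm1$pip), 1, tolerance = 1e-10)
})

test_that("perfect LD splits PIP and priors break the tie", {
  n <- 400
  set.seed(2000)
  x <- rbinom(n, 2, 0.4)
  v <- data.frame(chrom = "1", pos = c(100L, 200L), id = c("a", "b"),
                  ref = "A", alt = "G", maf = mean(x) / 2,
                  stringsAsFactors = FALSE)
  p <- genotype_panel(cbind(x, x), v)    # r = 1 duplicate pair
  y <- standardize_columns(cbind(x))[, 1] * 0.7 + rnorm(n, sd = 0.7)
  fm <- finemap_gene(y, p, 1:2, k_max = 1L)
  expect_equal(unname(fm$pip), c(0.5, 0.5), tolerance = 1e-10)
  # identical likelihood, non-uniform prior: posterior proportional to prior
  fmp <- finemap_gene(y, p, 1:2, k_max = 1L, prior = c(a = 0.9, b = 0.1),
                      prior_type = "product")
  expect_equal(unname(fmp$pip), c(0.9, 0.1), tolerance = 1e-10)
  # bernoulli convention: posterior follows the causal odds instead
  fmb <- finemap_gene(y, p, 1:2, k_max = 1L, prior = c(a = 0.9, b = 0.1))
  odds <- c(0.9 / 0.1, 0.1 / 0.9)
  expect_equal(unname(fmb$pip), odds / sum(odds), tolerance = 1e-10)
})

test_that("raising the causal prior never lowers its PIP", {
  panel <- small_panel()
  g <- small_gene()
  idx <- cis_region_index(g, panel)
  ids <- panel$variants$id[idx]
  set.seed(3000)
  y <- 0.5 * standardize_columns(panel$dosages)[, 10] + rnorm(120, sd = 0.9)
  target <- ids[10]
  last <- -Inf
  for (boost in c(1, 2, 5, 20)) {
    prior <- stats::setNames(rep(1, length(ids)), ids)
    prior[target] <- boost
    fm <- finemap_gene(y, panel, idx, prior = prior / sum(prior),
                       k_max = 2L, candidate_cap = 15L)
    expect_gte(fm$pip[[target]] + 1e-12, last)
    last <- fm$pip[[target]]
  }
})

test_that("external priors impute, floor and normalize as specified", {
  ext <- c(A = 0.9, B = NA, C = 0.1)
  pr <- build_external_prior(ext, c("A", "B", "C"), shrink = FALSE)
  expect_equal(unname(pr["B"]), 0.5)   # mean imputation
  expect_equal(attr(pr, "provenance"), "external_raw")
  expect_equal(unname(pr[c("A", "C")]), c(0.9, 0.1))  # as-is, unnormalized

  ext2 <- c(A = 0.9, B = 1e-6, C = 1e-6)
  pr2 <- build_external_prior(ext2, c("A", "B", "C"), shrink = TRUE)
  expect_equal(unname(pr2["A"]), 0.9 / 0.918, tolerance = 1e-12)
  expect_equal(unname(pr2["B"]), 0.009 / 0.918, tolerance = 1e-12)
  expect_equal(sum(pr2), 1, tolerance = 1e-12)
  expect_equal(attr(pr2, "provenance"), "external_shrunk")
  # variants absent from the external study are missing too
  pr3 <- build_external_prior(c(A = 0.4), c("A", "D"), shrink = FALSE)
  expect_equal(unname(pr3["D"]), 0.4)
  expect_error(build_external_prior(c(A = NA_real_), c("A", "B")),
               "ineligible")
})

test_that("the causal variant tops the PIPs for strongly heritable genes", {
  ms <- medium_sim()
  panel <- ms$panel
  genes <- ms$genes[1:40, ]
  idxs <- lapply(seq_len(nrow(genes)), function(i)
    cis_region_index(genes[i, ], panel))
  # force strong single-causal genes: h2 in [0.5, 0.9] on the grid
  hit <- vapply(seq_len(nrow(genes)), function(i) {
    h2 <- (50 + (i %% 41)) / 100
    cid <- assign_causals(genes[i, ], panel, k = 1L, seed = 5000 + i,
                          region_idx = idxs[[i]])
    tr <- sim_truth(genes$gene_id[i], h2, cid,
                    effect_size(h2, matrix(1, 1, 1)))
    y <- simulate_expression(panel, tr, seed = 6000 + i)
    fm <- finemap_gene(y, panel, idxs[[i]], k_max = 2L,
                       candidate_cap = 15L)
    names(which.max(fm$pip)) == cid
  }, logical(1))
  expect_gte(mean(hit), 0.8)
})
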