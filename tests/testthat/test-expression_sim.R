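test_that("heritability lands on the 0.01 grid with the configured null mass", {
  ids <- sprintf("G%05d", 1:19913)
  h2 <- assign_heritability(ids, seed = 1)
  expect_true(all(abs(h2 * 100 - round(h2 * 100)) < 1e-9))
  # binomial check of the realized null fraction against the spec mass
  n_null <- sum(h2 == 0)
  expected <- 19913 * 0.381
  expect_lt(abs(n_null - expected), 4 * sqrt(19913 * 0.381 * 0.619))

  # degenerate specs
  h2_all0 <- assign_heritability(ids[1:100],
                                 dist_spec = list(p_null = 1), seed = 2)
  expect_true(all(h2_all0 == 0))
  w <- numeric(99); w[50] <- 1   # all positive mass at h2 = 0.50
  h2_half <- assign_heritability(ids[1:10000],
                                 dist_spec = list(p_null = 0.5, weights = w),
                                 seed = 3)
  expect_true(all(h2_half %in% c(0, 0.5)))
  expect_error(assign_heritability(ids, dist_spec = list(p_null = 2)),
               "p_null")
})

test_that("causal probability follows the clipped log-log line", {
  flat <- dtss_curve(slope = 0, intercept = -1)
  expect_equal(causal_probability(c(10, 1e6), flat), c(0.1, 0.1))
  inv <- dtss_curve(slope = -1, intercept = 0)
  expect_equal(causal_probability(10, inv), 0.1)
  expect_equal(causal_probability(1000, inv), 0.001)
  # default curve decreases with distance and clips at 1
  expect_gt(causal_probability(5e3), causal_probability(5e5))
  expect_equal(causal_probability(0, dtss_curve(slope = -1, intercept = 5)), 1)
  expect_error(causal_probability(-5), "non-negative")
})

test_that("causal draws are dTSS-weighted without replacement", {
  p <- small_panel()
  g <- small_gene()
  idx <- cis_region_index(g, p)
  # k equal to region size selects everything
  all_ids <- assign_causals(g, p, k = min(5L, length(idx)), seed = 1,
                            region_idx = idx[1:5])
  expect_setequal(all_ids, p$variants$id[idx[1:5]])
  expect_error(assign_causals(g, p, k = 3L, region_idx = idx[1:2]), "fewer")

  # two-variant binomial check of the weighting: dTSS 10 vs 90 with a
  # slope of -1 gives weights 1/10 vs 1/90, i.e. a 0.9 / 0.1 draw
  v <- data.frame(chrom = "1", pos = c(11L, 91L), id = c("a", "b"),
                  ref = "A", alt = "G", maf = 0.3, stringsAsFactors = FALSE)
  panel2 <- genotype_panel(matrix(c(0, 1, 1, 2), 2, 2), v)
  gene2 <- list(gene_id = "G", chrom = "1", tss = 1L)
  curve <- dtss_curve(slope = -1, intercept = 0)
  w <- causal_probability(abs(v$pos - 1L), curve)
  expect_equal(w[1] / sum(w), 0.9, tolerance = 1e-6)
  hits <- vapply(1:10000, function(s)
    assign_causals(gene2, panel2, curve, k = 1L, seed = s) == "a",
    logical(1))
  expect_lt(abs(mean(hits) - 0.9), 4 * sqrt(0.09 / 10000))
})

test_that("noise has exact moments and honours edge cases", {
  e <- draw_noise(465L, 0.64, seed = 1)
  expect_lt(abs(mean(e)), 1e-12)
  expect_lt(abs(sum(e^2) / 465 - 0.36), 1e-12)
  e0 <- draw_noise(10L, 0, seed = 2)
  expect_lt(abs(sum(e0^2) / 10 - 1), 1e-12)
  expect_equal(draw_noise(7L, 1, seed = 3), numeric(7))
  expect_error(draw_noise(1L, 0.5), "n must be")
})

test_that("effect size satisfies beta^2 * sum(R) = h2", {
  expect_equal(effect_size(0.36, matrix(1, 1, 1)), 0.6)
  expect_equal(effect_size(0.5, diag(2))^2, 0.25)
  expect_equal(effect_size(0.4, matrix(1, 2, 2))^2, 0.1)
  expect_error(effect_size(0.5, matrix(c(1, -1, -1, 1), 2)), "positive")
})

test_that("simulated expression decomposes into exact genetic + noise parts", {
  p <- small_panel()
  n <- nrow(p$dosages)
  ids <- p$variants$id
  # h2 = 0: pure unit-variance noise
  t0 <- sim_truth("g0", 0, character(0), 0)
  y0 <- simulate_expression(p, t0, seed = 5)
  expect_lt(abs(sum(y0^2) / n - 1), 1e-10)
  # h2 = 1 single causal: y is the standardized genotype up to sign
  t1 <- sim_truth("g1", 0.99, ids[3], effect_size(0.99, matrix(1, 1, 1)))
  y1 <- simulate_expression(p, t1, seed = 6)
  x3 <- standardize_columns(p$dosages[, 3, drop = FALSE])[, 1]
  gvar <- sum((t1$beta * x3)^2) / n
  expect_lt(abs(gvar - 0.99), 1e-10)
  # orthogonalized noise gives total variance exactly 1
  t2 <- sim_truth("g2", 0.3, ids[c(2, 9)],
                  effect_size(0.3, stats::cor(p$dosages[, c(2, 9)])))
  y2 <- simulate_expression(p, t2, seed = 7, orthogonalize_noise = TRUE)
  expect_lt(abs(sum((y2 - mean(y2))^2) / n - 1), 1e-8)
  expect_error(simulate_expression(p, sim_truth("g", 0.5, "nope", 0.7)),
               "missing")
  expect_error(sim_truth("g", 0, "v1", 0.1), "empty")
  expect_error(sim_truth("g", 0.5, character(0), 0.1), "empty")
})

test_that("every simulated gene satisfies the exact heritability identity", {
  ms <- medium_sim()
  for (tr in ms$sim$truths) {
    if (tr$h2 == 0) next
    X <- standardize_columns(
      ms$panel$dosages[, match(tr$causal_ids, ms$panel$variants$id),
                       drop = FALSE])
    R <- crossprod(X) / nrow(X)
    expect_lt(abs(tr$beta^2 * sum(R) - tr$h2), 1e-10)
  }
  # heritability grid only
  h2s <- vapply(ms$sim$truths, `[[`, numeric(1), "h2")
  expect_true(all(abs(h2s * 100 - round(h2s * 100)) < 1e-9))
})

test_that("causal variants sit closer to the TSS than uniform placement", {
  ms <- medium_sim()
  panel <- ms$panel
  tssmap <- stats::setNames(ms$genes$tss, ms$genes$gene_id)
  causal_d <- unlist(lapply(ms$sim$truths, function(tr) {
    if (length(tr$causal_ids) == 0L) return(numeric(0))
    abs(panel$variants$pos[match(tr$causal_ids, panel$variants$id)] -
          tssmap[[tr$gene_id]])
  }))
  # uniform reference: all cis variants of the same genes
  unif_d <- unlist(lapply(ms$sim$truths, function(tr) {
    if (length(tr$causal_ids) == 0L) return(numeric(0))
    idx <- cis_region_index(ms$genes[ms$genes$gene_id == tr$gene_id, ], panel)
    abs(panel$variants$pos[idx] - tssmap[[tr$gene_id]])
  }))
  expect_gt(length(causal_d), 400)
  wt <- stats::wilcox.test(causal_d, unif_d, alternative = "less")
  expect_lt(wt$p.value, 0.01)
})

test_that("prior scenarios put the maximum prior where each case demands", {
  ms <- medium_sim()
  pool <- stats::runif(5000, 0, 0.009)
  scen <- make_prior_scenarios(ms$sim$truths, ms$panel, ms$genes, pool,
                               counts = c(matched = 12L, mismatched = 12L,
                                          null = 20L),
                               max_prior = 0.9, seed = 77)
  expect_length(scen, 44L)
  for (sc in scen) {
    expect_equal(unname(sc$prior[sc$top_id]), 0.9)
    expect_equal(sum(sc$prior >= 0.01), 1L)   # truncation rule
    tr <- ms$sim$truths[[sc$gene_id]]
    if (sc$case == "matched_eGene") {
      expect_equal(names(which.max(sc$prior)), tr$causal_ids[1])
      expect_gt(tr$h2, 0.05)
    } else if (sc$case == "mismatched_eGene") {
      expect_false(sc$top_id %in% tr$causal_ids)
      expect_gt(tr$h2, 0.05)
    } else {
      expect_equal(tr$h2, 0)
    }
  }
  expect_error(
    make_prior_scenarios(ms$sim$truths, ms$panel, ms$genes, pool,
                         counts = c(matched = 10000L, mismatched = 1L,
                                    null = 1L)),
    "eligible")
})
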