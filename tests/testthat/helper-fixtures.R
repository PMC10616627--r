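# Shared fixtures, built lazily and cached for the whole test run.

.fixture_env <- new.env(parent = emptyenv())

cached_fixture <- function(key, builder) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, builder(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# A small LD-structured panel for unit tests (120 samples, ~60 variants).
small_panel <- function() {
  cached_fixture("small_panel", function() {
    simulate_genotypes(n_samples = 120L, n_variants = 60L, n_chrom = 1L,
                       span_bp = 3e6, n_states = 6L, seed = 101L)
  })
}

# A single-gene scaffold over the small panel.
small_gene <- function() {
  data.frame(gene_id = "G1", chrom = "1", tss = 1500000L,
             stringsAsFactors = FALSE)
}

# Medium study: panel + genes + simulated expression, no knockoffs.
medium_sim <- function() {
  cached_fixture("medium_sim", function() {
    cfg <- kfc_config(n_genes = 400L, n_variants = 150L)
    panel <- simulate_genotypes(n_samples = cfg$n_samples,
                                n_variants = cfg$n_variants,
                                n_chrom = 1L, span_bp = cfg$span_bp,
                                n_states = cfg$n_states, seed = 202L)
    genes <- kfcombo:::make_gene_annotation(cfg, 203L)
    sim <- simulate_study_expression(panel, genes, cfg, seed = 204L)
    list(cfg = cfg, panel = panel, genes = genes, sim = sim)
  })
}

# Full acceptance-scale study run: 2000 genes (38.1% null), default
# panel, gaussian knockoffs, raw + KFc adjustments. Built once; shared by
# the acceptance criteria on lFDP control, PIP calibration and the
# prior-scenario experiment.
study_run <- function() {
  cached_fixture("study_run", function() {
    run_kfc_pipeline(kfc_config(), seed = 20260901L,
                     methods = c("raw", "kfc"), compute_gene_p = FALSE)
  })
}
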