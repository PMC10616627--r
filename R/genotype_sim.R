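#' Haplotype hidden Markov model container
#'
#' A left-to-right HMM over binary haplotype alleles: `init` is the state
#' distribution at the first locus, `trans[[j]]` the K x K transition
#' matrix from locus `j` to `j + 1`, and `emit[j, k]` the probability of
#' allele 1 at locus `j` in state `k`. This is the model class both the
#' LD-structured fixture generator and the knockoff engine operate on.
#'
#' @param init probability vector over the K states.
#' @param trans list of length `m - 1` of K x K row-stochastic matrices.
#' @param emit m x K matrix of allele-1 emission probabilities.
#' @return An object of class `haplotype_hmm`.
#' @export
haplotype_hmm <- function(init, trans, emit) {
  emit <- as.matrix(emit)
  K <- length(init)
  m <- nrow(emit)
  if (ncol(emit) != K) stop("emit must be m x K")
  if (length(trans) != m - 1L) stop("trans must have m - 1 matrices")
  check_rows <- function(p, what) {
    if (any(abs(rowSums(p) - 1) > 1e-12) || any(p < 0)) {
      stop(what, " rows must be non-negative and sum to 1 within 1e-12")
    }
  }
  check_rows(matrix(init, nrow = 1L), "init")
  for (Q in trans) {
    if (!all(dim(Q) == c(K, K))) stop("transition matrices must be K x K")
    check_rows(Q, "transition")
  }
  if (any(emit < 0 | emit > 1)) stop("emission probabilities must be in [0, 1]")
  structure(list(n_states = K, n_loci = m, init = init, trans = trans,
                 emit = emit),
            class = "haplotype_hmm")
}

#' @export
print.haplotype_hmm <- function(x, ...) {
  cat("haplotype_hmm:", x$n_states, "states x", x$n_loci, "loci\n")
  invisible(x)
}

#' Serialize / restore an HMM as a JSON text file
#' @param hmm a [haplotype_hmm()].
#' @param path file path.
#' @return `write_hmm` returns `path` invisibly; `read_hmm` the model.
#' @export
write_hmm <- function(hmm, path) {
  obj <- list(n_states = hmm$n_states, n_loci = hmm$n_loci, init = hmm$init,
              trans = lapply(hmm$trans, function(m) unname(as.matrix(m))),
              emit = unname(hmm$emit))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_hmm
#' @export
read_hmm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  haplotype_hmm(init = as.numeric(obj$init),
                trans = lapply(seq_len(obj$n_loci - 1L), function(j) {
                  matrix(obj$trans[j, , ], obj$n_states, obj$n_states)
                }),
                emit = matrix(obj$emit, obj$n_loci, obj$n_states))
}

#' Build the default LD-structured fixture HMM
#'
#' A haplotype-mosaic model: each state represents an ancestral
#' haplotype carrying a near-deterministic allele at every locus
#' (emission `1 - emit_noise` or `emit_noise`), and transitions mix a
#' per-locus stay probability with a jump to a common background state
#' distribution, so haplotype correlation decays geometrically with
#' locus lag. The per-locus allele frequency targeted by the state
#' alleles is drawn uniformly in `[emit_min, emit_max]`, giving a
#' common-variant-like MAF spectrum. Deterministic given `seed`.
#'
#' @param n_variants number of loci (>= 1).
#' @param n_states number of HMM states K (>= 1).
#' @param seed integer RNG seed.
#' @param stay_min,stay_max range the per-locus stay probability is drawn
#'   from uniformly.
#' @param emit_min,emit_max range of per-locus target allele frequencies.
#' @param emit_noise per-state allele miscopy probability (default 0.02).
#' @return A [haplotype_hmm()].
#' @export
make_default_hmm <- function(n_variants, n_states = 12L, seed = 1L,
                             stay_min = 0.9, stay_max = 0.995,
                             emit_min = 0.05, emit_max = 0.5,
                             emit_noise = 0.02) {
  if (n_states < 1L) stop("n_states must be >= 1")
  if (n_variants < 1L) stop("n_variants must be >= 1")
  set.seed(as.integer(seed))
  background <- stats::rgamma(n_states, shape = 2, rate = 1)
  background <- background / sum(background)
  init <- background
  stay <- stats::runif(max(n_variants - 1L, 0L), stay_min, stay_max)
  trans <- lapply(seq_len(max(n_variants - 1L, 0L)), function(j) {
    Q <- (1 - stay[j]) * matrix(background, n_states, n_states, byrow = TRUE)
    diag(Q) <- diag(Q) + stay[j]
    Q
  })
  freq <- stats::runif(n_variants, emit_min, emit_max)
  allele <- matrix(stats::rbinom(n_variants * n_states, 1L,
                                 rep(freq, n_states)),
                   nrow = n_variants, ncol = n_states)
  emit <- allele * (1 - emit_noise) + (1 - allele) * emit_noise
  haplotype_hmm(init, trans, emit)
}

#' Sample i.i.d. haplotypes from an HMM
#'
#' @param hmm a [haplotype_hmm()].
#' @param n_haplotypes even number of haplotypes to draw (paired into
#'   samples downstream).
#' @param seed integer RNG seed.
#' @return Binary matrix `n_haplotypes` x loci.
#' @export
sample_haplotypes <- function(hmm, n_haplotypes, seed = 1L) {
  if (n_haplotypes %% 2L != 0L) {
    stop("n_haplotypes must be even (haplotypes are paired into samples)")
  }
  m <- hmm$n_loci
  K <- hmm$n_states
  H <- matrix(0L, nrow = n_haplotypes, ncol = m)
  if (n_haplotypes == 0L) return(H)
  set.seed(as.integer(seed))
  state <- sample_categorical_rows(matrix(hmm$init, n_haplotypes, K,
                                          byrow = TRUE))
  H[, 1L] <- stats::rbinom(n_haplotypes, 1L, hmm$emit[1L, state])
  for (j in seq_len(m - 1L)) {
    probs <- hmm$trans[[j]][state, , drop = FALSE]
    state <- sample_categorical_rows(probs)
    H[, j + 1L] <- stats::rbinom(n_haplotypes, 1L, hmm$emit[j + 1L, state])
  }
  H
}

# Draw one categorical sample per row of a non-negative weight matrix
# (rows need not be normalized). Vectorized over rows.
sample_categorical_rows <- function(w) {
  n <- nrow(w)
  K <- ncol(w)
  tot <- rowSums(w)
  if (any(tot <= 0) || any(!is.finite(tot))) {
    stop("categorical weights must be finite with positive row sums")
  }
  u <- stats::runif(n) * tot
  pick <- rep.int(K, n)
  acc <- numeric(n)
  done <- rep.int(FALSE, n)
  for (k in seq_len(K - 1L)) {
    acc <- acc + w[, k]
    hit <- !done & (u <= acc)
    pick[hit] <- k
    done <- done | hit
  }
  pick
}

#' Pair haplotypes into a dosage panel
#'
#' Rows `2i - 1` and `2i` are summed into sample `i`; columns failing the
#' MAF filter (including monomorphic ones) are dropped from dosages,
#' haplotypes and metadata alike. The retained column indices are recorded
#' in attribute `kept`, so a knockoff built from the full haplotype matrix
#' can be filtered identically.
#'
#' @param haplotypes binary matrix with an even number of rows.
#' @param positions 1-based bp positions, one per column.
#' @param chrom chromosome label (recycled).
#' @param maf_min minimum in-sample MAF (monomorphic columns are always
#'   dropped when `maf_min > 0`).
#' @param id_prefix prefix for generated variant ids.
#' @return A [genotype_panel()] with attribute `kept`.
#' @export
haplotypes_to_panel <- function(haplotypes, positions, chrom = "1",
                                maf_min = 0.01, id_prefix = "v") {
  haplotypes <- as.matrix(haplotypes)
  if (nrow(haplotypes) %% 2L != 0L) stop("haplotype row count must be even")
  if (length(positions) != ncol(haplotypes)) {
    stop("positions length (", length(positions),
         ") does not match haplotype columns (", ncol(haplotypes), ")")
  }
  n <- nrow(haplotypes) %/% 2L
  dos <- haplotypes[seq(1, 2L * n, by = 2L), , drop = FALSE] +
    haplotypes[seq(2, 2L * n, by = 2L), , drop = FALSE]
  maf <- dosage_maf(dos)
  keep <- if (maf_min > 0) maf >= maf_min else rep(TRUE, length(maf))
  ord <- order(positions)
  keep_idx <- ord[keep[ord]]
  variants <- data.frame(
    chrom = rep_len(as.character(chrom), length(keep_idx)),
    pos = as.integer(positions[keep_idx]),
    id = sprintf("%s%s_%d", id_prefix, chrom, positions[keep_idx]),
    ref = "A", alt = "G",
    maf = maf[keep_idx],
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(variants$id)) {
    stop("duplicate variant positions on one chromosome are not supported")
  }
  panel <- genotype_panel(dos[, keep_idx, drop = FALSE], variants,
                          haplotypes = haplotypes[, keep_idx, drop = FALSE])
  attr(panel, "kept") <- keep_idx
  panel
}

#' Simulate a full LD-structured genotype panel
#'
#' Convenience wrapper: builds a default HMM per pseudo-chromosome, draws
#' haplotypes, places variant positions uniformly at random in the span
#' (sorted), and assembles one panel across chromosomes. The per-chromosome
#' generating HMMs are attached as attribute `hmms` so the knockoff engine
#' can consume the true model.
#'
#' @param n_samples number of diploid samples.
#' @param n_variants variants simulated per chromosome (before MAF filter).
#' @param n_chrom number of independent pseudo-chromosomes.
#' @param span_bp chromosome length in bp.
#' @param n_states HMM states.
#' @param maf_min MAF filter floor.
#' @param seed integer RNG seed.
#' @return A [genotype_panel()] with attributes `hmms` (list per
#'   chromosome) and `kept` (list of retained column indices per
#'   chromosome).
#' @export
simulate_genotypes <- function(n_samples = 465L, n_variants = 300L,
                               n_chrom = 1L, span_bp = 3e6, n_states = 12L,
                               maf_min = 0.01, seed = 1L) {
  panels <- vector("list", n_chrom)
  hmms <- vector("list", n_chrom)
  kept <- vector("list", n_chrom)
  for (cc in seq_len(n_chrom)) {
    seed_c <- as.integer(seed) + 7919L * (cc - 1L)
    hmm <- make_default_hmm(n_variants, n_states = n_states, seed = seed_c)
    H <- sample_haplotypes(hmm, 2L * n_samples, seed = seed_c + 1L)
    set.seed(seed_c + 2L)
    positions <- sort(sample.int(span_bp, n_variants, replace = FALSE))
    p <- haplotypes_to_panel(H, positions, chrom = as.character(cc),
                             maf_min = maf_min)
    panels[[cc]] <- p
    # keep the true model aligned with the MAF-filtered columns
    hmms[[cc]] <- subset_hmm(hmm, attr(p, "kept"))
    kept[[cc]] <- attr(p, "kept")
  }
  panel <- if (n_chrom == 1L) panels[[1L]] else do.call(cbind_panels, panels)
  attr(panel, "hmms") <- hmms
  attr(panel, "kept") <- kept
  attr(panel, "full_haplotypes") <- NULL
  panel
}

#' Column-bind panels over the same samples (different chromosomes)
#' @param ... `genotype_panel` objects with equal sample counts.
#' @return A combined [genotype_panel()].
#' @export
cbind_panels <- function(...) {
  ps <- list(...)
  ns <- vapply(ps, function(p) nrow(p$dosages), integer(1))
  if (length(unique(ns)) != 1L) stop("panels must share the sample count")
  has_h <- all(vapply(ps, function(p) !is.null(p$haplotypes), logical(1)))
  genotype_panel(
    dosages = do.call(cbind, lapply(ps, `[[`, "dosages")),
    variants = do.call(rbind, lapply(ps, `[[`, "variants")),
    haplotypes = if (has_h) do.call(cbind, lapply(ps, `[[`, "haplotypes")),
    sample_ids = ps[[1L]]$sample_ids
  )
}

#' Restrict an HMM to a subset of loci
#'
#' Dropping observation loci marginalizes the hidden Markov chain
#' exactly: the initial distribution is propagated to the first retained
#' locus and each retained-to-retained transition is the matrix product
#' of the per-step transitions in between. Used to keep the true
#' generating model aligned with a MAF-filtered panel.
#'
#' @param hmm a [haplotype_hmm()].
#' @param idx strictly increasing integer vector of retained loci.
#' @return A [haplotype_hmm()] over `length(idx)` loci.
#' @export
subset_hmm <- function(hmm, idx) {
  idx <- as.integer(idx)
  if (length(idx) < 1L || is.unsorted(idx, strictly = TRUE) ||
      idx[1L] < 1L || idx[length(idx)] > hmm$n_loci) {
    stop("idx must be strictly increasing positions within the model")
  }
  init <- hmm$init
  if (idx[1L] > 1L) {
    for (j in seq_len(idx[1L] - 1L)) init <- as.numeric(init %*% hmm$trans[[j]])
  }
  trans <- lapply(seq_len(length(idx) - 1L), function(k) {
    Q <- diag(hmm$n_states)
    for (j in idx[k]:(idx[k + 1L] - 1L)) Q <- Q %*% hmm$trans[[j]]
    Q / rowSums(Q)  # renormalize away accumulated round-off
  })
  haplotype_hmm(init / sum(init), trans,
                hmm$emit[idx, , drop = FALSE])
}

#' Marginal allele-1 probability at each locus by forward recursion
#'
#' Exact marginals from init/trans/emit; used as an independent oracle for
#' the haplotype sampler.
#'
#' @param hmm a [haplotype_hmm()].
#' @return Numeric vector of length `n_loci`.
#' @export
hmm_marginal_freq <- function(hmm) {
  p_state <- hmm$init
  out <- numeric(hmm$n_loci)
  out[1L] <- sum(p_state * hmm$emit[1L, ])
  for (j in seq_len(hmm$n_loci - 1L)) {
    p_state <- as.numeric(p_state %*% hmm$trans[[j]])
    out[j + 1L] <- sum(p_state * hmm$emit[j + 1L, ])
  }
  out
}
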