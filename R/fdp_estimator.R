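#' Per-gene knockoff statistic W
#'
#' `W = -log10(min_p_real) - (-log10(min_p_knockoff))`, i.e.
#' `log10(min_p_knockoff) - log10(min_p_real)`: large positive when the
#' real genotypes carry a much stronger signal than their knockoffs,
#' symmetric around 0 for null genes.
#'
#' @param min_p_real,min_p_knockoff gene-level minimum p-values in
#'   (0, 1]; floor p-values upstream, zero is an error here.
#' @return Numeric W (vectorized).
#' @export
compute_w <- function(min_p_real, min_p_knockoff) {
  if (any(min_p_real <= 0) || any(min_p_knockoff <= 0)) {
    stop("p-values must be positive; apply the p-value floor upstream")
  }
  if (any(min_p_real > 1) || any(min_p_knockoff > 1)) {
    stop("p-values must be <= 1")
  }
  log10(min_p_knockoff) - log10(min_p_real)
}

#' Rolling-window local false discovery probability estimate
#'
#' For each gene with `W = t > 0`, the positive W values are sorted and
#' the window is the 50 genes below and the 50 above `t` in sorted order
#' (shifted inward at the extremes so the denominator stays exactly 100
#' whenever enough positive-W genes exist). With `delta1`, `delta2` the
#' distances from `t` to the window edges, the estimate is the number of
#' genes with `W` in the open interval `(-(t + delta1), -(t - delta2))`
#' divided by the denominator -- a local count of sign-mirrored
#' (knockoff-favoring) genes. Genes with `W <= 0` get lFDP 1; estimates
#' above 1 are clipped to 1. Ties in W are ordered by gene id so the sort
#' is deterministic; the estimate is invariant to the input order of
#' genes.
#'
#' @param w numeric vector of W statistics, named by gene id (or pass
#'   `gene_ids`).
#' @param gene_ids optional gene ids aligned with `w`.
#' @param half_window genes on each side of the center (default 50).
#' @param target_denominator window size the estimator aims for
#'   (default 100).
#' @return data.frame of class `lfdp_table`: gene_id, W, lfdp, delta1,
#'   delta2, numerator, denominator.
#' @export
estimate_lfdp <- function(w, gene_ids = names(w), half_window = 50L,
                          target_denominator = 2L * half_window) {
  if (length(w) < 1L) stop("need at least one gene")
  if (is.null(gene_ids)) gene_ids <- as.character(seq_along(w))
  out <- data.frame(gene_id = gene_ids, W = as.numeric(w), lfdp = 1,
                    delta1 = NA_real_, delta2 = NA_real_,
                    numerator = NA_real_, denominator = NA_real_,
                    stringsAsFactors = FALSE)
  pos <- which(out$W > 0)
  if (length(pos) == 0L) {
    message("all W <= 0: every lFDP set to 1")
    class(out) <- c("lfdp_table", class(out))
    return(out)
  }
  ord <- pos[order(out$W[pos], out$gene_id[pos])]
  wpos <- out$W[ord]
  n_pos <- length(ord)
  n_others <- n_pos - 1L
  denom_full <- min(target_denominator, n_others)
  if (n_others < target_denominator) {
    warning("only ", n_pos, " positive-W genes; the lFDP denominator is ",
            denom_full, " instead of ", target_denominator)
  }
  wneg_sorted <- sort(out$W[out$W < 0])
  count_open <- function(lo, hi) {
    # #{W : lo < W < hi} among negative W, endpoints excluded
    if (length(wneg_sorted) == 0L) return(0L)
    n_le_hi <- findInterval(hi, wneg_sorted, left.open = TRUE)
    n_le_lo <- findInterval(lo, wneg_sorted)
    max(n_le_hi - n_le_lo, 0L)
  }
  half_lo <- floor(denom_full / 2)
  half_hi <- denom_full - half_lo
  for (r in seq_len(n_pos)) {
    t <- wpos[r]
    lo <- r - half_lo
    hi <- r + half_hi
    if (lo < 1L) { hi <- hi + (1L - lo); lo <- 1L }
    if (hi > n_pos) { lo <- max(1L, lo - (hi - n_pos)); hi <- n_pos }
    # window = sorted positives lo..hi excluding the gene itself
    edge_lo <- wpos[lo]
    edge_hi <- wpos[hi]
    delta2 <- t - edge_lo   # distance down
    delta1 <- edge_hi - t   # distance up
    denom <- (hi - lo + 1L) - 1L
    num <- count_open(-(t + delta1), -(t - delta2))
    i <- ord[r]
    out$delta1[i] <- delta1
    out$delta2[i] <- delta2
    out$numerator[i] <- num
    out$denominator[i] <- denom
    out$lfdp[i] <- min(num / max(denom, 1L), 1)
  }
  class(out) <- c("lfdp_table", class(out))
  out
}

#' Average lFDP tables from independent knockoff draws
#'
#' Smoothing individually noisy lFDP estimates: the per-gene arithmetic
#' mean of the estimates (re-clipped to [0, 1]) and the mean W. All
#' tables must cover the same genes.
#'
#' @param tables list of >= 2 `lfdp_table` objects.
#' @return A merged `lfdp_table` (window bookkeeping columns are NA).
#' @export
smooth_lfdp <- function(tables) {
  if (length(tables) < 2L) stop("need at least two lFDP tables to smooth")
  ids <- tables[[1L]]$gene_id
  for (tb in tables[-1L]) {
    if (!identical(sort(tb$gene_id), sort(ids))) {
      stop("lFDP tables cover different gene sets")
    }
  }
  aligned <- lapply(tables, function(tb) tb[match(ids, tb$gene_id), ])
  lf <- rowMeans(vapply(aligned, `[[`, numeric(length(ids)), "lfdp"))
  wm <- rowMeans(vapply(aligned, `[[`, numeric(length(ids)), "W"))
  out <- data.frame(gene_id = ids, W = wm,
                    lfdp = pmin(pmax(lf, 0), 1),
                    delta1 = NA_real_, delta2 = NA_real_,
                    numerator = NA_real_, denominator = NA_real_,
                    stringsAsFactors = FALSE)
  class(out) <- c("lfdp_table", class(out))
  out
}
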