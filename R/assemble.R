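#' Sparsify a posterior-mean network by thresholding
#'
#' Retains entries whose absolute value is strictly larger than `t`
#' verbatim; all other entries become exactly zero.  The Bayesian
#' shrinkage prior never produces exact zeros, so a preset threshold is
#' the variable-selection rule.
#'
#' @param Bhat A p x p numeric matrix.
#' @param t Nonnegative threshold (default 0.2).
#' @return The thresholded matrix.
#' @export
threshold_network <- function(Bhat, t = 0.2) {
  stopifnot(is.matrix(Bhat), t >= 0)
  Bhat * (abs(Bhat) > t)
}

# edge list (nonzero entries) of a weighted network matrix
network_edges <- function(B) {
  nz <- which(B != 0, arr.ind = TRUE)
  genes <- rownames(B)
  if (is.null(genes)) genes <- as.character(seq_len(nrow(B)))
  data.frame(source = genes[nz[, 1L]], target = genes[nz[, 2L]],
             weight = B[nz], stringsAsFactors = FALSE)
}

#' Differential network from two thresholded networks
#'
#' Entrywise difference of the two sparsified matrices (thresholding comes
#' first, then differencing), with the nonzero entries reported as a
#' labeled edge list.
#'
#' @param B1_sparse,B2_sparse Thresholded p x p matrices of the two
#'   conditions.
#' @return A list with `delta` (the difference matrix) and `edges` (data
#'   frame: source, target, weight_cond1, weight_cond2, delta).
#' @export
differential_network <- function(B1_sparse, B2_sparse) {
  if (!all(dim(B1_sparse) == dim(B2_sparse)))
    stop("condition matrices must have identical dimensions")
  delta <- B1_sparse - B2_sparse
  nz <- which(delta != 0, arr.ind = TRUE)
  genes <- rownames(delta)
  if (is.null(genes)) genes <- as.character(seq_len(nrow(delta)))
  edges <- data.frame(source = genes[nz[, 1L]], target = genes[nz[, 2L]],
                      weight_cond1 = B1_sparse[nz],
                      weight_cond2 = B2_sparse[nz],
                      delta = delta[nz], stringsAsFactors = FALSE)
  list(delta = delta, edges = edges)
}

#' Significance filter for differential edges
#'
#' A differential entry is biologically meaningful only when the change is
#' large relative to the effects themselves: entry (i, j) is retained iff
#' `|B1_ij - B2_ij| > min(|B1_ij|, |B2_ij|) / divisor`.  Absolute values
#' are used on both sides so that sign-mixed pairs cannot make the bound
#' negative and vacuous.  When one side is zero the bound is zero and any
#' nonzero change passes.
#'
#' @param B1_sparse,B2_sparse Thresholded p x p matrices.
#' @param divisor Relative-change divisor (default 5).
#' @return A logical p x p matrix marking retained entries.
#' @export
significant_differential <- function(B1_sparse, B2_sparse, divisor = 5) {
  if (!all(dim(B1_sparse) == dim(B2_sparse)))
    stop("condition matrices must have identical dimensions")
  stopifnot(divisor > 0)
  abs(B1_sparse - B2_sparse) > pmin(abs(B1_sparse), abs(B2_sparse)) / divisor
}

#' Bootstrap stability of inferred edges
#'
#' Resamples individuals with replacement (independently within each
#' condition, preserving the per-condition sample size), reruns the full
#' joint inference and thresholding on every bootstrap replicate, and
#' counts how often each edge is detected.  An edge is called stable when
#' its detection count is strictly greater than `keep_count`.  In
#' `"differential"` mode the differential significance filter is applied
#' on each replicate and stability refers to differential edges.
#'
#' @param data A `paired_dataset`.
#' @param hp A `hyperparams`.
#' @param n_boot Number of bootstrap replicates (default 100).
#' @param keep_count Stability cutoff; an edge must be detected more than
#'   this many times (default 80).
#' @param t Sparsification threshold (default 0.2).
#' @param mode `"network"` (edges of each condition's GRN) or
#'   `"differential"` (significance-filtered differential edges).
#' @param divisor Divisor of the differential significance filter.
#' @param paired Resample the same individuals in both conditions
#'   (default `FALSE`: the two cohorts are resampled independently).
#' @param seed Optional integer seed.
#' @return A list with detection-count matrices and stable-edge masks:
#'   in network mode `freq1`, `freq2`, `stable1`, `stable2`; in
#'   differential mode `freq_delta`, `stable_delta`; plus `n_boot`,
#'   `keep_count`, and `failures` (count of bootstrap replicates whose
#'   inference failed, counted as non-detections).
#' @export
bootstrap_stability <- function(data, hp = hyperparams(), n_boot = 100L,
                                keep_count = 80L, t = 0.2,
                                mode = c("network", "differential"),
                                divisor = 5, paired = FALSE, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(data, "paired_dataset"), n_boot >= 1,
            keep_count >= 0)
  if (!is.null(seed)) set.seed(seed)
  p <- data$p
  n <- data$n
  dn <- list(data$genes, data$genes)
  freq1 <- freq2 <- freq_delta <- matrix(0L, p, p, dimnames = dn)
  failures <- 0L

  for (b in seq_len(n_boot)) {
    idx1 <- sample.int(n, n, replace = TRUE)
    idx2 <- if (paired) idx1 else sample.int(n, n, replace = TRUE)
    boot <- data
    boot$Y1 <- data$Y1[idx1, , drop = FALSE]
    boot$X1 <- data$X1[idx1, , drop = FALSE]
    boot$Y2 <- data$Y2[idx2, , drop = FALSE]
    boot$X2 <- data$X2[idx2, , drop = FALSE]
    fit <- tryCatch(infer_all_genes(boot, hp), error = function(e) NULL)
    if (is.null(fit)) {
      failures <- failures + 1L
      next
    }
    B1s <- threshold_network(fit$Bhat1, t)
    B2s <- threshold_network(fit$Bhat2, t)
    if (mode == "network") {
      freq1 <- freq1 + (B1s != 0)
      freq2 <- freq2 + (B2s != 0)
    } else {
      sig <- significant_differential(B1s, B2s, divisor)
      freq_delta <- freq_delta + ((B1s - B2s) != 0 & sig)
    }
  }
  if (failures > 0L)
    warning(failures, " bootstrap replicate(s) failed and were counted ",
            "as non-detections")
  out <- list(n_boot = as.integer(n_boot),
              keep_count = as.integer(keep_count), mode = mode,
              failures = failures)
  if (mode == "network") {
    out$freq1 <- freq1
    out$freq2 <- freq2
    out$stable1 <- freq1 > keep_count
    out$stable2 <- freq2 > keep_count
  } else {
    out$freq_delta <- freq_delta
    out$stable_delta <- freq_delta > keep_count
  }
  out
}
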