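#' Power of detection and false discovery rate of edge recovery
#'
#' Support-based recovery metrics: `PD = |est & truth| / |truth|` (the
#' true-positive rate on edge support) and `FDR = |est \ truth| / |est|`,
#' defined as 0 when no edges are reported.  Signs and magnitudes are
#' ignored.
#'
#' @param estimated,truth Logical matrices of identical dimensions (edge
#'   supports over the same off-diagonal index space), or two-column index
#'   matrices of edge positions.
#' @param dim Matrix dimension `c(p, p)`, required when index matrices are
#'   given.
#' @return A list with `pd`, `fdr`, and the confusion counts `tp`, `fp`,
#'   `fn`.
#' @export
support_metrics <- function(estimated, truth, dim = NULL) {
  estimated <- as_support(estimated, dim)
  truth <- as_support(truth, dim)
  if (!all(dim(estimated) == dim(truth)))
    stop("estimated and truth supports must have identical dimensions")
  n_truth <- sum(truth)
  if (n_truth == 0)
    stop("the true edge set is empty; PD is undefined")
  tp <- sum(estimated & truth)
  fp <- sum(estimated & !truth)
  n_est <- tp + fp
  list(pd = tp / n_truth,
       fdr = if (n_est == 0) 0 else fp / n_est,
       tp = tp, fp = fp, fn = n_truth - tp)
}

as_support <- function(x, dim = NULL) {
  if (is.matrix(x) && is.numeric(x) && ncol(x) == 2L && !is.null(dim)) {
    out <- matrix(FALSE, dim[1L], dim[2L])
    out[x] <- TRUE
    return(out)
  }
  if (is.matrix(x)) return(x != 0)
  stop("unsupported edge-set representation")
}

#' Recovery metrics for a paired fit against simulator ground truth
#'
#' Pools true/false positives over both conditions' off-diagonal entries
#' for the `(B1, B2)` metrics (the pair is scored as a single recovery
#' problem), and scores the differential network by comparing the support
#' of the thresholded difference `|B1_sparse - B2_sparse| > t` against the
#' true set of unequal entries.
#'
#' @param B1_est,B2_est Estimated (unthresholded) network matrices.
#' @param truth A `ground_truth`.
#' @param t Sparsification threshold (default 0.2), applied to the
#'   condition networks and to the differential matrix alike.
#' @return A list with `pd_networks`, `fdr_networks`, `pd_delta`,
#'   `fdr_delta`, and per-condition components `cond1`, `cond2`.
#' @export
paired_network_metrics <- function(B1_est, B2_est, truth, t = 0.2) {
  stopifnot(inherits(truth, "ground_truth"))
  B1s <- threshold_network(B1_est, t)
  B2s <- threshold_network(B2_est, t)
  m1 <- support_metrics(B1s != 0, truth$B1 != 0)
  m2 <- support_metrics(B2s != 0, truth$B2 != 0)
  tp <- m1$tp + m2$tp
  fp <- m1$fp + m2$fp
  n_truth <- sum(truth$B1 != 0) + sum(truth$B2 != 0)
  delta_est <- abs(B1s - B2s) > t
  md <- support_metrics(delta_est, truth$delta_support)
  list(pd_networks = tp / n_truth,
       fdr_networks = if (tp + fp == 0) 0 else fp / (tp + fp),
       pd_delta = md$pd, fdr_delta = md$fdr,
       cond1 = m1, cond2 = m2)
}

#' Replicated simulation study over a grid of setups
#'
#' For every row of the setup grid, simulates `n_replicates` independent
#' paired datasets, runs the full joint inference, and scores recovery of
#' the separate and differential networks.  Per-replicate seeds are
#' derived from the master seed, so the whole table is bit-reproducible.
#'
#' @param setups Data frame of simulation setups with columns `p`, `n`,
#'   `n_e`, `sigma2`, `kind`, `t` (missing columns get defaults
#'   `n_e = 1`, `sigma2 = 0.01`, `kind = "dag"`, `t = 0.2`).
#' @param n_replicates Replicates per setup (default 20).
#' @param hp A `hyperparams`.
#' @param seed Master seed.
#' @return A list with `replicates` (tidy per-replicate data frame:
#'   setup columns + `replicate` + `pd_networks`, `fdr_networks`,
#'   `pd_delta`, `fdr_delta`, `converged`) and `means` (per-setup
#'   averages over the successful replicates; failed replicates are
#'   excluded with their count in `n_failed`).
#' @export
run_replicated_study <- function(setups, n_replicates = 20L,
                                 hp = hyperparams(), seed = NULL) {
  stopifnot(is.data.frame(setups), nrow(setups) >= 1, n_replicates >= 1)
  defaults <- list(n_e = 1, sigma2 = 0.01, kind = "dag", t = 0.2)
  for (nm in names(defaults))
    if (is.null(setups[[nm]])) setups[[nm]] <- defaults[[nm]]
  if (is.null(setups$p) || is.null(setups$n))
    stop("'setups' must provide columns 'p' and 'n'")

  if (!is.null(seed)) set.seed(seed)
  n_setups <- nrow(setups)
  seeds <- matrix(sample.int(.Machine$integer.max, n_setups * n_replicates),
                  n_setups, n_replicates)

  rows <- vector("list", n_setups * n_replicates)
  k <- 0L
  for (s in seq_len(n_setups)) {
    su <- setups[s, ]
    for (r in seq_len(n_replicates)) {
      k <- k + 1L
      rows[[k]] <- tryCatch({
        sim <- simulate_paired_dataset(p = su$p, n = su$n, n_e = su$n_e,
                                       sigma2 = su$sigma2, kind = su$kind,
                                       seed = seeds[s, r])
        fit <- infer_all_genes(sim$data, hp)
        if (length(fit$errors) > 0)
          stop("per-gene inference failures: ",
               paste(names(fit$errors), collapse = ", "))
        m <- paired_network_metrics(fit$Bhat1, fit$Bhat2, sim$truth, su$t)
        data.frame(setup = s, p = su$p, n = su$n, n_e = su$n_e,
                   sigma2 = su$sigma2, kind = su$kind, t = su$t,
                   replicate = r,
                   pd_networks = m$pd_networks,
                   fdr_networks = m$fdr_networks,
                   pd_delta = m$pd_delta, fdr_delta = m$fdr_delta,
                   converged = all(fit$converged),
                   failed = FALSE, stringsAsFactors = FALSE)
      }, error = function(e) {
        warning("replicate ", r, " of setup ", s, " failed: ",
                conditionMessage(e))
        data.frame(setup = s, p = su$p, n = su$n, n_e = su$n_e,
                   sigma2 = su$sigma2, kind = su$kind, t = su$t,
                   replicate = r, pd_networks = NA_real_,
                   fdr_networks = NA_real_, pd_delta = NA_real_,
                   fdr_delta = NA_real_, converged = NA,
                   failed = TRUE, stringsAsFactors = FALSE)
      })
    }
  }
  replicates <- do.call(rbind, rows)

  metric_cols <- c("pd_networks", "fdr_networks", "pd_delta", "fdr_delta")
  means <- do.call(rbind, lapply(split(replicates, replicates$setup),
    function(df) {
      ok <- !df$failed
      out <- df[1L, c("setup", "p", "n", "n_e", "sigma2", "kind", "t")]
      for (mc in metric_cols) out[[mc]] <- mean(df[[mc]][ok])
      out$n_replicates <- sum(ok)
      out$n_failed <- sum(!ok)
      out
    }))
  rownames(means) <- NULL
  list(replicates = replicates, means = means)
}
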