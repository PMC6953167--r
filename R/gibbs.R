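#' Hyperparameters and run settings for the fused Gibbs sampler
#'
#' @param a,b Shape and rate of the Gamma hyperprior on the adaptive
#'   shrinkage rates `psi_{1,j}` and `psi_{2,k}`; the defaults (1, 0.1)
#'   are essentially noninformative.
#' @param nu0,eta0 Hyperparameters of the Inverse-Gamma(nu0/2, eta0/2)
#'   prior on the residual variance.
#' @param n_chains Number of independent chains (>= 2, for convergence
#'   monitoring).
#' @param check_interval Sweeps between convergence checks.
#' @param max_iter Maximum sweeps per chain before giving up.
#' @param post_draws Post-convergence sweeps per chain retained for
#'   posterior summaries.
#' @param rhat_threshold Convergence when the largest potential scale
#'   reduction factor over all monitored scalars falls below this value
#'   (default 1.1).
#' @return An object of class `hyperparams`.
#' @export
hyperparams <- function(a = 1, b = 0.1, nu0 = 1, eta0 = 1,
                        n_chains = 3L, check_interval = 500L,
                        max_iter = 20000L, post_draws = 1000L,
                        rhat_threshold = 1.1) {
  stopifnot(a > 0, b > 0, nu0 > 0, eta0 > 0, n_chains >= 2,
            check_interval >= 2, max_iter >= check_interval,
            post_draws >= 2, rhat_threshold > 1)
  structure(list(a = a, b = b, nu0 = nu0, eta0 = eta0,
                 n_chains = as.integer(n_chains),
                 check_interval = as.integer(check_interval),
                 max_iter = as.integer(max_iter),
                 post_draws = as.integer(post_draws),
                 rhat_threshold = rhat_threshold),
            class = "hyperparams")
}

# clamping bounds for reciprocal scales (keeps the chain numerically
# finite in the strong-shrinkage regime)
.scale_lo <- 1e-10
.scale_hi <- 1e10

#' Precision matrix of the fused prior
#'
#' Builds the `2 p_i x 2 p_i` prior precision of the coefficient vector:
#' diagonal entries `1/tau2_j + 1/omega2_{m(j)}` (where `m(j)` pairs
#' coordinate j with its counterpart in the other condition) and
#' off-diagonal entries `-1/omega2_k` at positions (k, p_i + k), all other
#' entries zero.  Symmetric positive definite for any positive inputs.
#'
#' @param tau2 Positive vector of length `2 p_i` (per-coefficient scales).
#' @param omega2 Positive vector of length `p_i` (per-pair fusion scales).
#' @return The precision matrix.
#' @export
build_sigma_beta_inv <- function(tau2, omega2) {
  p_i <- length(omega2)
  if (length(tau2) != 2L * p_i)
    stop("'tau2' must have length 2 * length(omega2)")
  if (any(tau2 <= 0) || any(omega2 <= 0))
    stop("all scale parameters must be strictly positive")
  inv_om <- 1 / omega2
  M <- diag(1 / tau2 + rep(inv_om, 2), 2L * p_i)
  idx <- cbind(seq_len(p_i), p_i + seq_len(p_i))
  M[idx] <- -inv_om
  M[idx[, 2:1, drop = FALSE]] <- -inv_om
  M
}

# Cholesky with a single jitter retry
chol_jitter <- function(A) {
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(R)) {
    warning("precision matrix factorization failed; retrying with 1e-8 jitter")
    R <- chol(A + diag(1e-8, nrow(A)))
  }
  R
}

#' Draw the coefficient vector from its full conditional
#'
#' Exact multivariate-normal draw from
#' `N(A^{-1} W' y, sigma2 A^{-1})` with `A = W'W + Sigma_beta^{-1}`,
#' via Cholesky factorization (no explicit inverse).
#'
#' @param design A `subproblem`.
#' @param state Current sampler state (list with `sigma2`, `tau2`,
#'   `omega2`).
#' @return New coefficient vector of length `2 p_i`.
#' @export
sample_beta <- function(design, state) {
  WtW <- design$WtW %||% crossprod(design$W)
  Wty <- design$Wty %||% crossprod(design$W, design$y)
  A <- WtW + build_sigma_beta_inv(state$tau2, state$omega2)
  R <- chol_jitter(A)
  m <- backsolve(R, forwardsolve(t(R), Wty))
  z <- stats::rnorm(length(m))
  drop(m + sqrt(state$sigma2) * backsolve(R, z))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Draw the residual variance from its full conditional
#'
#' Inverse-Gamma(nu/2, eta/2) with `nu = n + 2 p_i + nu0 - 1` and
#' `eta = ||y - W beta||^2 + beta' Sigma_beta^{-1} beta + eta0`.
#'
#' @param design A `subproblem`.
#' @param state Current sampler state (uses `beta`, `tau2`, `omega2`).
#' @param hp A `hyperparams`.
#' @return New positive variance draw.
#' @export
sample_sigma2 <- function(design, state, hp) {
  beta <- state$beta
  r <- design$y - design$W %*% beta
  Sinv <- build_sigma_beta_inv(state$tau2, state$omega2)
  nu <- design$n + 2 * design$p_i + hp$nu0 - 1
  eta <- sum(r^2) + drop(crossprod(beta, Sinv %*% beta)) + hp$eta0
  1 / stats::rgamma(1L, shape = nu / 2, rate = eta / 2)
}

#' Inverse-Gaussian random variates
#'
#' Draws from the inverse-Gaussian distribution with mean `mean` and shape
#' `shape` by the chi-square transformation method with a uniform
#' acceptance correction (Michael, Schucany and Haas).
#'
#' @param n Number of draws.
#' @param mean Positive mean parameter (scalar or length-n).
#' @param shape Positive shape parameter (scalar or length-n).
#' @return Vector of strictly positive draws.
#' @export
rinvgauss_msh <- function(n, mean, shape) {
  if (any(mean <= 0) || any(shape <= 0))
    stop("'mean' and 'shape' must be strictly positive")
  mu <- rep_len(mean, n)
  lam <- rep_len(shape, n)
  y <- stats::rnorm(n)^2
  x <- mu + mu^2 * y / (2 * lam) -
    mu / (2 * lam) * sqrt(4 * mu * lam * y + mu^2 * y^2)
  x <- pmax(x, .Machine$double.xmin)
  u <- stats::runif(n)
  ifelse(u <= mu / (mu + x), x, mu^2 / x)
}

#' Draw the local scale parameters from their full conditionals
#'
#' The reciprocals follow inverse-Gaussian conditionals:
#' `1/tau2_j ~ IGauss(sqrt(2 psi1_j sigma2 / beta_j^2), 2 psi1_j)` and
#' `1/omega2_k ~ IGauss(sqrt(2 psi2_k sigma2 / (beta_{p_i+k} - beta_k)^2),
#' 2 psi2_k)`.  When a coefficient (or fused difference) is numerically
#' zero the inverse-Gaussian mean is capped at 1e10, and reciprocal scales
#' are clamped to [1e-10, 1e10], so the strong-shrinkage regime cannot
#' overflow.
#'
#' @param design A `subproblem` (for `p_i`).
#' @param state Current sampler state (uses `beta`, `sigma2`, `psi1`,
#'   `psi2`).
#' @return List with new `tau2` (length `2 p_i`) and `omega2`
#'   (length `p_i`), all strictly positive.
#' @export
sample_scales <- function(design, state) {
  p_i <- design$p_i
  beta <- state$beta
  s2 <- state$sigma2
  mu1 <- pmin(sqrt(2 * state$psi1 * s2) / pmax(abs(beta), 1e-10), .scale_hi)
  inv_tau2 <- rinvgauss_msh(2L * p_i, mu1, 2 * state$psi1)
  d <- beta[p_i + seq_len(p_i)] - beta[seq_len(p_i)]
  mu2 <- pmin(sqrt(2 * state$psi2 * s2) / pmax(abs(d), 1e-10), .scale_hi)
  inv_omega2 <- rinvgauss_msh(p_i, mu2, 2 * state$psi2)
  list(tau2 = 1 / pmin(pmax(inv_tau2, .scale_lo), .scale_hi),
       omega2 = 1 / pmin(pmax(inv_omega2, .scale_lo), .scale_hi))
}

#' Draw the adaptive shrinkage rates from their full conditionals
#'
#' Conjugate Gamma updates under the Gamma(a, b) hyperprior:
#' `psi1_j ~ Gamma(a + 1, rate = b + tau2_j)` and
#' `psi2_k ~ Gamma(a + 1, rate = b + omega2_k)` — one adaptive rate per
#' penalized term.
#'
#' @param design A `subproblem` (for `p_i`).
#' @param state Current sampler state (uses `tau2`, `omega2`).
#' @param hp A `hyperparams`.
#' @return List with new `psi1` (length `2 p_i`) and `psi2`
#'   (length `p_i`).
#' @export
sample_psi <- function(design, state, hp) {
  p_i <- design$p_i
  list(psi1 = stats::rgamma(2L * p_i, shape = hp$a + 1,
                            rate = hp$b + state$tau2),
       psi2 = stats::rgamma(p_i, shape = hp$a + 1,
                            rate = hp$b + state$omega2))
}

# one full Gibbs sweep, in the fixed update order beta, sigma2, scales, psi
gibbs_sweep <- function(design, state, hp) {
  state$beta <- sample_beta(design, state)
  state$sigma2 <- sample_sigma2(design, state, hp)
  sc <- sample_scales(design, state)
  state$tau2 <- sc$tau2
  state$omega2 <- sc$omega2
  ps <- sample_psi(design, state, hp)
  state$psi1 <- ps$psi1
  state$psi2 <- ps$psi2
  state
}

# cache the sufficient statistics once per design
with_design_cache <- function(design) {
  if (is.null(design$WtW)) {
    design$WtW <- crossprod(design$W)
    design$Wty <- drop(crossprod(design$W, design$y))
  }
  design
}

#' Potential scale reduction factor (Gelman-Rubin diagnostic)
#'
#' Classic PSRF `sqrt((m-1)/m + B/(m W))` for `m` draws per chain, where
#' `W` is the mean within-chain variance and `B/m` the variance of the
#' chain means.  Returns exactly 1 when all draws across all chains are
#' identical, and `Inf` when chains are stuck at different constants
#' (zero within-chain, positive between-chain variance).
#'
#' @param chains A list of numeric vectors (one per chain, equal length
#'   >= 4), or a matrix with one column per chain.
#' @return The scalar PSRF.
#' @export
gelman_rubin <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)),
                                          function(j) chains[, j])
  if (length(chains) < 2L)
    stop("at least 2 chains are required for the PSRF")
  m <- lengths(chains)
  if (any(m < 4L)) stop("each chain must have at least 4 draws")
  if (length(unique(m)) != 1L) stop("chains must have equal length")
  m <- m[1L]
  means <- vapply(chains, mean, numeric(1))
  W <- mean(vapply(chains, stats::var, numeric(1)))
  B_over_m <- stats::var(means)
  if (W == 0) return(if (B_over_m == 0) 1 else Inf)
  sqrt((m - 1) / m + B_over_m / W)
}

#' Run the fused Gibbs sampler on one integrated subproblem
#'
#' Runs `n_chains` chains from overdispersed starting points (one at
#' `beta = 0`, the rest at jittered ridge estimates; all scales 1,
#' `sigma2` at the sample variance of the response).  Every
#' `check_interval` sweeps the potential scale reduction factor is computed
#' for every coefficient and for `sigma2` from the second half of the
#' draws so far; once all fall below `rhat_threshold`, each chain
#' contributes `post_draws` further sweeps and those pooled draws form the
#' posterior summaries (means and 95% equal-tailed credible intervals).
#'
#' @param design A `subproblem`; requires `n > 3` (the geometric-ergodicity
#'   regime of this sampler family).
#' @param hp A `hyperparams`.
#' @return An object of class `posterior_samples`: list with `beta`
#'   (pooled draws, rows = draws), `sigma2` (pooled draws), `mean`,
#'   `ci_lower`, `ci_upper` (per coefficient), `sigma2_mean`, `rhat`
#'   (final monitored values), `converged`, `sweeps` (per-chain sweeps
#'   before the posterior stage), `chain` (chain id per pooled row), and
#'   the `design` labels.
#' @export
gibbs_run <- function(design, hp = hyperparams()) {
  stopifnot(inherits(design, "subproblem"), inherits(hp, "hyperparams"))
  if (design$n <= 3)
    stop("the sampler requires n > 3 samples (geometric ergodicity)")
  design <- with_design_cache(design)
  d <- 2L * design$p_i
  nch <- hp$n_chains

  ridge <- drop(solve(design$WtW + diag(d), design$Wty))
  init_beta <- vector("list", nch)
  init_beta[[1L]] <- rep(0, d)
  for (c in seq_len(nch)[-1L])
    init_beta[[c]] <- ridge + stats::rnorm(d, 0, 0.5)
  s2_init <- max(stats::var(design$y), 1e-6)

  states <- lapply(init_beta, function(b0)
    list(beta = b0, sigma2 = s2_init,
         tau2 = rep(1, d), omega2 = rep(1, design$p_i),
         psi1 = rep(1, d), psi2 = rep(1, design$p_i)))

  # monitored history: beta coordinates + sigma2, per chain
  hist <- lapply(seq_len(nch), function(c)
    matrix(NA_real_, hp$max_iter, d + 1L))
  it <- 0L
  converged <- FALSE
  rhat <- rep(NA_real_, d + 1L)
  while (it < hp$max_iter) {
    block <- min(hp$check_interval, hp$max_iter - it)
    for (c in seq_len(nch)) {
      st <- states[[c]]
      H <- hist[[c]]
      for (s in seq_len(block)) {
        st <- gibbs_sweep(design, st, hp)
        H[it + s, ] <- c(st$beta, st$sigma2)
      }
      states[[c]] <- st
      hist[[c]] <- H
    }
    it <- it + block
    keep <- seq.int(floor(it / 2) + 1L, it)   # discard first half as warm-up
    rhat <- vapply(seq_len(d + 1L), function(j)
      gelman_rubin(lapply(hist, function(H) H[keep, j])), numeric(1))
    if (max(rhat) < hp$rhat_threshold) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("Gibbs sampler did not reach R-hat < ", hp$rhat_threshold,
            " within ", hp$max_iter, " sweeps (max R-hat = ",
            signif(max(rhat), 4), ")")

  # posterior stage: post_draws further sweeps per chain
  nd <- hp$post_draws
  beta_draws <- matrix(NA_real_, nch * nd, d)
  sigma2_draws <- numeric(nch * nd)
  chain_id <- integer(nch * nd)
  for (c in seq_len(nch)) {
    st <- states[[c]]
    rows <- (c - 1L) * nd + seq_len(nd)
    for (s in seq_len(nd)) {
      st <- gibbs_sweep(design, st, hp)
      beta_draws[rows[s], ] <- st$beta
      sigma2_draws[rows[s]] <- st$sigma2
    }
    chain_id[rows] <- c
    states[[c]] <- st
  }

  qs <- apply(beta_draws, 2L, stats::quantile, probs = c(0.025, 0.975),
              names = FALSE)
  structure(list(beta = beta_draws, sigma2 = sigma2_draws,
                 mean = colMeans(beta_draws),
                 ci_lower = qs[1L, ], ci_upper = qs[2L, ],
                 sigma2_mean = mean(sigma2_draws),
                 rhat = rhat, converged = converged, sweeps = it,
                 chain = chain_id, labels = design$labels,
                 gene = design$i, p_i = design$p_i),
            class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf("Posterior samples for gene %d: %d pooled draws, %d coefficients, %s (max R-hat %.3f, %d sweeps)\n",
              x$gene, nrow(x$beta), ncol(x$beta),
              if (x$converged) "converged" else "NOT converged",
              max(x$rhat), x$sweeps))
  invisible(x)
}

#' Joint inference of both networks over all genes
#'
#' Runs the fused Gibbs sampler independently on every gene's integrated
#' subproblem and assembles the posterior-mean network matrices for the two
#' conditions (zero diagonals), the eQTL effect estimates, and per-entry
#' 95% equal-tailed credible intervals.  Genes are independent, so results
#' do not depend on execution order; a failure in one gene is recorded and
#' the remaining genes complete.
#'
#' @param data A `paired_dataset`.
#' @param hp A `hyperparams`.
#' @param seed Optional integer seed.
#' @param keep_samples Keep each gene's full `posterior_samples` object
#'   (memory-heavy; default `FALSE`).
#' @return An object of class `grn_fit`: list with `Bhat1`, `Bhat2`
#'   (p x p posterior means), `Fhat1`, `Fhat2` (q x p, nonzero only on the
#'   support), `ci` (list of p x p matrices `lower1`, `upper1`, `lower2`,
#'   `upper2`), `converged` and `max_rhat` per gene, `errors` (named list
#'   of per-gene failures), and optionally `samples`.
#' @export
infer_all_genes <- function(data, hp = hyperparams(), seed = NULL,
                            keep_samples = FALSE) {
  stopifnot(inherits(data, "paired_dataset"))
  if (!is.null(seed)) set.seed(seed)
  p <- data$p
  q <- data$q
  dn <- list(data$genes, data$genes)
  Bhat1 <- Bhat2 <- matrix(0, p, p, dimnames = dn)
  ci <- list(lower1 = matrix(0, p, p, dimnames = dn),
             upper1 = matrix(0, p, p, dimnames = dn),
             lower2 = matrix(0, p, p, dimnames = dn),
             upper2 = matrix(0, p, p, dimnames = dn))
  Fhat1 <- Fhat2 <- matrix(0, q, p, dimnames = list(data$eqtls, data$genes))
  converged <- rep(NA, p)
  max_rhat <- rep(NA_real_, p)
  errors <- list()
  samples <- if (keep_samples) vector("list", p) else NULL

  for (i in seq_len(p)) {
    res <- tryCatch({
      design <- build_subproblem(data, i)
      ps <- gibbs_run(design, hp)
      est <- extract_network_column(ps$mean, design)
      lo <- extract_network_column(ps$ci_lower, design)
      hi <- extract_network_column(ps$ci_upper, design)
      Bhat1 <- insert_gene_column(Bhat1, i, est$b1)
      Bhat2 <- insert_gene_column(Bhat2, i, est$b2)
      ci$lower1 <- insert_gene_column(ci$lower1, i, lo$b1)
      ci$upper1 <- insert_gene_column(ci$upper1, i, hi$b1)
      ci$lower2 <- insert_gene_column(ci$lower2, i, lo$b2)
      ci$upper2 <- insert_gene_column(ci$upper2, i, hi$b2)
      S <- data$supports[[i]]
      Fhat1[S, i] <- est$f1
      Fhat2[S, i] <- est$f2
      converged[i] <- ps$converged
      max_rhat[i] <- max(ps$rhat)
      if (keep_samples) samples[[i]] <- ps
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) errors[[data$genes[i]]] <- res
  }
  if (length(errors))
    warning("inference failed for ", length(errors), " gene(s): ",
            paste(names(errors), collapse = ", "))
  structure(list(Bhat1 = Bhat1, Bhat2 = Bhat2, Fhat1 = Fhat1, Fhat2 = Fhat2,
                 ci = ci, converged = converged, max_rhat = max_rhat,
                 errors = errors, samples = samples, genes = data$genes),
            class = "grn_fit")
}

#' @export
print.grn_fit <- function(x, ...) {
  cat(sprintf("Joint GRN fit: %d genes, %d/%d converged, %d failed\n",
              length(x$genes), sum(x$converged, na.rm = TRUE),
              length(x$genes), length(x$errors)))
  invisible(x)
}

#' Export pooled posterior draws to a long-format table
#'
#' @param ps A `posterior_samples` object.
#' @return A data frame with columns `iteration`, `chain`, `parameter`,
#'   `value` suitable for external MCMC diagnostics.
#' @export
samples_to_table <- function(ps) {
  stopifnot(inherits(ps, "posterior_samples"))
  d <- ncol(ps$beta)
  nm <- c(paste0("beta", seq_len(d)), "sigma2")
  vals <- cbind(ps$beta, ps$sigma2)
  per_chain_iter <- ave(seq_along(ps$chain), ps$chain, FUN = seq_along)
  data.frame(iteration = rep(per_chain_iter, times = d + 1L),
             chain = rep(ps$chain, times = d + 1L),
             parameter = rep(nm, each = nrow(vals)),
             value = as.vector(vals))
}
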