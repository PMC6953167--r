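# Shared fixtures, all built in code.

# a fixed small integrated design with a known coefficient vector:
# W is n x 2*p_i, y = W beta + noise
make_toy_design <- function(n = 50, p_i = 4, beta = NULL, sigma = 0.1,
                            seed = 100) {
  set.seed(seed)
  d <- 2L * p_i
  if (is.null(beta)) beta <- c(0.8, -0.6, 0, 0, 0.8, -0.6, 0, 0.7)[seq_len(d)]
  W <- matrix(rnorm(n * d), n, d)
  y <- drop(W %*% beta + rnorm(n, 0, sigma))
  structure(list(y = y, W = W, i = 1L, p_i = as.integer(p_i),
                 q_i = 1L, n = as.integer(n), labels = NULL,
                 beta_true = beta),
            class = "subproblem")
}

# a valid sampler state for a given design
make_state <- function(design, beta = NULL, sigma2 = 1) {
  d <- 2L * design$p_i
  list(beta = if (is.null(beta)) rep(0.5, d) else beta,
       sigma2 = sigma2,
       tau2 = rep(1, d), omega2 = rep(1, design$p_i),
       psi1 = rep(1, d), psi2 = rep(1, design$p_i))
}

edge_set <- function(B) which(B != 0, arr.ind = TRUE)
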