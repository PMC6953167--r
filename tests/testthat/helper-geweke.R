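# Joint-distribution validation machinery for the Gibbs sampler
# ("getting it right"): two simulators whose stationary distribution must
# agree — independent draws from the generative model followed by one
# transition, versus a long chain alternating parameter updates with
# data re-draws.

draw_prior_state <- function(design, hp) {
  d <- 2L * design$p_i
  psi1 <- rgamma(d, shape = hp$a, rate = hp$b)
  psi2 <- rgamma(design$p_i, shape = hp$a, rate = hp$b)
  tau2 <- rexp(d, rate = psi1)
  omega2 <- rexp(design$p_i, rate = psi2)
  sigma2 <- 1 / rgamma(1, shape = hp$nu0 / 2, rate = hp$eta0 / 2)
  Sinv <- build_sigma_beta_inv(tau2, omega2)
  R <- chol(Sinv)
  beta <- drop(backsolve(R, rnorm(d))) * sqrt(sigma2)
  list(beta = beta, sigma2 = sigma2, tau2 = tau2, omega2 = omega2,
       psi1 = psi1, psi2 = psi2)
}

draw_data <- function(design, state) {
  y <- drop(design$W %*% state$beta) +
    rnorm(design$n, 0, sqrt(state$sigma2))
  design$y <- y
  design$Wty <- drop(crossprod(design$W, y))
  design
}

record_state <- function(state) {
  c(beta1 = state$beta[1L], sigma2 = state$sigma2,
    tau2_1 = state$tau2[1L], omega2_1 = state$omega2[1L])
}

# independent joint draws: prior -> data -> one Gibbs transition
marginal_conditional_sim <- function(design, hp, n_draws) {
  out <- matrix(NA_real_, n_draws, 4L)
  for (i in seq_len(n_draws)) {
    st <- draw_prior_state(design, hp)
    de <- draw_data(design, st)
    st <- fusedgrn:::gibbs_sweep(de, st, hp)
    out[i, ] <- record_state(st)
  }
  colnames(out) <- c("beta1", "sigma2", "tau2_1", "omega2_1")
  out
}

# long chain alternating parameter transition and data re-draw
successive_conditional_sim <- function(design, hp, n_draws, thin = 10L) {
  st <- draw_prior_state(design, hp)
  de <- draw_data(design, st)
  out <- matrix(NA_real_, n_draws, 4L)
  for (i in seq_len(n_draws * thin)) {
    st <- fusedgrn:::gibbs_sweep(de, st, hp)
    de <- draw_data(de, st)
    if (i %% thin == 0L) out[i %/% thin, ] <- record_state(st)
  }
  colnames(out) <- c("beta1", "sigma2", "tau2_1", "omega2_1")
  out
}
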