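#' Split one condition's SEM at a single gene
#'
#' For gene `i` under condition `k`, returns the pieces of the per-gene
#' regression `y_i = Y_{-i} b_i + X_{S_i} f_i + e_i`: the i-th expression
#' column, the expression matrix with column i removed (original gene order
#' preserved), and the genotype columns of gene i's cis-eQTL support set.
#'
#' @param data A `paired_dataset`.
#' @param i Gene index (1..p).
#' @param k Condition (1 or 2).
#' @return A list with `y` (n-vector), `Y_minus` (n x (p-1)), `X_S`
#'   (n x q_i).
#' @export
split_gene <- function(data, i, k) {
  stopifnot(inherits(data, "paired_dataset"))
  if (!(k %in% c(1, 2))) stop("'k' must be 1 or 2")
  if (!is.numeric(i) || length(i) != 1L || i < 1 || i > data$p)
    stop("gene index 'i' must be in 1..", data$p)
  i <- as.integer(i)
  S <- data$supports[[i]]
  if (length(S) == 0)
    stop("gene ", data$genes[i], " has no cis-eQTL support; ",
         "at least one unique cis-eQTL per gene is required for ",
         "identifiability")
  Y <- if (k == 1) data$Y1 else data$Y2
  X <- if (k == 1) data$X1 else data$X2
  list(y = Y[, i],
       Y_minus = Y[, -i, drop = FALSE],
       X_S = X[, S, drop = FALSE])
}

#' Build the integrated per-gene regression design
#'
#' Re-parameterizes the two per-gene regressions into one linear model:
#' the response is the elementwise sum `y_i = y_i^(1) + y_i^(2)` and the
#' design is the horizontal concatenation `W_i = [W_i^(1), W_i^(2)]` with
#' `W_i^(k) = [Y_{-i}^(k), X_{S_i}^(k)]`.  The coefficient vector is
#' `beta_i = [beta_i^(1); beta_i^(2)]` of length `2 p_i`,
#' `p_i = p - 1 + q_i`, and the fused differences are
#' `beta_{p_i + k} - beta_k` for k = 1..p_i.
#'
#' @param data A `paired_dataset` with equal per-condition sample sizes.
#' @param i Gene index.
#' @return An object of class `subproblem`: list with `y`, `W`, `i`,
#'   `p_i`, `q_i`, `n`, and `labels` — a data frame with one row per
#'   column of `W` giving (condition, type, name) where type is `"gene"`
#'   or `"eqtl"`.
#' @export
build_subproblem <- function(data, i) {
  stopifnot(inherits(data, "paired_dataset"))
  if (nrow(data$Y1) != nrow(data$Y2))
    stop("paired sample size violated: the integrated model requires the ",
         "same number of samples under both conditions")
  s1 <- split_gene(data, i, 1)
  s2 <- split_gene(data, i, 2)
  q_i <- ncol(s1$X_S)
  p_i <- data$p - 1L + q_i
  W <- cbind(s1$Y_minus, s1$X_S, s2$Y_minus, s2$X_S)
  per_cond <- data.frame(
    type = c(rep("gene", data$p - 1L), rep("eqtl", q_i)),
    name = c(data$genes[-i], data$eqtls[data$supports[[i]]]),
    stringsAsFactors = FALSE)
  labels <- rbind(cbind(condition = 1L, per_cond),
                  cbind(condition = 2L, per_cond))
  colnames(W) <- paste0("c", labels$condition, ":", labels$name)
  structure(list(y = unname(s1$y + s2$y), W = W, i = as.integer(i),
                 p_i = p_i, q_i = q_i, n = nrow(W), labels = labels),
            class = "subproblem")
}

#' @export
print.subproblem <- function(x, ...) {
  cat(sprintf("Integrated subproblem for gene %d: n = %d, p_i = %d (q_i = %d), %d coefficients\n",
              x$i, x$n, x$p_i, x$q_i, 2L * x$p_i))
  invisible(x)
}

#' Unpack an integrated coefficient vector
#'
#' Inverse of the packing used by [build_subproblem()]: splits a `2 p_i`
#' coefficient vector into the per-condition network coefficients
#' (length p-1, named by source gene) and eQTL effects (length q_i).
#'
#' @param beta Numeric vector of length `2 p_i`.
#' @param design The `subproblem` the vector belongs to.
#' @return A list with `b1`, `b2` (named (p-1)-vectors), `f1`, `f2`
#'   (named q_i-vectors).
#' @export
extract_network_column <- function(beta, design) {
  stopifnot(inherits(design, "subproblem"))
  p_i <- design$p_i
  if (length(beta) != 2L * p_i)
    stop("'beta' must have length 2 * p_i = ", 2L * p_i)
  lab <- design$labels
  gene_idx <- which(lab$type == "gene" & lab$condition == 1L)
  eqtl_idx <- which(lab$type == "eqtl" & lab$condition == 1L)
  nm_g <- lab$name[gene_idx]
  nm_e <- lab$name[eqtl_idx]
  list(b1 = stats::setNames(beta[gene_idx], nm_g),
       b2 = stats::setNames(beta[gene_idx + p_i], nm_g),
       f1 = stats::setNames(beta[eqtl_idx], nm_e),
       f2 = stats::setNames(beta[eqtl_idx + p_i], nm_e))
}

# reinsert the structural zero at the diagonal when writing the inferred
# regulators of gene i into column i of a p x p matrix
insert_gene_column <- function(B, i, b) {
  p <- nrow(B)
  stopifnot(length(b) == p - 1L)
  B[-i, i] <- b
  B[i, i] <- 0
  B
}

# true integrated coefficient vector for gene i, assembled from ground
# truth (used by tests and the noiseless-identity checks)
true_beta <- function(truth, data, i) {
  S <- data$supports[[i]]
  c(truth$B1[-i, i], truth$F$effects[S, i],
    truth$B2[-i, i], truth$F$effects[S, i])
}
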