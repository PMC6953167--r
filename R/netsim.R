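#' Generate a random GRN adjacency matrix
#'
#' Draws the directed topology of a gene regulatory network with `p` genes
#' and (on average) `n_e` outgoing edges per node.  Two topology classes are
#' supported: directed acyclic graphs (`"dag"`), generated by placing edges
#' in the strict upper triangle induced by a uniformly random node
#' permutation, and directed cyclic graphs (`"dcg"`), generated by placing
#' edges uniformly off-diagonal and regenerating until at least one directed
#' cycle is present.
#'
#' @param p Number of genes (nodes); at least 2.
#' @param n_e Average number of edges per node; the total edge count is
#'   `round(n_e * p)` (capped at the number of available positions for a
#'   DAG).
#' @param kind `"dag"` or `"dcg"`.
#' @return An object of class `grn_adjacency`: a list with elements
#'   `entries` (p x p binary matrix, zero diagonal), `p`, `kind`, and for
#'   DAGs `topo_order` (a node ordering under which the matrix is strictly
#'   upper triangular).
#' @examples
#' set.seed(1)
#' A <- generate_adjacency(10, n_e = 1, kind = "dag")
#' sum(A$entries)
#' @export
generate_adjacency <- function(p, n_e, kind = c("dag", "dcg")) {
  kind <- match.arg(kind)
  if (!is.numeric(p) || length(p) != 1L || p < 2)
    stop("'p' must be a single integer >= 2")
  if (!is.numeric(n_e) || length(n_e) != 1L || n_e < 1)
    stop("'n_e' must be a single number >= 1")
  p <- as.integer(p)
  m <- as.integer(round(n_e * p))
  if (m > p * (p - 1L))
    stop("requested edge count ", m, " exceeds the ", p * (p - 1L),
         " available off-diagonal positions")

  if (kind == "dag") {
    # cap at the number of strict-upper-triangle cells; for p = 2 only one
    # acyclic position exists
    m <- min(m, (p * (p - 1L)) %/% 2L)
    ord <- sample.int(p)
    A_perm <- matrix(0L, p, p)
    cells <- which(upper.tri(A_perm))
    A_perm[if (length(cells) == m) cells else sample(cells, m)] <- 1L
    A <- matrix(0L, p, p)
    A[ord, ord] <- A_perm
    out <- list(entries = A, p = p, kind = kind, topo_order = ord)
  } else {
    off <- which(diag(p) == 0)
    for (try in seq_len(1000L)) {
      A <- matrix(0L, p, p)
      A[if (length(off) == m) off else sample(off, m)] <- 1L
      if (!is_acyclic(A)) break
      if (try == 1000L)
        stop("failed to generate a cyclic topology in 1000 attempts; ",
             "increase 'n_e'")
    }
    out <- list(entries = A, p = p, kind = kind, topo_order = NULL)
  }
  structure(out, class = "grn_adjacency")
}

#' @export
print.grn_adjacency <- function(x, ...) {
  cat(sprintf("GRN adjacency (%s): %d genes, %d edges\n",
              toupper(x$kind), x$p, sum(x$entries)))
  invisible(x)
}

# acyclicity via topological sortability
is_acyclic <- function(A) {
  g <- igraph::graph_from_adjacency_matrix(A != 0, mode = "directed")
  igraph::is_dag(g)
}

topological_order <- function(A) {
  g <- igraph::graph_from_adjacency_matrix(A != 0, mode = "directed")
  as.integer(igraph::topo_sort(g, mode = "out"))
}

#' Perturb an adjacency matrix into a second-condition topology
#'
#' Rewires a fraction of the edges of `A1` to produce the condition-2
#' topology `A2`: `n_d` entries change state, where `n_d` is
#' `change_fraction * nnz(A1)` rounded to the nearest even integer with a
#' floor of 2, so that the number of deletions (`1 -> 0`) equals the number
#' of insertions (`0 -> 1`), each being `n_c = n_d / 2`.  The total edge
#' count is conserved.  For DAGs, insertions are restricted to positions
#' consistent with a topological order of `A1`, so `A2` remains acyclic.
#'
#' @param A1 A `grn_adjacency`.
#' @param change_fraction Proportion of edges to rewire (default 0.10).
#'   Zero returns `A1` unchanged.
#' @return A list with elements `A2` (a `grn_adjacency`), `removed` and
#'   `added` (two-column index matrices of the flipped cells).
#' @export
perturb_adjacency <- function(A1, change_fraction = 0.10) {
  stopifnot(inherits(A1, "grn_adjacency"))
  nnz <- sum(A1$entries)
  if (change_fraction < 0) stop("'change_fraction' must be >= 0")
  empty <- matrix(integer(0), 0L, 2L,
                  dimnames = list(NULL, c("row", "col")))
  if (change_fraction == 0)
    return(list(A2 = A1, removed = empty, added = empty))
  if (nnz < 2L) stop("'A1' must have at least 2 edges to perturb")

  n_d <- max(2L, 2L * as.integer(round(change_fraction * nnz / 2)))
  n_c <- n_d %/% 2L

  p <- A1$p
  A <- A1$entries
  edge_cells <- which(A == 1L)
  removed_cells <- if (length(edge_cells) == n_c) edge_cells else
    sample(edge_cells, n_c)

  if (A1$kind == "dag") {
    ord <- if (is.null(A1$topo_order)) topological_order(A) else A1$topo_order
    pos <- integer(p)
    pos[ord] <- seq_len(p)
    rows <- row(A); cols <- col(A)
    legal <- A == 0L & rows != cols & pos[rows] < pos[cols]
  } else {
    legal <- A == 0L & row(A) != col(A)
  }
  legal_cells <- which(legal)
  if (length(legal_cells) < n_c)
    stop("cannot place ", n_c, " new edges: only ", length(legal_cells),
         " legal positions remain")
  added_cells <- if (length(legal_cells) == n_c) legal_cells else
    sample(legal_cells, n_c)

  A2 <- A
  A2[removed_cells] <- 0L
  A2[added_cells] <- 1L
  A2 <- structure(list(entries = A2, p = p, kind = A1$kind,
                       topo_order = A1$topo_order),
                  class = "grn_adjacency")
  list(A2 = A2,
       removed = cell_index(removed_cells, p),
       added = cell_index(added_cells, p))
}

cell_index <- function(cells, p) {
  out <- cbind(row = (cells - 1L) %% p + 1L,
               col = (cells - 1L) %/% p + 1L)
  out[order(cells), , drop = FALSE]
}

# one weight draw per requested entry: sign +/-1 equiprobable, magnitude
# Uniform(0.5, 1)
draw_weights <- function(k) {
  sample(c(-1, 1), k, replace = TRUE) * stats::runif(k, 0.5, 1)
}

#' Assign regulatory weights to an adjacency matrix
#'
#' Each edge receives an independent weight uniform on
#' \eqn{(-1,-0.5)\cup(0.5,1)}; non-edges stay exactly zero.
#'
#' @param A A `grn_adjacency`.
#' @return A p x p numeric weight matrix with the same support as `A`.
#' @export
weights_from_adjacency <- function(A) {
  stopifnot(inherits(A, "grn_adjacency"))
  B <- matrix(0, A$p, A$p)
  nz <- which(A$entries == 1L)
  B[nz] <- draw_weights(length(nz))
  B
}

#' Derive condition-2 weights from the perturbed topology
#'
#' Entries absent from `A2` are zero; edges new in `A2` get fresh weight
#' draws; among the edges shared with condition 1, `n_c` randomly selected
#' entries are re-drawn and all the rest copy their condition-1 weights
#' exactly, so that the differential network contains both rewired and
#' re-weighted edges.
#'
#' @param A2 The perturbed `grn_adjacency`.
#' @param B1 Condition-1 weight matrix; its nonzero support is the
#'   condition-1 topology.
#' @param n_c Number of shared edges to re-weight.
#' @return A list with `B2` (p x p weight matrix) and `reweighted`
#'   (two-column index matrix of the shared edges whose weights were
#'   re-drawn).
#' @export
derive_condition2_weights <- function(A2, B1, n_c) {
  stopifnot(inherits(A2, "grn_adjacency"))
  p <- A2$p
  stopifnot(all(dim(B1) == c(p, p)))
  shared <- which(A2$entries == 1L & B1 != 0)
  new_edges <- which(A2$entries == 1L & B1 == 0)
  if (n_c > length(shared))
    stop("'n_c' (", n_c, ") exceeds the number of shared edges (",
         length(shared), ")")
  B2 <- matrix(0, p, p)
  B2[shared] <- B1[shared]
  B2[new_edges] <- draw_weights(length(new_edges))
  rw <- if (n_c > 0) {
    rw_cells <- if (length(shared) == n_c) shared else sample(shared, n_c)
    B2[rw_cells] <- draw_weights(n_c)
    cell_index(rw_cells, p)
  } else cell_index(integer(0), p)
  list(B2 = B2, reweighted = rw)
}

#' Simulate F2-cross genotypes
#'
#' Independent genotype codes drawn from \{1, 2, 3\} (the two homozygotes
#' and the heterozygote of an F2 intercross) with probabilities
#' (0.25, 0.5, 0.25).
#'
#' @param n Number of individuals (rows).
#' @param q Number of cis-eQTL loci (columns).
#' @return An n x q numeric matrix with entries in \{1, 2, 3\}.
#' @export
simulate_genotypes <- function(n, q) {
  stopifnot(n >= 1, q >= 1)
  matrix(sample(c(1, 2, 3), n * q, replace = TRUE,
                prob = c(0.25, 0.5, 0.25)), n, q)
}

#' Build the cis-eQTL effect map
#'
#' The eQTL effect matrix F is a row permutation of the stacked pair of
#' p-dimensional identity matrices, so q = 2p, every eQTL feeds exactly one
#' gene with unit effect, and every gene has exactly two cis-eQTLs.  The
#' same map is used for both conditions.
#'
#' @param p Number of genes.
#' @return An object of class `eqtl_map`: list with `effects` (q x p 0/1
#'   matrix), `supports` (per-gene integer index sets into the eQTL rows),
#'   `q`.
#' @export
build_eqtl_effects <- function(p) {
  stopifnot(p >= 1)
  q <- 2L * p
  F0 <- rbind(diag(p), diag(p))
  Fm <- F0[sample.int(q), , drop = FALSE]
  supports <- lapply(seq_len(p), function(i) which(Fm[, i] != 0))
  structure(list(effects = Fm, supports = supports, q = q),
            class = "eqtl_map")
}

#' Simulate expression data from the structural equation model
#'
#' Solves the SEM `Y = Y B + X F + E` for the observed expression matrix:
#' `Y = (X F + E) (I - B)^{-1}`, with i.i.d. Gaussian noise
#' `E ~ N(0, sigma2)`.
#'
#' @param B p x p weight matrix (zero diagonal).
#' @param Fmap An `eqtl_map` (or a bare q x p effect matrix).
#' @param X n x q genotype matrix.
#' @param sigma2 Noise variance (>= 0).
#' @param E Optional pre-drawn n x p noise matrix (for exact identity
#'   checks); drawn internally when `NULL`.
#' @return The n x p expression matrix `Y`, with the realized noise matrix
#'   attached as attribute `"noise"`.
#' @export
simulate_expression <- function(B, Fmap, X, sigma2, E = NULL) {
  Fm <- if (inherits(Fmap, "eqtl_map")) Fmap$effects else Fmap
  p <- ncol(B)
  n <- nrow(X)
  stopifnot(nrow(B) == p, ncol(Fm) == p, nrow(Fm) == ncol(X), sigma2 >= 0)
  if (is.null(E))
    E <- matrix(stats::rnorm(n * p, 0, sqrt(sigma2)), n, p)
  ImB <- diag(p) - B
  if (rcond(ImB) < .Machine$double.eps * 100)
    stop("(I - B) is numerically singular; cannot solve the SEM")
  Y <- (X %*% Fm + E) %*% solve(ImB)
  attr(Y, "noise") <- E
  Y
}

#' Simulate a paired two-condition dataset with full ground truth
#'
#' Orchestrates the whole generation recipe: a condition-1 topology, a
#' rewired condition-2 topology conserving edge count, weights uniform on
#' \eqn{(-1,-0.5)\cup(0.5,1)} with `n_c` shared edges re-weighted, a shared
#' eQTL map with two unit-effect cis-eQTLs per gene (q = 2p), independent
#' F2-cross genotype cohorts for the two conditions, and expression via the
#' SEM with Gaussian noise.  Weight matrices are re-drawn if `I - B` is
#' ill-conditioned (condition number above `cond_cap`), which can occur for
#' cyclic topologies.
#'
#' @param p Number of genes.
#' @param n Per-condition sample size (identical across conditions).
#' @param n_e Average edges per node (default 1).
#' @param sigma2 Noise variance (default 0.01).
#' @param kind `"dag"` or `"dcg"`.
#' @param change_fraction Fraction of edges rewired between conditions
#'   (default 0.10).
#' @param cond_cap Condition-number cap for `I - B` (default 1e8).
#' @param seed Optional integer seed for full reproducibility.
#' @return A list with `data` (a `paired_dataset`: `Y1`, `Y2` n x p;
#'   `X1`, `X2` n x q; `supports`; labels) and `truth` (a `ground_truth`:
#'   `B1`, `B2`, `F`, logical `delta_support`, `sigma2`, and a generation
#'   `log` with the removed/added/re-weighted cells and noise matrices).
#' @examples
#' sim <- simulate_paired_dataset(p = 6, n = 30, seed = 1)
#' dim(sim$data$Y1)
#' sum(sim$truth$delta_support)
#' @export
simulate_paired_dataset <- function(p, n, n_e = 1, sigma2 = 0.01,
                                    kind = c("dag", "dcg"),
                                    change_fraction = 0.10,
                                    cond_cap = 1e8, seed = NULL) {
  kind <- match.arg(kind)
  if (!is.null(seed)) set.seed(seed)

  A1 <- generate_adjacency(p, n_e, kind)
  pert <- perturb_adjacency(A1, change_fraction)
  A2 <- pert$A2
  n_c <- nrow(pert$added)

  for (try in seq_len(100L)) {
    B1 <- weights_from_adjacency(A1)
    d2 <- derive_condition2_weights(A2, B1, n_c)
    B2 <- d2$B2
    if (kappa(diag(p) - B1, exact = TRUE) <= cond_cap &&
        kappa(diag(p) - B2, exact = TRUE) <= cond_cap) break
    if (try == 100L)
      stop("could not draw weights with well-conditioned (I - B) ",
           "in 100 attempts")
  }

  Fmap <- build_eqtl_effects(p)
  q <- Fmap$q
  X1 <- simulate_genotypes(n, q)
  X2 <- simulate_genotypes(n, q)
  Y1 <- simulate_expression(B1, Fmap, X1, sigma2)
  Y2 <- simulate_expression(B2, Fmap, X2, sigma2)
  E1 <- attr(Y1, "noise"); attr(Y1, "noise") <- NULL
  E2 <- attr(Y2, "noise"); attr(Y2, "noise") <- NULL

  genes <- sprintf("G%02d", seq_len(p))
  eqtls <- sprintf("E%03d", seq_len(q))
  samples1 <- sprintf("S1_%03d", seq_len(n))
  samples2 <- sprintf("S2_%03d", seq_len(n))
  dimnames(Y1) <- list(samples1, genes)
  dimnames(Y2) <- list(samples2, genes)
  dimnames(X1) <- list(samples1, eqtls)
  dimnames(X2) <- list(samples2, eqtls)
  dimnames(B1) <- dimnames(B2) <- list(genes, genes)
  dimnames(Fmap$effects) <- list(eqtls, genes)
  supports <- stats::setNames(Fmap$supports, genes)

  data <- structure(list(Y1 = Y1, Y2 = Y2, X1 = X1, X2 = X2,
                         supports = supports, n = n, p = p, q = q,
                         genes = genes, eqtls = eqtls),
                    class = "paired_dataset")
  truth <- structure(list(B1 = B1, B2 = B2, F = Fmap,
                          delta_support = B1 != B2, sigma2 = sigma2,
                          log = list(kind = kind, n_e = n_e,
                                     change_fraction = change_fraction,
                                     removed = pert$removed,
                                     added = pert$added,
                                     reweighted = d2$reweighted,
                                     E1 = E1, E2 = E2)),
                     class = "ground_truth")
  list(data = data, truth = truth)
}

#' @export
print.paired_dataset <- function(x, ...) {
  cat(sprintf("Paired expression/genotype dataset: %d genes, %d eQTLs, %d samples per condition\n",
              x$p, x$q, x$n))
  invisible(x)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("Ground truth: %d + %d edges, %d differential entries, sigma2 = %g\n",
              sum(x$B1 != 0), sum(x$B2 != 0), sum(x$delta_support), x$sigma2))
  invisible(x)
}
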