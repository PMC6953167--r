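#' Read a labeled numeric matrix from delimited text
#'
#' Expects a header row of variable labels and a first column of sample
#' labels; the delimiter is sniffed from the extension (`.csv` comma,
#' anything else tab).  Row order is preserved; labels must be unique and
#' every cell numeric.
#'
#' @param path File path.
#' @return A numeric matrix with row and column names.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("matrix file must have a label column and at ",
                          "least one data column: ", path)
  labels <- as.character(df[[1L]])
  if (anyDuplicated(labels))
    stop("duplicate row labels in ", path, ": ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  if (anyDuplicated(colnames(df)[-1L]))
    stop("duplicate column labels in ", path)
  vals <- df[, -1L, drop = FALSE]
  bad <- which(!vapply(vals, is.numeric, logical(1)))
  if (length(bad))
    stop("non-numeric values in column(s) ",
         paste(colnames(vals)[bad], collapse = ", "), " of ", path)
  m <- as.matrix(vals)
  rownames(m) <- labels
  m
}

#' Write a labeled numeric matrix to delimited text
#'
#' Counterpart of [read_matrix()]; the delimiter follows the extension.
#'
#' @param m Matrix with dimnames.
#' @param path Destination path.
#' @param label_header Header of the sample-label column (default
#'   `"sample"`).
#' @export
write_matrix <- function(m, path, label_header = "sample") {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- label_header
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-to-eQTL support map
#'
#' JSON object `{gene_label: [eqtl_labels, ...]}`; every gene must appear
#' with at least one eQTL, and all labels are validated against the
#' expression and genotype matrix headers.
#'
#' @param path JSON file path.
#' @param genes Character vector of gene labels (expression columns).
#' @param eqtls Character vector of eQTL labels (genotype columns).
#' @return A named list of integer column indices into the genotype
#'   matrix, one entry per gene in `genes` order.
#' @export
read_supports <- function(path, genes, eqtls) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  missing <- setdiff(genes, names(raw))
  if (length(missing))
    stop("support map lacks gene(s): ", paste(missing, collapse = ", "))
  supports <- lapply(genes, function(g) {
    labs <- as.character(raw[[g]])
    if (length(labs) == 0)
      stop("gene ", g, " has an empty cis-eQTL support; at least one ",
           "unique cis-eQTL per gene is required for identifiability")
    idx <- match(labs, eqtls)
    if (anyNA(idx))
      stop("support of gene ", g, " names eQTL(s) absent from the ",
           "genotype matrix: ", paste(labs[is.na(idx)], collapse = ", "))
    idx
  })
  stats::setNames(supports, genes)
}

#' Write a support map to JSON
#'
#' @param supports Named list of integer eQTL indices per gene.
#' @param eqtls Character vector of eQTL labels.
#' @param path Destination path.
#' @export
write_supports <- function(supports, eqtls, path) {
  obj <- lapply(supports, function(idx) eqtls[idx])
  jsonlite::write_json(obj, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' Assemble a paired dataset from matrices on disk
#'
#' Labels (not positions) are the join key: the two expression matrices
#' must share an identical gene label set, the two genotype matrices an
#' identical eQTL label set, and the support map must resolve against
#' them.  Per-condition sample sizes must be equal.
#'
#' @param y1,y2 Paths to the condition-1/2 expression matrices (samples x
#'   genes).
#' @param x1,x2 Paths to the genotype matrices (samples x eQTLs).
#' @param supports Path to the JSON support map.
#' @return A `paired_dataset`.
#' @export
read_paired_dataset <- function(y1, y2, x1, x2, supports) {
  Y1 <- read_matrix(y1); Y2 <- read_matrix(y2)
  X1 <- read_matrix(x1); X2 <- read_matrix(x2)
  if (!identical(colnames(Y1), colnames(Y2)))
    stop("gene labels of the two expression matrices differ")
  if (!identical(colnames(X1), colnames(X2)))
    stop("eQTL labels of the two genotype matrices differ")
  if (nrow(Y1) != nrow(X1) || nrow(Y2) != nrow(X2))
    stop("expression and genotype matrices disagree on sample count")
  if (nrow(Y1) != nrow(Y2))
    stop("paired sample size violated: both conditions must have the ",
         "same number of samples")
  genes <- colnames(Y1)
  eqtls <- colnames(X1)
  sup <- read_supports(supports, genes, eqtls)
  structure(list(Y1 = Y1, Y2 = Y2, X1 = X1, X2 = X2, supports = sup,
                 n = nrow(Y1), p = length(genes), q = length(eqtls),
                 genes = genes, eqtls = eqtls),
            class = "paired_dataset")
}

#' Write a simulated paired dataset (and its ground truth) to a directory
#'
#' Produces `Y1.tsv`, `Y2.tsv`, `X1.tsv`, `X2.tsv`, `supports.json`, and,
#' when `truth` is given, `truth_edges.tsv` (source, target,
#' weight_cond1, weight_cond2 for every edge present in either condition).
#'
#' @param data A `paired_dataset`.
#' @param dir Output directory (created if needed).
#' @param truth Optional `ground_truth`.
#' @return The directory path, invisibly.
#' @export
write_paired_dataset <- function(data, dir, truth = NULL) {
  stopifnot(inherits(data, "paired_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix(data$Y1, file.path(dir, "Y1.tsv"))
  write_matrix(data$Y2, file.path(dir, "Y2.tsv"))
  write_matrix(data$X1, file.path(dir, "X1.tsv"))
  write_matrix(data$X2, file.path(dir, "X2.tsv"))
  write_supports(data$supports, data$eqtls, file.path(dir, "supports.json"))
  if (!is.null(truth)) {
    stopifnot(inherits(truth, "ground_truth"))
    nz <- which(truth$B1 != 0 | truth$B2 != 0, arr.ind = TRUE)
    edges <- data.frame(source = data$genes[nz[, 1L]],
                        target = data$genes[nz[, 2L]],
                        weight_cond1 = truth$B1[nz],
                        weight_cond2 = truth$B2[nz],
                        stringsAsFactors = FALSE)
    utils::write.table(edges, file.path(dir, "truth_edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read a ground-truth edge list back into weight matrices
#'
#' @param path `truth_edges.tsv` as written by [write_paired_dataset()].
#' @param genes Gene label vector fixing the matrix dimension and order.
#' @return A `ground_truth` (without generation log or noise matrices).
#' @export
read_truth_edges <- function(path, genes) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  p <- length(genes)
  B1 <- B2 <- matrix(0, p, p, dimnames = list(genes, genes))
  ri <- match(df$source, genes)
  ci <- match(df$target, genes)
  if (anyNA(ri) || anyNA(ci))
    stop("truth edge list names genes absent from the dataset")
  B1[cbind(ri, ci)] <- df$weight_cond1
  B2[cbind(ri, ci)] <- df$weight_cond2
  structure(list(B1 = B1, B2 = B2, F = NULL,
                 delta_support = B1 != B2, sigma2 = NA_real_, log = NULL),
            class = "ground_truth")
}

#' Write an inferred fit to a directory
#'
#' Writes the posterior-mean matrices (`Bhat1.tsv`, `Bhat2.tsv`), the
#' thresholded edge lists (`edges_B1.tsv`, `edges_B2.tsv`), and the
#' differential edge list (`edges_delta.tsv`) with credible-interval
#' columns.
#'
#' @param fit A `grn_fit`.
#' @param dir Output directory.
#' @param t Sparsification threshold.
#' @return The directory path, invisibly.
#' @export
write_fit <- function(fit, dir, t = 0.2) {
  stopifnot(inherits(fit, "grn_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix(fit$Bhat1, file.path(dir, "Bhat1.tsv"), "gene")
  write_matrix(fit$Bhat2, file.path(dir, "Bhat2.tsv"), "gene")
  B1s <- threshold_network(fit$Bhat1, t)
  B2s <- threshold_network(fit$Bhat2, t)

  annotate <- function(edges) {
    idx <- cbind(match(edges$source, fit$genes),
                 match(edges$target, fit$genes))
    edges$ci_low_1 <- fit$ci$lower1[idx]
    edges$ci_high_1 <- fit$ci$upper1[idx]
    edges$ci_low_2 <- fit$ci$lower2[idx]
    edges$ci_high_2 <- fit$ci$upper2[idx]
    edges
  }
  e1 <- annotate(network_edges(B1s))
  e2 <- annotate(network_edges(B2s))
  ed <- annotate(differential_network(B1s, B2s)$edges)
  utils::write.table(e1, file.path(dir, "edges_B1.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(e2, file.path(dir, "edges_B2.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ed, file.path(dir, "edges_delta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
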