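#' FPKM normalization
#'
#' Converts raw counts to fragments per kilobase of transcript per million
#' mapped fragments:
#' \deqn{FPKM_{gs} = \frac{c_{gs}}{(L_g/10^3)(T_s/10^6)}}
#' where \eqn{c_{gs}} is the count, \eqn{L_g} the gene length in bp and
#' \eqn{T_s} the per-sample total count. Totals are computed over the
#' analysed gene set (mapped-read totals are not available once the data
#' are reduced to a count matrix).
#'
#' @param experiment a `CountExperiment`.
#' @return an `ExpressionMatrix` object: a list with `values` (gene x
#'   sample FPKM matrix), `log_transformed` flag and `samples` metadata.
#' @export
fpkm <- function(experiment) {
  stopifnot(inherits(experiment, "CountExperiment"))
  counts <- experiment$counts
  totals <- colSums(counts)
  if (any(totals == 0)) {
    stop("sample(s) with zero total count: ",
         paste(colnames(counts)[totals == 0], collapse = ", "))
  }
  len_kb <- experiment$gene_lengths / 1e3
  vals <- counts / outer(len_kb, totals / 1e6)
  expression_matrix(vals, samples = experiment$samples,
                    log_transformed = FALSE)
}

#' Construct an ExpressionMatrix container
#'
#' @param values numeric gene x sample matrix (FPKM or log2 FPKM).
#' @param samples sample metadata data frame (may be `NULL`).
#' @param log_transformed whether `values` are already on the log2 scale.
#' @return an `ExpressionMatrix` object.
#' @export
expression_matrix <- function(values, samples = NULL,
                              log_transformed = FALSE) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("expression values must be finite")
  if (!log_transformed && any(values < 0)) {
    stop("non-log expression values must be nonnegative")
  }
  if (!is.null(samples) &&
      !identical(colnames(values), samples$sample_id)) {
    stop("sample metadata does not match expression columns")
  }
  structure(list(values = values, samples = samples,
                 log_transformed = isTRUE(log_transformed)),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix:", nrow(x$values), "genes x", ncol(x$values),
      "samples", if (x$log_transformed) "(log2)" else "(linear)", "\n")
  invisible(x)
}

#' Log2-transform an expression matrix
#'
#' @param m an `ExpressionMatrix` on the linear scale.
#' @param pseudocount positive offset added before taking log2 (default 1).
#' @return the log2-transformed `ExpressionMatrix`.
#' @export
log_transform <- function(m, pseudocount = 1) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$log_transformed) stop("matrix is already log-transformed")
  if (length(pseudocount) != 1 || !is.finite(pseudocount) ||
      pseudocount <= 0) {
    stop("pseudocount must be a positive real")
  }
  expression_matrix(log2(m$values + pseudocount), samples = m$samples,
                    log_transformed = TRUE)
}

#' Principal component analysis of samples
#'
#' Samples are the observations; each gene (row) is mean-centred before
#' the decomposition. By default genes are not scaled to unit variance.
#'
#' @param m an `ExpressionMatrix`.
#' @param n_components number of components to keep; at most
#'   `min(genes, samples - 1)`.
#' @param scale. scale genes to unit variance before decomposition.
#' @return a `PcaResult`: list with `scores` (sample x component),
#'   `explained_variance_ratio` and `n_components`.
#' @export
pca_samples <- function(m, n_components = 2, scale. = FALSE) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  x <- t(m$values)  # samples x genes
  if (nrow(x) < 2) stop("PCA requires at least 2 samples")
  max_k <- min(ncol(x), nrow(x) - 1)
  if (n_components < 1 || n_components > max_k) {
    stop("n_components must be in [1, ", max_k, "]")
  }
  if (scale.) {
    sds <- apply(x, 2, stats::sd)
    x <- x[, sds > 0, drop = FALSE]
  }
  fit <- stats::prcomp(x, center = TRUE, scale. = scale.)
  var_all <- fit$sdev^2
  evr <- var_all / sum(var_all)
  scores <- fit$x[, seq_len(n_components), drop = FALSE]
  rownames(scores) <- rownames(x)
  structure(list(scores = scores,
                 explained_variance_ratio = evr[seq_len(n_components)],
                 n_components = n_components),
            class = "PcaResult")
}

#' Per-group mean expression profiles
#'
#' Averages replicate columns within each (condition, time point, arm)
#' group. Groups are ordered lexicographically by condition, then time
#' point, then arm, so output column order is deterministic.
#'
#' @param m an `ExpressionMatrix` with sample metadata.
#' @param by character vector of grouping columns among `condition`,
#'   `time_point`, `arm`.
#' @return gene x group matrix of means; column names join the group
#'   levels with `"."`.
#' @export
group_means <- function(m, by = c("condition", "time_point", "arm")) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (is.null(m$samples)) stop("expression matrix has no sample metadata")
  by <- match.arg(by, c("condition", "time_point", "arm"),
                  several.ok = TRUE)
  key <- do.call(paste, c(m$samples[by], sep = "."))
  levels_sorted <- sort(unique(key))
  out <- vapply(levels_sorted, function(k) {
    cols <- which(key == k)
    if (!length(cols)) stop("empty group: ", k)
    rowMeans(m$values[, cols, drop = FALSE])
  }, numeric(nrow(m$values)))
  out <- matrix(out, nrow = nrow(m$values),
                dimnames = list(rownames(m$values), levels_sorted))
  out
}
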