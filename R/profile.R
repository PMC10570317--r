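#' Row-wise Z-score standardization of group mean profiles
#'
#' Standardizes each gene's profile across groups to mean 0 and standard
#' deviation 1, using the population (divide-by-n) convention. Constant
#' rows become all zeros.
#'
#' @param group_mean_matrix gene x group numeric matrix (>= 2 groups),
#'   e.g. from [group_means()].
#' @return a `ZScoreMatrix`: the standardized matrix with attribute
#'   `constant_rows` listing genes whose profile was constant.
#' @export
zscore <- function(group_mean_matrix) {
  x <- as.matrix(group_mean_matrix)
  if (ncol(x) < 2) stop("Z-scores need >= 2 groups")
  mu <- rowMeans(x)
  sd_pop <- sqrt(rowMeans((x - mu)^2))
  const <- sd_pop == 0
  z <- (x - mu) / ifelse(const, 1, sd_pop)
  z[const, ] <- 0
  if (any(const)) {
    message(sum(const), " constant row(s) set to zero in Z-score matrix")
  }
  structure(z, constant_rows = rownames(x)[const],
            class = c("ZScoreMatrix", class(z)))
}

#' Cluster Z-score expression profiles
#'
#' Groups genes into `k` clusters by their standardized profiles, either
#' by hierarchical clustering with Ward linkage on Euclidean distances
#' (default, deterministic) or by seeded k-means with 10 restarts.
#'
#' @param z a `ZScoreMatrix` (or any gene x group matrix).
#' @param k number of clusters, `2 <= k <= n_genes`.
#' @param method `"hierarchical_ward"` (default) or `"kmeans"`.
#' @param seed seed used by the k-means restarts.
#' @return a `ClusterAssignment`: list with `cluster` (named integer
#'   vector gene -> cluster id in 1..k), `k`, `method` and `order` (row
#'   display order: by cluster, then dendrogram/within-cluster order).
#' @export
cluster_profiles <- function(z, k, method = c("hierarchical_ward", "kmeans"),
                             seed = 1L) {
  method <- match.arg(method)
  x <- unclass(as.matrix(z))
  n <- nrow(x)
  if (k < 2 || k > n) stop("k must lie in [2, ", n, "]")
  if (method == "hierarchical_ward") {
    hc <- stats::hclust(stats::dist(x), method = "ward.D2")
    cl <- stats::cutree(hc, k = k)
    ord <- hc$order[order(cl[hc$order])]
  } else {
    set.seed(seed)
    km <- stats::kmeans(x, centers = k, nstart = 10)
    cl <- km$cluster
    ord <- order(cl, rownames(x))
  }
  names(cl) <- rownames(x)
  stopifnot(length(unique(cl)) == k)
  structure(list(cluster = cl, k = k, method = method,
                 order = rownames(x)[ord]),
            class = "ClusterAssignment")
}

#' Render a clustered Z-score heatmap with a TF indicator track
#'
#' Rows are ordered by cluster, then by the within-cluster dendrogram
#' order recorded in the assignment; a row annotation marks transcription
#' factors. The heatmap is written to `out_path` (format inferred from
#' the extension: .png or .pdf).
#'
#' @param z a `ZScoreMatrix`.
#' @param clusters a `ClusterAssignment` covering the genes of `z`.
#' @param tf_genes character vector of TF gene ids.
#' @param out_path output image path.
#' @return invisibly, the row order used (gene ids, top to bottom).
#' @export
render_heatmap <- function(z, clusters, tf_genes, out_path) {
  x <- unclass(as.matrix(z))
  if (!nrow(x)) stop("nothing to render: empty gene list")
  if (!all(rownames(x) %in% names(clusters$cluster))) {
    stop("cluster assignment does not cover all profiled genes")
  }
  ord <- clusters$order[clusters$order %in% rownames(x)]
  x <- x[ord, , drop = FALSE]
  ann_row <- data.frame(
    cluster = factor(clusters$cluster[ord]),
    TF = factor(ifelse(ord %in% tf_genes, "TF", "non-TF"),
                levels = c("TF", "non-TF")),
    row.names = ord
  )
  ext <- tolower(tools::file_ext(out_path))
  if (!ext %in% c("png", "pdf")) {
    stop("unsupported heatmap format: ", ext, " (use .png or .pdf)")
  }
  ph <- pheatmap::pheatmap(
    x, cluster_rows = FALSE, cluster_cols = FALSE,
    annotation_row = ann_row,
    annotation_colors = list(TF = c("TF" = "red", "non-TF" = "grey80")),
    show_rownames = nrow(x) <= 60, silent = TRUE
  )
  if (ext == "png") {
    grDevices::png(out_path, width = 1200, height = 200 + 14 * nrow(x),
                   res = 120)
  } else {
    grDevices::pdf(out_path, width = 8, height = 2 + 0.12 * nrow(x))
  }
  grid::grid.newpage()
  grid::grid.draw(ph$gtable)
  grDevices::dev.off()
  if (!file.exists(out_path)) stop("failed to write heatmap: ", out_path)
  invisible(ord)
}
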