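#' Construct a CoexpressionNetwork container
#'
#' @param nodes data frame with columns `gene_id`, `is_tf`, `go_terms`
#'   (semicolon-joined GO ids), `source_conditions` (semicolon-joined
#'   condition labels).
#' @param edges data frame with columns `source`, `target`, `r`,
#'   `source_conditions`; edges are canonicalized so `source < target`
#'   and rows are sorted.
#' @param params list with `r_threshold` and `mode`.
#' @return a `CoexpressionNetwork` object.
#' @export
coexpression_network <- function(nodes, edges, params) {
  need_n <- c("gene_id", "is_tf", "go_terms", "source_conditions")
  need_e <- c("source", "target", "r", "source_conditions")
  stopifnot(all(need_n %in% names(nodes)), all(need_e %in% names(edges)))
  if (anyDuplicated(nodes$gene_id)) stop("duplicate node gene ids")
  if (nrow(edges)) {
    if (any(edges$source == edges$target)) stop("self-loops are not allowed")
    swap <- edges$source > edges$target
    tmp <- edges$source[swap]
    edges$source[swap] <- edges$target[swap]
    edges$target[swap] <- tmp
    edges <- edges[order(edges$source, edges$target), , drop = FALSE]
    if (anyDuplicated(paste(edges$source, edges$target))) {
      stop("duplicate edges")
    }
    if (!all(c(edges$source, edges$target) %in% nodes$gene_id)) {
      stop("edge endpoint missing from node table")
    }
  }
  nodes <- nodes[order(nodes$gene_id), , drop = FALSE]
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, params = params),
            class = "CoexpressionNetwork")
}

#' @export
print.CoexpressionNetwork <- function(x, ...) {
  cat("CoexpressionNetwork:", nrow(x$nodes), "nodes,", nrow(x$edges),
      "edges (r_threshold =", x$params$r_threshold,
      ", mode =", x$params$mode, ")\n")
  invisible(x)
}

# Annotation lookup helpers used when decorating nodes.
.node_frame <- function(gene_ids, annotation, source_label) {
  if (!is.null(annotation)) {
    idx <- match(gene_ids, annotation$gene_id)
    is_tf <- ifelse(is.na(idx), FALSE, annotation$is_tf[idx] > 0)
    go <- ifelse(is.na(idx), "", annotation$go_terms[idx])
  } else {
    is_tf <- rep(FALSE, length(gene_ids))
    go <- rep("", length(gene_ids))
  }
  data.frame(gene_id = gene_ids, is_tf = is_tf, go_terms = go,
             source_conditions = rep(source_label, length(gene_ids)),
             stringsAsFactors = FALSE)
}

#' Build a per-condition gene co-expression network
#'
#' Computes Pearson correlations between all pairs of the condition's
#' DEGs on log expression across all samples of the condition (mock and
#' treated, all time points) and keeps edges whose correlation passes the
#' threshold: `r >= r_threshold` in `signed` mode (the default) or
#' `|r| >= r_threshold` in `absolute` mode. Genes with zero variance are
#' excluded before correlation; genes with no retained edge are dropped
#' from the node set, so isolated DEGs do not appear as nodes.
#'
#' The pairwise computation is blocked so memory stays bounded for large
#' DEG sets.
#'
#' @param expr an `ExpressionMatrix` restricted to one condition's
#'   samples (log2 scale recommended; see [log_transform()]).
#' @param deg_genes character vector of DEG ids (subset of matrix genes).
#' @param r_threshold correlation threshold in (0, 1); default 0.9.
#' @param mode `"signed"` or `"absolute"`.
#' @param condition label recorded as the network's source condition.
#' @param annotation optional annotation data frame used to decorate
#'   nodes with `is_tf` and `go_terms`.
#' @param block_size number of genes per correlation block (memory
#'   guard).
#' @return a `CoexpressionNetwork`.
#' @export
build_gcn <- function(expr, deg_genes, r_threshold = 0.9,
                      mode = c("signed", "absolute"),
                      condition = "condition", annotation = NULL,
                      block_size = 2000L) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  mode <- match.arg(mode)
  if (length(r_threshold) != 1 || r_threshold <= 0 || r_threshold >= 1) {
    stop("r_threshold must lie in (0, 1)")
  }
  if (ncol(expr$values) < 3) {
    stop("network construction needs >= 3 samples")
  }
  missing_genes <- setdiff(deg_genes, rownames(expr$values))
  if (length(missing_genes)) {
    stop("deg_genes not in expression matrix: ",
         paste(utils::head(missing_genes, 3), collapse = ", "))
  }
  empty <- coexpression_network(
    .node_frame(character(0), annotation, condition),
    data.frame(source = character(0), target = character(0),
               r = numeric(0), source_conditions = character(0)),
    params = list(r_threshold = r_threshold, mode = mode)
  )
  if (!length(deg_genes)) {
    warning("empty DEG set for condition ", condition,
            "; returning empty network")
    return(empty)
  }
  x <- expr$values[deg_genes, , drop = FALSE]
  sds <- apply(x, 1, stats::sd)
  x <- x[sds > 0, , drop = FALSE]
  n <- nrow(x)
  if (n < 2) return(empty)

  genes <- rownames(x)
  xt <- t(x)  # samples x genes, for stats::cor
  blocks <- split(seq_len(n), ceiling(seq_len(n) / block_size))
  src <- tgt <- character(0)
  rv <- numeric(0)
  for (bi in seq_along(blocks)) {
    for (bj in bi:length(blocks)) {
      ii <- blocks[[bi]]
      jj <- blocks[[bj]]
      cm <- stats::cor(xt[, ii, drop = FALSE], xt[, jj, drop = FALSE])
      keep <- if (mode == "signed") cm >= r_threshold else
        abs(cm) >= r_threshold
      if (bi == bj) keep[lower.tri(keep, diag = TRUE)] <- FALSE
      hits <- which(keep, arr.ind = TRUE)
      if (nrow(hits)) {
        src <- c(src, genes[ii[hits[, 1]]])
        tgt <- c(tgt, genes[jj[hits[, 2]]])
        rv <- c(rv, cm[hits])
      }
    }
  }
  node_ids <- sort(unique(c(src, tgt)))
  coexpression_network(
    .node_frame(node_ids, annotation, condition),
    data.frame(source = src, target = tgt, r = rv,
               source_conditions = rep(condition, length(src)),
               stringsAsFactors = FALSE),
    params = list(r_threshold = r_threshold, mode = mode)
  )
}

#' Basic network statistics
#'
#' @param net a `CoexpressionNetwork` or `CoreNetwork`.
#' @return list with `n_nodes`, `n_edges`, `degree` (named per-node
#'   degree) and `degree_distribution` (table of degree frequencies).
#' @export
network_stats <- function(net) {
  nodes <- net$nodes$gene_id
  deg <- stats::setNames(rep(0L, length(nodes)), nodes)
  if (nrow(net$edges)) {
    tab <- table(c(net$edges$source, net$edges$target))
    deg[names(tab)] <- as.integer(tab)
  }
  list(n_nodes = length(nodes), n_edges = nrow(net$edges),
       degree = deg, degree_distribution = table(deg))
}
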