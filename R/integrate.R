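.split_semi <- function(x) strsplit(x, ";", fixed = TRUE)

.join_semi <- function(x) paste(sort(unique(x)), collapse = ";")

#' Merge per-condition networks into an integrated network
#'
#' Node and edge sets are unioned; each node and edge carries
#' `source_conditions`, the set of input networks containing it. An edge
#' present in several inputs keeps every per-source correlation in the
#' `r_by_source` column ("cond=r;..."); its `r` column holds the maximum.
#' The optional `shared_only` filter retains only nodes present in at
#' least `m` inputs (then takes the induced edge set); the default
#' `m = 1` is a pure union.
#'
#' @param nets list of `CoexpressionNetwork` objects built with identical
#'   parameters (threshold and mode).
#' @param shared_only minimum number of source networks a node must
#'   appear in (default 1).
#' @return the merged `CoexpressionNetwork`.
#' @export
merge_networks <- function(nets, shared_only = 1L) {
  if (length(nets) < 2) stop("merge_networks needs >= 2 networks")
  stopifnot(all(vapply(nets, inherits, logical(1), "CoexpressionNetwork")))
  pars <- lapply(nets, function(n) n$params[c("r_threshold", "mode")])
  if (!all(vapply(pars[-1], identical, logical(1), pars[[1]]))) {
    stop("networks were built with different parameters")
  }

  all_nodes <- do.call(rbind, lapply(nets, `[[`, "nodes"))
  node_src <- unlist(lapply(all_nodes$source_conditions, identity))
  agg_src <- tapply(all_nodes$source_conditions, all_nodes$gene_id,
                    function(s) .join_semi(unlist(.split_semi(s))))
  first <- all_nodes[!duplicated(all_nodes$gene_id), , drop = FALSE]
  first <- first[order(first$gene_id), , drop = FALSE]
  first$source_conditions <- as.character(agg_src[first$gene_id])

  all_edges <- do.call(rbind, lapply(nets, function(n) {
    e <- n$edges
    if (!nrow(e)) return(e)
    if (is.null(e$r_by_source)) {
      e$r_by_source <- paste0(e$source_conditions, "=",
                              sprintf("%.15g", e$r))
    }
    e
  }))
  if (is.null(all_edges)) {
    all_edges <- data.frame(source = character(0), target = character(0),
                            r = numeric(0), source_conditions = character(0),
                            r_by_source = character(0))
  }
  if (nrow(all_edges)) {
    key <- paste(all_edges$source, all_edges$target, sep = "\r")
    agg_e_src <- tapply(all_edges$source_conditions, key,
                        function(s) .join_semi(unlist(.split_semi(s))))
    agg_r <- tapply(all_edges$r, key, max)
    agg_rbs <- tapply(all_edges$r_by_source, key,
                      function(s) paste(sort(unique(unlist(.split_semi(s)))),
                                        collapse = ";"))
    efirst <- all_edges[!duplicated(key), , drop = FALSE]
    ekey <- paste(efirst$source, efirst$target, sep = "\r")
    efirst$source_conditions <- as.character(agg_e_src[ekey])
    efirst$r <- as.numeric(agg_r[ekey])
    efirst$r_by_source <- as.character(agg_rbs[ekey])
    all_edges <- efirst
  }

  if (shared_only > 1) {
    n_src <- lengths(.split_semi(first$source_conditions))
    first <- first[n_src >= shared_only, , drop = FALSE]
    keep <- all_edges$source %in% first$gene_id &
      all_edges$target %in% first$gene_id
    all_edges <- all_edges[keep, , drop = FALSE]
  }
  coexpression_network(first, all_edges, params = c(
    pars[[1]], list(shared_only = as.integer(shared_only))
  ))
}

#' First neighborhood of a seed set
#'
#' @param net a `CoexpressionNetwork`.
#' @param seeds character vector of node gene ids.
#' @return character vector: the seeds plus every node sharing an edge
#'   with a seed.
#' @export
first_neighbors <- function(net, seeds) {
  unknown <- setdiff(seeds, net$nodes$gene_id)
  if (length(unknown)) {
    stop("seed gene(s) not in network: ",
         paste(utils::head(unknown, 3), collapse = ", "))
  }
  e <- net$edges
  nb <- c(e$target[e$source %in% seeds], e$source[e$target %in% seeds])
  sort(unique(c(seeds, nb)))
}

.node_has_go <- function(go_terms, go_filter) {
  vapply(.split_semi(go_terms), function(tt) any(tt %in% go_filter),
         logical(1))
}

#' Reconstruct a TF-centred, GO-filtered core network
#'
#' Mirrors the core-network reconstruction used for stress networks:
#' 1. seeds = transcription factors in the network (restricted to those
#'    carrying a term of `go_filter`, if one is given);
#' 2. candidates = seeds plus their direct neighbors;
#' 3. with a GO filter, only candidates carrying a filter term are
#'    retained (seeds always survive);
#' 4. the core is the induced subgraph on the retained nodes, so edges
#'    between two retained non-seed neighbors are kept;
#' 5. hubs are ranked by degree within the core (ties broken by gene id);
#'    betweenness is available as a secondary metric.
#'
#' @param net an integrated `CoexpressionNetwork` whose nodes carry
#'   `is_tf` and `go_terms`.
#' @param tf_genes character vector of TF gene ids (seeds are drawn from
#'   its intersection with the network's nodes).
#' @param go_filter character vector of GO ids, or `NULL` for no GO
#'   filtering.
#' @param hub_metric `"degree"` (default) or `"betweenness"`.
#' @return a `CoreNetwork`: list with `nodes`, `edges`, `seed_tfs`,
#'   `hub_ranking` (data frame gene_id / score / degree / is_tf, sorted)
#'   and `parent_params`.
#' @export
reconstruct_core <- function(net, tf_genes, go_filter = NULL,
                             hub_metric = c("degree", "betweenness")) {
  hub_metric <- match.arg(hub_metric)
  nodes <- net$nodes
  tf_in_net <- intersect(tf_genes, nodes$gene_id)
  if (!length(tf_in_net)) {
    stop("no annotated TFs in network")
  }
  seeds <- tf_in_net
  if (!is.null(go_filter)) {
    has_go <- .node_has_go(nodes$go_terms, go_filter)
    names(has_go) <- nodes$gene_id
    seeds <- seeds[has_go[seeds]]
    if (!length(seeds)) stop("no annotated TFs in network")
  }
  candidates <- first_neighbors(net, seeds)
  if (!is.null(go_filter)) {
    keep <- candidates[.node_has_go(
      nodes$go_terms[match(candidates, nodes$gene_id)], go_filter)]
    candidates <- sort(unique(c(seeds, keep)))
  }
  core_nodes <- nodes[nodes$gene_id %in% candidates, , drop = FALSE]
  e <- net$edges
  core_edges <- e[e$source %in% candidates & e$target %in% candidates, ,
                  drop = FALSE]
  rownames(core_nodes) <- rownames(core_edges) <- NULL

  deg <- stats::setNames(rep(0L, nrow(core_nodes)), core_nodes$gene_id)
  if (nrow(core_edges)) {
    tab <- table(c(core_edges$source, core_edges$target))
    deg[names(tab)] <- as.integer(tab)
  }
  score <- deg
  if (hub_metric == "betweenness" && nrow(core_edges)) {
    g <- igraph::graph_from_data_frame(
      core_edges[, c("source", "target")], directed = FALSE,
      vertices = core_nodes$gene_id)
    btw <- igraph::betweenness(g, directed = FALSE)
    score <- btw[core_nodes$gene_id]
  }
  ord <- order(-score, core_nodes$gene_id)
  hub_ranking <- data.frame(
    gene_id = core_nodes$gene_id[ord],
    score = as.numeric(score[ord]),
    degree = as.integer(deg[core_nodes$gene_id[ord]]),
    is_tf = core_nodes$is_tf[ord],
    stringsAsFactors = FALSE
  )
  structure(list(nodes = core_nodes, edges = core_edges,
                 seed_tfs = sort(seeds), hub_ranking = hub_ranking,
                 hub_metric = hub_metric, parent_params = net$params),
            class = c("CoreNetwork", "CoexpressionNetwork"))
}

#' @export
print.CoreNetwork <- function(x, ...) {
  cat("CoreNetwork:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges,",
      length(x$seed_tfs), "seed TFs\n")
  if (nrow(x$hub_ranking)) {
    cat("  top hub:", x$hub_ranking$gene_id[1], "(degree",
        x$hub_ranking$degree[1], ")\n")
  }
  invisible(x)
}

#' Decompose a merged network's edges by exact source set
#'
#' @param merged a merged `CoexpressionNetwork` whose edges carry
#'   `source_conditions`.
#' @return data frame with columns `sources` (semicolon-joined source
#'   set) and `count`; counts sum to the total edge count.
#' @export
shared_edge_decomposition <- function(merged) {
  if (!nrow(merged$edges)) {
    return(data.frame(sources = character(0), count = integer(0)))
  }
  tab <- table(merged$edges$source_conditions)
  out <- data.frame(sources = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(out$sources), , drop = FALSE]
  rownames(out) <- NULL
  stopifnot(sum(out$count) == nrow(merged$edges))
  out
}
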