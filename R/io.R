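# Canonical table dialect: TSV, UTF-8, Unix newlines, no quoting.
write_tsv_file <- function(df, path) {
  df2 <- df
  for (j in seq_along(df2)) {
    if (is.list(df2[[j]])) df2[[j]] <- vapply(df2[[j]], paste,
                                              character(1), collapse = ";")
  }
  utils::write.table(df2, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Read a counts TSV
#'
#' Expects a tab-separated file whose first column is `gene_id` and whose
#' remaining columns are sample ids holding integer counts.
#'
#' @param path path to `counts.tsv`.
#' @return integer matrix, genes x samples.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("counts file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_id") {
    stop("counts file must start with a 'gene_id' column")
  }
  if (anyDuplicated(df$gene_id)) stop("duplicate gene ids in counts file")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (nrow(df) && (anyNA(m) || any(m < 0) || any(m != round(m)))) {
    bad <- which(rowSums(is.na(m) | m < 0 | m != round(m)) > 0)
    stop("non-integer or negative counts at line(s): ",
         paste(utils::head(bad + 1L, 5), collapse = ", "))
  }
  storage.mode(m) <- "integer"
  rownames(m) <- df$gene_id
  m
}

#' Read a sample-metadata TSV
#'
#' Expects columns `sample_id`, `condition`, `time_point`, `replicate`,
#' `arm` with `arm` in {mock, treated}.
#'
#' @param path path to `samples.tsv`.
#' @return data frame of sample records.
#' @export
read_samples <- function(path) {
  if (!file.exists(path)) stop("samples file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  req <- c("sample_id", "condition", "time_point", "replicate", "arm")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("samples file missing column(s): ",
                         paste(miss, collapse = ", "))
  df$replicate <- as.integer(df$replicate)
  if (!all(df$arm %in% c("mock", "treated"))) {
    stop("arm must be 'mock' or 'treated' at line(s): ",
         paste(utils::head(which(!df$arm %in% c("mock", "treated")) + 1L, 5),
               collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids")
  df[, req]
}

#' Write node and edge tables for a network
#'
#' Emits `nodes.tsv` (gene_id, is_tf, go_terms, degree,
#' source_conditions) and `edges.tsv` (source, target, r,
#' source_conditions) with deterministic lexicographic row order.
#'
#' @param net a `CoexpressionNetwork` or `CoreNetwork`.
#' @param dir output directory (created if absent).
#' @param prefix optional file-name prefix.
#' @return invisibly, the two file paths.
#' @export
write_network_tables <- function(net, dir, prefix = "") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  st <- network_stats(net)
  nodes <- net$nodes
  nodes$degree <- as.integer(st$degree[nodes$gene_id])
  nodes <- nodes[order(nodes$gene_id),
                 c("gene_id", "is_tf", "go_terms", "degree",
                   "source_conditions")]
  edges <- net$edges[, intersect(c("source", "target", "r",
                                   "source_conditions"),
                                 names(net$edges)), drop = FALSE]
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  np <- file.path(dir, paste0(prefix, "nodes.tsv"))
  ep <- file.path(dir, paste0(prefix, "edges.tsv"))
  write_tsv_file(nodes, np)
  write_tsv_file(edges, ep)
  invisible(c(nodes = np, edges = ep))
}

#' Read node and edge tables back into a network
#'
#' @param nodes_path,edges_path paths written by
#'   [write_network_tables()].
#' @param r_threshold,mode build parameters to record on the object.
#' @return a `CoexpressionNetwork`.
#' @export
read_network_tables <- function(nodes_path, edges_path,
                                r_threshold = NA_real_, mode = "signed") {
  nodes <- utils::read.delim(nodes_path, stringsAsFactors = FALSE,
                             colClasses = "character")
  req_n <- c("gene_id", "is_tf", "go_terms", "source_conditions")
  miss <- setdiff(req_n, names(nodes))
  if (length(miss)) stop("node table missing column(s): ",
                         paste(miss, collapse = ", "))
  nodes$is_tf <- nodes$is_tf %in% c("TRUE", "1")
  nodes$go_terms[is.na(nodes$go_terms)] <- ""
  edges <- utils::read.delim(edges_path, stringsAsFactors = FALSE)
  req_e <- c("source", "target", "r", "source_conditions")
  miss <- setdiff(req_e, names(edges))
  if (length(miss)) stop("edge table missing column(s): ",
                         paste(miss, collapse = ", "))
  edges$r <- as.numeric(edges$r)
  coexpression_network(nodes[, req_n], edges[, req_e],
                       params = list(r_threshold = r_threshold, mode = mode))
}

#' Write a DEG table to TSV
#'
#' @param deg_table a `DegTable`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_deg_table <- function(deg_table, path) {
  d <- as.data.frame(deg_table)
  d <- d[order(d$condition, d$time_point, d$gene_id), , drop = FALSE]
  write_tsv_file(d, path)
}

#' Export a network as a Cytoscape SIF file
#'
#' One line per edge: `source<TAB>co<TAB>target`.
#'
#' @param net a `CoexpressionNetwork`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
export_sif <- function(net, path) {
  e <- net$edges[order(net$edges$source, net$edges$target), , drop = FALSE]
  lines <- if (nrow(e)) paste(e$source, "co", e$target, sep = "\t") else
    character(0)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Export a network as GraphML
#'
#' Nodes carry `is_tf`, `go_terms` and `source_conditions` attributes;
#' edges carry `r`. The file loads in Cytoscape and other standard graph
#' tools.
#'
#' @param net a `CoexpressionNetwork`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
export_graphml <- function(net, path) {
  g <- igraph::make_empty_graph(directed = FALSE)
  if (nrow(net$nodes)) {
    g <- igraph::add_vertices(g, nrow(net$nodes),
                              name = net$nodes$gene_id,
                              is_tf = as.logical(net$nodes$is_tf),
                              go_terms = net$nodes$go_terms,
                              source_conditions =
                                net$nodes$source_conditions)
    if (nrow(net$edges)) {
      idx <- rbind(match(net$edges$source, net$nodes$gene_id),
                   match(net$edges$target, net$nodes$gene_id))
      g <- igraph::add_edges(g, as.vector(idx), r = net$edges$r)
    }
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Build and validate a pipeline configuration
#'
#' Defaults follow standard practice for stress co-expression analysis:
#' correlation threshold 0.9 (signed), DEG thresholds |log2FC| > 1 and
#' FDR < 0.05, GO filter `GO:0050896` (response to stimulus).
#'
#' @param counts,samples,annotation input file paths.
#' @param output_dir output directory; must differ from the input paths.
#' @param log2fc_cutoff,fdr_cutoff DEG thresholds.
#' @param r_threshold,gcn_mode,block_size network construction settings.
#' @param shared_only,hub_metric integration settings.
#' @param network_groups named list mapping integrated-network label to
#'   the conditions it merges; `NULL` merges all conditions under
#'   `"integrated"`.
#' @param k_clusters clusters for Z-score profiling.
#' @param cluster_method `"hierarchical_ward"` or `"kmeans"`.
#' @param go_filter GO ids used for core-network filtering.
#' @param seed integer seed.
#' @return a validated `PipelineConfig` list.
#' @export
pipeline_config <- function(counts, samples, annotation, output_dir,
                            log2fc_cutoff = 1, fdr_cutoff = 0.05,
                            r_threshold = 0.9, gcn_mode = "signed",
                            block_size = 2000L, shared_only = 1L,
                            hub_metric = "degree", network_groups = NULL,
                            k_clusters = 5L,
                            cluster_method = "hierarchical_ward",
                            go_filter = STRESS_GO, seed = 1L) {
  cfg <- list(counts = counts, samples = samples, annotation = annotation,
              output_dir = output_dir, log2fc_cutoff = log2fc_cutoff,
              fdr_cutoff = fdr_cutoff, r_threshold = r_threshold,
              gcn_mode = gcn_mode, block_size = as.integer(block_size),
              shared_only = as.integer(shared_only),
              hub_metric = hub_metric, network_groups = network_groups,
              k_clusters = as.integer(k_clusters),
              cluster_method = cluster_method, go_filter = go_filter,
              seed = as.integer(seed))
  validate_pipeline_config(cfg)
  structure(cfg, class = "PipelineConfig")
}

validate_pipeline_config <- function(cfg) {
  if (cfg$r_threshold <= 0 || cfg$r_threshold >= 1) {
    stop("r_threshold must lie in (0, 1)")
  }
  if (cfg$fdr_cutoff <= 0 || cfg$fdr_cutoff >= 1) {
    stop("fdr_cutoff must lie in (0, 1)")
  }
  if (cfg$log2fc_cutoff <= 0) stop("log2fc_cutoff must be positive")
  if (cfg$k_clusters < 2) stop("k_clusters must be >= 2")
  if (!cfg$gcn_mode %in% c("signed", "absolute")) {
    stop("gcn_mode must be 'signed' or 'absolute'")
  }
  if (!cfg$cluster_method %in% c("hierarchical_ward", "kmeans")) {
    stop("unknown cluster_method: ", cfg$cluster_method)
  }
  ins <- normalizePath(c(cfg$counts, cfg$samples, cfg$annotation),
                       mustWork = FALSE)
  out <- normalizePath(cfg$output_dir, mustWork = FALSE)
  if (out %in% ins) stop("output_dir must differ from the input paths")
  invisible(TRUE)
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return a validated `PipelineConfig`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Run the full co-expression-network pipeline
#'
#' Executes, in order: FPKM normalization, per-condition DEG calling,
#' Venn partition of DEG sets, per-condition network construction,
#' network integration per group, TF-centred GO-filtered core
#' reconstruction with hub ranking, GO enrichment of core genes, Z-score
#' profiling with clustering and a heatmap, plus SIF/GraphML exports and
#' a JSON run manifest recording the configuration and per-stage counts.
#'
#' @param config a `PipelineConfig` from [pipeline_config()] or
#'   [read_config()].
#' @param quiet suppress per-stage log messages.
#' @return invisibly, the manifest list (also written as
#'   `manifest.json` in the output directory).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  t0 <- Sys.time()
  log_stage <- function(...) if (!quiet) message("[stressgcn] ", ...)
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = unclass(config), stages = list())
  stage <- function(name, fun) {
    st <- Sys.time()
    res <- tryCatch(fun(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    el <- round(as.numeric(difftime(Sys.time(), st, units = "secs")), 2)
    log_stage(name, " done in ", el, "s")
    res
  }

  counts <- stage("read_counts", function() read_counts(config$counts))
  samples <- stage("read_samples", function() read_samples(config$samples))
  annotation <- stage("read_annotation",
                      function() read_annotation(config$annotation))
  exp <- count_experiment(counts, samples,
                          stats::setNames(annotation$length_bp,
                                          annotation$gene_id))
  manifest$stages$input <- list(n_genes = nrow(counts),
                                n_samples = ncol(counts))

  lg <- stage("fpkm", function() log_transform(fpkm(exp)))

  conditions <- sort(unique(samples$condition))
  deg_tables <- list()
  deg_sets <- list()
  for (cond in conditions) {
    dt <- stage(paste0("deg_", cond), function() {
      call_degs(exp, cond, log2fc_cutoff = config$log2fc_cutoff,
                fdr_cutoff = config$fdr_cutoff)
    })
    deg_tables[[cond]] <- dt
    deg_sets[[cond]] <- deg_set(dt)
    write_deg_table(dt, file.path(out, paste0("deg_", cond, ".tsv")))
  }
  manifest$stages$deg <- lapply(deg_sets, length)

  if (length(conditions) >= 2) {
    vp <- stage("venn_partition", function() venn_partition(deg_sets))
    write_tsv_file(as.data.frame(vp)[, c("subset", "count")],
                   file.path(out, "venn_partition.tsv"))
    manifest$stages$venn <- list(
      union_size = attr(vp, "universe_size"))
  }

  nets <- list()
  for (cond in conditions) {
    nets[[cond]] <- stage(paste0("gcn_", cond), function() {
      cols <- samples$sample_id[samples$condition == cond]
      sub <- expression_matrix(lg$values[, cols, drop = FALSE],
                               samples = samples[match(
                                 cols, samples$sample_id), ],
                               log_transformed = TRUE)
      build_gcn(sub, deg_sets[[cond]], r_threshold = config$r_threshold,
                mode = config$gcn_mode, condition = cond,
                annotation = annotation, block_size = config$block_size)
    })
    write_network_tables(nets[[cond]], out, prefix = paste0("gcn_", cond,
                                                            "_"))
  }
  manifest$stages$gcn <- lapply(nets, function(n) {
    st <- network_stats(n)
    list(nodes = st$n_nodes, edges = st$n_edges)
  })

  groups <- config$network_groups
  if (is.null(groups)) groups <- list(integrated = conditions)
  tf_genes <- annotation$gene_id[annotation$is_tf > 0]
  gm_all <- group_means(lg, by = c("condition", "time_point", "arm"))

  manifest$stages$integrated <- list()
  for (gname in names(groups)) {
    members <- intersect(groups[[gname]], conditions)
    if (!length(members)) next
    merged <- if (length(members) >= 2) {
      stage(paste0("merge_", gname), function() {
        merge_networks(nets[members], shared_only = config$shared_only)
      })
    } else {
      nets[[members]]
    }
    write_network_tables(merged, out, prefix = paste0(gname, "_"))
    export_sif(merged, file.path(out, paste0(gname, ".sif")))
    export_graphml(merged, file.path(out, paste0(gname, ".graphml")))

    core <- tryCatch(
      stage(paste0("core_", gname), function() {
        reconstruct_core(merged, tf_genes, go_filter = config$go_filter,
                         hub_metric = config$hub_metric)
      }),
      error = function(e) NULL)
    mstats <- network_stats(merged)
    ginfo <- list(nodes = mstats$n_nodes, edges = mstats$n_edges)
    if (!is.null(core)) {
      write_network_tables(core, out, prefix = paste0("core_", gname, "_"))
      write_tsv_file(core$hub_ranking,
                     file.path(out, paste0("core_", gname, "_hubs.tsv")))
      export_sif(core, file.path(out, paste0("core_", gname, ".sif")))
      export_graphml(core, file.path(out, paste0("core_", gname,
                                                 ".graphml")))
      cstats <- network_stats(core)
      ginfo$core_nodes <- cstats$n_nodes
      ginfo$core_edges <- cstats$n_edges

      enr <- tryCatch(stage(paste0("enrich_", gname), function() {
        enrich(core$nodes$gene_id, annotation$gene_id, annotation,
               method = "hypergeometric")
      }), error = function(e) NULL)
      if (!is.null(enr)) {
        write_tsv_file(enr, file.path(out, paste0("enrichment_", gname,
                                                  ".tsv")))
      }

      core_genes <- core$nodes$gene_id
      if (length(core_genes) >= max(3, config$k_clusters)) {
        prof <- stage(paste0("profile_", gname), function() {
          gm <- gm_all[core_genes, , drop = FALSE]
          z <- zscore(gm)
          nonconst <- setdiff(rownames(z), attr(z, "constant_rows"))
          k <- min(config$k_clusters, length(nonconst))
          cl <- cluster_profiles(z, k = k, method = config$cluster_method,
                                 seed = config$seed)
          zt <- data.frame(gene_id = rownames(z), unclass(z),
                           cluster = cl$cluster[rownames(z)],
                           check.names = FALSE)
          write_tsv_file(zt, file.path(out, paste0("zscore_", gname,
                                                   ".tsv")))
          render_heatmap(z, cl, tf_genes,
                         file.path(out, paste0("heatmap_", gname, ".png")))
          cl
        })
        ginfo$n_clusters <- prof$k
      }
    }
    manifest$stages$integrated[[gname]] <- ginfo
  }

  manifest$seed <- config$seed
  manifest$r_version <- as.character(getRversion())
  manifest$elapsed_sec <- round(as.numeric(difftime(Sys.time(), t0,
                                                    units = "secs")), 2)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_stage("pipeline complete in ", manifest$elapsed_sec, "s")
  invisible(manifest)
}
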