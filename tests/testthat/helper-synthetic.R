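# Shared fixtures, generated in code. Kept small so the suite stays fast.

small_params <- function(seed = 7, ...) {
  simulation_params(n_genes = 300, n_conditions = 2,
                    time_points = c("6h", "24h"), n_replicates = 3,
                    n_modules = 2, module_size_range = c(10, 10),
                    seed = seed, ...)
}

# memoised default small experiment used across test files
.small_sim_cache <- new.env(parent = emptyenv())
small_sim <- function() {
  if (is.null(.small_sim_cache$sim)) {
    .small_sim_cache$sim <- generate_experiment(small_params())
  }
  .small_sim_cache$sim
}

# random expression matrix (log scale) for network tests
random_log_expr <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  # a latent factor plus noise so correlations span the threshold range
  f <- rnorm(n_samples)
  load <- runif(n_genes, -2, 2)
  x <- outer(load, f) + matrix(rnorm(n_genes * n_samples, sd = 0.7),
                               n_genes, n_samples)
  rownames(x) <- sprintf("g%04d", seq_len(n_genes))
  colnames(x) <- sprintf("s%03d", seq_len(n_samples))
  x
}

# brute-force O(n^2) Pearson-threshold oracle
brute_force_edges <- function(x, threshold, mode = "signed") {
  sds <- apply(x, 1, sd)
  x <- x[sds > 0, , drop = FALSE]
  genes <- rownames(x)
  n <- nrow(x)
  out <- list()
  k <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r <- cor(x[i, ], x[j, ])
      keep <- if (mode == "signed") r >= threshold else abs(r) >= threshold
      if (keep) {
        k <- k + 1
        a <- sort(c(genes[i], genes[j]))
        out[[k]] <- data.frame(source = a[1], target = a[2], r = r,
                               stringsAsFactors = FALSE)
      }
    }
  }
  if (!k) {
    return(data.frame(source = character(0), target = character(0),
                      r = numeric(0)))
  }
  e <- do.call(rbind, out)
  e[order(e$source, e$target), , drop = FALSE]
}

edge_key <- function(edges) {
  if (!nrow(edges)) return(character(0))
  sort(paste(pmin(edges$source, edges$target),
             pmax(edges$source, edges$target)))
}

# small hand-built network helper
toy_network <- function(edges_df, tf = character(0), go = list(),
                        condition = "c1", r_threshold = 0.9,
                        mode = "signed") {
  ids <- sort(unique(c(edges_df$source, edges_df$target)))
  nodes <- data.frame(
    gene_id = ids,
    is_tf = ids %in% tf,
    go_terms = vapply(ids, function(g) {
      paste(go[[g]], collapse = ";")
    }, character(1)),
    source_conditions = condition,
    stringsAsFactors = FALSE
  )
  if (is.null(edges_df$r)) edges_df$r <- 0.95
  edges_df$source_conditions <- condition
  coexpression_network(nodes, edges_df,
                       params = list(r_threshold = r_threshold, mode = mode))
}

# run the DEG -> GCN -> merge -> core chain the pipeline executes,
# programmatically, for planted-truth recovery checks
run_core_chain <- function(sim, go_filter = STRESS_GO) {
  lg <- log_transform(fpkm(sim$experiment))
  smp <- sim$experiment$samples
  nets <- list()
  degsets <- list()
  for (cond in sort(unique(smp$condition))) {
    degsets[[cond]] <- deg_set(call_degs(sim$experiment, cond))
    cols <- smp$sample_id[smp$condition == cond]
    sub <- expression_matrix(lg$values[, cols, drop = FALSE],
                             samples = smp[match(cols, smp$sample_id), ],
                             log_transformed = TRUE)
    nets[[cond]] <- suppressWarnings(
      build_gcn(sub, degsets[[cond]], condition = cond,
                annotation = sim$annotation))
  }
  merged <- if (length(nets) >= 2) merge_networks(nets) else nets[[1]]
  core <- tryCatch(
    reconstruct_core(merged, sim$truth$tf_genes, go_filter = go_filter),
    error = function(e) NULL)
  list(deg_sets = degsets, nets = nets, merged = merged, core = core)
}
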