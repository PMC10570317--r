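#' Simulation parameters for synthetic multi-stress count experiments
#'
#' Constructs and validates the parameter set for
#' [generate_experiment()]. The defaults describe a compact multi-stress
#' design: several stress conditions, each with mock and treated arms over
#' a shared time course, negative-binomial counts, a subset of genes
#' differentially expressed per condition, and planted co-expression
#' modules organised around a designated transcription-factor (TF) hub.
#'
#' @param n_genes number of genes.
#' @param n_conditions number of stress conditions; each condition has its
#'   own mock and treated arms.
#' @param time_points character vector of time-point labels shared by all
#'   conditions.
#' @param n_replicates replicates per (condition, time point, arm).
#' @param baseline_mean_log2_range interval for per-gene baseline
#'   expression, in log2 expression units.
#' @param nb_dispersion negative-binomial dispersion alpha, so that
#'   Var(count) = mu + alpha * mu^2.
#' @param n_modules number of planted co-expression modules.
#' @param module_size_range integer interval for module sizes (genes);
#'   lower bound must be at least 3.
#' @param module_latent_sd standard deviation of the per-sample module
#'   latent factor (log2 units).
#' @param module_noise_sd standard deviation of the member-specific
#'   Gaussian noise added on top of the latent factor (log2 units).
#' @param de_fraction fraction of genes planted as background
#'   differentially expressed per condition, on top of the module
#'   members, which always respond (coherently up-regulated) in every
#'   condition so planted regulons survive DEG filtering.
#' @param de_log2fc_range interval for the magnitude of planted log2
#'   fold-changes (sign is drawn at random).
#' @param tf_fraction fraction of genes flagged as transcription factors
#'   (module hubs are always TFs, on top of this fraction).
#' @param stress_go_fraction fraction of non-module genes carrying the
#'   stress GO label (`GO:0050896`).
#' @param module_go_prob probability that a module member carries the
#'   stress GO label; default 1 so core-network reconstruction can find
#'   planted modules.
#' @param gene_length_range interval for gene lengths in bp.
#' @param library_size_range interval for per-sample library sizes
#'   (fragments); sizes are drawn log-uniformly.
#' @param condition_names optional condition labels; defaults to
#'   `stress1..stressK`.
#' @param seed integer seed; the whole experiment is deterministic given
#'   this seed.
#' @return an object of class `SimulationParams` (a validated list).
#' @export
simulation_params <- function(n_genes = 2000,
                              n_conditions = 4,
                              time_points = c("6h", "12h", "24h", "48h"),
                              n_replicates = 3,
                              baseline_mean_log2_range = c(3, 9),
                              nb_dispersion = 0.05,
                              n_modules = 3,
                              module_size_range = c(20, 20),
                              module_latent_sd = 1.0,
                              module_noise_sd = 0.3,
                              de_fraction = 0.1,
                              de_log2fc_range = c(1, 3),
                              tf_fraction = 0.1,
                              stress_go_fraction = 0.3,
                              module_go_prob = 1,
                              gene_length_range = c(500, 5000),
                              library_size_range = c(1e6, 5e6),
                              condition_names = NULL,
                              seed = 1L) {
  p <- list(
    n_genes = as.integer(n_genes), n_conditions = as.integer(n_conditions),
    time_points = as.character(time_points),
    n_replicates = as.integer(n_replicates),
    baseline_mean_log2_range = as.numeric(baseline_mean_log2_range),
    nb_dispersion = as.numeric(nb_dispersion),
    n_modules = as.integer(n_modules),
    module_size_range = as.integer(module_size_range),
    module_latent_sd = as.numeric(module_latent_sd),
    module_noise_sd = as.numeric(module_noise_sd),
    de_fraction = as.numeric(de_fraction),
    de_log2fc_range = as.numeric(de_log2fc_range),
    tf_fraction = as.numeric(tf_fraction),
    stress_go_fraction = as.numeric(stress_go_fraction),
    module_go_prob = as.numeric(module_go_prob),
    gene_length_range = as.numeric(gene_length_range),
    library_size_range = as.numeric(library_size_range),
    condition_names = condition_names,
    seed = as.integer(seed)
  )
  validate_simulation_params(p)
  if (is.null(p$condition_names)) {
    p$condition_names <- paste0("stress", seq_len(p$n_conditions))
  } else {
    p$condition_names <- as.character(p$condition_names)
    if (length(p$condition_names) != p$n_conditions ||
        anyDuplicated(p$condition_names)) {
      stop("condition_names must be ", p$n_conditions, " unique labels")
    }
  }
  structure(p, class = "SimulationParams")
}

validate_simulation_params <- function(p) {
  chk_count <- function(x, name, min = 0L) {
    if (length(x) != 1 || is.na(x) || x < min) {
      stop("invalid ", name, ": must be a count >= ", min)
    }
  }
  chk_interval <- function(x, name, lo = -Inf) {
    if (length(x) != 2 || any(is.na(x)) || x[1] > x[2] || x[1] < lo) {
      stop("invalid ", name, ": must be an interval low <= high",
           if (is.finite(lo)) paste0(" with low >= ", lo) else "")
    }
  }
  chk_frac <- function(x, name) {
    if (length(x) != 1 || is.na(x) || x < 0 || x > 1) {
      stop("invalid ", name, ": must be a proportion in [0, 1]")
    }
  }
  chk_pos <- function(x, name, strict = TRUE) {
    if (length(x) != 1 || is.na(x) || (if (strict) x <= 0 else x < 0)) {
      stop("invalid ", name, ": must be ",
           if (strict) "positive" else "nonnegative")
    }
  }
  chk_count(p$n_genes, "n_genes", 1L)
  chk_count(p$n_conditions, "n_conditions", 1L)
  if (length(p$time_points) < 1 || anyDuplicated(p$time_points)) {
    stop("invalid time_points: need >= 1 unique label")
  }
  chk_count(p$n_replicates, "n_replicates", 1L)
  chk_interval(p$baseline_mean_log2_range, "baseline_mean_log2_range")
  chk_pos(p$nb_dispersion, "nb_dispersion", strict = FALSE)
  chk_count(p$n_modules, "n_modules", 0L)
  if (p$n_modules > 0) {
    chk_interval(p$module_size_range, "module_size_range", lo = 3)
    if (p$module_size_range[2] * p$n_modules > p$n_genes) {
      stop("invalid module_size_range: upper bound x n_modules exceeds n_genes")
    }
  }
  chk_pos(p$module_latent_sd, "module_latent_sd", strict = FALSE)
  chk_pos(p$module_noise_sd, "module_noise_sd", strict = FALSE)
  chk_frac(p$de_fraction, "de_fraction")
  chk_interval(p$de_log2fc_range, "de_log2fc_range", lo = 0)
  chk_frac(p$tf_fraction, "tf_fraction")
  chk_frac(p$stress_go_fraction, "stress_go_fraction")
  chk_frac(p$module_go_prob, "module_go_prob")
  chk_interval(p$gene_length_range, "gene_length_range", lo = 1)
  chk_interval(p$library_size_range, "library_size_range", lo = 1)
  chk_count(p$seed, "seed")
  invisible(TRUE)
}

#' Stress-response GO identifier used for planted annotations
#' @export
STRESS_GO <- "GO:0050896"

# Filler GO pool so enrichment analyses have a realistic term universe.
.filler_go_pool <- sprintf("GO:%07d", c(6950, 9409, 9414, 9611, 9737,
                                        9751, 42542, 50832, 71456, 80167))

.tf_families <- c("AP2/ERF", "WRKY", "MYB", "NAC", "bZIP", "HSF")

# Per-gene RNG stream key: survives gene subsetting because each gene's
# counts depend only on (seed, gene index) and the sample layout.
.gene_seed <- function(seed, g) {
  as.integer((as.double(seed) * 7919 + as.double(g) * 104729) %% 2147483647)
}

#' Generate a synthetic multi-stress RNA-seq count experiment
#'
#' Simulates negative-binomial counts (Gamma-Poisson mixture) for a
#' multi-condition mock/treated time-course design with planted structure:
#'
#' * co-expression modules: member genes share a per-sample latent factor
#'   with gene-specific loadings; the designated hub TF carries the
#'   largest loading magnitude, so its centrality must emerge in the
#'   downstream network rather than being wired in;
#' * differential expression: selected genes receive a signed log2
#'   fold-change in the treated arms of their assigned condition;
#' * annotation: module hubs are TFs; module members carry the stress GO
#'   label (`GO:0050896`) with probability `module_go_prob`.
#'
#' @param params a `SimulationParams` object from [simulation_params()].
#' @return a list with components `experiment` (a `CountExperiment`),
#'   `annotation` (an annotation data frame, see [read_annotation()]),
#'   `truth` (a `SyntheticTruth` ledger) and `log2_expected` (the gene x
#'   sample expected log2 expression surface before count sampling).
#' @export
generate_experiment <- function(params) {
  if (!inherits(params, "SimulationParams")) {
    params <- do.call(simulation_params, as.list(params))
  }
  p <- params
  set.seed(p$seed)

  gene_ids <- sprintf("gene%05d", seq_len(p$n_genes))
  gene_lengths <- round(stats::runif(p$n_genes, p$gene_length_range[1],
                                     p$gene_length_range[2]))
  names(gene_lengths) <- gene_ids

  samples <- expand.grid(
    replicate = seq_len(p$n_replicates),
    arm = c("mock", "treated"),
    time_point = p$time_points,
    condition = p$condition_names,
    stringsAsFactors = FALSE
  )[, c("condition", "time_point", "arm", "replicate")]
  samples$sample_id <- with(samples, paste(condition, time_point, arm,
                                           paste0("r", replicate), sep = "."))
  samples <- samples[, c("sample_id", "condition", "time_point",
                         "replicate", "arm")]
  n_samp <- nrow(samples)
  lib_sizes <- exp(stats::runif(n_samp, log(p$library_size_range[1]),
                                log(p$library_size_range[2])))
  names(lib_sizes) <- samples$sample_id

  # --- planted structure ------------------------------------------------
  baseline <- stats::runif(p$n_genes, p$baseline_mean_log2_range[1],
                           p$baseline_mean_log2_range[2])

  module_membership <- rep(NA_integer_, p$n_genes)
  loadings <- rep(0, p$n_genes)
  hub_tf_of_module <- integer(0)
  if (p$n_modules > 0) {
    size_choices <- seq(p$module_size_range[1], p$module_size_range[2])
    sizes <- size_choices[sample.int(length(size_choices), p$n_modules,
                                     replace = TRUE)]
    pool <- sample.int(p$n_genes, sum(sizes))
    off <- 0L
    hub_tf_of_module <- integer(p$n_modules)
    for (m in seq_len(p$n_modules)) {
      members <- pool[(off + 1):(off + sizes[m])]
      off <- off + sizes[m]
      module_membership[members] <- m
      # Positive loadings model a co-induced stress regulon; magnitudes
      # must dominate the NB count noise for pairs to clear correlation
      # thresholds near 0.9. The hub carries the largest loading.
      # Loading spread makes hub centrality emerge in the thresholded
      # network: pairwise correlation behaves like sqrt(h_i h_j) with
      # h the communality, so the hub (largest loading) keeps edges to
      # weak members that weak members lose among themselves.
      load_m <- stats::runif(sizes[m], 0.9, 1.3)
      hub_local <- sample.int(sizes[m], 1)
      load_m[hub_local] <- 2.8
      loadings[members] <- load_m
      hub_tf_of_module[m] <- members[hub_local]
    }
  }

  tf_idx <- which(stats::runif(p$n_genes) < p$tf_fraction)
  tf_idx <- sort(union(tf_idx, hub_tf_of_module))
  tf_family <- rep(NA_character_, p$n_genes)
  tf_family[tf_idx] <- sample(.tf_families, length(tf_idx), replace = TRUE)

  in_module <- !is.na(module_membership)
  go_flag <- logical(p$n_genes)
  go_flag[in_module] <- stats::runif(sum(in_module)) < p$module_go_prob
  go_flag[!in_module] <- stats::runif(sum(!in_module)) < p$stress_go_fraction

  # DE assignment: per condition, a fixed gene set planted at every time
  # point of that condition's treated arm. Module members are always
  # part of the response (coherently up-regulated, so the regulon's
  # co-expression survives the mock/treated contrast); de_fraction
  # controls additional background DE genes with random signs.
  de_genes <- list()
  de_add <- matrix(0, p$n_genes, n_samp)
  module_idx <- which(!is.na(module_membership))
  n_de <- round(p$de_fraction * p$n_genes)
  n_tp <- length(p$time_points)
  for (ci in seq_len(p$n_conditions)) {
    cond <- p$condition_names[ci]
    # Members respond through the module axis at every time point:
    # treated arms shift the regulon's activity by one latent-sd unit,
    # so each member's planted log2FC equals its loading. The response
    # and the co-expression structure then share a single factor with
    # spread communalities instead of two competing shared factors.
    per_tp_idx <- rep(list(integer(0)), n_tp)
    per_tp_lfc <- rep(list(numeric(0)), n_tp)
    if (length(module_idx)) {
      for (ti in seq_len(n_tp)) {
        per_tp_idx[[ti]] <- module_idx
        per_tp_lfc[[ti]] <- loadings[module_idx]
      }
    }
    if (n_de > 0) {
      # Background DE genes have gene-specific kinetics: each responds
      # at a random nonempty subset of time points, so the background
      # response is incoherent across genes (early/late/transient
      # responders) rather than one synchronized block.
      bg_pool <- setdiff(seq_len(p$n_genes), module_idx)
      bg <- sample(bg_pool, min(n_de, length(bg_pool)))
      bg_lfc <- stats::runif(length(bg), p$de_log2fc_range[1],
                             p$de_log2fc_range[2]) *
        sample(c(-1, 1), length(bg), replace = TRUE)
      for (bi in seq_along(bg)) {
        resp <- which(stats::runif(n_tp) < 0.6)
        if (!length(resp)) resp <- sample.int(n_tp, 1)
        for (ti in resp) {
          per_tp_idx[[ti]] <- c(per_tp_idx[[ti]], bg[bi])
          per_tp_lfc[[ti]] <- c(per_tp_lfc[[ti]], bg_lfc[bi])
        }
      }
    }
    for (ti in seq_len(n_tp)) {
      tp <- p$time_points[ti]
      idx <- per_tp_idx[[ti]]
      lfc <- per_tp_lfc[[ti]]
      o <- order(idx)
      idx <- idx[o]
      lfc <- lfc[o]
      cols_tt <- which(samples$condition == cond &
                         samples$time_point == tp &
                         samples$arm == "treated")
      de_add[idx, cols_tt] <- de_add[idx, cols_tt, drop = FALSE] + lfc
      de_genes[[paste(cond, tp, sep = "|")]] <-
        data.frame(gene_id = gene_ids[idx], log2fc = lfc,
                   stringsAsFactors = FALSE)
    }
  }

  # Module latent factors: one draw per (module, condition, time point),
  # shared by both arms and all replicates of that group. Regulon
  # activity then varies along the time course -- driving co-expression
  # across all of a condition's samples -- while cancelling out of the
  # mock/treated contrast, so planted DE stays detectable for module
  # members.
  grp <- paste(samples$condition, samples$time_point, sep = "\r")
  grp_levels <- unique(grp)
  grp_cond <- samples$condition[match(grp_levels, grp)]
  latent <- if (p$n_modules > 0) {
    lat_g <- matrix(stats::rnorm(p$n_modules * length(grp_levels)),
                    p$n_modules, length(grp_levels))
    # Standardize realized draws within each condition so the factor's
    # realized variance equals module_latent_sd^2 exactly: with only a
    # handful of time points per condition, raw draws would make module
    # co-expression strength fluctuate wildly between runs.
    for (cc in unique(grp_cond)) {
      cols_c <- which(grp_cond == cc)
      if (length(cols_c) >= 2) {
        v <- lat_g[, cols_c, drop = FALSE]
        mu_v <- rowMeans(v)
        sd_v <- sqrt(rowMeans((v - mu_v)^2))
        sd_v[sd_v == 0] <- 1
        lat_g[, cols_c] <- (v - mu_v) / sd_v * p$module_latent_sd
      } else {
        lat_g[, cols_c] <- lat_g[, cols_c, drop = FALSE] *
          p$module_latent_sd
      }
    }
    lat_g[, match(grp, grp_levels), drop = FALSE]
  } else {
    matrix(0, 0, n_samp)
  }
  noise <- matrix(0, p$n_genes, n_samp)
  if (any(in_module) && p$module_noise_sd > 0) {
    noise[in_module, ] <- stats::rnorm(sum(in_module) * n_samp, 0,
                                       p$module_noise_sd)
  }

  # log2 expected expression per gene x sample
  log2_expr <- matrix(baseline, p$n_genes, n_samp)
  if (any(in_module)) {
    log2_expr[in_module, ] <- log2_expr[in_module, ] +
      loadings[in_module] * latent[module_membership[in_module], ,
                                   drop = FALSE] +
      noise[in_module, , drop = FALSE]
  }
  log2_expr <- log2_expr + de_add

  # Expected counts: mu = expression * (length/1kb) * (library/1e6), i.e.
  # the planted log2 expression behaves like a log2 FPKM.
  mu <- 2^log2_expr *
    (gene_lengths / 1000) *
    rep(lib_sizes / 1e6, each = p$n_genes)

  counts <- matrix(0L, p$n_genes, n_samp,
                   dimnames = list(gene_ids, samples$sample_id))
  alpha <- p$nb_dispersion
  for (g in seq_len(p$n_genes)) {
    set.seed(.gene_seed(p$seed, g))
    lam <- if (alpha > 0) {
      stats::rgamma(n_samp, shape = 1 / alpha, scale = alpha * mu[g, ])
    } else {
      mu[g, ]
    }
    counts[g, ] <- stats::rpois(n_samp, lam)
  }

  experiment <- count_experiment(counts, samples, gene_lengths)

  go_terms <- character(p$n_genes)
  set.seed(.gene_seed(p$seed, 0L))
  n_extra <- sample(0:2, p$n_genes, replace = TRUE)
  for (g in seq_len(p$n_genes)) {
    terms <- if (n_extra[g] > 0) sample(.filler_go_pool, n_extra[g]) else
      character(0)
    if (go_flag[g]) terms <- c(STRESS_GO, terms)
    go_terms[g] <- paste(sort(terms), collapse = ";")
  }
  annotation <- data.frame(
    gene_id = gene_ids,
    length_bp = as.integer(gene_lengths),
    is_tf = as.integer(seq_len(p$n_genes) %in% tf_idx),
    tf_family = ifelse(is.na(tf_family), "", tf_family),
    go_terms = go_terms,
    stringsAsFactors = FALSE
  )

  mm <- module_membership
  names(mm) <- gene_ids
  hubs <- gene_ids[hub_tf_of_module]
  if (length(hubs)) names(hubs) <- as.character(seq_along(hubs))
  truth <- structure(list(
    module_membership = mm[!is.na(mm)],
    hub_tf_of_module = hubs,
    de_genes = de_genes,
    go_annotated = gene_ids[go_flag],
    tf_genes = gene_ids[tf_idx]
  ), class = "SyntheticTruth")
  stopifnot(all(truth$hub_tf_of_module %in% truth$tf_genes))

  # log2_expected is the deterministic-plus-Gaussian expression surface
  # before count sampling; useful for checking the planted correlation
  # structure without NB discretization noise.
  dimnames(log2_expr) <- dimnames(counts)
  list(experiment = experiment, annotation = annotation, truth = truth,
       log2_expected = log2_expr)
}

#' Construct a CountExperiment container
#'
#' @param counts integer matrix, genes x samples, with gene ids as row
#'   names and sample ids as column names.
#' @param samples data frame with columns `sample_id`, `condition`,
#'   `time_point`, `replicate`, `arm` (one row per counts column).
#' @param gene_lengths named numeric vector of gene lengths in bp.
#' @return an object of class `CountExperiment`.
#' @export
count_experiment <- function(counts, samples, gene_lengths) {
  counts <- as.matrix(counts)
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      is.null(colnames(counts))) {
    stop("counts must have gene row names and sample column names")
  }
  if (is.null(rownames(counts))) rownames(counts) <- character(0)
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids in counts")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids in counts")
  req <- c("sample_id", "condition", "time_point", "replicate", "arm")
  miss <- setdiff(req, names(samples))
  if (length(miss)) stop("samples table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!setequal(samples$sample_id, colnames(counts)) ||
      anyDuplicated(samples$sample_id)) {
    stop("samples$sample_id must match counts columns one-to-one")
  }
  samples <- samples[match(colnames(counts), samples$sample_id), req,
                     drop = FALSE]
  rownames(samples) <- NULL
  if (!all(samples$arm %in% c("mock", "treated"))) {
    stop("arm must be 'mock' or 'treated'")
  }
  gl <- gene_lengths[rownames(counts)]
  if (anyNA(gl)) {
    stop("missing gene length for gene(s): ",
         paste(utils::head(rownames(counts)[is.na(gl)], 3), collapse = ", "))
  }
  if (any(gl < 1)) stop("all gene lengths must be >= 1 bp")
  if (any(counts < 0)) stop("counts must be nonnegative")
  structure(list(counts = counts, samples = samples,
                 gene_lengths = gl),
            class = "CountExperiment")
}

#' @export
print.CountExperiment <- function(x, ...) {
  cat("CountExperiment:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples\n")
  cat("  conditions:", paste(unique(x$samples$condition), collapse = ", "),
      "\n")
  cat("  time points:", paste(unique(x$samples$time_point), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
print.SyntheticTruth <- function(x, ...) {
  cat("SyntheticTruth:", length(unique(x$module_membership)), "modules,",
      length(x$tf_genes), "TFs,", length(x$go_annotated),
      "GO-labelled genes\n")
  invisible(x)
}

#' Write a synthetic experiment to disk
#'
#' Emits `counts.tsv`, `samples.tsv`, `annotation.tsv` and `truth.json`
#' into `directory`. The TSV files round-trip losslessly through
#' [read_counts()], [read_samples()] and [read_annotation()]; the truth
#' ledger round-trips through [read_truth()].
#'
#' @param experiment a `CountExperiment`.
#' @param annotation annotation data frame.
#' @param truth a `SyntheticTruth` ledger (or `NULL` to skip).
#' @param directory output directory, created if absent.
#' @return invisibly, the vector of file paths written.
#' @export
write_experiment <- function(experiment, annotation, truth, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  paths <- c(counts = file.path(directory, "counts.tsv"),
             samples = file.path(directory, "samples.tsv"),
             annotation = file.path(directory, "annotation.tsv"),
             truth = file.path(directory, "truth.json"))
  rn <- rownames(experiment$counts)
  if (is.null(rn)) rn <- character(0)
  cts <- data.frame(gene_id = rn,
                    experiment$counts, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write_tsv_file(cts, paths["counts"])
  write_tsv_file(experiment$samples, paths["samples"])
  write_tsv_file(annotation, paths["annotation"])
  if (!is.null(truth)) {
    tr <- list(
      module_membership = as.list(truth$module_membership),
      hub_tf_of_module = as.list(truth$hub_tf_of_module),
      de_genes = truth$de_genes,
      go_annotated = truth$go_annotated,
      tf_genes = truth$tf_genes
    )
    jsonlite::write_json(tr, paths["truth"], auto_unbox = TRUE, digits = NA)
  } else {
    paths <- paths[names(paths) != "truth"]
  }
  invisible(paths)
}

#' Read a synthetic-truth ledger written by [write_experiment()]
#' @param path path to `truth.json`.
#' @return a `SyntheticTruth` object.
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) stop("truth file not found: ", path)
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  de <- lapply(tr$de_genes, function(d) {
    if (is.null(d) || length(d) == 0 || NROW(d) == 0) {
      data.frame(gene_id = character(0), log2fc = numeric(0))
    } else {
      data.frame(gene_id = as.character(d$gene_id),
                 log2fc = as.numeric(d$log2fc), stringsAsFactors = FALSE)
    }
  })
  structure(list(
    module_membership = unlist(tr$module_membership),
    hub_tf_of_module = unlist(tr$hub_tf_of_module),
    de_genes = de,
    go_annotated = as.character(unlist(tr$go_annotated)),
    tf_genes = as.character(unlist(tr$tf_genes))
  ), class = "SyntheticTruth")
}
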