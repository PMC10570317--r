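#' Median-of-ratios size factors
#'
#' DESeq-style normalization: for each sample, the size factor is the
#' median across genes (restricted to genes with an all-positive row,
#' hence a positive geometric mean) of the ratio count / geometric mean.
#' Factors are rescaled to have geometric mean 1. If no gene has positive
#' counts in every sample the method falls back to total-count ratios,
#' with a warning.
#'
#' @param counts gene x sample count matrix.
#' @return positive numeric vector of per-sample size factors.
#' @export
estimate_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  ok <- rowSums(counts <= 0) == 0
  if (!any(ok)) {
    warning("no gene with all-positive counts; ",
            "falling back to total-count size factors")
    sf <- colSums(counts)
    if (any(sf == 0)) stop("sample with zero total count")
  } else {
    logc <- log(counts[ok, , drop = FALSE])
    log_geo <- rowMeans(logc)
    sf <- apply(exp(logc - log_geo), 2, stats::median)
  }
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(counts))
}

#' Method-of-moments negative-binomial dispersion
#'
#' Per-gene dispersion `alpha` such that Var = mu + alpha * mu^2,
#' estimated on size-factor-normalized counts after removing the arm-mean
#' difference (so planted treatment effects do not inflate the variance):
#' `alpha = max((var - mu) / mu^2, alpha_min)`.
#'
#' @param counts gene x sample count matrix.
#' @param size_factors per-sample size factors.
#' @param arms factor/character of length `ncol(counts)` giving the arm of
#'   each sample; the arm mean is removed before pooling residuals.
#' @param alpha_min dispersion floor (default 1e-8).
#' @return per-gene numeric vector of dispersions.
#' @export
estimate_dispersion <- function(counts, size_factors, arms = NULL,
                                alpha_min = 1e-8) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 3) stop("dispersion estimation needs >= 3 samples")
  y <- sweep(counts, 2, size_factors, "/")
  mu <- rowMeans(y)
  if (is.null(arms)) arms <- rep("all", ncol(counts))
  arms <- as.character(arms)
  resid <- y
  df_lost <- 0L
  for (a in unique(arms)) {
    cols <- arms == a
    resid[, cols] <- y[, cols, drop = FALSE] -
      rowMeans(y[, cols, drop = FALSE])
    df_lost <- df_lost + 1L
  }
  df <- ncol(counts) - df_lost
  v <- rowSums(resid^2) / max(df, 1L)
  alpha <- (v - mu) / mu^2
  alpha[!is.finite(alpha)] <- alpha_min
  pmax(alpha, alpha_min)
}

#' Negative-binomial Wald test for one gene
#'
#' Compares treated versus mock normalized means. The log2 fold-change is
#' `log2((mean_t + c) / (mean_m + c))` with pseudocount `c` (default 0.5
#' normalized counts). The Wald statistic is the difference of log means
#' with the NB variance `mu + alpha mu^2` propagated by the delta method;
#' the p-value is two-sided from a t reference with
#' `n_t + n_m - 2` degrees of freedom (the moment-based variance estimate
#' makes the normal reference anticonservative at small replicate
#' numbers).
#'
#' @param treated,mock raw count vectors for the two arms.
#' @param sf_treated,sf_mock size factors matching the two vectors.
#' @param dispersion NB dispersion alpha for this gene.
#' @param pseudocount offset `c` in normalized-count units.
#' @return list with `log2fc` and `p_value`. An all-zero gene in both
#'   arms returns `log2fc = 0, p = 1`.
#' @export
test_gene <- function(treated, mock, sf_treated, sf_mock, dispersion,
                      pseudocount = 0.5) {
  if (all(treated == 0) && all(mock == 0)) {
    return(list(log2fc = 0, p_value = 1))
  }
  yt <- treated / sf_treated
  ym <- mock / sf_mock
  mt <- mean(yt)
  mm <- mean(ym)
  log2fc <- log2((mt + pseudocount) / (mm + pseudocount))
  # Var(count_s) = mu_s + alpha mu_s^2 with mu_s = arm mean x sf_s;
  # Var(normalized mean) = sum Var(count_s)/sf_s^2 / n^2, then delta
  # method onto the log scale.
  var_mean <- function(m, sf) {
    mu_s <- m * sf
    sum((mu_s + dispersion * mu_s^2) / sf^2) / length(sf)^2
  }
  vt <- var_mean(mt, sf_treated) / (mt + pseudocount)^2
  vm <- var_mean(mm, sf_mock) / (mm + pseudocount)^2
  se <- sqrt(vt + vm)
  if (se == 0) return(list(log2fc = log2fc, p_value = 1))
  z <- (log(mt + pseudocount) - log(mm + pseudocount)) / se
  df <- max(length(treated) + length(mock) - 2L, 1L)
  p <- 2 * stats::pt(-abs(z), df = df)
  list(log2fc = log2fc, p_value = min(p, 1))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement; the output
#' preserves the input order. Ties are handled by the stable ordering of
#' the sort.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return numeric vector of BH-adjusted p-values (FDR).
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  n <- length(p)
  if (n == 0) return(numeric(0))
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

#' Call differentially expressed genes for one condition
#'
#' For each time point of `condition`, the treated replicates are tested
#' against the matching mock replicates: size factors and dispersions are
#' estimated on that comparison's samples only, each gene gets an NB Wald
#' test, and p-values are BH-adjusted within the comparison. A gene is a
#' DEG of the condition if it passes `|log2fc| > log2fc_cutoff` and
#' `fdr < fdr_cutoff` at any time point.
#'
#' @param experiment a `CountExperiment`.
#' @param condition condition label to test.
#' @param log2fc_cutoff fold-change cutoff (default 1; an alternative
#'   convention of 2 is sometimes used and can be supplied here).
#' @param fdr_cutoff FDR cutoff (default 0.05).
#' @return a `DegTable`: data frame with columns `gene_id`, `condition`,
#'   `time_point`, `log2fc`, `p_value`, `fdr`, `is_deg`, plus the
#'   thresholds as attributes `log2fc_cutoff` / `fdr_cutoff`.
#' @export
call_degs <- function(experiment, condition, log2fc_cutoff = 1,
                      fdr_cutoff = 0.05) {
  stopifnot(inherits(experiment, "CountExperiment"))
  smp <- experiment$samples
  if (!condition %in% smp$condition) {
    stop("unknown condition: ", condition)
  }
  tps <- unique(smp$time_point[smp$condition == condition])
  rows <- vector("list", length(tps))
  for (i in seq_along(tps)) {
    tp <- tps[i]
    sel_t <- smp$condition == condition & smp$time_point == tp &
      smp$arm == "treated"
    sel_m <- smp$condition == condition & smp$time_point == tp &
      smp$arm == "mock"
    if (!any(sel_m) || !any(sel_t)) {
      stop("condition ", condition, " time point ", tp,
           " lacks a ", if (!any(sel_m)) "mock" else "treated", " arm")
    }
    cols <- which(sel_t | sel_m)
    sub <- experiment$counts[, cols, drop = FALSE]
    sf <- estimate_size_factors(sub)
    arms <- smp$arm[cols]
    alpha <- estimate_dispersion(sub, sf, arms = arms)
    t_idx <- arms == "treated"
    res <- matrix(0, nrow(sub), 2)
    for (g in seq_len(nrow(sub))) {
      r <- test_gene(sub[g, t_idx], sub[g, !t_idx],
                     sf[t_idx], sf[!t_idx], alpha[g])
      res[g, ] <- c(r$log2fc, r$p_value)
    }
    fdr <- bh_adjust(res[, 2])
    rows[[i]] <- data.frame(
      gene_id = rownames(sub), condition = condition, time_point = tp,
      log2fc = res[, 1], p_value = res[, 2], fdr = fdr,
      is_deg = abs(res[, 1]) > log2fc_cutoff & fdr < fdr_cutoff,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "log2fc_cutoff") <- log2fc_cutoff
  attr(out, "fdr_cutoff") <- fdr_cutoff
  class(out) <- c("DegTable", "data.frame")
  out
}

#' Extract the DEG set of a condition from a DegTable
#'
#' @param deg_table a `DegTable` from [call_degs()] (rows may span several
#'   conditions if tables were row-bound).
#' @param condition optional condition label; default: all rows.
#' @return character vector of gene ids flagged `is_deg` at any time
#'   point.
#' @export
deg_set <- function(deg_table, condition = NULL) {
  d <- deg_table
  if (!is.null(condition)) d <- d[d$condition == condition, , drop = FALSE]
  sort(unique(d$gene_id[d$is_deg]))
}

#' Exclusive Venn partition of per-condition DEG sets
#'
#' For every nonempty subset S of conditions, counts the genes that are
#' DEGs in exactly the conditions of S (the cells of a Venn diagram).
#'
#' @param deg_sets named list mapping condition label to character vector
#'   of DEG ids (>= 2 conditions, <= 8).
#' @return a `VennPartition`: data frame with columns `subset`
#'   (ampersand-joined condition labels), `conditions` (list column) and
#'   `count`; attribute `universe_size` holds the union size.
#' @export
venn_partition <- function(deg_sets) {
  k <- length(deg_sets)
  if (k < 2) stop("venn_partition needs >= 2 condition sets")
  if (k > 8) stop("venn_partition supports at most 8 conditions")
  if (is.null(names(deg_sets)) || anyDuplicated(names(deg_sets))) {
    stop("deg_sets must have unique names")
  }
  conds <- names(deg_sets)
  universe <- sort(unique(unlist(deg_sets, use.names = FALSE)))
  member <- vapply(deg_sets, function(s) universe %in% s,
                   logical(length(universe)))
  member <- matrix(member, nrow = length(universe), ncol = k,
                   dimnames = list(universe, conds))
  # classify each gene by its exact membership pattern
  pattern <- if (length(universe)) {
    apply(member, 1, function(r) paste(which(r), collapse = ","))
  } else {
    character(0)
  }
  subsets <- lapply(seq_len(2^k - 1), function(code) {
    which(bitwAnd(code, 2^(seq_len(k) - 1)) > 0)
  })
  counts <- vapply(subsets, function(idx) {
    sum(pattern == paste(idx, collapse = ","))
  }, integer(1))
  out <- data.frame(
    subset = vapply(subsets, function(i) paste(conds[i], collapse = "&"),
                    character(1)),
    count = counts, stringsAsFactors = FALSE
  )
  out$conditions <- lapply(subsets, function(i) conds[i])
  stopifnot(sum(out$count) == length(universe))
  attr(out, "universe_size") <- length(universe)
  class(out) <- c("VennPartition", "data.frame")
  out
}
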