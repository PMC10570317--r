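#' Read a gene annotation table
#'
#' Expects a TSV with columns `gene_id`, `length_bp`, `is_tf` (0/1),
#' `tf_family` and `go_terms` (semicolon-separated GO identifiers of the
#' form `GO:` followed by seven digits; may be empty).
#'
#' @param path path to the annotation TSV.
#' @return a data frame (class `AnnotationTable`, `data.frame`).
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  ann <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  req <- c("gene_id", "length_bp", "is_tf", "tf_family", "go_terms")
  miss <- setdiff(req, names(ann))
  if (length(miss)) {
    stop("annotation missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(ann$gene_id)) {
    stop("duplicate gene id(s) in annotation: ",
         paste(utils::head(unique(ann$gene_id[duplicated(ann$gene_id)]), 3),
               collapse = ", "))
  }
  ann$length_bp <- as.integer(ann$length_bp)
  ann$is_tf <- as.integer(ann$is_tf)
  if (anyNA(ann$length_bp) || any(ann$length_bp < 1)) {
    stop("gene lengths must be integers >= 1")
  }
  ann$go_terms[is.na(ann$go_terms)] <- ""
  terms <- .split_semi(ann$go_terms)
  bad <- vapply(terms, function(tt) {
    tt <- tt[nzchar(tt)]
    any(!grepl("^GO:[0-9]{7}$", tt))
  }, logical(1))
  if (any(bad)) {
    stop("malformed GO id(s) at line(s): ",
         paste(utils::head(which(bad) + 1L, 5), collapse = ", "),
         " (expected GO: followed by 7 digits)")
  }
  class(ann) <- c("AnnotationTable", "data.frame")
  ann
}

#' Genes carrying a stress-related GO term
#'
#' @param annotation annotation data frame.
#' @param filter_terms nonempty character vector of GO ids; default the
#'   response-to-stimulus category `GO:0050896`.
#' @return sorted character vector of gene ids whose annotation
#'   intersects `filter_terms`.
#' @export
stress_go_filter <- function(annotation, filter_terms = STRESS_GO) {
  if (!length(filter_terms)) stop("filter_terms must be nonempty")
  hit <- .node_has_go(annotation$go_terms, filter_terms)
  sort(annotation$gene_id[hit])
}

#' GO over-representation analysis
#'
#' Tests each GO term for over-representation of `gene_set` within
#' `background`. Two methods:
#'
#' * `hypergeometric`: one-sided hypergeometric tail
#'   `P(X >= k)` with `k` hits in the set, `K` hits in the background,
#'   set size `n`, background size `N`;
#' * `length_weighted`: accounts for gene-length selection bias in the
#'   spirit of length-aware RNA-seq enrichment methods. A logistic
#'   regression of set membership on log gene length gives per-gene
#'   sampling weights; the null distribution of `k` is obtained by
#'   Monte-Carlo draws of weighted gene sets of size `n` (seeded), and
#'   the p-value is the (add-one) fraction of draws with at least `k`
#'   hits.
#'
#' P-values are BH-adjusted across terms.
#'
#' @param gene_set character vector of genes of interest (subset of
#'   `background`).
#' @param background character vector of background genes (subset of the
#'   annotated genes).
#' @param annotation annotation data frame.
#' @param method `"hypergeometric"` (default) or `"length_weighted"`.
#' @param n_draws Monte-Carlo draws for `length_weighted` (default
#'   10000).
#' @param seed seed for the Monte-Carlo null.
#' @return data frame with columns `go_id`, `k`, `K`, `n`, `N`,
#'   `p_value`, `fdr`, sorted by p-value.
#' @export
enrich <- function(gene_set, background, annotation,
                   method = c("hypergeometric", "length_weighted"),
                   n_draws = 10000L, seed = 1L) {
  method <- match.arg(method)
  if (!length(gene_set)) stop("gene_set must be nonempty")
  if (!all(gene_set %in% background)) {
    stop("gene_set must be a subset of background")
  }
  if (!all(background %in% annotation$gene_id)) {
    stop("background must be a subset of annotated genes")
  }
  ann <- annotation[match(background, annotation$gene_id), , drop = FALSE]
  terms_by_gene <- .split_semi(ann$go_terms)
  terms_by_gene <- lapply(terms_by_gene, function(t) t[nzchar(t)])
  all_terms <- sort(unique(unlist(terms_by_gene)))
  if (!length(all_terms)) {
    return(data.frame(go_id = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p_value = numeric(0),
                      fdr = numeric(0)))
  }
  in_set <- background %in% gene_set
  N <- length(background)
  n <- sum(in_set)
  gene_term <- data.frame(
    gene = rep(seq_len(N), lengths(terms_by_gene)),
    term = unlist(terms_by_gene), stringsAsFactors = FALSE
  )
  K_tab <- table(factor(gene_term$term, levels = all_terms))
  k_tab <- table(factor(gene_term$term[in_set[gene_term$gene]],
                        levels = all_terms))
  K <- as.integer(K_tab)
  k <- as.integer(k_tab)

  if (method == "hypergeometric") {
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  } else {
    len <- log(ann$length_bp)
    fit <- suppressWarnings(
      stats::glm(in_set ~ len, family = stats::binomial()))
    w <- stats::fitted(fit)
    w <- pmax(w, 1e-10)
    set.seed(seed)
    hit_counts <- matrix(0L, n_draws, length(all_terms))
    term_by_gene_idx <- lapply(seq_len(N), function(g) {
      match(terms_by_gene[[g]], all_terms)
    })
    for (d in seq_len(n_draws)) {
      draw <- sample.int(N, n, prob = w)
      t_idx <- unlist(term_by_gene_idx[draw])
      if (length(t_idx)) {
        tb <- tabulate(t_idx, nbins = length(all_terms))
        hit_counts[d, ] <- tb
      }
    }
    p <- (1 + colSums(hit_counts >= rep(k, each = n_draws))) / (n_draws + 1)
  }
  out <- data.frame(go_id = all_terms, k = k, K = K, n = n, N = N,
                    p_value = as.numeric(p), stringsAsFactors = FALSE)
  out$fdr <- bh_adjust(out$p_value)
  out <- out[order(out$p_value, out$go_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
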