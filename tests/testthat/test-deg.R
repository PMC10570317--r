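test_that("size factors: identity, exact scaling, median-of-ratios oracle", {
  set.seed(41)
  base <- matrix(rpois(200 * 2, 60) + 1, 200, 2,
                 dimnames = list(sprintf("g%03d", 1:200), c("a", "b")))
  base[, 2] <- base[, 1]
  expect_equal(unname(estimate_size_factors(base)), c(1, 1))

  doubled <- cbind(a = base[, 1], b = base[, 1] * 2L)
  sf <- estimate_size_factors(doubled)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  counts <- matrix(rpois(200 * 6, 80) + 1, 200, 6,
                   dimnames = list(sprintf("g%03d", 1:200),
                                   sprintf("s%d", 1:6)))
  sf <- estimate_size_factors(counts)
  geo <- exp(rowMeans(log(counts)))
  oracle <- apply(counts / geo, 2, median)
  oracle <- oracle / exp(mean(log(oracle)))
  expect_equal(sf, oracle)
})

test_that("size factors fall back to totals when no all-positive gene exists", {
  counts <- matrix(c(0, 5, 10, 0), 2, 2,
                   dimnames = list(c("g1", "g2"), c("a", "b")))
  expect_warning(sf <- estimate_size_factors(counts), "total-count")
  expect_equal(exp(mean(log(sf))), 1)
})

test_that("dispersion estimation: floor at Poisson, recovery of known alpha", {
  set.seed(42)
  # Poisson genes hit the floor
  pois <- matrix(rpois(50 * 40, 100), 50, 40,
                 dimnames = list(sprintf("g%02d", 1:50),
                                 sprintf("s%02d", 1:40)))
  a <- estimate_dispersion(pois, rep(1, 40))
  expect_gte(min(a), 1e-8)
  expect_lt(median(a), 0.02)
  # constant gene at floor
  const <- matrix(7L, 2, 10,
                  dimnames = list(c("g1", "g2"), sprintf("s%d", 1:10)))
  expect_equal(unname(estimate_dispersion(const, rep(1, 10))), rep(1e-8, 2))
  # NB genes with alpha = 0.2 recovered in order of magnitude
  n <- 50
  mu <- 200
  nb <- t(replicate(300, rpois(n, rgamma(n, shape = 5, scale = mu / 5))))
  dimnames(nb) <- list(sprintf("g%03d", 1:300), sprintf("s%02d", 1:n))
  a <- estimate_dispersion(nb, rep(1, n))
  expect_gt(median(a), 0.1)
  expect_lt(median(a), 0.3)
})

test_that("test_gene conventions: null identity and all-zero genes", {
  sf <- rep(1, 10)
  r0 <- test_gene(rep(0, 5), rep(0, 5), sf[1:5], sf[6:10], 0.1)
  expect_equal(r0$log2fc, 0)
  expect_equal(r0$p_value, 1)
  same <- c(30, 31, 29, 30, 30)
  r1 <- test_gene(same, same, sf[1:5], sf[6:10], 0.1)
  expect_equal(r1$log2fc, 0)
  expect_gt(r1$p_value, 0.9)
})

test_that("Wald p-values agree with a permutation oracle on null genes", {
  set.seed(43)
  n <- 5
  n_genes <- 100
  alpha <- 0.1
  mu <- exp(runif(n_genes, log(50), log(500)))
  counts <- matrix(rpois(n_genes * 2 * n,
                         rgamma(n_genes * 2 * n, shape = 1 / alpha,
                                scale = alpha * rep(mu, 2 * n))),
                   n_genes, 2 * n)
  sf <- rep(1, 2 * n)
  arms <- rep(c("mock", "treated"), each = n)
  dimnames(counts) <- list(sprintf("g%03d", seq_len(n_genes)),
                           sprintf("s%02d", seq_len(2 * n)))
  disp <- estimate_dispersion(counts, sf, arms = arms)
  splits <- combn(2 * n, n)
  p_wald <- p_perm <- numeric(n_genes)
  for (g in seq_len(n_genes)) {
    y <- counts[g, ]
    p_wald[g] <- test_gene(y[arms == "treated"], y[arms == "mock"],
                           sf[1:n], sf[1:n], disp[g])$p_value
    obs <- abs(log2((mean(y[arms == "treated"]) + 0.5) /
                      (mean(y[arms == "mock"]) + 0.5)))
    stats_perm <- apply(splits, 2, function(idx) {
      abs(log2((mean(y[idx]) + 0.5) / (mean(y[-idx]) + 0.5)))
    })
    p_perm[g] <- mean(stats_perm >= obs - 1e-12)
  }
  # the two null distributions must agree in rank and in calibration
  expect_gt(cor(p_wald, p_perm, method = "spearman"), 0.8)
  expect_lt(abs(mean(p_wald < 0.2) - mean(p_perm < 0.2)), 0.12)
})

test_that("BH adjustment matches the step-up definition and stats::p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(44)
  for (i in 1:25) {
    p <- runif(sample(1:200, 1))
    expect_equal(bh_adjust(p), p.adjust(p, method = "BH"))
  }
  # monotone: sorting by p sorts fdr non-decreasingly
  p <- runif(100)
  f <- bh_adjust(p)
  expect_true(all(diff(f[order(p)]) >= -1e-15))
})

test_that("call_degs applies thresholds and unions over time points", {
  sim <- small_sim()
  dt <- call_degs(sim$experiment, "stress1", log2fc_cutoff = 1,
                  fdr_cutoff = 0.05)
  expect_s3_class(dt, "DegTable")
  expect_identical(dt$is_deg, abs(dt$log2fc) > 1 & dt$fdr < 0.05)
  # within each comparison fdr is the BH transform of p
  for (tp in unique(dt$time_point)) {
    d <- dt[dt$time_point == tp, ]
    expect_equal(d$fdr, bh_adjust(d$p_value))
  }
  # deg_set is the union over time points
  expect_setequal(deg_set(dt),
                  unique(dt$gene_id[dt$is_deg]))
  # boundary: |log2fc| exactly below cutoff is not a DEG
  expect_false(any(dt$is_deg[abs(dt$log2fc) <= 1]))
  expect_error(call_degs(sim$experiment, "nope"), "unknown condition")
})

test_that("DEG calls recover planted truth on synthetic data", {
  p <- simulation_params(n_genes = 400, n_conditions = 1, seed = 19,
                         de_log2fc_range = c(2, 2), n_replicates = 5)
  sim <- generate_experiment(p)
  called <- deg_set(call_degs(sim$experiment, "stress1"))
  truth <- unique(unlist(lapply(sim$truth$de_genes, function(d) d$gene_id)))
  expect_gte(mean(truth %in% called), 0.8)
  expect_lte(mean(!called %in% truth), 0.1)
})

test_that("log2fc estimates are invariant to scaling one sample", {
  sim <- small_sim()
  exp1 <- sim$experiment
  scaled <- exp1$counts
  scaled[, 3] <- scaled[, 3] * 3L
  exp2 <- count_experiment(scaled, exp1$samples, exp1$gene_lengths)
  d1 <- call_degs(exp1, "stress1")
  d2 <- call_degs(exp2, "stress1")
  expect_equal(d1$log2fc, d2$log2fc, tolerance = 0.02)
})

test_that("venn partition matches brute-force membership counting", {
  sets <- list(A = c("g1", "g2"), B = c("g2", "g3"))
  vp <- venn_partition(sets)
  get <- function(s) vp$count[vp$subset == s]
  expect_equal(get("A"), 1L)
  expect_equal(get("B"), 1L)
  expect_equal(get("A&B"), 1L)

  disjoint <- venn_partition(list(A = c("x1"), B = c("x2"), C = c("x3")))
  expect_equal(disjoint$count[disjoint$subset %in% c("A&B", "A&C", "B&C",
                                                     "A&B&C")],
               rep(0L, 4))

  set.seed(45)
  genes <- sprintf("g%04d", 1:1000)
  sets4 <- setNames(lapply(1:4, function(i) {
    sample(genes, sample(100:400, 1))
  }), LETTERS[1:4])
  vp4 <- venn_partition(sets4)
  expect_equal(sum(vp4$count), length(unique(unlist(sets4))))
  for (i in seq_len(nrow(vp4))) {
    inside <- vp4$conditions[[i]]
    outside <- setdiff(names(sets4), inside)
    members <- Reduce(intersect, sets4[inside])
    for (o in outside) members <- setdiff(members, sets4[[o]])
    expect_identical(vp4$count[i], length(members))
  }
  expect_error(venn_partition(sets4[1]), ">= 2")
  expect_error(venn_partition(setNames(rep(list("g"), 9), letters[1:9])),
               "at most 8")
})
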