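random_toy_network <- function(seed, condition, n_nodes = 30,
                               n_edges = 40) {
  set.seed(seed)
  ids <- sprintf("g%03d", sort(sample(1:60, n_nodes)))
  pairs <- t(combn(ids, 2))
  pick <- sample(nrow(pairs), min(n_edges, nrow(pairs)))
  edges <- data.frame(source = pairs[pick, 1], target = pairs[pick, 2],
                      r = round(runif(length(pick), 0.9, 1), 4),
                      stringsAsFactors = FALSE)
  used <- sort(unique(c(edges$source, edges$target)))
  nodes <- data.frame(gene_id = used, is_tf = FALSE, go_terms = "",
                      source_conditions = condition,
                      stringsAsFactors = FALSE)
  edges$source_conditions <- condition
  coexpression_network(nodes, edges,
                       params = list(r_threshold = 0.9, mode = "signed"))
}

test_that("merge is idempotent and sums edge-disjoint inputs", {
  n <- random_toy_network(1, "a")
  m <- merge_networks(list(n, n))
  expect_identical(edge_key(m$edges), edge_key(n$edges))
  expect_identical(sort(m$nodes$gene_id), sort(n$nodes$gene_id))

  n1 <- toy_network(data.frame(source = "a", target = "b"),
                    condition = "c1")
  n2 <- toy_network(data.frame(source = "c", target = "d"),
                    condition = "c2")
  m2 <- merge_networks(list(n1, n2))
  expect_identical(nrow(m2$edges), 2L)
})

test_that("merge matches the set-union oracle with source tracking", {
  for (rep in 1:6) {
    nets <- lapply(1:4, function(i) {
      random_toy_network(seed = rep * 10 + i, condition = paste0("c", i))
    })
    m <- merge_networks(nets)
    node_oracle <- sort(unique(unlist(lapply(nets,
                                             function(n) n$nodes$gene_id))))
    edge_oracle <- sort(unique(unlist(lapply(nets,
                                             function(n) edge_key(n$edges)))))
    expect_identical(m$nodes$gene_id, node_oracle)
    expect_identical(edge_key(m$edges), edge_oracle)
    for (g in node_oracle) {
      src_oracle <- paste(sort(paste0("c", which(vapply(nets, function(n) {
        g %in% n$nodes$gene_id
      }, logical(1))))), collapse = ";")
      expect_identical(
        m$nodes$source_conditions[m$nodes$gene_id == g], src_oracle)
    }
  }
})

test_that("merge is associative and commutative on node and edge sets", {
  nets <- lapply(1:3, function(i) random_toy_network(i + 50, paste0("c", i)))
  m_abc <- merge_networks(nets)
  m_cba <- merge_networks(rev(nets))
  m_nested <- merge_networks(list(merge_networks(nets[1:2]), nets[[3]]))
  expect_identical(edge_key(m_abc$edges), edge_key(m_cba$edges))
  expect_identical(edge_key(m_abc$edges), edge_key(m_nested$edges))
  expect_identical(m_abc$nodes$gene_id, m_nested$nodes$gene_id)
})

test_that("merged edges keep every per-source correlation", {
  e1 <- data.frame(source = "a", target = "b", r = 0.91)
  e2 <- data.frame(source = "a", target = "b", r = 0.97)
  n1 <- toy_network(e1, condition = "c1")
  n2 <- toy_network(e2, condition = "c2")
  m <- merge_networks(list(n1, n2))
  expect_identical(m$edges$source_conditions, "c1;c2")
  expect_equal(m$edges$r, 0.97)
  expect_match(m$edges$r_by_source, "c1=0.91")
  expect_match(m$edges$r_by_source, "c2=0.97")
})

test_that("shared_only filter keeps nodes present in >= m inputs", {
  n1 <- toy_network(data.frame(source = c("a", "a"), target = c("b", "c")),
                    condition = "c1")
  n2 <- toy_network(data.frame(source = c("a", "b"), target = c("b", "d")),
                    condition = "c2")
  m <- merge_networks(list(n1, n2), shared_only = 2)
  expect_setequal(m$nodes$gene_id, c("a", "b"))
  expect_identical(edge_key(m$edges), "a b")
})

test_that("merge rejects parameter mismatches", {
  n1 <- toy_network(data.frame(source = "a", target = "b"),
                    r_threshold = 0.9)
  n2 <- toy_network(data.frame(source = "a", target = "b"),
                    r_threshold = 0.8)
  expect_error(merge_networks(list(n1, n2)), "different parameters")
})

test_that("first neighbors: isolated seed, path, adjacency oracle", {
  path <- toy_network(data.frame(source = c("a", "b"), target = c("b", "c")))
  expect_identical(first_neighbors(path, "a"), c("a", "b"))
  iso <- toy_network(data.frame(source = c("a", "x"), target = c("b", "y")))
  expect_identical(first_neighbors(iso, "x"), c("x", "y"))
  expect_error(first_neighbors(path, "zz"), "not in network")

  net <- random_toy_network(99, "c")
  seeds <- net$nodes$gene_id[1:10]
  got <- first_neighbors(net, seeds)
  e <- net$edges
  oracle <- sort(unique(c(seeds,
                          e$target[e$source %in% seeds],
                          e$source[e$target %in% seeds])))
  expect_identical(got, oracle)
})

test_that("core reconstruction: star case, isolation case, GO filtering", {
  go <- setNames(rep(list("GO:0050896"), 5), c("hub", "n1", "n2", "n3", "n4"))
  star <- toy_network(data.frame(source = rep("hub", 4),
                                 target = paste0("n", 1:4)),
                      tf = "hub", go = go)
  core <- reconstruct_core(star, "hub", go_filter = "GO:0050896")
  expect_setequal(core$nodes$gene_id, c("hub", paste0("n", 1:4)))
  expect_identical(core$hub_ranking$gene_id[1], "hub")

  # TF with no GO-labelled neighbors keeps only the seed
  go2 <- list(hub = "GO:0050896")
  star2 <- toy_network(data.frame(source = rep("hub", 3),
                                  target = paste0("n", 1:3)),
                       tf = "hub", go = go2)
  core2 <- reconstruct_core(star2, "hub", go_filter = "GO:0050896")
  expect_identical(core2$nodes$gene_id, "hub")
  expect_identical(nrow(core2$edges), 0L)

  expect_error(reconstruct_core(star, "absent"), "no annotated TFs")
})

test_that("core with no GO filter and all-TF seeds returns the full network", {
  net <- random_toy_network(7, "c1")
  core <- reconstruct_core(net, net$nodes$gene_id, go_filter = NULL)
  expect_identical(sort(core$nodes$gene_id), sort(net$nodes$gene_id))
  expect_identical(edge_key(core$edges), edge_key(net$edges))
})

test_that("core output is always a subgraph with a valid hub ranking", {
  sim <- small_sim()
  chain <- run_core_chain(sim)
  core <- chain$core
  expect_false(is.null(core))
  expect_true(all(edge_key(core$edges) %in% edge_key(chain$merged$edges)))
  expect_true(all(core$nodes$gene_id %in% chain$merged$nodes$gene_id))
  # every core node is a seed or a neighbor of one
  nb <- first_neighbors(chain$merged, core$seed_tfs)
  expect_true(all(core$nodes$gene_id %in% nb))
  # ranking sorted by degree desc, ties by gene id
  hr <- core$hub_ranking
  expect_true(all(diff(hr$degree) <= 0))
  ties <- which(diff(hr$degree) == 0)
  expect_true(all(hr$gene_id[ties] < hr$gene_id[ties + 1]))
})

test_that("planted hub TFs rank at the top of the integrated core network", {
  p <- simulation_params(n_genes = 500, n_conditions = 2, seed = 4,
                         de_fraction = 0, n_replicates = 5)
  sim <- generate_experiment(p)
  chain <- run_core_chain(sim)
  hubs <- sim$truth$hub_tf_of_module
  expect_true(all(hubs %in% chain$core$hub_ranking$gene_id[1:5]))
})

test_that("shared edge decomposition partitions edges exactly", {
  n1 <- toy_network(data.frame(source = c("a", "c"), target = c("b", "d")),
                    condition = "c1")
  n2 <- toy_network(data.frame(source = c("a", "e"), target = c("b", "f")),
                    condition = "c2")
  m <- merge_networks(list(n1, n2))
  dec <- shared_edge_decomposition(m)
  expect_equal(dec$count[dec$sources == "c1;c2"], 1L)
  expect_equal(sum(dec$count), nrow(m$edges))

  single <- shared_edge_decomposition(n1)
  expect_identical(nrow(single), 1L)
  expect_equal(single$count, 2L)

  nets <- lapply(1:3, function(i) random_toy_network(i + 30, paste0("c", i)))
  m3 <- merge_networks(nets)
  dec3 <- shared_edge_decomposition(m3)
  keys <- lapply(nets, function(n) edge_key(n$edges))
  all_keys <- sort(unique(unlist(keys)))
  oracle <- table(vapply(all_keys, function(k) {
    paste(paste0("c", which(vapply(keys, function(kk) k %in% kk,
                                   logical(1)))), collapse = ";")
  }, character(1)))
  expect_equal(sum(dec3$count), length(all_keys))
  for (s in names(oracle)) {
    expect_equal(dec3$count[dec3$sources == s], unname(oracle[s]))
  }
})
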