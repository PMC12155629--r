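test_that("identical-target clustering forms exact equivalence classes", {
  cat_ <- make_catalog(c("A", "B", "C"),
                       targets = list("X", "X", c("X", "Y")))
  cl <- cluster_by_identical_targets(cat_)
  expect_equal(nrow(cl), 2)
  expect_identical(cl$member_drug_ids[[1]], c("A", "B"))
  expect_identical(cl$member_drug_ids[[2]], "C")
  # all-distinct targets: one cluster per drug
  cat2 <- make_catalog(c("A", "B", "C"),
                       targets = list("X", "Y", "Z"))
  expect_equal(nrow(cluster_by_identical_targets(cat2)), 3)
  # empty target sets form an excluded pool
  cat3 <- make_catalog(c("A", "B"), targets = list("X", character(0)))
  cl3 <- cluster_by_identical_targets(cat3)
  expect_equal(nrow(cl3), 1)
  expect_identical(attr(cl3, "excluded_drugs"), "B")
})

test_that("clustering equals components of the similarity==1 adjacency", {
  # brute-force oracle: adjacency where target Jaccard == 1, then
  # connected components
  set.seed(31)
  genes <- sprintf("g%02d", 1:12)
  for (trial in 1:100) {
    n <- sample(4:10, 1)
    tsets <- lapply(seq_len(n), function(i)
      sort(sample(genes, sample(1:3, 1))))
    # force some duplicates
    if (n >= 4) tsets[[2]] <- tsets[[1]]
    cat_ <- make_catalog(sprintf("D%02d", seq_len(n)), targets = tsets)
    cl <- cluster_by_identical_targets(cat_)
    adj <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j)
      jaccard_sets(tsets[[i]], tsets[[j]]) == 1))
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             diag = FALSE)
    comp <- igraph::components(g)$membership
    oracle <- unname(split(cat_$drug_id, comp))
    oracle <- lapply(oracle, sort)
    got <- cl$member_drug_ids
    expect_setequal(vapply(got, paste, "", collapse = ","),
                    vapply(oracle, paste, "", collapse = ","))
  }
})

test_that("proximity score is zero inside the module and averages distances", {
  # path a-b-c-d-e, module {a,b}, targets {b,d}: d = (0 + 2)/2 = 1
  g <- molecular_network(data.frame(gene_a = c("a", "b", "c", "d"),
                                    gene_b = c("b", "c", "d", "e")))
  sc <- proximity_score(g, c("b", "d"), c("a", "b"))
  expect_identical(sc$d, 1)
  expect_identical(proximity_score(g, c("a", "b"), c("a", "b"))$d, 0)
  # unmapped target excluded and counted
  sc2 <- proximity_score(g, c("a", "zz"), c("a", "b"))
  expect_identical(sc2$d, 0)
  expect_identical(sc2$n_targets_unmapped, 1L)
})

test_that("proximity score matches the Floyd-Warshall oracle", {
  set.seed(52)
  for (trial in 1:30) {
    gr <- random_small_graph(sample(6:20, 1))
    module <- sample(gr$nodes, sample(2:4, 1))
    targets <- sample(gr$nodes, sample(1:5, 1))
    got <- proximity_score(gr$graph, targets, module)$d
    oracle <- fw_proximity(gr$nodes, gr$edges, targets, module)
    expect_equal(got, oracle, tolerance = 1e-12)
  }
})

test_that("proximity is monotone non-increasing in the module", {
  set.seed(53)
  for (trial in 1:20) {
    gr <- random_small_graph(12)
    module <- sample(gr$nodes, 3)
    bigger <- union(module, sample(gr$nodes, 3))
    targets <- sample(gr$nodes, 3)
    d1 <- proximity_score(gr$graph, targets, module)$d
    d2 <- proximity_score(gr$graph, targets, bigger)$d
    expect_lte(d2, d1)
  }
})

test_that("degree bins merge upward to the occupancy floor", {
  d <- default_dataset()
  bins <- degree_bins(d$network, min_occupancy = 20L)
  occ <- lengths(bins$members)
  expect_true(all(occ >= 20L))
  expect_identical(sort(unname(unlist(bins$members))),
                   sort(igraph::V(d$network)$name))
})

test_that("null sampling on a 6-cycle reproduces the exact distance law", {
  # all degrees equal (single bin); module = one node; k = 1: null support
  # {0,1,1,2,2,3}, mean 1.5
  g <- molecular_network(data.frame(
    gene_a = c("n1", "n2", "n3", "n4", "n5", "n6"),
    gene_b = c("n2", "n3", "n4", "n5", "n6", "n1")))
  cfg <- null_model_config(n_iter = 4000, min_bin_occupancy = 2, seed = 9)
  nul <- sample_null(g, "n3", "n1", cfg)
  expect_length(nul, 4000)
  expect_setequal(unique(nul), c(0, 1, 2, 3))
  expect_equal(mean(nul), 1.5, tolerance = 0.05)
  # determinism under the seed
  nul2 <- sample_null(g, "n3", "n1", cfg)
  expect_identical(nul, nul2)
})

test_that("significance computes z, normal and empirical tails", {
  nul <- rep(c(1, 3), each = 50)  # mean 2, population sd 1
  s <- significance(1, nul)
  expect_equal(s$z, -1)
  expect_equal(s$p_normal, stats::pnorm(-1), tolerance = 1e-12)
  s2 <- significance(2, rep(c(1.5, 2.5), each = 50))
  expect_equal(s2$z, 0)
  expect_equal(s2$p_normal, 0.5)
  # d below every null score: empirical floor 1/(n+1)
  s3 <- significance(-1, stats::runif(1000, 1, 2))
  expect_equal(s3$p_empirical, 1 / 1001)
  # degenerate null: no z, but empirical p still defined
  s4 <- significance(1, rep(2, 100))
  expect_true(is.na(s4$z))
  expect_false(is.na(s4$p_empirical))
  expect_error(significance(1, 1:10), "at least 100")
})

test_that("cluster screening shares one score across identical-target drugs", {
  d <- default_dataset()
  mod <- build_disease_module(d$network, d$deg_list)
  cl <- cluster_by_identical_targets(d$catalog)
  sc <- screen_clusters(cl, d$network, mod,
                        cfg = null_model_config(n_iter = 200, seed = 5))
  expect_equal(nrow(sc$results), nrow(cl))
  # drugs expanded from one cluster inherit one score
  multi <- sc$drugs[duplicated(sc$drugs$cluster_id) |
                    duplicated(sc$drugs$cluster_id, fromLast = TRUE), ]
  if (nrow(multi) > 0) {
    per <- split(multi$d, multi$cluster_id)
    expect_true(all(vapply(per, function(x) length(unique(x)) == 1,
                           logical(1))))
  }
  # alpha = 0 retains nothing
  sc0 <- screen_clusters(cl, d$network, mod,
                         cfg = null_model_config(n_iter = 200, seed = 5),
                         alpha = 1e-12)
  expect_equal(nrow(sc0$drugs), 0)
})
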