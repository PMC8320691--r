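chain_table <- function() {
  # three perfectly correlated features spaced 2.02 apart
  tibble::tibble(
    feature_id = c("a", "b", "c"),
    mz = c(100.00, 102.02, 104.04),
    s1 = c(10, 5, 2), s2 = c(20, 10, 4), s3 = c(30, 15, 6),
    s4 = c(15, 7.5, 3)
  )
}

test_that("peak networks connect correlated features at matching PMDs", {
  net <- build_peak_network(chain_table(), 2.02)
  top <- topology(net)
  expect_equal(top$n_nodes, 3L)
  expect_equal(top$n_edges, 2L)
  expect_equal(top$average_degree, 4 / 3)
  # an unreachable correlation threshold empties the edge set
  net2 <- build_peak_network(chain_table(), 2.02, cor_cutoff = 1.0)
  expect_equal(nrow(net2$edges), 0L)
})

test_that("peak-network edges equal the pair-filter composition oracle", {
  withr::with_seed(51, {
    sim <- rand_peak_table(n_features = 24, n_samples = 10, n_pairs = 4)
    t <- sim$peaks
    net <- build_peak_network(t, 2.02, cor_cutoff = 0.6)
    want <- find_pairs(t, 2.02) |>
      pair_statistics(t = t) |>
      classify_static(rsd_cutoff = Inf, cor_cutoff = 0.6)
    want <- want[want$static, ]
    expect_setequal(paste(net$edges$from, net$edges$to),
                    paste(want$from, want$to))
  })
})

test_that("recursive search expands a chain from its seed", {
  net <- recursive_target_network(chain_table(), 100.00, 2.02)
  expect_setequal(net$nodes$node_id, c("a", "b", "c"))
  expect_equal(sort(net$nodes$generation), c(0L, 1L, 2L))
  # depth limit stops expansion
  net1 <- recursive_target_network(chain_table(), 100.00, 2.02,
                                   max_depth = 1)
  expect_setequal(net1$nodes$node_id, c("a", "b"))
  # a seed with no partners stays alone
  lone <- tibble::tibble(feature_id = c("a", "z"), mz = c(100, 300),
                         s1 = c(1, 1), s2 = c(2, 2), s3 = c(3, 3))
  net0 <- recursive_target_network(lone, 300, 2.02)
  expect_equal(net0$nodes$node_id, "z")
  expect_error(recursive_target_network(lone, 555.5, 2.02), "555.5")
})

test_that("unbounded recursive search equals the seed's connected component", {
  withr::with_seed(52, {
    for (i in 1:20) {
      sim <- rand_peak_table(n_features = 16, n_samples = 8, n_pairs = 3)
      t <- sim$peaks
      seed_feat <- sim$manifest$pairs$from[1]
      seed_mz <- t$mz[t$feature_id == seed_feat]
      net <- recursive_target_network(t, seed_mz, 2.02)
      full <- build_peak_network(t, 2.02, include_isolated = TRUE)
      comp <- igraph::components(full$graph)
      seeds <- t$feature_id[reactomics:::round_pmd(t$mz, 2) ==
                              reactomics:::round_pmd(seed_mz, 2)]
      want <- names(comp$membership)[
        comp$membership %in% comp$membership[seeds]]
      expect_setequal(net$nodes$node_id, want)
    }
  })
})

test_that("compound networks follow the PMD edge set", {
  cp <- data.frame(id = c("a", "b", "c"),
                   mass = c(100.000, 102.016, 116.032))
  net <- build_compound_network(cp, c(2.016, 14.016), digits = 3)
  expect_equal(nrow(net$edges), 2L)
  expect_false(any(net$edges$pmd == 16.032))
  # no matching PMD isolates everything; dropping isolates empties it
  net0 <- build_compound_network(cp, 5.5, drop_isolated = TRUE)
  expect_equal(nrow(net0$nodes), 0L)
  withr::with_seed(53, {
    n <- 100
    cp <- data.frame(id = paste0("c", 1:n), mass = runif(n, 50, 600))
    set <- c(2.02, 14.02)
    net <- build_compound_network(cp, set, digits = 2)
    want <- 0L
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (round(abs(cp$mass[i] - cp$mass[j]), 2) %in% set) want <- want + 1L
    }
    expect_equal(nrow(net$edges), want)
  })
})

test_that("topology metrics match hand-enumerated small graphs", {
  # single edge
  cp <- data.frame(id = c("a", "b"), mass = c(100, 102.016))
  t1 <- topology(build_compound_network(cp, 2.016))
  expect_equal(t1$average_degree, 1)
  expect_equal(t1$average_path_length, 1)
  # 4-node path: distances 1,1,1,2,2,3 over the 6 pairs
  cp4 <- data.frame(id = letters[1:4], mass = 100 + (0:3) * 2.016)
  t4 <- topology(build_compound_network(cp4, 2.016))
  expect_equal(t4$average_degree, 1.5)
  expect_equal(t4$average_path_length, 10 / 6)
  empty <- reactomics:::new_pmd_network(
    tibble::tibble(node_id = character(0), mass = numeric(0),
                   label = character(0), kind = character(0)),
    tibble::tibble(from = character(0), to = character(0),
                   pmd = numeric(0), pearson_r = numeric(0)), 3)
  expect_warning(t0 <- topology(empty), "empty")
  expect_equal(t0$n_nodes, 0L)
})

test_that("average degree equals the handshake-lemma degree sum", {
  withr::with_seed(54, {
    for (i in 1:20) {
      n <- sample(10:40, 1)
      cp <- data.frame(id = paste0("c", 1:n), mass = runif(n, 50, 300))
      net <- build_compound_network(cp, c(1.5, 2.02, 14.02), digits = 1)
      top <- topology(net)
      degs <- node_degrees(net)
      expect_equal(top$average_degree, sum(degs$degree) / top$n_nodes)
    }
  })
})

test_that("topology is invariant under node relabelling", {
  cp <- data.frame(id = letters[1:5], mass = 100 + (0:4) * 2.016)
  cp2 <- cp; cp2$id <- rev(LETTERS[1:5])
  expect_equal(topology(build_compound_network(cp, 2.016)),
               topology(build_compound_network(cp2, 2.016)))
})

test_that("source appointment follows component average degree", {
  # one component with 10 nodes and 17 edges: average degree 3.4
  edges <- tibble::tibble(
    from = c("a", "a", "a", "a", "b", "b", "b", "c", "c", "d",
             "e", "f", "g", "h", "i", "f", "g"),
    to   = c("b", "c", "d", "e", "c", "d", "e", "d", "e", "e",
             "f", "g", "h", "i", "j", "h", "i"),
    pmd = 2.016, pearson_r = NA_real_)
  nodes <- tibble::tibble(node_id = letters[1:10], mass = 1:10,
                          label = letters[1:10], kind = "compound")
  net <- reactomics:::new_pmd_network(nodes, edges, 3)
  cl <- source_classify(net, "j")
  expect_equal(cl$component_avg_degree, 3.4)
  expect_equal(cl$classification, "endogenous")
  # an isolated node is exogenous
  nodes2 <- dplyr::bind_rows(nodes,
                             tibble::tibble(node_id = "iso", mass = 99,
                                            label = "iso", kind = "compound"))
  net2 <- reactomics:::new_pmd_network(nodes2, edges, 3)
  cl2 <- source_classify(net2, "iso")
  expect_equal(cl2$classification, "exogenous")
  expect_equal(cl2$degree, 0L)
  expect_error(source_classify(net, "nope"), "absent")
})

test_that("dense and sparse synthetic pools classify as endogenous/exogenous", {
  pools <- gen_compound_pools(seed = 55)
  pool <- dplyr::bind_rows(pools$endogenous, pools$exogenous)
  db <- compound_pairwise_pmd_db(pool, digits = 3, unique_by = "mass")
  top <- top_k_pmds(db, 10)
  net_e <- build_compound_network(pools$endogenous, top)
  net_x <- build_compound_network(pools$exogenous, top)
  cl_e <- source_classify(net_e)
  cl_x <- source_classify(net_x)
  expect_gt(mean(cl_e$classification == "endogenous"), 0.8)
  expect_gt(mean(cl_x$classification == "exogenous"), 0.8)
})

test_that("degree resampling is symmetric, seeded, and matches a single-shot oracle", {
  pools <- gen_compound_pools(seed = 56)
  # identical pools on both sides give overlapping intervals
  same <- resample_degree_contrast(pools$endogenous, pools$endogenous,
                                   n_draw = 40, n_rep = 30, seed = 1)
  s <- same$summary
  expect_true(s$ci_lo[1] <= s$ci_hi[2] && s$ci_lo[2] <= s$ci_hi[1])
  # fixed seed reproduces bit-identically
  r1 <- resample_degree_contrast(pools$endogenous, pools$exogenous,
                                 n_rep = 10, seed = 9)
  r2 <- resample_degree_contrast(pools$endogenous, pools$exogenous,
                                 n_rep = 10, seed = 9)
  expect_identical(r1$replicates, r2$replicates)
  # n_rep = 1 with the full exogenous pool equals a direct construction
  one <- resample_degree_contrast(pools$endogenous, pools$exogenous,
                                  n_draw = nrow(pools$exogenous),
                                  n_rep = 1, seed = 2)
  pool <- dplyr::bind_rows(pools$endogenous, pools$exogenous)
  db <- compound_pairwise_pmd_db(pool, digits = 3, unique_by = "mass")
  top <- top_k_pmds(db, 10)
  net <- build_compound_network(pool, top, digits = 3)
  degs <- node_degrees(net)
  is_endo <- degs$node_id %in% pools$endogenous$compound_id
  expect_equal(one$replicates$mean_degree[
    one$replicates$group == "endogenous"], mean(degs$degree[is_endo]))
  expect_equal(one$replicates$mean_degree[
    one$replicates$group == "exogenous"], mean(degs$degree[!is_endo]))
})
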