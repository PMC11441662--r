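# Nodal overlap: proportions, entropy, module maps, system summaries.

# bowtie: node 3 joins two triangles -> its edges split across two modules
bowtie_setup <- function() {
  net <- net_from_adj(adj_from_edges(5, list(c(1, 2), c(1, 3), c(2, 3),
                                             c(3, 4), c(3, 5), c(4, 5))))
  edges <- network_edges(net)
  left <- edges$i <= 3 & edges$j <= 3
  partition <- structure(list(labels = ifelse(left, 1L, 2L), n_modules = 2L,
                              modularity = NA_real_, seed = 0L),
                         class = "edge_partition")
  list(net = net, partition = partition)
}

test_that("node distributions count incident-edge module shares", {
  bt <- bowtie_setup()
  d <- node_distribution(bt$partition, bt$net)
  # node 3 has 4 edges: 2 in module 1, 2 in module 2
  n3 <- d[d$node == 3, ]
  expect_equal(sort(n3$proportion), c(0.5, 0.5))
  # node 1 entirely in module 1
  expect_equal(d$proportion[d$node == 1], 1)
  # proportions sum to 1 per node
  sums <- tapply(d$proportion, d$node, sum)
  expect_equal(as.numeric(sums), rep(1, 5))

  # direct count example: edges in modules {2, 2, 5} -> p = {2/3, 1/3}
  net3 <- net_from_adj(adj_from_edges(4, list(c(1, 2), c(1, 3), c(1, 4))))
  part3 <- structure(list(labels = c(2L, 2L, 5L), n_modules = 2L,
                          modularity = NA_real_, seed = 0L),
                     class = "edge_partition")
  d3 <- node_distribution(part3, net3)
  n1 <- d3[d3$node == 1, ]
  expect_equal(n1$proportion[n1$module == 2], 2 / 3)
  expect_equal(n1$proportion[n1$module == 5], 1 / 3)

  bad <- bt$partition; bad$labels <- bad$labels[-1]
  expect_error(node_distribution(bad, bt$net),
               class = "overlapnet_consistency_error")
})

test_that("normalized entropy matches hand-computed values", {
  expect_equal(nodal_entropy(1), 0)                      # single module
  expect_equal(nodal_entropy(c(0.5, 0.5)), 1)            # uniform over 2
  expect_equal(nodal_entropy(c(0.75, 0.25)),
               -(0.75 * log2(0.75) + 0.25 * log2(0.25)), tolerance = 1e-12)
  expect_equal(round(nodal_entropy(c(0.75, 0.25)), 4), 0.8113)
  expect_equal(nodal_entropy(c(1 / 3, 1 / 3, 1 / 3)), 1) # uniform over 3
  expect_equal(nodal_entropy(c(0.5, 0.5, 0)), 1)         # zeros ignored
  expect_error(nodal_entropy(c(0.5, 0.4)), class = "overlapnet_domain_error")
  expect_error(nodal_entropy(c(-0.1, 1.1)), class = "overlapnet_domain_error")
})

test_that("involved-module number is the support size", {
  expect_equal(involved_number(1), 1L)
  expect_equal(involved_number(c(0.5, 0.3, 0.2)), 3L)
  expect_equal(involved_number(c(0.5, 0.5, 0)), 2L)
})

test_that("node overlap flags edgeless nodes as missing", {
  net <- net_from_adj(adj_from_edges(4, list(c(1, 2), c(1, 3), c(2, 3))))
  part <- structure(list(labels = c(1L, 1L, 2L), n_modules = 2L,
                         modularity = NA_real_, seed = 0L),
                    class = "edge_partition")
  ov <- node_overlap(part, net)
  expect_true(ov$missing[4])
  expect_true(is.na(ov$entropy[4]))
  expect_false(any(ov$missing[1:3]))
  expect_equal(ov$n_involved[2], 2)   # node 2's edges span modules 1 and 2
})

test_that("instance averaging and global entropy honour missingness", {
  net <- net_from_adj(adj_from_edges(4, list(c(1, 2), c(1, 3), c(2, 3))))
  p1 <- structure(list(labels = c(1L, 1L, 2L), n_modules = 2L,
                       modularity = 0.1, seed = 1L), class = "edge_partition")
  p2 <- structure(list(labels = c(1L, 2L, 2L), n_modules = 2L,
                       modularity = 0.3, seed = 2L), class = "edge_partition")
  ens <- structure(list(partitions = list(p1, p2), modal_n = 2L,
                        mean_modularity = 0.2), class = "instance_ensemble")
  s <- summarize_instances(ens, net)
  e1 <- node_overlap(p1, net)$entropy
  e2 <- node_overlap(p2, net)$entropy
  expect_equal(s$node_summary$entropy[1:3], ((e1 + e2) / 2)[1:3])
  expect_true(is.na(s$node_summary$entropy[4]))
  expect_equal(s$global_entropy, mean(((e1 + e2) / 2)[1:3]))
  expect_equal(s$mean_q, 0.2)

  # identical instances equal the single-instance values
  ens_same <- structure(list(partitions = list(p1, p1), modal_n = 2L,
                             mean_modularity = 0.1), class = "instance_ensemble")
  expect_equal(summarize_instances(ens_same, net)$node_summary$entropy[1:3], e1[1:3])
})

test_that("module maps stack to the node distribution and match hand counts", {
  bt <- bowtie_setup()
  maps <- module_maps(bt$partition, bt$net)
  expect_equal(maps$M1, c(1, 1, 0.5, 0, 0))
  expect_equal(maps$M2, c(0, 0, 0.5, 1, 1))
  expect_equal(maps$M1 + maps$M2, rep(1, 5))
})

test_that("module matching recovers a label shuffle and survives noise", {
  bt <- bowtie_setup()
  maps <- module_maps(bt$partition, bt$net)
  shuffled <- maps[, c("node", "node_id", "M2", "M1")]
  names(shuffled) <- c("node", "node_id", "M1", "M2")
  m <- match_modules(maps, shuffled)
  expect_equal(m$map_b[m$map_a == "M1"], "M2")
  expect_equal(m$map_b[m$map_a == "M2"], "M1")
  expect_equal(m$r, c(1, 1))

  # identity matching on self input
  self <- match_modules(maps, maps)
  expect_equal(self$map_a, self$map_b)
  expect_equal(self$r, c(1, 1))

  noisy <- maps
  withr::with_seed(8, {
    noisy$M1 <- noisy$M1 + rnorm(5, sd = 0.01)
    noisy$M2 <- noisy$M2 + rnorm(5, sd = 0.01)
  })
  mn <- match_modules(maps, noisy)
  expect_equal(mn$map_b, c("M1", "M2"))
  expect_true(all(mn$r < 1 & mn$r > 0.99))
})

test_that("system composition percentages sum to 100", {
  parc <- gen_parcellation(8)   # one node per system
  vals <- c(1, 1, 0, 0, 0, 0, 0.4, 0)
  comp <- system_composition(vals, parc)
  expect_equal(sum(comp$pct), 100)
  expect_setequal(comp$system, c("VIS", "SM", "DM"))
  expect_equal(comp$pct, rep(100 / 3, 3))

  # module confined to one system
  only <- system_composition(c(1, 0, 0, 0, 0, 0, 0, 0), parc)
  expect_equal(only$system, "VIS")
  expect_equal(only$pct, 100)
})

test_that("system entropy means aggregate to the weighted global mean", {
  parc <- tibble::tibble(node_id = as.character(1:5),
                         system = c("VIS", "VIS", "SM", "SM", "SM"))
  ent <- c(0.2, 0.4, 0.6, 0.6, 0.6)
  se <- system_entropy(ent, parc)
  expect_equal(se$mean_entropy[se$system == "VIS"], 0.3)
  expect_equal(se$mean_entropy[se$system == "SM"], 0.6)
  expect_equal(attr(se, "global_mean"),
               sum(se$mean_entropy * se$n_nodes) / sum(se$n_nodes))
})
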