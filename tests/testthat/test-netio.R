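# Correlation-matrix IO and density thresholding.

test_that("loading symmetrizes, forces unit diagonal, and reports parse errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1.0,0.5,0.1", "0.3,1.0,0.2", "0.1,0.2,0.9"), path)
  m <- load_correlation_matrix(path)
  expect_equal(m[1, 2], 0.4)      # (0.5 + 0.3) / 2
  expect_equal(m[2, 1], 0.4)
  expect_equal(unname(diag(unclass(m))), rep(1, 3))

  # identity-like file
  writeLines(c("1 0 0", "0 1 0", "0 0 1"), path)
  id <- load_correlation_matrix(path)
  expect_equal(unclass(id), diag(3), ignore_attr = TRUE)

  # header row becomes node ids
  writeLines(c("a,b,c", "1,0.2,0.3", "0.2,1,0.4", "0.3,0.4,1"), path)
  expect_equal(attr(load_correlation_matrix(path), "node_ids"), c("a", "b", "c"))

  writeLines(c("1 0 0", "0 1 0"), path)
  expect_error(load_correlation_matrix(path), class = "overlapnet_format_error")
  writeLines(c("1 0 x", "0 1 0", "0 0 1"), path)
  expect_error(load_correlation_matrix(path), "row 1, column 3",
               class = "overlapnet_parse_error")
})

test_that("density thresholding keeps the ceiling count of top positive edges", {
  # 232 nodes at 15% -> 4,020 edges (ceiling of 0.15 * 26,796 = 4,019.4)
  g <- gen_overlapping_network(n_nodes = 232, seed = 11)
  net <- threshold_by_density(g$corr, 0.15)
  expect_equal(net$n_edges, 4020L)
  expect_equal(sum(net$adjacency > 0) / 2, 4020)
  expect_true(all(diag(net$adjacency) == 0))
  expect_true(all(net$adjacency >= 0))

  # exact ceiling count whenever positives suffice
  for (n in c(10, 50)) {
    gs <- gen_overlapping_network(n_nodes = n, n_modules = 2,
                                  between_strength = 0.2, seed = n)
    nt <- threshold_by_density(gs$corr, 0.3)
    expect_equal(nt$n_edges, as.integer(ceiling(0.3 * n * (n - 1) / 2)))
  }

  expect_error(threshold_by_density(g$corr, 0), class = "overlapnet_domain_error")
  expect_error(threshold_by_density(g$corr, 1.2), class = "overlapnet_domain_error")
})

test_that("thresholding selects exactly the strongest pairs (brute-force check)", {
  withr::with_seed(5, {
    m <- matrix(runif(25, 0.01, 0.99), 5)
    m <- (m + t(m)) / 2; diag(m) <- 1
  })
  cm <- corr_matrix(m)
  net <- threshold_by_density(cm, 0.4)          # top 4 of 10 pairs
  ut <- which(upper.tri(m), arr.ind = TRUE)
  vals <- m[ut]
  top4 <- ut[order(-vals)[1:4], , drop = FALSE]
  kept <- which(upper.tri(net$adjacency) & net$adjacency > 0, arr.ind = TRUE)
  expect_setequal(paste(top4[, 1], top4[, 2]), paste(kept[, 1], kept[, 2]))
  # retained minimum >= maximum discarded
  expect_gte(min(net$adjacency[net$adjacency > 0]),
             max(m[upper.tri(m)][order(-vals)[5:10]]))

  # full density keeps all 10 edges of an all-positive matrix
  expect_equal(threshold_by_density(cm, 1)$n_edges, 10L)
})

test_that("shortfall of positive correlations is flagged", {
  m <- diag(4); m[1, 2] <- m[2, 1] <- 0.5; m[3, 4] <- m[4, 3] <- -0.2
  expect_warning(net <- threshold_by_density(corr_matrix(m), 0.9))
  expect_true(net$shortfall)
  expect_equal(net$n_edges, 1L)   # only one positive pair exists
})

test_that("group networks average raw correlations then threshold", {
  g1 <- gen_overlapping_network(n_nodes = 20, n_modules = 2, seed = 1)$corr
  g2 <- gen_overlapping_network(n_nodes = 20, n_modules = 2, seed = 2)$corr

  # single-matrix group == individual network
  solo <- build_group_network(list(g1), 0.2)
  indiv <- threshold_by_density(g1, 0.2)
  expect_equal(solo$adjacency, indiv$adjacency)

  # identical matrices: mean is a no-op
  same <- build_group_network(list(g1, g1, g1), 0.2)
  expect_equal(same$adjacency, indiv$adjacency)

  # elementwise mean pre-threshold
  m1 <- diag(4); m1[1, 2] <- m1[2, 1] <- 0.2
  m2 <- diag(4); m2[1, 2] <- m2[2, 1] <- 0.6
  grp <- suppressWarnings(build_group_network(list(corr_matrix(m1), corr_matrix(m2)), 1))
  expect_equal(grp$adjacency[1, 2], 0.4)

  bad <- corr_matrix(diag(3) + 0.1 - diag(0.1, 3))
  expect_error(build_group_network(list(g1, bad), 0.2),
               class = "overlapnet_alignment_error")
})

test_that("network round-trips through edge-list TSV + sidecar", {
  net <- random_net(12, seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, path)
  back <- read_network(path)
  expect_equal(back$adjacency, net$adjacency)
  expect_equal(back$n_edges, net$n_edges)
})

test_that("parcellation reader validates system labels", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(gen_parcellation(16), path)
  parc <- read_parcellation(path)
  expect_equal(nrow(parc), 16)
  expect_true(all(parc$system %in% c("VIS", "SM", "DA", "VA", "LIM", "FP", "DM", "SUB")))

  bad <- gen_parcellation(8); bad$system[1] <- "XX"
  readr::write_tsv(bad, path)
  expect_error(read_parcellation(path), class = "overlapnet_format_error")
})
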