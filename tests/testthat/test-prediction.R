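# SVR prediction pipelines and supporting utilities.

test_that("one scan per subject is selected reproducibly", {
  co <- gen_longitudinal_cohort(n_subjects = 60, scan_counts = c(0.3, 0.4, 0.3),
                                node_slopes = c(node_1 = 0.02), seed = 3)
  sel1 <- select_independent_scans(co$panel, seed = 5)
  sel2 <- select_independent_scans(co$panel, seed = 5)
  expect_equal(nrow(sel1), 60)
  expect_equal(dplyr::n_distinct(sel1$subject_id), 60)
  expect_identical(sel1$scan_id, sel2$scan_id)
  # different seeds pick differently for some multi-scan subject
  sel3 <- select_independent_scans(co$panel, seed = 6)
  expect_true(any(sel1$scan_id != sel3$scan_id))
})

test_that("age-stratified folds balance sizes and age means", {
  ages <- withr::with_seed(1, runif(100, 6, 14))
  folds <- stratified_folds(ages, k = 10, seed = 2)
  expect_equal(as.integer(table(folds)), rep(10L, 10))

  # fold means hug the global mean more tightly than random splits
  strat_dev <- max(abs(tapply(ages, folds, mean) - mean(ages)))
  rand_dev <- withr::with_seed(3, replicate(200, {
    f <- sample(rep(1:10, 10))
    max(abs(tapply(ages, f, mean) - mean(ages)))
  }))
  expect_lt(strat_dev, quantile(rand_dev, 0.05))

  # k = n is leave-one-out; 20 items in 10 folds -> all size 2
  expect_equal(sort(stratified_folds(ages[1:12], k = 12, seed = 1)), 1:12)
  expect_equal(as.integer(table(stratified_folds(ages[1:20], 10, 1))), rep(2L, 10))
  expect_error(stratified_folds(ages[1:5], k = 10), class = "overlapnet_domain_error")
})

test_that("scaling parameters come from the training folds only", {
  withr::with_seed(4, {
    x <- matrix(runif(60 * 5), 60)
    y <- rnorm(60)
  })
  folds <- rep(1:10, 6)
  base <- predict_age(x, y, folds)
  # an extreme outlier in fold 1's test rows must not change fold 1's model
  x_out <- x
  x_out[which(folds == 1)[1], ] <- 1e4
  mod <- predict_age(x_out, y, folds)
  unchanged <- folds == 1 & seq_along(y) != which(folds == 1)[1]
  expect_equal(mod$predictions$predicted[unchanged],
               base$predictions$predicted[unchanged])
})

test_that("planted age signal is detected; permutation null is calibrated", {
  withr::with_seed(11, {
    ages <- runif(80, 6, 14)
    x <- matrix(rnorm(80 * 30), 80)
    x[, 1:10] <- x[, 1:10] + ages / 2     # SNR ~ 2 on 10 informative nodes
  })
  folds <- stratified_folds(ages, 10, seed = 1)
  res <- age_prediction_null(x, ages, folds, n = 99, seed = 2)
  expect_gt(res$r, quantile(res$null_r, 0.95))
  expect_equal(res[["p"]], 1 / 100)
  expect_lt(abs(mean(res$null_r)), 0.15)  # null accuracies centered near 0

  # feature order permutation leaves predictions unchanged (up to order)
  perm <- withr::with_seed(5, sample(30))
  res_perm <- predict_age(x[, perm], ages, folds)
  expect_equal(res_perm$predictions$predicted, res$predictions$predicted,
               tolerance = 1e-8)
})

test_that("contribution weights localize a single informative node", {
  withr::with_seed(21, {
    ages <- runif(60, 6, 14)
    x <- matrix(rnorm(60 * 12, sd = 0.2), 60)
    x[, 7] <- x[, 7] + ages
  })
  cw <- contribution_weights(x, ages, parc = gen_parcellation(12))
  expect_equal(which.max(abs(cw$weights$weight)), 7L)
  expect_true(all(c("system", "direction", "mean_weight") %in% names(cw$by_system)))
  signs <- ifelse(cw$weights$weight >= 0, "positive", "negative")
  agg <- tapply(cw$weights$weight, list(gen_parcellation(12)$system, signs), mean)
  for (r in rownames(agg)) for (cc in colnames(agg)) {
    if (!is.na(agg[r, cc])) {
      expect_equal(cw$by_system$mean_weight[cw$by_system$system == r &
                                              cw$by_system$direction == cc],
                   agg[r, cc])
    }
  }
})

test_that("residualization removes covariate and random effects, keeps age", {
  co <- gen_longitudinal_cohort(n_subjects = 150, scan_counts = c(0.3, 0.4, 0.3),
                                node_slopes = c(node_1 = 0.03),
                                beta_mFD = -2, re_sd = c(0.2, 0.02), seed = 13)
  adj <- residualize_for_prediction(co$panel, "node_1")
  expect_lt(abs(cor(adj$node_1, adj$mFD)), 0.1)
  expect_gt(abs(cor(co$panel$node_1, co$panel$mFD)), 0.3)
  # fixed-age signal survives adjustment
  expect_gt(cor(adj$node_1, adj$age), 0.5)
})

test_that("FA strength sums off-diagonal mean-FA values", {
  fa <- matrix(0, 3, 3)
  fa[1, 2] <- fa[2, 1] <- 0.4
  fa[1, 3] <- fa[3, 1] <- 0.5
  expect_equal(fa_strength(fa), c(0.9, 0.4, 0.5))
  expect_equal(fa_strength(matrix(0, 4, 4)), rep(0, 4))

  withr::with_seed(6, {
    m <- matrix(runif(400), 20); m <- (m + t(m)) / 2
  })
  brute <- vapply(1:20, function(i) sum(m[i, -i]), numeric(1))
  expect_equal(fa_strength(m), brute)

  asym <- m; asym[1, 2] <- asym[1, 2] + 1
  expect_error(fa_strength(asym), class = "overlapnet_consistency_error")
})

test_that("structure-based prediction recovers planted coupling and nulls out", {
  ent <- withr::with_seed(31, runif(60))
  sf <- gen_structural_features(ent, noise_sd = 0.4, seed = 32)
  res <- predict_entropy_from_structure(sf$features, ent, seed = 33)
  expect_gt(res$r, 0.5)
  expect_equal(nrow(res$feature_weights), 6)

  # dominant planted feature attains the largest |weight|
  dom <- gen_structural_features(ent, loadings = c(CV = 0, CT = 1, CC = 0,
                                                   FI = 0, SA = 0,
                                                   FA_strength = 0),
                                 noise_sd = 0.3, seed = 34)
  rd <- predict_entropy_from_structure(dom$features, ent, seed = 35)
  expect_equal(which.max(abs(rd$feature_weights$weight)), 2L)

  # features independent of entropy -> near-zero accuracy on average
  rs <- vapply(1:8, function(i) {
    f <- gen_structural_features(withr::with_seed(50 + i, runif(60)),
                                 seed = 60 + i)$features
    predict_entropy_from_structure(f, withr::with_seed(70 + i, runif(60)),
                                   seed = 80 + i)$r
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.25)

  expect_error(predict_entropy_from_structure(sf$features[, 1:4], ent),
               class = "overlapnet_format_error")
})

test_that("aggregated structure null has the right size and location", {
  scans <- lapply(1:3, function(i) {
    ent <- withr::with_seed(90 + i, runif(40))
    list(features = gen_structural_features(ent, seed = 95 + i)$features,
         entropy = withr::with_seed(100 + i, runif(40)))  # decoupled
  })
  nu <- structure_prediction_null(scans, shuffles_per_scan = 4, seed = 7)
  expect_equal(length(nu$null_r), 12L)    # 3 scans x 4 shuffles
  expect_equal(nrow(nu$per_scan), 3L)
  expect_lt(abs(mean(nu$null_r)), 0.3)
})

test_that("univariate correlations match the direct formula", {
  ent <- withr::with_seed(41, runif(50))
  f <- cbind(a = ent, b = -ent, c = withr::with_seed(42, rnorm(50)))
  uc <- univariate_structure_correlations(f, ent)
  expect_equal(uc$r[uc$feature == "a"], 1)
  expect_equal(uc$r[uc$feature == "b"], -1)
  v <- f[, "c"]
  expect_equal(uc$r[uc$feature == "c"],
               sum((v - mean(v)) * (ent - mean(ent))) /
                 sqrt(sum((v - mean(v))^2) * sum((ent - mean(ent))^2)))
  const <- cbind(d = rep(1, 50))
  expect_true(is.na(univariate_structure_correlations(const, ent)$r))
})
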