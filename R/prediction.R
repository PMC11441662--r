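# Cross-validated linear SVR pipelines: chronological age from nodal
# entropy maps, and per-scan entropy maps from structural features.

#' Linear SVR configuration
#'
#' Hyperparameters of the epsilon-insensitive linear support vector
#' regression used throughout (libsvm defaults: C = 1, epsilon = 0.1).
#' `scale_features` toggles the train-set min-max scaling applied before
#' fitting.
#'
#' @param cost Regularization constant C.
#' @param epsilon Epsilon-insensitive tube width.
#' @param tolerance Optimizer termination tolerance.
#' @param scale_features Min-max scale each feature on the training set
#'   and apply the same parameters to the test set.
#' @return A list of class `svr_config`.
#' @export
svr_config <- function(cost = 1, epsilon = 0.1, tolerance = 0.001,
                       scale_features = TRUE) {
  structure(list(cost = cost, epsilon = epsilon, tolerance = tolerance,
                 scale_features = scale_features), class = "svr_config")
}

# Min-max scaling parameters learned on the training rows only.
minmax_fit <- function(x_train) {
  lo <- apply(x_train, 2, min)
  hi <- apply(x_train, 2, max)
  list(lo = lo, span = ifelse(hi > lo, hi - lo, 1), constant = hi == lo)
}

minmax_apply <- function(x, sc) {
  out <- sweep(sweep(x, 2, sc$lo, "-"), 2, sc$span, "/")
  if (any(sc$constant)) out[, sc$constant] <- 0
  out
}

# Fit linear eps-SVR; returns primal weights and intercept for fast predict.
fit_linear_svr <- function(x, y, config) {
  m <- e1071::svm(x, y, type = "eps-regression", kernel = "linear",
                  cost = config$cost, epsilon = config$epsilon,
                  tolerance = config$tolerance,
                  scale = FALSE, fitted = FALSE)
  list(w = as.numeric(crossprod(m$coefs, m$SV)), rho = m$rho)
}

svr_predict <- function(fit, x) as.numeric(x %*% fit$w - fit$rho)

# Shared cross-validation engine: out-of-fold predictions without any
# result packaging (also used by the high-volume permutation nulls).
cv_svr_pred <- function(x, y, folds, config) {
  pred <- numeric(length(y))
  for (f in unique.default(folds)) {
    te <- folds == f
    xtr <- x[!te, , drop = FALSE]
    xte <- x[te, , drop = FALSE]
    if (config$scale_features) {
      sc <- minmax_fit(xtr)
      xtr <- minmax_apply(xtr, sc)
      xte <- minmax_apply(xte, sc)
    }
    fit <- fit_linear_svr(xtr, y[!te], config)
    pred[te] <- svr_predict(fit, xte)
  }
  pred
}

#' Select one scan per subject at random
#'
#' Longitudinal scans of the same child must not straddle the train/test
#' split, so prediction runs on one randomly chosen scan per subject.
#'
#' @param panel Cohort tibble (see [fit_mixed_linear()]).
#' @param seed Integer seed.
#' @return Tibble with one row per subject.
#' @export
select_independent_scans <- function(panel, seed = 1L) {
  check_panel(panel)
  withr::with_seed(seed, {
    panel |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::slice_sample(n = 1) |>
      dplyr::ungroup()
  })
}

#' Age-stratified cross-validation folds
#'
#' Items are sorted by age and dealt in consecutive age blocks of size `k`,
#' with a random fold permutation inside each block, giving folds of
#' near-identical size and similar age distributions (lower fold-mean
#' spread than random splits).
#'
#' @param ages Numeric ages.
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return Integer fold assignment (1..k) aligned with `ages`.
#' @export
stratified_folds <- function(ages, k = 10L, seed = 1L) {
  n <- length(ages)
  if (k > n) stop_domain("more folds than items")
  ord <- order(ages)
  fold <- integer(n)
  withr::with_seed(seed, {
    pos <- 1L
    while (pos <= n) {
      block <- ord[pos:min(pos + k - 1L, n)]
      fold[block] <- sample.int(k, length(block))
      pos <- pos + k
    }
  })
  fold
}

#' Cross-validated linear SVR prediction of age from nodal features
#'
#' Per fold: min-max scale each feature on the training rows, apply the
#' scaling to the held-out rows, fit a linear SVR, predict.  Accuracy is
#' the Pearson correlation between pooled out-of-fold predictions and the
#' actual ages.
#'
#' @param features Numeric scan-by-node matrix.
#' @param ages Numeric target vector aligned with rows.
#' @param folds Integer fold assignment (see [stratified_folds()]).
#' @param config An [svr_config()].
#' @return A `prediction_result`: `predictions` tibble
#'   `(item, actual, predicted, fold)`, accuracy `r`, and the config.
#' @export
predict_age <- function(features, ages, folds, config = svr_config()) {
  features <- as.matrix(features)
  if (nrow(features) != length(ages) || length(folds) != length(ages)) {
    stop_domain("features, ages and folds must align by row")
  }
  pred <- cv_svr_pred(features, ages, folds, config)
  structure(list(
    predictions = tibble(item = seq_along(ages), actual = ages,
                         predicted = pred, fold = folds),
    r = cor(pred, ages),
    config = config
  ), class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("<prediction_result> n = %d, r = %.3f%s\n",
              nrow(x$predictions), x$r,
              if (!is.null(x[["p"]])) sprintf(", permutation p = %.4g", x[["p"]]) else ""))
  invisible(x)
}

#' Permutation null for the age-prediction accuracy
#'
#' Shuffles the ages across scans and reruns the full cross-validated
#' pipeline for each permutation; `p = (1 + #{r_null >= r_obs}) / (1 + n)`.
#'
#' @inheritParams predict_age
#' @param n Number of permutations.
#' @param seed Integer seed.
#' @return A `prediction_result` with `null_r` and `p` filled in.
#' @export
age_prediction_null <- function(features, ages, folds, n = 1000, seed = 1L,
                                config = svr_config()) {
  obs <- predict_age(features, ages, folds, config)
  perm_seeds <- derive_seeds(seed, n)
  x <- as.matrix(features)
  null_r <- vapply(seq_len(n), function(b) {
    ya <- withr::with_seed(perm_seeds[b], sample(ages))
    cor(cv_svr_pred(x, ya, folds, config), ya)
  }, numeric(1))
  obs$null_r <- null_r
  obs$p <- (1 + sum(null_r >= obs$r)) / (1 + n)
  obs
}

#' Repeated random scan selection and prediction
#'
#' Repeats one-scan-per-subject selection, age-stratified fold assignment
#' and cross-validated prediction, returning the distribution of accuracy
#' across repeats; optionally collects whole-sample SVR weights per repeat
#' for contribution analysis.
#'
#' @param panel Cohort tibble.
#' @param measure_cols Names of the per-node feature columns.
#' @param n_repeats Number of random selections (default 1000).
#' @param k Folds per repeat.
#' @param seed Integer seed.
#' @param config An [svr_config()].
#' @param collect_weights Also fit an SVR on all selected scans per repeat
#'   and average the primal weights across repeats.
#' @return List: `r_values` tibble `(rep, r)`, `summary` (mean and 5th/95th
#'   percentiles), and `mean_weights` (per-node, `NULL` unless requested).
#' @export
resample_and_predict <- function(panel, measure_cols, n_repeats = 1000,
                                 k = 10L, seed = 1L, config = svr_config(),
                                 collect_weights = FALSE) {
  rep_seeds <- derive_seeds(seed, 2 * n_repeats)
  wsum <- NULL
  rs <- vapply(seq_len(n_repeats), function(b) {
    sel <- select_independent_scans(panel, seed = rep_seeds[b])
    x <- as.matrix(sel[, measure_cols])
    folds <- stratified_folds(sel$age, k = k, seed = rep_seeds[n_repeats + b])
    if (collect_weights) {
      xs <- if (config$scale_features) minmax_apply(x, minmax_fit(x)) else x
      w <- fit_linear_svr(xs, sel$age, config)$w
      wsum <<- if (is.null(wsum)) w else wsum + w
    }
    predict_age(x, sel$age, folds, config)$r
  }, numeric(1))
  list(r_values = tibble(rep = seq_len(n_repeats), r = rs),
       summary = tibble(mean_r = mean(rs),
                        p5 = quantile(rs, 0.05, names = FALSE),
                        p95 = quantile(rs, 0.95, names = FALSE)),
       mean_weights = if (collect_weights) wsum / n_repeats else NULL)
}

#' Feature contribution weights of a whole-sample linear SVR
#'
#' Fits one linear SVR on all rows (after global min-max scaling) and
#' reports the primal coefficients as feature importances.  With a
#' parcellation, positive and negative node weights are additionally
#' averaged separately within each functional system.
#'
#' @param features Numeric scan-by-node matrix.
#' @param targets Numeric target vector.
#' @param config An [svr_config()] (linear kernel only).
#' @param parc Optional parcellation tibble (row per node, `system` column).
#' @return A `contribution_weights` list: `weights` tibble
#'   `(node, weight)` and `by_system` tibble
#'   `(system, direction, mean_weight, n)` when `parc` is given.
#' @export
contribution_weights <- function(features, targets, config = svr_config(),
                                 parc = NULL) {
  features <- as.matrix(features)
  x <- if (config$scale_features) minmax_apply(features, minmax_fit(features)) else features
  w <- fit_linear_svr(x, targets, config)$w
  weights <- tibble(node = seq_along(w), weight = w)
  by_system <- NULL
  if (!is.null(parc)) {
    if (nrow(parc) != length(w)) {
      abort("parcellation does not cover the feature nodes",
            class = "overlapnet_labeling_error")
    }
    by_system <- tibble(system = parc$system, weight = w) |>
      dplyr::mutate(direction = ifelse(.data$weight >= 0, "positive", "negative")) |>
      dplyr::group_by(.data$system, .data$direction) |>
      dplyr::summarise(mean_weight = mean(.data$weight), n = dplyr::n(),
                       .groups = "drop")
  }
  structure(list(weights = weights, by_system = by_system),
            class = "contribution_weights")
}

#' Remove covariate and subject-specific effects before prediction
#'
#' For each measure, fits the linear mixed age model and subtracts the
#' estimated sex effect, mFD effect and subject-specific random effects
#' (intercept and age slope), keeping the population fixed-age signal and
#' the residual.
#'
#' @param panel Cohort tibble.
#' @param measures Measure column names to adjust.
#' @return The panel with each measure column replaced by its adjusted
#'   values (`NA` where the model could not be fitted).
#' @export
residualize_for_prediction <- function(panel, measures) {
  check_panel(panel)
  for (m in measures) {
    fit <- fit_mixed_linear(panel, m)
    if (is.null(fit$model)) {
      panel[[m]] <- NA_real_
      next
    }
    fx <- fit$fixed
    beta <- setNames(fx$estimate, fx$term)
    # with `||` random effects the grouping factor appears once per term
    re_list <- lme4::ranef(fit$model)
    re <- do.call(cbind, unname(re_list[names(re_list) == "subject"]))
    subj <- as.character(panel$subject_id)
    b0 <- if ("(Intercept)" %in% colnames(re)) re[subj, "(Intercept)"] else 0
    b_age <- if ("age" %in% colnames(re)) re[subj, "age"] else 0
    adj <- panel[[m]] -
      beta[["sex"]] * panel$sex -
      beta[["mFD"]] * panel$mFD -
      b0 - b_age * panel$age
    panel[[m]] <- as.numeric(adj)
  }
  panel
}

#' Nodal FA strength from a mean-FA connection matrix
#'
#' Sums the mean fractional anisotropy of a node's connections to all
#' other nodes (row sums of the FA matrix, diagonal excluded).
#'
#' @param fa_matrix Symmetric nonnegative node-by-node matrix of mean FA
#'   values per connection.
#' @param tol Symmetry tolerance.
#' @return Numeric per-node FA strength.
#' @export
fa_strength <- function(fa_matrix, tol = 1e-8) {
  if (!is.matrix(fa_matrix) || nrow(fa_matrix) != ncol(fa_matrix) ||
      max(abs(fa_matrix - t(fa_matrix))) > tol) {
    abort("FA matrix must be square and symmetric",
          class = "overlapnet_consistency_error")
  }
  if (any(fa_matrix < 0)) stop_domain("FA values must be nonnegative")
  as.numeric(rowSums(fa_matrix) - diag(fa_matrix))
}

structural_feature_names <- c("CV", "CT", "CC", "FI", "SA", "FA_strength")

#' Predict a scan's nodal entropy map from structural features
#'
#' Nodes are the cross-validation items: they are split into `k` random
#' folds, and for each fold a linear SVR trained on the remaining nodes'
#' six structural features (cortical volume, thickness, curvature,
#' folding index, surface area, FA strength) predicts the held-out nodes'
#' entropy.  A whole-scan refit provides per-feature weights.
#'
#' @param features Node-by-6 matrix or tibble with columns `CV`, `CT`,
#'   `CC`, `FI`, `SA`, `FA_strength`.
#' @param entropy Numeric per-node entropy (NA allowed; such nodes are
#'   dropped).
#' @param k Number of node folds (default 10).
#' @param seed Integer seed for the random fold split.
#' @param config An [svr_config()].
#' @param fit_weights Also refit on all nodes for feature weights.
#' @return A `prediction_result` with an extra `feature_weights` tibble
#'   `(feature, weight)` when `fit_weights = TRUE`.
#' @export
predict_entropy_from_structure <- function(features, entropy, k = 10L,
                                           seed = 1L, config = svr_config(),
                                           fit_weights = TRUE) {
  if (is.data.frame(features)) {
    missing_cols <- setdiff(structural_feature_names, names(features))
    if (length(missing_cols) > 0) {
      stop_format(sprintf("missing structural feature columns: %s",
                          paste(missing_cols, collapse = ", ")))
    }
    features <- as.matrix(features[, structural_feature_names])
  }
  keep <- !is.na(entropy) & stats::complete.cases(features)
  x <- features[keep, , drop = FALSE]
  y <- entropy[keep]
  if (length(y) < k) stop_domain("fewer non-missing nodes than folds")
  folds <- withr::with_seed(seed, sample(rep_len(seq_len(k), length(y))))
  res <- predict_age(x, y, folds, config)  # same CV engine, nodes as items
  res$predictions$item <- which(keep)
  if (fit_weights) {
    xs <- if (config$scale_features) minmax_apply(x, minmax_fit(x)) else x
    w <- fit_linear_svr(xs, y, config)$w
    res$feature_weights <- tibble(feature = colnames(features) %||%
                                    structural_feature_names,
                                  weight = w)
  }
  res
}

#' Aggregated shuffled null for structure-based entropy prediction
#'
#' For every scan the entropy map is shuffled across nodes
#' `shuffles_per_scan` times and the node-fold prediction rerun; null
#' accuracies are pooled over scans.  A scan is significant when its
#' observed accuracy exceeds the pooled 95th percentile.
#'
#' @param scans List of scans, each a list with elements `features`
#'   (node x 6) and `entropy` (per-node).
#' @param shuffles_per_scan Shuffles per scan (default 100).
#' @param k,config,seed As in [predict_entropy_from_structure()].
#' @return List: `null_r` (length `n_scans * shuffles_per_scan`),
#'   `threshold95`, `per_scan` tibble `(scan, r, significant)`.
#' @export
structure_prediction_null <- function(scans, shuffles_per_scan = 100,
                                      k = 10L, seed = 1L,
                                      config = svr_config()) {
  n_scans <- length(scans)
  seeds <- derive_seeds(seed, n_scans * 2L)
  null_r <- numeric(n_scans * shuffles_per_scan)
  obs_r <- numeric(n_scans)
  idx <- 0L
  for (s in seq_len(n_scans)) {
    sc <- scans[[s]]
    x <- if (is.data.frame(sc$features)) {
      as.matrix(sc$features[, structural_feature_names])
    } else as.matrix(sc$features)
    keep <- !is.na(sc$entropy) & stats::complete.cases(x)
    x <- x[keep, , drop = FALSE]
    y <- sc$entropy[keep]
    if (length(y) < k) stop_domain("fewer non-missing nodes than folds")
    folds <- withr::with_seed(seeds[s], sample(rep_len(seq_len(k), length(y))))
    obs_r[s] <- cor(cv_svr_pred(x, y, folds, config), y)
    withr::with_seed(seeds[n_scans + s], {
      for (b in seq_len(shuffles_per_scan)) {
        yp <- sample(y)
        idx <- idx + 1L
        null_r[idx] <- cor(cv_svr_pred(x, yp, folds, config), yp)
      }
    })
  }
  thr <- quantile(null_r, 0.95, names = FALSE)
  list(null_r = null_r, threshold95 = thr,
       per_scan = tibble(scan = seq_len(n_scans), r = obs_r,
                         significant = obs_r > thr))
}

#' Univariate structure-entropy correlations
#'
#' Pearson correlation across nodes between the entropy map and each
#' structural feature.
#'
#' @param features Node-by-feature matrix or tibble.
#' @param entropy Numeric per-node entropy.
#' @return Tibble `(feature, r)`; constant features give `NA`.
#' @export
univariate_structure_correlations <- function(features, entropy) {
  features <- as.matrix(if (is.data.frame(features)) features else features)
  keep <- !is.na(entropy) & stats::complete.cases(features)
  purrr::map_dfr(seq_len(ncol(features)), function(jc) {
    v <- features[keep, jc]
    r <- if (sd(v) == 0 || sd(entropy[keep]) == 0) NA_real_ else cor(v, entropy[keep])
    tibble(feature = colnames(features)[jc] %||% as.character(jc), r = r)
  })
}
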