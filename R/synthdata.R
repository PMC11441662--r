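# Synthetic cohorts with planted ground truth: overlapping modular
# correlation matrices, longitudinal measures from the linear mixed
# generative model, structural features coupled to entropy, and sphere
# coordinates for spatial-autocorrelation tests.

#' Generate a correlation matrix with planted overlapping modules
#'
#' Nodes are assigned to `n_modules` contiguous primary blocks; a fraction
#' of nodes receives a second, randomly chosen module membership.  The
#' correlation between two nodes is
#' `between + within * |shared modules| / max(|m_i|, |m_j|)` plus
#' symmetric Gaussian noise, clipped to (-0.99, 0.99) with unit diagonal.
#' Dual-membership nodes connect into two blocks and are the planted
#' "overlapping regions".
#'
#' @param n_nodes Number of nodes (default 232).
#' @param n_modules Number of planted modules (default 7).
#' @param overlap_fraction Fraction of nodes given a second membership.
#' @param within_strength Added correlation for a fully shared membership.
#' @param between_strength Baseline correlation between all node pairs.
#' @param noise_sd Standard deviation of the symmetric Gaussian noise.
#' @param seed Integer seed.
#' @return List with `corr` (a [corr_matrix()]) and `truth` (memberships,
#'   overlap indicator, parameters, seed).
#' @export
gen_overlapping_network <- function(n_nodes = 232L, n_modules = 7L,
                                    overlap_fraction = 0.3,
                                    within_strength = 0.6,
                                    between_strength = 0.05,
                                    noise_sd = 0.05, seed = 1L) {
  if (overlap_fraction < 0 || overlap_fraction > 1) {
    stop_domain("overlap_fraction must lie in [0, 1]")
  }
  if (between_strength + within_strength >= 1 || between_strength < 0) {
    stop_domain("strengths must satisfy 0 <= between and between + within < 1")
  }
  withr::with_seed(seed, {
    primary <- sort(rep_len(seq_len(n_modules), n_nodes))
    membership <- lapply(primary, function(m) m)
    n_dual <- round(overlap_fraction * n_nodes)
    dual_nodes <- sort(sample.int(n_nodes, n_dual))
    for (nd in dual_nodes) {
      extra <- sample(setdiff(seq_len(n_modules), membership[[nd]]), 1)
      membership[[nd]] <- sort(c(membership[[nd]], extra))
    }
    share <- matrix(0, n_nodes, n_nodes)
    for (a in seq_len(n_nodes)) {
      ma <- membership[[a]]
      for (b in seq_len(n_nodes)) {
        mb <- membership[[b]]
        share[a, b] <- length(intersect(ma, mb)) / max(length(ma), length(mb))
      }
    }
    noise <- matrix(rnorm(n_nodes^2, sd = noise_sd), n_nodes)
    noise <- (noise + t(noise)) / 2
    m <- between_strength + within_strength * share + noise
    m <- pmin(pmax(m, -0.99), 0.99)
    corr <- corr_matrix(m)
    list(corr = corr,
         truth = list(membership = membership,
                      dual_nodes = dual_nodes,
                      n_memberships = lengths(membership),
                      n_modules = n_modules,
                      params = list(overlap_fraction = overlap_fraction,
                                    within_strength = within_strength,
                                    between_strength = between_strength,
                                    noise_sd = noise_sd),
                      seed = seed))
  })
}

#' Generate a longitudinal cohort from the linear mixed age model
#'
#' Each subject receives 1-3 scans about one year apart (jittered),
#' baseline ages uniform over the cohort range; per-node measures follow
#' `y = beta0 + b_i + (beta_age + b_age_i) * age + beta_sex * sex +
#' beta_mFD * mFD + eps` with independent Gaussian random effects.  Sex is
#' Bernoulli(0.5); mFD is drawn from a right-skewed lognormal capped at
#' 0.5 mm (the usual motion-exclusion ceiling).
#'
#' @param n_subjects Number of subjects (default 305, the reference cohort
#'   size yielding 491 scans in expectation with the default mix).
#' @param scan_counts Either a named vector of exact subject counts per
#'   scan number (e.g. `c("1" = 166, "2" = 92, "3" = 47)`, the default) or
#'   probabilities over 1..3 scans.
#' @param age_range Baseline-age range in years (default `c(6, 14)`).
#' @param node_slopes Named numeric vector of true fixed age slopes, one
#'   per measure column (names become column names).
#' @param beta0 Fixed intercept.
#' @param beta_sex,beta_mFD Fixed covariate effects.
#' @param re_sd Length-2 vector: SDs of the random intercept and random
#'   age slope.
#' @param noise_sd Residual SD.
#' @param seed Integer seed.
#' @return List with `panel` (cohort tibble) and `truth`.
#' @export
gen_longitudinal_cohort <- function(n_subjects = 305L,
                                    scan_counts = c("1" = 166, "2" = 92, "3" = 47),
                                    age_range = c(6, 14),
                                    node_slopes = c(node_1 = 0.02),
                                    beta0 = 0.5, beta_sex = 0.02,
                                    beta_mFD = -0.1,
                                    re_sd = c(0.05, 0.01),
                                    noise_sd = 0.05, seed = 1L) {
  if (length(age_range) != 2 || diff(age_range) <= 0) {
    stop_domain("age_range must be an increasing length-2 vector")
  }
  if (is.null(names(node_slopes))) {
    names(node_slopes) <- paste0("node_", seq_along(node_slopes))
  }
  withr::with_seed(seed, {
    counts <- scan_counts
    if (!is.null(names(counts)) && sum(counts) == n_subjects) {
      n_scans <- sample(rep(as.integer(names(counts)), times = counts))
    } else {
      pr <- counts / sum(counts)
      n_scans <- sample(seq_along(pr), n_subjects, replace = TRUE, prob = pr)
    }
    sex <- rbinom(n_subjects, 1, 0.5)
    b0 <- rnorm(n_subjects, sd = re_sd[1])
    b_age <- matrix(rnorm(n_subjects * length(node_slopes), sd = re_sd[2]),
                    n_subjects)
    rows <- purrr::map_dfr(seq_len(n_subjects), function(i) {
      ns <- n_scans[i]
      base_age <- runif(1, age_range[1], age_range[2] - (ns - 1))
      gaps <- if (ns > 1) cumsum(c(0, 1 + rnorm(ns - 1, sd = 0.1))) else 0
      ages <- pmin(base_age + gaps, age_range[2])
      tibble(subject_id = sprintf("sub-%03d", i),
             scan_id = sprintf("sub-%03d_ses-%d", i, seq_len(ns)),
             age = ages, sex = sex[i],
             mFD = pmin(rlnorm(ns, meanlog = log(0.12), sdlog = 0.4), 0.5))
    })
    subj_idx <- as.integer(factor(rows$subject_id,
                                  levels = sprintf("sub-%03d", seq_len(n_subjects))))
    for (jn in seq_along(node_slopes)) {
      mcol <- names(node_slopes)[jn]
      rows[[mcol]] <- beta0 + b0[subj_idx] +
        (node_slopes[jn] + b_age[subj_idx, jn]) * rows$age +
        beta_sex * rows$sex + beta_mFD * rows$mFD +
        rnorm(nrow(rows), sd = noise_sd)
    }
    list(panel = rows,
         truth = list(node_slopes = node_slopes, beta0 = beta0,
                      beta_sex = beta_sex, beta_mFD = beta_mFD,
                      re_sd = re_sd, noise_sd = noise_sd,
                      n_scans = n_scans, seed = seed))
  })
}

#' Generate structural features linearly coupled to an entropy map
#'
#' Each of the six features (cortical volume, thickness, curvature,
#' folding index, surface area, FA strength) is
#' `loading * standardize(entropy) + Gaussian noise`.  Default loadings
#' follow the empirical sign pattern: thickness couples positively,
#' the other five negatively.
#'
#' @param entropy Numeric per-node entropy map.
#' @param loadings Named length-6 vector of loadings (names `CV`, `CT`,
#'   `CC`, `FI`, `SA`, `FA_strength`).
#' @param noise_sd Feature noise SD (on the standardized scale).
#' @param seed Integer seed.
#' @return List with `features` (node x 6 tibble) and `truth`.
#' @export
gen_structural_features <- function(entropy,
                                    loadings = c(CV = -0.6, CT = 0.6,
                                                 CC = -0.6, FI = -0.6,
                                                 SA = -0.6, FA_strength = -0.6),
                                    noise_sd = 0.8, seed = 1L) {
  if (!all(is.finite(loadings)) || length(loadings) != 6) {
    stop_domain("loadings must be 6 finite values")
  }
  z <- as.numeric(scale(entropy))
  withr::with_seed(seed, {
    cols <- lapply(seq_along(loadings), function(f) {
      loadings[f] * z + rnorm(length(z), sd = noise_sd)
    })
    features <- tibble::as_tibble(setNames(cols, names(loadings)))
    list(features = features,
         truth = list(loadings = loadings, noise_sd = noise_sd, seed = seed))
  })
}

#' Generate quasi-uniform node coordinates on a sphere
#'
#' Golden-spiral (Fibonacci) points on a sphere of the given radius with a
#' small seeded angular jitter; supports distance-based surrogate tests.
#'
#' @param n_nodes Number of nodes (>= 4).
#' @param radius Sphere radius in mm (default 80, brain-scale).
#' @param seed Integer seed for the jitter.
#' @return Tibble `(node, x, y, z)`.
#' @export
gen_coordinates <- function(n_nodes, radius = 80, seed = 1L) {
  if (n_nodes < 4) stop_domain("need at least 4 nodes")
  golden <- pi * (3 - sqrt(5))
  i <- seq_len(n_nodes) - 1
  z <- 1 - 2 * (i + 0.5) / n_nodes
  theta <- golden * i
  withr::with_seed(seed, {
    theta <- theta + rnorm(n_nodes, sd = 0.01)
    r_xy <- sqrt(pmax(0, 1 - z^2))
    tibble(node = seq_len(n_nodes),
           x = radius * r_xy * cos(theta),
           y = radius * r_xy * sin(theta),
           z = radius * z)
  })
}

#' Pairwise Euclidean distances between node coordinates
#'
#' @param coords Tibble with `x`, `y`, `z` columns (see [gen_coordinates()]).
#' @return Symmetric distance matrix with zero diagonal.
#' @export
coordinate_distances <- function(coords) {
  as.matrix(stats::dist(as.matrix(coords[, c("x", "y", "z")])))
}

#' Assign nodes to functional systems in contiguous blocks
#'
#' Synthetic stand-in for a parcellation table: the eight systems (VIS,
#' SM, DA, VA, LIM, FP, DM, SUB) are laid out as contiguous node blocks.
#'
#' @param n_nodes Number of nodes.
#' @return Parcellation tibble `(node_id, name, system)`.
#' @export
gen_parcellation <- function(n_nodes = 232L) {
  systems <- c("VIS", "SM", "DA", "VA", "LIM", "FP", "DM", "SUB")
  sys <- sort(rep_len(seq_along(systems), n_nodes))
  tibble(node_id = default_node_ids(n_nodes),
         name = sprintf("%s_%d", systems[sys], seq_len(n_nodes)),
         system = systems[sys])
}
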