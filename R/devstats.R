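# Longitudinal age-effect estimation: linear and quadratic mixed models
# with subject-level random intercepts and age slopes, AIC selection,
# node-wise FDR, decile binning of effect maps.

check_panel <- function(panel, measure = NULL) {
  required <- c("subject_id", "scan_id", "age", "sex", "mFD")
  missing_cols <- setdiff(required, names(panel))
  if (length(missing_cols) > 0) {
    stop_format(sprintf("cohort panel missing columns: %s",
                        paste(missing_cols, collapse = ", ")))
  }
  if (!is.null(measure) && !measure %in% names(panel)) {
    stop_format(sprintf("measure column '%s' not in panel", measure))
  }
  invisible(panel)
}

#' Read / write a longitudinal cohort table
#'
#' CSV with columns `subject_id`, `scan_id`, `age` (years), `sex` (0/1),
#' `mFD` (mm) and any number of measure columns.
#'
#' @param path CSV path.
#' @return For `read_cohort`, a validated cohort tibble.
#' @export
read_cohort <- function(path) {
  panel <- readr::read_csv(path, show_col_types = FALSE)
  check_panel(panel)
  panel
}

#' @param panel Cohort tibble.
#' @rdname read_cohort
#' @export
write_cohort <- function(panel, path) {
  check_panel(panel)
  readr::write_csv(panel, path)
  invisible(path)
}

fit_mixed <- function(panel, measure, quadratic) {
  check_panel(panel, measure)
  if (dplyr::n_distinct(panel$subject_id) < 2) {
    stop_domain("mixed model needs at least 2 subjects")
  }
  d <- data.frame(y = panel[[measure]],
                  age = panel$age, age2 = panel$age^2,
                  sex = panel$sex, mFD = panel$mFD,
                  subject = factor(panel$subject_id))
  forms <- if (quadratic) {
    list(full = y ~ age + age2 + sex + mFD + (1 + age + age2 || subject),
         intercept = y ~ age + age2 + sex + mFD + (1 | subject))
  } else {
    list(full = y ~ age + sex + mFD + (1 + age || subject),
         intercept = y ~ age + sex + mFD + (1 | subject))
  }
  fallback <- "none"
  fit <- NULL
  for (level in names(forms)) {
    res <- tryCatch({
      withCallingHandlers(
        lmerTest::lmer(forms[[level]], data = d, REML = FALSE,
                       control = lme4::lmerControl(calc.derivs = FALSE,
                                                   check.conv.singular =
                                                     lme4::.makeCC(action = "ignore", tol = 1e-4))),
        warning = function(w) {
          if (grepl("converge", conditionMessage(w), ignore.case = TRUE)) {
            invokeRestart("muffleWarning")  # handled via optinfo below
          }
        })
    }, error = function(e) NULL)
    if (!is.null(res)) {
      msgs <- unlist(res@optinfo$conv$lme4$messages)
      failed <- any(grepl("failed to converge", msgs, ignore.case = TRUE))
      if (!failed) { fit <- res; fallback <- level; break }
      if (is.null(fit)) { fit <- res; fallback <- paste0(level, " (unconverged)") }
    }
  }
  if (is.null(fit)) {
    return(structure(list(model = NULL, model_type = if (quadratic) "quadratic" else "linear",
                          converged = FALSE, fallback = "none", aic = Inf,
                          loglik = NA_real_, fixed = NULL, measure = measure),
                     class = "mixed_fit"))
  }
  converged <- !grepl("unconverged", fallback, fixed = TRUE)
  ct <- as.data.frame(coef(summary(fit)))
  fixed <- tibble(term = rownames(ct),
                  estimate = ct[["Estimate"]],
                  std_error = ct[["Std. Error"]],
                  statistic = ct[["t value"]],
                  df = ct[["df"]],
                  p_value = ct[["Pr(>|t|)"]])
  structure(list(model = fit,
                 model_type = if (quadratic) "quadratic" else "linear",
                 converged = converged,
                 fallback = fallback,
                 aic = AIC(fit),
                 loglik = as.numeric(logLik(fit)),
                 fixed = fixed,
                 measure = measure),
            class = "mixed_fit")
}

#' Linear mixed-effects age model
#'
#' Fits `y ~ age + sex + mFD` with a subject-specific random intercept and
#' random age slope (independent random effects), estimated by maximum
#' likelihood.  Degrees of freedom and p-values for fixed effects use the
#' Satterthwaite approximation.  On optimizer non-convergence the model
#' falls back to a random intercept only; the ladder step taken is
#' recorded in `fallback`.
#'
#' @param panel Cohort tibble with columns `subject_id`, `scan_id`, `age`
#'   (years), `sex` (0/1), `mFD` (mm) and measure columns.
#' @param measure Name of the measure column to model.
#' @return A `mixed_fit`; see [tidy.mixed_fit()] and [glance.mixed_fit()].
#' @export
fit_mixed_linear <- function(panel, measure) fit_mixed(panel, measure, quadratic = FALSE)

#' Quadratic mixed-effects age model
#'
#' As [fit_mixed_linear()] with fixed and random `age^2` terms added.
#'
#' @inheritParams fit_mixed_linear
#' @return A `mixed_fit`.
#' @export
fit_mixed_quadratic <- function(panel, measure) fit_mixed(panel, measure, quadratic = TRUE)

#' @export
print.mixed_fit <- function(x, ...) {
  cat(sprintf("<mixed_fit> %s model of '%s' (AIC %.2f, %s)\n",
              x$model_type, x$measure %||% "?", x$aic,
              if (x$converged) "converged" else "NOT converged"))
  if (!is.null(x$fixed)) print(x$fixed)
  invisible(x)
}

# Age term summarizing developmental change: the highest-order age term of
# the fitted model.
age_term <- function(fit) if (fit$model_type == "quadratic") "age2" else "age"

#' Select among candidate mixed fits by AIC
#'
#' Non-converged fits are excluded; ties go to the earlier (simpler)
#' candidate in the list order.
#'
#' @param fits List of `mixed_fit` objects (conventionally linear first).
#' @return The chosen `mixed_fit`.
#' @export
select_by_aic <- function(fits) {
  ok <- Filter(function(f) isTRUE(f$converged), fits)
  if (length(ok) == 0) {
    abort("no converged fit to select from", class = "overlapnet_selection_error")
  }
  aics <- vapply(ok, function(f) f$aic, numeric(1))
  ok[[which.min(aics)]]  # which.min returns the first minimum: simpler wins ties
}

#' Benjamini-Hochberg FDR correction
#'
#' @param pvals Numeric p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return Tibble `(p_value, p_adj, significant)` in input order.
#' @export
fdr_correct <- function(pvals, q = 0.05) {
  if (length(pvals) == 0) stop_domain("empty p-value vector")
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop_domain("p-values must lie in [0, 1]")
  adj <- p.adjust(pvals, method = "BH")
  tibble(p_value = pvals, p_adj = adj, significant = !is.na(adj) & adj <= q)
}

#' Node-wise age effects with AIC model selection and FDR
#'
#' For every measure column, fits the linear and quadratic mixed models,
#' keeps the AIC-preferred one, takes the t and p of its highest-order age
#' term, and corrects p across nodes by Benjamini-Hochberg.
#'
#' @inheritParams fit_mixed_linear
#' @param measures Character vector of measure column names (one per node).
#' @param q FDR level.
#' @param quadratic Set `FALSE` to skip the quadratic candidate (faster;
#'   linear-only screening).
#' @return An `age_effect_map` tibble `(node, model, estimate, t, p, p_adj,
#'   significant, converged, fallback)`.
#' @export
nodewise_age_effects <- function(panel, measures, q = 0.05, quadratic = TRUE) {
  rows <- purrr::map_dfr(measures, function(m) {
    cands <- list(fit_mixed_linear(panel, m))
    if (quadratic) cands <- c(cands, list(fit_mixed_quadratic(panel, m)))
    ok <- any(vapply(cands, function(f) isTRUE(f$converged), logical(1)))
    if (!ok) {
      return(tibble(node = m, model = NA_character_, estimate = NA_real_,
                    t = NA_real_, p = NA_real_, converged = FALSE,
                    fallback = "none"))
    }
    fit <- select_by_aic(cands)
    row <- fit$fixed[fit$fixed$term == age_term(fit), ]
    tibble(node = m, model = fit$model_type, estimate = row$estimate,
           t = row$statistic, p = row$p_value, converged = TRUE,
           fallback = fit$fallback)
  })
  adj <- fdr_correct(ifelse(is.na(rows$p), 1, rows$p), q = q)
  rows$p_adj <- ifelse(is.na(rows$p), NA_real_, adj$p_adj)
  rows$significant <- !is.na(rows$p) & adj$significant
  class(rows) <- c("age_effect_map", class(rows))
  rows
}

#' Decile bins of a nodal effect map
#'
#' Sorts nodes by value in decreasing order and splits them into 10
#' near-equal contiguous bins (bin 1 = highest values).  When the node
#' count is not divisible by 10 the first `n %% 10` bins receive one extra
#' node, e.g. 232 nodes give sizes 24, 24, 23, ..., 23.
#'
#' @param values Numeric per-node values (length >= 10).
#' @param node_ids Optional labels.
#' @return Tibble `(node, node_id, value, bin)`; the 10 bins partition the
#'   node set.
#' @export
decile_bins <- function(values, node_ids = NULL) {
  n <- length(values)
  if (n < 10) stop_domain("need at least 10 nodes for decile bins")
  node_ids <- node_ids %||% default_node_ids(n)
  sizes <- rep(n %/% 10L, 10L)
  rem <- n %% 10L
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  ord <- order(-values)  # stable for ties
  bin <- integer(n)
  bin[ord] <- rep(seq_len(10L), times = sizes)
  tibble(node = seq_len(n), node_id = node_ids, value = values, bin = bin)
}
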