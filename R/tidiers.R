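# broom-style tidiers for the package's fitted/derived objects.

#' Tidy a mixed-effects age-model fit
#'
#' @param x A `mixed_fit`.
#' @param ... Unused.
#' @return Tibble of fixed effects `(term, estimate, std_error, statistic,
#'   df, p_value)`.
#' @method tidy mixed_fit
#' @export
tidy.mixed_fit <- function(x, ...) {
  if (is.null(x$fixed)) return(tibble(term = character(), estimate = numeric()))
  x$fixed
}

#' @rdname tidy.mixed_fit
#' @return For `glance`: one-row tibble with model type, AIC,
#'   log-likelihood and convergence information.
#' @method glance mixed_fit
#' @export
glance.mixed_fit <- function(x, ...) {
  tibble(model = x$model_type, aic = x$aic, log_lik = x$loglik,
         converged = x$converged, fallback = x$fallback)
}

#' Tidy an edge partition
#'
#' @param x An `edge_partition`.
#' @param ... Unused.
#' @return Tibble `(edge_id, module)`.
#' @method tidy edge_partition
#' @export
tidy.edge_partition <- function(x, ...) {
  tibble(edge_id = seq_along(x$labels), module = x$labels)
}

#' @rdname tidy.edge_partition
#' @method glance edge_partition
#' @export
glance.edge_partition <- function(x, ...) {
  tibble(n_modules = x$n_modules, modularity = x$modularity,
         seed = x$seed, converged = x$converged %||% NA,
         iterations = x$iterations %||% NA_integer_)
}

#' Tidy a Louvain instance ensemble
#'
#' @param x An `instance_ensemble`.
#' @param ... Unused.
#' @return Tibble with one row per instance `(instance, seed, n_modules,
#'   modularity)`.
#' @method tidy instance_ensemble
#' @export
tidy.instance_ensemble <- function(x, ...) {
  tibble(instance = seq_along(x$partitions), seed = x$seeds,
         n_modules = x$n_per_instance, modularity = x$q_per_instance)
}

#' @rdname tidy.instance_ensemble
#' @method glance instance_ensemble
#' @export
glance.instance_ensemble <- function(x, ...) {
  tibble(n_instances = length(x$partitions), modal_n = x$modal_n,
         mean_modularity = x$mean_modularity)
}

#' Tidy a prediction result
#'
#' @param x A `prediction_result`.
#' @param ... Unused.
#' @return Tibble of pooled out-of-fold predictions.
#' @method tidy prediction_result
#' @export
tidy.prediction_result <- function(x, ...) x$predictions

#' @rdname tidy.prediction_result
#' @method glance prediction_result
#' @export
glance.prediction_result <- function(x, ...) {
  tibble(n = nrow(x$predictions), r = x$r,
         p = x[["p"]] %||% NA_real_,
         n_permutations = if (is.null(x[["null_r"]])) NA_integer_ else length(x[["null_r"]]))
}

#' Tidy contribution weights
#'
#' @param x A `contribution_weights` object.
#' @param ... Unused.
#' @return The per-node weight tibble.
#' @method tidy contribution_weights
#' @export
tidy.contribution_weights <- function(x, ...) x$weights
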