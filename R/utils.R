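# Internal helpers shared across modules.

# Derive `n` reproducible child seeds from one master seed.  Children stay
# below 2^31 - 1 so they remain valid R integer seeds.
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Stable default node labels when a matrix carries none.
default_node_ids <- function(n) as.character(seq_len(n) - 1L)

stop_domain <- function(msg, ...) abort(msg, class = "overlapnet_domain_error", ...)
stop_format <- function(msg, ...) abort(msg, class = "overlapnet_format_error", ...)
stop_parse  <- function(msg, ...) abort(msg, class = "overlapnet_parse_error", ...)

check_square_symmetric <- function(m, tol = 1e-10, what = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop_format(sprintf("%s must be a square matrix", what))
  }
  if (max(abs(m - t(m))) > tol) {
    stop_format(sprintf("%s is not symmetric within tolerance %g", what, tol))
  }
  invisible(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
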