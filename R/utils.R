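# Internal helpers shared across modules.

#' @useDynLib plumetrics, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Structured error with a machine-readable class, so callers and tests can
# match on condition class rather than message text.
pf_stop <- function(code, msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(code, "plumetrics_error", "error"),
                      call = call))
}

pf_warn <- function(code, msg) {
  warning(warningCondition(msg, class = c(code, "plumetrics_warning",
                                          "warning")))
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream; generators must be pure functions of their spec.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    pf_stop("invalid_spec", "seed must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Nearest-rank quantile: value at position ceiling(p * n) of the sorted
# vector. Bit-reproducible; used for all intensity thresholds.
nearest_rank_quantile <- function(x, p) {
  stopifnot(p > 0, p <= 1)
  s <- sort(x, method = "quick")
  s[max(1L, ceiling(p * length(s)))]
}

# Nematic angle representative in [0, pi).
wrap_nematic <- function(theta) {
  out <- theta %% pi
  out[out >= pi] <- 0
  out
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    pf_stop("invalid_spec", sprintf("%s must be a single positive number", name))
  invisible(x)
}
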