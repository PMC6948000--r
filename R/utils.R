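#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef complete.cases lm lm.fit model.matrix pchisq pf pnorm
#'   pt qnorm qt rbeta rbinom rgamma rlnorm rnorm runif sd setNames var
#' @importFrom utils head modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Two-sided normal quantile for a confidence level
#'
#' @param level confidence level in (0, 1), e.g. 0.95.
#' @return the multiplier z such that effect +/- z * se spans the interval.
#' @export
ci_multiplier <- function(level = 0.95) {
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    stop("`level` must be a single number in (0, 1)", call. = FALSE)
  }
  qnorm(1 - (1 - level) / 2)
}

# smallest representable two-sided p, used to keep p in (0, 1] for
# degenerate (perfect) fits
.p_floor <- function(p) pmax(p, .Machine$double.xmin)

# validate that a scalar field is a finite number, naming the field on failure
.check_finite <- function(value, field) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value)) {
    stop(sprintf("config field `%s` must be a single finite number", field),
         call. = FALSE)
  }
  invisible(value)
}

# Dirichlet draws via normalized gammas; alpha is the concentration vector
.rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  x / rowSums(x)
}

# derive a stream-specific seed from a base seed, kept below 2^31
.derived_seed <- function(seed, offset) {
  as.integer((as.double(seed) + offset) %% .Machine$integer.max)
}
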