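# Independent oracles used across test files. These deliberately avoid the
# package's own code paths: plain lm()/solve() arithmetic only.

# brute-force LMG: average incremental R-squared over all orderings of the
# predictor columns, each R-squared from summary(lm())
lmg_bruteforce <- function(y, X) {
  X <- as.matrix(X)
  p <- ncol(X)
  orderings <- perms(seq_len(p))
  shares <- numeric(p)
  r2_of <- function(cols) {
    if (length(cols) == 0L) return(0)
    summary(lm(y ~ X[, cols, drop = FALSE]))$r.squared
  }
  for (o in seq_len(nrow(orderings))) {
    ord <- orderings[o, ]
    prev <- 0
    for (i in seq_len(p)) {
      cur <- r2_of(ord[seq_len(i)])
      shares[ord[i]] <- shares[ord[i]] + (cur - prev)
      prev <- cur
    }
  }
  shares / nrow(orderings)
}

# all permutations of a vector, rows of a matrix
perms <- function(v) {
  if (length(v) == 1L) return(matrix(v, 1))
  out <- NULL
  for (i in seq_along(v)) {
    rest <- perms(v[-i])
    out <- rbind(out, cbind(v[i], rest))
  }
  out
}

# closed-form OLS via the normal equations, returning effect and SE of the
# column named (or indexed) `which`
ols_oracle <- function(y, X, which = 2L) {
  XtX_inv <- solve(t(X) %*% X)
  beta <- XtX_inv %*% t(X) %*% y
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  s2 <- sum(res^2) / df
  c(effect = beta[which], se = sqrt(s2 * XtX_inv[which, which]))
}

# small default cohort config for tests that just need structure
test_config <- function(...) {
  args <- utils::modifyList(list(n_samples = 80, n_probes = 300,
                                 n_causal = 20, seed = 42L), list(...))
  do.call(synthetic_config, args)
}

cell_col_names <- paste0("cf_", c("B", "CD4T", "CD8T", "Gran", "Mono", "NK"))
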