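# Reference-based leukocyte deconvolution: per-sample nonnegative least
# squares projection onto a cell-type reference profile (Houseman-style),
# followed by sum-to-one normalization.

# Lawson-Hanson active-set nonnegative least squares: minimise ||Ax - b||^2
# subject to x >= 0. Deterministic; adequate for the small systems here
# (tens of probes x six cell types).
.nnls <- function(A, b, tol = NULL) {
  n <- ncol(A)
  if (is.null(tol)) tol <- 10 * .Machine$double.eps * max(abs(A)) * max(dim(A))
  x <- numeric(n)
  passive <- logical(n)
  w <- drop(crossprod(A, b))
  iter <- 0L
  max_iter <- 30L * n
  while (any(!passive) && any(w[!passive] > tol) && iter < max_iter) {
    iter <- iter + 1L
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      Ap <- A[, passive, drop = FALSE]
      z <- numeric(n)
      z[passive] <- qr.coef(qr(Ap), b)
      z[is.na(z)] <- 0
      if (all(z[passive] > tol)) break
      zp <- z[passive]
      xp <- x[passive]
      neg <- zp <= tol & (xp - zp) > tol
      if (!any(neg)) { x <- pmax(z, 0); break }
      alpha <- min(xp[neg] / (xp[neg] - zp[neg]))
      x <- x + alpha * (z - x)
      passive[passive] <- x[passive] > tol
      x[!passive] <- 0
      if (!any(passive)) break
    }
    x <- z
    x[!passive] <- 0
    w <- drop(crossprod(A, b - A %*% x))
  }
  x
}

#' Synthetic cell-type reference profile
#'
#' A small discriminating probe set (10 probes per cell type by default) with
#' well-separated mean beta values: each block is highly methylated in its
#' own cell type and lowly methylated elsewhere, with deterministic jitter.
#' This is a synthetic stand-in for published whole-blood L-DMR reference
#' libraries, which are not redistributed here; a real library in the same
#' layout (probes x cell types) can be supplied instead.
#'
#' @param probes_per_type discriminating probes per cell type.
#' @param cell_types character vector of cell-type labels.
#' @param seed deterministic jitter seed.
#' @return matrix (probes x cell types) of mean beta values in `[0, 1]`.
#' @export
synthetic_cell_reference <- function(probes_per_type = 10,
                                     cell_types = .cell_types,
                                     seed = 20200107L) {
  k <- length(cell_types)
  m <- probes_per_type * k
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ref <- matrix(runif(m * k, 0.05, 0.20), m, k)
  for (j in seq_len(k)) {
    rows <- (j - 1L) * probes_per_type + seq_len(probes_per_type)
    ref[rows, j] <- runif(probes_per_type, 0.80, 0.95)
  }
  dimnames(ref) <- list(sprintf("cellref_%03d", seq_len(m)), cell_types)
  ref
}

#' Estimate leukocyte cell fractions by constrained projection
#'
#' For each sample, finds the nonnegative mixture of reference cell-type
#' profiles closest (least squares) to the observed betas on the shared
#' probe set, then normalizes the weights to sum to one.
#'
#' @param meth methylation beta matrix (probes x samples) whose rownames
#'   share probes with the reference.
#' @param ref cell reference matrix (probes x cell types), values in
#'   `[0, 1]`, at least two cell types, full column rank on shared probes.
#' @return matrix of class `cell_fractions` (samples x cell types), rows
#'   summing to 1; attribute `n_shared_probes` records the overlap used.
#' @export
estimate_cell_fractions <- function(meth, ref) {
  stopifnot(is.matrix(meth), is.matrix(ref))
  if (ncol(ref) < 2L) stop("reference needs at least two cell types",
                           call. = FALSE)
  if (anyNA(ref)) stop("reference contains missing entries", call. = FALSE)
  shared <- intersect(rownames(meth), rownames(ref))
  if (length(shared) == 0L) {
    stop("no shared probes between methylation matrix and reference",
         call. = FALSE)
  }
  A <- ref[shared, , drop = FALSE]
  if (qr(A)$rank < ncol(A)) {
    stop("reference is rank deficient on the shared probe set", call. = FALSE)
  }
  Y <- meth[shared, , drop = FALSE]
  out <- t(apply(Y, 2, function(b) {
    x <- .nnls(A, b)
    s <- sum(x)
    if (s <= 0) rep(1 / ncol(A), ncol(A)) else x / s
  }))
  dimnames(out) <- list(colnames(meth), colnames(ref))
  attr(out, "n_shared_probes") <- length(shared)
  class(out) <- c("cell_fractions", class(out))
  out
}
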