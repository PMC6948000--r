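# Detection p-value quality control: a sample or probe is excluded when the
# fraction of its measurements with detection p above `p_threshold` strictly
# exceeds `max_fail_fraction` (the classic "p > 0.01 in more than 5% of
# measures" array rule).

#' Flag samples and probes failing detection p-value QC
#'
#' Failing fractions for samples and probes are computed on the full matrix
#' simultaneously and both sets removed in one pass, which makes the result
#' independent of evaluation order. An iterative mode re-evaluates fractions
#' after each removal round until a fixed point.
#'
#' @param det detection p-value matrix, probes x samples, values in `[0, 1]`.
#' @param p_threshold detection p above this value counts as a failure
#'   (strict inequality).
#' @param max_fail_fraction a sample/probe is excluded when its failing
#'   fraction strictly exceeds this limit.
#' @param iterative re-evaluate after removals until stable (default FALSE).
#' @return object of class `qc_report`: lists of `excluded_samples` and
#'   `excluded_probes`, the per-entity failing fractions, and the thresholds.
#' @export
qc_filter <- function(det, p_threshold = 0.01, max_fail_fraction = 0.05,
                      iterative = FALSE) {
  if (!is.matrix(det) || nrow(det) == 0L || ncol(det) == 0L) {
    stop("detection matrix must be a non-empty matrix", call. = FALSE)
  }
  for (nm in c("p_threshold", "max_fail_fraction")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v >= 1) {
      stop(sprintf("`%s` must lie in (0, 1)", nm), call. = FALSE)
    }
  }
  if (is.null(rownames(det))) rownames(det) <- sprintf("p%d", seq_len(nrow(det)))
  if (is.null(colnames(det))) colnames(det) <- sprintf("s%d", seq_len(ncol(det)))

  fail <- det > p_threshold
  sample_frac <- colMeans(fail)
  probe_frac <- rowMeans(fail)
  excl_s <- names(sample_frac)[sample_frac > max_fail_fraction]
  excl_p <- names(probe_frac)[probe_frac > max_fail_fraction]

  if (iterative) {
    repeat {
      keep_p <- setdiff(rownames(det), excl_p)
      keep_s <- setdiff(colnames(det), excl_s)
      sub <- fail[keep_p, keep_s, drop = FALSE]
      if (nrow(sub) == 0L || ncol(sub) == 0L) break
      new_s <- names(which(colMeans(sub) > max_fail_fraction))
      new_p <- names(which(rowMeans(sub) > max_fail_fraction))
      if (length(new_s) == 0L && length(new_p) == 0L) break
      excl_s <- union(excl_s, new_s)
      excl_p <- union(excl_p, new_p)
    }
  }

  structure(list(
    excluded_samples = excl_s,
    excluded_probes = excl_p,
    sample_fail_fraction = sample_frac,
    probe_fail_fraction = probe_frac,
    p_threshold = p_threshold,
    max_fail_fraction = max_fail_fraction,
    iterative = iterative
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "<qc_report> %d sample(s), %d probe(s) excluded (p > %g in > %g%% of measures)\n",
    length(x$excluded_samples), length(x$excluded_probes),
    x$p_threshold, 100 * x$max_fail_fraction))
  invisible(x)
}

#' Subset a methylation matrix by a QC report
#'
#' Removes the excluded probes (rows) and samples (columns) while preserving
#' the order of survivors.
#'
#' @param meth methylation beta matrix, probes x samples, with dimnames.
#' @param report a [qc_filter()] result referring to `meth`'s identifiers.
#' @return the filtered matrix.
#' @export
apply_qc <- function(meth, report) {
  stopifnot(is.matrix(meth), inherits(report, "qc_report"))
  ids <- c(report$excluded_probes, report$excluded_samples)
  known <- c(rownames(meth), colnames(meth))
  missing <- setdiff(ids, known)
  if (length(missing)) {
    stop(sprintf("QC report names identifiers absent from the matrix: %s",
                 missing[1L]), call. = FALSE)
  }
  keep_p <- !(rownames(meth) %in% report$excluded_probes)
  keep_s <- !(colnames(meth) %in% report$excluded_samples)
  meth[keep_p, keep_s, drop = FALSE]
}
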