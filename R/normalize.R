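#' Positive-control normalization factor
#'
#' One factor per sample derived from the geometric mean of its
#' positive-control probes. In the default `"corrective"` direction the
#' factor is grand-mean-of-geomeans / sample-geomean, so multiplying one
#' sample's counts by c divides its factor by c and the factors cancel
#' technical depth. The `"literal"` direction returns the reciprocal
#' (sample-geomean / grand mean), which amplifies rather than corrects depth
#' differences; it is kept for auditability.
#'
#' @param raw an `immune_cohort` (counts + annotation).
#' @param direction "corrective" (default) or "literal".
#' @param zero_action what to do when a positive probe count is 0:
#'   "error" (default) or "offset" (add 0.5 before the geometric mean).
#' @param class probe class to use ("positive" here; "housekeeping" in
#'   [housekeeping_factor()]).
#' @return named numeric vector, one strictly positive factor per sample.
#' @export
positive_control_factor <- function(raw,
                                    direction = c("corrective", "literal"),
                                    zero_action = c("error", "offset"),
                                    class = "positive") {
  direction <- match.arg(direction)
  zero_action <- match.arg(zero_action)
  raw <- as_raw_counts(raw)
  probes <- raw$annotation$probe_id[raw$annotation$class == class]
  if (!length(probes)) {
    stop_cfg("no probes of class '%s' in the annotation", class)
  }
  m <- raw$counts[, probes, drop = FALSE]
  if (zero_action == "offset") m <- m + 0.5
  bad <- rownames(m)[apply(m, 1, function(x) any(!is.finite(x) | x <= 0))]
  if (length(bad)) {
    stop_cfg("non-positive %s-probe counts in sample(s): %s (geometric mean undefined)",
             class, paste(bad, collapse = ", "))
  }
  gm <- apply(m, 1, geomean)
  f <- if (direction == "corrective") mean(gm) / gm else gm / mean(gm)
  stats::setNames(f, rownames(m))
}

#' Housekeeping normalization factor
#'
#' Second-step factor, computed exactly as [positive_control_factor()] but on
#' the housekeeping probes of the positive-normalized intermediate matrix.
#'
#' @param intermediate an `immune_cohort` whose counts have already been
#'   scaled by the positive-control factor.
#' @inheritParams positive_control_factor
#' @return named numeric vector of per-sample factors.
#' @export
housekeeping_factor <- function(intermediate,
                                direction = c("corrective", "literal"),
                                zero_action = c("error", "offset")) {
  positive_control_factor(intermediate, direction = match.arg(direction),
                          zero_action = match.arg(zero_action),
                          class = "housekeeping")
}

#' Floor at 1 and log2-transform
#'
#' Replaces all values below 1 by 1, then applies log2, so the output is
#' non-negative and sub-detection values map to exactly 0.
#'
#' @param m numeric matrix with finite, non-negative values.
#' @return matrix of log2 values, same dimnames.
#' @export
floor_log2 <- function(m) {
  if (any(is.na(m)) || any(!is.finite(m))) {
    stop_cfg("floor_log2: matrix contains NA/NaN/Inf values")
  }
  if (any(m < 0)) stop_cfg("floor_log2: negative values are not allowed")
  log2(pmax(m, 1))
}

#' Two-step control-based normalization of raw panel counts
#'
#' Applies, in order: the positive-control factor (technical depth), the
#' housekeeping factor (RNA content) computed on the intermediate matrix,
#' then floor-at-1 and log2, restricted to endogenous probes.
#' Negative-control probes are carried in the input but take no part in
#' normalization (no background subtraction is performed).
#'
#' @inheritParams positive_control_factor
#' @return object of class `normalized_expr`: `log2` (samples x endogenous
#'   probes, all values >= 0), `pos_factor`, `hk_factor`, `direction`,
#'   `samples` metadata.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(diseases = sentinel_panel(), seed = 1))
#' norm <- normalize_counts(cohort)
#' range(norm$log2)
normalize_counts <- function(raw, direction = c("corrective", "literal"),
                             zero_action = c("error", "offset")) {
  direction <- match.arg(direction)
  zero_action <- match.arg(zero_action)
  raw <- as_raw_counts(raw)
  if (any(raw$counts < 0)) stop_cfg("negative counts in input")

  pf <- positive_control_factor(raw, direction, zero_action)
  intermediate <- raw
  intermediate$counts <- raw$counts * pf  # row-wise: factors recycle by row
  hf <- housekeeping_factor(intermediate, direction, zero_action)
  final <- intermediate$counts * hf

  endo <- raw$annotation$probe_id[raw$annotation$class == "endogenous"]
  if (!length(endo)) stop_cfg("no endogenous probes in the annotation")
  structure(list(
    log2 = floor_log2(final[, endo, drop = FALSE]),
    pos_factor = pf,
    hk_factor = hf,
    direction = direction,
    samples = raw$samples
  ), class = "normalized_expr")
}

#' Wrap a pre-normalized log2 expression matrix
#'
#' Entry point for expression data normalized outside the package (e.g.
#' variance-stabilized RNA-seq): wraps a samples x genes matrix of
#' non-negative log-scale values so every downstream stage accepts it.
#'
#' @param m numeric matrix, samples x genes, finite values.
#' @param samples optional sample metadata data.frame (sample_id, disease,
#'   role, ...).
#' @return a `normalized_expr` object (unit normalization factors).
#' @export
as_normalized <- function(m, samples = NULL) {
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop_cfg("matrix must carry sample rownames and gene colnames")
  }
  if (any(!is.finite(m))) stop_cfg("non-finite values in expression matrix")
  structure(list(
    log2 = m,
    pos_factor = stats::setNames(rep(1, nrow(m)), rownames(m)),
    hk_factor = stats::setNames(rep(1, nrow(m)), rownames(m)),
    direction = "none",
    samples = samples %||% data.frame(sample_id = rownames(m),
                                      stringsAsFactors = FALSE)
  ), class = "normalized_expr")
}

#' @export
print.normalized_expr <- function(x, ...) {
  cat(sprintf("normalized_expr: %d samples x %d endogenous probes (%s direction)\n",
              nrow(x$log2), ncol(x$log2), x$direction))
  cat(sprintf("  log2 range: [%.2f, %.2f]\n", min(x$log2), max(x$log2)))
  invisible(x)
}

# accept either a normalized_expr or a bare log2 matrix
as_log2_matrix <- function(x) {
  if (inherits(x, "normalized_expr")) x$log2
  else if (is.matrix(x) && is.numeric(x)) x
  else stop_cfg("expected a 'normalized_expr' or a numeric matrix")
}
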