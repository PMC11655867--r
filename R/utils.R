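#' Geometric mean
#'
#' @param x numeric vector, all values strictly positive.
#' @return the geometric mean of `x`.
#' @keywords internal
geomean <- function(x) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("geometric mean requires strictly positive finite values", call. = FALSE)
  }
  exp(mean(log(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canonical immune module names
#'
#' The seven immune pathways tracked by the package: Th1, Th2, Th17 adaptive
#' axes, type I interferon, and the three myeloid compartments (neutrophilic,
#' macrophagic, eosinophilic).
#'
#' @return character vector of the seven module names.
#' @export
module_names <- function() {
  c("Th1", "Th2", "Th17", "IFN1", "neutro", "macro", "eosino")
}

stop_cfg <- function(...) stop(sprintf(...), call. = FALSE)

# coerce a cohort-like object or matrix into a samples x probes count matrix
# plus annotation; used by normalize and io
as_raw_counts <- function(x) {
  if (inherits(x, "immune_cohort")) {
    return(x)
  }
  if (is.list(x) && !is.null(x$counts) && !is.null(x$annotation)) {
    structure(x, class = "immune_cohort")
  } else {
    stop_cfg("expected an 'immune_cohort' (counts + annotation); got %s",
             paste(class(x), collapse = "/"))
  }
}
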