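#' Raw module scores
#'
#' The raw score of module m in sample s is the arithmetic mean of the log2
#' normalized expression of the module's genes in that sample.
#'
#' @param norm a `normalized_expr` or samples x genes log2 matrix.
#' @param modules a `module_set` (or named list of gene vectors).
#' @return numeric matrix, samples x modules.
#' @export
score_modules <- function(norm, modules) {
  m <- as_log2_matrix(norm)
  mods <- if (inherits(modules, "module_set")) modules$modules else modules
  if (any(!lengths(mods))) {
    stop_cfg("empty module(s): %s",
             paste(names(mods)[!lengths(mods)], collapse = ", "))
  }
  missing <- setdiff(unlist(mods, use.names = FALSE), colnames(m))
  if (length(missing)) {
    stop_cfg("module genes absent from the matrix: %s",
             paste(missing, collapse = ", "))
  }
  out <- vapply(mods, function(g) rowMeans(m[, g, drop = FALSE]),
                numeric(nrow(m)))
  if (nrow(m) == 1L) out <- matrix(out, nrow = 1,
                                   dimnames = list(rownames(m), names(mods)))
  out
}

#' Fit a module's activation threshold from sentinel scores
#'
#' The threshold is the local minimum of a Gaussian kernel density estimate
#' (Silverman's rule-of-thumb bandwidth, 512-point grid) of the pooled
#' positive and negative sentinel scores, searched between the two highest
#' density modes (ties in mode height resolved toward the lower-score mode).
#' The two groups contribute equal total mass to the density, so the valley
#' separates the positive and negative score distributions rather than
#' reflecting their (usually very unequal) sample sizes. If the pooled
#' density is unimodal, or the minimum falls outside the interval spanned by
#' the two group means, the midpoint of the group means is used. The fitted
#' threshold always lies strictly between the negative-group and
#' positive-group means.
#'
#' @param scores numeric vector of sentinel raw scores for one module.
#' @param positive logical vector: is the sentinel positive for the module?
#' @param bw kernel bandwidth rule or value passed to [stats::density()].
#' @param n_grid density grid size.
#' @return the threshold (numeric scalar).
#' @export
fit_threshold <- function(scores, positive, bw = "nrd0", n_grid = 512) {
  if (length(scores) != length(positive)) {
    stop_cfg("scores and positive must have equal length")
  }
  if (sum(positive) < 3 || sum(!positive) < 3) {
    stop_cfg("threshold fitting needs >= 3 positive and >= 3 negative sentinels (got %d / %d)",
             sum(positive), sum(!positive))
  }
  m_pos <- mean(scores[positive])
  m_neg <- mean(scores[!positive])
  lo <- min(m_neg, m_pos)
  hi <- max(m_neg, m_pos)
  midpoint <- (m_neg + m_pos) / 2
  if (lo == hi) return(midpoint)

  w <- ifelse(positive, 0.5 / sum(positive), 0.5 / sum(!positive))
  if (is.character(bw)) {
    bw <- switch(bw, nrd0 = stats::bw.nrd0(scores),
                 nrd = stats::bw.nrd(scores), SJ = stats::bw.SJ(scores),
                 stop_cfg("unknown bandwidth rule '%s'", bw))
  }
  d <- stats::density(scores, bw = bw, n = n_grid, weights = w)
  y <- d$y
  is_mode <- which(diff(sign(diff(y))) == -2) + 1L
  if (y[1] > y[2]) is_mode <- c(1L, is_mode)
  if (y[n_grid] > y[n_grid - 1L]) is_mode <- c(is_mode, n_grid)
  if (length(is_mode) < 2) return(midpoint)

  # two highest modes; equal heights resolve toward the lower-score mode
  ord <- is_mode[order(-y[is_mode], d$x[is_mode])]
  top2 <- sort(ord[1:2])
  seg <- seq(top2[1], top2[2])
  # flat valleys (density numerically 0 between well-separated groups):
  # take the center of the minimal region
  flat <- seg[y[seg] <= min(y[seg]) + 1e-9 * max(y)]
  t_hat <- d$x[flat[ceiling(length(flat) / 2)]]
  if (t_hat <= lo || t_hat >= hi) midpoint else t_hat
}

#' Logistic activation score
#'
#' Maps a raw module score onto [0,1] with a logistic anchored at the fitted
#' threshold: activation is exactly 0.5 at the threshold, and the steepness
#' k = ln(99) / min(t - min, max - t) makes the curve reach 0.01 or 0.99 at
#' the nearer of the sentinel score extremes.
#'
#' @param x raw score(s).
#' @param threshold fitted threshold t, with min < t < max.
#' @param min,max sentinel score range for the module.
#' @return activation value(s) in [0,1], strictly increasing in `x`.
#' @export
activation <- function(x, threshold, min, max) {
  if (min >= max) stop_cfg("degenerate score range: min >= max")
  if (threshold <= min || threshold >= max) {
    stop_cfg("threshold must lie strictly inside (min, max)")
  }
  k <- log(99) / base::min(threshold - min, max - threshold)
  pmin(pmax(stats::plogis(k * (x - threshold)), 0), 1)
}

#' Fit the activation model on sentinel scores
#'
#' Per module: the bimodal threshold ([fit_threshold()]), the sentinel score
#' range, and the logistic steepness of [activation()].
#'
#' @param scores sentinel raw score matrix (samples x modules) from
#'   [score_modules()].
#' @param positive logical matrix (samples x modules): which sentinels are
#'   positive for each module. See [module_positivity()].
#' @param drop_unfittable drop (with a warning) modules lacking the 3
#'   positive and 3 negative sentinels the threshold fit requires, instead
#'   of failing (default TRUE).
#' @return an `activation_model` with a per-module parameter table;
#'   use `predict()` to map new raw scores to activations.
#' @export
fit_activation <- function(scores, positive, drop_unfittable = TRUE) {
  if (!all(dim(scores) == dim(positive))) {
    stop_cfg("scores and positive matrices must have identical dimensions")
  }
  mods <- colnames(scores)
  if (drop_unfittable) {
    ok <- colSums(positive) >= 3 & colSums(!positive) >= 3
    if (!all(ok)) {
      warning(sprintf("dropping module(s) without 3 positive and 3 negative sentinels: %s",
                      paste(mods[!ok], collapse = ", ")), call. = FALSE)
      mods <- mods[ok]
    }
    if (!length(mods)) stop_cfg("no module has enough sentinels to fit")
  }
  par <- do.call(rbind, lapply(mods, function(m) {
    t_m <- fit_threshold(scores[, m], positive[, m])
    data.frame(module = m, threshold = t_m,
               min = min(scores[, m]), max = max(scores[, m]),
               stringsAsFactors = FALSE)
  }))
  par$k <- log(99) / pmin(par$threshold - par$min, par$max - par$threshold)
  rownames(par) <- par$module
  structure(list(parameters = par), class = "activation_model")
}

#' @export
print.activation_model <- function(x, ...) {
  cat("activation_model (logistic, anchored at the bimodal threshold):\n")
  print(format(x$parameters, digits = 3), ...)
  invisible(x)
}

#' @param object an `activation_model`.
#' @param newdata raw score matrix (samples x modules).
#' @param ... unused.
#' @rdname fit_activation
#' @export
predict.activation_model <- function(object, newdata, ...) {
  par <- object$parameters
  missing <- setdiff(par$module, colnames(newdata))
  if (length(missing)) {
    stop_cfg("score matrix lacks module(s): %s", paste(missing, collapse = ", "))
  }
  out <- vapply(par$module, function(m) {
    activation(newdata[, m], par[m, "threshold"], par[m, "min"], par[m, "max"])
  }, numeric(nrow(newdata)))
  if (nrow(newdata) == 1L) {
    out <- matrix(out, nrow = 1,
                  dimnames = list(rownames(newdata), par$module))
  }
  out
}

#' Expected module positivity of sentinel samples
#'
#' Which samples count as positive for each module when fitting thresholds:
#' a sample is positive for every module its generating/assigned disease
#' expresses (dominant or co-dominant), as given by a disease -> modules map.
#'
#' @param diseases character vector of per-sample disease labels.
#' @param disease_modules named list: disease -> character vector of modules
#'   expressed by that disease (empty for healthy-like labels). For simulated
#'   cohorts use `cohort$truth$dominant`-style maps or
#'   [panel_disease_modules()].
#' @param modules module names (columns of the result).
#' @return logical matrix, samples x modules.
#' @export
module_positivity <- function(diseases, disease_modules,
                              modules = module_names()) {
  bad <- setdiff(unique(diseases), names(disease_modules))
  if (length(bad)) {
    stop_cfg("no module map for disease(s): %s", paste(bad, collapse = ", "))
  }
  out <- t(vapply(diseases, function(d) modules %in% disease_modules[[d]],
                  logical(length(modules))))
  dimnames(out) <- list(names(diseases) %||% NULL, modules)
  out
}

#' Disease-to-module map of a disease panel
#'
#' @param panel list of [disease_profile()]s.
#' @param include_subdominant count subdominant modules as positive? Default
#'   FALSE: threshold fitting contrasts full expression against the rest.
#' @return named list disease -> modules.
#' @export
panel_disease_modules <- function(panel = default_disease_panel(),
                                  include_subdominant = FALSE) {
  out <- lapply(panel, function(p) {
    c(p$dominant, if (include_subdominant) p$subdominant)
  })
  stats::setNames(out, vapply(panel, `[[`, "", "name"))
}

#' Co-dominant module set of one sample
#'
#' Modules whose activation exceeds 0.5 and lies within 30% of the highest
#' activation (multiplicatively: a >= 0.7 * max activation).
#'
#' @param a named numeric vector of activations for one sample.
#' @param gate activation gate (default 0.5).
#' @param within relative closeness to the maximum (default 0.7).
#' @return character vector of co-dominant module names (possibly empty).
#' @export
call_codominance <- function(a, gate = 0.5, within = 0.7) {
  names(a)[a > gate & a >= within * max(a)]
}

#' Dominance call for one sample
#'
#' A module is dominant when its activation exceeds 0.5 and its score is
#' significantly greater than every other module's, assessed by a one-sided
#' gene-resampling bootstrap: module genes are resampled with replacement
#' and the score difference recomputed, B times. The resampled values are
#' the sample's gene-level *deviations* from a reference expression profile
#' (typically the per-gene mean across the sentinel cohort): fixed
#' expression differences between genes carry no information about the
#' sample's module enrichment and would otherwise dominate the resampling
#' variance. Only the module with the maximal raw score can satisfy the
#' test, so the called dominant module always has the top raw score. If no
#' module qualifies but two or more exceed the 0.5 gate, the sample is
#' called co-dominant ([call_codominance()]); if none exceed the gate, the
#' status is "none". Exact score ties never produce an arbitrary dominant
#' call.
#'
#' @param a named activation vector for the sample.
#' @param gene_values named list: module -> numeric vector of the sample's
#'   log2 values on the module's genes.
#' @param B bootstrap replicates (>= 100; default 1000).
#' @param alpha one-sided significance level (default 0.05).
#' @param gate activation gate (default 0.5).
#' @param center named list matching `gene_values`: per-gene reference
#'   means subtracted before resampling. NULL resamples the raw values.
#' @return list: `status` ("dominant" | "co-dominant" | "none"), `dominant`
#'   (module or NA), `codominant` (character vector), `p_values` (bootstrap
#'   p of the candidate against each other module, or NULL).
#' @export
call_dominance <- function(a, gene_values, B = 1000, alpha = 0.05,
                           gate = 0.5, center = NULL) {
  if (B < 100) stop_cfg("bootstrap needs B >= 100 (got %d)", B)
  stopifnot(setequal(names(a), names(gene_values)))
  scores <- vapply(gene_values, mean, 0)[names(a)]
  deviations <- if (is.null(center)) {
    gene_values
  } else {
    stats::setNames(lapply(names(gene_values), function(m) {
      gene_values[[m]] - center[[m]]
    }), names(gene_values))
  }

  none <- list(status = "none", dominant = NA_character_,
               codominant = character(), p_values = NULL)
  over <- names(a)[a > gate]
  if (!length(over)) return(none)

  # only the top raw scorer can beat all others; ties are never broken
  cand <- names(scores)[which.max(scores)]
  p_values <- NULL
  if (cand %in% over && sum(scores == scores[cand]) == 1L) {
    others <- setdiff(names(a), cand)
    boot_means <- function(g) {
      idx <- sample.int(length(g), length(g) * B, replace = TRUE)
      colMeans(matrix(g[idx], nrow = length(g)))
    }
    bm_cand <- boot_means(deviations[[cand]])
    p_values <- vapply(others, function(m) {
      mean(bm_cand - boot_means(deviations[[m]]) <= 0)
    }, 0)
    if (all(p_values < alpha)) {
      return(list(status = "dominant", dominant = cand,
                  codominant = character(), p_values = p_values))
    }
  }
  if (length(over) >= 2) {
    return(list(status = "co-dominant", dominant = NA_character_,
                codominant = call_codominance(a, gate = gate),
                p_values = p_values))
  }
  none
}

#' Score a cohort: activations and dominance calls for every sample
#'
#' Convenience wrapper composing [score_modules()], an activation model and
#' per-sample dominance/co-dominance calls.
#'
#' @inheritParams score_modules
#' @param model a fitted `activation_model`.
#' @param B,alpha bootstrap parameters of [call_dominance()].
#' @param seed optional seed for the bootstrap resampling.
#' @param gene_center named per-gene reference means used to center gene
#'   values in the dominance bootstrap; typically the sentinel cohort's
#'   per-gene means (a `cartography`'s `center` field). Defaults to the
#'   column means of the matrix being scored, which is appropriate when
#'   scoring the sentinel cohort itself.
#' @return an `activation_table`: `scores`, `activations` (matrices) and
#'   `calls` (data.frame: sample_id, status, dominant, codominant).
#' @export
call_modules <- function(norm, modules, model, B = 1000, alpha = 0.05,
                         seed = NULL, gene_center = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  m <- as_log2_matrix(norm)
  mods <- if (inherits(modules, "module_set")) modules$modules else modules
  mods <- mods[intersect(names(mods), model$parameters$module)]
  scores <- score_modules(m, mods)
  act <- predict(model, scores)
  gene_center <- gene_center %||% colMeans(m)
  ctr <- lapply(mods, function(g) gene_center[g])
  calls <- do.call(rbind, lapply(seq_len(nrow(m)), function(i) {
    gv <- lapply(mods, function(g) m[i, g])
    res <- call_dominance(act[i, ], gv, B = B, alpha = alpha, center = ctr)
    data.frame(sample_id = rownames(m)[i], status = res$status,
               dominant = res$dominant,
               codominant = paste(res$codominant, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  structure(list(scores = scores, activations = act, calls = calls),
            class = "activation_table")
}

#' @export
print.activation_table <- function(x, ...) {
  cat(sprintf("activation_table: %d samples x %d modules\n",
              nrow(x$scores), ncol(x$scores)))
  print(table(status = x$calls$status), ...)
  invisible(x)
}
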