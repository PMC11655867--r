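#' Fit the sentinel reference cartography
#'
#' Builds the diagnostic reference from sentinel biopsies: the normalized
#' matrix restricted to the chosen gene set, per-gene z-score parameters
#' (mean and SD across sentinels; constant genes are dropped with a warning),
#' a dendrogram on 1 - Pearson correlation between samples (complete
#' linkage, computed on the normalized expression), and a PCA embedding of
#' the z-scored matrix used for back-projecting query samples. The embedding
#' is a deterministic linear map, so classification needs no stochastic seed.
#'
#' @param norm a `normalized_expr` or samples x genes log2 matrix of the
#'   sentinel biopsies.
#' @param labels per-sentinel disease labels.
#' @param modules a `module_set` (required when `gene_set = "module"`).
#' @param gene_set "module" (module genes only, the default) or "all".
#' @param rank number of embedding components retained (default 10, capped
#'   at n - 1 and at the number of variance-bearing components).
#' @return a `cartography` object.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(diseases = sentinel_panel(), seed = 1))
#' norm <- normalize_counts(cohort)
#' carto <- fit_cartography(norm, cohort$samples$disease,
#'                          modules = cohort$truth$module_genes)
#' summary(carto)
fit_cartography <- function(norm, labels,
                            modules = NULL,
                            gene_set = c("module", "all"),
                            rank = 10) {
  gene_set <- match.arg(gene_set)
  m <- as_log2_matrix(norm)
  labels <- as.character(labels)
  if (length(labels) != nrow(m)) {
    stop_cfg("labels length (%d) != number of sentinels (%d)",
             length(labels), nrow(m))
  }
  if (length(unique(labels)) < 2) {
    stop_cfg("cartography needs at least 2 diseases")
  }
  small <- table(labels)
  if (any(small < 3)) {
    warning(sprintf("disease(s) with < 3 sentinels: %s",
                    paste(names(small)[small < 3], collapse = ", ")),
            call. = FALSE)
  }

  if (gene_set == "module") {
    if (is.null(modules)) stop_cfg("gene_set='module' requires a module set")
    mods <- if (inherits(modules, "module_set")) modules$modules else modules
    genes <- unlist(mods, use.names = FALSE)
    missing <- setdiff(genes, colnames(m))
    if (length(missing)) {
      stop_cfg("module genes absent from the matrix: %s",
               paste(missing, collapse = ", "))
    }
  } else {
    genes <- colnames(m)
  }
  x <- m[, genes, drop = FALSE]

  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  if (any(sd == 0)) {
    warning(sprintf("dropping %d constant gene(s): %s", sum(sd == 0),
                    paste(utils::head(genes[sd == 0], 5), collapse = ", ")),
            call. = FALSE)
    keep <- sd > 0
    x <- x[, keep, drop = FALSE]
    mu <- mu[keep]; sd <- sd[keep]; genes <- genes[keep]
  }
  z <- sweep(sweep(x, 2, mu), 2, sd, "/")

  # dendrogram on the normalized expression (not z-scores), as the reference
  # clustering; complete linkage over 1 - Pearson between samples
  hc <- stats::hclust(stats::as.dist(1 - stats::cor(t(x))),
                      method = "complete")

  pca <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  pos_var <- sum(pca$sdev > 1e-10)
  r <- min(rank, nrow(z) - 1L, pos_var)
  structure(list(
    x = x, z = z, labels = stats::setNames(labels, rownames(x)),
    genes = genes, center = mu, scale = sd,
    hclust = hc,
    rotation = pca$rotation[, seq_len(r), drop = FALSE],
    embedding = pca$x[, seq_len(r), drop = FALSE],
    rank = r,
    k = length(unique(labels)),
    gene_set = gene_set
  ), class = "cartography")
}

#' @export
print.cartography <- function(x, ...) {
  cat(sprintf("cartography: %d sentinels, %d diseases, %d genes (%s set), embedding rank %d\n",
              nrow(x$z), x$k, length(x$genes), x$gene_set, x$rank))
  invisible(x)
}

#' @export
summary.cartography <- function(object, ...) {
  print(object)
  tb <- table(object$labels)
  cat("  sentinels per disease:",
      paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  sd_diag <- sentinel_diagnosis(object)
  cat(sprintf("  dendrogram cut at k=%d: FM = %.3f vs sentinel labels\n",
              object$k, fm_index(sd_diag$cluster, object$labels)))
  invisible(object)
}

#' Plot the sentinel map
#'
#' First two embedding components, colored by disease; optionally overlays
#' projected query samples as filled triangles.
#'
#' @param x a `cartography`.
#' @param queries optional matrix of query samples (samples x genes) to
#'   back-project.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cartography <- function(x, queries = NULL, ...) {
  lv <- sort(unique(x$labels))
  col <- stats::setNames(grDevices::hcl.colors(length(lv), "Dark 3"), lv)
  graphics::plot(x$embedding[, 1], x$embedding[, 2],
                 col = col[x$labels], pch = 1,
                 xlab = "component 1", ylab = "component 2", ...)
  if (!is.null(queries)) {
    zq <- project_onto(x, queries)
    graphics::points(zq[, 1], zq[, 2], pch = 17)
  }
  graphics::legend("topright", legend = lv, col = col, pch = 1, cex = 0.7)
  invisible(x)
}

# z-score a query matrix with sentinel parameters and project into the
# fitted embedding
project_onto <- function(carto, newdata) {
  if (is.null(dim(newdata))) {
    newdata <- matrix(newdata, nrow = 1,
                      dimnames = list("query", names(newdata)))
  }
  missing <- setdiff(carto$genes, colnames(newdata))
  if (length(missing)) {
    stop_cfg("query lacks cartography gene(s): %s",
             paste(utils::head(missing, 10), collapse = ", "))
  }
  z <- sweep(sweep(newdata[, carto$genes, drop = FALSE], 2, carto$center),
             2, carto$scale, "/")
  z %*% carto$rotation
}

#' Classify query samples by back-projection onto the sentinel map
#'
#' Each query is z-scored with the sentinel parameters, projected into the
#' fitted embedding, and assigned the majority disease among its k nearest
#' sentinels (Euclidean distance in the embedding; `method = "direct"`
#' instead uses 1 - Pearson correlation in the z-scored gene space). Voting
#' ties are broken toward the tied disease with the smallest mean distance.
#'
#' @param object a `cartography`.
#' @param newdata query matrix (samples x genes) or a single named vector;
#'   a `normalized_expr` is also accepted.
#' @param k number of neighbors (default 5; must not exceed the sentinel
#'   count).
#' @param method "embedding" (default) or "direct".
#' @param expected_dominant optional named map disease -> module; together
#'   with `dominant_calls` it fills the concordance flag.
#' @param dominant_calls optional per-query dominant-module calls.
#' @param ... unused.
#' @return data.frame: sample_id, assigned, votes (winning votes out of k),
#'   one `dist_<disease>` column per disease (mean embedding distance to
#'   that disease's sentinels), and `concordant` when determinable.
#' @export
predict.cartography <- function(object, newdata, k = 5,
                                method = c("embedding", "direct"),
                                expected_dominant = NULL,
                                dominant_calls = NULL, ...) {
  method <- match.arg(method)
  newdata <- as_log2_matrix_or_vector(newdata)
  if (k > nrow(object$z)) {
    stop_cfg("k = %d exceeds the number of sentinels (%d)", k, nrow(object$z))
  }
  if (method == "embedding") {
    q <- project_onto(object, newdata)
    ref <- object$embedding
    dmat <- outer_dist(q, ref)
  } else {
    missing <- setdiff(object$genes, colnames(newdata))
    if (length(missing)) {
      stop_cfg("query lacks cartography gene(s): %s",
               paste(utils::head(missing, 10), collapse = ", "))
    }
    zq <- sweep(sweep(newdata[, object$genes, drop = FALSE], 2,
                      object$center), 2, object$scale, "/")
    dmat <- 1 - stats::cor(t(zq), t(object$z))
    if (is.null(dim(dmat))) dmat <- matrix(dmat, nrow = 1)
  }
  labels <- object$labels
  diseases <- sort(unique(labels))

  res <- do.call(rbind, lapply(seq_len(nrow(dmat)), function(i) {
    d <- dmat[i, ]
    nn <- order(d)[seq_len(k)]
    votes <- table(factor(labels[nn], levels = diseases))
    mean_d <- vapply(diseases, function(g) mean(d[labels == g]), 0)
    top <- names(votes)[votes == max(votes)]
    assigned <- if (length(top) == 1L) top else top[which.min(mean_d[top])]
    out <- data.frame(sample_id = rownames(dmat)[i] %||% rownames(newdata)[i],
                      assigned = assigned,
                      votes = as.integer(max(votes)),
                      stringsAsFactors = FALSE)
    for (g in diseases) out[[paste0("dist_", g)]] <- mean_d[[g]]
    out
  }))
  if (!is.null(expected_dominant) && !is.null(dominant_calls)) {
    res$concordant <- unname(
      unlist(expected_dominant[res$assigned]) == dominant_calls |
        vapply(seq_along(dominant_calls), function(i) {
          dominant_calls[i] %in% expected_dominant[[res$assigned[i]]]
        }, TRUE))
  }
  rownames(res) <- NULL
  res
}

as_log2_matrix_or_vector <- function(x) {
  if (inherits(x, "normalized_expr")) return(x$log2)
  if (is.null(dim(x))) {
    return(matrix(x, nrow = 1, dimnames = list("query", names(x))))
  }
  x
}

# Euclidean distances between rows of a and rows of b
outer_dist <- function(a, b) {
  aa <- rowSums(a^2); bb <- rowSums(b^2)
  d2 <- outer(aa, bb, "+") - 2 * a %*% t(b)
  d <- sqrt(pmax(d2, 0))
  rownames(d) <- rownames(a)
  d
}

#' Dendrogram-based diagnosis of the sentinels
#'
#' Cuts the sentinel dendrogram at k clusters and maps each cluster to a
#' disease by optimal one-to-one (Hungarian) assignment on the cluster x
#' disease contingency table. This is the route used to compute reference
#' performance metrics for sentinel samples.
#'
#' @param carto a `cartography`.
#' @param k number of clusters (default: number of diseases).
#' @return data.frame: sample_id, cluster (integer), predicted (disease).
#' @export
sentinel_diagnosis <- function(carto, k = NULL) {
  k <- k %||% carto$k
  cl <- stats::cutree(carto$hclust, k = k)
  tab <- table(cluster = cl, disease = carto$labels)
  map <- hungarian_assignment(as.matrix(tab))
  map[map > ncol(tab)] <- NA_integer_  # surplus clusters map to no disease
  names(map) <- rownames(tab)
  predicted <- colnames(tab)[map[as.character(cl)]]
  data.frame(sample_id = names(cl), cluster = unname(cl),
             predicted = predicted, stringsAsFactors = FALSE)
}

# maximum-weight one-to-one assignment of rows to columns of a non-negative
# score matrix (Hungarian algorithm with row/column potentials and
# shortest augmenting paths on the square-padded cost matrix). Returns the
# assigned column index for each row; padded columns may appear when there
# are more rows than columns.
hungarian_assignment <- function(score) {
  nr <- nrow(score); nc <- ncol(score)
  n <- max(nr, nc)
  a <- matrix(0, n, n)
  a[seq_len(nr), seq_len(nc)] <- max(score) - score
  inf <- .Machine$double.xmax / 4
  u <- numeric(n)            # row potentials, 1..n
  v <- numeric(n + 1)        # column potentials, index j+1 for j = 0..n
  p <- integer(n + 1)        # p[j+1]: row matched to column j (0 = free)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]; delta <- inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- a[i0, j] - u[i0] - v[j + 1]
          if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
          if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          if (p[j + 1] > 0) u[p[j + 1]] <- u[p[j + 1]] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(n)) if (p[j + 1] > 0) ans[p[j + 1]] <- j
  ans[seq_len(nr)]
}
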