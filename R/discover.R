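#' One-vs-rest differential expression
#'
#' Compares a target disease group against a set of rest groups on the log2
#' normalized matrix. The log2 fold change is the difference of group means;
#' p-values come from a moderated t-test (empirical-Bayes pooled variance via
#' limma, the default) or from a per-gene Welch t-test, with
#' Benjamini-Hochberg adjustment across all tested genes.
#'
#' @param norm a `normalized_expr` or samples x genes log2 matrix.
#' @param labels character/factor vector of group labels, one per sample.
#' @param target label of the target group.
#' @param rest labels forming the rest group; default all other labels.
#' @param method "moderated" (limma empirical Bayes) or "welch".
#' @return a `de_result` data.frame: gene, log2fc (target minus rest),
#'   p, padj.
#' @export
differential_expression <- function(norm, labels, target, rest = NULL,
                                    method = c("moderated", "welch")) {
  method <- match.arg(method)
  m <- as_log2_matrix(norm)
  labels <- as.character(labels)
  if (length(labels) != nrow(m)) {
    stop_cfg("labels length (%d) != number of samples (%d)",
             length(labels), nrow(m))
  }
  rest <- rest %||% setdiff(unique(labels), target)
  missing <- setdiff(c(target, rest), labels)
  if (length(missing)) {
    stop_cfg("group(s) absent from labels: %s", paste(missing, collapse = ", "))
  }
  keep <- labels %in% c(target, rest)
  m <- m[keep, , drop = FALSE]
  grp <- labels[keep] == target
  if (sum(grp) < 2 || sum(!grp) < 2) {
    stop_cfg("differential expression needs >= 2 samples per side (target %d, rest %d)",
             sum(grp), sum(!grp))
  }

  log2fc <- colMeans(m[grp, , drop = FALSE]) - colMeans(m[!grp, , drop = FALSE])

  if (method == "moderated") {
    design <- cbind(Intercept = 1, target = as.numeric(grp))
    fit <- limma::eBayes(limma::lmFit(t(m), design))
    p <- fit$p.value[, "target"]
  } else {
    p <- apply(m, 2, function(x) {
      a <- x[grp]; b <- x[!grp]
      if (stats::sd(a) == 0 && stats::sd(b) == 0) {
        return(if (mean(a) == mean(b)) 1 else 0)
      }
      stats::t.test(a, b)$p.value
    })
  }
  # degenerate genes: no variance anywhere and equal means carry no evidence
  flat <- apply(m, 2, function(x) stats::sd(x) == 0)
  p[flat] <- 1
  log2fc[flat] <- 0
  p[is.na(p)] <- 1

  structure(data.frame(gene = colnames(m), log2fc = unname(log2fc),
                       p = unname(p), padj = stats::p.adjust(p, "BH"),
                       stringsAsFactors = FALSE),
            class = c("de_result", "data.frame"),
            target = target, rest = rest, method = method)
}

#' Select up-regulated module genes from a DE table
#'
#' Genes with log2 fold change above `fc_threshold` and (adjusted or raw)
#' p-value below `p_threshold`; only the up-regulated side defines a module.
#'
#' @param de a `de_result`.
#' @param fc_threshold log2 fold-change cut (default 1, i.e. fold change 2).
#' @param p_threshold p-value cut (default 0.01).
#' @param use_adjusted gate on the BH-adjusted p (default) or the raw p.
#' @return character vector of selected genes.
#' @export
select_module_genes <- function(de, fc_threshold = 1, p_threshold = 0.01,
                                use_adjusted = TRUE) {
  if (fc_threshold <= 0 || p_threshold <= 0) {
    stop_cfg("thresholds must be strictly positive")
  }
  if (!nrow(de)) return(character())
  pv <- if (use_adjusted) de$padj else de$p
  de$gene[de$log2fc > fc_threshold & pv < p_threshold]
}

#' Default module-defining contrasts
#'
#' Each adaptive/interferon module is defined by its model disease against
#' all other groups; the myeloid signature is split into neutrophilic,
#' macrophagic and eosinophilic modules by the three-way contrast between
#' neutrophilic dermatoses, COVID-associated skin lesions and Wells syndrome.
#'
#' @return named list: module -> list(target, rest); `rest = NULL` means all
#'   other groups present in the labels.
#' @export
default_contrasts <- function() {
  list(
    Th17 = list(target = "PsO", rest = NULL),
    Th2  = list(target = "AD",  rest = NULL),
    Th1  = list(target = "LP",  rest = NULL),
    IFN1 = list(target = "CLE", rest = NULL),
    neutro = list(target = "NeuD", rest = c("COVIDskin", "Wells")),
    macro  = list(target = "COVIDskin", rest = c("NeuD", "Wells")),
    eosino = list(target = "Wells", rest = c("NeuD", "COVIDskin"))
  )
}

#' Build a disjoint immune module set by one-vs-rest discovery
#'
#' Runs one differential-expression contrast per module, selects up-regulated
#' genes passing the fold-change and significance gates, assigns genes that
#' pass several contrasts to the contrast with the largest log2 fold change
#' (so module gene lists are pairwise disjoint), and removes genes on a
#' user-supplied exclusion list (the reproducible stand-in for manual
#' curation of functionally unrelated genes).
#'
#' @inheritParams differential_expression
#' @param contrasts named list module -> list(target, rest) as in
#'   [default_contrasts()].
#' @param fc_threshold,p_threshold,use_adjusted gates passed to
#'   [select_module_genes()].
#' @param exclusion character vector of genes to drop from every module.
#' @return a `module_set`: named list of gene vectors plus provenance
#'   (thresholds, contrast and DE method per module, exclusions applied).
#' @export
build_module_set <- function(norm, labels, contrasts = default_contrasts(),
                             fc_threshold = 1, p_threshold = 0.01,
                             use_adjusted = TRUE, exclusion = character(),
                             method = c("moderated", "welch")) {
  method <- match.arg(method)
  labels <- as.character(labels)
  groups <- unique(labels)
  for (nm in names(contrasts)) {
    cc <- contrasts[[nm]]
    bad <- setdiff(c(cc$target, cc$rest), groups)
    if (length(bad)) {
      stop_cfg("contrast '%s' references unknown group(s): %s", nm,
               paste(bad, collapse = ", "))
    }
  }
  de_tables <- lapply(contrasts, function(cc) {
    differential_expression(norm, labels, cc$target, cc$rest, method = method)
  })
  hits <- lapply(de_tables, select_module_genes,
                 fc_threshold = fc_threshold, p_threshold = p_threshold,
                 use_adjusted = use_adjusted)

  # resolve multi-module genes toward the contrast with the largest log2FC
  all_genes <- unique(unlist(hits, use.names = FALSE))
  assigned <- stats::setNames(vector("list", length(contrasts)),
                              names(contrasts))
  for (g in all_genes) {
    in_mods <- names(hits)[vapply(hits, function(h) g %in% h, TRUE)]
    fcs <- vapply(in_mods, function(mn) {
      tb <- de_tables[[mn]]
      tb$log2fc[match(g, tb$gene)]
    }, 0)
    winner <- in_mods[which.max(fcs)]
    assigned[[winner]] <- c(assigned[[winner]], g)
  }
  modules <- lapply(assigned, function(g) setdiff(g %||% character(), exclusion))

  structure(list(
    modules = modules,
    provenance = list(fc_threshold = fc_threshold, p_threshold = p_threshold,
                      use_adjusted = use_adjusted, method = method,
                      contrasts = contrasts, exclusion = exclusion)
  ), class = "module_set")
}

#' Construct a module set from explicit gene lists
#'
#' @param modules named list of character gene vectors; lists must be
#'   pairwise disjoint.
#' @param provenance optional provenance record.
#' @return a `module_set`.
#' @export
module_set <- function(modules, provenance = list(source = "user")) {
  if (is.null(names(modules)) || any(names(modules) == "")) {
    stop_cfg("modules must be a named list")
  }
  genes <- unlist(modules, use.names = FALSE)
  if (anyDuplicated(genes)) {
    stop_cfg("module gene lists overlap: %s",
             paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  structure(list(modules = lapply(modules, as.character),
                 provenance = provenance),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("module_set: %d modules\n", length(x$modules)))
  for (nm in names(x$modules)) {
    g <- x$modules[[nm]]
    cat(sprintf("  %-7s %3d genes%s\n", nm, length(g),
                if (length(g)) paste0(" (", paste(utils::head(g, 3),
                                                  collapse = ", "),
                                      if (length(g) > 3) ", ..." else "", ")")
                else ""))
  }
  invisible(x)
}

#' Write / read a module set as JSON
#'
#' @param x a `module_set`.
#' @param path file path.
#' @return `write_module_set` returns `path` invisibly; `read_module_set`
#'   returns a `module_set`.
#' @export
write_module_set <- function(x, path) {
  stopifnot(inherits(x, "module_set"))
  jsonlite::write_json(list(modules = x$modules, provenance = x$provenance),
                       path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_module_set
#' @export
read_module_set <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  module_set(as.list(obj$modules),
             provenance = as.list(obj$provenance %||% list(source = path)))
}
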