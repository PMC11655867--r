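#' Read raw panel counts from TSV files
#'
#' Counts are stored probes x samples on disk (panel convention), first
#' column the probe id; the in-memory orientation is samples x probes. The
#' annotation must cover every probe with a known class (endogenous,
#' positive, negative, housekeeping). Missing values and negative counts are
#' rejected, never imputed.
#'
#' @param counts_path TSV of counts (probes x samples, first column
#'   `probe_id`).
#' @param annotation_path TSV with columns probe_id, class and optionally
#'   true_module.
#' @param metadata_path optional TSV with a `sample_id` column plus
#'   disease/role/treatment/response columns.
#' @return an `immune_cohort` (no truth component).
#' @export
read_counts <- function(counts_path, annotation_path, metadata_path = NULL) {
  raw <- utils::read.delim(counts_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (!ncol(raw) >= 2) stop_cfg("counts file needs a probe id column plus samples")
  probe_id <- as.character(raw[[1]])
  if (anyDuplicated(probe_id)) {
    stop_cfg("duplicate probe id(s): %s",
             paste(unique(probe_id[duplicated(probe_id)]), collapse = ", "))
  }
  m <- as.matrix(raw[, -1, drop = FALSE])
  if (anyDuplicated(colnames(m))) stop_cfg("duplicate sample ids in counts")
  if (!is.numeric(m) || any(is.na(m))) {
    stop_cfg("counts must be numeric with no missing values")
  }
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    stop_cfg("negative count at probe '%s', sample '%s'",
             probe_id[bad[1]], colnames(m)[bad[2]])
  }
  rownames(m) <- probe_id

  ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
  if (!all(c("probe_id", "class") %in% names(ann))) {
    stop_cfg("annotation needs probe_id and class columns")
  }
  known <- c("endogenous", "positive", "negative", "housekeeping")
  bad_class <- setdiff(unique(ann$class), known)
  if (length(bad_class)) {
    stop_cfg("unknown probe class(es): %s", paste(bad_class, collapse = ", "))
  }
  uncovered <- setdiff(probe_id, ann$probe_id)
  if (length(uncovered)) {
    stop_cfg("probe(s) missing from annotation: %s",
             paste(utils::head(uncovered, 5), collapse = ", "))
  }
  ann <- ann[match(probe_id, ann$probe_id), , drop = FALSE]
  if (is.null(ann$true_module)) ann$true_module <- NA_character_

  samples <- if (!is.null(metadata_path)) {
    md <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
    if (!"sample_id" %in% names(md)) stop_cfg("metadata needs a sample_id column")
    md[match(colnames(m), md$sample_id), , drop = FALSE]
  } else {
    data.frame(sample_id = colnames(m), stringsAsFactors = FALSE)
  }

  structure(list(counts = t(m), annotation = ann, samples = samples),
            class = "immune_cohort")
}

#' Write a cohort to TSV files (plus truth JSON when present)
#'
#' @param cohort an `immune_cohort`.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  cohort <- as_raw_counts(cohort)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  counts <- data.frame(probe_id = colnames(cohort$counts),
                       t(cohort$counts), check.names = FALSE)
  utils::write.table(counts, file.path(dir, "counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$annotation, file.path(dir, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$samples, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$truth)) {
    jsonlite::write_json(
      list(disease = as.list(cohort$truth$disease),
           module_genes = cohort$truth$module_genes,
           dominant = cohort$truth$dominant,
           depth = as.list(cohort$truth$depth)),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

write_provenance <- function(dir, stage, params) {
  jsonlite::write_json(
    list(stage = stage, params = params,
         package = as.character(utils::packageVersion("immunocarto"))),
    file.path(dir, paste0(stage, "_provenance.json")),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the full profiling pipeline
#'
#' Composes the stages end to end: simulate (or read) counts, normalize,
#' discover modules (or use supplied/true gene lists), fit the activation
#' model on sentinels, call dominance, build the cartography, classify
#' challenger samples when provided, evaluate clustering (FM index, per-class
#' metrics) and match treatments when metadata carries them. Every stage
#' writes its artifact and a JSON provenance record into `out_dir`.
#'
#' @param config list with elements: either `sim` (a [sim_config()]) or
#'   `counts`/`annotation`/`metadata` paths; optional `modules` (path to a
#'   module JSON, a `module_set`, or "truth" to use planted gene lists,
#'   the default for simulated cohorts); `direction` (normalization),
#'   `bootstrap` (B), `alpha`, `knn`, `gene_set`, `seed`.
#' @param out_dir output directory.
#' @return list of in-memory artifacts (cohort, norm, modules, activation
#'   table, cartography, evaluation, match summary), invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L

  cohort <- if (!is.null(config$sim)) {
    simulate_cohort(config$sim)
  } else {
    if (is.null(config$counts) || !file.exists(config$counts)) {
      stop_cfg("config$counts path is missing or does not exist")
    }
    read_counts(config$counts, config$annotation, config$metadata)
  }
  write_cohort(cohort, file.path(out_dir, "cohort"))
  write_provenance(out_dir, "simulate",
                   list(seed = seed, simulated = !is.null(config$sim)))

  norm <- normalize_counts(cohort, direction = config$direction %||% "corrective")
  utils::write.table(
    data.frame(probe_id = colnames(norm$log2), t(norm$log2),
               check.names = FALSE),
    file.path(out_dir, "normalized.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = names(norm$pos_factor),
               pos_factor = norm$pos_factor, hk_factor = norm$hk_factor),
    file.path(out_dir, "factors.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  write_provenance(out_dir, "normalize",
                   list(direction = norm$direction, seed = seed))

  modules <- resolve_modules(config, cohort, norm)
  write_module_set(modules, file.path(out_dir, "modules.json"))

  labels <- cohort$samples$disease
  scores <- score_modules(norm, modules)
  dm <- panel_disease_modules(cohort$config$diseases %||%
                                default_disease_panel())
  positive <- module_positivity(labels, dm, modules = colnames(scores))
  act_model <- fit_activation(scores, positive)
  act_tab <- call_modules(norm, modules, act_model,
                          B = config$bootstrap %||% 1000,
                          alpha = config$alpha %||% 0.05, seed = seed)
  utils::write.table(
    data.frame(sample_id = rownames(scores), scores, check.names = FALSE),
    file.path(out_dir, "scores.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = rownames(act_tab$activations),
               act_tab$activations, check.names = FALSE),
    file.path(out_dir, "activations.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(act_tab$calls, file.path(out_dir, "dominance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_provenance(out_dir, "score",
                   list(bootstrap = config$bootstrap %||% 1000,
                        alpha = config$alpha %||% 0.05, seed = seed))

  carto <- fit_cartography(norm, labels, modules = modules,
                           gene_set = config$gene_set %||% "module")
  diag <- sentinel_diagnosis(carto)
  fm <- fm_index(diag$cluster, labels)
  metrics <- class_metrics(diag$predicted, labels)
  utils::write.table(metrics, file.path(out_dir, "metrics.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(fm_index = fm),
                       file.path(out_dir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA)
  write_provenance(out_dir, "cartography",
                   list(gene_set = carto$gene_set, k = carto$k, seed = seed))

  match_summary <- NULL
  trt <- cohort$samples$treatment
  if (!all(is.na(trt))) {
    has_trt <- !is.na(trt)
    mods3 <- intersect(c("Th1", "Th2", "Th17"), colnames(act_tab$activations))
    mr <- match_cohort(act_tab$activations[has_trt, mods3, drop = FALSE],
                       trt[has_trt],
                       patient_id = cohort$samples$sample_id[has_trt],
                       response = cohort$samples$response[has_trt])
    utils::write.table(mr, file.path(out_dir, "match.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    match_summary <- cohort_match_summary(mr)
    write_provenance(out_dir, "match", list(rule = "argmax", seed = seed))
  }

  invisible(list(cohort = cohort, norm = norm, modules = modules,
                 activation = act_tab, cartography = carto,
                 evaluation = list(fm_index = fm, metrics = metrics),
                 match = match_summary))
}

resolve_modules <- function(config, cohort, norm) {
  spec <- config$modules %||% "truth"
  if (inherits(spec, "module_set")) return(spec)
  if (identical(spec, "truth")) {
    if (is.null(cohort$truth)) {
      stop_cfg("modules='truth' requires a simulated cohort; supply a module JSON")
    }
    return(module_set(cohort$truth$module_genes,
                      provenance = list(source = "planted truth")))
  }
  if (identical(spec, "discover")) {
    groups <- unique(cohort$samples$disease)
    contrasts <- Filter(function(cc) {
      all(c(cc$target, cc$rest) %in% groups)
    }, default_contrasts())
    return(build_module_set(norm, cohort$samples$disease,
                            contrasts = contrasts))
  }
  read_module_set(spec)
}
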