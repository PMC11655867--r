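#' Disease generative profile
#'
#' Describes one disease for the cohort simulator: its sample size, the
#' module(s) planted at full effect (dominant; several names mean co-dominant
#' expression) and the module(s) planted at a configurable fraction of the
#' full effect (subdominant).
#'
#' @param name disease label (e.g. "PsO").
#' @param n number of samples to simulate.
#' @param dominant character vector of module names planted at the full
#'   log2 effect. Empty for healthy-like profiles.
#' @param subdominant character vector of module names planted at
#'   `subdominant_fraction` of the full effect.
#' @param role sample role recorded in the metadata ("sentinel", "test",
#'   "erythroderma", ...).
#' @return a `disease_profile` list.
#' @export
disease_profile <- function(name, n, dominant = character(),
                            subdominant = character(), role = "sentinel") {
  known <- module_names()
  bad <- setdiff(c(dominant, subdominant), known)
  if (length(bad)) {
    stop_cfg("unknown module name(s) in profile '%s': %s", name,
             paste(bad, collapse = ", "))
  }
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop_cfg("profile '%s': n must be a positive integer", name)
  }
  structure(list(name = name, n = as.integer(n), dominant = dominant,
                 subdominant = subdominant, role = role),
            class = "disease_profile")
}

#' Default inflammatory skin disease panel
#'
#' The generative profiles emulated by default: psoriasis (Th17 dominant with
#' subdominant neutrophilic and type I IFN co-expression), atopic dermatitis
#' (Th2 dominant, subdominant Th1/Th17), lichen planus (Th1), cutaneous lupus
#' (type I IFN), neutrophilic dermatoses (neutrophilic), Wells syndrome
#' (eosinophilic), COVID-associated skin lesions (macrophagic), bullous
#' pemphigoid (co-dominant Th2 + myeloid), drug hypersensitivity reactions
#' (co-dominant Th2 + myeloid + type I IFN) and healthy skin (no module).
#' Sample sizes follow the profiled cohorts the panel emulates.
#'
#' @return list of [disease_profile()] objects.
#' @export
default_disease_panel <- function() {
  list(
    disease_profile("PsO",  25, dominant = "Th17",
                    subdominant = c("neutro", "IFN1")),
    disease_profile("AD",   16, dominant = "Th2",
                    subdominant = c("Th1", "Th17")),
    disease_profile("LP",   12, dominant = "Th1"),
    disease_profile("CLE",  12, dominant = "IFN1"),
    disease_profile("NeuD", 10, dominant = "neutro"),
    disease_profile("Wells", 3, dominant = "eosino"),
    disease_profile("COVIDskin", 10, dominant = "macro"),
    disease_profile("BP",   12,
                    dominant = c("Th2", "neutro", "macro", "eosino")),
    disease_profile("DHR",  10,
                    dominant = c("Th2", "neutro", "macro", "eosino", "IFN1")),
    disease_profile("Healthy", 8)
  )
}

#' Module-discovery panel
#'
#' The cohort composition used to derive module gene lists: the six model
#' diseases plus the macrophage-dominated COVID-associated skin lesions
#' needed by the three-way myeloid contrast. Co-dominant diseases (BP, DHR)
#' are deliberately excluded: modules are defined against diseases with a
#' single dominant pathway.
#'
#' @param n optional common per-disease sample size overriding the panel
#'   defaults (e.g. 10 for a balanced discovery cohort).
#' @return list of [disease_profile()] objects.
#' @export
discovery_panel <- function(n = NULL) {
  panel <- default_disease_panel()
  keep <- c("LP", "AD", "PsO", "NeuD", "CLE", "Wells", "COVIDskin")
  panel <- panel[vapply(panel, function(p) p$name, "") %in% keep]
  if (!is.null(n)) panel <- lapply(panel, function(p) { p$n <- as.integer(n); p })
  panel
}

#' Sentinel panel of the six model diseases
#'
#' Convenience subset used for reference-map construction: LP (12), AD (16),
#' PsO (25), NeuD (10), CLE (12) and Wells (3), optionally with healthy skin.
#'
#' @param healthy include the healthy profile (n = 8)?
#' @return list of [disease_profile()] objects.
#' @export
sentinel_panel <- function(healthy = FALSE) {
  panel <- default_disease_panel()
  keep <- c("LP", "AD", "PsO", "NeuD", "CLE", "Wells",
            if (healthy) "Healthy")
  panel[vapply(panel, function(p) p$name, "") %in% keep]
}

#' Simulation configuration
#'
#' Parameters of the NanoString-like cohort simulator. Probe content mirrors
#' an immune panel: seven planted modules, background endogenous probes,
#' housekeeping probes, a positive-control titration ladder and negative
#' controls. Counts are negative-binomial around lognormal per-gene baselines,
#' scaled by a per-sample lognormal depth factor captured by the control and
#' housekeeping probes.
#'
#' @param diseases list of [disease_profile()] objects.
#' @param n_module_genes genes per module (default 15).
#' @param n_background endogenous probes with no disease effect (default 480).
#' @param n_housekeeping housekeeping probes (default 15).
#' @param n_positive positive-control probes (default 6).
#' @param n_negative negative-control probes (default 8).
#' @param dominant_log2fc planted dominant-module effect, log2 units
#'   (default 2.0).
#' @param effect_jitter_sd SD of the per-gene, per-disease jitter around the
#'   planted effect (default 0.5); jitter is centered within each module so
#'   the module-average effect equals the configured value exactly.
#' @param subdominant_fraction fraction of the dominant effect applied to
#'   subdominant modules, in (0,1) (default 0.4).
#' @param depth_sd lognormal SD of the per-sample depth factor (default 0.3).
#' @param bio_sd SD (log2 units) of independent per-sample biological
#'   variability on every endogenous probe, disease-unrelated (default 0.6).
#' @param n_nuisance_factors number of latent patient-level factors loading
#'   on the background probes (default 3): disease-unrelated expression
#'   programs (tissue composition, keratinocyte state, ...) that make the
#'   full gene panel a noisier classifier than the module genes.
#' @param nuisance_sd per-gene SD (log2 units) of the summed nuisance-factor
#'   contribution on background probes (default 0.7).
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); 0 gives Poisson counting noise (default 0.1).
#' @param baseline_log2_mean,baseline_log2_sd lognormal baseline of
#'   endogenous probes, log2 scale (defaults 6 and 1.5).
#' @param module_baseline_sd within-module SD of module-gene baselines
#'   (default 0.8): co-regulated pathway genes on a curated panel span a
#'   narrower expression range than the panel at large, which is what makes
#'   a mean module score (and the gene-resampling dominance bootstrap)
#'   informative.
#' @param seed integer seed; fixed seed gives bit-identical cohorts.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(diseases = default_disease_panel(),
                       n_module_genes = 15L,
                       n_background = 480L,
                       n_housekeeping = 15L,
                       n_positive = 6L,
                       n_negative = 8L,
                       dominant_log2fc = 2.0,
                       effect_jitter_sd = 0.5,
                       subdominant_fraction = 0.4,
                       depth_sd = 0.3,
                       bio_sd = 0.6,
                       n_nuisance_factors = 3L,
                       nuisance_sd = 0.7,
                       nb_dispersion = 0.1,
                       baseline_log2_mean = 6,
                       baseline_log2_sd = 1.5,
                       module_baseline_sd = 0.8,
                       seed = 1L) {
  sizes <- c(n_module_genes = n_module_genes, n_background = n_background,
             n_housekeeping = n_housekeeping, n_positive = n_positive,
             n_negative = n_negative)
  if (any(sizes < 1)) {
    stop_cfg("all probe-set sizes must be strictly positive (%s)",
             paste(names(sizes)[sizes < 1], collapse = ", "))
  }
  if (!length(diseases)) stop_cfg("at least one disease profile is required")
  diseases <- lapply(diseases, function(p) {
    if (!inherits(p, "disease_profile")) {
      do.call(disease_profile, p)
    } else p
  })
  if (anyDuplicated(vapply(diseases, `[[`, "", "name"))) {
    stop_cfg("duplicate disease names in config")
  }
  if (subdominant_fraction <= 0 || subdominant_fraction >= 1) {
    stop_cfg("subdominant_fraction must lie in (0,1)")
  }
  if (dominant_log2fc < 0 || depth_sd < 0 || nb_dispersion < 0 || bio_sd < 0) {
    stop_cfg("dominant_log2fc, depth_sd, bio_sd and nb_dispersion must be >= 0")
  }
  structure(list(
    diseases = diseases,
    n_module_genes = as.integer(n_module_genes),
    n_background = as.integer(n_background),
    n_housekeeping = as.integer(n_housekeeping),
    n_positive = as.integer(n_positive),
    n_negative = as.integer(n_negative),
    dominant_log2fc = dominant_log2fc,
    effect_jitter_sd = effect_jitter_sd,
    subdominant_fraction = subdominant_fraction,
    depth_sd = depth_sd,
    bio_sd = bio_sd,
    n_nuisance_factors = as.integer(n_nuisance_factors),
    nuisance_sd = nuisance_sd,
    nb_dispersion = nb_dispersion,
    baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd,
    module_baseline_sd = module_baseline_sd,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# gene-level generative parameters shared by all samples of a cohort:
# probe table, log2 baselines, per-disease log2 effect matrix
build_gene_params <- function(config) {
  mods <- module_names()
  module_genes <- lapply(mods, function(m) {
    sprintf("%s_G%02d", m, seq_len(config$n_module_genes))
  })
  names(module_genes) <- mods
  bg <- sprintf("BG_G%03d", seq_len(config$n_background))
  hk <- sprintf("HK_%02d", seq_len(config$n_housekeeping))
  pos <- sprintf("POS_%s", LETTERS[seq_len(config$n_positive)])
  neg <- sprintf("NEG_%s", LETTERS[seq_len(config$n_negative)])

  annotation <- data.frame(
    probe_id = c(unlist(module_genes, use.names = FALSE), bg, hk, pos, neg),
    class = rep(c("endogenous", "endogenous", "housekeeping",
                  "positive", "negative"),
                c(length(mods) * config$n_module_genes, length(bg),
                  length(hk), length(pos), length(neg))),
    true_module = c(rep(mods, each = config$n_module_genes),
                    rep(NA_character_,
                        length(bg) + length(hk) + length(pos) + length(neg))),
    stringsAsFactors = FALSE
  )

  n_probe <- nrow(annotation)
  baseline <- numeric(n_probe)
  names(baseline) <- annotation$probe_id
  for (m in mods) {
    b <- stats::rnorm(config$n_module_genes, config$baseline_log2_mean,
                      config$module_baseline_sd)
    # center each module at the common baseline so raw module scores are
    # comparable across modules, mirroring a curated panel
    baseline[module_genes[[m]]] <- b - mean(b) + config$baseline_log2_mean
  }
  baseline[bg] <- stats::rnorm(length(bg), config$baseline_log2_mean,
                               config$baseline_log2_sd)
  baseline[hk] <- stats::rnorm(length(hk), 9, 0.5)
  # titration ladder: successive 4-fold dilutions on the log2 scale
  baseline[pos] <- seq(15, by = -2, length.out = length(pos))
  baseline[neg] <- 2

  dis_names <- vapply(config$diseases, `[[`, "", "name")
  effects <- matrix(0, nrow = length(dis_names), ncol = n_probe,
                    dimnames = list(dis_names, annotation$probe_id))
  for (p in config$diseases) {
    for (m in p$dominant) {
      j <- stats::rnorm(config$n_module_genes, 0, config$effect_jitter_sd)
      effects[p$name, module_genes[[m]]] <-
        config$dominant_log2fc + (j - mean(j))
    }
    for (m in p$subdominant) {
      f <- config$subdominant_fraction
      j <- stats::rnorm(config$n_module_genes, 0, config$effect_jitter_sd * f)
      effects[p$name, module_genes[[m]]] <-
        f * config$dominant_log2fc + (j - mean(j))
    }
  }
  # latent nuisance loadings: background probes only, scaled so the summed
  # factor contribution has per-gene SD nuisance_sd
  loadings <- matrix(0, nrow = n_probe, ncol = config$n_nuisance_factors,
                     dimnames = list(annotation$probe_id, NULL))
  if (config$n_nuisance_factors > 0 && config$nuisance_sd > 0) {
    loadings[bg, ] <- stats::rnorm(
      length(bg) * config$n_nuisance_factors, 0,
      config$nuisance_sd / sqrt(config$n_nuisance_factors))
  }

  list(annotation = annotation, baseline = baseline, effects = effects,
       module_genes = module_genes, loadings = loadings)
}

# draw counts for a vector of per-sample diseases given gene params
draw_counts <- function(config, params, diseases, sample_ids) {
  n <- length(diseases)
  depth <- stats::rlnorm(n, 0, config$depth_sd)
  lam_base <- 2^params$baseline
  is_neg <- params$annotation$class == "negative"
  is_endo <- params$annotation$class == "endogenous"
  counts <- matrix(0L, nrow = n, ncol = nrow(params$annotation),
                   dimnames = list(sample_ids, params$annotation$probe_id))
  n_fac <- ncol(params$loadings)
  for (i in seq_len(n)) {
    mu <- lam_base * 2^params$effects[diseases[i], ]
    if (config$bio_sd > 0) {
      mu[is_endo] <- mu[is_endo] *
        2^stats::rnorm(sum(is_endo), 0, config$bio_sd)
    }
    if (n_fac > 0) {
      mu <- mu * 2^drop(params$loadings %*% stats::rnorm(n_fac))
    }
    mu[!is_neg] <- mu[!is_neg] * depth[i]  # negatives are depth-independent
    counts[i, ] <- if (config$nb_dispersion > 0) {
      stats::rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion)
    } else {
      stats::rpois(length(mu), mu)
    }
  }
  list(counts = counts, depth = depth)
}

#' Simulate a NanoString-like cohort with planted immune modules
#'
#' Generates a samples x probes count matrix with probe annotation, sample
#' metadata and ground-truth labels. Gene-level parameters (baselines and
#' per-disease effects) are drawn once and stored in the returned object so
#' that additional samples from the same generative process can be drawn with
#' [simulate_samples()].
#'
#' @param config a [sim_config()].
#' @return an object of class `immune_cohort` with elements `counts`
#'   (samples x probes integer matrix), `annotation` (probe table:
#'   probe_id, class, true_module), `samples` (sample metadata), `truth`
#'   (generating disease, true module gene lists, true dominant/co-dominant
#'   modules, depth factors) and `gene_params`.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(diseases = sentinel_panel(), seed = 7))
#' dim(cohort$counts)
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) stop_cfg("config must be a sim_config")
  set.seed(config$seed)
  params <- build_gene_params(config)

  diseases <- rep(vapply(config$diseases, `[[`, "", "name"),
                  vapply(config$diseases, `[[`, 1L, "n"))
  roles <- rep(vapply(config$diseases, `[[`, "", "role"),
               vapply(config$diseases, `[[`, 1L, "n"))
  ids <- unlist(lapply(config$diseases, function(p) {
    sprintf("%s_%02d", p$name, seq_len(p$n))
  }), use.names = FALSE)

  drawn <- draw_counts(config, params, diseases, ids)
  prof <- stats::setNames(config$diseases,
                          vapply(config$diseases, `[[`, "", "name"))
  truth <- list(
    disease = stats::setNames(diseases, ids),
    module_genes = params$module_genes,
    dominant = lapply(prof[diseases], `[[`, "dominant"),
    subdominant = lapply(prof[diseases], `[[`, "subdominant"),
    depth = stats::setNames(drawn$depth, ids)
  )
  names(truth$dominant) <- names(truth$subdominant) <- ids

  structure(list(
    counts = drawn$counts,
    annotation = params$annotation,
    samples = data.frame(sample_id = ids, disease = diseases, role = roles,
                         treatment = NA_character_, response = NA_character_,
                         stringsAsFactors = FALSE),
    truth = truth,
    gene_params = params,
    config = config
  ), class = "immune_cohort")
}

#' Draw additional samples from a fitted cohort's generative process
#'
#' Reuses the gene-level baselines and disease effects of an existing
#' simulated cohort and draws new samples with independent depth and counting
#' noise. This is how challenger-style samples (test biopsies, erythroderma)
#' are emulated: same disease biology, new patients.
#'
#' @param cohort an `immune_cohort` from [simulate_cohort()].
#' @param n named integer vector: samples per disease (names must be diseases
#'   configured in the cohort).
#' @param seed integer seed for the new noise draw.
#' @param role role recorded in the metadata (default "erythroderma").
#' @return an `immune_cohort` sharing the original probe annotation and gene
#'   parameters.
#' @export
simulate_samples <- function(cohort, n, seed, role = "erythroderma") {
  cohort <- as_raw_counts(cohort)
  if (is.null(cohort$gene_params)) {
    stop_cfg("cohort carries no generative parameters; simulate it first")
  }
  bad <- setdiff(names(n), rownames(cohort$gene_params$effects))
  if (length(bad)) {
    stop_cfg("disease(s) not in the cohort's generative model: %s",
             paste(bad, collapse = ", "))
  }
  set.seed(as.integer(seed))
  diseases <- rep(names(n), n)
  ids <- unlist(lapply(names(n), function(d) {
    sprintf("%s_%s_%02d", role, d, seq_len(n[[d]]))
  }), use.names = FALSE)
  drawn <- draw_counts(cohort$config, cohort$gene_params, diseases, ids)
  prof <- stats::setNames(cohort$config$diseases,
                          vapply(cohort$config$diseases, `[[`, "", "name"))
  structure(list(
    counts = drawn$counts,
    annotation = cohort$annotation,
    samples = data.frame(sample_id = ids, disease = diseases, role = role,
                         treatment = NA_character_, response = NA_character_,
                         stringsAsFactors = FALSE),
    truth = list(disease = stats::setNames(diseases, ids),
                 module_genes = cohort$gene_params$module_genes,
                 dominant = stats::setNames(
                   lapply(prof[diseases], `[[`, "dominant"), ids),
                 subdominant = stats::setNames(
                   lapply(prof[diseases], `[[`, "subdominant"), ids),
                 depth = stats::setNames(drawn$depth, ids)),
    gene_params = cohort$gene_params,
    config = cohort$config
  ), class = "immune_cohort")
}

#' Expected probe intensities of the generative model
#'
#' Noise-free expected counts (depth factor times 2^(baseline + effect)) for
#' given diseases and depth factors; used to reason about the counting model
#' without sampling noise.
#'
#' @param cohort an `immune_cohort`.
#' @param diseases character vector of generating diseases.
#' @param depth numeric vector of depth factors (recycled).
#' @return matrix length(diseases) x probes of expected counts.
#' @export
expected_counts <- function(cohort, diseases, depth = 1) {
  cohort <- as_raw_counts(cohort)
  params <- cohort$gene_params
  depth <- rep_len(depth, length(diseases))
  is_neg <- params$annotation$class == "negative"
  t(vapply(seq_along(diseases), function(i) {
    mu <- 2^(params$baseline + params$effects[diseases[i], ])
    mu[!is_neg] <- mu[!is_neg] * depth[i]
    mu
  }, numeric(nrow(params$annotation))))
}

#' @export
print.immune_cohort <- function(x, ...) {
  cls <- table(x$annotation$class)
  cat(sprintf("immune_cohort: %d samples x %d probes\n",
              nrow(x$counts), ncol(x$counts)))
  cat("  probe classes:",
      paste(sprintf("%s=%d", names(cls), cls), collapse = ", "), "\n")
  if (!is.null(x$samples$disease)) {
    tb <- table(x$samples$disease)
    cat("  diseases:",
        paste(sprintf("%s(%d)", names(tb), tb), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Paired pre/post-treatment module-switch scenario
#'
#' Simulates paired biopsies for patients whose dominant module shifts under
#' targeted therapy (e.g. Th2-dominant atopic dermatitis acquiring a dominant
#' Th1 profile on anti-IL-4RA treatment, associated with non-response).
#'
#' @param cohort an `immune_cohort` supplying the generative model.
#' @param n number of patients.
#' @param pre_disease,post_disease generating profiles of the pre- and
#'   post-treatment biopsies. Identical profiles simulate a stable patient.
#' @param seed integer seed.
#' @return list with `pre` and `post` cohorts (sample ids aligned by patient).
#' @export
simulate_switch_pairs <- function(cohort, n, pre_disease = "AD",
                                  post_disease = "LP", seed = 1L) {
  pre <- simulate_samples(cohort, stats::setNames(n, pre_disease),
                          seed = seed, role = "pre_treatment")
  post <- simulate_samples(cohort, stats::setNames(n, post_disease),
                           seed = seed + 1L, role = "post_treatment")
  pid <- sprintf("PT_%02d", seq_len(n))
  rownames(pre$counts) <- pre$samples$sample_id <- paste0(pid, "_pre")
  names(pre$truth$disease) <- pre$samples$sample_id
  rownames(post$counts) <- post$samples$sample_id <- paste0(pid, "_post")
  names(post$truth$disease) <- post$samples$sample_id
  list(pre = pre, post = post, patient_id = pid)
}
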