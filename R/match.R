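#' Default treatment-to-target-module map
#'
#' Mechanism-level targets of the systemic therapies handled by the package:
#' anti-IL-4RA / anti-IL-13 biologics block the Th2 axis, anti-IL-17A/F and
#' anti-IL-23 (p19/p40) biologics block the Th17 axis, and JAK1/2 inhibitors
#' are used to block Th1-driven inflammation.
#'
#' @return named character vector treatment -> module (names lower-case).
#' @export
default_treatment_targets <- function() {
  c(dupilumab = "Th2", tralokinumab = "Th2",
    secukinumab = "Th17", ixekizumab = "Th17", bimekizumab = "Th17",
    tildrakizumab = "Th17", guselkumab = "Th17", risankizumab = "Th17",
    ustekinumab = "Th17",
    baricitinib = "Th1", upadacitinib = "Th1")
}

#' Target module of a treatment
#'
#' Case-insensitive lookup; unknown treatments raise an error rather than
#' defaulting silently.
#'
#' @param treatment treatment name(s).
#' @param map named treatment -> module vector
#'   ([default_treatment_targets()]).
#' @return character vector of target modules.
#' @export
treatment_target <- function(treatment, map = default_treatment_targets()) {
  names(map) <- tolower(names(map))
  key <- tolower(trimws(treatment))
  unknown <- unique(treatment[!key %in% names(map)])
  if (length(unknown)) {
    stop_cfg("unknown treatment(s): %s", paste(unknown, collapse = ", "))
  }
  unname(map[key])
}

#' Match one module-score profile against a treatment target
#'
#' The dominant module is the argmax of the supplied module scores (the rule
#' used for post-treatment matching tables, where sub-0.5 maxima still count
#' as dominant); `rule = "gated"` additionally flags maxima at or below
#' `gate` as weak. A profile is matched when its dominant module equals the
#' treatment's target module. Exact score ties make the status
#' indeterminate.
#'
#' @param scores named numeric vector of module scores (>= 2 modules, no
#'   NA).
#' @param treatment treatment name.
#' @param map treatment -> target map.
#' @param rule "argmax" (default) or "gated".
#' @param gate activation gate used by the gated rule (default 0.5).
#' @return one-row data.frame: dominant, target, status
#'   ("matched" | "non matched" | "indeterminate"), weak (logical).
#' @export
match_profile <- function(scores, treatment,
                          map = default_treatment_targets(),
                          rule = c("argmax", "gated"), gate = 0.5) {
  rule <- match.arg(rule)
  if (length(scores) < 2) stop_cfg("need scores for at least 2 modules")
  if (any(is.na(scores))) stop_cfg("NA module scores")
  target <- treatment_target(treatment, map)
  top <- names(scores)[scores == max(scores)]
  if (length(top) > 1L) {
    return(data.frame(dominant = NA_character_, target = target,
                      status = "indeterminate", weak = NA,
                      stringsAsFactors = FALSE))
  }
  data.frame(dominant = top, target = target,
             status = if (top == target) "matched" else "non matched",
             weak = rule == "gated" && max(scores) <= gate,
             stringsAsFactors = FALSE)
}

#' Match a cohort of score profiles to their treatment targets
#'
#' @param scores data.frame or matrix of module scores with one row per
#'   patient (columns = modules, e.g. Th1/Th2/Th17).
#' @param treatment per-patient treatment vector.
#' @param patient_id optional patient identifiers.
#' @param response optional response labels ("responder"/"non-responder" or
#'   similar).
#' @inheritParams match_profile
#' @return `match_result` data.frame: patient_id, treatment, dominant,
#'   target, status, weak, response.
#' @export
match_cohort <- function(scores, treatment, patient_id = NULL,
                         response = NULL,
                         map = default_treatment_targets(),
                         rule = c("argmax", "gated"), gate = 0.5) {
  rule <- match.arg(rule)
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (length(treatment) != n) stop_cfg("one treatment per score row required")
  patient_id <- patient_id %||% rownames(scores) %||% sprintf("P%03d", seq_len(n))
  out <- do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(data.frame(patient_id = patient_id[i], treatment = treatment[i],
                     stringsAsFactors = FALSE),
          match_profile(scores[i, ], treatment[i], map, rule, gate))
  }))
  out$response <- if (is.null(response)) NA_character_ else response
  class(out) <- c("match_result", "data.frame")
  out
}

#' Cohort-level matching summary
#'
#' Counts of matched / non-matched profiles, split by responder status when
#' available, with the observed response rate and the hypothetical response
#' rate had therapy been restricted to matched profiles (responders among
#' matched / matched total).
#'
#' @param results a `match_result` (or data.frame with `status` and
#'   `response`).
#' @param responder_label value of `response` identifying responders
#'   (default "responder").
#' @return list: `counts` (status x response table), `n_matched`,
#'   `n_non_matched`, `observed_response_rate`,
#'   `matched_only_response_rate` (NA without response data).
#' @export
cohort_match_summary <- function(results, responder_label = "responder") {
  status <- results$status
  n_matched <- sum(status == "matched")
  n_non <- sum(status == "non matched")
  has_resp <- !all(is.na(results$response))
  obs <- matched_only <- NA_real_
  counts <- table(status = status)
  if (has_resp) {
    counts <- table(status = status, response = results$response)
    resp <- results$response == responder_label
    obs <- mean(resp)
    if (n_matched > 0) {
      matched_only <- sum(resp & status == "matched") / n_matched
    }
  }
  list(counts = counts, n_matched = n_matched, n_non_matched = n_non,
       observed_response_rate = obs,
       matched_only_response_rate = matched_only)
}

#' Detect a module switch between paired pre/post-treatment profiles
#'
#' @param pre_scores,post_scores module-score matrices with one row per
#'   patient (rows aligned).
#' @return data.frame: patient, pre_dominant, post_dominant, switched.
#' @export
module_switch <- function(pre_scores, post_scores) {
  pre_scores <- as.matrix(pre_scores)
  post_scores <- as.matrix(post_scores)
  if (nrow(pre_scores) != nrow(post_scores)) {
    stop_cfg("pre and post matrices must have the same number of patients")
  }
  argmax <- function(m) colnames(m)[max.col(m, ties.method = "first")]
  pre_dom <- argmax(pre_scores)
  post_dom <- argmax(post_scores)
  data.frame(patient = rownames(pre_scores) %||% seq_len(nrow(pre_scores)),
             pre_dominant = pre_dom, post_dominant = post_dom,
             switched = pre_dom != post_dom, stringsAsFactors = FALSE)
}

#' Post-treatment module scores of the 17 profiled non-responders
#'
#' The packaged table of the 17 non-responding patients profiled after
#' targeted treatment: diagnosis, treatment, Th1/Th2/Th17 module scores, the
#' printed matching status and the re-matched treatment outcome where one
#' was attempted.
#'
#' @return data.frame with 17 rows.
#' @export
table2_fixture <- function() {
  path <- system.file("extdata", "table2_nonresponders.csv",
                      package = "immunocarto", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
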