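# shared fixtures, built in code and memoised per test run

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# balanced discovery cohort (7 diseases x 10 samples), canonical seed
discovery_cohort <- function() {
  memo("discovery", simulate_cohort(sim_config(diseases = discovery_panel(n = 10),
                                               seed = 1)))
}

# sentinel cohort with healthy skin, canonical seed
sentinel_cohort <- function() {
  memo("sentinel",
       simulate_cohort(sim_config(diseases = sentinel_panel(healthy = TRUE),
                                  seed = 1)))
}

# hand-built minimal raw cohort: 3 samples, 2 endogenous, 2 positive, 2 hk
tiny_raw <- function(depths = c(1, 1, 1)) {
  probes <- c("G1", "G2", "POS_A", "POS_B", "HK_1", "HK_2")
  base <- c(G1 = 8, G2 = 32, POS_A = 100, POS_B = 400, HK_1 = 50, HK_2 = 200)
  counts <- t(vapply(depths, function(d) base * d, numeric(6)))
  rownames(counts) <- paste0("S", seq_along(depths))
  structure(list(
    counts = counts,
    annotation = data.frame(
      probe_id = probes,
      class = c("endogenous", "endogenous", "positive", "positive",
                "housekeeping", "housekeeping"),
      true_module = NA_character_, stringsAsFactors = FALSE),
    samples = data.frame(sample_id = rownames(counts),
                         stringsAsFactors = FALSE)
  ), class = "immune_cohort")
}

# Jaccard similarity of two gene sets
jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
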