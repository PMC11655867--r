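test_that("raw module scores are gene means", {
  m <- matrix(c(2, 4, 9, 7, 7, 7), nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("g1", "g2", "g3")))
  mods <- list(all3 = c("g1", "g2", "g3"), single = "g2")
  sc <- score_modules(m, mods)
  expect_equal(sc["s1", "all3"], 5.0)
  expect_equal(sc["s1", "single"], 4)
  expect_equal(unname(sc["s2", ]), c(7, 7))
  expect_error(score_modules(m, list(a = "missing_gene")), "absent")
  expect_error(score_modules(m, list(a = character())), "empty")
})

test_that("bimodal threshold sits between well-separated groups", {
  # two point masses with a tiny bandwidth: valley center is the midpoint
  scores <- c(0, 0, 0, 10, 10, 10)
  positive <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  t1 <- fit_threshold(scores, positive, bw = 0.1)
  expect_lt(abs(t1 - 5), 0.5)
  expect_gt(t1, 0); expect_lt(t1, 10)

  # gaussian groups: threshold in (2,4) and close to a brute-force
  # grid search over an independently computed weighted KDE
  set.seed(14)
  neg <- rnorm(50, 1, 0.1); pos <- rnorm(50, 5, 0.1)
  scores <- c(neg, pos)
  positive <- rep(c(FALSE, TRUE), each = 50)
  t2 <- fit_threshold(scores, positive)
  expect_gt(t2, 2); expect_lt(t2, 4)
  bw <- stats::bw.nrd0(scores)
  w <- ifelse(positive, 0.5 / 50, 0.5 / 50)
  grid <- seq(mean(neg), mean(pos), length.out = 2000)
  dens <- vapply(grid, function(x) sum(w * stats::dnorm(x, scores, bw)), 0)
  expect_lt(abs(t2 - grid[which.min(dens)]), 0.3)

  # degenerate pooled data: fallback to the midpoint of the group means
  expect_equal(fit_threshold(rep(3, 10), rep(c(TRUE, FALSE), 5)), 3)
  expect_error(fit_threshold(1:5, c(TRUE, TRUE, FALSE, FALSE, FALSE)),
               ">= 3 positive")
})

test_that("activation is anchored, bounded, monotone and exact at the edges", {
  expect_equal(activation(5, threshold = 5, min = 0, max = 10), 0.5)
  expect_equal(activation(0, 5, 0, 10), 0.01)
  expect_equal(activation(10, 5, 0, 10), 0.99)
  x <- seq(-5, 15, by = 0.25)
  a <- activation(x, 5, 0, 10)
  expect_true(all(a >= 0 & a <= 1))
  expect_true(all(diff(a) > 0))
  expect_error(activation(1, 5, 5, 5), "degenerate")
  expect_error(activation(1, 0, 0, 10), "strictly inside")
})

test_that("the fitted activation model anchors 0.5 at each threshold", {
  sent <- sentinel_cohort()
  norm <- normalize_counts(sent)
  scores <- score_modules(norm, sent$truth$module_genes)
  pos <- module_positivity(sent$samples$disease, panel_disease_modules())
  model <- suppressWarnings(fit_activation(scores, pos))
  par <- model$parameters
  at_t <- matrix(par$threshold, nrow = 1, dimnames = list("q", par$module))
  expect_equal(unname(predict(model, at_t)[1, ]), rep(0.5, nrow(par)))
  act <- predict(model, scores[, par$module])
  expect_true(all(act >= 0 & act <= 1))
  expect_true(all(par$k > 0))
  expect_true(all(par$threshold > par$min & par$threshold < par$max))
})

test_that("fitted thresholds separate planted positives from negatives", {
  sent <- sentinel_cohort()
  norm <- normalize_counts(sent)
  scores <- score_modules(norm, sent$truth$module_genes)
  pos <- module_positivity(sent$samples$disease, panel_disease_modules())
  model <- suppressWarnings(fit_activation(scores, pos))
  for (m in model$parameters$module) {
    t_m <- model$parameters[m, "threshold"]
    expect_gt(t_m, mean(scores[!pos[, m], m]))
    expect_lt(t_m, mean(scores[pos[, m], m]))
  }
})

test_that("co-dominance follows the 0.5 gate and 30% rule", {
  a <- c(m1 = 0.9, m2 = 0.7, m3 = 0.2)
  expect_setequal(call_codominance(a), c("m1", "m2"))
  expect_equal(call_codominance(c(m1 = 0.9, m2 = 0.55, m3 = 0.2)), "m1")
  expect_length(call_codominance(c(m1 = 0.5, m2 = 0.3, m3 = 0.1)), 0)
})

test_that("dominance rules: margins, gates, ties and fall-through", {
  set.seed(15)
  gv <- list(m1 = rnorm(15, 9, 0.2), m2 = rnorm(15, 6, 0.2),
             m3 = rnorm(15, 6, 0.2))
  a <- c(m1 = 0.9, m2 = 0.1, m3 = 0.1)
  res <- call_dominance(a, gv, B = 1000)
  expect_equal(res$status, "dominant")
  expect_equal(res$dominant, "m1")
  expect_true(all(res$p_values < 0.05))

  # all activations below the gate: healthy-like sample
  res2 <- call_dominance(c(m1 = 0.4, m2 = 0.3, m3 = 0.1), gv, B = 1000)
  expect_equal(res2$status, "none")

  # two statistically indistinguishable high modules fall to co-dominance
  gv3 <- list(m1 = rnorm(15, 8, 1), m2 = rnorm(15, 8, 1),
              m3 = rnorm(15, 6, 0.2))
  res3 <- call_dominance(c(m1 = 0.8, m2 = 0.8, m3 = 0.1), gv3, B = 1000)
  expect_equal(res3$status, "co-dominant")
  expect_setequal(res3$codominant, c("m1", "m2"))

  # exact score ties never produce an arbitrary dominant call
  gv4 <- list(m1 = rep(8, 15), m2 = rep(8, 15), m3 = rep(6, 15))
  res4 <- call_dominance(c(m1 = 0.8, m2 = 0.8, m3 = 0.1), gv4, B = 1000)
  expect_false(identical(res4$status, "dominant"))

  expect_error(call_dominance(a, gv, B = 50), "B >= 100")
})

test_that("called dominant modules have the maximal raw score and match truth", {
  sent <- sentinel_cohort()
  norm <- normalize_counts(sent)
  scores <- score_modules(norm, sent$truth$module_genes)
  pos <- module_positivity(sent$samples$disease, panel_disease_modules())
  model <- suppressWarnings(fit_activation(scores, pos))
  tab <- call_modules(norm, sent$truth$module_genes, model, B = 500, seed = 1)

  dom <- tab$calls$status == "dominant"
  argmax <- colnames(tab$scores)[max.col(tab$scores, ties.method = "first")]
  expect_true(all(tab$calls$dominant[dom] == argmax[dom]))

  # no wrongly attributed dominant module on planted single-dominant samples
  td <- vapply(sent$truth$dominant,
               function(d) if (length(d) == 1) d else NA_character_, "")
  sing <- !is.na(td)
  wrong <- dom[sing] & tab$calls$dominant[sing] != td[sing]
  expect_equal(sum(wrong), 0)

  # healthy samples are never called dominant or co-dominant
  healthy <- sent$samples$disease == "Healthy"
  expect_true(all(tab$calls$status[healthy] == "none"))
})
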