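test_that("well-separated diseases are recovered by the dendrogram cut", {
  cohort <- simulate_cohort(sim_config(
    diseases = list(disease_profile("A", 8, dominant = "Th17"),
                    disease_profile("B", 8, dominant = "Th2")),
    seed = 16))
  norm <- normalize_counts(cohort)
  carto <- fit_cartography(norm, cohort$samples$disease,
                           modules = cohort$truth$module_genes)
  diag <- sentinel_diagnosis(carto, k = 2)
  expect_equal(fm_index(diag$cluster, cohort$samples$disease), 1.0)
  expect_equal(diag$predicted, cohort$samples$disease)
})

test_that("Pearson distance is zero to self and affine-invariant per sample", {
  sent <- sentinel_cohort()
  norm <- normalize_counts(sent)
  x <- norm$log2[1:5, ]
  d <- 1 - stats::cor(t(x))
  expect_equal(unname(diag(d)), rep(0, 5))
  # per-sample affine rescaling leaves the correlation distance unchanged
  y <- x
  y[2, ] <- 3 * y[2, ] + 7
  d2 <- 1 - stats::cor(t(y))
  expect_equal(d, d2)
})

test_that("back-projection classifies queries by neighborhood vote", {
  sent <- sentinel_cohort()
  norm <- normalize_counts(sent)
  carto <- fit_cartography(norm, sent$samples$disease,
                           modules = sent$truth$module_genes)

  # a query identical to a sentinel is assigned that sentinel's disease
  q <- norm$log2[7, , drop = FALSE]
  pred <- predict(carto, q, k = 3)
  expect_equal(pred$assigned, sent$samples$disease[7])
  expect_equal(pred[[paste0("dist_", pred$assigned)]] >= 0, TRUE)

  # fresh draws from two disease profiles are assigned correctly
  qc <- simulate_samples(sent, c(AD = 6, LP = 4), seed = 77)
  qn <- normalize_counts(qc)
  pred2 <- predict(carto, qn, k = 5)
  expect_equal(pred2$assigned, unname(qc$truth$disease))
  expect_true(all(pred2$votes >= 4))
  # the embedding-free correlation route agrees
  pred3 <- predict(carto, qn, k = 5, method = "direct")
  expect_equal(pred3$assigned, pred2$assigned)

  expect_error(predict(carto, qn, k = 1e4), "exceeds")
  expect_error(predict(carto, qn$log2[, 1:10]), "lacks")
})

test_that("k = 1 reduces to nearest-neighbor assignment", {
  set.seed(17)
  m <- matrix(rnorm(4 * 30, 6, 1), nrow = 4,
              dimnames = list(paste0("s", 1:4), paste0("g", 1:30)))
  suppressWarnings({
    carto <- fit_cartography(m, c("A", "B", "C", "D"), gene_set = "all",
                             rank = 3)
    q <- m[3, ] + rnorm(30, 0, 0.01)
    pred <- predict(carto, q, k = 1)
  })
  expect_equal(pred$assigned, "C")
})

test_that("classification is deterministic", {
  sent <- sentinel_cohort()
  norm <- normalize_counts(sent)
  carto1 <- fit_cartography(norm, sent$samples$disease,
                            modules = sent$truth$module_genes)
  carto2 <- fit_cartography(norm, sent$samples$disease,
                            modules = sent$truth$module_genes)
  qc <- simulate_samples(sent, c(PsO = 5), seed = 33)
  qn <- normalize_counts(qc)
  expect_identical(predict(carto1, qn), predict(carto2, qn))
})

test_that("per-class metrics match hand-enumerated confusion matrices", {
  perfect <- class_metrics(c("A", "B", "C"), c("A", "B", "C"))
  expect_true(all(perfect$precision == 1))
  expect_true(all(perfect$recall == 1))
  expect_true(all(perfect$specificity == 1))

  m <- class_metrics(c("A", "A", "B"), c("A", "B", "B"))
  expect_equal(m$precision[m$class == "A"], 0.5)
  expect_equal(m$recall[m$class == "A"], 1.0)
  expect_equal(m$precision[m$class == "B"], 1.0)
  expect_equal(m$recall[m$class == "B"], 0.5)

  all_a <- class_metrics(rep("A", 4), c("A", "A", "B", "B"))
  expect_equal(all_a$recall[all_a$class == "B"], 0)
  expect_error(class_metrics("A", c("A", "B")), "length")
})

test_that("FM index equals brute-force pair enumeration", {
  expect_equal(fm_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1.0)
  expect_equal(fm_index(c("x", "x", "y"), c("a", "b", "b")), 0.0)

  brute_fm <- function(a, b) {
    pairs <- utils::combn(length(a), 2)
    sa <- a[pairs[1, ]] == a[pairs[2, ]]
    sb <- b[pairs[1, ]] == b[pairs[2, ]]
    tp <- sum(sa & sb)
    if (sum(sa) == 0 || sum(sb) == 0) return(0)
    tp / sqrt(sum(sa) * sum(sb))
  }
  expect_equal(fm_index(c(1, 1, 2, 2), c(1, 1, 2, 3)),
               brute_fm(c(1, 1, 2, 2), c(1, 1, 2, 3)))
  set.seed(18)
  for (i in 1:20) {
    a <- sample(letters[1:3], 8, replace = TRUE)
    b <- sample(1:4, 8, replace = TRUE)
    expect_equal(fm_index(a, b), brute_fm(a, b))
    # symmetry and label-renaming invariance
    expect_equal(fm_index(a, b), fm_index(b, a))
    ren <- c(a = "z", b = "q", c = "m")[a]
    expect_equal(fm_index(ren, b), fm_index(a, b))
  }
  expect_error(fm_index(1, 1), "at least 2")
})

test_that("Hungarian cluster mapping is optimal against brute force", {
  brute_best <- function(M) {
    n <- nrow(M)
    perms <- gtools_permutations(n)
    best <- -Inf
    for (i in seq_len(nrow(perms))) {
      s <- sum(M[cbind(seq_len(n), perms[i, ])])
      if (s > best) best <- s
    }
    best
  }
  gtools_permutations <- function(n) {
    if (n == 1) return(matrix(1))
    sub <- gtools_permutations(n - 1)
    do.call(rbind, lapply(seq_len(n), function(k) {
      cbind(k, matrix(ifelse(sub >= k, sub + 1, sub), nrow = nrow(sub)))
    }))
  }
  set.seed(19)
  for (i in 1:10) {
    M <- matrix(sample(0:20, 25, replace = TRUE), 5, 5)
    assign <- immunocarto:::hungarian_assignment(M)
    expect_equal(sum(M[cbind(1:5, assign)]), brute_best(M))
    expect_equal(sort(assign), 1:5)
  }
})

test_that("clustering degrades with biological noise and module genes beat the panel", {
  fm_at <- function(bio, seeds) {
    mean(vapply(seeds, function(s) {
      cohort <- simulate_cohort(sim_config(diseases = sentinel_panel(),
                                           bio_sd = bio, seed = s))
      norm <- normalize_counts(cohort)
      carto <- fit_cartography(norm, cohort$samples$disease,
                               modules = cohort$truth$module_genes)
      fm_index(sentinel_diagnosis(carto)$cluster, cohort$samples$disease)
    }, 0))
  }
  expect_gte(fm_at(0.6, 31:33), fm_at(2.5, 31:33))

  cohort <- simulate_cohort(sim_config(diseases = sentinel_panel(), seed = 34))
  norm <- normalize_counts(cohort)
  lab <- cohort$samples$disease
  fm_mod <- fm_index(sentinel_diagnosis(
    fit_cartography(norm, lab, modules = cohort$truth$module_genes))$cluster, lab)
  fm_all <- fm_index(sentinel_diagnosis(
    fit_cartography(norm, lab, gene_set = "all"))$cluster, lab)
  expect_gt(fm_mod, fm_all)
})

test_that("constant genes are dropped with a warning and errors are early", {
  m <- matrix(rnorm(6 * 20, 6, 1), nrow = 6,
              dimnames = list(paste0("s", 1:6), paste0("g", 1:20)))
  m[, "g1"] <- 5
  expect_warning(
    carto <- fit_cartography(m, rep(c("A", "B"), each = 3), gene_set = "all"),
    "constant")
  expect_false("g1" %in% carto$genes)
  expect_error(fit_cartography(m, rep("A", 6), gene_set = "all"),
               "at least 2 diseases")
})
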