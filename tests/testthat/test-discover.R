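test_that("constant matrices yield no differential expression", {
  m <- matrix(5, nrow = 8, ncol = 6,
              dimnames = list(paste0("s", 1:8), paste0("g", 1:6)))
  de <- differential_expression(m, rep(c("A", "B"), each = 4), "A")
  expect_true(all(de$log2fc == 0))
  expect_true(all(de$p == 1))
  expect_length(select_module_genes(de), 0)
})

test_that("a planted shift is estimated and the Welch path matches t.test", {
  set.seed(11)
  n1 <- 10; n2 <- 40
  m <- matrix(rnorm((n1 + n2) * 50, 6, 0.1), nrow = n1 + n2,
              dimnames = list(NULL, paste0("g", 1:50)))
  m[1:n1, "g1"] <- m[1:n1, "g1"] + 3
  rownames(m) <- paste0("s", seq_len(n1 + n2))
  labels <- rep(c("T", "R"), c(n1, n2))

  de <- differential_expression(m, labels, "T", method = "moderated")
  g1 <- de[de$gene == "g1", ]
  expect_lt(abs(g1$log2fc - 3), 0.2)
  expect_lt(g1$padj, 0.01)

  dew <- differential_expression(m, labels, "T", method = "welch")
  # oracle: direct Welch t computation per gene
  oracle_p <- apply(m, 2, function(x) {
    stats::t.test(x[labels == "T"], x[labels == "R"])$p.value
  })
  expect_equal(dew$p, unname(oracle_p))
  expect_equal(de$log2fc, dew$log2fc)  # FC is the group-mean difference
})

test_that("BH adjustment matches the step-up procedure enumerated by hand", {
  set.seed(12)
  m <- matrix(rnorm(10 * 4, 6, 1), nrow = 10,
              dimnames = list(paste0("s", 1:10), paste0("g", 1:4)))
  de <- differential_expression(m, rep(c("A", "B"), each = 5), "A",
                                method = "welch")
  # brute-force step-up: padj_(i) = min over j >= i of p_(j) * n / j
  p <- de$p
  n <- length(p)
  ord <- order(p)
  brute <- numeric(n)
  for (i in seq_len(n)) {
    r <- which(ord == i)
    brute[i] <- min(pmin(p[ord[r:n]] * n / (r:n), 1))
  }
  expect_equal(de$padj, brute)
  # and the spec's worked vector
  pv <- c(0.001, 0.01, 0.03, 0.04)
  expect_equal(stats::p.adjust(pv, "BH"),
               c(0.004, 0.02, 0.04, 0.04))
})

test_that("swapping target and rest negates the fold change exactly", {
  cohort <- discovery_cohort()
  norm <- normalize_counts(cohort)
  lab <- cohort$samples$disease
  a <- differential_expression(norm, lab, "PsO", c("AD", "LP"))
  # swapped: target group becomes the pooled rest
  lab2 <- ifelse(lab == "PsO", "rest2", lab)
  m <- norm$log2[lab %in% c("PsO", "AD", "LP"), ]
  l <- lab[lab %in% c("PsO", "AD", "LP")]
  fwd <- differential_expression(m, l, "PsO", c("AD", "LP"))
  l3 <- ifelse(l == "PsO", "X", "Y")
  rev <- differential_expression(m, l3, "Y", "X")
  expect_equal(fwd$log2fc, -rev$log2fc)
})

test_that("selection gates act on fold change and the chosen p column", {
  de <- structure(data.frame(
    gene = c("a", "b", "c"),
    log2fc = c(1.5, 0.9, 1.2),
    p = c(0.004, 1e-7, 0.5),
    padj = c(0.005, 1e-6, 0.9), stringsAsFactors = FALSE),
    class = c("de_result", "data.frame"))
  expect_equal(select_module_genes(de), "a")
  expect_equal(select_module_genes(de, use_adjusted = FALSE), "a")
  expect_error(select_module_genes(de, fc_threshold = 0), "positive")
  empty <- de[0, ]
  expect_length(select_module_genes(empty), 0)
})

test_that("multi-contrast genes go to the largest fold change and lists stay disjoint", {
  # planted matrix: gene 'shared' is up in A (log2FC 2.1) and B (1.4)
  set.seed(13)
  n <- 6
  genes <- c("shared", "onlyA", "onlyB", paste0("bg", 1:20))
  m <- matrix(rnorm(3 * n * length(genes), 6, 0.05), nrow = 3 * n,
              dimnames = list(paste0("s", 1:(3 * n)), genes))
  grp <- rep(c("A", "B", "C"), each = n)
  m[grp == "A", "shared"] <- m[grp == "A", "shared"] + 2.1
  m[grp == "B", "shared"] <- m[grp == "B", "shared"] + 1.4
  m[grp == "A", "onlyA"] <- m[grp == "A", "onlyA"] + 3
  m[grp == "B", "onlyB"] <- m[grp == "B", "onlyB"] + 3
  contrasts <- list(modA = list(target = "A", rest = "C"),
                    modB = list(target = "B", rest = "C"))
  ms <- build_module_set(m, grp, contrasts = contrasts)
  expect_true("shared" %in% ms$modules$modA)
  expect_false("shared" %in% ms$modules$modB)
  expect_setequal(ms$modules$modB, "onlyB")
  # exclusion list removes genes from every module
  ms2 <- build_module_set(m, grp, contrasts = contrasts,
                          exclusion = c("shared", "onlyB"))
  expect_false("shared" %in% unlist(ms2$modules))
  expect_false("onlyB" %in% unlist(ms2$modules))
  expect_error(build_module_set(m, grp,
                                contrasts = list(x = list(target = "Z"))),
               "unknown group")
})

test_that("module sets validate disjointness and round-trip through JSON", {
  expect_error(module_set(list(a = c("g1", "g2"), b = c("g2"))), "overlap")
  ms <- module_set(list(a = c("g1", "g2"), b = c("g3")))
  path <- tempfile(fileext = ".json")
  write_module_set(ms, path)
  back <- read_module_set(path)
  expect_equal(back$modules, ms$modules)
})

test_that("discovery on the planted cohort recovers module structure", {
  cohort <- discovery_cohort()
  norm <- normalize_counts(cohort)
  ms <- build_module_set(norm, cohort$samples$disease)
  truth <- cohort$truth$module_genes

  # disjointness after deduplication, always
  got <- unlist(ms$modules, use.names = FALSE)
  expect_false(anyDuplicated(got) > 0)

  # background admission stays below 5% of selected genes
  bg <- sum(!got %in% unlist(truth, use.names = FALSE))
  expect_lte(bg / length(got), 0.05)

  # every module is recovered with high (if not complete) fidelity:
  # per-gene effect jitter places a few planted genes below the fold-change
  # gate, so fidelity is bounded away from 1 by construction
  jac <- vapply(names(truth), function(m) jaccard(ms$modules[[m]], truth[[m]]), 0)
  expect_true(all(jac >= 0.7))
  expect_gte(mean(jac), 0.85)
})
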