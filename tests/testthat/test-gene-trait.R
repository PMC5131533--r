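test_that("contingency tables count functionality against phenotype", {
  g <- toy_states(matrix(c("I", "I", "P", "P"), ncol = 1), genes = "g")
  p <- toy_pheno(matrix(c(1L, 1L, 0L, 0L), ncol = 1), sugars = "sug")
  expect_identical(buildContingencyTable(g, p, "g", "sug"),
                   c(a = 2L, b = 0L, c = 0L, d = 2L))
  # SINGULAR is non-functional under the default policy
  g2 <- toy_states(matrix(c("S", "I"), ncol = 1), genes = "g")
  p2 <- toy_pheno(matrix(c(1L, 1L), ncol = 1), sugars = "sug")
  expect_identical(buildContingencyTable(g2, p2, "g", "sug"),
                   c(a = 1L, b = 0L, c = 1L, d = 0L))
  # ... but functional under an override
  pol <- functionalityPolicy(overrides = list(g = c(SINGULAR = TRUE)))
  expect_identical(buildContingencyTable(g2, p2, "g", "sug", pol),
                   c(a = 2L, b = 0L, c = 0L, d = 0L))
  expect_error(buildContingencyTable(g, p, "nope", "sug"), "gene not found")
})

test_that("the prose melibiase example yields the (29,0,4,8) table", {
  ex <- prose_melibiose_example()
  tab <- buildContingencyTable(ex$genes, ex$phenotypes, "galA", "melibiose")
  expect_identical(tab, c(a = 29L, b = 0L, c = 4L, d = 8L))
  expect_lt(fisherExactTwoSided(tab), 0.001)
})

test_that("two-sided Fisher p matches enumeration on worked examples", {
  expect_equal(fisherExactTwoSided(c(10, 0, 0, 10)), 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_equal(fisherExactTwoSided(c(5, 5, 5, 5)), 1)
  # full enumeration over the 3 outcomes of the 2/2 margins
  expect_equal(fisherExactTwoSided(c(2, 0, 0, 2)), enum_fisher_p(2, 0, 0, 2))
  expect_equal(fisherExactTwoSided(c(2, 0, 0, 2)), 1 / 3, tolerance = 1e-12)
})

test_that("Fisher p agrees with stats::fisher.test across random tables", {
  set.seed(7)
  for (i in 1:100) {
    t <- as.integer(stats::rmultinom(1, sample(4:50, 1), rep(0.25, 4)))
    expect_equal(fisherExactTwoSided(t),
                 stats::fisher.test(matrix(t, 2))$p.value, tolerance = 1e-9)
  }
})

test_that("a gene tracking branch membership is not flagged by the lineage test", {
  groups <- setNames(c(rep("A", 20), rep("B", 20)), paste0("s", 1:40))
  g <- toy_states(matrix(ifelse(groups == "B", "I", "P"), ncol = 1),
                  genes = "g", strains = names(groups))
  set.seed(3)
  y <- rbinom(40, 1, ifelse(groups == "B", 0.8, 0.2))
  p <- toy_pheno(matrix(as.integer(y), ncol = 1), sugars = "sug",
                 strains = names(groups))
  pv <- lineagePermutationP(g, p, "g", "sug", groups = groups,
                            nPerm = 200, seed = 1)
  # the statistic is invariant under within-group shuffles
  expect_equal(pv, 1)
})

test_that("the permutation p is deterministic under a seed and validates input", {
  groups <- setNames(rep(c("A", "B"), each = 6), paste0("s", 1:12))
  g <- random_states(12, "g", seed = 5)
  set.seed(6)
  p <- toy_pheno(matrix(rbinom(12, 1, 0.5), ncol = 1), sugars = "sug")
  p1 <- lineagePermutationP(g, p, "g", "sug", groups = groups,
                            nPerm = 150, seed = 11)
  p2 <- lineagePermutationP(g, p, "g", "sug", groups = groups,
                            nPerm = 150, seed = 11)
  expect_identical(p1, p2)
  expect_error(lineagePermutationP(g, p, "g", "sug", groups = groups,
                                   nPerm = 0), "at least 100")
  expect_message(
    lineagePermutationP(g, p, "g", "sug", nPerm = 150, seed = 1,
                        groups = setNames(c(rep("A", 11), "Z"), names(groups))),
    "left unshuffled")
})

test_that("BH adjustment and result ordering follow the step-up rule", {
  # hand-applied step-up on (0.01, 0.02, 0.9): q = (0.03, 0.03, 0.9)
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.9), "BH"),
               c(0.03, 0.03, 0.9))
  g <- toy_states(matrix(c("I", "I", "P", "P",    # perfect for sug
                           "I", "P", "I", "P",    # unrelated
                           "A", "A", "A", "A"),   # degenerate
                         nrow = 4), genes = c("hit", "meh", "gone"))
  p <- toy_pheno(matrix(c(1L, 1L, 0L, 0L), ncol = 1), sugars = "sug")
  res <- screenAssociations(g, p)
  expect_equal(nrow(res), 3L)
  expect_true(res$perfect[res$gene == "hit"])
  expect_true(res$degenerate[res$gene == "gone"])
  expect_equal(res$p_exact[res$gene == "gone"], 1)
  expect_false(res$perfect[res$gene == "meh"])
  # sorted by q then p; within one sugar q = BH(p)
  expect_equal(res$q_fdr, stats::p.adjust(res$p_exact, "BH")[order(
    stats::p.adjust(res$p_exact, "BH"), res$p_exact, res$gene)],
    tolerance = 1e-12)
  # single gene/sugar: q equals p
  solo <- screenAssociations(g, p, geneIds = "hit")
  expect_equal(solo$q_fdr, solo$p_exact)
})

test_that("a perfect association attains the minimum p for its margins", {
  set.seed(9)
  for (i in 1:25) {
    npos <- sample(2:10, 1); nneg <- sample(2:10, 1)
    tab <- c(a = npos, b = 0L, c = 0L, d = nneg)
    p_perf <- fisherExactTwoSided(tab)
    # all tables with the same margins
    ps <- vapply(max(0, npos - nneg):min(npos, npos), function(a)
      fisherExactTwoSided(c(a, npos - a, npos - a, nneg - npos + a)),
      numeric(1))
    expect_equal(p_perf, min(ps), tolerance = 1e-12)
  }
})
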