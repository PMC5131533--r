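test_that("Yule tree simulation is reproducible and structurally sound", {
  tr <- simulateStrainTree(3, seed = 4)
  expect_equal(length(tr$tip.label), 3L)
  expect_equal(tr$Nnode, 2L)
  expect_equal(nrow(tr$edge), 4L)          # 2n - 2 edges in a rooted binary tree
  tr2 <- simulateStrainTree(3, seed = 4)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))
  big <- simulateStrainTree(25, seed = 4)
  expect_equal(nrow(big$edge), 48L)
  expect_error(simulateStrainTree(2), "at least 3")
})

test_that("all-zero rates freeze the root state at every tip", {
  tr <- simulateStrainTree(8, seed = 1)
  g <- simulateGeneStates(tr, 5,
    rates = list(gain = 0, loss = 0, pseudo = 0, decay = 0, singular = 0),
    rootProbs = c(ABSENT = 0, INTACT = 1, PSEUDOGENE = 0), seed = 2)
  expect_true(all(geneStates(g) == "INTACT"))
  expect_equal(nrow(attr(g, "events")), 0L)
})

test_that("strong pseudogenization is absorbing toward PSEUDOGENE/ABSENT", {
  tr <- simulateStrainTree(10, seed = 3)
  g <- simulateGeneStates(tr, 20,
    rates = list(gain = 0, loss = 0, pseudo = 50, decay = 0, singular = 0),
    rootProbs = c(ABSENT = 0, INTACT = 1, PSEUDOGENE = 0), seed = 4)
  expect_true(all(geneStates(g) %in% c("PSEUDOGENE", "ABSENT")))
})

test_that("tip frequencies at a long branch match the chain's stationary law", {
  rates <- list(gain = 1, loss = 0.3, pseudo = 0.5, decay = 0.3, singular = 0)
  # stationary distribution from the rate matrix (independent oracle)
  Q <- rbind(ABSENT     = c(-rates$gain, rates$gain, 0),
             INTACT     = c(rates$loss, -(rates$loss + rates$pseudo), rates$pseudo),
             PSEUDOGENE = c(rates$decay, 0, -rates$decay))
  A <- rbind(t(Q), rep(1, 3))      # pi %*% Q = 0 with sum(pi) = 1
  pi <- qr.solve(A, c(0, 0, 0, 1))
  names(pi) <- c("ABSENT", "INTACT", "PSEUDOGENE")

  tree <- ape::read.tree(text = "(a:60,b:60);")
  g <- simulateGeneStates(tree, 2000, rates = rates,
                          rootProbs = c(ABSENT = 0, INTACT = 1,
                                        PSEUDOGENE = 0), seed = 5)
  freq <- table(factor(geneStates(g)["a", ], levels = names(pi))) / 2000
  for (s in names(pi)) {
    se <- sqrt(pi[s] * (1 - pi[s]) / 2000)
    expect_lt(abs(freq[[s]] - pi[[s]]), 3 * se + 1e-9)
  }
})

test_that("event-log replay reproduces the simulated tip states exactly", {
  tr <- simulateStrainTree(15, seed = 6)
  g <- simulateGeneStates(tr, 8, seed = 7)
  replayed <- replayEvents(tr, attr(g, "events"), attr(g, "rootStates"))
  expect_identical(replayed[rownames(geneStates(g)), ], geneStates(g))
})

test_that("phenotype generation applies exactly the recorded flips", {
  # epsilon = 0: phenotypes equal rule predictions
  tr <- simulateStrainTree(12, seed = 8)
  g <- simulateGeneStates(tr, c("g1", "g2"), seed = 9)
  rule <- PathwayModel("sug", list(list("g1"), list("g2")))
  p0 <- generatePhenotypes(g, list(rule), epsilon = 0, seed = 1)
  pred <- predictPhenotypes(g, rule)
  expect_identical(unname(phenotypeCalls(p0)[, "sug"]),
                   as.integer(pred$predicted == "POSITIVE"))
  expect_equal(nrow(attr(p0, "flips")), 0L)
  expect_error(generatePhenotypes(g, list(rule), epsilon = 0.5), "0, 0.5")

  # observed flip fraction over 10,000 calls matches epsilon
  big <- GeneStateMatrix(matrix("INTACT", 10000, 1,
    dimnames = list(paste0("s", 1:10000), "g1")))
  single <- PathwayModel("sug", list(list("g1")))
  eps <- 0.1
  pb <- generatePhenotypes(big, list(single), epsilon = eps, seed = 2)
  frac <- nrow(attr(pb, "flips")) / 10000
  expect_lt(abs(frac - eps), 3 * sqrt(eps * (1 - eps) / 10000))
  # phenotype equals rule output XOR recorded flips
  flipped <- rownames(phenotypeCalls(pb)) %in% attr(pb, "flips")$strain
  expect_identical(unname(phenotypeCalls(pb)[, "sug"]),
                   as.integer(xor(TRUE, flipped)))
})

test_that("datasets are fully determined by their configuration", {
  cfg <- simulationConfig(nTips = 12, seed = 99)
  d1 <- simulateDataset(cfg)
  d2 <- simulateDataset(cfg)
  expect_identical(ape::write.tree(d1@tree), ape::write.tree(d2@tree))
  expect_identical(geneStates(d1@genes), geneStates(d2@genes))
  expect_identical(phenotypeCalls(d1@phenotypes), phenotypeCalls(d2@phenotypes))
  expect_identical(d1@events, d2@events)
  expect_identical(d1@flips, d2@flips)
})

test_that("pseudogenization produces phenotype loss without gene loss", {
  # single-route rule, pseudogenization rate x tree depth >= 1
  cfg <- simulationConfig(nTips = 41, seed = 10, epsilon = 0, nDecoys = 0,
    rules = list(PathwayModel("sug", list(list("g1")))),
    rates = list(gain = 0.5, loss = 0.05, pseudo = 0.3, decay = 0.05,
                 singular = 0))
  hits <- vapply(1:50, function(i) {
    cfg_i <- cfg; cfg_i$seed <- cfg$seed + i
    d <- simulateDataset(cfg_i)
    st <- geneStates(d@genes)[, "g1"]
    y <- phenotypeCalls(d@phenotypes)[, "sug"]
    any(st == "PSEUDOGENE" & y == 0L)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("the recovery benchmark is deterministic under config and seed", {
  cfg <- simulationConfig(nTips = 15, seed = 3, epsilon = 0, nDecoys = 3)
  b1 <- benchmarkRecovery(cfg, nReps = 5)
  b2 <- benchmarkRecovery(cfg, nReps = 5)
  expect_identical(b1, b2)
  expect_true(all(b1$recovered[b1$identifiable]))
})
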