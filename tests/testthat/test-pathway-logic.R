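test_that("route evaluation honours conjunctions, rescues and blocking groups", {
  ara <- loadFixture("arabinose_states")
  rule <- loadFixture("rules/arabinose")
  pred <- predictPhenotypes(ara, rule)
  by_strain <- setNames(pred$predicted, pred$strain)
  # truncated araA or araB: negative, no rescue exists
  expect_identical(unname(by_strain[c("AWRI_B429", "IOEB_S450",
                                      "ATCC_BAA-1163")]),
                   rep("NEGATIVE", 3))
  # araD truncated without araD1: negative; with araD1: rescued
  expect_identical(unname(by_strain["IOEB_0607"]), "NEGATIVE")
  expect_identical(unname(by_strain["AWRI_B419"]), "POSITIVE")
  # everything intact: positive
  expect_identical(unname(by_strain["VF"]), "POSITIVE")
  blocked <- pred$blocking[pred$strain == "IOEB_0607"]
  expect_match(blocked, "araD")
  expect_error(
    predictPhenotypes(ara, PathwayModel("x", list(list("nonexistent")))),
    "absent from the matrix")
})

test_that("zero-route and empty-route models are the constant predictors", {
  g <- random_states(5, c("g1", "g2"), seed = 2)
  none <- predictPhenotypes(g, PathwayModel("x", list()))
  expect_true(all(none$predicted == "NEGATIVE"))
  always <- predictPhenotypes(g, PathwayModel("x", list(list())))
  expect_true(all(always$predicted == "POSITIVE"))
})

test_that("predictions are monotone in gene state upgrades", {
  upgrade <- c(ABSENT = "PSEUDOGENE", PSEUDOGENE = "SINGULAR",
               SINGULAR = "INTACT", INTACT = "INTACT")
  set.seed(13)
  for (rep in 1:20) {
    g <- random_states(8, paste0("g", 1:4), seed = 100 + rep)
    model <- PathwayModel("x", list(list("g1", c("g2", "g3")), list("g4")))
    before <- predictPhenotypes(g, model)$predicted
    st <- geneStates(g)
    i <- sample(nrow(st), 1); j <- sample(ncol(st), 1)
    st[i, j] <- upgrade[[st[i, j]]]
    after <- predictPhenotypes(GeneStateMatrix(st), model)$predicted
    # POSITIVE can never become NEGATIVE through an upgrade
    expect_false(any(before == "POSITIVE" & after == "NEGATIVE"))
  }
})

test_that("prediction is idempotent and order-independent over strains", {
  g <- random_states(10, paste0("g", 1:3), seed = 42)
  model <- PathwayModel("x", list(list("g1"), list("g2", "g3")))
  p1 <- predictPhenotypes(g, model)
  p2 <- predictPhenotypes(g, model)
  expect_identical(p1, p2)
  shuf <- GeneStateMatrix(geneStates(g)[sample(10), , drop = FALSE])
  p3 <- predictPhenotypes(shuf, model)
  expect_identical(setNames(p3$predicted, p3$strain)[p1$strain],
                   setNames(p1$predicted, p1$strain))
})

test_that("concordance reports confusion counts and named discordants", {
  rib <- loadFixture("ribose_states")
  rule <- loadFixture("rules/ribose")
  tab <- loadFixture("table1")
  cc <- ruleConcordance(predictPhenotypes(rib, rule), tab, "ribose")
  expect_equal(cc$TP + cc$FP + cc$FN + cc$TN, 41L)
  # the four ribT-truncated strains are true negatives, C23 a true positive
  expect_equal(cc$TN, 4L)
  expect_equal(cc$FN, 0L)
  expect_equal(cc$FP, 0L)
  expect_equal(cc$accuracy, 1)
  # a rule with zero routes: everything predicted negative
  cc0 <- ruleConcordance(predictPhenotypes(rib, PathwayModel("ribose", list())),
                         tab, "ribose")
  expect_equal(cc0$TP, 0L)
  expect_equal(cc0$TN, 4L)
  expect_equal(nrow(cc0$discordant), 37L)
  expect_true(all(cc0$discordant$direction == "false_negative"))
})

test_that("complementation detection finds the phosphotrehalase rescues", {
  tre <- loadFixture("trehalose_states")
  tab <- loadFixture("table1")
  ev <- detectComplementation(tre, tab,
                              list(trehalose = c("treC", "treC1")))
  resc <- ev[ev$type == "rescue", ]
  expect_setequal(resc$strain, c("ATCC_BAA-1163", "S13", "AWRI_B419"))
  expect_true(all(resc$rescuer == "treC1"))
  # all members functional: no event
  g <- toy_states(matrix("I", 2, 2), genes = c("p", "q"))
  p <- toy_pheno(matrix(1L, 2, 1), sugars = "s")
  expect_equal(nrow(detectComplementation(g, p, list(s = c("p", "q")))), 0L)
  # primary broken, no rescuer, still positive: unexplained
  g2 <- toy_states(matrix(c("P", "A"), 1, 2), genes = c("p", "q"))
  p2 <- toy_pheno(matrix(1L, 1, 1), sugars = "s")
  ev2 <- detectComplementation(g2, p2, list(s = c("p", "q")))
  expect_identical(ev2$type, "unexplained_positive")
})

test_that("the packaged fructose rule explains exactly the fifteen strains", {
  fru <- loadFixture("fructose_states")
  rule <- loadFixture("rules/fructose")
  pred <- predictPhenotypes(fru, rule)
  pos <- pred$strain[pred$predicted == "POSITIVE"]
  manC_route <- c("IOEB_B10", "S13", "IOEB_0501", "IOEB_0502", "IOEB_9803",
                  "IOEB_9805", "IOEB_8417", "IOEB_9304", "IOEB_C28")
  ptsfru_route <- c("S19", "IOEB_1491", "ATCC_BAA-1163", "IOEB_C23", "IOEB_C52")
  expect_setequal(pos, c(manC_route, ptsfru_route, "S12"))
  expect_length(pos, 15L)
  # S12 is positive through both routes
  expect_equal(pred$n_active_routes[pred$strain == "S12"], 2L)
})

test_that("rule inference recovers a planted rule on the 8-strain toy", {
  grid <- expand.grid(g1 = c("I", "P"), g2 = c("I", "P"), g3 = c("I", "P"),
                      stringsAsFactors = FALSE)
  st <- as.matrix(grid)
  g <- toy_states(st)
  y <- as.integer((st[, "g1"] == "I" & st[, "g2"] == "I") | st[, "g3"] == "I")
  p <- toy_pheno(matrix(y, ncol = 1), sugars = "toy")
  fit <- inferRules(g, p, "toy", c("g1", "g2", "g3"))
  expect_equal(fit@concordance, 1)
  truth <- ruleSignature(PathwayModel("toy", list(list("g1", "g2"),
                                                  list("g3"))))
  sigs <- vapply(fit@rules, ruleSignature, character(1))
  expect_true(truth %in% sigs)
  expect_length(sigs, 1L)  # no equally scoring minimal alternative
  expect_false(fit@lowConfidence)
})

test_that("degenerate phenotypes produce the constant minimal rules", {
  g <- random_states(6, c("g1", "g2"), seed = 21)
  all_pos <- toy_pheno(matrix(1L, 6, 1), sugars = "s")
  fit <- inferRules(g, all_pos, "s", c("g1", "g2"))
  expect_equal(fit@concordance, 1)
  # the single empty route (always positive) is the unique minimal rule
  expect_length(fit@rules, 1L)
  expect_identical(routes(fit@rules[[1L]]), list(list()))
})

test_that("uninformative candidates are reported with a low-confidence flag", {
  g <- toy_states(matrix(c("I", "I", "P", "P"), ncol = 1), genes = "g1")
  p <- toy_pheno(matrix(c(1L, 0L, 1L, 0L), ncol = 1), sugars = "s")
  fit <- inferRules(g, p, "s", "g1", maxRoutes = 1)
  expect_true(fit@lowConfidence)
  expect_equal(fit@concordance, 0.5)  # majority class
})

test_that("the enumeration guard rejects oversized searches", {
  g <- random_states(4, paste0("g", 1:30), seed = 33)
  p <- toy_pheno(matrix(c(1L, 0L, 1L, 0L), ncol = 1), sugars = "s")
  expect_error(inferRules(g, p, "s", paste0("g", 1:30), maxRoutes = 3,
                          maxLiteralsPerRoute = 2),
               "rule space too large")
  expect_error(inferRules(g, p, "s", character(0)), "no candidate")
})

test_that("declared isoform groups act as single literals", {
  st <- matrix(c("P", "I", "P",    # araD broken everywhere but s2
                 "I", "P", "P"),   # araD1 rescues s1
               nrow = 3, dimnames = list(paste0("s", 1:3), c("araD", "araD1")))
  g <- GeneStateMatrix(st)
  p <- toy_pheno(matrix(c(1L, 1L, 0L), ncol = 1), sugars = "s",
                 strains = paste0("s", 1:3))
  fit <- inferRules(g, p, "s", list(Dgroup = c("araD", "araD1")),
                    maxRoutes = 1, maxLiteralsPerRoute = 1)
  expect_equal(fit@concordance, 1)
  expect_identical(routes(fit@rules[[1L]])[[1L]][[1L]], c("araD", "araD1"))
})
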