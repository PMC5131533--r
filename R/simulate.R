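#' Simulation configuration for synthetic strain collections
#'
#' Bundles every knob of the generator.  The defaults emulate the
#' statistical structure of the studied collection: a pure-birth (Yule)
#' tree over 41 strains, genes evolving by gain, loss and -- dominantly
#' -- pseudogenization (punctual mutations that lose the phenotype
#' without losing the gene), a monotone two-route ground-truth rule
#' `(g1 & g2) | g3`, nine decoy genes with no phenotypic role, and a
#' small phenotype flip-noise rate.
#'
#' @param nTips number of strains (>= 3; default 41).
#' @param birthRate Yule birth rate (default 1; branch lengths are in
#'   arbitrary time units).
#' @param rates named list of per-gene transition rates: `gain`
#'   (ABSENT -> INTACT), `loss` (INTACT -> ABSENT), `pseudo`
#'   (INTACT -> PSEUDOGENE), `decay` (PSEUDOGENE -> ABSENT) and
#'   `singular` (probability of annotating an INTACT tip as SINGULAR).
#' @param rootProbs named probabilities of the root state over
#'   ABSENT / INTACT / PSEUDOGENE.
#' @param rules list of true [PathwayModel-class] objects, one per
#'   simulated sugar.
#' @param epsilon phenotype flip-noise rate in `[0, 0.5)`.
#' @param nDecoys number of decoy genes appended after the rule genes.
#' @param seed RNG seed for the dataset.
#' @return a validated list of class `"SimulationConfig"`.
#' @export
simulationConfig <- function(nTips = 41L, birthRate = 1,
                             rates = list(gain = 0.5, loss = 0.05,
                                          pseudo = 0.3, decay = 0.05,
                                          singular = 0.02),
                             rootProbs = c(ABSENT = 0.05, INTACT = 0.95,
                                           PSEUDOGENE = 0),
                             rules = list(PathwayModel("simsugar",
                               list(list("g1", "g2"), list("g3")))),
                             epsilon = 0.02, nDecoys = 9L, seed = 1L) {
  if (nTips < 3L) stop("nTips must be at least 3")
  need <- c("gain", "loss", "pseudo", "decay", "singular")
  if (!all(need %in% names(rates))) stop("rates must name: ",
                                         paste(need, collapse = ", "))
  if (any(unlist(rates) < 0)) stop("rates must be non-negative")
  if (epsilon < 0 || epsilon >= 0.5) stop("epsilon must be in [0, 0.5)")
  if (abs(sum(rootProbs) - 1) > 1e-9) stop("rootProbs must sum to 1")
  structure(list(nTips = as.integer(nTips), birthRate = birthRate,
                 rates = rates, rootProbs = rootProbs, rules = rules,
                 epsilon = epsilon, nDecoys = as.integer(nDecoys),
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' Simulate a pure-birth (Yule) strain tree
#'
#' @param nTips number of tips (>= 3).
#' @param birthRate birth rate of the Yule process.
#' @param seed optional RNG seed; with a seed the returned Newick string
#'   is identical across calls.
#' @return an ape `phylo` tree with tips `s1..sN`.
#' @export
simulateStrainTree <- function(nTips, birthRate = 1, seed = NULL) {
  if (nTips < 3L) stop("nTips must be at least 3")
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(nTips, birth = birthRate, death = 0)
  tr$tip.label <- paste0("s", seq_len(nTips))
  tr
}

## CTMC on {ABSENT, INTACT, PSEUDOGENE}:
##   ABSENT -(gain)-> INTACT -(loss)-> ABSENT
##                    INTACT -(pseudo)-> PSEUDOGENE -(decay)-> ABSENT
.sim_branch <- function(state, len, rates) {
  events <- list(); t_at <- 0
  repeat {
    out <- switch(state,
      ABSENT     = c(INTACT = rates$gain),
      INTACT     = c(ABSENT = rates$loss, PSEUDOGENE = rates$pseudo),
      PSEUDOGENE = c(ABSENT = rates$decay))
    tot <- sum(out)
    if (tot <= 0) break
    wait <- stats::rexp(1L, tot)
    if (t_at + wait > len) break
    t_at <- t_at + wait
    nxt <- names(out)[sample.int(length(out), 1L, prob = out)]
    events[[length(events) + 1L]] <- list(time = t_at, from = state, to = nxt)
    state <- nxt
  }
  list(state = state, events = events)
}

#' Simulate gene functionality states along a tree
#'
#' Each gene evolves independently down every branch under a
#' continuous-time Markov chain on `{ABSENT, INTACT, PSEUDOGENE}` with
#' gains (ABSENT to INTACT), losses (INTACT to ABSENT),
#' pseudogenizations (INTACT to PSEUDOGENE) and pseudogene decay
#' (PSEUDOGENE to ABSENT).  After the tip states are recorded, INTACT
#' tips are independently annotated SINGULAR with probability
#' `rates$singular` -- the singular state is an annotation-level, not an
#' evolutionary, category.  Every transition is kept in an event log
#' whose replay ([replayEvents()]) reproduces the tip states exactly.
#'
#' @param tree an ape `phylo` tree.
#' @param nGenes number of genes, or a character vector of gene ids.
#' @param rates,rootProbs see [simulationConfig()].
#' @param seed optional RNG seed.
#' @return a [GeneStateMatrix-class]; the event log is in
#'   `attr(, "events")` (columns gene, node, time, from, to; `node` is
#'   the child node of the branch, tip annotations carry `time = NA`)
#'   and the sampled root states in `attr(, "rootStates")`.
#' @export
simulateGeneStates <- function(tree, nGenes,
                               rates = list(gain = 0.5, loss = 0.05,
                                            pseudo = 0.3, decay = 0.05,
                                            singular = 0.02),
                               rootProbs = c(ABSENT = 0.05, INTACT = 0.95,
                                             PSEUDOGENE = 0),
                               seed = NULL) {
  genes <- if (is.character(nGenes)) nGenes else paste0("g", seq_len(nGenes))
  if (!is.null(seed)) set.seed(seed)
  tr <- stats::reorder(tree, "cladewise")   # parents before children
  ntip <- length(tr$tip.label)
  root <- ntip + 1L
  states <- matrix(NA_character_, nrow = ntip, ncol = length(genes),
                   dimnames = list(tr$tip.label, genes))
  ev_acc <- vector("list", 0L)   # one record per event, bound once at the end
  root_states <- character(length(genes)); names(root_states) <- genes

  for (gi in seq_along(genes)) {
    node_state <- character(max(tr$edge))
    node_state[root] <- sample(names(rootProbs), 1L, prob = rootProbs)
    root_states[gi] <- node_state[root]
    for (e in seq_len(nrow(tr$edge))) {
      parent <- tr$edge[e, 1L]; child <- tr$edge[e, 2L]
      res <- .sim_branch(node_state[parent], tr$edge.length[e], rates)
      node_state[child] <- res$state
      for (ev in res$events)
        ev_acc[[length(ev_acc) + 1L]] <- list(genes[gi], child, ev$time,
                                              ev$from, ev$to)
      if (child <= ntip) {
        st <- node_state[child]
        if (st == "INTACT" && rates$singular > 0 &&
            stats::runif(1L) < rates$singular) {
          st <- "SINGULAR"
          ev_acc[[length(ev_acc) + 1L]] <- list(genes[gi], child, NA_real_,
                                                "INTACT", "SINGULAR")
        }
        states[child, gi] <- st
      }
    }
  }
  out <- GeneStateMatrix(states)
  attr(out, "events") <- data.frame(
    gene = vapply(ev_acc, `[[`, character(1), 1L),
    node = vapply(ev_acc, `[[`, integer(1), 2L),
    time = vapply(ev_acc, `[[`, numeric(1), 3L),
    from = vapply(ev_acc, `[[`, character(1), 4L),
    to = vapply(ev_acc, `[[`, character(1), 5L))
  attr(out, "rootStates") <- root_states
  out
}

#' Replay an event log to recover tip states
#'
#' Deterministically re-applies the recorded transitions branch by
#' branch; the result must equal the simulated tip states exactly.
#'
#' @param tree the `phylo` tree the log was simulated on.
#' @param events event-log data.frame from [simulateGeneStates()].
#' @param rootStates named character vector of root states per gene.
#' @return character matrix of tip states, strains x genes.
#' @export
replayEvents <- function(tree, events, rootStates) {
  tr <- stats::reorder(tree, "cladewise")
  ntip <- length(tr$tip.label)
  root <- ntip + 1L
  genes <- names(rootStates)
  states <- matrix(NA_character_, nrow = ntip, ncol = length(genes),
                   dimnames = list(tr$tip.label, genes))
  for (gi in seq_along(genes)) {
    ev_g <- events[events$gene == genes[gi], , drop = FALSE]
    node_state <- character(max(tr$edge))
    node_state[root] <- rootStates[gi]
    for (e in seq_len(nrow(tr$edge))) {
      parent <- tr$edge[e, 1L]; child <- tr$edge[e, 2L]
      st <- node_state[parent]
      ev_e <- ev_g[ev_g$node == child, , drop = FALSE]
      if (nrow(ev_e)) st <- ev_e$to[nrow(ev_e)]
      node_state[child] <- st
      if (child <= ntip) states[child, gi] <- st
    }
  }
  states
}

#' Generate phenotypes from pathway rules with flip noise
#'
#' Evaluates each true rule on the gene states, then flips every call
#' independently with probability `epsilon`; the flips actually applied
#' are recorded so that `phenotype == rule output XOR flip` holds
#' exactly.
#'
#' @param genes a [GeneStateMatrix-class].
#' @param rules list of [PathwayModel-class] objects (distinct sugars).
#' @param epsilon flip probability in `[0, 0.5)`.
#' @param seed optional RNG seed.
#' @param policy a [FunctionalityPolicy-class].
#' @return a [PhenotypeMatrix-class] with one column per rule;
#'   `attr(, "flips")` is a data.frame of the (strain, sugar) flips.
#' @export
generatePhenotypes <- function(genes, rules, epsilon = 0, seed = NULL,
                               policy = defaultPolicy()) {
  if (epsilon < 0 || epsilon >= 0.5) stop("epsilon must be in [0, 0.5)")
  if (!is.null(seed)) set.seed(seed)
  strains <- rownames(genes@states)
  sugars <- vapply(rules, sugarId, character(1))
  if (anyDuplicated(sugars)) stop("rules must target distinct sugars")
  v <- matrix(0L, nrow = length(strains), ncol = length(sugars),
              dimnames = list(strains, sugars))
  flips <- list()
  for (ri in seq_along(rules)) {
    pred <- predictPhenotypes(genes, rules[[ri]], policy)
    y <- as.integer(pred$predicted == "POSITIVE")
    flip <- stats::runif(length(y)) < epsilon
    v[, ri] <- ifelse(flip, 1L - y, y)
    if (any(flip))
      flips[[length(flips) + 1L]] <- data.frame(strain = strains[flip],
                                                sugar = sugars[ri])
  }
  out <- PhenotypeMatrix(v)
  attr(out, "flips") <- if (length(flips)) do.call(rbind, flips)
                        else data.frame(strain = character(), sugar = character())
  out
}

#' Simulate a complete dataset with known ground truth
#'
#' Tree, gene states (rule genes first, then decoys) and noisy
#' phenotypes, fully determined by the configuration (including its
#' seed).
#'
#' @param config a [simulationConfig()].
#' @return a [SimulatedDataset-class].
#' @examples
#' d <- simulateDataset(simulationConfig(nTips = 10, seed = 7))
#' d
#' @export
simulateDataset <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  tree <- ape::rphylo(config$nTips, birth = config$birthRate, death = 0)
  tree$tip.label <- paste0("s", seq_len(config$nTips))
  rule_genes <- unique(unlist(lapply(config$rules, routes)))
  genes <- c(rule_genes,
             if (config$nDecoys > 0L) paste0("d", seq_len(config$nDecoys)))
  gm <- simulateGeneStates(tree, genes, rates = config$rates,
                           rootProbs = config$rootProbs)
  pm <- generatePhenotypes(gm, config$rules, epsilon = config$epsilon)
  new("SimulatedDataset", tree = tree, genes = gm, phenotypes = pm,
      rules = config$rules, events = attr(gm, "events"),
      flips = attr(pm, "flips"), config = unclass(config))
}

#' Benchmark rule-inference recovery on synthetic data
#'
#' Repeatedly simulates a dataset from `config` (advancing the seed by
#' one per replicate), runs [inferRules()] on the first simulated sugar
#' with every simulated gene as a candidate, and reports per replicate
#' whether the exact true rule was recovered in the minimal set, whether
#' it is in the maximal-concordance set, and whether it was identifiable
#' (scores maximally and no rule with fewer literals ties it).  Decoy
#' false alarms -- non-degenerate perfect-association flags on decoy
#' genes -- are counted as an association-layer summary.
#'
#' @param config a [simulationConfig()].
#' @param nReps number of replicates.
#' @param maxRoutes,maxLiteralsPerRoute search bounds for [inferRules()].
#' @return data.frame with one row per replicate and columns seed,
#'   identifiable, recovered, inMaxSet, concordance, decoyPerfect;
#'   summary rates in `attr(, "summary")`.
#' @export
benchmarkRecovery <- function(config, nReps = 100L, maxRoutes = 2L,
                              maxLiteralsPerRoute = 2L) {
  stopifnot(inherits(config, "SimulationConfig"))
  truth <- config$rules[[1L]]
  truth_sig <- ruleSignature(truth)
  truth_size <- sum(lengths(routes(truth)))
  sugar <- sugarId(truth)
  rows <- vector("list", nReps)
  for (rep in seq_len(nReps)) {
    cfg <- config; cfg$seed <- config$seed + rep - 1L
    d <- simulateDataset(cfg)
    cand <- geneNames(d@genes)
    fit <- inferRules(d@genes, d@phenotypes, sugar, cand,
                      maxRoutes = maxRoutes,
                      maxLiteralsPerRoute = maxLiteralsPerRoute)
    max_sigs <- vapply(fit@maxSet, ruleSignature, character(1))
    max_sizes <- vapply(fit@maxSet, function(m) sum(lengths(routes(m))),
                        numeric(1))
    in_max <- truth_sig %in% max_sigs
    identifiable <- in_max && !any(max_sizes < truth_size)
    recovered <- truth_sig %in% vapply(fit@rules, ruleSignature, character(1))
    decoys <- grep("^d", cand, value = TRUE)
    decoy_perfect <- FALSE
    for (dg in decoys) {
      tab <- buildContingencyTable(d@genes, d@phenotypes, dg, sugar)
      degen <- any(c(tab["a"] + tab["b"], tab["c"] + tab["d"],
                     tab["a"] + tab["c"], tab["b"] + tab["d"]) == 0L)
      if (!degen && ((tab["b"] == 0L && tab["c"] == 0L) ||
                     (tab["a"] == 0L && tab["d"] == 0L))) {
        decoy_perfect <- TRUE; break
      }
    }
    rows[[rep]] <- data.frame(seed = cfg$seed, identifiable = identifiable,
                              recovered = recovered, inMaxSet = in_max,
                              concordance = fit@concordance,
                              decoyPerfect = decoy_perfect)
  }
  out <- do.call(rbind, rows)
  n_ident <- sum(out$identifiable)
  attr(out, "summary") <- list(
    recoveryGivenIdentifiable = if (n_ident) mean(out$recovered[out$identifiable]) else NA_real_,
    inMaxSetRate = mean(out$inMaxSet),
    identifiableRate = mean(out$identifiable),
    decoyPerfectRate = mean(out$decoyPerfect))
  out
}
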