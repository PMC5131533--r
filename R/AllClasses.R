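#' @import methods
NULL

## canonical state and call alphabets used across the package
.PHENO_LEVELS <- c("POSITIVE", "NEGATIVE")
.CALL_LEVELS  <- c("POSITIVE", "NEGATIVE", "INDETERMINATE")
.GENE_STATES  <- c("ABSENT", "PSEUDOGENE", "SINGULAR", "INTACT")
.STATE_CODES  <- c(A = "ABSENT", P = "PSEUDOGENE", S = "SINGULAR", I = "INTACT")
.PRODUCTS     <- c("lactate", "acetate", "ethanol", "mannitol", "CO2")

#' Binary strain-by-carbohydrate phenotype matrix
#'
#' Growth calls for a strain collection over a panel of carbohydrates,
#' stored as a 0/1 integer matrix (1 = POSITIVE) with unique strain row
#' names and sugar column names.  An optional branch map assigns each
#' strain to a phylogenomic group (for this species, dendrogram branches
#' "A", "B" and "C").
#'
#' @slot values integer matrix of 0/1 growth calls, strains x sugars.
#' @slot branchOf named character vector mapping every strain to a group
#'   label, or length zero when no grouping is attached.
#'
#' @seealso [readPhenotypeMatrix()], [loadFixture()], [substrateUsage()]
#' @export
setClass("PhenotypeMatrix",
  representation(values = "matrix", branchOf = "character"))

setValidity("PhenotypeMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "values must have strain row names and sugar column names")
  else {
    if (anyDuplicated(rownames(v)))
      msg <- c(msg, sprintf("duplicate strain id: %s",
                            rownames(v)[duplicated(rownames(v))][1L]))
    if (anyDuplicated(colnames(v)))
      msg <- c(msg, sprintf("duplicate sugar id: %s",
                            colnames(v)[duplicated(colnames(v))][1L]))
  }
  if (!all(v %in% c(0L, 1L)))
    msg <- c(msg, "phenotype entries must all be 0 (NEGATIVE) or 1 (POSITIVE)")
  if (length(object@branchOf)) {
    missing <- setdiff(rownames(v), names(object@branchOf))
    if (length(missing))
      msg <- c(msg, sprintf("branch map does not cover strain(s): %s",
                            paste(missing, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Strain-by-gene functionality-state matrix
#'
#' Functionality state of each gene in each strain genome, one of
#' `ABSENT`, `PSEUDOGENE` (truncated/disrupted copy), `SINGULAR`
#' (strain-specific protein variant of uncertain activity) or `INTACT`.
#' This encodes the colour code of published genotype/phenotype panels
#' (beige = absent, red = pseudogene, orange = singular, green = intact).
#'
#' @slot states character matrix, strains x genes, entries from the
#'   four-state alphabet.
#'
#' @seealso [readGeneStateMatrix()], [FunctionalityPolicy-class]
#' @export
setClass("GeneStateMatrix", representation(states = "matrix"))

setValidity("GeneStateMatrix", function(object) {
  s <- object@states
  msg <- character()
  if (is.null(rownames(s)) || is.null(colnames(s)))
    msg <- c(msg, "states must have strain row names and gene column names")
  else {
    if (anyDuplicated(rownames(s)))
      msg <- c(msg, sprintf("duplicate strain id: %s",
                            rownames(s)[duplicated(rownames(s))][1L]))
    if (anyDuplicated(colnames(s)))
      msg <- c(msg, sprintf("duplicate gene id: %s",
                            colnames(s)[duplicated(colnames(s))][1L]))
  }
  bad <- !(s %in% .GENE_STATES)
  if (any(bad)) {
    i <- arrayInd(which(bad)[1L], dim(s))
    msg <- c(msg, sprintf("unknown state '%s' at strain '%s', gene '%s'",
                          s[bad][1L], rownames(s)[i[1L]], colnames(s)[i[2L]]))
  }
  if (length(msg)) msg else TRUE
})

#' Monotone OR-of-AND pathway-completeness model
#'
#' A pathway model predicts a growth phenotype from gene functionality:
#' the phenotype is POSITIVE when at least one route is satisfied, and a
#' route is satisfied when every one of its isoform groups contains at
#' least one functional gene.  Complementation (a functional isoform
#' rescuing a pseudogenized primary gene) is therefore expressed by
#' putting both genes in one isoform group.
#'
#' An empty `routes` list predicts NEGATIVE for every strain; a route
#' with zero isoform groups is vacuously satisfied and predicts POSITIVE
#' for every strain.
#'
#' @slot sugar carbohydrate id the model predicts growth on.
#' @slot routes list of routes; each route is a list of isoform groups;
#'   each isoform group is a non-empty character vector of gene ids.
#' @slot name free-text description.
#'
#' @seealso [predictPhenotypes()], [readPathwayModel()], [inferRules()]
#' @export
setClass("PathwayModel",
  representation(sugar = "character", routes = "list", name = "character"))

setValidity("PathwayModel", function(object) {
  msg <- character()
  if (length(object@sugar) != 1L || !nzchar(object@sugar))
    msg <- c(msg, "sugar must be a single non-empty string")
  for (r in object@routes) {
    if (!is.list(r)) { msg <- c(msg, "each route must be a list of isoform groups"); break }
    for (g in r) {
      if (!is.character(g) || length(g) == 0L) {
        msg <- c(msg, "each isoform group must be a non-empty character vector")
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Map from gene functionality states to functional/non-functional
#'
#' The default policy counts only `INTACT` genes as functional: absent
#' and pseudogenized copies obviously are not, and `SINGULAR` variants
#' are conservatively treated as inactivating (motivated by the singular
#' PTS-mannose IIC permease subunit found in exactly the mannose-negative
#' strains).  Per-gene overrides let a model tolerate specific singular
#' variants (for example a hexokinase mutation outside the catalytic
#' site).
#'
#' @slot functional named logical vector over the four states.
#' @slot overrides named list; each element is a named logical vector of
#'   state -> functional overrides for one gene.
#'
#' @seealso [functionalityPolicy()], [isFunctional()]
#' @export
setClass("FunctionalityPolicy",
  representation(functional = "logical", overrides = "list"))

setValidity("FunctionalityPolicy", function(object) {
  msg <- character()
  if (!setequal(names(object@functional), .GENE_STATES))
    msg <- c(msg, "policy must assign a flag to each of the four states")
  for (g in names(object@overrides)) {
    o <- object@overrides[[g]]
    if (!is.logical(o) || !all(names(o) %in% .GENE_STATES))
      msg <- c(msg, sprintf("override for gene '%s' must be a named logical over the states", g))
  }
  if (length(msg)) msg else TRUE
})

#' Stoichiometry of one fermentation route
#'
#' Product yields in mol per mol of substrate consumed, over the axes
#' lactate, acetate, ethanol, mannitol and CO2.  Carbon balance against
#' a six-carbon substrate is checked at construction.
#'
#' @slot name route label.
#' @slot substrate substrate id (a hexose).
#' @slot yields named numeric vector over the five product axes.
#'
#' @seealso [builtinRoutes()], [predictYields()]
#' @export
setClass("RouteStoichiometry",
  representation(name = "character", substrate = "character", yields = "numeric"))

## carbon atoms per mol of each product; substrates are hexoses (6 C)
.PRODUCT_CARBONS <- c(lactate = 3, acetate = 2, ethanol = 2, mannitol = 6, CO2 = 1)

setValidity("RouteStoichiometry", function(object) {
  y <- object@yields
  msg <- character()
  if (!identical(names(y), .PRODUCTS))
    msg <- c(msg, sprintf("yields must be named exactly (%s)",
                          paste(.PRODUCTS, collapse = ", ")))
  else {
    if (any(y < 0)) msg <- c(msg, "yields must be non-negative")
    carbon <- sum(y * .PRODUCT_CARBONS)
    if (abs(carbon - 6) > 1e-9)
      msg <- c(msg, sprintf("carbon balance violated: %.12f of 6 substrate carbons accounted", carbon))
  }
  if (length(msg)) msg else TRUE
})

#' Observed end-product yields for one strain
#'
#' Yields per mol substrate consumed.  `NA` marks an unmeasured product
#' axis (it then contributes nothing to fitting residuals); a product
#' flagged `"le"` in `bounds` was only reported as an upper bound (for
#' example "less than 0.1 mmol of mannitol") and only penalizes
#' predictions exceeding it.
#'
#' @slot strain strain label.
#' @slot substrate substrate id.
#' @slot yields named numeric vector over the five product axes, `NA`
#'   where unmeasured.
#' @slot bounds named character vector, `"eq"` or `"le"` per axis.
#'
#' @seealso [fermentationProfile()], [fitFluxSplit()], [classifyFermentationMode()]
#' @export
setClass("FermentationProfile",
  representation(strain = "character", substrate = "character",
                 yields = "numeric", bounds = "character"))

setValidity("FermentationProfile", function(object) {
  msg <- character()
  if (!identical(names(object@yields), .PRODUCTS))
    msg <- c(msg, "yields must cover the five product axes")
  if (any(!is.na(object@yields) & object@yields < 0))
    msg <- c(msg, "yields must be non-negative")
  if (!identical(names(object@bounds), .PRODUCTS) ||
      !all(object@bounds %in% c("eq", "le")))
    msg <- c(msg, "bounds must be 'eq' or 'le' per product axis")
  if (length(msg)) msg else TRUE
})

#' Flux split over fermentation routes
#'
#' Non-negative route fractions summing to one, with the residual norm
#' of the fitted fit.
#'
#' @slot fractions named numeric vector over routes, on the simplex.
#' @slot residual numeric root-sum-of-squares residual of the fit.
#'
#' @seealso [fitFluxSplit()], [predictYields()]
#' @export
setClass("FluxSplit",
  representation(fractions = "numeric", residual = "numeric"))

setValidity("FluxSplit", function(object) {
  f <- object@fractions
  msg <- character()
  if (is.null(names(f))) msg <- c(msg, "fractions must be named by route")
  if (any(f < 0)) msg <- c(msg, "fractions must be non-negative")
  if (abs(sum(f) - 1) > 1e-9) msg <- c(msg, "fractions must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Result of an exhaustive monotone rule search
#'
#' All minimal maximal-concordance monotone DNF rules found by
#' [inferRules()], with the search bounds and diagnostic flags.
#'
#' @slot rules list of [PathwayModel-class] objects, every one achieving
#'   the maximal concordance and minimal (no literal or route can be
#'   dropped without strictly decreasing concordance), ordered by total
#'   literal count then lexicographically.
#' @slot concordance maximal training concordance achieved.
#' @slot maxSet list of all (not necessarily minimal) rules achieving the
#'   maximal concordance.
#' @slot lowConfidence TRUE when the best rule does no better than always
#'   predicting the majority class.
#' @slot bounds list with the search bounds used.
#'
#' @seealso [inferRules()]
#' @export
setClass("InferredRuleSet",
  representation(rules = "list", concordance = "numeric", maxSet = "list",
                 lowConfidence = "logical", bounds = "list"))

#' A simulated strain collection with known ground truth
#'
#' Output of [simulateDataset()]: a Yule strain tree, gene functionality
#' states evolved along it, phenotypes generated from a known pathway
#' rule with flip noise, plus the per-branch event log and the noise
#' flips actually applied.
#'
#' @slot tree ape `phylo` tree.
#' @slot genes [GeneStateMatrix-class] of simulated tip states.
#' @slot phenotypes [PhenotypeMatrix-class] of noisy rule outputs.
#' @slot rules list of the true [PathwayModel-class] objects per sugar.
#' @slot events data.frame event log of state transitions per branch.
#' @slot flips data.frame of (strain, sugar) phenotype flips applied.
#' @slot config list, the [simulationConfig()] used (seed included).
#'
#' @seealso [simulateDataset()], [benchmarkRecovery()]
#' @export
setClass("SimulatedDataset",
  representation(tree = "ANY", genes = "GeneStateMatrix",
                 phenotypes = "PhenotypeMatrix", rules = "list",
                 events = "data.frame", flips = "data.frame", config = "list"))
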