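#' Strain identifiers of an object
#' @param x a PhenotypeMatrix or GeneStateMatrix.
#' @return character vector of strain ids, in storage order.
#' @export
setGeneric("strainNames", function(x) standardGeneric("strainNames"))

#' Sugar identifiers of a phenotype matrix
#' @param x a PhenotypeMatrix.
#' @return character vector of sugar ids, in storage (preference) order.
#' @export
setGeneric("sugarNames", function(x) standardGeneric("sugarNames"))

#' Gene identifiers of a gene-state matrix
#' @param x a GeneStateMatrix.
#' @return character vector of gene ids.
#' @export
setGeneric("geneNames", function(x) standardGeneric("geneNames"))

#' Growth-call matrix of a phenotype object
#' @param x a PhenotypeMatrix.
#' @return integer 0/1 matrix, strains x sugars.
#' @export
setGeneric("phenotypeCalls", function(x) standardGeneric("phenotypeCalls"))

#' Branch (lineage group) labels of the strains
#' @param x a PhenotypeMatrix.
#' @return named character vector, or NULL when no grouping is attached.
#' @export
setGeneric("branchOf", function(x) standardGeneric("branchOf"))

#' Functionality-state matrix of a gene-state object
#' @param x a GeneStateMatrix.
#' @return character matrix, strains x genes, four-state alphabet.
#' @export
setGeneric("geneStates", function(x) standardGeneric("geneStates"))

#' Routes of a pathway model
#' @param x a PathwayModel.
#' @return list of routes (lists of isoform-group character vectors).
#' @export
setGeneric("routes", function(x) standardGeneric("routes"))

#' Sugar a pathway model predicts growth on
#' @param x a PathwayModel.
#' @return single sugar id string.
#' @export
setGeneric("sugarId", function(x) standardGeneric("sugarId"))

#' @describeIn PhenotypeMatrix-class strain ids
#' @param x a PhenotypeMatrix.
#' @export
setMethod("strainNames", "PhenotypeMatrix", function(x) rownames(x@values))

#' @describeIn GeneStateMatrix-class strain ids
#' @param x a GeneStateMatrix.
#' @export
setMethod("strainNames", "GeneStateMatrix", function(x) rownames(x@states))

#' @describeIn PhenotypeMatrix-class sugar ids
#' @export
setMethod("sugarNames", "PhenotypeMatrix", function(x) colnames(x@values))

#' @describeIn GeneStateMatrix-class gene ids
#' @export
setMethod("geneNames", "GeneStateMatrix", function(x) colnames(x@states))

#' @describeIn PhenotypeMatrix-class 0/1 growth-call matrix
#' @export
setMethod("phenotypeCalls", "PhenotypeMatrix", function(x) x@values)

#' @describeIn PhenotypeMatrix-class branch labels (NULL when absent)
#' @export
setMethod("branchOf", "PhenotypeMatrix",
  function(x) if (length(x@branchOf)) x@branchOf else NULL)

#' @describeIn GeneStateMatrix-class state matrix
#' @export
setMethod("geneStates", "GeneStateMatrix", function(x) x@states)

#' @describeIn PathwayModel-class route list
#' @export
setMethod("routes", "PathwayModel", function(x) x@routes)

#' @describeIn PathwayModel-class sugar id
#' @export
setMethod("sugarId", "PathwayModel", function(x) x@sugar)

#' @describeIn PhenotypeMatrix-class number of strains
#' @export
setMethod("nrow", "PhenotypeMatrix", function(x) base::nrow(x@values))

#' @describeIn GeneStateMatrix-class number of strains
#' @export
setMethod("nrow", "GeneStateMatrix", function(x) base::nrow(x@states))

setMethod("show", "PhenotypeMatrix", function(object) {
  v <- object@values
  cat(sprintf("PhenotypeMatrix: %d strains x %d sugars (%d positive calls)\n",
              nrow(v), ncol(v), sum(v)))
  if (length(object@branchOf)) {
    tab <- table(object@branchOf[rownames(v)])
    cat("  branches:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  cat("  sugars:", paste(utils::head(colnames(v), 6), collapse = ", "),
      if (ncol(v) > 6) "..." else "", "\n")
})

setMethod("show", "GeneStateMatrix", function(object) {
  s <- object@states
  tab <- table(factor(s, levels = .GENE_STATES))
  cat(sprintf("GeneStateMatrix: %d strains x %d genes\n", nrow(s), ncol(s)))
  cat("  states:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
})

setMethod("show", "PathwayModel", function(object) {
  fmt_route <- function(r) {
    if (!length(r)) return("<always satisfied>")
    paste(vapply(r, function(g) {
      if (length(g) > 1L) sprintf("(%s)", paste(g, collapse = "|")) else g
    }, character(1)), collapse = " & ")
  }
  cat(sprintf("PathwayModel for %s: %d route(s)\n", object@sugar,
              length(object@routes)))
  if (length(object@name) && nzchar(object@name))
    cat(" ", object@name, "\n")
  for (r in object@routes) cat("   ", fmt_route(r), "\n")
  if (!length(object@routes)) cat("    <no routes: predicts NEGATIVE for all>\n")
})

setMethod("show", "FluxSplit", function(object) {
  cat("FluxSplit:",
      paste(sprintf("%s=%.3f", names(object@fractions), object@fractions),
            collapse = ", "),
      sprintf("(residual %.4g)\n", object@residual))
})

setMethod("show", "RouteStoichiometry", function(object) {
  cat(sprintf("RouteStoichiometry '%s' (%s):\n  ", object@name, object@substrate))
  cat(paste(sprintf("%s=%.3g", names(object@yields), object@yields),
            collapse = ", "), "\n")
})

setMethod("show", "FermentationProfile", function(object) {
  y <- object@yields
  lab <- ifelse(is.na(y), "NA",
                paste0(ifelse(object@bounds == "le", "<=", ""), signif(y, 3)))
  cat(sprintf("FermentationProfile for %s on %s:\n  ", object@strain, object@substrate))
  cat(paste(sprintf("%s=%s", names(y), lab), collapse = ", "), "\n")
})

setMethod("show", "InferredRuleSet", function(object) {
  cat(sprintf("InferredRuleSet: %d minimal rule(s) at concordance %.4f%s\n",
              length(object@rules), object@concordance,
              if (object@lowConfidence) " [low confidence]" else ""))
  for (m in utils::head(object@rules, 5)) show(m)
  if (length(object@rules) > 5) cat("  ...\n")
})

setMethod("show", "SimulatedDataset", function(object) {
  cat(sprintf("SimulatedDataset: %d tips, %d genes, %d sugar(s), %d recorded events, %d noise flips\n",
              nrow(object@genes@states), ncol(object@genes@states),
              ncol(object@phenotypes@values), nrow(object@events),
              nrow(object@flips)))
})
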