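#' Construct a phenotype matrix
#'
#' @param values 0/1 matrix (strains x sugars) with dimnames, or a
#'   logical matrix.
#' @param branchOf optional named character vector of group labels
#'   covering every strain.
#' @return a [PhenotypeMatrix-class].
#' @examples
#' m <- matrix(c(1, 0, 0, 1), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("glucose", "ribose")))
#' PhenotypeMatrix(m)
#' @export
PhenotypeMatrix <- function(values, branchOf = NULL) {
  storage.mode(values) <- "integer"
  new("PhenotypeMatrix", values = values,
      branchOf = if (is.null(branchOf)) character() else branchOf)
}

#' Construct a gene-state matrix
#'
#' @param states character matrix (strains x genes) over the alphabet
#'   ABSENT / PSEUDOGENE / SINGULAR / INTACT (one-letter codes A/P/S/I
#'   are expanded).
#' @return a [GeneStateMatrix-class].
#' @export
GeneStateMatrix <- function(states) {
  short <- states %in% names(.STATE_CODES)
  states[short] <- .STATE_CODES[states[short]]
  new("GeneStateMatrix", states = states)
}

#' Construct a pathway model
#'
#' @param sugar sugar id the model predicts growth on.
#' @param routes list of routes; each route a list of isoform groups
#'   (character vectors of gene ids).  A bare character vector route is
#'   promoted to singleton isoform groups.
#' @param name free-text description.
#' @return a [PathwayModel-class].
#' @examples
#' PathwayModel("L-arabinose",
#'              list(list("araA", "araB", c("araD", "araD1"))))
#' @export
PathwayModel <- function(sugar, routes = list(), name = "") {
  routes <- lapply(routes, function(r) {
    if (is.character(r)) r <- as.list(r)
    lapply(r, as.character)
  })
  new("PathwayModel", sugar = sugar, routes = routes, name = name)
}

.read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    colClasses = "character", quote = "", comment.char = "",
                    na.strings = NULL, fileEncoding = "UTF-8")
}

#' Read a phenotype matrix from TSV
#'
#' Expected layout: header row of sugar ids, first column of strain ids,
#' cells `1` (POSITIVE), `0` or blank (NEGATIVE) -- blanks because the
#' published table only marks positives.
#'
#' @param path TSV file path.
#' @param branches optional path to a two-column TSV (strain, branch)
#'   attaching lineage group labels.
#' @return a [PhenotypeMatrix-class].
#' @export
readPhenotypeMatrix <- function(path, branches = NULL) {
  df <- .read_tsv(path)
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate strain id: ", ids[duplicated(ids)][1L])
  sugars <- colnames(df)[-1L]
  if (anyDuplicated(sugars))
    stop("duplicate sugar id: ", sugars[duplicated(sugars)][1L])
  cells <- as.matrix(df[, -1L, drop = FALSE])
  bad <- !(cells %in% c("0", "1", ""))
  if (any(bad)) {
    i <- arrayInd(which(bad)[1L], dim(cells))
    stop(sprintf("invalid phenotype cell '%s' at row %d (strain '%s'), column '%s'",
                 cells[bad][1L], i[1L], ids[i[1L]], sugars[i[2L]]))
  }
  v <- matrix(as.integer(cells == "1"), nrow = length(ids),
              dimnames = list(ids, sugars))
  br <- NULL
  if (!is.null(branches)) {
    b <- .read_tsv(branches)
    br <- stats::setNames(b[[2L]], b[[1L]])
  }
  PhenotypeMatrix(v, branchOf = br)
}

#' Write a phenotype matrix to TSV
#'
#' Writes explicit 0/1 cells; [readPhenotypeMatrix()] round-trips the
#' result entry for entry.
#'
#' @param x a [PhenotypeMatrix-class].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writePhenotypeMatrix <- function(x, path) {
  df <- cbind(strain = rownames(x@values),
              as.data.frame(x@values, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a gene functionality-state matrix from TSV
#'
#' Cells may use one-letter codes (`A`, `P`, `S`, `I`) or the long state
#' names.
#'
#' @param path TSV file path (header = gene ids, first column = strain ids).
#' @return a [GeneStateMatrix-class].
#' @export
readGeneStateMatrix <- function(path) {
  df <- .read_tsv(path)
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate strain id: ", ids[duplicated(ids)][1L])
  genes <- colnames(df)[-1L]
  if (anyDuplicated(genes))
    stop("duplicate gene id: ", genes[duplicated(genes)][1L])
  cells <- as.matrix(df[, -1L, drop = FALSE])
  ok <- cells %in% c(names(.STATE_CODES), .GENE_STATES)
  if (any(!ok)) {
    i <- arrayInd(which(!ok)[1L], dim(cells))
    stop(sprintf("unknown state token '%s' at row %d (strain '%s'), column '%s'",
                 cells[!ok][1L], i[1L], ids[i[1L]], genes[i[2L]]))
  }
  dimnames(cells) <- list(ids, genes)
  GeneStateMatrix(cells)
}

#' Write a gene-state matrix to TSV (one-letter codes)
#'
#' @param x a [GeneStateMatrix-class].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeGeneStateMatrix <- function(x, path) {
  codes <- stats::setNames(names(.STATE_CODES), .STATE_CODES)
  s <- matrix(codes[x@states], nrow = nrow(x@states), dimnames = dimnames(x@states))
  df <- cbind(strain = rownames(s), as.data.frame(s, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a rooted strain phylogeny from a Newick file
#'
#' @param path Newick file path.
#' @return an ape `phylo` object with unique tip labels.
#' @export
readStrainTree <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("Newick parse failure: ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("Newick parse failure: no tree in file")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip label: ", tr$tip.label[duplicated(tr$tip.label)][1L])
  tr
}

#' Read a pathway model from JSON
#'
#' Expected document shape (also shipped as
#' `extdata/rules/pathway_model_schema.json`):
#' `{"sugar": str, "name": str, "routes": [[[gene, ...], ...], ...]}`
#' where the inner lists are isoform groups.  The structure is validated
#' on load.
#'
#' @param path JSON file path.
#' @return a [PathwayModel-class].
#' @export
readPathwayModel <- function(path) {
  obj <- jsonlite::read_json(path)
  if (!is.list(obj) || is.null(obj$sugar) || !is.character(obj$sugar[[1L]]))
    stop("pathway model JSON must carry a string 'sugar' field: ", path)
  if (!is.null(obj$routes) && !is.list(obj$routes))
    stop("pathway model 'routes' must be an array: ", path)
  routes <- lapply(obj$routes, function(r) {
    if (!is.list(r)) stop("each route must be an array of isoform groups: ", path)
    lapply(r, function(g) {
      g <- unlist(g)
      if (!length(g) || !is.character(g))
        stop("each isoform group must be a non-empty array of gene ids: ", path)
      g
    })
  })
  PathwayModel(sugar = obj$sugar[[1L]], routes = routes,
               name = if (is.null(obj$name)) "" else obj$name[[1L]])
}

#' Write a pathway model to JSON
#'
#' @param x a [PathwayModel-class].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writePathwayModel <- function(x, path) {
  obj <- list(sugar = x@sugar, name = x@name,
              routes = lapply(x@routes, function(r) lapply(r, as.list)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
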