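## round half away from zero, the convention that reproduces every
## printed percentage of the source table (e.g. 8/41 -> 20, 36/41 -> 88)
roundHalfUp <- function(x) floor(x + 0.5)

#' Call a growth phenotype from a fermentation assay readout
#'
#' A strain is scored POSITIVE on a sugar when the two-week assay shows
#' a significant pH-indicator colour change together with more than
#' 10 mM lactate produced; lactate below 5 mM is NEGATIVE (in the source
#' assays always accompanied by no colour change); anything in between
#' is INDETERMINATE.  A small OD600 increase alone never makes a call
#' positive, since slight OD changes occur without carbohydrate
#' degradation.
#'
#' @param lactate_mM lactate produced, mM (non-negative).
#' @param color_change logical, did the bromocresol-green indicator turn?
#' @param od600_delta optional OD600 change; recorded but never flips a
#'   call.
#' @return one of `"POSITIVE"`, `"NEGATIVE"`, `"INDETERMINATE"`.
#' @examples
#' callPhenotype(12, TRUE)   # POSITIVE
#' callPhenotype(0, FALSE)   # NEGATIVE
#' callPhenotype(7, TRUE)    # INDETERMINATE
#' @export
callPhenotype <- function(lactate_mM, color_change, od600_delta = NULL) {
  if (!is.numeric(lactate_mM) || is.na(lactate_mM) || lactate_mM < 0)
    stop("lactate_mM must be a non-negative number")
  if (lactate_mM > 10 && isTRUE(color_change)) return("POSITIVE")
  if (lactate_mM < 5) return("NEGATIVE")
  "INDETERMINATE"
}

#' Per-sugar substrate-usage summary
#'
#' Positive counts and integer percentages per sugar, reproducing the
#' "total" and "Total (%)" rows of the published table (percentages
#' rounded half-up).
#'
#' @param x a [PhenotypeMatrix-class].
#' @return data.frame with columns sugar, count, percent, in input
#'   column order.
#' @examples
#' u <- substrateUsage(loadFixture("table1"))
#' u[u$sugar == "trehalose", ]   # 40 positives, 98%
#' @export
substrateUsage <- function(x) {
  stopifnot(is(x, "PhenotypeMatrix"))
  v <- x@values
  if (!nrow(v) || !ncol(v)) stop("empty phenotype matrix")
  counts <- colSums(v)
  data.frame(sugar = colnames(v), count = as.integer(counts),
             percent = as.integer(roundHalfUp(100 * counts / nrow(v))),
             row.names = NULL)
}

#' Number of sugars metabolized by each strain
#'
#' @param x a [PhenotypeMatrix-class].
#' @return named integer vector of per-strain totals.
#' @export
strainTotals <- function(x) {
  stopifnot(is(x, "PhenotypeMatrix"))
  stats::setNames(as.integer(rowSums(x@values)), rownames(x@values))
}

#' Bin strains by how many sugars they metabolize
#'
#' @param x a [PhenotypeMatrix-class].
#' @param bin_edges strictly increasing integer cut points; a strain
#'   with total t falls in bin k when `bin_edges[k] <= t < bin_edges[k+1]`,
#'   with open-ended first and last bins added below and above.  The
#'   default `c(5, 10)` gives the source's three classes
#'   (<=4, 5..9, >=10).
#' @return named integer vector of bin counts, summing to the number of
#'   strains.
#' @examples
#' binStrainTotals(loadFixture("table1"))   # 5, 30, 6
#' @export
binStrainTotals <- function(x, bin_edges = c(5, 10)) {
  if (length(bin_edges) < 1L || is.unsorted(bin_edges, strictly = TRUE))
    stop("bin_edges must be strictly increasing")
  tot <- strainTotals(x)
  breaks <- c(-Inf, bin_edges, Inf)
  lab <- character(length(breaks) - 1L)
  for (k in seq_along(lab)) {
    lo <- breaks[k]; hi <- breaks[k + 1L] - 1
    lab[k] <- if (is.infinite(lo)) sprintf("<=%d", hi)
              else if (is.infinite(breaks[k + 1L])) sprintf(">=%d", lo)
              else sprintf("%d-%d", lo, hi)
  }
  cnt <- table(cut(tot, breaks = breaks, right = FALSE, labels = lab))
  stats::setNames(as.integer(cnt), names(cnt))
}

#' Mean number of sugars used, per phylogenomic branch
#'
#' Both the raw and the half-up rounded group means are returned; the
#' rounded value is the comparison surface (the source prose prints
#' rounded values: branch A strains grow on about 6 sugars, branch B on
#' about 10).
#'
#' @param x a [PhenotypeMatrix-class] with branch labels attached.
#' @return data.frame with columns branch, n, mean_raw, mean_rounded.
#' @export
groupMeanUsage <- function(x) {
  br <- branchOf(x)
  if (is.null(br)) stop("phenotype matrix carries no branch labels")
  tot <- strainTotals(x)
  groups <- sort(unique(br[names(tot)]))
  out <- lapply(groups, function(g) {
    t_g <- tot[names(tot)[br[names(tot)] == g]]
    data.frame(branch = g, n = length(t_g), mean_raw = mean(t_g),
               mean_rounded = as.integer(roundHalfUp(mean(t_g))))
  })
  do.call(rbind, out)
}

#' Sugars ordered by how many strains use them
#'
#' Stable sort by descending positive count; ties keep input column
#' order, so the five never-used sugars stay in their original relative
#' order at the end.
#'
#' @param x a [PhenotypeMatrix-class].
#' @return character vector of sugar ids, most-used first.
#' @export
preferenceOrder <- function(x) {
  u <- substrateUsage(x)
  u$sugar[order(-u$count)]    # order() is a stable sort
}
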