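#' Build the 2x2 gene-by-phenotype contingency table
#'
#' Cross-tabulates gene functionality (under a policy) against the
#' growth phenotype over the strains shared by both matrices:
#' `a` = functional & positive, `b` = functional & negative,
#' `c` = non-functional & positive, `d` = non-functional & negative.
#'
#' @param genes a [GeneStateMatrix-class].
#' @param phenotypes a [PhenotypeMatrix-class].
#' @param gene gene id to tabulate.
#' @param sugar sugar id to tabulate.
#' @param policy a [FunctionalityPolicy-class]; default [defaultPolicy()].
#' @return named integer vector `c(a, b, c, d)`.
#' @export
buildContingencyTable <- function(genes, phenotypes, gene, sugar,
                                  policy = defaultPolicy()) {
  stopifnot(is(genes, "GeneStateMatrix"), is(phenotypes, "PhenotypeMatrix"))
  if (!gene %in% colnames(genes@states)) stop("gene not found: ", gene)
  if (!sugar %in% colnames(phenotypes@values)) stop("sugar not found: ", sugar)
  shared <- intersect(rownames(genes@states), rownames(phenotypes@values))
  if (!length(shared)) stop("no strains shared between gene and phenotype matrices")
  fun <- isFunctional(genes@states[shared, , drop = FALSE], policy)[, gene]
  pos <- phenotypes@values[shared, sugar] == 1L
  c(a = sum(fun & pos), b = sum(fun & !pos),
    c = sum(!fun & pos), d = sum(!fun & !pos))
}

#' Two-sided Fisher exact p-value (point-probability rule)
#'
#' With margins fixed, sums the hypergeometric probabilities of all
#' tables whose probability does not exceed that of the observed table
#' (ties included up to a 1e-7 relative tolerance, so that floating-
#' point noise cannot drop an exactly tied table).
#'
#' @param table named integer vector `c(a, b, c, d)` as produced by
#'   [buildContingencyTable()], or four counts in that order.
#' @return two-sided p-value in (0, 1].
#' @examples
#' fisherExactTwoSided(c(a = 10, b = 0, c = 0, d = 10))  # 2 / choose(20, 10)
#' fisherExactTwoSided(c(a = 5, b = 5, c = 5, d = 5))    # 1
#' @export
fisherExactTwoSided <- function(table) {
  t <- as.integer(table)
  if (length(t) != 4L || any(t < 0)) stop("need four non-negative counts a,b,c,d")
  a <- t[1L]; b <- t[2L]; c <- t[3L]; d <- t[4L]
  m <- a + b              # functional strains
  n2 <- c + d             # non-functional strains
  k <- a + c              # positive strains
  support <- max(0L, k - n2):min(k, m)
  probs <- stats::dhyper(support, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Lineage-aware permutation p-value for a gene-phenotype association
#'
#' Permutes phenotype labels only within lineage groups (by default the
#' dendrogram branches attached to the phenotype matrix), so that a gene
#' merely tracking branch membership -- the dominant confounder in a
#' clonal species whose branch-B strains are systematically more
#' versatile -- is not scored as associated.  The association statistic
#' is the absolute log odds ratio with Haldane correction (+0.5 per
#' cell).  Groups with fewer than two strains cannot be shuffled and are
#' left fixed (with a message).
#'
#' @param genes a [GeneStateMatrix-class].
#' @param phenotypes a [PhenotypeMatrix-class].
#' @param gene,sugar ids to test.
#' @param groups optional named character vector strain -> group;
#'   default `branchOf(phenotypes)`.
#' @param nPerm number of permutations (>= 100).
#' @param seed RNG seed for reproducibility.
#' @param policy a [FunctionalityPolicy-class].
#' @return permutation p-value `(1 + #\{perm >= obs\}) / (1 + nPerm)`.
#' @export
lineagePermutationP <- function(genes, phenotypes, gene, sugar, groups = NULL,
                                nPerm = 1000L, seed = NULL,
                                policy = defaultPolicy()) {
  if (nPerm < 100L) stop("nPerm must be at least 100")
  shared <- intersect(rownames(genes@states), rownames(phenotypes@values))
  if (!length(shared)) stop("no strains shared between gene and phenotype matrices")
  if (is.null(groups)) groups <- branchOf(phenotypes)
  if (is.null(groups)) stop("no grouping: supply 'groups' or attach branch labels")
  if (!all(shared %in% names(groups)))
    stop("grouping does not cover all shared strains")
  if (!gene %in% colnames(genes@states)) stop("gene not found: ", gene)
  if (!sugar %in% colnames(phenotypes@values)) stop("sugar not found: ", sugar)

  g <- as.numeric(isFunctional(genes@states[shared, , drop = FALSE], policy)[, gene])
  y <- as.numeric(phenotypes@values[shared, sugar])
  grp <- groups[shared]

  idx_by_group <- split(seq_along(shared), grp)
  small <- vapply(idx_by_group, length, integer(1)) < 2L
  if (any(small))
    message("group(s) with <2 strains left unshuffled: ",
            paste(names(idx_by_group)[small], collapse = ", "))
  shuffle_groups <- idx_by_group[!small]

  haldane_stat <- function(a, b, c, d)
    abs(log((a + 0.5) * (d + 0.5) / ((b + 0.5) * (c + 0.5))))

  n <- length(y)
  obs <- haldane_stat(sum(g * y), sum(g * (1 - y)),
                      sum((1 - g) * y), sum((1 - g) * (1 - y)))

  if (!is.null(seed)) set.seed(seed)
  P <- matrix(y, nrow = n, ncol = nPerm)
  for (idx in shuffle_groups) {
    for (j in seq_len(nPerm)) P[idx, j] <- y[idx[sample.int(length(idx))]]
  }
  a <- as.numeric(crossprod(g, P))
  k <- colSums(P)
  m <- sum(g)
  stat <- haldane_stat(a, m - a, k - a, n - m - (k - a))
  (1 + sum(stat >= obs - 1e-12)) / (1 + nPerm)
}

#' Genome-wide gene-trait association screen
#'
#' For every requested (gene, sugar) pair: the 2x2 table under the
#' policy, the two-sided Fisher exact p, optionally a lineage-aware
#' permutation p, a Benjamini-Hochberg q-value computed within each
#' sugar, and a perfect-association flag (`b == 0 && c == 0`, or the
#' mirror `a == 0 && d == 0`: functionality separates the phenotype
#' exactly).  Genes with no functional variation across strains (or
#' sugars with no phenotype variation) are degenerate: they are reported
#' with p = 1 and flagged, never dropped.
#'
#' @param genes a [GeneStateMatrix-class].
#' @param phenotypes a [PhenotypeMatrix-class].
#' @param policy a [FunctionalityPolicy-class].
#' @param geneIds,sugarIds subsets to screen; default all.
#' @param nPerm permutations for the lineage-aware p (0 = skip).
#' @param groups grouping for the permutation test; default branch labels.
#' @param seed RNG seed for the permutation layer.
#' @return data.frame with columns gene, sugar, a, b, c, d, p_exact,
#'   p_perm, q_fdr, perfect, degenerate, sorted by q then p.
#' @export
screenAssociations <- function(genes, phenotypes, policy = defaultPolicy(),
                               geneIds = NULL, sugarIds = NULL, nPerm = 0L,
                               groups = NULL, seed = NULL) {
  stopifnot(is(genes, "GeneStateMatrix"), is(phenotypes, "PhenotypeMatrix"))
  if (is.null(geneIds)) geneIds <- colnames(genes@states)
  if (is.null(sugarIds)) sugarIds <- colnames(phenotypes@values)
  shared <- intersect(rownames(genes@states), rownames(phenotypes@values))
  if (!length(shared)) stop("no strains shared between gene and phenotype matrices")

  rows <- list()
  for (sugar in sugarIds) {
    for (gene in geneIds) {
      tab <- buildContingencyTable(genes, phenotypes, gene, sugar, policy)
      degenerate <- (tab["a"] + tab["b"] == 0L) || (tab["c"] + tab["d"] == 0L) ||
                    (tab["a"] + tab["c"] == 0L) || (tab["b"] + tab["d"] == 0L)
      p <- if (degenerate) 1 else fisherExactTwoSided(tab)
      pp <- NA_real_
      if (nPerm > 0L && !degenerate)
        pp <- lineagePermutationP(genes, phenotypes, gene, sugar,
                                  groups = groups, nPerm = nPerm, seed = seed,
                                  policy = policy)
      perfect <- (tab["b"] == 0L && tab["c"] == 0L) ||
                 (tab["a"] == 0L && tab["d"] == 0L)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = gene, sugar = sugar,
        a = tab[["a"]], b = tab[["b"]], c = tab[["c"]], d = tab[["d"]],
        p_exact = p, p_perm = pp, q_fdr = NA_real_,
        perfect = perfect, degenerate = degenerate)
    }
  }
  out <- do.call(rbind, rows)
  for (sugar in unique(out$sugar)) {
    sel <- out$sugar == sugar
    out$q_fdr[sel] <- stats::p.adjust(out$p_exact[sel], method = "BH")
  }
  out[order(out$q_fdr, out$p_exact, out$gene), , drop = FALSE]
}
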