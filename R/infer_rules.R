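## canonical text form of a monotone DNF rule: routes sorted, literals
## sorted, gene ids sorted inside isoform groups -- used to compare rules
## for identity irrespective of enumeration order

#' Canonical signature of a pathway model
#'
#' Order-independent text form (genes sorted within isoform groups,
#' groups sorted within routes, routes sorted), so two models are the
#' same monotone DNF iff their signatures are equal.
#'
#' @param model a [PathwayModel-class].
#' @return single string.
#' @export
ruleSignature <- function(model) {
  rs <- vapply(model@routes, function(r) {
    paste(sort(vapply(r, function(g) paste(sort(g), collapse = "|"),
                      character(1))), collapse = "&")
  }, character(1))
  paste(sort(rs), collapse = " + ")
}

#' Exhaustively infer monotone pathway rules from data
#'
#' Enumerates every monotone DNF over the candidate literals -- up to
#' `maxRoutes` routes, each route a conjunction of up to
#' `maxLiteralsPerRoute` literals -- plus the constant rules (no route:
#' always NEGATIVE; one empty route: always POSITIVE), scores each by
#' concordance with the observed phenotype, and returns every rule
#' achieving the maximal concordance, filtered to the minimal ones: a
#' rule is minimal when removing any route, or any literal from a
#' multi-literal route, strictly decreases concordance.  Equally scoring
#' minimal rules are all reported, never silently tie-broken, ordered by
#' total literal count and then lexicographically.
#'
#' A literal is a single candidate gene, or a declared isoform group (a
#' named element of `candidates` holding several gene ids, satisfied
#' when any member is functional).
#'
#' The search is exhaustive within its bounds, not heuristic; it errors
#' if the bounds imply more than `maxEvaluations` rule evaluations.
#'
#' @param genes a [GeneStateMatrix-class].
#' @param phenotypes a [PhenotypeMatrix-class].
#' @param sugar phenotype column to fit.
#' @param candidates character vector of gene ids, or a (possibly named)
#'   list mixing gene ids and isoform-group character vectors.
#' @param maxRoutes maximum number of routes (default 2).
#' @param maxLiteralsPerRoute maximum literals per route (default 2).
#' @param policy a [FunctionalityPolicy-class].
#' @param maxEvaluations enumeration guard (default 1e7 rules).
#' @return an [InferredRuleSet-class].
#' @examples
#' ## an 8-strain toy whose phenotype is (g1 & g2) | g3
#' s <- expand.grid(g1 = c("I", "P"), g2 = c("I", "P"), g3 = c("I", "P"))
#' st <- as.matrix(s); rownames(st) <- paste0("s", 1:8)
#' gm <- GeneStateMatrix(st)
#' y <- as.integer((st[, "g1"] == "INTACT" & st[, "g2"] == "INTACT") |
#'                 st[, "g3"] == "INTACT")
#' pm <- PhenotypeMatrix(matrix(y, ncol = 1,
#'         dimnames = list(rownames(st), "toy")))
#' inferRules(gm, pm, "toy", c("g1", "g2", "g3"))
#' @export
inferRules <- function(genes, phenotypes, sugar, candidates, maxRoutes = 2L,
                       maxLiteralsPerRoute = 2L, policy = defaultPolicy(),
                       maxEvaluations = 1e7) {
  stopifnot(is(genes, "GeneStateMatrix"), is(phenotypes, "PhenotypeMatrix"))
  if (length(candidates) == 0L) stop("no candidate genes supplied")
  if (is.character(candidates)) candidates <- as.list(candidates)
  lit_genes <- lapply(candidates, as.character)
  lit_names <- vapply(lit_genes, function(g) paste(sort(g), collapse = "|"),
                      character(1))
  if (anyDuplicated(lit_names)) stop("duplicate candidate literals")
  if (!sugar %in% colnames(phenotypes@values)) stop("sugar not found: ", sugar)
  unknown <- setdiff(unique(unlist(lit_genes)), colnames(genes@states))
  if (length(unknown))
    stop("candidate gene(s) absent from the matrix: ",
         paste(unknown, collapse = ", "))
  shared <- intersect(rownames(genes@states), rownames(phenotypes@values))
  if (!length(shared)) stop("no strains shared between gene and phenotype matrices")

  fun <- isFunctional(genes@states[shared, , drop = FALSE], policy)
  L <- vapply(lit_genes, function(g) rowSums(fun[, g, drop = FALSE]) > 0,
              logical(length(shared)))    # strains x literals
  if (length(shared) == 1L) L <- matrix(L, nrow = 1L)
  y <- phenotypes@values[shared, sugar] == 1L
  n <- length(y); npos <- sum(y); nneg <- n - npos

  ## enumerate candidate routes: literal subsets of size 1..k
  nlit <- length(lit_genes)
  k <- min(maxLiteralsPerRoute, nlit)
  route_sets <- list()
  for (s in seq_len(k))
    route_sets <- c(route_sets,
                    utils::combn(nlit, s, simplify = FALSE))
  R <- length(route_sets)
  n_rules <- 2 + sum(vapply(seq_len(min(maxRoutes, R)), function(r)
    choose(R, r), numeric(1)))
  if (n_rules > maxEvaluations)
    stop(sprintf("rule space too large (%.3g rules > %.3g); tighten maxRoutes/maxLiteralsPerRoute",
                 n_rules, maxEvaluations))

  RP <- vapply(route_sets, function(rs)
    rowSums(L[, rs, drop = FALSE]) == length(rs), logical(n))
  if (n == 1L) RP <- matrix(RP, nrow = 1L)
  route_key <- vapply(route_sets, function(rs) paste(rs, collapse = ","),
                      character(1))
  route_index <- stats::setNames(seq_len(R), route_key)

  ## correct-call counts (integer concordance) per rule
  pos_hits <- as.integer(crossprod(RP, y))        # predicted & observed positive
  neg_hits <- as.integer(crossprod(RP, !y))       # predicted positive, observed negative
  correct_single <- pos_hits + (nneg - neg_hits)

  best <- max(nneg, npos)                         # constant rules
  rules_at <- list()
  add_rule <- function(idx, cnt) {
    if (cnt > best) { best <<- cnt; rules_at <<- list() }
    if (cnt == best) rules_at[[length(rules_at) + 1L]] <<- idx
  }
  ## constant rules: integer(0) = always NEGATIVE; NA_integer_ marks the
  ## single-empty-route rule = always POSITIVE
  if (nneg >= npos) add_rule(integer(0), nneg)
  if (npos >= nneg) add_rule(NA_integer_, npos)
  for (i in seq_len(R)) add_rule(i, correct_single[i])

  if (maxRoutes >= 2L && R >= 2L) {
    Ppos <- crossprod(RP & y)                     # pairwise overlap on positives
    Pneg <- crossprod(RP & !y)
    ## correct(i|j) = pos_i + pos_j - Ppos_ij + nneg - (neg_i + neg_j - Pneg_ij)
    C2 <- outer(pos_hits, pos_hits, "+") - Ppos + nneg -
          (outer(neg_hits, neg_hits, "+") - Pneg)
    ut <- which(upper.tri(C2) & C2 >= best, arr.ind = TRUE)
    if (nrow(ut)) {
      for (z in seq_len(nrow(ut)))
        add_rule(c(ut[z, 1L], ut[z, 2L]), C2[ut[z, 1L], ut[z, 2L]])
    }
  }
  if (maxRoutes >= 3L && R >= 3L) {
    for (r in 3:min(maxRoutes, R)) {
      combos <- utils::combn(R, r, simplify = FALSE)
      for (cc in combos) {
        pred <- rowSums(RP[, cc, drop = FALSE]) > 0
        add_rule(cc, sum(pred == y))
      }
    }
  }

  rule_correct <- function(idx) {
    if (length(idx) == 1L && is.na(idx[1L])) return(npos)
    if (!length(idx)) return(nneg)
    pred <- rowSums(RP[, idx, drop = FALSE]) > 0
    sum(pred == y)
  }

  ## minimality: dropping any route, or any literal from a multi-literal
  ## route, must strictly decrease the correct-call count
  is_minimal <- function(idx) {
    if (length(idx) == 1L && is.na(idx[1L]))
      return(rule_correct(integer(0)) < best)
    if (!length(idx)) return(TRUE)
    for (j in seq_along(idx)) {
      if (rule_correct(idx[-j]) >= best) return(FALSE)
      rs <- route_sets[[idx[j]]]
      if (length(rs) > 1L) {
        for (drop in seq_along(rs)) {
          sub <- route_index[[paste(rs[-drop], collapse = ",")]]
          if (rule_correct(c(idx[-j], sub)) >= best) return(FALSE)
        }
      }
    }
    TRUE
  }

  to_model <- function(idx) {
    if (length(idx) == 1L && is.na(idx[1L]))
      return(PathwayModel(sugar, list(list()), name = "always positive"))
    PathwayModel(sugar, lapply(idx, function(i)
      lapply(route_sets[[i]], function(li) lit_genes[[li]])))
  }
  n_literals <- function(idx) {
    if (!length(idx) || (length(idx) == 1L && is.na(idx[1L]))) return(0L)
    sum(lengths(route_sets[idx]))
  }

  minimal <- Filter(is_minimal, rules_at)
  models <- lapply(minimal, to_model)
  sizes <- vapply(minimal, n_literals, integer(1))
  sigs <- vapply(models, ruleSignature, character(1))
  ord <- order(sizes, sigs)
  new("InferredRuleSet",
      rules = models[ord],
      concordance = best / n,
      maxSet = lapply(rules_at, to_model),
      lowConfidence = best <= max(npos, nneg),
      bounds = list(maxRoutes = maxRoutes,
                    maxLiteralsPerRoute = maxLiteralsPerRoute,
                    nCandidates = nlit, nRules = n_rules))
}
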