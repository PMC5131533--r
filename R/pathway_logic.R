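#' Evaluate a pathway model on a gene-state matrix
#'
#' A route is satisfied for a strain when every one of its isoform
#' groups contains at least one functional gene (under the policy); the
#' predicted phenotype is POSITIVE when at least one route is satisfied.
#' The evaluation is deterministic and monotone: upgrading any gene
#' state toward functional can never flip a prediction from POSITIVE to
#' NEGATIVE.
#'
#' @param genes a [GeneStateMatrix-class].
#' @param model a [PathwayModel-class]; every gene the model references
#'   must be present in `genes`.
#' @param policy a [FunctionalityPolicy-class].
#' @return data.frame with one row per strain: strain, predicted
#'   (POSITIVE/NEGATIVE), n_active_routes, active_routes
#'   (comma-separated route indices) and blocking (for each unsatisfied
#'   route, its first unsatisfied isoform group, `;`-separated across
#'   routes).
#' @examples
#' ara <- loadFixture("arabinose_states")
#' rule <- loadFixture("rules/arabinose")
#' pred <- predictPhenotypes(ara, rule)
#' pred[pred$strain == "AWRI_B419", ]   # POSITIVE via the araD1 rescue
#' @export
predictPhenotypes <- function(genes, model, policy = defaultPolicy()) {
  stopifnot(is(genes, "GeneStateMatrix"), is(model, "PathwayModel"))
  used <- unique(unlist(model@routes))
  unknown <- setdiff(used, colnames(genes@states))
  if (length(unknown))
    stop("model references gene(s) absent from the matrix: ",
         paste(unknown, collapse = ", "))
  fun <- isFunctional(genes@states, policy)
  strains <- rownames(genes@states)
  n <- length(strains)

  ## per-route satisfaction and first blocking group
  route_sat <- matrix(TRUE, nrow = n, ncol = length(model@routes))
  blocking <- matrix("", nrow = n, ncol = length(model@routes))
  for (ri in seq_along(model@routes)) {
    for (grp in model@routes[[ri]]) {
      ok <- rowSums(fun[, grp, drop = FALSE]) > 0
      newly <- route_sat[, ri] & !ok
      blocking[newly, ri] <- paste(grp, collapse = "|")
      route_sat[newly, ri] <- FALSE
    }
  }
  active <- apply(route_sat, 1L, function(z) paste(which(z), collapse = ","))
  block <- apply(blocking, 1L, function(z) paste(z[nzchar(z)], collapse = ";"))
  n_active <- rowSums(route_sat)
  data.frame(strain = strains,
             predicted = ifelse(n_active > 0, "POSITIVE", "NEGATIVE"),
             n_active_routes = as.integer(n_active),
             active_routes = active, blocking = block,
             row.names = NULL)
}

#' Concordance between rule predictions and observed phenotypes
#'
#' @param predictions data.frame from [predictPhenotypes()], or a named
#'   character vector of POSITIVE/NEGATIVE predictions per strain.
#' @param phenotypes a [PhenotypeMatrix-class].
#' @param sugar sugar id of the observed phenotype column.
#' @return list with confusion counts (TP, FP, FN, TN), accuracy,
#'   n, and a data.frame `discordant` naming each mismatching strain
#'   and its direction (`"false_positive"` / `"false_negative"`).
#' @export
ruleConcordance <- function(predictions, phenotypes, sugar) {
  stopifnot(is(phenotypes, "PhenotypeMatrix"))
  if (is.data.frame(predictions))
    predictions <- stats::setNames(predictions$predicted, predictions$strain)
  if (!sugar %in% colnames(phenotypes@values)) stop("sugar not found: ", sugar)
  shared <- intersect(names(predictions), rownames(phenotypes@values))
  if (!length(shared)) stop("no strains shared between predictions and phenotypes")
  pred <- predictions[shared] == "POSITIVE"
  obs <- phenotypes@values[shared, sugar] == 1L
  tp <- sum(pred & obs); fp <- sum(pred & !obs)
  fn <- sum(!pred & obs); tn <- sum(!pred & !obs)
  disc <- data.frame(
    strain = shared[pred != obs],
    direction = ifelse(pred[pred != obs], "false_positive", "false_negative"),
    row.names = NULL)
  list(TP = tp, FP = fp, FN = fn, TN = tn, n = length(shared),
       accuracy = (tp + tn) / length(shared), discordant = disc)
}

#' Detect isoform complementation (rescue) events
#'
#' Within a declared isoform group whose first member is the primary
#' gene, a rescue event is a strain where the primary gene is
#' non-functional, another group member is functional, and the strain's
#' phenotype is nevertheless POSITIVE (e.g. the locus-B phosphotrehalase
#' standing in for a truncated primary copy).  Strains whose primary
#' gene is non-functional with no functional rescuer yet a POSITIVE
#' phenotype are flagged as unexplained positives.
#'
#' @param genes a [GeneStateMatrix-class].
#' @param phenotypes a [PhenotypeMatrix-class].
#' @param isoform_groups named list; names are sugar ids, each element a
#'   character vector of gene ids with the primary gene first.
#' @param policy a [FunctionalityPolicy-class].
#' @return data.frame with columns sugar, group, strain, rescuer, type
#'   (`"rescue"` or `"unexplained_positive"`).
#' @export
detectComplementation <- function(genes, phenotypes, isoform_groups,
                                  policy = defaultPolicy()) {
  stopifnot(is(genes, "GeneStateMatrix"), is(phenotypes, "PhenotypeMatrix"))
  shared <- intersect(rownames(genes@states), rownames(phenotypes@values))
  fun <- isFunctional(genes@states[shared, , drop = FALSE], policy)
  rows <- list()
  for (sugar in names(isoform_groups)) {
    grp <- isoform_groups[[sugar]]
    if (length(grp) < 1L) next
    if (!sugar %in% colnames(phenotypes@values)) stop("sugar not found: ", sugar)
    pos <- phenotypes@values[shared, sugar] == 1L
    primary <- grp[1L]
    others <- grp[-1L]
    for (s in which(!fun[, primary] & pos)) {
      rescuers <- others[fun[s, others]]
      rows[[length(rows) + 1L]] <- data.frame(
        sugar = sugar, group = paste(grp, collapse = "|"),
        strain = shared[s],
        rescuer = if (length(rescuers)) paste(rescuers, collapse = ",") else NA_character_,
        type = if (length(rescuers)) "rescue" else "unexplained_positive")
    }
  }
  if (!length(rows))
    return(data.frame(sugar = character(), group = character(),
                      strain = character(), rescuer = character(),
                      type = character()))
  do.call(rbind, rows)
}
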