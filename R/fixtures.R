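.fixture_path <- function(...) {
  p <- system.file("extdata", ..., package = "carbotrait", mustWork = FALSE)
  if (!nzchar(p)) stop("fixture file not found: ", paste(..., collapse = "/"))
  p
}

.STATE_FIXTURES <- c("arabinose_states", "ribose_states", "mannose_states",
                     "fructose_states", "trehalose_states", "maltose_states",
                     "melibiose_states")
.RULE_FIXTURES <- paste0("rules/", c("arabinose", "ribose", "mannose",
                                     "fructose", "trehalose", "maltose",
                                     "melibiose", "glucose"))

#' Names of the packaged fixtures
#'
#' @return character vector of names accepted by [loadFixture()]:
#'   `"table1"` (the 41-strain x 18-sugar phenotype table with branch
#'   labels), the prose-derived gene-state fixtures
#'   (`"arabinose_states"`, ...), and the per-sugar pathway rules
#'   (`"rules/arabinose"`, ...).
#' @export
fixtureNames <- function() c("table1", .STATE_FIXTURES, .RULE_FIXTURES)

#' Load a packaged fixture
#'
#' `"table1"` returns the published 41 x 18 strain-by-carbohydrate
#' growth table (blank = negative) with dendrogram branch labels
#' attached (A: 29 strains, B: 11, C: 1).  `"<sugar>_states"` fixtures
#' carry the gene functionality states stated in the source prose;
#' unstated cells default to INTACT (ABSENT for accessory genes) and the
#' stated evidence is available through [fixtureEvidence()].
#' `"rules/<sugar>"` fixtures are the per-sugar pathway-completeness
#' models.
#'
#' @param name one of [fixtureNames()].
#' @return a [PhenotypeMatrix-class], [GeneStateMatrix-class] or
#'   [PathwayModel-class].
#' @examples
#' tab <- loadFixture("table1")
#' colSums(phenotypeCalls(tab))[1:6]
#' loadFixture("rules/arabinose")
#' @export
loadFixture <- function(name) {
  if (identical(name, "table1")) {
    return(readPhenotypeMatrix(.fixture_path("table1_phenotypes.tsv"),
                               branches = .fixture_path("table1_branches.tsv")))
  }
  if (name %in% .STATE_FIXTURES) {
    return(readGeneStateMatrix(.fixture_path(paste0(name, ".tsv"))))
  }
  if (name %in% .RULE_FIXTURES) {
    sugar <- sub("^rules/", "", name)
    return(readPathwayModel(.fixture_path("rules", paste0(sugar, ".json"))))
  }
  stop("unknown fixture name '", name, "'; see fixtureNames()")
}

#' Evidence backing a gene-state fixture
#'
#' Gene-state fixtures are transcribed from prose; only the cells listed
#' here are stated in the source, every other cell is an assumed
#' default.
#'
#' @param name a `"<sugar>_states"` fixture name.
#' @return data.frame with columns strain, gene, state, note.
#' @export
fixtureEvidence <- function(name) {
  if (!name %in% .STATE_FIXTURES)
    stop("no evidence sidecar for fixture '", name, "'")
  .read_tsv(.fixture_path(paste0(name, "_evidence.tsv")))
}

#' Normalize strain spellings to their canonical table forms
#'
#' The source prose spells several strains inconsistently
#' (e.g. "AWRIB-429", "ATCC_BAA1163", "IOEB_L65_2"); this maps known
#' variants onto the canonical forms used by the `"table1"` fixture.
#' Unknown labels pass through unchanged.
#'
#' @param x character vector of strain labels.
#' @return character vector of canonical labels.
#' @export
normalizeStrainNames <- function(x) {
  map <- .read_tsv(.fixture_path("strain_name_map.tsv"))
  m <- stats::setNames(map$canonical, map$variant)
  hit <- x %in% names(m)
  x[hit] <- m[x[hit]]
  x
}
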