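#' Construct a functionality policy
#'
#' @param singularFunctional should `SINGULAR` (strain-specific variant)
#'   states count as functional?  Default `FALSE`: the conservative
#'   reading, under which a singular variant is treated like a
#'   pseudogene.
#' @param overrides named list of per-gene overrides; each element is a
#'   named logical vector over (a subset of) the four states, e.g.
#'   `list(nagC = c(SINGULAR = TRUE))` to tolerate a singular hexokinase.
#'
#' @return a [FunctionalityPolicy-class] object.
#' @examples
#' pol <- functionalityPolicy()
#' isFunctional(matrix("SINGULAR", 1, 1, dimnames = list("s", "g")), pol)
#' @export
functionalityPolicy <- function(singularFunctional = FALSE, overrides = list()) {
  fun <- c(ABSENT = FALSE, PSEUDOGENE = FALSE,
           SINGULAR = isTRUE(singularFunctional), INTACT = TRUE)
  new("FunctionalityPolicy", functional = fun, overrides = overrides)
}

#' The default functionality policy
#'
#' Only `INTACT` genes are functional; `SINGULAR` variants are treated
#' as non-functional.
#' @return a [FunctionalityPolicy-class] object.
#' @export
defaultPolicy <- function() functionalityPolicy()

#' Map gene states to functional flags under a policy
#'
#' @param states a character matrix of gene states (strains x genes), a
#'   [GeneStateMatrix-class], or a character vector of states.
#' @param policy a [FunctionalityPolicy-class]; default [defaultPolicy()].
#'
#' @return logical object of the same shape: TRUE where the gene copy is
#'   considered functional.
#' @export
isFunctional <- function(states, policy = defaultPolicy()) {
  if (is(states, "GeneStateMatrix")) states <- states@states
  if (is.matrix(states)) {
    out <- matrix(policy@functional[states], nrow = nrow(states),
                  dimnames = dimnames(states))
    for (g in intersect(names(policy@overrides), colnames(out))) {
      o <- policy@overrides[[g]]
      hit <- states[, g] %in% names(o)
      out[hit, g] <- o[states[hit, g]]
    }
    out
  } else {
    unname(policy@functional[states])
  }
}
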