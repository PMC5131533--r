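#' Construct a route stoichiometry
#'
#' @param name route label.
#' @param substrate substrate id (a hexose; 6 carbons).
#' @param yields named numeric vector of mol product per mol substrate;
#'   missing product axes are filled with 0.  Carbon balance against the
#'   six substrate carbons is checked to 1e-9 at registration.
#' @return a [RouteStoichiometry-class].
#' @export
routeStoichiometry <- function(name, substrate, yields) {
  full <- stats::setNames(numeric(length(.PRODUCTS)), .PRODUCTS)
  bad <- setdiff(names(yields), .PRODUCTS)
  if (length(bad)) stop("unknown product axis: ", paste(bad, collapse = ", "))
  full[names(yields)] <- yields
  new("RouteStoichiometry", name = name, substrate = substrate, yields = full)
}

#' Built-in fermentation routes for hexose catabolism
#'
#' Three textbook end-product stoichiometries, per mol of hexose
#' consumed:
#' \describe{
#'   \item{EMP_homolactic}{glycolytic homolactic fermentation: 2 lactate.
#'     Available to strains assimilating fructose as fructose-1-P
#'     through a PTS-fructose permease; energetically the most
#'     profitable.}
#'   \item{PK_ethanol}{the heterofermentative phosphoketolase pathway:
#'     1 lactate + 1 ethanol + 1 CO2.}
#'   \item{PK_mannitol_sink}{phosphoketolase flux with fructose itself
#'     as the electron acceptor, the classic dismutation of 3 fructose
#'     into 2 mannitol + 1 lactate + 1 acetate + 1 CO2, normalized per
#'     mol: 1/3 lactate + 1/3 acetate + 2/3 mannitol + 1/3 CO2.}
#' }
#'
#' @param substrate substrate label attached to the routes (default
#'   `"fructose"`).
#' @return named list of [RouteStoichiometry-class] objects.
#' @examples
#' builtinRoutes()$EMP_homolactic
#' @export
builtinRoutes <- function(substrate = "fructose") {
  list(
    EMP_homolactic = routeStoichiometry("EMP_homolactic", substrate,
      c(lactate = 2)),
    PK_ethanol = routeStoichiometry("PK_ethanol", substrate,
      c(lactate = 1, ethanol = 1, CO2 = 1)),
    PK_mannitol_sink = routeStoichiometry("PK_mannitol_sink", substrate,
      c(lactate = 1/3, acetate = 1/3, mannitol = 2/3, CO2 = 1/3)))
}

#' Construct an observed fermentation profile
#'
#' @param strain strain label.
#' @param yields named numeric vector of observed mol product per mol
#'   substrate; axes not supplied are `NA` (unmeasured).
#' @param bounds optional named character vector; `"le"` marks a yield
#'   reported only as an upper bound.
#' @param substrate substrate id.
#' @return a [FermentationProfile-class].
#' @examples
#' ## "1.5 lactate, 0.2 acetate and less than 0.1 mannitol per mol fructose"
#' fermentationProfile("S19", c(lactate = 1.5, acetate = 0.2, mannitol = 0.1),
#'                     bounds = c(mannitol = "le"))
#' @export
fermentationProfile <- function(strain, yields, bounds = character(),
                                substrate = "fructose") {
  full <- stats::setNames(rep(NA_real_, length(.PRODUCTS)), .PRODUCTS)
  bad <- setdiff(names(yields), .PRODUCTS)
  if (length(bad)) stop("unknown product axis: ", paste(bad, collapse = ", "))
  full[names(yields)] <- yields
  b <- stats::setNames(rep("eq", length(.PRODUCTS)), .PRODUCTS)
  b[names(bounds)] <- bounds
  new("FermentationProfile", strain = strain, substrate = substrate,
      yields = full, bounds = b)
}

.route_matrix <- function(routes) {
  vapply(routes, function(r) r@yields, numeric(length(.PRODUCTS)))
}

#' Predict end-product yields from a flux split
#'
#' The convex combination of the route yield vectors under the split
#' fractions.
#'
#' @param split a [FluxSplit-class], or a named numeric vector of
#'   fractions over the routes.
#' @param routes named list of [RouteStoichiometry-class] objects;
#'   default [builtinRoutes()] restricted to the split's route names.
#' @return named numeric vector of yields over the five product axes.
#' @examples
#' ## equal flux through homolactic EMP and phosphoketolase routes
#' predictYields(c(EMP_homolactic = 0.5, PK_ethanol = 0.5))["lactate"]  # 1.5
#' @export
predictYields <- function(split, routes = NULL) {
  f <- if (is(split, "FluxSplit")) split@fractions else split
  if (abs(sum(f) - 1) > 1e-9 || any(f < 0))
    stop("fractions must be non-negative and sum to 1")
  if (is.null(routes)) routes <- builtinRoutes()[names(f)]
  if (any(vapply(routes, is.null, logical(1))) ||
      !all(names(f) %in% names(routes)))
    stop("unknown route name(s) in split")
  Y <- .route_matrix(routes[names(f)])
  stats::setNames(as.numeric(Y %*% f), .PRODUCTS)
}

#' Fit a flux split to an observed fermentation profile
#'
#' Least-squares non-negative route fractions on the simplex, by grid
#' search at resolution 0.001 (exhaustive for up to three routes).
#' Unmeasured (`NA`) product axes contribute nothing to the residual;
#' axes flagged `"le"` (upper bounds) are penalized only when the
#' prediction exceeds the bound; CO2 is never fitted (it was not
#' measured in the source HPLC setup).  Exact residual ties are broken
#' toward the split with the highest homolactic (EMP) fraction.
#'
#' @param profile a [FermentationProfile-class].
#' @param routes named list of [RouteStoichiometry-class] objects (1 to
#'   3 of them); default [builtinRoutes()].
#' @param resolution grid step on the simplex (default 0.001).
#' @return a [FluxSplit-class].
#' @examples
#' s19 <- fermentationProfile("S19",
#'   c(lactate = 1.5, acetate = 0.2, mannitol = 0.1),
#'   bounds = c(mannitol = "le"))
#' fitFluxSplit(s19, builtinRoutes()[c("EMP_homolactic", "PK_ethanol")])
#' @export
fitFluxSplit <- function(profile, routes = builtinRoutes(),
                         resolution = 0.001) {
  stopifnot(is(profile, "FermentationProfile"))
  if (length(routes) < 1L) stop("need at least one route")
  if (length(routes) > 3L) stop("grid search supports at most three routes")
  obs <- profile@yields
  measured <- !is.na(obs) & .PRODUCTS != "CO2"
  if (!any(measured)) stop("profile has no measured product axes")
  le <- profile@bounds == "le"
  Y <- .route_matrix(routes)[measured, , drop = FALSE]
  obs_m <- obs[measured]
  le_m <- le[measured]

  steps <- round(1 / resolution)
  if (length(routes) == 1L) {
    grid <- matrix(1, nrow = 1L)
  } else if (length(routes) == 2L) {
    f1 <- seq(0L, steps) / steps
    grid <- rbind(f1, 1 - f1)
  } else {
    f1 <- rep(seq(0L, steps), times = steps + 1L - seq(0L, steps))
    f2 <- unlist(lapply(seq(0L, steps), function(i) seq(0L, steps - i)))
    grid <- rbind(f1 / steps, f2 / steps, (steps - f1 - f2) / steps)
  }
  pred <- Y %*% grid                                 # measured axes x grid
  dev <- pred - obs_m
  if (any(le_m)) dev[le_m, ] <- pmax(dev[le_m, , drop = FALSE], 0)
  rss <- colSums(dev^2)

  ## tie-break toward the highest EMP fraction among exact-tie minima
  best <- which(rss <= min(rss) + 1e-12)
  if (length(best) > 1L) {
    emp_row <- grep("^EMP", names(routes))
    if (length(emp_row) == 1L) best <- best[which.max(grid[emp_row, best])]
    else best <- best[1L]
  }
  new("FluxSplit",
      fractions = stats::setNames(grid[, best[1L]], names(routes)),
      residual = sqrt(rss[best[1L]]))
}

#' Classify a fermentation profile as homolactic-dominant or not
#'
#' Homolactic-dominant when lactate exceeds the summed acetate, ethanol
#' and mannitol yields (unmeasured axes count as zero); otherwise
#' heterofermentative.  The boundary (equality, or an all-zero profile)
#' is heterofermentative.
#'
#' @param profile a [FermentationProfile-class].
#' @return `"homolactic-dominant"` or `"heterofermentative"`.
#' @export
classifyFermentationMode <- function(profile) {
  stopifnot(is(profile, "FermentationProfile"))
  y <- profile@yields
  y[is.na(y)] <- 0
  if (y["lactate"] > y["acetate"] + y["ethanol"] + y["mannitol"])
    "homolactic-dominant" else "heterofermentative"
}
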