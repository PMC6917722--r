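#' @import methods
#' @importFrom Matrix sparseMatrix Matrix colSums rowSums t
NULL

#' MetabolicModel: a constraint-based metabolic network
#'
#' Container for a genome-scale (or toy) stoichiometric model: metabolites,
#' reactions with flux bounds and subsystem labels, a sparse stoichiometric
#' matrix and a linear objective. Together these define the flux balance
#' analysis problem max/min c'v subject to S v = 0 and lb <= v <= ub.
#'
#' Flux sign convention (used package-wide): for an exchange reaction written
#' as `met ->`, negative flux is uptake into the system and positive flux is
#' secretion out of it.
#'
#' @slot id character(1) model identifier.
#' @slot compartments data.frame with columns `id`, `name`.
#' @slot metabolites data.frame with columns `id`, `name`, `compartment`,
#'   `formula`, `charge`.
#' @slot reactions data.frame with columns `id`, `name`, `lower_bound`,
#'   `upper_bound`, `subsystem`, `is_exchange`.
#' @slot stoichiometry sparse `Matrix` (metabolites x reactions); column j's
#'   nonzeros are reaction j's stoichiometric coefficients (negative =
#'   consumed).
#' @slot objective named numeric of objective coefficients, names are
#'   reaction ids.
#' @slot annotation list of free-form model-level annotations (e.g. flux
#'   units, provenance of a merge).
#'
#' @seealso [readModel()], [writeModel()], [validateModel()], [solveFBA()]
#' @export
setClass("MetabolicModel",
  representation(
    id = "character",
    compartments = "data.frame",
    metabolites = "data.frame",
    reactions = "data.frame",
    stoichiometry = "Matrix",
    objective = "numeric",
    annotation = "list"
  ),
  prototype(
    id = "model",
    compartments = data.frame(id = character(), name = character(),
                              stringsAsFactors = FALSE),
    metabolites = data.frame(id = character(), name = character(),
                             compartment = character(), formula = character(),
                             charge = integer(), stringsAsFactors = FALSE),
    reactions = data.frame(id = character(), name = character(),
                           lower_bound = numeric(), upper_bound = numeric(),
                           subsystem = character(), is_exchange = logical(),
                           stringsAsFactors = FALSE),
    stoichiometry = Matrix::Matrix(0, 0, 0, sparse = TRUE),
    objective = numeric(0),
    annotation = list()
  )
)

# Validity is representational only: the matrix, tables and name vectors must
# be mutually consistent. Semantic findings (lb > ub, dangling compartments,
# malformed exchanges, ...) are reported by validateModel() so that invalid
# models can still be constructed and diagnosed.
setValidity("MetabolicModel", function(object) {
  msg <- character()
  S <- object@stoichiometry
  if (nrow(S) != nrow(object@metabolites))
    msg <- c(msg, "stoichiometry row count != number of metabolites")
  if (ncol(S) != nrow(object@reactions))
    msg <- c(msg, "stoichiometry column count != number of reactions")
  if (nrow(S) > 0 && !identical(rownames(S), object@metabolites$id))
    msg <- c(msg, "stoichiometry rownames != metabolite ids")
  if (ncol(S) > 0 && !identical(colnames(S), object@reactions$id))
    msg <- c(msg, "stoichiometry colnames != reaction ids")
  req <- c("id", "name", "lower_bound", "upper_bound", "subsystem", "is_exchange")
  if (!all(req %in% names(object@reactions)))
    msg <- c(msg, "reactions table lacks required columns")
  if (!all(c("id", "name", "compartment") %in% names(object@metabolites)))
    msg <- c(msg, "metabolites table lacks required columns")
  if (length(object@objective) && is.null(names(object@objective)))
    msg <- c(msg, "objective must be a named numeric vector")
  if (length(msg)) msg else TRUE
})

#' CoMetabolismModel: host and microbe joined through a shared lumen
#'
#' A merged [MetabolicModel-class] in which a host and a microbe network,
#' namespaced by prefixes, exchange metabolites through a common lumen
#' compartment. Former organism-level exchange reactions on shared
#' metabolites are rewritten as directed organism-lumen transports (split
#' into an uptake and a secretion reaction where the original exchange was
#' reversible, preserving the original bound magnitudes), and each lumen
#' metabolite gets one boundary exchange through which diet components enter
#' and surplus leaves.
#'
#' @slot hostPrefix,microbePrefix character(1) id namespacing prefixes.
#' @slot lumenCompartment character(1) lumen compartment id.
#' @slot dietExchanges character, lumen boundary exchange reaction ids.
#' @slot hostUptake,hostSecretion,microbeUptake,microbeSecretion character,
#'   disjoint sets of lumen transport reaction ids.
#' @slot biomassReaction character(1) microbe biomass reaction id, or
#'   `NA_character_` when none was identified.
#'
#' @seealso [mergeComodel()], [capMicrobeSecretion()], [applyPrebiotic()]
#' @export
setClass("CoMetabolismModel",
  contains = "MetabolicModel",
  representation(
    hostPrefix = "character",
    microbePrefix = "character",
    lumenCompartment = "character",
    dietExchanges = "character",
    hostUptake = "character",
    hostSecretion = "character",
    microbeUptake = "character",
    microbeSecretion = "character",
    biomassReaction = "character"
  ),
  prototype(
    hostPrefix = "H_", microbePrefix = "M_", lumenCompartment = "lu",
    dietExchanges = character(), hostUptake = character(),
    hostSecretion = character(), microbeUptake = character(),
    microbeSecretion = character(), biomassReaction = NA_character_
  )
)

setValidity("CoMetabolismModel", function(object) {
  msg <- character()
  sets <- list(object@hostUptake, object@hostSecretion,
               object@microbeUptake, object@microbeSecretion)
  all_ids <- unlist(sets)
  if (anyDuplicated(all_ids))
    msg <- c(msg, "lumen transport sets must be disjoint")
  known <- c(all_ids, object@dietExchanges)
  missing <- setdiff(known, object@reactions$id)
  if (length(missing))
    msg <- c(msg, paste("unknown reaction ids in transport/diet sets:",
                        paste(missing, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' FluxSolution: result of a flux balance optimization
#'
#' @slot status character(1): `"optimal"`, `"infeasible"` or `"unbounded"`.
#' @slot objectiveValue numeric(1) optimal objective (c'v); `NA` unless
#'   optimal.
#' @slot fluxes named numeric flux vector v (empty unless optimal).
#' @slot objectiveIds character, the reaction(s) carrying objective weight.
#' @slot feasibilityTolerance numeric(1) tolerance at which S v = 0 and the
#'   bounds are satisfied.
#' @slot parsimonious logical(1) whether the vector is the parsimonious
#'   (total-flux-minimal) representative of the optimal face.
#'
#' @seealso [solveFBA()], [solvePFBA()]
#' @export
setClass("FluxSolution",
  representation(
    status = "character",
    objectiveValue = "numeric",
    fluxes = "numeric",
    objectiveIds = "character",
    feasibilityTolerance = "numeric",
    parsimonious = "logical"
  ),
  prototype(status = "infeasible", objectiveValue = NA_real_,
            fluxes = numeric(0), objectiveIds = character(),
            feasibilityTolerance = 1e-9, parsimonious = FALSE)
)

#' DietSpec: diet preset as exchange-bound constraints
#'
#' @slot name character(1) preset name (e.g. `"western"`).
#' @slot bounds data.frame with columns `id`, `lower_bound`, `upper_bound`
#'   (model flux units); ids must resolve against the co-model's diet
#'   exchanges.
#' @seealso [applyDiet()], [readDietSpec()]
#' @export
setClass("DietSpec",
  representation(name = "character", bounds = "data.frame"),
  prototype(name = "empty",
            bounds = data.frame(id = character(), lower_bound = numeric(),
                                upper_bound = numeric(),
                                stringsAsFactors = FALSE))
)

setValidity("DietSpec", function(object) {
  b <- object@bounds
  if (!all(c("id", "lower_bound", "upper_bound") %in% names(b)))
    return("bounds must have columns id, lower_bound, upper_bound")
  if (any(b$lower_bound > b$upper_bound))
    return("diet bounds must satisfy lower_bound <= upper_bound")
  TRUE
})

#' PrebioticSpec: dose-in-grams to uptake-flux-bound definition
#'
#' A prebiotic is a mixture of components (for scFOS: kestose GF2,
#' kestotetraose GF3, kestopentaose GF4; for inulin: one average-DP polymer).
#' A dose of `d` grams over `horizonHours` hours allows uptake of component
#' i at up to `d * mass_fraction_i / grams_per_mmol_i / horizonHours *
#' fluxScale` mmol/h through its exchange reaction (see [doseToFlux()]).
#'
#' @slot name character(1), e.g. `"inulin"`, `"scFOS"` or a custom label.
#' @slot components data.frame with columns `exchange_id`, `mass_fraction`
#'   (sums to 1), `grams_per_mmol` (g/mmol, > 0).
#' @slot horizonHours numeric(1) dose amortization horizon (h).
#' @slot fluxScale numeric(1) per-gDW normalization constant applied to all
#'   bounds (default 1).
#' @seealso [doseToFlux()], [applyPrebiotic()], [inulinSpec()], [scfosSpec()]
#' @export
setClass("PrebioticSpec",
  representation(name = "character", components = "data.frame",
                 horizonHours = "numeric", fluxScale = "numeric"),
  prototype(name = "custom",
            components = data.frame(exchange_id = character(),
                                    mass_fraction = numeric(),
                                    grams_per_mmol = numeric(),
                                    stringsAsFactors = FALSE),
            horizonHours = 24, fluxScale = 1)
)

setValidity("PrebioticSpec", function(object) {
  cm <- object@components
  if (!all(c("exchange_id", "mass_fraction", "grams_per_mmol") %in% names(cm)))
    return("components must have columns exchange_id, mass_fraction, grams_per_mmol")
  if (nrow(cm)) {
    if (abs(sum(cm$mass_fraction) - 1) > 1e-9)
      return("component mass fractions must sum to 1")
    if (any(cm$grams_per_mmol <= 0))
      return("grams_per_mmol must be positive")
  }
  if (object@horizonHours <= 0) return("horizonHours must be positive")
  if (object@fluxScale <= 0) return("fluxScale must be positive")
  TRUE
})
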