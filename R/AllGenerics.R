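#' @include AllClasses.R
NULL

#' Accessors for MetabolicModel and FluxSolution objects
#'
#' Standard accessor generics. `reactions()` and `metabolites()` return the
#' annotation tables, `stoichiometricMatrix()` the sparse S matrix,
#' `objectiveCoefficients()` the named objective vector. For
#' [FluxSolution-class] objects, `fluxes()` returns the named flux vector,
#' `objectiveValue()` the optimum and `solverStatus()` the LP status.
#'
#' @param object a [MetabolicModel-class], [CoMetabolismModel-class] or
#'   [FluxSolution-class] object.
#' @return The corresponding slot content (see above).
#' @name accessors
#' @aliases reactions metabolites compartments stoichiometricMatrix
#'   objectiveCoefficients fluxes objectiveValue solverStatus
#' @examples
#' m <- makeToyHost()
#' nrow(reactions(m))
#' objectiveCoefficients(m)
NULL

#' @rdname accessors
#' @export
setGeneric("reactions", function(object) standardGeneric("reactions"))
#' @rdname accessors
#' @export
setGeneric("metabolites", function(object) standardGeneric("metabolites"))
#' @rdname accessors
#' @export
setGeneric("compartments", function(object) standardGeneric("compartments"))
#' @rdname accessors
#' @export
setGeneric("stoichiometricMatrix",
           function(object) standardGeneric("stoichiometricMatrix"))
#' @rdname accessors
#' @export
setGeneric("objectiveCoefficients",
           function(object) standardGeneric("objectiveCoefficients"))
#' @rdname accessors
#' @export
setGeneric("fluxes", function(object) standardGeneric("fluxes"))
#' @rdname accessors
#' @export
setGeneric("objectiveValue", function(object) standardGeneric("objectiveValue"))
#' @rdname accessors
#' @export
setGeneric("solverStatus", function(object) standardGeneric("solverStatus"))

#' Accessors for co-metabolism model structure
#'
#' `dietExchanges()` returns the ids of the lumen boundary exchanges,
#' `hostUptake()`/`hostSecretion()`/`microbeUptake()`/`microbeSecretion()`
#' the disjoint sets of organism-lumen transport reaction ids,
#' `biomassReaction()` the microbe biomass reaction id (`NA` when none was
#' identified) and `lumenCompartment()` the lumen compartment id.
#'
#' @param object a [CoMetabolismModel-class].
#' @return character vector of reaction ids (or a single id).
#' @name comodel-accessors
#' @aliases dietExchanges hostUptake hostSecretion microbeUptake
#'   microbeSecretion biomassReaction lumenCompartment
#' @examples
#' cm <- makeToyComodel()
#' microbeSecretion(cm)
NULL

#' @rdname comodel-accessors
#' @export
setGeneric("dietExchanges", function(object) standardGeneric("dietExchanges"))
#' @rdname comodel-accessors
#' @export
setGeneric("hostUptake", function(object) standardGeneric("hostUptake"))
#' @rdname comodel-accessors
#' @export
setGeneric("hostSecretion", function(object) standardGeneric("hostSecretion"))
#' @rdname comodel-accessors
#' @export
setGeneric("microbeUptake", function(object) standardGeneric("microbeUptake"))
#' @rdname comodel-accessors
#' @export
setGeneric("microbeSecretion", function(object) standardGeneric("microbeSecretion"))
#' @rdname comodel-accessors
#' @export
setGeneric("biomassReaction", function(object) standardGeneric("biomassReaction"))
#' @rdname comodel-accessors
#' @export
setGeneric("lumenCompartment", function(object) standardGeneric("lumenCompartment"))
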