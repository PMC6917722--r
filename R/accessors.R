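#' @include AllGenerics.R
NULL

#' @rdname accessors
setMethod("reactions", "MetabolicModel", function(object) object@reactions)
#' @rdname accessors
setMethod("metabolites", "MetabolicModel", function(object) object@metabolites)
#' @rdname accessors
setMethod("compartments", "MetabolicModel", function(object) object@compartments)
#' @rdname accessors
setMethod("stoichiometricMatrix", "MetabolicModel",
          function(object) object@stoichiometry)
#' @rdname accessors
setMethod("objectiveCoefficients", "MetabolicModel",
          function(object) object@objective)

#' @rdname accessors
setMethod("fluxes", "FluxSolution", function(object) object@fluxes)
#' @rdname accessors
setMethod("objectiveValue", "FluxSolution", function(object) object@objectiveValue)
#' @rdname accessors
setMethod("solverStatus", "FluxSolution", function(object) object@status)

#' @rdname comodel-accessors
setMethod("dietExchanges", "CoMetabolismModel", function(object) object@dietExchanges)
#' @rdname comodel-accessors
setMethod("hostUptake", "CoMetabolismModel", function(object) object@hostUptake)
#' @rdname comodel-accessors
setMethod("hostSecretion", "CoMetabolismModel", function(object) object@hostSecretion)
#' @rdname comodel-accessors
setMethod("microbeUptake", "CoMetabolismModel", function(object) object@microbeUptake)
#' @rdname comodel-accessors
setMethod("microbeSecretion", "CoMetabolismModel",
          function(object) object@microbeSecretion)
#' @rdname comodel-accessors
setMethod("biomassReaction", "CoMetabolismModel", function(object) object@biomassReaction)
#' @rdname comodel-accessors
setMethod("lumenCompartment", "CoMetabolismModel",
          function(object) object@lumenCompartment)

setMethod("show", "MetabolicModel", function(object) {
  cat("MetabolicModel \"", object@id, "\"\n", sep = "")
  cat("  ", nrow(object@metabolites), " metabolites, ",
      nrow(object@reactions), " reactions, ",
      nrow(object@compartments), " compartments\n", sep = "")
  nex <- sum(object@reactions$is_exchange)
  cat("  ", nex, " exchange reactions\n", sep = "")
  if (length(object@objective)) {
    cat("  objective:",
        paste(sprintf("%g*%s", unname(object@objective),
                      names(object@objective)), collapse = " + "), "\n")
  } else cat("  objective: none\n")
  invisible(NULL)
})

setMethod("show", "CoMetabolismModel", function(object) {
  callNextMethod()
  cat("  lumen compartment: ", object@lumenCompartment,
      " (", length(object@dietExchanges), " diet exchanges)\n", sep = "")
  cat("  transports host up/sec: ", length(object@hostUptake), "/",
      length(object@hostSecretion), "; microbe up/sec: ",
      length(object@microbeUptake), "/", length(object@microbeSecretion),
      "\n", sep = "")
  cat("  microbe biomass reaction: ", object@biomassReaction, "\n", sep = "")
  invisible(NULL)
})

setMethod("show", "FluxSolution", function(object) {
  cat("FluxSolution: status ", object@status, sep = "")
  if (identical(object@status, "optimal")) {
    cat(", objective ", format(object@objectiveValue),
        if (object@parsimonious) " (parsimonious)" else "", sep = "")
  }
  cat("\n  objective reaction(s): ",
      paste(object@objectiveIds, collapse = ", "), "\n", sep = "")
  if (length(object@fluxes)) {
    nz <- sum(abs(object@fluxes) > object@feasibilityTolerance)
    cat("  ", length(object@fluxes), " fluxes (", nz, " nonzero at tol ",
        format(object@feasibilityTolerance), ")\n", sep = "")
  }
  invisible(NULL)
})

setMethod("show", "DietSpec", function(object) {
  cat("DietSpec \"", object@name, "\": ", nrow(object@bounds),
      " exchange bounds\n", sep = "")
  invisible(NULL)
})

setMethod("show", "PrebioticSpec", function(object) {
  cat("PrebioticSpec \"", object@name, "\": ", nrow(object@components),
      " component(s), horizon ", object@horizonHours, " h\n", sep = "")
  if (nrow(object@components)) {
    with(object@components, cat(paste0(
      "  ", exchange_id, ": fraction ", signif(mass_fraction, 4),
      ", ", signif(grams_per_mmol, 6), " g/mmol\n"), sep = ""))
  }
  invisible(NULL)
})
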