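#' @include comodel.R
NULL

#' Construct a diet specification
#'
#' @param name preset name.
#' @param bounds data.frame with columns `id`, `lower_bound`, `upper_bound`
#'   (model flux units; negative lower bound allows uptake).
#' @return a [DietSpec-class].
#' @examples
#' d <- dietSpec("toy-western",
#'               data.frame(id = "EX_glc_lu", lower_bound = -3, upper_bound = 0))
#' @export
dietSpec <- function(name, bounds) {
  new("DietSpec", name = name,
      bounds = data.frame(id = as.character(bounds$id),
                          lower_bound = as.numeric(bounds$lower_bound),
                          upper_bound = as.numeric(bounds$upper_bound),
                          stringsAsFactors = FALSE))
}

#' Construct a prebiotic specification
#'
#' @param name label, e.g. `"inulin"`, `"scFOS"` or custom.
#' @param components data.frame with columns `exchange_id`, `mass_fraction`
#'   (summing to 1) and `grams_per_mmol`.
#' @param horizonHours dose amortization horizon in hours (default 24).
#' @param fluxScale per-gDW normalization constant multiplying every bound
#'   (default 1).
#' @return a [PrebioticSpec-class].
#' @seealso [inulinSpec()], [scfosSpec()], [doseToFlux()]
#' @export
prebioticSpec <- function(name, components, horizonHours = 24, fluxScale = 1) {
  new("PrebioticSpec", name = name,
      components = data.frame(
        exchange_id = as.character(components$exchange_id),
        mass_fraction = as.numeric(components$mass_fraction),
        grams_per_mmol = as.numeric(components$grams_per_mmol),
        stringsAsFactors = FALSE),
      horizonHours = horizonHours, fluxScale = fluxScale)
}

# average formula weight of a GF(n) fructan in g/mmol: one glucose plus n
# fructose units joined with loss of n waters
.fructanGramsPerMmol <- function(n) (180.156 + n * 162.141) / 1000

#' Built-in prebiotic presets
#'
#' `inulinSpec()` treats inulin as a single average-DP fructan polymer;
#' `scfosSpec()` is the kestose (GF2) / kestotetraose (GF3) /
#' kestopentaose (GF4) mixture, by default in equal mass thirds. Molar
#' masses come from the average GF(n) formula weight (GF2 0.50444, GF3
#' 0.66658, GF4 0.82872 g/mmol); all values are overridable through
#' [prebioticSpec()] when calibrating against an external supplement table.
#'
#' @param dp inulin degree of polymerization (default 10).
#' @param exchange_id exchange reaction id carrying the uptake bound (for
#'   scFOS, one id per component).
#' @param fractions scFOS mass split over GF2/GF3/GF4.
#' @param horizonHours,fluxScale see [prebioticSpec()].
#' @return a [PrebioticSpec-class].
#' @examples
#' scfosSpec()
#' @export
inulinSpec <- function(dp = 10, exchange_id = "EX_inulin",
                       horizonHours = 24, fluxScale = 1) {
  prebioticSpec("inulin",
                data.frame(exchange_id = exchange_id, mass_fraction = 1,
                           grams_per_mmol = .fructanGramsPerMmol(dp)),
                horizonHours, fluxScale)
}

#' @rdname inulinSpec
#' @export
scfosSpec <- function(exchange_id = c("EX_kestose", "EX_kestotetraose",
                                      "EX_kestopentaose"),
                      fractions = c(1, 1, 1) / 3,
                      horizonHours = 24, fluxScale = 1) {
  stopifnot(length(exchange_id) == 3)
  prebioticSpec("scFOS",
                data.frame(exchange_id = exchange_id,
                           mass_fraction = fractions,
                           grams_per_mmol = .fructanGramsPerMmol(2:4)),
                horizonHours, fluxScale)
}

#' Convert a prebiotic dose in grams to uptake flux bounds
#'
#' For each component i, the allowed uptake flux is
#' `b_i = dose_grams * mass_fraction_i / grams_per_mmol_i / horizonHours *
#' fluxScale` (mmol/h, scaled per gDW by `fluxScale`). Linear in the dose;
#' a dose of 0 gives all-zero bounds.
#'
#' @param prebiotic a [PrebioticSpec-class].
#' @param dose_grams non-negative dose (g).
#' @return named numeric of uptake bounds, names are component exchange ids.
#' @examples
#' gf2 <- prebioticSpec("GF2", data.frame(exchange_id = "EX_kestose",
#'   mass_fraction = 1, grams_per_mmol = 0.50444))
#' doseToFlux(gf2, 10)     # ~0.8262 mmol/h over a 24 h horizon
#' @export
doseToFlux <- function(prebiotic, dose_grams) {
  stopifnot(is(prebiotic, "PrebioticSpec"), dose_grams >= 0)
  validObject(prebiotic)
  cm <- prebiotic@components
  b <- dose_grams * cm$mass_fraction / cm$grams_per_mmol /
    prebiotic@horizonHours * prebiotic@fluxScale
  names(b) <- cm$exchange_id
  b
}

# resolve a component exchange id against a model: exact id, the lumenized
# diet exchange, or NA
.resolveDietExchange <- function(model, id) {
  ids <- model@reactions$id
  if (id %in% ids) return(id)
  if (is(model, "CoMetabolismModel")) {
    base <- sub("^EX_", "", id)
    cand <- paste0("EX_", base, "_", model@lumenCompartment)
    if (cand %in% ids) return(cand)
  }
  NA_character_
}

#' Apply a diet preset to a co-metabolism model
#'
#' Sets the bounds of the named lumen diet exchanges; every diet exchange
#' not named in the spec gets its uptake closed (`lower_bound = 0`) while
#' secretion (lumen efflux) stays open. Re-application is idempotent.
#'
#' @param comodel a [CoMetabolismModel-class].
#' @param diet a [DietSpec-class].
#' @return the constrained model.
#' @examples
#' cm <- applyDiet(makeToyComodel(), toyDiet())
#' @export
applyDiet <- function(comodel, diet) {
  stopifnot(is(comodel, "CoMetabolismModel"), is(diet, "DietSpec"))
  resolved <- vapply(diet@bounds$id,
                     function(i) .resolveDietExchange(comodel, i), character(1))
  if (anyNA(resolved)) {
    bad <- diet@bounds$id[is.na(resolved)]
    near <- vapply(bad, function(b) {
      d <- utils::adist(b, comodel@dietExchanges)
      paste(comodel@dietExchanges[order(d)][seq_len(min(3, length(d)))],
            collapse = ", ")
    }, character(1))
    stop("diet exchange id(s) not found: ",
         paste(paste0(bad, " (nearest: ", near, ")"), collapse = "; "))
  }
  m <- comodel
  unlisted <- setdiff(comodel@dietExchanges, resolved)
  if (length(unlisted)) m <- setBounds(m, unlisted, lower = 0)
  setBounds(m, resolved, diet@bounds$lower_bound, diet@bounds$upper_bound)
}

#' Apply a prebiotic dose to a co-metabolism model
#'
#' Converts the dose with [doseToFlux()] and constrains each component's
#' diet exchange to `(-b_i, 0)`: uptake allowed up to the dose-derived
#' bound, no efflux of the prebiotic itself. This allow-up-to reading of
#' dose constraints keeps the model feasible at every dose and makes the
#' dose response monotone non-decreasing. Bounds are overwritten, so the
#' last application wins. A component exchange missing from the co-model is
#' created in the lumen with a warning (the organism then simply cannot
#' reach it).
#'
#' @param comodel a [CoMetabolismModel-class].
#' @param prebiotic a [PrebioticSpec-class].
#' @param dose_grams dose (g).
#' @return the supplemented model.
#' @examples
#' cm <- applyPrebiotic(makeToyComodel(), toyFructan(), 1)
#' @export
applyPrebiotic <- function(comodel, prebiotic, dose_grams) {
  b <- doseToFlux(prebiotic, dose_grams)
  m <- comodel
  for (k in seq_along(b)) {
    rid <- .resolveDietExchange(m, names(b)[k])
    if (is.na(rid)) {
      base <- sub("^EX_", "", names(b)[k])
      warning("prebiotic exchange '", names(b)[k],
              "' absent from co-model; creating lumen exchange for '",
              base, "'")
      m <- .addLumenExchange(m, base)
      rid <- paste0("EX_", base, "_", m@lumenCompartment)
    }
    m <- setBounds(m, rid, lower = -b[k], upper = 0)
  }
  m
}

# append a lumen metabolite plus its boundary exchange to a co-model
.addLumenExchange <- function(cm, base) {
  lum <- paste0(base, "[", cm@lumenCompartment, "]")
  rid <- paste0("EX_", base, "_", cm@lumenCompartment)
  mets <- rbind(cm@metabolites,
                data.frame(id = lum, name = base,
                           compartment = cm@lumenCompartment,
                           formula = NA_character_, charge = NA_integer_))
  rxns <- rbind(cm@reactions,
                data.frame(id = rid, name = paste("lumen exchange of", base),
                           lower_bound = 0, upper_bound = 1000,
                           subsystem = "Lumen exchange", is_exchange = TRUE))
  S <- rbind(cm@stoichiometry,
             Matrix::Matrix(0, 1, ncol(cm@stoichiometry), sparse = TRUE))
  newcol <- Matrix::sparseMatrix(i = nrow(S), j = 1, x = -1,
                                 dims = c(nrow(S), 1))
  S <- cbind(S, newcol)
  dimnames(S) <- list(mets$id, rxns$id)
  methods::initialize(cm, metabolites = mets, reactions = rxns,
                      stoichiometry = S,
                      dietExchanges = c(cm@dietExchanges, rid))
}

#' Read diet / prebiotic specifications from YAML
#'
#' Diet YAML: `name:` plus `bounds:` mapping exchange id to `[lower,
#' upper]`. Prebiotic YAML: `name:`, `horizon_hours:`, `flux_scale:` and
#' `components:` list of `{exchange_id, mass_fraction, grams_per_mmol}`.
#'
#' @param path YAML file.
#' @return a [DietSpec-class] or [PrebioticSpec-class].
#' @examples
#' f <- system.file("extdata", "prebiotic_scfos.yaml", package = "LumenFBA")
#' readPrebioticSpec(f)
#' @export
readDietSpec <- function(path) {
  y <- yaml::read_yaml(path)
  b <- do.call(rbind, lapply(names(y$bounds), function(id)
    data.frame(id = id, lower_bound = y$bounds[[id]][[1]],
               upper_bound = y$bounds[[id]][[2]])))
  dietSpec(if (is.null(y$name)) "diet" else y$name, b)
}

#' @rdname readDietSpec
#' @export
readPrebioticSpec <- function(path) {
  y <- yaml::read_yaml(path)
  cm <- do.call(rbind, lapply(y$components, function(comp)
    data.frame(exchange_id = comp$exchange_id,
               mass_fraction = comp$mass_fraction,
               grams_per_mmol = comp$grams_per_mmol)))
  prebioticSpec(if (is.null(y$name)) "custom" else y$name, cm,
                horizonHours = if (is.null(y$horizon_hours)) 24
                  else y$horizon_hours,
                fluxScale = if (is.null(y$flux_scale)) 1 else y$flux_scale)
}
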