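#' @include conditions.R
NULL

# table-driven model assembly from equation strings
.modelFromEquations <- function(id, comps, mets, rxndefs, objective,
                                annotation = list()) {
  rx <- do.call(rbind, lapply(rxndefs, function(r)
    data.frame(id = r$id, name = r$name, lower_bound = r$lb,
               upper_bound = r$ub, subsystem = r$sub,
               stringsAsFactors = FALSE)))
  st <- do.call(rbind, lapply(rxndefs, function(r) {
    s <- .parseEquation(r$eq)
    s$reaction <- r$id
    s
  }))
  .buildModel(id = id, compartments = comps, metabolites = mets,
              reactions = rx, stoich = st, objective = objective,
              annotation = annotation)
}

.rx <- function(id, eq, lb = 0, ub = 1000, sub = "", name = id)
  list(id = id, eq = eq, lb = lb, ub = ub, sub = sub, name = name)

#' Toy host model: gut-fed provitamin D3 biosynthesis
#'
#' A 12-reaction host network emulating the route from absorbed microbial
#' fermentation acids to 25-hydroxyvitamin D3 secretion: glucose (and any
#' absorbed acetate, lactate or pyruvate) feeds an acetyl-CoA pool; three
#' acetyl-CoA lump the acetoacetyl-CoA/HMG-CoA chain into one
#' 7-dehydrocholesterol (7-DHC) synthesis step with a finite capacity
#' (`hmgsCapacity`), followed by hydroxylation to 25-OH-D3 and secretion
#' (`EX_d25`, the default maximization objective representing vitamin-D
#' deficient demand). Glucose uptake is bounded at `glucoseBound`, so the
#' baseline optimum is `2 * glucoseBound / 3` (2.0 by default).
#'
#' With `cofactors = TRUE` a 15-reaction variant tracks ATP and NADH:
#' glycolysis yields ATP, the pyruvate decarboxylase route (`PDH`) yields
#' NADH (re-oxidized by `OXP`), and both the acyl-transfer route (`ADHL`)
#' and acetate activation (`ACS`) consume ATP. Energy bookkeeping makes
#' the parsimonious route choice dose-dependent, which is what the
#' flux-mode analysis exercises.
#'
#' @param glucoseBound maximal glucose uptake flux (default 3).
#' @param hmgsCapacity upper bound of the lumped 7-DHC synthesis step
#'   (default 5); this downstream capacity causes dose-response saturation.
#' @param cofactors build the ATP/NADH-aware variant.
#' @return a validated [MetabolicModel-class].
#' @examples
#' objectiveValue(solveFBA(makeToyHost()))   # 2
#' @export
makeToyHost <- function(glucoseBound = 3, hmgsCapacity = 5,
                        cofactors = FALSE) {
  comps <- data.frame(id = c("c", "e"),
                      name = c("cytosol", "extracellular"))
  met <- function(id, name, comp) data.frame(id = id, name = name,
                                             compartment = comp)
  mets <- rbind(
    met("glc[e]", "glucose", "e"), met("lac[e]", "lactate", "e"),
    met("ac[e]", "acetate", "e"), met("pyr[e]", "pyruvate", "e"),
    met("d25[e]", "25-hydroxyvitamin D3", "e"),
    met("accoa[c]", "acetyl-CoA", "c"),
    met("dhc7[c]", "7-dehydrocholesterol", "c"),
    met("d25[c]", "25-hydroxyvitamin D3", "c"))
  core <- list(
    .rx("EX_glc", "glc[e] ->", -glucoseBound, 1000, "Exchange"),
    .rx("EX_lac", "lac[e] ->", -1000, 1000, "Exchange"),
    .rx("EX_ac", "ac[e] ->", -1000, 1000, "Exchange"),
    .rx("EX_pyr", "pyr[e] ->", -1000, 1000, "Exchange"),
    .rx("EX_d25", "d25[e] ->", 0, 1000, "Exchange"),
    .rx("LDH", "lac[e] -> pyr[e]", 0, 1000, "Acetyl-CoA synthesis",
        name = "lactate dehydrogenase (lumped)"),
    .rx("HMGS", "3 accoa[c] -> dhc7[c]", 0, hmgsCapacity,
        "Cholesterol biosynthesis",
        name = "acetyl-CoA to 7-DHC (lumped HMG-CoA chain)"),
    .rx("VD3H", "dhc7[c] -> d25[c]", 0, 1000, "Vitamin D metabolism",
        name = "7-DHC hydroxylation (lumped)"),
    .rx("D25S", "d25[c] -> d25[e]", 0, 1000, "Vitamin D metabolism",
        name = "25-OH-D3 secretion"))
  if (!cofactors) {
    rxns <- c(core, list(
      .rx("GLYC", "glc[e] -> 2 accoa[c]", 0, 1000, "Glycolysis"),
      .rx("PDH", "pyr[e] -> accoa[c]", 0, 1000, "Acetyl-CoA synthesis",
          name = "pyruvate decarboxylase route"),
      .rx("ACS", "ac[e] -> accoa[c]", 0, 1000, "Acetyl-CoA synthesis",
          name = "acetate activation")))
  } else {
    mets <- rbind(mets, met("atp[c]", "ATP", "c"), met("nadh[c]", "NADH", "c"),
                  met("adhl[c]", "S-acetyldihydrolipoamide pool", "c"))
    rxns <- c(core, list(
      .rx("GLYC", "glc[e] -> 2 accoa[c] + 1 atp[c]", 0, 1000, "Glycolysis"),
      .rx("PDH", "pyr[e] -> accoa[c] + 1 nadh[c]", 0, 2,
          "Acetyl-CoA synthesis", name = "pyruvate decarboxylase (NADH)"),
      .rx("ADHL", "pyr[e] + 1 atp[c] -> accoa[c]", 0, 1000,
          "Acetyl-CoA synthesis",
          name = "acyl transfer via S-acetyldihydrolipoamide (ATP)"),
      .rx("ACS", "ac[e] + 1 atp[c] -> accoa[c]", 0, 1000,
          "Acetyl-CoA synthesis", name = "acetate activation (ATP)"),
      .rx("OXP", "nadh[c] -> 2 atp[c]", 0, 1000,
          "Oxidative phosphorylation"),
      .rx("ATPM", "atp[c] ->", 0, 1000, "Maintenance",
          name = "ATP maintenance drain")))
  }
  .modelFromEquations("toy_host", comps, mets, rxns,
                      objective = c(EX_d25 = 1),
                      annotation = list(units = "mmol/gDW/h",
                                        family = "toy",
                                        cofactors = cofactors))
}

#' Toy microbe fermentation profiles
#'
#' The archetypes carry the organism-specific fermentation stoichiometry
#' fructan -> a acetate + l lactate + p pyruvate: `"fp"`
#' (*F. prausnitzii*-like; a=2, l=4, p=0), `"bt"`
#' (*B. thetaiotaomicron*-like; a=2, l=0, p=3) and `"null"` (cannot use the
#' fructan at all; grows on a small glucose allowance instead).
#'
#' @param name archetype name, or `"custom"` with explicit coefficients.
#' @param acetate,lactate,pyruvate non-negative fermentation coefficients.
#' @param biomassYield biomass flux per fructan consumed (default 0.1).
#' @return a list with class `"toyMicrobeProfile"`.
#' @examples
#' toyMicrobeProfile("bt")
#' @export
toyMicrobeProfile <- function(name = c("fp", "bt", "null", "custom"),
                              acetate = 0, lactate = 0, pyruvate = 0,
                              biomassYield = 0.1) {
  name <- match.arg(name)
  coefs <- switch(name,
    fp = c(a = 2, l = 4, p = 0),
    bt = c(a = 2, l = 0, p = 3),
    null = c(a = 0, l = 0, p = 0),
    custom = c(a = acetate, l = lactate, p = pyruvate))
  if (any(coefs < 0)) stop("fermentation coefficients must be non-negative")
  if (biomassYield < 0) stop("biomassYield must be non-negative")
  structure(list(name = name, acetate = unname(coefs["a"]),
                 lactate = unname(coefs["l"]), pyruvate = unname(coefs["p"]),
                 utilizer = name != "null", biomassYield = biomassYield),
            class = "toyMicrobeProfile")
}

#' Toy gut microbe model
#'
#' Builds a small microbe network from a [toyMicrobeProfile()]: fructan
#' uptake and transport, one fermentation reaction with the profile's
#' stoichiometry, secretion exchanges for acetate, lactate and pyruvate,
#' cytosolic overflow drains for the three acids (so fermentation can
#' continue when a secretion route is blocked), and a biomass reaction
#' consuming `1/biomassYield` fructan per unit growth. The `"null"`
#' archetype has no fructan machinery and grows on glucose.
#'
#' @param profile a [toyMicrobeProfile()].
#' @param fructanUptakeMax maximal fructan uptake of the standalone model
#'   (default 1000; the binding limit normally comes from the prebiotic
#'   dose).
#' @return a validated [MetabolicModel-class] with the biomass reaction as
#'   objective.
#' @examples
#' m <- makeToyMicrobe(toyMicrobeProfile("fp"))
#' @export
makeToyMicrobe <- function(profile = toyMicrobeProfile("fp"),
                           fructanUptakeMax = 1000) {
  stopifnot(inherits(profile, "toyMicrobeProfile"))
  comps <- data.frame(id = c("c", "e"),
                      name = c("cytosol", "extracellular"))
  met <- function(id, name, comp) data.frame(id = id, name = name,
                                             compartment = comp)
  mets <- rbind(
    met("ac[e]", "acetate", "e"), met("lac[e]", "lactate", "e"),
    met("pyr[e]", "pyruvate", "e"), met("ac[c]", "acetate", "c"),
    met("lac[c]", "lactate", "c"), met("pyr[c]", "pyruvate", "c"))
  rxns <- list(
    .rx("EX_ac", "ac[e] ->", 0, 1000, "Exchange"),
    .rx("EX_lac", "lac[e] ->", 0, 1000, "Exchange"),
    .rx("EX_pyr", "pyr[e] ->", 0, 1000, "Exchange"),
    .rx("T_AC", "ac[c] -> ac[e]", 0, 1000, "Transport"),
    .rx("T_LAC", "lac[c] -> lac[e]", 0, 1000, "Transport"),
    .rx("T_PYR", "pyr[c] -> pyr[e]", 0, 1000, "Transport"),
    .rx("SK_AC", "ac[c] ->", 0, 1000, "Overflow",
        name = "acetate overflow drain"),
    .rx("SK_LAC", "lac[c] ->", 0, 1000, "Overflow",
        name = "lactate overflow drain"),
    .rx("SK_PYR", "pyr[c] ->", 0, 1000, "Overflow",
        name = "pyruvate overflow drain"))
  inv_yield <- if (profile$biomassYield > 0) 1 / profile$biomassYield else NA
  if (profile$utilizer) {
    mets <- rbind(mets, met("fructan[e]", "fructan", "e"),
                  met("fructan[c]", "fructan", "c"))
    prods <- c()
    if (profile$acetate > 0)
      prods <- c(prods, paste(profile$acetate, "ac[c]"))
    if (profile$lactate > 0)
      prods <- c(prods, paste(profile$lactate, "lac[c]"))
    if (profile$pyruvate > 0)
      prods <- c(prods, paste(profile$pyruvate, "pyr[c]"))
    ferm_eq <- paste("fructan[c] ->", paste(prods, collapse = " + "))
    rxns <- c(rxns, list(
      .rx("EX_fructan", "fructan[e] ->", -fructanUptakeMax, 0, "Exchange"),
      .rx("T_FRU", "fructan[e] -> fructan[c]", 0, 1000, "Transport"),
      .rx("FERM", ferm_eq, 0, 1000, "Fermentation",
          name = "fructan fermentation"),
      .rx("BIOMASS_toy", paste(inv_yield, "fructan[c] ->"), 0, 1000,
          "Biomass", name = "biomass")))
  } else {
    mets <- rbind(mets, met("glc[e]", "glucose", "e"),
                  met("glc[c]", "glucose", "c"))
    rxns <- c(rxns, list(
      .rx("EX_glc", "glc[e] ->", -1, 0, "Exchange"),
      .rx("T_GLC", "glc[e] -> glc[c]", 0, 1000, "Transport"),
      .rx("BIOMASS_toy", paste(inv_yield, "glc[c] ->"), 0, 1000,
          "Biomass", name = "biomass")))
  }
  .modelFromEquations(paste0("toy_microbe_", profile$name), comps, mets, rxns,
                      objective = c(BIOMASS_toy = 1),
                      annotation = list(units = "mmol/gDW/h",
                                        family = "toy",
                                        profile = unclass(profile)))
}

#' Toy western diet and toy fructan prebiotic
#'
#' `toyDiet()` allows glucose uptake into the lumen (bound 3) and closes
#' every other diet input. `toyFructan()` maps dose grams one-to-one onto
#' the fructan uptake bound (1 g/mmol over a 1 h horizon), which keeps the
#' toy arithmetic transparent: a dose of 1 g allows a fructan uptake flux
#' of 1.
#'
#' @param glucoseBound glucose uptake allowance (default 3).
#' @return a [DietSpec-class] / [PrebioticSpec-class].
#' @examples
#' doseToFlux(toyFructan(), 1)
#' @export
toyDiet <- function(glucoseBound = 3) {
  dietSpec("toy-western",
           data.frame(id = "EX_glc_lu", lower_bound = -glucoseBound,
                      upper_bound = 0))
}

#' @rdname toyDiet
#' @export
toyFructan <- function() {
  prebioticSpec("toy-fructan",
                data.frame(exchange_id = "EX_fructan", mass_fraction = 1,
                           grams_per_mmol = 1),
                horizonHours = 1, fluxScale = 1)
}

#' Toy co-metabolism model
#'
#' Merges [makeToyHost()] with [makeToyMicrobe()] through a lumen and
#' applies [toyDiet()]. The resulting fixture reproduces the package's
#' reference numbers: baseline objective 2.0; 4.0 at a fructan uptake
#' bound of 1 with the FP-like microbe; 8/3 after knocking off the
#' microbe's lactate secretion.
#'
#' @param profile a [toyMicrobeProfile()] (default FP-like).
#' @param diet a [DietSpec-class] (default [toyDiet()]).
#' @inheritParams makeToyHost
#' @return a [CoMetabolismModel-class].
#' @examples
#' cm <- makeToyComodel()
#' objectiveValue(solveFBA(cm))   # 2: no prebiotic yet
#' @export
makeToyComodel <- function(profile = toyMicrobeProfile("fp"),
                           diet = toyDiet(), glucoseBound = 3,
                           hmgsCapacity = 5, cofactors = FALSE) {
  host <- makeToyHost(glucoseBound, hmgsCapacity, cofactors)
  microbe <- makeToyMicrobe(profile)
  cm <- mergeComodel(host, microbe)
  applyDiet(cm, diet)
}

#' Seeded synthetic microbe collection
#'
#' Draws `n` toy microbes from the three archetypes (FP-like, BT-like and
#' non-utilizing; mixture weights 0.4/0.4/0.2) with biomass yields drawn
#' uniformly from [0.05, 0.2]. The draw is fully reproducible: the same
#' seed gives byte-identical models. Used as the scale fixture for
#' collection screening.
#'
#' @param n number of models.
#' @param seed integer RNG seed (the caller's RNG state is preserved).
#' @param dir optional directory; when given, each model is written as
#'   COBRA JSON and the file paths are returned instead of model objects.
#' @return list of [MetabolicModel-class], or character paths when `dir`
#'   is given; the drawn archetype names are attached as
#'   `attr(, "archetypes")`.
#' @examples
#' mods <- makeToyCollection(3, seed = 1)
#' attr(mods, "archetypes")
#' @export
makeToyCollection <- function(n, seed, dir = NULL) {
  stopifnot(n >= 0)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  archetypes <- if (n > 0)
    sample(c("fp", "bt", "null"), n, replace = TRUE, prob = c(.4, .4, .2))
  else character()
  yields <- round(stats::runif(n, 0.05, 0.2), 4)
  mods <- lapply(seq_len(n), function(i) {
    m <- makeToyMicrobe(toyMicrobeProfile(archetypes[i],
                                          biomassYield = yields[i]))
    m@id <- sprintf("toy_micro_%03d_%s", i, archetypes[i])
    m
  })
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- vapply(mods, function(m) {
      p <- file.path(dir, paste0(m@id, ".json"))
      writeModel(m, p, "json")
      p
    }, character(1))
    attr(paths, "archetypes") <- archetypes
    return(paths)
  }
  attr(mods, "archetypes") <- archetypes
  mods
}
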