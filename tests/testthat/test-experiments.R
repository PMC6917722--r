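# the four analyses on the toy co-models

test_that("dose response rises with dose and the capped control stays flat", {
  cm <- makeToyComodel()
  dr <- runDoseResponse(cm, toyFructan(), c(0, 0.5, 1),
                        trackedReactions = c("H_HMGS", "EX_d25_lu"))
  expect_identical(dr$status, rep("optimal", 3))
  expect_equal(dr$objective, c(2, 3, 4), tolerance = 1e-9)
  expect_equal(dr$H_HMGS, c(2, 3, 4), tolerance = 1e-6)
  expect_equal(dr$EX_d25_lu, dr$objective, tolerance = 1e-6)

  ctrl <- runDoseResponse(cm, toyFructan(), c(0, 0.5, 1), control = TRUE)
  expect_equal(ctrl$objective, c(2, 2, 2), tolerance = 1e-9)

  expect_identical(nrow(runDoseResponse(cm, toyFructan(), numeric())), 0L)
  expect_error(runDoseResponse(cm, toyFructan(), c(1, 0.5)),
               "strictly increasing")
  expect_error(runDoseResponse(cm, toyFructan(), 1, trackedReactions = "xx"),
               "not in co-model")
})

test_that("secretion/absorption profile recovers the organism-specific pattern", {
  cm <- makeToyComodel()
  sol <- solvePFBA(applyPrebiotic(cm, toyFructan(), 1))
  p <- profileSecretionAbsorption(sol, cm)
  rownames(p) <- p$metabolite
  expect_equal(p["lac", "microbe_secretion"], 4, tolerance = 1e-6)
  expect_equal(p["ac", "microbe_secretion"], 2, tolerance = 1e-6)
  expect_equal(p["pyr", "microbe_secretion"], 0, tolerance = 1e-6)
  expect_equal(p$host_absorption, p$microbe_secretion, tolerance = 1e-6)

  # dose 0: nothing moves
  p0 <- profileSecretionAbsorption(solvePFBA(cm), cm)
  expect_true(all(abs(p0$microbe_secretion) < 1e-6))
  expect_true(all(abs(p0$host_absorption) < 1e-6))

  # BT-like contrast: pyruvate instead of lactate
  cmb <- makeToyComodel(toyMicrobeProfile("bt"))
  pb <- profileSecretionAbsorption(
    solvePFBA(applyPrebiotic(cmb, toyFructan(), 1)), cmb)
  rownames(pb) <- pb$metabolite
  expect_equal(pb["pyr", "microbe_secretion"], 3, tolerance = 1e-6)
  expect_equal(pb["lac", "microbe_secretion"], 0, tolerance = 1e-6)

  # a metabolite without transports is reported as not transported
  px <- profileSecretionAbsorption(sol, cm, metabolites = c("lac", "unobtainium"))
  expect_false(px$transported[px$metabolite == "unobtainium"])
  expect_identical(px$microbe_secretion[px$metabolite == "unobtainium"], 0)
})

test_that("lumen mass balance holds in every profile row", {
  for (prof in c("fp", "bt")) {
    cm <- applyPrebiotic(makeToyComodel(toyMicrobeProfile(prof)),
                         toyFructan(), 1)
    sol <- solvePFBA(cm)
    v <- fluxes(sol)
    S <- stoichiometricMatrix(cm)
    for (b in c("ac", "lac", "pyr", "glc", "fructan")) {
      met <- paste0(b, "[", lumenCompartment(cm), "]")
      expect_lt(abs(sum(S[met, ] * v[colnames(S)])), 1e-6)
    }
  }
})

test_that("knock-off scan quantifies the lactate dependence of the FP route", {
  cm <- makeToyComodel()
  ko <- runKnockoffScan(cm, microbeSecretion(cm), toyFructan(), 1)
  rownames(ko) <- ko$reaction
  expect_equal(ko["M_SEC_lac", "objective_before"], 4, tolerance = 1e-9)
  expect_equal(ko["M_SEC_lac", "objective_after"], 8 / 3, tolerance = 1e-9)
  expect_equal(ko["M_SEC_lac", "percent_reduction"], 100 * (4 - 8 / 3) / 4,
               tolerance = 1e-6)
  # pyruvate secretion carries no flux in the FP model: knocking it is free
  expect_equal(ko["M_SEC_pyr", "percent_reduction"], 0, tolerance = 1e-9)
  expect_true(all(ko$objective_after <= ko$objective_before + 1e-9))
  # flux readjustment bookkeeping is attached
  fd <- attr(ko, "flux_deltas")
  expect_true(all(c("reaction", "tracked", "before", "after") %in% names(fd)))
  expect_equal(fd$before[fd$reaction == "M_SEC_lac" & fd$tracked == "M_SEC_lac"],
               4, tolerance = 1e-6)

  # knocking all three secretions at once recovers the no-microbe baseline
  m <- applyPrebiotic(cm, toyFructan(), 1)
  for (rid in microbeSecretion(cm)) m <- knockOff(m, rid)
  expect_equal(objectiveValue(solveFBA(m)), 2, tolerance = 1e-9)
})

test_that("collection screen classifies archetypes and is byte-identical on rerun", {
  mods <- list(makeToyMicrobe(toyMicrobeProfile("fp")),
               makeToyMicrobe(toyMicrobeProfile("bt")),
               makeToyMicrobe(toyMicrobeProfile("null")))
  grid <- seq(0, 10, length.out = 6)
  sc <- screenCollection(mods, toyFructan(), doseGrid = grid)
  expect_identical(sc$utilizes, c(TRUE, TRUE, FALSE))
  umax <- 10    # toy fructan: 10 g -> uptake bound 10
  expect_equal(sc$max_lac, c(4 * umax, 0, 0), tolerance = 1e-9)
  expect_equal(sc$max_pyr, c(0, 3 * umax, 0), tolerance = 1e-9)
  expect_equal(sc$max_ac, c(2 * umax, 2 * umax, 0), tolerance = 1e-9)
  # the non-utilizer's profile is flat at the zero-dose value
  prof <- attr(sc, "profiles")
  nullprof <- prof[prof$organism == "toy_microbe_null", ]
  expect_true(all(nullprof$flux == 0))

  f1 <- tempfile(); f2 <- tempfile()
  screenCollection(mods, toyFructan(), doseGrid = grid, file = f1)
  screenCollection(mods, toyFructan(), doseGrid = grid, file = f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  unlink(c(f1, f2))

  expect_error(screenCollection(mods, toyFructan(), doseGrid = numeric()),
               "non-empty")

  # unreadable path is flagged, screening continues
  sc2 <- screenCollection(c(tempfile(fileext = ".json")), toyFructan(),
                          doseGrid = c(0, 10))
  expect_false(sc2$ok)
  expect_true(is.na(sc2$utilizes))
})

test_that("growth-coupled screening mode also sees the fermentation products", {
  mods <- list(makeToyMicrobe(toyMicrobeProfile("fp")))
  sc <- screenCollection(mods, toyFructan(), doseGrid = c(0, 10),
                         mode = "growth")
  expect_true(sc$utilizes)
  # biomass maximization routes all fructan to growth, so secretion under
  # the growth objective stays at zero: the two modes answer different
  # questions and must both be available
  expect_equal(sc$max_lac, 0, tolerance = 1e-9)
  expect_identical(attr(sc, "mode"), "growth")
})

test_that("flux modes switch with dose in the cofactor-aware co-model", {
  cm <- makeToyComodel(cofactors = TRUE)
  fm <- extractFluxModes(cm, toyFructan(), c(0, 0.25, 1))
  expect_true(all(fm$present))
  at <- function(d, r) fm[fm$dose_grams == d & fm$reaction == r, ]
  # no prebiotic: no absorbed acids, all acid routes silent
  for (r in c("H_LDH", "H_PDH", "H_ADHL", "H_ACS"))
    expect_false(at(0, r)$active)
  # low dose: ATP surplus from glycolysis feeds the acyl-transfer route;
  # the NADH-generating decarboxylase stays off
  expect_true(at(0.25, "H_ADHL")$active)
  expect_false(at(0.25, "H_PDH")$active)
  expect_false(at(0.25, "H_OXP")$active)
  # high dose: ATP demand exceeds the glycolytic surplus, the
  # decarboxylase/oxidative-phosphorylation mode switches on
  expect_true(at(1, "H_PDH")$active)
  expect_true(at(1, "H_OXP")$active)
  expect_equal(at(1, "H_PDH")$flux, 1, tolerance = 1e-6)

  # activity tolerance larger than every flux marks everything inactive
  fml <- extractFluxModes(cm, toyFructan(), 1, tol = 1e6)
  expect_false(any(fml$active))

  # BT-like co-model never uses the lactate route
  cmb <- makeToyComodel(toyMicrobeProfile("bt"))
  fmb <- extractFluxModes(cmb, toyFructan(), c(0.5, 1, 2))
  expect_false(any(fmb$active[fmb$reaction == "H_LDH"]))

  # absent pathway ids are listed, not fatal
  fmx <- extractFluxModes(cm, toyFructan(), 1, pathway = c("H_PDH", "H_GHOST"))
  expect_identical(fmx$present, c(TRUE, FALSE))
  expect_true(is.na(fmx$flux[fmx$reaction == "H_GHOST"]))
})

test_that("subsystem flux-change fractions follow the counting formula", {
  # BT-like co-model at a fructan bound of 1: pyruvate and acetate routes
  # change, the lactate route does not -> 2/3 in the acetyl-CoA subsystem
  cm <- makeToyComodel(toyMicrobeProfile("bt"))
  rep <- subsystemFluxChange(cm, toyFructan(), 1)
  rownames(rep) <- rep$subsystem
  expect_true(all(rep$fraction >= 0 & rep$fraction <= 1))
  expect_true(all(rep$n_changed <= rep$n_total))
  expect_equal(rep["Acetyl-CoA synthesis", "fraction"], 2 / 3,
               tolerance = 1e-12)
  expect_identical(rep["Acetyl-CoA synthesis", "n_total"], 3L)
  expect_equal(rep["Glycolysis", "fraction"], 0)
  # every reaction of a fully recruited subsystem counts
  expect_equal(rep["Vitamin D metabolism", "fraction"], 1)

  # a microbe that cannot touch the prebiotic changes nothing
  cmn <- makeToyComodel(toyMicrobeProfile("null"))
  suppressWarnings(rep0 <- subsystemFluxChange(cmn, toyFructan(), 1))
  expect_true(all(rep0$fraction == 0))
  det <- attr(rep0, "reactions")
  expect_false(any(det$selected))

  expect_error(subsystemFluxChange(cm, toyFructan(), 0), "dose > 0")
})
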