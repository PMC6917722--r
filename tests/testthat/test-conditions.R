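# diet presets, gram-to-flux conversion, prebiotic constraints

test_that("doseToFlux follows the mass-fraction / molar-mass / horizon arithmetic", {
  gf2 <- prebioticSpec("GF2", data.frame(exchange_id = "EX_kestose",
                                         mass_fraction = 1,
                                         grams_per_mmol = 0.50444))
  expect_equal(unname(doseToFlux(gf2, 10)), 10 / 0.50444 / 24,
               tolerance = 1e-12)
  expect_equal(unname(doseToFlux(gf2, 10)), 0.8260, tolerance = 1e-4)
  expect_identical(unname(doseToFlux(gf2, 0)), 0)

  sc <- scfosSpec()
  b <- doseToFlux(sc, 3)
  expect_length(b, 3)
  expect_equal(unname(b), 1 / sc@components$grams_per_mmol / 24,
               tolerance = 1e-12)

  # linearity in the dose
  expect_equal(unname(doseToFlux(sc, 7)), 7 * unname(doseToFlux(sc, 1)),
               tolerance = 1e-12)

  # fluxScale and horizon enter multiplicatively
  scaled <- prebioticSpec("GF2", gf2@components, horizonHours = 12,
                          fluxScale = 0.5)
  expect_equal(unname(doseToFlux(scaled, 10)), 10 / 0.50444 / 12 * 0.5,
               tolerance = 1e-12)

  expect_error(prebioticSpec("bad", data.frame(exchange_id = "x",
                                               mass_fraction = 1,
                                               grams_per_mmol = 0)),
               "grams_per_mmol")
  expect_error(prebioticSpec("bad", data.frame(exchange_id = c("a", "b"),
                                               mass_fraction = c(0.6, 0.6),
                                               grams_per_mmol = 1)),
               "sum to 1")
})

test_that("built-in presets use consistent GF(n) molar masses", {
  expect_equal(scfosSpec()@components$grams_per_mmol,
               c(0.50444, 0.66658, 0.82872), tolerance = 1e-4)
  expect_equal(inulinSpec(dp = 2)@components$grams_per_mmol, 0.50444,
               tolerance = 1e-4)
})

test_that("applyDiet constrains listed exchanges, closes the rest, and is idempotent", {
  cm <- makeToyComodel()          # toy western diet already applied
  # starvation: empty diet closes every uptake, objective collapses to 0
  starved <- applyDiet(cm, dietSpec("empty", data.frame(
    id = character(), lower_bound = numeric(), upper_bound = numeric())))
  rx <- reactions(starved)
  expect_true(all(rx$lower_bound[rx$id %in% dietExchanges(starved)] == 0))
  expect_equal(objectiveValue(solveFBA(starved)), 0, tolerance = 1e-12)

  # the toy western preset restores the glucose-limited baseline of 2
  again <- applyDiet(starved, toyDiet())
  expect_equal(objectiveValue(solveFBA(again)), 2, tolerance = 1e-9)
  expect_identical(reactions(applyDiet(again, toyDiet())), reactions(again))

  expect_error(applyDiet(cm, dietSpec("typo", data.frame(
    id = "EX_glk_lu", lower_bound = -1, upper_bound = 0))),
    "not found.*nearest.*EX_glc_lu")
})

test_that("applyPrebiotic sets allow-up-to bounds and last write wins", {
  cm <- makeToyComodel()
  m1 <- applyPrebiotic(cm, toyFructan(), 1)
  rx <- reactions(m1)
  expect_equal(rx$lower_bound[rx$id == "EX_fructan_lu"], -1)
  expect_equal(rx$upper_bound[rx$id == "EX_fructan_lu"], 0)

  m0 <- applyPrebiotic(cm, toyFructan(), 0)
  rx <- reactions(m0)
  expect_equal(rx$lower_bound[rx$id == "EX_fructan_lu"], 0)
  expect_equal(objectiveValue(solveFBA(m0)), objectiveValue(solveFBA(cm)),
               tolerance = 1e-9)

  m2 <- applyPrebiotic(applyPrebiotic(cm, toyFructan(), 5), toyFructan(), 2)
  rx <- reactions(m2)
  expect_equal(rx$lower_bound[rx$id == "EX_fructan_lu"], -2)

  # an unknown component exchange is created in the lumen with a warning
  odd <- prebioticSpec("odd", data.frame(exchange_id = "EX_levan",
                                         mass_fraction = 1,
                                         grams_per_mmol = 1))
  expect_warning(m3 <- applyPrebiotic(cm, odd, 1), "creating lumen exchange")
  expect_true("EX_levan_lu" %in% reactions(m3)$id)
  expect_equal(objectiveValue(solveFBA(m3)), 2, tolerance = 1e-9)
})

test_that("objective is non-decreasing in the dose (allow-up-to semantics)", {
  for (prof in c("fp", "bt")) {
    cm <- makeToyComodel(toyMicrobeProfile(prof))
    vals <- vapply(seq(0, 10, by = 1), function(d)
      objectiveValue(solveFBA(applyPrebiotic(cm, toyFructan(), d))),
      numeric(1))
    expect_true(all(diff(vals) >= -1e-9))
  }
})

test_that("diet and prebiotic YAML presets round through their readers", {
  sc <- readPrebioticSpec(system.file("extdata", "prebiotic_scfos.yaml",
                                      package = "LumenFBA"))
  expect_identical(sc@name, "scFOS")
  expect_equal(sum(sc@components$mass_fraction), 1, tolerance = 1e-12)
  inu <- readPrebioticSpec(system.file("extdata", "prebiotic_inulin.yaml",
                                       package = "LumenFBA"))
  expect_equal(inu@components$grams_per_mmol,
               inulinSpec()@components$grams_per_mmol, tolerance = 1e-6)
  d <- readDietSpec(system.file("extdata", "diet_toy.yaml",
                                package = "LumenFBA"))
  expect_identical(d@bounds$id, "EX_glc_lu")
  expect_equal(d@bounds$lower_bound, -3)
})
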