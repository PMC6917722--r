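# LP engine: oracle equivalence, pFBA, knock-off, feasibility

test_that("simplex optimum equals brute-force vertex enumeration on all toy fixtures", {
  fixtures <- list(
    host = makeToyHost(),
    host_cofactor = makeToyHost(cofactors = TRUE),
    microbe_fp = setBounds(makeToyMicrobe(toyMicrobeProfile("fp")),
                           "EX_fructan", lower = -1),
    microbe_bt = setBounds(makeToyMicrobe(toyMicrobeProfile("bt")),
                           "EX_fructan", lower = -1),
    microbe_null = makeToyMicrobe(toyMicrobeProfile("null")))
  for (nm in names(fixtures)) {
    m <- fixtures[[nm]]
    sol <- solveFBA(m)
    ora <- vertexOracleModel(m)
    expect_identical(solverStatus(sol), "optimal")
    expect_lt(abs(objectiveValue(sol) - ora$objval), 1e-9)
  }
  # also under a non-default objective (secretion potential)
  fp <- fixtures$microbe_fp
  sol <- solveFBA(fp, objective = "EX_lac")
  expect_lt(abs(objectiveValue(sol) -
                vertexOracleModel(fp, "EX_lac")$objval), 1e-9)
  expect_equal(objectiveValue(sol), 4, tolerance = 1e-9)
  bt <- fixtures$microbe_bt
  expect_equal(objectiveValue(solveFBA(bt, objective = "EX_pyr")), 3,
               tolerance = 1e-9)
})

test_that("all-zero bounds force the zero flux vector", {
  m <- makeToyHost()
  m <- setBounds(m, reactions(m)$id, lower = 0, upper = 0)
  sol <- solveFBA(m)
  expect_identical(solverStatus(sol), "optimal")
  expect_equal(objectiveValue(sol), 0)
  expect_true(all(abs(fluxes(sol)) < 1e-12))
})

test_that("infeasible and unbounded problems are reported as such", {
  m <- makeToyHost()
  # forced uptake of a metabolite nothing consumes
  forced <- setBounds(m, "EX_d25", lower = -1, upper = -1)
  sol <- solveFBA(forced)
  expect_identical(solverStatus(sol), "infeasible")
  expect_length(fluxes(sol), 0)
  expect_false(checkFeasible(forced))
  expect_true(checkFeasible(m))
  expect_false(checkFeasible(m, list(EX_d25 = c(-1, -1))))

  # a reversible loop with an unbounded objective
  loop <- m
  loop@reactions$lower_bound[loop@reactions$id == "EX_lac"] <- -Inf
  loop@reactions$upper_bound[loop@reactions$id == "EX_lac"] <- Inf
  loop2 <- loop
  loop2@reactions$lower_bound[loop2@reactions$id == "EX_pyr"] <- -Inf
  loop2@reactions$upper_bound[loop2@reactions$id == "EX_pyr"] <- Inf
  loop2@reactions$upper_bound[loop2@reactions$id == "LDH"] <- Inf
  sol <- solveFBA(loop2, objective = "EX_pyr")
  expect_identical(solverStatus(sol), "unbounded")
})

test_that("microbe with forced minimum growth but no carbon is infeasible", {
  m <- makeToyMicrobe(toyMicrobeProfile("fp"))
  m <- setBounds(m, "EX_fructan", lower = 0)     # no carbon source
  expect_false(checkFeasible(m, list(BIOMASS_toy = c(0.01, 1000))))
  m2 <- setBounds(m, "EX_fructan", lower = -1)
  expect_true(checkFeasible(m2, list(BIOMASS_toy = c(0.01, 1000))))
})

test_that("pFBA picks the flux-minimal alternate optimum and keeps the objective", {
  # two parallel routes of equal stoichiometry but different length:
  # IN -> a; P1: a -> b; P2a: a -> x; P2b: x -> b; OUT: b -> (objective)
  comps <- data.frame(id = "c", name = "cytosol")
  mets <- data.frame(id = c("a[c]", "b[c]", "x[c]"), name = c("a", "b", "x"),
                     compartment = "c")
  rx <- data.frame(
    id = c("IN", "P1", "P2a", "P2b", "OUT"),
    name = c("IN", "P1", "P2a", "P2b", "OUT"),
    lower_bound = c(-2, 0, 0, 0, 0), upper_bound = c(0, 10, 10, 10, 10),
    subsystem = "", is_exchange = c(TRUE, FALSE, FALSE, FALSE, TRUE))
  st <- data.frame(
    reaction = c("IN", "P1", "P1", "P2a", "P2a", "P2b", "P2b", "OUT"),
    metabolite = c("a[c]", "a[c]", "b[c]", "a[c]", "x[c]", "x[c]", "b[c]",
                   "b[c]"),
    coefficient = c(-1, -1, 1, -1, 1, -1, 1, -1))
  m <- LumenFBA:::.buildModel("parallel", comps, mets, rx, st,
                              objective = c(OUT = 1))
  p <- solvePFBA(m)
  expect_identical(solverStatus(p), "optimal")
  expect_true(p@parsimonious)
  expect_equal(objectiveValue(p), 2, tolerance = 1e-8)
  # short route carries everything; the worst alternate vertex routes
  # through P2a/P2b and has a strictly larger total flux
  expect_equal(unname(fluxes(p)["P1"]), 2, tolerance = 1e-6)
  expect_lt(abs(fluxes(p)["P2a"]), 1e-6)
  worst <- 2 + 2 + 2 + 2 + 2       # |IN| + P2a + P2b + OUT + 0
  expect_lt(sum(abs(fluxes(p))), worst - 1e-6)
})

test_that("pFBA on a unique optimum reproduces the plain FBA vector", {
  # glucose-only host: the optimal flux vector is unique
  m <- setBounds(makeToyHost(), c("EX_lac", "EX_ac", "EX_pyr"), lower = 0)
  f <- solveFBA(m); p <- solvePFBA(m)
  expect_equal(objectiveValue(p), objectiveValue(f), tolerance = 1e-8)
  expect_equal(fluxes(p), fluxes(f), tolerance = 1e-6)
  # all-zero model gives the zero vector
  z <- setBounds(m, reactions(m)$id, lower = 0, upper = 0)
  expect_true(all(abs(fluxes(solvePFBA(z))) < 1e-9))
})

test_that("knock-off zeroes one reaction and never increases the objective", {
  cm <- applyPrebiotic(makeToyComodel(), toyFructan(), 1)
  base <- objectiveValue(solveFBA(cm))
  for (rid in c(microbeSecretion(cm), "H_LDH", "H_ACS", "M_FERM")) {
    ko <- knockOff(cm, rid)
    rx <- reactions(ko)
    expect_identical(rx$lower_bound[rx$id == rid], 0)
    expect_identical(rx$upper_bound[rx$id == rid], 0)
    sol <- solveFBA(ko)
    after <- if (solverStatus(sol) == "optimal") objectiveValue(sol) else 0
    expect_lte(after, base + 1e-9)
  }
  # knocking a reaction already at (0,0) changes nothing
  z <- setBounds(cm, "M_SEC_pyr", lower = 0, upper = 0)
  expect_equal(objectiveValue(solveFBA(knockOff(z, "M_SEC_pyr"))),
               objectiveValue(solveFBA(z)), tolerance = 1e-9)
  # knocking the objective reaction itself gives 0
  expect_equal(objectiveValue(solveFBA(knockOff(cm, "EX_d25_lu"))), 0,
               tolerance = 1e-12)
  expect_error(knockOff(cm, "nope"), "unknown reaction")
})

test_that("relaxation monotonicity: widening bounds never lowers a maximum", {
  cm <- applyPrebiotic(makeToyComodel(), toyFructan(), 0.5)
  base <- objectiveValue(solveFBA(cm))
  rx <- reactions(cm)
  set.seed(11)
  for (rid in sample(rx$id, 12)) {
    wider <- setBounds(cm, rid,
                       lower = rx$lower_bound[rx$id == rid] - 1,
                       upper = rx$upper_bound[rx$id == rid] + 1)
    expect_gte(objectiveValue(solveFBA(wider)), base - 1e-9)
    tighter <- setBounds(cm, rid, lower = 0,
                         upper = max(0, min(rx$upper_bound[rx$id == rid], 0.1)))
    sol <- solveFBA(tighter)
    after <- if (solverStatus(sol) == "optimal") objectiveValue(sol) else 0
    expect_lte(after, base + 1e-9)
  }
})

test_that("every optimal solution satisfies steady state within tolerance", {
  cases <- list(
    solveFBA(makeToyHost()),
    solvePFBA(makeToyHost(cofactors = TRUE)),
    solvePFBA(applyPrebiotic(makeToyComodel(), toyFructan(), 1)),
    solvePFBA(applyPrebiotic(makeToyComodel(toyMicrobeProfile("bt")),
                             toyFructan(), 2)))
  models <- list(makeToyHost(), makeToyHost(cofactors = TRUE),
                 applyPrebiotic(makeToyComodel(), toyFructan(), 1),
                 applyPrebiotic(makeToyComodel(toyMicrobeProfile("bt")),
                                toyFructan(), 2))
  for (k in seq_along(cases)) expectSteadyState(models[[k]], cases[[k]])
})

test_that("flux export writes a two-column TSV", {
  sol <- solveFBA(makeToyHost())
  f <- tempfile(fileext = ".tsv")
  exportFluxes(sol, f)
  tab <- utils::read.delim(f)
  expect_identical(names(tab), c("reaction_id", "flux"))
  expect_identical(nrow(tab), 12L)
  unlink(f)
})
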