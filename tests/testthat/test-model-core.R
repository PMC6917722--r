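# domain types, validation findings, format round-trips

toy_pair <- function() list(host = makeToyHost(),
                            microbe = makeToyMicrobe(toyMicrobeProfile("fp")))

test_that("validateModel reports findings instead of raising", {
  h <- makeToyHost()
  expect_identical(nrow(validateModel(h)), 0L)

  bad <- setBounds(h, "GLYC", lower = 5, upper = 1)
  f <- validateModel(bad)
  expect_identical(f$severity, "error")
  expect_identical(f$element, "GLYC")
  expect_match(f$message, "lower_bound")

  # exchange flagged but touching two metabolites
  two <- h
  two@reactions$is_exchange[two@reactions$id == "GLYC"] <- TRUE
  f <- validateModel(two)
  expect_identical(f$element, "GLYC")
  expect_match(f$message, "exactly one metabolite")

  # undeclared compartment
  stray <- h
  stray@metabolites$compartment[1] <- "nowhere"
  f <- validateModel(stray)
  expect_identical(f$severity, "error")
  expect_match(f$message, "compartment")
})

test_that("stoichiometric matrix assembly matches reaction definitions", {
  for (m in toy_pair()) {
    S <- stoichiometricMatrix(m)
    rx <- reactions(m)
    expect_identical(dim(S), c(nrow(metabolites(m)), nrow(rx)))
    expect_identical(colnames(S), rx$id)
    expect_true(all(Matrix::colSums(S != 0) >= 1))
    # exchange columns have exactly one nonzero
    expect_true(all(Matrix::colSums(S[, rx$is_exchange, drop = FALSE] != 0) == 1))
  }
  # spot-check a column against the written equation
  h <- makeToyHost()
  col <- stoichiometricMatrix(h)[, "HMGS"]
  expect_identical(col[col != 0],
                   c("accoa[c]" = -3, "dhc7[c]" = 1))
})

roundtrip_equal <- function(a, b) {
  expect_identical(reactions(b), reactions(a))
  expect_identical(metabolites(b)$id, metabolites(a)$id)
  expect_identical(metabolites(b)$compartment, metabolites(a)$compartment)
  expect_identical(sort(compartments(b)$id), sort(compartments(a)$id))
  expect_true(all(stoichiometricMatrix(b) == stoichiometricMatrix(a)))
  expect_equal(objectiveCoefficients(b), objectiveCoefficients(a))
}

test_that("read(write(m)) is the identity for both formats, with and without gz", {
  models <- list(makeToyHost(), makeToyMicrobe(toyMicrobeProfile("bt")),
                 makeToyComodel())
  for (m in models) {
    for (ext in c(".json", ".xml", ".json.gz", ".xml.gz")) {
      f <- tempfile(fileext = ext)
      writeModel(m, f)
      roundtrip_equal(m, readModel(f))
      unlink(f)
    }
  }
})

test_that("empty subsystem labels survive a round-trip", {
  h <- makeToyHost()
  h@reactions$subsystem[h@reactions$id == "LDH"] <- ""
  for (ext in c(".json", ".xml")) {
    f <- tempfile(fileext = ext)
    writeModel(h, f)
    b <- readModel(f)
    expect_identical(b@reactions$subsystem[b@reactions$id == "LDH"], "")
    unlink(f)
  }
})

test_that("co-model round-trips with its compartment set and structure", {
  cm <- makeToyComodel()
  f <- tempfile(fileext = ".json")
  writeModel(cm, f)
  back <- asCoMetabolismModel(readModel(f))
  roundtrip_equal(cm, back)
  expect_identical(sort(dietExchanges(back)), sort(dietExchanges(cm)))
  expect_identical(sort(microbeSecretion(back)), sort(microbeSecretion(cm)))
  expect_identical(biomassReaction(back), biomassReaction(cm))
  unlink(f)
})

test_that("bundled toy-host fixture loads with 12 reactions and the D3 objective", {
  f <- system.file("extdata", "toy_host.json", package = "LumenFBA")
  m <- readModel(f)
  expect_identical(nrow(reactions(m)), 12L)
  expect_equal(objectiveCoefficients(m), c(EX_d25 = 1))
  expect_identical(nrow(validateModel(m)), 0L)
  roundtrip_equal(makeToyHost(), m)
})

test_that("malformed SBML input raises a validation error naming the element", {
  f <- tempfile(fileext = ".xml")
  writeModel(makeToyHost(), f)
  txt <- readLines(f)
  # reference a species that is never declared
  txt <- sub('species="M_glc__91__e__93__" stoichiometry="1"',
             'species="M_ghost" stoichiometry="1"', txt)
  writeLines(txt, f)
  expect_error(readModel(f), "undeclared species.*M_ghost")
  unlink(f)
  expect_error(readModel(tempfile()), "not found")
})

test_that("format auto-detection falls back to content sniffing", {
  f <- tempfile(fileext = ".model")     # uninformative extension
  writeModel(makeToyHost(), f, format = "json")
  expect_identical(nrow(reactions(readModel(f))), 12L)
  unlink(f)
})

test_that("written models are readable by an independent COBRA implementation", {
  py <- Sys.which("python")
  expect_true(nzchar(py))
  fx <- tempfile(fileext = ".xml"); fj <- tempfile(fileext = ".json")
  writeModel(makeToyHost(), fx); writeModel(makeToyHost(), fj)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import cobra.io, sys",
    sprintf("m1 = cobra.io.read_sbml_model('%s')", fx),
    sprintf("m2 = cobra.io.load_json_model('%s')", fj),
    "r = m1.reactions.get_by_id('EX_glc')",
    "print(len(m1.reactions), len(m2.reactions), r.lower_bound,",
    "      m2.reactions.get_by_id('GLYC').subsystem)"), script)
  out <- system2(py, script, stdout = TRUE, stderr = FALSE)
  expect_identical(tail(strsplit(out[length(out)], " +")[[1]], 4),
                   c("12", "12", "-3.0", "Glycolysis"))
  unlink(c(fx, fj, script))
})
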