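# SBML Level 3 Version 1 with the FBC version 2 extension. Ids are escaped
# to valid SBML SIds the way the COBRA tools do it ("[" -> "__91__", with
# "M_"/"R_" prefixes), so files interoperate with cobrapy-written models.
# Subsystem labels are carried in reaction notes ("SUBSYSTEM: ..."), the
# legacy COBRA convention.

.SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
.FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

.sidEscape <- function(x, prefix = "") {
  vapply(x, function(id) {
    chars <- strsplit(id, "")[[1]]
    esc <- vapply(chars, function(ch) {
      if (grepl("[A-Za-z0-9_]", ch)) ch else sprintf("__%d__", utf8ToInt(ch))
    }, character(1))
    paste0(prefix, paste(esc, collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

.sidUnescape <- function(x, prefix = "") {
  out <- x
  if (nzchar(prefix)) {
    has <- startsWith(out, prefix)
    out[has] <- substring(out[has], nchar(prefix) + 1L)
  }
  vapply(out, function(id) {
    m <- gregexpr("__([0-9]+)__", id)[[1]]
    if (m[1] == -1) return(id)
    parts <- regmatches(id, gregexpr("__([0-9]+)__", id))[[1]]
    for (p in unique(parts)) {
      code <- as.integer(gsub("__", "", p, fixed = TRUE))
      id <- gsub(p, intToUtf8(code), id, fixed = TRUE)
    }
    id
  }, character(1), USE.NAMES = FALSE)
}

.xmlq <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

.num <- function(x) vapply(x, function(v) sprintf("%.17g", v), character(1))

.writeModelSBML <- function(model, path) {
  mets <- model@metabolites; rxns <- model@reactions
  S <- model@stoichiometry
  comp_sid <- .sidEscape(model@compartments$id)
  met_sid <- .sidEscape(mets$id, "M_")
  rxn_sid <- .sidEscape(rxns$id, "R_")
  met_comp <- .sidEscape(mets$compartment)

  # one shared parameter per distinct bound value
  vals <- sort(unique(c(rxns$lower_bound, rxns$upper_bound)))
  pid <- paste0("bnd_", .sidEscape(.num(vals)))
  names(pid) <- .num(vals)

  out <- character()
  p <- function(...) out[[length(out) + 1L]] <<- paste0(...)
  p('<?xml version="1.0" encoding="UTF-8"?>')
  p('<sbml xmlns="', .SBML_NS, '" xmlns:fbc="', .FBC_NS,
    '" level="3" version="1" fbc:required="false">')
  p('  <model id="', .sidEscape(model@id), '" fbc:strict="true">')
  p('    <listOfCompartments>')
  for (i in seq_len(nrow(model@compartments)))
    p('      <compartment id="', comp_sid[i], '" name="',
      .xmlq(model@compartments$name[i]), '" constant="true"/>')
  p('    </listOfCompartments>')
  p('    <listOfSpecies>')
  for (i in seq_len(nrow(mets))) {
    extra <- ""
    if (!is.na(mets$charge[i]))
      extra <- paste0(extra, ' fbc:charge="', mets$charge[i], '"')
    if (!is.na(mets$formula[i]))
      extra <- paste0(extra, ' fbc:chemicalFormula="', .xmlq(mets$formula[i]), '"')
    p('      <species id="', met_sid[i], '" name="', .xmlq(mets$name[i]),
      '" compartment="', met_comp[i],
      '" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"',
      extra, '/>')
  }
  p('    </listOfSpecies>')
  p('    <listOfParameters>')
  for (k in seq_along(vals))
    p('      <parameter id="', pid[k], '" value="', .num(vals[k]),
      '" constant="true"/>')
  p('    </listOfParameters>')
  p('    <listOfReactions>')
  for (j in seq_len(nrow(rxns))) {
    lbp <- pid[.num(rxns$lower_bound[j])]
    ubp <- pid[.num(rxns$upper_bound[j])]
    p('      <reaction id="', rxn_sid[j], '" name="', .xmlq(rxns$name[j]),
      '" reversible="', tolower(rxns$lower_bound[j] < 0), '" fast="false"',
      ' fbc:lowerFluxBound="', lbp, '" fbc:upperFluxBound="', ubp, '">')
    if (nzchar(rxns$subsystem[j])) {
      p('        <notes><body xmlns="http://www.w3.org/1999/xhtml">',
        '<p>SUBSYSTEM: ', .xmlq(rxns$subsystem[j]), '</p></body></notes>')
    }
    nz <- which(S[, j] != 0)
    coefs <- S[nz, j]
    neg <- nz[coefs < 0]; pos <- nz[coefs > 0]
    if (length(neg)) {
      p('        <listOfReactants>')
      for (i in seq_along(neg))
        p('          <speciesReference species="', met_sid[neg[i]],
          '" stoichiometry="', .num(-coefs[match(neg[i], nz)]),
          '" constant="true"/>')
      p('        </listOfReactants>')
    }
    if (length(pos)) {
      p('        <listOfProducts>')
      for (i in seq_along(pos))
        p('          <speciesReference species="', met_sid[pos[i]],
          '" stoichiometry="', .num(coefs[match(pos[i], nz)]),
          '" constant="true"/>')
      p('        </listOfProducts>')
    }
    p('      </reaction>')
  }
  p('    </listOfReactions>')
  if (length(model@objective)) {
    p('    <fbc:listOfObjectives fbc:activeObjective="obj">')
    p('      <fbc:objective fbc:id="obj" fbc:type="maximize">')
    p('        <fbc:listOfFluxObjectives>')
    for (k in seq_along(model@objective))
      p('          <fbc:fluxObjective fbc:reaction="',
        .sidEscape(names(model@objective)[k], "R_"),
        '" fbc:coefficient="', .num(unname(model@objective[k])), '"/>')
    p('        </fbc:listOfFluxObjectives>')
    p('      </fbc:objective>')
    p('    </fbc:listOfObjectives>')
  }
  p('  </model>')
  p('</sbml>')
  .writeTextMaybeGz(paste0(paste(out, collapse = "\n"), "\n"), path)
}

.xfind <- function(node, what)
  xml2::xml_find_all(node, paste0(".//*[local-name()='", what, "']"))

.readModelSBML <- function(path) {
  txt <- .readTextMaybeGz(path)
  doc <- tryCatch(xml2::read_xml(txt),
                  error = function(e)
                    stop("SBML parse failure in '", path, "': ",
                         conditionMessage(e)))
  mdl <- .xfind(doc, "model")
  if (!length(mdl)) stop("no <model> element in '", path, "'")
  mdl <- mdl[[1]]
  attr1 <- function(nodes, a) xml2::xml_attr(nodes, a)

  cn <- .xfind(mdl, "compartment")
  compartments <- data.frame(
    id = .sidUnescape(attr1(cn, "id")),
    name = ifelse(is.na(attr1(cn, "name")), .sidUnescape(attr1(cn, "id")),
                  attr1(cn, "name")),
    stringsAsFactors = FALSE)

  sn <- .xfind(mdl, "species")
  sp_sid <- attr1(sn, "id")
  mets <- data.frame(
    id = .sidUnescape(sp_sid, "M_"),
    name = ifelse(is.na(attr1(sn, "name")), "", attr1(sn, "name")),
    compartment = .sidUnescape(attr1(sn, "compartment")),
    formula = attr1(sn, "chemicalFormula"),
    charge = suppressWarnings(as.integer(attr1(sn, "charge"))),
    stringsAsFactors = FALSE)
  # fbc-namespaced attributes: xml_attr() matches the local name above only
  # when unprefixed attrs are absent; fall back to the qualified lookup
  if (all(is.na(mets$formula)))
    mets$formula <- attr1(sn, "fbc:chemicalFormula")
  if (all(is.na(mets$charge)))
    mets$charge <- suppressWarnings(as.integer(attr1(sn, "fbc:charge")))

  pn <- .xfind(mdl, "parameter")
  pvals <- as.numeric(attr1(pn, "value"))
  names(pvals) <- attr1(pn, "id")

  rn <- .xfind(mdl, "reaction")
  rxn_sid <- attr1(rn, "id")
  get_bound <- function(node, which, fallback) {
    ref <- xml2::xml_attr(node, which)
    if (is.na(ref)) ref <- xml2::xml_attr(node, paste0("fbc:", which))
    if (!is.na(ref) && ref %in% names(pvals)) unname(pvals[ref]) else fallback
  }
  rlist <- lapply(seq_along(rn), function(j) {
    node <- rn[[j]]
    rev <- identical(xml2::xml_attr(node, "reversible"), "true")
    lb <- get_bound(node, "lowerFluxBound", if (rev) -1000 else 0)
    ub <- get_bound(node, "upperFluxBound", 1000)
    sub <- ""
    notes <- .xfind(node, "p")
    for (nt in notes) {
      tx <- xml2::xml_text(nt)
      mm <- regmatches(tx, regexec("^\\s*SUBSYSTEM:\\s*(.*)$", tx))[[1]]
      if (length(mm) == 2) sub <- trimws(mm[2])
    }
    reac <- .xfind(node, "listOfReactants")
    prod <- .xfind(node, "listOfProducts")
    side <- function(ln, sign) {
      if (!length(ln)) return(NULL)
      refs <- .xfind(ln[[1]], "speciesReference")
      if (!length(refs)) return(NULL)
      data.frame(species = attr1(refs, "species"),
                 coefficient = sign * as.numeric(attr1(refs, "stoichiometry")),
                 stringsAsFactors = FALSE)
    }
    st <- rbind(side(reac, -1), side(prod, 1))
    nm <- xml2::xml_attr(node, "name")
    list(id = .sidUnescape(rxn_sid[j], "R_"),
         name = if (is.na(nm)) "" else nm,
         lower_bound = lb, upper_bound = ub, subsystem = sub, stoich = st)
  })
  rxns <- do.call(rbind, lapply(rlist, function(r) data.frame(
    id = r$id, name = r$name, lower_bound = r$lower_bound,
    upper_bound = r$upper_bound, subsystem = r$subsystem,
    stringsAsFactors = FALSE)))
  stoich <- do.call(rbind, lapply(rlist, function(r) {
    if (is.null(r$stoich)) return(NULL)
    bad <- setdiff(r$stoich$species, sp_sid)
    if (length(bad))
      stop("reaction '", r$id, "' in '", path,
           "' references undeclared species: ", paste(bad, collapse = ", "))
    data.frame(reaction = r$id,
               metabolite = .sidUnescape(r$stoich$species, "M_"),
               coefficient = r$stoich$coefficient, stringsAsFactors = FALSE)
  }))

  obj <- numeric(0)
  fo <- .xfind(mdl, "fluxObjective")
  if (length(fo)) {
    orx <- attr1(fo, "reaction")
    if (all(is.na(orx))) orx <- attr1(fo, "fbc:reaction")
    oco <- suppressWarnings(as.numeric(attr1(fo, "coefficient")))
    if (all(is.na(oco))) oco <- as.numeric(attr1(fo, "fbc:coefficient"))
    obj <- oco
    names(obj) <- .sidUnescape(orx, "R_")
  }
  mid <- xml2::xml_attr(mdl, "id")
  model <- .buildModel(id = if (is.na(mid)) "model" else .sidUnescape(mid),
                       compartments = compartments, metabolites = mets,
                       reactions = rxns, stoich = stoich, objective = obj)
  .assertValid(model)
}
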