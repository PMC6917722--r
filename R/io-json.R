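# COBRA JSON dialect (schema used by the COBRA ecosystem, version 1).

.readTextMaybeGz <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  rawToChar(readBin(con, "raw", n = 64L * 1024L^2))
}

.writeTextMaybeGz <- function(txt, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(txt), con)
  invisible(path)
}

.readModelJSON <- function(path) {
  txt <- .readTextMaybeGz(path)
  doc <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                  error = function(e)
                    stop("JSON parse failure in '", path, "': ",
                         conditionMessage(e)))
  comp <- doc$compartments
  compartments <- data.frame(
    id = as.character(names(comp)),
    name = vapply(comp, function(x) as.character(x)[1], character(1)),
    stringsAsFactors = FALSE)
  g <- function(x, field, default) {
    v <- x[[field]]
    if (is.null(v) || length(v) == 0) default else v
  }
  mets <- do.call(rbind, lapply(doc$metabolites, function(m) data.frame(
    id = g(m, "id", stop("metabolite without id in '", path, "'")),
    name = as.character(g(m, "name", "")),
    compartment = as.character(g(m, "compartment", NA_character_)),
    formula = as.character(g(m, "formula", NA_character_)),
    charge = as.integer(g(m, "charge", NA_integer_)),
    stringsAsFactors = FALSE)))
  rxns <- do.call(rbind, lapply(doc$reactions, function(r) data.frame(
    id = g(r, "id", stop("reaction without id in '", path, "'")),
    name = as.character(g(r, "name", "")),
    lower_bound = as.numeric(g(r, "lower_bound", -1000)),
    upper_bound = as.numeric(g(r, "upper_bound", 1000)),
    subsystem = as.character(g(r, "subsystem", "")),
    stringsAsFactors = FALSE)))
  stoich <- do.call(rbind, lapply(doc$reactions, function(r) {
    sm <- r$metabolites
    if (is.null(sm) || !length(sm)) return(NULL)
    data.frame(reaction = r$id, metabolite = names(sm),
               coefficient = as.numeric(unlist(sm)),
               stringsAsFactors = FALSE)
  }))
  obj <- vapply(doc$reactions,
                function(r) as.numeric(g(r, "objective_coefficient", 0)),
                numeric(1))
  names(obj) <- rxns$id
  obj <- obj[obj != 0]
  ann <- list()
  if (!is.null(doc$annotation)) ann <- doc$annotation
  if (!is.null(doc$notes)) ann$notes <- doc$notes
  model <- .buildModel(id = if (is.null(doc$id)) "model" else doc$id,
                       compartments = compartments, metabolites = mets,
                       reactions = rxns, stoich = stoich, objective = obj,
                       annotation = ann)
  .assertValid(model)
}

.writeModelJSON <- function(model, path) {
  S <- model@stoichiometry
  mets <- model@metabolites
  rxns <- model@reactions
  met_list <- lapply(seq_len(nrow(mets)), function(i) {
    m <- list(id = mets$id[i], name = mets$name[i],
              compartment = mets$compartment[i])
    if (!is.na(mets$formula[i])) m$formula <- mets$formula[i]
    if (!is.na(mets$charge[i])) m$charge <- mets$charge[i]
    m
  })
  rxn_list <- lapply(seq_len(nrow(rxns)), function(j) {
    nz <- which(S[, j] != 0)
    coefs <- as.list(S[nz, j])
    names(coefs) <- rownames(S)[nz]
    list(id = rxns$id[j], name = rxns$name[j], metabolites = coefs,
         lower_bound = rxns$lower_bound[j], upper_bound = rxns$upper_bound[j],
         gene_reaction_rule = "", subsystem = rxns$subsystem[j],
         objective_coefficient =
           if (rxns$id[j] %in% names(model@objective))
             unname(model@objective[rxns$id[j]]) else 0)
  })
  comp <- as.list(model@compartments$name)
  names(comp) <- model@compartments$id
  doc <- list(id = model@id, version = "1", compartments = comp,
              metabolites = met_list, reactions = rxn_list, genes = list())
  if (length(model@annotation)) doc$annotation <- model@annotation
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .writeTextMaybeGz(paste0(txt, "\n"), path)
}
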