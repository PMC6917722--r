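#' @include AllClasses.R
NULL

# assemble a MetabolicModel from tables plus a long stoichiometry table
# stoich: data.frame(reaction, metabolite, coefficient)
.buildModel <- function(id, compartments, metabolites, reactions, stoich,
                        objective = numeric(0), annotation = list(),
                        class = "MetabolicModel", ...) {
  metabolites$id <- as.character(metabolites$id)
  reactions$id <- as.character(reactions$id)
  if (!"formula" %in% names(metabolites)) metabolites$formula <- NA_character_
  if (!"charge" %in% names(metabolites)) metabolites$charge <- NA_integer_
  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  if (!"name" %in% names(reactions)) reactions$name <- reactions$id
  if (!"subsystem" %in% names(reactions)) reactions$subsystem <- ""
  reactions$subsystem[is.na(reactions$subsystem)] <- ""
  rownames(metabolites) <- NULL; rownames(reactions) <- NULL
  i <- match(stoich$metabolite, metabolites$id)
  j <- match(stoich$reaction, reactions$id)
  if (anyNA(i))
    stop("stoichiometry references unknown metabolite(s): ",
         paste(unique(stoich$metabolite[is.na(i)]), collapse = ", "))
  if (anyNA(j))
    stop("stoichiometry references unknown reaction(s): ",
         paste(unique(stoich$reaction[is.na(j)]), collapse = ", "))
  S <- Matrix::sparseMatrix(i = i, j = j, x = stoich$coefficient,
                            dims = c(nrow(metabolites), nrow(reactions)),
                            dimnames = list(metabolites$id, reactions$id))
  if (!"is_exchange" %in% names(reactions))
    reactions$is_exchange <- .detectExchange(reactions$id, S)
  reactions <- reactions[, c("id", "name", "lower_bound", "upper_bound",
                             "subsystem", "is_exchange")]
  metabolites <- metabolites[, c("id", "name", "compartment", "formula", "charge")]
  new(class, id = as.character(id), compartments = compartments,
      metabolites = metabolites, reactions = reactions, stoichiometry = S,
      objective = objective, annotation = annotation, ...)
}

# exchange detection: single-metabolite columns OR a configurable id prefix;
# the prefix convention wins on conflict (VMH files rely on it).
.detectExchange <- function(ids, S, prefix = "EX_") {
  single <- Matrix::colSums(S != 0) == 1
  by_prefix <- startsWith(ids, prefix)
  ifelse(by_prefix, TRUE, single)
}

# compact reaction-equation builder used by the toy generators and tests:
# .rxn("GLYC", "glc[e] -> 2 accoa[c]", lb, ub, subsystem)
.parseEquation <- function(eq) {
  sides <- strsplit(eq, "->", fixed = TRUE)[[1]]
  if (length(sides) > 2) stop("bad equation: ", eq)
  parse_side <- function(s, sign) {
    s <- trimws(s)
    if (s == "") return(NULL)
    terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    out <- lapply(terms, function(tm) {
      parts <- strsplit(tm, " ", fixed = TRUE)[[1]]
      parts <- parts[nzchar(parts)]
      if (length(parts) == 2)
        data.frame(metabolite = parts[2],
                   coefficient = sign * as.numeric(parts[1]))
      else data.frame(metabolite = parts[1], coefficient = sign)
    })
    do.call(rbind, out)
  }
  rbind(parse_side(sides[1], -1),
        if (length(sides) == 2) parse_side(sides[2], 1))
}

#' Validate a metabolic model
#'
#' Checks the semantic invariants of a [MetabolicModel-class] and returns a
#' findings table instead of raising conditions: duplicated metabolite or
#' reaction ids, metabolites assigned to undeclared compartments, reactions
#' with `lower_bound > upper_bound` or with empty stoichiometry, exchange
#' reactions touching more than one metabolite, and objective coefficients
#' on unknown reactions. An empty table means the model is valid.
#'
#' @param model a [MetabolicModel-class].
#' @return data.frame with columns `severity` (`"error"`/`"warning"`),
#'   `element` (the offending id) and `message`; zero rows when valid.
#' @examples
#' validateModel(makeToyHost())   # zero findings
#' @export
validateModel <- function(model) {
  stopifnot(is(model, "MetabolicModel"))
  f <- list()
  add <- function(severity, element, message)
    f[[length(f) + 1L]] <<- data.frame(severity = severity, element = element,
                                       message = message)
  mets <- model@metabolites; rxns <- model@reactions
  S <- model@stoichiometry
  dup <- unique(mets$id[duplicated(mets$id)])
  for (d in dup) add("error", d, "duplicated metabolite id")
  dup <- unique(rxns$id[duplicated(rxns$id)])
  for (d in dup) add("error", d, "duplicated reaction id")
  bad <- mets$id[!(mets$compartment %in% model@compartments$id)]
  for (d in bad) add("error", d, "metabolite compartment not declared in model")
  bad <- rxns$id[rxns$lower_bound > rxns$upper_bound]
  for (d in bad) add("error", d, "lower_bound exceeds upper_bound")
  nnz <- Matrix::colSums(S != 0)
  for (d in rxns$id[nnz == 0]) add("error", d, "reaction has empty stoichiometry")
  bad <- rxns$id[rxns$is_exchange & nnz != 1]
  for (d in bad)
    add("error", d, "exchange reaction must involve exactly one metabolite")
  bad <- setdiff(names(model@objective), rxns$id)
  for (d in bad) add("error", d, "objective coefficient on unknown reaction")
  if (length(f)) do.call(rbind, f)
  else data.frame(severity = character(), element = character(),
                  message = character(), stringsAsFactors = FALSE)
}

.assertValid <- function(model) {
  rep <- validateModel(model)
  err <- rep[rep$severity == "error", , drop = FALSE]
  if (nrow(err))
    stop("invalid model '", model@id, "': ",
         paste(paste0(err$element, ": ", err$message), collapse = "; "))
  invisible(model)
}

#' Set flux bounds on reactions
#'
#' Returns a copy of the model with the bounds of the named reactions
#' replaced. `lower` and `upper` are recycled to the number of ids; `NA`
#' leaves the existing bound in place.
#'
#' @param model a [MetabolicModel-class].
#' @param ids character vector of reaction ids.
#' @param lower,upper numeric replacement bounds (flux units).
#' @return the modified model.
#' @examples
#' m <- setBounds(makeToyHost(), "EX_glc", lower = -1)
#' @export
setBounds <- function(model, ids, lower = NA_real_, upper = NA_real_) {
  idx <- match(ids, model@reactions$id)
  if (anyNA(idx))
    stop("unknown reaction id(s): ", paste(ids[is.na(idx)], collapse = ", "))
  lower <- rep_len(as.numeric(lower), length(idx))
  upper <- rep_len(as.numeric(upper), length(idx))
  sel <- !is.na(lower)
  model@reactions$lower_bound[idx[sel]] <- lower[sel]
  sel <- !is.na(upper)
  model@reactions$upper_bound[idx[sel]] <- upper[sel]
  model
}

#' Find the exchange reaction of a metabolite
#'
#' Resolves a metabolite (by full id or by base name, i.e. the id with any
#' trailing compartment tag such as `[e]` or `_e` removed) to the exchange
#' reaction(s) that move it across the model boundary.
#'
#' @param model a [MetabolicModel-class].
#' @param metabolite metabolite id or base name.
#' @return character vector of exchange reaction ids (possibly empty).
#' @examples
#' findExchange(makeToyHost(), "glc")
#' @export
findExchange <- function(model, metabolite) {
  rxns <- model@reactions
  S <- model@stoichiometry
  ex <- which(rxns$is_exchange)
  if (!length(ex)) return(character())
  hits <- vapply(ex, function(j) {
    ms <- rownames(S)[which(S[, j] != 0)]
    any(ms == metabolite | .baseMetName(ms, model) == metabolite)
  }, logical(1))
  rxns$id[ex[hits]]
}

# strip the compartment tag from metabolite ids: "glc[e]" / "glc_e" -> "glc"
.baseMetName <- function(ids, model) {
  comp <- model@metabolites$compartment[match(ids, model@metabolites$id)]
  out <- ids
  for (k in seq_along(ids)) {
    if (is.na(comp[k])) next
    suf1 <- paste0("[", comp[k], "]")
    suf2 <- paste0("_", comp[k])
    if (endsWith(ids[k], suf1))
      out[k] <- substr(ids[k], 1, nchar(ids[k]) - nchar(suf1))
    else if (endsWith(ids[k], suf2))
      out[k] <- substr(ids[k], 1, nchar(ids[k]) - nchar(suf2))
  }
  out
}

# single metabolite id of an exchange column
.exchangeMet <- function(model, rid) {
  j <- match(rid, model@reactions$id)
  rownames(model@stoichiometry)[which(model@stoichiometry[, j] != 0)]
}
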