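#' @include model-build.R fba.R
NULL

#' Merge a host and a microbe model through a shared lumen compartment
#'
#' Builds a [CoMetabolismModel-class]: both networks are namespaced with id
#' prefixes, their extracellular boundary metabolites (per `join_policy`)
#' become shared lumen species, each organism's former exchange reaction on
#' a shared metabolite is rewritten as directed organism-lumen transport(s)
#' that preserve the original bound magnitudes (a reversible exchange
#' yields one uptake and one secretion transport, so the four transport
#' sets stay disjoint), and every lumen metabolite gets a single boundary
#' exchange through which diet enters (negative flux) and surplus leaves
#' (positive flux). Boundary reactions on non-shared metabolites are kept
#' as organism-level exchanges. The merged objective is the host objective;
#' when a host objective reaction was itself rewritten, its coefficient is
#' transferred to the corresponding lumen boundary exchange (so "secretion
#' maximization" remains a boundary flux).
#'
#' @param host,microbe valid [MetabolicModel-class] objects.
#' @param hostPrefix,microbePrefix id namespacing prefixes (default `"H_"`,
#'   `"M_"`).
#' @param lumenId compartment id for the new lumen (default `"lu"`).
#' @param join_policy either the character method `"extracellular"` (share
#'   all boundary metabolites whose compartment is in `extracellular`) or a
#'   character vector of metabolite base names to share.
#' @param extracellular compartment id(s) treated as extracellular
#'   (default `"e"`).
#' @param biomassPattern regular expression used to locate the microbe
#'   biomass reaction (case-insensitive match on reaction id or name); no
#'   match raises a warning and leaves the slot `NA`.
#' @return a validated [CoMetabolismModel-class].
#' @examples
#' cm <- mergeComodel(makeToyHost(), makeToyMicrobe(toyMicrobeProfile("fp")))
#' dietExchanges(cm)
#' @seealso [capMicrobeSecretion()], [applyDiet()], [applyPrebiotic()]
#' @export
mergeComodel <- function(host, microbe, hostPrefix = "H_",
                         microbePrefix = "M_", lumenId = "lu",
                         join_policy = "extracellular",
                         extracellular = "e",
                         biomassPattern = "biomass") {
  .assertValid(host); .assertValid(microbe)
  if (identical(hostPrefix, microbePrefix))
    stop("host and microbe prefixes must differ")

  share_policy <- function(model) {
    ex <- model@reactions$id[model@reactions$is_exchange]
    met <- vapply(ex, function(r) .exchangeMet(model, r)[1], character(1))
    comp <- model@metabolites$compartment[match(met, model@metabolites$id)]
    base <- .baseMetName(met, model)
    shared <- if (identical(join_policy, "extracellular"))
      comp %in% extracellular else base %in% join_policy
    data.frame(rxn = ex, met = met, base = base, shared = shared,
               stringsAsFactors = FALSE)
  }
  hshare <- share_policy(host)
  mshare <- share_policy(microbe)

  prefixed <- function(model, prefix) {
    mets <- model@metabolites
    rxns <- model@reactions
    mets$id <- paste0(prefix, mets$id)
    mets$compartment <- paste0(prefix, mets$compartment)
    rxns$id <- paste0(prefix, rxns$id)
    comp <- model@compartments
    comp$id <- paste0(prefix, comp$id)
    S <- model@stoichiometry
    dimnames(S) <- list(mets$id, rxns$id)
    list(mets = mets, rxns = rxns, comp = comp, S = S)
  }
  H <- prefixed(host, hostPrefix)
  M <- prefixed(microbe, microbePrefix)
  if (length(intersect(H$rxns$id, M$rxns$id)))
    stop("reaction id collision after prefixing")
  if (length(intersect(H$mets$id, M$mets$id)))
    stop("metabolite id collision after prefixing")

  lumen_met <- function(base) paste0(base, "[", lumenId, "]")
  lumen_ex <- function(base) paste0("EX_", base, "_", lumenId)

  # accumulate long-format pieces
  stoich <- list(); add_st <- function(df) stoich[[length(stoich) + 1L]] <<- df
  long_of <- function(S) {
    tri <- methods::as(methods::as(S, "generalMatrix"), "TsparseMatrix")
    keep <- tri@x != 0
    data.frame(reaction = colnames(S)[tri@j[keep] + 1L],
               metabolite = rownames(S)[tri@i[keep] + 1L],
               coefficient = tri@x[keep], stringsAsFactors = FALSE)
  }
  new_rxns <- list(); add_rxn <- function(df) new_rxns[[length(new_rxns) + 1L]] <<- df
  sets <- list(host_up = character(), host_sec = character(),
               microbe_up = character(), microbe_sec = character())

  drop_rxn <- character(); lumen_bases <- character()
  rewrite <- function(part, share, prefix, org) {
    for (k in which(share$shared)) {
      rid <- paste0(prefix, share$rxn[k])
      met_org <- paste0(prefix, share$met[k])
      base <- share$base[k]
      j <- match(rid, part$rxns$id)
      lb <- part$rxns$lower_bound[j]; ub <- part$rxns$upper_bound[j]
      # original exchange convention: coefficient of the metabolite is
      # negative, so positive flux secretes; preserve that orientation
      coef <- part$S[met_org, rid]
      if (coef > 0) { tmp <- lb; lb <- -ub; ub <- -tmp }
      drop_rxn <<- c(drop_rxn, rid)
      lumen_bases <<- unique(c(lumen_bases, base))
      if (ub > 0) {
        sid <- paste0(prefix, "SEC_", base)
        add_rxn(data.frame(id = sid, name = paste(org, "secretion of", base),
                           lower_bound = 0, upper_bound = ub,
                           subsystem = "Lumen transport", is_exchange = FALSE))
        add_st(data.frame(reaction = sid,
                          metabolite = c(met_org, lumen_met(base)),
                          coefficient = c(-1, 1)))
        sets[[paste0(org, "_sec")]] <<- c(sets[[paste0(org, "_sec")]], sid)
      }
      if (lb < 0) {
        uid <- paste0(prefix, "UP_", base)
        add_rxn(data.frame(id = uid, name = paste(org, "uptake of", base),
                           lower_bound = 0, upper_bound = -lb,
                           subsystem = "Lumen transport", is_exchange = FALSE))
        add_st(data.frame(reaction = uid,
                          metabolite = c(lumen_met(base), met_org),
                          coefficient = c(-1, 1)))
        sets[[paste0(org, "_up")]] <<- c(sets[[paste0(org, "_up")]], uid)
      }
    }
  }
  rewrite(H, hshare, hostPrefix, "host")
  rewrite(M, mshare, microbePrefix, "microbe")

  diet_ids <- character()
  for (base in sort(lumen_bases)) {
    did <- lumen_ex(base)
    add_rxn(data.frame(id = did, name = paste("lumen exchange of", base),
                       lower_bound = 0, upper_bound = 1000,
                       subsystem = "Lumen exchange", is_exchange = TRUE))
    add_st(data.frame(reaction = did, metabolite = lumen_met(base),
                      coefficient = -1))
    diet_ids <- c(diet_ids, did)
  }

  keep_h <- !(H$rxns$id %in% drop_rxn)
  keep_m <- !(M$rxns$id %in% drop_rxn)
  rxns <- rbind(H$rxns[keep_h, ], M$rxns[keep_m, ], do.call(rbind, new_rxns))
  lum_mets <- data.frame(id = lumen_met(sort(lumen_bases)),
                         name = sort(lumen_bases),
                         compartment = lumenId,
                         formula = NA_character_, charge = NA_integer_,
                         stringsAsFactors = FALSE)
  mets <- rbind(H$mets, M$mets, lum_mets)
  comp <- rbind(H$comp, M$comp,
                data.frame(id = lumenId, name = "shared gut lumen"))
  st <- rbind(long_of(H$S[, keep_h, drop = FALSE]),
              long_of(M$S[, keep_m, drop = FALSE]),
              do.call(rbind, stoich))

  # host objective, remapped onto lumen exchanges where rewritten
  objective <- numeric(0)
  if (length(host@objective)) {
    onames <- paste0(hostPrefix, names(host@objective))
    remap <- match(onames, paste0(hostPrefix, hshare$rxn))
    onames <- ifelse(!is.na(remap) & hshare$shared[remap],
                     lumen_ex(hshare$base[remap]), onames)
    objective <- unname(host@objective); names(objective) <- onames
  }

  # locate microbe biomass reaction
  mr <- M$rxns[keep_m, ]
  hit <- grepl(biomassPattern, mr$id, ignore.case = TRUE) |
    grepl(biomassPattern, mr$name, ignore.case = TRUE)
  biomass <- if (any(hit)) mr$id[which(hit)[1]] else {
    warning("no microbe reaction matches biomass pattern '",
            biomassPattern, "'")
    NA_character_
  }

  provenance <- list(host_id = host@id, microbe_id = microbe@id,
                     host_prefix = hostPrefix, microbe_prefix = microbePrefix,
                     rewritten_exchanges = drop_rxn)
  # structure annotation survives a JSON round-trip; asCoMetabolismModel()
  # rebuilds the S4 class from it
  structure_ann <- list(host_prefix = hostPrefix,
                        microbe_prefix = microbePrefix,
                        lumen_compartment = lumenId,
                        diet_exchanges = diet_ids,
                        host_uptake = sets$host_up,
                        host_secretion = sets$host_sec,
                        microbe_uptake = sets$microbe_up,
                        microbe_secretion = sets$microbe_sec,
                        biomass_reaction = biomass)
  cm <- .buildModel(id = paste0(host@id, "__", microbe@id),
                    compartments = comp, metabolites = mets,
                    reactions = rxns, stoich = st, objective = objective,
                    annotation = c(host@annotation,
                                   list(merge_provenance = provenance,
                                        comodel_structure = structure_ann)),
                    class = "CoMetabolismModel",
                    hostPrefix = hostPrefix, microbePrefix = microbePrefix,
                    lumenCompartment = lumenId, dietExchanges = diet_ids,
                    hostUptake = sets$host_up, hostSecretion = sets$host_sec,
                    microbeUptake = sets$microbe_up,
                    microbeSecretion = sets$microbe_sec,
                    biomassReaction = biomass)
  .assertValid(cm)
}

#' Cap microbe secretion into the lumen
#'
#' Restricts the upper bound of every microbe-to-lumen secretion transport
#' to `min(current, cap)`. This is the control condition in which the
#' microbe's metabolic outputs are limited while the system stays viable:
#' with the cap at 0, any prebiotic-driven gain of the host objective
#' disappears and the dose response is flat.
#'
#' With `policy = "viability"` the cap is the smallest value on `grid`
#' that keeps the microbe biomass LP feasible at `minGrowth`.
#'
#' @param comodel a [CoMetabolismModel-class].
#' @param cap non-negative flux cap (`Inf` leaves the model unchanged).
#' @param policy `"fixed"` (use `cap` as given) or `"viability"`.
#' @param minGrowth minimum microbe biomass flux enforced as a lower bound
#'   when positive (default 0; growth coupling is optional).
#' @param grid candidate caps tried in increasing order under
#'   `policy = "viability"`.
#' @return the capped [CoMetabolismModel-class].
#' @examples
#' cm <- capMicrobeSecretion(makeToyComodel(), cap = 0)
#' @export
capMicrobeSecretion <- function(comodel, cap = 0,
                                policy = c("fixed", "viability"),
                                minGrowth = 0,
                                grid = c(0, 10^seq(-3, 3))) {
  policy <- match.arg(policy)
  stopifnot(is(comodel, "CoMetabolismModel"), cap >= 0)
  apply_cap <- function(m, value) {
    ids <- m@microbeSecretion
    if (!length(ids) || !is.finite(value)) return(m)
    j <- match(ids, m@reactions$id)
    m@reactions$upper_bound[j] <- pmin(m@reactions$upper_bound[j], value)
    m
  }
  growth_bounds <- function() {
    if (minGrowth <= 0) return(NULL)
    if (is.na(comodel@biomassReaction))
      stop("minGrowth > 0 requires an identified biomass reaction")
    b <- list(c(minGrowth,
                comodel@reactions$upper_bound[
                  match(comodel@biomassReaction, comodel@reactions$id)]))
    names(b) <- comodel@biomassReaction
    b
  }
  if (policy == "viability") {
    for (g in sort(grid)) {
      m <- apply_cap(comodel, g)
      if (checkFeasible(m, growth_bounds())) return(m)
    }
    stop("no cap on the grid keeps the co-model viable at minimum growth ",
         minGrowth, "; binding constraints: ",
         paste(comodel@microbeSecretion, collapse = ", "))
  }
  m <- apply_cap(comodel, cap)
  if (!checkFeasible(m, growth_bounds()))
    stop("capping microbe secretion at ", cap,
         " makes the co-model infeasible at minimum growth ", minGrowth,
         "; binding constraints: ",
         paste(comodel@microbeSecretion, collapse = ", "))
  m
}
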