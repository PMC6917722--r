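#' @include conditions.R
NULL

.writeTSV <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Dose-response of the host objective to prebiotic supplementation
#'
#' For each dose: apply the prebiotic, optionally cap microbe secretion
#' (the control condition), solve parsimonious FBA and record the
#' objective plus any tracked reaction fluxes. Under the allow-up-to dose
#' semantics the objective is non-decreasing in the dose and saturates
#' once a downstream capacity becomes binding. Infeasible dose points are
#' recorded with their status and skipped, not fatal.
#'
#' @param comodel a [CoMetabolismModel-class].
#' @param prebiotic a [PrebioticSpec-class].
#' @param doses strictly increasing non-negative doses (g).
#' @param objective forwarded to [solvePFBA()] (default: model objective).
#' @param trackedReactions reaction ids whose fluxes are recorded per dose
#'   (e.g. the 7-DHC synthesis step and the 25-OH-D3 secretion exchange).
#' @param control logical; cap microbe secretion at `cap` first.
#' @param cap control cap (default 0).
#' @return data.frame with columns `dose_grams`, `status`, `objective` and
#'   one column per tracked reaction.
#' @examples
#' runDoseResponse(makeToyComodel(), toyFructan(), c(0, 0.5, 1),
#'                 trackedReactions = c("H_HMGS", "EX_d25_lu"))
#' @export
runDoseResponse <- function(comodel, prebiotic, doses,
                            objective = NULL, trackedReactions = character(),
                            control = FALSE, cap = 0) {
  stopifnot(all(doses >= 0))
  if (is.unsorted(doses, strictly = TRUE))
    stop("doses must be strictly increasing")
  missing <- setdiff(trackedReactions, comodel@reactions$id)
  if (length(missing))
    stop("tracked reaction(s) not in co-model: ",
         paste(missing, collapse = ", "))
  base <- if (control) capMicrobeSecretion(comodel, cap) else comodel
  rows <- lapply(doses, function(d) {
    m <- applyPrebiotic(base, prebiotic, d)
    sol <- solvePFBA(m, objective)
    tracked <- if (sol@status == "optimal")
      sol@fluxes[trackedReactions] else rep(NA_real_, length(trackedReactions))
    out <- data.frame(dose_grams = d, status = sol@status,
                      objective = if (sol@status == "optimal")
                        sol@objectiveValue else NA_real_)
    for (k in seq_along(trackedReactions))
      out[[trackedReactions[k]]] <- unname(tracked[k])
    out
  })
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(dose_grams = numeric(), status = character(),
               objective = numeric())
  attr(res, "prebiotic") <- prebiotic@name
  attr(res, "control") <- control
  res
}

#' Microbe secretion and host absorption fluxes per lumen metabolite
#'
#' Reads, from a parsimonious solution of a co-model, the flux each
#' metabolite takes from the microbe into the lumen (secretion, signed
#' positive towards the lumen) and from the lumen into the host
#' (absorption). Metabolites without the relevant transports are reported
#' as not transported with zero flux.
#'
#' @param solution an optimal [FluxSolution-class] for `comodel`
#'   (parsimonious recommended; a warning is issued otherwise).
#' @param comodel the [CoMetabolismModel-class] the solution belongs to.
#' @param metabolites lumen metabolite base names (default acetate,
#'   lactate, pyruvate).
#' @return data.frame with columns `metabolite`, `microbe_secretion`,
#'   `host_absorption`, `transported`.
#' @examples
#' cm <- applyPrebiotic(makeToyComodel(), toyFructan(), 1)
#' profileSecretionAbsorption(solvePFBA(cm), cm)
#' @export
profileSecretionAbsorption <- function(solution, comodel,
                                       metabolites = c("ac", "lac", "pyr")) {
  stopifnot(is(solution, "FluxSolution"), is(comodel, "CoMetabolismModel"))
  if (solution@status != "optimal")
    stop("solution is not optimal (status ", solution@status, ")")
  if (!solution@parsimonious)
    warning("profiling a non-parsimonious solution; fluxes may be degenerate")
  S <- comodel@stoichiometry
  v <- solution@fluxes
  lumen_flux <- function(rids, met) {
    rids <- intersect(rids, names(v))
    if (!length(rids) || !met %in% rownames(S)) return(c(0, FALSE))
    coefs <- S[met, rids]
    touching <- rids[coefs != 0]
    if (!length(touching)) return(c(0, FALSE))
    c(sum(v[touching] * S[met, touching]), TRUE)
  }
  rows <- lapply(metabolites, function(b) {
    met <- paste0(b, "[", comodel@lumenCompartment, "]")
    sec <- lumen_flux(comodel@microbeSecretion, met)   # + into lumen
    up <- lumen_flux(comodel@hostUptake, met)          # - out of lumen
    data.frame(metabolite = b, microbe_secretion = sec[1],
               host_absorption = -up[1],
               transported = as.logical(sec[2] | up[2]))
  })
  do.call(rbind, rows)
}

#' Single-reaction knock-off scan
#'
#' Solves the supplemented co-model once as baseline, then silences each
#' candidate reaction in turn ([knockOff()]) and re-solves, recording the
#' objective drop and the readjustment of tracked exchange fluxes. A
#' knock-off that makes the model infeasible is recorded with objective 0
#' and its status.
#'
#' @param comodel a [CoMetabolismModel-class].
#' @param candidates reaction ids to knock off one at a time (e.g.
#'   `microbeSecretion(comodel)`).
#' @param prebiotic,dose supplementation applied before all solves.
#' @param objective forwarded to [solvePFBA()].
#' @param trackedExchanges reaction ids whose before/after fluxes are kept
#'   (default: the microbe secretion transports).
#' @return data.frame with columns `reaction`, `status`,
#'   `objective_before`, `objective_after`, `percent_reduction`; the
#'   before/after fluxes of tracked exchanges are in
#'   `attr(, "flux_deltas")`.
#' @examples
#' runKnockoffScan(makeToyComodel(), "M_SEC_lac", toyFructan(), 1)
#' @export
runKnockoffScan <- function(comodel, candidates, prebiotic, dose,
                            objective = NULL, trackedExchanges = NULL) {
  missing <- setdiff(candidates, comodel@reactions$id)
  if (length(missing))
    stop("unknown candidate reaction(s): ", paste(missing, collapse = ", "))
  if (is.null(trackedExchanges)) trackedExchanges <- comodel@microbeSecretion
  m <- applyPrebiotic(comodel, prebiotic, dose)
  base <- solvePFBA(m, objective)
  if (base@status != "optimal")
    stop("baseline is not optimal (status ", base@status, ")")
  before <- base@objectiveValue
  deltas <- list()
  rows <- lapply(candidates, function(rid) {
    sol <- solvePFBA(knockOff(m, rid), objective)
    after <- if (sol@status == "optimal") sol@objectiveValue else 0
    deltas[[rid]] <<- data.frame(
      reaction = rid, tracked = trackedExchanges,
      before = unname(base@fluxes[trackedExchanges]),
      after = if (sol@status == "optimal")
        unname(sol@fluxes[trackedExchanges])
      else rep(NA_real_, length(trackedExchanges)))
    data.frame(reaction = rid, status = sol@status,
               objective_before = before, objective_after = after,
               percent_reduction = if (before > 0)
                 100 * (before - after) / before else 0)
  })
  res <- do.call(rbind, rows)
  attr(res, "flux_deltas") <- do.call(rbind, deltas)
  res
}

#' Screen a collection of microbe models for prebiotic-dependent secretion
#'
#' For each standalone microbe model and each prebiotic: decide whether the
#' organism utilizes the prebiotic (its component exchange exists and
#' maximal growth with supplementation exceeds growth without by more than
#' `relTol`), then compute the secretion flux of each target metabolite at
#' every dose on the grid and record the maximum over the grid (the
#' heatmap statistic). Two secretion objectives are available:
#' `"potential"` maximizes each metabolite's secretion exchange directly
#' per dose; `"growth"` maximizes biomass and reports the parsimonious
#' secretion fluxes. Unreadable models are flagged and skipped; the scan
#' streams row by row (constant memory in the collection size) and can
#' append to a TSV as it goes.
#'
#' @param models character vector of model file paths, or a list of
#'   [MetabolicModel-class] objects.
#' @param prebiotics a [PrebioticSpec-class] or named list of them.
#' @param doseGrid non-empty numeric vector of doses (g); default 21
#'   evenly spaced points over 0-10 g.
#' @param metabolites metabolite base names to profile.
#' @param mode `"potential"` or `"growth"`.
#' @param relTol relative growth-improvement tolerance for utilization.
#' @param file optional TSV path streamed to while screening.
#' @return data.frame with one row per (organism, prebiotic):
#'   `organism`, `prebiotic`, `ok` (model readable), `utilizes` and one
#'   `max_<metabolite>` column per metabolite; full dose profiles are in
#'   `attr(, "profiles")`.
#' @examples
#' mods <- makeToyCollection(3, seed = 1)
#' screenCollection(mods, toyFructan(), doseGrid = c(0, 5, 10))
#' @export
screenCollection <- function(models, prebiotics,
                             doseGrid = seq(0, 10, length.out = 21),
                             metabolites = c("ac", "lac", "pyr"),
                             mode = c("potential", "growth"),
                             relTol = 1e-6, file = NULL) {
  mode <- match.arg(mode)
  if (!length(doseGrid)) stop("doseGrid must be non-empty")
  if (is(prebiotics, "PrebioticSpec")) {
    nm <- prebiotics@name
    prebiotics <- list(prebiotics); names(prebiotics) <- nm
  }
  if (is.list(models) && !is.null(names(models))) models <- unname(models)
  rows <- list(); profiles <- list()
  header_written <- FALSE
  for (mi in seq_along(models)) {
    entry <- models[[mi]]
    model <- if (is.character(entry)) {
      tryCatch(readModel(entry), error = function(e) e)
    } else entry
    org <- if (is(model, "MetabolicModel")) model@id
      else sub("\\.(json|xml|sbml)(\\.gz)?$", "", basename(entry))
    for (pi in seq_along(prebiotics)) {
      pb <- prebiotics[[pi]]
      pname <- if (!is.null(names(prebiotics))) names(prebiotics)[pi] else pb@name
      if (!is(model, "MetabolicModel")) {
        row <- data.frame(organism = org, prebiotic = pname, ok = FALSE,
                          utilizes = NA)
        for (b in metabolites) row[[paste0("max_", b)]] <- NA_real_
      } else {
        row <- .screenOne(model, pb, pname, doseGrid, metabolites, mode,
                          relTol)
        profiles[[length(profiles) + 1L]] <- attr(row, "profile")
        attr(row, "profile") <- NULL
      }
      rows[[length(rows) + 1L]] <- row
      if (!is.null(file)) {
        utils::write.table(row, file, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = !header_written,
                           append = header_written)
        header_written <- TRUE
      }
    }
  }
  res <- do.call(rbind, rows)
  attr(res, "profiles") <- do.call(rbind, profiles)
  attr(res, "mode") <- mode
  res
}

.screenOne <- function(model, pb, pname, doseGrid, metabolites, mode, relTol) {
  comp_ids <- pb@components$exchange_id
  present <- comp_ids[comp_ids %in% model@reactions$id]
  has_ex <- length(present) > 0
  close_all <- function(m) if (has_ex) setBounds(m, present, lower = 0) else m
  with_dose <- function(m, d) {
    if (!has_ex) return(close_all(m))
    b <- doseToFlux(pb, d)[match(present, comp_ids)]
    setBounds(close_all(m), present, lower = -b, upper = 0)
  }
  growth <- function(m) {
    s <- solveFBA(m)
    if (s@status == "optimal") s@objectiveValue else 0
  }
  g0 <- growth(close_all(model))
  g1 <- growth(with_dose(model, max(doseGrid)))
  utilizes <- has_ex && (g1 > g0 * (1 + relTol) + relTol)
  ex_of <- vapply(metabolites, function(b) {
    hit <- findExchange(model, b)
    if (length(hit)) hit[1] else NA_character_
  }, character(1))
  prof <- expand.grid(dose_grams = sort(doseGrid), metabolite = metabolites,
                      stringsAsFactors = FALSE)
  prof$organism <- model@id; prof$prebiotic <- pname
  prof$flux <- NA_real_
  for (d in sort(unique(doseGrid))) {
    md <- with_dose(model, d)
    if (mode == "potential") {
      for (b in metabolites) {
        fx <- if (is.na(ex_of[b])) 0 else {
          s <- solveFBA(md, objective = ex_of[b])
          if (s@status == "optimal") s@objectiveValue else 0
        }
        prof$flux[prof$dose_grams == d & prof$metabolite == b] <- fx
      }
    } else {
      s <- solvePFBA(md)
      for (b in metabolites) {
        fx <- if (is.na(ex_of[b]) || s@status != "optimal") 0
          else unname(s@fluxes[ex_of[b]])
        prof$flux[prof$dose_grams == d & prof$metabolite == b] <- fx
      }
    }
  }
  row <- data.frame(organism = model@id, prebiotic = pname, ok = TRUE,
                    utilizes = utilizes)
  for (b in metabolites)
    row[[paste0("max_", b)]] <- max(prof$flux[prof$metabolite == b])
  attr(row, "profile") <- prof[, c("organism", "prebiotic", "metabolite",
                                   "dose_grams", "flux")]
  row
}

#' Flux modes of the host conversion pathway across doses
#'
#' Runs parsimonious FBA at each dose and reports, for every reaction of
#' the pathway definition, its flux and whether it is active (absolute
#' flux at or above `tol`). Pathway ids missing from the model are listed
#' as absent rather than raising an error. The default pathway covers the
#' host routes from absorbed lactate, pyruvate and acetate to acetyl-CoA
#' and on to 25-OH-D3 secretion.
#'
#' @param comodel a [CoMetabolismModel-class].
#' @param prebiotic a [PrebioticSpec-class].
#' @param doses numeric doses (g).
#' @param pathway character reaction ids; `NULL` for the default host set.
#' @param tol activity tolerance (default 1e-6).
#' @param objective forwarded to [solvePFBA()].
#' @return data.frame with columns `dose_grams`, `reaction`, `present`,
#'   `flux`, `active`.
#' @examples
#' extractFluxModes(makeToyComodel(), toyFructan(), c(0, 1))
#' @export
extractFluxModes <- function(comodel, prebiotic, doses, pathway = NULL,
                             tol = 1e-6, objective = NULL) {
  if (is.null(pathway)) {
    core <- c("LDH", "PDH", "ADHL", "ACS", "OXP", "GLYC", "HMGS", "VD3H",
              "D25S")
    pathway <- paste0(comodel@hostPrefix, core)
    pathway <- pathway[pathway %in% comodel@reactions$id]
  }
  rows <- lapply(doses, function(d) {
    sol <- solvePFBA(applyPrebiotic(comodel, prebiotic, d), objective)
    present <- pathway %in% comodel@reactions$id
    fx <- rep(NA_real_, length(pathway))
    if (sol@status == "optimal")
      fx[present] <- unname(sol@fluxes[pathway[present]])
    data.frame(dose_grams = d, reaction = pathway, present = present,
               flux = fx, active = !is.na(fx) & abs(fx) >= tol)
  })
  do.call(rbind, rows)
}

#' Subsystem distribution of prebiotic-driven flux changes
#'
#' Compares parsimonious flux vectors without and with supplementation at
#' one dose, computes the percent relative flux change
#' `100 * |v_supp - v_base| / max(|v_base|, eps)` for every internal host
#' reaction, retains the top fraction (`percentile`, by rank of the
#' change; reactions switching from zero to nonzero rank above every
#' finite percent change because of the `eps` guard) and reports per
#' subsystem the fraction `n_changed / n_total`.
#'
#' @param comodel a [CoMetabolismModel-class].
#' @param prebiotic a [PrebioticSpec-class].
#' @param dose positive dose (g).
#' @param objective forwarded to [solvePFBA()].
#' @param percentile fraction of changed reactions retained (default 0.9,
#'   count-based: `ceiling(percentile * n_changed)` kept, ties broken by
#'   percent change then id).
#' @param eps division guard for zero baseline flux (default 1e-9).
#' @param changeTol absolute flux-difference threshold below which a
#'   reaction counts as unchanged (default 1e-6).
#' @return data.frame with columns `subsystem`, `n_changed`, `n_total`,
#'   `fraction`; per-reaction detail in `attr(, "reactions")`, selection
#'   parameters in `attr(, "params")`.
#' @examples
#' subsystemFluxChange(makeToyComodel(toyMicrobeProfile("bt")),
#'                     toyFructan(), dose = 1)
#' @export
subsystemFluxChange <- function(comodel, prebiotic, dose, objective = NULL,
                                percentile = 0.9, eps = 1e-9,
                                changeTol = 1e-6) {
  stopifnot(dose > 0)
  base <- solvePFBA(comodel, objective)
  supp <- solvePFBA(applyPrebiotic(comodel, prebiotic, dose), objective)
  if (base@status != "optimal" || supp@status != "optimal")
    stop("baseline or supplemented solution not optimal")
  rxns <- comodel@reactions
  transports <- c(comodel@hostUptake, comodel@hostSecretion)
  internal <- startsWith(rxns$id, comodel@hostPrefix) &
    !rxns$is_exchange & !(rxns$id %in% transports)
  ids <- rxns$id[internal]
  vb <- base@fluxes[ids]; vs <- supp@fluxes[ids]
  delta <- abs(vs - vb)
  pct <- 100 * delta / pmax(abs(vb), eps)
  changed <- delta > changeTol
  sub <- rxns$subsystem[internal]
  sub[!nzchar(sub)] <- "unlabelled"
  keep <- character()
  if (any(changed)) {
    cids <- ids[changed]
    ord <- order(-pct[changed], cids)
    keep <- cids[ord][seq_len(ceiling(percentile * length(cids)))]
  }
  tab <- data.frame(subsystem = sub, id = ids, selected = ids %in% keep)
  agg <- do.call(rbind, lapply(split(tab, tab$subsystem), function(g)
    data.frame(subsystem = g$subsystem[1], n_changed = sum(g$selected),
               n_total = nrow(g),
               fraction = sum(g$selected) / nrow(g))))
  rownames(agg) <- NULL
  attr(agg, "reactions") <- data.frame(
    id = ids, subsystem = sub, flux_base = unname(vb),
    flux_supplemented = unname(vs), percent_change = unname(pct),
    changed = unname(changed), selected = ids %in% keep)
  attr(agg, "params") <- list(dose = dose, percentile = percentile,
                              eps = eps, changeTol = changeTol,
                              prebiotic = prebiotic@name)
  agg
}

#' Quick dose-response plot
#'
#' Minimal ggplot2 line plot of [runDoseResponse()] output (objective plus
#' any tracked reactions against dose). Requires ggplot2.
#'
#' @param dr data.frame from [runDoseResponse()].
#' @return a ggplot object.
#' @export
plotDoseResponse <- function(dr) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotDoseResponse requires ggplot2")
  value_cols <- setdiff(names(dr), c("dose_grams", "status"))
  long <- do.call(rbind, lapply(value_cols, function(cn)
    data.frame(dose_grams = dr$dose_grams, series = cn, flux = dr[[cn]])))
  ggplot2::ggplot(long, ggplot2::aes(x = dose_grams, y = flux,
                                     colour = series)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "dose (g)", y = "flux")
}
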