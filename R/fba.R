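#' @include model-build.R lp.R
NULL

# resolve an objective argument to a named coefficient vector
.resolveObjective <- function(model, objective) {
  if (is.null(objective)) {
    if (!length(model@objective))
      stop("model '", model@id, "' has no objective; supply one")
    obj <- model@objective
  } else if (is.character(objective)) {
    obj <- rep(1, length(objective)); names(obj) <- objective
  } else if (is.numeric(objective) && !is.null(names(objective))) {
    obj <- objective
  } else stop("objective must be NULL, reaction id(s), or a named numeric")
  missing <- setdiff(names(obj), model@reactions$id)
  if (length(missing))
    stop("objective reaction(s) not in model: ", paste(missing, collapse = ", "))
  obj
}

.objVector <- function(model, obj) {
  cc <- numeric(nrow(model@reactions))
  cc[match(names(obj), model@reactions$id)] <- unname(obj)
  cc
}

#' Solve the flux balance analysis linear program
#'
#' Maximizes (or minimizes) the linear objective c'v over the steady-state
#' flux polytope \{v : S v = 0, lb <= v <= ub\}. The LP is solved with the
#' package's deterministic bounded-variable simplex, so identical inputs
#' give identical solutions; when the optimal face is degenerate the
#' returned vertex is reproducible but arbitrary — use [solvePFBA()] when
#' individual reaction fluxes are reported.
#'
#' @param model a valid [MetabolicModel-class].
#' @param objective `NULL` (use the model's stored objective), a character
#'   vector of reaction ids (coefficient 1 each), or a named numeric
#'   coefficient map.
#' @param sense `"max"` or `"min"`.
#' @param tol feasibility/optimality tolerance (default 1e-9).
#' @return a [FluxSolution-class]; `solverStatus()` is `"optimal"`,
#'   `"infeasible"` or `"unbounded"` (fluxes are empty in the latter two).
#' @examples
#' sol <- solveFBA(makeToyHost())
#' objectiveValue(sol)       # 2: glucose-limited 25-OH-D3 secretion
#' @seealso [solvePFBA()], [knockOff()], [checkFeasible()]
#' @export
solveFBA <- function(model, objective = NULL, sense = c("max", "min"),
                     tol = 1e-9) {
  sense <- match.arg(sense)
  .assertValid(model)
  obj <- .resolveObjective(model, objective)
  rxns <- model@reactions
  res <- .lpSolveDense(.objVector(model, obj),
                       as.matrix(model@stoichiometry),
                       rep(0, nrow(model@metabolites)),
                       rxns$lower_bound, rxns$upper_bound, sense, tol = tol)
  if (res$status != "optimal")
    return(new("FluxSolution", status = res$status,
               objectiveValue = NA_real_, fluxes = numeric(0),
               objectiveIds = names(obj), feasibilityTolerance = tol,
               parsimonious = FALSE))
  v <- res$x; names(v) <- rxns$id
  new("FluxSolution", status = "optimal", objectiveValue = res$objval,
      fluxes = v, objectiveIds = names(obj), feasibilityTolerance = tol,
      parsimonious = FALSE)
}

#' Parsimonious FBA: flux-minimal representative of the optimal face
#'
#' Two-stage optimization. Stage 1 is plain [solveFBA()]. Stage 2 minimizes
#' total absolute flux sum(|v|) subject to the original constraints plus
#' c'v >= optimum - tol, with each flux split into non-negative forward and
#' reverse parts to linearize |v|. This pins down a reproducible flux
#' vector when alternate optima exist, which is why all reported flux
#' tables in this package are parsimonious.
#'
#' @inheritParams solveFBA
#' @param relTol relative tolerance on the stage-1 optimum retained during
#'   stage 2.
#' @return a [FluxSolution-class] with `parsimonious = TRUE`; the objective
#'   value is the stage-1 optimum.
#' @examples
#' sol <- solvePFBA(makeToyHost())
#' sum(abs(fluxes(sol)))
#' @export
solvePFBA <- function(model, objective = NULL, sense = c("max", "min"),
                      tol = 1e-9, relTol = 1e-9) {
  sense <- match.arg(sense)
  s1 <- solveFBA(model, objective, sense, tol)
  if (s1@status != "optimal") return(s1)
  obj <- .resolveObjective(model, objective)
  rxns <- model@reactions
  n <- nrow(rxns)
  S <- as.matrix(model@stoichiometry)
  lb <- rxns$lower_bound; ub <- rxns$upper_bound
  # v = p - q with p, q >= 0; p in [max(lb,0), max(ub,0)], q in
  # [max(-ub,0), max(-lb,0)] keeps v within its bounds
  plb <- pmax(lb, 0); pub <- pmax(ub, 0)
  qlb <- pmax(-ub, 0); qub <- pmax(-lb, 0)
  cc <- .objVector(model, obj)
  opt <- s1@objectiveValue
  slack <- max(tol, relTol * abs(opt))
  # slack s >= 0 turns the objective-retention inequality into an equality:
  # max: c'(p - q) - s = opt - slack  (c'v >= opt - slack)
  # min: -c'(p - q) - s = -(opt + slack)  (c'v <= opt + slack)
  csign <- if (sense == "max") 1 else -1
  A <- cbind(rbind(S, csign * cc), rbind(-S, -csign * cc),
             c(rep(0, nrow(S)), -1))
  bvec <- c(rep(0, nrow(S)), csign * opt - slack)
  res <- .lpSolveDense(c(rep(1, 2 * n), 0), A, bvec,
                       c(plb, qlb, 0), c(pub, qub, Inf), "min", tol = tol)
  if (res$status != "optimal")
    stop("pFBA stage 2 did not reach optimality (status ", res$status,
         "); consider loosening relTol")
  v <- res$x[seq_len(n)] - res$x[n + seq_len(n)]
  names(v) <- rxns$id
  new("FluxSolution", status = "optimal", objectiveValue = opt, fluxes = v,
      objectiveIds = names(obj), feasibilityTolerance = tol,
      parsimonious = TRUE)
}

#' Knock off a reaction
#'
#' Simulates a reaction knock-off by constraining both the lower and the
#' upper flux bound of the reaction to zero; all other constraints and the
#' objective are left unchanged.
#'
#' @param model a [MetabolicModel-class].
#' @param reaction_id a single reaction id.
#' @return a copy of the model with the reaction silenced.
#' @examples
#' m <- knockOff(makeToyHost(), "ACS")
#' @export
knockOff <- function(model, reaction_id) {
  stopifnot(length(reaction_id) == 1L)
  if (!reaction_id %in% model@reactions$id)
    stop("unknown reaction id: ", reaction_id)
  setBounds(model, reaction_id, lower = 0, upper = 0)
}

#' Check feasibility of a model's flux polytope
#'
#' Tests whether \{v : S v = 0, lb <= v <= ub\} (optionally with additional
#' temporary bounds) contains any point. Deterministic; used for microbe
#' viability checks.
#'
#' @param model a [MetabolicModel-class].
#' @param extraBounds optional named list `id = c(lower, upper)` of bounds
#'   applied on top of the model's (not intersected: they replace).
#' @param tol feasibility tolerance.
#' @return logical(1).
#' @examples
#' checkFeasible(makeToyHost())
#' @export
checkFeasible <- function(model, extraBounds = NULL, tol = 1e-9) {
  m <- model
  if (!is.null(extraBounds)) {
    for (id in names(extraBounds))
      m <- setBounds(m, id, extraBounds[[id]][1], extraBounds[[id]][2])
  }
  rxns <- m@reactions
  res <- .lpSolveDense(rep(0, nrow(rxns)), as.matrix(m@stoichiometry),
                       rep(0, nrow(m@metabolites)),
                       rxns$lower_bound, rxns$upper_bound, "max", tol = tol)
  res$status == "optimal"
}
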