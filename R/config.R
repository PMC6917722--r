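#' @include experiments.R toys.R
NULL

.err <- function(class, ...) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Reconstruct a co-metabolism model from an annotated plain model
#'
#' [mergeComodel()] records the co-model structure (prefixes, lumen id,
#' transport and diet-exchange sets, biomass reaction) in the model
#' annotation, which survives a COBRA-JSON round-trip. This helper
#' re-instates the [CoMetabolismModel-class] from such a file. SBML output
#' does not carry the annotation, so co-models meant to be reloaded should
#' be stored as JSON.
#'
#' @param model a [MetabolicModel-class] read back from disk.
#' @return a [CoMetabolismModel-class].
#' @examples
#' f <- tempfile(fileext = ".json")
#' writeModel(makeToyComodel(), f)
#' cm <- asCoMetabolismModel(readModel(f))
#' @export
asCoMetabolismModel <- function(model) {
  if (is(model, "CoMetabolismModel")) return(model)
  st <- model@annotation$comodel_structure
  if (is.null(st))
    stop("model carries no co-model structure annotation")
  chr <- function(x) if (is.null(x)) character() else unlist(x)
  new("CoMetabolismModel", model,
      hostPrefix = st$host_prefix, microbePrefix = st$microbe_prefix,
      lumenCompartment = st$lumen_compartment,
      dietExchanges = chr(st$diet_exchanges),
      hostUptake = chr(st$host_uptake), hostSecretion = chr(st$host_secretion),
      microbeUptake = chr(st$microbe_uptake),
      microbeSecretion = chr(st$microbe_secretion),
      biomassReaction = if (is.null(st$biomass_reaction)) NA_character_
        else st$biomass_reaction)
}

#' Load a run configuration from YAML
#'
#' One YAML file drives every command: model sources (`host_model` +
#' `microbe_model` paths, a `comodel` JSON path, a `collection_dir`, or
#' `toy: {profile: fp, cofactors: false}`), `diet` (YAML path), `prebiotic`
#' (YAML path or one of `"inulin"`, `"scfos"`, `"toy-fructan"`), the dose
#' grid (`doses:` list or `dose_grid: {from, to, points}`), `objective`,
#' `output_dir`, and mode flags (`control`, `cap`, `screen_mode`,
#' `percentile`, `tracked_reactions`, `candidates`, `seed`). The resolved
#' configuration and its hash are written next to every command's outputs
#' for reproducibility.
#'
#' @param path YAML file.
#' @return a list of class `"lumenRunConfig"`.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) .err("lumenfba_missing_file",
                               "config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  cfg$config_path <- normalizePath(path)
  if (is.null(cfg$output_dir)) cfg$output_dir <- "lumenfba_out"
  if (is.null(cfg$doses) && !is.null(cfg$dose_grid))
    cfg$doses <- seq(cfg$dose_grid$from, cfg$dose_grid$to,
                     length.out = cfg$dose_grid$points)
  if (is.null(cfg$doses)) cfg$doses <- seq(0, 10, length.out = 21)
  cfg$doses <- as.numeric(unlist(cfg$doses))
  structure(cfg, class = "lumenRunConfig")
}

.configHash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  keep <- cfg[setdiff(names(cfg), "config_path")]
  yaml::write_yaml(keep[order(names(keep))], tmp)
  unname(tools::md5sum(tmp))
}

.cfgPrebiotic <- function(cfg) {
  p <- cfg$prebiotic
  if (is.null(p)) p <- "toy-fructan"
  if (file.exists(p)) return(readPrebioticSpec(p))
  switch(p,
         inulin = inulinSpec(),
         scfos = scfosSpec(),
         "toy-fructan" = toyFructan(),
         .err("lumenfba_unresolved", "unknown prebiotic: ", p))
}

.cfgComodel <- function(cfg) {
  if (!is.null(cfg$toy)) {
    prof <- toyMicrobeProfile(if (is.null(cfg$toy$profile)) "fp"
                              else cfg$toy$profile)
    cm <- makeToyComodel(prof,
                         cofactors = isTRUE(cfg$toy$cofactors))
  } else if (!is.null(cfg$comodel)) {
    if (!file.exists(cfg$comodel))
      .err("lumenfba_missing_file", "co-model file not found: ", cfg$comodel)
    cm <- asCoMetabolismModel(readModel(cfg$comodel))
  } else if (!is.null(cfg$host_model) && !is.null(cfg$microbe_model)) {
    for (f in c(cfg$host_model, cfg$microbe_model))
      if (!file.exists(f))
        .err("lumenfba_missing_file", "model file not found: ", f)
    cm <- mergeComodel(readModel(cfg$host_model), readModel(cfg$microbe_model))
  } else .err("lumenfba_unresolved",
              "config must define toy:, comodel:, or host_model:+microbe_model:")
  if (!is.null(cfg$diet)) {
    if (!file.exists(cfg$diet))
      .err("lumenfba_missing_file", "diet file not found: ", cfg$diet)
    cm <- applyDiet(cm, readDietSpec(cfg$diet))
  }
  cm
}

.cmdSetup <- function(cfg) {
  if (!inherits(cfg, "lumenRunConfig")) cfg <- readRunConfig(cfg)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- .configHash(cfg)
  resolved <- cfg[setdiff(names(cfg), "config_path")]
  resolved$config_hash <- hash
  yaml::write_yaml(resolved, file.path(cfg$output_dir, "resolved_config.yaml"))
  list(cfg = cfg, hash = hash)
}

.logRun <- function(cfg, what, files, hash) {
  msg <- paste0("[", what, "] config ", hash, " -> ",
                paste(basename(files), collapse = ", "))
  message(msg)
  cat(paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " ", msg, "\n"),
      file = file.path(cfg$output_dir, "run.log"), append = TRUE)
  invisible(files)
}

#' Command-level entry points
#'
#' Thin wrappers that read a run configuration, execute one analysis and
#' write TSV outputs plus the resolved configuration (with hash) and a run
#' log into `output_dir`. These back the `lumenfba` command-line script in
#' `system.file("scripts", "lumenfba", package = "LumenFBA")`; identical
#' configurations give identical result files.
#'
#' @param cfg a config YAML path or a list from [readRunConfig()].
#' @return invisibly, the written file paths.
#' @name commands
NULL

#' @rdname commands
#' @export
cmdDoseResponse <- function(cfg) {
  s <- .cmdSetup(cfg); cfg <- s$cfg
  cm <- .cfgComodel(cfg)
  pb <- .cfgPrebiotic(cfg)
  tracked <- intersect(unlist(cfg$tracked_reactions), cm@reactions$id)
  dr <- runDoseResponse(cm, pb, sort(unique(cfg$doses)),
                        objective = cfg$objective,
                        trackedReactions = tracked,
                        control = isTRUE(cfg$control),
                        cap = if (is.null(cfg$cap)) 0 else cfg$cap)
  f <- file.path(cfg$output_dir, "dose_response.tsv")
  .writeTSV(dr, f)
  .logRun(cfg, "dose-response", f, s$hash)
}

#' @rdname commands
#' @export
cmdKnockoff <- function(cfg) {
  s <- .cmdSetup(cfg); cfg <- s$cfg
  cm <- .cfgComodel(cfg)
  pb <- .cfgPrebiotic(cfg)
  cand <- unlist(cfg$candidates)
  if (is.null(cand)) cand <- microbeSecretion(cm)
  bad <- setdiff(cand, cm@reactions$id)
  if (length(bad)) .err("lumenfba_unresolved",
                        "unknown candidate reaction(s): ",
                        paste(bad, collapse = ", "))
  dose <- if (is.null(cfg$dose)) max(cfg$doses) else cfg$dose
  ko <- runKnockoffScan(cm, cand, pb, dose, objective = cfg$objective)
  f1 <- file.path(cfg$output_dir, "knockoff.tsv")
  f2 <- file.path(cfg$output_dir, "knockoff_flux_deltas.tsv")
  .writeTSV(ko, f1)
  .writeTSV(attr(ko, "flux_deltas"), f2)
  .logRun(cfg, "knockoff", c(f1, f2), s$hash)
}

#' @rdname commands
#' @export
cmdScreen <- function(cfg) {
  s <- .cmdSetup(cfg); cfg <- s$cfg
  models <- if (!is.null(cfg$collection_dir)) {
    if (!dir.exists(cfg$collection_dir))
      .err("lumenfba_missing_file", "collection dir not found: ",
           cfg$collection_dir)
    sort(list.files(cfg$collection_dir, "\\.(json|xml|sbml)(\\.gz)?$",
                    full.names = TRUE))
  } else .err("lumenfba_unresolved", "screen needs collection_dir:")
  pb <- .cfgPrebiotic(cfg)
  sc <- screenCollection(models, pb, doseGrid = cfg$doses,
                         mode = if (is.null(cfg$screen_mode)) "potential"
                           else cfg$screen_mode)
  f1 <- file.path(cfg$output_dir, "screen_heatmap.tsv")
  f2 <- file.path(cfg$output_dir, "screen_profiles.tsv")
  .writeTSV(sc, f1)
  .writeTSV(attr(sc, "profiles"), f2)
  .logRun(cfg, "screen", c(f1, f2), s$hash)
}

#' @rdname commands
#' @export
cmdSubsystems <- function(cfg) {
  s <- .cmdSetup(cfg); cfg <- s$cfg
  cm <- .cfgComodel(cfg)
  pb <- .cfgPrebiotic(cfg)
  dose <- if (is.null(cfg$dose)) 5 else cfg$dose
  rep <- subsystemFluxChange(cm, pb, dose, objective = cfg$objective,
                             percentile = if (is.null(cfg$percentile)) 0.9
                               else cfg$percentile)
  f1 <- file.path(cfg$output_dir, "subsystems.tsv")
  f2 <- file.path(cfg$output_dir, "subsystem_reactions.tsv")
  .writeTSV(rep, f1)
  .writeTSV(attr(rep, "reactions"), f2)
  .logRun(cfg, "subsystems", c(f1, f2), s$hash)
}

#' @rdname commands
#' @export
cmdMakeToy <- function(cfg) {
  s <- .cmdSetup(cfg); cfg <- s$cfg
  n <- if (is.null(cfg$n)) 10 else cfg$n
  seed <- if (is.null(cfg$seed)) 1 else cfg$seed
  dir <- file.path(cfg$output_dir, "toy_collection")
  paths <- makeToyCollection(n, seed, dir = dir)
  host <- file.path(cfg$output_dir, "toy_host.json")
  writeModel(makeToyHost(), host)
  comodel <- file.path(cfg$output_dir, "toy_comodel.json")
  writeModel(makeToyComodel(), comodel)
  .logRun(cfg, "make-toy", c(host, comodel, paths), s$hash)
}
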