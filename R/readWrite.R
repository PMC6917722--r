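#' Read a metabolic model from SBML-FBC or COBRA JSON
#'
#' Reads a genome-scale (or toy) model from SBML Level 3 with the FBC v2
#' extension or from the COBRA JSON dialect. Gzip-compressed files
#' (`*.gz`) are handled transparently. With `format = "auto"` the dialect is
#' chosen from the file extension, falling back to content sniffing.
#'
#' Bounds absent from a file default to the COBRA convention of +/-1000
#' (for SBML, a reaction declared `reversible="false"` gets a lower bound of
#' 0 instead). The FBC objective is imported when present. Gene-protein-
#' reaction rules are ignored. Exchange reactions are flagged for
#' single-metabolite boundary columns or ids starting with `"EX_"` (the
#' prefix convention wins on conflict).
#'
#' @param path file path.
#' @param format `"auto"`, `"sbml"` or `"json"`.
#' @return a validated [MetabolicModel-class]; structural problems in the
#'   file (duplicate ids, undeclared species or compartments) raise errors
#'   naming the offending element.
#' @examples
#' f <- system.file("extdata", "toy_host.json", package = "LumenFBA")
#' m <- readModel(f)
#' @seealso [writeModel()], [validateModel()]
#' @export
readModel <- function(path, format = c("auto", "sbml", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    base <- sub("\\.gz$", "", path)
    ext <- tolower(tools::file_ext(base))
    format <- if (ext %in% c("xml", "sbml")) "sbml"
      else if (ext == "json") "json"
      else {
        head <- substr(trimws(.readTextMaybeGz(path)), 1, 1)
        if (head == "<") "sbml" else "json"
      }
  }
  switch(format, sbml = .readModelSBML(path), json = .readModelJSON(path))
}

#' Write a metabolic model to SBML-FBC or COBRA JSON
#'
#' The written file round-trips through [readModel()]: ids, stoichiometry,
#' bounds, subsystem labels, compartments and the objective are preserved
#' structurally. A `.gz` suffix triggers gzip compression.
#'
#' @param model a valid [MetabolicModel-class] (checked with
#'   [validateModel()] before writing).
#' @param path output file path.
#' @param format `"auto"` (from extension), `"sbml"` or `"json"`.
#' @return `path`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".json")
#' writeModel(makeToyHost(), f)
#' @export
writeModel <- function(model, path, format = c("auto", "sbml", "json")) {
  format <- match.arg(format)
  .assertValid(model)
  if (format == "auto") {
    base <- sub("\\.gz$", "", path)
    ext <- tolower(tools::file_ext(base))
    format <- if (ext %in% c("xml", "sbml")) "sbml" else "json"
  }
  switch(format, sbml = .writeModelSBML(model, path),
         json = .writeModelJSON(model, path))
  invisible(path)
}

#' Export a flux solution as TSV
#'
#' Writes a two-column table (`reaction_id`, `flux`) for an optimal
#' [FluxSolution-class].
#'
#' @param solution a [FluxSolution-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
exportFluxes <- function(solution, path) {
  stopifnot(is(solution, "FluxSolution"))
  df <- data.frame(reaction_id = names(solution@fluxes),
                   flux = unname(solution@fluxes))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
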