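# SBML reading/writing for the subset needed to force ODE models with
# periodic signals: compartments, species, global parameters, reactions with
# kinetic laws, assignment/rate rules, function definitions, sboTerm.
# Built on xml2; XPath uses local-name() so SBML Level 2 and Level 3
# documents (different namespaces) are handled uniformly.

SBML_L3V1_NS <- "http://www.sbml.org/sbml/level3/version1/core"

.xfind <- function(node, path) xml2::xml_find_all(node, path)

.model_node <- function(doc) {
  m <- xml2::xml_find_first(doc, "/*[local-name()='sbml']/*[local-name()='model']")
  if (inherits(m, "xml_missing")) stop("document has no <model> element")
  m
}

.num_attr <- function(node, attr, default = NA_real_) {
  v <- xml2::xml_attr(node, attr)
  ifelse(is.na(v), default, suppressWarnings(as.numeric(v)))
}

# variable -> rule type map ("assignment", "rate", "algebraic", "event")
.governed_variables <- function(model_node) {
  out <- character(0)
  rules <- .xfind(model_node, "./*[local-name()='listOfRules']/*")
  for (r in rules) {
    nm <- xml2::xml_name(r)
    var <- xml2::xml_attr(r, "variable")
    type <- switch(nm, assignmentRule = "assignment", rateRule = "rate",
                   algebraicRule = "algebraic", NA_character_)
    if (!is.na(type) && !is.na(var)) out[var] <- type
  }
  eas <- .xfind(model_node, paste0(
    "./*[local-name()='listOfEvents']/*[local-name()='event']",
    "/*[local-name()='listOfEventAssignments']/*"))
  for (ea in eas) {
    var <- xml2::xml_attr(ea, "variable")
    if (!is.na(var) && is.na(out[var])) out[var] <- "event"
  }
  out
}

.parameter_index <- function(model_node) {
  pars <- .xfind(model_node,
    "./*[local-name()='listOfParameters']/*[local-name()='parameter']")
  governed <- .governed_variables(model_node)
  ids <- xml2::xml_attr(pars, "id")
  data.frame(
    id = ids,
    value = vapply(pars, .num_attr, numeric(1), attr = "value"),
    constant = !(xml2::xml_attr(pars, "constant") %in% "false"),
    rule = ifelse(is.na(governed[ids]), "", governed[ids]),
    stringsAsFactors = FALSE, row.names = NULL)
}

.new_handle <- function(doc, path = NA_character_) {
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "sbml")
    stop("not an SBML document (root element is <", xml2::xml_name(root), ">)")
  level <- as.integer(xml2::xml_attr(root, "level"))
  version <- as.integer(xml2::xml_attr(root, "version"))
  model <- .model_node(doc)
  idx <- .parameter_index(model)
  structure(list(doc = doc, level = level, version = version,
                 parameter_index = idx, path = path),
            class = "sbml_model")
}

#' Load an SBML model
#'
#' Parses an SBML Level 2 or Level 3 file, runs structural consistency
#' checks (fatal problems stop; recoverable oddities warn) and returns a
#' model handle carrying the parsed document plus an index of its global
#' parameters.
#'
#' @param path Path to an SBML XML file, or a single string of SBML XML.
#' @return An object of class `sbml_model` with fields `doc` (the `xml2`
#'   document), `level`, `version` and `parameter_index` (a data frame with
#'   columns `id`, `value`, `constant`, `rule`).
#' @export
load_model <- function(path) {
  if (length(path) == 1 && !file.exists(path) && grepl("^\\s*<", path)) {
    doc <- xml2::read_xml(path)
  } else {
    if (!file.exists(path)) stop("file not found: ", path)
    doc <- tryCatch(xml2::read_xml(path),
                    error = function(e) stop("SBML parse failure in '", path,
                                             "': ", conditionMessage(e)))
  }
  h <- .new_handle(doc, path = if (file.exists(path[1])) path else NA_character_)
  .check_consistency(h)
  h
}

# Structural consistency checks: cheap stand-in for a full SBML validator.
.check_consistency <- function(h) {
  model <- .model_node(h$doc)
  idx <- h$parameter_index
  if (nrow(idx) == 0)
    stop("model declares no global parameters; nothing can be forced")
  if (anyDuplicated(idx$id))
    stop("duplicate parameter ids: ",
         paste(unique(idx$id[duplicated(idx$id)]), collapse = ", "))
  sp <- .xfind(model, "./*[local-name()='listOfSpecies']/*[local-name()='species']")
  spid <- xml2::xml_attr(sp, "id")
  if (anyDuplicated(spid))
    stop("duplicate species ids: ", paste(spid[duplicated(spid)], collapse = ", "))
  known <- c(idx$id, spid,
             xml2::xml_attr(.xfind(model,
               "./*[local-name()='listOfCompartments']/*"), "id"))
  governed <- .governed_variables(model)
  bad <- setdiff(names(governed), known)
  if (length(bad))
    warning("rules reference unknown variables: ", paste(bad, collapse = ", "))
  invisible(h)
}

#' @export
print.sbml_model <- function(x, ...) {
  cat(sprintf("<sbml_model> L%dV%d, %d global parameter(s)\n",
              x$level, x$version, nrow(x$parameter_index)))
  if (nrow(x$parameter_index)) {
    ruled <- x$parameter_index$rule != ""
    cat("  parameters:", paste0(x$parameter_index$id,
        ifelse(ruled, paste0(" [", x$parameter_index$rule, "]"), ""),
        collapse = ", "), "\n")
  }
  invisible(x)
}

#' List parameters available for signal injection
#'
#' Global parameters not already governed by a rule or event assignment;
#' these are the valid targets for [inject_issf()].
#'
#' @param model An `sbml_model` handle.
#' @return Character vector of parameter identifiers.
#' @export
list_controllable_parameters <- function(model) {
  stopifnot(inherits(model, "sbml_model"))
  idx <- model$parameter_index
  idx$id[idx$rule == ""]
}

#' Write an SBML model to disk
#'
#' @param model An `sbml_model` handle.
#' @param path Output path; serialized SBML re-loads to an equivalent handle.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "sbml_model"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  ok <- tryCatch({ xml2::write_xml(model$doc, path); TRUE },
                 error = function(e) stop("cannot write '", path, "': ",
                                          conditionMessage(e)))
  invisible(path)
}

# Deep-copy a handle so injection never mutates the caller's document
# (xml2 documents are mutable references).
.copy_handle <- function(model) {
  doc <- xml2::read_xml(as.character(model$doc))
  .new_handle(doc, path = model$path)
}

# Re-derive the index after a mutation.
.reindex <- function(model) {
  model$parameter_index <- .parameter_index(.model_node(model$doc))
  model
}
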