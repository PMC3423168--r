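# Injection of the step function into an SBML document: one reusable
# FunctionDefinition (a pure lambda -- SBML forbids the time csymbol inside
# function bodies, so time is always passed in as the first argument from
# the rule) plus one AssignmentRule per target parameter. Multi-segment
# schedules become nested piecewise over absolute time rather than events,
# so any rule-capable simulator can run the result.

ISSF_FUNCTION_ID <- "issf"
ISSF_SBO_DEFAULT <- 475L

#' Describe the wiring of signals onto a model parameter
#'
#' @param target_parameter Identifier of the global model parameter to force.
#' @param signal An [issf_params()], [issf_schedule()] or [issf_composite()].
#' @param sbo_term Integer accession of the ontology term annotating the
#'   injected function definition (default 475, the step-function input
#'   signal term).
#' @return An object of class `signal_assignment`.
#' @export
signal_assignment <- function(target_parameter, signal,
                              sbo_term = ISSF_SBO_DEFAULT) {
  if (!is.character(target_parameter) || length(target_parameter) != 1)
    stop("target_parameter must be a single identifier")
  if (!inherits(signal, "issf_composite"))
    signal <- issf_composite(list(signal))
  sbo_term <- as.integer(sbo_term)
  if (is.na(sbo_term) || sbo_term < 0 || sbo_term > 9999999)
    stop("sbo_term must be a non-negative integer accession")
  structure(list(target_parameter = target_parameter, signal = signal,
                 sbo_term = sbo_term),
            class = "signal_assignment")
}

# MathML body of issf(t, theta0, theta1, tP, tC, tR, phi).
# u = (t + phi) - tC * floor((t + phi) / tC); pieces are mutually exclusive:
#   plateau  [tR, tP)        -> theta0 + theta1
#   up-ramp  [0, tR)         -> theta0 + theta1 * u / tR
#   down-ramp[tP, tP + tR)   -> theta0 + theta1 * (1 - (u - tP) / tR)
#   otherwise                -> theta0
# With tR = 0 the ramp pieces have empty support and the plateau piece
# covers [0, tP): a right-continuous square wave.
.issf_lambda_mathml <- function() {
  x <- mml_apply("plus", mml_ci("t"), mml_ci("phi"))
  u <- mml_apply("minus", x,
         mml_apply("times", mml_ci("tC"),
           mml_apply("floor", mml_apply("divide", x, mml_ci("tC")))))
  plateau <- mml_apply("plus", mml_ci("theta0"), mml_ci("theta1"))
  up <- mml_apply("plus", mml_ci("theta0"),
          mml_apply("divide",
            mml_apply("times", mml_ci("theta1"), u), mml_ci("tR")))
  down <- mml_apply("plus", mml_ci("theta0"),
            mml_apply("times", mml_ci("theta1"),
              mml_apply("minus", mml_cn(1),
                mml_apply("divide",
                  mml_apply("minus", u, mml_ci("tP")), mml_ci("tR")))))
  pw <- mml_piecewise(list(
    list(value = plateau,
         cond = mml_apply("and",
                  mml_apply("geq", u, mml_ci("tR")),
                  mml_apply("lt", u, mml_ci("tP")))),
    list(value = up, cond = mml_apply("lt", u, mml_ci("tR"))),
    list(value = down,
         cond = mml_apply("and",
                  mml_apply("geq", u, mml_ci("tP")),
                  mml_apply("lt", u,
                    mml_apply("plus", mml_ci("tP"), mml_ci("tR")))))),
    otherwise = mml_ci("theta0"))
  bvars <- paste0(vapply(c("t", "theta0", "theta1", "tP", "tC", "tR", "phi"),
                         function(v) paste0("<bvar>", mml_ci(v), "</bvar>"),
                         character(1)), collapse = "")
  mml_math(paste0("<lambda>", bvars, pw, "</lambda>"))
}

.issf_call_mathml <- function(p) {
  mml_call(ISSF_FUNCTION_ID, mml_time(),
           mml_cn(p$offset), mml_cn(p$amplitude), mml_cn(p$pulse_duration),
           mml_cn(p$cycle_period), mml_cn(p$ramp_duration), mml_cn(p$phase))
}

# A schedule becomes nested piecewise over the time csymbol: segment i
# applies while time < start_{i+1} (half-open boundaries: the later segment
# wins at the boundary instant). The first segment extends backwards to the
# simulation start.
.schedule_mathml <- function(sched) {
  n <- length(sched$starts)
  if (n == 1) return(.issf_call_mathml(sched$params[[1]]))
  pieces <- lapply(seq_len(n - 1), function(i)
    list(value = .issf_call_mathml(sched$params[[i]]),
         cond = mml_apply("lt", mml_time(), mml_cn(sched$starts[i + 1]))))
  mml_piecewise(pieces, otherwise = .issf_call_mathml(sched$params[[n]]))
}

.composite_mathml <- function(comp) {
  terms <- vapply(comp$signals, .schedule_mathml, character(1))
  if (length(terms) == 1 && comp$combiner %in% c("sum", "product"))
    return(terms[[1]])
  switch(comp$combiner,
    sum = mml_apply("plus", terms),
    product = mml_apply("times", terms),
    max = Reduce(function(a, b)
      mml_piecewise(list(list(value = a, cond = mml_apply("geq", a, b))),
                    otherwise = b),
      terms))
}

.sbo_attr <- function(term) sprintf("SBO:%07d", as.integer(term))

# parse an XML fragment and append it as the last child of `parent`
.append_fragment <- function(parent, fragment_xml) {
  frag <- xml2::read_xml(fragment_xml)
  xml2::xml_add_child(parent, frag)
}

.find_or_create_list <- function(model_node, list_name, after_candidates) {
  lst <- xml2::xml_find_first(model_node,
    paste0("./*[local-name()='", list_name, "']"))
  if (!inherits(lst, "xml_missing")) return(lst)
  xml2::xml_add_child(model_node, list_name)
  xml2::xml_find_first(model_node, paste0("./*[local-name()='", list_name, "']"))
}

#' Inject a step-function signal into an SBML model
#'
#' Adds (a) a reusable `issf` FunctionDefinition holding the piecewise
#' MathML of the waveform, annotated with its ontology term; (b) an
#' AssignmentRule on the target parameter whose math calls `issf` with the
#' time csymbol and the numeric signal parameters (schedules encoded as
#' nested piecewise over time, composites folded with their combiner); and
#' (c) clears the target parameter's `constant` flag. Everything else in
#' the document is left untouched. The input handle is never mutated; a
#' modified copy is returned.
#'
#' @param model An `sbml_model` handle.
#' @param assignment A [signal_assignment()], or a bare signal if `target`
#'   is given.
#' @param target Convenience: target parameter id when passing a bare signal.
#' @param replace If `TRUE`, an existing assignment rule on the target is
#'   replaced; the default is to error rather than stack rules.
#' @return A new `sbml_model` handle with the signal wired in.
#' @export
inject_issf <- function(model, assignment, target = NULL, replace = FALSE) {
  stopifnot(inherits(model, "sbml_model"))
  if (!inherits(assignment, "signal_assignment")) {
    if (is.null(target))
      stop("pass a signal_assignment(), or a signal plus target=")
    assignment <- signal_assignment(target, assignment)
  }
  tgt <- assignment$target_parameter
  out <- .copy_handle(model)
  mnode <- .model_node(out$doc)
  idx <- out$parameter_index

  if (!tgt %in% idx$id) {
    # reaction-local parameters cannot carry rules; demand explicit promotion
    loc <- .xfind(mnode, paste0(
      "./*[local-name()='listOfReactions']//*",
      "[local-name()='localParameter' or local-name()='parameter']",
      "[@id='", tgt, "']"))
    if (length(loc) > 0)
      stop("'", tgt, "' is a reaction-local parameter; promote it to a ",
           "global parameter before injecting (promote_local_parameter())")
    stop("no global parameter '", tgt, "' in the model (available: ",
         paste(idx$id, collapse = ", "), ")")
  }
  rule_type <- idx$rule[idx$id == tgt]
  if (rule_type != "" && !replace)
    stop("parameter '", tgt, "' is already governed by ", rule_type,
         " (use replace = TRUE to override an assignment rule)")
  if (rule_type != "" && replace) {
    if (rule_type != "assignment")
      stop("cannot replace a ", rule_type, " rule on '", tgt, "'")
    old <- xml2::xml_find_first(mnode, paste0(
      "./*[local-name()='listOfRules']/*[local-name()='assignmentRule']",
      "[@variable='", tgt, "']"))
    xml2::xml_remove(old)
  }

  ns_uri <- xml2::xml_ns(out$doc)[[1]]

  # (a) the shared function definition, added once per document
  fd <- xml2::xml_find_first(mnode, paste0(
    "./*[local-name()='listOfFunctionDefinitions']/*",
    "[local-name()='functionDefinition'][@id='", ISSF_FUNCTION_ID, "']"))
  if (inherits(fd, "xml_missing")) {
    lofd <- .find_or_create_list(mnode, "listOfFunctionDefinitions")
    .append_fragment(lofd, sprintf(
      "<functionDefinition xmlns=\"%s\" id=\"%s\" name=\"input signal step function\" sboTerm=\"%s\">%s</functionDefinition>",
      ns_uri, ISSF_FUNCTION_ID, .sbo_attr(assignment$sbo_term),
      .issf_lambda_mathml()))
  }

  # (b) the assignment rule
  lor <- .find_or_create_list(mnode, "listOfRules")
  .append_fragment(lor, sprintf(
    "<assignmentRule xmlns=\"%s\" variable=\"%s\" sboTerm=\"%s\">%s</assignmentRule>",
    ns_uri, tgt, .sbo_attr(assignment$sbo_term),
    mml_math(.composite_mathml(assignment$signal))))

  # (c) the target is no longer a constant
  pnode <- xml2::xml_find_first(mnode, paste0(
    "./*[local-name()='listOfParameters']/*[local-name()='parameter']",
    "[@id='", tgt, "']"))
  xml2::xml_set_attr(pnode, "constant", "false")

  .reindex(out)
}

#' Promote a reaction-local parameter to a global parameter
#'
#' SBML forbids rules on reaction-scoped parameters; promotion moves the
#' parameter to the global list (renaming is the caller's responsibility if
#' the id collides) so it can then be a signal target.
#'
#' @param model An `sbml_model` handle.
#' @param id Identifier of the local parameter.
#' @return A new handle with the parameter promoted.
#' @export
promote_local_parameter <- function(model, id) {
  stopifnot(inherits(model, "sbml_model"))
  out <- .copy_handle(model)
  mnode <- .model_node(out$doc)
  if (id %in% out$parameter_index$id)
    stop("'", id, "' already exists as a global parameter")
  loc <- xml2::xml_find_first(mnode, paste0(
    "./*[local-name()='listOfReactions']//*",
    "[local-name()='localParameter' or local-name()='parameter']",
    "[@id='", id, "']"))
  if (inherits(loc, "xml_missing"))
    stop("no reaction-local parameter '", id, "' found")
  val <- xml2::xml_attr(loc, "value")
  ns_uri <- xml2::xml_ns(out$doc)[[1]]
  lop <- .find_or_create_list(mnode, "listOfParameters")
  .append_fragment(lop, sprintf(
    "<parameter xmlns=\"%s\" id=\"%s\" value=\"%s\" constant=\"true\"/>",
    ns_uri, id, val))
  xml2::xml_remove(loc)
  .reindex(out)
}
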