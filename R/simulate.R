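# Compile an SBML model (the subset this package reads) into an ODE system
# and run it. State variables are the non-boundary, non-constant species not
# governed by assignment rules, plus any parameter or species with a rate
# rule. Assignment rules are (re)evaluated at every right-hand-side call in
# document order; reactions contribute stoichiometry-weighted kinetic-law
# rates divided by the species' compartment size.

.substitute_expr <- function(expr, vals) {
  if (is.name(expr)) {
    nm <- as.character(expr)
    if (nm %in% names(vals)) return(vals[[nm]])
    return(expr)
  }
  if (is.call(expr)) {
    expr[-1] <- lapply(as.list(expr)[-1], .substitute_expr, vals = vals)
    return(expr)
  }
  expr
}

.rule_math_expr <- function(rule_node) {
  math <- xml2::xml_find_first(rule_node, "./*[local-name()='math']")
  if (inherits(math, "xml_missing")) stop("rule without <math>")
  mathml_to_expr(math)
}

#' Compile an SBML model into an ODE system
#'
#' @param model An `sbml_model` handle.
#' @return A list with `rhs(t, y)`, initial state `y0` (named), the
#'   evaluation environment, the ordered assignment rules, and `hmax_hint`
#'   (half the shortest positive ramp of any injected step-function call,
#'   or `Inf`).
#' @keywords internal
compile_odes <- function(model) {
  stopifnot(inherits(model, "sbml_model"))
  mnode <- .model_node(model$doc)
  ev <- new.env(parent = baseenv())

  # function definitions
  fds <- .xfind(mnode, paste0("./*[local-name()='listOfFunctionDefinitions']",
                              "/*[local-name()='functionDefinition']"))
  for (fd in fds) {
    id <- xml2::xml_attr(fd, "id")
    math <- xml2::xml_find_first(fd, "./*[local-name()='math']")
    assign(id, lambda_to_function(math, ev), envir = ev)
  }

  # compartments
  comps <- .xfind(mnode, paste0("./*[local-name()='listOfCompartments']",
                                "/*[local-name()='compartment']"))
  comp_size <- stats::setNames(
    vapply(comps, function(cn) {
      s <- .num_attr(cn, "size", default = .num_attr(cn, "volume", 1))
      if (is.na(s)) 1 else s
    }, numeric(1)),
    xml2::xml_attr(comps, "id"))
  for (id in names(comp_size)) assign(id, comp_size[[id]], envir = ev)

  governed <- .governed_variables(mnode)

  # species
  sps <- .xfind(mnode,
    "./*[local-name()='listOfSpecies']/*[local-name()='species']")
  sp_ids <- xml2::xml_attr(sps, "id")
  sp_init <- vapply(sps, function(s) {
    v <- .num_attr(s, "initialConcentration")
    if (is.na(v)) {
      amt <- .num_attr(s, "initialAmount")
      sz <- comp_size[xml2::xml_attr(s, "compartment")]
      v <- if (is.na(amt)) 0 else amt / ifelse(is.na(sz), 1, sz)
    }
    v
  }, numeric(1))
  names(sp_init) <- sp_ids
  sp_comp <- stats::setNames(xml2::xml_attr(sps, "compartment"), sp_ids)
  sp_fixed <- stats::setNames(
    xml2::xml_attr(sps, "boundaryCondition") %in% "true" |
      xml2::xml_attr(sps, "constant") %in% "true", sp_ids)

  # parameters
  idx <- model$parameter_index
  for (i in seq_len(nrow(idx)))
    assign(idx$id[i],
           if (is.na(idx$value[i])) 0 else idx$value[i], envir = ev)
  for (id in sp_ids) assign(id, sp_init[[id]], envir = ev)

  # rules, in document order
  rules <- .xfind(mnode, "./*[local-name()='listOfRules']/*")
  assign_rules <- list()
  rate_rules <- list()
  for (r in rules) {
    nm <- xml2::xml_name(r)
    var <- xml2::xml_attr(r, "variable")
    if (nm == "assignmentRule") {
      assign_rules[[length(assign_rules) + 1]] <-
        list(var = var, expr = .rule_math_expr(r))
    } else if (nm == "rateRule") {
      rate_rules[[length(rate_rules) + 1]] <-
        list(var = var, expr = .rule_math_expr(r))
    } else if (nm == "algebraicRule") {
      stop("algebraic rules are not supported")
    }
  }

  # reactions
  rxns <- .xfind(mnode,
    "./*[local-name()='listOfReactions']/*[local-name()='reaction']")
  reaction_list <- lapply(rxns, function(rx) {
    kl <- xml2::xml_find_first(rx, "./*[local-name()='kineticLaw']")
    if (inherits(kl, "xml_missing"))
      stop("reaction '", xml2::xml_attr(rx, "id"), "' has no kinetic law")
    math <- xml2::xml_find_first(kl, "./*[local-name()='math']")
    expr <- mathml_to_expr(math)
    # inline reaction-local parameters (they shadow globals inside the law)
    locals <- .xfind(kl, paste0(".//*[local-name()='localParameter' or ",
                                "local-name()='parameter']"))
    if (length(locals) > 0) {
      vals <- stats::setNames(
        as.list(vapply(locals, .num_attr, numeric(1), attr = "value")),
        xml2::xml_attr(locals, "id"))
      expr <- .substitute_expr(expr, vals)
    }
    grab <- function(listname) {
      refs <- .xfind(rx, paste0("./*[local-name()='", listname,
                                "']/*[local-name()='speciesReference']"))
      data.frame(species = xml2::xml_attr(refs, "species"),
                 stoich = vapply(refs, .num_attr, numeric(1),
                                 attr = "stoichiometry", default = 1),
                 stringsAsFactors = FALSE)
    }
    list(expr = expr, reactants = grab("listOfReactants"),
         products = grab("listOfProducts"))
  })

  # state vector: dynamic species + rate-ruled parameters
  assigned_vars <- vapply(assign_rules, `[[`, character(1), "var")
  rate_vars <- vapply(rate_rules, `[[`, character(1), "var")
  dyn_species <- sp_ids[!sp_fixed[sp_ids] & !(sp_ids %in% assigned_vars)]
  state_ids <- unique(c(dyn_species, rate_vars))
  y0 <- vapply(state_ids, function(id)
    get(id, envir = ev), numeric(1))
  n <- length(state_ids)
  if (n == 0) stop("model has no dynamic state (nothing to integrate)")

  rate_expr_for <- stats::setNames(lapply(rate_rules, `[[`, "expr"),
                                   rate_vars)
  # per-reaction derivative wiring: (state index, +/- stoich / compartment)
  wiring <- lapply(reaction_list, function(rl) {
    tgt <- integer(0); coef <- numeric(0)
    add <- function(df, sign) {
      for (j in seq_len(nrow(df))) {
        sid <- df$species[j]
        if (sid %in% state_ids) {
          tgt <<- c(tgt, match(sid, state_ids))
          size <- comp_size[sp_comp[sid]]
          coef <<- c(coef, sign * df$stoich[j] / ifelse(is.na(size), 1, size))
        }
      }
    }
    add(rl$reactants, -1); add(rl$products, +1)
    list(expr = rl$expr, tgt = tgt, coef = coef)
  })

  rhs <- function(t, y) {
    assign("time", t, envir = ev)
    for (j in seq_len(n)) assign(state_ids[j], y[j], envir = ev)
    for (ar in assign_rules)
      assign(ar$var, eval(ar$expr, ev), envir = ev)
    dy <- numeric(n)
    for (w in wiring) {
      if (length(w$tgt) == 0) next
      rate <- eval(w$expr, ev)
      dy[w$tgt] <- dy[w$tgt] + w$coef * rate
    }
    for (j in seq_len(n)) {
      id <- state_ids[j]
      if (!is.null(rate_expr_for[[id]]))
        dy[j] <- dy[j] + eval(rate_expr_for[[id]], ev)
    }
    dy
  }

  # bound on internal steps: half the shortest positive ramp of any
  # injected issf(...) call found in the assignment rules
  ramps <- unlist(lapply(assign_rules, function(ar)
    .collect_issf_ramps(ar$expr)))
  ramps <- ramps[is.finite(ramps) & ramps > 0]
  hmax_hint <- if (length(ramps)) min(ramps) / 2 else Inf

  list(rhs = rhs, y0 = y0, env = ev, assign_rules = assign_rules,
       state_ids = state_ids, hmax_hint = hmax_hint)
}

# walk an expression for calls issf(time, theta0, theta1, tP, tC, tR, phi)
# and collect the numeric ramp arguments
.collect_issf_ramps <- function(expr) {
  out <- numeric(0)
  walk <- function(e) {
    if (is.call(e)) {
      if (identical(e[[1]], as.name(ISSF_FUNCTION_ID)) && length(e) == 8) {
        tr <- e[[7]]
        if (is.numeric(tr)) out <<- c(out, tr)
      }
      for (a in as.list(e)[-1]) walk(a)
    }
  }
  walk(expr)
  out
}

#' Simulate an SBML model
#'
#' Deterministic ODE trajectory of all dynamic species and rate-ruled
#' parameters, plus every assignment-ruled symbol (e.g. an injected signal
#' parameter) evaluated on the output grid. Internal integrator steps are
#' bounded above by half the shortest ramp of any injected signal so ramps
#' are never stepped over.
#'
#' @param model An `sbml_model` handle.
#' @param t_end End time, hours.
#' @param output_step Output sampling interval, hours.
#' @param t_start Start time (default 0).
#' @param atol,rtol Integrator tolerances (defaults 1e-9 / 1e-7).
#' @param hmax Override for the maximum internal step; default derives it
#'   from the injected signals.
#' @return An `issf_timeseries` with columns `time`, the state variables,
#'   then the assignment-ruled symbols.
#' @export
simulate_model <- function(model, t_end, output_step = 0.1, t_start = 0,
                           atol = 1e-9, rtol = 1e-7, hmax = NULL) {
  if (t_end <= t_start) stop("t_end must exceed t_start")
  sys <- compile_odes(model)
  if (is.null(hmax)) hmax <- sys$hmax_hint
  times <- seq(t_start, t_end, by = output_step)
  if (times[length(times)] < t_end) times <- c(times, t_end)
  res <- tryCatch(
    ode_integrate(sys$rhs, sys$y0, times, atol = atol, rtol = rtol,
                  hmax = hmax),
    error = function(e) stop("integration failed: ", conditionMessage(e)))
  df <- as.data.frame(res)
  # evaluate assignment rules on the output grid
  for (ar in sys$assign_rules) {
    vals <- numeric(nrow(df))
    for (i in seq_len(nrow(df))) {
      assign("time", df$time[i], envir = sys$env)
      for (id in sys$state_ids)
        assign(id, df[[id]][i], envir = sys$env)
      for (ar2 in sys$assign_rules)
        assign(ar2$var, eval(ar2$expr, sys$env), envir = sys$env)
      vals[i] <- get(ar$var, envir = sys$env)
    }
    df[[ar$var]] <- vals
  }
  as_timeseries(df)
}
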