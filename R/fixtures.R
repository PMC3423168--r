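# Self-contained SBML fixtures so every protocol runs without downloads:
# a Goodwin-type circadian oscillator (negative feedback X -> Y -> Z -| X
# with Hill repression and saturable degradation) standing in for published
# clock models, and a one-species accumulator whose state equals the time
# integral of its forcing signal -- the analytic oracle for the simulator.

#' Frozen rate constants of the Goodwin fixture
#'
#' Calibrated once to a free-running period of 22.0 h (all first-order
#' rates scaled uniformly, an exact time rescaling) and frozen so fixture
#' behaviour is deterministic across installs. Michaelis-type degradation
#' lets the loop oscillate at Hill coefficient 4. Time is in hours,
#' concentrations in arbitrary units.
#'
#' @format Named numeric vector of 10 rate constants (v1, K1, v2, K2, k3,
#'   v4, K4, k5, v6, K6).
#' @export
GOODWIN_DEFAULT_RATES <- c(
  v1 = 0.752443, K1 = 1, v2 = 0.3762215, K2 = 1,
  k3 = 0.752443, v4 = 0.3762215, K4 = 1,
  k5 = 0.752443, v6 = 0.3762215, K6 = 1)

#' Configuration of the Goodwin oscillator fixture
#'
#' @param free_running_period Target intrinsic period in constant darkness,
#'   hours; the shipped default rate constants are calibrated to ~22 h.
#' @param light_parameter_id Identifier of the forcing parameter.
#' @param light_coupling `"production"` (light adds to X production, the
#'   default: the simplest mechanism yielding type-1-like phase response)
#'   or `"degradation"` (light scales Z degradation).
#' @param hill_coefficient Integer Hill coefficient of the repression,
#'   >= 4 for sustained oscillation with the default rates.
#' @param rates Named numeric vector of rate constants (see
#'   `GOODWIN_DEFAULT_RATES`); all must be positive.
#' @return An object of class `goodwin_config`.
#' @export
goodwin_config <- function(free_running_period = 22,
                           light_parameter_id = "L",
                           light_coupling = c("production", "degradation"),
                           hill_coefficient = 4L,
                           rates = GOODWIN_DEFAULT_RATES) {
  light_coupling <- match.arg(light_coupling)
  need <- names(GOODWIN_DEFAULT_RATES)
  if (!all(need %in% names(rates)))
    stop("rates must include: ", paste(need, collapse = ", "))
  rates <- rates[need]
  if (any(rates <= 0)) stop("all rate constants must be positive")
  hill_coefficient <- as.integer(hill_coefficient)
  if (hill_coefficient < 1) stop("hill_coefficient must be >= 1")
  structure(list(free_running_period = free_running_period,
                 light_parameter_id = light_parameter_id,
                 light_coupling = light_coupling,
                 hill_coefficient = hill_coefficient,
                 rates = rates),
            class = "goodwin_config")
}

.sbml_skeleton <- function(model_id, species, parameters, body) {
  sp <- paste0(vapply(names(species), function(id) sprintf(
    paste0("<species id=\"%s\" compartment=\"cell\" initialConcentration=\"%s\"",
           " hasOnlySubstanceUnits=\"false\" boundaryCondition=\"false\"",
           " constant=\"false\"/>"),
    id, format(species[[id]], digits = 15)), character(1)), collapse = "")
  par <- paste0(vapply(names(parameters), function(id) sprintf(
    "<parameter id=\"%s\" value=\"%s\" constant=\"true\"/>",
    id, format(parameters[[id]], digits = 15)), character(1)), collapse = "")
  sprintf(paste0(
    "<sbml xmlns=\"%s\" level=\"3\" version=\"1\">",
    "<model id=\"%s\" timeUnits=\"time\">",
    "<listOfCompartments>",
    "<compartment id=\"cell\" spatialDimensions=\"3\" size=\"1\" constant=\"true\"/>",
    "</listOfCompartments>",
    "<listOfSpecies>%s</listOfSpecies>",
    "<listOfParameters>%s</listOfParameters>",
    "%s</model></sbml>"),
    SBML_L3V1_NS, model_id, sp, par, body)
}

.reaction_xml <- function(id, reactants, products, law_mathml) {
  ref <- function(ids) paste0(vapply(ids, function(s) sprintf(
    "<speciesReference species=\"%s\" stoichiometry=\"1\" constant=\"true\"/>",
    s), character(1)), collapse = "")
  paste0("<reaction id=\"", id, "\" reversible=\"false\" fast=\"false\">",
         if (length(reactants)) paste0("<listOfReactants>", ref(reactants),
                                       "</listOfReactants>") else "",
         if (length(products)) paste0("<listOfProducts>", ref(products),
                                      "</listOfProducts>") else "",
         "<kineticLaw>", mml_math(law_mathml), "</kineticLaw>",
         "</reaction>")
}

#' Build the Goodwin oscillator fixture
#'
#' Emits a three-variable negative-feedback oscillator as SBML Level 3
#' Version 1: X is produced under Hill repression by Z, X drives Y, Y
#' drives Z, and each variable decays by saturable (Michaelis-type)
#' degradation. The light parameter enters additively in X production (or
#' multiplicatively in Z degradation) and defaults to 0, i.e. constant
#' darkness. With default settings the free-running period is ~22 h and
#' moderate 24-h forcing entrains the oscillator 1:1.
#'
#' @param config A [goodwin_config()].
#' @param check If `TRUE` (default), simulate the unforced model and verify
#'   sustained oscillation (period finite, amplitude non-decaying),
#'   stopping with diagnostics on calibration failure.
#' @return An `sbml_model` handle.
#' @export
make_goodwin_oscillator <- function(config = goodwin_config(), check = TRUE) {
  stopifnot(inherits(config, "goodwin_config"))
  r <- as.list(config$rates)
  n <- config$hill_coefficient
  Lid <- config$light_parameter_id

  hill <- mml_apply("divide",
    mml_apply("times", mml_ci("v1"), mml_apply("power", mml_ci("K1"), mml_cn(n))),
    mml_apply("plus", mml_apply("power", mml_ci("K1"), mml_cn(n)),
              mml_apply("power", mml_ci("Z"), mml_cn(n))))
  prodX <- if (config$light_coupling == "production")
    mml_apply("plus", hill, mml_ci(Lid)) else hill
  mm <- function(v, K, S) mml_apply("divide",
    mml_apply("times", mml_ci(v), mml_ci(S)),
    mml_apply("plus", mml_ci(K), mml_ci(S)))
  degZ <- if (config$light_coupling == "degradation")
    mml_apply("times", mm("v6", "K6", "Z"),
              mml_apply("plus", mml_cn(1), mml_ci(Lid)))
  else mm("v6", "K6", "Z")

  reactions <- paste0(
    .reaction_xml("production_X", character(0), "X", prodX),
    .reaction_xml("degradation_X", "X", character(0), mm("v2", "K2", "X")),
    .reaction_xml("production_Y", character(0), "Y",
                  mml_apply("times", mml_ci("k3"), mml_ci("X"))),
    .reaction_xml("degradation_Y", "Y", character(0), mm("v4", "K4", "Y")),
    .reaction_xml("production_Z", character(0), "Z",
                  mml_apply("times", mml_ci("k5"), mml_ci("Y"))),
    .reaction_xml("degradation_Z", "Z", character(0), degZ))

  params <- c(r, stats::setNames(list(0), Lid))
  xml <- .sbml_skeleton("goodwin_fixture",
                        species = list(X = 0.1, Y = 0.2, Z = 1.5),
                        parameters = params,
                        body = paste0("<listOfReactions>", reactions,
                                      "</listOfReactions>"))
  h <- load_model(xml)
  if (check) .check_oscillation(h, config)
  h
}

# Calibration check: unforced model must show sustained, non-decaying
# oscillation with a sensible period after the transient.
.check_oscillation <- function(h, config) {
  ts <- simulate_model(h, t_end = 280, output_step = 0.2)
  pk <- tryCatch(detect_peaks(ts, "X", after = 60),
                 error = function(e) numeric(0))
  if (length(pk) < 5)
    stop("calibration failure: the unforced oscillator shows ",
         length(pk), " peak(s) in 60-280 h; no sustained oscillation ",
         "(hill_coefficient = ", config$hill_coefficient,
         " may be below the oscillation threshold)")
  heights <- vapply(pk, function(t0)
    max(ts$X[abs(ts$time - t0) <= 0.5]), numeric(1))
  trough <- min(ts$X[ts$time >= 60])
  amp_first <- heights[2] - trough
  amp_last <- heights[length(heights) - 1] - trough
  if (!is.finite(amp_last) || amp_last < 0.8 * amp_first)
    stop("calibration failure: oscillation amplitude decays (",
         format(amp_first, digits = 4), " -> ", format(amp_last, digits = 4),
         " over the probed window); increase the Hill coefficient")
  invisible(h)
}

#' Build the accumulator fixture
#'
#' A one-species model `dx/dt = L(t)`, `x(0) = 0`, with `L` a controllable
#' parameter. After signal injection, `x(t)` is the exact running integral
#' of the signal, so the simulated terminal value can be compared against
#' the closed-form [period_integral()] -- the analytic correctness oracle
#' for the whole inject-and-simulate pipeline.
#'
#' @param light_parameter_id Identifier of the forcing parameter.
#' @return An `sbml_model` handle.
#' @export
make_accumulator_model <- function(light_parameter_id = "L") {
  body <- paste0("<listOfRules><rateRule variable=\"x\">",
                 mml_math(mml_ci(light_parameter_id)),
                 "</rateRule></listOfRules>")
  xml <- .sbml_skeleton("accumulator",
                        species = list(x = 0),
                        parameters = stats::setNames(list(0),
                                                     light_parameter_id),
                        body = body)
  load_model(xml)
}
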