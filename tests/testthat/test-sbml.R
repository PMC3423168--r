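test_that("fixture models load with their light parameter indexed", {
  acc <- make_accumulator_model()
  expect_s3_class(acc, "sbml_model")
  expect_equal(acc$level, 3L)
  expect_true("L" %in% acc$parameter_index$id)
  expect_true("L" %in% list_controllable_parameters(acc))

  gw <- cached_goodwin()
  expect_true("L" %in% list_controllable_parameters(gw))
})

test_that("malformed or unsuitable documents are rejected with clear errors", {
  bad <- tempfile(fileext = ".xml")
  writeLines("<sbml><model><unclosed>", bad)
  expect_error(load_model(bad), "parse")

  notsbml <- tempfile(fileext = ".xml")
  writeLines("<foo/>", notsbml)
  expect_error(load_model(notsbml), "not an SBML")

  expect_error(load_model(tempfile()), "not found")

  noparams <- paste0(
    "<sbml xmlns=\"http://www.sbml.org/sbml/level3/version1/core\" ",
    "level=\"3\" version=\"1\"><model id=\"m\"/></sbml>")
  expect_error(load_model(noparams), "no global parameters")
})

test_that("write/load round trip preserves the parameter index", {
  acc <- make_accumulator_model()
  path <- tempfile(fileext = ".xml")
  write_model(acc, path)
  again <- load_model(path)
  expect_equal(again$parameter_index, acc$parameter_index)
  expect_error(write_model(acc, file.path(tempfile(), "x.xml")),
               "does not exist")
})

test_that("injection adds exactly one function definition and one rule", {
  acc <- make_accumulator_model()
  p <- issf_params(0, 1, 8, 24, 0.1, 0)
  inj <- inject_issf(acc, signal_assignment("L", p))

  xml <- as.character(inj$doc)
  expect_equal(length(gregexpr("<functionDefinition", xml)[[1]]), 1)
  expect_equal(length(gregexpr("<assignmentRule", xml)[[1]]), 1)
  # target parameter is no longer constant nor controllable
  idx <- inj$parameter_index
  expect_false(idx$constant[idx$id == "L"])
  expect_equal(idx$rule[idx$id == "L"], "assignment")
  expect_false("L" %in% list_controllable_parameters(inj))
  # the original handle is untouched
  expect_true("L" %in% list_controllable_parameters(acc))
})

test_that("injected function definition carries the SBO:0000475 annotation", {
  acc <- make_accumulator_model()
  inj <- inject_issf(acc, signal_assignment("L", issf_params(0, 1, 8, 24)))
  fd <- xml2::xml_find_first(inj$doc,
    "//*[local-name()='functionDefinition']")
  expect_equal(xml2::xml_attr(fd, "sboTerm"), "SBO:0000475")
  # and it survives a disk round trip
  path <- tempfile(fileext = ".xml")
  write_model(inj, path)
  again <- load_model(path)
  fd2 <- xml2::xml_find_first(again$doc,
    "//*[local-name()='functionDefinition']")
  expect_equal(xml2::xml_attr(fd2, "sboTerm"), "SBO:0000475")
  expect_equal(again$parameter_index, inj$parameter_index)
})

test_that("re-injection without replace errors instead of stacking rules", {
  acc <- make_accumulator_model()
  p <- issf_params(0, 1, 8, 24)
  inj <- inject_issf(acc, signal_assignment("L", p))
  expect_error(inject_issf(inj, signal_assignment("L", p)),
               "already governed")
  # explicit replacement keeps exactly one rule
  inj2 <- inject_issf(inj, signal_assignment("L", issf_params(0, 2, 6, 24)),
                      replace = TRUE)
  xml <- as.character(inj2$doc)
  expect_equal(length(gregexpr("<assignmentRule", xml)[[1]]), 1)
})

test_that("injection errors on unknown targets and leaves the rest intact", {
  gw <- cached_goodwin()
  expect_error(inject_issf(gw, signal_assignment("nope", issf_params())),
               "no global parameter 'nope'")
  inj <- inject_issf(gw, signal_assignment("L", issf_params(0, 0.1, 12, 24)))
  # deep diff: only the documented changes appear
  before <- xml2::xml_find_all(gw$doc, "//*[local-name()='reaction']")
  after <- xml2::xml_find_all(inj$doc, "//*[local-name()='reaction']")
  expect_equal(as.character(after), as.character(before))
  sp_b <- xml2::xml_find_all(gw$doc, "//*[local-name()='species']")
  sp_a <- xml2::xml_find_all(inj$doc, "//*[local-name()='species']")
  expect_equal(as.character(sp_a), as.character(sp_b))
  other <- setdiff(gw$parameter_index$id, "L")
  expect_equal(inj$parameter_index[inj$parameter_index$id %in% other, ],
               gw$parameter_index[gw$parameter_index$id %in% other, ])
})

test_that("simulated rule trajectory equals direct evaluation (MathML round trip)", {
  acc <- make_accumulator_model()
  # single signal
  p <- issf_params(0.5, 1.5, 12, 24, 1, 0)
  inj <- inject_issf(acc, signal_assignment("L", p))
  ts <- simulate_model(inj, t_end = 48, output_step = 0.05)
  expect_lt(max(abs(ts$L - issf_value(p, ts$time))), 1e-6)

  # schedule + pulse composite, sum combiner
  sched <- issf_schedule(c(0, 48), list(issf_params(1.6, 0.4, 12, 24, 0.1, 0),
                                        issf_params(1.6, 0, 12, 24, 0.1, 0)))
  pulse <- issf_params(0, 0.4, 12, 360, 0.1, -60)
  comp <- issf_composite(list(sched, pulse))
  inj2 <- inject_issf(acc, signal_assignment("L", comp))
  ts2 <- simulate_model(inj2, t_end = 100, output_step = 0.05)
  expect_lt(max(abs(ts2$L - issf_value(comp, ts2$time))), 1e-6)

  # square wave (ramp 0) through the same pipeline
  sq <- issf_params(1, 2, 6, 24, 0, -1)
  inj3 <- inject_issf(acc, signal_assignment("L", sq))
  ts3 <- simulate_model(inj3, t_end = 48, output_step = 0.05, hmax = 0.25)
  expect_lt(max(abs(ts3$L - issf_value(sq, ts3$time))), 1e-6)

  # product and max combiners survive the MathML encoding too
  a <- issf_params(1, 1, 6, 24, 0.5, 0)
  b <- issf_params(0.5, 2, 10, 24, 1, -3)
  for (cmb in c("product", "max")) {
    cc <- issf_composite(list(a, b), cmb)
    injc <- inject_issf(acc, signal_assignment("L", cc))
    tsc <- simulate_model(injc, t_end = 48, output_step = 0.1)
    expect_lt(max(abs(tsc$L - issf_value(cc, tsc$time))), 1e-6)
  }
})

test_that("local parameters cannot be targeted and can be promoted", {
  xml <- paste0(
    "<sbml xmlns=\"http://www.sbml.org/sbml/level3/version1/core\" ",
    "level=\"3\" version=\"1\"><model id=\"m\">",
    "<listOfCompartments><compartment id=\"c\" size=\"1\" constant=\"true\"/></listOfCompartments>",
    "<listOfSpecies><species id=\"s\" compartment=\"c\" initialConcentration=\"1\" ",
    "hasOnlySubstanceUnits=\"false\" boundaryCondition=\"false\" constant=\"false\"/></listOfSpecies>",
    "<listOfParameters><parameter id=\"g\" value=\"1\" constant=\"true\"/></listOfParameters>",
    "<listOfReactions><reaction id=\"r\" reversible=\"false\" fast=\"false\">",
    "<listOfReactants><speciesReference species=\"s\" stoichiometry=\"1\" constant=\"true\"/></listOfReactants>",
    "<kineticLaw><math xmlns=\"http://www.w3.org/1998/Math/MathML\">",
    "<apply><times/><ci> kloc </ci><ci> s </ci></apply></math>",
    "<listOfLocalParameters><localParameter id=\"kloc\" value=\"0.1\"/></listOfLocalParameters>",
    "</kineticLaw></reaction></listOfReactions></model></sbml>")
  m <- load_model(xml)
  expect_error(inject_issf(m, signal_assignment("kloc", issf_params())),
               "promote")
  m2 <- promote_local_parameter(m, "kloc")
  expect_true("kloc" %in% list_controllable_parameters(m2))
  inj <- inject_issf(m2, signal_assignment("kloc", issf_params(0, 1, 6, 24)))
  expect_equal(inj$parameter_index$rule[inj$parameter_index$id == "kloc"],
               "assignment")
})
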