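# MathML <-> R expression machinery for the SBML subset this package reads
# and writes: arithmetic, relational and boolean operators, floor and
# friends, piecewise, ci/cn, csymbol time, and user function applications.
# Piecewise is compiled to nested `if` calls, so unused branches are never
# evaluated (a ramp term with ramp_duration = 0 must not divide by zero).

SBML_TIME_URL <- "http://www.sbml.org/sbml/symbols/time"
MATHML_NS <- "http://www.w3.org/1998/Math/MathML"

.mathml_binops <- c(plus = "+", minus = "-", times = "*", divide = "/",
                    power = "^")
.mathml_relops <- c(lt = "<", leq = "<=", gt = ">", geq = ">=",
                    eq = "==", neq = "!=")
.mathml_funs <- c(floor = "floor", ceiling = "ceiling", abs = "abs",
                  exp = "exp", ln = "log", sin = "sin", cos = "cos",
                  tan = "tan", arctan = "atan", arcsin = "asin",
                  arccos = "acos")

.cn_value <- function(node) {
  type <- xml2::xml_attr(node, "type")
  txt <- xml2::xml_text(node, trim = TRUE)
  if (!is.na(type) && type == "e-notation") {
    parts <- strsplit(txt, "\\s+")[[1]]
    parts <- parts[nzchar(parts)]
    return(as.numeric(parts[1]) * 10^as.numeric(parts[2]))
  }
  if (!is.na(type) && type == "rational") {
    parts <- strsplit(txt, "\\s+")[[1]]
    parts <- parts[nzchar(parts)]
    return(as.numeric(parts[1]) / as.numeric(parts[2]))
  }
  as.numeric(txt)
}

.node_to_expr <- function(node) {
  name <- xml2::xml_name(node)
  switch(name,
    math = {
      kids <- xml2::xml_children(node)
      if (length(kids) != 1) stop("<math> must have exactly one child")
      .node_to_expr(kids[[1]])
    },
    cn = .cn_value(node),
    ci = as.name(xml2::xml_text(node, trim = TRUE)),
    csymbol = {
      url <- xml2::xml_attr(node, "definitionURL")
      if (identical(url, SBML_TIME_URL)) as.name("time")
      else stop("unsupported csymbol: ", url)
    },
    true = TRUE,
    false = FALSE,
    pi = pi,
    exponentiale = exp(1),
    notanumber = NaN,
    infinity = Inf,
    apply = .apply_to_expr(node),
    piecewise = .piecewise_to_expr(node),
    lambda = stop("<lambda> only allowed at a function definition root"),
    stop("unsupported MathML element: <", name, ">")
  )
}

.apply_to_expr <- function(node) {
  kids <- xml2::xml_children(node)
  if (length(kids) < 1) stop("empty <apply>")
  head <- kids[[1]]
  op <- xml2::xml_name(head)

  if (op == "log") {
    rest <- kids[-1]
    base <- 10
    is_lb <- vapply(rest, function(k) xml2::xml_name(k) == "logbase",
                    logical(1))
    if (any(is_lb)) {
      base <- eval(.node_to_expr(xml2::xml_children(rest[is_lb][[1]])[[1]]))
      rest <- rest[!is_lb]
    }
    args <- lapply(rest, .node_to_expr)
    return(as.call(c(as.name("log"), args, list(base = base))))
  }
  if (op == "root") {
    rest <- kids[-1]
    deg <- 2
    is_dg <- vapply(rest, function(k) xml2::xml_name(k) == "degree",
                    logical(1))
    if (any(is_dg)) {
      deg <- eval(.node_to_expr(xml2::xml_children(rest[is_dg][[1]])[[1]]))
      rest <- rest[!is_dg]
    }
    args <- lapply(rest, .node_to_expr)
    return(as.call(list(as.name("^"), args[[1]], 1 / deg)))
  }

  args <- lapply(kids[-1], .node_to_expr)

  if (op %in% names(.mathml_binops)) {
    sym <- as.name(.mathml_binops[[op]])
    if (op == "minus" && length(args) == 1)
      return(as.call(c(sym, args)))          # unary minus
    if (length(args) == 0) stop("<", op, "> needs arguments")
    if (length(args) == 1) return(args[[1]])
    return(Reduce(function(a, b) as.call(list(sym, a, b)), args))
  }
  if (op %in% names(.mathml_relops)) {
    if (length(args) != 2) stop("relational <", op, "> needs 2 arguments")
    return(as.call(c(as.name(.mathml_relops[[op]]), args)))
  }
  if (op %in% names(.mathml_funs)) {
    return(as.call(c(as.name(.mathml_funs[[op]]), args)))
  }
  switch(op,
    and = Reduce(function(a, b) as.call(list(as.name("&&"), a, b)), args),
    or  = Reduce(function(a, b) as.call(list(as.name("||"), a, b)), args),
    xor = as.call(c(as.name("xor"), args)),
    not = as.call(c(as.name("!"), args)),
    ci  = as.call(c(as.name(xml2::xml_text(head, trim = TRUE)), args)),
    stop("unsupported MathML operator: <", op, ">")
  )
}

.piecewise_to_expr <- function(node) {
  kids <- xml2::xml_children(node)
  pieces <- list()
  otherwise <- NaN
  for (k in kids) {
    nm <- xml2::xml_name(k)
    ck <- xml2::xml_children(k)
    if (nm == "piece") {
      if (length(ck) != 2) stop("<piece> needs value and condition")
      pieces[[length(pieces) + 1]] <-
        list(value = .node_to_expr(ck[[1]]), cond = .node_to_expr(ck[[2]]))
    } else if (nm == "otherwise") {
      otherwise <- .node_to_expr(ck[[1]])
    } else stop("unexpected <", nm, "> inside <piecewise>")
  }
  expr <- otherwise
  for (p in rev(pieces))
    expr <- as.call(list(as.name("if"), p$cond, p$value, expr))
  expr
}

#' Convert an SBML MathML node to an R expression
#'
#' @param math An `xml2` node: either the `<math>` element or its content.
#' @return An R language object (or a numeric constant). `time` appears as
#'   the symbol `time`; user function applications as ordinary calls.
#' @keywords internal
mathml_to_expr <- function(math) .node_to_expr(math)

# Convert a <lambda> function definition body into an R function whose
# enclosing environment is `env` (so it can call other function definitions).
lambda_to_function <- function(math_node, env) {
  kids <- xml2::xml_children(math_node)
  if (length(kids) != 1 || xml2::xml_name(kids[[1]]) != "lambda")
    stop("function definition <math> must contain a single <lambda>")
  lam <- xml2::xml_children(kids[[1]])
  argnames <- character(0)
  body_expr <- NULL
  for (k in lam) {
    if (xml2::xml_name(k) == "bvar") {
      argnames <- c(argnames, xml2::xml_text(k, trim = TRUE))
    } else {
      if (!is.null(body_expr)) stop("<lambda> has multiple body expressions")
      body_expr <- .node_to_expr(k)
    }
  }
  if (is.null(body_expr)) stop("<lambda> has no body")
  args <- stats::setNames(rep(list(quote(expr = )), length(argnames)), argnames)
  as.function(c(args, body_expr), envir = env)
}

# ---- MathML builders (writing) ---------------------------------------------
# These emit plain MathML strings; the enclosing <math> carries the MathML
# namespace so fragments can be parsed and inserted into an SBML document.

mml_cn <- function(x) {
  if (is.finite(x) && x == round(x) && abs(x) < 1e15)
    sprintf("<cn type=\"integer\"> %d </cn>", as.integer(x))
  else
    sprintf("<cn> %s </cn>", format(x, digits = 17))
}

mml_ci <- function(name) sprintf("<ci> %s </ci>", name)

mml_time <- function()
  sprintf("<csymbol encoding=\"text\" definitionURL=\"%s\"> time </csymbol>",
          SBML_TIME_URL)

mml_apply <- function(op, ...) {
  paste0("<apply><", op, "/>", paste0(c(...), collapse = ""), "</apply>")
}

mml_call <- function(fname, ...) {
  paste0("<apply>", mml_ci(fname), paste0(c(...), collapse = ""), "</apply>")
}

mml_piecewise <- function(pieces, otherwise = NULL) {
  body <- paste0(vapply(pieces, function(p)
    paste0("<piece>", p$value, p$cond, "</piece>"), character(1)),
    collapse = "")
  if (!is.null(otherwise))
    body <- paste0(body, "<otherwise>", otherwise, "</otherwise>")
  paste0("<piecewise>", body, "</piecewise>")
}

mml_math <- function(content) {
  paste0("<math xmlns=\"", MATHML_NS, "\">", content, "</math>")
}
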