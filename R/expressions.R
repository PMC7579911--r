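# Arithmetic expression layer: model right-hand sides, objectives and
# constraints are written as strings in a small grammar (+, -, *, /, ^,
# parentheses, numeric literals, symbol references and a few elementary
# functions). Expressions are parsed once, validated against the problem's
# symbol table, and differentiated symbolically with stats::D().

.allowed_calls <- c("+", "-", "*", "/", "^", "(", "exp", "log", "sqrt",
                    "sin", "cos", "tan")

#' Parse a model expression
#'
#' Parses a scalar arithmetic expression given as a string and checks that it
#' only uses the documented grammar: binary/unary \code{+ - * / ^},
#' parentheses, numeric literals, symbol references and the elementary
#' functions \code{exp, log, sqrt, sin, cos, tan}.
#'
#' @param text character scalar with the expression.
#' @param allowed character vector of symbol names that may be referenced;
#'   if \code{NULL}, symbol resolution is not checked.
#' @param what label used in error messages.
#' @return the parsed expression (an R call or name or literal).
#' @export
parse_model_expr <- function(text, allowed = NULL, what = "expression") {
  if (is.numeric(text) && length(text) == 1L) return(as.numeric(text))
  stopifnot(is.character(text), length(text) == 1L)
  ex <- tryCatch(str2lang(text),
                 error = function(e) stop("cannot parse ", what, " '", text,
                                          "': ", conditionMessage(e),
                                          call. = FALSE))
  check_expr_grammar(ex, allowed, what = what, src = text)
  ex
}

check_expr_grammar <- function(ex, allowed, what, src) {
  if (is.numeric(ex) || is.integer(ex)) return(invisible(TRUE))
  if (is.name(ex)) {
    nm <- as.character(ex)
    if (!is.null(allowed) && !(nm %in% allowed))
      stop("symbol '", nm, "' in ", what, " '", src,
           "' does not resolve to a state, control, parameter or t",
           call. = FALSE)
    return(invisible(TRUE))
  }
  if (is.call(ex)) {
    fn <- as.character(ex[[1L]])
    if (!(fn %in% .allowed_calls))
      stop("function or operator '", fn, "' in ", what, " '", src,
           "' is outside the supported grammar", call. = FALSE)
    for (k in seq_along(ex)[-1L]) check_expr_grammar(ex[[k]], allowed, what, src)
    return(invisible(TRUE))
  }
  stop("unsupported construct in ", what, " '", src, "'", call. = FALSE)
}

# Symbols referenced by an expression.
expr_symbols <- function(ex) {
  if (is.name(ex)) return(as.character(ex))
  if (is.call(ex)) {
    fn <- setdiff(unlist(lapply(as.list(ex)[-1L], expr_symbols)), character(0))
    return(unique(fn))
  }
  character(0)
}

# Symbolic partial derivative; returns NULL when identically zero, which
# callers use to keep sparsity patterns tight.
expr_deriv <- function(ex, var) {
  if (is.numeric(ex)) return(NULL)
  if (!(var %in% expr_symbols(ex))) return(NULL)
  d <- tryCatch(stats::D(ex, var),
                error = function(e) stop("symbolic differentiation failure for '",
                                         deparse1(ex), "' with respect to '",
                                         var, "'", call. = FALSE))
  if (is.numeric(d) && identical(as.numeric(d), 0)) return(NULL)
  d
}

# expr1 + expr2 at the language level, simplifying NULL/0 operands.
expr_add <- function(a, b) {
  zero <- function(e) is.null(e) || (is.numeric(e) && identical(as.numeric(e), 0))
  if (zero(a)) return(if (zero(b)) 0 else b)
  if (zero(b)) return(a)
  call("+", a, b)
}

expr_mul <- function(a, b) {
  zero <- function(e) is.null(e) || (is.numeric(e) && identical(as.numeric(e), 0))
  one  <- function(e) is.numeric(e) && identical(as.numeric(e), 1)
  if (zero(a) || zero(b)) return(NULL)
  if (one(a)) return(b)
  if (one(b)) return(a)
  call("*", a, b)
}

expr_sub_bound <- function(ex, bound) {
  if (bound == 0) return(ex)
  call("-", ex, bound)
}

# Substitute symbols in an expression: subs is a named list mapping symbol
# name -> replacement language object (or numeric).
expr_substitute <- function(ex, subs) {
  if (is.name(ex)) {
    nm <- as.character(ex)
    if (nm %in% names(subs)) return(subs[[nm]])
    return(ex)
  }
  if (is.call(ex)) {
    for (k in seq_along(ex)[-1L]) ex[[k]] <- expr_substitute(ex[[k]], subs)
    return(ex)
  }
  ex
}

# Evaluate an expression in a list-of-bindings environment; values may be
# vectors (vectorized evaluation over grid nodes). Scalars recycle.
eval_model_expr <- function(ex, bindings) {
  if (is.numeric(ex)) return(ex)
  v <- eval(ex, envir = bindings, enclos = baseenv())
  v
}

# Full-precision deparse of a numeric for code generation.
num_lit <- function(x) sprintf("%.17g", x)
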