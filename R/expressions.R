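# Rate-law expression grammar: arithmetic over declared identifiers plus a
# built-in Hill term. The grammar is deliberately small so that symbolic
# differentiation is total on it.

.EXPR_OPS <- c("+", "-", "*", "/", "^", "(")

#' Parse and validate a rate-law expression
#'
#' The supported grammar is: numeric literals, declared identifiers, the binary
#' operators `+ - * / ^`, unary minus, parentheses, and the built-in function
#' `hill(x, K, h) = 1 / (1 + (x/K)^h)`. Anything else (other function calls,
#' indexing, assignment, ...) is rejected.
#'
#' @param text single character string with the rate law.
#' @param allowed_ids character vector of identifiers that may appear.
#' @param context label used in error messages (e.g. the reaction id).
#' @return the parsed expression (a call or name or numeric).
#' @keywords internal
parse_rate_expression <- function(text, allowed_ids, context = "rate") {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text))) {
    stop(sprintf("malformed expression in %s: empty or non-string rate", context),
         call. = FALSE)
  }
  expr <- tryCatch(str2lang(text), error = function(e) {
    stop(sprintf("malformed expression in %s: %s", context, conditionMessage(e)),
         call. = FALSE)
  })
  check_expression_grammar(expr, allowed_ids, context)
  expr
}

check_expression_grammar <- function(expr, allowed_ids, context) {
  if (is.numeric(expr)) {
    if (!is.finite(expr)) {
      stop(sprintf("malformed expression in %s: non-finite literal", context),
           call. = FALSE)
    }
    return(invisible(TRUE))
  }
  if (is.name(expr)) {
    id <- as.character(expr)
    if (!id %in% allowed_ids) {
      stop(sprintf("undeclared identifier '%s' in %s", id, context), call. = FALSE)
    }
    return(invisible(TRUE))
  }
  if (is.call(expr)) {
    fn <- as.character(expr[[1L]])
    if (fn %in% .EXPR_OPS) {
      for (i in seq_along(expr)[-1L]) {
        check_expression_grammar(expr[[i]], allowed_ids, context)
      }
      return(invisible(TRUE))
    }
    if (fn == "hill") {
      if (length(expr) != 4L) {
        stop(sprintf("malformed expression in %s: hill() takes 3 arguments", context),
             call. = FALSE)
      }
      for (i in 2:4) check_expression_grammar(expr[[i]], allowed_ids, context)
      return(invisible(TRUE))
    }
    stop(sprintf("unsupported construct '%s' in %s", fn, context), call. = FALSE)
  }
  stop(sprintf("malformed expression in %s", context), call. = FALSE)
}

# Rewrite hill(x, K, h) -> 1/(1 + (x/K)^h) so that stats::D can differentiate.
expand_hill <- function(expr) {
  if (is.call(expr)) {
    if (identical(as.character(expr[[1L]]), "hill")) {
      x <- expand_hill(expr[[2L]])
      K <- expand_hill(expr[[3L]])
      h <- expand_hill(expr[[4L]])
      return(substitute(1 / (1 + (x / K)^h), list(x = x, K = K, h = h)))
    }
    for (i in seq_along(expr)[-1L]) expr[[i]] <- expand_hill(expr[[i]])
  }
  expr
}

# Symbolic partial derivative of a rate expression with respect to `var`.
deriv_rate_expression <- function(expr, var) {
  stats::D(expand_hill(expr), var)
}

# Evaluation environment: species amounts and parameter values by id,
# plus the hill() builtin.
rate_eval_env <- function(state, params) {
  env <- new.env(parent = baseenv())
  for (id in names(state)) assign(id, unname(state[[id]]), envir = env)
  for (id in names(params)) assign(id, unname(params[[id]]), envir = env)
  assign("hill", function(x, K, h) 1 / (1 + (x / K)^h), envir = env)
  env
}
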