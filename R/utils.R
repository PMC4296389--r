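# Shared internal helpers: state normalisation, token formatting, seeded RNG.

VAR_TOKEN_RE <- "^[A-Za-z0-9_]+$"

check_variables <- function(variables, what = "variables") {
  if (!is.character(variables) || length(variables) < 1L) {
    stop(sprintf("%s must be a non-empty character vector", what), call. = FALSE)
  }
  bad <- variables[!grepl(VAR_TOKEN_RE, variables)]
  if (length(bad) > 0L) {
    stop(sprintf("invalid variable name(s): %s (allowed: [A-Za-z0-9_]+)",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(variables)) {
    stop("variable names must be unique", call. = FALSE)
  }
  variables
}

# A state is the subset of variables that are true; normalised to the order
# of the program/trace variable set (closed-world reading: everything else
# is false).
as_state <- function(x, variables) {
  if (is.null(x) || length(x) == 0L) return(character(0))
  x <- as.character(x)
  unknown <- setdiff(x, variables)
  if (length(unknown) > 0L) {
    stop(sprintf("state mentions unknown variable(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  variables[variables %in% x]
}

#' Format a state as a compact token
#'
#' States (interpretations) print as the concatenation of their true
#' variables, each prefixed with `+`; the empty state prints as `-`.
#'
#' @param state character vector of true variables.
#' @return a single character token.
#' @examples
#' format_state(c("a", "b"))
#' format_state(character(0))
#' @export
format_state <- function(state) {
  if (length(state) == 0L) "-" else paste0("+", state, collapse = "")
}

lit_token <- function(var, delay, positive) {
  paste0(ifelse(positive, "", "not "), var, "[-", delay, "]")
}

# Evaluate `expr` under a private RNG stream, restoring the caller's state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}
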