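# Propositional rule algebra over timed literals: literals, rules, programs.
#
# A rule  h <- l1, ..., lm  has a head atom and a body of timed literals.
# A timed literal is a possibly negated variable read at a fixed delay
# d >= 1 before the current step (value at time t - d).  Plain 1-step rules
# are timed rules whose delays are all 1; the Markov(1) case is never
# special-cased.

#' Create a timed literal
#'
#' A timed literal refers to the value of a variable `delay` steps before the
#' current time step (`v` at time t - delay), either positively (the atom) or
#' negatively (its negation).
#'
#' @param var variable name (token over `[A-Za-z0-9_]`).
#' @param delay integer delay, at least 1.
#' @param positive logical; `TRUE` for the atom, `FALSE` for its negation.
#' @return an object of class `timed_literal`.
#' @examples
#' lit("b", 2)
#' lit("a", 1, positive = FALSE)
#' @export
lit <- function(var, delay = 1L, positive = TRUE) {
  check_variables(var, "literal variable")
  delay <- as.integer(delay)
  if (length(delay) != 1L || is.na(delay) || delay < 1L) {
    stop("delay must be a single integer >= 1", call. = FALSE)
  }
  structure(list(var = var, delay = delay, positive = isTRUE(positive)),
            class = "timed_literal")
}

#' @export
format.timed_literal <- function(x, ...) lit_token(x$var, x$delay, x$positive)

#' @export
print.timed_literal <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# Internal constructor from parallel vectors; sorts canonically by
# (delay, variable, sign) and checks for contradictory bodies.
new_rule <- function(head, var = character(0), delay = integer(0),
                     positive = logical(0)) {
  if (length(var) > 0L) {
    key <- paste(var, delay)
    if (anyDuplicated(key)) {
      dup <- key[duplicated(key)][1L]
      both <- positive[key == dup]
      if (length(unique(both)) > 1L) {
        stop(sprintf("contradictory body: variable at delay (%s) occurs both positively and negatively",
                     dup), call. = FALSE)
      }
      keep <- !duplicated(key)
      var <- var[keep]; delay <- delay[keep]; positive <- positive[keep]
    }
    o <- order(delay, var, !positive)
    var <- var[o]; delay <- delay[o]; positive <- positive[o]
  }
  structure(list(head = head, var = as.character(var),
                 delay = as.integer(delay), positive = as.logical(positive)),
            class = "lp_rule")
}

#' Create a rule
#'
#' A rule consists of a head atom and a body of timed literals; the head is
#' true at time t whenever every positive body literal holds and no negative
#' body literal holds in the preceding states.  A rule with an empty body is
#' a fact rule: its head is predicted true in every next state.  Bodies in
#' which the same variable occurs at the same delay both positively and
#' negatively are rejected at construction.
#'
#' @param head head variable name.
#' @param body a list of [lit()] timed literals (possibly empty).
#' @return an object of class `lp_rule` with the body in canonical
#'   (delay, variable, sign) order.
#' @examples
#' lp_rule("a", list(lit("b", 1), lit("b", 2)))
#' lp_rule("b", list(lit("a", 2), lit("b", 2, positive = FALSE)))
#' lp_rule("c")  # fact rule
#' @export
lp_rule <- function(head, body = list()) {
  check_variables(head, "rule head")
  if (inherits(body, "timed_literal")) body <- list(body)
  if (!is.list(body)) stop("body must be a list of timed literals", call. = FALSE)
  ok <- vapply(body, inherits, logical(1), "timed_literal")
  if (!all(ok)) stop("body must be a list of timed literals", call. = FALSE)
  var <- vapply(body, `[[`, character(1), "var")
  delay <- vapply(body, `[[`, integer(1), "delay")
  positive <- vapply(body, `[[`, logical(1), "positive")
  key <- paste(var, delay)
  if (anyDuplicated(key)) {
    # distinguish duplicate literal (ignored) from contradiction (error)
    for (k in unique(key[duplicated(key)])) {
      if (length(unique(positive[key == k])) > 1L) {
        stop(sprintf("contradictory body: %s occurs both positively and negatively",
                     var[key == k][1L]), call. = FALSE)
      }
    }
  }
  new_rule(head, var, delay, positive)
}

#' Create a fact rule
#'
#' @param head head variable name.
#' @return an `lp_rule` with an empty body.
#' @export
fact_rule <- function(head) new_rule(head)

#' Is a rule a fact rule?
#'
#' @param r an `lp_rule`.
#' @return `TRUE` if the body is empty.
#' @export
is_fact <- function(r) {
  stopifnot(inherits(r, "lp_rule"))
  length(r$var) == 0L
}

rule_body_tokens <- function(r) {
  if (length(r$var) == 0L) character(0)
  else lit_token(r$var, r$delay, r$positive)
}

rule_key <- function(r) {
  paste0(r$head, " <- ", paste(rule_body_tokens(r), collapse = ", "), ".")
}

#' @export
format.lp_rule <- function(x, ...) {
  if (length(x$var) == 0L) paste0(x$head, " <-.")
  else paste0(x$head, " <- ", paste(rule_body_tokens(x), collapse = ", "), ".")
}

#' @export
print.lp_rule <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Rule subsumption
#'
#' `r1` subsumes `r2` when both rules share the same head and every body
#' literal of `r1` (matching variable, delay and sign) also occurs in the
#' body of `r2`.  A subsumed rule is redundant: whenever it can fire, the
#' subsuming (more general) rule fires too.
#'
#' @param r1,r2 rules of class `lp_rule`.
#' @return logical.
#' @examples
#' r1 <- lp_rule("a", list(lit("b")))
#' r2 <- lp_rule("a", list(lit("a"), lit("b")))
#' subsumes(r1, r2)  # TRUE
#' subsumes(r2, r1)  # FALSE
#' @export
subsumes <- function(r1, r2) {
  stopifnot(inherits(r1, "lp_rule"), inherits(r2, "lp_rule"))
  if (r1$head != r2$head) return(FALSE)
  if (length(r1$var) == 0L) return(TRUE)
  all(rule_body_tokens(r1) %in% rule_body_tokens(r2))
}

rules_identical <- function(r1, r2) rule_key(r1) == rule_key(r2)

sort_rules <- function(rules) {
  if (length(rules) == 0L) return(rules)
  heads <- vapply(rules, `[[`, character(1), "head")
  keys <- vapply(rules, rule_key, character(1))
  rules[order(heads, lengths(lapply(rules, `[[`, "var")), keys)]
}

dedupe_rules <- function(rules) {
  if (length(rules) == 0L) return(rules)
  keys <- vapply(rules, rule_key, character(1))
  rules[!duplicated(keys)]
}

#' Create a logic program
#'
#' A logic program over an ordered variable set (the Herbrand base) with a
#' maximum delay `max_delay` is a set of rules whose heads are variables of
#' the base and whose body delays all lie in `[1, max_delay]`.  Such a
#' program encodes a Markov(k) state transition system: the next state is
#' computed synchronously from the `max_delay` previous states by the
#' immediate consequence operator ([tp_next()]).
#'
#' Rules and bodies are kept in a deterministic canonical order (head name,
#' body size, then body literals sorted by delay, variable and sign) so that
#' serialized output is reproducible run to run.
#'
#' @param variables ordered character vector of variable names.
#' @param max_delay integer k >= 1; every body delay must be <= k.
#' @param rules list of [lp_rule()] objects (duplicates are dropped).
#' @return an object of class `logic_program`.
#' @examples
#' logic_program(c("a", "b"), 2, list(
#'   lp_rule("a", list(lit("b", 1), lit("b", 2))),
#'   lp_rule("b", list(lit("a", 2), lit("b", 2, positive = FALSE)))
#' ))
#' @export
logic_program <- function(variables, max_delay, rules = list()) {
  variables <- check_variables(variables)
  max_delay <- as.integer(max_delay)
  if (length(max_delay) != 1L || is.na(max_delay) || max_delay < 1L) {
    stop("max_delay must be a single integer >= 1", call. = FALSE)
  }
  if (inherits(rules, "lp_rule")) rules <- list(rules)
  ok <- vapply(rules, inherits, logical(1), "lp_rule")
  if (!all(ok)) stop("rules must be a list of lp_rule objects", call. = FALSE)
  for (r in rules) {
    if (!(r$head %in% variables)) {
      stop(sprintf("rule head '%s' is not in the variable set", r$head),
           call. = FALSE)
    }
    unknown <- setdiff(r$var, variables)
    if (length(unknown) > 0L) {
      stop(sprintf("rule '%s' mentions unknown variable(s): %s",
                   format(r), paste(unknown, collapse = ", ")), call. = FALSE)
    }
    if (length(r$delay) > 0L && max(r$delay) > max_delay) {
      stop(sprintf("rule '%s' uses delay %d > max_delay %d",
                   format(r), max(r$delay), max_delay), call. = FALSE)
    }
  }
  rules <- sort_rules(dedupe_rules(rules))
  structure(list(variables = variables, max_delay = max_delay, rules = rules),
            class = "logic_program")
}

#' @export
format.logic_program <- function(x, ...) {
  c(sprintf("vars: %s.", paste(x$variables, collapse = ", ")),
    sprintf("delay: %d.", x$max_delay),
    vapply(x$rules, format, character(1)))
}

#' @export
print.logic_program <- function(x, ...) {
  cat(sprintf("Logic program: %d variable(s), max delay %d, %d rule(s)\n",
              length(x$variables), x$max_delay, length(x$rules)))
  cat(format(x), sep = "\n")
  invisible(x)
}

#' Number of rules in a logic program
#' @param x a `logic_program`.
#' @return integer rule count.
#' @export
n_rules <- function(x) {
  stopifnot(inherits(x, "logic_program"))
  length(x$rules)
}
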