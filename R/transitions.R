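# Interpretation transitions: the learner's unit of observation.
#
# An n-step interpretation transition pairs a condition interpretation over
# the timed Herbrand base (which variables were true at which delay, over a
# window of n past states) with the observed next state.

#' Create an interpretation transition
#'
#' An n-step interpretation transition is the pair (I, J) extracted from a
#' trace window: `condition` records, as positive timed atoms, which
#' variables were true at which delay in the `depth` states preceding the
#' observed `next_state`.  Every (variable, delay) pair of the timed base not
#' listed in the condition was false (closed world).
#'
#' @param condition a data frame with columns `var` and `delay` (one row per
#'   true timed atom), or a list of positive [lit()] literals.
#' @param next_state character vector: the variables true in the observed
#'   next state.
#' @param depth integer n >= 1, the window length (maximum delay spanned).
#' @return an object of class `itransition`.
#' @examples
#' # the 2-step reading of the trace {a,b} -> {b} -> {a}
#' itransition(data.frame(var = c("b", "a", "b"), delay = c(1, 2, 2)),
#'             next_state = "a", depth = 2)
#' @export
itransition <- function(condition, next_state, depth) {
  depth <- as.integer(depth)
  if (length(depth) != 1L || is.na(depth) || depth < 1L) {
    stop("depth must be a single integer >= 1", call. = FALSE)
  }
  if (is.list(condition) && !is.data.frame(condition)) {
    ok <- vapply(condition, inherits, logical(1), "timed_literal")
    if (!all(ok)) stop("condition must be positive timed literals", call. = FALSE)
    if (any(!vapply(condition, `[[`, logical(1), "positive"))) {
      stop("condition literals must be positive", call. = FALSE)
    }
    condition <- data.frame(
      var = vapply(condition, `[[`, character(1), "var"),
      delay = vapply(condition, `[[`, integer(1), "delay"),
      stringsAsFactors = FALSE)
  }
  if (!is.data.frame(condition) || !all(c("var", "delay") %in% names(condition))) {
    stop("condition must be a data frame with columns var, delay", call. = FALSE)
  }
  var <- as.character(condition$var)
  delay <- as.integer(condition$delay)
  if (length(delay) > 0L && (any(delay < 1L) || any(delay > depth))) {
    stop("condition delays must lie in [1, depth]", call. = FALSE)
  }
  if (anyDuplicated(paste(var, delay))) {
    stop("condition mentions a (variable, delay) pair more than once",
         call. = FALSE)
  }
  o <- order(delay, var)
  structure(list(var = var[o], delay = delay[o],
                 next_state = sort(unique(as.character(next_state))),
                 depth = depth),
            class = "itransition")
}

cond_tokens <- function(tr) {
  if (length(tr$var) == 0L) character(0) else paste0(tr$var, "[-", tr$delay, "]")
}

#' @export
format.itransition <- function(x, ...) {
  lhs <- if (length(x$var) == 0L) "-" else paste(cond_tokens(x), collapse = " ")
  sprintf("(%s => %s) [%d-step]", lhs, format_state(x$next_state), x$depth)
}

#' @export
print.itransition <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Consistency of a rule with an interpretation transition
#'
#' A rule is inconsistent with a transition exactly when its body holds under
#' the condition interpretation (every positive body literal is present and
#' no negative body literal is present) while its head is absent from the
#' observed next state; it is consistent otherwise.  A rule whose body looks
#' further back than the transition's window is incomparable and raises an
#' error.
#'
#' @param r an `lp_rule`.
#' @param tr an [itransition()].
#' @return logical.
#' @examples
#' tr <- itransition(data.frame(var = "b", delay = 1), next_state = "a", depth = 1)
#' rule_consistent(lp_rule("a", list(lit("b", 1))), tr)  # body fires, head present
#' @export
rule_consistent <- function(r, tr) {
  stopifnot(inherits(r, "lp_rule"), inherits(tr, "itransition"))
  if (length(r$delay) > 0L && max(r$delay) > tr$depth) {
    stop(sprintf("rule '%s' looks back %d steps but the transition spans only %d (incomparable horizon)",
                 format(r), max(r$delay), tr$depth), call. = FALSE)
  }
  !(rule_fires(r, tr) && !(r$head %in% tr$next_state))
}

# Does the body of r hold under the condition interpretation of tr?
rule_fires <- function(r, tr) {
  if (length(r$var) == 0L) return(TRUE)
  present <- paste(r$var, r$delay) %in% paste(tr$var, tr$delay)
  all(present == r$positive)
}

#' Anti-rules of an interpretation transition
#'
#' For every variable of the base absent from the next state of a transition
#' (I, J), the anti-rule is the fully specified rule whose body encodes I
#' exactly over the timed base of the transition's depth: every (variable,
#' delay) pair present in the condition occurs positively, every absent pair
#' negatively.  A hypothesis rule that subsumes an anti-rule fires on I yet
#' its head is absent from J, so it is inconsistent with the transition and
#' must be specialized.
#'
#' @param tr an [itransition()].
#' @param variables the variable set (Herbrand base).
#' @return a list of fully specified `lp_rule` objects, one per variable
#'   absent from the next state, each with `length(variables) * depth` body
#'   literals.
#' @examples
#' tr <- itransition(data.frame(var = "a", delay = 1), character(0), depth = 1)
#' anti_rules(tr, c("a", "b", "c"))
#' @export
anti_rules <- function(tr, variables) {
  stopifnot(inherits(tr, "itransition"))
  variables <- check_variables(variables)
  unknown <- setdiff(c(tr$var, tr$next_state), variables)
  if (length(unknown) > 0L) {
    stop(sprintf("transition mentions unknown variable(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  absent <- setdiff(variables, tr$next_state)
  if (length(absent) == 0L) return(list())
  all_var <- rep(variables, times = tr$depth)
  all_delay <- rep(seq_len(tr$depth), each = length(variables))
  pos <- paste(all_var, all_delay) %in% paste(tr$var, tr$delay)
  lapply(absent, function(h) new_rule(h, all_var, all_delay, pos))
}

#' Consistency of a program with a set of transitions
#'
#' A program is consistent with a set of interpretation transitions when
#' every rule is consistent with every transition of comparable horizon
#' (rule/transition pairs where the rule looks further back than the
#' transition spans are skipped).  The empty program is vacuously consistent.
#'
#' @param p a [logic_program()].
#' @param transitions a list of [itransition()] objects.
#' @return logical.
#' @export
program_consistent <- function(p, transitions) {
  stopifnot(inherits(p, "logic_program"))
  if (inherits(transitions, "itransition")) transitions <- list(transitions)
  for (tr in transitions) {
    stopifnot(inherits(tr, "itransition"))
    for (r in p$rules) {
      if (length(r$delay) > 0L && max(r$delay) > tr$depth) next
      if (!rule_consistent(r, tr)) return(FALSE)
    }
  }
  TRUE
}
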