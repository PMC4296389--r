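# Synchronous execution of Markov(k) logic programs: trace generation,
# exhaustive state-transition-diagram enumeration and seeded random
# ground-truth generators for closed-loop testing.

#' Simulate a logic program synchronously
#'
#' Starting from an initial history of exactly k states (k = the program's
#' maximum delay), repeatedly applies the immediate consequence operator: all
#' variables are updated at the same time and the run is deterministic.
#'
#' @param p a [logic_program()].
#' @param initial list of exactly `p$max_delay` states, most recent last.
#' @param steps number of synchronous steps to simulate (>= 1).
#' @return a [bn_trace()] of `p$max_delay + steps` states: the initial
#'   history followed by the simulated states.
#' @examples
#' p <- logic_program(c("a", "b"), 2, list(
#'   lp_rule("a", list(lit("b", 1), lit("b", 2))),
#'   lp_rule("b", list(lit("a", 2), lit("b", 2, positive = FALSE)))
#' ))
#' simulate_program(p, list(c("a", "b"), "b"), steps = 1)  # +a+b -> +b -> +a
#' @export
simulate_program <- function(p, initial, steps) {
  stopifnot(inherits(p, "logic_program"))
  steps <- as.integer(steps)
  if (length(steps) != 1L || is.na(steps) || steps < 1L) {
    stop("steps must be a single integer >= 1", call. = FALSE)
  }
  if (!is.list(initial)) initial <- list(initial)
  k <- p$max_delay
  if (length(initial) != k) {
    stop(sprintf("initial history must have exactly %d state(s)", k),
         call. = FALSE)
  }
  states <- lapply(initial, as_state, variables = p$variables)
  cp <- compile_program(p)
  for (i in seq_len(steps)) {
    L <- length(states)
    cond <- matrix(history_to_cond(states[(L - k + 1L):L], p$variables, k),
                   ncol = 1)
    states <- c(states,
                list(cond_col_to_state(tp_matrix(cp, cond), p$variables)))
  }
  bn_trace(states, p$variables)
}

# All 2^S slot assignments as an S x H 0/1 matrix; slot 1 is the least
# significant bit of the history index (deterministic enumeration order).
all_conditions <- function(S) {
  H <- 2^S
  m <- matrix(0, nrow = S, ncol = H)
  for (s in seq_len(S)) {
    m[s, ] <- rep(rep(c(0, 1), each = 2^(s - 1L)), length.out = H)
  }
  m
}

cond_col_to_history <- function(col, variables, k) {
  n <- length(variables)
  lapply(rev(seq_len(k)), function(d) {
    variables[col[slot_index(seq_len(n), d, n)] > 0]
  })
}

#' Enumerate the full state transition diagram
#'
#' Computes the synchronous successor of every possible k-state history of a
#' program: the total mapping over all `2^(n*k)` histories (n variables,
#' maximum delay k).  Projecting the mapping onto the last history state
#' yields the possibly non-deterministic 1-step transition diagram (see
#' [one_step_successors()]).
#'
#' @param p a [logic_program()].
#' @param cap guard on the number of histories; enumeration is refused above
#'   it (sample trajectories with [generate_traces()] instead).
#' @return a data frame with one row per history: columns `history` (the k
#'   states as [format_state()] tokens joined by `|`, oldest first) and
#'   `next_state`.
#' @examples
#' p <- logic_program("a", 1, lp_rule("a", lit("a", 1, positive = FALSE)))
#' enumerate_diagram(p)
#' @export
enumerate_diagram <- function(p, cap = 2^20) {
  stopifnot(inherits(p, "logic_program"))
  n <- length(p$variables)
  k <- p$max_delay
  S <- n * k
  if (2^S > cap) {
    stop(sprintf("2^%d histories exceed the enumeration cap (%g); sample traces instead",
                 S, cap), call. = FALSE)
  }
  cp <- compile_program(p)
  conds <- all_conditions(S)
  nxt <- tp_matrix(cp, conds)
  hist_keys <- character(ncol(conds))
  next_keys <- character(ncol(conds))
  for (h in seq_len(ncol(conds))) {
    states <- cond_col_to_history(conds[, h], p$variables, k)
    hist_keys[h] <- paste(vapply(states, format_state, character(1)),
                          collapse = "|")
    next_keys[h] <- format_state(cond_col_to_state(nxt[, h, drop = FALSE],
                                                   p$variables))
  }
  data.frame(history = hist_keys, next_state = next_keys,
             stringsAsFactors = FALSE)
}

#' One-step successor set of a state
#'
#' The set of next states a program can reach from histories ending in the
#' given state, across all completions of the earlier history.  For a
#' Markov(1) program this is a single state; for deeper programs the 1-step
#' projection of the transition diagram can be non-deterministic, which is
#' precisely the signature of delayed influences.
#'
#' @param p a [logic_program()].
#' @param state character vector: the most recent state.
#' @param cap enumeration guard, as in [enumerate_diagram()].
#' @return a list of states (each a character vector), deduplicated, in
#'   enumeration order.
#' @export
one_step_successors <- function(p, state, cap = 2^20) {
  stopifnot(inherits(p, "logic_program"))
  state <- as_state(state, p$variables)
  dg <- enumerate_diagram(p, cap)
  last <- vapply(strsplit(dg$history, "|", fixed = TRUE),
                 function(x) x[[length(x)]], character(1))
  succ <- unique(dg$next_state[last == format_state(state)])
  lapply(succ, parse_state_token, variables = p$variables)
}

parse_state_token <- function(tok, variables) {
  if (tok == "-") return(character(0))
  as_state(strsplit(sub("^\\+", "", tok), "+", fixed = TRUE)[[1L]], variables)
}

#' Configuration for the random program generator
#'
#' Bundles the knobs of [generate_program()].  The defaults mirror the
#' dimensions of published delayed Boolean models of the yeast cell cycle
#' (16 variables, delays up to 5) with sparse regulation: each variable gets
#' one or two rules of at most three regulators, the typical in-degree of
#' curated Boolean gene-regulatory models.
#'
#' @param n_variables number of variables (>= 1).
#' @param max_delay maximum body delay k (>= 1).
#' @param max_body_literals maximum number of literals per rule body (>= 1).
#' @param rules_per_variable integer vector of candidate rule counts per
#'   head; each head draws uniformly from it.
#' @param seed integer seed; the same configuration always yields the same
#'   program.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_variables = 16L, max_delay = 5L,
                             max_body_literals = 3L,
                             rules_per_variable = 1:2, seed = 1L) {
  n_variables <- as.integer(n_variables)
  max_delay <- as.integer(max_delay)
  max_body_literals <- as.integer(max_body_literals)
  rules_per_variable <- as.integer(rules_per_variable)
  if (n_variables < 1L || max_delay < 1L || max_body_literals < 1L ||
      any(rules_per_variable < 0L) || length(rules_per_variable) < 1L) {
    stop("all generator bounds must be positive", call. = FALSE)
  }
  structure(list(n_variables = n_variables, max_delay = max_delay,
                 max_body_literals = max_body_literals,
                 rules_per_variable = rules_per_variable,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("Generator config: %d variable(s), max delay %d, <= %d body literal(s), %s rule(s) per variable, seed %d\n",
              x$n_variables, x$max_delay, x$max_body_literals,
              paste(range(x$rules_per_variable), collapse = "-"), x$seed))
  invisible(x)
}

#' Generate a random Markov(k) logic program
#'
#' Draws a seeded, reproducible random program within the bounds of a
#' [generator_config()]: for each variable, a random number of rules, each
#' with a random non-contradictory body of distinct (variable, delay) atoms
#' and random signs.  Variables are named `x1`, `x2`, ...  Used as ground
#' truth for closed-loop benchmarking of the learner.
#'
#' @param cfg a [generator_config()].
#' @return a [logic_program()]; the configuration is attached as attribute
#'   `generator_config`.
#' @examples
#' generate_program(generator_config(n_variables = 3, max_delay = 2, seed = 7))
#' @export
generate_program <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  vars <- sprintf("x%d", seq_len(cfg$n_variables))
  n <- cfg$n_variables
  S <- n * cfg$max_delay
  rules <- with_seed(cfg$seed, {
    out <- list()
    for (h in vars) {
      nr <- if (length(cfg$rules_per_variable) == 1L) cfg$rules_per_variable
            else sample(cfg$rules_per_variable, 1L)
      for (r in seq_len(nr)) {
        bs <- sample.int(min(cfg$max_body_literals, S), 1L)
        slots <- sample.int(S, bs)
        signs <- sample(c(TRUE, FALSE), bs, replace = TRUE)
        out <- c(out, list(new_rule(h,
                                    vars[(slots - 1L) %% n + 1L],
                                    (slots - 1L) %/% n + 1L,
                                    signs)))
      }
    }
    out
  })
  p <- logic_program(vars, cfg$max_delay, rules)
  attr(p, "generator_config") <- cfg
  p
}

random_state <- function(variables) {
  variables[stats::runif(length(variables)) < 0.5]
}

#' Generate traces of execution from a program
#'
#' Simulates traces with exactly `n_transitions` transitions each
#' (`n_transitions + 1` states): the first k states are the initial history
#' and the remaining `n_transitions - k + 1` states are synchronous steps.
#' In `random` mode, `n_traces` initial histories are drawn uniformly over
#' states under the given seed; in `exhaustive` mode one trace is emitted per
#' possible initial k-history (2^(n*k) traces, guarded by `cap`) and
#' `n_traces` is ignored.
#'
#' @param p a [logic_program()].
#' @param n_traces number of traces (random mode).
#' @param n_transitions transitions per trace; must be >= `p$max_delay` so
#'   that each trace contains at least one simulated step.
#' @param seed integer seed for random mode (`NULL` uses the current RNG
#'   state).
#' @param mode `"random"` or `"exhaustive"`.
#' @param cap enumeration guard for exhaustive mode.
#' @return a named list of [bn_trace()] objects.
#' @examples
#' p <- logic_program("a", 1, lp_rule("a", lit("a", 1, positive = FALSE)))
#' generate_traces(p, n_transitions = 1, mode = "exhaustive")
#' @export
generate_traces <- function(p, n_traces = 10L, n_transitions = p$max_delay,
                            seed = NULL, mode = c("random", "exhaustive"),
                            cap = 2^20) {
  stopifnot(inherits(p, "logic_program"))
  mode <- match.arg(mode)
  k <- p$max_delay
  n_transitions <- as.integer(n_transitions)
  if (n_transitions < k) {
    stop(sprintf("n_transitions must be >= max_delay (%d): the first %d states of a trace are the seed history",
                 k, k), call. = FALSE)
  }
  steps <- n_transitions - k + 1L
  if (mode == "exhaustive") {
    S <- length(p$variables) * k
    if (2^S > cap) {
      stop(sprintf("2^%d initial histories exceed the cap (%g); use random mode",
                   S, cap), call. = FALSE)
    }
    conds <- all_conditions(S)
    inits <- lapply(seq_len(ncol(conds)), function(h) {
      cond_col_to_history(conds[, h], p$variables, k)
    })
  } else {
    n_traces <- as.integer(n_traces)
    if (n_traces < 1L) stop("n_traces must be >= 1", call. = FALSE)
    inits <- with_seed(seed, {
      lapply(seq_len(n_traces), function(i) {
        lapply(seq_len(k), function(d) random_state(p$variables))
      })
    })
  }
  # step all traces in lockstep on the compiled program: the condition matrix
  # holds one column per trace; advancing a step shifts every delay block by
  # one and installs the new states at delay 1
  n <- length(p$variables)
  S <- n * k
  cp <- compile_program(p)
  conds <- vapply(inits, history_to_cond, numeric(S),
                  variables = p$variables, k = k)
  conds <- matrix(conds, nrow = S)
  step_states <- vector("list", steps)
  for (st in seq_len(steps)) {
    nxt <- tp_matrix(cp, conds)
    step_states[[st]] <- nxt
    if (st < steps) {
      conds <- if (k == 1L) nxt else rbind(nxt, conds[seq_len(S - n), , drop = FALSE])
    }
  }
  traces <- lapply(seq_along(inits), function(h) {
    sim <- lapply(step_states, function(m) p$variables[m[, h] > 0])
    bn_trace(c(inits[[h]], sim), p$variables)
  })
  names(traces) <- sprintf("trace_%d", seq_along(traces))
  traces
}
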