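# Shared fixtures and independent oracles.  The oracles deliberately avoid
# the package's compiled matrix path: they evaluate rules by plain set
# membership so that learner and simulator outputs can be cross-checked
# against a second, naive route.

# Markov(2) worked system: a <- b[-1], b[-2];  b <- a[-2], not b[-2].
example4_program <- function() {
  logic_program(c("a", "b"), 2, list(
    lp_rule("a", list(lit("b", 1), lit("b", 2))),
    lp_rule("b", list(lit("a", 2), lit("b", 2, positive = FALSE)))))
}

# Three-variable Markov(1) program used for its (a, eps) transition.
example3_program <- function() {
  logic_program(c("a", "b", "c"), 1, list(
    lp_rule("a", lit("b", 1)),
    lp_rule("b", list(lit("a", 1), lit("c", 1))),
    lp_rule("c", lit("a", 1, positive = FALSE))))
}

# The two readings of the three-gene network's update for a:
# disjunctive (not a and b) or c, and guarded not a and (b or c).
b1_disj_program <- function() {
  logic_program(c("a", "b", "c"), 1, list(
    lp_rule("a", list(lit("a", 1, positive = FALSE), lit("b", 1))),
    lp_rule("a", lit("c", 1)),
    lp_rule("b", list(lit("a", 1), lit("c", 1))),
    lp_rule("c", lit("a", 1, positive = FALSE))))
}

b1_guard_program <- function() {
  logic_program(c("a", "b", "c"), 1, list(
    lp_rule("a", list(lit("a", 1, positive = FALSE), lit("b", 1))),
    lp_rule("a", list(lit("a", 1, positive = FALSE), lit("c", 1))),
    lp_rule("b", list(lit("a", 1), lit("c", 1))),
    lp_rule("c", lit("a", 1, positive = FALSE))))
}

negation_program <- function() {
  logic_program("a", 1, lp_rule("a", lit("a", 1, positive = FALSE)))
}

all_states <- function(variables) {
  n <- length(variables)
  lapply(seq_len(2^n) - 1L, function(m) {
    variables[bitwAnd(m, 2^(seq_len(n) - 1L)) > 0]
  })
}

all_histories <- function(variables, k) {
  states <- all_states(variables)
  idx <- do.call(expand.grid, rep(list(seq_along(states)), k))
  lapply(seq_len(nrow(idx)), function(r) {
    lapply(seq_len(k), function(d) states[[idx[r, d]]])
  })
}

# Naive immediate-consequence oracle: direct set-membership evaluation.
oracle_tp <- function(p, history) {
  L <- length(history)
  fired <- character(0)
  for (r in p$rules) {
    holds <- TRUE
    if (length(r$var) > 0L) {
      for (i in seq_along(r$var)) {
        present <- r$var[i] %in% history[[L - r$delay[i] + 1L]]
        if (present != r$positive[i]) { holds <- FALSE; break }
      }
    }
    if (holds) fired <- c(fired, r$head)
  }
  p$variables[p$variables %in% fired]
}

# Naive consistency of a candidate body with a window (history, next state).
oracle_body_consistent <- function(head, var, delay, positive, windows) {
  for (w in windows) {
    history <- w$history
    L <- length(history)
    holds <- TRUE
    if (length(var) > 0L) {
      for (i in seq_along(var)) {
        present <- var[i] %in% history[[L - delay[i] + 1L]]
        if (present != positive[i]) { holds <- FALSE; break }
      }
    }
    if (holds && !(head %in% w$next_state)) return(FALSE)
  }
  TRUE
}

# Complete depth-k interpretation-transition set of a program: one window per
# possible k-history, successor computed by the naive oracle.
complete_windows <- function(p, k = p$max_delay) {
  pk <- logic_program(p$variables, k, p$rules)
  lapply(all_histories(p$variables, k), function(h) {
    list(history = h, next_state = oracle_tp(pk, h))
  })
}

history_to_itransition <- function(history, next_state, variables) {
  k <- length(history)
  var <- character(0); delay <- integer(0)
  for (d in seq_len(k)) {
    st <- history[[k - d + 1L]]
    var <- c(var, st); delay <- c(delay, rep(d, length(st)))
  }
  itransition(data.frame(var = var, delay = delay, stringsAsFactors = FALSE),
              next_state, max(1L, k))
}

complete_itransitions <- function(p, k = p$max_delay) {
  lapply(complete_windows(p, k), function(w) {
    history_to_itransition(w$history, w$next_state, p$variables)
  })
}

# Semantic equivalence of two programs: identical successors on every
# history up to the larger delay (checked against the naive oracle).
programs_equivalent <- function(p1, p2) {
  stopifnot(identical(p1$variables, p2$variables))
  k <- max(p1$max_delay, p2$max_delay)
  q1 <- logic_program(p1$variables, k, p1$rules)
  q2 <- logic_program(p2$variables, k, p2$rules)
  for (h in all_histories(p1$variables, k)) {
    if (!identical(oracle_tp(q1, h), oracle_tp(q2, h))) return(FALSE)
  }
  TRUE
}

# Reference LF1T driven entirely through the public per-step operations
# (anti_rules + ms_program); used to cross-check the compiled engine.
lf1t_naive <- function(transitions, variables, depth) {
  p <- initial_program(variables, depth)
  for (tr in transitions) {
    for (anti in anti_rules(tr, variables)) {
      p <- ms_program(p, anti)
    }
  }
  p
}

random_small_rule <- function(variables, k) {
  S <- length(variables) * k
  bs <- sample.int(min(3L, S), 1L)
  slots <- sample.int(S, bs)
  lp_rule(sample(variables, 1L),
          lapply(seq_len(bs), function(i) {
            lit(variables[(slots[i] - 1L) %% length(variables) + 1L],
                (slots[i] - 1L) %/% length(variables) + 1L,
                sample(c(TRUE, FALSE), 1L))
          }))
}
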