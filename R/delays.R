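# The delayed-influence layer: timed Herbrand bases, traces of execution,
# decomposition of traces into timed interpretation transitions, trace
# consistency diagnostics, per-depth learning and the final merge (LFkT).

#' Timed Herbrand base
#'
#' The timed Herbrand base of period k contains one copy of each variable per
#' delay 1..k: the atom `v` at time t - i for every variable v and every
#' i in 1..k.
#'
#' @param variables the Herbrand base.
#' @param k period (maximum delay), >= 1.
#' @return a list of positive [lit()] literals of size `length(variables) * k`,
#'   ordered by delay, then declaration order.
#' @examples
#' timed_herbrand_base(c("a", "b"), 2)
#' @export
timed_herbrand_base <- function(variables, k) {
  variables <- check_variables(variables)
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L) {
    stop("k must be a single integer >= 1", call. = FALSE)
  }
  out <- vector("list", length(variables) * k)
  i <- 0L
  for (d in seq_len(k)) {
    for (v in variables) {
      i <- i + 1L
      out[[i]] <- lit(v, d)
    }
  }
  out
}

#' Create a trace of execution
#'
#' A trace is a finite sequence of at least two states over a shared variable
#' set, written S0 -> S1 -> ... -> Sn; it records n >= 1 synchronous state
#' transitions.
#'
#' @param states a list of states (character vectors of true variables), in
#'   temporal order.
#' @param variables the shared variable set; every state must be a subset.
#' @return an object of class `bn_trace`.
#' @examples
#' bn_trace(list(c("a", "b"), "b", "a"), c("a", "b"))
#' @export
bn_trace <- function(states, variables) {
  variables <- check_variables(variables)
  if (!is.list(states)) stop("states must be a list", call. = FALSE)
  if (length(states) < 2L) {
    stop("a trace needs at least 2 states (one transition)", call. = FALSE)
  }
  states <- lapply(states, as_state, variables = variables)
  structure(list(states = states, variables = variables), class = "bn_trace")
}

#' @export
format.bn_trace <- function(x, ...) {
  paste(vapply(x$states, format_state, character(1)), collapse = " -> ")
}

#' @export
print.bn_trace <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Number of transitions in a trace
#' @param t a [bn_trace()].
#' @return integer: number of states minus one.
#' @export
n_transitions <- function(t) {
  stopifnot(inherits(t, "bn_trace"))
  length(t$states) - 1L
}

as_trace_list <- function(traces) {
  if (inherits(traces, "bn_trace")) traces <- list(traces)
  ok <- vapply(traces, inherits, logical(1), "bn_trace")
  if (!all(ok)) stop("expected bn_trace objects", call. = FALSE)
  if (length(traces) == 0L) stop("empty trace set", call. = FALSE)
  vars <- traces[[1L]]$variables
  for (t in traces) {
    if (!identical(t$variables, vars)) {
      stop("all traces must share the same variable set (same order)",
           call. = FALSE)
    }
  }
  if (is.null(names(traces))) {
    names(traces) <- sprintf("trace_%d", seq_along(traces))
  }
  traces
}

# internal fast itransition constructor for windows already in canonical form
new_itransition <- function(var, delay, next_state, depth) {
  o <- order(delay, var)
  structure(list(var = var[o], delay = delay[o], next_state = next_state,
                 depth = as.integer(depth)),
            class = "itransition")
}

#' Decompose a trace into timed interpretation transitions
#'
#' Every position i >= 1 of the trace, together with every window length n
#' with 1 <= n <= min(i, k), yields one n-step interpretation transition: the
#' condition encodes the n states immediately preceding S_i (the state d
#' steps back contributes `v` at delay d for each true variable v) and the
#' next state is S_i.  A trace of m transitions therefore yields
#' sum over n = 1..min(m, k) of (m - n + 1) transitions; for m = k = 5 that
#' is 15 (one 5-step, two 4-step, three 3-step, four 2-step, five 1-step).
#'
#' @param t a [bn_trace()].
#' @param max_depth maximum window length k >= 1.
#' @return a list of [itransition()] objects, ordered by position then depth.
#' @examples
#' tr <- bn_trace(list(c("a", "b"), "b", "a"), c("a", "b"))
#' decompose_trace(tr, 2)  # the three readings of ab -> b -> a
#' @export
decompose_trace <- function(t, max_depth) {
  stopifnot(inherits(t, "bn_trace"))
  k <- as.integer(max_depth)
  if (length(k) != 1L || is.na(k) || k < 1L) {
    stop("max_depth must be a single integer >= 1", call. = FALSE)
  }
  s <- t$states
  L <- length(s)
  lens <- lengths(s)
  out <- vector("list", sum(vapply(seq_len(L - 1L), function(i) min(i, k),
                                   integer(1))))
  w <- 0L
  for (j in 2:L) {          # successor state index (position i = j - 1)
    nmax <- min(j - 1L, k)
    for (n in seq_len(nmax)) {
      idx <- (j - 1L):(j - n)              # states at delays 1..n
      var <- unlist(s[idx], use.names = FALSE)
      delay <- rep.int(seq_len(n), lens[idx])
      w <- w + 1L
      out[[w]] <- new_itransition(as.character(var), as.integer(delay),
                                  s[[j]], n)
    }
  }
  out
}

trace_position_keys <- function(t, k) {
  s <- t$states
  m <- length(s) - 1L
  keys <- character(m)
  nxt <- character(m)
  for (i in 0:(m - 1L)) {
    prev <- if (i == 0L || k == 0L) list() else s[max(1L, i - k + 1L):i]
    keys[i + 1L] <- paste(vapply(c(prev, s[i + 1L]), format_state,
                                 character(1)), collapse = "|")
    nxt[i + 1L] <- format_state(s[[i + 2L]])
  }
  data.frame(pos = 0:(m - 1L), key = keys, next_state = nxt,
             stringsAsFactors = FALSE)
}

#' k-consistency of two traces
#'
#' Two traces are k-inconsistent when they contain positions with the same
#' state, different successors, and identical k-lookbacks (the at-most-k
#' states preceding the position, clipped at the trace start).  Such a pair
#' cannot be realized by any deterministic Markov(k) program whose memory is
#' limited to the observed lookback.  When `k` is omitted it defaults to the
#' larger of the two transition counts.
#'
#' Note that the lookback is compared as observed: two traces that disagree
#' immediately after an identical clipped prefix (in particular, identical
#' initial states) are reported inconsistent even though unobserved earlier
#' states might disambiguate them; see [lfkt_learn()] for the weaker
#' learnability check used before learning.
#'
#' @param t1,t2 traces over the same variable set ([bn_trace()]).
#' @param k lookback horizon; `NULL` for max of the transition counts.
#' @return logical.
#' @examples
#' v <- c("a", "b")
#' traces_k_consistent(bn_trace(list("b", "a"), v),
#'                     bn_trace(list("b", "b"), v))  # FALSE
#' @export
traces_k_consistent <- function(t1, t2, k = NULL) {
  stopifnot(inherits(t1, "bn_trace"), inherits(t2, "bn_trace"))
  if (!identical(t1$variables, t2$variables)) {
    stop("traces must share the same variable set", call. = FALSE)
  }
  if (is.null(k)) k <- max(length(t1$states), length(t2$states)) - 1L
  k <- as.integer(k)
  k1 <- trace_position_keys(t1, k)
  k2 <- trace_position_keys(t2, k)
  m <- merge(k1, k2, by = "key")
  !any(m$next_state.x != m$next_state.y)
}

#' Check a trace set for k-consistency
#'
#' Performs the pairwise (and self) k-consistency check of
#' [traces_k_consistent()] over a whole trace set and reports every
#' conflicting witness: a state plus lookback that occurs with two different
#' successors.
#'
#' @param traces a list of [bn_trace()] objects over a shared variable set.
#' @param k lookback horizon.
#' @return an object of class `trace_check_report`: a list with elements
#'   `consistent` (logical), `k`, and `witnesses` (a data frame with one row
#'   per conflicting trace position: the shared lookback/state key, trace
#'   name, position and observed successor).
#' @export
check_trace_set <- function(traces, k) {
  traces <- as_trace_list(traces)
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 0L) {
    stop("k must be a single non-negative integer", call. = FALSE)
  }
  tabs <- lapply(names(traces), function(nm) {
    tab <- trace_position_keys(traces[[nm]], k)
    tab$trace <- nm
    tab
  })
  all_tab <- do.call(rbind, tabs)
  nconf <- tapply(all_tab$next_state, all_tab$key,
                  function(x) length(unique(x)))
  bad_keys <- names(nconf)[nconf > 1L]
  witnesses <- all_tab[all_tab$key %in% bad_keys,
                       c("key", "trace", "pos", "next_state")]
  witnesses <- witnesses[order(witnesses$key, witnesses$trace, witnesses$pos), ]
  rownames(witnesses) <- NULL
  structure(list(consistent = length(bad_keys) == 0L, k = k,
                 n_traces = length(traces), witnesses = witnesses),
            class = "trace_check_report")
}

#' @export
print.trace_check_report <- function(x, ...) {
  if (x$consistent) {
    cat(sprintf("%d trace(s): %d-consistent\n", x$n_traces, x$k))
  } else {
    cat(sprintf("%d trace(s): NOT %d-consistent; %d conflicting position(s):\n",
                x$n_traces, x$k, nrow(x$witnesses)))
    print(x$witnesses)
  }
  invisible(x)
}

#' Merge per-depth learned programs
#'
#' Merges the k programs learned at depths 1..k into one.  From each depth-n
#' program with n >= 2, every rule whose body contains no literal at delay n
#' is dropped first: if such a rule is consistent with the observations it
#' was also learned by the shallower learners, and if it is not, keeping it
#' would contradict them.  The depth-1 program is exempt (there is no
#' shallower learner).  The pooled rules are then pruned for subsumption
#' (a rule subsumed by a different kept rule is dropped) and returned in
#' canonical order.
#'
#' @param programs list of [logic_program()] objects; element n must have
#'   `max_delay = n`.
#' @return a [logic_program()] with `max_delay = length(programs)`.
#' @export
merge_programs <- function(programs) {
  if (inherits(programs, "logic_program")) programs <- list(programs)
  k <- length(programs)
  if (k < 1L) stop("need at least one program", call. = FALSE)
  vars <- programs[[1L]]$variables
  for (n in seq_len(k)) {
    p <- programs[[n]]
    stopifnot(inherits(p, "logic_program"))
    if (!identical(p$variables, vars)) {
      stop("programs must share the same variable set", call. = FALSE)
    }
    if (p$max_delay != n) {
      stop(sprintf("program %d must have max_delay %d (got %d)",
                   n, n, p$max_delay), call. = FALSE)
    }
  }
  pool <- list()
  for (n in seq_len(k)) {
    rules <- programs[[n]]$rules
    if (n >= 2L) {
      keep <- vapply(rules, function(r) {
        length(r$delay) > 0L && max(r$delay) == n
      }, logical(1))
      rules <- rules[keep]
    }
    pool <- c(pool, rules)
  }
  pool <- dedupe_rules(pool)
  if (length(pool) > 1L) {
    keys <- vapply(pool, rule_key, character(1))
    drop <- logical(length(pool))
    for (i in seq_along(pool)) {
      for (j in seq_along(pool)) {
        if (i != j && !drop[j] && subsumes(pool[[j]], pool[[i]])) {
          drop[i] <- TRUE
          break
        }
      }
    }
    pool <- pool[!drop]
  }
  logic_program(vars, k, pool)
}

# Extract the learning windows anchored at positions with a full k-lookback:
# for every successor index with at least k predecessors, the depth-n window
# (n = 1..k) reads the n most recent lookback states.  Returns, per depth,
# parallel lists of condition vectors and next states, deduped, plus the
# anchors (trace, position) of each depth-k window for conflict reporting.
aligned_windows <- function(traces, k) {
  vars <- traces[[1L]]$variables
  total <- sum(vapply(traces, function(t) max(0L, length(t$states) - k),
                      integer(1)))
  conds <- vector("list", total)
  nexts <- vector("list", total)
  anchor_trace <- character(total)
  anchor_pos <- integer(total)
  w <- 0L
  for (nm in names(traces)) {
    s <- traces[[nm]]$states
    L <- length(s)
    if (L < k + 1L) next
    for (j in (k + 1L):L) {
      w <- w + 1L
      conds[[w]] <- history_to_cond(s[(j - k):(j - 1L)], vars, k)
      nexts[[w]] <- s[[j]]
      anchor_trace[w] <- nm
      anchor_pos[w] <- j - 2L   # 0-based position of the source state
    }
  }
  list(conds = conds, nexts = nexts,
       anchor_trace = anchor_trace, anchor_pos = anchor_pos)
}

#' Learn a delayed logic program from traces of execution (LFkT)
#'
#' Learns the dynamics of a Markov(k) system from a set of execution traces
#' in four steps: (1) initialize k most-general programs, one per depth
#' n = 1..k; (2) convert the traces into timed interpretation transitions;
#' (3) revise each depth-n program by the n-step transitions through minimal
#' specialization ([lf1t_learn()]); (4) merge the k programs into one
#' ([merge_programs()]).
#'
#' The learners consume the windows anchored at trace positions with a full
#' k-state lookback (the depth-n window at such a position reads the n most
#' recent lookback states).  Anchoring all depths at the same positions
#' guarantees that a depth-n rule dropped by the merge filter is recovered by
#' a shallower learner, so that on every observed position with full
#' k-lookback the merged program reproduces the observed successor exactly.
#' Positions closer than k to a trace start (whose lookback is truncated and,
#' for generated traces, seeded rather than simulated) contribute to the
#' decomposition bookkeeping but not to the hypothesis.
#'
#' Before learning, the extracted depth-k windows are checked for
#' contradictions (same full-k condition, different next states), which no
#' Markov(k) program can realize.  In strict mode (default) a contradiction
#' is an error whose condition object carries the witness report in
#' `$report`; with `strict = FALSE` the conflicting depth-k windows are
#' skipped with a warning and learning proceeds best-effort.
#'
#' @param traces a [bn_trace()] or list of them, over a shared variable set.
#' @param max_delay the delay bound k; must not exceed the transition count
#'   of the longest trace.
#' @param strict logical; see above.
#' @return the merged [logic_program()].  Attribute `bookkeeping` is a data
#'   frame with, per depth, the number of interpretation transitions
#'   extracted by full decomposition, the number of deduplicated windows the
#'   learner absorbed, and the rule count of the depth program; attribute
#'   `depth_programs` holds the per-depth programs before the merge.
#' @examples
#' v <- "a"
#' tr <- bn_trace(list(character(0), character(0)), v)
#' lfkt_learn(tr, 1)  # a <- a[-1]
#' @export
lfkt_learn <- function(traces, max_delay, strict = TRUE) {
  traces <- as_trace_list(traces)
  vars <- traces[[1L]]$variables
  n <- length(vars)
  k <- as.integer(max_delay)
  if (length(k) != 1L || is.na(k) || k < 1L) {
    stop("max_delay must be a single integer >= 1", call. = FALSE)
  }
  m_max <- max(vapply(traces, function(t) length(t$states), integer(1))) - 1L
  if (k > m_max) {
    stop(sprintf("max_delay %d exceeds the longest trace (%d transition(s))",
                 k, m_max), call. = FALSE)
  }
  aw <- aligned_windows(traces, k)

  # contradiction check at full depth k
  ckey <- vapply(aw$conds, paste, character(1), collapse = "")
  nkey <- vapply(aw$nexts, format_state, character(1))
  succ_per_cond <- tapply(nkey, ckey, function(x) length(unique(x)))
  bad <- names(succ_per_cond)[succ_per_cond > 1L]
  drop_w <- rep(FALSE, length(ckey))
  if (length(bad) > 0L) {
    rows <- ckey %in% bad
    report <- data.frame(condition = ckey[rows],
                         trace = aw$anchor_trace[rows],
                         position = aw$anchor_pos[rows],
                         next_state = nkey[rows], stringsAsFactors = FALSE)
    report <- report[order(report$condition, report$trace, report$position), ]
    rownames(report) <- NULL
    if (strict) {
      stop(errorCondition(
        sprintf("traces are not learnable at depth %d: %d condition(s) with conflicting successors (set strict = FALSE to skip them)",
                k, length(bad)),
        class = c("lfkt_inconsistent", "error", "condition"),
        report = report))
    }
    warning(sprintf("skipping %d conflicting window(s) at depth %d; the learned program cannot realize them",
                    sum(rows), k), call. = FALSE)
    drop_w <- rows
  }

  depth_programs <- vector("list", k)
  used <- integer(k)
  for (d in seq_len(k)) {
    Sd <- n * d
    dconds <- lapply(aw$conds, function(cv) cv[seq_len(Sd)])
    dnexts <- aw$nexts
    if (d == k && any(drop_w)) {
      dconds <- dconds[!drop_w]
      dnexts <- dnexts[!drop_w]
    }
    dkey <- paste(vapply(dconds, paste, character(1), collapse = ""),
                  vapply(dnexts, format_state, character(1)))
    first <- !duplicated(dkey)
    used[d] <- sum(first)
    # deterministic processing order
    o <- order(dkey[first])
    depth_programs[[d]] <- lf1t_engine(dconds[first][o], dnexts[first][o],
                                       vars, d)
  }
  merged <- merge_programs(depth_programs)

  m <- vapply(traces, function(t) length(t$states), integer(1)) - 1L
  extracted <- vapply(seq_len(k), function(d) sum(pmax(0L, m - d + 1L)),
                      integer(1))
  attr(merged, "bookkeeping") <- data.frame(
    depth = seq_len(k),
    extracted = extracted,
    used = used,
    rules = vapply(depth_programs, n_rules, integer(1)))
  attr(merged, "depth_programs") <- depth_programs
  merged
}
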