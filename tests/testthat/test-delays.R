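# The delayed layer: timed bases, trace decomposition, consistency, LFkT.

test_that("the timed Herbrand base has one atom per variable and delay", {
  b1 <- timed_herbrand_base(c("a", "b"), 1)
  expect_identical(vapply(b1, format, character(1)), c("a[-1]", "b[-1]"))
  b2 <- timed_herbrand_base(c("a", "b"), 2)
  expect_identical(vapply(b2, format, character(1)),
                   c("a[-1]", "b[-1]", "a[-2]", "b[-2]"))
  expect_length(timed_herbrand_base("a", 3), 3)
  expect_error(timed_herbrand_base("a", 0), ">= 1")
})

test_that("traces need at least one transition and known variables", {
  expect_error(bn_trace(list("a"), "a"), "at least 2 states")
  expect_error(bn_trace(list("a", "z"), "a"), "unknown")
})

test_that("decomposition emits every window of every depth", {
  v <- c("a", "b")
  tr <- bn_trace(list(c("a", "b"), "b", "a"), v)
  d <- decompose_trace(tr, 2)
  expect_length(d, 3)
  expect_setequal(vapply(d, format, character(1)),
                  c("(a[-1] b[-1] => +b) [1-step]",
                    "(b[-1] => +a) [1-step]",
                    "(b[-1] a[-2] b[-2] => +a) [2-step]"))
  # one transition: exactly one 1-step window regardless of k
  short <- bn_trace(list("a", "b"), v)
  expect_length(decompose_trace(short, 5), 1)
  expect_identical(decompose_trace(short, 5)[[1]]$depth, 1L)
})

test_that("decomposition counts follow the window formula", {
  v <- c("a", "b", "c")
  set.seed(71)
  for (i in 1:10) {
    m <- sample(2:7, 1); k <- sample(1:6, 1)
    states <- lapply(seq_len(m + 1), function(j) v[runif(3) < 0.5])
    d <- decompose_trace(bn_trace(states, v), k)
    expected <- sum(vapply(seq_len(min(m, k)), function(n) m - n + 1L,
                           integer(1)))
    expect_length(d, expected)
    # per-depth tally
    depths <- vapply(d, `[[`, integer(1), "depth")
    for (n in seq_len(min(m, k))) expect_identical(sum(depths == n), m - n + 1L)
  }
})

test_that("k-consistency compares lookbacks as observed", {
  v <- c("a", "b")
  t_same <- bn_trace(list(c("a", "b"), "b", "a"), v)
  expect_true(traces_k_consistent(t_same, t_same))
  expect_true(traces_k_consistent(t_same, t_same, k = 1))
  # equal initial state, empty lookbacks, different successors
  t1 <- bn_trace(list("b", "a"), v)
  t2 <- bn_trace(list("b", "b"), v)
  for (k in 1:3) expect_false(traces_k_consistent(t1, t2, k))
  # the conflicting {b} positions are separated by their 2-lookbacks
  u1 <- bn_trace(list(c("a", "b"), "b", "a"), v)
  u2 <- bn_trace(list("a", "b", "b"), v)
  expect_true(traces_k_consistent(u1, u2, 2))
  expect_false(traces_k_consistent(u1, u2, 0))
})

test_that("check_trace_set reports witnesses over whole trace sets", {
  p <- example4_program()
  # trajectories seeded at pairwise distinct initial states never collide
  # on clipped lookbacks; later positions are covered by determinism
  inits <- list(list(character(0), character(0)), list("a", "a"),
                list("b", "b"), list(c("a", "b"), c("a", "b")))
  traces <- lapply(inits, function(h) simulate_program(p, h, 4))
  rep <- check_trace_set(traces, 2)
  expect_true(rep$consistent)
  expect_identical(nrow(rep$witnesses), 0L)

  v <- c("a", "b")
  bad <- list(bn_trace(list("b", "a"), v), bn_trace(list("b", "b"), v))
  rep2 <- check_trace_set(bad, 2)
  expect_false(rep2$consistent)
  expect_identical(nrow(rep2$witnesses), 2L)
  expect_setequal(rep2$witnesses$next_state, c("+a", "+b"))
})

test_that("the ambiguous state has three 1-step successors but none 2-step", {
  p <- example4_program()
  succ <- one_step_successors(p, "b")
  expect_setequal(vapply(succ, format_state, character(1)),
                  c("-", "+a", "+b"))
  # at full 2-lookback the system is deterministic
  dg <- enumerate_diagram(p)
  expect_identical(anyDuplicated(dg$history), 0L)
})

test_that("merge drops deep rules without a literal at their depth", {
  v <- c("a", "b")
  p1 <- logic_program(v, 1, lp_rule("a", lit("b", 1)))
  p2 <- logic_program(v, 2, lp_rule("a", lit("b", 1)))
  merged <- merge_programs(list(p1, p2))
  expect_identical(vapply(merged$rules, format, character(1)), "a <- b[-1].")

  # depth-2 rule with a delay-2 literal is kept but pruned by subsumption
  p2b <- logic_program(v, 2, lp_rule("a", list(lit("b", 1), lit("b", 2))))
  merged2 <- merge_programs(list(p1, p2b))
  expect_identical(vapply(merged2$rules, format, character(1)), "a <- b[-1].")

  # k = 1: merge is the identity on the single program
  expect_identical(merge_programs(list(p1))$rules, p1$rules)
  expect_error(merge_programs(list(p2)), "max_delay 1")
})

test_that("LFkT recovers the Markov(2) worked system from exhaustive traces", {
  truth <- example4_program()
  traces <- generate_traces(truth, n_transitions = 2, mode = "exhaustive")
  expect_length(traces, 16)
  learned <- lfkt_learn(traces, 2)
  expect_true(programs_equivalent(learned, truth))
  bk <- attr(learned, "bookkeeping")
  expect_identical(bk$extracted, c(32L, 16L))
})

test_that("a Markov(1) system learned at k = 2 keeps no delay-2 rule", {
  p1 <- logic_program(c("a", "b"), 1, list(
    lp_rule("a", lit("b", 1)),
    lp_rule("b", lit("a", 1, positive = FALSE))))
  embedded <- logic_program(p1$variables, 2, p1$rules)
  l2 <- lfkt_learn(generate_traces(embedded, n_transitions = 2,
                                   mode = "exhaustive"), 2)
  expect_false(any(vapply(l2$rules, function(r) {
    length(r$delay) > 0 && max(r$delay) == 2
  }, logical(1))))
  l1 <- lfkt_learn(generate_traces(p1, n_transitions = 1,
                                   mode = "exhaustive"), 1)
  expect_true(programs_equivalent(l1, l2))
})

test_that("a single constant trace yields the self-activation rule", {
  tr <- bn_trace(list(character(0), character(0)), "a")
  p <- lfkt_learn(tr, 1)
  expect_identical(vapply(p$rules, format, character(1)), "a <- a[-1].")
})

test_that("LFkT validates the delay bound and rejects conflicting data", {
  v <- c("a", "b")
  tr <- bn_trace(list("b", "a"), v)
  expect_error(lfkt_learn(tr, 2), "exceeds the longest trace")
  bad <- list(bn_trace(list("b", "a"), v), bn_trace(list("b", "b"), v))
  err <- tryCatch(lfkt_learn(bad, 1), condition = function(e) e)
  expect_s3_class(err, "lfkt_inconsistent")
  expect_identical(nrow(err$report), 2L)
  expect_setequal(err$report$next_state, c("+a", "+b"))
  # permissive mode warns and learns best-effort from the rest
  expect_warning(p <- lfkt_learn(bad, 1, strict = FALSE), "skipping")
  expect_s3_class(p, "logic_program")
})

test_that("more traces from the same system never break earlier ones", {
  truth <- generate_program(generator_config(3, 2, 3, 1:2, seed = 1234))
  all_traces <- generate_traces(truth, n_transitions = 3, mode = "exhaustive")
  small <- all_traces[seq(1, length(all_traces), by = 7)]
  learned_small <- lfkt_learn(small, 2)
  learned_big <- lfkt_learn(all_traces, 2)
  # full-lookback windows of the early subset remain realized and consistent
  full_small <- unlist(lapply(small, function(t) {
    Filter(function(x) x$depth == 2, decompose_trace(t, 2))
  }), recursive = FALSE)
  expect_true(program_consistent(learned_small, full_small))
  expect_true(program_consistent(learned_big, full_small))
})

test_that("merged rules are consistent with the full-depth windows", {
  for (i in 1:4) {
    truth <- generate_program(generator_config(3, 2, 3, 1:2, seed = 400 + i))
    traces <- generate_traces(truth, n_transitions = 2, mode = "exhaustive")
    learned <- lfkt_learn(traces, 2)
    full <- unlist(lapply(traces, function(t) {
      Filter(function(x) x$depth == 2, decompose_trace(t, 2))
    }), recursive = FALSE)
    expect_true(program_consistent(learned, full))
    # realization: on every full lookback the prediction is the observation
    for (t in traces) {
      expect_identical(tp_next(learned, t$states[1:2]), t$states[[3]])
    }
  }
})
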