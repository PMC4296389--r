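# Rule algebra: subsumption, consistency, anti-rules, the T_P operator.

test_that("subsumption compares heads and literal-wise body containment", {
  r_b <- lp_rule("a", lit("b", 1))
  r_ab <- lp_rule("a", list(lit("a", 1), lit("b", 1)))
  r_bnc <- lp_rule("a", list(lit("b", 1), lit("c", 1, positive = FALSE)))
  expect_true(subsumes(r_b, r_ab))
  # heads differ
  expect_false(subsumes(r_b, lp_rule("b", list(lit("a", 1), lit("b", 1)))))
  expect_false(subsumes(r_bnc, r_b))
  # sign and delay must match, not just the variable
  expect_false(subsumes(lp_rule("a", lit("b", 1, positive = FALSE)), r_ab))
  expect_false(subsumes(lp_rule("a", lit("b", 2)), r_ab))
})

test_that("subsumption is reflexive, transitive and antisymmetric", {
  set.seed(42)
  vars <- c("a", "b", "c")
  for (i in 1:40) {
    r1 <- random_small_rule(vars, 2)
    r2 <- random_small_rule(vars, 2)
    r3 <- random_small_rule(vars, 2)
    expect_true(subsumes(r1, r1))
    if (subsumes(r1, r2) && subsumes(r2, r3)) expect_true(subsumes(r1, r3))
    if (subsumes(r1, r2) && subsumes(r2, r1)) {
      expect_identical(format(r1), format(r2))
    }
  }
})

test_that("contradictory bodies are rejected at construction", {
  expect_error(lp_rule("a", list(lit("b", 1), lit("b", 1, positive = FALSE))),
               "contradictory")
  # same variable at different delays is fine
  expect_s3_class(lp_rule("a", list(lit("b", 1), lit("b", 2, positive = FALSE))),
                  "lp_rule")
})

test_that("rule consistency with an interpretation transition", {
  tr_fire <- itransition(data.frame(var = "b", delay = 1), "a", 1)
  expect_true(rule_consistent(lp_rule("a", lit("b", 1)), tr_fire))
  # a fact rule always fires; head absent from the empty next state
  tr_eps <- itransition(data.frame(var = "a", delay = 1), character(0), 1)
  expect_false(rule_consistent(fact_rule("a"), tr_eps))
  # body does not fire: vacuously consistent
  tr_b <- itransition(data.frame(var = "b", delay = 1), character(0), 1)
  expect_true(rule_consistent(lp_rule("a", lit("c", 1)), tr_b))
  # incomparable horizon is an error, not a verdict
  expect_error(rule_consistent(lp_rule("a", lit("b", 2)), tr_fire),
               "incomparable horizon")
})

test_that("tp_next evaluates timed bodies against the recent history", {
  p3 <- example3_program()
  expect_identical(tp_next(p3, list("a")), character(0))
  expect_identical(tp_next(p3, list(character(0))), "c")
  p4 <- example4_program()
  expect_identical(tp_next(p4, list(c("a", "b"), "b")), "a")
  expect_error(tp_next(p4, list("b")), "history")
})

test_that("tp_next agrees with the naive set-membership oracle", {
  set.seed(7)
  for (i in 1:15) {
    n <- sample(2:3, 1); k <- sample(1:2, 1)
    p <- generate_program(generator_config(n, k, 3, 1:2, seed = 300 + i))
    for (h in all_histories(p$variables, k)) {
      expect_identical(tp_next(p, h), oracle_tp(p, h))
    }
  }
})

test_that("a program of fact rules predicts everything true", {
  vars <- c("a", "b", "c")
  p <- initial_program(vars, 2)
  for (h in all_histories(vars, 2)[c(1, 5, 16, 64)]) {
    expect_identical(tp_next(p, h), vars)
  }
})

test_that("anti-rules are fully specified, one per absent head", {
  vars <- c("a", "b", "c")
  tr <- itransition(data.frame(var = "a", delay = 1), character(0), 1)
  ar <- anti_rules(tr, vars)
  expect_length(ar, 3)
  expect_setequal(vapply(ar, `[[`, character(1), "head"), vars)
  for (r in ar) {
    expect_identical(format(r),
                     paste0(r$head, " <- a[-1], not b[-1], not c[-1]."))
  }
  # no absent head: no anti-rules
  tr_all <- itransition(data.frame(var = character(0), delay = integer(0)),
                        "a", 1)
  expect_length(anti_rules(tr_all, "a"), 0)
  # depth-2 condition
  tr2 <- itransition(data.frame(var = c("a", "a"), delay = c(1, 2)), "a", 2)
  ar2 <- anti_rules(tr2, c("a", "b"))
  expect_length(ar2, 1)
  expect_identical(format(ar2[[1]]),
                   "b <- a[-1], not b[-1], a[-2], not b[-2].")
})

test_that("every anti-rule body covers the whole timed base", {
  set.seed(11)
  vars <- c("a", "b", "c")
  for (i in 1:20) {
    k <- sample(1:3, 1)
    cond_var <- vars[runif(3) < 0.5]
    d <- sample(seq_len(k), length(cond_var), replace = TRUE)
    nxt <- vars[runif(3) < 0.5]
    tr <- itransition(data.frame(var = cond_var, delay = d), nxt, k)
    for (r in anti_rules(tr, vars)) {
      expect_length(r$var, length(vars) * k)
    }
  }
})

test_that("program consistency is the conjunction over comparable pairs", {
  expect_true(program_consistent(logic_program("a", 1, list()), list(
    itransition(data.frame(var = "a", delay = 1), character(0), 1))))
  tr_eps <- itransition(data.frame(var = "a", delay = 1), character(0), 1)
  expect_false(program_consistent(logic_program("a", 1, fact_rule("a")),
                                  list(tr_eps)))
  # a rule looking deeper than the window is skipped, not violated
  p2 <- logic_program("a", 2, lp_rule("a", lit("a", 2)))
  expect_true(program_consistent(p2, list(tr_eps)))
})

test_that("removing a subsumed rule never changes the dynamics", {
  set.seed(21)
  for (i in 1:10) {
    p <- generate_program(generator_config(3, 2, 2, 1L, seed = 500 + i))
    base <- p$rules[[sample(length(p$rules), 1)]]
    extra_lit <- lit(sample(p$variables, 1), sample(1:2, 1),
                     sample(c(TRUE, FALSE), 1))
    if (paste(extra_lit$var, extra_lit$delay) %in% paste(base$var, base$delay)) next
    sub_rule <- lp_rule(base$head, c(
      lapply(seq_along(base$var), function(j) {
        lit(base$var[j], base$delay[j], base$positive[j])
      }), list(extra_lit)))
    bigger <- logic_program(p$variables, 2, c(p$rules, list(sub_rule)))
    expect_true(programs_equivalent(p, bigger))
  }
})
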