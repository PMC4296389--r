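---
title: "Learning delayed Boolean network dynamics from state transition traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning delayed Boolean network dynamics from state transition traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfkt)
```

## The problem

Boolean networks are the workhorse discrete model of gene regulatory
networks: each gene is a binary variable (expressed / not expressed) and a
Boolean update function computes its next value from the current state of
its regulators, all genes updating synchronously.  The classical model
assumes every influence acts with a homogeneous one-step delay.  Real
regulation is not like that: transcription, translation, transport and
binding all take time, and some interactions act on the product of a gene
several measurement steps ago.  A system with such *delayed influences* has
memory — its next state depends on up to the k previous states, a Markov(k)
dynamics — and a one-step model of it looks spuriously non-deterministic.

`lfkt` solves the corresponding inverse problem: given observed **traces of
execution** (finite sequences of states produced by the synchronous
dynamics), infer a logic program over **timed literals** that reproduces the
dynamics, including its delayed influences.

## The model

A *state* is the subset of variables currently true (the empty state prints
as `-`).  A *rule*

```
a <- b[-1], not b[-2].
```

reads: `a` is true at time t when `b` was true at t−1 and false at t−2.  The
literal `v[-d]` is the variable `v` read at delay `d >= 1`; a rule with an
empty body (`a <-.`) is a *fact rule* and fires unconditionally.  A *logic
program* over a variable set B with maximum delay k is a set of such rules
with all body delays in `[1, k]`; its semantics is the immediate consequence
operator ([tp_next()]): the next state contains exactly the heads of the
rules whose bodies hold in the last k states.  This is a synchronous,
deterministic Markov(k) state transition system.

```{r model}
p <- logic_program(c("a", "b"), 2, list(
  lp_rule("a", list(lit("b", 1), lit("b", 2))),
  lp_rule("b", list(lit("a", 2), lit("b", 2, positive = FALSE)))))
p
simulate_program(p, initial = list(c("a", "b"), "b"), steps = 3)
```

Projected onto single states, a Markov(2) system can look non-deterministic:

```{r ambiguity}
sapply(one_step_successors(p, "b"), format_state)
```

Seen only through 1-step transitions, state `+b` has three possible
successors; the ambiguity is resolved by the state at t−2.  This signature
is exactly what the learner exploits to identify delays.

## Learning one depth: anti-rules and minimal specialization

The single-depth learner ([lf1t_learn()]) works bottom-up.  It starts from
the most general hypothesis — one fact rule per variable, predicting
everything true — and revises it against each observed *interpretation
transition* (I, J), where I records which variables were true at which delay
in the window before the observed next state J.  For every variable `A`
absent from J, the fully specified **anti-rule** `A <- I` marks a condition
under which `A` must *not* be derived.  Every hypothesis rule that subsumes
the anti-rule (same head, body contained in the anti-rule body) is replaced
by its **minimal specializations**: one offspring per excess literal of the
anti-rule, extending the body with that literal's negation.  Offspring
subsumed by a surviving rule are discarded.

Two properties make this more than a heuristic.  The hypothesis is *any
time*: after each absorbed transition it is consistent with everything seen
so far.  And on a complete, non-contradictory transition set the final
program is the set of all most-general consistent rules — every body is a
*prime implicant condition*: no strict sub-body remains consistent with the
observations.  The test suite checks both by brute force on exhaustively
enumerated small systems.

```{r lf1t}
trs <- list(
  itransition(data.frame(var = character(0), delay = integer(0)), "a", 1),
  itransition(data.frame(var = "a", delay = 1), character(0), 1))
lf1t_learn(trs, "a", depth = 1)
```

## Learning delays: decomposition, per-depth learners, merge

[lfkt_learn()] lifts the learner to Markov(k).  A trace of m transitions is
decomposed into timed windows: every position and every window length n with
`1 <= n <= min(position, k)` yields one n-step interpretation transition, so
a 5-transition trace carries 15 windows at k = 5 (one 5-step, two 4-step,
three 3-step, four 2-step, five 1-step) — [decompose_trace()] reports
exactly this bookkeeping.  One learner per depth n absorbs n-step windows;
finally the k programs are merged: from the depth-n program (n >= 2) every
rule with no literal at delay n is dropped — a rule that does not actually
use its depth belongs to a shallower learner, which either learned it too
(it is redundant here) or refuted it (it must not survive) — and the pooled
rules are pruned for subsumption.

One design choice deserves emphasis.  The learners consume only windows
**anchored at positions with a full k-state lookback**; the depth-n window
at such a position reads the n most recent lookback states.  The first k
states of a trace are its seed history: they are initial conditions, not
products of the dynamics, and in exhaustively generated trace sets they
realize every possible state combination.  Feeding seed-internal windows to
the shallow learners would let these arbitrary juxtapositions refute
genuinely shallow rules, and the merge filter would then lose every rule
whose maximum delay is below k.  Anchoring all depths at the same positions
gives an alignment property — a depth-n rule consistent with the anchored
n-step windows is consistent with the anchored d-step windows for every
d below n — which is what makes the merge filter sound.  The cost is that
traces shorter than k+1 states contribute bookkeeping but no hypothesis
windows.

```{r lfkt}
traces <- generate_traces(p, n_transitions = 2, mode = "exhaustive")
learned <- lfkt_learn(traces, max_delay = 2)
learned
attr(learned, "bookkeeping")
identical(enumerate_diagram(learned), enumerate_diagram(p))
```

## Two notions of trace consistency

The package deliberately exposes two different checks.

[check_trace_set()] / [traces_k_consistent()] are *diagnostics*: two traces
conflict when the same state, with the same observed lookback (clipped at
the trace start), is followed by different successors.  Lookbacks are
compared exactly as observed, so two traces that disagree immediately after
identical initial states are flagged even though unobserved earlier states
might disambiguate them.  This is the conservative notion a curator wants
when auditing a data set.

[lfkt_learn()] pre-checks *learnability* instead: an error is raised only
when two windows with full k-lookback share a condition but disagree on the
successor — the one situation no Markov(k) program can realize.  Exhaustive
trace sets of a deterministic program always pass this check, although their
seed histories trip the stricter diagnostic for k >= 2 (all seed
combinations occur, so some pair shares a clipped prefix and diverges).  In
strict mode (default) a conflict is a hard error carrying a witness report;
`strict = FALSE` downgrades it to a warning and skips the conflicting
windows, for exploratory use on noisy data — the realization guarantee is
then void.

## Tunable parameters

* `max_delay` (k, in time steps of the trace sampling): the delay bound the
  learner searches within.  It is an input, not estimated; the CLI defaults
  it to the transition count of the longest trace, the largest learnable
  horizon.
* `n_transitions` in [generate_traces()]: total transitions per trace; the
  first k states are the seed history, so `n_transitions = k` yields the
  shortest usable traces (one simulated step) and larger values add
  simulated steps.
* [generator_config()] defaults — 16 variables, `max_delay` 5, at most 3
  body literals, 1–2 rules per variable: the dimensions of published delayed
  Boolean models of the yeast cell cycle, with in-degrees typical of curated
  Boolean gene models.  Identical seed and configuration always reproduce
  the same program.
* `cap` (default 2^20 histories) guards [enumerate_diagram()] and exhaustive
  generation: the history space has size `2^(n*k)` and enumeration beyond
  ~10^6 columns is better replaced by sampling.

## Numerical and degenerate-input choices

Rules and bodies live in a canonical order (head name, body size, then
literals by delay, variable, sign), so serialized output is diffable and
run-to-run stable.  Bodies with a variable at the same delay in both signs
are rejected at construction — the semantics never constructs them.
Duplicate transitions are absorbed idempotently; window processing order is
fixed by sorting, which makes intermediate hypotheses reproducible (final
semantics on complete input is order-independent, and a property test
checks this).  Degenerate inputs error early with precise messages: empty
variable sets, traces with fewer than two states, histories shorter than
the delay bound, delays outside the declared range in the rule language,
non-binary or gapped trace tables.

## What the generator does and does not emulate

The random generator reproduces the *shape* of published delayed
gene-network benchmarks — variable counts, delay bounds, trace lengths,
sparse rule bodies — with random rule content, and the simulator produces
noise-free, perfectly synchronous, fully observed Boolean traces.  Passing
the closed-loop recovery suite therefore shows that the learner identifies
Markov(k) dynamics exactly under those idealized conditions.  It does not
show robustness to measurement noise, to discretization error (inputs are
assumed already binarized), to unobserved regulators, or to asynchronous or
multi-valued update schemes — all outside this package's scope.

## Problem sizes and known limitations

The bundled tests and the acceptance script run the recovery suite on 100
random programs with up to 4 variables and delays up to 3 (history spaces up
to 2^12, exhaustively enumerated), brute-force minimality checks on systems
with up to 3 variables and depth 2, and bookkeeping-only scaling sweeps at
16 variables with up to 10,000 traces.  These sizes were chosen to keep the
closed loop exhaustive — every history checked, no sampling error.

The main structural limitation is the version space: with S timed atoms and
very few observations, the set of most-general consistent rules can grow
combinatorially (minimal hitting sets over the falsifying literals of each
forbidden condition), so learning 16-variable, depth-5 systems from a
handful of traces is intractable for any complete specialization learner —
data volume, not variable count, is what tames the hypothesis space.
Further limitations: the delay bound k is supplied, not selected by model
comparison; dynamics must be deterministic and synchronous; recovery is of
the dynamics (semantic equivalence), not necessarily of the syntactic rule
set that generated them.
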