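# lfkt

Inference of Boolean networks with **delayed influences** from observed
state-transition traces.

## The problem

Boolean networks model gene regulation as binary variables updated
synchronously by Boolean functions of their regulators. The classical model
gives every influence the same one-step delay, but real interactions act on
the state of a regulator several measurement steps back — the system has
memory. Such a **Markov(k)** dynamics, viewed through single transitions,
looks non-deterministic; the extra successors are the footprint of delays.

`lfkt` is for computational biologists and modellers who have discretized
time-series of expression states and want an executable, delay-aware model
back. It represents the dynamics as a **normal logic program with timed
bodies**: a rule

```
a <- b[-1], not b[-2].
```

says `a` is true at time t when `b` was true at t−1 and false at t−2. The
semantics is the immediate consequence operator T_P: the next state contains
exactly the heads of the rules whose bodies hold in the last k states,

```
T_P(I) = { h(R) : R in P, b+(R) ⊆ I, b−(R) ∩ I = ∅ },
```

with I an interpretation over the timed base B_k = { v[-d] : v ∈ B, 1 ≤ d ≤ k }.

## The algorithm

Learning is bottom-up by **minimal specialization** (the LF1T/LFkT family):

1. start from the most general program, one fact rule per variable;
2. decompose each trace into timed interpretation transitions (a
   5-transition trace yields 15 windows at k = 5: one 5-step … five 1-step);
3. for every window and every variable absent from its next state, build the
   fully specified **anti-rule** and replace each hypothesis rule subsuming
   it by its minimal specializations (one flipped excess literal each),
   one learner per delay depth;
4. merge the k per-depth programs, dropping depth-n rules that use no
   delay-n literal and pruning subsumed rules.

On complete, non-contradictory input the result realizes every observed
transition and every rule body is a **prime implicant condition** — no
strict sub-body stays consistent with the data.

## Worked example

The Markov(2) system `{a <- b[-1], b[-2];  b <- a[-2], not b[-2]}`:

```r
library(lfkt)
p <- logic_program(c("a", "b"), 2, list(
  lp_rule("a", list(lit("b", 1), lit("b", 2))),
  lp_rule("b", list(lit("a", 2), lit("b", 2, positive = FALSE)))))

simulate_program(p, initial = list(c("a", "b"), "b"), steps = 3)
#> +a+b -> +b -> +a -> - -> +b
```

A single trace carries several timed readings:

```r
tr <- bn_trace(list(c("a", "b"), "b", "a"), c("a", "b"))
decompose_trace(tr, 2)
#> (a[-1] b[-1] => +b) [1-step]
#> (b[-1] => +a) [1-step]
#> (b[-1] a[-2] b[-2] => +a) [2-step]
```

Learning from the 16 exhaustive traces (every 2-state history plus one
synchronous step) recovers the generator exactly:

```r
traces <- generate_traces(p, n_transitions = 2, mode = "exhaustive")
learned <- lfkt_learn(traces, max_delay = 2)
learned
#> Logic program: 2 variable(s), max delay 2, 2 rule(s)
#> vars: a, b.
#> delay: 2.
#> a <- b[-1], b[-2].
#> b <- a[-2], not b[-2].

attr(learned, "bookkeeping")
#>   depth extracted used rules
#> 1     1        32   10     0
#> 2     2        16   16     2

identical(enumerate_diagram(learned), enumerate_diagram(p))
#> [1] TRUE

sapply(one_step_successors(learned, "b"), format_state)
#> [1] "-"  "+b" "+a"
```

The bookkeeping rows show the decomposition arithmetic (32 one-step and 16
two-step windows extracted from 16 two-transition traces) and that the
depth-1 learner alone finds no rule at all — state `+b` has three distinct
1-step successors (`-`, `+b`, `+a`), so the dynamics is identifiable only at
depth 2.

## Command line

A thin CLI wraps the same functions (installed under `exec/`):

```sh
lfkt generate --n-variables 3 --delay 2 --seed 5 \
     --out-rules net.lp --n-traces 10 --n-transitions 5 --out-traces tr.csv
lfkt learn    --traces tr.csv --delay 2 --out learned.lp
lfkt check    --traces tr.csv --delay 2
lfkt simulate --rules net.lp --steps 5 --seed 9
lfkt diagram  --rules net.lp --out edges.tsv
```

`learn` logs the per-depth transition counts and rule counts to stderr;
exit codes are 0 (success), 1 (input error), 2 (inconsistent traces).

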