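Package: lfkt
Title: Learning Delayed Boolean Network Dynamics from State Transition Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers normal logic programs -- equivalently Boolean networks
    with delayed, Markov(k) influences -- from observed traces of synchronous
    state transitions.  Implements bottom-up rule learning by minimal
    specialization (LF1T) and its extension to delayed influences (LFkT):
    traces are decomposed into timed interpretation transitions, one learner
    per delay depth revises a most-general hypothesis against anti-rules, and
    the per-depth programs are merged into a single delayed logic program.
    Includes a synchronous simulator, exhaustive state-transition-diagram
    enumeration, seeded random ground-truth generators for closed-loop
    benchmarking, a plain-text rule language and trace tables, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
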