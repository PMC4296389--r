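# LF1T: bottom-up learning by minimal specialization.
#
# The learner starts from the most general program (one fact rule per
# variable, which predicts everything true) and revises it transition by
# transition: for every variable absent from an observed next state, the
# fully specified anti-rule marks the condition where that head must not be
# derived, and every hypothesis rule subsuming the anti-rule is replaced by
# its minimal specializations (one flipped excess literal each).  On a
# complete, non-contradictory transition set the result is the set of all
# most-general rules consistent with the observations: each body is a prime
# implicant condition for its head.
#
# The hot loop runs on the compiled incidence-matrix representation (one
# pos/neg 0/1 matrix pair per head); the public operations ms_rule() and
# ms_program() expose the same specialization step on plain rule objects.

#' Most general initial program
#'
#' The starting hypothesis of the learner: one fact rule per variable, so
#' that every variable is predicted true in every next state.  Learning
#' proceeds by specializing these rules against the observations.
#'
#' @param variables character vector, the Herbrand base (non-empty).
#' @param depth maximum delay of the program to be learned (>= 1).
#' @return a [logic_program()] of fact rules with `max_delay = depth`.
#' @examples
#' initial_program(c("a", "b"), depth = 2)
#' @export
initial_program <- function(variables, depth) {
  variables <- check_variables(variables)
  logic_program(variables, depth, lapply(variables, fact_rule))
}

#' Minimal specialization of one rule over another
#'
#' Given `r1` subsuming `r2` (same head, body of `r1` contained in the body
#' of `r2`), returns the least-general weakenings of `r1` that no longer
#' subsume `r2`: one rule per excess literal `l` of `body(r2) \ body(r1)`,
#' each extending `body(r1)` with the sign-flipped literal `not l`.  The
#' result is empty when the bodies are equal.
#'
#' @param r1,r2 rules of class `lp_rule` with equal heads, `r1` subsuming
#'   `r2`; violating the precondition is an error.
#' @return a list of `lp_rule` objects.
#' @examples
#' ms_rule(fact_rule("a"),
#'         lp_rule("a", list(lit("a", 1), lit("b", 1, positive = FALSE))))
#' @export
ms_rule <- function(r1, r2) {
  stopifnot(inherits(r1, "lp_rule"), inherits(r2, "lp_rule"))
  if (r1$head != r2$head) {
    stop("ms_rule requires rules with equal heads", call. = FALSE)
  }
  if (!subsumes(r1, r2)) {
    stop("ms_rule requires that r1 subsumes r2", call. = FALSE)
  }
  excess <- !(rule_body_tokens(r2) %in% rule_body_tokens(r1))
  idx <- which(excess)
  lapply(idx, function(i) {
    new_rule(r1$head,
             c(r1$var, r2$var[i]),
             c(r1$delay, r2$delay[i]),
             c(r1$positive, !r2$positive[i]))
  })
}

#' Minimal specialization of a program against a rule
#'
#' Every rule of `p` that subsumes `anti` is replaced by its [ms_rule()]
#' offspring; rules that never subsumed `anti` are untouched.  Offspring that
#' are subsumed by another rule of the result are discarded, keeping the
#' program irredundant.  Afterwards no rule of the result subsumes `anti`.
#'
#' @param p a [logic_program()].
#' @param anti the rule to avoid subsuming (typically an anti-rule from
#'   [anti_rules()]).
#' @return the revised [logic_program()].
#' @export
ms_program <- function(p, anti) {
  stopifnot(inherits(p, "logic_program"), inherits(anti, "lp_rule"))
  hits <- vapply(p$rules, subsumes, logical(1), r2 = anti)
  if (!any(hits)) return(p)
  kept <- p$rules[!hits]
  offspring <- dedupe_rules(unlist(lapply(p$rules[hits], ms_rule, r2 = anti),
                                   recursive = FALSE))
  # sort by body size so a potential subsumer is considered first
  if (length(offspring) > 1L) {
    offspring <- offspring[order(lengths(lapply(offspring, `[[`, "var")))]
  }
  accepted <- list()
  for (cand in offspring) {
    dominated <- any(vapply(kept, subsumes, logical(1), r2 = cand)) ||
      any(vapply(accepted, subsumes, logical(1), r2 = cand))
    if (!dominated) accepted <- c(accepted, list(cand))
  }
  logic_program(p$variables, p$max_delay, c(kept, accepted))
}

# ---- compiled engine -------------------------------------------------------

# One head's hypothesis: R x S incidence matrices (rows = rules).
engine_init_head <- function(S) {
  list(pos = matrix(0, nrow = 1L, ncol = S),
       neg = matrix(0, nrow = 1L, ncol = S))
}

# Specialize one head's rules against a fully specified condition `cvec`
# (0/1 over slots) on which the head must not be derived.
engine_specialize <- function(mats, cvec) {
  R <- nrow(mats$pos)
  if (R == 0L) return(mats)
  viol <- mats$pos %*% (1 - cvec) + mats$neg %*% cvec
  sub <- which(viol == 0)
  if (length(sub) == 0L) return(mats)
  keep <- setdiff(seq_len(R), sub)
  kpos <- mats$pos[keep, , drop = FALSE]
  kneg <- mats$neg[keep, , drop = FALSE]
  S <- ncol(mats$pos)

  opos_list <- vector("list", length(sub))
  oneg_list <- vector("list", length(sub))
  for (ii in seq_along(sub)) {
    r <- sub[ii]
    free <- which(mats$pos[r, ] == 0 & mats$neg[r, ] == 0)
    m <- length(free)
    if (m == 0L) next
    op <- matrix(mats$pos[r, ], nrow = m, ncol = S, byrow = TRUE)
    on <- matrix(mats$neg[r, ], nrow = m, ncol = S, byrow = TRUE)
    j <- seq_len(m)
    in_cond <- cvec[free] == 1
    # flipped excess literal: a positive anti literal joins negatively
    if (any(in_cond)) on[cbind(j[in_cond], free[in_cond])] <- 1
    if (any(!in_cond)) op[cbind(j[!in_cond], free[!in_cond])] <- 1
    opos_list[[ii]] <- op
    oneg_list[[ii]] <- on
  }
  opos <- do.call(rbind, opos_list)
  oneg <- do.call(rbind, oneg_list)
  if (is.null(opos) || nrow(opos) == 0L) {
    return(list(pos = kpos, neg = kneg))
  }
  one_parent <- length(sub) == 1L
  if (!one_parent) {
    # offspring of distinct parents can coincide; dedupe
    key <- paste(apply(opos, 1L, paste, collapse = ""),
                 apply(oneg, 1L, paste, collapse = ""))
    first <- !duplicated(key)
    opos <- opos[first, , drop = FALSE]
    oneg <- oneg[first, , drop = FALSE]
  }
  # drop offspring subsumed by a surviving rule
  if (nrow(kpos) > 0L) {
    z <- (kpos %*% t(1 - opos) == 0) & (kneg %*% t(1 - oneg) == 0)
    dominated <- colSums(z) > 0
    opos <- opos[!dominated, , drop = FALSE]
    oneg <- oneg[!dominated, , drop = FALSE]
  }
  # drop offspring subsumed by a more general sibling (same-parent siblings
  # have equal body sizes and cannot subsume one another)
  if (!one_parent && nrow(opos) > 1L) {
    sizes <- rowSums(opos) + rowSums(oneg)
    o <- order(sizes)
    opos <- opos[o, , drop = FALSE]
    oneg <- oneg[o, , drop = FALSE]
    keep_row <- rep(TRUE, nrow(opos))
    for (jj in 2:nrow(opos)) {
      gen <- which(keep_row[seq_len(jj - 1L)])
      if (length(gen) == 0L) next
      z <- (opos[gen, , drop = FALSE] %*% (1 - opos[jj, ]) == 0) &
           (oneg[gen, , drop = FALSE] %*% (1 - oneg[jj, ]) == 0)
      if (any(z)) keep_row[jj] <- FALSE
    }
    opos <- opos[keep_row, , drop = FALSE]
    oneg <- oneg[keep_row, , drop = FALSE]
  }
  list(pos = rbind(kpos, opos), neg = rbind(kneg, oneg))
}

# Decode one head's incidence matrices back into lp_rule objects.
engine_decompile <- function(head, mats, variables) {
  n <- length(variables)
  lapply(seq_len(nrow(mats$pos)), function(r) {
    sp <- which(mats$pos[r, ] > 0)
    sn <- which(mats$neg[r, ] > 0)
    s <- c(sp, sn)
    new_rule(head,
             variables[(s - 1L) %% n + 1L],
             (s - 1L) %/% n + 1L,
             rep(c(TRUE, FALSE), c(length(sp), length(sn))))
  })
}

# Core learner shared by lf1t_learn() and lfkt_learn(): `conds` is a list of
# 0/1 condition vectors over B_depth, `nexts` the matching list of next
# states (character vectors).  Duplicate windows are absorbed idempotently.
lf1t_engine <- function(conds, nexts, variables, depth) {
  n <- length(variables)
  S <- n * depth
  engines <- lapply(variables, function(v) engine_init_head(S))
  names(engines) <- variables
  seen <- new.env(parent = emptyenv())
  for (w in seq_along(conds)) {
    key <- paste(paste(conds[[w]], collapse = ""),
                 paste(nexts[[w]], collapse = ","))
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    absent <- setdiff(variables, nexts[[w]])
    for (h in absent) {
      engines[[h]] <- engine_specialize(engines[[h]], conds[[w]])
    }
  }
  rules <- unlist(lapply(variables, function(h) {
    engine_decompile(h, engines[[h]], variables)
  }), recursive = FALSE)
  logic_program(variables, depth, rules)
}

itransition_to_cond <- function(tr, variables, depth) {
  cvec <- numeric(length(variables) * depth)
  if (length(tr$var) > 0L) {
    cvec[slot_index(match(tr$var, variables), tr$delay, length(variables))] <- 1
  }
  cvec
}

#' Learn a logic program from fixed-depth interpretation transitions
#'
#' Runs the bottom-up specialization learner on a set of interpretation
#' transitions that all share the same depth.  Starting from the most general
#' program ([initial_program()]), each transition's anti-rules trigger
#' minimal specialization of every hypothesis rule that subsumes them; the
#' learner is any-time (the hypothesis is valid after each absorbed
#' transition) and duplicate transitions have no effect the second time.
#'
#' The input is assumed non-contradictory at its depth (no two transitions
#' with the same condition and different next states); contradictions are
#' detected upstream by [lfkt_learn()] / [check_trace_set()].
#'
#' @param transitions list of [itransition()] objects, all of depth `depth`.
#' @param variables the Herbrand base.
#' @param depth window depth of the transitions.
#' @return the learned [logic_program()]; on complete input, every rule body
#'   is a prime implicant condition for its head.
#' @examples
#' trs <- list(
#'   itransition(data.frame(var = character(0), delay = integer(0)), "a", 1),
#'   itransition(data.frame(var = "a", delay = 1), character(0), 1))
#' lf1t_learn(trs, "a", depth = 1)  # a <- not a[-1]
#' @export
lf1t_learn <- function(transitions, variables, depth) {
  variables <- check_variables(variables)
  depth <- as.integer(depth)
  if (inherits(transitions, "itransition")) transitions <- list(transitions)
  ok <- vapply(transitions, inherits, logical(1), "itransition")
  if (!all(ok)) stop("transitions must be itransition objects", call. = FALSE)
  depths <- vapply(transitions, `[[`, integer(1), "depth")
  if (length(depths) > 0L && any(depths != depth)) {
    stop("all transitions must share the given depth", call. = FALSE)
  }
  conds <- lapply(transitions, itransition_to_cond, variables = variables,
                  depth = depth)
  nexts <- lapply(transitions, `[[`, "next_state")
  lf1t_engine(conds, nexts, variables, depth)
}
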