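# The immediate consequence operator over timed bodies, plus the compiled
# matrix representation used by the simulator and the learner.
#
# Slot encoding: with n variables and depth k, the timed base has S = n * k
# slots; the (variable i, delay d) atom occupies slot (d - 1) * n + i.  A
# condition interpretation is a 0/1 vector over slots; a rule body is a pair
# of 0/1 incidence vectors (positive / negative literals).  Rule firing over
# many conditions then reduces to two matrix products.

slot_index <- function(var_idx, delay, n) (delay - 1L) * n + var_idx

# Compile a program (or an arbitrary rule list) to incidence matrices over
# the slots of B_k.  Returns R x S matrices `pos` and `neg`, integer vector
# `heads` (variable index per rule), plus the slot geometry.
compile_rules <- function(rules, variables, k) {
  n <- length(variables)
  S <- n * k
  R <- length(rules)
  pos <- matrix(0, nrow = R, ncol = S)
  neg <- matrix(0, nrow = R, ncol = S)
  heads <- integer(R)
  for (i in seq_len(R)) {
    r <- rules[[i]]
    heads[i] <- match(r$head, variables)
    if (length(r$var) > 0L) {
      s <- slot_index(match(r$var, variables), r$delay, n)
      pos[i, s[r$positive]] <- 1
      neg[i, s[!r$positive]] <- 1
    }
  }
  list(variables = variables, n = n, k = k, S = S,
       heads = heads, pos = pos, neg = neg)
}

compile_program <- function(p, k = p$max_delay) {
  stopifnot(inherits(p, "logic_program"))
  compile_rules(p$rules, p$variables, k)
}

# Turn a history (list of k states, most recent last) into a 0/1 condition
# vector over the S slots: the state at offset d before "now" contributes
# slot (d - 1) * n + i for each true variable i.
history_to_cond <- function(history, variables, k) {
  n <- length(variables)
  cond <- numeric(n * k)
  L <- length(history)
  for (d in seq_len(k)) {
    st <- history[[L - d + 1L]]
    if (length(st) > 0L) {
      idx <- match(st, variables)
      if (anyNA(idx)) {
        stop(sprintf("history mentions unknown variable(s): %s",
                     paste(st[is.na(idx)], collapse = ", ")), call. = FALSE)
      }
      cond[slot_index(idx, d, n)] <- 1
    }
  }
  cond
}

# Next states for a compiled program over a S x H matrix of conditions.
# Returns an n x H 0/1 matrix of next-state memberships.
tp_matrix <- function(cp, cond) {
  H <- ncol(cond)
  out <- matrix(0, nrow = cp$n, ncol = H)
  if (length(cp$heads) == 0L) return(out)
  fires <- (cp$pos %*% (1 - cond) == 0) & (cp$neg %*% cond == 0)
  for (h in unique(cp$heads)) {
    rows <- which(cp$heads == h)
    out[h, ] <- as.numeric(colSums(fires[rows, , drop = FALSE]) > 0)
  }
  out
}

cond_col_to_state <- function(col, variables) {
  variables[col[seq_along(variables)] > 0]
}

#' Immediate consequence operator (synchronous next state)
#'
#' Computes the synchronous next state of a Markov(k) logic program from the
#' last k observed states: the result contains exactly the heads of the rules
#' whose timed bodies hold in the history (a positive literal `v` at delay d
#' holds iff `v` is true in the state d steps back).  The operator is
#' deterministic and all variables are updated simultaneously.
#'
#' @param p a [logic_program()].
#' @param history a list of states (character vectors of true variables),
#'   most recent last, of length at least `p$max_delay`.
#' @return a character vector: the next state.
#' @examples
#' p <- logic_program(c("a", "b"), 2, list(
#'   lp_rule("a", list(lit("b", 1), lit("b", 2))),
#'   lp_rule("b", list(lit("a", 2), lit("b", 2, positive = FALSE)))
#' ))
#' tp_next(p, list(c("a", "b"), "b"))  # "a"
#' @export
tp_next <- function(p, history) {
  stopifnot(inherits(p, "logic_program"))
  if (!is.list(history)) history <- list(history)
  if (length(history) < p$max_delay) {
    stop(sprintf("history has %d state(s) but the program needs the last %d",
                 length(history), p$max_delay), call. = FALSE)
  }
  history <- lapply(history, as_state, variables = p$variables)
  cp <- compile_program(p)
  cond <- matrix(history_to_cond(history, p$variables, p$max_delay), ncol = 1)
  cond_col_to_state(tp_matrix(cp, cond), p$variables)
}
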