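# Serialization: the plain-text rule language and comma-separated trace
# tables.  Both formats round-trip bit-exactly through the canonical
# in-memory form.
#
# Rule language, one statement per line, '%' starts a comment:
#
#   vars: a, b.
#   delay: 2.
#   a <- b[-1], b[-2].
#   b <- a[-2], not b[-2].
#   c <-.                      % fact rule
#
# A literal is  name[-d]  or  not name[-d];  the delay tag [-1] may be
# omitted (a bare name means delay 1).
#
# Trace tables are CSV with header  trace,step,var1,...,varN ; one row per
# (trace, time step), values 0/1, steps consecutive from 0 within a trace.

#' Serialize a logic program to rule-language text
#'
#' Emits the canonical, deterministic textual form of a program: a `vars:`
#' declaration (declaration order defines the variable order), a `delay:`
#' declaration, then one rule per line in canonical order.  Fact rules print
#' as `a <-.`.
#'
#' @param p a [logic_program()].
#' @return a single character string (lines joined by newlines).
#' @seealso [parse_rules()] for the inverse.
#' @export
serialize_rules <- function(p) {
  stopifnot(inherits(p, "logic_program"))
  paste(format(p), collapse = "\n")
}

#' Write a logic program to a file
#' @param p a [logic_program()].
#' @param path file path.
#' @return `p`, invisibly.
#' @export
write_program <- function(p, path) {
  writeLines(serialize_rules(p), path)
  invisible(p)
}

LIT_RE <- "^(not[ \t]+)?([A-Za-z0-9_]+)(\\[-([0-9]+)\\])?$"

parse_error <- function(line_no, msg) {
  stop(sprintf("line %d: %s", line_no, msg), call. = FALSE)
}

#' Parse rule-language text into a logic program
#'
#' Parses the textual rule language (see [serialize_rules()]) with
#' line-precise diagnostics: unknown variables, delays exceeding the declared
#' bound, contradictory bodies and malformed syntax each raise a distinct
#' error naming the offending line.
#'
#' @param text a character scalar (possibly multi-line) or vector of lines.
#' @return a [logic_program()] in canonical order, so that
#'   `parse_rules(serialize_rules(p))` reproduces `p` exactly.
#' @examples
#' parse_rules(c("vars: a, b.", "delay: 2.",
#'               "a <- b[-1], b[-2].", "b <- a[-2], not b[-2]."))
#' @export
parse_rules <- function(text) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  }
  vars <- NULL
  delay <- NULL
  rules <- list()
  for (i in seq_along(text)) {
    line <- sub("%.*$", "", text[i])
    line <- trimws(line)
    if (nchar(line) == 0L) next
    if (grepl("^vars[ \t]*:", line)) {
      if (!is.null(vars)) parse_error(i, "duplicate vars declaration")
      body <- sub("^vars[ \t]*:", "", line)
      if (!grepl("\\.$", body)) parse_error(i, "missing terminating '.'")
      body <- sub("\\.$", "", body)
      vars <- trimws(strsplit(body, ",", fixed = TRUE)[[1L]])
      vars <- vars[nchar(vars) > 0L]
      if (length(vars) == 0L) parse_error(i, "empty variable declaration")
      bad <- vars[!grepl(VAR_TOKEN_RE, vars)]
      if (length(bad) > 0L) {
        parse_error(i, sprintf("invalid variable name '%s'", bad[1L]))
      }
      if (anyDuplicated(vars)) parse_error(i, "duplicate variable name")
      next
    }
    if (grepl("^delay[ \t]*:", line)) {
      if (!is.null(delay)) parse_error(i, "duplicate delay declaration")
      body <- trimws(sub("\\.$", "", sub("^delay[ \t]*:", "", line)))
      if (!grepl("^[0-9]+$", body)) {
        parse_error(i, "delay declaration must be a positive integer")
      }
      delay <- as.integer(body)
      if (delay < 1L) parse_error(i, "delay must be >= 1")
      next
    }
    # rule line
    if (is.null(vars)) parse_error(i, "rule before vars declaration")
    if (is.null(delay)) parse_error(i, "rule before delay declaration")
    m <- regmatches(line, regexec("^([A-Za-z0-9_]+)[ \t]*<-[ \t]*(.*)\\.$", line))[[1L]]
    if (length(m) == 0L) {
      parse_error(i, sprintf("syntax error: expected 'head <- literal, ... .' (got '%s')", line))
    }
    head <- m[2L]
    if (!(head %in% vars)) parse_error(i, sprintf("unknown variable '%s'", head))
    body_txt <- trimws(m[3L])
    bvar <- character(0); bdelay <- integer(0); bpos <- logical(0)
    if (nchar(body_txt) > 0L) {
      toks <- trimws(strsplit(body_txt, ",", fixed = TRUE)[[1L]])
      for (tok in toks) {
        lm <- regmatches(tok, regexec(LIT_RE, tok))[[1L]]
        if (length(lm) == 0L || nchar(lm[3L]) == 0L) {
          parse_error(i, sprintf("syntax error in literal '%s'", tok))
        }
        v <- lm[3L]
        if (!(v %in% vars)) parse_error(i, sprintf("unknown variable '%s'", v))
        d <- if (nchar(lm[5L]) > 0L) as.integer(lm[5L]) else 1L
        if (d < 1L) parse_error(i, sprintf("delay must be >= 1 in '%s'", tok))
        if (d > delay) {
          parse_error(i, sprintf("delay %d in '%s' exceeds declared delay %d",
                                 d, tok, delay))
        }
        bvar <- c(bvar, v); bdelay <- c(bdelay, d)
        bpos <- c(bpos, nchar(lm[2L]) == 0L)
      }
      key <- paste(bvar, bdelay)
      for (kk in unique(key[duplicated(key)])) {
        if (length(unique(bpos[key == kk])) > 1L) {
          parse_error(i, sprintf("contradictory body: '%s' occurs both positively and negatively",
                                 bvar[key == kk][1L]))
        }
      }
    }
    rules <- c(rules, list(new_rule(head, bvar, bdelay, bpos)))
  }
  if (is.null(vars)) stop("missing vars declaration", call. = FALSE)
  if (is.null(delay)) stop("missing delay declaration", call. = FALSE)
  logic_program(vars, delay, rules)
}

#' Read a logic program from a file
#' @param path file path to rule-language text.
#' @return a [logic_program()].
#' @export
read_program <- function(path) parse_rules(readLines(path))

#' Write traces to a trace table
#'
#' Encodes a set of traces as a long-format table: columns `trace`, `step`
#' and one 0/1 column per variable (header order defines the variable order),
#' one row per (trace, time step) with steps counted from 0.
#'
#' @param traces a [bn_trace()] or named list of them.
#' @param path optional CSV file path; when given, the table is also written.
#' @return the table as a data frame, invisibly when `path` is given.
#' @export
write_traces <- function(traces, path = NULL) {
  traces <- as_trace_list(traces)
  vars <- traces[[1L]]$variables
  rows <- lapply(names(traces), function(nm) {
    s <- traces[[nm]]$states
    vals <- vapply(s, function(st) as.integer(vars %in% st),
                   integer(length(vars)))
    df <- data.frame(trace = nm, step = seq_along(s) - 1L,
                     stringsAsFactors = FALSE)
    cbind(df, as.data.frame(t(matrix(vals, nrow = length(vars),
                                     dimnames = list(vars, NULL)))))
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (!is.null(path)) {
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
    return(invisible(tab))
  }
  tab
}

#' Read traces from a trace table
#'
#' Parses the long-format trace table of [write_traces()] (a data frame or a
#' CSV file path).  Non-binary values, gaps or disorder in the step column
#' and single-row traces are each reported with the offending trace, row or
#' column named.
#'
#' @param x a data frame or a CSV file path.
#' @return a named list of [bn_trace()] objects; variables are taken from the
#'   header order.
#' @export
read_traces <- function(x) {
  tab <- if (is.character(x)) {
    utils::read.csv(x, stringsAsFactors = FALSE, check.names = FALSE)
  } else if (is.data.frame(x)) x
  else stop("x must be a data frame or a file path", call. = FALSE)
  need <- c("trace", "step")
  if (!all(need %in% names(tab))) {
    stop("trace table must have columns 'trace' and 'step'", call. = FALSE)
  }
  vars <- setdiff(names(tab), need)
  if (length(vars) == 0L) stop("trace table has no variable columns", call. = FALSE)
  check_variables(vars)
  for (v in vars) {
    bad <- which(!(tab[[v]] %in% c(0L, 1L)))
    if (length(bad) > 0L) {
      stop(sprintf("non-binary value '%s' in column '%s', row %d",
                   as.character(tab[[v]][bad[1L]]), v, bad[1L]), call. = FALSE)
    }
  }
  ids <- unique(tab$trace)
  traces <- lapply(ids, function(id) {
    block <- tab[tab$trace == id, , drop = FALSE]
    if (nrow(block) < 2L) {
      stop(sprintf("trace '%s' has a single row; a trace needs at least 2 states",
                   id), call. = FALSE)
    }
    block <- block[order(block$step), , drop = FALSE]
    if (!identical(as.integer(block$step), seq_len(nrow(block)) - 1L)) {
      stop(sprintf("trace '%s': steps must be consecutive from 0 (got %s)",
                   id, paste(block$step, collapse = ",")), call. = FALSE)
    }
    states <- lapply(seq_len(nrow(block)), function(r) {
      vars[as.logical(unlist(block[r, vars]))]
    })
    bn_trace(states, vars)
  })
  names(traces) <- as.character(ids)
  traces
}
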