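# Batch session runner: builds triads, assigns bargainers to resource
# positions (randomly or by earned effort rank), plays each triad under one
# of the two protocols, models dropout, and round-trips outcome tables.

#' Configure a simulation session
#'
#' @param game a [game_config()].
#' @param protocol `"one_step"` or `"alt_offers"`.
#' @param n_triads number of triads (each triad is one independent game and
#'   one unit of observation).
#' @param roster agent specification for each triad: a character vector or
#'   list of 3 entries, each a strategy name (`"equity"`, `"equal_split"`,
#'   `"random"`) or a list with `strategy` plus optional `timeout_prob` and
#'   `effort`.
#' @param resource_mode `"random"` (positions assigned uniformly at random)
#'   or `"earned"` (higher effort scores earn higher-resource positions, as
#'   with a real-effort task).
#' @param dropout session-wide per-decision probability of missing a
#'   deadline, combined independently with any agent-level `timeout_prob`; a
#'   timeout aborts the whole triad.
#' @param seed master seed; per-triad and per-agent streams are derived from
#'   it with [derive_seed()], so the session replays exactly.
#' @param effort_dist function of `n` returning effort scores for earned
#'   mode when an agent does not carry one (default standard normal -- the
#'   real-effort task itself is interface, not computation).
#' @return an object of class `coalsim_session`.
#' @export
session_config <- function(game, protocol = c("one_step", "alt_offers"),
                           n_triads, roster = c("equity", "equity", "equity"),
                           resource_mode = c("random", "earned"),
                           dropout = 0, seed = 1L,
                           effort_dist = stats::rnorm) {
  protocol <- match.arg(protocol)
  resource_mode <- match.arg(resource_mode)
  stopifnot(inherits(game, "coalsim_game"))
  if (!is_count(n_triads)) {
    stop_coalsim("bad_config", "n_triads must be a positive integer")
  }
  roster <- as.list(roster)
  if (length(roster) != 3) {
    stop_coalsim("bad_config", "the roster must yield exactly 3 agents")
  }
  lapply(roster, make_agent) # validate specs early
  if (!is.numeric(dropout) || dropout < 0 || dropout > 1) {
    stop_coalsim("bad_config", "dropout must be a probability")
  }
  structure(
    list(game = game, protocol = protocol, n_triads = as.integer(n_triads),
         roster = roster, resource_mode = resource_mode,
         dropout = as.numeric(dropout), seed = as.integer(seed),
         effort_dist = effort_dist),
    class = "coalsim_session"
  )
}

#' Assign bargainers to resource positions
#'
#' In `"random"` mode, agents are mapped to positions by a uniformly random
#' bijection. In `"earned"` mode, agents are ranked by effort score
#' (descending) and assigned to positions in descending-resource order, so
#' the hardest worker holds the most resources; effort ties are broken by the
#' stream, and with all-equal efforts the assignment is a uniform random
#' bijection.
#'
#' @param mode `"random"` or `"earned"`.
#' @param agents list of agents; in earned mode each must carry an `effort`
#'   score.
#' @param game a [game_config()].
#' @param stream a [make_stream()] used for the bijection / tie-breaks.
#' @return a record list: `mode`, `efforts`, `position_of_agent` (position
#'   held by each roster agent), and `agent_at_position` (its inverse).
#' @export
assign_resources <- function(mode = c("random", "earned"), agents, game,
                             stream) {
  mode <- match.arg(mode)
  n <- length(agents)
  efforts <- vapply(agents, function(a) a$effort %||% NA_real_, numeric(1))
  if (mode == "random") {
    position_of_agent <- stream_eval(stream, sample.int(n))
  } else {
    if (anyNA(efforts)) {
      stop_coalsim("bad_config", "earned mode requires effort scores")
    }
    tie <- stream_eval(stream, stats::runif(n))
    agents_best_first <- order(-efforts, tie)
    positions_richest_first <- order(-game$resources, seq_len(n))
    position_of_agent <- integer(n)
    position_of_agent[agents_best_first] <- positions_richest_first
  }
  list(mode = mode, efforts = efforts,
       position_of_agent = position_of_agent,
       agent_at_position = order(position_of_agent))
}

#' Run a batch session
#'
#' Plays `n_triads` independent games. Every source of randomness (resource
#' assignment, effort draws, agent tie-breaks, dropout) runs on streams
#' derived from the master seed, so `(config, seed)` fully determines all
#' outputs. A per-triad failure (an agent emitting an invalid object) aborts
#' only that triad, recorded as `ABORTED` with the reason.
#'
#' @param session a [session_config()].
#' @param verbose emit per-triad progress to stderr?
#' @return a `coalsim_session_result`: list with `outcomes` (list of
#'   `coalsim_outcome`), `table` (the outcome data frame, see
#'   [write_outcomes()]), `summary` (counts by status and by formed
#'   coalition), and the `session`.
#' @examples
#' g <- game_config(c(4, 3, 2), 5, payoff = 100)
#' res <- run_session(session_config(g, "one_step", n_triads = 5, seed = 42))
#' res$summary$by_coalition
#' @export
run_session <- function(session, verbose = FALSE) {
  stopifnot(inherits(session, "coalsim_session"))
  outcomes <- vector("list", session$n_triads)
  for (i in seq_len(session$n_triads)) {
    tseed <- derive_seed(session$seed, 1000L, i)
    agents <- lapply(session$roster, make_agent)
    for (j in seq_along(agents)) {
      agents[[j]]$stream <- make_stream(derive_seed(tseed, 17L, j))
      if (session$dropout > 0) {
        p0 <- agents[[j]]$timeout_prob %||% 0
        agents[[j]]$timeout_prob <- 1 - (1 - p0) * (1 - session$dropout)
      }
    }
    astream <- make_stream(derive_seed(tseed, 29L))
    if (session$resource_mode == "earned") {
      for (j in seq_along(agents)) {
        if (is.na(agents[[j]]$effort)) {
          agents[[j]]$effort <- stream_eval(astream, session$effort_dist(1))
        }
      }
    }
    rec <- assign_resources(session$resource_mode, agents, session$game,
                            astream)
    by_pos <- agents[rec$agent_at_position]
    rec$strategy_at_position <- vapply(by_pos, function(a) a$strategy, "")
    out <- tryCatch(
      if (session$protocol == "one_step") {
        run_one_step_game(session$game, by_pos, triad_id = i)
      } else {
        run_alt_offers_game(session$game, by_pos, triad_id = i)
      },
      coalsim_agent_fault = function(e) {
        new_outcome(session$game, i, "ABORTED", session$protocol,
                    reason = conditionMessage(e))
      }
    )
    out$assignment <- rec
    outcomes[[i]] <- out
    if (verbose) {
      message(sprintf("triad %d/%d: %s %s", i, session$n_triads, out$status,
                      out$coalition_label))
    }
  }
  structure(
    list(outcomes = outcomes, table = outcomes_table(outcomes),
         summary = summarize_outcomes(outcomes), session = session),
    class = "coalsim_session_result"
  )
}

#' Summarize session outcomes
#'
#' @param outcomes list of `coalsim_outcome` objects (or a session result).
#' @return list with `n`, `by_status` (named counts), and `by_coalition`
#'   (named counts among formed outcomes).
#' @export
summarize_outcomes <- function(outcomes) {
  if (inherits(outcomes, "coalsim_session_result")) {
    outcomes <- outcomes$outcomes
  }
  status <- vapply(outcomes, function(o) o$status, "")
  formed <- vapply(outcomes, function(o) o$coalition_label, "")
  list(
    n = length(outcomes),
    by_status = table(factor(status,
                             levels = c("FORMED", "NO_AGREEMENT", "ABORTED"))),
    by_coalition = table(formed[nzchar(formed)])
  )
}

#' @export
print.coalsim_session_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Session: %d triads, %s protocol, %s resources\n", s$n,
              x$session$protocol, x$session$resource_mode))
  cat("  by status:   ",
      paste(names(s$by_status), as.integer(s$by_status), sep = "=",
            collapse = "  "), "\n")
  if (length(s$by_coalition)) {
    cat("  by coalition:",
        paste(names(s$by_coalition), as.integer(s$by_coalition), sep = "=",
              collapse = "  "), "\n")
  }
  invisible(x)
}

# --- outcome table I/O -----------------------------------------------------

outcomes_header <- "#coalsim_outcomes v1"

outcome_columns <- function() {
  c("triad_id", "status", "coalition", "rounds_used",
    "share_A", "share_B", "share_C", "bonus_A", "bonus_B", "bonus_C",
    "strategy_A", "strategy_B", "strategy_C", "resource_mode")
}

#' Tabulate outcomes
#'
#' Flattens a list of outcomes into one row per triad, allocations serialized
#' as per-position `share_*` columns (NA for non-members and unformed
#' triads).
#'
#' @param outcomes list of `coalsim_outcome`s or a session result.
#' @return a data frame with columns `r paste(outcome_columns(), collapse=", ")`.
#' @export
outcomes_table <- function(outcomes) {
  if (inherits(outcomes, "coalsim_session_result")) {
    outcomes <- outcomes$outcomes
  }
  rows <- lapply(outcomes, function(o) {
    strat <- o$assignment$strategy_at_position %||% rep(NA_character_, 3)
    data.frame(
      triad_id = as.integer(o$triad_id), status = o$status,
      coalition = o$coalition_label, rounds_used = o$rounds_used,
      share_A = o$allocation[["A"]], share_B = o$allocation[["B"]],
      share_C = o$allocation[["C"]],
      bonus_A = o$bonus[["A"]], bonus_B = o$bonus[["B"]],
      bonus_C = o$bonus[["C"]],
      strategy_A = strat[1], strategy_B = strat[2], strategy_C = strat[3],
      resource_mode = o$assignment$mode %||% NA_character_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Write / read the outcomes CSV
#'
#' The file starts with a schema version line (`#coalsim_outcomes v1`)
#' followed by a plain CSV, one row per triad, with the allocation in
#' per-position `share_*` columns. The round-trip is lossless:
#' `read_outcomes(write_outcomes(x))` equals the outcome table of `x`, and
#' rewriting produces a byte-identical file.
#'
#' @param outcomes a session result, a list of outcomes, or an outcome data
#'   frame as returned by [outcomes_table()].
#' @param path file path.
#' @return `write_outcomes()` returns `path` invisibly; `read_outcomes()`
#'   returns the outcome data frame. Malformed files raise a
#'   `coalsim_bad_outcomes_file` error naming the offending line.
#' @export
write_outcomes <- function(outcomes, path) {
  df <- if (is.data.frame(outcomes)) outcomes else outcomes_table(outcomes)
  stopifnot(identical(names(df), outcome_columns()))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(outcomes_header, con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_outcomes
#' @export
read_outcomes <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !identical(lines[1], outcomes_header)) {
    stop_coalsim("bad_outcomes_file", sprintf(
      "line 1: expected schema header '%s'", outcomes_header))
  }
  if (length(lines) < 2) {
    stop_coalsim("bad_outcomes_file", "line 2: missing column header")
  }
  ncols <- length(outcome_columns())
  classes <- c("integer", "character", "character", "integer",
               rep("numeric", 6), rep("character", 3), "character")
  df <- tryCatch(
    utils::read.csv(text = lines[-1], stringsAsFactors = FALSE,
                    colClasses = classes, na.strings = "NA"),
    error = function(e) {
      stop_coalsim("bad_outcomes_file",
                   sprintf("cannot parse outcomes CSV: %s",
                           conditionMessage(e)))
    }
  )
  if (!identical(names(df), outcome_columns())) {
    stop_coalsim("bad_outcomes_file", sprintf(
      "line 2: expected columns %s", paste(outcome_columns(), collapse = ",")))
  }
  nfields <- utils::count.fields(textConnection(lines[-(1:2)]), sep = ",")
  bad <- which(nfields != ncols)
  if (length(bad)) {
    stop_coalsim("bad_outcomes_file", sprintf(
      "line %d: expected %d fields, found %d", bad[1] + 2L, ncols,
      nfields[bad[1]]))
  }
  df
}

#' Write the per-round event log CSV
#'
#' One row per logged protocol event across all triads (offers, selections,
#' resolutions, and -- under the alternative-offers protocol -- tentative
#' coalitions, alternatives, ratification choices, and defections).
#'
#' @param outcomes a session result or list of outcomes.
#' @param path file path.
#' @export
write_events <- function(outcomes, path) {
  if (inherits(outcomes, "coalsim_session_result")) {
    outcomes <- outcomes$outcomes
  }
  evs <- do.call(rbind, lapply(outcomes, function(o) o$events))
  utils::write.csv(evs, path, row.names = FALSE)
  invisible(path)
}
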