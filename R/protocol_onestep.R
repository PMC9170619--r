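# One-step display protocol.
#
# Each round has three phases. Phase I: every bargainer simultaneously makes
# a (mandatory, validated) coalition offer. Phase II: all offers are shown on
# a display board, duplicates merged, and every bargainer selects one offer
# that includes themselves (or, optionally, no coalition). Phase III: if all
# members of some displayed offer selected it, that coalition forms
# immediately and the payoff is divided as proposed; otherwise a new round
# starts, until the round limit is reached.

entry_key <- function(members, allocation) {
  paste0(coalition_label(members), ":",
         paste(unname(allocation), collapse = "/"))
}

#' Build the Phase-II display board
#'
#' Merges the Phase-I offers into a deduplicated board: offers with identical
#' coalition and allocation appear once, with all their proposers listed.
#' Entries are ordered deterministically: by coalition label, then by the
#' lowest-indexed proposer's own share, descending (so reruns produce
#' identical logs; the display order is otherwise arbitrary).
#'
#' @param offers list of validated [offer()]s, exactly one per bargainer
#'   position (Phase-I offers are mandatory).
#' @param config a [game_config()].
#' @return an object of class `coalsim_board`: a list of entries, each with
#'   `members`, `allocation`, `proposers` (sorted positions), and `key`.
#' @export
build_board <- function(offers, config) {
  n <- length(config$resources)
  proposers <- vapply(offers, function(o) o$proposer, integer(1))
  if (anyDuplicated(proposers)) {
    stop_coalsim("duplicate_proposer", sprintf(
      "more than one Phase-I offer from position %s",
      position_label(proposers[duplicated(proposers)][1])))
  }
  if (!setequal(proposers, seq_len(n))) {
    stop_coalsim("missing_proposer", sprintf(
      "Phase-I offers are mandatory; missing offer(s) from %s",
      paste(position_label(setdiff(seq_len(n), proposers)), collapse = ", ")))
  }
  entries <- list()
  for (o in offers) {
    key <- entry_key(o$members, o$allocation)
    if (is.null(entries[[key]])) {
      entries[[key]] <- list(members = o$members, allocation = o$allocation,
                             proposers = o$proposer, key = key)
    } else {
      entries[[key]]$proposers <- sort(c(entries[[key]]$proposers, o$proposer))
    }
  }
  entries <- unname(entries)
  lab <- vapply(entries, function(e) coalition_label(e$members), "")
  prop_share <- vapply(entries, function(e) {
    unname(e$allocation[position_label(min(e$proposers))])
  }, numeric(1))
  entries <- entries[order(lab, -prop_share,
                           vapply(entries, function(e) e$key, ""))]
  structure(entries, class = "coalsim_board")
}

#' @export
print.coalsim_board <- function(x, ...) {
  cat(sprintf("Display board (%d offer%s):\n", length(x),
              if (length(x) == 1) "" else "s"))
  for (i in seq_along(x)) {
    e <- x[[i]]
    cat(sprintf("  [%d] %s  %s  (proposed by %s)\n", i,
                coalition_label(e$members),
                paste0(names(e$allocation), "=", e$allocation, collapse = ", "),
                paste(position_label(e$proposers), collapse = ", ")))
  }
  invisible(x)
}

#' Entries a bargainer may select
#'
#' A bargainer may select any displayed offer whose coalition includes them
#' -- their own offer or someone else's. Because Phase-I offers are
#' mandatory, the list is never empty. When the game enables it, the
#' explicit "no coalition" option is also available.
#'
#' @param board a [build_board()] result.
#' @param selector position (letter or index).
#' @param config a [game_config()].
#' @return a list with `entries` (integer indices into the board) and
#'   `no_coalition` (is opting out permitted?).
#' @export
eligible_entries <- function(board, selector, config) {
  selector <- as_positions(selector, length(config$resources))
  idx <- which(vapply(board, function(e) selector %in% e$members, logical(1)))
  list(entries = idx, no_coalition = config$allow_no_selection)
}

#' Construct a Phase-II selection
#'
#' @param selector position (letter or index).
#' @param choice an integer index into the display board, or `"none"` for the
#'   no-coalition option.
#' @return an object of class `coalsim_selection`.
#' @export
selection <- function(selector, choice) {
  structure(list(selector = as_positions(selector), choice = choice),
            class = "coalsim_selection")
}

#' Resolve Phase III of a round
#'
#' A coalition forms iff every member of some displayed offer selected that
#' offer. At most one entry can be unanimous in a triad (any two feasible
#' coalitions share a member, and each bargainer submits one selection), so
#' the formed coalition -- when there is one -- is unique.
#'
#' @param board a [build_board()] result.
#' @param selections list of [selection()]s, one per bargainer.
#' @param config a [game_config()].
#' @param round_number round index for the record.
#' @return an object of class `coalsim_round` with fields `round`, `board`,
#'   `selections`, and `formed` (`NULL`, or a list with `members` and
#'   `allocation`).
#' @export
resolve_round <- function(board, selections, config, round_number = 1L) {
  n <- length(config$resources)
  sel_by <- vapply(selections, function(s) s$selector, integer(1))
  if (!setequal(sel_by, seq_len(n)) || length(sel_by) != n) {
    stop_coalsim("invalid_selection", "need exactly one selection per bargainer")
  }
  choice_of <- rep(NA_integer_, n)
  for (s in selections) {
    if (identical(s$choice, "none")) {
      if (!config$allow_no_selection) {
        stop_coalsim("invalid_selection", sprintf(
          "position %s selected no coalition, but that option is disabled",
          position_label(s$selector)))
      }
      next
    }
    ch <- s$choice
    if (!is.numeric(ch) || length(ch) != 1 || is.na(ch) ||
        ch < 1 || ch > length(board)) {
      stop_coalsim("invalid_selection", sprintf(
        "position %s selected a nonexistent board entry",
        position_label(s$selector)))
    }
    if (!(s$selector %in% board[[ch]]$members)) {
      stop_coalsim("invalid_selection", sprintf(
        "position %s selected entry %s, which does not include them",
        position_label(s$selector), board[[ch]]$key))
    }
    choice_of[s$selector] <- as.integer(ch)
  }
  unanimous <- which(vapply(seq_along(board), function(i) {
    all(choice_of[board[[i]]$members] == i, na.rm = FALSE) &&
      !anyNA(choice_of[board[[i]]$members])
  }, logical(1)))
  stopifnot(length(unanimous) <= 1) # structural: winning coalitions intersect
  formed <- if (length(unanimous) == 1) {
    list(members = board[[unanimous]]$members,
         allocation = board[[unanimous]]$allocation)
  }
  structure(
    list(round = as.integer(round_number), board = board,
         selections = selections, formed = formed),
    class = "coalsim_round"
  )
}

# --- shared Phase I-II machinery ------------------------------------------

propose_view <- function(config, position) {
  feas <- feasible_coalitions(config)
  mine <- feas[vapply(feas, function(m) position %in% m, logical(1))]
  list(config = config, position = position, feasible = mine)
}

# Runs Phases I and II for one round. Returns either
# list(status="ABORTED", position=) on a timeout, or
# list(status="OK", board=, selections=).
run_phase_1_2 <- function(config, agents, round, log) {
  n <- length(config$resources)
  offers <- vector("list", n)
  for (i in seq_len(n)) {
    a <- agents[[i]]
    if (identical(agent_deadline(a), "TIMEOUT")) {
      log_event(log, round, "I", position_label(i), "timeout")
      return(list(status = "ABORTED", position = i))
    }
    off <- agent_propose(a, propose_view(config, i))
    tryCatch(validate_offer(config, off),
             coalsim_error = function(e) agent_fault(i, e))
    log_event(log, round, "I", position_label(i), "offer",
              coalition = coalition_label(off$members),
              allocation = alloc_string(off$allocation))
    offers[[i]] <- off
  }
  board <- build_board(offers, config)
  selections <- vector("list", n)
  for (i in seq_len(n)) {
    a <- agents[[i]]
    if (identical(agent_deadline(a), "TIMEOUT")) {
      log_event(log, round, "II", position_label(i), "timeout")
      return(list(status = "ABORTED", position = i))
    }
    el <- eligible_entries(board, i, config)
    view <- list(config = config, position = i, board = board,
                 eligible = el$entries, no_coalition = el$no_coalition,
                 own_offer = offers[[i]])
    ch <- agent_select(a, view)
    sel <- selection(i, ch)
    log_event(log, round, "II", position_label(i), "select",
              chosen_entry = if (identical(ch, "none")) "NONE"
                             else board[[ch]]$key)
    selections[[i]] <- sel
  }
  list(status = "OK", board = board, selections = selections)
}

#' Play one triad under the one-step protocol
#'
#' Runs the offer/select/resolve loop until a coalition forms, the round
#' limit is reached (`NO_AGREEMENT`), or an agent misses a decision deadline
#' (`ABORTED`; the remaining bargainers are forwarded to the end, as in an
#' online session where an idle participant is kicked).
#'
#' @param config a [game_config()] with exactly 3 positions.
#' @param agents list of 3 agents (see [equity_agent()] and friends); agent
#'   `i` plays position `i`.
#' @param seed optional integer; when given, each agent's private stream is
#'   seeded deterministically from it. Agents that already carry streams are
#'   left alone when `seed` is `NULL`.
#' @param triad_id identifier recorded in the outcome and event log.
#' @return an object of class `coalsim_outcome`; its `events` field holds the
#'   full per-round event log as a data frame.
#' @examples
#' g <- game_config(c(4, 3, 2), 5, payoff = 100)
#' out <- run_one_step_game(g, list(equity_agent(), equity_agent(),
#'                                  equity_agent()), seed = 1)
#' out$coalition_label # "BC": the strong bargainer is excluded
#' @export
run_one_step_game <- function(config, agents, seed = NULL, triad_id = 1L) {
  agents <- prepare_agents(agents, config, seed)
  log <- new_event_log(triad_id)
  for (round in seq_len(config$max_rounds)) {
    p12 <- run_phase_1_2(config, agents, round, log)
    if (identical(p12$status, "ABORTED")) {
      return(new_outcome(config, triad_id, "ABORTED", "one_step",
                         rounds_used = round, events = log_frame(log),
                         reason = sprintf("timeout at position %s",
                                          position_label(p12$position))))
    }
    rr <- resolve_round(p12$board, p12$selections, config, round)
    log_event(log, round, "III", "", "resolve",
              coalition = if (is.null(rr$formed)) ""
                          else coalition_label(rr$formed$members),
              allocation = if (is.null(rr$formed)) ""
                           else alloc_string(rr$formed$allocation),
              formed_flag = !is.null(rr$formed))
    if (!is.null(rr$formed)) {
      return(new_outcome(config, triad_id, "FORMED", "one_step",
                         members = rr$formed$members,
                         allocation = rr$formed$allocation,
                         rounds_used = round, events = log_frame(log)))
    }
  }
  new_outcome(config, triad_id, "NO_AGREEMENT", "one_step",
              rounds_used = config$max_rounds, events = log_frame(log))
}

# Give each agent its position and (if needed) a private stream.
prepare_agents <- function(agents, config, seed) {
  if (length(agents) != 3 || length(config$resources) != 3) {
    stop_coalsim("bad_config",
                 "the bargaining protocols support exactly 3 bargainers")
  }
  for (i in seq_along(agents)) {
    agents[[i]]$position <- i
    if (is.null(agents[[i]]$stream)) {
      if (is.null(seed)) {
        stop_coalsim("bad_config",
                     "agents have no streams and no seed was given")
      }
      agents[[i]]$stream <- make_stream(derive_seed(seed, 7L, i))
    } else if (!is.null(seed)) {
      agents[[i]]$stream <- make_stream(derive_seed(seed, 7L, i))
    }
  }
  agents
}
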