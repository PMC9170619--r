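# Alternative-offers protocol.
#
# Phases I and II are identical to the one-step protocol. A unanimously
# selected offer does not form a coalition immediately but becomes a
# *tentative* coalition (Phase III). The excluded bargainer may then make an
# alternative offer to one member of the tentative coalition (Phase IV),
# trying to tempt them to break away. In Phase V the tentative members either
# ratify (the coalition forms and pays out), or the targeted member defects
# to the alternative -- which becomes the new tentative coalition, with a
# newly excluded bargainer who may counter in turn -- or, if the opt-out is
# enabled, a member selects nothing and play returns to Phase I.

#' Turn a resolved round into a tentative coalition
#'
#' @param round_result a [resolve_round()] result.
#' @return a `coalsim_tentative` (fields `members`, `allocation`, `origin`)
#'   when some entry was selected unanimously, otherwise `NULL` (the caller
#'   loops back to Phase I, consuming a round).
#' @export
to_tentative <- function(round_result) {
  if (is.null(round_result$formed)) return(NULL)
  structure(
    list(members = round_result$formed$members,
         allocation = round_result$formed$allocation,
         origin = "phase_3"),
    class = "coalsim_tentative"
  )
}

#' Solicit an alternative offer from the excluded bargainer
#'
#' Asks the excluded agent for a counteroffer and validates it: the proposed
#' coalition must be exactly the dyad of the excluded bargainer and one
#' member of the tentative coalition, and must pass [validate_offer()]. The
#' agent may also pass (the opportunity is optional). When the tentative
#' coalition is the grand coalition there is no excluded bargainer and this
#' operation must be skipped.
#'
#' @param tentative a [to_tentative()] result.
#' @param agent the excluded bargainer's agent (its `position` must not be a
#'   tentative member).
#' @param config a [game_config()].
#' @return a `coalsim_alternative`: either `list(type = "pass")` or
#'   `list(type = "offer", offer = <offer>, target = <position>)`.
#' @export
solicit_alternative <- function(tentative, agent, config) {
  n <- length(config$resources)
  if (length(tentative$members) == n) {
    stop_coalsim("no_excluded_bargainer",
                 "the grand coalition excludes nobody; skip Phase IV")
  }
  pos <- agent$position
  if (pos %in% tentative$members) {
    stop_coalsim("bad_config", "the counter-offering agent must be excluded")
  }
  view <- list(config = config, position = pos, tentative = tentative,
               targets = tentative$members)
  res <- agent_counter(agent, view)
  if (identical(res, "pass")) {
    return(structure(list(type = "pass"), class = "coalsim_alternative"))
  }
  if (!inherits(res, "coalsim_offer")) {
    stop_coalsim("alternative_invalid",
                 "counter must return an offer or \"pass\"")
  }
  target <- setdiff(res$members, pos)
  if (res$proposer != pos || length(res$members) != 2 ||
      !(pos %in% res$members) || length(target) != 1 ||
      !(target %in% tentative$members)) {
    stop_coalsim("alternative_invalid", paste0(
      "an alternative offer must be the dyad of the excluded bargainer and ",
      "one tentative member"))
  }
  tryCatch(validate_offer(config, res),
           coalsim_error = function(e) agent_fault(pos, e))
  structure(list(type = "offer", offer = res, target = target),
            class = "coalsim_alternative")
}

#' Resolve a ratification vote
#'
#' Each tentative member chooses `"ratify"`, or -- if they are the target of
#' the alternative offer -- `"alternative"`, or `"none"` when the opt-out is
#' enabled. All members ratifying forms the coalition; the target defecting
#' makes the alternative the new tentative coalition (with a new excluded
#' bargainer); any `"none"` sends play back to Phase I.
#'
#' @param tentative a [to_tentative()] result.
#' @param alternative a [solicit_alternative()] result, or `NULL` when no
#'   alternative is on the table (pass, or grand coalition).
#' @param choices named list/vector of choices, one per tentative member,
#'   names being position letters.
#' @param config a [game_config()].
#' @return a list with `result` being one of `"formed"` (plus `members`,
#'   `allocation`), `"new_tentative"` (plus `tentative`, `excluded`), or
#'   `"back_to_phase_1"`.
#' @export
ratify_tentative <- function(tentative, alternative, choices, config) {
  members <- tentative$members
  labels <- position_label(members)
  choices <- as.list(choices)
  if (!setequal(names(choices), labels)) {
    stop_coalsim("invalid_ratify",
                 "need exactly one choice per tentative member")
  }
  has_alt <- !is.null(alternative) && identical(alternative$type, "offer")
  target <- if (has_alt) alternative$target else NA_integer_
  for (lab in labels) {
    ch <- choices[[lab]]
    if (identical(ch, "none")) {
      if (!config$allow_no_selection) {
        stop_coalsim("invalid_ratify", sprintf(
          "position %s chose no coalition, but that option is disabled", lab))
      }
    } else if (identical(ch, "alternative")) {
      if (!has_alt || !identical(lab, position_label(target))) {
        stop_coalsim("invalid_ratify", sprintf(
          "position %s cannot take an alternative offer not addressed to them",
          lab))
      }
    } else if (!identical(ch, "ratify")) {
      stop_coalsim("invalid_ratify", sprintf(
        "position %s: unknown ratification choice %s", lab, format(ch)))
    }
  }
  if (any(vapply(choices, identical, logical(1), "none"))) {
    return(list(result = "back_to_phase_1"))
  }
  if (has_alt && identical(choices[[position_label(target)]], "alternative")) {
    new_tent <- structure(
      list(members = alternative$offer$members,
           allocation = alternative$offer$allocation,
           origin = "alternative"),
      class = "coalsim_tentative"
    )
    return(list(result = "new_tentative", tentative = new_tent,
                excluded = setdiff(members, target)))
  }
  list(result = "formed", members = members, allocation = tentative$allocation)
}

#' Play one triad under the alternative-offers protocol
#'
#' As [run_one_step_game()], but a unanimous Phase-III selection yields a
#' tentative coalition that must survive the alternative-offer / ratification
#' loop of Phases IV-V before it forms. One round is one full Phase I-III
#' pass; defection cycles within a round are capped separately by
#' `max_cycles` (default `payoff / payoff_granularity`, the largest possible
#' number of strictly improving counteroffers), after which play returns to
#' Phase I.
#'
#' @inheritParams run_one_step_game
#' @param max_cycles cap on Phase IV-V defection cycles within one round.
#' @return an object of class `coalsim_outcome`; the event log additionally
#'   records `tentative`, `alternative`/`pass`, `ratify`, and `defect`
#'   events.
#' @export
run_alt_offers_game <- function(config, agents, seed = NULL, triad_id = 1L,
                                max_cycles = NULL) {
  agents <- prepare_agents(agents, config, seed)
  if (is.null(max_cycles)) {
    max_cycles <- max(1, round(config$payoff / config$payoff_granularity))
  }
  log <- new_event_log(triad_id)
  abort <- function(round, pos) {
    new_outcome(config, triad_id, "ABORTED", "alt_offers",
                rounds_used = round, events = log_frame(log),
                reason = sprintf("timeout at position %s",
                                 position_label(pos)))
  }
  for (round in seq_len(config$max_rounds)) {
    p12 <- run_phase_1_2(config, agents, round, log)
    if (identical(p12$status, "ABORTED")) return(abort(round, p12$position))
    rr <- resolve_round(p12$board, p12$selections, config, round)
    tent <- to_tentative(rr)
    log_event(log, round, "III", "", "tentative",
              coalition = if (is.null(tent)) ""
                          else coalition_label(tent$members),
              allocation = if (is.null(tent)) ""
                           else alloc_string(tent$allocation),
              formed_flag = FALSE)
    if (is.null(tent)) next
    cycle <- 0L
    repeat {
      cycle <- cycle + 1L
      excluded <- setdiff(seq_along(config$resources), tent$members)
      alt <- NULL
      if (length(excluded) == 1) {
        if (identical(agent_deadline(agents[[excluded]]), "TIMEOUT")) {
          log_event(log, round, "IV", position_label(excluded), "timeout")
          return(abort(round, excluded))
        }
        alt <- solicit_alternative(tent, agents[[excluded]], config)
        if (identical(alt$type, "pass")) {
          log_event(log, round, "IV", position_label(excluded), "pass")
          alt <- NULL
        } else {
          log_event(log, round, "IV", position_label(excluded), "alternative",
                    coalition = coalition_label(alt$offer$members),
                    allocation = alloc_string(alt$offer$allocation))
        }
      }
      choices <- list()
      for (m in tent$members) {
        if (identical(agent_deadline(agents[[m]]), "TIMEOUT")) {
          log_event(log, round, "V", position_label(m), "timeout")
          return(abort(round, m))
        }
        is_target <- !is.null(alt) && m == alt$target
        view <- list(config = config, position = m, tentative = tent,
                     my_share = unname(tent$allocation[position_label(m)]),
                     alternative = if (is_target) alt$offer else NULL,
                     is_target = is_target)
        ch <- agent_ratify(agents[[m]], view)
        log_event(log, round, "V", position_label(m), "ratify",
                  chosen_entry = as.character(ch))
        choices[[position_label(m)]] <- ch
      }
      res <- ratify_tentative(tent, alt, choices, config)
      if (identical(res$result, "formed")) {
        log_event(log, round, "V", "", "resolve",
                  coalition = coalition_label(res$members),
                  allocation = alloc_string(res$allocation),
                  formed_flag = TRUE)
        return(new_outcome(config, triad_id, "FORMED", "alt_offers",
                           members = res$members,
                           allocation = res$allocation,
                           rounds_used = round, events = log_frame(log)))
      }
      if (identical(res$result, "back_to_phase_1")) {
        log_event(log, round, "V", "", "back_to_phase_1")
        break
      }
      # defection: the alternative becomes the new tentative coalition
      log_event(log, round, "V", position_label(alt$target), "defect",
                coalition = coalition_label(res$tentative$members),
                allocation = alloc_string(res$tentative$allocation))
      tent <- res$tentative
      if (cycle >= max_cycles) {
        log_event(log, round, "V", "", "back_to_phase_1")
        break
      }
    }
  }
  new_outcome(config, triad_id, "NO_AGREEMENT", "alt_offers",
              rounds_used = config$max_rounds, events = log_frame(log))
}
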