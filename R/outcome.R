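# Outcome and event-log plumbing shared by both protocol runners.

alloc_string <- function(allocation) {
  if (is.null(allocation) || !length(allocation)) return("")
  paste0(names(allocation), "=", unname(allocation), collapse = ";")
}

new_event_log <- function(triad_id) {
  e <- new.env(parent = emptyenv())
  e$rows <- list()
  e$triad_id <- triad_id
  e
}

log_event <- function(log, round, phase, actor, action, coalition = "",
                      allocation = "", chosen_entry = "", formed_flag = NA) {
  log$rows[[length(log$rows) + 1L]] <- data.frame(
    triad_id = log$triad_id, round = round, phase = phase, actor = actor,
    action = action, coalition = coalition, allocation = allocation,
    chosen_entry = chosen_entry, formed_flag = formed_flag,
    stringsAsFactors = FALSE
  )
  invisible(log)
}

log_frame <- function(log) {
  if (!length(log$rows)) {
    return(data.frame(triad_id = integer(), round = integer(),
                      phase = character(), actor = character(),
                      action = character(), coalition = character(),
                      allocation = character(), chosen_entry = character(),
                      formed_flag = logical(), stringsAsFactors = FALSE))
  }
  do.call(rbind, log$rows)
}

# Terminal result of one triad's game.
new_outcome <- function(config, triad_id, status, protocol,
                        members = NULL, allocation = NULL,
                        rounds_used = 0L, events = NULL, reason = "") {
  n <- length(config$resources)
  full_alloc <- stats::setNames(rep(NA_real_, n), position_label(seq_len(n)))
  bonus <- stats::setNames(rep(0, n), position_label(seq_len(n)))
  if (identical(status, "FORMED")) {
    stopifnot(abs(sum(allocation) - config$payoff) < 1e-9)
    full_alloc[names(allocation)] <- allocation
    bonus[names(allocation)] <- bonus_payment(config, allocation)
  }
  structure(
    list(
      triad_id = triad_id,
      status = status,
      protocol = protocol,
      coalition = if (is.null(members)) integer() else members,
      coalition_label = if (is.null(members)) "" else coalition_label(members),
      allocation = full_alloc,
      bonus = bonus,
      rounds_used = as.integer(rounds_used),
      reason = reason,
      events = events,
      assignment = NULL
    ),
    class = "coalsim_outcome"
  )
}

#' @export
print.coalsim_outcome <- function(x, ...) {
  cat(sprintf("Triad %s [%s]: %s", x$triad_id, x$protocol, x$status))
  if (identical(x$status, "FORMED")) {
    shares <- x$allocation[!is.na(x$allocation)]
    cat(sprintf(" %s (%s)", x$coalition_label,
                paste0(names(shares), "=", shares, collapse = ", ")))
  }
  if (nzchar(x$reason)) cat(sprintf(" (%s)", x$reason))
  cat(sprintf(", rounds used: %d\n", x$rounds_used))
  invisible(x)
}

# A classed condition carrying the offending agent's position, rethrown when
# an agent emits an invalid object so session runners can attribute the fault.
agent_fault <- function(position, cond) {
  stop(errorCondition(
    sprintf("agent at position %s: %s", position_label(position),
            conditionMessage(cond)),
    class = c("coalsim_agent_fault", class(cond))
  ))
}
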