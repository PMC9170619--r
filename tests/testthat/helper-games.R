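# Shared fixtures: the canonical 5(4-3-2) game, the worked three-offer
# round, brute-force oracles, and two synthetic test-only agent strategies
# (registered on the package generics at load time).

g532 <- function(...) game_config(c(4, 3, 2), 5, payoff = 100, ...)

# A: AC (A=60, C=40); B: BC (B=55, C=45); C: BC (50/50)
worked_offers <- function() {
  list(offer("A", "AC", c(A = 60, C = 40)),
       offer("B", "BC", c(B = 55, C = 45)),
       offer("C", "BC", c(B = 50, C = 50)))
}

board_key <- function(entry) {
  paste0(coalition_label(entry$members), ":",
         paste(unname(entry$allocation), collapse = "/"))
}

# Independent feasibility oracle: filter the full powerset by bitmask.
brute_feasible <- function(resources, decision_point, grand) {
  n <- length(resources)
  out <- character()
  for (mask in seq_len(2^n - 1)) {
    m <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(m) < 2) next
    if (length(m) == n && !grand) next
    if (sum(resources[m]) >= decision_point) {
      out <- c(out, coalition_label(m))
    }
  }
  out
}

# Independent unanimity oracle: count board entries every member selected.
brute_unanimous <- function(board, choice_of) {
  sum(vapply(seq_along(board), function(i) {
    m <- board[[i]]$members
    !anyNA(choice_of[m]) && all(choice_of[m] == i)
  }, logical(1)))
}

new_test_agent <- function(class, fields = list()) {
  structure(
    c(list(strategy = class, position = NA_integer_, effort = NA_real_,
           timeout_prob = 0, stream = NULL), fields),
    class = c(paste0(class, "_agent"), "coalsim_agent")
  )
}

with_stream <- function(seed, agent) {
  agent$stream <- make_stream(seed)
  agent
}

# --- stubborn agents: fixed cyclic proposals, always select own offer ------
# A proposes AB, B proposes BC, C proposes AC (each keeping 99): no entry is
# ever unanimous, so no coalition can form.

stubborn_agent <- function() new_test_agent("stubborn")

registerS3method("agent_propose", "stubborn_agent", function(agent, view) {
  pos <- view$position
  partner <- if (pos == 3) 1 else pos + 1
  members <- sort(c(pos, partner))
  alloc <- setNames(c(0, 0), position_label(members))
  alloc[position_label(pos)] <- 99
  alloc[position_label(partner)] <- view$config$payoff - 99
  offer(pos, members, alloc)
}, envir = asNamespace("coalsim"))

registerS3method("agent_select", "stubborn_agent", function(agent, view) {
  own_key <- board_key(list(members = view$own_offer$members,
                            allocation = view$own_offer$allocation))
  keys <- vapply(view$board, board_key, "")
  which(keys == own_key)[1]
}, envir = asNamespace("coalsim"))

registerS3method("agent_counter", "stubborn_agent", function(agent, view) {
  "pass"
}, envir = asNamespace("coalsim"))

registerS3method("agent_ratify", "stubborn_agent", function(agent, view) {
  "ratify"
}, envir = asNamespace("coalsim"))

# --- overbid agents: equity play, but counter by topping the target's ------
# tentative share by a fixed step. Every defection strictly increases the
# target's share, so the ratification loop must terminate.

overbid_agent <- function(step = 10) new_test_agent("overbid",
                                                    list(step = step))

registerS3method("agent_propose", "overbid_agent", function(agent, view) {
  getS3method("agent_propose", "equity_agent")(agent, view)
}, envir = asNamespace("coalsim"))

registerS3method("agent_select", "overbid_agent", function(agent, view) {
  getS3method("agent_select", "equity_agent")(agent, view)
}, envir = asNamespace("coalsim"))

registerS3method("agent_ratify", "overbid_agent", function(agent, view) {
  getS3method("agent_ratify", "equity_agent")(agent, view)
}, envir = asNamespace("coalsim"))

registerS3method("agent_counter", "overbid_agent", function(agent, view) {
  cfg <- view$config
  pos <- view$position
  feas <- names(feasible_coalitions(cfg))
  best <- NULL
  for (t in view$targets) {
    if (!coalition_label(c(pos, t)) %in% feas) next
    bid <- unname(view$tentative$allocation[position_label(t)]) + agent$step
    if (bid > cfg$payoff) next
    own <- cfg$payoff - bid
    if (is.null(best) || own > best$own) best <- list(t = t, bid = bid, own = own)
  }
  if (is.null(best)) return("pass")
  members <- sort(c(pos, best$t))
  alloc <- setNames(c(0, 0), position_label(members))
  alloc[position_label(best$t)] <- best$bid
  alloc[position_label(pos)] <- best$own
  offer(pos, members, alloc)
}, envir = asNamespace("coalsim"))
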