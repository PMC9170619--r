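# Software bargainers.
#
# An agent is a small S3 object implementing five decision points -- propose,
# select, counter (alternative offer), ratify, and a deadline response --
# each depending only on the view it is handed plus the agent's private
# random stream. The shipped strategies are deliberately simple stand-ins
# for human participants: an equity bargainer demanding shares proportional
# to contributed resources, an equal splitter, a uniform-random fuzzer, and
# a timeout wrapper modelling dropout. Custom strategies plug in by defining
# methods for the five generics on a new agent class; the shipped agents are
# myopic (no cross-round memory).

#' Agent decision generics
#'
#' The behavior contract for simulated bargainers. Each generic receives the
#' agent and a view list; decisions must depend only on the view and the
#' agent's private stream.
#'
#' * `agent_propose(agent, view)`: Phase I. View has `config`, `position`,
#'   and `feasible` (the feasible coalitions containing the agent). Must
#'   return an [offer()] that passes [validate_offer()].
#' * `agent_select(agent, view)`: Phase II. View has `config`, `position`,
#'   `board`, `eligible` (entry indices), `no_coalition`, `own_offer`.
#'   Returns an entry index or `"none"`.
#' * `agent_counter(agent, view)`: Phase IV (alternative-offers protocol
#'   only). View has `config`, `position`, `tentative`, `targets`. Returns an
#'   [offer()] for a dyad with one tentative member, or `"pass"`.
#' * `agent_ratify(agent, view)`: Phase V. View has `config`, `position`,
#'   `tentative`, `my_share`, `alternative` (the offer addressed to this
#'   agent, or `NULL`), `is_target`. Returns `"ratify"`, `"alternative"`, or
#'   `"none"`.
#' * `agent_deadline(agent)`: returns `"ACT"` or `"TIMEOUT"`; the default
#'   method times out with probability `timeout_prob` per decision.
#'
#' @param agent an agent object.
#' @param view a view list, see above.
#' @name agent-contract
NULL

#' @rdname agent-contract
#' @export
agent_propose <- function(agent, view) UseMethod("agent_propose")

#' @rdname agent-contract
#' @export
agent_select <- function(agent, view) UseMethod("agent_select")

#' @rdname agent-contract
#' @export
agent_counter <- function(agent, view) UseMethod("agent_counter")

#' @rdname agent-contract
#' @export
agent_ratify <- function(agent, view) UseMethod("agent_ratify")

#' @rdname agent-contract
#' @export
agent_deadline <- function(agent) UseMethod("agent_deadline")

#' @export
agent_deadline.coalsim_agent <- function(agent) {
  p <- agent$timeout_prob %||% 0
  if (p <= 0) return("ACT")
  if (stream_eval(agent$stream, stats::runif(1)) < p) "TIMEOUT" else "ACT"
}

new_agent <- function(strategy, timeout_prob = 0, effort = NA_real_) {
  structure(
    list(strategy = strategy, position = NA_integer_, effort = effort,
         timeout_prob = timeout_prob, stream = NULL),
    class = c(paste0(strategy, "_agent"), "coalsim_agent")
  )
}

#' @export
print.coalsim_agent <- function(x, ...) {
  cat(sprintf("<%s agent%s%s>\n", x$strategy,
              if (is.na(x$position)) ""
              else paste0(" at position ", position_label(x$position)),
              if ((x$timeout_prob %||% 0) > 0)
                sprintf(", timeout_prob=%g", x$timeout_prob) else ""))
  invisible(x)
}

#' Reference agent strategies
#'
#' @description
#' * `equity_agent()` demands a share proportional to the resources it
#'   contributes: it proposes the feasible coalition maximizing its own
#'   resource proportion `r_self / sum(r_members)`, allocating each member
#'   their equity share rounded to the payoff granularity with the rounding
#'   remainder kept by the proposer. It selects the displayed offer paying it
#'   most (preferring its own on ties), counters with its best-equity dyad,
#'   and ratifies unless it is offered a strictly larger share.
#' * `equal_split_agent()` proposes the cheapest feasible coalition it
#'   belongs to (smallest pooled resources) with equal shares, leftover units
#'   going to members in position order; it otherwise behaves like the equity
#'   agent (payoff-maximizing selection and myopic ratification).
#' * `random_agent()` makes uniformly random valid decisions everywhere --
#'   useful for fuzzing the engine.
#' * `timeout_agent()` wraps a base strategy and misses each decision
#'   deadline with probability `timeout_prob`, modelling an idle participant
#'   who gets kicked (the triad then aborts).
#'
#' All randomness (tie-breaks included) comes from the agent's private
#' stream, so replays under a fixed seed are identical.
#'
#' @param timeout_prob per-decision probability of missing the deadline.
#' @param effort effort score used by the session runner's earned-resources
#'   mode; `NA` means "draw from the session's effort distribution".
#' @param base strategy name wrapped by `timeout_agent()`.
#' @return an agent object (class `<strategy>_agent` / `coalsim_agent`).
#' @examples
#' g <- game_config(c(4, 3, 2), 5, payoff = 100)
#' a <- equity_agent()
#' a$position <- 2; a$stream <- make_stream(1)
#' agent_propose(a, list(config = g, position = 2,
#'                       feasible = feasible_coalitions(g)[c("AB", "BC")]))
#' @export
equity_agent <- function(timeout_prob = 0, effort = NA_real_) {
  new_agent("equity", timeout_prob, effort)
}

#' @rdname equity_agent
#' @export
equal_split_agent <- function(timeout_prob = 0, effort = NA_real_) {
  new_agent("equal_split", timeout_prob, effort)
}

#' @rdname equity_agent
#' @export
random_agent <- function(timeout_prob = 0, effort = NA_real_) {
  new_agent("random", timeout_prob, effort)
}

#' @rdname equity_agent
#' @export
timeout_agent <- function(timeout_prob = 1, base = "equity",
                          effort = NA_real_) {
  stopifnot(base %in% c("equity", "equal_split", "random"))
  new_agent(base, timeout_prob, effort)
}

# Build an agent from a roster spec: a strategy name, or a list with
# `strategy` plus optional `timeout_prob` and `effort`.
make_agent <- function(spec) {
  if (inherits(spec, "coalsim_agent")) return(spec)
  if (is.character(spec) && length(spec) == 1) spec <- list(strategy = spec)
  if (!is.list(spec) || is.null(spec$strategy)) {
    stop_coalsim("bad_config", "agent spec must be a strategy name or list")
  }
  if (!spec$strategy %in% c("equity", "equal_split", "random")) {
    stop_coalsim("bad_config",
                 sprintf("unknown agent strategy: %s", spec$strategy))
  }
  new_agent(spec$strategy, spec$timeout_prob %||% 0,
            spec$effort %||% NA_real_)
}

# Break a tie among candidate indices with the agent's private stream.
stream_pick <- function(agent, idx) {
  if (length(idx) == 1) return(idx)
  idx[stream_eval(agent$stream, sample.int(length(idx), 1))]
}

# Equity shares rounded to granularity; the rounding remainder goes to the
# proposer. Falls back to flooring the others if half-up rounding would
# leave the proposer with a negative share.
equity_offer <- function(config, proposer, members) {
  r <- config$resources
  g <- config$payoff_granularity
  others <- setdiff(members, proposer)
  total <- sum(r[members])
  ideal <- r[others] / total * config$payoff
  sh <- round_half_up(ideal / g) * g
  if (config$payoff - sum(sh) < 0) sh <- floor(ideal / g) * g
  alloc <- stats::setNames(numeric(length(members)), position_label(members))
  alloc[position_label(others)] <- sh
  alloc[position_label(proposer)] <- config$payoff - sum(sh)
  offer(proposer, members, alloc)
}

equal_split_offer <- function(config, proposer, members) {
  g <- config$payoff_granularity
  k <- length(members)
  units <- round(config$payoff / g)
  base <- units %/% k
  rem <- units - base * k
  sh_units <- rep(base, k) + c(rep(1, rem), rep(0, k - rem))
  alloc <- stats::setNames(sh_units * g, position_label(sort(members)))
  offer(proposer, members, alloc)
}

# --- equity agent ----------------------------------------------------------

#' @export
agent_propose.equity_agent <- function(agent, view) {
  cfg <- view$config
  pos <- view$position
  score <- vapply(view$feasible, function(m) {
    cfg$resources[pos] / sum(cfg$resources[m])
  }, numeric(1))
  best <- which(score >= max(score) - 1e-12)
  pick <- stream_pick(agent, best)
  equity_offer(cfg, pos, view$feasible[[pick]])
}

my_share_in <- function(entry, position) {
  unname(entry$allocation[position_label(position)])
}

# Payoff-maximizing selection shared by equity and equal-split agents:
# take the eligible entry with the highest own share, prefer the entry you
# proposed on ties, then break remaining ties with the private stream.
select_max_share <- function(agent, view) {
  idx <- view$eligible
  shares <- vapply(idx, function(i) my_share_in(view$board[[i]], view$position),
                   numeric(1))
  best <- idx[shares >= max(shares) - 1e-12]
  if (length(best) > 1) {
    own <- best[vapply(best, function(i) {
      view$position %in% view$board[[i]]$proposers
    }, logical(1))]
    if (length(own)) best <- own
  }
  stream_pick(agent, best)
}

#' @export
agent_select.equity_agent <- function(agent, view) {
  select_max_share(agent, view)
}

#' @export
agent_counter.equity_agent <- function(agent, view) {
  cfg <- view$config
  pos <- view$position
  feas <- names(feasible_coalitions(cfg))
  targets <- view$targets[vapply(view$targets, function(t) {
    coalition_label(c(pos, t)) %in% feas
  }, logical(1))]
  if (!length(targets)) return("pass")
  score <- cfg$resources[pos] / (cfg$resources[pos] + cfg$resources[targets])
  best <- which(score >= max(score) - 1e-12)
  t <- targets[stream_pick(agent, best)]
  equity_offer(cfg, pos, sort(c(pos, t)))
}

# Myopic ratification: defect only for a strictly larger share.
#' @export
agent_ratify.equity_agent <- function(agent, view) {
  if (view$is_target && !is.null(view$alternative)) {
    alt_share <- my_share_in(view$alternative, view$position)
    if (alt_share > view$my_share + 1e-12) return("alternative")
  }
  "ratify"
}

# --- equal-split agent -----------------------------------------------------

#' @export
agent_propose.equal_split_agent <- function(agent, view) {
  cfg <- view$config
  cost <- vapply(view$feasible, function(m) sum(cfg$resources[m]), numeric(1))
  best <- which(cost <= min(cost) + 1e-12)
  pick <- stream_pick(agent, best)
  equal_split_offer(cfg, view$position, view$feasible[[pick]])
}

#' @export
agent_select.equal_split_agent <- function(agent, view) {
  select_max_share(agent, view)
}

#' @export
agent_counter.equal_split_agent <- function(agent, view) {
  cfg <- view$config
  pos <- view$position
  feas <- names(feasible_coalitions(cfg))
  targets <- view$targets[vapply(view$targets, function(t) {
    coalition_label(c(pos, t)) %in% feas
  }, logical(1))]
  if (!length(targets)) return("pass")
  cost <- cfg$resources[pos] + cfg$resources[targets]
  best <- which(cost <= min(cost) + 1e-12)
  t <- targets[stream_pick(agent, best)]
  equal_split_offer(cfg, pos, sort(c(pos, t)))
}

#' @export
agent_ratify.equal_split_agent <- function(agent, view) {
  agent_ratify.equity_agent(agent, view)
}

# --- random agent ----------------------------------------------------------

#' @export
agent_propose.random_agent <- function(agent, view) {
  cfg <- view$config
  pick <- stream_eval(agent$stream, sample.int(length(view$feasible), 1))
  members <- view$feasible[[pick]]
  k <- length(members)
  units <- round(cfg$payoff / cfg$payoff_granularity)
  sh <- stream_eval(agent$stream,
                    as.vector(stats::rmultinom(1, units, rep(1, k))))
  alloc <- stats::setNames(sh * cfg$payoff_granularity,
                           position_label(sort(members)))
  offer(view$position, members, alloc)
}

#' @export
agent_select.random_agent <- function(agent, view) {
  opts <- as.list(view$eligible)
  if (view$no_coalition) opts <- c(opts, list("none"))
  opts[[stream_eval(agent$stream, sample.int(length(opts), 1))]]
}

#' @export
agent_counter.random_agent <- function(agent, view) {
  cfg <- view$config
  pos <- view$position
  feas <- names(feasible_coalitions(cfg))
  targets <- view$targets[vapply(view$targets, function(t) {
    coalition_label(c(pos, t)) %in% feas
  }, logical(1))]
  opts <- c(as.list(targets), list("pass"))
  pick <- opts[[stream_eval(agent$stream, sample.int(length(opts), 1))]]
  if (identical(pick, "pass")) return("pass")
  members <- sort(c(pos, pick))
  units <- round(cfg$payoff / cfg$payoff_granularity)
  sh <- stream_eval(agent$stream,
                    as.vector(stats::rmultinom(1, units, c(1, 1))))
  offer(pos, members, stats::setNames(sh * cfg$payoff_granularity,
                                      position_label(members)))
}

#' @export
agent_ratify.random_agent <- function(agent, view) {
  opts <- list("ratify")
  if (view$is_target && !is.null(view$alternative)) {
    opts <- c(opts, list("alternative"))
  }
  if (view$config$allow_no_selection) opts <- c(opts, list("none"))
  opts[[stream_eval(agent$stream, sample.int(length(opts), 1))]]
}
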