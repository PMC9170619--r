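# Simple weighted majority games: configuration, coalition feasibility, and
# offer validation.
#
# A game q(r_A-r_B-r_C) gives each bargainer position an integer resource
# endowment; any coalition of two or more positions whose pooled resources
# meet the decision point q wins a fixed payoff, which its members must split
# exactly. Positions are 1-based integers internally and rendered as letters
# A, B, C, ... in all user-facing output.

stop_coalsim <- function(class, msg, call. = FALSE) {
  stop(errorCondition(msg, class = c(paste0("coalsim_", class), "coalsim_error")))
}

round_half_up <- function(x) floor(x + 0.5)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x > 0 && x == floor(x)
}

#' Position labels
#'
#' Positions are integers internally; all user-facing output labels them
#' A, B, C, ... in position order.
#'
#' @param i integer position indices.
#' @return character labels.
#' @export
position_label <- function(i) LETTERS[i]

# Normalize a position spec (letters "A","B",... or integer indices) to a
# plain integer vector. Bounds are checked against n when given.
as_positions <- function(x, n = NULL) {
  if (is.character(x)) {
    x <- unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE)
    idx <- match(toupper(x), LETTERS)
    if (anyNA(idx)) {
      stop_coalsim("unknown_position", sprintf(
        "unknown position label(s): %s", paste(x[is.na(idx)], collapse = ", ")))
    }
  } else {
    idx <- as.integer(x)
    if (anyNA(idx)) stop_coalsim("unknown_position", "non-integer position index")
  }
  if (!is.null(n) && (any(idx < 1) || any(idx > n))) {
    stop_coalsim("unknown_position", sprintf(
      "position index out of range 1..%d: %s", n,
      paste(idx[idx < 1 | idx > n], collapse = ", ")))
  }
  idx
}

#' Coalition label
#'
#' @param members integer positions or letters.
#' @return a string such as `"BC"`.
#' @export
coalition_label <- function(members) {
  paste(LETTERS[sort(as_positions(members))], collapse = "")
}

#' Define a simple weighted majority game
#'
#' Constructs and validates the configuration of a simple weighted majority
#' game: each bargainer position holds `resources[i]` units, and any coalition
#' of at least two positions whose pooled resources reach `decision_point` may
#' form and divide `payoff` among its members. The classic 5(4-3-2) game is
#' `game_config(c(4, 3, 2), 5)`.
#'
#' @param resources non-negative integer resource endowment per position, in
#'   position order (position 1 = A, 2 = B, ...). At least 3 positions.
#' @param decision_point positive integer resource threshold a coalition must
#'   meet or exceed to be formable.
#' @param payoff positive payoff available to a formed coalition, in payoff
#'   units (e.g. 100 for "$100 million"); must be a multiple of
#'   `payoff_granularity`.
#' @param payoff_granularity smallest allocatable unit of payoff (default 1).
#'   Allocations must be integer multiples of this; fractional shares are
#'   rejected, not rounded, so conservation is exact.
#' @param allow_grand_coalition may the coalition of all positions form?
#' @param allow_no_selection may a bargainer decline to select any coalition
#'   (and, in the alternative-offers protocol, decline to ratify)?
#' @param max_rounds maximum number of bargaining rounds before the game ends
#'   without agreement.
#' @param conversion_rate bonus currency per payoff unit used by
#'   [bonus_payment()]; 0 means hypothetical payoffs (no bonus), which are
#'   still fully simulated.
#' @return an object of class `coalsim_game`.
#' @details Single-position "coalitions" are never feasible, even if one
#'   bargainer's resources alone meet the decision point: coalition formation
#'   is the joint use of resources, so the smallest coalition is the dyad.
#'   A configuration in which no coalition of two or more members can reach
#'   the decision point (given the grand-coalition toggle) is unwinnable and
#'   is rejected at construction.
#' @examples
#' g <- game_config(c(4, 3, 2), 5, payoff = 100)
#' coalition_resources(g, "BC")
#' @export
game_config <- function(resources, decision_point, payoff = 100,
                        payoff_granularity = 1,
                        allow_grand_coalition = FALSE,
                        allow_no_selection = FALSE,
                        max_rounds = 10,
                        conversion_rate = 0) {
  if (length(resources) < 3) {
    stop_coalsim("bad_config", "a game needs at least 3 bargainer positions")
  }
  if (!is.numeric(resources) || any(resources < 0) ||
      any(resources != floor(resources))) {
    stop_coalsim("bad_config", "resources must be non-negative integers")
  }
  if (!is_count(decision_point)) {
    stop_coalsim("bad_config", "decision_point must be a positive integer")
  }
  if (!is.numeric(payoff) || length(payoff) != 1 || payoff <= 0) {
    stop_coalsim("bad_config", "payoff must be positive")
  }
  if (!is.numeric(payoff_granularity) || payoff_granularity <= 0) {
    stop_coalsim("bad_config", "payoff_granularity must be positive")
  }
  if (abs(payoff / payoff_granularity -
          round(payoff / payoff_granularity)) > 1e-9) {
    stop_coalsim("bad_config",
                 "payoff must be a positive multiple of payoff_granularity")
  }
  if (!is_count(max_rounds)) {
    stop_coalsim("bad_config", "max_rounds must be a positive integer")
  }
  if (!is.numeric(conversion_rate) || conversion_rate < 0) {
    stop_coalsim("bad_config", "conversion_rate must be >= 0")
  }
  cfg <- structure(
    list(
      resources = as.integer(resources),
      decision_point = as.integer(decision_point),
      payoff = as.numeric(payoff),
      payoff_granularity = as.numeric(payoff_granularity),
      allow_grand_coalition = isTRUE(allow_grand_coalition),
      allow_no_selection = isTRUE(allow_no_selection),
      max_rounds = as.integer(max_rounds),
      conversion_rate = as.numeric(conversion_rate)
    ),
    class = "coalsim_game"
  )
  if (length(feasible_coalitions(cfg)) == 0) {
    stop_coalsim("unwinnable_game", paste0(
      "no coalition of >= 2 members reaches the decision point (",
      decision_point, "): the game cannot be won"))
  }
  cfg
}

#' @export
print.coalsim_game <- function(x, ...) {
  cat(sprintf("Simple weighted majority game %d(%s)\n",
              x$decision_point, paste(x$resources, collapse = "-")))
  cat(sprintf("  positions: %s\n",
              paste(position_label(seq_along(x$resources)), collapse = " ")))
  cat(sprintf("  payoff: %g (granularity %g), grand coalition %s, %s\n",
              x$payoff, x$payoff_granularity,
              if (x$allow_grand_coalition) "allowed" else "prohibited",
              if (x$allow_no_selection) "opt-out enabled" else "selection mandatory"))
  cat(sprintf("  max rounds: %d, conversion rate: %g\n",
              x$max_rounds, x$conversion_rate))
  invisible(x)
}

#' Pooled resources of a coalition
#'
#' @param config a [game_config()].
#' @param coalition positions, as letters (`"BC"`) or integer indices.
#' @return the sum of the members' resources.
#' @examples
#' g <- game_config(c(4, 3, 2), 5)
#' coalition_resources(g, "AB") # 7
#' @export
coalition_resources <- function(config, coalition) {
  members <- as_positions(coalition, length(config$resources))
  sum(config$resources[members])
}

#' Enumerate feasible coalitions
#'
#' All coalitions of two or more positions whose pooled resources meet the
#' decision point. The grand coalition (all positions) is included only when
#' `allow_grand_coalition` is set. The enumeration is exhaustive over the
#' powerset of positions.
#'
#' @param config a [game_config()].
#' @return a list of sorted integer member vectors; names are coalition
#'   labels such as `"BC"`.
#' @export
feasible_coalitions <- function(config) {
  n <- length(config$resources)
  out <- list()
  for (k in 2:n) {
    if (k == n && !config$allow_grand_coalition) next
    cmb <- utils::combn(n, k)
    for (j in seq_len(ncol(cmb))) {
      m <- cmb[, j]
      if (sum(config$resources[m]) >= config$decision_point) {
        out[[coalition_label(m)]] <- m
      }
    }
  }
  out
}

#' Construct a coalition offer
#'
#' An offer names a coalition and an exact division of the payoff among its
#' members. Construction only normalizes the pieces; all game-level rules are
#' checked by [validate_offer()].
#'
#' @param proposer the proposing position (letter or index).
#' @param members coalition members (letters like `"AC"` or integer indices).
#' @param shares numeric payoff shares; either named by position letters, or
#'   unnamed and aligned with the sorted member order.
#' @return an object of class `coalsim_offer` with fields `proposer`,
#'   `members` (sorted integer positions), and `allocation` (numeric named by
#'   position letters).
#' @examples
#' offer("A", "AC", c(A = 60, C = 40))
#' @export
offer <- function(proposer, members, shares) {
  proposer <- as_positions(proposer)
  if (length(proposer) != 1) stop_coalsim("bad_offer", "exactly one proposer")
  members <- sort(unique(as_positions(members)))
  shares <- stats::setNames(as.numeric(shares), names(shares))
  if (is.null(names(shares)) || !any(nzchar(names(shares)))) {
    if (length(shares) != length(members)) {
      stop_coalsim("nonmember_allocation",
                   "unnamed shares must align with the member list")
    }
    names(shares) <- position_label(members)
  } else {
    # keep the given keys; validate_offer() checks them against the members
    ord <- order(match(names(shares), LETTERS))
    shares <- shares[ord]
  }
  structure(
    list(proposer = proposer, members = members, allocation = shares),
    class = "coalsim_offer"
  )
}

#' @export
print.coalsim_offer <- function(x, ...) {
  cat(sprintf("Offer by %s: %s [%s]\n",
              position_label(x$proposer), coalition_label(x$members),
              paste0(names(x$allocation), "=", x$allocation, collapse = ", ")))
  invisible(x)
}

#' Validate an offer against a game
#'
#' Checks every offer rule and returns the offer unchanged when all hold:
#' the proposer belongs to the proposed coalition
#' (`coalsim_proposer_not_member`), the allocation covers exactly the
#' coalition members (`coalsim_nonmember_allocation`), every share is
#' non-negative (`coalsim_negative_share`) and an integer multiple of the
#' payoff granularity (`coalsim_non_granular_share`), the shares sum exactly
#' to the payoff (`coalsim_allocation_sum`), and the coalition is feasible
#' under the game's decision point and grand-coalition toggle
#' (`coalsim_infeasible_coalition`). Each failure signals a condition of the
#' named class, so callers (and user interfaces) can tell a malformed
#' allocation from an infeasible coalition.
#'
#' @param config a [game_config()].
#' @param off a [offer()].
#' @return `off`, invisibly, if valid; otherwise a classed error is signalled.
#' @export
validate_offer <- function(config, off) {
  n <- length(config$resources)
  as_positions(off$members, n)
  as_positions(off$proposer, n)
  if (!(off$proposer %in% off$members)) {
    stop_coalsim("proposer_not_member", sprintf(
      "proposer %s is not a member of coalition %s",
      position_label(off$proposer), coalition_label(off$members)))
  }
  alloc_pos <- match(names(off$allocation), LETTERS)
  if (anyNA(alloc_pos) || length(alloc_pos) != length(off$members) ||
      !setequal(alloc_pos, off$members)) {
    stop_coalsim("nonmember_allocation", sprintf(
      "allocation keys {%s} must be exactly the coalition members {%s}",
      paste(names(off$allocation), collapse = ","),
      paste(position_label(off$members), collapse = ",")))
  }
  if (any(off$allocation < 0)) {
    stop_coalsim("negative_share", "allocation shares must be >= 0")
  }
  g <- config$payoff_granularity
  if (any(abs(off$allocation / g - round(off$allocation / g)) > 1e-9)) {
    stop_coalsim("non_granular_share", sprintf(
      "shares must be multiples of the payoff granularity (%g)", g))
  }
  if (abs(sum(off$allocation) - config$payoff) > 1e-9) {
    stop_coalsim("allocation_sum", sprintf(
      "shares sum to %g, not the payoff %g", sum(off$allocation),
      config$payoff))
  }
  feas <- feasible_coalitions(config)
  if (!(coalition_label(off$members) %in% names(feas))) {
    stop_coalsim("infeasible_coalition", sprintf(
      "coalition %s is not feasible in this game",
      coalition_label(off$members)))
  }
  invisible(off)
}

#' Convert a payoff share to a bonus payment
#'
#' Multiplies a share (in payoff units) by the game's conversion rate and
#' rounds half-up to the bonus currency's cent. With the laboratory rate of
#' $0.05 per payoff unit, a share of 100 units pays a $5.00 bonus.
#'
#' @param config a [game_config()].
#' @param share payoff share, `>= 0`.
#' @return bonus amount in currency units, rounded to 2 decimals (half-up).
#' @export
bonus_payment <- function(config, share) {
  if (any(share < 0)) stop_coalsim("negative_share", "share must be >= 0")
  round_half_up(share * config$conversion_rate * 100) / 100
}

# --- flat key-value config file -------------------------------------------

config_keys <- c("resources", "decision_point", "payoff", "payoff_granularity",
                 "grand_coalition", "allow_no_selection", "max_rounds",
                 "conversion_rate")

#' Write / read a game configuration file
#'
#' The on-disk format is a flat `key = value` file with one line per field;
#' `resources` is comma-separated. The keys (`resources`, `decision_point`,
#' `payoff`, `payoff_granularity`, `grand_coalition`, `allow_no_selection`,
#' `max_rounds`, `conversion_rate`) are this package's own naming. A
#' configuration round-trips exactly: `read_game_config(write_game_config(g))`
#' is `identical()` to `g`.
#'
#' @param config a [game_config()].
#' @param path file path.
#' @return `write_game_config()` returns `path` invisibly;
#'   `read_game_config()` returns a `coalsim_game`.
#' @export
write_game_config <- function(config, path) {
  lines <- c(
    paste0("resources = ", paste(config$resources, collapse = ",")),
    paste0("decision_point = ", config$decision_point),
    paste0("payoff = ", as.character(config$payoff)),
    paste0("payoff_granularity = ", as.character(config$payoff_granularity)),
    paste0("grand_coalition = ", config$allow_grand_coalition),
    paste0("allow_no_selection = ", config$allow_no_selection),
    paste0("max_rounds = ", config$max_rounds),
    paste0("conversion_rate = ", as.character(config$conversion_rate))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_game_config
#' @export
read_game_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  m <- regmatches(lines, regexec("^\\s*([a-z_]+)\\s*=\\s*(.*?)\\s*$", lines))
  bad <- which(lengths(m) != 3)
  if (length(bad)) {
    stop_coalsim("bad_config_file",
                 sprintf("cannot parse config line %d: %s", bad[1], lines[bad[1]]))
  }
  kv <- stats::setNames(vapply(m, `[`, "", 3), vapply(m, `[`, "", 2))
  unknown <- setdiff(names(kv), config_keys)
  if (length(unknown)) {
    stop_coalsim("bad_config_file",
                 sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  missing <- setdiff(config_keys, names(kv))
  if (length(missing)) {
    stop_coalsim("bad_config_file",
                 sprintf("missing config key(s): %s", paste(missing, collapse = ", ")))
  }
  game_config(
    resources = as.numeric(strsplit(kv[["resources"]], ",")[[1]]),
    decision_point = as.numeric(kv[["decision_point"]]),
    payoff = as.numeric(kv[["payoff"]]),
    payoff_granularity = as.numeric(kv[["payoff_granularity"]]),
    allow_grand_coalition = as.logical(kv[["grand_coalition"]]),
    allow_no_selection = as.logical(kv[["allow_no_selection"]]),
    max_rounds = as.numeric(kv[["max_rounds"]]),
    conversion_rate = as.numeric(kv[["conversion_rate"]])
  )
}
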