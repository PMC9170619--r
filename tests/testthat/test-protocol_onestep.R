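test_that("build_board deduplicates identical offers and orders entries", {
  g <- g532()
  board <- build_board(worked_offers(), g)
  expect_length(board, 3)
  expect_equal(vapply(board, board_key, ""),
               c("AC:60/40", "BC:55/45", "BC:50/50"))
  # B and C proposing the exact same equal split display once, with both named
  dup <- build_board(list(offer("A", "AC", c(A = 60, C = 40)),
                          offer("B", "BC", c(B = 50, C = 50)),
                          offer("C", "BC", c(B = 50, C = 50))), g)
  expect_length(dup, 2)
  bc <- dup[[which(vapply(dup, board_key, "") == "BC:50/50")]]
  expect_identical(bc$proposers, c(2L, 3L))
  # three identical offers collapse to one entry with all three proposers
  gg <- g532(allow_grand_coalition = TRUE)
  same <- build_board(list(offer("A", "ABC", c(A = 34, B = 33, C = 33)),
                           offer("B", "ABC", c(A = 34, B = 33, C = 33)),
                           offer("C", "ABC", c(A = 34, B = 33, C = 33))), gg)
  expect_length(same, 1)
  expect_identical(same[[1]]$proposers, 1:3)
})

test_that("build_board rejects missing or duplicate proposers", {
  g <- g532()
  expect_error(build_board(worked_offers()[1:2], g),
               class = "coalsim_missing_proposer")
  expect_error(
    build_board(list(offer("A", "AC", c(A = 60, C = 40)),
                     offer("A", "AB", c(A = 60, B = 40)),
                     offer("C", "BC", c(B = 50, C = 50))), g),
    class = "coalsim_duplicate_proposer")
  trip <- build_board(list(offer("A", "AB", c(A = 50, B = 50)),
                           offer("B", "AB", c(A = 50, B = 50)),
                           offer("C", "BC", c(B = 50, C = 50))), g)
  expect_length(trip, 2)
  expect_identical(trip[[1]]$proposers, c(1L, 2L))
})

test_that("eligible_entries filters by membership and exposes the opt-out", {
  g <- g532()
  board <- build_board(worked_offers(), g)
  elB <- eligible_entries(board, "B", g)
  expect_setequal(elB$entries, c(2L, 3L))
  expect_false(elB$no_coalition)
  elA <- eligible_entries(board, "A", g)
  expect_identical(elA$entries, 1L)
  expect_true(length(elA$entries) >= 1) # own mandatory offer always qualifies
  g2 <- g532(allow_no_selection = TRUE)
  expect_true(eligible_entries(build_board(worked_offers(), g2), "B",
                               g2)$no_coalition)
})

test_that("resolve_round forms exactly the unanimously selected entry", {
  g <- g532()
  board <- build_board(worked_offers(), g)
  # both B and C pick B's offer: BC forms at 55/45, A is excluded
  rr <- resolve_round(board, list(selection("A", 1), selection("B", 2),
                                  selection("C", 2)), g)
  expect_equal(rr$formed$members, c(2L, 3L))
  expect_equal(rr$formed$allocation, c(B = 55, C = 45))
  # split selections: nothing forms
  rr2 <- resolve_round(board, list(selection("A", 1), selection("B", 2),
                                   selection("C", 3)), g)
  expect_null(rr2$formed)
  # unanimity over all three members forms the grand coalition
  gg <- g532(allow_grand_coalition = TRUE)
  ob <- build_board(list(offer("A", "ABC", c(A = 34, B = 33, C = 33)),
                         offer("B", "ABC", c(A = 34, B = 33, C = 33)),
                         offer("C", "ABC", c(A = 34, B = 33, C = 33))), gg)
  rr3 <- resolve_round(ob, list(selection("A", 1), selection("B", 1),
                                selection("C", 1)), gg)
  expect_equal(coalition_label(rr3$formed$members), "ABC")
})

test_that("resolve_round rejects invalid selections", {
  g <- g532()
  board <- build_board(worked_offers(), g)
  expect_error(resolve_round(board, list(selection("A", 2), selection("B", 2),
                                         selection("C", 2)), g),
               class = "coalsim_invalid_selection")
  expect_error(resolve_round(board, list(selection("A", "none"),
                                         selection("B", 2),
                                         selection("C", 2)), g),
               class = "coalsim_invalid_selection")
  expect_error(resolve_round(board, list(selection("B", 2),
                                         selection("C", 2)), g),
               class = "coalsim_invalid_selection")
})

test_that("at most one coalition forms per round (brute force over profiles)", {
  set.seed(2024)
  for (rep in 1:25) {
    allow_none <- rep %% 2 == 0
    g <- g532(allow_no_selection = allow_none)
    agents <- lapply(1:3, function(i) {
      a <- random_agent()
      a$position <- i
      with_stream(1000 + rep * 10 + i, a)
    })
    offers <- lapply(agents, function(a) {
      feas <- feasible_coalitions(g)
      mine <- feas[vapply(feas, function(m) a$position %in% m, logical(1))]
      validate_offer(g, agent_propose(a, list(config = g,
                                              position = a$position,
                                              feasible = mine)))
    })
    board <- build_board(offers, g)
    opts <- lapply(1:3, function(i) {
      el <- eligible_entries(board, i, g)$entries
      if (allow_none) c(as.list(el), list("none")) else as.list(el)
    })
    grid <- expand.grid(a = seq_along(opts[[1]]), b = seq_along(opts[[2]]),
                        c = seq_along(opts[[3]]))
    for (r in seq_len(nrow(grid))) {
      sel <- list(selection(1, opts[[1]][[grid$a[r]]]),
                  selection(2, opts[[2]][[grid$b[r]]]),
                  selection(3, opts[[3]][[grid$c[r]]]))
      rr <- resolve_round(board, sel, g)
      choice_of <- rep(NA_integer_, 3)
      for (s in sel) {
        if (!identical(s$choice, "none")) choice_of[s$selector] <- s$choice
      }
      n_unanimous <- brute_unanimous(board, choice_of)
      expect_lte(n_unanimous, 1)
      expect_identical(is.null(rr$formed), n_unanimous == 0)
    }
  }
})

test_that("equity agents settle on BC(60/40) in round one", {
  g <- g532()
  out <- run_one_step_game(g, list(equity_agent(), equity_agent(),
                                   equity_agent()), seed = 11)
  expect_identical(out$status, "FORMED")
  expect_identical(out$coalition_label, "BC")
  expect_equal(out$allocation, c(A = NA_real_, B = 60, C = 40))
  expect_identical(out$rounds_used, 1L)
})

test_that("non-converging agents exhaust the round budget and halt", {
  g <- g532(max_rounds = 1)
  out <- run_one_step_game(g, list(stubborn_agent(), stubborn_agent(),
                                   stubborn_agent()), seed = 5)
  expect_identical(out$status, "NO_AGREEMENT")
  expect_identical(out$rounds_used, 1L)
  g4 <- g532(max_rounds = 4)
  out4 <- run_one_step_game(g4, list(stubborn_agent(), stubborn_agent(),
                                     stubborn_agent()), seed = 5)
  expect_identical(out4$status, "NO_AGREEMENT")
  expect_identical(out4$rounds_used, 4L)
  expect_equal(max(out4$events$round), 4)
})

test_that("a timing-out agent aborts the triad", {
  g <- g532()
  out <- run_one_step_game(g, list(equity_agent(),
                                   timeout_agent(timeout_prob = 1),
                                   equity_agent()), seed = 3)
  expect_identical(out$status, "ABORTED")
  expect_match(out$reason, "position B")
  expect_true(all(is.na(out$allocation)))
})

test_that("replay under an identical seed is byte-identical", {
  g <- g532(allow_no_selection = TRUE, max_rounds = 6)
  roster <- function() list(random_agent(), random_agent(), equity_agent())
  o1 <- run_one_step_game(g, roster(), seed = 99)
  o2 <- run_one_step_game(g, roster(), seed = 99)
  expect_identical(o1, o2)
  o3 <- run_one_step_game(g, roster(), seed = 100)
  expect_false(identical(o1$events, o3$events))
})

test_that("formed outcomes always conserve the payoff", {
  g <- g532(allow_no_selection = TRUE, max_rounds = 5,
            allow_grand_coalition = TRUE)
  for (s in 1:30) {
    out <- run_one_step_game(g, list(random_agent(), random_agent(),
                                     random_agent()), seed = s)
    expect_lte(out$rounds_used, g$max_rounds)
    if (out$status == "FORMED") {
      expect_equal(sum(out$allocation, na.rm = TRUE), g$payoff)
    }
  }
})
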