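make_tentative <- function(g, sels = list(selection("A", 1), selection("B", 2),
                                          selection("C", 2))) {
  to_tentative(resolve_round(build_board(worked_offers(), g), sels, g))
}

test_that("to_tentative promotes the unanimous entry and nothing else", {
  g <- g532()
  tent <- make_tentative(g)
  expect_s3_class(tent, "coalsim_tentative")
  expect_equal(tent$members, c(2L, 3L))
  expect_equal(tent$allocation, c(B = 55, C = 45))
  expect_null(make_tentative(g, list(selection("A", 1), selection("B", 2),
                                     selection("C", 3))))
  gg <- g532(allow_grand_coalition = TRUE)
  ob <- build_board(list(offer("A", "ABC", c(A = 34, B = 33, C = 33)),
                         offer("B", "ABC", c(A = 34, B = 33, C = 33)),
                         offer("C", "ABC", c(A = 34, B = 33, C = 33))), gg)
  tg <- to_tentative(resolve_round(ob, list(selection("A", 1),
                                            selection("B", 1),
                                            selection("C", 1)), gg))
  expect_equal(coalition_label(tg$members), "ABC")
})

test_that("solicit_alternative validates the excluded bargainer's dyad", {
  g <- g532()
  tent <- make_tentative(g)
  a <- with_stream(7, equity_agent())
  a$position <- 1L
  alt <- solicit_alternative(tent, a, g)
  expect_identical(alt$type, "offer")
  expect_identical(alt$target, 3L)                 # C is A's best equity dyad
  expect_equal(alt$offer$allocation, c(A = 67, C = 33))
  # grand tentative: nobody is excluded, the operation must be skipped
  gg <- g532(allow_grand_coalition = TRUE)
  tg <- structure(list(members = 1:3,
                       allocation = c(A = 34, B = 33, C = 33),
                       origin = "phase_3"), class = "coalsim_tentative")
  expect_error(solicit_alternative(tg, a, gg),
               class = "coalsim_no_excluded_bargainer")
  # a counter that is not the {excluded, target} dyad is rejected
  bad <- new_test_agent("badalt")
  registerS3method("agent_counter", "badalt_agent",
                   function(agent, view) offer("B", "BC", c(B = 50, C = 50)),
                   envir = asNamespace("coalsim"))
  bad$position <- 1L
  expect_error(solicit_alternative(tent, bad, g),
               class = "coalsim_alternative_invalid")
})

test_that("ratify_tentative implements form / defect / back-to-phase-I", {
  g <- g532()
  tent <- make_tentative(g)
  alt <- structure(list(type = "offer",
                        offer = offer("A", "AC", c(A = 50, C = 50)),
                        target = 3L), class = "coalsim_alternative")
  # unanimous ratification forms the tentative coalition as agreed
  res <- ratify_tentative(tent, alt, list(B = "ratify", C = "ratify"), g)
  expect_identical(res$result, "formed")
  expect_equal(res$allocation, c(B = 55, C = 45))
  # the target defecting makes the alternative the new tentative coalition,
  # and the excluded bargainer changes identity
  res2 <- ratify_tentative(tent, alt, list(B = "ratify", C = "alternative"), g)
  expect_identical(res2$result, "new_tentative")
  expect_equal(coalition_label(res2$tentative$members), "AC")
  expect_identical(res2$excluded, 2L)
  # opting out sends play back to Phase I -- only when enabled
  gn <- g532(allow_no_selection = TRUE)
  res3 <- ratify_tentative(tent, alt, list(B = "ratify", C = "none"), gn)
  expect_identical(res3$result, "back_to_phase_1")
  expect_error(ratify_tentative(tent, alt, list(B = "ratify", C = "none"), g),
               class = "coalsim_invalid_ratify")
  expect_error(ratify_tentative(tent, alt,
                                list(B = "alternative", C = "ratify"), g),
               class = "coalsim_invalid_ratify")
  expect_error(ratify_tentative(tent, NULL,
                                list(B = "ratify", C = "alternative"), g),
               class = "coalsim_invalid_ratify")
})

test_that("equity agents ratify BC(60/40): the counter cannot beat equity", {
  g <- g532()
  out <- run_alt_offers_game(g, list(equity_agent(), equity_agent(),
                                     equity_agent()), seed = 21)
  expect_identical(out$status, "FORMED")
  expect_identical(out$coalition_label, "BC")
  expect_equal(out$allocation[["B"]], 60)
  expect_equal(out$allocation[["C"]], 40)
  ev <- out$events
  # A did counter (equity AC pays C only ~33 < 40) but C stayed
  expect_true(any(ev$action == "alternative" & ev$actor == "A"))
  expect_false(any(ev$action == "defect"))
})

test_that("an overbidding excluded bargainer triggers defection", {
  g <- g532()
  out <- run_alt_offers_game(g, list(overbid_agent(), equity_agent(),
                                     equity_agent()), seed = 31)
  ev <- out$events
  expect_gte(sum(ev$action == "defect"), 1)
  expect_identical(out$status, "FORMED")
  expect_identical(out$coalition_label, "AC") # A buys C away from BC(60/40)
  expect_equal(out$allocation[["C"]], 50)
})

test_that("strictly-improving counters terminate and rotate the excluded seat", {
  g <- g532()
  out <- run_alt_offers_game(g, list(overbid_agent(), overbid_agent(),
                                     overbid_agent()), seed = 41)
  expect_true(out$status %in% c("FORMED", "NO_AGREEMENT"))
  expect_lte(out$rounds_used, g$max_rounds)
  if (out$status == "FORMED") {
    expect_equal(sum(out$allocation, na.rm = TRUE), g$payoff)
  }
  # every defection hands the alternative to a new tentative coalition, so
  # consecutive Phase-IV counters come from different excluded bargainers
  ev <- out$events
  for (r in unique(ev$round)) {
    counters <- ev$actor[ev$round == r & ev$action %in% c("alternative", "pass")]
    if (length(counters) > 1) {
      expect_true(all(counters[-1] != counters[-length(counters)]))
    }
  }
})

test_that("round budget, abort, and replay behave as in the one-step runner", {
  g <- g532(max_rounds = 3)
  out <- run_alt_offers_game(g, list(stubborn_agent(), stubborn_agent(),
                                     stubborn_agent()), seed = 8)
  expect_identical(out$status, "NO_AGREEMENT")
  expect_identical(out$rounds_used, 3L)
  out2 <- run_alt_offers_game(g, list(equity_agent(),
                                      timeout_agent(timeout_prob = 1),
                                      equity_agent()), seed = 8)
  expect_identical(out2$status, "ABORTED")
  r1 <- run_alt_offers_game(g532(allow_no_selection = TRUE),
                            list(random_agent(), random_agent(),
                                 random_agent()), seed = 77)
  r2 <- run_alt_offers_game(g532(allow_no_selection = TRUE),
                            list(random_agent(), random_agent(),
                                 random_agent()), seed = 77)
  expect_identical(r1, r2)
})

test_that("no outcome forms from a tentative state without unanimous ratify", {
  # random agents exercise defect/none/ratify freely; every FORMED outcome
  # must still conserve the payoff and end via a ratification, i.e. the last
  # Phase-V resolve event carries the formed allocation
  for (s in 1:20) {
    out <- run_alt_offers_game(g532(allow_no_selection = TRUE),
                               list(random_agent(), random_agent(),
                                    random_agent()), seed = 400 + s)
    if (out$status == "FORMED") {
      expect_equal(sum(out$allocation, na.rm = TRUE), 100)
      last <- out$events[nrow(out$events), ]
      expect_identical(last$action, "resolve")
      expect_identical(last$phase, "V")
      ratifiers <- out$events[out$events$round == last$round &
                                out$events$phase == "V" &
                                out$events$action == "ratify", ]
      expect_gte(nrow(ratifiers), 2)
    }
  }
})
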