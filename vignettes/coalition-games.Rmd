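---
title: "Simulating three-player coalition bargaining: models, agents, and statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating three-player coalition bargaining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coalsim)
```

## The model

coalsim simulates *simple weighted majority games*: three bargainers hold
integer resource endowments $r_A, r_B, r_C$, and any coalition $S$ of at
least two bargainers with $\sum_{i \in S} r_i \ge q$ — where $q$ is the
*decision point* — may form and divide a fixed payoff $v$ among its members.
The notation $q(r_A\text{-}r_B\text{-}r_C)$ names a game; the canonical
example is 5(4-3-2), where every two-player coalition is winning (AB pools 7,
AC 6, BC 5) and the bargaining question is not *whether* an agreement forms
but *who* is excluded from it. The empirical regularity of interest is the
Strength-is-Weakness effect: the strongest bargainer (A) tends to be
excluded, because B and C can win together more cheaply and equity reasoning
makes A the most expensive partner.

Single players never count as coalitions here, even if one endowment alone
reaches $q$: coalition formation is defined as the *joint* use of resources,
so the smallest admissible coalition is the dyad. Unwinnable configurations
(no admissible coalition reaches $q$) are rejected at construction rather
than discovered mid-game.

Two classic bargaining protocols are implemented, both with simultaneous
initial offers so that first offers are mutually independent:

* **One-step** (`run_one_step_game()`): each round, (I) every bargainer makes
  a mandatory, validated offer — a coalition plus an exact division of $v$;
  (II) all offers are displayed, duplicates merged with all proposers
  credited, and each bargainer selects one offer that includes them (or,
  optionally, none); (III) an offer selected by *all* its members forms
  immediately. Otherwise the next round begins, up to `max_rounds`.
* **Alternative offers** (`run_alt_offers_game()`): Phases I–II as above, but
  a unanimous selection only creates a *tentative* coalition. The excluded
  bargainer may then (IV) offer one tentative member a better deal; (V) the
  members ratify — forming the coalition — unless the targeted member defects
  to the alternative, which becomes the new tentative coalition with a new
  excluded bargainer, or a member opts out (when enabled), returning play to
  Phase I.

At most one coalition can form per round: every bargainer casts a single
selection and any two winning coalitions in a triad share a member, so two
entries can never both be unanimous. The test suite checks this against
brute-force enumeration of selection profiles rather than trusting the
argument.

## Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| `resources` | resource units per position | — | defines bargaining strength; order is position order A, B, C |
| `decision_point` | resource units | — | winning threshold $q$; with `resources` it fixes which coalitions exist |
| `payoff` | payoff units (e.g. \$1M) | 100 | the amount a winning coalition divides |
| `payoff_granularity` | payoff units | 1 | smallest allocatable unit; non-granular shares are *rejected*, not rounded, so conservation is exact |
| `allow_grand_coalition` | flag | `FALSE` | whether ABC may form; classic Strength-is-Weakness designs prohibit it |
| `allow_no_selection` | flag | `FALSE` | explicit opt-out in Phase II / Phase V; most useful under alternative offers as an exit back to Phase I |
| `max_rounds` | rounds | 10 | round budget before `NO_AGREEMENT`; no canonical value exists, 10 gives myopic agents ample room while bounding runtime |
| `conversion_rate` | bonus currency per payoff unit | 0 | converts attained shares to a bonus (`bonus_payment()`, half-up cent rounding); 0 = hypothetical payoffs |

The alternative-offers runner additionally caps defection cycles within a
round at `payoff / payoff_granularity` — the largest possible number of
strictly improving counteroffers — because rounds are defined as Phase I–III
passes and an endless Phase IV–V cycle must not be able to stall a round.

## Agents

Agents stand in for human participants; they exercise the engine, they do
not model people. Each implements five decisions (propose, select, counter,
ratify, deadline response) as S3 methods, sees only the view it is handed,
and draws any randomness — tie-breaks included — from a private stream, so a
decision replayed with the same seed and view is identical.

* **Equity** (`equity_agent()`): demands shares proportional to contributed
  resources. It proposes the feasible coalition maximizing its own
  proportion $r_i / \sum_{j \in S} r_j$ — for B in 5(4-3-2) that is BC
  ($3/5$ of 100 = 60 beats $3/7$ of 100 in AB) — allocating partners their
  equity share rounded to the granularity, remainder to the proposer. It
  selects the displayed offer paying it most (own offer preferred on ties),
  counters with its best-equity dyad, and ratifies unless offered strictly
  more. In 5(4-3-2) three equity agents produce BC(60/40) in round one,
  deterministically: a hand-derivable Strength-is-Weakness outcome that the
  acceptance suite asserts at 100% of triads. Under the alternative-offers
  protocol the same outcome survives Phase IV because A's best equity
  counter gives C only $\approx 2/6 \cdot 100 = 33 < 40$.
* **Equal split** (`equal_split_agent()`): proposes the cheapest feasible
  coalition it belongs to with equal shares, leftover units to members in
  position order; otherwise behaves like the equity agent.
* **Random** (`random_agent()`): uniformly random valid decisions everywhere;
  the fuzzing workhorse. Ten thousand fuzzed proposals (and full fuzzed
  games under both protocols) must pass the validator.
* **Timeout** (`timeout_agent()`): wraps a base strategy and misses each
  decision deadline with a configured probability — the dropout model. A
  timeout aborts the whole triad (`ABORTED`), mirroring online sessions
  where an idle participant is kicked and their partners forwarded out.

No shipped agent reproduces the intermediate 55/45 splits human bargainers
favor (between equity's 60/40 and the equal split); modeling concession
behavior is a user-level extension via the S3 hook, not a packaged claim.

## Sessions, replay, and output

`run_session()` plays `n_triads` independent triads. Resources are assigned
randomly (uniform bijection of agents to positions) or *earned*: agents
ranked by an effort score take positions in descending-resource order, ties
broken randomly — the computational core of real-effort designs, with effort
scores drawn from a configurable distribution (default standard normal; the
effort task itself is interface, not computation). Per-triad and per-agent
streams are derived from the master seed by integer mixing, so a session is
a pure function of its configuration: replays are byte-identical, which the
tests assert on the serialized CSV.

Outcomes are written as a schema-versioned CSV (one row per triad,
allocation in per-position `share_*` columns) and a per-event log (offers,
selections, resolutions, tentative coalitions, alternatives, ratifications,
defections). Both are exercised round-trip in the tests; malformed files
fail with the offending line number. The column naming is this package's
own.

## Statistics

For a formed-coalition distribution against expected proportions $\pi_i$
(default uniform over the coalitions the configuration allows to form — the
one-third-each benchmark when three are formable):

* **Cohen's w**: $w = \sqrt{\sum_i (p_i - \pi_i)^2 / \pi_i}$, with the
  goodness-of-fit statistic $X^2 = n w^2$ on $k - 1$ df.
* **Power / MDES**: the test's power at effect $w$ is
  $P[\chi^2_{df}(\lambda = n w^2) > \chi^2_{df,1-\alpha}]$ (noncentral
  chi-square); `min_detectable_w()` inverts this by bisection on $\lambda$
  over $[10^{-6}, 10^3]$ to a $10^{-10}$ bracket — derivative-free and
  robust, and the two functions are mutual inverses to $10^{-6}$ wherever
  the power has not saturated at 1.
* **Odds ratio** and **Cohen's d** (pooled SD) for condition contrasts.

All values are kept at full precision internally; rounding to two decimals
happens only in display layers.

### Why the Monte-Carlo power check runs at n = 1000

The noncentral chi-square power formula is an asymptotic approximation to
the exact multinomial rejection rate. At $n = 52$ tables the two differ by
about 0.03 — hundreds of times the Monte-Carlo standard error at $10^5$
replicates — so a simulation at that size would measure the approximation
gap, not the correctness of the implementation. The acceptance check
therefore simulates $10^5$ multinomial tables of $n = 1000$ draws at a true
effect of $w = 0.10$ (mid-range power $\approx 0.82$), squarely inside the
asymptotic regime, and requires agreement within 3 standard errors. A green
result establishes that the power computation is right; it does not make the
asymptotic formula exact at small $n$ (no implementation could).

## What the synthetic world does and does not establish

The agents are deterministic caricatures: equity triads produce the *modal*
human outcome (BC formation, strong-player exclusion) with probability 1,
whereas human triads produced it in 65–67% of cases with intermediate
splits. Green engine tests therefore establish protocol correctness —
validation, unanimity, conservation, termination, replay — not behavioral
realism. Conversely, the statistics module is validated against printed
study summaries directly (effect sizes, MDES, OR, d recomputed from the
published proportions, means, and SDs), independent of any agent behavior.

## Numerical and edge-case choices

* Shares are validated as integer multiples of the granularity with a
  $10^{-9}$ tolerance; sums must match the payoff exactly at that tolerance.
  Rejecting rather than rounding keeps conservation exact by construction.
* Bonus conversion rounds half-up to the cent (`floor(x + 0.5)` on cents), so
  a half-cent bonus pays the cent, matching how experimenters round payments
  in participants' favor.
* Display-board order is (coalition label, lowest-indexed proposer's share
  descending, allocation string): arbitrary but fixed, for reproducible
  logs; protocol semantics never depend on entry order.
* Positions are 1-based integers internally (idiomatic R) and letters
  A, B, C everywhere user-facing.
* If every bargainer opts out of selecting, the round simply advances; no
  penalty attaches to a "lost" round beyond consuming the round budget.
* If a grand tentative coalition fails ratification, play returns to
  Phase I.
* Re-proposing an identical offer across rounds is permitted; nothing in the
  protocols forbids it, so stubborn non-convergence is representable (and is
  used in the termination tests).

## Known limitations

* Exactly three bargainers; quota games with coalition-specific payoffs are
  out of scope.
* No real-time concerns: matching lobbies, page timers, and payment
  integration are represented only by the dropout model and the `ABORTED`
  status.
* No learning or concession agents ship; the S3 contract supports stateful
  strategies but none is packaged.
* The odds ratio for *first offers to the strongest bargainer* reported in
  the literature was computed from unrounded counts unavailable in print;
  recomputing it from rounded proportions gives 1.44–1.45, so the package
  documents the function but asserts nothing about that particular value.
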