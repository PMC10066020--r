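#' Bundled example datasets
#'
#' Small published experimental datasets used throughout the documentation
#' and tests, each returned as a long-format tibble ready for the test
#' functions. Available names (see `fixture_names()`):
#'
#' * `caginalp_prices` — session-average asset prices from a 7-session
#'   asset-market experiment: 3 cash-rich vs 4 asset-rich sessions.
#' * `bohr_peaks` — peak asset prices, 6 private-savings vs 6
#'   government-savings sessions.
#' * `holt_smith_rents` — total rent-seeking expenditures, 4 low-effort-cost
#'   vs 4 high-effort-cost sessions.
#' * `davis_holt_prices` — average posted-offer prices for 12 oligopoly
#'   sessions under three treatments (5 sellers without market power,
#'   5 sellers with market power, 3 sellers with market power); `block` is
#'   the session id.
#' * `davis_holt_market_power` — the 6 matched pairs (S1–S6) contrasting
#'   market power at 5 sellers.
#' * `davis_holt_numbers_effect` — the 6 matched pairs (S7–S12) contrasting
#'   3 vs 5 sellers, both with market power.
#' * `holt_sprott_auctions` — session-average wind-lease auction earnings
#'   for three auction formats, 4 sessions each.
#' * `smith_auctions` — session-average double-auction contract prices under
#'   three trading rules (sellers offer, double auction, buyers bid), with
#'   the trader-group-size row as `stratum`.
#' * `holt_gender_bubbles` — peak bubble prices for 25-period vs 15-period
#'   asset markets, stratified by gender-sorted session pools.
#' * `comeig_risk` — 256 binary risky-lottery choices (1 = risky option),
#'   upside-risk vs downside-risk framing, stratified by gender x payoff
#'   scale.
#' * `comeig_risk_counts` — the same data summarised as per-stratum counts.
#' * `capra_claims` — traveler's-dilemma session-average claims with their
#'   incentive parameters, Parts A and B of each of six sessions (columns
#'   `session`, `part`, `incentive`, `claim`).
#'
#' @param name Fixture name.
#' @return `load_fixture()` returns a tibble; `fixture_names()` the
#'   available names; `fixture_catalog()` a tibble of names with one-line
#'   descriptions.
#' @examples
#' load_fixture("caginalp_prices")
#' fixture_names()
#' @export
load_fixture <- function(name) {
  cat <- fixture_builders()
  if (!name %in% names(cat)) {
    abort(paste0("unknown fixture `", name, "`; see `fixture_names()`."))
  }
  cat[[name]]$build()
}

#' @rdname load_fixture
#' @export
fixture_names <- function() names(fixture_builders())

#' @rdname load_fixture
#' @export
fixture_catalog <- function() {
  cat <- fixture_builders()
  tibble(
    name = names(cat),
    description = vapply(cat, function(f) f$description, character(1))
  )
}

fixture_builders <- function() {
  list(
    caginalp_prices = list(
      description = "asset-market session-average prices, cash-rich vs asset-rich",
      build = function() labeled_data(
        value = c(3.43, 3.73, 3.97, 3.03, 3.32, 2.55, 3.06),
        treatment = rep(c("cash_rich", "asset_rich"), c(3, 4))
      )
    ),
    bohr_peaks = list(
      description = "peak asset prices, private vs government savings",
      build = function() labeled_data(
        value = c(42, 36, 53, 61.5, 38.5, 70,
                  42.5, 21.25, 30, 26, 43, 38),
        treatment = rep(c("private_savings", "government_savings"), each = 6)
      )
    ),
    holt_smith_rents = list(
      description = "rent-seeking expenditures, low vs high effort cost",
      build = function() labeled_data(
        value = c(77, 83, 130, 81, 132, 111, 93, 87),
        treatment = rep(c("low_cost", "high_cost"), each = 4)
      )
    ),
    davis_holt_prices = list(
      description = "posted-offer oligopoly prices, 12 sessions x 2 treatments each",
      build = function() {
        s16 <- paste0("S", 1:6)
        s712 <- paste0("S", 7:12)
        labeled_data(
          value = c(329, 308, 341, 410, 310, 397,        # 5 sellers, no power
                    407, 468, 430, 455, 397, 441,        # 5 sellers, power (S1-6)
                    415, 471, 392, 401, 392, 512,        # 5 sellers, power (S7-12)
                    425, 470, 408, 436, 424, 517),       # 3 sellers, power
          treatment = rep(c("five_no_power", "five_power", "five_power", "three_power"),
                          each = 6),
          block = c(s16, s16, s712, s712),
          levels = c("five_no_power", "five_power", "three_power")
        )
      }
    ),
    davis_holt_market_power = list(
      description = "matched pairs S1-S6: market power vs none, 5 sellers",
      build = function() labeled_data(
        value = c(407, 468, 430, 455, 397, 441,
                  329, 308, 341, 410, 310, 397),
        treatment = rep(c("five_power", "five_no_power"), each = 6),
        block = rep(paste0("S", 1:6), 2)
      )
    ),
    davis_holt_numbers_effect = list(
      description = "matched pairs S7-S12: 3 vs 5 sellers, both with power",
      build = function() labeled_data(
        value = c(425, 470, 408, 436, 424, 517,
                  415, 471, 392, 401, 392, 512),
        treatment = rep(c("three_power", "five_power"), each = 6),
        block = rep(paste0("S", 7:12), 2)
      )
    ),
    holt_sprott_auctions = list(
      description = "wind-lease auction earnings, three formats x 4 sessions",
      build = function() labeled_data(
        value = c(-0.61, -3.64, 0.82, 1.39,
                  3.84, 1.04, 3.17, 3.97,
                  0.22, -0.24, 0.42, 1.13),
        treatment = rep(c("uk_multi_round", "us_clock", "single_round"), each = 4)
      )
    ),
    smith_auctions = list(
      description = "double-auction prices under three trading rules, group size as stratum",
      build = function() labeled_data(
        value = c(208, 213, 217, 195, 209, 213),
        treatment = rep(c("sellers_offer", "double_auction", "buyers_bid"), 2),
        stratum = rep(c("group_a", "group_b"), each = 3)
      )
    ),
    holt_gender_bubbles = list(
      description = "peak bubble prices, 25- vs 15-period markets, gender-sorted strata",
      build = function() labeled_data(
        value = c(87, 95, 61, 177.5, 75.5, 37, 152, # female, 25-period
                  66, 36, 58, 64, 42,               # female, 15-period
                  55, 48, 68, 85, 65, 56.5, 50,     # male, 25-period
                  50, 70, 45, 43, 53),              # male, 15-period
        treatment = rep(c("p25", "p15", "p25", "p15"), c(7, 5, 7, 5)),
        stratum = rep(c("female", "male"), each = 12),
        levels = c("p25", "p15")
      )
    ),
    comeig_risk = list(
      description = "256 binary risky-choice outcomes, upside vs downside framing, 4 strata",
      build = function() {
        counts <- comeig_counts()
        rows <- lapply(seq_len(nrow(counts)), function(i) {
          n <- counts$n[i]
          k <- counts$risky[i]
          tibble(
            value = rep(c(1, 0), c(k, n - k)),
            treatment = counts$treatment[i],
            stratum = counts$stratum[i]
          )
        })
        out <- dplyr::bind_rows(rows)
        labeled_data(out$value, out$treatment, stratum = out$stratum,
                     levels = c("upside", "downside"))
      }
    ),
    comeig_risk_counts = list(
      description = "risky-choice counts per stratum and framing (summary of comeig_risk)",
      build = comeig_counts
    ),
    capra_claims = list(
      description = "traveler's dilemma session-average claims and incentives, parts A and B",
      build = function() tibble(
        session = rep(paste0("S", 1:6), 2),
        part = rep(c("A", "B"), each = 6),
        incentive = c(80, 10, 50, 20, 25, 5,
                      10, 80, 20, 50, 5, 25),
        claim = c(82, 186, 92, 116, 146, 196,
                  163, 99, 86, 82, 171, 170)
      )
    )
  )
}

comeig_counts <- function() {
  tibble(
    stratum = rep(c("male_1x", "male_5x", "female_1x", "female_5x"), each = 2),
    treatment = rep(c("downside", "upside"), 4),
    risky = c(25, 30, 17, 28, 19, 29, 4, 27),
    n = 32
  )
}
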