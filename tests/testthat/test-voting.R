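test_that("consensus implements the inclusive supermajority threshold", {
  expect_equal(consensus(c(X = 2, Y = 1), 0.60), list(key = "X", fraction = 2 / 3))
  expect_equal(consensus(c(X = 3, Y = 2), 0.60), list(key = "X", fraction = 0.6))
  expect_null(consensus(c(X = 2, Y = 1), 0.70))
  expect_equal(consensus(c(X = 1), 0.70), list(key = "X", fraction = 1.0))
  # unnamed vote vectors are tabulated
  expect_identical(consensus(c("a", "a", "b"), 0.6)$key, "a")
  expect_error(consensus(c(X = 2), 0.5), "ambiguous-winner")
  expect_error(consensus(c(X = 2), 0.49), "ambiguous-winner")
})

test_that("consensus winner is always unique for thresholds above one half", {
  set.seed(5)
  for (rep in 1:500) {
    n_keys <- sample(1:5, 1L)
    tally <- stats::setNames(sample(1:6, n_keys, replace = TRUE),
                             paste0("k", seq_len(n_keys)))
    thr <- stats::runif(1L, 0.501, 1)
    res <- consensus(tally, thr)
    winners <- sum(tally / sum(tally) >= thr - 1e-9)
    expect_lte(winners, 1L)
    expect_identical(is.null(res), winners == 0L)
  }
})

test_that("synonyms classify into discrepancy groups A-D", {
  expect_identical(classify_group(mk_ledger("x", "d1", 1L, 1L)), "A")
  expect_identical(classify_group(
    mk_ledger("x", c("d1", "d2", "d3"), 1:3, 1L)), "B")
  expect_identical(classify_group(
    mk_ledger("x", c("d1", "d1"), 1:2, 1L)), "C")
  expect_identical(classify_group(
    mk_ledger("x", c("d1", "d1", "d2"), 1:3, 1L)), "D")
})

test_that("intra-depositor voting follows the per-SID tally", {
  keys <- mk_keys(1:3, ste = c(1, 1, 2))
  # 2-of-3 at the exact level: cids 1,1,2 -> key I1 wins
  w <- intra_depositor_vote(c(1L, 1L, 2L), keys, "CID", 0.60)
  expect_identical(w$key, "I1")
  # 50:50 split fails any admissible threshold
  expect_null(intra_depositor_vote(c(1L, 2L), keys, "CID", 0.60))
  # a single SID is unanimous
  expect_identical(intra_depositor_vote(3L, keys, "CID", 0.60)$key, "I3")
  expect_error(intra_depositor_vote(9L, keys, "CID", 0.60), "missing")
})

test_that("single mode gives one vote per intra-consistent depositor", {
  keys <- mk_keys(1:3)
  led <- mk_ledger("x", c("d1", "d2", "d3", "d3"), 1:4, c(1L, 1L, 2L, 3L))
  # d3 is internally split and contributes nothing: d1, d2 vote I1
  w <- inter_depositor_vote(led, keys, "CID", voting_strategy("I"))
  expect_identical(w$key, "I1")
  expect_equal(w$fraction, 1.0)
  expect_equal(w$voters, 2L)
})

test_that("multiple mode counts every SID", {
  keys <- mk_keys(1:2)
  led5 <- mk_ledger("x", paste0("d", 1:5), 1:5, c(1L, 1L, 1L, 2L, 2L))
  w <- inter_depositor_vote(led5, keys, "CID", voting_strategy("III"))
  expect_equal(w$fraction, 0.6)  # 3 of 5, inclusive
  led2 <- mk_ledger("x", c("d1", "d2"), 1:2, c(1L, 2L))
  expect_null(inter_depositor_vote(led2, keys, "CID", voting_strategy("III")))
})

test_that("resolution walks the ladder to the first consensus level", {
  # three depositors, three distinct CIDs, two sharing a stereo key:
  # no CID consensus (1/3 each), STE consensus 2/3
  keys <- mk_keys(c(10L, 11L, 12L), ste = c(1, 1, 2))
  led <- mk_ledger("x", c("d1", "d2", "d3"), 1:3, c(10L, 11L, 12L))
  r <- resolve_synonym(led, keys, "I")
  expect_identical(r$status, "resolved")
  expect_identical(r$level, "STE")
  expect_identical(r$cids, c(10L, 11L))
  expect_equal(r$fraction, 2 / 3)
  expect_identical(r$category, "STE")
  expect_matches_oracle(led, keys, "I")

  # unanimity in CID: category CID-STD at fraction 1
  led2 <- mk_ledger("y", c("d1", "d2", "d3"), 4:6, 10L)
  r2 <- resolve_synonym(led2, keys, "I")
  expect_identical(r2$category, "CID-STD")
  expect_equal(r2$fraction, 1.0)

  # four structurally unrelated CIDs: discarded at every level
  keys4 <- mk_keys(1:4)
  led4 <- mk_ledger("z", paste0("d", 1:4), 1:4, 1:4)
  r4 <- resolve_synonym(led4, keys4, "I")
  expect_identical(r4$status, "discarded")
  expect_identical(r4$cids, integer(0))

  # group A bypasses voting entirely
  rA <- resolve_synonym(mk_ledger("a", "d1", 1L, 5L), keys4[0, ], "I")
  expect_identical(rA$status, "singleton")
  expect_identical(rA$category, "GROUP_A")
})

test_that("a sub-unanimous exact-level consensus is categorized CID-FILT", {
  keys <- mk_keys(1:2)
  led <- mk_ledger("x", paste0("d", 1:5), 1:5, c(1L, 1L, 1L, 1L, 2L))
  r <- resolve_synonym(led, keys, "I")
  expect_identical(r$level, "CID")
  expect_identical(r$category, "CID-FILT")
  expect_equal(r$fraction, 0.8)
})

test_that("resolution agrees with the brute-force oracle on random instances", {
  uni <- small_universe()
  for (seed in 1:400) {
    led <- random_instance(seed)
    preset <- c("I", "II", "III", "IV")[(seed %% 4L) + 1L]
    expect_matches_oracle(led, uni, preset)
  }
})

test_that("in multiple mode, lowering the threshold never pushes resolution to a coarser level", {
  uni <- small_universe()
  lvl_rank <- stats::setNames(seq_along(EQUIV_LEVELS), EQUIV_LEVELS)
  for (seed in 401:550) {
    led <- random_instance(seed)
    hi <- resolve_synonym(led, uni, voting_strategy(vote_mode = "multiple",
                                                    threshold = 0.7))
    lo <- resolve_synonym(led, uni, voting_strategy(vote_mode = "multiple",
                                                    threshold = 0.6))
    if (hi$status == "resolved") {
      expect_false(lo$status == "discarded")
      if (lo$status == "resolved") {
        expect_lte(lvl_rank[[lo$level]], lvl_rank[[hi$level]])
      }
    }
  }
})

test_that("coarsening the level never decreases the winning share (nested keys)", {
  uni <- small_universe()
  for (seed in 551:650) {
    led <- random_instance(seed)
    atCID <- inter_depositor_vote(led, uni, "CID", voting_strategy("III"))
    if (is.null(atCID)) next
    atCON <- inter_depositor_vote(led, uni, "CON", voting_strategy("III"))
    expect_false(is.null(atCON))
    expect_gte(atCON$fraction, atCID$fraction - 1e-12)
  }
})

test_that("exact-level voting is equivalent to voting on CIDs directly", {
  uni <- small_universe()
  for (seed in 651:700) {
    led <- random_instance(seed)
    w <- inter_depositor_vote(led, uni, "CID", voting_strategy("III"))
    direct <- consensus(as.character(led$cid), 0.6)
    expect_identical(is.null(w), is.null(direct))
    if (!is.null(w)) {
      expect_identical(w$key, uni$k_cid[uni$cid == as.integer(direct$key)])
      expect_equal(w$fraction, direct$fraction)
    }
  }
})
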