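# Independent brute-force voting oracle.
#
# Works by direct enumeration: at every ladder level it tabulates every
# candidate key and tests the threshold with exact integer arithmetic
# (count * q >= p * total for a threshold of p/q), never touching the
# package's consensus machinery.

oracle_consensus <- function(votes, p, q) {
  if (!length(votes)) return(NULL)
  tab <- table(votes)
  hit <- as.integer(tab) * q >= p * length(votes)
  if (!any(hit)) return(NULL)
  stopifnot(sum(hit) == 1L)  # p/q > 1/2 forces a unique winner
  key <- names(tab)[hit]
  list(key = key, fraction = as.integer(tab[[key]]) / length(votes))
}

oracle_resolve <- function(assertions, keys, vote_mode, p, q) {
  lvl_col <- c(CID = "k_cid", STE = "k_ste", PCID = "k_pcid",
               PSTE = "k_pste", CON = "k_con", PCON = "k_pcon")
  deps <- unique(assertions$depositor)
  if (length(deps) == 1L && nrow(assertions) == 1L) {
    return(list(status = "singleton", level = NA_character_,
                key = NA_character_, fraction = NA_real_,
                cids = assertions$cid, sids = assertions$sid))
  }
  for (lv in names(lvl_col)) {
    kv <- keys[[lvl_col[[lv]]]][match(assertions$cid, keys$cid)]
    if (vote_mode == "multiple") {
      votes <- kv
    } else {
      votes <- character(0)
      for (d in deps) {
        w <- oracle_consensus(kv[assertions$depositor == d], p, q)
        if (!is.null(w)) votes <- c(votes, w$key)
      }
    }
    w <- oracle_consensus(votes, p, q)
    if (is.null(w)) next
    keep <- kv == w$key
    if (vote_mode == "single") {
      for (d in deps) {
        sel <- assertions$depositor == d
        wd <- oracle_consensus(kv[sel], p, q)
        if (is.null(wd) || wd$key != w$key) keep[sel] <- FALSE
      }
    }
    return(list(status = "resolved", level = lv, key = w$key,
                fraction = w$fraction,
                cids = sort(unique(assertions$cid[kv == w$key])),
                sids = sort(assertions$sid[keep])))
  }
  list(status = "discarded", level = NA_character_, key = NA_character_,
       fraction = NA_real_, cids = integer(0), sids = integer(0))
}

# strategy presets as exact rationals for the oracle
oracle_strategies <- list(
  I   = list(vote_mode = "single",   p = 3L, q = 5L),
  II  = list(vote_mode = "single",   p = 7L, q = 10L),
  III = list(vote_mode = "multiple", p = 3L, q = 5L),
  IV  = list(vote_mode = "multiple", p = 7L, q = 10L)
)

expect_matches_oracle <- function(assertions, keys, preset) {
  os <- oracle_strategies[[preset]]
  got <- resolve_synonym(assertions, keys, preset)
  want <- oracle_resolve(assertions, keys, os$vote_mode, os$p, os$q)
  expect_identical(got$status, want$status)
  expect_identical(got$level, want$level)
  if (want$status == "resolved") {
    expect_identical(got$winning_key, want$key)
    expect_equal(got$fraction, want$fraction)
  }
  expect_identical(got$cids, want$cids)
  expect_identical(got$sids, want$sids)
  invisible(NULL)
}
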