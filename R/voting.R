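#' Define a crowd-voting strategy
#'
#' A strategy fixes (1) how intra-depositor discrepancy is handled — `single`
#' (one vote per depositor, determined by an intra-depositor vote) or
#' `multiple` (every SID votes, intra-depositor discrepancy ignored) — and
#' (2) the consensus threshold. Four named presets are used in practice:
#'
#' | preset | votes per depositor | threshold |
#' |--------|--------------------|-----------|
#' | I      | single             | 60%       |
#' | II     | single             | 70%       |
#' | III    | multiple           | 60%       |
#' | IV     | multiple           | 70%       |
#'
#' Thresholds must exceed 50% so the winner is always unique.
#'
#' @param preset one of `"I"`, `"II"`, `"III"`, `"IV"`, or `NULL` to give
#'   `vote_mode` and `threshold` explicitly.
#' @param vote_mode `"single"` or `"multiple"`.
#' @param threshold consensus fraction in (0.5, 1].
#' @return an object of class `"voting_strategy"`.
#' @examples
#' voting_strategy("I")
#' voting_strategy(vote_mode = "multiple", threshold = 0.65)
#' @export
voting_strategy <- function(preset = NULL, vote_mode = NULL, threshold = NULL) {
  presets <- list(
    I   = list(vote_mode = "single",   threshold = 0.60),
    II  = list(vote_mode = "single",   threshold = 0.70),
    III = list(vote_mode = "multiple", threshold = 0.60),
    IV  = list(vote_mode = "multiple", threshold = 0.70)
  )
  if (!is.null(preset)) {
    if (inherits(preset, "voting_strategy")) return(preset)
    preset <- as.character(preset)
    if (!preset %in% names(presets)) {
      stop("unknown strategy preset; use I, II, III or IV")
    }
    p <- presets[[preset]]
    if (!is.null(vote_mode)) p$vote_mode <- vote_mode
    if (!is.null(threshold)) p$threshold <- threshold
    name <- preset
  } else {
    if (is.null(vote_mode) || is.null(threshold)) {
      stop("give a preset or both vote_mode and threshold")
    }
    p <- list(vote_mode = vote_mode, threshold = threshold)
    name <- "custom"
  }
  p$vote_mode <- match.arg(p$vote_mode, c("single", "multiple"))
  if (!is.numeric(p$threshold) || p$threshold <= 0.5 || p$threshold > 1) {
    stop("ambiguous-winner threshold: consensus threshold must be in (0.5, 1]")
  }
  structure(list(name = name, vote_mode = p$vote_mode,
                 threshold = p$threshold),
            class = "voting_strategy")
}

#' @export
print.voting_strategy <- function(x, ...) {
  cat(sprintf("Crowd-voting strategy %s: %s vote(s) per depositor, %.0f%% consensus threshold\n",
              x$name, x$vote_mode, 100 * x$threshold))
  invisible(x)
}

#' Consensus test over a vote tally
#'
#' Given a tally of votes per candidate key, returns the key holding at
#' least `threshold` of the total (inclusive comparison: 3 of 5 reaches a
#' 60% threshold, and 3 of 3 — but not 2 of 3 — reaches 70%). Because the
#' threshold exceeds one half, at most one key can qualify.
#'
#' @param tally named numeric vector of vote counts per key (or a vector of
#'   key labels, which is tabulated first).
#' @param threshold consensus fraction in (0.5, 1].
#' @return `list(key=, fraction=)`, or `NULL` when no key reaches the
#'   threshold.
#' @examples
#' consensus(c(X = 2, Y = 1), 0.60)  # X wins with 2/3
#' consensus(c(X = 2, Y = 1), 0.70)  # NULL: 70% needs 3 of 3
#' @export
consensus <- function(tally, threshold) {
  if (!is.numeric(threshold) || threshold <= 0.5 || threshold > 1) {
    stop("ambiguous-winner threshold: consensus threshold must be in (0.5, 1]")
  }
  if (is.null(names(tally))) {
    tab <- table(tally)
    tally <- as.vector(tab)
    names(tally) <- names(tab)
  }
  total <- sum(tally)
  if (total < 1L) return(NULL)
  top <- which.max(tally)
  if (.frac_ge(tally[[top]], total, threshold)) {
    return(list(key = names(tally)[top], fraction = tally[[top]] / total))
  }
  NULL
}

#' Classify a synonym's assertions into discrepancy groups A-D
#'
#' * `A` — one depositor, one SID: no discrepancy at all (bypasses voting);
#' * `B` — several depositors, one SID each: inter-depositor discrepancy
#'   possible, no intra;
#' * `C` — one depositor with several SIDs: intra-depositor only;
#' * `D` — several depositors, at least one with several SIDs: both.
#'
#' @param assertions ledger rows of one normalized name.
#' @return one of `"A"`, `"B"`, `"C"`, `"D"`.
#' @export
classify_group <- function(assertions) {
  stopifnot(nrow(assertions) >= 1L)
  per_dep <- table(assertions$depositor)
  n_dep <- length(per_dep)
  if (n_dep == 1L) {
    if (per_dep[[1L]] == 1L) "A" else "C"
  } else {
    if (all(per_dep == 1L)) "B" else "D"
  }
}

#' Intra-depositor vote of one depositor at one equivalence level
#'
#' Each of the depositor's SIDs casts one vote for its CID's key at `level`;
#' the depositor's position is the consensus key, or none when its own
#' records disagree too much (e.g. two SIDs with different keys is a 50:50
#' split, below any admissible threshold).
#'
#' @param cids CIDs of the depositor's SIDs (one entry per SID).
#' @param key_table key table covering those CIDs.
#' @param level one of [EQUIV_LEVELS].
#' @param threshold consensus fraction.
#' @return `list(key=, fraction=)` or `NULL`.
#' @export
intra_depositor_vote <- function(cids, key_table, level, threshold) {
  keys <- .keys_at(cids, key_table, level)
  consensus(keys, threshold)
}

#' Inter-depositor vote over a synonym's assertions at one level
#'
#' In `single` mode each depositor first resolves its own records with an
#' intra-depositor vote at the same threshold; depositors reaching an intra
#' consensus cast one vote each, the rest are ignored at this level (they
#' re-enter at coarser levels where their SIDs may agree). In `multiple`
#' mode every SID votes directly. The winner is then determined by
#' [consensus()] at the strategy threshold over the eligible votes.
#'
#' @param assertions ledger rows of one normalized name.
#' @param key_table key table covering the asserted CIDs.
#' @param level one of [EQUIV_LEVELS].
#' @param strategy a [voting_strategy()].
#' @return `list(key=, fraction=, voters=)` or `NULL`; `voters` is the
#'   number of eligible votes at this level.
#' @export
inter_depositor_vote <- function(assertions, key_table, level, strategy) {
  strategy <- voting_strategy(strategy)
  if (strategy$vote_mode == "multiple") {
    votes <- .keys_at(assertions$cid, key_table, level)
  } else {
    deps <- split(assertions$cid, assertions$depositor)
    votes <- character(0)
    for (d in deps) {
      w <- intra_depositor_vote(d, key_table, level, strategy$threshold)
      if (!is.null(w)) votes <- c(votes, w$key)
    }
  }
  if (!length(votes)) return(NULL)
  res <- consensus(votes, strategy$threshold)
  if (is.null(res)) return(NULL)
  res$voters <- length(votes)
  res
}

#' Resolve one synonym against the equivalence ladder
#'
#' Group A synonyms (one depositor, one SID) bypass voting and keep their
#' single CID. All others descend the ladder `CID > STE > PCID > PSTE >
#' CON > PCON`; the first level at which [inter_depositor_vote()] finds a
#' consensus wins, and the synonym keeps every asserted CID whose key at
#' that level equals the winning key. If no level yields a consensus the
#' synonym is discarded (no structure assigned).
#'
#' Category accounting distinguishes `CID-STD` — resolved at the exact level
#' with a single distinct asserted CID, i.e. structure standardization alone
#' disambiguated the name — from `CID-FILT`, resolved at the exact level by
#' an actual sub-unanimous vote.
#'
#' @param assertions ledger rows of one normalized name.
#' @param key_table key table covering the asserted CIDs.
#' @param strategy a [voting_strategy()] or preset name.
#' @return a list with `name`, `status` (`singleton` / `resolved` /
#'   `discarded`), `group`, `level`, `category`, `winning_key`, `fraction`,
#'   `cids` (retained CID set) and `sids` (retained SIDs).
#' @export
resolve_synonym <- function(assertions, key_table, strategy) {
  strategy <- voting_strategy(strategy)
  name <- assertions$name[1L]
  grp <- classify_group(assertions)
  if (grp == "A") {
    return(list(
      name = name, status = "singleton", group = grp, level = NA_character_,
      category = "GROUP_A", winning_key = NA_character_, fraction = NA_real_,
      cids = assertions$cid, sids = assertions$sid
    ))
  }
  missing <- setdiff(assertions$cid, key_table$cid)
  if (length(missing)) {
    stop(sprintf("CID(s) %s missing from key table",
                 paste(utils::head(sort(missing), 5L), collapse = ", ")))
  }
  for (level in EQUIV_LEVELS) {
    win <- inter_depositor_vote(assertions, key_table, level, strategy)
    if (is.null(win)) next
    keys <- .keys_at(assertions$cid, key_table, level)
    match_key <- keys == win$key
    cids <- sort(unique(assertions$cid[match_key]))
    keep <- match_key
    if (strategy$vote_mode == "single") {
      # drop SIDs of depositors whose own consensus differs from the winner
      for (d in unique(assertions$depositor)) {
        sel <- assertions$depositor == d
        w <- intra_depositor_vote(assertions$cid[sel], key_table, level,
                                  strategy$threshold)
        if (is.null(w) || w$key != win$key) keep[sel] <- FALSE
      }
    }
    category <- if (level == "CID") {
      if (length(unique(assertions$cid)) == 1L) "CID-STD" else "CID-FILT"
    } else level
    return(list(
      name = name, status = "resolved", group = grp, level = level,
      category = category, winning_key = win$key, fraction = win$fraction,
      cids = cids, sids = sort(assertions$sid[keep])
    ))
  }
  list(
    name = name, status = "discarded", group = grp, level = NA_character_,
    category = "DISCARDED", winning_key = NA_character_, fraction = NA_real_,
    cids = integer(0), sids = integer(0)
  )
}

# keys of a CID vector at one ladder level, with missing-CID error
.keys_at <- function(cids, key_table, level) {
  level <- match.arg(level, EQUIV_LEVELS)
  idx <- match(cids, key_table$cid)
  if (anyNA(idx)) {
    stop(sprintf("CID(s) %s missing from key table",
                 paste(utils::head(sort(unique(cids[is.na(idx)])), 5L),
                       collapse = ", ")))
  }
  key_table[[.level_cols[[level]]]][idx]
}
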