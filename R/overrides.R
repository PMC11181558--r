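#' Remove known non-chemical names before voting
#'
#' Depositors routinely submit gene/protein names, organism names (garlic,
#' ginseng, ...) or chemical class names as synonyms. Given a vocabulary of
#' such terms, every assertion whose normalized name is in the vocabulary is
#' removed from the ledger before any voting takes place. The mechanism is
#' generic: vocabularies are user supplied.
#'
#' @param ledger a ledger data.frame.
#' @param vocab character vector of terms (normalized with
#'   [normalize_name()]; un-normalized input is normalized here).
#' @return `list(ledger=, removed=)` where `removed` is the sorted vector of
#'   distinct excluded names actually present in the ledger.
#' @export
apply_vocabulary_exclusion <- function(ledger, vocab) {
  vocab <- unique(stats::na.omit(normalize_name(vocab)))
  hit <- ledger$name %in% vocab
  removed <- sort(unique(ledger$name[hit]))
  if (length(removed)) {
    message(sprintf("vocabulary exclusion removed %d assertion(s) of %d name(s)",
                    sum(hit), length(removed)))
  }
  list(ledger = ledger[!hit, , drop = FALSE], removed = removed)
}

#' Apply white/black-list overrides to resolution results
#'
#' Crowd-voting checks consistency, not accuracy: when depositors copy a
#' wrong association from each other, the crowd can confirm an error.
#' Curator overrides correct this after the fact. A whitelist entry pins a
#' name to one CID (status forced to `resolved`, category `WHITELIST`)
#' regardless of the vote; a blacklist entry bans the name outright
#' (status `discarded`, category `BLACKLIST`). Names in neither list are
#' untouched. Overrides are idempotent and independent across names.
#'
#' @param results results data.frame of a [synonym_filter()] fit.
#' @param overrides override table (see [read_overrides()]).
#' @param ledger optional ledger, used to recover the retained SIDs of a
#'   whitelisted (name, CID) pair; without it whitelisted names keep no SID.
#' @return the modified results data.frame.
#' @export
apply_overrides <- function(results, overrides, ledger = NULL) {
  stopifnot(all(c("name", "mode", "cid") %in% names(overrides)))
  conflict <- intersect(overrides$name[overrides$mode == "whitelist"],
                        overrides$name[overrides$mode == "blacklist"])
  if (length(conflict)) {
    stop(sprintf("name(s) both white- and black-listed: %s",
                 paste(utils::head(conflict, 5L), collapse = ", ")))
  }
  for (i in seq_len(nrow(overrides))) {
    j <- which(results$name == overrides$name[i])
    if (!length(j)) next
    if (overrides$mode[i] == "whitelist") {
      cid <- overrides$cid[i]
      results$status[j] <- "resolved"
      results$category[j] <- "WHITELIST"
      results$level[j] <- NA_character_
      results$winning_key[j] <- NA_character_
      results$fraction[j] <- NA_real_
      results$cids[[j]] <- cid
      results$sids[[j]] <- if (is.null(ledger)) integer(0) else
        sort(ledger$sid[ledger$name == overrides$name[i] &
                        ledger$cid == cid])
    } else {
      results$status[j] <- "discarded"
      results$category[j] <- "BLACKLIST"
      results$level[j] <- NA_character_
      results$winning_key[j] <- NA_character_
      results$fraction[j] <- NA_real_
      results$cids[[j]] <- integer(0)
      results$sids[[j]] <- integer(0)
    }
  }
  results
}
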