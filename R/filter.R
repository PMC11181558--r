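#' Crowd-voting synonym filter
#'
#' The main entry point: resolves every distinct normalized synonym of a
#' ledger against the six-level equivalence ladder under a chosen voting
#' strategy, optionally after vocabulary-based exclusion of non-chemical
#' names and before white/black-list overrides.
#'
#' Processing is fully deterministic: names are handled in lexicographic
#' order and no randomness is involved, so identical inputs give
#' byte-identical outputs.
#'
#' @param ledger a synonym ledger (see [read_synonym_ledger()]), or a path
#'   to one.
#' @param key_table a structure-key table (see [read_key_table()]), or a
#'   path to one.
#' @param strategy a [voting_strategy()] or preset name (`"I"` default).
#' @param vocab optional character vector of normalized names (or file path,
#'   see [read_vocab()]) removed from the ledger before voting.
#' @param overrides optional override table (or file path, see
#'   [read_overrides()]) applied to the results after voting.
#' @param warn_short_names if `TRUE`, warn about filtered names of five
#'   characters or fewer (acronyms are notoriously ambiguous); never removes
#'   anything.
#' @return an object of class `"synonym_filter"`: a list with
#'   * `results` — one row per distinct name: `name`, `status`, `group`,
#'     `level`, `category`, `winning_key`, `fraction`, plus list columns
#'     `cids` (retained CID set) and `sids` (retained SIDs);
#'   * `counters` — A-E accounting before/after filtering with deltas
#'     (see [filter_counters()]);
#'   * `strategy`, `n_names`, `excluded` (names removed by vocabulary),
#'     and the filtered `ledger`.
#' @examples
#' sim <- simulate_submissions(synth_config(n_names = 20, seed = 7))
#' fit <- synonym_filter(sim$ledger, sim$keys, strategy = "I")
#' summary(fit)
#' @export
synonym_filter <- function(ledger, key_table, strategy = "I",
                           vocab = NULL, overrides = NULL,
                           warn_short_names = FALSE) {
  if (is.character(ledger) && length(ledger) == 1L) {
    ledger <- read_synonym_ledger(ledger)
  }
  if (is.character(key_table) && length(key_table) == 1L) {
    key_table <- read_key_table(key_table)
  }
  ledger <- validate_ledger(ledger)
  strategy <- voting_strategy(strategy)

  excluded <- character(0)
  if (!is.null(vocab)) {
    if (is.character(vocab) && length(vocab) == 1L && file.exists(vocab)) {
      vocab <- read_vocab(vocab)
    }
    ex <- apply_vocabulary_exclusion(ledger, vocab)
    ledger <- ex$ledger
    excluded <- ex$removed
  }

  counters_before <- filter_counters(ledger)
  by_name <- split(ledger, ledger$name)
  res_list <- lapply(by_name[sort(names(by_name))], resolve_synonym,
                     key_table = key_table, strategy = strategy)
  results <- .bind_results(res_list)

  if (!is.null(overrides)) {
    if (is.character(overrides) && length(overrides) == 1L) {
      overrides <- read_overrides(overrides)
    }
    results <- apply_overrides(results, overrides, ledger)
  }

  if (warn_short_names) {
    short <- results$name[nchar(results$name) <= 5L &
                          results$status != "discarded"]
    if (length(short)) {
      warning(sprintf(
        "%d filtered name(s) have 5 characters or fewer and may be ambiguous acronyms",
        length(short)), call. = FALSE)
    }
  }

  filtered_ledger <- .restrict_ledger(ledger, results)
  counters_after <- filter_counters(filtered_ledger)

  structure(list(
    results  = results,
    counters = list(
      before = counters_before,
      after  = counters_after,
      delta  = counters_after - counters_before
    ),
    strategy = strategy,
    n_names  = nrow(results),
    excluded = excluded,
    ledger   = ledger
  ), class = "synonym_filter")
}

#' A-E accounting of a ledger
#'
#' Classifies distinct synonyms by multiplicity: `A` — names with a single
#' SID; `B` — with multiple SIDs, split into `C` (all SIDs carry one CID)
#' and `D` (several CIDs); `E = A + C` is the number of names that map to a
#' single structure; `total = A + B`. The identities `B = C + D` and
#' `E = A + C` hold by construction.
#'
#' @param ledger a ledger data.frame.
#' @return named integer vector with elements `A`, `B`, `C`, `D`, `E`,
#'   `total`.
#' @export
filter_counters <- function(ledger) {
  if (nrow(ledger) == 0L) {
    return(c(A = 0L, B = 0L, C = 0L, D = 0L, E = 0L, total = 0L))
  }
  n_sid <- tapply(ledger$sid, ledger$name, function(x) length(unique(x)))
  n_cid <- tapply(ledger$cid, ledger$name, function(x) length(unique(x)))
  a <- sum(n_sid == 1L)
  c_ <- sum(n_sid > 1L & n_cid == 1L)
  d <- sum(n_sid > 1L & n_cid > 1L)
  c(A = a, B = c_ + d, C = c_, D = d, E = a + c_, total = a + c_ + d)
}

# ledger restricted to retained SIDs per name (discarded names vanish)
.restrict_ledger <- function(ledger, results) {
  kept <- unlist(lapply(seq_len(nrow(results)), function(i) {
    paste(results$name[i], results$sids[[i]], sep = "\r")
  }))
  ledger[paste(ledger$name, ledger$sid, sep = "\r") %in% kept, , drop = FALSE]
}

.bind_results <- function(res_list) {
  if (!length(res_list)) {
    return(data.frame(
      name = character(), status = character(), group = character(),
      level = character(), category = character(),
      winning_key = character(), fraction = numeric(),
      cids = I(list()), sids = I(list()), stringsAsFactors = FALSE))
  }
  df <- data.frame(
    name        = vapply(res_list, `[[`, "", "name"),
    status      = vapply(res_list, `[[`, "", "status"),
    group       = vapply(res_list, `[[`, "", "group"),
    level       = vapply(res_list, `[[`, "", "level"),
    category    = vapply(res_list, `[[`, "", "category"),
    winning_key = vapply(res_list, `[[`, "", "winning_key"),
    fraction    = vapply(res_list, `[[`, 0.0, "fraction"),
    stringsAsFactors = FALSE
  )
  df$cids <- I(unname(lapply(res_list, `[[`, "cids")))
  df$sids <- I(unname(lapply(res_list, `[[`, "sids")))
  rownames(df) <- NULL
  df
}

#' @export
print.synonym_filter <- function(x, ...) {
  cat("Crowd-voting synonym filter\n")
  print(x$strategy)
  tab <- table(factor(x$results$status,
                      levels = c("singleton", "resolved", "discarded")))
  cat(sprintf("  %d distinct synonym(s): %d singleton, %d resolved, %d discarded\n",
              x$n_names, tab[["singleton"]], tab[["resolved"]],
              tab[["discarded"]]))
  if (length(x$excluded)) {
    cat(sprintf("  %d name(s) removed by vocabulary exclusion\n",
                length(x$excluded)))
  }
  invisible(x)
}

#' @export
summary.synonym_filter <- function(object, ...) {
  cats <- c("GROUP_A", "CID-STD", "CID-FILT", "STE", "PCID", "PSTE",
            "CON", "PCON", "WHITELIST", "BLACKLIST", "DISCARDED")
  by_cat <- table(factor(object$results$category, levels = cats))
  structure(list(
    strategy = object$strategy,
    counters = object$counters,
    by_category = by_cat,
    n_names = object$n_names,
    n_excluded = length(object$excluded)
  ), class = "summary.synonym_filter")
}

#' @export
print.summary.synonym_filter <- function(x, ...) {
  cat("Crowd-voting synonym filter\n")
  print(x$strategy)
  cat("\nSynonym counts (A = single SID, B = multiple SIDs = C + D,\n")
  cat("                C = single CID, D = multiple CIDs, E = A + C):\n")
  m <- rbind(before = x$counters$before, after = x$counters$after,
             delta = x$counters$delta)
  print(m)
  cat("\nResolution by category:\n")
  print(x$by_category)
  invisible(x)
}
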