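#' Format a share as a percentage string
#'
#' Human-readable reports print percentages at one decimal, rounded
#' half-up (so 5.75% prints as "5.8%", independent of the banker's rounding
#' of `round()`). Raw fractions are kept at full precision in JSON.
#'
#' @param numerator,denominator the counts (or any numbers on a common
#'   scale).
#' @param digits decimal places (default 1).
#' @return character vector like `"5.8%"`.
#' @examples
#' format_percent(7946214, 137555572)  # "5.8%"
#' @export
format_percent <- function(numerator, denominator, digits = 1L) {
  pct <- 100 * numerator / denominator
  scale <- 10^digits
  half_up <- floor(pct * scale + 0.5) / scale
  sprintf(paste0("%.", digits, "f%%"), half_up)
}

#' Compile the filtering and mapping reports
#'
#' Produces the standard accounting of a filtering run as one JSON-ready
#' list:
#'
#' * `counters` — the A-E synonym counts before and after filtering with
#'   deltas (identities `B = C + D`, `E = A + C` hold on every run);
#' * `by_level` — multi-SID synonyms resolved per equivalence level, with
#'   the exact level split into `Standardization` (unanimous CID before
#'   voting) and `Synonym filtering` (sub-unanimous consensus), plus the
#'   discarded count;
#' * `mesh` — MNID/CID cross counts with and without MeSH filtering (when a
#'   mapping is supplied);
#' * `top_synonyms` — the `top_k` names with the largest retained CID sets.
#'
#' The report is a pure function of the run outputs: recomputing it from
#' the same fit reproduces it exactly.
#'
#' @param fit a [synonym_filter()] fit.
#' @param mesh optional [mesh_map()] result.
#' @param top_k how many top synonyms to list (default 10).
#' @return a list; serialize with [jsonlite::write_json()]
#'   (`auto_unbox = TRUE`).
#' @export
compute_reports <- function(fit, mesh = NULL, top_k = 10L) {
  stopifnot(inherits(fit, "synonym_filter"))
  res <- fit$results
  lv <- c("CID-STD", "CID-FILT", "STE", "PCID", "PSTE", "CON", "PCON")
  # per-level accounting covers the voted (multi-SID) names, not group A
  voted <- res[res$group != "A", , drop = FALSE]
  by_level <- vapply(lv, function(k) sum(voted$category == k), 0L)
  level_tab <- c(
    CID = unname(by_level[["CID-STD"]] + by_level[["CID-FILT"]]),
    Standardization = unname(by_level[["CID-STD"]]),
    `Synonym filtering` = unname(by_level[["CID-FILT"]]),
    STE = unname(by_level[["STE"]]), PCID = unname(by_level[["PCID"]]),
    PSTE = unname(by_level[["PSTE"]]), CON = unname(by_level[["CON"]]),
    PCON = unname(by_level[["PCON"]]),
    Total = sum(by_level)
  )
  n_cids <- vapply(res$cids, length, 0L)
  ord <- order(-n_cids, res$name)
  top <- utils::head(ord[n_cids[ord] > 0L], top_k)
  rep_ <- list(
    strategy = list(name = fit$strategy$name,
                    vote_mode = fit$strategy$vote_mode,
                    threshold = fit$strategy$threshold),
    counters = list(
      before = as.list(fit$counters$before),
      after = as.list(fit$counters$after),
      delta = as.list(fit$counters$delta)
    ),
    by_level = as.list(level_tab),
    discarded = sum(res$status == "discarded"),
    excluded_by_vocabulary = length(fit$excluded),
    top_synonyms = lapply(top, function(i) {
      list(name = res$name[i], n_cids = n_cids[i],
           cids = res$cids[[i]])
    })
  )
  if (!is.null(mesh)) {
    rep_$mesh <- list(
      threshold = mesh$threshold,
      without_filter = as.list(mesh$stats$without_filter),
      with_filter = as.list(mesh$stats$with_filter)
    )
  }
  rep_
}

#' Write a report to JSON
#'
#' @param report a [compute_reports()] list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
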