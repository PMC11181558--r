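#' Build an exact-match index over MeSH terms
#'
#' Maps each normalized term (heading, entry term or registry number) to the
#' set of MeSH numeric IDs (MNIDs) that list it. A term may legitimately
#' belong to several records; duplicate (MNID, term) rows are collapsed with
#' a warning.
#'
#' @param mesh_records MeSH term table (see [read_mesh_terms()]).
#' @return an object of class `"mesh_index"` (an environment keyed by term).
#' @export
build_term_index <- function(mesh_records) {
  key <- paste(mesh_records$mnid, mesh_records$term, sep = "\r")
  ndup <- sum(duplicated(key))
  if (ndup > 0L) {
    warning(sprintf("collapsed %d duplicate (MNID, term) row(s)", ndup),
            call. = FALSE)
    mesh_records <- mesh_records[!duplicated(key), , drop = FALSE]
  }
  env <- new.env(parent = emptyenv(), hash = TRUE)
  for (i in seq_len(nrow(mesh_records))) {
    t <- mesh_records$term[i]
    env[[t]] <- c(env[[t]], mesh_records$mnid[i])
  }
  structure(list(env = env, n_terms = length(ls(env))),
            class = "mesh_index")
}

#' Look up a term in a MeSH index
#'
#' @param index a [build_term_index()] object.
#' @param term character vector of terms (normalized here for symmetry:
#'   `lookup(a) == lookup(normalize_name(a))`).
#' @return for a single term, an integer vector of MNIDs (possibly empty);
#'   for several, a list of such vectors.
#' @export
mesh_lookup <- function(index, term) {
  term <- normalize_name(term)
  one <- function(t) {
    if (is.na(t)) return(integer(0))
    v <- index$env[[t]]
    if (is.null(v)) integer(0) else sort(unique(v))
  }
  if (length(term) == 1L) one(term) else lapply(term, one)
}

#' Match filtered synonyms to MeSH records
#'
#' A compound (CID) becomes linked to a MeSH record (MNID) when any of its
#' filtered synonyms exactly matches one of the record's terms. Each link
#' carries its supporting depositors: those contributing at least one
#' retained SID of that CID under a matching synonym.
#'
#' @param results results data.frame of a [synonym_filter()] fit (or the
#'   fit itself).
#' @param ledger the ledger the fit was run on (taken from the fit when a
#'   fit is given).
#' @param index a [build_term_index()] object.
#' @return data.frame of raw links: `cid`, `mnid`, `support` (number of
#'   supporting depositors), plus list column `depositors`. Links without
#'   support are not emitted.
#' @export
match_filtered_synonyms <- function(results, index, ledger = NULL) {
  if (inherits(results, "synonym_filter")) {
    if (is.null(ledger)) ledger <- results$ledger
    results <- results$results
  }
  if (is.null(ledger)) stop("a ledger is required to attribute depositors")
  keep <- results$status != "discarded"
  triples <- list()
  for (i in which(keep)) {
    mnids <- mesh_lookup(index, results$name[i])
    if (!length(mnids)) next
    sids <- results$sids[[i]]
    if (!length(sids)) next
    rows <- ledger[ledger$sid %in% sids & ledger$name == results$name[i], ,
                   drop = FALSE]
    # only SIDs whose CID survived into the result's CID set support a link
    rows <- rows[rows$cid %in% results$cids[[i]], , drop = FALSE]
    if (!nrow(rows)) next
    for (m in mnids) {
      triples[[length(triples) + 1L]] <- data.frame(
        cid = rows$cid, mnid = m, depositor = rows$depositor,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(triples)) {
    return(data.frame(cid = integer(), mnid = integer(), support = integer(),
                      depositors = I(list()), stringsAsFactors = FALSE))
  }
  tr <- unique(do.call(rbind, triples))
  grp <- split(tr$depositor, paste(tr$cid, tr$mnid, sep = "\r"))
  ids <- strsplit(names(grp), "\r", fixed = TRUE)
  out <- data.frame(
    cid = as.integer(vapply(ids, `[[`, "", 1L)),
    mnid = as.integer(vapply(ids, `[[`, "", 2L)),
    support = vapply(grp, function(d) length(unique(d)), 0L),
    stringsAsFactors = FALSE
  )
  out$depositors <- I(lapply(grp, function(d) sort(unique(d))))
  out <- out[order(out$cid, out$mnid), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Crowd-vote filter over CID-MeSH links
#'
#' For each compound, a link to a MeSH record is retained when at least half
#' (inclusive) of the compound's eligible depositors support it. The
#' denominator is the number of distinct depositors supporting *any* link of
#' that compound — agreement is only observable among depositors expressing
#' a MeSH-linkable name. Two shares of at least one half exhaust the total,
#' so a compound keeps at most two MeSH records; the exact 50:50 tie retains
#' both.
#'
#' @param links raw links from [match_filtered_synonyms()].
#' @param threshold consensus fraction, 0.5 by default; must be in (0, 1].
#' @return the links with `denom`, `fraction` and `retained` columns added.
#' @export
mesh_filter <- function(links, threshold = 0.5) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop("MeSH consensus threshold must be in (0, 1]")
  }
  if (!nrow(links)) {
    links$denom <- integer(0); links$fraction <- numeric(0)
    links$retained <- logical(0)
    return(links)
  }
  dep_by_cid <- split(links$depositors, links$cid)
  denom_by_cid <- vapply(dep_by_cid,
                         function(dl) length(unique(unlist(dl))), 0L)
  links$denom <- denom_by_cid[as.character(links$cid)]
  links$fraction <- links$support / links$denom
  links$retained <- .frac_ge(links$support, links$denom, threshold)
  links
}

#' Map filtered synonyms to MeSH records and filter the links
#'
#' Convenience wrapper: [match_filtered_synonyms()] then [mesh_filter()],
#' returning a classed object with Table-style cross counts.
#'
#' @param fit a [synonym_filter()] fit.
#' @param mesh_records MeSH term table (see [read_mesh_terms()]), or a path.
#' @param threshold MeSH consensus fraction (default 0.5).
#' @return an object of class `"mesh_map"`: list with `links` (all columns
#'   of [mesh_filter()]), `threshold`, and `stats` — MNID/CID cross counts
#'   with and without the MeSH filter.
#' @export
mesh_map <- function(fit, mesh_records, threshold = 0.5) {
  if (is.character(mesh_records) && length(mesh_records) == 1L) {
    mesh_records <- read_mesh_terms(mesh_records)
  }
  index <- build_term_index(mesh_records)
  links <- match_filtered_synonyms(fit, index)
  links <- mesh_filter(links, threshold)
  structure(list(
    links = links,
    threshold = threshold,
    stats = mesh_link_stats(links)
  ), class = "mesh_map")
}

#' Cross counts of CID-MeSH links
#'
#' The Table-5-style accounting: number of MNIDs linked to one / several
#' CIDs and number of CIDs linked to one / several MNIDs, both before
#' ("without MeSH filtering", all links) and after (retained links only).
#'
#' @param links links data.frame with a `retained` column.
#' @return named list of two named integer vectors, `without_filter` and
#'   `with_filter`.
#' @export
mesh_link_stats <- function(links) {
  count <- function(lk) {
    if (!nrow(lk)) {
      return(c(mnids_with_cids = 0L, mnids_single_cid = 0L,
               mnids_multiple_cids = 0L, cids_with_mnids = 0L,
               cids_single_mnid = 0L, cids_multiple_mnids = 0L))
    }
    per_mnid <- table(lk$mnid)
    per_cid <- table(lk$cid)
    c(mnids_with_cids = length(per_mnid),
      mnids_single_cid = sum(per_mnid == 1L),
      mnids_multiple_cids = sum(per_mnid > 1L),
      cids_with_mnids = length(per_cid),
      cids_single_mnid = sum(per_cid == 1L),
      cids_multiple_mnids = sum(per_cid > 1L))
  }
  list(without_filter = count(links),
       with_filter = count(links[links$retained, , drop = FALSE]))
}

#' @export
print.mesh_map <- function(x, ...) {
  cat(sprintf("CID-MeSH mapping (consensus threshold %.0f%%)\n",
              100 * x$threshold))
  cat(sprintf("  %d raw link(s), %d retained\n",
              nrow(x$links), sum(x$links$retained)))
  s <- x$stats$with_filter
  cat(sprintf("  after filtering: %d CID(s) linked, %d with multiple MeSH records\n",
              s[["cids_with_mnids"]], s[["cids_multiple_mnids"]]))
  invisible(x)
}
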