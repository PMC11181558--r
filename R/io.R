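#' Read a synonym ledger
#'
#' A ledger is the vote record: one row per depositor-provided
#' (synonym, SID, CID) association. The canonical on-disk form is UTF-8 TSV
#' with header `SYNONYM`, `DEPOSITOR`, `SID`, `CID` (chemical names routinely
#' contain commas, so TSV, not CSV).
#'
#' On read, names are normalized with [normalize_name()]; rows whose name is
#' empty after normalization are dropped with a warning; duplicated
#' (normalized name, SID) rows collapse to a single assertion (a vote unit is
#' an association, not a file row) with the collapsed count reported in a
#' warning. Two invariants are enforced: every SID maps to exactly one CID
#' and to exactly one depositor — a violation is a hard error, since a SID is
#' one depositor's record of one standardized structure.
#'
#' @param path file path to the TSV ledger.
#' @return a `data.frame` with columns `raw_name`, `name` (normalized),
#'   `depositor`, `sid`, `cid`.
#' @seealso [write_filtered_output()], [read_key_table()]
#' @export
read_synonym_ledger <- function(path) {
  df <- .read_tsv(path, c("SYNONYM", "DEPOSITOR", "SID", "CID"))
  led <- data.frame(
    raw_name  = df$SYNONYM,
    name      = NA_character_,
    depositor = as.character(df$DEPOSITOR),
    sid       = .as_id(df$SID, "SID", path),
    cid       = .as_id(df$CID, "CID", path),
    stringsAsFactors = FALSE
  )
  led$name <- normalize_name(led$raw_name)
  bad <- is.na(led$name)
  if (any(bad)) {
    warning(sprintf("dropped %d row(s) with empty synonym in %s",
                    sum(bad), path), call. = FALSE)
    led <- led[!bad, , drop = FALSE]
  }
  validate_ledger(led)
}

#' Validate (and deduplicate) an in-memory ledger
#'
#' @param ledger data.frame with columns `name`, `depositor`, `sid`, `cid`
#'   (`raw_name` optional).
#' @return the ledger with duplicate (name, sid) rows collapsed, rows ordered
#'   by (name, depositor, sid).
#' @export
validate_ledger <- function(ledger) {
  stopifnot(is.data.frame(ledger),
            all(c("name", "depositor", "sid", "cid") %in% names(ledger)))
  if (!"raw_name" %in% names(ledger)) ledger$raw_name <- ledger$name
  # SID -> CID and SID -> depositor must be functions
  u <- unique(ledger[c("sid", "cid")])
  dup <- u$sid[duplicated(u$sid)]
  if (length(dup)) {
    stop(sprintf("ledger inconsistent: SID(s) %s mapped to multiple CIDs",
                 paste(utils::head(sort(unique(dup)), 5L), collapse = ", ")))
  }
  ud <- unique(ledger[c("sid", "depositor")])
  dupd <- ud$sid[duplicated(ud$sid)]
  if (length(dupd)) {
    stop(sprintf("ledger inconsistent: SID(s) %s carried by multiple depositors",
                 paste(utils::head(sort(unique(dupd)), 5L), collapse = ", ")))
  }
  key <- paste(ledger$name, ledger$sid, sep = "\r")
  ndup <- sum(duplicated(key))
  if (ndup > 0L) {
    warning(sprintf("collapsed %d duplicate (name, SID) row(s)", ndup),
            call. = FALSE)
    ledger <- ledger[!duplicated(key), , drop = FALSE]
  }
  ledger <- ledger[order(ledger$name, ledger$depositor, ledger$sid), ,
                   drop = FALSE]
  rownames(ledger) <- NULL
  ledger
}

#' Read a structure-key table
#'
#' One row per CID with its six equivalence keys, header
#' `CID`, `K_CID`, `K_STE`, `K_PCID`, `K_PSTE`, `K_CON`, `K_PCON`.
#' Keys are opaque tokens; the table's nesting coherence can be checked with
#' [validate_key_nesting()] (reading performs the uniqueness check only).
#'
#' @param path file path.
#' @param check if `TRUE` (default) fail on any nesting violation.
#' @return data.frame with columns `cid`, `k_cid`, `k_ste`, `k_pcid`,
#'   `k_pste`, `k_con`, `k_pcon`.
#' @export
read_key_table <- function(path, check = TRUE) {
  hdr <- c("CID", "K_CID", "K_STE", "K_PCID", "K_PSTE", "K_CON", "K_PCON")
  df <- .read_tsv(path, hdr)
  keys <- data.frame(
    cid    = .as_id(df$CID, "CID", path),
    k_cid  = as.character(df$K_CID),
    k_ste  = as.character(df$K_STE),
    k_pcid = as.character(df$K_PCID),
    k_pste = as.character(df$K_PSTE),
    k_con  = as.character(df$K_CON),
    k_pcon = as.character(df$K_PCON),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(keys$cid)) stop("duplicate CID row(s) in key table")
  if (check) {
    v <- validate_key_nesting(keys)
    if (nrow(v)) {
      stop(sprintf("key table violates nesting (%d violation(s)); first: %s",
                   nrow(v), v$detail[1L]))
    }
  }
  keys
}

#' Read a covalent-unit component table
#'
#' One row per unit occurrence of a (possibly multicomponent) structure,
#' header `CID`, `UNIT_KEY_CID`, `UNIT_KEY_STE`, `UNIT_KEY_CON`,
#' `HEAVY_ATOMS`, `HAS_CARBON`, `MULTIPLICITY`. Used by
#' [select_parent_unit()] / [build_key_set()].
#'
#' @param path file path.
#' @return data.frame with columns `cid`, `unit_key_cid`, `unit_key_ste`,
#'   `unit_key_con`, `heavy_atoms`, `has_carbon`, `multiplicity`.
#' @export
read_component_table <- function(path) {
  hdr <- c("CID", "UNIT_KEY_CID", "UNIT_KEY_STE", "UNIT_KEY_CON",
           "HEAVY_ATOMS", "HAS_CARBON", "MULTIPLICITY")
  df <- .read_tsv(path, hdr)
  data.frame(
    cid          = .as_id(df$CID, "CID", path),
    unit_key_cid = as.character(df$UNIT_KEY_CID),
    unit_key_ste = as.character(df$UNIT_KEY_STE),
    unit_key_con = as.character(df$UNIT_KEY_CON),
    heavy_atoms  = as.integer(df$HEAVY_ATOMS),
    has_carbon   = .as_flag(df$HAS_CARBON),
    multiplicity = as.integer(df$MULTIPLICITY),
    stringsAsFactors = FALSE
  )
}

#' Read a MeSH term table
#'
#' Header `MNID`, `MESH_UID`, `TERM`, `KIND` with `KIND` one of
#' `heading`, `entry`, `registry`. Terms are normalized with
#' [normalize_name()] on read so matching against filtered synonyms is
#' normalization-symmetric.
#'
#' @param path file path.
#' @return data.frame with columns `mnid`, `mesh_uid`, `term`, `kind`.
#' @export
read_mesh_terms <- function(path) {
  df <- .read_tsv(path, c("MNID", "MESH_UID", "TERM", "KIND"))
  kind <- tolower(as.character(df$KIND))
  ok <- kind %in% c("heading", "entry", "registry")
  if (!all(ok)) {
    stop(sprintf("invalid term kind '%s' in %s", kind[!ok][1L], path))
  }
  data.frame(
    mnid     = as.integer(df$MNID),
    mesh_uid = as.character(df$MESH_UID),
    term     = normalize_name(df$TERM),
    kind     = kind,
    stringsAsFactors = FALSE
  )
}

#' Read an override (white/black-list) table
#'
#' Header `NAME`, `MODE`, `CID`; `MODE` is `whitelist` (pins the name to the
#' given CID) or `blacklist` (bans the name; CID column empty or 0).
#'
#' @param path file path.
#' @return data.frame with columns `name` (normalized), `mode`, `cid`
#'   (`NA` for blacklist entries).
#' @export
read_overrides <- function(path) {
  df <- .read_tsv(path, c("NAME", "MODE", "CID"))
  mode <- tolower(as.character(df$MODE))
  if (!all(mode %in% c("whitelist", "blacklist"))) {
    stop("override MODE must be 'whitelist' or 'blacklist'")
  }
  cid <- suppressWarnings(as.integer(df$CID))
  cid[!is.na(cid) & cid == 0L] <- NA_integer_
  if (any(mode == "whitelist" & is.na(cid))) {
    stop("whitelist entries must carry a CID")
  }
  cid[mode == "blacklist"] <- NA_integer_
  out <- data.frame(
    name = normalize_name(df$NAME),
    mode = mode,
    cid  = cid,
    stringsAsFactors = FALSE
  )
  conflict <- intersect(out$name[out$mode == "whitelist"],
                        out$name[out$mode == "blacklist"])
  if (length(conflict)) {
    stop(sprintf("name(s) both white- and black-listed: %s",
                 paste(utils::head(conflict, 5L), collapse = ", ")))
  }
  out
}

#' Read a vocabulary exclusion list
#'
#' Plain text, one term per line; blank lines and `#` comments ignored.
#' Terms are normalized on read.
#'
#' @param path file path.
#' @return character vector of normalized terms (unique).
#' @export
read_vocab <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  unique(normalize_name(lines))
}

#' Write per-synonym resolution results
#'
#' Deterministic TSV sorted by normalized name, columns `SYNONYM`, `STATUS`,
#' `LEVEL`, `WINNING_KEY`, `CIDS` (ascending, semicolon-joined), `FRACTION`
#' (six decimals). Byte-identical across runs on identical input.
#'
#' @param results the `results` data.frame of a [synonym_filter()] fit (or
#'   the fit itself).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_filtered_output <- function(results, path) {
  if (inherits(results, "synonym_filter")) results <- results$results
  res <- results[order(results$name), , drop = FALSE]
  out <- data.frame(
    SYNONYM     = res$name,
    STATUS      = res$status,
    LEVEL       = ifelse(is.na(res$level), "", res$level),
    WINNING_KEY = ifelse(is.na(res$winning_key), "", res$winning_key),
    CIDS        = vapply(res$cids, function(x)
                         paste(sort(unique(x)), collapse = ";"), ""),
    FRACTION    = ifelse(is.na(res$fraction), "",
                         sprintf("%.6f", res$fraction)),
    stringsAsFactors = FALSE
  )
  .write_tsv(out, path)
}

#' Write CID-MeSH links
#'
#' Deterministic TSV sorted by (CID, MNID), columns `CID`, `MNID`, `SUPPORT`,
#' `DENOM`, `FRACTION`, `RETAINED`.
#'
#' @param links links data.frame from [mesh_map()] / [mesh_filter()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mesh_links <- function(links, path) {
  if (inherits(links, "mesh_map")) links <- links$links
  lk <- links[order(links$cid, links$mnid), , drop = FALSE]
  out <- data.frame(
    CID      = lk$cid,
    MNID     = lk$mnid,
    SUPPORT  = lk$support,
    DENOM    = lk$denom,
    FRACTION = sprintf("%.6f", lk$fraction),
    RETAINED = ifelse(lk$retained, "1", "0"),
    stringsAsFactors = FALSE
  )
  .write_tsv(out, path)
}

#' Write a ledger back to TSV
#'
#' Inverse of [read_synonym_ledger()]: writing then reading reproduces the
#' same multiset of assertions (raw names are written normalized).
#'
#' @param ledger ledger data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_synonym_ledger <- function(ledger, path) {
  out <- data.frame(
    SYNONYM   = ledger$name,
    DEPOSITOR = ledger$depositor,
    SID       = ledger$sid,
    CID       = ledger$cid,
    stringsAsFactors = FALSE
  )
  .write_tsv(out, path)
}

#' @keywords internal
.write_key_table <- function(keys, path) {
  out <- data.frame(
    CID = keys$cid, K_CID = keys$k_cid, K_STE = keys$k_ste,
    K_PCID = keys$k_pcid, K_PSTE = keys$k_pste,
    K_CON = keys$k_con, K_PCON = keys$k_pcon,
    stringsAsFactors = FALSE
  )
  .write_tsv(out, path)
}

.write_component_table <- function(comp, path) {
  out <- data.frame(
    CID = comp$cid, UNIT_KEY_CID = comp$unit_key_cid,
    UNIT_KEY_STE = comp$unit_key_ste, UNIT_KEY_CON = comp$unit_key_con,
    HEAVY_ATOMS = comp$heavy_atoms,
    HAS_CARBON = ifelse(comp$has_carbon, "1", "0"),
    MULTIPLICITY = comp$multiplicity,
    stringsAsFactors = FALSE
  )
  .write_tsv(out, path)
}

.write_mesh_terms <- function(mesh, path) {
  out <- data.frame(
    MNID = mesh$mnid, MESH_UID = mesh$mesh_uid,
    TERM = mesh$term, KIND = mesh$kind,
    stringsAsFactors = FALSE
  )
  .write_tsv(out, path)
}

# --- low-level helpers -------------------------------------------------------

.read_tsv <- function(path, expected_header) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                      colClasses = "character", check.names = FALSE,
                      comment.char = "", fileEncoding = "UTF-8",
                      fill = FALSE),
    # read.delim's message carries the offending line number
    error = function(e) stop(sprintf("cannot parse %s: %s",
                                     path, conditionMessage(e)))
  )
  if (!identical(names(df), expected_header)) {
    stop(sprintf("%s: expected header %s, found %s", path,
                 paste(expected_header, collapse = "\t"),
                 paste(names(df), collapse = "\t")))
  }
  df
}

.as_id <- function(x, what, path) {
  v <- suppressWarnings(as.integer(x))
  bad <- which(is.na(v) | v <= 0L)
  if (length(bad)) {
    stop(sprintf("%s: malformed %s '%s' at data row %d",
                 path, what, x[bad[1L]], bad[1L]))
  }
  v
}

.as_flag <- function(x) {
  v <- tolower(as.character(x))
  out <- v %in% c("1", "true", "t", "yes")
  bad <- !v %in% c("1", "true", "t", "yes", "0", "false", "f", "no")
  if (any(bad)) stop(sprintf("malformed boolean '%s'", v[bad][1L]))
  out
}

.write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con, sep = "\n")
  if (nrow(df)) {
    lines <- do.call(paste, c(unname(as.list(df)), sep = "\t"))
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}
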