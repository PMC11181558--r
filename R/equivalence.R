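#' Select the parent covalent unit of a multicomponent structure
#'
#' Salts and mixtures are deposited as multicomponent structures; the parent
#' compound is their chemically important part. A unit qualifies as parent
#' when it contains at least one carbon atom and carries at least 70% of the
#' heavy (non-hydrogen) atoms summed over the *unique* covalent units —
#' stoichiometric multiplicity is ignored, so a 2:1 salt counts its
#' counterion once. Because 0.70 + 0.70 > 1, at most one unit can qualify.
#'
#' @param inventory data.frame of covalent units of one structure, columns
#'   `unit_key_cid`, `unit_key_ste`, `unit_key_con`, `heavy_atoms`,
#'   `has_carbon` (and optionally `multiplicity`, ignored here).
#' @return the one-row data.frame of the qualifying unit, or `NULL` when no
#'   unit qualifies (e.g. a 50:50 mixture of two organics).
#' @examples
#' salt <- data.frame(
#'   unit_key_cid = c("acetate", "Ca", "acetate"),
#'   unit_key_ste = c("acetate", "Ca", "acetate"),
#'   unit_key_con = c("acetate", "Ca", "acetate"),
#'   heavy_atoms = c(4L, 1L, 4L), has_carbon = c(TRUE, FALSE, TRUE))
#' select_parent_unit(salt)$unit_key_cid  # "acetate": 4 of 5 heavy atoms
#' @export
select_parent_unit <- function(inventory) {
  stopifnot(is.data.frame(inventory), nrow(inventory) >= 1L)
  uni <- inventory[!duplicated(inventory$unit_key_cid), , drop = FALSE]
  h_total <- sum(uni$heavy_atoms)
  if (h_total <= 0L) stop("no heavy atoms in inventory")
  ok <- uni$has_carbon & .frac_ge(uni$heavy_atoms, h_total, 0.70)
  if (!any(ok)) return(NULL)
  if (sum(ok) > 1L) stop("internal: multiple qualifying parent units")
  uni[which(ok), , drop = FALSE]
}

#' Build the six-level key set of one compound
#'
#' Combines the full-structure keys (exact/stereo/connectivity) with the
#' parent-compound keys derived from the covalent-unit inventory. When the
#' structure is single-component, has no inventory, or no unit passes the
#' parent rule, the parent-level keys fall back to the full-structure keys,
#' so parent-level voting degenerates to the corresponding full-structure
#' level instead of abstaining.
#'
#' @param cid compound identifier (positive integer).
#' @param k_cid,k_ste,k_con full-structure keys at the exact, stereo and
#'   connectivity granularities.
#' @param inventory optional covalent-unit data.frame
#'   (see [select_parent_unit()]).
#' @return one-row data.frame with columns `cid`, `k_cid`, `k_ste`,
#'   `k_pcid`, `k_pste`, `k_con`, `k_pcon`.
#' @export
build_key_set <- function(cid, k_cid, k_ste, k_con, inventory = NULL) {
  parent <- NULL
  if (!is.null(inventory) && nrow(inventory) > 1L ||
      (!is.null(inventory) &&
       length(unique(inventory$unit_key_cid)) > 1L)) {
    parent <- select_parent_unit(inventory)
  }
  if (is.null(parent)) {
    pk <- c(k_cid, k_ste, k_con)
  } else {
    pk <- c(parent$unit_key_cid, parent$unit_key_ste, parent$unit_key_con)
  }
  data.frame(
    cid = as.integer(cid),
    k_cid = k_cid, k_ste = k_ste,
    k_pcid = pk[1L], k_pste = pk[2L],
    k_con = k_con, k_pcon = pk[3L],
    stringsAsFactors = FALSE
  )
}

#' Check the nesting coherence of a key table
#'
#' The six keys of a compound are not independent: isotope-resolved identity
#' refines stereo identity refines connectivity (same for the parent keys),
#' and a shared full-structure key forces a shared parent key at the same
#' granularity. Concretely, for any two rows: equal `k_cid` implies equal
#' `k_ste` implies equal `k_con`; equal `k_pcid` implies equal `k_pste`
#' implies equal `k_pcon`; equal `k_cid`/`k_ste`/`k_con` imply equal
#' `k_pcid`/`k_pste`/`k_pcon` respectively. In addition `k_cid` must be
#' unique per CID (two distinct standardized structures can never share
#' connectivity, stereochemistry and isotopes).
#'
#' Violations are data, not exceptions: the return value is a (possibly
#' empty) data.frame describing each offending implication.
#'
#' @param keys a key table as returned by [read_key_table()].
#' @return data.frame with columns `rule`, `key`, `detail`; zero rows when
#'   the table is coherent.
#' @export
validate_key_nesting <- function(keys) {
  viol <- list()
  add <- function(rule, key, detail) {
    viol[[length(viol) + 1L]] <<- data.frame(
      rule = rule, key = key, detail = detail, stringsAsFactors = FALSE)
  }
  dup <- unique(keys$k_cid[duplicated(keys$k_cid)])
  for (k in dup) {
    add("CID-unique", k,
        sprintf("k_cid '%s' shared by CIDs %s", k,
                paste(sort(keys$cid[keys$k_cid == k]), collapse = ",")))
  }
  implies <- function(finer, coarser, rule) {
    # every finer key must map to exactly one coarser key
    m <- unique(data.frame(f = keys[[finer]], c = keys[[coarser]],
                           stringsAsFactors = FALSE))
    bad <- unique(m$f[duplicated(m$f)])
    for (k in bad) {
      add(rule, k,
          sprintf("%s '%s' maps to several %s values: %s",
                  finer, k, coarser,
                  paste(sort(unique(m$c[m$f == k])), collapse = ",")))
    }
  }
  implies("k_cid",  "k_ste",  "CID=>STE")
  implies("k_ste",  "k_con",  "STE=>CON")
  implies("k_pcid", "k_pste", "PCID=>PSTE")
  implies("k_pste", "k_pcon", "PSTE=>PCON")
  implies("k_cid",  "k_pcid", "CID=>PCID")
  implies("k_ste",  "k_pste", "STE=>PSTE")
  implies("k_con",  "k_pcon", "CON=>PCON")
  if (!length(viol)) {
    return(data.frame(rule = character(), key = character(),
                      detail = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, viol)
}

#' Assemble a key table from full keys and a component table
#'
#' Applies [build_key_set()] to every CID of `full_keys`, looking up its
#' covalent units in `components` (CIDs absent from the component table are
#' treated as single-component).
#'
#' @param full_keys data.frame with columns `cid`, `k_cid`, `k_ste`, `k_con`.
#' @param components component table (see [read_component_table()]), or
#'   `NULL`.
#' @return a full key table (see [read_key_table()]).
#' @export
build_key_table <- function(full_keys, components = NULL) {
  comp_split <- if (is.null(components)) list() else
    split(components, components$cid)
  rows <- lapply(seq_len(nrow(full_keys)), function(i) {
    cid <- full_keys$cid[i]
    build_key_set(cid, full_keys$k_cid[i], full_keys$k_ste[i],
                  full_keys$k_con[i], comp_split[[as.character(cid)]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
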