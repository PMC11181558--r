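# In-code fixture builders shared across test files.

# quick ledger: vectors recycled, validated (collapses dups, sorts)
mk_ledger <- function(name, depositor, sid, cid) {
  suppressWarnings(validate_ledger(data.frame(
    raw_name = name, name = name, depositor = depositor,
    sid = as.integer(sid), cid = as.integer(cid),
    stringsAsFactors = FALSE)))
}

# key table with controllable grouping; defaults give all-distinct keys at
# every level (nesting holds trivially). `ste`/`con` give group labels:
# cids sharing a label share that key. Parent keys default to the full keys.
mk_keys <- function(cid, ste = NULL, con = NULL,
                    pcid = NULL, pste = NULL, pcon = NULL) {
  cid <- as.integer(cid)
  k_cid <- paste0("I", cid)
  k_ste <- if (is.null(ste)) k_cid else paste0("S", ste)
  k_con <- if (is.null(con)) k_ste else paste0("C", con)
  k_pcid <- if (is.null(pcid)) k_cid else paste0("PI", pcid)
  k_pste <- if (is.null(pste)) {
    if (is.null(pcid)) k_ste else k_pcid
  } else paste0("PS", pste)
  k_pcon <- if (is.null(pcon)) {
    if (is.null(pcid) && is.null(pste)) k_con else k_pste
  } else paste0("PC", pcon)
  data.frame(cid = cid, k_cid = k_cid, k_ste = k_ste, k_pcid = k_pcid,
             k_pste = k_pste, k_con = k_con, k_pcon = k_pcon,
             stringsAsFactors = FALSE)
}

# a small fixed nested universe for randomized voting tests:
# 4 connectivity families x 2 stereo x 2 isotopes = 16 CIDs
small_universe <- function() {
  grid <- expand.grid(iso = 1:2, ste = 1:2, fam = 1:4)
  cid <- seq_len(nrow(grid))
  data.frame(
    cid = cid,
    k_cid = sprintf("I%d.%d.%d", grid$fam, grid$ste, grid$iso),
    k_ste = sprintf("S%d.%d", grid$fam, grid$ste),
    k_pcid = sprintf("I%d.%d.%d", grid$fam, grid$ste, grid$iso),
    k_pste = sprintf("S%d.%d", grid$fam, grid$ste),
    k_con = sprintf("C%d", grid$fam),
    k_pcon = sprintf("C%d", grid$fam),
    stringsAsFactors = FALSE)
}

# random small voting instance over the fixed universe:
# <= 6 depositors, each with 1..3 SIDs
random_instance <- function(seed, universe = small_universe()) {
  set.seed(seed)
  n_dep <- sample(1:6, 1L)
  dep <- character(0); sid <- integer(0); cid <- integer(0)
  s <- 0L
  for (d in seq_len(n_dep)) {
    k <- sample(1:3, 1L)
    for (j in seq_len(k)) {
      s <- s + 1L
      dep <- c(dep, sprintf("D%02d", d))
      sid <- c(sid, s)
      cid <- c(cid, sample(universe$cid, 1L))
    }
  }
  mk_ledger("X", dep, sid, cid)
}
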