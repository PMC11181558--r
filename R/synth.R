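#' Configuration of the synthetic submission generator
#'
#' Describes a simulated depositor ecosystem: a structure universe (nested
#' connectivity/stereo/isotope families plus salt and mixture forms) and a
#' ledger of depositor submissions with a planted consensus structure per
#' name and controlled discrepancy.
#'
#' Defaults emulate the qualitative regime reported for depositor-provided
#' names in a large public compound database: most contested names have few
#' contributors (1-6 depositors, 1-2 records each), a planted majority share
#' of 0.7, intra-depositor discrepancy rarer than inter-depositor
#' discrepancy.
#'
#' @param n_names number of distinct synonyms to generate.
#' @param n_depositors size of the depositor pool.
#' @param depositors_per_name integer range `c(lo, hi)`; each name draws its
#'   contributor count uniformly from it.
#' @param sids_per_depositor integer range; each name draws one per-depositor
#'   SID count from it (all depositors of a name submit the same number of
#'   records, so vote shares are identical under both vote modes).
#' @param intra_discrepancy_rate probability that a multi-SID depositor of a
#'   dissenting name is internally inconsistent (one of its SIDs replaced by
#'   the dissent structure).
#' @param inter_discrepancy_rate probability that a multi-depositor name has
#'   dissenting depositors at all.
#' @param planted_majority_share fraction in (0.5, 1] of depositors planted
#'   on the consensus structure (rounded up).
#' @param dissent where dissenting votes live: `"unrelated"` (different
#'   connectivity family — resolvable only at the exact level),
#'   `"isotope"` (isotope sibling, same stereo — resolves at the stereo
#'   level when the exact level fails), `"stereo"` (stereo sibling, same
#'   connectivity — resolves at the connectivity level when finer levels
#'   fail), or `"mixed"` (drawn uniformly per name).
#' @param n_families number of connectivity families in the universe.
#' @param stereo_per_family,isotopes_per_stereo variants per family.
#' @param salt_fraction fraction of families that also get two salt forms
#'   (multicomponent, parent rule satisfied at >= 70% heavy atoms).
#' @param mixture_fraction fraction of families that get one mixture form
#'   with no qualifying parent (two organic units near 50:50).
#' @param seed integer seed; all generator output is a pure function of the
#'   configuration including the seed.
#' @return an object of class `"synth_config"`.
#' @export
synth_config <- function(n_names = 200L,
                         n_depositors = 25L,
                         depositors_per_name = c(1L, 6L),
                         sids_per_depositor = c(1L, 2L),
                         intra_discrepancy_rate = 0.1,
                         inter_discrepancy_rate = 0.3,
                         planted_majority_share = 0.7,
                         dissent = c("unrelated", "isotope", "stereo", "mixed"),
                         n_families = 40L,
                         stereo_per_family = 2L,
                         isotopes_per_stereo = 2L,
                         salt_fraction = 0.2,
                         mixture_fraction = 0.05,
                         seed = 1L) {
  dissent <- match.arg(dissent)
  cfg <- list(
    n_names = as.integer(n_names),
    n_depositors = as.integer(n_depositors),
    depositors_per_name = as.integer(depositors_per_name),
    sids_per_depositor = as.integer(sids_per_depositor),
    intra_discrepancy_rate = intra_discrepancy_rate,
    inter_discrepancy_rate = inter_discrepancy_rate,
    planted_majority_share = planted_majority_share,
    dissent = dissent,
    n_families = as.integer(n_families),
    stereo_per_family = as.integer(stereo_per_family),
    isotopes_per_stereo = as.integer(isotopes_per_stereo),
    salt_fraction = salt_fraction,
    mixture_fraction = mixture_fraction,
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_names >= 1L, cfg$n_depositors >= 1L,
    length(cfg$depositors_per_name) == 2L,
    cfg$depositors_per_name[1L] >= 1L,
    cfg$depositors_per_name[2L] >= cfg$depositors_per_name[1L],
    cfg$depositors_per_name[2L] <= cfg$n_depositors,
    length(cfg$sids_per_depositor) == 2L,
    cfg$sids_per_depositor[1L] >= 1L,
    cfg$sids_per_depositor[2L] >= cfg$sids_per_depositor[1L],
    cfg$intra_discrepancy_rate >= 0, cfg$intra_discrepancy_rate <= 1,
    cfg$inter_discrepancy_rate >= 0, cfg$inter_discrepancy_rate <= 1,
    cfg$planted_majority_share > 0.5, cfg$planted_majority_share <= 1,
    cfg$stereo_per_family >= 1L, cfg$isotopes_per_stereo >= 1L,
    cfg$salt_fraction >= 0, cfg$salt_fraction <= 1,
    cfg$mixture_fraction >= 0, cfg$mixture_fraction <= 1
  )
  if (cfg$n_families < 1L) stop("degenerate config: need at least 1 family")
  if (cfg$dissent %in% c("isotope", "mixed") && cfg$isotopes_per_stereo < 2L) {
    stop("isotope dissent requires isotopes_per_stereo >= 2")
  }
  if (cfg$dissent %in% c("stereo", "mixed") && cfg$stereo_per_family < 2L) {
    stop("stereo dissent requires stereo_per_family >= 2")
  }
  if (cfg$dissent %in% c("unrelated", "mixed") && cfg$n_families < 2L) {
    stop("unrelated dissent requires at least 2 families")
  }
  structure(cfg, class = "synth_config")
}

#' Generate a nested structure universe
#'
#' Keys are generated as a tree (connectivity family -> stereo variant ->
#' isotope variant), so the ladder nesting invariants hold by construction.
#' A fraction of families additionally receive salt forms (unique
#' full-structure keys, parent keys equal to the family base variant's keys,
#' with a carbon-bearing unit holding at least 70% of the heavy atoms) and
#' mixture forms (two organic units near 50:50 — no qualifying parent, so
#' the parent keys fall back to the mixture's own full keys). Parent keys
#' are derived through [build_key_table()], i.e. by the same parent rule the
#' filter itself uses.
#'
#' @param config a [synth_config()].
#' @return list with `keys` (key table), `components` (covalent-unit
#'   table) and `catalog` (per-CID provenance: `cid`, `family`, `stereo`,
#'   `iso`, `kind` in mono/salt/mixture).
#' @export
generate_structure_universe <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  fam_heavy <- sample(8:40, config$n_families, replace = TRUE)
  full <- list(); comp <- list(); cat_ <- list()
  cid <- 0L
  add <- function(k_cid, k_ste, k_con, units, family, stereo, iso, kind) {
    cid <<- cid + 1L
    full[[length(full) + 1L]] <<- data.frame(
      cid = cid, k_cid = k_cid, k_ste = k_ste, k_con = k_con,
      stringsAsFactors = FALSE)
    units$cid <- cid
    comp[[length(comp) + 1L]] <<- units
    cat_[[length(cat_) + 1L]] <<- data.frame(
      cid = cid, family = family, stereo = stereo, iso = iso, kind = kind,
      stringsAsFactors = FALSE)
  }
  unit_row <- function(kc, ks, kn, heavy, carbon, mult = 1L) {
    data.frame(unit_key_cid = kc, unit_key_ste = ks, unit_key_con = kn,
               heavy_atoms = as.integer(heavy), has_carbon = carbon,
               multiplicity = as.integer(mult), stringsAsFactors = FALSE)
  }
  for (f in seq_len(config$n_families)) {
    k_con <- sprintf("CON%04d", f)
    for (s in seq_len(config$stereo_per_family)) {
      k_ste <- sprintf("STE%04d.%d", f, s)
      for (i in seq_len(config$isotopes_per_stereo)) {
        k_cid <- sprintf("ISO%04d.%d.%d", f, s, i)
        add(k_cid, k_ste, k_con,
            unit_row(k_cid, k_ste, k_con, fam_heavy[f], TRUE),
            f, s, i, "mono")
      }
    }
  }
  n_salt_fam <- floor(config$salt_fraction * config$n_families)
  for (f in seq_len(n_salt_fam)) {
    h <- fam_heavy[f]
    ion_h <- max(1L, as.integer(floor(3 * h / 7)))  # keeps parent >= 70%
    for (j in 1:2) {
      org <- unit_row(sprintf("ISO%04d.1.1", f), sprintf("STE%04d.1", f),
                      sprintf("CON%04d", f), h, TRUE)
      ion <- unit_row(sprintf("IONC%04d.%d", f, j),
                      sprintf("IONS%04d.%d", f, j),
                      sprintf("IONN%04d.%d", f, j), ion_h, FALSE, j)
      add(sprintf("SALT%04d.%d", f, j), sprintf("SSTE%04d.%d", f, j),
          sprintf("SCON%04d.%d", f, j), rbind(org, ion), f, NA_integer_,
          NA_integer_, "salt")
    }
  }
  n_mix_fam <- floor(config$mixture_fraction * config$n_families)
  for (f in seq_len(n_mix_fam)) {
    u1 <- unit_row(sprintf("MIXA%04d", f), sprintf("MIXAS%04d", f),
                   sprintf("MIXAN%04d", f), 10L, TRUE)
    u2 <- unit_row(sprintf("MIXB%04d", f), sprintf("MIXBS%04d", f),
                   sprintf("MIXBN%04d", f), 9L, TRUE)
    add(sprintf("MIX%04d", f), sprintf("MIXS%04d", f), sprintf("MIXN%04d", f),
        rbind(u1, u2), f, NA_integer_, NA_integer_, "mixture")
  }
  full <- do.call(rbind, full)
  components <- do.call(rbind, comp)
  keys <- build_key_table(full, components)
  list(keys = keys, components = components,
       catalog = do.call(rbind, cat_))
}

#' Generate a depositor ledger with planted ground truth
#'
#' Each synonym gets a planted consensus structure (a single-component CID).
#' With probability `inter_discrepancy_rate` a multi-depositor name receives
#' dissenting depositors: `ceiling(planted_majority_share * n_depositors)`
#' depositors assert the planted CID, the rest assert a dissent CID chosen
#' per the configured dissent placement. Dissenting names may additionally
#' have internally inconsistent depositors (see `intra_discrepancy_rate`).
#' Given a fixed configuration the output is byte-identical across calls.
#'
#' @param universe a [generate_structure_universe()] result.
#' @param config the same [synth_config()].
#' @return list with `ledger` (validated ledger data.frame) and `truth` —
#'   one row per name: `name`, `planted_cid`, `n_depositors`, `n_planted`,
#'   `sids_per_depositor`, `dissent` (`"none"` when unanimous),
#'   `share` (planted depositor fraction), `has_intra`.
#' @export
generate_ledger <- function(universe, config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 1L)
  cat_ <- universe$catalog
  mono <- cat_[cat_$kind == "mono", , drop = FALSE]
  pool <- sprintf("DEP%03d", seq_len(config$n_depositors))
  rows <- list(); truth <- list()
  sid <- 0L
  pick_dissent <- function(planted, type) {
    p <- mono[mono$cid == planted, ]
    cand <- switch(type,
      isotope   = mono$cid[mono$family == p$family & mono$stereo == p$stereo &
                           mono$cid != planted],
      stereo    = mono$cid[mono$family == p$family & mono$stereo != p$stereo],
      unrelated = mono$cid[mono$family != p$family]
    )
    cand[sample.int(length(cand), 1L)]
  }
  # uniform draw from an integer range, safe for degenerate lo == hi ranges
  draw <- function(rng) {
    if (rng[1L] == rng[2L]) rng[1L] else
      sample(seq(rng[1L], rng[2L]), 1L)
  }
  for (i in seq_len(config$n_names)) {
    name <- sprintf("CHEM-%05d", i)
    n_dep <- draw(config$depositors_per_name)
    k_sid <- draw(config$sids_per_depositor)
    deps <- sample(pool, n_dep)
    planted <- mono$cid[sample.int(nrow(mono), 1L)]
    dissent_type <- "none"
    n_planted <- n_dep
    has_intra <- FALSE
    dep_cid <- rep(planted, n_dep)
    if (n_dep >= 2L &&
        stats::runif(1L) < config$inter_discrepancy_rate) {
      n_planted <- as.integer(ceiling(config$planted_majority_share * n_dep))
      if (n_planted < n_dep) {
        dissent_type <- if (config$dissent == "mixed") {
          sample(c("unrelated", "isotope", "stereo"), 1L)
        } else config$dissent
        for (d in seq(n_planted + 1L, n_dep)) {
          dep_cid[d] <- pick_dissent(planted, dissent_type)
        }
      } else {
        n_planted <- n_dep
      }
    }
    for (d in seq_len(n_dep)) {
      cids <- rep(dep_cid[d], k_sid)
      if (dissent_type != "none" && k_sid >= 2L &&
          stats::runif(1L) < config$intra_discrepancy_rate) {
        # one stray record inside this depositor
        cids[k_sid] <- pick_dissent(planted, dissent_type)
        has_intra <- has_intra || length(unique(cids)) > 1L
      }
      for (cc in cids) {
        sid <- sid + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          raw_name = name, name = name, depositor = deps[d],
          sid = sid, cid = cc, stringsAsFactors = FALSE)
      }
    }
    truth[[length(truth) + 1L]] <- data.frame(
      name = name, planted_cid = planted, n_depositors = n_dep,
      n_planted = n_planted, sids_per_depositor = k_sid,
      dissent = dissent_type, share = n_planted / n_dep,
      has_intra = has_intra, stringsAsFactors = FALSE)
  }
  ledger <- suppressWarnings(validate_ledger(do.call(rbind, rows)))
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(ledger = ledger, truth = truth)
}

#' Generate a complete synthetic study
#'
#' Universe plus ledger plus ground truth in one call.
#'
#' @param config a [synth_config()].
#' @return list with `ledger`, `keys`, `components`, `catalog`, `truth`,
#'   `config`.
#' @export
simulate_submissions <- function(config = synth_config()) {
  uni <- generate_structure_universe(config)
  led <- generate_ledger(uni, config)
  list(ledger = led$ledger, keys = uni$keys, components = uni$components,
       catalog = uni$catalog, truth = led$truth, config = config)
}

#' Score filtering results against planted ground truth
#'
#' For each name the expected outcome is derived analytically from the
#' planted configuration: a planted depositor share at or above the
#' strategy threshold resolves at the exact (`CID`) level with exactly the
#' planted structure; below the threshold, isotope-sibling dissent resolves
#' at `STE` (planted and dissenters share the stereo key), stereo-sibling
#' dissent at `CON`, and unrelated dissent is discarded. Names with
#' planted intra-depositor inconsistency are excluded from the exact-level
#' score (their expectation depends on the vote mode) but still count for
#' containment/false-resolution.
#'
#' @param fit a [synonym_filter()] fit on the generated ledger.
#' @param truth the `truth` table from [generate_ledger()].
#' @param keys the universe key table.
#' @return list with `exact_recovery` (share of clean names landing on the
#'   expected level with the expected CID set), `containment` (share of
#'   names expected to resolve whose result contains the planted CID),
#'   `false_resolution` (share of resolved names missing their planted CID),
#'   and `n_scored`.
#' @export
evaluate_recovery <- function(fit, truth, keys) {
  res <- fit$results
  if (!setequal(res$name, truth$name)) {
    stop("results and ground truth cover different names")
  }
  m <- match(truth$name, res$name)
  threshold <- fit$strategy$threshold
  exp_level <- ifelse(
    .frac_ge(truth$n_planted, truth$n_depositors, threshold), "CID",
    ifelse(truth$dissent == "isotope", "STE",
           ifelse(truth$dissent == "stereo", "CON", "DISCARD")))
  lk <- function(cids, level) .keys_at(cids, keys, level)
  ok_exact <- logical(nrow(truth)); scored <- !truth$has_intra
  contain <- logical(nrow(truth)); resolved <- res$status[m] != "discarded"
  for (i in seq_len(nrow(truth))) {
    r <- res[m[i], ]
    asserted <- unique(fit$ledger$cid[fit$ledger$name == truth$name[i]])
    if (exp_level[i] == "DISCARD") {
      ok_exact[i] <- r$status == "discarded"
      contain[i] <- NA
      next
    }
    exp_key <- lk(truth$planted_cid[i], exp_level[i])
    exp_cids <- sort(asserted[lk(asserted, exp_level[i]) == exp_key])
    obs_level <- if (r$status == "singleton") "CID" else r$level
    ok_exact[i] <- r$status != "discarded" &&
      identical(obs_level, exp_level[i]) &&
      identical(sort(r$cids[[1L]]), exp_cids)
    contain[i] <- r$status != "discarded" &&
      truth$planted_cid[i] %in% r$cids[[1L]]
  }
  planted_in <- vapply(seq_len(nrow(truth)), function(i) {
    truth$planted_cid[i] %in% res$cids[[m[i]]]
  }, NA)
  list(
    exact_recovery = if (any(scored)) mean(ok_exact[scored]) else NA_real_,
    containment = mean(contain[!is.na(contain)]),
    false_resolution = if (any(resolved))
      mean(!planted_in[resolved]) else 0,
    n_scored = sum(scored)
  )
}
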