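test_that("generated universes always satisfy the nesting invariants", {
  for (seed in c(1, 7, 23)) {
    uni <- generate_structure_universe(
      synth_config(n_families = 10, salt_fraction = 0.4,
                   mixture_fraction = 0.2, seed = seed))
    expect_equal(nrow(validate_key_nesting(uni$keys)), 0L)
  }
})

test_that("the variant tree realizes the intended sharing pattern", {
  uni <- generate_structure_universe(
    synth_config(n_families = 2, stereo_per_family = 1,
                 isotopes_per_stereo = 2, salt_fraction = 0,
                 mixture_fraction = 0, dissent = "unrelated", seed = 5))
  mono <- uni$keys[uni$catalog$kind == "mono", ]
  fam1 <- mono[1:2, ]  # two isotopes of one stereo form
  expect_identical(fam1$k_ste[1L], fam1$k_ste[2L])
  expect_identical(fam1$k_con[1L], fam1$k_con[2L])
  expect_false(fam1$k_cid[1L] == fam1$k_cid[2L])
})

test_that("salt forms share parent keys with their base compound; mixtures fall back", {
  cfg <- synth_config(n_families = 5, salt_fraction = 0.4,
                      mixture_fraction = 0.2, seed = 31)
  uni <- generate_structure_universe(cfg)
  cat_ <- uni$catalog
  salts <- uni$keys[cat_$kind == "salt", ]
  expect_gt(nrow(salts), 0L)
  for (i in seq_len(nrow(salts))) {
    fam <- cat_$family[cat_$cid == salts$cid[i]]
    base <- uni$keys[uni$keys$k_cid == sprintf("ISO%04d.1.1", fam), ]
    expect_identical(salts$k_pcid[i], base$k_cid)
    expect_identical(salts$k_pcon[i], base$k_con)
    # the parent rule really held: organic unit >= 70% of unique heavy atoms
    comp <- uni$components[uni$components$cid == salts$cid[i], ]
    org <- comp[comp$has_carbon, ]
    expect_gte(org$heavy_atoms / sum(comp$heavy_atoms), 0.70)
  }
  mixes <- uni$keys[cat_$kind == "mixture", ]
  expect_gt(nrow(mixes), 0L)
  expect_identical(mixes$k_pcid, mixes$k_cid)  # no qualifying parent
})

test_that("generation is a pure function of the configuration", {
  cfg <- synth_config(n_names = 25, seed = 77)
  s1 <- simulate_submissions(cfg)
  s2 <- simulate_submissions(cfg)
  expect_identical(s1$ledger, s2$ledger)
  expect_identical(s1$keys, s2$keys)
  expect_identical(s1$truth, s2$truth)
})

test_that("a planted share of 1 makes every multi-depositor name unanimous", {
  sim <- simulate_submissions(
    synth_config(n_names = 40, planted_majority_share = 1.0,
                 inter_discrepancy_rate = 1.0, seed = 4))
  per_name <- tapply(sim$ledger$cid, sim$ledger$name,
                     function(x) length(unique(x)))
  expect_true(all(per_name == 1L))
})

test_that("recovery is exactly 1 when the planted share meets the threshold", {
  cfg <- synth_config(n_names = 150, depositors_per_name = c(2L, 6L),
                      sids_per_depositor = c(1L, 2L),
                      planted_majority_share = 0.7,
                      inter_discrepancy_rate = 0.5,
                      intra_discrepancy_rate = 0,
                      dissent = "unrelated", seed = 101)
  sim <- simulate_submissions(cfg)
  for (preset in c("I", "II", "III", "IV")) {
    fit <- synonym_filter(sim$ledger, sim$keys, preset)
    rec <- evaluate_recovery(fit, sim$truth, sim$keys)
    expect_identical(rec$exact_recovery, 1)
    expect_identical(rec$false_resolution, 0)
  }
})

test_that("a planted share below the threshold fails at the exact level as designed", {
  # 11 of 20 depositors = 55%: below the 60% bar with unrelated dissent
  cfg <- synth_config(n_names = 40, n_depositors = 20,
                      depositors_per_name = c(20L, 20L),
                      sids_per_depositor = c(1L, 1L),
                      planted_majority_share = 0.55,
                      inter_discrepancy_rate = 1.0,
                      intra_discrepancy_rate = 0,
                      dissent = "unrelated", seed = 55)
  sim <- simulate_submissions(cfg)
  fit <- synonym_filter(sim$ledger, sim$keys, "I")
  dissenting <- sim$truth$dissent != "none"
  expect_true(any(dissenting))
  expect_true(all(fit$results$status[match(sim$truth$name[dissenting],
                                           fit$results$name)] == "discarded"))
  rec <- evaluate_recovery(fit, sim$truth, sim$keys)
  expect_identical(rec$exact_recovery, 1)  # the analytic expectation is "discard"
})

test_that("sibling dissent below threshold resolves exactly one rung down", {
  base <- list(n_names = 60, n_depositors = 20,
               depositors_per_name = c(20L, 20L),
               sids_per_depositor = c(1L, 1L),
               planted_majority_share = 0.55,
               inter_discrepancy_rate = 1.0, intra_discrepancy_rate = 0,
               seed = 66)
  for (d in c("isotope", "stereo")) {
    cfg <- do.call(synth_config, c(base, list(dissent = d)))
    sim <- simulate_submissions(cfg)
    fit <- synonym_filter(sim$ledger, sim$keys, "I")
    rec <- evaluate_recovery(fit, sim$truth, sim$keys)
    expect_identical(rec$exact_recovery, 1)
    expect_identical(rec$containment, 1)
    want <- if (d == "isotope") "STE" else "CON"
    hit <- fit$results$level[fit$results$status == "resolved" &
                             fit$results$group != "A"]
    expect_true(all(hit == want))
  }
})

test_that("generated fixtures pass the ledger and key validators end to end", {
  sim <- simulate_submissions(synth_config(n_names = 50, seed = 12,
                                           dissent = "mixed"))
  expect_silent(validate_ledger(sim$ledger))
  expect_equal(nrow(validate_key_nesting(sim$keys)), 0L)
  expect_true(all(sim$ledger$cid %in% sim$keys$cid))
})

test_that("recovery scoring rejects mismatched names", {
  sim <- simulate_submissions(synth_config(n_names = 10, seed = 1))
  fit <- synonym_filter(sim$ledger, sim$keys, "I")
  bad_truth <- sim$truth; bad_truth$name[1L] <- "NOT-A-NAME"
  expect_error(evaluate_recovery(fit, bad_truth, sim$keys),
               "different names")
})
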