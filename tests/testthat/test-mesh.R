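mesh_table <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(mnid = r[[1L]], mesh_uid = r[[2L]],
               term = normalize_name(r[[3L]]), kind = r[[4L]],
               stringsAsFactors = FALSE)
  }))
}

test_that("term index does exact lookup, many-to-many, with normalization symmetry", {
  mesh <- mesh_table(
    list(68000082L, "D000082", "acetaminophen", "heading"),
    list(68000082L, "D000082", "tylenol", "entry"),
    list(2009860L, "D000068677", "sildenafil citrate", "heading"),
    list(77L, "D77", "tylenol", "entry"))
  idx <- build_term_index(mesh)
  expect_identical(mesh_lookup(idx, "ACETAMINOPHEN"), 68000082L)
  expect_identical(mesh_lookup(idx, "acetaminophen"), 68000082L)  # symmetric
  expect_identical(mesh_lookup(idx, "tylenol"), c(77L, 68000082L))
  expect_identical(mesh_lookup(idx, "no such thing"), integer(0))
  dup <- rbind(mesh, mesh[1L, ])
  expect_warning(build_term_index(dup), "duplicate")
})

test_that("links carry the depositors of retained matching synonyms", {
  keys <- mk_keys(1:2)
  led <- mk_ledger(c("aspirin", "aspirin", "other"),
                   c("d1", "d2", "d3"), 1:3, c(1L, 1L, 2L))
  fit <- synonym_filter(led, keys, "I")
  idx <- build_term_index(mesh_table(list(5L, "D5", "aspirin", "heading")))
  links <- match_filtered_synonyms(fit, idx)
  expect_equal(nrow(links), 1L)
  expect_identical(links$cid, 1L)
  expect_identical(links$mnid, 5L)
  expect_identical(links$support, 2L)
  # compound with no MeSH-matching synonym yields no link
  expect_false(2L %in% links$cid)
})

test_that("one MeSH record can legitimately link to several distinct compounds", {
  # entry terms naming close analogues (the sildenafil-citrate pattern)
  keys <- mk_keys(1:2)
  led <- mk_ledger(c("sildenafil", "desmethylsildenafil"),
                   c("d1", "d2"), 1:2, c(1L, 2L))
  fit <- synonym_filter(led, keys, "I")
  idx <- build_term_index(mesh_table(
    list(2009860L, "D000068677", "sildenafil", "entry"),
    list(2009860L, "D000068677", "desmethylsildenafil", "entry")))
  links <- match_filtered_synonyms(fit, idx)
  expect_identical(sort(links$cid), c(1L, 2L))
  expect_true(all(links$mnid == 2009860L))
})

test_that("the 50% link filter keeps at most two records, ties keeping both", {
  raw <- function(cid, mnid, deps) {
    data.frame(cid = cid, mnid = mnid, support = length(deps),
               depositors = I(list(deps)), stringsAsFactors = FALSE)
  }
  # 2-2 split of 4 depositors: both records at exactly one half survive
  tie <- rbind(raw(1L, 10L, c("a", "b")), raw(1L, 20L, c("c", "d")))
  ft <- mesh_filter(tie)
  expect_identical(ft$retained, c(TRUE, TRUE))
  expect_equal(ft$fraction, c(0.5, 0.5))
  # 3-1 of 4: only the majority record
  maj <- rbind(raw(2L, 10L, c("a", "b", "c")), raw(2L, 20L, "d"))
  expect_identical(mesh_filter(maj)$retained, c(TRUE, FALSE))
  # 1-1-1 of 3: nothing reaches one half
  thirds <- rbind(raw(3L, 10L, "a"), raw(3L, 20L, "b"), raw(3L, 30L, "c"))
  expect_identical(mesh_filter(thirds)$retained, rep(FALSE, 3L))
})

test_that("no single-vote tally retains more than two records per compound", {
  # one vote per depositor: disjoint supports, so two half-shares exhaust
  # the denominator and a third record can never reach one half
  set.seed(21)
  for (rep in 1:300) {
    n_dep <- sample(2:8, 1L)
    n_mnid <- sample(1:5, 1L)
    vote <- sample(n_mnid, n_dep, replace = TRUE)
    links <- do.call(rbind, lapply(unique(vote), function(m) {
      supp <- paste0("d", which(vote == m))
      data.frame(cid = 1L, mnid = m * 10L, support = length(supp),
                 depositors = I(list(supp)), stringsAsFactors = FALSE)
    }))
    ft <- mesh_filter(links)
    expect_lte(sum(ft$retained), 2L)
    # the filter is a pure subset operation on the links
    expect_identical(ft[, c("cid", "mnid", "support")],
                     links[, c("cid", "mnid", "support")])
  }
})

test_that("denominator counts only depositors supporting some link of the compound", {
  raw <- function(cid, mnid, deps) {
    data.frame(cid = cid, mnid = mnid, support = length(deps),
               depositors = I(list(deps)), stringsAsFactors = FALSE)
  }
  lk <- rbind(raw(1L, 10L, c("a", "b", "c")), raw(1L, 20L, c("c", "d")),
              raw(2L, 10L, "e"))
  ft <- mesh_filter(lk)
  expect_identical(ft$denom, c(4L, 4L, 1L))
  expect_identical(ft$retained, c(TRUE, TRUE, TRUE))  # 3/4, 2/4, 1/1
})

test_that("the full mapping wrapper produces coherent cross counts", {
  sim <- simulate_submissions(synth_config(n_names = 40, seed = 13))
  fit <- synonym_filter(sim$ledger, sim$keys, "I")
  # MeSH table naming a handful of the planted structures via their synonyms
  some <- fit$results[fit$results$status != "discarded", ][1:5, ]
  mesh <- do.call(rbind, lapply(seq_len(5L), function(i) {
    data.frame(mnid = 1000L + i, mesh_uid = sprintf("D%04d", i),
               term = some$name[i], kind = "entry", stringsAsFactors = FALSE)
  }))
  mm <- mesh_map(fit, mesh)
  expect_s3_class(mm, "mesh_map")
  expect_true(all(mm$links$fraction >= 0 & mm$links$fraction <= 1))
  s <- mm$stats
  expect_identical(s$without_filter[["mnids_with_cids"]],
                   s$without_filter[["mnids_single_cid"]] +
                   s$without_filter[["mnids_multiple_cids"]])
  expect_lte(s$with_filter[["cids_with_mnids"]],
             s$without_filter[["cids_with_mnids"]])
  per_cid <- table(mm$links$cid[mm$links$retained])
  if (length(per_cid)) expect_lte(max(per_cid), 2L)
})
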