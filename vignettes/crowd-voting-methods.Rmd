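---
title: "Crowd-voting synonym filtering: model, design choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crowd-voting synonym filtering: model, design choices, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synfilter)
```

## The model

The unit of evidence is one depositor-provided association between a
chemical name and a substance record: a `(name, depositor, SID, CID)`
row of the synonym ledger. Names are canonicalized first — ASCII
lower-case letters are upper-cased and curly/square brackets become round
brackets; we additionally strip edge whitespace and collapse internal
whitespace runs, because whitespace variants would otherwise defeat exact
term matching. Only those rules are applied: punctuation variants, Greek
letters and other non-ASCII characters pass through untouched, so the
mapping is locale-independent and idempotent.

Each distinct name is classified by its discrepancy structure: group A
(one depositor, one SID — nothing to vote on), B (several depositors, one
SID each), C (one depositor, several SIDs), D (both kinds of multiplicity).
Groups B–D are put to a vote over the six-level equivalence ladder
`CID > STE > PCID > PSTE > CON > PCON`. At a given level every SID's CID
is replaced by its equivalence key at that level, and a key wins when it
holds at least the threshold fraction of the votes. In *single* mode each
depositor first votes internally over its own SIDs at the same threshold,
and only depositors reaching an internal consensus cast one external vote;
in *multiple* mode every SID votes directly. The first level with a
consensus wins; the name keeps every asserted CID whose key at that level
equals the winning key. A name with no consensus anywhere is discarded —
assigned to no structure at all.

The assumptions worth stating explicitly:

* **Consistency, not accuracy.** The vote detects disagreement; it cannot
  detect a consensus error. If depositors copy a wrong association from
  each other, the crowd confirms it — which is exactly why the package
  also implements white/black-list overrides as a post-hoc correction
  channel.
* **Votes are SIDs, not file rows.** Duplicate `(name, SID)` rows collapse
  on read. Whether a depositor submitting the same structure under many
  SIDs should count once or many times is precisely the single/multiple
  axis of the strategy table, so both are first-class.
* **The key ladder is coherent.** Two structures equal at a finer grain
  must be equal at every coarser grain, and a shared full-structure key
  forces a shared parent key at the same grain. `validate_key_nesting()`
  checks all seven implications; generated universes satisfy them by
  construction (keys are generated as a tree).

## Threshold semantics

The consensus comparison is **inclusive**: `k/n >= t`. The descriptive
phrase "more than a certain percentage" might suggest a strict inequality,
but the canonical worked examples (3-of-5 agreeing at the 60% threshold;
3-of-4 at 70%) only hold under `>=`, so the inclusive reading is treated
as normative throughout, including the 70% parent-compound rule and the
50% MeSH vote (where inclusivity is what permits a 2–2 tie to retain two
records).

Numerically the comparison is implemented as
`count >= threshold * total - 1e-9`. The absolute epsilon makes the
inclusive boundary immune to binary floating-point representation (e.g.
`0.6 * 5` need not be exactly `3`); with vote totals of database scale
(well below 1e7) and thresholds of magnitude 1, the epsilon cannot flip a
genuinely strict comparison. The test suite's independent oracle instead
uses exact integer arithmetic (`count * q >= p * total` for a threshold
`p/q`), so the two routes cross-validate each other on thousands of random
instances.

Thresholds at or below ½ are rejected for synonym voting: above ½ the
winner is unique by pigeonhole, which is what lets the engine return a
single key without tie-breaking rules. The MeSH stage deliberately uses
½ and accepts up to two winners.

## Parent compounds

A multicomponent structure (salt, hydrate, mixture) is reduced to its
*parent* unit for the three parent-level rungs: the unit must contain at
least one carbon atom and carry at least 70% (inclusive) of the heavy
atoms summed over the *unique* units — stoichiometry is ignored, so a 2:1
salt counts its counterion once. Since two shares of 70% cannot coexist,
at most one unit qualifies.

Where no unit qualifies (a near-50:50 organic mixture), or the structure
is single-component, the parent keys **fall back to the full-structure
keys**. The alternative — abstaining from parent-level votes — would
silently shrink the denominator for some names and not others, making
fractions incomparable across levels. With the identity fallback,
parent-level voting for such structures degenerates to a repeat of the
corresponding full-structure level: a no-op rather than an exclusion. This
fallback is our decision; the source protocol leaves the case undefined.

## Category accounting

Names resolved at the exact level split into `CID-STD` — the asserted
structures were unanimous before any voting, i.e. structure
standardization alone disambiguated the name — and `CID-FILT`, where a
genuine sub-unanimous vote decided. We define `CID-STD` by *unanimity of
asserted CIDs*, not by a winning fraction of 1.0: in single mode a
depositor that fails its internal vote is excluded, and the remaining
voters can be unanimous even though several CIDs were asserted. Counting
such names as "standardization" would wrongly credit standardization for
work the filter did, and would make the standardization column depend on
the strategy; under the unanimity definition it is strategy-invariant, as
it should be.

One subtle single-mode behavior is intentional: a depositor excluded at
one level (no internal consensus there) **re-enters at coarser levels**,
where its SIDs may well agree — exclusion is per level, not per name.
And when a lone single-SID depositor outlasts a discordant multi-SID
depositor, the filtered name retains exactly one SID; this is the
mechanism that *grows* the single-SID count (ΔA > 0) under single-vote
strategies, and the regression suite pins it down.

## The MeSH stage

Filtered names are matched *exactly* (after normalization) against MeSH
headings, entry terms and registry numbers; each match links every CID the
name retained to the term's record (MNID). A link's support is the set of
depositors contributing a retained SID of that CID under a matching name.
The 50% vote then retains links supported by at least half of the
compound's *eligible* depositors.

Two deliberate choices here:

* **Denominator.** "Half of the depositors" is only observable among
  depositors expressing any MeSH-linkable name, so the denominator is the
  set of depositors supporting *some* link of the compound — not all
  depositors of the compound. The choice is isolated in `mesh_filter()`.
* **Multi-support.** A depositor naming several synonyms may support
  several records simultaneously; supports are not split fractionally.
  Consequently the "at most two records per compound" bound is analytic
  only for single-vote tallies (disjoint supports), where two half-shares
  exhaust the denominator. With overlapping multi-synonym support, more
  than two links can each clear ½ — the property tests and the
  acceptance script therefore measure the bound over true tallies.

MNIDs are opaque integers read from the term table; no arithmetic between
MeSH unique IDs and MNIDs is attempted.

## The synthetic generator

`synth_config()` + `simulate_submissions()` emulate the discrepancy
structure the filter is built for: a structure universe generated as a
connectivity → stereo → isotope tree (nesting holds by construction),
plus salt forms (unique full keys, parent keys shared with the base
compound, counterion sized so the 70% rule holds) and mixtures with no
qualifying parent (exercising the fallback). Ledgers plant a consensus
CID per name: `ceiling(share × n_depositors)` depositors assert it and
the rest dissent — in an unrelated family (resolvable only at the exact
level), as an isotope sibling (falls to `STE`), or a stereo sibling
(falls to `CON`). Dissent placement is a configuration axis precisely
because it determines *which* rung resolves. All depositors of a name
submit the same number of SIDs, so vote shares coincide under both vote
modes, and `ceiling` guarantees the planted share meets any threshold at
or below the configured share — which is what makes exact (not
approximate) recovery a testable contract.

Defaults — 1–6 depositors per contested name, 1–2 SIDs each, planted
share 0.7, inter-depositor discrepancy more common than intra (0.3 vs
0.1) — reflect the regime reported for depositor-provided names at
database scale, where most contested names have very few contributors
(hence thresholds chosen so that 2-of-3 or 3-of-5 can settle them).

What the generator does **not** emulate: the heavy-tailed frequency
distribution of real synonyms (no names with thousands of SIDs),
correlated errors from depositors copying each other, non-chemical junk
names, tautomer standardization edge cases, and real CACTVS-style hash
keys (keys are opaque tokens; nothing in the engine inspects them).
Passing recovery tests therefore demonstrates the *mechanism* is
implemented correctly under controlled discrepancy, not that any
particular real-world error rate will be achieved.

## Degenerate inputs and determinism

Empty names after normalization are rejected with a warning; a SID
asserted with two CIDs (or two depositors) is a hard error, since it
violates what a substance record is. An empty ledger yields an empty,
well-formed result. Zero eligible voters at a level (single mode, every
depositor internally split) means no consensus at that level, and the
ladder continues. Names are processed in lexicographic order, no step
uses randomness, and writers emit fixed-format TSV — identical inputs
give byte-identical outputs. Generator output is a pure function of the
configuration, seed included.

## Problem sizes

The shipped suites run the voting oracle cross-check on 10,000 random
instances of up to 6 depositors × 3 SIDs, recovery on 1,000-name planted
ledgers for all four strategies, the MeSH bound on 10,000 random tallies,
and mixed-discrepancy studies of several hundred names — sizes chosen so
the full suite completes in minutes while every code path (all six
levels, salts, mixtures, overrides, vocabulary exclusion) is exercised.

## Known limitations

* Consistency checking cannot repair systematic copying errors; the
  white/black-lists exist for that, but are user-supplied.
* Exact term matching means lexical variants beyond the normalization
  rules (hyphenation, Greek spelling, inverted chemical names) do not
  match MeSH terms.
* Class names ("indoles", "ketones") and short acronyms are not detected
  automatically; vocabulary exclusion lists are the mechanism, and a
  `warn_short_names` flag highlights — but never removes — names of five
  characters or fewer.
* The equivalence ladder is only as good as the supplied key table; the
  package validates nesting but cannot derive keys from structures (an
  adapter from real structure representations would be a separate,
  optional component).
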