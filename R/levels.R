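#' The six-level chemical equivalence ladder
#'
#' Structural "sameness" of two standardized compounds is judged at six
#' granularities, ordered from most to least specific:
#'
#' * `CID`  — connectivity + stereochemistry + isotopes (exact structure);
#' * `STE`  — connectivity + stereochemistry, isotopes ignored;
#' * `PCID` — exact structure of the parent compound (salts/mixtures reduced
#'   to their chemically important covalent unit);
#' * `PSTE` — stereo structure of the parent compound;
#' * `CON`  — connectivity only;
#' * `PCON` — connectivity of the parent compound.
#'
#' Voting descends this ladder (`CID > STE > PCID > PSTE > CON > PCON`) until
#' a consensus is found. For single-component structures the parent levels
#' coincide with the corresponding full-structure levels.
#'
#' @format A character vector of the six level names in specificity order.
#' @export
EQUIV_LEVELS <- c("CID", "STE", "PCID", "PSTE", "CON", "PCON")

# key-table column carrying each level's key
.level_cols <- c(
  CID = "k_cid", STE = "k_ste", PCID = "k_pcid",
  PSTE = "k_pste", CON = "k_con", PCON = "k_pcon"
)

.key_cols <- unname(.level_cols[EQUIV_LEVELS])

# inclusive fraction comparison: count/total >= threshold, robust to the
# binary representation of thresholds like 0.6 (3/5 must count as consensus)
.frac_ge <- function(count, total, threshold) {
  count >= threshold * total - 1e-9
}
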