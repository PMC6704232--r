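# High-sensitivity (HS) and high-efficiency (HE) siRNA classification.
#
# HS (off-target search): strand-selection rules only — the duplex is
# counted when the guide-strand prediction favors the antisense (mRNA-
# complementary) strand. HE (construct design): strict conjunction of the
# sequence rule, the thermodynamic rule, the >1 kcal/mol end-asymmetry
# margin, and target-site accessibility above the LAP threshold.

#' High-sensitivity classification
#'
#' @param verdict One row (or several) of [strand_selection()] output.
#' @return Logical: `TRUE` where `predicted_guide == "antisense"`, i.e. the
#'   sequence rule or the thermodynamic rule favors the mRNA-complementary
#'   strand.
#' @export
classify_hs <- function(verdict) {
  verdict$predicted_guide == "antisense"
}

#' High-efficiency classification of one siRNA/target-site pair
#'
#' @param verdict One row of [strand_selection()] output for the duplex.
#' @param hit One row of [find_hits()] output placing the duplex on the
#'   target transcript.
#' @param profile [partition_unpaired()] profile of that transcript.
#' @param params [accessibility_params()] (supplies the LAP threshold).
#' @param k siRNA length.
#' @return List of class `efficiency_verdict`: `hs_pass`, `he_pass`,
#'   `reasons` (identifiers of failed HE conjuncts among `"orientation"`,
#'   `"sequence_rule"`, `"thermo_rule"`, `"strict_thermo"`,
#'   `"accessibility"`), and `accessibility_value` (site LAP, `NA` when the
#'   orientation made it unnecessary).
#' @export
classify_he <- function(verdict, hit, profile, params, k) {
  reasons <- character()
  lap <- NA_real_
  if (hit$orientation != "sense-match") {
    # guide strand would not pair this transcript's mRNA
    reasons <- "orientation"
  } else {
    if (!verdict$sequence_rule_pass) reasons <- c(reasons, "sequence_rule")
    if (!verdict$thermo_rule_pass) reasons <- c(reasons, "thermo_rule")
    if (!verdict$strict_thermo_pass) reasons <- c(reasons, "strict_thermo")
    lap <- site_accessibility(profile, hit$position, k)
    if (is.na(lap) || lap < params$threshold) {
      reasons <- c(reasons, "accessibility")
    }
  }
  structure(list(hs_pass = unname(classify_hs(verdict)),
                 he_pass = length(reasons) == 0L,
                 reasons = reasons,
                 accessibility_value = lap),
            class = "efficiency_verdict")
}

# Vectorized HE over a hit table (used by the pipeline). `profiles` is a
# named list of accessibility_profile keyed by transcript_id; hits on
# transcripts without a profile (non-main targets) get he_pass = FALSE.
classify_he_table <- function(hits, verdicts, profiles, params, k) {
  n <- nrow(hits)
  vi <- match(hits$sirna_start, verdicts$start)
  hs <- classify_hs(verdicts)[vi]
  site_lap <- rep(NA_real_, n)
  he <- logical(n)
  failed <- character(n)
  for (i in seq_len(n)) {
    if (hits$orientation[i] != "sense-match" ||
        !hits$transcript_id[i] %in% names(profiles)) {
      failed[i] <- "orientation"
      next
    }
    r <- character()
    v <- verdicts[vi[i], ]
    if (!v$sequence_rule_pass) r <- c(r, "sequence_rule")
    if (!v$thermo_rule_pass) r <- c(r, "thermo_rule")
    if (!v$strict_thermo_pass) r <- c(r, "strict_thermo")
    lap <- site_accessibility(profiles[[hits$transcript_id[i]]],
                              hits$position[i], k)
    site_lap[i] <- lap
    if (is.na(lap) || lap < params$threshold) r <- c(r, "accessibility")
    he[i] <- length(r) == 0L
    failed[i] <- paste(r, collapse = ",")
  }
  hits$hs_pass <- hs
  hits$he_pass <- he
  hits$delta_mfe <- verdicts$delta_mfe[vi]
  hits$site_lap <- site_lap
  hits$failed_rules <- failed
  hits
}
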