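# Two variants in cis: additive baseline, synergy score, and the scenario
# taxonomy for combined pathogenicity.

SYNERGY_SCENARIOS <- c("both_above", "additive_pathogenic", "combined_rescue",
                       "negative_synergy", "positive_synergy",
                       "synergy_subthreshold_pathogenic",
                       "additive_nonpathogenic")

#' Additive baseline of two single-variant ddG values
#'
#' @param ddg_1,ddg_2 Numeric vectors (kcal/mol).
#' @return `ddg_1 + ddg_2`, exactly.
#' @examples
#' additive_baseline(0.81, 0.74) # 1.55
#' @export
additive_baseline <- function(ddg_1, ddg_2) {
  stopifnot(is.numeric(ddg_1), is.numeric(ddg_2))
  ddg_1 + ddg_2
}

#' Synergy score of a double variant
#'
#' Deviation of the combined-mutant estimate from additivity:
#' `ddg_double - (ddg_1 + ddg_2)`. Positive values mean the double mutant is
#' more destabilized than the sum of its parts; with no synergy the score
#' tends to zero.
#'
#' @param ddg_double Combined-mutant ddG (kcal/mol).
#' @param ddg_1,ddg_2 Single-variant ddG values (kcal/mol).
#' @return Numeric vector (kcal/mol).
#' @export
synergy_score <- function(ddg_double, ddg_1, ddg_2) {
  ddg_double - additive_baseline(ddg_1, ddg_2)
}

classify_double_one <- function(d1, d2, dd, thr, tol) {
  has_dd <- is.finite(dd)
  s <- d1 + d2
  a1 <- d1 > thr; a2 <- d2 > thr
  s_above <- s > thr
  c_above <- has_dd && dd > thr
  eff <- if (has_dd) dd else s
  e_above <- eff > thr
  sig <- has_dd && abs(dd - s) > tol
  scenario <-
    if (a1 && a2) "both_above"
    else if (sig && !s_above && c_above) {
      if (!a1 && !a2) "synergy_subthreshold_pathogenic" else "positive_synergy"
    }
    else if (sig && s_above && !c_above) "negative_synergy"
    else if (has_dd && !s_above && c_above && !a1 && !a2)
      "synergy_subthreshold_pathogenic"
    else if ((a1 || a2) && !e_above) "combined_rescue"
    else if (e_above) "additive_pathogenic"
    else "additive_nonpathogenic"
  tibble(additive_sum = s,
         synergy_score = if (has_dd) dd - s else NA_real_,
         scenario = scenario,
         pathogenic_combined = e_above,
         near_cutoff = abs(eff - thr) <= tol / 2)
}

#' Classify double variants in cis
#'
#' Scores each pair of in-cis variants against the destabilization cutoff
#' (default 1.6 kcal/mol) using the single-variant ddG values, their exact
#' additive sum, and (when present) the combined-mutant estimate
#' `ddg_double`. The effective combined ddG is `ddg_double` when present,
#' else the additive sum; `pathogenic_combined` is `TRUE` when it strictly
#' exceeds the cutoff. The scenario taxonomy is total and mutually
#' exclusive:
#' \describe{
#'   \item{both_above}{both singles above the cutoff (trivially pathogenic).}
#'   \item{positive_synergy / synergy_subthreshold_pathogenic}{the sum is at
#'     or below the cutoff but the combined estimate is above it; the
#'     sub-threshold label applies when neither single exceeds the cutoff
#'     either.}
#'   \item{negative_synergy}{the sum is above the cutoff but the combined
#'     estimate drops below it by more than the synergy tolerance.}
#'   \item{combined_rescue}{at least one single is above the cutoff but the
#'     effective combined value is below it.}
#'   \item{additive_pathogenic}{the effective combined value is above the
#'     cutoff without a significant synergistic deviation.}
#'   \item{additive_nonpathogenic}{everything at or below the cutoff.}
#' }
#' A synergy scenario requires `|ddg_double - sum| >` the tolerance, so when
#' the combined estimate equals the additive sum exactly no synergy scenario
#' is ever emitted. Pairs whose effective combined value lies within half a
#' tolerance of the cutoff are flagged `near_cutoff`.
#'
#' @param records Tibble with numeric columns `ddg_1`, `ddg_2` and optional
#'   `ddg_double` (absent or `NA` restricts scenarios to the additive
#'   subset).
#' @param cfg An [analysis_config()]; supplies the cutoff.
#' @param synergy_tolerance Minimum |deviation| (kcal/mol) from additivity
#'   to call synergy; default 0.8 (one predictor SD).
#' @return The input with `additive_sum`, `synergy_score`, `scenario`
#'   (factor), `pathogenic_combined` and `near_cutoff` added; label order of
#'   the two variants never changes any output.
#' @export
classify_double <- function(records, cfg = analysis_config(),
                            synergy_tolerance = 0.8) {
  records <- as_tibble(records)
  stopifnot(all(c("ddg_1", "ddg_2") %in% names(records)))
  if (!"ddg_double" %in% names(records)) records$ddg_double <- NA_real_
  thr <- cfg$destabilization_threshold
  if (nrow(records) == 0) {
    records$additive_sum <- numeric(0)
    records$synergy_score <- numeric(0)
    records$scenario <- factor(character(0), levels = SYNERGY_SCENARIOS)
    records$pathogenic_combined <- logical(0)
    records$near_cutoff <- logical(0)
    return(records)
  }
  ann <- purrr::pmap(list(records$ddg_1, records$ddg_2, records$ddg_double),
                     classify_double_one, thr = thr, tol = synergy_tolerance)
  ann <- dplyr::bind_rows(ann)
  ann$scenario <- factor(ann$scenario, levels = SYNERGY_SCENARIOS)
  dplyr::bind_cols(records, ann)
}
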