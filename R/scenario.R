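#' Planted-signal search scenario
#'
#' Compact cohort configuration for exercising the Objective II searches
#' against ground truth at desk scale: 20 predictors of which six carry
#' signal — two strong marginal predictors with the avolition/anhedonia
#' dissociation (severe in clusters 1+2 vs severe in cluster 1 only), one
#' graded neurocognitive predictor, one moderate emotional-intelligence
#' predictor, and two interaction-only predictors (the
#' hippocampal-volume/IRI pattern) whose separation is conditional on a
#' marginal partner's tertile — plus 14 nuisance predictors. Functioning
#' items and cluster structure match the default cohort.
#'
#' @param n_participants Cohort size (default 282).
#' @param seed Integer seed.
#' @param missing_rate MCAR missingness (default 0: the scenario targets
#'   the searches, not the imputation).
#' @return A [cohort_config()].
#' @export
search_scenario_config <- function(n_participants = 282, seed = 1L,
                                   missing_rate = 0) {
  signal <- tibble::tibble(
    name = c("SANS Avolition", "SANS Anhedonia", "Processing Speed",
             "MSCEIT", "Left Hippocampal Volume", "IRI Fantasy"),
    block = c("SYMP", "SYMP", "COG", "SCOG", "MRI", "SELF"),
    kind = "continuous",
    bilateral_pair = NA_character_)
  nuisance <- tibble::tibble(
    name = sprintf("Nuisance %02d", 1:14),
    block = "NOISE", kind = "continuous",
    bilateral_pair = NA_character_)
  cohort_config(
    n_participants = n_participants,
    predictors = dplyr::bind_rows(signal, nuisance),
    predictor_effects = list(
      "SANS Avolition"   = c(0.9, 0.9, -1.2),
      "SANS Anhedonia"   = c(1.3, -0.45, -0.45),
      "Processing Speed" = c(-0.7, 0, 0.7),
      "MSCEIT"           = c(-0.5, -0.5, 0.8)),
    interaction_effects = list(
      "Left Hippocampal Volume" =
        list(partner = "SANS Avolition", means = c(-0.9, 0, 0.9)),
      "IRI Fantasy" =
        list(partner = "SANS Anhedonia", means = c(-0.8, 0.8, 0))),
    bilateral_r = 0.84,
    missing_rate = missing_rate,
    seed = seed)
}
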