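# Cohort presets: per-subject parameter distributions (mean, SD) that the
# phantom cohorts emulate. The force-direction ratios, short-axis force
# levels, EDV, ejection fraction and sphericity index encode the group
# summary statistics of published healthy and dilated-cardiomyopathy (DCM)
# 4D flow cohorts (n = 10 per group; the "dcm_normal_diastolic" preset is the
# n = 5 DCM subgroup with echocardiographically normal diastolic function).
# These numbers parameterize simulation; the package does not re-derive them.

.presets <- list(
  healthy = list(
    ratio_e = c(mean = 0.23, sd = 0.12),
    ratio_a = c(mean = 0.26, sd = 0.09),
    mean_sax_e = c(mean = 0.032, sd = 0.007),
    mean_sax_a = c(mean = 0.034, sd = 0.012),
    edv = c(mean = 137, sd = 15),
    si = c(mean = 0.56, sd = 0.06),
    ef = c(mean = 0.61, sd = 0.03),
    si_coupling = 0.3,           # within-group ratio_e ~ SI correlation
    jet_e = 0.85, jet_a = 0.5, jet_sys = 0.9,
    noise_sd = 0.02, background_amp = 0.02, wrap = TRUE),
  dcm = list(
    ratio_e = c(mean = 0.53, sd = 0.15),
    ratio_a = c(mean = 0.44, sd = 0.21),
    mean_sax_e = c(mean = 0.045, sd = 0.011),
    mean_sax_a = c(mean = 0.032, sd = 0.014),
    edv = c(mean = 177, sd = 33),
    si = c(mean = 0.75, sd = 0.12),
    ef = c(mean = 0.41, sd = 0.05),
    si_coupling = 0.3,
    jet_e = 1.25, jet_a = 0.5, jet_sys = 0.8,
    noise_sd = 0.02, background_amp = 0.02, wrap = TRUE),
  dcm_normal_diastolic = list(
    ratio_e = c(mean = 0.58, sd = 0.11),
    ratio_a = c(mean = 0.37, sd = 0.1479),
    mean_sax_e = c(mean = 0.045, sd = 0.011),
    mean_sax_a = c(mean = 0.032, sd = 0.014),
    edv = c(mean = 177, sd = 33),
    si = c(mean = 0.75, sd = 0.12),
    ef = c(mean = 0.41, sd = 0.05),
    si_coupling = 0.3,
    jet_e = 1.25, jet_a = 0.5, jet_sys = 0.8,
    noise_sd = 0.02, background_amp = 0.02, wrap = TRUE))

#' Cohort preset parameter sets
#'
#' @param name \code{"healthy"}, \code{"dcm"} or
#'   \code{"dcm_normal_diastolic"}.
#' @return An object of class \code{"cohort_preset"}: named list of
#'   \code{c(mean, sd)} pairs for the per-subject parameters (force-direction
#'   ratios, short-axis force levels, EDV mL, sphericity index, ejection
#'   fraction), the ratio-SI coupling coefficient, jet speeds and artifact
#'   levels.
#' @export
cohort_preset <- function(name = c("healthy", "dcm", "dcm_normal_diastolic")) {
  name <- match.arg(name)
  structure(c(.presets[[name]], list(name = name)), class = "cohort_preset")
}
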