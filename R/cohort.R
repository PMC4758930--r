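# Seeded cohort generation: per-subject parameters drawn from a preset's
# distributions, one phantom per subject. Generation is a pure function of
# (preset, n, seed).

rtrunc_norm <- function(n, mean, sd, lower, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  guard <- 0L
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lower | x > upper)
    guard <- guard + 1L
    if (guard > 1000L) stop("spec error: truncation bounds exclude the distribution")
  }
  x
}

#' Sample per-subject phantom parameters from a cohort preset
#'
#' Draws the force-direction targets, EDV, ejection fraction and sphericity
#' index from the preset's (truncated) normal distributions; the sphericity
#' index is coupled to the standardized E-wave ratio with the preset's
#' coupling coefficient. Uses the current RNG state.
#'
#' @param preset A \code{\link{cohort_preset}}.
#' @param n Number of subjects.
#' @return Data frame with one row per subject: \code{ratio_e},
#'   \code{ratio_a}, \code{mean_sax_e}, \code{mean_sax_a}, \code{edv},
#'   \code{ef}, \code{si}.
#' @export
sample_subject_params <- function(preset, n) {
  stopifnot(inherits(preset, "cohort_preset"), n >= 1)
  p <- preset
  ratio_e <- rtrunc_norm(n, p$ratio_e["mean"], p$ratio_e["sd"], 0.02)
  ratio_a <- rtrunc_norm(n, p$ratio_a["mean"], p$ratio_a["sd"], 0.02)
  mean_sax_e <- rtrunc_norm(n, p$mean_sax_e["mean"], p$mean_sax_e["sd"], 0.004)
  mean_sax_a <- rtrunc_norm(n, p$mean_sax_a["mean"], p$mean_sax_a["sd"], 0.004)
  edv <- rtrunc_norm(n, p$edv["mean"], p$edv["sd"], 70, 350)
  ef <- rtrunc_norm(n, p$ef["mean"], p$ef["sd"], 0.15, 0.75)
  rc <- p$si_coupling
  z_ratio <- (ratio_e - p$ratio_e["mean"]) / p$ratio_e["sd"]
  si <- p$si["mean"] + p$si["sd"] *
    (rc * z_ratio + sqrt(1 - rc^2) * stats::rnorm(n))
  si <- pmin(pmax(si, 0.30), 1.10)
  data.frame(ratio_e = ratio_e, ratio_a = ratio_a,
             mean_sax_e = mean_sax_e, mean_sax_a = mean_sax_a,
             edv = edv, ef = ef, si = si)
}

#' Generate a seeded phantom cohort
#'
#' @param preset Preset name or \code{\link{cohort_preset}} object.
#' @param n Number of subjects (>= 2).
#' @param seed Integer seed; regeneration with the same arguments is
#'   bit-identical.
#' @param out_dir Optional directory: each subject is written as NIfTI
#'   velocity components + sidecar, a segmentation NIfTI, a landmarks JSON
#'   and a covariates JSON under \code{subject_XX/}, plus a cohort-level
#'   ground-truth CSV.
#' @param ... Further arguments passed to \code{\link{phantom_spec}} (e.g.
#'   \code{voxel_size}, \code{n_frames}) overriding the defaults.
#' @return An object of class \code{"phantom_cohort"}: list with
#'   \code{subjects} (each a \code{\link{lv_phantom}} result), \code{params}
#'   (the sampled ground-truth table), \code{preset}, \code{seed}.
#' @export
generate_cohort <- function(preset, n, seed, out_dir = NULL, ...) {
  if (is.character(preset)) preset <- cohort_preset(preset)
  stopifnot(inherits(preset, "cohort_preset"))
  if (n < 2) stop("spec error: a cohort needs n >= 2 subjects")
  set.seed(as.integer(seed))
  params <- sample_subject_params(preset, n)
  subjects <- vector("list", n)
  for (s in seq_len(n)) {
    spec <- phantom_spec(edv = params$edv[s], si = params$si[s],
                         ef = params$ef[s],
                         ratio_e = params$ratio_e[s],
                         ratio_a = params$ratio_a[s],
                         mean_sax_e = params$mean_sax_e[s],
                         mean_sax_a = params$mean_sax_a[s],
                         jet_e = preset$jet_e, jet_a = preset$jet_a,
                         jet_sys = preset$jet_sys,
                         noise_sd = preset$noise_sd,
                         background_amp = preset$background_amp,
                         wrap = preset$wrap, ...)
    subjects[[s]] <- lv_phantom(spec)
  }
  cohort <- structure(list(subjects = subjects, params = params,
                           preset = preset$name, seed = seed),
                      class = "phantom_cohort")
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

#' Write a phantom cohort to disk
#' @param cohort A \code{"phantom_cohort"}.
#' @param out_dir Output directory.
#' @return Invisibly, the subject directories.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dirs <- character(length(cohort$subjects))
  for (s in seq_along(cohort$subjects)) {
    sub <- cohort$subjects[[s]]
    d <- file.path(out_dir, sprintf("subject_%02d", s))
    dirs[s] <- d
    write_velocity(sub$velocity, d)
    write_mask(sub$seg, file.path(d, "seg.nii"))
    jsonlite::write_json(list(voxel_size_mm = sub$seg$voxel_size,
                              frame_times_ms = sub$seg$frame_times),
                         file.path(d, "seg_meta.json"),
                         auto_unbox = TRUE, digits = NA)
    write_landmarks(sub$landmarks, file.path(d, "landmarks.json"))
    jsonlite::write_json(sub$covariates, file.path(d, "covariates.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  utils::write.csv(cbind(subject = seq_along(cohort$subjects), cohort$params),
                   file.path(out_dir, "ground_truth.csv"), row.names = FALSE)
  invisible(dirs)
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort> preset '%s', %d subjects, seed %d\n",
              x$preset, length(x$subjects), x$seed))
  invisible(x)
}
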