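# Per-subject analysis pipeline and cohort comparison. The stages mirror the
# acquisition-to-metrics order: velocity corrections -> mask resampling ->
# pressure gradients -> force integration -> axes/phases -> metrics.

#' Pipeline configuration
#'
#' @param unwrap Temporal VENC unwrapping on (default \code{TRUE}).
#' @param background Polynomial background correction on (default
#'   \code{TRUE}).
#' @param degree Background polynomial total degree (default 4).
#' @param sd_scale Static-tissue soft-mask scale, m/s (default 0.05).
#' @param onset_frac Phase-onset threshold fraction (default 0.05).
#' @param include_viscous Include the viscous term (default \code{TRUE}).
#' @param erode_mask Erode the LV mask by one voxel before integration
#'   (excludes partially filled border voxels; default \code{FALSE}).
#' @return A named list of class \code{"hf_config"}.
#' @export
hf_config <- function(unwrap = TRUE, background = TRUE, degree = 4,
                      sd_scale = 0.05, onset_frac = 0.05,
                      include_viscous = TRUE, erode_mask = FALSE) {
  structure(list(unwrap = unwrap, background = background, degree = degree,
                 sd_scale = sd_scale, onset_frac = onset_frac,
                 include_viscous = include_viscous, erode_mask = erode_mask),
            class = "hf_config")
}

# 6-neighbor one-voxel erosion, per frame
erode_mask_series <- function(mask) {
  occ <- mask$occupancy
  for (f in seq_len(dim(occ)[4])) {
    m <- occ[, , , f]
    mm <- array(FALSE, dim(m))
    keep <- m
    for (ax in 1:3) for (s in c(-1L, 1L)) {
      nb <- shift3(m * 1, ax, s)
      nb[is.na(nb)] <- 0
      keep <- keep & (nb > 0)
    }
    occ[, , , f] <- keep
  }
  mask_series(occ, mask$voxel_size, mask$frame_times)
}

with_stage <- function(stage, expr, verbose = FALSE) {
  if (verbose) {
    t0 <- proc.time()[3]
    on.exit(message(sprintf("[%s] %.2f s", stage, proc.time()[3] - t0)))
  }
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Global LV hemodynamic force analysis for one subject
#'
#' Runs the full per-subject pipeline: preprocessing of the velocity data
#' (unwrapping, background-offset removal), resampling of the segmentation
#' onto the velocity grid, the Navier-Stokes pressure-gradient field and its
#' volume integral (the global force trace), the anatomical axes frame and
#' planar projections, cardiac-phase detection from the valve-plane speed
#' traces, and the diastolic force-direction metrics.
#'
#' @param velocity A \code{\link{velocity_field}}.
#' @param seg A \code{\link{mask_series}} on its own grid/time base (resampled
#'   internally when it does not match the velocity grid).
#' @param landmarks An \code{\link{lv_landmarks}} object.
#' @param covariates Named list of external scalars (\code{si} is used).
#' @param config A \code{\link{hf_config}}.
#' @param verbose Log stage timings.
#' @return An object of class \code{"hemoforce"}: \code{metrics}
#'   (\code{\link{subject_metrics}}), \code{projected} (per-frame projected
#'   force), \code{trace} (\code{\link{force_trace}}), \code{phases},
#'   \code{axes}, \code{speed_traces}, \code{config}.
#' @seealso \code{\link{run_pipeline}} for the file-based entry point,
#'   \code{\link{compare_cohorts}} for group statistics.
#' @export
hemoforce <- function(velocity, seg, landmarks, covariates = list(),
                      config = hf_config(), verbose = FALSE) {
  stopifnot(inherits(velocity, "velocity_field"))
  field <- with_stage("preprocess", preprocess_velocity(
    velocity, unwrap = config$unwrap, background = config$background,
    degree = config$degree, sd_scale = config$sd_scale), verbose)
  mask <- with_stage("mask_resample", {
    same_grid <- all(dim(seg$occupancy)[1:3] == dim(field$values)[1:3]) &&
      dim(seg$occupancy)[4] == field$meta$n_frames
    if (same_grid) seg else resample_mask(seg, field)
  }, verbose)
  if (config$erode_mask)
    mask <- with_stage("mask_erode", erode_mask_series(mask), verbose)
  traces <- with_stage("speed_traces",
                       extract_speed_traces(field, landmarks), verbose)
  phases <- with_stage("phase_detection",
                       detect_phases(traces, field$meta,
                                     onset_frac = config$onset_frac), verbose)
  pg <- with_stage("pressure_gradient",
                   pressure_gradient(field, mask,
                                     include_viscous = config$include_viscous),
                   verbose)
  trace <- with_stage("force_integration",
                      integrate_force(pg, mask, field$meta), verbose)
  axes <- with_stage("axes", build_axes(landmarks, mask, phases), verbose)
  projected <- with_stage("projection", project_force(trace, axes), verbose)
  metrics <- with_stage("metrics",
                        subject_metrics(projected, traces, phases, mask,
                                        covariates), verbose)
  structure(list(metrics = metrics, projected = projected, trace = trace,
                 phases = phases, axes = axes, speed_traces = traces,
                 covariates = covariates, config = config,
                 meta = field$meta),
            class = "hemoforce")
}

#' @export
print.hemoforce <- function(x, ...) {
  cat("Global LV hemodynamic force analysis\n")
  fmag <- sqrt(rowSums(x$trace$F^2))
  cat(sprintf("  %d frames; |F| peak %.3f N\n", length(fmag), max(fmag)))
  print(x$phases)
  print(x$metrics)
  invisible(x)
}

#' @export
summary.hemoforce <- function(object, ...) {
  x <- object
  lab <- phase_labels(x$phases)
  fmag <- sqrt(x$projected$F_long^2 + x$projected$F_sax1^2 +
                 x$projected$F_sax2^2)
  per_phase <- t(vapply(c("systole", "e_wave", "diastasis", "a_wave"),
                        function(ph) {
                          i <- lab == ph
                          if (!any(i)) return(c(frames = 0, peak_N = NA,
                                                mean_N = NA))
                          c(frames = sum(i), peak_N = max(fmag[i]),
                            mean_N = mean(fmag[i]))
                        }, numeric(3)))
  out <- list(metrics = x$metrics, per_phase = per_phase)
  class(out) <- "summary.hemoforce"
  out
}

#' @export
print.summary.hemoforce <- function(x, ...) {
  print(x$metrics)
  cat("Force magnitude per phase:\n")
  print(round(x$per_phase, 4))
  invisible(x)
}

#' @export
coef.hemoforce <- function(object, ...) {
  m <- object$metrics
  c(ratio_e = m$ratio_e, ratio_a = m$ratio_a,
    mean_sax_e = m$mean_sax_e, mean_sax_a = m$mean_sax_a,
    lax_max_e = m$lax_max_e, lax_max_a = m$lax_max_a,
    sax_max_e = m$sax_max_e, sax_max_a = m$sax_max_a,
    peak_lag_e = m$peak_lag_e, edv = m$edv, si = m$si)
}

#' @export
as.data.frame.hemoforce <- function(x, ...) {
  df <- as.data.frame(x$projected)
  df$phase <- phase_labels(x$phases)
  df$mv_speed <- x$speed_traces$mv_speed
  df$aov_speed <- x$speed_traces$aov_speed
  df
}

#' @export
plot.hemoforce <- function(x, which = c("loops", "trace"), ...) {
  which <- match.arg(which)
  lab <- phase_labels(x$phases)
  cols <- c(systole = "forestgreen", e_wave = "firebrick",
            diastasis = "goldenrod", a_wave = "royalblue")[lab]
  if (which == "loops") {
    op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
    cl <- function(v) c(v, v[1])
    graphics::plot(cl(x$projected$F_sax1), cl(x$projected$F_long), type = "l",
                   col = "grey60", xlab = "F_sax1 (N)", ylab = "F_long (N)",
                   main = "LAx (three-chamber) plane", asp = 1)
    graphics::points(x$projected$F_sax1, x$projected$F_long, col = cols,
                     pch = 19, cex = 0.7)
    graphics::abline(h = 0, v = 0, col = "grey85")
    graphics::plot(cl(x$projected$F_sax1), cl(x$projected$F_sax2), type = "l",
                   col = "grey60", xlab = "F_sax1 (N)", ylab = "F_sax2 (N)",
                   main = "Basal SAx plane", asp = 1)
    graphics::points(x$projected$F_sax1, x$projected$F_sax2, col = cols,
                     pch = 19, cex = 0.7)
    graphics::abline(h = 0, v = 0, col = "grey85")
  } else {
    fmag <- sqrt(x$projected$F_long^2 + x$projected$F_sax1^2 +
                   x$projected$F_sax2^2)
    graphics::plot(x$projected$time_ms, fmag, type = "l",
                   xlab = "time (ms)", ylab = "|F| (N)",
                   main = "Global hemodynamic force magnitude")
    graphics::points(x$projected$time_ms, fmag, col = cols, pch = 19,
                     cex = 0.7)
  }
  invisible(x)
}

#' Run the pipeline for one subject
#'
#' Accepts either a subject directory (as written by
#' \code{\link{write_cohort}}: \code{vel_[xyz].nii} + \code{vel_meta.json},
#' \code{seg.nii} + \code{seg_meta.json}, \code{landmarks.json}, optional
#' \code{covariates.json}) or an in-memory subject list with elements
#' \code{velocity}, \code{seg}, \code{landmarks}, \code{covariates} (e.g. a
#' \code{\link{lv_phantom}} result).
#'
#' @param subject Directory path or subject list.
#' @param config A \code{\link{hf_config}}.
#' @param verbose Log stage timings.
#' @return A \code{\link{hemoforce}} object.
#' @export
run_pipeline <- function(subject, config = hf_config(), verbose = FALSE) {
  if (is.character(subject)) {
    d <- subject
    subject <- with_stage("read", {
      vel <- read_velocity(file.path(d, paste0("vel_", c("x", "y", "z"), ".nii")),
                           file.path(d, "vel_meta.json"))
      sm <- jsonlite::read_json(file.path(d, "seg_meta.json"),
                                simplifyVector = TRUE)
      seg <- read_mask(file.path(d, "seg.nii"), voxel_size = sm$voxel_size_mm,
                       frame_times = sm$frame_times_ms)
      cov_path <- file.path(d, "covariates.json")
      cov <- if (file.exists(cov_path))
        jsonlite::read_json(cov_path, simplifyVector = TRUE) else list()
      list(velocity = vel, seg = seg,
           landmarks = read_landmarks(file.path(d, "landmarks.json")),
           covariates = cov)
    }, verbose)
  }
  hemoforce(subject$velocity, subject$seg, subject$landmarks,
            covariates = subject$covariates, config = config,
            verbose = verbose)
}

metrics_row <- function(m) {
  data.frame(ratio_e = m$ratio_e, ratio_a = m$ratio_a,
             mean_sax_e = m$mean_sax_e, mean_sax_a = m$mean_sax_a,
             lax_max_e = m$lax_max_e, lax_max_a = m$lax_max_a,
             sax_max_e = m$sax_max_e, sax_max_a = m$sax_max_a,
             loop_dir_e = m$loop_dir_e, loop_dir_a = m$loop_dir_a,
             peak_lag_e = m$peak_lag_e, si = m$si, edv = m$edv)
}

cohort_inputs <- function(x, config, verbose) {
  if (is.character(x)) {
    dirs <- sort(list.dirs(x, recursive = FALSE))
    fits <- lapply(dirs, run_pipeline, config = config, verbose = verbose)
  } else if (inherits(x, "phantom_cohort")) {
    fits <- lapply(x$subjects, run_pipeline, config = config,
                   verbose = verbose)
  } else {
    fits <- lapply(x, function(s)
      if (inherits(s, "hemoforce")) s
      else run_pipeline(s, config = config, verbose = verbose))
  }
  fits
}

#' Compare two cohorts
#'
#' Runs the pipeline for every subject of both groups, assembles the cohort
#' table, and performs the primary group comparisons (SAx-max/LAx-max ratio
#' at E- and A-wave; time-averaged SAx-plane force during early and late
#' filling) with unpaired t-tests, plus the pooled force-ratio vs sphericity
#' regressions.
#'
#' @param group_a,group_b Phantom cohorts, subject directories, or lists of
#'   subjects / \code{hemoforce} fits (>= 2 subjects each).
#' @param labels Length-2 character group labels.
#' @param config A \code{\link{hf_config}}.
#' @param variant t-test variant (\code{"student"} default).
#' @param verbose Log stage timings.
#' @return An object of class \code{"cohort_comparison"}: \code{table}
#'   (per-subject metrics + group), \code{comparisons} (list of
#'   \code{\link{ttest_unpaired}} results), \code{regressions} (E and A
#'   pooled ratio~SI fits), \code{summary} (group mean/SD/range per metric).
#' @export
compare_cohorts <- function(group_a, group_b, labels = c("a", "b"),
                            config = hf_config(),
                            variant = c("student", "welch"),
                            verbose = FALSE) {
  variant <- match.arg(variant)
  fits_a <- cohort_inputs(group_a, config, verbose)
  fits_b <- cohort_inputs(group_b, config, verbose)
  if (length(fits_a) < 2L || length(fits_b) < 2L)
    stop("domain error: each group needs >= 2 subjects")
  tab_a <- do.call(rbind, lapply(fits_a, function(f) metrics_row(f$metrics)))
  tab_b <- do.call(rbind, lapply(fits_b, function(f) metrics_row(f$metrics)))
  tab_a$group <- labels[1]; tab_b$group <- labels[2]
  table <- rbind(tab_a, tab_b)

  prim <- c("ratio_e", "ratio_a", "mean_sax_e", "mean_sax_a")
  comparisons <- lapply(prim, function(m)
    ttest_unpaired(tab_a[[m]], tab_b[[m]], variant = variant, metric = m))
  names(comparisons) <- prim
  regressions <- list(E = regress_ratio_si(table, "E"),
                      A = regress_ratio_si(table, "A"))

  num <- c(prim, "lax_max_e", "lax_max_a", "sax_max_e", "sax_max_a",
           "peak_lag_e", "si", "edv")
  gsum <- do.call(rbind, lapply(split(table[num], table$group), function(g) {
    data.frame(metric = num, mean = vapply(g, mean, 1),
               sd = vapply(g, stats::sd, 1), min = vapply(g, min, 1),
               max = vapply(g, max, 1), row.names = NULL)
  }))
  gsum$group <- rep(sort(unique(table$group)), each = length(num))

  structure(list(table = table, comparisons = comparisons,
                 regressions = regressions, summary = gsum,
                 labels = labels, variant = variant),
            class = "cohort_comparison")
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat(sprintf("Cohort comparison: %s (n=%d) vs %s (n=%d), %s t-tests\n",
              x$labels[1], sum(x$table$group == x$labels[1]),
              x$labels[2], sum(x$table$group == x$labels[2]), x$variant))
  for (cmp in x$comparisons) print(cmp)
  for (w in c("E", "A")) {
    r <- x$regressions[[w]]
    cat(sprintf("ratio ~ SI (%s, pooled n=%d): slope %.3f, R^2 %.3f, p %.4g\n",
                w, r$n, r$slope, r$r_squared, r$p))
  }
  invisible(x)
}

#' Write a cohort-comparison report
#'
#' @param comparison A \code{"cohort_comparison"}.
#' @param dir Output directory: writes \code{cohort_table.csv},
#'   \code{group_summary.csv} and \code{comparisons.csv}.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(comparison, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "cohort_table.csv")
  utils::write.csv(comparison$table, p1, row.names = FALSE)
  p2 <- file.path(dir, "group_summary.csv")
  utils::write.csv(comparison$summary, p2, row.names = FALSE)
  p3 <- file.path(dir, "comparisons.csv")
  cmp <- do.call(rbind, lapply(comparison$comparisons, function(x)
    data.frame(metric = x$metric, mean_a = x$mean_a, sd_a = x$sd_a,
               n_a = x$n_a, mean_b = x$mean_b, sd_b = x$sd_b, n_b = x$n_b,
               t = x$t, df = x$df, p = x$p, variant = x$variant)))
  utils::write.csv(cmp, p3, row.names = FALSE)
  invisible(c(p1, p2, p3))
}
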