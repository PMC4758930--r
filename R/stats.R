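# Cohort statistics: unpaired two-sample t-tests (pooled-variance student by
# default, Welch by flag) accepting raw samples or summary statistics, and
# the pooled linear regression of the force ratio on the sphericity index.

summ <- function(x) {
  if (is.list(x)) x <- unlist(x)
  if (!is.null(names(x)) && all(c("mean", "sd", "n") %in% names(x)))
    return(list(mean = unname(x["mean"]), sd = unname(x["sd"]),
                n = unname(x["n"]), summary = TRUE))
  x <- x[is.finite(x)]
  if (length(x) < 2L) stop("domain error: each sample needs n >= 2 finite values")
  list(mean = mean(x), sd = stats::sd(x), n = length(x), summary = FALSE)
}

#' Unpaired two-sample t-test (raw samples or summary statistics)
#'
#' @param a,b Numeric samples, or summary input as a named vector/list with
#'   elements \code{mean}, \code{sd}, \code{n}.
#' @param variant \code{"student"} (pooled variance; default) or
#'   \code{"welch"} (Welch-Satterthwaite degrees of freedom).
#' @param metric Optional metric name carried into the result.
#' @return An object of class \code{"comparison_result"}: group means/SDs/ns,
#'   \code{t}, \code{df}, two-tailed \code{p}, \code{variant}. Two groups
#'   with zero variance and equal means give \code{t = 0, p = 1} by
#'   convention.
#' @export
ttest_unpaired <- function(a, b, variant = c("student", "welch"),
                           metric = NULL) {
  variant <- match.arg(variant)
  sa <- summ(a); sb <- summ(b)
  if (sa$n < 2 || sb$n < 2)
    stop("domain error: each group needs n >= 2")
  va <- sa$sd^2; vb <- sb$sd^2
  if (va == 0 && vb == 0) {
    if (sa$mean == sb$mean) {
      t_stat <- 0; df <- sa$n + sb$n - 2; p <- 1
    } else {
      t_stat <- sign(sa$mean - sb$mean) * Inf; df <- sa$n + sb$n - 2; p <- 0
    }
  } else if (variant == "student") {
    df <- sa$n + sb$n - 2
    sp2 <- ((sa$n - 1) * va + (sb$n - 1) * vb) / df
    se <- sqrt(sp2 * (1 / sa$n + 1 / sb$n))
    t_stat <- (sa$mean - sb$mean) / se
    p <- 2 * stats::pt(-abs(t_stat), df)
  } else {
    se2 <- va / sa$n + vb / sb$n
    t_stat <- (sa$mean - sb$mean) / sqrt(se2)
    df <- se2^2 / ((va / sa$n)^2 / (sa$n - 1) + (vb / sb$n)^2 / (sb$n - 1))
    p <- 2 * stats::pt(-abs(t_stat), df)
  }
  structure(list(metric = metric,
                 mean_a = sa$mean, sd_a = sa$sd, n_a = sa$n,
                 mean_b = sb$mean, sd_b = sb$sd, n_b = sb$n,
                 t = t_stat, df = df, p = p, variant = variant),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  nm <- if (is.null(x$metric)) "" else paste0(x$metric, ": ")
  cat(sprintf("%s%.3g +/- %.3g (n=%d) vs %.3g +/- %.3g (n=%d): t=%.3f, df=%.1f, p=%.4g [%s]\n",
              nm, x$mean_a, x$sd_a, as.integer(x$n_a), x$mean_b, x$sd_b,
              as.integer(x$n_b), x$t, x$df, x$p, x$variant))
  invisible(x)
}

#' Linear regression of the force ratio on the sphericity index
#'
#' Ordinary least squares over all subjects pooled (both groups), as the
#' force-direction ratio and sphericity both separate the groups and the
#' relation of interest spans the spectrum.
#'
#' @param table Data frame with columns \code{si} and \code{ratio_e} /
#'   \code{ratio_a} (e.g. from \code{\link{compare_cohorts}}).
#' @param wave \code{"E"} or \code{"A"}.
#' @return List with \code{slope}, \code{intercept}, \code{r_squared},
#'   \code{p} (two-tailed, for the slope) and \code{n}.
#' @export
regress_ratio_si <- function(table, wave = c("E", "A")) {
  wave <- match.arg(wave)
  ratio <- if (wave == "E") table$ratio_e else table$ratio_a
  keep <- is.finite(ratio) & is.finite(table$si)
  ratio <- ratio[keep]; si <- table$si[keep]
  if (length(ratio) < 3L)
    stop("domain error: need >= 3 subjects with finite ratio and SI")
  if (stats::sd(si) == 0)
    stop("domain error: constant sphericity index")
  fit <- stats::lm(ratio ~ si)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p = unname(sm$coefficients[2, 4]),
       n = length(ratio))
}
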