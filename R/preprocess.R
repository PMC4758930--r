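# Phase-contrast preprocessing: temporal velocity unwrapping (aliasing beyond
# +/-VENC) and removal of a slowly varying background phase offset, fitted as a
# low-order polynomial to static tissue identified by a soft temporal-SD mask.

# alias velocities into [-venc, venc) the way the phase reconstruction does
alias_velocity <- function(v, venc) {
  ((v + venc) %% (2 * venc)) - venc
}

#' Correct velocity aliasing (phase wraps) along the cardiac cycle
#'
#' For each voxel and component the frame-to-frame velocity series is walked
#' cyclically from a reference frame of minimal global mean speed; at each step
#' the stored value is shifted by the multiple of \code{2*venc} (among
#' \code{-2..2}) that minimizes the temporal jump to the already-corrected
#' neighbor. True speeds are assumed below \code{2*venc}, and true temporal
#' jumps below \code{venc}. Output values may exceed \code{+/-venc}.
#'
#' @param field A \code{\link{velocity_field}}.
#' @return The unwrapped \code{\link{velocity_field}}.
#' @export
unwrap_velocity <- function(field) {
  v <- field$values
  venc <- field$meta$venc
  nf <- field$meta$n_frames
  if (nf < 2L) return(field)
  # reference frame: minimal global mean speed
  speed_mean <- vapply(seq_len(nf), function(f) {
    mean(sqrt(v[, , , 1, f]^2 + v[, , , 2, f]^2 + v[, , , 3, f]^2))
  }, numeric(1))
  ref <- which.min(speed_mean)
  order_f <- ((ref - 1L + seq_len(nf - 1L)) %% nf) + 1L  # frames after ref, cyclic
  prev <- ref
  for (f in order_f) {
    for (c_i in 1:3) {
      vp <- v[, , , c_i, prev]
      vf <- v[, , , c_i, f]
      k <- round((vp - vf) / (2 * venc))
      k[k > 2] <- 2L; k[k < -2] <- -2L
      v[, , , c_i, f] <- vf + 2 * venc * k
    }
    prev <- f
  }
  field$values <- v
  field
}

#' Soft static-tissue weights from temporal speed variation
#'
#' Voxels whose speed barely varies over the cycle are treated as static
#' tissue. The weight is \code{exp(-(sd_speed / scale)^2)} with \code{sd_speed}
#' the temporal standard deviation of the voxel speed.
#'
#' @param field A \code{\link{velocity_field}} with at least 2 frames.
#' @param scale Soft-mask scale in m/s (default 0.05): the speed SD at which
#'   the weight drops to \code{exp(-1)}.
#' @return 3-D array of weights in \code{[0, 1]}.
#' @export
static_tissue_weights <- function(field, scale = 0.05) {
  v <- field$values
  nf <- dim(v)[5]
  if (nf < 2L) stop("domain error: need >= 2 frames for static-tissue weights")
  d <- dim(v)[1:3]
  speed <- sqrt(v[, , , 1, ]^2 + v[, , , 2, ]^2 + v[, , , 3, ]^2)
  dim(speed) <- c(prod(d), nf)
  mu <- rowMeans(speed)
  sd_speed <- sqrt(rowMeans(speed^2) - mu^2)
  sd_speed[sd_speed < 0 | !is.finite(sd_speed)] <- 0
  w <- exp(-(sd_speed / scale)^2)
  array(w, d)
}

# polynomial design matrix: monomials x^a y^b z^c with a+b+c <= degree, on
# coordinates centered/scaled to ~[-1, 1] for conditioning
poly_design <- function(coords, degree) {
  ex <- expand.grid(a = 0:degree, b = 0:degree, c = 0:degree)
  ex <- ex[ex$a + ex$b + ex$c <= degree, , drop = FALSE]
  X <- matrix(1, nrow(coords), nrow(ex))
  for (t in seq_len(nrow(ex))) {
    X[, t] <- coords[, 1]^ex$a[t] * coords[, 2]^ex$b[t] * coords[, 3]^ex$c[t]
  }
  list(X = X, exponents = ex)
}

scaled_coords <- function(dims, voxel_size) {
  ctr <- (dims - 1) / 2 * voxel_size
  half <- pmax(dims - 1, 1) / 2 * voxel_size
  g <- expand.grid(x = axis_coords(dims[1], voxel_size[1]),
                   y = axis_coords(dims[2], voxel_size[2]),
                   z = axis_coords(dims[3], voxel_size[3]))
  cbind((g$x - ctr[1]) / half[1], (g$y - ctr[2]) / half[2],
        (g$z - ctr[3]) / half[3])
}

#' Fit a polynomial background-offset model to static tissue
#'
#' Weighted least-squares fit, per velocity component, of a 3-D polynomial of
#' total degree \code{degree} (default 4) to the time-averaged velocity,
#' weighted by the static-tissue soft mask. The fitted field models the
#' time-constant background phase offset (eddy currents).
#'
#' @param field A \code{\link{velocity_field}}.
#' @param static_weights 3-D weight array in \code{[0, 1]}, e.g. from
#'   \code{\link{static_tissue_weights}}.
#' @param degree Total polynomial degree (default 4; 35 terms).
#' @return An object of class \code{"background_model"} with per-component
#'   coefficients, the weight array, and residual summaries (weighted RMS,
#'   m/s).
#' @export
fit_background <- function(field, static_weights, degree = 4) {
  d <- dim(field$values)[1:3]
  w <- as.numeric(static_weights)
  if (any(w < 0 | w > 1)) stop("fit error: weights must lie in [0, 1]")
  n_terms <- choose(degree + 3, 3)
  if (sum(w > 0) < n_terms)
    stop("fit error: fewer positive-weight voxels than polynomial terms")
  coords <- scaled_coords(d, field$meta$voxel_size)
  des <- poly_design(coords, degree)
  sw <- sqrt(w)
  Xw <- des$X * sw
  qrX <- qr(Xw)
  if (qrX$rank < n_terms)
    stop("fit error: rank-deficient design (degenerate weight support)")
  nf <- dim(field$values)[5]
  coef <- matrix(0, n_terms, 3)
  resid_rms <- numeric(3)
  for (c_i in 1:3) {
    vbar <- rowMeans(matrix(field$values[, , , c_i, ], prod(d), nf))
    beta <- qr.coef(qrX, vbar * sw)
    coef[, c_i] <- beta
    r <- vbar - des$X %*% beta
    resid_rms[c_i] <- sqrt(sum(w * r^2) / sum(w))
  }
  structure(list(coefficients = coef, exponents = des$exponents,
                 weights = array(w, d), degree = degree, dims = d,
                 voxel_size = field$meta$voxel_size, resid_rms = resid_rms),
            class = "background_model")
}

#' Evaluate a background model on its grid
#' @param model A \code{"background_model"} from \code{\link{fit_background}}.
#' @return 4-D array \code{[i, j, k, component]} of offsets (m/s).
#' @export
eval_background <- function(model) {
  coords <- scaled_coords(model$dims, model$voxel_size)
  X <- poly_design(coords, model$degree)$X
  off <- X %*% model$coefficients
  array(off, c(model$dims, 3L))
}

#' Subtract a fitted background offset from a velocity field
#'
#' The offset is time-constant: the same per-voxel correction is applied to
#' every frame. Correction is linear in the model (applying model A then B
#' equals applying A+B).
#'
#' @param field A \code{\link{velocity_field}}.
#' @param model A \code{"background_model"}.
#' @return The corrected \code{\link{velocity_field}}.
#' @export
apply_background <- function(field, model) {
  off <- eval_background(model)
  nf <- dim(field$values)[5]
  for (c_i in 1:3) {
    field$values[, , , c_i, ] <-
      field$values[, , , c_i, ] - as.numeric(off[, , , c_i])
  }
  field
}

#' Standard preprocessing: unwrap, then background correction
#'
#' @param field A \code{\link{velocity_field}}.
#' @param unwrap Apply temporal unwrapping first (default \code{TRUE}); wraps
#'   corrupt the temporal mean used by the background fit, so the order is
#'   fixed.
#' @param background Fit and subtract the polynomial background (default
#'   \code{TRUE}).
#' @param degree Background polynomial degree.
#' @param sd_scale Static-tissue soft-mask scale (m/s).
#' @return The preprocessed \code{\link{velocity_field}}.
#' @export
preprocess_velocity <- function(field, unwrap = TRUE, background = TRUE,
                                degree = 4, sd_scale = 0.05) {
  if (unwrap) field <- unwrap_velocity(field)
  if (background) {
    w <- static_tissue_weights(field, scale = sd_scale)
    model <- fit_background(field, w, degree = degree)
    field <- apply_background(field, model)
  }
  field
}
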