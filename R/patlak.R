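#' Patlak regressors for a tissue curve
#'
#' Builds the graphical-analysis coordinates after the equilibrium time t*:
#' the ordinate is the normalized tissue concentration `y = C_T(t)/Cp(t)`
#' and the abscissa the normalized input integral, from time zero for the
#' standard Patlak plot or from t* for the relative Patlak (RP) plot,
#' \deqn{x_{std}(t) = \int_0^t C_p / C_p(t), \qquad
#'       x_{rel}(t) = \int_{t^*}^t C_p / C_p(t).}
#' Only frames whose start time is at or after t* enter, so the relative
#' integral covers acquired data only; frame mid-times are the abscissa and
#' the input integrals use continuous quadrature of the input model.
#'
#' @param curve a [tissue_curve()] (or any list with `values` and
#'   `schedule`).
#' @param f plasma input function.
#' @param t_star equilibrium time t* (minutes).
#' @param method `"standard"` or `"relative"`.
#' @return list with `x`, `y`, `t` (retained frame mid-times) and `durations`.
#' @export
patlak_xy <- function(curve, f, t_star = 40,
                      method = c("standard", "relative")) {
  method <- match.arg(method)
  sched <- curve$schedule
  keep <- which(sched$starts >= t_star - 1e-9)
  if (length(keep) < 2L)
    stop("need at least 2 frames starting at or after t* = ", t_star)
  mids <- frame_mids(sched)[keep]
  cp <- eval_input(f, mids)
  if (any(cp <= 0))
    stop("plasma input must be positive at all retained frame mid-times")
  lo <- if (method == "standard") 0 else t_star
  ints <- vapply(mids, function(tm) integrate_input(f, lo, tm), numeric(1))
  list(x = ints / cp, y = curve$values[keep] / cp, t = mids,
       durations = frame_durations(sched)[keep], method = method,
       t_star = t_star)
}

#' Fit the standard or relative Patlak plot
#'
#' The central model fit: an ordinary (optionally frame-duration-weighted)
#' least-squares line through the Patlak coordinates of [patlak_xy()]. For
#' the standard plot the slope is the net influx rate Ki (mL/min/cm^3) and
#' the intercept b mixes blood volume and the free-tracer distribution
#' volume; for the relative plot the slope Ki' equals alpha * Ki with a
#' subject-level global scaling factor alpha, and the intercept b' equals
#' the SUV ratio C_T(t*)/Cp(t*).
#'
#' @inheritParams patlak_xy
#' @param weights `"none"` (default) for ordinary least squares or
#'   `"duration"` to weight frames by their duration.
#' @return an object of class `patlak` with `coefficients`
#'   (`intercept`, `slope`), `r2`, `n_points`, fitted values and residuals.
#' @examples
#' f <- feng_input()
#' p <- kinetic_params(0.1, 0.13, 0.06)
#' tc <- tissue_curve(f, p, late_schedule(40, 4, 5))
#' fit <- patlak(tc, f, t_star = 40, method = "relative")
#' coef(fit)
#' @export
patlak <- function(curve, f, t_star = 40,
                   method = c("standard", "relative"),
                   weights = c("none", "duration")) {
  method <- match.arg(method)
  weights <- match.arg(weights)
  xy <- patlak_xy(curve, f, t_star, method)
  w <- if (weights == "duration") xy$durations else rep(1, length(xy$x))
  if (stats::var(xy$x) <= 0 || diff(range(xy$x)) < 1e-12)
    stop("degenerate Patlak abscissa (zero variance)")
  X <- cbind(intercept = 1, slope = xy$x)
  fit <- stats::lm.wfit(X, xy$y, w)
  yhat <- X %*% fit$coefficients
  ss_res <- sum(w * (xy$y - yhat)^2)
  ss_tot <- sum(w * (xy$y - stats::weighted.mean(xy$y, w))^2)
  r2 <- if (ss_tot > 0) max(0, min(1, 1 - ss_res / ss_tot)) else 1
  structure(list(coefficients = fit$coefficients,
                 r2 = r2, n_points = length(xy$x),
                 method = method, t_star = t_star, weights = weights,
                 x = xy$x, y = xy$y, t = xy$t,
                 fitted.values = as.numeric(yhat),
                 residuals = xy$y - as.numeric(yhat),
                 w = w, input = f),
            class = "patlak")
}

#' @export
print.patlak <- function(x, ...) {
  lab <- if (x$method == "standard") c("Ki", "b") else c("Ki'", "b'")
  cat(sprintf("%s Patlak fit (t* = %g min, %d frames)\n",
              if (x$method == "standard") "Standard" else "Relative",
              x$t_star, x$n_points))
  cat(sprintf("  %s = %.5g mL/min/cm^3, %s = %.5g, R^2 = %.4f\n",
              lab[1L], x$coefficients[["slope"]],
              lab[2L], x$coefficients[["intercept"]], x$r2))
  invisible(x)
}

#' @export
summary.patlak <- function(object, ...) {
  n <- object$n_points
  dof <- n - 2L
  se <- if (dof > 0) {
    sxx <- sum(object$w * (object$x - stats::weighted.mean(object$x, object$w))^2)
    s2 <- sum(object$w * object$residuals^2) / dof
    sqrt(s2 / sxx)
  } else NA_real_
  out <- list(fit = object, slope_se = se, df = dof)
  class(out) <- "summary.patlak"
  out
}

#' @export
print.summary.patlak <- function(x, ...) {
  print(x$fit)
  if (is.finite(x$slope_se)) {
    q <- stats::qt(0.975, x$df)
    s <- x$fit$coefficients[["slope"]]
    cat(sprintf("  slope SE = %.3g, 95%% CI [%.5g, %.5g]\n",
                x$slope_se, s - q * x$slope_se, s + q * x$slope_se))
  }
  invisible(x)
}

#' @export
coef.patlak <- function(object, ...) object$coefficients

#' @export
residuals.patlak <- function(object, ...) object$residuals

#' @export
fitted.patlak <- function(object, ...) object$fitted.values

#' @export
predict.patlak <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x else
    if (is.list(newdata)) newdata$x else as.numeric(newdata)
  object$coefficients[["intercept"]] + object$coefficients[["slope"]] * x
}

#' @export
plot.patlak <- function(x, ...) {
  xl <- if (x$method == "standard")
    expression(integral(C[p] * d * tau, 0, t) / C[p](t)) else
    expression(integral(C[p] * d * tau, "t*", t) / C[p](t))
  graphics::plot(x$x, x$y, xlab = xl, ylab = expression(C[T](t) / C[p](t)),
                 pch = 19, ...)
  graphics::abline(x$coefficients[["intercept"]],
                   x$coefficients[["slope"]], col = 2)
  invisible(x)
}

# mask rule shared by the voxel-wise fits: last-frame activity above 1% of
# the frame maximum (excludes air, where Cp-normalized ratios blow up)
default_mask <- function(img) {
  lf <- img$data[, , , dim(img$data)[4L]]
  lf > 0.01 * max(lf)
}

#' Voxel-wise parametric Patlak imaging
#'
#' Fits the (standard or relative) Patlak line in every masked voxel of a
#' dynamic image. The abscissa depends only on the global plasma input, so
#' it is computed once and the voxel-wise least squares reduces to a single
#' matrix product per volume. Voxels where the fit is impossible are
#' excluded from the mask with a reported count.
#'
#' @param img a [dynamic_image()].
#' @param f plasma input function.
#' @inheritParams patlak
#' @param mask logical 3D array; default retains voxels whose last-frame
#'   activity exceeds 1% of the frame maximum.
#' @return an object of class `parametric_image`: `slope` and `intercept`
#'   3D arrays (zero outside the mask), `method`, `t_star`, `mask`.
#' @export
fit_parametric <- function(img, f, t_star = 40,
                           method = c("standard", "relative"),
                           mask = NULL, weights = c("none", "duration")) {
  method <- match.arg(method)
  weights <- match.arg(weights)
  stopifnot(inherits(img, "dynamic_image"))
  d <- dim(img$data)
  if (is.null(mask)) mask <- default_mask(img)
  if (!identical(dim(mask), d[1:3])) stop("mask shape must match the image")
  sched <- img$schedule
  keep <- which(sched$starts >= t_star - 1e-9)
  if (length(keep) < 2L)
    stop("need at least 2 frames starting at or after t* = ", t_star)
  mids <- frame_mids(sched)[keep]
  cp <- eval_input(f, mids)
  if (any(cp <= 0)) stop("plasma input must be positive at retained frames")
  lo <- if (method == "standard") 0 else t_star
  xv <- vapply(mids, function(tm) integrate_input(f, lo, tm), numeric(1)) / cp
  w <- if (weights == "duration") frame_durations(sched)[keep] else
    rep(1, length(keep))
  midx <- which(mask)
  if (length(midx) == 0L) stop("empty mask")
  mat <- matrix(img$data, prod(d[1:3]), d[4L])
  Y <- t(mat[midx, keep, drop = FALSE]) / cp   # frames x voxels, y = C/Cp
  X <- cbind(1, xv)
  XtX <- crossprod(X * w, X)
  beta <- solve(XtX, crossprod(X * w, Y))      # 2 x nvox
  bad <- !is.finite(beta[1L, ]) | !is.finite(beta[2L, ])
  if (any(bad)) {
    beta[, bad] <- 0
    mask[midx[bad]] <- FALSE
    message(sum(bad), " voxel(s) dropped from the mask (non-finite fit)")
  }
  slope <- array(0, d[1:3]); slope[midx] <- beta[2L, ]
  intercept <- array(0, d[1:3]); intercept[midx] <- beta[1L, ]
  slope[!mask] <- 0; intercept[!mask] <- 0
  structure(list(slope = slope, intercept = intercept, method = method,
                 t_star = t_star, mask = mask, voxel_mm = img$voxel_mm,
                 n_frames = length(keep)),
            class = "parametric_image")
}

#' @export
print.parametric_image <- function(x, ...) {
  cat(sprintf(
    "%s Patlak parametric image (t* = %g min): %s grid, %d masked voxels\n",
    if (x$method == "standard") "Standard" else "Relative", x$t_star,
    paste(dim(x$slope), collapse = "x"), sum(x$mask)))
  sv <- x$slope[x$mask]
  cat(sprintf("  slope range [%.4g, %.4g] mL/min/cm^3\n", min(sv), max(sv)))
  invisible(x)
}

#' SUV-like late-uptake image
#'
#' Duration-weighted mean activity concentration over the frames inside a
#' late time window (default: the last 5 minutes of the schedule), the
#' activity-concentration surrogate for an SUV image; dose/body-weight
#' normalization is a single scalar applied uniformly and does not affect
#' any ratio statistic.
#'
#' @param img a [dynamic_image()].
#' @param window `c(start, end)` in minutes; frames fully inside it are
#'   averaged.
#' @param scale optional scalar normalization factor.
#' @return 3D array.
#' @export
suv_image <- function(img, window = NULL, scale = 1) {
  stopifnot(inherits(img, "dynamic_image"))
  sched <- img$schedule
  tend <- sched$ends[length(sched)]
  if (is.null(window)) window <- c(tend - 5, tend)
  keep <- which(sched$starts >= window[1L] - 1e-9 &
                sched$ends <= window[2L] + 1e-9)
  if (length(keep) == 0L) stop("no frames inside the SUV window")
  durs <- frame_durations(sched)[keep]
  d <- dim(img$data)
  out <- array(0, d[1:3])
  for (i in seq_along(keep))
    out <- out + durs[i] * img$data[, , , keep[i]]
  out * scale / sum(durs)
}

#' SUV ratio image at the equilibrium time
#'
#' The ratio of tissue activity to plasma activity at t*, which the
#' relative Patlak intercept b' equals in theory. The tissue value at t* is
#' taken from the frames bracketing t*: by default the per-frame normalized
#' ratios `C_T/Cp` at the two nearest frame mid-times are interpolated
#' linearly to t* (exact for data on the Patlak line); `frame = "nearest"`
#' instead uses the single frame whose mid-time is closest to t*.
#'
#' @param img a [dynamic_image()].
#' @param f plasma input function.
#' @param t_star equilibrium time (minutes).
#' @param frame `"interpolate"` (default) or `"nearest"`.
#' @return 3D array of SUVr values.
#' @export
suvr_image <- function(img, f, t_star = 40,
                       frame = c("interpolate", "nearest")) {
  frame <- match.arg(frame)
  stopifnot(inherits(img, "dynamic_image"))
  sched <- img$schedule
  if (t_star < sched$starts[1L] - 1e-9 ||
      t_star > sched$ends[length(sched)] + 1e-9)
    stop("t* is not covered by the schedule")
  mids <- frame_mids(sched)
  cp <- eval_input(f, mids)
  if (any(cp[mids >= t_star - 5] <= 0)) stop("plasma input must be positive")
  if (frame == "nearest" || t_star <= mids[1L] || t_star >= mids[length(mids)]) {
    i <- which.min(abs(mids - t_star))
    return(img$data[, , , i] / cp[i])
  }
  i1 <- max(which(mids <= t_star))
  i2 <- i1 + 1L
  a <- (t_star - mids[i1]) / (mids[i2] - mids[i1])
  (1 - a) * img$data[, , , i1] / cp[i1] + a * img$data[, , , i2] / cp[i2]
}

#' Estimate the global scaling factor alpha between Ki' and Ki
#'
#' The relative Patlak slope image is, in theory, the standard Patlak slope
#' image multiplied by a single subject-level constant alpha determined by
#' the input-function shape. This estimates alpha as the ordinary
#' least-squares slope of the voxel scatter of Ki' on Ki.
#'
#' @param ki standard-method `parametric_image`.
#' @param kip relative-method `parametric_image` of the same geometry.
#' @param mask optional logical array; default is the intersection of the
#'   two fit masks.
#' @return list with `alpha`, `intercept` and the correlation `r`.
#' @export
estimate_alpha <- function(ki, kip, mask = NULL) {
  stopifnot(inherits(ki, "parametric_image"),
            inherits(kip, "parametric_image"))
  if (!identical(dim(ki$slope), dim(kip$slope)))
    stop("parametric images must share geometry")
  if (ki$method != "standard" || kip$method != "relative")
    stop("'ki' must be a standard-method and 'kip' a relative-method image")
  if (is.null(mask)) mask <- ki$mask & kip$mask
  x <- ki$slope[mask]; y <- kip$slope[mask]
  if (length(x) < 10L) stop("need at least 10 voxels to estimate alpha")
  fit <- stats::lm.fit(cbind(1, x), y)
  list(alpha = unname(fit$coefficients[2L]),
       intercept = unname(fit$coefficients[1L]),
       r = stats::cor(x, y))
}
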