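#' ROI label set
#'
#' An integer label volume plus a label-to-name map, used to read ROI
#' statistics off image volumes.
#'
#' @param labels integer 3D array (0 = background).
#' @param names character vector; `names[i]` names label `i`.
#' @return an object of class `roi_set`.
#' @export
roi_set <- function(labels, names) {
  stopifnot(is.array(labels), length(dim(labels)) == 3L)
  counts <- tabulate(as.integer(labels), nbins = length(names))
  if (any(counts == 0L))
    stop("empty ROI label(s): ", paste(names[counts == 0L], collapse = ", "))
  structure(list(labels = labels, names = names), class = "roi_set")
}

.roi_values <- function(vol, rois, name) {
  stopifnot(inherits(rois, "roi_set"))
  i <- match(name, rois$names)
  if (is.na(i)) stop("unknown ROI: ", name)
  if (!identical(dim(vol), dim(rois$labels)))
    stop("volume and ROI geometry differ")
  v <- vol[rois$labels == i]
  if (length(v) == 0L) stop("ROI '", name, "' is empty")
  v
}

#' ROI statistics
#'
#' `roi_mean` is the arithmetic mean over a named ROI; `noise_level` is the
#' ROI sample SD divided by the ROI mean (the liver noise metric of
#' parametric image quality); `contrast_ratio` is the lesion-to-background
#' ratio of ROI means (background defaults to liver).
#'
#' @param vol 3D array.
#' @param rois an [roi_set()] with matching geometry.
#' @param name ROI name.
#' @return a single number.
#' @export
roi_mean <- function(vol, rois, name) mean(.roi_values(vol, rois, name))

#' @rdname roi_mean
#' @export
noise_level <- function(vol, rois, name = "liver") {
  v <- .roi_values(vol, rois, name)
  if (length(v) < 2L) stop("ROI must contain at least 2 voxels")
  m <- mean(v)
  if (m == 0) stop("ROI mean is zero")
  stats::sd(v) / m
}

#' @rdname roi_mean
#' @param lesion_name,background_name ROI names for the contrast ratio.
#' @export
contrast_ratio <- function(vol, rois, lesion_name,
                           background_name = "liver") {
  bg <- roi_mean(vol, rois, background_name)
  if (bg == 0) stop("background ROI mean is zero")
  roi_mean(vol, rois, lesion_name) / bg
}

#' Percentage differences
#'
#' `cr_percent_diff(a, b)` is the relative contrast-ratio difference
#' `100 (a - b) / b` (positive means `a` has the better contrast);
#' `roi_percent_diff` is the same formula for a denoised-vs-reference ROI
#' value (the Delta-Ki' quantification-accuracy metric).
#'
#' @param cr_a,cr_b contrast ratios to compare.
#' @return percent.
#' @export
cr_percent_diff <- function(cr_a, cr_b) {
  if (cr_b == 0) stop("reference contrast ratio is zero")
  100 * (cr_a - cr_b) / cr_b
}

#' @rdname cr_percent_diff
#' @param v_denoised,v_ref ROI values to compare.
#' @export
roi_percent_diff <- function(v_denoised, v_ref) {
  if (v_ref == 0) stop("reference ROI value is zero")
  100 * (v_denoised - v_ref) / v_ref
}

#' Coefficient of variation
#'
#' Sample SD divided by the mean, used to summarize the between-subject
#' spread of the global scaling factor alpha.
#'
#' @param values numeric vector, `n >= 2`, non-zero mean.
#' @return a single number.
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  m <- mean(values)
  if (m == 0) stop("mean is zero")
  stats::sd(values) / m
}

#' Linear agreement regression with CI and prediction interval
#'
#' Ordinary least-squares regression of `y` on `x` with the 95% confidence
#' interval of the slope, the per-point 95% prediction interval, and the
#' Pearson correlation with its two-sided p-value — the standard agreement
#' analysis between two quantitative imaging measures.
#'
#' @param x,y numeric vectors, `n >= 3`.
#' @return object of class `agreement`: `slope`, `intercept`, `r`, `p`,
#'   `ci95` (slope), `pi95` (n x 2 matrix), `n`, and the underlying `lm`.
#' @export
agreement_regression <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' lengths differ")
  if (length(x) < 3L) stop("need at least 3 points")
  if (stats::var(x) <= 0) stop("zero variance in x")
  df <- data.frame(x = x, y = y)
  fit <- stats::lm(y ~ x, data = df)
  ci <- stats::confint(fit, "x", level = 0.95)
  pi <- stats::predict(fit, newdata = df, interval = "prediction",
                       level = 0.95)
  ct <- stats::cor.test(x, y)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r = unname(ct$estimate), p = ct$p.value,
                 ci95 = c(ci[1L], ci[2L]),
                 pi95 = pi[, c("lwr", "upr"), drop = FALSE],
                 n = length(x), model = fit),
            class = "agreement")
}

#' @export
print.agreement <- function(x, ...) {
  cat(sprintf(
    "Agreement regression (n = %d): y = %.5g x + %.5g\n", x$n, x$slope,
    x$intercept))
  cat(sprintf("  slope 95%% CI [%.5g, %.5g], r = %.4f, p = %.3g\n",
              x$ci95[1L], x$ci95[2L], x$r, x$p))
  invisible(x)
}

#' @export
plot.agreement <- function(x, ...) {
  xv <- x$model$model$x; yv <- x$model$model$y
  o <- order(xv)
  graphics::plot(xv, yv, pch = 19, xlab = "reference", ylab = "measure", ...)
  graphics::abline(0, 1, col = "grey60", lty = 2)
  graphics::abline(x$intercept, x$slope, col = 2)
  graphics::lines(xv[o], x$pi95[o, 1L], lty = 3, col = 2)
  graphics::lines(xv[o], x$pi95[o, 2L], lty = 3, col = 2)
  invisible(x)
}

#' Bland-Altman analysis of paired measures
#'
#' Mean difference and 95% limits of agreement (mean +/- 1.96 SD of the
#' paired differences `a - b`).
#'
#' @param a,b paired numeric vectors.
#' @return object of class `bland_altman`: `mean_diff`, `loa`, `diffs`,
#'   `means`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("'a' and 'b' lengths differ")
  if (length(a) < 2L) stop("need at least 2 pairs")
  d <- a - b
  s <- stats::sd(d)
  structure(list(mean_diff = mean(d),
                 loa = c(mean(d) - 1.96 * s, mean(d) + 1.96 * s),
                 diffs = d, means = (a + b) / 2),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: mean difference %.4g, LoA [%.4g, %.4g]\n",
              x$mean_diff, x$loa[1L], x$loa[2L]))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$means, x$diffs, pch = 19, xlab = "mean of measures",
                 ylab = "difference", ...)
  graphics::abline(h = x$mean_diff, col = 2)
  graphics::abline(h = x$loa, col = 2, lty = 2)
  invisible(x)
}

#' Calibrate a relative Patlak image to absolute Ki
#'
#' Divides the relative Patlak slope image by a cohort-level global scaling
#' factor (e.g. the mean alpha of healthy subjects), turning Ki' into an
#' absolute Ki estimate without any early-time input data.
#'
#' @param kip a relative-method [fit_parametric()] image.
#' @param alpha_cohort positive scalar.
#' @return a `parametric_image` with method `"standard-calibrated"`.
#' @export
calibrate_ki <- function(kip, alpha_cohort) {
  stopifnot(inherits(kip, "parametric_image"))
  if (!is.finite(alpha_cohort) || alpha_cohort <= 0)
    stop("'alpha_cohort' must be positive")
  kip$slope <- kip$slope / alpha_cohort
  kip$method <- "standard-calibrated"
  kip
}

#' Population-based input function (PIF)
#'
#' Builds a cohort-average input curve: each subject's input is evaluated
#' on a common fine grid, normalized by its mean over an anchor window
#' (late-time blood data that exists even for a short scan), and the
#' normalized curves are averaged pointwise. Applying the PIF to a new
#' subject rescales it by that subject's measured blood mean over the same
#' window, via [scale_pif()].
#'
#' @param inputs list of `input_function`s (>= 2).
#' @param anchor_window `c(start, end)` minutes.
#' @param t_max end of the common grid (minutes); default the anchor end.
#' @param step grid step (minutes).
#' @return a [sampled_input()] whose anchor-window mean is 1, with the
#'   anchor window attached as attribute `anchor_window`.
#' @export
build_pif <- function(inputs, anchor_window, t_max = NULL, step = 0.05) {
  if (length(inputs) < 2L) stop("need at least 2 subject inputs")
  if (is.null(t_max)) t_max <- anchor_window[2L]
  grid <- seq(0, t_max, by = step)
  dur <- anchor_window[2L] - anchor_window[1L]
  if (dur <= 0) stop("empty anchor window")
  curves <- vapply(inputs, function(f) {
    anc <- integrate_input(f, anchor_window[1L], anchor_window[2L],
                           step = step) / dur
    if (anc <= 0) stop("non-positive anchor mean in a subject input")
    eval_input(f, grid) / anc
  }, numeric(length(grid)))
  pif <- sampled_input(grid[-1L], rowMeans(curves)[-1L])  # drop t=0 (Cp=0)
  attr(pif, "anchor_window") <- anchor_window
  pif
}

#' @rdname build_pif
#' @param pif a PIF from [build_pif()].
#' @param blood_mean the subject's measured blood-pool mean activity over
#'   the PIF's anchor window (kBq/mL).
#' @return the PIF rescaled to the subject, a `sampled_input`.
#' @export
scale_pif <- function(pif, blood_mean) {
  stopifnot(inherits(pif, "input_function"), pif$kind == "sampled")
  if (blood_mean <= 0) stop("'blood_mean' must be positive")
  out <- sampled_input(pif$times, pif$values * blood_mean)
  attr(out, "anchor_window") <- attr(pif, "anchor_window")
  out
}

#' Paired comparison tests
#'
#' Two-sided paired t test and Wilcoxon signed-rank test of two matched
#' samples (e.g. contrast ratios under two methods), reported together;
#' the Wilcoxon test is exact for n <= 25.
#'
#' @param a,b paired numeric vectors.
#' @return list with `t_p` and `wilcoxon_p`.
#' @export
paired_tests <- function(a, b) {
  if (length(a) != length(b)) stop("'a' and 'b' lengths differ")
  list(t_p = stats::t.test(a, b, paired = TRUE)$p.value,
       wilcoxon_p = stats::wilcox.test(a, b, paired = TRUE,
                                       exact = length(a) <= 25)$p.value)
}
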