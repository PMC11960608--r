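# Standard and relative Patlak estimation, ROI-level and voxel-wise.

# closed-form antiderivative of the Feng model, the independent quadrature
# oracle for the input integrals
.feng_integral <- function(f, a, b) {
  p <- f$params
  F <- function(t) {
    (p[["A1"]] * (t / p[["l1"]] - 1 / p[["l1"]]^2) -
       (p[["A2"]] + p[["A3"]]) / p[["l1"]]) * exp(p[["l1"]] * t) +
      p[["A2"]] / p[["l2"]] * exp(p[["l2"]] * t) +
      p[["A3"]] / p[["l3"]] * exp(p[["l3"]] * t)
  }
  F(b) - F(a)
}

test_that("Patlak coordinates match the closed-form input-integral oracle", {
  f <- feng_input()
  sched <- late_schedule(40, 4, 5)
  tc <- tissue_curve(f, kinetic_params(0.1, 0.13, 0.06, 0.05), sched)
  mids <- frame_mids(sched)
  cp <- eval_input(f, mids)
  rel <- patlak_xy(tc, f, 40, "relative")
  expect_rel_equal(rel$x,
                   vapply(mids, function(t) .feng_integral(f, 40, t),
                          numeric(1)) / cp, 1e-6)
  expect_equal(rel$y, tc$values / cp)
  # the standard abscissa includes the sharp bolus, where the fixed-step
  # trapezoid is accurate to its O(h^2) truncation only
  std <- patlak_xy(tc, f, 40, "standard")
  expect_rel_equal(std$x,
                   vapply(mids, function(t) .feng_integral(f, 0, t),
                          numeric(1)) / cp, 1e-3)
})

test_that("relative abscissa under a constant input is elapsed time", {
  const <- sampled_input(c(0.001, 1000), c(3, 3))
  sched <- late_schedule(40, 4, 5)
  tc <- tissue_curve(const, kinetic_params(0.1, 0.2, 0.05), sched)
  xy <- patlak_xy(tc, const, 40, "relative")
  expect_rel_equal(xy$x, frame_mids(sched) - 40, 1e-9)
})

test_that("frames before t* are dropped and degenerate fits error", {
  f <- feng_input()
  sched <- default_schedule_1h()
  tc <- tissue_curve(f, kinetic_params(0.1, 0.13, 0.06), sched)
  xy <- patlak_xy(tc, f, 40, "standard")
  expect_length(xy$x, 4L)            # only the frames starting at >= 40 min
  expect_true(all(xy$t >= 42.5))
  expect_error(patlak_xy(tc, f, 58), "at least 2 frames")
})

test_that("an exact Patlak line is recovered to machine precision", {
  f <- feng_input()
  sched <- late_schedule(40, 4, 5)
  base <- tissue_curve(f, kinetic_params(0.1, 0.13, 0.06), sched)
  for (method in c("standard", "relative")) {
    xy <- patlak_xy(base, f, 40, method)
    exact <- base
    exact$values <- (0.01 * xy$x + 0.5) * eval_input(f, frame_mids(sched))
    fit <- patlak(exact, f, 40, method)
    expect_rel_equal(coef(fit)[["slope"]], 0.01, 1e-11)
    expect_rel_equal(coef(fit)[["intercept"]], 0.5, 1e-11)
    expect_equal(fit$r2, 1)
  }
})

test_that("a no-influx tissue fits zero slope and intercept vb", {
  # linear input: frame averages equal mid-time samples exactly, so the
  # blood-only curve sits exactly on y = vb
  lin <- sampled_input(c(0.001, 100), c(30, 10))
  sched <- late_schedule(40, 4, 5)
  tc <- tissue_curve(lin, kinetic_params(0, 1, 0, vb = 0.25), sched)
  fit <- patlak(tc, lin, 40, "standard")
  expect_lt(abs(coef(fit)[["slope"]]), 1e-9)
  expect_rel_equal(coef(fit)[["intercept"]], 0.25, 1e-6)
})

test_that("a fitted relative intercept equals the SUV ratio at t*", {
  f <- feng_input()
  sched <- late_schedule(40, 4, 5)
  base <- tissue_curve(f, kinetic_params(0.3, 0.6, 0.15), sched)
  xy <- patlak_xy(base, f, 40, "relative")
  exact <- base
  exact$values <- (0.04 * xy$x + 1.3) * eval_input(f, frame_mids(sched))
  fit <- patlak(exact, f, 40, "relative")
  # at t* the relative integral vanishes, so C_T(t*)/Cp(t*) is the line's
  # value at x = 0, i.e. the intercept
  expect_rel_equal(coef(fit)[["intercept"]], 1.3, 1e-9)
})

test_that("patlak objects support the standard modelling methods", {
  f <- feng_input()
  tc <- tissue_curve(f, kinetic_params(0.1, 0.13, 0.06),
                     late_schedule(40, 4, 5))
  fit <- patlak(tc, f, 40, "standard")
  expect_s3_class(fit, "patlak")
  expect_named(coef(fit), c("intercept", "slope"))
  expect_equal(fitted(fit) + residuals(fit), fit$y)
  expect_equal(predict(fit), fitted(fit))
  expect_equal(predict(fit, newdata = 0), coef(fit)[["intercept"]])
  expect_output(print(fit), "Standard Patlak")
  expect_output(print(summary(fit)), "95% CI")
  dur <- patlak(tc, f, 40, "standard", weights = "duration")
  # equal-duration late frames: duration weighting changes nothing
  expect_equal(coef(dur), coef(fit))
})

test_that("voxel-wise fitting agrees with per-voxel ROI fits", {
  img <- small_noisy_late()
  f <- feng_input()
  pim <- fit_parametric(img, f, 40, "relative")
  midx <- which(pim$mask)
  set.seed(4)
  pick <- sample(midx, 100L)
  d <- dim(img$data)
  mat <- matrix(img$data, prod(d[1:3]), d[4L])
  for (v in pick) {
    tc <- list(values = mat[v, ], schedule = img$schedule)
    fit <- patlak(tc, f, 40, "relative")
    expect_rel_equal(pim$slope[v], coef(fit)[["slope"]], 1e-10)
    expect_rel_equal(pim$intercept[v], coef(fit)[["intercept"]], 1e-10)
  }
})

test_that("noise-free parametric maps are constant within each organ", {
  ph <- small_phantom()
  img <- small_noisefree_late()
  pim <- fit_parametric(img, feng_input(), 40, "standard")
  for (i in seq_along(ph$organ_names)) {
    if (ph$organ_names[i] == "blood_pool") next
    v <- pim$slope[ph$labels == i & pim$mask]
    expect_lt(stats::sd(v) / abs(mean(v)), 0.01)
  }
})

test_that("SUV images average the requested late window", {
  img <- small_noisefree_late()
  last <- img$data[, , , 4L]
  expect_equal(suv_image(img, c(55, 60)), last)
  two <- suv_image(img, c(50, 60))
  expect_equal(two, (img$data[, , , 3L] + last) / 2)
  expect_error(suv_image(img, c(10, 20)), "no frames")
  # blood-pool SUV equals the frame-averaged input
  ph <- small_phantom()
  f <- feng_input()
  grid <- seq(55, 60, by = 0.01)
  cp_avg <- mean(eval_input(f, grid))
  bp <- suv_image(img)[ph$labels == which(ph$organ_names == "blood_pool")]
  expect_rel_equal(mean(bp), cp_avg, 1e-3)
})

test_that("SUVr is unity in blood and invariant to joint rescaling", {
  ph <- small_phantom()
  img <- small_noisefree_late()
  f <- feng_input()
  sr <- suvr_image(img, f, 41)
  bp <- sr[ph$labels == which(ph$organ_names == "blood_pool")]
  expect_rel_equal(bp, rep(1, length(bp)), 0.02)
  # doubling the image alone doubles SUVr; doubling input too restores it
  img2 <- img; img2$data <- img$data * 2
  mids <- frame_mids(img$schedule)
  f2 <- sampled_input(mids, 2 * eval_input(f, mids))
  sr_img2 <- suvr_image(img2, f, 41)
  expect_rel_equal(sr_img2, 2 * sr, 1e-12)
  sr_both <- suvr_image(img2, f2, 42.5, frame = "nearest")
  sr_ref <- suvr_image(img, sampled_input(mids, eval_input(f, mids)),
                       42.5, frame = "nearest")
  expect_rel_equal(sr_both, sr_ref, 1e-12)
})

test_that("alpha estimation recovers constructed scalings", {
  base <- fit_parametric(small_noisefree_late(), feng_input(), 40,
                         "standard")
  kip <- base
  kip$method <- "relative"
  kip$slope <- 1.3 * base$slope
  a <- estimate_alpha(base, kip)
  expect_rel_equal(a$alpha, 1.3, 1e-9)
  expect_lt(abs(a$intercept), 1e-12)
  expect_equal(a$r, 1)
  ident <- base
  ident$method <- "relative"
  expect_rel_equal(estimate_alpha(base, ident)$alpha, 1, 1e-12)
  expect_error(estimate_alpha(base, base), "relative-method")
})
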