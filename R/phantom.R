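#' Default organ kinetics for the total-body phantom
#'
#' Literature-typical FDG rate constants for the major organs sampled in
#' total-body dynamic studies, plus three hypermetabolic lesions (lung,
#' liver, pelvis) whose net influx rate exceeds that of the liver.
#' `blood_pool` is treated specially by the simulator: its voxels carry the
#' plasma input itself.
#'
#' @return named list of [kinetic_params()], one entry per organ.
#' @export
default_organ_params <- function() {
  list(
    blood_pool  = kinetic_params(0,    1,    0,    vb = 1 - 1e-9),
    liver       = kinetic_params(0.85, 0.98, 0.010, vb = 0.10),
    lung        = kinetic_params(0.02, 0.25, 0.012, vb = 0.14),
    spleen      = kinetic_params(1.00, 1.30, 0.005, vb = 0.20),
    muscle      = kinetic_params(0.03, 0.25, 0.020, vb = 0.02),
    gray_matter = kinetic_params(0.10, 0.13, 0.060, vb = 0.05),
    bone_marrow = kinetic_params(0.09, 0.30, 0.030, vb = 0.04),
    myocardium  = kinetic_params(0.60, 1.20, 0.100, vb = 0.25),
    lesion_1    = kinetic_params(0.35, 0.60, 0.180, vb = 0.05),
    lesion_2    = kinetic_params(0.30, 0.65, 0.120, vb = 0.05),
    lesion_3    = kinetic_params(0.40, 0.70, 0.150, vb = 0.05)
  )
}

# logical ellipsoid mask; centre and semi-axes in fractions of grid dims
.ellipsoid <- function(shape, centre, semi) {
  cx <- centre * shape; ax <- pmax(semi * shape, 0.5)
  dx2 <- ((seq_len(shape[1L]) - cx[1L]) / ax[1L])^2
  dy2 <- ((seq_len(shape[2L]) - cx[2L]) / ax[2L])^2
  dz2 <- ((seq_len(shape[3L]) - cx[3L]) / ax[3L])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
}

# z-axis cylinder; xy centre/radius in fractions of x-dim, z range in
# fractions of z-dim
.cylinder <- function(shape, cxy, r_frac, z_frac) {
  cx <- cxy * shape[1:2]; r <- max(r_frac * shape[1L], 0.6)
  dx2 <- (seq_len(shape[1L]) - cx[1L])^2
  dy2 <- (seq_len(shape[2L]) - cx[2L])^2
  disc <- outer(dx2, dy2, `+`) <= r^2
  z <- seq_len(shape[3L])
  zin <- z >= z_frac[1L] * shape[3L] & z <= z_frac[2L] * shape[3L]
  outer(disc, zin, `&`)
}

#' Build a deterministic total-body phantom label volume
#'
#' Composes ellipsoids and cylinders into an integer organ label map at the
#' requested grid: a torso of background muscle, a gray-matter head, two
#' lungs, myocardium, liver, spleen, a spinal bone-marrow column, an aortic
#' blood pool, and spherical lesions (radius 1--3 voxels at the default
#' grid) embedded in lung, liver and pelvis. Later organs overwrite earlier
#' ones where shapes overlap. The construction is deterministic: the same
#' configuration always yields the same volume.
#'
#' @param shape integer grid dimensions, default `c(48, 48, 96)` (a
#'   desk-scale stand-in for the full 150 x 150 x 486 total-body grid).
#' @param voxel_mm isotropic voxel edge (mm), default 4.
#' @param n_lesions number of lesions, 1--3; at least one is required.
#' @param organ_params named list of [kinetic_params()] as in
#'   [default_organ_params()].
#' @return an object of class `phantom_spec` with fields `labels` (integer
#'   3D array, 0 = background air), `organ_params`, `organ_names` (label ->
#'   name), `voxel_mm`, `shape`.
#' @export
build_phantom <- function(shape = c(48, 48, 96), voxel_mm = 4,
                          n_lesions = 3, organ_params = default_organ_params()) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 8L))
  if (n_lesions < 1L)
    stop("the phantom must contain at least one lesion")
  if (n_lesions > 3L) stop("at most 3 lesions are defined")
  organs <- c("blood_pool", "liver", "lung", "spleen", "muscle",
              "gray_matter", "bone_marrow", "myocardium",
              paste0("lesion_", seq_len(n_lesions)))
  missing <- setdiff(organs, names(organ_params))
  if (length(missing))
    stop("missing kinetic parameters for: ", paste(missing, collapse = ", "))
  liver_ki <- ki_true(organ_params$liver)
  les_ki <- vapply(paste0("lesion_", seq_len(n_lesions)),
                   function(nm) ki_true(organ_params[[nm]]), numeric(1))
  if (!any(les_ki > liver_ki))
    stop("at least one lesion must have Ki greater than the liver")

  names_vec <- c("muscle", "gray_matter", "lung", "myocardium", "liver",
                 "spleen", "bone_marrow", "blood_pool",
                 paste0("lesion_", seq_len(n_lesions)))
  masks <- list(
    muscle      = .ellipsoid(shape, c(0.50, 0.50, 0.60), c(0.40, 0.30, 0.40)),
    gray_matter = .ellipsoid(shape, c(0.50, 0.50, 0.10), c(0.16, 0.16, 0.075)),
    lung        = .ellipsoid(shape, c(0.32, 0.46, 0.345), c(0.14, 0.12, 0.10)) |
                  .ellipsoid(shape, c(0.68, 0.46, 0.345), c(0.14, 0.12, 0.10)),
    myocardium  = .ellipsoid(shape, c(0.55, 0.42, 0.40), c(0.09, 0.09, 0.055)),
    liver       = .ellipsoid(shape, c(0.35, 0.50, 0.545), c(0.19, 0.15, 0.095)),
    spleen      = .ellipsoid(shape, c(0.70, 0.54, 0.53), c(0.09, 0.08, 0.055)),
    bone_marrow = .cylinder(shape, c(0.50, 0.72), 0.05, c(0.25, 0.85)),
    blood_pool  = .cylinder(shape, c(0.50, 0.60), 0.045, c(0.28, 0.75))
  )
  lesion_geom <- list(
    lesion_1 = list(c(0.32, 0.46, 0.33), 0.065),
    lesion_2 = list(c(0.40, 0.54, 0.56), 0.045),
    lesion_3 = list(c(0.55, 0.50, 0.80), 0.060)
  )
  for (nm in paste0("lesion_", seq_len(n_lesions))) {
    g <- lesion_geom[[nm]]
    masks[[nm]] <- .ellipsoid(shape, g[[1L]],
                              rep(g[[2L]], 3) * shape[1L] / shape)
  }
  labels <- array(0L, shape)
  for (i in seq_along(names_vec)) labels[masks[[names_vec[i]]]] <- i
  counts <- tabulate(labels, nbins = length(names_vec))
  if (any(counts == 0L))
    stop("empty organ(s) at this grid: ",
         paste(names_vec[counts == 0L], collapse = ", "))
  structure(list(labels = labels,
                 organ_params = organ_params[names_vec],
                 organ_names = names_vec,
                 voxel_mm = voxel_mm,
                 shape = shape),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("Total-body phantom: %s grid, %g mm voxels\n",
              paste(x$shape, collapse = "x"), x$voxel_mm))
  counts <- tabulate(x$labels, nbins = length(x$organ_names))
  for (i in seq_along(x$organ_names))
    cat(sprintf("  %2d %-12s %6d voxels  Ki=%.4g\n", i, x$organ_names[i],
                counts[i], ki_true(x$organ_params[[x$organ_names[i]]])))
  invisible(x)
}

#' Dynamic PET image container
#'
#' Bundles a 4D activity array (x, y, z, frame; decay-corrected kBq/mL)
#' with its frame schedule and voxel size. All fitting functions consume
#' this unit.
#'
#' @param data 4D numeric array.
#' @param schedule a [frame_schedule()] whose length matches the 4th dim.
#' @param voxel_mm isotropic voxel edge (mm).
#' @return an object of class `dynamic_image`.
#' @export
dynamic_image <- function(data, schedule, voxel_mm = 4) {
  stopifnot(inherits(schedule, "frame_schedule"))
  d <- dim(data)
  if (length(d) != 4L || d[4L] != length(schedule))
    stop("'data' must be 4D with one volume per schedule frame")
  if (any(!is.finite(data))) stop("image values must be finite")
  structure(list(data = data, schedule = schedule, voxel_mm = voxel_mm),
            class = "dynamic_image")
}

#' @export
print.dynamic_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Dynamic PET image: %dx%dx%d voxels, %d frames [%g, %g] min\n",
              d[1L], d[2L], d[3L], d[4L], x$schedule$starts[1L],
              x$schedule$ends[length(x$schedule)]))
  invisible(x)
}

#' Simulate a dynamic PET acquisition of a phantom
#'
#' Generates the noise-free organ time-activity curves with
#' [tissue_curve()], broadcasts them over the label volume (blood-pool
#' voxels carry the frame-averaged plasma input itself), and adds
#' count-scaled Gaussian noise: the per-frame noise SD is
#' `noise_scale * sqrt(mean_activity / duration)`, where `mean_activity`
#' is the noise-free frame mean over body voxels. This reproduces the
#' characteristic duration and activity dependence of reconstructed PET
#' noise (shorter frames are noisier) without modelling the projection
#' domain. Negative noisy values are kept; masking is left to the fitting
#' stage.
#'
#' @param spec a [build_phantom()] result.
#' @param f plasma input function.
#' @param sched a [frame_schedule()].
#' @param noise_scale noise magnitude knob, `>= 0`; 0 gives noise-free data.
#' @param seed integer seed for the noise; reproducible given the seed.
#' @param step kinetic integration step (minutes).
#' @return a [dynamic_image()].
#' @export
simulate_dynamic <- function(spec, f, sched, noise_scale = 0, seed = NULL,
                             step = 0.05) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (noise_scale < 0) stop("'noise_scale' must be non-negative")
  nf <- length(sched)
  nlab <- length(spec$organ_names)
  curves <- matrix(0, nlab, nf)
  tmax <- sched$ends[nf]
  grid <- seq(0, tmax, length.out = ceiling(tmax / step) + 1L)
  cp_frames <- .frame_average(grid, eval_input(f, grid), sched)
  for (i in seq_len(nlab)) {
    nm <- spec$organ_names[i]
    curves[i, ] <- if (nm == "blood_pool") cp_frames else
      tissue_curve(f, spec$organ_params[[nm]], sched, step = step)$values
  }
  lab <- as.integer(spec$labels)
  nvox <- length(lab)
  data <- array(0, c(spec$shape, nf))
  lookup <- rbind(0, curves)  # row 1 = background
  body <- lab > 0L
  for (fr in seq_len(nf))
    data[, , , fr] <- lookup[lab + 1L, fr]
  if (noise_scale > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
      set.seed(seed)
    }
    durs <- frame_durations(sched)
    for (fr in seq_len(nf)) {
      mu <- mean(data[, , , fr][body])
      sdf <- noise_scale * sqrt(max(mu, 0) / durs[fr])
      if (sdf > 0)
        data[, , , fr] <- data[, , , fr] + stats::rnorm(nvox, sd = sdf)
    }
  }
  dynamic_image(data, sched, spec$voxel_mm)
}

#' ROI label set of a phantom
#'
#' @param spec a [build_phantom()] result.
#' @return an [roi_set()] over the phantom organ labels.
#' @export
phantom_rois <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  roi_set(spec$labels, spec$organ_names)
}
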