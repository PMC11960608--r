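#' Composite late frames and their mean label
#'
#' Groups the frames of a (late-time) dynamic image into `nz` contiguous,
#' equal-sized composite images z_1..z_nz and forms their arithmetic mean
#' z_a. The composites are the image prior of the kernel denoiser and the
#' mean is the self-supervised training label. With the default 4 x 5-min
#' late schedule each composite is one 5-min frame.
#'
#' @param img a [dynamic_image()].
#' @param nz number of composites (default 4); must divide the frame count.
#' @return an object of class `composite_set`: `frames` (list of 3D
#'   arrays), `mean_image`, `nz`, plus the grid dimensions.
#' @export
make_composites <- function(img, nz = 4) {
  stopifnot(inherits(img, "dynamic_image"))
  nf <- dim(img$data)[4L]
  if (nz < 2L) stop("'nz' must be at least 2")
  if (nf %% nz != 0L)
    stop("frame count (", nf, ") is not divisible into ", nz, " groups")
  g <- nf %/% nz
  frames <- lapply(seq_len(nz), function(m) {
    idx <- ((m - 1L) * g + 1L):(m * g)
    out <- img$data[, , , idx[1L]]
    for (i in idx[-1L]) out <- out + img$data[, , , i]
    out / g
  })
  mean_image <- Reduce(`+`, frames) / nz
  structure(list(frames = frames, mean_image = mean_image, nz = nz,
                 dim = dim(img$data)[1:3]),
            class = "composite_set")
}

# per-composite z-scored feature matrix over the masked voxels
.kernel_features <- function(Z, midx) {
  vapply(Z$frames, function(fr) {
    v <- fr[midx]
    s <- stats::sd(v)
    if (s <= 0) s <- 1
    (v - mean(v)) / s
  }, numeric(length(midx)))
}

.kernel_check <- function(k, radius) {
  if (k < 1L) stop("'k' must be at least 1")
  if (k > (2L * radius + 1L)^3L)
    stop("'k' exceeds the spatial search window (", (2L * radius + 1L)^3L,
         " voxels); enlarge 'radius'")
}

# row-normalized Gaussian weights from squared distances (k x N)
.kernel_weights <- function(d2, sigma, nfeat) {
  W <- exp(-d2 / (2 * sigma^2 * nfeat))
  sweep(W, 2L, colSums(W), `/`)
}

.kernel_model <- function(idx, pad, W, theta, midx, dim, k, radius, sigma,
                          trained, losses = NULL) {
  structure(list(idx = idx, pad = pad, weights = W, theta = theta,
                 mask_idx = midx, dim = dim, k = k, radius = radius,
                 sigma = sigma, trained = trained, losses = losses),
            class = "kernel_model")
}

#' @export
print.kernel_model <- function(x, ...) {
  cat(sprintf(
    "%s kernel denoiser: k=%d, window %dx%dx%d, sigma=%g, %d voxels\n",
    if (x$trained) "Deep (trained)" else "Conventional", x$k,
    2L * x$radius + 1L, 2L * x$radius + 1L, 2L * x$radius + 1L,
    x$sigma, length(x$mask_idx)))
  if (!is.null(x$losses))
    cat(sprintf("  training loss %.6g -> %.6g over %d iterations\n",
                x$losses[1L], x$losses[length(x$losses)],
                length(x$losses) - 1L))
  invisible(x)
}

#' Conventional kernel denoiser
#'
#' The empirical (non-trained) baseline: each voxel's feature vector is its
#' `nz` composite values (z-scored per composite), neighbours are the `k`
#' nearest in feature space within a cubic spatial search window, and the
#' weights are row-normalized Gaussians of the feature distances. The
#' resulting operator is row-stochastic, so it preserves constants and acts
#' as a feature-adaptive nonlocal mean.
#'
#' @param Z a [make_composites()] result.
#' @param k neighbourhood size (default 200).
#' @param sigma Gaussian bandwidth in z-scored feature units (default 1).
#' @param radius half-width of the spatial search window in voxels
#'   (default 4, i.e. 9 x 9 x 9).
#' @param mask logical 3D array of voxels the kernel operates on; default
#'   all voxels.
#' @return an object of class `kernel_model`.
#' @export
build_conventional_kernel <- function(Z, k = 200, sigma = 1, radius = 4,
                                      mask = NULL) {
  stopifnot(inherits(Z, "composite_set"))
  .kernel_check(k, radius)
  if (is.null(mask)) mask <- array(TRUE, Z$dim)
  midx <- which(mask)
  F <- .kernel_features(Z, midx)
  nn <- kk_knn(t(F), midx, as.integer(Z$dim), as.integer(radius),
               as.integer(k))
  W <- .kernel_weights(nn$d2, sigma, ncol(F))
  .kernel_model(nn$idx, nn$pad, W, theta = NULL, midx, Z$dim, k, radius,
                sigma, trained = FALSE)
}

# forward pass of the feature transform: residual two-layer perceptron
.dk_forward <- function(F, th) {
  H <- tanh(sweep(F %*% t(th$W1), 2L, th$b1, `+`))
  G <- F + H %*% t(th$W2)
  G <- sweep(G, 2L, th$b2, `+`)
  list(G = G, H = H)
}

#' Train the self-supervised deep-kernel denoiser
#'
#' Learns a per-voxel feature transform (a small residual two-layer
#' perceptron on the nz-vector of composite values) whose induced
#' row-normalized Gaussian k-NN kernel K minimizes the self-supervised
#' objective
#' \deqn{\sum_{m=1}^{n_z} \| z_a - K(\theta; Z)\, z_m \|^2,}
#' i.e. each noisy composite frame, passed through the kernel, should
#' reproduce the mean image z_a (the clean training label). The neighbour
#' topology is built once from the raw z-scored features and frozen; only
#' the Gaussian weights are differentiated. The transform is initialized at
#' the identity, so iteration 0 reproduces the conventional kernel, and is
#' optimized with Adam. Training is seeded and single-threaded, hence
#' bit-reproducible.
#'
#' @inheritParams build_conventional_kernel
#' @param iters training iterations (default 300).
#' @param lr learning rate (default 1e-3).
#' @param width hidden width of the feature transform (default 8).
#' @param seed integer seed for the weight initialization.
#' @return a trained `kernel_model`; `$losses` traces the objective from
#'   iteration 0 (conventional kernel) to the final iterate.
#' @export
train_deep_kernel <- function(Z, k = 200, sigma = 1, radius = 4,
                              mask = NULL, iters = 300, lr = 1e-3,
                              width = 8, seed = 1) {
  stopifnot(inherits(Z, "composite_set"))
  .kernel_check(k, radius)
  if (is.null(mask)) mask <- array(TRUE, Z$dim)
  midx <- which(mask)
  F <- .kernel_features(Z, midx)
  D <- ncol(F)
  nn <- kk_knn(t(F), midx, as.integer(Z$dim), as.integer(radius),
               as.integer(k))
  ZT <- t(vapply(Z$frames, function(fr) fr[midx], numeric(length(midx))))
  za <- Z$mean_image[midx]
  den <- 2 * sigma^2 * D

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  th <- list(W1 = matrix(stats::rnorm(width * D, sd = 1 / sqrt(D)), width, D),
             b1 = numeric(width),
             W2 = matrix(0, D, width),   # residual branch off => identity
             b2 = numeric(D))
  mom <- lapply(th, function(p) p * 0)
  vel <- lapply(th, function(p) p * 0)
  b1a <- 0.9; b2a <- 0.999; eps <- 1e-8
  losses <- numeric(iters + 1L)
  for (it in seq_len(iters + 1L)) {
    fw <- .dk_forward(F, th)
    lg <- kk_loss_grad(t(fw$G), nn$idx, nn$pad, ZT, za, den)
    if (!is.finite(lg$loss))
      stop("non-finite training loss at iteration ", it - 1L,
           " (sigma too small or degenerate features)")
    losses[it] <- lg$loss
    if (it > iters) break
    dG <- t(lg$dG)
    grads <- list(W1 = NULL, b1 = NULL, W2 = t(dG) %*% fw$H,
                  b2 = colSums(dG))
    dH <- (dG %*% th$W2) * (1 - fw$H^2)
    grads$W1 <- t(dH) %*% F
    grads$b1 <- colSums(dH)
    for (nm in names(th)) {
      mom[[nm]] <- b1a * mom[[nm]] + (1 - b1a) * grads[[nm]]
      vel[[nm]] <- b2a * vel[[nm]] + (1 - b2a) * grads[[nm]]^2
      mhat <- mom[[nm]] / (1 - b1a^it)
      vhat <- vel[[nm]] / (1 - b2a^it)
      th[[nm]] <- th[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  G <- .dk_forward(F, th)$G
  W <- .kernel_weights(kk_edge_dist2(t(G), nn$idx, nn$pad), sigma, D)
  .kernel_model(nn$idx, nn$pad, W, theta = th, midx, Z$dim, k, radius,
                sigma, trained = TRUE, losses = losses)
}

#' Apply a kernel denoiser to a volume
#'
#' Row-stochastic neighbour averaging: each masked voxel becomes the
#' weighted mean of its k feature-space neighbours. The operator is linear
#' and preserves constants; voxels outside the kernel's mask pass through
#' unchanged.
#'
#' @param model a `kernel_model`.
#' @param vol 3D array matching the model geometry.
#' @return the denoised 3D array.
#' @export
apply_kernel <- function(model, vol) {
  stopifnot(inherits(model, "kernel_model"))
  if (!identical(dim(vol), model$dim))
    stop("volume shape does not match the kernel model")
  out <- vol
  out[model$mask_idx] <- kk_apply(model$weights, model$idx,
                                  vol[model$mask_idx])
  out
}

#' Self-supervised objective of a kernel model
#'
#' Evaluates the training objective (sum over composites of the squared
#' distance between the kernel-filtered composite and the mean image) for
#' any kernel model, trained or conventional, enabling direct comparison.
#'
#' @param model a `kernel_model`.
#' @param Z the [make_composites()] set it was built from.
#' @return a single number.
#' @export
kernel_objective <- function(model, Z) {
  stopifnot(inherits(model, "kernel_model"), inherits(Z, "composite_set"))
  za <- Z$mean_image[model$mask_idx]
  sum(vapply(Z$frames, function(fr) {
    y <- kk_apply(model$weights, model$idx, fr[model$mask_idx])
    sum((za - y)^2)
  }, numeric(1)))
}

#' Denoised relative Patlak parametric imaging
#'
#' The full short-scan pipeline: split the late frames (start >= t*) into
#' nz composites, train the deep kernel (or build the conventional one),
#' apply it to each late dynamic frame, and fit the parametric image from
#' the denoised frames. Optionally the kernel is also applied to the fitted
#' slope/intercept maps (`post_smooth_parametric`).
#'
#' @param img a [dynamic_image()].
#' @param f plasma input function.
#' @inheritParams fit_parametric
#' @inheritParams train_deep_kernel
#' @param nz number of composite frames (default 4).
#' @param kernel `"deep"` (trained, default) or `"conventional"`.
#' @param kernel_mask logical 3D array, the domain the kernel operates on;
#'   default keeps voxels whose composite-mean activity exceeds 2% of its
#'   maximum (a noise-robust body mask: averaging the composites suppresses
#'   background noise before thresholding). Voxels outside it pass through
#'   the denoiser unchanged.
#' @param post_smooth_parametric also filter the fitted parameter maps
#'   (default `FALSE`).
#' @return list of class `denoise_fit`: `parametric` (the denoised
#'   [fit_parametric()] result), `model` (the kernel), `mask`.
#' @export
denoise_parametric <- function(img, f, t_star = 40,
                               method = c("standard", "relative"),
                               mask = NULL, nz = 4,
                               kernel = c("deep", "conventional"),
                               kernel_mask = NULL,
                               k = 200, sigma = 1, radius = 4,
                               iters = 300, lr = 1e-3, width = 8, seed = 1,
                               post_smooth_parametric = FALSE) {
  method <- match.arg(method)
  kernel <- match.arg(kernel)
  stopifnot(inherits(img, "dynamic_image"))
  if (is.null(mask)) mask <- default_mask(img)
  keep <- which(img$schedule$starts >= t_star - 1e-9)
  if (length(keep) < 2L) stop("need at least 2 frames at or after t*")
  late <- dynamic_image(img$data[, , , keep, drop = FALSE],
                        frame_schedule(img$schedule$starts[keep],
                                       img$schedule$ends[keep]),
                        img$voxel_mm)
  Z <- make_composites(late, nz = nz)
  if (is.null(kernel_mask))
    kernel_mask <- Z$mean_image > 0.02 * max(Z$mean_image)
  model <- if (kernel == "deep")
    train_deep_kernel(Z, k = k, sigma = sigma, radius = radius,
                      mask = kernel_mask, iters = iters, lr = lr,
                      width = width, seed = seed)
  else
    build_conventional_kernel(Z, k = k, sigma = sigma, radius = radius,
                              mask = kernel_mask)
  den <- late
  for (i in seq_along(keep))
    den$data[, , , i] <- apply_kernel(model, late$data[, , , i])
  pim <- fit_parametric(den, f, t_star = t_star, method = method,
                        mask = mask)
  if (post_smooth_parametric) {
    pim$slope <- apply_kernel(model, pim$slope)
    pim$intercept <- apply_kernel(model, pim$intercept)
  }
  structure(list(parametric = pim, model = model, mask = mask),
            class = "denoise_fit")
}

#' @export
print.denoise_fit <- function(x, ...) {
  print(x$model)
  print(x$parametric)
  invisible(x)
}
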