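# tiny rolling hash of a string (mod 2^32), used to stamp sidecars with a
# config fingerprint
.config_hash <- function(x) {
  h <- 5381
  for (b in utf8ToInt(x)) h <- (h * 33 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

.sidecar_path <- function(path) sub("\\.nii(\\.gz)?$", ".json", path)

.write_sidecar <- function(path, fields) {
  fields$package_version <- as.character(utils::packageVersion("relpatlak"))
  fields$config_hash <- .config_hash(jsonlite::toJSON(fields, auto_unbox = TRUE))
  jsonlite::write_json(fields, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
}

#' Read and write dynamic PET images as NIfTI + JSON sidecar
#'
#' A dynamic image is stored as a 4D NIfTI volume (decay-corrected kBq/mL)
#' with a JSON sidecar carrying the frame schedule in minutes
#' (`starts_min`, `ends_min`), the voxel size, and any simulation metadata.
#' The round trip is lossless for data, schedule and voxel size.
#'
#' @param img a [dynamic_image()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param extra named list merged into the sidecar (e.g. `seed`,
#'   `noise_scale`).
#' @return `write_dynamic` returns `path` invisibly; `read_dynamic`
#'   returns a [dynamic_image()].
#' @export
write_dynamic <- function(img, path, extra = list()) {
  stopifnot(inherits(img, "dynamic_image"))
  RNifti::writeNifti(RNifti::asNifti(img$data,
                                     pixdim = rep(img$voxel_mm, 3)), path)
  .write_sidecar(path, c(list(starts_min = img$schedule$starts,
                              ends_min = img$schedule$ends,
                              voxel_mm = img$voxel_mm), extra))
  invisible(path)
}

#' @rdname write_dynamic
#' @export
read_dynamic <- function(path) {
  sc_path <- .sidecar_path(path)
  if (!file.exists(sc_path))
    stop("missing JSON sidecar for '", path, "' (expected ", sc_path, ")")
  sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  data <- array(as.numeric(RNifti::readNifti(path)),
                dim = dim(RNifti::readNifti(path)))
  if (length(dim(data)) != 4L || dim(data)[4L] != length(sc$starts_min))
    stop("frame count mismatch between '", path, "' and its sidecar")
  dynamic_image(data, frame_schedule(sc$starts_min, sc$ends_min),
                voxel_mm = sc$voxel_mm)
}

#' Write a parametric image pair
#'
#' Writes the slope and intercept volumes as two NIfTI files
#' (`<prefix>_slope.nii.gz`, `<prefix>_intercept.nii.gz`) plus a JSON
#' sidecar recording method, t*, and the mask size.
#'
#' @param pimg a [fit_parametric()] result.
#' @param prefix output path prefix.
#' @return the sidecar path, invisibly.
#' @export
write_parametric <- function(pimg, prefix) {
  stopifnot(inherits(pimg, "parametric_image"))
  slope_path <- paste0(prefix, "_slope.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(pimg$slope,
                                     pixdim = rep(pimg$voxel_mm, 3)),
                     slope_path)
  RNifti::writeNifti(RNifti::asNifti(pimg$intercept,
                                     pixdim = rep(pimg$voxel_mm, 3)),
                     paste0(prefix, "_intercept.nii.gz"))
  .write_sidecar(slope_path,
                 list(method = pimg$method, t_star_min = pimg$t_star,
                      mask_rule = "last_frame_gt_1pct_max",
                      n_mask_voxels = sum(pimg$mask),
                      voxel_mm = pimg$voxel_mm))
  invisible(.sidecar_path(slope_path))
}

#' Read and write plasma input tables
#'
#' The serialized form of an image-derived input function: 2-column
#' delimited text (time in minutes, activity in kBq/mL), with or without a
#' header line; comma, tab or whitespace separated.
#'
#' @param path file path.
#' @return `read_input_table` returns a [sampled_input()].
#' @export
read_input_table <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  probe <- strsplit(trimws(first), if (sep == ",") "," else "[ \t]+")[[1L]]
  header <- suppressWarnings(any(is.na(as.numeric(probe))))
  tab <- utils::read.table(path, header = header, sep = sep)
  if (ncol(tab) < 2L) stop("input table needs 2 columns (time, activity)")
  if (nrow(tab) < 2L) stop("input table needs at least 2 rows")
  if (any(diff(tab[[1L]]) <= 0))
    stop("input table times must be strictly increasing")
  sampled_input(tab[[1L]], tab[[2L]])
}

#' @rdname read_input_table
#' @param f a sampled `input_function`.
#' @export
write_input_table <- function(f, path) {
  stopifnot(inherits(f, "input_function"), f$kind == "sampled")
  utils::write.csv(data.frame(time_min = f$times, kBq_per_mL = f$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a frame schedule from CSV
#'
#' Accepts the 2-column form (start, end in minutes) and, with a warning,
#' the legacy 3-column dialect whose first column is a frame index.
#'
#' @param path file path.
#' @return a [frame_schedule()].
#' @export
read_schedule <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  probe <- strsplit(trimws(first), if (sep == ",") "," else "[ \t]+")[[1L]]
  header <- suppressWarnings(any(is.na(as.numeric(probe))))
  tab <- utils::read.table(path, header = header, sep = sep)
  if (ncol(tab) == 3L) {
    warning("legacy 3-column schedule file; ignoring the first column")
    tab <- tab[, 2:3]
  }
  if (ncol(tab) != 2L) stop("schedule file must have 2 (or legacy 3) columns")
  frame_schedule(tab[[1L]], tab[[2L]])
}

#' Image-derived input function from a blood-pool ROI
#'
#' Averages the dynamic image over a blood-pool ROI frame by frame and
#' returns the resulting time-activity curve as a sampled input function at
#' the frame mid-times — the image-derived input used in place of arterial
#' sampling.
#'
#' @param img a [dynamic_image()].
#' @param rois an [roi_set()].
#' @param name blood ROI name (default `"blood_pool"`).
#' @return a [sampled_input()].
#' @export
extract_input_from_image <- function(img, rois, name = "blood_pool") {
  stopifnot(inherits(img, "dynamic_image"))
  i <- match(name, rois$names)
  if (is.na(i)) stop("unknown ROI: ", name)
  sel <- rois$labels == i
  if (!any(sel)) stop("ROI '", name, "' is empty")
  nf <- dim(img$data)[4L]
  vals <- vapply(seq_len(nf), function(fr) mean(img$data[, , , fr][sel]),
                 numeric(1))
  sampled_input(frame_mids(img$schedule), pmax(vals, 0))
}

#' Write phantom organ kinetics as YAML
#'
#' @param spec a [build_phantom()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_organ_params <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to write organ parameters")
  lst <- lapply(spec$organ_params, function(p)
    list(K1 = p$K1, k2 = p$k2, k3 = p$k3, vb = p$vb))
  yaml::write_yaml(lst, path)
  invisible(path)
}
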