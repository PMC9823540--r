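#' Construct a patient study
#'
#' A `patient_study` bundles one CTA image volume with its per-slice binary
#' ground-truth thrombus masks and spacing metadata. Slices are stored as an
#' `H x W x S` numeric array and masks as an `H x W x S` integer array with
#' values in `{0, 1}` (1 = thrombus ROI). `slice_indices` records each
#' slice's 0-based position in the original acquisition so that slices can be
#' dropped (e.g. by [filter_slices_with_roi()]) without losing axial order.
#'
#' @param study_id character scalar identifying the study.
#' @param slices `H x W x S` numeric array (or a list of `H x W` matrices) of
#'   axial slice intensities.
#' @param gt_masks `H x W x S` array (or list of matrices) of binary masks,
#'   aligned 1:1 with `slices`.
#' @param pixel_spacing in-plane pixel spacing in millimetres (isotropic).
#' @param slice_indices integer vector of 0-based axial positions, strictly
#'   increasing; defaults to `0:(S-1)`.
#' @return An object of class `patient_study`.
#' @export
patient_study <- function(study_id, slices, gt_masks, pixel_spacing = 1,
                          slice_indices = NULL) {
  if (is.list(slices)) slices <- simplify2array(slices)
  if (is.list(gt_masks)) gt_masks <- simplify2array(gt_masks)
  if (length(dim(slices)) == 2L) slices <- array(slices, c(dim(slices), 1L))
  if (length(dim(gt_masks)) == 2L) gt_masks <- array(gt_masks, c(dim(gt_masks), 1L))
  if (is.null(slice_indices)) slice_indices <- seq_len(dim(slices)[3]) - 1L
  x <- structure(
    list(study_id = as.character(study_id),
         slices = slices,
         gt_masks = gt_masks,
         pixel_spacing = as.numeric(pixel_spacing),
         slice_indices = as.integer(slice_indices)),
    class = "patient_study")
  validate_study(x)
  x
}

#' @export
print.patient_study <- function(x, ...) {
  d <- dim(x$slices)
  cat("<patient_study> ", x$study_id, ": ", d[3], " slices of ", d[1], "x",
      d[2], ", spacing ", x$pixel_spacing, " mm\n", sep = "")
  invisible(x)
}

n_slices <- function(study) dim(study$slices)[3]

validate_study <- function(x) {
  stopifnot(inherits(x, "patient_study"))
  ds <- dim(x$slices)
  dm <- dim(x$gt_masks)
  if (!identical(ds, dm))
    stop("slices and gt_masks differ in shape", call. = FALSE)
  if (length(x$slice_indices) != ds[3])
    stop("slice_indices length must equal the slice count", call. = FALSE)
  if (ds[3] > 1 && any(diff(x$slice_indices) <= 0))
    stop("slice_indices must be strictly increasing", call. = FALSE)
  check_binary_mask(x$gt_masks)
  invisible(x)
}

check_binary_mask <- function(m) {
  if (!all(m %in% c(0, 1)))
    stop("mask is not binary: values outside {0, 1} present", call. = FALSE)
  invisible(m)
}

#' Rescale an intensity volume to 8 bits
#'
#' Linearly maps the full intensity range to `[0, 255]` with no window-level
#' adjustment, then rounds half-to-even. In `volume_minmax` mode the map
#' spans the volume's own minimum and maximum; in `fixed_range` mode it spans
#' `range[1]..range[2]` and inputs outside that interval are clipped. A
#' constant volume in `volume_minmax` mode maps to all zeros (degenerate
#' min == max case), not an error.
#'
#' @param volume non-empty numeric array.
#' @param mode `"volume_minmax"` (default) or `"fixed_range"`.
#' @param range length-2 numeric `c(lo, hi)` with `lo < hi`; required in
#'   `fixed_range` mode.
#' @return An integer array of the same shape with values in `0..255`.
#' @export
rescale_to_8bit <- function(volume, mode = c("volume_minmax", "fixed_range"),
                            range = NULL) {
  mode <- match.arg(mode)
  if (length(volume) == 0) stop("empty volume", call. = FALSE)
  if (mode == "volume_minmax") {
    lo <- min(volume)
    hi <- max(volume)
    if (hi == lo) {
      out <- volume
      out[] <- 0L
      storage.mode(out) <- "integer"
      return(out)
    }
  } else {
    if (is.null(range) || length(range) != 2 || !(range[1] < range[2]))
      stop("fixed_range mode needs range = c(lo, hi) with lo < hi", call. = FALSE)
    lo <- range[1]
    hi <- range[2]
    volume <- pmin(pmax(volume, lo), hi)
  }
  out <- round((volume - lo) / (hi - lo) * 255)
  storage.mode(out) <- "integer"
  out
}

#' Fit tight bounding boxes to a binary mask
#'
#' Derives detection-style ground truth by fitting axis-aligned rectangles to
#' a segmentation mask. With `per_component = TRUE` (default) one tight box
#' is returned per 8-connected foreground component; otherwise a single box
#' over all foreground. Coordinates are 0-based `(row, col)` and inclusive at
#' both ends, so a single pixel at (3, 4) yields the box (3, 4, 3, 4).
#'
#' @param mask binary matrix (values in `{0, 1}`).
#' @param per_component one box per connected component, or one overall box.
#' @return A data frame with columns `row_min`, `col_min`, `row_max`,
#'   `col_max`; zero rows for an empty mask.
#' @export
fit_bounding_boxes <- function(mask, per_component = TRUE) {
  check_binary_mask(mask)
  empty <- data.frame(row_min = integer(), col_min = integer(),
                      row_max = integer(), col_max = integer())
  if (!any(mask > 0)) return(empty)
  box_of <- function(sel) {
    w <- which(sel, arr.ind = TRUE)
    data.frame(row_min = min(w[, 1]) - 1L, col_min = min(w[, 2]) - 1L,
               row_max = max(w[, 1]) - 1L, col_max = max(w[, 2]) - 1L)
  }
  if (!per_component) return(box_of(mask > 0))
  lab <- label_components(mask, connectivity = 8L)
  do.call(rbind, lapply(seq_len(max(lab)), function(i) box_of(lab == i)))
}

#' Keep only slices whose ground-truth mask contains thrombus
#'
#' Reproduces the study-preprocessing step of excluding images in which no
#' thrombus ROI exists. The surviving slices keep their original
#' `slice_indices`.
#'
#' @param study a [patient_study()].
#' @return A `patient_study` with only ROI-bearing slices.
#' @export
filter_slices_with_roi <- function(study) {
  validate_study(study)
  keep <- vapply(seq_len(n_slices(study)),
                 function(s) any(study$gt_masks[, , s] > 0), logical(1))
  if (!any(keep))
    stop("no slice contains a thrombus ROI; study is unusable", call. = FALSE)
  patient_study(study$study_id,
                study$slices[, , keep, drop = FALSE],
                study$gt_masks[, , keep, drop = FALSE],
                study$pixel_spacing,
                study$slice_indices[keep])
}

#' Write a patient study to disk
#'
#' Two on-disk dialects are supported: `nifti` (an `image.nii.gz` +
#' `mask.nii.gz` pair plus a `study.json` sidecar with id, spacing and slice
#' order) and `png_stack` (one 8-bit PNG per slice and mask plus a
#' `manifest.json`). The PNG dialect requires intensities in `0..255`.
#'
#' @param study a [patient_study()].
#' @param path directory to create/populate.
#' @param format `"nifti"` or `"png_stack"`.
#' @return `path`, invisibly.
#' @export
write_study <- function(study, path, format = c("nifti", "png_stack")) {
  format <- match.arg(format)
  validate_study(study)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  meta <- list(study_id = study$study_id,
               pixel_spacing = study$pixel_spacing,
               slice_indices = study$slice_indices,
               format = format)
  if (format == "nifti") {
    img <- study$slices
    storage.mode(img) <- "integer"
    msk <- study$gt_masks
    storage.mode(msk) <- "integer"
    RNifti::writeNifti(RNifti::asNifti(img, pixdim = rep(study$pixel_spacing, 3)),
                       file.path(path, "image.nii.gz"), datatype = "int16")
    RNifti::writeNifti(RNifti::asNifti(msk, pixdim = rep(study$pixel_spacing, 3)),
                       file.path(path, "mask.nii.gz"), datatype = "uint8")
    jsonlite::write_json(meta, file.path(path, "study.json"), auto_unbox = TRUE)
  } else {
    if (min(study$slices) < 0 || max(study$slices) > 255)
      stop("png_stack requires 8-bit intensities in 0..255; run rescale_to_8bit first",
           call. = FALSE)
    S <- n_slices(study)
    for (s in seq_len(S)) {
      png::writePNG(study$slices[, , s] / 255,
                    file.path(path, sprintf("slice_%04d.png", s)))
      png::writePNG(study$gt_masks[, , s] + 0,   # writePNG needs doubles
                    file.path(path, sprintf("mask_%04d.png", s)))
    }
    meta$n_slices <- S
    jsonlite::write_json(meta, file.path(path, "manifest.json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' Load a patient study from disk
#'
#' Counterpart of [write_study()]; round trips are bit-exact for integer
#' intensity payloads. The mask volume must be binary.
#'
#' @param path study directory.
#' @param format `"nifti"` or `"png_stack"`.
#' @return A [patient_study()].
#' @export
load_study <- function(path, format = c("nifti", "png_stack")) {
  format <- match.arg(format)
  if (!dir.exists(path)) stop("no such study directory: ", path, call. = FALSE)
  if (format == "nifti") {
    mfile <- file.path(path, "mask.nii.gz")
    if (!file.exists(mfile)) stop("mask volume missing in ", path, call. = FALSE)
    img <- RNifti::readNifti(file.path(path, "image.nii.gz"))
    img <- array(as.numeric(img), dim(img))
    msk <- RNifti::readNifti(mfile)
    msk <- array(as.numeric(msk), dim(msk))
    meta <- jsonlite::read_json(file.path(path, "study.json"), simplifyVector = TRUE)
  } else {
    mf <- file.path(path, "manifest.json")
    if (!file.exists(mf)) stop("manifest.json missing in ", path, call. = FALSE)
    meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
    S <- meta$n_slices
    rd <- function(stem) {
      simplify2array(lapply(seq_len(S), function(s) {
        f <- file.path(path, sprintf("%s_%04d.png", stem, s))
        if (!file.exists(f)) stop("missing ", f, call. = FALSE)
        round(png::readPNG(f) * 255)
      }))
    }
    img <- rd("slice")
    msk <- rd("mask") / 255
  }
  if (length(dim(img)) == 2L) img <- array(img, c(dim(img), 1L))
  if (length(dim(msk)) == 2L) msk <- array(msk, c(dim(msk), 1L))
  if (!identical(dim(img), dim(msk)))
    stop("slice/mask shape mismatch in ", path, call. = FALSE)
  check_binary_mask(msk)
  patient_study(meta$study_id, img, msk, meta$pixel_spacing,
                as.integer(meta$slice_indices))
}
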