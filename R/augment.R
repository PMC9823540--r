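#' Augmentation specification
#'
#' The two augmentations applied during training: in-plane rotation by an
#' angle drawn uniformly within `rotation_max_deg` degrees, and elastic
#' deformation in the style of random displacement fields smoothed by a
#' Gaussian (`elastic_alpha` scales the displacement magnitude in pixels,
#' `elastic_sigma` is the smoothing standard deviation in pixels). One
#' geometric transform is always applied identically to an image and its
#' mask: images are resampled bilinearly, masks nearest-neighbour so they
#' stay binary.
#'
#' @param rotation_max_deg maximum absolute rotation (default 10).
#' @param elastic_alpha displacement magnitude in pixels (default 8).
#' @param elastic_sigma Gaussian smoothing std in pixels (default 4).
#' @param seed integer seed; the same spec yields the same transform.
#' @param enabled logical master switch.
#' @return An object of class `augmentation_spec`.
#' @export
augmentation_spec <- function(rotation_max_deg = 10, elastic_alpha = 8,
                              elastic_sigma = 4, seed = 1L, enabled = TRUE) {
  if (rotation_max_deg < 0) stop("rotation_max_deg must be >= 0", call. = FALSE)
  if (elastic_alpha < 0 || elastic_sigma < 0)
    stop("elastic parameters must be >= 0", call. = FALSE)
  structure(list(rotation_max_deg = rotation_max_deg,
                 elastic_alpha = elastic_alpha,
                 elastic_sigma = elastic_sigma,
                 seed = as.integer(seed), enabled = isTRUE(enabled)),
            class = "augmentation_spec")
}

#' Build the N-pair slice sequences fed to the head
#'
#' One sequence is produced per slice of the study, centered on it, with the
#' slice's attention map paired to it. Positions that would fall before the
#' first or after the last slice are filled per the boundary policy
#' (`"replicate"` clamps to the first/last slice, `"reflect"` mirrors) and
#' marked in `padding_flags`.
#'
#' @param study a [patient_study()].
#' @param maps list of [attention_map()]s (or matrices), one per slice.
#' @param N odd sequence length `>= 1` (default 5).
#' @param boundary `"replicate"` (default) or `"reflect"`.
#' @return A list of `pair_sequence` objects, one per slice, each with
#'   `pairs` (list of `slice` + `attention`), `target_index` (1-based
#'   position of the centre), `padding_flags`, `target_gt`, `study_id`, and
#'   `slice_index` (the target's original axial position).
#' @export
build_sequences <- function(study, maps, N = 5L, boundary = c("replicate", "reflect")) {
  boundary <- match.arg(boundary)
  validate_study(study)
  N <- as.integer(N)
  if (N < 1L) stop("N must be >= 1", call. = FALSE)
  if (N %% 2L == 0L) stop("sequence length N must be odd", call. = FALSE)
  S <- n_slices(study)
  if (length(maps) != S)
    stop("need one attention map per slice", call. = FALSE)
  h <- (N - 1L) %/% 2L
  lapply(seq_len(S), function(s) {
    offs <- (s - h):(s + h)
    padded <- offs < 1L | offs > S
    idx <- vapply(offs, function(o) {
      if (boundary == "replicate") min(max(o, 1L), S)
      else {
        # reflect about the volume ends: 0 -> 2, -1 -> 3, S+1 -> S-1, ...
        while (o < 1L || o > S) {
          if (o < 1L) o <- 2L - o
          if (o > S) o <- 2L * S - o
        }
        o
      }
    }, integer(1))
    structure(list(
      pairs = lapply(idx, function(i)
        list(slice = study$slices[, , i],
             attention = if (inherits(maps[[i]], "attention_map")) maps[[i]]
                         else attention_map(maps[[i]]))),
      target_index = h + 1L,
      padding_flags = padded,
      target_gt = study$gt_masks[, , s],
      study_id = study$study_id,
      slice_index = study$slice_indices[s]),
      class = "pair_sequence")
  })
}

# sample the transform parameters of one augmentation draw
sample_transform <- function(spec, H, W) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  theta <- stats::runif(1, -spec$rotation_max_deg, spec$rotation_max_deg) * pi / 180
  dr <- dc <- matrix(0, H, W)
  if (spec$elastic_alpha > 0) {
    dr <- gaussian_smooth(matrix(stats::runif(H * W, -1, 1), H, W),
                          spec$elastic_sigma) * spec$elastic_alpha
    dc <- gaussian_smooth(matrix(stats::runif(H * W, -1, 1), H, W),
                          spec$elastic_sigma) * spec$elastic_alpha
  }
  list(theta = theta, dr = dr, dc = dc)
}

# source-coordinate fields for the two transforms
elastic_coords <- function(tr, H, W) {
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  list(r = rows + tr$dr, c = cols + tr$dc)
}

rotate_coords <- function(theta, H, W) {
  cr <- (H + 1) / 2
  cc <- (W + 1) / 2
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  dr <- rows - cr
  dc <- cols - cc
  list(r = cr + cos(theta) * dr - sin(theta) * dc,
       c = cc + sin(theta) * dr + cos(theta) * dc)
}

apply_coords <- function(image, mask, co) {
  list(image = warp_bilinear(image, co$r, co$c),
       mask = warp_nearest(mask, co$r, co$c))
}

#' Elastic deformation of an image/mask pair
#'
#' One random displacement field (uniform noise smoothed by a Gaussian of
#' `elastic_sigma` pixels, scaled to `elastic_alpha` pixels) is sampled per
#' call and applied to both inputs: linear interpolation for the image,
#' nearest-neighbour for the mask, so the mask stays binary. Deterministic
#' given `spec$seed`.
#'
#' @param image 2D intensity matrix.
#' @param mask binary matrix of the same shape.
#' @param spec an [augmentation_spec()].
#' @return A list with the warped `image` and `mask`.
#' @export
elastic_deform <- function(image, mask, spec) {
  stopifnot(inherits(spec, "augmentation_spec"))
  if (!identical(dim(image), dim(mask)))
    stop("image and mask differ in shape", call. = FALSE)
  if (!spec$enabled || spec$elastic_alpha == 0)
    return(list(image = image, mask = mask))
  tr <- sample_transform(spec, nrow(image), ncol(image))
  apply_coords(image, mask, elastic_coords(tr, nrow(image), ncol(image)))
}

#' Random small rotation of an image/mask pair
#'
#' One angle drawn uniformly within the spec's maximum (10 degrees by
#' default) rotates both inputs about the image centre; the mask is
#' resampled nearest-neighbour. Deterministic given `spec$seed`.
#'
#' @inheritParams elastic_deform
#' @return A list with the rotated `image` and `mask`, and the `angle_deg`
#'   actually applied.
#' @export
random_rotate <- function(image, mask, spec) {
  stopifnot(inherits(spec, "augmentation_spec"))
  if (!identical(dim(image), dim(mask)))
    stop("image and mask differ in shape", call. = FALSE)
  if (!spec$enabled || spec$rotation_max_deg == 0)
    return(list(image = image, mask = mask, angle_deg = 0))
  tr <- sample_transform(spec, nrow(image), ncol(image))
  out <- apply_coords(image, mask, rotate_coords(tr$theta, nrow(image), ncol(image)))
  out$angle_deg <- tr$theta * 180 / pi
  out
}

#' Augment a whole pair sequence with one shared transform
#'
#' Samples a single rotation + elastic field and applies it to every slice,
#' attention map and the target ground truth of the sequence, preserving the
#' volumetric coherence across the N pairs (independent per-slice warps
#' would destroy exactly the structure the Bi-CLSTM learns). Attention maps
#' are warped alongside the images (bilinear, then clamped).
#'
#' @param seq a `pair_sequence`.
#' @param spec an [augmentation_spec()].
#' @return The augmented `pair_sequence`.
#' @export
augment_sequence <- function(seq, spec) {
  stopifnot(inherits(seq, "pair_sequence"), inherits(spec, "augmentation_spec"))
  if (!spec$enabled) return(seq)
  d <- dim(seq$pairs[[1]]$slice)
  tr <- sample_transform(spec, d[1], d[2])
  rot <- rotate_coords(tr$theta, d[1], d[2])
  el <- elastic_coords(tr, d[1], d[2])
  # compose: elastic displacement looked up after rotation
  co <- list(r = warp_bilinear(el$r, rot$r, rot$c),
             c = warp_bilinear(el$c, rot$r, rot$c))
  seq$pairs <- lapply(seq$pairs, function(p) {
    list(slice = warp_bilinear(p$slice, co$r, co$c),
         attention = attention_map(
           warp_bilinear(attention_values(p$attention), co$r, co$c),
           if (inherits(p$attention, "attention_map")) p$attention$provider_tag
           else "external_file"))
  })
  seq$target_gt <- warp_nearest(seq$target_gt, co$r, co$c)
  seq
}
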