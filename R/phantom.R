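#' Parameters of the synthetic postoperative-CTA phantom
#'
#' The phantom emulates the salient properties of postoperative CTA volumes
#' after endovascular aneurysm repair: on each axial slice a bright circular
#' lumen (the stented channel), an annular thrombus region around it with an
#' irregular outer boundary (low-frequency radial perturbation), a
#' surrounding soft-tissue field whose intensity distribution overlaps the
#' thrombus distribution by a controllable fraction, optional bright
#' stent-graft streak artifacts crossing the annulus, and additive Gaussian
#' noise. The thrombus centroid drifts smoothly from slice to slice, giving
#' the volumetric coherence that the Bi-CLSTM head exploits.
#'
#' All lengths are in pixels on an `image_size x image_size` grid; intensity
#' levels are on the 8-bit scale. `tissue_overlap` in `[0, 1]` widens the
#' thrombus and soft-tissue intensity distributions toward each other: at 0
#' they are strictly separated by their midpoint, at 1 they overlap heavily,
#' making intensity thresholding progressively useless.
#'
#' @param image_size pixels per side (default 64; use 256 for demos).
#' @param n_slices number of axial slices.
#' @param lumen_radius_range length-2 range the per-study lumen radius is
#'   drawn from.
#' @param thrombus_thickness_range length-2 range for the mean annulus
#'   thickness.
#' @param center_drift maximum per-slice centroid displacement (pixels).
#' @param intensity_levels named numeric vector with entries `background`,
#'   `tissue`, `thrombus`, `lumen`, `stent`.
#' @param tissue_overlap fraction in `[0, 1]`.
#' @param stent_artifact logical; draw bright stent streaks.
#' @param stent_streaks number of streaks per slice when enabled.
#' @param noise_sigma additive Gaussian noise standard deviation.
#' @param seed integer seed; generation is fully deterministic given the
#'   parameter set.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(image_size = 64,
                           n_slices = 12,
                           lumen_radius_range = c(4, 7) * image_size / 64,
                           thrombus_thickness_range = c(4, 9) * image_size / 64,
                           center_drift = 1.5,
                           intensity_levels = c(background = 20, tissue = 90,
                                                thrombus = 150, lumen = 230,
                                                stent = 252),
                           tissue_overlap = 0.3,
                           stent_artifact = TRUE,
                           stent_streaks = 3,
                           noise_sigma = 5,
                           seed = 1L) {
  p <- structure(
    list(image_size = as.integer(image_size), n_slices = as.integer(n_slices),
         lumen_radius_range = as.numeric(lumen_radius_range),
         thrombus_thickness_range = as.numeric(thrombus_thickness_range),
         center_drift = center_drift, intensity_levels = intensity_levels,
         tissue_overlap = tissue_overlap, stent_artifact = stent_artifact,
         stent_streaks = as.integer(stent_streaks), noise_sigma = noise_sigma,
         seed = as.integer(seed)),
    class = "phantom_params")
  validate_phantom_params(p)
  p
}

validate_phantom_params <- function(p) {
  if (p$n_slices < 1) stop("n_slices must be >= 1", call. = FALSE)
  if (any(p$lumen_radius_range <= 0) || any(p$thrombus_thickness_range <= 0))
    stop("radii and thicknesses must be positive", call. = FALSE)
  if (p$tissue_overlap < 0 || p$tissue_overlap > 1)
    stop("tissue_overlap must lie in [0, 1]", call. = FALSE)
  need <- c("background", "tissue", "thrombus", "lumen", "stent")
  if (!all(need %in% names(p$intensity_levels)))
    stop("intensity_levels must name ", paste(need, collapse = ", "), call. = FALSE)
  # the vessel (lumen + thickest perturbed annulus + drift) must fit inside
  max_r <- max(p$lumen_radius_range) + max(p$thrombus_thickness_range) * 1.35 +
    p$center_drift * p$n_slices / 2
  if (max_r >= p$image_size / 2)
    stop("phantom geometry does not fit inside image_size/2 ",
         "(reduce radii, thickness, drift or slice count)", call. = FALSE)
  invisible(p)
}

#' Generate one synthetic phantom study
#'
#' Deterministic given `params` (same parameters and seed give bit-identical
#' studies). The returned ground-truth masks mark exactly the generated
#' thrombus annulus pixels before noise and streaks are added to the image.
#'
#' @param params a [phantom_params()].
#' @param study_id identifier for the resulting study.
#' @return A [patient_study()].
#' @export
generate_study <- function(params, study_id = sprintf("phantom_%05d", params$seed)) {
  validate_phantom_params(params)
  L <- params$image_size
  S <- params$n_slices
  lv <- params$intensity_levels
  ov <- params$tissue_overlap
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(params$seed)

  lumen_r <- stats::runif(1, params$lumen_radius_range[1], params$lumen_radius_range[2])
  thick <- stats::runif(1, params$thrombus_thickness_range[1],
                        params$thrombus_thickness_range[2])
  # irregular outer boundary: low-frequency radial perturbation, fixed per study
  n_harm <- 3L
  amp <- stats::runif(n_harm, 0, 0.12)
  pha <- stats::runif(n_harm, 0, 2 * pi)

  # smooth centroid drift: random per-slice steps bounded by center_drift
  ctr <- matrix(0, S, 2)
  ctr[1, ] <- (L + 1) / 2 + stats::runif(2, -1, 1)
  # the continuous centre moves at most 0.8 * center_drift per slice, leaving
  # headroom so the rasterized mask centroid also respects the center_drift
  # bound despite pixelization jitter
  if (S > 1) for (s in 2:S) {
    ang <- stats::runif(1, 0, 2 * pi)
    step <- stats::runif(1, 0, 0.8 * params$center_drift)
    ctr[s, ] <- ctr[s - 1, ] + step * c(cos(ang), sin(ang))
  }

  gap <- lv[["thrombus"]] - lv[["tissue"]]
  width <- (0.49 + 0.51 * ov) * gap   # distribution half-width toward the midpoint

  rows <- matrix(seq_len(L), L, L)
  cols <- t(rows)
  body_r <- 0.47 * L
  slices <- array(0, c(L, L, S))
  masks <- array(0L, c(L, L, S))
  for (s in seq_len(S)) {
    dr <- rows - ctr[s, 1]
    dc <- cols - ctr[s, 2]
    rad <- sqrt(dr * dr + dc * dc)
    th <- atan2(dc, dr)
    outer_r <- (lumen_r + thick) *
      (1 + Reduce(`+`, lapply(seq_len(n_harm), function(m)
        amp[m] * cos((m + 1) * th + pha[m]))))
    mask <- rad > lumen_r & rad <= outer_r
    body <- sqrt((rows - (L + 1) / 2)^2 + (cols - (L + 1) / 2)^2) <= body_r

    img <- matrix(lv[["background"]], L, L)
    tissue_tex <- lv[["tissue"]] + width * matrix(stats::runif(L * L), L, L)
    img[body] <- tissue_tex[body]
    thr_tex <- lv[["thrombus"]] - width * matrix(stats::runif(L * L), L, L)
    img[mask] <- thr_tex[mask]
    img[rad <= lumen_r] <- lv[["lumen"]]
    masks[, , s] <- mask

    if (params$stent_artifact && params$stent_streaks > 0) {
      for (k in seq_len(params$stent_streaks)) {
        ang <- stats::runif(1, 0, pi)
        off <- stats::runif(1, -lumen_r - thick / 2, lumen_r + thick / 2)
        # streak: thin line at distance `off` from the centroid, direction ang
        d <- abs(dr * cos(ang) + dc * sin(ang) - off)
        img[d < 0.7 & rad <= outer_r + 2] <- lv[["stent"]]
      }
    }
    if (params$noise_sigma > 0)
      img <- img + matrix(stats::rnorm(L * L, 0, params$noise_sigma), L, L)
    slices[, , s] <- pmin(pmax(img, 0), 255)
  }
  patient_study(study_id, slices, masks, pixel_spacing = 0.8,
                slice_indices = seq_len(S) - 1L)
}

#' Generate a reproducible cohort of phantom studies
#'
#' Per-study seeds are derived from the cohort seed by a counter-based
#' scheme (`study_seed_i = (seed + 7919 * i) mod 2^31 - 1`), so each study is
#' reproducible independently of generation order. When `n_slices_range` is
#' given, each study's slice count is drawn uniformly from it (inclusive).
#'
#' @param n_studies number of studies (>= 1).
#' @param params baseline [phantom_params()] shared by all studies.
#' @param seed cohort seed.
#' @param n_slices_range optional length-2 integer range for per-study slice
#'   counts; `NULL` keeps `params$n_slices` for all studies.
#' @return A list of [patient_study()] objects with distinct ids.
#' @export
generate_cohort <- function(n_studies, params = phantom_params(), seed = 1L,
                            n_slices_range = NULL) {
  if (n_studies < 1) stop("n_studies must be >= 1", call. = FALSE)
  validate_phantom_params(params)
  lapply(seq_len(n_studies), function(i) {
    p <- params
    p$seed <- study_seed(seed, i)
    if (!is.null(n_slices_range)) {
      old <- .Random.seed_save()
      on.exit(.Random.seed_restore(old))
      set.seed(p$seed)
      p$n_slices <- as.integer(sample(seq(n_slices_range[1], n_slices_range[2]), 1))
      p$seed <- study_seed(seed, i) + 1L   # content stream distinct from the draw
    }
    generate_study(p, study_id = sprintf("phantom_%03d", i))
  })
}

#' @rdname generate_cohort
#' @param i 1-based study counter.
#' @export
study_seed <- function(seed, i) as.integer((as.numeric(seed) + 7919 * i) %% (2^31 - 1))

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
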