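#' Spatial attention map
#'
#' A per-slice soft foreground map in `[0, 1]` with the same spatial
#' dimensions as its slice, tagged with the provider that produced it.
#'
#' @param values numeric matrix in `[0, 1]`.
#' @param provider_tag `"detector"`, `"lightweight"` or `"external_file"`.
#' @return An object of class `attention_map`.
#' @export
attention_map <- function(values, provider_tag = "external_file") {
  values <- pmin(pmax(as.matrix(values), 0), 1)
  structure(list(values = values, provider_tag = provider_tag),
            class = "attention_map")
}

#' @rdname attention_map
#' @param x an `attention_map` or plain matrix.
#' @export
attention_values <- function(x) {
  if (inherits(x, "attention_map")) x$values else as.matrix(x)
}

#' Detection-backbone configuration
#'
#' Mirrors the configuration surface of the instance-segmentation detector
#' used to extract spatial attention maps: a 50-layer residual backbone,
#' region proposals from anchor boxes with exactly three scales and three
#' aspect ratios, RoI-aligned features, and box/class heads of `head_width`
#' neurons. Only the mask branch of the detector is consumed downstream.
#'
#' @param backbone_name backbone identifier (default `"resnet50"`).
#' @param anchor_scales exactly three anchor sizes in pixels.
#' @param anchor_ratios exactly three aspect ratios.
#' @param roi_output_size RoI-aligned feature resolution.
#' @param score_threshold detection score cut in `[0, 1]`.
#' @param head_width neurons in the box/class heads.
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(backbone_name = "resnet50",
                            anchor_scales = c(32, 64, 128),
                            anchor_ratios = c(0.5, 1, 2),
                            roi_output_size = 14L,
                            score_threshold = 0.5,
                            head_width = 1024L) {
  if (length(anchor_scales) != 3L)
    stop("exactly 3 anchor scales are required", call. = FALSE)
  if (length(anchor_ratios) != 3L)
    stop("exactly 3 anchor aspect ratios are required", call. = FALSE)
  if (score_threshold < 0 || score_threshold > 1)
    stop("score_threshold must be in [0, 1]", call. = FALSE)
  structure(list(backbone_name = backbone_name,
                 anchor_scales = as.numeric(anchor_scales),
                 anchor_ratios = as.numeric(anchor_ratios),
                 roi_output_size = as.integer(roi_output_size),
                 score_threshold = score_threshold,
                 head_width = as.integer(head_width)),
            class = "detector_config")
}

#' Serialize / restore a detector configuration
#'
#' @param cfg a [detector_config()].
#' @param path YAML file path.
#' @return `path`, or the restored `detector_config`.
#' @export
write_detector_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "detector_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_detector_config
#' @export
read_detector_config <- function(path) {
  v <- yaml::read_yaml(path)
  detector_config(v$backbone_name, v$anchor_scales, v$anchor_ratios,
                  v$roi_output_size, v$score_threshold, v$head_width)
}

# small fully convolutional network shared by both providers:
# conv(1->f) -> ReLU -> conv(f->f) -> ReLU -> 1x1 conv(f->1) logit.
# The final bias starts strongly negative so an untrained network scores
# (almost) nothing above threshold.
new_pixel_net <- function(filters = 8L, kernel_size = 3L, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  net <- list(conv1 = new_conv(kernel_size, 1L, filters),
              conv2 = new_conv(kernel_size, filters, filters),
              out = new_conv(1L, filters, 1L))
  net$out$b <- -4
  net
}

pixel_net_fwd <- function(net, img, keep_cache = FALSE) {
  x <- array(img / 255, c(dim(img), 1L, 1L))   # intensities on the 8-bit scale
  c1 <- conv2d(x, net$conv1$W, net$conv1$b, keep_cols = keep_cache)
  r1 <- relu(c1$out)
  c2 <- conv2d(r1, net$conv2$W, net$conv2$b, keep_cols = keep_cache)
  r2 <- relu(c2$out)
  c3 <- conv2d(r2, net$out$W, net$out$b, keep_cols = keep_cache)
  prob <- sigmoid(matrix(c3$out, dim(img)[1], dim(img)[2]))
  list(prob = prob, cache = list(c1 = c1, r1 = r1, c2 = c2, r2 = r2, c3 = c3))
}

pixel_net_bwd <- function(net, cache, dlogit) {
  k3 <- conv2d_bwd(array(dlogit, c(dim(dlogit), 1L, 1L)), cache$c3$cols, net$out$W)
  dr2 <- k3$dx * (cache$r2 > 0)
  k2 <- conv2d_bwd(dr2, cache$c2$cols, net$conv2$W)
  dr1 <- k2$dx * (cache$r1 > 0)
  k1 <- conv2d_bwd(dr1, cache$c1$cols, net$conv1$W, need_dx = FALSE)
  list(conv1 = list(W = k1$dW, b = k1$db),
       conv2 = list(W = k2$dW, b = k2$db),
       out = list(W = k3$dW, b = k3$db))
}

#' Lightweight attention-map provider
#'
#' A small fully convolutional encoder-decoder producing a dense per-pixel
#' thrombus probability for one slice. It honors the same output contract as
#' the detector provider and is intended for CPU-scale experiments and
#' tests.
#'
#' @param filters hidden channels (default 8).
#' @param kernel_size odd kernel extent.
#' @param seed initialization seed.
#' @return An object of class `lightweight_backbone`.
#' @export
lightweight_backbone <- function(filters = 8L, kernel_size = 3L, seed = 1L) {
  structure(list(net = new_pixel_net(filters, kernel_size, seed),
                 trained = FALSE),
            class = "lightweight_backbone")
}

#' Configure the instance-segmentation detector provider
#'
#' Validates the full detector configuration contract and returns a provider
#' handle exposing train/predict with a single foreground class (thrombus).
#' The handle scores candidate instances and exposes classification scores,
#' box estimates and soft masks; only the mask of the highest-scoring
#' instance is consumed downstream. The scoring network behind the handle is
#' a compact fully convolutional model whose thresholded output is split
#' into 8-connected candidate instances; each candidate's score is its peak
#' probability and its box is the tight rectangle around it.
#'
#' @param cfg a [detector_config()].
#' @param seed initialization seed for the scoring network.
#' @return An object of class `thrombus_detector`.
#' @export
configure_detector <- function(cfg = detector_config(), seed = 1L) {
  stopifnot(inherits(cfg, "detector_config"))
  structure(list(cfg = cfg, net = new_pixel_net(8L, 3L, seed), trained = FALSE),
            class = "thrombus_detector")
}

#' Run the detector on one slice
#'
#' @param detector a [configure_detector()] handle.
#' @param image 2D intensity matrix (8-bit scale).
#' @return A list with `boxes` (data frame: `row_min`, `col_min`, `row_max`,
#'   `col_max`, `score`, 0-based inclusive) and `masks` (list of soft masks,
#'   full-image coordinates). Zero detections give zero rows.
#' @export
detect_instances <- function(detector, image) {
  stopifnot(inherits(detector, "thrombus_detector"))
  prob <- pixel_net_fwd(detector$net, image)$prob
  thr <- detector$cfg$score_threshold
  cand <- prob >= thr
  empty <- list(boxes = data.frame(row_min = integer(), col_min = integer(),
                                   row_max = integer(), col_max = integer(),
                                   score = numeric()),
                masks = list())
  if (!any(cand)) return(empty)
  lab <- label_components(cand * 1, connectivity = 8L)
  boxes <- NULL
  masks <- list()
  for (i in seq_len(max(lab))) {
    sel <- lab == i
    bb <- fit_bounding_boxes(sel * 1, per_component = FALSE)
    bb$score <- max(prob[sel])
    boxes <- rbind(boxes, bb)
    m <- matrix(0, nrow(prob), ncol(prob))
    m[sel] <- prob[sel]
    masks[[i]] <- m
  }
  list(boxes = boxes, masks = masks)
}

#' Extract the spatial attention map of one slice
#'
#' For the detector provider: the soft mask of the highest-scoring thrombus
#' detection pasted into full-image coordinates, zeros elsewhere; when no
#' detection clears the score threshold the map is all-zero (not an error;
#' ties between detections are broken by the lower detection index). For the
#' lightweight provider: the dense per-pixel foreground probability. Values
#' are always clamped to `[0, 1]`.
#'
#' @param slice 2D intensity matrix.
#' @param provider a `thrombus_detector` or `lightweight_backbone`.
#' @param allow_untrained permit an untrained provider (default `FALSE`).
#' @param binarize threshold the map at 0.5 before returning (the detector's
#'   native binary mask branch behaviour; default `FALSE`, soft maps).
#' @return An [attention_map()].
#' @export
extract_attention_map <- function(slice, provider, allow_untrained = FALSE,
                                  binarize = FALSE) {
  slice <- as.matrix(slice)
  if (!isTRUE(provider$trained) && !allow_untrained)
    stop("provider is untrained; pass allow_untrained = TRUE to override",
         call. = FALSE)
  if (inherits(provider, "lightweight_backbone")) {
    vals <- pixel_net_fwd(provider$net, slice)$prob
    tag <- "lightweight"
  } else if (inherits(provider, "thrombus_detector")) {
    det <- detect_instances(provider, slice)
    if (nrow(det$boxes) == 0) {
      vals <- matrix(0, nrow(slice), ncol(slice))
    } else {
      vals <- det$masks[[which.max(det$boxes$score)]]
    }
    tag <- "detector"
  } else stop("unknown provider type", call. = FALSE)
  if (binarize) vals <- (vals >= 0.5) * 1
  attention_map(vals, tag)
}

#' Train an attention-map provider
#'
#' Stochastic gradient descent on the per-pixel focal loss of single slices
#' sampled uniformly from the training studies. Every training slice must
#' contain a thrombus ROI (apply [filter_slices_with_roi()] first); the
#' matching bounding boxes are derivable via [fit_bounding_boxes()].
#'
#' @param provider a `lightweight_backbone` or `thrombus_detector`.
#' @param studies nonempty list of [patient_study()] objects.
#' @param lr learning rate (default 1e-4).
#' @param steps SGD steps.
#' @param alpha,gamma focal-loss parameters.
#' @param seed RNG seed.
#' @return A list with the trained `provider` and per-step loss `trace`.
#' @export
train_backbone <- function(provider, studies, lr = 1e-4, steps = 200L,
                           alpha = 0.25, gamma = 2, seed = 1L) {
  if (length(studies) == 0) stop("empty training set", call. = FALSE)
  for (st in studies) {
    validate_study(st)
    for (s in seq_len(n_slices(st)))
      if (!any(st$gt_masks[, , s] > 0))
        stop("training slices without ROI present; apply filter_slices_with_roi first",
             call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  pool <- do.call(rbind, lapply(seq_along(studies), function(i)
    cbind(i, seq_len(n_slices(studies[[i]])))))
  trace <- numeric(steps)
  net <- provider$net
  for (step in seq_len(steps)) {
    j <- pool[sample.int(nrow(pool), 1L), ]
    img <- studies[[j[1]]]$slices[, , j[2]]
    gt <- studies[[j[1]]]$gt_masks[, , j[2]]
    fwd <- pixel_net_fwd(net, img, keep_cache = TRUE)
    trace[step] <- focal_loss(fwd$prob, gt, alpha, gamma)
    dl <- focal_grad_logit(fwd$prob, gt, alpha, gamma)
    grads <- pixel_net_bwd(net, fwd$cache, dl)
    net <- sgd_step(net, grads, lr)
  }
  provider$net <- net
  provider$trained <- TRUE
  list(provider = provider, trace = trace)
}
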