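#' Voxelwise confusion counts between a predicted and a ground-truth mask
#'
#' @param pred,gt binary matrices/arrays of identical shape.
#' @return Named numeric vector with `TP`, `FP`, `FN` counts, where
#'   `TP = |pred & gt|`, `FP = |pred & !gt|`, `FN = |!pred & gt|`.
#' @export
confusion_counts <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt)))
    stop("prediction and ground truth differ in shape", call. = FALSE)
  check_binary_mask(pred)
  check_binary_mask(gt)
  p <- pred > 0
  g <- gt > 0
  c(TP = sum(p & g), FP = sum(p & !g), FN = sum(!p & g))
}

#' The five overlap metrics for one prediction / ground-truth pair
#'
#' With `A` the prediction and `B` the (nonempty) ground truth:
#' total overlap `TO = |A n B| / |B|`, false-negative rate
#' `FN = |B \\ A| / |B|`, false-positive rate `FP = |A \\ B| / |A|`,
#' `Dice = 2|A n B| / (|A| + |B|)` and `Jaccard = |A n B| / |A u B|`.
#' These satisfy `TO + FN = 1` exactly and `Dice = 2J / (1 + J)`.
#' An empty prediction gives `TO = Dice = Jaccard = 0`, `FN = 1` and, by
#' convention, `FP = 0` (its `|A|` denominator is empty).
#' `fp_denominator = "gt"` switches FP's denominator to `|B|`, a variant
#' found in parts of the segmentation literature.
#'
#' @param pred,gt binary masks of identical shape; `gt` must be nonempty.
#' @param level aggregation tag stored in the report.
#' @param fp_denominator `"pred"` (default) or `"gt"`.
#' @return A `metrics_report`: list with `TO`, `Dice`, `Jaccard`, `FN`, `FP`,
#'   `level`, `n_items`.
#' @export
compute_metrics <- function(pred, gt, level = "slice",
                            fp_denominator = c("pred", "gt")) {
  fp_denominator <- match.arg(fp_denominator)
  cc <- confusion_counts(pred, gt)
  nB <- cc[["TP"]] + cc[["FN"]]
  if (nB == 0) stop("ground-truth mask is empty: metrics undefined", call. = FALSE)
  nA <- cc[["TP"]] + cc[["FP"]]
  to <- cc[["TP"]] / nB
  fn <- cc[["FN"]] / nB
  fp <- if (fp_denominator == "gt") cc[["FP"]] / nB
        else if (nA == 0) 0 else cc[["FP"]] / nA
  dice <- 2 * cc[["TP"]] / (nA + nB)
  jac <- cc[["TP"]] / (nA + nB - cc[["TP"]])
  metrics_report(TO = to, Dice = dice, Jaccard = jac, FN = fn, FP = fp,
                 level = level, n_items = 1L)
}

metrics_report <- function(TO, Dice, Jaccard, FN, FP, level, n_items) {
  structure(list(TO = TO, Dice = Dice, Jaccard = Jaccard, FN = FN, FP = FP,
                 level = level, n_items = as.integer(n_items)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report level=%s n=%d> TO=%.4f Dice=%.4f Jaccard=%.4f FN=%.4f FP=%.4f\n",
              x$level, x$n_items, x$TO, x$Dice, x$Jaccard, x$FN, x$FP))
  invisible(x)
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(TO = x$TO, Dice = x$Dice, Jaccard = x$Jaccard, FN = x$FN,
             FP = x$FP, level = x$level, n_items = x$n_items)
}

#' Aggregate metric reports by unweighted mean
#'
#' Climbing the slice -> study -> fold -> overall hierarchy, each step is an
#' unweighted arithmetic mean of the five metrics, so patients (not voxels)
#' carry equal weight in cohort-level numbers.
#'
#' @param reports nonempty list of `metrics_report` objects of a common level.
#' @param level level tag of the aggregate.
#' @return A `metrics_report`.
#' @export
aggregate_metrics <- function(reports, level = "study") {
  if (length(reports) == 0) stop("nothing to aggregate", call. = FALSE)
  stopifnot(all(vapply(reports, inherits, logical(1), "metrics_report")))
  m <- function(f) mean(vapply(reports, `[[`, numeric(1), f))
  metrics_report(TO = m("TO"), Dice = m("Dice"), Jaccard = m("Jaccard"),
                 FN = m("FN"), FP = m("FP"), level = level,
                 n_items = length(reports))
}

#' Patient-wise k-fold cross-validation splits
#'
#' Studies (not slices) are the cross-validation unit: ids are shuffled once
#' with the given seed and partitioned into `k` contiguous test sets of size
#' `floor(n/k)` or `ceiling(n/k)`; each study is tested exactly once and the
#' remaining studies form that fold's training set. With 60 studies and
#' `k = 4` this yields the 45/15 train/test rotation.
#'
#' @param study_ids character vector of distinct ids, `length >= k`.
#' @param k number of folds (default 4).
#' @param seed shuffle seed.
#' @return A list of `k` fold splits, each a list with `fold_id`,
#'   `train_ids`, `test_ids`.
#' @export
make_cv_folds <- function(study_ids, k = 4L, seed = 1L) {
  n <- length(study_ids)
  if (any(duplicated(study_ids))) stop("study ids must be distinct", call. = FALSE)
  if (n < k) stop("need at least k study ids", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  shuffled <- sample(study_ids)
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  lapply(seq_len(k), function(i) {
    test <- shuffled[starts[i]:ends[i]]
    structure(list(fold_id = i, train_ids = setdiff(study_ids, test),
                   test_ids = test),
              class = "fold_split")
  })
}
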