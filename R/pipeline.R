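#' Default run configuration for the command-line pipeline
#'
#' A single nested list drives every pipeline stage (generation, attention
#' precomputation, training, prediction, evaluation). All seeds are explicit
#' so two runs of the same configuration are identical. Learning rates
#' default to 1e-4 for the attention backbone and 0.005 for the Bi-CLSTM
#' head.
#'
#' @param out_dir output directory for all stages.
#' @param n_studies cohort size.
#' @param image_size phantom slice size in pixels.
#' @param n_slices slices per phantom study.
#' @param k number of cross-validation folds.
#' @param N sequence length (odd).
#' @param seed master seed.
#' @param backbone_lr,backbone_steps backbone SGD settings.
#' @param head_lr,head_steps head SGD settings.
#' @param noise_sigma,tissue_overlap phantom difficulty knobs.
#' @return A nested configuration list (class `run_config`).
#' @export
run_config <- function(out_dir, n_studies = 4L, image_size = 32L, n_slices = 8L,
                       k = 2L, N = 5L, seed = 1L,
                       backbone_lr = 1e-4, backbone_steps = 150L,
                       head_lr = 0.005, head_steps = 150L,
                       noise_sigma = 2, tissue_overlap = 0.2,
                       center_drift = 0.5) {
  structure(list(
    version = "1",
    out_dir = out_dir,
    seed = as.integer(seed),
    phantom = list(n_studies = as.integer(n_studies),
                   image_size = as.integer(image_size),
                   n_slices = as.integer(n_slices),
                   noise_sigma = noise_sigma, tissue_overlap = tissue_overlap,
                   center_drift = center_drift),
    cv = list(k = as.integer(k)),
    sequence = list(N = as.integer(N), boundary = "replicate"),
    backbone = list(filters = 8L, lr = backbone_lr, steps = as.integer(backbone_steps)),
    head = list(residual_filters = 8L, clstm_filters = 16L, fusion_filters = 8L,
                lr = head_lr, steps = as.integer(head_steps))),
    class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  structure(yaml::read_yaml(path), class = "run_config")
}

cohort_dir <- function(config) file.path(config$out_dir, "studies")

log_msg <- function(...) message("[thrombseg] ", ...)

#' Pipeline stage: generate a phantom cohort on disk
#'
#' Generates the configured cohort in memory first (so invalid parameters
#' abort before anything is written), then writes one NIfTI study directory
#' per phantom plus a cohort `manifest.json` listing ids, seeds and
#' parameters. Reruns with the same configuration are byte-identical.
#'
#' @param config a [run_config()].
#' @return The manifest, invisibly.
#' @export
cmd_generate <- function(config) {
  ph <- config$phantom
  params <- phantom_params(image_size = ph$image_size, n_slices = ph$n_slices,
                           noise_sigma = ph$noise_sigma,
                           tissue_overlap = ph$tissue_overlap,
                           center_drift = ph$center_drift)
  cohort <- generate_cohort(ph$n_studies, params, seed = config$seed)
  dir.create(cohort_dir(config), recursive = TRUE, showWarnings = FALSE)
  for (st in cohort) write_study(st, file.path(cohort_dir(config), st$study_id))
  manifest <- list(
    study_ids = vapply(cohort, `[[`, character(1), "study_id"),
    seeds = vapply(seq_along(cohort), function(i) study_seed(config$seed, i),
                   integer(1)),
    params = unclass(params)[setdiff(names(unclass(params)), "seed")],
    cohort_seed = config$seed)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_msg("generated ", length(cohort), " studies in ", cohort_dir(config))
  invisible(manifest)
}

load_cohort <- function(config) {
  mf <- file.path(config$out_dir, "manifest.json")
  if (!file.exists(mf))
    stop("no cohort manifest in ", config$out_dir, "; run cmd_generate first",
         call. = FALSE)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  studies <- lapply(manifest$study_ids, function(id)
    load_study(file.path(cohort_dir(config), id)))
  names(studies) <- manifest$study_ids
  studies
}

attention_cache_file <- function(config, fold_id, study_id)
  file.path(config$out_dir, "attention", sprintf("fold%d_%s.rds", fold_id, study_id))

# compute (or reuse) the per-slice attention maps of one study
cached_attention <- function(config, fold_id, study, provider) {
  f <- attention_cache_file(config, fold_id, study$study_id)
  if (file.exists(f)) {
    log_msg("attention cache hit: ", basename(f))
    return(readRDS(f))
  }
  maps <- lapply(seq_len(n_slices(study)), function(s)
    extract_attention_map(study$slices[, , s], provider))
  dir.create(dirname(f), recursive = TRUE, showWarnings = FALSE)
  saveRDS(maps, f)
  maps
}

fold_backbone <- function(config, fold, train_studies) {
  bb <- lightweight_backbone(filters = config$backbone$filters,
                             seed = config$seed + fold$fold_id)
  train_backbone(bb, train_studies, lr = config$backbone$lr,
                 steps = config$backbone$steps,
                 seed = config$seed + fold$fold_id)$provider
}

#' Pipeline stage: precompute and cache attention maps per fold
#'
#' Trains each fold's backbone and caches the per-slice attention maps of
#' its training studies, so a later [cmd_train()] finds them ready (cache
#' hits are logged). Backbone training is deterministic given the config
#' seed, so the maps are identical to the ones [cmd_train()] would compute.
#'
#' @param config a [run_config()].
#' @return Invisibly, the fold descriptors.
#' @export
cmd_attention <- function(config) {
  studies <- load_cohort(config)
  folds <- make_cv_folds(names(studies), k = config$cv$k, seed = config$seed)
  for (fold in folds) {
    train_studies <- lapply(studies[fold$train_ids], filter_slices_with_roi)
    bb <- fold_backbone(config, fold, train_studies)
    for (st in train_studies) cached_attention(config, fold$fold_id, st, bb)
    log_msg("fold ", fold$fold_id, ": attention maps cached")
  }
  invisible(folds)
}

#' Pipeline stage: train one model per cross-validation fold
#'
#' For each fold: the attention backbone is trained on the fold's training
#' studies (slices without ROI excluded first), per-slice attention maps are
#' computed and cached, N-pair sequences are built, and the Bi-CLSTM head is
#' trained with SGD on focal loss. Each fold writes a checkpoint and a loss
#' trace named by fold.
#'
#' @param config a [run_config()].
#' @return Invisibly, the list of fold descriptors.
#' @export
cmd_train <- function(config) {
  studies <- load_cohort(config)
  folds <- make_cv_folds(names(studies), k = config$cv$k, seed = config$seed)
  ckpt_dir <- file.path(config$out_dir, "checkpoints")
  dir.create(ckpt_dir, recursive = TRUE, showWarnings = FALSE)
  for (fold in folds) {
    log_msg("fold ", fold$fold_id, ": training on ",
            length(fold$train_ids), " studies")
    train_studies <- lapply(studies[fold$train_ids], filter_slices_with_roi)
    bb <- fold_backbone(config, fold, train_studies)
    sequences <- list()
    for (st in train_studies) {
      maps <- cached_attention(config, fold$fold_id, st, bb)
      sequences <- c(sequences,
                     build_sequences(st, maps, N = config$sequence$N,
                                     boundary = config$sequence$boundary))
    }
    cfg <- head_config(residual_filters = config$head$residual_filters,
                       clstm_filters = config$head$clstm_filters,
                       fusion_filters = config$head$fusion_filters)
    model <- biclstm_head(cfg, seed = config$seed + fold$fold_id)
    tr <- train_head(model, sequences, lr = config$head$lr,
                     steps = config$head$steps,
                     seed = config$seed + fold$fold_id)
    save_checkpoint(tr$model, file.path(ckpt_dir, sprintf("fold%d.rds", fold$fold_id)))
    utils::write.csv(
      data.frame(step = seq_along(tr$trace), loss = tr$trace),
      file.path(ckpt_dir, sprintf("fold%d_trace.csv", fold$fold_id)),
      row.names = FALSE)
    saveRDS(bb, file.path(ckpt_dir, sprintf("fold%d_backbone.rds", fold$fold_id)))
    log_msg("fold ", fold$fold_id, ": final loss ",
            signif(utils::tail(tr$trace, 1), 4))
  }
  saveRDS(folds, file.path(ckpt_dir, "folds.rds"))
  invisible(folds)
}

#' Predict thrombus masks for one study
#'
#' @param config a [run_config()].
#' @param study a [patient_study()] (its slices are used; masks ignored).
#' @param fold_id which fold's checkpoint to use.
#' @return A `patient_study` whose masks are the predictions.
#' @export
cmd_predict <- function(config, study, fold_id = 1L) {
  ckpt_dir <- file.path(config$out_dir, "checkpoints")
  model <- load_checkpoint(file.path(ckpt_dir, sprintf("fold%d.rds", fold_id)))
  bb <- readRDS(file.path(ckpt_dir, sprintf("fold%d_backbone.rds", fold_id)))
  maps <- lapply(seq_len(n_slices(study)), function(s)
    extract_attention_map(study$slices[, , s], bb))
  # prediction needs no ground truth; feed a placeholder mask
  shadow <- patient_study(study$study_id, study$slices,
                          array(0L, dim(study$slices)) + 1L,
                          study$pixel_spacing, study$slice_indices)
  seqs <- build_sequences(shadow, maps, N = config$sequence$N,
                          boundary = config$sequence$boundary)
  pred <- array(0L, dim(study$slices))
  for (s in seq_along(seqs)) pred[, , s] <- predict(model, seqs[[s]])$mask
  patient_study(study$study_id, study$slices, pred, study$pixel_spacing,
                study$slice_indices)
}

#' Pipeline stage: evaluate each study in the fold where it is a test item
#'
#' Writes slice-, study- and fold-level CSV reports plus an overall JSON
#' summary; the overall report is the unweighted mean of the fold reports.
#' With `gt_self = TRUE` the ground truth is evaluated against itself (a
#' debugging identity: all overlap metrics 1, error metrics 0).
#'
#' @param config a [run_config()].
#' @param gt_self debug flag.
#' @return The overall `metrics_report`, invisibly.
#' @export
cmd_evaluate <- function(config, gt_self = FALSE) {
  studies <- load_cohort(config)
  ckpt_dir <- file.path(config$out_dir, "checkpoints")
  ff <- file.path(ckpt_dir, "folds.rds")
  if (!file.exists(ff)) stop("no trained folds; run cmd_train first", call. = FALSE)
  folds <- readRDS(ff)
  rep_dir <- file.path(config$out_dir, "reports")
  dir.create(rep_dir, recursive = TRUE, showWarnings = FALSE)
  slice_rows <- list()
  study_reports <- list()
  fold_reports <- list()
  for (fold in folds) {
    model <- load_checkpoint(file.path(ckpt_dir, sprintf("fold%d.rds", fold$fold_id)))
    bb <- readRDS(file.path(ckpt_dir, sprintf("fold%d_backbone.rds", fold$fold_id)))
    per_study <- list()
    for (id in fold$test_ids) {
      st <- filter_slices_with_roi(studies[[id]])
      maps <- lapply(seq_len(n_slices(st)), function(s)
        extract_attention_map(st$slices[, , s], bb))
      seqs <- build_sequences(st, maps, N = config$sequence$N,
                              boundary = config$sequence$boundary)
      slice_reports <- lapply(seq_along(seqs), function(s) {
        pred <- if (gt_self) st$gt_masks[, , s] else predict(model, seqs[[s]])$mask
        compute_metrics(pred, st$gt_masks[, , s], level = "slice")
      })
      for (s in seq_along(slice_reports)) {
        row <- as.data.frame(slice_reports[[s]])
        row$study_id <- id
        row$fold <- fold$fold_id
        row$slice_index <- st$slice_indices[s]
        slice_rows[[length(slice_rows) + 1L]] <- row
      }
      sr <- aggregate_metrics(slice_reports, level = "study")
      per_study[[id]] <- sr
      srow <- as.data.frame(sr)
      srow$study_id <- id
      srow$fold <- fold$fold_id
      study_reports[[id]] <- srow
    }
    fold_reports[[fold$fold_id]] <- aggregate_metrics(per_study, level = "fold")
  }
  overall <- aggregate_metrics(fold_reports, level = "overall")
  utils::write.csv(do.call(rbind, slice_rows),
                   file.path(rep_dir, "slices.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, unname(study_reports)),
                   file.path(rep_dir, "studies.csv"), row.names = FALSE)
  utils::write.csv(
    do.call(rbind, lapply(seq_along(fold_reports), function(i) {
      r <- as.data.frame(fold_reports[[i]])
      r$fold <- i
      r
    })),
    file.path(rep_dir, "folds.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(overall = as.data.frame(overall),
         folds = do.call(rbind, lapply(fold_reports, as.data.frame))),
    file.path(rep_dir, "summary.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  log_msg(sprintf("overall: TO=%.4f Dice=%.4f Jaccard=%.4f FN=%.4f FP=%.4f",
                  overall$TO, overall$Dice, overall$Jaccard, overall$FN,
                  overall$FP))
  invisible(overall)
}

#' Run the whole pipeline: generate, train, evaluate
#'
#' @param config a [run_config()].
#' @return The overall `metrics_report`, invisibly.
#' @export
run_pipeline <- function(config) {
  cmd_generate(config)
  cmd_train(config)
  cmd_evaluate(config)
}
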