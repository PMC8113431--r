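#' Image-set labels of the evaluation design
#'
#' Five whole-body image sets per test subject: the 4-min gold standard, and
#' the 1.5-min and 1-min short acquisitions with and without network
#' enhancement.
#' @export
IMAGE_SETS <- c("4 min", "1.5 min", "1.5 min CNN", "1 min", "1 min CNN")

#' End-to-end study configuration
#'
#' Collects every knob of the simulate - prepare - train - denoise -
#' evaluate - compare pipeline. The acquisition design is fixed: training
#' subjects contribute one 6-min frame per bed position, reconstructed at
#' beta 200 (clean target) and split into four 1.5-min quarters and the
#' first four 1-min sixths (noisy inputs, beta 500); test subjects are
#' acquired for 4 min (beta 300 reference) with 1.5-min and 1-min
#' sub-frames drawn from the same acquisition (beta 500).
#'
#' @param n_train_subjects,n_test_subjects phantom counts for the two arms.
#' @param train_shape,test_shape phantom grids `(rows, cols, slices)`;
#'   training uses a 64 x 64 in-plane grid so training blocks are natively
#'   64 x 64 x 5.
#' @param betas named durations-to-beta map.
#' @param calib a [scanner_calib()].
#' @param model_config a [cnn_config()] shared by the two networks (each is
#'   trained independently on its own pair set).
#' @param n_aug augmented samples per training reconstruction.
#' @param weight_kg,injected_MBq simulated subject metadata (4 MBq/kg).
#' @param seed master seed; every stage seed is derived from it.
#' @return a `run_config` list.
#' @export
run_config <- function(n_train_subjects = 3L, n_test_subjects = 10L,
                       train_shape = c(64L, 64L, 71L),
                       test_shape = c(128L, 128L, 71L),
                       betas = c("6" = 200, "4" = 300, "1.5" = 500,
                                 "1" = 500),
                       calib = scanner_calib(),
                       model_config = cnn_config(n_layers = 4L,
                                                 n_filters = 8L,
                                                 epochs = 12L,
                                                 learning_rate = 0.01,
                                                 batch_size = 4L),
                       n_aug = 1L, weight_kg = 70, injected_MBq = 280,
                       seed = 1L) {
  stopifnot(n_train_subjects >= 0, n_test_subjects >= 0,
            all(c("6", "4", "1.5", "1") %in% names(betas)),
            inherits(calib, "scanner_calib"),
            inherits(model_config, "cnn_config"))
  structure(list(n_train_subjects = as.integer(n_train_subjects),
                 n_test_subjects = as.integer(n_test_subjects),
                 train_shape = as.integer(train_shape),
                 test_shape = as.integer(test_shape),
                 betas = betas, calib = calib, model_config = model_config,
                 n_aug = as.integer(n_aug), weight_kg = weight_kg,
                 injected_MBq = injected_MBq, seed = as.integer(seed)),
            class = "run_config")
}

derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Simulate one training subject
#'
#' Builds a random phantom, acquires one 6-min frame, reconstructs the clean
#' target (beta 200), and derives the noisy reconstructions by exact count
#' splitting: the four 1.5-min quarters and the first four 1-min sixths,
#' both at beta 500.
#'
#' @param config a [run_config()].
#' @param subject_seed integer seed for this subject.
#' @param id subject identifier.
#' @return list with `id`, `clean`, and per-duration noisy reconstruction
#'   lists `noisy_1min`, `noisy_1p5min`.
#' @export
simulate_training_subject <- function(config, subject_seed, id) {
  seeds <- derive_seeds(subject_seed, 4L)
  spec <- random_phantom_spec(seeds[1], shape = config$train_shape)
  act <- build_phantom(spec)
  frame6 <- simulate_frame(act, 6, config$calib, seeds[2])
  recon <- function(fr, beta) {
    emulate_reconstruction(fr, beta, config$calib,
                           config$weight_kg, config$injected_MBq)
  }
  quarters <- split_frame(frame6, 4L, seeds[3])
  sixths <- split_frame(frame6, 6L, seeds[4])
  list(id = id,
       clean = recon(frame6, config$betas[["6"]]),
       noisy_1p5min = lapply(quarters, recon, beta = config$betas[["1.5"]]),
       noisy_1min = lapply(sixths[1:4], recon, beta = config$betas[["1"]]))
}

#' Simulate one test subject's five image sets
#'
#' Builds a random phantom, acquires one 4-min frame, reconstructs the 4-min
#' reference (beta 300) and the 1.5-min and 1-min sub-frames (binomial
#' thinning of the same acquisition, beta 500). The CNN image sets are added
#' later by [run_study()] once the networks are trained.
#'
#' @inheritParams simulate_training_subject
#' @return list with `id`, `volumes` (named: `4 min`, `1.5 min`, `1 min`),
#'   `masks` (phantom masks) and `rois` (liver ROI set).
#' @export
simulate_test_subject <- function(config, subject_seed, id) {
  seeds <- derive_seeds(subject_seed, 4L)
  spec <- random_phantom_spec(seeds[1], shape = config$test_shape)
  act <- build_phantom(spec)
  frame4 <- simulate_frame(act, 4, config$calib, seeds[2])
  recon <- function(fr, beta) {
    emulate_reconstruction(fr, beta, config$calib,
                           config$weight_kg, config$injected_MBq)
  }
  vols <- list(
    "4 min" = recon(frame4, config$betas[["4"]]),
    "1.5 min" = recon(subframe(frame4, 1.5, seeds[3]),
                      config$betas[["1.5"]]),
    "1 min" = recon(subframe(frame4, 1, seeds[4]), config$betas[["1"]]))
  list(id = id, volumes = vols, masks = phantom_masks(act),
       rois = liver_rois_from_phantom(act))
}

#' Build the two training-pair sets
#'
#' @param config a [run_config()].
#' @return list with elements `pairs_1min` and `pairs_1p5min`
#'   ([build_pairs()] tibbles) — one per network.
#' @export
prepare_training_pairs <- function(config) {
  if (config$n_train_subjects == 0L) {
    return(list(pairs_1min = NULL, pairs_1p5min = NULL))
  }
  seeds <- derive_seeds(config$seed + 1L, config$n_train_subjects)
  subjects <- lapply(seq_len(config$n_train_subjects), function(i) {
    simulate_training_subject(config, seeds[i], paste0("train_", i))
  })
  src <- function(field) {
    lapply(subjects, function(s) {
      list(id = s$id, clean = s$clean, noisy = s[[field]])
    })
  }
  list(
    pairs_1min = build_pairs(src("noisy_1min"), n_aug = config$n_aug,
                             seed = config$seed + 11L),
    pairs_1p5min = build_pairs(src("noisy_1p5min"), n_aug = config$n_aug,
                               seed = config$seed + 12L))
}

#' Run the full synthetic study
#'
#' Simulates the training arm, trains the two denoising networks (one for
#' 1-min, one for 1.5-min inputs), simulates the test arm, produces the five
#' image sets per test subject, computes the quantitative metrics, and runs
#' the statistical comparison suite.
#'
#' @param config a [run_config()].
#' @param verbose print stage progress.
#' @param keep_volumes retain every test subject's five image sets in the
#'   result (memory permitting); used by [run_pipeline()] to persist them.
#' @return list: `config`, `models` (named list), `metrics` (tibble),
#'   `comparison` ([run_comparison_suite()] result), `preservation`
#'   (lesion-preservation checks), `pair_counts`, and optionally `volumes`.
#' @export
run_study <- function(config = run_config(), verbose = FALSE,
                      keep_volumes = FALSE) {
  say <- function(...) if (verbose) message(...)
  say("stage: prepare (simulate training arm, build pairs)")
  pairs <- prepare_training_pairs(config)
  models <- list()
  if (is.null(pairs$pairs_1min) || nrow(pairs$pairs_1min) == 0L) {
    warning("no training pairs available; training stage skipped",
            call. = FALSE)
  } else {
    say("stage: train 1 min network (", nrow(pairs$pairs_1min), " pairs)")
    cfg1 <- config$model_config; cfg1$seed <- config$seed + 21L
    models[["1 min"]] <- cnn_train(cnn_build(cfg1), pairs$pairs_1min)
    say("stage: train 1.5 min network (", nrow(pairs$pairs_1p5min),
        " pairs)")
    cfg2 <- config$model_config; cfg2$seed <- config$seed + 22L
    models[["1.5 min"]] <- cnn_train(cnn_build(cfg2), pairs$pairs_1p5min)
  }

  say("stage: simulate test arm and evaluate")
  seeds <- derive_seeds(config$seed + 2L, max(config$n_test_subjects, 1L))
  metrics <- list()
  preservation <- list()
  volumes <- list()
  for (i in seq_len(config$n_test_subjects)) {
    subj <- simulate_test_subject(config, seeds[i], sprintf("test_%02d", i))
    vols <- subj$volumes
    if (length(models) == 2L) {
      vols[["1.5 min CNN"]] <- denoise_volume(models[["1.5 min"]],
                                              vols[["1.5 min"]])
      vols[["1 min CNN"]] <- denoise_volume(models[["1 min"]],
                                            vols[["1 min"]])
      preservation[[subj$id]] <- check_lesion_preservation(
        vols[["1.5 min"]], vols[["1.5 min CNN"]], subj$masks)
    }
    lesions <- subj$masks[grep("^lesion_", names(subj$masks))]
    metrics[[i]] <- evaluate_image_sets(vols[IMAGE_SETS[IMAGE_SETS %in%
                                                          names(vols)]],
                                        lesions, subj$rois,
                                        subject = subj$id)
    if (keep_volumes) {
      volumes[[subj$id]] <- list(volumes = vols, masks = subj$masks)
    }
  }
  metrics <- dplyr::bind_rows(metrics)
  comparison <- NULL
  if (length(models) == 2L && config$n_test_subjects >= 2L) {
    say("stage: compare")
    comparison <- run_comparison_suite(metrics)
  }
  out <- list(config = config, models = models, metrics = metrics,
              comparison = comparison, preservation = preservation,
              pair_counts = vapply(pairs, function(p) if (is.null(p)) 0L
                                   else nrow(p), 1L))
  if (keep_volumes) out$volumes <- volumes
  out
}

#' Run the pipeline and persist every artifact
#'
#' [run_study()] plus provenance: writes each test subject's five image sets
#' as NIfTI, the metrics as a tidy CSV, the omnibus/pairwise statistics
#' tables as CSVs, the two model checkpoints, and a manifest recording the
#' config hash and all derived seeds. Re-running with the same config
#' reproduces all outputs bitwise.
#'
#' @inheritParams run_study
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config = run_config(), out_dir, verbose = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- run_study(config, verbose = verbose, keep_volumes = TRUE)
  for (id in names(res$volumes)) {
    sd <- file.path(out_dir, id)
    dir.create(sd, showWarnings = FALSE)
    vols <- res$volumes[[id]]$volumes
    for (nm in names(vols)) {
      write_volume(vols[[nm]],
                   file.path(sd, paste0(gsub("[ .]", "_", nm), ".nii.gz")))
    }
    write_masks(res$volumes[[id]]$masks, dim(vols[[1]]),
                voxel_size(vols[[1]]), file.path(sd, "masks.nii.gz"))
  }
  utils::write.csv(res$metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  if (!is.null(res$comparison)) {
    utils::write.csv(res$comparison$omnibus,
                     file.path(out_dir, "stats_omnibus.csv"),
                     row.names = FALSE)
    utils::write.csv(res$comparison$pairwise,
                     file.path(out_dir, "stats_pairwise.csv"),
                     row.names = FALSE)
  }
  for (nm in names(res$models)) {
    save_model(res$models[[nm]],
               file.path(out_dir, paste0("model_", gsub("[ .]", "_", nm),
                                         ".json")))
  }
  manifest <- list(
    config_hash = rlang::hash(config),
    seed = config$seed,
    n_train_subjects = config$n_train_subjects,
    n_test_subjects = config$n_test_subjects,
    image_sets = IMAGE_SETS,
    examinations = nrow(examination_manifest(config$n_test_subjects)),
    pair_counts = as.list(res$pair_counts),
    created = "run_pipeline")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Examination manifest
#'
#' One row per (subject, image set): with the full design of 25 test
#' subjects and 5 image sets this enumerates 125 examinations.
#'
#' @param n_subjects number of test subjects.
#' @param image_sets image-set labels.
#' @return tibble with columns `subject`, `image_set`, `examination`.
#' @export
examination_manifest <- function(n_subjects = 25L,
                                 image_sets = IMAGE_SETS) {
  m <- tidyr::expand_grid(subject = sprintf("test_%02d",
                                            seq_len(n_subjects)),
                          image_set = image_sets)
  dplyr::mutate(m, examination = dplyr::row_number())
}

#' Summary plot of a metric across image sets
#'
#' @param metrics tibble from [evaluate_image_sets()] / [run_study()].
#' @param metric one of `"cov"`, `"suv_max"`, `"suv_peak"`.
#' @return a ggplot: per-image-set mean with SD error bars.
#' @export
plot_image_set_metrics <- function(metrics, metric = c("cov", "suv_max",
                                                       "suv_peak")) {
  metric <- match.arg(metric)
  df <- dplyr::summarise(
    dplyr::group_by(metrics, .data$image_set),
    mean = mean(.data[[metric]]), sd = stats::sd(.data[[metric]]),
    .groups = "drop")
  df$image_set <- factor(df$image_set,
                         levels = image_set_order(df$image_set))
  ggplot2::ggplot(df, ggplot2::aes(.data$image_set, .data$mean)) +
    ggplot2::geom_col(fill = "steelblue", alpha = 0.8) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.25) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal()
}
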