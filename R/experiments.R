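# End-to-end phantom experiments mirroring the two-experiment design:
# experiment 1 compares the single-phase network (DCNN-F, hepatobiliary
# phase only) against the full-size fusion network (DFN-F); experiment 2
# runs the ROI-constrained fusion network (DFN-R). Everything is a
# deterministic function of the configuration and its master seed.

#' Experiment configuration
#'
#' @param phantom a [phantom_spec()] describing the study conditions (its
#'   seed field is replaced per case).
#' @param n_cases number of synthetic patients (LOOCV folds).
#' @param seed master seed; every other seed is derived from it.
#' @param roster subset of `c("DCNN-F", "DFN-F", "DFN-R")`.
#' @param input_size network input size (divisible by 8).
#' @param base_channels width of the first conv block.
#' @param dcnn_train [train_config()] for staged per-phase training.
#' @param fusion_train [train_config()] for the fusion stage.
#' @param fusion [fusion_config()] used when building fusion networks.
#' @param aug [augment_params()] for stage-3 fine-tuning.
#' @param roi_jitter,roi_margin ROI stand-in settings for DFN-R: ground-truth
#'   bounding boxes jittered by up to `roi_jitter` voxels per face, expanded
#'   by `roi_margin` (emulating a rough manual box).
#' @param register run B-spline registration of phase 2 per case (skipped
#'   automatically when the phantom has no deformation).
#' @param threshold binarization threshold.
#' @param outdir optional output directory for metrics JSON and reports.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(phantom = phantom_spec(
                                confounder_mode = "organ_mimic",
                                deformation_amplitude = 1.5),
                              n_cases = 8L, seed = 1L,
                              roster = c("DCNN-F", "DFN-F", "DFN-R"),
                              input_size = 32L, base_channels = 8L,
                              dcnn_train = train_config(
                                optimizer = "adam", base_lr = 3e-3,
                                epochs = c(3L, 6L, 6L)),
                              fusion_train = train_config(
                                optimizer = "sgd", base_lr = 0.05,
                                momentum = 0.9, epochs_fusion = 10L),
                              fusion = fusion_config(),
                              aug = augment_params(multiplicity = 1L),
                              roi_jitter = 2L, roi_margin = 2L,
                              register = TRUE, threshold = 0.5,
                              outdir = NULL) {
  roster <- match.arg(roster, several.ok = TRUE)
  if (length(roster) == 0) stopf("model roster must be nonempty")
  structure(list(phantom = phantom, n_cases = as.integer(n_cases),
                 seed = as.integer(seed), roster = roster,
                 input_size = as.integer(input_size),
                 base_channels = as.integer(base_channels),
                 dcnn_train = dcnn_train, fusion_train = fusion_train,
                 fusion = fusion, aug = aug, roi_jitter = as.integer(roi_jitter),
                 roi_margin = as.integer(roi_margin),
                 register = register, threshold = threshold,
                 outdir = outdir),
            class = "experiment_config")
}

# Generate the phantom cohort, register phase 2 per case where deformation
# is present, and attach network-ready tumor slice pairs.
prepare_experiment_cases <- function(cfg) {
  ds <- generate_dataset(cfg$phantom, cfg$n_cases, derive_seed(cfg$seed, 101))
  lapply(ds$cases, function(cs) {
    if (cfg$register && cfg$phantom$deformation_amplitude > 0) {
      sp <- pmax(dim(cs$phase1) %/% 6, 3)
      reg <- register_phase2_to_phase1(
        cs$phase2, cs$phase1,
        registration_params(spacings = list(sp * 2, sp), iterations = 30))
      cs$phase2_registered <- reg$registered
    }
    cs$pairs <- make_network_pairs(cs, cfg$input_size)
    cs
  })
}

model_seed <- function(cfg, model) {
  derive_seed(cfg$seed, 1000 + match(model, c("DCNN-F", "DFN-F", "DFN-R")))
}

sub_dcnn_cfg <- function(cfg)
  dcnn_config(cfg$input_size, cfg$base_channels)

with_fold_seed <- function(tc, fold_seed) {
  tc$seed <- as.integer(fold_seed %% 2147483647)
  tc
}

fit_dcnn_f <- function(cfg) {
  function(train_cases, fold_seed) {
    pairs <- do.call(c, lapply(train_cases, `[[`, "pairs"))
    net <- build_dcnn(sub_dcnn_cfg(cfg), derive_seed(fold_seed, 5))
    aug <- cfg$aug; aug$seed <- as.integer(derive_seed(fold_seed, 6))
    train_dcnn_staged(net, pairs, with_fold_seed(cfg$dcnn_train, fold_seed),
                      aug, phase = 1)$net
  }
}

fit_dfn <- function(cfg, roi_mode = FALSE) {
  function(train_cases, fold_seed) {
    pairs <- if (roi_mode)
      do.call(c, lapply(train_cases, function(cs) cs$roi_pairs))
    else do.call(c, lapply(train_cases, `[[`, "pairs"))
    dfn <- build_dfn(cfg$fusion, sub_dcnn_cfg(cfg),
                     derive_seed(fold_seed, 5))
    aug <- cfg$aug; aug$seed <- as.integer(derive_seed(fold_seed, 6))
    train_dfn(dfn, pairs, with_fold_seed(cfg$dcnn_train, fold_seed),
              with_fold_seed(cfg$fusion_train, fold_seed), aug)$net
  }
}

# ROI stand-in for one case: jittered ground-truth bounding box.
case_roi <- function(cfg, case) {
  roi_from_mask(case$gt_mask, jitter = cfg$roi_jitter,
                margin = cfg$roi_margin,
                seed = derive_seed(cfg$seed, 500 + case$seed %% 100000))
}

# Cropped-training pairs for DFN-R: each training case restricted to its
# (jittered) ROI box before slice selection.
attach_roi_pairs <- function(cfg, cases) {
  lapply(cases, function(cs) {
    box <- case_roi(cfg, cs)
    p2 <- cs$phase2_registered %||% cs$phase2
    crop_case <- list(phase1 = crop_to_roi(cs$phase1, box),
                      phase2 = crop_to_roi(p2, box),
                      gt_mask = crop_to_roi(cs$gt_mask, box),
                      id = cs$id)
    cs$roi_box <- box
    cs$roi_pairs <- make_network_pairs(crop_case, cfg$input_size)
    cs
  })
}

#' Run experiment 1: full-size models
#'
#' Leave-one-out cross-validation of the single-phase network (phase 1
#' input) and/or the full-size fusion network on the phantom cohort.
#'
#' @param cfg an [experiment_config()] whose roster includes `"DCNN-F"`
#'   and/or `"DFN-F"`.
#' @param cases optional pre-built cohort from `prepare_experiment_cases`
#'   (rebuilt from `cfg` when omitted).
#' @return named list per model: `results` data.frame and fold `manifests`.
#' @export
run_experiment1 <- function(cfg, cases = NULL) {
  roster <- intersect(cfg$roster, c("DCNN-F", "DFN-F"))
  if (length(roster) == 0) stopf("experiment 1 needs DCNN-F and/or DFN-F")
  if (is.null(cases)) cases <- prepare_experiment_cases(cfg)
  icfg <- infer_config(cfg$input_size, cfg$threshold, phase = 1)
  out <- list()
  for (m in roster) {
    train_fn <- if (m == "DCNN-F") fit_dcnn_f(cfg) else fit_dfn(cfg)
    out[[m]] <- run_loocv(cases, train_fn,
                          function(model, case) segment_case(model, case, icfg),
                          seed = model_seed(cfg, m))
  }
  out
}

#' Run experiment 2: ROI-constrained fusion network
#'
#' Per-case ROI boxes are generated from the ground truth with the
#' configured jitter and margin (standing in for manually dragged
#' rectangles); the fusion network is trained on ROI crops and evaluated
#' with predictions pasted back into the full grid.
#'
#' @inheritParams run_experiment1
#' @return list with `results` and `manifests` for DFN-R.
#' @export
run_experiment2 <- function(cfg, cases = NULL) {
  if (!"DFN-R" %in% cfg$roster) stopf("experiment 2 needs DFN-R in the roster")
  if (is.null(cases)) cases <- prepare_experiment_cases(cfg)
  cases <- attach_roi_pairs(cfg, cases)
  icfg <- infer_config(cfg$input_size, cfg$threshold, phase = 1)
  run_loocv(cases, fit_dfn(cfg, roi_mode = TRUE),
            function(model, case)
              segment_roi(model, case, case$roi_box, icfg),
            seed = model_seed(cfg, "DFN-R"))
}

#' Compare models with paired t-tests
#'
#' Pairwise paired t-tests on the per-case DSC vectors, plus a rendered
#' report. Case id sets must match across models.
#'
#' @param metrics named list of per-model `results` data.frames (columns
#'   `case_id`, `dsc`, `precision`, `recall`).
#' @param reference model name the report's p-value column compares against
#'   (default: the first model).
#' @return list with `report`, `summaries`, and `tests` (named list of
#'   [paired_t_test()] results per model pair).
#' @export
compare_models <- function(metrics, reference = names(metrics)[1]) {
  if (length(metrics) < 1) stopf("need at least one model")
  ids <- lapply(metrics, function(m) sort(m$case_id))
  for (i in seq_along(ids))
    if (!identical(ids[[i]], ids[[1]]))
      stopf("models were evaluated on different case sets")
  tests <- list()
  nm <- names(metrics)
  if (length(nm) >= 2) {
    for (i in seq_along(nm)) for (j in seq_along(nm)) {
      if (i >= j) next
      a <- metrics[[i]][order(metrics[[i]]$case_id), "dsc"]
      b <- metrics[[j]][order(metrics[[j]]$case_id), "dsc"]
      tests[[paste0(nm[i], "_vs_", nm[j])]] <- paired_t_test(a, b)
    }
  }
  summaries <- lapply(metrics, aggregate_metrics)
  pcol <- NULL
  if (length(nm) >= 2) {
    pcol <- vapply(setdiff(nm, reference), function(m) {
      key <- if (paste0(reference, "_vs_", m) %in% names(tests))
        paste0(reference, "_vs_", m) else paste0(m, "_vs_", reference)
      tests[[key]]$p
    }, numeric(1))
  }
  list(report = make_report(summaries, pcol), summaries = summaries,
       tests = tests)
}

#' Run the full experiment suite
#'
#' Generates the cohort once, runs the configured models through their
#' LOOCV protocols, compares them, and (optionally) writes per-model metric
#' JSON files, the fold manifests, and the report to `cfg$outdir`. The
#' entire output is a deterministic function of the configuration.
#'
#' @param cfg an [experiment_config()].
#' @return list with `metrics` (named list of data.frames), `manifests`,
#'   `comparison` (from [compare_models()]), and `cases_seed`.
#' @export
run_experiment <- function(cfg) {
  cases <- prepare_experiment_cases(cfg)
  metrics <- list(); manifests <- list()
  if (length(intersect(cfg$roster, c("DCNN-F", "DFN-F")))) {
    e1 <- run_experiment1(cfg, cases)
    for (m in names(e1)) {
      metrics[[m]] <- e1[[m]]$results
      manifests[[m]] <- e1[[m]]$manifests
    }
  }
  if ("DFN-R" %in% cfg$roster) {
    e2 <- run_experiment2(cfg, cases)
    metrics[["DFN-R"]] <- e2$results
    manifests[["DFN-R"]] <- e2$manifests
  }
  comparison <- compare_models(metrics)
  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
    for (m in names(metrics))
      jsonlite::write_json(metrics[[m]],
                           file.path(cfg$outdir,
                                     paste0("metrics_", gsub("-", "_", m),
                                            ".json")),
                           dataframe = "rows", digits = NA)
    jsonlite::write_json(manifests,
                         file.path(cfg$outdir, "fold_manifests.json"))
    write_report_csv(comparison$report, file.path(cfg$outdir, "report.csv"))
    writeLines(format_report_text(comparison$report),
               file.path(cfg$outdir, "report.txt"))
  }
  list(metrics = metrics, manifests = manifests, comparison = comparison)
}

#' Desk-scale experiment presets
#'
#' `desk_experiment_config()` is the default small-cohort setting (8 cases,
#' 64x64x16 phantoms, 32x32 network input, 8 base channels, reduced epochs);
#' `mini_experiment_config()` is the smallest preset (48x48x12 phantoms,
#' 24x24 input) used where many repeated runs are needed.
#'
#' @param seed master seed.
#' @param roster model roster.
#' @name experiment_presets
#' @export
desk_experiment_config <- function(seed = 1L,
                                   roster = c("DCNN-F", "DFN-F", "DFN-R")) {
  experiment_config(
    phantom = phantom_spec(volume_shape = c(64, 64, 16),
                           liver_axes = c(26, 24, 6.5),
                           lesion_radius_range = c(5, 7),
                           confounder_mode = "organ_mimic",
                           deformation_amplitude = 1.5),
    n_cases = 8L, seed = seed, roster = roster,
    input_size = 32L, base_channels = 8L)
}

#' @rdname experiment_presets
#' @export
mini_experiment_config <- function(seed = 1L,
                                   roster = c("DCNN-F", "DFN-F", "DFN-R")) {
  experiment_config(
    phantom = phantom_spec(volume_shape = c(48, 48, 12),
                           liver_axes = c(20, 18, 5),
                           lesion_radius_range = c(4, 6),
                           confounder_mode = "organ_mimic",
                           deformation_amplitude = 1.2),
    n_cases = 8L, seed = seed, roster = roster,
    input_size = 24L, base_channels = 8L)
}
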