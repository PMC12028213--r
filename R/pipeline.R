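# End-to-end orchestration: phantom -> parametric maps -> ROI perturbation
# -> feature extraction -> ICC robustness gate -> nested selection and
# classification, with a manifest recording inputs, parameters, seeds and
# per-stage timing, and checkpoint-based resumption.

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run.  Validated eagerly so a
#' bad configuration fails before any compute.
#'
#' @param acq An [acquisition_spec()].
#' @param cohort A [cohort_spec()].
#' @param aif_model AIF model name for simulation and fitting.
#' @param bin_widths Named per-map discretisation widths.
#' @param icc_threshold Robustness gate on the ICC, in (0, 1).
#' @param selectors,classifiers Method lists for the final stage.
#' @param cv_k,cv_repetitions Fold count and repetitions of the outer CV.
#' @param relieff_permutations Label shuffles for the ReliefF null.
#' @param seed Master seed for fold plans and stochastic selectors.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(acq = acquisition_spec(),
                            cohort = cohort_spec(),
                            aif_model = "weinmann",
                            bin_widths = default_bin_widths(),
                            icc_threshold = 0.9,
                            selectors = c("auc", "relieff", "lasso",
                                          "backward"),
                            classifiers = c("lda", "knn", "svm", "nnet"),
                            cv_k = 5L, cv_repetitions = 10L,
                            relieff_permutations = 500L,
                            seed = 1L) {
  stopifnot(inherits(acq, "acquisition_spec"), inherits(cohort, "cohort_spec"))
  if (!(icc_threshold > 0 && icc_threshold < 1))
    stop("icc_threshold must lie in (0, 1)")
  if (!all(map_names() %in% names(bin_widths)))
    stop("bin_widths must cover all 12 maps")
  selectors <- match.arg(selectors, c("auc", "relieff", "lasso", "backward"),
                         several.ok = TRUE)
  classifiers <- match.arg(classifiers, c("lda", "knn", "svm", "nnet"),
                           several.ok = TRUE)
  structure(list(acq = acq, cohort = cohort, aif_model = aif_model,
                 bin_widths = bin_widths, icc_threshold = icc_threshold,
                 selectors = selectors, classifiers = classifiers,
                 cv_k = as.integer(cv_k),
                 cv_repetitions = as.integer(cv_repetitions),
                 relieff_permutations = as.integer(relieff_permutations),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Accepts a YAML file whose top-level keys mirror the arguments of
#' [pipeline_config()], [acquisition_spec()] (under `acquisition`) and
#' [cohort_spec()] (under `cohort`, excluding the distribution tables).
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  acq <- do.call(acquisition_spec, y$acquisition %||% list())
  ch <- y$cohort %||% list()
  if (!is.null(ch$n_per_class)) ch$n_per_class <- unlist(ch$n_per_class)
  cohort <- do.call(cohort_spec, ch)
  args <- y[setdiff(names(y), c("acquisition", "cohort"))]
  if (!is.null(args$bin_widths)) args$bin_widths <- unlist(args$bin_widths)
  do.call(pipeline_config, c(list(acq = acq, cohort = cohort), args))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# compute the 12 parametric maps of one lesion over the union of its ROI
# variants (so every variant indexes defined map voxels)
lesion_parametric_maps <- function(lesion, acq, aif_obj, pset) {
  union_arr <- Reduce(`|`, lapply(pset$variants, function(m) m$data),
                      lesion$mask$data)
  umask <- mask3d(union_arr, lesion$mask$spacing)
  mf <- model_free_maps(lesion$dce, umask)
  tf <- fit_tofts_maps(lesion$dce, umask, aif_obj, alpha = acq$alpha)
  iv <- ivim_maps(lesion$dwi, umask)
  list(maps = c(mf$maps, tf$maps, iv$maps),
       qc = list(model_free = mf$qc, tofts = tf$qc, ivim = iv$qc))
}

.stage_done <- function(manifest, stage) {
  isTRUE(manifest$stages[[stage]]$done)
}

.mark_stage <- function(manifest, stage, t0, extra = list()) {
  manifest$stages[[stage]] <- c(list(done = TRUE,
                                     seconds = round(as.numeric(
                                       Sys.time()) - t0, 2)), extra)
  manifest
}

.write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
}

#' Run the full pipeline
#'
#' Executes, in order: phantom generation, ROI perturbation, parametric
#' mapping (9 DCE + 3 DWI maps per lesion, fitted over the union of the 16
#' ROI variants), feature extraction (93 features x 12 maps x 16 variants
#' per lesion), the ICC robustness gate, and nested cross-validated
#' selection/classification.  Every stage writes its outputs under
#' `out_dir` and records itself in `manifest.json`; a rerun with the same
#' `out_dir` resumes after the last completed stage.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param write_images Write per-lesion NIfTI series/maps (default FALSE:
#'   only tables, reports and the manifest are written; image output is
#'   bulky and optional).
#' @param verbose Print stage progress.
#' @return List with `cohort`, `feature_table`, `robust`, `cv`,
#'   `manifest`, invisibly.
#' @export
run_pipeline <- function(config, out_dir, write_images = FALSE,
                         verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path) else list(stages = list())
  manifest$package_version <- as.character(utils::packageVersion("robustrad"))
  manifest$seed <- config$seed
  manifest$cohort_seed <- config$cohort$rng_seed
  manifest$parameters <- list(
    icc_threshold = config$icc_threshold,
    cv_k = config$cv_k, cv_repetitions = config$cv_repetitions,
    relieff_permutations = config$relieff_permutations,
    aif_model = config$aif_model,
    selectors = config$selectors, classifiers = config$classifiers)

  aif_obj <- aif(config$aif_model)
  truth_path <- file.path(out_dir, "truth_table.csv")
  ftab_path <- file.path(out_dir, "feature_table.csv")
  icc_path <- file.path(out_dir, "icc_report.csv")
  iccmat_path <- file.path(out_dir, "icc_matrix.csv")
  perf_path <- file.path(out_dir, "cv_performance.csv")
  selfreq_path <- file.path(out_dir, "selection_frequency.csv")

  # --- stage 1+2+3+4: phantom, perturbation, maps, features -------------
  # (kept in one pass per lesion to bound memory; checkpointed as a whole
  # through the feature table)
  if (.stage_done(manifest, "features") && file.exists(ftab_path) &&
      file.exists(truth_path)) {
    say("features: resuming from %s", ftab_path)
    ftab <- read_feature_table(ftab_path)
    truth_table <- utils::read.csv(truth_path)
    cohort <- NULL
  } else {
    t0 <- as.numeric(Sys.time())
    say("phantom: generating cohort (%d lesions)...",
        sum(config$cohort$n_per_class))
    cohort <- make_cohort(config$cohort, config$acq, aif_obj)
    truth_table <- cohort$truth_table
    utils::write.csv(truth_table, truth_path, row.names = FALSE)
    manifest <- .mark_stage(manifest, "phantom", t0,
                            list(n_lesions = nrow(truth_table)))
    .write_manifest(manifest, out_dir)

    t0 <- as.numeric(Sys.time())
    lesion_entries <- vector("list", length(cohort$lesions))
    n_variants <- NA_integer_
    qc_all <- list()
    for (i in seq_along(cohort$lesions)) {
      les <- cohort$lesions[[i]]
      pset <- generate_artificial_rois(les$mask)
      n_variants <- length(pset$variants)
      pm <- lesion_parametric_maps(les, config$acq, aif_obj, pset)
      qc_all[[les$id]] <- pm$qc
      rois <- c(list(original = les$mask), pset$variants)
      lesion_entries[[i]] <- list(id = les$id, maps = pm$maps, rois = rois)
      if (write_images) {
        img_dir <- file.path(out_dir, "images")
        dir.create(img_dir, showWarnings = FALSE)
        write_series(les$dce, file.path(img_dir,
                                        paste0(les$id, "_dce.nii.gz")))
        write_series(les$dwi, file.path(img_dir,
                                        paste0(les$id, "_dwi.nii.gz")))
        write_mask(les$mask, file.path(img_dir,
                                       paste0(les$id, "_mask.nii.gz")))
        for (mn in names(pm$maps))
          write_map(pm$maps[[mn]], config$acq$voxel_spacing,
                    file.path(img_dir, paste0(les$id, "_", mn, ".nii.gz")))
      }
      say("maps+rois: %s (%d/%d)", les$id, i, length(cohort$lesions))
      # free the series once maps exist
      cohort$lesions[[i]]$dce <- NULL
      cohort$lesions[[i]]$dwi <- NULL
    }
    jsonlite::write_json(qc_all, file.path(out_dir, "map_qc.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest <- .mark_stage(manifest, "maps", t0,
                            list(n_maps = length(map_names()),
                                 n_variants_per_lesion = n_variants + 1L))
    .write_manifest(manifest, out_dir)

    t0 <- as.numeric(Sys.time())
    say("features: extracting %d x %d x %d vectors...",
        length(lesion_entries), n_variants + 1L, length(map_names()))
    ftab <- extract_feature_table(lesion_entries, config$bin_widths)
    write_feature_table(ftab, ftab_path)
    manifest <- .mark_stage(manifest, "features", t0,
                            list(n_rows = nrow(ftab),
                                 n_features = ncol(ftab) - 2L))
    .write_manifest(manifest, out_dir)
  }

  # --- stage 5: ICC robustness gate -------------------------------------
  t0 <- as.numeric(Sys.time())
  robust <- robust_feature_set(ftab, threshold = config$icc_threshold)
  utils::write.csv(robust$report, icc_path, row.names = FALSE)
  utils::write.csv(robust$matrix, iccmat_path)
  say("icc: %d / %d features robust (ICC > %.2f)",
      length(robust$retained), nrow(robust$report), config$icc_threshold)
  manifest <- .mark_stage(manifest, "icc", t0,
                          list(n_robust = length(robust$retained),
                               threshold = config$icc_threshold))
  .write_manifest(manifest, out_dir)

  # --- stage 6: nested selection + classification -----------------------
  t0 <- as.numeric(Sys.time())
  if (length(robust$retained) == 0L)
    stop("no robust features survive the ICC gate")
  orig <- ftab[ftab$roi_variant == "original", ]
  orig <- orig[match(truth_table$lesion_id, orig$lesion_id), ]
  X <- as.matrix(orig[, robust$retained, drop = FALSE])
  labels3 <- factor(truth_table$class,
                    levels = c("adenoma", "warthin", "malignant"))
  labels2 <- factor(ifelse(truth_table$class == "malignant",
                           "malignant", "benign"),
                    levels = c("benign", "malignant"))
  plan <- make_fold_plan(labels2, k = config$cv_k,
                         repetitions = config$cv_repetitions,
                         seed = config$seed)
  cv <- run_nested_cv(X, labels3, labels2, plan,
                      selectors = config$selectors,
                      classifiers = config$classifiers,
                      relieff_permutations = config$relieff_permutations)
  utils::write.csv(cv$performance, perf_path, row.names = FALSE)
  if (!is.null(cv$selection))
    utils::write.csv(cv$selection, selfreq_path, row.names = FALSE)
  manifest <- .mark_stage(manifest, "classify", t0,
                          list(n_lesions = nrow(X),
                               n_features_in = ncol(X),
                               skipped_repetitions = length(cv$skipped)))
  manifest$counts <- list(
    lesions = nrow(truth_table),
    roi_variants = length(unique(ftab$roi_variant)),
    maps = length(map_names()),
    feature_columns = ncol(ftab) - 2L,
    robust_features = length(robust$retained))
  .write_manifest(manifest, out_dir)
  say("done: results in %s", out_dir)
  invisible(list(cohort = cohort, feature_table = ftab, robust = robust,
                 cv = cv, manifest = manifest))
}
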