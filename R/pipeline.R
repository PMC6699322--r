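# End-to-end pipeline: breast mask -> denoising -> parameter maps -> band
# expansion -> ATGP targets -> SAM training samples -> per-target KCEM
# detection -> per-target entropy thresholding -> region-level decision-tree
# voting -> tissue label map -> case summary.
#
# Classification granularity: the decision tree is evaluated per detected
# region (the mean D/PF over a detector's thresholded support), not per
# pixel, because pixelwise IVIM estimates at clinical SNR are far too noisy
# to threshold individually; pixels outside every detected region are
# normal tissue. This mirrors the histogram-analysis step of the clinical
# workflow: lesions are detected first, then characterized by the parameter
# statistics of the detected region.

#' Pipeline configuration
#'
#' Bundles and validates every stage's tuning parameters. All defaults
#' follow the package conventions documented in the individual stage
#' functions.
#'
#' @param fit_method `"full"` or `"segmented"` biexponential fit.
#' @param b_split segmented-fit high-b cutoff (s/mm^2).
#' @param presmooth masked Gaussian sd (pixels) for pre-fit/pre-detection
#'   denoising of the cube; 0 disables.
#' @param bep_order,bep_sqrt,bep_log,bep_normalize band-expansion options;
#'   the default (order 2, no stretches) expands 12 bands to 90.
#' @param n_targets ATGP target budget.
#' @param atgp_epsilon optional ATGP stopping threshold (SAM radians).
#' @param sam_threshold SAM radius for training-sample selection (radians);
#'   the default 0.05 sits between the within-tissue angular spread of a
#'   denoised expanded cube (~0.03) and the smallest between-tissue
#'   signature angle (~0.08).
#' @param kernel `"linear"` (default) or `"rbf"` KCEM kernel. The
#'   linear kernel keeps the constrained filter's unit mean response over
#'   the training set, which gives full coverage of the targeted tissue;
#'   the RBF kernel is sharper around the mean signature and typically
#'   needs a manually chosen `sigma` and a generous ridge.
#' @param sigma RBF bandwidth (`NULL` = median heuristic).
#' @param ridge detector ridge (`NULL` = scale-free default).
#' @param background_size KCEM background sample budget.
#' @param thresholder `"local_entropy"` or `"otsu"`.
#' @param quant_levels gray levels for thresholding.
#' @param manual_threshold optional manual gray-level override.
#' @param thresholds a [decision_thresholds()].
#' @param split_mode tumor zone split mode (`"threshold"` or `"median"`).
#' @param seed master seed for every stochastic stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(fit_method = "full", b_split = 250,
                            presmooth = 0.8,
                            bep_order = 2L, bep_sqrt = FALSE,
                            bep_log = FALSE, bep_normalize = FALSE,
                            n_targets = 5L, atgp_epsilon = NULL,
                            sam_threshold = 0.05,
                            kernel = c("linear", "rbf"), sigma = NULL,
                            ridge = NULL, background_size = 2000L,
                            thresholder = c("local_entropy", "otsu"),
                            quant_levels = 256L, manual_threshold = NULL,
                            thresholds = decision_thresholds(),
                            split_mode = "threshold", seed = 1L) {
  kernel <- match.arg(kernel)
  thresholder <- match.arg(thresholder)
  if (!fit_method %in% c("segmented", "full"))
    stop_ivim("Unknown fit method '", fit_method, "'.")
  if (!bep_order %in% 1:3) stop_ivim("`bep_order` must be 1, 2 or 3.")
  check_number(presmooth, "presmooth", min = 0)
  check_number(sam_threshold, "sam_threshold", min = 0, strict_min = TRUE)
  stopifnot(inherits(thresholds, "decision_thresholds"))
  structure(as.list(environment()), class = "pipeline_config")
}

#' Classify pixels from detected regions
#'
#' Region-level application of the decision tree: each detector's
#' thresholded support is summarized by the mean D and PF of its valid
#' pixels and classified once through [classify_pixel()]; every pixel
#' covered by at least one detector takes the class voted by the
#' highest-response detector covering it, pixels covered by none are normal
#' tissue, and invalid fits are `"other"`. Tumor-voted pixels are split into
#' central/peripheral zones per pixel with [split_central_peripheral()], so
#' zone labels exist only inside detected lesion support.
#'
#' @param maps a `param_maps` object.
#' @param masks list of logical arrays, one detected support per detector.
#' @param responses numeric matrix, pixels x detectors, the detector
#'   responses used to resolve overlaps.
#' @param thresholds a [decision_thresholds()].
#' @param body_mask logical array of tissue pixels.
#' @param split_mode passed to [split_central_peripheral()].
#' @return List with `labels` (a `tissue_labels` map), `votes` (tibble
#'   `detector`, `n_pixels`, `mean_d`, `mean_pf`, `class`) and
#'   `lesion_support` (logical array: union of non-normal detector masks).
#' @export
classify_detected <- function(maps, masks, responses,
                              thresholds = decision_thresholds(),
                              body_mask = NULL, split_mode = "threshold") {
  stopifnot(inherits(maps, "param_maps"))
  d3 <- dim(maps$valid)
  if (is.null(body_mask)) body_mask <- maps$valid
  n_det <- length(masks)
  if (n_det == 0L) stop_ivim("No detector masks given.")
  if (ncol(responses) != n_det)
    stop_ivim("`responses` must have one column per detector mask.")
  votes <- purrr::map_dfr(seq_len(n_det), function(j) {
    px <- which(masks[[j]] & maps$valid & body_mask)
    if (!length(px))
      return(tibble(detector = j, n_pixels = 0L, mean_d = NA_real_,
                    mean_pf = NA_real_, class = NA_character_))
    md <- mean(maps$d[px]); mp <- mean(maps$pf[px])
    tibble(detector = j, n_pixels = length(px), mean_d = md, mean_pf = mp,
           class = classify_pixel(md, mp, thresholds))
  })
  lab <- array("background", d3)
  lab[body_mask] <- "normal"
  lab[body_mask & !maps$valid] <- "other"
  covered <- Reduce(`|`, masks)
  idx <- which(covered & body_mask & maps$valid)
  if (length(idx)) {
    resp <- responses[idx, , drop = FALSE]
    in_mask <- vapply(masks, function(m) m[idx], logical(length(idx)))
    if (is.null(dim(in_mask))) in_mask <- rbind(in_mask)
    resp[!in_mask] <- -Inf
    win <- max.col(resp, ties.method = "first")
    cls <- votes$class[win]
    cls[is.na(cls)] <- "normal"
    lab[idx] <- cls
  }
  tumor <- lab == "tumor"
  if (any(tumor))
    lab[tumor] <- split_central_peripheral(maps$d[tumor], thresholds,
                                           mode = split_mode)
  lesion_votes <- votes$detector[!is.na(votes$class) &
                                   votes$class != "normal"]
  lesion_support <- if (length(lesion_votes))
    Reduce(`|`, masks[lesion_votes]) & body_mask else array(FALSE, d3)
  list(labels = new_tissue_labels(lab), votes = votes,
       lesion_support = lesion_support)
}

#' Run the full detection-and-classification pipeline on a cube
#'
#' Stages, in order: per-slice breast-region extraction on the b = 0 volume;
#' masked Gaussian denoising of the cube; per-pixel mono- and biexponential
#' parameter maps inside the body; band expansion of the denoised cube;
#' ATGP target generation (masked to the body); SAM training-sample harvest
#' and per-target desired signatures; per-target KCEM detection maps over a
#' shared background model; per-target thresholding into detected supports
#' (the merged, maximum-combined map is also thresholded and kept as the
#' lesion mask artifact); region-level decision-tree voting into the tissue
#' label map ([classify_detected()]); per-case summary table. Deterministic
#' given `(cube, config)` including the seed.
#'
#' @param cube an `ivim_cube`.
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, every artifact is written
#'   (NIfTI maps and masks, CSV tables, JSON manifest).
#' @return A list with `body_mask`, `maps`, `bands` (manifest), `targets`,
#'   `training`, `detection` (merged `detection_map`), `detector_masks`,
#'   `lesion` (merged-map thresholding result, mask restricted to the
#'   body), `votes`, `labels` (`tissue_labels`), `summary` (tibble) and
#'   `manifest`.
#' @export
run_pipeline <- function(cube, config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(cube, "ivim_cube"), inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  timings <- list()
  tick <- function(stage) {
    timings[[stage]] <<- as.numeric(Sys.time() - t0, units = "secs")
    t0 <<- Sys.time()
  }
  d3 <- cube_spatial_dim(cube)

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop_ivim("Pipeline stage '", stage, "' failed: ",
                conditionMessage(e)))
  }

  body_mask <- run_stage("breast_mask", {
    m <- array(FALSE, d3)
    for (s in seq_len(d3[3L]))
      m[, , s] <- extract_breast_region(cube$data[, , s, 1L])$mask
    m
  })
  tick("breast_mask")

  work <- run_stage("denoise",
    if (config$presmooth > 0) smooth_cube(cube, body_mask, config$presmooth)
    else cube)
  maps <- run_stage("param_maps",
    compute_param_maps(work, body_mask, method = config$fit_method,
                       b_split = config$b_split, presmooth = 0))
  tick("param_maps")

  bands <- run_stage("bep",
    expand_bands(work, order = config$bep_order,
                 include_sqrt = config$bep_sqrt,
                 include_log = config$bep_log,
                 normalize = config$bep_normalize))
  tick("bep")

  # zero out non-body spectra so targets and background live in the breast
  masked <- bands
  masked$data <- bands$data * as.vector(body_mask)
  targets <- run_stage("atgp",
    atgp(masked, n_targets = config$n_targets,
         epsilon = config$atgp_epsilon))
  training <- run_stage("sam",
    select_training_samples(masked, targets, config$sam_threshold))
  tick("targets")

  det <- run_stage("kcem", {
    X <- as_pixel_matrix(masked)
    Xb <- X[as.vector(body_mask), , drop = FALSE]
    sigma <- config$sigma
    if (config$kernel == "rbf" && is.null(sigma))
      sigma <- median_heuristic_sigma(Xb, seed = config$seed)
    ctx <- kcem_background(Xb, config$kernel, sigma, config$ridge,
                           config$background_size, config$seed)
    resp <- kcem_response(ctx, training$signatures, X)
    list(resp = resp, sigma = sigma, ridge = ctx$ridge)
  })
  detection <- new_detection_map(
    array(do.call(pmax, asplit(det$resp, 2L)), d3),
    detector = paste0("kcem-", config$kernel),
    ridge = det$ridge, sigma = det$sigma,
    n_targets = nrow(training$signatures))
  tick("kcem")

  detector_masks <- run_stage("threshold", lapply(
    seq_len(ncol(det$resp)), function(j) {
      r <- threshold_map(array(det$resp[, j], d3),
                         method = config$thresholder,
                         G = config$quant_levels,
                         manual = config$manual_threshold)
      r$mask & body_mask
    }))
  lesion <- run_stage("threshold_merged",
    threshold_map(detection, method = config$thresholder,
                  G = config$quant_levels,
                  manual = config$manual_threshold))
  lesion$mask <- lesion$mask & body_mask
  tick("threshold")

  cls <- run_stage("classify",
    classify_detected(maps, detector_masks, det$resp,
                      thresholds = config$thresholds,
                      body_mask = body_mask,
                      split_mode = config$split_mode))
  summary <- run_stage("summary", summarize_case(cls$labels, maps))
  tick("classify")

  manifest <- list(
    package_version = as.character(utils::packageVersion("ivimhsi")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    bvalues = cube$bvalues,
    config = config_to_list(config),
    n_bands = nrow(bands$manifest),
    n_targets = nrow(targets$signatures),
    rbf_sigma = det$sigma,
    lesion_threshold = lesion$threshold,
    detector_votes = as.list(stats::na.omit(cls$votes$class)),
    timings_sec = lapply(timings, function(x) round(x, 3)))

  result <- list(body_mask = body_mask, maps = maps,
                 bands = bands$manifest, targets = targets,
                 training = training, detection = detection,
                 detector_masks = detector_masks, lesion = lesion,
                 votes = cls$votes, lesion_support = cls$lesion_support,
                 labels = cls$labels, summary = summary,
                 manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_artifacts(result, cube, out_dir)
  result
}

config_to_list <- function(config) {
  x <- unclass(config)
  x$thresholds <- unclass(x$thresholds)
  lapply(x, function(v) if (is.null(v)) "auto" else v)
}

write_pipeline_artifacts <- function(result, cube, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_ivim_cube(cube, file.path(out_dir, "cube.nii.gz"))
  write_map_set(list(adc = result$maps$adc, slope = result$maps$slope,
                     d = result$maps$d, dstar = result$maps$dstar,
                     pf = result$maps$pf,
                     valid = result$maps$valid * 1L),
                out_dir, "param")
  write_map_set(list(body = result$body_mask * 1L,
                     lesion = result$lesion$mask * 1L,
                     lesion_support = result$lesion_support * 1L,
                     detection = result$detection$data,
                     labels = result$labels$data * 1L),
                out_dir, "map")
  utils::write.csv(tidy.param_maps(result$maps),
                   file.path(out_dir, "param_maps.csv"), row.names = FALSE)
  utils::write.csv(result$summary, file.path(out_dir, "case_summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(result$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
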