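# Threshold decision tree + histogram analysis for tissue classification.
# D (pure diffusion) is the primary split -- it carries the largest and most
# reliable class separation -- with PF confirming cysts; ADC, slope and D*
# are carried along as reported statistics. Tumor pixels are split into a
# central (low-D) and peripheral zone. All cuts are midpoints of adjacent
# class means and fully configurable.

#' Decision thresholds for the tissue tree
#'
#' @param d_tumor D cut separating tumor from everything else
#'   (pixels with `D < d_tumor` go to the tumor branch), 1e-3 mm^2/s.
#' @param d_cyst D cut above which (together with `pf_cyst`) a pixel is a
#'   cyst.
#' @param pf_cyst PF cut (fraction) confirming cysts.
#' @param d_central within-tumor D cut: `D <= d_central` is central tumor.
#' @return A `decision_thresholds` list.
#' @export
decision_thresholds <- function(d_tumor = 1.035, d_cyst = 1.365,
                                pf_cyst = 0.361, d_central = 0.845) {
  check_number(d_tumor, "d_tumor", min = 0, strict_min = TRUE)
  check_number(d_cyst, "d_cyst", min = 0, strict_min = TRUE)
  check_number(pf_cyst, "pf_cyst", min = 0, max = 1)
  check_number(d_central, "d_central", min = 0, strict_min = TRUE)
  if (d_tumor >= d_cyst)
    stop_ivim("`d_tumor` must be below `d_cyst` (tree ordering).")
  structure(list(d_tumor = d_tumor, d_cyst = d_cyst, pf_cyst = pf_cyst,
                 d_central = d_central),
            class = "decision_thresholds")
}

#' @export
print.decision_thresholds <- function(x, ...) {
  cat(sprintf(paste0("<decision_thresholds> D<%.3f tumor | D>=%.3f & ",
                     "PF>=%.3f cyst | else normal; central if D<=%.3f\n"),
              x$d_tumor, x$d_cyst, x$pf_cyst, x$d_central))
  invisible(x)
}

#' Derive decision thresholds from per-class parameter means
#'
#' Each cut is the midpoint of the two adjacent class means it separates:
#' tumor cut between the peripheral-tumor and normal D means, cyst cut
#' between the normal and cyst D means, PF cut between the normal and cyst
#' PF means, and the central/peripheral cut between the two tumor-zone D
#' means. Equal adjacent means are an error (no separating cut exists).
#'
#' @param class_means data frame with columns `class` (containing
#'   `tumor_central`, `tumor_peripheral`, `cyst`, `normal`), `d` and `pf`.
#'   [default_tissue_table()] (renaming `tissue` to `class`) reproduces the
#'   package defaults.
#' @return A `decision_thresholds` object.
#' @examples
#' tab <- dplyr::rename(default_tissue_table(), class = tissue)
#' derive_thresholds(tab)
#' @export
derive_thresholds <- function(class_means) {
  need <- c("tumor_central", "tumor_peripheral", "cyst", "normal")
  if (!all(c("class", "d", "pf") %in% names(class_means)))
    stop_ivim("`class_means` needs columns class, d, pf.")
  if (!all(need %in% class_means$class))
    stop_ivim("`class_means` must contain classes: ",
              paste(need, collapse = ", "), ".")
  g <- function(cls, par) class_means[[par]][match(cls, class_means$class)]
  midpoint <- function(a, b, what) {
    if (a == b) stop_ivim("Equal class means for ", what,
                          "; no separating threshold exists.")
    (a + b) / 2
  }
  decision_thresholds(
    d_tumor = midpoint(g("tumor_peripheral", "d"), g("normal", "d"),
                       "tumor-vs-normal D"),
    d_cyst = midpoint(g("normal", "d"), g("cyst", "d"), "normal-vs-cyst D"),
    pf_cyst = midpoint(g("normal", "pf"), g("cyst", "pf"),
                       "normal-vs-cyst PF"),
    d_central = midpoint(g("tumor_central", "d"), g("tumor_peripheral", "d"),
                         "central-vs-peripheral D"))
}

#' Classify pixels with the threshold decision tree
#'
#' D-first tree: `D < d_tumor` is tumor; otherwise `D >= d_cyst` and
#' `PF >= pf_cyst` is cyst; otherwise normal. Non-finite parameters give
#' `"other"`. Vectorized over pixels; tumor pixels are *not* yet split into
#' zones (see [split_central_peripheral()]).
#'
#' @param d,pf numeric vectors of fitted D (1e-3 mm^2/s) and PF (fraction).
#' @param thresholds a [decision_thresholds()].
#' @return Character vector in `{"tumor", "cyst", "normal", "other"}`.
#' @examples
#' classify_pixel(c(0.76, 1.59, 1.14), c(0.215, 0.411, 0.311),
#'                decision_thresholds())
#' @export
classify_pixel <- function(d, pf, thresholds = decision_thresholds()) {
  stopifnot(inherits(thresholds, "decision_thresholds"))
  if (length(d) != length(pf)) stop_ivim("`d` and `pf` lengths differ.")
  out <- rep("other", length(d))
  ok <- is.finite(d) & is.finite(pf)
  out[ok & d < thresholds$d_tumor] <- "tumor"
  cyst <- ok & d >= thresholds$d_cyst & pf >= thresholds$pf_cyst
  out[cyst] <- "cyst"
  out[ok & out == "other" & d >= thresholds$d_tumor & !cyst] <- "normal"
  out
}

#' Split tumor pixels into central and peripheral zones
#'
#' With `mode = "threshold"` (default), pixels with D at or below the
#' within-tumor cut are central, the rest peripheral (ties go to central;
#' the cut defaults to the midpoint of the central and peripheral reference
#' means). With `mode = "median"`, the cut is the within-tumor median and
#' pixels strictly below it are central.
#'
#' @param d fitted D of the tumor pixels (length >= 1; >= 2 for
#'   `mode = "median"`).
#' @param thresholds a [decision_thresholds()] (used in threshold mode).
#' @param mode `"threshold"` or `"median"`.
#' @return Character vector in `{"tumor_central", "tumor_peripheral"}`.
#' @export
split_central_peripheral <- function(d, thresholds = decision_thresholds(),
                                     mode = c("threshold", "median")) {
  mode <- match.arg(mode)
  if (!length(d)) stop_ivim("Empty tumor pixel set.")
  central <- if (mode == "threshold") {
    d <= thresholds$d_central
  } else {
    if (length(d) < 2L) stop_ivim("Median split needs >= 2 tumor pixels.")
    d < median(d)
  }
  ifelse(central, "tumor_central", "tumor_peripheral")
}

# ---- label maps -------------------------------------------------------------

new_tissue_labels <- function(labels) {
  lv <- tissue_levels()
  if (is.character(labels)) {
    data <- array(unname(lv[labels]), dim(labels))
  } else data <- labels
  structure(list(data = data, levels = lv), class = "tissue_labels")
}

#' @export
print.tissue_labels <- function(x, ...) {
  tb <- table(factor(names(x$levels)[match(x$data, x$levels)],
                     levels = names(x$levels)))
  cat("<tissue_labels> ", paste(dim(x$data), collapse = " x "), "\n", sep = "")
  print(tb)
  invisible(x)
}

#' Tidy a tissue label map
#' @param x a `tissue_labels` object.
#' @param ... unused.
#' @return Tibble with `row`, `col`, `slice`, `tissue`.
#' @export
tidy.tissue_labels <- function(x, ...) {
  spatial_index(dim(x$data)) |>
    dplyr::mutate(tissue = names(x$levels)[match(as.vector(x$data),
                                                 x$levels)]) |>
    dplyr::select(-"pixel")
}

#' Build a full tissue label map from parameter maps
#'
#' Applies the decision tree to every valid pixel inside `body_mask`, then
#' splits tree-tumor pixels into central/peripheral zones -- but only inside
#' `lesion_mask` (the detected-lesion support): tumor-like pixels outside
#' the detection mask are labeled `"other"`, keeping the zone labels
#' anchored to detected lesions. With `lesion_mask = NULL` all tumor pixels
#' are split.
#'
#' @param maps a `param_maps` object.
#' @param thresholds a [decision_thresholds()].
#' @param body_mask logical array of pixels to classify (default: valid
#'   pixels).
#' @param lesion_mask optional logical array gating the tumor zone split.
#' @param split_mode passed to [split_central_peripheral()].
#' @return A `tissue_labels` object.
#' @export
classify_map <- function(maps, thresholds = decision_thresholds(),
                         body_mask = NULL, lesion_mask = NULL,
                         split_mode = "threshold") {
  stopifnot(inherits(maps, "param_maps"))
  d3 <- dim(maps$valid)
  if (is.null(body_mask)) body_mask <- maps$valid
  lab <- array("background", d3)
  idx <- which(body_mask)
  if (!length(idx)) stop_ivim("Empty body mask.")
  cls <- classify_pixel(maps$d[idx], maps$pf[idx], thresholds)
  cls[!maps$valid[idx]] <- "other"
  tumor <- which(cls == "tumor")
  if (length(tumor)) {
    ti <- idx[tumor]
    in_lesion <- if (is.null(lesion_mask)) rep(TRUE, length(ti)) else
      lesion_mask[ti]
    zone <- rep("other", length(ti))
    if (any(in_lesion))
      zone[in_lesion] <- split_central_peripheral(
        maps$d[ti[in_lesion]], thresholds, mode = split_mode)
    cls[tumor] <- zone
  }
  lab[idx] <- cls
  new_tissue_labels(lab)
}

# ---- histogram statistics and case summaries --------------------------------

#' Histogram statistics of a parameter sample
#'
#' Mean, median, Fisher-Pearson sample skewness (`g1`) and excess kurtosis
#' (`g2`; a normal distribution gives 0), plus the count. Statistics whose
#' minimum sample size is not met (2 for skewness/kurtosis) are `NA` rather
#' than an error.
#'
#' @param values numeric vector (length >= 1; `NA`s dropped).
#' @return One-row tibble: `n`, `mean`, `median`, `skewness`, `kurtosis`.
#' @examples
#' histogram_stats(c(1, 2, 3))  # symmetric: skewness 0
#' @export
histogram_stats <- function(values) {
  values <- values[is.finite(values)]
  if (!length(values)) stop_ivim("No finite values to summarize.")
  n <- length(values)
  sk <- if (n >= 2L && sd(values) > 0)
    e1071::skewness(values, type = 1L) else NA_real_
  ku <- if (n >= 2L && sd(values) > 0)
    e1071::kurtosis(values, type = 1L) else NA_real_
  tibble(n = n, mean = mean(values), median = median(values),
         skewness = sk, kurtosis = ku)
}

#' Append an overall average row to a per-slice parameter table
#'
#' Given one row per slice of per-slice parameter means, appends an
#' `"average"` row holding the arithmetic mean of each parameter column --
#' the layout used for single-case summary tables.
#'
#' @param slice_table data frame with a `slice` column and numeric parameter
#'   columns.
#' @return Tibble: the input rows plus an average row (slice = `"average"`).
#' @export
case_average <- function(slice_table) {
  if (!"slice" %in% names(slice_table))
    stop_ivim("`slice_table` needs a `slice` column.")
  if (nrow(slice_table) < 1L) stop_ivim("Empty slice table.")
  num <- names(slice_table)[vapply(slice_table, is.numeric, logical(1L))]
  num <- setdiff(num, "slice")
  avg <- slice_table |>
    dplyr::summarise(dplyr::across(dplyr::all_of(num),
                                   ~ mean(.x, na.rm = TRUE)))
  dplyr::bind_rows(
    dplyr::mutate(slice_table, slice = as.character(.data$slice)),
    dplyr::mutate(avg, slice = "average")) |>
    dplyr::relocate("slice") |>
    as_tibble()
}

#' Per-slice, per-class case summary of the parameter maps
#'
#' For every slice and tissue class, the mean of each of the five
#' parameters over that class's labeled (valid) pixels; the overall rows
#' (slice `"average"`) are the arithmetic means of the per-slice means, one
#' per class.
#'
#' @param labels a `tissue_labels` map.
#' @param maps a `param_maps` object on the same grid.
#' @return Tibble with `slice`, `class`, `n_pixels`, `adc`, `slope`, `d`,
#'   `dstar`, `pf`.
#' @export
summarize_case <- function(labels, maps) {
  stopifnot(inherits(labels, "tissue_labels"), inherits(maps, "param_maps"))
  if (!identical(dim(labels$data), dim(maps$valid)))
    stop_ivim("Label map and parameter maps have different shapes.")
  df <- tidy.param_maps(maps) |>
    dplyr::mutate(class = tidy.tissue_labels(labels)$tissue) |>
    dplyr::filter(.data$valid,
                  !.data$class %in% c("background", "other"))
  if (!nrow(df)) stop_ivim("No labeled, valid pixels to summarize.")
  per_slice <- df |>
    dplyr::group_by(.data$slice, .data$class) |>
    dplyr::summarise(n_pixels = dplyr::n(),
                     dplyr::across(dplyr::all_of(c("adc", "slope", "d",
                                                   "dstar", "pf")), mean),
                     .groups = "drop")
  overall <- per_slice |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(n_pixels = sum(.data$n_pixels),
                     dplyr::across(dplyr::all_of(c("adc", "slope", "d",
                                                   "dstar", "pf")), mean),
                     .groups = "drop")
  dplyr::bind_rows(
    dplyr::mutate(per_slice, slice = as.character(.data$slice)),
    dplyr::mutate(overall, slice = "average")) |>
    dplyr::arrange(.data$class, .data$slice)
}
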