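#' Fuse band channels, vegetation indices and lodging into one feature table
#'
#' Joins the per-sample reduced band channels and vegetation indices with the
#' field map: every sample row receives its line's yield class as label and,
#' if `with_lodging`, the line's lodging index (count of lodged replicates)
#' as an extra feature column. With the default 22 channels and 41 indices
#' this yields 64 feature columns with lodging and 63 without.
#'
#' @param samples a `sample_set` (provides the per-row plot/line provenance).
#' @param fieldmap the `field_map` the samples were drawn from.
#' @param bands samples x channels matrix from [average_band_groups()] or
#'   [pca_reduce()].
#' @param indices samples x indices matrix from
#'   [compute_vegetation_indices()].
#' @param with_lodging include the lodging index column?
#' @return data frame of class `feature_table`: provenance columns
#'   (`plot_id`, `line_id`, `replicate`), feature columns, and `class`
#'   (factor A/B/C). Attribute `feature_cols` names the feature columns.
#' @export
fuse_features <- function(samples, fieldmap, bands, indices,
                          with_lodging = TRUE) {
  meta <- samples$meta
  if (nrow(bands) != nrow(meta) || nrow(indices) != nrow(meta)) {
    stop("pairing error: feature blocks and sample metadata differ in rows",
         call. = FALSE)
  }
  orphans <- setdiff(unique(meta$plot_id), fieldmap$plot_id)
  if (length(orphans) > 0L) {
    stop("join error: sample plots absent from field map: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }
  if (anyNA(bands) || anyNA(indices)) {
    stop("feature table would contain missing values; inspect the index ",
         "columns for undefined samples", call. = FALSE)
  }
  fm_row <- match(meta$plot_id, fieldmap$plot_id)
  tab <- cbind(meta[, c("plot_id", "line_id", "replicate")],
               as.data.frame(bands), as.data.frame(indices))
  feature_cols <- c(colnames(bands), colnames(indices))
  if (isTRUE(with_lodging)) {
    idx_by_line <- tapply(fieldmap$lodging, fieldmap$line_id, sum)
    tab$lodging_index <- as.integer(idx_by_line[meta$line_id])
    feature_cols <- c(feature_cols, "lodging_index")
  }
  tab$class <- factor(fieldmap$class[fm_row], levels = c("A", "B", "C"))
  rownames(tab) <- NULL
  structure(tab, feature_cols = feature_cols,
            class = c("feature_table", "data.frame"))
}

#' Run the full preprocessing + feature pipeline on a scene
#'
#' Convenience wrapper chaining the standard stages: build the SAM reference
#' library from the scene's endmember means (ground truth when available,
#' otherwise the canonical endmember curves), classify background, select
#' edge-trimmed plot ROIs, sample `n_samples` pixels per plot, aggregate
#' bands, compute vegetation indices, and fuse with the field map.
#'
#' @param sim a `field_sim` (from [simulate_field()] or [read_scene()]).
#' @param n_samples pixels sampled per plot (default 300).
#' @param margin_px ROI edge trim (default 2).
#' @param g bands per aggregation group (default 8).
#' @param registry vegetation-index registry.
#' @param with_lodging include the lodging index?
#' @param seed sampling seed.
#' @return a `feature_table`.
#' @export
extract_features <- function(sim, n_samples = 300, margin_px = 2, g = 8,
                             registry = default_vi_registry(),
                             with_lodging = TRUE, seed = 1) {
  scene <- sim$scene
  wl <- scene$wavelengths_nm
  lib <- scene_reference_library(sim)
  mask <- sam_classify(scene$cube, lib)
  rois <- select_plot_rois(mask, sim$fieldmap, margin_px = margin_px)
  cube <- scene$cube
  attr(cube, "wavelengths_nm") <- wl
  samples <- sample_pixels(cube, rois, sim$fieldmap, n = n_samples,
                           seed = seed)
  bands <- average_band_groups(samples, g = g)
  vis <- compute_vegetation_indices(samples, wl, registry = registry)
  fuse_features(samples, sim$fieldmap, bands, vis,
                with_lodging = with_lodging)
}

#' Build a SAM reference library for a scene
#'
#' Averages the spectra of ground-truth rice and soil pixels when the scene
#' carries truth labels (the synthetic case, mirroring hand-picked pure
#' ROIs); otherwise falls back to the canonical endmember curves at the
#' scene's wavelengths.
#'
#' @param sim a `field_sim`.
#' @return a [spectral_library()].
#' @export
scene_reference_library <- function(sim) {
  scene <- sim$scene
  d <- dim(scene$cube)
  if (!is.null(scene$truth_label)) {
    px <- matrix(scene$cube, d[1] * d[2], d[3])
    lab <- as.vector(scene$truth_label)
    spectral_library(colMeans(px[lab == "rice", , drop = FALSE]),
                     colMeans(px[lab == "soil", , drop = FALSE]))
  } else {
    spectral_library(rice_canopy_spectrum(scene$wavelengths_nm),
                     soil_spectrum(scene$wavelengths_nm))
  }
}

#' Write a feature table as CSV with a JSON provenance sidecar
#'
#' @param features a `feature_table`.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.meta.json`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  utils::write.csv(as.data.frame(features), path, row.names = FALSE)
  jsonlite::write_json(
    list(feature_cols = attr(features, "feature_cols"),
         provenance_cols = c("plot_id", "line_id", "replicate"),
         label_col = "class"),
    paste0(path, ".meta.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @export
print.feature_table <- function(x, ...) {
  fc <- attr(x, "feature_cols")
  cat(sprintf("Feature table: %d samples, %d feature columns (%s), classes %s\n",
              nrow(x), length(fc),
              if ("lodging_index" %in% fc) "with lodging" else "no lodging",
              paste(levels(x$class), collapse = "/")))
  NextMethod()
}
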