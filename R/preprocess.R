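#' Calibrate raw sensor counts to reflectance
#'
#' Standard white/dark frame calibration:
#' `reflectance = panel_reflectance * (raw - dark) / (white - dark)` per band,
#' where `panel_reflectance` is the known reflectance of the white reference
#' panel (default sensor preset 0.34). Values are clipped to \[0, 1\] by
#' default; counts above the white panel are treated as sensor saturation.
#'
#' @param raw raw counts: a rows x cols x bands array, or a pixels x bands
#'   matrix, or a single spectrum.
#' @param frames a `calib_frames` object (per-band `white`, `dark`,
#'   `panel_reflectance`).
#' @param clip clip the result to \[0, 1\]? Set `FALSE` to inspect the exact
#'   inverse of the affine sensor model.
#' @return reflectance with the shape of `raw`, finite everywhere.
#' @export
calibrate_reflectance <- function(raw, frames, clip = TRUE) {
  if (is.null(dim(raw))) raw <- matrix(raw, nrow = 1L)
  nb <- if (length(dim(raw)) == 3L) dim(raw)[3] else ncol(raw)
  check_frames(frames, nb)
  denom <- frames$white - frames$dark
  band_dim <- length(dim(raw))
  refl <- sweep(sweep(raw, band_dim, frames$dark, "-"), band_dim,
                frames$panel_reflectance / denom, "*")
  if (clip) refl <- pmin(pmax(refl, 0), 1)
  refl
}

#' Spectral angle between two spectra
#'
#' The angle `acos(<x, r> / (|x| |r|))` in radians, in \[0, pi\]. Invariant to
#' positive scaling of either argument, which is what makes spectral-angle
#' classification robust to illumination differences.
#'
#' @param x,r numeric spectra of equal length; neither may be the zero vector.
#' @return angle in radians.
#' @examples
#' spectral_angle(c(1, 0), c(0, 1)) # pi/2
#' spectral_angle(c(1, 0), c(1, 1)) # pi/4
#' @export
spectral_angle <- function(x, r) {
  if (length(x) != length(r)) {
    stop("spectra must have the same number of bands", call. = FALSE)
  }
  nx <- sqrt(sum(x^2)); nr <- sqrt(sum(r^2))
  if (nx == 0 || nr == 0) {
    stop("spectral angle is undefined for a zero spectrum", call. = FALSE)
  }
  acos(pmin(1, pmax(-1, sum(x * r) / (nx * nr))))
}

#' Reference spectra library for SAM classification
#'
#' Holds the mean rice and mean soil spectra (typically the averages of
#' hand-picked pure regions of interest) used as SAM references.
#'
#' @param rice_mean,soil_mean numeric spectra of equal length, both nonzero.
#' @return an object of class `spectral_library`.
#' @export
spectral_library <- function(rice_mean, soil_mean) {
  if (length(rice_mean) != length(soil_mean)) {
    stop("reference spectra must have equal band counts", call. = FALSE)
  }
  if (sum(rice_mean^2) == 0 || sum(soil_mean^2) == 0) {
    stop("reference spectra must be nonzero", call. = FALSE)
  }
  structure(list(rice_mean = as.numeric(rice_mean),
                 soil_mean = as.numeric(soil_mean)),
            class = "spectral_library")
}

#' Classify pixels as rice or background with the spectral angle mapper
#'
#' Each pixel is compared with the library's rice and soil means; it is
#' labelled `"background"` iff its spectral angle to soil is no larger than
#' its angle to rice (ties go to background, the conservative choice that
#' keeps soil out of the rice samples), otherwise `"rice"`.
#'
#' @param cube calibrated reflectance array (rows x cols x bands).
#' @param library a [spectral_library()]; band count must match the cube.
#' @return character matrix (rows x cols) with values `"rice"` /
#'   `"background"`, of class `pixel_mask`.
#' @export
sam_classify <- function(cube, library) {
  if (!inherits(library, "spectral_library")) {
    stop("`library` must be a `spectral_library`", call. = FALSE)
  }
  d <- dim(cube)
  if (length(d) != 3L) stop("`cube` must be a 3-D array", call. = FALSE)
  if (d[3] != length(library$rice_mean)) {
    stop("library band count does not match the cube", call. = FALSE)
  }
  px <- matrix(cube, nrow = d[1] * d[2], ncol = d[3])
  norms <- sqrt(rowSums(px^2))
  norms[norms == 0] <- NA_real_ # zero pixels: angle undefined -> background
  cos_rice <- (px %*% library$rice_mean) /
    (norms * sqrt(sum(library$rice_mean^2)))
  cos_soil <- (px %*% library$soil_mean) /
    (norms * sqrt(sum(library$soil_mean^2)))
  ang_rice <- acos(pmin(1, pmax(-1, cos_rice)))
  ang_soil <- acos(pmin(1, pmax(-1, cos_soil)))
  lab <- ifelse(!is.na(ang_rice) & (ang_soil > ang_rice), "rice", "background")
  structure(matrix(lab, d[1], d[2]), class = "pixel_mask")
}

#' Select edge-trimmed per-plot regions of interest
#'
#' For each plot in the field map, shrinks the plot's pixel rectangle by
#' `margin_px` on all four sides (removing edge rows/columns where adjacent
#' plots and borders mix) and intersects it with the rice-labelled pixels of
#' `mask`.
#'
#' @param mask a `pixel_mask` from [sam_classify()] (or any character matrix
#'   with values `"rice"` / `"background"`).
#' @param fieldmap a `field_map` whose `px_row0/px_row1/px_col0/px_col1`
#'   columns give each plot's 0-based, half-open pixel rectangle.
#' @param margin_px non-negative edge trim in pixels (default 2).
#' @return named list (by plot id) of two-column integer matrices of eligible
#'   0-based (row, col) pixel coordinates; class `plot_rois`.
#' @export
select_plot_rois <- function(mask, fieldmap, margin_px = 2) {
  stopifnot_scalar_number(margin_px, "margin_px", lower = 0)
  m <- as.integer(margin_px)
  need <- c("plot_id", "px_row0", "px_row1", "px_col0", "px_col1")
  if (!all(need %in% names(fieldmap))) {
    stop("`fieldmap` lacks pixel rectangle columns", call. = FALSE)
  }
  rois <- vector("list", nrow(fieldmap))
  names(rois) <- fieldmap$plot_id
  for (p in seq_len(nrow(fieldmap))) {
    r0 <- fieldmap$px_row0[p] + m; r1 <- fieldmap$px_row1[p] - m
    c0 <- fieldmap$px_col0[p] + m; c1 <- fieldmap$px_col1[p] - m
    if (r1 <= r0 || c1 <= c0) {
      stop(sprintf("empty ROI for plot %s: margin %d exhausts the plot",
                   fieldmap$plot_id[p], m), call. = FALSE)
    }
    rows <- (r0 + 1L):r1 # 1-based interior rows
    cols <- (c0 + 1L):c1
    sub <- mask[rows, cols, drop = FALSE] == "rice"
    if (!any(sub)) {
      stop(sprintf("empty ROI for plot %s: no rice pixels after masking",
                   fieldmap$plot_id[p]), call. = FALSE)
    }
    idx <- which(sub, arr.ind = TRUE)
    rois[[p]] <- cbind(row = rows[idx[, 1]] - 1L, col = cols[idx[, 2]] - 1L)
  }
  structure(rois, class = "plot_rois")
}

#' Randomly sample pixels without repetition from plot ROIs
#'
#' Draws exactly `n` distinct pixel positions per plot, uniformly without
#' replacement, from the ROI pixels whose spectra are not identically zero
#' (zero spectra mark removed background). Deterministic given `seed`.
#'
#' @param cube reflectance array the ROIs index into.
#' @param rois a `plot_rois` from [select_plot_rois()].
#' @param fieldmap the `field_map` (for line / replicate provenance).
#' @param n samples per plot (default 300).
#' @param seed integer seed.
#' @return an object of class `sample_set`: list with `meta` (data frame:
#'   plot_id, line_id, replicate, px_row, px_col), `spectra` (matrix, one row
#'   per sample) and `wavelengths_nm` (if the cube carries them via
#'   `attr(cube, "wavelengths_nm")`, else NULL).
#' @export
sample_pixels <- function(cube, rois, fieldmap, n = 300, seed = 1) {
  stopifnot_scalar_number(n, "n", lower = 1)
  n <- as.integer(n)
  d <- dim(cube)
  px_mat <- matrix(cube, d[1] * d[2], d[3])
  metas <- list(); specs <- list()
  with_seed(seed, {
    for (pid in names(rois)) {
      coords <- rois[[pid]]
      flat <- (coords[, "col"]) * d[1] + coords[, "row"] + 1L # column-major
      spec_all <- px_mat[flat, , drop = FALSE]
      eligible <- which(rowSums(spec_all != 0) > 0L)
      if (length(eligible) < n) {
        stop(sprintf(
          "sampling error for plot %s: %d eligible pixels, %d requested (deficit %d)",
          pid, length(eligible), n, n - length(eligible)), call. = FALSE)
      }
      take <- sort(sample(eligible, n))
      fm_row <- match(pid, fieldmap$plot_id)
      metas[[pid]] <- data.frame(
        plot_id = pid,
        line_id = fieldmap$line_id[fm_row],
        replicate = fieldmap$replicate[fm_row],
        px_row = coords[take, "row"], px_col = coords[take, "col"],
        stringsAsFactors = FALSE)
      specs[[pid]] <- spec_all[take, , drop = FALSE]
    }
  })
  meta <- do.call(rbind, metas)
  rownames(meta) <- NULL
  spectra <- do.call(rbind, specs)
  colnames(spectra) <- sprintf("band_%03d", seq_len(d[3]))
  structure(list(meta = meta, spectra = spectra,
                 wavelengths_nm = attr(cube, "wavelengths_nm", exact = TRUE)),
            class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("Sample set: %d pixels from %d plots, %d bands\n",
              nrow(x$meta), length(unique(x$meta$plot_id)), ncol(x$spectra)))
  invisible(x)
}
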