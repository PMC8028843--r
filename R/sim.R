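#' Simulation configuration for synthetic field scenes
#'
#' Bundles every knob of the synthetic-scene generator. Defaults mirror the
#' trial design the pipeline targets: 13 japonica lines planted in triplicate
#' on a 3-row x 13-cell grid, a 176-band sensor spanning 400--1000 nm, a 34%
#' white reference panel, Gaussian per-band pixel noise within plots, a small
#' positive spectral offset for high-yield (class A) lines, and canopy/stem
#' mixing with weight `lodging_alpha` on lodged plots.
#'
#' `class_sizes` gives the number of lines per yield class (A, B, C); the
#' default for 13 lines is 2/7/4. `lodging_profile` fixes the per-line lodging
#' index (count of lodged replicates, 0..`n_replicates`); by default class A
#' lines carry index 1 while B and C lines overlap in \{0, 2, 3\}, so the
#' lodging index alone identifies class A but cannot separate B from C.
#'
#' @param n_lines number of rice lines.
#' @param n_replicates field replicates per line (grid rows).
#' @param n_bands spectral bands.
#' @param wl_range_nm first and last band-center wavelength (nm).
#' @param plot_px side length of the square rice area of one plot, in pixels.
#' @param gap_px soil gap around each plot inside its grid cell, in pixels.
#' @param noise_sd standard deviation of independent per-band Gaussian pixel
#'   noise (reflectance units).
#' @param class_offsets named additive reflectance offsets per class (flat
#'   across bands; a weak brightness shift for high-yield canopies).
#' @param class_contrast named amplitudes of a pigment-like Gaussian bump on
#'   the visible bands (centred 620 nm); by default class A sits midway
#'   between B and C on this axis, so the contrast separates B from C while
#'   leaving A spectrally ambiguous.
#' @param lodging_alpha canopy/stem mixing weight applied to lodged plots.
#' @param line_scale_sd standard deviation of the per-line multiplicative
#'   brightness factor (biological variation between lines).
#' @param plot_scale_sd standard deviation of the per-plot multiplicative
#'   factor (replicate-to-replicate growth variation within a line).
#' @param class_sizes integer vector c(A, B, C) summing to `n_lines`, or NULL
#'   for the default split.
#' @param lodging_profile integer vector of per-line lodging indices in line
#'   order, or NULL for the default profile.
#' @param panel_reflectance reflectance of the white calibration panel.
#' @param yield_rule a [yield_class_rule()].
#' @return an object of class `sim_config`.
#' @seealso [simulate_field()]
#' @export
sim_config <- function(n_lines = 13,
                       n_replicates = 3,
                       n_bands = 176,
                       wl_range_nm = c(400, 1000),
                       plot_px = 24,
                       gap_px = 2,
                       noise_sd = 0.025,
                       class_offsets = c(A = 0.006, B = 0, C = 0),
                       class_contrast = c(A = 0, B = 0.006, C = -0.006),
                       lodging_alpha = 0.4,
                       line_scale_sd = 0.012,
                       plot_scale_sd = 0.005,
                       class_sizes = NULL,
                       lodging_profile = NULL,
                       panel_reflectance = 0.34,
                       yield_rule = yield_class_rule()) {
  stopifnot_scalar_number(n_lines, "n_lines", lower = 1)
  stopifnot_scalar_number(n_replicates, "n_replicates", lower = 1)
  stopifnot_scalar_number(n_bands, "n_bands", lower = 2)
  stopifnot_scalar_number(plot_px, "plot_px", lower = 1)
  stopifnot_scalar_number(gap_px, "gap_px", lower = 0)
  stopifnot_scalar_number(noise_sd, "noise_sd", lower = 0)
  stopifnot_scalar_number(lodging_alpha, "lodging_alpha", lower = 0, upper = 1)
  stopifnot_scalar_number(line_scale_sd, "line_scale_sd", lower = 0)
  stopifnot_scalar_number(plot_scale_sd, "plot_scale_sd", lower = 0)
  stopifnot_scalar_number(panel_reflectance, "panel_reflectance",
                          lower = 1e-6, upper = 1 - 1e-6)
  if (!all(c("A", "B", "C") %in% names(class_offsets))) {
    stop("`class_offsets` must be named with A, B, C", call. = FALSE)
  }
  if (!all(c("A", "B", "C") %in% names(class_contrast))) {
    stop("`class_contrast` must be named with A, B, C", call. = FALSE)
  }

  if (is.null(class_sizes)) {
    class_sizes <- default_class_sizes(n_lines)
  }
  class_sizes <- as.integer(class_sizes)
  if (length(class_sizes) != 3L || any(class_sizes < 1L) ||
      sum(class_sizes) != n_lines) {
    stop("`class_sizes` must be three positive counts summing to `n_lines`",
         call. = FALSE)
  }
  if (is.null(lodging_profile)) {
    lodging_profile <- default_lodging_profile(class_sizes, n_replicates)
  }
  lodging_profile <- as.integer(lodging_profile)
  if (length(lodging_profile) != n_lines ||
      any(lodging_profile < 0L | lodging_profile > n_replicates)) {
    stop("`lodging_profile` must give one index in 0..n_replicates per line",
         call. = FALSE)
  }

  structure(list(
    n_lines = as.integer(n_lines), n_replicates = as.integer(n_replicates),
    n_bands = as.integer(n_bands), wl_range_nm = wl_range_nm,
    plot_px = as.integer(plot_px), gap_px = as.integer(gap_px),
    noise_sd = noise_sd, class_offsets = class_offsets,
    class_contrast = class_contrast,
    lodging_alpha = lodging_alpha, line_scale_sd = line_scale_sd,
    plot_scale_sd = plot_scale_sd,
    class_sizes = stats::setNames(class_sizes, c("A", "B", "C")),
    lodging_profile = lodging_profile,
    panel_reflectance = panel_reflectance,
    yield_rule = yield_rule
  ), class = "sim_config")
}

# 2/7/4 for the 13-line trial; otherwise an even split with >= 1 line each.
default_class_sizes <- function(n_lines) {
  if (n_lines == 13L) return(c(2L, 7L, 4L))
  if (n_lines < 3L) {
    stop("default class sizes need `n_lines` >= 3; pass `class_sizes`",
         call. = FALSE)
  }
  base <- n_lines %/% 3L
  sizes <- c(base, base, base)
  extra <- n_lines - 3L * base
  if (extra >= 1L) sizes[2] <- sizes[2] + 1L
  if (extra == 2L) sizes[3] <- sizes[3] + 1L
  sizes
}

# Class A lines: exactly one lodged replicate each (index 1, unique to A).
# B and C lines cycle through overlapping patterns drawn from {0, 2, 3}.
default_lodging_profile <- function(class_sizes, n_replicates) {
  pat_b <- c(0L, 0L, 0L, 2L, 3L, 0L, 2L)
  pat_c <- c(0L, 2L, 3L, 0L)
  prof <- c(
    rep(1L, class_sizes[1]),
    pat_b[(seq_len(class_sizes[2]) - 1L) %% length(pat_b) + 1L],
    pat_c[(seq_len(class_sizes[3]) - 1L) %% length(pat_c) + 1L]
  )
  pmin(prof, n_replicates)
}

#' Simulate a hyperspectral field scene with ground truth
#'
#' Generates a reflectance cube, a field map and calibration frames with the
#' statistical structure the downstream analysis assumes:
#' \itemize{
#'   \item a `n_replicates`-row x `n_lines`-column plot grid, each row holding
#'     one replicate of every line with the column order permuted per row;
#'   \item within-plot rice pixel spectra equal to the line endmember (canopy
#'     curve times a per-line brightness factor) plus the class offset, mixed
#'     with the stem endmember via [apply_lodging_effect()] on lodged plots,
#'     plus independent Gaussian noise per band -- so each band within a plot
#'     is exactly normally distributed;
#'   \item soil background everywhere else;
#'   \item calibration frames from an affine sensor model
#'     `raw = gain * reflectance + dark` (band-wise gain), which
#'     [calibrate_reflectance()] inverts exactly.
#' }
#' All randomness flows from `seed`; the result is bit-reproducible.
#'
#' @param config a [sim_config()].
#' @param seed integer seed fixing all randomness.
#' @return a list of class `field_sim` with elements
#'   \describe{
#'     \item{scene}{class `hs_scene`: `cube` (rows x cols x bands reflectance
#'       array), `wavelengths_nm`, `truth_label` (character matrix,
#'       "rice"/"soil"), `truth_plot` (plot id per pixel, NA on soil).}
#'     \item{fieldmap}{class `field_map` data frame: one row per plot with
#'       grid position, line id, replicate, yield (kg per mu), class, lodging
#'       flag and the plot's pixel rectangle (0-based, half-open).}
#'     \item{frames}{class `calib_frames`: per-band `white` and `dark` raw
#'       counts and the panel reflectance.}
#'     \item{config, seed}{the inputs.}
#'   }
#' @examples
#' sim <- simulate_field(sim_config(), seed = 1)
#' dim(sim$scene$cube)    # 84 364 176
#' nrow(sim$fieldmap)     # 39 plots
#' @export
simulate_field <- function(config = sim_config(), seed = 1) {
  if (!inherits(config, "sim_config")) {
    stop("`config` must be a `sim_config`", call. = FALSE)
  }
  cfg <- config
  if (cfg$n_lines * cfg$n_replicates < 1L) {
    stop("layout error: empty grid", call. = FALSE)
  }
  wl <- default_wavelengths(cfg$n_bands, cfg$wl_range_nm)
  nb <- cfg$n_bands
  cell <- cfg$plot_px + 2L * cfg$gap_px
  nr_px <- cfg$n_replicates * cell
  nc_px <- cfg$n_lines * cell

  canopy <- rice_canopy_spectrum(wl)
  stem <- rice_stem_spectrum(wl)
  soil <- soil_spectrum(wl)

  line_ids <- sprintf("L%02d", seq_len(cfg$n_lines))
  classes <- rep(c("A", "B", "C"), times = cfg$class_sizes)

  with_seed(seed, {
    # per-line biological variation: multiplicative brightness factor
    line_scale <- pmax(0.85, 1 + rnorm(cfg$n_lines, 0, cfg$line_scale_sd))
    # row-wise reordering of the lines
    order_by_row <- lapply(seq_len(cfg$n_replicates),
                           function(r) sample.int(cfg$n_lines))
    # per-line yields drawn inside their class band
    yield <- numeric(cfg$n_lines)
    yield[classes == "A"] <- runif(sum(classes == "A"), 758, 800)
    yield[classes == "B"] <- runif(sum(classes == "B"), 705, 748)
    yield[classes == "C"] <- runif(sum(classes == "C"), 640, 695)
    # which replicates lodge, per line
    lodged_reps <- lapply(seq_len(cfg$n_lines), function(i) {
      k <- cfg$lodging_profile[i]
      if (k == 0L) integer(0) else sort(sample.int(cfg$n_replicates, k))
    })

    # field map
    plots <- do.call(rbind, lapply(seq_len(cfg$n_replicates), function(r) {
      ord <- order_by_row[[r]]
      data.frame(
        plot_id = sprintf("r%d_c%02d", r, seq_len(cfg$n_lines)),
        row = r, col = seq_len(cfg$n_lines),
        line_id = line_ids[ord], replicate = r,
        yield_kg_per_mu = yield[ord],
        class = classes[ord],
        lodging = as.integer(vapply(ord, function(i) r %in% lodged_reps[[i]],
                                    logical(1))),
        stringsAsFactors = FALSE
      )
    }))
    plots$px_row0 <- (plots$row - 1L) * cell + cfg$gap_px
    plots$px_row1 <- plots$px_row0 + cfg$plot_px
    plots$px_col0 <- (plots$col - 1L) * cell + cfg$gap_px
    plots$px_col1 <- plots$px_col0 + cfg$plot_px
    class(plots) <- c("field_map", "data.frame")

    # cube: soil background + noise everywhere, then paint the plots
    cube <- array(rep(soil, each = nr_px * nc_px), dim = c(nr_px, nc_px, nb))
    if (cfg$noise_sd > 0) {
      cube <- cube + rnorm(length(cube), 0, cfg$noise_sd)
    }
    truth_label <- matrix("soil", nr_px, nc_px)
    truth_plot <- matrix(NA_character_, nr_px, nc_px)

    offsets <- cfg$class_offsets
    contrast <- cfg$class_contrast
    # class-dependent pigment-like contrast on the visible bands, a spectral
    # direction orthogonal to overall canopy brightness
    contrast_shape <- exp(-((wl - 620) / 60)^2)
    # replicate-to-replicate growth variation within a line
    plot_scale <- pmax(0.9, 1 + rnorm(nrow(plots), 0, cfg$plot_scale_sd))
    for (p in seq_len(nrow(plots))) {
      li <- match(plots$line_id[p], line_ids)
      base <- (canopy * line_scale[li] + offsets[[plots$class[p]]] +
                 contrast[[plots$class[p]]] * contrast_shape) *
        plot_scale[p]
      if (plots$lodging[p] == 1L) {
        base <- apply_lodging_effect(base, stem, cfg$lodging_alpha)
      }
      rows <- (plots$px_row0[p] + 1L):plots$px_row1[p]
      cols <- (plots$px_col0[p] + 1L):plots$px_col1[p]
      npx <- length(rows) * length(cols)
      px <- rep(base, each = npx)
      if (cfg$noise_sd > 0) px <- px + rnorm(npx * nb, 0, cfg$noise_sd)
      cube[rows, cols, ] <- px
      truth_label[rows, cols] <- "rice"
      truth_plot[rows, cols] <- plots$plot_id[p]
    }

    # affine sensor model: band-wise gain and dark offset
    gain <- 2000 + 10 * seq_len(nb)
    dark <- 80 + 0.1 * seq_len(nb)
    frames <- structure(list(
      white = gain * cfg$panel_reflectance + dark,
      dark = dark,
      panel_reflectance = cfg$panel_reflectance
    ), class = "calib_frames")

    scene <- structure(list(
      cube = cube, wavelengths_nm = wl,
      truth_label = truth_label, truth_plot = truth_plot
    ), class = "hs_scene")

    structure(list(scene = scene, fieldmap = plots, frames = frames,
                   config = cfg, seed = seed),
              class = "field_sim")
  })
}

#' Convert a reflectance scene to raw sensor counts
#'
#' Applies the affine sensor model implied by a set of calibration frames
#' (`raw = gain * reflectance + dark`, with `gain = (white - dark) /
#' panel_reflectance` per band), producing the raw-counts cube a sensor would
#' have recorded. [calibrate_reflectance()] inverts this exactly.
#'
#' @param scene an `hs_scene`.
#' @param frames a `calib_frames` object.
#' @return raw counts array with the scene's dimensions.
#' @export
simulate_raw_counts <- function(scene, frames) {
  check_frames(frames, dim(scene$cube)[3])
  gain <- (frames$white - frames$dark) / frames$panel_reflectance
  d <- dim(scene$cube)
  sweep(sweep(scene$cube, 3, gain, "*"), 3, frames$dark, "+")
}

check_frames <- function(frames, n_bands) {
  if (!inherits(frames, "calib_frames")) {
    stop("`frames` must be a `calib_frames` object", call. = FALSE)
  }
  if (length(frames$white) != n_bands || length(frames$dark) != n_bands) {
    stop("calibration frames do not match the cube's band count", call. = FALSE)
  }
  if (any(frames$white <= frames$dark)) {
    stop("calibration error: white frame must exceed dark frame at every band",
         call. = FALSE)
  }
  invisible(frames)
}

#' @export
print.field_sim <- function(x, ...) {
  d <- dim(x$scene$cube)
  cat(sprintf(
    "Synthetic field scene: %d x %d px, %d bands (%.0f-%.0f nm), %d plots\n",
    d[1], d[2], d[3], min(x$scene$wavelengths_nm),
    max(x$scene$wavelengths_nm), nrow(x$fieldmap)))
  invisible(x)
}
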