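#' Write and read a simulated scene on disk
#'
#' Persists a scene in the exchange layout common to hyperspectral toolchains:
#' an ENVI-style text header (`scene.hdr`) plus a raw binary cube
#' (`scene.raw`, band-interleaved-by-line, 32-bit little-endian floats), the
#' field map as both JSON (`fieldmap.json`) and CSV (`fieldmap.csv`),
#' calibration frames as JSON, and the per-pixel ground-truth plot grid as an
#' ASCII matrix. `read_scene(write_scene(x))` reproduces the cube to 32-bit
#' float precision (max absolute error well below 1e-6 for reflectances).
#'
#' @param sim a `field_sim` object from [simulate_field()].
#' @param path directory to write into (created if missing).
#' @return `write_scene` returns `path` invisibly; `read_scene` returns a
#'   `field_sim`-like list with `scene`, `fieldmap` and `frames`.
#' @export
write_scene <- function(sim, path) {
  if (!inherits(sim, "field_sim")) stop("`sim` must be a `field_sim`", call. = FALSE)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  cube <- sim$scene$cube
  d <- dim(cube)

  hdr <- c(
    "ENVI",
    "description = { synthetic rice field scene }",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    "interleave = bil",
    "byte order = 0",
    "wavelength units = Nanometers",
    paste0("wavelength = { ",
           paste(format(sim$scene$wavelengths_nm, trim = TRUE, digits = 10),
                 collapse = ", "), " }")
  )
  writeLines(hdr, file.path(path, "scene.hdr"))

  # BIL: for each image line, all bands of that line (band-major within line)
  con <- file(file.path(path, "scene.raw"), "wb")
  on.exit(close(con))
  bil <- aperm(cube, c(2L, 3L, 1L)) # samples x bands x lines
  writeBin(as.numeric(bil), con, size = 4L, endian = "little")

  fm <- as.data.frame(sim$fieldmap)
  utils::write.csv(fm, file.path(path, "fieldmap.csv"), row.names = FALSE)
  jsonlite::write_json(fm, file.path(path, "fieldmap.json"),
                       dataframe = "rows", digits = NA, auto_unbox = TRUE)
  jsonlite::write_json(
    list(white = sim$frames$white, dark = sim$frames$dark,
         panel_reflectance = sim$frames$panel_reflectance),
    file.path(path, "frames.json"), digits = NA, auto_unbox = TRUE)

  truth <- sim$scene$truth_plot
  truth_idx <- matrix(match(truth, fm$plot_id, nomatch = 0L), nrow(truth))
  utils::write.table(truth_idx, file.path(path, "pixel_truth.txt"),
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  hdr_file <- file.path(path, "scene.hdr")
  raw_file <- file.path(path, "scene.raw")
  if (!file.exists(hdr_file) || !file.exists(raw_file)) {
    stop("format error: missing scene.hdr or scene.raw in ", path, call. = FALSE)
  }
  hdr <- parse_envi_header(hdr_file)
  ns <- hdr$samples; nl <- hdr$lines; nb <- hdr$bands
  expected <- as.double(ns) * nl * nb * 4
  if (file.info(raw_file)$size != expected) {
    stop(sprintf(
      "format error: scene.raw has %.0f bytes, header implies %.0f",
      file.info(raw_file)$size, expected), call. = FALSE)
  }
  if (!identical(hdr$interleave, "bil")) {
    stop("format error: only bil interleave is supported", call. = FALSE)
  }
  con <- file(raw_file, "rb")
  on.exit(close(con))
  vals <- readBin(con, "numeric", n = ns * nl * nb, size = 4L,
                  endian = "little")
  cube <- aperm(array(vals, dim = c(ns, nb, nl)), c(3L, 1L, 2L))

  fm <- utils::read.csv(file.path(path, "fieldmap.csv"),
                        stringsAsFactors = FALSE)
  class(fm) <- c("field_map", "data.frame")
  fr <- jsonlite::read_json(file.path(path, "frames.json"),
                            simplifyVector = TRUE)
  frames <- structure(list(white = fr$white, dark = fr$dark,
                           panel_reflectance = fr$panel_reflectance),
                      class = "calib_frames")

  truth_plot <- NULL
  truth_label <- NULL
  tp <- file.path(path, "pixel_truth.txt")
  if (file.exists(tp)) {
    idx <- as.matrix(utils::read.table(tp))
    dimnames(idx) <- NULL
    truth_plot <- matrix(ifelse(idx > 0L, fm$plot_id[pmax(idx, 1L)],
                                NA_character_), nrow(idx))
    truth_label <- matrix(ifelse(idx > 0L, "rice", "soil"), nrow(idx))
  }

  scene <- structure(list(cube = cube, wavelengths_nm = hdr$wavelength,
                          truth_label = truth_label, truth_plot = truth_plot),
                     class = "hs_scene")
  structure(list(scene = scene, fieldmap = fm, frames = frames),
            class = "field_sim")
}

parse_envi_header <- function(file) {
  lines <- readLines(file, warn = FALSE)
  if (length(lines) == 0L || trimws(lines[1]) != "ENVI") {
    stop("format error: header does not start with the ENVI magic", call. = FALSE)
  }
  txt <- paste(lines[-1], collapse = "\n")
  fields <- list()
  # split on newlines not inside braces
  depth <- 0L; cur <- ""; out <- character(0)
  for (ch in strsplit(txt, "")[[1]]) {
    if (ch == "{") depth <- depth + 1L
    if (ch == "}") depth <- depth - 1L
    if (ch == "\n" && depth == 0L) { out <- c(out, cur); cur <- "" }
    else cur <- paste0(cur, ch)
  }
  out <- c(out, cur)
  for (ln in out) {
    if (!grepl("=", ln, fixed = TRUE)) next
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    fields[[key]] <- val
  }
  need <- c("samples", "lines", "bands", "interleave")
  if (!all(need %in% names(fields))) {
    stop("format error: header missing ",
         paste(setdiff(need, names(fields)), collapse = ", "), call. = FALSE)
  }
  res <- list(
    samples = as.integer(fields$samples),
    lines = as.integer(fields$lines),
    bands = as.integer(fields$bands),
    interleave = tolower(fields$interleave)
  )
  if (!is.null(fields$wavelength)) {
    wl <- gsub("[{}]", "", fields$wavelength)
    res$wavelength <- as.numeric(trimws(strsplit(wl, ",")[[1]]))
  }
  res
}
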