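#' Define a vegetation index over wavelength anchors
#'
#' A vegetation index is declared as a set of named wavelength anchors (nm)
#' and an arithmetic expression over the anchor names. The expression grammar
#' is deliberately tiny -- `+ - * /`, parentheses and numeric constants --
#' so registries can round-trip through JSON and be swapped wholesale.
#'
#' @param name index name (used as the feature column name).
#' @param anchors named numeric vector of wavelengths in nm, e.g.
#'   `c(NIR = 800, RED = 670)`.
#' @param expr formula string over the anchor names, e.g.
#'   `"(NIR - RED) / (NIR + RED)"`.
#' @param citation free-text provenance tag.
#' @return an object of class `vi_def`.
#' @export
vi_def <- function(name, anchors, expr, citation = "") {
  if (is.null(names(anchors)) || any(names(anchors) == "")) {
    stop("`anchors` must be a fully named numeric vector", call. = FALSE)
  }
  parsed <- str2lang(expr)
  check_vi_expr(parsed, names(anchors), name)
  structure(list(name = name, anchors = anchors, expr = expr,
                 parsed = parsed, citation = citation),
            class = "vi_def")
}

# Allow only arithmetic over declared anchors and numeric literals.
check_vi_expr <- function(e, anchor_names, vi_name) {
  if (is.numeric(e)) return(invisible(TRUE))
  if (is.name(e)) {
    if (!(as.character(e) %in% anchor_names)) {
      stop(sprintf("index %s references undeclared anchor `%s`",
                   vi_name, as.character(e)), call. = FALSE)
    }
    return(invisible(TRUE))
  }
  if (is.call(e)) {
    op <- as.character(e[[1]])
    if (!(op %in% c("+", "-", "*", "/", "("))) {
      stop(sprintf("index %s uses disallowed operator `%s`", vi_name, op),
           call. = FALSE)
    }
    for (i in seq_along(e)[-1]) check_vi_expr(e[[i]], anchor_names, vi_name)
    return(invisible(TRUE))
  }
  stop(sprintf("index %s has an invalid expression", vi_name), call. = FALSE)
}

#' The default vegetation-index registry
#'
#' 41 literature indices over visible/NIR wavelength anchors, restricted to
#' rational formulas so the whole registry fits the package's arithmetic
#' grammar. The roster covers the standard families: normalized differences
#' (NDVI, GNDVI, NDRE, PRI, ...), simple and modified ratios (SR, ZM, GM1,
#' CIgreen, ...), soil-adjusted forms (SAVI, OSAVI, EVI, EVI2), chlorophyll /
#' carotenoid / anthocyanin indices (MCARI, TCARI, MTCI, CRI, ARI, PSRI,
#' SIPI), triangular forms (TVI, MTVI1, MCARI1) and red-edge position
#' interpolation (REIP). The registry is user-replaceable: pass any list of
#' [vi_def()]s (e.g. from [read_vi_registry()]) to
#' [compute_vegetation_indices()].
#'
#' @return list of 41 `vi_def` objects.
#' @export
default_vi_registry <- function() {
  defs <- list(
    list("NDVI",  c(NIR = 800, RED = 670), "(NIR - RED) / (NIR + RED)"),
    list("GNDVI", c(NIR = 800, GRN = 550), "(NIR - GRN) / (NIR + GRN)"),
    list("BNDVI", c(NIR = 800, BLU = 450), "(NIR - BLU) / (NIR + BLU)"),
    list("NDVI705", c(R750 = 750, R705 = 705), "(R750 - R705) / (R750 + R705)"),
    list("NDRE",  c(R790 = 790, R720 = 720), "(R790 - R720) / (R790 + R720)"),
    list("SR",    c(NIR = 800, RED = 670), "NIR / RED"),
    list("SR705", c(R750 = 750, R705 = 705), "R750 / R705"),
    list("GRVI",  c(NIR = 800, GRN = 550), "NIR / GRN"),
    list("DVI",   c(NIR = 800, RED = 670), "NIR - RED"),
    list("GDVI",  c(NIR = 800, GRN = 550), "NIR - GRN"),
    list("EVI",   c(NIR = 800, RED = 670, BLU = 450),
         "2.5 * (NIR - RED) / (NIR + 6 * RED - 7.5 * BLU + 1)"),
    list("EVI2",  c(NIR = 800, RED = 670),
         "2.5 * (NIR - RED) / (NIR + 2.4 * RED + 1)"),
    list("SAVI",  c(NIR = 800, RED = 670),
         "1.5 * (NIR - RED) / (NIR + RED + 0.5)"),
    list("OSAVI", c(NIR = 800, RED = 670),
         "1.16 * (NIR - RED) / (NIR + RED + 0.16)"),
    list("WDRVI", c(NIR = 800, RED = 670),
         "(0.2 * NIR - RED) / (0.2 * NIR + RED)"),
    list("VARI",  c(GRN = 550, RED = 670, BLU = 450),
         "(GRN - RED) / (GRN + RED - BLU)"),
    list("VIgreen", c(GRN = 550, RED = 670), "(GRN - RED) / (GRN + RED)"),
    list("PSRI",  c(R680 = 680, R500 = 500, R750 = 750),
         "(R680 - R500) / R750"),
    list("SIPI",  c(NIR = 800, R445 = 445, R680 = 680),
         "(NIR - R445) / (NIR - R680)"),
    list("NPCI",  c(R680 = 680, R430 = 430), "(R680 - R430) / (R680 + R430)"),
    list("ARI1",  c(GRN = 550, R700 = 700), "1 / GRN - 1 / R700"),
    list("ARI2",  c(NIR = 800, GRN = 550, R700 = 700),
         "NIR * (1 / GRN - 1 / R700)"),
    list("CRI550", c(R510 = 510, GRN = 550), "1 / R510 - 1 / GRN"),
    list("CRI700", c(R510 = 510, R700 = 700), "1 / R510 - 1 / R700"),
    list("CIgreen", c(NIR = 800, GRN = 550), "NIR / GRN - 1"),
    list("CIrededge", c(NIR = 800, R720 = 720), "NIR / R720 - 1"),
    list("MTCI",  c(R754 = 754, R709 = 709, R681 = 681),
         "(R754 - R709) / (R709 - R681)"),
    list("MCARI", c(R700 = 700, RED = 670, GRN = 550),
         "((R700 - RED) - 0.2 * (R700 - GRN)) * (R700 / RED)"),
    list("TCARI", c(R700 = 700, RED = 670, GRN = 550),
         "3 * ((R700 - RED) - 0.2 * (R700 - GRN) * (R700 / RED))"),
    list("TVI",   c(R750 = 750, GRN = 550, RED = 670),
         "0.5 * (120 * (R750 - GRN) - 200 * (RED - GRN))"),
    list("MTVI1", c(NIR = 800, GRN = 550, RED = 670),
         "1.2 * (1.2 * (NIR - GRN) - 2.5 * (RED - GRN))"),
    list("MCARI1", c(NIR = 800, RED = 670, GRN = 550),
         "1.2 * (2.5 * (NIR - RED) - 1.3 * (NIR - GRN))"),
    list("NLI",   c(NIR = 800, RED = 670),
         "(NIR * NIR - RED) / (NIR * NIR + RED)"),
    list("MNLI",  c(NIR = 800, RED = 670),
         "1.5 * (NIR * NIR - RED) / (NIR * NIR + RED + 0.5)"),
    list("PRI",   c(R531 = 531, R570 = 570), "(R531 - R570) / (R531 + R570)"),
    list("Datt1", c(R850 = 850, R710 = 710, R680 = 680),
         "(R850 - R710) / (R850 - R680)"),
    list("REIP",  c(RED = 670, R780 = 780, R700 = 700, R740 = 740),
         "700 + 40 * ((RED + R780) / 2 - R700) / (R740 - R700)"),
    list("ZM",    c(R750 = 750, R710 = 710), "R750 / R710"),
    list("GM1",   c(R750 = 750, GRN = 550), "R750 / GRN"),
    list("GM2",   c(R750 = 750, R700 = 700), "R750 / R700"),
    list("LCI",   c(R850 = 850, R710 = 710, R680 = 680),
         "(R850 - R710) / (R850 + R680)")
  )
  lapply(defs, function(d) vi_def(d[[1]], d[[2]], d[[3]]))
}

#' Compute vegetation indices for sampled spectra
#'
#' Resolves each index's wavelength anchors to the nearest band center and
#' evaluates its formula per sample. An anchor outside the wavelength range
#' is a coverage error; a zero denominator yields `NA` for that sample (an
#' undefined-index flag), with a warning.
#'
#' @param spectra samples x bands matrix, `sample_set`, or single spectrum.
#' @param wavelengths_nm band-center wavelengths; taken from a `sample_set`
#'   automatically.
#' @param registry list of [vi_def()]s (default [default_vi_registry()]).
#' @return samples x length(registry) numeric matrix, one column per index.
#' @examples
#' wl <- c(670, 800)
#' compute_vegetation_indices(c(0.1, 0.5), wl,
#'   registry = list(vi_def("NDVI", c(NIR = 800, RED = 670),
#'                          "(NIR - RED) / (NIR + RED)")))
#' @export
compute_vegetation_indices <- function(spectra, wavelengths_nm = NULL,
                                       registry = default_vi_registry()) {
  if (inherits(spectra, "sample_set") && is.null(wavelengths_nm)) {
    wavelengths_nm <- spectra$wavelengths_nm
  }
  X <- as_spectra_matrix(spectra)
  if (is.null(wavelengths_nm)) {
    stop("`wavelengths_nm` is required", call. = FALSE)
  }
  if (length(wavelengths_nm) != ncol(X)) {
    stop("wavelength axis does not match the band count", call. = FALSE)
  }
  out <- matrix(NA_real_, nrow(X), length(registry))
  colnames(out) <- vapply(registry, `[[`, character(1), "name")
  rng <- range(wavelengths_nm)
  for (i in seq_along(registry)) {
    def <- registry[[i]]
    env <- new.env(parent = baseenv())
    for (a in names(def$anchors)) {
      target <- def$anchors[[a]]
      if (target < rng[1] || target > rng[2]) {
        stop(sprintf(
          "coverage error: anchor %s = %g nm of index %s outside %g-%g nm",
          a, target, def$name, rng[1], rng[2]), call. = FALSE)
      }
      band <- which.min(abs(wavelengths_nm - target))
      assign(a, X[, band], envir = env)
    }
    val <- eval(def$parsed, envir = env)
    bad <- !is.finite(val)
    if (any(bad)) {
      warning(sprintf("index %s undefined (zero denominator) for %d sample(s)",
                      def$name, sum(bad)), call. = FALSE)
      val[bad] <- NA_real_
    }
    out[, i] <- val
  }
  out
}

#' Read / write a vegetation-index registry as JSON
#'
#' @param path JSON file path.
#' @param registry list of [vi_def()]s.
#' @return `read_vi_registry` returns a list of `vi_def`s.
#' @export
write_vi_registry <- function(registry, path) {
  jsonlite::write_json(
    lapply(registry, function(d) {
      list(name = d$name, anchors_nm = as.list(d$anchors), expression = d$expr,
           citation = d$citation)
    }), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_vi_registry
#' @export
read_vi_registry <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(d) {
    vi_def(d$name, unlist(d$anchors_nm), d$expression,
           citation = if (is.null(d$citation)) "" else d$citation)
  })
}
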