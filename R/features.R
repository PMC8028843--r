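#' Band-to-band correlation and contiguous redundancy runs
#'
#' Computes the Pearson correlation between every pair of bands over the
#' sampled pixels, and for each band the length of the maximal contiguous
#' band interval containing it whose members all correlate with it above
#' `r_min`. Adjacent narrow bands are highly redundant; the run lengths are
#' the diagnostic used to justify how many consecutive bands can be averaged
#' into one channel.
#'
#' @param spectra samples x bands numeric matrix, or a `sample_set`.
#' @param r_min correlation threshold (default 0.9).
#' @return list with `correlation` (bands x bands matrix), `run_length`
#'   (integer per band; NA for zero-variance bands) and `constant_bands`
#'   (indices of zero-variance bands, excluded from runs).
#' @export
band_correlation_matrix <- function(spectra, r_min = 0.9) {
  X <- as_spectra_matrix(spectra)
  if (nrow(X) < 3L) stop("need at least 3 samples", call. = FALSE)
  nb <- ncol(X)
  sds <- apply(X, 2, stats::sd)
  constant <- which(sds == 0)
  cm <- suppressWarnings(stats::cor(X))
  run <- rep(NA_integer_, nb)
  for (b in setdiff(seq_len(nb), constant)) {
    ok <- !is.na(cm[, b]) & cm[, b] > r_min
    lo <- b
    while (lo > 1L && ok[lo - 1L]) lo <- lo - 1L
    hi <- b
    while (hi < nb && ok[hi + 1L]) hi <- hi + 1L
    run[b] <- hi - lo + 1L
  }
  list(correlation = cm, run_length = run, constant_bands = constant)
}

#' Average consecutive band groups into broad channels
#'
#' Reduces spectral dimensionality by averaging non-overlapping consecutive
#' groups of `g` bands (default 8, turning 176 bands into 22 channels). If the
#' band count is not divisible by `g`, the trailing remainder forms a final
#' short group.
#'
#' @param spectra samples x bands matrix, `sample_set`, or a single spectrum.
#' @param g bands per group (positive integer, default 8).
#' @return samples x n_groups matrix with columns `bg01`, `bg02`, ...;
#'   attribute `groups` lists each group's band indices.
#' @examples
#' average_band_groups(matrix(1:8, nrow = 1), g = 8) # 4.5
#' @export
average_band_groups <- function(spectra, g = 8) {
  stopifnot_scalar_number(g, "g", lower = 1)
  g <- as.integer(g)
  X <- as_spectra_matrix(spectra)
  nb <- ncol(X)
  if (nb < g) stop("band count is smaller than the group size", call. = FALSE)
  grp <- (seq_len(nb) - 1L) %/% g + 1L
  ng <- max(grp)
  out <- matrix(0, nrow(X), ng)
  for (k in seq_len(ng)) {
    out[, k] <- rowMeans(X[, grp == k, drop = FALSE])
  }
  colnames(out) <- sprintf("bg%02d", seq_len(ng))
  attr(out, "groups") <- split(seq_len(nb), grp)
  out
}

#' Principal-component scores of pooled spectra
#'
#' The alternative dimension-reduction route: scores of the pooled,
#' mean-centred pixel spectra on the first `k` principal components (default
#' 22, matching the band-averaging channel count).
#'
#' @param spectra samples x bands matrix or `sample_set`.
#' @param k number of components; must not exceed min(n_samples, n_bands).
#' @return samples x k score matrix with attribute `explained_variance`
#'   (non-increasing proportion per component).
#' @export
pca_reduce <- function(spectra, k = 22) {
  X <- as_spectra_matrix(spectra)
  stopifnot_scalar_number(k, "k", lower = 1)
  k <- as.integer(k)
  if (k > min(dim(X))) {
    stop("`k` exceeds min(n_samples, n_bands)", call. = FALSE)
  }
  fit <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  scores <- fit$x[, seq_len(k), drop = FALSE]
  colnames(scores) <- sprintf("pc%02d", seq_len(k))
  attr(scores, "explained_variance") <-
    (fit$sdev^2 / sum(fit$sdev^2))[seq_len(k)]
  scores
}

as_spectra_matrix <- function(spectra) {
  if (inherits(spectra, "sample_set")) return(spectra$spectra)
  if (is.null(dim(spectra))) return(matrix(as.numeric(spectra), nrow = 1L))
  as.matrix(spectra)
}
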