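#' Local texture maps: range, standard deviation, entropy
#'
#' Per-pixel neighborhood statistics of a grayscale image: local range
#' (max - min) and local standard deviation over a `range_window` /
#' `std_window` square (default 3 x 3), and local Shannon entropy of the
#' gray-level histogram over an `entropy_window` square (default 9 x 9,
#' `n_gray` levels spanning the image's global range). Edges are handled by
#' reflective (symmetric) padding. Texture maps are diagnostic extras; they
#' are not part of the default fused feature table.
#'
#' @param img 2-D numeric matrix (grayscale image).
#' @param range_window,std_window,entropy_window odd window sides in pixels.
#' @param n_gray number of gray levels for the entropy histogram.
#' @return list of matrices `range`, `std`, `entropy`, each the size of `img`.
#' @examples
#' texture_features(matrix(1:9, 3, 3))$range[2, 2] # 8
#' @export
texture_features <- function(img, range_window = 3, std_window = 3,
                             entropy_window = 9, n_gray = 32) {
  if (length(dim(img)) != 2L) stop("`img` must be a 2-D matrix", call. = FALSE)
  for (w in c(range_window, std_window, entropy_window)) {
    if (w %% 2 != 1 || w < 1) {
      stop("window sizes must be odd positive integers", call. = FALSE)
    }
  }
  rng <- window_reduce(img, range_window, c("min", "max"))
  std <- window_reduce(img, std_window, "sd")
  ent <- window_entropy(img, entropy_window, n_gray)
  list(range = rng$max - rng$min, std = std$sd, entropy = ent)
}

# symmetric padding indices (period-2n mirror; valid for pad larger than n)
reflect_idx <- function(n, pad) {
  i <- (1L - pad):(n + pad)
  j <- ((i - 1L) %% (2L * n) + 2L * n) %% (2L * n) # fold into 0..2n-1
  ifelse(j < n, j + 1L, 2L * n - j)
}

pad_reflect <- function(img, pad) {
  img[reflect_idx(nrow(img), pad), reflect_idx(ncol(img), pad), drop = FALSE]
}

window_reduce <- function(img, w, stats) {
  pad <- (w - 1L) %/% 2L
  P <- pad_reflect(img, pad)
  nr <- nrow(img); nc <- ncol(img)
  acc_min <- NULL; acc_max <- NULL; acc_sum <- NULL; acc_sq <- NULL
  for (di in seq_len(w)) {
    for (dj in seq_len(w)) {
      S <- P[di:(di + nr - 1L), dj:(dj + nc - 1L), drop = FALSE]
      if ("min" %in% stats) acc_min <- if (is.null(acc_min)) S else pmin(acc_min, S)
      if ("max" %in% stats) acc_max <- if (is.null(acc_max)) S else pmax(acc_max, S)
      if ("sd" %in% stats) {
        acc_sum <- if (is.null(acc_sum)) S else acc_sum + S
        acc_sq <- if (is.null(acc_sq)) S^2 else acc_sq + S^2
      }
    }
  }
  out <- list()
  if ("min" %in% stats) out$min <- acc_min
  if ("max" %in% stats) out$max <- acc_max
  if ("sd" %in% stats) {
    n <- w * w
    v <- (acc_sq - acc_sum^2 / n) / (n - 1)
    v[v < 0] <- 0 # numeric guard for constant windows
    out$sd <- sqrt(v)
  }
  out
}

window_entropy <- function(img, w, n_gray) {
  pad <- (w - 1L) %/% 2L
  rg <- range(img)
  if (rg[2] == rg[1]) return(matrix(0, nrow(img), ncol(img)))
  lev <- matrix(pmin(n_gray, 1L + floor((img - rg[1]) / (rg[2] - rg[1]) * n_gray)),
                nrow(img))
  P <- pad_reflect(lev, pad)
  nr <- nrow(img); nc <- ncol(img)
  n <- w * w
  ent <- matrix(0, nr, nc)
  for (l in sort(unique(as.vector(lev)))) {
    cnt <- matrix(0, nr, nc)
    B <- P == l
    for (di in seq_len(w)) {
      for (dj in seq_len(w)) {
        cnt <- cnt + B[di:(di + nr - 1L), dj:(dj + nc - 1L), drop = FALSE]
      }
    }
    p <- cnt / n
    ent <- ent - ifelse(p > 0, p * log2(p), 0)
  }
  ent
}
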