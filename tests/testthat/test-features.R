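test_that("band correlation matrix has unit diagonal and duplicate detection", {
  set.seed(41)
  X <- matrix(rnorm(200), 20, 10)
  X[, 4] <- X[, 3] # duplicated band
  res <- band_correlation_matrix(X)
  expect_equal(unname(diag(res$correlation)), rep(1, 10))
  expect_equal(unname(res$correlation[3, 4]), 1)
  expect_error(band_correlation_matrix(X[1:2, ]), "3 samples")
})

test_that("constant bands are reported and excluded from runs", {
  set.seed(42)
  X <- matrix(rnorm(150), 15, 10)
  X[, 5] <- 2.5
  res <- band_correlation_matrix(X)
  expect_equal(res$constant_bands, 5L)
  expect_true(is.na(res$run_length[5]))
  expect_true(all(!is.na(res$run_length[-5])))
})

test_that("run lengths equal the exhaustive over-all-intervals oracle", {
  brute_run <- function(cm, b, r_min) {
    nb <- ncol(cm)
    best <- 0L
    for (lo in 1:b) for (hi in b:nb) {
      if (all(cm[lo:hi, b] > r_min)) best <- max(best, hi - lo + 1L)
    }
    best
  }
  for (s in 1:5) {
    set.seed(500 + s)
    nb <- sample(5:20, 1)
    # first-order autocorrelation across the band axis gives contiguous
    # correlation blocks with decaying off-diagonal structure
    n <- 60; rho <- 0.9
    X <- matrix(0, n, nb)
    X[, 1] <- rnorm(n)
    for (b in 2:nb) X[, b] <- rho * X[, b - 1] + sqrt(1 - rho^2) * rnorm(n)
    for (r_min in c(0.3, 0.6, 0.9)) {
      res <- band_correlation_matrix(X, r_min = r_min)
      oracle <- vapply(seq_len(nb), function(b) brute_run(res$correlation, b, r_min),
                       integer(1))
      expect_equal(res$run_length, oracle)
    }
  }
})

test_that("band-group averaging reduces 176 bands to 22 channels", {
  X <- matrix(runif(176 * 5), 5, 176)
  out <- average_band_groups(X, g = 8)
  expect_equal(ncol(out), 22L)
  expect_equal(out[, 1], rowMeans(X[, 1:8]))
})

test_that("band-group means match hand arithmetic and handle remainders", {
  expect_equal(as.numeric(average_band_groups(matrix(1:8, 1), g = 8)), 4.5)
  const <- average_band_groups(matrix(0.7, 3, 176), g = 8)
  expect_equal(unname(as.vector(const)), rep(0.7, 3 * 22))
  # 10 bands, g = 4 -> groups of 4, 4, 2
  out <- average_band_groups(matrix(1:10, 1), g = 4)
  expect_equal(as.numeric(out), c(2.5, 6.5, 9.5))
  expect_error(average_band_groups(matrix(1:10, 1), g = 0), "g")
})

test_that("band-group averaging commutes with affine changes of the spectra", {
  set.seed(43)
  X <- matrix(runif(32 * 4), 4, 32)
  base <- average_band_groups(X, g = 8)
  expect_equal(average_band_groups(3 * X + 2, g = 8), 3 * base + 2,
               ignore_attr = TRUE)
})

test_that("PCA reduction returns ordered components with sane variance", {
  set.seed(44)
  X <- matrix(rnorm(50 * 30), 50, 30)
  sc <- pca_reduce(X, k = 22)
  expect_equal(ncol(sc), 22L)
  ev <- attr(sc, "explained_variance")
  expect_true(all(diff(ev) <= 1e-12))
  # rank-1 data: first component carries essentially all variance
  r1 <- outer(rnorm(40), runif(10)) + matrix(rnorm(400, sd = 1e-4), 40)
  ev1 <- attr(pca_reduce(r1, k = 3), "explained_variance")
  expect_gte(ev1[1], 0.999)
  expect_error(pca_reduce(X, k = 60), "exceeds")
})

test_that("NDVI evaluates its closed form and the registry has 41 entries", {
  reg <- default_vi_registry()
  expect_length(reg, 41L)
  expect_length(unique(vapply(reg, `[[`, character(1), "name")), 41L)
  wl <- c(670, 800)
  ndvi_def <- reg[vapply(reg, `[[`, character(1), "name") == "NDVI"]
  v <- compute_vegetation_indices(c(0.1, 0.5), wl, registry = ndvi_def)
  expect_equal(as.numeric(v), (0.5 - 0.1) / (0.5 + 0.1), tolerance = 1e-12)
  v0 <- compute_vegetation_indices(c(0.4, 0.4), wl, registry = ndvi_def)
  expect_equal(as.numeric(v0), 0)
})

test_that("default indices are finite on positive spectra; NDVI bounded", {
  wl <- default_wavelengths(176)
  set.seed(45)
  for (i in 1:20) {
    spec <- runif(176, 0.02, 0.9)
    v <- compute_vegetation_indices(spec, wl)
    expect_true(all(is.finite(v)))
    expect_true(abs(v[, "NDVI"]) <= 1)
  }
})

test_that("anchor coverage and zero denominators are flagged", {
  wl <- seq(500, 900, length.out = 40)
  bad <- list(vi_def("X", c(SWIR = 1600, NIR = 800), "SWIR / NIR"))
  expect_error(compute_vegetation_indices(runif(40), wl, registry = bad),
               "coverage error")
  zdef <- list(vi_def("Z", c(A = 600, B = 700), "A / (A - B)"))
  spec <- rep(0.5, 40)
  expect_warning(v <- compute_vegetation_indices(spec, wl, registry = zdef),
                 "undefined")
  expect_true(is.na(v[1, 1]))
})

test_that("index registry validates its grammar and round-trips JSON", {
  expect_error(vi_def("bad", c(NIR = 800), "sqrt(NIR)"), "disallowed operator")
  expect_error(vi_def("bad", c(NIR = 800), "NIR + RED"), "undeclared anchor")
  dir <- withr::local_tempdir()
  path <- file.path(dir, "registry.json")
  write_vi_registry(default_vi_registry(), path)
  back <- read_vi_registry(path)
  expect_length(back, 41L)
  wl <- default_wavelengths(176)
  spec <- runif(176, 0.1, 0.8)
  expect_equal(compute_vegetation_indices(spec, wl, registry = back),
               compute_vegetation_indices(spec, wl))
})

test_that("texture maps match hand-computed neighborhood statistics", {
  img <- matrix(1:9, 3, 3, byrow = TRUE)
  tx <- texture_features(img)
  expect_equal(tx$range[2, 2], 8)
  expect_equal(tx$std[2, 2], sd(1:9))
  const <- texture_features(matrix(4, 5, 5))
  expect_true(all(const$range == 0))
  expect_true(all(const$std == 0))
  expect_true(all(const$entropy == 0))
  expect_error(texture_features(img, range_window = 4), "odd")
})

test_that("lodging index counts lodged replicates and validates flags", {
  expect_identical(lodging_index(c(0, 0, 0)), 0L)
  expect_identical(lodging_index(c(1, 1, 1)), 3L)
  expect_identical(lodging_index(c(1, 0, 0)), 1L)
  expect_error(lodging_index(c(1, 2, 0)), "0 or 1")
  expect_error(lodging_index(c(1, 0)), "replicate flags")
})

test_that("yield classes follow the threshold rule and partition yields", {
  expect_identical(as.character(assign_yield_class(c(760, 725, 690))),
                   c("A", "B", "C"))
  expect_identical(as.character(assign_yield_class(c(750, 700))), c("B", "B"))
  expect_identical(as.character(assign_yield_class(750.0001)), "A")
  ys <- c(0, runif(200, 0, 1500))
  cls <- assign_yield_class(ys)
  expect_false(anyNA(cls))
  expect_error(assign_yield_class(-5), "non-negative")
})

test_that("fusion produces the expected column layout and labels", {
  sim <- small_sim(seed = 46)
  ft_with <- extract_features(sim, n_samples = 15, margin_px = 1, seed = 2,
                              with_lodging = TRUE)
  ft_wo <- extract_features(sim, n_samples = 15, margin_px = 1, seed = 2,
                            with_lodging = FALSE)
  # 40 bands at g = 8 -> 5 channels, +41 indices
  expect_length(attr(ft_with, "feature_cols"), 5 + 41 + 1)
  expect_length(attr(ft_wo, "feature_cols"), 5 + 41)
  expect_equal(nrow(ft_with), 15 * 9)
  fm <- sim$fieldmap
  expect_identical(as.character(ft_with$class),
                   fm$class[match(ft_with$plot_id, fm$plot_id)])
  # lodging index equals the per-line flag sum
  idx <- tapply(fm$lodging, fm$line_id, sum)
  expect_equal(unname(ft_with$lodging_index), unname(as.integer(idx[ft_with$line_id])))
})

test_that("fusion rejects mismatched inputs", {
  sim <- small_sim(seed = 47)
  ft <- extract_features(sim, n_samples = 10, margin_px = 1, seed = 1)
  samples <- list(meta = data.frame(plot_id = "nope", line_id = "L99",
                                    replicate = 1, px_row = 0, px_col = 0))
  expect_error(
    fuse_features(samples, sim$fieldmap, matrix(0, 1, 2), matrix(0, 1, 2)),
    "join error")
  expect_error(
    fuse_features(list(meta = sim$fieldmap[1:2, ]), sim$fieldmap,
                  matrix(0, 3, 2), matrix(0, 3, 2)),
    "pairing error")
})

test_that("default trial-scale fusion yields 64 and 63 feature columns", {
  sim <- simulate_field(sim_config(), seed = 48)
  ft_with <- extract_features(sim, n_samples = 10, seed = 3)
  ft_wo <- extract_features(sim, n_samples = 10, seed = 3,
                            with_lodging = FALSE)
  expect_length(attr(ft_with, "feature_cols"), 64L)
  expect_length(attr(ft_wo, "feature_cols"), 63L)
})
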