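test_that("S/N and mass-range filtering", {
  p <- peak_list(c(150, 200, 300), c(10, 20, 30), sn = c(3.9, 4.0, 10))
  expect_equal(nrow(sn_filter(p, 4)), 2)       # boundary inclusive
  p2 <- peak_list(c(128.9, 150), c(1, 1), sn = c(10, 10))
  expect_equal(sn_filter(p2, 4)$mz, 150)       # default range drops 128.9
  p3 <- peak_list(c(130, 900), c(1, 2))        # no S/N column: passes
  expect_equal(nrow(sn_filter(p3, 0, c(129, 1000))), 2)
  expect_identical(sn_filter(p, 0, c(1, 1e4))$mz, p$mz)  # no-op case
  expect_warning(sn_filter(p, 1e9), "removed every peak")
})

test_that("peak lists are sorted and near-duplicates collapsed to max", {
  p <- peak_list(c(200, 150, 150 + 1e-8), c(5, 1, 7))
  expect_equal(p$mz, c(150 + 1e-8, 200))
  expect_equal(p$intensity, c(7, 5))
})

test_that("linear calibration recovers a known drift", {
  ref <- sort(mz_of_ion(seed_formula_table()$mass[seq(1, 280, by = 14)]))
  slope <- 1 + 2e-7
  p <- peak_list(slope * ref, rep(1, length(ref)), sample = "s")
  res <- calibrate(p, ref)
  expect_equal(res$calibration$slope, 1 / slope, tolerance = 1e-8)
  expect_lt(res$calibration$residual_ppb, 10)
  expect_equal(res$peaks$mz, ref, tolerance = 1e-10)
  expect_true(res$calibration$accepted)
})

test_that("calibration of already-calibrated data is the identity", {
  ref <- sort(mz_of_ion(seed_formula_table()$mass[seq(1, 280, by = 10)]))
  p <- peak_list(ref, rep(1, length(ref)))
  res <- calibrate(p, ref)
  expect_equal(res$calibration$slope, 1, tolerance = 1e-9)
  expect_equal(res$calibration$offset, 0, tolerance = 1e-7)
  expect_equal(res$peaks$mz / ref, rep(1, length(ref)), tolerance = 1e-9)
  # idempotence: a second fit is within numerical noise of the identity
  res2 <- calibrate(res$peaks, ref)
  expect_equal(res2$calibration$slope, 1, tolerance = 1e-9)
  expect_equal(res2$calibration$offset, 0, tolerance = 1e-7)
})

test_that("calibration needs a minimum number of matched references", {
  p <- peak_list(c(200, 300, 400), c(1, 1, 1))
  expect_error(calibrate(p, c(200, 300, 400)), "calibration failed")
  expect_error(calibrate(p, c(200, 300, 400), min_matches = 3), NA)
})

test_that("ppm-window alignment merges and splits correctly", {
  a <- peak_list(400.00000, 10, sample = "a")
  b <- peak_list(400.00030, 12, sample = "b")   # 0.75 ppm apart
  fm <- align(list(a, b), window = 1)
  expect_equal(length(fm$mz), 1)
  expect_equal(fm$mz, (400 * 10 + 400.0003 * 12) / 22, tolerance = 1e-9)

  b2 <- peak_list(400.0008, 12, sample = "b")   # 2 ppm apart
  fm2 <- align(list(a, b2), window = 1)
  expect_equal(length(fm2$mz), 2)

  # single sample: features are its peaks
  s <- peak_list(c(150, 151, 800), c(1, 2, 3), sample = "s")
  fm3 <- align(list(s))
  expect_equal(fm3$mz, s$mz)
  expect_equal(ncol(fm3$intensity), 1)
})

test_that("alignment is invariant to sample order", {
  set.seed(7)
  pls <- lapply(1:4, function(i) {
    mz <- sort(runif(60, 130, 1000))
    mz <- mz * (1 + rnorm(60, 0, 1e-7))
    peak_list(mz, runif(60, 1, 100), sample = paste0("s", i))
  })
  f1 <- align(pls)
  f2 <- align(rev(pls))
  expect_equal(f1$mz, f2$mz, tolerance = 1e-12)
  expect_equal(f1$intensity[, f1$samples$sample],
               f2$intensity[, f1$samples$sample])
})

test_that("same-sample collisions keep the nearer peak", {
  a <- peak_list(c(400.00000, 400.00030), c(10, 5), sample = "a")  # 0.75 ppm apart
  b <- peak_list(400.00002, 8, sample = "b")
  fm <- align(list(a, b), window = 1)
  # sample a contributes at most one peak per feature
  expect_true(all(colSums(fm$intensity > 0) <= length(fm$mz)))
  expect_equal(length(fm$mz), 2)
  expect_true(all(rowSums(fm$intensity > 0) >= 1))
})

test_that("triplicate filter keeps features complete in some replicate group", {
  groups <- c(A = 3, B = 3)
  mat <- rbind(c(1, 1, 1, 0, 0, 0),   # full in A -> kept
               c(1, 1, 0, 1, 1, 0),   # 2/3 everywhere -> dropped
               c(0, 0, 0, 5, 4, 3))   # full in B -> kept
  fm <- fm_of(c(150, 300, 500), mat, groups)
  out <- triplicate_filter(fm)
  expect_equal(out$mz, c(150, 500))
  bad <- feature_matrix(c(150), matrix(1, 1, 5), paste0("s", 1:5),
                        c("A", "A", "A", "B", "B"))
  expect_error(triplicate_filter(bad), "replicate count")
})

test_that("IQR-Euclidean normalization matches the hand-worked example", {
  # column (3,4,5,100,0): non-zero {3,4,5,100}, Q1 = 3.75, Q3 = 28.75,
  # inside IQR {4,5}, norm = sqrt(41)
  mat <- cbind(c(3, 4, 5, 100, 0), c(1, 2, 3, 4, 5))
  fm <- feature_matrix(1:5, mat, c("s1", "s2"), c("g", "g"))
  out <- iqr_euclidean_normalize(fm)
  expect_equal(out$intensity[, 1], c(3, 4, 5, 100, 0) / sqrt(41),
               tolerance = 1e-12)
})

test_that("normalization is exactly scale invariant and symmetric", {
  set.seed(11)
  mat <- matrix(rlnorm(40, 10, 1), 10, 4)
  mat[sample(40, 5)] <- 0
  fm <- feature_matrix(sort(runif(10, 130, 900)), mat,
                       paste0("s", 1:4), rep("g", 4))
  n1 <- iqr_euclidean_normalize(fm)
  fm2 <- fm
  fm2$intensity[, 2] <- fm$intensity[, 2] * 2^13   # exact binary scaling
  n2 <- iqr_euclidean_normalize(fm2)
  expect_identical(n1$intensity[, 2], n2$intensity[, 2])  # bit-exact
  fm3 <- fm
  fm3$intensity[, 2] <- fm$intensity[, 2] * 17.3   # arbitrary scaling
  n3 <- iqr_euclidean_normalize(fm3)
  expect_equal(n1$intensity[, 2], n3$intensity[, 2], tolerance = 1e-14)
  # all-identical samples normalize identically
  same <- feature_matrix(1:6, matrix(rep(c(1, 2, 3, 4, 5, 0), 3), ncol = 3),
                         paste0("s", 1:3), rep("g", 3))
  ns <- iqr_euclidean_normalize(same)
  expect_identical(ns$intensity[, 1], ns$intensity[, 3])
  few <- feature_matrix(1:4, cbind(c(1, 2, 3, 0)), "s1", "g")
  expect_error(iqr_euclidean_normalize(few), "fewer than 4")
})

test_that("peak list and feature matrix files round-trip", {
  p <- peak_list(c(150.123456789, 800.987654321), c(1e5, 2e6),
                 sn = c(5, 50), sample = "s1")
  f <- tempfile(fileext = ".txt")
  write_peak_list(p, f)
  p2 <- read_peak_list(f, sample = "s1")
  expect_equal(p2$mz, p$mz, tolerance = 1e-9 / 150)
  expect_equal(p2$intensity, p$intensity, tolerance = 1e-6)

  fm <- fm_of(c(150.123456789, 500.1), matrix(c(1, 2, 0, 4), 2, 2),
              c(A = 1, B = 1))
  f2 <- tempfile(fileext = ".tsv")
  write_feature_matrix(fm, f2)
  fm2 <- read_feature_matrix(f2)
  expect_equal(fm2$mz, fm$mz, tolerance = 1e-9 / 150)
  expect_equal(unname(fm2$intensity), unname(fm$intensity))
  expect_equal(fm2$samples$group, fm$samples$group)
})
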