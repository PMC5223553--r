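test_that("combinatorial enumeration finds the expected formulas", {
  # palmitic acid: unique candidate at 0.5 ppm
  cand <- enumerate_candidates(256.240230)
  expect_equal(cand$formula, "C16H32O2")
  # glucose: present and ranked first by |ppm|
  cand2 <- enumerate_candidates(monoisotopic_mass("C6H12O6"))
  expect_equal(cand2$formula[1], "C6H12O6")
  expect_lt(abs(cand2$ppm[1]), 1e-6)
  # degenerate small mass: nothing on the grid
  expect_equal(nrow(enumerate_candidates(12.000000)), 0)
  # every candidate within tolerance, sorted by |ppm|
  cand3 <- enumerate_candidates(522.3, tol = 0.5)
  expect_true(all(abs(cand3$ppm) <= 0.5))
  expect_false(is.unsorted(abs(cand3$ppm)))
})

test_that("pruned enumeration equals the naive full-grid oracle", {
  set.seed(31)
  masses <- runif(8, 130, 1000)
  for (m in masses) {
    expect_identical(sort(enumerate_candidates(m)$formula),
                     naive_enumerate(m))
  }
})

test_that("vectorized validity checks agree with the scalar predicates", {
  set.seed(5)
  counts <- cbind(C = sample(1:60, 40, TRUE), H = sample(0:120, 40, TRUE),
                  O = sample(0:30, 40, TRUE), N = sample(0:15, 40, TRUE),
                  S = sample(0:3, 40, TRUE), P = sample(0:3, 40, TRUE))
  sv <- mdinet:::senior_valid_matrix(counts)
  rv <- mdinet:::ratio_valid_matrix(counts)
  for (i in seq_len(nrow(counts))) {
    f <- elemental_formula(counts = counts[i, ])
    expect_identical(sv[i], senior_check(f)$valid)
    expect_identical(rv[i], unname(ratio_check(f)))
  }
})

test_that("noise level is the minimum of the per-sample maxima", {
  fm <- fm_of(c(150, 300), rbind(c(100, 40), c(60, 10)), c(A = 1, B = 1))
  expect_equal(noise_level(fm), 40)
  one <- fm_of(c(150, 300), cbind(c(7, 3)), c(A = 1))
  expect_equal(noise_level(one), 7)
  # adding a feature below all maxima leaves the value unchanged
  fm2 <- fm_of(c(150, 300, 400), rbind(c(100, 40), c(60, 10), c(5, 5)),
               c(A = 1, B = 1))
  expect_equal(noise_level(fm2), 40)
})

test_that("isotope verification validates, rejects and measures ratios", {
  # unobservable pattern (expected M+1 below noise) validates by default
  fm <- fm_of(c(255.232954), matrix(1000, 1, 2), c(A = 2))
  counts <- c(C = 16, H = 32, O = 2, N = 0, S = 0, P = 0)
  expect_true(isotope_verify(1, counts, fm, noise = 500))
  # observable pattern with no M+1 feature in the window: rejected
  fm2 <- fm_of(c(255.232954), matrix(1e6, 1, 2), c(A = 2))
  expect_false(isotope_verify(1, counts, fm2, noise = 500))
  # correct simulated M+1 at the expected position and ratio: validated
  ratio <- expected_isotopologue_ratio("C16H32O2")
  fm3 <- fm_of(c(255.232954, 255.232954 + isotopologue_shift()),
               rbind(c(1e6, 1e6), ratio * c(1e6, 1e6)), c(A = 2))
  d <- isotope_verify(1, counts, fm3, noise = 500, detail = TRUE)
  expect_true(d$ok)
  expect_equal(d$n_obs, 2L)
  expect_equal(d$mean_log_rel, 0, tolerance = 1e-12)
  expect_equal(d$iso_feature, 2L)
  # ratio off by more than rel_tol: rejected
  fm4 <- fm3
  fm4$intensity[2, ] <- fm3$intensity[2, ] * 2
  expect_false(isotope_verify(1, counts, fm4, noise = 500, rel_tol = 0.5))
})

test_that("network propagation assigns homologs and respects the grid", {
  glc <- monoisotopic_mass("C6H12O6")
  targets <- c(glc, monoisotopic_mass("C7H14O6"))
  fm <- fm_of(mz_of_ion(targets), matrix(c(10, 10, 5, 5), 2, 2), c(A = 2))
  seeds <- data.frame(feature = 1L, formula = "C6H12O6")
  prop <- propagate_network(seeds, fm, remds = load_remds(), tol = 0.5)
  expect_equal(prop$feature, 2L)
  expect_equal(prop$formula, "C7H14O6")
  expect_equal(prop$remd, "methylene")
  expect_equal(prop$seed_feature, 1L)

  # empty REMD library: no new assignments
  empty <- load_remds()[0, ]
  expect_equal(nrow(propagate_network(seeds, fm, remds = empty)), 0)

  # grid bound: propagation may not exceed S3
  s3 <- "C10H20O8S3"   # valid: S/C = 0.3, even valence sum
  expect_true(senior_check(s3)$valid && ratio_check(s3))
  m_s4 <- monoisotopic_mass(s3) + monoisotopic_mass("S")
  fm2 <- fm_of(mz_of_ion(c(monoisotopic_mass(s3), m_s4)),
               matrix(5, 2, 2), c(A = 2))
  prop2 <- propagate_network(data.frame(feature = 1L, formula = s3), fm2,
                             remds = load_remds())
  expect_false(2L %in% prop2$feature)
})

test_that("propagation is monotone in the REMD library", {
  # a CH2 ladder reachable only via methylene: adding REMDs never removes
  # an assignment
  fs <- sprintf("C%dH%dO2", 10:14, 2 * (10:14))
  mzs <- mz_of_ion(vapply(fs, monoisotopic_mass, numeric(1)))
  fm <- fm_of(mzs, matrix(3, 5, 2), c(A = 2))
  seeds <- data.frame(feature = 3L, formula = fs[3])
  lib1 <- load_remds()[load_remds()$name == "methylene", ]
  lib2 <- load_remds()[load_remds()$name %in% c("methylene", "hydration"), ]
  p1 <- propagate_network(seeds, fm, remds = lib1)
  p2 <- propagate_network(seeds, fm, remds = lib2)
  expect_true(all(paste(p1$feature, p1$formula) %in%
                    paste(p2$feature, p2$formula)))
  expect_setequal(p1$feature, c(1, 2, 4, 5))
  expect_true(all(p1$depth <= 2))
})

test_that("finalized assignment tables are internally consistent", {
  rec <- data.frame(feature = 1:3, mz = c(150, 200, 250),
                    formula = c("C6H12O6", NA, "C7H14O6"),
                    ppm = c(0.1, NA, -0.2),
                    status = c("validated-isotope", "unassigned",
                               "validated-network"),
                    provenance = c("combinatorial", NA, "propagated"),
                    seed_feature = c(NA, NA, 1L), remd = c(NA, NA, "methylene"))
  out <- finalize_assignments(rec)
  expect_equal(unname(out$summary[["features"]]), 3)
  expect_equal(unname(out$summary[["unassigned"]]), 1)
  expect_equal(sum(out$summary[c("isotope_validated", "network_propagated",
                                 "isotopologue", "unassigned")]), 3)
  expect_error(finalize_assignments(rec[c(1, 1, 2), ]), "consistency")
})

test_that("assignment cascade recovers ground truth on a small simulation", {
  run <- cached_pipeline()
  ann <- run$assignments
  truth <- run$sim$truth
  fmf <- run$fm_filtered
  idx <- vapply(truth$mz_theoretical, function(z) {
    d <- abs(fmf$mz - z) / z * 1e6
    i <- which.min(d)
    if (d[i] <= 1) i else NA_integer_
  }, integer(1))
  det <- which(!is.na(idx))
  expect_gt(length(det), 200)
  hit <- ann$assignments$formula[idx[det]] == truth$formula[det]
  expect_gte(mean(hit, na.rm = TRUE), 0.99)
  # no accepted assignment beyond the 0.5 ppm tolerance
  acc <- ann$assignments[!is.na(ann$assignments$formula), ]
  expect_true(all(abs(acc$ppm) <= 0.5))
})
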