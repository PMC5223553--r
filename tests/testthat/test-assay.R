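test_that("single-hit model constant: 63.2% positive at one producer per well", {
  # P(positive) = 1 - exp(-f c); at f*c = 1 this is 1 - 1/e
  expect_equal(1 - exp(-1), 0.632, tolerance = 5e-4 / 0.632)
})

test_that("crossing estimator inverts the single-hit model", {
  # fractions exactly on the model for f = 0.01: crossing at c* = 100
  cells <- 1000 / 3^(0:7)
  p <- 1 - exp(-0.01 * cells)
  wells <- rep(100000, 8)
  s <- dilution_series(cells, wells, round(p * wells))
  est <- ld_frequency_crossing(s)
  expect_equal(est$f, 0.01, tolerance = 0.005)
  expect_equal(est$flag, "ok")
  expect_true(est$ci[1] <= est$f && est$f <= est$ci[2])

  # single informative dilution: closed form f = -log(1-p)/c
  s2 <- dilution_series(c(50, 16.7), c(24, 24), c(12, 0))
  est2 <- ld_frequency_crossing(s2)
  expect_equal(est2$f, -log(1 - 0.5) / 50, tolerance = 1e-9)

  # all-negative and all-positive boundaries are flagged
  s3 <- dilution_series(c(100, 33), c(24, 24), c(0, 0))
  est3 <- ld_frequency_crossing(s3)
  expect_equal(est3$f, 0)
  expect_equal(est3$flag, "all-negative")
  expect_gt(est3$ci[2], 0)
  s4 <- dilution_series(c(100, 33), c(24, 24), c(24, 24))
  est4 <- ld_frequency_crossing(s4)
  expect_equal(est4$flag, "all-positive")
})

test_that("crossing estimator recovers a planted frequency on average", {
  set.seed(55)
  ests <- replicate(300, ld_frequency_crossing(rseries(1 / 200))$f)
  expect_lt(abs(stats::median(ests) - 1 / 200) / (1 / 200), 0.15)
})

test_that("single-hit MLE: boundaries, consistency and unimodality", {
  # all negative: likelihood maximized at f -> 0
  s0 <- dilution_series(c(100, 33), c(24, 24), c(0, 0))
  e0 <- ld_frequency_mle(s0)
  expect_equal(e0$f, 0)
  expect_equal(e0$flag, "all-negative")

  # large-n data at the model: MLE close to crossing estimate, inside CI
  cells <- 1000 / 3^(0:7)
  wells <- rep(100000, 8)
  s <- dilution_series(cells, wells, round((1 - exp(-0.005 * cells)) * wells))
  mle <- ld_frequency_mle(s)
  cross <- ld_frequency_crossing(s)
  expect_equal(mle$f, 0.005, tolerance = 0.01)
  expect_true(cross$f >= mle$ci[1] && cross$f <= mle$ci[2])
  # profile CI is a genuine interval around the estimate
  expect_lt(mle$ci[1], mle$f)
  expect_gt(mle$ci[2], mle$f)

  # unimodality: the log-likelihood has a single interior maximum on a grid
  set.seed(77)
  for (i in 1:5) {
    s <- rseries(10^runif(1, -3.2, -1.5))
    if (all(s$positives == 0)) next
    grid <- exp(seq(log(1e-6), log(0.5), length.out = 200))
    ll <- vapply(grid, function(f) mdinet:::single_hit_loglik(f, s), numeric(1))
    peaks <- sum(diff(sign(diff(ll))) < 0)
    expect_lte(peaks, 1)
  }
})

test_that("reactivation frequencies normalize to genomic load", {
  expect_identical(normalize_reactivation(0.01, 5e4, 0.01, 5e4), 1)
  expect_identical(normalize_reactivation(0.02, 5e4, 0.01, 5e4), 2)
  expect_identical(normalize_reactivation(0.01, 1e5, 0.01, 5e4), 0.5)
  expect_error(normalize_reactivation(0.01, 0, 0.01, 5e4))
})

test_that("2^-dCt expression and control anchoring", {
  expect_equal(relative_expression_ddct(25, 20), 2^-5)
  expect_equal(relative_expression_ddct(20, 20), 1)
  # shift invariance: adding a constant to both Ct values changes nothing
  expect_equal(relative_expression_ddct(25 + 3.7, 20 + 3.7),
               relative_expression_ddct(25, 20), tolerance = 1e-12)
  x <- c(0.8, 1.0, 1.2, 3, 4)
  ctrl <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  r <- rescale_to_control(x, ctrl)
  expect_equal(mean(r[ctrl]), 1, tolerance = 1e-12)

  df <- data.frame(
    sample = rep(paste0("m", 1:4), each = 2),
    group = rep(c("virus_29d", "virus_29d", "virus_cnp", "virus_cnp"), each = 2),
    gene = rep(c("ORF50", "ORF73"), 4),
    ct = c(30, 24, 31, 24, 27, 24, 26, 24))
  out <- expression_ratio(df, "ORF50", "ORF73", "virus_29d")
  expect_equal(mean(out$ratio[out$group == "virus_29d"]), 1, tolerance = 1e-12)
  expect_gt(mean(out$ratio[out$group == "virus_cnp"]), 1)
})

test_that("overlap filter applies the >= threshold rule against all controls", {
  # 6 features with hand-set values; case groups c1,c2 vs controls k1,k2
  tab <- rbind(
    f1 = c(c1 = 3.0, c2 = 3.2, k1 = 1.0, k2 = 1.1),  # up everywhere
    f2 = c(c1 = 1.6, c2 = 1.8, k1 = 1.0, k2 = 1.0),  # up (>= 1.5 in all)
    f3 = c(c1 = 3.0, c2 = 1.2, k1 = 1.0, k2 = 1.0),  # fails one case group
    f4 = c(c1 = 0.5, c2 = 0.6, k1 = 1.0, k2 = 1.0),  # down everywhere
    f5 = c(c1 = 0.5, c2 = 0.9, k1 = 1.0, k2 = 1.0),  # fails one comparison
    f6 = c(c1 = 1.0, c2 = 1.0, k1 = 1.0, k2 = 1.0))  # unchanged
  res <- overlap_filter(tab, c("c1", "c2"), c("k1", "k2"))
  expect_equal(names(res$up), c("f1", "f2"))
  expect_equal(names(res$down), "f4")
  expect_length(intersect(res$up, res$down), 0)

  # boundary inclusive: exactly 1.5-fold everywhere counts as up
  tb <- rbind(fb = c(c1 = 1.5, k1 = 1.0))
  expect_equal(names(overlap_filter(tb, "c1", "k1")$up), "fb")

  # threshold 1: consistent direction passes, up/down stay disjoint
  res1 <- overlap_filter(tab, c("c1", "c2"), c("k1", "k2"), threshold = 1)
  expect_length(intersect(res1$up, res1$down), 0)
  expect_true(all(c("f1", "f2") %in% names(res1$up)))
  expect_error(overlap_filter(tab, "c1", "missing"), "missing group")
})

test_that("up and down overlap sets are always disjoint", {
  set.seed(14)
  for (i in 1:10) {
    tab <- matrix(rlnorm(40), 10, 4,
                  dimnames = list(NULL, c("c1", "c2", "k1", "k2")))
    res <- overlap_filter(tab, c("c1", "c2"), c("k1", "k2"),
                          threshold = 1 + runif(1))
    expect_length(intersect(res$up, res$down), 0)
  }
})
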