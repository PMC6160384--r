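# independent tail oracle: R's exact negative-binomial CDF in place of the
# package's own log-space summation
ac_oracle <- function(x, N1, y, N2) {
  pr1 <- N1 / (N1 + N2); pr2 <- N2 / (N1 + N2)
  up1 <- stats::pnbinom(y - 1, size = x + 1, prob = pr1, lower.tail = FALSE)
  lo1 <- stats::pnbinom(y, size = x + 1, prob = pr1)
  up2 <- stats::pnbinom(x, size = y + 1, prob = pr2)              # P(X <= x | y)
  lo2 <- stats::pnbinom(x - 1, size = y + 1, prob = pr2, lower.tail = FALSE)
  min(1, 2 * min((up1 + up2) / 2, (lo1 + lo2) / 2))
}

test_that("the two-library count test matches the exact tail oracle", {
  g <- expand.grid(x = seq(0, 30, by = 3), y = seq(0, 30, by = 3))
  for (N in c(1e4, 1e6)) {
    p <- ac_test(g$x, N, g$y, N)$p_value
    po <- mapply(ac_oracle, g$x, N, g$y, N)
    expect_lt(max(abs(p - po)), 1e-12)
  }
  p <- ac_test(g$x, 1e4, g$y, 3e4)$p_value
  po <- mapply(ac_oracle, g$x, 1e4, g$y, 3e4)
  expect_lt(max(abs(p - po)), 1e-12)
})

test_that("the count test is symmetric, calibrated at the corners, and monotone", {
  expect_equal(ac_test(0, 10, 0, 10)$p_value, 1)
  expect_equal(ac_test(5, 1e4, 5, 1e4)$p_value, 1)
  expect_lt(ac_test(0, 1e6, 30, 1e6)$p_value, 1e-6)
  # swap invariance
  x <- c(3, 7, 0, 20, 2); y <- c(10, 2, 30, 5, 40)
  expect_equal(ac_test(x, 1e4, y, 2e4)$p_value,
               ac_test(y, 2e4, x, 1e4)$p_value)
  # p decreases as the count imbalance grows, totals fixed
  ps <- ac_test(rep(10, 6), 1e5, c(10, 15, 20, 30, 40, 60), 1e5)$p_value
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("expression screening flags planted changes and nothing on identical input", {
  prof <- function(ids, top, tot = top) {
    data.frame(mirna_id = ids, precursor_id = ids, arm = "5p", annotated = TRUE,
               total_count = tot, canonical = top, isomir_5p = 0L,
               isomir_3p = tot - top, isomir_53p = 0L, isomir_3e = 0L,
               top_variant_count = top, stringsAsFactors = FALSE)
  }
  ids <- sprintf("m%02d", 1:10)
  p1 <- prof(ids, rep(200L, 10), rep(260L, 10))
  # identical libraries: nothing flagged
  de0 <- de_screen(p1, p1, N1 = 1e6, N2 = 1e6)
  expect_equal(sum(de0$flagged), 0)
  # an 8-fold planted change at mean 200 is caught at p < 0.001
  p2 <- prof(ids, c(1600L, rep(200L, 9)), c(2080L, rep(260L, 9)))
  de1 <- de_screen(p1, p2, N1 = 1e6, N2 = 1e6)
  expect_true(de1$flagged[de1$mirna_id == "m01"])
  expect_equal(sum(de1$flagged), 1)
  # a miRNA absent from both libraries gets p = 1
  p1z <- prof(ids, c(rep(200L, 9), 0L), c(rep(260L, 9), 0L))
  p2z <- prof(ids, c(rep(200L, 9), 0L), c(rep(260L, 9), 0L))
  dez <- de_screen(p1z, p2z, N1 = 1e6, N2 = 1e6)
  expect_equal(dez$p[dez$mirna_id == "m10"], 1)
  expect_error(de_screen(p1[0, ], p1), "empty")
})

test_that("isomiR pattern screening applies the chi-square and both filters", {
  mk <- function(tot, shares) {
    make_profiles("m-5p", canonical = round(tot * shares[1]),
                  i5 = round(tot * shares[2]), i3 = round(tot * shares[3]),
                  i53 = round(tot * shares[4]), i3e = round(tot * shares[5]))
  }
  # identical composition: chi2 = 0, not flagged
  a <- mk(2000, c(0.55, 0.05, 0.30, 0.05, 0.05))
  out <- isomir_pattern_screen(a, a)
  expect_equal(out$chi2, 0)
  expect_false(out$flagged)
  # planted ISOMIR_3P share drop 30% -> 15% at totals 5000: flagged,
  # and the statistic matches the textbook contingency computation
  b1 <- mk(5000, c(0.55, 0.05, 0.30, 0.05, 0.05))
  b2 <- mk(5000, c(0.70, 0.05, 0.15, 0.05, 0.05))
  out <- isomir_pattern_screen(b1, b2)
  expect_true(out$flagged)
  m <- rbind(as.numeric(b1[1, c("isomir_5p", "isomir_3p", "isomir_53p", "isomir_3e")]),
             as.numeric(b2[1, c("isomir_5p", "isomir_3p", "isomir_53p", "isomir_3e")]))
  expect_equal(out$chi2, chi2_oracle(m), tolerance = 1e-9)
  expect_equal(out$df, 3)
  expect_equal(out$max_share_shift, 15, tolerance = 0.1)
  # same shift at totals 500/600: abundance filter blocks the flag
  c1 <- mk(500, c(0.55, 0.05, 0.30, 0.05, 0.05))
  c2 <- mk(600, c(0.70, 0.05, 0.15, 0.05, 0.05))
  out <- isomir_pattern_screen(c1, c2)
  expect_false(out$flagged)
  expect_lt(out$p, 0.05)  # significant but filtered
})

test_that("arm-ratio switches are detected with the inclusive 1.5-fold rule", {
  ac <- function(c5, c3) data.frame(precursor_id = "pre-x", count5p = c5,
                                    count3p = c3, stringsAsFactors = FALSE)
  # control 5p/3p about 1:2, knockdown 5p about 12% above 3p
  out <- arm_switch_scan(ac(100, 200), ac(112, 100))
  expect_true(out$flagged)
  expect_equal(out$direction, "UP_5P")
  expect_equal(out$fold_change, ((112 + 1) / (100 + 1)) / ((100 + 1) / (200 + 1)),
               tolerance = 1e-12)
  expect_gt(out$fold_change, 2.2)
  # equal ratios: fold 1, silent
  out <- arm_switch_scan(ac(100, 200), ac(100, 200))
  expect_false(out$flagged)
  expect_equal(out$fold_change, 1)
  # boundary exactly 1.5 is flagged (inclusive)
  r1 <- ac(299, 99)   # ratio 3
  r2 <- ac(199, 99)   # ratio 2
  out <- arm_switch_scan(ac(199, 99), ac(299, 99))
  expect_equal(out$fold_change, 1.5)
  expect_true(out$flagged)
})

test_that("null simulations stay quiet in both screens", {
  set.seed(20)
  # arm scan: Poisson null at deep per-arm coverage raises no flags
  lam5 <- runif(100, 5000, 20000); lam3 <- runif(100, 5000, 20000)
  a1 <- data.frame(precursor_id = sprintf("p%03d", 1:100),
                   count5p = rpois(100, lam5), count3p = rpois(100, lam3))
  a2 <- data.frame(precursor_id = sprintf("p%03d", 1:100),
                   count5p = rpois(100, lam5), count3p = rpois(100, lam3))
  expect_equal(sum(arm_switch_scan(a1, a2)$flagged), 0)
  # and recovers every planted 2-fold ratio switch
  sw1 <- data.frame(precursor_id = sprintf("s%02d", 1:20),
                    count5p = rpois(20, 8000), count3p = rpois(20, 8000))
  sw2 <- data.frame(precursor_id = sprintf("s%02d", 1:20),
                    count5p = rpois(20, 16000), count3p = rpois(20, 8000))
  expect_equal(sum(arm_switch_scan(sw1, sw2)$flagged), 20)
})
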