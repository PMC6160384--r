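test_that("the univariate Cox fit recovers planted effects and rejects degenerate input", {
  prm <- cohort_params(survival_beta = c(gA = 1), censor_rate = 0.2, seed = 1)
  sv <- simulate_survival_cohort(prm, n = 500)
  z <- scale(log(sv$expression["gA", ]))[, 1]
  fit <- cox_fit_univariate(sv$clinical$time, sv$clinical$event, z)
  expect_gt(fit$beta, 0.85)
  expect_lt(fit$beta, 1.15)
  # all samples censored
  expect_error(cox_fit_univariate(1:10, rep(0, 10), rnorm(10)), "events")
  # constant covariate
  expect_error(cox_fit_univariate(1:10, rep(1, 10), rep(2, 10)), "constant")
})

test_that("null covariates are rarely called significant by the Cox fit", {
  set.seed(2)
  hits <- vapply(1:100, function(i) {
    n <- 120
    tm <- rexp(n, 0.01); ev <- rep(1L, n); x <- rnorm(n)
    fit <- cox_fit_univariate(tm, ev, x)
    abs(fit$beta) > 2 * fit$se
  }, logical(1))
  expect_lte(mean(hits), 0.1)
})

test_that("risk grouping splits on the median score with the documented tie rule", {
  rg <- risk_groups(2, c(1, 2, 3, 4))
  expect_equal(as.character(rg$group), c("LOW", "LOW", "HIGH", "HIGH"))
  # negative coefficient inverts the grouping relative to expression
  rg2 <- risk_groups(-2, c(1, 2, 3, 4))
  expect_equal(as.character(rg2$group), c("HIGH", "HIGH", "LOW", "LOW"))
  # group sizes differ by <= 1 on distinct scores
  rg3 <- risk_groups(1, rnorm(101))
  expect_lte(abs(diff(table(rg3$group))), 1)
  # exact-median ties go LOW; all-equal scores are all LOW
  rg4 <- risk_groups(1, c(5, 5, 5, 5))
  expect_true(all(rg4$group == "LOW"))
})

test_that("the log-rank test matches a hand-tabulated oracle and its edge cases", {
  # duplicated samples across groups: no difference
  t0 <- c(5, 10, 15, 20, 25, 30); e0 <- c(1, 1, 0, 1, 1, 1)
  lr0 <- logrank_test(factor(rep(c("LOW", "HIGH"), each = 6)), c(t0, t0), c(e0, e0))
  expect_equal(lr0$chi2, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1)
  # textbook O/E/V tabulation over distinct event times
  tm <- c(3, 5, 7, 9, 11, 14, 2, 4, 6, 8, 10, 12)
  ev <- c(1, 1, 1, 0, 1, 1, 1, 1, 1, 1, 0, 1)
  gr <- factor(rep(c("LOW", "HIGH"), each = 6), levels = c("LOW", "HIGH"))
  lr <- logrank_test(gr, tm, ev)
  o <- e <- v <- 0
  for (t in sort(unique(tm[ev == 1]))) {
    at <- tm >= t
    n1 <- sum(at & gr == "HIGH"); n <- sum(at)
    d <- sum(tm == t & ev == 1); d1 <- sum(tm == t & ev == 1 & gr == "HIGH")
    o <- o + d1
    e <- e + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  expect_equal(lr$chi2, (o - e)^2 / v, tolerance = 1e-9)
  # complete separation is highly significant
  tm2 <- c(seq(1, 20, length.out = 20), seq(100, 200, length.out = 20))
  gr2 <- factor(rep(c("HIGH", "LOW"), each = 20), levels = c("LOW", "HIGH"))
  lr2 <- logrank_test(gr2, tm2, rep(1, 40))
  expect_lt(lr2$p_value, 0.01)
  expect_error(logrank_test(factor(rep("LOW", 6)), t0, e0), "empty")
})

test_that("the survival screen flags planted features with the right direction", {
  prm <- cohort_params(survival_beta = c(risky = 1, protective = -1),
                       censor_rate = 0.2, seed = 3)
  sv <- simulate_survival_cohort(prm, n = 300, n_features = 6)
  scr <- survival_screen(sv$expression, sv$clinical)
  tab <- scr$table
  expect_equal(tab$direction[tab$feature_id == "risky"], "HIGH_EXPR_RISK")
  # protective feature: low expressors form the HIGH risk group
  expect_equal(tab$direction[tab$feature_id == "protective"], "LOW_EXPR_RISK")
  expect_lt(tab$adj_p[tab$feature_id == "risky"], 0.05)
  expect_lt(tab$adj_p[tab$feature_id == "protective"], 0.05)
  # KM coordinates exist per fitted feature
  expect_true(all(c("risky", "protective") %in% names(scr$km)))
  # single-feature screen: adjusted p equals raw p
  one <- survival_screen(sv$expression["risky", , drop = FALSE], sv$clinical)
  expect_equal(one$table$adj_p, one$table$p)
})

test_that("unmatched samples are dropped with a message", {
  prm <- cohort_params(survival_beta = c(g = 0.5), censor_rate = 0, seed = 4)
  sv <- simulate_survival_cohort(prm, n = 60)
  cl <- sv$clinical
  cl$sample_id[1] <- "not-a-sample"
  expect_message(scr <- survival_screen(sv$expression, cl), "unmatched")
  expect_equal(scr$table$n_high + scr$table$n_low, 59)
})
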