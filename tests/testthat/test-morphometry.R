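# Morphometry statistics: heteroscedastic ANOVAs, two-stage BKY FDR,
# Kruskal-Wallis/Dunn, KS, percent change, intensity-diameter regression.

test_that("Welch ANOVA reduces to the squared Welch t for two groups", {
  set.seed(61)
  a <- rnorm(20, 0, 1)
  b <- rnorm(15, 0.5, 2)
  w <- welch_anova(list(a, b))
  tt <- t.test(a, b, var.equal = FALSE)
  expect_equal(w$statistic, unname(tt$statistic)^2)
  expect_equal(w$df2, unname(tt$parameter))
  expect_equal(w$p, tt$p.value)
  expect_error(welch_anova(list(rep(1, 5), rep(1, 5))), "zero variance")
  expect_error(welch_anova(list(rnorm(5), 3)), "at least 2")
})

test_that("Brown-Forsythe F* equals the classical F for balanced designs", {
  set.seed(62)
  groups <- replicate(3, rnorm(25, 0, 1), simplify = FALSE)
  bf <- brown_forsythe_anova(groups)
  x <- unlist(groups)
  g <- factor(rep(1:3, each = 25))
  classical <- unname(summary(stats::aov(x ~ g))[[1]]$`F value`[1])
  expect_equal(bf$statistic, classical, tolerance = 1e-10)
  expect_equal(bf$df1, 2)

  # two identical groups: F* = 0
  z <- rnorm(10)
  bf0 <- brown_forsythe_anova(list(z, z))
  expect_equal(bf0$statistic, 0)
})

test_that("the two-stage BKY procedure matches the brute-force oracle", {
  p_example <- c(0.001, 0.01, 0.02, 0.2, 0.9)
  got <- bky_two_stage(p_example, q = 0.05)
  expect_identical(got$rejected, bky_oracle(p_example, 0.05))
  expect_identical(sum(got$rejected), 3L)
  expect_identical(got$r1, 3L)

  expect_false(any(bky_two_stage(rep(1, 5))$rejected))
  expect_true(all(bky_two_stage(rep(0, 5))$rejected))

  set.seed(63)
  sizes <- integer(0)
  for (i in 1:300) {
    m <- sample(3:8, 1)
    p <- round(runif(m)^sample(1:6, 1), 3)
    r <- bky_two_stage(p, q = 0.05)
    expect_identical(r$rejected, bky_oracle(p, 0.05))
    # never reject a p-value larger than a rejected one; superset of stage-1 BH
    if (any(r$rejected) && any(!r$rejected)) {
      expect_lt(max(p[r$rejected]), min(p[!r$rejected]) + 1e-12)
    }
    sizes <- c(sizes, sum(r$rejected))
  }
  # the full range of achievable rejection sizes was exercised
  expect_true(all(c(0, 1, 2, 3) %in% sizes))

  # adjusted values are monotone in p
  set.seed(64)
  p <- runif(8)
  r <- bky_two_stage(p)
  expect_true(all(diff(r$adjusted[order(p)]) >= -1e-12))
})

test_that("BKY rejections are a superset of stage-1 BH rejections", {
  set.seed(65)
  for (i in 1:50) {
    p <- runif(6)^3
    bky <- bky_two_stage(p, 0.05)$rejected
    bh1 <- p.adjust(p, "BH") <= 0.05 / 1.05
    expect_true(all(!bh1 | bky))
  }
})

test_that("Kruskal-Wallis/Dunn agrees with rank-sum equivalents", {
  set.seed(66)
  a <- rnorm(18)
  b <- rnorm(14, 1)
  kd <- kruskal_dunn(list(a = a, b = b))
  mw <- wilcox.test(a, b, exact = FALSE, correct = FALSE)
  expect_equal(kd$p, mw$p.value, tolerance = 1e-10)

  same <- kruskal_dunn(list(g1 = rep(2, 6), g2 = rep(2, 8)))
  expect_equal(same$H, 0)
  expect_equal(same$p, 1)

  three <- kruskal_dunn(list(a = a, b = b, c = rnorm(10, 2)))
  expect_identical(nrow(three$pairwise), 3L)
  expect_true(all(three$pairwise$p_adjusted >= three$pairwise$p))
  expect_true(all(three$pairwise$p_adjusted <= 1))
})

test_that("KS test handles identical and disjoint samples", {
  x <- c(1, 2, 3, 4.5)
  same <- ks_two_sample(x, x)
  expect_equal(same$D, 0)
  disj <- ks_two_sample(1:10, 101:110)
  expect_equal(disj$D, 1)
  expect_error(ks_two_sample(numeric(0), 1:3), "non-empty")
})

test_that("percent change is plain relative arithmetic", {
  expect_equal(percent_change(108.1, 100), 8.1)
  expect_equal(percent_change(5, 5), 0)
  expect_equal(percent_change(50, 100), -50)
  expect_error(percent_change(3, 0), "zero")
})

test_that("intensity-diameter regression: exact fits, recovery, exclusions", {
  d <- seq(2, 40, length.out = 50)
  exact <- data.frame(diameter = d, intensity = 3 * d + 7)
  fit <- suppressWarnings(fit_intensity_vs_diameter(exact, "linear"))
  expect_equal(fit$slope, 3)
  expect_equal(fit$adj_r_squared, 1)
  expect_lt(fit$slope_p, 1e-15)

  set.seed(67)
  noisy <- data.frame(diameter = d, intensity = 2.5 * d + rnorm(50, 0, 4))
  f2 <- fit_intensity_vs_diameter(noisy, "linear")
  se_slope <- summary(f2$fit)$coefficients["x", "Std. Error"]
  expect_lt(abs(f2$slope - 2.5), 2 * se_slope)
  expect_lte(f2$adj_r_squared, f2$r_squared)

  quad <- data.frame(diameter = d, intensity = 1 + 2 * d + 0.3 * d^2)
  f3 <- suppressWarnings(fit_intensity_vs_diameter(quad, "quadratic"))
  expect_equal(f3$quadratic, 0.3)

  # pure noise: adjusted R^2 ~ 0 on average
  set.seed(68)
  adj <- vapply(1:100, function(i) {
    fit_intensity_vs_diameter(
      data.frame(diameter = rnorm(100, 20, 5),
                 intensity = rnorm(100)), "linear")$adj_r_squared
  }, numeric(1))
  expect_lt(abs(mean(adj)), 0.02)

  expect_error(fit_intensity_vs_diameter(
    data.frame(diameter = rep(5, 10), intensity = rnorm(10))), "constant")

  # vessels wider than 50 um are excluded up front
  rec <- data.frame(diameter = c(5, 20, 50, 51, 80),
                    intensity = c(1, 2, 3, 4, 5))
  expect_identical(nrow(vessel_records(rec)), 3L)
  expect_error(vessel_records(data.frame(diameter = -1, intensity = 1)),
               "positive")
})

test_that("group comparison reports contrasts, q-values and percent changes", {
  set.seed(69)
  rec <- data.frame(
    group = rep(c("e3/3", "e3/4", "e4/4"), each = 40),
    intensity = c(rnorm(40, 100, 8), rnorm(40, 108.1, 8), rnorm(40, 126.6, 8))
  )
  out <- compare_groups(rec, reference_group = "e3/3", test = "welch")
  expect_identical(out$contrasts$group, c("e3/4", "e4/4"))
  expect_true(all(out$contrasts$q_value >= 0))
  expect_true(out$contrasts$rejected[out$contrasts$group == "e4/4"])
  pc <- out$contrasts$percent_change
  expect_lt(abs(pc[2] - 26.6), 8)   # recovers the planted group shift
  ko <- compare_groups(rec, "e3/3", test = "kruskal")
  expect_identical(nrow(ko$contrasts), 2L)
})
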