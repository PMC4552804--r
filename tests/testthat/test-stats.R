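test_that("Bland-Altman bias and limits follow the 1.96 convention", {
  x <- c(10, 9.5, 8, 11, 7.2)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$mean_diff, 0)
  expect_equal(ba0$loa_low, 0)
  expect_equal(ba0$loa_high, 0)

  ba1 <- bland_altman(x + 1, x)
  expect_equal(ba1$mean_diff, 1)
  expect_equal(ba1$sd_diff, 0)
  expect_equal(c(ba1$loa_low, ba1$loa_high), c(1, 1))

  set.seed(20)
  a <- rnorm(500, 10, 2)
  ba <- bland_altman(a + rnorm(500), a)
  expect_equal(ba$loa_high - ba$mean_diff, 1.96 * ba$sd_diff)
  expect_true(ba$loa_low <= ba$mean_diff && ba$mean_diff <= ba$loa_high)
  expect_equal(nrow(ba$table), 500L)

  expect_error(bland_altman(1, 1:2), "equal length")
  expect_error(bland_altman(1, 2), "at least 2")
})

test_that("per-hour rank-sum tests match enumeration and adjust by step-up", {
  # complete 3 vs 3 separation: exact two-sided p = 2 / choose(6, 3) = 0.1
  d <- data.frame(hour = 0, group = rep(c("a", "b"), each = 3),
                  value = c(1, 2, 3, 10, 11, 12))
  out <- ranksum_by_time(d)
  expect_equal(out$p, 0.1, tolerance = 1e-12)
  expect_equal(out$p, ranksum_enum_p(c(1, 2, 3), c(10, 11, 12)),
               tolerance = 1e-12)

  # identical groups: all ranks tied, p = 1
  d2 <- data.frame(hour = 4, group = rep(c("a", "b"), each = 4), value = 5)
  expect_equal(ranksum_by_time(d2)$p, 1)

  # exact p agrees with enumeration on random tie-free data
  set.seed(33)
  xa <- rnorm(5); xb <- rnorm(6) + 0.5
  d3 <- data.frame(hour = 0, group = rep(c("a", "b"), c(5, 6)),
                   value = c(xa, xb))
  expect_equal(ranksum_by_time(d3)$p, ranksum_enum_p(xa, xb),
               tolerance = 1e-12)

  # step-up adjustment across hours: {0.01, 0.02, 0.03} -> all 0.03
  d4 <- do.call(rbind, lapply(1:3, function(h) {
    data.frame(hour = h, group = rep(c("a", "b"), each = 3),
               value = rnorm(6))
  }))
  out4 <- ranksum_by_time(d4)
  expect_equal(out4$p_adj, p.adjust(out4$p, "BH"))
  expect_true(all(out4$p_adj >= out4$p))
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))

  # an hour with an empty group is skipped with a message
  d5 <- rbind(d, data.frame(hour = 8, group = "a", value = 1:3))
  expect_message(out5 <- ranksum_by_time(d5), "skipped")
  expect_equal(out5$hour, 0)
})

test_that("Kruskal-Wallis matches the hand formula and handles ties", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(10, 11, 12)))
  expect_equal(kw$H, 12 / (6 * 7) * (3 * 2^2 + 3 * 5^2) - 3 * 7,
               tolerance = 1e-9)   # 3.857
  expect_equal(kw$df, 1L)

  expect_equal(kruskal_wallis(list(c(1, 2), c(1, 2)))$H,
               unname(kruskal.test(c(1, 2, 1, 2),
                                   factor(rep(1:2, each = 2)))$statistic))
  ident <- kruskal_wallis(rep(3, 9), rep(1:3, 3))
  expect_equal(ident$H, 0)
  expect_equal(ident$p, 1)

  # null p-values are uniform (rank test calibration)
  set.seed(71)
  ps <- replicate(300, {
    kruskal_wallis(rnorm(18), rep(1:3, each = 6))$p
  })
  # rank configurations recur, so ks.test sees ties; the comparison stands
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("ANOVA-type statistics detect the designed group trajectory difference", {
  hours <- c(0, 4, 8, 12, 16, 20, 24)
  mk <- function(seed, treated_effect = TRUE) {
    set.seed(seed)
    d <- expand.grid(animal = 1:9, hour = hours)
    d$group <- ifelse(d$animal <= 4, "control", "treated")
    d$animal <- paste0("A", d$animal)
    mu <- ifelse(d$group == "treated" & treated_effect,
                 0.0103 * d$hour^2 - 0.3844 * d$hour + 9.2147,
                 10.7016)   # flat control
    d$value <- mu + rnorm(nrow(d), 0, 0.5)
    d
  }
  ats <- anova_type_statistic(mk(1))
  expect_equal(ats$effect, c("group", "time", "group:time"))
  expect_true(all(ats$p >= 0 & ats$p <= 1))
  expect_lt(ats$p[ats$effect == "group"], 0.01)

  # power at the printed effect size and study n
  rej <- vapply(1:60, function(s) {
    a <- anova_type_statistic(mk(s))
    a$p[a$effect == "group"] < 0.05 && a$p[a$effect == "group:time"] < 0.05
  }, TRUE)
  expect_gte(mean(rej), 0.8)

  # rank invariance under strictly monotone transforms
  d <- mk(2)
  a1 <- anova_type_statistic(d)
  d$value <- exp(d$value / 5)
  a2 <- anova_type_statistic(d)
  expect_equal(a1$statistic, a2$statistic, tolerance = 1e-12)

  # constant data: degenerate, statistic 0 and p = 1
  dc <- expand.grid(animal = 1:6, hour = c(0, 4))
  dc$group <- rep(c("g1", "g2"), 3)[dc$animal]
  dc$value <- 7
  ac <- anova_type_statistic(dc)
  expect_equal(ac$statistic, rep(0, 3))
  expect_equal(ac$p, rep(1, 3))

  # a single-animal group is inestimable
  bad <- data.frame(animal = c("x", "y", "y"), group = c("g1", "g2", "g2"),
                    hour = c(0, 0, 4), value = 1:3)
  expect_error(anova_type_statistic(bad), "fewer than 2 animals")
})

test_that("quadratic fits recover exact coefficients and define R^2 sanely", {
  t <- c(0, 4, 8, 12, 16, 20, 24)
  y <- 0.0103 * t^2 - 0.3844 * t + 9.2147
  fit <- fit_quadratic(t, y)
  expect_equal(fit$a, 0.0103, tolerance = 1e-9)
  expect_equal(fit$b, -0.3844, tolerance = 1e-9)
  expect_equal(fit$c, 9.2147, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  # residuals of any least-squares fit sum to zero
  set.seed(44)
  noisy <- y + rnorm(7, 0, 0.5)
  nf <- fit_quadratic(t, noisy)
  expect_equal(sum(nf$residuals), 0, tolerance = 1e-9)
  expect_true(nf$r_squared >= 0 && nf$r_squared <= 1)
  # R^2 invariant under affine rescaling of the response
  nf2 <- fit_quadratic(t, 3 * noisy - 10)
  expect_equal(nf2$r_squared, nf$r_squared, tolerance = 1e-9)

  expect_warning(cf <- fit_quadratic(t, rep(5, 7)), "constant response")
  expect_equal(cf$a, 0, tolerance = 1e-12)
  expect_equal(cf$c, 5, tolerance = 1e-12)
  expect_equal(cf$r_squared, 0)

  expect_error(fit_quadratic(c(0, 1), c(1, 2)), "3 distinct hours")
})
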