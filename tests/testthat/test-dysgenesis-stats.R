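test_that("dysgenic proportion is the scored fraction", {
  expect_equal(dysgenic_proportion(20, 80), 0.20)
  expect_equal(dysgenic_proportion(93, 7), 0.93)
  expect_equal(dysgenic_proportion(0, 50), 0)
  expect_error(dysgenic_proportion(0, 0), "at least one")
})

test_that("Fisher's exact test matches enumeration and fisher.test", {
  expect_equal(fisher_exact_2x2(3, 1, 1, 3), 0.4857143, tolerance = 1e-6)
  expect_equal(fisher_exact_2x2(5, 0, 0, 5), 2 / 252, tolerance = 1e-9)
  expect_equal(fisher_exact_2x2(5, 5, 5, 5), 1)
  expect_equal(fisher_exact_2x2(0, 0, 0, 0), 1)
  expect_equal(fisher_exact_2x2(0, 0, 1, 2), 1)

  set.seed(83)
  for (i in 1:200) {
    tab <- sample(0:15, 4, replace = TRUE)
    if (sum(tab) == 0) next
    mine <- fisher_exact_2x2(tab[1], tab[2], tab[3], tab[4])
    expect_equal(mine, oracle_fisher(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-9)
    expect_equal(mine,
                 stats::fisher.test(matrix(tab, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-7)
  }
})

test_that("binomial GLM recovers the closed-form log odds ratio and a flat
           null", {
  tbl <- data.frame(line = c("L1", "L2"), tester_subline = "S1",
                    direction = "dysgenic",
                    n_dysgenic = c(30L, 70L), n_normal = c(70L, 30L))
  fit <- line_effect_glm(tbl)
  expect_equal(unname(fit$coefficients["lineL2"]),
               log((70 / 30) / (30 / 70)), tolerance = 1e-4)
  expect_false(fit$separation)

  flat <- data.frame(line = c("L1", "L2", "L3"), tester_subline = "S1",
                     direction = "dysgenic",
                     n_dysgenic = 40L, n_normal = 60L)
  f0 <- line_effect_glm(flat)
  expect_lt(f0$lrt_stat, 1e-8)
  expect_gt(f0$p, 0.999)
})

test_that("GLM detects distinct planted line effects and flags separation", {
  hits <- 0L
  for (s in 1:40) {
    des <- cross_design(lines = c(A = -1, B = 1), n_f1_per_cross = 200,
                        directions = "dysgenic", seed = 9000 + s)
    fit <- line_effect_glm(simulate_cross_counts(des))
    if (fit$p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 38)

  sep <- data.frame(line = c("L1", "L2"), tester_subline = "S1",
                    direction = "dysgenic",
                    n_dysgenic = c(0L, 100L), n_normal = c(100L, 0L))
  expect_true(suppressWarnings(line_effect_glm(sep))$separation)
})

test_that("screen correlation follows the t transform", {
  x <- c(0.2, 0.4, 0.5, 0.7, 0.9)
  expect_equal(screen_correlation(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_equal(screen_correlation(x, -x)$r, -1, tolerance = 1e-12)
  set.seed(89)
  y <- x + rnorm(5, 0, 0.1)
  sc <- screen_correlation(x, y)
  t_cf <- sc$r * sqrt((5 - 2) / (1 - sc$r^2))
  expect_equal(sc$t, t_cf, tolerance = 1e-10)
  expect_equal(sc$p, 2 * pt(-abs(t_cf), 3), tolerance = 1e-10)
  # an r of 0.877 at n = 12 corresponds to p ~ 2e-4 under the t transform
  r <- 0.877; n <- 12
  p <- 2 * pt(-r * sqrt((n - 2) / (1 - r^2)), n - 2)
  expect_lt(p, 5e-4)
  expect_error(screen_correlation(rep(0.5, 5), x), "non-constant")
})

test_that("extreme-line classification is deterministic with flagged ties", {
  p <- c(A = 0.1, B = 0.5, C = 0.9)
  cls <- classify_extremes(p, 1)
  expect_equal(cls$resistant, "A")
  expect_equal(cls$susceptible, "C")
  expect_false(cls$ties)

  set.seed(97)
  p12 <- setNames(runif(12), sprintf("L%02d", 1:12))
  c3 <- classify_extremes(p12, 3)
  expect_length(intersect(c3$resistant, c3$susceptible), 0)
  expect_length(c3$resistant, 3)

  tied <- c(B = 0.2, A = 0.2, C = 0.8, D = 0.9)
  ct <- classify_extremes(tied, 1)
  expect_equal(ct$resistant, "A")   # lexicographic resolution
  expect_true(ct$ties)
})

test_that("relative expression reproduces the exponential Ct identities", {
  q <- expand.grid(line = "A", direction = "dysgenic", temperature = 29,
                   replicate = 1, target = c("spliced", "total", "reference"),
                   stringsAsFactors = FALSE)
  q$ct <- c(20, 19, 20)
  e <- relative_expression(q)
  expect_equal(e$spliced_expr, 1)
  expect_equal(e$total_expr, 2)
  expect_equal(e$splicing_efficiency, 0.5)

  q$ct <- c(18, 18, 20)
  e2 <- relative_expression(q)
  expect_equal(e2$spliced_expr, 4)          # 2 cycles => 2^2
  # invariance to a constant shift of every Ct in the cell
  q$ct <- q$ct + 3.7
  expect_equal(relative_expression(q)$spliced_expr, 4)

  q_missing <- q[q$target != "reference", ]
  expect_error(relative_expression(q_missing), "reference")
})

test_that("Box-Cox profile likelihood matches MASS and recovers canonical
           lambdas", {
  expect_equal(boxcox_lambda(c(2, 3, 4, 5, 6), grid = 1)$transformed,
               c(2, 3, 4, 5, 6) - 1)
  expect_error(boxcox_lambda(c(-1, 2, 3, 4, 5)), "positive")

  set.seed(103)
  x_norm <- rnorm(500, 10, 3)
  x_norm <- x_norm[x_norm > 0]
  expect_lt(abs(boxcox_lambda(x_norm)$lambda - 1), 0.5)
  x_lnorm <- exp(rnorm(500, 0, 1))
  expect_lt(abs(boxcox_lambda(x_lnorm)$lambda), 0.2)

  # cross-check the profile against MASS on the same grid
  bl <- boxcox_lambda(x_lnorm)
  mb <- MASS::boxcox(x_lnorm ~ 1, lambda = bl$loglik$lambda, plotit = FALSE)
  expect_equal(bl$lambda, mb$x[which.max(mb$y)], tolerance = 0.011)
})

test_that("splicing ANOVA: sequential sums of squares, F = t^2 on two-level
           designs, constant response", {
  set.seed(107)
  d <- expand.grid(line = sprintf("L%d", 1:4),
                   direction = c("dysgenic", "reciprocal"),
                   temperature = c(25, 29), replicate = 1:3,
                   stringsAsFactors = FALSE)
  d$y <- rnorm(nrow(d)) + 2 * (d$direction == "dysgenic")
  tab <- splicing_anova(d, "y")
  expect_equal(tab$term, c("direction", "temperature", "line", "Residuals"))
  expect_equal(tab$F[1], max(tab$F, na.rm = TRUE))

  # two groups, single factor: F equals the square of the pooled t
  d2 <- d[d$temperature == 25 & d$line == "L1", ]
  tab2 <- splicing_anova(d2, "y")
  tt <- t.test(y ~ direction, data = d2, var.equal = TRUE)
  expect_equal(tab2$F[1], unname(tt$statistic)^2, tolerance = 1e-10)

  # constant response: every factor sum of squares is exactly zero
  d$y <- 1
  tab3 <- suppressWarnings(splicing_anova(d, "y"))  # zero-residual fit
  expect_true(all(abs(tab3$sum_sq) < 1e-20))
})

test_that("a 1-cycle direction shift is detected by the downstream ANOVA
           with high power", {
  hits <- vapply(1:200, function(s) {
    des <- qpcr_design(lines = c("A", "B"), temperatures = 25,
                       direction_effect = c(spliced = 1, total = 0),
                       temperature_effect = c(spliced = 0, total = 0),
                       replicate_sd = 0.3, n_replicates = 3,
                       seed = 70000 + s)
    e <- relative_expression(simulate_qpcr(des))
    e$y <- boxcox_lambda(e$spliced_expr)$transformed
    tab <- suppressWarnings(splicing_anova(e, "y"))
    tab$p[tab$term == "direction"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("resistance summarises repeated dysgenic crosses and extreme
           recovery works at wide separation", {
  des <- cross_design(lines = c(R1 = -2, R2 = -1.8, S1 = 2, S2 = 1.8,
                                M1 = 0, M2 = 0.1),
                      tester_sublines = c(T1 = 0, T2 = 0.1),
                      n_f1_per_cross = 150, seed = 5)
  cc <- simulate_cross_counts(des)
  res <- resistance_from_crosses(cc)
  expect_length(res, 6)
  expect_true(all(res[c("R1", "R2")] > res[c("S1", "S2")]))
  dprop <- 1 - res
  cls <- classify_extremes(dprop, 2)
  expect_setequal(cls$resistant, c("R1", "R2"))
  expect_setequal(cls$susceptible, c("S1", "S2"))
  lr <- resistance_from_crosses(cc, log_transform = TRUE)
  expect_equal(lr, log(res))
})
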