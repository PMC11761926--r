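test_that("critical value reduces to Student t for one comparison", {
  for (df in c(4, 10, 24, 60)) {
    expect_equal(dunnett_critical_value(1, df, 0.05),
                 qt(0.975, df), tolerance = 1e-3)
  }
})

test_that("critical value matches a seeded Monte-Carlo oracle", {
  # max|T_i| for balanced many-to-one comparisons: T_i = (Zi - Z0)/(sqrt(2) S)
  set.seed(20240915)
  B <- 1e6
  Z0 <- rnorm(B)
  S <- sqrt(rchisq(B, 24) / 24)
  mx <- abs(matrix(rnorm(B * 5), B, 5) - Z0) / (sqrt(2) * S)
  mx <- do.call(pmax, as.data.frame(mx))
  d <- dunnett_critical_value(5, 24, 0.05)
  cover <- mean(mx <= d)
  se <- sqrt(0.95 * 0.05 / B)
  expect_lt(abs(cover - 0.95), 2 * se)
})

test_that("critical value grows with the number of comparisons", {
  d2 <- dunnett_critical_value(2, 24)
  d5 <- dunnett_critical_value(5, 24)
  expect_gt(d5, d2)
  expect_gt(d2, qt(0.975, 24))
})

test_that("distribution function agrees with the multivariate-t integrator", {
  skip_if_not_installed("mvtnorm")
  lam <- rep(sqrt(0.5), 5)
  R <- outer(lam, lam)
  diag(R) <- 1
  for (d in c(1.5, 2.5, 3.2)) {
    p_own <- imcoh:::pdunnett(d, lam, 24)
    set.seed(1)
    p_ref <- as.numeric(mvtnorm::pmvt(
      lower = rep(-d, 5), upper = rep(d, 5), df = 24, corr = R,
      algorithm = mvtnorm::GenzBretz(abseps = 1e-6, maxpts = 500000)))
    expect_equal(p_own, p_ref, tolerance = 1e-5)
  }
  # unbalanced product-correlation case
  lam_u <- imcoh:::dunnett_loadings(c(3, 4, 5), 6)
  Ru <- outer(lam_u, lam_u)
  diag(Ru) <- 1
  set.seed(1)
  p_ref <- as.numeric(mvtnorm::pmvt(
    lower = rep(-2.2, 3), upper = rep(2.2, 3), df = 14, corr = Ru,
    algorithm = mvtnorm::GenzBretz(abseps = 1e-6, maxpts = 500000)))
  expect_equal(imcoh:::pdunnett(2.2, lam_u, 14), p_ref, tolerance = 1e-5)
})

test_that("balanced groups give equicorrelation exactly 0.5", {
  R <- imcoh:::dunnett_loadings(rep(5, 5), 5)
  expect_equal(outer(R, R)[1, 2], 0.5, tolerance = 1e-15)
  lam_u <- imcoh:::dunnett_loadings(c(4, 6), 8)
  expect_equal(lam_u[1] * lam_u[2],
               sqrt(4 * 6 / ((4 + 8) * (6 + 8))), tolerance = 1e-15)
})

test_that("many-to-one comparisons detect a large planted shift", {
  set.seed(81)
  cond <- rep(c("EOFT", "ECFT", "EOTanDB", "ECTanDB", "EOTanDF", "ECTanDF"),
              each = 5)
  v <- rnorm(30, sd = 0.02)
  sp <- 0.02
  v[cond == "ECTanDB"] <- v[cond == "ECTanDB"] + 10 * sp
  dn <- dunnett_many_to_one(v, cond, baseline = "EOFT")
  hit <- dn[dn$condition == "ECTanDB", ]
  expect_true(hit$significant)
  expect_gt(hit$ci_lo, 0)
  expect_false(any(dn$significant[dn$condition != "ECTanDB"]))
  expect_identical(nrow(dn), 5L)
  expect_identical(unique(dn$df), 24L)
})

test_that("degenerate all-identical inputs are flagged, never significant", {
  cond <- rep(c("EOFT", "A", "B"), each = 5)
  dn <- dunnett_many_to_one(rep(0.3, 15), cond, baseline = "EOFT")
  expect_true(all(dn$degenerate))
  expect_true(all(dn$diff == 0))
  expect_true(all(dn$ci_lo == 0 & dn$ci_hi == 0))
  expect_false(any(dn$significant))
  expect_true(all(is.na(dn$p_adj)))
})

test_that("input validation: missing baseline, tiny groups, bad ordering", {
  cond <- rep(c("EOFT", "A"), each = 3)
  v <- rnorm(6)
  expect_error(dunnett_many_to_one(v, cond, baseline = "ZZ"), "baseline")
  expect_error(dunnett_many_to_one(v[c(1, 4:6)], cond[c(1, 4:6)],
                                   baseline = "EOFT"),
               "at least 2")
  expect_error(dunnett_many_to_one(v, cond, baseline = "EOFT",
                                   condition_order = c("EOFT", "B")),
               "condition_order")
})

test_that("interval excludes zero exactly when adjusted p is below alpha", {
  set.seed(82)
  for (rep in 1:40) {
    k <- sample(2:5, 1)
    npg <- sample(3:6, 1)
    cond <- rep(c("base", paste0("c", seq_len(k))), each = npg)
    v <- rnorm(length(cond)) + rep(c(0, runif(k, -1, 1)), each = npg)
    dn <- dunnett_many_to_one(v, cond, baseline = "base")
    excl <- dn$ci_lo > 0 | dn$ci_hi < 0
    expect_identical(excl, dn$p_adj < dn$alpha)
    expect_identical(dn$significant, dn$p_adj < dn$alpha)
    expect_true(all(dn$ci_lo <= dn$diff & dn$diff <= dn$ci_hi))
  }
})

test_that("results agree with an independent general linear hypothesis solver", {
  skip_if_not_installed("multcomp")
  set.seed(83)
  cond <- factor(rep(c("EOFT", "ECFT", "EOTanDB", "ECTanDB"), each = 6),
                 levels = c("EOFT", "ECFT", "EOTanDB", "ECTanDB"))
  v <- rnorm(24, mean = rep(c(0, 0.1, 0.3, 0.05), each = 6), sd = 0.1)
  dn <- dunnett_many_to_one(v, as.character(cond), baseline = "EOFT",
                            condition_order = levels(cond))
  dat <- data.frame(v = v, cond = cond)
  fit <- stats::aov(v ~ cond, data = dat)
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(cond = "Dunnett"))
  ci <- stats::confint(gl)$confint
  expect_equal(dn$diff, unname(ci[, "Estimate"]), tolerance = 1e-10)
  # glht's quantile is itself quasi-Monte-Carlo; compare loosely
  expect_equal(dn$ci_lo, unname(ci[, "lwr"]), tolerance = 5e-3)
  expect_equal(dn$ci_hi, unname(ci[, "upr"]), tolerance = 5e-3)
  ps <- summary(gl)$test$pvalues
  expect_lt(max(abs(dn$p_adj - as.numeric(ps))), 2e-3)
})

test_that("familywise error under the global null is controlled at alpha", {
  # 2000 replicates of 6 balanced null groups; rejection happens iff
  # max|t| exceeds the package's simultaneous critical value
  set.seed(84)
  B <- 2000
  g <- 6
  npg <- 5
  crit <- dunnett_critical_value(g - 1, g * npg - g, 0.05)
  rejected <- logical(B)
  for (b in seq_len(B)) {
    m <- matrix(rnorm(g * npg), npg, g)
    means <- colMeans(m)
    sp2 <- sum((m - rep(means, each = npg))^2) / (g * npg - g)
    tt <- (means[-1] - means[1]) / sqrt(sp2 * (2 / npg))
    rejected[b] <- max(abs(tt)) > crit
  }
  expect_gte(mean(rejected), 0.03)
  expect_lte(mean(rejected), 0.07)

  # decision path of dunnett_many_to_one matches the vectorized rule
  set.seed(85)
  cond <- rep(c("base", paste0("c", 1:5)), each = npg)
  for (b in 1:100) {
    v <- rnorm(30)
    dn <- dunnett_many_to_one(v, cond, baseline = "base")
    m <- matrix(v, npg, g)
    means <- colMeans(m)
    sp2 <- sum((m - rep(means, each = npg))^2) / (g * npg - g)
    tt <- (means[-1] - means[1]) / sqrt(sp2 * (2 / npg))
    expect_identical(any(dn$significant), max(abs(tt)) > crit)
  }
})

test_that("simultaneous intervals jointly cover the null in ~95% of replicates", {
  set.seed(86)
  B <- 800
  npg <- 5
  cond <- rep(c("base", paste0("c", 1:5)), each = npg)
  crit <- dunnett_critical_value(5, 24, 0.05)
  cover <- vapply(seq_len(B), function(b) {
    m <- matrix(rnorm(30), npg, 6)
    means <- colMeans(m)
    sp2 <- sum((m - rep(means, each = npg))^2) / 24
    tt <- (means[-1] - means[1]) / sqrt(sp2 * (2 / npg))
    all(abs(tt) <= crit)
  }, logical(1))
  expect_gte(mean(cover), 0.95 - 0.01 - 2 * sqrt(0.05 * 0.95 / B))
})

test_that("assumption screens report standard statistics", {
  set.seed(87)
  cond <- rep(c("EOFT", "ECFT", "EOTanDB"), each = 8)
  v <- rnorm(24)
  sc <- assumption_screen(v, cond)
  expect_identical(nrow(sc$shapiro), 3L)
  expect_true(all(sc$shapiro$p >= 0 & sc$shapiro$p <= 1))
  expect_true(sc$levene$p >= 0 && sc$levene$p <= 1)
  expect_equal(sc$anova$df_between, 2)
  expect_equal(sc$anova$df_within, 21)

  # two-group ANOVA F equals the squared pooled t statistic
  cond2 <- rep(c("a", "b"), each = 10)
  v2 <- rnorm(20)
  sc2 <- assumption_screen(v2, cond2)
  tt <- t.test(v2 ~ cond2, var.equal = TRUE)
  expect_equal(sc2$anova$F, unname(tt$statistic)^2, tolerance = 1e-9)

  # no dispersion differences -> Levene statistic 0
  v3 <- rep(c(1, 2, 3, 1, 2, 3), each = 2)
  cond3 <- rep(c("a", "b"), each = 6)
  sc3 <- assumption_screen(v3, cond3)
  expect_equal(sc3$levene$statistic, 0, tolerance = 1e-12)
})

test_that("Shapiro p-values are uniform under Gaussian sampling", {
  set.seed(88)
  ps <- vapply(1:3000, function(i) stats::shapiro.test(rnorm(30))$p.value,
               numeric(1))
  ks <- max(abs(sort(ps) - (seq_along(ps) - 0.5) / length(ps)))
  expect_lt(ks, 0.05)
})

test_that("comparison bookkeeping: 5 many-to-one vs 15 all-pairs for 6 conditions", {
  cc <- comparison_counts(6)
  expect_identical(cc$many_to_one, 5L)
  expect_equal(cc$all_pairs, 15)
})
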