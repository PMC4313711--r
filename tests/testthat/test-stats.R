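test_that("SSCP matrices match a brute-force computation on tiny data", {
  d <- data.frame(g = rep(c("A", "B"), each = 3),
                  y1 = c(1, 2, 3, 5, 6, 7), y2 = c(2, 1, 3, 2, 4, 3))
  dec <- sscpDecompose(d, c("y1", "y2"), ~ g)
  Y <- as.matrix(d[, c("y1", "y2")])
  # brute force: between-group and within-group cross-products
  mA <- colMeans(Y[1:3, ]); mB <- colMeans(Y[4:6, ]); mm <- colMeans(Y)
  Hbf <- 3 * tcrossprod(mA - mm) + 3 * tcrossprod(mB - mm)
  Ebf <- crossprod(sweep(Y[1:3, ], 2, mA)) + crossprod(sweep(Y[4:6, ], 2, mB))
  expect_equal(unname(dec$H$g), unname(Hbf), tolerance = 1e-10)
  expect_equal(unname(dec$E), unname(Ebf), tolerance = 1e-10)
  expect_equal(dec$ve, 4)
  expect_equal(unname(dec$dfh["g"]), 1L)
})

test_that("duplicated responses make the error SSCP singular", {
  d <- data.frame(g = rep(c("A", "B"), each = 5), y = rnorm(10))
  d$y2 <- d$y
  expect_error(sscpDecompose(d, c("y", "y2"), ~ g), "singular|collinear")
})

test_that("empty design cells are reported by name", {
  d <- data.frame(g = c("A", "A", "B", "B"), a = c("x", "x", "x", "x"),
                  y = rnorm(4))
  d2 <- rbind(d, data.frame(g = "A", a = "y", y = 1))
  expect_error(sscpDecompose(d2, "y", ~ g * a), "empty design cell")
})

test_that("Rao df formulas reproduce the closed forms", {
  # s = 1 effects: df2 = ve - p + 1 exactly
  for (p in 1:6) for (ve in c(20, 100, 262, 270))
    expect_equal(raoDf(p, 1, ve)$df2Exact, ve - p + 1)
  # p = 1 reduces to the univariate test: df2 = ve
  for (dfh in 1:5) expect_equal(raoDf(1, dfh, 50)$df2Exact, 50)
})

test_that("Wilks lambda with p = 1 equals the univariate F test", {
  set.seed(1)
  d <- data.frame(g = rep(c("A", "B"), c(7, 9)),
                  ag = sample(c("u", "v"), 16, TRUE), y = rnorm(16))
  man <- cohortManova(d, "y", ~ g + ag)
  an <- factorialAnova(d, "y", ~ g + ag)
  expect_equal(man$F, an$effects$F, tolerance = 1e-10)
  expect_equal(man$p_value, an$effects$p_value, tolerance = 1e-10)
  # and a one-factor F equals the squared pooled two-sample t
  d1 <- data.frame(g = rep(c("A", "B"), c(6, 8)), y = rnorm(14, 0, 2))
  tt <- t.test(y ~ g, data = d1, var.equal = TRUE)
  an1 <- factorialAnova(d1, "y", ~ g)
  expect_equal(an1$effects$F, unname(tt$statistic)^2, tolerance = 1e-10)
})

test_that("identical cell values give zero F in a balanced factorial", {
  d <- expand.grid(g = c("A", "B"), a = c("x", "y"), rep = 1:4)
  d$y <- 5
  an <- factorialAnova(d, "y", ~ g * a)
  expect_true(all(an$effects$F == 0))
})

test_that("MANOVA and ANOVA agree with the car reference implementation", {
  set.seed(42)
  n <- 140
  d <- data.frame(ag = sample(c("8", "9-10", "11-12"), n, TRUE),
                  g = sample(c("CN", "US"), n, TRUE))
  d$y1 <- rnorm(n) + 0.6 * (d$g == "US")
  d$y2 <- rnorm(n) + 0.3 * as.numeric(factor(d$ag))
  d$y3 <- rnorm(n)
  man <- cohortManova(d, c("y1", "y2", "y3"), ~ ag * g)
  mod <- lm(cbind(y1, y2, y3) ~ ag * g, data = d,
            contrasts = list(ag = contr.sum, g = contr.sum))
  ref <- car::Manova(mod, type = 3, test.statistic = "Wilks")
  s <- summary(ref, multivariate = TRUE)
  for (eff in c("ag", "g", "ag:g")) {
    mt <- s$multivariate.tests[[eff]]
    lamRef <- Re(prod(1 / (1 + eigen(solve(mt$SSPE, mt$SSPH))$values)))
    expect_equal(man$lambda[man$effect == eff], lamRef, tolerance = 1e-8)
  }
  anv <- factorialAnova(d, "y1", ~ ag * g)
  refA <- car::Anova(lm(y1 ~ ag * g, data = d,
                        contrasts = list(ag = contr.sum, g = contr.sum)),
                     type = 3)
  expect_equal(anv$effects$F,
               refA$`F value`[match(anv$effects$effect, rownames(refA))],
               tolerance = 1e-8)
})

test_that("lambda is invariant under nonsingular response transforms", {
  set.seed(6)
  n <- 60
  d <- data.frame(g = sample(c("A", "B"), n, TRUE))
  Y <- matrix(rnorm(3 * n), n, 3); Y[d$g == "B", 1] <- Y[d$g == "B", 1] + 1
  d[c("y1", "y2", "y3")] <- as.data.frame(Y)
  base <- cohortManova(d, c("y1", "y2", "y3"), ~ g)
  for (seed in 1:3) {
    set.seed(seed + 100)
    A <- matrix(rnorm(9), 3, 3)
    while (abs(det(A)) < 0.1) A <- matrix(rnorm(9), 3, 3)
    d2 <- d
    d2[c("y1", "y2", "y3")] <- as.data.frame(Y %*% A)
    tr <- cohortManova(d2, c("y1", "y2", "y3"), ~ g)
    expect_equal(tr$lambda, base$lambda, tolerance = 1e-8)
  }
})

test_that("one-way ANOVA power matches the noncentral-F closed form", {
  nPer <- 50; delta <- 1; reps <- 500
  crit <- qf(0.95, 1, 2 * nPer - 2)
  power <- 1 - pf(crit, 1, 2 * nPer - 2, ncp = nPer * delta^2 / 2)
  set.seed(77)
  rej <- mean(replicate(reps, {
    d <- data.frame(g = rep(c("A", "B"), each = nPer),
                    y = rnorm(2 * nPer) + rep(c(0, delta), each = nPer))
    factorialAnova(d, "y", ~ g)$effects$p_value < 0.05
  }))
  expect_lt(abs(rej - power), 1.96 * sqrt(power * (1 - power) / reps) + 0.01)
})

test_that("quadratic peak fitting recovers noise-free vertices", {
  age <- rep(seq(8, 16, by = 0.5), 2)
  co <- data.frame(age = age, group = "A", y = 100 - 2 * (age - 13)^2)
  fit <- fitPeakTrajectory(co, "y", "A", nBoot = 50, seed = 1)
  expect_equal(fit$shape, "inverted-U")
  expect_equal(fit$peakAge, 13, tolerance = 1e-8)
  expect_lt(fit$b2, 0)
  # noise-free linear data: no peak is reported
  co$y <- 10 + 2 * age
  fitLin <- fitPeakTrajectory(co, "y", "A", nBoot = 0)
  expect_equal(fitLin$shape, "linear-ish")
  expect_true(is.na(fitLin$peakAge))
  expect_error(fitPeakTrajectory(data.frame(age = c(8, 8, 12), group = "A",
                                            y = 1:3), "y", "A"),
               "distinct ages")
})

test_that("group peak ages are recovered from simulated cohorts", {
  m <- growthModel(list(
    vol = list(kind = "quadratic", peakValue = 100, peakAge = 13,
               curvature = 1.5, groupPeakAge = c(A = 0, B = -2),
               residualSd = 5)), groups = c("A", "B"))
  nt <- data.frame(group = rep(c("A", "B"), each = 9), age = rep(8:16, 2),
                   n = rep(5, 18))   # 45 per group over the full age span
  co <- simulateCohort(m, nt, seed = 20)$cohort
  fa <- fitPeakTrajectory(co, "vol", "A", nBoot = 500, seed = 2)
  fb <- fitPeakTrajectory(co, "vol", "B", nBoot = 500, seed = 3)
  expect_true(fa$ci[1] <= 13 && 13 <= fa$ci[2])
  expect_true(fb$ci[1] <= 11 && 11 <= fb$ci[2])
  cmp <- comparePeakAges(co, "vol", c("A", "B"), nBoot = 500, seed = 4)
  expect_true(cmp$diffCi[1] > 0)   # A peaks later; difference excludes 0
})
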