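test_that("a 2-level within factor reproduces the paired t-squared identity", {
  set.seed(22)
  for (i in 1:10) {
    n <- sample(5:12, 1)
    Y <- matrix(rnorm(2 * n, sd = 2), n)
    tab <- rmAnova(Y, list(A = c("a1", "a2")))
    tt <- t.test(Y[, 1], Y[, 2], paired = TRUE)
    expect_equal(tab$F, unname(tt$statistic)^2, tolerance = 1e-8)
    expect_equal(tab$p, tt$p.value, tolerance = 1e-8)
    expect_equal(tab$epsilon, 1)
  }
})

test_that("SS, F, GG epsilon, and corrected p match the mlm route on a 2-factor design", {
  set.seed(24)
  n <- 8; A <- 3; B <- 4
  Y <- matrix(rnorm(n * A * B), n) + matrix(rep(rnorm(A * B), each = n), n)
  factors <- list(A = paste0("a", 1:A), B = paste0("b", 1:B))
  tab <- rmAnova(Y, factors)
  idata <- expand.grid(A = factor(paste0("a", 1:A)),
                       B = factor(paste0("b", 1:B)))
  av <- suppressWarnings( # car warns about HF epsilon > 1, not used here
    summary(car::Anova(lm(Y ~ 1), idata = idata, idesign = ~A * B,
                       type = 3), multivariate = FALSE))
  uni <- av$univariate.tests
  adj <- av$pval.adjustments
  for (eff in c("A", "B", "A:B")) {
    row <- tab[tab$effect == eff, ]
    expect_equal(row$ss, uni[eff, "Sum Sq"], tolerance = 1e-8)
    expect_equal(row$errorSs, uni[eff, "Error SS"], tolerance = 1e-8)
    expect_equal(row$F, uni[eff, "F value"], tolerance = 1e-8)
    expect_equal(row$epsilon, adj[eff, "GG eps"], tolerance = 1e-8)
    expect_equal(row$p, adj[eff, "Pr(>F[GG])"], tolerance = 1e-8)
  }
})

test_that("effect and error SS decompose the total within-subject SS", {
  set.seed(26)
  n <- 6
  factors <- list(A = letters[1:3], B = letters[1:2], C = letters[1:4])
  p <- prod(lengths(factors))
  Y <- matrix(rnorm(n * p), n)
  tab <- rmAnova(Y, factors)
  # total within-subject SS: deviations from subject means
  ssWithin <- sum((Y - rowMeans(Y))^2)
  expect_equal(sum(tab$ss) + sum(tab$errorSs), ssWithin,
               tolerance = 1e-8 * ssWithin)
})

test_that("GG epsilon is bounded and equals 1 under compound symmetry", {
  set.seed(28)
  k <- 5; n <- 200
  # compound-symmetric covariance: equal variances, equal correlations
  Sigma <- 0.5 * diag(k) + 0.5
  L <- chol(Sigma)
  Y <- matrix(rnorm(n * k), n) %*% L
  tab <- rmAnova(Y, list(A = letters[1:k]))
  expect_gt(tab$epsilon, 0.9) # sample estimate near the theoretical 1
  for (i in 1:10) {
    Yr <- matrix(rnorm(8 * k), 8) %*% diag(c(5, 2, 1, 0.5, 0.1))
    e <- rmAnova(Yr, list(A = letters[1:k]))$epsilon
    expect_gte(e, 1 / (k - 1))
    expect_lte(e, 1)
  }
})

test_that("constant responses yield zero effect SS", {
  Y <- matrix(0.7, 5, 6)
  tab <- rmAnova(Y, list(A = letters[1:3], B = letters[1:2]))
  expect_equal(tab$ss, rep(0, 3), tolerance = 1e-12)
  expect_true(all(is.na(tab$F)))
})

test_that("one-way simple effects agree with the full ANOVA when others are collapsed", {
  set.seed(30)
  n <- 7
  factors <- list(A = letters[1:3], B = "b1")
  Y <- matrix(rnorm(n * 3), n)
  full <- rmAnova(Y, factors["A"])
  simple <- rmAnova1way(Y, factors, "A")
  expect_equal(simple$F, full$F, tolerance = 1e-10)
  expect_equal(simple$p, full$p, tolerance = 1e-10)
  # fixing a factor level picks out the right sub-design
  factors2 <- list(A = letters[1:3], B = c("b1", "b2"))
  Y2 <- matrix(rnorm(n * 6), n)
  atB1 <- rmAnova1way(Y2, factors2, "A", at = list(B = "b1"))
  oracle <- rmAnova(Y2[, 1:3], list(A = letters[1:3]))
  expect_equal(atB1$F, oracle$F, tolerance = 1e-10)
  expect_match(atB1$effect, "at B=b1")
})

test_that("three-condition five-subject dataset matches the longhand computation", {
  # fixed small repeated-measures dataset, worked with the classical formulas
  Y <- matrix(c(30, 28, 16,
                14, 18, 10,
                24, 20, 18,
                38, 34, 20,
                26, 28, 14), 5, 3, byrow = TRUE)
  tab <- rmAnova(Y, list(cond = c("c1", "c2", "c3")))
  n <- 5; k <- 3
  grand <- mean(Y)
  ssCond <- n * sum((colMeans(Y) - grand)^2)
  ssSubj <- k * sum((rowMeans(Y) - grand)^2)
  ssTot <- sum((Y - grand)^2)
  ssErr <- ssTot - ssCond - ssSubj
  Fhand <- (ssCond / (k - 1)) / (ssErr / ((k - 1) * (n - 1)))
  expect_equal(tab$ss, ssCond, tolerance = 1e-10)
  expect_equal(tab$errorSs, ssErr, tolerance = 1e-10)
  expect_equal(tab$F, Fhand, tolerance = 1e-10)
  # classical Greenhouse-Geisser epsilon from the sample covariance
  S <- stats::cov(Y)
  dbar <- mean(diag(S)); sbar <- mean(S)
  rowbar <- rowMeans(S)
  num <- (k * (dbar - sbar))^2
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(rowbar^2) + k^2 * sbar^2)
  expect_equal(tab$epsilon, max(min(num / den, 1), 1 / (k - 1)),
               tolerance = 1e-10)
})

test_that("Bonferroni post hoc scales raw p-values by the comparison count", {
  set.seed(32)
  n <- 9
  factors <- list(Classifier = paste0("k", 1:6))
  Y <- matrix(rnorm(n * 6), n)
  ph <- posthocBonferroni(Y, factors, "Classifier")
  expect_identical(nrow(ph), 15L)
  expect_equal(ph$pAdjusted, pmin(1, ph$pRaw * 15), tolerance = 1e-12)
  # k = 2: adjusted equals raw
  ph2 <- posthocBonferroni(Y[, 1:2], list(A = c("a", "b")), "A")
  expect_equal(ph2$pAdjusted, ph2$pRaw, tolerance = 1e-12)
  # identical level means: nothing significant
  Yc <- matrix(rep(rnorm(n), 4), n)
  ph3 <- posthocBonferroni(Yc, list(A = letters[1:4]), "A")
  expect_false(any(ph3$significant))
})

test_that("estimated marginal means honor equivariance and marginality", {
  set.seed(34)
  n <- 6
  factors <- list(A = letters[1:3], B = letters[1:2])
  Y <- matrix(rnorm(n * 6), n)
  emmA <- estimatedMarginalMeans(Y, factors, "A")
  # single factor, single subject: level means equal raw means
  emm1 <- estimatedMarginalMeans(Y[1, , drop = FALSE], factors, "A")
  cells <- expand.grid(A = factors$A, B = factors$B)
  for (lv in factors$A)
    expect_equal(emm1$emm[emm1$A == lv], mean(Y[1, cells$A == lv]),
                 tolerance = 1e-12)
  # adding a constant shifts every EMM by that constant
  emmShift <- estimatedMarginalMeans(Y + 2.5, factors, "A")
  expect_equal(emmShift$emm, emmA$emm + 2.5, tolerance = 1e-12)
  # a factor's EMM equals the mean of its two-way EMMs over the other factor
  emmAB <- estimatedMarginalMeans(Y, factors, c("A", "B"))
  for (lv in factors$A)
    expect_equal(emmA$emm[emmA$A == lv],
                 mean(emmAB$emm[emmAB$A == lv]), tolerance = 1e-12)
})

test_that("the formatted table renders tiny p-values as <0.001", {
  tab <- data.frame(effect = "A", ss = 1, df = 2, epsilon = 0.9,
                    dfCorrected = 1.8, ms = 0.55, errorSs = 0.1,
                    errorDf = 10, errorDfCorrected = 9, errorMs = 0.01,
                    F = 50, p = 0.0002, partialEtaSq = 0.9)
  out <- formatAnovaTable(tab)
  expect_identical(out$P.value, "<0.001")
})

test_that("GG-corrected type-I error stays at or below nominal under the global null", {
  factors <- list(Freq = paste0("f", 1:5), SF = paste0("s", 1:5),
                  Classifier = paste0("k", 1:6))
  set.seed(36)
  nRep <- 2000
  rates <- NULL
  for (r in seq_len(nRep)) {
    Y <- matrix(rnorm(9 * 150), 9)
    tab <- rmAnova(Y, factors)
    if (is.null(rates)) rates <- setNames(numeric(nrow(tab)), tab$effect)
    rates <- rates + (tab$p < 0.01)
  }
  rates <- rates / nRep
  for (eff in names(rates)) expect_lte(rates[[eff]], 0.015)
})
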