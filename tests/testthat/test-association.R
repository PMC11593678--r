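makePooled <- function(values, ids = sprintf("s%02d", seq_along(values))) {
  m <- matrix(values, 1, length(values), dimnames = list("FOLR1", ids))
  PooledCohort(m, dataset = rep("c1", length(values)),
               reference = rep(TRUE, length(values)))
}

test_that("median split dichotomizes at the series median with ties low", {
  sp <- medianSplit(makePooled(c(1, 2, 3, 4)), "FOLR1")
  expect_equal(sp$rule@cutoff, 2.5)
  expect_equal(as.character(sp$labels),
               c("low", "low", "high", "high"))

  # odd n: the median itself is a tie -> low
  sp2 <- medianSplit(makePooled(c(1, 2, 3)), "FOLR1")
  expect_equal(sp2$rule@cutoff, 2)
  expect_equal(as.character(sp2$labels), c("low", "low", "high"))
  expect_equal(sp2$rule@tiePolicy, "ties_low")

  expect_error(medianSplit(makePooled(rep(1, 4)), "FOLR1"), "degenerate")
  expect_error(medianSplit(makePooled(1:4), "TP53"), "not found")
})

test_that("median split recovers the simulator's true anchor class", {
  sim <- tinySim(seed = 21, anchorNoiseSd = 0.05, samplesPerCohort = 300,
                 nGenes = 60, nModuleGenes = 6)
  tum <- tumorIdsOf(sim)
  pooled <- standardizeAndPool(sim$cohorts, tum)
  labels <- medianSplit(pooled, "FOLR1")$labels[tum]
  agree <- mean(as.character(labels) == sim$truth$anchorClass[tum])
  expect_gte(agree, 0.95)
})

test_that("odds ratios reproduce the published contingency tables", {
  # serous histology vs FOLR1 class
  serous <- oddsRatio2x2(480, 24, 449, 55)
  expect_equal(round(oddsRatio(serous), 2), 2.45)
  expect_lt(pValue(serous), 0.001)
  # advanced FIGO stage
  expect_equal(round(oddsRatio(oddsRatio2x2(615, 62, 580, 100)), 2), 1.71)
  # high grade
  expect_equal(round(oddsRatio(oddsRatio2x2(548, 149, 493, 194)), 2), 1.45)
})

test_that("odds ratio symmetries and degenerate cells", {
  sym <- oddsRatio2x2(10, 10, 10, 10)
  expect_equal(oddsRatio(sym), 1)
  expect_equal(pValue(sym), 1)

  a <- 12; b <- 5; cc <- 7; d <- 21
  or1 <- oddsRatio2x2(a, b, cc, d)
  # transposing rows and columns together leaves the OR unchanged
  expect_equal(oddsRatio(oddsRatio2x2(a, cc, b, d)), oddsRatio(or1))
  # swapping one margin inverts it
  expect_equal(oddsRatio(oddsRatio2x2(b, a, d, cc)), 1 / oddsRatio(or1))
  # CI contains the point estimate
  expect_true(confInt(or1)[["low"]] <= oddsRatio(or1))
  expect_true(confInt(or1)[["high"]] >= oddsRatio(or1))

  zero <- oddsRatio2x2(0, 5, 3, 7)
  expect_true(zero@corrected)
  expect_equal(oddsRatio(zero), (0.5 * 7.5) / (5.5 * 3.5))
  expect_error(oddsRatio2x2(-1, 2, 3, 4), "non-negative")
  expect_error(oddsRatio2x2(1.5, 2, 3, 4), "non-negative")
})

test_that("Fisher p equals hypergeometric enumeration on small tables", {
  # exhaustive over all tables with margins <= 8
  for (a in 0:8) for (b in 0:(8 - a)) for (cc in 0:8) for (d in 0:(8 - cc)) {
    if (a + cc > 8 || b + d > 8) next
    if ((a + b) == 0 || (cc + d) == 0) next
    expect_equal(pValue(oddsRatio2x2(a, b, cc, d)),
                 oracleFisherP(a, b, cc, d), tolerance = 1e-10)
  }
  # random tables with margins up to 30
  set.seed(10)
  for (i in 1:200) {
    a <- sample(0:15, 1); b <- sample(0:15, 1)
    cc <- sample(0:15, 1); d <- sample(0:15, 1)
    if ((a + b) == 0 || (cc + d) == 0) next
    expect_equal(pValue(oddsRatio2x2(a, b, cc, d)),
                 oracleFisherP(a, b, cc, d), tolerance = 1e-10)
  }
})

test_that("Fisher test holds its size under the simulator's null covariate", {
  set.seed(12)
  n <- 200
  rejections <- replicate(2000, {
    cls <- rep(c(TRUE, FALSE), each = n / 2)
    x <- rbinom(n, 1, 0.5)   # covariate odds ratio 1 vs class
    tab <- table(factor(x, 0:1), cls)
    fisher.test(tab)$p.value < 0.05
  })
  expect_lte(mean(rejections), 0.06)
})

test_that("two-group t-test behaves at its boundaries", {
  same <- twoGroupTTest(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  expect_error(twoGroupTTest(c(0, 0, 1, 1), rep(c("a", "b"), each = 2)),
               "degenerate")
  expect_error(twoGroupTTest(1:3, c("a", "a", "b")), ">= 2 samples")
  # Welch power on shifted Gaussians approximates the Monte-Carlo rate
  set.seed(14)
  n <- 200
  rej <- replicate(500, {
    x <- rnorm(n); y <- rnorm(n, 1)
    t.test(x, y)$p.value < 0.05
  })
  got <- replicate(200, {
    vals <- c(rnorm(n), rnorm(n, 1))
    twoGroupTTest(vals, rep(c("a", "b"), each = n))$p.value < 0.05
  })
  expect_lt(abs(mean(got) - mean(rej)), 0.05)
})

test_that("one-way ANOVA guards its preconditions", {
  set.seed(15)
  vals <- rnorm(30)
  g3 <- rep(c("a", "b", "c"), each = 10)
  out <- anovaOneway(vals, g3)
  expect_true(out$p.value > 0 && out$p.value <= 1)
  expect_error(anovaOneway(vals, rep(c("a", "b"), 15)), "twoGroupTTest")
  expect_error(anovaOneway(rep(1, 30), g3), "zero within-group variance")
  # null calibration: uniform p-values
  ps <- replicate(400, anovaOneway(rnorm(30), g3)$p.value)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.04)
})

test_that("Pearson correlation matches the covariance formula", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearsonCorrelation(x, x)$r, 1)
  expect_equal(pearsonCorrelation(x, -x)$r, -1)
  expect_error(pearsonCorrelation(x, rep(1, 4)), "constant")
  expect_error(pearsonCorrelation(1:3, 1:4), "unequal")
  set.seed(16)
  a <- rnorm(50); b <- 0.5 * a + rnorm(50)
  direct <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearsonCorrelation(a, b)$r, direct, tolerance = 1e-12)
})

test_that("association table reports counts, ORs and per-variable p-values", {
  set.seed(18)
  n <- 300
  clinical <- data.frame(
    sample_id = sprintf("s%03d", 1:n),
    age = rnorm(n, 60, 10),
    serous = rbinom(n, 1, 0.9),
    subtype = sample(c("diff", "immuno", "mesen", "prolif"), n, TRUE))
  labels <- setNames(factor(rep(c("low", "high"), each = n / 2),
                            levels = c("low", "high")),
                     clinical$sample_id)
  tab <- associationTable(labels, clinical, c("age", "serous", "subtype"))
  expect_setequal(unique(tab$variable), c("age", "serous", "subtype"))
  expect_equal(tab$level[tab$variable == "age"], "(continuous)")
  sub <- tab[tab$variable == "subtype", ]
  expect_equal(nrow(sub), 4)
  expect_equal(sum(sub$n), n)
  expect_equal(sum(!is.na(sub$p_value)), 1)   # one overall p
  # the binary OR agrees with the direct 2x2 computation
  s <- tab[tab$variable == "serous" & tab$level == "1", ]
  a <- sum(clinical$serous == 1 & labels == "high")
  b <- sum(clinical$serous == 0 & labels == "high")
  cc <- sum(clinical$serous == 1 & labels == "low")
  d <- sum(clinical$serous == 0 & labels == "low")
  expect_equal(s$odds_ratio, (a * d) / (b * cc))
})
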