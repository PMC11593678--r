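test_that("Kaplan-Meier estimator matches closed forms", {
  # no events: flat survival, undefined median
  km <- kmEstimate(c(5, 10, 15), c(0, 0, 0))
  expect_true(all(km$surv == 1))
  expect_true(is.na(km$median))

  # all events, no censoring: empirical survival function
  km2 <- kmEstimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km2$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km2$median, 2)

  expect_error(kmEstimate(c(0, 1), c(1, 1)), "positive")
  expect_error(kmEstimate(c(1, 2), c(1, 2)), "0/1")
})

test_that("Kaplan-Meier equals the product-limit oracle under censoring", {
  set.seed(52)
  time <- round(rexp(80, 0.05), 1) + 0.1
  event <- rbinom(80, 1, 0.7)
  km <- kmEstimate(time, event)
  ora <- oracleKM(time, event)
  atEvents <- km$surv[match(ora$time, km$time)]
  expect_equal(atEvents, ora$surv, tolerance = 1e-12)

  # KM with no censoring is the empirical survival function
  km2 <- kmEstimate(time, rep(1, 80))
  emp <- vapply(km2$time, function(t) mean(time > t), numeric(1))
  expect_equal(km2$surv, emp, tolerance = 1e-12)
})

test_that("five-year style rates carry Greenwood confidence intervals", {
  set.seed(54)
  time <- rexp(300, 0.015)
  km <- kmEstimate(time, rep(1, 300), rateTimes = 60)
  r <- km$rates
  expect_equal(nrow(r), 1)
  expect_true(r$lower < r$surv && r$surv < r$upper)
  expect_lt(abs(r$surv - exp(-0.015 * 60)), 0.1)
})

test_that("log-rank statistic is zero on duplicated groups", {
  time <- c(3, 5, 8, 12, 20)
  event <- c(1, 0, 1, 1, 0)
  lr <- logrankTest(c(time, time), c(event, event),
                    rep(c("a", "b"), each = 5))
  expect_equal(lr$chisq, 0, tolerance = 1e-12)
  expect_equal(lr$p.value, 1)
})

test_that("log-rank matches the manual O-E computation on a toy example", {
  # six subjects, two groups
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(1, 1, 1, 1, 0, 1)
  group <- c("a", "b", "a", "b", "a", "b")
  lr <- logrankTest(time, event, group)
  expect_equal(lr$chisq, oracleLogrank(time, event, group),
               tolerance = 1e-10)
  # symmetric under relabeling
  swapped <- ifelse(group == "a", "b", "a")
  expect_equal(logrankTest(time, event, swapped)$chisq, lr$chisq)

  expect_error(logrankTest(time, event, rep("a", 6)), "2 non-empty")
  expect_error(logrankTest(time, rep(0, 6), group), "no events")
})

test_that("log-rank detects the planted hazard ratio with high power", {
  set.seed(56)
  rejected <- replicate(30, {
    n <- 750
    cls <- rep(c("high", "low"), each = n)
    t <- c(rexp(n, 0.02 * 0.71), rexp(n, 0.02))
    cens <- rexp(2 * n, 0.008)
    lr <- logrankTest(pmin(t, cens), as.integer(t <= cens), cls)
    lr$p.value < 0.05
  })
  expect_gte(mean(rejected), 0.8)
})

test_that("Cox regression recovers a planted hazard ratio", {
  set.seed(58)
  n <- 1500
  cls <- rep(c(1, 0), each = n / 2)
  t <- rexp(n, 0.02 * 0.71^cls)
  cens <- rexp(n, 0.008)
  recs <- data.frame(time = pmin(t, cens), event = as.integer(t <= cens),
                     class = factor(ifelse(cls == 1, "high", "low"),
                                    levels = c("low", "high")))
  fit <- coxFit(recs, "class")
  expect_lt(abs(fit$table$hr - 0.71) / 0.71, 0.10)
  expect_true(fit$table$ci_low < 0.71 && 0.71 < fit$table$ci_high)
  expect_equal(fit$nEvents, sum(recs$event))
})

test_that("Cox null calibration: CI covers 1 at roughly the nominal rate", {
  set.seed(60)
  covered <- replicate(100, {
    n <- 150
    recs <- data.frame(time = rexp(n, 0.03),
                       event = rbinom(n, 1, 0.8),
                       x = rbinom(n, 1, 0.5))
    f <- coxFit(recs, "x")
    f$table$ci_low <= 1 && 1 <= f$table$ci_high
  })
  expect_gte(mean(covered), 0.88)
})

test_that("Cox degenerate inputs raise errors", {
  set.seed(62)
  recs <- data.frame(time = rexp(40, 0.05), event = rbinom(40, 1, 0.8),
                     x = rbinom(40, 1, 0.5))
  recs$y <- recs$x   # identical columns -> collinear
  expect_error(coxFit(recs, c("x", "y")), "collinear|singular|converge")
  # perfectly separated covariate: events only when z = 0
  recs$z <- as.integer(recs$event == 0)
  expect_error(coxFit(recs, "z"),
               "separated|monotone|infinite|converge")
  few <- data.frame(time = c(2, 4, 6, 8, 10, 12, 14, 16),
                    event = c(1, 1, 1, 0, 0, 0, 0, 0),
                    x = c(1, 0, 1, 0, 1, 0, 1, 0))
  expect_warning(coxFit(few, "x"), "events")
})

test_that("Cox interaction terms are supported", {
  set.seed(64)
  n <- 400
  sub <- factor(sample(c("s1", "s2"), n, TRUE))
  x <- rbinom(n, 1, 0.5)
  haz <- 0.02 * ifelse(sub == "s1", 0.5, 1.5)^x
  t <- rexp(n, haz)
  recs <- data.frame(time = t, event = 1, x = x, sub = sub)
  fit <- coxFit(recs, c("x", "sub"), interactions = "x:sub")
  expect_true(any(grepl(":", fit$table$term)))
  expect_equal(nrow(fit$table), 3)
})

test_that("time-stratified hazard ratios are constant when the effect is", {
  set.seed(66)
  n <- 3000
  cls <- rep(c(1, 0), each = n / 2)
  t <- rexp(n, 0.03 * 0.6^cls)
  cens <- rexp(n, 0.01)
  recs <- data.frame(time = pmin(t, cens), event = as.integer(t <= cens),
                     class = cls)
  out <- coxTimeStratified(recs, "class", cutpoints = c(6, 12))
  expect_equal(nrow(out), 3)
  expect_true(all(is.finite(out$hr)))
  # interval estimates agree with each other (time-constant truth)
  expect_lt(max(out$hr) / min(out$hr), 1.6)
  expect_lt(abs(mean(log(out$hr)) - log(0.6)), 0.3)
})

test_that("time stratification handles empty intervals and bad cutpoints", {
  recs <- data.frame(time = c(8, 9, 14, 20), event = c(1, 1, 1, 0),
                     class = c(1, 0, 1, 0))
  out <- coxTimeStratified(recs, "class", cutpoints = c(6, 12))
  expect_true(is.na(out$hr[out$interval == "(0,6]"]))  # no events before 6
  expect_error(coxTimeStratified(recs, "class", cutpoints = c(12, 6)),
               "increasing")
})

test_that("multivariate screen retains univariately significant covariates", {
  set.seed(68)
  n <- 600
  sig <- rbinom(n, 1, 0.5)
  noise <- rbinom(n, 1, 0.5)
  t <- rexp(n, 0.03 * 0.5^sig)
  recs <- data.frame(time = t, event = 1, sig = sig, noise = noise)
  out <- multivariateScreen(recs, c("sig", "noise"))
  expect_true("sig" %in% out$retained)
  hrSig <- out$multivariate$table$hr[out$multivariate$table$term == "sig"]
  expect_lt(abs(hrSig - 0.5) / 0.5, 0.2)

  # single passing candidate: multivariate equals univariate
  out2 <- multivariateScreen(recs, "sig")
  expect_equal(out2$multivariate$table$hr, out2$univariate$sig$table$hr)

  # all-null input: multivariate usually skipped
  set.seed(70)
  empties <- replicate(20, {
    r <- data.frame(time = rexp(100, 0.03), event = 1,
                    a = rbinom(100, 1, 0.5), b = rbinom(100, 1, 0.5))
    res <- suppressMessages(multivariateScreen(r, c("a", "b")))
    is.null(res$multivariate)
  })
  expect_gte(mean(empties), 0.7)
})

test_that("survival records are assembled and validated from clinical data", {
  sim <- tinySim(seed = 72, nGenes = 20, nModuleGenes = 2, nNormal = 5)
  recs <- survivalRecords(sim$clinical, "OS", covariates = "serous")
  expect_true(all(recs$time > 0))
  expect_true(all(recs$event %in% c(0, 1)))
  # normals (NA survival) are dropped
  expect_false(any(grepl("^N", recs$sample_id)))
  recsP <- survivalRecords(sim$clinical, "PFS")
  expect_true(all(recsP$sample_id %in% tumorIdsOf(sim)))
  bad <- sim$clinical
  bad$os_time[1] <- -1
  expect_error(survivalRecords(bad, "OS"), "nonpositive")
})
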