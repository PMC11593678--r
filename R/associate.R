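#' Dichotomize a gene at the pooled-series median
#'
#' Splits samples into `"high"` / `"low"` using the median expression of
#' `geneId` over the pooled tumor reference series as cutoff. A sample is
#' `"high"` iff its expression is strictly above the cutoff; samples at or
#' below the cutoff (ties included) are `"low"`.
#'
#' @param pooled a [PooledCohort-class].
#' @param geneId gene to split on (e.g. `"FOLR1"`).
#' @param samples optional sample ids to label (default: all samples; the
#'   cutoff is always computed over the reference population).
#' @return list with `labels` (named factor, levels `low`, `high`) and
#'   `rule` (a [DiscretizationRule-class]).
#' @examples
#' \donttest{
#' sim <- simulateCohorts(simConfig(nCohorts = 2, samplesPerCohort = 40,
#'                                  nGenes = 200, nModuleGenes = 20, seed = 3))
#' tum <- sim$clinical$sample_id[sim$clinical$sample_type == "tumor"]
#' pooled <- standardizeAndPool(sim$cohorts, tum)
#' split <- medianSplit(pooled, "FOLR1")
#' table(split$labels)
#' }
#' @export
medianSplit <- function(pooled, geneId, samples = colnames(pooled)) {
  stopifnot(is(pooled, "PooledCohort"))
  m <- assayMatrix(pooled)
  if (!geneId %in% rownames(m))
    stop(sprintf("gene '%s' not found in pooled matrix", geneId))
  refVals <- m[geneId, referenceSamples(pooled)]
  if (length(unique(refVals)) == 1L)
    stop("degenerate split: all reference expression values are equal")
  cutoff <- median(refVals)
  vals <- m[geneId, samples]
  labels <- factor(ifelse(vals > cutoff, "high", "low"),
                   levels = c("low", "high"))
  names(labels) <- samples
  list(labels = labels,
       rule = new("DiscretizationRule", geneId = geneId, cutoff = cutoff,
                  tiePolicy = "ties_low"))
}

#' Odds ratio with Woolf confidence interval and Fisher exact p
#'
#' For the 2x2 table
#' \preformatted{            feature+  feature-
#'   class high     a         b
#'   class low      c         d}
#' the odds ratio is `(a*d)/(b*c)` (odds of the feature in the high class
#' versus the low class), with a 95% Woolf log-method interval
#' `exp(log(OR) +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))` and a two-sided
#' Fisher exact p-value. Any zero cell triggers the Haldane-Anscombe +0.5
#' correction for the OR and CI (flagged in the result); the exact p is
#' unaffected.
#'
#' @param a,b,c,d non-negative integer counts.
#' @return a [ContingencyResult-class].
#' @examples
#' oddsRatio2x2(480, 24, 449, 55)  # OR = 2.45
#' @export
oddsRatio2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("oddsRatio2x2: counts must be non-negative integers")
  tab <- matrix(as.integer(cells[c("a", "b", "c", "d")]), nrow = 2L,
                byrow = TRUE,
                dimnames = list(class = c("high", "low"),
                                feature = c("pos", "neg")))
  corrected <- any(cells == 0)
  w <- if (corrected) cells + 0.5 else cells
  or <- (w[["a"]] * w[["d"]]) / (w[["b"]] * w[["c"]])
  se <- sqrt(sum(1 / w))
  ci <- exp(log(or) + c(-1, 1) * qnorm(0.975) * se)
  p <- fisher.test(tab)$p.value
  new("ContingencyResult", table = tab, oddsRatio = or,
      ciLow = ci[1], ciHigh = ci[2], pValue = p, method = "fisher",
      corrected = corrected)
}

#' Welch two-group t-test
#'
#' @param values numeric vector.
#' @param labels two-level factor/vector of the same length.
#' @param varEqual pool variances instead of the Welch default?
#' @return list with `statistic`, `p.value`, `df`, `estimate` (group-mean
#'   difference).
#' @export
twoGroupTTest <- function(values, labels, varEqual = FALSE) {
  labels <- factor(labels)
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]; labels <- droplevels(labels[keep])
  if (nlevels(labels) != 2L)
    stop("twoGroupTTest: exactly two groups required")
  ns <- table(labels)
  if (any(ns < 2L)) stop("twoGroupTTest: each group needs >= 2 samples")
  vs <- tapply(values, labels, var)
  if (all(vs == 0)) stop("twoGroupTTest: degenerate groups (zero variance)")
  ht <- t.test(values ~ labels, var.equal = varEqual)
  list(statistic = unname(ht$statistic), p.value = ht$p.value,
       df = unname(ht$parameter), estimate = unname(diff(rev(ht$estimate))))
}

#' Classical one-way ANOVA F-test
#'
#' For variables with three or more groups; with two groups the caller is
#' pointed at [twoGroupTTest()].
#'
#' @param values numeric vector.
#' @param labels grouping vector with `k >= 3` levels, each with >= 2
#'   observations.
#' @return list with `statistic` (F), `p.value`, `df`.
#' @export
anovaOneway <- function(values, labels) {
  labels <- factor(labels)
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]; labels <- droplevels(labels[keep])
  if (nlevels(labels) < 3L)
    stop("anovaOneway: fewer than 3 groups; use twoGroupTTest()")
  if (any(table(labels) < 2L))
    stop("anovaOneway: each group needs >= 2 samples")
  if (all(tapply(values, labels, var) == 0))
    stop("anovaOneway: zero within-group variance")
  ht <- oneway.test(values ~ labels, var.equal = TRUE)
  list(statistic = unname(ht$statistic), p.value = ht$p.value,
       df = unname(ht$parameter))
}

#' Pearson correlation with two-sided t-transform p-value
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return list with `r`, `p.value`, `n`.
#' @export
pearsonCorrelation <- function(x, y) {
  if (length(x) != length(y)) stop("pearsonCorrelation: unequal lengths")
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("pearsonCorrelation: need >= 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    stop("pearsonCorrelation: constant vector")
  ht <- cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p.value = ht$p.value, n = length(x))
}

#' Clinicopathological association battery
#'
#' Builds a Table-1 style summary of the relation between a high/low class
#' label and clinical variables. Binary and multi-level categorical variables
#' get per-level counts and percentages, a target-vs-rest odds ratio per
#' level (Woolf CI), and an overall p-value: Fisher exact for 2-level
#' variables, the full R x 2 Fisher test (chi-square fallback for large
#' tables) otherwise. Continuous variables get a Welch t-test between
#' classes. Samples with NA in a variable are dropped for that variable only.
#'
#' @param labels named factor (`low`/`high`) as returned by [medianSplit()].
#' @param clinical data.frame with `sample_id` plus the variables.
#' @param variables character vector of clinical column names to test.
#' @return data.frame with columns `variable`, `level`, `n`, `pct_all`,
#'   `n_low`, `pct_low`, `n_high`, `pct_high`, `odds_ratio`, `ci_low`,
#'   `ci_high`, `p_value` (overall p repeated on the variable's first row).
#' @export
associationTable <- function(labels, clinical, variables) {
  stopifnot(all(variables %in% names(clinical)),
            "sample_id" %in% names(clinical))
  idx <- match(clinical$sample_id, names(labels))
  cls <- labels[idx]

  rows <- lapply(variables, function(v) {
    x <- clinical[[v]]
    keep <- !is.na(x) & !is.na(cls)
    xv <- x[keep]; cv <- droplevels(cls[keep])
    if (is.numeric(xv) && length(unique(xv)) > 6L) {
      tt <- twoGroupTTest(xv, cv)
      return(data.frame(variable = v, level = "(continuous)",
                        n = length(xv), pct_all = NA_real_,
                        n_low = sum(cv == "low"), pct_low = NA_real_,
                        n_high = sum(cv == "high"), pct_high = NA_real_,
                        odds_ratio = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p_value = tt$p.value,
                        stringsAsFactors = FALSE))
    }
    xv <- factor(xv)
    tab <- table(xv, cv)   # levels x (low, high)
    overallP <- if (nlevels(xv) == 2L) {
      fisher.test(tab)$p.value
    } else {
      tryCatch(fisher.test(tab, workspace = 2e6)$p.value,
               error = function(e) chisq.test(tab)$p.value)
    }
    do.call(rbind, lapply(seq_len(nlevels(xv)), function(i) {
      lev <- levels(xv)[i]
      a <- tab[i, "high"]; b <- sum(tab[-i, "high"])
      cc <- tab[i, "low"]; dd <- sum(tab[-i, "low"])
      or <- oddsRatio2x2(a, b, cc, dd)
      data.frame(variable = v, level = lev,
                 n = sum(tab[i, ]),
                 pct_all = 100 * sum(tab[i, ]) / sum(tab),
                 n_low = cc, pct_low = 100 * cc / sum(tab[, "low"]),
                 n_high = a, pct_high = 100 * a / sum(tab[, "high"]),
                 odds_ratio = oddsRatio(or), ci_low = confInt(or)[["low"]],
                 ci_high = confInt(or)[["high"]],
                 p_value = if (i == 1L) overallP else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
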