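# Invert the trigamma function: find x with trigamma(x) = y.
# Newton iteration on the log scale with a bisection fallback; trigamma is
# strictly decreasing on (0, Inf) so the root is unique.
.trigammaInverse <- function(y, tol = 1e-8, maxit = 100L) {
  if (y <= 0) return(Inf)
  # trigamma(x) ~ 1/x + 1/(2x^2): start from the large-x asymptote
  x <- 0.5 + 1 / y
  for (i in seq_len(maxit)) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2L)
    x <- x + dif
    if (!is.finite(x) || x <= 0) { x <- NA_real_; break }
    if (abs(dif) < tol * x) return(x)
  }
  if (is.finite(x)) return(x)
  # bisection fallback on a wide bracket
  lo <- 1e-6; hi <- 1e6
  if (trigamma(lo) < y) return(lo)
  if (trigamma(hi) > y) return(hi)
  uniroot(function(z) trigamma(z) - y, c(lo, hi), tol = tol)$root
}

#' Estimate the empirical-Bayes variance prior
#'
#' Fits the scaled inverse chi-square prior (`d0`, `s0Sq`) to the observed
#' gene-wise residual variances by the method of moments on
#' `z_g = log(s_g^2)`: under the model, `z` is a constant plus the log of a
#' scaled F variate, so its mean and variance are expressed through digamma
#' and trigamma functions of `df/2` and `d0/2`. `d0` solves
#' `trigamma(d0/2) = var(z) - trigamma(df/2)`; when the observed variance of
#' `z` does not exceed the sampling contribution `trigamma(df/2)`, the prior
#' is degenerate and `d0 = Inf` (all variances shrunk fully to `s0Sq`).
#'
#' @param sSq positive numeric vector of gene-wise residual variances
#'   (>= 50 genes recommended for a stable fit).
#' @param residualDf residual degrees of freedom of each variance (single
#'   value, >= 1).
#' @return a [ModeratedTPrior-class].
#' @examples
#' set.seed(1)
#' s2 <- 4 * 0.25 / rchisq(5000, df = 4) * rchisq(5000, df = 10) / 10
#' fitEBPrior(s2, residualDf = 10)
#' @export
fitEBPrior <- function(sSq, residualDf) {
  if (any(!is.finite(sSq)) || any(sSq <= 0))
    stop("fitEBPrior: variances must be positive and finite")
  if (residualDf < 1) stop("fitEBPrior: residualDf must be >= 1")
  if (length(sSq) < 2L || var(log(sSq)) == 0)
    return(ModeratedTPrior(d0 = Inf, s0Sq = sSq[[1L]]))
  z <- log(sSq)
  excess <- var(z) - trigamma(residualDf / 2)
  if (excess <= 0) {
    s0Sq <- exp(mean(z) - digamma(residualDf / 2) + log(residualDf / 2))
    return(ModeratedTPrior(d0 = Inf, s0Sq = s0Sq))
  }
  d0 <- 2 * .trigammaInverse(excess)
  s0Sq <- exp(mean(z) - digamma(residualDf / 2) + log(residualDf / 2) +
                digamma(d0 / 2) - log(d0 / 2))
  ModeratedTPrior(d0 = d0, s0Sq = s0Sq)
}

# large-df cap used when d0 = Inf so pt() stays defined
.DF_CAP <- 1e6

#' Moderated t-statistics for a two-class comparison
#'
#' For each gene, the pooled two-class residual variance `s_g^2` (df =
#' n1 + n2 - 2) is shrunk toward the prior:
#' `s~_g^2 = (d0 * s0^2 + df * s_g^2) / (d0 + df)`, and
#' `t_mod = (mean_high - mean_low) / (s~_g * sqrt(1/n1 + 1/n2))` is referred
#' to a t distribution on `d0 + df` degrees of freedom (capped at 1e6 when
#' `d0 = Inf`). `d0 = 0` reproduces the classical pooled-variance t exactly.
#' Genes with zero total variance are flagged and given `p = 1`.
#' Benjamini-Hochberg q-values are attached via [bhFDR()].
#'
#' @param pooled a [PooledCohort-class] (or plain genes x samples matrix).
#' @param labels named factor/character with levels `low`/`high` covering the
#'   samples to compare; both classes need >= 2 samples.
#' @param prior a [ModeratedTPrior-class]; by default estimated from the data
#'   with [fitEBPrior()].
#' @return a [DEResult-class] with selection gates not yet applied.
#' @seealso [selectGenes()], [runDE()]
#' @export
moderatedT <- function(pooled, labels, prior = NULL) {
  m <- if (is(pooled, "PooledCohort")) assayMatrix(pooled) else as.matrix(pooled)
  labels <- labels[!is.na(labels)]
  common <- intersect(colnames(m), names(labels))
  lab <- factor(as.character(labels[common]), levels = c("low", "high"))
  hi <- common[lab == "high"]; lo <- common[lab == "low"]
  n1 <- length(hi); n2 <- length(lo)
  if (n1 < 2L || n2 < 2L)
    stop("moderatedT: both classes need >= 2 samples")

  mh <- rowMeans(m[, hi, drop = FALSE])
  ml <- rowMeans(m[, lo, drop = FALSE])
  ssHi <- rowSums((m[, hi, drop = FALSE] - mh)^2)
  ssLo <- rowSums((m[, lo, drop = FALSE] - ml)^2)
  df <- n1 + n2 - 2L
  sSq <- (ssHi + ssLo) / df

  if (is.null(prior)) {
    ok <- sSq > 0
    if (!any(ok)) stop("moderatedT: all genes have zero variance")
    prior <- fitEBPrior(sSq[ok], residualDf = df)
  }
  stopifnot(is(prior, "ModeratedTPrior"))
  d0 <- prior@d0; s0Sq <- prior@s0Sq

  sTildeSq <- if (is.infinite(d0)) rep(s0Sq, length(sSq)) else
    (d0 * s0Sq + df * sSq) / (d0 + df)
  dfTotal <- min(d0 + df, .DF_CAP)
  flagged <- sTildeSq <= 0
  sTildeSq[flagged] <- NA_real_
  tMod <- (mh - ml) / sqrt(sTildeSq * (1 / n1 + 1 / n2))
  p <- 2 * pt(-abs(tMod), df = dfTotal)
  tMod[flagged] <- 0; p[flagged] <- 1

  res <- data.frame(
    gene = rownames(m), log2fc = mh - ml, sSq = sSq, tMod = tMod,
    dfTotal = dfTotal, p = p, q = bhFDR(p), selected = NA,
    direction = ifelse(mh - ml >= 0, "up", "down"), flagged = flagged,
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  new("DEResult", results = res, prior = prior, config = DEConfig(),
      nHigh = n1, nLow = n2)
}

#' Benjamini-Hochberg step-up q-values
#'
#' `q_i = min_{j : p_j >= p_i} (m * p_j / rank_j)`, capped at 1; monotone in
#' p. Delegates to `stats::p.adjust(method = "BH")`.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return q-values, same length and order as `p`.
#' @export
bhFDR <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("bhFDR: p-values must be in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Apply the significance gates to a DEResult
#'
#' A gene is selected iff `p < pMax`, `q < qMax` and
#' `|log2fc| > log2(fcMin)` — all three gates simultaneously.
#'
#' @param de a [DEResult-class].
#' @param config a [DEConfig-class]; defaults to the gates p < 0.05,
#'   q < 0.01, FC > |1.25x|.
#' @return the [DEResult-class] with `selected` flags and `config` set; use
#'   [selectedGenes()] to extract the sorted list.
#' @export
selectGenes <- function(de, config = DEConfig()) {
  stopifnot(is(de, "DEResult"), is(config, "DEConfig"))
  r <- de@results
  r$selected <- r$p < config@pMax & r$q < config@qMax &
    abs(r$log2fc) > log2(config@fcMin) & !r$flagged
  de@results <- r
  de@config <- config
  de
}

#' One-call differential expression: prior, moderated t, gates
#'
#' @inheritParams moderatedT
#' @inheritParams selectGenes
#' @return a gated [DEResult-class].
#' @export
runDE <- function(pooled, labels, config = DEConfig(), prior = NULL) {
  selectGenes(moderatedT(pooled, labels, prior), config)
}
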