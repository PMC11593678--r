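# Independent brute-force oracles used across the suite. Each re-derives the
# quantity from its definition, never through the package's own code path.

# quantile normalization by explicit re-sorting
oracleQuantileNormalize <- function(m) {
  ord <- apply(m, 2, order)
  target <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) out[ord[, j], j] <- target
  out
}

# two-sided Fisher exact p by full hypergeometric enumeration over all tables
# with the observed margins
oracleFisherP <- function(a, b, c, d) {
  m <- a + b          # row 1 margin
  n <- c + d          # row 2 margin
  k <- a + c          # column 1 margin
  support <- max(0L, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  pObs <- dhyper(a, m, n, k)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# O(m^2) Benjamini-Hochberg from the step-up definition:
# q_i = min over sorted positions j with p_(j) >= p_i of m * p_(j) / j
oracleBH <- function(p) {
  m <- length(p)
  sp <- sort(p)
  vapply(p, function(pi) {
    js <- which(sp >= pi)
    min(1, min(m * sp[js] / js))
  }, numeric(1))
}

# per-gene moderated t from the formula, one gene at a time
oracleModeratedT <- function(m, hi, lo, d0, s0Sq) {
  n1 <- length(hi); n2 <- length(lo); df <- n1 + n2 - 2
  t(vapply(seq_len(nrow(m)), function(g) {
    x <- m[g, hi]; y <- m[g, lo]
    s2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / df
    st2 <- if (is.infinite(d0)) s0Sq else (d0 * s0Sq + df * s2) / (d0 + df)
    tm <- (mean(x) - mean(y)) / sqrt(st2 * (1 / n1 + 1 / n2))
    c(t = tm, p = 2 * pt(-abs(tm), df = min(d0 + df, 1e6)))
  }, numeric(2)))
}

# Kaplan-Meier product-limit by direct accumulation at event times
oracleKM <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(ts))
  for (i in seq_along(ts)) {
    atRisk <- sum(time >= ts[i])
    died <- sum(time == ts[i] & event == 1)
    s <- s * (1 - died / atRisk)
    surv[i] <- s
  }
  data.frame(time = ts, surv = surv)
}

# two-group log-rank chi-square from the O-E / hypergeometric-variance table
oracleLogrank <- function(time, event, group) {
  g <- factor(group)
  ts <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (tt in ts) {
    n <- sum(time >= tt)
    n1 <- sum(time >= tt & g == levels(g)[1])
    d <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & g == levels(g)[1])
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# small simulation shared by several tests
tinySim <- function(seed = 1, ...) {
  args <- list(nCohorts = 2, samplesPerCohort = 40, nGenes = 300,
               nModuleGenes = 30, seed = seed)
  args[names(list(...))] <- list(...)
  simulateCohorts(do.call(simConfig, args))
}

tumorIdsOf <- function(sim) {
  sim$clinical$sample_id[sim$clinical$sample_type == "tumor"]
}
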