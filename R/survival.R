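#' Assemble survival records from a clinical table
#'
#' Picks the endpoint columns (`os_time`/`os_event` or
#' `pfs_time`/`pfs_event`, months) and the requested covariates, dropping
#' samples with missing time or event.
#'
#' @param clinical data.frame with `sample_id` and endpoint columns.
#' @param endpoint `"OS"` or `"PFS"`.
#' @param covariates optional character vector of clinical columns to carry.
#' @return data.frame with `sample_id`, `time`, `event`, covariates.
#' @export
survivalRecords <- function(clinical, endpoint = c("OS", "PFS"),
                            covariates = character()) {
  endpoint <- match.arg(endpoint)
  cols <- if (endpoint == "OS") c("os_time", "os_event") else
    c("pfs_time", "pfs_event")
  stopifnot(all(cols %in% names(clinical)),
            all(covariates %in% names(clinical)))
  df <- data.frame(sample_id = clinical$sample_id,
                   time = clinical[[cols[1]]],
                   event = clinical[[cols[2]]],
                   clinical[, covariates, drop = FALSE],
                   stringsAsFactors = FALSE)
  df <- df[!is.na(df$time) & !is.na(df$event), , drop = FALSE]
  if (any(df$time <= 0)) stop("survivalRecords: nonpositive survival times")
  if (!all(df$event %in% c(0, 1))) stop("survivalRecords: event must be 0/1")
  rownames(df) <- NULL
  df
}

#' Kaplan-Meier estimate
#'
#' Product-limit estimator with Greenwood variance. The median is the
#' earliest time at which the estimated survival drops to 0.5 or below
#' (NA when it never does); `rateAt` reads the survival probability (with
#' its Greenwood CI) at given times, e.g. 60 months for five-year rates.
#'
#' @param time positive times in months.
#' @param event 0/1 event indicators.
#' @param rateTimes times at which to report survival rates (default 60).
#' @return list: `fit` (the `survfit` object), `time`, `surv`, `median`,
#'   `rates` (data.frame `time`, `surv`, `lower`, `upper`).
#' @export
kmEstimate <- function(time, event, rateTimes = 60) {
  if (any(is.na(time)) || any(time <= 0))
    stop("kmEstimate: times must be positive")
  if (!all(event %in% c(0, 1))) stop("kmEstimate: event must be 0/1")
  fit <- survfit(Surv(time, event) ~ 1, conf.type = "log")
  med <- unname(summary(fit)$table["median"])
  sm <- summary(fit, times = pmin(rateTimes, max(time)), extend = FALSE)
  rates <- data.frame(time = sm$time, surv = sm$surv,
                      lower = sm$lower, upper = sm$upper)
  list(fit = fit, time = fit$time, surv = fit$surv,
       median = if (is.na(med)) NA_real_ else med, rates = rates)
}

#' Log-rank test
#'
#' Observed-minus-expected statistic with hypergeometric variance;
#' chi-square on k - 1 degrees of freedom.
#'
#' @param time,event as in [kmEstimate()].
#' @param group grouping vector (>= 2 non-empty groups; >= 1 event overall).
#' @return list with `chisq`, `df`, `p.value`, `obs`, `exp`.
#' @export
logrankTest <- function(time, event, group) {
  group <- factor(group)
  if (nlevels(droplevels(group)) < 2L)
    stop("logrankTest: need >= 2 non-empty groups")
  if (any(table(group) == 0L))
    stop("logrankTest: a group has zero samples at risk")
  if (sum(event) < 1L) stop("logrankTest: no events")
  sd <- survdiff(Surv(time, event) ~ group)
  df <- length(sd$n) - 1L
  list(chisq = sd$chisq, df = df,
       p.value = pchisq(sd$chisq, df = df, lower.tail = FALSE),
       obs = sd$obs, exp = sd$exp)
}

# per-coefficient table from a coxph fit
.coxTable <- function(fit, conf = 0.95) {
  s <- summary(fit, conf.int = conf)
  co <- s$coefficients
  ci <- s$conf.int
  data.frame(term = rownames(co), coef = co[, "coef"],
             hr = co[, "exp(coef)"],
             ci_low = ci[, 3], ci_high = ci[, 4],
             wald_p = co[, "Pr(>|z|)"],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cox proportional-hazards fit with Wald tests
#'
#' Partial-likelihood maximization with the Efron tie approximation.
#' Supports interaction terms (e.g. expression class x molecular subtype).
#' Warns when the number of events is below five per coefficient; errors on
#' non-convergence, collinear covariates, or monotone likelihood (perfect
#' separation, detected as an infinite coefficient).
#'
#' @param records data.frame from [survivalRecords()] (columns `time`,
#'   `event`, covariates).
#' @param covariates character vector of covariate columns.
#' @param interactions optional character vector of `"a:b"` interaction
#'   terms.
#' @return list: `table` (term, coef, hr, ci_low, ci_high, wald_p), `n`,
#'   `nEvents`, `loglik`, `fit`.
#' @export
coxFit <- function(records, covariates, interactions = NULL) {
  stopifnot(all(covariates %in% names(records)))
  terms <- c(covariates, interactions)
  fml <- stats::as.formula(paste("Surv(time, event) ~",
                                 paste(terms, collapse = " + ")))
  fit <- withCallingHandlers(
    coxph(fml, data = records, ties = "efron",
          control = coxph.control(iter.max = 100)),
    warning = function(w) {
      if (grepl("infinite|converge|singular", conditionMessage(w)))
        stop("coxFit: ", conditionMessage(w), call. = FALSE)
      invokeRestart("muffleWarning")
    })
  if (any(is.na(coef(fit))))
    stop("coxFit: collinear covariates (NA coefficient)")
  if (any(!is.finite(coef(fit))) || any(abs(coef(fit)) > 15))
    stop("coxFit: monotone likelihood / separated covariate")
  k <- length(coef(fit))
  if (fit$nevent < 5 * k)
    warning(sprintf("coxFit: only %d events for %d coefficients", fit$nevent, k))
  list(table = .coxTable(fit), n = fit$n, nEvents = fit$nevent,
       loglik = fit$loglik[2], fit = fit)
}

#' Time-stratified Cox hazard ratios
#'
#' Splits follow-up into episodes at the cutpoints (default 6 and 12 months)
#' and estimates a separate hazard ratio for the covariate in each interval
#' through an interval x covariate interaction with no main effect.
#' Intervals without events yield an undefined (NA) hazard ratio.
#'
#' @param records data.frame from [survivalRecords()].
#' @param covariate single covariate column name.
#' @param cutpoints strictly increasing positive cutpoints (months).
#' @return data.frame: `interval`, `hr`, `ci_low`, `ci_high`, `wald_p`,
#'   `n_events`.
#' @export
coxTimeStratified <- function(records, covariate, cutpoints = c(6, 12)) {
  if (is.unsorted(cutpoints, strictly = TRUE) || any(cutpoints <= 0))
    stop("coxTimeStratified: cutpoints must be strictly increasing and > 0")
  df <- records[, c("time", "event", covariate)]
  split <- survSplit(Surv(time, event) ~ ., data = df, cut = cutpoints,
                     episode = "interval")
  bounds <- c(0, cutpoints, Inf)
  labs <- paste0("(", bounds[-length(bounds)], ",", bounds[-1], "]")
  split$interval <- factor(labs[split$interval], levels = labs)
  nEv <- tapply(split$event, split$interval, sum)
  nEv[is.na(nEv)] <- 0

  out <- data.frame(interval = labs, hr = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, wald_p = NA_real_,
                    n_events = as.integer(nEv[labs]),
                    stringsAsFactors = FALSE)
  ok <- out$n_events > 0
  if (!any(ok)) return(out)
  sub <- split[split$interval %in% labs[ok], , drop = FALSE]
  sub$interval <- droplevels(sub$interval)
  fml <- stats::as.formula(paste(
    "Surv(tstart, time, event) ~ interval:", covariate))
  fit <- withCallingHandlers(
    coxph(fml, data = sub, ties = "efron",
          control = coxph.control(iter.max = 100)),
    warning = function(w) {
      # sparse intervals can leave a coefficient unestimable; such
      # intervals are reported as undefined below
      if (grepl("infinite|converged", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  tab <- .coxTable(fit)
  tab$coef[abs(tab$coef) > 15] <- NA_real_
  for (i in which(ok)) {
    row <- which(startsWith(tab$term, paste0("interval", labs[i], ":")))
    if (length(row) == 1L && is.finite(tab$coef[row])) {
      out[i, c("hr", "ci_low", "ci_high", "wald_p")] <-
        tab[row, c("hr", "ci_low", "ci_high", "wald_p")]
    }
  }
  out
}

#' Univariate screen followed by multivariate Cox model
#'
#' Fits a univariate Cox model per candidate covariate; candidates with a
#' Wald p-value below `alpha` (any coefficient, for factors) enter one joint
#' multivariate model. When no candidate passes, the multivariate step is
#' skipped and reported as such.
#'
#' @param records data.frame from [survivalRecords()].
#' @param candidates character vector of candidate covariate columns.
#' @param alpha univariate inclusion threshold (default 0.05).
#' @return list: `univariate` (named list of [coxFit()] results),
#'   `retained` (character), `multivariate` ([coxFit()] result or NULL).
#' @export
multivariateScreen <- function(records, candidates, alpha = 0.05) {
  uni <- lapply(candidates, function(v)
    tryCatch(coxFit(records, v), error = function(e) NULL))
  names(uni) <- candidates
  passed <- vapply(uni, function(f)
    !is.null(f) && any(f$table$wald_p < alpha), logical(1))
  retained <- candidates[passed]
  multi <- NULL
  if (length(retained)) {
    multi <- coxFit(records, retained)
  } else {
    message("multivariateScreen: no candidate passed univariate screening")
  }
  list(univariate = uni, retained = retained, multivariate = multi)
}
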