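#' Simulation configuration
#'
#' Parameters of the multi-cohort generator. Defaults mirror the study design
#' the pipeline targets: a pooled series of primary ovarian tumors spread over
#' several cohorts with cohort-specific location/scale effects, one anchor
#' gene (FOLR1), a planted module of 187 genes whose mean shifts with the
#' anchor class, clinicopathological covariates tied to the anchor class at
#' the odds ratios observed in that setting (serous 2.45, FIGO III-IV 1.71,
#' high grade 1.45, platinum sensitivity 1.03), and exponential
#' proportional-hazards survival with a planted module hazard ratio of 0.71.
#'
#' @slot nCohorts number of tumor cohorts.
#' @slot samplesPerCohort tumors per cohort.
#' @slot nGenes total genes (anchor included).
#' @slot nModuleGenes planted signature size (default 187).
#' @slot anchorGeneId id of the anchor gene (default `"FOLR1"`).
#' @slot moduleLog2FC mean shift (log2 units) of module genes in anchor-high
#'   samples; half the module shifts up, half down.
#' @slot anchorNoiseSd measurement noise SD added to the anchor gene on top of
#'   its latent (unit-variance) biological value.
#' @slot cohortShiftSd SD of the per-cohort additive location effect.
#' @slot cohortScaleRange length-2 range of the per-cohort multiplicative
#'   scale effect.
#' @slot covariateOdds named numeric vector: target odds ratio of each binary
#'   covariate versus the anchor-high class.
#' @slot baselineHazard event rate per month in the anchor-low class.
#' @slot signatureHr planted hazard ratio of the module-high class (default
#'   0.71).
#' @slot censorRate target fraction of censored survival records, in [0, 1].
#' @slot nNormal normal ovarian tissue samples (appended to the first cohort,
#'   outside the tumor reference population).
#' @slot normalOffset downward shift (log2 units) of the anchor gene in normal
#'   tissue.
#' @slot seed integer master seed; every stage derives its stream from it.
#' @exportClass SimConfig
setClass("SimConfig",
  representation(
    nCohorts = "integer", samplesPerCohort = "integer", nGenes = "integer",
    nModuleGenes = "integer", anchorGeneId = "character",
    moduleLog2FC = "numeric", anchorNoiseSd = "numeric",
    cohortShiftSd = "numeric", cohortScaleRange = "numeric",
    covariateOdds = "numeric", baselineHazard = "numeric",
    signatureHr = "numeric", censorRate = "numeric",
    nNormal = "integer", normalOffset = "numeric", seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  bad <- function(cond, what) if (cond) what else NULL
  msg <- c(
    bad(object@nCohorts < 1L, "nCohorts must be >= 1"),
    bad(object@samplesPerCohort < 1L, "samplesPerCohort must be >= 1"),
    bad(object@nGenes < 1L, "nGenes must be >= 1"),
    bad(object@nModuleGenes < 1L, "nModuleGenes must be >= 1"),
    bad(object@nModuleGenes >= object@nGenes,
        "nModuleGenes must be < nGenes"),
    bad(object@signatureHr <= 0, "signatureHr must be > 0"),
    bad(object@censorRate < 0 || object@censorRate >= 1,
        "censorRate must be in [0, 1)"),
    bad(object@anchorNoiseSd < 0, "anchorNoiseSd must be >= 0"),
    bad(object@baselineHazard <= 0, "baselineHazard must be > 0"),
    bad(length(object@cohortScaleRange) != 2L ||
          any(object@cohortScaleRange <= 0) ||
          diff(object@cohortScaleRange) < 0,
        "cohortScaleRange must be an increasing positive pair"),
    bad(any(object@covariateOdds <= 0), "covariateOdds must be > 0"),
    bad(object@nNormal < 0L, "nNormal must be >= 0")
  )
  if (length(msg)) msg else TRUE
})

#' @rdname SimConfig-class
#' @param nCohorts,samplesPerCohort,nGenes,nModuleGenes,anchorGeneId
#'   see slots.
#' @param moduleLog2FC,anchorNoiseSd,cohortShiftSd,cohortScaleRange see slots.
#' @param covariateOdds,baselineHazard,signatureHr,censorRate see slots.
#' @param nNormal,normalOffset,seed see slots.
#' @return A validated [SimConfig-class].
#' @examples
#' cfg <- simConfig(nCohorts = 2, samplesPerCohort = 50, nGenes = 500,
#'                  nModuleGenes = 40, seed = 7)
#' @export
simConfig <- function(nCohorts = 4, samplesPerCohort = 150, nGenes = 2000,
                      nModuleGenes = 187, anchorGeneId = "FOLR1",
                      moduleLog2FC = 1.0, anchorNoiseSd = 0.3,
                      cohortShiftSd = 0.5, cohortScaleRange = c(0.8, 1.25),
                      covariateOdds = c(serous = 2.45, figo_34 = 1.71,
                                        grade_high = 1.45,
                                        platinum_sensitive = 1.03),
                      baselineHazard = 0.02, signatureHr = 0.71,
                      censorRate = 0.3, nNormal = 30, normalOffset = 2,
                      seed = 1L) {
  new("SimConfig",
      nCohorts = as.integer(nCohorts),
      samplesPerCohort = as.integer(samplesPerCohort),
      nGenes = as.integer(nGenes), nModuleGenes = as.integer(nModuleGenes),
      anchorGeneId = anchorGeneId, moduleLog2FC = moduleLog2FC,
      anchorNoiseSd = anchorNoiseSd, cohortShiftSd = cohortShiftSd,
      cohortScaleRange = as.numeric(cohortScaleRange),
      covariateOdds = covariateOdds, baselineHazard = baselineHazard,
      signatureHr = signatureHr, censorRate = censorRate,
      nNormal = as.integer(nNormal), normalOffset = normalOffset,
      seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(paste0(
    "SimConfig: %d cohorts x %d tumors + %d normals, %d genes ",
    "(%d module @ log2FC %.2g), HR %.2g, seed %d\n"),
    object@nCohorts, object@samplesPerCohort, object@nNormal, object@nGenes,
    object@nModuleGenes, object@moduleLog2FC, object@signatureHr,
    object@seed))
})

# baseline prevalence of each covariate in the anchor-low class; unlisted
# covariates fall back to 0.5
.COVARIATE_BASELINE <- c(serous = 0.89, figo_34 = 0.85, grade_high = 0.71,
                         platinum_sensitive = 0.88)

# deterministic per-stage RNG substreams derived from the master seed
.stageSeed <- function(seed, stage) {
  offsets <- c(genes = 101L, biology = 211L, covariates = 307L,
               survival = 401L, cohort = 503L)
  (as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max
}

# censoring rate c solving mean_i c/(c + h_i) = target
.censorHazard <- function(eventHaz, target) {
  if (target <= 0) return(0)
  f <- function(cc) mean(cc / (cc + eventHaz)) - target
  uniroot(f, lower = 1e-10, upper = 1e6, tol = 1e-12)$root
}

#' Simulate a multi-cohort expression study with planted structure
#'
#' Generates, for each cohort, a gene x sample log2 expression matrix under a
#' gene-wise Gaussian model whose variances are drawn from a scaled inverse
#' chi-square distribution (so the empirical-Bayes variance prior is a
#' well-specified estimation target). A latent standard-normal anchor value
#' per tumor defines the true anchor class (above/below the population median,
#' i.e. 0); module genes shift by `moduleLog2FC` (half up, half down) in
#' anchor-high samples; binary covariates are drawn at the configured odds
#' ratios versus the anchor class; overall and progression-free survival times
#' come from an exponential proportional-hazards model with hazard ratio
#' `signatureHr` for the module-high (= anchor-high) class, with independent
#' exponential censoring tuned to `censorRate`. Cohort location/scale effects
#' are applied after the biology. Normal-tissue samples (anchor shifted down
#' by `normalOffset`, no module shift, no survival) are appended to the first
#' cohort so that every cohort retains primary tumors as its standardization
#' reference.
#'
#' @param config a [SimConfig-class].
#' @return A list with class `"SimOutput"`:
#'   \describe{
#'     \item{cohorts}{list of [ExpressionCohort-class] objects}
#'     \item{clinical}{data.frame: `sample_id`, `dataset`, `sample_type`,
#'       `age`, one 0/1 column per covariate, `os_time`, `os_event`,
#'       `pfs_time`, `pfs_event` (times in months; NA for normals)}
#'     \item{truth}{list: `moduleGenes`, `moduleSign` (named +1/-1),
#'       `anchorClass` (named "high"/"low" per tumor), `hazardClass`}
#'     \item{config}{the input configuration}
#'   }
#' @examples
#' sim <- simulateCohorts(simConfig(nCohorts = 2, samplesPerCohort = 40,
#'                                  nGenes = 300, nModuleGenes = 30,
#'                                  seed = 11))
#' length(sim$cohorts)
#' @export
simulateCohorts <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)

  nC <- config@nCohorts
  nS <- config@samplesPerCohort
  nG <- config@nGenes
  nTum <- nC * nS

  ## gene universe and gene-level parameters
  set.seed(.stageSeed(config@seed, "genes"))
  geneIds <- c(config@anchorGeneId,
               sprintf("G%05d", seq_len(nG - 1L)))
  mu <- rnorm(nG, mean = 7, sd = 1.5)
  d0True <- 4; s0SqTrue <- 0.25
  sigmaSq <- d0True * s0SqTrue / rchisq(nG, df = d0True)
  sigma <- sqrt(sigmaSq)
  names(mu) <- names(sigma) <- geneIds
  sigma[config@anchorGeneId] <- config@anchorNoiseSd
  moduleGenes <- sort(sample(geneIds[-1L], config@nModuleGenes))
  moduleSign <- setNames(
    rep(c(1, -1), length.out = config@nModuleGenes), moduleGenes)

  ## latent anchor biology per tumor
  set.seed(.stageSeed(config@seed, "biology"))
  tumorIds <- sprintf("T%04d", seq_len(nTum))
  tumorCohort <- rep(sprintf("C%02d", seq_len(nC)), each = nS)
  aLatent <- rnorm(nTum)
  anchorClass <- setNames(ifelse(aLatent > 0, "high", "low"), tumorIds)
  isHigh <- aLatent > 0

  normalIds <- if (config@nNormal > 0L)
    sprintf("N%03d", seq_len(config@nNormal)) else character()
  nAll <- nTum + config@nNormal

  expr <- matrix(rnorm(nG * nAll, sd = rep(sigma, times = nAll)),
                 nrow = nG, ncol = nAll,
                 dimnames = list(geneIds, c(tumorIds, normalIds)))
  expr <- expr + mu
  expr[config@anchorGeneId, tumorIds] <-
    expr[config@anchorGeneId, tumorIds] + aLatent
  if (config@nNormal > 0L)
    expr[config@anchorGeneId, normalIds] <-
      expr[config@anchorGeneId, normalIds] - config@normalOffset
  shift <- config@moduleLog2FC * moduleSign
  expr[moduleGenes, tumorIds[isHigh]] <-
    expr[moduleGenes, tumorIds[isHigh]] + shift

  ## covariates at configured odds ratios vs anchor class
  set.seed(.stageSeed(config@seed, "covariates"))
  covTab <- lapply(names(config@covariateOdds), function(nm) {
    p0 <- if (nm %in% names(.COVARIATE_BASELINE))
      .COVARIATE_BASELINE[[nm]] else 0.5
    p1 <- plogis(qlogis(p0) + log(config@covariateOdds[[nm]]))
    rbinom(nTum, 1L, ifelse(isHigh, p1, p0))
  })
  names(covTab) <- names(config@covariateOdds)
  age <- pmin(pmax(round(rnorm(nTum, 59, 11), 1), 21), 90)

  ## proportional-hazards survival, months
  set.seed(.stageSeed(config@seed, "survival"))
  hazOS <- config@baselineHazard * config@signatureHr^isHigh
  hazPFS <- 1.5 * hazOS
  survDraw <- function(haz) {
    tEvent <- rexp(nTum, rate = haz)
    cRate <- .censorHazard(haz, config@censorRate)
    tCens <- if (cRate > 0) rexp(nTum, rate = cRate) else rep(Inf, nTum)
    time <- pmin(tEvent, tCens)
    list(time = round(pmax(time, 0.03), 2), event = as.integer(tEvent <= tCens))
  }
  os <- survDraw(hazOS)
  pfs <- survDraw(hazPFS)

  ## cohort location/scale effects, applied after the biology
  set.seed(.stageSeed(config@seed, "cohort"))
  shiftC <- rnorm(nC, 0, config@cohortShiftSd)
  scaleC <- runif(nC, config@cohortScaleRange[1], config@cohortScaleRange[2])

  sampleCohort <- c(tumorCohort,
                    rep(sprintf("C%02d", 1L), config@nNormal))
  cohorts <- lapply(seq_len(nC), function(k) {
    cid <- sprintf("C%02d", k)
    cols <- colnames(expr)[sampleCohort == cid]
    m <- shiftC[k] + scaleC[k] * expr[, cols, drop = FALSE]
    ExpressionCohort(m, cohortId = cid, platformClass = "processed_array",
                     isLog2 = TRUE)
  })

  clinical <- data.frame(
    sample_id = c(tumorIds, normalIds),
    dataset = sampleCohort,
    sample_type = c(rep("tumor", nTum), rep("normal", config@nNormal)),
    age = c(age, rep(NA_real_, config@nNormal)),
    stringsAsFactors = FALSE
  )
  for (nm in names(covTab))
    clinical[[nm]] <- c(covTab[[nm]], rep(NA_integer_, config@nNormal))
  clinical$os_time <- c(os$time, rep(NA_real_, config@nNormal))
  clinical$os_event <- c(os$event, rep(NA_integer_, config@nNormal))
  clinical$pfs_time <- c(pfs$time, rep(NA_real_, config@nNormal))
  clinical$pfs_event <- c(pfs$event, rep(NA_integer_, config@nNormal))

  out <- list(
    cohorts = cohorts,
    clinical = clinical,
    truth = list(moduleGenes = moduleGenes, moduleSign = moduleSign,
                 anchorClass = anchorClass, hazardClass = anchorClass),
    config = config
  )
  class(out) <- "SimOutput"
  out
}

#' @export
print.SimOutput <- function(x, ...) {
  cat(sprintf("SimOutput: %d cohorts, %d samples (%d tumors), %d genes, %d module genes\n",
              length(x$cohorts), nrow(x$clinical),
              sum(x$clinical$sample_type == "tumor"),
              nrow(assayMatrix(x$cohorts[[1]])),
              length(x$truth$moduleGenes)))
  invisible(x)
}

#' Write a SimOutput to disk as plain-text artifacts
#'
#' One expression TSV per cohort (`<cohortId>.tsv`, first column `gene_id`),
#' `clinical.tsv`, and `truth.json`.
#'
#' @param sim a `SimOutput` from [simulateCohorts()].
#' @param dir output directory, created if absent.
#' @return invisibly, the paths written.
#' @export
writeSimOutput <- function(sim, dir) {
  stopifnot(inherits(sim, "SimOutput"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(sim$cohorts, function(co) {
    p <- file.path(dir, paste0(cohortId(co), ".tsv"))
    writeExpressionTSV(assayMatrix(co), p)
    p
  }, character(1))
  clinPath <- file.path(dir, "clinical.tsv")
  write.table(sim$clinical, clinPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  truthPath <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(moduleGenes = sim$truth$moduleGenes,
         moduleSign = as.list(sim$truth$moduleSign),
         anchorClass = as.list(sim$truth$anchorClass)),
    truthPath, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, clinPath, truthPath))
}
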