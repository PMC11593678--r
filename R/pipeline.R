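#' Run the full analysis pipeline
#'
#' Orchestrates simulate/load -> harmonize -> median split -> differential
#' expression on the learning cohort -> centroid signature -> classification
#' of the validation cohorts -> association battery -> survival analysis,
#' writing all stage artifacts plus a reproducibility manifest to
#' `outputDir`.
#'
#' `config` is a list (or a path to a YAML/JSON file encoding one) with
#' fields:
#' \describe{
#'   \item{simulate}{list of [simConfig()] arguments, \emph{or}}
#'   \item{cohorts}{named list of expression TSV/GCT paths with
#'     `clinical` path alongside}
#'   \item{targetGene}{gene to dichotomize, default `"FOLR1"`}
#'   \item{learningCohortId}{cohort used as learning set; default: largest}
#'   \item{de}{list of [DEConfig()] arguments}
#'   \item{endpoint}{`"OS"` (default) or `"PFS"`}
#'   \item{outputDir}{where artifacts are written}
#'   \item{seed}{integer, governs every stochastic stage}
#' }
#'
#' @param config list or path as above.
#' @return invisibly, a list with all stage objects (`sim`, `pooled`,
#'   `split`, `de`, `model`, `calls`, `associations`, `survival`,
#'   `manifest`).
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- .readRunConfig(config)
  stopifnot(is.list(config))
  outDir <- config$outputDir %||% tempfile("folrsig_run_")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  targetGene <- config$targetGene %||% "FOLR1"
  endpoint <- config$endpoint %||% "OS"
  deCfg <- do.call(DEConfig, config$de %||% list())

  ## stage 1: data
  if (!is.null(config$simulate)) {
    simArgs <- config$simulate
    simArgs$seed <- simArgs$seed %||% seed
    sim <- simulateCohorts(do.call(simConfig, simArgs))
    cohorts <- sim$cohorts
    clinical <- sim$clinical
  } else if (!is.null(config$cohorts)) {
    sim <- NULL
    cohorts <- lapply(names(config$cohorts), function(nm) {
      path <- config$cohorts[[nm]]
      if (!file.exists(path)) stop(sprintf("cohort file not found: %s", path))
      m <- if (grepl("\\.gct$", path, ignore.case = TRUE)) readGCT(path)
           else readExpressionTSV(path)
      ExpressionCohort(m, cohortId = nm)
    })
    if (is.null(config$clinical) || !file.exists(config$clinical))
      stop("clinical table path missing or not found")
    clinical <- readClinicalTable(config$clinical)
  } else stop("config needs either 'simulate' or 'cohorts'")

  ## stage 2: harmonization (per-cohort quantile normalization, then
  ## per-dataset standardization against the primary tumor reference)
  cohorts <- lapply(cohorts, function(co) {
    m <- quantileNormalize(assayMatrix(co))
    ExpressionCohort(m, cohortId = cohortId(co),
                     platformClass = co@platformClass, isLog2 = co@isLog2)
  })
  tumorIds <- clinical$sample_id[clinical$sample_type == "tumor"]
  pooled <- standardizeAndPool(cohorts, tumorIds)
  writeExpressionTSV(assayMatrix(pooled), file.path(outDir, "pooled.tsv"))

  ## stage 3: target-gene median split (tumors only for downstream stats)
  split <- medianSplit(pooled, targetGene)
  tumLabels <- split$labels[intersect(names(split$labels), tumorIds)]

  ## stage 4: DE on the learning cohort
  ds <- datasetOf(pooled)
  learnId <- config$learningCohortId %||%
    names(which.max(table(ds[names(tumLabels)])))
  learnSamples <- names(tumLabels)[ds[names(tumLabels)] == learnId]
  validSamples <- setdiff(names(tumLabels), learnSamples)
  if (length(learnSamples) == 0L)
    stop(sprintf("learning cohort '%s' has no tumor samples", learnId))
  de <- runDE(subsetSamples(pooled, learnSamples),
              tumLabels[learnSamples], deCfg)
  deTab <- deTable(de)
  write.table(deTab[order(deTab$p), ], file.path(outDir, "de_results.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  sel <- selectedGenes(de)

  ## stage 5: signature model + classification of validation samples
  model <- NULL; calls <- NULL
  if (nrow(sel) >= 2L) {
    model <- buildCentroid(subsetSamples(pooled, learnSamples),
                           tumLabels[learnSamples], sel$gene,
                           learningSetId = learnId)
    writeSignatureModel(model, file.path(outDir, "signature_model.json"))
    classifySet <- if (length(validSamples)) validSamples else learnSamples
    calls <- classifySamples(model, subsetSamples(pooled, classifySet))
    write.table(calls, file.path(outDir, "signature_calls.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    message("runPipeline: fewer than 2 selected genes; skipping signature stage")
  }

  ## stage 6: clinicopathological associations
  assocVars <- intersect(
    config$associationVariables %||%
      setdiff(names(clinical),
              c("sample_id", "dataset", "sample_type",
                "os_time", "os_event", "pfs_time", "pfs_event")),
    names(clinical))
  assoc <- associationTable(split$labels, clinical, assocVars)
  write.table(assoc, file.path(outDir, "associations.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  ## stage 7: survival by target class and by signature class
  surv <- list()
  recs <- survivalRecords(clinical, endpoint)
  recs$targetClass <- as.character(split$labels[recs$sample_id])
  surv$target <- .survBattery(recs[!is.na(recs$targetClass), ], "targetClass")
  if (!is.null(calls)) {
    recs2 <- recs[match(calls$sample_id, recs$sample_id), ]
    recs2$sigClass <- calls$label
    recs2 <- recs2[!is.na(recs2$time), ]
    surv$signature <- .survBattery(recs2, "sigClass")
  }
  survTab <- do.call(rbind, lapply(names(surv), function(nm) {
    ct <- surv[[nm]]$cox$table
    cbind(analysis = nm, ct)
  }))
  write.table(survTab, file.path(outDir, "survival_cox.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  ## manifest
  cfgPath <- file.path(outDir, "config.json")
  cfgJson <- config
  cfgJson$outputDir <- NULL
  jsonlite::write_json(cfgJson, cfgPath, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  manifest <- list(
    package_version = as.character(packageVersion("FolrSig")),
    seed = seed,
    config_md5 = unname(tools::md5sum(cfgPath)),
    n_cohorts = length(cohorts),
    n_genes_pooled = nrow(pooled),
    n_samples_pooled = ncol(pooled),
    learning_cohort = learnId,
    n_learning = length(learnSamples),
    n_validation = length(validSamples),
    n_selected_genes = nrow(sel),
    target_gene = targetGene,
    endpoint = endpoint
  )
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(sim = sim, pooled = pooled, split = split, de = de,
                 model = model, calls = calls, associations = assoc,
                 survival = surv, manifest = manifest, outputDir = outDir))
}

.survBattery <- function(recs, classCol) {
  out <- list()
  out$km <- lapply(split(recs, recs[[classCol]]),
                   function(d) kmEstimate(d$time, d$event))
  out$logrank <- logrankTest(recs$time, recs$event, recs[[classCol]])
  out$cox <- coxFit(recs, classCol)
  out
}

.readRunConfig <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required to read YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
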