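#' @import methods
#' @importFrom stats median var sd quantile rnorm rexp runif rbinom rchisq
#'   pt qt pnorm qnorm plogis qlogis fisher.test chisq.test t.test oneway.test
#'   cor cor.test p.adjust setNames aggregate uniroot complete.cases
#' @importFrom stats pchisq coef
#' @importFrom utils read.delim write.table packageVersion head
#' @importFrom S4Vectors DataFrame metadata `metadata<-`
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom survival Surv survfit survdiff coxph coxph.control survSplit
NULL

.PLATFORM_CLASSES <- c("processed_array", "raw_array", "rnaseq")

#' ExpressionCohort: one cohort's feature-by-sample expression matrix
#'
#' Container for a single cohort (one GEO series, one TCGA platform, ...):
#' a numeric features x samples matrix on (or convertible to) the log2 scale,
#' a platform class describing its processing semantics, and an optional
#' probe-to-gene map used by [collapseProbes()].
#'
#' @slot exprs numeric matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids).
#' @slot cohortId single character cohort identifier.
#' @slot platformClass one of `"processed_array"`, `"raw_array"`, `"rnaseq"`.
#' @slot probeMap `NULL`, or a data.frame with columns `probe_id`, `gene_id`.
#' @slot isLog2 logical flag; `TRUE` once values are on the log2 scale.
#'
#' @seealso [ExpressionCohort()] the constructor, [collapseProbes()],
#'   [standardizeAndPool()]
#' @exportClass ExpressionCohort
setClass("ExpressionCohort",
  representation(
    exprs = "matrix",
    cohortId = "character",
    platformClass = "character",
    probeMap = "ANY",
    isLog2 = "logical"
  )
)

setValidity("ExpressionCohort", function(object) {
  msg <- character()
  m <- object@exprs
  if (!is.numeric(m)) msg <- c(msg, "exprs must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    msg <- c(msg, "exprs must have feature rownames and sample colnames")
  if (anyDuplicated(colnames(m)))
    msg <- c(msg, "duplicate sample ids in cohort")
  if (length(object@cohortId) != 1L || is.na(object@cohortId))
    msg <- c(msg, "cohortId must be a single string")
  if (!object@platformClass %in% .PLATFORM_CLASSES)
    msg <- c(msg, sprintf("platformClass must be one of %s",
                          paste(.PLATFORM_CLASSES, collapse = ", ")))
  pm <- object@probeMap
  if (!is.null(pm)) {
    if (!is.data.frame(pm) || !all(c("probe_id", "gene_id") %in% names(pm)))
      msg <- c(msg, "probeMap must be NULL or a data.frame with probe_id, gene_id")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionCohort
#'
#' @param exprs numeric matrix, features x samples, with dimnames.
#' @param cohortId cohort identifier.
#' @param platformClass `"processed_array"` (default), `"raw_array"` or
#'   `"rnaseq"`.
#' @param probeMap optional data.frame with columns `probe_id`, `gene_id`.
#' @param isLog2 are the values already log2? Default `TRUE`.
#' @return An [ExpressionCohort-class] object.
#' @examples
#' m <- matrix(rnorm(20), 4, 5,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
#' ExpressionCohort(m, "toy")
#' @export
ExpressionCohort <- function(exprs, cohortId,
                             platformClass = "processed_array",
                             probeMap = NULL, isLog2 = TRUE) {
  new("ExpressionCohort", exprs = exprs, cohortId = cohortId,
      platformClass = platformClass, probeMap = probeMap, isLog2 = isLog2)
}

#' PooledCohort: standardized multi-cohort expression matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding the gene-intersected,
#' per-dataset standardized concatenation of several cohorts. The single assay
#' `"exprs"` is in standardized units (per cohort and gene: mean 0, SD 1 over
#' that cohort's reference samples). `colData` carries `dataset` (cohort id of
#' each sample) and `reference` (logical; member of the primary-tumor
#' reference population).
#'
#' @seealso [standardizeAndPool()], [medianSplit()]
#' @exportClass PooledCohort
setClass("PooledCohort", contains = "SummarizedExperiment")

setValidity("PooledCohort", function(object) {
  cd <- colData(object)
  msg <- character()
  if (!all(c("dataset", "reference") %in% names(cd)))
    msg <- c(msg, "colData must contain 'dataset' and 'reference'")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate sample ids")
  if (length(msg)) msg else TRUE
})

#' @rdname PooledCohort-class
#' @param exprs standardized genes x samples matrix with dimnames.
#' @param dataset character vector, cohort id per sample (column).
#' @param reference logical vector, reference-population membership per sample.
#' @return A [PooledCohort-class] object.
#' @export
PooledCohort <- function(exprs, dataset, reference) {
  se <- SummarizedExperiment(
    assays = list(exprs = exprs),
    colData = DataFrame(dataset = as.character(dataset),
                        reference = as.logical(reference),
                        row.names = colnames(exprs))
  )
  new("PooledCohort", se)
}

#' Empirical-Bayes variance prior for the moderated t-statistic
#'
#' The prior is a scaled inverse chi-square on the gene-wise residual
#' variances, parameterized by prior degrees of freedom `d0` (possibly `Inf`)
#' and prior variance `s0Sq`. Estimated by [fitEBPrior()].
#'
#' @slot d0 prior degrees of freedom, `>= 0`, `Inf` allowed.
#' @slot s0Sq prior variance, `> 0`.
#' @exportClass ModeratedTPrior
setClass("ModeratedTPrior",
  representation(d0 = "numeric", s0Sq = "numeric"))

setValidity("ModeratedTPrior", function(object) {
  if (length(object@d0) != 1L || is.na(object@d0) || object@d0 < 0)
    return("d0 must be a single non-negative number (Inf allowed)")
  if (length(object@s0Sq) != 1L || is.na(object@s0Sq) || object@s0Sq <= 0)
    return("s0Sq must be a single positive number")
  TRUE
})

#' @rdname ModeratedTPrior-class
#' @param d0 prior degrees of freedom.
#' @param s0Sq prior variance.
#' @export
ModeratedTPrior <- function(d0, s0Sq) new("ModeratedTPrior", d0 = d0, s0Sq = s0Sq)

#' Selection gates for differential expression
#'
#' Thresholds defining a "significant" gene: raw p-value below `pMax`,
#' Benjamini-Hochberg q-value below `qMax`, and absolute fold change above
#' `fcMin` on the linear scale (i.e. `|log2FC| > log2(fcMin)`).
#'
#' @slot pMax maximum raw p-value (default 0.05).
#' @slot qMax maximum BH q-value (default 0.01).
#' @slot fcMin minimum linear fold change (default 1.25).
#' @exportClass DEConfig
setClass("DEConfig",
  representation(pMax = "numeric", qMax = "numeric", fcMin = "numeric"))

setValidity("DEConfig", function(object) {
  ok1 <- object@pMax > 0 && object@pMax < 1
  ok2 <- object@qMax > 0 && object@qMax < 1
  ok3 <- object@fcMin > 1
  if (!ok1) return("pMax must be in (0, 1)")
  if (!ok2) return("qMax must be in (0, 1)")
  if (!ok3) return("fcMin must be > 1 (linear scale)")
  TRUE
})

#' @rdname DEConfig-class
#' @param pMax,qMax,fcMin see slots.
#' @export
DEConfig <- function(pMax = 0.05, qMax = 0.01, fcMin = 1.25)
  new("DEConfig", pMax = pMax, qMax = qMax, fcMin = fcMin)

#' Per-gene differential expression results
#'
#' @slot results data.frame with one row per gene: `gene`, `log2fc` (mean of
#'   the high class minus mean of the low class, standardized log2 units),
#'   `sSq` (residual variance), `tMod` (moderated t), `dfTotal`, `p`, `q`,
#'   `selected`, `direction` (`"up"`/`"down"`), `flagged` (zero-variance
#'   genes).
#' @slot prior the [ModeratedTPrior-class] used.
#' @slot config the [DEConfig-class] applied by [selectGenes()] (all-NA
#'   `selected` until then).
#' @slot nHigh,nLow class sizes.
#' @exportClass DEResult
setClass("DEResult",
  representation(results = "data.frame", prior = "ModeratedTPrior",
                 config = "DEConfig", nHigh = "integer", nLow = "integer"))

#' Median-centroid metagene signature
#'
#' The "high-like" signature model: the selected gene ids together with the
#' per-gene median of the standardized expression over the high-class learning
#' samples. Independent samples are classified by the sign of their Pearson
#' correlation with this centroid ([classifySamples()]).
#'
#' @slot geneIds ordered character vector of signature genes.
#' @slot centroid named numeric vector, same length/order as `geneIds`.
#' @slot learningSetId identifier of the learning cohort.
#' @exportClass SignatureModel
setClass("SignatureModel",
  representation(geneIds = "character", centroid = "numeric",
                 learningSetId = "character"))

setValidity("SignatureModel", function(object) {
  if (length(object@centroid) != length(object@geneIds))
    return("centroid and geneIds lengths differ")
  if (!all(is.finite(object@centroid)))
    return("centroid must be finite")
  TRUE
})

#' Rule used to dichotomize a gene at the pooled-series median
#'
#' @slot geneId gene that was split.
#' @slot cutoff the median over the pooled tumor (reference) series.
#' @slot tiePolicy `"ties_low"`: samples exactly at the cutoff are "low".
#' @exportClass DiscretizationRule
setClass("DiscretizationRule",
  representation(geneId = "character", cutoff = "numeric",
                 tiePolicy = "character"))

#' 2x2 contingency analysis result
#'
#' @slot table 2x2 integer matrix of counts.
#' @slot oddsRatio point estimate `(a*d)/(b*c)`.
#' @slot ciLow,ciHigh Woolf (log-method) 95% confidence limits.
#' @slot pValue two-sided Fisher exact p.
#' @slot method `"fisher"`.
#' @slot corrected `TRUE` when a zero cell forced the Haldane-Anscombe +0.5
#'   correction for the OR and CI.
#' @exportClass ContingencyResult
setClass("ContingencyResult",
  representation(table = "matrix", oddsRatio = "numeric", ciLow = "numeric",
                 ciHigh = "numeric", pValue = "numeric", method = "character",
                 corrected = "logical"))

# ---- show methods -----------------------------------------------------------

setMethod("show", "ExpressionCohort", function(object) {
  cat(sprintf("ExpressionCohort '%s': %d features x %d samples [%s%s]\n",
              object@cohortId, nrow(object@exprs), ncol(object@exprs),
              object@platformClass,
              if (object@isLog2) ", log2" else ", linear"))
  if (!is.null(object@probeMap))
    cat(sprintf("  probe map: %d entries\n", nrow(object@probeMap)))
})

setMethod("show", "PooledCohort", function(object) {
  cd <- colData(object)
  cat(sprintf("PooledCohort: %d genes x %d samples, %d datasets, %d reference samples\n",
              nrow(object), ncol(object),
              length(unique(cd$dataset)), sum(cd$reference)))
})

setMethod("show", "ModeratedTPrior", function(object) {
  cat(sprintf("ModeratedTPrior: d0 = %s, s0^2 = %.6g\n",
              format(object@d0), object@s0Sq))
})

setMethod("show", "DEResult", function(object) {
  r <- object@results
  nsel <- sum(r$selected, na.rm = TRUE)
  cat(sprintf("DEResult: %d genes (%d high vs %d low); %s selected\n",
              nrow(r), object@nHigh, object@nLow,
              if (all(is.na(r$selected))) "gates not applied," else nsel))
})

setMethod("show", "SignatureModel", function(object) {
  cat(sprintf("SignatureModel: %d genes, learning set '%s'\n",
              length(object@geneIds), object@learningSetId))
})

setMethod("show", "ContingencyResult", function(object) {
  cat(sprintf("ContingencyResult: OR = %.4g [%.4g-%.4g], p = %.3g (%s%s)\n",
              object@oddsRatio, object@ciLow, object@ciHigh, object@pValue,
              object@method,
              if (object@corrected) ", +0.5 corrected" else ""))
})

# ---- accessors --------------------------------------------------------------

#' @describeIn ExpressionCohort-class expression matrix accessor
#' @param x,object an object of the documented class.
#' @export
setGeneric("assayMatrix", function(x) standardGeneric("assayMatrix"))

#' @export
setMethod("assayMatrix", "ExpressionCohort", function(x) x@exprs)

#' @export
setMethod("assayMatrix", "PooledCohort", function(x) assay(x, "exprs"))

#' @describeIn ExpressionCohort-class cohort identifier accessor
#' @export
setGeneric("cohortId", function(x) standardGeneric("cohortId"))

#' @export
setMethod("cohortId", "ExpressionCohort", function(x) x@cohortId)

#' Per-sample dataset ids of a PooledCohort
#' @param x a [PooledCohort-class]
#' @return named character vector, cohort id per sample.
#' @export
datasetOf <- function(x) {
  stopifnot(is(x, "PooledCohort"))
  setNames(colData(x)$dataset, colnames(x))
}

#' Reference-population sample ids of a PooledCohort
#' @param x a [PooledCohort-class]
#' @return character vector of sample ids.
#' @export
referenceSamples <- function(x) {
  stopifnot(is(x, "PooledCohort"))
  colnames(x)[colData(x)$reference]
}

#' Per-gene results table of a DEResult
#' @param x a [DEResult-class]
#' @return data.frame, one row per gene.
#' @export
deTable <- function(x) {
  stopifnot(is(x, "DEResult"))
  x@results
}

#' Genes passing all selection gates, sorted by p-value
#' @param x a [DEResult-class] on which [selectGenes()] has been run.
#' @return data.frame with columns `gene`, `log2fc`, `p`, `q`, `direction`.
#' @export
selectedGenes <- function(x) {
  stopifnot(is(x, "DEResult"))
  r <- x@results
  if (all(is.na(r$selected)))
    stop("selection gates not applied yet; run selectGenes() first")
  out <- r[which(r$selected), c("gene", "log2fc", "p", "q", "direction")]
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Signature gene ids / centroid accessors
#' @param x a [SignatureModel-class]
#' @return `signatureGenes`: character vector; `signatureCentroid`: named
#'   numeric vector.
#' @export
signatureGenes <- function(x) {
  stopifnot(is(x, "SignatureModel"))
  x@geneIds
}

#' @rdname signatureGenes
#' @export
signatureCentroid <- function(x) {
  stopifnot(is(x, "SignatureModel"))
  setNames(x@centroid, x@geneIds)
}

#' Odds ratio / p-value accessors for a ContingencyResult
#' @param x a [ContingencyResult-class]
#' @export
oddsRatio <- function(x) {
  stopifnot(is(x, "ContingencyResult"))
  x@oddsRatio
}

#' @rdname oddsRatio
#' @export
pValue <- function(x) {
  stopifnot(is(x, "ContingencyResult"))
  x@pValue
}

#' @rdname oddsRatio
#' @export
confInt <- function(x) {
  stopifnot(is(x, "ContingencyResult"))
  c(low = x@ciLow, high = x@ciHigh)
}
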