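#' Quantile normalization
#'
#' Forces every column (sample) to share one empirical distribution — the
#' row-wise mean of the column-sorted matrix — while preserving within-column
#' ranks. Ties within a column receive the mean of the reference values their
#' ranks span.
#'
#' @param m numeric matrix, features x samples, no missing values.
#' @return matrix of the same dimensions and dimnames. With fewer than two
#'   columns the input is returned unchanged with a warning.
#' @examples
#' m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
#' quantileNormalize(m)  # both columns become (2.5, 3.5, 4.5)
#' @export
quantileNormalize <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("quantileNormalize: missing values are not allowed")
  if (ncol(m) < 2L) {
    warning("quantileNormalize: fewer than 2 columns, returning input unchanged")
    return(m)
  }
  target <- rowMeans(apply(m, 2L, sort))
  out <- apply(m, 2L, function(col) {
    r <- rank(col, ties.method = "average")
    lo <- target[floor(r)]
    hi <- target[ceiling(r)]
    (lo + hi) / 2
  })
  dimnames(out) <- dimnames(m)
  out
}

#' Log2-transform a linear-scale expression matrix
#'
#' @param m numeric matrix.
#' @param alreadyLog2 if `TRUE` the matrix is returned unchanged.
#' @param offset pseudo-count added before the log (default 1, suitable for
#'   TPM-like RNA-seq values).
#' @return `log2(m + offset)`, or `m` when `alreadyLog2`.
#' @export
log2Transform <- function(m, alreadyLog2 = FALSE, offset = 1) {
  if (alreadyLog2) return(m)
  if (any(m < 0, na.rm = TRUE))
    stop("log2Transform: negative values on the linear scale")
  log2(m + offset)
}

#' Collapse probes to genes by maximal variance
#'
#' When several probes map to one gene, keeps the probe with the largest
#' variance across the cohort's samples (sample variance, n-1 denominator).
#' Probes without a gene mapping are dropped and counted in the
#' `"collapseReport"` attribute of the result. Output rows are gene ids,
#' sorted lexicographically.
#'
#' @param cohort an [ExpressionCohort-class] whose `probeMap` maps its feature
#'   ids to gene ids.
#' @return A gene-level [ExpressionCohort-class] (`probeMap = NULL`), with
#'   `attr(, "collapseReport")`: a list with `nUnmapped`, `nProbes`, `nGenes`.
#' @export
collapseProbes <- function(cohort) {
  stopifnot(is(cohort, "ExpressionCohort"))
  pm <- cohort@probeMap
  if (is.null(pm))
    stop("collapseProbes: cohort has no probeMap")
  m <- cohort@exprs
  pm <- pm[!is.na(pm$gene_id) & nzchar(pm$gene_id), , drop = FALSE]
  mapped <- intersect(rownames(m), pm$probe_id)
  nUnmapped <- nrow(m) - length(mapped)
  if (length(mapped) == 0L)
    stop("collapseProbes: no probe maps to a gene")
  gene <- setNames(pm$gene_id, pm$probe_id)[mapped]
  v <- apply(m[mapped, , drop = FALSE], 1L, var)
  keep <- vapply(split(mapped, gene),
                 function(p) p[which.max(v[p])], character(1))
  genes <- sort(names(keep))
  out <- m[keep[genes], , drop = FALSE]
  rownames(out) <- genes
  res <- ExpressionCohort(out, cohortId = cohort@cohortId,
                          platformClass = cohort@platformClass,
                          probeMap = NULL, isLog2 = cohort@isLog2)
  attr(res, "collapseReport") <- list(nUnmapped = nUnmapped,
                                      nProbes = nrow(m),
                                      nGenes = length(genes))
  res
}

#' Standardize cohorts against a tumor reference and pool them
#'
#' The cross-cohort harmonization step: within each cohort, every gene is
#' centered and scaled by the mean and sample SD computed over that cohort's
#' *reference* samples only (the primary tumor population); normals and any
#' other non-reference samples are transformed with the same parameters, so
#' they stay comparable to the tumors. Genes are restricted to the strict
#' intersection across cohorts. Genes with any missing value in a cohort are
#' excluded from that cohort before intersection; genes with zero reference
#' SD in any cohort are dropped from the pooling run (with a message).
#'
#' @param cohorts list of gene-level [ExpressionCohort-class] objects.
#' @param referenceSampleIds character vector of reference (primary tumor)
#'   sample ids; must intersect every cohort.
#' @return A [PooledCohort-class] in standardized units: for every cohort and
#'   gene, the mean over that cohort's reference samples is 0 and the SD is 1.
#' @export
standardizeAndPool <- function(cohorts, referenceSampleIds) {
  stopifnot(length(cohorts) >= 1L,
            all(vapply(cohorts, is, logical(1), "ExpressionCohort")))
  ids <- vapply(cohorts, cohortId, character(1))
  if (anyDuplicated(ids)) stop("duplicate cohort ids")

  mats <- lapply(cohorts, function(co) {
    m <- co@exprs
    m[!apply(m, 1L, anyNA), , drop = FALSE]
  })
  genes <- sort(Reduce(intersect, lapply(mats, rownames)))
  if (length(genes) == 0L) stop("empty gene intersection across cohorts")

  pieces <- vector("list", length(cohorts))
  dropGenes <- character()
  for (k in seq_along(cohorts)) {
    m <- mats[[k]][genes, , drop = FALSE]
    ref <- intersect(colnames(m), referenceSampleIds)
    if (length(ref) == 0L)
      stop(sprintf("reference set does not intersect cohort '%s'", ids[k]))
    mu <- rowMeans(m[, ref, drop = FALSE])
    sdv <- apply(m[, ref, drop = FALSE], 1L, sd)
    dropGenes <- union(dropGenes, genes[!is.finite(sdv) | sdv == 0])
    pieces[[k]] <- list(m = m, mu = mu, sd = sdv, ref = ref)
  }
  if (length(dropGenes)) {
    message(sprintf("standardizeAndPool: dropping %d gene(s) with zero reference SD: %s",
                    length(dropGenes),
                    paste(head(dropGenes, 5), collapse = ", ")))
    genes <- setdiff(genes, dropGenes)
    if (length(genes) == 0L) stop("no genes left after zero-SD filtering")
  }

  std <- lapply(seq_along(pieces), function(k) {
    p <- pieces[[k]]
    (p$m[genes, , drop = FALSE] - p$mu[genes]) / p$sd[genes]
  })
  pooled <- do.call(cbind, std)
  if (anyDuplicated(colnames(pooled)))
    stop("duplicate sample ids across cohorts")
  dataset <- rep(ids, times = vapply(std, ncol, integer(1)))
  reference <- colnames(pooled) %in% referenceSampleIds
  out <- PooledCohort(pooled, dataset = dataset, reference = reference)
  metadata(out)$standardized <- TRUE
  out
}

#' Split a PooledCohort back into per-dataset cohorts
#'
#' Convenience inverse of [standardizeAndPool()] (in structure, not in
#' units): returns one [ExpressionCohort-class] per dataset id, carrying the
#' standardized values. Useful for re-standardization checks and for
#' classifying validation cohorts separately.
#'
#' @param pooled a [PooledCohort-class].
#' @return named list of [ExpressionCohort-class] objects.
#' @export
asCohortList <- function(pooled) {
  stopifnot(is(pooled, "PooledCohort"))
  ds <- datasetOf(pooled)
  m <- assayMatrix(pooled)
  out <- lapply(unique(ds), function(d) {
    ExpressionCohort(m[, names(ds)[ds == d], drop = FALSE], cohortId = d,
                     platformClass = "processed_array", isLog2 = TRUE)
  })
  names(out) <- unique(ds)
  out
}

#' Subset a PooledCohort by sample ids
#'
#' Keeps colData in step; the standardized values are untouched.
#'
#' @param pooled a [PooledCohort-class].
#' @param sampleIds samples to keep.
#' @return a [PooledCohort-class].
#' @export
subsetSamples <- function(pooled, sampleIds) {
  stopifnot(is(pooled, "PooledCohort"))
  missing <- setdiff(sampleIds, colnames(pooled))
  if (length(missing))
    stop(sprintf("unknown sample ids: %s",
                 paste(head(missing, 5), collapse = ", ")))
  pooled[, sampleIds]
}
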