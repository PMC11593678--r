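#' Build the high-class median centroid
#'
#' The metagene model: for each selected gene, the median of its standardized
#' expression over the high-class samples of the learning set. With
#' `method = "difference"` the centroid is instead the high-class median minus
#' the low-class median (a sensitivity-analysis variant).
#'
#' @param pooled a [PooledCohort-class] restricted to (or containing) the
#'   learning set.
#' @param labels named factor/character (`low`/`high`) over the learning
#'   samples; at least one `high` sample required.
#' @param genes character vector of signature genes (typically
#'   `selectedGenes(de)$gene`).
#' @param learningSetId identifier stored with the model.
#' @param method `"high_median"` (default) or `"difference"`.
#' @return a [SignatureModel-class].
#' @export
buildCentroid <- function(pooled, labels, genes,
                          learningSetId = "learning",
                          method = c("high_median", "difference")) {
  method <- match.arg(method)
  m <- if (is(pooled, "PooledCohort")) assayMatrix(pooled) else as.matrix(pooled)
  missing <- setdiff(genes, rownames(m))
  if (length(missing))
    stop(sprintf("buildCentroid: genes missing from matrix: %s",
                 paste(missing, collapse = ", ")))
  labels <- labels[!is.na(labels)]
  common <- intersect(colnames(m), names(labels))
  lab <- as.character(labels[common])
  hi <- common[lab == "high"]
  if (length(hi) == 0L) stop("buildCentroid: no high-labeled samples")
  cen <- apply(m[genes, hi, drop = FALSE], 1L, median)
  if (method == "difference") {
    lo <- common[lab == "low"]
    if (length(lo) == 0L) stop("buildCentroid: no low-labeled samples")
    cen <- cen - apply(m[genes, lo, drop = FALSE], 1L, median)
  }
  new("SignatureModel", geneIds = genes, centroid = unname(cen),
      learningSetId = learningSetId)
}

#' Classify samples by correlation with the centroid
#'
#' Each sample's standardized expression over the signature genes is
#' correlated (Pearson) with the centroid; the sample is called
#' `"high_like"` when r > 0 and `"low_like"` otherwise (r = 0 inclusive, a
#' deterministic tie-break for a measure-zero event). Genes are matched by
#' id; samples may be missing up to `maxMissingFrac` of the model genes, in
#' which case the correlation uses the intersection. A sample that is
#' constant over the signature genes is called `"low_like"` with r recorded
#' as 0 and flagged.
#'
#' @param model a [SignatureModel-class].
#' @param pooled a [PooledCohort-class] (standardized per its own datasets)
#'   or a plain genes x samples matrix.
#' @param maxMissingFrac maximum tolerated fraction of model genes absent
#'   from the matrix (default 0.1).
#' @return data.frame with columns `sample_id`, `r`, `label`
#'   (`high_like`/`low_like`), `flagged`.
#' @export
classifySamples <- function(model, pooled, maxMissingFrac = 0.1) {
  stopifnot(is(model, "SignatureModel"))
  m <- if (is(pooled, "PooledCohort")) assayMatrix(pooled) else as.matrix(pooled)
  present <- intersect(model@geneIds, rownames(m))
  missFrac <- 1 - length(present) / length(model@geneIds)
  if (missFrac > maxMissingFrac)
    stop(sprintf(
      "classifySamples: %.0f%% of model genes missing (max %.0f%%)",
      100 * missFrac, 100 * maxMissingFrac))
  cen <- signatureCentroid(model)[present]
  if (sd(cen) == 0)
    stop("classifySamples: degenerate (constant) centroid")
  sub <- m[present, , drop = FALSE]
  r <- vapply(seq_len(ncol(sub)), function(j) {
    x <- sub[, j]
    if (sd(x) == 0) NA_real_ else cor(x, cen)
  }, numeric(1))
  flagged <- is.na(r)
  r[flagged] <- 0
  data.frame(sample_id = colnames(sub), r = r,
             label = ifelse(r > 0, "high_like", "low_like"),
             flagged = flagged, stringsAsFactors = FALSE)
}
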