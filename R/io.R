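#' Read / write expression matrices as TSV
#'
#' The tab-delimited interchange format: first column holds feature ids
#' (header `gene_id` on write, any name on read), remaining columns one
#' sample each.
#'
#' @param path file path.
#' @return `readExpressionTSV`: numeric matrix with feature rownames and
#'   sample colnames.
#' @export
readExpressionTSV <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression TSV needs an id column plus samples")
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1L]])
  m
}

#' @rdname readExpressionTSV
#' @param m numeric matrix with dimnames.
#' @export
writeExpressionTSV <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write GCT 1.2 expression files
#'
#' The Broad GCT 1.2 layout: `#1.2`, a dimensions line, then a table with
#' `Name` and `Description` columns followed by one column per sample.
#'
#' @param path file path.
#' @return `readGCT`: numeric matrix (rownames = `Name` column).
#' @export
readGCT <- function(path) {
  header <- readLines(path, n = 2L)
  if (!startsWith(header[1L], "#1.2"))
    stop("not a GCT 1.2 file (missing '#1.2' header)")
  dims <- as.integer(strsplit(header[2L], "\t")[[1L]][1:2])
  df <- read.delim(path, skip = 2L, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1L]])
  if (nrow(m) != dims[1L] || ncol(m) != dims[2L])
    warning("GCT dimension line disagrees with table; using the table")
  m
}

#' @rdname readGCT
#' @param m numeric matrix with dimnames.
#' @param description optional per-feature description column.
#' @export
writeGCT <- function(m, path, description = rownames(m)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(m), ncol(m), sep = "\t")), con)
  df <- data.frame(Name = rownames(m), Description = description, m,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column probe map (probe_id, gene_id)
#' @param path TSV path; first two columns are used.
#' @return data.frame with columns `probe_id`, `gene_id`.
#' @export
readProbeMap <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("probe map needs two columns")
  data.frame(probe_id = as.character(df[[1L]]),
             gene_id = as.character(df[[2L]]), stringsAsFactors = FALSE)
}

#' Read a clinical annotation table
#'
#' Tab-delimited, one row per sample; must contain `sample_id`. Survival
#' endpoint columns follow the `os_time`/`os_event`/`pfs_time`/`pfs_event`
#' convention in months.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
readClinicalTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df))
    stop("clinical table must have a 'sample_id' column")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in clinical table")
  df
}

#' Persist / restore a SignatureModel as JSON
#'
#' @param model a [SignatureModel-class].
#' @param path JSON path.
#' @return `writeSignatureModel`: the path, invisibly; `readSignatureModel`:
#'   the model.
#' @export
writeSignatureModel <- function(model, path) {
  stopifnot(is(model, "SignatureModel"))
  jsonlite::write_json(
    list(gene_ids = model@geneIds,
         centroid = unname(model@centroid),
         learning_set_id = model@learningSetId),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSignatureModel
#' @export
readSignatureModel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("SignatureModel", geneIds = x$gene_ids,
      centroid = as.numeric(x$centroid),
      learningSetId = x$learning_set_id)
}
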