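#' Expression bundle: log2 matrix plus aligned sample metadata
#'
#' The unit of data flowing through the pipeline: a genes x samples matrix of
#' log2-scale intensities together with one metadata record per sample
#' (cohort, diagnostic group, batch, clinical covariates, optional traits).
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids). All values must be finite.
#' @param metadata data.frame with one row per sample. Must contain a
#'   `sample` column matching `colnames(values)` (same order after
#'   alignment), and normally `cohort`, `group`, `batch`; clinical columns
#'   (`fructosamine`, `glucose`, `insulin`) and trait columns are optional.
#'
#' @return An object of class `expression_bundle`: a list with elements
#'   `values` (matrix) and `metadata` (data.frame, rows aligned to columns
#'   of `values`).
#' @export
#' @examples
#' m <- matrix(rnorm(6), 2, 3, dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' md <- data.frame(sample = c("s1", "s2", "s3"), group = c("ND", "ND", "T2D"))
#' b <- expression_bundle(m, md)
expression_bundle <- function(values, metadata) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids")
  if (!all(is.finite(values)))
    stop("`values` contains non-finite entries")
  if (!is.data.frame(metadata) || is.null(metadata$sample))
    stop("`metadata` must be a data.frame with a `sample` column")
  if (!setequal(metadata$sample, colnames(values)))
    stop("sample ids in metadata and matrix do not match")
  metadata <- metadata[match(colnames(values), metadata$sample), , drop = FALSE]
  rownames(metadata) <- NULL
  structure(list(values = values, metadata = metadata),
            class = "expression_bundle")
}

#' @export
print.expression_bundle <- function(x, ...) {
  cat(sprintf("expression_bundle: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$metadata$group))
    print(table(group = x$metadata$group))
  invisible(x)
}

#' @export
dim.expression_bundle <- function(x) dim(x$values)

#' Subset a bundle by genes and/or samples
#'
#' @param bundle an [expression_bundle()].
#' @param genes character vector of gene ids to keep (default all).
#' @param samples character vector of sample ids to keep (default all).
#' @return the subsetted `expression_bundle`.
#' @export
subset_bundle <- function(bundle, genes = rownames(bundle$values),
                          samples = colnames(bundle$values)) {
  stopifnot(inherits(bundle, "expression_bundle"))
  missing_g <- setdiff(genes, rownames(bundle$values))
  if (length(missing_g))
    stop("genes not in bundle: ", paste(utils::head(missing_g, 5), collapse = ", "))
  missing_s <- setdiff(samples, colnames(bundle$values))
  if (length(missing_s))
    stop("samples not in bundle: ", paste(utils::head(missing_s, 5), collapse = ", "))
  expression_bundle(bundle$values[genes, samples, drop = FALSE],
                    bundle$metadata[match(samples, bundle$metadata$sample), , drop = FALSE])
}
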