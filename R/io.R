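#' Read a log2 expression matrix from TSV
#'
#' Expects a header row of sample ids and a first column of gene ids.
#' Malformed input (ragged rows, non-numeric cells, duplicated gene ids) is
#' rejected rather than silently coerced.
#'
#' @param path path to a tab-separated file.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = NA)
  if (ncol(df) < 2) stop("expression TSV needs a gene id column plus >=1 sample")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate gene ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- colnames(mat)[!vapply(seq_len(ncol(mat)),
                                 function(j) is.numeric(df[[j + 1]]), logical(1))]
    stop("non-numeric expression values in column(s): ",
         paste(bad, collapse = ", "))
  }
  rownames(mat) <- ids
  mat
}

#' Write a log2 expression matrix to TSV
#'
#' Inverse of [read_expression_matrix()]; values are written with enough
#' digits (15 significant) that a write/read roundtrip is loss-free to at
#' least 12 significant digits.
#'
#' @param mat numeric matrix with dimnames.
#' @param path output path.
#' @param id_column name for the first (gene id) column.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path, id_column = "gene") {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  df <- data.frame(rownames(mat), signif(mat, 15), check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(id_column, colnames(mat))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' @param path TSV with a header; must contain a `sample` column.
#' @return data.frame.
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (is.null(md$sample)) stop("metadata must contain a `sample` column")
  if (anyDuplicated(md$sample)) stop("duplicate sample ids in metadata")
  md
}

#' Write a data.frame as TSV
#'
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then members. Duplicate members within a line collapse (set semantics);
#' empty sets are dropped with a warning; lines with fewer than three
#' fields are an error.
#'
#' @param path path to a GMT file.
#' @return named list of character vectors (unique member ids); the
#'   `description` attribute on each element carries the second field.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("GMT line with <3 fields: ", substr(ln, 1, 60))
    members <- unique(f[-(1:2)][nzchar(f[-(1:2)])])
    if (!length(members)) {
      warning("empty gene set dropped: ", f[1])
      next
    }
    attr(members, "description") <- f[2]
    sets[[f[1]]] <- members
  }
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm) {
    desc <- attr(sets[[nm]], "description")
    if (is.null(desc)) desc <- "na"
    paste(c(nm, desc, unique(as.character(sets[[nm]]))), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a signed TF -> target edge list
#'
#' Three tab-separated columns: regulator, target, sign. Signs may be given
#' numerically (`+1`/`-1`/`1`) or as words (`activation`/`repression`).
#' Duplicate (tf, target) pairs with agreeing signs collapse to one edge;
#' conflicting duplicates are an error.
#'
#' @param path TSV path (a header line `tf  target  sign` is detected and
#'   skipped).
#' @return data.frame with columns `tf`, `target`, `sign` (integer +1/-1).
#' @export
read_edge_list <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) != 3) stop("edge list must have exactly 3 columns")
  colnames(df) <- c("tf", "target", "sign")
  if (identical(tolower(as.character(df$tf[1])), "tf"))
    df <- df[-1, , drop = FALSE]
  tok <- tolower(trimws(as.character(df$sign)))
  sign <- ifelse(tok %in% c("+1", "1", "activation"), 1L,
          ifelse(tok %in% c("-1", "repression"), -1L, NA_integer_))
  if (anyNA(sign))
    stop("invalid sign token(s): ",
         paste(unique(tok[is.na(sign)]), collapse = ", "))
  edges <- data.frame(tf = as.character(df$tf), target = as.character(df$target),
                      sign = sign, stringsAsFactors = FALSE)
  key <- paste(edges$tf, edges$target, sep = "\r")
  agg <- tapply(edges$sign, key, function(s) length(unique(s)))
  conflicts <- names(agg)[agg > 1]
  if (length(conflicts))
    stop("conflicting signs for edge(s): ",
         paste(gsub("\r", " -> ", conflicts), collapse = ", "))
  edges[!duplicated(key), , drop = FALSE]
}

#' Write a signed edge list to TSV
#'
#' @param edges data.frame with columns `tf`, `target`, `sign`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  stopifnot(all(c("tf", "target", "sign") %in% colnames(edges)))
  utils::write.table(edges[, c("tf", "target", "sign")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}
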