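#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie adjusted Rand index from the contingency table of two
#' label vectors; 1 for identical partitions (up to label renaming), ~0
#' for independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return the adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (maxi - expected)
}

#' Precision/recall of the recovered concordant signature
#'
#' Compares a [concordant_signature()] call against the generator truth:
#' the positive class is the planted concordant gene set.
#'
#' @param signature a `signature_table` (or character vector of recovered
#'   concordant genes).
#' @param truth the `truth` element of [simulate_cohorts()].
#' @return list with `precision`, `recall`, `n_true`, `n_called`,
#'   `n_correct`.
#' @export
evaluate_signature_recovery <- function(signature, truth) {
  called <- if (inherits(signature, "signature_table"))
    signature$table$gene[signature$table$concordant]
  else as.character(signature)
  true_set <- truth$signature_genes$gene[
    truth$signature_genes$scope == "concordant"]
  n_correct <- length(intersect(called, true_set))
  list(precision = if (length(called)) n_correct / length(called) else NA_real_,
       recall = if (length(true_set)) n_correct / length(true_set) else NA_real_,
       n_true = length(true_set), n_called = length(called),
       n_correct = n_correct)
}

#' Precision/recall of recovered active regulators
#'
#' @param tfs character vector of regulator ids retained in a network.
#' @param truth the `truth` element of [simulate_cohorts()].
#' @return list with `precision`, `recall`.
#' @export
evaluate_regulator_recovery <- function(tfs, truth) {
  true_set <- truth$active_regulators$tf
  n_correct <- length(intersect(tfs, true_set))
  list(precision = if (length(tfs)) n_correct / length(tfs) else NA_real_,
       recall = if (length(true_set)) n_correct / length(true_set) else NA_real_)
}
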