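#' Upper-tail hypergeometric overlap probability
#'
#' `P(X >= k)` for the overlap of a size-`K` list and a size-`n` list drawn
#' from a universe of `N` genes (inclusive upper tail, the standard
#' over-representation convention). Computed via the stable log-space
#' hypergeometric tail in [stats::phyper()].
#'
#' @param k observed overlap.
#' @param K size of list A.
#' @param n size of list B.
#' @param N background universe size.
#' @return the upper-tail probability; `1` exactly when `k = 0`.
#' @export
#' @examples
#' hypergeom_tail(2, 4, 3, 10)  # 1/3
hypergeom_tail <- function(k, K, n, N) {
  stopifnot(k >= 0, K >= 0, n >= 0, N >= 1, K <= N, n <= N)
  if (k > min(K, n)) stop("inconsistent counts: k exceeds min(K, n)")
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Cross-cohort concordant signature
#'
#' Merges two called DE tables (identical thresholds assumed): the overlap
#' is the set of genes called in both cohorts; an overlap gene is
#' concordant iff `sign(ratio_od - 1) == sign(ratio_ppp - 1)`. Concordant
#' genes form the signature; discordant ones are reported but excluded.
#'
#' @param de_od,de_ppp called DE tables (from [call_de()]) with columns
#'   `gene`, `ratio`, `q`, `called`. Gene ids must be unique per table
#'   (collapse probes first, see [collapse_by_gene()]).
#' @return list of class `signature_table`: `table` (per overlap gene:
#'   `gene`, `od_ratio`, `ppp_ratio`, `od_q`, `ppp_q`, `direction_od`,
#'   `direction_ppp`, `concordant`) and `summary` (`n_overlap`,
#'   `n_concordant`, `n_down`, `n_up`, `n_discordant`).
#' @export
concordant_signature <- function(de_od, de_ppp) {
  for (tab in list(de_od, de_ppp)) {
    stopifnot(all(c("gene", "ratio", "q", "called") %in% colnames(tab)))
    if (anyDuplicated(tab$gene))
      stop("duplicate gene ids after collapsing: ",
           paste(unique(tab$gene[duplicated(tab$gene)]), collapse = ", "))
  }
  a <- de_od[de_od$called, c("gene", "ratio", "q")]
  b <- de_ppp[de_ppp$called, c("gene", "ratio", "q")]
  tab <- merge(a, b, by = "gene", suffixes = c("_od", "_ppp"))
  names(tab) <- c("gene", "od_ratio", "od_q", "ppp_ratio", "ppp_q")
  tab <- tab[, c("gene", "od_ratio", "ppp_ratio", "od_q", "ppp_q")]
  tab$direction_od <- ifelse(tab$od_ratio < 1, "down", "up")
  tab$direction_ppp <- ifelse(tab$ppp_ratio < 1, "down", "up")
  tab$concordant <- sign(tab$od_ratio - 1) == sign(tab$ppp_ratio - 1)
  tab <- tab[order(tab$gene), , drop = FALSE]
  rownames(tab) <- NULL
  summary <- list(n_overlap = nrow(tab),
                  n_concordant = sum(tab$concordant),
                  n_down = sum(tab$concordant & tab$direction_od == "down"),
                  n_up = sum(tab$concordant & tab$direction_od == "up"),
                  n_discordant = sum(!tab$concordant))
  structure(list(table = tab, summary = summary), class = "signature_table")
}

#' @export
print.signature_table <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("signature_table: %d overlap genes; %d concordant ",
                     "(%d down, %d up), %d discordant\n"),
              s$n_overlap, s$n_concordant, s$n_down, s$n_up, s$n_discordant))
  invisible(x)
}

#' Hypergeometric test of the overlap of two DE lists
#'
#' @param k observed overlap count.
#' @param K,n sizes of the two DE lists.
#' @param N background universe of expressed genes.
#' @return list (`k`, `K`, `n`, `N`, `p`) with the inclusive upper-tail p.
#' @export
overlap_test <- function(k, K, n, N) {
  list(k = k, K = K, n = n, N = N, p = hypergeom_tail(k, K, n, N))
}

#' Condition-wise fold-change profile of the signature genes
#'
#' For each condition's DE table (all sharing the non-diabetic reference),
#' extracts the linear ratio of every signature gene, plus per-condition
#' counts of genes with `max(ratio, 1/ratio)` above a reporting threshold
#' (default 1.2). A gene absent from a condition table is recorded as `NA`
#' (missing), never imputed.
#'
#' @param signature a [concordant_signature()] result (or a character
#'   vector of signature gene ids).
#' @param de_tables named list of condition DE tables (columns `gene`,
#'   `ratio`).
#' @param report_threshold linear fold-change reporting threshold (> 1).
#' @return list with `profile` (genes x conditions ratio matrix) and
#'   `n_above` (named per-condition counts above the threshold).
#' @export
signature_condition_profile <- function(signature, de_tables,
                                        report_threshold = 1.2) {
  stopifnot(report_threshold > 1)
  genes <- if (inherits(signature, "signature_table"))
    signature$table$gene[signature$table$concordant] else as.character(signature)
  if (!length(genes))
    return(list(profile = matrix(numeric(0), 0, length(de_tables),
                                 dimnames = list(NULL, names(de_tables))),
                n_above = stats::setNames(integer(length(de_tables)),
                                          names(de_tables))))
  profile <- sapply(de_tables, function(tab) {
    tab$ratio[match(genes, tab$gene)]
  })
  profile <- matrix(profile, nrow = length(genes),
                    dimnames = list(genes, names(de_tables)))
  n_above <- apply(profile, 2, function(r) {
    sum(pmax(r, 1 / r) > report_threshold, na.rm = TRUE)
  })
  list(profile = profile, n_above = n_above)
}
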