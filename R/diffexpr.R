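#' Empirical-Bayes moderated two-group t-test
#'
#' Per gene, an ordinary two-group fit gives the log2 mean difference
#' `beta_g` (groupB - groupA), pooled residual variance `s2_g` and residual
#' df `d_g = n1 + n2 - 2`. Across genes the variances are modelled as
#' scaled inverse-chi-square draws with prior df `d0` and prior variance
#' `s02`; `(d0, s02)` are estimated by matching the first two moments of
#' `log s2_g` using the digamma/trigamma closed forms, inverting the
#' trigamma function by Newton iteration (tolerance 1e-8). The posterior
#' variance `s2_tilde = (d0 s02 + d_g s2_g) / (d0 + d_g)` yields the
#' moderated statistic `t = beta / (s_tilde sqrt(1/n1 + 1/n2))` with
#' `d0 + d_g` df; `d0 = Inf` (no excess dispersion of the log variances)
#' collapses every `s2_tilde` to `s02` and uses the normal reference.
#'
#' @param bundle an [expression_bundle()].
#' @param contrast length-2 character vector `c(groupA, groupB)`; the
#'   reported effect is mean(log2 B) - mean(log2 A), e.g. `c("ND", "T2D")`
#'   for a diabetes-vs-control ratio.
#' @param prior_df optionally force the prior df: `0` recovers the
#'   classical pooled t-test, `Inf` the common-variance z-statistic.
#' @return list of class `moderated_result`: `table` (data.frame with
#'   `gene`, `effect` (log2), `ratio` (linear `2^effect`), `s2`, `df`,
#'   `t`, `p`, `q`, `zero_variance` flag) and `prior` (`d0`, `s02`).
#' @export
moderated_ttest <- function(bundle, contrast = c("ND", "T2D"),
                            prior_df = NULL) {
  stopifnot(inherits(bundle, "expression_bundle"), length(contrast) == 2)
  grp <- bundle$metadata$group
  iA <- which(grp == contrast[1]); iB <- which(grp == contrast[2])
  n1 <- length(iA); n2 <- length(iB)
  if (n1 < 2 || n2 < 2)
    stop("need >= 2 samples per group (", contrast[1], ": ", n1, ", ",
         contrast[2], ": ", n2, ")")
  Y <- bundle$values
  mA <- rowMeans(Y[, iA, drop = FALSE]); mB <- rowMeans(Y[, iB, drop = FALSE])
  effect <- mB - mA
  df <- n1 + n2 - 2
  ssA <- rowSums((Y[, iA, drop = FALSE] - mA)^2)
  ssB <- rowSums((Y[, iB, drop = FALSE] - mB)^2)
  s2 <- (ssA + ssB) / df

  if (is.null(prior_df)) {
    fit <- fit_variance_prior(s2, df)
    d0 <- fit$d0; s02 <- fit$s02
  } else {
    d0 <- prior_df
    s02 <- if (is.finite(prior_df) && prior_df > 0)
      fit_variance_prior(s2, df)$s02 else mean(s2)
  }

  zero_var <- s2 <= 0
  if (is.infinite(d0)) {
    s2_tilde <- rep(s02, length(s2))
    tdf <- Inf
  } else if (d0 == 0) {
    s2_tilde <- s2
    tdf <- df
  } else {
    s2_tilde <- (d0 * s02 + df * s2) / (d0 + df)
    tdf <- d0 + df
  }
  se <- sqrt(s2_tilde * (1 / n1 + 1 / n2))
  t <- effect / se
  p <- 2 * stats::pt(-abs(t), df = tdf)
  # zero-variance genes with no moderation: infinite t, p = 0, flagged
  bad <- zero_var & s2_tilde <= 0
  if (any(bad)) {
    t[bad] <- sign(effect[bad]) * Inf
    p[bad] <- 0
  }
  tab <- data.frame(gene = rownames(Y), effect = effect, ratio = 2^effect,
                    s2 = s2, df = df, t = t, p = p, q = bh_adjust(p),
                    zero_variance = zero_var,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab,
                 prior = list(d0 = d0, s02 = s02, n1 = n1, n2 = n2)),
            class = "moderated_result")
}

#' @export
print.moderated_result <- function(x, ...) {
  cat(sprintf("moderated_result: %d genes, n = %d/%d, d0 = %.3g, s02 = %.3g\n",
              nrow(x$table), x$prior$n1, x$prior$n2, x$prior$d0, x$prior$s02))
  invisible(x)
}

# Moment-matching estimator of the scaled inverse-chi-square variance prior.
# e_g = log s2_g - digamma(d/2) + log(d/2) has mean log s02 - digamma(d0/2)
# + log(d0/2) and across-gene variance trigamma(d/2) + trigamma(d0/2).
fit_variance_prior <- function(s2, df) {
  ok <- s2 > 0
  if (sum(ok) < 2) stop("too few positive variances to fit a prior")
  e <- log(s2[ok]) - digamma(df / 2) + log(df / 2)
  excess <- stats::var(e) - trigamma(df / 2)
  if (!is.finite(excess) || excess <= 0)
    return(list(d0 = Inf, s02 = exp(mean(e))))
  d0 <- 2 * trigamma_inverse(excess)
  s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

# Newton inversion of trigamma(x) = y, tolerance 1e-8 on the step.
trigamma_inverse <- function(y) {
  stopifnot(y > 0)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif) < 1e-8) break
  }
  x
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment `q_(i) = min_{j >= i} min(1, p_(j) m / j)` on the
#' sorted p-values; order-preserving, ties share a q. Input outside [0, 1]
#' is an error.
#'
#' @param pvalues numeric vector of p-values.
#' @return adjusted q-values, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (any(!is.na(pvalues) & (pvalues < 0 | pvalues > 1)))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Call differentially expressed genes
#'
#' A gene is called iff `q <= fdr` and `max(ratio, 1/ratio) >= fold_change`
#' (linear-scale ratio `2^effect`); direction is `down` for ratio < 1,
#' `up` otherwise. The returned table is sorted by q.
#'
#' @param result a [moderated_ttest()] result (or its `table`).
#' @param fdr FDR threshold in (0, 1).
#' @param fold_change linear fold-change threshold, > 1.
#' @return the result table with added `direction` and `called` columns,
#'   sorted by `q`.
#' @export
call_de <- function(result, fdr = 0.05, fold_change = 1.5) {
  stopifnot(fdr > 0, fdr < 1, fold_change > 1)
  tab <- if (inherits(result, "moderated_result")) result$table else result
  if (!nrow(tab)) {
    tab$direction <- character(0); tab$called <- logical(0)
    return(tab)
  }
  tab$direction <- ifelse(tab$ratio < 1, "down", "up")
  tab$called <- tab$q <= fdr & pmax(tab$ratio, 1 / tab$ratio) >= fold_change
  tab[order(tab$q), , drop = FALSE]
}

#' Collapse a probe-level DE table to gene level
#'
#' When several probes map to one gene, the probe with the smallest q
#' represents the gene (standard convention for gene-level counting).
#'
#' @param de_table a DE table with a `probe` identifier column and a
#'   `gene` column giving the mapped gene symbol, plus a `q` column.
#' @return one row per gene (smallest q), same columns.
#' @export
collapse_by_gene <- function(de_table) {
  stopifnot(all(c("gene", "q") %in% colnames(de_table)))
  de_table <- de_table[order(de_table$q), , drop = FALSE]
  out <- de_table[!duplicated(de_table$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
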