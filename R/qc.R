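#' Expression filter: retained genes
#'
#' A gene is retained iff, in at least one diagnostic group, its intensity
#' strictly exceeds tau in at least `sample_fraction` of that group's
#' samples, where tau is the pooled `quantile` (default 75th percentile) of
#' all intensities in the cohort. With a constant matrix tau equals the
#' constant and the strict inequality retains nothing.
#'
#' @param bundle an [expression_bundle()].
#' @param quantile pooled intensity quantile defining tau, in (0, 1).
#' @param sample_fraction required fraction of a group's samples, in (0, 1].
#' @param groups grouping vector (defaults to `metadata$group`).
#' @return character vector of retained gene ids.
#' @export
filter_expressed <- function(bundle, quantile = 0.75, sample_fraction = 0.25,
                             groups = bundle$metadata$group) {
  stopifnot(inherits(bundle, "expression_bundle"),
            quantile > 0, quantile < 1,
            sample_fraction > 0, sample_fraction <= 1)
  if (is.null(groups) || !length(groups)) stop("empty grouping")
  if (length(groups) != ncol(bundle$values))
    stop("grouping length must match the number of samples")
  tau <- stats::quantile(bundle$values, probs = quantile, names = FALSE)
  keep <- rep(FALSE, nrow(bundle$values))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (!length(idx)) next
    frac <- rowMeans(bundle$values[, idx, drop = FALSE] > tau)
    keep <- keep | (frac >= sample_fraction)
  }
  rownames(bundle$values)[keep]
}

#' Sample exclusion rules
#'
#' Flags (a) samples without a diabetes history (groups ND and IGT) whose
#' blood fructosamine exceeds `fructosamine_max` (umol/l) or glucose
#' exceeds `glucose_max` (mmol/l); and (b) samples whose insulin measure
#' falls more than `insulin_sd` SDs below the mean of their
#' (cohort, group) stratum -- low secretors. A sample missing the fields a
#' rule needs is skipped for that rule with a warning, never silently
#' excluded. The operation is idempotent and order-independent.
#'
#' @param metadata per-sample data.frame with `sample`, `group` and,
#'   where available, `cohort`, `fructosamine`, `glucose`, `insulin`.
#' @param fructosamine_max,glucose_max,insulin_sd thresholds (see
#'   [analysis_config()]).
#' @return data.frame with columns `sample`, `reason`
#'   (`fructosamine` | `glucose` | `insulin`); zero rows if nothing is
#'   flagged. A sample may appear once per triggered rule.
#' @export
exclude_samples <- function(metadata, fructosamine_max = 285,
                            glucose_max = 11.1, insulin_sd = 1) {
  stopifnot(fructosamine_max > 0, glucose_max > 0, insulin_sd > 0)
  out <- data.frame(sample = character(0), reason = character(0),
                    stringsAsFactors = FALSE)
  if (!nrow(metadata)) return(out)
  if (is.null(metadata$group)) stop("metadata must contain `group`")
  no_hist <- metadata$group %in% c("ND", "IGT")

  flag <- function(field, threshold, reason) {
    v <- metadata[[field]]
    if (is.null(v)) {
      warning("metadata lacks `", field, "`; ", reason, " rule skipped")
      return(NULL)
    }
    miss <- no_hist & is.na(v)
    if (any(miss))
      warning(sum(miss), " sample(s) missing `", field,
              "`; skipped for the ", reason, " rule")
    hit <- no_hist & !is.na(v) & v > threshold
    if (any(hit)) data.frame(sample = metadata$sample[hit], reason = reason,
                             stringsAsFactors = FALSE)
  }
  out <- rbind(out, flag("fructosamine", fructosamine_max, "fructosamine"),
               flag("glucose", glucose_max, "glucose"))

  if (is.null(metadata$insulin)) {
    warning("metadata lacks `insulin`; insulin rule skipped")
  } else {
    strat <- if (is.null(metadata$cohort)) metadata$group
             else paste(metadata$cohort, metadata$group)
    for (s in unique(strat)) {
      idx <- which(strat == s & !is.na(metadata$insulin))
      if (length(idx) < 2) next
      v <- metadata$insulin[idx]
      low <- v < mean(v) - insulin_sd * stats::sd(v)
      if (any(low))
        out <- rbind(out, data.frame(sample = metadata$sample[idx][low],
                                     reason = "insulin",
                                     stringsAsFactors = FALSE))
    }
    miss <- is.na(metadata$insulin)
    if (any(miss))
      warning(sum(miss), " sample(s) missing `insulin`; skipped for the insulin rule")
  }
  rownames(out) <- NULL
  out
}

#' Exocrine/ductal contamination marker check
#'
#' Scores each sample by the mean log2 expression of each marker set and
#' compares the scores between cohorts with a two-sided Welch two-sample
#' t test.
#'
#' @param bundle an [expression_bundle()] holding the pooled samples
#'   (metadata must carry `cohort`).
#' @param marker_sets named list of character vectors of marker genes;
#'   each must intersect the bundle's gene universe.
#' @return list with `scores` (samples x sets matrix), `by_group`
#'   (data.frame of per-(set, cohort) mean and SD) and `comparison`
#'   (per-set estimated cohort difference, 95% CI and p value).
#' @export
contamination_check <- function(bundle, marker_sets) {
  stopifnot(inherits(bundle, "expression_bundle"), is.list(marker_sets))
  cohort <- bundle$metadata$cohort
  if (is.null(cohort) || length(unique(cohort)) != 2)
    stop("contamination_check needs exactly two cohorts in metadata$cohort")
  scores <- sapply(names(marker_sets), function(nm) {
    g <- intersect(marker_sets[[nm]], rownames(bundle$values))
    if (!length(g))
      stop("marker set `", nm, "` is disjoint from the gene universe")
    colMeans(bundle$values[g, , drop = FALSE])
  })
  scores <- matrix(scores, ncol = length(marker_sets),
                   dimnames = list(colnames(bundle$values), names(marker_sets)))
  by_group <- do.call(rbind, lapply(names(marker_sets), function(nm) {
    data.frame(set = nm, cohort = unique(cohort),
               mean = tapply(scores[, nm], cohort, mean)[unique(cohort)],
               sd = tapply(scores[, nm], cohort, stats::sd)[unique(cohort)],
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  comparison <- do.call(rbind, lapply(names(marker_sets), function(nm) {
    tt <- stats::t.test(scores[, nm] ~ cohort)
    data.frame(set = nm, difference = unname(diff(rev(tt$estimate))),
               ci_lo = tt$conf.int[1], ci_hi = tt$conf.int[2],
               p = tt$p.value, row.names = NULL, stringsAsFactors = FALSE)
  }))
  list(scores = scores, by_group = by_group, comparison = comparison)
}

#' PCA embedding of samples
#'
#' Samples are the observations; genes are centred (and optionally scaled)
#' variables. Thin wrapper over [stats::prcomp()] returning coordinates and
#' per-component variance fractions.
#'
#' @param matrix genes x samples numeric matrix (or an
#'   [expression_bundle()]).
#' @param scale. logical, scale genes to unit variance (default FALSE:
#'   log2 intensities share a scale).
#' @return list with `coordinates` (samples x components), `variance_fraction`
#'   (non-increasing, sums to 1 over all components) and `sdev`.
#' @export
pca_embed <- function(matrix, scale. = FALSE) {
  if (inherits(matrix, "expression_bundle")) matrix <- matrix$values
  if (ncol(matrix) < 2) stop("PCA needs at least 2 samples")
  keep <- apply(matrix, 1, stats::var) > 0 | !scale.
  p <- stats::prcomp(t(matrix[keep, , drop = FALSE]),
                     center = TRUE, scale. = scale.)
  vf <- p$sdev^2 / sum(p$sdev^2)
  list(coordinates = p$x, variance_fraction = vf, sdev = p$sdev)
}
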