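#' Parametric empirical-Bayes location-scale batch adjustment
#'
#' Removes per-(gene, batch) location and scale effects from a log2
#' expression matrix while protecting covariate (e.g. diagnostic group)
#' differences. The model is the classic location-scale formulation:
#' `Y_gj = alpha_g + X_j beta_g + gamma_{g,i(j)} + delta_{g,i(j)} eps_gj`.
#' Per gene, data are standardized as `Z = (Y - alpha - X beta) / sigma`;
#' per batch, location estimates `gamma_hat` get a normal prior and scale
#' estimates `delta2_hat` an inverse-gamma prior, with hyperparameters by
#' method of moments across genes; the posterior point estimates
#' `(gamma*, delta2*)` are found by the standard fixed-point iteration
#' (maximum absolute change < 1e-4, capped at 100 iterations) and the
#' adjusted data are `(sigma / sqrt(delta2*)) (Z - gamma*) + alpha + X beta`.
#'
#' With a single batch there is nothing to adjust and the input is returned
#' unchanged. Degenerate priors (zero across-gene dispersion of the batch
#' estimates) collapse to no shrinkage of the scale and exact shrinkage of
#' the location to the common prior mean, so a batch effect that is
#' identical for every gene is removed exactly.
#'
#' @param bundle an [expression_bundle()] (or a bare genes x samples
#'   matrix if `batch` is given explicitly).
#' @param batch batch labels, one per sample (defaults to
#'   `metadata$batch`). Every batch must hold at least 2 samples.
#' @param covariates per-sample data.frame (or vector) of covariates to
#'   protect, e.g. the diagnostic group. When the argument is omitted it
#'   defaults to `metadata$group` (when present); pass `NULL` explicitly
#'   to adjust without covariates. Must not be confounded with batch.
#' @param tol,max_iter fixed-point convergence controls.
#' @return list with `bundle` (adjusted; same class as the input) and
#'   `model` (list of per-batch hyperparameters `gamma_bar`, `tau2`,
#'   `lambda`, `theta`, the shrunken `gamma_star`/`delta2_star` matrices,
#'   pooled `sigma2` and iteration counts).
#' @export
eb_batch_adjust <- function(bundle, batch = NULL, covariates,
                            tol = 1e-4, max_iter = 100) {
  is_bundle <- inherits(bundle, "expression_bundle")
  Y <- if (is_bundle) bundle$values else bundle
  stopifnot(is.matrix(Y), is.numeric(Y))
  if (is.null(batch) && is_bundle) batch <- bundle$metadata$batch
  if (is.null(batch)) stop("batch labels required")
  batch <- factor(batch)
  if (length(batch) != ncol(Y)) stop("one batch label per sample required")
  if (missing(covariates)) {
    covariates <- if (is_bundle && !is.null(bundle$metadata$group) &&
                      length(unique(bundle$metadata$group)) > 1)
      bundle$metadata$group else NULL
  }

  if (nlevels(batch) == 1) {
    message("single batch: adjustment is the identity")
    return(list(bundle = bundle, model = list(n_batches = 1L)))
  }
  nb <- table(batch)
  if (any(nb < 2)) stop("every batch needs >= 2 samples (offending: ",
                        paste(names(nb)[nb < 2], collapse = ", "), ")")

  B <- stats::model.matrix(~ 0 + batch)          # batch indicators
  X <- if (!is.null(covariates)) {
    cov_df <- as.data.frame(covariates)
    mm <- stats::model.matrix(~ ., data = cov_df)
    mm[, -1, drop = FALSE]                       # intercept lives in B
  } else NULL
  design <- cbind(B, X)
  if (qr(design)$rank < ncol(design))
    stop("batch is confounded with the covariates; cannot adjust")

  n <- ncol(Y)
  n_batch <- nlevels(batch)
  Bhat <- solve(crossprod(design), crossprod(design, t(Y)))   # p x genes
  grand <- crossprod(Bhat[seq_len(n_batch), , drop = FALSE],
                     as.numeric(nb) / n)                      # genes x 1
  stand_mean <- matrix(grand, nrow(Y), n)
  if (!is.null(X)) {
    tmp <- design; tmp[, seq_len(n_batch)] <- 0
    stand_mean <- stand_mean + t(tmp %*% Bhat)
  }
  resid <- Y - t(design %*% Bhat)
  sigma2 <- rowSums(resid^2) / n
  if (any(sigma2 <= 0)) stop("zero-variance gene(s); filter before adjusting")
  Z <- (Y - stand_mean) / sqrt(sigma2)

  gamma_hat <- delta2_hat <- matrix(0, nrow(Y), n_batch,
                                    dimnames = list(rownames(Y), levels(batch)))
  for (i in seq_len(n_batch)) {
    idx <- which(batch == levels(batch)[i])
    gamma_hat[, i] <- rowMeans(Z[, idx, drop = FALSE])
    delta2_hat[, i] <- apply(Z[, idx, drop = FALSE], 1, stats::var)
  }

  gamma_star <- gamma_hat; delta2_star <- delta2_hat
  hyper <- data.frame(batch = levels(batch), gamma_bar = NA_real_,
                      tau2 = NA_real_, lambda = NA_real_, theta = NA_real_,
                      iterations = NA_integer_)
  for (i in seq_len(n_batch)) {
    idx <- which(batch == levels(batch)[i])
    ni <- length(idx)
    g_hat <- gamma_hat[, i]; d_hat <- delta2_hat[, i]
    g_bar <- mean(g_hat); tau2 <- stats::var(g_hat)
    m <- mean(d_hat); v <- stats::var(d_hat)
    degenerate_scale <- !is.finite(v) || v < 1e-12
    lambda <- if (degenerate_scale) NA_real_ else (2 * v + m^2) / v
    theta  <- if (degenerate_scale) NA_real_ else (m * v + m^3) / v
    g_new <- g_hat; d_new <- d_hat
    it <- 0L
    repeat {
      it <- it + 1L
      g_old <- g_new; d_old <- d_new
      g_new <- if (tau2 < 1e-12) rep(g_bar, length(g_hat))
               else (ni * tau2 * g_hat + d_old * g_bar) / (ni * tau2 + d_old)
      if (degenerate_scale) {
        d_new <- d_hat
      } else {
        ss <- rowSums((Z[, idx, drop = FALSE] - g_new)^2)
        d_new <- (theta + 0.5 * ss) / (ni / 2 + lambda - 1)
      }
      if (max(abs(g_new - g_old), abs(d_new - d_old)) < tol || it >= max_iter)
        break
    }
    gamma_star[, i] <- g_new
    delta2_star[, i] <- d_new
    hyper[i, 2:6] <- c(g_bar, tau2, lambda, theta, it)
  }

  adj <- Z
  for (i in seq_len(n_batch)) {
    idx <- which(batch == levels(batch)[i])
    adj[, idx] <- (Z[, idx, drop = FALSE] - gamma_star[, i]) /
      sqrt(delta2_star[, i])
  }
  adj <- adj * sqrt(sigma2) + stand_mean
  out <- if (is_bundle) expression_bundle(adj, bundle$metadata) else adj
  list(bundle = out,
       model = list(n_batches = n_batch, hyper = hyper,
                    gamma_hat = gamma_hat, delta2_hat = delta2_hat,
                    gamma_star = gamma_star, delta2_star = delta2_star,
                    sigma2 = sigma2))
}
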