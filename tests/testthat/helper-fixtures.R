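# shared fixture builders; everything generated in code, no files

toy_bundle <- function(values, groups, cohort = "OD", batch = NULL,
                       extra = NULL) {
  md <- data.frame(sample = colnames(values), cohort = cohort,
                   group = groups, stringsAsFactors = FALSE)
  if (!is.null(batch)) md$batch <- batch
  if (!is.null(extra)) md <- cbind(md, extra)
  expression_bundle(values, md)
}

rand_bundle <- function(ng = 50, n1 = 6, n2 = 6, sd = 1, delta = 0,
                        seed = 1, prefix = "s") {
  set.seed(seed)
  n <- n1 + n2
  Y <- matrix(rnorm(ng * n, 7, sd), ng, n,
              dimnames = list(sprintf("g%03d", seq_len(ng)),
                              sprintf("%s%03d", prefix, seq_len(n))))
  grp <- rep(c("ND", "T2D"), c(n1, n2))
  if (delta != 0) Y[1, grp == "T2D"] <- Y[1, grp == "T2D"] + delta
  toy_bundle(Y, grp)
}

small_sim_config <- function(...) {
  args <- utils::modifyList(list(
    n_genes = 600,
    modules = list(c(size = 60, loading = 0.4), c(size = 50, loading = 0.4),
                   c(size = 40, loading = 0.4)),
    signature = list(n_concordant = 10, n_od_only = 10, n_ppp_only = 5,
                     log2fc_range = c(log2(1.5), log2(3))),
    tf = list(n_regulators = 6, regulon_size = 20, motif_fp_rate = 0.05,
              motif_fn_rate = 0.05, sign_error_rate = 0.05, n_active = 3)),
    list(...))
  do.call(sim_config, args)
}

null_sim_config <- function(n_genes = 300,
                            group_sizes = list(OD = c(ND = 20, T2D = 20),
                                               PPP = c(ND = 20, T2D = 20))) {
  sim_config(n_genes = n_genes, group_sizes = group_sizes,
             n_batches_per_cohort = 1, batch_shift_sd = 0,
             modules = list(),
             signature = list(n_concordant = 0, n_od_only = 0,
                              n_ppp_only = 0,
                              log2fc_range = c(log2(1.5), log2(3))),
             traits = list(),
             tf = list(n_regulators = 0, regulon_size = 0,
                       motif_fp_rate = 0, motif_fn_rate = 0,
                       sign_error_rate = 0, n_active = 0),
             exclusion_fraction = 0)
}

# independent brute-force oracles ------------------------------------------

hyper_tail_enum <- function(k, K, n, N) {
  if (k == 0) return(1)
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  qs <- vapply(seq_len(m), function(i) {
    min(1, min(ps[i:m] * m / (i:m)))
  }, numeric(1))
  q <- numeric(m)
  q[o] <- qs
  q
}
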