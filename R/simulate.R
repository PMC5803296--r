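#' Configuration for the two-cohort synthetic data generator
#'
#' Defines the statistical structure the pipeline assumes: two cohorts (OD:
#' enzymatically isolated organ-donor islets; PPP: laser-capture
#' microdissected islets from pancreatectomised patients) with a dominant
#' within-cohort batch axis, planted concordant and cohort-specific
#' differentially expressed genes, block co-expression modules driving
#' clinical traits, and TF regulons observed through noisy motif annotations
#' and noisy signed literature edges.
#'
#' Group sizes default to the profiled cohort sizes of the study this
#' pipeline models (OD: 84 non-diabetic, 19 type 2 diabetic; PPP: 32
#' non-diabetic, 36 type 2 diabetic, 15 IGT, 20 type 3c diabetic). Planted
#' log2 fold changes are uniform on `[log2 1.5, log2 3]`, i.e. from the DE
#' calling threshold up to 3-fold. IGT and type 3c samples receive
#' attenuated versions (factors 0.25 and 0.6) of the concordant type 2
#' diabetes effects, mirroring the muted fold-change profile observed for
#' those conditions.
#'
#' @param n_genes number of genes in the universe.
#' @param group_sizes named list `list(OD = c(...), PPP = c(...))` of named
#'   per-group sample counts.
#' @param n_batches_per_cohort batches per cohort (balanced assignment).
#' @param batch_shift_sd SD (log2 units) of per-(gene, batch) location shifts.
#' @param baseline_mean,baseline_sd mean/SD of per-gene baseline log2 level.
#' @param noise_sd residual SD (log2 units) per observation.
#' @param modules list of `c(size =, loading =)` pairs; each module is a
#'   latent factor with constant loading over its member genes.
#' @param signature list with `n_concordant`, `n_od_only`, `n_ppp_only`
#'   counts of free planted DE genes and `log2fc_range` for the effect
#'   magnitude. Targets of active regulators are additional concordant
#'   signature genes on top of `n_concordant`.
#' @param attenuation named factors applied to concordant effects in the
#'   IGT and T3cD groups.
#' @param traits list of `list(module =, slope =, noise_sd =)` trait models;
#'   trait value = slope * module factor + Gaussian noise.
#' @param tf list with `n_regulators`, `regulon_size`, `motif_fp_rate`,
#'   `motif_fn_rate`, `sign_error_rate`, `n_active`. Active regulators'
#'   regulons are drawn inside distinct co-expression modules and their
#'   targets receive coherent planted effects.
#' @param exclusion_fraction fraction of non-diabetic-history samples
#'   injected as QC violators (fructosamine or glucose above threshold).
#' @param seed default root seed used when the generator is called without
#'   an explicit seed.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       group_sizes = list(OD  = c(ND = 84, T2D = 19),
                                          PPP = c(ND = 32, T2D = 36,
                                                  IGT = 15, T3cD = 20)),
                       n_batches_per_cohort = 2,
                       batch_shift_sd = 0.8,
                       baseline_mean = 7, baseline_sd = 1.5,
                       noise_sd = 0.25,
                       modules = list(c(size = 150, loading = 0.4),
                                      c(size = 120, loading = 0.4),
                                      c(size = 100, loading = 0.4)),
                       signature = list(n_concordant = 19, n_od_only = 40,
                                        n_ppp_only = 20,
                                        log2fc_range = c(log2(1.5), log2(3))),
                       attenuation = c(IGT = 0.25, T3cD = 0.6),
                       traits = list(list(module = 1, slope = 1,  noise_sd = 0.5),
                                     list(module = 2, slope = -1, noise_sd = 0.5)),
                       tf = list(n_regulators = 15, regulon_size = 30,
                                 motif_fp_rate = 0.05, motif_fn_rate = 0.05,
                                 sign_error_rate = 0.05, n_active = 3),
                       exclusion_fraction = 0.05,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), group_sizes = group_sizes,
              n_batches_per_cohort = as.integer(n_batches_per_cohort),
              batch_shift_sd = batch_shift_sd, baseline_mean = baseline_mean,
              baseline_sd = baseline_sd, noise_sd = noise_sd,
              modules = modules, signature = signature,
              attenuation = attenuation, traits = traits, tf = tf,
              exclusion_fraction = exclusion_fraction, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c(cfg$n_genes, cfg$n_batches_per_cohort,
              unlist(cfg$group_sizes, use.names = FALSE),
              cfg$signature$n_concordant, cfg$signature$n_od_only,
              cfg$signature$n_ppp_only, cfg$tf$n_regulators,
              cfg$tf$regulon_size, cfg$tf$n_active)
  if (any(counts < 0)) stop("all counts must be >= 0")
  if (any(unlist(cfg$group_sizes) <= 0)) stop("group sizes must be positive")
  msizes <- vapply(cfg$modules, function(m) m[["size"]], numeric(1))
  if (length(msizes) && sum(msizes) > cfg$n_genes)
    stop("module sizes exceed n_genes")
  rates <- c(cfg$tf$motif_fp_rate, cfg$tf$motif_fn_rate, cfg$tf$sign_error_rate,
             cfg$exclusion_fraction)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  fc <- cfg$signature$log2fc_range
  if (length(fc) != 2 || fc[1] <= 0 || fc[2] < fc[1])
    stop("log2fc_range lower bound must be > 0 and range non-decreasing")
  if (cfg$tf$n_regulators > 0 && cfg$tf$regulon_size > cfg$n_genes)
    stop("regulon_size exceeds n_genes")
  if (cfg$tf$n_active > 0) {
    if (cfg$tf$n_active > cfg$tf$n_regulators)
      stop("n_active exceeds n_regulators")
    if (cfg$tf$n_active > length(cfg$modules))
      stop("n_active exceeds the number of modules (active regulons live in modules)")
    if (length(msizes) && cfg$tf$regulon_size > min(msizes[seq_len(cfg$tf$n_active)]))
      stop("regulon_size exceeds the host module size")
  }
  invisible(cfg)
}

# Derive an independent 31-bit seed stream from a root seed and a stream
# index, so adding a cohort/network does not perturb the draws of another.
derive_seed <- function(seed, stream) {
  x <- (as.double(seed) %% 2147483647) + 1
  for (i in seq_len(stream + 1)) x <- (x * 48271) %% 2147483647
  as.integer(x)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# All structural randomness (gene roles, regulons, signs, magnitudes) lives
# in one stream shared by simulate_cohorts() and simulate_networks().
sim_truth <- function(cfg, seed) {
  with_seed(derive_seed(seed, 0L), {
    genes <- sprintf("g%04d", seq_len(cfg$n_genes))
    msizes <- vapply(cfg$modules, function(m) m[["size"]], numeric(1))
    module_assignment <- stats::setNames(rep("unassigned", cfg$n_genes), genes)
    pool <- genes
    module_genes <- list()
    for (m in seq_along(cfg$modules)) {
      gm <- sample(pool, msizes[m])
      module_genes[[paste0("M", m)]] <- gm
      module_assignment[gm] <- paste0("M", m)
      pool <- setdiff(pool, gm)
    }

    ntf <- cfg$tf$n_regulators
    tfs <- if (ntf > 0) sprintf("TF%02d", seq_len(ntf)) else character(0)
    n_active <- cfg$tf$n_active
    regulons <- list(); edge_sign <- list()
    active <- data.frame(tf = character(0), state = character(0),
                         module = character(0), stringsAsFactors = FALSE)
    for (k in seq_along(tfs)) {
      if (k <= n_active) {
        host <- paste0("M", k)
        regulons[[tfs[k]]] <- sample(module_genes[[host]], cfg$tf$regulon_size)
        active <- rbind(active, data.frame(
          tf = tfs[k], state = sample(c("activated", "inhibited"), 1),
          module = host, stringsAsFactors = FALSE))
      } else {
        regulons[[tfs[k]]] <- sample(genes, min(cfg$tf$regulon_size, cfg$n_genes))
      }
      edge_sign[[tfs[k]]] <- sample(c(1L, -1L), length(regulons[[tfs[k]]]),
                                    replace = TRUE)
    }

    # concordant signature = active regulators' targets (coherent direction)
    # plus free concordant genes outside modules
    sig <- data.frame(gene = character(0), direction = character(0),
                      scope = character(0), lfc = numeric(0),
                      stringsAsFactors = FALSE)
    rng <- cfg$signature$log2fc_range
    for (k in seq_len(n_active)) {
      tfk <- active$tf[k]
      s_state <- if (active$state[k] == "activated") 1L else -1L
      d <- s_state * edge_sign[[tfk]]
      sig <- rbind(sig, data.frame(
        gene = regulons[[tfk]],
        direction = ifelse(d > 0, "up", "down"),
        scope = "concordant",
        lfc = d * stats::runif(length(d), rng[1], rng[2]),
        stringsAsFactors = FALSE))
    }
    free_pool <- setdiff(pool, sig$gene)
    plant <- function(n, scope) {
      if (n == 0) return(NULL)
      g <- sample(free_pool, n)
      free_pool <<- setdiff(free_pool, g)
      d <- sample(c(1L, -1L), n, replace = TRUE)
      data.frame(gene = g, direction = ifelse(d > 0, "up", "down"),
                 scope = scope, lfc = d * stats::runif(n, rng[1], rng[2]),
                 stringsAsFactors = FALSE)
    }
    sig <- rbind(sig, plant(cfg$signature$n_concordant, "concordant"),
                 plant(cfg$signature$n_od_only, "od_only"),
                 plant(cfg$signature$n_ppp_only, "ppp_only"))

    # planted structure lives in the expressed stratum: a real DE/module
    # signature is only discoverable among expressed genes, so the QC
    # expression filter must not silently delete the ground truth
    expressed <- union(unlist(module_genes, use.names = FALSE), sig$gene)

    # baseline log2 level is a gene property shared by both cohorts; the
    # expressed stratum is lifted above the pooled 75th-percentile cutoff
    # (tau sits near background quantile 0.75/(1-f) when a fraction f of
    # genes is lifted clear of it)
    mu <- stats::rnorm(cfg$n_genes, cfg$baseline_mean, cfg$baseline_sd)
    if (length(expressed)) {
      f <- length(expressed) / cfg$n_genes
      pooled_sd <- sqrt(cfg$baseline_sd^2 + cfg$noise_sd^2 +
                          if (cfg$n_batches_per_cohort > 1)
                            cfg$batch_shift_sd^2 else 0)
      kq <- stats::qnorm(min(0.75 / (1 - f), 0.995))
      idx <- match(expressed, genes)
      mu[idx] <- cfg$baseline_mean + kq * pooled_sd +
        stats::runif(length(idx), 0.75, 2.0)
    }

    trait_map <- if (length(cfg$traits))
      stats::setNames(vapply(cfg$traits, function(t) paste0("M", t$module),
                             character(1)),
                      paste0("trait", seq_along(cfg$traits))) else character(0)

    list(genes = genes, mu = mu, module_assignment = module_assignment,
         module_genes = module_genes, expressed = expressed,
         regulons = regulons,
         edge_sign = edge_sign,
         active_regulators = active[, c("tf", "state", "module")],
         signature_genes = sig, trait_map = trait_map)
  })
}

#' Generate the two synthetic cohorts and their ground truth
#'
#' Per gene g and sample j the model is
#' `x_gj = mu_g + sum_m L_gm f_mj + delta_gj + gamma_{g, batch(j)} + eps_gj`
#' with standard-normal per-sample module factors `f_mj`, Gaussian noise
#' `eps` with SD `noise_sd`, per-(gene, batch) shifts `gamma` with SD
#' `batch_shift_sd`, and planted effect `delta` applied to the diabetic
#' groups (full size in T2D; attenuated by the configured factors in IGT
#' and T3cD for concordant genes only). Output is deterministic given
#' `(config, seed)`.
#'
#' @param config a [sim_config()].
#' @param seed integer root seed (defaults to `config$seed`). Independent
#'   streams are derived per cohort so one cohort's draws never perturb the
#'   other's.
#' @return list with elements `od`, `ppp` (each an [expression_bundle()]
#'   whose metadata carries `cohort`, `group`, `batch`, `fructosamine`,
#'   `glucose`, `insulin` and trait columns) and `truth` (list with
#'   `signature_genes`, `module_assignment`, `active_regulators`,
#'   `trait_map`, `excluded`, plus the generating regulons).
#' @export
simulate_cohorts <- function(config, seed = config$seed) {
  cfg <- validate_sim_config(config)
  truth <- sim_truth(cfg, seed)
  excluded <- list()
  bundles <- list()
  for (ci in seq_along(cfg$group_sizes)) {
    cohort <- names(cfg$group_sizes)[ci]
    res <- with_seed(derive_seed(seed, ci), {
      sim_one_cohort(cfg, truth, cohort)
    })
    bundles[[tolower(cohort)]] <- res$bundle
    excluded[[cohort]] <- res$excluded
  }
  truth$excluded <- do.call(rbind, c(excluded, list(make.row.names = FALSE)))
  truth$module_genes <- NULL
  list(od = bundles$od, ppp = bundles$ppp, truth = truth)
}

sim_one_cohort <- function(cfg, truth, cohort) {
  sizes <- cfg$group_sizes[[cohort]]
  n <- sum(sizes)
  genes <- truth$genes
  group <- rep(names(sizes), sizes)
  sample_id <- sprintf("%s_%03d", cohort, seq_len(n))
  batch <- paste0(cohort, "_b",
                  rep_len(seq_len(cfg$n_batches_per_cohort), n))

  x <- matrix(truth$mu, cfg$n_genes, n, dimnames = list(genes, sample_id))

  # module factors and loadings
  fac <- matrix(stats::rnorm(length(cfg$modules) * n), length(cfg$modules), n)
  for (m in seq_along(cfg$modules)) {
    gm <- names(truth$module_assignment)[truth$module_assignment == paste0("M", m)]
    if (length(gm))
      x[gm, ] <- x[gm, ] + cfg$modules[[m]][["loading"]] *
        matrix(fac[m, ], length(gm), n, byrow = TRUE)
  }

  # planted effects
  sig <- truth$signature_genes
  if (nrow(sig)) {
    scope_here <- c("concordant", if (cohort == "OD") "od_only" else "ppp_only")
    for (grp in intersect(names(sizes), c("T2D", "IGT", "T3cD"))) {
      att <- if (grp == "T2D") 1 else unname(cfg$attenuation[[grp]])
      rows <- if (grp == "T2D") sig$scope %in% scope_here
              else sig$scope == "concordant"  # attenuated effects: concordant only
      idx <- which(group == grp)
      if (any(rows) && length(idx))
        x[sig$gene[rows], idx] <- x[sig$gene[rows], idx] + att * sig$lfc[rows]
    }
  }

  # batch shifts: per (gene, batch) location offsets
  if (cfg$batch_shift_sd > 0 && cfg$n_batches_per_cohort > 1) {
    for (b in unique(batch)) {
      gb <- stats::rnorm(cfg$n_genes, 0, cfg$batch_shift_sd)
      x[, batch == b] <- x[, batch == b] + gb
    }
  }

  x <- x + matrix(stats::rnorm(cfg$n_genes * n, 0, cfg$noise_sd), cfg$n_genes, n)

  # clinical covariates; inject explicit QC violators among samples without
  # a diabetes history (ND, IGT) so exclusion recall is testable
  fructosamine <- ifelse(group %in% c("ND", "IGT"),
                         stats::rnorm(n, 200, 30), stats::rnorm(n, 250, 40))
  glucose <- ifelse(group %in% c("ND", "IGT"),
                    stats::rnorm(n, 5.5, 1), stats::rnorm(n, 9, 2))
  fructosamine <- pmin(fructosamine, 280)  # keep non-violators under threshold
  glucose <- pmin(glucose, 11.0)
  insulin <- stats::rnorm(n, 1, 0.2)
  no_hist <- which(group %in% c("ND", "IGT"))
  n_viol <- round(cfg$exclusion_fraction * length(no_hist))
  excluded <- data.frame(sample = character(0), cohort = character(0),
                         reason = character(0), stringsAsFactors = FALSE)
  if (n_viol > 0) {
    viol <- sample(no_hist, n_viol)
    reason <- sample(c("fructosamine", "glucose"), n_viol, replace = TRUE)
    fructosamine[viol[reason == "fructosamine"]] <-
      stats::runif(sum(reason == "fructosamine"), 290, 380)
    glucose[viol[reason == "glucose"]] <-
      stats::runif(sum(reason == "glucose"), 11.5, 20)
    excluded <- data.frame(sample = sample_id[viol], cohort = cohort,
                           reason = reason, stringsAsFactors = FALSE)
  }

  md <- data.frame(sample = sample_id, cohort = cohort, group = group,
                   batch = batch, fructosamine = fructosamine,
                   glucose = glucose, insulin = insulin,
                   stringsAsFactors = FALSE)
  for (t in seq_along(cfg$traits)) {
    tm <- cfg$traits[[t]]
    md[[paste0("trait", t)]] <- tm$slope * fac[tm$module, ] +
      stats::rnorm(n, 0, tm$noise_sd)
  }
  list(bundle = expression_bundle(x, md), excluded = excluded)
}

#' Generate the noisy regulator annotation channels
#'
#' Each regulator has a true regulon (drawn in a stream shared with
#' [simulate_cohorts()], so active regulators' targets carry coherent
#' planted directions in the expression data). The motif channel observes
#' the regulon with false-negative removals (each true target dropped with
#' probability `motif_fn_rate`) and false-positive additions (each
#' non-member added with probability
#' `motif_fp_rate * regulon_size / (n_genes - regulon_size)`, so the
#' expected spurious count is `motif_fp_rate * regulon_size`). The
#' literature channel observes the regulon with true signs, each flipped
#' independently with probability `sign_error_rate`.
#'
#' @param config a [sim_config()].
#' @param seed integer root seed (defaults to `config$seed`).
#' @return list with `motif_targets` (named list of character vectors, one
#'   per regulator) and `causal_edges` (data.frame `tf`, `target`, `sign`).
#' @export
simulate_networks <- function(config, seed = config$seed) {
  cfg <- validate_sim_config(config)
  truth <- sim_truth(cfg, seed)
  with_seed(derive_seed(seed, 99L), {
    motif <- list(); edges <- list()
    for (tf in names(truth$regulons)) {
      reg <- truth$regulons[[tf]]
      keep <- stats::runif(length(reg)) >= cfg$tf$motif_fn_rate
      others <- setdiff(truth$genes, reg)
      p_add <- if (length(others))
        cfg$tf$motif_fp_rate * length(reg) / length(others) else 0
      spurious <- others[stats::runif(length(others)) < p_add]
      motif[[tf]] <- c(reg[keep], spurious)
      s <- truth$edge_sign[[tf]]
      flip <- stats::runif(length(s)) < cfg$tf$sign_error_rate
      edges[[tf]] <- data.frame(tf = tf, target = reg,
                                sign = ifelse(flip, -s, s),
                                stringsAsFactors = FALSE)
    }
    list(motif_targets = motif,
         causal_edges = do.call(rbind, c(edges, list(make.row.names = FALSE))))
  })
}
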