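#' Run the full dual-cohort signature pipeline
#'
#' Orchestrates the stages in order: sample exclusion -> expression filter
#' -> batch adjustment -> per-cohort moderated-t differential expression ->
#' cross-cohort concordant signature with hypergeometric overlap test ->
#' condition fold-change profile -> co-expression modules (per cohort,
#' non-diabetic samples), cross-cohort module preservation, eigengene-trait
#' correlation, signature-in-module enrichment -> TF inference (sequence
#' and literature channels, intersection network). The orchestration is a
#' pure function of (inputs, config): re-runs are identical except for
#' timestamps in the run log. Any stage error aborts with the stage name.
#'
#' @param od,ppp [expression_bundle()]s for the two cohorts.
#' @param config an [analysis_config()].
#' @param motif_targets optional named list of motif-target sets (sequence
#'   channel); skipped when absent.
#' @param causal_edges optional signed edge data.frame (literature
#'   channel); skipped when absent.
#' @param marker_sets optional contamination marker sets.
#' @param trait_columns metadata columns holding clinical/functional
#'   traits (default: every column whose name starts with `trait`).
#' @param outdir optional directory; when given, every intermediate table
#'   is written as TSV along with a run log.
#' @return list with elements `qc`, `batch`, `de`, `signature`,
#'   `overlap`, `condition_profile`, `modules`, `tf` (each a list of the
#'   stage's tables/objects), plus `universe` (expressed-gene background).
#' @export
run_pipeline <- function(od, ppp, config = analysis_config(),
                         motif_targets = NULL, causal_edges = NULL,
                         marker_sets = NULL, trait_columns = NULL,
                         outdir = NULL) {
  stopifnot(inherits(od, "expression_bundle"),
            inherits(ppp, "expression_bundle"),
            inherits(config, "analysis_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE))
  }
  cohorts <- list(OD = od, PPP = ppp)

  ## --- QC ---------------------------------------------------------------
  qc <- stage("qc", {
    res <- lapply(names(cohorts), function(cn) {
      b <- cohorts[[cn]]
      excl <- exclude_samples(b$metadata, config$fructosamine_max,
                              config$glucose_max, config$insulin_sd)
      keep_samples <- setdiff(b$metadata$sample, excl$sample)
      b2 <- subset_bundle(b, samples = keep_samples)
      retained <- filter_expressed(b2, config$expression_quantile,
                                   config$expression_sample_fraction)
      if (!length(retained)) stop("no genes pass the expression filter (", cn, ")")
      list(exclusions = excl, bundle = subset_bundle(b2, genes = retained),
           retained = retained)
    })
    names(res) <- names(cohorts)
    res
  })
  universe <- union(qc$OD$retained, qc$PPP$retained)

  contamination <- if (!is.null(marker_sets)) stage("contamination", {
    sg <- intersect(qc$OD$retained, qc$PPP$retained)
    shared_cols <- intersect(colnames(qc$OD$bundle$metadata),
                             colnames(qc$PPP$bundle$metadata))
    pooled <- expression_bundle(
      cbind(qc$OD$bundle$values[sg, , drop = FALSE],
            qc$PPP$bundle$values[sg, , drop = FALSE]),
      rbind(qc$OD$bundle$metadata[, shared_cols, drop = FALSE],
            qc$PPP$bundle$metadata[, shared_cols, drop = FALSE]))
    contamination_check(pooled, marker_sets)
  }) else NULL

  pca <- stage("pca", {
    shared <- intersect(qc$OD$retained, qc$PPP$retained)
    pooled <- cbind(qc$OD$bundle$values[shared, , drop = FALSE],
                    qc$PPP$bundle$values[shared, , drop = FALSE])
    pca_embed(pooled)
  })

  ## --- batch adjustment --------------------------------------------------
  batch <- stage("batch", {
    lapply(qc, function(q) {
      b <- q$bundle
      if (is.null(b$metadata$batch) ||
          length(unique(b$metadata$batch)) < 2) {
        list(bundle = b, model = list(n_batches = 1L))
      } else {
        eb_batch_adjust(b, covariates = b$metadata$group)
      }
    })
  })

  ## --- differential expression -------------------------------------------
  de <- stage("diffexpr", {
    res <- list()
    for (cn in names(cohorts)) {
      b <- batch[[cn]]$bundle
      groups <- unique(b$metadata$group)
      for (g in intersect(c("T2D", "IGT", "T3cD"), groups)) {
        if (sum(b$metadata$group == g) < 2) next
        mt <- moderated_ttest(b, contrast = c("ND", g))
        res[[paste0(cn, "_", g)]] <- call_de(mt, config$fdr, config$fold_change)
      }
    }
    res
  })

  ## --- signature -----------------------------------------------------------
  signature <- stage("signature", {
    concordant_signature(de$OD_T2D, de$PPP_T2D)
  })
  overlap <- stage("signature", {
    overlap_test(signature$summary$n_overlap, sum(de$OD_T2D$called),
                 sum(de$PPP_T2D$called), length(universe))
  })
  condition_profile <- stage("signature", {
    cond <- de[grep("^PPP_", names(de))]
    names(cond) <- sub("^PPP_", "", names(cond))
    signature_condition_profile(signature, cond,
                                report_threshold = config$tf_fold_change)
  })

  ## --- co-expression modules ----------------------------------------------
  modules <- stage("coexpression", {
    shared <- intersect(qc$OD$retained, qc$PPP$retained)
    per_cohort <- lapply(names(cohorts), function(cn) {
      b <- subset_bundle(batch[[cn]]$bundle, genes = shared)
      net <- build_network(b, beta = config$soft_power)
      assignment <- detect_modules(net, config$cut_height,
                                   config$min_module_size)
      ms <- if (any(assignment != "unassigned"))
        eigengenes_kme(b, assignment, top_k = config$hub_top_k) else NULL
      tc <- NULL
      if (!is.null(ms)) {
        tcols <- if (is.null(trait_columns))
          grep("^trait", colnames(b$metadata), value = TRUE) else trait_columns
        tcols <- intersect(tcols, colnames(b$metadata))
        if (length(tcols)) {
          tr <- b$metadata[, tcols, drop = FALSE]
          rownames(tr) <- b$metadata$sample
          tc <- trait_correlation(ms, tr)
        }
      }
      list(assignment = assignment, module_set = ms, trait_corr = tc)
    })
    names(per_cohort) <- names(cohorts)
    mo <- module_overlap(per_cohort$OD$assignment, per_cohort$PPP$assignment,
                         universe = length(shared),
                         alpha = config$overlap_alpha)
    preserved <- unique(mo$od_module[mo$preserved])
    enr <- NULL
    sig_genes <- intersect(signature$table$gene[signature$table$concordant],
                           shared)
    if (length(preserved) && length(sig_genes))
      enr <- signature_module_enrichment(sig_genes,
                                         per_cohort$OD$assignment,
                                         modules = preserved,
                                         universe = length(shared))
    list(od = per_cohort$OD, ppp = per_cohort$PPP, overlap = mo,
         preserved_od_modules = preserved, signature_enrichment = enr,
         shared_universe = shared)
  })

  ## --- TF networks ----------------------------------------------------------
  tf <- stage("tfnet", {
    preserved <- modules$preserved_od_modules
    a_od <- modules$od$assignment
    module_genes <- lapply(preserved, function(m) names(a_od)[a_od == m])
    names(module_genes) <- preserved
    seq_net <- if (!is.null(motif_targets) && length(module_genes))
      build_sequence_network(module_genes,
                             lapply(motif_targets, intersect,
                                    modules$shared_universe),
                             modules$shared_universe,
                             alpha = config$enrichment_alpha) else NULL
    lit <- NULL
    if (!is.null(causal_edges)) {
      nets <- lapply(de[c("OD_T2D", "PPP_T2D")], function(tab)
        build_literature_network(causal_edges, tab, module_genes,
                                 universe = length(universe),
                                 z_threshold = config$z_cutoff,
                                 alpha = config$enrichment_alpha))
      ed <- unique(rbind(nets[[1]]$edges, nets[[2]]$edges))
      lit <- tf_network(ed, list(OD = nets[[1]]$scores,
                                 PPP = nets[[2]]$scores), "literature")
    }
    inter <- if (!is.null(seq_net) && !is.null(lit))
      intersect_networks(lit, seq_net) else NULL
    list(sequence = seq_net, literature = lit, intersection = inter)
  })

  result <- list(qc = qc, contamination = contamination, pca = pca,
                 batch = batch, de = de, signature = signature,
                 overlap = overlap, condition_profile = condition_profile,
                 modules = modules, tf = tf, universe = universe,
                 config = config)
  if (!is.null(outdir)) write_pipeline_outputs(result, outdir)
  invisible(result)
}

write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  excl <- do.call(rbind, lapply(names(result$qc), function(cn)
    cbind(cohort = cn, result$qc[[cn]]$exclusions)))
  write_tsv(excl, p("qc_exclusions.tsv"))
  writeLines(result$universe, p("retained_genes.txt"))
  write_tsv(data.frame(sample = rownames(result$pca$coordinates),
                       result$pca$coordinates[, seq_len(min(5,
                         ncol(result$pca$coordinates))), drop = FALSE]),
            p("pca.tsv"))
  for (cn in names(result$batch))
    write_expression_matrix(result$batch[[cn]]$bundle$values,
                            p(paste0("adjusted_", tolower(cn), ".tsv")))
  for (nm in names(result$de))
    write_tsv(result$de[[nm]], p(paste0("de_", tolower(nm), ".tsv")))
  write_tsv(result$signature$table, p("signature.tsv"))
  write_tsv(as.data.frame(result$overlap), p("overlap_test.tsv"))
  prof <- result$condition_profile$profile
  write_tsv(data.frame(gene = rownames(prof), prof), p("condition_profile.tsv"))
  mods <- result$modules
  write_tsv(data.frame(gene = names(mods$od$assignment),
                       od_module = unname(mods$od$assignment),
                       ppp_module = unname(mods$ppp$assignment)),
            p("module_assignment.tsv"))
  write_tsv(mods$overlap, p("module_overlap.tsv"))
  for (cn in c("od", "ppp")) {
    ms <- mods[[cn]]$module_set
    if (is.null(ms)) next
    write_tsv(data.frame(sample = rownames(ms$eigengenes), ms$eigengenes),
              p(paste0("eigengenes_", cn, ".tsv")))
    write_tsv(data.frame(gene = rownames(ms$kme), ms$kme),
              p(paste0("kme_", cn, ".tsv")))
    write_tsv(data.frame(module = rep(names(ms$hubs),
                                      lengths(ms$hubs)),
                         gene = unlist(ms$hubs, use.names = FALSE)),
              p(paste0("hubs_", cn, ".tsv")))
    if (!is.null(mods[[cn]]$trait_corr))
      write_tsv(mods[[cn]]$trait_corr, p(paste0("trait_corr_", cn, ".tsv")))
  }
  if (!is.null(mods$signature_enrichment))
    write_tsv(as.data.frame(mods$signature_enrichment),
              p("signature_module_enrichment.tsv"))
  for (ch in c("sequence", "literature", "intersection")) {
    net <- result$tf[[ch]]
    if (!is.null(net)) {
      write_tsv(net$edges, p(paste0(ch, "_network.tsv")))
      if (ch == "literature")
        for (cn in names(net$scores))
          write_tsv(net$scores[[cn]],
                    p(paste0("regulator_scores_", tolower(cn), ".tsv")))
    }
  }
  cfg <- result$config
  log_lines <- c(
    paste0("duosig ", as.character(utils::packageVersion("duosig"))),
    paste0("R ", R.version.string),
    paste0("timestamp ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    paste0("config_seed ", cfg$seed),
    paste0("config ", paste(names(cfg), unlist(cfg), sep = "=",
                            collapse = " ")))
  writeLines(log_lines, p("run_log.txt"))
  invisible(outdir)
}
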