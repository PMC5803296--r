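#' Weighted co-expression network: adjacency and topological overlap
#'
#' Unsigned adjacency `a_ij = |cor(x_i, x_j)|^beta` over the chosen samples
#' (by default the non-diabetic samples, from which modules are derived),
#' connectivity `k_i = sum_{j != i} a_ij`, and topological overlap
#' `w_ij = (sum_{u != i,j} a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`
#' with `w_ii = 1`. Zero-variance genes are rejected before correlation.
#'
#' @param bundle an [expression_bundle()] or a genes x samples matrix.
#' @param beta soft-thresholding power (>= 1).
#' @param samples sample ids to use; defaults to the non-diabetic (`ND`)
#'   samples when the bundle has group metadata, else all samples.
#' @return list of class `coexpression_network` with `adjacency`, `tom`,
#'   `connectivity`, `beta`, `genes`.
#' @export
build_network <- function(bundle, beta = 6, samples = NULL) {
  stopifnot(beta >= 1)
  if (inherits(bundle, "expression_bundle")) {
    if (is.null(samples))
      samples <- if (!is.null(bundle$metadata$group) &&
                     any(bundle$metadata$group == "ND"))
        bundle$metadata$sample[bundle$metadata$group == "ND"]
      else bundle$metadata$sample
    x <- bundle$values[, samples, drop = FALSE]
  } else {
    x <- if (is.null(samples)) bundle else bundle[, samples, drop = FALSE]
  }
  if (ncol(x) < 4) stop("network construction needs >= 4 samples")
  v <- apply(x, 1, stats::var)
  if (any(v == 0))
    stop("zero-variance gene(s): ",
         paste(utils::head(rownames(x)[v == 0], 5), collapse = ", "))
  A <- abs(stats::cor(t(x)))^beta
  diag(A) <- 0
  k <- rowSums(A)
  L <- A %*% A                       # shared-neighbour term sum_u a_iu a_uj
  denom <- outer(k, k, pmin) + 1 - A
  tom <- (L + A) / denom
  tom <- (tom + t(tom)) / 2          # enforce exact symmetry
  diag(tom) <- 1
  structure(list(adjacency = A, tom = tom, connectivity = k, beta = beta,
                 genes = rownames(x)),
            class = "coexpression_network")
}

#' Detect modules by static cut of the TOM dendrogram
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`,
#' cut at a fixed height; clusters smaller than `min_size` become
#' `unassigned`. Modules are labelled `M1, M2, ...` in decreasing size, so
#' the partition is deterministic and invariant to gene order.
#'
#' @param network a [build_network()] result.
#' @param cut_height static cut height in (0, 1). TOM dissimilarities
#'   concentrate near 1, so useful cuts sit high (default 0.95).
#' @param min_size minimum module size (>= 2).
#' @return named character vector gene -> module label (`"unassigned"`
#'   allowed).
#' @export
detect_modules <- function(network, cut_height = 0.95, min_size = 20) {
  stopifnot(inherits(network, "coexpression_network"),
            cut_height > 0, cut_height < 1, min_size >= 2)
  genes <- network$genes
  if (length(genes) < min_size)
    return(stats::setNames(rep("unassigned", length(genes)), genes))
  d <- stats::as.dist(1 - network$tom)
  hc <- stats::hclust(d, method = "average")
  cl <- stats::cutree(hc, h = cut_height)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_size]
  assignment <- stats::setNames(rep("unassigned", length(genes)), genes)
  keep <- keep[order(-sizes[keep], as.integer(keep))]
  for (i in seq_along(keep))
    assignment[cl == as.integer(keep[i])] <- paste0("M", i)
  assignment
}

#' Module eigengenes, kME and hub genes
#'
#' The eigengene of a module is the first principal component of its
#' standardized (per-gene z-scored) expression, scaled to unit variance and
#' sign-oriented so the mean kME of the module's genes is >= 0. kME is the
#' correlation of every gene with every eigengene (module membership);
#' hubs are the `top_k` genes by |kME| within their own module. A
#' single-gene module's eigengene is the standardized gene itself.
#'
#' @param bundle an [expression_bundle()] or genes x samples matrix.
#' @param assignment named gene -> module vector (see [detect_modules()]).
#' @param top_k hub genes per module.
#' @param samples sample ids over which to compute eigengenes (default all
#'   columns).
#' @return list of class `module_set`: `assignment`, `eigengenes`
#'   (samples x modules matrix, unit variance columns), `kme` (genes x
#'   modules), `hubs` (named list per module).
#' @export
eigengenes_kme <- function(bundle, assignment, top_k = 10, samples = NULL) {
  x <- if (inherits(bundle, "expression_bundle")) bundle$values else bundle
  if (!is.null(samples)) x <- x[, samples, drop = FALSE]
  if (!all(names(assignment) %in% rownames(x)))
    stop("assignment names must be genes of the bundle")
  mods <- setdiff(sort(unique(assignment)), "unassigned")
  if (!length(mods)) stop("no assigned modules")
  eig <- matrix(NA_real_, ncol(x), length(mods),
                dimnames = list(colnames(x), mods))
  for (m in mods) {
    g <- names(assignment)[assignment == m]
    z <- t(scale(t(x[g, , drop = FALSE])))   # per-gene standardization
    if (length(g) == 1) {
      e <- as.numeric(z)
    } else {
      e <- svd(z, nu = 0, nv = 1)$v[, 1]
    }
    e <- e / stats::sd(e)
    if (mean(stats::cor(t(x[g, , drop = FALSE]), e)) < 0) e <- -e
    eig[, m] <- e
  }
  kme <- stats::cor(t(x), eig)
  hubs <- lapply(mods, function(m) {
    g <- names(assignment)[assignment == m]
    g[order(-abs(kme[g, m]))][seq_len(min(top_k, length(g)))]
  })
  names(hubs) <- mods
  structure(list(assignment = assignment, eigengenes = eig, kme = kme,
                 hubs = hubs),
            class = "module_set")
}

#' Cross-cohort module overlap (preservation) test
#'
#' For every pair of one OD and one PPP module, the overlap count is
#' tested with the inclusive upper-tail hypergeometric against the shared
#' gene universe; BH adjustment runs across all pairs and pairs with
#' `q <= alpha` are flagged preserved.
#'
#' @param assign_od,assign_ppp named gene -> module vectors over a shared
#'   universe (identical name sets).
#' @param universe universe size `N` (defaults to the number of shared
#'   genes).
#' @param alpha preservation threshold on q.
#' @return data.frame per module pair: `od_module`, `ppp_module`, `n_od`,
#'   `n_ppp`, `k`, `p`, `q`, `preserved`.
#' @export
module_overlap <- function(assign_od, assign_ppp,
                           universe = length(assign_od), alpha = 0.05) {
  if (!setequal(names(assign_od), names(assign_ppp)))
    stop("assignments must share one gene universe")
  assign_ppp <- assign_ppp[names(assign_od)]
  mo <- setdiff(sort(unique(assign_od)), "unassigned")
  mp <- setdiff(sort(unique(assign_ppp)), "unassigned")
  out <- expand.grid(od_module = mo, ppp_module = mp,
                     stringsAsFactors = FALSE)
  if (!nrow(out)) return(cbind(out, n_od = integer(0), n_ppp = integer(0),
                               k = integer(0), p = numeric(0), q = numeric(0),
                               preserved = logical(0)))
  stats_ <- t(apply(out, 1, function(r) {
    go <- names(assign_od)[assign_od == r[["od_module"]]]
    gp <- names(assign_ppp)[assign_ppp == r[["ppp_module"]]]
    k <- length(intersect(go, gp))
    c(n_od = length(go), n_ppp = length(gp), k = k,
      p = hypergeom_tail(k, length(go), length(gp), universe))
  }))
  out <- cbind(out, as.data.frame(stats_))
  out$q <- bh_adjust(out$p)
  out$preserved <- out$q <= alpha
  out
}

#' Module-trait correlation
#'
#' Pearson correlation of each module eigengene with each trait; the p
#' value comes from `t = r sqrt((n - 2) / (1 - r^2))` on `n - 2` df.
#' Missing trait values are dropped pairwise; a constant trait is reported
#' as missing with a reason; |r| = 1 is reported with p = 0 and a flag.
#'
#' @param module_set an [eigengenes_kme()] result.
#' @param traits data.frame of per-sample numeric traits, rows aligned
#'   with the eigengene sample order (or carrying matching rownames).
#' @return data.frame per (module, trait): `module`, `trait`, `n`, `r`,
#'   `p`, `flag` (`""`, `"perfect_correlation"`, `"constant_trait"`,
#'   `"too_few_pairs"`).
#' @export
trait_correlation <- function(module_set, traits) {
  stopifnot(inherits(module_set, "module_set"), is.data.frame(traits))
  eig <- module_set$eigengenes
  if (!is.null(rownames(traits)) &&
      all(rownames(eig) %in% rownames(traits)))
    traits <- traits[rownames(eig), , drop = FALSE]
  if (nrow(traits) != nrow(eig))
    stop("traits must align with the eigengene samples")
  out <- expand.grid(module = colnames(eig), trait = colnames(traits),
                     stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(out)), function(i) {
    e <- eig[, out$module[i]]
    tv <- traits[[out$trait[i]]]
    ok <- !is.na(e) & !is.na(tv)
    n <- sum(ok)
    if (n < 4)
      return(data.frame(n = n, r = NA_real_, p = NA_real_,
                        flag = "too_few_pairs"))
    if (stats::sd(tv[ok]) == 0)
      return(data.frame(n = n, r = NA_real_, p = NA_real_,
                        flag = "constant_trait"))
    r <- stats::cor(e[ok], tv[ok])
    if (abs(r) >= 1 - 1e-12)
      return(data.frame(n = n, r = sign(r), p = 0,
                        flag = "perfect_correlation"))
    ct <- stats::cor.test(e[ok], tv[ok], method = "pearson")
    data.frame(n = n, r = unname(ct$estimate), p = ct$p.value, flag = "")
  })
  cbind(out, do.call(rbind, res))
}

#' Enrichment of the signature genes in the selected modules
#'
#' Tests whether signature genes concentrate in a chosen set of modules:
#' `K` = genes inside the selected modules, `n` = signature size, `k` =
#' signature genes inside, inclusive upper-tail hypergeometric against the
#' universe.
#'
#' @param signature character vector of signature gene ids (must lie in
#'   the universe).
#' @param module_set an [eigengenes_kme()] result, or a named gene ->
#'   module assignment vector.
#' @param modules module labels to pool (default all assigned modules).
#' @param universe universe size `N`.
#' @return an overlap-test list (`k`, `K`, `n`, `N`, `p`).
#' @export
signature_module_enrichment <- function(signature, module_set,
                                        modules = NULL, universe) {
  assignment <- if (inherits(module_set, "module_set"))
    module_set$assignment else module_set
  if (is.null(modules))
    modules <- setdiff(unique(assignment), "unassigned")
  if (!length(modules)) stop("empty module selection")
  inside <- names(assignment)[assignment %in% modules]
  k <- length(intersect(signature, inside))
  overlap_test(k, length(inside), length(signature), universe)
}
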