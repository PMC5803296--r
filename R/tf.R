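#' Over-representation analysis of gene sets
#'
#' Inclusive upper-tail hypergeometric of the query's overlap with each
#' set (sets are intersected with the universe first), BH adjustment
#' across sets, significance at `q <= alpha`.
#'
#' @param query character vector of gene ids, a subset of the universe.
#' @param sets named list of character vectors (e.g. from [read_gmt()]).
#' @param universe character vector of background gene ids (or its size,
#'   in which case sets/query are assumed pre-restricted).
#' @param alpha significance threshold on q.
#' @return data.frame per set: `set`, `set_size`, `k`, `p`, `q`,
#'   `significant`, sorted by p.
#' @export
ora <- function(query, sets, universe, alpha = 0.05) {
  if (is.character(universe)) {
    if (!length(universe)) stop("empty universe")
    bad <- setdiff(query, universe)
    if (length(bad))
      stop("query genes outside the universe: ",
           paste(utils::head(bad, 5), collapse = ", "))
    sets <- lapply(sets, intersect, universe)
    N <- length(universe)
  } else {
    N <- as.integer(universe)
    if (N < 1) stop("empty universe")
  }
  query <- unique(query)
  out <- data.frame(set = names(sets),
                    set_size = vapply(sets, length, integer(1)),
                    k = vapply(sets, function(s) length(intersect(query, s)),
                               integer(1)),
                    row.names = NULL, stringsAsFactors = FALSE)
  out$p <- mapply(hypergeom_tail, out$k, out$set_size,
                  MoreArgs = list(n = length(query), N = N))
  out$q <- bh_adjust(out$p)
  out$significant <- out$q <= alpha
  out[order(out$p), , drop = FALSE]
}

#' Regulator activation z-scores from signed causal edges
#'
#' For each regulator, restrict its signed edges to targets among the
#' called DE genes and score the sign consistency between edge sign `s_e`
#' and observed DE direction `d_t` (+1 up, -1 down):
#' `z = sum(s_e d_t) / sqrt(n)` over the `n` matched targets. `|z| >= 2`
#' calls the regulator `activated` (z > 0) or `inhibited` (z < 0); the
#' target-set overlap with the DE list also gets an upper-tail
#' hypergeometric p against the universe. Regulators with no matched
#' target are omitted.
#'
#' @param edges signed edge data.frame (`tf`, `target`, `sign`), see
#'   [read_edge_list()].
#' @param de a called DE table (from [call_de()]) with `gene`,
#'   `direction`, `called`.
#' @param universe background size for the overlap test (default: number
#'   of genes in the DE table).
#' @param z_cutoff |z| threshold for the activation call.
#' @return data.frame per regulator: `tf`, `n`, `z`, `state`, `overlap_p`,
#'   sorted by |z| decreasing.
#' @export
causal_activation_scores <- function(edges, de, universe = nrow(de),
                                     z_cutoff = 2) {
  stopifnot(all(c("tf", "target", "sign") %in% colnames(edges)),
            all(c("gene", "direction", "called") %in% colnames(de)))
  called <- de[de$called, , drop = FALSE]
  dirs <- stats::setNames(ifelse(called$direction == "up", 1L, -1L),
                          called$gene)
  measured <- de$gene
  out <- lapply(split(edges, edges$tf), function(e) {
    hit <- e$target %in% names(dirs)
    n <- sum(hit)
    if (n == 0) return(NULL)
    z <- sum(e$sign[hit] * dirs[e$target[hit]]) / sqrt(n)
    n_targets <- sum(e$target %in% measured)
    data.frame(tf = e$tf[1], n = n, z = z,
               state = if (z >= z_cutoff) "activated"
                       else if (z <= -z_cutoff) "inhibited" else "none",
               overlap_p = hypergeom_tail(n, n_targets, nrow(called),
                                          universe),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  if (is.null(out))
    return(data.frame(tf = character(0), n = integer(0), z = numeric(0),
                      state = character(0), overlap_p = numeric(0)))
  out[order(-abs(out$z)), , drop = FALSE]
}

tf_network <- function(edges, scores = NULL, channel) {
  rownames(edges) <- NULL
  structure(list(edges = edges, scores = scores, channel = channel),
            class = "tf_network")
}

#' @export
print.tf_network <- function(x, ...) {
  cat(sprintf("tf_network (%s): %d TFs, %d edges\n", x$channel,
              length(unique(x$edges$tf)), nrow(x$edges)))
  invisible(x)
}

#' Sequence channel: motif-target enrichment per module
#'
#' For each module, runs [ora()] of every regulator's motif-target set
#' (derived from a declared promoter window, conventionally TSS +/- 5 kb)
#' against the module's genes; regulators significant at `q <= alpha`
#' contribute edges `tf -> (targets intersect module genes)`, labelled
#' with the module.
#'
#' @param module_genes named list of character vectors (genes per module).
#' @param motif_targets named list of motif-target sets (e.g.
#'   [read_gmt()]).
#' @param universe character vector of background genes (module genes must
#'   be a subset).
#' @param alpha enrichment threshold on q.
#' @return a `tf_network` (channel `"sequence"`) with per-edge `module`
#'   labels and the per-(module, tf) enrichment table in `$scores`.
#' @export
build_sequence_network <- function(module_genes, motif_targets, universe,
                                   alpha = 0.05) {
  stopifnot(is.list(module_genes), is.list(motif_targets))
  edges <- list(); enr <- list()
  for (m in names(module_genes)) {
    res <- ora(module_genes[[m]], motif_targets, universe, alpha)
    res$module <- m
    enr[[m]] <- res
    for (tf in res$set[res$significant & res$k > 0]) {
      tg <- intersect(motif_targets[[tf]], module_genes[[m]])
      edges[[paste(m, tf)]] <- data.frame(tf = tf, target = tg, module = m,
                                          stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges))
    do.call(rbind, c(edges, list(make.row.names = FALSE)))
  else data.frame(tf = character(0), target = character(0),
                  module = character(0), stringsAsFactors = FALSE)
  edges$channel <- rep("sequence", nrow(edges))
  tf_network(edges, do.call(rbind, c(enr, list(make.row.names = FALSE))),
             "sequence")
}

#' Literature channel: signed-causal network of consistent regulators
#'
#' Scores every regulator with [causal_activation_scores()]; regulators
#' with `|z| >= z_threshold` and DE-overlap p `<= alpha` contribute their
#' matched called-DE target edges, labelled with the target's module where
#' one is assigned.
#'
#' @param edges signed causal edge list (`tf`, `target`, `sign`).
#' @param de a called DE table.
#' @param module_genes optional named list of module gene sets used to
#'   label edges.
#' @param universe background size for the overlap test.
#' @param z_threshold,alpha the two regulator gates.
#' @return a `tf_network` (channel `"literature"`) with the regulator
#'   score table in `$scores`.
#' @export
build_literature_network <- function(edges, de, module_genes = NULL,
                                     universe = nrow(de), z_threshold = 2,
                                     alpha = 0.05) {
  scores <- causal_activation_scores(edges, de, universe, z_threshold)
  keep_tf <- scores$tf[abs(scores$z) >= z_threshold &
                         scores$overlap_p <= alpha]
  called <- de$gene[de$called]
  sel <- edges[edges$tf %in% keep_tf & edges$target %in% called,
               c("tf", "target"), drop = FALSE]
  sel$module <- rep("unassigned", nrow(sel))
  if (!is.null(module_genes))
    for (m in names(module_genes))
      sel$module[sel$target %in% module_genes[[m]]] <- m
  sel$channel <- rep("literature", nrow(sel))
  tf_network(sel, scores, "literature")
}

#' Intersection of two TF networks
#'
#' The exact (tf, target) set intersection; retained TFs are those with at
#' least one surviving edge; per-TF scores from both parents are carried
#' along. Commutative, associative and idempotent on the edge sets.
#'
#' @param a,b `tf_network` objects sharing an id space.
#' @return a `tf_network` (channel `"intersection"`).
#' @export
intersect_networks <- function(a, b) {
  stopifnot(inherits(a, "tf_network"), inherits(b, "tf_network"))
  key_a <- paste(a$edges$tf, a$edges$target, sep = "\r")
  key_b <- paste(b$edges$tf, b$edges$target, sep = "\r")
  keep <- a$edges[key_a %in% key_b, c("tf", "target"), drop = FALSE]
  keep <- keep[!duplicated(paste(keep$tf, keep$target, sep = "\r")), ,
               drop = FALSE]
  mod <- a$edges$module[match(paste(keep$tf, keep$target, sep = "\r"), key_a)]
  keep$module <- if (is.null(mod)) rep("unassigned", nrow(keep)) else mod
  keep$channel <- rep("intersection", nrow(keep))
  tf_network(keep, list(a = a$scores, b = b$scores), "intersection")
}
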