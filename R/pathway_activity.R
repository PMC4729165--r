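# Sign-weighted mean log-expression pathway activity: each pathway's
# activity in a sample is the sum of member log2 ratios, repressors
# entering with weight -1, normalized by pathway size; significance comes
# from a gene-label permutation null.

#' Construct a sign-weighted pathway
#'
#' @param id Pathway identifier.
#' @param weights Named numeric vector gene -> weight in `{+1, -1}`
#'   (repressors are -1).
#' @return An object of class `weighted_pathway`.
#' @export
weighted_pathway <- function(id, weights) {
  if (length(weights) == 0) stop("weighted pathway must be non-empty")
  if (!all(weights %in% base::c(-1, 1)))
    stop("weights must be +1 or -1")
  structure(list(id = id, weights = weights), class = "weighted_pathway")
}

#' Derive repressor weights from signed topologies
#'
#' A member whose outgoing edges are all inhibitory is taken as a
#' repressor (weight -1); everything else gets +1. An explicit weight file
#' (see [read_pathway_weights()]) overrides this heuristic.
#'
#' @param tops Named list of [pathway_topology()] objects.
#' @return Named list of [weighted_pathway()] objects.
#' @export
weights_from_topologies <- function(tops) {
  out <- lapply(tops, function(tp) {
    outdeg <- colSums(tp$beta != 0)
    inhib <- colSums(tp$beta < 0)
    w <- ifelse(outdeg > 0 & inhib == outdeg, -1, 1)
    weighted_pathway(tp$id, stats::setNames(w, tp$genes))
  })
  stats::setNames(out, vapply(tops, `[[`, "", "id"))
}

#' Read / write pathway weight tables
#'
#' TSV `pathway_id  gene  weight` with a header.
#'
#' @param path File path.
#' @return Named list of [weighted_pathway()] objects.
#' @export
read_pathway_weights <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  sp <- split(df, df$pathway_id)
  stats::setNames(
    lapply(sp, function(d)
      weighted_pathway(d$pathway_id[1], stats::setNames(d$weight, d$gene))),
    names(sp))
}

#' @rdname read_pathway_weights
#' @param pathways Named list of [weighted_pathway()] objects.
#' @export
write_pathway_weights <- function(pathways, path) {
  df <- do.call(rbind, lapply(pathways, function(wp)
    data.frame(pathway_id = wp$id, gene = names(wp$weights),
               weight = unname(wp$weights), stringsAsFactors = FALSE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pathway activity index in one sample
#'
#' `A = sum_g w_g * log2ratio_g / size`, summed over measured member
#' genes; the denominator is either the measured member count (default) or
#' the full annotated pathway size.
#'
#' @param values Named numeric vector gene -> log2 ratio for one sample.
#' @param wp A [weighted_pathway()].
#' @param denominator `"measured_size"` (default) or `"annotated_size"`.
#' @return A single activity value.
#' @export
activity_index <- function(values, wp,
                           denominator = c("measured_size", "annotated_size")) {
  denominator <- match.arg(denominator)
  genes <- intersect(names(wp$weights), names(values))
  if (length(genes) == 0) stop("no measured member genes for pathway ", wp$id)
  size <- if (denominator == "measured_size") length(genes)
          else length(wp$weights)
  sum(wp$weights[genes] * values[genes]) / size
}

#' Pathway x sample activity matrix
#'
#' @param tc Gene x sample matrix of log2 ratios.
#' @param pathways Named list of [weighted_pathway()] objects.
#' @inheritParams activity_index
#' @return Numeric matrix (pathway x sample). Pathways with no measured
#'   member are dropped with a message.
#' @export
activity_matrix <- function(tc, pathways,
                            denominator = c("measured_size", "annotated_size")) {
  denominator <- match.arg(denominator)
  tc <- as.matrix(tc)
  measured <- vapply(pathways, function(wp)
    sum(names(wp$weights) %in% rownames(tc)), integer(1))
  if (any(measured == 0)) {
    message(sprintf("activity_matrix: dropping %d pathways with no measured members",
                    sum(measured == 0)))
    pathways <- pathways[measured > 0]
  }
  t(vapply(pathways, function(wp) {
    genes <- intersect(names(wp$weights), rownames(tc))
    size <- if (denominator == "measured_size") length(genes)
            else length(wp$weights)
    base::colSums(tc[genes, , drop = FALSE] * wp$weights[genes]) / size
  }, numeric(ncol(tc))))
}

#' Permutation significance of pathway activities
#'
#' The null permutes the gene-to-value assignment (one shared label
#' permutation across samples per iteration, equivalent to drawing a
#' random gene set of equal size); with one pooled array per condition a
#' sample-label permutation cannot form a within-condition null. Per
#' pathway the empirical FDR is the fraction of permutations whose maximal
#' absolute null activity across samples reaches the observed maximum,
#' floored at `1/n_perm`; per-sample empirical p-values and a BH-adjusted
#' variant are also reported.
#'
#' @param tc Gene x sample matrix of log2 ratios.
#' @param pathways Named list of [weighted_pathway()] objects.
#' @param n_perm Number of permutations (default 1000).
#' @param seed RNG seed.
#' @param fdr_cutoff Inclusion gate (default 0.01).
#' @inheritParams activity_index
#' @return List of class `activity_result`: `activity` (pathway x sample),
#'   `fdr` (empirical, per pathway), `q_bh` (BH over the empirical values),
#'   `p_sample` (pathway x sample empirical p), `included` (logical),
#'   `n_perm`, `seed`.
#' @export
activity_fdr <- function(tc, pathways, n_perm = 1000, seed = NULL,
                         fdr_cutoff = 0.01,
                         denominator = c("measured_size", "annotated_size")) {
  stopifnot(n_perm >= 1)
  denominator <- match.arg(denominator)
  tc <- as.matrix(tc)
  obs <- activity_matrix(tc, pathways, denominator)
  pathways <- pathways[rownames(obs)]
  # sparse pathway x gene weight operator, so each permutation is one matmul
  trip <- lapply(seq_along(pathways), function(p) {
    wp <- pathways[[p]]
    genes <- intersect(names(wp$weights), rownames(tc))
    size <- if (denominator == "measured_size") length(genes)
            else length(wp$weights)
    base::cbind(p, match(genes, rownames(tc)),
                unname(wp$weights[genes]) / size)
  })
  trip <- do.call(rbind, trip)
  W <- Matrix::sparseMatrix(i = trip[, 1], j = trip[, 2], x = trip[, 3],
                            dims = base::c(length(pathways), nrow(tc)))
  obs_max <- apply(abs(obs), 1, max)
  exceed <- numeric(nrow(obs))
  exceed_s <- matrix(0, nrow(obs), ncol(obs), dimnames = dimnames(obs))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      nullA <- as.matrix(W %*% tc[sample.int(nrow(tc)), , drop = FALSE])
      exceed <- exceed + (apply(abs(nullA), 1, max) >= obs_max)
      exceed_s <- exceed_s + (abs(nullA) >= abs(obs))
    }
  })
  fdr <- pmax(exceed, 1) / n_perm
  p_sample <- pmax(exceed_s, 1) / n_perm
  structure(list(activity = obs, fdr = fdr, q_bh = bh_fdr(fdr),
                 p_sample = p_sample, included = fdr < fdr_cutoff,
                 n_perm = n_perm,
                 seed = if (is.null(seed)) NA_integer_ else seed),
            class = "activity_result")
}

#' @export
print.activity_result <- function(x, ...) {
  cat(sprintf("activity_result: %d pathways x %d samples, %d included (FDR gate)\n",
              nrow(x$activity), ncol(x$activity), sum(x$included)))
  invisible(x)
}

#' Cluster significant pathway activity profiles
#'
#' Average-linkage, 1 - Pearson hierarchical clustering (via
#' [hierarchical_cluster()]) of the pathways passing the inclusion gate.
#'
#' @param res An [activity_fdr()] result.
#' @return List with the included activity `matrix`, `row_order`
#'   (dendrogram leaf order) and the `hclust` tree (`NULL` when fewer than
#'   2 pathways are included, with a warning).
#' @export
cluster_activities <- function(res) {
  m <- res$activity[res$included, , drop = FALSE]
  if (nrow(m) < 2) {
    warning("fewer than 2 included pathways; returning unclustered matrix")
    return(list(matrix = m, row_order = seq_len(nrow(m)), tree = NULL))
  }
  hc <- hierarchical_cluster(m)
  list(matrix = m, row_order = hc$order, tree = hc)
}
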