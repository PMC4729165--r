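# Functional network modules: a co-expression filter over differentially
# expressed genes, intersection with a functional interaction database, and
# partitioning with the Markov Cluster Algorithm.

#' Read / write an interaction database
#'
#' SIF (`geneA  interaction  geneB`) or 2-column TSV of undirected gene
#' pairs; self-loops are dropped and pairs stored canonically (unordered).
#'
#' @param path File path.
#' @return data.frame `a, b` of canonical pairs.
#' @export
read_interactions <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  pairs <- if (ncol(df) >= 3) df[, base::c(1, 3)] else df[, 1:2]
  names(pairs) <- base::c("a", "b")
  pairs <- pairs[pairs$a != pairs$b, ]
  unique(canonical_pairs(pairs$a, pairs$b))
}

#' @rdname read_interactions
#' @param db data.frame of gene pairs (`a`, `b`).
#' @param interaction Interaction label for the SIF middle column.
#' @export
write_interactions <- function(db, path, interaction = "FI") {
  utils::write.table(data.frame(db$a, interaction, db$b),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Co-expression filter over a time course
#'
#' Keeps exactly the gene pairs whose Pearson correlation across the
#' region's time grid exceeds `r_cutoff` (strict; signed r by default, the
#' literal reading of "correlation greater than 0.8" — set `use_abs` for
#' |r|). Zero-variance genes are excluded with a message.
#'
#' @param tc Gene x time matrix of log2 ratios (>= 3 time points).
#' @param genes Differentially expressed genes to consider.
#' @param r_cutoff Correlation threshold (default 0.8).
#' @param use_abs Threshold |r| instead of signed r.
#' @return A `correlation_network`: data.frame `a, b, r` (canonical pairs)
#'   with attribute `nodes`.
#' @export
correlation_filter <- function(tc, genes = rownames(tc), r_cutoff = 0.8,
                               use_abs = FALSE) {
  tc <- as.matrix(tc)[intersect(genes, rownames(tc)), , drop = FALSE]
  if (ncol(tc) < 3) stop("need at least 3 time points for correlation")
  sds <- apply(tc, 1, stats::sd)
  if (any(sds == 0)) {
    message(sprintf("correlation_filter: excluding %d zero-variance genes",
                    sum(sds == 0)))
    tc <- tc[sds > 0, , drop = FALSE]
  }
  cc <- stats::cor(t(tc))
  score <- if (use_abs) abs(cc) else cc
  idx <- which(upper.tri(score) & score > r_cutoff, arr.ind = TRUE)
  edges <- canonical_pairs(rownames(tc)[idx[, 1]], rownames(tc)[idx[, 2]])
  edges$r <- cc[idx]
  structure(edges[order(edges$a, edges$b), ], nodes = rownames(tc),
            class = base::c("correlation_network", "data.frame"))
}

#' Intersect a correlation network with an interaction database
#'
#' Keeps edges present in both; genes left isolated are dropped from the
#' node set.
#'
#' @param net A [correlation_filter()] result (or data.frame `a, b`).
#' @param db Interaction pairs from [read_interactions()].
#' @return A `correlation_network` restricted to supported edges.
#' @export
intersect_with_db <- function(net, db) {
  key_net <- paste(net$a, net$b, sep = "\r")
  dbc <- canonical_pairs(db$a, db$b)
  keep <- key_net %in% paste(dbc$a, dbc$b, sep = "\r")
  if (!any(keep)) warning("no network edge is supported by the database")
  out <- net[keep, , drop = FALSE]
  structure(out, nodes = sort(unique(base::c(out$a, out$b))),
            class = base::c("correlation_network", "data.frame"))
}

#' Markov Cluster Algorithm
#'
#' Adds self-loops, column-normalizes the adjacency, then alternates
#' expansion (matrix power) and inflation (entrywise power with
#' renormalization), pruning small entries, until the matrix is stable.
#' Clusters are read off the limit matrix as connected components of its
#' support; module ids are assigned 0..(k-1) by descending size
#' (deterministic tie-break on smallest member).
#'
#' @param net Edge data.frame (`a`, `b`, optional `weight`) or a
#'   `correlation_network`.
#' @param inflation Inflation exponent (> 1), default 2.
#' @param expansion Expansion power (integer >= 2), default 2.
#' @param self_loops Self-loop weight added to every node, default 1.
#' @param prune Entries below this are zeroed each iteration (1e-5).
#' @param max_iter Iteration cap (200).
#' @param tol Convergence threshold on the max entry change (1e-8).
#' @return A `module_partition`: named integer vector gene -> module id
#'   (0-based), with attributes `sizes` and `converged`.
#' @export
mcl <- function(net, inflation = 2, expansion = 2, self_loops = 1,
                prune = 1e-5, max_iter = 200, tol = 1e-8) {
  stopifnot(inflation > 1, expansion >= 2, expansion == round(expansion))
  nodes <- attr(net, "nodes")
  if (is.null(nodes)) nodes <- sort(unique(base::c(net$a, net$b)))
  nodes <- sort(nodes)
  n <- length(nodes)
  w <- if ("weight" %in% names(net)) abs(net$weight) else rep(1, nrow(net))
  i <- match(net$a, nodes); j <- match(net$b, nodes)
  M <- Matrix::sparseMatrix(i = base::c(i, j, seq_len(n)),
                            j = base::c(j, i, seq_len(n)),
                            x = base::c(w, w, rep(self_loops, n)),
                            dims = base::c(n, n))
  normalize <- function(m) {
    cs <- Matrix::colSums(m)
    cs[cs == 0] <- 1
    m %*% Matrix::Diagonal(x = 1 / cs)
  }
  M <- normalize(M)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    prev <- M
    Mp <- M
    for (e in seq_len(expansion - 1)) Mp <- Mp %*% M
    M <- Mp^inflation
    M <- Matrix::drop0(M * (M >= prune))
    M <- normalize(M)
    delta <- max(abs(M - prev))
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("mcl did not converge within max_iter; returning current partition")
  supp <- as(M != 0, "TsparseMatrix")
  g <- igraph::graph_from_data_frame(
    data.frame(from = nodes[supp@i + 1L], to = nodes[supp@j + 1L]),
    directed = FALSE, vertices = nodes)
  comp <- igraph::components(g)$membership[nodes]
  groups <- split(nodes, comp)
  ord <- order(-lengths(groups), vapply(groups, min, character(1)))
  part <- integer(n); names(part) <- nodes
  for (m_id in seq_along(ord)) part[groups[[ord[m_id]]]] <- m_id - 1L
  structure(part, sizes = as.integer(lengths(groups)[ord]),
            converged = converged, class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  sz <- attr(x, "sizes")
  cat(sprintf("module_partition: %d genes in %d modules (sizes %s)\n",
              length(x), length(sz), paste(sz, collapse = ", ")))
  invisible(x)
}

#' Write / read a module partition (TSV `gene  module_id`)
#'
#' @param part A `module_partition` (named integer vector).
#' @param path File path.
#' @export
write_partition <- function(part, path) {
  utils::write.table(data.frame(gene = names(part), module_id = as.integer(part)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  sizes <- sort(table(df$module_id), decreasing = TRUE)
  structure(stats::setNames(as.integer(df$module_id), df$gene),
            sizes = as.integer(sizes), converged = NA,
            class = "module_partition")
}

#' Annotate modules with representative ontology terms
#'
#' Per module: EASE-mode over-representation with BH correction at
#' `q_cutoff`, semantic-similarity redundancy reduction, and the surviving
#' term with the smallest q as representative; modules with no significant
#' term are labeled `"unannotated"`.
#'
#' @param part A `module_partition`.
#' @param background Gene universe.
#' @param sets Named list of gene sets.
#' @param ic,dag As in [semantic_similarity()].
#' @param q_cutoff Significance gate (default 0.01).
#' @param sim_cutoff Redundancy cutoff (default 0.7).
#' @return data.frame `module, representative, term_name_q` per module.
#' @export
annotate_modules <- function(part, background, sets, ic, dag,
                             q_cutoff = 0.01, sim_cutoff = 0.7) {
  mods <- sort(unique(as.integer(part)))
  rows <- lapply(mods, function(m_id) {
    genes <- intersect(names(part)[part == m_id], background)
    rep_term <- "unannotated"; rep_q <- NA_real_
    if (length(genes) > 0) {
      res <- suppressMessages(ora(genes, background, sets, mode = "ease"))
      res <- res[res$q < q_cutoff, , drop = FALSE]
      if (nrow(res) > 0) {
        red <- reduce_redundancy(res, ic, dag, sim_cutoff = sim_cutoff)
        best <- red$survivors[which.min(red$survivors$q), ]
        rep_term <- best$term; rep_q <- best$q
      }
    }
    data.frame(module = m_id, representative = rep_term, q = rep_q,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare module composition between two partitions
#'
#' @param a,b `module_partition` objects over overlapping gene universes.
#' @return List with `counts` (|module_i(a) n module_j(b)| matrix) and
#'   `jaccard` (intersection over union per module pair).
#' @export
compare_module_composition <- function(a, b) {
  ma <- sort(unique(as.integer(a))); mb <- sort(unique(as.integer(b)))
  counts <- matrix(0L, length(ma), length(mb),
                   dimnames = list(ma, mb))
  jac <- matrix(0, length(ma), length(mb), dimnames = list(ma, mb))
  for (i in seq_along(ma)) for (j in seq_along(mb)) {
    ga <- names(a)[a == ma[i]]; gb <- names(b)[b == mb[j]]
    inter <- length(intersect(ga, gb))
    counts[i, j] <- inter
    uni <- length(union(ga, gb))
    jac[i, j] <- if (uni > 0) inter / uni else 0
  }
  list(counts = counts, jaccard = jac)
}
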