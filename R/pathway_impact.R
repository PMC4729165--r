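# Two-evidence signaling pathway impact analysis: hypergeometric
# over-representation (P_NDE) and propagation of log2 fold changes through
# the signed pathway topology (P_PERT via bootstrap), combined into a
# global P_G.

#' Construct a signed pathway topology
#'
#' Edges carry beta(i <- j) = +1 (activation) or -1 (inhibition), possibly
#' scaled by a weight; the perturbation model divides each source gene's
#' outgoing influence by its downstream out-degree.
#'
#' @param id Pathway identifier.
#' @param genes Member genes.
#' @param edges data.frame with columns `src, dst, type` (`"activation"` or
#'   `"inhibition"`) and optional `weight`; both endpoints must be members.
#' @param name Display name (defaults to `id`).
#' @return An object of class `pathway_topology` with the beta matrix
#'   (`dst x src`) and per-gene downstream out-degree.
#' @export
pathway_topology <- function(id, genes, edges, name = id) {
  genes <- unique(as.character(genes))
  B <- matrix(0, length(genes), length(genes), dimnames = list(genes, genes))
  if (nrow(edges)) {
    if (!all(edges$src %in% genes) || !all(edges$dst %in% genes))
      stop("edge endpoints must be pathway members")
    sgn <- ifelse(edges$type == "inhibition", -1, 1)
    w <- if ("weight" %in% names(edges)) edges$weight else 1
    B[cbind(match(edges$dst, genes), match(edges$src, genes))] <- sgn * w
  }
  nds <- colSums(B != 0)
  structure(list(id = id, name = name, genes = genes, beta = B, nds = nds),
            class = "pathway_topology")
}

#' @export
print.pathway_topology <- function(x, ...) {
  cat(sprintf("pathway_topology %s: %d genes, %d edges (%d inhibitory)\n",
              x$id, length(x$genes), sum(x$beta != 0), sum(x$beta < 0)))
  invisible(x)
}

#' Read signed pathway topologies from a TSV edge list
#'
#' Format: `pathway_id  src  dst  type  [weight]` plus an optional
#' membership TSV `pathway_id  gene` declaring members without edges.
#'
#' @param path Edge-list TSV with a header.
#' @param members_path Optional membership TSV (header `pathway_id  gene`).
#' @return Named list of [pathway_topology()] objects.
#' @export
read_topologies <- function(path, members_path = NULL) {
  ed <- utils::read.delim(path, stringsAsFactors = FALSE)
  mem <- if (!is.null(members_path))
    utils::read.delim(members_path, stringsAsFactors = FALSE) else NULL
  ids <- unique(base::c(ed$pathway_id, mem$pathway_id))
  out <- lapply(ids, function(pid) {
    e <- ed[ed$pathway_id == pid, , drop = FALSE]
    genes <- unique(base::c(e$src, e$dst, mem$gene[mem$pathway_id == pid]))
    pathway_topology(pid, genes, e[names(e) != "pathway_id"])
  })
  stats::setNames(out, ids)
}

#' Write pathway topologies to TSV edge list + membership
#'
#' @param tops Named list of [pathway_topology()] objects.
#' @param path Edge-list output path.
#' @param members_path Membership output path.
#' @export
write_topologies <- function(tops, path, members_path) {
  ed <- do.call(rbind, lapply(tops, function(tp) {
    idx <- which(tp$beta != 0, arr.ind = TRUE)
    if (nrow(idx) == 0) return(NULL)
    data.frame(pathway_id = tp$id,
               src = tp$genes[idx[, 2]], dst = tp$genes[idx[, 1]],
               type = ifelse(tp$beta[idx] < 0, "inhibition", "activation"),
               weight = abs(tp$beta[idx]), stringsAsFactors = FALSE)
  }))
  utils::write.table(ed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  mem <- do.call(rbind, lapply(tops, function(tp)
    data.frame(pathway_id = tp$id, gene = tp$genes, stringsAsFactors = FALSE)))
  utils::write.table(mem, members_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Influence matrix M[i, j] = beta(i <- j) / N_ds(j); PF = (I - M)^{-1} dE.
.influence <- function(top) {
  nds <- pmax(top$nds, 1)
  sweep(top$beta, 2, nds, "/")
}

#' Propagate perturbation through a signed topology
#'
#' Solves the linear system `PF(i) = dE(i) + sum_j beta(i<-j) PF(j)/N_ds(j)`
#' for the perturbation factor of every member gene; the accumulation
#' `Acc = PF - dE` beyond each gene's own change sums to the pathway's net
#' total accumulation `t_A`.
#'
#' @param top A [pathway_topology()].
#' @param dE Named numeric vector of log2 fold changes on member genes
#'   (members absent from `dE` count as 0).
#' @return List with `pf`, `acc` (named per gene) and `t_a`.
#' @export
net_perturbation <- function(top, dE) {
  x <- stats::setNames(rep(0, length(top$genes)), top$genes)
  common <- intersect(names(dE), top$genes)
  x[common] <- dE[common]
  A <- diag(length(top$genes)) - .influence(top)
  if (rcond(A) < 1e-12)
    stop("singular propagation system (I - B not invertible) for pathway ",
         top$id)
  pf <- solve(A, x)
  acc <- pf - x
  list(pf = pf, acc = acc, t_a = sum(acc))
}

#' Hypergeometric over-representation evidence
#'
#' Upper-tail `P(X >= k)` for `k` differentially expressed genes inside a
#' pathway of `K` measured members, with `n` DE genes among `N` background
#' genes.
#'
#' @param k,K,n,N Counts as above.
#' @return Probability in (0, 1].
#' @export
p_nde <- function(k, K, n, N) {
  stopifnot(k <= min(K, n))
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Bootstrap perturbation evidence
#'
#' Null total accumulations are built by placing `n_de_in_path` values
#' drawn (with replacement) from the pool of all DE log2 fold changes on
#' uniformly random member genes; the two-sided p-value around the null
#' median is floored at `1/n_boot`.
#'
#' @param top A [pathway_topology()].
#' @param dE_pool Numeric vector of all DE log2 fold changes.
#' @param n_de_in_path Number of DE genes observed in the pathway.
#' @param t_a Observed total accumulation.
#' @param n_boot Bootstrap iterations (default 3000).
#' @param seed RNG seed.
#' @return List with `p_pert` and the null vector `t_a_null`.
#' @export
p_pert_bootstrap <- function(top, dE_pool, n_de_in_path, t_a,
                             n_boot = 3000, seed = NULL) {
  stopifnot(n_boot >= 1, n_de_in_path >= 0)
  if (n_de_in_path == 0)
    return(list(p_pert = 1, t_a_null = rep(0, n_boot)))
  A <- diag(length(top$genes)) - .influence(top)
  v <- base::colSums(solve(A)) - 1  # t_A = sum((M_inv - I) dE) = v . dE
  ng <- length(top$genes)
  null <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      pos <- sample.int(ng, n_de_in_path)
      vals <- dE_pool[sample.int(length(dE_pool), n_de_in_path, replace = TRUE)]
      sum(v[pos] * vals)
    }, numeric(1))
  })
  med <- stats::median(null)
  p <- sum(abs(null - med) >= abs(t_a - med)) / n_boot
  list(p_pert = max(p, 1 / n_boot), t_a_null = null)
}

#' Combine over-representation and perturbation evidence
#'
#' Fisher-style product combination: with `c = p_nde * p_pert`,
#' `P_G = c - c ln(c)`; symmetric in its arguments and monotone in `c`.
#'
#' @param p_nde,p_pert Probabilities in (0, 1].
#' @return Global p-value in (0, 1].
#' @export
combine_pg <- function(p_nde, p_pert) {
  if (any(p_nde <= 0) || any(p_pert <= 0)) {
    warning("zero evidence p clamped to machine minimum")
    p_nde <- pmax(p_nde, .Machine$double.xmin)
    p_pert <- pmax(p_pert, .Machine$double.xmin)
  }
  cc <- p_nde * p_pert
  cc - cc * log(cc)
}

#' Run the two-evidence pathway impact analysis
#'
#' Per pathway: over-representation evidence, perturbation propagation
#' with bootstrap null, combination into `P_G`, BH and Bonferroni
#' correction over pathways, and activation status from the sign of
#' `t_A`. Pathways with fewer than 2 measured members, or with a singular
#' propagation system, are skipped with a log message. Results are
#' invariant to the input order of pathways (per-pathway RNG substreams
#' are tied to sorted pathway ids).
#'
#' @param de Named numeric vector: DE genes -> log2 fold change.
#' @param background Character vector, the measured gene universe.
#' @param tops List of [pathway_topology()] objects.
#' @param n_boot Bootstrap iterations (default 3000).
#' @param seed RNG seed (mandatory for reproducibility).
#' @return data.frame `pathway, name, size, n_de, p_nde, t_a, p_pert, p_g,
#'   q_fdr, q_bonferroni, status`, ordered by `p_g`.
#' @export
run_spia <- function(de, background, tops, n_boot = 3000, seed = 1) {
  if (!all(names(de) %in% background))
    stop("DE genes must be a subset of the background")
  tops <- tops[order(vapply(tops, `[[`, "", "id"))]
  N <- length(unique(background)); n <- length(de)
  rows <- lapply(seq_along(tops), function(i) {
    tp <- tops[[i]]
    measured <- intersect(tp$genes, background)
    if (length(measured) < 2) {
      message("run_spia: skipping pathway ", tp$id, " (<2 measured members)")
      return(NULL)
    }
    de_in <- intersect(names(de), tp$genes)
    k <- length(de_in)
    pn <- p_nde(k, length(measured), n, N)
    res <- tryCatch({
      prop <- net_perturbation(tp, de)
      pp <- p_pert_bootstrap(tp, unname(de), k, prop$t_a, n_boot,
                             seed = child_seed(seed, i))
      list(t_a = prop$t_a, p_pert = pp$p_pert)
    }, error = function(e) {
      message("run_spia: skipping pathway ", tp$id, " (", conditionMessage(e), ")")
      NULL
    })
    if (is.null(res)) return(NULL)
    data.frame(pathway = tp$id, name = tp$name, size = length(measured),
               n_de = k, p_nde = pn, t_a = res$t_a, p_pert = res$p_pert,
               p_g = combine_pg(pn, res$p_pert),
               status = if (res$t_a > 0) "activated" else "inhibited",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no pathway could be analyzed")
  out$q_fdr <- bh_fdr(out$p_g)
  out$q_bonferroni <- pmin(1, length(out$p_g) * out$p_g)
  out <- out[order(out$p_g, out$pathway), ]
  rownames(out) <- NULL
  out[base::c("pathway", "name", "size", "n_de", "p_nde", "t_a", "p_pert",
              "p_g", "q_fdr", "q_bonferroni", "status")]
}

#' Derive the DE input for pathway analysis from a time course
#'
#' The union over non-reference time points of genes reaching the fold
#' threshold, each carrying its maximal-magnitude log2 fold change.
#'
#' @param tc Gene x time matrix of log2 ratios.
#' @param fold Fold-change threshold (default 2).
#' @param genes Optional restriction (e.g. one pattern's genes).
#' @param ref_time Reference time column.
#' @return Named numeric vector gene -> signed log2 fold change.
#' @export
de_from_timecourse <- function(tc, fold = 2, genes = rownames(tc),
                               ref_time = 0) {
  tc <- as.matrix(tc)[genes, , drop = FALSE]
  r <- ref_column(tc, ref_time)
  x <- tc[, -r, drop = FALSE]
  imax <- max.col(abs(x), ties.method = "first")
  val <- x[cbind(seq_len(nrow(x)), imax)]
  sel <- abs(val) >= log2(fold)
  stats::setNames(val[sel], rownames(tc)[sel])
}
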