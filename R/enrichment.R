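# Over-representation analysis against named gene-set collections, plus an
# information-content view of a small ontology for semantic-similarity-based
# redundancy reduction of enriched terms.

#' Read a gene set collection (GMT)
#'
#' @param path Path to a GMT file (term, description, members...).
#' @return Named list of character vectors (term id -> member genes).
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write a gene set collection (GMT)
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional named descriptions (defaults to the ids).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- names(sets)
  lines <- vapply(seq_along(sets), function(i)
    paste(base::c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an ontology from OBO (is_a hierarchy only)
#'
#' Minimal parser for `[Term]` stanzas honoring `id`, `name`, `is_a` and
#' `is_obsolete`; all other relationship types are ignored.
#'
#' @param path Path to an OBO file.
#' @return An `ontology_dag`; see [ontology_dag()].
#' @export
read_obo <- function(path) {
  lines <- readLines(path)
  starts <- grep("^\\[Term\\]\\s*$", lines)
  bounds <- base::c(starts, length(lines) + 1L)
  ids <- character(0); nms <- character(0); parents <- list()
  for (i in seq_along(starts)) {
    block <- lines[starts[i]:(bounds[i + 1] - 1L)]
    if (any(grepl("^is_obsolete: true", block))) next
    id <- sub("^id: *", "", grep("^id: ", block, value = TRUE)[1])
    nm <- sub("^name: *", "", grep("^name: ", block, value = TRUE)[1])
    isa <- sub("^is_a: *([^ !]+).*$", "\\1", grep("^is_a: ", block, value = TRUE))
    ids <- base::c(ids, id)
    nms <- base::c(nms, if (is.na(nm)) id else nm)
    parents[[id]] <- isa
  }
  ontology_dag(ids, stats::setNames(nms, ids), parents)
}

#' Construct an ontology DAG
#'
#' Directed is_a edges child -> parent; must be acyclic with every term
#' reaching a root (a term with no parents).
#'
#' @param terms Character vector of term ids.
#' @param names Named character vector of term names.
#' @param parents Named list, term id -> character vector of parent ids.
#' @return An object of class `ontology_dag` with precomputed ancestor
#'   sets (each term is its own ancestor) and depths.
#' @export
ontology_dag <- function(terms, names = stats::setNames(terms, terms),
                         parents = list()) {
  parents <- parents[terms[terms %in% base::names(parents)]]
  for (t in setdiff(terms, base::names(parents))) parents[[t]] <- character(0)
  unknown <- setdiff(unlist(parents), terms)
  if (length(unknown))
    stop("is_a parents not declared as terms: ", paste(unknown, collapse = ", "))
  anc <- vector("list", length(terms)); base::names(anc) <- terms
  depth <- stats::setNames(rep(NA_integer_, length(terms)), terms)
  get_anc <- function(t, seen = character(0)) {
    if (!is.null(anc[[t]])) return(anc[[t]])
    if (t %in% seen) stop("cycle detected at term ", t)
    ps <- parents[[t]]
    res <- t
    for (p in ps) res <- union(res, get_anc(p, base::c(seen, t)))
    anc[[t]] <<- res
    res
  }
  for (t in terms) get_anc(t)
  # depth = shortest is_a path to a root
  roots <- terms[lengths(parents[terms]) == 0]
  if (length(roots) == 0) stop("ontology has no root")
  depth[roots] <- 0L
  frontier <- roots
  children <- split(rep(base::names(parents), lengths(parents)), unlist(parents))
  while (length(frontier)) {
    nxt <- character(0)
    for (p in frontier) for (ch in children[[p]])
      if (is.na(depth[ch])) { depth[ch] <- depth[p] + 1L; nxt <- base::c(nxt, ch) }
    frontier <- nxt
  }
  if (anyNA(depth)) stop("terms not reaching a root: ",
                         paste(terms[is.na(depth)], collapse = ", "))
  structure(list(terms = terms, names = names, parents = parents,
                 ancestors = anc, roots = roots, depth = depth),
            class = "ontology_dag")
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat(sprintf("ontology_dag: %d terms, %d root(s), max depth %d\n",
              length(x$terms), length(x$roots), max(x$depth)))
  invisible(x)
}

#' Write an ontology to OBO
#'
#' @param dag An [ontology_dag()].
#' @param path Output path.
#' @export
write_obo <- function(dag, path) {
  out <- base::c("format-version: 1.2", "")
  for (t in dag$terms) {
    ps <- dag$parents[[t]]
    out <- base::c(out, "[Term]", paste0("id: ", t),
                   paste0("name: ", dag$names[[t]]),
                   if (length(ps)) paste0("is_a: ", ps), "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a gene annotation corpus (2-column TSV) and propagate
#'
#' The corpus file holds `gene  term` rows; annotations are closed under
#' ancestor propagation against the DAG.
#'
#' @param path Path to the TSV (no header).
#' @param dag An [ontology_dag()].
#' @return Named list, gene -> character vector of terms (propagated).
#' @export
read_annotations <- function(path, dag) {
  df <- utils::read.delim(path, header = FALSE,
                          col.names = base::c("gene", "term"),
                          stringsAsFactors = FALSE)
  propagate_annotations(split(df$term, df$gene), dag)
}

#' @rdname read_annotations
#' @param corpus Named list gene -> terms (not necessarily propagated).
#' @export
propagate_annotations <- function(corpus, dag) {
  lapply(corpus, function(ts)
    unique(unlist(dag$ancestors[intersect(ts, dag$terms)], use.names = FALSE)))
}

#' Write a gene annotation corpus (2-column TSV)
#'
#' @param corpus Named list gene -> terms.
#' @param path Output path.
#' @export
write_annotations <- function(corpus, path) {
  df <- data.frame(gene = rep(base::names(corpus), lengths(corpus)),
                   term = unlist(corpus, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Over-representation analysis (hypergeometric / EASE)
#'
#' One-sided hypergeometric upper tail `P(X >= k)` for the overlap `k` of
#' the query with each set, against a finite background universe. The
#' `ease` mode is the conservative variant that decrements the observed
#' overlap by one before taking the tail. Terms with no background overlap
#' are skipped with a message.
#'
#' @param query Character vector of genes (subset of `background`).
#' @param background Character vector, the measured gene universe.
#' @param sets Named list of gene sets.
#' @param mode `"ease"` (default) or `"fisher"`.
#' @return data.frame `term, k, K, n, N, p, q` sorted by p; `q` is the
#'   Benjamini-Hochberg adjusted p over the tested terms.
#' @export
ora <- function(query, background, sets, mode = c("ease", "fisher")) {
  mode <- match.arg(mode)
  if (length(query) == 0) stop("empty query gene list")
  if (!all(query %in% background)) stop("query must be a subset of background")
  query <- unique(query); background <- unique(background)
  N <- length(background); n <- length(query)
  K <- vapply(sets, function(s) length(intersect(s, background)), integer(1))
  k <- vapply(sets, function(s) length(intersect(s, query)), integer(1))
  skip <- K == 0
  if (any(skip))
    message(sprintf("ora: skipping %d sets with no background overlap", sum(skip)))
  K <- K[!skip]; k <- k[!skip]
  keff <- if (mode == "ease") pmax(k - 1L, 0L) else k
  p <- stats::phyper(keff - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(term = base::names(K), k = k, K = K, n = n, N = N, p = p,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$term), ]
  out$q <- bh_fdr(out$p)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' `q_(i) = min_{j >= i} (m/j) p_(j)` clipped at 1, returned in input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Information content of ontology terms
#'
#' `IC(t) = -ln(freq(t) / freq(root))` over a propagated annotation
#' corpus, where `freq` counts annotated genes. The root has IC 0 and IC is
#' non-decreasing from parent to child. Terms unused in the corpus get
#' `NA` and are flagged with a message.
#'
#' @param corpus Named list gene -> propagated terms.
#' @param dag An [ontology_dag()].
#' @return Named numeric vector of IC per term (`NA` where undefined).
#' @export
information_content <- function(corpus, dag) {
  freq <- table(factor(unlist(corpus, use.names = FALSE), levels = dag$terms))
  freq <- as.numeric(freq); base::names(freq) <- dag$terms
  root_freq <- max(freq[dag$roots])
  ic <- -log(freq / root_freq)
  ic[freq == 0] <- NA_real_
  if (anyNA(ic))
    message(sprintf("information_content: %d terms unused in corpus (IC undefined)",
                    sum(is.na(ic))))
  ic
}

#' Semantic similarity between ontology terms
#'
#' Resnik similarity is the IC of the most informative common ancestor
#' (MICA); Lin similarity rescales it as `2 IC(MICA) / (IC(t1) + IC(t2))`,
#' bounded in `[0, 1]`. With no common ancestor (multi-root ontologies)
#' similarity is 0, with a warning.
#'
#' @param t1,t2 Term ids.
#' @param ic Named IC vector from [information_content()].
#' @param dag An [ontology_dag()].
#' @param method `"lin"` (default) or `"resnik"`.
#' @return A single similarity value.
#' @export
semantic_similarity <- function(t1, t2, ic, dag, method = c("lin", "resnik")) {
  method <- match.arg(method)
  if (is.na(ic[t1]) || is.na(ic[t2])) stop("both terms must have defined IC")
  common <- intersect(dag$ancestors[[t1]], dag$ancestors[[t2]])
  common <- common[!is.na(ic[common])]
  if (length(common) == 0) {
    warning("no common ancestor; similarity 0")
    return(0)
  }
  mica <- max(ic[common])
  if (method == "resnik") return(mica)
  denom <- ic[[t1]] + ic[[t2]]
  if (denom == 0) return(0)
  2 * mica / denom
}

#' Pairwise semantic similarity matrix
#'
#' @param terms Term ids.
#' @inheritParams semantic_similarity
#' @return Symmetric matrix of similarities.
#' @export
similarity_matrix <- function(terms, ic, dag, method = c("lin", "resnik")) {
  method <- match.arg(method)
  n <- length(terms)
  m <- matrix(0, n, n, dimnames = list(terms, terms))
  if (n < 2) { diag(m) <- 1; return(m) }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- suppressWarnings(semantic_similarity(terms[i], terms[j], ic, dag, method))
    m[i, j] <- m[j, i] <- s
  }
  diag(m) <- if (method == "lin") 1 else vapply(terms, function(t) ic[[t]], 0)
  m
}

#' Reduce redundant enriched terms by semantic similarity
#'
#' Greedy, REVIGO-flavored: term pairs are processed by descending
#' similarity; when a pair exceeds `sim_cutoff` and both terms are still
#' alive, the one with the larger q is marked dispensable (ties: the more
#' general term, i.e. smaller IC, then lexicographically larger id). The
#' lowest-q term of any similarity component always survives. Each removed
#' term receives a dispensability score: its maximal similarity to a
#' survivor.
#'
#' @param results An [ora()]-style data.frame carrying `term` and `q`.
#' @param ic,dag As in [semantic_similarity()].
#' @param sim_cutoff Similarity above which two terms are redundant
#'   (default 0.7, a "medium" reduction).
#' @param method Similarity flavor passed to [similarity_matrix()].
#' @return List with `survivors` (subset of `results`) and `dispensability`
#'   (data.frame `term, dispensability, absorbed_by`).
#' @export
reduce_redundancy <- function(results, ic, dag, sim_cutoff = 0.7,
                              method = "lin") {
  if (!all(base::c("term", "q") %in% base::names(results)))
    stop("results must carry term and q columns")
  terms <- results$term
  if (length(terms) < 2)
    return(list(survivors = results,
                dispensability = data.frame(term = character(0),
                                            dispensability = numeric(0),
                                            absorbed_by = character(0))))
  sim <- similarity_matrix(terms, ic, dag, method)
  qv <- stats::setNames(results$q, terms)
  pairs <- which(upper.tri(sim) & sim > sim_cutoff, arr.ind = TRUE)
  ord <- order(-sim[pairs], terms[pairs[, 1]], terms[pairs[, 2]])
  pairs <- pairs[ord, , drop = FALSE]
  alive <- stats::setNames(rep(TRUE, length(terms)), terms)
  for (rr in seq_len(nrow(pairs))) {
    t1 <- terms[pairs[rr, 1]]; t2 <- terms[pairs[rr, 2]]
    if (!alive[t1] || !alive[t2]) next
    drop <- if (qv[t1] > qv[t2]) t1
            else if (qv[t2] > qv[t1]) t2
            else if (ic[[t1]] < ic[[t2]]) t1   # more general term goes
            else if (ic[[t2]] < ic[[t1]]) t2
            else max(t1, t2)
    alive[drop] <- FALSE
  }
  surv <- terms[alive[terms]]
  removed <- terms[!alive[terms]]
  disp <- vapply(removed, function(t) max(sim[t, surv]), numeric(1))
  absorbed <- vapply(removed, function(t) surv[which.max(sim[t, surv])],
                     character(1))
  list(survivors = results[results$term %in% surv, , drop = FALSE],
       dispensability = data.frame(term = removed, dispensability = disp,
                                   absorbed_by = absorbed,
                                   stringsAsFactors = FALSE))
}

#' Similarity network over surviving terms
#'
#' Nodes are surviving terms (attributes: -log10 q and hierarchy depth);
#' edges connect pairs with similarity above `edge_cutoff`, weighted by
#' similarity.
#'
#' @param survivors data.frame with `term` and `q`.
#' @param sim Similarity matrix covering the survivors.
#' @param dag An [ontology_dag()].
#' @param edge_cutoff Minimum similarity for an edge (default 0.1).
#' @return An [igraph::graph] with vertex attributes `neg_log10_q`,
#'   `depth` and edge attribute `weight`.
#' @export
term_network <- function(survivors, sim, dag, edge_cutoff = 0.1) {
  terms <- survivors$term
  s <- sim[terms, terms, drop = FALSE]
  s[s <= edge_cutoff] <- 0
  diag(s) <- 0
  g <- igraph::graph_from_adjacency_matrix(s, mode = "undirected",
                                           weighted = TRUE)
  igraph::V(g)$neg_log10_q <- -log10(pmax(survivors$q, .Machine$double.xmin))
  igraph::V(g)$depth <- as.integer(dag$depth[terms])
  g
}

#' Per-time-point enrichment track
#'
#' At every non-reference time point the query is the genes with
#' `|log2 ratio| >= log2(fold)` at that time; [ora()] plus [bh_fdr()] give
#' a term x time matrix of q-values, masked (`NA`) where `q >= q_cutoff`.
#'
#' @param tc Gene x time matrix of log2 ratios.
#' @param sets Named list of gene sets.
#' @param background Gene universe (defaults to rownames of `tc`).
#' @param fold Per-time-point fold threshold (default 2).
#' @param q_cutoff Significance gate (default 0.01).
#' @param mode [ora()] mode.
#' @param ref_time Reference time column.
#' @return List with `q` (full term x time q matrix) and `masked` (same
#'   with non-significant cells set `NA`).
#' @export
per_timepoint_enrichment <- function(tc, sets, background = rownames(tc),
                                     fold = 2, q_cutoff = 0.01,
                                     mode = "ease", ref_time = 0) {
  tc <- as.matrix(tc)
  r <- ref_column(tc, ref_time)
  times <- colnames(tc)[-r]
  qmat <- matrix(1, length(sets), length(times),
                 dimnames = list(base::names(sets), times))
  for (t in times) {
    query <- rownames(tc)[abs(tc[, t]) >= log2(fold)]
    if (length(query) == 0) {
      message(sprintf("per_timepoint_enrichment: empty query at time %s", t))
      next
    }
    res <- ora(query, background, sets, mode = mode)
    qmat[res$term, t] <- res$q
  }
  masked <- qmat
  masked[masked >= q_cutoff] <- NA_real_
  list(q = qmat, masked = masked)
}
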