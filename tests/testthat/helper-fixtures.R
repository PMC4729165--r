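# Shared in-code fixtures for the test suite.

# Tiny probe table: 3 genes x 2 duplicated probes x 3 samples.
toy_probe_table <- function() {
  genes <- c("gA", "gB", "gC")
  probe_id <- c(paste0(genes, "_1"), paste0(genes, "_2"))
  sig <- matrix(c(200, 400, 800,
                  210, 390, 810,
                  100, 300, 500,
                  110, 290, 510,
                  400, 200, 100,
                  390, 210, 110), nrow = 6, byrow = TRUE,
                dimnames = list(probe_id, c("s1", "s2", "s3")))
  bg <- matrix(50, 6, 3, dimnames = dimnames(sig))
  probe_table(probe_id, rep(genes, 2), sig, bg)
}

# Hand-built 5-term chain ontology with controllable annotation counts:
# root -> a -> b, root -> c; frequencies set through the corpus.
toy_dag <- function() {
  ontology_dag(
    terms = c("root", "a", "b", "c"),
    names = stats::setNames(c("root", "a", "b", "c"),
                            c("root", "a", "b", "c")),
    parents = list(root = character(0), a = "root", b = "a", c = "root"))
}

# Corpus with freq(root)=8, freq(a)=4, freq(b)=2, freq(c)=4 (propagated).
toy_corpus <- function() {
  corpus <- c(
    lapply(1:2, function(i) "b"),
    lapply(1:2, function(i) "a"),
    lapply(1:4, function(i) "c"))
  names(corpus) <- paste0("g", 1:8)
  propagate_annotations(corpus, toy_dag())
}

# Simple linear activation chain topology over n genes.
chain_topology <- function(n, id = "chain", type = "activation") {
  genes <- sprintf("c%02d", seq_len(n))
  pathway_topology(id, genes,
                   data.frame(src = genes[-n], dst = genes[-1], type = type))
}

# Random acyclic signed topology (forward edges only => never singular).
random_topology <- function(n, id, p_edge = 0.2, p_inhib = 0.3) {
  genes <- sprintf("r%02d", seq_len(n))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(idx)) < p_edge
  idx <- idx[keep, , drop = FALSE]
  edges <- data.frame(
    src = genes[idx[, 1]], dst = genes[idx[, 2]],
    type = ifelse(runif(nrow(idx)) < p_inhib, "inhibition", "activation"))
  pathway_topology(id, genes, edges)
}

# Damped Jacobi fixed-point iteration: the independent oracle for the
# perturbation propagation linear system.
jacobi_perturbation <- function(top, dE, damp = 0.5, tol = 1e-12,
                                max_iter = 20000) {
  genes <- top$genes
  x <- stats::setNames(rep(0, length(genes)), genes)
  x[intersect(names(dE), genes)] <- dE[intersect(names(dE), genes)]
  M <- sweep(top$beta, 2, pmax(top$nds, 1), "/")
  pf <- x
  for (i in seq_len(max_iter)) {
    nxt <- (1 - damp) * pf + damp * (x + as.vector(M %*% pf))
    if (max(abs(nxt - pf)) < tol) break
    pf <- nxt
  }
  list(pf = pf, acc = pf - x, t_a = sum(pf - x))
}

# Exhaustive hypergeometric upper tail from binomial coefficients: the
# independent oracle for over-representation p-values.
brute_hyper_tail <- function(k, K, n, N) {
  if (k <= 0) return(1)
  kk <- seq(k, min(K, n))
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Small pure-noise gene x time matrix.
noise_matrix <- function(n_genes, times = 0:4, sd = 0.3) {
  m <- matrix(rnorm(n_genes * length(times), 0, sd), n_genes,
              dimnames = list(sprintf("n%04d", seq_len(n_genes)), times))
  m
}
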