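test_that("over-representation p-values match exhaustive enumeration", {
  bg <- sprintf("g%03d", 1:20)
  sets <- list(S = bg[1:5])
  res_f <- ora(bg[1:5], bg, sets, mode = "fisher")
  expect_equal(res_f$p, 1 / choose(20, 5), tolerance = 1e-14)
  # EASE decrements the overlap, so its p is strictly larger
  res_e <- ora(bg[1:5], bg, sets, mode = "ease")
  expect_gt(res_e$p, res_f$p)
  expect_equal(res_e$p, brute_hyper_tail(4, 5, 5, 20), tolerance = 1e-14)
  # zero overlap
  res0 <- ora(bg[6:10], bg, list(S = bg[1:5]), mode = "fisher")
  expect_equal(res0$p, 1)
  # random small tables against the brute-force oracle
  set.seed(3)
  for (i in 1:25) {
    N <- sample(10:60, 1); K <- sample(1:(N - 1), 1); n <- sample(1:(N - 1), 1)
    bgr <- sprintf("x%03d", 1:N)
    q <- sample(bgr, n); s <- list(S = bgr[1:K])
    k <- length(intersect(q, s$S))
    got <- suppressMessages(ora(q, bgr, s, mode = "fisher"))$p
    expect_equal(got, brute_hyper_tail(k, K, n, N), tolerance = 1e-12)
  }
  expect_error(ora(character(0), bg, sets), "empty")
  expect_error(ora("nope", bg, sets), "subset")
})

test_that("BH adjustment reproduces the step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(5)
  p <- runif(30)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-15))  # monotone along sorted p
})

test_that("information content is zero at the root and grows down the DAG", {
  dag <- toy_dag()
  corpus <- toy_corpus()
  ic <- information_content(corpus, dag)
  expect_equal(unname(ic["root"]), 0)
  expect_equal(unname(ic["a"]), log(2))   # annotated to half the corpus
  expect_equal(unname(ic["b"]), log(4))
  for (t in c("a", "b", "c"))
    for (p in dag$parents[[t]])
      expect_gte(ic[[t]], ic[[p]])
})

test_that("semantic similarity follows the Resnik/Lin formulas", {
  dag <- toy_dag()
  ic <- information_content(toy_corpus(), dag)
  expect_equal(semantic_similarity("b", "b", ic, dag, "lin"), 1)
  # MICA of a and c is the root
  expect_equal(semantic_similarity("a", "c", ic, dag, "resnik"), 0)
  expect_equal(semantic_similarity("a", "c", ic, dag, "lin"), 0)
  # chain root -> a -> b with hand frequencies: lin = 2 IC(a)/(IC(a)+IC(b))
  expect_equal(semantic_similarity("a", "b", ic, dag, "lin"),
               2 * log(2) / (log(2) + log(4)))
  # symmetry and bounds
  expect_equal(semantic_similarity("a", "b", ic, dag, "lin"),
               semantic_similarity("b", "a", ic, dag, "lin"))
  s <- similarity_matrix(c("a", "b", "c"), ic, dag, "lin")
  expect_true(all(s >= 0 & s <= 1))
  expect_equal(s, t(s))
})

test_that("redundancy reduction keeps the most significant term of a clique", {
  dag <- toy_dag()
  ic <- information_content(toy_corpus(), dag)
  # b and b-like duplicate: use a and b with forced high similarity cutoff 0
  res <- data.frame(term = c("a", "b"), q = c(0.01, 0.001),
                    stringsAsFactors = FALSE)
  red <- reduce_redundancy(res, ic, dag, sim_cutoff = 0.5)
  expect_identical(red$survivors$term, "b")       # larger q removed
  expect_equal(red$dispensability$term, "a")
  expect_gt(red$dispensability$dispensability, 0.5)
  # all similarities below the cutoff: identity
  res2 <- data.frame(term = c("a", "c"), q = c(0.01, 0.001))
  red2 <- reduce_redundancy(res2, ic, dag, sim_cutoff = 0.5)
  expect_setequal(red2$survivors$term, c("a", "c"))
  # three terms, (a,b) similar, c unrelated, q_a < q_b -> survivors {a, c}
  res3 <- data.frame(term = c("a", "b", "c"), q = c(0.001, 0.01, 0.5))
  red3 <- reduce_redundancy(res3, ic, dag, sim_cutoff = 0.5)
  expect_setequal(red3$survivors$term, c("a", "c"))
  # the lowest-q member of the similar pair always survives
  expect_true("a" %in% red3$survivors$term)
})

test_that("term networks connect similar survivors with weighted edges", {
  dag <- toy_dag()
  ic <- information_content(toy_corpus(), dag)
  sim <- similarity_matrix(c("a", "b", "c"), ic, dag, "lin")
  g1 <- term_network(data.frame(term = "a", q = 0.01), sim, dag)
  expect_equal(igraph::vcount(g1), 1)
  expect_equal(igraph::ecount(g1), 0)
  g2 <- term_network(data.frame(term = c("a", "b"), q = c(0.01, 0.001)),
                     sim, dag, edge_cutoff = 0.1)
  expect_equal(igraph::ecount(g2), 1)
  expect_equal(igraph::E(g2)$weight, sim["a", "b"])
  expect_equal(igraph::V(g2)$depth, c(1L, 2L))
})

test_that("per-time-point enrichment localizes a planted signal", {
  set.seed(8)
  genes <- sprintf("g%03d", 1:200)
  m <- matrix(rnorm(200 * 4, 0, 0.1), 200, 4, dimnames = list(genes, 0:3))
  planted <- genes[1:25]
  m[planted, "2"] <- 3
  sets <- list(PL = planted, RND = sample(genes, 25))
  out <- suppressMessages(per_timepoint_enrichment(m, sets, fold = 2, q_cutoff = 0.01))
  expect_lt(out$q["PL", "2"], 0.01)
  expect_true(is.na(out$masked["PL", "1"]))
  expect_true(is.na(out$masked["PL", "3"]))
  # an unreachable fold threshold empties every query and masks everything
  out2 <- suppressMessages(
    per_timepoint_enrichment(m, sets, fold = 1e6, q_cutoff = 0.01))
  expect_true(all(is.na(out2$masked)))
  expect_true(all(out2$q == 1))
})

test_that("GMT, OBO and annotation files round-trip", {
  dag <- toy_dag()
  path_o <- withr::local_tempfile(fileext = ".obo")
  write_obo(dag, path_o)
  back <- read_obo(path_o)
  expect_setequal(back$terms, dag$terms)
  expect_equal(back$parents[dag$terms], dag$parents[dag$terms])
  expect_equal(back$depth[dag$terms], dag$depth[dag$terms])

  sets <- list(A = c("g1", "g2"), B = c("g3"))
  path_g <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path_g)
  expect_equal(read_gmt(path_g), sets)

  corpus <- toy_corpus()
  path_a <- withr::local_tempfile(fileext = ".tsv")
  write_annotations(corpus, path_a)
  back_c <- read_annotations(path_a, dag)
  expect_equal(lapply(back_c[names(corpus)], sort), lapply(corpus, sort))
})
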