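test_that("correlation filtering keeps exactly the pairs above the cutoff", {
  t_grid <- 0:4
  base <- c(0, 1, 2, 3, 4)
  m <- rbind(a = base, b = base + 0.01 * c(1, -1, 0, 1, -1), c = -base,
             d = c(0, 2, 1, 4, 2))
  colnames(m) <- t_grid
  net <- correlation_filter(m, rownames(m), r_cutoff = 0.8)
  expect_true(any(net$a == "a" & net$b == "b"))        # near-identical
  expect_false(any((net$a == "a" & net$b == "c") |
                     (net$a == "c" & net$b == "a")))   # r = -1 excluded
  # signed-vs-absolute reading
  net_abs <- correlation_filter(m, rownames(m), r_cutoff = 0.8, use_abs = TRUE)
  expect_true(any(net_abs$a == "a" & net_abs$b == "c"))
  # brute-force oracle on a random matrix
  set.seed(30)
  r <- matrix(rnorm(60 * 5), 60, 5,
              dimnames = list(sprintf("g%02d", 1:60), 0:4))
  got <- correlation_filter(r, rownames(r), r_cutoff = 0.3)
  want <- 0L
  for (i in 1:59) for (j in (i + 1):60)
    if (cor(r[i, ], r[j, ]) > 0.3) want <- want + 1L
  expect_equal(nrow(got), want)
  for (e in seq_len(nrow(got)))
    expect_gt(cor(r[got$a[e], ], r[got$b[e], ]), 0.3)
  # zero-variance genes are excluded
  rz <- rbind(r, zz = rep(1, 5))
  expect_message(correlation_filter(rz, rownames(rz), 0.3), "zero-variance")
})

test_that("database intersection keeps supported edges only", {
  net <- structure(data.frame(a = c("a", "a", "b", "c", "d"),
                              b = c("b", "c", "c", "d", "e"),
                              r = rep(0.9, 5)),
                   nodes = letters[1:5],
                   class = c("correlation_network", "data.frame"))
  all_db <- expand.grid(a = letters[1:5], b = letters[1:5],
                        stringsAsFactors = FALSE)
  expect_equal(nrow(intersect_with_db(net, all_db)), 5)
  expect_warning(out0 <- intersect_with_db(net, data.frame(a = "x", b = "y")),
                 "no network edge")
  expect_equal(nrow(out0), 0)
  db3 <- data.frame(a = c("b", "c", "e"), b = c("a", "a", "d"))  # unordered
  out3 <- intersect_with_db(net, db3)
  expect_equal(nrow(out3), 3)
  expect_setequal(attr(out3, "nodes"), c("a", "b", "c", "d", "e"))
})

test_that("MCL recovers connected components and clique structure", {
  tri2 <- data.frame(a = c("a1", "a2", "a3", "b1", "b2", "b3"),
                     b = c("a2", "a3", "a1", "b2", "b3", "b1"))
  part <- mcl(tri2)
  expect_equal(length(attr(part, "sizes")), 2)
  expect_equal(attr(part, "sizes"), c(3L, 3L))
  # two disjoint triangles match graph components exactly
  g <- igraph::graph_from_data_frame(tri2, directed = FALSE)
  comp <- igraph::components(g)$membership[names(part)]
  expect_equal(adjusted_rand_index(part, comp), 1)

  clique <- t(combn(sprintf("k%d", 1:6), 2))
  part_k <- mcl(data.frame(a = clique[, 1], b = clique[, 2]))
  expect_equal(length(attr(part_k, "sizes")), 1)

  # two 5-cliques joined by one weak edge split at default inflation
  c1 <- t(combn(sprintf("x%d", 1:5), 2)); c2 <- t(combn(sprintf("y%d", 1:5), 2))
  bridge <- rbind(c1, c2, c("x1", "y1"))
  part_b <- mcl(data.frame(a = bridge[, 1], b = bridge[, 2]), inflation = 2)
  expect_equal(length(attr(part_b, "sizes")), 2)
  truth <- c(rep(0, 5), rep(1, 5))
  names(truth) <- c(sprintf("x%d", 1:5), sprintf("y%d", 1:5))
  expect_equal(adjusted_rand_index(part_b[names(truth)], truth), 1)
})

test_that("MCL output is a valid partition invariant to node order", {
  set.seed(31)
  edges <- data.frame(a = sample(letters[1:12], 40, TRUE),
                      b = sample(letters[1:12], 40, TRUE))
  edges <- edges[edges$a != edges$b, ]
  part <- mcl(edges)
  expect_setequal(names(part), unique(c(edges$a, edges$b)))
  expect_false(anyNA(part))
  sizes <- attr(part, "sizes")
  expect_true(all(diff(sizes) <= 0))                   # non-increasing
  expect_equal(sort(unique(as.integer(part))), seq_along(sizes) - 1L)
  part_rev <- mcl(edges[rev(seq_len(nrow(edges))), ])
  expect_equal(as.vector(part_rev[names(part)]), as.vector(part[names(part)]))
  # disjoint components are never merged
  two <- data.frame(a = c("u1", "u2", "v1", "v2"), b = c("u2", "u3", "v2", "v3"))
  pt <- mcl(two)
  expect_equal(length(unique(pt[c("u1", "u2", "u3")])), 1)
  expect_equal(length(unique(pt[c("v1", "v2", "v3")])), 1)
  expect_false(pt[["u1"]] == pt[["v1"]])
})

test_that("module composition comparison counts and Jaccard-scores overlaps", {
  a <- structure(stats::setNames(c(0L, 0L, 0L, 1L, 1L, 1L),
                                 sprintf("g%d", 1:6)),
                 class = "module_partition")
  ident <- compare_module_composition(a, a)
  expect_equal(unname(diag(ident$jaccard)), c(1, 1))
  expect_equal(unname(ident$counts["0", "0"]), 3L)
  # one swapped gene: hand-computed Jaccard
  b <- a; b["g3"] <- 1L
  cmp <- compare_module_composition(a, b)
  expect_equal(unname(cmp$jaccard["0", "0"]), 2 / 3)     # {1,2} / {1,2,3}
  expect_equal(unname(cmp$jaccard["1", "1"]), 3 / 4)     # {4,5,6} / {3,4,5,6}
  expect_equal(unname(cmp$counts["0", "1"]), 1L)
  # disjoint universes give all zeros
  c_ <- structure(stats::setNames(c(0L, 0L), c("h1", "h2")),
                  class = "module_partition")
  expect_true(all(compare_module_composition(a, c_)$counts == 0))
})

test_that("adjusted Rand agrees with the mclust reference implementation", {
  skip_if_not_installed("mclust")
  set.seed(32)
  for (i in 1:10) {
    x <- sample(1:4, 50, TRUE); y <- sample(1:3, 50, TRUE)
    expect_equal(adjusted_rand_index(x, y), mclust::adjustedRandIndex(x, y))
  }
  expect_equal(adjusted_rand_index(1:10, 1:10), 1)
})

test_that("module annotation picks the planted term and flags empty modules", {
  genes <- sprintf("g%03d", 1:150)
  part <- structure(stats::setNames(c(rep(0L, 30), rep(1L, 30)), genes[1:60]),
                    class = "module_partition")
  sets <- list("GO:PL" = genes[1:30], "GO:RN" = genes[101:130])
  dag <- ontology_dag(c("root", "GO:PL", "GO:RN"),
                      parents = list(root = character(0), "GO:PL" = "root",
                                     "GO:RN" = "root"))
  corpus <- propagate_annotations(
    c(stats::setNames(lapply(genes[1:30], function(g) "GO:PL"), genes[1:30]),
      stats::setNames(lapply(genes[101:130], function(g) "GO:RN"), genes[101:130])),
    dag)
  for (g in genes) if (is.null(corpus[[g]])) corpus[[g]] <- "root"
  ic <- suppressMessages(information_content(corpus, dag))
  ann <- annotate_modules(part, genes, sets, ic, dag, q_cutoff = 0.01)
  expect_equal(ann$representative[ann$module == 0], "GO:PL")
  expect_equal(ann$representative[ann$module == 1], "unannotated")
})

test_that("interaction and partition files round-trip", {
  db <- data.frame(a = c("g1", "g2"), b = c("g2", "g3"))
  path <- withr::local_tempfile(fileext = ".sif")
  write_interactions(db, path)
  expect_equal(read_interactions(path), db)
  part <- structure(stats::setNames(c(0L, 0L, 1L), c("g1", "g2", "g3")),
                    sizes = c(2L, 1L), converged = TRUE,
                    class = "module_partition")
  pp <- withr::local_tempfile(fileext = ".tsv")
  write_partition(part, pp)
  back <- read_partition(pp)
  expect_equal(as.integer(back), as.integer(part))
  expect_identical(names(back), names(part))
})
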