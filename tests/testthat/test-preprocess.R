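test_that("probe filtering is strict, order-preserving and idempotent", {
  pt <- probe_table(
    c("p1", "p2", "p3"), c("g1", "g2", "g3"),
    signal = matrix(c(150, 140, 200), 3, 1, dimnames = list(NULL, "s1")),
    background = matrix(100, 3, 1, dimnames = list(NULL, "s1")))
  out <- suppressMessages(filter_probes(pt, k = 1.4))
  # 150 > 140 retained, 140 not strictly greater dropped, 200 retained
  expect_identical(out$probe_id, c("p1", "p3"))
  # ratios {1.5, 1.4, 2.0} leave exactly 2 probes
  expect_equal(length(out$probe_id), 2)
  again <- suppressMessages(filter_probes(out, k = 1.4))
  expect_identical(again$signal, out$signal)

  pt2 <- probe_table(
    c("a", "b", "c"), c("g1", "g2", "g3"),
    signal = matrix(c(150, 139, 200), 3, 1, dimnames = list(NULL, "s1")),
    background = matrix(100, 3, 1, dimnames = list(NULL, "s1")))
  out2 <- suppressMessages(filter_probes(pt2, k = 1.4))
  expect_identical(out2$probe_id, c("a", "c"))
})

test_that("probe filtering modes differ and bad background is rejected", {
  sig <- rbind(c(150, 150), c(150, 120))
  colnames(sig) <- c("s1", "s2")
  bg <- matrix(100, 2, 2, dimnames = list(NULL, c("s1", "s2")))
  pt <- probe_table(c("p1", "p2"), c("g1", "g2"), sig, bg)
  expect_identical(suppressMessages(filter_probes(pt, 1.4, "all_samples"))$probe_id, "p1")
  expect_identical(suppressMessages(filter_probes(pt, 1.4, "any_sample"))$probe_id,
                   c("p1", "p2"))
  bg[1, 1] <- 0
  pt_bad <- probe_table(c("p1", "p2"), c("g1", "g2"), sig, bg)
  expect_error(filter_probes(pt_bad), "background")
})

test_that("quantile normalization equalizes column value multisets", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  out <- quantile_normalize(m)
  expect_equal(unname(out[, "a"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out[, "b"]), c(2.5, 3.5, 4.5))

  same <- cbind(a = c(3, 1, 2), b = c(3, 1, 2))
  expect_equal(quantile_normalize(same), same)

  set.seed(4)
  r <- matrix(rexp(60), 20, 3)
  rn <- quantile_normalize(r)
  expect_equal(sort(rn[, 1]), sort(rn[, 2]))
  expect_equal(sort(rn[, 2]), sort(rn[, 3]))
  expect_warning(quantile_normalize(r[, 1, drop = FALSE]), "single sample")
})

test_that("duplicate averaging collapses probes by gene mean", {
  m <- matrix(c(10, 20, 5, 1, 2, 6), 6, 1,
              dimnames = list(c("p1", "p2", "p3", "q1", "q2", "q3"), "s1"))
  map <- c(p1 = "gA", p2 = "gA", p3 = "gB", q1 = "gC", q2 = "gC", q3 = "gC")
  out <- average_duplicates(m, map)
  expect_equal(out["gA", 1], 15)
  expect_equal(out["gB", 1], 5)   # single probe passes through
  expect_equal(out["gC", 1], 3)
  expect_error(average_duplicates(m, character(0)), "empty")
})

test_that("log ratios are base-2 against the control and scale-invariant", {
  design <- data.frame(
    sample_id = c("CTRL", "F0", "F1"), region = c("control", "focal", "focal"),
    time = c(0, 0, 1), dose = c(0, 90, 90))
  m <- rbind(gU = c(2, 2, 2), gE = c(2, 2, 8), gD = c(12, 12, 3))
  colnames(m) <- c("CTRL", "F0", "F1")
  tc <- compute_log_ratios(m, design)
  expect_equal(tc$focal["gE", "1"], 2)    # 8 / 2
  expect_equal(tc$focal["gU", "1"], 0)    # sample equals control
  expect_equal(tc$focal["gD", "1"], -2)   # 3 / 12
  # multiplying all intensities by a constant leaves ratios unchanged
  tc2 <- compute_log_ratios(7 * m, design)
  expect_equal(tc2$focal, tc$focal)
})

test_that("zero control intensities exclude the gene with a report", {
  design <- data.frame(sample_id = c("CTRL", "F1"),
                       region = c("control", "focal"),
                       time = c(0, 1), dose = c(0, 90))
  m <- matrix(c(0, 4, 2, 8), 2, 2,
              dimnames = list(c("bad", "ok"), c("CTRL", "F1")))
  expect_message(tc <- suppressWarnings(compute_log_ratios(m, design)),
                 "excluding 1 genes")
  expect_identical(rownames(tc$focal), "ok")
})

test_that("average-linkage correlation clustering behaves on known geometries", {
  r <- c(0, 1, 2, 3, 4)
  m <- rbind(a = r, b = r, c = -r + 1)
  hc <- hierarchical_cluster(m)
  expect_equal(hc$height[1], 0)                      # identical rows merge at 0
  expect_equal(max(hc$height), 2, tolerance = 1e-12) # r vs -r distance
  # two tight pairs merge first
  set.seed(1)
  m4 <- rbind(p1 = c(1, 2, 3, 4), p2 = c(1.1, 2, 3, 4.1),
              q1 = c(4, 1, 3, 2), q2 = c(4.1, 1, 3.1, 2))
  hc4 <- hierarchical_cluster(m4)
  first_two <- list(sort(hc4$merge[1, ]), sort(hc4$merge[2, ]))
  expect_setequal(lapply(first_two, function(x) sort(abs(as.numeric(x)))),
                  list(c(1, 2), c(3, 4)))
  expect_warning(hierarchical_cluster(rbind(a = c(1, 1, 1), b = c(1, 2, 3))),
                 "zero variance")
})

test_that("delta-delta-Ct fold change follows the closed form", {
  expect_equal(ddct_fold_change(25, 20, 26, 20), 2)
  expect_equal(ddct_fold_change(25, 20, 25, 20), 1)
  expect_equal(ddct_fold_change(27, 20, 25, 20), 0.25)
  # identity for any (a, b) repeated in test and control
  for (i in 1:10) {
    ab <- runif(2, 10, 35)
    expect_equal(ddct_fold_change(ab[1], ab[2], ab[1], ab[2]), 1)
  }
  expect_error(ddct_fold_change(Inf, 20, 25, 20), "finite")
})

test_that("probe tables round-trip through TSV", {
  pt <- toy_probe_table()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_probe_table(pt, path)
  back <- read_probe_table(path)
  expect_equal(back$signal, pt$signal)
  expect_equal(back$background, pt$background)
  expect_identical(back$gene_symbol, pt$gene_symbol)
})
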