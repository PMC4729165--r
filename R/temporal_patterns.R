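# Short time-series model-profile clustering: a library of integer template
# trajectories is enumerated, genes are assigned to the best-correlated
# template, and template significance is scored against a permutation null
# of each gene's time-point order.

ref_column <- function(m, ref_time = 0) {
  hit <- which(as.numeric(colnames(m)) == ref_time)
  if (length(hit) != 1) stop("reference time point not found in time grid")
  hit
}

#' Select temporally responsive genes
#'
#' Genes whose log2 ratio moves by at least `log2(fold)` away from the
#' reference time point at one or more later times.
#'
#' @param tc Gene x time matrix of log2 ratios, columns named by time.
#' @param fold Linear fold-change threshold (> 1); default 2.
#' @param ref_time Reference time (default 0).
#' @return Character vector of selected gene ids (input order).
#' @export
select_variable_genes <- function(tc, fold = 2, ref_time = 0) {
  stopifnot(fold > 1)
  tc <- as.matrix(tc)
  if (ncol(tc) < 2) stop("time grid must contain the reference and at least one later point")
  r <- ref_column(tc, ref_time)
  dev <- abs(tc[, -r, drop = FALSE] - tc[, r])
  rownames(tc)[apply(dev, 1, max) >= log2(fold)]
}

#' Enumerate and select model expression profiles
#'
#' Candidate profiles are all integer trajectories of length `n_time`
#' starting at 0 with successive steps bounded by `c` in absolute value
#' (`(2c+1)^(n_time-1)` candidates). A library of `m` profiles is chosen by
#' greedy maximin 1 - Pearson distance, seeded deterministically at the
#' steepest rising profile; ties resolve to the earliest candidate in
#' enumeration order, so the result is fully deterministic.
#'
#' @param n_time Number of time points (>= 2).
#' @param c Maximum unit change between consecutive points (>= 1).
#' @param m Library size; 50 mirrors the reference tool's default.
#' @return A `profile_library`: list with `profiles` (m x n_time integer
#'   matrix, rows are profile ids), `c` and `m`.
#' @export
generate_model_profiles <- function(n_time, c = 2, m = 50) {
  stopifnot(n_time >= 2, c >= 1)
  steps <- lapply(seq_len(n_time - 1), function(i) seq(-c, c))
  grid <- as.matrix(expand.grid(steps))
  cs <- grid
  if (ncol(grid) > 1)
    for (j in 2:ncol(grid)) cs[, j] <- cs[, j - 1] + grid[, j]
  cand <- cbind(0L, cs)
  storage.mode(cand) <- "integer"
  colnames(cand) <- NULL
  n_cand <- nrow(cand)
  if (m >= n_cand) {
    if (m > n_cand)
      warning(sprintf("requested %d profiles but only %d candidates exist", m, n_cand))
    lib <- cand
  } else {
    d <- 1 - suppressWarnings(stats::cor(t(cand)))
    d[!is.finite(d)] <- 1  # the flat candidate has undefined correlation
    extreme <- (seq_len(n_time) - 1) * c
    start <- which(rowSums(abs(sweep(cand, 2, extreme))) == 0)[1]
    chosen <- start
    mind <- d[, start]
    while (length(chosen) < m) {
      mind[chosen] <- -Inf
      nxt <- which.max(round(mind, 10))  # earliest index wins ties
      chosen <- base::c(chosen, nxt)    # `c` is shadowed by the unit-change arg
      mind <- pmin(mind, d[, nxt])
    }
    lib <- cand[chosen, , drop = FALSE]
  }
  structure(list(profiles = lib, c = c, m = nrow(lib)),
            class = "profile_library")
}

#' @export
print.profile_library <- function(x, ...) {
  cat(sprintf("profile_library: %d profiles of length %d (unit change <= %d)\n",
              x$m, ncol(x$profiles), x$c))
  invisible(x)
}

# Row-standardize for Pearson correlation; zero-variance rows become NA.
.standardize_rows <- function(m) {
  mu <- rowMeans(m)
  ctr <- m - mu
  sd <- sqrt(rowSums(ctr^2))
  sd[sd == 0] <- NA_real_
  ctr / sd
}

# Fast best-profile assignment for a gene x time matrix; returns integer
# profile index (NA for zero-variance genes) and achieved correlation.
.assign_matrix <- function(tc, zp) {
  zg <- .standardize_rows(tc)
  cc <- zg %*% t(zp)            # Pearson correlation gene x profile
  cc_r <- round(cc, 10)         # guard float noise in the tie-break
  cc_r[is.na(cc_r)] <- -Inf
  idx <- max.col(cc_r, ties.method = "first")
  zero_var <- is.na(zg[, 1])
  idx[zero_var] <- NA_integer_
  corr <- cc[cbind(seq_len(nrow(cc)), ifelse(is.na(idx), 1L, idx))]
  corr[zero_var] <- NA_real_
  list(profile = idx, correlation = corr)
}

#' Assign genes to model profiles
#'
#' Each gene goes to the profile with the highest Pearson correlation to
#' its trajectory (invariant to positive affine transformations of the
#' trajectory); ties break to the lowest profile id. Genes with
#' zero-variance trajectories are left unassigned, as is anything matching
#' only the flat profile.
#'
#' @param tc Gene x time matrix of log2 ratios.
#' @param genes Genes to assign (subset of rownames).
#' @param lib A [generate_model_profiles()] library on the same time grid.
#' @return A `pattern_assignment`: data.frame `gene, profile, correlation`
#'   plus attributes `unassigned`, `lib`, and the input matrix rows.
#' @export
assign_genes <- function(tc, genes, lib) {
  tc <- as.matrix(tc)[genes, , drop = FALSE]
  if (ncol(tc) != ncol(lib$profiles))
    stop("gene trajectories and model profiles must share the time grid")
  zp <- .standardize_rows(lib$profiles)
  a <- .assign_matrix(tc, zp)
  ok <- !is.na(a$profile)
  structure(
    data.frame(gene = genes[ok], profile = a$profile[ok],
               correlation = a$correlation[ok], stringsAsFactors = FALSE),
    unassigned = genes[!ok], lib = lib, tc = tc,
    class = c("pattern_assignment", "data.frame"))
}

# All permutations of 1..n (n small) in a deterministic order.
.perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- setdiff(seq_len(n), k)
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

#' Permutation significance of model profiles
#'
#' For each profile the observed assigned gene count is compared against
#' re-assignments after permuting every gene's time-point order (reference
#' fixed). Reports the permutation-expected count `s`, an analytic
#' hypergeometric tail p (population N genes, `round(s)` successes, `n`
#' draws), a per-profile empirical permutation p (`p_perm`, conservative,
#' floored at `1/n_perm`) with its mid-p variant (`p_mid`, half weight on
#' permutations tying the observed integer count -- the calibrated
#' diagnostic for the discrete null), and a plug-in empirical FDR `q`
#' (mean permuted count of profiles at or above each observed-count
#' threshold over the observed count at that threshold).
#'
#' @param assignment A [assign_genes()] result.
#' @param n_perm Number of permutations (>= 1); default 1000.
#' @param seed RNG seed (recorded in the result's metadata).
#' @param ref_time Reference time held fixed under permutation.
#' @return data.frame `profile, n, s, p_hyper, p_perm, q` with attributes
#'   `n_perm` and `seed`.
#' @export
profile_significance <- function(assignment, n_perm = 1000, seed = NULL,
                                 ref_time = 0) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  lib <- attr(assignment, "lib")
  tc <- attr(assignment, "tc")
  n_prof <- lib$m
  n_genes <- nrow(tc)
  obs <- tabulate(assignment$profile, nbins = n_prof)
  zp <- .standardize_rows(lib$profiles)
  r <- ref_column(tc, ref_time)
  free <- setdiff(seq_len(ncol(tc)), r)
  k <- length(free)
  perm_pool <- if (k <= 6) .perms(k) else NULL

  s_acc <- numeric(n_prof)
  exceed <- numeric(n_prof)      # perms with count_j >= obs_j
  equal <- numeric(n_prof)       # perms with count_j == obs_j (for mid-p)
  v_acc <- numeric(n_prof)       # false discoveries at threshold obs_j
  obs_sorted_thr <- obs
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      pm <- matrix(NA_real_, n_genes, ncol(tc))
      pm[, r] <- tc[, r]
      if (is.null(perm_pool)) {
        ord <- apply(matrix(stats::runif(n_genes * k), n_genes), 1, order)
        idx <- t(ord)
      } else {
        idx <- perm_pool[sample.int(nrow(perm_pool), n_genes, replace = TRUE), ,
                         drop = FALSE]
      }
      gather <- matrix(free[idx], n_genes)
      pm[, free] <- tc[cbind(rep(seq_len(n_genes), k), as.vector(gather))]
      cnt <- tabulate(.assign_matrix(pm, zp)$profile, nbins = n_prof)
      s_acc <- s_acc + cnt
      exceed <- exceed + (cnt >= obs)
      equal <- equal + (cnt == obs)
      # profiles whose permuted count reaches each observed-count threshold
      v_acc <- v_acc + vapply(obs_sorted_thr, function(t) sum(cnt >= t),
                              numeric(1))
    }
  })
  s <- s_acc / n_perm
  p_perm <- pmax(exceed, 1) / n_perm
  # Lancaster mid-p: half weight on ties with the observed integer count;
  # the calibrated diagnostic for the discrete count null (p_perm stays
  # the conservative inferential value)
  p_mid <- pmin(1, pmax((exceed - 0.5 * equal) / n_perm, 0.5 / n_perm))
  r_at <- vapply(obs, function(t) sum(obs >= t), numeric(1))
  q <- pmin(1, (v_acc / n_perm) / pmax(1, r_at))
  p_hyper <- stats::phyper(obs - 1, round(s), n_genes - round(s), obs,
                           lower.tail = FALSE)
  p_hyper[obs == 0] <- 1
  structure(
    data.frame(profile = seq_len(n_prof), n = obs, s = s,
               p_hyper = p_hyper, p_perm = p_perm, p_mid = p_mid, q = q),
    n_perm = n_perm, seed = if (is.null(seed)) NA_integer_ else seed,
    class = c("profile_significance", "data.frame"))
}

#' Group assigned genes into labeled patterns
#'
#' The headline patterns (e.g. "down at mid-course", "monotone up", "early
#' spike") are explicit user-labeled groups of profile ids; this maps an
#' assignment through such a grouping to named gene lists.
#'
#' @param assignment A [assign_genes()] result.
#' @param groups Named list, pattern label -> integer vector of profile ids.
#' @return Named list of character gene vectors.
#' @export
pattern_gene_lists <- function(assignment, groups) {
  lapply(groups, function(ids)
    assignment$gene[assignment$profile %in% ids])
}

#' Map library profiles onto template trajectories
#'
#' Convenience grouping: each profile is labeled with the template it
#' correlates with best, provided the correlation reaches `min_cor`;
#' remaining profiles stay ungrouped.
#'
#' @param lib A [generate_model_profiles()] library.
#' @param templates Named list of numeric template trajectories on the
#'   same grid.
#' @param min_cor Minimum Pearson correlation to accept a label.
#' @return Named list, template label -> integer profile ids, suitable for
#'   [pattern_gene_lists()].
#' @export
profile_groups_by_template <- function(lib, templates, min_cor = 0.5) {
  zt <- .standardize_rows(do.call(rbind, templates))
  a <- .assign_matrix(lib$profiles, zt)
  lab <- names(templates)[a$profile]
  lab[is.na(a$profile) | a$correlation < min_cor] <- NA
  out <- lapply(names(templates), function(l) which(!is.na(lab) & lab == l))
  names(out) <- names(templates)
  out
}

#' Cross-tabulate pattern memberships between two regions
#'
#' For every pair of pattern groups reports the intersection size and the
#' percentage of the first region's pattern that recurs in the second.
#'
#' @param a,b Named lists of gene vectors (label -> genes), e.g. from
#'   [pattern_gene_lists()].
#' @return data.frame `pattern_a, pattern_b, n_a, n_b, common, pct_of_a`.
#' @export
compare_patterns <- function(a, b) {
  out <- expand.grid(pattern_a = names(a), pattern_b = names(b),
                     stringsAsFactors = FALSE)
  out$n_a <- lengths(a)[out$pattern_a]
  out$n_b <- lengths(b)[out$pattern_b]
  out$common <- mapply(function(x, y) length(intersect(a[[x]], b[[y]])),
                       out$pattern_a, out$pattern_b)
  out$pct_of_a <- ifelse(out$n_a > 0, 100 * out$common / out$n_a, 0)
  rownames(out) <- NULL
  out
}
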