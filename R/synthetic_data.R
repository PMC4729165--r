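# Synthetic study generator: time-course expression with planted temporal
# patterns, gene-set catalogs with planted enrichment, signed pathway
# topologies with a planted perturbation, and an interaction network with
# planted modules -- the ground truth every pipeline stage is scored
# against.

#' Configuration for the synthetic study
#'
#' Defaults emulate the focal-irradiation design at a reduced gene count:
#' one pooled array per condition, a focally irradiated and a neighboring
#' 90 Gy region sampled weekly over weeks 0-4, a 20 Gy whole-lung series
#' over months, and a single non-irradiated control. Pattern fractions
#' mirror the observed proportions of down-regulated (P1), gradually
#' up-regulated (P2) and initially up-regulated (P3) genes.
#'
#' @param n_genes Number of genes (default 2000; ~21600 at full study scale).
#' @param times_focal Week grid for the two 90 Gy regions.
#' @param times_whole Month grid for the 20 Gy whole-lung series.
#' @param frac_p1,frac_p2,frac_p3 Pattern fractions (sum <= 1).
#' @param effect Planted effect size a in log2 units (default 2).
#' @param rho Neighbor-region damping of the focal templates in `[0, 1]`.
#' @param sigma i.i.d. Gaussian noise SD on the log2 scale.
#' @param baseline_mean,baseline_sd Baseline log2 intensity distribution.
#' @param background_level Linear local-background level of the array.
#' @param low_frac Fraction of additional near-background genes emitted to
#'   exercise probe filtering.
#' @param module_shape_sd SD of the per-module trajectory bump (truncated
#'   at +-0.5) that differentiates modules within a pattern.
#' @param n_gene_sets,set_size Catalog size and set-size range.
#' @param n_planted_per_pattern,planted_purity Planted sets per pattern and
#'   the fraction of each drawn from the pattern's genes.
#' @param n_pathways,pathway_size,n_perturbed Topology catalog shape.
#' @param extra_edge_prob Probability of extra feed-forward edges beyond
#'   the backbone chain.
#' @param inhibition_frac Fraction of inhibitory edges in null pathways.
#' @param n_modules,p_in,p_out Stochastic-block-model module structure over
#'   the pattern genes (requires `p_in > p_out`).
#' @param n20_down,n20_up,p20_overlap 20 Gy down/up group sizes and the
#'   fraction of each drawn from P1/P2 genes.
#' @param seed Mandatory RNG seed.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 2000,
                             times_focal = 0:4,
                             times_whole = base::c(0, 1, 3, 6, 9, 12),
                             frac_p1 = 0.21, frac_p2 = 0.03, frac_p3 = 0.01,
                             effect = 2, rho = 0.7, sigma = 0.2,
                             baseline_mean = 9, baseline_sd = 1.5,
                             background_level = 1, low_frac = 0.05,
                             module_shape_sd = 0.3,
                             n_gene_sets = 60, set_size = base::c(20, 60),
                             n_planted_per_pattern = 2, planted_purity = 0.8,
                             n_pathways = 20, pathway_size = 50,
                             n_perturbed = 1, extra_edge_prob = 0.15,
                             inhibition_frac = 0.2,
                             n_modules = 8, p_in = 0.25, p_out = 0.01,
                             n20_down = 150, n20_up = 100, p20_overlap = 0.55,
                             seed) {
  if (missing(seed)) stop("a seed is mandatory in the synthetic config")
  if (frac_p1 + frac_p2 + frac_p3 > 1) stop("pattern fractions must sum to <= 1")
  if (sigma < 0) stop("sigma must be >= 0")
  if (rho < 0 || rho > 1) stop("rho must be in [0, 1]")
  if (p_in <= p_out) stop("module structure requires p_in > p_out")
  cfg <- as.list(environment())
  structure(cfg, class = "synthetic_config")
}

.pattern_templates <- function(times, a) {
  T_ <- length(times)
  p1 <- rep(0, T_); p1[seq(max(2, T_ - 2), max(2, T_ - 1))] <- -a
  p2 <- seq(0, a, length.out = T_)
  p3 <- rep(0, T_); p3[2] <- a; if (T_ >= 3) p3[3] <- a / 2
  list(P1 = p1, P2 = p2, P3 = p3)
}

.whole_templates <- function(times, a) {
  T_ <- length(times)
  down <- base::c(0, 0, -a / 2, -a, -a, -a / 2)[seq_len(T_)]
  up <- base::c(0, 0, a / 2, a, a, a)[seq_len(T_)]
  down[is.na(down)] <- 0; up[is.na(up)] <- 0
  list(down = down, up = up)
}

#' Simulate the time-course study
#'
#' Emits a duplicated-probe table with a background channel (so the whole
#' preprocessing path is exercised), the sample design, and the ground
#' truth: each gene's planted pattern, its module (within-pattern module
#' bumps make same-module trajectories coherent), and the 20 Gy down/up
#' groups. Pure function of the config (same seed, identical output).
#'
#' @param cfg A [synthetic_config()].
#' @return List with `probes` ([probe_table()]), `design` (data.frame) and
#'   `truth` (list).
#' @export
simulate_timecourse <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_genes
    genes <- sprintf("g%05d", seq_len(n))
    n1 <- round(cfg$frac_p1 * n); n2 <- round(cfg$frac_p2 * n)
    n3 <- round(cfg$frac_p3 * n)
    pattern <- stats::setNames(rep("null", n), genes)
    pattern[seq_len(n1)] <- "P1"
    pattern[n1 + seq_len(n2)] <- "P2"
    pattern[n1 + n2 + seq_len(n3)] <- "P3"

    tf <- cfg$times_focal
    tmpl <- .pattern_templates(tf, cfg$effect)
    wt <- .whole_templates(cfg$times_whole, cfg$effect)

    # modules: allocated to patterns proportionally (each non-empty pattern
    # gets at least one); contiguous chunks of the pattern's genes
    counts <- base::c(P1 = n1, P2 = n2, P3 = n3)
    counts <- counts[counts > 0]
    modules <- stats::setNames(integer(0), character(0))
    mod_pattern <- character(0)
    m_next <- 0L
    if (length(counts) > 0) {
      alloc <- stats::setNames(pmax(1, round(cfg$n_modules * counts / sum(counts))),
                               names(counts))
      while (sum(alloc) > cfg$n_modules) alloc[which.max(alloc)] <- alloc[which.max(alloc)] - 1
      while (sum(alloc) < cfg$n_modules) alloc[which.max(counts / alloc)] <- alloc[which.max(counts / alloc)] + 1
      for (p in names(alloc)) {
        gs <- genes[pattern == p]
        sp <- sort(rep_len(seq_len(alloc[[p]]), length(gs)))
        modules <- base::c(modules, stats::setNames(m_next + sp - 1L, gs))
        mod_pattern <- base::c(mod_pattern, rep(p, alloc[[p]]))
        m_next <- m_next + alloc[[p]]
      }
    }
    n_mod <- max(m_next, 1L)
    bump <- matrix(pmin(pmax(stats::rnorm(n_mod * length(tf), 0,
                                          cfg$module_shape_sd), -0.5), 0.5),
                   n_mod, length(tf))
    bump[, 1] <- 0  # reference time stays at the template's zero

    eff_focal <- matrix(0, n, length(tf), dimnames = list(genes, tf))
    for (p in base::c("P1", "P2", "P3")) {
      gs <- genes[pattern == p]
      if (length(gs) == 0) next
      eff_focal[gs, ] <- matrix(tmpl[[p]], length(gs), length(tf), byrow = TRUE) +
        bump[modules[gs] + 1L, , drop = FALSE]
    }
    eff_neighbor <- cfg$rho * eff_focal

    # 20 Gy groups partially overlap the 90 Gy patterns
    nulls <- genes[pattern == "null"]
    pick <- function(target, from_pat, pool_null) {
      k_pat <- min(length(from_pat), round(cfg$p20_overlap * target))
      base::c(sample(from_pat, k_pat),
              sample(pool_null, target - k_pat))
    }
    g20_down <- pick(cfg$n20_down, genes[pattern == "P1"], nulls)
    g20_up <- pick(cfg$n20_up, genes[pattern == "P2"],
                   setdiff(nulls, g20_down))
    eff_whole <- matrix(0, n, length(cfg$times_whole),
                        dimnames = list(genes, cfg$times_whole))
    eff_whole[g20_down, ] <- matrix(wt$down, length(g20_down),
                                    length(cfg$times_whole), byrow = TRUE)
    eff_whole[g20_up, ] <- matrix(wt$up, length(g20_up),
                                  length(cfg$times_whole), byrow = TRUE)

    baseline <- stats::rnorm(n, cfg$baseline_mean, cfg$baseline_sd)
    design <- rbind(
      data.frame(sample_id = "CTRL", region = "control", time = 0, dose = 0),
      data.frame(sample_id = sprintf("FI_w%d", tf), region = "focal_90Gy",
                 time = tf, dose = 90),
      data.frame(sample_id = sprintf("NB_w%d", tf), region = "neighbor_90Gy",
                 time = tf, dose = 0),
      data.frame(sample_id = sprintf("WL_m%d", cfg$times_whole),
                 region = "whole_20Gy", time = cfg$times_whole, dose = 20))
    eff <- cbind(CTRL = 0, eff_focal, eff_neighbor, eff_whole)
    colnames(eff) <- design$sample_id
    log2expr <- baseline + eff +
      matrix(stats::rnorm(n * nrow(design), 0, cfg$sigma), n)
    dimnames(log2expr) <- list(genes, design$sample_id)

    # duplicated probes (independent spot-level jitter scales with sigma)
    probe_sd <- cfg$sigma / 4
    all_log2 <- rbind(log2expr, log2expr) +
      matrix(stats::rnorm(2 * n * nrow(design), 0, probe_sd), 2 * n)
    probe_id <- base::c(sprintf("%s_A", genes), sprintf("%s_B", genes))
    gene_of <- base::c(genes, genes)
    signal <- 2^all_log2
    # near-background genes that must be removed by the probe filter
    n_low <- round(cfg$low_frac * n)
    if (n_low > 0) {
      low_genes <- sprintf("low%05d", seq_len(n_low))
      low_sig <- cfg$background_level *
        matrix(stats::runif(2 * n_low * nrow(design), 0.7, 1.3), 2 * n_low)
      probe_id <- base::c(probe_id, sprintf("%s_A", low_genes),
                          sprintf("%s_B", low_genes))
      gene_of <- base::c(gene_of, low_genes, low_genes)
      signal <- rbind(signal, low_sig)
    }
    background <- cfg$background_level *
      2^matrix(stats::rnorm(length(probe_id) * nrow(design), 0, 0.05),
               length(probe_id))
    colnames(signal) <- colnames(background) <- design$sample_id
    probes <- probe_table(probe_id, gene_of, signal, background)

    truth <- list(pattern = pattern, modules = modules,
                  module_pattern = mod_pattern,
                  templates = tmpl, whole_templates = wt, bump = bump,
                  genes20_down = g20_down, genes20_up = g20_up)
    list(probes = probes, design = design, truth = truth)
  })
}

#' Simulate a gene-set catalog with planted enrichment
#'
#' For each non-empty pattern, `n_planted_per_pattern` sets are drawn
#' mostly (`planted_purity`) from that pattern's genes; the rest of the
#' catalog is uniform random. A small 3-level is_a DAG (root, intermediate
#' terms, one leaf per set) and a propagated annotation corpus enable
#' information-content computation.
#'
#' @param truth Ground truth from [simulate_timecourse()].
#' @param cfg The same [synthetic_config()].
#' @return List with `sets`, `dag` ([ontology_dag()]), `corpus`
#'   (propagated) and `planted` (pattern -> planted set ids).
#' @export
simulate_genesets <- function(truth, cfg) {
  with_seed(child_seed(cfg$seed, 2L), {
    genes <- names(truth$pattern)
    sets <- list(); planted <- list()
    idx <- 0
    for (p in base::c("P1", "P2", "P3")) {
      gs <- genes[truth$pattern == p]
      if (length(gs) == 0) {
        message("simulate_genesets: pattern ", p, " empty, no planted set")
        next
      }
      for (r in seq_len(cfg$n_planted_per_pattern)) {
        idx <- idx + 1
        size <- min(cfg$set_size[2],
                    max(5, min(mean(cfg$set_size), floor(length(gs) * 0.9))))
        if (size > length(genes)) stop("set size exceeds gene universe")
        k_pat <- min(length(gs), round(cfg$planted_purity * size))
        id <- sprintf("GO:S%03d", idx)
        sets[[id]] <- base::c(sample(gs, k_pat),
                              sample(setdiff(genes, gs), size - k_pat))
        planted[[p]] <- base::c(planted[[p]], id)
      }
    }
    while (idx < cfg$n_gene_sets) {
      idx <- idx + 1
      size <- sample(seq(cfg$set_size[1], cfg$set_size[2]), 1)
      sets[[sprintf("GO:S%03d", idx)]] <- sample(genes, size)
    }
    n_mid <- 5
    mids <- sprintf("GO:M%02d", seq_len(n_mid))
    parents <- stats::setNames(
      lapply(seq_along(sets), function(i) mids[(i - 1) %% n_mid + 1]),
      names(sets))
    for (m in mids) parents[[m]] <- "GO:ROOT"
    parents[["GO:ROOT"]] <- character(0)
    terms <- base::c("GO:ROOT", mids, names(sets))
    dag <- ontology_dag(terms, stats::setNames(terms, terms), parents)
    member_of <- split(rep(names(sets), lengths(sets)),
                       unlist(sets, use.names = FALSE))
    corpus <- propagate_annotations(member_of, dag)
    # annotate remaining genes to the root so the corpus covers the universe
    for (g in setdiff(genes, names(corpus))) corpus[[g]] <- "GO:ROOT"
    list(sets = sets, dag = dag, corpus = corpus, planted = planted)
  })
}

#' Simulate signed pathway topologies with a planted perturbation
#'
#' Perturbed pathways place up-regulated pattern genes at the upstream end
#' of a coherent activation cascade (backbone chain plus extra
#' feed-forward activation edges), so the expected net accumulation is
#' positive. Null pathways are wired identically over null genes with the
#' configured inhibition fraction. All edges point forward along the
#' member order, so the propagation system is never singular.
#'
#' @inheritParams simulate_genesets
#' @return List with `topologies` (named list of [pathway_topology()]),
#'   `weights` (derived [weighted_pathway()] list) and `perturbed`
#'   (data.frame `pathway, direction`).
#' @export
simulate_topologies <- function(truth, cfg) {
  if (cfg$n_perturbed < 1) stop("at least one perturbed pathway is required")
  with_seed(child_seed(cfg$seed, 3L), {
    genes <- names(truth$pattern)
    up <- genes[truth$pattern %in% base::c("P2", "P3")]
    nulls <- genes[truth$pattern == "null"]
    mk_edges <- function(members, signs) {
      n <- length(members)
      src <- members[seq_len(n - 1)]; dst <- members[-1]
      extra <- which(matrix(stats::runif(n * n), n) < cfg$extra_edge_prob &
                       upper.tri(matrix(0, n, n), diag = FALSE) &
                       row(matrix(0, n, n)) < col(matrix(0, n, n)) - 1,
                     arr.ind = TRUE)
      src <- base::c(src, members[extra[, 1]])
      dst <- base::c(dst, members[extra[, 2]])
      type <- if (signs == "activation") rep("activation", length(src))
              else ifelse(stats::runif(length(src)) < cfg$inhibition_frac,
                          "inhibition", "activation")
      data.frame(src = src, dst = dst, type = type, stringsAsFactors = FALSE)
    }
    tops <- list()
    perturbed <- character(0)
    for (i in seq_len(cfg$n_pathways)) {
      id <- sprintf("PW%03d", i)
      if (i <= cfg$n_perturbed) {
        n_up <- min(15, length(up))
        members <- base::c(sample(up, n_up),
                           sample(nulls, cfg$pathway_size - n_up))
        tops[[id]] <- pathway_topology(id, members, mk_edges(members, "activation"))
        perturbed <- base::c(perturbed, id)
      } else {
        members <- sample(nulls, cfg$pathway_size)
        tops[[id]] <- pathway_topology(id, members, mk_edges(members, "mixed"))
      }
    }
    list(topologies = tops, weights = weights_from_topologies(tops),
         perturbed = data.frame(pathway = perturbed, direction = "activated",
                                stringsAsFactors = FALSE))
  })
}

#' Simulate the functional interaction database
#'
#' A stochastic block model over the pattern (differentially expressed)
#' genes: same-module pairs connect with probability `p_in`, cross-module
#' pairs with `p_out`.
#'
#' @inheritParams simulate_genesets
#' @return data.frame of canonical gene pairs (`a`, `b`).
#' @export
simulate_interactions <- function(truth, cfg) {
  if (cfg$p_in <= cfg$p_out) stop("p_in must exceed p_out")
  with_seed(child_seed(cfg$seed, 4L), {
    genes <- names(truth$modules)
    mod <- truth$modules
    n <- length(genes)
    ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    same <- mod[ut[, 1]] == mod[ut[, 2]]
    keep <- stats::runif(nrow(ut)) < ifelse(same, cfg$p_in, cfg$p_out)
    canonical_pairs(genes[ut[keep, 1]], genes[ut[keep, 2]])
  })
}

#' Write / read ground truth as JSON
#'
#' @param truth Ground-truth list from [simulate_timecourse()] (optionally
#'   augmented with planted set / pathway info).
#' @param path File path.
#' @export
write_ground_truth <- function(truth, path) {
  # named atomic vectors must serialize as JSON objects, not bare arrays
  for (f in intersect(base::c("pattern", "modules"), names(truth)))
    truth[[f]] <- as.list(truth[[f]])
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$pattern <- unlist(x$pattern)
  x$modules <- unlist(x$modules)
  x
}

#' Reference log-ratio time course of a simulated study
#'
#' Builds the `time_course` from the emitted probe table by probe
#' filtering, duplicate averaging and ratio formation against the control.
#' Quantile normalization is deliberately not applied here: the generator
#' draws every array on a common intensity scale (no technical
#' between-array bias), and forcing identical value distributions onto
#' columns that genuinely differ (a fifth of the genome shifts down at
#' mid-course) would saturate the planted effects of extreme-baseline
#' genes. The normalization operator is exercised by its own tests.
#'
#' @param sim Output of [simulate_timecourse()].
#' @param k,mode Probe-filter parameters.
#' @return A `time_course`.
#' @export
synthetic_timecourse <- function(sim, k = 1.4, mode = "all_samples") {
  kept <- filter_probes(sim$probes, k = k, mode = mode)
  gene_mat <- average_duplicates(kept$signal,
                                 stats::setNames(kept$gene_symbol, kept$probe_id))
  compute_log_ratios(gene_mat, sim$design)
}

#' Run the preprocessing pipeline on a probe table
#'
#' Filter against background, quantile-normalize, average duplicated
#' probes, and form log2 ratios versus the control -- in that order.
#'
#' @param probes A [probe_table()].
#' @param design A validated sample design.
#' @param k,mode Probe-filter parameters (see [filter_probes()]).
#' @return A `time_course` (see [compute_log_ratios()]).
#' @export
preprocess_probes <- function(probes, design, k = 1.4, mode = "all_samples") {
  kept <- filter_probes(probes, k = k, mode = mode)
  norm <- quantile_normalize(kept$signal)
  gene_mat <- average_duplicates(norm,
                                 stats::setNames(kept$gene_symbol, kept$probe_id))
  compute_log_ratios(gene_mat, design)
}
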