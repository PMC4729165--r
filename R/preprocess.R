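#' Probe-level intensity table
#'
#' Container for raw two-channel-free array data: per-probe signal and local
#' background intensities over a common set of samples. Probes map to gene
#' symbols (possibly many probes per gene; duplicated spots are averaged
#' later by [average_duplicates()]).
#'
#' @param probe_id Character vector of unique probe identifiers.
#' @param gene_symbol Character vector, one symbol per probe (`NA` allowed
#'   for unmapped probes).
#' @param signal,background Numeric matrices (probes x samples) of
#'   non-negative intensities with identical dimnames.
#' @return An object of class `probe_table`.
#' @export
probe_table <- function(probe_id, gene_symbol, signal, background) {
  probe_id <- as.character(probe_id)
  if (anyDuplicated(probe_id))
    stop("probe_id values must be unique")
  signal <- as.matrix(signal)
  background <- as.matrix(background)
  if (!identical(dim(signal), dim(background)))
    stop("signal and background must have identical dimensions")
  if (!identical(colnames(signal), colnames(background)))
    stop("signal and background must cover the same samples in the same order")
  if (any(!is.finite(signal)) || any(!is.finite(background)))
    stop("intensities must be finite")
  if (any(signal < 0) || any(background < 0))
    stop("intensities must be non-negative")
  rownames(signal) <- rownames(background) <- probe_id
  structure(
    list(probe_id = probe_id,
         gene_symbol = as.character(gene_symbol),
         signal = signal,
         background = background),
    class = "probe_table")
}

#' @export
print.probe_table <- function(x, ...) {
  cat(sprintf("probe_table: %d probes (%d genes) x %d samples\n",
              length(x$probe_id),
              length(unique(stats::na.omit(x$gene_symbol))),
              ncol(x$signal)))
  invisible(x)
}

#' Read a probe table from TSV
#'
#' Expects a header `probe_id  gene_symbol  <sample>:signal
#' <sample>:background` with one row per probe.
#'
#' @param path Path to a tab-separated file.
#' @return A [probe_table()].
#' @export
read_probe_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("probe_id", "gene_symbol") %in% names(df)))
    stop("probe table must have probe_id and gene_symbol columns")
  sig_cols <- grep(":signal$", names(df), value = TRUE)
  bg_cols <- grep(":background$", names(df), value = TRUE)
  samples <- sub(":signal$", "", sig_cols)
  if (!setequal(samples, sub(":background$", "", bg_cols)))
    stop("every sample needs both a :signal and a :background column")
  sig <- as.matrix(df[sig_cols])
  bg <- as.matrix(df[paste0(samples, ":background")])
  colnames(sig) <- colnames(bg) <- samples
  probe_table(df$probe_id, df$gene_symbol, sig, bg)
}

#' Write a probe table to TSV
#'
#' @param pt A [probe_table()].
#' @param path Output path.
#' @export
write_probe_table <- function(pt, path) {
  df <- data.frame(probe_id = pt$probe_id, gene_symbol = pt$gene_symbol,
                   check.names = FALSE, stringsAsFactors = FALSE)
  for (s in colnames(pt$signal)) {
    df[[paste0(s, ":signal")]] <- pt$signal[, s]
    df[[paste0(s, ":background")]] <- pt$background[, s]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample design table
#'
#' CSV with columns `sample_id,region,time,dose`. Time is in weeks for the
#' 90 Gy regions and months for the 20 Gy series; each comparison group has
#' exactly one control sample.
#'
#' @param path Path to a CSV file.
#' @return A data.frame with validated columns.
#' @export
read_sample_design <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_sample_design(df)
}

#' @rdname read_sample_design
#' @param design A data.frame with columns sample_id, region, time, dose.
#' @export
validate_sample_design <- function(design) {
  need <- c("sample_id", "region", "time", "dose")
  if (!all(need %in% names(design)))
    stop("design needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(design$sample_id))
    stop("sample_id values must be unique")
  if (anyDuplicated(design[c("region", "time")]))
    stop("(region, time) pairs must be unique")
  if (any(design$time < 0)) stop("time must be non-negative")
  if (sum(design$region == "control") != 1)
    stop("exactly one control sample is required")
  design
}

#' Filter probes against local background
#'
#' Retains probes whose signal exceeds `k` times the local background
#' (strict inequality), either in every sample (`all_samples`, the stricter
#' default) or in at least one (`any_sample`). Probe order is preserved and
#' the operation is idempotent.
#'
#' @param pt A [probe_table()].
#' @param k Ratio threshold (> 0); 1.4 is the conventional default.
#' @param mode `"all_samples"` or `"any_sample"`.
#' @return The filtered [probe_table()].
#' @export
filter_probes <- function(pt, k = 1.4, mode = c("all_samples", "any_sample")) {
  mode <- match.arg(mode)
  stopifnot(inherits(pt, "probe_table"), k > 0)
  if (any(pt$background <= 0))
    stop("background must be strictly positive wherever the ratio is tested")
  pass <- pt$signal > k * pt$background
  keep <- if (mode == "all_samples") apply(pass, 1, all) else apply(pass, 1, any)
  message(sprintf("filter_probes: retained %d of %d probes (k = %g, %s)",
                  sum(keep), length(keep), k, mode))
  probe_table(pt$probe_id[keep], pt$gene_symbol[keep],
              pt$signal[keep, , drop = FALSE],
              pt$background[keep, , drop = FALSE])
}

#' Quantile-normalize an intensity matrix
#'
#' Forces every column onto the across-sample mean of order statistics so
#' that all columns share one value multiset; ties within a column receive
#' the mean of their target quantiles (Bolstad convention). Delegates to
#' [limma::normalizeQuantiles()].
#'
#' @param m Numeric matrix (features x samples), linear or log2 scale.
#' @return Matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2) {
    warning("quantile_normalize: single sample, returning input unchanged")
    return(m)
  }
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Average duplicated probes per gene
#'
#' Collapses a probe-level matrix to one row per gene symbol by the
#' arithmetic mean of each gene's probes on the stored scale. Probes
#' missing from the mapping (or mapped to `NA`) are dropped with a message.
#'
#' @param m Numeric matrix with probe ids as rownames.
#' @param probe_to_gene Named character vector, probe id -> gene symbol.
#' @return Matrix with gene symbols as rownames.
#' @export
average_duplicates <- function(m, probe_to_gene) {
  m <- as.matrix(m)
  if (length(probe_to_gene) == 0) stop("empty probe-to-gene mapping")
  genes <- probe_to_gene[rownames(m)]
  unmapped <- is.na(genes)
  if (any(unmapped)) {
    message(sprintf("average_duplicates: dropping %d unmapped probes",
                    sum(unmapped)))
    m <- m[!unmapped, , drop = FALSE]
    genes <- genes[!unmapped]
  }
  if (nrow(m) == 0) stop("no mapped probes left to collapse")
  out <- rowsum(m, group = genes, reorder = TRUE)
  out / as.vector(table(genes)[rownames(out)])
}

#' Log2 expression ratios versus the control sample
#'
#' Forms, per region and time point, `log2(intensity / control intensity)`
#' gene-wise on linear-scale intensities. Genes with a zero or negative
#' control intensity are excluded and reported.
#'
#' @param m Gene x sample matrix of linear intensities; columns must cover
#'   every `sample_id` in `design`.
#' @param design A validated sample design (see [read_sample_design()]).
#' @return A `time_course` object: a named list of per-region gene x time
#'   matrices of log2 ratios (columns named by time, increasing, including
#'   the reference time), with the design attached.
#' @export
compute_log_ratios <- function(m, design) {
  design <- validate_sample_design(design)
  m <- as.matrix(m)
  if (!all(design$sample_id %in% colnames(m)))
    stop("expression matrix is missing declared samples")
  ctrl_id <- design$sample_id[design$region == "control"]
  ctrl <- m[, ctrl_id]
  bad <- ctrl <= 0
  if (any(bad)) {
    message(sprintf(
      "compute_log_ratios: excluding %d genes with non-positive control intensity",
      sum(bad)))
    m <- m[!bad, , drop = FALSE]
    ctrl <- ctrl[!bad]
  }
  if (any(m[, design$sample_id] <= 0))
    stop("linear intensities must be strictly positive")
  regions <- setdiff(unique(design$region), "control")
  out <- lapply(regions, function(rg) {
    d <- design[design$region == rg, ]
    d <- d[order(d$time), ]
    ratios <- log2(m[, d$sample_id, drop = FALSE] / ctrl)
    colnames(ratios) <- d$time
    if (d$time[1] != 0)
      warning(sprintf("region %s has no time-0 reference sample", rg))
    ratios
  })
  names(out) <- regions
  structure(out, design = design, class = "time_course")
}

#' @export
print.time_course <- function(x, ...) {
  cat("time_course with regions:\n")
  for (rg in names(x))
    cat(sprintf("  %-14s %5d genes, times: %s\n", rg, nrow(x[[rg]]),
                paste(colnames(x[[rg]]), collapse = ", ")))
  invisible(x)
}

#' Read/write a gene x time log-ratio matrix
#'
#' TSV with genes in rows and samples (time points) in columns, the
#' exchange format between pipeline stages.
#'
#' @param path File path.
#' @return `read_timecourse_matrix` returns a numeric matrix.
#' @export
read_timecourse_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1)
  as.matrix(df)
}

#' @rdname read_timecourse_matrix
#' @param m Matrix to write.
#' @export
write_timecourse_matrix <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Average-linkage hierarchical clustering under correlation distance
#'
#' Clusters rows of a log-ratio matrix with distance 1 - Pearson
#' correlation (centered by default; the uncentered variant of the original
#' Cluster program is available). Rows with zero variance get correlation 0
#' (distance 1) to everything, with a warning.
#'
#' @param m Numeric matrix, rows are the objects to cluster.
#' @param linkage Agglomeration method, `"average"`.
#' @param centered Use centered Pearson correlation (default) or the
#'   uncentered cosine-style variant.
#' @return An [stats::hclust] object (merge tree plus leaf order).
#' @export
hierarchical_cluster <- function(m, linkage = "average", centered = TRUE) {
  m <- as.matrix(m)
  if (nrow(m) < 2) stop("need at least 2 rows to cluster")
  if (centered) {
    sds <- apply(m, 1, stats::sd)
    cc <- suppressWarnings(stats::cor(t(m)))
  } else {
    norms <- sqrt(rowSums(m^2))
    cc <- (m %*% t(m)) / outer(norms, norms)
    sds <- norms
  }
  if (any(sds == 0 | !is.finite(sds))) {
    warning("rows with zero variance assigned correlation 0 (distance 1)")
  }
  cc[!is.finite(cc)] <- 0
  d <- stats::as.dist(1 - cc)
  stats::hclust(d, method = linkage)
}

#' Relative qRT-PCR fold change (delta-delta-Ct)
#'
#' `2 ^ -((ct_target_test - ct_ref_test) - (ct_target_ctrl - ct_ref_ctrl))`.
#'
#' @param ct_target_test,ct_ref_test Ct of the target and the reference
#'   gene in the test sample.
#' @param ct_target_ctrl,ct_ref_ctrl Same in the control sample.
#' @return Fold change relative to control (vectorized).
#' @export
ddct_fold_change <- function(ct_target_test, ct_ref_test,
                             ct_target_ctrl, ct_ref_ctrl) {
  cts <- cbind(ct_target_test, ct_ref_test, ct_target_ctrl, ct_ref_ctrl)
  if (any(!is.finite(cts))) stop("all Ct values must be finite")
  ddct <- (ct_target_test - ct_ref_test) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}
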