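# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. seed = NULL runs `code` with the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Derive a bounded child seed from a parent seed and an index, so that
# independent substreams are reproducible and order-invariant.
child_seed <- function(seed, i) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(i) * 9973L
}

# Canonical (unordered) representation of gene pairs: a < b lexicographically.
canonical_pairs <- function(a, b) {
  swap <- a > b
  tmp <- a[swap]
  a[swap] <- b[swap]
  b[swap] <- tmp
  data.frame(a = a, b = b, stringsAsFactors = FALSE)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two clusterings of the same objects,
#' used to score module recovery against a planted ground truth. 1 means
#' identical partitions (up to label permutation), 0 is the expectation
#' under independent random partitions.
#'
#' @param x,y Cluster labels (vectors of equal length; any atomic type).
#' @return A single number in (-1, 1].
#' @export
adjusted_rand_index <- function(x, y) {
  stopifnot(length(x) == length(y))
  tab <- table(x, y)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- ai * bj / n2
  maxi <- (ai + bj) / 2
  if (maxi == expected) return(1)
  (nij - expected) / (maxi - expected)
}
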