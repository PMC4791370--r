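with_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

# Rank matrix of the n(n-1)/2 pairwise dissimilarities (average ranks on
# ties), stored symmetrically with a zero diagonal.
rank_matrix <- function(d) {
  n <- nrow(d)
  lower <- lower.tri(d)
  r <- matrix(0, n, n)
  r[lower] <- rank(d[lower])
  r + t(r)
}

#' ANOSIM R statistic
#'
#' R = (mean between-group rank - mean within-group rank) / (M/2) with
#' M = n(n-1)/2, computed on the ranks of all pairwise dissimilarities
#' (average ranks on ties). R is 1 when all between-group dissimilarities
#' exceed all within-group ones, near 0 when grouping is random.
#'
#' @param d Symmetric dissimilarity matrix.
#' @param groups Group labels, one per sample (k >= 2 non-empty groups).
#' @return The R statistic, in `[-1, 1]`.
#' @export
anosim_r <- function(d, groups) {
  d <- as.matrix(d)
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) stop("need at least two groups")
  r <- rank_matrix(d)
  anosim_r_ranked(r, groups)
}

anosim_r_ranked <- function(r, groups) {
  n <- nrow(r)
  same <- outer(as.integer(groups), as.integer(groups), `==`)
  lower <- lower.tri(r)
  within <- same & lower
  if (!any(within)) stop("no within-group pairs (all groups singletons)")
  between <- !same & lower
  m <- n * (n - 1) / 2
  (mean(r[between]) - mean(r[within])) / (m / 2)
}

#' k-R clustering: partition samples to maximize ANOSIM R
#'
#' Non-hierarchical analogue of k-means for arbitrary dissimilarities:
#' starting from random partitions, single samples are greedily reallocated
#' between groups as long as a move increases the ANOSIM R of the
#' partition, so that samples most similar on average to the members of a
#' group end up in that group. The best of `restarts` random
#' initializations is returned; the result is locally optimal (no single
#' reallocation increases R).
#'
#' @param d Symmetric dissimilarity matrix.
#' @param k Number of groups (2 <= k <= n-1).
#' @param restarts Number of random initializations (default 50).
#' @param seed Optional integer seed for reproducibility.
#' @return A list of class `kr_partition`: `groups` (factor of labels
#'   `g1..gk`), `r` (the achieved ANOSIM R), `k`, `restarts`.
#' @export
kr_cluster <- function(d, k = 2, restarts = 50, seed = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (k < 2 || k > n - 1) stop("k must be in [2, n-1]")
  if (all(d == 0)) stop("degenerate dissimilarity matrix (all zero)")
  with_seed(seed)
  r <- rank_matrix(d)
  best <- NULL
  best_r <- -Inf
  for (s in seq_len(restarts)) {
    g <- random_partition(n, k)
    res <- kr_local_search(r, g, k)
    if (res$r > best_r) {
      best_r <- res$r
      best <- res$groups
    }
  }
  labels <- factor(paste0("g", best), levels = paste0("g", seq_len(k)))
  if (!is.null(rownames(d))) names(labels) <- rownames(d)
  structure(list(groups = labels, r = best_r, k = k, restarts = restarts),
            class = "kr_partition")
}

#' @export
print.kr_partition <- function(x, ...) {
  cat("k-R clustering: k =", x$k, " ANOSIM R =", format(x$r, digits = 4),
      "\n")
  print(table(x$groups))
  invisible(x)
}

# random k-group assignment guaranteed non-empty
random_partition <- function(n, k) {
  g <- sample(rep(seq_len(k), length.out = n))
  g
}

kr_local_search <- function(r, g, k) {
  cur <- anosim_r_ranked(r, factor(g, levels = seq_len(k)))
  n <- length(g)
  repeat {
    improved <- FALSE
    for (i in seq_len(n)) {
      if (sum(g == g[i]) == 1L) next  # move would empty the group
      for (target in seq_len(k)) {
        if (target == g[i]) next
        cand <- g
        cand[i] <- target
        val <- tryCatch(
          anosim_r_ranked(r, factor(cand, levels = seq_len(k))),
          error = function(e) -Inf)
        if (val > cur + 1e-12) {
          g <- cand
          cur <- val
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  list(groups = g, r = cur)
}

#' Exhaustive k = 2 partition search (reference implementation)
#'
#' Enumerates all 2^(n-1) - 1 two-group partitions and returns the one
#' with maximal ANOSIM R. Intended as a brute-force reference for
#' validating [kr_cluster()] on small n.
#'
#' @param d Symmetric dissimilarity matrix (n <= 20 advisable).
#' @return As [kr_cluster()].
#' @export
kr_exhaustive_k2 <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  r <- rank_matrix(d)
  best <- NULL
  best_r <- -Inf
  # sample 1 fixed in group 1 to avoid label-swapped duplicates
  for (code in seq_len(2^(n - 1) - 1)) {
    bits <- as.integer(intToBits(code))[seq_len(n - 1)]
    g <- c(1L, bits + 1L)
    val <- anosim_r_ranked(r, factor(g, levels = 1:2))
    if (val > best_r) {
      best_r <- val
      best <- g
    }
  }
  labels <- factor(paste0("g", best), levels = c("g1", "g2"))
  if (!is.null(rownames(d))) names(labels) <- rownames(d)
  structure(list(groups = labels, r = best_r, k = 2L, restarts = NA_integer_),
            class = "kr_partition")
}
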