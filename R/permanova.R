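#' Permutational multivariate analysis of variance (one-way)
#'
#' Pseudo-F for a fixed one-way design on a dissimilarity matrix:
#' SS_total = sum of squared dissimilarities / n, SS_within = per-group
#' sums of squared dissimilarities / group size, F = ((SS_total -
#' SS_within)/(k-1)) / (SS_within/(n-k)). The p-value is obtained by
#' permuting sample labels: p = (number of permuted F >= observed F + 1) /
#' (B + 1).
#'
#' @param d Symmetric dissimilarity matrix.
#' @param groups Group labels (k >= 2).
#' @param permutations Number of label permutations B (default 999).
#' @param seed Optional integer seed.
#' @return A list of class `permutation_test` with `statistic` (pseudo-F),
#'   `p_value`, `n_permutations`, `seed`, `method`.
#' @export
permanova <- function(d, groups, permutations = 999, seed = NULL) {
  d <- as.matrix(d)
  groups <- as.factor(groups)
  n <- nrow(d)
  k <- nlevels(droplevels(groups))
  if (k < 2) stop("need at least two groups")
  if (n <= k) stop("need more samples than groups")
  with_seed(seed)
  d2 <- d^2
  f_obs <- permanova_f(d2, as.integer(groups), k, n)
  g0 <- as.integer(groups)
  exceed <- 0L
  for (b in seq_len(permutations)) {
    f_b <- permanova_f(d2, g0[sample.int(n)], k, n)
    if (f_b >= f_obs - 1e-12) exceed <- exceed + 1L
  }
  permutation_test(f_obs, (exceed + 1) / (permutations + 1), permutations,
                   seed, "PERMANOVA pseudo-F")
}

permanova_f <- function(d2, g, k, n) {
  ss_total <- sum(d2[lower.tri(d2)]) / n
  ss_within <- 0
  for (lev in seq_len(k)) {
    idx <- which(g == lev)
    ng <- length(idx)
    if (ng > 1) {
      sub <- d2[idx, idx]
      ss_within <- ss_within + sum(sub[lower.tri(sub)]) / ng
    }
  }
  ((ss_total - ss_within) / (k - 1)) / (ss_within / (n - k))
}

permutation_test <- function(statistic, p_value, n_permutations, seed,
                             method) {
  structure(list(statistic = statistic, p_value = p_value,
                 n_permutations = n_permutations,
                 seed = if (is.null(seed)) NA_integer_ else seed,
                 method = method),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(x$method, ": statistic =", format(x$statistic, digits = 4),
      ", p =", format(x$p_value, digits = 4),
      " (", x$n_permutations, "permutations )\n")
  invisible(x)
}

#' One-way ANOVA on a single variable
#'
#' Classical fixed-effects one-way analysis of variance, used to test
#' single environmental variables between sample groups.
#'
#' @param values Numeric vector, one value per sample.
#' @param groups Group labels.
#' @return A list with `f`, `p`, `df`.
#' @export
anova_oneway <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2) stop("need at least two groups")
  tab <- anova(lm(values ~ groups))
  list(f = tab$`F value`[1], p = tab$`Pr(>F)`[1],
       df = tab$Df)
}

#' Matrix correlation between two dissimilarity matrices (RELATE)
#'
#' Spearman rank correlation of the corresponding off-diagonal
#' dissimilarities of two matrices over the same samples, with
#' significance assessed by permuting the sample identities of the second
#' matrix (a Mantel-type test).
#'
#' @param d1,d2 Symmetric dissimilarity matrices with identical sample
#'   labels.
#' @param permutations Number of permutations (default 999).
#' @param seed Optional integer seed.
#' @return A `permutation_test` with `statistic` = Spearman rho.
#' @export
relate <- function(d1, d2, permutations = 999, seed = NULL) {
  d1 <- as.matrix(d1)
  d2 <- as.matrix(d2)
  if (!identical(dim(d1), dim(d2)))
    stop("matrices must have the same dimensions")
  if (!is.null(rownames(d1)) && !is.null(rownames(d2)) &&
      !identical(rownames(d1), rownames(d2)))
    stop("sample labels differ between matrices")
  with_seed(seed)
  n <- nrow(d1)
  lower <- lower.tri(d1)
  r1 <- rank(d1[lower])
  rank2 <- rank_matrix(d2)  # permutation-invariant rank values
  rho_obs <- cor(r1, rank2[lower])
  exceed <- 0L
  for (b in seq_len(permutations)) {
    p <- sample.int(n)
    rho_b <- cor(r1, rank2[p, p][lower])
    if (rho_b >= rho_obs - 1e-12) exceed <- exceed + 1L
  }
  permutation_test(rho_obs, (exceed + 1) / (permutations + 1), permutations,
                   seed, "RELATE (Spearman matrix correlation)")
}
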