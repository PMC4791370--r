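# Shared fixtures and independent oracles used across test files.

# Brute-force formula enumeration by full nested expansion over small
# element ranges; the independent oracle for enumerate_candidates().
small_ranges <- function() {
  element_ranges(c = c(1L, 20L), h = c(1L, 40L), n = c(0L, 2L),
                 o = c(0L, 10L), s = c(0L, 1L), p = c(0L, 1L))
}

oracle_grid <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      r <- small_ranges()
      g <- expand.grid(c = r$c[1]:r$c[2], h = r$h[1]:r$h[2],
                       n = r$n[1]:r$n[2], o = r$o[1]:r$o[2],
                       s = r$s[1]:r$s[2], p = r$p[1]:r$p[2])
      g$mass <- formula_mass(g$c, g$h, g$n, g$o, g$s, g$p)
      cache <<- g
    }
    cache
  }
})

oracle_enumerate <- function(neutral_mass, tolerance_ppm) {
  g <- oracle_grid()
  tol <- neutral_mass * tolerance_ppm * 1e-6
  hit <- abs(g$mass - neutral_mass) <= tol
  sub <- g[hit, , drop = FALSE]
  sort(formula_string(sub))
}

# Two well-separated Gaussian clouds with labelled samples.
two_cloud_distance <- function(n_per = 5, sep = 10, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * 2), ncol = 2),
             matrix(rnorm(n_per * 2, mean = sep), ncol = 2))
  rownames(x) <- paste0("s", seq_len(2 * n_per))
  list(d = as.matrix(dist(x)),
       groups = factor(rep(c("A", "B"), each = n_per)))
}

random_distance <- function(n, seed) {
  set.seed(seed)
  x <- matrix(rnorm(n * 3), n)
  rownames(x) <- paste0("s", seq_len(n))
  as.matrix(dist(x))
}

adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}
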