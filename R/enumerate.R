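#' Default element count ranges for formula assignment
#'
#' Bounds of the CHNOSP search space used by [enumerate_candidates()].
#' Defaults cover marine DOM: C 1-100, H 1-200, N 0-4, O 0-50, S 0-2,
#' P 0-1.
#'
#' @param c,h,n,o,s,p Length-2 integer vectors `c(min, max)` per element.
#' @return A named list of ranges.
#' @export
element_ranges <- function(c = base::c(1L, 100L), h = base::c(1L, 200L),
                           n = base::c(0L, 4L), o = base::c(0L, 50L),
                           s = base::c(0L, 2L), p = base::c(0L, 1L)) {
  r <- list(c = c, h = h, n = n, o = o, s = s, p = p)
  for (el in names(r)) {
    if (length(r[[el]]) != 2L || any(r[[el]] < 0) || r[[el]][1] > r[[el]][2])
      stop("invalid range for element ", el)
  }
  r
}

# Grid of (c, n, o, s, p) combinations with their partial masses, cached per
# range set so repeated peak lookups only pay the vector scan.
.range_grid_cache <- new.env(parent = emptyenv())

candidate_grid <- function(ranges) {
  key <- paste(unlist(ranges), collapse = ",")
  if (!is.null(.range_grid_cache[[key]])) return(.range_grid_cache[[key]])
  g <- expand.grid(
    c = seq.int(ranges$c[1], ranges$c[2]),
    n = seq.int(ranges$n[1], ranges$n[2]),
    o = seq.int(ranges$o[1], ranges$o[2]),
    s = seq.int(ranges$s[1], ranges$s[2]),
    p = seq.int(ranges$p[1], ranges$p[2]),
    KEEP.OUT.ATTRS = FALSE
  )
  g$base <- formula_mass(c = g$c, n = g$n, o = g$o, s = g$s, p = g$p)
  ord <- order(g$base)
  g <- g[ord, , drop = FALSE]
  .range_grid_cache[[key]] <- g
  g
}

#' Enumerate molecular formulas matching a neutral mass
#'
#' Exhaustively searches the CHNOSP space within the element ranges for
#' formulas whose neutral monoisotopic mass lies within a relative mass
#' tolerance of the query. The hydrogen count is solved from the mass
#' remainder of each (C, N, O, S, P) combination, which makes the search
#' equivalent to full nested enumeration.
#'
#' @param neutral_mass Query neutral mass in Da.
#' @param tolerance_ppm Relative mass tolerance in ppm (> 0).
#' @param ranges Element ranges from [element_ranges()].
#' @return A formula table with an extra `error_ppm` column (signed,
#'   candidate minus query), sorted by absolute mass error. Zero rows if
#'   nothing matches.
#' @export
enumerate_candidates <- function(neutral_mass, tolerance_ppm = 0.5,
                                 ranges = element_ranges()) {
  if (tolerance_ppm <= 0) stop("tolerance_ppm must be positive")
  g <- candidate_grid(ranges)
  tol <- ppm_window(neutral_mass, tolerance_ppm)
  mh <- ATOMIC_MASS[["h"]]
  # base masses must leave room for at least h_min hydrogens
  upper <- findInterval(neutral_mass + tol - ranges$h[1] * mh, g$base)
  if (upper < 1L) return(empty_candidates())
  base <- g$base[seq_len(upper)]
  h <- round((neutral_mass - base) / mh)
  mass <- base + h * mh
  ok <- h >= ranges$h[1] & h <= ranges$h[2] & abs(mass - neutral_mass) <= tol
  if (!any(ok)) return(empty_candidates())
  idx <- which(ok)
  out <- formula_table(c = g$c[idx], h = h[idx], n = g$n[idx],
                       o = g$o[idx], s = g$s[idx], p = g$p[idx])
  out$error_ppm <- (out$mass - neutral_mass) / neutral_mass * 1e6
  out[order(abs(out$error_ppm)), , drop = FALSE]
}

empty_candidates <- function() {
  out <- formula_table(c = 1L, h = 1L)[0L, , drop = FALSE]
  out$error_ppm <- numeric(0)
  out
}

#' Double bond equivalents of a molecular formula
#'
#' DBE = 1 + (2C - H + N + P) / 2, the degree of unsaturation.
#'
#' @param f A formula table (rows vectorized).
#' @return Numeric DBE values (half-integers indicate chemically invalid
#'   electron counts and are rejected by [chemical_filters()]).
#' @export
dbe <- function(f) 1 + (2 * f$c - f$h + f$n + f$p) / 2

#' Chemical plausibility filter for candidate formulas
#'
#' Retains formulas with at least one C and one H, an integer DBE >= 0,
#' elemental ratios 0.3 <= H/C <= 2.5 and O/C <= 1.2, and counts within
#' the supplied ranges. These bounds delimit compositions observed in
#' natural organic matter.
#'
#' @param f A formula table.
#' @param ranges Element ranges from [element_ranges()].
#' @return Logical vector, `TRUE` for formulas passing all rules.
#' @export
chemical_filters <- function(f, ranges = element_ranges()) {
  d <- dbe(f)
  within <- rep(TRUE, nrow(f))
  for (el in ELEMENTS) {
    within <- within & f[[el]] >= ranges[[el]][1] & f[[el]] <= ranges[[el]][2]
  }
  hc <- ifelse(f$c > 0, f$h / f$c, Inf)
  oc <- ifelse(f$c > 0, f$o / f$c, Inf)
  f$c >= 1 & f$h >= 1 &
    abs(d - round(d)) < 1e-9 & d >= 0 &
    hc >= 0.3 & hc <= 2.5 & oc <= 1.2 &
    within
}

# Excluded heteroatom signatures: exact (N, S, P) patterns; NSP means all
# three present in any count.
HETEROATOM_EXCLUSIONS <- rbind(
  c(2, 1, 0), c(3, 1, 0), c(4, 1, 0),      # N2S, N3S, N4S
  c(2, 0, 1), c(3, 0, 1), c(4, 0, 1),      # N2P, N3P, N4P
  c(1, 2, 0), c(2, 2, 0), c(3, 2, 0), c(4, 2, 0),  # NS2..N4S2
  c(0, 2, 1)                               # PS2
)

#' Heteroatom-combination exclusion
#'
#' Flags formulas whose (N, S, P) signature matches one of the improbable
#' heteroatom combinations removed from DOM assignments: NSP (all three
#' present), N2S, N3S, N4S, N2P, N3P, N4P, NS2, N2S2, N3S2, N4S2, PS2.
#'
#' @param f A formula table.
#' @return Logical vector, `TRUE` for formulas to exclude.
#' @export
heteroatom_exclusion <- function(f) {
  nsp <- f$n >= 1 & f$s >= 1 & f$p >= 1
  key <- paste(f$n, f$s, f$p)
  listed <- key %in% paste(HETEROATOM_EXCLUSIONS[, 1],
                           HETEROATOM_EXCLUSIONS[, 2],
                           HETEROATOM_EXCLUSIONS[, 3])
  nsp | listed
}
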