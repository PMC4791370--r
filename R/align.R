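#' Align mass peaks across samples
#'
#' Groups m/z values from all samples by single-linkage within a relative
#' tolerance: sorted masses are chained while consecutive gaps stay below
#' the tolerance. Each input peak lands in exactly one aligned column. If
#' two peaks of one sample fall into the same column the more intense one
#' is kept and the conflict is recorded.
#'
#' @param peaks A long-format data frame with columns `sample_id`, `mz`,
#'   `intensity`, `sn` (signal-to-noise); `resolution` optional.
#' @param tolerance_ppm Alignment tolerance in ppm.
#' @return A list of class `aligned_mass_table` with elements
#'   `intensity` (samples x columns matrix, 0 = absent), `sn` (matching
#'   matrix of signal-to-noise, 0 = absent), `mz` (per-column
#'   intensity-weighted mean m/z), `samples`, and `conflicts` (dropped
#'   duplicate peaks).
#' @export
align_masses <- function(peaks, tolerance_ppm = 0.5) {
  stopifnot(all(c("sample_id", "mz", "intensity", "sn") %in% names(peaks)))
  if (nrow(peaks) == 0L) stop("no peaks to align")
  samples <- sort(unique(as.character(peaks$sample_id)))
  ord <- order(peaks$mz)
  p <- peaks[ord, , drop = FALSE]
  gap <- diff(p$mz)
  # single linkage: break a chain where the gap exceeds the local window
  new_col <- c(TRUE, gap > ppm_window(p$mz[-nrow(p)], tolerance_ppm))
  col_id <- cumsum(new_col)
  ncol_ <- max(col_id)

  intensity <- matrix(0, nrow = length(samples), ncol = ncol_,
                      dimnames = list(samples, NULL))
  sn <- intensity
  conflicts <- p[0L, , drop = FALSE]
  # within (column, sample), keep the most intense peak
  key <- paste(col_id, p$sample_id)
  by_int <- order(-p$intensity)
  keep <- logical(nrow(p))
  keep[by_int] <- !duplicated(key[by_int])
  dup <- !keep
  if (any(dup)) conflicts <- p[dup, , drop = FALSE]
  kept <- p[keep, , drop = FALSE]
  kcol <- col_id[keep]
  idx <- cbind(match(as.character(kept$sample_id), samples), kcol)
  intensity[idx] <- kept$intensity
  sn[idx] <- kept$sn
  mz <- as.numeric(tapply(seq_len(nrow(kept)), kcol, function(i) {
    sum(kept$mz[i] * kept$intensity[i]) / sum(kept$intensity[i])
  }))
  structure(list(intensity = intensity, sn = sn, mz = mz,
                 samples = samples, conflicts = conflicts),
            class = "aligned_mass_table")
}

#' @export
print.aligned_mass_table <- function(x, ...) {
  cat("Aligned mass table:", length(x$samples), "samples x",
      length(x$mz), "masses\n")
  if (nrow(x$conflicts) > 0L)
    cat(" ", nrow(x$conflicts), "within-sample alignment conflicts dropped\n")
  invisible(x)
}

#' Signal-to-noise screen on aligned peaks
#'
#' Zeroes out aligned peaks below a minimum signal-to-noise ratio (default
#' 4) before any occurrence counting or formula assignment.
#'
#' @param tab An `aligned_mass_table`.
#' @param min_sn Minimum S/N for a peak to be considered detected.
#' @return The table with sub-threshold peaks removed; columns left with
#'   no detections are dropped.
#' @export
sn_filter <- function(tab, min_sn = 4) {
  low <- tab$sn < min_sn
  tab$intensity[low] <- 0
  tab$sn[low] <- 0
  drop_columns(tab, colSums(tab$intensity > 0) > 0L)
}

#' Cross-sample occurrence filter
#'
#' Keeps an aligned mass if it is detected in more than two samples, or,
#' when present in fewer than 20% of the samples, if its signal-to-noise
#' ratio exceeds `min_sn_single` in at least one sample.
#'
#' @param tab An `aligned_mass_table`.
#' @param min_sn_single S/N that rescues a rare mass (default 20).
#' @return The filtered table.
#' @export
cross_sample_filter <- function(tab, min_sn_single = 20) {
  n <- length(tab$samples)
  occ <- colSums(tab$intensity > 0)
  max_sn <- apply(tab$sn, 2, max)
  keep <- occ > 2 | (occ < 0.2 * n & max_sn > min_sn_single)
  drop_columns(tab, keep)
}

drop_columns <- function(tab, keep) {
  tab$intensity <- tab$intensity[, keep, drop = FALSE]
  tab$sn <- tab$sn[, keep, drop = FALSE]
  tab$mz <- tab$mz[keep]
  tab
}
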