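#' Assign formulas to aligned masses and resolve ambiguities
#'
#' For every aligned mass, candidates are enumerated at the given
#' tolerance, screened by [chemical_filters()] and purged of excluded
#' heteroatom combinations ([heteroatom_exclusion()]). A mass with exactly
#' one surviving candidate yields an assignment; masses with two or more
#' surviving candidates (double assignments) are dropped entirely.
#'
#' @param tab An `aligned_mass_table`, already S/N- and occurrence-filtered.
#' @param tolerance_ppm Assignment tolerance in ppm.
#' @param ranges Element ranges from [element_ranges()].
#' @return A list of class `formula_assignments`: `formulas` (formula table,
#'   one row per retained aligned mass, with `error_ppm`), `intensity` and
#'   `sn` matrices restricted to assigned columns, `mz`, `samples`, and
#'   `n_ambiguous` (count of dropped double assignments).
#' @export
assign_and_resolve <- function(tab, tolerance_ppm = 0.5,
                               ranges = element_ranges()) {
  ncol_ <- length(tab$mz)
  keep <- logical(ncol_)
  rows <- vector("list", ncol_)
  n_ambiguous <- 0L
  for (j in seq_len(ncol_)) {
    cand <- enumerate_candidates(neutral_mass_from_mz(tab$mz[j]),
                                 tolerance_ppm, ranges)
    if (nrow(cand) == 0L) next
    cand <- cand[chemical_filters(cand, ranges) & !heteroatom_exclusion(cand),
                 , drop = FALSE]
    if (nrow(cand) == 1L) {
      keep[j] <- TRUE
      rows[[j]] <- cand
    } else if (nrow(cand) > 1L) {
      n_ambiguous <- n_ambiguous + 1L
    }
  }
  formulas <- do.call(rbind, rows[keep])
  if (is.null(formulas)) formulas <- empty_candidates()
  structure(list(formulas = formulas,
                 intensity = tab$intensity[, keep, drop = FALSE],
                 sn = tab$sn[, keep, drop = FALSE],
                 mz = tab$mz[keep],
                 samples = tab$samples,
                 n_ambiguous = n_ambiguous),
            class = "formula_assignments")
}

#' @export
print.formula_assignments <- function(x, ...) {
  cat("Formula assignments:", nrow(x$formulas), "formulas across",
      length(x$samples), "samples\n")
  if (x$n_ambiguous > 0L)
    cat(" ", x$n_ambiguous, "ambiguous masses dropped\n")
  invisible(x)
}

#' Remove contaminant series and their isotopologs
#'
#' Removes assignments whose neutral mass matches (within tolerance) a
#' listed contaminant mass, any CH2-homolog of a contaminant (mass +- k x
#' 14.01565 Da within the evaluated window), or the 13C isotopolog
#' (+1.003355 Da) of any removed mass.
#'
#' @param assignments A `formula_assignments` object.
#' @param contaminant_masses Numeric vector of known contaminant neutral
#'   masses (Da); may be empty.
#' @param tolerance_ppm Matching tolerance in ppm.
#' @param mass_window Mass range over which homologous series are expanded.
#' @return The pruned `formula_assignments`.
#' @export
remove_contaminants <- function(assignments, contaminant_masses = numeric(0),
                                tolerance_ppm = 0.5,
                                mass_window = c(150, 2000)) {
  if (length(contaminant_masses) == 0L) return(assignments)
  series <- unlist(lapply(contaminant_masses, function(m) {
    k_up <- floor((mass_window[2] - m) / mass_constants[["ch2"]])
    k_dn <- floor((m - mass_window[1]) / mass_constants[["ch2"]])
    m + mass_constants[["ch2"]] * seq.int(-max(k_dn, 0), max(k_up, 0))
  }))
  removed <- c(series, series + mass_constants[["c13"]])
  masses <- assignments$formulas$mass
  bad <- vapply(masses, function(m) {
    any(abs(removed - m) <= ppm_window(m, tolerance_ppm))
  }, logical(1))
  keep_assignment_subset(assignments, !bad)
}

keep_assignment_subset <- function(assignments, keep) {
  assignments$formulas <- assignments$formulas[keep, , drop = FALSE]
  assignments$intensity <- assignments$intensity[, keep, drop = FALSE]
  assignments$sn <- assignments$sn[, keep, drop = FALSE]
  assignments$mz <- assignments$mz[keep]
  assignments
}

#' Sum-normalize assigned intensities into a DOM table
#'
#' Divides each sample's intensities by their total so that relative
#' intensities sum to one per sample; these are treated as quantitative
#' relative abundances of the assigned formulas.
#'
#' @param assignments A `formula_assignments` object.
#' @return A `dom_table`: numeric matrix (samples x formulas, columns named
#'   by formula string) with attribute `formulas` holding the formula table.
#' @export
normalize_intensities <- function(assignments) {
  m <- assignments$intensity
  totals <- rowSums(m)
  if (any(totals == 0)) {
    stop("no retained assignments for sample(s): ",
         paste(assignments$samples[totals == 0], collapse = ", "))
  }
  rel <- m / totals
  colnames(rel) <- assignments$formulas$formula
  dom_table(rel, assignments$formulas)
}

#' Construct a DOM relative-intensity table
#'
#' @param rel Numeric matrix, samples x formulas; rows must sum to 1.
#' @param formulas Formula table describing the columns (same order).
#' @return A matrix of class `dom_table` with a `formulas` attribute.
#' @export
dom_table <- function(rel, formulas) {
  stopifnot(ncol(rel) == nrow(formulas))
  if (any(rel < 0)) stop("relative intensities must be non-negative")
  if (any(abs(rowSums(rel) - 1) > 1e-9))
    stop("dom_table rows must sum to 1")
  structure(rel, formulas = formulas, class = c("dom_table", "matrix"))
}

#' Full formula-assignment cascade for peak lists
#'
#' Runs the complete pipeline: S/N screen (>= 4), cross-sample alignment,
#' occurrence filter, candidate enumeration with chemical and heteroatom
#' filters, double-assignment removal, contaminant/isotopolog removal, and
#' sum normalization.
#'
#' @param peaks Long-format peak data frame (see [align_masses()]).
#' @param tolerance_ppm Mass tolerance in ppm used throughout.
#' @param ranges Element ranges from [element_ranges()].
#' @param contaminant_masses Known contaminant neutral masses (Da).
#' @param min_sn Detection threshold on signal-to-noise (default 4).
#' @param min_sn_single S/N rescuing rare masses (default 20).
#' @return A `dom_table` (see [normalize_intensities()]).
#' @export
assign_formulas <- function(peaks, tolerance_ppm = 0.5,
                            ranges = element_ranges(),
                            contaminant_masses = numeric(0),
                            min_sn = 4, min_sn_single = 20) {
  tab <- align_masses(peaks, tolerance_ppm)
  tab <- sn_filter(tab, min_sn)
  tab <- cross_sample_filter(tab, min_sn_single)
  a <- assign_and_resolve(tab, tolerance_ppm, ranges)
  a <- remove_contaminants(a, contaminant_masses, tolerance_ppm)
  normalize_intensities(a)
}
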