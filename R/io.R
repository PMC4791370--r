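#' Read peak lists from TSV
#'
#' Accepts either one long-format file with a `sample_id` column or a
#' directory of per-sample files (file name becomes the sample id).
#' Expected columns: `mz`, `intensity`, `sn`; `resolution` optional.
#'
#' @param path A TSV file or a directory of TSV files.
#' @return A long-format peak data frame (see [align_masses()]).
#' @export
read_peak_lists <- function(path) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.tsv$", full.names = TRUE)
    if (length(files) == 0L) stop("no .tsv files in ", path)
    out <- lapply(files, function(f) {
      d <- read.delim(f, check.names = FALSE)
      d$sample_id <- sub("\\.tsv$", "", basename(f))
      d
    })
    peaks <- do.call(rbind, out)
  } else {
    peaks <- read.delim(path, check.names = FALSE)
  }
  required <- c("sample_id", "mz", "intensity", "sn")
  missing <- setdiff(required, names(peaks))
  if (length(missing) > 0)
    stop("peak list lacks column(s): ", paste(missing, collapse = ", "))
  peaks
}

#' Read a samples-x-features TSV table
#'
#' First column is taken as the sample id and becomes the row names.
#'
#' @param path TSV file path.
#' @return Numeric matrix with sample row names.
#' @export
read_sample_table <- function(path) {
  d <- read.delim(path, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- as.character(d[[1]])
  storage.mode(m) <- "double"
  m
}

#' Read a contaminant mass list (one neutral mass in Da per line)
#'
#' @param path Text file path; blank lines and `#` comments are ignored.
#' @return Numeric vector of masses.
#' @export
read_contaminant_list <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  as.numeric(lines)
}

#' Write a DOM table to TSV
#'
#' Samples as rows, formula strings as column names.
#'
#' @param dom A `dom_table`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_dom_table <- function(dom, path) {
  write.table(data.frame(sample = rownames(dom), unclass(dom),
                         check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a DOM table written by [write_dom_table()]
#'
#' Formula strings in the header are parsed back into element counts.
#'
#' @param path TSV file path.
#' @return A `dom_table`.
#' @export
read_dom_table <- function(path) {
  m <- read_sample_table(path)
  dom_table(m / rowSums(m), parse_formula(colnames(m)))
}
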