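# Peak-list and sequence I/O plus intensity-based peak selection.
# FASTA parsing rides on Biostrings; MGF and two-column CSV peak lists are
# simple line formats handled here with strict (reject, don't coerce)
# validation.

#' Construct a peak list
#'
#' An ordered set of (m/z, intensity) centroids. Peaks are sorted ascending
#' in m/z on construction; duplicates are preserved.
#'
#' @param mz Numeric vector of m/z values (> 0).
#' @param intensity Numeric vector of non-negative intensities.
#' @param mode Acquisition mode, `"reflectron"` or `"linear"`.
#' @param label Free-text label (sample / condition).
#' @return An object of class `peak_list` with elements `peaks`
#'   (data.frame `mz`, `intensity`), `mode`, `label`.
#' @export
peak_list <- function(mz = numeric(0), intensity = numeric(0),
                      mode = c("reflectron", "linear"), label = "") {
  mode <- match.arg(mode)
  stopifnot(length(mz) == length(intensity))
  if (length(mz)) {
    if (any(!is.finite(mz)) || any(mz <= 0))
      stop("m/z values must be finite and positive", call. = FALSE)
    if (any(!is.finite(intensity)) || any(intensity < 0))
      stop("intensities must be finite and non-negative", call. = FALSE)
  }
  o <- order(mz)
  structure(list(peaks = data.frame(mz = as.numeric(mz[o]),
                                    intensity = as.numeric(intensity[o])),
                 mode = mode, label = label),
            class = "peak_list")
}

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf("<peak_list> %d peaks, mode=%s%s\n", nrow(x$peaks), x$mode,
              if (nzchar(x$label)) paste0(", label=", x$label) else ""))
  if (nrow(x$peaks)) {
    cat(sprintf("  m/z range %.4f - %.4f\n",
                min(x$peaks$mz), max(x$peaks$mz)))
  }
  invisible(x)
}

#' Read a protein FASTA file
#'
#' Headers are split into `accession` (first whitespace-delimited token)
#' and `description` (the remainder). Sequence content before the first
#' header is rejected with its line number.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame of class `protein_records` with columns
#'   `accession`, `description`, `sequence`.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  first_rec <- which(startsWith(lines, ">"))[1]
  junk <- which(nzchar(trimws(lines)))
  junk <- junk[is.na(first_rec) | junk < first_rec]
  if (length(junk))
    stop(sprintf("malformed FASTA: sequence data before first header at line %d",
                 junk[1]), call. = FALSE)
  if (is.na(first_rec)) {
    return(new_protein_records(character(0), character(0), character(0)))
  }
  set <- Biostrings::readAAStringSet(path)
  headers <- names(set)
  acc <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  new_protein_records(acc, desc, as.character(set))
}

new_protein_records <- function(accession, description, sequence) {
  df <- data.frame(accession = accession, description = description,
                   sequence = unname(sequence), stringsAsFactors = FALSE)
  class(df) <- c("protein_records", "data.frame")
  df
}

#' Write protein records as FASTA
#'
#' Round-trip stable with [read_fasta()] on accession and sequence.
#'
#' @param records A `protein_records` data.frame (columns `accession`,
#'   `description`, `sequence`).
#' @param path Output path.
#' @param width Line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    hdr <- records$accession[i]
    if (!is.null(records$description) && nzchar(records$description[i]))
      hdr <- paste(hdr, records$description[i])
    writeLines(paste0(">", hdr), con)
    s <- records$sequence[i]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# strict numeric CSV (m/z, intensity); optional single header line
read_csv_peaks <- function(path, mode = "linear", label = "") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(peak_list(mode = mode, label = label))
  fields <- strsplit(lines, ",", fixed = TRUE)
  start <- 1L
  suppressWarnings(
    first <- as.numeric(trimws(fields[[1]]))
  )
  if (any(is.na(first))) start <- 2L  # header line
  mz <- numeric(0); intensity <- numeric(0)
  for (i in seq(start, length.out = max(0L, length(lines) - start + 1L))) {
    f <- trimws(fields[[i]])
    if (length(f) < 2L)
      stop(sprintf("malformed peak row at line %d: need m/z,intensity", i),
           call. = FALSE)
    suppressWarnings(v <- as.numeric(f[1:2]))
    if (any(is.na(v)))
      stop(sprintf("non-numeric peak row at line %d", i), call. = FALSE)
    mz <- c(mz, v[1]); intensity <- c(intensity, v[2])
  }
  peak_list(mz, intensity, mode = mode, label = label)
}

write_csv_peaks <- function(pl, path) {
  utils::write.table(
    data.frame(mz = pl$peaks$mz, intensity = pl$peaks$intensity),
    path, sep = ",", row.names = FALSE, col.names = c("mz", "intensity"),
    quote = FALSE)
  invisible(path)
}

#' Read an MGF file (MS/MS peak lists)
#'
#' Standard `BEGIN IONS` / `END IONS` blocks with `TITLE=`, `PEPMASS=` and
#' `CHARGE=` keys. Each block becomes a `peak_list` carrying attributes
#' `pepmass`, `charge` and `title`. Non-numeric peak rows are rejected with
#' their line number.
#'
#' @param path Path to an MGF file.
#' @return List of `peak_list` objects.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (trimws(lines[i]) == "BEGIN IONS") {
      title <- ""; pepmass <- NA_real_; charge <- NA_integer_
      mz <- numeric(0); intensity <- numeric(0)
      i <- i + 1L
      while (i <= length(lines) && trimws(lines[i]) != "END IONS") {
        ln <- trimws(lines[i])
        if (startsWith(ln, "TITLE=")) {
          title <- sub("^TITLE=", "", ln)
        } else if (startsWith(ln, "PEPMASS=")) {
          pepmass <- as.numeric(strsplit(sub("^PEPMASS=", "", ln),
                                         "\\s+")[[1]][1])
        } else if (startsWith(ln, "CHARGE=")) {
          charge <- as.integer(sub("\\+$", "", sub("^CHARGE=", "", ln)))
        } else if (nzchar(ln) && !grepl("=", ln, fixed = TRUE)) {
          suppressWarnings(
            v <- as.numeric(strsplit(ln, "[[:space:],]+")[[1]][1:2]))
          if (any(is.na(v)))
            stop(sprintf("non-numeric MGF peak row at line %d", i),
                 call. = FALSE)
          mz <- c(mz, v[1]); intensity <- c(intensity, v[2])
        }
        i <- i + 1L
      }
      if (i > length(lines))
        stop("malformed MGF: BEGIN IONS without END IONS", call. = FALSE)
      pl <- peak_list(mz, intensity, mode = "reflectron", label = title)
      attr(pl, "pepmass") <- pepmass
      attr(pl, "charge") <- charge
      attr(pl, "title") <- title
      out[[length(out) + 1L]] <- pl
    }
    i <- i + 1L
  }
  out
}

#' Write peak lists as MGF
#'
#' @param spectra A `peak_list` or list of `peak_list`s; the `pepmass`,
#'   `charge` and `title` attributes are emitted when present.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  if (inherits(spectra, "peak_list")) spectra <- list(spectra)
  con <- file(path, "w")
  on.exit(close(con))
  for (pl in spectra) {
    writeLines("BEGIN IONS", con)
    title <- attr(pl, "title")
    if (!is.null(title) && nzchar(title))
      writeLines(paste0("TITLE=", title), con)
    pm <- attr(pl, "pepmass")
    if (!is.null(pm) && !is.na(pm))
      writeLines(sprintf("PEPMASS=%.6f", pm), con)
    ch <- attr(pl, "charge")
    if (!is.null(ch) && !is.na(ch))
      writeLines(sprintf("CHARGE=%d+", ch), con)
    writeLines(sprintf("%.4f %.4f", pl$peaks$mz, pl$peaks$intensity), con)
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}

#' Read a peak list from CSV or MGF
#'
#' @param path Input path.
#' @param format `"auto"` (by extension), `"csv"` or `"mgf"`.
#' @param mode Acquisition mode recorded on CSV peak lists.
#' @param label Label recorded on CSV peak lists.
#' @return A `peak_list` (CSV) or list of `peak_list`s (MGF).
#' @export
read_peaklist <- function(path, format = c("auto", "csv", "mgf"),
                          mode = "linear", label = "") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "mgf") "mgf" else "csv"
  }
  if (format == "mgf") read_mgf(path)
  else read_csv_peaks(path, mode = mode, label = label)
}

#' Write a peak list to CSV or MGF
#'
#' @inheritParams read_peaklist
#' @param pl A `peak_list` (or list of them, MGF only).
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(pl, path, format = c("auto", "csv", "mgf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "mgf") "mgf" else "csv"
  }
  if (format == "mgf") write_mgf(pl, path) else write_csv_peaks(pl, path)
}

#' Intensity-based peak selection
#'
#' Implements the search-input filter: keep peaks at least 10% above the
#' noise level, then return the `max_n` most intense of those, re-sorted by
#' m/z. When `noise` is not supplied it is estimated as the median peak
#' intensity.
#'
#' @param pl A `peak_list`.
#' @param max_n Maximum number of peaks to return (default 50).
#' @param noise Noise intensity level, or `NULL` to use the median.
#' @return A filtered `peak_list` (always a subset of the input;
#'   idempotent only in the trivial sense that re-selecting never adds
#'   peaks).
#' @export
select_peaks <- function(pl, max_n = 50, noise = NULL) {
  stopifnot(inherits(pl, "peak_list"), max_n >= 0)
  if (!nrow(pl$peaks)) return(pl)
  if (is.null(noise)) noise <- stats::median(pl$peaks$intensity)
  keep <- pl$peaks[pl$peaks$intensity >= 1.1 * noise, , drop = FALSE]
  if (nrow(keep) > max_n) {
    o <- order(-keep$intensity, keep$mz)
    keep <- keep[o[seq_len(max_n)], , drop = FALSE]
  }
  peak_list(keep$mz, keep$intensity, mode = pl$mode, label = pl$label)
}
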