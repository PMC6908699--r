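# In-silico tryptic digestion with missed cleavages and variable-modification
# expansion. Peptide collections are plain data.frames (class "peptide_spans")
# so downstream code can use ordinary subsetting.

#' Construct a peptide-span collection
#'
#' @param sequence Character vector of peptide residue strings.
#' @param parent_id Parent identifier(s).
#' @param start,end 1-based inclusive parent coordinates (default a
#'   standalone 1..nchar placement).
#' @param missed_cleavages Internal uncleaved-site counts.
#' @return A `peptide_spans` data.frame.
#' @export
peptide_spans <- function(sequence, parent_id = "peptide",
                          start = rep(1L, length(sequence)),
                          end = nchar(sequence),
                          missed_cleavages = rep(0L, length(sequence))) {
  stopifnot(all(end - start + 1L == nchar(sequence)))
  if (!length(sequence)) {
    return(new_peptide_spans(data.frame(
      parent_id = character(0), start = integer(0), end = integer(0),
      sequence = character(0), missed_cleavages = integer(0),
      stringsAsFactors = FALSE)))
  }
  new_peptide_spans(data.frame(
    parent_id = parent_id, start = as.integer(start),
    end = as.integer(end), sequence = sequence,
    missed_cleavages = as.integer(missed_cleavages),
    stringsAsFactors = FALSE))
}

new_peptide_spans <- function(df) {
  stopifnot(all(c("parent_id", "start", "end", "sequence",
                  "missed_cleavages") %in% names(df)))
  n <- nrow(df)
  if (!"n_mods" %in% names(df)) df$n_mods <- rep(0L, n)
  if (!"mod_positions" %in% names(df)) df$mod_positions <- rep("", n)
  if (!"mod_delta_mono" %in% names(df)) df$mod_delta_mono <- rep(0, n)
  if (!"mod_delta_avg" %in% names(df)) df$mod_delta_avg <- rep(0, n)
  class(df) <- c("peptide_spans", "data.frame")
  df
}

# K/R positions not followed by P (Keil rule), excluding the C-terminus
cleavage_sites <- function(sequence) {
  res <- residue_vector(sequence)
  n <- length(res)
  if (n < 2) return(integer(0))
  idx <- which(res[-n] %in% c("K", "R"))
  idx[res[idx + 1L] != "P"]
}

#' Tryptic in-silico digestion
#'
#' Cleaves after K or R except when the next residue is P (Keil rule) and
#' returns every peptide carrying 0 to `max_missed` internal uncleaved
#' sites. The zero-missed peptides tile the parent exactly; a k-missed
#' peptide is the concatenation of k+1 consecutive zero-missed peptides.
#' Output is ordered by start, then end.
#'
#' @param sequence Parent residue string.
#' @param max_missed Maximum number of missed cleavages (default 2,
#'   the usual search-engine setting).
#' @param parent_id Identifier recorded in the `parent_id` column.
#' @return A `peptide_spans` data.frame with columns `parent_id`, `start`,
#'   `end`, `sequence`, `missed_cleavages` (1-based inclusive coordinates).
#' @examples
#' digest_trypsin("AKRPGK", max_missed = 1)
#' @export
digest_trypsin <- function(sequence, max_missed = 2, parent_id = "protein") {
  stopifnot(max_missed >= 0)
  res <- residue_vector(sequence)
  n <- length(res)
  if (n == 0L) {
    return(new_peptide_spans(data.frame(
      parent_id = character(0), start = integer(0), end = integer(0),
      sequence = character(0), missed_cleavages = integer(0),
      stringsAsFactors = FALSE)))
  }
  cuts <- cleavage_sites(sequence)
  # boundaries of the 0-missed peptides
  starts0 <- c(1L, cuts + 1L)
  ends0 <- c(cuts, n)
  k_max <- min(max_missed, length(starts0) - 1L)
  out <- vector("list", k_max + 1L)
  for (k in 0:k_max) {
    i <- seq_len(length(starts0) - k)
    out[[k + 1L]] <- data.frame(
      parent_id = parent_id, start = starts0[i], end = ends0[i + k],
      missed_cleavages = k, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  df <- df[order(df$start, df$end), , drop = FALSE]
  df$sequence <- substring(sequence, df$start, df$end)
  rownames(df) <- NULL
  new_peptide_spans(df[, c("parent_id", "start", "end", "sequence",
                           "missed_cleavages")])
}

#' Expand variable modifications over a peptide collection
#'
#' For each peptide, enumerates every combination of 0..`max_sites`
#' modified target residues (the unmodified form always included), for
#' each variable modification in `mods`. With `s` candidate sites the
#' peptide yields `sum_k choose(s, k)` forms for `k = 0..max_sites`.
#'
#' @param spans A `peptide_spans` data.frame (e.g. from [digest_trypsin()]).
#' @param mods List of variable [modification_spec()] objects
#'   (default: phospho-S/T).
#' @param max_sites Maximum simultaneously modified sites per peptide
#'   (default 2, bounding the combinatorics as search engines do).
#' @return A `peptide_spans` data.frame with additional columns `n_mods`,
#'   `mod_positions` (peptide-relative indices, ";"-separated),
#'   `mod_delta_mono`, `mod_delta_avg`.
#' @export
expand_variable_mods <- function(spans, mods = list(phospho_st()),
                                 max_sites = 2) {
  if (max_sites < 0) stop("max_sites must be >= 0", call. = FALSE)
  for (m in mods) {
    stopifnot(inherits(m, "modification_spec"))
    if (!m$variable) stop("all mods must be variable", call. = FALSE)
  }
  base <- as.data.frame(spans, stringsAsFactors = FALSE)
  base$n_mods <- 0L
  base$mod_positions <- ""
  base$mod_delta_mono <- 0
  base$mod_delta_avg <- 0
  pieces <- list(base)
  for (m in mods) {
    targets <- m$target_residues
    for (i in seq_len(nrow(base))) {
      res <- strsplit(base$sequence[i], "", fixed = TRUE)[[1]]
      sites <- which(res %in% targets)
      if (!length(sites)) next
      for (k in seq_len(min(max_sites, length(sites)))) {
        combos <- utils::combn(sites, k, simplify = FALSE)
        rows <- base[rep(i, length(combos)), , drop = FALSE]
        rows$n_mods <- k
        rows$mod_positions <- vapply(combos, paste, "", collapse = ";")
        rows$mod_delta_mono <- k * m$delta_mono
        rows$mod_delta_avg <- k * m$delta_avg
        pieces[[length(pieces) + 1L]] <- rows
      }
    }
  }
  df <- do.call(rbind, pieces)
  df <- df[order(df$start, df$end, df$n_mods, df$mod_positions), ,
           drop = FALSE]
  rownames(df) <- NULL
  new_peptide_spans(df)
}

#' Singly protonated monoisotopic mass of each peptide in a collection
#'
#' Residue sum + water + modification deltas + one proton, vectorised over
#' a `peptide_spans` data.frame.
#'
#' @param spans A `peptide_spans` data.frame.
#' @param tab A [mass_table()].
#' @return Numeric vector of \[M+H\]+ values in Da.
#' @export
span_mh <- function(spans, tab = mass_table()) {
  vapply(seq_len(nrow(spans)), function(i) {
    sum(tab$residue_mono[strsplit(spans$sequence[i], "", fixed = TRUE)[[1]]])
  }, numeric(1)) + tab$water_mono + spans$mod_delta_mono + tab$proton
}
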