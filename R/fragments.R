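# Theoretical b- and y-ion series for MS/MS matching. Only singly charged
# fragments are generated (MALDI-TOF/TOF regime); b1 is included so a
# "complete" b-series covers every prefix.

fragment_frame <- function(series, index, mz, composition) {
  data.frame(series = series, index = index, mz = mz,
             composition = composition, stringsAsFactors = FALSE)
}

# per-residue modification deltas from a peptide_spans row
.mod_deltas <- function(sequence, mod_positions = "", delta = 0) {
  n <- nchar(sequence)
  d <- numeric(n)
  if (nzchar(mod_positions)) {
    pos <- as.integer(strsplit(mod_positions, ";", fixed = TRUE)[[1]])
    d[pos] <- delta / length(pos)
  }
  d
}

#' Theoretical b-ion series
#'
#' `b_i` = sum of the first `i` residue monoisotopic masses (including any
#' modification deltas on those residues) plus one proton, for
#' `i = 1 .. n-1`.
#'
#' @param sequence Peptide residue string (length >= 2 for a non-empty
#'   series).
#' @param mod_positions Peptide-relative modified positions,
#'   ";"-separated string (as produced by [expand_variable_mods()]).
#' @param mod_delta_mono Total monoisotopic modification delta, split
#'   evenly across `mod_positions`.
#' @param tab A [mass_table()].
#' @return data.frame with columns `series`, `index`, `mz`, `composition`.
#' @examples
#' b_series("AG")  # b1 = 72.0444
#' @export
b_series <- function(sequence, mod_positions = "", mod_delta_mono = 0,
                     tab = mass_table()) {
  res <- residue_vector(sequence, tab)
  n <- length(res)
  if (n < 2) return(fragment_frame(character(0), integer(0),
                                   numeric(0), character(0)))
  d <- .mod_deltas(sequence, mod_positions, mod_delta_mono)
  cum <- cumsum(tab$residue_mono[res] + d)
  i <- seq_len(n - 1L)
  fragment_frame("b", i, cum[i] + tab$proton,
                 substring(sequence, 1L, i))
}

#' Theoretical y-ion series
#'
#' `y_i` = sum of the last `i` residue masses (with modification deltas)
#' plus water plus one proton, for `i = 1 .. n-1`.
#'
#' @inheritParams b_series
#' @return data.frame with columns `series`, `index`, `mz`, `composition`.
#' @export
y_series <- function(sequence, mod_positions = "", mod_delta_mono = 0,
                     tab = mass_table()) {
  res <- residue_vector(sequence, tab)
  n <- length(res)
  if (n < 2) return(fragment_frame(character(0), integer(0),
                                   numeric(0), character(0)))
  d <- .mod_deltas(sequence, mod_positions, mod_delta_mono)
  cum <- cumsum(rev(tab$residue_mono[res] + d))
  i <- seq_len(n - 1L)
  fragment_frame("y", i, cum[i] + tab$water_mono + tab$proton,
                 substring(sequence, n - i + 1L, n))
}

#' Combined b + y fragment table
#'
#' @inheritParams b_series
#' @param series `"both"`, `"b"` or `"y"`.
#' @return data.frame of fragment ions, ascending in m/z within series.
#' @export
fragment_ions <- function(sequence, series = c("both", "b", "y"),
                          mod_positions = "", mod_delta_mono = 0,
                          tab = mass_table()) {
  series <- match.arg(series)
  out <- switch(series,
    b = b_series(sequence, mod_positions, mod_delta_mono, tab),
    y = y_series(sequence, mod_positions, mod_delta_mono, tab),
    both = rbind(b_series(sequence, mod_positions, mod_delta_mono, tab),
                 y_series(sequence, mod_positions, mod_delta_mono, tab)))
  rownames(out) <- NULL
  out
}
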