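# Mass, m/z, ppm, average-mass and isoelectric-point arithmetic.
# All other modules route their mass bookkeeping through this file.

#' Residue mass table and physical constants
#'
#' Monoisotopic and average masses of the 20 canonical amino-acid residues
#' plus the constants every m/z computation needs. Monoisotopic masses are
#' used for reflectron-mode peptide work (10 ppm regime), average masses for
#' linear-mode intact-protein work.
#'
#' @return An object of class `mass_table` with elements
#'   `residue_mono`, `residue_avg` (named numeric vectors, Da),
#'   `water_mono`, `water_avg`, `proton` (Da).
#' @examples
#' tab <- mass_table()
#' tab$residue_mono[["G"]]
#' @export
mass_table <- function() {
  structure(list(
    residue_mono = c(
      G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
      T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
      N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
      E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
      R = 156.10111, Y = 163.06333, W = 186.07931),
    residue_avg = c(
      G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
      T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594,
      N = 114.1038, D = 115.0886, Q = 128.1307, K = 128.1741,
      E = 129.1155, M = 131.1926, H = 137.1411, F = 147.1766,
      R = 156.1875, Y = 163.1760, W = 186.2132),
    water_mono = 18.010565,
    water_avg  = 18.01528,
    proton     = 1.007276
  ), class = "mass_table")
}

# split a sequence into residues, rejecting non-canonical letters with
# the offending position (B, Z, X, U etc. are rejected, never guessed)
residue_vector <- function(sequence, tab = mass_table()) {
  stopifnot(is.character(sequence), length(sequence) == 1L, !is.na(sequence))
  if (!nzchar(sequence)) return(character(0))
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!res %in% names(tab$residue_mono))
  if (length(bad)) {
    stop(sprintf("non-canonical residue '%s' at position %d",
                 res[bad[1]], bad[1]), call. = FALSE)
  }
  res
}

#' Define a (variable) modification
#'
#' @param name Modification name.
#' @param target_residues Character vector of residue letters the
#'   modification can sit on.
#' @param delta_mono,delta_avg Mass shifts in Da.
#' @param variable Logical; variable modifications are expanded
#'   combinatorially by [expand_variable_mods()].
#' @return An object of class `modification_spec`.
#' @seealso [phospho_st()]
#' @export
modification_spec <- function(name, target_residues, delta_mono,
                              delta_avg = delta_mono, variable = TRUE) {
  stopifnot(is.character(name), length(target_residues) >= 1L,
            is.finite(delta_mono), is.finite(delta_avg))
  structure(list(name = name,
                 target_residues = unique(target_residues),
                 delta_mono = delta_mono, delta_avg = delta_avg,
                 variable = isTRUE(variable)),
            class = "modification_spec")
}

#' Phosphorylation of serine/threonine
#'
#' The variable modification used throughout the search defaults
#' (HPO3, +79.96633 Da monoisotopic).
#' @return A `modification_spec`.
#' @export
phospho_st <- function() {
  modification_spec("Phospho", c("S", "T"),
                    delta_mono = 79.96633, delta_avg = 79.9799,
                    variable = TRUE)
}

#' Neutral (uncharged) mass of a peptide
#'
#' Sum of residue masses plus one water, plus any applied modification
#' deltas. `mods` is a list of applications, each a list with elements
#' `spec` (a [modification_spec()]) and `position` (1-based residue index);
#' an application on a residue outside the spec's target set is rejected.
#'
#' @param sequence Residue string (canonical letters only).
#' @param mods List of modification applications (may be `NULL`).
#' @param mode `"mono"` or `"average"`.
#' @param tab A [mass_table()].
#' @return Neutral mass in Da.
#' @examples
#' peptide_neutral_mass("GG")                      # 132.0535
#' peptide_neutral_mass("AST",
#'   mods = list(list(spec = phospho_st(), position = 2)))
#' @export
peptide_neutral_mass <- function(sequence, mods = NULL,
                                 mode = c("mono", "average"),
                                 tab = mass_table()) {
  mode <- match.arg(mode)
  res <- residue_vector(sequence, tab)
  masses <- if (mode == "mono") tab$residue_mono else tab$residue_avg
  water  <- if (mode == "mono") tab$water_mono else tab$water_avg
  m <- sum(masses[res]) + water
  for (app in mods) {
    spec <- app$spec
    pos <- app$position
    stopifnot(inherits(spec, "modification_spec"))
    if (pos < 1L || pos > length(res))
      stop(sprintf("modification position %d outside peptide", pos),
           call. = FALSE)
    if (!res[pos] %in% spec$target_residues)
      stop(sprintf("modification '%s' applied to non-target residue '%s' at %d",
                   spec$name, res[pos], pos), call. = FALSE)
    m <- m + if (mode == "mono") spec$delta_mono else spec$delta_avg
  }
  m
}

#' Convert a neutral mass to m/z at a given charge
#'
#' `(M + z * proton) / z` for positive-mode protonated species
#' ([M+H]+, [M+2H]2+, [M+3H]3+ ...).
#'
#' @param neutral_mass Neutral mass in Da (vectorised).
#' @param charge Positive integer charge.
#' @param tab A [mass_table()].
#' @return m/z in Da per unit charge.
#' @export
mz_from_mass <- function(neutral_mass, charge, tab = mass_table()) {
  if (any(charge < 1) || any(charge != round(charge)))
    stop("charge must be a positive integer", call. = FALSE)
  (neutral_mass + charge * tab$proton) / charge
}

#' Recover the neutral mass from an observed m/z and charge
#'
#' Inverse of [mz_from_mass()]: `M = mz * z - z * proton`.
#' @inheritParams mz_from_mass
#' @param mz Observed m/z.
#' @return Neutral mass in Da.
#' @export
mass_from_mz <- function(mz, charge, tab = mass_table()) {
  if (any(charge < 1) || any(charge != round(charge)))
    stop("charge must be a positive integer", call. = FALSE)
  mz * charge - charge * tab$proton
}

#' Signed relative mass error in parts per million
#'
#' @param observed,theoretical Masses in Da; `theoretical` must be > 0.
#' @return `(observed - theoretical) / theoretical * 1e6`.
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0))
    stop("theoretical mass must be positive", call. = FALSE)
  (observed - theoretical) / theoretical * 1e6
}

#' Average (isotope-abundance weighted) mass of a protein
#'
#' @param sequence Residue string.
#' @param tab A [mass_table()].
#' @return Average mass in Da.
#' @export
average_protein_mass <- function(sequence, tab = mass_table()) {
  res <- residue_vector(sequence, tab)
  sum(tab$residue_avg[res]) + tab$water_avg
}

# Bjellqvist pKa set. Side chains plus termini; the N-terminal pKa depends
# on the first residue.
.pka_side <- c(C = 9.00, D = 4.05, E = 4.45, H = 5.98, K = 10.00,
               R = 12.00, Y = 10.00)
.pka_cterm <- 3.55
.pka_nterm <- c(A = 7.59, M = 7.00, S = 6.93, P = 8.36, T = 6.82,
                V = 7.44, E = 7.70, G = 7.50)
.pka_nterm_default <- 7.50

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch sum over the termini and the ionisable side chains
#' (D, E, C, Y, H, K, R) using the Bjellqvist pKa set.
#'
#' @param sequence Residue string.
#' @param pH pH value (vectorised).
#' @return Net charge (signed).
#' @export
net_charge <- function(sequence, pH) {
  res <- residue_vector(sequence)
  if (!length(res)) return(rep(0, length(pH)))
  counts <- table(res)
  nterm_pka <- if (res[1] %in% names(.pka_nterm)) .pka_nterm[[res[1]]]
               else .pka_nterm_default
  pos_frac <- function(pka) 1 / (1 + 10^(pH - pka))
  neg_frac <- function(pka) 1 / (1 + 10^(pka - pH))
  n_of <- function(a) if (a %in% names(counts)) counts[[a]] else 0
  pos <- pos_frac(nterm_pka) +
    n_of("K") * pos_frac(.pka_side[["K"]]) +
    n_of("R") * pos_frac(.pka_side[["R"]]) +
    n_of("H") * pos_frac(.pka_side[["H"]])
  neg <- neg_frac(.pka_cterm) +
    n_of("D") * neg_frac(.pka_side[["D"]]) +
    n_of("E") * neg_frac(.pka_side[["E"]]) +
    n_of("C") * neg_frac(.pka_side[["C"]]) +
    n_of("Y") * neg_frac(.pka_side[["Y"]])
  pos - neg
}

#' Isoelectric point of a protein
#'
#' pH at which [net_charge()] crosses zero, found by bisection on
#' \[0, 14\] to the requested precision. The charge curve is monotonically
#' decreasing in pH, so the bisection always converges.
#'
#' @param sequence Residue string.
#' @param precision Bisection stopping width in pH units.
#' @return The pI as a pH value.
#' @export
isoelectric_point <- function(sequence, precision = 0.001) {
  lo <- 0; hi <- 14
  while (hi - lo > precision) {
    mid <- (lo + hi) / 2
    if (net_charge(sequence, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
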