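# Seeded synthetic-data generators. Every generator is a pure function of
# (parameters, seed) and returns its ground truth alongside the data so
# recovery tests never peek at the implementation under test.

# run code under a local RNG state so generators do not disturb the
# caller's random stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

.CANONICAL <- c("G","A","S","P","V","T","C","L","I","N",
                "D","Q","K","E","M","H","F","R","Y","W")

#' Random protein database
#'
#' Uniform residue composition over the 20 canonical letters; accessions
#' `SYN0001`, `SYN0002`, ... Deterministic for a given seed.
#'
#' @param n Number of proteins (>= 0).
#' @param length_range Length bounds in residues (inclusive).
#' @param seed Integer seed.
#' @return A `protein_records` data.frame.
#' @export
random_protein_db <- function(n, length_range = c(200, 500), seed = 1) {
  stopifnot(n >= 0)
  with_seed(seed, {
    lens <- if (n) length_range[1] - 1L +
              sample.int(length_range[2] - length_range[1] + 1L, n,
                         replace = TRUE)
            else integer(0)
    seqs <- vapply(lens, function(L)
      paste(sample(.CANONICAL, L, replace = TRUE), collapse = ""), "")
    protein_records(sprintf("SYN%04d", seq_len(n)), seqs,
                    description = "synthetic random protein")
  })
}

#' Plant substitutions into a sequence (isoform emulation)
#'
#' Substitutes `n_subs` distinct positions to different residues and
#' returns the substitution list as ground truth. With
#' `preserve_cleavage = TRUE` (default) K/R/P positions are never touched
#' and K/R/P are never introduced, so the tryptic span structure of parent
#' and isoform coincide and every discriminating peptide necessarily
#' overlaps a planted substitution.
#'
#' @param sequence Parent residue string.
#' @param n_subs Number of substitutions (<= eligible positions).
#' @param seed Integer seed.
#' @param preserve_cleavage Keep the tryptic cleavage pattern intact.
#' @return List with `sequence` (the isoform) and `substitutions`
#'   (data.frame `position`, `a` = parent residue, `b` = isoform residue).
#' @export
mutate_isoform <- function(sequence, n_subs, seed = 1,
                           preserve_cleavage = TRUE) {
  res <- residue_vector(sequence)
  eligible <- if (preserve_cleavage)
    which(!res %in% c("K", "R", "P")) else seq_along(res)
  if (n_subs > length(eligible))
    stop(sprintf("n_subs (%d) exceeds eligible positions (%d)",
                 n_subs, length(eligible)), call. = FALSE)
  targets_pool <- if (preserve_cleavage)
    setdiff(.CANONICAL, c("K", "R", "P")) else .CANONICAL
  with_seed(seed, {
    pos <- sort(sample(eligible, n_subs))
    new <- vapply(pos, function(p)
      sample(setdiff(targets_pool, res[p]), 1L), "")
    out <- res
    out[pos] <- new
    list(sequence = paste(out, collapse = ""),
         substitutions = data.frame(position = pos, a = res[pos], b = new,
                                    stringsAsFactors = FALSE))
  })
}

#' Simulate a peptide mass fingerprint
#'
#' Digest, take the unique theoretical \[M+H\]+ masses, apply Gaussian ppm
#' jitter, drop a random fraction, append uniform contaminant masses, and
#' shuffle. Ground truth (source accession, true masses, kept indices) is
#' returned alongside.
#'
#' @param protein Single-row `protein_records` or residue string.
#' @param ppm_sd Jitter SD in ppm.
#' @param dropout Fraction of peptide masses discarded (in \[0, 1)).
#' @param n_contaminants Number of contaminant masses appended.
#' @param seed Integer seed.
#' @param max_missed Missed cleavages for the digest.
#' @return List with `masses` (the query list) and `truth` (list:
#'   `accession`, `true_masses`, `n_real`, `ppm_sd`, `dropout`, `seed`).
#' @export
simulate_pmf <- function(protein, ppm_sd = 3, dropout = 0,
                         n_contaminants = 0, seed = 1, max_missed = 2) {
  stopifnot(ppm_sd >= 0, dropout >= 0, dropout < 1)
  seq <- .as_sequence(protein)
  acc <- if (is.data.frame(protein)) protein$accession[1] else "protein"
  spans <- digest_trypsin(seq, max_missed, acc)
  mh <- sort(unique(span_mh(spans)))
  with_seed(seed, {
    jit <- mh * (1 + stats::rnorm(length(mh), 0, ppm_sd * 1e-6))
    keep <- stats::runif(length(jit)) >= dropout
    obs <- jit[keep]
    contam <- if (n_contaminants > 0)
      stats::runif(n_contaminants, min(mh) * 0.8, max(mh) * 1.2)
      else numeric(0)
    masses <- sample(c(obs, contam))
    list(masses = masses,
         truth = list(accession = acc, true_masses = mh[keep],
                      n_real = sum(keep), ppm_sd = ppm_sd,
                      dropout = dropout, seed = seed))
  })
}

#' Simulate an MS/MS spectrum of a peptide
#'
#' Theoretical b and/or y ion m/z values with Gaussian jitter and
#' log-normal intensities, plus uniform noise peaks over the fragment m/z
#' range at lower intensity.
#'
#' @param sequence Peptide residue string (length >= 2).
#' @param series `"both"`, `"b"` or `"y"`.
#' @param frag_sd_da Fragment m/z jitter SD in Da (keep below tol/3).
#' @param n_noise Number of uniform noise peaks.
#' @param seed Integer seed.
#' @return A `peak_list` with attribute `truth` (list: `sequence`,
#'   `series`, `precursor_mh`, `n_signal`, `seed`).
#' @export
simulate_msms <- function(sequence, series = c("both", "b", "y"),
                          frag_sd_da = 0.02, n_noise = 0, seed = 1) {
  series <- match.arg(series)
  stopifnot(frag_sd_da >= 0, n_noise >= 0)
  theo <- fragment_ions(sequence, series)
  mh <- peptide_neutral_mass(sequence) + mass_table()$proton
  with_seed(seed, {
    mz <- theo$mz + stats::rnorm(nrow(theo), 0, frag_sd_da)
    intensity <- stats::rlnorm(nrow(theo), meanlog = 4, sdlog = 0.5)
    if (n_noise > 0) {
      lo <- min(theo$mz) * 0.9; hi <- max(theo$mz) * 1.05
      mz <- c(mz, stats::runif(n_noise, lo, hi))
      intensity <- c(intensity,
                     stats::rlnorm(n_noise, meanlog = 2.5, sdlog = 0.5))
    }
    pl <- peak_list(mz, intensity, mode = "reflectron", label = sequence)
    attr(pl, "pepmass") <- mh
    attr(pl, "charge") <- 1L
    attr(pl, "title") <- sequence
    attr(pl, "truth") <- list(sequence = sequence, series = series,
                              precursor_mh = mh, n_signal = nrow(theo),
                              seed = seed)
    pl
  })
}

#' Simulate a linear-mode multicharge protein profile
#'
#' For each component and each charge state with non-zero weight, emits
#' one peak: the neutral mass receives relative Gaussian jitter
#' (`rel_mass_sd`, independently per charge state, emulating centroid
#' scatter), and the intensity is abundance times charge weight.
#'
#' @param components data.frame with columns `mass` and `abundance`
#'   (e.g. from [table1_components()]).
#' @param charge_weights Named numeric weights for charges `"1"`, `"2"`,
#'   `"3"`.
#' @param rel_mass_sd Relative mass jitter SD (default 0.002, matching the
#'   0.1-0.6% accuracy regime of linear-mode profiling).
#' @param seed Integer seed.
#' @param label Label for the peak list.
#' @return A linear-mode `peak_list` with attribute `truth` (list:
#'   `masses`, `abundances`, `rel_mass_sd`, `seed`).
#' @export
simulate_linear_profile <- function(components,
                                    charge_weights = c(`1` = 1, `2` = 0.5,
                                                       `3` = 0.25),
                                    rel_mass_sd = 0.002, seed = 1,
                                    label = "") {
  stopifnot(rel_mass_sd >= 0, all(c("mass", "abundance") %in%
                                    names(components)))
  tab <- mass_table()
  charges <- as.integer(names(charge_weights))
  with_seed(seed, {
    mz <- numeric(0); intensity <- numeric(0)
    for (i in seq_len(nrow(components))) {
      for (k in seq_along(charges)) {
        w <- charge_weights[[k]]
        if (w <= 0) next
        m_jit <- components$mass[i] * (1 + stats::rnorm(1, 0, rel_mass_sd))
        mz <- c(mz, mz_from_mass(m_jit, charges[k], tab))
        intensity <- c(intensity, components$abundance[i] * w)
      }
    }
    pl <- peak_list(mz, intensity, mode = "linear", label = label)
    attr(pl, "truth") <- list(masses = components$mass,
                              abundances = components$abundance,
                              rel_mass_sd = rel_mass_sd, seed = seed)
    pl
  })
}

#' Reference component masses of the cardiac-extract profile
#'
#' The measured protein-level masses (Da, linear mode) of the twelve
#' identified components of the goldfish cardiac extract profile, with
#' their reported SDs and the condition in which each was detected. The
#' hypoxic profile contains the 39163 Da aldolase B signal, the normoxic
#' profile the 39668 Da aldolase C signal; neither contains the other.
#'
#' @param condition `"all"`, `"hypoxia"` or `"normoxia"`.
#' @return data.frame with columns `mass`, `sd`, `protein`, `normoxia`,
#'   `hypoxia`, `abundance` (unit abundance for simulation).
#' @export
table1_components <- function(condition = c("all", "hypoxia", "normoxia")) {
  condition <- match.arg(condition)
  df <- data.frame(
    mass = c(44164, 47057, 39163, 39668, 42278, 32183, 35468, 35683,
             15864, 16185, 54613, 41202, 50396),
    sd = c(45, 62, 153, 83, 22, 49, 224, 147, 82, 52, 69, 21, 140),
    protein = c("VTC1A", "ENOB", "ALDOB", "ALDOC", "ACTS", "TPM1", "G3P",
                "LDHA", "MYG", "HBB", "OMA1", "HIF1N", "unknown"),
    normoxia = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                 TRUE, TRUE, FALSE, FALSE),
    hypoxia = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE,
                TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  df$abundance <- 1
  switch(condition,
         all = df,
         hypoxia = df[df$hypoxia, , drop = FALSE],
         normoxia = df[df$normoxia, , drop = FALSE])
}

#' Write a ground-truth sidecar file
#'
#' Flat `key = value` plain-text format; vectors are ";"-separated.
#' @param truth Named list of scalars/vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  lines <- vapply(names(truth), function(k)
    sprintf("%s = %s", k, paste(format(truth[[k]], digits = 15),
                                collapse = ";")), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a ground-truth sidecar file
#'
#' @param path Path written by [write_ground_truth()].
#' @return Named list of character vectors (callers coerce as needed).
#' @export
read_ground_truth <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, " = ", fixed = TRUE)[[1]]
    out[[trimws(kv[1])]] <- strsplit(trimws(kv[2]), ";", fixed = TRUE)[[1]]
  }
  out
}
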