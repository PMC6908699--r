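# PMF search, MS/MS matching and isoform discrimination. The PMF score is
# deliberately transparent: matched-mass count with mean-|ppm| and coverage
# tie-breaks, in place of proprietary search-engine scores.

#' Construct protein records
#'
#' @param accession Character vector of accessions.
#' @param sequence Character vector of residue strings.
#' @param description Optional descriptions.
#' @return A `protein_records` data.frame.
#' @export
protein_records <- function(accession, sequence, description = "") {
  stopifnot(length(accession) == length(sequence))
  if (length(description) == 1L)
    description <- rep(description, length(accession))
  new_protein_records(accession, description, sequence)
}

# digest + variable-mod expansion + [M+H]+ for one protein
.theoretical_peptides <- function(sequence, parent_id, max_missed = 2,
                                  mods = list(phospho_st()),
                                  max_mod_sites = 2, tab = mass_table()) {
  spans <- digest_trypsin(sequence, max_missed = max_missed,
                          parent_id = parent_id)
  if (length(mods) && max_mod_sites > 0)
    spans <- expand_variable_mods(spans, mods, max_sites = max_mod_sites)
  else
    spans <- new_peptide_spans(as.data.frame(spans))
  spans$mh <- span_mh(spans, tab)
  spans
}

# mass-only theoretical peptide table for PMF: cumulative-sum arithmetic,
# no substring materialisation. Modification deltas are position-
# independent, so per-peptide mod *counts* suffice for mass matching.
.pmf_theoretical <- function(sequence, max_missed, mods, max_mod_sites,
                             tab = mass_table()) {
  res <- residue_vector(sequence, tab)
  n <- length(res)
  cum <- c(0, cumsum(tab$residue_mono[res]))
  sites <- which(res[-n] %in% c("K", "R"))
  sites <- sites[res[sites + 1L] != "P"]
  starts0 <- c(1L, sites + 1L)
  ends0 <- c(sites, n)
  k_max <- min(max_missed, length(starts0) - 1L)
  starts <- integer(0); ends <- integer(0)
  for (k in 0:k_max) {
    i <- seq_len(length(starts0) - k)
    starts <- c(starts, starts0[i])
    ends <- c(ends, ends0[i + k])
  }
  base <- cum[ends + 1L] - cum[starts] + tab$water_mono + tab$proton
  out <- list(start = starts, end = ends, mh = base)
  if (max_mod_sites > 0) for (mod in mods) {
    tcum <- c(0, cumsum(res %in% mod$target_residues))
    s <- tcum[ends + 1L] - tcum[starts]
    for (k in seq_len(max_mod_sites)) {
      idx <- which(s >= k)
      if (!length(idx)) break
      out$start <- c(out$start, starts[idx])
      out$end <- c(out$end, ends[idx])
      out$mh <- c(out$mh, base[idx] + k * mod$delta_mono)
    }
  }
  out
}

#' Peptide mass fingerprinting search
#'
#' Each database protein is digested (trypsin, `max_missed`), expanded over
#' the variable modifications, and its theoretical \[M+H\]+ masses compared
#' with the query masses. Every query mass is matched to at most one
#' theoretical peptide (nearest in ppm within tolerance). Proteins are
#' ranked by matched count (descending), then mean |ppm| (ascending), then
#' coverage (descending), then accession; the resulting order is total.
#'
#' @param query_masses Numeric vector of observed \[M+H\]+ masses (Da).
#' @param db A `protein_records` data.frame.
#' @param precursor_tol_ppm Precursor tolerance in ppm (default 10).
#' @param max_missed Maximum missed cleavages (default 2).
#' @param mods Variable modifications (default phospho-S/T); `list()`
#'   disables expansion.
#' @param max_mod_sites Cap on simultaneously modified sites.
#' @return data.frame of class `pmf_results` with columns `accession`,
#'   `matched_count`, `total_query_masses`, `mean_abs_ppm`, `coverage_pct`;
#'   the matched spans per protein are in `attr(, "matched_spans")`.
#' @export
pmf_search <- function(query_masses, db, precursor_tol_ppm = 10,
                       max_missed = 2, mods = list(phospho_st()),
                       max_mod_sites = 2) {
  if (!length(query_masses)) {
    out <- data.frame(accession = character(0), matched_count = integer(0),
                      total_query_masses = integer(0),
                      mean_abs_ppm = numeric(0), coverage_pct = numeric(0))
    class(out) <- c("pmf_results", "data.frame")
    return(out)
  }
  stopifnot(nrow(db) >= 1L)
  tab <- mass_table()
  rows <- vector("list", nrow(db))
  matched_spans <- vector("list", nrow(db))
  for (p in seq_len(nrow(db))) {
    theo <- .pmf_theoretical(db$sequence[p], max_missed, mods,
                             max_mod_sites, tab)
    hit_idx <- integer(0)
    ppms <- numeric(0)
    for (q in query_masses) {
      ppm <- (q - theo$mh) / theo$mh * 1e6
      ok <- which(abs(ppm) <= precursor_tol_ppm)
      if (length(ok)) {
        best <- ok[which.min(abs(ppm[ok]))]
        hit_idx <- c(hit_idx, best)
        ppms <- c(ppms, ppm[best])
      }
    }
    uniq <- unique(hit_idx)
    if (length(uniq)) {
      hits <- data.frame(start = theo$start[uniq], end = theo$end[uniq])
      hits$sequence <- substring(db$sequence[p], hits$start, hits$end)
    } else {
      hits <- data.frame(start = integer(0), end = integer(0),
                         sequence = character(0))
    }
    cov <- if (nrow(hits))
      coverage(hits, nchar(db$sequence[p])) else 0
    rows[[p]] <- data.frame(
      accession = db$accession[p],
      matched_count = length(ppms),
      total_query_masses = length(query_masses),
      mean_abs_ppm = if (length(ppms)) mean(abs(ppms)) else NA_real_,
      coverage_pct = cov, stringsAsFactors = FALSE)
    matched_spans[[p]] <- hits
  }
  out <- do.call(rbind, rows)
  o <- order(-out$matched_count,
             ifelse(is.na(out$mean_abs_ppm), Inf, out$mean_abs_ppm),
             -out$coverage_pct, out$accession)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "matched_spans") <- stats::setNames(matched_spans[o],
                                                out$accession)
  class(out) <- c("pmf_results", "data.frame")
  out
}

# one-to-one nearest-first assignment of theoretical ions to peaks
.match_fragments <- function(theo_mz, peak_mz, tol_da) {
  if (!length(theo_mz) || !length(peak_mz)) return(integer(0))
  grid <- expand.grid(t = seq_along(theo_mz), p = seq_along(peak_mz))
  grid$d <- abs(theo_mz[grid$t] - peak_mz[grid$p])
  grid <- grid[grid$d <= tol_da, , drop = FALSE]
  grid <- grid[order(grid$d, grid$t), , drop = FALSE]
  used_t <- logical(length(theo_mz)); used_p <- logical(length(peak_mz))
  hits <- integer(0)
  for (k in seq_len(nrow(grid))) {
    if (!used_t[grid$t[k]] && !used_p[grid$p[k]]) {
      used_t[grid$t[k]] <- TRUE
      used_p[grid$p[k]] <- TRUE
      hits <- c(hits, grid$t[k])
    }
  }
  sort(hits)
}

#' Match an MS/MS spectrum against candidate peptides
#'
#' Candidates are filtered by precursor tolerance (|ppm| of their \[M+H\]+
#' against `precursor_mz`), then scored by the fraction of their
#' theoretical b+y ions with a peak within `frag_tol_da`. Peak assignment
#' is one-to-one, nearest mass first, so a dense peak cannot satisfy many
#' theoretical ions. Ranking: score descending, |precursor ppm| ascending,
#' sequence as final deterministic tie-break.
#'
#' @param pl A `peak_list` (the MS/MS spectrum).
#' @param candidates A `peptide_spans` data.frame.
#' @param precursor_mz Observed precursor m/z (assumed singly charged).
#' @param frag_tol_da Fragment tolerance in Da (default 0.2).
#' @param precursor_tol_ppm Precursor tolerance in ppm (default 10).
#' @return data.frame of class `msms_matches` with columns `parent_id`,
#'   `sequence`, `start`, `end`, `precursor_ppm`, `b_matched`, `y_matched`,
#'   `n_theoretical`, `score`.
#' @export
msms_match <- function(pl, candidates, precursor_mz, frag_tol_da = 0.2,
                       precursor_tol_ppm = 10) {
  stopifnot(inherits(pl, "peak_list"))
  tab <- mass_table()
  empty <- data.frame(parent_id = character(0), sequence = character(0),
                      start = integer(0), end = integer(0),
                      precursor_ppm = numeric(0), b_matched = integer(0),
                      y_matched = integer(0), n_theoretical = integer(0),
                      score = numeric(0))
  if (!nrow(candidates)) {
    class(empty) <- c("msms_matches", "data.frame")
    return(empty)
  }
  candidates <- new_peptide_spans(as.data.frame(candidates))
  mh <- span_mh(candidates, tab)
  ppm <- (precursor_mz - mh) / mh * 1e6
  keep <- which(abs(ppm) <= precursor_tol_ppm)
  if (!length(keep)) {
    class(empty) <- c("msms_matches", "data.frame")
    return(empty)
  }
  rows <- lapply(keep, function(i) {
    b <- b_series(candidates$sequence[i], candidates$mod_positions[i],
                  candidates$mod_delta_mono[i], tab)
    y <- y_series(candidates$sequence[i], candidates$mod_positions[i],
                  candidates$mod_delta_mono[i], tab)
    theo <- c(b$mz, y$mz)
    hits <- .match_fragments(theo, pl$peaks$mz, frag_tol_da)
    nb <- sum(hits <= nrow(b))
    ny <- length(hits) - nb
    data.frame(parent_id = candidates$parent_id[i],
               sequence = candidates$sequence[i],
               start = candidates$start[i], end = candidates$end[i],
               precursor_ppm = ppm[i], b_matched = nb, y_matched = ny,
               n_theoretical = length(theo),
               score = if (length(theo)) length(hits) / length(theo) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, abs(out$precursor_ppm), out$sequence), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("msms_matches", "data.frame")
  out
}

# global Needleman-Wunsch via Biostrings: match +1, mismatch 0,
# gap open 10, gap extend 0.5, end gaps penalised
.global_alignment <- function(seq_a, seq_b) {
  letters <- sort(unique(c(strsplit(seq_a, "")[[1]], strsplit(seq_b, "")[[1]])))
  mat <- matrix(0, length(letters), length(letters),
                dimnames = list(letters, letters))
  diag(mat) <- 1
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "global", substitutionMatrix = mat,
    gapOpening = 10, gapExtension = 0.5)
  list(a = as.character(Biostrings::alignedPattern(aln)),
       b = as.character(Biostrings::alignedSubject(aln)))
}

#' Global percent identity between two proteins
#'
#' Needleman-Wunsch global alignment (match +1, mismatch 0, gap open -10,
#' gap extend -0.5, end gaps penalised); identity = identical columns /
#' alignment length * 100 (the EMBOSS convention), rounded to 3 decimals.
#'
#' @param a,b Residue strings, or single-row `protein_records`.
#' @return Percent identity.
#' @export
global_identity <- function(a, b) {
  a <- .as_sequence(a); b <- .as_sequence(b)
  al <- .global_alignment(a, b)
  ca <- strsplit(al$a, "")[[1]]
  cb <- strsplit(al$b, "")[[1]]
  round(sum(ca == cb & ca != "-") / length(ca) * 100, 3)
}

.as_sequence <- function(x) {
  if (is.data.frame(x)) x$sequence[1] else x
}

#' Substitution map between two homologous proteins
#'
#' Aligns the sequences globally and reports every column where both
#' residues are present and differ, with positions in the first protein's
#' ungapped coordinates. Indel columns are counted separately in
#' `attr(, "n_indel_columns")`.
#'
#' @param a,b Residue strings or single-row `protein_records`.
#' @return data.frame with columns `position`, `a`, `b`;
#'   `attr(, "n_substitutions")` and `attr(, "n_indel_columns")`.
#' @export
substitutions <- function(a, b) {
  a <- .as_sequence(a); b <- .as_sequence(b)
  al <- .global_alignment(a, b)
  ca <- strsplit(al$a, "")[[1]]
  cb <- strsplit(al$b, "")[[1]]
  pos_a <- cumsum(ca != "-")
  is_sub <- ca != "-" & cb != "-" & ca != cb
  out <- data.frame(position = pos_a[is_sub], a = ca[is_sub], b = cb[is_sub],
                    stringsAsFactors = FALSE)
  attr(out, "n_substitutions") <- nrow(out)
  attr(out, "n_indel_columns") <- sum(ca == "-" | cb == "-")
  out
}

#' Sequence coverage of a protein by peptide spans
#'
#' Fraction of residue positions covered by at least one span (overlaps
#' counted once), as a percentage. Reporting contexts round to the nearest
#' integer; the exact value is returned here.
#'
#' @param spans A `peptide_spans` data.frame (or any data.frame with
#'   `start`/`end`).
#' @param protein_length Parent length in residues.
#' @return Coverage percentage in \[0, 100\].
#' @export
coverage <- function(spans, protein_length) {
  stopifnot(protein_length >= 1)
  if (!nrow(spans)) return(0)
  if (any(spans$start < 1) || any(spans$end > protein_length) ||
      any(spans$start > spans$end))
    stop("span out of bounds [1, protein_length]", call. = FALSE)
  covered <- logical(protein_length)
  for (i in seq_len(nrow(spans)))
    covered[spans$start[i]:spans$end[i]] <- TRUE
  sum(covered) / protein_length * 100
}

#' Isoform discrimination report
#'
#' Digests both proteins and reports the peptides of each that are absent
#' (by sequence) from the other's digest, annotated with the substitutions
#' they span, plus global identity, the substitution count and, when
#' matched spans are supplied, per-isoform coverage.
#'
#' @param a,b Single-row `protein_records` (accession + sequence).
#' @param max_missed Missed cleavages for the digests.
#' @param matched_spans_a,matched_spans_b Optional `peptide_spans`
#'   actually observed for each protein, used for the coverage fields.
#' @return An object of class `isoform_report`: list with
#'   `discriminating_a`, `discriminating_b` (peptide_spans with an
#'   `n_substitutions_spanned` column), `substitutions`,
#'   `n_substitutions`, `identity_pct`, `coverage_a_pct`,
#'   `coverage_b_pct`.
#' @export
discriminating_peptides <- function(a, b, max_missed = 2,
                                    matched_spans_a = NULL,
                                    matched_spans_b = NULL) {
  seq_a <- .as_sequence(a); seq_b <- .as_sequence(b)
  acc_a <- if (is.data.frame(a)) a$accession[1] else "A"
  acc_b <- if (is.data.frame(b)) b$accession[1] else "B"
  dig_a <- digest_trypsin(seq_a, max_missed, acc_a)
  dig_b <- digest_trypsin(seq_b, max_missed, acc_b)
  subs <- substitutions(seq_a, seq_b)
  disc_a <- dig_a[!dig_a$sequence %in% dig_b$sequence, , drop = FALSE]
  disc_b <- dig_b[!dig_b$sequence %in% dig_a$sequence, , drop = FALSE]
  count_subs <- function(spans, positions) {
    vapply(seq_len(nrow(spans)), function(i)
      sum(positions >= spans$start[i] & positions <= spans$end[i]),
      integer(1))
  }
  # map B-side substitution coordinates for annotating B's peptides
  al <- .global_alignment(seq_a, seq_b)
  cb <- strsplit(al$b, "")[[1]]
  ca <- strsplit(al$a, "")[[1]]
  pos_b <- cumsum(cb != "-")
  sub_pos_b <- pos_b[ca != "-" & cb != "-" & ca != cb]
  if (nrow(disc_a))
    disc_a$n_substitutions_spanned <- count_subs(disc_a, subs$position)
  if (nrow(disc_b))
    disc_b$n_substitutions_spanned <- count_subs(disc_b, sub_pos_b)
  structure(list(
    discriminating_a = disc_a, discriminating_b = disc_b,
    substitutions = subs,
    n_substitutions = attr(subs, "n_substitutions"),
    n_indel_columns = attr(subs, "n_indel_columns"),
    identity_pct = global_identity(seq_a, seq_b),
    coverage_a_pct = if (!is.null(matched_spans_a))
      coverage(matched_spans_a, nchar(seq_a)) else NA_real_,
    coverage_b_pct = if (!is.null(matched_spans_b))
      coverage(matched_spans_b, nchar(seq_b)) else NA_real_,
    accession_a = acc_a, accession_b = acc_b),
    class = "isoform_report")
}

#' @export
print.isoform_report <- function(x, ...) {
  cat(sprintf("<isoform_report> %s vs %s\n", x$accession_a, x$accession_b))
  cat(sprintf("  identity %.3f%%, %d substitutions, %d indel columns\n",
              x$identity_pct, x$n_substitutions, x$n_indel_columns))
  cat(sprintf("  discriminating peptides: %d (%s), %d (%s)\n",
              nrow(x$discriminating_a), x$accession_a,
              nrow(x$discriminating_b), x$accession_b))
  if (!is.na(x$coverage_a_pct))
    cat(sprintf("  coverage: %d%% (%s), %d%% (%s)\n",
                round(x$coverage_a_pct), x$accession_a,
                round(x$coverage_b_pct), x$accession_b))
  invisible(x)
}
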