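# End-to-end orchestration: profile comparison (deconvolution ->
# within-condition averaging -> alignment -> differential report) and
# MS/MS identification (precursor filter -> fragment matching -> isoform
# report), with a JSON config file and a plain-text parameter log.

#' Build a run configuration
#'
#' All tolerances the pipeline applies, in one auditable block. CLI flags
#' override config-file values; every effective value is written to the
#' run log.
#'
#' @param precursor_tol_ppm Precursor tolerance, ppm.
#' @param frag_tol_da Fragment tolerance, Da.
#' @param profile_rel_tol Relative mass tolerance for profile alignment
#'   and charge-family assignment.
#' @param max_missed Missed cleavages for digests.
#' @param max_mod_sites Cap on variable-modification sites per peptide.
#' @param use_phospho Include variable phospho-S/T.
#' @param seed Integer seed for any randomised step.
#' @param out_dir Output directory.
#' @return List of class `run_config`.
#' @export
run_config <- function(precursor_tol_ppm = 10, frag_tol_da = 0.2,
                       profile_rel_tol = 0.001, max_missed = 2,
                       max_mod_sites = 2, use_phospho = TRUE, seed = 1,
                       out_dir = ".") {
  stopifnot(precursor_tol_ppm > 0, frag_tol_da > 0, profile_rel_tol > 0,
            max_missed >= 0, max_mod_sites >= 0)
  structure(list(precursor_tol_ppm = precursor_tol_ppm,
                 frag_tol_da = frag_tol_da,
                 profile_rel_tol = profile_rel_tol,
                 max_missed = max_missed, max_mod_sites = max_mod_sites,
                 use_phospho = isTRUE(use_phospho), seed = seed,
                 out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from a JSON file
#'
#' Unknown keys are rejected; missing keys take the [run_config()]
#' defaults.
#'
#' @param path Path to a JSON object file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  do.call(run_config, vals)
}

.log_lines <- function(path, lines) {
  if (!is.null(path)) cat(lines, file = path, sep = "\n", append = TRUE)
  invisible(NULL)
}

.log_config <- function(log, cfg, extra = character(0)) {
  .log_lines(log, c(
    sprintf("timestamp = %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("precursor_tol_ppm = %g", cfg$precursor_tol_ppm),
    sprintf("frag_tol_da = %g", cfg$frag_tol_da),
    sprintf("profile_rel_tol = %g", cfg$profile_rel_tol),
    sprintf("max_missed = %d", cfg$max_missed),
    sprintf("max_mod_sites = %d", cfg$max_mod_sites),
    sprintf("use_phospho = %s", cfg$use_phospho),
    sprintf("seed = %d", cfg$seed),
    extra))
}

#' Compare two conditions' linear profiles
#'
#' Each profile CSV (or `peak_list`) is deconvolved into components; the
#' replicates of each condition are merged at the profile tolerance; the
#' two merged component sets are aligned and rendered as a differential
#' TSV.
#'
#' @param profiles_a,profiles_b Character vectors of CSV paths, or lists
#'   of `peak_list`s (conditions A and B).
#' @param config A [run_config()].
#' @param report_path Optional TSV output path.
#' @param log_path Optional log file path (parameters + row counts).
#' @return List with `comparison` (a `profile_comparison`), `report`
#'   (the differential data.frame), `components_a`, `components_b`.
#' @export
run_compare <- function(profiles_a, profiles_b, config = run_config(),
                        report_path = NULL, log_path = NULL) {
  load_all <- function(x, tag) {
    if (is.character(x)) {
      missing <- x[!file.exists(x)]
      if (length(missing))
        stop(sprintf("missing %s profile input: %s", tag, missing[1]),
             call. = FALSE)
      lapply(x, read_peaklist, format = "csv", mode = "linear")
    } else if (inherits(x, "peak_list")) list(x) else x
  }
  pls_a <- load_all(profiles_a, "condition-A")
  pls_b <- load_all(profiles_b, "condition-B")
  if (!length(pls_a) || !length(pls_b))
    stop("both conditions need at least one profile", call. = FALSE)
  if (!is.null(log_path)) .log_config(log_path, config,
    c(sprintf("n_profiles_a = %d", length(pls_a)),
      sprintf("n_profiles_b = %d", length(pls_b))))
  dec <- function(pls, label) merge_components(
    lapply(pls, deconvolve_profile, rel_tol = config$profile_rel_tol),
    rel_tol = config$profile_rel_tol, label = label)
  comp_a <- dec(pls_a, "A")
  comp_b <- dec(pls_b, "B")
  cmp <- align_profiles(comp_a, comp_b, rel_tol = config$profile_rel_tol)
  report <- differential_report(cmp, path = report_path)
  .log_lines(log_path, sprintf(
    "components_a = %d ; components_b = %d ; shared = %d ; a_only = %d ; b_only = %d",
    nrow(comp_a), nrow(comp_b), nrow(cmp$shared), nrow(cmp$unique_a),
    nrow(cmp$unique_b)))
  list(comparison = cmp, report = report,
       components_a = comp_a, components_b = comp_b)
}

#' Identify MS/MS spectra against a sequence database
#'
#' For each spectrum in the MGF, candidate tryptic peptides (with variable
#' phospho expansion) are filtered by the precursor tolerance and scored
#' by b/y fragment matching; the top hit per spectrum is tabulated. When
#' `isoform_pair` names two accessions of the database, an isoform report
#' is generated with the matched spans of each.
#'
#' @param mgf_path Path to an MGF file (or a list of `peak_list`s with
#'   `pepmass` attributes).
#' @param fasta_path Path to the FASTA database (or a `protein_records`).
#' @param config A [run_config()].
#' @param isoform_pair Optional character vector of two accessions.
#' @param report_path Optional TSV output path.
#' @param log_path Optional log file path.
#' @return List with `hits` (data.frame: one row per spectrum) and
#'   `isoform_report` (an `isoform_report` or `NULL`).
#' @export
run_identify <- function(mgf_path, fasta_path, config = run_config(),
                         isoform_pair = NULL, report_path = NULL,
                         log_path = NULL) {
  spectra <- if (is.character(mgf_path)) {
    if (!file.exists(mgf_path))
      stop(sprintf("missing MGF input: %s", mgf_path), call. = FALSE)
    read_mgf(mgf_path)
  } else mgf_path
  db <- if (is.character(fasta_path)) {
    if (!file.exists(fasta_path))
      stop(sprintf("missing FASTA input: %s", fasta_path), call. = FALSE)
    read_fasta(fasta_path)
  } else fasta_path
  if (!is.null(log_path)) .log_config(log_path, config,
    c(sprintf("n_spectra = %d", length(spectra)),
      sprintf("n_db_proteins = %d", nrow(db))))
  mods <- if (config$use_phospho) list(phospho_st()) else list()
  all_spans <- do.call(rbind, lapply(seq_len(nrow(db)), function(p)
    .theoretical_peptides(db$sequence[p], db$accession[p],
                          config$max_missed, mods, config$max_mod_sites)))
  hits <- list()
  by_protein <- list()
  for (i in seq_along(spectra)) {
    pl <- spectra[[i]]
    pm <- attr(pl, "pepmass")
    if (is.null(pm) || is.na(pm)) {
      warning(sprintf("spectrum %d has no PEPMASS; skipped", i),
              call. = FALSE)
      next
    }
    ranked <- msms_match(pl, all_spans, pm,
                         frag_tol_da = config$frag_tol_da,
                         precursor_tol_ppm = config$precursor_tol_ppm)
    if (!nrow(ranked)) next
    top <- ranked[1, ]
    top$spectrum <- if (!is.null(attr(pl, "title")) &&
                        nzchar(attr(pl, "title"))) attr(pl, "title")
                    else sprintf("spectrum_%d", i)
    top$precursor_mz <- pm
    hits[[length(hits) + 1L]] <- top
    by_protein[[top$parent_id]] <- rbind(
      by_protein[[top$parent_id]],
      top[, c("start", "end"), drop = FALSE])
  }
  hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(spectrum = character(0), parent_id = character(0),
               sequence = character(0), precursor_mz = numeric(0),
               precursor_ppm = numeric(0), score = numeric(0))
  if (!length(hits) || !nrow(hits))
    warning("no spectrum produced a match within tolerance", call. = FALSE)
  iso <- NULL
  if (!is.null(isoform_pair)) {
    stopifnot(length(isoform_pair) == 2L,
              all(isoform_pair %in% db$accession))
    a <- db[db$accession == isoform_pair[1], ][1, ]
    b <- db[db$accession == isoform_pair[2], ][1, ]
    iso <- discriminating_peptides(
      a, b, max_missed = config$max_missed,
      matched_spans_a = by_protein[[isoform_pair[1]]],
      matched_spans_b = by_protein[[isoform_pair[2]]])
  }
  if (!is.null(report_path))
    utils::write.table(hits, report_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  .log_lines(log_path, sprintf("n_hits = %d", nrow(hits)))
  list(hits = hits, isoform_report = iso)
}
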