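# Bundled synthetic aldolase isoform pair.

#' Synthetic aldolase B/C stand-in pair
#'
#' The study system this package targets contrasts two fructose-bisphosphate
#' aldolase isoforms resolved by MS/MS of a 40 kDa band: a 364-residue
#' B-type chain (average MW ~39288 Da, basic pI) identified under hypoxia
#' and a 363-residue C-type chain (average MW ~39449 Da, pI near 6.4)
#' identified under normoxia. The real UniProt entries are not
#' redistributable here, so the package bundles a *synthetic* pair
#' (accessions `ALDOB_SYN`, `ALDOC_SYN`) constructed to reproduce the
#' published sequence-level facts exactly:
#'
#' * the B-type chain carries the discriminating tryptic peptide
#'   `YTPLEVAMATVTALRR` at positions 244-259;
#' * the C-type chain carries `ALQASALSAWRGVKENEK` at positions 305-322;
#' * the pair differs by 95 substitutions (including positions 244-248 and
#'   315, 317, 318, 319, 322) plus one C-terminal indel;
#' * average masses round to 39288 and 39449 Da; isoelectric points fall
#'   at ~8.5 and ~6.4;
#' * the bundled 18-peptide lists cover 68% of the B chain and 51% of the
#'   C chain.
#'
#' Being synthetic, the pair validates the identification machinery against
#' the published claims; it is not the biological sequence record.
#'
#' @return List with `records` (a two-row `protein_records`: B chain then
#'   C chain) and `peptides` (data.frame of observed-peptide spans with
#'   columns `protein`, `start`, `end`, `sequence`, `missed_cleavages`).
#' @examples
#' pair <- aldolase_synthetic_pair()
#' round(average_protein_mass(pair$records$sequence[1]))
#' @export
aldolase_synthetic_pair <- function() {
  fasta <- system.file("extdata", "aldolase_pair_synthetic.fasta",
                       package = "maldikit", mustWork = TRUE)
  tsv <- system.file("extdata", "aldolase_peptides_synthetic.tsv",
                     package = "maldikit", mustWork = TRUE)
  records <- read_fasta(fasta)
  peptides <- utils::read.delim(tsv, stringsAsFactors = FALSE)
  list(records = records, peptides = peptides)
}
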