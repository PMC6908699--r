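# Beer-Lambert assay arithmetic (pyruvate, LDH), hemodynamic indices and
# the unpaired two-sample t-test used for condition comparison.

#' Spectrophotometric assay configuration
#'
#' Defaults reflect the standard NADH assay at 340 nm: molar extinction
#' coefficient 6220 1/(M cm), 1 cm light path, 3 mL reaction volume.
#'
#' @param epsilon_nadh Molar extinction coefficient of NADH, 1/(M cm).
#' @param path_cm Cuvette light path, cm.
#' @param reaction_volume_ml Reaction mixture volume, mL.
#' @param sample_volume_ul Sample (extract) volume added, uL.
#' @param protein_conc_mg_ml Protein concentration of the extract, mg/mL.
#' @return An object of class `assay_config`.
#' @export
assay_config <- function(epsilon_nadh = 6220, path_cm = 1,
                         reaction_volume_ml = 3, sample_volume_ul = 70,
                         protein_conc_mg_ml = 1) {
  vals <- c(epsilon_nadh, path_cm, reaction_volume_ml, sample_volume_ul,
            protein_conc_mg_ml)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all assay parameters must be positive", call. = FALSE)
  structure(list(epsilon_nadh = epsilon_nadh, path_cm = path_cm,
                 reaction_volume_ml = reaction_volume_ml,
                 sample_volume_ul = sample_volume_ul,
                 protein_conc_mg_ml = protein_conc_mg_ml),
            class = "assay_config")
}

.protein_mass_mg <- function(cfg) {
  mg <- cfg$sample_volume_ul * 1e-3 * cfg$protein_conc_mg_ml
  if (mg <= 0) stop("sample protein mass must be positive", call. = FALSE)
  mg
}

#' Pyruvate concentration from an endpoint NADH assay
#'
#' The absorbance drop `OD1 - OD2` at 340 nm measures NADH consumed by the
#' LDH-coupled reduction of pyruvate: `dOD / (epsilon * l)` gives mol/L in
#' the cuvette, times the reaction volume gives mol pyruvate, divided by
#' the sample protein mass gives umol per mg protein.
#'
#' @param od1,od2 Initial and final absorbance at 340 nm.
#' @param cfg An [assay_config()].
#' @return Pyruvate in umol per mg protein.
#' @examples
#' pyruvate_conc(0.5, 0.4378, assay_config(sample_volume_ul = 70))
#' @export
pyruvate_conc <- function(od1, od2, cfg = assay_config()) {
  stopifnot(inherits(cfg, "assay_config"))
  d_od <- od1 - od2
  if (any(d_od < 0))
    warning("OD2 > OD1: negative absorbance drop", call. = FALSE)
  mol <- d_od / (cfg$epsilon_nadh * cfg$path_cm) *
    (cfg$reaction_volume_ml / 1000)
  (mol * 1e6) / .protein_mass_mg(cfg)
}

#' Lactate dehydrogenase activity from an NADH oxidation slope
#'
#' `slope / (epsilon * l)` converts the rate of absorbance decrease at
#' 340 nm to mol NADH oxidised per litre per minute; times the reaction
#' volume gives umol/min = international units (UI, 1 umol NADH/min at
#' 25 degrees C); divided by the sample protein mass gives UI/mg.
#'
#' @param slope_per_min Magnitude of the A340 decrease per minute (>= 0).
#' @param cfg An [assay_config()] (LDH protocol: 2 uL sample).
#' @return LDH activity in UI per mg protein.
#' @export
ldh_activity <- function(slope_per_min, cfg = assay_config(sample_volume_ul = 2)) {
  stopifnot(inherits(cfg, "assay_config"))
  if (any(slope_per_min < 0))
    stop("slope must be the magnitude of the decrease (>= 0)", call. = FALSE)
  ui <- slope_per_min / (cfg$epsilon_nadh * cfg$path_cm) *
    (cfg$reaction_volume_ml / 1000) * 1e6
  ui / .protein_mass_mg(cfg)
}

#' Hemodynamic indices of the perfused working heart
#'
#' Stroke volume `SV = CO / HR` (mL/kg) and stroke work
#' `SW = (afterload - preload) * SV / ventricle_mass` (mJ/g, with
#' pressures in kPa).
#'
#' @param co Cardiac output, mL/min/kg body mass.
#' @param hr Heart rate, beats/min (> 0).
#' @param afterload,preload Pressures, kPa.
#' @param ventricle_mass Ventricle mass, g (> 0).
#' @return List with `sv` (mL/kg) and `sw` (mJ/g).
#' @export
hemodynamic_indices <- function(co, hr, afterload, preload, ventricle_mass) {
  if (hr <= 0) stop("heart rate must be positive", call. = FALSE)
  if (ventricle_mass <= 0)
    stop("ventricle mass must be positive", call. = FALSE)
  sv <- co / hr
  list(sv = sv, sw = (afterload - preload) * sv / ventricle_mass)
}

#' Unpaired two-sample Student's t-test
#'
#' Pooled-variance (equal variance) t statistic with two-sided p-value,
#' the classical test for comparing condition means of small replicate
#' groups.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @param alpha Significance level (default 0.05).
#' @return List with `t`, `df`, `p`, `significant`.
#' @export
unpaired_t <- function(group_a, group_b, alpha = 0.05) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2 || nb < 2)
    stop("each group needs at least 2 observations", call. = FALSE)
  ma <- mean(group_a); mb <- mean(group_b)
  sp2 <- ((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) /
    (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  t <- if (se == 0) 0 else (ma - mb) / se
  df <- na + nb - 2
  p <- if (se == 0) 1 else 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p, significant = p < alpha)
}

#' Summarise assay replicates as mean +/- SEM
#'
#' @param values Numeric vector of replicate results.
#' @return List with `mean`, `sem`, `n`.
#' @export
assay_summary <- function(values) {
  n <- length(values)
  list(mean = mean(values),
       sem = if (n > 1) stats::sd(values) / sqrt(n) else 0,
       n = n)
}
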