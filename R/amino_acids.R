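# Compound-specific 15N stable-isotope probing of the total hydrolysable
# amino-acid (THAA) pool: internal-standard quantification, sand-recovery
# correction, per-AA and pool enrichment, incorporation percentages, and
# the GC-C-IRMS run-acceptance gate.

#' Amino-acid reference table
#'
#' Free amino acids resolved in soil hydrolysates (NAIP derivatives), with
#' molar mass (g/mol) and N atoms per molecule of the free analyte. Asx and
#' Glx denote the combined Asp+Asn and Glu+Gln pools (the amides are
#' deamidated during acid hydrolysis) and carry the acid's single N; Lys has
#' two. Norleucine (Nle) is flagged as the internal quantification standard
#' and is excluded from THAA aggregates. The acetyl N added during
#' derivatisation carries no tracer and is not counted.
#'
#' @return A data frame with columns `code`, `name`, `molar_mass`,
#'   `n_atoms`, `internal_standard`.
#' @export
aa_reference <- function() {
  df <- data.frame(
    code = c("Ala", "Gly", "Val", "Leu", "Ile", "Pro", "Hyp", "Ser", "Thr",
             "Asx", "Glx", "Phe", "Tyr", "Lys", "Met", "Nle"),
    name = c("alanine", "glycine", "valine", "leucine", "isoleucine",
             "proline", "hydroxyproline", "serine", "threonine",
             "aspartate+asparagine", "glutamate+glutamine", "phenylalanine",
             "tyrosine", "lysine", "methionine", "norleucine"),
    molar_mass = c(89.09, 75.07, 117.15, 131.17, 131.17, 115.13, 131.13,
                   105.09, 119.12, 133.10, 147.13, 165.19, 181.19, 146.19,
                   149.21, 131.17),
    n_atoms = c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 2L, 1L, 1L),
    stringsAsFactors = FALSE
  )
  df$internal_standard <- df$code == "Nle"
  df
}

#' Quantify an amino acid against the internal standard
#'
#' concentration = (area_aa / area_istd) * istd_mass * response_factor /
#' sample_mass. With a response factor of 1 this is the plain
#' internal-standard ratio method; a calibration table of per-analyte
#' response factors can be supplied where available.
#'
#' @param area_aa,area_istd Integrated peak areas of the analyte and of the
#'   internal standard (area_istd > 0).
#' @param istd_mass Mass of internal standard added (e.g. mg).
#' @param response_factor Relative response factor (default 1).
#' @param sample_mass Sample mass the concentration is expressed per (g).
#' @return Concentration in units of `istd_mass` per unit `sample_mass`.
#' @export
quantify_aa <- function(area_aa, area_istd, istd_mass, response_factor = 1,
                        sample_mass = 1) {
  stopifnot(is.numeric(area_aa), is.numeric(area_istd))
  if (any(!is.finite(area_istd) | area_istd <= 0))
    stop("failed run: internal-standard peak area must be positive", call. = FALSE)
  if (any(sample_mass <= 0)) stop("sample_mass must be positive", call. = FALSE)
  if (any(area_aa < 0)) stop("peak areas must be >= 0", call. = FALSE)
  (area_aa / area_istd) * istd_mass * response_factor / sample_mass
}

#' Correct a measured mass for analyte recovery
#'
#' Divides the measured mass by the recovery fraction determined from
#' standards (e.g. amino-acid standards leached through sand). Recoveries
#' above 1 are permitted (over-recovery) but flagged with a warning.
#'
#' @param measured Measured mass(es).
#' @param recovery Recovery fraction(s) in (0, 1.5]; recycled.
#' @return Recovery-corrected mass(es).
#' @export
correct_recovery <- function(measured, recovery) {
  stopifnot(is.numeric(measured), is.numeric(recovery))
  if (any(!is.finite(recovery) | recovery <= 0))
    stop("invalid recovery: fractions must be positive", call. = FALSE)
  if (any(recovery > 1))
    warning("recovery > 1 (over-recovery); corrected mass is below measured",
            call. = FALSE)
  measured / recovery
}

#' Excess 15N in the THAA pool from per-AA concentrations and delta15N
#'
#' For each amino acid, the moles of analyte N are
#' n_N = concentration * mass_basis / molar_mass * n_atoms, the
#' atom-fraction excess is AFE(delta_sample, delta_control), and the excess
#' 15N is E = n_N * AFE. The pool value is the sum over amino acids,
#' excluding the internal standard; the per-AA values are retained for
#' incorporation profiles.
#'
#' @param measurements Data frame with columns `aa_code`,
#'   `concentration_mg_per_g` and `delta15n_permil` (one row per AA).
#' @param control_deltas Named numeric vector of control (unlabelled)
#'   delta15N per AA code; AAs not named fall back to `default_control`.
#' @param mass_basis_g Mass of material the concentrations refer to
#'   (g; e.g. the soil mass of the compartment).
#' @param default_control Fallback control delta15N (per mil); 0 is natural
#'   abundance on the Air scale.
#' @param constants An [isotope_constants()] object.
#' @return A list of class `thaa_enrichment` with `e_mol` (total moles of
#'   excess 15N in the THAA pool), `n_n_mol` (total analyte N, moles),
#'   `tn_g` (total analyte N, g, using 14.007 g/mol), and `per_aa` (data
#'   frame with per-AA `n_n_mol`, `afe` and `e_mol`).
#' @export
thaa_enrichment <- function(measurements, control_deltas = NULL,
                            mass_basis_g = 1, default_control = 0,
                            constants = isotope_constants()) {
  req <- c("aa_code", "concentration_mg_per_g", "delta15n_permil")
  miss <- setdiff(req, names(measurements))
  if (length(miss))
    stop("measurements lack column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  ref <- aa_reference()
  unknown <- setdiff(unique(measurements$aa_code), ref$code)
  if (length(unknown))
    stop("unknown analyte code(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  m <- measurements[!measurements$aa_code %in% ref$code[ref$internal_standard], ,
                    drop = FALSE]
  idx <- match(m$aa_code, ref$code)
  ctrl <- rep(default_control, nrow(m))
  if (!is.null(control_deltas)) {
    hit <- match(m$aa_code, names(control_deltas))
    ctrl[!is.na(hit)] <- control_deltas[hit[!is.na(hit)]]
  }
  n_n <- m$concentration_mg_per_g * 1e-3 * mass_basis_g /
    ref$molar_mass[idx] * ref$n_atoms[idx]
  afe <- atom_fraction_excess(
    delta_to_atom_fraction(m$delta15n_permil, constants),
    delta_to_atom_fraction(ctrl, constants)
  )
  e <- n_n * afe
  per_aa <- data.frame(aa_code = m$aa_code, n_n_mol = n_n, afe = afe,
                       e_mol = e, stringsAsFactors = FALSE)
  structure(list(e_mol = sum(e), n_n_mol = sum(n_n), tn_g = sum(n_n) * 14.007,
                 per_aa = per_aa),
            class = "thaa_enrichment")
}

#' Percent of a 15N reference incorporated into the THAA pool
#'
#' With the applied dose as reference this is the percent of applied 15N
#' assimilated into soil amino acids (all pathways combined); with the bulk
#' soil enrichment as reference it is the percent of soil-retained 15N the
#' microbial community has built into protein.
#'
#' @param e_thaa A `thaa_enrichment` object (or moles of excess 15N).
#' @param reference An `applied_dose` object, a number (moles of excess
#'   15N), or a data frame row from [enrichment_moles()].
#' @return Percent incorporation.
#' @export
percent_incorporation <- function(e_thaa, reference) {
  e <- if (inherits(e_thaa, "thaa_enrichment")) e_thaa$e_mol else e_thaa
  ref <- if (inherits(reference, "applied_dose")) reference$e_a_mol
         else if (is.data.frame(reference)) sum(reference$e)
         else reference
  if (!is.numeric(ref) || length(ref) != 1L || !is.finite(ref) || ref <= 0)
    stop("division by zero: reference excess 15N must be positive", call. = FALSE)
  100 * e / ref
}

#' Nitrogen transfer into the soil protein (THAA) pool
#'
#' Same ratio calculation as plant transfer, with the THAA pool as the
#' receiver: P = 15N_THAA / (15N_THAA + 15N_D + 15N_S),
#' N_transfer = P * TN_D, Ndft = 100 * N_transfer / TN_THAA.
#'
#' @param n15_thaa Excess-15N content of the THAA pool.
#' @param n15_donor,n15_soil Excess-15N contents of the donor reference pool
#'   and bulk soil (same units as `n15_thaa`).
#' @param tn_donor Total N of the donor reference pool.
#' @param tn_thaa Total N of the THAA pool (> 0), same units as `tn_donor`.
#' @return A `transfer_result` list (see [transfer_result()]).
#' @export
aa_ndft <- function(n15_thaa, n15_donor, n15_soil, tn_donor, tn_thaa) {
  transfer_result(n15_thaa, n15_donor, n15_soil, tn_donor, tn_thaa)
}

#' GC-C-IRMS run acceptance gate
#'
#' A run of the in-house amino-acid standard mixture is accepted when at
#' least 75% of the standards deviate from their known delta15N by at most
#' 1.0 permil and every remaining standard deviates by at most 1.5 permil.
#'
#' @param deviations Numeric vector of measured-minus-known delta15N
#'   deviations (per mil), one per standard; must be non-empty.
#' @param frac_within Required fraction within the tight tolerance (0.75).
#' @param tol_tight,tol_max Tight and maximum tolerances in per mil.
#' @return TRUE (accept) or FALSE (reject).
#' @examples
#' qc_gate(c(rep(0.5, 16), rep(1.4, 4)))  # accept
#' qc_gate(c(rep(0, 19), 1.6))            # reject
#' @export
qc_gate <- function(deviations, frac_within = 0.75, tol_tight = 1.0, tol_max = 1.5) {
  if (!is.numeric(deviations) || length(deviations) == 0L || any(!is.finite(deviations)))
    stop("invalid QC run: need a non-empty numeric vector of deviations", call. = FALSE)
  dev <- abs(deviations)
  mean(dev <= tol_tight) >= frac_within && max(dev) <= tol_max
}
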