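#' n15trace: split-root 15N tracer mass balance and nitrogen transfer
#'
#' Tools for analysing split-root 15N-labelling experiments in mixed
#' legume-grass systems: isotope scale conversions, pool mass balance and
#' percent retention of an applied label, plant-to-plant and
#' plant-to-soil-protein nitrogen transfer, compound-specific amino-acid
#' stable-isotope probing, treatment statistics, and a synthetic-experiment
#' generator with known ground truth.
#'
#' @keywords internal
#' @importFrom stats aov anova t.test shapiro.test sd rnorm rlnorm rgamma
#'   pf setNames aggregate complete.cases
#' @importFrom utils read.csv write.csv
"_PACKAGE"

#' 15N/14N isotope ratio of atmospheric N2 (Air), the international standard
#'
#' @format A single numeric value, 0.0036765 (dimensionless ratio).
#' @export
R_STD_AIR <- 0.0036765

#' Isotope constants for the 15N system
#'
#' Bundles the standard ratio and the natural-abundance atom fraction derived
#' from it. Used as the default reference everywhere a conversion between the
#' delta scale and the atom-fraction scale is needed.
#'
#' @param r_std 15N/14N ratio of the standard (Air). Must be positive.
#' @return A list of class `isotope_constants` with elements `r_std` and
#'   `natural_atom_fraction` (= r_std / (1 + r_std)).
#' @examples
#' isotope_constants()$natural_atom_fraction  # ~0.0036630
#' @export
isotope_constants <- function(r_std = R_STD_AIR) {
  if (!is.numeric(r_std) || length(r_std) != 1L || !is.finite(r_std) || r_std <= 0)
    stop("`r_std` must be a single positive number", call. = FALSE)
  structure(list(r_std = r_std, natural_atom_fraction = r_std / (1 + r_std)),
            class = "isotope_constants")
}

#' Natural-abundance 15N atom fraction of Air
#'
#' @param constants An [isotope_constants()] object.
#' @return The dimensionless natural-abundance atom fraction.
#' @export
natural_atom_fraction <- function(constants = isotope_constants()) {
  constants$natural_atom_fraction
}

#' Convert delta15N (per mil vs. Air) to 15N atom fraction
#'
#' Applies the standard identity AF = R / (1 + R) with
#' R = r_std * (delta/1000 + 1). Delta values at or below -1000 permil are
#' rejected: they would imply a non-positive isotope ratio.
#'
#' @param delta delta15N in per mil vs. Air; vectorised.
#' @param constants An [isotope_constants()] object.
#' @return Atom fraction(s) in (0, 1), strictly increasing in `delta`.
#' @examples
#' delta_to_atom_fraction(0)     # natural abundance, ~0.0036630
#' delta_to_atom_fraction(1000)  # ~0.0072993
#' @export
delta_to_atom_fraction <- function(delta, constants = isotope_constants()) {
  stopifnot(is.numeric(delta))
  if (any(!is.finite(delta)) || any(delta <= -1000))
    stop("invalid delta15N: values must be finite and > -1000 permil", call. = FALSE)
  r <- constants$r_std * (delta / 1000 + 1)
  r / (1 + r)
}

#' Convert 15N atom fraction to delta15N (per mil vs. Air)
#'
#' Exact inverse of [delta_to_atom_fraction()]. Highly enriched material
#' (e.g. a 98 atom% label) maps to delta values far above 1e6 permil, which
#' is why enriched bulk pools are carried on the atom% scale instead.
#'
#' @param af Atom fraction(s), strictly inside (0, 1); vectorised.
#' @param constants An [isotope_constants()] object.
#' @return delta15N in per mil vs. Air.
#' @examples
#' atom_fraction_to_delta(natural_atom_fraction())  # 0
#' @export
atom_fraction_to_delta <- function(af, constants = isotope_constants()) {
  stopifnot(is.numeric(af))
  if (any(!is.finite(af)) || any(af <= 0) || any(af >= 1))
    stop("invalid atom fraction: values must lie strictly inside (0, 1)", call. = FALSE)
  r <- af / (1 - af)
  1000 * (r / constants$r_std - 1)
}

#' Atom-fraction excess (the tracer signal)
#'
#' AFE = AF_sample - AF_control. Negative values can arise from observation
#' noise on near-natural-abundance material and are retained here; they are
#' clamped to zero only in final reported percentages (see
#' [percent_retention()] consumers).
#'
#' @param sample,control Atom fractions in (0, 1); vectorised, recycled.
#' @return Atom-fraction excess (dimensionless, may be negative).
#' @export
atom_fraction_excess <- function(sample, control) {
  stopifnot(is.numeric(sample), is.numeric(control))
  if (any(sample <= 0) || any(sample >= 1) || any(control <= 0) || any(control >= 1))
    stop("atom fractions must lie strictly inside (0, 1)", call. = FALSE)
  sample - control
}

#' Moles of excess 15N in a pool
#'
#' E = n_N * AFE: the number of moles of 15N in a pool derived from the
#' applied substrate, given the pool's total N in moles and its
#' atom-fraction excess.
#'
#' @param n_n Moles of total N in the pool (>= 0); vectorised.
#' @param afe Atom-fraction excess; vectorised.
#' @return A data frame with columns `n_n`, `afe`, `e` (moles excess 15N).
#' @export
enrichment_moles <- function(n_n, afe) {
  stopifnot(is.numeric(n_n), is.numeric(afe))
  if (any(!is.finite(n_n)) || any(n_n < 0))
    stop("invalid pool: n_n must be finite and >= 0", call. = FALSE)
  data.frame(n_n = n_n, afe = afe, e = n_n * afe)
}

#' Moles of excess 15N applied with a labelled dose
#'
#' E_A = volume x molarity x n_atoms x (label_af - natural abundance): the
#' moles of 15N applied above natural abundance. For the canonical 1 mL of
#' 30 mM 98 atom% 15N-urea (2 N per molecule) this is ~58.58 umol.
#'
#' @param volume_l Dose volume in litres.
#' @param molarity_mol_l Substrate molarity in mol/L.
#' @param n_atoms N atoms per substrate molecule (2 for urea).
#' @param label_af Atom fraction of the label (0.98 for 98 atom%).
#' @param constants An [isotope_constants()] object.
#' @return A list of class `applied_dose` with the inputs and `e_a_mol`,
#'   the moles of excess 15N applied.
#' @examples
#' applied_excess_moles(1e-3, 0.030, 2, 0.98)$e_a_mol * 1e6  # ~58.58 umol
#' @export
applied_excess_moles <- function(volume_l, molarity_mol_l, n_atoms, label_af,
                                 constants = isotope_constants()) {
  vals <- c(volume_l, molarity_mol_l, n_atoms, label_af)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("invalid dose: volume, molarity, n_atoms and label_af must all be positive",
         call. = FALSE)
  if (label_af >= 1) stop("invalid dose: label_af must be < 1", call. = FALSE)
  if (label_af < constants$natural_atom_fraction)
    stop("invalid dose: label_af below natural abundance", call. = FALSE)
  e_a <- volume_l * molarity_mol_l * n_atoms *
    (label_af - constants$natural_atom_fraction)
  structure(list(volume_l = volume_l, molarity_mol_l = molarity_mol_l,
                 n_atoms = n_atoms, label_af = label_af, e_a_mol = e_a),
            class = "applied_dose")
}

#' Percent retention of the applied label in a pool
#'
#' 100 * E / E_A: the share of the applied excess 15N recovered in a pool.
#' Additive over disjoint pools of a conserved label.
#'
#' @param e Moles of excess 15N in the pool (or a data frame from
#'   [enrichment_moles()], whose `e` column is used).
#' @param dose An `applied_dose` object from [applied_excess_moles()], or the
#'   moles of excess 15N applied as a plain number.
#' @param clamp If TRUE (default), negative retentions (possible on noisy
#'   near-natural-abundance pools) are clamped to 0 with a warning; raw
#'   values are preserved when FALSE.
#' @return Percent retention (vectorised over `e`).
#' @export
percent_retention <- function(e, dose, clamp = TRUE) {
  if (is.data.frame(e)) e <- e$e
  e_a <- if (inherits(dose, "applied_dose")) dose$e_a_mol else dose
  if (!is.numeric(e_a) || length(e_a) != 1L || !is.finite(e_a) || e_a <= 0)
    stop("division by zero: dose excess 15N must be positive", call. = FALSE)
  out <- 100 * e / e_a
  if (clamp && any(out < 0, na.rm = TRUE)) {
    warning("negative retention clamped to 0 (observation noise below natural abundance)",
            call. = FALSE)
    out[out < 0] <- 0
  }
  out
}

#' Mass of excess 15N in a pool from atom% excess and total N
#'
#' 15N_X = (atom% 15N excess / 100) * TN_X. Units follow `tn` (e.g. mg N in,
#' mg excess 15N out). This is the mass-based pool content entering the
#' transfer calculation; since it is proportional to the molar excess, the
#' ratio-based transfer proportions are identical on either basis.
#'
#' @param atom_pct_excess Atom percent 15N excess of the pool; vectorised.
#' @param tn Total nitrogen content of the pool (mass, >= 0); vectorised.
#' @return Mass of excess 15N, in the units of `tn`.
#' @export
pool_15N_content <- function(atom_pct_excess, tn) {
  stopifnot(is.numeric(atom_pct_excess), is.numeric(tn))
  if (any(!is.finite(tn)) || any(tn < 0))
    stop("invalid pool: tn must be finite and >= 0", call. = FALSE)
  (atom_pct_excess / 100) * tn
}
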