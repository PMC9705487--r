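# Shipped ground-truth presets, one per treatment of the split-root design.
# Allocations, biomass and %TN are shaped on the published treatment-level
# magnitudes of the clover-ryegrass study the package targets (documented
# as presets, not as claims about the original raw data): dose 1 mL of
# 30 mM 98 atom% 15N-urea, n = 4, soil 15 g at 0.57% TN, clover shoots
# 4.5% N, clover roots 3.0% N, grass 2.0% N.

#' Ground-truth preset for a named treatment
#'
#' Returns an [experiment_truth()] for one of the study's treatments:
#' `"urea"` (label only), `"decomposition"` (labelled shoot residue
#' incorporated; donor reference is the shoots), `"exudation"` (labelled
#' root exudates watered in), `"defoliation"`, `"sterile"`, `"fungi"`,
#' `"weevil"`, and the three-compartment directions `"clover_to_grass"`
#' and `"grass_to_clover"`.
#'
#' @param treatment Preset name.
#' @param noise A [noise_spec()]; use [zero_noise()] for conservation
#'   checks.
#' @param n_reps Replicates (default 4).
#' @return An `experiment_truth`.
#' @export
treatment_truth <- function(treatment = c("urea", "decomposition", "exudation",
                                          "defoliation", "sterile", "fungi",
                                          "weevil", "clover_to_grass",
                                          "grass_to_clover"),
                            noise = noise_spec(), n_reps = 4L) {
  treatment <- match.arg(treatment)
  soil <- c(soil_trac = 15000)
  soil_tn <- c(soil_trac = 0.57)
  two <- function(alloc, biomass, tn, donor_reference = "donor_roots_trac",
                  thaa_frac = 0.08)
    experiment_truth(treatment, alloc,
                     biomass_mg = c(biomass, soil),
                     tn_percent = c(tn, soil_tn),
                     donor_reference = donor_reference,
                     thaa_15n_fraction = thaa_frac,
                     noise = noise, n_reps = n_reps, layout = "two")
  switch(treatment,
    urea = two(
      c(donor_shoots = 0.37, donor_roots_trac = 0.018, soil_trac = 0.0069,
        receiver_roots_trac = 0.0034, receiver_shoots = 0.0014),
      c(donor_shoots = 228, donor_roots_trac = 111,
        receiver_roots_trac = 435, receiver_shoots = 380),
      c(donor_shoots = 4.5, donor_roots_trac = 3.0,
        receiver_roots_trac = 2.0, receiver_shoots = 2.0),
      thaa_frac = 0.10),
    decomposition = two(
      c(donor_shoots = 0.40, donor_roots_trac = 0.0033, soil_trac = 0.068,
        receiver_roots_trac = 0.019, receiver_shoots = 0.040),
      c(donor_shoots = 245, donor_roots_trac = 100,
        receiver_roots_trac = 252, receiver_shoots = 457),
      c(donor_shoots = 4.8, donor_roots_trac = 3.0,
        receiver_roots_trac = 2.0, receiver_shoots = 2.0),
      donor_reference = "donor_shoots", thaa_frac = 0.18),
    exudation = two(
      c(donor_shoots = 0.29, donor_roots_trac = 0.012, soil_trac = 0.0040,
        receiver_roots_trac = 0.0005, receiver_shoots = 0.0009),
      c(donor_shoots = 200, donor_roots_trac = 100,
        receiver_roots_trac = 446, receiver_shoots = 515),
      c(donor_shoots = 4.5, donor_roots_trac = 3.0,
        receiver_roots_trac = 2.0, receiver_shoots = 2.0)),
    defoliation = two(
      c(donor_shoots = 0.23, donor_roots_trac = 0.0057, soil_trac = 0.0067,
        receiver_roots_trac = 0.0016, receiver_shoots = 0.0008),
      c(donor_shoots = 150, donor_roots_trac = 67.4,
        receiver_roots_trac = 265, receiver_shoots = 428),
      c(donor_shoots = 4.5, donor_roots_trac = 3.0,
        receiver_roots_trac = 2.0, receiver_shoots = 2.0)),
    sterile = two(
      c(donor_shoots = 0.24, donor_roots_trac = 0.0047, soil_trac = 0.0053,
        receiver_roots_trac = 0.0036, receiver_shoots = 0.0038),
      c(donor_shoots = 220, donor_roots_trac = 56,
        receiver_roots_trac = 346, receiver_shoots = 470),
      c(donor_shoots = 4.5, donor_roots_trac = 3.0,
        receiver_roots_trac = 2.0, receiver_shoots = 2.0)),
    fungi = two(
      c(donor_shoots = 0.22, donor_roots_trac = 0.0084, soil_trac = 0.0039,
        receiver_roots_trac = 0.0009, receiver_shoots = 0.0017),
      c(donor_shoots = 291, donor_roots_trac = 118,
        receiver_roots_trac = 163, receiver_shoots = 420),
      c(donor_shoots = 4.5, donor_roots_trac = 3.0,
        receiver_roots_trac = 2.0, receiver_shoots = 2.0)),
    weevil = two(
      c(donor_shoots = 0.25, donor_roots_trac = 0.029, soil_trac = 0.0051,
        receiver_roots_trac = 0.0028, receiver_shoots = 0.0007),
      c(donor_shoots = 284, donor_roots_trac = 72,
        receiver_roots_trac = 188, receiver_shoots = 320),
      c(donor_shoots = 4.5, donor_roots_trac = 3.0,
        receiver_roots_trac = 2.0, receiver_shoots = 2.0)),
    clover_to_grass = experiment_truth(
      treatment,
      c(donor_roots_labc = 0.18, donor_shoots = 0.23,
        donor_roots_trac = 0.0072, soil_trac = 0.0031,
        receiver_roots_trac = 4e-05, receiver_shoots = 4e-05,
        receiver_roots_rec = 2e-05, soil_rec = 0),
      biomass_mg = c(donor_roots_labc = 39, donor_shoots = 190,
                     donor_roots_trac = 38, receiver_roots_trac = 19,
                     receiver_shoots = 317, receiver_roots_rec = 40,
                     soil_trac = 15000, soil_rec = 15000),
      tn_percent = c(donor_roots_labc = 3.0, donor_shoots = 4.5,
                     donor_roots_trac = 3.0, receiver_roots_trac = 2.0,
                     receiver_shoots = 2.0, receiver_roots_rec = 2.0,
                     soil_trac = 0.57, soil_rec = 0.57),
      thaa_15n_fraction = 0.10, noise = noise, n_reps = n_reps,
      layout = "three", detection_limit_atom_pct_excess = 1e-4),
    grass_to_clover = experiment_truth(
      treatment,
      c(donor_roots_labc = 0.040, donor_shoots = 0.67,
        donor_roots_trac = 0.016, soil_trac = 0.0052,
        receiver_roots_trac = 0.0052, receiver_shoots = 2e-04,
        receiver_roots_rec = 5e-05, soil_rec = 0.0021),
      biomass_mg = c(donor_roots_labc = 17, donor_shoots = 289,
                     donor_roots_trac = 58, receiver_roots_trac = 15,
                     receiver_shoots = 114, receiver_roots_rec = 16,
                     soil_trac = 15000, soil_rec = 15000),
      tn_percent = c(donor_roots_labc = 2.0, donor_shoots = 2.0,
                     donor_roots_trac = 2.0, receiver_roots_trac = 3.0,
                     receiver_shoots = 4.5, receiver_roots_rec = 3.0,
                     soil_trac = 0.57, soil_rec = 0.57),
      thaa_15n_fraction = 0.10, noise = noise, n_reps = n_reps,
      layout = "three")
  )
}
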