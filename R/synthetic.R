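# Synthetic split-root labelling experiments with known ground truth.
# The generator allocates the applied excess 15N across plant and soil
# pools, converts to per-pool bulk atom% 15N through each pool's total N,
# pushes a configured share of the soil 15N into per-amino-acid delta15N
# values by biosynthetic incorporation weights, and adds observation noise
# on the scales the instruments report (atom% for bulk pools, per mil for
# amino acids).

MEASURED_POOLS <- list(
  two = data.frame(
    key = c("donor_shoots", "donor_roots_trac", "soil_trac",
            "receiver_roots_trac", "receiver_shoots"),
    pool = c("donor_shoots", "donor_roots", "soil", "receiver_roots",
             "receiver_shoots"),
    compartment = c("T_ra_C", "T_ra_C", "T_ra_C", "T_ra_C", "T_ra_C"),
    stringsAsFactors = FALSE),
  three = data.frame(
    key = c("donor_roots_labc", "donor_shoots", "donor_roots_trac",
            "soil_trac", "receiver_roots_trac", "receiver_shoots",
            "receiver_roots_rec", "soil_rec"),
    pool = c("donor_roots", "donor_shoots", "donor_roots", "soil",
             "receiver_roots", "receiver_shoots", "receiver_roots", "soil"),
    compartment = c("L_ab_C", "T_ra_C", "T_ra_C", "T_ra_C", "T_ra_C",
                    "T_ra_C", "R_ec_C", "R_ec_C"),
    stringsAsFactors = FALSE)
)

#' Noise specification for the synthetic generator
#'
#' Between-replicate variability is decomposed into three biological terms
#' and two observation terms: a common label-uptake multiplier shared by all
#' pools of a replicate (lognormal, `uptake_cv`) — the ratio-based transfer
#' calculation cancels it by construction; per-pool biomass variation
#' (lognormal, `biomass_cv`, named by pool key or scalar) which the
#' measured pool N tracks, so the yield-dependent transfer calculation
#' absorbs it too; residual per-pool enrichment jitter (`enrichment_cv`);
#' and Gaussian observation noise on the atom% scale (`sd_atom_pct`, named
#' by pool key or scalar) and the per-mil scale (`sd_delta_permil`).
#'
#' @param uptake_cv CV of the common per-replicate label-uptake multiplier.
#' @param biomass_cv CV of per-pool biomass variation (scalar or named by
#'   pool key; soil mass is fixed at 0 unless named).
#' @param enrichment_cv CV of residual per-pool allocation jitter.
#' @param sd_atom_pct SD of bulk atom% observation noise (scalar or named).
#' @param sd_delta_permil SD of AA delta15N observation noise (per mil).
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(uptake_cv = 0.15, biomass_cv = c(shoots = 0.15, roots = 0.30),
                       enrichment_cv = 0.20, sd_atom_pct = 2e-4,
                       sd_delta_permil = 0.5) {
  vals <- c(uptake_cv, biomass_cv, enrichment_cv, sd_atom_pct, sd_delta_permil)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("noise parameters must be finite and >= 0", call. = FALSE)
  structure(list(uptake_cv = uptake_cv, biomass_cv = biomass_cv,
                 enrichment_cv = enrichment_cv, sd_atom_pct = sd_atom_pct,
                 sd_delta_permil = sd_delta_permil),
            class = "noise_spec")
}

#' Zero-noise specification (conservation oracle)
#' @return A `noise_spec` with every component 0.
#' @export
zero_noise <- function() noise_spec(0, 0, 0, 0, 0)

.lookup <- function(x, key, default = 0) {
  if (length(x) == 1L && is.null(names(x))) return(unname(x))
  if (!is.null(names(x))) {
    if (key %in% names(x)) return(unname(x[[key]]))
    # allow coarse keys: "shoots", "roots", "soil"
    for (coarse in names(x)) if (grepl(coarse, key)) return(unname(x[[coarse]]))
  }
  default
}

#' Ground truth for one synthetic treatment
#'
#' Fixes everything the generator needs and everything the recovery tests
#' assert against: the allocation of the applied excess 15N across pools
#' (summing with the unknown pool to 1), per-pool dry biomass and %TN, the
#' THAA share of the soil 15N and of soil N, per-AA incorporation weights,
#' the noise model, and the replication.
#'
#' @param treatment Treatment name.
#' @param allocations Named numeric vector of excess-15N allocation
#'   fractions over the measured pool keys of the layout (see
#'   `MEASURED_POOLS`); the remainder to 1 is the unknown pool. Must sum
#'   with the unknown to 1 within 1e-12 and lie in `[0, 1]`.
#' @param biomass_mg Named numeric vector of dry biomass per pool key (mg;
#'   soil entries are the compartment soil mass).
#' @param tn_percent Named numeric vector of %TN per pool key.
#' @param donor_reference `"donor_roots_trac"` or `"donor_shoots"`: the
#'   pool whose 15N content represents the donor in the transfer ratio.
#' @param thaa_15n_fraction Fraction of the transfer-compartment soil
#'   excess 15N residing in the THAA pool.
#' @param thaa_conc_profile Named numeric vector of per-AA concentrations
#'   (mg per g soil); defaults to a typical soil hydrolysate profile.
#' @param aa_weights Named numeric vector of per-AA incorporation weights
#'   (normalised internally); defaults follow biosynthetic proximity to the
#'   assimilated N (Glx highest; Hyp, Tyr lowest).
#' @param noise A [noise_spec()].
#' @param n_reps Replicates per treatment (>= 2).
#' @param layout `"two"` or `"three"` compartment design.
#' @param dose An `applied_dose` from [applied_excess_moles()].
#' @param detection_limit_atom_pct_excess Atom%-excess below which a
#'   generated bulk value is reported as not detected (0 disables).
#' @return A validated list of class `experiment_truth`.
#' @export
experiment_truth <- function(treatment, allocations, biomass_mg, tn_percent,
                             donor_reference = "donor_roots_trac",
                             thaa_15n_fraction = 0.10,
                             thaa_conc_profile = default_thaa_profile(),
                             aa_weights = default_aa_weights(),
                             noise = noise_spec(),
                             n_reps = 4L,
                             layout = c("two", "three"),
                             dose = applied_excess_moles(1e-3, 0.030, 2, 0.98),
                             detection_limit_atom_pct_excess = 0) {
  layout <- match.arg(layout)
  keys <- MEASURED_POOLS[[layout]]$key
  miss <- setdiff(names(allocations), keys)
  if (length(miss))
    stop("invalid truth: allocation key(s) not in layout: ",
         paste(miss, collapse = ", "), call. = FALSE)
  alloc <- setNames(rep(0, length(keys)), keys)
  alloc[names(allocations)] <- allocations
  unknown <- 1 - sum(alloc)
  if (any(alloc < 0) || any(alloc > 1) || unknown < -1e-12)
    stop("invalid truth: allocations must lie in [0, 1] and sum to <= 1",
         call. = FALSE)
  if (abs(sum(alloc) + unknown - 1) > 1e-12)
    stop("invalid truth: allocations plus unknown must sum to 1", call. = FALSE)
  need_bio <- setdiff(keys, names(biomass_mg))
  if (length(need_bio))
    stop("invalid truth: biomass_mg missing pool(s): ",
         paste(need_bio, collapse = ", "), call. = FALSE)
  need_tn <- setdiff(keys, names(tn_percent))
  if (length(need_tn))
    stop("invalid truth: tn_percent missing pool(s): ",
         paste(need_tn, collapse = ", "), call. = FALSE)
  if (!donor_reference %in% c("donor_roots_trac", "donor_shoots"))
    stop("donor_reference must be 'donor_roots_trac' or 'donor_shoots'",
         call. = FALSE)
  if (n_reps < 2L) stop("invalid truth: n_reps must be >= 2", call. = FALSE)
  if (thaa_15n_fraction < 0 || thaa_15n_fraction > 1)
    stop("thaa_15n_fraction must lie in [0, 1]", call. = FALSE)
  w <- aa_weights[aa_weights > 0]
  structure(list(treatment = treatment, allocations = alloc,
                 unknown = unknown, biomass_mg = biomass_mg[keys],
                 tn_percent = tn_percent[keys],
                 donor_reference = donor_reference,
                 thaa_15n_fraction = thaa_15n_fraction,
                 thaa_conc_profile = thaa_conc_profile,
                 aa_weights = w / sum(w),
                 noise = noise, n_reps = as.integer(n_reps), layout = layout,
                 dose = dose,
                 detection_limit = detection_limit_atom_pct_excess),
            class = "experiment_truth")
}

#' Default soil THAA concentration profile (mg per g soil)
#' @return Named numeric vector over the amino acids of [aa_reference()]
#'   (internal standard excluded), totalling ~12.6 mg/g.
#' @export
default_thaa_profile <- function() {
  c(Ala = 1.2, Gly = 1.2, Val = 0.8, Leu = 1.0, Ile = 0.6, Pro = 0.7,
    Hyp = 0.3, Ser = 0.8, Thr = 0.7, Asx = 1.5, Glx = 1.7, Phe = 0.6,
    Tyr = 0.4, Lys = 0.8, Met = 0.3)
}

#' Default per-AA 15N incorporation weights
#'
#' Shaped by biosynthetic proximity to microbially assimilated N:
#' glutamate/glutamine (the entry point of N assimilation) dominates,
#' followed by transamination products; hydroxyproline and tyrosine receive
#' the least.
#' @return Named numeric vector (normalised downstream).
#' @export
default_aa_weights <- function() {
  c(Glx = 0.30, Asx = 0.20, Ala = 0.13, Gly = 0.10, Pro = 0.08, Ser = 0.05,
    Thr = 0.04, Leu = 0.03, Ile = 0.02, Lys = 0.02, Met = 0.013, Val = 0.01,
    Phe = 0.01, Hyp = 0.005, Tyr = 0.005)
}

.rln <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic split-root experiment
#'
#' Produces the pool and amino-acid measurement tables the pipeline reads,
#' for one or more treatments plus (optionally) an unlabelled control, with
#' the generating truths attached. Reproducible: the same seed yields
#' identical tables.
#'
#' @param truths An `experiment_truth` or list of them (distinct treatment
#'   names; shared dose).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @param include_control Emit an unlabelled control treatment (natural
#'   abundance + observation noise) named `control_name`.
#' @param control_name Name for the control treatment.
#' @return A list of class `synthetic_experiment` with `pools` (data
#'   frame), `aa` (data frame), `truths`, `control_name`.
#' @export
generate_experiment <- function(truths, seed = NULL, include_control = TRUE,
                                control_name = "control") {
  if (inherits(truths, "experiment_truth")) truths <- list(truths)
  stopifnot(all(vapply(truths, inherits, TRUE, "experiment_truth")))
  if (!is.null(seed)) set.seed(seed)
  constants <- isotope_constants()
  nat_pct <- 100 * constants$natural_atom_fraction
  ref <- aa_reference()

  pool_rows <- list(); aa_rows <- list()
  emit_pools <- function(truth, labelled) {
    mp <- MEASURED_POOLS[[truth$layout]]
    e_a <- truth$dose$e_a_mol
    n <- truth$n_reps
    treat <- if (labelled) truth$treatment else control_name
    u <- .rln(n, truth$noise$uptake_cv)        # common uptake multiplier
    soil_e <- rep(0, n)
    for (i in seq_len(nrow(mp))) {
      key <- mp$key[i]
      b_jit <- .rln(n, .lookup(truth$noise$biomass_cv, key, 0))
      biomass <- truth$biomass_mg[[key]] * b_jit
      n_n_mol <- biomass * 1e-3 * truth$tn_percent[[key]] / 100 / 14.007
      e <- if (labelled)
        e_a * truth$allocations[[key]] * u * b_jit *
          .rln(n, truth$noise$enrichment_cv)
      else rep(0, n)
      if (key == "soil_trac") soil_e <- e
      afe <- ifelse(n_n_mol > 0, e / n_n_mol, 0)
      obs <- 100 * (afe + constants$natural_atom_fraction) +
        rnorm(n, 0, .lookup(truth$noise$sd_atom_pct, key, 0))
      obs <- pmin(pmax(obs, 1e-6), 100 - 1e-6)
      nd <- labelled & truth$detection_limit > 0 &
        (obs - nat_pct) < truth$detection_limit
      pool_rows[[length(pool_rows) + 1L]] <<- data.frame(
        treatment = treat, replicate = seq_len(n),
        compartment = mp$compartment[i], pool = mp$pool[i],
        biomass_mg = biomass, tn_percent = truth$tn_percent[[key]],
        atom_pct_15n = ifelse(nd, NA_real_, obs),
        below_detection = nd, stringsAsFactors = FALSE)
    }
    # soil protein pool of the transfer compartment
    e_thaa <- if (labelled) truth$thaa_15n_fraction * soil_e else rep(0, n)
    soil_mass_g <- truth$biomass_mg[["soil_trac"]] * 1e-3
    w <- truth$aa_weights
    for (code in names(truth$thaa_conc_profile)) {
      conc <- truth$thaa_conc_profile[[code]]
      j <- match(code, ref$code)
      n_n_aa <- conc * 1e-3 * soil_mass_g / ref$molar_mass[j] * ref$n_atoms[j]
      e_aa <- e_thaa * (if (code %in% names(w)) w[[code]] else 0)
      af <- e_aa / n_n_aa + constants$natural_atom_fraction
      delta <- atom_fraction_to_delta(af, constants) +
        rnorm(n, 0, truth$noise$sd_delta_permil)
      aa_rows[[length(aa_rows) + 1L]] <<- data.frame(
        treatment = treat, replicate = seq_len(n), compartment = "T_ra_C",
        aa_code = code, concentration_mg_per_g = conc,
        delta15n_permil = delta, stringsAsFactors = FALSE)
    }
  }
  for (truth in truths) emit_pools(truth, labelled = TRUE)
  if (include_control) emit_pools(truths[[1L]], labelled = FALSE)
  structure(list(pools = do.call(rbind, pool_rows), aa = do.call(rbind, aa_rows),
                 truths = truths, control_name = if (include_control)
                   control_name else NULL),
            class = "synthetic_experiment")
}

#' Closed-form expected results implied by a truth record
#'
#' The values the pipeline must recover in the absence of noise: per-pool
#' percent retention, the unknown pool, the transfer proportions and Ndft
#' for the receiver plant, the bulk soil and the THAA pool, and the
#' incorporation percentages of applied (%15N_A) and soil-retained
#' (%15N_R) label in the THAA pool.
#'
#' @param truth An `experiment_truth`.
#' @return A list with `retention_pct` (named by pool key),
#'   `unknown_pct`, `p_transfer`, `ndft_receiver_pct`, `ndft_soil_pct`,
#'   `ndft_thaa_pct`, `pct_15n_a`, `pct_15n_r`, `tn_thaa_mg`.
#' @export
true_values <- function(truth) {
  alloc <- truth$allocations
  tn <- truth$biomass_mg * truth$tn_percent / 100  # mg N per pool
  # 15N contents are proportional to allocations (common factor cancels)
  recv_keys <- grep("^receiver", names(alloc), value = TRUE)
  n15_r <- sum(alloc[recv_keys])
  n15_d <- alloc[[truth$donor_reference]]
  n15_s <- alloc[["soil_trac"]]
  tn_d <- tn[[truth$donor_reference]]
  tn_r <- sum(tn[recv_keys])
  p <- n15_r / (n15_r + n15_d + n15_s)
  ndft_recv <- 100 * p * tn_d / tn_r
  p_soil <- n15_s / (n15_s + n15_d)
  ndft_soil <- 100 * p_soil * tn_d / tn[["soil_trac"]]
  ref <- aa_reference()
  idx <- match(names(truth$thaa_conc_profile), ref$code)
  soil_mass_g <- truth$biomass_mg[["soil_trac"]] * 1e-3
  n_n_thaa <- sum(truth$thaa_conc_profile * 1e-3 * soil_mass_g /
                    ref$molar_mass[idx] * ref$n_atoms[idx])
  tn_thaa_mg <- n_n_thaa * 14.007 * 1e3
  n15_thaa <- truth$thaa_15n_fraction * n15_s
  p_thaa <- n15_thaa / (n15_thaa + n15_d + n15_s)
  ndft_thaa <- 100 * p_thaa * tn_d / tn_thaa_mg
  list(retention_pct = 100 * alloc, unknown_pct = 100 * truth$unknown,
       p_transfer = p, ndft_receiver_pct = ndft_recv,
       ndft_soil_pct = ndft_soil, ndft_thaa_pct = ndft_thaa,
       pct_15n_a = 100 * truth$thaa_15n_fraction * n15_s,
       pct_15n_r = 100 * truth$thaa_15n_fraction,
       tn_thaa_mg = tn_thaa_mg)
}
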