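# Readers and validators for the measurement tables, experiment
# configuration, and results writers. CSV dialect: UTF-8, comma separator,
# "." decimal, mandatory header; "n.d." or an empty cell in the enrichment
# column means below detection.

POOL_LEVELS <- c("donor_shoots", "donor_roots", "receiver_shoots",
                 "receiver_roots", "soil")
COMPARTMENT_LEVELS <- c("L_ab_C", "T_ra_C", "R_ec_C")

#' Experiment configuration
#'
#' Describes the labelling design: the applied dose, the compartment layout,
#' the control (unlabelled) treatment, and the donor reference pool used for
#' the transfer calculation in each treatment. The donor reference defaults
#' to the donor roots in the transfer compartment — the pool most
#' representative of the 15N available for transfer since the label is not
#' evenly distributed through the plant; treatments where labelled shoot
#' material is the source (e.g. residue decomposition) use the donor shoots
#' instead.
#'
#' @param treatments Character vector of labelled treatment names.
#' @param control_treatment Name of the unlabelled control treatment, or
#'   `NULL` to baseline against natural abundance.
#' @param donor_reference Named character vector mapping treatment names to
#'   `"donor_roots"` or `"donor_shoots"`; unnamed treatments default to
#'   `"donor_roots"`.
#' @param dose_volume_ml,dose_molarity_mm,dose_n_atoms,dose_label_atom_pct
#'   The applied labelled substrate (defaults: 1 mL of 30 mM urea, 2 N per
#'   molecule, 98 atom% 15N).
#' @param layout `"two"` or `"three"` compartment design.
#' @param soil_mass_g Soil mass per compartment (g), the mass basis for
#'   THAA concentrations.
#' @param alpha Significance level for all statistics.
#' @return A validated list of class `experiment_config`.
#' @export
experiment_config <- function(treatments,
                              control_treatment = NULL,
                              donor_reference = NULL,
                              dose_volume_ml = 1,
                              dose_molarity_mm = 30,
                              dose_n_atoms = 2,
                              dose_label_atom_pct = 98,
                              layout = c("two", "three"),
                              soil_mass_g = 15,
                              alpha = 0.05) {
  layout <- match.arg(layout)
  stopifnot(is.character(treatments), length(treatments) >= 1L)
  ref <- setNames(rep("donor_roots", length(treatments)), treatments)
  if (!is.null(donor_reference)) {
    bad <- setdiff(donor_reference, c("donor_roots", "donor_shoots"))
    if (length(bad))
      stop("donor_reference must be 'donor_roots' or 'donor_shoots'", call. = FALSE)
    unknown <- setdiff(names(donor_reference), treatments)
    if (length(unknown))
      stop("donor_reference names unknown treatment(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    ref[names(donor_reference)] <- donor_reference
  }
  dose <- applied_excess_moles(dose_volume_ml * 1e-3, dose_molarity_mm * 1e-3,
                               dose_n_atoms, dose_label_atom_pct / 100)
  if (!is.null(control_treatment))
    stopifnot(is.character(control_treatment), length(control_treatment) == 1L)
  if (!(is.numeric(alpha) && alpha > 0 && alpha < 1))
    stop("alpha must lie in (0, 1)", call. = FALSE)
  if (!(is.numeric(soil_mass_g) && soil_mass_g > 0))
    stop("soil_mass_g must be positive", call. = FALSE)
  structure(list(treatments = treatments, control_treatment = control_treatment,
                 donor_reference = ref, dose = dose, layout = layout,
                 soil_mass_g = soil_mass_g, alpha = alpha),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML or JSON
#'
#' @param path Path to a YAML (or JSON, a YAML subset) file whose keys are
#'   the arguments of [experiment_config()].
#' @return An `experiment_config` object.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$donor_reference)) raw$donor_reference <- unlist(raw$donor_reference)
  if (!is.null(raw$treatments)) raw$treatments <- as.character(unlist(raw$treatments))
  do.call(experiment_config, raw)
}

.check_columns <- function(df, required, what) {
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("schema error in ", what, ": missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
}

.parse_numeric <- function(x, column, allow_nd = FALSE) {
  if (is.numeric(x)) return(x)
  x <- trimws(as.character(x))
  nd <- allow_nd & (x %in% c("n.d.", "nd", "ND", "") | is.na(x))
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !nd)
  if (length(bad))
    stop("unparseable numeric in column '", column, "' at data row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  out
}

#' Load and validate a pool measurement table
#'
#' One row per replicate x pool: treatment, replicate, compartment
#' (`L_ab_C`/`T_ra_C`/`R_ec_C`), pool (`donor_shoots`, `donor_roots`,
#' `receiver_shoots`, `receiver_roots`, `soil`), dry biomass (mg), total N
#' (% of dry mass), and bulk atom% 15N. `"n.d."` or an empty enrichment
#' cell is parsed as below detection (carried as a flag and treated as zero
#' excess in sums, never dropped silently).
#'
#' @param path Path to a CSV file.
#' @return A data frame with numeric columns and a logical
#'   `below_detection` column.
#' @export
load_pool_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  .check_columns(df, c("treatment", "replicate", "compartment", "pool",
                       "biomass_mg", "tn_percent", "atom_pct_15n"),
                 "pool table")
  bad_pool <- setdiff(unique(df$pool), POOL_LEVELS)
  if (length(bad_pool))
    stop("unknown pool value(s): ", paste(bad_pool, collapse = ", "), call. = FALSE)
  bad_comp <- setdiff(unique(df$compartment), COMPARTMENT_LEVELS)
  if (length(bad_comp))
    stop("unknown compartment value(s): ", paste(bad_comp, collapse = ", "),
         call. = FALSE)
  df$biomass_mg <- .parse_numeric(df$biomass_mg, "biomass_mg")
  df$tn_percent <- .parse_numeric(df$tn_percent, "tn_percent")
  raw <- df$atom_pct_15n
  df$atom_pct_15n <- .parse_numeric(raw, "atom_pct_15n", allow_nd = TRUE)
  df$below_detection <- is.na(df$atom_pct_15n)
  if (any(df$biomass_mg < 0)) stop("biomass_mg must be >= 0", call. = FALSE)
  if (any(df$tn_percent < 0 | df$tn_percent > 100))
    stop("tn_percent must lie in [0, 100]", call. = FALSE)
  ok <- is.na(df$atom_pct_15n) | (df$atom_pct_15n > 0 & df$atom_pct_15n < 100)
  if (!all(ok)) stop("atom_pct_15n must lie in (0, 100) when present", call. = FALSE)
  message(sprintf("loaded pool table: %d rows, %d treatments",
                  nrow(df), length(unique(df$treatment))))
  df
}

#' Load and validate an amino-acid measurement table
#'
#' One row per replicate x amino acid: treatment, replicate, compartment,
#' `aa_code` (see [aa_reference()]), concentration (mg per g soil) and
#' delta15N (per mil vs. Air). Tables carrying peak areas instead of
#' concentrations (`area_aa`, `area_istd` columns) are quantified against
#' the internal standard on load.
#'
#' @param path Path to a CSV file.
#' @param istd_mass_mg Internal-standard mass added (mg), used only for
#'   area-based tables.
#' @param sample_mass_g Hydrolysed sample mass (g), used only for
#'   area-based tables.
#' @return A data frame with columns `treatment`, `replicate`,
#'   `compartment`, `aa_code`, `concentration_mg_per_g`, `delta15n_permil`.
#' @export
load_aa_table <- function(path, istd_mass_mg = 0.04, sample_mass_g = 0.1) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  .check_columns(df, c("treatment", "replicate", "compartment", "aa_code",
                       "delta15n_permil"), "AA table")
  if (!"concentration_mg_per_g" %in% names(df)) {
    .check_columns(df, c("area_aa", "area_istd"), "AA table")
    df$concentration_mg_per_g <- quantify_aa(
      .parse_numeric(df$area_aa, "area_aa"),
      .parse_numeric(df$area_istd, "area_istd"),
      istd_mass_mg, sample_mass = sample_mass_g)
  }
  ref <- aa_reference()
  unknown <- setdiff(unique(df$aa_code), ref$code)
  if (length(unknown))
    stop("unknown analyte code(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  df$concentration_mg_per_g <- .parse_numeric(df$concentration_mg_per_g,
                                              "concentration_mg_per_g")
  df$delta15n_permil <- .parse_numeric(df$delta15n_permil, "delta15n_permil")
  if (any(df$concentration_mg_per_g < 0))
    stop("concentration_mg_per_g must be >= 0", call. = FALSE)
  message(sprintf("loaded AA table: %d rows, %d analytes",
                  nrow(df), length(unique(df$aa_code))))
  df
}

#' Write a pool table, rendering below-detection values as "n.d."
#'
#' @param pools A pool data frame (see [load_pool_table()]).
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_pool_table <- function(pools, path) {
  out <- pools
  val <- ifelse(!is.na(out$atom_pct_15n), format(out$atom_pct_15n, digits = 10,
                                                 scientific = FALSE, trim = TRUE),
                "n.d.")
  out$atom_pct_15n <- val
  out$below_detection <- NULL
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Published summary tables shipped with the package
#'
#' Treatment-level mean and standard error summaries (n = 4) from a
#' split-root 15N-urea labelling study of a clover-ryegrass system, used as
#' reference inputs for mass-balance checks: per-pool percent retention for
#' the two-compartment treatments, per-pool percent retention for the
#' bidirectional three-compartment experiment, and receiver-plant Ndft per
#' treatment.
#'
#' @param which One of `"retention_two_compartment"`,
#'   `"retention_three_compartment"`, `"ndft_receiver"`.
#' @return A data frame; `NA` in a value column means not detected.
#' @export
reference_summaries <- function(which = c("retention_two_compartment",
                                          "retention_three_compartment",
                                          "ndft_receiver")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0(which, ".csv"), package = "n15trace",
                      mustWork = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (col in intersect(c("mean_pct", "se_pct"), names(df)))
    df[[col]] <- .parse_numeric(df[[col]], col, allow_nd = TRUE)
  df
}
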