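# Plant-to-plant and plant-to-soil nitrogen transfer: the ratio-based
# proportion transferred, the yield-dependent transfer mass, and the
# percentage of receiver N derived from donor transfer.

#' Proportion of donor-available 15N transferred to the receiver
#'
#' P_transfer = 15N_R / (15N_R + 15N_D + 15N_S), where the three terms are
#' the excess-15N contents of the receiver pool(s), the donor reference pool
#' and the shared soil. Including the soil term avoids overestimating
#' transfer to the receiver when transfer to soil is significant. The ratio
#' is invariant to a common rescaling of all three contents, so
#' replicate-level variation in overall label uptake cancels.
#'
#' @param n15_receiver,n15_donor,n15_soil Excess-15N contents (same units),
#'   each >= 0 after clamping; vectorised, recycled.
#' @return The transferred proportion in `[0, 1]`. All-zero denominators
#'   yield `NA` with a warning (undefined transfer, reported as missing).
#' @export
p_transfer <- function(n15_receiver, n15_donor, n15_soil) {
  stopifnot(is.numeric(n15_receiver), is.numeric(n15_donor), is.numeric(n15_soil))
  if (any(n15_receiver < 0, na.rm = TRUE) || any(n15_donor < 0, na.rm = TRUE) ||
      any(n15_soil < 0, na.rm = TRUE))
    stop("15N contents must be >= 0 (clamp before calling)", call. = FALSE)
  denom <- n15_receiver + n15_donor + n15_soil
  out <- n15_receiver / denom
  zero <- !is.na(denom) & denom == 0
  if (any(zero)) {
    warning("undefined transfer proportion (all 15N contents zero); reported as NA",
            call. = FALSE)
    out[zero] <- NA_real_
  }
  out
}

#' Mass of N transferred from donor to receiver
#'
#' N_transfer = P_transfer x TN_D, where TN_D is the total N content of the
#' donor reference pool. Units follow `tn_donor`.
#'
#' @param p Transferred proportion in `[0, 1]`; vectorised.
#' @param tn_donor Total N content of the donor reference pool (>= 0).
#' @return Transferred N mass in the units of `tn_donor`.
#' @export
n_transfer <- function(p, tn_donor) {
  stopifnot(is.numeric(p), is.numeric(tn_donor))
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("transfer proportion must lie in [0, 1]", call. = FALSE)
  if (any(tn_donor < 0, na.rm = TRUE))
    stop("tn_donor must be >= 0", call. = FALSE)
  p * tn_donor
}

#' Percentage of receiver N derived from donor transfer (Ndft)
#'
#' Ndft = 100 * N_transfer / TN_R. The receiver may be the companion plant,
#' the bulk soil, or the soil protein (THAA) pool; TN_R is the corresponding
#' total N content.
#'
#' @param n_transferred Transferred N mass (same units as `tn_receiver`).
#' @param tn_receiver Total N content of the receiver pool (> 0).
#' @return Ndft in percent; vectorised.
#' @export
ndft <- function(n_transferred, tn_receiver) {
  stopifnot(is.numeric(n_transferred), is.numeric(tn_receiver))
  if (any(!is.finite(tn_receiver) | tn_receiver <= 0))
    stop("division by zero: tn_receiver must be positive", call. = FALSE)
  100 * n_transferred / tn_receiver
}

#' Transfer quantities for one donor/receiver/soil triple
#'
#' Convenience wrapper chaining [p_transfer()], [n_transfer()] and [ndft()].
#'
#' @param n15_receiver,n15_donor,n15_soil Excess-15N contents (same units).
#' @param tn_donor Total N of the donor reference pool.
#' @param tn_receiver Total N of the receiver pool.
#' @return A list of class `transfer_result` with `p_transfer`, `n_transfer`
#'   and `ndft_pct`.
#' @export
transfer_result <- function(n15_receiver, n15_donor, n15_soil, tn_donor, tn_receiver) {
  p <- p_transfer(n15_receiver, n15_donor, n15_soil)
  nt <- n_transfer(p, tn_donor)
  structure(list(p_transfer = p, n_transfer = nt,
                 ndft_pct = ndft(nt, tn_receiver)),
            class = "transfer_result")
}

#' Mass balance of the applied label: accounted and unknown pools
#'
#' The unknown pool is the difference between the 15N accounted for in the
#' measured pools and the total applied, expressed in percent of the dose.
#' It absorbs unmeasured sinks (e.g. highly enriched labelling-compartment
#' roots, residual label in the labelling substrate).
#'
#' @param accounted_percentages Numeric vector of per-pool percent
#'   retentions (each >= 0, post-clamp). May be empty.
#' @return A list of class `mass_balance` with `accounted`, `unknown`
#'   (always summing to 100 exactly) and `overaccounted` (TRUE with a
#'   warning if accounted > 100).
#' @examples
#' unknown_pool(c(37, 1.8, 0.69, 0.34, 0.14))  # unknown ~60
#' @export
unknown_pool <- function(accounted_percentages) {
  stopifnot(is.numeric(accounted_percentages))
  if (any(accounted_percentages < 0, na.rm = TRUE))
    stop("accounted percentages must be >= 0 (clamp before calling)", call. = FALSE)
  acc <- sum(accounted_percentages, na.rm = TRUE)
  over <- acc > 100
  if (over)
    warning("accounted 15N exceeds 100% of the applied dose; unknown pool is negative",
            call. = FALSE)
  structure(list(accounted = acc, unknown = 100 - acc, overaccounted = over),
            class = "mass_balance")
}

#' Mean and standard error over replicates
#'
#' Treatment-level aggregation used for every reported quantity: arithmetic
#' mean and standard error sd/sqrt(n) over non-missing replicate values,
#' with the number used reported and a flag when replicates were dropped.
#'
#' @param values Numeric vector of per-replicate values; `NA`s are dropped.
#' @return A list of class `replicate_summary` with `mean`, `se`, `n`,
#'   and `n_missing`.
#' @examples
#' summarize_treatment(c(1, 2, 3, 4))  # mean 2.5, se ~0.6455
#' @export
summarize_treatment <- function(values) {
  stopifnot(is.numeric(values))
  keep <- values[!is.na(values)]
  if (length(keep) < 2L)
    stop("insufficient replication: need >= 2 non-missing replicates", call. = FALSE)
  structure(list(mean = mean(keep), se = sd(keep) / sqrt(length(keep)),
                 n = length(keep), n_missing = length(values) - length(keep)),
            class = "replicate_summary")
}
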