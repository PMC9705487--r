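# End-to-end analysis: bulk pool tables and AA tables in, per-treatment
# retention, transfer (receiver plant / bulk soil / THAA pool) and
# treatment statistics out.

.log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full tracer analysis
#'
#' Orchestrates the mass-balance and transfer calculations: per-replicate
#' pool excess-15N from bulk atom% against the control baseline, percent
#' retention of the dose with the unknown pool, transfer proportions and
#' Ndft for the receiver plant, the transfer-compartment bulk soil and the
#' soil protein (THAA) pool, amino-acid incorporation profiles, and
#' one-way ANOVA with step-down Holm-Sidak letters across treatments.
#' Deterministic given its inputs.
#'
#' @param config An [experiment_config()].
#' @param pools A pool data frame from [load_pool_table()] or a
#'   `synthetic_experiment`'s `pools` element.
#' @param aa Optional AA data frame from [load_aa_table()].
#' @return An object of class `n15_analysis`: a list with `retention`
#'   (per-replicate, long), `retention_summary`, `transfer`
#'   (per-replicate), `transfer_summary`, `aa_profiles`, `stats`, `config`.
#' @export
run_pipeline <- function(config, pools, aa = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  if (inherits(pools, "synthetic_experiment")) {
    if (is.null(aa)) aa <- pools$aa
    pools <- pools$pools
  }
  if (!"below_detection" %in% names(pools))
    pools$below_detection <- is.na(pools$atom_pct_15n)
  constants <- isotope_constants()
  nat_pct <- 100 * constants$natural_atom_fraction

  ctrl <- config$control_treatment
  if (!is.null(ctrl) && !ctrl %in% pools$treatment)
    stop("configuration error: control treatment '", ctrl,
         "' absent from the pool table", call. = FALSE)
  missing_tr <- setdiff(config$treatments, pools$treatment)
  if (length(missing_tr))
    stop("configuration error: treatment(s) absent from the pool table: ",
         paste(missing_tr, collapse = ", "), call. = FALSE)

  # control baseline atom% per pool x compartment (natural abundance default)
  baseline <- function(pool, compartment) {
    if (!is.null(ctrl)) {
      sub <- pools[pools$treatment == ctrl & pools$pool == pool &
                     pools$compartment == compartment & !pools$below_detection, ]
      if (nrow(sub) > 0) return(mean(sub$atom_pct_15n))
    }
    nat_pct
  }
  .log_stage("baseline", "control baseline: %s",
             if (is.null(ctrl)) "natural abundance" else ctrl)

  dat <- pools[pools$treatment %in% config$treatments, , drop = FALSE]
  base_pct <- mapply(baseline, dat$pool, dat$compartment)
  obs_pct <- ifelse(dat$below_detection, base_pct, dat$atom_pct_15n)
  dat$atom_pct_excess <- obs_pct - base_pct
  dat$tn_mg <- dat$biomass_mg * dat$tn_percent / 100
  dat$n_n_mol <- dat$tn_mg * 1e-3 / 14.007
  dat$e_mol <- dat$n_n_mol * dat$atom_pct_excess / 100
  dat$n15_mg <- pool_15N_content(dat$atom_pct_excess, dat$tn_mg)
  e_a <- config$dose$e_a_mol
  dat$retention_pct <- suppressWarnings(
    percent_retention(dat$e_mol, config$dose, clamp = TRUE))
  if (any(dat$e_mol < 0))
    .log_stage("retention", "%d pool value(s) below baseline clamped to 0",
               sum(dat$e_mol < 0))

  # --- retention summary (per treatment x pool x compartment, + total/unknown)
  key <- interaction(dat$treatment, dat$pool, dat$compartment, drop = TRUE)
  retention_summary <- do.call(rbind, lapply(split(dat, key), function(s) {
    sm <- summarize_treatment(s$retention_pct)
    data.frame(treatment = s$treatment[1], pool = s$pool[1],
               compartment = s$compartment[1], mean_pct = sm$mean,
               se_pct = sm$se, n = sm$n, stringsAsFactors = FALSE)
  }))
  totals <- do.call(rbind, lapply(split(dat, dat$treatment), function(s) {
    per_rep <- vapply(split(s, s$replicate),
                      function(r) sum(r$retention_pct), 1)
    unk <- vapply(per_rep, function(acc) unknown_pool(acc)$unknown, 1)
    smt <- summarize_treatment(per_rep); smu <- summarize_treatment(unk)
    data.frame(treatment = s$treatment[1],
               pool = c("total", "unknown"), compartment = NA,
               mean_pct = c(smt$mean, smu$mean), se_pct = c(smt$se, smu$se),
               n = c(smt$n, smu$n), stringsAsFactors = FALSE)
  }))
  retention_summary <- rbind(retention_summary, totals)
  rownames(retention_summary) <- NULL

  # --- transfer per replicate
  donor_pool <- function(tr) {
    if (config$donor_reference[[tr]] == "donor_shoots") {
      list(pool = "donor_shoots", compartment = "T_ra_C")
    } else list(pool = "donor_roots", compartment = "T_ra_C")
  }
  aa_by_key <- NULL
  if (!is.null(aa)) {
    ctrl_deltas <- NULL
    if (!is.null(ctrl)) {
      ca <- aa[aa$treatment == ctrl, , drop = FALSE]
      if (nrow(ca) > 0)
        ctrl_deltas <- vapply(split(ca$delta15n_permil, ca$aa_code), mean, 1)
    }
    aa_lab <- aa[aa$treatment %in% config$treatments, , drop = FALSE]
    aa_by_key <- lapply(split(aa_lab,
                              interaction(aa_lab$treatment, aa_lab$replicate,
                                          drop = TRUE)),
                        function(s) {
      th <- thaa_enrichment(
        data.frame(aa_code = s$aa_code,
                   concentration_mg_per_g = s$concentration_mg_per_g,
                   delta15n_permil = s$delta15n_permil),
        control_deltas = ctrl_deltas, mass_basis_g = config$soil_mass_g,
        constants = constants)
      list(treatment = s$treatment[1], replicate = s$replicate[1], thaa = th)
    })
  }
  transfer <- do.call(rbind, lapply(split(dat, dat$treatment), function(s) {
    dp <- donor_pool(s$treatment[1])
    do.call(rbind, lapply(split(s, s$replicate), function(r) {
      pick <- function(pool, compartment)
        r[r$pool == pool & r$compartment == compartment, , drop = FALSE]
      d <- pick(dp$pool, dp$compartment)
      soil <- pick("soil", "T_ra_C")
      recv <- r[r$pool %in% c("receiver_roots", "receiver_shoots"), ,
                drop = FALSE]
      if (nrow(d) == 0 || nrow(soil) == 0 || nrow(recv) == 0)
        return(NULL)
      cl <- function(x) pmax(x, 0)
      n15_d <- cl(sum(d$n15_mg)); n15_s <- cl(sum(soil$n15_mg))
      n15_r <- cl(sum(recv$n15_mg))
      tr_plant <- transfer_result(n15_r, n15_d, n15_s, sum(d$tn_mg),
                                  sum(recv$tn_mg))
      p_soil <- p_transfer(n15_s, n15_d, 0)
      ndft_soil <- ndft(n_transfer(p_soil, sum(d$tn_mg)), sum(soil$tn_mg))
      out <- data.frame(treatment = r$treatment[1], replicate = r$replicate[1],
                        donor_reference = dp$pool,
                        p_transfer = tr_plant$p_transfer,
                        n_transfer_mg = tr_plant$n_transfer,
                        ndft_receiver_pct = tr_plant$ndft_pct,
                        ndft_soil_pct = ndft_soil,
                        ndft_thaa_pct = NA_real_, pct_15n_a = NA_real_,
                        pct_15n_r = NA_real_, stringsAsFactors = FALSE)
      if (!is.null(aa_by_key)) {
        k <- paste(r$treatment[1], r$replicate[1], sep = ".")
        hit <- aa_by_key[[k]]
        if (!is.null(hit)) {
          th <- hit$thaa
          n15_thaa <- cl(th$e_mol * 14.007 * 1e3)  # mg, same basis as bulk
          tn_thaa_mg <- th$tn_g * 1e3
          tr_thaa <- aa_ndft(n15_thaa, n15_d, n15_s, sum(d$tn_mg), tn_thaa_mg)
          out$ndft_thaa_pct <- tr_thaa$ndft_pct
          out$pct_15n_a <- percent_incorporation(max(th$e_mol, 0), config$dose)
          e_soil <- sum(soil$e_mol)
          out$pct_15n_r <- if (e_soil > 0)
            percent_incorporation(max(th$e_mol, 0), e_soil) else NA_real_
        }
      }
      out
    }))
  }))
  rownames(transfer) <- NULL

  transfer_summary <- do.call(rbind, lapply(split(transfer, transfer$treatment),
                                            function(s) {
    one <- function(col) {
      v <- s[[col]]
      if (sum(!is.na(v)) < 2L) return(c(NA_real_, NA_real_, sum(!is.na(v))))
      sm <- summarize_treatment(v); c(sm$mean, sm$se, sm$n)
    }
    vars <- c("p_transfer", "ndft_receiver_pct", "ndft_soil_pct",
              "ndft_thaa_pct", "pct_15n_a", "pct_15n_r")
    vals <- vapply(vars, one, numeric(3))
    data.frame(treatment = s$treatment[1], quantity = vars,
               donor_reference = s$donor_reference[1],
               mean = vals[1, ], se = vals[2, ], n = vals[3, ],
               stringsAsFactors = FALSE)
  }))
  rownames(transfer_summary) <- NULL

  # --- AA incorporation profiles (per-AA share of THAA excess 15N)
  aa_profiles <- NULL
  if (!is.null(aa_by_key)) {
    prof <- do.call(rbind, lapply(aa_by_key, function(h) {
      p <- h$thaa$per_aa
      tot <- sum(pmax(p$e_mol, 0))
      data.frame(treatment = h$treatment, replicate = h$replicate,
                 aa_code = p$aa_code, e_mol = p$e_mol,
                 share = if (tot > 0) pmax(p$e_mol, 0) / tot else NA_real_,
                 stringsAsFactors = FALSE)
    }))
    aa_profiles <- do.call(rbind, lapply(
      split(prof, interaction(prof$treatment, prof$aa_code, drop = TRUE)),
      function(s) data.frame(treatment = s$treatment[1], aa_code = s$aa_code[1],
                             mean_share = mean(s$share, na.rm = TRUE),
                             stringsAsFactors = FALSE)))
    rownames(aa_profiles) <- NULL
  }

  # --- treatment statistics on Ndft and per-pool retention
  stats_out <- list()
  if (length(config$treatments) >= 2L) {
    grp <- function(df, col) {
      g <- split(df[[col]], df$treatment)
      g <- lapply(g, function(x) x[!is.na(x)])
      g[vapply(g, length, 1L) >= 2L]
    }
    add_stat <- function(name, groups) {
      if (length(groups) < 2L) return()
      res <- tryCatch(list(
        checks = assumption_checks(groups, config$alpha),
        pairwise = pairwise_holm_sidak(groups, config$alpha)
      ), error = function(e) NULL)
      if (!is.null(res)) stats_out[[name]] <<- res
    }
    add_stat("ndft_receiver_pct", grp(transfer, "ndft_receiver_pct"))
    add_stat("ndft_soil_pct", grp(transfer, "ndft_soil_pct"))
    if (!all(is.na(transfer$ndft_thaa_pct)))
      add_stat("ndft_thaa_pct", grp(transfer, "ndft_thaa_pct"))
    for (pl in unique(dat$pool)) {
      sub <- dat[dat$pool == pl & dat$compartment == "T_ra_C", ]
      add_stat(paste0("retention_", pl), grp(sub, "retention_pct"))
    }
  }
  .log_stage("stats", "computed %d treatment comparisons", length(stats_out))

  structure(list(retention = dat[, c("treatment", "replicate", "compartment",
                                     "pool", "atom_pct_excess", "tn_mg",
                                     "e_mol", "n15_mg", "retention_pct")],
                 retention_summary = retention_summary,
                 transfer = transfer, transfer_summary = transfer_summary,
                 aa_profiles = aa_profiles, stats = stats_out,
                 config = config),
            class = "n15_analysis")
}

#' @export
print.n15_analysis <- function(x, ...) {
  cat("Split-root 15N tracer analysis\n")
  cat(sprintf("  treatments: %s\n", paste(x$config$treatments, collapse = ", ")))
  cat(sprintf("  applied excess 15N: %.2f umol\n", x$config$dose$e_a_mol * 1e6))
  tot <- x$retention_summary[x$retention_summary$pool == "total", ]
  for (i in seq_len(nrow(tot)))
    cat(sprintf("  %s: %.1f +/- %.1f%% of dose accounted for (n = %d)\n",
                tot$treatment[i], tot$mean_pct[i], tot$se_pct[i], tot$n[i]))
  invisible(x)
}

#' @export
summary.n15_analysis <- function(object, ...) {
  cat("Percent retention of applied 15N (mean +/- SE):\n")
  print(object$retention_summary, row.names = FALSE, digits = 3)
  cat("\nNitrogen transfer (mean +/- SE):\n")
  ts <- object$transfer_summary
  print(ts[ts$quantity %in% c("ndft_receiver_pct", "ndft_soil_pct",
                              "ndft_thaa_pct"), ],
        row.names = FALSE, digits = 3)
  if (length(object$stats)) {
    cat("\nANOVA / Holm-Sidak letters:\n")
    for (nm in names(object$stats)) {
      pw <- object$stats[[nm]]$pairwise
      cat(sprintf("  %s: F = %.2f, p = %.3g; letters: %s\n", nm,
                  pw$anova$f, pw$anova$p,
                  paste(names(pw$letters), pw$letters, sep = "=",
                        collapse = ", ")))
    }
  }
  invisible(object)
}

#' Plot treatment-level transfer or retention with standard-error bars
#'
#' @param x An `n15_analysis`.
#' @param which `"ndft"` (receiver-plant Ndft per treatment) or
#'   `"retention"` (per-pool retention for one treatment).
#' @param treatment Treatment shown when `which = "retention"` (default:
#'   first configured treatment).
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the plotted summary data frame.
#' @export
plot.n15_analysis <- function(x, which = c("ndft", "retention"),
                              treatment = NULL, ...) {
  which <- match.arg(which)
  if (which == "ndft") {
    ts <- x$transfer_summary
    df <- ts[ts$quantity == "ndft_receiver_pct", ]
    heights <- setNames(df$mean, df$treatment)
    ylab <- "Ndft (% of receiver N)"
  } else {
    if (is.null(treatment)) treatment <- x$config$treatments[1]
    rs <- x$retention_summary
    df <- rs[rs$treatment == treatment & !rs$pool %in% c("total", "unknown"), ]
    heights <- setNames(df$mean_pct, paste(df$pool, df$compartment))
    df$mean <- df$mean_pct; df$se <- df$se_pct
    ylab <- sprintf("%% of applied 15N (%s)", treatment)
  }
  up <- df$mean + df$se
  mid <- graphics::barplot(heights, ylab = ylab, las = 2,
                           ylim = c(0, max(up) * 1.15), ...)
  graphics::arrows(mid, df$mean - df$se, mid, up, angle = 90, code = 3,
                   length = 0.04)
  invisible(df)
}

#' Write the result tables of an analysis to CSV
#'
#' Emits `retention.csv`, `retention_summary.csv`, `transfer.csv`,
#' `transfer_summary.csv`, and (when present) `aa_profiles.csv` into a
#' directory. Writing then re-reading a table is the identity.
#'
#' @param x An `n15_analysis`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_results <- function(x, dir) {
  stopifnot(inherits(x, "n15_analysis"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  emit <- function(df, name)
    write.csv(df, file.path(dir, paste0(name, ".csv")), row.names = FALSE)
  emit(x$retention, "retention")
  emit(x$retention_summary, "retention_summary")
  emit(x$transfer, "transfer")
  emit(x$transfer_summary, "transfer_summary")
  if (!is.null(x$aa_profiles)) emit(x$aa_profiles, "aa_profiles")
  invisible(dir)
}
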