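# The synthetic-experiment generator: validation, determinism,
# conservation, noise pass-through and closed-form expected values.

test_that("truth validation enforces the allocation simplex and replication", {
  expect_error(
    experiment_truth("x", c(donor_shoots = 0.8, soil_trac = 0.4),
                     biomass_mg = c(donor_shoots = 200, donor_roots_trac = 100,
                                    soil_trac = 15000, receiver_roots_trac = 300,
                                    receiver_shoots = 300),
                     tn_percent = c(donor_shoots = 4, donor_roots_trac = 3,
                                    soil_trac = 0.57, receiver_roots_trac = 2,
                                    receiver_shoots = 2)),
    "sum")
  expect_error(treatment_truth("urea", n_reps = 1), "n_reps")
  expect_error(
    experiment_truth("x", c(nonsense_pool = 0.1),
                     biomass_mg = c(a = 1), tn_percent = c(a = 1)),
    "not in layout")
})

test_that("the same seed reproduces identical tables", {
  tr <- treatment_truth("urea")
  s1 <- generate_experiment(tr, seed = 99)
  s2 <- generate_experiment(tr, seed = 99)
  expect_identical(s1$pools, s2$pools)
  expect_identical(s1$aa, s2$aa)
  s3 <- generate_experiment(tr, seed = 100)
  expect_false(identical(s1$pools$atom_pct_15n, s3$pools$atom_pct_15n))
})

test_that("zero-noise generation conserves the label exactly", {
  tr <- treatment_truth("urea", noise = zero_noise())
  sim <- generate_experiment(tr, seed = 5)
  cfg <- experiment_config("urea", control_treatment = "control")
  res <- suppressMessages(run_pipeline(cfg, sim))
  tv <- true_values(tr)
  rs <- res$retention_summary
  per_pool <- rs[!rs$pool %in% c("total", "unknown"), ]
  expect_equal(per_pool$se_pct, rep(0, nrow(per_pool)), tolerance = 1e-8)
  # each measured pool returns its allocated share exactly
  for (i in seq_len(nrow(per_pool))) {
    key <- if (per_pool$pool[i] == "soil") "soil_trac"
           else if (per_pool$pool[i] == "donor_roots") "donor_roots_trac"
           else if (per_pool$pool[i] == "receiver_roots") "receiver_roots_trac"
           else per_pool$pool[i]
    expect_equal(per_pool$mean_pct[i], tv$retention_pct[[key]],
                 tolerance = 1e-10)
  }
  unk <- rs[rs$pool == "unknown", "mean_pct"]
  tot <- rs[rs$pool == "total", "mean_pct"]
  expect_equal(tot + unk, 100, tolerance = 1e-12)
  expect_equal(unk, tv$unknown_pct, tolerance = 1e-10)
})

test_that("zero-noise transfer recovery equals the generator truth to 1e-10", {
  for (name in c("urea", "decomposition")) {
    tr <- treatment_truth(name, noise = zero_noise())
    sim <- generate_experiment(tr, seed = 8)
    cfg <- experiment_config(
      name, control_treatment = "control",
      donor_reference = if (name == "decomposition")
        c(decomposition = "donor_shoots") else NULL)
    res <- suppressMessages(run_pipeline(cfg, sim))
    tv <- true_values(tr)
    got <- res$transfer_summary
    pick <- function(q) got[got$quantity == q, "mean"]
    expect_equal(pick("ndft_receiver_pct"), tv$ndft_receiver_pct,
                 tolerance = 1e-10)
    expect_equal(pick("ndft_soil_pct"), tv$ndft_soil_pct, tolerance = 1e-10)
    expect_equal(pick("ndft_thaa_pct"), tv$ndft_thaa_pct, tolerance = 1e-8)
    expect_equal(pick("pct_15n_a"), tv$pct_15n_a, tolerance = 1e-8)
    expect_equal(pick("pct_15n_r"), tv$pct_15n_r, tolerance = 1e-8)
  }
})

test_that("a configured atom% noise SD is reproduced in the generated spread", {
  tr <- treatment_truth("urea",
                        noise = noise_spec(uptake_cv = 0, biomass_cv = 0,
                                           enrichment_cv = 0,
                                           sd_atom_pct = c(donor_shoots = 0.3),
                                           sd_delta_permil = 0),
                        n_reps = 2000)
  sim <- generate_experiment(tr, seed = 13, include_control = FALSE)
  shoots <- sim$pools[sim$pools$pool == "donor_shoots", "atom_pct_15n"]
  expect_equal(sd(shoots), 0.3, tolerance = 0.05)
  soil <- sim$pools[sim$pools$pool == "soil", "atom_pct_15n"]
  expect_equal(sd(soil), 0, tolerance = 1e-12)
})

test_that("per-AA incorporation ordering follows the configured weights", {
  tr <- treatment_truth("urea", noise = zero_noise())
  sim <- generate_experiment(tr, seed = 3)
  cfg <- experiment_config("urea", control_treatment = "control")
  res <- suppressMessages(run_pipeline(cfg, sim))
  prof <- res$aa_profiles
  share <- setNames(prof$mean_share, prof$aa_code)
  w <- default_aa_weights()
  expect_gt(share[["Glx"]], share[["Ala"]])
  expect_gt(share[["Ala"]], share[["Hyp"]])
  expect_gt(share[["Ala"]], share[["Tyr"]])
  # shares reproduce the normalised weights under zero noise
  expect_equal(share[names(w)], w / sum(w), tolerance = 1e-6)
})

test_that("closed-form expected values satisfy their defining identities", {
  tr <- treatment_truth("urea")
  tv <- true_values(tr)
  alloc <- tr$allocations
  tn <- tr$biomass_mg * tr$tn_percent / 100
  r <- alloc[["receiver_roots_trac"]] + alloc[["receiver_shoots"]]
  d <- alloc[["donor_roots_trac"]]; s <- alloc[["soil_trac"]]
  expect_equal(tv$p_transfer, r / (r + d + s))
  expect_equal(tv$ndft_receiver_pct,
               100 * tv$p_transfer * tn[["donor_roots_trac"]] /
                 (tn[["receiver_roots_trac"]] + tn[["receiver_shoots"]]))
  expect_equal(tv$unknown_pct, 100 * (1 - sum(alloc)))
  expect_equal(tv$pct_15n_a, 100 * tr$thaa_15n_fraction * s)
})
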