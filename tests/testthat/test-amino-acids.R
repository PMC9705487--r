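# Compound-specific SIP: internal-standard quantification, recovery
# correction, THAA enrichment and the GC-C-IRMS acceptance gate.

test_that("internal-standard quantification is a linear area ratio", {
  # equal areas, RF 1, 40 ug standard in 0.1 g soil -> 0.4 mg/g
  expect_equal(quantify_aa(100, 100, 0.04, 1, 0.1), 0.4)
  expect_identical(quantify_aa(0, 100, 0.04, 1, 0.1), 0)
  expect_equal(quantify_aa(50, 100, 0.04, 2, 0.1),
               2 * quantify_aa(50, 100, 0.04, 1, 0.1))
  expect_error(quantify_aa(100, 0, 0.04), "failed run")
})

test_that("recovery correction inverts an applied recovery loss", {
  expect_identical(correct_recovery(0.05, 1), 0.05)
  expect_equal(correct_recovery(0.05, 0.5), 0.10)
  expect_warning(over <- correct_recovery(0.06, 1.2), "over-recovery")
  expect_lt(over, 0.06)
  true_mass <- runif(10, 0.01, 1)
  rec <- runif(10, 0.05, 1)
  expect_equal(correct_recovery(true_mass * rec, rec), true_mass)
})

test_that("THAA enrichment matches the per-AA spreadsheet chain and is additive", {
  # independent oracle: explicit per-step arithmetic for a single AA
  glx <- data.frame(aa_code = "Glx", concentration_mg_per_g = 2,
                    delta15n_permil = 500)
  th <- thaa_enrichment(glx, mass_basis_g = 1)
  r_sample <- R_STD_AIR * (500 / 1000 + 1)
  afe_oracle <- r_sample / (1 + r_sample) - R_STD_AIR / (1 + R_STD_AIR)
  n_n_oracle <- 2e-3 / 147.13 * 1
  expect_equal(th$e_mol, n_n_oracle * afe_oracle, tolerance = 1e-12)
  expect_equal(th$e_mol, 2.48e-8, tolerance = 1e-2)

  # no enrichment over the control -> zero pool excess
  flat <- data.frame(aa_code = c("Ala", "Glx"),
                     concentration_mg_per_g = c(1, 2),
                     delta15n_permil = c(3, 3))
  th0 <- thaa_enrichment(flat, control_deltas = c(Ala = 3, Glx = 3))
  expect_equal(th0$e_mol, 0)

  # additivity over AAs
  two <- data.frame(aa_code = c("Ala", "Glx"),
                    concentration_mg_per_g = c(1, 2),
                    delta15n_permil = c(120, 500))
  parts <- lapply(1:2, function(i) thaa_enrichment(two[i, ]))
  expect_equal(thaa_enrichment(two)$e_mol,
               parts[[1]]$e_mol + parts[[2]]$e_mol)

  # the internal standard never contributes to the pool sum
  with_istd <- rbind(two, data.frame(aa_code = "Nle",
                                     concentration_mg_per_g = 0.4,
                                     delta15n_permil = 900))
  expect_equal(thaa_enrichment(with_istd)$e_mol, thaa_enrichment(two)$e_mol)
  expect_error(thaa_enrichment(data.frame(aa_code = "Xyz",
                                          concentration_mg_per_g = 1,
                                          delta15n_permil = 0)),
               "unknown analyte")
})

test_that("incorporation percentages and THAA transfer behave like the bulk forms", {
  dose <- applied_excess_moles(1e-3, 0.030, 2, 0.98)
  expect_equal(percent_incorporation(dose$e_a_mol, dose), 100)
  expect_identical(percent_incorporation(0, dose), 0)
  # soil retains less than the dose -> %15N_R >= %15N_A
  e_thaa <- 1e-8; e_soil <- 4e-7
  expect_gte(percent_incorporation(e_thaa, e_soil),
             percent_incorporation(e_thaa, dose))
  expect_error(percent_incorporation(1e-8, 0), "division by zero")
  tr <- aa_ndft(0, 1, 1, 10, 20)
  expect_identical(tr$ndft_pct, 0)
  tr1 <- aa_ndft(1, 7, 2, 14, 20)
  tr2 <- aa_ndft(1000, 7000, 2000, 14, 20)
  expect_equal(tr1$ndft_pct, tr2$ndft_pct)
})

test_that("QC gate applies the 75% / 1.0 / 1.5 permil rule", {
  expect_true(qc_gate(rep(0, 10)))
  expect_true(qc_gate(c(rep(0.5, 16), rep(1.4, 4))))   # exactly 80% tight
  expect_false(qc_gate(c(rep(0, 19), 1.6)))             # one outside 1.5
  expect_false(qc_gate(c(rep(0.2, 14), rep(1.2, 6))))   # only 70% tight
  expect_true(qc_gate(c(rep(-0.9, 3), 1.5)))            # signs irrelevant
  expect_error(qc_gate(numeric(0)), "invalid QC run")
})

test_that("QC gate matches a brute-force oracle on all small panels", {
  # exhaustive multisets of deviation magnitudes for panels of up to 8
  levels <- c(0, 0.5, 1.0, 1.1, 1.5, 1.6)
  oracle <- function(dev) {
    n_ok <- 0L
    for (d in abs(dev)) if (d <= 1.0) n_ok <- n_ok + 1L
    if (n_ok / length(dev) < 0.75) return(FALSE)
    for (d in abs(dev)) if (d > 1.5) return(FALSE)
    TRUE
  }
  for (n in 1:8) {
    panels <- utils::combn(length(levels) + n - 1L, n,
                           function(i) levels[i - seq_len(n) + 1L])
    if (length(dim(panels)) < 2L) panels <- matrix(panels, nrow = n)
    for (k in seq_len(ncol(panels))) {
      dev <- panels[, k]
      expect_identical(qc_gate(dev), oracle(dev),
                       info = paste("panel:", paste(dev, collapse = ",")))
    }
  }
})
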