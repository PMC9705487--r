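# Scale conversions and mass-balance primitives. Derived expectations were
# computed by hand from AF = R/(1+R), R = r_std(delta/1000 + 1) with
# r_std = 0.0036765.

test_that("delta to atom fraction matches hand-evaluated closed form", {
  expect_equal(delta_to_atom_fraction(0), 0.0036630, tolerance = 1e-4)
  expect_equal(delta_to_atom_fraction(0), R_STD_AIR / (1 + R_STD_AIR),
               tolerance = 1e-12)
  # delta = +1000 permil doubles the ratio: R = 2 * r_std
  expect_equal(delta_to_atom_fraction(1000),
               2 * R_STD_AIR / (1 + 2 * R_STD_AIR), tolerance = 1e-12)
  expect_equal(delta_to_atom_fraction(1000), 0.0072993, tolerance = 1e-4)
  expect_error(delta_to_atom_fraction(-1000), "invalid delta")
  expect_error(delta_to_atom_fraction(-1500), "invalid delta")
})

test_that("atom fraction to delta is the exact inverse over the full scale", {
  expect_equal(atom_fraction_to_delta(natural_atom_fraction()), 0,
               tolerance = 1e-9)
  # a 98 atom% label sits far above the working range of the delta scale
  expect_gt(atom_fraction_to_delta(0.98), 1e6)
  deltas <- c(-900, -500, -10, 0, 10, 500, 5000, 1e5, 1e7)
  back <- atom_fraction_to_delta(delta_to_atom_fraction(deltas))
  expect_equal(back, deltas, tolerance = 1e-9)
  expect_error(atom_fraction_to_delta(0), "invalid atom fraction")
  expect_error(atom_fraction_to_delta(1), "invalid atom fraction")
})

test_that("conversion is strictly monotone and near-linear at low enrichment", {
  d <- seq(-900, 2000, by = 7)
  af <- delta_to_atom_fraction(d)
  expect_true(all(diff(af) > 0))
  # linearisation AF ~ R: relative gap equals AF itself, so it holds to
  # 0.5% while AF stays below ~0.45 atom%
  low <- af[af < 0.0045]
  approx <- R_STD_AIR * (d[af < 0.0045] / 1000 + 1)
  expect_lt(max(abs(approx - low) / low), 0.005)
})

test_that("atom fraction excess is a plain antisymmetric difference", {
  expect_identical(atom_fraction_excess(0.5, 0.5), 0)
  # enriched shoot material at 2.1 atom% against the natural baseline
  expect_equal(atom_fraction_excess(0.021, 0.0036630), 0.0173370,
               tolerance = 1e-10)
  expect_equal(atom_fraction_excess(0.98, 0.0036630), 0.9763370,
               tolerance = 1e-10)
  x <- runif(20, 0.001, 0.999); y <- runif(20, 0.001, 0.999)
  expect_equal(atom_fraction_excess(x, y), -atom_fraction_excess(y, x))
})

test_that("pool enrichment is linear in pool size and excess", {
  expect_identical(enrichment_moles(0, 0.5)$e, 0)
  expect_equal(enrichment_moles(60e-6, 0.05)$e, 3e-6)
  e1 <- enrichment_moles(7.3e-6, 0.021)$e
  e2 <- enrichment_moles(2 * 7.3e-6, 0.021)$e
  expect_equal(e2, 2 * e1)
  expect_error(enrichment_moles(-1, 0.1), "invalid pool")
})

test_that("applied dose excess matches the hand oracle for the urea label", {
  # 1 mL x 30 mM x 2 N = 60 umol N; x (0.98 - 0.0036630) = 58.58 umol
  dose <- applied_excess_moles(1e-3, 0.030, 2, 0.98)
  expect_equal(dose$e_a_mol * 1e6, 60 * (0.98 - R_STD_AIR / (1 + R_STD_AIR)),
               tolerance = 1e-9)
  expect_equal(dose$e_a_mol * 1e6, 58.58, tolerance = 1e-4)
  half <- applied_excess_moles(1e-3, 0.030, 1, 0.98)
  expect_equal(half$e_a_mol, dose$e_a_mol / 2)
  expect_error(applied_excess_moles(0, 0.030, 2, 0.98), "invalid dose")
  expect_error(applied_excess_moles(1e-3, 0.030, 2, 0.001), "invalid dose")
})

test_that("percent retention is the dose share and additive over pools", {
  dose <- applied_excess_moles(1e-3, 0.030, 2, 0.98)
  expect_equal(percent_retention(dose$e_a_mol, dose), 100)
  expect_equal(percent_retention(5.858e-6, 58.58e-6), 10.0, tolerance = 1e-3)
  expect_identical(percent_retention(0, dose), 0)
  parts <- c(1e-6, 3e-6, 0.5e-6)
  expect_equal(percent_retention(sum(parts), dose),
               sum(percent_retention(parts, dose)))
  expect_error(percent_retention(1e-6, 0), "division by zero")
  expect_warning(r <- percent_retention(-1e-9, dose), "clamped")
  expect_identical(r, 0)
})

test_that("mass-based pool 15N content scales with atom% excess and TN", {
  expect_identical(pool_15N_content(0, 10), 0)
  expect_equal(pool_15N_content(0.5, 10), 0.05)
  expect_equal(pool_15N_content(0.5, 5), pool_15N_content(0.5, 10) / 2)
  expect_error(pool_15N_content(0.5, -1), "invalid pool")
})
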