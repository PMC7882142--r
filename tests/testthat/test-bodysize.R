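# Proportional body-length estimation: the worked elasmosaurid chain and the
# estimator's algebraic properties.

test_that("part/whole fractions reproduce the reference-taxon values", {
  expect_equal(fraction_from_lengths(1216, 4299), 0.283)
  expect_equal(fraction_from_lengths(1860, 4180), 0.445)
  expect_equal(fraction_from_lengths(1632, 3627), 0.450)
  expect_equal(fraction_from_lengths(123, 246), 0.500)
  expect_error(fraction_from_lengths(300, 300), "smaller")
  expect_error(fraction_from_lengths(-1, 300), "positive")
})

test_that("caudal extrapolation from the trunk matches the worked example", {
  expect_equal(caudal_from_fraction(1398, 0.283), 552)
  expect_equal(caudal_from_fraction(1398, 0.450), 1144)
  expect_equal(caudal_from_fraction(1700, 0.5), 1700) # f = 1/2: caudal = trunk
  expect_error(caudal_from_fraction(1398, 1), "inside")
  expect_error(caudal_from_fraction(1398, 0), "inside")
})

test_that("postcranial extrapolation and isometric scaling match the chain", {
  expect_equal(round_half_up(postcranial_from_postcervical(2246, 0.607) / 1000, 1), 3.7)
  expect_equal(round_half_up(postcranial_from_postcervical(2246, 0.375) / 1000, 1), 6.0)
  expect_equal(postcranial_from_postcervical(1234, 1), 1234)
  expect_error(postcranial_from_postcervical(1234, 0), "fraction")
  expect_equal(isometric_scale(5.2, 1.32), 6.9)
  expect_equal(isometric_scale(4.4, 1), 4.4)
  expect_equal(isometric_scale(2.0, 0.5), 1.0)
})

test_that("the full chained estimate reproduces the published worked example", {
  est <- estimate_body_size(
    specimen_measurements(1398, 400, 300, scale_ratio_to_largest = 1.32),
    reference_proportions()
  )
  expect_equal(unname(est$caudal_range_mm), c(552, 1144))
  expect_equal(est$caudal_avg_mm, 848)
  expect_equal(est$postcervical_mm, 2246)
  expect_equal(unname(est$postcranial_range_m), c(3.7, 6.0))
  expect_equal(unname(est$total_range_m), c(4.0, 6.3))
  expect_equal(est$total_avg_m, 5.2)
  expect_equal(est$scaled_total_m, 6.9)
  # every step is on the provenance trail
  expect_true(all(c("caudal_low_mm", "postcervical_mm", "total_avg_m",
                    "scaled_total_m") %in% est$provenance$step))
})

test_that("a single proportion per part kind collapses ranges to a point", {
  props <- list(
    comparative_proportion("X", "caudal_of_postcervical", 350, 1000),
    comparative_proportion("Y", "neck_of_postcranial", 400, 1000)
  )
  est <- estimate_body_size(specimen_measurements(1500, 300, 250), props)
  expect_equal(est$caudal_range_mm[["low"]], est$caudal_range_mm[["high"]])
  expect_equal(est$caudal_avg_mm, est$caudal_range_mm[["low"]])
  expect_equal(est$total_range_m[["low"]], est$total_range_m[["high"]])
  expect_equal(est$total_avg_m, est$total_range_m[["low"]])
})

test_that("missing part kinds and malformed inputs are rejected", {
  caud_only <- list(comparative_proportion("X", "caudal_of_postcervical", 350, 1000))
  expect_error(estimate_body_size(specimen_measurements(1500, 300, 250),
                                  caud_only), "neck_of_postcranial")
  expect_error(specimen_measurements(-1, 300, 250), "positive")
  expect_error(specimen_measurements(1500, 300, 250, 0.9), ">= 1")
})

test_that("caudal extrapolation round-trips through the fraction", {
  for (trunk in c(2500, 5000, 12000)) {
    for (f in seq(0.05, 0.9, by = 0.05)) {
      caud <- caudal_from_fraction(trunk, f)
      expect_equal(fraction_from_lengths(caud, trunk + caud), f)
    }
  }
})

test_that("the chain is monotone in its arguments", {
  f <- seq(0.1, 0.9, by = 0.1)
  expect_true(all(diff(vapply(f, caudal_from_fraction, 0,
                              trunk_mm = 1398)) > 0))
  trunks <- seq(500, 5000, by = 500)
  expect_true(all(diff(vapply(trunks, caudal_from_fraction, 0,
                              fraction = 0.35)) > 0))
  expect_true(all(diff(vapply(f, postcranial_from_postcervical,
                              0, postcervical_mm = 2246)) < 0))
})

test_that("noiseless synthetic skeletons are inverted up to reporting rounding", {
  for (seed in 1:50) {
    sim <- gen_specimen_proportions(seed = seed,
                                    trunk_mm = 500 + 40 * seed,
                                    caudal_fraction = 0.2 + 0.01 * (seed %% 30),
                                    neck_fraction = 0.3 + 0.01 * (seed %% 25),
                                    noise_sd = 0)
    est <- estimate_body_size(sim$spec, sim$props)
    # metre reporting rounds to 0.1 m; the midpoint construction adds at most
    # one further half-unit
    expect_lt(abs(est$total_avg_m - sim$true_total_m), 0.1 + 1e-9)
  }
})
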