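test_that("atom fraction excess subtracts the baseline and clamps at zero", {
  expect_equal(atom_fraction_excess(1.07, 1.07), 0)
  expect_equal(atom_fraction_excess(2.07, 1.07), 0.01)
  expect_warning(afe <- atom_fraction_excess(1.0, 1.07), "clamped")
  expect_equal(afe, 0)
  expect_error(atom_fraction_excess(101, 1), "\\[0, 100\\]")
})

test_that("secreted carbon flux is the afe x carbon x dry-mass product", {
  expect_equal(secreted_carbon_flux(0, 40, 10), 0)
  expect_equal(secreted_carbon_flux(0.01, 40, 10), 0.04)
  # linear in each argument
  base <- secreted_carbon_flux(0.004, 37, 12)
  expect_equal(secreted_carbon_flux(0.008, 37, 12), 2 * base)
  expect_equal(secreted_carbon_flux(0.004, 37, 24), 2 * base)
  expect_error(secreted_carbon_flux(1.5, 40, 10), "afe")
  expect_error(secreted_carbon_flux(0.01, 40, 0), "dry_weight")
})

test_that("elemental stoichiometry and water content follow their definitions", {
  expect_equal(cn_ratio(40, 5), 8)
  expect_error(cn_ratio(40, 0), "pct_N")
  expect_equal(water_content(10, 2), 80)
  expect_equal(water_content(3, 3), 0)
  expect_error(water_content(2, 3), "exceeds")
  w <- water_content(runif(20, 1, 5), runif(20, 0, 1))
  expect_true(all(w >= 0 & w <= 100))
})

test_that("ddCt fold change matches closed forms and is plate-offset invariant", {
  rec <- data.frame(ct_target = c(20, 21, 20, 21),
                    ct_housekeeping = c(15, 16, 15, 16),
                    group = c("CD", "CD", "FFD", "FFD"))
  expect_equal(ddct_fold_change(rec, "CD"), 1)

  rec$ct_target[rec$group == "FFD"] <- rec$ct_target[rec$group == "FFD"] + 1
  expect_equal(ddct_fold_change(rec, "CD"), 0.5)
  rec$ct_target[rec$group == "FFD"] <- rec$ct_target[rec$group == "FFD"] - 3
  expect_equal(ddct_fold_change(rec, "CD"), 4)

  shifted <- rec
  shifted$ct_target <- shifted$ct_target + 2.5
  shifted$ct_housekeeping <- shifted$ct_housekeeping + 2.5
  expect_equal(ddct_fold_change(shifted, "CD"), ddct_fold_change(rec, "CD"))
  expect_error(ddct_fold_change(rec, "chow"), "not present")
})

test_that("tracer report recovers the configured enrichment from the 12C controls", {
  cfg <- default_scenario()
  st <- generate_study(cfg, seed = 19)
  tr <- tracer_report(st)
  for (comp in c("cecum", "colon")) {
    for (d in c("CD", "FFD")) {
      got <- mean(tr$afe_13C[tr$compartment == comp & tr$diet == d]) * 100
      want <- cfg$tracer$excess_atom_pct_13C[[d]][[comp]]
      expect_equal(got, want, tolerance = 3 * cfg$tracer$measurement_cv * want)
    }
  }
})

test_that("fiber-deprived mice secrete less labeled carbon", {
  lower <- sapply(1:20, function(s) {
    st <- generate_study(small_scenario(), seed = 300 + s)
    tr <- tracer_report(st)
    agg <- tapply(tr$flux_mg_13C, tr$diet, mean)
    agg["FFD"] < agg["CD"]
  })
  expect_gte(mean(lower), 0.95)
})

test_that("ddCt estimator recovers a true four-fold reduction", {
  set.seed(55)
  est <- replicate(100, {
    rec <- data.frame(
      ct_target = c(rnorm(6, 20, 0.2), rnorm(6, 22, 0.2)),
      ct_housekeeping = rnorm(12, 15, 0.2),
      group = rep(c("CD", "FFD"), each = 6))
    ddct_fold_change(rec, "CD")
  })
  expect_gte(mean(est >= 0.15 & est <= 0.40), 0.9)
})
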