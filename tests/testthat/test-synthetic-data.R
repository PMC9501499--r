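test_that("generation is deterministic given the seed", {
  cfg <- small_scenario()
  a <- generate_study(cfg, seed = 11)
  b <- generate_study(cfg, seed = 11)
  expect_identical(a$counts, b$counts)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$tracer, b$tracer)
  c <- generate_study(cfg, seed = 12)
  expect_false(identical(a$counts, c$counts))
})

test_that("degenerate configurations are rejected", {
  expect_error(default_scenario(n_mice_per_diet = 1), "n_mice_per_diet")
  expect_error(default_scenario(diet_load_ratio = 0), "diet_load_ratio")
  cfg <- default_scenario()
  cfg$guilds$fiber_responsive$total_fraction <- 0.5
  expect_error(generate_study(cfg), "sum to 1")
})

test_that("read sampling follows the copy-number-weighted multinomial model", {
  set.seed(5)
  # closed form: p_j = l_j c_j / sum l_k c_k = (1*1, 1*2)/3
  r <- sample_reads(c(1, 1), c(1, 2), depth = 2e5)
  expect_equal(sum(r), 2e5)
  expect_equal(r / 2e5, c(1 / 3, 2 / 3), tolerance = 0.01)

  expect_identical(sample_reads(c(1, 1), c(1, 1), 0), c(0L, 0L))
  expect_identical(sample_reads(5, 3, 100), 100L)
  expect_error(sample_reads(c(0, 0), c(1, 1), 10), "zero")
})

test_that("observed relative abundances converge to copy-number-weighted truth", {
  cfg <- noise_free_scenario(small_scenario())
  cfg$exact_reads <- FALSE
  cfg$seq_depth_mean <- 1e6
  cfg$seq_depth_dispersion <- 1e9  # essentially fixed depth
  st <- generate_study(cfg, seed = 21)
  gt <- st$ground_truth
  i <- which(st$metadata$compartment == "cecum")[1]
  p_expected <- gt$true_abs_per_g[i, ] * st$copy_numbers /
    sum(gt$true_abs_per_g[i, ] * st$copy_numbers)
  p_obs <- st$counts[i, ] / sum(st$counts[i, ])
  expect_lt(max(abs(p_obs - p_expected)), 0.005)
})

test_that("planted ground-truth fold changes follow the scenario algebra", {
  cfg <- default_scenario(diet_load_ratio = 0.2)
  st <- generate_study(cfg, seed = 2)
  gt <- st$ground_truth$true_l2fc
  akk <- gt[gt$guild == "mucus_degrader", ]
  expect_equal(akk$l2fc_absolute, 0)
  expect_equal(akk$l2fc_relative, -log2(0.2), tolerance = 1e-12)
  # total-load ratio is exact: sum_j f_j m_j = rho
  taxa <- st$ground_truth$taxa
  expect_equal(sum(taxa$baseline_fraction * taxa$ffd_multiplier), 0.2,
               tolerance = 1e-12)
  expect_true(all(taxa$baseline_fraction > 0))
  expect_equal(sum(taxa$baseline_fraction), 1, tolerance = 1e-9)
})

test_that("inverse consistency: correction recovers true proportions from expected reads", {
  cfg <- noise_free_scenario(small_scenario())
  st <- generate_study(cfg, seed = 31)
  for (i in c(1, 5, 9)) {
    rel <- copy_number_correct(st$counts[i, ], st$copy_numbers)
    truth <- st$ground_truth$true_abs_per_g[i, ] /
      sum(st$ground_truth$true_abs_per_g[i, ])
    expect_equal(rel, truth, tolerance = 1e-12)
  }
})

test_that("flow-cytometry replicates average to the recorded density", {
  st <- generate_study(small_scenario(), seed = 41)
  reps <- st$cell_replicates
  means <- tapply(reps$cells_per_g, reps$sample_id, mean)
  expect_equal(as.numeric(means[st$metadata$sample_id]),
               st$metadata$cell_density_cells_per_g, tolerance = 1e-12)
})
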