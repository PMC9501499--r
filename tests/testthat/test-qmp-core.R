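test_that("copy-number correction matches its closed form", {
  expect_equal(copy_number_correct(c(10, 10), c(1, 2)), c(2 / 3, 1 / 3))
  # equal copy numbers: raw read fractions
  expect_equal(copy_number_correct(c(3, 1), c(4, 4)), c(0.75, 0.25))
  # 5/1 = 5, 0/4 = 0, 15/3 = 5 -> [0.5, 0, 0.5]
  expect_equal(copy_number_correct(c(5, 0, 15), c(1, 4, 3)),
               c(0.5, 0, 0.5))
  expect_error(copy_number_correct(c(0, 0), c(1, 1)), "zero reads")
  expect_error(copy_number_correct(c(1, 1), c(1, 0)), "positive")
})

test_that("correction is scale- and permutation-equivariant", {
  set.seed(7)
  reads <- rpois(20, 50)
  cn <- runif(20, 1, 10)
  base <- copy_number_correct(reads, cn)
  expect_equal(copy_number_correct(reads, 7.3 * cn), base)
  p <- sample(20)
  expect_equal(copy_number_correct(reads[p], cn[p]), base[p])
})

test_that("per-gram and per-compartment scaling behave algebraically", {
  expect_equal(absolute_per_gram(c(0.25, 0.75), 4e9), c(1e9, 3e9))
  expect_equal(absolute_per_gram(c(0.5, 0.5), 0), c(0, 0))
  expect_equal(absolute_per_gram(rep(0.2, 5), 1e10), rep(2e9, 5))
  expect_error(absolute_per_gram(c(0.3, 0.3), 1e9), "sum to 1")
  expect_error(absolute_per_gram(c(0.5, 0.5), -1), "non-negative")

  expect_equal(load_per_compartment(c(1e9, 3e9), 0.5), c(5e8, 1.5e9))
  expect_equal(load_per_compartment(c(1e9, 3e9), 0), c(0, 0))
  expect_error(load_per_compartment(c(1e9), 0.5, compartment = "feces"),
               "feces")

  # composition: load sums to density x weight exactly
  rel <- copy_number_correct(c(12, 5, 3), c(2, 7, 1.5))
  load <- load_per_compartment(absolute_per_gram(rel, 3.7e10), 0.42)
  expect_equal(sum(load), 3.7e10 * 0.42)
})

test_that("sample load equals cell density times wet weight for every sample", {
  st <- generate_study(small_scenario(), seed = 3)
  pr <- qmp_profile(st)
  md <- pr$metadata
  term <- md$compartment != "feces"
  expect_equal(
    unname(sample_load(pr)[term]),
    md$cell_density_cells_per_g[term] * md$content_wet_weight_g[term],
    tolerance = 1e-9)
  # feces have no per-compartment load
  expect_true(all(is.na(sample_load(pr)[!term])))
  # relative rows sum to 1
  expect_equal(unname(rowSums(pr$rel_corrected)),
               rep(1, nrow(pr$rel_corrected)), tolerance = 1e-9)
})

test_that("noise-free pipeline recovers true loads exactly", {
  st <- generate_study(noise_free_scenario(small_scenario()), seed = 13)
  pr <- qmp_profile(st)
  term <- st$metadata$compartment != "feces"
  est <- pr$abs_per_compartment[term, ]
  tru <- st$ground_truth$true_load_per_compartment[term, ]
  expect_lt(max(abs(est - tru) / tru), 1e-6)
})

test_that("multinomial sampling leaves compartment loads unbiased", {
  # one fixed sample; only sequencing noise across seeds
  set.seed(99)
  loads <- c(5, 3, 1.5, 0.4, 0.1) * 1e9
  cn <- c(3, 1.2, 7, 2.5, 4.4)
  density <- sum(loads)
  est <- replicate(50, {
    reads <- sample_reads(loads, cn, 50000)
    absolute_per_gram(copy_number_correct(reads, cn), density)
  })
  rel_err <- abs(rowMeans(est) - loads) / loads
  expect_lt(mean(rel_err), 0.02)
})
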