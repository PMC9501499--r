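test_that("alpha-diversity indices match their closed forms", {
  expect_equal(shannon_index(rep(5, 4)), log(4))
  expect_equal(simpson_index(rep(5, 4)), 0.75)
  expect_equal(observed_richness(rep(5, 4)), 4)

  expect_equal(shannon_index(c(0, 10, 0)), 0)
  expect_equal(simpson_index(c(0, 10, 0)), 0)
  expect_equal(observed_richness(c(0, 10, 0)), 1)

  # hand computation for [1, 1, 2]
  p <- c(0.25, 0.25, 0.5)
  expect_equal(shannon_index(c(1, 1, 2)), -sum(p * log(p)))

  expect_error(shannon_index(c(0, 0)), "empty")
})

test_that("indices are invariant to taxon order and integer count scaling", {
  x <- c(4, 1, 0, 7, 2)
  expect_equal(shannon_index(x), shannon_index(rev(x)))
  expect_equal(shannon_index(x), shannon_index(3L * x))
  expect_equal(simpson_index(x), simpson_index(sample(x)))
  expect_equal(simpson_index(x), simpson_index(10L * x))
})

test_that("rarefaction draws without replacement at the requested depth", {
  x <- c(a = 100, b = 50, c = 3, d = 0)
  expect_identical(rarefy_counts(x, sum(x)), as.integer(x))
  expect_identical(rarefy_counts(c(200), 100), 100L)
  expect_error(rarefy_counts(x, 1000), "exceeds library size")

  set.seed(1)
  r <- rarefy_counts(x, 60)
  expect_equal(sum(r), 60)
  expect_true(all(r <= x))
  expect_identical(r[4], 0L)
})

test_that("expected rarefied counts equal depth times the taxon proportion", {
  x <- c(120, 60, 15, 5)
  depth <- 50
  set.seed(42)
  draws <- replicate(1000, rarefy_counts(x, depth))
  p <- x / sum(x)
  expected <- depth * p
  # hypergeometric SE of the mean over 1000 draws
  se <- sqrt(depth * p * (1 - p) * (sum(x) - depth) / (sum(x) - 1) / 1000)
  expect_true(all(abs(rowMeans(draws) - expected) < 3 * se + 1e-9))
})

test_that("Bray-Curtis matches its formula and bounds", {
  expect_equal(bray_curtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(bray_curtis(c(5, 0), c(0, 3)), 1)
  expect_equal(bray_curtis(c(1, 2), c(3, 0)), 2 / 3)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  expect_error(bray_curtis(c(-1, 2), c(1, 1)), "non-negative")
})

test_that("PCoA recovers geometry of known configurations", {
  # points on a line: one dominant axis, gaps recovered up to sign
  pts <- c(0, 1, 3, 7)
  d <- as.matrix(dist(pts))
  ord <- pcoa_ordination(d)
  expect_gt(ord$proportion_explained[1], 0.999)
  ax1 <- ord$coordinates[, 1]
  if (cor(ax1, pts) < 0) ax1 <- -ax1
  expect_equal(unname(diff(ax1)), diff(pts), tolerance = 1e-9)

  # three mutually equidistant points: first two eigenvalues equal
  d3 <- matrix(1, 3, 3) - diag(3)
  ord3 <- pcoa_ordination(d3)
  expect_equal(ord3$eigenvalues[1], ord3$eigenvalues[2], tolerance = 1e-9)

  # duplicate samples are coincident
  m <- rbind(a = c(1, 0), b = c(1, 0), c = c(0, 1))
  ordd <- pcoa_ordination(as.matrix(bray_curtis_matrix(m)))
  expect_equal(ordd$coordinates[1, ], ordd$coordinates[2, ],
               tolerance = 1e-9)

  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(pcoa_ordination(bad), "symmetric")
})

test_that("PERMANOVA separates identical groups maximally and rejects one group", {
  mat <- rbind(matrix(rep(c(10, 0, 0), 4), 4, byrow = TRUE),
               matrix(rep(c(0, 10, 0), 4), 4, byrow = TRUE))
  d <- bray_curtis_matrix(mat)
  set.seed(8)
  res <- permanova(d, rep(c("A", "B"), each = 4), n_permutations = 199)
  # permutations preserving the 4+4 partition of identical samples tie
  # with the observed F, so the exact p is 2 * 4!4!/8! ~= 0.029, not the
  # minimum attainable 1/200
  expect_gte(res$p_value[1], 1 / 200)
  expect_lte(res$p_value[1], 0.05)
  expect_gt(res$R2[1], 0.99)
  expect_error(permanova(d, rep("A", 8)), ">= 2 groups")
})

test_that("PERMANOVA observed statistics agree with vegan::adonis2", {
  set.seed(12)
  mat <- matrix(rpois(15 * 6, 30), 15, 6)
  md <- data.frame(g = rep(c("A", "B", "C"), 5),
                   h = rep(c("x", "y"), length.out = 15))
  d <- bray_curtis_matrix(mat)
  mine <- permanova(d, md, n_permutations = 99)
  ref <- vegan::adonis2(d ~ g + h, data = md, permutations = 99,
                        by = "terms")
  expect_equal(mine$pseudo_F[1:2], ref$F[1:2], tolerance = 1e-10)
  expect_equal(mine$R2[1:2], ref$R2[1:2], tolerance = 1e-10)
  expect_equal(mine$SS, ref$SumOfSqs[1:3], tolerance = 1e-10)
})

test_that("PERMANOVA R2 for the diet effect grows with load-ratio deviation", {
  r2_for <- function(ratio) {
    st <- generate_study(null_scenario(ratio, n_mice_per_diet = 5,
                                       seq_depth_mean = 8000), seed = 17)
    pr <- qmp_profile(st)
    idx <- which(pr$metadata$compartment == "cecum")
    d <- bray_curtis_matrix(pr$abs_per_compartment[idx, ])
    permanova(d, pr$metadata$diet[idx], n_permutations = 99)$R2[1]
  }
  set.seed(17)
  r2 <- c(r2_for(0.95), r2_for(0.5), r2_for(0.2))
  expect_true(all(diff(r2) > 0))
})
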