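test_that("top-taxa selection ranks by pooled mean with lexicographic ties", {
  mat <- cbind(zeta = c(4, 4), alpha = c(4, 4), mid = c(2, 2))
  rownames(mat) <- c("s1", "s2")
  expect_equal(select_top_taxa(mat, 2), c("alpha", "zeta"))
  expect_warning(top <- select_top_taxa(mat, 50), "returning all")
  expect_equal(top, c("alpha", "zeta", "mid"))
  expect_error(select_top_taxa(mat[, 0], 5), "empty")
})

test_that("log2 fold change uses group means with pseudocount", {
  expect_equal(l2fc(c(2, 4), c(1, 5), pseudocount = 1), 0)
  expect_equal(l2fc(c(0, 0), c(0, 0), pseudocount = 0.5), 0)
  expect_equal(l2fc(3, 1, pseudocount = 1), 1)  # log2(4/2)
  expect_error(l2fc(c(-1, 2), c(1, 1), 1), "non-negative")
})

test_that("diet test is a two-sample t-test with sane degenerate behavior", {
  expect_equal(diet_test(c(2, 2, 2), c(2, 2, 2)), 1)
  p <- diet_test(c(1, 2, 3), c(101, 102, 103), var_equal = TRUE)
  expect_lt(p, 1e-6)
  # matches the closed-form Student statistic t = -100 / sqrt(2/3)
  tt <- t.test(c(1, 2, 3), c(101, 102, 103), var.equal = TRUE)
  expect_equal(unname(tt$statistic), -100 / sqrt(2 / 3), tolerance = 1e-10)
  expect_warning(pna <- diet_test(1, c(1, 2)), "fewer than 2")
  expect_true(is.na(pna))
})

test_that("t-test p-values are uniform under a permuted-label null", {
  set.seed(31)
  p <- replicate(1000, diet_test(rnorm(10), rnorm(10)))
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the planted mucus degrader is flagged as a relative-only increase", {
  st <- generate_study(default_scenario(), seed = 5)
  pr <- qmp_profile(filter_min_reads(st))
  rep <- build_l2fc_report(pr)
  akk <- rep[rep$taxon_id == "Akkermansia" & rep$compartment == "cecum", ]
  expect_equal(akk$artifact_flag, "relative_only_increase")
  expect_gt(akk$l2fc_relative, 1.5)
  expect_lt(abs(akk$l2fc_absolute), 1)
  # flag invariant holds for every record
  with(rep, expect_equal(
    artifact_flag == "relative_only_increase",
    significant_relative & l2fc_relative > 0 & !significant_absolute))
})

test_that("swapping diet labels negates every fold change", {
  st <- generate_study(small_scenario(), seed = 6)
  pr <- qmp_profile(filter_min_reads(st))
  rep1 <- build_l2fc_report(pr)
  pr2 <- pr
  pr2$metadata$diet <- ifelse(pr$metadata$diet == "CD", "FFD", "CD")
  rep2 <- build_l2fc_report(pr2)
  m <- merge(rep1, rep2, by = c("taxon_id", "compartment"))
  expect_equal(m$l2fc_absolute.x, -m$l2fc_absolute.y, tolerance = 1e-12)
  expect_equal(m$l2fc_relative.x, -m$l2fc_relative.y, tolerance = 1e-12)
  expect_equal(m$p_absolute.x, m$p_absolute.y, tolerance = 1e-12)
})

test_that("a no-effect scenario yields almost no significant records", {
  clean <- sapply(1:20, function(s) {
    st <- generate_study(null_scenario(1, n_mice_per_diet = 5,
                                       seq_depth_mean = 5000), seed = 100 + s)
    rep <- build_l2fc_report(qmp_profile(filter_min_reads(st)))
    # one family per compartment x scale: fraction with zero rejections
    fam <- c(tapply(rep$significant_absolute, rep$compartment, any),
             tapply(rep$significant_relative, rep$compartment, any))
    mean(!fam)
  })
  expect_gte(mean(clean), 0.9)
})

test_that("a true doubling on constant total load is significant on both scales", {
  # cohort at the real study's scale (~19 mice per diet): with a single
  # true positive among 50 taxa, BH demands a raw p ~ 0.001
  cfg <- null_scenario(1, n_mice_per_diet = 19)
  cfg$guilds$mucus_degrader$ffd_multiplier <- 2  # others solved below 1
  st <- generate_study(cfg, seed = 23)
  rep <- build_l2fc_report(qmp_profile(filter_min_reads(st)))
  akk <- rep[rep$taxon_id == "Akkermansia" & rep$compartment == "cecum", ]
  expect_true(akk$significant_absolute)
  expect_true(akk$significant_relative)
  expect_equal(akk$artifact_flag, "none")
  expect_equal(akk$l2fc_absolute, 1, tolerance = 0.45)
})

test_that("Kendall's W spans perfect concordance to antithesis", {
  base <- c(3, 1, 4, 2, 5)
  expect_equal(kendall_w(rbind(base, base * 2, base + 10))$W, 1)
  expect_equal(kendall_w(rbind(base, -base))$W, 0)
  expect_error(kendall_w(rbind(rep(1, 4), rep(2, 4))), "constant")
})

test_that("Kendall's W matches the rank-sum formula and vegan", {
  set.seed(9)
  mat <- matrix(sample(1:12), 3, 4)  # untied 3 judges x 4 objects
  m <- nrow(mat); n <- ncol(mat)
  r_sums <- colSums(t(apply(mat, 1, rank)))
  w_direct <- (12 * sum(r_sums^2) - 3 * m^2 * n * (n + 1)^2) /
    (m^2 * n * (n^2 - 1))
  res <- kendall_w(mat)
  expect_equal(res$W, w_direct, tolerance = 1e-12)
  ref <- vegan::kendall.global(t(mat))
  expect_equal(res$W, ref$Concordance_analysis["W", 1], tolerance = 1e-10)

  # tie correction agrees with vegan on tied data
  mat_t <- matrix(c(1, 2, 2, 4, 3, 3, 1, 2, 5, 5, 2, 1), 3, 4, byrow = TRUE)
  expect_equal(kendall_w(mat_t)$W,
               vegan::kendall.global(t(mat_t))$Concordance_analysis["W", 1],
               tolerance = 1e-10)
})

test_that("planted anti-correlated blocks are recovered as two guilds", {
  set.seed(77)
  pb <- planted_blocks()
  g <- guild_cluster(pb$mat, diet = rep(c("CD", "FFD"), 15))
  expect_equal(g$k_selected, 2)
  expect_equal(two_cluster_agreement(unname(g$clusters), pb$truth), 1)
})

test_that("guild clustering is invariant to monotone abundance transforms", {
  set.seed(78)
  pb <- planted_blocks()
  diet <- rep(c("CD", "FFD"), 15)
  g1 <- guild_cluster(pb$mat, diet)
  g2 <- guild_cluster(pb$mat^3, diet)  # monotone, rank-preserving
  expect_identical(g1$clusters, g2$clusters)
  expect_equal(g1$kendall_W, g2$kendall_W)
  expect_warning(
    guild_cluster(cbind(pb$mat, const = 1), diet), "constant")
})
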