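# Shared fixtures and independent oracles used across the suite.

# All permutations of 1..n (recursive enumeration) for exact permutation
# tests; n is kept tiny by the callers.
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- setdiff(seq_len(n), k)
    cbind(k, matrix(rest[sub], nrow(sub), n - 1))
  }))
}

# A tiny three-sample, two-taxon study built in code.
tiny_study <- function(libs = c(1500, 2000, 2500)) {
  counts <- rbind(
    s1 = c(taxA = libs[1] - 500, taxB = 500),
    s2 = c(taxA = libs[2] - 800, taxB = 800),
    s3 = c(taxA = libs[3] - 100, taxB = 100)
  )
  md <- data.frame(
    sample_id = rownames(counts),
    mouse_id = c("m1", "m2", "m3"),
    sex = "F",
    diet = c("CD", "FFD", "CD"),
    day = 7L,
    compartment = "cecum",
    content_wet_weight_g = c(0.3, 0.25, 0.35),
    content_dry_weight_g = c(0.08, 0.07, 0.09),
    tissue_weight_g = 0.2,
    body_weight_g = 25,
    cell_density_cells_per_g = c(1e10, 4e9, 2e10),
    stringsAsFactors = FALSE
  )
  qmp_study(counts, md, c(taxA = 2, taxB = 5))
}

# Small, fast variant of the default scenario.
small_scenario <- function(...) {
  default_scenario(n_mice_per_diet = 4, seq_depth_mean = 5000, ...)
}

# Null scenario: every guild multiplier solved, so all taxa scale by
# diet_load_ratio; with ratio 1 there is no diet effect on any scale.
null_scenario <- function(ratio = 1, ...) {
  cfg <- default_scenario(diet_load_ratio = ratio, ...)
  for (g in names(cfg$guilds)) cfg$guilds[[g]]$ffd_multiplier <- NULL
  cfg
}

# Two anti-correlated planted blocks of taxon profiles (positive values;
# ranks carry the block structure).
planted_blocks <- function(n_per_block = 25, n_samples = 30, noise_sd = 0.3) {
  z <- stats::rnorm(n_samples)
  block <- function(sign) {
    sapply(seq_len(n_per_block), function(i)
      exp(sign * z + stats::rnorm(n_samples, sd = noise_sd)))
  }
  mat <- cbind(block(1), block(-1))
  colnames(mat) <- sprintf("tax%02d", seq_len(2 * n_per_block))
  rownames(mat) <- sprintf("s%02d", seq_len(n_samples))
  list(mat = mat, truth = rep(1:2, each = n_per_block))
}

# Agreement of a 2-cluster assignment with the planted labels, under the
# best of the two label matchings.
two_cluster_agreement <- function(assign, truth) {
  max(mean(assign == truth), mean(assign != truth))
}

# Hand sums-of-squares oracle for a balanced two-way layout.
hand_ss <- function(v, a, b) {
  gm <- mean(v)
  ma <- tapply(v, a, mean); mb <- tapply(v, b, mean)
  mab <- tapply(v, interaction(a, b), mean)
  n_a <- table(a); n_b <- table(b); n_ab <- table(interaction(a, b))
  ss_a <- sum(n_a * (ma - gm)^2)
  ss_b <- sum(n_b * (mb - gm)^2)
  ss_cells <- sum(n_ab * (mab - gm)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_res <- sum((v - mab[interaction(a, b)])^2)
  c(A = ss_a, B = ss_b, AB = ss_ab, res = ss_res)
}
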