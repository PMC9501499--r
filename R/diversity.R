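# Rarefaction, alpha diversity, Bray-Curtis / PCoA, and PERMANOVA.
# Alpha-diversity indices and Bray-Curtis go through vegan; PCoA through
# ape. PERMANOVA is implemented here (trace form of the pseudo-F on the
# Gower-centered dissimilarity matrix) so that exhaustive-permutation
# oracles and vegan::adonis2 can both serve as independent cross-checks.

#' Rarefy a count vector to fixed depth
#'
#' Draws `depth` reads without replacement from the sample, so the
#' rarefied count of taxon j is hypergeometric with expectation
#' `depth * counts_j / sum(counts)`.
#'
#' @param counts non-negative integer read counts.
#' @param depth number of reads to draw; must not exceed the library
#'   size (filter low-depth samples first, see [filter_min_reads()]).
#' @return integer vector summing to `depth`, elementwise `<= counts`.
#' @export
rarefy_counts <- function(counts, depth = 1763) {
  stopifnot(depth >= 0)
  if (any(counts < 0) || any(abs(counts - round(counts)) > 1e-8)) {
    stop("counts must be non-negative integers")
  }
  total <- sum(counts)
  if (depth > total) {
    stop("depth (", depth, ") exceeds library size (", total,
         "); filter samples to a minimum library size first")
  }
  if (depth == total) return(as.integer(round(counts)))
  drawn <- sample.int(total, depth)
  # map read indices back to taxa via cumulative library layout
  breaks <- c(0, cumsum(counts))
  as.integer(tabulate(findInterval(drawn, breaks, left.open = TRUE),
                      nbins = length(counts)))
}

#' Observed richness
#' @param counts non-negative abundance vector with at least one read.
#' @return number of taxa with positive count.
#' @export
observed_richness <- function(counts) {
  if (sum(counts) <= 0) stop("empty sample")
  sum(counts > 0)
}

#' Shannon diversity (natural log)
#' @inheritParams observed_richness
#' @return `-sum(p log p)` over positive proportions.
#' @export
shannon_index <- function(counts) {
  if (sum(counts) <= 0) stop("empty sample")
  unname(vegan::diversity(counts, index = "shannon"))
}

#' Gini-Simpson index
#'
#' Reported in the `1 - sum(p^2)` form, bounded in \[0, 1\].
#' @inheritParams observed_richness
#' @export
simpson_index <- function(counts) {
  if (sum(counts) <= 0) stop("empty sample")
  unname(vegan::diversity(counts, index = "simpson"))
}

#' Per-sample alpha diversity at fixed rarefaction depth
#'
#' Rarefies every sample to `depth` (samples below `depth` reads are an
#' error; filter first) and computes observed richness, Shannon and
#' Gini-Simpson indices.
#'
#' @param counts samples x taxa integer matrix.
#' @param depth rarefaction depth (default 1763).
#' @return data.frame with columns `sample_id`, `observed_richness`,
#'   `shannon`, `simpson`, `rarefaction_depth`.
#' @export
alpha_diversity <- function(counts, depth = 1763) {
  rare <- t(apply(counts, 1, rarefy_counts, depth = depth))
  data.frame(
    sample_id = rownames(counts),
    observed_richness = apply(rare, 1, observed_richness),
    shannon = apply(rare, 1, shannon_index),
    simpson = apply(rare, 1, simpson_index),
    rarefaction_depth = depth,
    stringsAsFactors = FALSE
  )
}

#' Bray-Curtis dissimilarity between two samples
#'
#' `sum|x - y| / sum(x + y)`, in \[0, 1\]; a semimetric (the triangle
#' inequality may fail).
#'
#' @param x,y non-negative abundance vectors of equal length, not both
#'   all-zero.
#' @export
bray_curtis <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (any(x < 0) || any(y < 0)) stop("abundances must be non-negative")
  if (sum(x) + sum(y) <= 0) stop("both samples are all-zero")
  as.numeric(vegan::vegdist(rbind(x, y), method = "bray"))
}

#' Bray-Curtis dissimilarity matrix
#' @param mat samples x taxa non-negative matrix (rows not all-zero).
#' @return a `dist` object.
#' @export
bray_curtis_matrix <- function(mat) {
  if (any(mat < 0)) stop("abundances must be non-negative")
  if (any(rowSums(mat) <= 0)) stop("all-zero sample in matrix")
  vegan::vegdist(mat, method = "bray")
}

#' Principal coordinates analysis
#'
#' Gower double-centering and eigen-decomposition of a dissimilarity
#' matrix (via [ape::pcoa()]); axes ordered by eigenvalue.
#'
#' @param d a `dist` or a symmetric matrix with zero diagonal.
#' @return list with `coordinates` (samples x axes), `eigenvalues`, and
#'   `proportion_explained` (relative to the sum of positive
#'   eigenvalues).
#' @export
pcoa_ordination <- function(d) {
  m <- as.matrix(d)
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-12))) {
    stop("dissimilarity matrix must be symmetric")
  }
  if (any(abs(diag(m)) > 1e-12)) stop("dissimilarity diagonal must be 0")
  res <- ape::pcoa(stats::as.dist(m))
  ev <- res$values$Eigenvalues
  pos <- ev > 1e-12 * max(abs(ev))
  coords <- res$vectors
  list(
    coordinates = coords,
    eigenvalues = ev,
    proportion_explained = ifelse(ev > 0, ev / sum(ev[pos]), 0)
  )
}

# Gower-centered inner-product matrix of a dissimilarity matrix:
# G = (I - 11'/n) (-D^2/2) (I - 11'/n). tr(G) is the total sum of
# squares; projecting G onto design hat matrices partitions it.
gower_center <- function(d) {
  a <- -0.5 * as.matrix(d)^2
  n <- nrow(a)
  c1 <- a - matrix(colMeans(a), n, n, byrow = TRUE)
  c1 - matrix(rowMeans(c1), n, n)
}

hat_matrix <- function(x) {
  q <- qr(x)
  qq <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  tcrossprod(qq)
}

#' PERMANOVA on a dissimilarity matrix
#'
#' Permutational multivariate analysis of variance: partitions the total
#' sum of squared dissimilarities among terms fitted sequentially
#' (Type I, in the order given), with a permutation p-value
#' `(#{F* >= F} + 1) / (n_perm + 1)`.
#'
#' @param d a `dist` or symmetric dissimilarity matrix.
#' @param factors data.frame (or vector, treated as one factor) of
#'   grouping factors, one row per sample, fitted in column order.
#' @param n_permutations number of random label permutations (>= 99);
#'   ignored if `permutations` is given.
#' @param permutations optional integer matrix of permutation index rows
#'   (e.g. all permutations, for an exact test); overrides
#'   `n_permutations`.
#' @return data.frame with one row per term plus a residual row:
#'   `df`, `SS`, `R2`, `pseudo_F`, `p_value`, `n_permutations`.
#' @export
permanova <- function(d, factors, n_permutations = 999,
                      permutations = NULL) {
  if (!is.data.frame(factors)) factors <- data.frame(group = factors)
  g <- gower_center(d)
  n <- nrow(g)
  if (nrow(factors) != n) stop("factors must have one row per sample")
  for (j in seq_along(factors)) {
    factors[[j]] <- factor(factors[[j]])
    if (nlevels(factors[[j]]) < 2) {
      stop("each grouping factor needs >= 2 groups")
    }
  }
  if (is.null(permutations) && n_permutations < 99) {
    stop("n_permutations must be >= 99")
  }

  terms <- names(factors)
  hats <- vector("list", length(terms))
  x <- matrix(1, n, 1)
  h_prev <- hat_matrix(x)
  rank_prev <- 1
  df <- numeric(length(terms))
  for (k in seq_along(terms)) {
    x <- cbind(x, stats::model.matrix(~ factors[[k]])[, -1, drop = FALSE])
    hats[[k]] <- hat_matrix(x)
    rank_k <- qr(x)$rank
    df[k] <- rank_k - rank_prev
    rank_prev <- rank_k
  }
  df_res <- n - rank_prev
  if (df_res < 1) stop("no residual degrees of freedom")

  ss_terms <- function(gm) {
    tot <- sum(diag(gm))
    tr <- vapply(hats, function(h) sum(h * gm), numeric(1))
    ss <- diff(c(sum(h_prev * gm), tr))
    list(ss = ss, ss_res = tot - tr[length(tr)], tot = tot)
  }
  obs <- ss_terms(g)
  f_obs <- (obs$ss / df) / (obs$ss_res / df_res)

  if (is.null(permutations)) {
    permutations <- t(vapply(seq_len(n_permutations),
                             function(i) sample.int(n), integer(n)))
  }
  n_perm <- nrow(permutations)
  exceed <- numeric(length(terms))
  for (i in seq_len(n_perm)) {
    p <- permutations[i, ]
    pp <- ss_terms(g[p, p])
    f_p <- (pp$ss / df) / (pp$ss_res / df_res)
    exceed <- exceed + (f_p >= f_obs - 1e-12)
  }
  p_val <- (exceed + 1) / (n_perm + 1)

  out <- data.frame(
    term = c(terms, "Residual"),
    df = c(df, df_res),
    SS = c(obs$ss, obs$ss_res),
    R2 = c(obs$ss, obs$ss_res) / obs$tot,
    pseudo_F = c(f_obs, NA),
    p_value = c(p_val, NA),
    n_permutations = n_perm,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
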