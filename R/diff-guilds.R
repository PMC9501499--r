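# Per-compartment log2 fold changes of the top genera in absolute AND
# relative abundance, significance testing with multiple-testing
# correction, compositional-artifact flagging, Kendall concordance, and
# Spearman/Ward co-abundance guild clustering with silhouette-selected k.

#' Select the top-k taxa by mean abundance
#'
#' Taxa ranked by mean abundance over all samples supplied (both diets
#' pooled); ties broken lexicographically by taxon id.
#'
#' @param mat samples x taxa abundance matrix.
#' @param k number of taxa to keep (default 50); if fewer taxa are
#'   present, all are returned with a warning.
#' @return character vector of taxon ids, in rank order.
#' @export
select_top_taxa <- function(mat, k = 50) {
  if (is.null(dim(mat)) || ncol(mat) == 0 || nrow(mat) == 0) {
    stop("empty abundance table")
  }
  means <- colMeans(mat, na.rm = TRUE)
  ord <- order(-means, colnames(mat))
  if (ncol(mat) < k) {
    warning("only ", ncol(mat), " taxa present; returning all")
    k <- ncol(mat)
  }
  colnames(mat)[ord][seq_len(k)]
}

#' Log2 fold change of group means with pseudocount
#'
#' `log2((mean(FFD) + pc) / (mean(CD) + pc))`; the pseudocount keeps the
#' ratio finite when a group mean is zero.
#'
#' @param values_ffd,values_cd non-negative abundance values for the
#'   treatment (FFD) and reference (CD) groups.
#' @param pseudocount positive offset added to both means.
#' @export
l2fc <- function(values_ffd, values_cd, pseudocount) {
  if (any(values_ffd < 0) || any(values_cd < 0)) {
    stop("abundances must be non-negative")
  }
  stopifnot(pseudocount > 0)
  log2((mean(values_ffd) + pseudocount) / (mean(values_cd) + pseudocount))
}

#' Two-sample t-test p-value for a diet contrast
#'
#' Welch's t-test by default; set `var_equal = TRUE` for Student's.
#' Returns `NA` with a warning when a group has fewer than 2 samples or
#' both groups are constant.
#'
#' @param values_ffd,values_cd per-sample abundances by diet.
#' @param var_equal assume equal variances (Student's t-test)?
#' @return two-sided p-value, or `NA`.
#' @export
diet_test <- function(values_ffd, values_cd, var_equal = FALSE) {
  if (length(values_ffd) < 2 || length(values_cd) < 2) {
    warning("fewer than 2 samples in a diet group; p-value is NA")
    return(NA_real_)
  }
  if (stats::sd(values_ffd) == 0 && stats::sd(values_cd) == 0) {
    # identical constants: no evidence against equality
    return(if (mean(values_ffd) == mean(values_cd)) 1 else NA_real_)
  }
  stats::t.test(values_ffd, values_cd, var.equal = var_equal)$p.value
}

#' Paired absolute/relative differential-abundance report
#'
#' For each intestinal compartment (terminal day-7 samples; feces have
#' no per-compartment load and are excluded) the top `top_k` genera by
#' mean absolute abundance are tested for a diet effect on BOTH scales:
#' per-compartment absolute load and copy-number-corrected relative
#' abundance. Each taxon gets log2 fold changes (FFD/CD, pseudocount
#' added to the group means), raw and adjusted p-values, significance
#' calls, and a compositional-artifact flag:
#' * `relative_only_increase` — significant relative increase without a
#'   significant absolute change (the mucus-degrader "pseudo-bloom"),
#' * `relative_only_decrease` — the mirror case,
#' * `discordant_sign` — significant on both scales with opposite signs,
#' * `none` otherwise.
#'
#' @param profile a `qmp_abundance` from [qmp_profile()].
#' @param top_k number of genera per compartment (default 50).
#' @param alpha significance level applied to adjusted p-values.
#' @param p_adjust multiple-testing method across the top taxa within a
#'   compartment and scale: `"BH"` (default) or `"bonferroni"`.
#' @param pseudocount positive number, or `NULL` (default) for the
#'   smallest non-zero value of the compartment's table on each scale.
#' @param var_equal use Student's instead of Welch's t-test.
#' @param day study day of the terminal samples (default 7).
#' @return data.frame of L2FC records, one row per taxon x compartment,
#'   with attribute `pseudocounts` (per compartment x scale).
#' @export
build_l2fc_report <- function(profile, top_k = 50, alpha = 0.05,
                              p_adjust = "BH", pseudocount = NULL,
                              var_equal = FALSE, day = 7) {
  stopifnot(inherits(profile, "qmp_abundance"))
  md <- profile$metadata
  keep <- md$compartment != "feces" & md$day == day
  comps <- intersect(QMP_COMPARTMENTS, unique(md$compartment[keep]))
  records <- list()
  pcs <- list()

  for (comp in comps) {
    idx <- which(keep & md$compartment == comp)
    diets <- md$diet[idx]
    if (length(unique(diets)) < 2) {
      warning("compartment ", comp, " has a single diet; skipped")
      next
    }
    abs_mat <- profile$abs_per_compartment[idx, , drop = FALSE]
    rel_mat <- profile$rel_corrected[idx, , drop = FALSE]
    ok <- stats::complete.cases(abs_mat) & stats::complete.cases(rel_mat)
    abs_mat <- abs_mat[ok, , drop = FALSE]
    rel_mat <- rel_mat[ok, , drop = FALSE]
    diets <- diets[ok]

    top <- select_top_taxa(abs_mat, k = top_k)
    pc_abs <- pseudocount %||% min(abs_mat[abs_mat > 0])
    pc_rel <- pseudocount %||% min(rel_mat[rel_mat > 0])
    pcs[[comp]] <- c(absolute = pc_abs, relative = pc_rel)

    ffd <- diets == "FFD"
    one_scale <- function(mat, pc) {
      fc <- vapply(top, function(tx) l2fc(mat[ffd, tx], mat[!ffd, tx], pc),
                   numeric(1))
      p <- vapply(top, function(tx)
        diet_test(mat[ffd, tx], mat[!ffd, tx], var_equal = var_equal),
        numeric(1))
      list(l2fc = fc, p = p, padj = stats::p.adjust(p, method = p_adjust))
    }
    a <- one_scale(abs_mat, pc_abs)
    r <- one_scale(rel_mat, pc_rel)

    sig_a <- !is.na(a$padj) & a$padj <= alpha
    sig_r <- !is.na(r$padj) & r$padj <= alpha
    flag <- rep("none", length(top))
    flag[sig_r & r$l2fc > 0 & !sig_a] <- "relative_only_increase"
    flag[sig_r & r$l2fc < 0 & !sig_a] <- "relative_only_decrease"
    flag[sig_r & sig_a & sign(r$l2fc) != sign(a$l2fc)] <- "discordant_sign"

    records[[comp]] <- data.frame(
      taxon_id = top, compartment = comp,
      l2fc_absolute = unname(a$l2fc), l2fc_relative = unname(r$l2fc),
      p_absolute = unname(a$p), p_relative = unname(r$p),
      padj_absolute = unname(a$padj), padj_relative = unname(r$padj),
      significant_absolute = unname(sig_a),
      significant_relative = unname(sig_r),
      artifact_flag = flag,
      stringsAsFactors = FALSE
    )
  }
  if (length(records) == 0) stop("no compartment with both diets present")
  out <- do.call(rbind, records)
  rownames(out) <- NULL
  attr(out, "pseudocounts") <- pcs
  attr(out, "settings") <- list(top_k = top_k, alpha = alpha,
                                p_adjust = p_adjust,
                                t_test = if (var_equal) "Student" else "Welch")
  out
}

#' Kendall's coefficient of concordance
#'
#' Agreement of the sample rankings produced by each taxon (taxa are the
#' judges, samples the objects), with tie correction; p-value from the
#' chi-square approximation `m (n - 1) W` on `n - 1` degrees of freedom.
#'
#' @param mat judges x objects matrix (taxa x samples), >= 2 rows and
#'   >= 2 columns, not all rows constant.
#' @return list with `W` in \[0, 1\], `chisq`, `df`, `p_value`.
#' @export
kendall_w <- function(mat) {
  if (nrow(mat) < 2 || ncol(mat) < 2) {
    stop("need >= 2 judges (taxa) and >= 2 objects (samples)")
  }
  m <- nrow(mat); n <- ncol(mat)
  ranks <- t(apply(mat, 1, rank))
  if (all(apply(mat, 1, function(r) stats::sd(r) == 0))) {
    stop("all judge rankings are constant; W undefined")
  }
  ties <- apply(mat, 1, function(r) {
    t <- table(rank(r))
    sum(t^3 - t)
  })
  r_sums <- colSums(ranks)
  s <- sum((r_sums - mean(r_sums))^2)
  denom <- m^2 * (n^3 - n) / 12 - m * sum(ties) / 12
  if (denom <= 0) stop("degenerate ranks; W undefined")
  w <- s / denom
  chisq <- m * (n - 1) * w
  list(W = w, chisq = chisq, df = n - 1,
       p_value = stats::pchisq(chisq, df = n - 1, lower.tail = FALSE))
}

#' Co-abundance guild clustering
#'
#' Taxa are clustered on `1 - Spearman(rho)` distance between their
#' abundance profiles across all samples of a compartment (diets
#' pooled), with Ward linkage (`ward.D2`); the number of clusters is the
#' `k` in `k_range` maximizing the mean silhouette width. Per-cluster
#' total abundances (summed over member taxa per sample) are compared
#' between diets by t-test, and concordance of the taxon rankings is
#' quantified by Kendall's W.
#'
#' @param mat samples x taxa absolute-abundance matrix.
#' @param diet per-sample diet labels (`CD` / `FFD`).
#' @param k_range candidate cluster numbers (default `2:8`).
#' @param var_equal use Student's instead of Welch's t-test for the
#'   per-cluster diet comparison.
#' @return a `guild_result` list: `k_selected`, `clusters` (named taxon
#'   assignment), `silhouette` (per candidate k), `kendall_W`,
#'   `kendall_p`, `cluster_summary` (per cluster x diet mean total
#'   abundance and diet-comparison p), `hclust`, `linkage`.
#' @export
guild_cluster <- function(mat, diet, k_range = 2:8, var_equal = FALSE) {
  if (nrow(mat) < 3) stop("need >= 3 samples to correlate profiles")
  constant <- apply(mat, 2, function(x) stats::sd(x) == 0)
  if (any(constant)) {
    warning("dropping constant taxon profile(s): ",
            paste(colnames(mat)[constant], collapse = ", "))
    mat <- mat[, !constant, drop = FALSE]
  }
  if (ncol(mat) < max(k_range) + 1) {
    stop("need more taxa than max(k_range) to cluster")
  }
  rho <- stats::cor(mat, method = "spearman")
  d <- stats::as.dist(1 - rho)
  hc <- stats::hclust(d, method = "ward.D2")

  sil <- vapply(k_range, function(k) {
    cl <- stats::cutree(hc, k)
    mean(cluster::silhouette(cl, d)[, "sil_width"])
  }, numeric(1))
  k_sel <- k_range[which.max(sil)]
  clusters <- stats::cutree(hc, k_sel)

  kw <- kendall_w(t(mat))

  summ <- do.call(rbind, lapply(sort(unique(clusters)), function(cl) {
    tot <- rowSums(mat[, clusters == cl, drop = FALSE])
    p <- diet_test(tot[diet == "FFD"], tot[diet == "CD"],
                   var_equal = var_equal)
    data.frame(cluster = cl, n_taxa = sum(clusters == cl),
               mean_total_CD = mean(tot[diet == "CD"]),
               mean_total_FFD = mean(tot[diet == "FFD"]),
               p_diet = p, stringsAsFactors = FALSE)
  }))

  structure(list(
    k_selected = k_sel,
    clusters = clusters,
    silhouette = stats::setNames(sil, paste0("k", k_range)),
    kendall_W = kw$W, kendall_p = kw$p_value,
    cluster_summary = summ,
    hclust = hc,
    linkage = "ward.D2 on 1 - Spearman rho"
  ), class = "guild_result")
}

#' Guild clustering for every compartment of a profile
#'
#' Applies [guild_cluster()] to the top `top_k` taxa (by mean absolute
#' abundance) of each terminal compartment.
#'
#' @inheritParams build_l2fc_report
#' @param k_range candidate cluster numbers.
#' @return named list of `guild_result`, one per compartment.
#' @export
guild_clusters <- function(profile, top_k = 50, k_range = 2:8, day = 7,
                           var_equal = FALSE) {
  stopifnot(inherits(profile, "qmp_abundance"))
  md <- profile$metadata
  keep <- md$compartment != "feces" & md$day == day
  comps <- intersect(QMP_COMPARTMENTS, unique(md$compartment[keep]))
  out <- list()
  for (comp in comps) {
    idx <- which(keep & md$compartment == comp)
    mat <- profile$abs_per_compartment[idx, , drop = FALSE]
    ok <- stats::complete.cases(mat)
    mat <- mat[ok, , drop = FALSE]
    top <- select_top_taxa(mat, k = top_k)
    out[[comp]] <- guild_cluster(mat[, top, drop = FALSE],
                                 diet = md$diet[idx][ok],
                                 k_range = k_range, var_equal = var_equal)
  }
  out
}
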