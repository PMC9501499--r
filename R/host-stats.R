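# Assumption-gated two-way ANOVA workflow applied uniformly to host and
# microbiome endpoints: Shapiro-Wilk on residuals gates a single
# square-root retry, Levene (Brown-Forsythe) documents
# homoscedasticity, sums of squares are sequential for balanced designs
# and Type II otherwise, and significant factors trigger Bonferroni-
# adjusted pairwise Student t-tests.

#' Two-way ANOVA workflow with assumption gates
#'
#' Fits `values ~ factor_a * factor_b`, tests residual normality
#' (Shapiro-Wilk); if `p < alpha` the values are square-root transformed
#' once and the model refitted (negative values make the transform an
#' error advising an offset). Homoscedasticity is recorded via Levene's
#' test (median-centered). Per-factor R2 is the factor's share of the
#' total sum of squares. Factors significant at `alpha` get pairwise
#' Student's t-tests with Bonferroni adjustment over the comparisons of
#' that factor.
#'
#' @param values numeric response.
#' @param factor_a,factor_b grouping factors (>= 2 levels each; a
#'   single-level factor is dropped with a warning, reducing to one-way
#'   ANOVA).
#' @param alpha gate and significance level (default 0.05).
#' @param sqrt_fallback allow the square-root retry (default `TRUE`).
#' @return an `anova_workflow` list: `transformation`, `normality_p`,
#'   `homoscedasticity_p`, `anova_table` (term, df, SS, F, p, R2),
#'   `posthoc` (possibly empty data.frame), `ss_type`.
#' @export
anova_workflow <- function(values, factor_a, factor_b, alpha = 0.05,
                           sqrt_fallback = TRUE) {
  stopifnot(length(values) == length(factor_a),
            length(values) == length(factor_b))
  fa <- factor(factor_a); fb <- factor(factor_b)
  labs <- c("factor_a", "factor_b")
  if (nlevels(fa) < 2 && nlevels(fb) < 2) {
    stop("both factors have a single level")
  }
  one_way <- NULL
  if (nlevels(fb) < 2) {
    warning("factor_b has one level; reducing to one-way ANOVA")
    one_way <- "factor_a"
  } else if (nlevels(fa) < 2) {
    warning("factor_a has one level; reducing to one-way ANOVA")
    one_way <- "factor_b"
    fa <- fb
  }

  if (stats::sd(values) == 0) {
    tab <- data.frame(term = if (is.null(one_way))
      c(labs, "interaction", "Residual") else c(one_way, "Residual"),
      df = NA, SS = 0, F = NA_real_, p = NA_real_, R2 = NA_real_)
    return(structure(list(transformation = "none", normality_p = NA,
                          homoscedasticity_p = NA, anova_table = tab,
                          posthoc = empty_posthoc(), ss_type = NA),
                     class = "anova_workflow"))
  }

  fit_model <- function(v) {
    if (is.null(one_way)) stats::lm(v ~ fa * fb) else stats::lm(v ~ fa)
  }

  fit <- fit_model(values)
  norm_p <- shapiro_safe(stats::residuals(fit))
  transformation <- "none"
  v_used <- values
  if (sqrt_fallback && !is.na(norm_p) && norm_p < alpha) {
    if (any(values < 0)) {
      stop("residuals non-normal but values are negative; ",
           "add an offset before the square-root transform")
    }
    v_used <- sqrt(values)
    fit <- fit_model(v_used)
    transformation <- "sqrt"
    norm_p <- shapiro_safe(stats::residuals(fit))
  }

  cells <- if (is.null(one_way)) interaction(fa, fb, drop = TRUE) else fa
  if (any(table(cells) == 0)) stop("empty factor cell")
  lev_p <- tryCatch(
    car::leveneTest(v_used ~ cells, center = stats::median)[1, "Pr(>F)"],
    error = function(e) NA_real_)

  balanced <- length(unique(table(cells))) == 1
  if (balanced || !is.null(one_way)) {
    at <- stats::anova(fit)
    ss_type <- "I"
  } else {
    at <- car::Anova(fit, type = 2)
    ss_type <- "II"
  }
  terms <- rownames(at)
  res_row <- which(terms == "Residuals")
  ss <- at[["Sum Sq"]]
  tot_ss <- sum(ss)
  term_labels <- vapply(terms, function(t) {
    if (t == "Residuals") "Residual"
    else if (t == "fa") (if (is.null(one_way)) labs[1] else one_way)
    else if (t == "fb") labs[2]
    else "interaction"
  }, character(1))
  tab <- data.frame(
    term = unname(term_labels),
    df = at[["Df"]],
    SS = ss,
    F = at[["F value"]],
    p = at[["Pr(>F)"]],
    R2 = ss / tot_ss,
    stringsAsFactors = FALSE
  )

  posthoc <- empty_posthoc()
  fac_list <- if (is.null(one_way)) list(factor_a = fa, factor_b = fb) else
    stats::setNames(list(fa), one_way)
  for (nm in names(fac_list)) {
    lab <- if (is.null(one_way)) nm else one_way
    p_fac <- tab$p[tab$term == lab]
    if (length(p_fac) == 1 && !is.na(p_fac) && p_fac <= alpha) {
      lev <- levels(fac_list[[nm]])
      comps <- t(utils::combn(lev, 2))
      ph <- posthoc_bonferroni(v_used, fac_list[[nm]], comps)
      ph$factor <- lab
      posthoc <- rbind(posthoc, ph[, names(empty_posthoc())])
    }
  }

  structure(list(transformation = transformation,
                 normality_p = norm_p,
                 homoscedasticity_p = lev_p,
                 anova_table = tab,
                 posthoc = posthoc,
                 ss_type = ss_type),
            class = "anova_workflow")
}

empty_posthoc <- function() {
  data.frame(factor = character(), group_1 = character(),
             group_2 = character(), t = numeric(), p_raw = numeric(),
             p_bonferroni = numeric(), stringsAsFactors = FALSE)
}

shapiro_safe <- function(res) {
  n <- length(res)
  if (n < 3) return(NA_real_)
  if (n > 5000) res <- sample(res, 5000)
  tryCatch(stats::shapiro.test(res)$p.value, error = function(e) NA_real_)
}

#' Pairwise Student t-tests with Bonferroni adjustment
#'
#' `p_adj = min(1, p_raw * m)` with `m` the number of comparisons
#' performed in this call.
#'
#' @param values numeric response.
#' @param groups group label per value.
#' @param comparisons 2-column matrix (or data.frame) of group-label
#'   pairs to compare; each compared group needs >= 2 samples.
#' @return data.frame with columns `factor` (NA here), `group_1`,
#'   `group_2`, `t`, `p_raw`, `p_bonferroni`.
#' @export
posthoc_bonferroni <- function(values, groups, comparisons) {
  comparisons <- as.matrix(comparisons)
  if (ncol(comparisons) != 2) stop("comparisons must have two columns")
  groups <- as.character(groups)
  unknown <- setdiff(unique(as.vector(comparisons)), unique(groups))
  if (length(unknown) > 0) {
    stop("unknown group label(s): ", paste(unknown, collapse = ", "))
  }
  m <- nrow(comparisons)
  out <- lapply(seq_len(m), function(i) {
    g1 <- values[groups == comparisons[i, 1]]
    g2 <- values[groups == comparisons[i, 2]]
    if (length(g1) < 2 || length(g2) < 2) {
      stop("each compared group needs >= 2 samples")
    }
    tt <- stats::t.test(g1, g2, var.equal = TRUE)
    data.frame(factor = NA_character_,
               group_1 = comparisons[i, 1], group_2 = comparisons[i, 2],
               t = unname(tt$statistic), p_raw = tt$p.value,
               p_bonferroni = min(1, tt$p.value * m),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
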