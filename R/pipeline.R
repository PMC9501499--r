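# End-to-end orchestration: simulate (or read) a study, QMP-profile it,
# run diversity, differential-abundance/guild and tracer/host-statistics
# stages, and write every stage's TSV plus a JSON run manifest. Each
# stage is also callable on its own; re-running a stage from the on-disk
# TSVs reproduces the in-memory results.

#' Run the full QMP analysis pipeline
#'
#' Stages, in order: (1) obtain a study — generate from a scenario, or
#' read `counts.tsv`/`metadata.tsv`/`copy_numbers.tsv` from `input_dir`;
#' (2) filter samples below `min_reads`; (3) QMP profile; (4) alpha
#' diversity at `rarefaction_depth` (on samples deep enough) plus
#' Bray-Curtis, PCoA and a diet/compartment PERMANOVA on relative
#' abundances of terminal samples; (5) paired absolute/relative L2FC
#' report with artifact flags, and guild clustering; (6) tracer report
#' (if tracer data exist) and the ANOVA workflow on load, water content
#' and C:N endpoints. All outputs land in `out_dir`; every file carries
#' the seed in a `#` header, and `run_manifest.json` echoes the
#' configuration.
#'
#' @param scenario a `scenario_config`, a scenario YAML path, or `NULL`
#'   when `input_dir` is given.
#' @param input_dir directory holding the three study TSVs (alternative
#'   to `scenario`).
#' @param out_dir output directory (created).
#' @param seed integer seed for generation, rarefaction and PERMANOVA.
#' @param min_reads library-size filter (default 1000).
#' @param rarefaction_depth alpha-diversity depth (default 1763).
#' @param top_k genera per compartment in the differential report
#'   (default 50).
#' @param alpha significance level (default 0.05).
#' @param n_permutations PERMANOVA permutations (default 999).
#' @param k_range candidate guild cluster numbers (default `2:8`).
#' @return invisibly, a list with the in-memory stage results and the
#'   paths written.
#' @export
run_pipeline <- function(scenario = NULL, input_dir = NULL,
                         out_dir, seed = 1, min_reads = 1000,
                         rarefaction_depth = 1763, top_k = 50,
                         alpha = 0.05, n_permutations = 999,
                         k_range = 2:8) {
  if (is.null(scenario) && is.null(input_dir)) {
    stop("give either a scenario or an input_dir")
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  hdr <- paste0("seed: ", seed)

  if (!is.null(scenario)) {
    if (is.character(scenario)) scenario <- read_scenario(scenario)
    study <- generate_study(scenario, seed = seed)
    write_study(study, file.path(out_dir, "input"), header = hdr)
    gt <- study$ground_truth
    write_tsv(gt$true_l2fc, file.path(out_dir, "input", "ground_truth.tsv"),
              hdr)
  } else {
    study <- read_study(file.path(input_dir, "counts.tsv"),
                        file.path(input_dir, "metadata.tsv"),
                        file.path(input_dir, "copy_numbers.tsv"))
  }

  set.seed(seed)
  study_f <- filter_min_reads(study, min_reads)
  profile <- qmp_profile(study_f)
  write_abundance(profile, file.path(out_dir, "absolute_abundance.tsv"), hdr)

  # diversity on samples deep enough for the rarefaction depth
  deep <- library_sizes(study_f) >= rarefaction_depth
  alpha_df <- alpha_diversity(
    round(study_f$counts[deep, , drop = FALSE]), depth = rarefaction_depth)
  alpha_df <- merge(alpha_df, study_f$metadata[, c("sample_id", "diet",
                                                   "day", "compartment")],
                    by = "sample_id", sort = FALSE)
  write_tsv(alpha_df, file.path(out_dir, "diversity.tsv"), hdr)

  md <- profile$metadata
  term <- md$compartment != "feces" & md$day == 7 &
    !is.na(md$cell_density_cells_per_g)
  rel_term <- profile$rel_corrected[term, , drop = FALSE]
  ok <- stats::complete.cases(rel_term)
  bc <- bray_curtis_matrix(rel_term[ok, , drop = FALSE])
  ord <- pcoa_ordination(bc)
  ord_df <- data.frame(sample_id = rownames(rel_term)[ok],
                       ord$coordinates[, 1:2, drop = FALSE])
  names(ord_df)[2:3] <- c("PCo1", "PCo2")
  write_tsv(ord_df, file.path(out_dir, "ordination.tsv"), hdr)
  perm <- permanova(bc, md[term, c("diet", "compartment")][ok, ],
                    n_permutations = n_permutations)
  write_tsv(perm, file.path(out_dir, "permanova.tsv"), hdr)

  report <- build_l2fc_report(profile, top_k = top_k, alpha = alpha)
  write_tsv(report, file.path(out_dir, "l2fc_report.tsv"), hdr)
  writeLines(artifact_summary(report),
             file.path(out_dir, "artifact_summary.txt"))

  guilds <- guild_clusters(profile, top_k = top_k, k_range = k_range)
  guilds_df <- do.call(rbind, lapply(names(guilds), function(comp) {
    g <- guilds[[comp]]
    data.frame(compartment = comp, taxon_id = names(g$clusters),
               cluster = unname(g$clusters), k_selected = g$k_selected,
               kendall_W = g$kendall_W, kendall_p = g$kendall_p,
               stringsAsFactors = FALSE)
  }))
  write_tsv(guilds_df, file.path(out_dir, "guilds.tsv"), hdr)

  tracer <- NULL
  if (!is.null(study$tracer)) {
    tracer <- tracer_report(study_f)
    write_tsv(tracer, file.path(out_dir, "tracer_report.tsv"), hdr)
  }

  stats_rows <- host_endpoint_stats(profile, tracer, alpha = alpha)
  write_tsv(stats_rows, file.path(out_dir, "stats_report.tsv"), hdr)

  manifest <- list(
    package = "qmpguilds",
    version = as.character(utils::packageVersion("qmpguilds")),
    seed = seed,
    parameters = list(min_reads = min_reads,
                      rarefaction_depth = rarefaction_depth,
                      top_k = top_k, alpha = alpha,
                      n_permutations = n_permutations,
                      k_range = range(k_range)),
    scenario = if (!is.null(scenario))
      scenario[setdiff(names(scenario), "guilds")] else NULL,
    input_dir = input_dir,
    notes = c(
      "simpson index reported in Gini-Simpson (1 - sum p^2) form",
      "shannon uses natural log",
      "beta diversity on unrarefied copy-number-corrected relative abundances",
      "t-tests are Welch unless var_equal is set",
      "multiple testing: Benjamini-Hochberg across top taxa per compartment and scale",
      "guild linkage: ward.D2 on 1 - Spearman rho"
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")

  invisible(list(study = study, profile = profile, alpha = alpha_df,
                 ordination = ord_df, permanova = perm, l2fc = report,
                 guilds = guilds, tracer = tracer, stats = stats_rows,
                 out_dir = out_dir))
}

artifact_summary <- function(report) {
  s <- attr(report, "settings")
  flagged <- report[report$artifact_flag != "none", , drop = FALSE]
  lines <- c(
    "Compositional-artifact summary",
    sprintf("top %d genera per compartment; %s t-test; %s-adjusted at alpha=%.2f",
            s$top_k, s$t_test, s$p_adjust, s$alpha),
    sprintf("%d of %d taxon-compartment records flagged",
            nrow(flagged), nrow(report))
  )
  if (nrow(flagged) > 0) {
    lines <- c(lines, "", sprintf(
      "%-24s %-16s %-24s l2fc_rel=%+.2f l2fc_abs=%+.2f",
      flagged$taxon_id, flagged$compartment, flagged$artifact_flag,
      flagged$l2fc_relative, flagged$l2fc_absolute))
  }
  lines
}

# ANOVA workflow over the standard endpoints: total load, water content
# and C:N by diet x compartment.
host_endpoint_stats <- function(profile, tracer, alpha = 0.05) {
  md <- profile$metadata
  term <- md$compartment != "feces" & md$day == 7
  rows <- list()

  add <- function(name, values, fa, fb) {
    ok <- !is.na(values) & !is.na(fa) & !is.na(fb)
    if (sum(ok) < 8 || length(unique(fa[ok])) < 2) return()
    res <- tryCatch(
      suppressWarnings(anova_workflow(values[ok], fa[ok], fb[ok],
                                      alpha = alpha)),
      error = function(e) NULL)
    if (is.null(res)) return()
    tab <- res$anova_table
    tab$endpoint <- name
    tab$transformation <- res$transformation
    tab$normality_p <- res$normality_p
    tab$homoscedasticity_p <- res$homoscedasticity_p
    rows[[length(rows) + 1]] <<- tab
  }

  load <- profile$sample_load_per_compartment[term]
  add("sample_load", load, md$diet[term], md$compartment[term])

  wet <- md$content_wet_weight_g[term]
  dry <- md$content_dry_weight_g[term]
  okw <- !is.na(wet) & wet > 0 & !is.na(dry)
  water <- rep(NA_real_, sum(term))
  water[okw] <- water_content(wet[okw], dry[okw])
  add("water_content", water, md$diet[term], md$compartment[term])

  if (!is.null(tracer)) {
    add("cn_ratio", tracer$cn_ratio, tracer$diet, tracer$compartment)
    add("flux_mg_13C", tracer$flux_mg_13C, tracer$diet, tracer$compartment)
  }

  if (length(rows) == 0) {
    return(data.frame(endpoint = character(), term = character(),
                      df = numeric(), SS = numeric(), F = numeric(),
                      p = numeric(), R2 = numeric()))
  }
  out <- do.call(rbind, rows)
  out[, c("endpoint", "term", "df", "SS", "F", "p", "R2",
          "transformation", "normality_p", "homoscedasticity_p")]
}
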