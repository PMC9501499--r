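# Stable-isotope (EA-IRMS) secretion flux, elemental stoichiometry,
# water content, and qPCR delta-delta-Ct expression fold changes.

#' Atom fraction excess
#'
#' Isotopic enrichment above the unlabeled baseline, as a fraction of
#' total atoms: `max(0, sample - baseline) / 100`. A negative excess
#' (sample below baseline) clamps to 0 with a warning.
#'
#' @param sample_atom_pct,baseline_atom_pct atom percentages in
#'   \[0, 100\].
#' @return dimensionless atom fraction excess in \[0, 1\].
#' @export
atom_fraction_excess <- function(sample_atom_pct, baseline_atom_pct) {
  if (any(sample_atom_pct < 0 | sample_atom_pct > 100) ||
      any(baseline_atom_pct < 0 | baseline_atom_pct > 100)) {
    stop("atom percentages must be in [0, 100]")
  }
  excess <- (sample_atom_pct - baseline_atom_pct) / 100
  if (any(excess < 0)) {
    warning("negative atom-percent excess clamped to 0")
    excess <- pmax(excess, 0)
  }
  excess
}

#' Secreted carbon flux per compartment
#'
#' The amount of tracer-derived carbon in the luminal contents:
#' excess 13C atom fraction x carbon content x dry mass,
#' `afe * (pct_C / 100) * dry_weight_mg`, in mg excess 13C per
#' compartment. Linear in each argument.
#'
#' @param afe_13C atom fraction excess of 13C, in \[0, 1\].
#' @param pct_C total carbon content of the dry biomass, percent.
#' @param dry_weight_mg dry weight of the compartment contents, mg (> 0).
#' @export
secreted_carbon_flux <- function(afe_13C, pct_C, dry_weight_mg) {
  if (any(afe_13C < 0 | afe_13C > 1)) stop("afe_13C must be in [0, 1]")
  if (any(pct_C < 0 | pct_C > 100)) stop("pct_C must be in [0, 100]")
  if (any(dry_weight_mg <= 0)) stop("dry_weight_mg must be > 0")
  afe_13C * (pct_C / 100) * dry_weight_mg
}

#' Carbon-to-nitrogen mass ratio
#' @param pct_C,pct_N elemental percentages; `pct_N` must be > 0.
#' @export
cn_ratio <- function(pct_C, pct_N) {
  if (any(pct_N <= 0)) stop("pct_N must be > 0")
  pct_C / pct_N
}

#' Water content of luminal contents
#'
#' `100 * (wet - dry) / wet`, percent.
#' @param wet_g,dry_g wet and dry weights in grams; `wet_g > 0`,
#'   `dry_g <= wet_g`.
#' @export
water_content <- function(wet_g, dry_g) {
  if (any(wet_g <= 0)) stop("wet weight must be > 0")
  if (any(dry_g < 0)) stop("dry weight must be >= 0")
  if (any(dry_g > wet_g + 1e-12)) stop("dry weight exceeds wet weight")
  100 * (wet_g - dry_g) / wet_g
}

#' Fold change by the 2^-ddCt method
#'
#' Per sample, `dCt = ct_target - ct_housekeeping`; the fold change of
#' the treatment group relative to the reference group is
#' `2^-(mean dCt_treatment - mean dCt_reference)`. Invariant to a
#' constant (plate) offset added to every Ct.
#'
#' @param records data.frame with columns `ct_target`,
#'   `ct_housekeeping`, `group` (two groups).
#' @param reference_group label of the reference (e.g. `"CD"`).
#' @return the fold change (1 = no change).
#' @export
ddct_fold_change <- function(records, reference_group = "CD") {
  stopifnot(all(c("ct_target", "ct_housekeeping", "group") %in%
                  names(records)))
  groups <- unique(records$group)
  if (!reference_group %in% groups) {
    stop("reference group '", reference_group, "' not present")
  }
  treat <- setdiff(groups, reference_group)
  if (length(treat) != 1) stop("need exactly one treatment group")
  dct <- records$ct_target - records$ct_housekeeping
  ddct <- mean(dct[records$group == treat]) -
    mean(dct[records$group == reference_group])
  2^(-ddct)
}

#' Per-sample tracer report for a synthetic or assembled study
#'
#' Computes, for every EA-IRMS measurement: the 13C atom fraction excess
#' (baseline = mean atom% of the 12C-control animals in the same
#' compartment, falling back to `natural_baseline` when no controls are
#' present), the secreted-carbon flux, the C:N ratio, and — where
#' content weights exist — the water content.
#'
#' @param study a study with a `tracer` data.frame (see
#'   [generate_study()]) and sample metadata.
#' @param natural_baseline atom% 13C used when no unlabeled controls are
#'   available (default 1.07, natural abundance).
#' @return data.frame, one row per labeled tracer measurement.
#' @export
tracer_report <- function(study, natural_baseline = 1.07) {
  tr <- study$tracer
  if (is.null(tr)) stop("study carries no tracer measurements")
  md <- study$metadata
  comp <- md$compartment[match(tr$sample_id, md$sample_id)]

  baseline <- vapply(seq_len(nrow(tr)), function(i) {
    ctrl <- tr$is_control_12C & comp == comp[i]
    if (any(ctrl)) mean(tr$atom_pct_13C[ctrl]) else natural_baseline
  }, numeric(1))

  lab <- !tr$is_control_12C
  afe <- atom_fraction_excess(tr$atom_pct_13C[lab], baseline[lab])
  i <- match(tr$sample_id[lab], md$sample_id)
  data.frame(
    sample_id = tr$sample_id[lab],
    compartment = comp[lab],
    diet = md$diet[i],
    afe_13C = afe,
    flux_mg_13C = secreted_carbon_flux(afe, tr$pct_C[lab],
                                       tr$dry_weight_mg[lab]),
    cn_ratio = cn_ratio(tr$pct_C[lab], tr$pct_N[lab]),
    pct_C = tr$pct_C[lab],
    atom_pct_15N = tr$atom_pct_15N[lab],
    water_pct = ifelse(
      is.na(md$content_wet_weight_g[i]) | md$content_wet_weight_g[i] <= 0,
      NA_real_,
      100 * (md$content_wet_weight_g[i] - md$content_dry_weight_g[i]) /
        md$content_wet_weight_g[i]),
    stringsAsFactors = FALSE
  )
}
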