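# Synthetic-study generator. Emulates a fiber-deprivation diet experiment:
# two diets (control CD, fiber-free FFD), fecal pellets at days 0/2/7,
# terminal small-intestine/cecum/colon samples at day 7, flow-cytometry
# cell densities in triplicate, copy-number-biased multinomial read
# sampling, and a 13C-threonine tracer with unlabeled-control animals.
# Ground truth (true loads, guild labels, true fold changes, true flux)
# is carried alongside the observables so every downstream stage can be
# checked against what was planted.

#' Default synthetic scenario ("cecum collapse")
#'
#' Fifty genera in three guilds: 31 fiber-responsive taxa whose absolute
#' load collapses under the fiber-free diet, one mucus degrader whose
#' absolute load is unchanged, and 18 neutral taxa scaled so that the
#' total load under FFD is `diet_load_ratio` (default 0.2) times the
#' control load. Under these conditions the degrader's true absolute
#' log2 fold change is 0 while its true relative log2 fold change is
#' -log2(0.2) ~= 2.32 — the compositional artifact the pipeline must
#' flag.
#'
#' @param ... named overrides of top-level scenario fields.
#' @return a `scenario_config` list.
#' @export
default_scenario <- function(...) {
  path <- system.file("extdata", "cecum_collapse.yaml", package = "qmpguilds")
  cfg <- read_scenario(path)
  overrides <- list(...)
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  validate_scenario(cfg)
}

#' Read a scenario configuration from YAML
#'
#' @param path YAML file; see `inst/extdata/cecum_collapse.yaml` for the
#'   schema.
#' @return a validated `scenario_config`.
#' @export
read_scenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_scenario(cfg)
}

validate_scenario <- function(cfg) {
  req <- c("n_mice_per_diet", "diet_load_ratio", "guilds", "compartments",
           "seq_depth_mean", "seed")
  missing <- setdiff(req, names(cfg))
  if (length(missing) > 0) {
    stop("scenario missing field(s): ", paste(missing, collapse = ", "))
  }
  if (cfg$n_mice_per_diet < 2) stop("n_mice_per_diet must be >= 2")
  if (cfg$diet_load_ratio <= 0 || cfg$diet_load_ratio > 1) {
    stop("diet_load_ratio must be in (0, 1]")
  }
  n_taxa <- sum(vapply(cfg$guilds, function(g) g$n_taxa, numeric(1)))
  if (n_taxa < 1) stop("scenario has no taxa")
  tot_frac <- sum(vapply(cfg$guilds, function(g) g$total_fraction,
                         numeric(1)))
  if (abs(tot_frac - 1) > 1e-9) {
    stop("guild total_fraction values must sum to 1 (found ", tot_frac, ")")
  }
  if (!is.null(cfg$tracer)) {
    tr <- cfg$tracer
    ap <- c(tr$baseline_atom_pct_13C,
            unlist(tr$excess_atom_pct_13C, use.names = FALSE))
    if (any(ap < 0 | ap > 100)) stop("tracer atom percentages must be in [0,100]")
    pc <- unlist(tr$pct_C, use.names = FALSE)
    if (any(pc + tr$pct_N > 100)) stop("pct_C + pct_N must be <= 100")
  }
  structure(cfg, class = "scenario_config")
}

#' Noise-free variant of a scenario
#'
#' Sets every noise source (mouse effect, per-taxon noise, cell-count CV,
#' weight CV, tracer measurement CV, library-size spread) to zero and
#' switches read sampling to exact expected (real-valued) read counts, so
#' the QMP algebra can be checked for exact inverse consistency.
#'
#' @param cfg a `scenario_config` (default: [default_scenario()]).
#' @return the modified `scenario_config`.
#' @export
noise_free_scenario <- function(cfg = default_scenario()) {
  cfg$mouse_sdlog <- 0
  cfg$taxon_sdlog <- 0
  cfg$cellcount_cv <- 0
  cfg$weight_cv <- 0
  cfg$exact_reads <- TRUE
  if (!is.null(cfg$tracer)) cfg$tracer$measurement_cv <- 0
  cfg
}

# Per-taxon table derived deterministically from the guild blocks:
# taxon ids, guild labels, baseline relative loads (geometric rank-
# abundance within guild, guild totals as configured), and FFD absolute
# multipliers. The neutral guild's multiplier is solved so that the
# planted total-load ratio is exact:
#   sum_j f_j m_j = diet_load_ratio.
scenario_taxa <- function(cfg) {
  guilds <- cfg$guilds
  ids <- list(); guild <- list(); frac <- list(); mult <- list()
  decay <- if (is.null(cfg$rank_abundance_decay)) 0.85 else
    cfg$rank_abundance_decay
  for (g in names(guilds)) {
    spec <- guilds[[g]]
    n <- spec$n_taxa
    nm <- spec$taxa
    if (is.null(nm)) nm <- character(0)
    if (length(nm) < n) {
      nm <- c(nm, sprintf("%s_taxon_%02d", g, seq_len(n - length(nm))))
    }
    w <- decay^(seq_len(n) - 1)
    ids[[g]] <- nm[seq_len(n)]
    guild[[g]] <- rep(g, n)
    frac[[g]] <- spec$total_fraction * w / sum(w)
    mult[[g]] <- rep(if (is.null(spec$ffd_multiplier)) NA_real_ else
      spec$ffd_multiplier, n)
  }
  tab <- data.frame(taxon_id = unlist(ids, use.names = FALSE),
                    guild = unlist(guild, use.names = FALSE),
                    baseline_fraction = unlist(frac, use.names = FALSE),
                    ffd_multiplier = unlist(mult, use.names = FALSE),
                    stringsAsFactors = FALSE)
  free <- is.na(tab$ffd_multiplier)
  if (any(free)) {
    solved <- (cfg$diet_load_ratio -
                 sum(tab$baseline_fraction[!free] * tab$ffd_multiplier[!free])) /
      sum(tab$baseline_fraction[free])
    if (solved < 0) {
      stop("diet_load_ratio unattainable with the fixed guild multipliers")
    }
    tab$ffd_multiplier[free] <- solved
  }
  achieved <- sum(tab$baseline_fraction * tab$ffd_multiplier)
  if (abs(achieved - cfg$diet_load_ratio) > 1e-9) {
    stop("guild multipliers inconsistent with diet_load_ratio")
  }
  tab
}

#' Multinomial read sampling with copy-number bias
#'
#' The forward model of amplicon sequencing that copy-number correction
#' inverts: taxon j is observed with probability proportional to
#' `true_loads[j] * copy_numbers[j]`.
#'
#' @param true_loads non-negative true absolute loads, not all zero.
#' @param copy_numbers 16S copy numbers (>= 1), same length.
#' @param depth library size to draw (>= 0).
#' @return integer vector of reads summing to `depth`.
#' @export
sample_reads <- function(true_loads, copy_numbers, depth) {
  stopifnot(length(true_loads) == length(copy_numbers), depth >= 0)
  if (any(true_loads < 0)) stop("true_loads must be >= 0")
  tot <- sum(true_loads * copy_numbers)
  if (tot <= 0) stop("all true loads are zero; nothing to sequence")
  if (depth == 0) return(integer(length(true_loads)))
  p <- true_loads * copy_numbers / tot
  as.integer(stats::rmultinom(1, size = depth, prob = p)[, 1])
}

#' Generate a complete synthetic study
#'
#' Draws, per mouse, a lognormal host effect shared by all taxa; per
#' sample, true absolute taxon loads (compartment baseline x baseline
#' fraction x diet/day multiplier x host effect x per-taxon lognormal
#' noise), triplicate flow-cytometry counts around the true total
#' density, content wet/dry weights, a negative-binomial library size and
#' a copy-number-biased multinomial read vector, and tracer (EA-IRMS)
#' measurements including unlabeled 12C-control animals. Deterministic
#' given `seed`.
#'
#' @param cfg a `scenario_config`.
#' @param seed integer seed; defaults to `cfg$seed`.
#' @return a `synthetic_study`, which is also a valid `qmp_study`
#'   (elements `counts`, `metadata`, `copy_numbers`) with extra elements
#'   `cell_replicates`, `tracer`, `ground_truth`, `config`, `seed`.
#' @export
generate_study <- function(cfg = default_scenario(), seed = cfg$seed) {
  cfg <- validate_scenario(cfg)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)

  taxa <- scenario_taxa(cfg)
  n_taxa <- nrow(taxa)
  exact <- isTRUE(cfg$exact_reads)
  mouse_sdlog <- cfg$mouse_sdlog %||% 0.3
  taxon_sdlog <- cfg$taxon_sdlog %||% 0.2
  cell_cv <- cfg$cellcount_cv %||% 0.1
  weight_cv <- cfg$weight_cv %||% 0.1
  disp <- cfg$seq_depth_dispersion %||% 10
  ffd_wet_ratio <- cfg$ffd_wet_ratio %||% 1
  ffd_dry_frac_ratio <- cfg$ffd_dry_frac_ratio %||% 1
  day_ramp <- cfg$day_ramp %||% list(`0` = 0, `2` = 0.5, `7` = 1)
  n_ctrl <- cfg$n_control_mice_per_diet %||% 0

  cn_range <- cfg$copy_number_range %||% c(1, 10)
  copy_numbers <- round(stats::runif(n_taxa, cn_range[1], cn_range[2]), 1)
  names(copy_numbers) <- taxa$taxon_id

  mice <- data.frame(
    mouse_id = sprintf("M%02d", seq_len(2 * cfg$n_mice_per_diet)),
    diet = rep(QMP_DIETS, each = cfg$n_mice_per_diet),
    sex = rep_len(c("F", "M"), 2 * cfg$n_mice_per_diet),
    stringsAsFactors = FALSE
  )
  mice$is_control_12C <- FALSE
  for (d in QMP_DIETS) {
    idx <- which(mice$diet == d)
    if (n_ctrl > 0) mice$is_control_12C[idx[seq_len(n_ctrl)]] <- TRUE
  }
  mice$host_effect <- if (mouse_sdlog > 0) {
    stats::rlnorm(nrow(mice), -mouse_sdlog^2 / 2, mouse_sdlog)
  } else rep(1, nrow(mice))
  mice$body_weight_g <- round(stats::rnorm(nrow(mice), 25, 1.5), 2)

  # sample plan: feces at days 0/2/7, terminal compartments at day 7
  plan <- do.call(rbind, lapply(seq_len(nrow(mice)), function(i) {
    rbind(
      data.frame(mouse_idx = i, compartment = "feces", day = QMP_DAYS),
      data.frame(mouse_idx = i,
                 compartment = c("small_intestine", "cecum", "colon"),
                 day = 7L)
    )
  }))
  n_samp <- nrow(plan)
  sample_id <- sprintf("%s_%s_d%d", mice$mouse_id[plan$mouse_idx],
                       c(small_intestine = "SI", cecum = "Ce",
                         colon = "Co", feces = "Fe")[plan$compartment],
                       plan$day)

  lnoise <- function(n, sdlog) {
    if (sdlog > 0) stats::rlnorm(n, -sdlog^2 / 2, sdlog) else rep(1, n)
  }

  true_abs_per_g <- matrix(0, n_samp, n_taxa,
                           dimnames = list(sample_id, taxa$taxon_id))
  counts <- matrix(0, n_samp, n_taxa,
                   dimnames = list(sample_id, taxa$taxon_id))
  wet <- dry <- rep(NA_real_, n_samp)
  tissue <- rep(NA_real_, n_samp)
  cell_density <- rep(NA_real_, n_samp)
  reps <- matrix(NA_real_, n_samp, 3)

  for (i in seq_len(n_samp)) {
    m <- mice[plan$mouse_idx[i], ]
    comp <- plan$compartment[i]
    comp_cfg <- cfg$compartments[[comp]]
    ramp <- if (m$diet == "FFD") day_ramp[[as.character(plan$day[i])]] else 0
    mult <- taxa$ffd_multiplier^ramp
    # Diet multipliers are planted on per-compartment loads (population
    # sizes). Terminal per-gram densities therefore absorb the FFD
    # wet-weight change: fewer grams of content, same cells per
    # compartment => proportionally higher density per gram.
    wr_load <- if (m$diet == "FFD" && comp != "feces") ffd_wet_ratio else 1
    loads <- comp_cfg$load_cells_per_g * taxa$baseline_fraction *
      (mult / wr_load) * m$host_effect * lnoise(n_taxa, taxon_sdlog)
    true_abs_per_g[i, ] <- loads

    dens <- sum(loads)
    reps[i, ] <- dens * lnoise(3, sqrt(log(1 + cell_cv^2)))
    cell_density[i] <- mean(reps[i, ])

    if (comp != "feces") {
      wr <- if (m$diet == "FFD") ffd_wet_ratio else 1
      # dry fraction gets its own (smaller) noise so water content
      # varies within groups, as in real gravimetric measurements
      dfr <- comp_cfg$dry_fraction *
        (if (m$diet == "FFD") ffd_dry_frac_ratio else 1) *
        lnoise(1, sqrt(log(1 + (weight_cv / 2)^2)))
      wet[i] <- comp_cfg$wet_weight_g * wr * lnoise(1, sqrt(log(1 + weight_cv^2)))
      dry[i] <- wet[i] * min(dfr, 1)
      tissue[i] <- 0.2 * lnoise(1, sqrt(log(1 + weight_cv^2)))
    }

    if (exact) {
      p <- loads * copy_numbers / sum(loads * copy_numbers)
      counts[i, ] <- p * cfg$seq_depth_mean
    } else {
      depth <- stats::rnbinom(1, mu = cfg$seq_depth_mean, size = disp)
      counts[i, ] <- sample_reads(loads, copy_numbers, depth)
    }
  }

  metadata <- data.frame(
    sample_id = sample_id,
    mouse_id = mice$mouse_id[plan$mouse_idx],
    sex = mice$sex[plan$mouse_idx],
    diet = mice$diet[plan$mouse_idx],
    day = plan$day,
    compartment = plan$compartment,
    content_wet_weight_g = wet,
    content_dry_weight_g = dry,
    tissue_weight_g = tissue,
    body_weight_g = mice$body_weight_g[plan$mouse_idx],
    cell_density_cells_per_g = cell_density,
    stringsAsFactors = FALSE
  )

  cell_replicates <- data.frame(
    sample_id = rep(sample_id, each = 3),
    replicate = rep(1:3, n_samp),
    cells_per_g = as.vector(t(reps))
  )

  tracer <- generate_tracer(cfg, metadata, mice, plan)

  study <- qmp_study(counts, metadata, copy_numbers,
                     integer_counts = !exact)
  study$cell_replicates <- cell_replicates
  study$tracer <- tracer
  study$ground_truth <- ground_truth(cfg, taxa, true_abs_per_g, metadata)
  study$config <- cfg
  study$seed <- seed
  class(study) <- c("synthetic_study", "qmp_study")
  study
}

`%||%` <- function(a, b) if (is.null(a)) b else a

generate_tracer <- function(cfg, metadata, mice, plan) {
  tr <- cfg$tracer
  if (is.null(tr)) return(NULL)
  term <- which(metadata$compartment != "feces")
  cv <- tr$measurement_cv %||% 0
  sdlog <- sqrt(log(1 + cv^2))
  ln <- function(n) if (cv > 0) stats::rlnorm(n, -sdlog^2 / 2, sdlog) else
    rep(1, n)
  out <- lapply(term, function(i) {
    m <- mice[plan$mouse_idx[i], ]
    comp <- metadata$compartment[i]
    base13 <- tr$baseline_atom_pct_13C
    excess <- if (m$is_control_12C) 0 else
      tr$excess_atom_pct_13C[[m$diet]][[comp]] * ln(1)
    pc <- tr$pct_C[[m$diet]] * ln(1)
    pn <- tr$pct_N * ln(1)
    data.frame(
      sample_id = metadata$sample_id[i],
      atom_pct_13C = base13 + excess,
      atom_pct_15N = (tr$baseline_atom_pct_15N %||% 0.37) + 0.5 * excess,
      pct_C = pc, pct_N = pn,
      dry_weight_mg = metadata$content_dry_weight_g[i] * 1000,
      is_control_12C = m$is_control_12C,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

# Closed-form ground truth: planted per-taxon fold changes follow from
# the scenario algebra alone. With FFD multiplier m_j and total-load
# ratio rho = sum_k f_k m_k, the true absolute L2FC is log2(m_j) and the
# true relative L2FC is log2(m_j / rho).
ground_truth <- function(cfg, taxa, true_abs_per_g, metadata) {
  rho <- cfg$diet_load_ratio
  true_l2fc <- data.frame(
    taxon_id = taxa$taxon_id,
    guild = taxa$guild,
    l2fc_absolute = log2(taxa$ffd_multiplier),
    l2fc_relative = log2(taxa$ffd_multiplier / rho),
    stringsAsFactors = FALSE
  )
  wet <- metadata$content_wet_weight_g
  true_load <- true_abs_per_g * ifelse(is.na(wet), NA, wet)

  true_flux <- NULL
  if (!is.null(cfg$tracer)) {
    tr <- cfg$tracer
    grid <- expand.grid(diet = QMP_DIETS,
                        compartment = setdiff(QMP_COMPARTMENTS, "feces"),
                        stringsAsFactors = FALSE)
    grid$flux_mg_13C <- mapply(function(d, comp) {
      cc <- cfg$compartments[[comp]]
      dry_mg <- cc$wet_weight_g * cc$dry_fraction * 1000 *
        (if (d == "FFD") (cfg$ffd_wet_ratio %||% 1) *
           (cfg$ffd_dry_frac_ratio %||% 1) else 1)
      (tr$excess_atom_pct_13C[[d]][[comp]] / 100) *
        (tr$pct_C[[d]] / 100) * dry_mg
    }, grid$diet, grid$compartment)
    true_flux <- grid
  }

  list(taxa = taxa,
       true_abs_per_g = true_abs_per_g,
       true_load_per_compartment = true_load,
       true_l2fc = true_l2fc,
       true_flux = true_flux,
       diet_load_ratio = rho)
}
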