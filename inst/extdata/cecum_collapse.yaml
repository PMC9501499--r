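# Default synthetic scenario: fiber-free diet collapses total microbial
# load to 20% of control while the single mucus-degrading genus keeps a
# constant absolute population. Relative abundances then falsely suggest
# a mucus-degrader bloom (true relative L2FC = -log2(0.2) ~= 2.32 at a
# true absolute L2FC of 0).
n_mice_per_diet: 10
n_control_mice_per_diet: 1    # unlabeled 12C tracer controls per diet
diet_load_ratio: 0.2          # FFD total load / CD total load, every compartment

guilds:
  fiber_responsive:
    n_taxa: 31
    total_fraction: 0.68
    ffd_multiplier: 0.1       # absolute load under FFD = 10% of CD
    taxa: [Muribaculum, Duncaniella, Alistipes, Paramuribaculum,
           Kineothrix, Clostridium, Roseburia, Eubacterium]
  mucus_degrader:
    n_taxa: 1
    total_fraction: 0.02
    ffd_multiplier: 1.0       # constant absolute load: the planted artifact
    taxa: [Akkermansia]
  neutral:
    n_taxa: 18
    total_fraction: 0.30
    # ffd_multiplier omitted: solved so total FFD/CD load = diet_load_ratio
    taxa: [Faecalibaculum, Desulfovibrio, Bacteroides, Lactobacillus]

compartments:
  small_intestine: {load_cells_per_g: 1.0e+09,  wet_weight_g: 0.50, dry_fraction: 0.15}
  cecum:           {load_cells_per_g: 1.0e+11, wet_weight_g: 0.30, dry_fraction: 0.25}
  colon:           {load_cells_per_g: 1.0e+11, wet_weight_g: 0.20, dry_fraction: 0.30}
  feces:           {load_cells_per_g: 1.0e+11, wet_weight_g: .na,  dry_fraction: .na}

rank_abundance_decay: 0.85    # within-guild geometric rank-abundance weight
ffd_wet_ratio: 0.6            # FFD luminal contents weigh less (water loss)
ffd_dry_frac_ratio: 1.25      # FFD contents are drier (lower water content)
day_ramp: {0: 0, 2: 0.5, 7: 1}  # fecal time series: diet effect ramps in

mouse_sdlog: 0.3              # lognormal host effect shared by all taxa
taxon_sdlog: 0.2              # per-taxon per-sample lognormal noise
cellcount_cv: 0.1             # flow-cytometry triplicate CV
weight_cv: 0.1                # content/tissue weight CV
seq_depth_mean: 50000
seq_depth_dispersion: 10      # negative-binomial library-size dispersion
copy_number_range: [1, 10]    # 16S copy numbers drawn uniformly, 0.1 steps

tracer:
  baseline_atom_pct_13C: 1.07   # natural 13C abundance
  baseline_atom_pct_15N: 0.37
  excess_atom_pct_13C:          # labeled mice, atom% above baseline
    CD:  {small_intestine: 0.30, cecum: 0.50, colon: 0.80}
    FFD: {small_intestine: 0.15, cecum: 0.25, colon: 0.40}
  pct_C: {CD: 45, FFD: 38}      # FFD lumen is carbon-poorer
  pct_N: 5
  measurement_cv: 0.1

seed: 20220901
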