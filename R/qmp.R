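# Quantitative microbiome profiling: read counts -> copy-number-corrected
# relative abundances -> absolute abundances per gram (via flow-cytometry
# cell density) -> loads per whole compartment (via luminal content wet
# weight).

#' Copy-number-corrected relative abundances
#'
#' Divides each taxon's reads by its 16S rRNA gene copy number and
#' renormalizes: `out_j = (r_j / c_j) / sum_k (r_k / c_k)`. Removes the
#' amplification bias of multi-copy taxa; invariant to rescaling all
#' copy numbers by a constant.
#'
#' @param reads non-negative read counts (real-valued expected counts are
#'   accepted), at least one positive.
#' @param copy_numbers copy numbers (>= 1), same length as `reads`.
#' @return corrected relative abundances summing to 1.
#' @export
copy_number_correct <- function(reads, copy_numbers) {
  stopifnot(length(reads) == length(copy_numbers))
  if (any(reads < 0)) stop("reads must be >= 0")
  if (any(!is.finite(copy_numbers)) || any(copy_numbers <= 0)) {
    stop("copy numbers must be positive and finite")
  }
  w <- reads / copy_numbers
  tot <- sum(w)
  if (tot <= 0) stop("sample has zero reads; cannot normalize")
  w / tot
}

#' Absolute abundance per gram
#'
#' Scales corrected relative abundances by the flow-cytometry total cell
#' density so the taxon vector sums to cells per gram of content.
#'
#' @param rel_corrected relative abundances summing to 1.
#' @param cell_density_cells_per_g total microbial density (>= 0); the
#'   mean of the flow-cytometry triplicate, computed upstream.
#' @return absolute abundances (cells per gram) summing to the density.
#' @export
absolute_per_gram <- function(rel_corrected, cell_density_cells_per_g) {
  if (abs(sum(rel_corrected) - 1) > 1e-6) {
    stop("rel_corrected must sum to 1")
  }
  if (is.na(cell_density_cells_per_g) || cell_density_cells_per_g < 0) {
    stop("cell density must be a non-negative number")
  }
  rel_corrected * cell_density_cells_per_g
}

#' Load per whole compartment
#'
#' Multiplies per-gram abundances by the wet weight of the luminal
#' content, yielding total cells per intestinal compartment. Undefined
#' for feces (pellets are not a compartment with a content weight).
#'
#' @param abs_per_g absolute abundances, cells per gram.
#' @param content_wet_weight_g luminal content wet weight (>= 0).
#' @param compartment compartment name; `"feces"` is rejected.
#' @return absolute abundances per compartment (cells).
#' @export
load_per_compartment <- function(abs_per_g, content_wet_weight_g,
                                 compartment = "cecum") {
  if (identical(compartment, "feces")) {
    stop("per-compartment load is undefined for feces samples")
  }
  if (is.na(content_wet_weight_g) || content_wet_weight_g < 0) {
    stop("content wet weight must be a non-negative number")
  }
  abs_per_g * content_wet_weight_g
}

#' Total sample load
#'
#' Sums per-compartment absolute abundances over taxa: the total number
#' of microbial cells in the compartment.
#'
#' @param x a `qmp_abundance` object (see [qmp_profile()]) or a samples x
#'   taxa matrix of per-compartment abundances.
#' @return named vector of per-sample loads (cells).
#' @export
sample_load <- function(x) {
  mat <- if (inherits(x, "qmp_abundance")) x$abs_per_compartment else x
  rowSums(mat)
}

#' Quantitative microbiome profile of a study
#'
#' Applies [copy_number_correct()], [absolute_per_gram()] and
#' [load_per_compartment()] sample-wise. Samples without a cell density
#' get `NA` absolute abundances; feces samples (or samples without a
#' content weight) get `NA` per-compartment loads.
#'
#' @param study a `qmp_study`.
#' @return a `qmp_abundance` object: list with samples x taxa matrices
#'   `rel_corrected`, `abs_per_g`, `abs_per_compartment`, the vector
#'   `sample_load_per_compartment`, and the study `metadata`.
#' @export
qmp_profile <- function(study) {
  stopifnot(inherits(study, "qmp_study"))
  counts <- study$counts
  cn <- study$copy_numbers[colnames(counts)]
  md <- study$metadata

  rel <- t(apply(counts, 1, function(r) {
    if (sum(r) <= 0) rep(NA_real_, length(r)) else copy_number_correct(r, cn)
  }))
  dimnames(rel) <- dimnames(counts)

  dens <- md$cell_density_cells_per_g
  abs_g <- rel * ifelse(is.na(dens), NA_real_, dens)

  wet <- ifelse(md$compartment == "feces", NA_real_, md$content_wet_weight_g)
  abs_comp <- abs_g * ifelse(is.na(wet), NA_real_, wet)

  structure(list(
    rel_corrected = rel,
    abs_per_g = abs_g,
    abs_per_compartment = abs_comp,
    sample_load_per_compartment = rowSums(abs_comp),
    metadata = md
  ), class = "qmp_abundance")
}

#' Write an abundance profile as a long TSV
#'
#' One row per sample x taxon with `rel_corrected`, `abs_per_g` and
#' `abs_per_compartment` columns.
#'
#' @param profile a `qmp_abundance`.
#' @param path output TSV path.
#' @param header optional `#` comment lines (e.g. the run seed).
#' @return invisibly, `path`.
#' @export
write_abundance <- function(profile, path, header = NULL) {
  stopifnot(inherits(profile, "qmp_abundance"))
  long <- data.frame(
    sample_id = rep(rownames(profile$rel_corrected),
                    times = ncol(profile$rel_corrected)),
    taxon_id = rep(colnames(profile$rel_corrected),
                   each = nrow(profile$rel_corrected)),
    rel_corrected = as.vector(profile$rel_corrected),
    abs_per_g = as.vector(profile$abs_per_g),
    abs_per_compartment = as.vector(profile$abs_per_compartment)
  )
  write_tsv(long, path, header)
}
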