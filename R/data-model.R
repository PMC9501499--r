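# Domain vocabulary shared across the pipeline. Compartments are the
# intestinal segments sampled at sacrifice plus feces (time-series pellets,
# which carry no luminal content weight and therefore no per-compartment
# load).
QMP_COMPARTMENTS <- c("small_intestine", "cecum", "colon", "feces")
QMP_DIETS <- c("CD", "FFD")
QMP_DAYS <- c(0L, 2L, 7L)

QMP_METADATA_COLS <- c(
  "sample_id", "mouse_id", "sex", "diet", "day", "compartment",
  "content_wet_weight_g", "content_dry_weight_g", "tissue_weight_g",
  "body_weight_g", "cell_density_cells_per_g"
)

#' Assemble and validate a QMP study object
#'
#' A study bundles the three inputs every downstream stage consumes: a
#' genus-level read-count matrix, per-sample metadata (diet, day,
#' compartment, content weights, flow-cytometry cell density), and a
#' 16S rRNA gene copy-number table.
#'
#' @param counts numeric matrix, samples x taxa, non-negative integer read
#'   counts with unique row (sample) and column (taxon) names.
#' @param metadata data.frame with one row per sample; see
#'   `QMP_METADATA_COLS` for the required columns. Every sample present in
#'   `counts` must have a metadata row.
#' @param copy_numbers named numeric vector of 16S gene copy numbers
#'   (>= 1), named by taxon.
#' @param default_copy_number value used (with a warning) for taxa absent
#'   from `copy_numbers`; `NULL` (the default) makes a missing taxon an
#'   error.
#' @param integer_counts if `TRUE` (default) counts must be integer-valued;
#'   set `FALSE` for expected (real-valued) read tables from the noise-free
#'   generator.
#' @return an object of class `qmp_study`: a list with elements `counts`,
#'   `metadata`, `copy_numbers`.
#' @export
qmp_study <- function(counts, metadata, copy_numbers,
                      default_copy_number = NULL, integer_counts = TRUE) {
  counts <- validate_counts(counts, integer_counts = integer_counts)
  metadata <- validate_metadata(metadata)

  missing_meta <- setdiff(rownames(counts), metadata$sample_id)
  if (length(missing_meta) > 0) {
    stop("samples present in counts but missing metadata: ",
         paste(missing_meta, collapse = ", "))
  }
  # keep metadata in count order; metadata-only samples are dropped silently
  metadata <- metadata[match(rownames(counts), metadata$sample_id), ,
                       drop = FALSE]
  rownames(metadata) <- NULL

  copy_numbers <- validate_copy_numbers(copy_numbers)
  missing_cn <- setdiff(colnames(counts), names(copy_numbers))
  if (length(missing_cn) > 0) {
    if (is.null(default_copy_number)) {
      stop("taxa without a copy number and no default given: ",
           paste(missing_cn, collapse = ", "))
    }
    warning("using default copy number ", default_copy_number, " for ",
            length(missing_cn), " taxa: ",
            paste(missing_cn, collapse = ", "))
    filled <- rep(default_copy_number, length(missing_cn))
    names(filled) <- missing_cn
    copy_numbers <- c(copy_numbers, filled)
  }
  copy_numbers <- copy_numbers[colnames(counts)]

  structure(list(counts = counts, metadata = metadata,
                 copy_numbers = copy_numbers),
            class = "qmp_study")
}

validate_counts <- function(counts, integer_counts = TRUE) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("counts must be a numeric matrix (samples x taxa)")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have sample rownames and taxon colnames")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate sample_id in counts")
  if (anyDuplicated(colnames(counts))) stop("duplicate taxon_id in counts")
  if (anyNA(counts) || any(!is.finite(counts))) {
    stop("counts contain missing or non-finite values")
  }
  if (any(counts < 0)) stop("negative count found")
  if (integer_counts) {
    if (any(abs(counts - round(counts)) > 1e-8)) {
      stop("counts must be integer-valued")
    }
    if (max(counts) < .Machine$integer.max) {
      dn <- dimnames(counts)
      counts <- matrix(as.integer(round(counts)), nrow(counts),
                       dimnames = dn)
    }
  }
  zero <- rownames(counts)[rowSums(counts) == 0]
  if (length(zero) > 0) {
    warning("samples with zero reads: ", paste(zero, collapse = ", "))
  }
  counts
}

validate_metadata <- function(metadata) {
  if (!is.data.frame(metadata)) stop("metadata must be a data.frame")
  missing_cols <- setdiff(QMP_METADATA_COLS, names(metadata))
  if (length(missing_cols) > 0) {
    stop("metadata missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(metadata$sample_id)) {
    stop("duplicate sample_id in metadata")
  }
  bad_diet <- setdiff(unique(metadata$diet), QMP_DIETS)
  if (length(bad_diet) > 0) {
    stop("diet must be one of ", paste(QMP_DIETS, collapse = "/"),
         "; found: ", paste(bad_diet, collapse = ", "))
  }
  bad_comp <- setdiff(unique(metadata$compartment), QMP_COMPARTMENTS)
  if (length(bad_comp) > 0) {
    stop("compartment must be one of ",
         paste(QMP_COMPARTMENTS, collapse = "/"),
         "; found: ", paste(bad_comp, collapse = ", "))
  }
  if (!all(metadata$day %in% QMP_DAYS)) {
    stop("day must be one of ", paste(QMP_DAYS, collapse = "/"))
  }
  wet <- metadata$content_wet_weight_g
  dry <- metadata$content_dry_weight_g
  both <- !is.na(wet) & !is.na(dry)
  if (any(dry[both] > wet[both] + 1e-12)) {
    stop("content_dry_weight_g exceeds content_wet_weight_g for sample(s): ",
         paste(metadata$sample_id[both][dry[both] > wet[both] + 1e-12],
               collapse = ", "))
  }
  for (col in c("content_wet_weight_g", "content_dry_weight_g",
                "tissue_weight_g", "cell_density_cells_per_g")) {
    v <- metadata[[col]]
    if (any(!is.na(v) & v < 0)) stop(col, " must be >= 0")
  }
  bw <- metadata$body_weight_g
  if (any(!is.na(bw) & bw <= 0)) stop("body_weight_g must be > 0")
  metadata
}

validate_copy_numbers <- function(copy_numbers) {
  if (!is.numeric(copy_numbers) || is.null(names(copy_numbers))) {
    stop("copy_numbers must be a named numeric vector")
  }
  if (anyDuplicated(names(copy_numbers))) {
    stop("duplicate taxon_id in copy_numbers")
  }
  if (any(!is.finite(copy_numbers)) || any(copy_numbers < 1)) {
    stop("copy numbers must be finite and >= 1")
  }
  copy_numbers
}

#' Library sizes (total reads per sample)
#'
#' @param x a `qmp_study` or a samples x taxa count matrix.
#' @return named numeric vector of per-sample read totals.
#' @export
library_sizes <- function(x) {
  counts <- if (inherits(x, "qmp_study")) x$counts else x
  rowSums(counts)
}

#' Read a study from TSV files
#'
#' `counts.tsv` holds the genus read table with a leading `taxon_id`
#' column and one column per sample; `metadata.tsv` one row per sample;
#' `copy_numbers.tsv` columns `taxon_id`, `copy_number`. Lines starting
#' with `#` (run headers) are skipped.
#'
#' @param count_path,metadata_path,copy_number_path TSV file paths.
#' @inheritParams qmp_study
#' @return a validated `qmp_study`.
#' @export
read_study <- function(count_path, metadata_path, copy_number_path,
                       default_copy_number = NULL, integer_counts = TRUE) {
  counts_df <- read_tsv_checked(count_path, "taxon_id")
  mat <- as.matrix(counts_df[, -1, drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric cell in count table ", count_path)
  rownames(mat) <- counts_df$taxon_id
  counts <- t(mat)  # on disk taxa x samples; in memory samples x taxa

  metadata <- read_tsv_checked(metadata_path, "sample_id")
  cn_df <- read_tsv_checked(copy_number_path, "taxon_id")
  if (!"copy_number" %in% names(cn_df)) {
    stop("copy_numbers.tsv must have a copy_number column")
  }
  cn <- stats::setNames(cn_df$copy_number, cn_df$taxon_id)

  qmp_study(counts, metadata, cn,
            default_copy_number = default_copy_number,
            integer_counts = integer_counts)
}

read_tsv_checked <- function(path, first_col) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    utils::read.delim(path, sep = "\t", header = TRUE,
                      check.names = FALSE, comment.char = "#",
                      stringsAsFactors = FALSE),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (names(df)[1] != first_col) {
    stop(path, ": first column must be '", first_col, "', found '",
         names(df)[1], "'")
  }
  df
}

#' Write a study to TSV files
#'
#' Inverse of [read_study()]: writes `counts.tsv`, `metadata.tsv` and
#' `copy_numbers.tsv` into `dir`. Real values are written with 17
#' significant digits so a read/write round trip is exact for doubles
#' (and in particular preserves 12 significant digits).
#'
#' @param study a `qmp_study`.
#' @param dir output directory (created if absent).
#' @param header optional character vector written as leading `#` comment
#'   lines in every file (e.g. the run seed).
#' @return invisibly, the paths written.
#' @export
write_study <- function(study, dir, header = NULL) {
  stopifnot(inherits(study, "qmp_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  counts_df <- data.frame(taxon_id = colnames(study$counts),
                          t(study$counts), check.names = FALSE)
  cn_df <- data.frame(taxon_id = names(study$copy_numbers),
                      copy_number = unname(study$copy_numbers))
  paths <- c(counts = file.path(dir, "counts.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             copy_numbers = file.path(dir, "copy_numbers.tsv"))
  write_tsv(counts_df, paths["counts"], header)
  write_tsv(study$metadata, paths["metadata"], header)
  write_tsv(cn_df, paths["copy_numbers"], header)
  invisible(paths)
}

# TSV writer shared by all pipeline outputs: optional '#' header lines,
# reals at 17 significant digits (exact double round trip), no quoting.
write_tsv <- function(df, path, header = NULL) {
  num <- vapply(df, function(col) is.numeric(col) && !is.integer(col),
                logical(1))
  out <- df
  for (j in which(num)) {
    out[[j]] <- ifelse(is.na(df[[j]]), NA,
                       formatC(df[[j]], digits = 17, format = "g"))
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Drop samples below a minimum library size
#'
#' Low-depth libraries are removed before diversity and differential
#' analyses; the default threshold is 1000 reads.
#'
#' @param study a `qmp_study`.
#' @param min_reads minimum library size to keep (>= 0).
#' @return the filtered `qmp_study` (taxon set unchanged). Idempotent.
#' @export
filter_min_reads <- function(study, min_reads = 1000) {
  stopifnot(inherits(study, "qmp_study"), min_reads >= 0)
  keep <- library_sizes(study) >= min_reads
  if (!any(keep)) {
    stop("no samples with >= ", min_reads,
         " reads; the filtered study would be empty")
  }
  study$counts <- study$counts[keep, , drop = FALSE]
  study$metadata <- study$metadata[keep, , drop = FALSE]
  rownames(study$metadata) <- NULL
  study
}

#' @export
print.qmp_study <- function(x, ...) {
  cat("qmp_study:", nrow(x$counts), "samples x", ncol(x$counts), "taxa\n")
  cat("  diets:", paste(sort(unique(x$metadata$diet)), collapse = ", "),
      " compartments:",
      paste(sort(unique(x$metadata$compartment)), collapse = ", "), "\n")
  invisible(x)
}
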