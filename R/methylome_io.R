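#' @keywords internal
"_PACKAGE"

# Missing-value tokens accepted in beta matrices (case-insensitive).
.missing_tokens <- c("na", "", "nan")

# Pick a field separator from the file extension; default tab.
.sep_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

.strip_chr <- function(chrom) sub("^chr", "", as.character(chrom), ignore.case = TRUE)

.is_missing_token <- function(x) {
  x <- tolower(trimws(x))
  is.na(x) | x %in% .missing_tokens
}

#' Read a beta-value matrix
#'
#' Reads a TSV/CSV table of DNA methylation beta values (fractions in
#' \[0, 1\]) into a numeric matrix with probes in rows and samples in
#' columns. The first column of the file holds the row identifiers.
#' Missing values may be encoded as `NA`, `NaN` or an empty cell
#' (case-insensitive).
#'
#' @param path Path to a TSV (tab) or CSV (comma) file with a header row.
#' @param dialect Either `"probes_in_rows"` (default) or
#'   `"samples_in_rows"`; the latter transposes on read so the returned
#'   matrix is always probes x samples.
#' @return A numeric matrix with unique `rownames` (probe ids) and
#'   `colnames` (sample ids); values in \[0, 1\] or `NA`.
#' @export
read_beta_matrix <- function(path, dialect = c("probes_in_rows", "samples_in_rows")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = .sep_for(path),
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "", stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("beta matrix file must have an id column plus data columns: ", path)
  ids <- trimws(raw[[1L]])
  cols <- colnames(raw)[-1L]
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  vals <- matrix(NA_real_, nrow = nrow(cells), ncol = ncol(cells),
                 dimnames = list(ids, cols))
  miss <- matrix(.is_missing_token(cells), nrow = nrow(cells))
  num <- suppressWarnings(as.numeric(cells[!miss]))
  bad <- which(!miss, arr.ind = TRUE)[is.na(num), , drop = FALSE]
  if (nrow(bad) > 0L) {
    stop(sprintf("cannot parse value '%s' at row '%s', column '%s'",
                 cells[bad[1L, 1L], bad[1L, 2L]], ids[bad[1L, 1L]], cols[bad[1L, 2L]]))
  }
  vals[!miss] <- num
  out <- which(!is.na(vals) & (vals < 0 | vals > 1), arr.ind = TRUE)
  if (nrow(out) > 0L) {
    stop(sprintf("beta value %s out of [0, 1] at row '%s', column '%s'",
                 format(vals[out[1L, , drop = FALSE]]),
                 ids[out[1L, 1L]], cols[out[1L, 2L]]))
  }
  if (identical(dialect, "samples_in_rows")) vals <- t(vals)
  validate_beta_matrix(vals)
  vals
}

#' Validate a beta matrix
#'
#' Checks the invariants of the probes x samples beta matrix container:
#' numeric matrix, unique non-empty dimnames, all non-missing values in
#' \[0, 1\].
#'
#' @param mat A numeric matrix.
#' @return `mat`, invisibly, if valid; otherwise an error.
#' @export
validate_beta_matrix <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat)) stop("beta matrix must be a numeric matrix")
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("beta matrix must have probe rownames and sample colnames")
  if (anyDuplicated(rownames(mat))) stop("duplicate probe ids in beta matrix")
  if (anyDuplicated(colnames(mat))) stop("duplicate sample ids in beta matrix")
  v <- mat[!is.na(mat)]
  if (length(v) && (min(v) < 0 || max(v) > 1))
    stop("beta values must lie in [0, 1]")
  invisible(mat)
}

#' Write a beta-value matrix
#'
#' @param mat Probes x samples numeric matrix (see [read_beta_matrix()]).
#' @param path Output path; `.csv` writes comma-separated, anything else tab.
#' @param digits Decimal places written (fixed notation); default 6.
#' @param id_col Name of the identifier column; default `"probe_id"`.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(mat, path, digits = 6L, id_col = "probe_id") {
  validate_beta_matrix(mat)
  txt <- matrix(formatC(mat, digits = digits, format = "f"),
                nrow = nrow(mat), dimnames = dimnames(mat))
  txt[is.na(mat)] <- "NA"
  df <- data.frame(id = rownames(mat), txt, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_col
  utils::write.table(df, path, sep = .sep_for(path), quote = FALSE, row.names = FALSE)
  invisible(path)
}

.require_columns <- function(df, cols, what) {
  miss <- setdiff(cols, colnames(df))
  if (length(miss))
    stop(what, " is missing required column(s): ", paste(miss, collapse = ", "))
}

#' Read a sample sheet
#'
#' Reads per-sample metadata: sample id, mouse strain (e.g. `B6`, `DBA`),
#' sex (`M`/`F`) and chronological age in weeks. Extra columns are kept.
#'
#' @param path CSV/TSV file with columns `sample_id,strain,sex,age_weeks`.
#' @return A `data.frame` with one row per sample.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = .sep_for(path),
                          stringsAsFactors = FALSE, check.names = FALSE)
  .require_columns(df, c("sample_id", "strain", "sex", "age_weeks"), "sample sheet")
  df$sample_id <- as.character(df$sample_id)
  df$strain <- as.character(df$strain)
  df$sex <- as.character(df$sex)
  df$age_weeks <- as.numeric(df$age_weeks)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in sample sheet")
  if (!all(df$sex %in% c("M", "F"))) stop("sex must be 'M' or 'F'")
  if (any(is.na(df$age_weeks)) || any(df$age_weeks <= 0))
    stop("age_weeks must be positive")
  df
}

.context_levels <- c("island", "shore", "shelf", "open_sea")

#' Read a probe annotation table
#'
#' Reads per-probe genomic annotation: chromosome, 1-based position,
#' island-context category (`island`, `shore`, `shelf`, `open_sea`), gene
#' symbol, and SNP / cross-reactive flags.
#'
#' @param path CSV/TSV file with columns
#'   `probe_id,chrom,pos,context,gene,is_snp,is_cross_reactive`.
#' @return A `data.frame` with one row per probe.
#' @export
read_probe_annotation <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = .sep_for(path),
                          stringsAsFactors = FALSE, check.names = FALSE)
  .require_columns(df, c("probe_id", "chrom", "pos", "context", "gene",
                         "is_snp", "is_cross_reactive"), "probe annotation")
  df$probe_id <- as.character(df$probe_id)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df$context <- as.character(df$context)
  df$gene <- as.character(df$gene)
  df$is_snp <- as.logical(df$is_snp)
  df$is_cross_reactive <- as.logical(df$is_cross_reactive)
  if (anyDuplicated(df$probe_id)) stop("duplicate probe_id in annotation")
  if (!all(df$context %in% .context_levels))
    stop("unknown context label(s): ",
         paste(unique(setdiff(df$context, .context_levels)), collapse = ", "))
  if (any(df$pos < 1L, na.rm = TRUE)) stop("positions must be >= 1 (1-based)")
  df
}

#' Read a mouse-to-human homology table
#'
#' Each row pairs a mouse array probe with a human genomic interval from a
#' ~121-nt homology alignment window. Coordinates are 1-based inclusive.
#'
#' @param path TSV/CSV with columns `mouse_probe_id,mouse_chrom,mouse_pos,
#'   human_chrom,human_start,human_end,strand_flip`.
#' @return A `data.frame` of homology regions.
#' @export
read_homology_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = .sep_for(path),
                          stringsAsFactors = FALSE, check.names = FALSE)
  .require_columns(df, c("mouse_probe_id", "mouse_chrom", "mouse_pos",
                         "human_chrom", "human_start", "human_end",
                         "strand_flip"), "homology table")
  df$human_start <- as.integer(df$human_start)
  df$human_end <- as.integer(df$human_end)
  df$mouse_pos <- as.integer(df$mouse_pos)
  df$strand_flip <- as.logical(df$strand_flip)
  if (any(df$human_start > df$human_end))
    stop("homology regions must satisfy human_start <= human_end")
  width <- df$human_end - df$human_start + 1L
  if (any(width < 100L | width > 150L))
    warning("homology window width outside the expected 100-150 nt range for ",
            sum(width < 100L | width > 150L), " region(s)")
  df
}

#' Quality-control filtering of a beta matrix
#'
#' Applies the array QC cascade: (1) probes with any detection p-value
#' above `detection_p_threshold` are removed (skipped with a message when
#' no detection p-values are supplied, as processed beta exports usually
#' lack them); (2) probes missing in more than `max_probe_missing` of
#' samples are removed; (3) samples missing more than `max_sample_missing`
#' of the surviving probes are removed; (4) optionally, X/Y-chromosome
#' probes are removed. Probe filtering deliberately precedes sample
#' filtering so that bad probes do not inflate sample missingness.
#'
#' @param mat Probes x samples beta matrix.
#' @param annotation Optional probe annotation `data.frame` (required for
#'   `drop_xy`).
#' @param detection_p Optional probes x samples matrix of detection
#'   p-values aligned by dimnames.
#' @param detection_p_threshold Probes with any detection p-value above
#'   this are dropped; default 0.01.
#' @param max_probe_missing Maximum tolerated fraction of missing values
#'   per probe; default 0.10.
#' @param max_sample_missing Maximum tolerated fraction of missing values
#'   per sample (after probe filtering); default 0.10.
#' @param drop_xy Remove probes on the X or Y chromosome; default `FALSE`.
#'   Clock analyses drop them; the all-sample correlation matrix keeps them.
#' @return A list with elements `betas` (the filtered matrix) and `report`
#'   (class `qc_report`: removal tallies and removed sample ids).
#' @export
qc_filter <- function(mat, annotation = NULL, detection_p = NULL,
                      detection_p_threshold = 0.01,
                      max_probe_missing = 0.10, max_sample_missing = 0.10,
                      drop_xy = FALSE) {
  validate_beta_matrix(mat)
  report <- list(probes_removed_detection = 0L, probes_removed_missing = 0L,
                 samples_removed = character(0), probes_removed_xy = 0L)

  if (is.null(detection_p)) {
    message("no detection p-values supplied; detection filter skipped")
  } else {
    shared <- intersect(rownames(mat), rownames(detection_p))
    dp <- detection_p[shared, colnames(mat), drop = FALSE]
    bad <- shared[apply(dp, 1L, function(p) any(p > detection_p_threshold, na.rm = TRUE))]
    report$probes_removed_detection <- length(bad)
    mat <- mat[setdiff(rownames(mat), bad), , drop = FALSE]
  }

  probe_missing <- rowMeans(is.na(mat))
  drop_probes <- probe_missing > max_probe_missing
  report$probes_removed_missing <- sum(drop_probes)
  mat <- mat[!drop_probes, , drop = FALSE]

  sample_missing <- colMeans(is.na(mat))
  drop_samples <- sample_missing > max_sample_missing
  report$samples_removed <- colnames(mat)[drop_samples]
  mat <- mat[, !drop_samples, drop = FALSE]
  if (ncol(mat) == 0L) stop("QC removed every sample: empty cohort")

  if (isTRUE(drop_xy)) {
    if (is.null(annotation)) stop("drop_xy = TRUE requires a probe annotation")
    xy <- annotation$probe_id[.strip_chr(annotation$chrom) %in% c("X", "Y")]
    hit <- intersect(rownames(mat), xy)
    report$probes_removed_xy <- length(hit)
    mat <- mat[setdiff(rownames(mat), hit), , drop = FALSE]
  }

  class(report) <- "qc_report"
  list(betas = mat, report = report)
}

#' Write a QC report as JSON
#'
#' @param report A `qc_report` from [qc_filter()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  cat("  probes removed (detection p):", x$probes_removed_detection, "\n")
  cat("  probes removed (missingness):", x$probes_removed_missing, "\n")
  cat("  probes removed (X/Y):       ", x$probes_removed_xy, "\n")
  cat("  samples removed:            ",
      if (length(x$samples_removed)) paste(x$samples_removed, collapse = ", ") else "none", "\n")
  invisible(x)
}
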