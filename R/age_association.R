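#' Normalize chronological ages within strain and sex
#'
#' Mouse strains differ in life expectancy (C57BL/6 about 2.42 years,
#' DBA/2J about 1.87), so chronological age is put on a common scale
#' before CpGs are compared across strains. The default min-max transform
#' maps each (strain, sex) group's observed age range onto \[0, 1\]; with
#' beta values naturally on \[0, 1\], a slope of 0.3 then reads as a 30%
#' absolute methylation change over the observed lifespan. The
#' `"lifespan"` alternative divides age by the strain's life expectancy
#' in weeks.
#'
#' @param sheet Sample sheet `data.frame` (see [read_sample_sheet()]).
#' @param method `"minmax"` (default) or `"lifespan"`.
#' @param lifespan_weeks Named vector of strain life expectancies in weeks
#'   used by the `"lifespan"` method; defaults to 2.42 y (B6) and 1.87 y
#'   (DBA) at 52.1775 weeks/year.
#' @return The sample sheet with an added `age_norm` column.
#' @export
normalize_ages <- function(sheet, method = c("minmax", "lifespan"),
                           lifespan_weeks = c(B6 = 2.42 * 52.1775, DBA = 1.87 * 52.1775)) {
  method <- match.arg(method)
  .require_columns(sheet, c("sample_id", "strain", "sex", "age_weeks"), "sample sheet")
  if (method == "minmax") {
    key <- interaction(sheet$strain, sheet$sex, drop = TRUE)
    x <- rep(NA_real_, nrow(sheet))
    for (g in levels(key)) {
      i <- key == g
      a <- sheet$age_weeks[i]
      if (length(unique(a)) < 2L)
        stop("degenerate group '", g, "': need >= 2 distinct ages to normalize")
      x[i] <- (a - min(a)) / (max(a) - min(a))
    }
  } else {
    unknown <- setdiff(unique(sheet$strain), names(lifespan_weeks))
    if (length(unknown))
      stop("no life expectancy supplied for strain(s): ", paste(unknown, collapse = ", "))
    x <- sheet$age_weeks / lifespan_weeks[sheet$strain]
  }
  sheet$age_norm <- as.numeric(x)
  sheet
}

.paired_complete <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  list(x = x[keep], y = y[keep], n = sum(keep))
}

#' Age-association slope for one CpG
#'
#' The CpG selection statistic: the least-squares slope of beta value on
#' normalized age, `sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)`.
#' With age normalized to \[0, 1\] its magnitude is the absolute DNAm
#' change over the observed lifespan. Missing pairs are dropped pairwise.
#'
#' @param x Normalized ages.
#' @param y Beta values for one probe, same length as `x`.
#' @return The slope (a single numeric).
#' @export
slope_cpg <- function(x, y) {
  p <- .paired_complete(x, y)
  if (p$n < 3L) stop("need >= 3 paired non-missing observations")
  xc <- p$x - mean(p$x)
  sxx <- sum(xc^2)
  if (sxx == 0) stop("degenerate predictor: normalized ages have zero variance")
  sum(xc * (p$y - mean(p$y))) / sxx
}

#' Pearson correlation of methylation with age
#'
#' Pairwise-complete Pearson correlation coefficient; errors when either
#' vector has zero variance instead of returning `NA`.
#'
#' @param x Ages (normalized or raw — the coefficient is scale-free).
#' @param y Beta values for one probe.
#' @return The correlation coefficient in \[-1, 1\].
#' @export
pearson_age_r <- function(x, y) {
  p <- .paired_complete(x, y)
  if (p$n < 3L) stop("need >= 3 paired non-missing observations")
  if (stats::var(p$x) == 0 || stats::var(p$y) == 0)
    stop("undefined correlation: zero variance")
  stats::cor(p$x, p$y)
}

#' Per-probe slope and correlation table
#'
#' Computes the slope statistic and Pearson r for every probe of a beta
#' matrix against a vector of normalized ages. Rows without missing
#' values are handled with vectorized cross-products; rows with missing
#' values fall back to the pairwise-complete scalar path.
#'
#' @param mat Probes x samples beta matrix.
#' @param x Normalized ages, either named by sample id or in column order.
#' @param min_n Minimum paired observations per probe; probes below it get
#'   `NA` results. Default 3.
#' @return A `data.frame` with columns `probe_id`, `slope`, `pearson_r`, `n`.
#' @export
slope_table <- function(mat, x, min_n = 3L) {
  validate_beta_matrix(mat)
  if (!is.null(names(x))) {
    miss <- setdiff(colnames(mat), names(x))
    if (length(miss)) stop("normalized ages missing for sample(s): ",
                           paste(utils::head(miss, 3L), collapse = ", "))
    x <- x[colnames(mat)]
  }
  if (length(x) != ncol(mat)) stop("length(x) must equal ncol(mat)")
  n_probe <- nrow(mat)
  slope <- rep(NA_real_, n_probe)
  r <- rep(NA_real_, n_probe)
  n <- integer(n_probe)
  complete <- !apply(is.na(mat), 1L, any)
  if (any(complete)) {
    xc <- x - mean(x)
    sxx <- sum(xc^2)
    if (sxx == 0) stop("degenerate predictor: normalized ages have zero variance")
    Y <- mat[complete, , drop = FALSE]
    sxy <- as.vector(Y %*% xc)               # sum((x - mean x) * y) == centered cross product
    slope[complete] <- sxy / sxx
    ys <- sqrt(pmax(rowSums(Y^2) - length(x) * rowMeans(Y)^2, 0))
    rr <- ifelse(ys > 0, sxy / (sqrt(sxx) * ys), NA_real_)
    r[complete] <- pmin(1, pmax(-1, rr))
    n[complete] <- length(x)
  }
  for (i in which(!complete)) {
    p <- .paired_complete(x, mat[i, ])
    n[i] <- p$n
    if (p$n < min_n) next
    slope[i] <- slope_cpg(p$x, p$y)
    r[i] <- tryCatch(pearson_age_r(p$x, p$y), error = function(e) NA_real_)
  }
  data.frame(probe_id = rownames(mat), slope = slope, pearson_r = r, n = n,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Select age-associated candidate CpGs in one strain
#'
#' Keeps probes whose slope statistic exceeds the threshold in magnitude
#' (strictly: `|slope| > threshold`), i.e. CpGs with a large absolute
#' methylation change over the normalized lifespan. The matrix should be
#' QC-filtered with X/Y probes removed before selection.
#'
#' @param mat Beta matrix restricted to one strain's samples.
#' @param x Normalized ages for those samples (named or column-ordered).
#' @param threshold Slope-magnitude cutoff; default 0.3 (a 30% DNAm change).
#' @param strain Optional strain label carried into the result.
#' @return An object of class `candidate_set`: list with `strain`,
#'   `threshold`, `probe_ids` and the full slope `table`.
#' @export
select_candidates <- function(mat, x, threshold = 0.3, strain = NA_character_) {
  tab <- slope_table(mat, x)
  keep <- !is.na(tab$slope) & abs(tab$slope) > threshold
  structure(list(strain = strain, threshold = threshold,
                 probe_ids = tab$probe_id[keep], table = tab),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("candidate_set: %d CpGs with |slope| > %g (strain %s) of %d tested\n",
              length(x$probe_ids), x$threshold, x$strain, nrow(x$table)))
  invisible(x)
}

#' Intersect candidate sets across strains
#'
#' Cross-strain conserved candidates are the intersection of the
#' per-strain selections; the exclusive counts give the Venn layout.
#'
#' @param a,b `candidate_set` objects (or plain character vectors of probe ids).
#' @return A list of class `candidate_venn` with `shared`, `only_a`,
#'   `only_b` (probe id vectors) and a named `counts` vector.
#' @export
intersect_candidates <- function(a, b) {
  ids <- function(s) if (inherits(s, "candidate_set")) s$probe_ids else as.character(s)
  lab <- function(s, default) if (inherits(s, "candidate_set") && !is.na(s$strain)) s$strain else default
  ia <- ids(a); ib <- ids(b)
  shared <- intersect(ia, ib)
  out <- list(shared = shared, only_a = setdiff(ia, ib), only_b = setdiff(ib, ia),
              strain_a = lab(a, "a"), strain_b = lab(b, "b"))
  out$counts <- c(shared = length(out$shared), only_a = length(out$only_a),
                  only_b = length(out$only_b))
  class(out) <- "candidate_venn"
  out
}

#' @export
print.candidate_venn <- function(x, ...) {
  cat(sprintf("candidate overlap: %d shared | %d only %s | %d only %s\n",
              x$counts[["shared"]], x$counts[["only_a"]], x$strain_a,
              x$counts[["only_b"]], x$strain_b))
  invisible(x)
}

#' Summarize age correlations by genomic context
#'
#' Groups per-probe age correlations by island-context category (island,
#' shore, shelf, open sea) and reports the median per category — positive
#' medians indicate predominant age-associated hypermethylation in that
#' context, negative ones hypomethylation.
#'
#' @param r Named numeric vector of per-probe Pearson correlations.
#' @param annotation Probe annotation covering all names of `r`.
#' @param breaks Optional histogram break points applied per context.
#' @return A `data.frame` with `context`, `n`, `median_r` (and histogram
#'   counts as a `"histograms"` attribute when `breaks` is given); the raw
#'   per-context values are attached as attribute `"r_values"`.
#' @export
context_summary <- function(r, annotation, breaks = NULL) {
  if (is.null(names(r))) stop("r must be a named vector of per-probe correlations")
  idx <- match(names(r), annotation$probe_id)
  if (anyNA(idx)) stop("annotation does not cover probe(s): ",
                       paste(utils::head(names(r)[is.na(idx)], 3L), collapse = ", "))
  ctx <- annotation$context[idx]
  if (!all(ctx %in% .context_levels))
    stop("unknown context label(s): ", paste(setdiff(unique(ctx), .context_levels), collapse = ", "))
  present <- .context_levels[.context_levels %in% ctx]
  vals <- lapply(present, function(cc) unname(r[ctx == cc & !is.na(r)]))
  names(vals) <- present
  out <- data.frame(context = present,
                    n = vapply(vals, length, integer(1)),
                    median_r = vapply(vals, stats::median, numeric(1)),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "r_values") <- vals
  if (!is.null(breaks)) {
    attr(out, "histograms") <- lapply(vals, function(v)
      graphics::hist(v, breaks = breaks, plot = FALSE)$counts)
  }
  out
}
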