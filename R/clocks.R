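#' Fit the single-CpG ensemble clock
#'
#' For each candidate CpG an ordinary least-squares line of normalized
#' age on beta value is fitted (age is the response). The sample sheet's
#' per-(strain, sex) age ranges are stored so that predictions on the
#' normalized \[0, 1\] scale can be mapped back to weeks. Probes with
#' zero beta variance (or fewer than 3 complete pairs) are skipped with a
#' warning and recorded in the model metadata.
#'
#' @param mat Beta matrix restricted to the candidate probes, training
#'   samples in columns.
#' @param norm_ages Output of [normalize_ages()] for the training samples
#'   (must cover every column of `mat`).
#' @param calibration `"direct"` (default; regress age on beta) or
#'   `"inverse"` (regress beta on age, then invert the line when
#'   predicting).
#' @return An object of class `ensemble_clock`: per-probe `models`
#'   (`probe_id`, `slope`, `intercept`), the `denormalizer` table of
#'   per-(strain, sex) age ranges, the `calibration` mode, and ids of
#'   `skipped` probes.
#' @export
fit_ensemble <- function(mat, norm_ages, calibration = c("direct", "inverse")) {
  calibration <- match.arg(calibration)
  validate_beta_matrix(mat)
  .require_columns(norm_ages, c("sample_id", "strain", "sex", "age_norm", "age_weeks"),
                   "normalized ages")
  idx <- match(colnames(mat), norm_ages$sample_id)
  if (anyNA(idx)) stop("normalized ages missing for sample(s): ",
                       paste(utils::head(colnames(mat)[is.na(idx)], 3L), collapse = ", "))
  x <- norm_ages$age_norm[idx]
  if (ncol(mat) < 3L) stop("need >= 3 training samples")

  fit_one <- function(y) {
    p <- .paired_complete(x, y)
    if (p$n < 3L || stats::var(p$y) == 0) return(c(NA_real_, NA_real_))
    if (calibration == "direct") {
      b <- sum((p$y - mean(p$y)) * (p$x - mean(p$x))) / sum((p$y - mean(p$y))^2)
      c(b, mean(p$x) - b * mean(p$y))
    } else {
      b <- sum((p$x - mean(p$x)) * (p$y - mean(p$y))) / sum((p$x - mean(p$x))^2)
      c(b, mean(p$y) - b * mean(p$x))
    }
  }
  coefs <- t(apply(mat, 1L, fit_one))
  skipped <- rownames(mat)[is.na(coefs[, 1L])]
  if (length(skipped))
    warning(length(skipped), " probe(s) skipped (zero variance or too few observations)")
  models <- data.frame(probe_id = rownames(mat)[!is.na(coefs[, 1L])],
                       slope = coefs[!is.na(coefs[, 1L]), 1L],
                       intercept = coefs[!is.na(coefs[, 1L]), 2L],
                       stringsAsFactors = FALSE, row.names = NULL)
  if (nrow(models) == 0L) stop("no usable probes: every candidate was skipped")

  sheet <- norm_ages[idx, ]
  key <- interaction(sheet$strain, sheet$sex, drop = TRUE)
  denorm <- do.call(rbind, lapply(levels(key), function(g) {
    i <- key == g
    data.frame(strain = sheet$strain[i][1L], sex = sheet$sex[i][1L],
               age_min = min(sheet$age_weeks[i]), age_max = max(sheet$age_weeks[i]),
               stringsAsFactors = FALSE)
  }))
  if (any(denorm$age_max <= denorm$age_min)) stop("degenerate age range in training group")

  structure(list(models = models, denormalizer = denorm,
                 calibration = calibration, skipped = skipped),
            class = "ensemble_clock")
}

#' @export
print.ensemble_clock <- function(x, ...) {
  cat(sprintf("ensemble_clock: %d single-CpG models (%s calibration), %d skipped\n",
              nrow(x$models), x$calibration, length(x$skipped)))
  invisible(x)
}

# Age range used to map normalized predictions back to weeks for a
# (strain, sex) group; falls back to the pooled training range (with a
# warning) when the group was not in the training cohort — this is how a
# B6-trained clock is applied to DBA samples.
.denorm_range <- function(clock, strain, sex) {
  d <- clock$denormalizer
  hit <- d$strain == strain & d$sex == sex
  if (any(hit)) return(c(d$age_min[hit][1L], d$age_max[hit][1L]))
  warning(sprintf("group (%s, %s) absent from training; reusing the training age range",
                  strain, sex))
  c(min(d$age_min), max(d$age_max))
}

#' Predict age with the ensemble clock
#'
#' Every clock probe present in a sample contributes the age estimate
#' `slope * beta + intercept` on the normalized scale; the arithmetic
#' mean of these single-CpG estimates is the prediction, which is then
#' mapped back to weeks using the target group's training age range.
#' Probes missing in a sample are skipped.
#'
#' @param clock An `ensemble_clock`.
#' @param betas A named beta vector for one sample, or a probes x samples
#'   matrix.
#' @param strain,sex Target group used for denormalization to weeks.
#' @return Predicted age(s) in weeks (named when `betas` is a matrix).
#' @export
predict_ensemble <- function(clock, betas, strain, sex) {
  if (is.matrix(betas)) {
    return(vapply(colnames(betas), function(s)
      predict_ensemble(clock, betas[, s], strain, sex), numeric(1)))
  }
  if (is.null(names(betas))) stop("betas must be named by probe id")
  m <- clock$models
  b <- betas[m$probe_id]
  keep <- !is.na(b)
  if (!any(keep)) stop("no overlapping probes between clock and sample")
  est <- if (clock$calibration == "direct") {
    m$slope[keep] * b[keep] + m$intercept[keep]
  } else {
    (b[keep] - m$intercept[keep]) / m$slope[keep]
  }
  xhat <- mean(est)
  rng <- .denorm_range(clock, strain, sex)
  unname(rng[1L] + xhat * (rng[2L] - rng[1L]))
}

#' Exhaustive 4-CpG multivariate clock search
#'
#' Enumerates every combination of `k` CpGs drawn from `k` distinct
#' amplicons (one CpG per amplicon — neighboring CpGs on the same
#' amplicon are highly correlated), fits ordinary least squares of age in
#' weeks on the k methylation percentages for each, and returns the
#' combination with minimal training MAD (mean absolute deviation of
#' residuals). Ties are broken by higher r-squared, then by
#' lexicographically smallest CpG label set, so the search is
#' deterministic. Rank-deficient designs are skipped.
#'
#' @param meth Samples x CpG matrix of methylation percentages (0-100),
#'   columns named by CpG label.
#' @param amplicons Named character vector mapping each CpG label to its
#'   amplicon.
#' @param ages_weeks Chronological ages in weeks, one per sample.
#' @param k Number of CpGs (and amplicons) in the model; default 4.
#' @return An object of class `multivariate_clock` with `intercept`,
#'   `terms` (`label`, `coefficient`, `amplicon`), `provenance =
#'   "fitted"`, training metrics, and the number of combinations
#'   evaluated.
#' @export
fit_multivariate <- function(meth, amplicons, ages_weeks, k = 4L) {
  meth <- as.matrix(meth)
  if (is.null(colnames(meth))) stop("meth must have CpG labels as column names")
  miss <- setdiff(colnames(meth), names(amplicons))
  if (length(miss)) stop("no amplicon assignment for CpG(s): ", paste(miss, collapse = ", "))
  amp <- amplicons[colnames(meth)]
  amps <- unique(amp)
  if (length(amps) < k) stop("need at least ", k, " distinct amplicons, got ", length(amps))
  if (nrow(meth) < k + 2L) stop("need at least k + 2 samples")
  if (length(ages_weeks) != nrow(meth)) stop("ages_weeks must match nrow(meth)")

  by_amp <- split(colnames(meth), amp)[amps]
  amp_sets <- utils::combn(amps, k, simplify = FALSE)
  best <- NULL
  n_eval <- 0L
  for (aset in amp_sets) {
    grids <- do.call(expand.grid, c(by_amp[aset], list(stringsAsFactors = FALSE)))
    for (i in seq_len(nrow(grids))) {
      labels <- as.character(grids[i, ])
      X <- cbind(1, meth[, labels, drop = FALSE])
      qrX <- qr(X)
      if (qrX$rank < k + 1L) next                       # rank-deficient design: skip
      coef <- qr.coef(qrX, ages_weeks)
      resid <- ages_weeks - X %*% coef
      mad <- mean(abs(resid))
      fitted <- ages_weeks - resid
      r2 <- if (stats::var(as.vector(fitted)) > 0)
        stats::cor(as.vector(fitted), ages_weeks)^2 else 0
      n_eval <- n_eval + 1L
      key <- paste(sort(labels), collapse = "|")
      better <- is.null(best) || mad < best$mad ||
        (mad == best$mad && (r2 > best$r2 || (r2 == best$r2 && key < best$key)))
      if (better)
        best <- list(labels = labels, coef = coef, mad = mad, r2 = r2, key = key)
    }
  }
  if (is.null(best)) stop("every combination had a rank-deficient design")
  structure(list(intercept = unname(best$coef[1L]),
                 terms = data.frame(label = best$labels,
                                    coefficient = unname(best$coef[-1L]),
                                    amplicon = unname(amp[best$labels]),
                                    stringsAsFactors = FALSE, row.names = NULL),
                 provenance = "fitted",
                 training = list(mad = best$mad, r2 = best$r2, n = nrow(meth)),
                 n_combinations = n_eval),
            class = "multivariate_clock")
}

#' The published C57BL/6 4-CpG pyrosequencing clock
#'
#' The frozen multivariate model derived from pyrosequencing of four
#' amplicons in B6 blood:
#' `age_weeks = 167.4533 + 1.2421*Aspa_pos1 + 0.9824*Hsf4_pos3 - 1.3110*Wnt3a_pos2 - 1.6088*Prima1_pos1`
#' with DNAm inputs in percent. Aspa pos1 corresponds to array probe
#' cg29748675 and Prima1 pos1 to cg31044702; Hsf4 pos3 lies 5 bp upstream
#' of cg46095458 and Wnt3a pos2 9 bp upstream of cg29601161.
#'
#' @return A `multivariate_clock` with `provenance = "published"`.
#' @export
published_b6_clock <- function() {
  structure(list(
    intercept = 167.4533,
    terms = data.frame(
      label = c("Aspa_pos1", "Hsf4_pos3", "Wnt3a_pos2", "Prima1_pos1"),
      coefficient = c(1.2421, 0.9824, -1.3110, -1.6088),
      amplicon = c("Aspa", "Hsf4", "Wnt3a", "Prima1"),
      note = c("cg29748675", "5 bp upstream of cg46095458",
               "9 bp upstream of cg29601161", "cg31044702"),
      stringsAsFactors = FALSE),
    provenance = "published"),
    class = "multivariate_clock")
}

#' @export
print.multivariate_clock <- function(x, ...) {
  signs <- ifelse(x$terms$coefficient >= 0, "+", "-")
  cat(sprintf("multivariate_clock (%s): age_weeks = %.4f %s\n", x$provenance,
              x$intercept,
              paste(sprintf("%s %.4f*%s", signs, abs(x$terms$coefficient), x$terms$label),
                    collapse = " ")))
  invisible(x)
}

#' Predict age with a multivariate clock
#'
#' Computes `intercept + sum(coefficient * DNAm%)`. The output is not
#' clamped. Inputs outside \[0, 100\] trigger a warning but are still
#' used; missing values are an error.
#'
#' @param clock A `multivariate_clock`.
#' @param dnam_percent Numeric vector of DNAm percentages, one per clock
#'   term (reordered by name when named), or a samples x terms matrix /
#'   data.frame.
#' @return Predicted age(s) in weeks.
#' @export
predict_multivariate <- function(clock, dnam_percent) {
  labels <- clock$terms$label
  if (is.matrix(dnam_percent) || is.data.frame(dnam_percent)) {
    m <- as.matrix(dnam_percent)
    if (!is.null(colnames(m))) {
      miss <- setdiff(labels, colnames(m))
      if (length(miss)) stop("missing predictor(s): ", paste(miss, collapse = ", "))
      m <- m[, labels, drop = FALSE]
    }
    if (ncol(m) != length(labels)) stop("expected ", length(labels), " predictors")
    return(apply(m, 1L, function(v) predict_multivariate(clock, stats::setNames(v, labels))))
  }
  v <- dnam_percent
  if (!is.null(names(v))) {
    miss <- setdiff(labels, names(v))
    if (length(miss)) stop("missing predictor(s): ", paste(miss, collapse = ", "))
    v <- v[labels]
  }
  if (length(v) != length(labels)) stop("expected ", length(labels), " predictor values")
  if (anyNA(v)) stop("missing predictor value(s)")
  if (any(v < 0 | v > 100))
    warning("DNAm percentage outside [0, 100]; prediction computed anyway")
  unname(clock$intercept + sum(clock$terms$coefficient * v))
}

#' Serialize / deserialize clock models as JSON
#'
#' Models are stored as plain JSON documents with full-precision
#' coefficients so a write/read round trip is bit-identical.
#'
#' @param clock An `ensemble_clock` or `multivariate_clock`.
#' @param path JSON file path.
#' @return `write_clock`: `path` invisibly; `read_clock`: the clock object.
#' @export
write_clock <- function(clock, path) {
  type <- class(clock)[1L]
  payload <- c(list(clock_type = type), unclass(clock))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' @rdname write_clock
#' @export
read_clock <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  type <- payload$clock_type
  payload$clock_type <- NULL
  if (!type %in% c("ensemble_clock", "multivariate_clock"))
    stop("unknown clock_type: ", type)
  if (!is.null(payload$terms)) payload$terms <- as.data.frame(payload$terms)
  if (!is.null(payload$models)) payload$models <- as.data.frame(payload$models)
  if (!is.null(payload$denormalizer)) payload$denormalizer <- as.data.frame(payload$denormalizer)
  if (!is.null(payload$skipped)) payload$skipped <- as.character(payload$skipped)
  structure(payload, class = type)
}

#' Prediction-accuracy metrics
#'
#' Computes the study's evaluation metrics: MAE as the *median* absolute
#' error, MAD as the *mean* absolute deviation (both in weeks), and
#' r-squared as the squared Pearson correlation of predicted versus
#' chronological age. When either vector has zero variance, a classed
#' error (`museclock_r2_undefined`) is raised; its condition object
#' carries the still-computable `mae` and `mad`.
#'
#' @param predictions,truths Numeric vectors of equal length (>= 2).
#' @return An object of class `prediction_metrics`: list with `mae`,
#'   `mad`, `r2`, `n`.
#' @export
evaluate_predictions <- function(predictions, truths) {
  if (length(predictions) != length(truths)) stop("length mismatch")
  if (length(predictions) < 2L) stop("need >= 2 prediction/truth pairs")
  err <- abs(predictions - truths)
  mae <- stats::median(err)
  mad <- mean(err)
  if (stats::var(predictions) == 0 || stats::var(truths) == 0) {
    cond <- structure(class = c("museclock_r2_undefined", "error", "condition"),
                      list(message = "r2 undefined: zero variance in predictions or truths",
                           call = sys.call(-1L), mae = mae, mad = mad))
    stop(cond)
  }
  structure(list(mae = mae, mad = mad,
                 r2 = stats::cor(predictions, truths)^2,
                 n = length(predictions)),
            class = "prediction_metrics")
}

#' @export
print.prediction_metrics <- function(x, ...) {
  cat(sprintf("n = %d | R^2 = %.3f | MAE = %.2f weeks (median) | MAD = %.2f weeks (mean)\n",
              x$n, x$r2, x$mae, x$mad))
  invisible(x)
}
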