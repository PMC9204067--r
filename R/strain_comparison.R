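# Two-sample rank-sum (Mann-Whitney) test used by differential
# methylation and the sex-effect test. Routing:
#   * no ties and both groups <= 50: exact Wilcoxon distribution via
#     stats::wilcox.test(exact = TRUE);
#   * ties with a small assignment space (choose(n, n1) <= max_enum):
#     exact permutation enumeration over all group assignments of the
#     midranks, two-sided by symmetric deviation from the null mean;
#   * otherwise: normal approximation with continuity and tie correction
#     (stats::wilcox.test defaults).
# The statistic reported is the Mann-Whitney U (R's W).
.rank_sum_test <- function(a, b, max_enum = 20000L) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 < 1L || n2 < 1L) stop("empty group in rank-sum test")
  pooled <- c(a, b)
  has_ties <- anyDuplicated(pooled) > 0L
  rk <- rank(pooled)
  W <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (!has_ties && max(n1, n2) < 50L) {
    p <- stats::wilcox.test(a, b, exact = TRUE)$p.value
    method <- "exact"
  } else if (has_ties && choose(n1 + n2, n1) <= max_enum) {
    combs <- utils::combn(n1 + n2, n1)
    Wall <- colSums(matrix(rk[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    p <- mean(abs(Wall - mu) >= abs(W - mu) - 1e-9)
    method <- "exact-enumeration"
  } else {
    p <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
    method <- "normal-approximation"
  }
  list(statistic = W, p.value = p, method = method)
}

#' Pairwise sample correlation matrix
#'
#' Pearson correlation of methylation profiles for every pair of samples
#' over their shared non-missing probes. Strains cluster sharply in this
#' matrix; it is conventionally computed on *all* probes, X and Y
#' chromosomes included (unlike the clock analyses).
#'
#' @param mat Probes x samples beta matrix.
#' @param min_shared Minimum shared non-missing probes per pair; default 3.
#' @return Object of class `sample_cor`: list with `sample_ids` and the
#'   symmetric correlation matrix `r` (unit diagonal).
#' @export
sample_correlation_matrix <- function(mat, min_shared = 3L) {
  validate_beta_matrix(mat)
  if (ncol(mat) < 2L) stop("need >= 2 samples")
  shared <- crossprod(!is.na(mat))
  off <- shared; diag(off) <- min_shared
  if (any(off < min_shared)) {
    bad <- which(off < min_shared, arr.ind = TRUE)[1L, ]
    stop(sprintf("samples '%s' and '%s' share fewer than %d non-missing probes",
                 colnames(mat)[bad[1L]], colnames(mat)[bad[2L]], min_shared))
  }
  r <- stats::cor(mat, use = "pairwise.complete.obs")
  diag(r) <- 1
  structure(list(sample_ids = colnames(mat), r = r), class = "sample_cor")
}

#' @export
print.sample_cor <- function(x, ...) {
  cat(sprintf("sample correlation matrix: %d samples, off-diagonal r in [%.3f, %.3f]\n",
              length(x$sample_ids),
              min(x$r[upper.tri(x$r)]), max(x$r[upper.tri(x$r)])))
  invisible(x)
}

#' Per-CpG differential methylation between two groups
#'
#' Two-sided Wilcoxon rank-sum test per probe between exactly two groups
#' (e.g. strains), with Bonferroni control of the family-wise error.
#' Probes should be pre-filtered to exclude X/Y, SNP-overlapping and
#' cross-reactive probes before calling. See the package vignette for
#' the exact/approximate routing of the rank-sum p-value.
#'
#' @param mat Probes x samples beta matrix (pre-filtered).
#' @param sheet Sample sheet covering the columns of `mat`.
#' @param group_by Sheet column defining the two groups; default `"strain"`.
#' @param alpha Significance level on the adjusted p-value; default 0.01.
#' @param bonferroni_m Bonferroni divisor; default (`NULL`) the number of
#'   probes actually tested. Pass a fixed integer to correct for a full
#'   array instead.
#' @param min_group Minimum samples per group; default 4.
#' @return `data.frame` with `probe_id`, `stat` (Mann-Whitney U), `p_raw`,
#'   `p_adj` (= `min(1, p_raw * m)`), `significant` (`p_adj < alpha`);
#'   attributes `n_tested`, `m`, `groups`.
#' @export
differential_methylation <- function(mat, sheet, group_by = "strain",
                                     alpha = 0.01, bonferroni_m = NULL,
                                     min_group = 4L) {
  validate_beta_matrix(mat)
  .require_columns(sheet, c("sample_id", group_by), "sample sheet")
  idx <- match(colnames(mat), sheet$sample_id)
  if (anyNA(idx)) stop("sample sheet missing sample(s): ",
                       paste(utils::head(colnames(mat)[is.na(idx)], 3L), collapse = ", "))
  g <- as.character(sheet[[group_by]][idx])
  lev <- sort(unique(g))
  if (length(lev) != 2L) stop("group_by must define exactly 2 groups, got ", length(lev))
  if (any(table(g) < min_group))
    stop("underpowered design: each group needs >= ", min_group, " samples")
  ia <- g == lev[1L]; ib <- g == lev[2L]

  res <- apply(mat, 1L, function(y) {
    t <- .rank_sum_test(y[ia], y[ib])
    c(t$statistic, t$p.value)
  })
  m <- if (is.null(bonferroni_m)) nrow(mat) else as.integer(bonferroni_m)
  p_raw <- res[2L, ]
  out <- data.frame(probe_id = rownames(mat), stat = res[1L, ],
                    p_raw = p_raw, p_adj = pmin(1, p_raw * m),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$significant <- out$p_adj < alpha
  attr(out, "n_tested") <- nrow(mat)
  attr(out, "m") <- m
  attr(out, "groups") <- lev
  out
}

#' Sex effect on prediction errors
#'
#' Two-sided Mann-Whitney U test of delta age (predicted minus
#' chronological) between male and female samples, to check whether the
#' clock systematically mis-ages one sex.
#'
#' @param delta_ages Numeric vector of prediction errors in weeks.
#' @param sexes Character vector (`"M"`/`"F"`) aligned with `delta_ages`.
#' @param min_group Minimum samples per sex; default 3.
#' @return The two-sided p-value.
#' @export
sex_effect_test <- function(delta_ages, sexes, min_group = 3L) {
  if (length(delta_ages) != length(sexes)) stop("length mismatch")
  lev <- unique(sexes[!is.na(sexes)])
  if (length(lev) < 2L) stop("single-sex cohort: both sexes required")
  if (any(table(sexes) < min_group))
    stop("need >= ", min_group, " samples per sex")
  .rank_sum_test(delta_ages[sexes == lev[1L]], delta_ages[sexes == lev[2L]])$p.value
}

#' Global methylation trend with age
#'
#' Per sample, the fraction of probes called methylated (beta above
#' `call_threshold`), and the Pearson correlation of that fraction with
#' chronological age — a negative correlation reflects a genome-wide
#' loss of methylated CpGs with age.
#'
#' @param mat QC-filtered beta matrix.
#' @param sheet Sample sheet covering the columns of `mat`.
#' @param call_threshold Beta cutoff for calling a CpG methylated;
#'   default 0.5.
#' @return List with `fractions` (`data.frame`: `sample_id`, `fraction`,
#'   `age_weeks`) and `pearson_r`.
#' @export
global_methylation_trend <- function(mat, sheet, call_threshold = 0.5) {
  validate_beta_matrix(mat)
  idx <- match(colnames(mat), sheet$sample_id)
  if (anyNA(idx)) stop("sample sheet missing sample(s)")
  frac <- colMeans(mat > call_threshold, na.rm = TRUE)
  age <- sheet$age_weeks[idx]
  r <- pearson_age_r(age, frac)
  list(fractions = data.frame(sample_id = colnames(mat), fraction = unname(frac),
                              age_weeks = age, stringsAsFactors = FALSE),
       pearson_r = r)
}
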