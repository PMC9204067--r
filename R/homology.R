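#' Assign human array CpGs to mouse homology regions
#'
#' For every human CpG on a chromosome that carries at least one homology
#' region, the CpG is categorized as `"homolog"` when its position lies
#' inside a region's interval (1-based inclusive at both ends, distance
#' 0), otherwise as `"distance"` with the distance in bp to the center of
#' the closest region (`center = floor((start + end) / 2)`). Ties between
#' equidistant regions are broken by the lower start coordinate. Regions
#' on chromosomes absent from the annotation are skipped with a warning.
#'
#' @param regions Homology-region `data.frame` (see [read_homology_table()]).
#' @param human_annotation `data.frame` with at least `probe_id`, `chrom`,
#'   `pos` for the human array CpGs.
#' @return `data.frame` with `human_cpg_id`, `mouse_probe_id`, `category`
#'   (`homolog`/`distance`) and `distance_bp`.
#' @export
assign_human_cpgs <- function(regions, human_annotation) {
  if (nrow(regions) == 0L) stop("regions must be non-empty")
  .require_columns(human_annotation, c("probe_id", "chrom", "pos"), "human annotation")
  rchrom <- .strip_chr(regions$human_chrom)
  achrom <- .strip_chr(human_annotation$chrom)
  absent <- setdiff(unique(rchrom), unique(achrom))
  if (length(absent))
    warning("skipping region(s) on chromosome(s) absent from the annotation: ",
            paste(absent, collapse = ", "))
  center <- floor((regions$human_start + regions$human_end) / 2)

  out <- vector("list", length(unique(rchrom)))
  k <- 0L
  for (cc in setdiff(unique(rchrom), absent)) {
    ri <- which(rchrom == cc)
    ci <- which(achrom == cc)
    if (length(ci) == 0L) next
    pos <- human_annotation$pos[ci]
    # choose the candidate region by nearest center (lower start on ties);
    # containment wins over distance
    pick <- vapply(pos, function(p) {
      inside <- ri[regions$human_start[ri] <= p & p <= regions$human_end[ri]]
      cand <- if (length(inside)) inside else ri
      d <- abs(p - center[cand])
      best <- cand[d == min(d)]
      best <- best[order(regions$human_start[best])][1L]
      c(best, if (length(inside)) 0 else abs(p - center[best]), length(inside) > 0L)
    }, numeric(3))
    k <- k + 1L
    out[[k]] <- data.frame(
      human_cpg_id = human_annotation$probe_id[ci],
      mouse_probe_id = regions$mouse_probe_id[pick[1L, ]],
      category = ifelse(pick[3L, ] > 0, "homolog", "distance"),
      distance_bp = as.integer(pick[2L, ]),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[seq_len(k)])
  if (is.null(res))
    res <- data.frame(human_cpg_id = character(0), mouse_probe_id = character(0),
                      category = character(0), distance_bp = integer(0),
                      stringsAsFactors = FALSE)
  row.names(res) <- NULL
  res
}

#' Age association of human CpGs
#'
#' Pearson correlation of beta value with chronological age per CpG, with
#' the p-value from the t statistic for a linear correlation,
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom
#' (two-sided), Bonferroni-corrected. CpGs with zero beta variance are
#' skipped with a warning.
#'
#' @param human_betas Probes x samples beta matrix.
#' @param ages_years Chronological ages, one per sample (named or
#'   column-ordered).
#' @param m Bonferroni divisor; default (`NULL`) the number of CpGs
#'   analyzed. Pass the full array size to correct for the whole chip.
#' @param alpha Significance level on the adjusted p-value; default 0.01.
#' @return `data.frame` with `human_cpg_id`, `pearson_r`, `n`, `p_raw`,
#'   `p_adj`, `significant`.
#' @export
human_age_association <- function(human_betas, ages_years, m = NULL, alpha = 0.01) {
  validate_beta_matrix(human_betas)
  if (!is.null(names(ages_years))) ages_years <- ages_years[colnames(human_betas)]
  if (length(ages_years) != ncol(human_betas)) stop("ages_years must match samples")
  if (ncol(human_betas) < 10L) stop("need >= 10 samples")
  tab <- slope_table(human_betas, ages_years)
  skip <- is.na(tab$pearson_r)
  if (any(skip))
    warning(sum(skip), " CpG(s) skipped (zero beta variance)")
  tab <- tab[!skip, , drop = FALSE]
  if (is.null(m)) m <- nrow(tab)
  r <- tab$pearson_r
  n <- tab$n
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p_raw <- 2 * stats::pt(-abs(tstat), df = n - 2)
  out <- data.frame(human_cpg_id = tab$probe_id, pearson_r = r, n = n,
                    p_raw = p_raw, p_adj = pmin(1, p_raw * m),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$significant <- out$p_adj < alpha
  attr(out, "m") <- m
  out
}

#' Cross-species conserved candidate report
#'
#' Joins homolog-category human CpG assignments with the per-strain mouse
#' age correlations and the human age association, keeps human CpGs with
#' a significant age correlation, and flags whether the direction of
#' age-associated methylation change (hyper/hypo) is consistent across
#' both mouse strains and human.
#'
#' @param assignments Output of [assign_human_cpgs()].
#' @param mouse_a,mouse_b Per-strain slope tables (see [slope_table()])
#'   for the two mouse strains, keyed by `probe_id`.
#' @param human_results Output of [human_age_association()].
#' @return `data.frame` shaped like the study's conserved-CpG table:
#'   `mouse_probe_id`, `r_a`, `r_b`, `human_cpg_id`, `r_human`,
#'   `p_adj_human`, `sign_consistent`.
#' @export
conserved_candidates <- function(assignments, mouse_a, mouse_b, human_results) {
  hom <- assignments[assignments$category == "homolog", , drop = FALSE]
  sig <- human_results[human_results$significant, , drop = FALSE]
  j <- merge(hom, sig, by = "human_cpg_id")
  if (nrow(j) == 0L)
    return(data.frame(mouse_probe_id = character(0), r_a = numeric(0),
                      r_b = numeric(0), human_cpg_id = character(0),
                      r_human = numeric(0), p_adj_human = numeric(0),
                      sign_consistent = logical(0), stringsAsFactors = FALSE))
  ra <- mouse_a$pearson_r[match(j$mouse_probe_id, mouse_a$probe_id)]
  rb <- mouse_b$pearson_r[match(j$mouse_probe_id, mouse_b$probe_id)]
  out <- data.frame(mouse_probe_id = j$mouse_probe_id,
                    r_a = ra, r_b = rb,
                    human_cpg_id = j$human_cpg_id,
                    r_human = j$pearson_r,
                    p_adj_human = j$p_adj,
                    stringsAsFactors = FALSE)
  out$sign_consistent <- !is.na(ra) & !is.na(rb) &
    sign(ra) == sign(rb) & sign(rb) == sign(out$r_human)
  out <- out[order(out$mouse_probe_id, out$human_cpg_id), , drop = FALSE]
  row.names(out) <- NULL
  out
}
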