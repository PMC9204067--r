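#' Specification of a synthetic two-strain mouse cohort
#'
#' Defines the statistical structure of a simulated methylation cohort:
#' sample sizes per (strain, sex), age ranges, probe-class counts, effect
#' sizes and noise. Defaults copy the study design this package models:
#' 12 female B6 mice 11-117 weeks old and 6 male + 6 female DBA mice
#' 6-109 weeks old, with 20,000 probes of which 100 carry shared aging
#' trends of 0.5 beta over the lifespan at a measurement noise of 0.02.
#'
#' @param n_samples Named integer vector of samples per `strain_sex` group.
#' @param age_range_weeks Named list of per-strain age ranges in weeks.
#' @param n_probes Total probes on the synthetic array.
#' @param n_aging_shared Probes with the same-direction aging trend in
#'   both strains (the cross-strain conserved class).
#' @param n_aging_strain_private Named vector: probes with an aging trend
#'   in only one strain.
#' @param n_antagonistic Probes with opposite-direction trends per strain.
#' @param n_strain_offset Probes with a constant between-strain offset
#'   (the differential-methylation class).
#' @param effect_size Absolute beta change of aging probes over the
#'   strain's observed age range.
#' @param offset_size Between-strain beta shift of offset probes.
#' @param noise_sd Gaussian measurement noise sd on the beta scale
#'   (values are clipped to \[0, 1\] after noise).
#' @param context_mix Proportions of island/shore/shelf/open_sea probes.
#' @param island_direction_bias Named per-strain probability that a
#'   strain-private aging probe in a CpG island hypermethylates: B6
#'   islands tend to gain methylation with age, DBA islands to lose it.
#' @param n_xy Named counts of null probes planted on the X and Y
#'   chromosomes.
#' @param seed Integer seed making the cohort fully reproducible.
#' @return A validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = c(B6_F = 12L, DBA_M = 6L, DBA_F = 6L),
                        age_range_weeks = list(B6 = c(11, 117), DBA = c(6, 109)),
                        n_probes = 20000L,
                        n_aging_shared = 100L,
                        n_aging_strain_private = c(B6 = 50L, DBA = 30L),
                        n_antagonistic = 20L,
                        n_strain_offset = 500L,
                        effect_size = 0.5,
                        offset_size = 0.4,
                        noise_sd = 0.02,
                        context_mix = c(island = 0.30, shore = 0.25,
                                        shelf = 0.15, open_sea = 0.30),
                        island_direction_bias = c(B6 = 0.8, DBA = 0.2),
                        n_xy = c(X = 200L, Y = 50L),
                        seed = 1L) {
  spec <- list(n_samples = n_samples, age_range_weeks = age_range_weeks,
               n_probes = as.integer(n_probes),
               n_aging_shared = as.integer(n_aging_shared),
               n_aging_strain_private = n_aging_strain_private,
               n_antagonistic = as.integer(n_antagonistic),
               n_strain_offset = as.integer(n_strain_offset),
               effect_size = effect_size, offset_size = offset_size,
               noise_sd = noise_sd, context_mix = context_mix,
               island_direction_bias = island_direction_bias,
               n_xy = n_xy, seed = as.integer(seed))
  n_special <- spec$n_aging_shared + sum(spec$n_aging_strain_private) +
    spec$n_antagonistic + spec$n_strain_offset + sum(spec$n_xy)
  if (n_special > spec$n_probes)
    stop("infeasible spec: probe classes (", n_special,
         ") exceed n_probes (", spec$n_probes, ")")
  if (abs(sum(spec$context_mix) - 1) > 1e-8) stop("context_mix must sum to 1")
  if (spec$noise_sd < 0) stop("noise_sd must be >= 0")
  if (spec$effect_size < 0 || spec$effect_size > 0.9)
    stop("effect_size must be in [0, 0.9]")
  class(spec) <- "cohort_spec"
  spec
}

# Evenly spaced ages across the group's range emulate a designed cohort.
.group_ages <- function(n, range) {
  if (n == 1L) return(mean(range))
  seq(range[1L], range[2L], length.out = n)
}

#' Generate a synthetic mouse methylation cohort
#'
#' Simulates a two-strain beta matrix with planted probe classes: shared
#' aging probes (same-direction linear beta trend over each strain's age
#' span), strain-private aging probes, antagonistic probes (opposite
#' directions per strain), strain-offset probes (constant between-strain
#' shift), X/Y-planted null probes, and pure-noise null probes. Baselines
#' are drawn per island context (islands low, open sea high), trends are
#' linear in within-strain normalized age, truncated-Gaussian noise is
#' added on the beta scale and values are clipped to \[0, 1\]. The truth
#' table records every probe's class, per-strain direction and effect.
#'
#' @param spec A [cohort_spec()].
#' @return List with `betas` (probes x samples matrix), `sheet` (sample
#'   sheet `data.frame`), `annotation` (probe annotation `data.frame`)
#'   and `truth` (`data.frame`: `probe_id`, `class`, `direction_b6`,
#'   `direction_dba`, `effect`, `chrom`, `pos`, `context`).
#' @export
generate_mouse_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)

  groups <- names(spec$n_samples)
  sheet <- do.call(rbind, lapply(groups, function(g) {
    parts <- strsplit(g, "_", fixed = TRUE)[[1L]]
    strain <- parts[1L]; sex <- parts[2L]
    n <- spec$n_samples[[g]]
    ages <- .group_ages(n, spec$age_range_weeks[[strain]])
    data.frame(sample_id = sprintf("%s_%s_%02d_%03dwk", strain, sex, seq_len(n), round(ages)),
               strain = strain, sex = sex, age_weeks = ages,
               stringsAsFactors = FALSE)
  }))
  row.names(sheet) <- NULL
  n_samp <- nrow(sheet)

  # within-strain normalized age drives the planted trends
  xnorm <- stats::ave(sheet$age_weeks, sheet$strain, FUN = function(a)
    if (length(unique(a)) > 1L) (a - min(a)) / (max(a) - min(a)) else 0.5)
  is_b6 <- sheet$strain == "B6"

  np <- spec$n_probes
  probe_id <- sprintf("cg%07d", seq_len(np))
  classes <- rep("null", np)
  i <- 1L
  take <- function(n) { out <- seq.int(i, length.out = n); i <<- i + n; out }
  idx_shared <- take(spec$n_aging_shared)
  idx_priv <- lapply(spec$n_aging_strain_private, take)
  idx_antag <- take(spec$n_antagonistic)
  idx_offset <- take(spec$n_strain_offset)
  idx_xy <- lapply(spec$n_xy, take)
  classes[idx_shared] <- "aging_shared"
  for (s in names(idx_priv)) classes[idx_priv[[s]]] <- paste0("aging_private_", s)
  classes[idx_antag] <- "antagonistic"
  classes[idx_offset] <- "strain_offset"

  context <- sample(names(spec$context_mix), np, replace = TRUE, prob = spec$context_mix)
  chrom <- as.character(sample(1:19, np, replace = TRUE))
  chrom[idx_xy$X] <- "X"
  chrom[idx_xy$Y] <- "Y"
  pos <- sample.int(150000000L, np, replace = TRUE)
  annotation <- data.frame(probe_id = probe_id, chrom = chrom, pos = pos,
                           context = context, gene = NA_character_,
                           is_snp = FALSE, is_cross_reactive = FALSE,
                           stringsAsFactors = FALSE)

  # context-dependent baseline betas: islands low, open sea high
  base_params <- list(island = c(1.2, 8), shore = c(2, 4),
                      shelf = c(3, 3), open_sea = c(6, 2))
  base <- numeric(np)
  for (cc in names(base_params)) {
    j <- context == cc
    base[j] <- stats::rbeta(sum(j), base_params[[cc]][1L], base_params[[cc]][2L])
  }

  e <- spec$effect_size
  dir_b6 <- rep(0, np)
  dir_dba <- rep(0, np)
  # shared probes: hypomethylation predominates (direction -1 with p 0.65)
  d <- sample(c(1, -1), length(idx_shared), replace = TRUE, prob = c(0.35, 0.65))
  dir_b6[idx_shared] <- d; dir_dba[idx_shared] <- d
  # strain-private probes: island probes follow the strain's island bias
  for (s in names(idx_priv)) {
    j <- idx_priv[[s]]
    p_up <- ifelse(context[j] == "island", spec$island_direction_bias[[s]], 0.35)
    d <- ifelse(stats::runif(length(j)) < p_up, 1, -1)
    if (s == "B6") dir_b6[j] <- d else dir_dba[j] <- d
  }
  d <- sample(c(1, -1), length(idx_antag), replace = TRUE)
  dir_b6[idx_antag] <- d; dir_dba[idx_antag] <- -d
  offset_sign <- sample(c(1, -1), length(idx_offset), replace = TRUE)

  # keep aging trajectories inside [0.05, 0.95]; antagonistic probes get
  # per-strain baselines since their two trajectories cannot share one
  aging <- dir_b6 != 0 | dir_dba != 0
  lo_b6 <- ifelse(dir_b6 < 0, 0.05 + e, 0.05)
  hi_b6 <- ifelse(dir_b6 > 0, 0.95 - e, 0.95)
  lo_dba <- ifelse(dir_dba < 0, 0.05 + e, 0.05)
  hi_dba <- ifelse(dir_dba > 0, 0.95 - e, 0.95)
  lo <- pmax(lo_b6, lo_dba); hi <- pmin(hi_b6, hi_dba)
  shareable <- aging & lo < hi
  base[shareable] <- stats::runif(sum(shareable), lo[shareable], hi[shareable])
  base_dba <- base
  split_base <- aging & !shareable
  base[split_base] <- stats::runif(sum(split_base), lo_b6[split_base], hi_b6[split_base])
  base_dba[split_base] <- stats::runif(sum(split_base),
                                       lo_dba[split_base], hi_dba[split_base])
  base[idx_offset] <- stats::runif(length(idx_offset),
                                   0.05 + spec$offset_size, 0.95 - spec$offset_size)
  base_dba[idx_offset] <- base[idx_offset]

  mu <- matrix(0, nrow = np, ncol = n_samp)
  mu[, is_b6] <- base
  mu[, !is_b6] <- base_dba
  trend <- outer(dir_b6, ifelse(is_b6, 1, 0) * xnorm) +
    outer(dir_dba, ifelse(is_b6, 0, 1) * xnorm)
  mu <- mu + e * trend
  mu[idx_offset, !is_b6] <- mu[idx_offset, !is_b6] +
    spec$offset_size * offset_sign

  betas <- mu
  if (spec$noise_sd > 0)
    betas <- betas + matrix(stats::rnorm(np * n_samp, sd = spec$noise_sd), nrow = np)
  betas <- pmin(pmax(betas, 0), 1)
  dimnames(betas) <- list(probe_id, sheet$sample_id)

  eff <- rep(0, np)
  eff[aging] <- e
  eff[idx_offset] <- spec$offset_size * offset_sign
  truth <- data.frame(probe_id = probe_id, class = classes,
                      direction_b6 = dir_b6, direction_dba = dir_dba,
                      effect = eff, chrom = chrom, pos = pos, context = context,
                      stringsAsFactors = FALSE)

  list(betas = betas, sheet = sheet, annotation = annotation, truth = truth)
}

#' Generate a synthetic human validation cohort
#'
#' Emulates a large human blood methylation cohort (by default 656
#' samples aged 19-101 years, the shape of the reference human dataset).
#' Every shared aging probe of the linked mouse truth table gets a human
#' counterpart CpG; a `conservation_fraction` of them receive a
#' sign-matched linear age trend, the rest (plus `n_null_extra` unlinked
#' CpGs) are age-independent noise.
#'
#' @param linked_truth Mouse truth table from [generate_mouse_cohort()].
#' @param n_samples Number of human samples; default 656.
#' @param age_range_years Human age range; default 19-101.
#' @param conservation_fraction Fraction of shared mouse aging probes
#'   whose human homolog is also age-associated, in \[0, 1\].
#' @param effect_size Beta change of conserved human CpGs over the age
#'   range; default 0.3 (human blood effects are smaller than the
#'   within-strain mouse trends).
#' @param noise_sd Beta-scale noise sd; default 0.05.
#' @param n_null_extra Additional unlinked null human CpGs; default 500.
#' @param seed Integer seed.
#' @return List with `betas` (CpGs x samples), `ages_years` (named),
#'   `annotation` (human probe annotation) and `links` (`data.frame`:
#'   `mouse_probe_id`, `human_cpg_id`, `human_chrom`, `human_pos`,
#'   `conserved`, `direction`).
#' @export
generate_human_cohort <- function(linked_truth, n_samples = 656L,
                                  age_range_years = c(19, 101),
                                  conservation_fraction = 0.7,
                                  effect_size = 0.3, noise_sd = 0.05,
                                  n_null_extra = 500L, seed = 1L) {
  if (conservation_fraction < 0 || conservation_fraction > 1)
    stop("conservation_fraction must be in [0, 1]")
  set.seed(seed)
  shared <- linked_truth[linked_truth$class == "aging_shared", , drop = FALSE]
  n_link <- nrow(shared)
  conserved <- stats::runif(n_link) < conservation_fraction

  ages <- sort(stats::runif(n_samples, age_range_years[1L], age_range_years[2L]))
  sample_ids <- sprintf("HU_%04d", seq_len(n_samples))
  names(ages) <- sample_ids
  xnorm <- (ages - min(ages)) / (max(ages) - min(ages))

  human_ids <- c(if (n_link) sprintf("hcg%07d", seq_len(n_link)),
                 if (n_null_extra) sprintf("hnull%06d", seq_len(n_null_extra)))
  n_cpg <- length(human_ids)
  chrom <- as.character(sample(1:22, n_cpg, replace = TRUE))
  pos <- sample.int(200000000L, n_cpg, replace = TRUE)

  dirn <- rep(0, n_cpg)
  if (n_link) dirn[seq_len(n_link)] <- ifelse(conserved, shared$direction_b6, 0)
  lo <- ifelse(dirn < 0, 0.05 + effect_size, 0.05)
  hi <- ifelse(dirn > 0, 0.95 - effect_size, 0.95)
  base <- stats::runif(n_cpg, lo, hi)
  betas <- matrix(base, nrow = n_cpg, ncol = n_samples) +
    effect_size * outer(dirn, xnorm)
  if (noise_sd > 0)
    betas <- betas + matrix(stats::rnorm(n_cpg * n_samples, sd = noise_sd), nrow = n_cpg)
  betas <- pmin(pmax(betas, 0), 1)
  dimnames(betas) <- list(human_ids, sample_ids)

  annotation <- data.frame(probe_id = human_ids, chrom = chrom, pos = pos,
                           context = sample(.context_levels, n_cpg, replace = TRUE),
                           gene = NA_character_, is_snp = FALSE,
                           is_cross_reactive = FALSE, stringsAsFactors = FALSE)
  links <- if (n_link) {
    data.frame(mouse_probe_id = shared$probe_id,
               human_cpg_id = human_ids[seq_len(n_link)],
               mouse_chrom = shared$chrom, mouse_pos = shared$pos,
               human_chrom = chrom[seq_len(n_link)],
               human_pos = pos[seq_len(n_link)],
               conserved = conserved,
               direction = dirn[seq_len(n_link)],
               stringsAsFactors = FALSE)
  } else {
    data.frame(mouse_probe_id = character(0), human_cpg_id = character(0),
               mouse_chrom = character(0), mouse_pos = integer(0),
               human_chrom = character(0), human_pos = integer(0),
               conserved = logical(0), direction = numeric(0),
               stringsAsFactors = FALSE)
  }
  list(betas = betas, ages_years = ages, annotation = annotation, links = links)
}

#' Generate a synthetic homology-region table
#'
#' Builds alignment-window regions pairing mouse probes with human
#' intervals. Each linked mouse probe gets a `window_nt`-wide region on
#' its human CpG's chromosome; with probability `attrition` the region is
#' displaced so that it contains no array CpG, emulating homolog regions
#' whose human counterpart is not represented on the array.
#'
#' @param links Link table from [generate_human_cohort()].
#' @param window_nt Region width in nucleotides; default 121.
#' @param attrition Fraction of regions displaced off their human CpG.
#' @param seed Integer seed.
#' @return Homology-region `data.frame` (columns of
#'   [read_homology_table()]); attribute `"contains_cpg"` records which
#'   regions kept their CpG.
#' @export
generate_homology_table <- function(links, window_nt = 121L, attrition = 0,
                                    seed = 1L) {
  set.seed(seed)
  n <- nrow(links)
  if (n == 0L)
    return(data.frame(mouse_probe_id = character(0), mouse_chrom = character(0),
                      mouse_pos = integer(0), human_chrom = character(0),
                      human_start = integer(0), human_end = integer(0),
                      strand_flip = logical(0), stringsAsFactors = FALSE))
  drop <- stats::runif(n) < attrition
  offset <- sample.int(window_nt, n, replace = TRUE) - 1L
  start <- links$human_pos - offset
  # displaced regions start well past the CpG so it falls outside
  start[drop] <- links$human_pos[drop] + 10000L
  start <- pmax(1L, start)
  out <- data.frame(mouse_probe_id = links$mouse_probe_id,
                    mouse_chrom = links$mouse_chrom,
                    mouse_pos = links$mouse_pos,
                    human_chrom = links$human_chrom,
                    human_start = as.integer(start),
                    human_end = as.integer(start + window_nt - 1L),
                    strand_flip = sample(c(TRUE, FALSE), n, replace = TRUE),
                    stringsAsFactors = FALSE)
  attr(out, "contains_cpg") <- !drop
  out
}
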