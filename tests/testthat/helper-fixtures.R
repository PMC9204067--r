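# Shared fixtures, generated in code and cached per session.

.fixtures <- new.env(parent = emptyenv())

# A reduced two-strain cohort for fast module tests.
small_spec <- function(seed = 42L, ...) {
  cohort_spec(n_probes = 2000L, n_aging_shared = 40L,
              n_aging_strain_private = c(B6 = 20L, DBA = 10L),
              n_antagonistic = 10L, n_strain_offset = 100L,
              n_xy = c(X = 20L, Y = 5L), seed = seed, ...)
}

small_cohort <- function() {
  if (is.null(.fixtures$small)) .fixtures$small <- generate_mouse_cohort(small_spec())
  .fixtures$small
}

# The full default cohort (the study's design at array scale); cached so
# the acceptance blocks that need it generate it once.
default_cohort <- function() {
  if (is.null(.fixtures$default)) .fixtures$default <- generate_mouse_cohort(cohort_spec())
  .fixtures$default
}

# Per-strain candidate selection on a QC'd matrix.
strain_candidates <- function(mat, sheet, strain, threshold = 0.3) {
  norm <- normalize_ages(sheet)
  s <- norm[norm$strain == strain, , drop = FALSE]
  select_candidates(mat[, s$sample_id, drop = FALSE],
                    stats::setNames(s$age_norm, s$sample_id),
                    threshold = threshold, strain = strain)
}

# Write a small beta matrix fixture file from text lines.
write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Independent Mann-Whitney U enumeration oracle: counts pairs a_i > b_j
# (ties half) for every assignment of the pooled values into two groups.
u_enumeration_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a); n <- length(pooled)
  u_of <- function(g1, g2) sum(outer(g1, g2, ">")) + 0.5 * sum(outer(g1, g2, "=="))
  u_obs <- u_of(a, b)
  mu <- n1 * (n - n1) / 2
  combs <- utils::combn(n, n1)
  us <- apply(combs, 2L, function(i) u_of(pooled[i], pooled[-i]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}
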