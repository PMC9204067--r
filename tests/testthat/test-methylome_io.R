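test_that("beta matrix parsing handles missing tokens, order and both dialects", {
  path <- write_lines_tmp(c("probe_id\tS1\tS2",
                            "p1\t0.10\t0.90",
                            "p2\tNA\t0.50",
                            "p3\t0.30\t0.25"))
  mat <- read_beta_matrix(path)
  expect_identical(dim(mat), c(3L, 2L))
  expect_identical(rownames(mat), c("p1", "p2", "p3"))
  expect_identical(sum(is.na(mat)), 1L)
  expect_true(is.na(mat["p2", "S1"]))
  expect_equal(mat["p3", "S2"], 0.25)

  # empty cells and case-insensitive NaN are missing too
  path2 <- write_lines_tmp(c("id\ta\tb", "p1\t\t0.2", "p2\tnan\t0.3"))
  expect_identical(sum(is.na(read_beta_matrix(path2))), 2L)

  # transposed dialect comes back probes x samples
  path3 <- write_lines_tmp(c("sample_id\tp1\tp2", "S1\t0.1\t0.2", "S2\t0.3\t0.4"))
  tm <- read_beta_matrix(path3, dialect = "samples_in_rows")
  expect_identical(rownames(tm), c("p1", "p2"))
  expect_equal(tm["p2", "S1"], 0.2)
})

test_that("malformed cells, out-of-range values and duplicate ids are rejected", {
  bad_num <- write_lines_tmp(c("id\tS1", "p1\tx0.5"))
  expect_error(read_beta_matrix(bad_num), "cannot parse.*p1.*S1")
  out_of_range <- write_lines_tmp(c("id\tS1", "p1\t1.2"))
  expect_error(read_beta_matrix(out_of_range), "out of \\[0, 1\\]")
  dup <- write_lines_tmp(c("id\tS1", "p1\t0.5", "p1\t0.6"))
  expect_error(read_beta_matrix(dup), "duplicate probe")
})

test_that("beta matrices round-trip through write/read to 6 decimals", {
  set.seed(11)
  mat <- matrix(runif(60), nrow = 12,
                dimnames = list(sprintf("p%02d", 1:12), sprintf("S%d", 1:5)))
  mat[c(3, 25)] <- NA
  path <- tempfile(fileext = ".tsv")
  write_beta_matrix(mat, path)
  back <- read_beta_matrix(path)
  expect_equal(back, mat, tolerance = 1e-6)
  expect_identical(is.na(back), is.na(mat))
})

test_that("sample sheets parse typed records and reject missing columns", {
  path <- write_lines_tmp(c("sample_id,strain,sex,age_weeks,batch",
                            "m1,B6,F,11,A", "m2,DBA,M,6,A"), ext = ".csv")
  sheet <- read_sample_sheet(path)
  expect_identical(sheet$strain, c("B6", "DBA"))
  expect_identical(sheet$sex, c("F", "M"))
  expect_equal(sheet$age_weeks, c(11, 6))
  expect_true("batch" %in% colnames(sheet))   # extra columns preserved

  noage <- write_lines_tmp(c("sample_id,strain,sex", "m1,B6,F"), ext = ".csv")
  expect_error(read_sample_sheet(noage), "missing required column.*age_weeks")

  # the study design: 12 B6 females plus 6 male and 6 female DBA
  rows <- c(sprintf("b%d,B6,F,%g", 1:12, seq(11, 117, length.out = 12)),
            sprintf("dm%d,DBA,M,%g", 1:6, seq(6, 106, length.out = 6)),
            sprintf("df%d,DBA,F,%g", 1:6, seq(8, 108, length.out = 6)))
  design <- write_lines_tmp(c("sample_id,strain,sex,age_weeks", rows), ext = ".csv")
  parsed <- read_sample_sheet(design)
  expect_identical(nrow(parsed), 24L)
  expect_identical(unname(table(parsed$strain, parsed$sex)["DBA", ]), c(6L, 6L))
})

test_that("probe annotation validates contexts and coordinates", {
  path <- write_lines_tmp(c("probe_id,chrom,pos,context,gene,is_snp,is_cross_reactive",
                            "p1,11,73324349,island,Aspa,FALSE,FALSE",
                            "p2,X,100,open_sea,,TRUE,FALSE"), ext = ".csv")
  ann <- read_probe_annotation(path)
  expect_identical(ann$pos[1], 73324349L)
  expect_true(ann$is_snp[2])
  bad <- write_lines_tmp(c("probe_id,chrom,pos,context,gene,is_snp,is_cross_reactive",
                           "p1,1,5,lagoon,,FALSE,FALSE"), ext = ".csv")
  expect_error(read_probe_annotation(bad), "unknown context")
})

test_that("qc_filter applies probe, sample, and X/Y filters in order", {
  set.seed(3)
  mat <- matrix(runif(100), nrow = 10,
                dimnames = list(sprintf("p%02d", 1:10), sprintf("S%d", 1:10)))
  mat["p01", 1:2] <- NA        # 20% missing -> dropped
  res <- suppressMessages(qc_filter(mat))
  expect_identical(res$report$probes_removed_missing, 1L)
  expect_false("p01" %in% rownames(res$betas))

  # detection p all zero removes nothing
  dp <- matrix(0, nrow = 10, ncol = 10, dimnames = dimnames(mat))
  res2 <- qc_filter(mat, detection_p = dp)
  expect_identical(res2$report$probes_removed_detection, 0L)
  dp["p05", 3] <- 0.5
  res3 <- qc_filter(mat, detection_p = dp)
  expect_identical(res3$report$probes_removed_detection, 1L)

  # planted X probes are counted and removed only when drop_xy
  co <- small_cohort()
  resx <- suppressMessages(qc_filter(co$betas, co$annotation, drop_xy = TRUE))
  expect_identical(resx$report$probes_removed_xy, 25L)  # 20 X + 5 Y planted
  expect_length(intersect(rownames(resx$betas),
                          co$truth$probe_id[co$truth$chrom %in% c("X", "Y")]), 0L)

  # skipping detection p-values is announced
  expect_message(qc_filter(mat), "detection filter skipped")
})

test_that("qc_filter is idempotent, value-preserving, and sample filter can be disabled", {
  co <- small_cohort()
  mat <- co$betas
  mat[1:30, 1] <- NA
  mat[5, ] <- NA   # fully missing probe
  once <- suppressMessages(qc_filter(mat, co$annotation, drop_xy = TRUE))
  twice <- suppressMessages(qc_filter(once$betas, co$annotation, drop_xy = TRUE))
  expect_identical(once$betas, twice$betas)
  # surviving cells unchanged, sets are subsets
  expect_true(all(rownames(once$betas) %in% rownames(mat)))
  expect_true(all(colnames(once$betas) %in% colnames(mat)))
  expect_identical(once$betas, mat[rownames(once$betas), colnames(once$betas)])

  # a sample-missingness ceiling of 1.0 never removes samples
  holey <- mat
  holey[1:1500, 2] <- NA
  keep_all <- suppressMessages(qc_filter(holey, max_sample_missing = 1.0))
  expect_length(keep_all$report$samples_removed, 0L)
  dropped <- suppressMessages(qc_filter(holey))
  expect_identical(dropped$report$samples_removed, colnames(mat)[2])
})

test_that("homology tables read with coordinate validation and QC reports serialize", {
  path <- write_lines_tmp(c(
    "mouse_probe_id\tmouse_chrom\tmouse_pos\thuman_chrom\thuman_start\thuman_end\tstrand_flip",
    "cg29748675\t11\t73324349\t17\t3379534\t3379655\tFALSE"))
  ht <- read_homology_table(path)
  expect_identical(ht$human_end - ht$human_start + 1L, 122L)
  bad <- write_lines_tmp(c(
    "mouse_probe_id\tmouse_chrom\tmouse_pos\thuman_chrom\thuman_start\thuman_end\tstrand_flip",
    "p1\t1\t10\t2\t500\t400\tFALSE"))
  expect_error(read_homology_table(bad), "human_start <= human_end")

  res <- suppressMessages(qc_filter(small_cohort()$betas))
  json <- tempfile(fileext = ".json")
  write_qc_report(res$report, json)
  parsed <- jsonlite::read_json(json, simplifyVector = TRUE)
  expect_identical(parsed$probes_removed_missing, res$report$probes_removed_missing)
})
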