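make_norm_sheet <- function(ages, strain = "B6", sex = "F") {
  data.frame(sample_id = paste0("s", seq_along(ages)), strain = strain,
             sex = sex, age_weeks = ages,
               age_norm = (ages - min(ages)) / (max(ages) - min(ages)))
}

test_that("ensemble fitting recovers noiseless per-CpG lines and skips flat probes", {
  ages <- seq(10, 110, length.out = 10)
  sheet <- make_norm_sheet(ages)
  x <- sheet$age_norm
  mat <- rbind(ideal = x, flat = rep(0.4, 10), offset = 0.2 + 0.5 * x)
  colnames(mat) <- sheet$sample_id
  expect_warning(clock <- fit_ensemble(mat, sheet), "skipped")
  m <- clock$models
  expect_equal(m$slope[m$probe_id == "ideal"], 1, tolerance = 1e-12)
  expect_equal(m$intercept[m$probe_id == "ideal"], 0, tolerance = 1e-12)
  expect_identical(clock$skipped, "flat")
  expect_equal(m$slope[m$probe_id == "offset"], 2, tolerance = 1e-10)

  # inverse calibration stores the beta-on-age line and recovers planted
  # slopes within 10% under realistic noise
  set.seed(21)
  sheet24 <- make_norm_sheet(seq(10, 110, length.out = 24))
  x24 <- sheet24$age_norm
  planted <- runif(30, 0.3, 0.7) * sample(c(-1, 1), 30, replace = TRUE)
  noisy <- (0.5 - planted / 2) + outer(planted, x24) +
    matrix(rnorm(30 * 24, sd = 0.02), nrow = 30)
  noisy <- pmin(pmax(noisy, 0), 1)
  dimnames(noisy) <- list(sprintf("p%02d", 1:30), sheet24$sample_id)
  inv <- fit_ensemble(noisy, sheet24, calibration = "inverse")
  rel <- abs(inv$models$slope - planted) / abs(planted)
  expect_true(mean(rel < 0.10) >= 0.9)
})

test_that("ensemble prediction averages per-CpG estimates then denormalizes", {
  clock <- structure(list(
    models = data.frame(probe_id = c("a", "b"), slope = c(0, 0),
                        intercept = c(0.2, 0.8)),
    denormalizer = data.frame(strain = "B6", sex = "F", age_min = 10, age_max = 110),
    calibration = "direct", skipped = character(0)), class = "ensemble_clock")
  betas <- c(a = 0.5, b = 0.5)
  # estimates 0.2 and 0.8 -> mean 0.5 -> midpoint of the age range
  expect_equal(predict_ensemble(clock, betas, "B6", "F"), 60)

  # identical estimates land on the midpoint too
  clock$models$intercept <- c(0.5, 0.5)
  expect_equal(predict_ensemble(clock, betas, "B6", "F"), 60)

  # probe order and duplication leave the mean unchanged
  clock$models$intercept <- c(0.2, 0.8)
  rev_clock <- clock; rev_clock$models <- clock$models[2:1, ]
  dup_clock <- clock; dup_clock$models <- rbind(clock$models, clock$models)
  expect_equal(predict_ensemble(rev_clock, betas, "B6", "F"),
               predict_ensemble(clock, betas, "B6", "F"))
  expect_equal(predict_ensemble(dup_clock, betas, "B6", "F"),
               predict_ensemble(clock, betas, "B6", "F"))

  # missing probes are skipped; no overlap is an error; unseen groups fall
  # back to the training range with a warning
  expect_equal(predict_ensemble(clock, c(a = 0.5, b = NA), "B6", "F"),
               10 + 0.2 * 100)
  expect_error(predict_ensemble(clock, c(z = 0.5), "B6", "F"), "no overlapping")
  expect_warning(predict_ensemble(clock, betas, "DBA", "M"), "absent from training")
})

test_that("ensemble clock predicts held-out samples from the same design", {
  co <- small_cohort()
  norm <- normalize_ages(co$sheet)
  train <- norm[norm$strain == "B6", ]
  probes <- co$truth$probe_id[co$truth$class == "aging_shared"]
  clock <- fit_ensemble(co$betas[probes, train$sample_id], train)
  held <- norm[norm$strain == "DBA", ]
  pred <- suppressWarnings(
    predict_ensemble(clock, co$betas[, held$sample_id], "DBA", "F"))
  metrics <- evaluate_predictions(pred, held$age_weeks)
  expect_gte(metrics$r2, 0.9)
})

test_that("multivariate search enumerates amplicon-respecting combinations", {
  set.seed(9)
  # 4 amplicons x 1 CpG: the single combination is returned
  meth <- matrix(runif(48, 0, 100), nrow = 12,
                 dimnames = list(NULL, c("a1", "b1", "c1", "d1")))
  amp <- c(a1 = "A", b1 = "B", c1 = "C", d1 = "D")
  ages <- runif(12, 5, 120)
  fit <- fit_multivariate(meth, amp, ages)
  expect_identical(fit$n_combinations, 1L)
  expect_identical(sort(fit$terms$label), c("a1", "b1", "c1", "d1"))

  # enumeration size matches the combinatorial count for {2,2,3,3,3,4,4}
  sizes <- c(2, 2, 3, 3, 3, 4, 4)
  labels <- unlist(lapply(seq_along(sizes), function(i)
    sprintf("g%d_%d", i, seq_len(sizes[i]))))
  amp2 <- stats::setNames(rep(paste0("G", seq_along(sizes)), sizes), labels)
  meth2 <- matrix(runif(12 * length(labels), 0, 100), nrow = 12,
                  dimnames = list(NULL, labels))
  fit2 <- fit_multivariate(meth2, amp2, ages)
  oracle <- sum(apply(utils::combn(sizes, 4), 2, prod))
  expect_identical(fit2$n_combinations, as.integer(oracle))

  expect_error(fit_multivariate(meth[, 1:3], amp[1:3], ages), "distinct amplicons")
})

test_that("multivariate search exactly recovers a noise-free affine model", {
  set.seed(31)
  labels <- c("A1", "A2", "B1", "C1", "C2", "D1", "E1")
  amp <- stats::setNames(c("A", "A", "B", "C", "C", "D", "E"), labels)
  meth <- matrix(runif(12 * 7, 0, 100), nrow = 12, dimnames = list(NULL, labels))
  truth_terms <- c(A1 = 1.2421, B1 = 0.9824, C2 = -1.3110, D1 = -1.6088)
  ages <- 167.4533 + as.vector(meth[, names(truth_terms)] %*% truth_terms)
  fit <- fit_multivariate(meth, amp, ages)
  expect_identical(sort(fit$terms$label), sort(names(truth_terms)))
  got <- stats::setNames(fit$terms$coefficient, fit$terms$label)[names(truth_terms)]
  expect_equal(unname(got), unname(truth_terms), tolerance = 1e-8)
  expect_equal(fit$intercept, 167.4533, tolerance = 1e-8)
  expect_lt(fit$training$mad, 1e-8)
})

test_that("the published B6 clock evaluates its frozen equation", {
  clock <- published_b6_clock()
  expect_identical(clock$provenance, "published")
  expect_equal(predict_multivariate(clock, c(0, 0, 0, 0)), 167.4533)
  expect_equal(predict_multivariate(clock, rep(50, 4)),
               167.4533 + 50 * (1.2421 + 0.9824 - 1.3110 - 1.6088))
  # named inputs are reordered to the term labels
  v <- c(Prima1_pos1 = 10, Aspa_pos1 = 20, Wnt3a_pos2 = 30, Hsf4_pos3 = 40)
  expect_equal(predict_multivariate(clock, v),
               167.4533 + 1.2421 * 20 + 0.9824 * 40 - 1.3110 * 30 - 1.6088 * 10)
  expect_error(predict_multivariate(clock, c(1, 2, 3, NA)), "missing predictor")
  expect_warning(predict_multivariate(clock, c(10, 20, 30, 140)), "outside")
})

test_that("clock models serialize to JSON and round-trip bit-identically", {
  clock <- published_b6_clock()
  path <- tempfile(fileext = ".json")
  write_clock(clock, path)
  back <- read_clock(path)
  expect_identical(back$terms$coefficient, clock$terms$coefficient)
  expect_identical(back$intercept, clock$intercept)
  expect_s3_class(back, "multivariate_clock")

  co <- small_cohort()
  norm <- normalize_ages(co$sheet)
  train <- norm[norm$strain == "B6", ]
  probes <- co$truth$probe_id[co$truth$class == "aging_shared"][1:10]
  ec <- fit_ensemble(co$betas[probes, train$sample_id], train)
  path2 <- tempfile(fileext = ".json")
  write_clock(ec, path2)
  ec2 <- read_clock(path2)
  expect_equal(ec2$models$slope, ec$models$slope, tolerance = 1e-12)
  expect_equal(ec2$denormalizer$age_max, ec$denormalizer$age_max)
  expect_equal(predict_ensemble(ec2, co$betas[, 1], "B6", "F"),
               predict_ensemble(ec, co$betas[, 1], "B6", "F"))
})

test_that("evaluation metrics use median for MAE, mean for MAD, squared Pearson for r2", {
  truth <- c(10, 20, 30)
  pred <- truth + c(1, 2, -9)        # absolute errors 1, 2, 9
  m <- evaluate_predictions(pred, truth)
  expect_equal(m$mae, 2)             # median of {1, 2, 9}
  expect_equal(m$mad, 4)             # mean of {1, 2, 9}
  naive_err <- abs(pred - truth)
  expect_equal(m$mae, median(naive_err))
  expect_equal(m$mad, mean(naive_err))

  perfect <- evaluate_predictions(truth, truth)
  expect_equal(unlist(perfect[c("mae", "mad", "r2")]), c(mae = 0, mad = 0, r2 = 1))

  err <- tryCatch(evaluate_predictions(c(5, 5, 5), truth), condition = identity)
  expect_s3_class(err, "museclock_r2_undefined")
  expect_equal(err$mae, 15)          # mae/mad still carried on the condition
  expect_equal(err$mad, 15)
})
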