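# Normalization, filters, imputation, median-polish batch correction and
# bootstrap covariate regression.

test_that("channel-sum normalization equalizes column sums", {
  M <- abundance_matrix(matrix(c(2, 2, 4, 12), 2,
                               dimnames = list(c("P1|A", "P2|B"), c("s1", "s2"))),
                        "raw")
  out <- expect_silent_log(channel_sum_normalize(M))
  expect_equal(unname(out[, "s1"]), c(8, 8))      # scaled x4 to the max sum 16
  expect_equal(unname(out[, "s2"]), c(4, 12))     # max column unchanged
  expect_equal(unname(colSums(out)), c(16, 16))
  expect_equal(abn_scale(out), "normalized")

  single <- abundance_matrix(matrix(c(1, 5), 2, 1,
                                    dimnames = list(c("P1|A", "P2|B"), "s1")), "raw")
  expect_equal(channel_sum_normalize(single)[, 1], single[, 1])

  set.seed(1)
  R <- abundance_matrix(matrix(2^rnorm(200, 10), 20,
                               dimnames = list(make_protein_ids(20), sprintf("s%d", 1:10))),
                        "raw")
  out <- channel_sum_normalize(R)
  sums <- colSums(out)
  expect_lt(max(abs(sums / sums[1] - 1)), 1e-9)

  allna <- R; allna[, 3] <- NA
  expect_error(channel_sum_normalize(abundance_matrix(allna, "raw")), "s3")
})

test_that("missingness filter removes strictly-greater-than-threshold rows", {
  vals <- matrix(1, 3, 4, dimnames = list(c("P1|A", "P2|B", "P3|C"), paste0("s", 1:4)))
  vals["P2|B", 1:2] <- NA      # exactly 50% missing: retained
  vals["P3|C", 1:3] <- NA      # 75% missing: removed
  M <- abundance_matrix(vals, "raw")
  out <- expect_silent_log(filter_missingness(M, 0.5))
  expect_setequal(rownames(out), c("P1|A", "P2|B"))
  strict <- expect_silent_log(filter_missingness(M, 0))
  expect_equal(rownames(strict), "P1|A")
})

test_that("detection in k of n replicates follows the per-group rule", {
  vals <- matrix(NA_real_, 3, 3,
                 dimnames = list(c("P1|A", "P2|B", "P3|C"), c("r1", "r2", "r3")))
  vals["P1|A", c(1, 3)] <- 1   # 2 of 3
  vals["P2|B", 2] <- 1         # 1 of 3
  M <- abundance_matrix(vals, "raw")
  groups <- setNames(rep("HP", 3), colnames(M))
  expect_equal(detect_in_k_of_n(M, groups, k = 2)$HP, "P1|A")
  expect_setequal(detect_in_k_of_n(M, groups, k = 1)$HP, c("P1|A", "P2|B"))
  expect_error(detect_in_k_of_n(M, setNames("HP", "nope")), "unknown sample")
})

test_that("downshifted imputation has the stated degenerate limits", {
  set.seed(2)
  vals <- matrix(rnorm(60, 20, 2), 6,
                 dimnames = list(make_protein_ids(6), paste0("s", 1:10)))
  vals[cbind(c(1, 2, 4), c(3, 7, 9))] <- NA
  M <- abundance_matrix(vals, "log2")

  # width 0: every imputed value in column j is exactly m_j - 1.8 s_j
  out <- impute_downshifted(M, width = 0, seed = 1)
  for (idx in which(is.na(vals))) {
    j <- ((idx - 1) %/% 6) + 1
    expect_equal(out[idx], mean(vals[, j], na.rm = TRUE) - 1.8 * sd(vals[, j], na.rm = TRUE))
  }
  expect_identical(out[!is.na(vals)], M[!is.na(vals)])

  complete <- abundance_matrix(matrix(rnorm(20), 4, 5,
                                      dimnames = list(make_protein_ids(4), paste0("s", 1:5))),
                               "log2")
  expect_identical(impute_downshifted(complete, seed = 1)[, ], complete[, ])

  expect_identical(impute_downshifted(M, seed = 9)[, ],
                   impute_downshifted(M, seed = 9)[, ])
  expect_false(identical(impute_downshifted(M, seed = 9)[, ],
                         impute_downshifted(M, seed = 10)[, ]))

  thin <- M; thin[2:6, 1] <- NA
  expect_error(impute_downshifted(abundance_matrix(thin, "log2"), seed = 1),
               "fewer than 2")
})

test_that("median polish fixed point: identical columns give zero residuals", {
  prof <- c(4, 8, 16)
  vals <- matrix(rep(prof, 5), 3, 5,
                 dimnames = list(c("P1|A", "P2|B", "P3|C"), paste0("s", 1:5)))
  sheet <- data.frame(sample_id = paste0("s", 1:5), set_label = "Set1",
                      batch_label = "b1", is_gis = c(rep(FALSE, 4), TRUE),
                      diagnosis = c(rep("Control", 4), "GIS"),
                      stringsAsFactors = FALSE)
  out <- expect_silent_log(tampor(abundance_matrix(vals, "raw"), sheet))
  expect_equal(unname(out[, ]), matrix(rep(log2(prof), 5), 3), tolerance = 1e-12)
  out_ab <- expect_silent_log(tampor(abundance_matrix(vals, "raw"), sheet,
                                     output_scale = "abundance"))
  expect_equal(unname(out_ab[, ]), matrix(rep(prof, 5), 3), tolerance = 1e-12)
})

test_that("batch correction aligns noiseless GIS channels exactly", {
  sim <- tiny_study(31, batches_per_set = 4L, channels_per_batch = 8L,
                    n_proteins = 120L, sigma_batch = 0.5, sigma_channel = 0)
  M <- expect_silent_log(channel_sum_normalize(sim$abundance))
  out <- expect_silent_log(tampor(M, sim$sheet))
  gis <- sim$sheet$sample_id[sim$sheet$is_gis]
  pre_spread <- apply(log2(sim$abundance[, gis]), 1, function(x) diff(range(x)))
  post_spread <- apply(out[, gis], 1, function(x) diff(range(x)))
  expect_gt(median(pre_spread), 0.1)
  expect_lt(max(post_spread), 1e-8)
})

test_that("polished residuals have near-zero row and column medians", {
  sim <- tiny_study(37, batches_per_set = 3L, channels_per_batch = 10L,
                    n_proteins = 80L)
  M <- expect_silent_log(channel_sum_normalize(sim$abundance))
  out <- expect_silent_log(tampor(M, sim$sheet, tol = 1e-10))
  resid <- out - apply(log2(M), 1, median)
  expect_lt(max(abs(apply(resid, 2, median))), 1e-9)
  expect_lt(max(abs(apply(resid, 1, median))), 1e-9)
})

test_that("batch correction is idempotent on complete fixtures", {
  for (seed in 1:10) {
    sim <- tiny_study(seed, batches_per_set = 3L, channels_per_batch = 6L,
                      n_proteins = 50L, sigma_batch = 0.4)
    M <- expect_silent_log(channel_sum_normalize(sim$abundance))
    once <- expect_silent_log(tampor(M, sim$sheet))
    twice <- expect_silent_log(
      tampor(abundance_matrix(2^once, "normalized"), sim$sheet))
    expect_lt(max(abs(twice - once)), 1e-6)
  }
})

test_that("tampor validates denominators and supports all-sample mode", {
  sim <- tiny_study(41)
  M <- expect_silent_log(channel_sum_normalize(sim$abundance))
  sheet_no_gis <- sim$sheet
  sheet_no_gis$is_gis[sheet_no_gis$batch_label == sheet_no_gis$batch_label[1]] <- FALSE
  expect_error(expect_silent_log(tampor(M, sheet_no_gis)), "denominator")
  out <- expect_silent_log(tampor(M, sheet_no_gis, denominator = "all_samples"))
  expect_equal(abn_scale(out), "log2")
})

test_that("bootstrap regression removes a planted batch shift", {
  sim <- tiny_study(43, batches_per_set = 2L, channels_per_batch = 26L,
                    n_proteins = 60L, n_effect_proteins = 0L,
                    sigma_batch = 0, sigma_channel = 0, sigma_noise = 0.3)
  M <- log2(sim$abundance)
  b2 <- sim$sheet$sample_id[sim$sheet$batch_label == "Set1.b2"]
  M[, b2] <- M[, b2] + 1   # planted +1 log2 shift in one batch
  M <- abundance_matrix(M, "log2")
  out <- expect_silent_log(bootstrap_covariate_regress(
    M, sim$sheet, covariates = "batch_label", n_boot = 50, seed = 7))
  b1 <- setdiff(colnames(M), b2)
  gap <- rowMeans(out[, b2]) - rowMeans(out[, b1])
  expect_lt(max(abs(gap)), 0.05 * 5)          # per-protein means re-aligned
  expect_lt(abs(mean(gap)), 0.05)
})

test_that("a null covariate leaves the data essentially unchanged", {
  sim <- tiny_study(47, batches_per_set = 2L, channels_per_batch = 16L,
                    n_proteins = 50L, n_effect_proteins = 0L,
                    sigma_batch = 0, sigma_channel = 0, sigma_noise = 0.3)
  M <- abundance_matrix(log2(sim$abundance), "log2")
  out <- expect_silent_log(bootstrap_covariate_regress(
    M, sim$sheet, covariates = "age", n_boot = 50, seed = 7))
  # age was never used in generation: mean absolute change stays small
  expect_lt(mean(abs(out - M)), 0.1)
})

test_that("full-sample single fit equals plain OLS correction", {
  sim <- tiny_study(53, batches_per_set = 2L, channels_per_batch = 10L,
                    n_proteins = 30L, sigma_batch = 0.5)
  M <- abundance_matrix(log2(sim$abundance), "log2")
  boot1 <- expect_silent_log(bootstrap_covariate_regress(
    M, sim$sheet, covariates = "batch_label", n_boot = 1, seed = 1,
    full_sample = TRUE))
  # independent OLS oracle per protein
  sheet <- sim$sheet[match(colnames(M), sim$sheet$sample_id), ]
  X <- model.matrix(~ diagnosis + batch_label, data = sheet)
  cov_col <- grep("batch_label", colnames(X))
  for (i in c(1, 15, 30)) {
    beta <- qr.coef(qr(X), M[i, ])
    expected <- M[i, ] - beta[cov_col] * (X[, cov_col] - mean(X[, cov_col]))
    expect_equal(unname(boot1[i, ]), unname(expected), tolerance = 1e-10)
  }
})

test_that("bootstrap regression preserves planted group differences", {
  sim <- tiny_study(59, batches_per_set = 3L, channels_per_batch = 15L,
                    n_proteins = 100L, n_effect_proteins = 20L,
                    delta_log2 = 1, sigma_batch = 0.4)
  M <- abundance_matrix(log2(sim$abundance), "log2")
  out <- expect_silent_log(bootstrap_covariate_regress(
    M, sim$sheet, covariates = c("batch_label", "age", "sex"),
    n_boot = 50, seed = 3))
  groups <- sim$sheet$diagnosis; names(groups) <- sim$sheet$sample_id
  ad <- names(groups)[groups == "AD"]; ctl <- names(groups)[groups == "Control"]
  before <- rowMeans(M[, ad]) - rowMeans(M[, ctl])
  after <- rowMeans(out[, ad]) - rowMeans(out[, ctl])
  expect_lt(max(abs(after - before)), 0.05)
  expect_error(expect_silent_log(bootstrap_covariate_regress(
    M, sim$sheet, covariates = "diagnosis", protect = "diagnosis",
    n_boot = 2, seed = 1)), "collide")
})
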