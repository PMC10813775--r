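test_that("fit_severity screens on training rows, selects two features and reports metrics", {
  cfg <- small_cfg(n_low = 14, n_high = 30, seed = 7L)
  tab <- feature_table(simulate_cohort(cfg))
  fit <- fit_severity(tab, split = split_spec(seed = 3L))
  expect_s3_class(fit, "severity_fit")
  expect_length(fit$features, 2L)
  expect_equal(fit$split$counts$train, c(10L, 21L))
  expect_equal(nrow(fit$screen), 71L)
  # reported accuracies recompute from stored predictions
  expect_equal(fit$test$accuracy,
               mean(fit$test$predictions == fit$y[fit$split$test]))
  expect_equal(fit$train$accuracy,
               (fit$train$confusion$tp + fit$train$confusion$tn) /
                 length(fit$split$train))
  expect_length(fit$cv$fold_scores, 5L)
  # predict method round-trips on the training table
  pred <- predict(fit, tab)
  expect_equal(pred[fit$split$test], fit$test$predictions)
})

test_that("clinical PCA fusion feeds two components into the classifier", {
  cfg <- small_cfg(n_low = 10, n_high = 12, seed = 19L)
  tab <- feature_table(simulate_cohort(cfg))
  fit <- fit_severity(tab, with_clinical = TRUE, split = split_spec(seed = 3L))
  expect_equal(colnames(fit$x), c("PC1", "PC2"))
  expect_equal(dim(fit$fusion$loadings), c(4L, 2L))
  # fused predictions recompute from the stored loadings
  expect_equal(predict(fit, tab)[fit$split$test], fit$test$predictions)
})

test_that("planted group effects give near-perfect recovery; null cohorts stay at chance", {
  # effect cohort: default plateau contrasts, n = 60 per group
  cfg <- sim_config("VV", sampling_rate = 4, group_sizes = c(60, 60), seed = 31L)
  tab <- feature_table(simulate_cohort(cfg))
  # the designed contrasts separate the designated features by >= 2 pooled SD
  for (f in c("SD_HbO2_Stage3", "SM_HBT_Stage2")) {
    vL <- tab[[f]][tab$group == "L"]; vH <- tab[[f]][tab$group == "H"]
    pooled_sd <- sqrt(((length(vL) - 1) * var(vL) + (length(vH) - 1) * var(vH)) /
                        (length(vL) + length(vH) - 2))
    expect_gte(abs(mean(vH) - mean(vL)) / pooled_sd, 2)
  }
  fit <- fit_severity(tab, split = split_spec(seed = 11L))
  expect_gte(fit$test$accuracy, 0.9)
  expect_gte(fit$cv$mean, 0.85)

  # null cohort: CV accuracy within the 95% binomial interval of the majority share
  cfg0 <- sim_config("VV", sampling_rate = 4, group_sizes = c(30, 30),
                     effect = "null", seed = 32L)
  tab0 <- feature_table(simulate_cohort(cfg0))
  x0 <- as.matrix(tab0[, c("SM_HbO2_Stage3", "SM_HHb_Stage2")])
  cv0 <- cross_validate(x0, tab0$group, k = 5, seed = 12L)
  n0 <- nrow(tab0)
  p_maj <- max(table(tab0$group)) / n0
  half_width <- 1.96 * sqrt(p_maj * (1 - p_maj) / n0)
  expect_gte(cv0$mean, p_maj - half_width)
  expect_lte(cv0$mean, p_maj + half_width)
})

test_that("run configs validate and round-trip through YAML", {
  cfg <- run_config("VV", sim = small_cfg(seed = 2L), seed = 2L)
  expect_length(validate_config(cfg), 0L)
  bad <- cfg
  bad$filter <- filter_spec(cutoff_hz = 20)
  expect_match(validate_config(bad), "Nyquist", all = FALSE)
  bad2 <- cfg
  bad2$sim$white_noise_sd <- -1
  expect_match(validate_config(bad2), "white_noise_sd", all = FALSE)

  path <- tempfile(fileext = ".yaml")
  write_run_config(cfg, path)
  back <- read_run_config(path)
  expect_equal(back$sim$plateaus, cfg$sim$plateaus)
  expect_equal(back$seed, cfg$seed)
  expect_equal(back$sim$apache_params, cfg$sim$apache_params)
  unlink(path)
})

test_that("run_pipeline produces a 69-feature table and byte-identical artifacts", {
  cfg <- run_config("VV", sim = small_cfg(n_low = 6, n_high = 8, seed = 13L),
                    seed = 13L)
  d1 <- file.path(tempdir(), "run1"); d2 <- file.path(tempdir(), "run2")
  fit1 <- run_pipeline(cfg, out_dir = d1)
  fit2 <- run_pipeline(cfg, out_dir = d2)
  tab <- read.csv(file.path(d1, "feature_table.csv"), check.names = FALSE)
  expect_length(feature_names(tab), 69L)
  expect_identical(readLines(file.path(d1, "model_report.json")),
                   readLines(file.path(d2, "model_report.json")))
  expect_identical(readLines(file.path(d1, "feature_table.csv")),
                   readLines(file.path(d2, "feature_table.csv")))
  expect_equal(fit1$test$accuracy, fit2$test$accuracy)
  expect_true(file.exists(file.path(d1, "cohort", "metadata.csv")))
  expect_true(file.exists(file.path(d1, "screening.csv")))
  expect_true(file.exists(file.path(d1, "summary.txt")))
  unlink(c(d1, d2), recursive = TRUE)

  bad <- cfg
  bad$train_fraction <- 1.5
  expect_error(run_pipeline(bad), "train_fraction")
})
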