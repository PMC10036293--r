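test_that("fitted coefficients equal the normal-equation solution", {
  cov <- six_row_covariates()
  # TIV in units of 1e6 mm^3 keeps the oracle's X'X well conditioned
  cov$tiv_mm3 <- cov$tiv_mm3 / 1e6
  set.seed(301)
  y <- 5000 - 8 * cov$age_years + 120 * (cov$sex == "male") +
    2e3 * cov$tiv_mm3 + 40 * (cov$scanner == "B") + rnorm(6, 0, 25)
  meas <- data.frame(participant_id = cov$participant_id,
                     roi = "caudate", modality = "volume", value = y)
  fit <- fit_normative(meas, cov)
  # reference scanner: tie between A and B broken lexicographically -> A
  X <- cbind(1, cov$age_years, as.numeric(cov$sex == "male"), cov$tiv_mm3,
             as.numeric(cov$scanner == "B"))
  beta <- oracle_ols(X, y)
  expect_equal(unname(coef(fit)[1, ]), beta, tolerance = 1e-10)
  rss <- sum((y - drop(X %*% beta))^2)
  expect_equal(unname(sigma(fit)), sqrt(rss / (6 - 5)), tolerance = 1e-10)
  # alternative sigma convention divides by n - 1 instead
  fit1 <- fit_normative(meas, cov, sigma_df = "n-1")
  expect_equal(unname(sigma(fit1)), sqrt(rss / 5), tolerance = 1e-10)
})

test_that("constant control values yield a degenerate flagged model", {
  cov <- six_row_covariates()
  meas <- data.frame(participant_id = cov$participant_id,
                     roi = "caudate", modality = "volume", value = 100)
  fit <- suppressMessages(fit_normative(meas, cov))
  s <- summary(fit)
  expect_true(s$degenerate)
  expect_equal(unname(coef(fit)[1, 1]), 100, tolerance = 1e-6)
  expect_equal(max(abs(coef(fit)[1, -1])), 0, tolerance = 1e-6)
  # degenerate models refuse to score
  out <- suppressMessages(wscore(fit, meas, cov))
  expect_equal(nrow(out), 0L)
})

test_that("five scanner categories give exactly four scanner offsets", {
  spec <- small_spec(n_controls = 200)
  ctl <- generate_controls(spec, one_roi_model(), seed = 31)
  expect_setequal(unique(ctl$participants$scanner), scanner_types())
  fit <- fit_normative(ctl$measures, ctl$participants)
  nm <- colnames(coef(fit))
  expect_equal(sum(startsWith(nm, "scanner")), 4L)
  expect_false(any(grepl(fit$reference, nm)))
})

test_that("rank-deficient designs fail naming the collinear column", {
  cov <- six_row_covariates()
  cov$tiv_mm3 <- 1.4e6  # constant -> collinear with intercept
  meas <- data.frame(participant_id = cov$participant_id,
                     roi = "caudate", modality = "volume",
                     value = rnorm(6, 5000, 10))
  expect_error(fit_normative(meas, cov), "collinear.*tiv_mm3")
})

test_that("prediction is the linear predictor and rejects unseen scanners", {
  # noise-free generation: the fit recovers the generative coefficients,
  # so predictions at two ages differ by exactly beta_age * gap
  rm <- one_roi_model(beta_age = -5, sigma = 0)
  ctl <- generate_controls(small_spec(n_controls = 60), rm, seed = 32)
  fit <- suppressMessages(fit_normative(ctl$measures, ctl$participants))
  nd <- data.frame(participant_id = c("a", "b"), age_years = c(40, 50),
                   sex = "female", tiv_mm3 = 1.4e6,
                   scanner = "SiemensTrio")
  pred <- predict(fit, nd)
  expect_equal(diff(pred$predicted), -50, tolerance = 1e-6)
  nd$scanner <- "7T-X"
  expect_error(predict(fit, nd), "unseen scanner")
})

test_that("prediction at covariate means equals the control mean under balance", {
  # balanced one-scanner design: OLS passes through the mean point
  cov <- data.frame(participant_id = sprintf("P%02d", 1:20),
                    age_years = rep(c(40, 50), 10),
                    sex = rep(c("female", "male"), each = 10),
                    tiv_mm3 = rep(c(1.3e6, 1.5e6, 1.5e6, 1.3e6), 5),
                    scanner = "SiemensPrisma", stringsAsFactors = FALSE)
  set.seed(33)
  y <- rnorm(20, 6000, 300)
  meas <- data.frame(participant_id = cov$participant_id, roi = "putamen",
                     modality = "volume", value = y)
  fit <- fit_normative(meas, cov)
  nd <- data.frame(participant_id = "mean", age_years = 45, sex = "female",
                   tiv_mm3 = 1.4e6, scanner = "SiemensPrisma")
  pred_f <- predict(fit, nd)$predicted
  nd$sex <- "male"
  pred_m <- predict(fit, nd)$predicted
  expect_equal((pred_f + pred_m) / 2, mean(y), tolerance = 1e-8)
})

test_that("w-scores follow (x - predicted) / sigma exactly", {
  fit <- fixed_fit(intercept = 1000, sigma = 50)
  meas <- data.frame(participant_id = "c1", roi = "hippocampus",
                     modality = "volume", value = 935.9)
  cov <- data.frame(participant_id = "c1", age_years = 50, sex = "male",
                    tiv_mm3 = 1.4e6, scanner = "SiemensTrio")
  w <- wscore(fit, meas, cov)
  expect_equal(w$wscore, (935.9 - 1000) / 50)
  expect_equal(w$wscore, -1.282, tolerance = 1e-12)
  expect_equal(w$percentile, 100 * pnorm(-1.282))
  meas$value <- 1000
  expect_equal(wscore(fit, meas, cov)$wscore, 0)
})

test_that("in-sample control w-scores have mean 0 and unit-like SD", {
  spec <- default_genfi_spec()
  rm <- control_model_params(data.frame(roi = c("hippocampus", "UF", "UF"),
                                        modality = c("volume", "FA", "MD")))
  ctl <- generate_controls(spec, rm, seed = 34)
  fit <- fit_normative(ctl$measures, ctl$participants)
  w <- wscore(fit, ctl$measures, ctl$participants)
  for (k in unique(paste(w$roi, w$modality))) {
    wk <- w$wscore[paste(w$roi, w$modality) == k]
    expect_lt(abs(mean(wk)), 1e-10)
    expect_gt(sd(wk), 0.95)
    expect_lt(sd(wk), 1.05)
  }
})

test_that("w-scores are invariant to unit changes and covariate shifts", {
  spec <- small_spec(n_controls = 120)
  rm <- one_roi_model("thalamus", "volume")
  ctl <- generate_controls(spec, rm, seed = 35)
  car <- generate_carriers(spec, rm, list(), seed = 36)
  fit <- fit_normative(ctl$measures, ctl$participants)
  w0 <- wscore(fit, car$measures, car$participants)

  # unit change: multiply the raw values by 1000 and refit
  m2 <- ctl$measures; m2$value <- m2$value * 1000
  c2 <- car$measures; c2$value <- c2$value * 1000
  w2 <- wscore(fit_normative(m2, ctl$participants), c2, car$participants)
  expect_equal(w2$wscore, w0$wscore, tolerance = 1e-9)

  # covariate shift: add a constant to every age and every TIV and refit
  pc <- ctl$participants; pc$age_years <- pc$age_years + 100
  pc$tiv_mm3 <- pc$tiv_mm3 + 5e5
  pk <- car$participants; pk$age_years <- pk$age_years + 100
  pk$tiv_mm3 <- pk$tiv_mm3 + 5e5
  w3 <- wscore(fit_normative(ctl$measures, pc), car$measures, pk)
  expect_equal(w3$wscore, w0$wscore, tolerance = 1e-9)
})

test_that("percentile cut points and percentiles are mutual inverses", {
  expect_equal(percentile_cutpoint(0.5), 0)
  expect_equal(wscore_percentile(0), 50)
  expect_equal(round(wscore_percentile(-0.675)), 25)
  expect_error(percentile_cutpoint(0), "strictly in")
  expect_error(percentile_cutpoint(1), "strictly in")
  expect_error(wscore_percentile(Inf), "finite")
  w <- seq(-4, 4, by = 0.25)
  expect_equal(percentile_cutpoint(wscore_percentile(w) / 100), w,
               tolerance = 1e-9)
})

test_that("held-out control w-scores are approximately standard normal", {
  rm <- one_roi_model("thalamus", "volume")
  crit <- 1.358 / sqrt(500)  # 5% Kolmogorov-Smirnov critical value
  ok <- vapply(1:20, function(rep) {
    spec <- small_spec(seed = rep, n_controls = 240)
    ctl <- generate_controls(spec, rm, seed = 100 + rep)
    hold_spec <- small_spec(n_controls = 500)
    hold <- generate_controls(hold_spec, rm, seed = 200 + rep)
    fit <- fit_normative(ctl$measures, ctl$participants)
    w <- wscore(fit, hold$measures, hold$participants)
    unname(ks.test(w$wscore, "pnorm")$statistic) < crit
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("model JSON serialization round-trips at full precision", {
  ctl <- generate_controls(small_spec(n_controls = 100), one_roi_model(),
                           seed = 37)
  car <- generate_carriers(small_spec(), one_roi_model(), list(), seed = 38)
  fit <- fit_normative(ctl$measures, ctl$participants)
  path <- tempfile(fileext = ".json")
  write_normative_json(fit, path)
  fit2 <- read_normative_json(path)
  expect_equal(unname(coef(fit2)), unname(coef(fit)), tolerance = 1e-12)
  expect_equal(sigma(fit2), sigma(fit), tolerance = 1e-12)
  w1 <- wscore(fit, car$measures, car$participants)
  w2 <- wscore(fit2, car$measures, car$participants)
  expect_equal(w1$wscore, w2$wscore, tolerance = 1e-12)
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(list(a = 1), bad)
  expect_error(read_normative_json(bad), "not a normative model file")
})

test_that("rows with missing covariates are skipped with a log entry", {
  cov <- six_row_covariates()
  set.seed(39)
  meas <- data.frame(participant_id = rep(cov$participant_id, 2),
                     roi = "caudate", modality = "volume",
                     value = rnorm(12, 5000, 100))
  fit <- fit_normative(meas, cov)
  cov$age_years[2] <- NA
  expect_message(w <- wscore(fit, meas, cov), "missing covariates")
  expect_equal(nrow(w), 10L)
  expect_false("P02" %in% w$participant_id)
})
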