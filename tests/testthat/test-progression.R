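test_that("staging maps the global score deterministically", {
  clin <- data.frame(participant_id = paste0("p", 1:5),
                     cdr_global = c(0, 0.5, 1, 2, 3))
  st <- stage_participants(clin)
  expect_equal(st$stage, c("presymptomatic", "presymptomatic",
                           "symptomatic", "symptomatic", "symptomatic"))
  clin$cdr_global[2] <- 0.7
  expect_error(stage_participants(clin), "invalid CDR global.*p2")
})

test_that("visit pairing subtracts baseline from follow-up and logs unpaired", {
  clin <- data.frame(
    participant_id = c("a", "a", "b", "c", "c"),
    visit = c("baseline", "month12", "baseline", "baseline", "month12"),
    cdr_sb = c(0.2, 3.2, 1.0, 0.5, 0.5))
  expect_message(pr <- pair_visits(clin, "cdr_sb"), "1 participant")
  expect_equal(nrow(pr), 2L)
  expect_equal(pr$delta[pr$participant_id == "a"], 3.0)
  expect_equal(pr$delta[pr$participant_id == "c"], 0.0)
  clin2 <- rbind(clin, data.frame(participant_id = "a", visit = "month12",
                                  cdr_sb = 4))
  expect_error(pair_visits(clin2, "cdr_sb"), "duplicate visit")
})

test_that("exact signed-rank p-values match hand-enumerable cases", {
  expect_equal(exact_wilcoxon_signed_rank(c(1, -1))$p.value, 1.0)
  r5 <- exact_wilcoxon_signed_rank(c(1, 2, 3, 4, 5))
  expect_equal(r5$p.value, 0.0625)   # 2 / 2^5
  expect_equal(r5$statistic, 15)
  expect_equal(exact_wilcoxon_signed_rank(c(0.1, 0.7, 2, 3.5, 8, 9))$p.value,
               0.03125)              # 2 / 2^6
  # zeros are dropped before ranking, and reported
  rz <- exact_wilcoxon_signed_rank(c(0, 0, 1, 2, 3, 4, 5))
  expect_equal(rz$n_used, 5L)
  expect_equal(rz$n_zero, 2L)
  expect_equal(rz$p.value, 0.0625)
  all0 <- exact_wilcoxon_signed_rank(c(0, 0, 0))
  expect_true(is.na(all0$p.value))
  expect_match(all0$reason, "zero")
  expect_error(exact_wilcoxon_signed_rank(numeric(0)), "non-empty")
  expect_error(exact_wilcoxon_signed_rank(c(1, NA)), "finite")
})

test_that("exact p equals brute-force sign enumeration, including ties", {
  set.seed(51)
  for (i in 1:40) {
    n <- sample(2:12, 1)
    # small integer support forces ties and zeros
    d <- sample(-3:3, n, replace = TRUE)
    if (all(d == 0)) d[1] <- 1
    expect_equal(exact_wilcoxon_signed_rank(d)$p.value,
                 oracle_signed_rank_p(d), tolerance = 1e-12,
                 info = paste(d, collapse = ","))
  }
})

test_that("untied exact p agrees with the reference implementation", {
  set.seed(52)
  for (i in 1:20) {
    n <- sample(6:18, 1)
    d <- round(rnorm(n, 0.3, 1), 6)  # continuous: no ties, no zeros
    ours <- exact_wilcoxon_signed_rank(d)$p.value
    ref <- stats::wilcox.test(d, exact = TRUE)$p.value
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("p-values are symmetric under sign flips", {
  set.seed(53)
  for (i in 1:20) {
    d <- sample(-5:5, sample(3:15, 1), replace = TRUE)
    if (all(d == 0)) d[1] <- 2
    expect_equal(exact_wilcoxon_signed_rank(d)$p.value,
                 exact_wilcoxon_signed_rank(-d)$p.value)
  }
})

test_that("beyond the enumeration cutoff the tie-corrected approximation is used", {
  set.seed(54)
  d <- round(rnorm(35, 0.2, 1), 2)
  d <- d[d != 0]
  res <- exact_wilcoxon_signed_rank(d)
  expect_match(res$method, "normal approximation")
  ref <- stats::wilcox.test(d, exact = FALSE, correct = FALSE)$p.value
  expect_equal(res$p.value, ref, tolerance = 1e-10)
  # the cutoff itself is configurable
  res_exact <- exact_wilcoxon_signed_rank(d, exact_max_n = 40)
  expect_match(res_exact$method, "exact")
  expect_lt(abs(res_exact$p.value - res$p.value), 0.02)
})

test_that("the exact test holds its size under the null", {
  set.seed(55)
  rej <- vapply(1:2000, function(i) {
    p <- exact_wilcoxon_signed_rank(rnorm(20))$p.value
    p <= 0.05
  }, logical(1))
  expect_lte(mean(rej), 0.055)
})

test_that("the smallest attainable p crosses 0.05 exactly at n = 6", {
  expect_equal(min_attainable_p(1), 1.0)
  expect_equal(min_attainable_p(5), 0.0625)
  expect_equal(min_attainable_p(6), 0.03125)
  expect_true(all(diff(min_attainable_p(1:20)) < 0))
  expect_error(min_attainable_p(0), ">= 1")
  # agreement with enumeration: all-same-sign data attain the floor
  for (n in 2:10)
    expect_equal(exact_wilcoxon_signed_rank(seq_len(n))$p.value,
                 min_attainable_p(n))
})

test_that("progression strata apply the <3 exclusion and <6 caution rules", {
  mk_calls <- function(ids, label)
    data.frame(participant_id = ids, roi = "hippocampus",
               modality = "volume", label = label)
  part <- data.frame(participant_id = paste0("p", 1:12), group = "GRN",
                     cdr_global = 0, stringsAsFactors = FALSE)
  pairs <- data.frame(participant_id = paste0("p", 1:12), scale = "cdr_sb",
                      baseline = 1, month12 = 1 + (1:12) / 10,
                      delta = (1:12) / 10)
  # 2 abnormal vs 10 normal: abnormal stratum excluded
  calls <- mk_calls(part$participant_id,
                    rep(c("abnormal", "normal"), c(2, 10)))
  res <- progression_by_roi(calls, pairs, part, "GRN", B = 100, seed = 1)
  abn <- res[res$stratum == "abnormal", ]
  expect_equal(abn$flag, "excluded_lt3")
  expect_true(is.na(abn$p_value))
  expect_equal(abn$n_pairs, 2L)
  nor <- res[res$stratum == "normal", ]
  expect_equal(nor$flag, "ok")
  expect_false(is.na(nor$p_value))

  # 4 abnormal, all positive deltas: caution, p = 2/2^4 = 0.125
  calls <- mk_calls(part$participant_id,
                    rep(c("abnormal", "normal"), c(4, 8)))
  res <- progression_by_roi(calls, pairs, part, "GRN", B = 100, seed = 2)
  abn <- res[res$stratum == "abnormal", ]
  expect_equal(abn$flag, "caution_lt6")
  expect_equal(abn$p_value, 0.125)
})

test_that("symptomatic carriers never enter progression strata", {
  part <- data.frame(participant_id = paste0("p", 1:10), group = "MAPT",
                     cdr_global = rep(c(0, 1), each = 5))
  calls <- data.frame(participant_id = part$participant_id,
                      roi = "amygdala", modality = "volume",
                      label = "abnormal")
  pairs <- data.frame(participant_id = part$participant_id,
                      scale = "cdr_sb", baseline = 0,
                      month12 = 1:10, delta = 1:10)
  res <- progression_by_roi(calls, pairs, part, "MAPT", B = 50, seed = 3)
  expect_equal(sum(res$n_pairs), 5L)  # only the five presymptomatic
})

test_that("subfield regions are excluded from default progression runs", {
  part <- data.frame(participant_id = paste0("p", 1:8), group = "GRN",
                     cdr_global = 0)
  calls <- rbind(
    data.frame(participant_id = part$participant_id, roi = "pulvinar",
               modality = "volume", label = "abnormal"),
    data.frame(participant_id = part$participant_id, roi = "thalamus",
               modality = "volume", label = "abnormal"))
  pairs <- data.frame(participant_id = part$participant_id,
                      scale = "cdr_sb", baseline = 0, month12 = 1,
                      delta = 1)
  res <- progression_by_roi(calls, pairs, part, "GRN", B = 20, seed = 4)
  expect_false("pulvinar" %in% res$roi)
  expect_true("thalamus" %in% res$roi)
  # but an explicit ROI set may include them
  res2 <- progression_by_roi(calls, pairs, part, "GRN",
                             rois = c("pulvinar", "thalamus"), B = 20,
                             seed = 5)
  expect_true("pulvinar" %in% res2$roi)
  expect_error(progression_by_roi(calls[0, ], pairs, part, "GRN",
                                  B = 20), "empty ROI set")
})

test_that("a simulated +3-point abnormal-stratum change is detected", {
  set.seed(56)
  n_abn <- 30; n_nor <- 40
  ids <- paste0("p", seq_len(n_abn + n_nor))
  part <- data.frame(participant_id = ids, group = "C9orf72",
                     cdr_global = 0.5)
  calls <- data.frame(participant_id = ids, roi = "dlpfc",
                      modality = "volume",
                      label = rep(c("abnormal", "normal"),
                                  c(n_abn, n_nor)))
  base <- pmax(0, round(rnorm(n_abn + n_nor, 0.5, 0.5), 1))
  delta <- c(rnorm(n_abn, 3, 1), rnorm(n_nor, 0, 0.3))
  pairs <- data.frame(participant_id = ids, scale = "cdr_sb",
                      baseline = base, month12 = base + delta,
                      delta = delta)
  res <- progression_by_roi(calls, pairs, part, "C9orf72", B = 500,
                            seed = 6)
  abn <- res[res$stratum == "abnormal", ]
  expect_lt(abn$p_value, 0.001)
  expect_lt(abs(abn$mean_delta - 3), 0.6)
  expect_true(abn$ci_lo > 2 && abn$ci_hi < 4)
  nor <- res[res$stratum == "normal", ]
  expect_gt(nor$p_value, 0.001)
})
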