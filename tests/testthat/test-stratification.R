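test_that("assign_group agrees with the brute-force truth table on all 16 combinations", {
  tt <- oracle_truth_table()
  got <- assign_group(tt[, c("A", "T", "N", "V")])
  expect_equal(as.character(got), tt$label)
  # partition: exactly one label per row, sizes as enumerated by hand
  expect_equal(as.vector(table(got)[group_levels()]),
               c(N = 1, AD = 4, V = 2, AV = 4, OP = 3, EXCLUDED = 2),
               ignore_attr = TRUE)
})

test_that("biomarker thresholds are strict: boundary values classify negative", {
  # each threshold at its boundary, with the other markers clearly negative
  at_boundary <- data.frame(
    abeta42 = c(1030, 2000, 2000, 2000, 2000),
    ptau = c(10, 27, 10, 10, 10),
    ttau = c(150, 150, 300, 150, 150),
    fazekas = c(0, 0, 0, 1, 0),
    microbleeds = c(0, 0, 0, 0, 3),
    stroke_history = FALSE
  )
  st <- classify_biomarkers(at_boundary)
  expect_false(any(st$A | st$T | st$N | st$V))
  # ratio exactly at threshold is negative too: 0.023 * 2000 = 46
  st2 <- classify_biomarkers(data.frame(abeta42 = 2000, ptau = 46, ttau = 150,
                                        fazekas = 0, microbleeds = 0,
                                        stroke_history = FALSE))
  expect_false(st2$A)
  expect_true(st2$T)  # 46 > 27
})

test_that("classification matches worked examples", {
  ex <- data.frame(
    abeta42 = c(900, 1200),
    ptau = c(20, 30), ttau = c(200, 100),
    fazekas = 0, microbleeds = 0, stroke_history = FALSE
  )
  st <- classify_biomarkers(ex)
  expect_equal(st$A, c(TRUE, TRUE))   # 900 < 1030; 30/1200 = 0.025 > 0.023
  expect_equal(st$T, c(FALSE, TRUE))
  expect_equal(st$N, c(FALSE, FALSE))
  expect_equal(st$V, c(FALSE, FALSE))
})

test_that("thresholds are monotone in the pathological direction", {
  set.seed(42)
  for (i in 1:50) {
    rec <- data.frame(abeta42 = runif(1, 500, 2500), ptau = runif(1, 5, 60),
                      ttau = runif(1, 50, 600), fazekas = sample(0:3, 1),
                      microbleeds = sample(0:8, 1),
                      stroke_history = runif(1) < 0.2)
    st <- classify_biomarkers(rec)
    lower_ab <- rec; lower_ab$abeta42 <- rec$abeta42 * runif(1, 0.3, 0.99)
    higher_pt <- rec; higher_pt$ptau <- rec$ptau * runif(1, 1.01, 3)
    if (st$A) expect_true(classify_biomarkers(lower_ab)$A)
    if (st$T) expect_true(classify_biomarkers(higher_pt)$T)
  }
})

test_that("missing or non-positive abeta42 is rejected with a diagnostic", {
  bad <- data.frame(abeta42 = c(1500, 0), ptau = 15, ttau = 150, fazekas = 0,
                    microbleeds = 0, stroke_history = FALSE)
  expect_error(classify_biomarkers(bad), "abeta42")
  bad$abeta42 <- c(1500, NA)
  expect_error(classify_biomarkers(bad), "abeta42")
})

test_that("inclusion filters keep clean subjects and attach one reason per rejection", {
  coh <- make_cohort(10)
  coh$cdr_global[2] <- 0.5
  coh$qc_pass[5] <- FALSE
  coh$age[9] <- 48
  res <- apply_inclusion_filters(coh)
  expect_equal(nrow(res$kept), 7)
  expect_equal(res$rejected$subject_id, c("S002", "S005", "S009"))
  expect_equal(res$rejected$reason_code,
               c("cdr_nonzero", "qc_fail", "age_below_50"))
})

test_that("missing biomarker or vascular readings are rejected, not guessed", {
  coh <- make_cohort(4)
  coh$ptau[2] <- NA
  coh$fazekas[3] <- NA
  res <- apply_inclusion_filters(coh)
  expect_equal(nrow(res$kept), 2)
  expect_setequal(res$rejected$reason_code, c("missing_biomarker", "missing_vascular"))
})

test_that("an all-rejected cohort is a pipeline-level error", {
  coh <- make_cohort(3, cdr_global = 1)
  expect_error(apply_inclusion_filters(coh), "no subjects")
})

test_that("stratification partitions the 16-combination cohort as enumerated", {
  tt <- oracle_truth_table()
  # realize each A/T/N/V combination with concrete marker values
  coh <- make_cohort(16)
  coh$abeta42 <- ifelse(tt$A, 900, 2000)
  coh$ptau <- ifelse(tt$T, 35, 10)
  coh$ttau <- ifelse(tt$N, 400, 150)
  coh$fazekas <- ifelse(tt$V, 3, 0)
  st <- stratify_cohort(coh)
  expect_equal(st$sizes, c(N = 1, AD = 4, V = 2, AV = 4, OP = 3))
  expect_equal(nrow(st$excluded), 2)
  expect_equal(nrow(st$cohort) + nrow(st$excluded), 16)
})

test_that("stratification is idempotent and labels every subject exactly once", {
  coh <- generate_cohort(small_config(), seed = 11)
  st1 <- stratify_cohort(apply_inclusion_filters(coh)$kept)
  st2 <- stratify_cohort(st1$cohort)
  expect_equal(as.character(st1$cohort$group), as.character(st2$cohort$group))
  expect_equal(st1$sizes, st2$sizes)
  # all-negative cohort collapses to a single N group
  neg <- make_cohort(12)
  expect_equal(stratify_cohort(neg)$sizes,
               c(N = 12, AD = 0, V = 0, AV = 0, OP = 0))
})
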