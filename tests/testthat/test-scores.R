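ref5 <- function() {
  list(moca = list(mean = 28, sd = 2),
       stroop_colour = list(mean = 32, sd = 6),
       fluency_category = list(mean = 21, sd = 7),
       fluency_letter = list(mean = 17, sd = 6),
       hooper = list(mean = 25, sd = 3))
}

test_that("composite cognition z-scores, sign-flips timed tasks, averages", {
  rf <- ref5()
  at_mean <- list(moca = 28, stroop_colour = 32, fluency_category = 21,
                  fluency_letter = 17, hooper = 25)
  expect_equal(composite_cognitive_score(at_mean, rf), 0)
  # one reference-SD better on every component (Stroop: faster = better)
  better <- list(moca = 30, stroop_colour = 26, fluency_category = 28,
                 fluency_letter = 23, hooper = 28)
  expect_equal(composite_cognitive_score(better, rf), 1)
  # components at z = (+1, +1, -1, -1, 0) average to zero
  mixed <- list(moca = 30, stroop_colour = 26, fluency_category = 28,
                fluency_letter = 23, hooper = 25)
  mixed$stroop_colour <- 38       # z = -1 after flip
  mixed$fluency_category <- 14    # z = -1
  expect_equal(composite_cognitive_score(mixed, rf), 0)
  # missing handling
  missing_all <- list(moca = NA, stroop_colour = NA, fluency_category = NA,
                      fluency_letter = NA, hooper = NA)
  out <- composite_cognitive_score(missing_all, rf)
  expect_true(is.na(out))
  expect_match(attr(out, "reason"), "missing")
  partial <- at_mean; partial$hooper <- NA
  expect_true(is.na(composite_cognitive_score(partial, rf)))
  expect_equal(composite_cognitive_score(partial, rf, policy = "available"),
               0)
})

test_that("composites are invariant to affine rescaling with refit stats", {
  co <- data.frame(group = rep(c("control", "DLB"), each = 10),
                   moca = c(rnorm(10, 28, 1), rnorm(10, 21, 4)))
  set.seed(2)
  co$stroop_colour <- rnorm(20, 35, 8)
  co$fluency_category <- rnorm(20, 20, 5)
  co$fluency_letter <- rnorm(20, 16, 5)
  co$hooper <- rnorm(20, 24, 3)
  comps <- names(ref5())
  rf1 <- reference_stats(co, comps, "control")
  z1 <- composite_cognitive_score(as.list(co[15, ]), rf1)
  co2 <- co
  co2$moca <- 3 * co$moca + 7           # affine rescale one component
  rf2 <- reference_stats(co2, comps, "control")
  z2 <- composite_cognitive_score(as.list(co2[15, ]), rf2)
  expect_equal(z1, z2, tolerance = 1e-12)
})

test_that("NPI-4 estimate follows the configured mapping with provenance", {
  mapping <- list(list(fields = c("hads_dep", "phq9")),
                  list(fields = "umpdhq"),
                  list(fields = "updrs1"))
  rec <- list(hads_dep = 2, phq9 = NA, umpdhq = 1, updrs1 = 3)
  out <- npi4_estimate(rec, mapping)
  expect_equal(as.numeric(out), 6)
  expect_equal(attr(out, "provenance"), c("hads_dep", "umpdhq", "updrs1"))
  # fallback branch: HADS missing, PHQ-9 used and logged
  rec2 <- list(hads_dep = NA, phq9 = 5, umpdhq = 0, updrs1 = 0)
  out2 <- npi4_estimate(rec2, mapping)
  expect_equal(as.numeric(out2), 5)
  expect_equal(attr(out2, "provenance")[1], "phq9")
  # zero inputs give zero for any non-negative weighting
  rec0 <- list(hads_dep = 0, phq9 = 0, umpdhq = 0, updrs1 = 0)
  expect_equal(as.numeric(npi4_estimate(rec0, mapping)), 0)
  expect_error(npi4_estimate(list(umpdhq = 1), mapping),
               "hads_dep.*phq9|absent")
})

test_that("LBD symptom composite is a severity-aligned z average", {
  rf <- list(npi4 = list(mean = 4, sd = 2), updrs3 = list(mean = 30, sd = 10),
             dcfs = list(mean = 9, sd = 3), moca = list(mean = 24, sd = 4))
  expect_equal(lbd_symptom_composite(4, 30, 9, 24, rf), 0)
  # one component two SD worse, rest at reference: composite +0.5
  expect_equal(lbd_symptom_composite(8, 30, 9, 24, rf), 0.5)
  expect_equal(lbd_symptom_composite(4, 30, 9, 16, rf), 0.5)  # MoCA flipped
  expect_true(is.na(lbd_symptom_composite(NA, 30, 9, 24, rf)))
})

test_that("vascular-risk total counts positives over the seven items", {
  expect_equal(vascular_risk_score(rep(FALSE, 7)), 0L)
  expect_equal(vascular_risk_score(rep(TRUE, 7)), 7L)
  items <- c(angina = TRUE, mi = FALSE, stroke = FALSE, diabetes = TRUE,
             cholesterol = FALSE, hypertension = FALSE, smoker = TRUE)
  expect_equal(vascular_risk_score(items), 3L)
  expect_error(vascular_risk_score(rep(TRUE, 6)), "7")
  expect_true(is.na(vascular_risk_score(c(rep(TRUE, 6), NA),
                                        na_action = "na")))
  # monotone: adding a positive item never lowers the score
  set.seed(3)
  for (i in 1:10) {
    x <- sample(c(TRUE, FALSE), 7, replace = TRUE)
    j <- which(!x)[1]
    if (is.na(j)) next
    x2 <- x; x2[j] <- TRUE
    expect_gte(vascular_risk_score(x2), vascular_risk_score(x))
  }
})

test_that("SVD burden scores the four imaging criteria exactly", {
  expect_equal(svd_burden(2, 2, 1, 3), 4L)
  expect_equal(svd_burden(0, 0, 0, 0), 0L)
  expect_equal(svd_burden(1, 1, 0, 2), 2L)
  # rule-by-rule boundaries
  expect_equal(svd_burden(2, 0, 0, 0), 1L)   # Fazekas 2-3 scores
  expect_equal(svd_burden(1, 0, 0, 0), 0L)
  expect_equal(svd_burden(0, 0, 0, 2), 1L)   # EPVS grade 2-4 scores
  expect_equal(svd_burden(0, 0, 0, 1), 0L)
  expect_error(svd_burden(4, 0, 0, 0), "Fazekas")
  expect_error(svd_burden(0, 0, 0, 5), "EPVS")
  expect_error(svd_burden(0, -1, 0, 0), "counts")
})

test_that("inclusion filters cut at the stated boundaries and are idempotent", {
  co <- data.frame(
    id = sprintf("s%02d", 1:8),
    group = c("control", "control", "PD-NC", "PD-NC", "PDD", "PDD",
              "DLB", "DLB"),
    mmse = c(24, 25, 28, 29, 26, 27, 22, 21),
    duration = c(NA, NA, 9.9, 10.1, 12, 3, 10, 11),
    duration_dementia = c(NA, NA, NA, NA, 2, 1.5, NA, NA)
  )
  out <- apply_inclusion_filters(co)
  expect_false("s01" %in% out$cohort$id)   # control MMSE 24 excluded
  expect_true("s02" %in% out$cohort$id)    # MMSE 25 retained
  expect_true("s03" %in% out$cohort$id)    # 9.9 y retained
  expect_false("s04" %in% out$cohort$id)   # 10.1 y excluded
  expect_true("s05" %in% out$cohort$id)    # PDD judged on dementia duration
  expect_true("s07" %in% out$cohort$id)    # exactly 10 y retained
  expect_false("s08" %in% out$cohort$id)
  expect_setequal(out$log$rule[out$log$id == "s01"],
                  "control_mmse_lt_cutoff")
  # idempotent
  again <- apply_inclusion_filters(out$cohort)
  expect_identical(again$cohort, out$cohort)
  expect_equal(nrow(again$log), 0)
  # empty cohort passes through
  empty <- apply_inclusion_filters(co[0, ])
  expect_equal(nrow(empty$cohort), 0)
  expect_equal(nrow(empty$log), 0)
})
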