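test_that("cohort generation is reproducible byte for byte", {
  cfg <- cohort_config(seed = 1)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$patients, b$patients)
  expect_identical(a$foci, b$foci)
  expect_equal(nrow(a$patients), 465)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort(a, f1); write_cohort(b, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_equal(read_cohort(f1)$radial_mm, a$patients$radial_mm,
               tolerance = 1e-12)
})

test_that("every patient carries consistent EPE foci", {
  coh <- generate_cohort(cohort_config(n_patients = 300, seed = 4))
  p <- coh$patients
  counts <- table(coh$foci$patient_id)
  expect_true(all(p$patient_id %in% names(counts)))
  expect_identical(as.integer(counts[as.character(p$patient_id)]), p$n_epe)
  # index focus equals the patient-level radial distance, inside its bin
  idx <- coh$foci[!duplicated(coh$foci$patient_id), ]
  expect_equal(idx$r_mm, p$radial_mm)
  lo <- c(0, 0.75, 2, 5)[p$radial_bin]
  hi <- c(0.75, 2, 5, Inf)[p$radial_bin]
  expect_true(all(p$radial_mm > lo & p$radial_mm <= hi))
  # satellite foci never exceed the index radial distance
  expect_true(all(coh$foci$r_mm <= p$radial_mm[coh$foci$patient_id] + 1e-12))
  # nodule identities are distinct within a patient, so the counting rule
  # recovers the focus count
  by_pat <- split(coh$foci$nodule_id, coh$foci$patient_id)
  expect_identical(unname(vapply(by_pat, count_epe_foci, integer(1))),
                   as.integer(counts))
})

test_that("censoring calibration reproduces the target event fraction", {
  cfg <- cohort_config(seed = 1)
  fr <- vapply(1:50, function(i)
    mean(generate_cohort(cfg, seed = 100 + i)$patients$bcr_event),
    numeric(1))
  expect_lt(abs(mean(fr) - 255 / 465), 0.05)
})

test_that("radial-bin frequencies converge to their probabilities", {
  cfg <- cohort_config(n_patients = 50000, seed = 9)
  coh <- generate_cohort(cfg)
  obs <- tabulate(coh$patients$radial_bin, 4) / 50000
  expect_lt(max(abs(obs - cfg$radial_bin_probs)), 0.01)
  ct <- suppressWarnings(stats::chisq.test(tabulate(coh$patients$radial_bin, 4),
                                           p = cfg$radial_bin_probs))
  expect_gt(ct$p.value, 0.001)
  expect_lt(abs(mean(coh$patients$n_epe > 1) - cfg$multifocal_prob), 0.01)
})

test_that("the generator respects the proportional-hazards structure", {
  d <- simulate_group_survival(20000, c(a = 0.5, b = 0.5),
                               c(a = 0, b = 0.9), seed = 5)
  fit <- fit_cox(survival::Surv(time, event) ~ group, d)
  expect_lt(abs(fit$coefficients[["groupb"]] - 0.9), 0.05)
})

test_that("null effects give uniform log-rank p-values across groups", {
  cfg <- cohort_config(
    n_patients = 465,
    group_log_hr = setNames(rep(0, 7),
                            c("r1_n1", "r2_n1", "r3_n1", "r1_n2",
                              "r2_n2", "r3_n2", "r4")),
    seed = 1)
  pvals <- vapply(1:200, function(i) {
    coh <- generate_cohort(cfg, seed = 2000 + i)
    st <- stage_cohort(coh$patients)
    km_estimate(st$time, st$bcr_event, st$substage)$logrank_p
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})
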