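test_that("pT stage assignment follows EPE and SVI flags", {
  expect_identical(assign_pt_stage(TRUE, FALSE), "pT3a")
  expect_identical(assign_pt_stage(TRUE, TRUE), "pT3b")
  expect_identical(assign_pt_stage(FALSE, TRUE), "pT3b")
  expect_identical(assign_pt_stage(FALSE, FALSE), "pT2")
})

test_that("combined bins use right-closed boundaries and a merged top bin", {
  b <- assign_combined_bin(c(0.75, 3.0, 6.1, 0.76, 2.0, 5.0, 5.01),
                           c(1, 2, 1, 1, 2, 1, 2))
  expect_identical(b$radial_bin, c(1L, 3L, 4L, 2L, 2L, 3L, 4L))
  expect_identical(b$number_bin, c(1L, 2L, NA, 1L, 2L, 1L, NA))
  expect_identical(as.character(b$group),
                   c("r1_n1", "r3_n2", "r4", "r2_n1", "r2_n2", "r3_n1", "r4"))
  expect_error(assign_combined_bin(1.0, 0), "domain error")
  expect_error(assign_combined_bin(0, 1), "domain error")
})

test_that("substage tiers follow the radial-distance and focus-number rules", {
  expect_identical(as.character(assign_substage(0.5, 3)), "pT3a1")
  expect_identical(as.character(assign_substage(0.75, 9)), "pT3a1")
  expect_identical(as.character(assign_substage(1.5, 1)), "pT3a2")
  expect_identical(as.character(assign_substage(1.5, 2)), "pT3a3")
  expect_identical(as.character(assign_substage(2.0, 1)), "pT3a2")
  expect_identical(as.character(assign_substage(2.01, 1)), "pT3a3")
  expect_identical(as.character(assign_substage(7, 1)), "pT3a3")
  expect_error(assign_substage(-1, 1), "domain error")
  expect_error(assign_substage(1, 0), "domain error")
})

test_that("the classifier is total, monotone and consistent with the bins", {
  r_grid <- c(0.01, 0.5, 0.74, 0.75, 0.76, 1, 1.99, 2, 2.01, 3, 4.99, 5,
              5.01, 8, 20)
  n_grid <- 1:4
  grid <- expand.grid(r = r_grid, n = n_grid)
  sub <- assign_substage(grid$r, grid$n)
  bin <- assign_combined_bin(grid$r, grid$n)
  expect_false(anyNA(sub))                       # totality on the grid
  expect_false(anyNA(bin$group))
  expect_identical(assign_substage(grid$r, grid$n), sub)  # deterministic
  # substage recoverable from the combined bin alone
  expect_identical(as.character(substage_from_group(bin$group)),
                   as.character(sub))
  # monotone in r for fixed n, and in n for fixed r
  for (n in n_grid) {
    s <- as.integer(assign_substage(sort(r_grid), rep(n, length(r_grid))))
    expect_true(all(diff(s) >= 0))
  }
  for (r in r_grid) {
    s <- as.integer(assign_substage(rep(r, length(n_grid)), n_grid))
    expect_true(all(diff(s) >= 0))
  }
  # randomized totality
  set.seed(13)
  rr <- rexp(500, 0.5) + 1e-6
  nn <- sample(1:9, 500, replace = TRUE)
  expect_false(anyNA(assign_substage(rr, nn)))
  expect_identical(as.character(substage_from_group(
    assign_combined_bin(rr, nn)$group)),
    as.character(assign_substage(rr, nn)))
})

test_that("CM-combined groups merge the two indistinguishable subgroups", {
  g1 <- assign_cm_group("pT3a", "pT3a1", TRUE)
  expect_identical(as.character(g1$cm_group), "pT3a1+")
  expect_identical(as.character(g1$cm_merged_group), "level2")
  g2 <- assign_cm_group("pT3a", "pT3a3", FALSE)
  expect_identical(as.character(g2$cm_group), "pT3a2/3-")
  expect_identical(as.character(g2$cm_merged_group), "level2")
  g3 <- assign_cm_group("pT2", NA, FALSE)
  expect_identical(as.character(g3$cm_group), "pT2-")
  expect_identical(as.character(g3$cm_merged_group), "pT2-")
  # level 2 exactly when cm_group is pT3a1+ or pT3a2/3-
  all6 <- assign_cm_group(rep(c("pT2", "pT3a", "pT3a"), each = 2),
                          c(NA, NA, "pT3a1", "pT3a1", "pT3a2", "pT3a3"),
                          rep(c(FALSE, TRUE), 3))
  is2 <- all6$cm_merged_group == "level2"
  expect_identical(is2, all6$cm_group %in% c("pT3a1+", "pT3a2/3-"))
  expect_error(assign_cm_group("pT3a", "pT3a1", NA), "missing")
  expect_error(assign_cm_group("pT3a", NA, TRUE), "substage required")
})

test_that("stage_cohort validates and augments a patient table", {
  expect_error(stage_cohort(data.frame(radial_mm = 1)), "n_epe")
  df <- data.frame(radial_mm = c(0.4, 1.1, 3), n_epe = c(1, 3, 1),
                   cm = c(0, 1, 1))
  st <- stage_cohort(df)
  expect_identical(st$pt_stage, rep("pT3a", 3))
  expect_identical(as.character(st$substage), c("pT3a1", "pT3a3", "pT3a3"))
  expect_identical(as.character(st$cm_merged_group),
                   c("level1", "level3", "level3"))
  # pT2 passes through with an undefined substage
  df2 <- data.frame(radial_mm = 1, n_epe = 1, has_epe = FALSE,
                    has_svi = FALSE, cm = 0)
  st2 <- stage_cohort(df2)
  expect_identical(st2$pt_stage, "pT2")
  expect_true(is.na(st2$substage))
  expect_identical(as.character(st2$cm_group), "pT2-")
})
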